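#' @title Lexical diversity and demographic fidelity metrics
#' @description Distinct-1 (unique-unigram fraction), the Duplicate Ratio
#'   redundancy measure, per-role transcript diversity, chi-square
#'   goodness-of-fit of cohort counts against configured expectations, and a
#'   one-sided z-test for the pooled parental proportion.
#' @name metrics
NULL

#' Tokenize text into lowercase unigrams
#'
#' Documented rule: lowercase, strip punctuation except apostrophes internal
#' to a token, split on whitespace. Published Distinct-1 values depend on the
#' (unstated) tokenizer of the original analysis, so cross-study comparisons
#' carry a tolerance of about +/-0.03.
#'
#' @param text character scalar.
#' @return character vector of tokens (possibly empty).
#' @export
tokenize <- function(text) {
  if (length(text) == 0L || is.na(text) || !nzchar(text)) return(character(0))
  s <- tolower(text)
  s <- gsub("[^a-z0-9' ]+", " ", gsub("[[:space:]]+", " ", s))
  toks <- strsplit(trimws(s), " +")[[1L]]
  toks <- gsub("^'+|'+$", "", toks)   # apostrophes survive only mid-token
  toks[nzchar(toks)]
}

#' Distinct-1 lexical diversity
#'
#' The fraction of unique unigrams among all unigrams: 1 means every token is
#' unique, values near 0 mean heavy repetition.
#'
#' @param tokens character vector of tokens (see [tokenize()]).
#' @return list with `distinct1`, `n_tokens`, `n_unique`.
#' @export
distinct1 <- function(tokens) {
  n <- length(tokens)
  if (n == 0L) {
    stop("distinct1 is undefined for an empty token sequence", call. = FALSE)
  }
  u <- length(unique(tokens))
  list(distinct1 = u / n, n_tokens = n, n_unique = u)
}

#' Duplicate Ratio of a collection of text segments
#'
#' `n_dup` counts segments whose exact text occurs at least twice in the
#' collection; the ratio is `n_dup / n_tot`. Under the default `"all"`
#' counting rule every occurrence of a repeated value counts (four identical
#' segments give ratio 1); `"excess"` counts only occurrences beyond the
#' first of each value.
#'
#' @param segments character vector of generated segments.
#' @param rule counting rule, `"all"` (default) or `"excess"`.
#' @return list with `n_dup`, `n_tot`, `ratio`.
#' @export
duplicate_ratio <- function(segments, rule = c("all", "excess")) {
  rule <- match.arg(rule)
  n_tot <- length(segments)
  if (n_tot == 0L) {
    stop("duplicate_ratio is undefined for an empty segment list",
         call. = FALSE)
  }
  counts <- table(segments)
  n_dup <- switch(rule,
    all = sum(counts[counts >= 2L]),
    excess = sum(counts[counts >= 2L] - 1L))
  list(n_dup = as.integer(n_dup), n_tot = n_tot, ratio = n_dup / n_tot)
}

#' Per-role Distinct-1 of one interview transcript
#'
#' Concatenates each role's `RESPONSE:` payloads (the stop turn excluded),
#' tokenizes, and scores. A role with no turns is flagged missing rather than
#' raising an error.
#'
#' @param result an `interview_result`.
#' @return list with `patient` and `interviewer` entries (each a [distinct1()]
#'   score, or `NULL` with a `missing` flag naming absent roles).
#' @export
transcript_diversity <- function(result) {
  score_role <- function(role) {
    texts <- vapply(
      Filter(function(t) t$speaker == role && !t$is_stop, result$turns),
      `[[`, character(1), "text")
    if (length(texts) == 0L) return(NULL)
    toks <- tokenize(paste(texts, collapse = " "))
    if (length(toks) == 0L) return(NULL)
    distinct1(toks)
  }
  out <- list(patient = score_role("patient"),
              interviewer = score_role("interviewer"))
  out$missing <- names(out)[vapply(out, is.null, logical(1))]
  out
}

#' Chi-square upper-tail probability
#' @param chi2 test statistic.
#' @param df degrees of freedom.
#' @return upper-tail p-value.
#' @export
chisq_upper_p <- function(chi2, df) {
  stats::pchisq(chi2, df = df, lower.tail = FALSE)
}

#' Chi-square goodness-of-fit test of counts against a categorical distribution
#'
#' `chi2 = sum((O - E)^2 / E)` with `E = prob * n`, `df = k - 1`, and the
#' upper-tail p-value. Expected counts below 5 set a warning flag
#' (`low_expected`); an expected count of exactly 0 with nonzero observed is
#' an error.
#'
#' @param observed named or unnamed integer counts per category.
#' @param expected a [categorical_dist()] (or numeric probability vector) in
#'   the same category order.
#' @return list with `chi2`, `df`, `p`, `n`, `low_expected`.
#' @export
chi2_gof <- function(observed, expected) {
  probs <- if (inherits(expected, "categorical_dist")) expected$probs
           else as.numeric(expected)
  observed <- as.numeric(observed)
  if (length(observed) != length(probs)) {
    stop("chi2_gof: observed and expected category counts differ",
         call. = FALSE)
  }
  n <- sum(observed)
  if (n < 1) stop("chi2_gof: needs at least one observation", call. = FALSE)
  e <- probs * n
  if (any(e == 0 & observed > 0)) {
    stop("chi2_gof: expected count 0 with nonzero observed count",
         call. = FALSE)
  }
  keep <- e > 0
  chi2 <- sum((observed[keep] - e[keep])^2 / e[keep])
  df <- length(observed) - 1L
  list(chi2 = chi2, df = df, p = chisq_upper_p(chi2, df), n = n,
       low_expected = any(e < 5))
}

#' One-sided (lower-tail) standard normal p-value
#' @param z z-score.
#' @return `P(Z <= z)` under the standard normal.
#' @export
one_sided_z_p <- function(z) {
  stats::pnorm(z)
}

count_in_order <- function(values, labels) {
  vapply(labels, function(l) sum(values == l), numeric(1))
}

#' Demographic fidelity report for a synthetic cohort
#'
#' Goodness-of-fit rows for ethnicity, age group and disability type (the
#' latter among patients with a disability, against the configured type
#' shares), relationship-by-age and parental-by-age heatmap tables with the
#' configured expectations, a pooled relationship GOF (expected probabilities
#' mixed over the cohort's observed age-sex cells; df = categories - 1), and
#' a one-sided z-test of the pooled parental proportion against its
#' cell-weighted expectation. No multiple-testing correction is applied across
#' rows.
#'
#' @param cohort list of `patient_profile`s (or demographic bundles).
#' @param cfg the `population_config` the cohort was sampled from.
#' @return an object of class `fidelity_report`.
#' @export
cohort_fidelity <- function(cohort, cfg) {
  if (length(cohort) == 0L) {
    stop("cohort_fidelity: empty cohort", call. = FALSE)
  }
  get_dem <- function(p, f) {
    if (!is.null(p$demographics)) p$demographics[[f]] else p[[f]]
  }
  eth <- vapply(cohort, get_dem, character(1), f = "ethnicity")
  age <- vapply(cohort, get_dem, character(1), f = "age_bracket")
  sex <- vapply(cohort, get_dem, character(1), f = "sex")
  rel <- vapply(cohort, get_dem, character(1), f = "relationship_status")
  child <- vapply(cohort, function(p) isTRUE(get_dem(p, "has_children")),
                  logical(1))
  dis <- unlist(lapply(cohort, function(p) {
    if (!is.null(p$disabilities)) p$disabilities else p$disability
  }))

  check_known <- function(vals, labels, what) {
    bad <- setdiff(unique(vals), labels)
    if (length(bad) > 0L) {
      stop(sprintf("consistency error: %s value(s) %s absent from the configuration",
                   what, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  check_known(eth, cfg$ethnicity$labels, "ethnicity")
  check_known(age, cfg$age_groups$labels, "age group")
  check_known(dis, cfg$disability_type_shares$labels, "disability type")
  check_known(rel, cfg$relationship_by_age_sex$categories,
              "relationship status")

  gof <- list(
    ethnicity = chi2_gof(count_in_order(eth, cfg$ethnicity$labels),
                         cfg$ethnicity),
    age_group = chi2_gof(count_in_order(age, cfg$age_groups$labels),
                         cfg$age_groups)
  )
  gof$disability_type <- if (length(dis) > 0L) {
    chi2_gof(count_in_order(dis, cfg$disability_type_shares$labels),
             cfg$disability_type_shares)
  } else {
    NULL
  }

  # cell mixture weights from the cohort's observed (bracket, sex) counts
  keys <- cell_key(age, sex)
  key_counts <- table(keys)
  n <- length(cohort)

  rel_cats <- cfg$relationship_by_age_sex$categories
  exp_rel <- rep(0, length(rel_cats))
  for (k in names(key_counts)) {
    exp_rel <- exp_rel + (key_counts[[k]] / n) *
      cfg$relationship_by_age_sex$rows[[k]]$probs
  }
  gof$relationship <- chi2_gof(count_in_order(rel, rel_cats), exp_rel)

  p_exp <- sum(vapply(names(key_counts), function(k) {
    (key_counts[[k]] / n) * cfg$parental_by_age_sex[[k]]
  }, numeric(1)))
  p_obs <- mean(child)
  z <- if (p_exp > 0 && p_exp < 1) {
    (p_obs - p_exp) / sqrt(p_exp * (1 - p_exp) / n)
  } else {
    0
  }
  parental <- list(p_observed = p_obs, p_expected = p_exp, z = z,
                   p = one_sided_z_p(z), n = n)

  # heatmap tables: observed vs expected proportions per age bracket
  brackets <- cfg$age_groups$labels
  rel_tab <- do.call(rbind, lapply(brackets, function(b) {
    in_b <- age == b
    obs <- if (any(in_b)) count_in_order(rel[in_b], rel_cats) / sum(in_b)
           else rep(NA_real_, length(rel_cats))
    exp_b <- rep(0, length(rel_cats))
    tot_b <- 0
    for (s in cfg$sex$labels) {
      k <- cell_key(b, s)
      w <- if (k %in% names(key_counts)) key_counts[[k]] else 0
      exp_b <- exp_b + w * cfg$relationship_by_age_sex$rows[[k]]$probs
      tot_b <- tot_b + w
    }
    if (tot_b > 0) exp_b <- exp_b / tot_b
    data.frame(age_bracket = b, category = rel_cats, observed = obs,
               expected = exp_b, stringsAsFactors = FALSE)
  }))
  par_tab <- do.call(rbind, lapply(brackets, function(b) {
    in_b <- age == b
    exp_b <- 0; tot_b <- 0
    for (s in cfg$sex$labels) {
      k <- cell_key(b, s)
      w <- if (k %in% names(key_counts)) key_counts[[k]] else 0
      exp_b <- exp_b + w * cfg$parental_by_age_sex[[k]]
      tot_b <- tot_b + w
    }
    data.frame(age_bracket = b,
               observed = if (any(in_b)) mean(child[in_b]) else NA_real_,
               expected = if (tot_b > 0) exp_b / tot_b else NA_real_,
               stringsAsFactors = FALSE)
  }))

  structure(list(n = n, gof = gof, parental = parental,
                 relationship_by_age = rel_tab, parental_by_age = par_tab),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("<fidelity_report> cohort n = ", x$n, "\n", sep = "")
  for (nm in names(x$gof)) {
    g <- x$gof[[nm]]
    if (is.null(g)) next
    cat(sprintf("  %-16s chi2 = %6.2f, df = %d, p = %.4f%s\n", nm, g$chi2,
                g$df, g$p, if (g$low_expected) " [low expected counts]" else ""))
  }
  cat(sprintf("  parental         z = %.4f, p = %.4f (obs %.3f vs exp %.3f)\n",
              x$parental$z, x$parental$p, x$parental$p_observed,
              x$parental$p_expected))
  invisible(x)
}

#' Serialize a fidelity report to JSON
#' @param report a `fidelity_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fidelity_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Median per-role Distinct-1 over a directory of transcript JSON files
#'
#' Scores every `*.json` transcript in `dir` with [transcript_diversity()] and
#' returns the per-role medians (stats convention: `stats::median`), both over
#' all stop-compliant sessions and over inliers (sessions that are neither
#' full nor soft failures).
#'
#' @param dir directory of transcript JSON exports.
#' @return list with `all` and `inliers`, each `{patient, interviewer, n}`.
#' @export
transcript_dir_diversity <- function(dir) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0L) {
    stop(sprintf("no transcript JSON files in %s", dir), call. = FALSE)
  }
  results <- lapply(files, read_transcript)
  med <- function(rs) {
    if (length(rs) == 0L) return(list(patient = NA_real_,
                                      interviewer = NA_real_, n = 0L))
    scores <- lapply(rs, transcript_diversity)
    pull <- function(role) {
      v <- vapply(scores, function(s) {
        if (is.null(s[[role]])) NA_real_ else s[[role]]$distinct1
      }, numeric(1))
      stats::median(v, na.rm = TRUE)
    }
    list(patient = pull("patient"), interviewer = pull("interviewer"),
         n = length(rs))
  }
  status <- vapply(results, `[[`, character(1), "status")
  list(all = med(results[status != "full_failure"]),
       inliers = med(results[status == "compliant"]))
}
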