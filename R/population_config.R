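#' @title Population-statistics configuration
#' @description Loading, validation and sampling of the census-style tables
#'   that ground patient generation: marginal categorical distributions
#'   (ethnicity, age group, sex, disability type shares, name-locale weights),
#'   age-by-sex conditional tables (relationship status, parental status,
#'   disability prevalence) and the attribute catalog (psychiatric conditions
#'   with medications, unconstrained lists, comorbidity weights).
#' @name population_config
NULL

#' Construct a categorical distribution
#'
#' @param labels character vector of unique, non-empty category names.
#' @param probs numeric vector of fractions (0-1), same length as `labels`,
#'   summing to 1 within `1e-9` unless `normalize = TRUE`.
#' @param normalize if `TRUE`, `probs` are rescaled to sum to exactly 1
#'   (census-derived percentages rarely sum exactly).
#' @param name distribution name used in error messages.
#' @return an object of class `categorical_dist` with elements `labels`,
#'   `probs`.
#' @export
categorical_dist <- function(labels, probs, normalize = FALSE,
                             name = "categorical_dist") {
  labels <- as.character(labels)
  probs <- as.numeric(probs)
  if (length(labels) == 0L) {
    stop(sprintf("%s: no categories given", name), call. = FALSE)
  }
  if (length(labels) != length(probs)) {
    stop(sprintf("%s: %d labels but %d probabilities",
                 name, length(labels), length(probs)), call. = FALSE)
  }
  if (anyDuplicated(labels) || any(!nzchar(labels))) {
    stop(sprintf("%s: labels must be unique and non-empty", name),
         call. = FALSE)
  }
  if (any(!is.finite(probs)) || any(probs < 0)) {
    stop(sprintf("%s: probabilities must be finite and >= 0", name),
         call. = FALSE)
  }
  s <- sum(probs)
  if (isTRUE(normalize)) {
    if (s <= 0) {
      stop(sprintf("%s: cannot normalize, probabilities sum to 0", name),
           call. = FALSE)
    }
    probs <- probs / s
  } else if (abs(s - 1) > 1e-9) {
    stop(sprintf("normalization error in \"%s\": probabilities sum to %.10g, not 1",
                 name, s), call. = FALSE)
  }
  structure(list(labels = labels, probs = probs), class = "categorical_dist")
}

#' @export
print.categorical_dist <- function(x, ...) {
  cat("<categorical_dist> ", length(x$labels), " categories\n", sep = "")
  print(stats::setNames(round(x$probs, 4), x$labels))
  invisible(x)
}

#' Key for an (age bracket, sex) cell
#' @param bracket age bracket label, e.g. `"25-34"`.
#' @param sex sex label.
#' @return character key used in conditional tables.
#' @export
cell_key <- function(bracket, sex) paste(bracket, sex, sep = "|")

#' Construct an age-by-sex conditional table of categorical distributions
#'
#' @param categories category labels shared by every row.
#' @param rows named list: `cell_key(bracket, sex)` -> numeric probability
#'   vector over `categories`.
#' @param brackets,sexes the full grids the table must cover.
#' @param normalize passed to each row's [categorical_dist()].
#' @param name table name used in error messages.
#' @return object of class `conditional_table` with `categories` and `rows`
#'   (named list of `categorical_dist`).
#' @export
conditional_table <- function(categories, rows, brackets, sexes,
                              normalize = FALSE, name = "conditional_table") {
  needed <- as.vector(outer(brackets, sexes, cell_key))
  missing_keys <- setdiff(needed, names(rows))
  if (length(missing_keys) > 0L) {
    stop(sprintf("consistency error in \"%s\": missing row(s) %s",
                 name, paste(missing_keys, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(rows), needed)
  if (length(extra) > 0L) {
    stop(sprintf("consistency error in \"%s\": unknown row key(s) %s",
                 name, paste(extra, collapse = ", ")), call. = FALSE)
  }
  dists <- lapply(needed, function(k) {
    p <- as.numeric(rows[[k]])
    if (length(p) != length(categories)) {
      stop(sprintf(
        "consistency error in \"%s\" row %s: %d probabilities for %d categories",
        name, k, length(p), length(categories)), call. = FALSE)
    }
    categorical_dist(categories, p, normalize = normalize,
                     name = sprintf("%s[%s]", name, k))
  })
  names(dists) <- needed
  structure(list(categories = categories, rows = dists),
            class = "conditional_table")
}

#' Look up the conditional distribution for an (age bracket, sex) cell
#' @param tab a `conditional_table`.
#' @param bracket,sex cell coordinates.
#' @return a `categorical_dist`.
#' @export
conditional_row <- function(tab, bracket, sex) {
  k <- cell_key(bracket, sex)
  d <- tab$rows[[k]]
  if (is.null(d)) {
    stop(sprintf("no conditional row for cell %s", k), call. = FALSE)
  }
  d
}

validate_catalog <- function(cat) {
  if (length(cat$condition_to_meds) == 0L) {
    stop("catalog: condition_to_meds is empty", call. = FALSE)
  }
  for (cond in names(cat$condition_to_meds)) {
    meds <- cat$condition_to_meds[[cond]]
    if (length(meds) == 0L || any(!nzchar(meds))) {
      stop(sprintf("catalog: medication list for \"%s\" is empty", cond),
           call. = FALSE)
    }
  }
  cm <- cat$comorbidity
  if (is.null(cm$prob_any) || cm$prob_any < 0 || cm$prob_any > 1) {
    stop("catalog: comorbidity prob_any must be in [0, 1]", call. = FALSE)
  }
  w <- cm$count_weights
  if (!identical(sort(names(w)), c("1", "2", "3"))) {
    stop("catalog: comorbidity count_weights must be keyed 1, 2, 3",
         call. = FALSE)
  }
  if (abs(sum(unlist(w)) - 1) > 1e-9) {
    stop("normalization error in \"comorbidity count_weights\": weights do not sum to 1",
         call. = FALSE)
  }
  invisible(cat)
}

#' Load and validate a population-statistics configuration
#'
#' Reads the JSON schema documented in
#' `system.file("extdata", "population_config.json", package = "synthintake")`:
#' marginal distributions as `{labels, probs, normalize?}` objects, conditional
#' tables as `{categories, rows}` with rows keyed `"bracket|sex"`, per-cell
#' probability maps for parental status and disability prevalence, and the
#' attribute catalog. Every (bracket, sex) cell of every conditional structure
#' must be present; validation failures name the offending field and row key.
#'
#' @param path path to a population-configuration JSON file.
#' @return an object of class `population_config`.
#' @export
load_population_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("population config not found: %s", path), call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_population_config(raw)
}

#' Validate a population configuration given as a plain list
#' @param raw a list following the population-config JSON schema.
#' @return an object of class `population_config`.
#' @export
as_population_config <- function(raw) {
  req <- c("reference_date", "age_groups", "sex", "ethnicity",
           "relationship_by_age_sex", "parental_by_age_sex",
           "disability_any_by_age_sex", "disability_type_shares",
           "name_locale_weights", "catalog")
  missing_f <- setdiff(req, names(raw))
  if (length(missing_f) > 0L) {
    stop(sprintf("schema error: missing required table(s) %s",
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  }

  dist_from <- function(x, name) {
    categorical_dist(unlist(x$labels), unlist(x$probs),
                     normalize = isTRUE(x$normalize), name = name)
  }

  age_groups <- dist_from(raw$age_groups, "age_groups")
  bounds <- do.call(rbind, lapply(raw$age_groups$bounds, function(b) {
    as.integer(unlist(b))
  }))
  if (is.null(bounds) || nrow(bounds) != length(age_groups$labels) ||
      ncol(bounds) != 2L) {
    stop("schema error: age_groups$bounds must give [lo, hi] per bracket",
         call. = FALSE)
  }
  if (any(bounds[, 1] > bounds[, 2])) {
    stop("age_groups: bracket lower bound exceeds upper bound", call. = FALSE)
  }
  if (nrow(bounds) > 1L) {
    gaps <- bounds[-1L, 1L] - bounds[-nrow(bounds), 2L]
    if (any(gaps != 1L)) {
      stop("age_groups: bracket bounds must be ordered, disjoint and contiguous",
           call. = FALSE)
    }
  }

  sex <- dist_from(raw$sex, "sex")
  ethnicity <- dist_from(raw$ethnicity, "ethnicity")
  dts <- dist_from(raw$disability_type_shares, "disability_type_shares")
  nlw <- dist_from(raw$name_locale_weights, "name_locale_weights")

  brackets <- age_groups$labels
  sexes <- sex$labels

  rel <- conditional_table(
    categories = unlist(raw$relationship_by_age_sex$categories),
    rows = lapply(raw$relationship_by_age_sex$rows, unlist),
    brackets = brackets, sexes = sexes,
    normalize = isTRUE(raw$relationship_by_age_sex$normalize),
    name = "relationship_by_age_sex")

  check_cell_map <- function(m, name) {
    needed <- as.vector(outer(brackets, sexes, cell_key))
    missing_keys <- setdiff(needed, names(m))
    if (length(missing_keys) > 0L) {
      stop(sprintf("consistency error in \"%s\": missing cell(s) %s",
                   name, paste(missing_keys, collapse = ", ")), call. = FALSE)
    }
    v <- vapply(m[needed], function(x) as.numeric(x), numeric(1))
    if (any(!is.finite(v)) || any(v < 0 | v > 1)) {
      stop(sprintf("%s: probabilities must be in [0, 1]", name), call. = FALSE)
    }
    as.list(v)
  }
  parental <- check_cell_map(raw$parental_by_age_sex, "parental_by_age_sex")
  dis_any <- check_cell_map(raw$disability_any_by_age_sex,
                            "disability_any_by_age_sex")

  cat_raw <- raw$catalog
  catalog <- list(
    condition_to_meds = lapply(cat_raw$condition_to_meds,
                               function(x) as.character(unlist(x))),
    unconstrained_lists = lapply(cat_raw$unconstrained_lists,
                                 function(x) as.character(unlist(x))),
    comorbidity = list(
      prob_any = as.numeric(cat_raw$comorbidity$prob_any),
      count_weights = lapply(cat_raw$comorbidity$count_weights, as.numeric)
    )
  )
  validate_catalog(catalog)

  structure(list(
    reference_date = as.Date(unlist(raw$reference_date)),
    age_groups = age_groups,
    age_bounds = bounds,
    sex = sex,
    ethnicity = ethnicity,
    relationship_by_age_sex = rel,
    parental_by_age_sex = parental,
    disability_any_by_age_sex = dis_any,
    disability_type_shares = dts,
    name_locale_weights = nlw,
    catalog = catalog
  ), class = "population_config")
}

#' Serialize a population configuration back to its JSON schema
#' @param cfg a `population_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_population_config <- function(cfg, path) {
  dist_out <- function(d) list(labels = d$labels, probs = d$probs)
  out <- list(
    reference_date = format(cfg$reference_date),
    age_groups = c(dist_out(cfg$age_groups),
                   list(bounds = lapply(seq_len(nrow(cfg$age_bounds)),
                                        function(i) cfg$age_bounds[i, ]))),
    sex = dist_out(cfg$sex),
    ethnicity = dist_out(cfg$ethnicity),
    relationship_by_age_sex = list(
      categories = cfg$relationship_by_age_sex$categories,
      rows = lapply(cfg$relationship_by_age_sex$rows, function(d) d$probs)
    ),
    parental_by_age_sex = cfg$parental_by_age_sex,
    disability_any_by_age_sex = cfg$disability_any_by_age_sex,
    disability_type_shares = dist_out(cfg$disability_type_shares),
    name_locale_weights = dist_out(cfg$name_locale_weights),
    catalog = cfg$catalog
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Draw one label from a categorical distribution
#'
#' Inverse-CDF draw using a single uniform from the given stream, so repeated
#' calls with the same seed yield the identical label sequence.
#'
#' @param dist a [categorical_dist()].
#' @param rng an [rng_stream()].
#' @return one label.
#' @export
sample_categorical <- function(dist, rng) {
  stopifnot(inherits(dist, "categorical_dist"))
  u <- stream_runif(rng, 1L)
  pick_categorical(dist, u)
}

# Inverse-CDF pick from a pre-drawn uniform; shared by all samplers.
pick_categorical <- function(dist, u) {
  cs <- cumsum(dist$probs)
  idx <- findInterval(u, cs) + 1L
  dist$labels[min(idx, length(dist$labels))]
}

#' Path to the packaged population configuration fixture
#'
#' A synthetic but structurally faithful stand-in for regional census-style
#' tables (south-western British Columbia flavoured): 9 ethnicity categories,
#' 5 adult age groups, 2 sexes, 6 relationship-status categories by age and
#' sex, parental and disability prevalence by age and sex, and 10 disability
#' type shares. Values are documented placeholders, not scraped statistics.
#'
#' @return file path.
#' @export
default_population_config_path <- function() {
  system.file("extdata", "population_config.json", package = "synthintake",
              mustWork = TRUE)
}
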