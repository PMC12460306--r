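test_that("backend-driven template generation reproduces the canonical asset", {
  tpl <- generate_profile_template(fix_bank, mock_backend(seed = 0))
  expect_identical(tpl$fields, fix_template$fields)
  expect_setequal(unique(tpl$fields$section), bank_section_titles(fix_bank))
  expect_false(anyDuplicated(tpl$fields$field_id) > 0)
})

test_that("template coverage holds on a toy bank and empty banks error", {
  bank <- toy_bank("## Solo\n1. How do you sleep?\n2. What do you enjoy?")
  tpl <- generate_profile_template(bank, mock_backend(seed = 0))
  expect_gte(nrow(tpl$fields), 2L)
  expect_true(all(tpl$fields$section == "Solo"))
  empty <- structure(list(sections = list()), class = "question_bank")
  expect_error(generate_profile_template(empty, mock_backend()),
               "empty question bank")
})

test_that("zero-probability parental cells never produce children", {
  cfg <- tiny_cfg(function(raw) {
    raw$parental_by_age_sex <- lapply(raw$parental_by_age_sex, function(x) 0)
    raw
  })
  bundles <- lapply(1:200, function(i) {
    sample_demographics(cfg, rng_stream(derive_stream_seed(5, i)))
  })
  expect_false(any(vapply(bundles, `[[`, logical(1), "has_children")))
})

test_that("relationship frequencies match the conditional rows (binomial oracle)", {
  n <- 1500
  bundles <- lapply(seq_len(n), function(i) {
    sample_demographics(fix_cfg, rng_stream(derive_stream_seed(7, i)))
  })
  keys <- vapply(bundles, function(b) cell_key(b$age_bracket, b$sex),
                 character(1))
  rels <- vapply(bundles, `[[`, character(1), "relationship_status")
  for (k in unique(keys)) {
    idx <- keys == k
    nk <- sum(idx)
    if (nk < 50) next
    row <- fix_cfg$relationship_by_age_sex$rows[[k]]
    for (j in seq_along(row$labels)) {
      p <- row$probs[j]
      freq <- mean(rels[idx] == row$labels[j])
      expect_lt(abs(freq - p), max(3 * sqrt(p * (1 - p) / nk), 1e-12),
                label = sprintf("cell %s category %s", k, row$labels[j]))
    }
  }
})

test_that("patients are reproducible and order-independent", {
  b1 <- sample_demographics(fix_cfg, rng_stream(derive_stream_seed(42, 1)))
  b2 <- sample_demographics(fix_cfg, rng_stream(derive_stream_seed(42, 1)))
  expect_identical(b1, b2)

  solo <- generate_patient(fix_cfg, fix_template, mock_backend(seed = 1),
                           master_seed = 11, index = 3, enrich = FALSE)
  batch <- generate_cohort(fix_cfg, fix_template, mock_backend(seed = 1),
                           n = 5, master_seed = 11, enrich = FALSE)
  expect_identical(solo, batch[[3]])
})

test_that("disability assignment honours prevalence and shares", {
  cfg0 <- tiny_cfg(function(raw) {
    raw$disability_any_by_age_sex <- lapply(raw$disability_any_by_age_sex,
                                            function(x) 0)
    raw
  })
  rng <- rng_stream(3)
  b <- sample_demographics(cfg0, rng)
  expect_true(all(vapply(1:50, function(i) {
    length(assign_disability(b, cfg0, rng)) == 0L
  }, logical(1))))

  cfg1 <- tiny_cfg(function(raw) {
    raw$disability_any_by_age_sex <- lapply(raw$disability_any_by_age_sex,
                                            function(x) 1)
    raw$disability_type_shares <- list(labels = "Hearing", probs = 1.0)
    raw
  })
  expect_true(all(vapply(1:50, function(i) {
    identical(assign_disability(b, cfg1, rng), "Hearing")
  }, logical(1))))

  # product-probability oracle: P(type) = prevalence * share
  cfg2 <- tiny_cfg(function(raw) {
    raw$disability_any_by_age_sex <- lapply(raw$disability_any_by_age_sex,
                                            function(x) 0.3)
    raw
  })
  n <- 1e5
  rng2 <- rng_stream(13)
  hits <- vapply(seq_len(n), function(i) {
    d <- assign_disability(b, cfg2, rng2)
    length(d) == 1L && d == "Pain-related"
  }, logical(1))
  p <- 0.3 * 0.5
  expect_lt(abs(mean(hits) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("condition assignment follows the comorbidity weights (multinomial oracle)", {
  cat0 <- tiny_cfg(function(raw) {
    raw$catalog$comorbidity$prob_any <- 0
    raw
  })$catalog
  rng <- rng_stream(2)
  expect_true(all(vapply(1:50, function(i) {
    length(assign_conditions(cat0, rng)) == 0L
  }, logical(1))))

  cat1 <- tiny_cfg(function(raw) {
    raw$catalog$condition_to_meds <- list(
      "Major depressive disorder" = "Sertraline 50 mg daily")
    raw$catalog$comorbidity <- list(prob_any = 1,
                                    count_weights = list("1" = 1, "2" = 0,
                                                         "3" = 0))
    raw
  })$catalog
  out <- assign_conditions(cat1, rng)
  expect_identical(out, list(list(condition = "Major depressive disorder",
                                  medication = "Sertraline 50 mg daily")))

  cat2 <- tiny_cfg(function(raw) {
    raw$catalog$comorbidity <- list(prob_any = 1,
                                    count_weights = list("1" = 0.5, "2" = 0.3,
                                                         "3" = 0.2))
    raw
  })$catalog
  n <- 5e4
  rng2 <- rng_stream(17)
  draws <- lapply(seq_len(n), function(i) assign_conditions(cat2, rng2))
  counts <- vapply(draws, length, integer(1))
  for (k in 1:3) {
    p <- c(0.5, 0.3, 0.2)[k]
    expect_lt(abs(mean(counts == k) - p), 3 * sqrt(p * (1 - p) / n))
  }
  dup_free <- vapply(draws, function(d) {
    !anyDuplicated(vapply(d, `[[`, character(1), "condition"))
  }, logical(1))
  expect_true(all(dup_free))

  # demanding more conditions than the catalog holds is an error
  cat3 <- cat1
  cat3$comorbidity <- list(prob_any = 1,
                           count_weights = list("1" = 0, "2" = 0, "3" = 1))
  expect_error(assign_conditions(cat3, rng), "distinct conditions")
})

test_that("identity generation is locale-weighted and age-consistent", {
  cfg <- tiny_cfg(identity)
  rng <- rng_stream(19)
  b <- sample_demographics(cfg, rng)
  for (i in 1:20) {
    id <- assign_identity(b, cfg, fix_names, rng)
    expect_identical(id$name_locale, "english")
  }

  # date of birth implies the sampled exact age at the reference date
  for (i in 1:400) {
    rngi <- rng_stream(derive_stream_seed(23, i))
    bi <- sample_demographics(fix_cfg, rngi)
    idi <- assign_identity(bi, fix_cfg, fix_names, rngi)
    expect_identical(age_at(idi$date_of_birth, fix_cfg$reference_date), bi$age)
    bounds <- fix_cfg$age_bounds[match(bi$age_bracket,
                                       fix_cfg$age_groups$labels), ]
    expect_true(bi$age >= bounds[1] && bi$age <= bounds[2])
  }

  # locale frequencies match the weights (binomial oracle)
  cfg2 <- tiny_cfg(function(raw) {
    raw$name_locale_weights <- list(labels = c("english", "french"),
                                    probs = c(0.7, 0.3))
    raw
  })
  n <- 1e4
  rng3 <- rng_stream(29)
  locs <- vapply(seq_len(n), function(i) {
    assign_identity(b, cfg2, fix_names, rng3)$name_locale
  }, character(1))
  expect_lt(abs(mean(locs == "english") - 0.7), 3 * sqrt(0.7 * 0.3 / n))

  cfg3 <- tiny_cfg(function(raw) {
    raw$name_locale_weights <- list(labels = "klingon", probs = 1.0)
    raw
  })
  expect_error(assign_identity(b, cfg3, fix_names, rng),
               "locale \"klingon\" missing")
})

test_that("narrative enrichment fills every field deterministically", {
  p1 <- make_patient(master_seed = 31, index = 1)
  p2 <- make_patient(master_seed = 31, index = 1)
  expect_identical(p1, p2)
  narrative_ids <- fix_template$fields$field_id[
    fix_template$fields$kind == "narrative"]
  expect_setequal(names(p1$narrative), narrative_ids)
  expect_true(all(nzchar(trimws(unlist(p1$narrative)))))
  expect_true(all(unlist(p1$filled_by[narrative_ids]) == "backend"))

  # fixed fields are untouched by enrichment
  raw <- make_patient(master_seed = 31, index = 1, enrich = FALSE)
  expect_identical(raw$identity, p1$identity)
  expect_identical(raw$demographics, p1$demographics)
  expect_identical(raw$conditions, p1$conditions)

  # two patients identical except the name differ only where it interpolates
  alt <- raw
  alt$identity$name <- "Zofia Nowak"
  e1 <- enrich_narrative(raw, fix_template, mock_backend(seed = 1))
  e2 <- enrich_narrative(alt, fix_template, mock_backend(seed = 1))
  for (f in narrative_ids) {
    expect_identical(gsub("Zofia Nowak", raw$identity$name, e2$narrative[[f]],
                          fixed = TRUE),
                     e1$narrative[[f]])
  }
})

test_that("an empty backend completion is an enrichment error naming the field", {
  assign("chat.empty_backend", function(backend, messages, options) "",
         envir = globalenv())
  on.exit(rm("chat.empty_backend", envir = globalenv()), add = TRUE)
  be <- structure(list(id = "empty"), class = c("empty_backend", "chat_backend"))
  p <- make_patient(enrich = FALSE)
  expect_error(enrich_narrative(p, fix_template, be),
               "narrative enrichment.*field \"")
})

test_that("profile JSON-lines round-trip exactly and report bad lines", {
  cohort <- lapply(1:3, function(i) make_patient(master_seed = 37, index = i))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_profiles(cohort, path)
  expect_length(readLines(path), 3L)
  back <- read_profiles(path)
  expect_identical(back, cohort)

  write_profiles(list(), path)
  expect_identical(read_profiles(path), list())

  lines <- vapply(cohort, function(p) {
    as.character(jsonlite::toJSON(unclass(p), auto_unbox = TRUE, digits = NA))
  }, character(1))
  lines[2] <- substr(lines[2], 1, 40)
  writeLines(lines, path)
  expect_error(read_profiles(path), "line 2")
})

test_that("no generated profile violates its invariants (property)", {
  n <- 10000
  ok <- vapply(seq_len(n), function(i) {
    p <- generate_patient(fix_cfg, fix_template, mock_backend(seed = 1),
                          master_seed = 101, index = i, enrich = FALSE)
    validate_profile(p, fix_cfg)
  }, logical(1))
  expect_true(all(ok))
  ok_enriched <- vapply(seq_len(300), function(i) {
    p <- generate_patient(fix_cfg, fix_template, mock_backend(seed = 1),
                          master_seed = 103, index = i, enrich = TRUE)
    validate_profile(p, fix_cfg)
  }, logical(1))
  expect_true(all(ok_enriched))
})
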