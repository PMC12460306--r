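# Shared fixtures: the packaged configuration/bank plus small in-code
# configurations for targeted tests. Everything is built programmatically.

fix_cfg <- load_population_config(default_population_config_path())
fix_bank <- read_question_bank(default_question_bank_path())
fix_template <- canonical_profile_template()
fix_names <- default_name_table()

# A minimal raw config list (2 brackets x 2 sexes) that tests can perturb
# before handing it to as_population_config().
tiny_cfg_raw <- function() {
  brackets <- c("18-24", "25-34")
  sexes <- c("female", "male")
  keys <- as.vector(outer(brackets, sexes, cell_key))
  rel_rows <- stats::setNames(
    rep(list(c(0.5, 0.3, 0.2)), length(keys)), keys)
  list(
    reference_date = "2025-01-01",
    ethnicity = list(labels = c("E1", "E2"), probs = c(0.5, 0.5)),
    age_groups = list(labels = brackets, probs = c(0.4, 0.6),
                      bounds = list(c(18, 24), c(25, 34))),
    sex = list(labels = sexes, probs = c(0.5, 0.5)),
    relationship_by_age_sex = list(
      categories = c("Single", "Married", "Other"), rows = rel_rows),
    parental_by_age_sex = stats::setNames(as.list(rep(0.5, 4)), keys),
    disability_any_by_age_sex = stats::setNames(as.list(rep(0.25, 4)), keys),
    disability_type_shares = list(labels = c("Hearing", "Pain-related"),
                                  probs = c(0.5, 0.5)),
    name_locale_weights = list(labels = "english", probs = 1.0),
    catalog = list(
      condition_to_meds = list(
        "Major depressive disorder" = c("Sertraline 50 mg daily"),
        "Generalized anxiety disorder" = c("Escitalopram 10 mg daily"),
        "Panic disorder" = c("Sertraline 100 mg daily")
      ),
      unconstrained_lists = list(
        allergies = c("penicillin", "no known allergies"),
        supplements = c("none", "vitamin D"),
        recreational_drugs = c("none"),
        visit_reason = c("low mood and loss of interest")
      ),
      comorbidity = list(prob_any = 0.6,
                         count_weights = list("1" = 0.6, "2" = 0.3, "3" = 0.1))
    )
  )
}

tiny_cfg <- function(mutate = identity) {
  as_population_config(mutate(tiny_cfg_raw()))
}

toy_bank <- function(text = "## A\n1. q1\n2. q2\n## B\n1. q3") {
  parse_question_bank(text)
}

# A 2-section/6-point bank for interview-path tests; point texts are unique
# and never substrings of each other.
small_bank <- function() {
  parse_question_bank(paste(
    "## Opening",
    "1. How has your sleep been lately?",
    "2. How has your appetite changed recently?",
    "3. What does a typical week look like for you?",
    "## Closing",
    "1. How do you usually cope with stress?",
    "2. What supports do you have around you?",
    "3. Anything else you would like to add before we wrap up?",
    sep = "\n"))
}

# Demographics-only cohort (bundles), the sampler path used for calibration.
demo_cohort <- function(cfg, master_seed, n) {
  lapply(seq_len(n), function(i) {
    rng <- rng_stream(derive_stream_seed(master_seed, i))
    b <- sample_demographics(cfg, rng)
    b$disabilities <- assign_disability(b, cfg, rng)
    b
  })
}

make_patient <- function(master_seed = 42, index = 1, enrich = TRUE,
                         cfg = fix_cfg, template = fix_template,
                         backend = mock_backend(seed = 1)) {
  generate_patient(cfg, template, backend, master_seed, index, enrich = enrich)
}
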