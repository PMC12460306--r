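#' @title Synthetic patient profile generation
#' @description Builds complete synthetic psychiatric patients: a profile
#'   template derived from the question bank through the backend contract,
#'   demographic sampling from the population configuration, conditional
#'   attribute assignment (relationship, parental and disability status by age
#'   and sex; 0-3 comorbid psychiatric conditions with catalog medications),
#'   locale-weighted identity generation, and narrative enrichment of the
#'   free-text fields via the chat backend.
#' @name patient_generator
NULL

FIXED_FIELD_PATTERN <- paste0(
  "full name|date of birth|address|occupation|medication|allerg|supplement|",
  "recreational|relationship status|children|ethnic|brings you")

slugify <- function(s, max_words = 6L) {
  w <- strsplit(tolower(gsub("[^a-z0-9 ]", " ", tolower(s))),
                "[[:space:]]+")[[1L]]
  w <- w[nzchar(w)]
  paste(utils::head(w, max_words), collapse = "_")
}

# Deterministic field derivation rule shared by the scripted mock's
# template task: one field per question point, fixed when the point targets a
# sampler-owned attribute, narrative otherwise.
template_fields_from_bank <- function(bank) {
  out <- list()
  seen <- character()
  for (s in bank$sections) {
    for (p in s$points) {
      id <- slugify(p)
      while (id %in% seen) id <- paste0(id, "_2")
      seen <- c(seen, id)
      kind <- if (grepl(FIXED_FIELD_PATTERN, tolower(p))) "fixed" else "narrative"
      out[[length(out) + 1L]] <- list(field_id = id, section = s$title,
                                      kind = kind, prompt_hint = p)
    }
  }
  out
}

as_profile_template <- function(fields, bank = NULL) {
  df <- data.frame(
    field_id = vapply(fields, `[[`, character(1), "field_id"),
    section = vapply(fields, `[[`, character(1), "section"),
    kind = vapply(fields, `[[`, character(1), "kind"),
    prompt_hint = vapply(fields, `[[`, character(1), "prompt_hint"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(df$field_id)) {
    stop("profile template: field_ids must be unique", call. = FALSE)
  }
  if (!all(df$kind %in% c("fixed", "narrative"))) {
    stop("profile template: kind must be fixed or narrative", call. = FALSE)
  }
  if (!is.null(bank)) {
    missing_sec <- setdiff(bank_section_titles(bank), unique(df$section))
    if (length(missing_sec) > 0L) {
      stop(sprintf("template-coverage error: no field for section(s) %s",
                   paste(missing_sec, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(fields = df), class = "profile_template")
}

#' Generate a profile template from a question bank through the backend
#'
#' The backend is prompted with the full bank and must return a JSON array of
#' field specs `{field_id, section, kind, prompt_hint}` covering every bank
#' section. With the scripted mock this is deterministic and, on the packaged
#' bank, reproduces the packaged canonical template.
#'
#' @param bank a `question_bank`.
#' @param backend a chat backend.
#' @param options an [inference_options()].
#' @return an object of class `profile_template`.
#' @export
generate_profile_template <- function(bank, backend,
                                      options = inference_options()) {
  if (length(bank$sections) == 0L) {
    stop("cannot build a template from an empty question bank", call. = FALSE)
  }
  sys <- paste0(
    read_prompt_asset("template_prompt.txt"), "\n\n",
    "TASK: PROFILE_TEMPLATE\n",
    MOCK_MARKERS$bank_open, "\n", serialize_question_bank(bank), "\n",
    MOCK_MARKERS$bank_close)
  msgs <- list(chat_message("system", sys),
               chat_message("user", "Produce the profile template now."))
  completion <- chat(backend, msgs, options)
  fields <- tryCatch(
    jsonlite::fromJSON(completion, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("template generation: backend output is not valid JSON (%s)",
                   conditionMessage(e)), call. = FALSE)
    })
  as_profile_template(fields, bank = bank)
}

#' Read the packaged canonical profile template
#'
#' The reviewed template used by default for cohort generation; the
#' backend-driven template path is validated against it.
#'
#' @return a `profile_template`.
#' @export
canonical_profile_template <- function() {
  path <- system.file("extdata", "profile_template.json",
                      package = "synthintake", mustWork = TRUE)
  as_profile_template(jsonlite::read_json(path, simplifyVector = FALSE))
}

read_prompt_asset <- function(name) {
  path <- system.file("extdata", "prompts", name, package = "synthintake",
                      mustWork = TRUE)
  paste(readLines(path, encoding = "UTF-8"), collapse = "\n")
}

#' Sample the demographic bundle for one patient
#'
#' Draws ethnicity, age bracket plus an exact integer age uniform within the
#' bracket, sex, relationship status from the (bracket, sex) conditional row,
#' and parental status from the (bracket, sex) probability map.
#'
#' @param cfg a `population_config`.
#' @param rng an [rng_stream()].
#' @return a named list bundle.
#' @export
sample_demographics <- function(cfg, rng) {
  u <- stream_runif(rng, 6L)
  ethnicity <- pick_categorical(cfg$ethnicity, u[1L])
  bracket_i <- min(findInterval(u[2L], cumsum(cfg$age_groups$probs)) + 1L,
                   length(cfg$age_groups$labels))
  bracket <- cfg$age_groups$labels[bracket_i]
  lo <- cfg$age_bounds[bracket_i, 1L]
  hi <- cfg$age_bounds[bracket_i, 2L]
  age <- lo + min(as.integer(floor(u[3L] * (hi - lo + 1L))), hi - lo)
  sex <- pick_categorical(cfg$sex, u[4L])
  rel <- pick_categorical(
    conditional_row(cfg$relationship_by_age_sex, bracket, sex), u[5L])
  p_child <- cfg$parental_by_age_sex[[cell_key(bracket, sex)]]
  list(ethnicity = ethnicity, age_bracket = bracket, age = as.integer(age),
       sex = sex, relationship_status = rel,
       has_children = u[6L] < p_child)
}

#' Assign disability status and type
#'
#' With the (bracket, sex)-specific prevalence the patient receives exactly
#' one disability type drawn from the configured type shares; otherwise none.
#'
#' @param bundle a demographic bundle from [sample_demographics()].
#' @param cfg a `population_config`.
#' @param rng an [rng_stream()].
#' @return character vector of type labels (length 0 or 1).
#' @export
assign_disability <- function(bundle, cfg, rng) {
  u <- stream_runif(rng, 2L)
  prev <- cfg$disability_any_by_age_sex[[cell_key(bundle$age_bracket,
                                                  bundle$sex)]]
  if (u[1L] >= prev) return(character(0))
  pick_categorical(cfg$disability_type_shares, u[2L])
}

#' Assign 0-3 comorbid psychiatric conditions with medications
#'
#' With probability `prob_any` a condition count is drawn from the 1/2/3
#' weights; that many distinct conditions are sampled without replacement and
#' each is paired with one medication from its catalog list.
#'
#' @param catalog the attribute catalog from a `population_config`.
#' @param rng an [rng_stream()].
#' @return list of `{condition, medication}` pairs (possibly empty).
#' @export
assign_conditions <- function(catalog, rng) {
  cm <- catalog$comorbidity
  u <- stream_runif(rng, 2L)
  if (u[1L] >= cm$prob_any) return(list())
  w <- unlist(cm$count_weights[c("1", "2", "3")])
  count <- findInterval(u[2L], cumsum(w)) + 1L
  count <- min(count, 3L)
  conds <- names(catalog$condition_to_meds)
  if (count > length(conds)) {
    stop(sprintf("cannot draw %d distinct conditions from a catalog of %d",
                 count, length(conds)), call. = FALSE)
  }
  with_stream(rng, function() {
    chosen <- sample(conds, count)
    lapply(chosen, function(cn) {
      meds <- catalog$condition_to_meds[[cn]]
      list(condition = cn,
           medication = if (length(meds) == 1L) meds else sample(meds, 1L))
    })
  })
}

#' Load the packaged identity tables
#'
#' Synthetic locale-keyed name lists plus occupation and address components
#' standing in for an ethnicity-weighted name provider. All names are
#' fabricated.
#'
#' @return list with per-locale name tables, `occupations`, `streets`,
#'   `cities`.
#' @export
default_name_table <- function() {
  path <- system.file("extdata", "name_tables.json", package = "synthintake",
                      mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Calendar-safe year shift (Feb 29 maps to Feb 28).
add_years <- function(date, k) {
  p <- as.POSIXlt(date)
  p$year <- p$year + k
  out <- as.Date(p)
  if (is.na(out)) out <- as.Date(p) - 1L
  out
}

#' Age in completed years at a reference date
#' @param dob date of birth (`Date` or string).
#' @param ref reference date.
#' @return integer age.
#' @export
age_at <- function(dob, ref) {
  dob <- as.Date(dob); ref <- as.Date(ref)
  a <- as.POSIXlt(ref)$year - as.POSIXlt(dob)$year
  birthday <- add_years(dob, a)
  as.integer(a - (birthday > ref))
}

#' Assign identity fields: name, date of birth, address, occupation
#'
#' A name locale is drawn from the configured locale weights and the name from
#' that locale's table; the date of birth is uniform over the days consistent
#' with the bundle's exact age at the configuration's reference date.
#'
#' @param bundle a demographic bundle.
#' @param cfg a `population_config`.
#' @param name_table identity tables, see [default_name_table()].
#' @param rng an [rng_stream()].
#' @return list with `name`, `date_of_birth` (ISO string), `address`,
#'   `occupation`, `name_locale`.
#' @export
assign_identity <- function(bundle, cfg, name_table = default_name_table(),
                            rng) {
  locale <- sample_categorical(cfg$name_locale_weights, rng)
  tab <- name_table$locales[[locale]]
  if (is.null(tab)) {
    stop(sprintf("name locale \"%s\" missing from the name table", locale),
         call. = FALSE)
  }
  firsts <- tab$first_names[[bundle$sex]]
  if (is.null(firsts)) firsts <- unlist(tab$first_names, use.names = FALSE)
  u <- stream_runif(rng, 6L)
  pick <- function(v, uu) v[[min(length(v), floor(uu * length(v)) + 1L)]]
  name <- paste(pick(firsts, u[1L]), pick(tab$last_names, u[2L]))

  ref <- cfg$reference_date
  dob_end <- add_years(ref, -bundle$age)
  dob_start <- add_years(ref, -(bundle$age + 1L)) + 1L
  span <- as.integer(dob_end - dob_start) + 1L
  dob <- dob_start + min(span - 1L, as.integer(floor(u[3L] * span)))

  street_no <- 100L + as.integer(floor(u[4L] * 9000L))
  address <- paste0(street_no, " ", pick(name_table$streets, u[5L]), ", ",
                    pick(name_table$cities, u[6L]))
  occupation <- pick(name_table$occupations, stream_runif(rng, 1L))
  list(name = name, date_of_birth = format(dob), address = address,
       occupation = occupation, name_locale = locale)
}

# Canonicalize a profile list into the patient_profile class; shared by the
# generator and the JSON-lines reader so round-trips are exact.
as_patient_profile <- function(x) {
  prof <- list(
    id = as.character(x$id),
    seed_index = as.integer(x$seed_index),
    identity = list(
      name = as.character(x$identity$name),
      date_of_birth = as.character(x$identity$date_of_birth),
      address = as.character(x$identity$address),
      occupation = as.character(x$identity$occupation),
      name_locale = as.character(x$identity$name_locale)),
    demographics = list(
      age = as.integer(x$demographics$age),
      age_bracket = as.character(x$demographics$age_bracket),
      sex = as.character(x$demographics$sex),
      ethnicity = as.character(x$demographics$ethnicity),
      relationship_status = as.character(x$demographics$relationship_status),
      has_children = isTRUE(as.logical(x$demographics$has_children))),
    disabilities = as.character(unlist(x$disabilities)),
    conditions = lapply(x$conditions, function(cn) {
      list(condition = as.character(cn$condition),
           medication = as.character(cn$medication))
    }),
    attributes = lapply(x$attributes, as.character),
    narrative = lapply(x$narrative, as.character),
    filled_by = lapply(x$filled_by, as.character)
  )
  structure(prof, class = "patient_profile")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat("<patient_profile> ", x$id, ": ", x$identity$name, ", ",
      x$demographics$age, "y ", x$demographics$sex, ", ",
      x$demographics$ethnicity, "\n", sep = "")
  cat("  conditions: ",
      if (length(x$conditions) == 0L) "none" else
        paste(vapply(x$conditions, `[[`, character(1), "condition"),
              collapse = "; "), "\n", sep = "")
  cat("  narrative fields: ", length(x$narrative), "\n", sep = "")
  invisible(x)
}

#' Enrich a profile's narrative fields through the backend
#'
#' Every `kind = "narrative"` template field is filled with backend-generated
#' free text grounded in the fixed fields. Fixed fields are never modified.
#' With the scripted mock the text is a deterministic function of the field id
#' and the profile's fixed fields.
#'
#' @param profile a `patient_profile` with fixed fields assigned.
#' @param template a `profile_template`.
#' @param backend a chat backend.
#' @param options an [inference_options()].
#' @return the profile with all narrative fields non-empty.
#' @export
enrich_narrative <- function(profile, template, backend,
                             options = inference_options()) {
  base_prompt <- read_prompt_asset("narrative_prompt.txt")
  fields_block <- paste0(
    MOCK_MARKERS$fields_open, "\n",
    "name: ", profile$identity$name, "\n",
    "age: ", profile$demographics$age, "\n",
    "sex: ", profile$demographics$sex, "\n",
    "occupation: ", profile$identity$occupation, "\n",
    "ethnicity: ", profile$demographics$ethnicity, "\n",
    MOCK_MARKERS$fields_close)
  narr <- template$fields[template$fields$kind == "narrative", , drop = FALSE]
  for (i in seq_len(nrow(narr))) {
    fid <- narr$field_id[i]
    sys <- paste0(base_prompt, "\n\nTASK: NARRATIVE_FIELD field_id=", fid,
                  "\nTopic: ", narr$prompt_hint[i], "\n", fields_block)
    msgs <- list(chat_message("system", sys),
                 chat_message("user", "Write this profile field now."))
    text <- tryCatch(chat(backend, msgs, options), error = function(e) {
      stop(sprintf("narrative enrichment failed for field \"%s\": %s",
                   fid, conditionMessage(e)), call. = FALSE)
    })
    if (!nzchar(trimws(text))) {
      stop(sprintf("narrative enrichment returned empty text for field \"%s\"",
                   fid), call. = FALSE)
    }
    profile$narrative[[fid]] <- text
    profile$filled_by[[fid]] <- "backend"
  }
  as_patient_profile(profile)
}

#' Generate one synthetic patient
#'
#' Runs the full per-patient pipeline under a private RNG stream derived from
#' `(master_seed, index)`, so a patient is identical whether generated alone
#' or inside a batch.
#'
#' @param cfg a `population_config`.
#' @param template a `profile_template`.
#' @param backend a chat backend for narrative enrichment.
#' @param master_seed integer master seed of the cohort.
#' @param index 1-based patient index.
#' @param name_table identity tables, see [default_name_table()].
#' @param enrich if `FALSE`, skip narrative enrichment (demographics-only
#'   profiles for calibration studies).
#' @return a `patient_profile`.
#' @export
generate_patient <- function(cfg, template, backend, master_seed, index,
                             name_table = default_name_table(),
                             enrich = TRUE) {
  rng <- rng_stream(derive_stream_seed(master_seed, index))
  bundle <- sample_demographics(cfg, rng)
  disabilities <- assign_disability(bundle, cfg, rng)
  conditions <- assign_conditions(cfg$catalog, rng)
  identity <- assign_identity(bundle, cfg, name_table, rng)
  lists <- cfg$catalog$unconstrained_lists
  u <- stream_runif(rng, length(lists))
  attributes <- stats::setNames(lapply(seq_along(lists), function(i) {
    v <- lists[[i]]
    v[[min(length(v), floor(u[i] * length(v)) + 1L)]]
  }), names(lists))

  prof <- as_patient_profile(list(
    id = sprintf("patient_%06d", index),
    seed_index = index,
    identity = identity[c("name", "date_of_birth", "address", "occupation",
                          "name_locale")],
    demographics = c(bundle[c("age", "age_bracket", "sex", "ethnicity",
                              "relationship_status", "has_children")]),
    disabilities = disabilities,
    conditions = conditions,
    attributes = attributes,
    narrative = list(),
    filled_by = stats::setNames(
      as.list(rep("sampler", 4L)),
      c("identity", "demographics", "conditions", "attributes"))
  ))
  if (enrich) prof <- enrich_narrative(prof, template, backend)
  prof
}

#' Generate a cohort of synthetic patients
#' @inheritParams generate_patient
#' @param n cohort size.
#' @return list of `patient_profile`s.
#' @export
generate_cohort <- function(cfg, template, backend, n, master_seed,
                            name_table = default_name_table(),
                            enrich = TRUE) {
  lapply(seq_len(n), function(i) {
    generate_patient(cfg, template, backend, master_seed, i,
                     name_table = name_table, enrich = enrich)
  })
}

#' Check a profile against its structural invariants
#'
#' Age must be consistent with date of birth (at the configuration's reference
#' date) and bracket; 0-3 conditions, each medication from the catalog;
#' disabilities only from the configured types; narrative fields non-empty.
#'
#' @param profile a `patient_profile`.
#' @param cfg a `population_config`.
#' @return `TRUE`, or an error describing the violated invariant.
#' @export
validate_profile <- function(profile, cfg) {
  d <- profile$demographics
  bi <- match(d$age_bracket, cfg$age_groups$labels)
  if (is.na(bi)) stop("unknown age bracket", call. = FALSE)
  if (d$age < cfg$age_bounds[bi, 1L] || d$age > cfg$age_bounds[bi, 2L]) {
    stop(sprintf("%s: age %d outside bracket %s", profile$id, d$age,
                 d$age_bracket), call. = FALSE)
  }
  if (age_at(profile$identity$date_of_birth, cfg$reference_date) != d$age) {
    stop(sprintf("%s: date of birth inconsistent with age", profile$id),
         call. = FALSE)
  }
  if (length(profile$conditions) > 3L) {
    stop(sprintf("%s: more than 3 conditions", profile$id), call. = FALSE)
  }
  for (cn in profile$conditions) {
    meds <- cfg$catalog$condition_to_meds[[cn$condition]]
    if (is.null(meds) || !cn$medication %in% meds) {
      stop(sprintf("%s: medication not in catalog for %s", profile$id,
                   cn$condition), call. = FALSE)
    }
  }
  if (!all(profile$disabilities %in% cfg$disability_type_shares$labels)) {
    stop(sprintf("%s: disability type outside configured set", profile$id),
         call. = FALSE)
  }
  if (length(profile$narrative) > 0L &&
      any(!nzchar(trimws(unlist(profile$narrative))))) {
    stop(sprintf("%s: empty narrative field", profile$id), call. = FALSE)
  }
  TRUE
}

#' Write a cohort to a JSON-lines file
#' @param cohort list of `patient_profile`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(cohort, path) {
  lines <- vapply(cohort, function(p) {
    as.character(jsonlite::toJSON(unclass(p), auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a cohort from a JSON-lines file
#' @param path input path.
#' @return list of `patient_profile`s.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("profile file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    raw <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) {
        stop(sprintf("malformed profile JSON at line %d: %s", i,
                     conditionMessage(e)), call. = FALSE)
      })
    as_patient_profile(raw)
  })
}
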