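#' @title Two-agent interview orchestration
#' @description Runs the structured intake interview between a patient backend
#'   and an interview-assistant backend: per-perspective role relabeling,
#'   chunked question delivery with preemptive loading and context dumping,
#'   strict RESPONSE/Note/<STOP> protocol parsing, prompt-adherence failure
#'   classification, note-based summary assembly, and transcript export.
#' @name dialogue_engine
NULL

#' Literal protocol tags (case-sensitive)
#'
#' `RESPONSE:` prefixes every final payload; interviewer notes are wrapped in
#' `Note: ... <END_NOTE>`; the interviewer ends the session with a payload of
#' exactly `<STOP>`.
#'
#' @format list with `response_prefix`, `note_open`, `note_close`,
#'   `stop_token`.
#' @export
PROTOCOL_TAGS <- list(response_prefix = "RESPONSE:", note_open = "Note:",
                      note_close = "<END_NOTE>", stop_token = "<STOP>")

#' Hard-coded opening question the patient model answers first
#' @export
INTERVIEW_OPENER <- paste(
  "Hello, thank you for coming in today. I'm the intake assistant.",
  "To begin, can you tell me your full name and what brings you in today?")

#' Interview loop limits
#' @param max_turns hard cap on recorded turns; `NULL` means 4 x the number of
#'   bank points (guaranteeing termination; hitting it is a full failure).
#' @param max_clarifications_per_point clarification turns allowed before the
#'   engine signals the interviewer to move on.
#' @return list of limits.
#' @export
interview_limits <- function(max_turns = NULL, max_clarifications_per_point = 2L) {
  list(max_turns = max_turns,
       max_clarifications_per_point = as.integer(max_clarifications_per_point))
}

#' Parse a raw completion against the message protocol
#'
#' The payload is the trimmed text after the *last* `RESPONSE:` prefix. For
#' interviewer completions a `Note: ... <END_NOTE>` block is extracted.
#' Anomalies are flags, never errors: `leaked_cot` is set when non-whitespace
#' text other than a single well-formed note block precedes the prefix, when
#' the prefix occurs more than once, or when it is absent (the payload then
#' falls back to the full raw text). `is_stop` holds iff the payload equals
#' the stop token exactly after trimming; a stop token embedded in longer text
#' sets `embedded_stop` instead.
#'
#' @param raw non-empty completion text.
#' @param speaker `"interviewer"` or `"patient"`.
#' @return list with `payload`, `note` (string, `""` when absent), `is_stop`,
#'   `leaked_cot`, `embedded_stop`.
#' @export
parse_model_output <- function(raw, speaker = c("interviewer", "patient")) {
  speaker <- match.arg(speaker)
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  tags <- PROTOCOL_TAGS
  occ <- gregexpr(tags$response_prefix, raw, fixed = TRUE)[[1L]]
  n_occ <- if (occ[1L] == -1L) 0L else length(occ)

  note <- ""
  if (speaker == "interviewer") {
    nb <- extract_block(raw, tags$note_open, tags$note_close)
    if (!is.null(nb)) note <- nb
  }

  if (n_occ == 0L) {
    payload <- trimws(raw)
    leaked <- TRUE
  } else {
    last <- occ[n_occ]
    payload <- trimws(substr(raw, last + nchar(tags$response_prefix),
                             nchar(raw)))
    pre <- substr(raw, 1L, occ[1L] - 1L)
    if (speaker == "interviewer") {
      # one well-formed note block ahead of the prefix is part of the protocol
      i <- regexpr(tags$note_open, pre, fixed = TRUE)
      j <- regexpr(tags$note_close, pre, fixed = TRUE)
      if (i > 0L && j > i) {
        pre <- paste0(substr(pre, 1L, i - 1L),
                      substr(pre, j + nchar(tags$note_close), nchar(pre)))
      }
    }
    leaked <- n_occ > 1L || nzchar(trimws(pre))
  }
  is_stop <- identical(payload, tags$stop_token)
  embedded <- !is_stop && grepl(tags$stop_token, payload, fixed = TRUE)
  list(payload = payload, note = note, is_stop = is_stop,
       leaked_cot = leaked, embedded_stop = embedded)
}

#' Relabel a turn history for one model's perspective
#'
#' Under perspective `P`, `P`'s own turns carry role `assistant` and the
#' counterpart's turns carry role `user`; the system message is `P`'s prompt.
#' Leading turns spoken by `P` itself are dropped so the sequence alternates
#' user/assistant starting with user (they can only arise after a context
#' dump). For the patient perspective the hard-coded opener is prepended as
#' the first user message when `opener` is given.
#'
#' @param turns list of turns (each with `speaker`, `text`), strictly
#'   alternating and starting with a patient turn.
#' @param perspective `"patient"` or `"interviewer"`.
#' @param system_prompt the perspective's system prompt text.
#' @param opener opener text to prepend (patient perspective only), or `NULL`.
#' @return a validated message list.
#' @export
relabel_history <- function(turns, perspective = c("patient", "interviewer"),
                            system_prompt = "", opener = NULL) {
  perspective <- match.arg(perspective)
  speakers <- vapply(turns, `[[`, character(1), "speaker")
  if (length(speakers) > 1L &&
      any(speakers[-1L] == speakers[-length(speakers)])) {
    stop("protocol error: turns do not alternate speakers", call. = FALSE)
  }
  msgs <- list(chat_message("system", system_prompt))
  if (perspective == "patient" && !is.null(opener)) {
    msgs <- c(msgs, list(chat_message("user", opener)))
  } else {
    # drop leading own turns so the history starts with a user message
    while (length(turns) > 0L && turns[[1L]]$speaker == perspective) {
      turns <- turns[-1L]
    }
  }
  for (t in turns) {
    role <- if (t$speaker == perspective) "assistant" else "user"
    msgs <- c(msgs, list(chat_message(role, t$text)))
  }
  validate_messages(msgs)
}

truncate_to_tokens <- function(text, max_tokens) {
  w <- strsplit(trimws(text), "[[:space:]]+")[[1L]]
  keep <- min(length(w), floor(max_tokens / 1.3))
  paste(w[seq_len(keep)], collapse = " ")
}

#' Compose the final interview summary from the recorded notes
#'
#' Notes are grouped by question-bank section and handed to the backend; the
#' scripted mock returns a deterministic concatenation. An empty note list
#' yields a fixed "no notes recorded" summary without a backend call. On
#' backend failure the summary falls back to the structured note list and is
#' flagged.
#'
#' @param notes character vector of note digests.
#' @param backend a chat backend.
#' @param sections optional character vector of section titles, parallel to
#'   `notes`, used for grouping.
#' @param options an [inference_options()].
#' @return list with `text` and logical `fallback`.
#' @export
compose_summary <- function(notes, backend, sections = NULL,
                            options = inference_options()) {
  notes <- as.character(notes)
  if (length(notes) == 0L) {
    return(list(text = "No notes were recorded during this interview.",
                fallback = FALSE))
  }
  if (is.null(sections)) sections <- rep("Interview", length(notes))
  grouped <- vapply(unique(sections), function(s) {
    paste0(s, ": ", paste(notes[sections == s], collapse = " | "))
  }, character(1))
  body <- paste(grouped, collapse = ". ")
  sys <- paste0(read_prompt_asset("summary_prompt.txt"), "\n\nTASK: SUMMARY")
  msgs <- list(chat_message("system", sys), chat_message("user", body))
  text <- tryCatch(chat(backend, msgs, options), error = function(e) NULL)
  if (is.null(text) || !nzchar(trimws(text))) {
    return(list(text = paste0("Structured note list (summary backend failed): ",
                              body), fallback = TRUE))
  }
  list(text = text, fallback = FALSE)
}

bank_ref_string <- function(bank) {
  txt <- serialize_question_bank(bank)
  sprintf("qbank:%d sections:%d points:h%d", length(bank$sections),
          sum(bank_section_sizes(bank)), hash_string(txt))
}

# Canonicalize an interview result; shared by the engine and the JSON reader
# so exports round-trip exactly.
as_interview_result <- function(x) {
  structure(list(
    id = as.character(x$id),
    seed = as.integer(x$seed),
    status = as.character(x$status),
    opener = as.character(x$opener),
    profile_id = as.character(x$profile_id),
    bank_ref = as.character(x$bank_ref),
    options = list(temperature = as.numeric(x$options$temperature),
                   top_k = as.integer(x$options$top_k),
                   top_p = as.numeric(x$options$top_p),
                   num_ctx = as.integer(x$options$num_ctx)),
    turns = lapply(x$turns, function(t) {
      list(index = as.integer(t$index),
           speaker = as.character(t$speaker),
           text = as.character(t$text),
           raw = as.character(t$raw),
           note = as.character(t$note),
           is_stop = isTRUE(as.logical(t$is_stop)),
           leaked_cot = isTRUE(as.logical(t$leaked_cot)))
    }),
    notes = as.character(unlist(x$notes)),
    note_sections = as.character(unlist(x$note_sections)),
    chunk_summaries = as.character(unlist(x$chunk_summaries)),
    summary = as.character(x$summary),
    summary_fallback = isTRUE(as.logical(x$summary_fallback)),
    delivered_points = as.character(unlist(x$delivered_points)),
    undelivered_points = as.character(unlist(x$undelivered_points)),
    max_context_tokens = as.integer(x$max_context_tokens),
    error = as.character(x$error)
  ), class = "interview_result")
}

#' @export
print.interview_result <- function(x, ...) {
  cat("<interview_result> ", x$id, " | status: ", x$status, " | ",
      length(x$turns), " turns, ", length(x$notes), " notes\n", sep = "")
  cat("  points delivered: ", length(x$delivered_points), " (",
      length(x$undelivered_points), " undelivered) | peak context ~",
      x$max_context_tokens, " tokens\n", sep = "")
  invisible(x)
}

#' Run one structured intake interview
#'
#' Alternates patient answers and interviewer turns, starting from the
#' hard-coded opener. The interviewer's active context holds the current
#' question-bank chunk; the next chunk is preloaded when the current chunk's
#' final point is about to be asked, and a completed chunk's turns are dumped
#' from active context (archived in the result) and replaced by a brief
#' note-based summary. The loop terminates on the stop token, the turn cap,
#' or a backend error, and the session is classified by [classify_session()].
#'
#' @param profile a `patient_profile`.
#' @param bank a `question_bank`.
#' @param patient_backend,interviewer_backend chat backends.
#' @param options an [inference_options()].
#' @param limits an [interview_limits()].
#' @param seed integer recorded in the result (the scripted mocks carry their
#'   own seeds; the engine itself is deterministic).
#' @return an `interview_result`.
#' @export
run_interview <- function(profile, bank, patient_backend, interviewer_backend,
                          options = inference_options(),
                          limits = interview_limits(), seed = 0L) {
  all_points <- bank_points(bank)
  n_points <- length(all_points)
  max_turns <- limits$max_turns
  if (is.null(max_turns)) max_turns <- 4L * n_points
  sizes <- bank_section_sizes(bank)
  section_of_point <- rep(seq_along(sizes), sizes)
  titles <- bank_section_titles(bank)

  patient_sys_base <- paste0(
    read_prompt_asset("patient_prompt.txt"), "\n\n",
    MOCK_MARKERS$patient_open, "\n",
    as.character(jsonlite::toJSON(unclass(profile), auto_unbox = TRUE,
                                  digits = NA)), "\n",
    MOCK_MARKERS$patient_close)
  interviewer_base <- read_prompt_asset("interviewer_prompt.txt")

  turns <- list()
  notes <- character()
  note_sections <- character()
  chunk_summaries <- character()
  delivered <- logical(n_points)
  active_sections <- 1L
  archive_start <- 1L         # first active turn index
  pending_dump <- integer(0)  # sections completed, waiting for the answer
  clar_count <- 0L
  clar_exhausted <- FALSE
  max_ctx <- 0L
  err <- character(0)
  stopped <- FALSE

  active_turns <- function() {
    if (length(turns) < archive_start) list() else
      turns[seq.int(archive_start, length(turns))]
  }
  current_section <- function() {
    und <- which(!delivered)
    if (length(und) == 0L) length(sizes) else section_of_point[und[1L]]
  }
  interviewer_system <- function() {
    # preemptive loading: include the next chunk when only the current
    # chunk's final point remains undelivered
    cs <- current_section()
    active_sections <<- union(active_sections, cs)
    in_cs <- which(section_of_point == cs)
    und_cs <- sum(!delivered[in_cs])
    if (und_cs <= 1L && cs < length(sizes)) {
      active_sections <<- union(active_sections, cs + 1L)
    }
    pts <- all_points[section_of_point %in% active_sections]
    sys <- paste0(
      interviewer_base, "\n\n", MOCK_MARKERS$points_open, "\n",
      paste0("- ", pts, collapse = "\n"), "\n", MOCK_MARKERS$points_close)
    if (length(sizes) %in% active_sections) {
      sys <- paste0(sys, "\n", MOCK_MARKERS$final_section)
    }
    if (clar_exhausted) {
      sys <- paste0(sys, "\n", MOCK_MARKERS$clar_exhausted)
    }
    if (length(chunk_summaries) > 0L) {
      sys <- paste0(sys, "\n\nSummary of earlier discussion:\n",
                    paste(chunk_summaries, collapse = "\n"))
    }
    sys
  }
  track_ctx <- function(msgs) {
    est <- estimate_tokens(paste(vapply(msgs, `[[`, character(1), "content"),
                                 collapse = " "))
    if (est > max_ctx) max_ctx <<- est
  }

  run_loop <- function() {
    repeat {
      # --- patient answers ---
      include_opener <- archive_start == 1L
      pmsgs <- relabel_history(active_turns(), "patient", patient_sys_base,
                               opener = if (include_opener) INTERVIEW_OPENER
                                        else NULL)
      track_ctx(pmsgs)
      praw <- chat(patient_backend, pmsgs, options)
      pp <- parse_model_output(praw, "patient")
      turns[[length(turns) + 1L]] <<- list(
        index = length(turns) + 1L, speaker = "patient", text = pp$payload,
        raw = praw, note = "", is_stop = FALSE, leaked_cot = pp$leaked_cot)

      # dump a completed chunk now that its closing answer is recorded
      if (length(pending_dump) > 0L) {
        for (s in pending_dump) {
          sec_notes <- notes[note_sections == titles[s]]
          chunk_summaries <<- c(chunk_summaries, paste0(
            titles[s], ": ",
            truncate_to_tokens(paste(sec_notes, collapse = " | "), 200L)))
          active_sections <<- setdiff(active_sections, s)
        }
        archive_start <<- length(turns)  # keep the closing answer active
        pending_dump <<- integer(0)
      }
      if (length(turns) >= max_turns) break

      # --- interviewer turn ---
      imsgs <- relabel_history(active_turns(), "interviewer",
                               interviewer_system())
      track_ctx(imsgs)
      iraw <- chat(interviewer_backend, imsgs, options)
      ip <- parse_model_output(iraw, "interviewer")
      turns[[length(turns) + 1L]] <<- list(
        index = length(turns) + 1L, speaker = "interviewer",
        text = ip$payload, raw = iraw, note = ip$note,
        is_stop = ip$is_stop, leaked_cot = ip$leaked_cot)
      if (ip$is_stop) {
        stopped <<- TRUE
        break
      }
      if (nzchar(ip$note)) {
        notes <<- c(notes, ip$note)
        note_sections <<- c(note_sections, titles[current_section()])
      }

      # which point (if any) did this turn deliver?
      cand <- which(!delivered & section_of_point %in% active_sections)
      hit <- cand[vapply(cand, function(k) {
        grepl(all_points[k], ip$payload, fixed = TRUE)
      }, logical(1))]
      if (length(hit) > 0L) {
        k <- hit[1L]
        delivered[k] <<- TRUE
        clar_count <<- 0L
        clar_exhausted <<- FALSE
        s <- section_of_point[k]
        if (all(delivered[section_of_point == s]) && s < length(sizes)) {
          pending_dump <<- c(pending_dump, s)
        }
      } else {
        clar_count <<- clar_count + 1L
        if (clar_count >= limits$max_clarifications_per_point) {
          clar_exhausted <<- TRUE
        }
      }
      if (length(turns) >= max_turns) break
    }
  }
  tryCatch(run_loop(), error = function(e) {
    err <<- conditionMessage(e)
  })

  summ <- if (length(err) == 0L) {
    compose_summary(notes, interviewer_backend, sections = note_sections,
                    options = options)
  } else {
    list(text = paste0("Structured note list (interview aborted): ",
                       paste(notes, collapse = " | ")), fallback = TRUE)
  }

  res <- as_interview_result(list(
    id = sprintf("%s_s%d", profile$id, as.integer(seed)),
    seed = seed,
    status = "pending",
    opener = INTERVIEW_OPENER,
    profile_id = profile$id,
    bank_ref = bank_ref_string(bank),
    options = unclass(options),
    turns = turns,
    notes = notes,
    note_sections = note_sections,
    chunk_summaries = chunk_summaries,
    summary = summ$text,
    summary_fallback = summ$fallback,
    delivered_points = all_points[delivered],
    undelivered_points = all_points[!delivered],
    max_context_tokens = max_ctx,
    error = err
  ))
  res$status <- classify_session(res)
  res
}

#' Classify a session's prompt-adherence status
#'
#' `full_failure`: the interviewer never emitted the stop token, question
#' points remain undelivered at termination, or the session aborted on a
#' backend error. `soft_failure`: the session completed but some turn leaked
#' step-by-step reasoning around its `RESPONSE:` payload. Otherwise
#' `compliant`.
#'
#' @param result an `interview_result`.
#' @return one of `"compliant"`, `"full_failure"`, `"soft_failure"`.
#' @export
classify_session <- function(result) {
  stops <- vapply(result$turns, `[[`, logical(1), "is_stop")
  n <- length(result$turns)
  clean_stop <- n > 0L && stops[n] &&
    result$turns[[n]]$speaker == "interviewer"
  if (length(result$error) > 0L || !clean_stop ||
      length(result$undelivered_points) > 0L) {
    return("full_failure")
  }
  if (any(vapply(result$turns, `[[`, logical(1), "leaked_cot"))) {
    return("soft_failure")
  }
  "compliant"
}

#' Export a transcript as JSON and plain text
#'
#' Writes `<id>.json` (the full result schema; reading it back with
#' [read_transcript()] reproduces the result exactly) and `<id>.txt` with the
#' documented layout: a header line, a blank line, one `Interviewer:`/
#' `Patient:` line per turn (the opener is shown on the header's Interviewer
#' line count as turn context), and one final `Summary:` line.
#'
#' @param result an `interview_result`.
#' @param dir output directory (created if needed).
#' @return named character vector with the `json` and `txt` paths.
#' @export
export_transcript <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, paste0(result$id, ".json"))
  txt_path <- file.path(dir, paste0(result$id, ".txt"))
  writeLines(as.character(jsonlite::toJSON(unclass(result), auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             json_path, useBytes = TRUE)
  flat <- function(s) gsub("[\r\n]+", " / ", s)
  turn_lines <- vapply(result$turns, function(t) {
    who <- if (t$speaker == "patient") "Patient" else "Interviewer"
    paste0(who, ": ", flat(t$text))
  }, character(1))
  lines <- c(
    sprintf("Interview %s | status: %s | seed: %d", result$id, result$status,
            result$seed),
    "",
    turn_lines,
    paste0("Summary: ", flat(result$summary)))
  writeLines(lines, txt_path, useBytes = TRUE)
  c(json = json_path, txt = txt_path)
}

#' Read a transcript JSON back into an `interview_result`
#' @param path path to a `<id>.json` transcript.
#' @return an `interview_result`.
#' @export
read_transcript <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("transcript not found: %s", path), call. = FALSE)
  }
  as_interview_result(jsonlite::read_json(path, simplifyVector = FALSE))
}
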