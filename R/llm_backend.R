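#' @title Chat backend contract
#' @description All language-model calls go through a single `chat()` contract:
#'   an ordered message list (system first, then strictly alternating
#'   user/assistant) plus decoding options, returning one completion string.
#'   Two implementations ship: a deterministic scripted mock that plays both
#'   interview roles (plus profile-template, narrative-enrichment and summary
#'   tasks) entirely offline, and an HTTP adapter for Ollama-compatible
#'   servers. Decoding parameters are forwarded, never implemented, here.
#' @name llm_backend
NULL

#' Construct a chat message
#' @param role one of `"system"`, `"user"`, `"assistant"`.
#' @param content message text (non-null; may be empty only for assistants
#'   echoing a stop).
#' @return a list with `role` and `content`.
#' @export
chat_message <- function(role, content) {
  if (!role %in% c("system", "user", "assistant")) {
    stop(sprintf("protocol error: unknown message role \"%s\"", role),
         call. = FALSE)
  }
  if (is.null(content) || length(content) != 1L || is.na(content)) {
    stop("protocol error: message content must be a single string",
         call. = FALSE)
  }
  list(role = role, content = as.character(content))
}

#' Validate a message sequence against the chat protocol
#'
#' The first message must be `system`; the rest must strictly alternate
#' starting with `user`.
#'
#' @param messages list of [chat_message()]s.
#' @return `messages`, invisibly.
#' @export
validate_messages <- function(messages) {
  if (length(messages) == 0L || messages[[1L]]$role != "system") {
    stop("protocol error: first message must have role \"system\"",
         call. = FALSE)
  }
  roles <- vapply(messages, `[[`, character(1), "role")
  if (any(roles[-1L] == "system")) {
    stop("protocol error: only the first message may be \"system\"",
         call. = FALSE)
  }
  expected <- rep(c("user", "assistant"), length.out = length(roles) - 1L)
  if (length(roles) > 1L && !identical(roles[-1L], expected)) {
    stop("protocol error: roles must alternate user/assistant starting with user",
         call. = FALSE)
  }
  invisible(messages)
}

#' Inference (decoding) options forwarded to the backend
#'
#' Defaults follow the study configuration: `temperature = 0.9` balances
#' varied phrasing with coherence, `top_k = 40` truncates the sampling pool,
#' `top_p = 0.9` applies nucleus sampling, and `num_ctx = 6144` tokens is the
#' active context window the chunking-and-dumping engine must respect.
#'
#' @param temperature sampling temperature, `>= 0`.
#' @param top_k top-k truncation, `>= 1`.
#' @param top_p nucleus mass, in `(0, 1]`.
#' @param num_ctx context window in tokens, `>= 1024`.
#' @return an object of class `inference_options`.
#' @export
inference_options <- function(temperature = 0.9, top_k = 40L, top_p = 0.9,
                              num_ctx = 6144L) {
  if (temperature < 0) stop("temperature must be >= 0", call. = FALSE)
  if (top_k < 1) stop("top_k must be >= 1", call. = FALSE)
  if (top_p <= 0 || top_p > 1) stop("top_p must be in (0, 1]", call. = FALSE)
  if (num_ctx < 1024) stop("num_ctx must be >= 1024", call. = FALSE)
  structure(list(temperature = temperature, top_k = as.integer(top_k),
                 top_p = top_p, num_ctx = as.integer(num_ctx)),
            class = "inference_options")
}

#' Request one chat completion
#' @param backend a backend object (see [mock_backend()], [http_backend()]).
#' @param messages validated message list.
#' @param options an [inference_options()].
#' @return completion text (single string).
#' @export
chat <- function(backend, messages, options = inference_options()) {
  UseMethod("chat")
}

#' Estimate the token count of a text
#'
#' Documented heuristic: the whitespace-token count times 1.3, rounded up.
#' Deterministic, non-negative, and monotone under concatenation. Used to
#' instrument the active context window against `num_ctx`.
#'
#' @param text character scalar.
#' @return integer estimate.
#' @export
estimate_tokens <- function(text) {
  if (length(text) == 0L || !nzchar(trimws(text))) return(0L)
  n <- length(strsplit(trimws(text), "[[:space:]]+")[[1L]])
  as.integer(ceiling(n * 1.3))
}

# ---------------------------------------------------------------------------
# Scripted mock backend

# Markers the orchestration layers embed in system prompts so the scripted
# mock can recognize its task without any shared state.
MOCK_MARKERS <- list(
  patient_open = "<PATIENT_INFO>", patient_close = "</PATIENT_INFO>",
  points_open = "<QUESTION_POINTS>", points_close = "</QUESTION_POINTS>",
  final_section = "FINAL_SECTION: yes",
  clar_exhausted = "CLARIFICATION_BUDGET_EXHAUSTED",
  template_task = "TASK: PROFILE_TEMPLATE",
  narrative_task = "TASK: NARRATIVE_FIELD",
  summary_task = "TASK: SUMMARY",
  fields_open = "<PROFILE_FIELDS>", fields_close = "</PROFILE_FIELDS>",
  bank_open = "<QUESTION_BANK>", bank_close = "</QUESTION_BANK>"
)

VAGUE_PHRASES <- c(
  "I'm not really sure, it's hard to say.",
  "Hmm, I don't know... it's all a bit of a blur.",
  "It's hard to put into words, honestly."
)

CLARIFY_SIGNATURE <- "could you share a bit more"

ACK_PHRASES <- c(
  "Thank you for sharing that.",
  "I appreciate you telling me.",
  "That's helpful to know.",
  "Thanks, I've noted that.",
  "I see, thank you.",
  "Okay, that makes sense.",
  "Understood, thank you.",
  "Thank you, that's useful context."
)

#' Deterministic scripted mock chat backend
#'
#' A pure function of `(messages, seed)` that plays whichever role its system
#' prompt announces: patient (answers from the `<PATIENT_INFO>` profile),
#' interview assistant (emits `Note: ... <END_NOTE>` then `RESPONSE:` with the
#' next unasked `<QUESTION_POINTS>` entry, and `RESPONSE: <STOP>` when done),
#' profile-template generation, narrative-field enrichment, or note
#' summarization.
#'
#' @param seed integer; varies the mock's phrasing deterministically.
#' @param faults character vector of fault-injection flags, any of
#'   `"no_stop"` (never emits the stop token), `"premature_end"` (emits the
#'   stop token once two questions are visible in its active window, leaving
#'   points undelivered), `"leak_cot"` (prefixes step-by-step reasoning to
#'   every completion). These exist solely to exercise failure classification.
#' @param vague_prob probability (hash-deterministic per question) that the
#'   patient answers vaguely, exercising the clarification path.
#' @return an object of class `mock_backend`.
#' @export
mock_backend <- function(seed = 0L, faults = character(), vague_prob = 0) {
  bad <- setdiff(faults, c("no_stop", "premature_end", "leak_cot"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown fault flag(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(id = sprintf("mock(seed=%d)", as.integer(seed)),
                 seed = as.integer(seed), faults = faults,
                 vague_prob = vague_prob, deterministic = TRUE),
            class = c("mock_backend", "chat_backend"))
}

extract_block <- function(text, open, close) {
  i <- regexpr(open, text, fixed = TRUE)
  j <- regexpr(close, text, fixed = TRUE)
  if (i < 0 || j < 0 || j < i) return(NULL)
  trimws(substr(text, i + nchar(open), j - 1L))
}

first_words <- function(text, n = 12L) {
  w <- strsplit(trimws(text), "[[:space:]]+")[[1L]]
  paste(utils::head(w, n), collapse = " ")
}

pick_by_hash <- function(choices, key) {
  choices[(hash_string(key) %% length(choices)) + 1L]
}

#' @export
chat.mock_backend <- function(backend, messages, options = inference_options()) {
  validate_messages(messages)
  sys <- messages[[1L]]$content
  m <- MOCK_MARKERS
  out <-
    if (grepl(m$template_task, sys, fixed = TRUE)) {
      mock_template_completion(backend, sys)
    } else if (grepl(m$narrative_task, sys, fixed = TRUE)) {
      mock_narrative_completion(backend, sys)
    } else if (grepl(m$summary_task, sys, fixed = TRUE)) {
      mock_summary_completion(backend, messages)
    } else if (grepl(m$points_open, sys, fixed = TRUE)) {
      mock_interviewer_completion(backend, messages)
    } else if (grepl(m$patient_open, sys, fixed = TRUE)) {
      mock_patient_completion(backend, messages)
    } else {
      stop(sprintf("%s: system prompt matches no scripted task", backend$id),
           call. = FALSE)
    }
  if (!nzchar(out)) {
    stop(sprintf("%s: empty completion", backend$id), call. = FALSE)
  }
  out
}

mock_patient_completion <- function(backend, messages) {
  sys <- messages[[1L]]$content
  profile_json <- extract_block(sys, MOCK_MARKERS$patient_open,
                                MOCK_MARKERS$patient_close)
  if (is.null(profile_json)) {
    stop("mock patient: no <PATIENT_INFO> block in system prompt",
         call. = FALSE)
  }
  prof <- jsonlite::fromJSON(profile_json, simplifyVector = TRUE)
  roles <- vapply(messages, `[[`, character(1), "role")
  question <- messages[[max(which(roles == "user"))]]$content
  key <- paste(question, prof$identity$name, backend$seed, sep = "|")

  is_clarification <- grepl(CLARIFY_SIGNATURE, tolower(question), fixed = TRUE)
  if (!is_clarification && backend$vague_prob > 0 &&
      hash_unit(paste0("vague|", key)) < backend$vague_prob) {
    return(mock_wrap_response(backend, pick_by_hash(VAGUE_PHRASES, key)))
  }

  q <- tolower(question)
  cns <- prof$conditions
  meds <- if (is.data.frame(cns) && nrow(cns) > 0L) {
    paste(paste0(cns$medication, " for ", tolower(cns$condition)),
          collapse = "; ")
  } else if (is.list(cns) && length(cns) > 0L) {
    paste(vapply(cns, function(cn) {
      paste0(cn$medication, " for ", tolower(cn$condition))
    }, character(1)), collapse = "; ")
  } else {
    "nothing at the moment"
  }
  answer <-
    if (grepl("full name|your name", q)) {
      paste0("My name is ", prof$identity$name, ".")
    } else if (grepl("date of birth|born|how old|your age", q)) {
      paste0("I was born on ", prof$identity$date_of_birth, ", so I'm ",
             prof$demographics$age, " years old.")
    } else if (grepl("address|where do you live", q)) {
      paste0("I live at ", prof$identity$address, ".")
    } else if (grepl("occupation|for work|employed", q)) {
      paste0("I work as a ", tolower(prof$identity$occupation), ".")
    } else if (grepl("medication|prescri", q)) {
      paste0("I'm currently taking ", meds, ".")
    } else if (grepl("allerg", q)) {
      paste0("I'm allergic to ", tolower(prof$attributes$allergies), ".")
    } else if (grepl("supplement", q)) {
      paste0("I take ", tolower(prof$attributes$supplements),
             " most days.")
    } else if (grepl("recreational|substance|drug|alcohol", q)) {
      paste0("I occasionally use ", tolower(prof$attributes$recreational_drugs),
             ", nothing heavy.")
    } else if (grepl("brings you|reason for|why.*here|visit", q)) {
      paste0("I came in because of ", tolower(prof$attributes$visit_reason), ".")
    } else if (grepl("relationship status|married|partner", q)) {
      paste0("I'm ", tolower(prof$demographics$relationship_status),
             " at the moment.")
    } else if (grepl("children|kids", q)) {
      if (isTRUE(prof$demographics$has_children)) {
        "Yes, I do have children; they keep me busy."
      } else {
        "No, I don't have any children."
      }
    } else if (grepl("ethnic|background|heritage", q)) {
      paste0("My background is ", prof$demographics$ethnicity, ".")
    } else {
      mock_freeform_answer(prof, question, key)
    }
  mock_wrap_response(backend, answer)
}

# Freeform answer with hash-varied phrasing so transcripts are not a wall of
# identical sentences; echoes content words from the question for relevance.
mock_freeform_answer <- function(prof, question, key) {
  openers <- c("Honestly,", "Well,", "To be fair,", "Lately,", "I'd say",
               "Looking back,", "Most days,", "If I'm honest,")
  middles <- c("it has been fairly steady", "things have been up and down",
               "it changed quite a bit over the last year",
               "it is something I manage day by day",
               "it has improved since last spring",
               "it has been weighing on me somewhat",
               "it comes and goes depending on the week",
               "it has stayed about the same")
  closers <- c("overall.", "for the most part.", "though it varies.",
               "all things considered.", "more or less.",
               "which my family has noticed too.",
               "especially around work.", "but I cope.")
  words <- strsplit(tolower(gsub("[^a-zA-Z' ]", " ", question)),
                    "[[:space:]]+")[[1L]]
  words <- setdiff(words, c("", "the", "a", "an", "of", "and", "or", "you",
                            "your", "any", "do", "does", "have", "has", "how",
                            "what", "when", "please", "describe", "tell", "me",
                            "about", "is", "are", "to", "in", "for", "with"))
  topic <- if (length(words) > 0L) {
    paste(utils::head(words, 3L), collapse = " ")
  } else {
    "that"
  }
  paste(pick_by_hash(openers, paste0("o", key)),
        "regarding", paste0(topic, ","),
        pick_by_hash(middles, paste0("m", key)),
        pick_by_hash(closers, paste0("c", key)))
}

mock_wrap_response <- function(backend, text, note = NULL) {
  body <- paste0("RESPONSE: ", text)
  if (!is.null(note)) {
    body <- paste0("Note: ", note, " <END_NOTE>\n", body)
  }
  if ("leak_cot" %in% backend$faults) {
    body <- paste0("Step 1: I identified the previous question.\n",
                   "Step 2: I considered what to say next.\n", body)
  }
  body
}

mock_interviewer_completion <- function(backend, messages) {
  sys <- messages[[1L]]$content
  block <- extract_block(sys, MOCK_MARKERS$points_open,
                         MOCK_MARKERS$points_close)
  points <- character()
  if (!is.null(block) && nzchar(block)) {
    lines <- strsplit(block, "\n", fixed = TRUE)[[1L]]
    points <- sub("^- ", "", trimws(lines[startsWith(trimws(lines), "- ")]))
  }
  roles <- vapply(messages, `[[`, character(1), "role")
  contents <- vapply(messages, `[[`, character(1), "content")
  asked_text <- contents[roles == "assistant"]
  answers <- contents[roles == "user"]
  last_answer <- if (length(answers) > 0L) answers[length(answers)] else ""

  asked <- vapply(points, function(p) {
    any(vapply(asked_text, function(a) grepl(p, a, fixed = TRUE), logical(1)))
  }, logical(1))
  unasked <- points[!asked]
  n_questions <- length(asked_text)

  note <- if (nzchar(last_answer)) first_words(last_answer, 12L) else NULL

  if ("premature_end" %in% backend$faults && n_questions >= 2L) {
    return(mock_wrap_response(backend, "<STOP>"))
  }

  # Clarification path: the latest answer was vague and budget remains.
  vague <- any(vapply(VAGUE_PHRASES, function(v) {
    grepl(v, last_answer, fixed = TRUE)
  }, logical(1)))
  budget_left <- !grepl(MOCK_MARKERS$clar_exhausted, sys, fixed = TRUE)
  if (vague && budget_left && length(unasked) > 0L) {
    clar <- paste0("I understand this can be difficult - ",
                   CLARIFY_SIGNATURE, " about that?")
    return(mock_wrap_response(backend, clar, note = note))
  }

  if (length(unasked) == 0L) {
    if ("no_stop" %in% backend$faults) {
      return(mock_wrap_response(
        backend, "Thank you so much for your time today; take good care."))
    }
    return(mock_wrap_response(backend, "<STOP>"))
  }

  nxt <- unasked[[1L]]
  ack <- pick_by_hash(ACK_PHRASES, paste(last_answer, backend$seed, sep = "|"))
  mock_wrap_response(backend, paste(ack, nxt), note = note)
}

mock_template_completion <- function(backend, sys) {
  bank_text <- extract_block(sys, MOCK_MARKERS$bank_open,
                             MOCK_MARKERS$bank_close)
  if (is.null(bank_text) || !nzchar(bank_text)) {
    stop("mock template task: no <QUESTION_BANK> block", call. = FALSE)
  }
  bank <- parse_question_bank(bank_text)
  jsonlite::toJSON(template_fields_from_bank(bank), auto_unbox = TRUE,
                   pretty = TRUE)
}

mock_narrative_completion <- function(backend, sys) {
  line <- regmatches(sys, regexpr("TASK: NARRATIVE_FIELD field_id=[^\n]+", sys))
  field_id <- sub("TASK: NARRATIVE_FIELD field_id=", "", line)
  fields_block <- extract_block(sys, MOCK_MARKERS$fields_open,
                                MOCK_MARKERS$fields_close)
  if (is.null(fields_block)) {
    stop("mock narrative task: no <PROFILE_FIELDS> block", call. = FALSE)
  }
  kv <- strsplit(strsplit(fields_block, "\n", fixed = TRUE)[[1L]], ": ",
                 fixed = TRUE)
  vals <- stats::setNames(
    vapply(kv, function(x) paste(x[-1L], collapse = ": "), character(1)),
    vapply(kv, `[[`, character(1), 1L))
  patterns <- c(
    "%s, a %s-year-old %s, describes this area of life as settled and familiar, shaped mostly by routine and a small circle of people %s trusts.",
    "For %s (%s, working as a %s), this part of the story is uneven: some stretches were easy, others demanded real effort, and %s still thinks about both.",
    "%s reports that at age %s, balancing life as a %s, this topic comes up often at home, and %s tries to approach it with patience.",
    "When asked, %s - %s years old, employed as a %s - offers concrete examples from the past two years and notes that %s is gradually finding what works."
  )
  fmt <- pick_by_hash(patterns, field_id)
  sprintf(fmt, vals[["name"]], vals[["age"]], tolower(vals[["occupation"]]),
          vals[["name"]])
}

mock_summary_completion <- function(backend, messages) {
  notes_text <- messages[[length(messages)]]$content
  paste0("Intake summary. ", notes_text)
}

# ---------------------------------------------------------------------------
# HTTP adapter (Ollama-compatible)

#' Build the JSON request body for an Ollama-compatible chat endpoint
#'
#' Pure function, exposed so the wire format can be tested without a server.
#' Options are forwarded verbatim.
#'
#' @param model model name string.
#' @param messages validated message list.
#' @param options an [inference_options()].
#' @return JSON string.
#' @export
build_chat_request <- function(model, messages, options = inference_options()) {
  validate_messages(messages)
  body <- list(
    model = model,
    messages = lapply(messages, function(m) {
      list(role = m$role, content = m$content)
    }),
    stream = FALSE,
    options = list(temperature = options$temperature, top_k = options$top_k,
                   top_p = options$top_p, num_ctx = options$num_ctx)
  )
  as.character(jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA))
}

#' HTTP chat backend for an Ollama-compatible server
#'
#' POSTs `build_chat_request()` bodies to `<endpoint>/api/chat` and returns
#' `message$content` from the JSON reply. Requires the `curl` package.
#'
#' @param endpoint server base URL, e.g. `"http://localhost:11434"`.
#' @param model model name, e.g. `"llama3.3:70b"`.
#' @param timeout_s request timeout in seconds.
#' @return an object of class `http_backend`.
#' @export
http_backend <- function(endpoint, model, timeout_s = 600) {
  structure(list(id = sprintf("http(%s, %s)", endpoint, model),
                 endpoint = sub("/+$", "", endpoint), model = model,
                 timeout_s = timeout_s, deterministic = FALSE),
            class = c("http_backend", "chat_backend"))
}

#' @export
chat.http_backend <- function(backend, messages, options = inference_options()) {
  if (!requireNamespace("curl", quietly = TRUE)) {
    stop(sprintf("%s: the 'curl' package is required for the HTTP adapter",
                 backend$id), call. = FALSE)
  }
  body <- build_chat_request(backend$model, messages, options)
  h <- curl::new_handle(timeout = backend$timeout_s)
  curl::handle_setheaders(h, "Content-Type" = "application/json")
  curl::handle_setopt(h, postfields = body)
  res <- tryCatch(
    curl::curl_fetch_memory(paste0(backend$endpoint, "/api/chat"), handle = h),
    error = function(e) {
      stop(sprintf("%s: request failed: %s", backend$id, conditionMessage(e)),
           call. = FALSE)
    })
  if (res$status_code != 200L) {
    stop(sprintf("%s: HTTP %d from server", backend$id, res$status_code),
         call. = FALSE)
  }
  parsed <- jsonlite::fromJSON(rawToChar(res$content), simplifyVector = FALSE)
  out <- parsed$message$content
  if (is.null(out) || !nzchar(out)) {
    stop(sprintf("%s: empty completion from server", backend$id),
         call. = FALSE)
  }
  out
}
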