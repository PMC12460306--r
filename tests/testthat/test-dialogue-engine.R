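test_that("parse_model_output extracts payloads, notes, stops and leaks", {
  out <- parse_model_output(
    "Note: poor sleep, 3 months <END_NOTE>\nRESPONSE: Thank you. How is your appetite?",
    "interviewer")
  expect_identical(out$note, "poor sleep, 3 months")
  expect_identical(out$payload, "Thank you. How is your appetite?")
  expect_false(out$leaked_cot)
  expect_false(out$is_stop)

  stop_out <- parse_model_output("RESPONSE: <STOP>", "interviewer")
  expect_true(stop_out$is_stop)
  expect_identical(stop_out$payload, "<STOP>")

  leak <- parse_model_output(
    "Step 1: the previous question was... RESPONSE: I take sertraline.",
    "patient")
  expect_true(leak$leaked_cot)
  expect_identical(leak$payload, "I take sertraline.")

  # absent prefix falls back to the raw text and flags a leak
  noprefix <- parse_model_output("I just answered plainly.", "patient")
  expect_true(noprefix$leaked_cot)
  expect_identical(noprefix$payload, "I just answered plainly.")

  # repeated prefixes: payload comes from the last one
  multi <- parse_model_output("RESPONSE: draft\nRESPONSE: final", "patient")
  expect_true(multi$leaked_cot)
  expect_identical(multi$payload, "final")

  # a stop token buried in longer text is not a clean stop
  embedded <- parse_model_output("RESPONSE: Thanks, <STOP> and goodbye",
                                 "interviewer")
  expect_false(embedded$is_stop)
  expect_true(embedded$embedded_stop)
})

two_turns <- function() {
  list(list(speaker = "patient", text = "My name is A."),
       list(speaker = "interviewer", text = "How do you sleep?"))
}

test_that("relabel_history assigns perspective-dependent roles", {
  msgs <- relabel_history(two_turns(), "patient", "PPROMPT",
                          opener = "Hello, your name?")
  expect_identical(vapply(msgs, `[[`, character(1), "role"),
                   c("system", "user", "assistant", "user"))
  expect_identical(msgs[[1]]$content, "PPROMPT")
  expect_identical(msgs[[2]]$content, "Hello, your name?")

  empty <- relabel_history(list(), "patient", "PPROMPT", opener = "Hi?")
  expect_identical(vapply(empty, `[[`, character(1), "role"),
                   c("system", "user"))

  # perspectives are exact complements on shared turns
  imsgs <- relabel_history(two_turns(), "interviewer", "IPROMPT")
  proles <- vapply(msgs[3:4], `[[`, character(1), "role")
  iroles <- vapply(imsgs[2:3], `[[`, character(1), "role")
  expect_identical(proles, rev(iroles))
  expect_identical(iroles, c("user", "assistant"))

  bad <- list(list(speaker = "patient", text = "a"),
              list(speaker = "patient", text = "b"))
  expect_error(relabel_history(bad, "patient", "x"), "do not alternate")
})

test_that("a mock interview delivers every point once, in order, and stops", {
  p <- make_patient(master_seed = 51, index = 1, enrich = FALSE)
  res <- run_interview(p, fix_bank, mock_backend(seed = 5),
                       mock_backend(seed = 6), seed = 5)
  expect_identical(res$status, "compliant")
  expect_identical(res$delivered_points, bank_points(fix_bank))
  expect_length(res$undelivered_points, 0L)

  speakers <- vapply(res$turns, `[[`, character(1), "speaker")
  expect_identical(speakers[1], "patient")
  expect_true(all(speakers[-1] != speakers[-length(speakers)]))

  last <- res$turns[[length(res$turns)]]
  expect_true(last$is_stop)
  expect_identical(last$text, "<STOP>")

  n_interviewer_nonstop <- sum(speakers == "interviewer") - 1L
  expect_length(res$notes, n_interviewer_nonstop)
  expect_lte(res$max_context_tokens, res$options$num_ctx)
})

test_that("fault injection is classified correctly", {
  p <- make_patient(master_seed = 53, index = 1, enrich = FALSE)
  bank <- small_bank()
  base <- run_interview(p, bank, mock_backend(seed = 7), mock_backend(seed = 8),
                        seed = 7)
  expect_identical(base$status, "compliant")

  no_stop <- run_interview(p, bank, mock_backend(seed = 7),
                           mock_backend(seed = 8, faults = "no_stop"),
                           seed = 7)
  expect_identical(no_stop$status, "full_failure")

  leak <- run_interview(p, bank, mock_backend(seed = 7),
                        mock_backend(seed = 8, faults = "leak_cot"),
                        seed = 7)
  expect_identical(leak$status, "soft_failure")
  expect_identical(leak$delivered_points, bank_points(bank))

  premature <- run_interview(p, bank, mock_backend(seed = 7),
                             mock_backend(seed = 8, faults = "premature_end"),
                             seed = 7)
  expect_identical(premature$status, "full_failure")
  expect_gt(length(premature$undelivered_points), 0L)
})

test_that("a backend error yields a partial transcript marked full_failure", {
  counter <- new.env(); counter$n <- 0L
  assign("chat.flaky_backend", function(backend, messages, options) {
    counter$n <- counter$n + 1L
    if (counter$n > 3L) stop("connection reset")
    paste0("Note: ok <END_NOTE>\nRESPONSE: ",
           "Thanks. How has your sleep been lately?")
  }, envir = globalenv())
  on.exit(rm("chat.flaky_backend", envir = globalenv()), add = TRUE)
  flaky <- structure(list(id = "flaky"), class = c("flaky_backend",
                                                   "chat_backend"))
  p <- make_patient(master_seed = 57, index = 1, enrich = FALSE)
  res <- run_interview(p, small_bank(), mock_backend(seed = 1), flaky, seed = 1)
  expect_identical(res$status, "full_failure")
  expect_match(res$error, "connection reset")
  expect_gt(length(res$turns), 0L)
})

test_that("the vague-answer clarification path still completes the interview", {
  p <- make_patient(master_seed = 59, index = 1, enrich = FALSE)
  bank <- small_bank()
  res <- run_interview(p, bank, mock_backend(seed = 9, vague_prob = 1),
                       mock_backend(seed = 10),
                       limits = interview_limits(max_turns = 80L), seed = 9)
  expect_identical(res$status, "compliant")
  expect_identical(res$delivered_points, bank_points(bank))
  # clarifications add turns beyond the minimal 2 * points + 2
  expect_gt(length(res$turns), 2L * length(bank_points(bank)) + 1L)
})

test_that("the active context stays within the configured window across seeds", {
  p <- make_patient(master_seed = 61, index = 1, enrich = FALSE)
  for (s in 1:10) {
    res <- run_interview(p, fix_bank, mock_backend(seed = s),
                         mock_backend(seed = s + 100), seed = s)
    expect_identical(res$status, "compliant")
    expect_lte(res$max_context_tokens, 6144L)
  }
})

test_that("compose_summary references every note and degrades gracefully", {
  notes <- c("poor sleep for months", "appetite reduced", "supportive family")
  s <- compose_summary(notes, mock_backend(seed = 1),
                       sections = c("A", "A", "B"))
  expect_false(s$fallback)
  for (n in notes) expect_match(s$text, n, fixed = TRUE)
  expect_identical(s$text,
                   compose_summary(notes, mock_backend(seed = 1),
                                   sections = c("A", "A", "B"))$text)

  empty <- compose_summary(character(0), mock_backend(seed = 1))
  expect_match(empty$text, "[Nn]o notes")

  assign("chat.dead_backend", function(backend, messages, options) {
    stop("backend down")
  }, envir = globalenv())
  on.exit(rm("chat.dead_backend", envir = globalenv()), add = TRUE)
  dead <- structure(list(id = "dead"), class = c("dead_backend",
                                                 "chat_backend"))
  fb <- compose_summary(notes, dead)
  expect_true(fb$fallback)
  for (n in notes) expect_match(fb$text, n, fixed = TRUE)
})

test_that("transcript exports round-trip exactly and follow the TXT layout", {
  p <- make_patient(master_seed = 63, index = 1, enrich = FALSE)
  res <- run_interview(p, small_bank(), mock_backend(seed = 3),
                       mock_backend(seed = 4), seed = 3)
  dir1 <- withr::local_tempdir()
  paths <- export_transcript(res, dir1)
  expect_true(all(file.exists(paths)))

  back <- read_transcript(paths[["json"]])
  expect_identical(back, res)

  txt <- readLines(paths[["txt"]])
  expect_length(txt, 2L + length(res$turns) + 1L)
  expect_match(txt[1], res$status, fixed = TRUE)
  expect_match(txt[1], paste0("seed: ", res$seed), fixed = TRUE)
  expect_match(txt[length(txt)], "^Summary: ")

  # byte-identical re-export for the same (profile, bank, seed)
  res2 <- run_interview(p, small_bank(), mock_backend(seed = 3),
                        mock_backend(seed = 4), seed = 3)
  dir2 <- withr::local_tempdir()
  paths2 <- export_transcript(res2, dir2)
  expect_identical(readLines(paths2[["json"]]), readLines(paths[["json"]]))
})
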