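#' @title Question bank parsing and chunked delivery
#' @description The intake interview is structured by a plain-text question
#'   bank: header lines open sections ("chunks") and the non-blank lines below
#'   them are question points. The interview engine holds one chunk in active
#'   context at a time and preloads the next chunk just before a section's
#'   final point is asked.
#' @name question_bank
NULL

#' Parse a header-structured question bank
#'
#' A line starting with `## ` opens a new section (alternatively, with
#' `headers = "caps"`, any ALL-CAPS line does). Every other non-blank line is
#' a question point; a leading `"<number>."` enumeration is stripped.
#'
#' @param text the bank as a single string or a character vector of lines.
#' @param headers header syntax: `"hash"` (default, lines starting `##`) or
#'   `"caps"` (all-uppercase lines).
#' @return an object of class `question_bank`: list with `sections`, each
#'   `{title, points}`.
#' @export
parse_question_bank <- function(text, headers = c("hash", "caps")) {
  headers <- match.arg(headers)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("[[:space:]]+$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("format error: question bank is empty", call. = FALSE)
  }
  is_header <- switch(headers,
    hash = startsWith(lines, "## "),
    caps = grepl("^[A-Z][A-Z0-9 /&'-]*$", lines) & toupper(lines) == lines
  )
  if (!is_header[1L]) {
    stop("format error: question point before the first section header",
         call. = FALSE)
  }
  sections <- list()
  title <- NULL
  points <- character()
  flush <- function() {
    if (!is.null(title)) {
      if (length(points) == 0L) {
        stop(sprintf("format error: section \"%s\" has no points", title),
             call. = FALSE)
      }
      sections[[length(sections) + 1L]] <<- list(title = title, points = points)
    }
  }
  for (i in seq_along(lines)) {
    if (is_header[i]) {
      flush()
      title <- if (headers == "hash") sub("^## ", "", lines[i]) else lines[i]
      points <- character()
    } else {
      points <- c(points, sub("^[0-9]+[.)]\\s*", "", trimws(lines[i])))
    }
  }
  flush()
  titles <- vapply(sections, `[[`, character(1), "title")
  if (anyDuplicated(titles)) {
    stop("format error: duplicate section titles", call. = FALSE)
  }
  structure(list(sections = sections), class = "question_bank")
}

#' Read a question bank from a file
#' @param path text file path.
#' @inheritParams parse_question_bank
#' @return a `question_bank`.
#' @export
read_question_bank <- function(path, headers = "hash") {
  if (!file.exists(path)) {
    stop(sprintf("question bank not found: %s", path), call. = FALSE)
  }
  parse_question_bank(readLines(path, encoding = "UTF-8"), headers = headers)
}

#' Serialize a question bank to its text form
#' @param bank a `question_bank`.
#' @return a single string; `parse_question_bank(serialize_question_bank(b))`
#'   reproduces `b`.
#' @export
serialize_question_bank <- function(bank) {
  paste(vapply(bank$sections, function(s) {
    paste(c(paste0("## ", s$title),
            sprintf("%d. %s", seq_along(s$points), s$points)), collapse = "\n")
  }, character(1)), collapse = "\n\n")
}

#' @export
print.question_bank <- function(x, ...) {
  cat("<question_bank> ", length(x$sections), " sections, ",
      sum(bank_section_sizes(x)), " points\n", sep = "")
  for (s in x$sections) {
    cat("  ", s$title, " (", length(s$points), ")\n", sep = "")
  }
  invisible(x)
}

#' Section titles of a bank
#' @param bank a `question_bank`.
#' @return character vector.
#' @export
bank_section_titles <- function(bank) {
  vapply(bank$sections, `[[`, character(1), "title")
}

#' Points per section
#' @param bank a `question_bank`.
#' @return integer vector.
#' @export
bank_section_sizes <- function(bank) {
  vapply(bank$sections, function(s) length(s$points), integer(1))
}

#' All points of a bank in global order
#' @param bank a `question_bank`.
#' @return character vector.
#' @export
bank_points <- function(bank) {
  unlist(lapply(bank$sections, `[[`, "points"), use.names = FALSE)
}

#' Create a chunk cursor over a question bank
#' @param bank a `question_bank`.
#' @return an object of class `chunk_cursor` (mutable environment) with
#'   fields `section`, `point`, `exhausted`.
#' @export
chunk_cursor <- function(bank) {
  e <- new.env(parent = emptyenv())
  e$section <- 1L
  e$point <- 1L
  e$exhausted <- length(bank$sections) == 0L
  class(e) <- "chunk_cursor"
  e
}

#' Advance a cursor by one question point
#'
#' Delivers every point exactly once, in global (file) order.
#' `chunk_boundary` is `TRUE` exactly when the delivered point is the final
#' point of its section — the signal at which the engine preloads the next
#' chunk.
#'
#' @param cursor a [chunk_cursor()].
#' @param bank the `question_bank` the cursor was created for.
#' @return list with `point`, `section_title`, `section_index`,
#'   `chunk_boundary`, `exhausted`.
#' @export
advance <- function(cursor, bank) {
  if (cursor$exhausted) {
    stop("advance past exhaustion: all question points delivered",
         call. = FALSE)
  }
  sec <- bank$sections[[cursor$section]]
  point <- sec$points[[cursor$point]]
  boundary <- cursor$point == length(sec$points)
  out <- list(point = point,
              section_title = sec$title,
              section_index = cursor$section,
              chunk_boundary = boundary)
  if (boundary) {
    if (cursor$section == length(bank$sections)) {
      cursor$exhausted <- TRUE
    } else {
      cursor$section <- cursor$section + 1L
      cursor$point <- 1L
    }
  } else {
    cursor$point <- cursor$point + 1L
  }
  out$exhausted <- cursor$exhausted
  out
}

#' Path to the packaged question bank fixture
#'
#' A 5-section, 47-point structured psychiatric intake bank (General
#' Information, Medical History, Family History, Personal History, Additional
#' Comments). Points are original paraphrases of standard intake topics; the
#' final point closes the interview.
#'
#' @return file path.
#' @export
default_question_bank_path <- function() {
  system.file("extdata", "question_bank.txt", package = "synthintake",
              mustWork = TRUE)
}
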