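# Readers and writers for the standard carriers: FASTA sequences, two-column
# annotation TSV, CAFA-style prediction files, sentence files.

#' Read protein sequences from FASTA
#'
#' Parses FASTA via Biostrings; the header token up to the first whitespace
#' becomes the protein id, sequences are uppercased with line breaks joined.
#' Duplicate ids and residue characters outside A-Z are hard errors.
#'
#' @param x FASTA text or a file path.
#' @return Named character vector, protein id -> sequence.
#' @export
read_fasta <- function(x) {
  path <- x
  if (length(x) > 1L || grepl("\n", x[[1L]], fixed = TRUE) || !file.exists(x)) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(read_lines_flex(x), path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(setNames(character(0), character(0)))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop2("duplicate FASTA id: ", ids[duplicated(ids)][[1L]])
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^A-Z]", seqs)
  if (any(bad)) {
    stop2("sequence for ", ids[bad][[1L]], " contains non-letter characters")
  }
  setNames(seqs, ids)
}

#' Write protein sequences as FASTA
#'
#' @param sequences Named character vector, protein id -> sequence.
#' @param path Output file path.
#' @param width Line-wrap width (default 60).
#' @return Invisibly, the path.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  set <- Biostrings::BStringSet(unlist(sequences))
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read protein-to-GO annotations from two-column TSV
#'
#' Each line is `protein_id<TAB>GO:NNNNNNN`; repeated rows for one protein
#' accumulate into an ordered, deduplicated term list (insertion order is
#' preserved because the code-word sentence keeps the record order).
#'
#' @param x TSV text or a file path.
#' @return Named list, protein id -> character vector of term ids.
#' @export
read_annotations <- function(x) {
  lines <- read_lines_flex(x)
  lines_keep <- which(nzchar(lines))
  out <- list()
  for (i in lines_keep) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !grepl(GO_ID_RE, parts[[2L]])) {
      stop2("malformed annotation at line ", i, ": ", lines[[i]])
    }
    pid <- parts[[1L]]
    cur <- out[[pid]]
    if (is.null(cur) || !parts[[2L]] %in% cur) {
      out[[pid]] <- c(cur, parts[[2L]])
    }
  }
  out
}

#' Write protein-to-GO annotations as two-column TSV
#'
#' @param annotations Named list, protein id -> character vector of term ids.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_annotations <- function(annotations, path) {
  lines <- unlist(lapply(names(annotations), function(pid) {
    paste(pid, annotations[[pid]], sep = "\t")
  }))
  writeLines(lines %||% character(0), path)
  invisible(path)
}

#' Validate and normalize a prediction set
#'
#' A prediction set maps each protein id to a data frame with columns
#' `go_id` and `score` (scores in (0, 1]), deduplicated by term keeping the
#' maximum score and sorted by descending score (ties broken by term id for
#' determinism).
#'
#' @param x Named list of data frames with columns `go_id`, `score`.
#' @return The normalized prediction set (class `prediction_set`).
#' @export
prediction_set <- function(x) {
  stopifnot(is.list(x))
  if (length(x) > 0L && is.null(names(x))) stop2("prediction set must be named")
  out <- lapply(x, function(df) {
    df <- as.data.frame(df)[, c("go_id", "score")]
    if (nrow(df) == 0L) return(df)
    if (any(df$score <= 0) || any(df$score > 1)) {
      stop2("prediction scores must lie in (0, 1]")
    }
    df <- df[order(-df$score, df$go_id), , drop = FALSE]
    df <- df[!duplicated(df$go_id), , drop = FALSE]
    df <- df[order(-df$score, df$go_id), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  structure(out, class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  np <- sum(vapply(x, nrow, integer(1)))
  cat("prediction_set:", length(x), "proteins,", np, "scored terms\n")
  invisible(x)
}

#' Write predictions in CAFA submission format
#'
#' Emits `AUTHOR`, `MODEL`, `KEYWORDS machine learning.` header lines, then
#' one line per prediction `target_id GO-id score` with the score rendered to
#' two decimals, and a terminal `END`. Records are ordered by target id, then
#' by descending score. Scores that would render as 0.00 are clamped to 0.01
#' with a warning.
#'
#' @param preds A `prediction_set`.
#' @param path Output file path (or NULL to return the lines).
#' @param author Author tag for the header.
#' @param model_number Model number for the header.
#' @return The lines, invisibly if written to `path`.
#' @export
write_cafa_predictions <- function(preds, path = NULL, author = "seq2go",
                                   model_number = 1L) {
  lines <- c(paste("AUTHOR", author),
             paste("MODEL", model_number),
             "KEYWORDS machine learning.")
  for (pid in sort(names(preds))) {
    df <- preds[[pid]]
    if (nrow(df) == 0L) next
    sc <- round(df$score, 2)
    if (any(sc < 0.01)) {
      warning("score(s) for ", pid, " round to 0.00; clamped to 0.01",
              call. = FALSE)
      sc <- pmax(sc, 0.01)
    }
    lines <- c(lines, sprintf("%s %s %.2f", pid, df$go_id, sc))
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a CAFA-format prediction file back into a prediction set
#'
#' @param x CAFA prediction text or a file path.
#' @return A `prediction_set`.
#' @export
read_cafa_predictions <- function(x) {
  lines <- read_lines_flex(x)
  body <- lines[!grepl("^(AUTHOR|MODEL|KEYWORDS|END)", lines) & nzchar(lines)]
  out <- list()
  for (ln in body) {
    parts <- strsplit(ln, "\\s+")[[1L]]
    if (length(parts) != 3L || !grepl(GO_ID_RE, parts[[2L]])) {
      stop2("malformed CAFA prediction line: ", ln)
    }
    pid <- parts[[1L]]
    out[[pid]] <- rbind(out[[pid]],
                        data.frame(go_id = parts[[2L]],
                                   score = as.numeric(parts[[3L]])))
  }
  prediction_set(out)
}

#' Read and write tokenized sentences as plain text
#'
#' One protein per line: the id followed by its whitespace-separated tokens.
#'
#' @param sentences Named list of token vectors.
#' @param path File path.
#' @return `write_sentences()` the path invisibly; `read_sentences()` a named
#'   list of token vectors.
#' @export
write_sentences <- function(sentences, path) {
  lines <- vapply(names(sentences), function(id) {
    paste(c(id, sentences[[id]]), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sentences
#' @export
read_sentences <- function(path) {
  lines <- read_lines_flex(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\\s+")[[1L]]
    out[[parts[[1L]]]] <- parts[-1L]
  }
  out
}
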