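# Internal helpers shared across modules.

#' @importFrom stats runif setNames
#' @importFrom utils head read.table write.table
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop2 <- function(...) stop(..., call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Accept either a literal text blob (contains a newline or the path does not
# exist) or a file path; return the text split into lines.
read_lines_flex <- function(x) {
  if (!is.character(x)) stop2("expected text or a file path")
  if (length(x) > 1L) return(x)
  if (grepl("\n", x, fixed = TRUE)) return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  if (file.exists(x)) return(readLines(x, warn = FALSE))
  # a single line of literal text with no newline
  x
}

GO_ID_RE <- "^GO:[0-9]{7}$"

assert_go_ids <- function(ids, what = "GO id") {
  bad <- ids[!grepl(GO_ID_RE, ids)]
  if (length(bad) > 0L) {
    stop2("malformed ", what, ": ", paste(head(bad, 5L), collapse = ", "))
  }
  invisible(ids)
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
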