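# Protein "word" vocabulary and greedy longest-match segmentation: turns
# amino-acid sequences into sentences of frequent k-mers plus fallback runs.

#' Count overlapping k-mers across a sequence corpus
#'
#' Counts every stride-1 window of each length `k_min .. k_max` over all
#' sequences. Sequences shorter than a given `k` contribute no windows of
#' that length.
#'
#' @param sequences Character vector (or list) of amino-acid strings.
#' @param k_min,k_max Inclusive k-mer length range (defaults 3 and 5).
#' @return A named integer vector of k-mer counts (class `kmer_table`).
#' @export
count_kmers <- function(sequences, k_min = 3L, k_max = 5L) {
  stopifnot(k_min >= 1L, k_max >= k_min)
  sequences <- as.character(unlist(sequences, use.names = FALSE))
  all_kmers <- character(0)
  for (k in k_min:k_max) {
    for (s in sequences) {
      L <- nchar(s)
      if (L < k) next
      all_kmers <- c(all_kmers, substring(s, 1:(L - k + 1L), k:L))
    }
  }
  if (length(all_kmers) == 0L) {
    return(structure(setNames(integer(0), character(0)),
                     k_range = c(k_min, k_max), class = "kmer_table"))
  }
  tab <- table(all_kmers)
  structure(setNames(as.integer(tab), names(tab)),
            k_range = c(as.integer(k_min), as.integer(k_max)),
            class = "kmer_table")
}

#' Build the protein-word vocabulary from k-mer counts
#'
#' Core words are the k-mers whose corpus frequency strictly exceeds
#' `min_freq`. Fallback words (maximal unmatched runs observed during
#' segmentation) start empty and are accumulated by [tokenize_corpus()].
#'
#' @param table A `kmer_table` from [count_kmers()], or any named integer
#'   vector of k-mer counts.
#' @param min_freq Frequency threshold; a k-mer is kept iff count > min_freq
#'   (default 1000, the corpus-scale setting; desk-scale runs use smaller
#'   values).
#' @return A `word_vocabulary`: list with `core_counts` (named integer),
#'   `fallback_counts` (named integer, initially empty), `min_freq`,
#'   `k_range`.
#' @export
build_vocabulary <- function(table, min_freq = 1000L) {
  stopifnot(min_freq >= 1L)
  k_range <- attr(table, "k_range")
  counts <- setNames(as.integer(table), names(table))
  core <- counts[counts > min_freq]
  if (is.null(k_range)) {
    k_range <- if (length(counts)) range(nchar(names(counts))) else c(3L, 5L)
  }
  new_word_vocabulary(core, setNames(integer(0), character(0)),
                      as.integer(min_freq), as.integer(k_range))
}

new_word_vocabulary <- function(core_counts, fallback_counts, min_freq, k_range) {
  env <- new.env(parent = emptyenv(), size = max(16L, 2L * length(core_counts)))
  for (w in names(core_counts)) assign(w, TRUE, envir = env)
  structure(list(core_counts = core_counts, fallback_counts = fallback_counts,
                 min_freq = min_freq, k_range = k_range, .core = env),
            class = "word_vocabulary")
}

#' @export
print.word_vocabulary <- function(x, ...) {
  cat("word_vocabulary:", length(x$core_counts), "core words (k in [",
      x$k_range[1], ",", x$k_range[2], "], count >", x$min_freq, "),",
      length(x$fallback_counts), "fallback words\n")
  invisible(x)
}

#' Segment one sequence into a protein-word sentence
#'
#' Left-to-right scan: at each position the longest core word (lengths
#' `k_max` down to `k_min`) is tried first; on a match the word is emitted and
#' the scan advances past it. Residues that match no core word accumulate
#' into a pending run, emitted as a single fallback word when a match resumes
#' or the sequence ends. Matching uses core words only, so segmentation does
#' not depend on which fallback words earlier sequences produced. The
#' concatenation of the returned tokens always reproduces the input exactly.
#'
#' @param sequence A single amino-acid string (uppercase letters; nonstandard
#'   residue letters pass through into fallback runs).
#' @param vocab A `word_vocabulary`.
#' @return Character vector of tokens (empty for the empty sequence).
#' @export
segment <- function(sequence, vocab) {
  stopifnot(is_string(sequence) || (is.character(sequence) && length(sequence) == 1))
  stopifnot(inherits(vocab, "word_vocabulary"))
  L <- nchar(sequence)
  if (L == 0L) return(character(0))
  k_min <- vocab$k_range[1]
  k_max <- vocab$k_range[2]
  env <- vocab$.core
  tokens <- character(0)
  run_start <- 0L  # 0 = no pending run
  pos <- 1L
  while (pos <= L) {
    matched <- 0L
    hi <- min(k_max, L - pos + 1L)
    if (length(vocab$core_counts) > 0L && hi >= k_min) {
      for (k in hi:k_min) {
        w <- substr(sequence, pos, pos + k - 1L)
        if (exists(w, envir = env, inherits = FALSE)) {
          matched <- k
          break
        }
      }
    }
    if (matched > 0L) {
      if (run_start > 0L) {
        tokens <- c(tokens, substr(sequence, run_start, pos - 1L))
        run_start <- 0L
      }
      tokens <- c(tokens, substr(sequence, pos, pos + matched - 1L))
      pos <- pos + matched
    } else {
      if (run_start == 0L) run_start <- pos
      pos <- pos + 1L
    }
  }
  if (run_start > 0L) tokens <- c(tokens, substr(sequence, run_start, L))
  tokens
}

#' Segment a whole corpus and accumulate fallback words
#'
#' Applies [segment()] to every sequence and records each emitted fallback
#' word (a token that is not a core word) in the returned vocabulary's
#' `fallback_counts`. Fallback words never participate in matching, so
#' re-tokenizing with the updated vocabulary reproduces the same sentences.
#'
#' @param sequences Named character vector or named list, protein id ->
#'   sequence. Ids must be unique.
#' @param vocab A `word_vocabulary`.
#' @return List with `sentences` (named list of token vectors, in input
#'   order) and `vocab` (the vocabulary with fallback words added).
#' @export
tokenize_corpus <- function(sequences, vocab) {
  ids <- names(sequences)
  if (is.null(ids) || any(ids == "")) stop2("sequences must be named by protein id")
  if (anyDuplicated(ids)) {
    stop2("duplicate protein id: ", ids[duplicated(ids)][[1L]])
  }
  sentences <- vector("list", length(sequences))
  names(sentences) <- ids
  fallback <- vocab$fallback_counts
  core_env <- vocab$.core
  for (id in ids) {
    toks <- segment(as.character(sequences[[id]]), vocab)
    sentences[[id]] <- toks
    fb <- toks[!vapply(toks, exists, logical(1),
                       envir = core_env, inherits = FALSE)]
    if (length(fb) > 0L) {
      tab <- table(fb)
      for (w in names(tab)) {
        fallback[[w]] <- (if (w %in% names(fallback)) fallback[[w]] else 0L) +
          as.integer(tab[[w]])
      }
    }
  }
  vocab2 <- new_word_vocabulary(vocab$core_counts, fallback, vocab$min_freq,
                                vocab$k_range)
  list(sentences = sentences, vocab = vocab2)
}

#' Read and write a word vocabulary as plain text
#'
#' Format: one word per line, `word<TAB>count<TAB>kind` with kind `core` or
#' `fallback`, plus a `#` header carrying `min_freq` and the k range.
#'
#' @param vocab A `word_vocabulary`.
#' @param path File path.
#' @return `write_vocabulary()` returns the path invisibly;
#'   `read_vocabulary()` returns a `word_vocabulary`.
#' @export
write_vocabulary <- function(vocab, path) {
  hdr <- sprintf("# min_freq=%d k_min=%d k_max=%d", vocab$min_freq,
                 vocab$k_range[1], vocab$k_range[2])
  core <- sprintf("%s\t%d\tcore", names(vocab$core_counts), vocab$core_counts)
  fb <- sprintf("%s\t%d\tfallback", names(vocab$fallback_counts),
                vocab$fallback_counts)
  writeLines(c(hdr, core, fb), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  lines <- read_lines_flex(path)
  hdr <- lines[[1L]]
  m <- regmatches(hdr, regexec(
    "min_freq=([0-9]+) k_min=([0-9]+) k_max=([0-9]+)", hdr))[[1L]]
  if (length(m) != 4L) stop2("malformed vocabulary header: ", hdr)
  body <- lines[-1L][nzchar(lines[-1L])]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 3L)
  if (length(bad) > 0L) stop2("malformed vocabulary line ", bad[[1L]] + 1L)
  words <- vapply(parts, `[[`, character(1), 1L)
  counts <- as.integer(vapply(parts, `[[`, character(1), 2L))
  kind <- vapply(parts, `[[`, character(1), 3L)
  new_word_vocabulary(setNames(counts[kind == "core"], words[kind == "core"]),
                      setNames(counts[kind == "fallback"], words[kind == "fallback"]),
                      as.integer(m[[2L]]),
                      c(as.integer(m[[3L]]), as.integer(m[[4L]])))
}
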