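# Base-26 letter codes for GO terms and the deterministic post-order DFS
# numbering that defines them.

ALPHABET_MAX <- 26L^4L  # four letters: 456,976 ordinals

#' Encode 1-based ordinals as base-26 letter codes
#'
#' Ordinal `n` is encoded as the minimal base-26 representation of `n - 1`
#' with digit map 0 -> "A" ... 25 -> "Z". Codes are 1-4 letters long; a
#' multi-letter code never starts with "A" (no leading zeros). Examples:
#' 1 -> "A", 26 -> "Z", 27 -> "BA", 28678 -> "BQKZ".
#'
#' @param ordinal Integer vector of ordinals in `1 .. 26^4`.
#' @return Character vector of letter codes.
#' @export
encode_ordinal <- function(ordinal) {
  if (length(ordinal) == 0L) return(character(0))
  if (any(is.na(ordinal)) || any(ordinal != floor(ordinal))) {
    stop2("ordinals must be whole numbers")
  }
  if (any(ordinal < 1)) stop2("ordinal must be >= 1")
  if (any(ordinal > ALPHABET_MAX)) {
    stop2("ordinal exceeds four-letter capacity 26^4 = ", ALPHABET_MAX)
  }
  m <- as.numeric(ordinal) - 1
  d1 <- m %/% 17576 %% 26
  d2 <- m %/% 676 %% 26
  d3 <- m %/% 26 %% 26
  d4 <- m %% 26
  full <- paste0(LETTERS[d1 + 1], LETTERS[d2 + 1], LETTERS[d3 + 1], LETTERS[d4 + 1])
  len <- 1L + (m >= 26) + (m >= 676) + (m >= 17576)
  substring(full, 5L - len, 4L)
}

#' Decode base-26 letter codes back to ordinals
#'
#' Exact inverse of [encode_ordinal()].
#'
#' @param code Character vector of 1-4 uppercase letter codes.
#' @return Integer vector of 1-based ordinals.
#' @export
decode_alphabet <- function(code) {
  if (length(code) == 0L) return(integer(0))
  if (!is.character(code)) stop2("code must be character")
  len <- nchar(code)
  if (any(is.na(code)) || any(len < 1L) || any(len > 4L)) {
    stop2("codes must be 1-4 letters long")
  }
  if (any(!grepl("^[A-Z]+$", code))) {
    stop2("codes must contain only uppercase letters A-Z")
  }
  val <- numeric(length(code))
  for (j in 1:4) {
    ch <- substr(code, j, j)
    has <- nchar(code) >= j
    digit <- ifelse(has, match(ch, LETTERS) - 1L, 0L)
    # positional weight depends on code length: digit j of an l-letter code
    # has weight 26^(l - j)
    w <- ifelse(has, 26^(len - j), 0)
    val <- val + digit * w
  }
  as.integer(val + 1)
}

#' Deterministic post-order DFS numbering of a GO DAG
#'
#' Assigns each term a 1-based ordinal by depth-first search from each
#' namespace root, expanding children in ascending term-id order and numbering
#' a term when all of its not-yet-visited descendants are exhausted
#' (post-order, so each root receives the largest ordinal of its namespace
#' block). A term reachable along several paths is numbered once, on first
#' completion. Namespaces are processed in the fixed order biological_process,
#' cellular_component, molecular_function with continuous numbering across
#' them, so codes are globally unique.
#'
#' @param dag A `go_dag`.
#' @return An object of class `go_dfs_ordering`: list with `ordinal`
#'   (named integer vector, by term id) and `go_id` (character vector indexed
#'   by ordinal).
#' @export
dfs_postorder <- function(dag) {
  stopifnot(inherits(dag, "go_dag"))
  ordinal <- integer(0)
  counter <- 0L
  for (ns in GO_NAMESPACES) {
    if (!ns %in% names(dag$roots)) next
    root <- dag$roots[[ns]]
    visited <- new.env(parent = emptyenv())
    # iterative DFS: stack of (node, next-child index)
    nodes <- root
    child_idx <- 1L
    kids <- list(sort(dag$children[[root]]))
    assign(root, TRUE, envir = visited)
    idx_stack <- 1L
    while (length(nodes) > 0L) {
      top <- length(nodes)
      node <- nodes[[top]]
      ks <- kids[[top]]
      i <- idx_stack[[top]]
      advanced <- FALSE
      while (i <= length(ks)) {
        ch <- ks[[i]]
        i <- i + 1L
        if (!exists(ch, envir = visited, inherits = FALSE)) {
          idx_stack[[top]] <- i
          nodes <- c(nodes, ch)
          kids[[top + 1L]] <- sort(dag$children[[ch]])
          idx_stack[[top + 1L]] <- 1L
          assign(ch, TRUE, envir = visited)
          advanced <- TRUE
          break
        }
      }
      if (!advanced) {
        counter <- counter + 1L
        ordinal[[node]] <- counter
        nodes <- nodes[-top]
        kids[[top]] <- NULL
        idx_stack <- idx_stack[-top]
      }
    }
  }
  if (length(ordinal) != length(dag$ids)) {
    # terms unreachable from their root would violate go_dag invariants
    stop2("DFS did not reach every term; DAG invariants violated")
  }
  go_id <- character(length(ordinal))
  go_id[ordinal] <- names(ordinal)
  structure(list(ordinal = ordinal[sort(names(ordinal))], go_id = go_id),
            class = "go_dfs_ordering")
}

#' @export
print.go_dfs_ordering <- function(x, ...) {
  cat("go_dfs_ordering over", length(x$go_id), "terms\n")
  invisible(x)
}

#' Convert between GO term ids and letter codes
#'
#' `term_to_alphabet()` maps a term id to its base-26 code via the DFS
#' ordinal; `alphabet_to_term()` is its inverse. The two are mutually inverse
#' for every term covered by the ordering.
#'
#' @param ordering A `go_dfs_ordering` from [dfs_postorder()].
#' @param go_id Character vector of term ids.
#' @param code Character vector of letter codes.
#' @return Character vector of codes, respectively term ids.
#' @export
term_to_alphabet <- function(ordering, go_id) {
  ord <- ordering$ordinal[go_id]
  if (anyNA(ord)) {
    stop2("GO id(s) not in ordering: ",
          paste(head(go_id[is.na(ord)], 5L), collapse = ", "))
  }
  encode_ordinal(unname(ord))
}

#' @rdname term_to_alphabet
#' @export
alphabet_to_term <- function(ordering, code) {
  ord <- decode_alphabet(code)
  if (any(ord > length(ordering$go_id))) {
    stop2("code(s) decode beyond the ordering: ",
          paste(head(code[ord > length(ordering$go_id)], 5L), collapse = ", "))
  }
  ordering$go_id[ord]
}

#' Convert an ordered GO annotation record to a code-word sentence
#'
#' Each term id becomes its letter code; the order of the input record is
#' preserved and duplicate terms are dropped, keeping the first occurrence.
#'
#' @param ordering A `go_dfs_ordering`.
#' @param go_ids Ordered character vector of term ids (one annotation record).
#' @return Character vector of letter codes (a "GO language" sentence).
#' @export
annotation_to_golan <- function(ordering, go_ids) {
  if (length(go_ids) == 0L) return(character(0))
  go_ids <- go_ids[!duplicated(go_ids)]
  term_to_alphabet(ordering, go_ids)
}

#' Write the term-id to letter-code mapping as a two-column TSV
#'
#' One row per term: `GO:NNNNNNN<TAB>code`, in ordinal order, for audit.
#'
#' @param ordering A `go_dfs_ordering`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_alphabet_map <- function(ordering, path) {
  codes <- encode_ordinal(seq_along(ordering$go_id))
  writeLines(paste(ordering$go_id, codes, sep = "\t"), path)
  invisible(path)
}
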