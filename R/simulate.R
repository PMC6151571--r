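# Seeded synthetic ontologies and motif-planted annotated protein corpora.
# These emulate the statistical structure the translation method assumes:
# recurrent sequence motifs co-occurring with specific GO terms.

#' Configuration for the synthetic ontology and corpus generators
#'
#' @param seed RNG seed; every generator output is byte-identical for a
#'   given config.
#' @param terms_per_namespace Terms per namespace; scalar or a vector named
#'   by namespace (namespaces with 0 terms are omitted).
#' @param max_parents Maximum parents per non-root term (default 2).
#' @param n_proteins Corpus size (default 150).
#' @param seq_len_range Background sequence length range (default 80..120
#'   residues).
#' @param motif_len_range Motif length range; should lie within the
#'   tokenizer's k range (default 4..5).
#' @param terms_per_protein Range of true terms per protein (default 1..3).
#' @param insertions_per_term Motif copies planted per kept true term
#'   (default 2).
#' @param dropout Probability that a true term's motif is omitted from the
#'   sequence (default 0, the zero-noise setting).
#' @param spurious_rate Per-protein expected number of spurious motif
#'   insertions (motifs of terms the protein is not annotated with;
#'   default 0).
#' @param part_of_prob Probability that a parent edge is `part_of` rather
#'   than `is_a` (default 0.2).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, terms_per_namespace = 8L, max_parents = 2L,
                       n_proteins = 150L, seq_len_range = c(80L, 120L),
                       motif_len_range = c(4L, 5L),
                       terms_per_protein = c(1L, 3L),
                       insertions_per_term = 2L, dropout = 0,
                       spurious_rate = 0, part_of_prob = 0.2) {
  if (length(terms_per_namespace) == 1L && is.null(names(terms_per_namespace))) {
    terms_per_namespace <- setNames(rep(as.integer(terms_per_namespace), 3L),
                                    GO_NAMESPACES)
  }
  if (all(terms_per_namespace < 1L)) stop2("need at least one term")
  stopifnot(max_parents >= 1L, n_proteins >= 1L,
            dropout >= 0, dropout < 1, spurious_rate >= 0,
            insertions_per_term >= 1L)
  structure(list(seed = as.integer(seed),
                 terms_per_namespace = terms_per_namespace,
                 max_parents = as.integer(max_parents),
                 n_proteins = as.integer(n_proteins),
                 seq_len_range = as.integer(seq_len_range),
                 motif_len_range = as.integer(motif_len_range),
                 terms_per_protein = as.integer(terms_per_protein),
                 insertions_per_term = as.integer(insertions_per_term),
                 dropout = dropout, spurious_rate = spurious_rate,
                 part_of_prob = part_of_prob),
            class = "sim_config")
}

#' Simulate a random GO DAG and its OBO 1.2 text
#'
#' Per namespace, term 1 is the root and each later term attaches to
#' 1..`max_parents` uniformly chosen earlier terms of the same namespace, so
#' the graph is acyclic by construction. The emitted OBO text parses back
#' (via [parse_obo()]) into an identical DAG.
#'
#' @param config A [sim_config()].
#' @return List with `dag` (a `go_dag`) and `obo` (character scalar,
#'   OBO 1.2 text).
#' @export
simulate_dag <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    stanzas <- character(0)
    counter <- 0L
    for (ns in GO_NAMESPACES) {
      n <- config$terms_per_namespace[ns]
      if (is.na(n) || n < 1L) next
      ids <- sprintf("GO:%07d", counter + seq_len(n))
      counter <- counter + n
      for (i in seq_len(n)) {
        lines <- c("[Term]",
                   paste0("id: ", ids[[i]]),
                   paste0("name: synthetic term ", ids[[i]]),
                   paste0("namespace: ", ns))
        if (i > 1L) {
          k <- sample.int(min(config$max_parents, i - 1L), 1L)
          parents <- ids[sample.int(i - 1L, k)]
          for (p in parents) {
            if (runif(1) < config$part_of_prob) {
              lines <- c(lines, paste0("relationship: part_of ", p))
            } else {
              lines <- c(lines, paste0("is_a: ", p))
            }
          }
        }
        stanzas <- c(stanzas, paste(lines, collapse = "\n"))
      }
    }
    obo <- paste(c("format-version: 1.2", "", paste(stanzas, collapse = "\n\n"),
                   ""), collapse = "\n")
    list(dag = parse_obo(obo), obo = obo)
  })
}

random_peptide <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# uniform integer in [a, b] (safe for a == b, unlike sample())
rint <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L

# One attempt at a background sequence with the given motifs planted at
# non-overlapping positions and no motif occurrence anywhere else. Chance
# occurrences in background-only positions are resampled; if a stray
# occurrence cannot be scrubbed without touching a planted window, the
# attempt is abandoned (returns NULL) and the caller restarts.
build_planted_sequence <- function(config, ins_motifs, all_motifs) {
  L <- rint(config$seq_len_range[1L], config$seq_len_range[2L])
  seq <- random_peptide(L)
  pos <- integer(0)
  lens <- integer(0)
  for (m in ins_motifs) {
    ml <- nchar(m)
    placed <- FALSE
    for (attempt in 1:200) {
      p <- rint(1L, L - ml + 1L)
      if (!any(p <= pos + lens - 1L & p + ml - 1L >= pos)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
    substr(seq, p, p + ml - 1L) <- m
    pos <- c(pos, p)
    lens <- c(lens, ml)
  }
  in_planted <- logical(L)
  for (j in seq_along(pos)) in_planted[pos[j]:(pos[j] + lens[j] - 1L)] <- TRUE
  for (round in 1:100) {
    hits <- motif_hits(seq, all_motifs)
    if (!is.null(hits)) {
      legit <- paste(pos, ins_motifs)
      hits <- hits[!paste(hits$start, hits$motif) %in% legit, , drop = FALSE]
    }
    if (is.null(hits) || nrow(hits) == 0L) {
      return(list(seq = seq, pos = pos))
    }
    for (r in seq_len(nrow(hits))) {
      win <- hits$start[r]:(hits$start[r] + hits$len[r] - 1L)
      bg <- win[!in_planted[win]]
      if (length(bg) == 0L) return(NULL)  # stray spelled by planted windows
      substr(seq, bg[1L], bg[1L]) <- random_peptide(1L)
    }
  }
  NULL
}

# all occurrences of the motifs in `seq`: data.frame(start, len, motif)
motif_hits <- function(seq, motifs) {
  out <- lapply(motifs, function(m) {
    st <- gregexpr(m, seq, fixed = TRUE)[[1L]]
    st <- st[st > 0L]
    if (length(st) == 0L) return(NULL)
    data.frame(start = st, len = nchar(m), motif = m)
  })
  do.call(rbind, out)
}

#' Simulate a motif-planted annotated protein corpus
#'
#' Each protein draws its true terms uniformly from the leaf terms of the
#' DAG; each leaf term carries a distinct random motif. For every kept
#' (non-dropped-out) true term, `insertions_per_term` copies of its motif are
#' planted at non-overlapping positions in an i.i.d.-uniform background
#' sequence; spurious motifs (from unannotated terms) are planted at rate
#' `spurious_rate`. Background residues are resampled wherever they happen
#' to spell an unplanted motif, so at zero noise motif presence reflects
#' annotation exactly — which is what makes the baseline's conditional
#' probabilities exactly 1 on such a corpus.
#'
#' @param dag A `go_dag` (typically from [simulate_dag()]).
#' @param config A [sim_config()] (the same seed gives a byte-identical
#'   corpus).
#' @return List with `fasta` (FASTA text), `annotations` (named list,
#'   protein -> term ids), `truth` (list: `term_motif` named character,
#'   `protein_terms`, `planted` per-protein motif position data frames).
#' @export
simulate_corpus <- function(dag, config) {
  stopifnot(inherits(dag, "go_dag"), inherits(config, "sim_config"))
  with_local_seed(config$seed + 1L, {
    leaves <- dag$ids[vapply(dag$children[dag$ids], length, integer(1)) == 0L]
    if (length(leaves) == 0L) stop2("DAG has no leaf terms")
    # injective term -> motif assignment; no motif may contain another,
    # or planting one could spell the other
    term_motif <- character(0)
    tries <- 0L
    for (g in leaves) {
      repeat {
        tries <- tries + 1L
        if (tries > 1000L * length(leaves)) {
          stop2("could not draw ", length(leaves),
                " mutually substring-free motifs; enlarge motif_len_range")
        }
        len <- rint(config$motif_len_range[1L], config$motif_len_range[2L])
        m <- random_peptide(len)
        clash <- any(vapply(term_motif, function(x) {
          grepl(m, x, fixed = TRUE) || grepl(x, m, fixed = TRUE)
        }, logical(1)))
        if (!clash && !m %in% term_motif) break
      }
      term_motif[[g]] <- m
    }

    ids <- sprintf("prot%04d", seq_len(config$n_proteins))
    seqs <- character(length(ids))
    annotations <- setNames(vector("list", length(ids)), ids)
    planted <- setNames(vector("list", length(ids)), ids)
    all_motifs <- unname(term_motif)

    for (i in seq_along(ids)) {
      k <- rint(config$terms_per_protein[1L],
                min(config$terms_per_protein[2L], length(leaves)))
      terms <- sample(leaves, k)
      annotations[[i]] <- terms
      kept <- terms[runif(k) >= config$dropout]
      ins_motifs <- rep(unname(term_motif[kept]),
                        each = config$insertions_per_term)
      if (config$spurious_rate > 0) {
        n_spur <- stats::rpois(1L, config$spurious_rate)
        spur_pool <- setdiff(leaves, terms)
        if (n_spur > 0L && length(spur_pool) > 0L) {
          ins_motifs <- c(ins_motifs, unname(
            term_motif[spur_pool[sample.int(length(spur_pool), n_spur,
                                            replace = TRUE)]]))
        }
      }
      built <- NULL
      for (restart in 1:50) {
        built <- build_planted_sequence(config, ins_motifs, all_motifs)
        if (!is.null(built)) break
      }
      if (is.null(built)) {
        stop2("could not build a clean motif-planted sequence; ",
              "increase seq_len_range or reduce insertions")
      }
      seqs[[i]] <- built$seq
      planted[[i]] <- data.frame(motif = ins_motifs, start = built$pos)
    }
    fasta <- paste0(">", ids, "\n", seqs, collapse = "\n")
    list(fasta = paste0(fasta, "\n"),
         annotations = annotations,
         truth = list(term_motif = term_motif,
                      protein_terms = annotations,
                      planted = planted))
  })
}
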