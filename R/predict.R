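# Prediction post-processing: descendant expansion with decayed scores, the
# weighted model combiner, and the noisy-OR probabilistic baseline.

#' Expand scored GO terms with decay-scored descendants
#'
#' Adds every descendant of each input term to the set. A descendant at
#' shortest-path edge distance `k` below an original term scoring `s0`
#' receives `s0 * rate^k`, so terms far from the original annotation score
#' lower; a term reachable from several originals keeps the maximum score.
#' Used both to build the long training targets of the extended translation
#' model (scores ignored there) and to post-process predictions.
#'
#' @param dag A `go_dag`.
#' @param terms Data frame with columns `go_id`, `score` (scores in (0, 1]).
#' @param rate Decay per edge, in (0, 1] (default 0.8).
#' @return Data frame `go_id`, `score`, sorted by descending score then term
#'   id, deduplicated.
#' @export
expand_with_descendants <- function(dag, terms, rate = 0.8) {
  stopifnot(rate > 0, rate <= 1)
  terms <- as.data.frame(terms)
  assert_in_dag(dag, terms$go_id)
  best <- setNames(terms$score, terms$go_id)
  # keep max when the same term is listed twice
  if (anyDuplicated(terms$go_id)) {
    best <- tapply(terms$score, terms$go_id, max)
  }
  for (i in seq_len(nrow(terms))) {
    dist <- descendant_distances(dag, terms$go_id[[i]])
    if (length(dist) == 0L) next
    sc <- terms$score[[i]] * rate^dist
    upd <- names(dist)
    cur <- best[upd]
    cur[is.na(cur)] <- -Inf
    take <- sc > cur
    best[upd[take]] <- sc[take]
  }
  out <- data.frame(go_id = names(best), score = as.numeric(best))
  out <- out[order(-out$score, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ordered term list plus all descendants (for extended training targets)
#'
#' Original terms keep their record order; descendants follow, ordered by
#' distance from their nearest original, then term id.
#'
#' @param dag A `go_dag`.
#' @param go_ids Ordered character vector of term ids.
#' @return Character vector of term ids, originals first.
#' @export
extend_terms <- function(dag, go_ids) {
  go_ids <- go_ids[!duplicated(go_ids)]
  assert_in_dag(dag, go_ids)
  dist_all <- numeric(0)
  for (g in go_ids) {
    dist <- descendant_distances(dag, g)
    for (d in names(dist)) {
      if (is.na(dist_all[d]) || dist[[d]] < dist_all[[d]]) {
        dist_all[d] <- dist[[d]]
      }
    }
  }
  desc <- setdiff(names(dist_all), go_ids)
  if (length(desc) > 0L) desc <- desc[order(dist_all[desc], desc)]
  c(go_ids, desc)
}

#' Combination weights for the two translation models
#'
#' Weights are proportional to each model's area under the precision-recall
#' curve (top-n points, n = 1..10) on data with known truth:
#' `w_i = AUPR_i / (AUPR_nmt + AUPR_ext)`. If both areas are zero the
#' weights fall back to (0.5, 0.5) with a warning.
#'
#' @param preds_nmt,preds_ext `prediction_set`s from the two models over the
#'   same proteins.
#' @param truth Named list, protein id -> character vector of true term ids.
#' @param dag A `go_dag`.
#' @param n_range Top-n values for the PR curve (default 1:10).
#' @return List with `w_nmt`, `w_ext` (summing to 1) and the two AUPRs.
#' @export
calibrate_weights <- function(preds_nmt, preds_ext, truth, dag,
                              n_range = 1:10) {
  aupr <- function(preds) {
    pts <- pr_curve(preds, truth, dag, n = n_range)
    pr_auc(pts)
  }
  a1 <- aupr(preds_nmt)
  a2 <- aupr(preds_ext)
  if (a1 + a2 == 0) {
    warning("both models have zero PR area; falling back to equal weights",
            call. = FALSE)
    return(list(w_nmt = 0.5, w_ext = 0.5, aupr_nmt = a1, aupr_ext = a2))
  }
  list(w_nmt = a1 / (a1 + a2), w_ext = a2 / (a1 + a2),
       aupr_nmt = a1, aupr_ext = a2)
}

#' Combine two prediction sets with performance weights
#'
#' For each (protein, term), the combined score is
#' `max(w_nmt * s_nmt, w_ext * s_ext)` with a missing score treated as 0;
#' terms whose combined score is 0 are dropped.
#'
#' @param preds_nmt,preds_ext `prediction_set`s.
#' @param weights List with `w_nmt`, `w_ext` in \[0, 1\] summing to 1 (e.g.
#'   from [calibrate_weights()]).
#' @return A `prediction_set` over the union of proteins.
#' @export
combine_predictions <- function(preds_nmt, preds_ext, weights) {
  w1 <- weights$w_nmt
  w2 <- weights$w_ext
  stopifnot(w1 >= 0, w2 >= 0, abs(w1 + w2 - 1) < 1e-8)
  prots <- union(names(preds_nmt), names(preds_ext))
  out <- lapply(prots, function(pid) {
    d1 <- preds_nmt[[pid]]
    d2 <- preds_ext[[pid]]
    s1 <- if (is.null(d1)) numeric(0) else setNames(d1$score, d1$go_id)
    s2 <- if (is.null(d2)) numeric(0) else setNames(d2$score, d2$go_id)
    ids <- union(names(s1), names(s2))
    sc <- pmax(w1 * ifelse(is.na(s1[ids]), 0, s1[ids]),
               w2 * ifelse(is.na(s2[ids]), 0, s2[ids]))
    keep <- sc > 0
    data.frame(go_id = ids[keep], score = unname(sc[keep]))
  })
  names(out) <- prots
  prediction_set(out)
}

#' Fit the noisy-OR conditional probability table
#'
#' For every protein word `x` and term `y`,
#' `P(y | x) = (# proteins whose sentence contains x and whose annotation
#' contains y) / (# proteins whose sentence contains x)` — a word counts
#' once per protein at fit time (document frequency), however often it
#' repeats within the sentence.
#'
#' @param sentences Named list, protein id -> token vector.
#' @param annotations Named list, protein id -> character vector of term
#'   ids. Every annotated protein must have a sentence.
#' @return A `conditional_table`: list with `prob` (named list, word ->
#'   named numeric vector of P(term|word)) and `word_df` (named integer,
#'   word document frequencies).
#' @export
fit_baseline <- function(sentences, annotations) {
  missing <- setdiff(names(annotations), names(sentences))
  if (length(missing) > 0L) {
    stop2("annotated protein(s) without a sentence: ",
          paste(head(missing, 5L), collapse = ", "))
  }
  word_df <- new.env(parent = emptyenv())
  joint <- new.env(parent = emptyenv())  # word -> env(term -> count)
  for (pid in names(sentences)) {
    words <- unique(sentences[[pid]])
    terms <- unique(annotations[[pid]])
    for (w in words) {
      word_df[[w]] <- (word_df[[w]] %||% 0L) + 1L
      if (length(terms) > 0L) {
        te <- joint[[w]]
        if (is.null(te)) {
          te <- new.env(parent = emptyenv())
          joint[[w]] <- te
        }
        for (g in terms) te[[g]] <- (te[[g]] %||% 0L) + 1L
      }
    }
  }
  words <- ls(word_df)
  prob <- setNames(vector("list", length(words)), words)
  df <- setNames(integer(length(words)), words)
  for (w in words) {
    df[[w]] <- word_df[[w]]
    te <- joint[[w]]
    if (!is.null(te)) {
      gs <- ls(te)
      prob[[w]] <- setNames(
        vapply(gs, function(g) te[[g]], integer(1)) / df[[w]], gs)
    } else {
      prob[[w]] <- setNames(numeric(0), character(0))
    }
  }
  structure(list(prob = prob, word_df = df), class = "conditional_table")
}

#' @export
print.conditional_table <- function(x, ...) {
  cat("conditional_table:", length(x$word_df), "words,",
      sum(vapply(x$prob, length, integer(1))), "(word, term) probabilities\n")
  invisible(x)
}

#' Score GO terms for one sentence with the noisy-OR rule
#'
#' Each candidate term `y` with a nonzero conditional probability for any
#' sentence word is scored `1 - prod_i (1 - P(y | x_i))` over all token
#' occurrences `x_i` (a word repeated in the sentence contributes one factor
#' per occurrence). Words absent from the table contribute nothing.
#'
#' @param sentence Character vector of tokens.
#' @param table A `conditional_table` from [fit_baseline()].
#' @return Data frame `go_id`, `score`, sorted by descending score then term
#'   id; empty for an empty sentence.
#' @export
predict_baseline <- function(sentence, table) {
  if (length(sentence) == 0L) {
    return(data.frame(go_id = character(0), score = numeric(0)))
  }
  log_fail <- new.env(parent = emptyenv())  # term -> sum of log(1 - P)
  hit_one <- character(0)                   # terms with some P == 1
  for (w in sentence) {
    pv <- table$prob[[w]]
    if (is.null(pv) || length(pv) == 0L) next
    for (g in names(pv)) {
      p <- pv[[g]]
      if (p >= 1) {
        hit_one <- c(hit_one, g)
      } else {
        log_fail[[g]] <- (log_fail[[g]] %||% 0) + log1p(-p)
      }
    }
  }
  gs <- union(ls(log_fail), unique(hit_one))
  if (length(gs) == 0L) {
    return(data.frame(go_id = character(0), score = numeric(0)))
  }
  score <- vapply(gs, function(g) {
    if (g %in% hit_one) return(1)
    -expm1(log_fail[[g]])
  }, numeric(1))
  out <- data.frame(go_id = gs, score = unname(score))
  out <- out[order(-out$score, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Persist and restore a conditional probability table as text
#'
#' Three tab-separated columns: word, GO id, probability.
#'
#' @param table A `conditional_table`.
#' @param path File path.
#' @return `write_conditional_table()` the path invisibly;
#'   `read_conditional_table()` a `conditional_table`.
#' @export
write_conditional_table <- function(table, path) {
  lines <- character(0)
  for (w in names(table$prob)) {
    pv <- table$prob[[w]]
    if (length(pv) > 0L) {
      lines <- c(lines, sprintf("%s\t%s\t%.10g", w, names(pv), pv))
    }
  }
  hdr <- sprintf("# word_df %s=%d", names(table$word_df), table$word_df)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_conditional_table
#' @export
read_conditional_table <- function(path) {
  lines <- read_lines_flex(path)
  hdr <- lines[startsWith(lines, "# word_df ")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  m <- regmatches(hdr, regexec("^# word_df (.*)=([0-9]+)$", hdr))
  word_df <- setNames(as.integer(vapply(m, `[[`, character(1), 3L)),
                      vapply(m, `[[`, character(1), 2L))
  prob <- list()
  if (length(body) > 0L) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    ws <- vapply(parts, `[[`, character(1), 1L)
    gs <- vapply(parts, `[[`, character(1), 2L)
    ps <- as.numeric(vapply(parts, `[[`, character(1), 3L))
    for (w in unique(ws)) {
      sel <- ws == w
      prob[[w]] <- setNames(ps[sel], gs[sel])
    }
  }
  for (w in setdiff(names(word_df), names(prob))) {
    prob[[w]] <- setNames(numeric(0), character(0))
  }
  structure(list(prob = prob, word_df = word_df), class = "conditional_table")
}

#' Translate tokenized proteins into scored GO-term predictions
#'
#' Runs greedy decoding on each sentence, maps the emitted code words back to
#' GO term ids through the DFS ordering, and optionally applies
#' [expand_with_descendants()] to the decoded terms.
#'
#' @param model A trained `seq2seq_model` whose target language is the
#'   code-word language of `ordering`.
#' @param sentences Named list, protein id -> token vector.
#' @param ordering A `go_dfs_ordering`.
#' @param dag A `go_dag`; required when `expand_rate` is given.
#' @param expand_rate Optional decay rate for descendant expansion.
#' @return A `prediction_set`.
#' @export
translate_to_terms <- function(model, sentences, ordering, dag = NULL,
                               expand_rate = NULL) {
  out <- lapply(sentences, function(s) {
    dec <- nmt_translate(model, s)
    ok <- grepl("^[A-Z]{1,4}$", dec$tokens)
    ok[ok] <- decode_alphabet(dec$tokens[ok]) <= length(ordering$go_id)
    if (!any(ok)) return(data.frame(go_id = character(0), score = numeric(0)))
    df <- data.frame(go_id = alphabet_to_term(ordering, dec$tokens[ok]),
                     score = dec$scores[ok])
    if (!is.null(expand_rate)) {
      stopifnot(!is.null(dag))
      df <- expand_with_descendants(dag, df, expand_rate)
    }
    df
  })
  prediction_set(out)
}
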