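# Shared fixtures, built in code.

# Diamond ontology: root R with children A and B, C a child of both.
diamond_obo <- function() {
  paste(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: R", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: A", "namespace: biological_process",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: B", "namespace: biological_process",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000004", "name: C", "namespace: biological_process",
    "is_a: GO:0000002", "relationship: part_of GO:0000003",
    sep = "\n")
}

diamond_dag <- function() parse_obo(diamond_obo())

# short names for the diamond terms
D <- list(R = "GO:0000001", A = "GO:0000002", B = "GO:0000003", C = "GO:0000004")

# chain R <- A <- C (C below A below root R)
chain_dag <- function() {
  parse_obo(paste(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: R", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: A", "namespace: biological_process",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000004", "name: C", "namespace: biological_process",
    "is_a: GO:0000002",
    sep = "\n"))
}

# Deterministic toy translation language: 40 source words, 20 target tokens,
# each source word always emits one fixed target token; sentences use
# distinct targets so exact-sentence comparison is unaffected by
# deduplication in decoding.
make_toy_language <- function(seed, n_pairs = 300L) {
  withr::with_seed(seed, {
    tgt <- sprintf("t%02d", 1:20)
    src <- sprintf("w%02d", 1:40)
    map <- setNames(tgt[((seq_along(src) - 1L) %% 20L) + 1L], src)
    pairs <- lapply(seq_len(n_pairs), function(i) {
      k <- sample(1:5, 1L)
      ts <- sample(tgt, k)
      ws <- vapply(ts, function(tk) {
        cands <- names(map)[map == tk]
        cands[[sample.int(length(cands), 1L)]]
      }, character(1))
      list(source = unname(ws), target = unname(ts))
    })
    list(pairs = pairs, map = map)
  })
}

toy_buckets <- function() bucket_set(list(c(3, 3), c(5, 5)))

exact_sentence_accuracy <- function(model, pairs) {
  mean(vapply(pairs, function(p) {
    identical(nmt_translate(model, p$source)$tokens, p$target)
  }, logical(1)))
}

# Independent oracle for propagation-based precision/recall on the diamond
# fixture: closures are written out by hand and the metric is recomputed
# from first principles, without touching the package's graph code.
diamond_closure <- function(term) {
  switch(term,
         "GO:0000001" = "GO:0000001",
         "GO:0000002" = c("GO:0000002", "GO:0000001"),
         "GO:0000003" = c("GO:0000003", "GO:0000001"),
         "GO:0000004" = c("GO:0000004", "GO:0000002", "GO:0000003", "GO:0000001"))
}

oracle_pr <- function(pred_terms_by_protein, truth_by_protein, n) {
  precisions <- numeric(0)
  recalls <- numeric(0)
  for (pid in names(truth_by_protein)) {
    truth_prop <- unique(unlist(lapply(truth_by_protein[[pid]], diamond_closure)))
    sel <- head(pred_terms_by_protein[[pid]], n)
    if (length(sel) == 0L) {
      recalls <- c(recalls, 0)
      next
    }
    pred_prop <- unique(unlist(lapply(sel, diamond_closure)))
    correct <- sum(pred_prop %in% truth_prop)
    precisions <- c(precisions, correct / length(pred_prop))
    recalls <- c(recalls, correct / length(truth_prop))
  }
  list(precision = if (length(precisions)) mean(precisions) else NA_real_,
       recall = mean(recalls))
}
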