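test_that("descendant expansion applies the per-edge decay", {
  chain <- chain_dag()
  out <- expand_with_descendants(chain, data.frame(go_id = "GO:0000002",
                                                   score = 1.0), rate = 0.8)
  expect_equal(setNames(out$score, out$go_id),
               c("GO:0000002" = 1.0, "GO:0000004" = 0.8))
  # leaf input is returned unchanged
  leaf <- expand_with_descendants(chain, data.frame(go_id = "GO:0000004",
                                                    score = 0.6))
  expect_equal(leaf, data.frame(go_id = "GO:0000004", score = 0.6))
  # vanishing rate: descendants vanish, originals unchanged
  tiny <- expand_with_descendants(chain, data.frame(go_id = "GO:0000001",
                                                    score = 1.0), rate = 1e-9)
  expect_equal(tiny$score[tiny$go_id == "GO:0000001"], 1.0)
  expect_lt(max(tiny$score[tiny$go_id != "GO:0000001"]), 1e-8)
})

test_that("expansion keeps the maximum over multiple originals and counts sizes", {
  dag <- diamond_dag()
  # C is 1 edge below A (score 0.9) and 2 below R (score 1.0): 0.9*0.8 > 1*0.64
  out <- expand_with_descendants(
    dag, data.frame(go_id = c(D$R, D$A), score = c(1.0, 0.9)), rate = 0.8)
  expect_equal(out$score[out$go_id == D$C], 0.9 * 0.8)
  # output size = originals + union of descendant sets
  expect_equal(nrow(out), 4L)
  expect_error(expand_with_descendants(dag, data.frame(go_id = "GO:9999999",
                                                       score = 1)),
               "unknown")
})

test_that("extended targets list originals first, then descendants by depth", {
  dag <- diamond_dag()
  expect_equal(extend_terms(dag, D$R), c(D$R, D$A, D$B, D$C))
  expect_equal(extend_terms(dag, D$C), D$C)
  expect_equal(extend_terms(dag, c(D$A, D$B)), c(D$A, D$B, D$C))
})

test_that("combiner takes the weighted maximum and drops zero scores", {
  w <- list(w_nmt = 0.6, w_ext = 0.4)
  p1 <- prediction_set(list(p = data.frame(go_id = "GO:0000002", score = 0.5)))
  p2 <- prediction_set(list(p = data.frame(go_id = "GO:0000002", score = 0.9)))
  out <- combine_predictions(p1, p2, w)
  expect_equal(out$p$score, 0.36)  # max(0.6*0.5, 0.4*0.9)
  # a term present in only one model keeps its weighted score
  p3 <- prediction_set(list(p = data.frame(go_id = "GO:0000003", score = 0.8)))
  out2 <- combine_predictions(p1, p3, w)
  expect_equal(setNames(out2$p$score, out2$p$go_id),
               c("GO:0000003" = 0.32, "GO:0000002" = 0.3))
  # degenerate weights ignore the other model entirely
  out3 <- combine_predictions(p1, p2, list(w_nmt = 1, w_ext = 0))
  expect_equal(out3$p$score, 0.5)
  # equal inputs with equal weights halve all scores
  out4 <- combine_predictions(p1, p1, list(w_nmt = 0.5, w_ext = 0.5))
  expect_equal(out4$p$score, 0.25)
})

test_that("combiner weights are proportional to PR areas", {
  dag <- diamond_dag()
  truth <- list(p = c(D$A, D$B))
  # model 1's recall grows with n; model 2's recall is flat (zero area)
  m1 <- prediction_set(list(p = data.frame(go_id = c(D$A, D$B),
                                           score = c(0.9, 0.8))))
  m2 <- prediction_set(list(p = data.frame(go_id = D$C, score = 0.9)))
  w <- calibrate_weights(m1, m2, truth, dag)
  expect_gt(w$aupr_nmt, 0)
  expect_equal(w$aupr_ext, 0)
  expect_equal(c(w$w_nmt, w$w_ext), c(1, 0))
  # identical models split evenly
  w2 <- calibrate_weights(m1, m1, truth, dag)
  expect_equal(c(w2$w_nmt, w2$w_ext), c(0.5, 0.5))
  # both areas zero -> equal weights with a warning
  expect_warning(w3 <- calibrate_weights(m2, m2, truth, dag), "zero")
  expect_equal(c(w3$w_nmt, w3$w_ext), c(0.5, 0.5))
})

test_that("the conditional table counts words once per protein", {
  sentences <- list(p1 = c("w", "w", "a"), p2 = c("w", "b"))
  ann <- list(p1 = "GO:0000002", p2 = "GO:0000003")
  tab <- fit_baseline(sentences, ann)
  expect_equal(unname(tab$prob[["w"]][["GO:0000002"]]), 0.5)
  expect_equal(unname(tab$prob[["w"]][["GO:0000003"]]), 0.5)
  expect_equal(unname(tab$prob[["a"]][["GO:0000002"]]), 1.0)
  expect_false("GO:0000003" %in% names(tab$prob[["a"]]))
  expect_equal(unname(tab$word_df[["w"]]), 2L)
  expect_error(fit_baseline(sentences, list(p9 = "GO:0000002")),
               "without a sentence")
})

test_that("noisy-OR scoring multiplies over token occurrences", {
  tab <- structure(list(
    prob = list(x1 = c("GO:0000002" = 0.5), x2 = c("GO:0000002" = 0.5),
                x3 = c("GO:0000002" = 0.2), solo = c("GO:0000003" = 0.3)),
    word_df = c(x1 = 2L, x2 = 2L, x3 = 5L, solo = 10L)),
    class = "conditional_table")
  out <- predict_baseline(c("x1", "x2"), tab)
  expect_equal(out$score, 0.75)
  expect_equal(predict_baseline("solo", tab)$score, 0.3)
  out3 <- predict_baseline(c("x1", "x2", "x3"), tab)
  expect_equal(out3$score, 1 - 0.5 * 0.5 * 0.8)
  # duplicated word occurrences contribute one factor each
  out4 <- predict_baseline(c("x1", "x1"), tab)
  expect_equal(out4$score, 0.75)
  expect_equal(nrow(predict_baseline(character(0), tab)), 0L)
})

test_that("noisy-OR scores are monotone in added evidence and within [0, 1)", {
  set.seed(21)
  for (i in 1:20) {
    n_words <- sample(2:6, 1)
    probs <- runif(n_words, 0.05, 0.95)
    tab <- structure(list(
      prob = setNames(lapply(probs, function(p) c("GO:0000002" = p)),
                      paste0("w", seq_len(n_words))),
      word_df = setNames(rep(1L, n_words), paste0("w", seq_len(n_words)))),
      class = "conditional_table")
    words <- paste0("w", seq_len(n_words))
    prev <- 0
    for (k in seq_len(n_words)) {
      s <- predict_baseline(words[seq_len(k)], tab)$score
      expect_gte(s, prev)
      expect_lt(s, 1)
      prev <- s
    }
  }
})

test_that("conditional tables persist as three-column text", {
  sentences <- list(p1 = c("w", "a"), p2 = "w")
  ann <- list(p1 = "GO:0000002", p2 = "GO:0000003")
  tab <- fit_baseline(sentences, ann)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_conditional_table(tab, path)
  back <- read_conditional_table(path)
  expect_equal(back$word_df[sort(names(back$word_df))],
               tab$word_df[sort(names(tab$word_df))])
  for (w in names(tab$prob)) {
    expect_equal(back$prob[[w]][sort(names(back$prob[[w]]))],
                 tab$prob[[w]][sort(names(tab$prob[[w]]))])
  }
})
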