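test_that("propagation closes term sets over ancestors", {
  dag <- diamond_dag()
  expect_setequal(propagate(dag, D$C), c(D$C, D$A, D$B, D$R))
  expect_equal(propagate(dag, D$R), D$R)
  expect_equal(propagate(dag, character(0)), character(0))
  expect_error(propagate(dag, "GO:9999999"), "unknown")
})

test_that("precision/recall on the diamond fixture matches the hand trace", {
  dag <- diamond_dag()
  # truth {C} (closure size 4); predicting the ancestor A is fully correct
  preds <- prediction_set(list(p = data.frame(go_id = D$A, score = 0.9)))
  pr <- precision_recall(preds, list(p = D$C), dag, n = 1)
  expect_equal(pr$precision, 1.0)
  expect_equal(pr$recall, 0.5)
  # exact prediction gives 1/1
  preds2 <- prediction_set(list(p = data.frame(go_id = D$C, score = 0.9)))
  pr2 <- precision_recall(preds2, list(p = D$C), dag, n = 5)
  expect_equal(c(pr2$precision, pr2$recall), c(1, 1))
  # no predictions: recall 0, protein out of the precision mean
  pr3 <- precision_recall(prediction_set(list()), list(p = D$C), dag, n = 1)
  expect_equal(pr3$recall, 0)
  expect_equal(pr3$proteins_scored, 0L)
  expect_true(is.na(pr3$precision))
  # predictions without truth are skipped with a warning
  expect_warning(
    precision_recall(prediction_set(list(
      p = data.frame(go_id = D$C, score = 0.9),
      q = data.frame(go_id = D$C, score = 0.9))),
      list(p = D$C), dag, n = 1),
    "skipped")
})

test_that("an ancestor of a true term is always correct; a strict descendant only partially", {
  dag <- diamond_dag()
  # ancestor direction: prediction B for truth C
  prB <- precision_recall(prediction_set(list(
    p = data.frame(go_id = D$B, score = 1))), list(p = D$C), dag, n = 1)
  expect_equal(prB$precision, 1.0)
  # descendant direction: prediction C for truth A shares only {A, R}
  prC <- precision_recall(prediction_set(list(
    p = data.frame(go_id = D$C, score = 1))), list(p = D$A), dag, n = 1)
  expect_equal(prC$precision, 0.5)  # {A,R} of closure {C,A,B,R}
  expect_equal(prC$recall, 1.0)
})

test_that("precision/recall matches exhaustive enumeration over all truth subsets", {
  dag <- diamond_dag()
  all_terms <- c(D$R, D$A, D$B, D$C)
  pred_df <- data.frame(go_id = c(D$A, D$C, D$B),
                        score = c(0.9, 0.6, 0.3))
  preds <- prediction_set(list(p = pred_df))
  pred_order <- preds$p$go_id
  for (mask in 1:15) {
    truth <- all_terms[as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)))]
    for (n in 1:4) {
      got <- suppressWarnings(
        precision_recall(preds, list(p = truth), dag, n = n))
      want <- oracle_pr(list(p = pred_order), list(p = truth), n)
      expect_equal(got$precision, want$precision,
                   info = sprintf("mask=%d n=%d", mask, n))
      expect_equal(got$recall, want$recall,
                   info = sprintf("mask=%d n=%d", mask, n))
    }
  }
})

test_that("recall at top n is non-decreasing in n", {
  dag <- diamond_dag()
  preds <- prediction_set(list(
    p = data.frame(go_id = c(D$C, D$B, D$A), score = c(0.9, 0.5, 0.2)),
    q = data.frame(go_id = c(D$A, D$C), score = c(0.8, 0.4))))
  truth <- list(p = c(D$A, D$B), q = D$C)
  curve <- pr_curve(preds, truth, dag, n = 1:5)
  expect_true(all(diff(curve$recall) >= -1e-12))
})

test_that("pairwise GO similarity counts shared propagated nodes", {
  dag <- diamond_dag()
  expect_equal(go_pair_similarity(dag, D$A, D$C), 0.5)  # {A,R} vs {C,A,B,R}
  expect_equal(go_pair_similarity(dag, D$C, D$C), 1.0)
  # symmetry and range over all pairs
  for (a in dag$ids) {
    for (b in dag$ids) {
      s <- go_pair_similarity(dag, a, b)
      expect_equal(s, go_pair_similarity(dag, b, a))
      expect_gte(s, 0)
      expect_lte(s, 1)
      if (a == b) expect_equal(s, 1)
    }
  }
})

test_that("terms in different namespaces have similarity zero", {
  obo <- paste(
    diamond_obo(), "",
    "[Term]", "id: GO:0000005", "name: mf-root",
    "namespace: molecular_function",
    sep = "\n")
  dag <- parse_obo(obo)
  expect_equal(go_pair_similarity(dag, D$C, "GO:0000005"), 0)
})

test_that("similarity curves average over selected pairs and skip empty proteins", {
  dag <- diamond_dag()
  preds <- prediction_set(list(p = data.frame(go_id = D$C, score = 0.9)))
  truth <- list(p = D$C)
  curve <- average_similarity(preds, truth, dag, "top_n", 1:3)
  expect_equal(curve$mean_similarity, rep(1, 3))
  # threshold above all scores: protein skipped, point undefined
  curve2 <- average_similarity(preds, truth, dag, "threshold", c(0.5, 0.95))
  expect_equal(curve2$mean_similarity[[1L]], 1)
  expect_true(is.na(curve2$mean_similarity[[2L]]))
  expect_equal(curve2$proteins_scored, c(1L, 0L))
  # two pairs with similarities 0.5 and 1.0 average to 0.75
  preds3 <- prediction_set(list(p = data.frame(go_id = c(D$A, D$C),
                                               score = c(0.9, 0.8))))
  curve3 <- average_similarity(preds3, list(p = D$C), dag, "top_n", 2)
  expect_equal(curve3$mean_similarity, 0.75)
})

test_that("PR area follows the trapezoid rule without extrapolation", {
  expect_equal(pr_auc(data.frame(recall = c(0, 1), precision = c(1, 0))), 0.5)
  expect_equal(pr_auc(data.frame(recall = c(0.2, 0.6),
                                 precision = c(1.0, 0.5))), 0.3)
  expect_equal(pr_auc(data.frame(recall = c(0.1, 0.9),
                                 precision = c(0.7, 0.7))), 0.7 * 0.8)
  expect_error(pr_auc(data.frame(recall = 0.5, precision = 0.5)), "2 points")
})

test_that("the evaluation report combines PR and similarity rows", {
  dag <- diamond_dag()
  preds <- prediction_set(list(p = data.frame(go_id = D$C, score = 0.9)))
  path <- withr::local_tempfile(fileext = ".tsv")
  rep <- evaluation_report(preds, list(p = D$C), dag, n_values = 1:3,
                           thresholds = c(0.5), path = path)
  expect_equal(nrow(rep), 4L)
  back <- read.delim(path)
  expect_equal(back$precision, rep$precision)
  expect_equal(rep$precision[rep$mode == "top_n"], rep(1, 3))
})
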