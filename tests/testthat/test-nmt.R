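test_that("bucket assignment follows the first-fit rule with truncation overflow", {
  bks <- default_buckets()
  b <- assign_bucket(3, 4, bks)
  expect_equal(c(b$src_cap, b$tgt_cap), c(109L, 4L))
  expect_false(b$truncated)
  b2 <- assign_bucket(64, 3, bks)
  expect_equal(c(b2$src_cap, b2$tgt_cap), c(64L, 3L))
  b3 <- assign_bucket(301, 12, bks)
  expect_equal(c(b3$src_cap, b3$tgt_cap), c(300L, 10L))
  expect_true(b3$truncated)
})

test_that("bucket assignment is monotone in both lengths", {
  bks <- default_buckets()
  idx <- function(l1, l2) assign_bucket(l1, l2, bks)$index
  for (l1 in c(0, 10, 64, 65, 150, 299)) {
    for (l2 in c(0, 3, 4, 6, 9)) {
      expect_gte(idx(l1 + 1, l2), idx(l1, l2))
      expect_gte(idx(l1, l2 + 1), idx(l1, l2))
    }
  }
  expect_error(bucket_set(list(c(10, 5), c(10, 8))), "strictly increasing")
})

test_that("batch encoding pads, wraps targets and maps unknowns to <unk>", {
  si <- token_indexer(c("w1", "w2", "w3"))
  ti <- token_indexer(c("g1", "g2", "g3", "g4"))
  enc <- encode_batch(list(list(source = c("w1", "w2", "w3"),
                                target = c("g1", "g2", "g3", "g4"))),
                      assign_bucket(3, 4, default_buckets()), si, ti)
  expect_equal(ncol(enc$src), 109L)
  expect_equal(sum(enc$src == 1L), 106L)  # 106 pads after 3 real words
  # empty target becomes <go> <eos> <pad>...
  enc2 <- encode_batch(list(list(source = "w1", target = character(0))),
                       c(4, 3), si, ti)
  expect_equal(enc2$tgt[1, 1:3], c(2L, 3L, 1L))
  # unknown token -> <unk> id 4
  enc3 <- encode_batch(list(list(source = "never-seen", target = "g1")),
                       c(4, 3), si, ti)
  expect_equal(enc3$src[1, 1], 4L)
  expect_error(encode_batch(list(list(source = rep("w1", 9), target = "g1")),
                            c(4, 3), si, ti),
               "exceeds")
})

test_that("config validates its invariants", {
  expect_error(seq2seq_config(learning_rate = 1.5), "learning rate")
  expect_error(seq2seq_config(learning_rate = 0), "learning rate")
  expect_error(seq2seq_config(num_layers = 0), "num_layers")
  expect_error(seq2seq_config(cell = "lstm"), "GRU")
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- seq2seq_config(num_layers = 2, hidden_size = 3, embed_size = 2,
                        seed = 7)
  model <- seq2go:::nmt_init(cfg, paste0("s", 1:5), paste0("t", 1:4))
  set.seed(99)
  inflate <- function(x) {
    if (is.list(x)) lapply(x, inflate) else x + runif(length(x), -0.5, 0.5)
  }
  model$params <- inflate(model$params)
  enc <- encode_batch(list(list(source = c("s1", "s2"), target = c("t1", "t2")),
                           list(source = "s3", target = c("t3", "t4", "t1"))),
                      c(3, 3), model$src_indexer, model$tgt_indexer)
  fb <- seq2go:::seq2seq_batch(model, enc$src, enc$tgt, compute_grads = TRUE)
  loss <- function(m) {
    r <- seq2go:::seq2seq_batch(m, enc$src, enc$tgt, compute_grads = FALSE)
    r$nll / r$n_tokens
  }
  probe <- function(set, get, grad) {
    for (j in sample(length(grad), min(3L, length(grad)))) {
      v0 <- get(model)[j]
      up <- loss(set(model, j, v0 + 1e-5))
      dn <- loss(set(model, j, v0 - 1e-5))
      num <- (up - dn) / 2e-5
      expect_lt(abs(num - grad[j]),
                1e-4 * max(1, abs(num) + abs(grad[j])))
    }
  }
  probe(function(m, j, v) { m$params$Es[j] <- v; m },
        function(m) m$params$Es, fb$grads$Es)
  probe(function(m, j, v) { m$params$enc[[1]]$Wz[j] <- v; m },
        function(m) m$params$enc[[1]]$Wz, fb$grads$enc[[1]]$Wz)
  probe(function(m, j, v) { m$params$dec[[2]]$Ug[j] <- v; m },
        function(m) m$params$dec[[2]]$Ug, fb$grads$dec[[2]]$Ug)
  probe(function(m, j, v) { m$params$att$Wa[j] <- v; m },
        function(m) m$params$att$Wa, fb$grads$att$Wa)
  probe(function(m, j, v) { m$params$att$v[j] <- v; m },
        function(m) m$params$att$v, fb$grads$att$v)
  probe(function(m, j, v) { m$params$out$Wo[j] <- v; m },
        function(m) m$params$out$Wo, fb$grads$out$Wo)
})

test_that("a uniform output model has perplexity equal to the vocab size", {
  cfg <- seq2seq_config(num_layers = 1, hidden_size = 4, embed_size = 3,
                        seed = 3)
  model <- seq2go:::nmt_init(cfg, paste0("s", 1:5), paste0("t", 1:46))
  expect_equal(model$tgt_indexer$size, 50L)
  model$params$out$Wo[] <- 0
  model$params$out$bo[] <- 0
  model$buckets <- bucket_set(list(c(4, 4)))
  pairs <- list(list(source = c("s1", "s2"), target = c("t1", "t2")),
                list(source = "s3", target = "t9"))
  expect_equal(nmt_perplexity(model, pairs), 50, tolerance = 1e-12)
})

test_that("perplexity closed forms hold", {
  expect_equal(perplexity_from_probs(c(0.5, 0.125)), 4)
  expect_equal(perplexity_from_probs(rep(1, 7)), 1)
  expect_equal(perplexity_from_probs(rep(1 / 50, 3)), 50)
  expect_error(nmt_perplexity(structure(list(), class = "seq2seq_model"),
                              list()),
               "no pairs")
})

test_that("training is reproducible, traces are bookkept, errors are raised", {
  toy <- make_toy_language(3, n_pairs = 40)
  cfg <- seq2seq_config(num_layers = 1, hidden_size = 8, embed_size = 6,
                        max_steps = 60, eval_every = 20, batch_size = 8,
                        seed = 5)
  fit1 <- nmt_train(cfg, toy$pairs, buckets = toy_buckets())
  fit2 <- nmt_train(cfg, toy$pairs, buckets = toy_buckets())
  expect_identical(fit1$trace, fit2$trace)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_equal(nrow(fit1$trace), 3L)  # floor(max_steps / eval_every)
  expect_equal(fit1$trace$step, c(20L, 40L, 60L))
  ckpt <- attr(fit1$trace, "selected_checkpoint")
  expect_true(ckpt %in% fit1$trace$step)
  expect_error(nmt_train(cfg, list()), "empty")
})

test_that("sampled softmax trains and reduces the loss", {
  toy <- make_toy_language(4, n_pairs = 40)
  cfg <- seq2seq_config(num_layers = 1, hidden_size = 8, embed_size = 6,
                        max_steps = 120, eval_every = 40, batch_size = 8,
                        sampled_softmax_samples = 6, seed = 5)
  fit <- nmt_train(cfg, toy$pairs, buckets = toy_buckets())
  expect_true(all(is.finite(fit$trace$train_perplexity)))
  expect_lt(fit$trace$train_perplexity[3], fit$trace$train_perplexity[1])
})

test_that("greedy decoding respects score range, caps and deduplication", {
  toy <- make_toy_language(6, n_pairs = 60)
  cfg <- seq2seq_config(num_layers = 1, hidden_size = 12, embed_size = 8,
                        max_steps = 150, eval_every = 50, batch_size = 8,
                        seed = 6)
  fit <- nmt_train(cfg, toy$pairs, buckets = toy_buckets())
  for (p in toy$pairs[1:10]) {
    dec <- nmt_translate(fit$model, p$source)
    expect_lte(length(dec$tokens), 5L)  # largest bucket target capacity
    expect_true(all(dec$scores > 0 & dec$scores <= 1))
    expect_false(anyDuplicated(dec$tokens) > 0)
  }
  empty <- nmt_translate(fit$model, character(0))
  expect_length(empty$tokens, 0L)
})

test_that("checkpoints save and load losslessly", {
  toy <- make_toy_language(8, n_pairs = 30)
  cfg <- seq2seq_config(num_layers = 1, hidden_size = 6, embed_size = 4,
                        max_steps = 20, eval_every = 10, batch_size = 4,
                        seed = 2)
  fit <- nmt_train(cfg, toy$pairs, buckets = toy_buckets())
  path <- withr::local_tempfile(fileext = ".rds")
  nmt_save(fit$model, path, trace = fit$trace)
  back <- nmt_load(path)
  expect_identical(back$params, fit$model$params)
  expect_identical(attr(back, "trace"), fit$trace)
  src <- toy$pairs[[1]]$source
  expect_identical(nmt_translate(back, src), nmt_translate(fit$model, src))
})

test_that("the pipeline learns planted sequence-function associations end to end", {
  cfg <- sim_config(seed = 5, n_proteins = 120, terms_per_protein = c(1L, 2L),
                    seq_len_range = c(60L, 90L))
  sim <- simulate_dag(cfg)
  corp <- simulate_corpus(sim$dag, cfg)
  seqs <- read_fasta(corp$fasta)
  vocab <- build_vocabulary(count_kmers(seqs, 3, 5), min_freq = 15)
  tk <- tokenize_corpus(seqs, vocab)
  ordering <- dfs_postorder(sim$dag)
  pairs <- lapply(names(seqs), function(p) {
    list(source = tk$sentences[[p]],
         target = annotation_to_golan(ordering, corp$annotations[[p]]))
  })
  scfg <- seq2seq_config(num_layers = 1, hidden_size = 32, embed_size = 16,
                         max_steps = 1500, eval_every = 300, batch_size = 32,
                         seed = 5)
  fit <- nmt_train(scfg, pairs, buckets = bucket_set(list(c(24, 2), c(40, 3))))
  expect_gte(exact_sentence_accuracy(fit$model, pairs), 0.9)
})
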