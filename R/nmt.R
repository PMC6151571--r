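# Encoder-decoder recurrent translation model with additive attention,
# bucketing/padding, sampled-softmax training, perplexity tracking and greedy
# decoding. Written directly in base R matrix code; analytic gradients are
# verified against finite differences in the test suite.

# reserved special token indices (stable across save/load)
PAD_ID <- 1L
GO_ID <- 2L
EOS_ID <- 3L
UNK_ID <- 4L
SPECIAL_TOKENS <- c("<pad>", "<go>", "<eos>", "<unk>")

#' Token indexer with reserved special symbols
#'
#' Builds a token <-> integer bijection for one language. Indices 1-4 are the
#' reserved specials `<pad>`, `<go>`, `<eos>`, `<unk>`; real tokens follow in
#' sorted order, so the mapping is deterministic for a given token set.
#'
#' @param tokens Character vector of tokens (duplicates allowed, ignored).
#' @return A `token_indexer`: list with `tokens` (vector indexed by id) and
#'   `size`.
#' @export
token_indexer <- function(tokens) {
  real <- sort(unique(setdiff(as.character(tokens), SPECIAL_TOKENS)))
  structure(list(tokens = c(SPECIAL_TOKENS, real),
                 size = length(real) + 4L),
            class = "token_indexer")
}

#' Map tokens to integer ids (unknown tokens become `<unk>`)
#' @param indexer A `token_indexer`.
#' @param tokens Character vector.
#' @return Integer vector of ids.
#' @export
tokens_to_ids <- function(indexer, tokens) {
  ids <- match(tokens, indexer$tokens)
  ids[is.na(ids)] <- UNK_ID
  ids
}

#' Bucket sets for padded batching
#'
#' A bucket is a `(source capacity, target capacity)` pair; sentence pairs
#' are padded into the first bucket that fits both lengths. Capacities must
#' be strictly increasing in both coordinates.
#'
#' `default_buckets()` returns the standard set
#' `[(64,3), (109,4), (164,6), (300,10)]`, or with `extended = TRUE` the
#' descendant-expanded set `[(64,25), (164,50), (250,60)]`.
#'
#' @param caps List of length-2 integer vectors.
#' @param extended Use the extended (long-target) bucket set.
#' @return A `bucket_set`.
#' @export
bucket_set <- function(caps) {
  stopifnot(length(caps) >= 1L)
  m <- do.call(rbind, lapply(caps, function(b) {
    stopifnot(length(b) == 2L, all(b >= 1))
    as.integer(b)
  }))
  if (nrow(m) > 1L && (any(diff(m[, 1L]) <= 0L) || any(diff(m[, 2L]) <= 0L))) {
    stop2("bucket capacities must be strictly increasing in both coordinates")
  }
  structure(lapply(seq_len(nrow(m)), function(i) m[i, ]), class = "bucket_set")
}

#' @rdname bucket_set
#' @export
default_buckets <- function(extended = FALSE) {
  if (extended) {
    bucket_set(list(c(64, 25), c(164, 50), c(250, 60)))
  } else {
    bucket_set(list(c(64, 3), c(109, 4), c(164, 6), c(300, 10)))
  }
}

#' Select the bucket for a sentence pair
#'
#' Returns the first bucket whose source capacity is at least `L1` and whose
#' target capacity is at least `L2`. If no bucket fits, the last (largest)
#' bucket is returned with `truncated = TRUE`, meaning the pair must be cut
#' to that bucket's capacities.
#'
#' @param L1,L2 Source and target sentence lengths (tokens).
#' @param buckets A `bucket_set`.
#' @return List with `index`, `src_cap`, `tgt_cap`, `truncated`.
#' @export
assign_bucket <- function(L1, L2, buckets) {
  stopifnot(L1 >= 0, L2 >= 0)
  for (i in seq_along(buckets)) {
    b <- buckets[[i]]
    if (L1 <= b[[1L]] && L2 <= b[[2L]]) {
      return(list(index = i, src_cap = b[[1L]], tgt_cap = b[[2L]],
                  truncated = FALSE))
    }
  }
  b <- buckets[[length(buckets)]]
  list(index = length(buckets), src_cap = b[[1L]], tgt_cap = b[[2L]],
       truncated = TRUE)
}

#' Encode sentence pairs into padded integer matrices
#'
#' Source rows are padded with `<pad>` to the bucket's source capacity; the
#' target is wrapped as `<go> tokens... <eos>` and padded to capacity + 2.
#' Unknown tokens map to `<unk>`. Masks mark real (non-pad) positions; for
#' the target matrix the mask covers the decoder *output* positions (the
#' tokens after `<go>`, including `<eos>`).
#'
#' @param pairs List of pairs, each `list(source = tokens, target = tokens)`.
#' @param bucket A bucket from [assign_bucket()] or a length-2 capacity
#'   vector.
#' @param src_indexer,tgt_indexer `token_indexer`s for the two languages.
#' @param truncate Allow cutting pairs that exceed the bucket (default: the
#'   bucket's own `truncated` flag).
#' @return List with integer matrices `src` (B x L1), `tgt` (B x (L2 + 2))
#'   and logical masks `src_mask`, `tgt_mask`.
#' @export
encode_batch <- function(pairs, bucket, src_indexer, tgt_indexer,
                         truncate = NULL) {
  if (is.numeric(bucket)) {
    bucket <- list(src_cap = bucket[[1L]], tgt_cap = bucket[[2L]],
                   truncated = FALSE)
  }
  if (is.null(truncate)) truncate <- isTRUE(bucket$truncated)
  B <- length(pairs)
  L1 <- bucket$src_cap
  L2 <- bucket$tgt_cap
  src <- matrix(PAD_ID, B, L1)
  tgt <- matrix(PAD_ID, B, L2 + 2L)
  for (b in seq_len(B)) {
    s <- as.character(pairs[[b]]$source)
    t <- as.character(pairs[[b]]$target)
    if (length(s) > L1 || length(t) > L2) {
      if (!truncate) {
        stop2("pair ", b, " exceeds bucket (", L1, ", ", L2,
              ") and truncation is not enabled")
      }
      s <- head(s, L1)
      t <- head(t, L2)
    }
    if (length(s) > 0L) src[b, seq_along(s)] <- tokens_to_ids(src_indexer, s)
    tgt[b, 1L] <- GO_ID
    if (length(t) > 0L) {
      tgt[b, 1L + seq_along(t)] <- tokens_to_ids(tgt_indexer, t)
    }
    tgt[b, length(t) + 2L] <- EOS_ID
  }
  list(src = src, tgt = tgt,
       src_mask = src != PAD_ID,
       tgt_mask = tgt[, -1L, drop = FALSE] != PAD_ID)
}

#' Configuration for the sequence-to-sequence translator
#'
#' @param num_layers Recurrent layers on each side (default 3).
#' @param hidden_size Hidden state width (default 64).
#' @param embed_size Token embedding width (default 32).
#' @param cell Recurrent cell kind; only `"gru"` is implemented.
#' @param learning_rate Initial SGD learning rate, in (0, 1] (default 0.5).
#' @param lr_decay Multiplicative decay applied when training perplexity
#'   fails to improve at an evaluation (default 0.99).
#' @param max_steps Total training steps.
#' @param eval_every Evaluate and record the trace every this many steps
#'   (default 200).
#' @param sampled_softmax_samples Use sampled softmax during training when
#'   the target vocabulary exceeds this count (default 512); evaluation
#'   always uses the full softmax.
#' @param batch_size Training batch size (default 32).
#' @param clip_norm Global gradient-norm clip (default 5).
#' @param seed RNG seed controlling initialization and batch sampling.
#' @return A `seq2seq_config` list.
#' @export
seq2seq_config <- function(num_layers = 3L, hidden_size = 64L,
                           embed_size = 32L, cell = "gru",
                           learning_rate = 0.5, lr_decay = 0.99,
                           max_steps = 2000L, eval_every = 200L,
                           sampled_softmax_samples = 512L,
                           batch_size = 32L, clip_norm = 5,
                           seed = 1L) {
  stopifnot(num_layers >= 1L, hidden_size >= 1L, embed_size >= 1L)
  if (!(learning_rate > 0 && learning_rate <= 1)) {
    stop2("initial learning rate must lie in (0, 1]")
  }
  cell <- match.arg(cell, c("gru", "lstm"))
  if (cell != "gru") stop2("only the GRU cell is implemented")
  structure(list(num_layers = as.integer(num_layers),
                 hidden_size = as.integer(hidden_size),
                 embed_size = as.integer(embed_size), cell = cell,
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 max_steps = as.integer(max_steps),
                 eval_every = as.integer(eval_every),
                 sampled_softmax_samples = as.integer(sampled_softmax_samples),
                 batch_size = as.integer(batch_size),
                 clip_norm = clip_norm, seed = as.integer(seed)),
            class = "seq2seq_config")
}

rmat <- function(nr, nc, scale = 0.08) {
  matrix(runif(nr * nc, -scale, scale), nr, nc)
}

gru_params <- function(din, h) {
  list(Wz = rmat(din, h), Wr = rmat(din, h), Wg = rmat(din, h),
       Uz = rmat(h, h), Ur = rmat(h, h), Ug = rmat(h, h),
       bz = numeric(h), br = numeric(h), bg = numeric(h))
}

init_params <- function(cfg, Vs, Vt) {
  d <- cfg$embed_size
  h <- cfg$hidden_size
  L <- cfg$num_layers
  enc <- lapply(seq_len(L), function(l) gru_params(if (l == 1L) d else h, h))
  dec <- lapply(seq_len(L), function(l) gru_params(if (l == 1L) d + h else h, h))
  list(Es = rmat(Vs, d), Et = rmat(Vt, d), enc = enc, dec = dec,
       att = list(Wa = rmat(h, h), Ua = rmat(h, h), ba = numeric(h),
                  v = rmat(h, 1L)),
       # output layer reads the decoder state and the attention context
       out = list(Wo = rmat(2L * h, Vt), bo = numeric(Vt)))
}

nmt_init <- function(cfg, src_tokens, tgt_tokens) {
  src_indexer <- token_indexer(src_tokens)
  tgt_indexer <- token_indexer(tgt_tokens)
  params <- with_local_seed(cfg$seed,
                            init_params(cfg, src_indexer$size, tgt_indexer$size))
  structure(list(config = cfg, src_indexer = src_indexer,
                 tgt_indexer = tgt_indexer, params = params),
            class = "seq2seq_model")
}

#' @export
print.seq2seq_model <- function(x, ...) {
  cat("seq2seq_model:", x$config$num_layers, "GRU layer(s), hidden",
      x$config$hidden_size, "| source vocab", x$src_indexer$size,
      "| target vocab", x$tgt_indexer$size, "\n")
  invisible(x)
}

addb <- function(M, b) M + rep(b, each = nrow(M))
sigm <- function(x) 1 / (1 + exp(-x))

gru_step <- function(x, h, p) {
  z <- sigm(addb(x %*% p$Wz + h %*% p$Uz, p$bz))
  r <- sigm(addb(x %*% p$Wr + h %*% p$Ur, p$br))
  rh <- r * h
  g <- tanh(addb(x %*% p$Wg + rh %*% p$Ug, p$bg))
  hn <- (1 - z) * h + z * g
  list(h = hn, cache = list(x = x, h = h, z = z, r = r, g = g, rh = rh))
}

gru_back <- function(dh, cache, p, g) {
  z <- cache$z; r <- cache$r; gg <- cache$g; h <- cache$h; x <- cache$x
  dz <- dh * (gg - h)
  daz <- dz * z * (1 - z)
  dg <- dh * z
  dag <- dg * (1 - gg^2)
  dhprev <- dh * (1 - z)
  drh <- dag %*% t(p$Ug)
  dr <- drh * h
  dhprev <- dhprev + drh * r
  dar <- dr * r * (1 - r)
  dx <- daz %*% t(p$Wz) + dar %*% t(p$Wr) + dag %*% t(p$Wg)
  dhprev <- dhprev + daz %*% t(p$Uz) + dar %*% t(p$Ur)
  g$Wz <- g$Wz + crossprod(x, daz)
  g$Wr <- g$Wr + crossprod(x, dar)
  g$Wg <- g$Wg + crossprod(x, dag)
  g$Uz <- g$Uz + crossprod(h, daz)
  g$Ur <- g$Ur + crossprod(h, dar)
  g$Ug <- g$Ug + crossprod(cache$rh, dag)
  g$bz <- g$bz + colSums(daz)
  g$br <- g$br + colSums(dar)
  g$bg <- g$bg + colSums(dag)
  list(dx = dx, dh = dhprev, g = g)
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# add rows of `dx` into rows `idx` of gradient matrix `G` (duplicates summed)
acc_rows <- function(G, idx, dx) {
  agg <- rowsum(dx, group = idx)
  rows <- as.integer(rownames(agg))
  G[rows, ] <- G[rows, , drop = FALSE] + agg
  G
}

zeros_like <- function(x) {
  if (is.list(x)) lapply(x, zeros_like) else x * 0
}

# Full forward (and optionally backward) pass over one padded batch.
# Returns total NLL over real target positions, the count of real positions,
# gradients (normalized by that count) and, on request, per-position
# probabilities of the true tokens.
seq2seq_batch <- function(model, src, tgt, compute_grads = TRUE,
                          candidates = NULL, keep_probs = FALSE) {
  cfg <- model$config
  P <- model$params
  L <- cfg$num_layers
  hsz <- cfg$hidden_size
  B <- nrow(src)
  Ts <- ncol(src)
  Td <- ncol(tgt) - 1L
  inp <- tgt[, seq_len(Td), drop = FALSE]
  out <- tgt[, 1L + seq_len(Td), drop = FALSE]
  real <- out != PAD_ID
  N <- sum(real)
  if (N == 0L) stop2("no scorable target positions in batch")

  # ---- encoder ----
  H <- replicate(L, matrix(0, B, hsz), simplify = FALSE)
  enc_cache <- if (compute_grads) {
    replicate(Ts, vector("list", L), simplify = FALSE)
  }
  Henc <- vector("list", Ts)
  for (t in seq_len(Ts)) {
    x <- P$Es[src[, t], , drop = FALSE]
    for (l in seq_len(L)) {
      st <- gru_step(x, H[[l]], P$enc[[l]])
      if (compute_grads) enc_cache[[t]][[l]] <- st$cache
      H[[l]] <- st$h
      x <- st$h
    }
    Henc[[t]] <- H[[L]]
  }

  # attention keys computed once per batch
  att <- P$att
  hU <- lapply(Henc, function(hh) hh %*% att$Ua)
  src_real <- src != PAD_ID
  no_real <- !apply(src_real, 1L, any)

  # ---- decoder ----
  S <- H  # initial decoder states = final encoder states per layer
  Wo <- P$out$Wo
  bo <- P$out$bo
  use_cand <- !is.null(candidates)
  if (use_cand) {
    cand <- sort(unique(c(candidates, out[real])))
    Wo <- Wo[, cand, drop = FALSE]
    bo <- bo[cand]
    out_col <- matrix(match(out, cand), B, Td)
    out_col[is.na(out_col)] <- 1L  # pad positions; masked out of the loss
  } else {
    out_col <- out
  }
  Vc <- length(bo)
  dec_cache <- if (compute_grads) vector("list", Td)
  total_nll <- 0
  probs_true <- if (keep_probs) matrix(NA_real_, B, Td)

  for (t in seq_len(Td)) {
    q <- S[[L]]
    qW <- q %*% att$Wa
    e <- matrix(0, B, Ts)
    tanhs <- if (compute_grads) vector("list", Ts)
    for (i in seq_len(Ts)) {
      th <- tanh(addb(qW + hU[[i]], att$ba))
      if (compute_grads) tanhs[[i]] <- th
      e[, i] <- th %*% att$v
    }
    e[!src_real] <- -1e30
    e[no_real, ] <- 0
    alpha <- softmax_rows(e)
    ctx <- matrix(0, B, hsz)
    for (i in seq_len(Ts)) ctx <- ctx + alpha[, i] * Henc[[i]]

    x <- cbind(P$Et[inp[, t], , drop = FALSE], ctx)
    layer_caches <- if (compute_grads) vector("list", L)
    for (l in seq_len(L)) {
      st <- gru_step(x, S[[l]], P$dec[[l]])
      if (compute_grads) layer_caches[[l]] <- st$cache
      S[[l]] <- st$h
      x <- st$h
    }
    readout <- cbind(S[[L]], ctx)
    logits <- addb(readout %*% Wo, bo)
    probs <- softmax_rows(logits)
    rl <- real[, t]
    tp <- probs[cbind(seq_len(B), out_col[, t])]
    if (keep_probs) probs_true[, t] <- tp
    total_nll <- total_nll - sum(log(pmax(tp[rl], 1e-300)))
    if (compute_grads) {
      dlogits <- probs
      dlogits[cbind(seq_len(B), out_col[, t])] <-
        dlogits[cbind(seq_len(B), out_col[, t])] - 1
      dlogits[!rl, ] <- 0
      dec_cache[[t]] <- list(q = q, tanhs = tanhs, alpha = alpha,
                             layers = layer_caches, readout = readout,
                             dlogits = dlogits / N)
    }
  }

  res <- list(nll = total_nll, n_tokens = N)
  if (keep_probs) {
    res$probs_true <- probs_true
    res$real <- real
  }
  if (!compute_grads) return(res)

  # ---- backward ----
  G <- zeros_like(P)
  if (use_cand) {
    gWo <- matrix(0, nrow(P$out$Wo), Vc)
    gbo <- numeric(Vc)
  }
  dS <- replicate(L, matrix(0, B, hsz), simplify = FALSE)
  dHenc <- replicate(Ts, matrix(0, B, hsz), simplify = FALSE)
  v <- att$v
  for (t in rev(seq_len(Td))) {
    dc <- dec_cache[[t]]
    dlog <- dc$dlogits
    if (use_cand) {
      gWo <- gWo + crossprod(dc$readout, dlog)
      gbo <- gbo + colSums(dlog)
    } else {
      G$out$Wo <- G$out$Wo + crossprod(dc$readout, dlog)
      G$out$bo <- G$out$bo + colSums(dlog)
    }
    dreadout <- dlog %*% t(Wo)
    dtop <- dreadout[, seq_len(hsz), drop = FALSE]
    dctx_out <- dreadout[, hsz + seq_len(hsz), drop = FALSE]
    dx_above <- NULL
    for (l in rev(seq_len(L))) {
      dh <- dS[[l]]
      if (l == L) dh <- dh + dtop
      if (!is.null(dx_above)) dh <- dh + dx_above
      bk <- gru_back(dh, dc$layers[[l]], P$dec[[l]], G$dec[[l]])
      G$dec[[l]] <- bk$g
      dS[[l]] <- bk$dh
      dx_above <- if (l > 1L) bk$dx
      if (l == 1L) {
        d <- cfg$embed_size
        demb <- bk$dx[, seq_len(d), drop = FALSE]
        dctx <- bk$dx[, d + seq_len(hsz), drop = FALSE] + dctx_out
        G$Et <- acc_rows(G$Et, inp[, t], demb)
        # attention backward
        alpha <- dc$alpha
        dalpha <- matrix(0, B, Ts)
        for (i in seq_len(Ts)) {
          dalpha[, i] <- rowSums(dctx * Henc[[i]])
          dHenc[[i]] <- dHenc[[i]] + alpha[, i] * dctx
        }
        de <- alpha * (dalpha - rowSums(dalpha * alpha))
        dq <- matrix(0, B, hsz)
        for (i in seq_len(Ts)) {
          th <- dc$tanhs[[i]]
          dm <- (de[, i, drop = FALSE] %*% t(v)) * (1 - th^2)
          G$att$v <- G$att$v + crossprod(th, de[, i, drop = FALSE])
          G$att$Wa <- G$att$Wa + crossprod(dc$q, dm)
          G$att$Ua <- G$att$Ua + crossprod(Henc[[i]], dm)
          G$att$ba <- G$att$ba + colSums(dm)
          dq <- dq + dm %*% t(att$Wa)
          dHenc[[i]] <- dHenc[[i]] + dm %*% t(att$Ua)
        }
        dS[[L]] <- dS[[L]] + dq
      }
    }
  }
  if (use_cand) {
    G$out$Wo[, cand] <- gWo
    G$out$bo[cand] <- gbo
  }

  # encoder backward; decoder initial states were the final encoder states
  dH <- dS
  for (t in rev(seq_len(Ts))) {
    dx_above <- NULL
    for (l in rev(seq_len(L))) {
      dh <- dH[[l]]
      if (l == L) dh <- dh + dHenc[[t]]
      if (!is.null(dx_above)) dh <- dh + dx_above
      bk <- gru_back(dh, enc_cache[[t]][[l]], P$enc[[l]], G$enc[[l]])
      G$enc[[l]] <- bk$g
      dH[[l]] <- bk$dh
      dx_above <- if (l > 1L) bk$dx
      if (l == 1L) G$Es <- acc_rows(G$Es, src[, t], bk$dx)
    }
  }
  res$grads <- G
  res
}

grad_global_norm <- function(g) {
  sqrt(sum(unlist(rapply(g, function(x) sum(x^2), how = "unlist"))))
}

apply_sgd <- function(p, g, lr) {
  if (is.list(p)) {
    return(Map(apply_sgd, p, g, MoreArgs = list(lr = lr)))
  }
  p - lr * g
}

#' Train the sequence-to-sequence translator
#'
#' Trains the encoder-decoder (with `num_layers` GRU layers per side and
#' additive attention over encoder states) by stochastic gradient descent on
#' the conditional log-likelihood of target sentences, using sampled softmax
#' when the target vocabulary exceeds `sampled_softmax_samples` and the full
#' softmax otherwise. Every `eval_every` steps the training perplexity (over
#' the window since the previous evaluation) and per-bucket test perplexity
#' are recorded; the learning rate is multiplied by `lr_decay` whenever
#' training perplexity fails to improve on its best value so far. The
#' returned model carries the parameters of the checkpoint with the best
#' mean test perplexity.
#'
#' @param config A [seq2seq_config()].
#' @param train_pairs,test_pairs Lists of `list(source =, target =)` token
#'   vector pairs (`test_pairs` defaults to the training pairs).
#' @param buckets A `bucket_set` (default [default_buckets()]).
#' @return List with `model` (a `seq2seq_model`) and `trace` (a data frame
#'   with columns step, learning_rate, train_perplexity, one test-perplexity
#'   column per bucket; attribute `selected_checkpoint`).
#' @export
nmt_train <- function(config, train_pairs, test_pairs = NULL,
                      buckets = default_buckets()) {
  if (length(train_pairs) == 0L) stop2("empty training set")
  if (is.null(test_pairs)) test_pairs <- train_pairs
  src_tokens <- unlist(lapply(train_pairs, `[[`, "source"), use.names = FALSE)
  tgt_tokens <- unlist(lapply(train_pairs, `[[`, "target"), use.names = FALSE)
  model <- nmt_init(config, src_tokens, tgt_tokens)
  model$buckets <- buckets

  assign_all <- function(pairs) {
    vapply(pairs, function(p) {
      assign_bucket(length(p$source), length(p$target), buckets)$index
    }, integer(1))
  }
  train_idx <- assign_all(train_pairs)
  by_bucket <- split(seq_along(train_pairs), train_idx)
  bucket_probs <- vapply(by_bucket, length, integer(1))
  bucket_probs <- bucket_probs / sum(bucket_probs)

  use_sampled <- model$tgt_indexer$size > config$sampled_softmax_samples

  with_local_seed(config$seed + 1L, {
    lr <- config$learning_rate
    window_losses <- numeric(0)
    best_train_ppl <- Inf
    best_test_ppl <- Inf
    best_params <- model$params
    best_step <- NA_integer_
    trace <- NULL
    n_evals <- config$max_steps %/% config$eval_every

    for (step in seq_len(config$max_steps)) {
      bi <- sample(names(by_bucket), 1L, prob = bucket_probs)
      pool <- by_bucket[[bi]]
      take <- pool[sample.int(length(pool), config$batch_size, replace = TRUE)]
      bk <- buckets[[as.integer(bi)]]
      enc <- encode_batch(train_pairs[take],
                          list(src_cap = bk[[1L]], tgt_cap = bk[[2L]],
                               truncated = TRUE),
                          model$src_indexer, model$tgt_indexer)
      cand <- if (use_sampled) {
        sample(model$tgt_indexer$size, config$sampled_softmax_samples)
      }
      fb <- seq2seq_batch(model, enc$src, enc$tgt, compute_grads = TRUE,
                          candidates = cand)
      loss <- fb$nll / fb$n_tokens
      if (!is.finite(loss)) stop2("non-finite training loss at step ", step)
      window_losses <- c(window_losses, loss)
      gn <- grad_global_norm(fb$grads)
      scale <- if (gn > config$clip_norm) config$clip_norm / gn else 1
      model$params <- apply_sgd(model$params, fb$grads, lr * scale)

      if (step %% config$eval_every == 0L) {
        train_ppl <- exp(mean(window_losses))
        window_losses <- numeric(0)
        if (train_ppl >= best_train_ppl) {
          lr <- lr * config$lr_decay
        } else {
          best_train_ppl <- train_ppl
        }
        test_ppl <- per_bucket_perplexity(model, test_pairs, buckets)
        mean_test <- mean(test_ppl, na.rm = TRUE)
        if (is.finite(mean_test) && mean_test < best_test_ppl) {
          best_test_ppl <- mean_test
          best_params <- model$params
          best_step <- step
        }
        row <- data.frame(step = step, learning_rate = lr,
                          train_perplexity = train_ppl)
        for (k in seq_along(buckets)) {
          row[[paste0("test_perplexity_bucket", k)]] <- test_ppl[[k]]
        }
        trace <- rbind(trace, row)
      }
    }
    if (is.na(best_step)) {
      best_params <- model$params
      best_step <- config$max_steps
    }
    model$params <- best_params
    attr(trace, "selected_checkpoint") <- best_step
    class(trace) <- c("training_trace", class(trace))
    list(model = model, trace = trace)
  })
}

# Test perplexity computed separately per bucket (NA for empty buckets);
# always full softmax.
per_bucket_perplexity <- function(model, pairs, buckets) {
  idx <- vapply(pairs, function(p) {
    assign_bucket(length(p$source), length(p$target), buckets)$index
  }, integer(1))
  vapply(seq_along(buckets), function(k) {
    sel <- which(idx == k)
    if (length(sel) == 0L) return(NA_real_)
    nmt_perplexity(model, pairs[sel], buckets)
  }, numeric(1))
}

#' Corpus perplexity of a trained model
#'
#' `exp` of the mean negative log-likelihood of the true target token over
#' all real (non-pad) target positions, always under the full softmax. A
#' perfect model scores 1; a model spreading probability uniformly over a
#' target vocabulary of size V scores V.
#'
#' @param model A `seq2seq_model`.
#' @param pairs List of `list(source =, target =)` pairs (nonempty).
#' @param buckets A `bucket_set` (default: the model's own).
#' @return A single number >= 1.
#' @export
nmt_perplexity <- function(model, pairs, buckets = NULL) {
  if (length(pairs) == 0L) stop2("no pairs to score")
  if (is.null(buckets)) buckets <- model$buckets %||% default_buckets()
  idx <- vapply(pairs, function(p) {
    assign_bucket(length(p$source), length(p$target), buckets)$index
  }, integer(1))
  total_nll <- 0
  total_n <- 0L
  for (k in unique(idx)) {
    bk <- buckets[[k]]
    enc <- encode_batch(pairs[idx == k],
                        list(src_cap = bk[[1L]], tgt_cap = bk[[2L]],
                             truncated = TRUE),
                        model$src_indexer, model$tgt_indexer)
    fb <- seq2seq_batch(model, enc$src, enc$tgt, compute_grads = FALSE)
    total_nll <- total_nll + fb$nll
    total_n <- total_n + fb$n_tokens
  }
  if (total_n == 0L) stop2("zero scorable target positions")
  exp(total_nll / total_n)
}

#' Perplexity from per-position true-token probabilities
#'
#' Closed form `exp(mean(-log(p)))`; e.g. probabilities 0.5 and 0.125 give
#' exactly 4.
#'
#' @param p Numeric vector of probabilities in (0, 1].
#' @return A single number.
#' @export
perplexity_from_probs <- function(p) {
  stopifnot(length(p) > 0L, all(p > 0), all(p <= 1))
  exp(mean(-log(p)))
}

#' Greedy decoding of one source sentence
#'
#' Runs the encoder over the source, then decodes greedily from `<go>`,
#' stopping at `<eos>` or at the selected bucket's target capacity. Each
#' emitted token's score is its softmax probability at that step; duplicate
#' tokens are deduplicated keeping the higher score. Special symbols are
#' never emitted. An empty source yields an empty prediction.
#'
#' @param model A trained `seq2seq_model`.
#' @param sentence Character vector of source tokens.
#' @param buckets A `bucket_set` (default: the model's own).
#' @return List with `tokens` (character) and `scores` (numeric in (0, 1]).
#' @export
nmt_translate <- function(model, sentence, buckets = NULL) {
  if (is.null(buckets)) buckets <- model$buckets %||% default_buckets()
  sentence <- as.character(sentence)
  if (length(sentence) == 0L) {
    return(list(tokens = character(0), scores = numeric(0)))
  }
  bk <- assign_bucket(length(sentence), 0L, buckets)
  if (bk$truncated) sentence <- head(sentence, bk$src_cap)
  cfg <- model$config
  P <- model$params
  L <- cfg$num_layers
  hsz <- cfg$hidden_size
  src <- matrix(PAD_ID, 1L, bk$src_cap)
  src[1L, seq_along(sentence)] <- tokens_to_ids(model$src_indexer, sentence)

  H <- replicate(L, matrix(0, 1L, hsz), simplify = FALSE)
  Henc <- vector("list", bk$src_cap)
  for (t in seq_len(bk$src_cap)) {
    x <- P$Es[src[, t], , drop = FALSE]
    for (l in seq_len(L)) {
      st <- gru_step(x, H[[l]], P$enc[[l]])
      H[[l]] <- st$h
      x <- st$h
    }
    Henc[[t]] <- H[[L]]
  }
  att <- P$att
  hU <- lapply(Henc, function(hh) hh %*% att$Ua)
  src_real <- src != PAD_ID

  S <- H
  prev <- GO_ID
  toks <- character(0)
  scores <- numeric(0)
  for (step in seq_len(bk$tgt_cap + 1L)) {
    q <- S[[L]]
    qW <- q %*% att$Wa
    e <- vapply(seq_len(bk$src_cap), function(i) {
      as.numeric(tanh(addb(qW + hU[[i]], att$ba)) %*% att$v)
    }, numeric(1))
    e[!src_real[1L, ]] <- -1e30
    a <- exp(e - max(e))
    a <- a / sum(a)
    ctx <- matrix(0, 1L, hsz)
    for (i in seq_len(bk$src_cap)) ctx <- ctx + a[[i]] * Henc[[i]]
    x <- cbind(P$Et[prev, , drop = FALSE], ctx)
    for (l in seq_len(L)) {
      st <- gru_step(x, S[[l]], P$dec[[l]])
      S[[l]] <- st$h
      x <- st$h
    }
    logits <- addb(cbind(S[[L]], ctx) %*% P$out$Wo, P$out$bo)
    probs <- softmax_rows(logits)[1L, ]
    allowed <- probs
    allowed[c(PAD_ID, GO_ID, UNK_ID)] <- -Inf
    pick <- which.max(allowed)
    if (pick == EOS_ID || length(toks) >= bk$tgt_cap) break
    toks <- c(toks, model$tgt_indexer$tokens[[pick]])
    scores <- c(scores, probs[[pick]])
    prev <- pick
  }
  if (length(toks) > 0L) {
    ord <- order(-scores)
    keep_first <- !duplicated(toks[ord])
    kept <- sort(ord[keep_first])  # restore emission order
    toks2 <- toks[kept]
    scores2 <- vapply(toks2, function(w) max(scores[toks == w]), numeric(1))
    toks <- toks2
    scores <- unname(scores2)
  }
  list(tokens = toks, scores = scores)
}

#' Save and load a translator checkpoint
#'
#' The checkpoint bundles config, both token indexers, the bucket set, the
#' parameters and (when present) the training trace.
#'
#' @param model A `seq2seq_model`.
#' @param path Checkpoint file path (`.rds`).
#' @param trace Optional training trace to bundle.
#' @return `nmt_save()` the path invisibly; `nmt_load()` the model (with
#'   attribute `trace` if one was saved).
#' @export
nmt_save <- function(model, path, trace = NULL) {
  saveRDS(list(model = model, trace = trace), path)
  invisible(path)
}

#' @rdname nmt_save
#' @export
nmt_load <- function(path) {
  obj <- readRDS(path)
  model <- obj$model
  attr(model, "trace") <- obj$trace
  model
}
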