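# Independent brute-force oracles: explicit loops, no shared code with the
# package's vectorized implementations.

oracle_affine <- function(X, W, b) {
  out <- matrix(0, nrow(X), ncol(W))
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(ncol(W))) {
      s <- b[j]
      for (k in seq_len(ncol(X))) s <- s + X[i, k] * W[k, j]
      out[i, j] <- s
    }
  }
  out
}

oracle_spatial_matrix <- function(A, B) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (j in seq_len(n)) {
    logits <- numeric(n)
    for (i in seq_len(n)) logits[i] <- sum(A[i, ] * B[j, ])
    e <- exp(logits - max(logits))
    S[, j] <- e / sum(e)
  }
  S
}

oracle_apply_spatial <- function(S, D, X, alpha) {
  E <- matrix(0, nrow(X), ncol(X))
  for (j in seq_len(nrow(X))) {
    for (cc in seq_len(ncol(X))) {
      acc <- 0
      for (i in seq_len(nrow(X))) acc <- acc + S[i, j] * D[i, cc]
      E[j, cc] <- alpha * acc + X[j, cc]
    }
  }
  E
}

oracle_channel_matrix <- function(E) {
  C <- ncol(E)
  G <- matrix(0, C, C)
  for (i in seq_len(C)) {
    for (j in seq_len(C)) G[i, j] <- sum(E[, i] * E[, j])
  }
  Cm <- matrix(0, C, C)
  for (j in seq_len(C)) {
    e <- exp(G[, j] - max(G[, j]))
    Cm[, j] <- e / sum(e)
  }
  Cm
}

oracle_apply_channel <- function(Cmat, E, beta) {
  G <- matrix(0, nrow(E), ncol(E))
  for (n in seq_len(nrow(E))) {
    for (j in seq_len(ncol(E))) {
      acc <- 0
      for (i in seq_len(ncol(E))) acc <- acc + Cmat[i, j] * E[n, i]
      G[n, j] <- beta * acc + E[n, j]
    }
  }
  G
}

# stage-by-stage forward recomputation from the per-op oracles
oracle_forward_prob <- function(X, p) {
  relu_m <- function(m) { m[m < 0] <- 0; m }
  Xe <- relu_m(oracle_affine(X, p$W_enc, p$b_enc))
  A <- oracle_affine(Xe, p$W_A, p$b_A)
  B <- oracle_affine(Xe, p$W_B, p$b_B)
  D <- oracle_affine(Xe, p$W_D, p$b_D)
  S <- oracle_spatial_matrix(A, B)
  E <- oracle_apply_spatial(S, D, Xe, p$alpha)
  Cm <- oracle_channel_matrix(E)
  H <- oracle_apply_channel(Cm, E, p$beta)
  Hd <- relu_m(oracle_affine(H, p$W_dec, p$b_dec))
  n <- nrow(Hd)
  sc <- numeric(n)
  for (j in seq_len(n)) {
    hidden <- tanh(as.vector(p$V_pool %*% Hd[j, ]))
    sc[j] <- sum(p$w_pool * hidden)
  }
  w <- exp(sc - max(sc)); w <- w / sum(w)
  z <- numeric(ncol(Hd))
  for (cc in seq_len(ncol(Hd))) z[cc] <- sum(w * Hd[, cc])
  1 / (1 + exp(-(sum(z * p$w_cls) + p$b_cls)))
}

oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

oracle_confusion_metrics <- function(labels, probs, thr) {
  pred <- ifelse(probs >= thr, 1, 0)
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(labels)) {
    if (pred[i] == 1 && labels[i] == 1) tp <- tp + 1
    if (pred[i] == 0 && labels[i] == 0) tn <- tn + 1
    if (pred[i] == 1 && labels[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && labels[i] == 1) fn <- fn + 1
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(acc = (tp + tn) / length(labels),
       spec = if (tn + fp > 0) tn / (tn + fp) else 0,
       rec = rec,
       f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
}

# parameter set with active (non-zero) gates for gradient/oracle tests
active_params <- function(dim_in, dim_model = dim_in, dim_hidden = 5L,
                          fusion = "spatial_then_channel", seed = 7L) {
  p <- camil_params(dim_in, dim_model = dim_model, dim_hidden = dim_hidden,
                    fusion = fusion, seed = seed)
  set.seed(seed + 100)
  p$alpha <- 0.4
  p$beta <- -0.3
  p$w_cls <- rnorm(dim_model) * 0.5
  p$b_cls <- 0.1
  p
}

numeric_grad <- function(lossfn, params, nm, idx, h = 1e-5) {
  vapply(idx, function(i) {
    p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + h
    p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - h
    (lossfn(p1) - lossfn(p2)) / (2 * h)
  }, numeric(1))
}

tiny_bags <- function(n = 20, dim = 8, delta = 3, k = 3, seed = 5,
                      range_n = c(5, 10)) {
  simulate_mil_bags(n_bags = n, instances_per_bag = range_n,
                    feature_dim = dim, witness_rate = 0.2,
                    effect_size = delta, signal_channels = k, seed = seed)
}
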