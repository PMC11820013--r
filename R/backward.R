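## Analytic backpropagation through the full network. Each stage mirrors
## its forward counterpart in attention.R / forward.R; correctness is
## pinned down by finite-difference tests.

## Backward through one spatial stage. dOut is dLoss/d(stage output).
spatial_stage_backward <- function(dOut, cache, params) {
  Z <- cache$Z; A <- cache$A; B <- cache$B; D <- cache$D; S <- cache$S
  alpha <- params$alpha
  dalpha <- sum(dOut * crossprod(S, D))
  dS <- alpha * D %*% t(dOut)
  dD <- alpha * S %*% dOut
  ## column softmax backward: dM[,j] = S[,j] * (dS[,j] - <dS[,j], S[,j]>)
  dM <- S * sweep(dS, 2L, colSums(dS * S), "-")
  dA <- dM %*% B
  dB <- crossprod(dM, A)
  dZ <- dOut + tcrossprod(dA, params$W_A) + tcrossprod(dB, params$W_B) +
    tcrossprod(dD, params$W_D)
  list(dZ = dZ, dalpha = dalpha,
       dW_A = crossprod(Z, dA), db_A = colSums(dA),
       dW_B = crossprod(Z, dB), db_B = colSums(dB),
       dW_D = crossprod(Z, dD), db_D = colSums(dD))
}

## Backward through one channel stage.
channel_stage_backward <- function(dOut, cache, params) {
  Z <- cache$Z; Cmat <- cache$Cmat; beta <- params$beta
  dbeta <- sum(dOut * (Z %*% Cmat))
  dCmat <- beta * crossprod(Z, dOut)
  dZ <- dOut + beta * tcrossprod(dOut, Cmat)
  dGc <- Cmat * sweep(dCmat, 2L, colSums(dCmat * Cmat), "-")
  dZ <- dZ + Z %*% (dGc + t(dGc))
  list(dZ = dZ, dbeta = dbeta)
}

## Backward through the cascaded block. Returns dX plus parameter grads.
block_backward <- function(dH, cache, params) {
  g <- list(dalpha = 0, dbeta = 0,
            dW_A = params$W_A * 0, db_A = params$b_A * 0,
            dW_B = params$W_B * 0, db_B = params$b_B * 0,
            dW_D = params$W_D * 0, db_D = params$b_D * 0,
            dW_fuse = params$W_fuse * 0, db_fuse = params$b_fuse * 0)
  take_sp <- function(sp) {
    g$dalpha <<- g$dalpha + sp$dalpha
    for (nm in c("dW_A", "db_A", "dW_B", "db_B", "dW_D", "db_D")) {
      g[[nm]] <<- g[[nm]] + sp[[nm]]
    }
    sp$dZ
  }
  fusion <- cache$fusion
  if (fusion == "spatial_then_channel") {
    ch <- channel_stage_backward(dH, cache$ch, params)
    g$dbeta <- g$dbeta + ch$dbeta
    dX <- take_sp(spatial_stage_backward(ch$dZ, cache$sp, params))
  } else if (fusion == "channel_then_spatial") {
    dmid <- take_sp(spatial_stage_backward(dH, cache$sp, params))
    ch <- channel_stage_backward(dmid, cache$ch, params)
    g$dbeta <- g$dbeta + ch$dbeta
    dX <- ch$dZ
  } else if (fusion == "spatial_only") {
    dX <- take_sp(spatial_stage_backward(dH, cache$sp, params))
  } else if (fusion == "channel_only") {
    ch <- channel_stage_backward(dH, cache$ch, params)
    g$dbeta <- g$dbeta + ch$dbeta
    dX <- ch$dZ
  } else { # parallel_concat
    g$dW_fuse <- crossprod(cache$Hcat, dH)
    g$db_fuse <- colSums(dH)
    dHcat <- tcrossprod(dH, params$W_fuse)
    C <- params$dim_model
    dsp_out <- dHcat[, seq_len(C), drop = FALSE]
    dch_out <- dHcat[, C + seq_len(C), drop = FALSE]
    ch <- channel_stage_backward(dch_out, cache$ch, params)
    g$dbeta <- g$dbeta + ch$dbeta
    dX <- ch$dZ + take_sp(spatial_stage_backward(dsp_out, cache$sp, params))
  }
  g$dX <- dX
  g
}

## Full backward pass. Supply either a label y (gradients of the
## binary cross-entropy loss) or dlogit directly (e.g. 1 for gradients of
## the raw bag logit, as instance attribution uses). Returns parameter
## gradients plus "taps": the gradient of the objective with respect to
## the encoder output, the attention-block output, and the decoder output.
camil_backward <- function(params, cache, y = NULL, dlogit = NULL) {
  if (is.null(dlogit)) {
    if (is.null(y)) stop("need y or dlogit")
    dlogit <- sigmoid(cache$logit) - y   # d BCE / d logit
  }
  z <- cache$z
  dw_cls <- dlogit * z
  db_cls <- dlogit
  dz <- dlogit * params$w_cls

  ## attention pooling backward
  pc <- cache$pool
  Hd <- pc$H; Tm <- pc$Tm; wts <- pc$w
  dwts <- drop(Hd %*% dz)
  dHd <- outer(wts, dz)
  ds <- wts * (dwts - sum(dwts * wts))
  dT <- outer(ds, params$w_pool)
  dw_pool <- drop(crossprod(Tm, ds))
  dPreT <- dT * (1 - Tm^2)
  dHd <- dHd + dPreT %*% params$V_pool
  dV_pool <- crossprod(dPreT, Hd)

  ## decoder backward
  ddec_pre <- dHd * (cache$dec_pre > 0)
  dW_dec <- crossprod(cache$H, ddec_pre)
  db_dec <- colSums(ddec_pre)
  dH <- tcrossprod(ddec_pre, params$W_dec)

  ## cascaded block backward
  bb <- block_backward(dH, cache$block, params)
  dXe <- bb$dX

  ## encoder backward
  denc_pre <- dXe * (cache$enc_pre > 0)
  dW_enc <- crossprod(cache$X, denc_pre)
  db_enc <- colSums(denc_pre)

  grads <- list(W_enc = dW_enc, b_enc = db_enc,
                W_A = bb$dW_A, b_A = bb$db_A,
                W_B = bb$dW_B, b_B = bb$db_B,
                W_D = bb$dW_D, b_D = bb$db_D,
                alpha = bb$dalpha, beta = bb$dbeta,
                W_fuse = bb$dW_fuse, b_fuse = bb$db_fuse,
                W_dec = dW_dec, b_dec = db_dec,
                V_pool = dV_pool, w_pool = dw_pool,
                w_cls = dw_cls, b_cls = db_cls)
  list(grads = grads,
       taps = list(encoder = dXe, attention = dH, decoder = dHd))
}

## Binary cross-entropy of one bag, clamped away from 0/1 for stability.
bce_loss <- function(prob, y, eps = 1e-12) {
  p <- min(max(prob, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}
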