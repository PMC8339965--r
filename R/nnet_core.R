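#' Simulate the early-stopping rule on a validation-loss trajectory
#'
#' The training protocol for iterative backends: after each epoch the
#' validation loss is compared with the best loss so far; when it has failed
#' to improve for `patience` consecutive epochs, training stops and the
#' model is restored to the state with the best validation loss. This pure
#' function applies that rule to a given loss sequence and is the reference
#' for what the training loops do.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Consecutive non-improving epochs tolerated (default 4).
#' @param max_epochs Cap on epochs (default the trajectory length).
#'
#' @return A list with `stop_epoch` (last epoch run) and `best_epoch`
#'   (epoch whose state is restored; the argmin of the losses seen).
#' @export
#' @examples
#' early_stopping_trace(c(1.0, 0.9, 0.91, 0.92, 0.93, 0.94), patience = 4)
early_stopping_trace <- function(val_losses, patience = 4L,
                                 max_epochs = length(val_losses)) {
  best <- Inf
  best_epoch <- 0L
  since <- 0L
  last <- 0L
  for (e in seq_len(min(max_epochs, length(val_losses)))) {
    last <- e
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_epoch <- e
      since <- 0L
    } else {
      since <- since + 1L
    }
    if (since >= patience) break
  }
  list(stop_epoch = last, best_epoch = best_epoch)
}

# Generic epoch loop with patience-based early stopping and best-state
# restore. step_fn(state, epoch) must return list(state, train_loss,
# val_loss); the returned state is the snapshot with the lowest validation
# loss, exactly as early_stopping_trace() prescribes.
train_iterative <- function(state, step_fn, max_epochs, patience) {
  best <- Inf
  best_state <- state
  best_epoch <- 0L
  since <- 0L
  log <- list()
  stop_epoch <- 0L
  for (epoch in seq_len(max_epochs)) {
    res <- step_fn(state, epoch)
    state <- res$state
    stop_epoch <- epoch
    log[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = res$train_loss,
                                   val_loss = res$val_loss)
    if (res$val_loss < best) {
      best <- res$val_loss
      best_state <- state
      best_epoch <- epoch
      since <- 0L
    } else {
      since <- since + 1L
    }
    if (since >= patience) break
  }
  list(state = best_state, log = dplyr::bind_rows(log),
       stop_epoch = stop_epoch, best_epoch = best_epoch)
}

# ---- Adam optimizer over a named list of arrays ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (k in names(params)) {
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * grads[[k]]
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- opt$m[[k]] / (1 - beta1^opt$t)
    vhat <- opt$v[[k]] / (1 - beta2^opt$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

row_softmax <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

# ---- Tiny single-block self-attention pair encoder ----
#
# Token + position + segment embeddings, one single-head self-attention
# block with residual, one ReLU feed-forward block with residual, mean
# pooling, softmax head. Trained from random initialization; small enough
# to fit on a few hundred pairs in seconds on one CPU.

attn_init <- function(vocab_size, n_classes, d = 16L, dk = 16L, dff = 32L,
                      max_len = 32L) {
  g <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.2), nr, nc)
  list(E = g(vocab_size, d), P = g(max_len, d), S = g(2, d),
       Wq = g(d, dk), Wk = g(d, dk), Wv = g(d, dk), Wo = g(dk, d),
       W1 = g(d, dff), b1 = numeric(dff), W2 = g(dff, d), b2 = numeric(d),
       Wc = g(d, n_classes), bc = numeric(n_classes))
}

attn_forward <- function(params, ids, segs, label = NULL, want_grads = FALSE) {
  T_ <- length(ids)
  dk <- ncol(params$Wq)
  X <- params$E[ids, , drop = FALSE] +
    params$P[seq_len(T_), , drop = FALSE] +
    params$S[segs, , drop = FALSE]
  Q <- X %*% params$Wq
  K <- X %*% params$Wk
  V <- X %*% params$Wv
  Sc <- Q %*% t(K) / sqrt(dk)
  A <- row_softmax(Sc)
  Hp <- A %*% V
  H <- Hp %*% params$Wo
  Z <- X + H
  U <- sweep(Z %*% params$W1, 2, params$b1, `+`)
  R <- pmax(U, 0)
  F_ <- sweep(R %*% params$W2, 2, params$b2, `+`)
  Z2 <- Z + F_
  p <- colMeans(Z2)
  logits <- drop(p %*% params$Wc) + params$bc
  probs <- softmax(logits)
  out <- list(probs = probs)
  if (!is.null(label)) out$loss <- -log(max(probs[label], 1e-12))
  if (!want_grads) return(out)

  dlogits <- probs
  dlogits[label] <- dlogits[label] - 1
  g <- list()
  g$Wc <- outer(p, dlogits)
  g$bc <- dlogits
  dp <- drop(params$Wc %*% dlogits)
  dZ2 <- matrix(dp / T_, T_, length(dp), byrow = TRUE)
  # feed-forward block
  dF <- dZ2
  g$W2 <- t(R) %*% dF
  g$b2 <- colSums(dF)
  dR <- dF %*% t(params$W2)
  dU <- dR * (U > 0)
  g$W1 <- t(Z) %*% dU
  g$b1 <- colSums(dU)
  dZ <- dZ2 + dU %*% t(params$W1)
  # attention block
  dH <- dZ
  g$Wo <- t(Hp) %*% dH
  dHp <- dH %*% t(params$Wo)
  g_V <- t(A) %*% dHp
  dA <- dHp %*% t(V)
  dSc <- A * (dA - rowSums(dA * A))
  dQ <- dSc %*% K / sqrt(dk)
  dK <- t(dSc) %*% Q / sqrt(dk)
  g$Wq <- t(X) %*% dQ
  g$Wk <- t(X) %*% dK
  g$Wv <- t(X) %*% g_V
  dX <- dZ + dQ %*% t(params$Wq) + dK %*% t(params$Wk) + g_V %*% t(params$Wv)
  g$E <- matrix(0, nrow(params$E), ncol(params$E))
  g$P <- matrix(0, nrow(params$P), ncol(params$P))
  g$S <- matrix(0, 2, ncol(params$S))
  for (t in seq_len(T_)) {
    g$E[ids[t], ] <- g$E[ids[t], ] + dX[t, ]
    g$P[t, ] <- g$P[t, ] + dX[t, ]
    g$S[segs[t], ] <- g$S[segs[t], ] + dX[t, ]
  }
  out$grads <- g
  out
}

# ---- Tiny one-hidden-layer MLP on fixed feature vectors ----

mlp_init <- function(d_in, n_classes, hidden = 32L) {
  g <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(1 / nr)), nr, nc)
  list(W1 = g(d_in, hidden), b1 = numeric(hidden),
       W2 = g(hidden, n_classes), b2 = numeric(n_classes))
}

mlp_forward <- function(params, x, label = NULL, want_grads = FALSE) {
  u <- drop(x %*% params$W1) + params$b1
  r <- pmax(u, 0)
  logits <- drop(r %*% params$W2) + params$b2
  probs <- softmax(logits)
  out <- list(probs = probs)
  if (!is.null(label)) out$loss <- -log(max(probs[label], 1e-12))
  if (!want_grads) return(out)
  dlogits <- probs
  dlogits[label] <- dlogits[label] - 1
  g <- list()
  g$W2 <- outer(r, dlogits)
  g$b2 <- dlogits
  dr <- drop(params$W2 %*% dlogits)
  du <- dr * (u > 0)
  g$W1 <- outer(drop(x), du)
  g$b1 <- du
  out$grads <- g
  out
}

# Accumulate grads over a batch of closures returning list(loss, grads);
# returns averaged loss and grads plus L2 penalty gradient on weight
# matrices (biases and embeddings excluded from the penalty by name).
l2_grad_names <- function(params) {
  names(params)[vapply(params, is.matrix, logical(1))]
}

add_l2 <- function(grads, params, l2, n) {
  if (l2 <= 0) return(grads)
  for (k in l2_grad_names(params)) {
    grads[[k]] <- grads[[k]] + l2 * params[[k]]
  }
  grads
}

zero_like <- function(params) lapply(params, function(p) p * 0)
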