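# Layer plumbing for the convolutional streams.  Tensors are stored as
# (len x B) matrices of flattened per-sample arrays with layout
# pos(h, w, c) = h + (w-1)*H + (c-1)*H*W; convolutions are valid (no
# padding), stride 1, realised as im2col gathers + one BLAS GEMM; pooling is
# non-overlapping max pooling (trailing remainder rows/columns dropped).

# Index plan for one conv(+pool) stage.
.stagePlan <- function(C, H, W, kh, kw, outC, ph, pw) {
  H2 <- H - kh + 1L; W2 <- W - kw + 1L
  if (H2 < 1L || W2 < 1L)
    stop(sprintf("convolution kernel %dx%d larger than input %dx%d",
                 kh, kw, H, W))
  K <- C * kh * kw; P <- H2 * W2
  idx <- integer(K * P)
  e <- 1L
  # column p = i + (j-1)*H2; entry order (di, dj, c) fixed to match weights
  for (j in seq_len(W2)) for (i in seq_len(H2)) {
    for (c in seq_len(C)) for (dj in 0:(kw - 1L)) for (di in 0:(kh - 1L)) {
      idx[e] <- (i + di) + (j + dj - 1L) * H + (c - 1L) * H * W
      e <- e + 1L
    }
  }
  idx <- matrix(idx, K, P)
  H3 <- H2 %/% ph; W3 <- W2 %/% pw
  if (H3 < 1L || W3 < 1L)
    stop(sprintf("pool kernel %dx%d larger than feature map %dx%d",
                 ph, pw, H2, W2))
  Q <- H3 * W3 * outC
  gidx <- integer(ph * pw * Q)
  e <- 1L
  # pooled layout = next stage's input layout: i' + (j'-1)*H3 + (oc-1)*H3*W3
  for (oc in seq_len(outC)) for (jp in seq_len(W3)) for (ip in seq_len(H3)) {
    for (dj in 0:(pw - 1L)) for (di in 0:(ph - 1L)) {
      i <- (ip - 1L) * ph + 1L + di
      j <- (jp - 1L) * pw + 1L + dj
      gidx[e] <- oc + (i + (j - 1L) * H2 - 1L) * outC
      e <- e + 1L
    }
  }
  gidx <- matrix(gidx, ph * pw, Q)
  list(C = C, H = H, W = W, kh = kh, kw = kw, outC = outC, ph = ph, pw = pw,
       K = K, P = P, convH = H2, convW = W2, poolH = H3, poolW = W3, Q = Q,
       idx = idx, gidx = gidx)
}

# Two-stage plan for a branch spec (list with inChannels, inLength, conv1,
# depth1, pool1, conv2, depth2, pool2).  `bufs` caches per-batch-size
# workspaces so the training loop allocates nothing large per step.
.branchPlan <- function(spec) {
  s1 <- .stagePlan(1L, spec$inChannels, spec$inLength,
                   spec$conv1[1], spec$conv1[2], spec$depth1,
                   spec$pool1[1], spec$pool1[2])
  s2 <- .stagePlan(spec$depth1, s1$poolH, s1$poolW,
                   spec$conv2[1], spec$conv2[2], spec$depth2,
                   spec$pool2[1], spec$pool2[2])
  list(stage1 = s1, stage2 = s2, flattened = s2$Q,
       inLen = spec$inChannels * spec$inLength,
       bufs = new.env(parent = emptyenv()))
}

# Persistent per-batch-size single-precision workspace for one branch plan.
.getBufs <- function(plan, B) {
  key <- as.character(B)
  if (!is.null(plan$bufs[[key]])) return(plan$bufs[[key]])
  s1 <- plan$stage1; s2 <- plan$stage2
  ws <- cpp_branch_ws(as.integer(B), as.integer(plan$inLen),
                      s1$K, s1$P, s1$outC, s1$Q,
                      s2$K, s2$P, s2$outC, s2$Q)
  plan$bufs[[key]] <- ws
  ws
}

.initMat <- function(nr, nc) {
  s <- sqrt(6 / nc)   # fan-in scaled uniform
  matrix(runif(nr * nc, -s, s), nr, nc)
}

.initBranchParams <- function(plan) {
  list(W1 = .initMat(plan$stage1$outC, plan$stage1$K),
       b1 = numeric(plan$stage1$outC),
       W2 = .initMat(plan$stage2$outC, plan$stage2$K),
       b2 = numeric(plan$stage2$outC))
}

# Forward one branch through its persistent single-precision workspace;
# returns the flattened pooled features (Q2 x B).  The convolution
# activations are ReLU'd inside the fused max-pool kernel
# (max(0, max(group)) == maxpool(relu(x))), so the backward pass needs only
# the workspace state, which stays valid until the next forward pass on
# this plan and batch size.
.branchForward <- function(X, pars, plan, keepCache = FALSE) {
  s1 <- plan$stage1; s2 <- plan$stage2
  ws <- .getBufs(plan, ncol(X))
  F <- cpp_branch_fwd(ws, X, s1$idx, s1$gidx, s2$idx, s2$gidx,
                      pars$W1, pars$b1, pars$W2, pars$b2)
  list(F = F, ws = if (keepCache) ws)
}

# Backward one branch from dF (Q2 x B); returns weight gradients.  The
# fused ReLU needs no separate mask: clamped pooling groups carry argmax 0
# and receive no gradient.
.branchBackward <- function(dF, cache, pars, plan) {
  cpp_branch_bwd(cache$ws, dF, plan$stage2$idx, pars$W2)
}

# --- double-precision reference implementation -------------------------
# The same forward/backward pass written in plain R (double precision, no
# workspaces).  Used to verify the single-precision engine and for
# finite-difference gradient checks; not used on the training path.

.im2colRef <- function(X, idx) {
  K <- nrow(idx); P <- ncol(idx); B <- ncol(X)
  out <- matrix(0, K, P * B)
  for (b in seq_len(B))
    out[, ((b - 1) * P + 1):(b * P)] <- matrix(X[idx, b], K, P)
  out
}

.maxpoolRef <- function(A, gidx, P) {
  C <- nrow(A); B <- ncol(A) / P
  g <- nrow(gidx); Q <- ncol(gidx)
  out <- matrix(0, Q, B); amax <- matrix(0L, Q, B)
  for (b in seq_len(B)) {
    block <- as.vector(A[, ((b - 1) * P + 1):(b * P)])
    vals <- matrix(block[gidx], g, Q)
    top <- max.col(t(vals), ties.method = "first")
    mx <- vals[cbind(top, seq_len(Q))]
    keep <- mx > 0
    out[keep, b] <- mx[keep]
    amax[keep, b] <- gidx[cbind(top, seq_len(Q))][keep]
  }
  list(out = out, amax = amax)
}

.branchForwardRef <- function(X, pars, plan) {
  s1 <- plan$stage1; s2 <- plan$stage2
  Xc1 <- .im2colRef(X, s1$idx)
  A1 <- pars$W1 %*% Xc1 + pars$b1
  mp1 <- .maxpoolRef(A1, s1$gidx, s1$P)
  Xc2 <- .im2colRef(mp1$out, s2$idx)
  A2 <- pars$W2 %*% Xc2 + pars$b2
  mp2 <- .maxpoolRef(A2, s2$gidx, s2$P)
  list(F = mp2$out, Xc1 = Xc1, amax1 = mp1$amax, Xc2 = Xc2,
       amax2 = mp2$amax)
}

.maxpoolBwdRef <- function(dOut, amax, C, P) {
  B <- ncol(dOut)
  out <- matrix(0, C, P * B)
  S <- C * P
  for (b in seq_len(B)) {
    sel <- amax[, b] > 0
    idx <- amax[sel, b] + (b - 1) * S
    out[idx] <- out[idx] + dOut[sel, b]
  }
  out
}

.branchBackwardRef <- function(dF, cache, pars, plan) {
  s1 <- plan$stage1; s2 <- plan$stage2
  dA2 <- .maxpoolBwdRef(dF, cache$amax2, s2$outC, s2$P)
  dW2 <- tcrossprod(dA2, cache$Xc2)
  db2 <- rowSums(dA2)
  G2 <- crossprod(pars$W2, dA2)
  B <- ncol(dF)
  dX2 <- matrix(0, s1$Q, B)
  K2P2 <- s2$K * s2$P
  for (b in seq_len(B)) {
    g <- as.vector(G2[, ((b - 1) * s2$P + 1):(b * s2$P)])
    for (e in seq_len(K2P2))
      dX2[s2$idx[e], b] <- dX2[s2$idx[e], b] + g[e]
  }
  dA1 <- .maxpoolBwdRef(dX2, cache$amax1, s1$outC, s1$P)
  list(W1 = tcrossprod(dA1, cache$Xc1), b1 = rowSums(dA1),
       W2 = dW2, b2 = db2)
}

# Reference model forward/backward over branches + head, double precision.
.modelForwardRef <- function(params, plans, inputs, fcRelu) {
  feats <- list(); caches <- list()
  for (nm in names(plans)) {
    bf <- .branchForwardRef(inputs[[nm]], params[[nm]], plans[[nm]])
    feats[[nm]] <- bf$F
    caches[[nm]] <- bf
  }
  Fin <- if (length(feats) == 1L) feats[[1]] else do.call(rbind, feats)
  Hfc <- params$head$Wfc %*% Fin + params$head$bfc
  Rfc <- if (fcRelu) Hfc * (Hfc > 0) else Hfc
  logits <- params$head$Wout %*% Rfc + params$head$bout
  list(Fin = Fin, Hfc = Hfc, Rfc = Rfc, logits = logits,
       prob = .softmax(logits), caches = caches)
}

.modelBackwardRef <- function(params, plans, fwd, y, fcRelu) {
  B <- ncol(fwd$logits)
  dLogits <- fwd$prob
  dLogits[cbind(y, seq_len(B))] <- dLogits[cbind(y, seq_len(B))] - 1
  dLogits <- dLogits / B
  gHead <- list(Wout = tcrossprod(dLogits, fwd$Rfc),
                bout = rowSums(dLogits))
  dRfc <- crossprod(params$head$Wout, dLogits)
  dHfc <- if (fcRelu) dRfc * (fwd$Hfc > 0) else dRfc
  gHead$Wfc <- tcrossprod(dHfc, fwd$Fin)
  gHead$bfc <- rowSums(dHfc)
  dFin <- crossprod(params$head$Wfc, dHfc)
  grads <- list(head = gHead)
  off <- 0L
  for (nm in names(plans)) {
    q <- plans[[nm]]$flattened
    dF <- dFin[(off + 1L):(off + q), , drop = FALSE]
    off <- off + q
    grads[[nm]] <- .branchBackwardRef(dF, fwd$caches[[nm]], params[[nm]],
                                      plans[[nm]])
  }
  grads
}

.softmax <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Full forward through branches + head.  `inputs` is a named list of
# (len x B) matrices, one per branch (names match names(model$branches)).
.modelForward <- function(params, plans, inputs, fcRelu, keepCache = FALSE) {
  feats <- list(); caches <- list()
  for (nm in names(plans)) {
    bf <- .branchForward(inputs[[nm]], params[[nm]], plans[[nm]], keepCache)
    feats[[nm]] <- bf$F
    if (keepCache) caches[[nm]] <- bf
  }
  Fin <- if (length(feats) == 1L) feats[[1]] else do.call(rbind, feats)
  Hfc <- params$head$Wfc %*% Fin + params$head$bfc
  Rfc <- if (fcRelu) Hfc * (Hfc > 0) else Hfc
  logits <- params$head$Wout %*% Rfc + params$head$bout
  list(Fin = Fin, Hfc = Hfc, Rfc = Rfc, logits = logits,
       prob = .softmax(logits), caches = caches)
}

# Backward through head + branches; y is 1-based class index per column.
.modelBackward <- function(params, plans, fwd, y, fcRelu) {
  B <- ncol(fwd$logits)
  dLogits <- fwd$prob
  dLogits[cbind(y, seq_len(B))] <- dLogits[cbind(y, seq_len(B))] - 1
  dLogits <- dLogits / B
  gHead <- list(Wout = tcrossprod(dLogits, fwd$Rfc),
                bout = rowSums(dLogits))
  dRfc <- crossprod(params$head$Wout, dLogits)
  dHfc <- if (fcRelu) dRfc * (fwd$Hfc > 0) else dRfc
  gHead$Wfc <- tcrossprod(dHfc, fwd$Fin)
  gHead$bfc <- rowSums(dHfc)
  dFin <- crossprod(params$head$Wfc, dHfc)
  grads <- list(head = gHead)
  off <- 0L
  for (nm in names(plans)) {
    q <- plans[[nm]]$flattened
    dF <- dFin[(off + 1L):(off + q), , drop = FALSE]
    off <- off + q
    grads[[nm]] <- .branchBackward(dF, fwd$caches[[nm]], params[[nm]],
                                   plans[[nm]])
  }
  grads
}

# Adam optimiser state over a nested params list (two levels deep).
.adamInit <- function(params) {
  zero <- function(x) rapply(x, function(v) v * 0, how = "replace")
  list(m = zero(params), v = zero(params), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (g in names(params)) for (p in names(params[[g]])) {
    gr <- grads[[g]][[p]]
    state$m[[g]][[p]] <- beta1 * state$m[[g]][[p]] + (1 - beta1) * gr
    state$v[[g]][[p]] <- beta2 * state$v[[g]][[p]] + (1 - beta2) * gr * gr
    params[[g]][[p]] <- params[[g]][[p]] -
      lr * (state$m[[g]][[p]] / c1) / (sqrt(state$v[[g]][[p]] / c2) + eps)
  }
  list(params = params, state = state)
}
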