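# Trainable model internals: cached forward passes, hand-written backward
# passes and the assembly of the joint objective. No automatic
# differentiation is used anywhere; every gradient is analytic and the full
# pipeline is checked against central finite differences in the test suite.
#
# Parameter container (`par`, a nested list of numeric arrays only):
#   lambda_logits  fusion-weight logits (lambda = softmax)
#   W_in           input projection F x d
#   layers[[k]]    W / a_src / a_dst per head
#   gamma          multi-hop weights
#   Wc             per-drug classifier head (C x d)
#   head           pair-scoring MLP (W1, b1, w2, b2)
#   cross          cross-attention projections (Wq, Wk, Wv)

LEAKY_SLOPE <- 0.2
STAB_EPS <- 1e-8

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

init_model_params <- function(n_features, n_modalities, n_classes, cfg) {
  d <- cfg$hidden_dim
  with_seed(cfg$seed * 7919L + 13L, {
    a_scale <- sqrt(6 / (2 * d + 1))  # Glorot fan for the attention vector
    layers <- lapply(seq_len(cfg$gnn_layers), function(k) {
      list(W = lapply(seq_len(cfg$n_heads), function(h) glorot(d, d)),
           a_src = lapply(seq_len(cfg$n_heads), function(h)
             stats::runif(d, -a_scale, a_scale)),
           a_dst = lapply(seq_len(cfg$n_heads), function(h)
             stats::runif(d, -a_scale, a_scale)))
    })
    pooled_dim <- if (cfg$use_modality_views) 2L * d else 0L
    d_in <- 3L * d + pooled_dim
    list(lambda_logits = rep(0, n_modalities),
         W_in = glorot(n_features, d),
         layers = layers,
         gamma = rep(1 / cfg$gnn_layers, cfg$gnn_layers),
         Wc = glorot(n_classes, d) * 0.1,
         head = list(W1 = glorot(d_in, cfg$pair_hidden),
                     b1 = rep(0, cfg$pair_hidden),
                     w2 = stats::runif(cfg$pair_hidden, -0.1, 0.1),
                     b2 = 0),
         cross = list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d)))
  })
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

# ---- encoder forward / backward ------------------------------------------

enc_forward <- function(X, A, par, cfg, train_mode = FALSE) {
  H0 <- X %*% par$W_in
  K <- length(par$layers)
  states <- vector("list", K + 1L)
  states[[1L]] <- H0
  caches <- vector("list", K)
  H <- H0
  if (identical(cfg$ablation, "no_gbap")) {
    anorm <- A / rowSums(A)
    for (k in seq_len(K)) {
      pre <- anorm %*% (H %*% par$layers[[k]]$W[[1L]])
      hn <- relu(pre)
      caches[[k]] <- list(H = H, pre = pre)
      H <- hn
      states[[k + 1L]] <- H
    }
    return(list(Z = H, states = states, caches = caches, H0 = H0,
                A = A, anorm = anorm, mean_mode = TRUE))
  }
  n <- nrow(X)
  p_drop <- if (train_mode) cfg$dropout else 0
  for (k in seq_len(K)) {
    ly <- par$layers[[k]]
    nh <- length(ly$W)
    hc <- vector("list", nh)
    acc <- 0
    for (h in seq_len(nh)) {
      m <- H %*% ly$W[[h]]
      u <- drop(m %*% ly$a_src[[h]])
      v <- drop(m %*% ly$a_dst[[h]])
      e <- matrix(u, n, n) + matrix(v, n, n, byrow = TRUE)
      el <- leaky_relu(e, LEAKY_SLOPE)
      alpha <- row_softmax(el, mask = A)
      if (p_drop > 0) {
        dmask <- matrix(stats::rbinom(n * n, 1L, 1 - p_drop), n, n)
        alpha_d <- alpha * dmask / (1 - p_drop)
      } else {
        dmask <- NULL
        alpha_d <- alpha
      }
      s <- alpha_d %*% m
      acc <- acc + s
      hc[[h]] <- list(M = m, E = e, alpha = alpha, alpha_d = alpha_d,
                      dmask = dmask)
    }
    pre <- acc / nh
    act <- relu(pre)
    r <- act + H0
    nr <- row_norms(r)
    caches[[k]] <- list(H = H, heads = hc, pre = pre, R = r, nr = nr)
    H <- r / (nr + STAB_EPS)
    states[[k + 1L]] <- H
  }
  z <- 0
  for (k in seq_len(K)) z <- z + par$gamma[k] * states[[k + 1L]]
  list(Z = z, states = states, caches = caches, H0 = H0, A = A,
       mean_mode = FALSE)
}

# dZ: gradient wrt the encoder output; returns parameter gradients for this
# pass (same skeleton as `par`, encoder fields only).
enc_backward <- function(fw, dZ, X, par, cfg) {
  K <- length(par$layers)
  g <- list(W_in = par$W_in * 0,
            layers = lapply(par$layers, function(ly)
              list(W = lapply(ly$W, function(w) w * 0),
                   a_src = lapply(ly$a_src, function(a) a * 0),
                   a_dst = lapply(ly$a_dst, function(a) a * 0))),
            gamma = par$gamma * 0)
  if (fw$mean_mode) {
    dH <- dZ
    for (k in rev(seq_len(K))) {
      ck <- fw$caches[[k]]
      dpre <- dH * (ck$pre > 0)
      dp <- crossprod(fw$anorm, dpre)
      g$layers[[k]]$W[[1L]] <- crossprod(ck$H, dp)
      dH <- dp %*% t(par$layers[[k]]$W[[1L]])
    }
    g$W_in <- crossprod(X, dH)
    return(g)
  }
  dstates <- vector("list", K + 1L)
  for (k in seq_len(K)) {
    dstates[[k + 1L]] <- par$gamma[k] * dZ
    g$gamma[k] <- sum(dZ * fw$states[[k + 1L]])
  }
  dstates[[1L]] <- dZ * 0
  dH0 <- dZ * 0
  for (k in rev(seq_len(K))) {
    ck <- fw$caches[[k]]
    ly <- par$layers[[k]]
    nh <- length(ly$W)
    gout <- dstates[[k + 1L]]
    # normalization h = r / (|r| + eps)
    s <- ck$nr + STAB_EPS
    proj <- rowSums(gout * ck$R)
    safe_nr <- pmax(ck$nr, 1e-30)
    dR <- gout / s - (proj / (s^2 * safe_nr)) * ck$R
    dR[ck$nr == 0, ] <- gout[ck$nr == 0, ] / STAB_EPS
    dH0 <- dH0 + dR                      # residual path
    dpre <- dR * (ck$pre > 0)
    dH_prev <- ck$H * 0
    for (h in seq_len(nh)) {
      hh <- ck$heads[[h]]
      dS <- dpre / nh
      dalpha_d <- tcrossprod(dS, hh$M)
      dM <- crossprod(hh$alpha_d, dS)
      dalpha <- if (is.null(hh$dmask)) dalpha_d
                else dalpha_d * hh$dmask / (1 - cfg$dropout)
      dEL <- hh$alpha * (dalpha - rowSums(dalpha * hh$alpha))
      dE <- dEL * (LEAKY_SLOPE + (1 - LEAKY_SLOPE) * (hh$E > 0))
      dE <- dE * fw$A
      du <- rowSums(dE)
      dv <- colSums(dE)
      dM <- dM + outer(du, ly$a_src[[h]]) + outer(dv, ly$a_dst[[h]])
      g$layers[[k]]$a_src[[h]] <- drop(crossprod(hh$M, du))
      g$layers[[k]]$a_dst[[h]] <- drop(crossprod(hh$M, dv))
      g$layers[[k]]$W[[h]] <- crossprod(ck$H, dM)
      dH_prev <- dH_prev + dM %*% t(ly$W[[h]])
    }
    dstates[[k]] <- dstates[[k]] + dH_prev
  }
  dH0 <- dH0 + dstates[[1L]]
  g$W_in <- crossprod(X, dH0)
  g
}

# ---- vectorized pair head -------------------------------------------------

acc_rows <- function(target, rows, inc) {
  rs <- rowsum(inc, group = rows)
  idx <- as.integer(rownames(rs))
  target[idx, ] <- target[idx, , drop = FALSE] + rs
  target
}

# Cross-attention over per-modality embedding views for a batch of pairs.
# Direction: query states Zq m-views at rows `qi`, key/value states Zk at
# rows `ki`. Returns pooled (np x d) plus a cache for the backward pass.
.xattn_dir <- function(Zms, qi, ki, par, cfg) {
  m_cnt <- length(Zms)
  d <- ncol(Zms[[1L]])
  np <- length(qi)
  # project once per modality on all drugs, then index the pair rows
  q <- lapply(Zms, function(z) (z %*% par$cross$Wq)[qi, , drop = FALSE])
  k <- lapply(Zms, function(z) (z %*% par$cross$Wk)[ki, , drop = FALSE])
  v <- lapply(Zms, function(z) (z %*% par$cross$Wv)[ki, , drop = FALSE])
  scale <- sqrt(d)
  top_k <- min(cfg$top_k, m_cnt)
  logits <- array(0, c(np, m_cnt, m_cnt))
  for (a in seq_len(m_cnt)) for (b in seq_len(m_cnt))
    logits[, a, b] <- fast_rowsums(q[[a]] * k[[b]]) / scale
  mask <- NULL
  if (top_k < m_cnt) {
    # cosine pre-masking on the raw views
    mask <- array(0, c(np, m_cnt, m_cnt))
    cosim <- array(0, c(np, m_cnt, m_cnt))
    un <- lapply(Zms, function(z) .unit_rows(z)$U)
    for (a in seq_len(m_cnt)) for (b in seq_len(m_cnt))
      cosim[, a, b] <- fast_rowsums(un[[a]][qi, , drop = FALSE] *
                                      un[[b]][ki, , drop = FALSE])
    for (a in seq_len(m_cnt)) {
      sl <- cosim[, a, , drop = TRUE]
      if (is.null(dim(sl))) sl <- matrix(sl, ncol = m_cnt)
      sel <- t(apply(sl, 1L, function(r) order(-r, seq_along(r))[seq_len(top_k)]))
      for (c in seq_len(top_k))
        mask[cbind(seq_len(np), a, sel[, c])] <- 1
    }
    logits[mask == 0] <- -Inf
  }
  amax <- logits[, , 1L]
  if (m_cnt > 1L) for (b in 2:m_cnt) amax <- pmax(amax, logits[, , b])
  alpha <- exp(logits - as.vector(amax))
  alpha[!is.finite(alpha)] <- 0
  asum <- alpha[, , 1L]
  if (m_cnt > 1L) for (b in 2:m_cnt) asum <- asum + alpha[, , b]
  alpha <- alpha / as.vector(asum)
  pooled <- matrix(0, np, d)
  att <- vector("list", m_cnt)
  for (a in seq_len(m_cnt)) {
    acc <- matrix(0, np, d)
    for (b in seq_len(m_cnt)) acc <- acc + alpha[, a, b] * v[[b]]
    att[[a]] <- acc
    pooled <- pooled + acc / m_cnt
  }
  list(pooled = pooled, q = q, k = k, v = v, alpha = alpha, mask = mask,
       qi = qi, ki = ki, scale = scale)
}

# Backward through one cross-attention direction. dpooled: np x d. Adds into
# `gacc` (an environment with dZms, dWq, dWk, dWv).
.xattn_dir_backward <- function(cache, dpooled, Zms, par, gacc) {
  m_cnt <- length(Zms)
  np <- nrow(dpooled)
  d <- ncol(dpooled)
  alpha <- cache$alpha
  dq <- lapply(seq_len(m_cnt), function(a) matrix(0, np, d))
  dk <- lapply(seq_len(m_cnt), function(a) matrix(0, np, d))
  dv <- lapply(seq_len(m_cnt), function(a) matrix(0, np, d))
  for (a in seq_len(m_cnt)) {
    datt <- dpooled / m_cnt
    dalpha <- matrix(0, np, m_cnt)
    for (b in seq_len(m_cnt)) {
      dalpha[, b] <- fast_rowsums(datt * cache$v[[b]])
      dv[[b]] <- dv[[b]] + alpha[, a, b] * datt
    }
    arow <- alpha[, a, , drop = TRUE]
    if (is.null(dim(arow))) arow <- matrix(arow, ncol = m_cnt)
    dlog <- arow * (dalpha - fast_rowsums(dalpha * arow))
    for (b in seq_len(m_cnt)) {
      dq[[a]] <- dq[[a]] + dlog[, b] * cache$k[[b]] / cache$scale
      dk[[b]] <- dk[[b]] + dlog[, b] * cache$q[[a]] / cache$scale
    }
  }
  for (a in seq_len(m_cnt)) {
    # reduce to per-drug rows before the d x d projections
    rq <- rowsum(dq[[a]], group = cache$qi)
    rkv <- rowsum(dk[[a]], group = cache$ki)
    rv <- rowsum(dv[[a]], group = cache$ki)
    iq <- as.integer(rownames(rq))
    ik <- as.integer(rownames(rkv))
    zq <- Zms[[a]][iq, , drop = FALSE]
    zk <- Zms[[a]][ik, , drop = FALSE]
    gacc$dWq <- gacc$dWq + crossprod(zq, rq)
    gacc$dWk <- gacc$dWk + crossprod(zk, rkv)
    gacc$dWv <- gacc$dWv + crossprod(zk, rv)
    gacc$dZms[[a]][iq, ] <- gacc$dZms[[a]][iq, , drop = FALSE] +
      rq %*% t(par$cross$Wq)
    gacc$dZms[[a]][ik, ] <- gacc$dZms[[a]][ik, , drop = FALSE] +
      rkv %*% t(par$cross$Wk) + rv %*% t(par$cross$Wv)
  }
  invisible(NULL)
}

# Pair-head forward for index vectors I, J. pooled_mode:
#   "attn"   cross-attention over modality views (full model)
#   "concat" plain mean concatenation of the views (no_msi ablation)
#   "none"   embeddings only
pairhead_forward <- function(Z, Zms, I, J, par, cfg) {
  pooled_mode <- if (!cfg$use_modality_views) "none"
                 else if (identical(cfg$ablation, "no_msi")) "concat" else "attn"
  zi <- Z[I, , drop = FALSE]
  zj <- Z[J, , drop = FALSE]
  prod <- zi * zj
  cache <- list(I = I, J = J, zi = zi, zj = zj, pooled_mode = pooled_mode)
  if (pooled_mode == "attn") {
    dir_i <- .xattn_dir(Zms, I, J, par, cfg)
    dir_j <- .xattn_dir(Zms, J, I, par, cfg)
    pool_i <- dir_i$pooled
    pool_j <- dir_j$pooled
    cache$dir_i <- dir_i
    cache$dir_j <- dir_j
  } else if (pooled_mode == "concat") {
    m_cnt <- length(Zms)
    pool_i <- Reduce(`+`, lapply(Zms, function(z) z[I, , drop = FALSE])) / m_cnt
    pool_j <- Reduce(`+`, lapply(Zms, function(z) z[J, , drop = FALSE])) / m_cnt
  }
  x1 <- if (pooled_mode == "none") cbind(zi, zj, prod)
        else cbind(zi, zj, prod, pool_i, pool_j)
  x2 <- if (pooled_mode == "none") cbind(zj, zi, prod)
        else cbind(zj, zi, prod, pool_j, pool_i)
  hd <- par$head
  mlp <- function(x) {
    h1 <- relu(sweep(x %*% hd$W1, 2L, -hd$b1))
    list(h1 = h1, logit = drop(h1 %*% hd$w2) + hd$b2)
  }
  f1 <- mlp(x1)
  f2 <- mlp(x2)
  s1 <- logistic(f1$logit)
  s2 <- logistic(f2$logit)
  cache$x1 <- x1; cache$x2 <- x2; cache$f1 <- f1; cache$f2 <- f2
  cache$s1 <- s1; cache$s2 <- s2
  list(score = (s1 + s2) / 2, cache = cache)
}

# dscore: np vector. Returns gradients: dZ (n x d contribution), dZms,
# dhead, dcross.
pairhead_backward <- function(cache, dscore, Z, Zms, par, cfg) {
  d <- ncol(Z)
  hd <- par$head
  back_half <- function(f, x, dlogit) {
    dw2 <- drop(crossprod(f$h1, dlogit))
    db2 <- sum(dlogit)
    dh1 <- outer(dlogit, hd$w2)
    dpre <- dh1 * (f$h1 > 0)
    list(dW1 = crossprod(x, dpre), db1 = colSums(dpre), dw2 = dw2, db2 = db2,
         dx = dpre %*% t(hd$W1))
  }
  dl1 <- (dscore / 2) * cache$s1 * (1 - cache$s1)
  dl2 <- (dscore / 2) * cache$s2 * (1 - cache$s2)
  b1 <- back_half(cache$f1, cache$x1, dl1)
  b2 <- back_half(cache$f2, cache$x2, dl2)
  dhead <- list(W1 = b1$dW1 + b2$dW1, b1 = b1$db1 + b2$db1,
                w2 = b1$dw2 + b2$dw2, b2 = b1$db2 + b2$db2)
  cols <- function(k) ((k - 1L) * d + 1L):(k * d)
  dzi <- b1$dx[, cols(1)] + b2$dx[, cols(2)]
  dzj <- b1$dx[, cols(2)] + b2$dx[, cols(1)]
  dprod <- b1$dx[, cols(3)] + b2$dx[, cols(3)]
  dzi <- dzi + dprod * cache$zj
  dzj <- dzj + dprod * cache$zi
  dZ <- Z * 0
  dZ <- acc_rows(dZ, cache$I, dzi)
  dZ <- acc_rows(dZ, cache$J, dzj)
  dZms <- lapply(Zms, function(z) z * 0)
  dcross <- list(Wq = par$cross$Wq * 0, Wk = par$cross$Wk * 0,
                 Wv = par$cross$Wv * 0)
  if (cache$pooled_mode != "none") {
    dpool_i <- b1$dx[, cols(4)] + b2$dx[, cols(5)]
    dpool_j <- b1$dx[, cols(5)] + b2$dx[, cols(4)]
    if (cache$pooled_mode == "attn") {
      gacc <- new.env()
      gacc$dZms <- dZms
      gacc$dWq <- dcross$Wq; gacc$dWk <- dcross$Wk; gacc$dWv <- dcross$Wv
      .xattn_dir_backward(cache$dir_i, dpool_i, Zms, par, gacc)
      .xattn_dir_backward(cache$dir_j, dpool_j, Zms, par, gacc)
      dZms <- gacc$dZms
      dcross <- list(Wq = gacc$dWq, Wk = gacc$dWk, Wv = gacc$dWv)
    } else {
      m_cnt <- length(Zms)
      for (a in seq_len(m_cnt)) {
        dZms[[a]] <- acc_rows(dZms[[a]], cache$I, dpool_i / m_cnt)
        dZms[[a]] <- acc_rows(dZms[[a]], cache$J, dpool_j / m_cnt)
      }
    }
  }
  list(dZ = dZ, dZms = dZms, dhead = dhead, dcross = dcross)
}

# ---- objective assembly ---------------------------------------------------

# One full forward + loss + backward evaluation.
# data: list(X, Xm, A, S_list, context, topology, copresc, class_labels)
# batch: list(I, J, y) pair indices and labels; tb: triplet batch.
model_step <- function(par, data, cfg, batch, tb, want_grad = TRUE,
                       train_mode = TRUE) {
  w <- cfg$loss_weights
  no_cmrg <- identical(cfg$ablation, "no_cmrg")
  ctr_w <- if (no_cmrg) 0 else w$ctr
  alpha <- w$alpha
  if (no_cmrg) alpha[4:6] <- 0

  lambda <- softmax_vec(par$lambda_logits)
  fused <- fuse_similarities(data$S_list, lambda)

  fw <- enc_forward(data$X, data$A, par, cfg, train_mode = train_mode)
  Z <- fw$Z
  need_views <- cfg$use_modality_views || alpha[4] > 0
  fwm <- NULL
  Zms <- NULL
  if (need_views) {
    fwm <- lapply(data$Xm, function(x)
      enc_forward(x, data$A, par, cfg, train_mode = train_mode))
    Zms <- lapply(fwm, `[[`, "Z")
  }

  comp <- list()
  gZ <- Z * 0
  gZms <- if (need_views) lapply(Zms, function(z) z * 0) else NULL

  # contrastive
  if (ctr_w > 0 && length(tb$anchors) > 0) {
    r <- contrastive_triplet(Z, tb, grad = want_grad, reduce = "mean")
    if (want_grad) { comp$ctr <- r$value; gZ <- gZ + ctr_w * r$grad }
    else comp$ctr <- r
  } else comp$ctr <- 0

  # similarity preservation (cosine reconstruction of the fused similarity)
  r <- similarity_preserving(Z, fused, "cosine", grad = want_grad,
                             reduce = "mean")
  dlogits <- par$lambda_logits * 0
  if (want_grad) {
    comp$sim <- r$value
    gZ <- gZ + w$lambda[1] * r$grad
    if (!identical(cfg$ablation, "no_msi")) {
      # d L_sim / d lambda via the residual matrix
      ur <- .unit_rows(Z)
      cmat <- tcrossprod(ur$U)
      cmat[ur$zero, ] <- 0; cmat[, ur$zero] <- 0
      resid <- fused - cmat
      diag(resid) <- 0
      n <- nrow(Z)
      sc <- 1 / (n * (n - 1))
      dlambda <- vapply(data$S_list, function(s) {
        s <- unclass(s); diag(s) <- 0
        2 * sum(resid * s) * sc
      }, numeric(1))
      jac <- diag(lambda) - tcrossprod(lambda)
      dlogits <- w$lambda[1] * drop(jac %*% dlambda)
    }
  } else comp$sim <- r

  # supervised: pair BCE + per-drug context cross-entropy
  ph <- pairhead_forward(Z, Zms, batch$I, batch$J, par, cfg)
  s <- .clamp(ph$score, 1e-12, 1 - 1e-12)
  comp$bce <- -mean(batch$y * log(s) + (1 - batch$y) * log(1 - s))
  ce <- supervised_ce(Z, par$Wc, data$class_labels, grad = want_grad)
  dhead <- NULL; dcross <- NULL; gWc <- par$Wc * 0
  if (want_grad) {
    dscore <- w$lambda[2] * (s - batch$y) / (s * (1 - s)) / length(s)
    pb <- pairhead_backward(ph$cache, dscore, Z, Zms, par, cfg)
    gZ <- gZ + pb$dZ
    if (need_views) for (m in seq_along(gZms))
      gZms[[m]] <- gZms[[m]] + pb$dZms[[m]]
    dhead <- pb$dhead
    dcross <- pb$dcross
    comp$ce <- ce$value
    gZ <- gZ + w$lambda[2] * ce$grad
    gWc <- gWc + w$lambda[2] * ce$grad_head
  } else comp$ce <- ce
  comp$sup <- comp$bce + comp$ce

  # regularization suite
  r <- context_alignment(Z, data$context, grad = want_grad, reduce = "mean")
  if (want_grad) { comp$ctx <- r$value; gZ <- gZ + alpha[1] * r$grad }
  else comp$ctx <- r
  r <- laplacian_smoothness(Z, data$topology, grad = want_grad, reduce = "mean")
  if (want_grad) { comp$lap <- r$value; gZ <- gZ + alpha[2] * r$grad }
  else comp$lap <- r
  r <- coprescription_kl(Z, data$copresc, weighted = TRUE, grad = want_grad,
                         reduce = "mean")
  if (want_grad) { comp$co <- r$value; gZ <- gZ + alpha[3] * r$grad }
  else comp$co <- r
  if (alpha[4] > 0 && need_views) {
    r <- mmd_alignment(Zms, bandwidth = cfg$mmd_bandwidth, grad = want_grad,
                       reduce = "mean")
    if (want_grad) {
      comp$mmd <- r$value
      for (m in seq_along(gZms)) gZms[[m]] <- gZms[[m]] + alpha[4] * r$grad[[m]]
    } else comp$mmd <- r
  } else comp$mmd <- 0
  if (alpha[5] > 0 && length(tb$anchors) > 0) {
    r <- margin_ranking(Z, tb, margin = cfg$margins$delta, grad = want_grad,
                        reduce = "mean")
    if (want_grad) { comp$rank <- r$value; gZ <- gZ + alpha[5] * r$grad }
    else comp$rank <- r
  } else comp$rank <- 0
  if (alpha[6] > 0) {
    r <- entropy_regularizer(Z = Z, head = par$Wc, grad = want_grad,
                             reduce = "mean")
    if (want_grad) {
      comp$ent <- r$value
      gZ <- gZ + alpha[6] * r$grad
      gWc <- gWc + alpha[6] * r$grad_head
    } else comp$ent <- r
  } else comp$ent <- 0

  comp$total <- ctr_w * comp$ctr + w$lambda[1] * comp$sim +
    w$lambda[2] * comp$sup +
    sum(alpha * c(comp$ctx, comp$lap, comp$co, comp$mmd, comp$rank, comp$ent))

  if (!want_grad) return(list(components = comp, score = ph$score))

  # backward through the encoder passes
  genc <- enc_backward(fw, gZ, data$X, par, cfg)
  if (need_views) {
    for (m in seq_along(fwm)) {
      gm <- enc_backward(fwm[[m]], gZms[[m]], data$Xm[[m]], par, cfg)
      genc$W_in <- genc$W_in + gm$W_in
      genc$gamma <- genc$gamma + gm$gamma
      for (k in seq_along(genc$layers)) for (h in seq_along(genc$layers[[k]]$W)) {
        genc$layers[[k]]$W[[h]] <- genc$layers[[k]]$W[[h]] + gm$layers[[k]]$W[[h]]
        genc$layers[[k]]$a_src[[h]] <- genc$layers[[k]]$a_src[[h]] +
          gm$layers[[k]]$a_src[[h]]
        genc$layers[[k]]$a_dst[[h]] <- genc$layers[[k]]$a_dst[[h]] +
          gm$layers[[k]]$a_dst[[h]]
      }
    }
  }
  grad <- list(lambda_logits = dlogits,
               W_in = genc$W_in,
               layers = genc$layers,
               gamma = genc$gamma,
               Wc = gWc,
               head = if (is.null(dhead)) zero_like(par$head) else dhead,
               cross = if (is.null(dcross)) zero_like(par$cross) else dcross)
  if (identical(cfg$ablation, "no_msi")) grad$lambda_logits <- dlogits * 0
  list(components = comp, grad = grad, score = ph$score)
}

# ---- Adam on flattened parameters ----------------------------------------

adam_init <- function(par) {
  v <- unlist(par, use.names = FALSE)
  list(m = v * 0, v = v * 0, t = 0L)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  p <- unlist(par, use.names = FALSE)
  g <- unlist(grad, use.names = FALSE)
  if (weight_decay > 0) g <- g + weight_decay * p
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  p <- p - lr * mhat / (sqrt(vhat) + eps)
  list(par = utils::relist(p, par), state = state)
}
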