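# Independent scalar-loop reference implementations used as oracles.
# These are deliberately naive (double/triple loops, no vectorization) and
# stay independent of the package's code paths.

oracle_fuse <- function(mats, w) {
  n <- nrow(mats[[1]])
  out <- matrix(0, n, n)
  for (m in seq_along(mats)) for (i in 1:n) for (j in 1:n)
    out[i, j] <- out[i, j] + w[m] * mats[[m]][i, j]
  out
}

oracle_mean_layer <- function(state, adj, W, act = identity) {
  n <- nrow(state)
  a <- adj
  for (i in 1:n) if (sum(a[i, ]) == 0) a[i, i] <- 1
  out <- matrix(0, n, ncol(W))
  for (i in 1:n) {
    nb <- which(a[i, ] > 0)
    acc <- rep(0, ncol(W))
    for (j in nb) acc <- acc + drop(state[j, ] %*% W)
    out[i, ] <- act(acc / length(nb))
  }
  out
}

oracle_attention <- function(state, adj, W, a_vec, slope = 0.2) {
  n <- nrow(state)
  d <- ncol(W)
  a <- adj
  for (i in 1:n) if (sum(a[i, ]) == 0) a[i, i] <- 1
  lrelu <- function(x) if (x > 0) x else slope * x
  alpha <- matrix(0, n, n)
  for (i in 1:n) {
    nb <- which(a[i, ] > 0)
    logits <- sapply(nb, function(j) {
      mi <- drop(state[i, ] %*% W); mj <- drop(state[j, ] %*% W)
      lrelu(sum(a_vec * c(mi, mj)))
    })
    e <- exp(logits - max(logits))
    alpha[i, nb] <- e / sum(e)
  }
  alpha
}

oracle_gat_layer <- function(state, adj, W, a_vec, slope = 0.2) {
  # single head, identity activation, no residual, no normalization
  alpha <- oracle_attention(state, adj, W, a_vec, slope)
  n <- nrow(state)
  out <- matrix(0, n, ncol(W))
  for (i in 1:n) for (j in 1:n)
    out[i, ] <- out[i, ] + alpha[i, j] * drop(state[j, ] %*% W)
  out
}

oracle_multihop <- function(states, gamma) {
  out <- states[[1]] * 0
  for (k in seq_along(states)) for (i in seq_len(nrow(out)))
    out[i, ] <- out[i, ] + gamma[k] * states[[k]][i, ]
  out
}

oracle_auc <- function(scores, labels) {
  p <- scores[labels == 1]; q <- scores[labels == 0]
  tot <- 0
  for (a in p) for (b in q) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p) * length(q))
}

bfs_connected <- function(n, from, to) {
  seen <- rep(FALSE, n); seen[1] <- TRUE; queue <- 1
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- c(to[from == v], from[to == v])
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

# ---- loss oracles ---------------------------------------------------------

oracle_contrastive <- function(Z, a, p, k, clamp = 30) {
  tot <- 0
  for (t in seq_along(a)) {
    sp <- min(max(sum(Z[a[t], ] * Z[p[t], ]), -clamp), clamp)
    sn <- min(max(sum(Z[a[t], ] * Z[k[t], ]), -clamp), clamp)
    tot <- tot + log(1 + exp(sn)) - log(1 / (1 + exp(-sp)))
  }
  tot
}

oracle_sim_sqdist <- function(Z, S) {
  n <- nrow(Z); tot <- 0
  for (i in 1:n) for (j in 1:n) if (i != j)
    tot <- tot + S[i, j] * sum((Z[i, ] - Z[j, ])^2)
  tot
}

oracle_sim_cosine <- function(Z, S) {
  n <- nrow(Z); tot <- 0
  cosf <- function(x, y) {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) 0 else sum(x * y) / (nx * ny)
  }
  for (i in 1:n) for (j in 1:n) if (i != j)
    tot <- tot + (S[i, j] - cosf(Z[i, ], Z[j, ]))^2
  tot
}

oracle_ce <- function(Z, Wc, y) {
  n <- nrow(Z); tot <- 0
  for (i in 1:n) {
    logit <- drop(Wc %*% Z[i, ])
    pr <- exp(logit - max(logit)); pr <- pr / sum(pr)
    tot <- tot - log(max(pr[y[i]], 1e-12))
  }
  tot / n
}

oracle_ctx_double_sum <- function(Z, comem, w) {
  tot <- 0
  for (p in seq_along(comem)) {
    r <- comem[[p]]
    for (i in seq_len(nrow(r))) for (j in seq_len(nrow(r)))
      tot <- tot + w[[p]] * r[i, j] * sum((Z[i, ] - Z[j, ])^2)
  }
  unname(tot)
}

oracle_ctx_contrastive <- function(Z, comem, w, tau) {
  tot <- 0
  for (p in seq_along(comem)) {
    r <- comem[[p]]
    for (i in seq_len(nrow(r))) for (j in seq_len(nrow(r)))  if (i != j) {
      d <- sqrt(sum((Z[i, ] - Z[j, ])^2))
      tot <- tot + w[[p]] * (r[i, j] * d^2 + (1 - r[i, j]) * max(0, tau - d)^2)
    }
  }
  unname(tot)
}

oracle_half_sum <- function(Z, G) {
  n <- nrow(Z); tot <- 0
  for (i in 1:n) for (j in 1:n)
    tot <- tot + G[i, j] * sum((Z[i, ] - Z[j, ])^2)
  tot / 2
}

oracle_kl <- function(Z, P, W) {
  n <- nrow(Z); tot <- 0
  for (i in 1:n) for (j in 1:n) if (P[i, j] > 0) {
    s <- 1 / (1 + exp(-sum(Z[i, ] * Z[j, ])))
    s <- min(max(s, 1e-12), 1 - 1e-12)
    wij <- if (is.matrix(W)) W[i, j] else W
    tot <- tot + wij * P[i, j] * log(P[i, j] / s)
  }
  tot
}

oracle_mmd2 <- function(X, Y, sigma) {
  kf <- function(u, v) exp(-sum((u - v)^2) / (2 * sigma^2))
  nx <- nrow(X); ny <- nrow(Y)
  t1 <- 0; for (i in 1:nx) for (j in 1:nx) t1 <- t1 + kf(X[i, ], X[j, ])
  t2 <- 0; for (i in 1:ny) for (j in 1:ny) t2 <- t2 + kf(Y[i, ], Y[j, ])
  t3 <- 0; for (i in 1:nx) for (j in 1:ny) t3 <- t3 + kf(X[i, ], Y[j, ])
  t1 / nx^2 + t2 / ny^2 - 2 * t3 / (nx * ny)
}

oracle_rank <- function(Z, a, p, k, delta) {
  tot <- 0
  for (t in seq_along(a)) {
    dj <- sum((Z[a[t], ] - Z[p[t], ])^2)
    dk <- sum((Z[a[t], ] - Z[k[t], ])^2)
    tot <- tot + max(0, delta + dj - dk)
  }
  tot
}

oracle_entropy <- function(yhat) {
  tot <- 0
  for (i in seq_len(nrow(yhat))) for (c in seq_len(ncol(yhat)))
    if (yhat[i, c] > 0) tot <- tot - yhat[i, c] * log(yhat[i, c])
  tot
}

# ---- random instances and finite differences ------------------------------

rand_sym <- function(n, lo = 0, hi = 1) {
  m <- matrix(stats::runif(n * n, lo, hi), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

rand_graph <- function(n, p = 0.5) {
  a <- matrix(stats::rbinom(n * n, 1, p), n, n)
  a <- pmax(a, t(a))
  diag(a) <- 0
  suppressWarnings(interdrug::threshold_adjacency((a + t(a)) / 2, 0.5))
}

fd_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

expect_grad_match <- function(analytic, numeric, rtol = 1e-4) {
  denom <- max(abs(numeric), abs(analytic), 1e-8)
  expect_lt(max(abs(analytic - numeric)) / denom, rtol)
}
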