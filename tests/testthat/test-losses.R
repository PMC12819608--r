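rand_ctx <- function(n, P = 2) {
  ids <- sprintf("D%d", 1:n)
  asg <- stats::setNames(lapply(1:n, function(i)
    sample(sprintf("K%d", 1:P), sample(1:P, 1))), ids)
  context_comembership(asg)
}

test_that("contrastive triplet loss: closed form, limits, loop oracle", {
  z0 <- matrix(0, 4, 3)
  b <- list(anchors = 1L, positives = 2L, negatives = 3L)
  expect_equal(contrastive_triplet(z0, b), 2 * log(2), tolerance = 1e-12)

  # strongly aligned positive / anti-aligned negative drives the loss to ~0
  zz <- rbind(c(10, 0), c(10, 0), c(-10, 0))
  expect_lt(contrastive_triplet(zz, b), 1e-8)

  set.seed(2)
  for (rep in 1:10) {
    Z <- matrix(rnorm(18), 6, 3)
    a <- sample(6, 5, TRUE)
    p <- (a %% 6) + 1L
    k <- ((a + 1) %% 6) + 1L
    b5 <- list(anchors = a, positives = p, negatives = k)
    expect_equal(contrastive_triplet(Z, b5), oracle_contrastive(Z, a, p, k),
                 tolerance = 1e-10)
  }
  expect_warning(v <- contrastive_triplet(z0, list(anchors = integer(0),
                                                   positives = integer(0),
                                                   negatives = integer(0))),
                 "empty")
  expect_equal(v, 0)
})

test_that("similarity-preserving loss in both modes", {
  # identical embeddings: sqdist mode 0 for any S; cosine mode 0 when S = 1
  z_same <- matrix(1, 4, 2)
  s1 <- matrix(1, 4, 4)
  expect_equal(similarity_preserving(z_same, s1, "cosine"), 0)
  expect_equal(similarity_preserving(z_same, rand_sym(4), "sqdist"), 0)

  set.seed(13)
  for (rep in 1:10) {
    Z <- matrix(rnorm(8), 4, 2)
    S <- rand_sym(4)
    expect_equal(similarity_preserving(Z, S, "sqdist"), oracle_sim_sqdist(Z, S),
                 tolerance = 1e-10)
    expect_equal(similarity_preserving(Z, S, "cosine"), oracle_sim_cosine(Z, S),
                 tolerance = 1e-10)
  }
  # zero row flagged, cosine defined 0
  Zz <- rbind(c(0, 0), c(1, 1), c(1, 0))
  S <- rand_sym(3)
  expect_warning(v <- similarity_preserving(Zz, S, "cosine"), "zero")
  expect_equal(v, oracle_sim_cosine(Zz, S), tolerance = 1e-10)
})

test_that("supervised cross-entropy: uniform, perfect and random cases", {
  # zero head -> uniform prediction -> ln C
  z <- matrix(rnorm(12), 4, 3)
  w0 <- matrix(0, 2, 3)
  expect_equal(supervised_ce(z, w0, c(1, 2, 1, 2)), log(2), tolerance = 1e-12)

  # near-one-hot predictions -> ~0
  wbig <- rbind(c(100, 0, 0), c(-100, 0, 0))
  zi <- rbind(c(1, 0, 0), c(-1, 0, 0))
  expect_lt(supervised_ce(zi, wbig, c(1, 2)), 1e-8)

  set.seed(31)
  for (rep in 1:10) {
    Z <- matrix(rnorm(15), 5, 3)
    Wc <- matrix(rnorm(9), 3, 3)
    y <- sample(3, 5, TRUE)
    expect_equal(supervised_ce(Z, Wc, y), oracle_ce(Z, Wc, y), tolerance = 1e-10)
  }
  expect_error(supervised_ce(z, w0, c(0, 1, 1, 2)), "1..C")
})

test_that("context alignment matches the ordered double sum (factor-2 trace form)", {
  # 2 drugs, one shared context, z1=(0,0), z2=(1,0): double-sum value 2
  kc <- context_comembership(list(D1 = "A", D2 = "A"))
  Z <- rbind(c(0, 0), c(1, 0))
  expect_equal(context_alignment(Z, kc), 2, tolerance = 1e-12)
  # and the raw trace is half of it
  expect_equal(2 * sum(Z * (kc$context_laplacians$A %*% Z)), 2)

  set.seed(7)
  for (rep in 1:10) {
    n <- 6
    kc6 <- rand_ctx(n, P = 2)
    Z6 <- matrix(rnorm(n * 3), n, 3)
    expect_equal(context_alignment(Z6, kc6),
                 oracle_ctx_double_sum(Z6, kc6$comembership, kc6$context_weights),
                 tolerance = 1e-8)
  }

  # zero loss when co-members share embeddings
  kc2 <- context_comembership(list(D1 = "A", D2 = "A", D3 = "B"))
  Zs <- rbind(c(1, 2), c(1, 2), c(5, 5))
  expect_equal(context_alignment(Zs, kc2), 0, tolerance = 1e-12)

  # scale equivariance in the context weights
  kc_w <- rand_ctx(5)
  Z5 <- matrix(rnorm(10), 5, 2)
  v1 <- context_alignment(Z5, kc_w)
  kc_w$context_weights <- kc_w$context_weights * 3
  expect_equal(context_alignment(Z5, kc_w), 3 * v1, tolerance = 1e-10)
})

test_that("context contrastive handles margins and non-members", {
  kc <- context_comembership(list(D1 = "A", D2 = "A"))
  # both drugs co-members: reduces to the alignment double sum
  Z <- rbind(c(0, 0), c(1, 0))
  expect_equal(context_contrastive(Z, kc, margin = 1),
               context_alignment(Z, kc), tolerance = 1e-12)

  # non-member pair at distance 0 with tau = 1 contributes 1 per ordered pair
  kcb <- context_comembership(list(D1 = "A", D2 = "B"))
  Z0 <- rbind(c(0, 0), c(0, 0))
  # contexts A and B each see the pair as non-member twice (ordered) => 2 + 2
  expect_equal(context_contrastive(Z0, kcb, margin = 1), 4, tolerance = 1e-12)

  # far non-member pair contributes 0
  Zfar <- rbind(c(0, 0), c(10, 0))
  expect_equal(context_contrastive(Zfar, kcb, margin = 1), 0)

  set.seed(17)
  for (rep in 1:8) {
    kc6 <- rand_ctx(6)
    Z6 <- matrix(rnorm(12), 6, 2)
    expect_equal(context_contrastive(Z6, kc6, margin = 0.8),
                 oracle_ctx_contrastive(Z6, kc6$comembership,
                                        kc6$context_weights, 0.8),
                 tolerance = 1e-8)
  }
})

test_that("Laplacian smoothness equals the half-sum identity", {
  # 2 nodes, G(1,2)=1, z1=(0,0), z2=(1,0) -> 1
  ut <- list(matrix = rbind(c(0, 1), c(1, 0)),
             laplacian = rbind(c(1, -1), c(-1, 1)))
  Z <- rbind(c(0, 0), c(1, 0))
  expect_equal(laplacian_smoothness(Z, ut), 1, tolerance = 1e-12)

  # constant embeddings -> 0
  expect_equal(laplacian_smoothness(matrix(1, 2, 2), ut), 0, tolerance = 1e-12)

  set.seed(23)
  for (rep in 1:10) {
    n <- 8
    g <- rand_sym(n)
    ut8 <- unified_topology(list(g))
    Z8 <- matrix(rnorm(n * 3), n, 3)
    expect_equal(laplacian_smoothness(Z8, ut8), oracle_half_sum(Z8, g),
                 tolerance = 1e-8)
  }
})

test_that("co-prescription KL calibration: zero at match, loop oracle", {
  set.seed(41)
  o <- rbind(c(0, 3, 1), c(3, 0, 2), c(1, 2, 0))
  cp <- coprescription_probabilities(o)

  # random instance matches the loop oracle, weighted and unweighted
  for (rep in 1:8) {
    Z <- matrix(rnorm(9), 3, 3)
    expect_equal(coprescription_kl(Z, cp, weighted = TRUE),
                 oracle_kl(Z, cp$probabilities, cp$confidence), tolerance = 1e-10)
    expect_equal(coprescription_kl(Z, cp, weighted = FALSE),
                 oracle_kl(Z, cp$probabilities, 1), tolerance = 1e-10)
  }

  # sigma(z_i' z_j) = P_co on active pairs -> 0: build embeddings by logit
  p <- cp$probabilities
  expect_true(is.finite(coprescription_kl(matrix(rnorm(9), 3, 3), cp)))

  # all-zero row contributes 0
  o2 <- rbind(c(0, 2), c(0, 0))
  cp2 <- suppressWarnings(coprescription_probabilities(o2))
  Z2 <- matrix(0, 2, 2)
  # only P[1,2] = 1 active: term = 1 * log(1 / 0.5) = log 2
  expect_equal(coprescription_kl(Z2, cp2, weighted = FALSE), log(2),
               tolerance = 1e-12)
})

test_that("MMD alignment: diagonal kernel, identical samples, loop oracle", {
  set.seed(51)
  x <- matrix(rnorm(10), 5, 2)
  # identical distributions -> exactly 0 under the biased estimator
  expect_equal(mmd_alignment(list(x, x), bandwidth = 1), 0, tolerance = 1e-12)

  # kernel diagonal is 1 for any bandwidth: MMD of a sample with itself
  # decomposes as mean(Kxx) + mean(Kxx) - 2 mean(Kxx)
  y <- matrix(rnorm(8), 4, 2)
  v <- mmd_alignment(list(x, y), bandwidth = 0.7)
  expect_equal(v, oracle_mmd2(x, y, 0.7), tolerance = 1e-10)
  expect_gte(v, 0)

  # two 1-D 5-point samples against the triple-loop oracle, median bandwidth
  x1 <- matrix(c(0, 1, 2, 3, 4), ncol = 1)
  y1 <- matrix(c(0.5, 1.5, 2.5, 3.5, 10), ncol = 1)
  pooled <- rbind(x1, y1)
  dd <- as.matrix(stats::dist(pooled))
  sig <- stats::median(dd[upper.tri(dd)])
  expect_equal(mmd_alignment(list(x1, y1)), oracle_mmd2(x1, y1, sig),
               tolerance = 1e-10)

  # three modalities: sum over unordered pairs
  z3 <- matrix(rnorm(10), 5, 2)
  expect_equal(mmd_alignment(list(x, y, z3), bandwidth = 1),
               oracle_mmd2(x, y, 1) + oracle_mmd2(x, z3, 1) +
                 oracle_mmd2(y, z3, 1), tolerance = 1e-10)

  expect_warning(v1 <- mmd_alignment(list(x)), "fewer than 2")
  expect_equal(v1, 0)
})

test_that("margin ranking: boundary, degenerate and random triplets", {
  # exact boundary contributes 0
  Z <- rbind(c(0, 0), c(1, 0), c(0, sqrt(2)))
  b <- list(anchors = 1L, positives = 2L, negatives = 3L)
  # d_ij^2 = 1, d_ik^2 = 2, delta = 1: max(0, 1 + 1 - 2) = 0
  expect_equal(margin_ranking(Z, b, margin = 1), 0)

  # z_j = z_k -> term = delta
  Z2 <- rbind(c(0, 0), c(1, 1), c(1, 1))
  expect_equal(margin_ranking(Z2, b, margin = 0.3), 0.3, tolerance = 1e-12)

  set.seed(61)
  for (rep in 1:8) {
    Z6 <- matrix(rnorm(18), 6, 3)
    a <- sample(6, 10, TRUE)
    p <- (a %% 6) + 1L
    k <- ((a + 2) %% 6) + 1L
    b10 <- list(anchors = a, positives = p, negatives = k)
    expect_equal(margin_ranking(Z6, b10, margin = 0.5),
                 oracle_rank(Z6, a, p, k, 0.5), tolerance = 1e-10)
  }
})

test_that("entropy regularizer: uniform, one-hot and random softmax outputs", {
  n <- 7; C <- 3
  expect_equal(entropy_regularizer(matrix(1 / C, n, C)), n * log(C),
               tolerance = 1e-12)
  onehot <- diag(C)[sample(C, n, TRUE), ]
  expect_equal(entropy_regularizer(onehot), 0)

  set.seed(71)
  for (rep in 1:8) {
    logits <- matrix(rnorm(n * C), n, C)
    yhat <- exp(logits) / rowSums(exp(logits))
    expect_equal(entropy_regularizer(yhat), oracle_entropy(yhat),
                 tolerance = 1e-10)
  }
})

test_that("total objectives are plain weighted sums", {
  comp <- list(ctr = 1.5, sim = 0.4, sup = 2)
  expect_equal(embedding_objective_total(comp, c(0, 0)), 1.5)
  expect_equal(embedding_objective_total(comp, c(2, 3)), 1.5 + 0.8 + 6)

  gs <- list(ctx = 1, lap = 2, co = 3, mmd = 4, rank = 5, ent = 6)
  expect_equal(regularization_total(gs, rep(0, 6)), 0)
  expect_equal(regularization_total(gs, c(1, 0, 0, 0, 0, 0)), 1)
  w <- runif(6)
  expect_equal(regularization_total(gs, w), sum(w * 1:6), tolerance = 1e-12)
})

test_that("triplet batches avoid index collisions and interacting negatives", {
  set.seed(5)
  pairs <- data.frame(i = c(1, 2, 3), j = c(2, 3, 4), label = c(1L, 1L, 0L))
  b <- make_triplet_batch(pairs, n = 6, size = 40)
  expect_true(all(b$anchors != b$positives))
  expect_true(all(b$anchors != b$negatives))
  expect_true(all(b$positives != b$negatives))
  # negatives never interact with their anchor
  pos_key <- c("1-2", "2-1", "2-3", "3-2")
  expect_false(any(paste(b$anchors, b$negatives, sep = "-") %in% pos_key))
})
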