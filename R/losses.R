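# Loss terms for the embedding objective (contrastive, similarity-preserving,
# supervised) and for the regularization suite (context alignment and its
# contrastive variant, Laplacian smoothness, co-prescription KL calibration,
# MMD modality alignment, margin ranking, entropy).
#
# Every function returns a scalar; with `grad = TRUE` it returns
# `list(value, grad)` where `grad` is the analytic gradient with respect to
# the embedding matrix Z (plus head gradients where a classifier head is
# involved). `reduce = "sum"` is the raw formula; `reduce = "mean"` divides by
# the number of active terms so the magnitude is size-independent (used by the
# training loop; the formulas themselves are defined as sums).

.reduce_scale <- function(reduce, n_terms) {
  if (identical(reduce, "mean")) 1 / max(1, n_terms) else 1
}

#' Triplet batch for contrastive and ranking losses
#'
#' Mines `size` (anchor, positive, negative) index triples from a pair-label
#' table: anchors and positives are endpoints of interacting (label 1) pairs;
#' negatives are drawn uniformly from drugs not interacting with the anchor.
#' Uses the current RNG stream (callers reseed per epoch).
#'
#' @param pairs data frame with integer columns `i`, `j` and `label` (0/1),
#'   indices in `1..n`.
#' @param n number of drugs.
#' @param size number of triples requested.
#' @return list with integer vectors `anchors`, `positives`, `negatives`
#'   (class `triplet_batch`); empty vectors when no positive pair exists.
#' @export
make_triplet_batch <- function(pairs, n, size) {
  pos <- pairs[pairs$label == 1L, , drop = FALSE]
  if (nrow(pos) == 0L || size < 1L) {
    return(structure(list(anchors = integer(0), positives = integer(0),
                          negatives = integer(0)), class = "triplet_batch"))
  }
  partners <- vector("list", n)  # interacting partners per drug
  for (r in seq_len(nrow(pos))) {
    partners[[pos$i[r]]] <- c(partners[[pos$i[r]]], pos$j[r])
    partners[[pos$j[r]]] <- c(partners[[pos$j[r]]], pos$i[r])
  }
  sel <- sample.int(nrow(pos), size, replace = TRUE)
  flip <- stats::runif(size) < 0.5
  a <- ifelse(flip, pos$j[sel], pos$i[sel])
  p <- ifelse(flip, pos$i[sel], pos$j[sel])
  neg <- vapply(seq_len(size), function(t) {
    cand <- setdiff(seq_len(n), c(a[t], p[t], partners[[a[t]]]))
    if (length(cand) == 0L) return(NA_integer_)
    cand[sample.int(length(cand), 1L)]
  }, integer(1))
  ok <- !is.na(neg)
  structure(list(anchors = a[ok], positives = p[ok], negatives = neg[ok]),
            class = "triplet_batch")
}

#' Contrastive triplet loss
#'
#' Per anchor `i` with positive `j` and negative `k`:
#' `ln(1 + exp(z_i' z_k)) - ln sigmoid(z_i' z_j)`, inner products clamped to
#' +-30 before the exp/log for stability. At all-zero embeddings each anchor
#' contributes `2 ln 2`.
#'
#' @param Z embedding matrix (drugs x d).
#' @param batch `triplet_batch`.
#' @param grad return analytic gradient wrt `Z`.
#' @param reduce `"sum"` or `"mean"` (per anchor).
#' @param clamp clamping bound on inner products.
#' @export
contrastive_triplet <- function(Z, batch, grad = FALSE,
                                reduce = c("sum", "mean"), clamp = 30) {
  reduce <- match.arg(reduce)
  a <- batch$anchors; p <- batch$positives; k <- batch$negatives
  if (length(a) == 0L) {
    warning("empty triplet batch; contrastive loss is 0")
    out <- 0
    return(if (grad) list(value = out, grad = Z * 0) else out)
  }
  s_pos <- rowSums(Z[a, , drop = FALSE] * Z[p, , drop = FALSE])
  s_neg <- rowSums(Z[a, , drop = FALSE] * Z[k, , drop = FALSE])
  cp <- .clamp(s_pos, -clamp, clamp)
  cn <- .clamp(s_neg, -clamp, clamp)
  sc <- .reduce_scale(reduce, length(a))
  val <- sum(softplus(cn) + softplus(-cp)) * sc
  if (!grad) return(val)
  g <- Z * 0
  w_neg <- logistic(cn) * (abs(s_neg) < clamp)
  w_pos <- -logistic(-cp) * (abs(s_pos) < clamp)
  for (t in seq_along(a)) {
    g[a[t], ] <- g[a[t], ] + w_neg[t] * Z[k[t], ] + w_pos[t] * Z[p[t], ]
    g[k[t], ] <- g[k[t], ] + w_neg[t] * Z[a[t], ]
    g[p[t], ] <- g[p[t], ] + w_pos[t] * Z[a[t], ]
  }
  list(value = val, grad = g * sc)
}

.unit_rows <- function(Z) {
  nrm <- row_norms(Z)
  zero <- nrm == 0
  nrm[zero] <- 1
  list(U = Z / nrm, norm = nrm, zero = zero)
}

#' Similarity-preserving loss
#'
#' Two modes over all ordered pairs `i != j`:
#' * `"sqdist"`: `sum S_ij ||z_i - z_j||^2` (embedding smoothness weighted by
#'   fused similarity);
#' * `"cosine"`: `sum (S_ij - cos(z_i, z_j))^2` (reconstruction of the fused
#'   similarity by embedding cosines; the default operative form).
#' Zero embedding rows have cosine defined as 0 (flagged).
#'
#' @param Z embedding matrix.
#' @param fused fused similarity matrix.
#' @param mode `"cosine"` or `"sqdist"`.
#' @inheritParams contrastive_triplet
#' @export
similarity_preserving <- function(Z, fused, mode = c("cosine", "sqdist"),
                                  grad = FALSE, reduce = c("sum", "mean")) {
  mode <- match.arg(mode)
  reduce <- match.arg(reduce)
  n <- nrow(Z)
  if (nrow(fused) != n) stop("shape mismatch", call. = FALSE)
  s <- unclass(fused)
  sc <- .reduce_scale(reduce, n * (n - 1))
  if (mode == "sqdist") {
    w <- s; diag(w) <- 0
    d2 <- sq_dist(Z)
    val <- sum(w * d2) * sc
    if (!grad) return(val)
    cmat <- w + t(w)
    g <- 2 * (diag(rowSums(cmat)) - cmat) %*% Z
    return(list(value = val, grad = g * sc))
  }
  ur <- .unit_rows(Z)
  if (any(ur$zero)) warning("zero embedding row(s); cosine defined as 0")
  cmat <- tcrossprod(ur$U)
  cmat[ur$zero, ] <- 0; cmat[, ur$zero] <- 0
  resid <- s - cmat
  diag(resid) <- 0
  val <- sum(resid^2) * sc
  if (!grad) return(val)
  pmat <- -2 * resid                      # dL/dC, ordered pairs
  coef <- pmat + t(pmat)                  # both orders touch c_ij symmetric in z_i
  g <- (coef %*% ur$U - rowSums(coef * cmat) * ur$U) / ur$norm
  g[ur$zero, ] <- 0
  list(value = val, grad = g * sc)
}

classifier_probs <- function(Z, head) {
  row_softmax(Z %*% t(head))
}

#' Supervised cross-entropy over drugs
#'
#' Mean cross-entropy of `softmax(W_c z_i)` against integer class labels in
#' `1..C` (probabilities clamped at 1e-12 inside the log).
#'
#' @param Z embedding matrix.
#' @param head classifier weight matrix `W_c` (C x d).
#' @param labels integer labels in `1..C`.
#' @param grad also return gradients wrt `Z` and `head`.
#' @export
supervised_ce <- function(Z, head, labels, grad = FALSE) {
  n <- nrow(Z)
  cc <- nrow(head)
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > cc))
    stop("labels must lie in 1..C", call. = FALSE)
  p <- classifier_probs(Z, head)
  idx <- cbind(seq_len(n), labels)
  val <- -mean(log(.clamp(p[idx], 1e-12, 1)))
  if (!grad) return(val)
  y <- matrix(0, n, cc)
  y[idx] <- 1
  dlog <- (p - y) / n
  list(value = val, grad = dlog %*% head, grad_head = crossprod(dlog, Z))
}

#' Combined embedding objective
#'
#' `L_ctr + lambda1 * L_sim + lambda2 * L_sup`.
#'
#' @param components named list/vector with `ctr`, `sim`, `sup`.
#' @param weights numeric `(lambda1, lambda2)`.
#' @export
embedding_objective_total <- function(components, weights = c(1, 1)) {
  components$ctr + weights[1] * components$sim + weights[2] * components$sup
}

#' Context-aware alignment loss
#'
#' `sum_p omega_p sum_{i,j} R_p(i,j) ||z_i - z_j||^2` over ordered pairs,
#' computed through the trace form `2 * tr(Z' L_p Z)` (the factor 2 reconciles
#' the ordered double sum with `tr(Z' L Z) = 1/2 sum_ij R_ij ||z_i - z_j||^2`).
#'
#' @param Z embedding matrix.
#' @param context `knowledge_context`.
#' @inheritParams contrastive_triplet
#' @export
context_alignment <- function(Z, context, grad = FALSE,
                              reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  val <- 0
  g <- if (grad) Z * 0 else NULL
  n_terms <- 0
  for (p in context$contexts) {
    w <- context$context_weights[[p]]
    lp <- context$context_laplacians[[p]]
    val <- val + w * 2 * sum(Z * (lp %*% Z))
    n_terms <- n_terms + sum(context$comembership[[p]])
    if (grad) g <- g + w * 4 * (lp %*% Z)
  }
  sc <- .reduce_scale(reduce, n_terms)
  if (!grad) return(val * sc)
  list(value = val * sc, grad = g * sc)
}

#' Context-aware contrastive loss
#'
#' Over ordered pairs `i != j` and contexts `p`:
#' `omega_p * [ R_p ||z_i - z_j||^2 + (1 - R_p) max(0, tau - ||z_i - z_j||)^2 ]`.
#'
#' @param Z embedding matrix.
#' @param context `knowledge_context`.
#' @param margin margin `tau` >= 0.
#' @inheritParams contrastive_triplet
#' @export
context_contrastive <- function(Z, context, margin = 1, grad = FALSE,
                                reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  n <- nrow(Z)
  d2 <- sq_dist(Z)
  d <- sqrt(d2)
  off <- matrix(1, n, n); diag(off) <- 0
  hinge <- pmax(0, margin - d)
  val <- 0
  kacc <- if (grad) matrix(0, n, n) else NULL
  for (p in context$contexts) {
    w <- context$context_weights[[p]]
    r <- context$comembership[[p]]
    val <- val + w * (sum(r * d2) + sum((1 - r) * off * hinge^2))
    if (grad) {
      dpos <- d; dpos[dpos == 0] <- 1
      k <- 4 * r - 4 * (1 - r) * off * hinge / dpos
      k[d == 0] <- 4 * r[d == 0]  # hinge gradient undefined at d = 0; subgradient 0
      kacc <- kacc + w * k
    }
  }
  sc <- .reduce_scale(reduce, n * (n - 1) * length(context$contexts))
  if (!grad) return(val * sc)
  g <- (diag(rowSums(kacc)) - kacc) %*% Z
  list(value = val * sc, grad = g * sc)
}

#' Laplacian smoothness over the unified topology
#'
#' `tr(Z' L_G Z) = 1/2 sum_ij G_ij ||z_i - z_j||^2`.
#'
#' @param Z embedding matrix.
#' @param topology `unified_topology` (or any list with a `laplacian` field).
#' @inheritParams contrastive_triplet
#' @export
laplacian_smoothness <- function(Z, topology, grad = FALSE,
                                 reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  lg <- topology$laplacian
  n <- nrow(Z)
  sc <- .reduce_scale(reduce, n * (n - 1))
  val <- sum(Z * (lg %*% Z)) * sc
  if (!grad) return(val)
  list(value = val, grad = 2 * (lg %*% Z) * sc)
}

#' Co-prescription KL calibration loss
#'
#' `sum_ij w_ij P_co(i,j) ln( P_co(i,j) / sigmoid(z_i' z_j) )` with
#' `w_ij = rho_ij` when `weighted`, else 1; terms with `P_co = 0` contribute 0
#' and the sigmoid is clamped to `[1e-12, 1 - 1e-12]`. Can be negative as
#' defined (the sigmoid scores are not a normalized distribution); it is 0
#' when the sigmoid matches `P_co` on every active pair.
#'
#' @param Z embedding matrix.
#' @param data `coprescription_data`.
#' @param weighted apply the confidence prior `rho`.
#' @inheritParams contrastive_triplet
#' @export
coprescription_kl <- function(Z, data, weighted = TRUE, grad = FALSE,
                              reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  p <- data$probabilities
  w <- if (weighted) data$confidence else 1
  s <- tcrossprod(Z)
  sig <- .clamp(logistic(s), 1e-12, 1 - 1e-12)
  active <- p > 0
  sc <- .reduce_scale(reduce, sum(active))
  val <- sum((w * p * (log(p + !active) - log(sig)))[active]) * sc
  if (!grad) return(val)
  gmat <- matrix(0, nrow(Z), nrow(Z))
  gmat[active] <- (-(if (length(w) > 1) w[active] else w) * p[active] *
                     (1 - sig[active]))
  g <- (gmat + t(gmat)) %*% Z
  list(value = val, grad = g * sc)
}

.gaussian_gram <- function(x, y, sigma) exp(-sq_dist(x, y) / (2 * sigma^2))

#' MMD alignment across modality embeddings
#'
#' Sum over unordered modality pairs of the biased squared maximum mean
#' discrepancy with Gaussian kernel `exp(-||x - y||^2 / (2 sigma^2))`;
#' `bandwidth = "median"` uses the median pairwise distance over the pooled
#' points. The biased estimator (self terms included) guarantees
#' non-negativity and exact 0 for identical samples. For the gradient the
#' bandwidth is held fixed (treated as a hyperparameter).
#'
#' @param embeddings list of per-modality embedding matrices (same ncol).
#' @param bandwidth positive numeric or `"median"`.
#' @param grad return list of gradients, one per modality matrix.
#' @param reduce `"mean"` divides by the number of modality pairs.
#' @export
mmd_alignment <- function(embeddings, bandwidth = "median", grad = FALSE,
                          reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  m <- length(embeddings)
  if (m < 2L) {
    warning("fewer than 2 modalities; MMD alignment is 0")
    out <- 0
    return(if (grad) list(value = 0, grad = lapply(embeddings, function(z) z * 0))
           else out)
  }
  sigma <- if (identical(bandwidth, "median")) {
    median_pairwise_dist(do.call(rbind, embeddings))
  } else as.numeric(bandwidth)
  if (!is.finite(sigma) || sigma <= 0) stop("invalid MMD bandwidth", call. = FALSE)
  val <- 0
  gl <- if (grad) lapply(embeddings, function(z) z * 0) else NULL
  for (a in seq_len(m - 1L)) for (b in seq((a + 1L), m)) {
    x <- embeddings[[a]]; y <- embeddings[[b]]
    nx <- nrow(x); ny <- nrow(y)
    kxx <- .gaussian_gram(x, x, sigma)
    kyy <- .gaussian_gram(y, y, sigma)
    kxy <- .gaussian_gram(x, y, sigma)
    val <- val + mean(kxx) + mean(kyy) - 2 * mean(kxy)
    if (grad) {
      # d k(u,v)/du = k * (v - u) / sigma^2
      gx <- (2 / (nx^2)) * ((kxx %*% x) - rowSums(kxx) * x) / sigma^2
      gy <- (2 / (ny^2)) * ((kyy %*% y) - rowSums(kyy) * y) / sigma^2
      gx <- gx - (2 / (nx * ny)) * ((kxy %*% y) - rowSums(kxy) * x) / sigma^2
      gy <- gy - (2 / (nx * ny)) * ((t(kxy) %*% x) - colSums(kxy) * y) / sigma^2
      gl[[a]] <- gl[[a]] + gx
      gl[[b]] <- gl[[b]] + gy
    }
  }
  sc <- .reduce_scale(reduce, m * (m - 1) / 2)
  if (!grad) return(val * sc)
  list(value = val * sc, grad = lapply(gl, function(g) g * sc))
}

#' Margin ranking loss over triplets
#'
#' `sum_{(i,j,k)} max(0, delta + ||z_i - z_j||^2 - ||z_i - z_k||^2)` where `j`
#' is compatible and `k` incompatible with anchor `i`.
#'
#' @param Z embedding matrix.
#' @param batch `triplet_batch`.
#' @param margin margin `delta` >= 0.
#' @inheritParams contrastive_triplet
#' @export
margin_ranking <- function(Z, batch, margin = 1, grad = FALSE,
                           reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  a <- batch$anchors; p <- batch$positives; k <- batch$negatives
  if (length(a) == 0L) {
    warning("empty triplet batch; ranking loss is 0")
    return(if (grad) list(value = 0, grad = Z * 0) else 0)
  }
  dj <- rowSums((Z[a, , drop = FALSE] - Z[p, , drop = FALSE])^2)
  dk <- rowSums((Z[a, , drop = FALSE] - Z[k, , drop = FALSE])^2)
  term <- pmax(0, margin + dj - dk)
  sc <- .reduce_scale(reduce, length(a))
  val <- sum(term) * sc
  if (!grad) return(val)
  g <- Z * 0
  act <- which(term > 0)
  for (t in act) {
    g[a[t], ] <- g[a[t], ] + 2 * (Z[k[t], ] - Z[p[t], ])
    g[p[t], ] <- g[p[t], ] - 2 * (Z[a[t], ] - Z[p[t], ])
    g[k[t], ] <- g[k[t], ] + 2 * (Z[a[t], ] - Z[k[t], ])
  }
  list(value = val, grad = g * sc)
}

#' Entropy confidence regularizer
#'
#' `-sum_i sum_c yhat_ic ln yhat_ic` with `0 ln 0 := 0`. Supply either the
#' predicted probability matrix `yhat`, or `Z` and `head` (then
#' `yhat = softmax(Z W_c')` and gradients are available).
#'
#' @param yhat predicted probability matrix (rows sum to 1), or `NULL`.
#' @param Z,head embeddings and classifier head (required for `grad`).
#' @inheritParams supervised_ce
#' @param reduce `"mean"` divides by the number of drugs.
#' @export
entropy_regularizer <- function(yhat = NULL, Z = NULL, head = NULL,
                                grad = FALSE, reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  if (is.null(yhat)) {
    if (is.null(Z) || is.null(head)) stop("need yhat, or Z and head", call. = FALSE)
    yhat <- classifier_probs(Z, head)
  }
  lp <- log(.clamp(yhat, 1e-12, 1))
  lp[yhat == 0] <- 0
  hrow <- -rowSums(yhat * lp)
  sc <- .reduce_scale(reduce, nrow(yhat))
  val <- sum(hrow) * sc
  if (!grad) return(val)
  if (is.null(Z) || is.null(head))
    stop("gradient requires Z and head", call. = FALSE)
  # d(-sum y log y)/d logit_c = -y_c (log y_c + H_i)
  dlog <- -yhat * (lp + hrow)
  list(value = val, grad = (dlog %*% head) * sc,
       grad_head = crossprod(dlog, Z) * sc)
}

#' Combined regularization objective
#'
#' `a1 L_ctx + a2 L_lap + a3 L_co + a4 L_mmd + a5 L_rank + a6 L_ent`.
#'
#' @param components named list with `ctx`, `lap`, `co`, `mmd`, `rank`, `ent`.
#' @param weights numeric vector `alpha_1..alpha_6` in that order.
#' @export
regularization_total <- function(components, weights = rep(0.1, 6)) {
  sum(weights * c(components$ctx, components$lap, components$co,
                  components$mmd, components$rank, components$ent))
}
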