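# Per-modality similarity kernels, convex similarity fusion, relational graph
# construction (threshold / kNN sparsification), pharmacological context
# co-membership structures, the unified topology and co-prescription
# probabilities. All matrices are dense; the intended scale is a few thousand
# drugs at most.

#' Modality-specific similarity matrix
#'
#' Computes a symmetric drug-by-drug similarity matrix from one modality's
#' feature matrix under a chosen kernel. The Gaussian kernel uses
#' `exp(-||x_i - x_j||^2 / (2 sigma^2))` with bandwidth `sigma` equal to the
#' median pairwise distance unless supplied. Cosine rows that are exactly zero
#' get similarity 0 to every other row (flagged with a warning); Jaccard
#' requires strictly binary input. The diagonal is the kernel's
#' self-similarity.
#'
#' @param features numeric matrix, one row per drug (>= 2 rows).
#' @param kernel one of `"cosine"`, `"gaussian"`, `"jaccard"`.
#' @param bandwidth Gaussian bandwidth; `"median"` (default) uses the median
#'   pairwise Euclidean distance.
#' @return symmetric numeric matrix with an attribute `kernel`.
#' @export
modality_similarity <- function(features, kernel = c("cosine", "gaussian", "jaccard"),
                                bandwidth = "median") {
  kernel <- match.arg(kernel)
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 rows", call. = FALSE)
  n <- nrow(features)
  s <- switch(kernel,
    cosine = {
      nrm <- row_norms(features)
      zero <- nrm == 0
      if (any(zero))
        warning(sum(zero), " zero-vector row(s); cosine similarity set to 0 for them")
      nrm[zero] <- 1
      x <- features / nrm
      m <- tcrossprod(x)
      m[zero, ] <- 0
      m[, zero] <- 0
      diag(m) <- ifelse(zero, 0, 1)
      m
    },
    gaussian = {
      sig <- if (identical(bandwidth, "median")) median_pairwise_dist(features)
             else as.numeric(bandwidth)
      if (!is.finite(sig) || sig <= 0) stop("invalid gaussian bandwidth", call. = FALSE)
      m <- exp(-sq_dist(features) / (2 * sig^2))
      attr(m, "bandwidth") <- sig
      m
    },
    jaccard = {
      if (!all(features %in% c(0, 1)))
        stop("jaccard kernel requires binary (0/1) input", call. = FALSE)
      inter <- tcrossprod(features)
      sz <- rowSums(features)
      uni <- outer(sz, sz, "+") - inter
      m <- ifelse(uni > 0, inter / uni, 0)
      diag(m) <- 1
      m
    })
  s <- (s + t(s)) / 2  # kill floating asymmetry
  dimnames(s) <- list(rownames(features), rownames(features))
  attr(s, "kernel") <- kernel
  s
}

#' Convex fusion of per-modality similarity matrices
#'
#' Elementwise convex combination `sum_m lambda_m S^(m)` with simplex weights.
#'
#' @param matrices list of symmetric drug-by-drug similarity matrices.
#' @param weights non-negative vector of length `length(matrices)` summing to 1
#'   (within 1e-6). A trainable-weight caller must softmax/project first.
#' @return fused symmetric matrix.
#' @export
fuse_similarities <- function(matrices, weights) {
  if (!is.list(matrices) || length(matrices) < 1L)
    stop("matrices must be a non-empty list", call. = FALSE)
  if (length(weights) != length(matrices))
    stop("weights length must match number of matrices", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  dims <- vapply(matrices, function(m) dim(m)[1L], integer(1))
  if (length(unique(dims)) != 1L) stop("matrices must share dimensions", call. = FALSE)
  out <- matrix(0, dims[1L], dims[1L])
  for (m in seq_along(matrices)) out <- out + weights[m] * unclass(matrices[[m]])
  dimnames(out) <- dimnames(matrices[[1L]])
  out
}

relational_graph <- function(adjacency, epsilon = NA_real_, knn_k = NA_integer_) {
  a <- unclass(adjacency)
  diag(a) <- 0
  deg <- rowSums(a)
  lap <- diag(deg) - a
  dsi <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  nlap <- diag(nrow(a)) - (a * dsi) * rep(dsi, each = nrow(a))
  iso <- which(deg == 0)
  if (length(iso) > 0)
    warning(length(iso), " isolated node(s) in relational graph")
  structure(list(adjacency = a, degree = deg, laplacian = lap,
                 normalized_laplacian = nlap, epsilon = epsilon,
                 knn_k = knn_k, isolated = iso),
            class = "relational_graph")
}

#' @export
print.relational_graph <- function(x, ...) {
  cat("Relational drug graph:", nrow(x$adjacency), "nodes,",
      sum(x$adjacency) / 2, "edges")
  if (!is.na(x$epsilon)) cat(" (threshold", x$epsilon, ")")
  if (!is.na(x$knn_k)) cat(" (kNN k =", x$knn_k, ")")
  cat("\n")
  invisible(x)
}

#' Threshold a fused similarity into a relational graph
#'
#' `A_ij = 1` iff `i != j` and `fused_ij > epsilon` (strict); diagonal forced
#' to zero. Degree, combinatorial and symmetrically normalized Laplacians are
#' recomputed. Isolated nodes are valid but flagged with a warning.
#'
#' @param fused symmetric similarity matrix.
#' @param epsilon sparsity-promoting threshold.
#' @return `relational_graph` object.
#' @export
threshold_adjacency <- function(fused, epsilon) {
  sym_check(fused, "fused")
  a <- (unclass(fused) > epsilon) * 1
  relational_graph(a, epsilon = epsilon)
}

#' k-nearest-neighbor sparsification of a fused similarity
#'
#' Each node keeps edges to its `k` highest-similarity neighbors (ties broken
#' in favor of the lower drug index); the adjacency is then symmetrized by
#' union: an edge is kept if either endpoint selected it.
#'
#' @param fused symmetric similarity matrix.
#' @param k neighbor count, `1 <= k <= N - 1`.
#' @return `relational_graph` object.
#' @export
knn_sparsify <- function(fused, k) {
  sym_check(fused, "fused")
  n <- nrow(fused)
  k <- stopifnot_count(k, "k", 1L)
  if (k > n - 1L) stop("k must be at most N - 1", call. = FALSE)
  a <- matrix(0, n, n)
  f <- unclass(fused)
  for (i in seq_len(n)) {
    s <- f[i, ]
    s[i] <- -Inf
    # order by decreasing similarity, lower index first on ties
    sel <- order(-s, seq_len(n))[seq_len(k)]
    a[i, sel] <- 1
  }
  a <- pmax(a, t(a))  # union symmetrization
  dimnames(a) <- dimnames(f)
  relational_graph(a, knn_k = k)
}

#' Context co-membership structures
#'
#' Builds one binary symmetric co-membership matrix `R_p` per pharmacological
#' context (therapeutic class, ATC code, ...): `R_p(i, j) = 1` iff `i != j`
#' and both drugs carry context `p`. Also returns per-context Laplacians
#' `L_p = D_p - R_p` and the symmetric degree normalization
#' `D_p^{-1/2} R_p D_p^{-1/2}` with zero-degree rows passed through
#' unnormalized.
#'
#' @param assignments named list mapping each drug id to a character vector of
#'   context ids (possibly empty).
#' @param drug_ids ordered drug identifiers; defaults to `names(assignments)`.
#' @param weights optional named non-negative context weights `omega_p`
#'   (default 1 for every context).
#' @return object of class `knowledge_context` with fields `comembership`,
#'   `normalized`, `context_laplacians`, `context_weights`, `contexts`,
#'   `drug_ids`.
#' @export
context_comembership <- function(assignments, drug_ids = names(assignments),
                                 weights = NULL) {
  if (is.null(drug_ids)) stop("drug ids are required", call. = FALSE)
  if (!all(drug_ids %in% names(assignments)))
    stop("unknown drug id in 'drug_ids'", call. = FALSE)
  if (!all(names(assignments) %in% drug_ids))
    stop("assignments contain unknown drug id", call. = FALSE)
  n <- length(drug_ids)
  ctxs <- sort(unique(unlist(assignments, use.names = FALSE)))
  if (length(ctxs) < 1L) stop("need at least one context", call. = FALSE)
  comem <- norm_l <- lapl <- stats::setNames(vector("list", length(ctxs)), ctxs)
  for (p in ctxs) {
    member <- vapply(drug_ids, function(d) p %in% assignments[[d]], logical(1))
    r <- outer(member, member, "&") * 1
    diag(r) <- 0
    dimnames(r) <- list(drug_ids, drug_ids)
    deg <- rowSums(r)
    dsi <- ifelse(deg > 0, 1 / sqrt(deg), 1)  # zero-degree rows unnormalized
    comem[[p]] <- r
    norm_l[[p]] <- (r * dsi) * rep(dsi, each = n)
    lapl[[p]] <- diag(deg) - r
  }
  w <- rep(1, length(ctxs))
  names(w) <- ctxs
  if (!is.null(weights)) {
    if (any(weights < 0) || any(!is.finite(weights)))
      stop("context weights must be finite and non-negative", call. = FALSE)
    w[names(weights)] <- weights
  }
  structure(list(comembership = comem, normalized = norm_l,
                 context_laplacians = lapl, context_weights = w,
                 contexts = ctxs, drug_ids = drug_ids),
            class = "knowledge_context")
}

#' Unified relational topology
#'
#' `G = sum_m S^(m) + sum_p R_p`, consolidating multimodal similarities and
#' context co-membership into one matrix, with degree
#' `D_G(i,i) = sum_j G(i,j)` (the diagonal contribution of the similarity
#' matrices is included in the degree sum, unlike the zero-diagonal adjacency
#' convention) and Laplacian `L_G = D_G - G`.
#'
#' @param matrices list of per-modality similarity matrices.
#' @param context `knowledge_context` object or `NULL`.
#' @return object of class `unified_topology` with `matrix`, `degree`,
#'   `laplacian`.
#' @export
unified_topology <- function(matrices, context = NULL) {
  n <- nrow(matrices[[1L]])
  g <- matrix(0, n, n)
  for (s in matrices) {
    if (nrow(s) != n) stop("shape mismatch among similarity matrices", call. = FALSE)
    g <- g + unclass(s)
  }
  if (!is.null(context)) {
    for (r in context$comembership) {
      if (nrow(r) != n) stop("shape mismatch between similarities and contexts",
                             call. = FALSE)
      g <- g + r
    }
  }
  deg <- rowSums(g)
  structure(list(matrix = g, degree = deg, laplacian = diag(deg) - g),
            class = "unified_topology")
}

#' Co-prescription probabilities and confidence weights
#'
#' Row-normalizes a non-negative co-prescription count matrix `O` (diagonal
#' forced to zero) into conditional probabilities `P_co`, and computes the
#' confidence prior `rho_ij = min(1, ln(1 + O_ij))` (natural logarithm).
#' All-zero rows of `O` map to all-zero rows of `P_co` (flagged).
#'
#' @param counts non-negative drug-by-drug count matrix.
#' @return object of class `coprescription_data` with `counts`,
#'   `probabilities`, `confidence`.
#' @export
coprescription_probabilities <- function(counts) {
  o <- as.matrix(counts)
  if (any(o < 0)) stop("counts must be non-negative", call. = FALSE)
  diag(o) <- 0
  rs <- rowSums(o)
  if (any(rs == 0)) warning(sum(rs == 0), " all-zero count row(s); P_co rows left 0")
  p <- o / ifelse(rs > 0, rs, 1)
  rho <- pmin(log1p(o), 1)
  structure(list(counts = o, probabilities = p, confidence = rho),
            class = "coprescription_data")
}
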