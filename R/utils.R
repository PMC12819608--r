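#' @keywords internal
"_PACKAGE"

# Shared numerical helpers. Probability clamping at 1e-12 is used in every
# log-term; logistic/softplus are clamped at +-30 where a loss definition
# requires it.

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logistic <- function(x) 1 / (1 + exp(-x))

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(.clamp(x, -700, 30))))
}

row_softmax <- function(x, mask = NULL) {
  # softmax over each row; entries where mask == 0 are excluded (exact 0 out).
  if (!is.null(mask)) x[mask == 0] <- -Inf
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  m[!is.finite(m)] <- 0
  e <- exp(x - m)
  e[!is.finite(e)] <- 0
  s <- rowSums(e)
  s[s == 0] <- 1
  e / s
}

leaky_relu <- function(x, slope = 0.2) {
  pos <- x > 0
  x * pos + (slope * x) * !pos
}

relu <- function(x) pmax(x, 0)

sym_check <- function(m, name = "matrix", tol = 1e-8) {
  if (!isTRUE(all.equal(m, t(m), tolerance = tol, check.attributes = FALSE)))
    stop(name, " must be symmetric", call. = FALSE)
  invisible(TRUE)
}

stopifnot_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x))
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}

# row L2 norms
row_norms <- function(x) sqrt(rowSums(x^2))

# rowSums without dispatch/checks, for hot loops on plain numeric matrices
fast_rowsums <- function(x) .rowSums(x, nrow(x), ncol(x))

# squared euclidean distance matrix between rows of a and rows of b
sq_dist <- function(a, b = a) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d, 0)
}

# median of pairwise euclidean distances (off-diagonal, pooled)
median_pairwise_dist <- function(x, y = NULL) {
  pts <- if (is.null(y)) x else rbind(x, y)
  d <- sqrt(sq_dist(pts))
  v <- d[upper.tri(d)]
  if (length(v) == 0 || all(v == 0)) 1 else stats::median(v)
}
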