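# Synthetic multimodal drug cohorts with planted statistical structure.
#
# The generator emulates the kind of inputs a multimodal DDI model consumes:
# several per-drug feature tables (exactly one carries cluster-separable
# signal), categorical pharmacological contexts correlated with the clusters,
# a Poisson co-prescription count matrix elevated within clusters, and
# binary interaction labels on unordered drug pairs derived from cluster
# co-membership plus label noise.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic multimodal drug cohort
#'
#' Creates `n_drugs` drugs assigned to `n_clusters` latent clusters. Modality 1
#' (the informative modality) draws features from Gaussian cluster centroids
#' with noise `noise_sd`; all remaining modalities are pure noise (Gaussian, or
#' Bernoulli 0/1 fingerprint-like columns when `binary_noise = TRUE`). Context
#' labels are the cluster id plus one random extra context per drug.
#' Co-prescription counts are Poisson with a within-cluster rate `rate_within`
#' and a between-cluster rate `rate_between` (default ratio 5:1). Pair labels
#' are 1 for within-cluster pairs and 0 otherwise, each flipped independently
#' with probability `flip_prob`, after which negatives are subsampled to an
#' approximate 1:1 balance with positives.
#'
#' @param n_drugs number of drugs (>= 2 * n_clusters).
#' @param n_modalities number of feature modalities (>= 2).
#' @param dims integer vector of per-modality feature dimensions (recycled).
#' @param n_clusters number of latent clusters.
#' @param noise_sd Gaussian noise s.d. around centroids in the informative
#'   modality.
#' @param flip_prob label flip probability in `[0, 0.5)`.
#' @param rate_within,rate_between Poisson means for co-prescription counts.
#' @param binary_noise draw noise modalities as Bernoulli(0.5) 0/1 matrices so
#'   the Jaccard kernel path is exercisable.
#' @param n_extra_contexts size of the pool of uninformative extra contexts.
#' @param seed integer seed; the cohort is a pure function of the arguments.
#' @return an object of class `synthetic_cohort`.
#' @export
generate_cohort <- function(n_drugs, n_modalities = 4L,
                            dims = rep(16L, n_modalities),
                            n_clusters = 4L, noise_sd = 0.2,
                            flip_prob = 0.05,
                            rate_within = 5, rate_between = 1,
                            binary_noise = FALSE,
                            n_extra_contexts = 3L, seed) {
  n_drugs <- stopifnot_count(n_drugs, "n_drugs", 2L)
  n_modalities <- stopifnot_count(n_modalities, "n_modalities", 2L)
  n_clusters <- stopifnot_count(n_clusters, "n_clusters", 1L)
  if (n_drugs < 2L * n_clusters)
    stop("n_drugs must be >= 2 * n_clusters", call. = FALSE)
  dims <- as.integer(rep_len(dims, n_modalities))
  if (any(dims < 1L)) stop("all modality dimensions must be positive", call. = FALSE)
  if (!is.finite(flip_prob) || flip_prob < 0 || flip_prob >= 0.5)
    stop("flip_prob must lie in [0, 0.5); labels are uninformative otherwise",
         call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)

  with_seed(seed, {
    drug_ids <- sprintf("D%04d", seq_len(n_drugs))
    cluster <- sample(rep_len(seq_len(n_clusters), n_drugs))

    feats <- vector("list", n_modalities)
    centroids <- matrix(stats::rnorm(n_clusters * dims[1L]), n_clusters, dims[1L])
    feats[[1L]] <- centroids[cluster, , drop = FALSE] +
      matrix(stats::rnorm(n_drugs * dims[1L], sd = noise_sd), n_drugs, dims[1L])
    for (m in seq_len(n_modalities)[-1L]) {
      feats[[m]] <- if (binary_noise) {
        matrix(stats::rbinom(n_drugs * dims[m], 1L, 0.5), n_drugs, dims[m])
      } else {
        matrix(stats::rnorm(n_drugs * dims[m]), n_drugs, dims[m])
      }
    }
    for (m in seq_len(n_modalities)) rownames(feats[[m]]) <- drug_ids

    extra_pool <- sprintf("X%02d", seq_len(max(1L, n_extra_contexts)))
    contexts <- lapply(seq_len(n_drugs), function(i)
      c(sprintf("C%02d", cluster[i]), sample(extra_pool, 1L)))
    names(contexts) <- drug_ids

    same <- outer(cluster, cluster, "==")
    rates <- ifelse(same, rate_within, rate_between)
    counts <- matrix(0L, n_drugs, n_drugs, dimnames = list(drug_ids, drug_ids))
    ut <- upper.tri(counts)
    counts[ut] <- stats::rpois(sum(ut), rates[ut])
    counts <- counts + t(counts)

    ii <- which(ut, arr.ind = TRUE)
    lab <- as.integer(same[ut])
    if (flip_prob > 0) {
      flip <- stats::runif(length(lab)) < flip_prob
      lab[flip] <- 1L - lab[flip]
    }
    pos <- which(lab == 1L)
    neg <- which(lab == 0L)
    if (length(neg) > length(pos)) neg <- sort(sample(neg, length(pos)))
    keep <- sort(c(pos, neg))
    pairs <- data.frame(id_a = drug_ids[ii[keep, 1L]],
                        id_b = drug_ids[ii[keep, 2L]],
                        label = lab[keep],
                        stringsAsFactors = FALSE)

    structure(list(
      n_drugs = n_drugs,
      drug_ids = drug_ids,
      cluster_assignment = cluster,
      modality_features = feats,
      informative_modality_index = 1L,
      context_labels = contexts,
      coprescription_counts = counts,
      pair_labels = pairs,
      seed = as.integer(seed),
      params = list(n_modalities = n_modalities, dims = dims,
                    n_clusters = n_clusters, noise_sd = noise_sd,
                    flip_prob = flip_prob, rate_within = rate_within,
                    rate_between = rate_between, binary_noise = binary_noise,
                    n_extra_contexts = n_extra_contexts)
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic drug cohort:", x$n_drugs, "drugs,",
      length(x$modality_features), "modalities,",
      x$params$n_clusters, "clusters\n")
  cat("  pair labels:", nrow(x$pair_labels), "pairs (",
      sum(x$pair_labels$label), "positive )\n")
  invisible(x)
}

ATOM_TYPES <- c("C", "N", "O", "S", "P", "F", "Cl", "Br")
BOND_TYPES <- c("single", "double", "triple", "aromatic")

#' Generate random connected molecular toy graphs
#'
#' Each toy graph stands in for an RDKit-parsed molecule: a random spanning
#' tree over the atoms plus a few extra bonds, with categorical atom labels
#' (element type, aromatic flag, formal charge; degree is derived from the
#' final bond list) and categorical bond types drawn uniformly.
#'
#' @param n_drugs number of graphs.
#' @param size_range length-2 `(min, max)` atom counts, min >= 2.
#' @param seed integer seed.
#' @return list of `molecular_graph` objects with fields `drug_id`, `atoms`
#'   (data frame: type, degree, aromatic, charge) and `bonds` (data frame:
#'   from, to, type; each undirected bond stored once with from < to).
#' @export
generate_molecular_toys <- function(n_drugs, size_range = c(5L, 30L), seed) {
  n_drugs <- stopifnot_count(n_drugs, "n_drugs", 1L)
  if (length(size_range) != 2L || size_range[1L] > size_range[2L])
    stop("size_range must be (min, max) with min <= max", call. = FALSE)
  if (size_range[1L] < 2L) stop("minimum atom count must be >= 2", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)

  with_seed(seed, {
    lapply(seq_len(n_drugs), function(g) {
      n <- if (size_range[1L] == size_range[2L]) size_range[1L] else
        sample(size_range[1L]:size_range[2L], 1L)
      from <- integer(0); to <- integer(0)
      for (t in 2:n) {
        p <- if (t == 2L) 1L else sample(seq_len(t - 1L), 1L)
        from <- c(from, p); to <- c(to, t)
      }
      max_extra <- min(3L, n * (n - 1L) %/% 2L - (n - 1L))
      n_extra <- if (max_extra > 0L) sample(0:max_extra, 1L) else 0L
      tries <- 0L
      while (n_extra > 0L && tries < 50L) {
        uv <- sort(sample(seq_len(n), 2L))
        tries <- tries + 1L
        if (!any(from == uv[1L] & to == uv[2L])) {
          from <- c(from, uv[1L]); to <- c(to, uv[2L])
          n_extra <- n_extra - 1L
        }
      }
      o <- order(from, to)
      bonds <- data.frame(from = from[o], to = to[o],
                          type = sample(BOND_TYPES, length(from), replace = TRUE),
                          stringsAsFactors = FALSE)
      deg <- tabulate(c(bonds$from, bonds$to), nbins = n)
      atoms <- data.frame(type = sample(ATOM_TYPES, n, replace = TRUE),
                          degree = deg,
                          aromatic = sample(0:1, n, replace = TRUE),
                          charge = sample(-1:1, n, replace = TRUE),
                          stringsAsFactors = FALSE)
      structure(list(drug_id = sprintf("M%04d", g), n_atoms = n,
                     atoms = atoms, bonds = bonds),
                class = "molecular_graph")
    })
  })
}
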