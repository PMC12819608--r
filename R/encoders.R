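# Inter-drug attention propagation and intra-drug molecular encoding.
#
# Conventions: states are (nodes x dim) matrices and transforms are
# (dim_in x dim_out) matrices applied on the right (`state %*% W`). Attention
# is computed per head with a shared attention vector split into source and
# destination halves; isolated nodes receive a self-loop so every softmax
# neighborhood is nonempty.

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Initialize encoder parameters
#'
#' One input projection `W_in` (features -> hidden), `n_layers` attention
#' layers each with `n_heads` transform matrices and attention vectors, and
#' multi-hop weights `gamma` initialized to `1/K`.
#'
#' @param input_dim feature dimension F.
#' @param hidden_dim embedding dimension d.
#' @param n_layers number of propagation layers K.
#' @param n_heads attention heads per layer (combined by averaging).
#' @param leaky_slope LeakyReLU slope for attention logits.
#' @param stability_eps epsilon in the row normalization `h / (||h|| + eps)`.
#' @param seed integer seed for the initialization draw.
#' @export
encoder_params <- function(input_dim, hidden_dim = 256L, n_layers = 3L,
                           n_heads = 8L, leaky_slope = 0.2,
                           stability_eps = 1e-8, seed = 1L) {
  stopifnot(n_layers >= 1L, stability_eps > 0)
  with_seed(seed, {
    layers <- lapply(seq_len(n_layers), function(k) {
      list(W = lapply(seq_len(n_heads), function(h) glorot(hidden_dim, hidden_dim)),
           a_src = lapply(seq_len(n_heads), function(h)
             stats::runif(hidden_dim, -0.1, 0.1)),
           a_dst = lapply(seq_len(n_heads), function(h)
             stats::runif(hidden_dim, -0.1, 0.1)))
    })
    structure(list(W_in = glorot(input_dim, hidden_dim), layers = layers,
                   hop_weights = rep(1 / n_layers, n_layers),
                   n_layers = n_layers, hidden_dim = hidden_dim,
                   n_heads = n_heads, leaky_slope = leaky_slope,
                   stability_eps = stability_eps),
              class = "encoder_params")
  })
}

# adjacency with self-loops added for isolated nodes only
.adj_selfloop <- function(graph) {
  a <- graph$adjacency
  iso <- rowSums(a) == 0
  if (any(iso)) diag(a)[iso] <- 1
  a
}

.apply_activation <- function(x, activation) {
  switch(activation, relu = relu(x), identity = x,
         stop("unknown activation: ", activation, call. = FALSE))
}

#' Mean neighborhood aggregation layer
#'
#' `h_i <- act( (1/|N(i)|) sum_{j in N(i)} W' h_j )`; isolated nodes fall back
#' to a self-loop.
#'
#' @param state node state matrix (nodes x dim_in).
#' @param graph `relational_graph`.
#' @param transform weight matrix (dim_in x dim_out).
#' @param activation `"relu"` or `"identity"`.
#' @export
mean_aggregate_layer <- function(state, graph, transform,
                                 activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (nrow(state) != nrow(graph$adjacency)) stop("shape mismatch", call. = FALSE)
  a <- .adj_selfloop(graph)
  anorm <- a / rowSums(a)
  .apply_activation(anorm %*% (state %*% transform), activation)
}

#' Attention coefficients over graph neighborhoods
#'
#' For one head: `alpha_ij = softmax_{j in N(i)} LeakyReLU(a' [W'h_i || W'h_j])`
#' with the shared attention vector split as `a = (a_src, a_dst)`. Returns a
#' dense matrix with exact zeros outside each neighborhood; every scored row
#' sums to 1 (isolated nodes get a self-loop).
#'
#' @param state node state matrix.
#' @param graph `relational_graph`.
#' @param transform head transform (dim_in x dim_out).
#' @param attn attention vector of length `2 * dim_out`.
#' @param leaky_slope LeakyReLU slope.
#' @export
attention_coefficients <- function(state, graph, transform, attn,
                                   leaky_slope = 0.2) {
  if (!all(is.finite(state)))
    stop("non-finite node state at row ",
         which(!apply(is.finite(state), 1L, all))[1L], call. = FALSE)
  d_out <- ncol(transform)
  stopifnot(length(attn) == 2L * d_out)
  m <- state %*% transform
  u <- drop(m %*% attn[seq_len(d_out)])
  v <- drop(m %*% attn[d_out + seq_len(d_out)])
  a <- .adj_selfloop(graph)
  e <- leaky_relu(outer(u, rep(1, length(v))) + outer(rep(1, length(u)), v),
                  leaky_slope)
  row_softmax(e, mask = a)
}

#' One graph attention layer
#'
#' Per head: `h_i <- sum_j alpha_ij W' h_j`; heads are averaged, the
#' activation applied, then (optionally) the residual `+ h0` (the projected
#' input; dimensions must match) and the row normalization
#' `h_i / (||h_i|| + stability_eps)`.
#'
#' @param state node state matrix (nodes x hidden_dim).
#' @param graph `relational_graph`.
#' @param params `encoder_params`.
#' @param layer layer index `k`.
#' @param h0 projected input states for the residual (`NULL` disables it).
#' @param activation `"relu"` or `"identity"`.
#' @param normalize apply the row normalization.
#' @return next state matrix; attribute `"attention"` holds the per-head
#'   coefficient matrices.
#' @export
gat_layer <- function(state, graph, params, layer, h0 = NULL,
                      activation = "relu", normalize = TRUE) {
  ly <- params$layers[[layer]]
  n_heads <- length(ly$W)
  acc <- NULL
  maps <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    alpha <- attention_coefficients(state, graph, ly$W[[h]],
                                    c(ly$a_src[[h]], ly$a_dst[[h]]),
                                    params$leaky_slope)
    s <- alpha %*% (state %*% ly$W[[h]])
    acc <- if (is.null(acc)) s else acc + s
    maps[[h]] <- alpha
  }
  out <- .apply_activation(acc / n_heads, activation)
  if (!is.null(h0)) {
    if (!all(dim(h0) == dim(out)))
      stop("residual dimension mismatch: project inputs to hidden_dim first",
           call. = FALSE)
    out <- out + h0
  }
  if (normalize) out <- out / (row_norms(out) + params$stability_eps)
  attr(out, "attention") <- maps
  out
}

#' Multi-hop aggregation of layer states
#'
#' `Z_multi = sum_k gamma_k H^(k)`; the hop weights are unconstrained.
#'
#' @param states list of K state matrices of identical shape.
#' @param hop_weights numeric vector `gamma`, length K.
#' @export
multi_hop_aggregate <- function(states, hop_weights) {
  if (length(states) != length(hop_weights))
    stop("one hop weight per state is required", call. = FALSE)
  dims <- lapply(states, dim)
  if (length(unique(dims)) != 1L) stop("state shape mismatch", call. = FALSE)
  out <- states[[1L]] * 0
  for (k in seq_along(states)) out <- out + hop_weights[k] * unclass(states[[k]])
  out
}

#' Full inter-drug encoder forward pass
#'
#' Projects features to `hidden_dim`, applies `n_layers` attention layers
#' (residual to the projected input, row normalization) and aggregates the
#' layer states with the hop weights.
#'
#' @param features drug feature matrix (drugs x F).
#' @param graph `relational_graph`.
#' @param params `encoder_params`.
#' @param attention_maps keep per-layer attention matrices.
#' @return list with `layer_states` (H^(0..K), element 1 is the projected
#'   input), `final` (Z), and `attention` when requested.
#' @export
drug_encoder <- function(features, graph, params, attention_maps = FALSE) {
  h0 <- features %*% params$W_in
  states <- vector("list", params$n_layers + 1L)
  states[[1L]] <- h0
  maps <- if (attention_maps) vector("list", params$n_layers) else NULL
  h <- h0
  for (k in seq_len(params$n_layers)) {
    h <- gat_layer(h, graph, params, k, h0 = h0)
    if (attention_maps) maps[[k]] <- attr(h, "attention")
    attr(h, "attention") <- NULL
    states[[k + 1L]] <- h
  }
  z <- multi_hop_aggregate(states[-1L], params$hop_weights)
  list(layer_states = states, final = z, attention = maps)
}

# ---- intra-drug molecular encoder ----------------------------------------

.mol_atom_features <- function(atoms) {
  type <- match(atoms$type, ATOM_TYPES)
  if (anyNA(type)) stop("unknown atom type", call. = FALSE)
  deg <- pmin(pmax(atoms$degree, 0L), 5L)
  onehot <- function(idx, k) {
    m <- matrix(0, length(idx), k)
    m[cbind(seq_along(idx), idx)] <- 1
    m
  }
  cbind(onehot(type, length(ATOM_TYPES)),
        onehot(deg + 1L, 6L),
        onehot(atoms$aromatic + 1L, 2L),
        onehot(atoms$charge + 2L, 3L))
}

.mol_bond_features <- function(types) {
  idx <- match(types, BOND_TYPES)
  m <- matrix(0, length(types), length(BOND_TYPES))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Initialize molecular encoder parameters
#'
#' Attention layers over the atom graph with bond features concatenated to
#' neighbor messages, followed by global attention pooling.
#'
#' @param hidden_dim atom state / output dimension.
#' @param n_layers number of attention layers (default 3).
#' @param leaky_slope,stability_eps as in [encoder_params()].
#' @param seed initialization seed.
#' @export
molecule_params <- function(hidden_dim = 32L, n_layers = 3L,
                            leaky_slope = 0.2, stability_eps = 1e-8,
                            seed = 1L) {
  n_atom_feat <- length(ATOM_TYPES) + 6L + 2L + 3L
  n_bond_feat <- length(BOND_TYPES)
  with_seed(seed, {
    layers <- lapply(seq_len(n_layers), function(k)
      list(W_msg = glorot(hidden_dim + n_bond_feat, hidden_dim),
           W_self = glorot(hidden_dim, hidden_dim),
           a_src = stats::runif(hidden_dim, -0.1, 0.1),
           a_dst = stats::runif(hidden_dim, -0.1, 0.1)))
    structure(list(W_in = glorot(n_atom_feat, hidden_dim), layers = layers,
                   pool_query = stats::runif(hidden_dim, -0.1, 0.1),
                   hidden_dim = hidden_dim, n_layers = n_layers,
                   leaky_slope = leaky_slope, stability_eps = stability_eps),
              class = "molecule_params")
  })
}

#' Encode a molecular toy graph into a drug feature vector
#'
#' Runs attention layers over the atom graph (neighbor messages carry the
#' bond-type features) and pools atom states with global attention: softmax of
#' a learned scoring vector over atoms, then the weighted sum of atom states.
#' The result is permutation-invariant in the atom order.
#'
#' @param graph `molecular_graph`.
#' @param params `molecule_params`.
#' @return numeric vector of length `hidden_dim`; attributes `pooling` (the
#'   atom pooling weights) and `atom_states`.
#' @export
encode_molecule <- function(graph, params) {
  if (is.null(graph$atoms) || nrow(graph$atoms) == 0L)
    stop("empty molecular graph", call. = FALSE)
  n <- nrow(graph$atoms)
  h <- .mol_atom_features(graph$atoms) %*% params$W_in
  h0 <- h
  bf <- .mol_bond_features(graph$bonds$type)
  # undirected: expand each bond into both directions
  src <- c(graph$bonds$from, graph$bonds$to)
  dst <- c(graph$bonds$to, graph$bonds$from)
  ef <- rbind(bf, bf)
  for (k in seq_len(params$n_layers)) {
    ly <- params$layers[[k]]
    msg <- cbind(h[src, , drop = FALSE], ef) %*% ly$W_msg   # message j -> i (one per edge)
    u <- drop((h %*% ly$W_self) %*% ly$a_src)
    logit <- leaky_relu(u[dst] + drop(msg %*% ly$a_dst), params$leaky_slope)
    hn <- matrix(0, n, params$hidden_dim)
    for (i in seq_len(n)) {
      e_i <- which(dst == i)
      if (length(e_i) == 0L) { hn[i, ] <- h[i, ]; next }  # isolated atom: identity
      al <- exp(logit[e_i] - max(logit[e_i]))
      al <- al / sum(al)
      hn[i, ] <- colSums(al * msg[e_i, , drop = FALSE])
    }
    h <- relu(hn) + h0
    h <- h / (row_norms(h) + params$stability_eps)
  }
  sc <- drop(h %*% params$pool_query)
  w <- exp(sc - max(sc))
  w <- w / sum(w)
  out <- colSums(w * h)
  attr(out, "pooling") <- w
  attr(out, "atom_states") <- h
  out
}

# ---- pairwise cross-attention --------------------------------------------

#' Initialize cross-attention parameters
#'
#' Learned query/key/value projections, one triple per head.
#'
#' @param dim node state dimension.
#' @param n_heads number of heads (outputs averaged).
#' @param seed initialization seed.
#' @export
cross_attention_params <- function(dim, n_heads = 1L, seed = 1L) {
  with_seed(seed, {
    structure(list(
      Wq = lapply(seq_len(n_heads), function(h) glorot(dim, dim)),
      Wk = lapply(seq_len(n_heads), function(h) glorot(dim, dim)),
      Wv = lapply(seq_len(n_heads), function(h) glorot(dim, dim)),
      dim = dim, n_heads = n_heads), class = "cross_attention_params")
  })
}

.topk_mask <- function(states_q, states_k, top_k) {
  # cosine similarity of raw states; keep top_k columns per row, ties to the
  # lower index
  uq <- .unit_rows(states_q)$U
  uk <- .unit_rows(states_k)$U
  cs <- tcrossprod(uq, uk)
  mask <- matrix(0, nrow(cs), ncol(cs))
  for (i in seq_len(nrow(cs))) {
    sel <- order(-cs[i, ], seq_len(ncol(cs)))[seq_len(top_k)]
    mask[i, sel] <- 1
  }
  mask
}

.cross_direction <- function(states_q, states_kv, top_k, params) {
  mask <- .topk_mask(states_q, states_kv, top_k)
  dh <- params$dim
  att <- NULL
  amat <- matrix(0, nrow(states_q), nrow(states_kv))
  for (h in seq_len(params$n_heads)) {
    q <- states_q %*% params$Wq[[h]]
    k <- states_kv %*% params$Wk[[h]]
    v <- states_kv %*% params$Wv[[h]]
    logits <- tcrossprod(q, k) / sqrt(dh)
    alpha <- row_softmax(logits, mask = mask)
    o <- alpha %*% v
    att <- if (is.null(att)) o else att + o
    amat <- amat + alpha
  }
  list(attended = att / params$n_heads, alpha = amat / params$n_heads,
       mask = mask)
}

#' Cross-attention between the node states of two drugs
#'
#' For each node of drug i, cosine similarity to all nodes of drug j selects
#' the `top_k` most similar j-nodes; scaled dot-product attention with learned
#' query/key/value projections is computed over the retained set, and
#' symmetrically with the roles swapped. The pooled pair vector concatenates
#' the mean-pooled attended states of both directions.
#'
#' @param states_i,states_j node state matrices (substructure level) of the
#'   two drugs.
#' @param top_k nodes retained per query row (clamped with a warning when it
#'   exceeds the available nodes).
#' @param params `cross_attention_params`.
#' @return object of class `pair_representation` with fields
#'   `cross_attention_weights` (i-nodes x j-nodes, masked entries exactly 0),
#'   `cross_attention_weights_swapped`, `pooled`, `top_k`.
#' @export
cross_attention_pair <- function(states_i, states_j, top_k = 8L, params) {
  if (nrow(states_i) == 0L || nrow(states_j) == 0L)
    stop("empty state matrices", call. = FALSE)
  top_k <- stopifnot_count(top_k, "top_k", 1L)
  kk <- top_k
  if (kk > max(nrow(states_i), nrow(states_j))) {
    warning("top_k exceeds available nodes; clamped")
  }
  dir_ij <- .cross_direction(states_i, states_j, min(kk, nrow(states_j)), params)
  dir_ji <- .cross_direction(states_j, states_i, min(kk, nrow(states_i)), params)
  structure(list(
    states_i = states_i, states_j = states_j,
    cross_attention_weights = dir_ij$alpha,
    cross_attention_weights_swapped = dir_ji$alpha,
    pooled = c(colMeans(dir_ij$attended), colMeans(dir_ji$attended)),
    top_k = top_k), class = "pair_representation")
}

#' Initialize pair scoring head parameters
#'
#' A small MLP over `[z_i || z_j || z_i * z_j || pooled]`.
#'
#' @param dim embedding dimension d.
#' @param pooled_dim length of the pooled cross-attention vector (0 disables).
#' @param hidden hidden layer width (0 for a plain logistic model).
#' @param seed initialization seed.
#' @export
pair_head_params <- function(dim, pooled_dim = 0L, hidden = 16L, seed = 1L) {
  d_in <- 3L * dim + pooled_dim
  with_seed(seed, {
    if (hidden > 0L) {
      structure(list(W1 = glorot(d_in, hidden), b1 = rep(0, hidden),
                     w2 = stats::runif(hidden, -0.1, 0.1), b2 = 0,
                     dim = dim, pooled_dim = pooled_dim, hidden = hidden),
                class = "pair_head_params")
    } else {
      structure(list(W1 = NULL, b1 = NULL,
                     w2 = stats::runif(d_in, -0.1, 0.1), b2 = 0,
                     dim = dim, pooled_dim = pooled_dim, hidden = 0L),
                class = "pair_head_params")
    }
  })
}

.pair_head_forward <- function(x, head) {
  if (head$hidden > 0L) {
    h <- relu(drop(x %*% head$W1) + head$b1)
    drop(h %*% head$w2) + head$b2
  } else {
    drop(x %*% head$w2) + head$b2
  }
}

#' Interaction probability for a drug pair
#'
#' `logistic(MLP([z_i || z_j || z_i * z_j || pooled]))`, symmetrized as
#' `(score(i, j) + score(j, i)) / 2` (for the swapped order the two pooled
#' halves swap as well), so the result is exactly symmetric.
#'
#' @param z_i,z_j embedding vectors of the two drugs.
#' @param pair_repr optional `pair_representation` supplying `pooled`.
#' @param head `pair_head_params`.
#' @return probability in `[0, 1]`.
#' @export
pair_score <- function(z_i, z_j, pair_repr = NULL, head) {
  pooled <- if (!is.null(pair_repr)) pair_repr$pooled else numeric(0)
  if (length(pooled) != head$pooled_dim)
    stop("pooled vector length does not match the head", call. = FALSE)
  half <- length(pooled) / 2
  pooled_sw <- if (half > 0) c(pooled[-seq_len(half)], pooled[seq_len(half)])
               else pooled
  x_ij <- matrix(c(z_i, z_j, z_i * z_j, pooled), nrow = 1L)
  x_ji <- matrix(c(z_j, z_i, z_i * z_j, pooled_sw), nrow = 1L)
  (logistic(.pair_head_forward(x_ij, head)) +
     logistic(.pair_head_forward(x_ji, head))) / 2
}
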