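# End-to-end training, evaluation, ablation and robustness harness.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with initial learning rate
#' 1e-3, weight decay 1e-5, cosine-annealing schedule, mini-batch size 128,
#' 150 epochs with early stopping (patience 15) on the validation loss,
#' 80/10/10 label-stratified pair splits, dropout 0.1 on attention weights,
#' 8 heads, hidden dimension 256 and 3 attention layers. The documented grid
#' for tuning is learning rate {1e-2, 1e-3, 1e-4}, dropout {0.1, 0.3, 0.5}
#' and hidden dimension {128, 256, 512}; no grid search is run here.
#'
#' @param learning_rate,weight_decay,batch_size,max_epochs,early_stop_patience
#'   optimizer settings. `batch_size = Inf` trains full-batch.
#' @param split train/validation/test fractions (must sum to 1).
#' @param seed master seed for splitting, initialization and minibatching.
#' @param dropout attention-weight dropout probability during training.
#' @param n_heads,hidden_dim,gnn_layers encoder architecture.
#' @param loss_weights list with `ctr` (contrastive weight), `lambda`
#'   (lambda1, lambda2 for the similarity and supervised terms) and `alpha`
#'   (six regularization weights: context, Laplacian, co-prescription, MMD,
#'   ranking, entropy).
#' @param margins list with `tau` (context contrastive) and `delta` (ranking).
#' @param mmd_bandwidth Gaussian MMD bandwidth or `"median"`.
#' @param kernels kernel tag(s) for the per-modality similarities.
#' @param knn_k,epsilon graph sparsification: kNN neighbor count (default) or
#'   a similarity threshold (set `epsilon` to use thresholding instead).
#' @param graph_refresh rebuild the relational graph from the learned fusion
#'   weights every this many epochs (0 disables refresh).
#' @param steps_per_epoch cap on minibatch steps per epoch; each epoch draws a
#'   fresh random subset of batches, so all pairs cycle through over training
#'   (default `Inf`: every batch every epoch).
#' @param top_k cross-attention pre-masking size.
#' @param pair_hidden hidden width of the pair-scoring MLP.
#' @param n_triplets triplets mined per epoch for the contrastive/ranking terms.
#' @param use_modality_views compute per-modality embedding views (needed for
#'   the MMD term and the cross-attention pair head).
#' @param train_fraction fraction of training pairs actually used (robustness
#'   harness).
#' @param split_mode `"pairwise"` (random pairs) or `"drugwise"` (cold-start:
#'   whole drugs held out).
#' @param ablation `"none"`, `"no_msi"` (uniform frozen fusion weights and a
#'   concatenation pair head), `"no_gbap"` (mean aggregation instead of
#'   attention propagation), or `"no_cmrg"` (contrastive, MMD, ranking and
#'   entropy terms disabled).
#' @param lr_min floor of the cosine schedule.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-5,
                         batch_size = 128L, max_epochs = 150L,
                         early_stop_patience = 15L,
                         split = c(0.8, 0.1, 0.1), seed = 0L, dropout = 0.1,
                         n_heads = 8L, hidden_dim = 256L, gnn_layers = 3L,
                         loss_weights = list(ctr = 1, lambda = c(1, 1),
                                             alpha = rep(0.1, 6)),
                         margins = list(tau = 1, delta = 1),
                         mmd_bandwidth = "median",
                         kernels = "cosine", knn_k = 10L, epsilon = NULL,
                         graph_refresh = 10L, steps_per_epoch = Inf,
                         top_k = 8L, pair_hidden = 16L,
                         n_triplets = 256L, use_modality_views = TRUE,
                         train_fraction = 1,
                         split_mode = c("pairwise", "drugwise"),
                         ablation = c("none", "no_msi", "no_gbap", "no_cmrg"),
                         lr_min = 1e-5) {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1", call. = FALSE)
  if (early_stop_patience >= max_epochs)
    stop("patience must be smaller than max_epochs", call. = FALSE)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = batch_size, max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 split = split, seed = as.integer(seed), dropout = dropout,
                 n_heads = as.integer(n_heads),
                 hidden_dim = as.integer(hidden_dim),
                 gnn_layers = as.integer(gnn_layers),
                 loss_weights = loss_weights, margins = margins,
                 mmd_bandwidth = mmd_bandwidth, kernels = kernels,
                 knn_k = as.integer(knn_k), epsilon = epsilon,
                 graph_refresh = as.integer(graph_refresh),
                 steps_per_epoch = steps_per_epoch,
                 top_k = as.integer(top_k),
                 pair_hidden = as.integer(pair_hidden),
                 n_triplets = as.integer(n_triplets),
                 use_modality_views = use_modality_views,
                 train_fraction = train_fraction,
                 split_mode = match.arg(split_mode),
                 ablation = match.arg(ablation),
                 lr_min = lr_min),
            class = "train_config")
}

#' Stratified pair splitting
#'
#' Splits a pair-label table into disjoint train/validation/test subsets,
#' stratified by label, deterministically under `seed`.
#'
#' @param pairs data frame with a `label` column.
#' @param fractions length-3 fractions summing to 1.
#' @param seed integer seed.
#' @return list of data frames `train`, `val`, `test`.
#' @export
split_pairs <- function(pairs, fractions = c(0.8, 0.1, 0.1), seed = 0L) {
  if (nrow(pairs) < 10L) stop("need at least 10 pairs", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1", call. = FALSE)
  with_seed((seed * 1000003 + 17) %% 2147483647, {
    grp <- rep(NA_character_, nrow(pairs))
    for (lv in unique(pairs$label)) {
      idx <- which(pairs$label == lv)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      n_val <- round(fractions[2] * n)
      n_test <- round(fractions[3] * n)
      n_train <- n - n_val - n_test
      grp[idx] <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
    }
    out <- list(train = pairs[grp == "train", , drop = FALSE],
                val = pairs[grp == "val", , drop = FALSE],
                test = pairs[grp == "test", , drop = FALSE])
    for (s in c("val", "test"))
      if (length(unique(out[[s]]$label)) < 2L)
        warning("split '", s, "' has a single class; AUC will be undefined")
    out
  })
}

# drug-wise (cold-start) split: assign drugs to folds, a pair follows its
# fold only when both endpoints agree; mixed pairs go to train.
split_pairs_drugwise <- function(pairs, drug_ids, fractions, seed) {
  with_seed((seed * 1000003 + 29) %% 2147483647, {
    fold <- sample(c("train", "val", "test"), length(drug_ids), TRUE,
                   prob = fractions)
    names(fold) <- drug_ids
    fa <- fold[pairs$id_a]
    fb <- fold[pairs$id_b]
    grp <- ifelse(fa == fb, fa, "train")
    list(train = pairs[grp == "train", , drop = FALSE],
         val = pairs[grp == "val", , drop = FALSE],
         test = pairs[grp == "test", , drop = FALSE])
  })
}

# ---- metrics --------------------------------------------------------------

#' Rank-based ROC-AUC
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`, or `NA` for single-class input.
#' @export
roc_auc <- function(scores, labels) {
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Interpolated precision-recall AUC
#' @inheritParams roc_auc
#' @export
pr_auc <- function(scores, labels) {
  np <- sum(labels == 1)
  if (np == 0 || all(labels == 1)) return(NA_real_)
  o <- order(-scores, labels)  # ties: negatives first (pessimistic)
  lab <- labels[o]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / np
  # interpolated: precision envelope from the right
  prec_i <- rev(cummax(rev(prec)))
  keep <- which(lab == 1)
  sum(prec_i[keep] * diff(c(0, rec[keep])))
}

#' Classification metrics for scored pairs
#'
#' Accuracy, recall and F1 at threshold 0.5; rank-based ROC-AUC and
#' interpolated PR-AUC (reported as `NA` for single-class input).
#'
#' @param scores predicted probabilities.
#' @param labels 0/1 labels.
#' @return named list of metrics.
#' @export
evaluate_pairs <- function(scores, labels) {
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(accuracy = mean(pred == labels), recall = recall, f1 = f1,
       roc_auc = roc_auc(scores, labels), pr_auc = pr_auc(scores, labels))
}

# ---- training -------------------------------------------------------------

.build_data <- function(cohort, cfg) {
  feats <- cohort$modality_features
  m_cnt <- length(feats)
  kernels <- rep_len(cfg$kernels, m_cnt)
  s_list <- lapply(seq_len(m_cnt), function(m)
    suppressWarnings(modality_similarity(feats[[m]], kernels[m])))
  x <- do.call(cbind, feats)
  slices <- vector("list", m_cnt)
  off <- 0L
  for (m in seq_len(m_cnt)) {
    slices[[m]] <- off + seq_len(ncol(feats[[m]]))
    off <- off + ncol(feats[[m]])
  }
  xm <- lapply(seq_len(m_cnt), function(m) {
    z <- x * 0
    z[, slices[[m]]] <- x[, slices[[m]]]
    z
  })
  context <- context_comembership(cohort$context_labels,
                                  drug_ids = cohort$drug_ids)
  topology <- unified_topology(s_list, context)
  copresc <- suppressWarnings(
    coprescription_probabilities(cohort$coprescription_counts))
  primary <- vapply(cohort$context_labels, function(cs)
    if (length(cs) > 0) cs[[1L]] else "none", character(1))
  class_levels <- sort(unique(primary))
  list(X = x, Xm = xm, S_list = s_list, slices = slices, context = context,
       topology = topology, copresc = copresc,
       class_labels = match(primary, class_levels),
       class_levels = class_levels)
}

.build_graph <- function(s_list, lambda, cfg) {
  fused <- fuse_similarities(s_list, lambda)
  g <- if (!is.null(cfg$epsilon)) {
    suppressWarnings(threshold_adjacency(fused, cfg$epsilon))
  } else suppressWarnings(knn_sparsify(fused, cfg$knn_k))
  a <- g$adjacency
  iso <- rowSums(a) == 0
  if (any(iso)) diag(a)[iso] <- 1
  list(graph = g, A = a, fused = fused)
}

.pair_indices <- function(pairs, drug_ids) {
  list(I = match(pairs$id_a, drug_ids), J = match(pairs$id_b, drug_ids),
       y = pairs$label)
}

#' Train the interaction model on a cohort
#'
#' Builds per-modality similarities, the fused relational graph, context and
#' co-prescription structures, then jointly minimizes the embedding objective
#' (contrastive + similarity-preserving + supervised) and the regularization
#' suite (context alignment, Laplacian smoothness, co-prescription KL, MMD,
#' margin ranking, entropy) with Adam. Fusion weights are parameterized by a
#' softmax over unconstrained logits so the simplex constraint holds at every
#' step; the relational graph is refreshed from the learned weights every
#' `graph_refresh` epochs. Early stopping monitors the validation loss and
#' the returned parameters are those of the best validation epoch.
#'
#' @param cohort a `synthetic_cohort` (or an object with the same fields, for
#'   example from [read_cohort()]).
#' @param config a [train_config()].
#' @return object of class `ddi_model` with the best parameters, the
#'   per-epoch `history` (every loss component plus validation loss/AUC),
#'   learned fusion weights `lambda`, split membership and evaluation helpers.
#' @export
train_ddi <- function(cohort, config = train_config()) {
  cfg <- config
  data <- .build_data(cohort, cfg)
  n <- cohort$n_drugs
  set.seed(cfg$seed * 104729L + 1L)

  pairs <- cohort$pair_labels
  sp <- if (cfg$split_mode == "drugwise") {
    split_pairs_drugwise(pairs, cohort$drug_ids, cfg$split, cfg$seed)
  } else split_pairs(pairs, cfg$split, cfg$seed)
  if (cfg$train_fraction < 1) {
    keep <- sort(sample.int(nrow(sp$train),
                            max(2L, round(cfg$train_fraction * nrow(sp$train)))))
    sp$train <- sp$train[keep, , drop = FALSE]
  }
  tr <- .pair_indices(sp$train, cohort$drug_ids)
  va <- .pair_indices(sp$val, cohort$drug_ids)
  tr_df <- data.frame(i = tr$I, j = tr$J, label = tr$y)

  lambda0 <- rep(1 / length(data$S_list), length(data$S_list))
  gb <- .build_graph(data$S_list, lambda0, cfg)
  data$A <- gb$A

  par <- init_model_params(ncol(data$X), length(data$S_list),
                           length(data$class_levels), cfg)
  if (identical(cfg$mmd_bandwidth, "median") && cfg$use_modality_views) {
    # fix the MMD bandwidth once per run, from the initial modality views;
    # it is a kernel hyperparameter, not a trained quantity
    z0 <- lapply(data$Xm, function(x)
      enc_forward(x, data$A, par, cfg, train_mode = FALSE)$Z)
    cfg$mmd_bandwidth <- median_pairwise_dist(do.call(rbind, z0))
  }
  ast <- adam_init(par)
  n_train <- length(tr$I)
  bsz <- min(cfg$batch_size, n_train)
  history <- NULL
  best <- list(val = Inf, par = par, epoch = 0L)
  wait <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- cfg$lr_min + 0.5 * (cfg$learning_rate - cfg$lr_min) *
      (1 + cos(pi * (epoch - 1) / cfg$max_epochs))
    tb <- make_triplet_batch(tr_df, n, cfg$n_triplets)
    ord <- if (bsz < n_train) sample.int(n_train) else seq_len(n_train)
    starts <- seq(1L, n_train, by = bsz)
    if (is.finite(cfg$steps_per_epoch))
      starts <- starts[seq_len(min(length(starts), cfg$steps_per_epoch))]
    comps <- NULL
    for (b0 in starts) {
      sel <- ord[b0:min(b0 + bsz - 1L, n_train)]
      batch <- list(I = tr$I[sel], J = tr$J[sel], y = tr$y[sel])
      st <- model_step(par, data, cfg, batch, tb, want_grad = TRUE,
                       train_mode = TRUE)
      if (!is.finite(st$components$total)) {
        bad <- names(which(!vapply(st$components, is.finite, logical(1))))[1L]
        stop("training diverged: non-finite loss component '", bad,
             "' at epoch ", epoch, call. = FALSE)
      }
      up <- adam_step(par, st$grad, ast, lr,
                      weight_decay = cfg$weight_decay)
      par <- up$par
      ast <- up$state
      comps <- st$components  # last batch of the epoch
    }
    # validation (no dropout)
    ev <- model_step(par, data, cfg, list(I = va$I, J = va$J, y = va$y), tb,
                     want_grad = FALSE, train_mode = FALSE)
    val_loss <- ev$components$bce
    val_auc <- roc_auc(ev$score, va$y)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr,
      ctr = comps$ctr, sim = comps$sim, bce = comps$bce, ce = comps$ce,
      ctx = comps$ctx, lap = comps$lap, co = comps$co, mmd = comps$mmd,
      rank = comps$rank, ent = comps$ent, total = comps$total,
      val_loss = val_loss, val_auc = val_auc))
    if (is.finite(val_loss) && val_loss < best$val - 1e-9) {
      best <- list(val = val_loss, par = par, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stop_patience) break
    }
    if (cfg$graph_refresh > 0 && epoch %% cfg$graph_refresh == 0 &&
        !identical(cfg$ablation, "no_msi")) {
      gb <- .build_graph(data$S_list, softmax_vec(par$lambda_logits), cfg)
      data$A <- gb$A
    }
  }

  structure(list(par = best$par, best_epoch = best$epoch, config = cfg,
                 lambda = softmax_vec(best$par$lambda_logits),
                 data = data, graph_adjacency = data$A,
                 drug_ids = cohort$drug_ids, split = sp,
                 history = history,
                 class_levels = data$class_levels),
            class = "ddi_model")
}

#' @export
print.ddi_model <- function(x, ...) {
  cat("Trained DDI model:", length(x$drug_ids), "drugs,",
      length(x$lambda), "modalities; best epoch", x$best_epoch, "\n")
  cat("  fusion weights:", paste(sprintf("%.3f", x$lambda), collapse = " "), "\n")
  invisible(x)
}

#' Score drug pairs with a trained model
#'
#' @param model `ddi_model`.
#' @param pairs data frame with `id_a`, `id_b` (drug ids known to the model).
#' @return numeric vector of interaction probabilities.
#' @export
predict_pairs <- function(model, pairs) {
  idx <- .pair_indices(cbind(pairs, label = 0), model$drug_ids)
  if (anyNA(idx$I) || anyNA(idx$J)) stop("unknown drug id", call. = FALSE)
  cfg <- model$config
  data <- model$data
  fw <- enc_forward(data$X, data$A, model$par, cfg, train_mode = FALSE)
  zms <- NULL
  if (cfg$use_modality_views) {
    zms <- lapply(data$Xm, function(x)
      enc_forward(x, data$A, model$par, cfg, train_mode = FALSE)$Z)
  }
  ph <- pairhead_forward(fw$Z, zms, idx$I, idx$J, model$par, cfg)
  unname(ph$score)
}

#' Evaluate a trained model on a pair table
#'
#' @param model `ddi_model`.
#' @param pairs data frame with `id_a`, `id_b`, `label`; defaults to the
#'   model's held-out test split.
#' @return metric list from [evaluate_pairs()].
#' @export
evaluate_model <- function(model, pairs = model$split$test) {
  scores <- predict_pairs(model, pairs[, c("id_a", "id_b")])
  evaluate_pairs(scores, pairs$label)
}

#' Train and evaluate one ablated variant
#'
#' Variants: `no_msi` freezes the fusion weights at uniform and replaces the
#' cross-attention pair head by plain concatenation of the modality views;
#' `no_gbap` replaces attention propagation by plain mean aggregation (no
#' residuals, normalization or multi-hop weighting); `no_cmrg` zeroes the
#' contrastive, MMD, ranking and entropy weights. Everything else is
#' identical to the full model.
#'
#' @param cohort a cohort.
#' @param config a [train_config()].
#' @param variant one of `"no_msi"`, `"no_gbap"`, `"no_cmrg"` (or `"none"`).
#' @return list with the trained `model` and test `metrics`.
#' @export
run_ablation <- function(cohort, config = train_config(),
                         variant = c("no_msi", "no_gbap", "no_cmrg", "none")) {
  variant <- match.arg(variant)
  config$ablation <- variant
  model <- train_ddi(cohort, config)
  list(model = model, metrics = evaluate_model(model), variant = variant)
}

#' Mean and standard deviation of metrics over seeds
#'
#' Re-trains with each seed and aggregates test metrics.
#'
#' @param cohort a cohort.
#' @param config a [train_config()] (its `seed` field is overridden).
#' @param seeds integer seeds (default 0..4).
#' @param variant ablation variant passed through.
#' @return list with `per_seed` (one row per seed) and `summary`
#'   (mean and sd per metric), plus the per-seed fusion weights.
#' @export
seed_sweep <- function(cohort, config = train_config(), seeds = 0:4,
                       variant = "none") {
  config$ablation <- variant
  rows <- NULL
  lambdas <- NULL
  for (s in seeds) {
    config$seed <- as.integer(s)
    model <- train_ddi(cohort, config)
    met <- evaluate_model(model)
    rows <- rbind(rows, data.frame(seed = s, accuracy = met$accuracy,
                                   recall = met$recall, f1 = met$f1,
                                   roc_auc = met$roc_auc, pr_auc = met$pr_auc))
    lambdas <- rbind(lambdas, model$lambda)
  }
  summ <- data.frame(metric = c("accuracy", "recall", "f1", "roc_auc", "pr_auc"),
                     mean = vapply(rows[, -1L], mean, numeric(1)),
                     sd = vapply(rows[, -1L], stats::sd, numeric(1)))
  list(per_seed = rows, summary = summ, lambda = lambdas, variant = variant)
}

#' Attention report for one drug pair
#'
#' Recomputes the forward pass with attention maps and returns, for each
#' propagation layer, the head-averaged attention rows of the two drugs over
#' their graph neighborhoods, plus the pair's cross-attention matrix over the
#' modality views. Every unmasked row sums to 1; masked entries are exact
#' zeros.
#'
#' @param model `ddi_model`.
#' @param id_a,id_b drug identifiers.
#' @return list with `layer_rows` (per layer, a two-row matrix of attention
#'   weights) and `cross_attention` (the `pair_representation`).
#' @export
attention_report <- function(model, id_a, id_b) {
  i <- match(id_a, model$drug_ids)
  j <- match(id_b, model$drug_ids)
  if (is.na(i) || is.na(j)) stop("unknown drug id", call. = FALSE)
  cfg <- model$config
  data <- model$data
  par <- model$par
  g <- relational_graph_from_adjacency(data$A)
  h0 <- data$X %*% par$W_in
  h <- h0
  layer_rows <- list()
  for (k in seq_along(par$layers)) {
    ly <- par$layers[[k]]
    acc <- 0
    for (hh in seq_along(ly$W)) {
      acc <- acc + attention_coefficients(h, g, ly$W[[hh]],
                                          c(ly$a_src[[hh]], ly$a_dst[[hh]]),
                                          LEAKY_SLOPE)
    }
    am <- acc / length(ly$W)
    layer_rows[[k]] <- rbind(am[i, ], am[j, ])
    rownames(layer_rows[[k]]) <- c(id_a, id_b)
    colnames(layer_rows[[k]]) <- model$drug_ids
    # advance the state exactly as in the forward pass
    ep <- list(layers = list(ly), leaky_slope = LEAKY_SLOPE,
               stability_eps = STAB_EPS)
    class(ep) <- "encoder_params"
    h <- gat_layer(h, g, ep, 1L, h0 = h0)
    attr(h, "attention") <- NULL
  }
  cross <- NULL
  if (cfg$use_modality_views) {
    zms <- lapply(data$Xm, function(x)
      enc_forward(x, data$A, par, cfg, train_mode = FALSE)$Z)
    si <- do.call(rbind, lapply(zms, function(z) z[i, ]))
    sj <- do.call(rbind, lapply(zms, function(z) z[j, ]))
    cap <- structure(list(Wq = list(par$cross$Wq), Wk = list(par$cross$Wk),
                          Wv = list(par$cross$Wv), dim = ncol(si),
                          n_heads = 1L), class = "cross_attention_params")
    cross <- suppressWarnings(
      cross_attention_pair(si, sj, top_k = min(cfg$top_k, nrow(sj)),
                           params = cap))
  }
  list(layer_rows = layer_rows, cross_attention = cross)
}

relational_graph_from_adjacency <- function(a) {
  suppressWarnings(relational_graph(a))
}
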