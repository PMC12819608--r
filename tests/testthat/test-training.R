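tiny_cfg <- function(seed = 1, max_epochs = 3, early_stop_patience = 2,
                     dropout = 0, ...) {
  train_config(learning_rate = 0.02, hidden_dim = 8, n_heads = 1,
               gnn_layers = 1, pair_hidden = 4, batch_size = Inf,
               max_epochs = max_epochs,
               early_stop_patience = early_stop_patience, dropout = dropout,
               n_triplets = 20, knn_k = 4, seed = seed, ...)
}

test_that("pair splitting is stratified, disjoint and deterministic", {
  pairs <- data.frame(id_a = sprintf("A%03d", 1:100),
                      id_b = sprintf("B%03d", 1:100),
                      label = rep(c(0L, 1L), 50))
  sp <- split_pairs(pairs, c(0.8, 0.1, 0.1), seed = 3)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$val), 10)
  expect_equal(nrow(sp$test), 10)
  expect_equal(sum(sp$train$label), 40)
  expect_equal(sum(sp$val$label), 5)
  expect_equal(sum(sp$test$label), 5)
  all_ids <- sort(c(rownames(sp$train), rownames(sp$val), rownames(sp$test)))
  expect_equal(all_ids, sort(rownames(pairs)))
  sp2 <- split_pairs(pairs, c(0.8, 0.1, 0.1), seed = 3)
  expect_identical(sp, sp2)
  expect_error(split_pairs(pairs[1:5, ], seed = 1), "at least 10")
})

test_that("ROC-AUC and PR-AUC match counting oracles and edge cases", {
  # perfect separation
  expect_equal(roc_auc(c(.9, .8, .2, .1), c(1, 1, 0, 0)), 1)
  # constant scores
  expect_equal(roc_auc(rep(.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # hand-listed pairs vs brute-force concordance count
  s <- c(0.9, 0.4, 0.7, 0.3, 0.7, 0.1)
  y <- c(1, 0, 1, 1, 0, 0)
  expect_equal(roc_auc(s, y), oracle_auc(s, y))
  expect_true(is.na(roc_auc(c(.1, .2), c(1, 1))))

  set.seed(8)
  for (rep in 1:5) {
    s <- runif(30)
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                            direction = "<")))
      expect_equal(roc_auc(s, y), ref, tolerance = 1e-10)
    }
  }
  # PR-AUC: perfect ranking gives 1; sane range otherwise
  expect_equal(pr_auc(c(.9, .8, .2, .1), c(1, 1, 0, 0)), 1)
  v <- pr_auc(runif(40), rbinom(40, 1, 0.5))
  expect_true(v >= 0 && v <= 1)
})

test_that("classification metrics at threshold 0.5", {
  s <- c(0.9, 0.6, 0.4, 0.2)
  y <- c(1, 0, 1, 0)
  met <- evaluate_pairs(s, y)
  expect_equal(met$accuracy, 0.5)
  expect_equal(met$recall, 0.5)   # one of two positives above 0.5
  expect_equal(met$f1, 0.5)       # precision 0.5, recall 0.5
  expect_true(all(unlist(met) >= 0 & unlist(met) <= 1))
})

test_that("the full training gradient matches finite differences", {
  co <- generate_cohort(n_drugs = 12, n_modalities = 3, dims = c(4, 3, 3),
                        n_clusters = 2, seed = 2)
  cfg <- train_config(hidden_dim = 5, n_heads = 2, gnn_layers = 2,
                      pair_hidden = 4, dropout = 0, max_epochs = 5,
                      early_stop_patience = 2, seed = 1, n_triplets = 10,
                      knn_k = 3, mmd_bandwidth = 1.0)
  data <- interdrug:::.build_data(co, cfg)
  gb <- interdrug:::.build_graph(data$S_list, rep(1 / 3, 3), cfg)
  data$A <- gb$A
  par <- interdrug:::init_model_params(ncol(data$X), 3,
                                       length(data$class_levels), cfg)
  set.seed(4)
  tb <- make_triplet_batch(data.frame(i = 1:3, j = 4:6, label = 1L), 12, 8)
  batch <- list(I = c(1, 2, 3, 7), J = c(5, 6, 9, 10), y = c(1, 0, 1, 0))
  st <- interdrug:::model_step(par, data, cfg, batch, tb, want_grad = TRUE,
                               train_mode = FALSE)
  flat <- unlist(par, use.names = FALSE)
  gflat <- unlist(st$grad, use.names = FALSE)
  f <- function(v) {
    interdrug:::model_step(utils::relist(v, par), data, cfg, batch, tb,
                           want_grad = FALSE,
                           train_mode = FALSE)$components$total
  }
  idx <- sort(sample(length(flat), 60))
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    vp <- flat; vp[i] <- vp[i] + eps
    vm <- flat; vm[i] <- vm[i] - eps
    (f(vp) - f(vm)) / (2 * eps)
  }, numeric(1))
  err <- abs(gflat[idx] - num) / pmax(abs(num), abs(gflat[idx]), 1e-6)
  expect_lt(max(err), 1e-4)
})

test_that("training runs, records history and stops early correctly", {
  co <- generate_cohort(n_drugs = 30, n_modalities = 3, dims = c(6, 4, 4),
                        n_clusters = 2, seed = 5)
  m1 <- train_ddi(co, tiny_cfg(seed = 1, max_epochs = 2,
                               early_stop_patience = 1))
  expect_s3_class(m1, "ddi_model")
  expect_lte(nrow(m1$history), 2)
  expect_true(all(c("ctr", "sim", "bce", "ce", "ctx", "lap", "co", "mmd",
                    "rank", "ent", "total", "val_loss") %in%
                    names(m1$history)))
  # best epoch never after the last improvement
  expect_lte(m1$best_epoch, nrow(m1$history))
  # simplex constraint on the learned fusion weights
  expect_equal(sum(m1$lambda), 1, tolerance = 1e-8)
  expect_true(all(m1$lambda >= 0))
  # scores are probabilities
  sc <- predict_pairs(m1, co$pair_labels[1:10, c("id_a", "id_b")])
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("training is reproducible under a fixed seed", {
  co <- generate_cohort(n_drugs = 24, n_modalities = 3, dims = c(5, 4, 4),
                        n_clusters = 2, seed = 9)
  cfg <- tiny_cfg(seed = 7, max_epochs = 4, early_stop_patience = 3,
                  dropout = 0.1)
  m1 <- train_ddi(co, cfg)
  m2 <- train_ddi(co, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$par, m2$par)
  expect_identical(evaluate_model(m1), evaluate_model(m2))
})

test_that("supervised-only training reduces the pair loss", {
  co <- generate_cohort(n_drugs = 40, n_modalities = 3, dims = c(8, 4, 4),
                        n_clusters = 2, seed = 11)
  cfg <- tiny_cfg(seed = 0, max_epochs = 10, early_stop_patience = 9)
  cfg$loss_weights <- list(ctr = 0, lambda = c(0, 1), alpha = rep(0, 6))
  m <- train_ddi(co, cfg)
  expect_lt(m$history$bce[nrow(m$history)], m$history$bce[1])
})

test_that("ablation variants change exactly what they should", {
  co <- generate_cohort(n_drugs = 30, n_modalities = 3, dims = c(6, 4, 4),
                        n_clusters = 2, seed = 5)
  res <- run_ablation(co, tiny_cfg(seed = 1), variant = "no_cmrg")
  h <- res$model$history
  # disabled terms log exactly 0 every epoch
  expect_true(all(h$mmd == 0))
  expect_true(all(h$rank == 0))
  expect_true(all(h$ent == 0))
  expect_true(all(h$ctr == 0))

  res2 <- run_ablation(co, tiny_cfg(seed = 1), variant = "no_msi")
  # fusion weights stay frozen at uniform
  expect_equal(res2$model$lambda, rep(1 / 3, 3), tolerance = 1e-12)

  res3 <- run_ablation(co, tiny_cfg(seed = 1), variant = "no_gbap")
  expect_true(is.finite(res3$metrics$roc_auc))
  expect_error(run_ablation(co, tiny_cfg(), variant = "bogus"))
})

test_that("cold-start drugwise splits keep held-out drugs out of training", {
  co <- generate_cohort(n_drugs = 40, seed = 13)
  sp <- interdrug:::split_pairs_drugwise(co$pair_labels, co$drug_ids,
                                         c(0.6, 0.2, 0.2), seed = 1)
  test_drugs <- unique(c(sp$test$id_a, sp$test$id_b))
  train_drug_pairs <- paste(sp$train$id_a, sp$train$id_b)
  # no test pair appears in train
  expect_length(intersect(paste(sp$test$id_a, sp$test$id_b),
                          train_drug_pairs), 0)
})

test_that("attention reports are normalized and consistent with the model", {
  co <- generate_cohort(n_drugs = 20, n_modalities = 3, dims = c(5, 4, 4),
                        n_clusters = 2, seed = 3)
  m <- train_ddi(co, tiny_cfg(seed = 2, max_epochs = 2,
                              early_stop_patience = 1))
  rep <- attention_report(m, co$drug_ids[1], co$drug_ids[5])
  for (lr in rep$layer_rows) {
    expect_equal(rowSums(lr), c(1, 1), tolerance = 1e-6, ignore_attr = TRUE)
    expect_true(all(lr >= 0))
  }
  ca <- rep$cross_attention$cross_attention_weights
  expect_equal(rowSums(ca), rep(1, nrow(ca)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("vectorized pair scoring agrees with the reference pair operations", {
  co <- generate_cohort(n_drugs = 16, n_modalities = 3, dims = c(5, 4, 4),
                        n_clusters = 2, seed = 6)
  m <- train_ddi(co, tiny_cfg(seed = 3, max_epochs = 2,
                              early_stop_patience = 1))
  cfg <- m$config
  data <- m$data
  fw <- interdrug:::enc_forward(data$X, data$A, m$par, cfg)
  zms <- lapply(data$Xm, function(x)
    interdrug:::enc_forward(x, data$A, m$par, cfg)$Z)
  i <- 2L; j <- 9L
  ph <- interdrug:::pairhead_forward(fw$Z, zms, i, j, m$par, cfg)

  # rebuild the same score through the exported single-pair operations
  si <- do.call(rbind, lapply(zms, function(z) z[i, ]))
  sj <- do.call(rbind, lapply(zms, function(z) z[j, ]))
  cap <- structure(list(Wq = list(m$par$cross$Wq), Wk = list(m$par$cross$Wk),
                        Wv = list(m$par$cross$Wv), dim = ncol(si),
                        n_heads = 1L), class = "cross_attention_params")
  pr <- suppressWarnings(
    cross_attention_pair(si, sj, top_k = min(cfg$top_k, nrow(sj)), params = cap))
  head <- structure(list(W1 = m$par$head$W1, b1 = m$par$head$b1,
                         w2 = m$par$head$w2, b2 = m$par$head$b2,
                         dim = ncol(fw$Z), pooled_dim = 2L * ncol(fw$Z),
                         hidden = cfg$pair_hidden),
                    class = "pair_head_params")
  ref <- pair_score(fw$Z[i, ], fw$Z[j, ], pr, head)
  expect_equal(unname(ph$score), ref, tolerance = 1e-10)
})
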