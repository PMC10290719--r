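# Training loop, cross-validation, consensus, metrics.

test_that("fold assignment partitions records evenly and reproducibly", {
  f1 <- kfold_assign(100, 5, seed = 4)
  expect_equal(as.integer(table(f1)), rep(20L, 5))
  expect_length(f1, 100)
  expect_identical(f1, kfold_assign(100, 5, seed = 4))
  expect_false(identical(f1, kfold_assign(100, 5, seed = 5)))
  expect_error(kfold_assign(100, 1), "at least 2")
  expect_error(kfold_assign(3, 5), "at least k")
  # disjointness and coverage, exhaustively
  for (i in 1:5) {
    expect_equal(sum(f1 == i), 20)
  }
  expect_setequal(which(f1 >= 1), 1:100)
})

test_that("metrics match closed forms on tiny vectors", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$pcc, 1)
  expect_equal(m$r2, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$mae, 0)
  # anti-correlated: closed-form Pearson
  m2 <- compute_metrics(c(0, 1, 2), c(2, 1, 0))
  expect_equal(m2$pcc, -1)
  expect_equal(m2$r2, 1 - 8 / 2)          # SS_res = 8, SS_tot = 2
  expect_equal(m2$rmse, sqrt(8 / 3))
  expect_equal(m2$mae, 4 / 3)
  # RMSE >= MAE always; constant predictions flag PCC as undefined
  expect_warning(m3 <- compute_metrics(c(0, 0, 3, 3), c(1, 1, 1, 1)),
                 "constant predictions")
  expect_gte(m3$rmse, m3$mae)
  expect_true(is.na(m3$pcc))
  set.seed(2)
  for (i in 1:10) {
    a <- rnorm(20); b <- rnorm(20)
    mm <- compute_metrics(a, b)
    expect_gte(mm$rmse, mm$mae)
    expect_true(mm$pcc >= -1 && mm$pcc <= 1)
    expect_lte(mm$r2, 1)
  }
  # constant observations: PCC/R2 flagged undefined, errors still given
  expect_warning(mc <- compute_metrics(c(2, 2, 2), c(1, 2, 3)),
                 "undefined")
  expect_true(is.na(mc$pcc) && is.na(mc$r2))
  expect_equal(mc$rmse, sqrt(2 / 3))
  expect_true(mc$degenerate)
})

test_that("training learns, early-stops, and restores the best epoch", {
  fs <- fake_feature_set(n_rec = 80, signal = TRUE)
  cfg <- default_config(fs, seed = 1, conv_channels = 3L, heads = 2L,
                        embed = 8L, head_dims = c(12L, 6L))
  tc <- train_config(max_epochs = 60, patience = 10, batch_size = 32,
                     lr = 5e-3, seed = 2)
  tr <- which(seq_len(fs$n) %% 4 != 0)
  va <- which(seq_len(fs$n) %% 4 == 0)
  fit <- train_predictor(build_predictor(cfg), fs, tr, va, tc)
  h <- fit$history
  # learning happens: best val loss beats the first epoch's
  expect_lt(min(h$val_loss), h$val_loss[1])
  # the returned weights are the best-validation-epoch weights
  best <- attr(h, "best_epoch")
  expect_equal(h$val_loss[best], min(h$val_loss))
  got <- kinprof:::.val_loss(fit$predictor, fs, va,
                             kinprof:::.scaled_blocks(fs, fit$predictor$scaling))
  expect_equal(got, min(h$val_loss), tolerance = 1e-10)
  # determinism: identical loss history on a re-run
  fit2 <- train_predictor(build_predictor(cfg), fs, tr, va, tc)
  expect_identical(fit$history$val_loss, fit2$history$val_loss)
  # guard rails
  expect_error(train_predictor(build_predictor(cfg), fs, integer(0), va, tc),
               "empty")
  expect_error(train_predictor(build_predictor(cfg), fs, tr, tr[1], tc),
               "overlap")
})

test_that("pure-noise labels trigger early stopping long before the cap", {
  fs <- fake_feature_set(n_rec = 60, signal = FALSE, seed = 7)
  cfg <- default_config(fs, seed = 1, conv_channels = 3L, heads = 2L,
                        embed = 8L, head_dims = c(12L, 6L))
  tc <- train_config(max_epochs = 500, patience = 3, batch_size = 32,
                     lr = 5e-3, seed = 3)
  fit <- train_predictor(build_predictor(cfg), fs,
                         which(seq_len(fs$n) %% 3 != 0),
                         which(seq_len(fs$n) %% 3 == 0), tc)
  expect_lt(nrow(fit$history), 100)
})

test_that("a small model overfits a tiny sample (training-contract sanity)", {
  for (variant in c("1-1", "3-2")) {
    fs <- fake_feature_set(n_kin = 4, n_cmp = 8, n_rec = 32,
                           variant = variant, seed = 13)
    cfg <- default_config(fs, seed = 2, conv_channels = 4L, heads = 2L,
                          embed = 16L, head_dims = c(32L, 8L))
    tc <- train_config(max_epochs = 400, patience = 399, batch_size = 32,
                       lr = 1e-2, seed = 1)
    idx <- seq_len(fs$n)
    fit <- train_predictor(build_predictor(cfg), fs, idx[-1], idx[1], tc)
    expect_lt(min(fit$history$train_loss), 1e-2)
  }
})

test_that("cross-validation partitions, reports, and summarises correctly", {
  fs <- fake_feature_set(n_rec = 90, signal = TRUE, seed = 5)
  cfg <- default_config(fs, seed = 1, conv_channels = 3L, heads = 2L,
                        embed = 8L, head_dims = c(12L, 6L))
  tc <- train_config(max_epochs = 15, patience = 5, batch_size = 32,
                     lr = 5e-3, seed = 2)
  cv <- kfold_cv(fs, k = 3, model_config = cfg, config = tc, seed = 9)
  expect_length(cv$models, 3)
  expect_equal(sort(unique(cv$fold_id)), 1:3)
  expect_length(cv$fold_id, fs$n)
  # mean/sd recomputation matches the summary
  expect_equal(cv$summary$mean[cv$summary$metric == "pcc"],
               mean(cv$fold_metrics$pcc))
  expect_equal(cv$summary$sd[cv$summary$metric == "rmse"],
               sd(cv$fold_metrics$rmse))
  # same seed, same folds
  expect_identical(cv$fold_id, kfold_assign(fs$n, 3, seed = 9))
})

test_that("consensus prediction is the member mean with a shared contract", {
  fs <- fake_feature_set(n_rec = 30, seed = 3)
  cfg <- default_config(fs, seed = 1, conv_channels = 3L, heads = 2L,
                        embed = 8L, head_dims = c(12L, 6L))
  members <- lapply(1:5, function(k) constant_predictor(cfg, k))
  cons <- consensus_predictor(members)
  out <- consensus_predict(cons, fs, idx = 1:4)
  expect_equal(out, rep(3, 4))             # mean of {1..5}
  # single member is the identity
  one <- consensus_predictor(members[2])
  expect_equal(consensus_predict(one, fs, idx = 1:4), rep(2, 4))
  # consensus bounded by member extremes
  set.seed(6)
  real <- lapply(1:3, function(k) {
    cfg_k <- cfg; cfg_k$seed <- k
    build_predictor(cfg_k)
  })
  pc <- consensus_predict(consensus_predictor(real), fs, idx = 1:10)
  each <- sapply(real, kinprof:::.predict_fs, fs = fs, idx = 1:10)
  expect_true(all(pc >= apply(each, 1, min) - 1e-12))
  expect_true(all(pc <= apply(each, 1, max) + 1e-12))
  # contract mismatch across members is refused
  other <- constant_predictor(default_config(
    fake_feature_set(n_rec = 10, variant = "1-2", seed = 3),
    conv_channels = 3L, heads = 2L, embed = 8L,
    head_dims = c(12L, 6L)), 1)
  expect_error(consensus_predictor(list(members[[1]], other)),
               "variant")
})

test_that("per-entity correlations honour the strict > min_n rule", {
  # one kinase with 11 records (in), one with exactly 10 (out)
  rec <- data.frame(
    kinase_id = c(rep("KA", 11), rep("KB", 10)),
    compound_smiles = sprintf("C%02d", 1:21),
    bioactivity = c(seq(0, 5, length.out = 11), seq(1, 4, length.out = 10)),
    stringsAsFactors = FALSE)
  preds <- rec$bioactivity                 # perfect predictions
  tab <- per_entity_pcc(rec, preds, group_by = "kinase", min_n = 10)
  expect_equal(tab$entity, "KA")
  expect_equal(tab$n, 11L)
  expect_equal(tab$pcc, 1)
  # empty result is allowed
  tab2 <- per_entity_pcc(rec, preds, group_by = "kinase", min_n = 50)
  expect_equal(nrow(tab2), 0)
  # grouping by compound: every compound has one record, none pass
  tab3 <- per_entity_pcc(rec, preds, group_by = "compound", min_n = 10)
  expect_equal(nrow(tab3), 0)
  # downstream aggregate: fraction of entities above a threshold
  expect_equal(mean(tab$pcc > 0.7), 1)
})
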