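# Training loop with early stopping, five-fold cross-validation,
# consensus prediction, and regression metrics.  All metrics are on the
# log10(nM) bioactivity scale.

#' Training configuration
#'
#' @param max_epochs Maximum training epochs (default 3000).
#' @param patience Early-stopping patience: stop when the validation loss
#'   has not improved for this many consecutive epochs (default 100);
#'   the best-validation-epoch weights are restored.
#' @param batch_size Minibatch size (default 512).
#' @param lr Adam learning rate.
#' @param seed Seed for minibatch shuffling.
#' @param verbose Print per-epoch losses.
#' @return Object of class `train_config`.
#' @export
train_config <- function(max_epochs = 3000L, patience = 100L,
                         batch_size = 512L, lr = 1e-3, seed = 1L,
                         verbose = FALSE) {
  stopifnot(patience < max_epochs, batch_size >= 1L, lr > 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 lr = lr, seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

#' Featurize compounds for model input
#'
#' Computes the 2D blocks (and optionally 3CED) for a set of compounds
#' once; rows are indexed by the input SMILES.
#'
#' @param smiles Character vector of SMILES (canonical recommended).
#' @param use_3ced Include the conformer-ensemble block.
#' @param space `signature_space` for 3CED (default standard space).
#' @param seed Seed for conformer embedding.
#' @param max_conformers Conformer cap per molecule.
#' @return Named list of block matrices (PCPP, MCFP, MGFP[, CED3]).
#' @export
featurize_compounds <- function(smiles, use_3ced = TRUE, space = NULL,
                                seed = 1L, max_conformers = 16L) {
  blocks <- list(PCPP = compute_pcpp(smiles),
                 MCFP = compute_mcfp(smiles),
                 MGFP = compute_mgfp(smiles))
  attr(blocks$MGFP, "radii") <- NULL
  if (use_3ced) {
    blocks$CED3 <- featurize_3ced(smiles, space = space, seed = seed,
                                  max_n = max_conformers)
  }
  blocks
}

#' Assemble a feature set for training and prediction
#'
#' Binds activity records to their encoded kinases and featurized
#' compounds.  Kinase encodings (and their convolution windows) are
#' computed once per catalog entry and shared across folds and epochs.
#'
#' @param records Activity records (kinase_id, compound_smiles,
#'   bioactivity) with canonical SMILES.
#' @param catalog A `kinase_catalog` covering every kinase_id.
#' @param variant_id Model variant; fixes the kinase mode and whether
#'   CED3 is used.
#' @param compound_features Output of [featurize_compounds()] whose row
#'   names cover every compound_smiles.
#' @param site_map `active_site_map`, required for `2-*` variants.
#' @param kernels Convolution kernel sizes (must match the predictor
#'   config used later).
#' @return Object of class `feature_set`.
#' @export
build_feature_set <- function(records, catalog, variant_id,
                              compound_features, site_map = NULL,
                              kernels = c(3L, 5L, 7L)) {
  spec <- variant_spec(variant_id)
  kin_idx <- match(records$kinase_id, catalog$entries$kinase_id)
  if (anyNA(kin_idx)) {
    stop("records reference kinases absent from the catalog: ",
         paste(unique(records$kinase_id[is.na(kin_idx)]), collapse = ", "))
  }
  expected <- c("PCPP", "MCFP", "MGFP", if (spec$use_3ced) "CED3")
  if (!all(expected %in% names(compound_features))) {
    stop("compound_features lacks block(s): ",
         paste(setdiff(expected, names(compound_features)), collapse = ", "))
  }
  blocks <- compound_features[expected]
  comp_ids <- rownames(blocks[[1]])
  comp_idx <- match(records$compound_smiles, comp_ids)
  if (anyNA(comp_idx)) {
    stop("records reference compounds missing from compound_features")
  }
  n_kin <- nrow(catalog$entries)
  if (spec$kinase_mode == "identifier") {
    kin_prepared <- diag(1, n_kin, n_kin)
    seq_len_used <- NULL
  } else {
    if (spec$kinase_mode == "active_site" && is.null(site_map)) {
      stop("variant ", variant_id, " needs an active-site map")
    }
    enc <- lapply(seq_len(n_kin), function(i) {
      encode_kinase(catalog, catalog$entries$kinase_id[i],
                    mode = spec$kinase_mode, site_map = site_map)
    })
    kin_prepared <- lapply(enc, function(X) {
      list(enc = X, ic = lapply(kernels, function(k) .im2col(X, k)))
    })
    seq_len_used <- nrow(kin_prepared[[1]]$enc)
  }
  out <- list(y = records$bioactivity,
              records = records,
              variant_id = variant_id,
              kinase_mode = spec$kinase_mode,
              kinase_idx = kin_idx,
              compound_idx = comp_idx,
              kin_prepared = kin_prepared,
              blocks = blocks,
              kernels = as.integer(kernels),
              seq_len = seq_len_used,
              catalog_size = n_kin,
              n = nrow(records))
  class(out) <- "feature_set"
  out
}

#' Default predictor configuration for a feature set
#'
#' @param fs A `feature_set`.
#' @param seed Weight-initialisation seed.
#' @param ... Overrides passed to [predictor_config()].
#' @return A `predictor_config` matching the feature set shapes.
#' @export
default_config <- function(fs, seed = 1L, ...) {
  predictor_config(fs$variant_id,
                   catalog_size = fs$catalog_size,
                   seq_len = fs$seq_len,
                   block_dims = vapply(fs$blocks, ncol, integer(1)),
                   kernels = fs$kernels, seed = seed, ...)
}

# assemble a minibatch with per-batch uniquification of kinases and
# compounds (branch cost scales with distinct entities, not records)
.make_batch <- function(fs, idx, scaled_blocks) {
  uk <- unique(fs$kinase_idx[idx])
  uc <- unique(fs$compound_idx[idx])
  kin <- if (fs$kinase_mode == "identifier") {
    fs$kin_prepared[uk, , drop = FALSE]
  } else {
    fs$kin_prepared[uk]
  }
  list(kin = kin,
       kin_map = match(fs$kinase_idx[idx], uk),
       blocks = lapply(scaled_blocks, function(m) m[uc, , drop = FALSE]),
       comp_map = match(fs$compound_idx[idx], uc),
       y = fs$y[idx])
}

# fit per-column centering/scaling on the training compounds for the
# continuous blocks; fingerprint blocks stay raw
.fit_scaling <- function(fs, train_idx, which = c("PCPP", "CED3")) {
  sc <- list()
  uc <- unique(fs$compound_idx[train_idx])
  for (nm in intersect(which, names(fs$blocks))) {
    m <- fs$blocks[[nm]][uc, , drop = FALSE]
    center <- colMeans(m)
    scale <- apply(m, 2, stats::sd)
    scale[!is.finite(scale) | scale < 1e-8] <- 1
    sc[[nm]] <- list(center = center, scale = scale)
  }
  sc
}

.scaled_blocks <- function(fs, scaling) {
  blocks <- fs$blocks
  for (nm in names(scaling)) {
    blocks[[nm]] <- sweep(sweep(blocks[[nm]], 2, scaling[[nm]]$center, "-"),
                          2, scaling[[nm]]$scale, "/")
  }
  blocks
}

.val_loss <- function(predictor, fs, idx, scaled_blocks, chunk = 2048L) {
  sse <- 0
  for (start in seq(1L, length(idx), by = chunk)) {
    sub <- idx[start:min(start + chunk - 1L, length(idx))]
    b <- .make_batch(fs, sub, scaled_blocks)
    sse <- sse + sum((.forward(predictor, b)$yhat - b$y)^2)
  }
  sse / length(idx)
}

#' Train a predictor with early stopping
#'
#' Minimises mean squared error with Adam; stops at `max_epochs` or when
#' the validation loss has not improved for `patience` consecutive
#' epochs, and returns the weights of the best validation epoch.
#'
#' @param predictor A freshly built `kinprof_predictor` (or one to warm
#'   start from).
#' @param fs A `feature_set` compatible with the predictor config.
#' @param train_idx,val_idx Disjoint record indices into `fs`.
#' @param config A `train_config`.
#' @return List with `predictor` (best weights, scaling attached) and
#'   `history` (data.frame epoch, train_loss, val_loss).
#' @export
train_predictor <- function(predictor, fs, train_idx, val_idx,
                            config = train_config()) {
  stopifnot(inherits(predictor, "kinprof_predictor"),
            inherits(fs, "feature_set"), inherits(config, "train_config"))
  if (!length(train_idx) || !length(val_idx)) {
    stop("empty training or validation set")
  }
  if (length(intersect(train_idx, val_idx))) {
    stop("training and validation sets overlap")
  }
  scaling <- .fit_scaling(fs, train_idx)
  predictor$scaling <- scaling
  sb <- .scaled_blocks(fs, scaling)
  state <- .adam_init(predictor$params)
  best <- list(loss = Inf, params = predictor$params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  set.seed(config$seed)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(train_idx)
    starts <- seq(1L, length(ord), by = config$batch_size)
    tl <- 0
    for (st in starts) {
      sub <- ord[st:min(st + config$batch_size - 1L, length(ord))]
      b <- .make_batch(fs, sub, sb)
      fw <- .forward(predictor, b, keep = TRUE)
      tl <- tl + sum((fw$yhat - b$y)^2)
      gr <- .backward(predictor, b, fw)
      upd <- .adam_step(predictor$params, gr, state, lr = config$lr)
      predictor$params <- upd$params
      state <- upd$state
    }
    vl <- .val_loss(predictor, fs, val_idx, sb)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = tl / length(ord),
                                         val_loss = vl))
    if (config$verbose) {
      message(sprintf("epoch %d train %.4f val %.4f", epoch,
                      tl / length(ord), vl))
    }
    if (vl < best$loss) {
      best <- list(loss = vl, params = predictor$params, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
  }
  predictor$params <- best$params
  attr(history, "best_epoch") <- best$epoch
  list(predictor = predictor, history = history)
}

# batched prediction over a feature set
.predict_fs <- function(predictor, fs, idx = seq_len(fs$n), chunk = 2048L) {
  sb <- .scaled_blocks(fs, predictor$scaling)
  out <- numeric(length(idx))
  for (start in seq(1L, length(idx), by = chunk)) {
    take <- start:min(start + chunk - 1L, length(idx))
    b <- .make_batch(fs, idx[take], sb)
    out[take] <- .forward(predictor, b)$yhat
  }
  out
}

#' Seeded k-fold assignment
#'
#' @param n Number of records.
#' @param k Number of folds (>= 2).
#' @param seed Shuffle seed.
#' @return Integer vector of fold labels 1..k covering 1..n.
#' @export
kfold_assign <- function(n, k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("need at least k records")
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' k-fold cross-validation with consensus model
#'
#' Partitions the records into k disjoint folds by seeded shuffle; model
#' i trains on the other folds and is validated (and early-stopped) on
#' fold i.  Returns the per-fold models and metrics, their mean and
#' standard deviation, and the consensus predictor that averages the k
#' fold models.
#'
#' @param fs A `feature_set`.
#' @param k Number of folds (default 5).
#' @param model_config Optional `predictor_config` (default from
#'   [default_config()]).
#' @param config A `train_config`.
#' @param seed Fold-assignment seed.
#' @return Object of class `kinprof_cv`: list(models, fold_id,
#'   fold_metrics, summary, consensus, histories).
#' @export
kfold_cv <- function(fs, k = 5L, model_config = NULL,
                     config = train_config(), seed = 1L) {
  fold_id <- kfold_assign(fs$n, k, seed)
  if (is.null(model_config)) model_config <- default_config(fs)
  models <- vector("list", k)
  histories <- vector("list", k)
  fm <- NULL
  for (i in seq_len(k)) {
    tr <- which(fold_id != i)
    va <- which(fold_id == i)
    cfg_i <- model_config
    cfg_i$seed <- model_config$seed + i - 1L
    tc_i <- config
    tc_i$seed <- config$seed + i - 1L
    fit <- train_predictor(build_predictor(cfg_i), fs, tr, va, tc_i)
    models[[i]] <- fit$predictor
    histories[[i]] <- fit$history
    m <- compute_metrics(fs$y[va], .predict_fs(fit$predictor, fs, va))
    fm <- rbind(fm, data.frame(fold = i, pcc = m$pcc, r2 = m$r2,
                               rmse = m$rmse, mae = m$mae, n = m$n))
  }
  summ <- data.frame(
    metric = c("pcc", "r2", "rmse", "mae"),
    mean = vapply(c("pcc", "r2", "rmse", "mae"),
                  function(c_) mean(fm[[c_]]), numeric(1)),
    sd = vapply(c("pcc", "r2", "rmse", "mae"),
                function(c_) stats::sd(fm[[c_]]), numeric(1)))
  out <- list(models = models, fold_id = fold_id, fold_metrics = fm,
              summary = summ, consensus = consensus_predictor(models),
              histories = histories)
  class(out) <- "kinprof_cv"
  out
}

#' @export
print.kinprof_cv <- function(x, ...) {
  cat("k-fold cross-validation,", length(x$models), "folds, variant",
      x$models[[1]]$config$variant_id, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Consensus predictor over fold models
#'
#' @param members List of trained `kinprof_predictor` objects sharing a
#'   variant and input contract.
#' @return Object of class `consensus_predictor`.
#' @export
consensus_predictor <- function(members) {
  if (!length(members)) stop("consensus needs at least one member")
  v <- vapply(members, function(m) m$config$variant_id, character(1))
  if (length(unique(v)) != 1L) {
    stop("consensus members disagree on variant: ",
         paste(unique(v), collapse = ", "))
  }
  dims <- lapply(members, function(m) m$config$block_dims)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("consensus members disagree on input contract")
  }
  structure(list(members = members), class = "consensus_predictor")
}

#' Consensus prediction: mean over member models
#'
#' @param consensus A `consensus_predictor`.
#' @param fs A `feature_set`.
#' @param idx Record indices (default all).
#' @return Numeric vector: element-wise arithmetic mean of the member
#'   predictions.
#' @export
consensus_predict <- function(consensus, fs, idx = seq_len(fs$n)) {
  stopifnot(inherits(consensus, "consensus_predictor"))
  preds <- vapply(consensus$members, .predict_fs, numeric(length(idx)),
                  fs = fs, idx = idx)
  if (length(idx) == 1L) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

#' Regression metrics on the bioactivity scale
#'
#' Pearson correlation, R-squared (1 - SS_res/SS_tot), RMSE and MAE, all
#' on log10(nM) units.  For constant observed values PCC and R-squared
#' are undefined and reported as NA with `degenerate = TRUE`.
#'
#' @param y_true,y_pred Equal-length numeric vectors (n >= 2).
#' @return Object of class `metrics_report` (a list): pcc, r2, rmse,
#'   mae, n, degenerate.
#' @export
compute_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  err <- y_pred - y_true
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  sstot <- sum((y_true - mean(y_true))^2)
  degenerate <- sstot == 0
  if (degenerate) {
    warning("constant observed values: PCC and R2 undefined", call. = FALSE)
    pcc <- NA_real_
    r2 <- NA_real_
  } else if (stats::sd(y_pred) == 0) {
    warning("constant predictions: PCC undefined", call. = FALSE)
    pcc <- NA_real_
    r2 <- 1 - sum(err^2) / sstot
  } else {
    pcc <- stats::cor(y_true, y_pred)
    r2 <- 1 - sum(err^2) / sstot
  }
  structure(list(pcc = pcc, r2 = r2, rmse = rmse, mae = mae,
                 n = length(y_true), degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n=%d  PCC=%.3f  R2=%.3f  RMSE=%.3f  MAE=%.3f  [log10 nM]\n",
              x$n, x$pcc, x$r2, x$rmse, x$mae))
  invisible(x)
}

#' Per-kinase / per-compound prediction correlation
#'
#' Selects entities with strictly more than `min_n` records and computes
#' the Pearson correlation between observed and predicted bioactivity
#' within each.
#'
#' @param records Activity records aligned with `predictions`.
#' @param predictions Predicted bioactivities.
#' @param group_by "kinase" or "compound".
#' @param min_n Inclusion threshold: entities need more than this many
#'   records (default 10).
#' @return data.frame (entity, n, pcc), possibly empty.
#' @export
per_entity_pcc <- function(records, predictions,
                           group_by = c("kinase", "compound"),
                           min_n = 10L) {
  group_by <- match.arg(group_by)
  stopifnot(nrow(records) == length(predictions))
  key <- if (group_by == "kinase") records$kinase_id else
    records$compound_smiles
  out <- do.call(rbind, lapply(split(seq_along(key), key), function(ix) {
    if (length(ix) <= min_n) return(NULL)
    yt <- records$bioactivity[ix]
    if (stats::sd(yt) == 0) return(NULL)
    data.frame(entity = key[ix[1]], n = length(ix),
               pcc = stats::cor(yt, predictions[ix]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(entity = character(0), n = integer(0),
                      pcc = numeric(0))
  }
  rownames(out) <- NULL
  out
}
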