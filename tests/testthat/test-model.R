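# Architecture contracts, determinism, and gradient correctness.

tiny_cfg <- function(variant = "3-2", seed = 3) {
  dims <- c(PCPP = 5L, MCFP = 4L, MGFP = 6L)
  if (variant %in% c("1-2", "2-2", "3-2")) dims <- c(dims, CED3 = 7L)
  predictor_config(variant,
                   catalog_size = 4L, seq_len = 12L, block_dims = dims,
                   conv_channels = 3L, kernels = c(3L, 5L), heads = 2L,
                   embed = 6L, head_dims = c(8L, 4L), seed = seed)
}

tiny_batch <- function(cfg, B = 7, n_kin = 3, n_cmp = 4, seed = 42) {
  set.seed(seed)
  if (cfg$kinase_mode == "identifier") {
    kin <- diag(1, n_kin, cfg$catalog_size)
  } else {
    kin <- lapply(seq_len(n_kin), function(i) {
      s <- paste(sample(aa_channels(), cfg$seq_len, replace = TRUE),
                 collapse = "")
      Xe <- encode_sequence(s)
      list(ic = lapply(cfg$kernels, function(k) kinprof:::.im2col(Xe, k)))
    })
  }
  blocks <- lapply(cfg$block_dims, function(d) {
    matrix(stats::rnorm(n_cmp * d), n_cmp)
  })
  list(kin = kin, kin_map = sample(n_kin, B, replace = TRUE),
       blocks = blocks, comp_map = sample(n_cmp, B, replace = TRUE),
       y = stats::rnorm(B))
}

test_that("variant table fixes the kinase mode and 3CED usage", {
  expect_equal(variant_spec("1-1")$kinase_mode, "identifier")
  expect_false(variant_spec("1-1")$use_3ced)
  expect_equal(variant_spec("2-2")$kinase_mode, "active_site")
  expect_true(variant_spec("2-2")$use_3ced)
  expect_equal(variant_spec("3-2")$kinase_mode, "full_alignment")
  expect_true(variant_spec("3-2")$use_3ced)
  expect_error(variant_spec("4-1"), "unknown variant")
})

test_that("configs validate shapes against the variant contract", {
  expect_error(predictor_config("1-1", catalog_size = 10,
                                block_dims = c(PCPP = 5, MCFP = 4,
                                               MGFP = 6, CED3 = 7)),
               "exactly")
  expect_error(predictor_config("3-2", seq_len = 12,
                                block_dims = c(PCPP = 5, MCFP = 4,
                                               MGFP = 6)),
               "exactly")
  expect_error(predictor_config("3-1", block_dims = c(PCPP = 5, MCFP = 4,
                                                      MGFP = 6)),
               "seq_len")
  expect_error(predictor_config("1-1", catalog_size = 10,
                                block_dims = c(PCPP = 5, MCFP = 4,
                                               MGFP = 6),
                                kernels = c(2, 4)),
               "odd")
})

test_that("weight initialisation is seeded and reproducible", {
  p1 <- build_predictor(tiny_cfg(seed = 11))
  p2 <- build_predictor(tiny_cfg(seed = 11))
  expect_identical(p1$params, p2$params)
  p3 <- build_predictor(tiny_cfg(seed = 12))
  expect_false(identical(p1$params, p3$params))
})

test_that("all six variants build, run forward, and police their inputs", {
  for (v in c("1-1", "1-2", "2-1", "2-2", "3-1", "3-2")) {
    cfg <- tiny_cfg(v)
    pred <- build_predictor(cfg)
    spec <- variant_spec(v)
    kin_in <- if (spec$kinase_mode == "identifier") {
      matrix(c(1, 0, 0, 0), 1)
    } else {
      encode_sequence(paste(rep("A", cfg$seq_len), collapse = ""))
    }
    blocks <- lapply(cfg$block_dims, function(d) stats::rnorm(d))
    out <- predict(pred, kin_in, blocks)
    expect_length(out, 1)
    expect_true(is.finite(out))
    # wrong block set is rejected
    if (spec$use_3ced) {
      expect_error(predict(pred, kin_in, blocks[c("PCPP", "MCFP", "MGFP")]),
                   "expects compound blocks")
    } else {
      bad <- c(blocks, list(CED3 = stats::rnorm(7)))
      expect_error(predict(pred, kin_in, bad), "expects compound blocks")
    }
    # wrong kinase shape is rejected, naming the branch
    expect_error(predict(pred, matrix(0, 2, 5), blocks), "kinase branch")
  }
})

test_that("zeroed inputs through a zeroed head return the head bias", {
  cfg <- tiny_cfg("1-1")
  pred <- constant_predictor(cfg, 0.75)
  blocks <- lapply(cfg$block_dims, function(d) numeric(d))
  out <- predict(pred, matrix(0, 1, cfg$catalog_size), blocks)
  expect_equal(out, 0.75)
})

test_that("batched prediction is row-wise and permutation-equivariant", {
  cfg <- tiny_cfg("3-2")
  pred <- build_predictor(cfg)
  batch <- tiny_batch(cfg, B = 9)
  y1 <- kinprof:::.forward(pred, batch)$yhat
  expect_length(y1, 9)
  # identical rows give identical outputs
  same <- batch
  same$kin_map <- rep(batch$kin_map[1], 9)
  same$comp_map <- rep(batch$comp_map[1], 9)
  ys <- kinprof:::.forward(pred, same)$yhat
  expect_equal(ys, rep(ys[1], 9))
  # permuting batch rows permutes outputs identically
  set.seed(8)
  perm <- sample(9)
  pb <- batch
  pb$kin_map <- batch$kin_map[perm]
  pb$comp_map <- batch$comp_map[perm]
  pb$y <- batch$y[perm]
  expect_equal(kinprof:::.forward(pred, pb)$yhat, y1[perm])
})

test_that("analytic gradients match finite differences", {
  for (variant in c("3-2", "1-1")) {
    cfg <- tiny_cfg(variant)
    pred <- build_predictor(cfg)
    batch <- tiny_batch(cfg)
    fw <- kinprof:::.forward(pred, batch, keep = TRUE)
    gr <- kinprof:::.backward(pred, batch, fw)
    loss_at <- function(params) {
      p2 <- pred; p2$params <- params
      mean((kinprof:::.forward(p2, batch)$yhat - batch$y)^2)
    }
    eps <- 1e-6
    poke <- function(tree, pth, k, d) {
      if (length(pth) == 1) {
        tree[[pth[[1]]]][k] <- tree[[pth[[1]]]][k] + d
      } else {
        tree[[pth[[1]]]] <- poke(tree[[pth[[1]]]], pth[-1], k, d)
      }
      tree
    }
    paths <- if (variant == "1-1") {
      list(list("kin", "W"), list("blocks", "PCPP", "W"),
           list("blocks", "MGFP", "g"), list("outa"),
           list("head", "W1"), list("head", "W3"))
    } else {
      list(list("conv", 1L, "W"), list("conv", 2L, "b"), list("attnQ"),
           list("proj", "W"), list("blocks", "CED3", "g"),
           list("outa"), list("head", "W2"))
    }
    set.seed(5)
    for (pth in paths) {
      leaf_g <- gr
      for (p_ in pth) leaf_g <- leaf_g[[p_]]
      for (k in sample(length(leaf_g), min(4, length(leaf_g)))) {
        num <- (loss_at(poke(pred$params, pth, k, eps)) -
                  loss_at(poke(pred$params, pth, k, -eps))) / (2 * eps)
        expect_equal(unname(leaf_g[k]), num, tolerance = 1e-5)
      }
    }
  }
})

test_that("every parameter tensor receives gradient (no dead branches)", {
  for (variant in c("3-2", "1-1", "2-2")) {
    cfg <- tiny_cfg(variant)
    pred <- build_predictor(cfg)
    batch <- tiny_batch(cfg, B = 16, n_kin = 3, n_cmp = 5)
    fw <- kinprof:::.forward(pred, batch, keep = TRUE)
    gr <- kinprof:::.backward(pred, batch, fw)
    walk <- function(x, path = "") {
      if (is.list(x)) {
        for (nm in seq_along(x)) {
          walk(x[[nm]], paste0(path, "/", names(x)[nm]))
        }
      } else {
        expect_gt(sum(abs(x)), 0, label = paste("gradient norm of", path))
      }
    }
    walk(gr)
  }
})
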