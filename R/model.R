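# Attention-based bioactivity regressor.
#
# Six variants combine one kinase representation (identifier one-hot,
# active-site alignment slice, or full alignment) with the 2D compound
# blocks (PCPP, MCFP, MGFP) and optionally the 3D conformer-ensemble
# descriptor (3CED).  The network follows a five-block layout:
#   * Convolution: multi-kernel 1-D convolution over alignment positions
#     (sequence-mode kinase branch only; the identifier branch uses a
#     dense embedding, convolution over a length-1 sequence is vacuous);
#   * Input attention: multi-head attention pooling over positions for
#     the kinase branch, and a learned sigmoid feature gate for each flat
#     descriptor block;
#   * Concatenation of all branch embeddings;
#   * Output attention: a learned sigmoid gate over the concatenated
#     representation;
#   * Output: a dense head emitting one real value (bioactivity,
#     log10 nM).
# Forward and backward passes are explicit matrix algebra; optimisation
# is Adam.  All randomness is funnelled through the config seed.

VARIANT_TABLE <- data.frame(
  variant_id = c("1-1", "1-2", "2-1", "2-2", "3-1", "3-2"),
  kinase_mode = rep(c("identifier", "active_site", "full_alignment"),
                    each = 2),
  use_3ced = rep(c(FALSE, TRUE), 3),
  stringsAsFactors = FALSE)

#' Model variant specification
#'
#' Fixed mapping of the six variant ids to their input contracts:
#' `1-*` identifier, `2-*` active-site, `3-*` full alignment;
#' `*-2` adds the 3CED block, `*-1` does not.  Variant `3-2` is the
#' full model (alignment encoding plus all four compound blocks).
#'
#' @param variant_id One of "1-1", "1-2", "2-1", "2-2", "3-1", "3-2".
#' @return List with `variant_id`, `kinase_mode`, `use_3ced`.
#' @export
variant_spec <- function(variant_id) {
  i <- match(variant_id, VARIANT_TABLE$variant_id)
  if (is.na(i)) {
    stop("unknown variant '", variant_id, "'; expected one of ",
         paste(VARIANT_TABLE$variant_id, collapse = ", "))
  }
  as.list(VARIANT_TABLE[i, ])
}

#' Predictor configuration
#'
#' @param variant_id Model variant (see [variant_spec()]).
#' @param catalog_size Number of kinases (identifier mode input width).
#' @param seq_len Alignment positions seen by the kinase branch: the
#'   active-site map length or the alignment width.
#' @param block_dims Named integer vector of compound block widths, e.g.
#'   `c(PCPP = 208, MCFP = 167, MGFP = 1792, CED3 = 3348)`; must contain
#'   CED3 exactly when the variant uses 3CED.
#' @param conv_channels Channels per convolution kernel size.
#' @param kernels Odd 1-D convolution kernel sizes.
#' @param heads Attention-pooling heads.
#' @param embed Branch embedding width.
#' @param head_dims Hidden widths of the output head.
#' @param seed Seed for weight initialisation.
#' @return Object of class `predictor_config`.
#' @export
predictor_config <- function(variant_id, catalog_size = NULL, seq_len = NULL,
                             block_dims,
                             conv_channels = 64L, kernels = c(3L, 5L, 7L),
                             heads = 4L, embed = 128L,
                             head_dims = c(256L, 64L), seed = 1L) {
  spec <- variant_spec(variant_id)
  expected <- c("PCPP", "MCFP", "MGFP", if (spec$use_3ced) "CED3")
  if (!identical(sort(names(block_dims)), sort(expected))) {
    stop("variant ", variant_id, " needs block_dims for exactly: ",
         paste(expected, collapse = ", "))
  }
  block_dims <- block_dims[expected]
  if (spec$kinase_mode == "identifier") {
    if (is.null(catalog_size) || catalog_size < 1L) {
      stop("identifier mode needs catalog_size")
    }
  } else if (is.null(seq_len) || seq_len < max(kernels)) {
    stop("sequence modes need seq_len >= max kernel size")
  }
  if (any(kernels %% 2L == 0L)) stop("kernel sizes must be odd")
  stopifnot(conv_channels >= 1L, heads >= 1L, embed >= 1L,
            all(head_dims >= 1L))
  out <- list(variant_id = variant_id, kinase_mode = spec$kinase_mode,
              use_3ced = spec$use_3ced,
              catalog_size = catalog_size, seq_len = seq_len,
              block_dims = block_dims, conv_channels = as.integer(conv_channels),
              kernels = as.integer(kernels), heads = as.integer(heads),
              embed = as.integer(embed), head_dims = as.integer(head_dims),
              seed = as.integer(seed))
  class(out) <- "predictor_config"
  out
}

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build a predictor from a configuration
#'
#' Initialises all weights from the config seed (two builds from one
#' config are bit-identical).
#'
#' @param config A `predictor_config`.
#' @return Object of class `kinprof_predictor`.
#' @export
build_predictor <- function(config) {
  stopifnot(inherits(config, "predictor_config"))
  set.seed(config$seed)
  embed <- config$embed
  params <- list()
  if (config$kinase_mode == "identifier") {
    params$kin <- list(W = .glorot(config$catalog_size, embed),
                       b = numeric(embed))
  } else {
    C <- config$conv_channels
    D <- C * length(config$kernels)
    params$conv <- lapply(config$kernels, function(k) {
      list(W = .glorot(21L * k, C), b = numeric(C))
    })
    params$attnQ <- matrix(stats::rnorm(config$heads * D, sd = 0.1),
                           config$heads, D)
    params$proj <- list(W = .glorot(config$heads * D, embed),
                        b = numeric(embed))
  }
  params$blocks <- lapply(config$block_dims, function(d) {
    list(g = numeric(d), W = .glorot(d, embed), b = numeric(embed))
  })
  nb <- 1L + length(config$block_dims)
  params$outa <- numeric(embed * nb)
  h <- config$head_dims
  params$head <- list(W1 = .glorot(embed * nb, h[1]), b1 = numeric(h[1]),
                      W2 = .glorot(h[1], h[2]), b2 = numeric(h[2]),
                      W3 = .glorot(h[2], 1L), b3 = numeric(1L))
  out <- list(config = config, params = params, scaling = NULL)
  class(out) <- "kinprof_predictor"
  out
}

#' @export
print.kinprof_predictor <- function(x, ...) {
  cfg <- x$config
  cat("kinprof predictor, variant ", cfg$variant_id, " (",
      cfg$kinase_mode, if (cfg$use_3ced) " + 3CED", ")\n", sep = "")
  cat("  compound blocks:",
      paste(sprintf("%s(%d)", names(cfg$block_dims), cfg$block_dims),
            collapse = " "), "\n")
  cat("  ", .n_params(x$params), "trainable parameters\n")
  invisible(x)
}

.n_params <- function(p) {
  if (is.list(p)) sum(vapply(p, .n_params, numeric(1))) else length(p)
}

# im2col for 1-D convolution with same zero padding: row i holds the
# flattened k x 21 window centred on alignment position i
.im2col <- function(X, k) {
  L <- nrow(X)
  pad <- (k - 1L) %/% 2L
  out <- matrix(0, L, 21L * k)
  for (o in seq_len(k)) {
    shift <- o - 1L - pad
    src <- seq_len(L) + shift
    ok <- src >= 1L & src <= L
    out[ok, ((o - 1L) * 21L + 1L):(o * 21L)] <- X[src[ok], , drop = FALSE]
  }
  out
}

.softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# forward pass over a prepared batch; returns prediction and (optionally)
# every intermediate needed by the backward pass
#
# batch: list(kin, kin_map, blocks, comp_map, y) where
#   kin      - identifier mode: U_k x catalog one-hot matrix;
#              sequence modes: list of per-kinase list(ic = list of
#              im2col matrices, one per kernel)
#   blocks   - named list of U_c x d matrices (already scaled)
.forward <- function(predictor, batch, keep = FALSE) {
  cfg <- predictor$config
  par <- predictor$params
  embed <- cfg$embed
  cache <- list()

  if (cfg$kinase_mode == "identifier") {
    Epre <- batch$kin %*% par$kin$W +
      matrix(par$kin$b, nrow(batch$kin), embed, byrow = TRUE)
    Eu <- Epre * (Epre > 0)
    if (keep) cache$kin <- list(Epre = Epre)
  } else {
    U <- length(batch$kin)
    Eu <- matrix(0, U, embed)
    kin_cache <- vector("list", U)
    nk <- length(cfg$kernels)
    for (u in seq_len(U)) {
      ic <- batch$kin[[u]]$ic
      Z <- do.call(cbind, lapply(seq_len(nk), function(i) {
        ic[[i]] %*% par$conv[[i]]$W +
          matrix(par$conv[[i]]$b, nrow(ic[[i]]), cfg$conv_channels,
                 byrow = TRUE)
      }))
      Hr <- Z * (Z > 0)
      S <- Hr %*% t(par$attnQ)                       # L x heads
      A <- apply(S, 2, .softmax)
      if (is.null(dim(A))) A <- matrix(A, ncol = cfg$heads)
      P <- t(Hr) %*% A                               # D x heads
      p <- as.vector(P)
      epre <- drop(p %*% par$proj$W) + par$proj$b
      Eu[u, ] <- epre * (epre > 0)
      if (keep) kin_cache[[u]] <- list(Z = Z, Hr = Hr, A = A, p = p,
                                       epre = epre)
    }
    if (keep) cache$kin <- kin_cache
  }
  E <- Eu[batch$kin_map, , drop = FALSE]

  Arec <- vector("list", length(batch$blocks))
  names(Arec) <- names(batch$blocks)
  if (keep) cache$blocks <- vector("list", length(batch$blocks))
  for (bi in seq_along(batch$blocks)) {
    nm <- names(batch$blocks)[bi]
    Xb <- batch$blocks[[bi]]
    pb <- par$blocks[[nm]]
    G <- 1 / (1 + exp(-pb$g))
    Zb <- Xb * matrix(G, nrow(Xb), length(G), byrow = TRUE)
    Apre <- Zb %*% pb$W + matrix(pb$b, nrow(Zb), embed, byrow = TRUE)
    Au <- Apre * (Apre > 0)
    Arec[[bi]] <- Au[batch$comp_map, , drop = FALSE]
    if (keep) cache$blocks[[bi]] <- list(G = G, Zb = Zb, Apre = Apre)
  }

  Cc <- do.call(cbind, c(list(E), Arec))
  s <- 1 / (1 + exp(-par$outa))
  Ca <- Cc * matrix(s, nrow(Cc), length(s), byrow = TRUE)
  H1p <- Ca %*% par$head$W1 +
    matrix(par$head$b1, nrow(Ca), length(par$head$b1), byrow = TRUE)
  H1 <- H1p * (H1p > 0)
  H2p <- H1 %*% par$head$W2 +
    matrix(par$head$b2, nrow(H1), length(par$head$b2), byrow = TRUE)
  H2 <- H2p * (H2p > 0)
  yhat <- drop(H2 %*% par$head$W3) + par$head$b3
  if (keep) {
    cache$Eu <- Eu; cache$E <- E; cache$Arec <- Arec; cache$Cc <- Cc
    cache$s <- s; cache$Ca <- Ca; cache$H1p <- H1p; cache$H1 <- H1
    cache$H2p <- H2p; cache$H2 <- H2; cache$yhat <- yhat
  }
  list(yhat = yhat, cache = if (keep) cache)
}

# accumulate rows of `x` by integer group `map` into `n` rows
.scatter_sum <- function(x, map, n) {
  out <- rowsum(x, group = map)
  full <- matrix(0, n, ncol(x))
  full[as.integer(rownames(out)), ] <- out
  full
}

# backward pass: gradients of the mean-squared-error loss w.r.t. every
# parameter; mirrors the structure of `.forward`
.backward <- function(predictor, batch, fw) {
  cfg <- predictor$config
  par <- predictor$params
  cache <- fw$cache
  B <- length(fw$yhat)
  embed <- cfg$embed
  grads <- list()

  dyhat <- matrix(2 * (fw$yhat - batch$y) / B, ncol = 1)
  grads$head <- list(
    W3 = t(cache$H2) %*% dyhat, b3 = sum(dyhat))
  dH2 <- (dyhat %*% t(par$head$W3)) * (cache$H2p > 0)
  grads$head$W2 <- t(cache$H1) %*% dH2
  grads$head$b2 <- colSums(dH2)
  dH1 <- (dH2 %*% t(par$head$W2)) * (cache$H1p > 0)
  grads$head$W1 <- t(cache$Ca) %*% dH1
  grads$head$b1 <- colSums(dH1)
  dCa <- dH1 %*% t(par$head$W1)
  s <- cache$s
  grads$outa <- colSums(dCa * cache$Cc) * s * (1 - s)
  dCc <- dCa * matrix(s, B, length(s), byrow = TRUE)

  dE <- dCc[, seq_len(embed), drop = FALSE]
  off <- embed
  grads$blocks <- vector("list", length(batch$blocks))
  names(grads$blocks) <- names(batch$blocks)
  for (bi in seq_along(batch$blocks)) {
    nm <- names(batch$blocks)[bi]
    dArec <- dCc[, (off + 1L):(off + embed), drop = FALSE]
    off <- off + embed
    Uc <- nrow(batch$blocks[[bi]])
    dAu <- .scatter_sum(dArec, batch$comp_map, Uc)
    cb <- cache$blocks[[bi]]
    dApre <- dAu * (cb$Apre > 0)
    pb <- par$blocks[[nm]]
    dZb <- dApre %*% t(pb$W)
    grads$blocks[[bi]] <- list(
      g = colSums(dZb * batch$blocks[[bi]]) * cb$G * (1 - cb$G),
      W = t(cb$Zb) %*% dApre,
      b = colSums(dApre))
  }

  if (cfg$kinase_mode == "identifier") {
    Uk <- nrow(batch$kin)
    dEu <- .scatter_sum(dE, batch$kin_map, Uk)
    dEpre <- dEu * (cache$kin$Epre > 0)
    grads$kin <- list(W = t(batch$kin) %*% dEpre, b = colSums(dEpre))
  } else {
    Uk <- length(batch$kin)
    dEu <- .scatter_sum(dE, batch$kin_map, Uk)
    nk <- length(cfg$kernels)
    C <- cfg$conv_channels
    grads$conv <- lapply(par$conv, function(pc) {
      list(W = matrix(0, nrow(pc$W), ncol(pc$W)), b = numeric(length(pc$b)))
    })
    grads$attnQ <- matrix(0, nrow(par$attnQ), ncol(par$attnQ))
    grads$proj <- list(W = matrix(0, nrow(par$proj$W), ncol(par$proj$W)),
                       b = numeric(length(par$proj$b)))
    for (u in seq_len(Uk)) {
      ck <- cache$kin[[u]]
      de <- dEu[u, ]
      depre <- de * (ck$epre > 0)
      grads$proj$W <- grads$proj$W + outer(ck$p, depre)
      grads$proj$b <- grads$proj$b + depre
      dp <- drop(par$proj$W %*% depre)
      dP <- matrix(dp, ncol = cfg$heads)
      dA <- ck$Hr %*% dP                             # L x heads
      dHr <- ck$A %*% t(dP)                          # L x D
      dS <- matrix(0, nrow(ck$A), cfg$heads)
      for (h in seq_len(cfg$heads)) {
        a <- ck$A[, h]
        dS[, h] <- a * (dA[, h] - sum(dA[, h] * a))
      }
      dHr <- dHr + dS %*% par$attnQ
      grads$attnQ <- grads$attnQ + t(dS) %*% ck$Hr
      dZ <- dHr * (ck$Z > 0)
      for (i in seq_len(nk)) {
        cols <- ((i - 1L) * C + 1L):(i * C)
        ic <- batch$kin[[u]]$ic[[i]]
        grads$conv[[i]]$W <- grads$conv[[i]]$W +
          t(ic) %*% dZ[, cols, drop = FALSE]
        grads$conv[[i]]$b <- grads$conv[[i]]$b +
          colSums(dZ[, cols, drop = FALSE])
      }
    }
  }
  .align_tree(par, grads)
}

# reorder a nested gradient list to the exact structure of the params
.align_tree <- function(template, x) {
  if (!is.list(template)) return(x)
  nm <- names(template)
  out <- if (is.null(nm)) x else x[nm]
  for (i in seq_along(template)) {
    out[[i]] <- .align_tree(template[[i]], out[[i]])
  }
  out
}

# elementwise walk over parallel nested lists
.tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- vector("list", length(trees[[1]]))
    names(out) <- names(trees[[1]])
    for (i in seq_along(out)) {
      out[[i]] <- do.call(.tree_map,
                          c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

.adam_init <- function(params) {
  zeros <- function(p) .tree_map(function(x) x * 0, p)
  list(m = zeros(params), v = zeros(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- .tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- .tree_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

#' Predict bioactivity for explicit model inputs
#'
#' Validates the inputs against the predictor's contract (kinase
#' representation shape; exactly the expected compound blocks) and runs
#' the forward pass.  Stored feature scaling (set during training) is
#' applied to the continuous blocks.
#'
#' @param object A `kinprof_predictor`.
#' @param kinase_input One-hot kinase encoding: `(1, catalog)` for
#'   identifier mode or `(L, 21)` for sequence modes.  For a batch,
#'   a list of such matrices.
#' @param compound_blocks Named list of descriptor vectors (or matrices
#'   with one row per batch element): PCPP, MCFP, MGFP and, for `*-2`
#'   variants, CED3.
#' @param ... Unused.
#' @return Numeric vector of predicted bioactivities (log10 nM).
#' @export
predict.kinprof_predictor <- function(object, kinase_input, compound_blocks,
                                      ...) {
  cfg <- object$config
  expected <- names(cfg$block_dims)
  got <- names(compound_blocks)
  if (!setequal(got, expected)) {
    stop("variant ", cfg$variant_id, " expects compound blocks {",
         paste(expected, collapse = ", "), "}, got {",
         paste(got, collapse = ", "), "}")
  }
  blocks <- lapply(expected, function(nm) {
    x <- compound_blocks[[nm]]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    if (ncol(x) != cfg$block_dims[[nm]]) {
      stop("block ", nm, ": expected width ", cfg$block_dims[[nm]],
           ", got ", ncol(x))
    }
    x
  })
  names(blocks) <- expected
  if (!is.list(kinase_input)) kinase_input <- list(kinase_input)
  B <- max(nrow(blocks[[1]]), length(kinase_input))
  blocks <- lapply(blocks, function(x) {
    if (nrow(x) == 1L && B > 1L) x[rep(1L, B), , drop = FALSE] else x
  })
  if (length(kinase_input) == 1L && B > 1L) {
    kinase_input <- kinase_input[rep(1L, B)]
  }
  stopifnot(all(vapply(blocks, nrow, integer(1)) == B),
            length(kinase_input) == B)
  for (ki in kinase_input) {
    if (cfg$kinase_mode == "identifier") {
      if (!(nrow(ki) == 1L && ncol(ki) == cfg$catalog_size)) {
        stop("kinase branch: identifier input must be (1, ",
             cfg$catalog_size, ")")
      }
    } else if (!(nrow(ki) == cfg$seq_len && ncol(ki) == 21L)) {
      stop("kinase branch: expected (", cfg$seq_len, ", 21) encoding, got (",
           nrow(ki), ", ", ncol(ki), ")")
    }
  }
  blocks <- .apply_scaling(object, blocks)
  if (cfg$kinase_mode == "identifier") {
    kin <- do.call(rbind, kinase_input)
  } else {
    kin <- lapply(kinase_input, function(X) {
      list(ic = lapply(cfg$kernels, function(k) .im2col(X, k)))
    })
  }
  batch <- list(kin = kin, kin_map = seq_len(B), blocks = blocks,
                comp_map = seq_len(B))
  .forward(object, batch)$yhat
}

.apply_scaling <- function(predictor, blocks) {
  sc <- predictor$scaling
  if (is.null(sc)) return(blocks)
  for (nm in names(sc)) {
    if (!nm %in% names(blocks)) next
    blocks[[nm]] <- sweep(sweep(blocks[[nm]], 2, sc[[nm]]$center, "-"),
                          2, sc[[nm]]$scale, "/")
  }
  blocks
}
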