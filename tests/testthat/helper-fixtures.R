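# Shared fixtures and independent oracles, all built in code.

# a few small, chemically unambiguous molecules
FIX_MOLS <- c(ethanol = "CCO",
              benzene = "c1ccccc1",
              benzamide = "NC(=O)c1ccccc1",
              tyramine = "NCCc1ccc(O)cc1",
              flexible = "CC(=O)Nc1ccc(Oc2ccccc2)cc1")

# hand-built activity records without any chemistry involved
make_records <- function(n_kinases = 5, n_compounds = 8, seed = 1) {
  set.seed(seed)
  kin <- sprintf("K%02d", seq_len(n_kinases))
  cmp <- sprintf("FAKE%02d", seq_len(n_compounds))
  grid <- expand.grid(k = kin, c = cmp, stringsAsFactors = FALSE)
  data.frame(kinase_id = grid$k,
             compound_smiles = grid$c,
             measurement_type = "IC50",
             value_nM = 10^stats::runif(nrow(grid), 0, 5),
             bioactivity = NA_real_,
             source = "test",
             stringsAsFactors = FALSE) -> df
  df$bioactivity <- log10(df$value_nM)
  df
}

tiny_catalog <- function(n = 6, width = 40, groups = 2, seed = 3) {
  set.seed(seed)
  aa <- aa_channels()[1:20]
  seqs <- replicate(n, paste(sample(aa, width, replace = TRUE),
                             collapse = ""))
  ids <- sprintf("K%02d", seq_len(n))
  kinase_catalog(ids, seqs,
                 stats::setNames(sprintf("G%d", rep(seq_len(groups),
                                                    length.out = n)), ids))
}

# independent brute-force signature oracle: naive loops over ordered
# pairs/triples, slot located by scanning the space table (no hash
# lookup, no shared code with conformer_signature's canonicalisation)
brute_force_signature <- function(sites, space) {
  v <- numeric(space$dimension)
  n <- nrow(sites)
  if (n < 2) return(v)
  fam <- match(sites$family, space$families)
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  bin_of <- function(d) {
    for (b in seq_along(space$bins)) {
      if (d >= space$bins[[b]][1] && d < space$bins[[b]][2]) return(b)
    }
    NA_integer_
  }
  tab <- space$table
  if (2 %in% space$point_counts) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      b <- bin_of(sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
      if (is.na(b)) next
      fp <- sort(fam[c(i, j)])
      hit <- which(tab$points == 2 & tab$f1 == fp[1] & tab$f2 == fp[2] &
                     tab$b12 == b)
      v[hit] <- v[hit] + 1
    }
  }
  if (3 %in% space$point_counts && n >= 3) {
    combs <- utils::combn(n, 3)
    for (ci in seq_len(ncol(combs))) {
      trip <- combs[, ci]
      d <- c(sqrt(sum((xyz[trip[1], ] - xyz[trip[2], ])^2)),
             sqrt(sum((xyz[trip[1], ] - xyz[trip[3], ])^2)),
             sqrt(sum((xyz[trip[2], ] - xyz[trip[3], ])^2)))
      if (any(is.na(vapply(d, bin_of, integer(1))))) next
      # all orderings with sorted families; lexicographically smallest
      # bin triple wins
      perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      cand <- NULL
      for (p in perms) {
        s <- trip[p]
        f <- fam[s]
        if (is.unsorted(f)) next
        b <- c(bin_of(sqrt(sum((xyz[s[1], ] - xyz[s[2], ])^2))),
               bin_of(sqrt(sum((xyz[s[1], ] - xyz[s[3], ])^2))),
               bin_of(sqrt(sum((xyz[s[2], ] - xyz[s[3], ])^2))))
        code <- b[1] * 100 + b[2] * 10 + b[3]
        if (is.null(cand) || code < cand$code) {
          cand <- list(f = f, b = b, code = code)
        }
      }
      hit <- which(tab$points == 3 & tab$f1 == cand$f[1] &
                     tab$f2 == cand$f[2] & tab$f3 == cand$f[3] &
                     tab$b12 == cand$b[1] & tab$b13 == cand$b[2] &
                     tab$b23 == cand$b[3])
      v[hit] <- v[hit] + 1
    }
  }
  v
}

# mean pairwise sequence identity between two catalog entry index sets
pairwise_identity <- function(catalog, i, j) {
  a <- strsplit(catalog$entries$aligned_seq[i], "")[[1]]
  b <- strsplit(catalog$entries$aligned_seq[j], "")[[1]]
  mean(a == b)
}

# small random rigid motion (rotation + translation) applied to sites
rigid_transform <- function(sites, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(9), 3)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- stats::rnorm(3, sd = 5)
  xyz <- as.matrix(sites[, c("x", "y", "z")]) %*% R
  xyz <- sweep(xyz, 2, shift, "+")
  sites$x <- xyz[, 1]; sites$y <- xyz[, 2]; sites$z <- xyz[, 3]
  sites
}

# predictor whose output is a constant: zeroed weights, head bias = konst
constant_predictor <- function(cfg, konst) {
  p <- build_predictor(cfg)
  p$params <- kinprof:::.tree_map(function(x) x * 0, p$params)
  p$params$head$b3 <- konst
  p
}

# tiny identifier-mode feature set over fake descriptor blocks (no
# chemistry engine involved)
fake_feature_set <- function(n_kin = 4, n_cmp = 6, n_rec = 60, seed = 2,
                             variant = "1-1", signal = TRUE) {
  set.seed(seed)
  cat_ <- tiny_catalog(n_kin, width = 40)
  blocks <- list(PCPP = matrix(stats::rnorm(n_cmp * 10), n_cmp),
                 MCFP = matrix(stats::rbinom(n_cmp * 8, 1, 0.4), n_cmp),
                 MGFP = matrix(stats::rbinom(n_cmp * 12, 1, 0.3), n_cmp))
  if (variant %in% c("1-2", "2-2", "3-2")) {
    blocks$CED3 <- matrix(abs(stats::rnorm(n_cmp * 9)), n_cmp)
  }
  cmp_ids <- sprintf("CMP%02d", seq_len(n_cmp))
  blocks <- lapply(blocks, function(m) { rownames(m) <- cmp_ids; m })
  ki <- sample(n_kin, n_rec, replace = TRUE)
  ci <- sample(n_cmp, n_rec, replace = TRUE)
  y <- if (signal) {
    0.6 * blocks$PCPP[ci, 1] - 0.4 * blocks$PCPP[ci, 2] +
      0.5 * (ki %% 2) + stats::rnorm(n_rec, sd = 0.05)
  } else {
    stats::rnorm(n_rec)
  }
  records <- data.frame(kinase_id = cat_$entries$kinase_id[ki],
                        compound_smiles = cmp_ids[ci],
                        bioactivity = y, stringsAsFactors = FALSE)
  sm <- active_site_map(seq_len(29))
  build_feature_set(records, cat_, variant, blocks, site_map = sm,
                    kernels = c(3L, 5L))
}
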