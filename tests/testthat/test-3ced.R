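# Conformer-ensemble pharmacophore signature descriptor.

sp_default <- build_signature_space()

test_that("signature space dimension follows the enumeration law", {
  # derived oracle: independent combinatorial count
  # 2-point: C(f+1, 2) family multisets x B bins
  # 3-point: C(f+2, 3) family multisets x B^3 ordered bin triples
  size_law <- function(f, B) {
    B * choose(f + 1, 2) + B^3 * choose(f + 2, 3)
  }
  two <- build_signature_space(families = c("Donor", "Acceptor"),
                               point_counts = 2L)
  expect_equal(two$dimension, 9)          # 3 family pairs x 3 bins
  one_bin <- build_signature_space(families = c("Donor", "Acceptor"),
                                   bins = list(c(0, 9)),
                                   point_counts = 2L)
  expect_equal(one_bin$dimension, 3)
  for (f in c(2, 4, 8)) {
    sp <- build_signature_space(families = paste0("F", seq_len(f)))
    expect_equal(sp$dimension, size_law(f, 3))
    expect_equal(nrow(sp$table), sp$dimension)
  }
  expect_error(build_signature_space(families = character(0)))
  expect_error(build_signature_space(bins = list(c(0, 3), c(2, 6))),
               "non-overlapping")
})

test_that("the default space has dimension 3348 over bins 0-3/3-6/6-9 A", {
  expect_length(sp_default$families, 8)
  expect_equal(sp_default$bins, list(c(0, 3), c(3, 6), c(6, 9)))
  expect_equal(sp_default$dimension, 3348)
})

test_that("hand-built site geometries count into the expected slots", {
  # one donor and one acceptor 4.2 A apart: a single 2-point signature
  # in the [3, 6) bin
  sites <- data.frame(family = c("Donor", "Acceptor"),
                      x = c(0, 4.2), y = 0, z = 0)
  v <- conformer_signature(sites, sp_default)
  expect_equal(sum(v), 1)
  hit <- which(v == 1)
  row <- sp_default$table[hit, ]
  expect_equal(row$points, 2L)
  expect_equal(sort(sp_default$families[c(row$f1, row$f2)]),
               sort(c("Donor", "Acceptor")))
  expect_equal(row$b12, 2L)
  # no perceived features: zero vector
  empty <- data.frame(family = character(0), x = numeric(0),
                      y = numeric(0), z = numeric(0))
  expect_equal(sum(conformer_signature(empty, sp_default)), 0)
  # pairs at >= 9 A contribute nothing
  far <- data.frame(family = c("Donor", "Acceptor"), x = c(0, 9.5),
                    y = 0, z = 0)
  expect_equal(sum(conformer_signature(far, sp_default)), 0)
  # a triangle of three sites lands in exactly one 3-point slot (plus
  # its three 2-point slots)
  tri <- data.frame(family = c("Donor", "Acceptor", "Aromatic"),
                    x = c(0, 4, 0), y = c(0, 0, 7), z = 0)
  vt <- conformer_signature(tri, sp_default)
  expect_equal(sum(vt[sp_default$table$points == 2]), 3)
  expect_equal(sum(vt[sp_default$table$points == 3]), 1)
})

test_that("signatures match the brute-force enumeration oracle", {
  # random synthetic site sets
  set.seed(21)
  fams <- sp_default$families
  for (rep_ in 1:5) {
    n <- sample(3:7, 1)
    sites <- data.frame(family = sample(fams, n, replace = TRUE),
                        x = runif(n, 0, 8), y = runif(n, 0, 8),
                        z = runif(n, 0, 8))
    expect_equal(conformer_signature(sites, sp_default),
                 as.integer(brute_force_signature(sites, sp_default)))
  }
  # and perceived sites of real small-molecule conformers
  ens <- generate_conformers(unname(FIX_MOLS[c("ethanol", "benzamide")]),
                             max_n = 4, seed = 3)
  for (e in ens) {
    sites <- e$conformers[[1]]$sites
    expect_equal(conformer_signature(sites, sp_default),
                 as.integer(brute_force_signature(sites, sp_default)))
  }
})

test_that("signatures are invariant under rigid motion", {
  ens <- generate_conformers(unname(FIX_MOLS[["benzamide"]]), max_n = 4,
                             seed = 5)[[1]]
  sites <- ens$conformers[[1]]$sites
  v0 <- conformer_signature(sites, sp_default)
  expect_gt(sum(v0), 0)
  for (s in 1:3) {
    expect_equal(conformer_signature(rigid_transform(sites, seed = s),
                                     sp_default), v0)
  }
})

test_that("conformer ensembles respect the cap and the seed", {
  ens <- generate_conformers(c("C", unname(FIX_MOLS[["flexible"]])),
                             max_n = 16, seed = 7)
  expect_equal(length(ens[[1]]$conformers), 1)      # methane is rigid
  n_flex <- length(ens[[2]]$conformers)
  expect_gte(n_flex, 2)
  expect_lte(n_flex, 16)
  # determinism: identical coordinates across two runs with one seed
  again <- generate_conformers(unname(FIX_MOLS[["flexible"]]), max_n = 16,
                               seed = 7)[[1]]
  expect_equal(again$conformers[[1]]$coords, ens[[2]]$conformers[[1]]$coords)
  expect_equal(length(again$conformers), n_flex)
  # a smaller cap binds
  capped <- generate_conformers(unname(FIX_MOLS[["flexible"]]), max_n = 2,
                                seed = 7)[[1]]
  expect_lte(length(capped$conformers), 2)
})

test_that("3CED is the conformer mean and inherits its invariances", {
  ens <- generate_conformers(unname(FIX_MOLS[["flexible"]]), max_n = 8,
                             seed = 2)[[1]]
  v <- compute_3ced(ens, sp_default)
  expect_length(v, 3348)
  expect_true(all(v >= 0))
  sigs <- sapply(ens$conformers, conformer_signature, space = sp_default)
  expect_equal(v, rowMeans(sigs))
  # element-wise between per-conformer min and max
  expect_true(all(v >= apply(sigs, 1, min) - 1e-12))
  expect_true(all(v <= apply(sigs, 1, max) + 1e-12))
  # conformer order permutation leaves the mean unchanged
  perm <- ens
  set.seed(4)
  perm$conformers <- perm$conformers[sample(length(perm$conformers))]
  expect_equal(compute_3ced(perm, sp_default), v)
  # single conformer: identity; duplicated conformer: idempotent mean
  single <- ens; single$conformers <- ens$conformers[1]
  expect_equal(compute_3ced(single, sp_default),
               as.numeric(conformer_signature(ens$conformers[[1]],
                                              sp_default)))
  dup <- ens; dup$conformers <- ens$conformers[c(1, 1)]
  expect_equal(compute_3ced(dup, sp_default),
               compute_3ced(single, sp_default))
  # hand-crafted two-conformer mean: unit counts on different slots
  s1 <- data.frame(family = c("Donor", "Acceptor"), x = c(0, 1),
                   y = 0, z = 0)
  s2 <- data.frame(family = c("Donor", "Acceptor"), x = c(0, 4),
                   y = 0, z = 0)
  fake <- structure(list(smiles = "synthetic", canonical = "synthetic",
                         seed = 0L, max_n = 2L,
                         conformers = list(list(sites = s1),
                                           list(sites = s2))),
                    class = "conformer_ensemble")
  vf <- compute_3ced(fake, sp_default)
  expect_equal(sort(vf[vf > 0]), c(0.5, 0.5))
  empty <- fake; empty$conformers <- list()
  expect_error(compute_3ced(empty, sp_default), "empty")
})
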