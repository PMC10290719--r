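# Desk-scale synthetic study generator: an aligned kinase catalog with
# group structure, a drug-like compound library sample, and bioactivities
# with planted group selectivity plus a learnable compound term and
# Gaussian noise on the log10(nM) scale.  Every other module is testable
# on its output without any external download.

#' Simulation configuration
#'
#' Defaults define the package's standard desk-scale study: 24 kinases
#' in 4 groups at alignment width 200, 210 compounds (~5000 records),
#' 30% of compounds planted as group-selective with a 2 log-unit potency
#' gain on their group, residual noise 0.3 log units around a 10 uM
#' baseline.
#'
#' @param n_kinases Number of kinases.
#' @param alignment_width Alignment columns (>= 29, to support an
#'   active-site map).
#' @param n_groups Number of kinase groups (<= n_kinases).
#' @param n_compounds Number of compounds drawn from the library.
#' @param selective_fraction Fraction of compounds given a planted group
#'   selectivity.
#' @param effect_size Potency gain (log10 units) of a selective compound
#'   on its assigned group.
#' @param noise_sd Gaussian noise standard deviation (log10 units).
#' @param baseline Baseline bioactivity (log10 nM; 4.0 = 10 uM).
#' @param seed Master seed; every stage derives its randomness from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_kinases = 24L, alignment_width = 200L,
                       n_groups = 4L, n_compounds = 210L,
                       selective_fraction = 0.3, effect_size = 2.0,
                       noise_sd = 0.3, baseline = 4.0, seed = 1L) {
  stopifnot(n_groups <= n_kinases, noise_sd >= 0, alignment_width >= 29L,
            selective_fraction >= 0, selective_fraction <= 1)
  structure(list(n_kinases = as.integer(n_kinases),
                 alignment_width = as.integer(alignment_width),
                 n_groups = as.integer(n_groups),
                 n_compounds = as.integer(n_compounds),
                 selective_fraction = selective_fraction,
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline = baseline, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a group-structured kinase catalog
#'
#' Each group descends from a common root sequence: group consensus
#' sequences diverge from the root by random substitutions, members
#' diverge mildly from their consensus, and each group carries a private
#' set of gap columns so that alignment structure is informative about
#' group membership.  A 29-column active-site map is built from the most
#' group-discriminative columns.
#'
#' @param config A `sim_config`.
#' @return List with `catalog` (a `kinase_catalog`) and `site_map` (an
#'   `active_site_map` of 29 columns).
#' @export
simulate_catalog <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  aa <- aa_channels()[1:20]
  W <- config$alignment_width
  G <- config$n_groups
  root <- sample(aa, W, replace = TRUE)
  consensus <- lapply(seq_len(G), function(g) {
    s <- root
    mut <- stats::runif(W) < 0.3
    s[mut] <- sample(aa, sum(mut), replace = TRUE)
    s
  })
  gap_cols <- lapply(seq_len(G), function(g) sample.int(W, 5L))
  group_of <- rep(seq_len(G), length.out = config$n_kinases)
  seqs <- character(config$n_kinases)
  for (i in seq_len(config$n_kinases)) {
    g <- group_of[i]
    s <- consensus[[g]]
    mut <- stats::runif(W) < 0.05
    s[mut] <- sample(aa, sum(mut), replace = TRUE)
    s[gap_cols[[g]]] <- "-"
    seqs[i] <- paste(s, collapse = "")
  }
  ids <- sprintf("KIN%03d", seq_len(config$n_kinases))
  groups <- stats::setNames(sprintf("G%d", group_of), ids)
  catalog <- kinase_catalog(ids, seqs, groups)
  # active site: columns where the group consensus sequences (with their
  # gap columns applied) disagree the most
  cons_mat <- do.call(rbind, lapply(seq_len(G), function(g) {
    s <- consensus[[g]]
    s[gap_cols[[g]]] <- "-"
    s
  }))
  divers <- apply(cons_mat, 2, function(col) length(unique(col)))
  site_cols <- sort(order(-divers, seq_len(W))[1:29])
  list(catalog = catalog,
       site_map = active_site_map(site_cols, alignment_width = W))
}

#' Sample compounds from the shipped library
#'
#' Draws a seeded sample without replacement from the committed library
#' of valid, diverse drug-like SMILES.
#'
#' @param n Number of compounds (<= library size).
#' @param seed Sampling seed.
#' @param library_path Optional alternative SMILES file (one per line).
#' @return Character vector of n distinct SMILES.
#' @export
sample_compounds <- function(n, seed = 1L, library_path = NULL) {
  if (is.null(library_path)) {
    library_path <- system.file("extdata", "compound_library.smi",
                                package = "kinprof", mustWork = TRUE)
  }
  lib <- readLines(library_path)
  lib <- lib[nzchar(lib) & !startsWith(lib, "#")]
  if (n > length(lib)) {
    stop("requested ", n, " compounds but the library holds ", length(lib))
  }
  set.seed(seed)
  sort(sample(lib, n))
}

# fixed sparse linear compound effect over named physicochemical
# descriptors; reference location/scale are typical drug-like values so
# the term is roughly centred with spread ~1 log unit on the library
SIM_COMPOUND_EFFECT <- list(
  MolLogP = list(w = 1.1, center = 3.0, scale = 1.5),
  TPSA = list(w = 0.7, center = 60, scale = 25),
  NumRotatableBonds = list(w = -0.55, center = 5, scale = 2.5))

.compound_effect <- function(pcpp) {
  f <- numeric(nrow(pcpp))
  for (nm in names(SIM_COMPOUND_EFFECT)) {
    cf <- SIM_COMPOUND_EFFECT[[nm]]
    f <- f + cf$w * (pcpp[, nm] - cf$center) / cf$scale
  }
  f
}

#' Simulate bioactivity records with planted selectivity
#'
#' For every (kinase, compound) pair,
#' `bioactivity = baseline + group_effect + f(compound) + noise`, where a
#' selective compound gets `group_effect = -effect_size` on its assigned
#' group (round-robin over groups) and 0 elsewhere, `f` is a fixed sparse
#' linear function of named physicochemical descriptors (so models have
#' learnable compound signal), and the noise is Gaussian with
#' `noise_sd`.  Records are emitted as IC50 measurements in nM.
#'
#' @param catalog A `kinase_catalog` (e.g. from [simulate_catalog()]).
#' @param compounds Character vector of SMILES.
#' @param config A `sim_config`.
#' @return Activity records data.frame with attribute `truth`: a
#'   data.frame (compound, selective, group) describing the planted
#'   signal.
#' @export
simulate_bioactivity <- function(catalog, compounds,
                                 config = sim_config()) {
  stopifnot(inherits(catalog, "kinase_catalog"), length(compounds) >= 1L)
  can <- canonicalize(compounds)
  f <- .compound_effect(compute_pcpp(can))
  nC <- length(can)
  n_sel <- round(config$selective_fraction * nC)
  groups <- sort(unique(catalog$entries$group))
  truth <- data.frame(
    compound = can,
    selective = seq_len(nC) <= n_sel,
    group = NA_character_,
    stringsAsFactors = FALSE)
  if (n_sel > 0) {
    truth$group[seq_len(n_sel)] <-
      groups[(seq_len(n_sel) - 1L) %% length(groups) + 1L]
  }
  set.seed(config$seed + 1L)
  kin <- catalog$entries
  grid <- expand.grid(k = seq_len(nrow(kin)), c = seq_len(nC))
  ge <- ifelse(!is.na(truth$group[grid$c]) &
                 kin$group[grid$k] == truth$group[grid$c],
               -config$effect_size, 0)
  bio <- config$baseline + ge + f[grid$c] +
    stats::rnorm(nrow(grid), sd = config$noise_sd)
  records <- data.frame(
    kinase_id = kin$kinase_id[grid$k],
    compound_smiles = can[grid$c],
    measurement_type = "IC50",
    value_nM = from_bioactivity(bio),
    bioactivity = bio,
    source = "synthetic",
    stringsAsFactors = FALSE)
  attr(records, "truth") <- truth
  records
}

#' Simulate a complete desk-scale study
#'
#' Catalog + active-site map + compound sample + activity records in one
#' call, fully determined by the config seed.
#'
#' @param config A `sim_config`.
#' @return List with `catalog`, `site_map`, `compounds`, `records`,
#'   `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  cat_sim <- simulate_catalog(config)
  compounds <- sample_compounds(config$n_compounds, seed = config$seed)
  records <- simulate_bioactivity(cat_sim$catalog, compounds, config)
  list(catalog = cat_sim$catalog, site_map = cat_sim$site_map,
       compounds = compounds, records = records,
       truth = attr(records, "truth"), config = config)
}

#' Write a simulated study to disk
#'
#' Emits the aligned FASTA, group map TSV, active-site YAML and activity
#' TSV in the formats the curation and encoding readers consume.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aln <- Biostrings::AAStringSet(
    stats::setNames(sim$catalog$entries$aligned_seq,
                    sim$catalog$entries$kinase_id))
  Biostrings::writeXStringSet(aln, file.path(dir, "alignment.fasta"))
  utils::write.table(sim$catalog$entries[, c("kinase_id", "group")],
                     file.path(dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_active_site_map(sim$site_map, file.path(dir, "active_site.yaml"))
  utils::write.table(
    data.frame(kinase = sim$records$kinase_id,
               smiles = sim$records$compound_smiles,
               type = sim$records$measurement_type,
               value = sim$records$value_nM,
               unit = "nM"),
    file.path(dir, "activity.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
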