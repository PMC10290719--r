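# 3D conformer-ensemble pharmacophore signature descriptor (3CED).
#
# A molecule is embedded as up to 16 distance-geometry conformers.  For
# each conformer, pharmacophore feature sites (donor, acceptor, ionizable
# centres, aromatic rings, hydrophobes, ...) are perceived from SMARTS
# definitions, and every 2- and 3-point combination of sites is counted
# into a signature slot indexed by (feature-family multiset, distance-bin
# assignment) with bins 0-3, 3-6 and 6-9 Angstrom.  The 3CED vector is the
# element-wise mean of the per-conformer count vectors.

DEFAULT_3CED_BINS <- list(c(0, 3), c(3, 6), c(6, 9))

#' Pharmacophore family definitions
#'
#' Reads the shipped minimal pharmacophore definition table (family,
#' SMARTS).  The default set defines eight families: Donor, Acceptor,
#' PosIonizable, NegIonizable, ZnBinder, Aromatic, Hydrophobe and
#' LumpedHydrophobe.  Matches of each SMARTS are feature sites; a site's
#' position is the centroid of its matched heavy atoms.
#'
#' @param path Definition table; defaults to the shipped file.
#' @return `data.frame` with columns `family`, `smarts`.
#' @export
pharmacophore_families <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pharmacophore_families.tsv",
                        package = "kinprof", mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("family", "smarts") %in% names(df)))
  df
}

#' Enumerate the pharmacophore signature space
#'
#' Builds the index space of all (family multiset, distance-bin
#' assignment) combinations for 2- and 3-point signatures.  A 2-point
#' signature is an unordered family pair with one bin for its distance.
#' A 3-point signature is a family multiset `f1 <= f2 <= f3` together
#' with an ordered bin triple `(b12, b13, b23)` read off the sites in
#' family-sorted order; all `B^3` triples are distinct slots.  With the
#' default 8 families and 3 bins the dimension is
#' `3*C(9,2) + 27*C(10,3) = 108 + 3240 = 3348`.
#'
#' @param families Character vector of family names (order fixes index
#'   order); defaults to the families of [pharmacophore_families()].
#' @param bins List of `c(lo, hi)` half-open distance intervals in
#'   Angstrom, ordered and non-overlapping.
#' @param point_counts Integer subset of `c(2, 3)`.
#' @return Object of class `signature_space` with fields `families`,
#'   `bins`, `point_counts`, `dimension` and a `table` describing every
#'   slot.
#' @export
#' @examples
#' \dontrun{build_signature_space()$dimension  # 3348}
build_signature_space <- function(families = NULL,
                                  bins = DEFAULT_3CED_BINS,
                                  point_counts = c(2L, 3L)) {
  if (is.null(families)) families <- unique(pharmacophore_families()$family)
  stopifnot(length(families) >= 2L, !anyDuplicated(families))
  stopifnot(all(point_counts %in% c(2L, 3L)), length(point_counts) >= 1L)
  bins <- lapply(bins, as.numeric)
  if (!length(bins)) stop("at least one distance bin is required")
  lo <- vapply(bins, `[`, numeric(1), 1)
  hi <- vapply(bins, `[`, numeric(1), 2)
  if (any(hi <= lo) || is.unsorted(lo) || any(lo[-1] < hi[-length(hi)])) {
    stop("bins must be ordered, non-overlapping intervals")
  }
  f <- length(families)
  B <- length(bins)
  rows <- list()
  if (2L %in% point_counts) {
    for (i in seq_len(f)) for (j in i:f) for (b in seq_len(B)) {
      rows[[length(rows) + 1L]] <-
        data.frame(points = 2L, f1 = i, f2 = j, f3 = NA_integer_,
                   b12 = b, b13 = NA_integer_, b23 = NA_integer_)
    }
  }
  if (3L %in% point_counts) {
    for (i in seq_len(f)) for (j in i:f) for (k in j:f) {
      for (b12 in seq_len(B)) for (b13 in seq_len(B)) for (b23 in seq_len(B)) {
        rows[[length(rows) + 1L]] <-
          data.frame(points = 3L, f1 = i, f2 = j, f3 = k,
                     b12 = b12, b13 = b13, b23 = b23)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$index <- seq_len(nrow(tab))
  # O(1) slot lookup by composite key
  key <- .sig_key(tab)
  lookup <- new.env(parent = emptyenv(), size = nrow(tab))
  for (r in seq_len(nrow(tab))) assign(key[r], tab$index[r], envir = lookup)
  out <- list(families = families, bins = bins, point_counts = point_counts,
              dimension = nrow(tab), table = tab, lookup = lookup)
  class(out) <- "signature_space"
  out
}

.sig_key <- function(tab) {
  ifelse(tab$points == 2L,
         paste("P2", tab$f1, tab$f2, tab$b12, sep = "."),
         paste("P3", tab$f1, tab$f2, tab$f3,
               tab$b12, tab$b13, tab$b23, sep = "."))
}

#' @export
print.signature_space <- function(x, ...) {
  cat("pharmacophore signature space\n")
  cat("  families:", paste(x$families, collapse = ", "), "\n")
  cat("  bins (A):", paste(vapply(x$bins, function(b)
    sprintf("[%g,%g)", b[1], b[2]), character(1)), collapse = " "), "\n")
  cat("  points:", paste(x$point_counts, collapse = ","),
      "  dimension:", x$dimension, "\n")
  invisible(x)
}

.bin_of <- function(d, bins) {
  for (b in seq_along(bins)) {
    if (d >= bins[[b]][1] && d < bins[[b]][2]) return(b)
  }
  NA_integer_
}

#' Generate a seeded conformer ensemble
#'
#' Embeds up to `max_n` conformers per molecule by distance geometry
#' (ETKDG) with heavy-atom RMSD pruning, and perceives pharmacophore
#' feature sites on every conformer.  Deterministic for a fixed
#' (molecule, seed) pair; rigid molecules yield fewer conformers after
#' pruning.
#'
#' @param smiles Character vector of SMILES.
#' @param max_n Maximum conformers per molecule (default 16).
#' @param seed Integer seed for the embedding.
#' @param prune_rms Heavy-atom RMSD pruning threshold in Angstrom.
#' @param families Pharmacophore definition table
#'   ([pharmacophore_families()] format).
#' @return List of `conformer_ensemble` objects, one per molecule; each
#'   holds `canonical`, `seed` and `conformers`, a list of
#'   `list(coords, sites)` with `coords` an n_atoms x 3 matrix and
#'   `sites` a data.frame (family, x, y, z).
#' @export
generate_conformers <- function(smiles, max_n = 16L, seed = 1L,
                                prune_rms = 0.5,
                                families = pharmacophore_families()) {
  stopifnot(is.character(smiles), max_n >= 1L)
  fam_payload <- lapply(seq_len(nrow(families)), function(i) {
    list(family = families$family[i], smarts = families$smarts[i])
  })
  res <- chem_bridge("conformers",
                     list(smiles = smiles, max_n = max_n, seed = seed,
                          prune_rms = prune_rms, families = fam_payload))
  lapply(res$molecules, function(m) {
    if (!is.null(m$error)) {
      stop("conformer generation failed for '", m$input, "': ", m$error)
    }
    confs <- lapply(m$conformers, function(cf) {
      coords <- do.call(rbind, lapply(cf$coords, unlist))
      sites <- if (length(cf$sites)) {
        data.frame(
          family = vapply(cf$sites, `[[`, character(1), "family"),
          x = vapply(cf$sites, function(s) s$center[[1]], numeric(1)),
          y = vapply(cf$sites, function(s) s$center[[2]], numeric(1)),
          z = vapply(cf$sites, function(s) s$center[[3]], numeric(1)),
          stringsAsFactors = FALSE)
      } else {
        data.frame(family = character(0), x = numeric(0), y = numeric(0),
                   z = numeric(0))
      }
      list(coords = coords, sites = sites)
    })
    out <- list(smiles = m$input, canonical = m$canonical, seed = seed,
                max_n = max_n, conformers = confs)
    class(out) <- "conformer_ensemble"
    out
  })
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("conformer ensemble:", x$canonical, "\n")
  cat(" ", length(x$conformers), "conformer(s), seed", x$seed, "\n")
  invisible(x)
}

#' Count the pharmacophore signature of one conformer
#'
#' For every pair and triple of perceived feature sites whose pairwise
#' distances all fall inside the bin ranges, increments the canonical
#' signature slot.  Distances are Euclidean between site centroids in
#' Angstrom.  For triples, sites are ordered by family index; when tied
#' families admit several orderings, the lexicographically smallest bin
#' triple is the canonical one.
#'
#' @param sites Either a `list(coords, sites)` element of a
#'   `conformer_ensemble`, or a data.frame with columns family, x, y, z.
#' @param space A `signature_space`.
#' @return Non-negative integer count vector of length `space$dimension`.
#' @export
conformer_signature <- function(sites, space) {
  stopifnot(inherits(space, "signature_space"))
  if (is.list(sites) && !is.data.frame(sites) && !is.null(sites$sites)) {
    sites <- sites$sites
  }
  v <- integer(space$dimension)
  n <- nrow(sites)
  if (n < 2L) return(v)
  fam_idx <- match(sites$family, space$families)
  if (anyNA(fam_idx)) {
    stop("site family not in signature space: ",
         paste(unique(sites$family[is.na(fam_idx)]), collapse = ", "))
  }
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  D <- as.matrix(stats::dist(xyz))
  bmat <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) bmat[i, j] <- .bin_of(D[i, j], space$bins)
  }
  if (2L %in% space$point_counts) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      b <- bmat[i, j]
      if (is.na(b)) next
      fp <- sort(c(fam_idx[i], fam_idx[j]))
      k <- get0(paste("P2", fp[1], fp[2], b, sep = "."),
                envir = space$lookup)
      v[k] <- v[k] + 1L
    }
  }
  if (3L %in% space$point_counts && n >= 3L) {
    for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) {
      for (k in (j + 1L):n) {
        trip <- c(i, j, k)
        if (anyNA(c(bmat[i, j], bmat[i, k], bmat[j, k]))) next
        idx <- .canonical_triple(trip, fam_idx, bmat)
        slot <- get0(idx, envir = space$lookup)
        v[slot] <- v[slot] + 1L
      }
    }
  }
  v
}

# canonical slot key for a site triple: among orderings of the sites with
# non-decreasing family index, take the lexicographically smallest
# (b12, b13, b23)
.canonical_triple <- function(trip, fam_idx, bmat) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best <- NULL
  fams <- fam_idx[trip]
  for (p in perms) {
    f <- fams[p]
    if (f[1] > f[2] || f[2] > f[3]) next
    s <- trip[p]
    b <- c(bmat[s[1], s[2]], bmat[s[1], s[3]], bmat[s[2], s[3]])
    if (is.null(best) || b[1] < best$b[1] ||
        (b[1] == best$b[1] && (b[2] < best$b[2] ||
         (b[2] == best$b[2] && b[3] < best$b[3])))) {
      best <- list(f = f, b = b)
    }
  }
  paste("P3", best$f[1], best$f[2], best$f[3],
        best$b[1], best$b[2], best$b[3], sep = ".")
}

#' Conformer-ensemble descriptor (3CED)
#'
#' Element-wise arithmetic mean of the per-conformer signature count
#' vectors of an ensemble.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param space A `signature_space`.
#' @return Numeric vector of length `space$dimension` (all entries >= 0).
#' @export
compute_3ced <- function(ensemble, space) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (!length(ensemble$conformers)) stop("empty conformer ensemble")
  sigs <- vapply(ensemble$conformers, conformer_signature,
                 numeric(space$dimension), space = space)
  if (space$dimension == 1L) sigs <- matrix(sigs, nrow = 1L)
  rowMeans(sigs)
}

#' Batch 3CED featurization
#'
#' Convenience wrapper: embeds conformer ensembles for a SMILES vector
#' and returns the 3CED matrix.
#'
#' @inheritParams generate_conformers
#' @param space A `signature_space`; defaults to the standard space.
#' @return Numeric matrix, one row per molecule, `space$dimension` columns.
#' @export
featurize_3ced <- function(smiles, space = NULL, max_n = 16L, seed = 1L) {
  if (is.null(space)) space <- build_signature_space()
  spkey <- paste(paste(space$families, collapse = ","),
                 paste(unlist(space$bins), collapse = ","),
                 paste(space$point_counts, collapse = ","), sep = "|")
  keys <- paste0("ced::", spkey, "::", seed, "::", max_n, "::", smiles)
  miss <- vapply(keys, function(k) is.null(.cache_get(k)), logical(1))
  if (any(miss)) {
    ens <- generate_conformers(unique(smiles[miss]), max_n = max_n,
                               seed = seed)
    for (e in ens) {
      .cache_set(paste0("ced::", spkey, "::", seed, "::", max_n, "::",
                        e$smiles),
                 compute_3ced(e, space))
    }
  }
  out <- do.call(rbind, lapply(keys, .cache_get))
  rownames(out) <- smiles
  colnames(out) <- paste0("CED", seq_len(space$dimension))
  out
}
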