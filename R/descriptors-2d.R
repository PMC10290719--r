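# 2D molecular descriptor blocks: physicochemical properties (PCPP, 208),
# structural keys (MCFP, 167) and multi-radius circular fingerprints
# (MGFP, 256 + 512 + 1024 = 1792 bits at bond radii 2, 3, 4).

MGFP_RADII <- c(2L, 3L, 4L)
MGFP_WIDTHS <- c(`2` = 256L, `3` = 512L, `4` = 1024L)

#' The pinned physicochemical descriptor registry
#'
#' Exactly 208 named descriptors, shipped as a plain-text registry so the
#' PCPP block is reproducible across toolkit releases (descriptor sets
#' drift over time; the registry pins membership and order).
#'
#' @return Character vector of 208 descriptor names.
#' @export
#' @examples
#' length(pcpp_registry())
pcpp_registry <- function() {
  path <- system.file("extdata", "pcpp_registry.txt", package = "kinprof",
                      mustWork = TRUE)
  x <- readLines(path)
  x <- x[!startsWith(x, "#") & nzchar(x)]
  if (length(x) != 208L) {
    stop("corrupt PCPP registry: expected 208 descriptors, found ", length(x))
  }
  if (anyDuplicated(x)) stop("corrupt PCPP registry: duplicated names")
  x
}

#' Canonicalize SMILES strings
#'
#' Produces isomeric canonical SMILES.  Canonicalisation is idempotent and
#' stereochemistry is preserved, so equivalent notations map to one form
#' while E/Z and R/S isomers stay distinct.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length and order.
#' @export
#' @examples
#' \dontrun{canonicalize("OCC") == canonicalize("CCO")}
canonicalize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  res <- chem_bridge("canonicalize", list(smiles = smiles))
  out <- vapply(res$molecules, function(m) {
    if (!is.null(m$error)) NA_character_ else m$canonical
  }, character(1))
  if (anyNA(out)) {
    bad <- smiles[is.na(out)]
    stop("unparseable SMILES: ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  }
  out
}

# One engine round-trip for all three 2D blocks, memoised per molecule.
.features_2d <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  keys <- paste0("f2d::", smiles)
  miss <- !vapply(keys, function(k) !is.null(.cache_get(k)), logical(1))
  if (any(miss)) {
    reg <- pcpp_registry()
    res <- chem_bridge("descriptors_2d",
                       list(smiles = unique(smiles[miss]), registry = reg))
    for (m in res$molecules) {
      if (!is.null(m$error)) {
        stop("cannot featurize '", m$input, "': ", m$error)
      }
      nonfinite <- unlist(m$nonfinite)
      if (length(nonfinite)) {
        warning("non-finite descriptors set to 0 for '", m$input, "': ",
                paste(nonfinite, collapse = ", "), call. = FALSE)
      }
      .cache_set(paste0("f2d::", m$input), list(
        canonical = m$canonical,
        pcpp = stats::setNames(as.numeric(unlist(m$pcpp)), reg),
        mcfp = as.integer(unlist(m$maccs)),
        mgfp = as.integer(unlist(m$morgan))))
    }
  }
  lapply(keys, .cache_get)
}

#' Physicochemical property block (PCPP)
#'
#' Evaluates the 208 registry descriptors (topological and topochemical
#' indices, Crippen LogP and molar refractivity, Lipinski counts, ...).
#' Descriptors that fail or return non-finite values are recorded as 0
#' with a warning, so downstream models never see NaN.
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric matrix, one row per molecule, 208 named columns.
#' @export
compute_pcpp <- function(smiles) {
  feats <- .features_2d(smiles)
  out <- do.call(rbind, lapply(feats, `[[`, "pcpp"))
  rownames(out) <- smiles
  out
}

#' Structural key fingerprint block (MCFP)
#'
#' Standard 167-key MACCS structural fingerprint.
#'
#' @param smiles Character vector of SMILES.
#' @return Integer 0/1 matrix, one row per molecule, 167 columns.
#' @export
compute_mcfp <- function(smiles) {
  feats <- .features_2d(smiles)
  out <- do.call(rbind, lapply(feats, `[[`, "mcfp"))
  rownames(out) <- smiles
  colnames(out) <- paste0("MCFP", seq_len(ncol(out)))
  out
}

#' Multi-radius circular fingerprint block (MGFP)
#'
#' Morgan fingerprints at bond radii 2, 3 and 4, hashed to 256, 512 and
#' 1024 bits respectively and concatenated in radius order into a single
#' 1792-bit vector.
#'
#' @param smiles Character vector of SMILES.
#' @return Integer 0/1 matrix with 1792 columns; attribute `radii` gives
#'   the per-radius sub-block widths.
#' @export
compute_mgfp <- function(smiles) {
  feats <- .features_2d(smiles)
  out <- do.call(rbind, lapply(feats, `[[`, "mgfp"))
  rownames(out) <- smiles
  colnames(out) <- unlist(lapply(MGFP_RADII, function(r) {
    paste0("MGFP.r", r, ".", seq_len(MGFP_WIDTHS[[as.character(r)]]))
  }))
  attr(out, "radii") <- MGFP_WIDTHS
  out
}

#' Assemble the full 2D descriptor block set
#'
#' Blocks are ordered PCPP (208), MCFP (167), MGFP (1792); total length
#' 2167 features per molecule.
#'
#' @param smiles Character vector of SMILES.
#' @return Object of class `descriptor_set`: a list with elements
#'   `blocks` (named list of matrices), `canonical` (canonical SMILES),
#'   `block_lengths` and `total_length`.
#' @export
feature_block_2d <- function(smiles) {
  feats <- .features_2d(smiles)
  blocks <- list(PCPP = compute_pcpp(smiles),
                 MCFP = compute_mcfp(smiles),
                 MGFP = compute_mgfp(smiles))
  out <- list(blocks = blocks,
              canonical = vapply(feats, `[[`, character(1), "canonical"),
              block_lengths = vapply(blocks, ncol, integer(1)),
              total_length = sum(vapply(blocks, ncol, integer(1))))
  class(out) <- "descriptor_set"
  out
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat("2D descriptor set:", nrow(x$blocks[[1]]), "molecules\n")
  cat("  blocks:", paste(sprintf("%s(%d)", names(x$block_lengths),
                                 x$block_lengths), collapse = " "),
      "  total", x$total_length, "\n")
  invisible(x)
}

#' @export
as.matrix.descriptor_set <- function(x, ...) {
  do.call(cbind, x$blocks)
}
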