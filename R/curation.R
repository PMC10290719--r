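# Activity-data curation: parsing heterogeneous bioactivity exports,
# filtering to experimental IC50/Ki values, unit normalisation to nM,
# log10 transformation, per-pair deduplication and strict splits.
#
# Bioactivity throughout the package is log10 of the measurement in nM;
# the anchor is 3.0 <-> 1 uM.  Lower values mean more potent compounds.

UNIT_FACTORS_NM <- c(nm = 1, um = 1e3, mm = 1e6, m = 1e9)

.normalize_unit <- function(unit) {
  u <- tolower(trimws(unit))
  u <- gsub("µ|μ", "u", u)   # micro sign / Greek mu
  ifelse(u %in% names(UNIT_FACTORS_NM), u, NA_character_)
}

#' Convert a potency measurement to bioactivity
#'
#' Bioactivity is log10 of the value expressed in nM, so 1 uM maps to
#' exactly 3.0 and 1 nM to 0.
#'
#' @param value Positive measurement value(s).
#' @param unit Unit string(s): nM, uM (or the micro sign), mM, M;
#'   case-insensitive.
#' @return Numeric bioactivity on the log10(nM) scale.
#' @export
#' @examples
#' to_bioactivity(1, "uM")   # 3
#' to_bioactivity(50, "nM")  # log10(50)
to_bioactivity <- function(value, unit) {
  value <- as.numeric(value)
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("potency values must be positive and finite")
  }
  u <- .normalize_unit(unit)
  if (anyNA(u)) {
    stop("unrecognised unit token(s): ",
         paste(unique(unit[is.na(u)]), collapse = ", "))
  }
  unname(log10(value * UNIT_FACTORS_NM[u]))
}

#' Inverse of [to_bioactivity()]
#'
#' @param bioactivity Numeric bioactivity (log10 nM).
#' @return Value in nM.
#' @export
from_bioactivity <- function(bioactivity) 10^bioactivity

#' Parse a kinase-ligand activity table
#'
#' Reads a delimited export (BindingDB/DTC style), keeps rows that carry a
#' kinase identifier, a SMILES, an experimental IC50 or Ki measurement and
#' a parseable unit, converts values to nM and attaches the bioactivity.
#' Every dropped row is logged with a reason so that
#' `parsed == accepted + rejected` always holds.
#'
#' @param x Path to a CSV/TSV file, or a data.frame.
#' @param column_map Named list/vector with entries `kinase`, `smiles`,
#'   `type`, `value`, `unit` giving the source column names.  May also be
#'   a YAML file with those keys.
#' @param source Free-text provenance tag stored on each record.
#' @param sep Field separator when `x` is a path; guessed from the file
#'   extension by default.
#' @return List with `records` (data.frame: kinase_id, compound_smiles,
#'   measurement_type, value_nM, bioactivity, source) and `rejects`
#'   (data.frame: row, reason).
#' @export
parse_activity_table <- function(x, column_map, source = "unknown",
                                 sep = NULL) {
  if (is.character(column_map) && length(column_map) == 1L &&
      file.exists(column_map)) {
    column_map <- yaml::read_yaml(column_map)
  }
  column_map <- as.list(column_map)
  need <- c("kinase", "smiles", "type", "value", "unit")
  if (!all(need %in% names(column_map))) {
    stop("column_map must name columns: ", paste(need, collapse = ", "))
  }
  if (is.character(x)) {
    if (is.null(sep)) {
      sep <- if (grepl("\\.csv$", x, ignore.case = TRUE)) "," else "\t"
    }
    x <- utils::read.table(x, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  }
  missing_cols <- setdiff(unlist(column_map[need]), names(x))
  if (length(missing_cols)) {
    stop("malformed header: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  kin <- trimws(as.character(x[[column_map$kinase]]))
  smi <- trimws(as.character(x[[column_map$smiles]]))
  typ <- toupper(trimws(as.character(x[[column_map$type]])))
  val <- suppressWarnings(as.numeric(x[[column_map$value]]))
  unit <- .normalize_unit(as.character(x[[column_map$unit]]))

  reason <- rep(NA_character_, nrow(x))
  flag <- function(cond, why) {
    reason[is.na(reason) & cond] <<- why
  }
  flag(is.na(kin) | !nzchar(kin), "missing kinase")
  flag(is.na(smi) | !nzchar(smi), "missing smiles")
  flag(is.na(val), "missing bioactivity")
  flag(!(typ %in% c("IC50", "KI")), "measurement type")
  flag(is.na(unit), "bad unit")
  flag(val <= 0, "nonpositive value")

  keep <- is.na(reason)
  value_nM <- val[keep] * UNIT_FACTORS_NM[unit[keep]]
  records <- data.frame(
    kinase_id = kin[keep],
    compound_smiles = smi[keep],
    measurement_type = ifelse(typ[keep] == "KI", "Ki", "IC50"),
    value_nM = unname(value_nM),
    bioactivity = log10(unname(value_nM)),
    source = source,
    stringsAsFactors = FALSE)
  rejects <- data.frame(row = which(!keep), reason = reason[!keep],
                        stringsAsFactors = FALSE)
  stopifnot(nrow(records) + nrow(rejects) == nrow(x))
  list(records = records, rejects = rejects)
}

#' Canonicalize the SMILES column of an activity table
#'
#' Replaces `compound_smiles` by the canonical isomeric form, so that
#' deduplication keys on chemical identity rather than notation.
#'
#' @param records Activity records data.frame.
#' @return The records with canonical `compound_smiles`.
#' @export
canonicalize_records <- function(records) {
  u <- unique(records$compound_smiles)
  can <- stats::setNames(canonicalize(u), u)
  records$compound_smiles <- unname(can[records$compound_smiles])
  records
}

#' Deduplicate kinase-compound pairs by mean bioactivity
#'
#' Collapses multiple measurements of one (kinase, canonical SMILES) pair
#' into a single record whose bioactivity is the arithmetic mean on the
#' log scale; `value_nM` is recomputed from the mean (i.e. the geometric
#' mean in nM).  Output is sorted by kinase_id then SMILES, so the result
#' is independent of input order.
#'
#' @param records Activity records with canonical SMILES.
#' @return Deduplicated records with an `n_merged` column.
#' @export
deduplicate_pairs <- function(records) {
  if (!nrow(records)) {
    records$n_merged <- integer(0)
    return(records)
  }
  key <- paste(records$kinase_id, records$compound_smiles, sep = "\r")
  # weight by n_merged so re-deduplicating an already merged table is a
  # no-op (the mean of means stays the mean of the original records)
  w <- if ("n_merged" %in% names(records)) records$n_merged else
    rep(1L, nrow(records))
  agg <- tapply(records$bioactivity * w, key, sum) / tapply(w, key, sum)
  cnt <- tapply(w, key, sum)
  first <- records[!duplicated(key), , drop = FALSE]
  fkey <- paste(first$kinase_id, first$compound_smiles, sep = "\r")
  out <- data.frame(
    kinase_id = first$kinase_id,
    compound_smiles = first$compound_smiles,
    measurement_type = first$measurement_type,
    value_nM = unname(10^agg[fkey]),
    bioactivity = unname(agg[fkey]),
    source = first$source,
    n_merged = as.integer(unname(cnt[fkey])),
    stringsAsFactors = FALSE)
  out <- out[order(out$kinase_id, out$compound_smiles), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strict train/test split by held-out kinases or compounds
#'
#' Every record touching a held-out entity goes to the test set, so the
#' held-out entity class has zero train/test overlap.
#'
#' @param records Activity records.
#' @param holdout_kinases Character vector of kinase ids to hold out
#'   (strict split for kinases), or NULL.
#' @param holdout_compounds Character vector of canonical SMILES to hold
#'   out (strict split for compounds), or NULL.  Exactly one of the two
#'   must be given.
#' @return Object of class `split_dataset`: list(train, test, split_kind,
#'   counts).
#' @export
strict_split <- function(records, holdout_kinases = NULL,
                         holdout_compounds = NULL) {
  if (is.null(holdout_kinases) == is.null(holdout_compounds)) {
    stop("give exactly one of holdout_kinases or holdout_compounds")
  }
  if (!is.null(holdout_kinases)) {
    kind <- "strict_kinase"
    pool <- records$kinase_id
    holdout <- holdout_kinases
  } else {
    kind <- "strict_compound"
    pool <- records$compound_smiles
    holdout <- holdout_compounds
  }
  if (!length(holdout)) stop("empty holdout set")
  absent <- setdiff(holdout, pool)
  if (length(absent)) {
    warning("holdout entities absent from records: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  test_idx <- pool %in% holdout
  if (all(test_idx)) stop("holdout covers every record; empty training set")
  out <- list(train = records[!test_idx, , drop = FALSE],
              test = records[test_idx, , drop = FALSE],
              split_kind = kind,
              counts = c(train = sum(!test_idx), test = sum(test_idx)))
  class(out) <- "split_dataset"
  out
}

#' @export
print.split_dataset <- function(x, ...) {
  cat("strict split (", x$split_kind, "): train ", x$counts["train"],
      " / test ", x$counts["test"], "\n", sep = "")
  invisible(x)
}

#' Write a canonical activity table
#'
#' @param records Deduplicated activity records.
#' @param path Output TSV.
#' @export
write_activity_table <- function(records, path) {
  cols <- intersect(c("kinase_id", "compound_smiles", "bioactivity",
                      "n_merged", "source"), names(records))
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a rejection log
#'
#' @param rejects Rejection data.frame from [parse_activity_table()].
#' @param path Output TSV (columns: row, reason).
#' @export
write_rejection_log <- function(rejects, path) {
  utils::write.table(rejects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
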