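# Kinase-group selectivity profiling via odds ratios over positive /
# negative activity calls, classification-threshold method comparison,
# and kinome-tree annotation export.
#
# An interaction is "positive" when its bioactivity is at or below the
# cutoff (default 3.0 on the log10 nM scale, i.e. potency of 1 uM or
# better).  For a compound and a kinase group the odds ratio
#   OR = (N_GP / N_OP) / (N_GN / N_ON)
# compares positive vs negative calls inside and outside the group;
# OR >> 1 marks group-selective inhibition.

#' Classify bioactivity as positive or negative
#'
#' Positive means potency at or better than the cutoff (bioactivity <=
#' cutoff; the boundary counts as positive).  The default cutoff 3.0
#' corresponds to 1 uM.
#'
#' @param bioactivity Finite numeric bioactivities (log10 nM).
#' @param cutoff Classification cutoff on the same scale.
#' @return Character vector "positive"/"negative".
#' @export
classify_activity <- function(bioactivity, cutoff = 3.0) {
  if (any(!is.finite(bioactivity))) {
    stop("bioactivity must be finite for classification")
  }
  ifelse(bioactivity <= cutoff, "positive", "negative")
}

#' Contingency table of group vs outside activity calls
#'
#' @param n_gp Positive interactions inside the group.
#' @param n_op Positive interactions outside the group.
#' @param n_gn Negative interactions inside the group.
#' @param n_on Negative interactions outside the group.
#' @return Object of class `contingency_table`.
#' @export
contingency_table <- function(n_gp, n_op, n_gn, n_on) {
  counts <- c(n_gp = n_gp, n_op = n_op, n_gn = n_gn, n_on = n_on)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be non-negative integers")
  }
  structure(as.list(counts), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("          positive negative\n in group %8d %8d\n outside  %8d %8d\n",
              x$n_gp, x$n_gn, x$n_op, x$n_on))
  invisible(x)
}

#' Odds ratio of a selectivity contingency table
#'
#' `OR = (n_gp/n_op) / (n_gn/n_on)`.  With the default Haldane policy,
#' 0.5 is added to every cell whenever any cell is zero, keeping profiles
#' finite and rankable; the "limit" policy returns 0/Inf limits instead.
#'
#' @param table A `contingency_table` (or list with n_gp, n_op, n_gn,
#'   n_on).
#' @param zero_policy "haldane" (default) or "limit".
#' @return The odds ratio (positive real; possibly 0/Inf under "limit").
#' @export
odds_ratio <- function(table, zero_policy = c("haldane", "limit")) {
  zero_policy <- match.arg(zero_policy)
  n <- c(table$n_gp, table$n_op, table$n_gn, table$n_on)
  if (all(n == 0)) stop("odds ratio undefined for an all-zero table")
  if (any(n == 0) && zero_policy == "haldane") n <- n + 0.5
  (n[1] / n[2]) / (n[3] / n[4])
}

#' Group selectivity profile of one compound
#'
#' Classifies the compound's per-kinase bioactivities at the cutoff and
#' computes a contingency table and odds ratio for every kinase group.
#' The group with maximal OR (ties broken by group name) is the
#' predicted selectivity class.  Compounds whose calls are all positive
#' or all negative are not profilable and are returned with
#' `eligible = FALSE` and a reason.
#'
#' @param bioactivities Named numeric vector (names = kinase ids) of
#'   bioactivities for one compound.
#' @param catalog A `kinase_catalog` with group labels, or a data.frame
#'   (kinase_id, group).
#' @param cutoff Positive/negative cutoff (default 3.0 = 1 uM).
#' @param compound Optional compound label carried in the result.
#' @param zero_policy Passed to [odds_ratio()].
#' @return Object of class `profile_result`: list(compound, eligible,
#'   reason, per_group, predicted_group, n_kinases).
#' @export
group_profile <- function(bioactivities, catalog, cutoff = 3.0,
                          compound = NA_character_,
                          zero_policy = "haldane") {
  groups_df <- if (inherits(catalog, "kinase_catalog")) {
    catalog$entries[, c("kinase_id", "group")]
  } else {
    catalog
  }
  ids <- names(bioactivities)
  if (is.null(ids)) stop("bioactivities must be named by kinase id")
  grp <- groups_df$group[match(ids, groups_df$kinase_id)]
  if (anyNA(grp)) {
    stop("kinases missing from group map: ",
         paste(ids[is.na(grp)], collapse = ", "))
  }
  call_pos <- classify_activity(bioactivities, cutoff) == "positive"
  result <- list(compound = compound, n_kinases = length(ids),
                 cutoff = cutoff)
  if (all(call_pos) || all(!call_pos)) {
    result$eligible <- FALSE
    result$reason <- if (all(call_pos)) "all calls positive" else
      "all calls negative"
    result$per_group <- NULL
    result$predicted_group <- NA_character_
    class(result) <- "profile_result"
    return(result)
  }
  gnames <- sort(unique(grp))
  per_group <- lapply(gnames, function(g) {
    inside <- grp == g
    tab <- contingency_table(
      n_gp = sum(inside & call_pos), n_op = sum(!inside & call_pos),
      n_gn = sum(inside & !call_pos), n_on = sum(!inside & !call_pos))
    list(group = g, table = tab,
         or_value = odds_ratio(tab, zero_policy))
  })
  names(per_group) <- gnames
  ors <- vapply(per_group, `[[`, numeric(1), "or_value")
  result$eligible <- TRUE
  result$reason <- NA_character_
  result$per_group <- per_group
  # argmax OR; ties broken deterministically by group name order
  result$predicted_group <- gnames[which.max(ors)]
  class(result) <- "profile_result"
  result
}

#' @export
print.profile_result <- function(x, ...) {
  cat("selectivity profile", if (!is.na(x$compound)) x$compound else "",
      "\n")
  if (!x$eligible) {
    cat("  not profilable:", x$reason, "\n")
    return(invisible(x))
  }
  for (pg in x$per_group) {
    cat(sprintf("  %-10s OR = %.3f\n", pg$group, pg$or_value))
  }
  cat("  predicted group:", x$predicted_group, "\n")
  invisible(x)
}

#' Profile many compounds at once
#'
#' @param records Activity records (kinase_id, compound_smiles,
#'   bioactivity); one profile per distinct compound.
#' @param catalog A `kinase_catalog` or (kinase_id, group) data.frame.
#' @param cutoff Positive/negative cutoff.
#' @return List of `profile_result`, named by compound.
#' @export
profile_compounds <- function(records, catalog, cutoff = 3.0) {
  by_comp <- split(records, records$compound_smiles)
  lapply(by_comp, function(df) {
    group_profile(stats::setNames(df$bioactivity, df$kinase_id),
                  catalog, cutoff = cutoff,
                  compound = df$compound_smiles[1])
  })
}

#' Compare scoring methods at potency cutoffs
#'
#' Labels every interaction positive/negative at each cutoff (converted
#' from uM to the log10 nM scale), min-max scales each method's scores to
#' [0, 1], and reports threshold-free AUC plus point metrics (precision,
#' recall, F1, accuracy) at the scaled-score threshold 0.5.  Scores are
#' oriented like bioactivity: lower score means more active.
#'
#' @param scores Named list of numeric score vectors (e.g. predicted
#'   bioactivity, docking score), all aligned with `bioactivity`.
#' @param bioactivity Observed bioactivities (log10 nM).
#' @param cutoffs_um Potency cutoffs in uM (default 0.1, 1, 5).
#' @return data.frame (method, cutoff_um, auc, precision, recall, f1,
#'   accuracy, n_positive, n_negative); AUC and point metrics are NA when
#'   only one class is present at a cutoff.
#' @export
compare_methods <- function(scores, bioactivity,
                            cutoffs_um = c(0.1, 1, 5)) {
  stopifnot(is.list(scores), length(names(scores)) == length(scores))
  lens <- vapply(scores, length, integer(1))
  stopifnot(all(lens == length(bioactivity)))
  out <- NULL
  for (cut_um in cutoffs_um) {
    cutoff <- to_bioactivity(cut_um, "uM")
    lab <- classify_activity(bioactivity, cutoff)
    npos <- sum(lab == "positive")
    nneg <- sum(lab == "negative")
    for (nm in names(scores)) {
      s <- scores[[nm]]
      rng <- range(s)
      sc <- if (diff(rng) > 0) (s - rng[1]) / diff(rng) else rep(0.5,
                                                                 length(s))
      if (npos == 0L || nneg == 0L) {
        warning("single-class labels at cutoff ", cut_um,
                " uM: metrics undefined", call. = FALSE)
        row <- data.frame(method = nm, cutoff_um = cut_um, auc = NA_real_,
                          precision = NA_real_, recall = NA_real_,
                          f1 = NA_real_, accuracy = NA_real_,
                          n_positive = npos, n_negative = nneg)
      } else {
        roc <- pROC::roc(response = lab, predictor = sc,
                         levels = c("negative", "positive"),
                         direction = ">", quiet = TRUE)
        auc <- as.numeric(pROC::auc(roc))
        pred_pos <- sc <= 0.5
        tp <- sum(pred_pos & lab == "positive")
        fp <- sum(pred_pos & lab == "negative")
        fn <- sum(!pred_pos & lab == "positive")
        tn <- sum(!pred_pos & lab == "negative")
        precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
        recall <- tp / (tp + fn)
        f1 <- if (is.na(precision) || precision + recall == 0) NA_real_
          else 2 * precision * recall / (precision + recall)
        row <- data.frame(method = nm, cutoff_um = cut_um, auc = auc,
                          precision = precision, recall = recall, f1 = f1,
                          accuracy = (tp + tn) / length(lab),
                          n_positive = npos, n_negative = nneg)
      }
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}

#' Export a kinome-tree annotation file
#'
#' Writes a TSV (columns: xName, size, fill) consumable by web-based
#' kinome-tree annotators.  Values are mapped to marker sizes by linear
#' interpolation between `size_range` over the value range (monotone:
#' larger value, larger marker).
#'
#' @param per_kinase data.frame with columns `kinase` and `value` (e.g.
#'   odds ratios or bioactivities).
#' @param path Output file.
#' @param size_range Marker size bounds, c(min, max).
#' @param fill Marker fill colour.
#' @return The path, invisibly.
#' @export
export_kinmap <- function(per_kinase, path, size_range = c(20, 100),
                          fill = "#1f78b4") {
  stopifnot(all(c("kinase", "value") %in% names(per_kinase)))
  df <- per_kinase
  if (nrow(df)) {
    rng <- range(df$value)
    frac <- if (diff(rng) > 0) (df$value - rng[1]) / diff(rng) else
      rep(0.5, nrow(df))
    size <- size_range[1] + frac * diff(size_range)
    out <- data.frame(xName = df$kinase, size = round(size, 2), fill = fill)
  } else {
    out <- data.frame(xName = character(0), size = numeric(0),
                      fill = character(0))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
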