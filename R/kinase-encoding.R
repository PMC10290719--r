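# Kinase encodings from a structure-validated multiple sequence alignment:
# identifier one-hot (1 x n_kinases), active-site one-hot (29 x 21 by
# default) and full-alignment one-hot (alignment_width x 21).  The 21
# channels are the 20 standard amino acids (alphabetical one-letter code)
# followed by the gap symbol "-".

#' Sequence encoding channel order
#'
#' @return Character vector of the 21 channels: 20 standard amino acids in
#'   alphabetical one-letter order, then the gap symbol `-`.
#' @export
aa_channels <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
}

#' Build a kinase catalog from an aligned FASTA
#'
#' Reads a structure-validated MSA of kinase domains.  All sequences must
#' have equal length (the alignment width); the first whitespace-separated
#' token of each header is the kinase identifier; input order is preserved
#' and defines the identifier one-hot indices.
#'
#' @param path Aligned FASTA file.
#' @param group_map Optional mapping of kinase_id to group: a named
#'   character vector, or a TSV file with columns kinase_id, group.
#'   Unmapped kinases get group "unknown".
#' @return Object of class `kinase_catalog`: a list with `entries`
#'   (data.frame kinase_id, group, aligned_seq) and `alignment_width`.
#' @export
read_alignment <- function(path, group_map = NULL) {
  aln <- Biostrings::readAAStringSet(path)
  if (!length(aln)) stop("empty alignment: ", path)
  ids <- vapply(strsplit(names(aln), "\\s+"), `[`, character(1), 1)
  seqs <- as.character(aln)
  kinase_catalog(ids, seqs, group_map)
}

#' Construct a kinase catalog from vectors
#'
#' @param kinase_id Character vector of unique identifiers.
#' @param aligned_seq Character vector of aligned sequences (equal length,
#'   alphabet: 20 standard amino acids plus `-`).
#' @param group_map Optional named character vector or TSV path mapping
#'   kinase_id to group.
#' @return A `kinase_catalog`.
#' @export
kinase_catalog <- function(kinase_id, aligned_seq, group_map = NULL) {
  stopifnot(length(kinase_id) == length(aligned_seq))
  kinase_id <- unname(as.character(kinase_id))
  aligned_seq <- unname(as.character(aligned_seq))
  if (anyDuplicated(kinase_id)) {
    stop("duplicate kinase ids: ",
         paste(unique(kinase_id[duplicated(kinase_id)]), collapse = ", "))
  }
  widths <- nchar(aligned_seq)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: sequence widths ",
         paste(sort(unique(widths)), collapse = ", "))
  }
  bad <- setdiff(unique(unlist(strsplit(aligned_seq, ""))), aa_channels())
  if (length(bad)) {
    stop("alignment contains out-of-alphabet characters: ",
         paste(bad, collapse = " "))
  }
  groups <- rep("unknown", length(kinase_id))
  if (!is.null(group_map)) {
    if (is.character(group_map) && length(group_map) == 1L &&
        file.exists(group_map)) {
      gm <- utils::read.delim(group_map, stringsAsFactors = FALSE)
      group_map <- stats::setNames(gm$group, gm$kinase_id)
    }
    hit <- kinase_id %in% names(group_map)
    groups[hit] <- unname(group_map[kinase_id[hit]])
  }
  out <- list(entries = data.frame(kinase_id = kinase_id, group = groups,
                                   aligned_seq = aligned_seq,
                                   stringsAsFactors = FALSE),
              alignment_width = widths[1])
  class(out) <- "kinase_catalog"
  out
}

#' @export
print.kinase_catalog <- function(x, ...) {
  cat("kinase catalog:", nrow(x$entries), "kinases, alignment width",
      x$alignment_width, "\n")
  tg <- table(x$entries$group)
  cat("  groups:", paste(sprintf("%s(%d)", names(tg), tg), collapse = " "),
      "\n")
  invisible(x)
}

#' Identifier one-hot encoding of a kinase
#'
#' @param kinase_id Identifier present in the catalog.
#' @param catalog A `kinase_catalog`.
#' @return 1 x n_kinases 0/1 matrix with a single 1 at the catalog index.
#' @export
encode_identifier <- function(kinase_id, catalog) {
  stopifnot(inherits(catalog, "kinase_catalog"))
  i <- match(kinase_id, catalog$entries$kinase_id)
  if (is.na(i)) stop("unknown kinase id: ", kinase_id)
  m <- matrix(0L, 1L, nrow(catalog$entries),
              dimnames = list(kinase_id, catalog$entries$kinase_id))
  m[1L, i] <- 1L
  m
}

#' One-hot encode an aligned sequence
#'
#' Row i carries a single 1 in the channel of residue i; channel order is
#' [aa_channels()].  In strict mode (default) out-of-alphabet characters
#' are an error; in lenient mode they map to the gap channel with a
#' warning.
#'
#' @param aligned_seq A single aligned sequence string.
#' @param lenient Map non-standard residues to the gap channel instead of
#'   failing.
#' @return L x 21 0/1 matrix, one row per alignment column.
#' @export
encode_sequence <- function(aligned_seq, lenient = FALSE) {
  stopifnot(is.character(aligned_seq), length(aligned_seq) == 1L)
  chars <- strsplit(aligned_seq, "")[[1]]
  ch <- aa_channels()
  idx <- match(chars, ch)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    if (!lenient) {
      stop("out-of-alphabet characters: ", paste(bad, collapse = " "))
    }
    warning("mapping non-standard residues to gap: ",
            paste(bad, collapse = " "), call. = FALSE)
    idx[is.na(idx)] <- length(ch)
  }
  m <- matrix(0L, length(chars), length(ch),
              dimnames = list(NULL, ch))
  m[cbind(seq_along(idx), idx)] <- 1L
  m
}

#' Decode a one-hot sequence encoding
#'
#' Inverse of [encode_sequence()].
#'
#' @param mat L x 21 one-hot matrix.
#' @return The aligned sequence string.
#' @export
decode_sequence <- function(mat) {
  stopifnot(ncol(mat) == 21L, all(rowSums(mat) == 1L))
  paste(aa_channels()[max.col(mat)], collapse = "")
}

#' Active-site column map
#'
#' An ordered set of alignment column indices selecting the active-site
#' slice of the alignment.  Columns are 1-based (R convention, also used
#' in the YAML interchange format).
#'
#' @param columns Strictly increasing integer vector of alignment columns.
#' @param alignment_width Optional width for bounds checking.
#' @return Object of class `active_site_map`.
#' @export
active_site_map <- function(columns, alignment_width = NULL) {
  columns <- as.integer(columns)
  if (any(columns < 1L) || is.unsorted(columns, strictly = TRUE)) {
    stop("active-site columns must be strictly increasing and >= 1")
  }
  if (!is.null(alignment_width) && any(columns > alignment_width)) {
    stop("active-site column out of range for alignment width ",
         alignment_width)
  }
  structure(list(columns = columns), class = "active_site_map")
}

#' Read an active-site map from YAML
#'
#' The file holds a list (or `columns:` entry) of 1-based alignment
#' column indices.
#'
#' @param path YAML file.
#' @param alignment_width Optional width for bounds checking.
#' @return An `active_site_map`.
#' @export
read_active_site_map <- function(path, alignment_width = NULL) {
  y <- yaml::read_yaml(path)
  if (is.list(y) && !is.null(y$columns)) y <- y$columns
  active_site_map(unlist(y), alignment_width)
}

#' Write an active-site map to YAML
#'
#' @param map An `active_site_map`.
#' @param path Output file.
#' @export
write_active_site_map <- function(map, path) {
  yaml::write_yaml(list(columns = map$columns), path)
  invisible(path)
}

#' Active-site one-hot encoding
#'
#' Equals [encode_sequence()] applied to the subsequence selected by the
#' site map, in map order; (29, 21) with the default 29-column map.
#'
#' @param aligned_seq A single aligned sequence string.
#' @param site_map An `active_site_map` valid for the sequence width.
#' @param lenient Passed to [encode_sequence()].
#' @return |site_map| x 21 0/1 matrix.
#' @export
encode_active_site <- function(aligned_seq, site_map, lenient = FALSE) {
  stopifnot(inherits(site_map, "active_site_map"))
  L <- nchar(aligned_seq)
  if (any(site_map$columns > L)) {
    stop("active-site column out of range for sequence of width ", L)
  }
  chars <- strsplit(aligned_seq, "")[[1]]
  encode_sequence(paste(chars[site_map$columns], collapse = ""),
                  lenient = lenient)
}

#' Encode a catalog kinase for a given representation mode
#'
#' @param catalog A `kinase_catalog`.
#' @param kinase_id Identifier in the catalog.
#' @param mode One of "identifier", "active_site", "full_alignment".
#' @param site_map Required for mode "active_site".
#' @return One-hot matrix in the shape of the chosen representation.
#' @export
encode_kinase <- function(catalog, kinase_id,
                          mode = c("identifier", "active_site",
                                   "full_alignment"),
                          site_map = NULL) {
  mode <- match.arg(mode)
  i <- match(kinase_id, catalog$entries$kinase_id)
  if (is.na(i)) stop("unknown kinase id: ", kinase_id)
  switch(mode,
         identifier = encode_identifier(kinase_id, catalog),
         active_site = {
           if (is.null(site_map)) stop("active_site mode needs a site_map")
           encode_active_site(catalog$entries$aligned_seq[i], site_map)
         },
         full_alignment = encode_sequence(catalog$entries$aligned_seq[i]))
}
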