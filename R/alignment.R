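# Alignment data model, FASTA/Stockholm I/O, sequence weighting, weighted
# column profiles and alignment-column <-> reference-residue-number mapping.

#' The 20 standard amino-acid letters
#'
#' One-letter codes in alphabetical order. Gap is `"-"`, unknown/nonstandard
#' residues are normalised to `"X"` and treated as missing throughout.
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a gapped protein alignment
#'
#' The container used by all sequence statistics in the package: an ordered
#' set of equal-length gapped sequences over the 20 amino-acid letters plus
#' `"-"` (gap) and `"X"` (unknown). Letters are uppercased, `"."` is
#' normalised to `"-"`, and any letter outside the alphabet becomes `"X"`.
#'
#' @param ids character vector of unique, non-empty sequence identifiers.
#' @param seqs character vector of gapped sequences, same length as `ids`.
#' @return An object of class `"msa"`: a list with elements `ids`,
#'   `mat` (character matrix, one row per sequence, one column per
#'   alignment column) and `n_columns`.
#' @export
new_alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) == 0L) stop("empty alignment: no sequences")
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(ids))) stop("empty sequence id")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("alignment-shape error: sequences have unequal lengths (",
         paste(sort(unique(widths)), collapse = ", "), ")")
  }
  if (widths[1L] < 1L) stop("alignment-shape error: zero-length sequences")
  seqs <- chartr(".", "-", seqs)
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  bad <- !(mat %in% c(AMINO_ACIDS, "-", "X"))
  if (any(bad)) mat[bad] <- "X"
  rownames(mat) <- ids
  structure(list(ids = ids, mat = mat, n_columns = ncol(mat)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("Gapped protein alignment: %d sequences x %d columns\n",
              length(x$ids), x$n_columns))
  show <- utils::head(x$ids, 5L)
  for (id in show) {
    s <- paste(x$mat[id, seq_len(min(50L, x$n_columns))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", id, s,
                if (x$n_columns > 50L) "..." else ""))
  }
  if (length(x$ids) > 5L) cat("  ...\n")
  invisible(x)
}

#' Number of sequences / columns in an alignment
#' @param aln an `"msa"` object.
#' @return integer.
#' @export
n_sequences <- function(aln) length(aln$ids)

#' @rdname n_sequences
#' @export
n_columns <- function(aln) aln$n_columns

#' Extract a sub-alignment by sequence
#'
#' @param aln an `"msa"` object.
#' @param ids sequence identifiers (or integer indices) to keep, in order.
#' @return An `"msa"` with the requested rows.
#' @export
subset_alignment <- function(aln, ids) {
  if (is.numeric(ids)) ids <- aln$ids[ids]
  missing <- setdiff(ids, aln$ids)
  if (length(missing)) {
    stop("unknown sequence ids: ", paste(missing, collapse = ", "))
  }
  new_alignment(ids, apply(aln$mat[ids, , drop = FALSE], 1L, paste,
                           collapse = ""))
}

#' Read a gapped protein alignment
#'
#' Reads an aligned FASTA or single-block Stockholm file into an [`msa`
#' object][new_alignment]. Letters are uppercased and `"."` is normalised to
#' `"-"`; records must all have the same length.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return An `"msa"` object.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                    error = function(e) stop("input error reading FASTA: ",
                                             conditionMessage(e)))
    if (length(set) == 0L) stop("input error: empty FASTA file")
    ids <- sub("\\s.*$", "", names(set))
    new_alignment(ids, as.character(set))
  } else {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !grepl("^# STOCKHOLM", lines[1L])) {
      stop("input error: not a Stockholm file (missing '# STOCKHOLM' header)")
    }
    body <- lines[!grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))]
    if (!length(body)) stop("input error: Stockholm file has no sequences")
    parts <- regmatches(body, regexpr("^\\S+", body))
    seqs <- trimws(sub("^\\S+\\s+", "", body))
    # sequences may continue across blocks keyed by the same id
    agg <- tapply(seqs, factor(parts, levels = unique(parts)), paste,
                  collapse = "")
    new_alignment(names(agg), as.character(agg))
  }
}

#' Write a gapped protein alignment
#'
#' @param aln an `"msa"` object.
#' @param path output path.
#' @param format `"fasta"` or `"stockholm"` (single block).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  if (format == "fasta") {
    set <- Biostrings::AAStringSet(seqs)
    names(set) <- aln$ids
    Biostrings::writeXStringSet(set, path)
  } else {
    w <- max(nchar(aln$ids))
    writeLines(c("# STOCKHOLM 1.0",
                 sprintf("%-*s  %s", w, aln$ids, seqs),
                 "//"), path)
  }
  invisible(path)
}

#' Sequence weights for an alignment
#'
#' Computes per-sequence weights so that column frequency estimates reflect
#' sequence diversity rather than database redundancy. `position_based` is
#' Henikoff & Henikoff position-based weighting: at each column a sequence
#' carrying residue `r` receives `1 / (k * n_r)` where `k` is the number of
#' distinct residues in the column and `n_r` the number of sequences carrying
#' `r`; gaps and `"X"` contribute nothing. Per-sequence sums are normalised
#' so the maximum weight is 1. `uniform` gives every sequence weight 1.
#'
#' @param aln an `"msa"` object.
#' @param method `"position_based"` (default) or `"uniform"`.
#' @return An object of class `"seq_weights"`: list with `weights` (named
#'   numeric, one per sequence, each in (0, 1]), `effective_count`
#'   (`sum(weights)`) and `method`.
#' @references Henikoff S, Henikoff JG (1994) Position-based sequence
#'   weights. J Mol Biol 243:574-578.
#' @export
compute_weights <- function(aln, method = c("position_based", "uniform")) {
  method <- match.arg(method)
  n <- n_sequences(aln)
  if (method == "uniform") {
    w <- rep(1, n)
  } else {
    mat <- aln$mat
    w <- numeric(n)
    for (j in seq_len(ncol(mat))) {
      col <- mat[, j]
      keep <- col %in% AMINO_ACIDS
      if (!any(keep)) next
      tab <- table(col[keep])
      k <- length(tab)
      w[keep] <- w[keep] + 1 / (k * as.numeric(tab[col[keep]]))
    }
    if (all(w == 0)) w <- rep(1, n)  # all-gap degenerate alignment
    w <- w / max(w)
    w[w == 0] <- min(w[w > 0])  # all-gap sequences: smallest positive weight
  }
  names(w) <- aln$ids
  structure(list(weights = w, effective_count = sum(w), method = method),
            class = "seq_weights")
}

#' @export
print.seq_weights <- function(x, ...) {
  cat(sprintf("Sequence weights (%s): %d sequences, effective count %.2f\n",
              x$method, length(x$weights), x$effective_count))
  invisible(x)
}

#' Weighted residue frequency profile over alignment columns
#'
#' Per column, the weighted relative frequency of each amino-acid letter
#' among the chosen sequences, conditional on non-gap: `freq[j, r]` is the
#' summed weight of subset sequences carrying `r` at column `j`, divided by
#' the summed weight of subset sequences carrying any standard residue
#' there. Gaps and `"X"` are counted as missing: `gap_fraction[j]` is the
#' weighted fraction of the subset that carries `"-"` or `"X"` at column
#' `j`. A column that is all-gap within the subset has `NA` frequencies and
#' `gap_fraction` 1.
#'
#' @param aln an `"msa"` object.
#' @param w a `"seq_weights"` object (or `NULL` for uniform weights).
#' @param subset sequence ids or integer indices to profile; defaults to all.
#' @return An object of class `"column_profile"`: list with `freq`
#'   (n_columns x 20 matrix, columns named by [AMINO_ACIDS]),
#'   `gap_fraction`, `n_eff` (weighted non-gap count per column) and
#'   `subset`.
#' @export
column_profile <- function(aln, w = NULL, subset = NULL) {
  if (is.null(w)) w <- compute_weights(aln, "uniform")
  if (is.null(subset)) subset <- aln$ids
  if (is.numeric(subset)) subset <- aln$ids[subset]
  if (!length(subset)) stop("subset is empty")
  missing <- setdiff(subset, aln$ids)
  if (length(missing)) stop("unknown sequence ids in subset: ",
                            paste(missing, collapse = ", "))
  mat <- aln$mat[subset, , drop = FALSE]
  wt <- unname(w$weights[subset])
  if (anyNA(wt)) stop("weights do not cover the subset")
  L <- ncol(mat)
  counts <- matrix(0, nrow = L, ncol = length(AMINO_ACIDS),
                   dimnames = list(NULL, AMINO_ACIDS))
  for (r in AMINO_ACIDS) counts[, r] <- colSums(wt * (mat == r))
  n_eff <- rowSums(counts)
  total <- sum(wt)
  gap_fraction <- pmin(pmax((total - n_eff) / total, 0), 1)
  freq <- counts / ifelse(n_eff > 0, n_eff, NA_real_)
  structure(list(freq = freq, gap_fraction = gap_fraction, n_eff = n_eff,
                 subset = subset, total_weight = total),
            class = "column_profile")
}

#' Map alignment columns to reference residue numbers
#'
#' Builds the column -> residue-number map for a chosen reference sequence,
#' optionally shifted by a signal-peptide offset so that reported positions
#' use pre-mature numbering (mature residue `i` is numbered `i + offset`).
#' For human EGFR the conventional offset is 24 (the signal peptide length);
#' supply 0 when the reference sequence is already in pre-mature
#' coordinates.
#'
#' @param aln an `"msa"` object.
#' @param reference_id id of the reference sequence within `aln`.
#' @param signal_peptide_offset non-negative integer added to the 1-based
#'   non-gap residue index of the reference (default 24).
#' @return An object of class `"reference_map"`: list with `reference_id`,
#'   `signal_peptide_offset` and `refpos`, an integer vector of length
#'   `n_columns(aln)` holding the reference residue number per column, `NA`
#'   where the reference has a gap. The mapping is strictly increasing over
#'   mapped columns.
#' @export
map_columns <- function(aln, reference_id, signal_peptide_offset = 24L) {
  if (!reference_id %in% aln$ids) {
    stop("lookup error: reference id not in alignment: ", reference_id)
  }
  if (signal_peptide_offset < 0) stop("signal_peptide_offset must be >= 0")
  row <- aln$mat[reference_id, ]
  nongap <- row != "-"
  refpos <- rep(NA_integer_, length(row))
  refpos[nongap] <- seq_len(sum(nongap)) + as.integer(signal_peptide_offset)
  structure(list(reference_id = reference_id,
                 signal_peptide_offset = as.integer(signal_peptide_offset),
                 refpos = refpos),
            class = "reference_map")
}

#' Read / write a foreground-background partition label file
#'
#' Two-column tab-separated file without header: sequence id, then one of
#' `fore`, `back` or `query` (query ids are display-only and are treated as
#' foreground members for the statistics).
#'
#' @param path file path.
#' @return For `read_partition`, a `"partition_spec"` object (see
#'   [new_partition()]); query ids are carried in the `query_ids` element.
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("id", "class"),
                          colClasses = "character")
  cls <- tolower(df$class)
  ok <- cls %in% c("fore", "back", "query")
  if (any(!ok)) stop("input error: unknown partition label(s): ",
                     paste(unique(df$class[!ok]), collapse = ", "))
  membership <- ifelse(cls == "back", "back", "fore")
  names(membership) <- df$id
  part <- new_partition(membership, source = "given")
  part$query_ids <- df$id[cls == "query"]
  part
}

#' @rdname read_partition
#' @param part a `"partition_spec"` object.
#' @export
write_partition <- function(part, path) {
  lab <- part$membership
  lab[names(lab) %in% part$query_ids] <- "query"
  utils::write.table(data.frame(names(part$membership), lab),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
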