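# Recurrent somatic-mutation tables and their overlap with the selected
# pattern positions.

#' Parse a compact amino-acid change string
#'
#' Strings of the form `"L861Q(26)"`: wild-type residue, position
#' (pre-mature numbering), variant residue and, in parentheses, the
#' recurrence count (omitted count defaults to 1). Several changes may be
#' given in one string separated by whitespace.
#'
#' @param x character vector of compact strings.
#' @return data.frame: `refpos`, `wt`, `variant`, `count` (one row per
#'   change).
#' @examples
#' parse_mutation_string("L861Q(26)")
#' @export
parse_mutation_string <- function(x) {
  tokens <- unlist(strsplit(trimws(x), "\\s+"))
  tokens <- tokens[nzchar(tokens)]
  m <- regmatches(tokens,
                  regexec("^([A-Z])([0-9]+)([A-Z])(?:\\(([0-9]+)\\))?$",
                          tokens))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("parse error: malformed amino-acid change string: ",
         paste(tokens[bad], collapse = ", "))
  }
  out <- data.frame(
    refpos = vapply(m, function(g) as.integer(g[3]), integer(1)),
    wt = vapply(m, `[`, character(1), 2),
    variant = vapply(m, `[`, character(1), 4),
    count = vapply(m, function(g) {
      if (nzchar(g[5])) as.integer(g[5]) else 1L
    }, integer(1)),
    stringsAsFactors = FALSE)
  okres <- out$wt %in% AMINO_ACIDS & out$variant %in% AMINO_ACIDS
  if (any(!okres)) stop("parse error: non-standard residue letter in: ",
                        paste(tokens[!okres], collapse = ", "))
  if (any(out$wt == out$variant)) {
    stop("parse error: wild-type equals variant in: ",
         paste(tokens[out$wt == out$variant], collapse = ", "))
  }
  out
}

#' Read a recurrent-mutation table
#'
#' Accepts either an explicit tab-separated table with header columns
#' `position`, `wt`, `variant`, `site`, `count`, or a two-column table
#' with header `mutation`, `site` where `mutation` holds compact
#' amino-acid change strings (`"E709K(9)"`, several per cell allowed).
#' Identical changes (same position, wild type and variant) reported more
#' than once are summed, and their sites concatenated.
#'
#' @param path file path.
#' @return data.frame of class `"mutation_table"`: `refpos`, `wt`,
#'   `variant`, `site`, `count`.
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (all(c("position", "wt", "variant", "site", "count") %in% names(df))) {
    out <- data.frame(refpos = as.integer(df$position), wt = df$wt,
                      variant = df$variant, site = df$site,
                      count = as.integer(df$count), stringsAsFactors = FALSE)
    if (anyNA(out$refpos) || anyNA(out$count)) {
      stop("parse error: non-numeric position or count in ", path)
    }
    if (any(out$count < 1L)) stop("parse error: count must be >= 1")
    if (any(out$wt == out$variant)) {
      stop("parse error: wild-type equals variant")
    }
  } else if ("mutation" %in% names(df)) {
    rows <- lapply(seq_len(nrow(df)), function(i) {
      p <- tryCatch(parse_mutation_string(df$mutation[i]),
                    error = function(e) {
                      stop("parse error in row ", i, ": ",
                           conditionMessage(e))
                    })
      p$site <- if ("site" %in% names(df)) df$site[i] else NA_character_
      p
    })
    out <- do.call(rbind, rows)
    out <- out[c("refpos", "wt", "variant", "site", "count")]
  } else {
    stop("input error: unrecognised mutation table header in ", path)
  }
  # sum duplicate reports of the same change
  key <- paste(out$refpos, out$wt, out$variant)
  if (anyDuplicated(key)) {
    agg_count <- tapply(out$count, key, sum)
    agg_site <- tapply(out$site, key, function(s) {
      paste(unique(stats::na.omit(s)), collapse = "; ")
    })
    first <- !duplicated(key)
    out <- out[first, , drop = FALSE]
    out$count <- as.integer(agg_count[key[first]])
    out$site <- as.character(agg_site[key[first]])
  }
  out <- out[order(out$refpos, out$variant), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mutation_table", "data.frame")
  out
}

#' Overlay recurrent mutations onto the selected pattern positions
#'
#' Joins each mutation against the selected pattern positions (and,
#' optionally, the region/tether annotation), and quantifies the
#' positional overlap with a one-sided Fisher exact test on the 2x2 table
#' (position mutated? x position in pattern?) over all integer positions
#' in `ref_range`. Mutations outside `ref_range` are flagged and excluded
#' from the 2x2. The enrichment test is an extension beyond a plain
#' overlap report and is labelled as such in the output.
#'
#' @param muts a `"mutation_table"` (see [read_mutations()]).
#' @param pattern a `"contrast_result"` with reference positions, or an
#'   integer vector of pattern reference positions.
#' @param annot optional region annotation (see
#'   [read_region_annotation()]).
#' @param ref_range integer length-2, the reference position range over
#'   which enrichment is assessed.
#' @return An object of class `"mutation_overlay"`: list with `report`
#'   (per-mutation rows: `refpos`, `mutation`, `site`, `count`,
#'   `selected`, `region`, `tether`, `in_range`), `table2x2`, `p_value`
#'   (one-sided Fisher; `NA` when the mutation table is empty) and
#'   `method`.
#' @export
overlay_mutations <- function(muts, pattern, annot = NULL, ref_range) {
  pat_pos <- if (inherits(pattern, "contrast_result")) {
    pattern_positions(pattern, use_refpos = TRUE)
  } else as.integer(pattern)
  if (missing(ref_range)) {
    stop("ref_range (the reference position span) must be stated")
  }
  ref_range <- as.integer(ref_range)
  universe <- seq.int(ref_range[1], ref_range[2])
  report <- data.frame(
    refpos = muts$refpos,
    mutation = sprintf("%s%d%s", muts$wt, muts$refpos, muts$variant),
    site = muts$site, count = muts$count,
    selected = muts$refpos %in% pat_pos,
    in_range = muts$refpos >= ref_range[1] & muts$refpos <= ref_range[2],
    stringsAsFactors = FALSE)
  if (!is.null(annot)) {
    cls <- classify_tethers(muts$refpos, annot)
    idx <- match(muts$refpos, cls$refpos)
    report$region <- cls$region[idx]
    report$tether <- cls$tether[idx]
  } else {
    report$region <- rep(NA_character_, nrow(report))
    report$tether <- rep(NA_character_, nrow(report))
  }
  if (!nrow(muts)) {
    return(structure(list(report = report, table2x2 = NULL,
                          p_value = NA_real_,
                          method = "one-sided Fisher exact (extension)"),
                     class = "mutation_overlay"))
  }
  mut_pos <- unique(report$refpos[report$in_range])
  pat_in <- intersect(pat_pos, universe)
  a <- length(intersect(mut_pos, pat_in))
  b <- length(setdiff(pat_in, mut_pos))
  c_ <- length(setdiff(mut_pos, pat_in))
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, 2,
                dimnames = list(mutated = c("yes", "no"),
                                pattern = c("yes", "no")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  structure(list(report = report, table2x2 = tab, p_value = p,
                 method = "one-sided Fisher exact (extension)"),
            class = "mutation_overlay")
}

#' @export
print.mutation_overlay <- function(x, ...) {
  cat(sprintf("Mutation overlay: %d mutations, %d at pattern positions",
              nrow(x$report), sum(x$report$selected)))
  if (!is.na(x$p_value)) {
    cat(sprintf("; positional enrichment p = %.3g (%s)", x$p_value,
                x$method))
  }
  cat("\n")
  invisible(x)
}

#' Write a mutation overlay report as TSV
#'
#' @param ov a `"mutation_overlay"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(ov, path) {
  utils::write.table(ov$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
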