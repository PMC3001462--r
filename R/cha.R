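# Text rendering of a Contrast Hierarchical Alignment: query display
# sequences under a score histogram and pattern-dot row, above the
# foreground consensus with integer-tenths weighted frequencies and the
# background composition block.

#' Integer-tenths frequency digit
#'
#' Renders a frequency in \[0, 1\] as the single digit `floor(10 * freq)`;
#' digit `d` covers the band `[d/10, (d+1)/10)`, so e.g. `'6'` means the
#' residue occurs in 60-70% of the weighted sequences. The top band is
#' closed: any frequency of 0.9 or more, including exactly 1.0, renders as
#' `'9'` (a single-character constraint, stated here prominently). An `NA`
#' frequency (all-gap column) renders as a blank.
#'
#' @param freq numeric vector of frequencies in \[0, 1\] (`NA` allowed).
#' @return Character vector of single characters.
#' @examples
#' freq_digit(c(0.65, 0, 1))  # "6" "0" "9"
#' @export
freq_digit <- function(freq) {
  if (any(!is.na(freq) & (freq < 0 | freq > 1))) {
    stop("domain error: frequency outside [0, 1]")
  }
  out <- rep(" ", length(freq))
  ok <- !is.na(freq)
  out[ok] <- as.character(pmin(floor(10 * freq[ok]), 9))
  out
}

# Five-glyph ramp for histogram heights in [0, 1]: blank for exactly 0,
# then quarters of the nonzero range.
histogram_glyphs <- function(height) {
  glyphs <- c(" ", ".", ":", "|", "#")
  idx <- ifelse(height <= 0, 1L, 1L + pmin(ceiling(height * 4), 4))
  glyphs[idx]
}

# argmax consensus letter of a profile row; blank when all-gap.
consensus_letter <- function(freq_row) {
  if (all(is.na(freq_row))) return(" ")
  AMINO_ACIDS[which.max(freq_row)]  # which.max takes the first = alphabetical
}

#' Render a Contrast Hierarchical Alignment as monospaced text
#'
#' Produces the standard layout: a one-row score histogram (five-glyph ramp
#' over the normalised column heights), a dot row marking the selected
#' pattern positions, the query display sequences, the foreground consensus
#' with its weighted residue frequencies in integer tenths (see
#' [freq_digit()]), and the background consensus/frequency block. Effective
#' (weighted) and total sequence counts are shown in parentheses beside the
#' consensus labels. All rendered rows have equal character length.
#'
#' @param aln the `"msa"` the contrast was computed on.
#' @param result a `"contrast_result"` from [contrast_analysis()].
#' @param query_ids ordered ids of the display sequences (must be in
#'   `aln`).
#' @param window optional integer vector of length 2, first and last
#'   alignment column to render (default: all columns).
#' @return An object of class `"cha_document"`: list with `lines`
#'   (character vector of equal-width rows), `query_ids`, `window`,
#'   `width`.
#' @export
render_cha <- function(aln, result, query_ids, window = NULL) {
  missing <- setdiff(query_ids, aln$ids)
  if (length(missing)) stop("lookup error: unknown query id(s): ",
                            paste(missing, collapse = ", "))
  L <- n_columns(aln)
  if (is.null(window)) window <- c(1L, L)
  if (window[1] < 1L || window[2] > L || window[1] > window[2]) {
    stop("window outside alignment columns")
  }
  cols <- seq.int(window[1], window[2])
  m <- result$partition$membership
  wts <- result$weights$weights
  fore_ids <- names(m)[m == "fore"]
  back_ids <- names(m)[m == "back"]
  fore <- result$fore_profile
  back <- result$back_profile
  fore_cons <- vapply(cols, function(j) consensus_letter(fore$freq[j, ]),
                      character(1))
  back_cons <- vapply(cols, function(j) consensus_letter(back$freq[j, ]),
                      character(1))
  fore_top <- vapply(seq_along(cols), function(i) {
    j <- cols[i]
    if (fore_cons[i] == " ") NA_real_ else fore$freq[j, fore_cons[i]]
  }, numeric(1))
  back_top <- vapply(seq_along(cols), function(i) {
    j <- cols[i]
    if (back_cons[i] == " ") NA_real_ else back$freq[j, back_cons[i]]
  }, numeric(1))
  labels <- c("histogram", "pattern", query_ids,
              sprintf("conserved (%.1f, %d)", sum(wts[fore_ids]),
                      length(fore_ids)),
              "wt_res_freqs",
              sprintf("background (%.1f, %d)", sum(wts[back_ids]),
                      length(back_ids)),
              "bg_res_freqs")
  lw <- max(nchar(labels))
  row <- function(label, chars) {
    sprintf("%-*s  %s", lw, label, paste(chars, collapse = ""))
  }
  lines <- c(
    row("histogram", histogram_glyphs(result$histogram[cols])),
    row("pattern", ifelse(result$calls$selected[cols], "*", " ")))
  for (id in query_ids) lines <- c(lines, row(id, aln$mat[id, cols]))
  lines <- c(lines,
             row(sprintf("conserved (%.1f, %d)", sum(wts[fore_ids]),
                         length(fore_ids)), fore_cons),
             row("wt_res_freqs", freq_digit(fore_top)),
             row(sprintf("background (%.1f, %d)", sum(wts[back_ids]),
                         length(back_ids)), back_cons),
             row("bg_res_freqs", freq_digit(back_top)))
  structure(list(lines = lines, query_ids = query_ids,
                 window = as.integer(window),
                 width = unique(nchar(lines))),
            class = "cha_document")
}

#' @export
print.cha_document <- function(x, ...) {
  cat(x$lines, sep = "\n")
  invisible(x)
}

#' Write a rendered alignment to file
#'
#' @param doc a `"cha_document"` from [render_cha()].
#' @param path output path.
#' @param format `"text"` (default) or `"html"` (the same monospaced block
#'   wrapped in `<pre>`).
#' @return `path`, invisibly.
#' @export
write_cha <- function(doc, path, format = c("text", "html")) {
  format <- match.arg(format)
  if (format == "text") {
    writeLines(doc$lines, path)
  } else {
    esc <- gsub(">", "&gt;", gsub("<", "&lt;", gsub("&", "&amp;", doc$lines)))
    writeLines(c("<!DOCTYPE html><html><body><pre>", esc,
                 "</pre></body></html>"), path)
  }
  invisible(path)
}
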