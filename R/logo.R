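# Sequence-logo math: per-column residue counts, information content with
# the optional small-sample correction, and conserved-position reporting.

#' Per-column residue counts of a protein alignment
#'
#' @param alignment named character vector of equal-length aligned protein
#'   sequences (>= 2); residues over the 20-letter alphabet plus `-` for
#'   gaps.
#' @return object of class `alignment_profile`: a 21 x L count matrix
#'   (rows = residues plus `"-"`), with attributes `n_seq` and `n_col`.
#'   Each column sums to the number of sequences.
#' @export
column_profile <- function(alignment) {
  if (length(alignment) < 2) stop("need >= 2 sequences", call. = FALSE)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: unequal sequence lengths", call. = FALSE)
  chars <- do.call(rbind, strsplit(toupper(alignment), ""))
  letters21 <- c(AA20, "-")
  bad <- setdiff(unique(as.vector(chars)), letters21)
  if (length(bad))
    stop("unexpected alignment character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  counts <- apply(chars, 2, function(col)
    table(factor(col, levels = letters21)))
  counts <- matrix(as.integer(counts), nrow = length(letters21),
                   dimnames = list(letters21, NULL))
  structure(counts, class = "alignment_profile",
            n_seq = length(alignment), n_col = ncol(counts))
}

#' Per-column information content of an alignment profile
#'
#' `IC = log2(20) - H - e(n)`, where `H` is the Shannon entropy of the
#' gap-excluded residue frequencies, `n` the number of non-gap residues in
#' the column, and `e(n) = 19 / (2 ln(2) n)` the small-sample correction
#' when enabled. Values are floored at 0. All-gap columns get IC 0 and are
#' flagged; columns with more than 50% gaps are flagged `gappy`.
#'
#' @param profile an `alignment_profile`.
#' @param small_sample_correction apply `e(n)` (default `FALSE`).
#' @return numeric vector of bits per column, with attributes `all_gap` and
#'   `gappy` (logical vectors).
#' @export
information_content <- function(profile, small_sample_correction = FALSE) {
  stopifnot(inherits(profile, "alignment_profile"))
  counts <- unclass(profile)
  gap <- counts["-", ]
  res <- counts[AA20, , drop = FALSE]
  n <- colSums(res)
  ic <- vapply(seq_len(ncol(res)), function(j) {
    if (n[j] == 0) return(0)
    p <- res[, j] / n[j]
    p <- p[p > 0]
    h <- -sum(p * log2(p))
    e <- if (small_sample_correction) 19 / (2 * log(2) * n[j]) else 0
    max(0, log2(20) - h - e)
  }, numeric(1))
  attr(ic, "all_gap") <- n == 0
  attr(ic, "gappy") <- gap > (n + gap) / 2
  ic
}

#' Conserved positions of an alignment profile
#'
#' Columns whose modal gap-excluded residue frequency reaches
#' `min_fraction`; columns are reported 1-based.
#'
#' @param profile an `alignment_profile`.
#' @param min_fraction threshold in `(0, 1]`.
#' @return data.frame with `column` (1-based), `residue`, `fraction`.
#' @export
conserved_positions <- function(profile, min_fraction = 0.9) {
  stopifnot(inherits(profile, "alignment_profile"))
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must lie in (0, 1]", call. = FALSE)
  res <- unclass(profile)[AA20, , drop = FALSE]
  out <- lapply(seq_len(ncol(res)), function(j) {
    n <- sum(res[, j])
    if (n == 0) return(NULL)
    k <- which.max(res[, j])
    f <- res[k, j] / n
    if (f >= min_fraction)
      data.frame(column = j, residue = AA20[k], fraction = f)
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out))
    return(data.frame(column = integer(0), residue = character(0),
                      fraction = numeric(0)))
  do.call(rbind, out)
}

#' Bar plot of per-column information content
#'
#' Minimal graphical companion to the logo math: column IC as a bar chart
#' with the modal residue written above tall columns.
#'
#' @param profile an `alignment_profile`.
#' @param small_sample_correction passed to [information_content()].
#' @export
plot_information_content <- function(profile,
                                     small_sample_correction = FALSE) {
  ic <- information_content(profile, small_sample_correction)
  bp <- graphics::barplot(as.numeric(ic), names.arg = seq_along(ic), las = 2,
                          cex.names = 0.5, ylab = "bits",
                          ylim = c(0, log2(20) * 1.1))
  res <- unclass(profile)[AA20, , drop = FALSE]
  modal <- AA20[apply(res, 2, which.max)]
  tall <- ic > 0.75 * log2(20)
  if (any(tall))
    graphics::text(bp[tall], ic[tall] + 0.15, modal[tall], cex = 0.6)
  invisible(ic)
}
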