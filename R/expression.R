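# Expressed-set logic and the tissue/age/genotype partitions: per-group
# expressed counts, all-group intersections, group-specific transcripts,
# specificity shares, expression-breadth classes and heatmap transforms.
#
# An expression matrix is a nonnegative numeric matrix with transcript
# rownames and `"group:sample"` colnames (the group label before the first
# colon assigns each sample to a tissue/age/genotype group).

#' Group labels of an expression matrix's samples
#' @param matrix expression matrix with `"group:sample"` colnames.
#' @return character vector of group labels, one per column.
#' @export
sample_groups <- function(matrix) {
  cn <- colnames(matrix)
  if (is.null(cn) || !all(grepl(":", cn)))
    stop("expression matrix columns must be labelled 'group:sample'",
         call. = FALSE)
  sub(":.*$", "", cn)
}

validate_expression_matrix <- function(matrix) {
  if (is.null(rownames(matrix)))
    stop("expression matrix must have transcript rownames", call. = FALSE)
  if (any(matrix < 0))
    stop("expression matrix has negative values", call. = FALSE)
  invisible(sample_groups(matrix))
}

#' Transcripts expressed in one sample group
#'
#' A transcript is expressed in a group when its value is strictly greater
#' than `threshold` in at least one sample of the group.
#'
#' @param matrix expression matrix.
#' @param group group label.
#' @param threshold nonnegative expression cutoff (default 0).
#' @return character vector of transcript ids.
#' @export
expressed_set <- function(matrix, group, threshold = 0) {
  grp <- validate_expression_matrix(matrix)
  if (!group %in% grp) stop("unknown group: ", group, call. = FALSE)
  sub <- matrix[, grp == group, drop = FALSE]
  rownames(matrix)[apply(sub > threshold, 1, any)]
}

#' Venn partition of expressed transcripts across groups
#'
#' @param matrix expression matrix.
#' @param groups ordered group labels (default: all groups in column order).
#' @param threshold expression cutoff passed to [expressed_set()].
#' @return list with `per_group` (named counts), `intersection` (expressed in
#'   every group), `specific` (named counts of transcripts expressed in
#'   exactly that group), `union` (expressed anywhere), and `partition`
#'   (named counts over all 2^k - 1 nonempty membership patterns, names
#'   joined with `"+"`). The partition cells sum to `union`.
#' @export
group_venn <- function(matrix, groups = NULL, threshold = 0) {
  grp <- validate_expression_matrix(matrix)
  groups <- groups %||% unique(grp)
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  member <- sapply(groups, function(g)
    rownames(matrix) %in% expressed_set(matrix, g, threshold))
  member <- matrix(member, nrow = nrow(matrix),
                   dimnames = list(rownames(matrix), groups))
  in_any <- rowSums(member) > 0
  pattern <- apply(member[in_any, , drop = FALSE], 1, function(row)
    paste(groups[row], collapse = "+"))
  partition <- table(pattern)
  specific <- stats::setNames(vapply(groups, function(g)
    sum(pattern == g), integer(1)), groups)
  list(per_group = colSums(member),
       intersection = sum(rowSums(member) == length(groups)),
       specific = specific,
       union = sum(in_any),
       partition = stats::setNames(as.integer(partition), names(partition)))
}

#' Share of group-specific transcripts attributable to one group
#'
#' @param specific_counts named counts of group-specific transcripts.
#' @param focus the group of interest.
#' @param decimals decimal places (default 0).
#' @return half-up-rounded percentage of `specific_counts[focus]` among all
#'   group-specific transcripts.
#' @export
specificity_share <- function(specific_counts, focus, decimals = 0) {
  if (!focus %in% names(specific_counts))
    stop("focus group not present: ", focus, call. = FALSE)
  total <- sum(specific_counts)
  if (total == 0) stop("all specific counts are zero", call. = FALSE)
  unname(round_half_up(100 * specific_counts[[focus]] / total, decimals))
}

#' Expression-breadth classes across tissue groups
#'
#' Partitions the expressed transcripts into those expressed in every
#' tissue, in exactly one tissue (with the tissue identified), and in
#' several.
#'
#' @param matrix expression matrix over tissue groups.
#' @param threshold expression cutoff.
#' @return list with `n_expressed`, `all_tissues`, `single_tissue`,
#'   `multiple` counts and `single_by_tissue` (named counts of the
#'   single-tissue class by tissue).
#' @export
tissue_breadth <- function(matrix, threshold = 0) {
  grp <- validate_expression_matrix(matrix)
  tissues <- unique(grp)
  if (length(tissues) < 2) stop("need >= 2 tissue groups", call. = FALSE)
  member <- sapply(tissues, function(g)
    rownames(matrix) %in% expressed_set(matrix, g, threshold))
  member <- matrix(member, nrow = nrow(matrix),
                   dimnames = list(rownames(matrix), tissues))
  breadth <- rowSums(member)
  single <- breadth == 1
  single_by <- stats::setNames(integer(length(tissues)), tissues)
  if (any(single)) {
    hits <- apply(member[single, , drop = FALSE], 1, function(r) tissues[r])
    tb <- table(hits)
    single_by[names(tb)] <- as.integer(tb)
  }
  list(n_expressed = sum(breadth > 0),
       all_tissues = sum(breadth == length(tissues)),
       single_tissue = sum(single),
       multiple = sum(breadth > 1 & breadth < length(tissues)),
       single_by_tissue = single_by)
}

#' Coefficient of variation of per-group expressed counts
#'
#' With each genotype treated as a single-sample group, this is the CV of
#' the number of expressed transcripts per genotype (sample sd over mean).
#'
#' @param matrix expression matrix.
#' @param threshold expression cutoff.
#' @return list with `counts` (per group), `mean`, `cv`.
#' @export
expressed_count_cv <- function(matrix, threshold = 0) {
  grp <- validate_expression_matrix(matrix)
  groups <- unique(grp)
  counts <- vapply(groups, function(g)
    length(expressed_set(matrix, g, threshold)), integer(1))
  list(counts = counts, mean = mean(counts),
       cv = stats::sd(counts) / mean(counts))
}

#' Log-transform (and optionally row-scale) an expression matrix
#'
#' @param matrix expression matrix.
#' @param log_base base of the logarithm (default 2).
#' @param pseudo pseudo-count added before the log (must be > 0).
#' @param row_scale when `TRUE`, each row is z-scaled after the log
#'   transform; zero-variance rows map to all-zero rows.
#' @return transformed matrix with the same dimnames.
#' @export
heatmap_prep <- function(matrix, log_base = 2, pseudo = 1,
                         row_scale = FALSE) {
  if (pseudo <= 0) stop("pseudo must be > 0", call. = FALSE)
  out <- log(matrix + pseudo, base = log_base)
  if (row_scale) {
    out <- t(apply(out, 1, function(r) {
      s <- stats::sd(r)
      if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }))
    dimnames(out) <- dimnames(matrix)
  }
  out
}
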