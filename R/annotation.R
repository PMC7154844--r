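# Venn/category bookkeeping over a GO-annotation table. Annotation itself
# (BLAST, term mapping) happens upstream; this layer only counts.

#' Venn partition of transcripts over the three GO namespaces
#'
#' @param table data.frame with at least `transcript_id` and `namespace`
#'   columns; `namespace` must be one of `"BP"`, `"MF"`, `"CC"`. A transcript
#'   may have several rows (one per term/namespace) or none (unannotated).
#' @param universe character vector of all transcript ids under study; every
#'   table transcript must be in it (guards against identifier drift).
#' @return list with `per_namespace` (named counts), `cells` (the 8-cell
#'   membership partition, names like `"MF+CC"`, including `"none"`),
#'   `annotated` and `unannotated` totals. The cells sum to
#'   `length(universe)`.
#' @export
venn_namespace_counts <- function(table, universe) {
  if (!length(universe)) stop("universe must be nonempty", call. = FALSE)
  stopifnot(all(c("transcript_id", "namespace") %in% names(table)))
  bad_ns <- setdiff(unique(table$namespace), c("BP", "MF", "CC"))
  if (length(bad_ns))
    stop("unknown namespace: ", paste(bad_ns, collapse = ", "), call. = FALSE)
  stray <- setdiff(unique(table$transcript_id), universe)
  if (length(stray))
    stop("table transcript(s) not in universe: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  ns_order <- c("MF", "CC", "BP")
  member <- sapply(ns_order, function(ns)
    universe %in% table$transcript_id[table$namespace == ns])
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, ns_order))
  pattern <- apply(member, 1, function(row) {
    hit <- ns_order[row]
    if (!length(hit)) "none" else paste(hit, collapse = "+")
  })
  cell_names <- c("MF", "CC", "BP", "MF+CC", "MF+BP", "CC+BP",
                  "MF+CC+BP", "none")
  cells <- stats::setNames(integer(length(cell_names)), cell_names)
  tab <- table(pattern)
  cells[names(tab)] <- as.integer(tab)
  list(per_namespace = colSums(member),
       cells = cells,
       annotated = sum(pattern != "none"),
       unannotated = unname(cells["none"]))
}

#' Rounded percentages for category counts
#'
#' Percentages are rounded half-up at the last kept digit, which reproduces
#' printed (count, percent) pairs such as 90/99 -> 91 and 9/96 -> 9.4.
#'
#' @param counts numeric vector (named vectors keep their names).
#' @param denominator positive count to divide by.
#' @param decimals decimal places to keep (default 0).
#' @return vector of percentages on the 0-100 scale.
#' @export
category_percentages <- function(counts, denominator, decimals = 0) {
  if (!is.numeric(denominator) || denominator <= 0)
    stop("denominator must be > 0", call. = FALSE)
  round_half_up(100 * counts / denominator, decimals)
}
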