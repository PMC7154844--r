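# Distance-based tree building and clade/group assignment over SBP-domain
# alignments: p-distances, Saitou-Nei neighbor joining, and nearest-reference
# group labelling with a monophyly report.

#' Pairwise p-distance matrix from an aligned protein set
#'
#' For each pair, the fraction of differing sites over the columns where
#' neither sequence has a gap (`-`).
#'
#' @param alignment named character vector of equal-length aligned sequences
#'   (>= 3).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(alignment) {
  if (length(alignment) < 3) stop("need >= 3 sequences", call. = FALSE)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1)
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  if (is.null(names(alignment)))
    names(alignment) <- paste0("seq", seq_along(alignment))
  chars <- do.call(rbind, strsplit(toupper(alignment), ""))
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(ok))
        stop(sprintf("no comparable columns for pair (%s, %s)",
                     names(alignment)[i], names(alignment)[j]),
             call. = FALSE)
      d[i, j] <- d[j, i] <- mean(chars[i, ok] != chars[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing the Q
#' criterion is joined (ties broken by the smallest row/column index pair),
#' branch lengths follow the standard formulas, and a negative branch length
#' is clamped to zero with the deficit moved to its sister branch so the
#' joined pair's path length is preserved. The final three lineages are
#' joined at an unresolved internal node, giving an unrooted binary tree
#' with `2n - 3` branches.
#'
#' @param d symmetric distance matrix with zero diagonal, n >= 4, with
#'   dimnames.
#' @return an [ape::read.tree()] `phylo` object (unrooted).
#' @export
neighbor_joining <- function(d) {
  if (!isSymmetric(unname(as.matrix(d)), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  d <- as.matrix(d)
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  n <- nrow(d)
  if (n < 4) stop("need >= 4 taxa", call. = FALSE)
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  frags <- labels  # newick fragment per active lineage
  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest (i, j) pair among the minima
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    lens <- clamp_pair(li, lj)
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frags[i], lens[1],
                        frags[j], lens[2])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    du <- du[-c(i, j)]
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, du), c(du, 0))
    frags <- c(frags[-c(i, j)], new_frag)
  }
  # join the last three lineages at one internal node
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  lens <- pmax(c(l1, l2, l3), 0)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    frags[1], lens[1], frags[2], lens[2], frags[3], lens[3])
  ape::read.tree(text = newick)
}

#' Assign unlabeled leaves to groups by nearest labeled leaf
#'
#' Each query leaf receives the group of its nearest reference leaf by
#' patristic (path-length) distance; ties are broken by the
#' lexicographically smallest reference label and flagged ambiguous. Group
#' monophyly is reported under midpoint rooting.
#'
#' @param tree a `phylo` tree.
#' @param references named character vector: names are reference leaf
#'   labels present in the tree, values are group labels. Every group must
#'   have >= 1 reference.
#' @return list with `assignments` (data.frame: `leaf`, `group`,
#'   `nearest_ref`, `distance`, `ambiguous`) and `monophyletic` (named
#'   logical per group, over references plus assigned queries, midpoint
#'   rooted).
#' @export
assign_groups <- function(tree, references) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(references)) || !length(references))
    stop("references must be a named vector (leaf -> group)", call. = FALSE)
  missing_ref <- setdiff(names(references), tree$tip.label)
  if (length(missing_ref))
    stop("reference leaves not in tree: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  pd <- ape::cophenetic.phylo(tree)
  queries <- setdiff(tree$tip.label, names(references))
  refs <- sort(names(references))
  rows <- lapply(queries, function(q) {
    dist_to_refs <- pd[q, refs]
    best <- min(dist_to_refs)
    hits <- refs[dist_to_refs <= best + 1e-12]
    data.frame(leaf = q, group = unname(references[[hits[1]]]),
               nearest_ref = hits[1], distance = best,
               ambiguous = length(unique(references[hits])) > 1,
               stringsAsFactors = FALSE)
  })
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(leaf = character(0), group = character(0),
               nearest_ref = character(0), distance = numeric(0),
               ambiguous = logical(0))
  rooted <- phangorn::midpoint(tree)
  groups <- unique(references)
  mono <- vapply(groups, function(g) {
    leaves <- c(names(references)[references == g],
                assignments$leaf[assignments$group == g])
    if (length(leaves) < 2) return(TRUE)
    ape::is.monophyletic(rooted, leaves)
  }, logical(1))
  list(assignments = assignments,
       monophyletic = stats::setNames(mono, groups))
}
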