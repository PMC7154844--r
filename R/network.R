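# Spearman co-expression networks: correlation + p-value machinery,
# thresholded graph construction, the p-value threshold ladder, Markov
# clustering, and the 2/3-subsampling x 20-replicate statistics with
# random-background negative controls.

#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks).
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return rho in `[-1, 1]`; `NA` with a warning when either vector has zero
#'   variance (such transcripts are excluded from graphs).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero-variance vector; rho undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Two-sided p-value for a Spearman correlation
#'
#' Default is the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' with `n - 2` degrees of freedom; `|rho| = 1` gives p = 0. With
#' `exact = TRUE` (tie-free ranks, n <= 8) the p-value is computed by full
#' enumeration of the n! rank permutations,
#' `p = P(|rho_null| >= |rho_obs|)`. The t approximation can deviate from
#' the enumerated p by up to about 0.05 at n = 6 for mid-range rho; see the
#' methods vignette.
#'
#' @param rho correlation(s) in `[-1, 1]` (vectorized).
#' @param n number of paired samples (>= 4).
#' @param exact enumerate all rank permutations (n <= 8, assumes no ties).
#' @return two-sided p-value(s).
#' @export
rho_pvalue <- function(rho, n, exact = FALSE) {
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (any(abs(rho) > 1 + 1e-12, na.rm = TRUE))
    stop("|rho| must be <= 1", call. = FALSE)
  if (exact) {
    if (n > 8) stop("exact enumeration supported only for n <= 8",
                    call. = FALSE)
    null_rhos <- spearman_null_rhos(n)
    return(vapply(rho, function(r) {
      if (is.na(r)) NA_real_ else mean(abs(null_rhos) >= abs(r) - 1e-9)
    }, numeric(1)))
  }
  p <- rep(NA_real_, length(rho))
  exact1 <- !is.na(rho) & abs(rho) >= 1 - 1e-12
  p[exact1] <- 0
  ok <- !is.na(rho) & !exact1
  tval <- rho[ok] * sqrt((n - 2) / (1 - rho[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tval), df = n - 2)
  p
}

# Null Spearman rho values over all n! rank permutations (cached per n).
spearman_null_rhos <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      perm_all <- function(v) {
        if (length(v) == 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
          for (rest in perm_all(v[-i]))
            out[[length(out) + 1L]] <- c(v[i], rest)
        out
      }
      x <- seq_len(n)
      cache[[key]] <<- vapply(perm_all(x), function(p) stats::cor(x, p),
                              numeric(1))
    }
    cache[[key]]
  }
})

# All-pairs Spearman rho and p for a set of transcripts; zero-variance rows
# dropped with a warning. Returns a data.frame of pairs (a < b in the row
# order of `ids`).
pairwise_spearman <- function(matrix, ids) {
  sub <- matrix[ids, , drop = FALSE]
  v <- apply(sub, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance transcript(s) dropped before ",
            "correlation")
    sub <- sub[v > 0, , drop = FALSE]
  }
  m <- nrow(sub)
  if (m < 2)
    return(data.frame(a = character(0), b = character(0),
                      rho = numeric(0), p = numeric(0)))
  rho <- stats::cor(t(sub), method = "spearman")
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  data.frame(a = rownames(sub)[ut[, 1]], b = rownames(sub)[ut[, 2]],
             rho = rho[ut], p = rho_pvalue(rho[ut], ncol(sub)),
             stringsAsFactors = FALSE)
}

#' Build a thresholded Spearman co-expression graph
#'
#' All pairwise Spearman correlations among the requested transcripts are
#' computed; pairs with `p <= alpha` become edges. Transcripts with no
#' surviving edge are not counted as nodes, so node counts fall as `alpha`
#' shrinks.
#'
#' @param matrix expression matrix (transcripts x samples, >= 3 samples).
#' @param transcripts transcript ids to correlate (default: all rows).
#' @param alpha significance threshold on the raw (uncorrected) p-value.
#' @return object of class `coexpression_graph`: list with `nodes`, `edges`
#'   (data.frame `a`, `b`, `rho`, `p`), `alpha`, `n_samples`.
#' @export
build_network <- function(matrix, transcripts = rownames(matrix),
                          alpha = 0.05) {
  validate_expression_matrix(matrix)
  missing <- setdiff(transcripts, rownames(matrix))
  if (length(missing))
    stop("transcripts not in matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  if (ncol(matrix) < 3) stop("need >= 3 samples", call. = FALSE)
  pairs <- pairwise_spearman(matrix, transcripts)
  edges <- pairs[!is.na(pairs$p) & pairs$p <= alpha, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$a, edges$b))),
                 edges = edges, alpha = alpha, n_samples = ncol(matrix)),
            class = "coexpression_graph")
}

#' @export
print.coexpression_graph <- function(x, ...) {
  cat(sprintf("coexpression graph: %d nodes, %d edges (alpha = %g, n = %d)\n",
              length(x$nodes), nrow(x$edges), x$alpha, x$n_samples))
  invisible(x)
}

#' Mean node degree from node and edge counts
#' @param n_nodes,n_edges graph size counts (`n_nodes` > 0).
#' @return `2 * n_edges / n_nodes`.
#' @export
mean_degree <- function(n_nodes, n_edges) {
  if (n_nodes <= 0) stop("graph has no nodes", call. = FALSE)
  2 * n_edges / n_nodes
}

#' Average connectivity (mean node degree) of a co-expression graph
#' @param graph a `coexpression_graph`.
#' @return mean degree over the graph's nodes.
#' @export
average_connectivity <- function(graph) {
  stopifnot(inherits(graph, "coexpression_graph"))
  mean_degree(length(graph$nodes), nrow(graph$edges))
}

#' Convert a co-expression graph to an igraph object
#' @param graph a `coexpression_graph`.
#' @return undirected igraph with `rho` and `p` edge attributes.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "coexpression_graph"))
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = graph$nodes)
}

#' Markov clustering (MCL) of a co-expression graph
#'
#' Builds the column-stochastic adjacency matrix (unweighted edges plus
#' self-loops), then alternates expansion (matrix squaring) and inflation
#' (elementwise power and column renormalization), pruning entries below
#' `prune`, until the largest entry change falls below `tol` or `max_iter`
#' iterations. Clusters are the connected components of the converged
#' matrix's nonzero pattern; every node lands in exactly one cluster and
#' clusters never span connected components of the input graph.
#'
#' @param graph a `coexpression_graph` with >= 1 node.
#' @param inflation inflation exponent (> 1; default 2).
#' @param prune entries below this are zeroed each iteration.
#' @param tol convergence tolerance on the max entry change.
#' @param max_iter iteration cap; non-convergence returns the current
#'   clustering with attribute `converged = FALSE` and a warning.
#' @return list of character vectors (cluster memberships), largest first,
#'   with attribute `converged`.
#' @export
mcl_cluster <- function(graph, inflation = 2, prune = 1e-6, tol = 1e-8,
                        max_iter = 100L) {
  stopifnot(inherits(graph, "coexpression_graph"))
  if (inflation <= 1) stop("inflation must be > 1", call. = FALSE)
  nodes <- graph$nodes
  if (!length(nodes)) stop("empty graph", call. = FALSE)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ia <- match(graph$edges$a, nodes)
  ib <- match(graph$edges$b, nodes)
  A[cbind(ia, ib)] <- 1
  A[cbind(ib, ia)] <- 1
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    M2 <- sweep(M2, 2, cs, "/")
    if (max(abs(M2 - M)) < tol) {
      M <- M2
      converged <- TRUE
      break
    }
    M <- M2
  }
  if (!converged) warning("MCL did not converge within ", max_iter,
                          " iterations; returning current clustering")
  supp <- (M > prune) | (t(M) > prune)
  g <- igraph::graph_from_adjacency_matrix(supp * 1, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  clusters <- split(nodes, comp)
  clusters <- clusters[order(-lengths(clusters))]
  names(clusters) <- NULL
  attr(clusters, "converged") <- converged
  clusters
}

#' Node/edge counts of focal and control networks over a p-value ladder
#'
#' Correlations are computed once per transcript set; edges are then
#' re-thresholded at every alpha, so counts are exactly non-increasing as
#' alpha decreases (asserted).
#'
#' @param matrix expression matrix.
#' @param focal_ids,control_ids disjoint transcript sets.
#' @param alphas strictly decreasing significance thresholds.
#' @return data.frame of class `ladder_result`: `alpha`, `set`
#'   (`"focal"`/`"control"`), `n_nodes`, `n_edges`.
#' @export
pvalue_ladder <- function(matrix, focal_ids, control_ids,
                          alphas = c(0.05, 10^-(2:8))) {
  if (any(diff(alphas) >= 0))
    stop("alphas must be strictly decreasing", call. = FALSE)
  if (length(intersect(focal_ids, control_ids)))
    stop("focal and control sets overlap", call. = FALSE)
  count_one <- function(ids, set) {
    pairs <- pairwise_spearman(matrix, ids)
    out <- lapply(alphas, function(a) {
      sel <- !is.na(pairs$p) & pairs$p <= a
      data.frame(alpha = a, set = set,
                 n_nodes = length(unique(c(pairs$a[sel], pairs$b[sel]))),
                 n_edges = sum(sel), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  res <- rbind(count_one(focal_ids, "focal"),
               count_one(control_ids, "control"))
  for (s in unique(res$set)) {
    sub <- res[res$set == s, ]
    stopifnot(all(diff(sub$n_edges) <= 0), all(diff(sub$n_nodes) <= 0))
  }
  class(res) <- c("ladder_result", "data.frame")
  res
}

#' Subsampling replicate statistics with size-matched random controls
#'
#' Per replicate, `floor(fraction * length(focal_ids))` focal transcripts
#' are drawn without replacement, together with an equal number of controls
#' from `control_pool`; networks are thresholded over the alpha ladder and
#' node/edge counts recorded. The default fraction 2/3 with 20 repetitions
#' mirrors the subsampling design the package targets.
#'
#' @param matrix expression matrix.
#' @param focal_ids focal transcript set.
#' @param control_pool pool of background transcripts for the negative
#'   control (disjoint from `focal_ids`).
#' @param fraction subsample fraction of the focal set (default 2/3).
#' @param reps number of repetitions (default 20).
#' @param alphas strictly decreasing thresholds.
#' @param seed integer seed; draws use a dedicated stream so results are
#'   reproducible.
#' @return list of class `subsample_summary`: `summary` (data.frame with
#'   per-alpha, per-set mean and sd of node and edge counts), `replicates`
#'   (per-replicate counts), `k` (subset size), `reps`, `seed`.
#' @export
subsample_null <- function(matrix, focal_ids, control_pool,
                           fraction = 2 / 3, reps = 20L,
                           alphas = c(0.05, 10^-(2:8)), seed = 1L) {
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (any(diff(alphas) >= 0))
    stop("alphas must be strictly decreasing", call. = FALSE)
  if (length(intersect(focal_ids, control_pool)))
    stop("focal set and control pool overlap", call. = FALSE)
  k <- floor(fraction * length(focal_ids))
  if (k < 2) stop("subsample size < 2", call. = FALSE)
  if (length(control_pool) < k)
    stop("control pool too small for size-matched draws", call. = FALSE)
  reps_out <- with_seed(stream_seed(seed, "subsample"), {
    out <- vector("list", reps)
    for (r in seq_len(reps)) {
      foc <- sample(focal_ids, k)
      ctl <- sample(control_pool, k)
      lad <- suppressWarnings(pvalue_ladder(matrix, foc, ctl, alphas))
      lad$rep <- r
      out[[r]] <- as.data.frame(lad)
    }
    do.call(rbind, out)
  })
  agg <- do.call(rbind, lapply(split(
    reps_out, list(reps_out$alpha, reps_out$set), drop = TRUE),
    function(d) data.frame(
      alpha = d$alpha[1], set = d$set[1],
      mean_nodes = mean(d$n_nodes), sd_nodes = stats::sd(d$n_nodes),
      mean_edges = mean(d$n_edges), sd_edges = stats::sd(d$n_edges),
      stringsAsFactors = FALSE)))
  agg$sd_nodes[is.na(agg$sd_nodes)] <- 0
  agg$sd_edges[is.na(agg$sd_edges)] <- 0
  agg <- agg[order(agg$set, -agg$alpha), ]
  rownames(agg) <- NULL
  structure(list(summary = agg, replicates = reps_out, k = k,
                 reps = reps, seed = seed),
            class = "subsample_summary")
}

#' Write a graph's edge list as TSV
#' @param graph a `coexpression_graph`.
#' @param path output file.
#' @export
write_edge_list <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a graph as GraphML
#' @param graph a `coexpression_graph`.
#' @param path output file.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Plot ladder curves with error bars
#'
#' Simple base-graphics rendering of a [subsample_null()] summary: mean node
#' or edge counts against `-log10(alpha)` for the focal and control sets,
#' with +/- 1 sd error bars.
#'
#' @param summary a `subsample_summary`.
#' @param what `"edges"` or `"nodes"`.
#' @export
plot_ladder <- function(summary, what = c("edges", "nodes")) {
  what <- match.arg(what)
  s <- summary$summary
  mcol <- paste0("mean_", what)
  scol <- paste0("sd_", what)
  x <- -log10(s$alpha)
  graphics::plot(range(x), range(c(s[[mcol]] - s[[scol]], s[[mcol]] + s[[scol]])),
       type = "n", xlab = "-log10(alpha)", ylab = paste("mean", what))
  for (set in unique(s$set)) {
    d <- s[s$set == set, ]
    xi <- -log10(d$alpha)
    graphics::lines(xi, d[[mcol]], type = "b",
          col = if (set == "focal") "firebrick" else "grey40")
    suppressWarnings(graphics::arrows(xi, d[[mcol]] - d[[scol]],
                            xi, d[[mcol]] + d[[scol]],
                            angle = 90, code = 3, length = 0.03,
                            col = if (set == "focal") "firebrick" else "grey40"))
  }
  graphics::legend("topright", legend = unique(s$set), lty = 1,
         col = c("firebrick", "grey40")[seq_along(unique(s$set))])
  invisible(summary)
}
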