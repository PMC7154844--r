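# Shared fixtures built in code.

# Small multi-group sample layout used across expression/network tests.
groups4 <- function(n_per = 10L) {
  stats::setNames(rep(n_per, 4), paste0("g", 1:4))
}

# Expression matrix with explicit values: rows named, columns "group:sample".
manual_matrix <- function(values, transcript_ids, groups) {
  m <- matrix(values, nrow = length(transcript_ids), byrow = TRUE)
  dimnames(m) <- list(transcript_ids,
                      paste0(groups, ":", "s", seq_along(groups)))
  m
}

# A coexpression_graph built directly from an edge list (for graph-metric
# and clustering tests that do not need correlation machinery).
graph_from_edges <- function(edges, alpha = 0.05, n_samples = 14L) {
  edges$rho <- edges$rho %||% rep(0.9, nrow(edges))
  edges$p <- edges$p %||% rep(1e-4, nrow(edges))
  structure(list(nodes = sort(unique(c(edges$a, edges$b))), edges = edges,
                 alpha = alpha, n_samples = n_samples),
            class = "coexpression_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clique_edges <- function(ids) {
  cmb <- utils::combn(ids, 2)
  data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
}

# Exhaustive oracle: enumerate substitution-order pathways by hand for one
# codon pair and average syn/nonsyn counts, excluding stop pathways.
oracle_diffs <- function(c1, c2) {
  code <- splfam:::codon_table()
  n1 <- strsplit(c1, "")[[1]]; n2 <- strsplit(c2, "")[[1]]
  pos <- which(n1 != n2)
  if (!length(pos)) return(c(sd = 0, nd = 0))
  orders <- splfam:::perms(pos)
  walk <- function(ord, allow) {
    cur <- n1; sd <- 0; nd <- 0
    for (p in ord) {
      before <- code[[paste(cur, collapse = "")]]
      cur[p] <- n2[p]
      after <- code[[paste(cur, collapse = "")]]
      if (after == "*" && !allow) return(NULL)
      if (after == before) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(orders, walk, allow = FALSE))
  if (!length(res)) res <- lapply(orders, walk, allow = TRUE)
  colMeans(do.call(rbind, res))
}

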