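# Spearman machinery, graph construction, MCL, ladders, subsampling.

test_that("spearman rho matches a brute-force rank-then-Pearson oracle", {
  expect_equal(spearman_rho(1:10, 1:10), 1)
  expect_equal(spearman_rho(1:10, 10:1), -1)
  set.seed(3)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    x <- sample(round(rnorm(n), 1), n, replace = TRUE)  # ties likely
    y <- sample(round(rnorm(n), 1), n, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    rx <- rank(x); ry <- rank(y)
    oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(spearman_rho(x, y), oracle, tolerance = 1e-12)
  }
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "zero-variance")
  expect_true(is.na(r))
  expect_error(spearman_rho(1:3, 1:4), "length")
})

test_that("rho p-values follow the t approximation and its limits", {
  expect_equal(rho_pvalue(0, 10), 1)
  expect_equal(rho_pvalue(1, 5), 0)
  expect_equal(rho_pvalue(-1, 20), 0)
  expect_error(rho_pvalue(0.5, 3), "n >= 4")
  expect_error(rho_pvalue(1.5, 10), "rho")
})

test_that("exact mode reproduces the full n! permutation enumeration", {
  # independent oracle: enumerate all 720 rank permutations directly
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  x <- 1:6
  null_rhos <- vapply(perms(x), function(p) cor(x, p), numeric(1))
  grid <- sort(unique(abs(null_rhos)))
  for (obs in grid) {
    p_oracle <- mean(abs(null_rhos) >= obs - 1e-12)
    expect_equal(rho_pvalue(obs, 6, exact = TRUE), p_oracle,
                 tolerance = 1e-12)
    # t approximation tracks the enumerated p over the whole grid
    expect_lt(abs(rho_pvalue(obs, 6) - p_oracle), 0.05)
  }
  expect_error(rho_pvalue(0.5, 9, exact = TRUE), "n <= 8")
})

test_that("build_network recovers a planted block as one component", {
  cfg <- sim_config(n_spl = 12, n_background = 0,
                    samples_per_group = groups4(10),
                    block_spec = list(c(6, 0.95)),
                    specificity_spec = integer(), seed = 5)
  sim <- simulate_expression(cfg)
  g <- suppressWarnings(build_network(sim$matrix, alpha = 0.05))
  block <- sim$truth$transcript_id[!is.na(sim$truth$block)]
  ig <- as_igraph(g)
  comp <- igraph::components(ig)$membership
  expect_true(all(block %in% names(comp)))
  expect_equal(length(unique(comp[block])), 1)
  # alpha = 0: no edges at all
  g0 <- suppressWarnings(build_network(sim$matrix, alpha = 0))
  expect_equal(nrow(g0$edges), 0)
  expect_equal(length(g0$nodes), 0)
})

test_that("independent transcripts yield ~ alpha * C(m,2) edges", {
  edge_counts <- vapply(1:30, function(s) {
    cfg <- sim_config(n_spl = 12, n_background = 0,
                      samples_per_group = groups4(10),
                      block_spec = list(), specificity_spec = integer(),
                      dropout_rate = 0, seed = 100 + s)
    m <- simulate_expression(cfg)$matrix
    nrow(build_network(m, alpha = 0.05)$edges)
  }, numeric(1))
  expected <- 0.05 * choose(12, 2)
  se <- sqrt(0.05 * 0.95 * choose(12, 2) / 30)
  expect_lt(abs(mean(edge_counts) - expected), 3 * se + 0.2)
})

test_that("average connectivity reproduces printed-count arithmetic", {
  expect_equal(round(mean_degree(96, 527), 3), 10.979)
  expect_equal(round(mean_degree(90, 409), 3), 9.089)
  tri <- graph_from_edges(data.frame(a = c("x", "y", "x"),
                                     b = c("y", "z", "z")))
  expect_equal(average_connectivity(tri), 2)
  empty <- graph_from_edges(data.frame(a = character(0), b = character(0),
                                       rho = numeric(0), p = numeric(0)))
  expect_error(average_connectivity(empty), "no nodes")
})

test_that("degree identity holds on constructed graphs", {
  cfg <- sim_config(n_spl = 20, n_background = 0,
                    samples_per_group = groups4(8),
                    block_spec = list(c(8, 0.9)),
                    specificity_spec = integer(), seed = 2)
  m <- simulate_expression(cfg)$matrix
  g <- suppressWarnings(build_network(m, alpha = 0.05))
  ig <- as_igraph(g)
  expect_equal(sum(igraph::degree(ig)), 2 * nrow(g$edges))
  expect_true(all(g$edges$p <= g$alpha))
  expect_false(any(g$edges$a == g$edges$b))
})

test_that("MCL separates cliques and splits barbells at the bridge", {
  two <- rbind(clique_edges(paste0("a", 1:5)), clique_edges(paste0("b", 1:5)))
  cl <- mcl_cluster(graph_from_edges(two))
  expect_equal(length(cl), 2)
  expect_setequal(cl[[1]], paste0(substr(cl[[1]][1], 1, 1), 1:5))
  one <- clique_edges(paste0("k", 1:6))
  expect_equal(length(mcl_cluster(graph_from_edges(one))), 1)
  barbell <- rbind(two, data.frame(a = "a1", b = "b1"))
  clb <- mcl_cluster(graph_from_edges(barbell), inflation = 2)
  expect_equal(length(clb), 2)
  expect_setequal(clb[[c(which(vapply(clb, function(x) "a1" %in% x,
                                      logical(1))))]], paste0("a", 1:5))
  # every node in exactly one cluster
  expect_setequal(unlist(clb), unique(c(barbell$a, barbell$b)))
  expect_equal(anyDuplicated(unlist(clb)), 0)
  expect_error(mcl_cluster(graph_from_edges(one), inflation = 1), "inflation")
})

test_that("MCL clusters never span connected components", {
  set.seed(17)
  for (i in 1:20) {
    e1 <- clique_edges(paste0("p", 1:sample(3:6, 1)))
    e2 <- clique_edges(paste0("q", 1:sample(3:6, 1)))
    keep1 <- sample(nrow(e1), max(2, nrow(e1) - 2))
    g <- graph_from_edges(rbind(e1[keep1, ], e2))
    cl <- mcl_cluster(g)
    for (cluster in cl) {
      pref <- unique(substr(cluster, 1, 1))
      expect_equal(length(pref), 1)
    }
    expect_setequal(unlist(cl), g$nodes)
  }
})

test_that("ladder counts are monotone and consistent with build_network", {
  cfg <- sim_config(n_spl = 20, n_background = 40,
                    samples_per_group = groups4(8),
                    block_spec = list(c(8, 0.9)),
                    specificity_spec = integer(), seed = 19)
  sim <- simulate_expression(cfg)
  spl <- sim$truth$transcript_id[sim$truth$role != "background"]
  bg <- sim$truth$transcript_id[sim$truth$role == "background"]
  lad <- suppressWarnings(
    pvalue_ladder(sim$matrix, spl, bg, alphas = c(0.05, 1e-3, 1e-8)))
  for (s in c("focal", "control")) {
    sub <- lad[lad$set == s, ]
    expect_true(all(diff(sub$n_nodes) <= 0))
    expect_true(all(diff(sub$n_edges) <= 0))
  }
  # single-alpha ladder equals the direct graph counts
  one <- suppressWarnings(pvalue_ladder(sim$matrix, spl, bg, alphas = 0.05))
  g <- suppressWarnings(build_network(sim$matrix, spl, alpha = 0.05))
  expect_equal(one$n_edges[one$set == "focal"], nrow(g$edges))
  expect_equal(one$n_nodes[one$set == "focal"], length(g$nodes))
  expect_error(pvalue_ladder(sim$matrix, spl, spl[1], alphas = 0.05),
               "overlap")
  expect_error(pvalue_ladder(sim$matrix, spl, bg, alphas = c(0.01, 0.05)),
               "decreasing")
})

test_that("planted focal structure beats controls at small alphas", {
  wins <- vapply(1:10, function(s) {
    cfg <- sim_config(n_spl = 20, n_background = 40,
                      samples_per_group = groups4(8),
                      block_spec = list(c(10, 0.95), c(6, 0.9)),
                      specificity_spec = integer(), seed = 300 + s)
    sim <- simulate_expression(cfg)
    spl <- sim$truth$transcript_id[sim$truth$role != "background"]
    bg <- sim$truth$transcript_id[sim$truth$role == "background"]
    lad <- suppressWarnings(
      pvalue_ladder(sim$matrix, spl, bg, alphas = c(0.05, 1e-3, 1e-5)))
    small <- lad[lad$alpha <= 1e-3, ]
    all(small$n_edges[small$set == "focal"] >=
          small$n_edges[small$set == "control"])
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("subsampling is reproducible and degenerates to the full graph", {
  cfg <- sim_config(n_spl = 15, n_background = 30,
                    samples_per_group = groups4(8),
                    block_spec = list(c(6, 0.9)),
                    specificity_spec = integer(), seed = 23)
  sim <- simulate_expression(cfg)
  spl <- sim$truth$transcript_id[sim$truth$role != "background"]
  bg <- sim$truth$transcript_id[sim$truth$role == "background"]
  s1 <- subsample_null(sim$matrix, spl, bg, reps = 5,
                       alphas = c(0.05, 1e-3), seed = 7)
  s2 <- subsample_null(sim$matrix, spl, bg, reps = 5,
                       alphas = c(0.05, 1e-3), seed = 7)
  expect_identical(s1$summary, s2$summary)
  expect_equal(s1$k, floor(2 / 3 * length(spl)))
  expect_true(all(s1$summary$sd_nodes >= 0))
  # fraction 1, one rep: focal means equal the full-network counts
  sf <- subsample_null(sim$matrix, spl, bg, fraction = 1, reps = 1,
                       alphas = 0.05, seed = 7)
  g <- suppressWarnings(build_network(sim$matrix, spl, alpha = 0.05))
  foc <- sf$summary[sf$summary$set == "focal", ]
  expect_equal(foc$mean_edges, nrow(g$edges))
  expect_equal(foc$mean_nodes, length(g$nodes))
  expect_error(subsample_null(sim$matrix, spl, bg[1:3], seed = 1),
               "pool")
})

test_that("graph exports are readable", {
  g <- graph_from_edges(clique_edges(paste0("n", 1:4)))
  f <- tempfile(fileext = ".tsv")
  write_edge_list(g, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 6)
  f2 <- tempfile(fileext = ".graphml")
  write_graphml(g, f2)
  expect_true(any(grepl("graphml", readLines(f2, n = 3))))
})
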