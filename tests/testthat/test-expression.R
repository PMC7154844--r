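# Expressed sets, Venn partitions, specificity shares, breadth, transforms.

test_that("expressed_set follows its threshold definition", {
  m <- manual_matrix(c(1, 0, 0, 0,
                       0, 0, 0, 0,
                       5, 2, 0, 3), c("a", "b", "c"),
                     c("g1", "g1", "g2", "g2"))
  expect_equal(expressed_set(m, "g1"), c("a", "c"))
  expect_equal(expressed_set(m, "g2"), "c")
  expect_equal(expressed_set(m, "g2", threshold = 10), character(0))
  expect_error(expressed_set(m, "nope"), "unknown group")
  # monotone in the threshold
  set.seed(1)
  r <- matrix(rexp(60), nrow = 6,
              dimnames = list(paste0("t", 1:6),
                              paste0(rep(c("g1", "g2"), each = 5), ":",
                                     "s", 1:10)))
  prev <- expressed_set(r, "g1", 0)
  for (th in c(0.5, 1, 2, 5)) {
    cur <- expressed_set(r, "g1", th)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("group Venn reproduces a planted age-structure exactly", {
  # planted to mirror the published four-age structure:
  # per-group 42/47/53/64, shared 29, specific 3/3/3/14, union 81
  ages <- c("y5", "y12", "y18", "y25")
  # intermediate (pair/triple) patterns solved so that per-group totals,
  # the all-age intersection, the singles and the union all hit the targets
  patterns <- c(rep("y5+y12+y18+y25", 29), rep("y5", 3), rep("y12", 3),
                rep("y18", 3), rep("y25", 14),
                rep("y12+y18+y25", 9),
                rep("y5+y18", 5), rep("y5+y25", 5),
                rep("y12+y18", 3), rep("y12+y25", 3), rep("y18+y25", 4))
  stopifnot(length(patterns) == 81)
  n <- 106
  ids <- sprintf("T%03d", 1:n)
  m <- matrix(0, n, 4, dimnames = list(ids, paste0(ages, ":s", 1:4)))
  for (i in seq_along(patterns)) {
    for (g in strsplit(patterns[i], "+", fixed = TRUE)[[1]])
      m[i, startsWith(colnames(m), paste0(g, ":"))] <- 1
  }
  v <- group_venn(m, ages)
  expect_equal(unname(v$per_group), c(42, 47, 53, 64))
  expect_equal(v$intersection, 29)
  expect_equal(unname(v$specific), c(3, 3, 3, 14))
  expect_equal(v$union, 81)
  expect_equal(sum(v$partition), v$union)
  expect_equal(specificity_share(v$specific, "y25"), 61)
})

test_that("degenerate group structures behave as expected", {
  ids <- paste0("t", 1:5)
  same <- matrix(1, 5, 4, dimnames = list(ids, paste0("g", 1:4, ":s", 1:4)))
  v <- group_venn(same)
  expect_equal(unname(v$specific), rep(0L, 4))
  expect_equal(v$intersection, v$union)
  disj <- matrix(0, 4, 4, dimnames = list(ids[1:4],
                                          paste0("g", 1:4, ":s", 1:4)))
  diag(disj) <- 1
  v2 <- group_venn(disj)
  expect_equal(v2$intersection, 0)
  expect_equal(unname(v2$specific), unname(v2$per_group))
})

test_that("Venn partition cells sum to the union on random matrices", {
  set.seed(44)
  for (i in 1:200) {
    n <- sample(3:25, 1)
    k <- sample(2:5, 1)
    m <- matrix(rbinom(n * k, 1, 0.5) * rexp(n * k), n, k,
                dimnames = list(paste0("t", 1:n),
                                paste0("g", 1:k, ":s", 1:k)))
    v <- group_venn(m)
    expect_equal(sum(v$partition), v$union)
    expect_equal(sum(v$specific), sum(v$partition[
      names(v$partition) %in% paste0("g", 1:k)]))
  }
})

test_that("specificity share handles edge cases", {
  expect_equal(specificity_share(c(a = 5, b = 0), "a"), 100)
  expect_equal(specificity_share(c(a = 2, b = 2, c = 2, d = 2), "a"), 25)
  expect_error(specificity_share(c(a = 0, b = 0), "a"), "zero")
  expect_error(specificity_share(c(a = 1), "zz"), "not present")
})

test_that("tissue breadth partitions a planted 14-tissue matrix", {
  # 96 expressed of 106: 16 ubiquitous, 9 single-tissue (5 fruit pedicel,
  # 2 leaflet pedicel, 1 fruit peduncle, 1 main root cortex), 71 in several
  tissues <- splfam:::GINSENG_TISSUES
  n <- 106
  ids <- sprintf("T%03d", 1:n)
  m <- matrix(0, n, 14, dimnames = list(ids, paste0(tissues, ":s", 1:14)))
  m[1:16, ] <- 1                                   # ubiquitous
  single <- rep(c("fruit_pedicel", "leaflet_pedicel", "fruit_peduncle",
                  "main_root_cortex"), c(5, 2, 1, 1))
  for (i in seq_along(single))
    m[16 + i, startsWith(colnames(m), paste0(single[i], ":"))] <- 1
  m[26:96, 1:3] <- 1                               # several tissues
  tb <- tissue_breadth(m)
  expect_equal(tb$n_expressed, 96)
  expect_equal(tb$all_tissues, 16)
  expect_equal(tb$single_tissue, 9)
  expect_equal(tb$multiple, 71)
  expect_equal(unname(tb$single_by_tissue["fruit_pedicel"]), 5)
  expect_equal(category_percentages(tb$all_tissues, tb$n_expressed), 17)
  expect_equal(category_percentages(tb$single_tissue, tb$n_expressed, 1),
               9.4)
})

test_that("planted group-specific transcripts classify as specific", {
  cfg <- sim_config(n_spl = 20, n_background = 0,
                    samples_per_group = groups4(5),
                    block_spec = list(),
                    specificity_spec = c(g1 = 2L, g3 = 3L), seed = 13)
  sim <- simulate_expression(cfg)
  v <- group_venn(sim$matrix)
  spec_ids <- sim$truth$transcript_id[sim$truth$role == "specific"]
  for (id in spec_ids) {
    own <- sim$truth$group[sim$truth$transcript_id == id]
    expect_true(id %in% expressed_set(sim$matrix, own))
    for (g in setdiff(names(groups4()), own))
      expect_false(id %in% expressed_set(sim$matrix, g))
  }
  expect_gte(unname(v$specific["g1"]), 2)
  expect_gte(unname(v$specific["g3"]), 3)
})

test_that("per-genotype expressed-count CV is sample sd over mean", {
  m <- manual_matrix(c(1, 1, 0,
                       1, 0, 0,
                       1, 1, 1), c("a", "b", "c"),
                     c("s1", "s2", "s3"))
  cv <- expressed_count_cv(m)
  expect_equal(unname(cv$counts), c(3, 2, 1))
  expect_equal(cv$cv, sd(c(3, 2, 1)) / 2)
})

test_that("heatmap transform obeys its zero and monotonicity rules", {
  m <- manual_matrix(c(0, 0, 0, 0,
                       1, 3, 7, 15), c("z", "x"),
                     c("g1", "g1", "g2", "g2"))
  t1 <- heatmap_prep(m, log_base = 2, pseudo = 1)
  expect_equal(t1["z", ], setNames(rep(0, 4), colnames(m)))
  expect_equal(unname(t1["x", ]), c(1, 2, 3, 4))
  t2 <- heatmap_prep(m, row_scale = TRUE)
  expect_equal(unname(t2["z", ]), rep(0, 4))
  expect_equal(order(t2["x", ]), order(m["x", ]))
  expect_error(heatmap_prep(m, pseudo = 0), "pseudo")
})
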