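# End-to-end orchestration on synthetic inputs: simulate -> identify ->
# expression -> network -> phylo -> molevol -> logo, with a manifest of
# outputs and reproducible checksums.

#' Default pipeline configuration
#'
#' All thresholds mirror the analysis design the package implements: raw
#' p-value ladder from 0.05 down to 1e-8 by decades, subsample fraction 2/3
#' with 20 repetitions, MCL inflation 2, expression threshold 0.
#'
#' @param seed global integer seed.
#' @param n_spl,n_background simulated focal/background transcript counts.
#' @param reps subsampling repetitions.
#' @param fraction subsample fraction.
#' @param alphas strictly decreasing p-value ladder.
#' @param inflation MCL inflation.
#' @param expressed_threshold expression cutoff.
#' @param stages named logical vector of stage toggles.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_spl = 106L, n_background = 2000L,
                            reps = 20L, fraction = 2 / 3,
                            alphas = c(0.05, 10^-(2:8)), inflation = 2,
                            expressed_threshold = 0,
                            stages = c(simulate = TRUE, domains = TRUE,
                                       expression = TRUE, network = TRUE,
                                       phylo = TRUE, molevol = TRUE,
                                       logo = TRUE)) {
  if (any(diff(alphas) >= 0))
    stop("alphas must be strictly decreasing", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (inflation <= 1) stop("inflation must be > 1", call. = FALSE)
  if (expressed_threshold < 0)
    stop("expressed_threshold must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), n_spl = as.integer(n_spl),
                 n_background = as.integer(n_background),
                 reps = as.integer(reps), fraction = fraction,
                 alphas = alphas, inflation = inflation,
                 expressed_threshold = expressed_threshold,
                 stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$stages)) vals$stages <- unlist(vals$stages)
  do.call(pipeline_config, vals)
}

#' Run the full synthetic analysis pipeline
#'
#' Generates synthetic inputs, scans domains, computes expression
#' partitions, builds the co-expression network with ladder/subsampling
#' statistics and clusters, builds an NJ tree over the planted domains with
#' group assignment, estimates Ka/Ks on simulated codon pairs, and computes
#' the logo profile. Every output file is recorded in `manifest.tsv` with
#' its md5 checksum; rerunning with the same config reproduces the
#' checksums.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) list with per-stage results and the manifest
#'   data.frame.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(path, stage) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = basename(path), md5 = unname(tools::md5sum(path)),
      stage = stage, stringsAsFactors = FALSE)
  }
  on_stage <- function(s) isTRUE(config$stages[[s]])
  need <- function(s, wanted_by) {
    if (!on_stage(s))
      stop(sprintf("stage '%s' requires stage '%s', which is disabled",
                   wanted_by, s), call. = FALSE)
  }
  results <- list()

  if (on_stage("simulate")) {
    message("stage simulate: seed ", config$seed)
    cfg <- sim_config(n_spl = config$n_spl,
                      n_background = config$n_background,
                      seed = config$seed)
    sim <- simulate_expression(cfg)
    seqs3 <- simulate_spl_sequences(20, "C3HC2HC", seed = config$seed)
    seqs4 <- simulate_spl_sequences(8, "C4C2HC", seed = config$seed)
    pairs <- lapply(1:3, function(i)
      simulate_codon_pair(300, target_omega = 0.2,
                          seed = config$seed + i))
    f <- file.path(outdir, "expression.tsv")
    write_expression_tsv(sim$matrix, f); note(f, "simulate")
    f <- file.path(outdir, "truth.tsv")
    utils::write.table(sim$truth, f, sep = "\t", quote = FALSE,
                       row.names = FALSE); note(f, "simulate")
    f <- file.path(outdir, "proteins.fasta")
    write_fasta(c(seqs3$sequences, seqs4$sequences), f); note(f, "simulate")
    results$simulate <- list(sim = sim, seqs = c(seqs3$sequences,
                                                 seqs4$sequences),
                             seq_truth = rbind(seqs3$truth, seqs4$truth),
                             codon_pairs = pairs)
  }

  if (on_stage("domains")) {
    need("simulate", "domains")
    message("stage domains")
    hits <- scan_sbp_domains(results$simulate$seqs)
    f <- file.path(outdir, "domains.tsv")
    utils::write.table(hits, f, sep = "\t", quote = FALSE,
                       row.names = FALSE); note(f, "domains")
    results$domains <- hits
  }

  if (on_stage("expression")) {
    need("simulate", "expression")
    message("stage expression")
    m <- results$simulate$sim$matrix
    venn <- group_venn(m, threshold = config$expressed_threshold)
    breadth <- tissue_breadth(m, threshold = config$expressed_threshold)
    f <- file.path(outdir, "expression_summary.tsv")
    utils::write.table(
      data.frame(group = names(venn$per_group),
                 expressed = as.integer(venn$per_group)),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    note(f, "expression")
    results$expression <- list(venn = venn, breadth = breadth)
  }

  if (on_stage("network")) {
    need("simulate", "network")
    message("stage network")
    m <- results$simulate$sim$matrix
    truth <- results$simulate$sim$truth
    spl <- truth$transcript_id[truth$role != "background"]
    bg <- truth$transcript_id[truth$role == "background"]
    spl_expr <- intersect(spl, rownames(m)[rowSums(m > 0) > 0])
    graph <- suppressWarnings(
      build_network(m, spl_expr, alpha = config$alphas[1]))
    clusters <- if (length(graph$nodes))
      mcl_cluster(graph, inflation = config$inflation) else list()
    ctl <- with_seed(stream_seed(config$seed, "pipeline_control"),
                     sample(bg, min(length(bg), length(spl_expr))))
    ladder <- suppressWarnings(
      pvalue_ladder(m, spl_expr, ctl, config$alphas))
    sub <- suppressWarnings(
      subsample_null(m, spl_expr, bg, fraction = config$fraction,
                     reps = config$reps, alphas = config$alphas,
                     seed = config$seed))
    f <- file.path(outdir, "edges.tsv")
    write_edge_list(graph, f); note(f, "network")
    f <- file.path(outdir, "ladder.tsv")
    utils::write.table(ladder, f, sep = "\t", quote = FALSE,
                       row.names = FALSE); note(f, "network")
    f <- file.path(outdir, "subsample_summary.tsv")
    utils::write.table(sub$summary, f, sep = "\t", quote = FALSE,
                       row.names = FALSE); note(f, "network")
    f <- file.path(outdir, "clusters.tsv")
    utils::write.table(
      data.frame(transcript = unlist(clusters),
                 cluster = rep(seq_along(clusters), lengths(clusters))),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    note(f, "network")
    results$network <- list(graph = graph, clusters = clusters,
                            ladder = ladder, subsample = sub,
                            connectivity = if (length(graph$nodes))
                              average_connectivity(graph) else NA_real_)
  }

  if (on_stage("phylo")) {
    need("simulate", "phylo")
    message("stage phylo")
    tr <- results$simulate$seq_truth
    doms <- substr(results$simulate$seqs[tr$id], tr$start + 1, tr$end)
    names(doms) <- tr$id
    d <- p_distance_matrix(doms)
    tree <- neighbor_joining(d)
    refs_idx <- c(which(tr$type == "C3HC2HC")[1:3],
                  which(tr$type == "C4C2HC")[1:3])
    refs <- stats::setNames(tr$type[refs_idx], tr$id[refs_idx])
    assign <- assign_groups(tree, refs)
    f <- file.path(outdir, "tree.nwk")
    ape::write.tree(tree, f); note(f, "phylo")
    f <- file.path(outdir, "groups.tsv")
    utils::write.table(assign$assignments, f, sep = "\t", quote = FALSE,
                       row.names = FALSE); note(f, "phylo")
    results$phylo <- list(tree = tree, assignments = assign)
  }

  if (on_stage("molevol")) {
    need("simulate", "molevol")
    message("stage molevol")
    kk <- vapply(results$simulate$codon_pairs, function(p)
      ng86_kaks(p$ancestor, p$derived)$ratio, numeric(1))
    names(kk) <- paste0("pair", seq_along(kk))
    summ <- kaks_summary(kk)
    f <- file.path(outdir, "kaks.tsv")
    utils::write.table(data.frame(pair = names(kk), ratio = kk),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    note(f, "molevol")
    results$molevol <- list(ratios = kk, summary = summ)
  }

  if (on_stage("logo")) {
    need("simulate", "logo")
    message("stage logo")
    tr <- results$simulate$seq_truth
    doms <- substr(results$simulate$seqs[tr$id], tr$start + 1, tr$end)
    names(doms) <- tr$id
    prof <- column_profile(doms)
    ic <- information_content(prof)
    f <- file.path(outdir, "information_content.tsv")
    utils::write.table(data.frame(column = seq_along(ic), bits = ic),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    note(f, "logo")
    results$logo <- list(profile = prof, ic = ic)
  }

  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  results$manifest <- manifest
  invisible(results)
}
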