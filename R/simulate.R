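# Synthetic-data generators: expression matrices with planted structure,
# SPL-like proteins with embedded SBP domains, and codon pairs evolved at a
# controlled dN/dS. Everything downstream of quantification/identification is
# exercised on these, with ground truth returned alongside.

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# The 14 tissues sampled from a single 4-year-old plant in the study system.
GINSENG_TISSUES <- c(
  "fiber_root", "leg_root", "main_root_epiderm", "main_root_cortex",
  "rhizome", "arm_root", "stem", "leaf_peduncle", "leaflet_pedicel",
  "leaf_blade", "fruit_peduncle", "fruit_pedicel", "fruit_flesh", "seed"
)

#' Configuration for the synthetic expression generator
#'
#' Describes an expression experiment with planted structure: correlated
#' transcript blocks driven by shared latent factors, single-group-specific
#' transcripts, and a large pool of independent background ("unknown")
#' transcripts used as negative controls.
#'
#' The defaults emulate the study conditions the package targets: 106 focal
#' SPL-like transcripts, 2000 background transcripts, one sample for each of
#' 14 tissues of a single plant, three co-expressed blocks, and nine
#' single-tissue transcripts (five in fruit pedicel, two in leaflet pedicel,
#' one in fruit peduncle, one in main root cortex). The default dropout rate
#' of 0.05 adds zero-inflation while keeping planted blocks with loading
#' >= 0.9 recoverable by the network module, a stated contract of the
#' generator: independent zeroing is a gross rank perturbation (a zeroed
#' high-abundance value moves to the bottom of the ranking), so rank
#' correlation decays much faster than the squared keep-probability and
#' higher rates quickly erase planted structure (see the methods vignette).
#'
#' @param n_spl number of focal (SPL-like) transcripts.
#' @param n_background number of independent background transcripts.
#' @param samples_per_group named integer vector: samples per group label.
#' @param block_spec list of `c(size, loading)` pairs; each block shares one
#'   latent factor with the given loading in `[0, 1]`. `NULL` (default)
#'   resolves to the standard three blocks (sizes 12/10/8, loadings
#'   0.95/0.9/0.9) when they fit `n_spl`, otherwise to no blocks.
#' @param specificity_spec named integer vector: number of planted
#'   single-group-specific transcripts per group label. `NULL` (default)
#'   resolves to the standard single-tissue pattern when the tissue labels
#'   are present in `samples_per_group`, otherwise to none.
#' @param dropout_rate probability in `[0, 1]` that an individual value is
#'   zeroed (planted group-specific transcripts are exempt inside their own
#'   group so their specificity is exact).
#' @param dispersion positive scale of the log-normal noise.
#' @param base_log_mean mean of log-expression before noise.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_spl = 106L,
                       n_background = 2000L,
                       samples_per_group = stats::setNames(
                         rep(1L, length(GINSENG_TISSUES)), GINSENG_TISSUES),
                       block_spec = NULL,
                       specificity_spec = NULL,
                       dropout_rate = 0.05,
                       dispersion = 1,
                       base_log_mean = 2,
                       seed = 1L) {
  fail <- function(field, why) {
    stop(sprintf("invalid SimulationConfig field '%s': %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(n_spl) || length(n_spl) != 1 || n_spl < 0)
    fail("n_spl", "must be a single count >= 0")
  if (!is.numeric(n_background) || length(n_background) != 1 || n_background < 0)
    fail("n_background", "must be a single count >= 0")
  if (length(samples_per_group) < 1 || is.null(names(samples_per_group)) ||
      any(!nzchar(names(samples_per_group))) || any(samples_per_group < 1))
    fail("samples_per_group", "must be a named vector of counts >= 1")
  if (anyDuplicated(names(samples_per_group)))
    fail("samples_per_group", "duplicate group labels")
  # defaults resolve to the standard study conditions when they fit the
  # requested sizes and group labels; otherwise to no planted structure
  if (is.null(specificity_spec)) {
    std_spec <- c(fruit_pedicel = 5L, leaflet_pedicel = 2L,
                  fruit_peduncle = 1L, main_root_cortex = 1L)
    specificity_spec <- if (all(names(std_spec) %in%
                                names(samples_per_group)) &&
                            sum(std_spec) <= n_spl) std_spec else integer(0)
  }
  if (is.null(block_spec)) {
    std_blocks <- list(c(12, 0.95), c(10, 0.9), c(8, 0.9))
    block_spec <- if (30 + sum(specificity_spec) <= n_spl)
      std_blocks else list()
  }
  for (b in block_spec) {
    if (length(b) != 2 || b[1] < 1 || b[2] < 0 || b[2] > 1)
      fail("block_spec", "each block is c(size >= 1, loading in [0,1])")
  }
  if (length(specificity_spec) &&
      (is.null(names(specificity_spec)) ||
       !all(names(specificity_spec) %in% names(samples_per_group))))
    fail("specificity_spec", "group labels must appear in samples_per_group")
  if (any(specificity_spec < 0)) fail("specificity_spec", "counts must be >= 0")
  n_planted <- sum(vapply(block_spec, `[`, numeric(1), 1)) +
    sum(specificity_spec)
  if (n_planted > n_spl)
    fail("block_spec", "block sizes plus specific transcripts exceed n_spl")
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate > 1)
    fail("dropout_rate", "must lie in [0,1]")
  if (!is.numeric(dispersion) || dispersion <= 0)
    fail("dispersion", "must be > 0")
  if (!is.numeric(seed) || length(seed) != 1) fail("seed", "must be an integer")
  structure(list(
    n_spl = as.integer(n_spl), n_background = as.integer(n_background),
    samples_per_group = samples_per_group, block_spec = block_spec,
    specificity_spec = specificity_spec, dropout_rate = dropout_rate,
    dispersion = dispersion, base_log_mean = base_log_mean,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate an expression matrix with planted correlation structure
#'
#' Log-normal latent-factor model: for a transcript in a block with loading
#' `a`, `log(value) = mu + a * factor_s + dispersion * sqrt(1 - a^2) * eps`,
#' so the expected log-scale correlation of two transcripts in the same block
#' is `a^2`. Background transcripts are mutually independent. Planted
#' group-specific transcripts are exactly zero outside their own group and
#' exempt from dropout inside it. An independent Bernoulli dropout then zeroes
#' individual values.
#'
#' @param config a [sim_config()] object.
#' @return a list with components `matrix` (transcripts x samples, dimnames
#'   set, columns labelled `"group:sample"`), and `truth` (data.frame with
#'   `transcript_id`, `role` (`background`, `free`, `block`, `specific`),
#'   `block` (block index or NA) and `group` (specificity group or NA)).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  groups <- rep(names(config$samples_per_group), config$samples_per_group)
  sample_ids <- paste0(groups, ":", "s", seq_along(groups))
  n_samples <- length(groups)

  spl_ids <- sprintf("SPL%03d", seq_len(config$n_spl))
  bg_ids <- if (config$n_background > 0)
    sprintf("BG%04d", seq_len(config$n_background)) else character(0)
  ids <- c(spl_ids, bg_ids)

  truth <- data.frame(
    transcript_id = ids,
    role = c(rep("free", config$n_spl), rep("background", config$n_background)),
    block = NA_integer_, group = NA_character_,
    stringsAsFactors = FALSE)

  # block and specificity assignments, taken from the front of the SPL pool
  cursor <- 0L
  for (bi in seq_along(config$block_spec)) {
    size <- as.integer(config$block_spec[[bi]][1])
    idx <- cursor + seq_len(size)
    truth$role[idx] <- "block"
    truth$block[idx] <- bi
    cursor <- cursor + size
  }
  for (g in names(config$specificity_spec)) {
    ng <- config$specificity_spec[[g]]
    if (ng == 0) next
    idx <- cursor + seq_len(ng)
    truth$role[idx] <- "specific"
    truth$group[idx] <- g
    cursor <- cursor + ng
  }

  n_total <- length(ids)
  mat <- with_seed(stream_seed(config$seed, "expression"), {
    factors <- matrix(stats::rnorm(length(config$block_spec) * n_samples),
                      nrow = max(1L, length(config$block_spec)))
    logm <- matrix(config$base_log_mean +
                     config$dispersion * stats::rnorm(n_total * n_samples),
                   nrow = n_total)
    for (bi in seq_along(config$block_spec)) {
      a <- config$block_spec[[bi]][2]
      rows <- which(truth$block == bi)
      eps <- matrix(stats::rnorm(length(rows) * n_samples), nrow = length(rows))
      logm[rows, ] <- config$base_log_mean +
        matrix(a * factors[bi, ], nrow = length(rows), ncol = n_samples,
               byrow = TRUE) +
        config$dispersion * sqrt(1 - a^2) * eps
    }
    m <- exp(logm)
    keep <- matrix(stats::runif(n_total * n_samples) >= config$dropout_rate,
                   nrow = n_total)
    # group-specific transcripts: zero outside their group, kept inside it
    for (i in which(truth$role == "specific")) {
      own <- groups == truth$group[i]
      m[i, !own] <- 0
      keep[i, own] <- TRUE
    }
    m * keep
  })
  dimnames(mat) <- list(ids, sample_ids)
  list(matrix = mat, truth = truth)
}

# SBP-domain geometry, expressed as offsets inside a 74-residue domain.
# Derived from the spacings between the conserved alignment columns
# 214/219/236/239 (zinc finger 1), 255/258/262/274 (zinc finger 2) and
# 271/272/284/285/286/287 (NLS) reported for this family.
sbp_default_layout <- function(domain_length = 74L) {
  list(domain_length = as.integer(domain_length),
       zf1 = c(0L, 5L, 22L, 25L),     # C C C H  (C3HC2HC) / C C C C (C4C2HC)
       zf2 = c(41L, 44L, 48L, 60L),   # C C H C
       nls = c(57L, 58L, 70L, 71L, 72L, 73L),  # K R R R R K
       nls_residues = c("K", "R", "R", "R", "R", "K"))
}

#' Simulate SPL-like proteins with an embedded SBP domain
#'
#' Each sequence carries one 74-residue SBP-like domain (two zinc fingers and
#' a basic NLS at the canonical spacings) flanked by random residues. The
#' non-motif domain positions of all sequences in one call derive from a
#' shared type-level template, with each sequence mutated independently at
#' rate `divergence`, so sequences of one type form a cohesive family the
#' way real SPL groups are conserved beyond their motifs (and distance-based
#' trees separate the types). Flanks and non-motif positions are drawn from
#' the 18 residues other than C and H so the planted domain is the unique
#' motif match and the returned coordinates are exact ground truth.
#'
#' @param n number of sequences (>= 1).
#' @param domain_type `"C3HC2HC"` (His at the fourth finger-1 position) or
#'   `"C4C2HC"` (Cys there instead).
#' @param seed integer seed.
#' @param flank_range integer range for the lengths of the two random flanks.
#' @param divergence per-position mutation probability of non-motif domain
#'   positions away from the type template (default 0.1).
#' @return list with `sequences` (named character vector) and `truth`
#'   (data.frame of `id`, `start`, `end` 0-based half-open, `type`).
#' @export
simulate_spl_sequences <- function(n, domain_type = c("C3HC2HC", "C4C2HC"),
                                   seed = 1L, flank_range = c(20L, 80L),
                                   divergence = 0.1) {
  stopifnot(n >= 1, divergence >= 0, divergence <= 1)
  domain_type <- match.arg(domain_type)
  lay <- sbp_default_layout()
  bg <- setdiff(AA20, c("C", "H"))
  motif_pos <- c(lay$zf1, lay$zf2, lay$nls) + 1L
  motif_res <- c("C", "C", "C", if (domain_type == "C3HC2HC") "H" else "C",
                 "C", "C", "H", "C", lay$nls_residues)
  with_seed(stream_seed(seed, paste0("spl_seq_", domain_type)), {
    template <- sample(bg, lay$domain_length, replace = TRUE)
    template[motif_pos] <- motif_res
    free_pos <- setdiff(seq_len(lay$domain_length), motif_pos)
    seqs <- character(n)
    starts <- integer(n)
    for (i in seq_len(n)) {
      domain <- template
      mut <- free_pos[stats::runif(length(free_pos)) < divergence]
      if (length(mut)) domain[mut] <- sample(bg, length(mut), replace = TRUE)
      nl <- sample(flank_range[1]:flank_range[2], 1)
      nr <- sample(flank_range[1]:flank_range[2], 1)
      seqs[i] <- paste(c(sample(bg, nl, replace = TRUE), domain,
                         sample(bg, nr, replace = TRUE)), collapse = "")
      starts[i] <- nl
    }
    names(seqs) <- sprintf("%s_%03d", tolower(domain_type), seq_len(n))
    list(sequences = seqs,
         truth = data.frame(id = names(seqs), start = starts,
                            end = starts + lay$domain_length,
                            type = domain_type, stringsAsFactors = FALSE))
  })
}

#' Simulate a pair of coding sequences diverged at a controlled dN/dS
#'
#' An ancestral in-frame sequence of sense codons is drawn uniformly, then a
#' derived copy is evolved by single-nucleotide substitutions: proposals are
#' uniform over positions and alternative bases, changes creating stop codons
#' are rejected, and nonsynonymous (synonymous) proposals are accepted with
#' relative probability `target_omega` (1), so the realized nonsynonymous to
#' synonymous rate ratio equals `target_omega` in expectation.
#'
#' @param n_codons number of codons (>= 50 recommended; >= 2 enforced).
#' @param target_omega target dN/dS ratio (> 0).
#' @param seed integer seed.
#' @param n_subs number of accepted substitutions; default
#'   `round(0.35 * n_codons)` keeps divergence well below saturation.
#' @return list with `ancestor` and `derived` (character strings of equal
#'   length, multiple of 3, no stop codons) and `n_subs`.
#' @export
simulate_codon_pair <- function(n_codons, target_omega, seed = 1L,
                                n_subs = NULL) {
  if (!is.numeric(target_omega) || target_omega <= 0)
    stop("target_omega must be > 0", call. = FALSE)
  stopifnot(n_codons >= 2)
  n_subs <- as.integer(n_subs %||% round(0.35 * n_codons))
  code <- codon_table()
  sense <- names(code)[code != "*"]
  bases <- c("A", "C", "G", "T")
  p_acc_nonsyn <- min(1, target_omega)
  p_acc_syn <- min(1, 1 / target_omega)
  with_seed(stream_seed(seed, "codon_pair"), {
    anc_codons <- sample(sense, n_codons, replace = TRUE)
    der <- unlist(strsplit(paste(anc_codons, collapse = ""), ""))
    accepted <- 0L
    attempts <- 0L
    max_attempts <- max(1000L, 500L * n_subs)
    while (accepted < n_subs && attempts < max_attempts) {
      attempts <- attempts + 1L
      pos <- sample.int(length(der), 1)
      alt <- sample(setdiff(bases, der[pos]), 1)
      ci <- (pos - 1L) %/% 3L
      old_codon <- paste(der[ci * 3L + 1:3], collapse = "")
      new <- der[ci * 3L + 1:3]
      new[(pos - 1L) %% 3L + 1L] <- alt
      new_codon <- paste(new, collapse = "")
      if (code[[new_codon]] == "*") next
      syn <- code[[new_codon]] == code[[old_codon]]
      if (stats::runif(1) <= (if (syn) p_acc_syn else p_acc_nonsyn)) {
        der[pos] <- alt
        accepted <- accepted + 1L
      }
    }
    list(ancestor = paste(anc_codons, collapse = ""),
         derived = paste(der, collapse = ""),
         n_subs = accepted)
  })
}

#' Simulate a GO-style annotation table with prescribed marginals
#'
#' Assigns namespace membership patterns (BP/MF/CC) to transcripts so that the
#' per-namespace totals, the triple-annotated count and the annotated total
#' match the requested values exactly; used to exercise the Venn bookkeeping.
#'
#' @param universe transcript identifiers.
#' @param n_annotated,n_mf,n_cc,n_bp,n_triple target marginal counts. The
#'   defaults reproduce the family's published annotation structure
#'   (99 annotated of 106; 95 MF, 70 CC, 14 BP, 12 in all three).
#' @param seed integer seed used to shuffle which transcript gets which
#'   pattern.
#' @return data.frame with `transcript_id`, `namespace`, `term_id`,
#'   `term_label`, one row per (transcript, namespace).
#' @export
simulate_annotation_table <- function(universe, n_annotated = 99L,
                                      n_mf = 95L, n_cc = 70L, n_bp = 14L,
                                      n_triple = 12L, seed = 1L) {
  n <- length(universe)
  stopifnot(n_annotated <= n, n_triple <= min(n_mf, n_cc, n_bp))
  # pattern counts solved with BP placed entirely inside MF (beyond the
  # triple) and no CC+BP-only overlap; sufficient for the marginals used here
  g <- n_triple
  e <- n_bp - g                                   # MF+BP
  d <- (n_mf + n_cc + n_bp - n_annotated - 2L * g) - e  # MF+CC
  b <- n_cc - d - g                               # CC only
  a <- n_mf - d - e - g                           # MF only
  counts <- c(MF = a, CC = b, BP = 0L,
              `MF+CC` = d, `MF+BP` = e, `CC+BP` = 0L,
              `MF+CC+BP` = g)
  if (any(counts < 0) || sum(counts) != n_annotated)
    stop("marginals are not jointly satisfiable with this pattern layout",
         call. = FALSE)
  patterns <- rep(names(counts), counts)
  with_seed(stream_seed(seed, "annotation"), {
    chosen <- sample(universe, n_annotated)
    rows <- list()
    for (i in seq_along(chosen)) {
      for (ns in strsplit(patterns[i], "+", fixed = TRUE)[[1]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = chosen[i], namespace = ns,
          term_id = paste0("GO:", ns), term_label = tolower(ns),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Write an expression matrix as a self-describing TSV
#'
#' Row 1 holds `"group:sample"` headers, column 1 the transcript IDs.
#' @param mat matrix with dimnames as produced by [simulate_expression()].
#' @param path output file.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(transcript_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_tsv()]
#' @param path TSV file.
#' @return numeric matrix with transcript rownames and `"group:sample"`
#'   colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("expression matrix has negative values", call. = FALSE)
  m
}

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  stats::setNames(unname(seqs), ids)
}
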