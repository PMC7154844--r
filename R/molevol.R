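# Nei-Gojobori (1986) Ka/Ks: fractional synonymous/nonsynonymous site
# counts, equal-weight averaging over all minimal substitution pathways, and
# Jukes-Cantor correction of the proportions.

# Standard genetic code as a named vector codon -> one-letter amino acid.
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- stats::setNames(as.character(gc), names(gc))
    }
    tab
  }
})

split_codons <- function(seq, what) {
  s <- toupper(as.character(seq))
  if (nchar(s) %% 3 != 0)
    stop(what, " length is not a multiple of 3", call. = FALSE)
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

# Fractional count of synonymous sites in one codon: at each of the three
# positions, the fraction of the three possible changes that are synonymous;
# changes to stop codons count as nonsynonymous (original NG86 convention).
syn_sites_codon <- function(codon, code) {
  aa <- code[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  nt <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (alt in setdiff(bases, nt[pos])) {
      mut <- nt
      mut[pos] <- alt
      if (code[[paste(mut, collapse = "")]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# Average synonymous/nonsynonymous differences between two codons over all
# minimal substitution pathways; pathways through stop codons are dropped
# (all-invalid falls back to including them).
codon_differences <- function(c1, c2, code) {
  nt1 <- strsplit(c1, "")[[1]]
  nt2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(nt1 != nt2)
  k <- length(diff_pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  count_path <- function(order, allow_stop) {
    cur <- nt1
    sd <- 0; nd <- 0
    for (pos in order) {
      aa_before <- code[[paste(cur, collapse = "")]]
      cur[pos] <- nt2[pos]
      codon_after <- paste(cur, collapse = "")
      aa_after <- code[[codon_after]]
      if (aa_after == "*" && !allow_stop) return(NULL)
      if (aa_after == aa_before) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd)
  }
  orders <- perms(diff_pos)
  paths <- Filter(Negate(is.null),
                  lapply(orders, count_path, allow_stop = FALSE))
  if (!length(paths)) paths <- lapply(orders, count_path, allow_stop = TRUE)
  colMeans(do.call(rbind, paths))
}

# All permutations of a small vector (k <= 3 here).
perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)  # saturated
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka/Ks for a pair of in-frame coding sequences
#'
#' Synonymous and nonsynonymous sites are counted per codon as fractional
#' sites and averaged over the two sequences; observed differences are
#' averaged with equal weights over all minimal substitution pathways for
#' each differing codon (pathways through stop codons excluded); the
#' proportions are corrected with the Jukes-Cantor formula
#' `d = -(3/4) log(1 - 4p/3)`.
#'
#' Codons containing `N` or `-` in either sequence are skipped and reported
#' as excluded. Sequences must be gap-aligned, equal length, a multiple of 3,
#' with no stop codons.
#'
#' @param seq1,seq2 coding sequences (character strings).
#' @return list with `ka`, `ks`, `ratio` (NA + flag when Ks = 0), site and
#'   difference counts (`n_sites`, `s_sites`, `nd`, `sd`, `pn`, `ps`),
#'   `codons_excluded`, and `flags` (character vector; may contain
#'   `"ks_zero"`, `"ka_saturated"`, `"ks_saturated"`).
#' @export
ng86_kaks <- function(seq1, seq2) {
  code <- codon_table()
  c1 <- split_codons(seq1, "seq1")
  c2 <- split_codons(seq2, "seq2")
  if (length(c1) != length(c2))
    stop("sequences differ in codon length", call. = FALSE)
  usable <- !grepl("[^ACGT]", c1) & !grepl("[^ACGT]", c2)
  excl <- sum(!usable)
  c1 <- c1[usable]; c2 <- c2[usable]
  if (!length(c1)) stop("no usable codons", call. = FALSE)
  if (any(code[c1] == "*") || any(code[c2] == "*"))
    stop("internal stop codon", call. = FALSE)
  s1 <- vapply(c1, syn_sites_codon, numeric(1), code = code)
  s2 <- vapply(c2, syn_sites_codon, numeric(1), code = code)
  S <- (sum(s1) + sum(s2)) / 2
  N <- 3 * length(c1) - S
  diffs <- mapply(function(a, b) codon_differences(a, b, code), c1, c2)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  ks <- jc_correct(ps)
  ka <- jc_correct(pn)
  flags <- character(0)
  if (!is.na(ps) && ps >= 0.75) flags <- c(flags, "ks_saturated")
  if (!is.na(pn) && pn >= 0.75) flags <- c(flags, "ka_saturated")
  ratio <- if (!is.na(ks) && !is.na(ka) && ks > 0) ka / ks else NA_real_
  if (!is.na(ks) && ks == 0) flags <- c(flags, "ks_zero")
  list(ka = ka, ks = ks, ratio = ratio,
       n_sites = N, s_sites = S, nd = Nd, sd = Sd, pn = pn, ps = ps,
       codons_excluded = excl, flags = flags)
}

#' Summarize a set of pairwise Ka/Ks ratios
#'
#' @param ratios named numeric vector of ratios (names = pair labels);
#'   non-finite entries are dropped with a note in the result.
#' @param exclude optional character vector of labels; when given, a second
#'   summary is computed with any pair whose label matches (by substring)
#'   removed.
#' @return list with `mean`, `cv` (sample sd/mean), `min_pair`, `max_pair`,
#'   `n`, and (when `exclude` is used) `excluded_summary`.
#' @export
kaks_summary <- function(ratios, exclude = NULL) {
  if (is.null(names(ratios))) names(ratios) <- paste0("pair", seq_along(ratios))
  keep <- is.finite(ratios)
  if (!any(keep)) stop("all ratios are undefined", call. = FALSE)
  r <- ratios[keep]
  if (length(r) < 2) stop("need >= 2 finite ratios", call. = FALSE)
  out <- list(mean = mean(r), cv = stats::sd(r) / mean(r),
              min_pair = names(r)[which.min(r)],
              max_pair = names(r)[which.max(r)], n = length(r))
  if (!is.null(exclude)) {
    hit <- Reduce(`|`, lapply(exclude, function(e) grepl(e, names(r),
                                                         fixed = TRUE)))
    out$excluded_summary <- kaks_summary(r[!hit])
  }
  out
}
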