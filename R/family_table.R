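# Gene-family table: parsing and the protein-parameter recomputation
# contracts (longest ORF, average molecular weight, isoelectric point).

# Average (not monoisotopic) residue masses in Da, Expasy convention.
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

# Bjellqvist pKa values used for the isoelectric point.
PKA_SIDE_NEG <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)  # lose H+ above pKa
PKA_SIDE_POS <- c(H = 5.98, K = 10.0, R = 12.0)           # hold H+ below pKa
PKA_CTERM <- 3.55
PKA_NTERM_DEFAULT <- 7.5
PKA_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
               V = 7.44, E = 7.70)

#' Load the packaged SPL family table
#'
#' Convenience wrapper around [parse_family_table()] for the TSV shipped in
#' `inst/extdata/pgspl_family_table.tsv` (106 ginseng SPL transcripts from
#' 30 genes, with transcript length, ORF length, MW and pI as reported).
#' The numeric columns are stored metadata of the original report, kept as
#' printed (including its internal oddities), not recomputation targets.
#' @return data.frame of class `family_table`.
#' @export
spl_family_table <- function() {
  parse_family_table(system.file("extdata", "pgspl_family_table.tsv",
                                 package = "splfam", mustWork = TRUE))
}

#' Parse a gene-family table TSV
#'
#' Expects columns `gene`, `transcript`, `seq_length` (bp), `orf_length`
#' (aa), `mw` (kDa), `pi`.
#'
#' @param path path to a tab-separated file with the header above.
#' @return data.frame of class `family_table`, row order preserved.
#' @export
parse_family_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  expected <- c("gene", "transcript", "seq_length", "orf_length", "mw", "pi")
  if (!identical(names(raw), expected))
    stop("unexpected header; expected: ", paste(expected, collapse = ", "),
         call. = FALSE)
  for (col in c("seq_length", "orf_length", "mw", "pi")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & nzchar(raw[[col]]))
    if (length(bad))
      stop(sprintf("malformed numeric cell in column '%s', row %d ('%s')",
                   col, bad[1], raw[[col]][bad[1]]), call. = FALSE)
    raw[[col]] <- v
  }
  dup <- raw$transcript[duplicated(raw$transcript)]
  if (length(dup))
    stop("duplicate transcript_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (nrow(raw)) {
    if (any(raw$mw <= 0, na.rm = TRUE)) stop("mw must be > 0", call. = FALSE)
    if (any(raw$pi <= 0 | raw$pi >= 14, na.rm = TRUE))
      stop("pi must lie in (0, 14)", call. = FALSE)
    ok_prefix <- substr(raw$transcript, 1, nchar(raw$gene)) == raw$gene
    if (!all(ok_prefix))
      stop("transcript_id must begin with its gene_id (row ",
           which(!ok_prefix)[1], ")", call. = FALSE)
  }
  class(raw) <- c("family_table", "data.frame")
  raw
}

#' Write a family table back to TSV
#' @param table a `family_table` data.frame.
#' @param path output path.
#' @export
write_family_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Find the longest ORF in a nucleotide sequence
#'
#' Searches all six reading frames for the longest ATG-initiated,
#' stop-terminated open reading frame under the standard genetic code.
#' Ties are broken in favour of the forward strand, then the smaller
#' forward-strand start. Codons containing `N` translate as `X` and neither
#' start nor stop an ORF.
#'
#' @param seq DNA string over `A,C,G,T,N` (case-insensitive), length >= 6.
#' @return `NULL` if no ORF exists; otherwise a list with `frame` (0..2 on
#'   the reported strand), `strand` (`"+"`/`"-"`), `start`, `end` (0-based
#'   half-open, forward-strand coordinates, stop codon included) and
#'   `protein` (start Met included, stop excluded).
#' @export
find_longest_orf <- function(seq) {
  s <- toupper(as.character(seq))
  if (nchar(s) < 6) stop("sequence must have length >= 6", call. = FALSE)
  if (grepl("[^ACGTN]", s))
    stop("sequence must be over {A,C,G,T,N}", call. = FALSE)
  L <- nchar(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  code <- codon_table()
  best <- NULL
  consider <- function(cand) {
    if (is.null(best)) return(cand)
    if (nchar(cand$protein) > nchar(best$protein)) return(cand)
    if (nchar(cand$protein) < nchar(best$protein)) return(best)
    if (cand$strand != best$strand)
      return(if (cand$strand == "+") cand else best)
    if (cand$start < best$start) cand else best
  }
  for (strand in c("+", "-")) {
    str_seq <- if (strand == "+") s else rc
    for (frame in 0:2) {
      n_codons <- (L - frame) %/% 3
      if (n_codons < 2) next
      starts0 <- frame + 3 * (seq_len(n_codons) - 1)
      codons <- substring(str_seq, starts0 + 1, starts0 + 3)
      aa <- ifelse(grepl("N", codons), "X", unname(code[codons]))
      stops <- which(aa == "*")
      atgs <- which(codons == "ATG")
      prev <- 0L
      for (k in stops) {
        cand_atg <- atgs[atgs > prev & atgs < k]
        if (length(cand_atg)) {
          a <- cand_atg[1]
          prot <- paste(aa[a:(k - 1)], collapse = "")
          st0 <- starts0[a]          # strand-local
          en0 <- starts0[k] + 3
          if (strand == "+") {
            cand <- list(frame = frame, strand = "+", start = st0, end = en0,
                         protein = prot)
          } else {
            cand <- list(frame = frame, strand = "-", start = L - en0,
                         end = L - st0, protein = prot)
          }
          best <- consider(cand)
        }
        prev <- k
      }
    }
  }
  best
}

#' Average molecular weight of a protein, in kilodaltons
#'
#' Sum of average residue masses plus one water mass. Additive up to one
#' water: `mw(ab) == mw(a) + mw(b) - 0.01801524`.
#'
#' @param protein amino-acid string over the standard 20-letter alphabet
#'   (empty allowed: returns the water mass).
#' @return molecular weight in kDa.
#' @export
compute_mw <- function(protein) {
  p <- toupper(as.character(protein))
  res <- if (nchar(p)) strsplit(p, "")[[1]] else character(0)
  bad <- setdiff(unique(res), names(RESIDUE_MASS))
  if (length(bad))
    stop("non-standard residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  (sum(RESIDUE_MASS[res]) + WATER_MASS) / 1000
}

# Net charge of a protein at a given pH (Henderson-Hasselbalch over termini
# and ionizable side chains).
protein_charge <- function(residues, pH) {
  nterm_pka <- PKA_NTERM[residues[1]]
  if (is.na(nterm_pka)) nterm_pka <- PKA_NTERM_DEFAULT
  pos <- 1 / (1 + 10^(pH - nterm_pka))
  neg <- 1 / (1 + 10^(PKA_CTERM - pH))
  for (r in names(PKA_SIDE_POS)) {
    k <- sum(residues == r)
    if (k) pos <- pos + k / (1 + 10^(pH - PKA_SIDE_POS[[r]]))
  }
  for (r in names(PKA_SIDE_NEG)) {
    k <- sum(residues == r)
    if (k) neg <- neg + k / (1 + 10^(PKA_SIDE_NEG[[r]] - pH))
  }
  pos - neg
}

#' Theoretical isoelectric point of a protein
#'
#' The pH at which the Henderson-Hasselbalch net charge (termini plus
#' D/E/C/Y/H/K/R side chains, Bjellqvist pKa values) crosses zero, found by
#' bisection on `[0, 14]`; the net charge is monotone decreasing in pH so
#' the root is unique.
#'
#' @param protein non-empty amino-acid string over the standard alphabet.
#' @param tol bisection tolerance on pH (default `1e-4`).
#' @return isoelectric point in pH units.
#' @export
compute_pi <- function(protein, tol = 1e-4) {
  p <- toupper(as.character(protein))
  if (!nchar(p)) stop("protein must have at least one residue", call. = FALSE)
  res <- strsplit(p, "")[[1]]
  bad <- setdiff(unique(res), names(RESIDUE_MASS))
  if (length(bad))
    stop("non-standard residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_charge(res, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Mean and coefficient of variation of family sizes across species
#'
#' @param counts numeric vector of per-species gene-family sizes (a named
#'   vector keeps the species labels in the output).
#' @param cv_type `"sample"` (sd with n-1 denominator, default) or
#'   `"population"`.
#' @return list with `mean`, `cv` (sd/mean; `NA` with a warning for a single
#'   count under the sample convention), `n`.
#' @export
family_size_summary <- function(counts, cv_type = c("sample", "population")) {
  cv_type <- match.arg(cv_type)
  if (length(counts) == 0) stop("counts must be nonempty", call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  m <- mean(counts)
  s <- if (cv_type == "sample") {
    if (length(counts) < 2) {
      warning("sample CV undefined for a single count")
      NA_real_
    } else stats::sd(counts)
  } else {
    sqrt(mean((counts - m)^2))
  }
  list(mean = m, cv = if (m > 0) s / m else NA_real_, n = length(counts))
}
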