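# Family-table parsing, ORF finding, protein parameters, family-size stats.

test_that("packaged family table has the expected structure", {
  ft <- spl_family_table()
  expect_equal(nrow(ft), 106)
  expect_equal(length(unique(ft$gene)), 30)
  expect_true(all(substr(ft$transcript, 1, nchar(ft$gene)) == ft$gene))
  expect_true(all(ft$mw > 0))
  expect_true(all(ft$pi > 0 & ft$pi < 14))
})

test_that("packaged fixture digitization is frozen by checksum", {
  path <- system.file("extdata", "pgspl_family_table.tsv",
                      package = "splfam", mustWork = TRUE)
  expect_equal(unname(tools::md5sum(path)),
               "1309978ddacc82c364f8a7deefe6481b")
})

test_that("parser round-trips and rejects malformed input", {
  ft <- spl_family_table()
  f <- tempfile(fileext = ".tsv")
  write_family_table(ft, f)
  expect_equal(as.data.frame(parse_family_table(f)), as.data.frame(ft))

  hdr <- "gene\ttranscript\tseq_length\torf_length\tmw\tpi"
  f2 <- tempfile()
  writeLines(hdr, f2)
  expect_equal(nrow(parse_family_table(f2)), 0)  # header-only -> empty

  writeLines(c(hdr, "G1\tG1-01\tabc\t10\t1.0\t7.0"), f2)
  expect_error(parse_family_table(f2), "row 1")
  writeLines(c(hdr, "G1\tG1-01\t100\t10\t1.0\t7.0",
               "G1\tG1-01\t100\t10\t1.0\t7.0"), f2)
  expect_error(parse_family_table(f2), "duplicate")
  writeLines(c(hdr, "G1\tX9-01\t100\t10\t1.0\t7.0"), f2)
  expect_error(parse_family_table(f2), "begin with")
})

test_that("longest ORF matches hand-checkable cases", {
  o <- find_longest_orf("ATGAAATAA")
  expect_equal(o$protein, "MK")
  expect_equal(o$strand, "+")
  expect_equal(c(o$start, o$end), c(0, 9))

  # same ORF on the reverse strand, embedded in flanks
  rc <- "TTATTTCAT"  # revcomp of ATGAAATAA
  seq <- paste0("CCGCC", rc, "GGACC")
  o2 <- find_longest_orf(seq)
  expect_equal(o2$protein, "MK")
  expect_equal(o2$strand, "-")
  expect_equal(c(o2$start, o2$end), c(5, 14))

  expect_null(find_longest_orf("CCCCCCCCC"))
})

# Independent brute force: every ATG..stop span in all six frames.
brute_orf <- function(s) {
  code <- splfam:::codon_table()
  L <- nchar(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  best <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") s else rc
    for (frame in 0:2) {
      n <- (L - frame) %/% 3
      if (n < 2) next
      cods <- substring(q, frame + 3 * (0:(n - 1)) + 1, frame + 3 * (0:(n - 1)) + 3)
      aa <- ifelse(grepl("N", cods), "X", unname(code[cods]))
      for (a in which(cods == "ATG")) {
        stops <- which(aa == "*")
        stops <- stops[stops > a]
        if (!length(stops)) next
        k <- stops[1]
        if (any(aa[a:(k - 1)] == "*")) next
        prot <- paste(aa[a:(k - 1)], collapse = "")
        st <- frame + 3 * (a - 1); en <- frame + 3 * k
        cand <- if (strand == "+")
          list(strand = "+", start = st, end = en, protein = prot)
        else list(strand = "-", start = L - en, end = L - st, protein = prot)
        better <- is.null(best) ||
          nchar(cand$protein) > nchar(best$protein) ||
          (nchar(cand$protein) == nchar(best$protein) &&
             best$strand == "-" && cand$strand == "+") ||
          (nchar(cand$protein) == nchar(best$protein) &&
             cand$strand == best$strand && cand$start < best$start)
        if (better) best <- cand
      }
    }
  }
  best
}

test_that("longest ORF agrees with a six-frame brute-force scan", {
  set.seed(71)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
    got <- find_longest_orf(s)
    want <- brute_orf(s)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$protein, want$protein)
      expect_equal(got$strand, want$strand)
      expect_equal(c(got$start, got$end), c(want$start, want$end))
    }
  }
})

test_that("molecular weight follows the average-mass table", {
  expect_equal(compute_mw(""), 0.01801524, tolerance = 1e-9)
  # free glycine: residue mass 57.0519 + water, summed by hand
  expect_equal(compute_mw("G"), (57.0519 + 18.01524) / 1000,
               tolerance = 1e-9)
  set.seed(5)
  pep <- paste(sample(names(splfam:::RESIDUE_MASS), 40, TRUE), collapse = "")
  perm <- paste(sample(strsplit(pep, "")[[1]]), collapse = "")
  expect_equal(compute_mw(pep), compute_mw(perm))
  # additivity up to one water
  a <- "MKWV"; b <- "DDEE"
  expect_equal(compute_mw(paste0(a, b)),
               compute_mw(a) + compute_mw(b) - 0.01801524,
               tolerance = 1e-12)
  expect_error(compute_mw("MKX"), "X")
})

test_that("isoelectric point behaves and matches a grid-search oracle", {
  expect_gt(compute_pi("K"), compute_pi("D"))
  expect_gt(compute_pi(strrep("R", 10)), 10)
  set.seed(8)
  for (i in 1:10) {
    pep <- paste(sample(names(splfam:::RESIDUE_MASS), 20, TRUE),
                 collapse = "")
    grid <- seq(0, 14, by = 1e-3)
    res <- strsplit(pep, "")[[1]]
    charge <- vapply(grid, function(ph)
      splfam:::protein_charge(res, ph), numeric(1))
    oracle <- grid[which.min(abs(charge))]
    expect_lt(abs(compute_pi(pep) - oracle), 0.01)
  }
})

test_that("family-size summary reproduces the nine-species mean", {
  counts <- c(Creinhardtii = 7, Ppatens = 14, Smoellendorffii = 13,
              Ptaeda = 3, Pglauca = 2, Athaliana = 16, Ptrichocarpa = 26,
              Osativa = 18, Zmays = 21)
  s <- family_size_summary(counts)
  expect_equal(round(s$mean, 1), 13.3)
  expect_gt(s$cv, 0)
  expect_equal(family_size_summary(rep(4, 6))$cv, 0)
  expect_equal(family_size_summary(5, cv_type = "population")$cv, 0)
  expect_warning(s1 <- family_size_summary(5), "single")
  expect_true(is.na(s1$cv))
  expect_error(family_size_summary(numeric(0)), "nonempty")
})
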