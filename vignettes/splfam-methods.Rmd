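---
title: "Methods behind splfam: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind splfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splfam)
```

`splfam` characterizes SQUAMOSA promoter binding protein-like (SPL) gene
families at the transcript level: SBP-domain detection and zinc-finger
typing, family-table statistics, tissue/age/genotype expression partitions,
Spearman co-expression networks with threshold ladders and
random-background controls, distance-based group classification, Ka/Ks
summaries, and sequence-logo information content. This vignette explains
each model, its assumptions, the tunable parameters, and the design
decisions that were genuinely open.

## The synthetic-data generator

No public expression matrices or coding sequences exist for the ginseng
transcript set the family table describes, so every statistical stage is
exercised on synthetic data with known ground truth. The generator is
first-class, tested code, not a fixture.

**Expression model.** Values follow a log-normal latent-factor model. A
transcript in a co-expressed block with loading $a \in [0,1]$ has

$$\log v_{ts} = \mu + a f_{bs} + \sigma\sqrt{1-a^2}\,\varepsilon_{ts},$$

with a standard-normal factor $f_{bs}$ shared by the block within sample
$s$ and independent noise $\varepsilon$. Scaling the noise by
$\sqrt{1-a^2}$ makes the loading directly interpretable: the expected
log-scale correlation of two block members is $a^2$. Background
("unknown") transcripts are mutually independent and serve as negative
controls. Planted single-group-specific transcripts are exactly zero
outside their group. Zero-inflation is independent Bernoulli dropout at
rate `dropout_rate`.

**Why the dropout default is 0.05.** Rank correlation is unusually
sensitive to independent zeroing: a zeroed high-abundance observation
falls to the bottom of the ranking, a gross rank error, so the observed
Spearman correlation decays much faster than the naive
$(1-\text{rate})^2$ attenuation (measured: loading 0.95 gives within-block
rho of about 0.87 at rate 0, 0.49 at rate 0.1, and 0.35 at rate 0.2). The
generator carries a contract that blocks with loading $\ge 0.9$ and
$\ge 30$ samples are recoverable as single clusters at $\alpha = 0.05$ in
at least 90% of seeds; 0.05 is the default rate at which that contract
holds comfortably while still exercising the zero-handling paths.
Real quantified transcriptomes show abundance-*dependent* zero patterns
that are gentler on ranks than independent dropout; this is a known
limitation of the generator, so passing tests demonstrate correctness of
the machinery, not robustness to every real-data zero regime.

**Sample layout.** Group labels are encoded in the column names as
`"group:sample"`, keeping the TSV self-describing. The default layout is
the package's reference design: 106 focal transcripts, 2000 background
transcripts, one sample for each of 14 tissues of a single plant, three
blocks (sizes 12/10/8, loadings 0.95/0.9/0.9), and nine single-tissue
transcripts (5/2/1/1 over four tissues). The distributional form of the
original quantifications is unknown; log-normal is a stand-in chosen for
controllable rank structure and TPM-like nonnegativity, not an inference
about the original data.

**Protein simulator.** Each SPL-like protein embeds one 74-residue SBP
domain. Within a call, non-motif domain positions derive from a shared
type-level template with per-sequence mutations at rate `divergence`
(default 0.1), mirroring how real SPL groups are conserved beyond their
motifs; this also gives distance-based trees a signal to separate types.
Flanks and non-motif positions avoid C and H so the planted domain is the
unique motif match and the returned coordinates are exact truth.

**Codon-pair simulator.** An ancestral sequence of uniform sense codons is
evolved by single-nucleotide proposals; changes creating stops are
rejected, and nonsynonymous (synonymous) proposals are accepted with
relative probability $\omega$ (1), so the realized dN/dS equals the target
in expectation. The default number of accepted substitutions,
`round(0.35 * n_codons)`, keeps divergence well below the Jukes-Cantor
saturation point ($p < 3/4$).

Each sub-generator draws from a named stream derived from the global seed,
so adding a generator never perturbs another's draws, and identical
config + seed reproduce outputs byte-for-byte.

## SBP-domain scanning and typing

The SBP domain holds two zinc fingers (eight metal-coordinating residues)
and a basic nuclear localization signal. The scanner slides a 74-residue
window and checks domain-relative offsets derived from the spacings
between the family's conserved alignment columns: finger 1 at offsets
0/5/22/25 (C, C, C, then H for type C3HC2HC or C for C4C2HC), finger 2 at
41/44/48/60 (C, C, H, C), and six NLS positions (57/58/70/71/72/73) of
which at least 5 must be K or R. Absolute alignment columns are alignment
artifacts, so only the spacings are used, and they are configurable
(`layout` argument) because the exact spacers of C4C2HC variants are only
partly characterized. The literature quotes both 76 and 74 residues for
the domain; 74 is used because it is the span the logo analyses align,
with the length configurable.

A window with all eight zinc positions satisfied is a complete match;
windows with at least 6 of 8 are reported as incomplete
(`complete = FALSE`). Overlaps are resolved greedily, best first (zinc
count, then NLS count, then position). The scanner is position-covariant:
prepending $k$ residues shifts every coordinate by exactly $k$.

**Domain-length ratios.** The ratio of domain to transcript length uses
the nucleotide basis by default ($74 \times 3 = 222$ nt over transcript
bp), because the comparison it supports contrasts the domain with the
transcript's *total* sequence; an amino-acid basis is available. Group
comparisons use Welch's unequal-variance t-test — the safer default where
the pooled and Welch tests would disagree only far from the decision
boundary; identical zero-variance groups return p = 1 with a warning
rather than an error.

## Expression partitions

"Expressed" means strictly greater than a threshold (default 0) in at
least one sample of a group; the threshold is a configuration knob because
the underlying definition in quantified transcriptomes is
pipeline-dependent. Venn partitions over $2^k$ membership patterns are
computed exactly and always sum to the union (a fuzzed invariant).
Genotype panels are treated as single-sample groups, and the consistency
of expression across genotypes is summarized as the sample CV of
per-genotype expressed counts. The heatmap transform is
$\log_b(v + \text{pseudo})$ with optional per-row z-scaling; zero-variance
rows map to zero rather than NaN.

## Co-expression networks

Spearman's rank correlation (Pearson on average ranks) is computed for all
transcript pairs with nonzero variance; zero-variance transcripts are
dropped with a warning. Two-sided p-values use the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ with $n-2$ df. For small tie-free
samples ($n \le 8$) an exact mode enumerates all $n!$ rank permutations.
The t approximation deviates from the enumerated p by up to about 0.077 at
$n = 5$, 0.048 at $n = 6$ and 0.027 at $n = 7$ over the full grid of
achievable $|\rho|$ (largest in the mid-range); the tests assert the
approximation at the measured 0.05 bound for $n = 6$ and verify the exact
mode against an independent enumeration oracle.

P-values are deliberately **uncorrected** for multiple testing: the
thresholding design tabulates raw p at a ladder of cutoffs (0.05 down to
1e-8 by decades) and interprets counts *relative to a size-matched random
background*, which absorbs the multiplicity; applying FDR control would
change every count and break comparability. This is a statistical caveat
worth restating: a single network at p <= 0.05 over thousands of pairs
contains many false edges, and only the focal-versus-control contrast is
interpretable.

A transcript with no surviving edge at a threshold is not counted as a
node, so node counts fall as the threshold tightens. Ladder counts are
computed from one correlation pass and re-thresholded, making
monotonicity structural (and asserted on every run). The subsampling
design draws `floor(2/3 * |focal|)` focal transcripts and an equal number
of background controls, 20 repetitions by default, reporting mean and sd
of node and edge counts per threshold per set.

**Clustering** is Markov clustering (MCL) on the unweighted adjacency with
self-loops: expansion (matrix squaring) alternating with inflation
(elementwise power 2 by default, column renormalization), pruning entries
below 1e-6, until the largest entry change is below 1e-8 or 100
iterations (non-convergence returns the current clustering with a
warning). Clusters are connected components of the converged support,
guaranteeing a partition that never spans components of the input graph.
The visualization tool traditionally used for such networks clusters with
MCL, but the original cluster counts cannot be tied to a specific
inflation value, so cluster counts are reported, not asserted.

## Phylogeny and group assignment

Trees are built by Saitou-Nei neighbor joining on pairwise p-distances
(fraction of differing sites over columns where neither sequence is
gapped). NJ is implemented in-package because the required behaviour is
pinned down precisely: deterministic tie-breaks (smallest index pair on
the Q criterion) and negative branch lengths clamped to zero with the
deficit moved to the sister branch, preserving the joined pair's path
length. `ape::nj` serves as an independent oracle in the tests (exact
Robinson-Foulds agreement on additive matrices). NJ with p-distances is a
deliberate, documented surrogate for maximum-likelihood inference with
bootstrap support: the package's goal is reproducible group assignment,
which NJ supports exactly on additive inputs, not branch-support
estimation.

Group labels propagate from reference leaves to queries by nearest
patristic distance, with lexicographic tie-breaking (flagged ambiguous).
Monophyly is reported under midpoint rooting, since no outgroup rooting
procedure is prescribed for this family.

## Ka/Ks (NG86)

The Nei-Gojobori (1986) counting method is implemented in full:
fractional synonymous site counts per codon (changes to stops count as
nonsynonymous), sites averaged over the two sequences, observed
differences averaged with equal weights over all minimal substitution
pathways per codon (pathways through stop codons excluded; if every
pathway is invalid the computation falls back to including them), and
Jukes-Cantor correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$.
Saturation ($p \ge 3/4$) and $K_s = 0$ are flagged rather than silently
propagated. Codons containing N in either sequence are excluded and
counted. NG86 is used instead of the ML-flavoured YN00 because the
family-level conclusion it supports (all ratios below 1, purifying
selection) is method-robust, and NG86 admits an exhaustive
pathway-enumeration oracle that makes the implementation fully testable;
NG86 is known to be slightly conservative (it underestimates the
transition/transversion structure), which the neutral-calibration test
bounds empirically (mean estimated ratio within [0.9, 1.1] over 50
neutral simulations at 500 codons).

## Sequence-logo information content

Per-column information content is $IC = \log_2 20 - H$ with $H$ the
Shannon entropy of gap-excluded frequencies, optionally minus the
small-sample correction $e(n) = 19/(2 n \ln 2)$ with $n$ the column's
non-gap count, floored at zero. Frequencies are renormalized over non-gap
residues; columns with more than 50% gaps are flagged, and all-gap columns
get IC 0 with a flag. Columns are reported 1-based to match the
conventional coordinate style of domain-alignment reports.

## Problem sizes and reproducibility

The test-suite and acceptance-script simulations use deliberately compact
designs — 4 groups of 10 samples, 15-30 focal transcripts with 40-60
background transcripts, 20-seed recovery panels, 50-100 replicate
calibrations, 200-500 random trees, 500-codon neutral pairs — sizes at
which every Monte-Carlo band asserted (3 standard errors for calibration
rates, 90% planted recovery, 18/20 separation) has comfortable margin
under the generator's reference conditions. All randomness flows through
named, seed-derived streams; rerunning any stage with the same
configuration and seed reproduces outputs (and pipeline manifest
checksums) exactly.

## Known limitations

* The generator's independent dropout understates the abundance-dependence
  of real zero patterns (see above).
* Raw-p thresholding is only interpretable against the built-in
  size-matched background controls.
* NJ over p-distances ignores substitution-model heterogeneity and
  provides no branch support.
* The motif scanner is a surrogate for profile-HMM domain search; domains
  with unusual spacer lengths require a custom `layout`.
* NG86 omits transition/transversion and codon-frequency weighting; the
  neutral calibration bounds, but does not remove, its bias.
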