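---
title: "Methods: comparing translatomes and their CDS-length signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing translatomes and their CDS-length signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

TRAP-seq (translating ribosome affinity purification followed by RNA-seq)
profiles the ribosome-associated mRNA population — the translatome — of a
genetically defined cell type. A recurring question in synaptic-plasticity
work is whether two perturbations (a mutant versus its wild-type
littermates, or a chemically induced plasticity state versus an
unstimulated control) move the translatome in the same direction, in
opposite directions, or not at all, and whether any shift is coupled to
transcript coding-sequence (CDS) length: in neurons, long-CDS mRNAs encode
synaptic-structure and adhesion proteins while short ones encode
ribosomal and mitochondrial proteins, so a length-coupled shift is itself
a biological signature.

`translens` packages the statistical machinery of that comparison —
paired differential translation, signed-set overlap algebra, fold-change
association, CDS-length shift statistics, and classic-statistic preranked
gene-set enrichment — together with a synthetic generator whose ground
truth makes every stage testable end to end without external data.

# The synthetic generator

`simulate_counts()` draws a paired two-condition experiment with
`n_pairs` matched pairs (default 4, the conventional littermate design)
and `n_genes` genes. The per-gene true effect on the log2 scale is

$$
\mathrm{L2FC}_g \;=\; \beta_{\mathrm{len}}\,
\big(\log_{10}\mathrm{CDS}_g - \overline{\log_{10}\mathrm{CDS}}\big)
\;+\; s_g\,\delta \;+\; \epsilon_g ,
$$

three components that map onto the three phenomena the pipeline must
detect: a length-coupled shift with slope $\beta_{\mathrm{len}}$ per unit
log10 CDS length (positive for an LTP-like state, negative for an
LTD-like one); a length-independent induction $\delta$ (default +2 log2
units) of a small shared up-set $s_g$ emulating immediate-early genes,
which any stimulation switches on; and exchangeable gene-level noise
$\epsilon_g \sim N(0, \mathrm{effect\_sd}^2)$.

Counts are negative binomial with a single global dispersion $\phi$
(variance $\mu + \phi\mu^2$; $\phi = 0$ gives Poisson). Per-gene
dispersions are deliberately not modelled: the downstream contracts are
about set algebra and length statistics, not dispersion estimation, and a
global $\phi$ already produces realistic overdispersion. Both libraries
of a pair share a log-normal size factor (sd 0.2 on the natural-log
scale), which is exactly the structure that makes a paired analysis more
powerful than an unpaired one.

Defaults were fixed once at values a bulk TRAP-seq practitioner would
call typical and are not tuned per analysis: baseline means log-normal
(meanlog 5.5, sdlog 1.2; median ≈ 250 counts), $\phi = 0.05$
(biological-replicate scale), CDS lengths log-normal (meanlog 7.2, sdlog
0.9; median ≈ 1.3 kb, which spreads genes across all four length bins),
`effect_sd` 0.15, shared up-set 2% of genes. Each gene carries 1–3
transcripts whose TPMs split a Dirichlet share of an
expression-proportional gene abundance, so most-abundant-transcript
collapsing is nontrivial; the most abundant transcript carries the
gene's true lengths. 5′ and 3′UTR lengths are drawn independently of CDS
length by default (`utr_cds_coupling = 0`) so CDS-specific shifts are
distinguishable from UTR shifts.

Two RNG streams matter. Genome-level draws (lengths, transcript
structure, baseline means, shared up-set membership) come from
`genome_seed`; dataset-level draws (effect noise, pair factors, counts)
come from `seed`. Two datasets simulated with one `genome_seed` and
different `seed`s therefore share a genome and an IEG set while their
condition effects are independent — the structure of a real
cross-dataset comparison. The two streams are internally offset so the
default `genome_seed = seed` never reuses the same draws for lengths and
effect noise.

What the generator does *not* emulate: read-level artifacts (mapping,
positional bias, UMIs), per-gene dispersion heterogeneity, correlated
effects within pathways, and ontology structure among gene sets
(`simulate_genesets()` controls only size and long-CDS composition bias).
Passing tests therefore demonstrate that the statistics are implemented
correctly and calibrated under this model, not that they are robust to
every artifact of real libraries.

# The differential-translation stage

Normalization is the median-of-ratios estimator: each count is divided by
its gene's geometric mean across samples (genes expressed everywhere
only), and the per-sample median ratio is the factor. Factors are
rescaled to geometric mean 1, a pure anchoring choice that fixes the unit
of "normalized counts" without changing any ratio. The expression filter
retains genes with at least 10 normalized counts in at least 3 samples —
the conventional cutoff for this class of data.

The paired test is deliberately simple and fully specified: per pair
$i$, the log ratio
$r_i = \log_2\big((x^{pert}_i/f^{pert}_i + c)/(x^{ctl}_i/f^{ctl}_i + c)\big)$
with pseudocount $c = 0.5$ on normalized counts (avoiding infinities at
zero counts while perturbing large counts negligibly); the reported
`l2fc` is $\bar r$, its standard error $s_r/\sqrt{n}$, and the p value a
two-sided one-sample t test of the $r_i$ against zero, BH-adjusted over
retained genes. This is an honest stand-in for a negative-binomial Wald
test, not a reimplementation of one: no dispersion shrinkage, no
fold-change shrinkage (flagged in the output metadata), no independent
filtering. When GLM fidelity matters, externally computed DE tables enter
through `read_de_table()` and every downstream stage is unchanged. The
null calibration of the stand-in is good (the acceptance suite verifies
an empirical size of ~0.05 at the 0.05 level over hundreds of null
simulations), but with 4 pairs the test has only 3 degrees of freedom, so
p < 0.01 requires |t| > 5.84 — a point that matters below.

Two significance conventions are exposed: strict (`padj < 0.1`) for
within-dataset calls and relaxed (`pvalue < 0.01`) for cross-dataset
comparisons, where demanding adjusted significance in two independent
experiments is overly conservative.

# Gene-level length annotation

`select_most_abundant()` collapses a per-transcript feature table to one
record per gene: the transcript with maximal TPM wins; TPM ties break by
longest CDS, then lexicographic transcript id, so the result is
deterministic and order-insensitive. CDS bins are half-open with the
lower edge inclusive — [0, 1 kb), [1–2 kb), [2–4 kb), [4 kb, ∞) — a
convention chosen because bin edges (2,000 bases exactly, say) must land
somewhere and lower-inclusive is the least surprising choice; the "long"
class (> 2 kb) used for the long-transcript set is the union of the two
upper bins.

# Set comparison

Signed sets carry one sign per member (the sign of its fold change, or of
its NES for enrichment terms). Genes with a fold change of exactly zero
have no direction and are excluded, with a count kept. The percent
overlap follows the first-circle convention:
$100\,|A \cap B| / |A|$ — asymmetric on purpose, with the first-named
dataset as denominator; same-direction and opposite-direction percentages
are fractions of the overlap. Overlap significance is an upper-tail
hypergeometric probability $P(X \ge |A \cap B|)$ with the universe
defaulting to the genes tested in both datasets — the standard choice
when a Venn p value is wanted and nothing forces another background; the
universe is an explicit argument, so any other convention is one call
away.

# Cross-dataset association

`cross_correlate()` pairs the reference set's fold changes with the query
dataset's fold changes for the same genes: Pearson r with a two-sided p,
the OLS line, and a penalized cubic regression spline (`mgcv::gam`,
`bs = "cr"`, 10 basis functions, smoothness by GCV — the conventional
default when the only specification is "a GAM"). Both curves are
evaluated on a 100-point grid; their maximum absolute gap quantifies
departure from linearity, and the spline's deviance fraction is never
below the linear $R^2$ (the linear function lies in the spline's
penalty-free null space). The reported $R^2$ is exactly $r^2$ — plain,
not adjusted — and the package asserts that identity rather than leaving
the relation between its own two numbers ambiguous.

`group_shift()` tests reference-up and reference-down groups in the
query: Kruskal–Wallis across the two groups, then per-group two-sided
Wilcoxon rank-sum against the query fold changes of all genes in
*neither* group. Comparing to the remaining transcriptome (rather than
between the two groups, or to an exact zero) is what makes "no change in
the down-group" an interpretable outcome; a one-sample zero-median
alternative is available via `reference = "zero"`.

# The CDS-length shift

`length_correlation()` correlates fold change with
$\log_{10}(\mathrm{length} + 1)$ — lengths are roughly log-normal, so the
log scale keeps a handful of very long genes from dominating the
correlation; raw lengths are a switch away. `binned_ztest()` computes,
per bin, a two-sample z with unpooled (Welch-style) variances against a
reference population. Two reference conventions exist:

* `reference = "all"` (default) — the reference is every annotated gene,
  *bin included*, matching the usual ">4 kb vs all" presentation of such
  analyses. Because the bin overlaps its own reference, the statistic's
  null variance is overstated and the test is conservative; its p values
  are not uniform under the null (they pile up toward 1), which is a
  property of the convention, not a bug.
* `reference = "rest"` — the bin's complement; this is the calibrated
  Welch two-sample form, and it is the variant the calibration checks
  exercise.

The population entering the length analyses is a genuine design choice.
On real data with a high-powered NB Wald test, the relaxed-significant
population (p < 0.01, roughly the top few percent of genes) is the
natural one. Under the packaged t stand-in with 4 pairs, p < 0.01 selects
only the handful of genes beyond |t| > 5.84 — a set dominated by the
strongly induced IEGs and by null-tail noise — so bin statistics computed
on it measure selection artifacts rather than the length coupling. The
pipeline therefore defaults to `length_population = "all"` (the whole
filtered translatome), which is where a slope of ±0.3 per log10 CDS unit
is cleanly detectable at 2,000 genes, and offers `"significant"` for the
figure-faithful variant.

# Preranked enrichment

Genes are ranked by fold change, descending, ties broken by ascending
gene id (deterministic; no jitter). The classic, unweighted running-sum
statistic steps $+1/N_{hit}$ at members and $-1/N_{miss}$ at non-members;
the enrichment score is the signed maximum deviation from zero. Candidate
extremes are evaluated in integer arithmetic on the common denominator
$N_{hit} N_{miss}$, so an exact magnitude tie between the positive and
negative extreme is detected exactly and resolved to the positive side
(accumulating the running sum in floating point would let ~1e-16 drift
decide the sign). A set covering the whole list has no misses; its
running sum is $i/N$ and its ES is defined as 1, a degenerate case the
size filter excludes in practice.

The permutation null redraws each set's positions uniformly (gene-label
permutation with size held fixed — the only null available to a
preranked analysis; same-size sets share one null). NES divides ES by
the mean absolute same-sign null ES; the nominal p is the same-sign null
tail fraction, reported as 0 at the permutation floor (the convention of
the reference GSEA implementation, rather than an add-one-smoothed
floor); FDR q is the standard NES-based ratio of null-to-observed tail
fractions, capped at 1 and not clamped below the nominal p. Sets with
ES = 0 get NES = 0 and p = 1. Leading-edge reporting and the weighted
($p = 1$) statistic are out of scope. Over-representation of an
unordered hit list is the plain upper-tail hypergeometric per set with
BH across sets.

# Pipeline and determinism

`run_pipeline()` executes the stages in dependency order from one
declarative configuration (an R list or YAML file) in which every
threshold is a named key with its conventional default: strict 0.1,
relaxed 0.01, filter 10-in-3, GSEA size window 20–500 with 1,000
permutations. All outputs are tab-separated text; the manifest records
derived seeds, gene counts into and out of every filter (so the Venn
arithmetic is auditable from the log alone), headline statistics, and an
MD5 per file. Re-running an identical configuration reproduces every
file byte for byte, which the test suite asserts by hashing two runs.

The packaged demonstration (`run_demo()`) simulates an LTP-like
($\beta_{\mathrm{len}} = +0.3$) and an LTD-like ($-0.3$) dataset on one
shared genome with a common IEG up-set. Its expected phenotype: the
transcript-level overlap of relaxed-significant sets is dominated by the
shared IEGs and is therefore predominantly *same*-direction (the
specific-set operation then removes exactly that shared population, as
one does before asking stimulation-specific questions), while the two
length-shift reports show opposite-signed extreme-bin z statistics and
opposite-signed length correlations — the bidirectional long-mRNA
signature the package exists to detect.

# Problem sizes and numerical conventions

The test and acceptance suites use 300-gene simulations for the 500-seed
null-calibration runs and the full 2,000-gene, 4-pair configuration for
the 100-seed recovery runs in each direction — sizes at which every
targeted property is comfortably identifiable while a complete run stays
in the tens of seconds. Other conventions: missing values are "NA" in
all tables; size factors carry geometric mean 1 to 1e-9; BH adjustment
excludes missing p values and returns them missing; duplicate gene ids
are a hard error in tables and a warned first-occurrence-wins
deduplication when pairing across tables; degenerate rank tests
(single-member or constant groups) return NA with a warning rather than
failing.

# Known limitations

* The paired location test is a stand-in; its ranking of borderline
  genes will differ from an NB GLM with shrinkage, and with few pairs its
  relaxed-significant sets are small. Import real DE tables where that
  matters.
* The inclusive "vs all" z reference is conservative by construction;
  use `"rest"` when calibrated p values are needed.
* Synthetic gene sets have controlled size and length bias but no
  ontology structure; term-level conclusions transfer to real MSigDB
  collections only at the level of the statistics, not the semantics.
* The generator's single global dispersion understates the
  mean–dispersion trend of real data; calibration results say nothing
  about per-gene dispersion estimation because none is performed.
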