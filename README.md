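# translens

Cross-dataset translatome comparison and CDS-length shift analysis.

TRAP-seq (translating ribosome affinity purification + RNA-seq) profiles
the ribosome-associated mRNA population of a defined cell type. When two
such experiments exist — a mutant versus wild-type littermates, or a
chemically induced plasticity state versus its control — the recurring
questions are: do the two perturbations move the translatome in the same
or opposite directions, and is the shift coupled to coding-sequence (CDS)
length? In neurons long-CDS mRNAs encode synaptic-structure and adhesion
proteins while short ones encode ribosomal and mitochondrial proteins, so
a length-coupled shift is itself a signature of the plasticity state.

`translens` implements that comparison as composable stages, plus a
seeded synthetic generator with known ground truth so the whole analysis
is testable end to end:

* **Paired differential translation** — median-of-ratios size factors;
  the "≥ 10 normalized counts in ≥ 3 samples" filter; per-pair log2
  ratios r_i = log2((perturbed_i/f + c)/(control_i/f + c)), with
  l2fc = mean(r_i), a one-sample t test, and Benjamini–Hochberg
  adjustment. Externally computed DE tables (e.g. DESeq2 exports) can be
  supplied instead via `read_de_table()`.
* **Signed-set algebra** — significant sets at the strict (padj < 0.1)
  or relaxed (p < 0.01) convention; stimulation-specific sets (A minus
  B); percent overlap per the first-circle convention
  100·|A∩B|/|A|; upper-tail hypergeometric overlap significance;
  same/opposite-direction concordance.
* **Cross-dataset association** — Pearson r (with R² = r²), OLS line and
  penalized cubic-spline smoother with their maximum gap, and
  Kruskal–Wallis / Wilcoxon group-shift tests of reference-up and
  reference-down gene groups.
* **CDS-length shift** — correlation of l2fc with log10 CDS length of
  the most abundant transcript, per-bin (<1, 1–2, 2–4, >4 kb) two-sample
  z statistics z = (mean_bin − mean_ref)/√(s²_bin/n_bin + s²_ref/n_ref),
  and the long-transcript (>2 kb) set with its up-fraction.
* **Preranked enrichment** — the classic (unweighted) running-sum
  enrichment score, permutation NES, nominal p and FDR q at
  GSEA conventions (size window 20–500, 1,000 permutations), plus
  hypergeometric over-representation; term-level results feed the same
  signed-set overlap machinery.

## Worked example

Simulate an LTP-like experiment (effect slope +0.3 per log10 CDS unit, 4
littermate pairs, 2,000 genes), run the DE stage, and ask for the length
signature:

```r
library(translens)

cfg <- sim_config(n_genes = 2000, length_effect_slope = 0.3, seed = 1)
sim <- simulate_counts(cfg)

factors <- median_of_ratios(sim$counts)
keep <- filter_low_expression(sim$counts, factors)
de <- paired_de(sim$counts, sim$design, factors, keep$retained)

ann <- select_most_abundant(sim$truth$transcripts)
binned_ztest(de, ann)
#> length shift over 1994 annotated genes (mean l2fc 0.022, reference 'all')
#>     bin   n mean_l2fc      z        p
#>   <1 kb 755    -0.078 -5.476 4.35e-08
#>  1-2 kb 590     0.023  0.073 9.42e-01
#>  2-4 kb 428     0.097  3.517 4.37e-04
#>   >4 kb 221     0.213  7.578 3.52e-14

lc <- length_correlation(as_signed_set(de), ann)
#> r = 0.256, p = 3.9e-31 (n = 1994)
```

Short mRNAs are under-translated (z = −5.5 in the <1 kb bin), long ones
over-translated (z = +7.6 above 4 kb), and fold change correlates
positively with log CDS length (r ≈ 0.26) — the planted LTP-like
signature, recovered. Flipping the slope to −0.3 flips every sign
(LTD-like). The full two-dataset scenario — shared genome, shared
immediate-early-gene up-set, opposite length couplings, overlap and
concordance reports, GSEA on both datasets, and a hashed run manifest —
is one call:

```r
manifest <- run_demo(out_dir = "demo", seed = 1)
```

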