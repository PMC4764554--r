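# nmdprotect

Tools for asking, quantitatively, how mRNAs escape nonsense-mediated
decay (NMD) through PTBP1 binding near the stop codon.

NMD eliminates transcripts that terminate translation unusually far from
the poly(A) tail, which makes every long-3'UTR mRNA a potential
substrate — yet many such mRNAs are stable. When the polypyrimidine tract
binding protein PTBP1 occupies CU-rich elements immediately downstream of
the termination codon (TC), UPF1-dependent decay is suppressed. This
package implements the computational workflow behind that analysis for
people working with knockdown RNA-seq, CLIP peaks and reporter decay
assays:

* **Protection sets.** From a gene x sample matrix of 3'UTR-mapped read
  counts in a four-condition design (siNT, siUPF1, siPTBP1,
  siPTBP1+siUPF1): normalize (RPKM → upper-quartile → log2, with a
  25-read floor), test each gene with a one-way ANOVA, and classify genes
  *down-regulated* upon PTBP1 depletion (mean log2 FC < 0, p < 0.05, and
  the same fold-change sign in every replicate pairing) and *rescued*
  upon UPF1 co-depletion (the nested subset whose double-knockdown vs
  siPTBP1 fold change is reproducibly positive).
* **TC-anchored hexamer scanning.** All (including overlapping)
  occurrences of the six high-affinity PTBP1 hexamers
  (UUCUCU, UCUUCU, UCUCUU, UCUCUG, CUUUCU, CUUCUC) in 3'UTRs, with
  window membership in [0,400), [0,150), [0,50), [50,100) nt downstream
  of the TC under a full-containment rule.
* **CLIP positional analysis.** iCLIP / HITS-CLIP read-preprocessing
  rules, a strict <500 nt peak-width filter, assignment of peak centers
  to exemplar transcripts (the longest-3'UTR transcript per gene),
  20-nt-binned metagene density around the TC, positional gene classes
  ([0,200) vs [200,500) nt), and Kolmogorov–Smirnov comparisons of
  siUPF1 fold-change CDFs within a data-derived inter-quartile
  3'UTR-length band.
* **Decay kinetics.** Half-lives from semilog least squares
  (t_1/2 = ln2 / k_decay) with t-based 95% CIs, two-tailed ANCOVA on
  slope equality, ΔΔCt, and IP relative recovery.
* **Synthetic data.** A seeded generator producing annotation (GTF /
  refFlat), 3'UTR FASTA, counts, BED peaks and decay tables with planted
  ground truth, so the whole pipeline is testable end to end offline.

## Worked example

```r
library(nmdprotect)

# the printed PTBP1 binding-site cassette contains three hexamer matches
scan_hexamers("CTCTCTCTTCTTCTT")
#>   offset  motif
#> 1      3 TCTCTT
#> 2      5 TCTTCT
#> 3      8 TCTTCT

# a complete synthetic study: 2000 genes, 4% protected, planted truth
cfg <- pipeline_config(sim = simulation_config(seed = 42, n_genes = 2000))
res <- run_pipeline(cfg)

res$sets
#> <protection_sets: 83 down-regulated, 55 rescued (alpha = 0.05)>

res$decay_fits$thalf_120          # reporter planted with t1/2 = 120 min
#> <decay_fit: t1/2 = 116.3 min [109.6, 123.9], k = 0.00596/min, R2 = 0.992>
```

Reading those numbers: 83 genes were reproducibly down upon PTBP1
knockdown and 55 of them reproducibly rebounded when UPF1 was co-depleted
(the "rescued" = protected candidates). The reporter fit recovers the
planted 120-min half-life within its confidence interval. The report also
carries the positional results — at this seed the rescue-vs-knockdown
Spearman rho is −0.405, and the siUPF1 fold-change CDF of genes with a
CLIP peak centered within 200 nt of the TC is significantly left-shifted
against peak-free genes (K-S p = 0.032) while the 200–500 nt class is not
(p = 0.94), reproducing the positional specificity of the protection
signal. Setting `outdir` in `pipeline_config()` additionally writes all
per-gene tables, the simulated inputs (GTF/FASTA/BED/TSV), a JSON report
and a log that echoes every threshold.

A thin command-line wrapper with `simulate` and `report` subcommands is
installed at `inst/scripts/nmdprotect.R`.

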