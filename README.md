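# factormir

Joint latent factor analysis of mRNA and miRNA expression profiled on the
same samples.

## The problem

Transcriptional (mRNA) and post-transcriptional (miRNA) activity are
usually mined separately, which can miss *emergent* structure — patterns of
covariation that only appear when both molecular levels are analyzed as one
system. The canonical example this package is built around: a handful of
factor-selected miRNAs that turn out to sit together on the chromosome in
polycistronic transcripts (miR-17-92-like clusters), co-loading on a factor
that also discriminates tumor histotypes. Analyzing the miRNA table alone,
that signal never reaches significance; stacked with thousands of mRNAs it
does.

`factormir` implements the full pipeline for small-cohort two-level
expression studies (the reference design: 12 brain-tumor biopsies, ~5,000
mRNAs after filtering, 93 miRNAs):

1. **Preprocessing** — log2 transform (mRNA), maximum-fold-change filter
   (rows with max fold change < 2.5 removed), row normalization onto
   [0, 1] or [μᵢ, μᵢ+1], stacking into one joint table.
2. **Factor extraction** — the common factor model `D = LF + ε` with
   `D = Xᵀ` (samples are the variables, genes the observations; `L` is
   m×l sample loadings, `F` is l×n gene scores), fitted by iterated
   principal axes on the m×m sample correlation matrix with SMC
   initialization, then rotated obliquely (varimax-then-Promax). Factor
   count by the Kaiser criterion (eigenvalue > t, t = 1) or user choice.
3. **Model selection** — leave-one-out (jack-knife) linear discriminant
   analysis of clinical dichotomies on the sample loadings, greedy
   factor-subset search, confusion tables scored by a two-sided Fisher
   exact test; models with no contrast at p < 0.05 are dropped and ties
   go to the model with fewer factors.
4. **Gene selection** — regression (Thomson) factor scores per gene;
   genes outside μ ± 2σ of a factor's score distribution form its
   positive/negative gene sets.
5. **Enrichment** — exact hypergeometric upper-tail tests of genomic
   miRNA clusters among the selected miRNAs (background = all detected
   miRNAs), Bonferroni corrected; generic GMT term sets with
   Benjamini-Hochberg or Bonferroni; indirect miRNA annotation via
   target-gene joins.
6. **Synthetic data** — a seeded generator that plants loadings, scores,
   class-separating factors and clustered miRNAs, plus recovery metrics
   (Tucker congruence, selection precision/recall), so every stage is
   testable against ground truth.

## Worked example

```r
library(factormir)

ds  <- simulate_dataset(synthetic_spec(seed = 7))   # 5,059 x 12 joint world
out <- run_pipeline(ds)                             # filter + FA + selection
ev  <- evaluate_recovery(ds, out)

round(ev$congruence, 3)
#> [1] 0.971 0.971 0.995
ev$cluster_enrichment
#>               unit  N K  n k        p_raw        p_adj     method
#> 1   mir-17-92-like 93 4 10 4 7.192434e-05 2.157730e-04 bonferroni
#> 2 mir-106-363-like 93 3 10 3 9.247415e-04 2.774224e-03 bonferroni
#> 3            union 93 7 10 7 1.266675e-08 3.800025e-08 bonferroni
accuracy(ev$lda$anaplastic)
#> [1] 1
```

The three planted factors are recovered with congruence > 0.97, the two
planted polycistronic miRNA clusters are significantly over-represented
among the factor-selected miRNAs after Bonferroni correction, and the
planted 10/2 histotype dichotomy is classified 12/12 by leave-one-out LDA.

The published confusion tables reproduce directly:

```r
fisher_exact_two_sided(confusion_table(9, 0, 1, 2))   # grade
#> [1] 0.04545455
fisher_exact_two_sided(confusion_table(10, 0, 0, 2))  # anaplastic
#> [1] 0.01515152
accuracy(confusion_table(9, 0, 1, 2))
#> [1] 0.9166667
```

## Command line

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/factormir", package="factormir"))')
Rscript $CLI simulate   --seed 5 --outdir sim
Rscript $CLI preprocess --mrna sim/mrna.tsv --mirna sim/mirna.tsv \
                        --norm none --out joint.tsv --log prep.json
Rscript $CLI fa         --input joint.tsv --factors 3 --out model.json
Rscript $CLI classify   --model model.json --metadata sim/metadata.tsv \
                        --out report.tsv
Rscript $CLI enrich     --selected sel.txt --background bg.txt \
                        --clusters sim/clusters.bed --out enrich.tsv
```

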