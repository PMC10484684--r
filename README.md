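# tfoccupancy

Predicts ChIP-seq-like transcription factor (TF) binding profiles from
DNA sequence, a binding motif, TF abundance and chromatin
accessibility, and classifies how much each TF's binding depends on DNA
accessibility. It is aimed at regulatory-genomics analysts who want an
*explainable* model of TF binding: every prediction traces back to four
ingredients — a JASPAR-style position weight matrix (PWM), an
accessibility track (DNase-seq/ATAC-seq-like), the number of bound
molecules and a specificity factor — rather than to an opaque learned
representation.

## The model

For the site starting at position *j*, with PWM score *w_j* and
accessibility *a_j* ∈ [0, 1], the probability that one of the *N*
genome-bound TF molecules occupies the site is

```
P_j = N a_j exp(w_j / λ) / ( N a_j exp(w_j / λ) + L n ⟨ a_i exp(w_i / λ) ⟩ )
```

where λ is the specificity scaling factor, *L* and *n* are genome
length and ploidy, and ⟨·⟩ averages over all scanned sites. *N* and λ
are fitted by grid search, minimising the mean squared error between
the smoothed model profile and the ChIP signal over the
strongest-signal genomic bins; the fit is validated by ROC AUC over
windows of held-out bins.

Re-running the fit while only the top (1 − q) accessibility quantile of
the genome is considered accessible — the quantile density
accessibility (QDA) procedure, q from 0 to 0.99 — reveals each TF's
chromatin preference. TFs that stay predictable at every q are
accessibility independent factors (AIF); TFs predictable only at high
q are accessibility dependent (ADF); TFs predictable only at low q
are inaccessibility dependent (IDF), with partial classes in between.

A fully seeded synthetic-data generator (genome with planted motif
instances, block-structured accessibility, Poisson ChIP counts around
the model's own occupancy) makes the whole pipeline testable offline.

## Worked example

Generate a synthetic TF that binds only the most accessible chromatin,
run the full analysis, and classify it:

```r
library(tfoccupancy)

scn <- synthetic_scenario("open_only", seed = 42, genome_bp = 5e5)
ds  <- generate_dataset(scn)

res <- analyse_dataset(ds$genome, ds$access, ds$chip, ds$peaks, scn$pfm,
                       bin_bp = 25000, n_train = 6, n_validate = 12,
                       qda_grid = c(0, 0.1, 0.2, 0.8, 0.9, 0.95),
                       N_grid = c(5, 50, 500, 5000, 5e4),
                       lambda_grid = c(0.5, 1, 2, 4))

round(res$auc, 3)
#> qda_0.00 qda_0.10 qda_0.20 qda_0.80 qda_0.90 qda_0.95
#>    0.801    0.819    0.836    0.933    0.972    0.989

res$classification
#> dataset: partial_AIF_ADF (dense 0.819, open 0.965, diff +0.146)
```

Reading the output: at QDA 0 the model may place the TF anywhere in the
genome, and the many unbound motif matches in dense chromatin degrade
the prediction (AUC ≈ 0.80); restricted to the open top decile
(QDA 0.9) the prediction is nearly perfect (AUC ≈ 0.97). The mean AUC
over the dense window (QDA 0–0.2) is 0.819, over the open window
(QDA 0.8–0.95) 0.965, and the difference of 0.146 puts the TF in the
partial AIF/ADF class — a factor with a clear preference for open
chromatin, exactly the regime the generator planted.

`run_pipeline()` performs the same analysis from a configuration
(synthetic scenario or FASTA/bedGraph/BED/JASPAR inputs) and writes the
AUC row, fitted parameters, classification and a YAML manifest;
`inst/scripts/tfoccupancy.R` wraps it for shell use.

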