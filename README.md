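# prdscan

Prediction of Q/N-rich prion-forming domains (PrDs) in protein sequences.

Prion proteins carry low-complexity domains — typically rich in glutamine
and asparagine and depleted in charged residues and scattered prolines —
whose *composition* drives conversion to a self-templating aggregated
state. `prdscan` turns that compositional signature into a calibrated
probabilistic scanner for protein databases: it is aimed at
computational biologists triaging proteomes for prion-like candidates,
and at method developers who need the full benchmarking stack
(ROC/AUC, precision–recall, accuracy-versus-cutoff, rank-sum,
bootstrap) around a sequence classifier.

## The model

Each amino acid `i` carries a statistical potential in bits,

    LOr_i = log2(f_i / p_i)

with `f_i` its frequency among prion proteins and `p_i` its background
frequency in the protein universe. A window of length `L` scores

    Score_L = sum_l LOr_l + sum_j LOr(d_{j+1} - d_j)

where the second sum, over consecutive proline pairs at separation `d`,
scores the window's proline spacing pattern against a reference spacing
distribution (clustered prolines are tolerated in prion domains,
scattered ones are not). Sequences are scanned with a 60-residue sliding
window at step 1; windows at or above the 50-bit cutoff — the
accuracy-maximising calibration point — are reported as predictions.

The per-residue odds table of the prion-domain class ships with the
package (`builtin_propensity_table()`), as does a frozen Swiss-Prot
background composition; both can be replaced by training on your own
FASTA files. The bundled proline spacing model is trained on a
synthetic reference and is nearly neutral — see the methods vignette
(`vignettes/prion-domain-prediction.Rmd`) before interpreting the
proline term quantitatively.

## Worked example

```r
library(prdscan)

m <- prd_model()                 # published table, window 60, cutoff 50
round(coef(m)[c("N", "Q", "S", "Y", "E", "C")], 3)
#>      N      Q      S      Y      E      C
#>  2.511  2.044  0.733  0.786 -2.766 -3.816

# a synthetic 200-protein proteome with 6 planted prion domains
sim  <- make_proteome(n_proteins = 200, prd_fraction = 0.03, seed = 1)
pred <- predict(m, sim$records)
pred[, c("organism", "protein_id", "start", "end", "score_bits")]
#>              organism protein_id start end score_bits
#> 1   Synthetica primus   prot0003    75 134      70.05
#> 2   Synthetica primus   prot0015    76 135      72.24
#> 3 Synthetica secundus   prot0062    23  82      84.36
#> 4 Synthetica secundus   prot0090   162 221      80.92
#> 5 Synthetica secundus   prot0132   204 263      87.81
#> 6 Synthetica secundus   prot0170   273 332      79.45
```

All six planted domains (`sim$truth`) are recovered with no false calls;
scores of 70–88 bits sit far above the 50-bit cutoff. Predicted starts
land on or within a few residues of the planted starts (`prot0062` is
called 3 residues early — compositional domain boundaries are soft; see
the vignette's limitations section). Empirical p-values against the
proteome's per-protein best-score distribution:

```r
s <- predict(m, sim$records, type = "score")
signif(empirical_pvalue(pred$score_bits, s), 3)
#> [1] 0.03480 0.02990 0.01490 0.01990 0.00995 0.02490
```

with 200 reference proteins the add-one estimator bottoms out at
1/201 ≈ 0.005; on real proteomes of thousands of proteins the planted
domains separate much further.

Real data goes through the same verbs: `read_fasta()` /
`read_uniprot_flatfile()` to load, `predict()` or `scan_proteome()` to
scan, `write_predictions_tsv()` / `write_predictions_paper_format()`
to report, and `train_propensity_table()` / `train_proline_model()` to
refit either model component.

A command-line interface wraps the same functions:

```sh
prdscan simulate --kind benchmark --seed 3 --out bench
prdscan train --prd bench_pos.fasta --out table.tsv
prdscan scan --input proteome.fasta --table table.tsv --cutoff 50 --out hits.tsv
prdscan benchmark --pos bench_pos.fasta --neg bench_neg.fasta --out report/
```

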