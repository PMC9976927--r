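# pausescape

Predictive modeling of RNA polymerase II promoter-proximal pausing from
chromatin signatures.

After initiating transcription, Pol II typically stalls a few dozen
base pairs downstream of the transcription start site (TSS); the release
of this *promoter-proximally paused* polymerase into productive
elongation is a central regulatory step of metazoan gene expression.
`pausescape` is an R package for asking, genome-wide, *which DNA- and
RNA-binding factors carry information about the degree of pausing*. It
is aimed at computational genomicists working with nascent-transcription
(GRO-seq-style) coverage together with ENCODE-style ChIP-seq/eCLIP-seq
peak files, and at anyone who wants a fully synthetic, ground-truthed
sandbox for this class of pipeline.

## What it computes

**Pausing index.** For each transcript, with strand-specific per-base
coverage summed as `c_tss` over the sharp TSS window `[TSS-h, TSS+h]`
(default h = 1, i.e. 3 bp) and `c_body` over the remaining span
downstream,

```
PI = log2( (c_tss + 1) / w_tss ) - log2( (c_body + 1) / w_body )
```

with `w_tss = 2h+1`, `w_body = L - w_tss`, and a pseudocount of one
read per window. High PI = paused, low PI = elongating. The window
half-width is chosen by scanning a grid and keeping the half-width whose
PI correlates most negatively with log10 FPKM expression. Transcripts
pass RefSeq-confidence, two-replicate expression, dominant-CAGE-TSS,
clean-sequence, same-strand-overlap and nonzero-signal filters first.

**Feature matrix.** Binary region-resolved binding flags
(`chip.<FACTOR>.<region>`, `clip.<FACTOR>.<region>`, with
`5prime/codingexon/intron/3prime` regions, plus the same encoding on the
two most TSS-proximal ncRNAs), six CpG-island descriptors and twelve
annotation/sequence features, min-max scaled; Pol II (POLR2\*) columns
are split into a side table used only by an explicit reference model.

**Models and attributions.** Gradient-boosted tree regression of the PI
(5-fold CV for hyperparameters, 50% holdout for the headline R²),
synchronized cross-cell-line evaluation, differential-pausing groups,
random-feature baselines, and ridge/random-forest/plain-GBDT reference
learners. Fitted boosters are explained with exact TreeSHAP
attributions, aggregated to per-factor contribution scores; the minimal
factor set covering 50% of contributions is selected, and functional
factor sets (Chromatin, Initiation, Elongation, Splicing, Termination,
Processing, 7SK-binding — GO-derived plus a packaged literature list)
are scored and tested for enrichment with one-sided Fisher exact tests.

**Synthetic study.** `simulate_bundle()` writes a complete seeded bundle
(FASTA genome, GTF, per-factor BED peaks, plus/minus wiggle coverage,
expression/CAGE/CpG tables, ground-truth JSON) in which 10 of 60 factors
causally drive the pausing index, pause signal sits within ±1 bp of the
TSS, expression is anti-correlated with pausing, and every exclusion
filter has deliberately planted victims. All package claims are tested
as recovery experiments on these bundles.

## Worked example

```r
library(pausescape)

cfg <- generator_config(n_genes = 300, n_ncrnas = 20,
                        n_factors = 20, n_causal = 5)
dir <- tempfile("bundle")
b   <- simulate_bundle(cfg, dir, seed = 1)

run <- run_pipeline(dir,
                    spec = model_spec(eta = 0.05, max_depth = 3,
                                      nrounds_max = 500, seed = 1))
run
#> pause_run:
#>   transcripts modeled: 261
#>   TSS halfwidth: 1
#>   holdout R2: 0.193 (rho 0.458)
#>   minimal factor set: 4 factors (>= 61% of contributions)

run$exclusion_report
#>       reason     n
#>       <char> <int>
#> 1:  non_acgt     3
#> 2:   overlap     2
#> 3: no_signal     5
#> 4:  retained   261
```

The exclusion report shows each planted pathology caught by its filter:
the three transcripts with non-ACGT bases, the deliberately overlapping
same-strand pair, and the five silenced transcripts. The window scan
(`run$window_scan`) recovers the 3 bp TSS window, the computed PI
correlates with the planted PI at ρ ≈ 0.97, and the factor ranking
(`run$ranking`) puts the planted causal factors on top — at this toy
size the holdout R² is modest; at the default study size (3000 genes,
60 factors) it reaches ≈ 0.6:

```r
head(run$ranking, 4)
#>    factor_name         S     share
#>         <char>     <num>     <num>
#> 1:  annotation 0.6573556        NA
#> 2:         F05 0.3731965 0.1812052
#> 3:         F12 0.3297749 0.1601219
#> 4:         F04 0.3053882 0.1482810

unlist(b$truth$causal_factors)
#> [1] "F04" "F05" "F07" "F10" "F12"
```

`compare_cell_lines()` runs the synchronized two-cell-line analysis on a
pair of bundles sharing effect sizes but with cell-specific binding, and
`identify_7sk_binders()` recovers exactly the factors planted with CLIP
peaks on the 7SK (and sufficiently expressed pseudo-7SK) transcripts.

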