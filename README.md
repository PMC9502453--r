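# ms2fp — molecular fingerprint prediction from LC-MS/MS spectra

Spectral-library search can only identify compounds that are already in a
library, and fewer than a tenth of known metabolites have reference MS/MS
spectra. `ms2fp` takes the complementary route: learn a map from the
product-ion spectrum to the molecule's 166-bit MACCS substructure
fingerprint, then rank the structures of any candidate library by their
Jaccard–Tanimoto similarity to the *predicted* fingerprint. The compound
need not be in a spectral library, only in a structure database.

The package is aimed at computational metabolomics / chemometrics users
who want a self-contained, testable R implementation of this workflow —
from raw MSP-style library records to candidate rankings.

## The model

Spectra are binned on a fixed m/z grid (45.0–704.5 Da at 0.1 Da = 6596
bins, per-bin maximum intensity, per-spectrum normalisation to max 1), and
a multi-task feed-forward network maps the binned vector (or its sparse
PCA scores) to per-bit probabilities:

```
x ∈ [0,1]^p  →  FC(N, σ)  →  dropout  →  FC(NTS, σ)  →  166 sigmoid outputs
```

one output per MACCS key *t*, trained with mean binary cross-entropy.
Each bit is binarized with its own Bayes-optimal threshold (minimising
FP_t + FN_t on training scores), and the final label is the majority vote
over five replicate networks that differ only in their initialisation
seed. Performance is summarised per task by the non-error rate
NER_t = (Sn_t + Sp_t)/2 averaged over tasks, and per spectrum by the
Jaccard–Tanimoto similarity JT = a/(a+b+c) between predicted and true
fingerprints. Hyperparameters (N, NTS, learning rate, activation,
dropout, batch size, patience, optimizer) are tuned by a Tree-structured
Parzen Estimator maximising F = JT_val · (1 − |JT_train − JT_val|).

Supporting machinery: a metadata/spectrum curation cascade with per-rule
accounting, compound-grouped train/validation/test splitting (spectra of
one molecule never cross sets), sparse PCA with leakage-free projection,
classical MDS diagnostics of the fingerprint space, and a synthetic
spectrum–fingerprint generator with a planted, learnable bit→peak map
plus an adversarial (pure-noise) negative control.

## A worked example

```r
library(ms2fp)

cfg  <- synthConfig(seed = 101)            # 300 compounds, ~1500 spectra
ds   <- generateSynth(cfg)
cured <- cureSpectra(ds$records)           # all synthetic records pass
sm   <- binSpectra(cured$records, cfg$grid)
sp   <- groupSplit(cured$records, seed = 102)

x  <- as.matrix(matrixValues(sm))
y  <- spectrumTargets(ds, rownames(x))
tr <- splitRecords(sp, "train"); va <- splitRecords(sp, "val")
te <- splitRecords(sp, "test")

hp  <- hyperparameters(n_neurons = 150, n_task_specific = 250,
                       learning_rate = 0.001, activation = "relu",
                       dropout = 0.2, batch_size = 128, patience = 15,
                       optimizer = "adam")
ens <- trainEnsemble(hp, x[tr, ], y[tr, ], x[va, ], y[va, ],
                     n_replicates = 5, base_seed = 103, max_epochs = 50)

report <- evaluationReport(predict(ens, x[te, ]), y[te, ])
report$ner                        # 0.705
report$mean_jt                    # 0.390
randomBaselineMean(y[te, ], 10, seed = 104)   # 0.126
```

A test-set NER of 0.705 (0.5 = random guessing) and a mean JT of 0.390
against a maintained-active-fraction random baseline of 0.126 show the
ensemble recovering most of the planted spectrum→fingerprint structure
from unseen compounds; on the adversarial generator the same protocol
collapses to the baseline (JT 0.061, NER 0.502), confirming that nothing
but the planted signal is being learned. The methods vignette
(`vignettes/fingerprint-prediction.Rmd`) discusses why the synthetic
ceiling (~0.90) is not reached at this sample size and what changes at
repository scale.

The same pipeline runs as file-based stages with manifests:

```r
runPipeline("synth", config = list(paths = list(outdir = "run1")))
runPipeline("cure",  config = list(paths = list(outdir = "run1")))
# ... vectorize, split, train, predict, evaluate, match
```

or from a shell via `inst/scripts/ms2fp.R`.

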