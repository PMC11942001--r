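# regulome56

Most of a transcriptome is redundant with a small layer of regulatory
molecules. `regulome56` is an R package (plus a numbered analysis workflow)
for testing that premise quantitatively: it discovers a compact panel of
representative transcription factors (TFs) and microRNAs (miRNAs), predicts
every other gene from that panel with and without tissue context,
characterizes which genes are predictable, and diagnoses what breaks when
the model is transported to a dataset with shifted and renamed features.

## What it computes

**Regulatory components.** Each regulator is represented by its loadings
ν<sub>i</sub> ∈ R<sup>d</sup> on the top d principal components of the
regulator correlation structure (d chosen by a Bayesian step-function
criterion), scaled so ‖ν<sub>i</sub>‖² is the variance fraction explained.
Features with ‖ν<sub>i</sub>‖ < 0.35 are discarded; the remaining loading
*directions* are clustered on the hypersphere with a von Mises–Fisher
mixture (EM; K by BIC). Each cluster's medoid — the member closest to the
mean direction — represents the component.

**Transcriptome models.** With the medoid panel X and gene g in tissue t,
the Tissue-Aware model is

&nbsp;&nbsp;min Σ<sub>t</sub> ‖y<sub>tg</sub> − X<sub>t</sub>β<sub>tg</sub> −
α<sub>tg</sub> − α<sub>0g</sub>‖²,

fitted as a global OLS stage plus a per-tissue OLS of its residuals; the
Tissue-Agnostic model is the global stage alone. In-sample, per-gene
R²(aware) ≥ R²(agnostic) holds exactly.

**Predictability.** Beta mixtures (k = 1..4, BIC) decompose each R²
distribution into poorly/well-explained tails; genes are categorized
(0.3/0.7 global thresholds, tail switches, 4-fold rule). The correlation
score is the fraction of genes whose cor(ŷ<sub>g</sub>, y<sub>g</sub>)
beats the 95th percentile of a randomly-mismatched-pair null.

**Transportability.** K-means pseudo-tissues (K by 5-fold CV) replace
non-transferable tissue labels; target samples are assigned by nearest
centroid. Feature ids are matched across miRNA naming dialects
(exact > strip "-3p"/"-5p" > ranked-member substitution), and per-feature
covariate shift is measured by Wasserstein-1 distance against a
mismatched-pair null.

A seeded synthetic-data generator (`generator_config()`,
`generate_regulators()`, `generate_transcriptome()`,
`generate_shifted_target()`) produces cohorts with this exact structure
and full ground truth, so every stage is tested for recovery, not just for
execution.

## Worked example

The numbered drivers under `analysis/` run the whole study on a synthetic
cohort (500 samples, 4 tissues, 100 regulators in 5 clusters, 500 genes)
and write their tables under `results/run/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_components.R
Rscript analysis/03_fit_predict.R
Rscript analysis/04_evaluate.R
Rscript analysis/05_transport.R
```

Output (abridged) from one run:

```
selected dimension d = 5; retained 100 / 100 features
BIC selected K = 5 clusters
adjusted Rand index vs ground truth: 1.000
mean R^2: Tissue-Agnostic 0.534, Tissue-Aware 0.722
per-gene dominance violations (aware < agnostic): 0
correlation score (Tissue-Aware, in-sample): 0.8000
10-fold SVM tissue classification accuracy: 88.5%
optimal number of pseudo-tissues: K = 4
median W1, matched miRNAs: 4.57 (null 0.92); matched TFs: 0.00
correlation score — clean clone: 0.800; miRNA-shifted: 0.568; TF-only on shifted: 0.748
```

Reading this: the component stage recovers the 5 planted clusters exactly
(ARI 1.0) and selects one medoid per cluster; adding tissue context lifts
mean R² from 0.53 to 0.72 with no gene getting worse; cross-validated
pseudo-tissue tuning lands at K = 4, matching the 4 simulated tissues;
and the transport experiment reproduces the qualitative covariate-shift
story — severe miRNA shift drags the correlation score from 0.80 to 0.57,
while a TF-only model, whose inputs are unshifted, holds 0.75.

A minimal in-R session:

```r
library(regulome56)
cfg <- generator_config(seed = 1)
rg  <- generate_regulators(cfg)
gn  <- generate_transcriptome(rg$matrix, rg$truth, cfg)
cm  <- discover_components(rg$matrix, seed = 1)
X   <- em_subset(rg$matrix, features = cm$medoids)
fit <- fit_tissue_aware(X, gn$matrix)
summary(r_squared(gn$matrix, predict(fit, X)))
```

`run_pipeline()` executes the same stages from a single config (list or
YAML) and writes a manifest with content hashes.

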