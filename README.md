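# bsblfs — block-sparse Bayesian fuzzy classification of RNA modification sites

`bsblfs` predicts RNA modification sites (m6A / m5C-style) from fixed-length
sequence windows. It is aimed at computational epigenomics groups who want a
reproducible, fully inspectable sequence-level classifier: every stage — the
encoder, the fuzzy system, the Bayesian learner, the evaluation protocol and
the synthetic data used to test them — is an exported, documented function.

## The model

A 41-nt window centred on the candidate adenosine is encoded by
**position-specific 5-mer propensities**: component *j* of the feature
vector is F⁺(m, j) − F⁻(m, j), the difference between the positive- and
negative-class training frequencies of the window's 5-mer *m* starting at
position *j* (37 features for 41 nt).

The features enter a first-order **Takagi–Sugeno–Kang fuzzy system** with
K = 25 rules. Rule antecedents are Gaussian memberships
exp(−(x_j − c_j^k)² / δ_j^k) whose centres and widths come from fuzzy
c-means on the training features; the model output is the
firing-strength-weighted sum of affine rule consequents, equivalently
x_g · p for the lifted (1+d)K-column design row x_g.

The consequent vector p is learned by **block-sparse Bayesian learning**:
a Gaussian prior p_k ~ N(0, γ_k B_k) per rule block, hyperparameters
(γ, B, β) estimated by type-II maximum likelihood (EM on the evidence
cost log|C| + yᵀC⁻¹y), with first-order autoregressive intra-block
correlation, automatic block pruning, and no hand-set penalty constant.
Ablation baselines are included: plain sparse Bayesian learning (every
coefficient its own block) and ridge least squares (the classical TSK
consequent estimate). The methods vignette
(`vignettes/bsblfs-methods.Rmd`) derives the updates and records every
numerical choice.

## Worked example

```r
library(bsblfs)

# a motif-enriched synthetic benchmark: GGACA at positions 19-23 of the
# positives, GC-rich positive flanks vs AU-rich negative flanks
ds <- do.call(genMotifDataset,
              c(list(nPos = 1000, nNeg = 1000, seed = 7, name = "demo"),
                motifPreset("strong")))
ds
#> SiteDataset'demo'
#>   2000 sequences of 41 nt (1000 positive / 1000 negative)

cfg <- runConfig(seed = 7)          # 41 nt, k = 5, K = 25 rules, BSBL
model <- trainSiteModel(ds, cfg)
model@fit
#> BsblModel [bsbl]: 950 coefficients in 25 blocks (23 active)
#>   iterations: 84, converged: TRUE

head(predictSites(model, ds)[, c("id", "score", "probability", "label")], 3)
#>      id     score probability label
#> 1 pos_1 1.2077180   0.9999104     1
#> 2 pos_2 1.0817764   0.9996462     1
#> 3 pos_3 0.9889655   0.9990137     1

cv <- crossValidate(ds, cfg, folds = 5)
round(cv$mean, 4)
#>     SN     SP    ACC    MCC    AUC
#> 0.9650 0.9190 0.9420 0.8863 0.9415
```

The score is the fuzzy-system output x_g · μ (positive ⇒ predicted
modified site), the probability is the probit transform of the
standardized Gaussian predictive mean, and the cross-validation row
reports sensitivity, specificity, accuracy, Matthews correlation and AUC
averaged over the five stratified folds — two blocks were pruned by the
evidence optimization, and the held-out metrics show the strong preset is
recovered nearly perfectly.

A command-line wrapper over the same functions ships in `exec/bsblfs`:

```sh
bsblfs simulate --preset strong --n-pos 1000 --n-neg 1000 --out-dir data
bsblfs train --pos data/positives.fa --neg data/negatives.fa --out model.json
bsblfs predict --model model.json --fasta data/positives.fa --out scores.tsv
bsblfs cv --pos data/positives.fa --neg data/negatives.fa --out report
```

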