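---
title: "Estimating tumor fractions in cfDNA methylation profiles with an interpretable autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tumor fractions in cfDNA methylation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Circulating tumor DNA (ctDNA) is a small, variable fraction of the cell-free
DNA (cfDNA) in plasma. Because tumor tissue carries methylation patterns that
differ from those of the healthy cell types shedding DNA into blood, a bulk
cfDNA methylation profile can be *deconvolved* into a healthy and a tumor
component, and the tumor mixing fraction tracked over a course of treatment.
`cfdecon` implements that pipeline for Illumina 450K-style beta-value
matrices: selecting tumor-specific CpG markers from tissue reference data,
fabricating training mixtures with known fractions, fitting an interpretable
autoencoder whose latent space *is* the fraction pair, and testing
longitudinal fraction changes per patient.

## Data model and transforms

All matrices are probe-major (rows = CpG probes, columns = samples), written
and read as tab-separated text (`read_matrix()` / `write_matrix()`, `NA` for
missing). Raw array intensities convert to beta-values as
\(\beta = M/(M+U+\text{offset})\) with the conventional offset of 100
(`beta_from_signals()`), and probes whose detection p-value is \(\ge 0.01\) in
any sample are discarded (`detection_filter()`; the comparison is inclusive).
Differential testing operates on M-values,
\(M = \log_2\{\beta/(1-\beta)\}\) after clipping beta to
\([10^{-6}, 1-10^{-6}]\) (`beta_to_m()`): M-values are approximately
homoscedastic across the methylation range, where beta-values compress
variance near 0 and 1.

## Tumor-specific marker selection

`fit_group_means()` fits a per-probe cell-means linear model over three
groups — tumor tissue, adjacent normal tissue, healthy plasma — so each
coefficient is a group mean and the residual variance is pooled within
groups. With tens to hundreds of samples per group and hundreds of thousands
of probes, per-probe variances are noisy; `estimate_prior()` therefore fits a
scaled inverse-chi-square prior to the variances by method of moments on the
log scale (matching the mean and spread of \(\log s^2_g\) to their
digamma/trigamma expressions, with a Newton inversion of the trigamma
function). When the observed spread does not exceed the pure sampling spread
\(\psi'(d/2)\), the prior degrees of freedom are infinite and the common
variance is the pooled mean. `moderated_contrast()` then forms, per probe,

\[ \tilde s^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d}, \qquad
   \tilde t_g = \frac{c^\top \hat\beta_g}{\sqrt{\tilde s^2_g\; c^\top (X^\top X)^{-1} c}}, \]

referred to a t distribution with \(d_0 + d\) degrees of freedom (normal when
\(d_0 = \infty\); the ordinary linear-model t when \(d_0 = 0\), a limit the
API deliberately exposes so the moderation machinery can be checked against
plain least squares). P-values are two-sided and adjusted by
Benjamini–Hochberg.

Two contrasts are tested: tumor vs normal tissue, and normal tissue vs
plasma. `select_tumor_specific()` keeps probes with tumor-contrast
`adj.P.Val < 0.01` and `|logFC| > 0.2` (M-scale) whose tissue contrast is
non-specific (`adj.P.Val >= 0.05` **or** `|logFC| < 0.01` — the disjunction is
deliberate; an `AND` would be a stricter reading of "non-specific" but this is
the rule the pipeline defines), ranks by decreasing tumor `|logFC|` with probe
ID as a stable tie-break, and caps at 500. Excluding tissue-specific probes
matters because plasma cfDNA aggregates many tissues: a probe that separates
prostate tissue from plasma regardless of malignancy would masquerade as
tumor signal.

## Simulated training mixtures

True tumor fractions in patient plasma are unknown, so the model trains on
fabricated mixtures (`generate_simulated_data()`). Per sample, a fraction
pair \((w_h, w_t)\) is drawn from a Dirichlet distribution with prior
\((0.8, 0.2)\) over (healthy, tumor) — mean tumor fraction 0.2, heavily
weighted toward the low fractions seen in real plasma — or uniformly with
`method = "uniform"`. Each population profile is the per-probe average of
`k = 5` reference columns drawn with replacement, which adds between-sample
heterogeneity while keeping every profile inside the reference convex hull;
`k = 1` reproduces single-donor blending. The simulated sample is the convex
blend \(w_h p_h + w_t p_t\). No extra measurement noise is added by default:
the reference columns themselves carry biological spread, and any additional
noise model would be a claim the pipeline has no data to calibrate. The
generator is bit-reproducible given `random_state`.

## The autoencoder

The encoder stacks five affine layers of widths \((N, 512, 256, 128, 64, 2)\)
with CELU activations and dropout (rate 0.5) on the hidden layers; \(N\) is
the number of selected CpG markers. The latent pair represents (healthy,
tumor) fractions: unconstrained during training, clamped by a ReLU at
inference. The decoder is five *bias-free* linear layers of mirrored widths;
because a product of linear maps is a single linear map, the decoder is
summarized by its effective \(N \times 2\) matrix, and
\(\mathrm{sigmoid}(W_\text{eff})\) is read directly as a two-column
methylation atlas in \((0,1)\) (`effective_atlas()`). Reconstruction goes
through that same object — \(\hat x = \text{latent} \cdot
\mathrm{sigmoid}(W_\text{eff})^\top\) — rather than through the raw layer
stack, so the reconstruction loss trains exactly the matrix reported as the
atlas; this is the design choice that makes the model interpretable rather
than merely accurate.

Training (`train_deconv()`) minimizes a four-term loss with Adam
(learning rate \(10^{-4}\), batch size 128, 256 epochs by default):

* **Comp** — mean absolute error between the raw latent and the known
  fraction labels;
* **Recon** — mean absolute error between input and reconstruction;
* **Methy-H / Methy-T** — per-probe Bernoulli negative log-likelihood of the
  healthy / tumor reference mean profile under the corresponding atlas
  column, which anchors each atlas column to its population.

All four weights default to 1; they are exposed in `model_config()` because
no canonical weighting exists for this loss family. Gradients are computed
analytically (the decoder gradient of layer \(l\) is
\(P_{<l}^\top\, G\, P_{>l}^\top\) for prefix/suffix products \(P\)), and the
entire run — initialization, dropout masks, batch shuffling — is driven by
one seed, so training is deterministic on a single machine. There is no
early stopping or validation split: the epoch count is fixed and the
per-epoch loss trace is returned for inspection. Non-finite losses abort
with the offending term named.

Numerical details: reference means at exactly 0 or 1 are clipped to
\([10^{-6}, 1-10^{-6}]\) before the likelihood (warned once); hidden widths
are capped at \(N\) when \(N\) is smaller than the narrowest layer so tiny
test models remain well-formed; layer parameters initialize uniformly in
\(\pm 1/\sqrt{\text{fan-in}}\).

## Monitoring treatment response

`predict_fractions()` aligns input probes to the training features by name,
encodes in inference mode and (by default) renormalizes the fraction pair to
sum to one; an all-zero latent is reported as fully healthy with a warning.
`pair_baseline_followup()` takes the smallest timepoint per patient as
baseline and the next as first follow-up, averaging technical replicates
within a (patient, timepoint) slot — dropping them instead would discard
information and bias nothing either way, so averaging is the declared
convention. `paired_t_test()` is the two-sided one-sample t-test of the
deltas, with the degenerate zero-variance case reported explicitly rather
than as NaN.

## Synthetic data: what it emulates, what it does not

The generators in `fixture_spec()` / `make_reference()` /
`make_tissue_groups()` / `make_cohort()` draw per-probe beta-values from Beta
distributions in a mean/concentration parameterization (Gaussian noise was
rejected: it leaves \([0,1]\)). Planted tumor-specific probes put the tumor
group at mean 0.8 and both healthy populations at 0.2 (or reversed);
tissue-specific probes form a 0.2 / 0.5 / 0.8 gradient across plasma, normal
tissue and tumor so that they pass the tumor contrast and must be caught by
the exclusion rule. Longitudinal cohorts give each patient a baseline tumor
fraction uniform on \([0.2, 0.6]\); treatment-sensitive patients drop to
\(U(0, 0.3)\) of baseline at follow-up while resistant patients random-walk
with SD 0.05 — stylized dynamics of a therapy that eliminates non-resistant
tumor cells.

These fixtures reproduce the *statistical geometry* of the real task
(bounded bimodal betas, group structure, convex mixtures, longitudinal
pairing) but not its harder features: no array batch effects or probe-type
chemistry, no cross-platform normalization, no correlation among neighboring
CpGs, and planted effects larger than many real DMPs. Passing tests
therefore demonstrate that the machinery is correct and that the model
recovers fractions under its own generative assumptions — not that it meets
any particular accuracy on clinical data.

## Study scales used by the test suite

The test suite exercises the pipeline at desk scale, chosen so a full run
takes a few minutes on one CPU: marker selection on 2,000 probes
(550 planted tumor-specific + 100 tissue-specific; 50/50/60 samples), model
training on 1,000 mixtures over 200 probes for the default 256 epochs with
200 held-out mixtures, and monitoring cohorts of 12 patients per arm. At
those scales the held-out tumor-fraction RMSE lands well under the 0.08
guardrail the suite asserts, mean predictions increase strictly across true
fractions 0–0.5, and the learned atlas correlates with the true population
profiles above 0.9.

## Known limitations

* Two populations only; multi-tissue deconvolution is out of scope.
* Markers are selected on tissue data; markers that behave differently in
  cfDNA will degrade real-world accuracy (a limitation of the design, not of
  the implementation).
* The moderated-t machinery implements the plain variant only — no
  mean-variance trend, no robust winsorization.
* The paired test covers baseline vs first follow-up; longer trajectories
  need a longitudinal model.
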