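---
title: "ribostall: model, interpretability stack, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribostall: model, interpretability stack, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ribosome profiling (Ribo-seq) measures, for every codon of a coding
sequence, how densely ribosomes dwell there. Under amino-acid
deprivation, codons decoding the deprived amino acid starve for charged
tRNA and the ribosome stalls with that codon in its A-site, reshaping
the footprint profile. `ribostall` models this conditionally: given a
CDS and one of six condition identifiers (`CTRL` plus LEU, ILE, VAL
single deprivations and the LEU+ILE and LEU+ILE+VAL combinations), it
predicts the control footprint profile and the deprivation-induced
*difference* profile, and then interrogates the fitted model to recover
which codons and codon motifs drive stalling.

## The model

A gene is a codon sequence $s = (c_1, \dots, c_n)$; each position's
input vector is the sum of a learnable codon embedding and a learnable
condition embedding (additive injection keeps the output length equal to
$n$; a dedicated condition token would change the sequence length and is
not used here). The backbone is a stack of
relative multi-head attention blocks in the Transformer-XL
parameterization:

$$e_{ij} = (x_i W^Q + u)(x_j W_E^K)^\top + (x_i W^Q + v)(r_{i-j} W_R^K)^\top,
\qquad \alpha_{ij} = \mathrm{softmax}_j(e_{ij}/\sqrt{d_h}),
\qquad h_i = \sum_j \alpha_{ij}\, x_j W^V,$$

with fixed sinusoidal relative encodings $r_{i-j}$ covering every offset
up to the sequence length, no causal mask (profiles are predicted from
the whole CDS), and standard residual + layer-normalization sublayers
with a ReLU feed-forward block. The $1/\sqrt{d_h}$ logit scaling is the
standard stabilization and is applied identically in the test oracle. A
bidirectional tanh-recurrent backbone with the same input/output
contract is available as a drop-in alternative (`backbone = "birnn"`).

Two position-wise linear heads read out $\hat y_{\mathrm{CTRL}}$ and
$\hat y_{\Delta D}$; the deprivation-condition prediction is their exact
sum, $\hat y_{\mathrm{DC}} = \hat y_{\mathrm{CTRL}} + \hat y_{\Delta D}$.
Targets are $(y_{\mathrm{CTRL}}, y_{\Delta D})$ with
$y_{\Delta D} = y_{\mathrm{DC}} - y_{\mathrm{CTRL}}$; for control
samples $y_{\mathrm{DC}} = y_{\mathrm{CTRL}}$.

Training minimizes

$$L = \sum_{k \in \{\mathrm{CTRL}, \Delta D, \mathrm{DC}\}}
\bigl(1 - r(y_k, \hat y_k)\bigr) + \mathrm{MAE}(y_{\mathrm{DC}}, \hat y_{\mathrm{DC}}),$$

a Pearson-correlation loss on all three targets plus the mean absolute
error on the DC profile. Every term is computed on the
pairwise-annotated mask (missing targets are excluded; predictions are
still produced there, which is what makes imputation possible). A
correlation term with zero variance — e.g. the constant zero difference
target of a control sample — is undefined and contributes 0, so perfect
prediction always attains $L = 0$ and a training step never aborts.
Evaluation uses the Pearson correlation (PCC) of the DC profile as the
primary score, plus Spearman (midranks for ties), MSE, and MAAPE,
$\mathrm{MAAPE} = \tfrac{100}{N}\sum \arctan(|y - \hat y| / \max(|y|, 10^{-6}))$,
whose arctan bounds the percentage error when counts are near zero.

### Engines

The transformer forward/backward passes and the batched window scorer
exist twice: a compiled RcppArmadillo engine (the default) and a pure-R
reference implementation of the identical arithmetic
(`modelConfig(engine = "R")`). The test suite asserts agreement to
machine precision between the two and checks the one-layer output
against a third, dense per-equation oracle, and the analytic gradients
against finite differences. Training is plain Adam (batch accumulation
over individually processed sequences, so no padding ever enters
attention, loss, or metrics) with cosine learning-rate decay and early
stopping on the macro-averaged validation DC-PCC.

## Pre-processing

Replicates are first scaled to equal library-depth contribution (each
divided by its own mean over annotated positions) and then averaged
position-wise over the replicates annotated there, so the merged
annotation is the union. Whether the original pipeline normalized before
or after merging is ambiguous; scale-then-average is this package's
reading and makes the merge invariant to per-replicate depth. Profiles
are then normalized against the gene's average count and
$\log(x + 1)$-transformed. Zero counts are real observations, distinct
from missing (`NA`) values — coverage is the non-zero fraction of
*annotated* positions.

Three filters remove: genes with a run of more than 20 consecutive
observed zeros (missing values break a run — the filter is about
observed zeros), genes longer than 2000 codons, and genes with coverage
not strictly greater than 30%. The train/validation/test split sorts
genes by coverage (maximum over the gene's samples, ties broken by gene
id) and walks the list assigning genes cyclically train → val → test,
skipping val (test) once it holds 5% (20%) of the pre-split sample
count; all samples of a gene share one split. The quota-skipping walk is
this package's deterministic reading of the published alternation
scheme.

The interpretability gene set is selected by a per-sample likelihood
ratio test on the normalized difference profile: a Gaussian working
likelihood with shared maximum-likelihood variance, one common mean
under the null versus separate means for deprived-codon A-site positions
and the rest, statistic $n \log(s_0/s_1)$ referred to $\chi^2_1$. The
Gaussian working model and single degree of freedom are design choices;
the published description fixes only the chi-square reference.

## Pseudo-labeling

A teacher ensemble of five identically configured models (different
seeds) is trained on the raw training split; its position-wise mean DC
prediction imputes exactly the missing DC values of training samples
(annotated values are never altered; validation and test stay
untouched). The difference target is rederived, staying missing wherever
the control value is itself missing. A student is then retrained from a
fresh seed on the completed data. Imputation operates on the
normalized-log scale, as all modeling does.

## Interpretability

**Attributions.** Integrated gradients of one head's scalar output at a
chosen A-site, with respect to the combined input embeddings, from the
all-zero embedding baseline. The straight-line path integral is
discretized by a midpoint rule under the substitution $\alpha = t^{10}$
(weights normalized to unit mass). Each layer-normalization stage in the
backbone pushes the region where the output actually changes a few
decades closer to $\alpha = 0$ (for two layers the path integrand's
mass sits around $\alpha \sim 10^{-8}$), so uniform sampling leaves a
near-100% completeness gap; the strongly stretched rule is complete to
under 1% at 64 steps across one- and two-layer models and exact for a
linear model. The
$[n \times D]$ result is summed over the embedding axis to one value per
codon.

**Peaks and windows.** A peak (stalling site) is an annotated position
strictly above the profile mean plus one standard deviation; a trough
("fast" site) strictly below mean minus one sd. The standard deviation
uses denominator $n$ (population form), which the worked example in the
interface contract pins down. Control samples are assessed on the
footprint profile, deprived samples on the difference profile. The
significance window (SW) spans 10 codons up- and downstream of the
A-site — 21 codons untruncated. Attributions within a SW are
max-normalized by the window's largest absolute value, signs preserved;
top-k salient positions rank by signed value (largest
stalling-promoting first) and are reported relative to the A-site
(P-site = −1). Codon-wise summaries average the normalized attribution
over every occurrence of a codon inside analyzed SWs; control samples
use the control head, deprived samples the difference head.

**Counterfactual motifs.** For windows whose A-site is a trough, a beam
search looks for up to three codon substitutions that maximally raise
the predicted A-site count (control head for control windows, difference
head otherwise). The substitution alphabet is the 61 sense codons (stop
codons would break the CDS); the resident codon is excluded; the A-site
itself is mutable. Level 1 keeps the `width` best single substitutions;
each is frozen and extended by the remaining positions at level 2, and
again at level 3 — all levels are reported,
$w + w^2 + w^3 = 155$ motifs at width 5. Scores are cumulative against
the original window's baseline: signed-arctan percentage change
$s = \mathrm{sign}(\Delta) \cdot 100 \arctan(|\Delta| / \max(|\hat y_{\mathrm{orig}}|, 10^{-6}))$
(the exact published score formula is not written out; this signed
MAAPE-style form is the package's definition, and only its sign is
antisymmetric under swapping the pair). Ties resolve by higher score,
then smaller relative position, then codon order, making the search
fully deterministic. Motifs are written canonically with one `[SKIP]`
per gap codon, anchored at the smallest relative position.

**Enrichment.** The 50 most frequent canonical motifs (duplicates across
windows count as repeated discoveries) are tested for enrichment inside
the merged peak significance windows versus everywhere else: a gapped
motif matches at any alignment start (`[SKIP]` = any codon); an
occurrence is "inside" when its start lies in a merged window;
candidate alignment starts inside/outside form the margins of a 2×2
table tested with a two-sided Fisher exact test,
Benjamini–Hochberg-corrected per condition across the tested motifs.

## The synthetic generator

The generator plants recoverable ground truth: per-codon base log-dwell
times drawn once per configuration from $N(0, 0.5)$ (a 2–3-fold dwell
range, typical of codon-resolved elongation data), a small context
kernel (P-site proline codons CCA/CCG at +0.3, downstream GAA at +0.2),
condition effects on A-site log-dwell — VAL +1.0 (4 codons), ILE +0.8
(3 codons) plus a +0.4 long-range effect from ILE codons four positions
upstream, LEU +0.3 (6 codons), combined conditions taking unions —
multiplicative lognormal noise (log-sd 0.3), per-sample depth factors
(log-sd 0.3), missing runs (rate 10%, geometric mean length 3), and a
control-only GC-dependent end-bias artifact at footprint-edge offsets −5
and +3. Counts are continuous positive reals: the modeling pipeline
operates after normalization, so integer read sampling would add nothing
that these tests exercise. Defaults are 200 genes of 150–400 codons, and
one seeded RNG stream (genes in order; per gene the control draw, then
the five deprivation draws) makes every artifact reproducible.

What the generator does *not* emulate: ribosome traffic/collisions
(TASEP-style flux), initiation-limited regimes, fragment-length and
P-site-offset ambiguity, batch effects between data sources, and
integer sampling noise at low depth. Tests passing on this substrate
demonstrate that the machinery recovers planted signal under realistic
noise and missingness — not that the model resolves the harder
confounds of real libraries.

## Problem sizes and numerical choices

The test suite and the acceptance script run, by design, at desk scale:
the recovery analysis trains the default small configuration (D = 64, 2
layers, 4 heads, feed-forward width 128) for 5 epochs on the default
200-gene fixture; attributions use 60 peak windows at 32 integrated-
gradient steps (64 steps where completeness itself is the claim); the
counterfactual search runs width 5, depth 3 over 50 fast VAL windows;
the pseudo-labeling study uses an 80-gene, 30%-missingness fixture with
a 5-member ensemble at D = 32. Larger runs only change these counts.

Other fixed numerical choices: layer-normalization epsilon $10^{-5}$;
MAAPE/score denominator guard $10^{-6}$; coordinates are 0-based codon
positions with inclusive window bounds; the condition vocabulary is
closed (six values); checkpoint loading refuses files missing any
configuration field or carrying a different codon/condition vocabulary;
degenerate inputs (all-missing profiles, empty sequences, zero-variance
correlations) raise errors or return `NA` sentinels rather than numbers.

## Known limitations

The relative-encoding clipping distance equals the longest sequence, so
memory in attention grows quadratically with gene length — genes beyond
the 2000-codon filter are not meant to be pushed through training. The
LRT's Gaussian working likelihood is a pragmatic screen, not a count
model; at very low coverage its calibration degrades together with
everybody else's. Enrichment power depends on peak sparsity: when
planted effects cover a large codon fraction, merged peak windows absorb
most of the CDS and only pooling across many genes restores contrast.
The same density also dilutes every non-planted codon inside the peak
windows, so with large pooled totals the two-sided Fisher test can flag
control motifs as significantly *depleted*; the odds ratio separates
that composition artifact (OR < 1) from genuine stalling enrichment
(OR > 1).
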