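---
title: "Modeling enzyme-processivity coverage bias in RNA-seq libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling enzyme-processivity coverage bias in RNA-seq libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covbias)
```

## The generative model

RNA-seq library preparation converts each mRNA of length $l$ into
double-stranded cDNA in two enzymatic steps: first-strand synthesis
(reverse transcription), running 3'→5' from a priming site $s_1$ to a stop
point $e_1$, and second-strand synthesis, running 5'→3' from $s_2$ to
$e_2$. Both enzymes are processive but stop stochastically. With
exponentially distributed synthesis lengths — the standard assumption for
polymerase processivity — the conditional stop-point densities are
semi-continuous:

$$p(e_1 \mid s_1) = \varphi(s_1 - e_1,\, \theta_1)
  + \delta(e_1)\,[1 - \Phi(s_1, \theta_1)], \qquad
  \varphi(x, \theta) = \theta e^{-\theta x},$$

i.e. an exponential body plus a Dirac mass for syntheses that run into the
end of the template. The rates $\theta_1, \theta_2$ (per base) are the
*inverse processivities*: $1/\theta$ is the mean synthesis length in
bases. Positions are treated as continuous reals on $[0, l]$ with $x = 0$
at the 5' end; the closed forms below are the continuous approximation of
the per-base sums, which is accurate at the hundreds-to-thousands-of-bases
scale of real transcripts.

Only the double-stranded region $[s_2, e_2]$ of a molecule is sequenceable
after fragmentation. Fragmentation is uniform except near cDNA ends:
within distance $h$ of an end the read-start weight is $1/d$, while
interior positions carry weight $1/d + 1$ — interior coverage is higher by
the factor $d + 1$. Five priming/selection scenarios map onto common
protocol families:

| Model | First strand | Second strand | Selection | Protocol family |
|-------|--------------|---------------|-----------|-----------------|
| A | 3' end, full length | at 5' end, full length | both strands complete | idealized SMART/template switching |
| B | 3' end | at first-strand stop | complete second strands | poly-A tagging + full-length PCR |
| C | 3' end, full length | at 5' end | complete first strands | full-length selection, unselected second strand |
| D | 3' end | at first-strand stop | none | imperfect SMART / poly-A tagging |
| E | random priming | random priming | none | classical random-primed RT |
| B&D | $\alpha f_B + (1-\alpha) f_D$ | | | SMART-seq with partial PCR selection |

For each model the read-start intensity decomposes as
$f(x) = g_0(x)/d + \mathbf{1}[h < x < l-h]\, g_h(x)$, where
$g_0(x) = P(s_2 < x < e_2)$ and $g_h(x) = P(s_2 + h < x < e_2 - h)$ are
available in closed form (combinations of exponentials). `coverage_density()`
evaluates them, `coverage_area()` gives the exact integral
$\int_0^l f$ — the model's *correction factor*: the expected read yield of
a transcript of length $l$, up to a protocol constant.

Model E absorbs multiple random priming events into modified rates
$\theta_1' = \theta_1 + \alpha_1$, $\theta_2' = \theta_2 + \alpha_2$
(priming probabilities per base). Only the sums are identifiable, so
`model_params()` defaults $\alpha_1 = \alpha_2 = 0$ and the fitted rates
are reported as the modified processivities; when $\alpha_1\alpha_2 = 0$
the (purely multiplicative, always-cancelling) $\alpha_1\alpha_2$
prefactor of the unnormalized density is replaced by 1 so the intensity
remains usable. Local, sequence-specific bias (GC, priming hexamers) and
RNA degradation are outside the model's scope, as are Erlang-distributed
concatenated synthesis runs.

These shapes reproduce the qualitative behavior of real libraries: under
model D at the package's reference parameters
($\theta_1 = 2\times10^{-4}$, $\theta_2 = 5\times10^{-4}$, $d = 4$,
$h = 150$), short transcripts are 5'-biased, intermediate lengths
(~4 kb) are bimodal with depleted centers, and long transcripts are
3'-biased with the 5' interior edge lower than the 3' one:

```{r shapes, fig.width = 6, fig.height = 4}
p <- model_params(theta1 = 2e-4, theta2 = 5e-4, d = 4, h = 150)
op <- par(mfrow = c(1, 3), mar = c(4, 3, 2, 1))
for (l in c(1000, 4000, 12000)) {
  x <- seq(1, l - 1, length.out = 500)
  plot(x / l, coverage_density("D", p, x, l), type = "l",
       xlab = "relative position (5'→3')", ylab = "", main = paste(l, "b"))
}
par(op)
```

## Parameters

| Parameter | Meaning | Units | Default / prior |
|-----------|---------|-------|-----------------|
| $\theta_1$ | inverse first-strand processivity | 1/base | log-uniform $[10^{-6}, 10^{-2}]$ |
| $\theta_2$ | inverse second-strand processivity | 1/base | log-uniform $[10^{-6}, 10^{-2}]$ |
| $d$ | edge fragmentation divisor | — | uniform $(0, 100]$ |
| $h$ | end-effect distance | bases | uniform $[0, 1000]$ |
| $\alpha$ | weight of model B in B&D | — | uniform $[0, 1]$ |
| $\alpha_1, \alpha_2$ | per-base priming rates (model E) | 1/base | absorbed into $\theta'$ |

The priors are the package's choice (they are not dictated by the model):
log-uniform priors make the processivity scale-free over the
plausible 100 b – 1 Mb range, and the $d$, $h$ ranges comfortably bracket
every fit we have seen while keeping the posterior proper. The lower bound
$10^{-4}$ on $d$ is a numerical floor for log-space proposals.

## Inference

`mcmc_fit()` samples the *identifiable* parameter set of each model with a
robust adaptive random-walk Metropolis sampler. Because the per-read
likelihood is normalized per transcript (each read's position is
conditioned on its transcript), parameters that only scale a transcript's
total intensity cancel: model A retains only $\{d, h\}$ (the factor
$e^{-l(\theta_1+\theta_2)}$ cancels), model C drops $\theta_1$, model E
keeps the modified rates with $\alpha_1\alpha_2$ absorbed, and B, D and
B&D keep their full sets. Whether to normalize per transcript or jointly
across transcripts is a genuine design choice; per-transcript conditioning
is used throughout because it makes the likelihood independent of the
(protocol-dependent, strongly length-biased) read allocation between
transcripts — exactly the quantity the correction factors are later used
to model.

Numerical choices worth recording:

* **Subsampling.** Before fitting, reads are capped at 100 per transcript
  and transcripts are split into 10 equal-count length strata whose pooled
  read totals are equalized to the smallest stratum's, so no length range
  dominates the likelihood. Both knobs are `fit_config()` options.
* **Proposals.** $\theta$ and $d$ are proposed in log space ($d$ keeps its
  uniform prior via the Jacobian term); $h$ and $\alpha$ in natural space
  with out-of-bounds proposals rejected. During burn-in the proposal
  Cholesky factor is adapted by rank-one updates toward a 23% acceptance
  rate and frozen afterwards, so the post-burn-in chain is a valid
  fixed-kernel Metropolis sampler.
* **Initialization.** The chain starts from the best of 64 prior draws
  refined by a short Nelder-Mead climb from the three best draws. The
  posterior can contain a minor mode in which $h \to 0$ and a large $d$
  absorb the end effect; the multi-start climb reliably avoids it.
  Initialization failure (no finite-likelihood draw after 164 tries)
  aborts with a diagnostic.
* **Summaries.** Posterior medians and raw median absolute deviations are
  computed from post-burn-in samples only. A split-chain potential scale
  reduction factor is reported per parameter and values above 1.1 produce
  a warning, never a failure.
* **Maximum likelihood.** The reported maximum log-likelihood is the chain
  maximum refined by a Nelder-Mead climb (`polish = TRUE`), which makes
  likelihood-ratio comparisons between models reproducible rather than an
  artifact of which chain wandered closer to its optimum.
* **Degenerate parameters.** Parameter vectors with zero or non-finite
  area, or zero density at an observed read, score $-\infty$ and are
  rejected as proposals rather than raising errors. Read positions exactly
  at $x = l$ are clamped to $l(1 - 10^{-9})$ on ingestion (half-open
  convention); positions exactly at $x = 0$ are nudged inward by the same
  relative amount inside the likelihood only, because model E's density
  legitimately vanishes at the boundary.

`compare_models()` ranks fits by maximum log-likelihood and reports all
pairwise log-ratios. Ties are broken toward the model with fewer free
parameters, where "tie" is calibrated by a likelihood-ratio test: a model
with extra parameters wins only if twice its advantage exceeds the
$\chi^2_{0.95}$ quantile at the extra degrees of freedom. This is needed
because the models are partially nested (D contains A and C as $\theta \to
0$ limits; B&D contains B and D), so on data from the simpler model the
richer one always gains a small, spurious likelihood advantage of order
$\tfrac12\chi^2$ per extra parameter; raw-likelihood ordering would
therefore systematically prefer the wrong, over-parameterized model on its
own simulations.

## The simulator

`simulate_dataset()` draws synthesis events exactly as the models describe
them: full-length selection in models A–C is implemented by rejection —
mirroring the physical enrichment by PCR or template switching rather than
renormalized direct sampling — and model E implements its constant
per-base second-strand priming rate by weighting events by their
first-strand span. Read positions are then drawn position-wise with the
fragmentation weights, which makes the marginal of simulated read starts
*exactly* proportional to the closed-form density; the simulator and the
analytics are mutually validating oracles, and the test suite holds them
to agreement within three binomial standard errors per histogram bin.
Rejection loops are bounded ($10^6$ rejections per requested event) so
pathological parameter combinations fail with a diagnostic instead of
hanging.

Default study conditions: transcript lengths log-uniform on
0.5–20 kb (emulating the skew of single-isoform RefSeq mRNA lengths; an
empirical length list can be supplied), configurable reads per transcript,
and one root seed from which per-transcript child streams are derived
(`seed * 69069 + 104729 * i mod 2147483629`), so output is reproducible
and independent of transcript processing order. Reads can alternatively be
allocated multinomially with probability proportional to
`abundance × coverage_area(l)` — the physical yield — which is how the
equal-true-abundance experiments below are generated. The simulator does
not emulate sequencing error, PCR duplicates, UMIs, fragment-length
distributions, or any local sequence-specific bias, so passing tests
validate the enzymatic/global model, not those orthogonal features of real
data.

## Quantification and diagnostics

`corrected_abundance()` divides raw read counts by `coverage_area()`.
Because for model D the area is monotone *increasing* in $l$ (saturating
beyond a few kb), raw counts from an equal-abundance population correlate
positively with length, while FPKM-style `count / l` strongly
underestimates long transcripts; the corrected estimate removes both
distortions. In the model A / model E zero-rate limits the area becomes
proportional to $l$ and the correction reduces to FPKM exactly.

`bin_coverage()` produces the 20-bin, length-ordered coverage matrices
used for heatmaps; `uniformity_entropy_ratio()` compares two samples by
the median Shannon entropy (natural log, $0 \log 0 = 0$) of per-gene
20-bin profiles after equalizing detected-gene counts by random
subsampling ("detected" means at least one read);
`length_representation_ratio()` compares read fractions per 2-kb
transcript-length category; `spikein_fpkm()` implements the standard
spike-in formula $10^9 \cdot \text{reads} / (\text{probe length} \cdot
\text{total spike-in reads})$.

## Validation experiments and their sizes

The acceptance script (`scripts/acceptance.R`) and the test suite rerun
the package's validation battery at these sizes, chosen to give tight
checks at desk scale:

* oracle equivalence: $2\times10^5$ reads per model at $l = 6000$, 60
  bins;
* area exactness: 6 models × 5 parameter sets × 4 lengths, both
  $h$-branches, against `integrate()` at relative tolerance $10^{-6}$;
* parameter recovery: model D, 3000 transcripts × 30 reads (the fitting
  cap is 100), 20,000 iterations — medians land within 15% ($\theta$) and
  30% ($d$, $h$) of truth;
* model selection: 2 replicates per generating model, 300 transcripts ×
  50 reads on 0.5–6 kb (full-length selection makes model A's rejection
  acceptance decay like $e^{-l(\theta_1+\theta_2)}$, so the selection
  experiment keeps transcripts in the range such libraries are dominated
  by), 2500-iteration chains for all six candidate models — the
  generating model (or the B&D mixture, for data from B or D) ranks first
  in at least 90% of replicates; occasional single losses between nested
  near-ties are expected of maximum-likelihood ranking;
* mixture recovery: true $\alpha \in \{0.1, 0.5, 0.9\}$, 800 transcripts
  × 50 reads, 6000-iteration chains — fitted $\alpha$ is strictly
  increasing;
* bias correction: 1000 equal-abundance transcripts, $2\times10^5$ reads
  allocated by yield.

## Known limitations

* The continuous-position approximation breaks down for transcripts of a
  few dozen bases; none of the defaults generate them.
* $\theta_1$ and $\theta_2$ of model B are only weakly separable when
  $e^{-l(\theta_1+\theta_2)}$ is tiny for most transcripts (the constant
  term of $f_B$ vanishes); the posterior honestly reflects this as a wide
  ridge.
* Model comparison assumes all fits saw the identical subsampled read
  set; `compare_models()` enforces this with a checksum.
* The entropy uniformity metric depends on read depth (entropy of a
  finite sample is biased downward), which is why equal gene counts — and
  comparable read counts — between the two samples matter.
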