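# covbias

Enzyme-processivity models of RNA-seq coverage bias: closed-form coverage
densities for five library-preparation scenarios and their mixture, a
generative simulator, Bayesian MCMC parameter inference, likelihood-ratio
model comparison, and area-based correction factors for length-unbiased
transcript quantification.

## The problem

Virtually all RNA-seq and single-cell RNA-seq protocols build cDNA in two
enzymatic steps — reverse transcription (first strand) and second-strand
synthesis. Both polymerases stop stochastically, so which part of a
transcript becomes sequenceable cDNA depends on where synthesis starts
(the priming strategy) and how far it runs (the processivity). The result
is a *global*, transcript-length-dependent coverage bias: 3' bias that
worsens with length in poly-A-primed and SMART libraries, 5' bias under
random priming, bimodal coverage at intermediate lengths — and a strongly
non-linear relationship between a transcript's length and its expected
read count, which FPKM-style linear scaling gets wrong.

`covbias` models library preparation with exponential synthesis lengths:
the rates `theta1`, `theta2` (per base) are the inverse processivities,
`1/theta` the mean synthesis length. A fragmentation end effect (reduced
read-start weight `1/d` within distance `h` of a cDNA end; interior
positions weigh `1/d + 1`) completes the model. Five scenarios A–E cover
idealized full-length selection, poly-A tagging, partial selection,
unselected synthesis and random priming; the B&D mixture (weight `alpha`)
captures SMART libraries with partial PCR selection. For every model the
read-start density `f(x)` and its integral over the transcript — the
**correction factor**, proportional to the expected read yield at length
`l` — are available in closed form, so raw counts divided by the area give
length-unbiased abundance estimates, and MCMC fits of read start positions
recover the enzymes' processivities from sequencing data alone.

## Worked example

Simulate a SMART-like library (model D: poly-A primed first strand,
second strand primed at the first-strand stop, no selection), fit the
model, and correct abundances:

```r
library(covbias)

truth <- model_params(theta1 = 2e-4, theta2 = 5e-4, d = 4, h = 150)
rs <- simulate_dataset(sim_config(
  "D", truth, n_transcripts = 1000, length_range = c(500, 20000),
  reads_per_transcript = 50, seed = 1))

fit <- mcmc_fit(rs, fit_config("D", n_iterations = 8000, burn_in = 2500,
                               seed = 2))
fit
#> posterior_summary: model D, 50000 reads, 8000 iterations (burn-in 2500)
#>           theta1    theta2       d         h
#> median 1.959e-04 4.685e-04 3.81300 150.00000
#> mad    1.485e-06 8.058e-06 0.06096   0.03131
#> rhat   1.011e+00 1.019e+00 1.13700   1.00000
#> max log-likelihood: -397321.8  acceptance rate: 0.157
```

The posterior medians recover the generating parameters: mean first-strand
synthesis length `1/theta1` ≈ 5.1 kb, second strand ≈ 2.1 kb, interior
coverage `d + 1` ≈ 4.8-fold above the `h` ≈ 150-base cDNA ends. Correcting
read counts by the fitted coverage areas removes the length bias:

```r
params_hat <- do.call(model_params, as.list(fit$median))
ab <- corrected_abundance(rs, "D", params_hat)
head(ab, 3)
#>        transcript_id length raw_read_count corrected_abundance          z
#> T00001        T00001   1331             50          0.05929741  0.1595621
#> T00002        T00002   1973             50          0.04481623 -0.2532602
#> T00003        T00003   4137             50          0.03319532 -0.5845431
```

Dividing by the area (not by length) is what removes the bias: for this
equal-count library, `count/l` would underestimate every long transcript.
Other entry points: `coverage_density()` / `coverage_area()` (closed
forms), `sample_read()` / `sample_synthesis()` (generative process),
`compare_models()` (likelihood-ratio ranking of fitted models),
`bin_coverage()` (20-bin heatmap matrices), `uniformity_entropy_ratio()`
(entropy-based uniformity comparison), `read_alignments()` (SAM/BAM/TSV
ingestion), and the CLI at `inst/scripts/covbias-cli.R` with subcommands
`simulate`, `fit`, `compare`, `correct`, `heatmap`, `uniformity`.

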