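---
title: "Models and methods in ltspRecovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ltspRecovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltspRecovery)
```

## Scope

`ltspRecovery` analyses serial-dilution recovery experiments on bacteria
that adapted to long-term stationary phase (LTSP). During months of
starvation, *E. coli* populations repeatedly acquire convergent
adaptations in the RNA polymerase core enzyme (RNAPC), most of them at
three residues — RpoB 1272, RpoC 334, RpoC 428 — that are adaptive under
starvation but antagonistically pleiotropic: they cut the exponential
growth rate in fresh rich medium by roughly 20%. When such populations
or single clones are transferred daily 1:100 into fresh medium, the
costly alleles can be purged by frequency fluctuations among standing
genotypes, by reversion, or masked by compensatory second-site RNAPC
mutations. The package implements the four quantitative layers of that
analysis — growth-rate extraction, mutation catalogues, allele/outcome
classification, and fractional-site dN/dS — plus a serial-dilution
simulator that generates synthetic data with the statistical structure
the analysis assumes.

## Growth-rate estimation

The estimator is the sliding-window maximum: for every run of `window`
(default 5) consecutive OD600 readings above `odFloor`, fit ordinary
least squares of ln(OD) on time; among windows whose coefficient of
determination exceeds `r2Min` (strictly, default 0.99) return the
steepest. Relative growth is `100 * rate(sample) / rate(wild type)`, and
a recovery trajectory is summarised by its maximum and the first
dilution cycle at or above a 90% threshold.

Parameter choices that the estimator's definition leaves open:

* **Logarithm base** — natural log. Rates are exponential rate constants
  per minute; relative rates are ratios, so the base cancels.
* **`odFloor` (default 0.01 OD)** — readings at or below the floor are
  blank/noise-dominated and are excluded before the log transform. The
  floor should sit well above the instrument noise level.
* **Ties** — equal maximal slopes resolve to the earliest window, for
  determinism.
* **Degenerate windows** — zero variance in ln(OD) leaves R² undefined;
  such windows never qualify, so a flat curve yields an *unqualified*
  estimate (`NA` rate), not a zero rate. Fewer than `window` usable
  points is an explicit error.
* **No blank subtraction** — inputs are assumed background-corrected.

### Noise and the accuracy of window-maximum rates

The window maximum is an extreme-value statistic, and its accuracy is
governed by the measurement noise *relative to the OD* inside the
qualifying windows. With constant absolute noise of sd 0.002 OD, a
5-point window at OD 0.02–0.05 carries 3–5% standard error on its slope,
and Monte Carlo over hundreds of simulated plates shows relative-rate
errors of 5–20 percentage points — regardless of the OD floor chosen,
because the maximum-slope rule always selects the lowest usable (hence
noisiest) part of the curve, and because logistic damping then biases
genotypes of different rates differently. Under proportional
measurement error of 0.2% (sd 0.002 on the log scale) the same estimator
recovers configured relative rates to within about 1 percentage point.
The simulator therefore defaults to the proportional noise model
(`emitOdCurves(noiseModel = "proportional")`), which keeps the
signal-to-noise profile uniform across the fitted range; the additive
model remains available, and analyses of additive-noise data should
treat single-well relative rates as accurate only to several percentage
points or average replicate wells.

## Mutation catalogues and "new" mutations

A clone's genotype is its set of called mutations, keyed by
`(position, alternate allele)`; coordinates are 1-based on the reference
(NC_000913 conventions). Two notions of "new mutation" are provided:

* against the **founding ancestor** — the keyed set difference
  (an ancestral mutation missing from the descendant is *not* new; its
  absence is what the outcome classifier reads as reversion);
* against a **population history** — the union of all mutations ever
  seen in sequenced clones of that population; appropriate when the
  experiment was founded by a whole-population sample, whose standing
  variation would otherwise masquerade as new mutation.

Mutation classes are `nonsynonymous`, `synonymous`, `nonsense`,
`frameshift`, `noncoding`, `intergenic`, `large_deletion`,
`new_junction`; unknown annotation strings fall back to `noncoding` with
a warning. A large deletion spanning many genes is one event. Mutator
status is curated metadata; `hasMutatorMutation()` can rebuild it from a
configurable mismatch-repair gene list (default *mutS*, *mutL*, *mutH*,
*uvrD*).

## RNAPC classification and recovery outcomes

A clone is assigned the category of the configured anRNAPC site it
carries a coding mutation at (site categories take precedence), else
`other_RNAPC` if any mutation falls in *rpoA*/*rpoB*/*rpoC*, else
`none`. A clone hitting two configured sites — never observed in
practice — reports the lexicographically first site, with a message.

For experiments founded by a single clone, the outcome of a sequenced
descendant is classified from end-state genotypes only:

* `not_applicable` — the founder carried no anRNAPC mutation;
* `reversion` — the founder's anRNAPC allele (same position *and*
  alternate allele) is absent;
* `compensation` — the allele is retained and at least one new
  RNAPC-gene mutation is present;
* `retained` — otherwise.

Identity is nucleotide-level: a second substitution in the same codon
that restores the ancestral amino acid but not the ancestral nucleotide
is classified as compensation, not reversion. End-point sequencing
cannot order events, so a compensatory mutation that preceded a later
reversion is reported by the observed end state.

## Fractional site counting and dN/dS

Each coding position contributes fractionally to the nonsynonymous and
synonymous site totals: the fraction of its three possible
single-nucleotide substitutions producing each outcome. The third
position of a 4-fold degenerate codon is a full synonymous site; that of
a 2-fold degenerate codon contributes 1/3 synonymous and 2/3
nonsynonymous. Genome-wide counts are the sum over all codons of all
coding sequences. dN/dS is the ratio of per-site observed rates,

$$\mathrm{dN/dS} =
  \frac{n_\text{NS} / S_\text{NS}}{n_\text{S} / S_\text{S}},$$

undefined (reported `NA`) when no synonymous mutations were observed.
Enrichment against the neutral expectation — observed mutations split in
proportion to the site counts — is a two-category chi-squared goodness
of fit with 1 df and no continuity correction.

Numerical and policy choices:

* **Stop codons as targets** (`stop_as_ns`, default): substitutions
  creating a stop count as nonsynonymous, so every sense codon
  contributes exactly 3 sites; `exclude_stop_targets` removes them from
  the denominator for sensitivity analysis.
* **Terminal stops** are excluded from counting; internal stops are
  errors (or skip-with-warning).
* **Genetic code**: bacterial translation table 11, configurable.
* **Numerator classes**: only `nonsynonymous` and `synonymous` point
  mutations enter dN/dS; nonsense, frameshift, noncoding, intergenic and
  structural events count toward totals only.

Because site counts are linear in codon counts, the genome-wide totals
of a CDS complement are fully determined by its codon-usage
composition. The package ships the relative codon usage of the
*E. coli* K-12 MG1655 coding-gene set (`ecoliCodonUsage()`,
frequencies per 1000 codons) and computes site counts from it
(`siteCountsFromCodonUsage()`); the implied genome-wide NS:S site ratio
is 3.249. `siteCounts()` performs the same computation directly on a
CDS FASTA/`DNAStringSet` for users who have the sequence file, and
`syntheticCodingSequences()` generates usage-matched synthetic CDS sets
for exercising that path.

### Calibrating the neutrality property

dN/dS is a ratio estimator, so under neutral mutation generation its
expectation exceeds 1 by roughly $\sigma^2_S/\mu_S^2$ (Jensen's
inequality applied to $1/n_\text{S}$). At 200 mutations per replicate
this bias is ≈2%, which is *larger* than three standard errors of a
1000-replicate mean (≈1.6%) — a mean-versus-1 check at that depth would
reject a correct implementation. The package's property test therefore
draws 2000 mutations per replicate (bias ≈0.16%, three standard errors
≈0.5%) and additionally checks the pooled-count ratio, which is
bias-free at that scale, against a delta-method standard error.

## The serial-dilution simulator

Each daily cycle is **grow → mutate → dilute**:

* **Growth** is deterministic: the fastest genotype present completes
  exactly $g = \log_2(\text{dilution factor})$ doublings (≈6.64 for
  1:100), and genotype $i$ multiplies by
  $2^{\,g\,r_i/\max_j r_j}$. With two genotypes this gives an exact
  per-cycle change of $g\,\Delta r/\max r$ in log2 frequency odds — the
  closed form the tests check.
* **Mutation** happens at cycle boundaries: for each anRNAPC-carrying
  genotype the expected event count is `cells × generations × mu`
  (×`mutatorFactor` for mutators), Poisson-drawn. Reversion moves cells
  to a derived genotype with the allele removed and rate restored to 1;
  compensation retains the allele with the cost reduced by
  `compensationRateRecovery`. With $k$ equally likely compensatory
  targets and one reversion target at equal per-site rates, compensation
  outcomes outnumber reversions ≈ $k:1$ — the classical argument for why
  fixed costly alleles are usually rescued rather than reverted, and why
  mutators (more mutational input overall) are the ones that find the
  single reversion target.
* **Dilution** is a multinomial draw of `bottleneckN` cells — the
  dominant source of drift in serial passage. Equal-rate genotypes drift
  as a martingale; the tests verify mean-frequency conservation over
  replicate experiments.

Default conditions: 1:100 dilution, 16 cycles, anRNAPC cost 20%
(relative rate 0.8). The bottleneck size (10⁶) and mutation rates
(reversion 10⁻⁹, compensation 5×10⁻⁹ per genome per generation, mutator
factor 100) are not measured quantities; they are documented
illustrative values in a plausible range for *E. coli*, and every
analysis that depends on them takes them as explicit configuration.
Stochasticity enters only at mutation and dilution, keeping the growth
closed forms exact; mutation is applied in aggregate per cycle, not by
per-division lineage tracking, which is adequate for frequency-scale
questions but cannot represent within-cycle jackpot events.

"Detection" of an allele is modelled as its presence in a sampled set of
~10 sequenced clones, matching realistic sequencing depth, rather than
as a hard frequency threshold. In the structural scenario founded by 11
clones (9 allele carriers at 20% cost, 2 near wild type, 10⁶-cell
bottleneck, no mutation), the allele's expected frequency by cycle 10 is
$\approx 4.5\times10^{-4}$, so a 10-clone sample is allele-free with
probability ≈0.995 — the simulator reproduces the observed
disappearance of the costly adaptations below detection within ten
cycles.

What the generator does **not** emulate: the LTSP phase itself (death
phase, dormancy, balancing selection that built the standing variation),
within-cycle resource kinetics (growth is exponential-with-clock, not
Monod), clonal interference among new beneficial mutations, and
sequencing error in mutation tables. Passing round-trip tests therefore
demonstrate the internal consistency of estimator and generator — not
that real plate or sequencing data meet the generator's assumptions.

## Problem sizes in the test-suite

The property tests run at sizes chosen to keep three-standard-error
bounds meaningful while completing in minutes: 10⁴ replicate experiments
for drift conservation (bottleneck 100–200, 3–4 cycles), 10⁴ replicate
dilutions for binomial moments, 1000 × 2000 draws for dN/dS neutrality,
50–60 seeded experiments for the compensation:reversion ratio, 100
seeded experiments for the detection-limit scenario, and 61 × 9
substitution enumerations for the site-counting oracle.

## Known limitations

* Single-well relative growth rates under additive plate noise are
  intrinsically noisy (see the error analysis above); the estimator
  faithfully implements the window-maximum definition rather than a
  smoothing alternative.
* Outcome classification is end-state only; it cannot distinguish a
  compensatory mutation that preceded a reversion from one that followed
  it.
* Codon-usage-based site counts are exact for the composition they are
  given; different annotation releases of a genome differ slightly in
  their CDS complements and hence in the third decimal of the NS:S
  ratio.
* The GenomeDiff reader consumes evidence-free mutation lines only and
  maps structural records to the package's coarse class vocabulary.
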