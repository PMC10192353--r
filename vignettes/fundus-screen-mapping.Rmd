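---
title: "Simulating and mapping a fundus spot forward-genetics screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and mapping a fundus spot forward-genetics screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusmap)
```

## The screen design being modelled

ENU mutagenesis of G0 males induces random point mutations in
spermatogonia. A G1 son inherits a private heterozygous set of
coding/splice mutations — about 60 in this screen design — which are
identified by exome sequencing. The G1 male is crossed to wild-type
females; his G2 daughters each inherit any given mutation with
probability 1/2 (heterozygous if so, never homozygous). Backcrossing
G2 dams to the G1 sire produces the screened G3 generation, in which
a recessive allele can reach homozygosity: at any site the marginal
G3 genotype probabilities are REF 3/8, HET 1/2, VAR 1/8, and
conditional on a HET dam the classic 1:2:1. All mice are genotyped at
every pedigree site before phenotyping, so simulated tables carry no
missing calls.

`breed_pedigree()` implements exactly this scheme. The topology (one
sire, wild-type-derived G2 dams backcrossed to the sire) is the only
arrangement consistent with dams whose zygosity matters but who are
never VAR, and with VAR G3 mice; we adopt it as the package's model
of the breeding protocol. Sites are autosomal only: hemizygous X
males would need a fourth genotype state, the screen's documented
candidate is autosomal, and X segregation differs by sex — an
extension we deliberately exclude. Sites segregate independently (no
linkage map); the founder mutation count (`n_sites = 60`) refers to
the G1 founder's heterozygous set, of which each G3 mouse carries a
random subset (5/8 of sites in expectation). The default pedigree
shape, 5 G2 dams × 8 pups ≈ 40 G3 mice, matches typical screened
pedigree sizes; both knobs are parameters.

## The phenotype generator

No per-mouse count model is published for fundus spots, so the
generator makes the least-assumption choices explicit:

* Per eye, total spot count ~ negative binomial with mean
  λ = `baseline_mean` + g·`effect_size` + `age_slope`·age, where g is
  the genotype's susceptibility weight under the causal inheritance
  mode (recessive 0/0/1, additive 0/0.5/1, dominant 0/1/1 for
  REF/HET/VAR).
* The total is split across the four quadrants (superior, inferior,
  nasal, temporal) with equal multinomial probabilities — quadrant
  symmetry is the neutral default.
* The two eyes of a mouse are independent given genotype; the
  screen's scale sums eyes without modelling correlation, so we do
  not introduce one.

Parameter defaults and why:

| parameter | default | units | rationale |
|---|---|---|---|
| `baseline_mean` | 1 | spots/eye | wild-type-like eyes show zero to a few spots |
| `effect_size` | 40 | spots/eye | reservoir-like severe recessive effect: VAR mice reach four-quadrant involvement |
| `dispersion` | 8 | NB size | var = μ + μ²/8: realistic overdispersion that still separates VAR (score ≥ 6) from REF/HET (≤ 2) in ≥ 95% of mice at the defaults |
| `age_slope` | 0 | spots/eye/month | the screening window (4–6 months) is narrow |

The effect-class annotation of simulated mutations
(`probably_null` 0.08, `probably_damaging` 0.22, `possibly_damaging`
0.25, `probably_benign` 0.45) reflects a typical ENU coding-variant
spectrum — a small minority of outright nulls, about half damaging or
possibly damaging. It feeds only the `saturation()` accounting, not
the phenotype.

What the generator does *not* emulate: image acquisition and grader
behaviour (two-grader masking, inter-grader noise), eye-to-eye
correlation, spatially clustered spots, linkage between nearby sites,
and X-linked inheritance. Passing simulation-based tests therefore
demonstrates the correctness of the pipeline's statistics under a
clean Mendelian, overdispersed-count world — not robustness to real
imaging artefacts.

## The grading scale

Per eye: 0 = no spots; 1 = 1–10 spots; above 10 spots the grade is by
quadrant involvement — 2 for the equivalent of one involved quadrant,
3 for two to three, 4 for all four. The published scale is applied by
eye by masked graders; to make it computable, `score_eye()` counts a
quadrant as "involved" when it holds at least
`quadrant_involvement_threshold` spots (default 3), applied only when
the eye total exceeds 10. This is one consistent reading of
"equivalent of one fundus-quadrant of spots", flagged as an
operationalization rather than the graders' exact rule; the threshold
is a prominent, configurable parameter. The rule is monotone: adding
a spot can never lower a score. Two-eye sums give the 0–8 per-mouse
score with its 9 achievable values.

```{r scale}
score_eye(c(7, 0, 0, 0))     # 1-10 spots
score_eye(c(20, 20, 20, 20)) # all four quadrants
```

## The mapper

`scan_pedigree()` regresses the per-mouse score on the encoded
genotype at every site under each requested model (recessive 0/0/1,
semidominant 0/1/2, dominant 0/1/1 — 0/1/2 is equivalent to 0/0.5/1
up to slope rescaling, with identical p-values) and keeps the best
(smallest) non-degenerate p per site. Degeneracy is explicit: a site
with no VAR mice has zero variance under the recessive encoding and
is reported as `degenerate` there rather than imputed or set to
p = 1; it is still tested under the other encodings. Numerically,
p-values are floored at 1e-300 so that −log₁₀ p stays finite for
perfect fits, and zero-variance detection uses a 1e-12 relative
tolerance.

Candidate criteria: best p below the Bonferroni threshold
α/(n_sites × n_models) — counting models is the conservative reading
of "0.05 with Bonferroni correction", and `bonferroni_threshold(...,
n_models = 1)` gives the sites-only divisor — and a peak-dominance
margin of ≥ 3 logs over the highest peak at any *other* gene, so a
candidate is not defeated by a linked sibling mutation in its own
gene (in simulated data each site is its own gene). A single-site
scan has margin +Inf by convention, passing the rule vacuously. At
most one site per scan can hold a ≥ 3-log lead, matching the
at-most-one-candidate design.

For ordinal analyses the response is dichotomized (affected = score ≥
`dichotomize_cut`, default 6) and each site is tested with the exact
two-sided hypergeometric test of the affected × susceptible 2×2
table. The original screen software's "binomial calculations" for
ordinal traits are not specified in detail; the exact 2×2 test is one
defensible implementation and is labelled as such. The Manhattan
y-value is the min-p across models by default, but every per-model p
column is retained so a single-model view is always available.

The "at least 2 homozygotes" accounting requirement appears as the
`two_var` annotation column and in `saturation()`'s numerator rule;
it is deliberately not a test filter.

## Power and error simulation

`power_study()` replays the full pipeline per replicate: breed,
simulate exams, score, scan, call. A master seed fans out to child
seeds by the fixed rule `(master + 104729·i) mod (2³¹ − 1)`, so any
replicate can be regenerated alone. With `causal = TRUE` the pedigree
is redrawn (deterministically) until the causal site carries at least
`min_var_causal = 2` VAR mice, mirroring the screen's two-homozygote
requirement; without this conditioning ~3% of pedigrees would carry
an undetectable causal site (all dams REF) and power would measure
breeding luck rather than the mapper.

Two study conditions are fixed as the package's reference scenarios:

* **Reservoir-like**: the default `phenotype_model()` (baseline 1,
  effect 40, recessive). VAR mice score 7–8, others 0–2; 200
  replicates recover the causal site as the sole candidate in ≥ 95%
  of pedigrees, essentially always under the recessive encoding.
* **Moderate effect**: effect 12 (other defaults unchanged). VAR mice
  then average score ≈ 5 and only ~38% cross the affected cut of 6,
  so dichotomization discards most of the signal: at 500 replicates
  the continuous 0–8 analysis is markedly more powerful than the
  dichotomized exact test, which operationalizes the design's
  preference for continuous-variable linkage analysis.

Under the null (no causal site) the Bonferroni threshold plus the
3-log margin make candidates rare: the family-wise false-candidate
rate over 200 replicates sits near zero, well below α = 0.05, and
single-model p-values are approximately uniform (the 0–8 response is
mildly discrete, which perturbs uniformity slightly but visibly only
at very large draw counts).

Problem sizes used by the test suite and the acceptance script — 200
null and 200 causal replicates, 500 replicates per arm of the
sensitivity comparison, 10,000 mice for Mendelian checks — were
chosen so that Monte-Carlo error is small relative to every margin
being asserted while a full run stays within a couple of minutes.
The Mendelian checks use 10,000 dams with one pup each: with large
litters the dam-genotype sharing inflates the variance of the VAR
fraction ~2.5-fold over the binomial reference, so independent pups
are the correct design for a 3-SE binomial band.

## Numerical and statistical cross-checks

The closed-form OLS slope test is verified against `stats::lm` to
1e-10 and against Monte-Carlo permutation tests; the exact 2×2 test
against `stats::fisher.test` and brute-force enumeration of affected
assignments; `two_group_t()` (a thin wrapper over
`stats::t.test(var.equal = TRUE)`, with a Welch option) and
`trend_regression()` against hand-computed closed forms. One caveat
worth stating: at n = 8 the t reference differs from the exact
permutation distribution by O(0.01–0.05) in p — the permutation
distribution is discrete, with at most a few hundred distinct
assignments for a three-level genotype — so permutation agreement is
asserted up to that small-sample resolution, not to pure Monte-Carlo
error. This is a property of the t approximation itself, not of the
implementation.

Quartiles in `iqr_outliers()` use linear interpolation (type 7) by
default with a Tukey-hinges option; fences are open intervals
(strictly outside is removed), and with IQR = 0 equal values are
never removed. `percent_change()` rounds half away from zero when
integer rounding is requested. The `saturation()` denominator is an
explicit parameter (default 20,000 protein-coding genes) because no
universally agreed universe exists; report it alongside the
fraction.

## Limitations

Simulated pedigrees are idealized: no genotyping error, no missing
exams, no recombination or linkage disequilibrium, no multi-pedigree
"superpedigrees", no kinship or mixed-model correction (unnecessary
within a single pedigree design but essential across pedigrees), and
no machine-learning candidate prioritization downstream of the
mapper. The scale operations (`score_eye()`, `score_mouse()`,
`phenotype_table()`) are the only components intended to run on real
grader data unchanged.
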