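---
title: "Methods: strain-level deconvolution and priority-effect statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-level deconvolution and priority-effect statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainPriority)
```

## The scientific setting

Sequential-colonization experiments with gnotobiotic (microbiota-depleted)
honeybees test whether the *order of arrival* of bacterial strains shapes
the gut community ("priority effects"). Two defined communities, A and B,
contain the same 12 species — two *Bombilactobacillus*, four
*Lactobacillus* and six *Bifidobacterium* — but different strains of most
species. Bees receive one community on Day 0 and (in the sequential
treatments) the other on Day 3; guts are sampled on Day 10. If firstcomers
pre-empt the niches of their conspecific latecomers, sequential communities
should resemble the Day-0 community, and each strain should be far more
abundant when it arrived first than when it arrived late.

Strains of one species differ by only one or two SNPs across their
full-length 16S rRNA alleles, so strain-level readout requires full-length
16S amplicon sequencing plus a deconvolution step that maps amplicon
sequence variants (ASVs) back to strains. This package implements that
pipeline — deconvolution, absolute quantification, the priority-effect
statistics — together with a synthetic-experiment generator that emulates
the whole design, so every stage is testable end to end without external
data.

## Strain reference and copy matrix

Each strain contributes its 16S alleles with integer copy numbers. Alleles
identical in sequence — within a strain or across strains — collapse into
one ASV class; the **copy matrix** \(M\) records \(M_{ai}\), the number of
16S copies of strain \(i\) with sequence equal to ASV \(a\). Column sums
are the strains' total 16S copy numbers. ASV identity is exact sequence
equality (ASVs are denoised exact variants; no clustering), rows are
ordered lexicographically by sequence and columns by strain id so the
matrix is reproducible.

`check_identifiability()` reports, per community, whether every member
strain owns a unique ASV, its minimum SNP distance to co-members' alleles
(prefix-Hamming plus length difference — a diagnostic, not an alignment),
and whether the community submatrix has full column rank, the condition
under which noiseless deconvolution is exact. Strains sharing their entire
allele set are flagged, not repaired.

## Deconvolution model

For a sample with ASV counts \(y\) and inoculated ("candidate") strains
\(c\), strain units solve

\[\hat s \;=\; \arg\min_{s \ge 0}\; \lVert W^{1/2}\,(M_c\,s - y)\rVert_2 ,\]

with non-negativity enforced by a Lawson–Hanson active-set solver
(`nnls_solve()`); a strain unit is a genome equivalent, so assigned reads
are \(\hat s_i\) times the strain's copy total, rescaled to sum to the
sample's *known reads* (reads matching any reference ASV). Counts on ASVs
absent from the reference are tallied as unknown reads and take no part in
the fit. Restricting to inoculated strains reflects the gnotobiotic,
closed-community setting; `open_community = TRUE` fits all reference
strains instead. Rank-deficient candidate sets error by default rather
than silently splitting mass between indistinguishable strains.

**Residual weighting.** `infer_strain_counts()` defaults to ordinary
unweighted residuals (\(W = I\)), which keeps the plain least-squares
objective and its brute-force grid oracle meaningful. The pipeline,
however, defaults to Poisson weights \(W_{aa} = 1/\max(y_a, 1)\)
(residuals on the scale of their counting noise). The reason is concrete:
with any fixed per-ASV amplification-efficiency bias (even 5%), unweighted
least squares lets small *relative* misfits on a dominant firstcomer's
high-count shared ASVs outweigh the handful of reads on a rare latecomer's
private ASV, and the solver zeroes the latecomer out entirely. On failing
synthetic samples a latecomer truly present at ~20 reads was estimated at
0 unweighted and ~24 with Poisson weights. No per-ASV efficiency factors
are estimated under either scheme.

## Absolute quantification and QC

qPCR Ct values convert to total 16S copies per gut through a log-linear
standard curve, `copies = 10^((ct - intercept)/slope) * dilution_factor *
volume_scaling`. The defaults (slope −3.4 Ct per log10, intercept 38,
dilution 10, 30 µL elution scaling) are documented placeholders: a real
run must supply its calibrated curve, and the synthetic generator uses the
same curve to emit and to invert Ct values, so the placeholder cancels.

Samples are removed when Ct exceeds 26.53 (or is undetermined) or when
fewer than 100 known reads remain; both thresholds are strict inequalities
(a sample at exactly Ct 26.53 with exactly 100 reads is retained), and
each removal carries one primary reason, load before depth.

Relative abundance is assigned reads over known reads (the denominator is
configurable to total reads; known reads is the default for internal
consistency with the closed-community fit). Absolute abundance is relative
abundance times the qPCR total. The per-sample **detection limit** is the
copy equivalent of one read — total copies divided by reads — and any
abundance strictly below it is marked undetected and stored as exactly 1
(not 0, not NA), which keeps log10 transforms finite with 0 meaning
"undetected". One read therefore sits exactly at the limit and counts as
detected.

## Priority-effect statistics

* **Strength** of strain \(i\) in combination \(k\):
  \(\log_{10}(\mathrm{med}_{\text{first}} / \mathrm{med}_{\text{late}})\),
  medians over the bees of the two sequential treatments (undetected = 1
  values included by default; an option restricts to detected samples).
  Zero means no priority effect. Single-community controls and dropout
  cages are excluded. Strength is defined only for focal strains — strains
  private to one community; strains shared between both inocula have no
  first/late contrast and raise an error.
* **Colonization frequency**: percent of bees in which the strain was
  detected, firstcomers vs latecomers, with a two-sided Fisher exact test
  on the 2×2 table.
* **Abundance contrast**: two-sided Wilcoxon rank-sum on absolute
  abundance among detected samples, Benjamini–Hochberg corrected across
  strains within an analysis family.
* **Species totals**: summed conspecific abundance per sample, one- vs
  two-strain treatments (Wilcoxon); equality indicates colonization to a
  fixed carrying capacity.
* **Dropout rescue**: with the conspecific firstcomer omitted,
  \(100 \times (\mathrm{med}_{\text{dropout}} - \mathrm{med}_{\text{late}})
  / (\mathrm{med}_{\text{first}} - \mathrm{med}_{\text{late}})\), using
  only samples above the detection limit; 0% means no rescue, 100% full
  rescue, undefined (flagged) when firstcomer and latecomer medians
  coincide. The percentage is invariant to rescaling all medians.

## Community-level statistics

Log10 absolute abundances (undetected → 0) feed Bray–Curtis
dissimilarities (`vegan::vegdist` behind `bray_curtis()`; a semi-metric,
so no triangle inequality is asserted), classical-scaling PCoA (negative
eigenvalues reported, not dropped), and a one-way permutation PERMANOVA
implemented in the package:

\[F = \frac{SS_B/(a-1)}{SS_W/(n-a)}, \qquad
p = \frac{1 + \#\{F_{perm} \ge F\}}{1 + n_{perm}}, \qquad
\omega^2 = \frac{SS_B - (a-1)\,MS_W}{SS_T + MS_W}.\]

The omega-squared partition is stated explicitly rather than delegated to
an external helper; `vegan::adonis2` serves as an independent cross-check
in the tests, which also verify bit-exact reproducibility given a seed,
\(\omega^2 \le R^2\), a type-I error rate within [0.03, 0.07] at
\(\alpha = 0.05\) under a null simulation (1000 datasets, 199 permutations
each — at 199 permutations the null rejection probability is exactly
0.05), and \(\mathrm{mean}\,|\omega^2| < 0.02\) under that null. Only the
one-factor (treatment) design is implemented; multi-factor models and
dispersion tests are out of scope.

The arrival-order regression is a Gamma GLMM with log link,
`abs_abundance ~ order + (1 | combination)`, order ∈ {first, second,
only}, fitted by `lme4::glmer`. The contract is on sign and recovery (a
latecomer suppressed 1000× should yield a "second" coefficient near
−log 1000 and p < .05), not on exact coefficient equality across fitting
libraries; non-convergence is reported, never silently dropped. Under the
generator's lognormal noise the Gamma Wald z is anti-conservative — the
standard errors are underestimated by roughly 20–40% (null |z| < 2 in
~80–90% of replicates rather than the nominal ~95%), and non-converged
fits can produce extreme z — while the coefficient itself stays centred
at zero. Treat borderline GLMM p-values accordingly and discard flagged
non-converged fits.

## The synthetic experiment generator

The generator models the **outcome distribution** the analysis assumes,
not colonization dynamics — the experiments measure end-point abundances
only, and simulating ecology would invent mechanism. Per bee: total load
lognormal around a carrying capacity of 1e8 16S copies (sdlog 0.5);
species shares symmetric-Dirichlet (concentration 5, moderate evenness —
an acknowledged arbitrary choice); within a species colonized by a
first/late pair, the latecomer's share is the firstcomer's times
\(10^{-\text{strength} + \varepsilon}\), \(\varepsilon \sim N(0, 0.3)\) on
the log10 scale, which creates the across-bee spread seen in real data;
sole strains take the whole species share; in dropout cages the orphaned
latecomer reaches `rescue_level` (default 0.3) of the way back to the
firstcomer level. Reads are multinomial at 1e4 per sample over
copy-profile-weighted strain abundances times a fixed per-ASV lognormal
efficiency bias (sd 0.05), with 2% of reads emitted as junk ASVs; Ct
values follow the standard curve plus N(0, 0.3) cycles.

The strain layout regularizes the real study's irregular roster to exactly
22 strains: the two *Bombilactobacillus* species carry one strain shared
by both communities; the ten other species carry two strains each (20
focal strains). Six community combinations shuffle the focal strains
between A and B such that every focal strain's background differs by at
least five strains between any two combinations (enforced by bounding the
pairwise Hamming distance of the shuffle vectors to [4, 6], since a strain
may also switch communities between combinations; `design_background_check()`
verifies the realized design). Conspecific strains differ by 2 SNPs in one
variant allele and share their remaining alleles, so each strain owns a
private ASV (full-rank, identifiable) while conspecifics share ASVs — the
regime that actually stresses the deconvolution.

**Default strengths and the detection limit.** At 1e4 reads and ~1e8
copies per gut the detection limit is ~1e4 copies. A latecomer suppressed
by 3 log10 sits near 8e3 copies — below the limit — so its measured median
collapses to the undetected value and the strength estimate saturates at
\(\log_{10}(\text{first}/\text{limit})\) or beyond; exactly this censoring
is visible in real data, where several strains were almost entirely
undetectable as latecomers. Point recovery of a seeded strength is
therefore only meaningful in the uncensored window, and the default
`strength_map` spreads per-strain suppressions over [0.5, 1.6]. The
strong-dominance scenario (`scenario_config(strength = 3)`) is kept as a
separate fixed condition for the community-level contrasts, where
censoring only strengthens the signal; recovery of a strength of 3 as a
*point estimate* is demonstrated at depth 1e5, where the latecomer stays
above the limit.

What passing tests on this generator do **not** show about real data: no
chimeras or residual sequencing error beyond multinomial noise, no
sample-to-sample variation in amplification bias, independent random
sequences across species (real congeners are ~95% identical — irrelevant
to exact-match ASV classes but not to alignment-based approaches),
and no mechanistic colonization dynamics.

## Numerical choices and degenerate inputs

* NNLS: scale-aware KKT tolerance, iteration cap 50·n with a warning on
  non-convergence; the passive-set solve is exact QR, so noiseless
  full-rank recovery is exact to machine precision.
* All-zero count vectors return a flagged zero solution with a warning;
  all-zero sample pairs get Bray–Curtis distance 0 with a warning.
* Undetected abundance is exactly 1; log matrices reject values below 1 as
  upstream contract violations.
* Every stochastic stage derives its own stream from the scenario seed
  (reference, design, abundances, reads), so artifacts are byte-identical
  under a seed and stages can be regenerated independently; permutation
  tests require an explicit seed.
* Problem sizes used in the shipped analyses: 6 combinations × 4
  treatments × 10 bees (+ 6 dropout cages of 10), 1e4 reads per sample;
  the test suite uses a 2-combination, 4-bee, 2000-read scenario for unit
  tests and the full scenarios for end-to-end checks.

## Known limitations

* The qPCR curve is a placeholder; absolute levels are only as good as the
  calibration supplied.
* Per-ASV amplification bias is not corrected, only down-weighted; large
  biases (≳20%) degrade rare-strain resolution.
* Strength estimates censor at the detection limit; reported large
  strengths are lower bounds, not point estimates.
* One-factor PERMANOVA only; presence/absence (Jaccard) metrics are
  available on the detected flags but carry no validated claims.
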