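---
title: "Methods: two-strain pooled-sequencing divergence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-strain pooled-sequencing divergence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsweep)
```

## The design this package analyses

Two laboratory strains descend from one population split decades ago; one
strain (R) has since been under recurrent directional selection (the
motivating case is DDT selection in *Drosophila melanogaster*), the other
(C) has not. Each strain is sequenced as a pool of many individuals, so
read counts at a site estimate the strain's allele frequency rather than
any individual genotype. A related species (the outgroup; *D. simulans* in
the motivating case) supplies the ancestral state at polymorphic sites.

The analysis asks three questions. First, at sites where a strain is fixed
for a non-reference allele, is that allele *old* (ancestral — it matches
the outgroup) or *new* (derived)? Under neutral drift a new allele is
equally likely to fix in either strain, so an excess of unique new alleles
in the selected strain is the genome-wide fingerprint of selection.
Second, which coding variants change amino acids, and how are the affected
genes distributed across chromosome arms? Third, where does
differentiation concentrate: windowed F_ST and between-strain diversity
locate candidate sweep regions.

## Statistics

**Per-site F_ST from population heterozygosities.** With variant-allele
frequencies $p_1, p_2$ in the two strains:
$H_i = 2 p_i (1-p_i)$, $H_S = (H_1+H_2)/2$, $\bar p = (p_1+p_2)/2$,
$H_T = 2\bar p(1-\bar p)$, and $F_{ST} = (H_T - H_S)/H_T$, undefined (NA)
when $H_T = 0$. Algebraically $H_T - H_S = (p_1-p_2)^2/2$, an identity the
test suite checks to $10^{-12}$; $F_{ST} = 1$ iff the strains are fixed
for alternative alleles.

This is the Nei-style two-population G_ST with equal weights. The window
statistic aggregates as a **ratio of sums**, $(\sum H_T - \sum
H_S)/\sum H_T$ over the window's SNPs. Averaging per-site ratios instead
gives low-heterozygosity sites the same weight as informative ones and is
unstable when $H_T$ is small; it remains available via
`method = "mean_of_ratios"` because the choice is not neutral — both
estimators are implemented, ratio-of-sums is the default and the one used
throughout.

**Window tiling.** Windows are 10,000 bp advancing in 1,000 bp steps
(defaults; both settable). Starts stay on the step grid while a full-width
window fits; if the last full window stops short of the arm end, one
trailing partial window is appended. Between-strain diversity
$d_{xy} = \frac{1}{L}\sum_j [p_{1j}(1-p_{2j}) + p_{2j}(1-p_{1j})]$ always
uses the true covered length $L$, so partial windows are not inflated.
Monomorphic-identical sites contribute 0 and need not be enumerated.
Windows with $F_{ST} > 0.8$ (strict) are flagged extreme. The unplaced arm
"U" is parsed but excluded from scanning and from burden percentages.
Unsorted site input is an error, never silently sorted.

**Contingency and excess tests.** The strain × mutation-type table of
amino-acid-changing fixed ORF variants is tested with Pearson's χ²
(df = 1) *without* continuity correction — the uncorrected statistic is
the one that reproduces the published value 375.47 on the published
counts; Yates' correction is available behind a flag. Zero marginals are
an error, not NaN. The unique-allele excess uses a two-sided sign test
against p = 0.5 (the neutral symmetry argument): exact binomial for
n ≤ 1000, normal approximation above. The published "2.6% excess" has no
reproducible formula from the printed counts, so the report confines
itself to directly defined quantities: difference, its percentage of all
classified alleles, and the complement. (One published count is itself
internally inconsistent — 779 vs 781 variants for the control strain —
and the pipeline simply carries whatever its own tally produces.)

**Call filtering.** A candidate call passes iff central PHRED q ≥ 20,
all flanking q ≥ 15 (11 per side), depth ≥ 10 and variant frequency
≥ 0.10 — thresholds inclusive exactly as printed, identical for SNPs and
DIPs, each exposed as an argument. Sites within 11 bp of a contig end are
judged on the flanks that exist, rather than discarded for missing
context. Failure reporting lists *every* violated rule; the accept/reject
partition is exact by construction, and the filter is monotone (raising
any score never turns a pass into a fail), a property the suite tests.
Whether the variant frequency is per-strand is unknowable from the
published description; it is treated as pooled.

**Polarization.** Origin is a string comparison against the outgroup
allele: equal ⇒ old, unequal ⇒ new, missing/N ⇒ unpolarized (excluded
from old/new tallies — this also covers outgroup alignment gaps, for
which no mismatch tolerance is defined). DIP alleles compare as full
left-aligned strings. Fixation defaults to a threshold of 1.0 (literal
fixation, as the published wording implies); because pooled sequencing
rarely yields exactly 1.0 on real data, the threshold is an argument
(`threshold = 0.95` is a reasonable noise-tolerant choice) with the
constraint threshold ∈ (0.5, 1]. Multi-allelic sites are handled as one
record per alternate allele; a site is unique to a strain only when that
strain is fixed for the variant and the other is fixed reference.

**ORF effects and burden.** SNPs translate through the standard genetic
code on the coding strand; indels classify by length mod 3 (frameshift vs
in-frame); stop gain/loss counts as amino-acid-changing. Genes whose CDS
length is not a multiple of 3 are flagged and annotated best-effort on
the 5′ frame, never silently dropped. For multi-transcript genes the
longest CDS is used. Per-arm burden percentages divide genes-hit by
per-arm gene totals, which are an *input* (they depend on the annotation
release); the totals of the motivating study's annotation
(2939/3238/2950/3702/90/2381) ship as `dmel_arm_gene_totals()`.
Percentage labels use two significant figures, which is the convention
the published tables actually follow (0.46%, 0.76% are impossible at one
decimal place); raw percentages are returned alongside. Two published
cells do not reproduce from their own counts under any rounding
(4/3702 → 0.11 vs printed 0.12, and a proportion-vs-percent slip at
1/2950); they are documented, not imitated. Consensus ORF extraction
applies a strain's fixed variants right-to-left so indels shift
downstream coordinates consistently, and errors on overlapping variant
spans or reference mismatches.

## The synthetic-data generator

The generator exists because the raw study data are external; it emulates
the design, not any particular dataset, and every emitted variant carries
ground truth (origin, ancestral/selected status, true frequencies, the
ancestral frequency $p_0$).

Model, per arm: a uniform-random reference sequence; an outgroup copy
substituted at rate `outgroup_divergence` (default 0.05, the approximate
*melanogaster–simulans* genome-wide divergence); non-overlapping
single-interval CDS gene models (lengths multiples of 3). Standing
variation at the split is drawn at mutation–drift equilibrium —
segregating-site density $\theta L \sum_{i<2N} 1/i$ with $\theta = 4N\mu$
and frequencies from the neutral 1/i spectrum. A configurable fraction of
these sites (default 0.5) segregate for the *outgroup-matching* allele
(the outgroup base is pinned to the segregating allele at such sites,
representing retained ancestral polymorphism at diverged positions); the
rest carry derived alleles. Each strain then drifts independently for
`generations` rounds of binomial resampling of 2N gametes, with Poisson
influx of new mutations (expected $2N\mu L$ per strain per generation,
entering at 1/2N). New-mutation alleles are drawn to differ from the
outgroup base at their site, so origin labels are exactly consistent with
outgroup comparison — the generator models no homoplasy. A DIP fraction
(default 0.1) of mutations become 1–10 bp left-aligned indels. Selected
loci are injected as de-novo mutations present *only in strain R* at
initial frequency `selected_p0` (default 0.05 — a resistant founder
fraction), pushed each generation by $p' = p(1+s)/(1+ps)$ before
resampling. Pooled sequencing is depth ~ Poisson(`pool_coverage`,
default 40×) and supporting reads ~ Binomial(depth, true frequency).
Identical seed and configuration reproduce the study byte-identically.

Default scale: six arms named after the *Drosophila* arms, 200 kb each,
N = 100, t = 500, μ = 10⁻⁸ — a desk-scale stand-in for strains kept ~60
years at bottle population sizes. The number of generations and the
effective size of the real strains are unknown; these defaults are free
parameters of the emulation, not estimates.

**What the generator does not emulate.** Sites evolve independently
(free recombination): there is no linkage, so a sweep leaves no
hitchhiking footprint, and the extreme-window signal comes from the
selected site itself. Relatedly, standing variation is at *lab-scale*
equilibrium ($\theta = 4N\mu \approx 4\times10^{-6}$), orders of
magnitude below wild *Drosophila* diversity — real strains founded from
wild populations carry far denser variation, in which a single
fixed site could never dominate a 10 kb window's F_ST; detecting sweeps
there requires the linked diversity valley this generator does not
produce. There is also no sequencing-error substitution model (the
quality-profile module injects labelled filter failures instead), no
demographic structure beyond the single split, and no read-level
simulation. Passing tests therefore validate the estimators and
bookkeeping, not performance on wild-diversity data.

**Drift calibration.** The classic two-population pure-drift expectation
$F_{ST}(t) = 1 - e^{-t/2N}$ measures heterozygosity loss relative to the
*ancestral* heterozygosity. The windowed Nei estimator does not converge
to this value: its total heterozygosity is computed from contemporary
frequencies, which decay too, giving expectation $(1-e)/(1+e)$ with
$e = e^{-t/2N}$. The generator diagnostic `drift_fst()` therefore
computes $1 - \sum H_S / \sum H_0$ over ancestral sites from ground
truth, the estimator whose expectation is the classic formula; the
acceptance suite checks it over 20 replicates at N = 100, t = 50 against
$1-e^{-0.25} \approx 0.221$ within three Monte-Carlo standard errors.

## Numerical and edge-case conventions

* Coordinates are 1-based inclusive everywhere; the single half-open
  conversion lives in the BED writer/reader and is round-trip tested.
* Percent summaries that mirror printed values round half *up* (1.79,
  98.2), since banker's rounding would not reproduce them.
* Empty windows and zero-heterozygosity windows are NA, never 0; empty
  inputs give empty outputs and zero tallies, not errors.
* Degenerate configurations (zero population size, selected locus outside
  the genome, fixation threshold outside (0.5, 1], negative depth, zero
  contingency marginals) raise immediate errors with messages.
* Filter thresholds sit exactly at their published values and boundary
  cases (q = 20, flank 15, depth 10, frequency 0.10) pass.

## Problem sizes used by the test and acceptance suites

Simulation-based checks run at sizes chosen to make Monte-Carlo bands
tight while keeping the suites quick on one CPU: 20 replicates × 1 Mb for
the drift calibration (μ = 10⁻⁷ there, purely to raise the number of
ancestral sites per replicate and so tighten the Monte-Carlo standard
error); 20 replicates × 100 kb, t = 150 for sweep detection (long enough
for near-certain fixation of the selected allele; loss probability
≈ e^{-4Ns p_0} ≈ 2%); 10⁶ frequency pairs for the heterozygosity
identity; 10,000 sites for the brute-force window oracle; 10,000
fixed-margin tables for χ² null calibration; 20 seeds × (1 Mb, t = 500)
for the mutation-influx expectation 2NμLt = 1000.

## Known limitations

Beyond the generator limitations above: the pipeline treats the filter's
quality context as site-level (the variant's best-supported strain),
whereas a caller works per strain per read stack; polarization is a
single-outgroup string match, not a probabilistic ancestral
reconstruction; the window scan offers no significance machinery beyond
the fixed 0.8 extremeness rule, by design; and consensus extraction
refuses overlapping variants rather than attempting to phase them.
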