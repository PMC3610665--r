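---
title: "Phasing under double genotype sharing: the model, the failure mode and the mirror-subtraction remedy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing under double genotype sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrorphase)
```

## The model

`mirrorphase` phases unordered biallelic genotypes with the Li & Stephens
haplotype-copying model. An individual's two unknown haplotypes are modeled
as an ordered pair of imperfect mosaic copies of a pool of `K` template
haplotypes (all other individuals' current haplotypes, plus any phased
reference panel; the individual's own pair is always excluded). The hidden
state at marker `m` is an ordered template pair `(j, k)`; each chromatid
follows an independent jump process

> P(j → j') = (1 − θ_m)·[j = j'] + θ_m / K,

where `θ_m` is the per-interval template-switch probability, a stand-in for
historical recombination. The observed dosage `g ∈ {0, 1, 2}` is emitted by
copying each template allele with per-allele miscopy probability `e`:
`q(x | a) = 1 − e` if `x = a`, else `e`; missing genotypes emit probability 1.
The forward pass is renormalized per marker (scale factors reconstruct the
likelihood) and uses the rank-1 structure of the jump kernel, so each marker
costs `O(K²)` rather than `O(K⁴)`. Forward slices are symmetric in `(j, k)` —
emission, transitions and the uniform initial distribution are all
exchangeable in the chromatids — so only a triangle is computed.

Phasing iterates Gibbs-style: haplotypes start from random orientations,
then each sweep revisits every individual in a fresh random permutation,
resamples its template-pair path backwards from the forward probabilities,
reads haplotypes off the sampled templates (forcing genotype consistency;
template conflicts at heterozygous sites are resolved by a fair coin and
counted), and writes them back into the pool. After each sweep, `θ` and `e`
are re-estimated from the sampled paths with Jeffreys-like pseudocounts:

> θ_m = clamp((c_m + ½) / (n_transits + 1), 10⁻⁶, 0.5),
> e = clamp((mismatches + ½) / (comparisons + 1), 10⁻⁴, 0.05),

using only the current sweep's samples — the simplest defensible reading of
iterative re-estimation. The engine warns whenever some `θ_m` saturates at
its ceiling, the symptom that downstream imputation tools react badly to.

## The failure mode

When two individuals carry identical genotypes across a long region —
monozygotic twins everywhere, full siblings over roughly a quarter of their
genome, double cousins in shorter tracts — each one's posterior in that
region is dominated by the other's *current* haplotypes, whatever they are.
Starting from random initialization, A copies B's arbitrary phase, B copies
it back, and the pair forms a feedback loop the chain essentially never
leaves; iterating the transition estimates compounds it, because the single
dominant state also makes switches look rare. Phase in the shared region
then reflects nothing but the initial coin flips.

## The remedy, and where the subtraction must act

For a candidate pair `(j, k)`, the *mirror pair* is `(mate(j), mate(k))` —
the other haplotype of each contributing individual. If a pair carries no
more forward mass than its mirror, the match is phase-uninformative: any
orientation of the contributors would fit. The remedy subtracts the mirror's
weight and floors the result,

> w'(j, k) = max(w(j, k) − w(mate(j), mate(k)), ε),

with `ε` *relative*: `ε_abs = epsilon_rel · Σw` (default `epsilon_rel =
10⁻¹⁰`), which is scale-free under the per-marker renormalized forward pass,
then renormalizes. No state is ever logically excluded, only numerically
suppressed.

A design question with real teeth is *which* vector gets adjusted during
backward sampling. Two candidates:

* **Forward-slice subtraction (default).** Adjust the forward slice
  `F_m(·)` before multiplying in the transition factors toward the
  already-sampled next state. Because forward slices are symmetric, a copy
  pair `(B1, B2)` always satisfies `F(B1,B2) = F(B2,B1)`, so every copy pair
  is floored at every marker, unconditionally.
* **Conditional-weight subtraction** (`backward_sample(mirror_on =
  "conditional")`). Adjust the product `F_m(j,k)·T(j→j')·T(k→k')`. This
  looks equivalent but is not: entering the copy pair `(B1, B2)` from an
  adjacent half-copy state `(B1, y)` carries weight `F·(1−θ)·(θ/K)` while
  its mirror `(B2, B1)` carries only `F·(θ/K)²`, so the subtraction leaves
  the entry essentially untouched. In experiments with duplicated
  individuals the chain slid into the copy-pair sink through such half-copy
  states and spent >95% of its path there despite the adjustment.

We therefore default to forward-slice subtraction, which matches the plain
reading of "subtract the mirror's forward probability", and keep the
conditional variant for comparison. With an empty mate map both modes are
draw-for-draw identical to classical sampling, which the tests assert.

Mate links cover reference haplotypes too by default; a
`--no-mirror-on-reference` escape hatch severs them, for settings where the
panel is trusted and fixed.

## Imputation

The pre-phasing workflow fixes the study haplotypes and imputes masked
markers against a phased reference panel with a *haploid* copy model per
study haplotype: emission `1 − e` / `e` at typed sites, 1 at masked sites,
the same jump transitions with `K` = panel size. The reported posterior is
error-adjusted, `P(allele 1) = Σ_j post(j)·(a_j(1−e) + (1−a_j)e)`; hard
calls threshold at 0.5 with ties to allele 0 (determinism over
randomization). Pre-phased haplotypes are treated as error-free inputs,
and study haplotypes are never added to the panel.

## What the simulator emulates

The generator reproduces the four study designs used to expose the
breakdown: unrelated founder couples (`parents_only`), couples plus one
trio child each (`with_children`, 30 parents → 45 individuals), a
monozygotic duplicate for the first half of the parents
(`sibling_twins_half`, → 45), and a duplicate for every parent
(`twins_all`, → 60). Chromosome-wide twins stand in for the double-sharing
condition that real siblings produce over long tracts.

Founder haplotypes are mosaics of a small ancestral pool with i.i.d. allele
frequency 0.5 per site. Defaults, chosen once on realism grounds:

* `ancestral_pool_size = 8` — in a 30-parent cohort every haplotype then
  has several near-copies among the others. Abundant *single*-haplotype
  sharing is a necessary condition for copy-based phasing to work at all;
  with a large pool relative to the cohort, haplotypes have no partners and
  no method can phase the data.
* `mosaic_switch_rate = 0.005` per interval — shared tracts of expected
  length 200 intervals (≈ 2 cM at the default 0.01 cM spacing), the scale
  of identity-by-state haplotype segments in dense human chip data. Note a
  deliberate simplification: two *different* ancestral haplotypes are
  independent coin flips per site, so LD exists only through tract
  identity, with no allele-frequency spectrum and no gradual LD decay.
  Passing tests on this generator shows the chain exploits haplotype
  sharing correctly; it does not certify accuracy on real allele-frequency
  structure.
* `genotyping_error = 0.002` symmetric allele flips (array-scale error);
  twins are duplicated at the genotype level *after* error injection so
  twin pairs are exactly identical by state, as when one array sample is
  duplicated.
* children recombine via Haldane's map function,
  `(1 − exp(−2d/100))/2` per interval of `d` cM.
* a phased reference panel (`n_reference = 30` individuals, default) is
  drawn from the *same* ancestral pool, since a panel that shares no
  ancestry with the cohort cannot support imputation.

`mask_every_second()` clears the markers at even 1-based positions for
imputation testing, retaining the truth for scoring.

## Scoring conventions

Switch errors follow the standard flip convention: scoring is restricted to
sites heterozygous in truth where the inferred dosage matches, the
agreement bit is compared between adjacent scored sites, and a wholesale
pair swap is no error. Sites excluded by genotype mismatch are reported
separately. Each switch is attributed to the right-hand site of its
disagreeing pair, which is what makes per-marker error maps possible. For
cohorts phased from masked data, scoring uses the typed markers — the
markers the phaser actually saw; the masked half is scored through
imputation instead. "Double" genotype sharing means identical dosages,
"single" sharing means no opposing homozygotes (compatible with sharing one
haplotype); missing sites count as matching by default so missingness does
not break a true tract. When comparing the block structure of two
per-marker error maps, runs are thresholded at the *pooled* median of both
maps: per-method medians degenerate when one method's median is zero.

## Numerical choices

Per-marker renormalization (not log space) with stored scale factors;
degenerate `e = 0` is allowed with a warning, and an impossible genotype
under `e = 0` aborts naming the marker. The default error floor is `10⁻⁴`.
Random orientation at template-equal heterozygous sites consumes one RNG
draw per site in marker order, making every run reproducible from its seed.
Consensus output (optional; the default scores the final sample, matching
how a single phase sequence is evaluated) aligns each kept sample to the
first by the wholesale swap minimizing heterozygous disagreement, then
votes per site with ties to the first sample.

## Problem sizes

The bundled studies run the four designs at desk scale: 16 founder parents
(so 32 individuals in `twins_all`), 300 markers, 30 iterations, 10 seeds —
sizes at which a full two-mode, three-scenario comparison completes in a
few minutes on one core while leaving the lock-in effect unmistakable
(classical sampling degrades to near-random phase for twins; mirror
sampling stays near its unrelated-cohort accuracy). The parameter-recovery
study uses 30 parents and 500 markers with injected allele error 0.01 and
mosaic switch rate 0.02. Larger cohorts and denser maps scale as
`O(N·M·K²)` per sweep.

## Known limitations

Biallelic SNPs only; no genotype-likelihood input; no multi-allelic
markers. The state space is the full ordered-pair grid — none of the
state-space compression production tools use — so very large cohorts are
out of reach. The simulator's ancestral pool has no mutation model and a
flat frequency spectrum. Cross-validation flip rates diagnose poor mixing
without truth but phase each subset independently, so they measure
*instability*, not error. With exactly two genotype-identical individuals
and no informative third party, truth is unidentifiable in any mode; the
engine only guarantees genotype consistency there.
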