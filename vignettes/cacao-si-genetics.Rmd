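---
title: "Modeling the two-locus late-acting self-incompatibility system of cacao"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the two-locus late-acting self-incompatibility system of cacao}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cacaoSI)
```

## The genetic model

*Theobroma cacao* carries a late-acting self-incompatibility (LSI) system:
incompatible pollen tubes reach the ovary normally, but in part of the
ovules the male and female nuclei fail to fuse, and the flower or young
fruit is then shed.  Genetically the system behaves as two independent
loci with different mechanisms, and this package formalizes both as an
executable rule system.

**Sporophytic step.**  Each S-allele has an activity class (`active`
alleles carry an incompatibility specificity; `amorphous` alleles such as
the Amelonado *Sf* allele carry none) and an integer dominance rank
(lower = more dominant, equal ranks = codominant).  The classic series
S0 = S1 > S2 = S3 > *Sf* > S4 > S5 is encoded as ranks 1,1,2,2,3,4,5.
A diploid genotype *expresses* the active alleles among its
most-dominant pair members:

```{r}
m <- si_model()
expressed_specificities(c("Sf", "Sf"), m)     # nothing: self-compatible
expressed_specificities(c("Sf", "S_sca"), m)  # the dominant active allele
expressed_specificities(c("S2", "S3"), m)     # codominant: both
expressed_specificities(c("Sf", "S4"), m)     # S4 recessive to Sf: nothing
```

That last line is why trees carrying S4 or S5 under a dominant *Sf* are
self-compatible, and why *Sf*/*Sf* homozygotes always are.

**Gametic step (the chromosome-4 locus).**  An ovule's gamete pair
(female allele *f*, male allele *m*) fails fusion iff *f* = *m* = *s* for
some specificity *s* expressed in both parents (a `ch4_requires =
"mother"` variant is available; the printed crosses do not separate the
two readings, so "both" is the default).  Selfing a genotype expressing
one specificity therefore leaves 25% of ovules unfused, a codominant
pair 50%, and a homozygous active genotype 100% — the three classes
reported in the cacao cytology literature.  Among surviving offspring of
an *Sf*/active selfing the a:h:b law is 1/3 : 2/3 : 0, the "1/2
segregation with one homozygote absent" signature seen at the top of
chromosome 4 in the F2.

**Zygotic step (the chromosome-1 locus).**  A different selection acts
before gamete fusion: a zygote homozygous for a *target* allele is
eliminated whenever an *activator* allele is present in the parents (by
default in either parent; configurable, since the crosses in print do
not pin the parent down).  The canonical configuration is the Scavina-6
allele activating elimination of the Amelonado-allele homozygote; the
Criollo allele is not an activator, which is why an Amelonado x Criollo
heterozygous cross segregates 1:2:1 while the Amelonado x Scavina-6
heterozygous selfings lose the Amelonado homozygote class entirely
(0 : 2/3 : 1/3).  Because this elimination is pre-fusion, it adds no
ovule abortion: dissections of selfed and cross-pollinated fruits show
the same ~9–11% background abortion, which the model carries as
`baseline_abortion` (default 0.10).

## Simulation semantics

`simulate_progeny()` draws ovules until the requested number of
fertilized offspring exists.  Each ovule aborts with the baseline
probability, then gametes are drawn at every locus.  One modeling choice
deserves emphasis: a zygote hit by the elimination rule is replaced by a
**fresh draw of the whole gamete pair**, not of the pollen gamete alone.
Redrawing only the pollen gamete conditions on the female allele and
yields a different law (h:b = 3:1 for the elimination selfing); the
full-pair redraw is the rejection-sampling equivalent of drawing
directly from the renormalized conditional distribution, matches
`expected_genotype_distribution()` by construction, and reproduces the
observed 0/77/32-type counts (h:b close to 2:1).  The ovule is still
counted as fertilized, preserving the no-extra-abortion property.

`simulate_mixed_pollination()` adds mentor pollen: each ovule is
pollinated by the mentor with probability `mentor_fraction`; mentor
gametes always fuse but give flat, nonviable embryos.  A fruit is
retained iff its fused-ovule proportion reaches `retention_threshold`
(default 0 — mentor pollination always rescues the fruit, since the
source observations report rescue without quantifying a threshold).
Fused ovules of either parentage count toward retention; viable seeds
are the self-derived ones in retained fruits.

## Segregation scanning

`scan_markers()` tests each marker's a/h/b counts against an expected
ratio (1:2:1 for a selfed F2; the model-conditional 0:2:1 may be passed
to ask "does the distortion fit the SI model" instead of "is it
Mendelian").  The chi-square statistic is restricted to classes with
nonzero expectation; when any expected count drops below 5 an exact
multinomial tail (sum of probabilities of all outcomes no more probable
than the observed one) replaces the asymptotic p.  A nonzero count in a
zero-expectation class is reported as statistic `Inf`, p = 0.  Markers
need 20 non-missing calls to be testable (configurable);
Benjamini–Hochberg q-values control the FDR at `alpha = 0.05`.

`find_absent_runs()` reports maximal runs of consecutive markers with a
genotype class entirely absent, and `delimit_region()` bounds the
candidate region by the nearest *informative* flanking markers — the
closest outside markers where recombinant genotypes of the missing class
exist.  The span is the plain difference of flank positions (1-based bp
as printed; no +1), the convention that reproduces the published 70.3 kb
and 257.270 kb regions exactly.  Markers sharing a printed position are
kept distinct with input order as tie-break; a run touching a chromosome
end is flagged open-ended and measured from its outermost marker.

## The diagnostic screen

The screen formalizes marker-assisted prediction of self-compatibility:

* `combo_screen()` enumerates genotype combinations over 1–3 loci (from
  *observed* genotypes only, carrier count ≥ `min_support`, default 3 to
  avoid degenerate tables), tests each 2×2 carrier-by-status table with
  the exact test, and reports P(SC | carrier) and P(SC | non-carrier).
  These probabilities are the single-indicator logistic MLE, which
  equals the empirical group proportions; when a group is pure the MLE
  sits on the boundary and the row is flagged `separation`.
* `allele_presence_screen()` does the same per allele,
  `allele_dose_fit()` fits P(SC) against 0/1/2 copies by an
  iteratively-reweighted maximum-likelihood logistic fit (tolerance
  1e-8, 100 iterations).  Complete or quasi-complete separation — which
  genuinely occurs for strongly diagnostic alleles — triggers a
  Firth-type bias-reduced fit (Jeffreys-prior penalized score, damped
  steps) and a `separation` flag rather than an error or an infinite
  coefficient.
* The exact test and the logistic engine are implemented in the package
  by direct hypergeometric enumeration and IRLS respectively, because
  they are the computational core of the screening claim;
  `stats::fisher.test` and `stats::glm` serve as independent
  cross-checks in the test suite.  FDR control uses Benjamini–Hochberg
  (via `stats::p.adjust`) by default; a Storey-type pi0-rescaled variant
  is available but not the default, because pi0 estimation is unstable
  at small test counts.

## Synthetic data: what it emulates, and what it does not

`gen_progeny_marker_table()` plants an SI locus under any rule
configuration and derives each marker by per-gamete recombination at its
stated fraction against that locus only.  There is no marker–marker
interference and no full meiosis model: this suffices to reproduce the
fixture's pattern — a zero-count core region with small recombinant
counts (order 1–6) at flanking markers — but it does not emulate
crossover interference or segregation of unlinked background noise.

`gen_association_population()` emulates a diagnostic-screen population:
K subgroups with mixture weights, per-group S-haplotype frequencies
(self-compatibility follows deterministically from the S-genotype via
the same dominance engine as the simulator — one source of truth), and
per-group SSR profiles.  Linkage disequilibrium between one SSR allele
and one S-allele is planted per haplotype: with probability sqrt(r²) the
SSR allele is fully determined by the S-haplotype, otherwise drawn from
the marginal profile.  This yields a haplotype-level squared correlation
of exactly r², *provided* the linked SSR allele's marginal frequency
equals the linked S-allele's frequency within each group; the
constructor enforces this and the default profiles are built to satisfy
it.  Defaults: n = 700 individuals (the scale of the published screen
population), three groups (Amelonado-like 0.35, Criollo-like 0.15,
Trinitario-like 0.50), r² = 0.8.

One caveat the package makes explicit: with subgroups that differ both
in self-compatibility rate and in allele frequencies, a marginal screen
is confounded by structure, and p-values are far from uniform even at
r² = 0.  This is scientifically expected — structure-aware association
(mixed models) is deliberately out of scope here — so the null-behaviour
checks use a single-group population, where r² = 0 implies genuine
marker–phenotype independence.  Passing screens on these synthetic
populations therefore demonstrates calibration and recovery under the
stated LD model, not robustness to population structure, genotyping
error, or null alleles in real SSR data.

## qPCR quantification

`relative_expression()` implements the comparative-Ct method: per
replicate, dCt = Ct_target − mean(Ct_references) (arithmetic mean of
reference Ct, i.e. geometric mean of linear quantities; the averaging
rule is this package's choice), then fold = 2^−(dCt_sample −
dCt_calibrator).  With per-gene amplification efficiencies the
efficiency-corrected form E_target^−dCt / geomean(E_ref^−dCt) is used,
which reduces to 2^−ddCt exactly when every E = 2.  Pooled time windows
are treated as single conditions.  For differential expression between
replicate sets the default is an exact permutation test on mean
log-fold (all C(6,3) = 20 assignments at 3+3 replicates, so the
attainable minimum is 0.1); a categorical mode that dichotomizes
replicates at fold 1 and applies the exact test is kept as an option,
since the source material names an exact test without describing its
contingency construction — the ambiguity is recorded here rather than
resolved.

## Numerical choices and problem sizes

* Two-sided exact-test p: sum of hypergeometric probabilities ≤ the
  observed table's, with relative tolerance 1e-7 on the comparison.
* Exact multinomial tails are enumerated vectorized in log space.
* IRLS: tolerance 1e-8, max 100 iterations; separation declared on
  non-convergence or |coefficient| > 15.  Firth: tolerance 1e-6, max
  200 iterations, steps damped to length 5.
* Fully incompatible crosses raise an explicit error ("fully
  incompatible cross") rather than renormalizing an empty law; the
  simulator's gamete redraw is bounded (1000 vectorized rounds).
* Every stochastic function takes a required `seed`; no global RNG
  state is relied upon, and generators are bit-reproducible per seed.
* The test suite runs simulations at n = 10 000 with 100 seeds for the
  simulator-consistency checks and 100 populations of n = 700 for
  screen recovery — the sizes at which the binomial tolerances quoted
  in the tests are meaningful.

## Known limitations

* No molecular mechanism (pollen-tube kinetics, protein interactions),
  no QTL mapping, no S-genotype inference from sequence.
* No linkage-map construction or recombination-fraction estimation; the
  scanner takes map positions as given.
* No structure-corrected association testing; see above.
* Allele frequencies are plain copy-count proportions with no
  null-allele or inbreeding correction (the reference varieties are
  fully homozygous, making such corrections moot for their intended
  use).

One further calibration note: a single screen's p-values are mutually
correlated (the tests share individuals, and allele-presence indicators
within a marker are constrained), and two-sided exact-test p-values are
slightly conservative (null mean a little above 0.5).  Calibration
checks in the test suite therefore assess uniformity on independent
draws: one null p-value per simulated population.
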