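# cacaoSI

Genetic analysis of the late-acting self-incompatibility (LSI) system of
cacao (*Theobroma cacao*), for geneticists and breeders working on
marker-assisted selection of self-compatible trees.

Cacao self-incompatibility is expressed late, at the embryo sac: pollen
tubes reach the ovary, but in incompatible combinations gamete fusion
fails in part of the ovules and the fruit drops.  Genetically the system
behaves as two independent loci:

* a **gametic fusion-failure locus** (on chromosome 4): an ovule's gamete
  pair (female allele *f*, male allele *m*) fails fusion iff
  *f* = *m* = *s* for a specificity *s* expressed in both parents.  Which
  specificities a diploid genotype expresses follows a sporophytic
  dominance series — S0 = S1 > S2 = S3 > *Sf* > S4 > S5, with *Sf* the
  amorphous Amelonado allele — so selfings show 25%, 50% or 100% unfused
  ovules, and survivors of an *Sf*/active selfing segregate
  a:h:b = 1/3 : 2/3 : 0;
* a **zygotic pre-fusion elimination locus** (on chromosome 1): zygotes
  homozygous for a target allele are eliminated when an activator allele
  (the Scavina-6 type) is present in the parents, giving 0 : 2/3 : 1/3
  segregation with *no* extra ovule abortion.

The package provides: an executable formalization of this model and a
forward simulator of selfings, crosses and mentor-pollen pollinations
(`si_model()`, `simulate_progeny()`, `simulate_mixed_pollination()`); a
segregation-distortion scanner that finds absent-genotype runs in progeny
marker tables and delimits candidate regions by informative flanking
markers (`scan_markers()`, `find_regions()`); the diagnostic SSR-marker
screen — exact tests with FDR control, conditional probabilities
P(SC | genotype), and allele dose–response fits with Firth fallback under
separation (`combo_screen()`, `allele_presence_screen()`,
`allele_dose_fit()`); group allele frequencies and variety-specific
alleles (`allele_frequencies()`, `specific_alleles()`); comparative-Ct
qPCR quantification (`relative_expression()`); and synthetic-data
generators for every input (`gen_progeny_marker_table()`,
`gen_association_population()`, `gen_ct_table()`).  A thin CLI
(`si_cli()`, `inst/scripts/cacaosi.R`) drives the pipeline from a shell.

## Worked example

Scan the bundled F2 segregation table (selfed TSH 516, a/h/b counts per
SSR marker on the two incompatibility regions) and delimit the
chromosome-4 region:

```r
library(cacaoSI)
tab  <- counts_to_marker_table(f2_segregation_counts())
scan <- scan_markers(tab, "1:2:1")
head(scan[scan$chrom == "CH4", c("marker","pos","n_a","n_h","n_b",
                                 "statistic","q","distorted")], 4)
#>   marker   pos n_a n_h n_b statistic            q distorted
#>  mSI_462  1414 222 425   2  211.4037 4.587416e-46      TRUE
#>  mSI_466  4737 191 385   0  192.0104 4.408454e-42      TRUE
#>  mSI_474 10127 198 380   0  192.9619 3.013414e-42      TRUE
#>    mSI_7 20673 259 488   0  249.8032 4.560490e-54      TRUE
```

Every marker at the top of chromosome 4 rejects the Mendelian 1:2:1 ratio
(q far below 0.05), and the homozygote class `b` is entirely absent over a
run of consecutive markers:

```r
reg <- delimit_region(find_absent_runs(tab, "b"), tab)
#> region: CH4 class-b absent, mSI_466..mSI_535,
#>         flanked by mSI_462/mSI_411, span 257.270 kb
```

The span is measured between the nearest flanking markers that still show
recombinant `b` genotypes; the chromosome-1 scan likewise yields the
70.3 kb region flanked by mSI_103/mSI_375.  The model predicts the
distortion analytically:

```r
expected_genotype_distribution(
  cross_spec(mother = list(CH4 = c("Sf", "S_sca"))), si_model())$CH4$ahb
#>      a      h      b
#> 0.3333 0.6667 0.0000
```

Screen a synthetic 700-tree association population for diagnostic
alleles (the generator plants the mSI_460-161 allele in LD with *Sf*,
r² = 0.8):

```r
pop <- gen_association_population(assoc_pop_config(n = 700), seed = 1)
res <- allele_presence_screen(pop$ssr, pop$phenotype)
head(res[, c("marker","allele","n_present_sc","n_present_si","p","q")], 3)
#>   marker allele n_present_sc n_present_si            p            q
#>  mSI_460    161          328          170 1.054968e-62 4.641859e-61
#>  mSI_460    145           36          202 2.811256e-37 6.184762e-36
#>  mSI_460    155           42          172 8.440695e-24 1.237969e-22

round(allele_dose_fit(pop$ssr, pop$phenotype, "mSI_460", 161)$prob_sc, 3)
#>     0     1     2
#> 0.016 0.385 0.960
```

The planted allele ranks first by q, and the dose–response fit shows the
probability of self-compatibility rising from 1.6% (no copy) to 96%
(homozygous) — the pattern used to select SC trees from marker data
alone.

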