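---
title: "Scanning pedigreed populations for recessive lethal haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning pedigreed populations for recessive lethal haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lethalscan)
```

## The problem and the model

A fully recessive lethal allele is invisible in the animals that can
be genotyped: carriers are healthy, and homozygotes die before (or
shortly after) birth. In a closed, intensively genotyped breeding
population the allele nevertheless leaves two footprints:

1. **Missing homozygosity.** A marker haplotype in strong linkage
   with the lethal allele is carried by many live animals, yet no (or
   almost no) live animal is homozygous for it.
2. **Depressed fertility of carrier matings.** When both parents
   carry one copy, one quarter of the fetuses are homozygous and die
   — reducing total number born (TNB) when death is early, or
   producing mummified fetuses (MUM) when death occurs mid-gestation,
   because a fetus that dies after skeletal calcification is not
   resorbed but desiccates and is expelled at farrowing with its
   surviving littermates.

`lethal_scan()` formalises footprint 1. Phased haplotypes are
enumerated in sliding windows of 0.5, 1, 2 and 4 Mb (each grid
sliding by half a window), and every haplotype with frequency
strictly above 0.5 % is tested. The expected number of homozygous
offspring comes from genotyped parent–offspring trios by the
transmission-product rule: an offspring whose sire and dam carry
$c_s$ and $c_d$ copies contributes $(c_s/2)(c_d/2)$, so

$$E \;=\; \sum_{\text{offspring of carrier} \times \text{carrier trios}} \frac{c_s}{2}\,\frac{c_d}{2},$$

which is $n/4$ when all carrier parents are heterozygous. The
observed count $O$ is taken over **all** phased animals, not only
trio offspring — homozygotes outside genotyped trios are still
evidence — and a two-sided exact binomial test of $k = \min(O, n)$
out of $n$ trials with null success probability $E/n$ yields the
p-value. A haplotype is classified **MH** (missing homozygosity)
when $O = 0$ and $P < 5\times10^{-3}$, and **DH** (deficit of
homozygotes) when $O > 0$ and $P < 5\times10^{-6}$. The asymmetric
thresholds reflect that a total absence of homozygotes is a much
sharper signature than a shortfall.

The two-sided p-value uses the *point-probability* convention: all
outcomes whose point probability does not exceed that of $k$ (up to
a relative tie tolerance of $10^{-7}$) are summed, in log space.
This convention — not a doubled one-sided tail — is what reproduces
reference values such as $P(k{=}0, n{=}75, p{=}0.25) =
5.70\times10^{-10}$; a one-sided tail gives $4.26\times10^{-10}$.

Footprint 2 is quantified by `classify_matings()` and
`trait_effect()`: litters are classed C×C (both parents carry at
least one copy), C×NC (exactly one does), NC×NC, or unknown (a
parent ungenotyped or with undetermined phase in the window), and
C×C is contrasted against C×NC by class means, signed percent
difference $100(\bar{x}_{C\times C}-\bar{x}_{C\times
NC})/\bar{x}_{C\times NC}$, and a two-sided Welch t-test. C×NC — not
"all other litters" — is the comparison class because it shares the
carrier parent's genetic background while being unable to produce
homozygous fetuses. A composition chi-square (`ratio_chisq()`) on
the summed MUM/NSB/NBA counts, built from integer totals rather than
products of means, tests the overall shift, and
`het_carrier_fraction()` checks the Hardy–Weinberg footprint: among
surviving offspring of het × het matings a fully lethal haplotype
leaves a 2:1 ratio of heterozygotes to non-carriers, so the
heterozygous fraction tends to 66.7 % instead of 50 %.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `window_sizes` | 0.5, 1, 2, 4 Mb | doubling grid covering typical tag-haplotype lengths; smaller windows risk non-unique haplotypes, larger ones recombinants |
| `step_factor` | 0.5 | slide step as fraction of window size |
| `min_freq` | 0.005 | haplotype frequency retained (strict >); per window, per population |
| `mh_alpha`, `dh_alpha` | 5e-3, 5e-6 | classification thresholds (fixed, no genome-wide correction) |
| `null_p` | `NULL` (= `E/n`) | binomial null; equals 0.25 in the all-heterozygous case |
| `maf_min`, `marker_callrate_min` | 0.01, 0.85 | strict marker filters, MAF computed per marker on its non-missing calls |
| `animal_max_missing` | 0.30 | strict animal filter, applied after marker filters |

QC order is fixed — chromosome/position filters, then marker call
rate and MAF, then animals — because marker removal changes
per-animal missingness; running the filters twice changes nothing
(they are idempotent). Duplicate map positions keep the first marker
by input order. Windows are anchored at coordinate 0 of each
chromosome, which makes the grid reproducible across runs and
populations; abutting windows are half-open `[start, start + w)` so
they do not overlap.

Degenerate inputs are handled explicitly: haplotypes with no
carrier × carrier trio progeny are flagged `not_testable`; animals
with missing phase anywhere in a window are excluded from that
window's frequency denominator, from $O$, and from trio products
(no haplotype is fabricated from partial phase); when $O > n$ the
statistic is capped at $n$ and the record carries a note. In
`collapse_loci()` overlapping significant windows form loci by
transitive base-pair overlap and the lowest p-value wins, with ties
broken by smaller window then leftmost start — fully deterministic.

## What the simulator emulates

`sim_population()` gene-drops founder haplotypes through a closed
breeding line with discrete generations: a founder pool of
haplotypes (default 40) over a biallelic map, random mating of the
configured boars and sows, litter sizes Poisson(λ = 16 conceived,
truncated at one) so that total-born means land in the low teens
after losses — the scale of commercial sow lines — and one
recombination per Morgan (default 1 cM/Mb, uniform, no hotspots).
An embedded lethal haplotype is planted on a prescribed fraction of
founder chromosomes (at most one copy per founder), and every
conceived fetus homozygous for the lethal *founder label* across the
lethal window dies with the configured penetrance at the configured
stage: `early` (resorbed, never recorded), `mid_gestation`
(mummified), or `stillbirth`. Baseline mummification (1 %) and
stillbirth (5 %) rates apply to the surviving fetuses. Offspring are
genotyped at a configurable fraction, with their parents always
genotyped when trio enrichment is on (emulating the trio-rich
structure of livestock genomic-selection panels), and missing calls
are injected at a configurable rate. By default mummies are *not*
counted inside TNB, so TNB = NBA + NSB; the alternative convention
is a flag (`mum_in_tnb`), because farms record this inconsistently.
Everything derives from one seed; identical configurations give
byte-identical output.

The staged functions `build_pedigree()`, `gene_drop()`,
`apply_lethality()`, `emit_markers()` and `make_litters()` expose
the same machinery piecewise under neutral demography; in the
integrated simulator, each generation's breeding animals are drawn
from the *survivors* of the previous one, since a dead fetus cannot
breed.

Two realistic features of the generator deserve emphasis because
they bound what a passing test demonstrates. First, the lethal
haplotype's *marker string* is an imperfect tag of the lethal
*label*: a crossover inside the window can produce a chromatid that
matches the string over all window markers without carrying the
lethal, and a live animal homozygous for the string then moves the
record from MH to DH — the same incomplete-LD effect that makes
neighbouring haplotypes in real data show a handful of homozygous
carriers. Second, what the generator does **not** model: array
ascertainment bias, genotyping error beyond missingness,
recombination hotspots, selection on other traits that shapes which
piglets get genotyped, and farm-level under-recording of mummies.
Tests passing on synthetic data therefore show that the statistics
recover a planted signal under idealised sampling, not that every
real-data complication is handled.

## Runs of homozygosity

`roh_segments()` reports, per animal and chromosome, every maximal
marker stretch containing at most one heterozygous call, with at
least 20 markers and a span of at least 1 Mb (all configurable;
missing calls neither break a run nor count as heterozygous, with
an optional cap). These are *maximal-interval* semantics: the three
constraints fully determine the answer, and a segment cannot be
extended by one marker without violating a constraint. This is a
deliberate dialect difference from scanning-window ROH callers,
whose additional window parameters would otherwise have to be
guessed; results are deterministic and oracle-checkable by
exhaustive enumeration.

## Study sizes used in the validation suite

The packaged tests validate parameter recovery with a planted
mid-gestation lethal at frequency 0.10 and full penetrance in a
line of 40 boars × 175 sows bred for two generations (≈ 4,900
genotyped trio offspring, ≈ 350 litters) over a 20 Mb chromosome
carrying 500 markers — the marker density of an 80 K genome-wide
panel, giving 25 markers in the planted 1 Mb window. This size was
chosen so that a replicate typically contains on the order of a
hundred carrier × carrier progeny: enough that the exact binomial
test can clear the MH threshold (which needs at least 19 such
progeny) in essentially every replicate, while keeping a 50-replicate
recovery experiment at desk scale. Null calibration uses the same
design with no lethal planted, yielding several thousand testable
haplotypes per scan.

## Known limitations

* The scan tests each haplotype marginally with fixed thresholds;
  there is no genome-wide multiple-testing correction, by design.
* Expected counts come from genotyped trios only, so $E$
  underestimates the population-wide expectation; the $\min(O, n)$
  guard handles the resulting boundary case but the test is
  conservative.
* Trait contrasts are plain Welch tests; parity, farm and seasonal
  structure are not modelled, and repeated litters of one sow are
  treated as independent observations (as the mating counts in
  routine livestock data imply).
* Phasing and imputation are upstream of this package: the input is
  an already-phased VCF, and phase errors translate into haplotype
  noise the scan cannot distinguish from recombination.
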