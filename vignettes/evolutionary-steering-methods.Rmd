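---
title: "Models and methods for steering barcoded tumour-cell evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for steering barcoded tumour-cell evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evosteer)
```

## The experimental system this package models

A lung-adenocarcinoma cell population (HCC827) is tagged with ~10^6
ClonTracer-style lentiviral barcodes — 30-bp semi-random sequences that
alternate weak (A/T) and strong (G/C) bases — so that every founder cell
carries a unique, heritable label. The barcoded pool (the *POT*) is
expanded and split into replicate flasks: two DMSO controls, three flasks
treated with gefitinib (an EGFR inhibitor, 4 weeks) and three with
trametinib (a MEK inhibitor, 9 weeks). Because dying cells detach into the
medium, weekly media changes yield "floating" barcode samples that trace
the population's composition through time without disturbing the culture.
Deep amplicon sequencing of barcodes before and after treatment reveals
which lineages were pre-existing drug-resistant subclones, which were
sensitive, and how fast each grew under each drug — the quantitative basis
for *evolutionary steering*: choosing drug sequences that drive the
population toward collaterally sensitive states.

`evosteer` implements the computational side of this design as reusable,
tested components: stochastic simulators of the cell-growth processes, the
barcode-sequencing inference pipeline, post-variant-calling copy-number
statistics, drug-screen analytics, and a synthetic-data generator that
emulates the whole experiment so every stage can be validated end to end
against a known ground truth.

## Stochastic simulators

### Re-plating waiting times

In a standard re-plating experiment a culture is repeatedly grown from
$N_0$ to $N_{\max}$ cells and cut back. Each division creates a resistant
cell with probability $\mu$, so one expansion performs $N_{\max} - N_0$
divisions and

$$E(\#\text{mutants}) = \mu\,(N_{\max} - N_0) \times \text{replatings}.$$

With the defaults $\mu = 2\times10^{-8}$ (about 20 distinct
resistance-conferring point mutations at a per-bp rate of
$1\times10^{-9}$), $N_0 = 2\times10^6$ and $N_{\max} = 4\times10^7$, one
cycle yields 0.76 expected mutants. `simulate_replating_waiting_times()`
draws the cycle of first resistance from the exact per-cycle law
$P(\text{mutation in a cycle}) = 1-(1-\mu)^{N_{\max}-N_0}$ and places the
first mutant division inside the cycle by inverting its conditional
(truncated geometric) distribution, mapping division index to clock time
through the exponential growth curve. This is exact in distribution for
the first-occurrence time while running $10^4$ simulations in
milliseconds; a cell-by-cell Gillespie bookkeeping of $3.8\times10^7$
divisions per cycle would add nothing but cost. A `max_cycles` cap guards
$\mu = 0$; capped runs are returned as censored rather than silently
dropped.

### POT outgrowth and the 8-way split

`gillespie_birth_death()` is an exact event-driven simulation of linear
birth–death growth (rates $b\,n$ and $d\,n$, exponential waiting times),
with the event loop in compiled code driven by R's RNG stream so
`set.seed()` governs reproducibility. The default rates $b = 0.032$,
$d = 0.002$ per cell per hour are the published HCC827 values at 20%
oxygen and 2 g/L glucose.

`simulate_pot_split()` grows each founder lineage from one cell for
`t_grow` hours, discards extinct lineages (about $d/b = 6.25\%$), pools
the survivors, and performs a random *equal-size* split into 8 replicates
by permuting the physical cells — a multivariate hypergeometric split,
exactly matching how cells are physically distributed. The quantity of
interest is the fraction of surviving barcodes present in exactly $k$ of
8 replicates.

An analytic oracle accompanies the simulator:
`occupancy_distribution_exact(n, R)` gives, by inclusion–exclusion over
multinomial placement,

$$P(k \mid n) = \binom{R}{k}\sum_{j=0}^{k}(-1)^j\binom{k}{j}
\Big(\frac{k-j}{R}\Big)^{n},$$

and `occupancy_mixture_exact()` averages this over the realised clone
sizes. Every simulator run carries its own oracle values and Monte Carlo
standard errors, and the test suite requires agreement within 3 SE at
every $k$.

**Choice of outgrowth duration.** A surviving lineage of a supercritical
birth–death process started from one cell has a geometric size
distribution, so the occupancy fractions depend on the outgrowth only
through the mean surviving clone size. Published figures for this design
report ~90% of surviving barcodes in 8/8 replicates, 4% in 7/8 and 2% in
6/8, and separately describe the POT as holding roughly 150–200 cells per
barcode. The analytic mixture shows that a mean surviving size of 150
cells gives 87.2 / 4.7 / 2.5 — outside the reported occupancy — whereas a
mean of ~190 cells gives 89.8 / 3.8 / 2.0, matching it. Since the
occupancy triplet is the sharper constraint, the default
`t_grow = 173` h is calibrated (via the closed form, not by fitting to
simulation output) so that surviving lineages average ~190 cells, at the
upper end of the stated per-barcode range. The duration is an explicit
`sim_design()` field for users who want other regimes.

## The synthetic experiment generator

`simulate_experiment()` produces every input the inference consumes, with
a known truth table. Its defaults are the study's printed conditions:

* Three pre-existing resistant subclones at POT frequencies 2.4%
  (gefitinib-resistant), 0.91% (double-resistant) and 0.57%
  (trametinib-resistant) — together 3.88% of the POT, printed as 3.9% —
  with the remainder a drug-sensitive background.
* Per-condition clone growth rates (per week) derived from the pooled
  frequencies the clones reach at harvest: 32.8% and 22.4% for the
  gefitinib-resistant and double-resistant clones after 4 weeks of
  gefitinib; 86.1% and 4.2% for the double- and trametinib-resistant
  clones after 9 weeks of trametinib. The small cross-arm finals (0.1%,
  0.2%) and the sensitive remainders (44.7%, 9.5%) are set so each arm's
  final frequencies sum to one. This makes the planted rate of every
  clone equal the realised log-frequency slope of its barcodes — so the
  growth-rate estimator has a well-defined truth to recover.
* Replicate flasks seeded with 12 million cells (multinomial sampling of
  the POT — pure drift, as in the DMSO controls), sequencing censuses of
  3×10^5 reads (the lower end of the study's 300,000–600,000× depth),
  4- and 9-week drug exposures with weekly floating samples.
* A default of 2,000 founder lineages rather than 10^6 — frequencies,
  depths and cell counts keep their real-data scales while each barcode
  remains deeply covered; the lineage count is the one deliberately
  scaled-down quantity, chosen to keep a full synthetic run in seconds.

Within a drug replicate, barcode frequencies follow their clone's
deterministic exponential expectation between censuses, and stochasticity
enters at the physically-sampled points: the POT outgrowth
(per-lineage birth–death), replicate seeding (multinomial), and
sequencing (multinomial at census time). A full agent-based simulation of
every division under drug would only add variance the estimator cannot
distinguish from sampling noise; the estimator's behaviour is what the
generator exists to test. Dying cells accumulate within each week in
proportion to current frequency times a per-clone death weight
(drug-resistant clones contribute weight 0.3 under their drug, sensitive
clones 1), and are flushed into that week's floating census — matching
the weekly media-change protocol. One barcode per cell is assumed
throughout (the study estimates <1% doubly-barcoded cells).

Reads are emitted as Phred+33 FASTQ: forward flank + barcode + reverse
flank (the fixed 12-mers bracketing the barcode in the published 80-bp
amplicon), multinomial read counts, independent per-base substitution
errors, and a configurable fraction of reads carrying exactly one base at
Q = 20 — the boundary case of the strict "all bases above Q20" filter.

What the generator does *not* emulate: PCR amplification bias and
chimeras, indels, read-quality correlation along the read, batch effects
between samples, and cell-state plasticity (persistors). Passing
end-to-end tests therefore demonstrates correctness of the inference
under the stated noise model, not robustness to every artefact of real
libraries.

## Barcode inference

`read_and_filter_fastq()` keeps reads whose every base is strictly above
Q20, then extracts the 30-mer between exact flank matches.
`merge_barcodes()` implements error correction by Hamming distance:
pattern-conforming sequences act as representatives; every non-conforming
barcode merges into its nearest representative within `max_hamming`
(default 2 — at per-base error below 0.5%, three or more errors in a
30-mer are rare), and a conforming barcode merges into a strictly more
abundant representative in range, because roughly one substitution in
three preserves the weak/strong class of a base and therefore produces a
pattern-valid error sequence. Equidistant ties resolve to the more
abundant (then lexicographically first) representative; merging conserves
total counts; unmergeable non-conforming barcodes are kept and flagged
rather than dropped.

Growth inference follows the study's estimator exactly. The baseline
frequency of a barcode is the conservative maximum over the two DMSO
controls, $f_0 = \max(f_{D7}, f_{D8})$, and its growth rate in a treated
replicate harvested after $T$ weeks is

$$r = \frac{1}{T}\,\ln\frac{f_R}{f_0},$$

with $T = 4$ for gefitinib and $T = 9$ for trametinib. A barcode absent
from a treated census gets $r = -\infty$ (extinction is evidence of
negative growth, not missing data); a barcode absent from both DMSO
controls has no baseline and is classed UNDETERMINED. Phenotypes follow
the positivity rules in order: positive in ≥1 GEF and ≥1 TRM replicate →
double-resistant; ≥2 GEF and no TRM → gefitinib-resistant; ≥2 TRM and no
GEF → trametinib-resistant; exactly one positive replicate → putative de
novo; otherwise sensitive. "Positive" means $r > 0$ strictly, with no
minimum-frequency filter by default (a configurable threshold exists in
the reporting layer only). Barcodes are grouped into "functional
subclones" by complete-linkage hierarchical clustering of their
per-replicate rate vectors with a configurable cut height — the grouping
method is not specified in the source protocol, and complete linkage is
the natural choice when the claim is that *all* members share dynamics.

## Copy-number statistics

`compute_baf_lrr()` uses SNPs with global minor allele frequency in
[0.1, 0.2] and position ≥ 100 kb: major allele frequency = highest base
count / coverage; BAF = that value or its complement with probability ½
(emulating random A/B assignment); LRR = log2 coverage centred on its
global median. `segment_signal()` is a simplified recursive change-point
routine (maximal pooled-variance t statistic, accepted above a
threshold) — deliberately not a bit-exact CBS clone; externally computed
segments can be passed through for exact reproduction of a published
segmentation. Note that LRR alone cannot see a copy-neutral LOH boundary
(equal totals, e.g. (2,1)|(3,0)); such boundaries must come from the
external path or from BAF-aware downstream handling.

`test_segment_heterozygosity()` counts SNPs with major AF < 0.9 and runs
the one-sided exact binomial test against a 5% null at α = 0.05; for
heterozygous segments the median major AF over heterozygous SNPs
summarises allelic imbalance, and LOH segments use major-allele fraction
1 downstream.

`solve_ploidy()` fixes purity at 1 (cell lines) and grid-searches ψ over
[1.5, 5.5] in 0.01 steps: total copy = ψ·2^LRR (a depth-proportional
signal, i.e. platform gamma = 1), major = mBAF·total, and the SNP-weighted
squared distance of (major, minor) to their nearest integers is
minimised. Because LRR is median-centred, ψ is identifiable exactly when
the median-coverage locus carries a copy number equal to the ploidy —
true for genomes that are mostly at their modal ploidy (the intended use
case) and for the balanced synthetic profiles used in the tests; a
profile composed only of above-ploidy segments shifts the median and
biases ψ upward. Segment weighting by SNP count is the default
(`weighted = FALSE` reproduces an unweighted "all segments" reading).
Depth-ratio calls use exclusive thresholds: gain above 1.2, loss below
0.8.

## Drug-screen analytics

Percent inhibition converts plate fluorescence through the 14 drug-free
and 14 empty control wells: $\mathrm{PCI} = 100\,(c_{pos} - I)/(c_{pos} -
c_{neg})$. Hit calling ranks compounds by mean PCI change versus the
control line separately per concentration and replicate, excludes changes
below 5 points, keeps the top six (boundary ties all kept and flagged),
and calls compounds appearing in more than one list. Dose–response uses
the two-parameter log-logistic curve $y = 100/(1 + (x/\mathrm{ec50})^{h})$
with asymptotes fixed at 100 and 0, fitted by Levenberg–Marquardt least
squares on log(ec50) with ec50 bounded to [min dose/100, max dose×100]
and started at the dose nearest 50% response. Flat (no-inhibition) data
are flagged non-identifiable with ec50 at its bound rather than fitted.
`ic50_fold_change()` reports EC50 ratios between fits.

## Reproducibility and numerical choices

* One master seed per pipeline run spawns per-stage sub-seeds
  deterministically (`run_config()`); reruns are bit-identical.
* Census frequencies always sum to 1 within 1e-9; merging conserves read
  counts exactly; occupancy tables sum to 1.
* Monte Carlo checks in the tests compare against closed-form oracles at
  3 standard errors; exact quantities (binomial tails, PCI identities,
  noiseless fits) are checked to numerical precision.
* Problem sizes in the tests — 10^4 lineages and 10 splits for occupancy,
  10^4 waiting-time simulations, 2,000 lineages at 3×10^5 reads for the
  end-to-end run, 100 noisy dose–response curves — are the package's
  chosen defaults for a laptop-scale validation of the study-scale
  conditions.

## Worked example

```{r example, eval = FALSE}
library(evosteer)

# occupancy of barcodes across the 8 replicate flasks
res <- simulate_pot_split(sim_design(n_lineages = 10000, n_splits = 10),
                          seed = 1)
print(res)

# full synthetic experiment -> reads -> censuses -> phenotypes
report <- run_synthetic_end_to_end(run_config(seed = 1))
print(report)
print(report$confusion)
```

## Known limitations

* The barcode merge is a principled reconstruction of the published
  description, not the original (unpublished) implementation; absolute
  barcode counts from the real libraries are therefore not reproducible
  here, and only merge-invariant quantities (frequencies of abundant
  barcodes, growth rates, phenotypes) should be compared.
* Ploidy estimation inherits the median-normalisation identifiability
  condition described above.
* The segmentation routine targets clear steps (≥ ~3 SD); subtle or
  focal events should use externally supplied segments.
* Growth rates assume frequencies large enough that a handful of reads
  do not dominate; `min_f0` filters are available in the reporting layer
  for low-abundance barcodes.
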