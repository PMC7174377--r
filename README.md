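# evosteer

Stochastic models and inference for **evolutionary steering** of barcoded
tumour-cell populations.

## The problem

Drug resistance in cancer is often driven by rare pre-existing subclones.
If those subclones can be identified and their growth rates under
different drugs measured, therapy can be *sequenced* so that selection
itself pushes the population toward a drug-sensitive, collaterally
vulnerable state. The experimental design this package supports tags
~10^6 cells with unique 30-bp lentiviral barcodes (weak/strong alternating
bases), expands the pool (the POT), splits it into replicate flasks
treated with gefitinib, trametinib or DMSO, and reads barcode frequencies
by deep amplicon sequencing — including weekly "floating" samples of dead
cells recovered from spent media, which trace clonal dynamics through
time.

`evosteer` provides, as tested R functions:

* **Evolution simulators** — expected resistant-mutant counts
  `E = mu (Nmax - N0) x replatings`; waiting times to first resistance
  under serial re-plating; exact Gillespie birth–death growth
  (compiled core); the POT-outgrowth + random equal 8-way split, with an
  exact inclusion–exclusion occupancy oracle
  `P(k | n) = C(R,k) sum_j (-1)^j C(k,j) ((k-j)/R)^n`.
* **Barcode processing** — strict all-bases-above-Q20 FASTQ filtering,
  flank-anchored barcode extraction, Hamming-distance error merging onto
  weak/strong-conforming representatives.
* **Clonal inference** — conservative baselines `f0 = max(fD7, fD8)`,
  growth rates `r = (1/T) ln(fR / f0)` (T = 4 weeks gefitinib, 9 weeks
  trametinib), resistance-phenotype assignment from replicate positivity
  rules, floating-sample trajectories, log-linear growth-curve fits.
* **Genomic profiles** — 10x VAF-enrichment filtering, BAF/LRR from
  allele counts, change-point segmentation, exact binomial
  loss-of-heterozygosity testing, ASCAT-style ploidy grid search
  (rho = 1, psi in [1.5, 5.5]), depth-ratio gain/loss calls (>1.2 / <0.8).
* **Pharmacology** — plate percent-inhibition
  `PCI = 100 (cpos - I)/(cpos - cneg)`, top-six recurrent hit calling,
  two-parameter log-logistic dose–response fits and EC50 fold changes.
* **Synthetic data** — a generator that emulates the full experiment
  (pre-existing resistant clones at 2.4% / 0.91% / 0.57% of the POT,
  replicate seeding, selection, floating compartments, FASTQ reads with
  errors, SNP allele counts with known copy numbers, screening plates
  with 14+14 control wells) so every pipeline stage is testable against
  a known truth.

## Worked example

```r
library(evosteer)

# How representative is each replicate flask of the barcoded pool?
res <- simulate_pot_split(sim_design(n_lineages = 10000, n_splits = 10),
                          seed = 1)
print(res)
#> Replicate occupancy of surviving barcodes
#>   surviving lineages: 9372 (mean size 189.3 cells)
#>  k empirical  exact    se
#>  6     1.993  2.038 0.046
#>  7     3.848  3.689 0.063
#>  8    89.649 89.735 0.100     (abridged)
```

About 90% of barcodes that survive the POT outgrowth end up in all eight
replicates (4% in 7/8, 2% in 6/8), so rare pre-existing clones are seen
by every treatment arm — the premise that makes cross-replicate phenotype
calls meaningful. The `exact` column is the analytic occupancy oracle
evaluated on the same simulated clone sizes; `empirical` agrees with it
within Monte Carlo error.

```r
# Full chain: simulate -> FASTQ -> extract/merge -> infer -> score
report <- run_synthetic_end_to_end(run_config(seed = 1))
print(report)
#> Synthetic end-to-end steering report
#>   barcodes scored (f0 >= 0.0001): 1605
#>   phenotype recovery: 100.0%
#>   growth-rate RMSE: 0.0449 per week
#>   pooled resistant POT frequency: 0.0388
```

All barcodes with baseline frequency at least 1e-4 are assigned their
planted phenotype, per-replicate growth rates are recovered to within
0.045/week at a sequencing depth of 3x10^5 reads, and the pooled
frequency of planted resistant barcodes in the POT is 3.9%.

## Documentation

The methods vignette
(`vignettes/evolutionary-steering-methods.Rmd`) describes the models and
their assumptions, the synthetic generator's defaults and what they
emulate, numerical choices (tolerances, tie-breaks, degenerate inputs)
and known limitations.
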