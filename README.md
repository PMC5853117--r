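# divshift

Diversification tempo and host-shift dynamics in densely sampled
DNA-barcode radiations.

Tropical herbivorous insect radiations are often sampled as thousands of
mtCOI barcodes attached to rearing records (host plant species, host tissue,
collection region). `divshift` turns such data into a reproducible analysis
of **when lineages formed and what changed when they did**:

1. **Lineage delimitation** — raw pairwise differences, a neighbor-joining
   guide tree, and the finest monophyletic partition in which lineages are
   separated by ≥ 3 substitutions (0.5% of a 504-bp barcode), with explicit
   rules for surviving ancestral haplotypes; species-level clusters at < 4%
   divergence (single linkage) and medoid exemplars.
2. **Character coding & ancestral states** — per-lineage state frequencies
   from specimen records; polymorphic (≥ 5%), predominant (within 0.2 of the
   modal frequency) and simplified (modal) codings; Fitch parsimony with
   deterministic ACCTRAN/DELTRAN resolutions; Mk-model stochastic character
   mapping with the observed frequencies as tip priors.
3. **Split–shift tallies** — every lineage split classified as old/young
   around a 3 Ma breakpoint and shift/no-shift per character (host ∨ tissue
   composite = "host shift"), under parsimony and across stochastic maps,
   with a row-shuffle permutation test of
   `D = P_old − P_young`.
4. **Diversification analysis** — lineage-through-time profiles; the
   Pybus–Harvey gamma statistic
   `γ = [ (1/(n−2)) Σ T_i − T/2 ] / [ T √(1/(12(n−2))) ]`
   with two-tailed and one-tailed p-values; maximum-likelihood fits of pure
   birth (`λ̂ = (n−2)/T`), birth–death (Nee crown-conditioned, net rate `r`
   and extinction fraction `a`), logistic (`λ_k = r(1 − k/K)`, DDL) and
   exponential (`λ_k = r k^−x`, DDX) density dependence compared by AIC;
   1 Ma tree truncation; and a simulate–prune–compare procedure for
   sensitivity to missing taxa.
5. **Synthetic data** — a generator producing trees, era-dependent character
   histories with logged shift events, polymorphic specimen tables, and
   Jukes–Cantor barcode alignments, with full ground truth, so the whole
   pipeline is testable end to end.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
synthetic radiation shaped like the target study (115 lineages, 13 Ma
crown, host shifting that collapses after 3 Ma, era-constant dispersal):

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_delimit_lineages.R
Rscript analysis/03_ancestral_states.R
Rscript analysis/04_shift_tallies.R
Rscript analysis/05_diversification.R
```

Stage 2 recovers the simulated lineages from the barcodes alone:

```
  haplotype lineages (>= 3 mutations apart): 111
  species clusters (< 4% divergence): 48
  excluded ancestral haplotypes: 3
```

(111 of 115 true lineages — the youngest simulated splits have not yet
accumulated three substitutions, exactly the behavior the 0.5% threshold
trades away.)

Stage 4 finds the planted temporal asymmetry in host use and its absence
for region, and the permutation test rejects the shuffle null outright:

```
    character old_shift old_total young_shift young_total p_old p_young      D
 host_species        12        32           7          82 0.375  0.0854 0.2896
  host_tissue         7        32           2          82 0.219  0.0244 0.1944
       region        12        32          25          82 0.375  0.3049 0.0701
   host_shift        15        32           9          82 0.469  0.1098 0.3590

Permutation test (host-or-tissue shift): D = 0.241, raw p = 0,
corrected p = 0.000999 (m = 1000)
```

Here `p_old` is the fraction of splits older than 3 Ma whose two daughter
lineages differ in state (47% carry a host shift) versus 11% of younger
splits; `D` is the contrast the permutation test evaluates. Region shifts
show no such asymmetry (0.375 vs 0.305), as simulated.

Stage 5 summarizes the tempo of lineage accumulation; the generator's tree
is a constant-rate pure-birth tree, and the fits agree:

```
 clade  lineages   n gamma  p_two p_one_lower  best_model dAIC_dd
   all       all 115 1.258 0.2083       0.896  pure_birth   -2.00
   all truncated  81 1.962 0.0497       0.975 birth_death   -4.19
```

A negative `gamma` with small `p_two` would indicate a diversification
slowdown; `dAIC_dd` > 0 would favor a density-dependent model over the best
constant-rate model.

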