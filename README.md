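# panmixsel

Forward-in-time simulation of recurrent genomic selection in panmictic
(random-mating) animal populations.

## What it is for

Breeding programs increasingly select parents on genomic breeding values
predicted from SNP panels (GBLUP) rather than on phenotypes or pedigree
BLUP. How much genetic gain that buys — and what it costs in genetic
variance and inbreeding — depends on quantities that are hard to isolate
empirically: the population's linkage disequilibrium (LD), the training-set
policy, the selection intensity, and non-additive gene action. panmixsel is
a stochastic simulator for exactly these questions, aimed at quantitative
geneticists and breeding-program designers. It builds a multi-chromosome
genome and two reference populations with engineered LD, simulates a
complex trait (the bundled design emulates feed conversion ratio in
broilers, where *lower is better*), and runs replicated cycles of
truncation selection under eight schemes: GBLUP with several training
policies (GS, GS1, GS2, GS3), selection on the true genotypic value (GV),
pedigree BLUP with full or partial phenotyping (pbB, pbB1), and a
no-selection drift control (NS).

The core models, in the field's standard notation:

* **Founder LD.** Crossing two parental populations in linkage equilibrium
  and random-mating once gives a Hardy-Weinberg reference population whose
  gametic LD is Δ<sub>ab</sub> = (1−2θ)/4 · (p<sub>a1</sub>−p<sub>a2</sub>)
  (p<sub>b1</sub>−p<sub>b2</sub>): equal parental frequencies give LD
  centred at zero (low-LD design), divergent frequencies give systematic
  positive LD (high-LD design).
* **Trait.** Per-QTL effects m, a, d derived from genotypic bounds for
  homozygotes; dominance positive toward the unfavorable allele; optional
  constrained digenic epistasis using the classical two-locus F2 patterns
  (9:7, 15:1, 12:3:1, 9:3:4, 13:3, 9:6:1, and a four-class interaction),
  solved from a sampled anchor effect I₂₂ ~ N(0, k(σ²_A + σ²_D + 2σ_AD))
  and verified against Kempthorne's orthogonal partition; phenotypes at
  fixed broad-sense heritability H² = 0.30 per generation.
* **Evaluation.** y = Xβ + Σ Z<sub>k</sub>u<sub>k</sub> + ε with VanRaden
  additive (method 1), Su dominance, and Hadamard epistatic kernels
  (G#G, G#D, D#D), or the pedigree numerator matrix A; variance components
  by AI-REML with EM fallback; selection on the additive BLUP.
* **Inbreeding three ways.** Pedigree F (Meuwissen-Luo recursion), genomic
  F (G<sub>ii</sub> − 1), and realized F (identity-by-descent counted from
  unique founder-allele labels carried through every meiosis).

See `vignette("methods", package = "panmixsel")` for assumptions,
parameter defaults, numerical choices and limitations.

## A worked example

A small end-to-end run (the `toy` preset: 2 chromosomes, 200 SNPs, 20 QTL,
20 founders per sex, 3 selection cycles; seconds on a laptop):

```r
library(panmixsel)

cfg <- preset("toy")
ex  <- run_experiment(cfg, schemes = c("GS", "NS"), populations = "high",
                      replicates = 2, seed = 1)
rec <- ex$records
subset(as.data.frame(rec), scheme == "GS" & replicate == 1,
       select = c(generation, mean_gv, var_gv, accuracy, F_pedigree))
```

```
 generation mean_gv var_gv accuracy F_pedigree
          0    2.12 0.0912       NA      0.000
          1    2.12 0.0777    0.740      0.000
          2    1.76 0.0306    0.611      0.000
          3    1.56 0.0178    0.463      0.050
          4    1.47 0.0136       NA      0.118
```

Reading the table: `mean_gv` is the cohort mean of the true genotypic
values — feed conversion ratio, so selection drives it *down* (generation 1
to 4); `var_gv` is the genotypic variance, eroding as positive LD is
consumed; `accuracy` is the correlation between the additive BLUPs and the
true genotypic values of the candidates (no model is fitted for generation
0, nor after the last cycle); `F_pedigree` is mean pedigree inbreeding,
accumulating once grandparental relationships exist. Aggregation and
plotting are one-liners:

```r
aggregate_replicates(rec)             # tidy mean +/- SD per metric
autoplot(ex, metric = "mean_gv")      # trajectories by scheme
```

The lower-level surface is exported too: `build_genome()`,
`sample_allele_frequencies()`, `make_reference_population()`, `meiosis()`,
`make_generation()`, `allocate_mates()`, `trait_architecture()`,
`genotypic_value()`, `phenotype()`, `vanraden_G()`, `su_D()`,
`epistatic_kernels()`, `reml_fit()` (with broom-style `tidy()`/`glance()`),
`pedigree_A()`, `pedigree_inbreeding()`, `realized_inbreeding()`,
`run_scheme()`, and the metrics layer (`genetic_gain()`,
`prediction_accuracy()`, `count_selected_progenies()`,
`allele_frequency_summary()`). A thin command-line wrapper lives at
`inst/cli/panmixsel.R` (`preset`, `run`, `report` subcommands, YAML
configs).

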