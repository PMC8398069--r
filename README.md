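# cdvqtl

Canopy development dissection and kinship-corrected GWAS for tetraploid
potato under contrasting nitrogen inputs.

## What this package is for

Nitrogen drives potato canopy development and yield, and it does so in
strong interaction with the maturity type of the cultivar. This package
implements, as tested reusable R code, the two-step analysis used to
dissect that interaction genetically:

1. **Trait dissection.** Per field plot, a three-phase canopy
   development curve is fitted to weekly percent-soil-cover observations
   on a beta thermal-time axis: a beta build-up with inflection *tm1*
   reaching the maximum cover *Vx* at *t1*, a plateau to *t2*, and a
   senescence decline to *te*,

   v(t) = Vx (1 + (t1−t)/(t1−tm1)) (t/t1)^(t1/(t1−tm1)) for t ≤ t1.

   Derived traits are the phase durations, per-phase areas AP1–AP3, the
   total AUC, and the peak progression rate *Cm*. Tuber size
   distributions get a per-plot Gaussian fit
   Tb(mcl) = MX · exp(−(mcl−B)²/A) for weight and number, and harvest
   data yield the nitrogen-efficiency traits (Y_DM, NUpt, NUE, NUtE,
   NUptE, SCYi).

2. **Association mapping and QTL bookkeeping.** Genotype values per
   year × nitrogen level come from the split-plot mixed model
   Y = yr∗Mt + Mt.G + yr.row + yr.col + E (REML), optionally corrected
   for maturity-class means. Each trait is scanned over tetraploid SNP
   dosages (0–4) with the mixed model y = m·β + g + e,
   var(g) = K·σg², where K is a realised kinship matrix from 764
   markers; markers pass when −log10(p) > 4 and explained variance
   > 10%. Associations detected in both years are classified as
   nitrogen-independent (cm) or HN-/LN-exclusive, merged into QTLs with
   a 4 Mb single-linkage window (±4 Mb = the 8 Mb LD window), and
   flagged for colocalization with the chromosome-5 maturity locus.

A synthetic-data module (`scenario()`, `simulate_genotypes()`,
`simulate_experiment()`) generates structured tetraploid panels,
maturity-mediated trait architectures and complete two-year split-plot
trials, so the entire pipeline is exercised without external data.

## Worked example

Curve traits from the canonical parameter set, then a simulated
nitrogen-dependence study: one common, one high-N-only and one
low-N-only QTL planted at 25% variance in 169 cultivars, scanned and
bookkept end to end.

```r
library(cdvqtl)

p <- canopy_params(tm1 = 10, t1 = 20, t2 = 40, te = 60, Vx = 95)
unlist(derive_canopy_traits(p))
#>  dur_max  dur_sen       Cm      AP1      AP2      AP3      AUC
#>   20.000   20.000    7.125  950.000 1900.000  950.000 3800.000

sc    <- scenario("n_dependent", seed = 42)
panel <- filter_markers(sc$genotypes$panel)
K     <- compute_kinship(panel, seed = 42)
res   <- run_gwas_pipeline(sc$datasets, panel, K)
res$qtls[, c("trait", "chrom", "n_class", "peak_marker",
             "minus_log10_p", "explained_var_pct", "maturity_colocalized")]
#>      trait chrom n_class peak_marker minus_log10_p explained_var_pct
#> 1 trait_cm     1      cm chr01_m0060         11.94              26.2
#> 2 trait_hn     3      HN chr03_m0099          7.55              16.9
#> 3    mt_as     5      cm chr05_m0112         22.01              43.9
#> 4 trait_ln     7      LN chr07_m0124         10.77              23.8
#>   maturity_colocalized
#> 1                FALSE
#> 2                FALSE
#> 3                 TRUE
#> 4                FALSE
```

All three planted QTLs are recovered at their planted markers with the
correct nitrogen classification (−log10(p) well above the 4 threshold,
explained variance above 10%), and the maturity assessment maps to the
simulated chromosome-5 locus, flagged as maturity-colocalized.

The numbered scripts under `analysis/` run the same pipeline as a full
narrative workflow on a simulated 712-plot trial — simulation, per-plot
curve fits, trait calculation, mixed-model genotype values, corrected
and uncorrected scans, and the QTL tables — writing summary tables to
`results/`.

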