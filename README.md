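# gcmediate

Gene-centric mediation analysis of DNA methylation with composite-null
testing.

## The problem

Early-life exposures can leave lasting marks on DNA methylation that in
turn shift adult health outcomes.  Testing that chain formally is a
mediation problem with an awkward shape: one binary exposure *X*, an
outcome *Y* (continuous score or case/control status), and for every gene
a block of *K* correlated CpG mediators *M* measured on a methylation
array — with far more CpGs than samples genome-wide.  `gcmediate` is for
epidemiologists and statistical geneticists who want to run that analysis
per gene, with honest type-I error control under the composite null.

## The method

For each gene (CpG set = gene body + 500 bp upstream of the TSS,
strand-aware):

1. **Exposure path** — inverse regression: fit the logistic null
   `X ~ C` (covariates: age, sex, BMI, five blood-cell proportions) and
   test the CpG block as a random effect with a variance-component score
   test: `Q = r' M M' r`, null distribution `sum_j lambda_j chi2_1`,
   evaluated by characteristic-function inversion (Davies/Imhof-type,
   with a Liu-type moment-matching fallback).  Gives `p_alpha`.
2. **Outcome path** — fit `Y ~ X + C` under the outcome family (so the
   direct effect c' is adjusted) and test the same block the same way.
   Gives `p_beta`.
3. **Composite null** — the mediation null is the union of H00
   (alpha = 0, beta = 0), H01 (alpha = 0, beta != 0) and H10 (alpha != 0,
   beta = 0).  The per-gene mediation p-value is the weighted
   divide-aggregate statistic

   `p_ab = pi01 * p_alpha + pi10 * p_beta + pi00 * max(p_alpha, p_beta)^2`

   with sub-null proportions estimated genome-wide from the two p-value
   series by an empirical-null fit, a final empirical-null recalibration
   across genes, and Benjamini-Hochberg q-values.

A synthetic-data generator (`simulate_cohort`, `simulate_gene`,
`simulate_study`) produces labelled H00/H01/H10/H11 studies with a
confounded binary exposure, exchangeable-correlation CpG blocks, and
genome-wide or per-gene-isolated outcomes, so every stage is testable
without any data download.

## Worked example

```r
library(gcmediate)

base  <- sim_scenario("H11", n = 352, K = 16, rho = 0.5)
study <- simulate_study(400, c(H00 = .7, H01 = .1, H10 = .1, H11 = .1),
                        base, seed = 11)
res <- mediation_scan(study$phenotypes, study$methylation, study$gene_map)
w <- attr(res, "weights")
round(c(pi00 = w$pi00, pi01 = w$pi01, pi10 = w$pi10), 3)
#>  pi00  pi01  pi10
#> 0.754 0.027 0.219
head(res[order(res$p_mediation),
         c("gene", "m", "p_alpha", "p_beta", "p_mediation", "q_value")], 3)
#>       gene  m      p_alpha       p_beta  p_mediation    q_value
#> 39  G00039 16 6.439088e-08 5.653098e-05 1.237588e-05 0.00270720
#> 48  G00048 16 4.950447e-10 6.183779e-05 1.353600e-05 0.00270720
#> 288 G00288 16 1.608071e-09 1.820087e-03 4.008203e-04 0.04885146
```

The weights are estimated blind to the truth: roughly a fifth of genes
carry an exposure-path signal only (`pi10`, matching the simulated H10 +
H11 mass with strong alpha effects), while the outcome-path series looks
mostly null (`pi01` small) because each gene's outcome signal competes
with every other active gene's contribution to the same outcome.  The
genes that survive FDR control combine small p-values on *both* paths —
exactly the H11 signature.  Running the numbered scripts in `analysis/`
(`01_simulate_study.R` … `04_operating_characteristics.R`) reproduces a
full simulated study, its total-effect table, the mediation scan above and
the method's operating characteristics, writing tables under `results/`.

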