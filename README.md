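# snpbarcode

Search case-control genotype data for **high-order SNP barcodes** —
combinations of *m* SNPs, each fixed at one genotype (1 = homozygous
major, 2 = heterozygous, 3 = homozygous minor), whose carrier frequency
differs between controls and cases. The package is aimed at statistical
geneticists studying SNP-SNP interaction (epistasis) in case-control
cohorts, where the candidate space $\binom{p}{m}3^m$ rules out enumeration
beyond low orders.

The core is a **hybrid Taguchi-genetic algorithm (HTGA)**. A chromosome is
an order-*m* barcode $C = \{(s_1, g_1), \ldots, (s_m, g_m)\}$ with distinct
SNP indices $s_j$ and genotype codes $g_j \in \{1,2,3\}$, scored by the
carrier-count difference

$$F(C) = \#\{\text{controls carrying } C\} - \#\{\text{cases carrying } C\},$$

so large positive fitness flags protective combinations (odds ratio
$\mathrm{OR} = (TP \times TN)/(FP \times FN) < 1$). Each generation runs
tournament selection, uniform crossover (probability $p_c$), a Taguchi
refinement step — $\mathrm{round}(0.5\,M\,p_c)$ two-level
orthogonal-array experiments whose signal-to-noise factor effects
($\eta = \mathrm{sign}(y)y^2$) compose a predicted-optimal child from two
parents — element-wise mutation (rate $p_m$), and elitist replacement.
Plain GA, PSO and chaotic-PSO baselines, an exhaustive oracle for low
orders, and Woolf confidence intervals plus Pearson chi-square p-values
for identified barcodes are included. A bundled 26-SNP growth-factor-gene
table lets the package regenerate its breast-cancer study cohort (5000
cases, 5000 controls) with exact per-SNP genotype counts from published
marginals alone.

## Worked example

```r
library(snpbarcode)

cohort <- generate_cohort(snp_table(), n_per_group = 5000, seed = 0)
cohort
#> snp_cohort: 10000 samples (5000 cases, 5000 controls) x 26 SNPs

fit <- barcode_search(cohort, order = 2, method = "htga", seed = 1)
summary(fit)
#> barcode_search: HTGA, order 2
#> best barcode: snps=21,8 genotypes=1-3
#> fitness (controls - cases carrying): 135
#> snps=21,8 genotypes=1-3
#>   controls matching 756, cases matching 621 (difference 135)
#>   OR 0.796, 95% CI 0.71-0.89, p <.001
#> converged from 130 to 135 over 1000 iterations

barcode_search(cohort, order = 2, method = "exhaustive")
#> barcode_search: EXHAUSTIVE, order 2
#> best barcode: snps=8,21 genotypes=3-1
#> fitness (controls - cases carrying): 135
```

The HTGA's best order-2 barcode pairs rs2229765-AA (genotype 3 at SNP 8)
with rs1554286-CC (genotype 1 at SNP 21): 756 controls but only 621 cases
carry both genotypes, a difference of 135 with OR 0.796 (95% CI
0.71–0.89), i.e. a protective joint signal. The exhaustive scan of all
2925 order-2 candidates confirms this is the global optimum for this
simulated cohort. `plot(fit)` draws the convergence history, and
`run_htga()`, `run_ga()`, `run_pso()`, `run_cpso()` expose the individual
engines.

A thin command-line wrapper covers the same workflow from a shell:

```sh
Rscript inst/scripts/snpbarcode.R generate --seed 1 --out cohort.csv
Rscript inst/scripts/snpbarcode.R search --algorithm htga --order 2 \
    --cohort cohort.csv --out-prefix htga2
Rscript inst/scripts/snpbarcode.R stats --counts 1179,1309,3821,3691
```

`search` writes a report TSV (barcode, carrier counts, difference, OR,
CI, p), a per-iteration history, and a manifest (parameters, package
version, cohort MD5) sufficient to reproduce the run.

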