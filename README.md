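# snsplice

Analysis pipeline for studying how the abundance of the spliceosomal snRNAs
(U1, U2, U4, U5, U6) shapes alternative splicing — from qPCR quantification
of snRNA levels, through percent-spliced-in (PSI) estimation and
Bayes-factor differential-splicing calls, to cohort-level enrichment of
snRNA-sensitive missplicing in matched tumor/normal pairs. It is written
for computational biologists who want to run, audit, or extend each stage
of that analysis; a synthetic-data module generates toy genomes, gene
models, read counts, qPCR panels, coverage tracks and patient cohorts with
the statistical structure the methods assume, so the whole pipeline runs
end to end without any external data.

## The quantities at the core

* **snRNA levels**: ΔCt = Ct_assay − mean(Ct over 7SK/7SL/5S references)
  per sample; ΔΔCt calibrated against the cohort median or a control
  sample; relative abundance 2^−ΔΔCt, or α^−ΔΔCt with per-assay
  amplification efficiency α = 10^(−1/slope) from a dilution series.
  Replicate confidence intervals by balanced repeated replication
  (leave-one-out half-samples for triplicates, t-quantiles).
* **Splicing**: Ψ = I/(I+E) from junction-spanning and exon–intron boundary
  reads (6-nt minimum anchors, strand-specific); events usable at
  n = I+E ≥ 20 informative reads.
* **Differential splicing**: significant iff n ≥ 20 in both samples,
  |ΔΨ| ≥ 0.10, and BF₁₀ ≥ 1, where BF₁₀ is the BIC-approximate Bayes
  factor for two binomial proportions versus one
  (BF₁₀ = exp((BIC₀ − BIC₁)/2); equal proportions give (n₁+n₂)^(−1/2)).
* **Cohort enrichment**: per-event counts of patients with significant
  tumor/normal splicing differences; events in ≥ 10 patients are
  "frequently misspliced"; sensitive-vs-insensitive strata compared by a
  one-sided Kolmogorov–Smirnov test on the CDF grid implied by the cohort
  size (D⁺ with p = exp(−2·m_eff·D⁺²)).

## Worked example

Simulate 40 genes, deplete an snRNA so that 10 designated events lose 0.3
of their inclusion, and call differential splicing between control and
knockdown libraries:

```r
library(snsplice)
cfg <- sim_config(seed = 42, n_genes = 40, read_depth = 150, true_psi = 0.6)
ann <- sim_annotation(cfg)
psi_kd <- rep(0.6, 40); psi_kd[1:10] <- 0.3
ctrl <- simulate_condition_counts(ann$events, 0.6, 150, seed = 1)
kd   <- simulate_condition_counts(ann$events, psi_kd, 150, seed = 2)
calls <- call_differential(estimate_psi(ctrl, ann$events, "ctrl"),
                           estimate_psi(kd, ann$events, "U2kd"))
table(truth = seq_len(40) %in% 1:10, called = calls$significant)
#>        called
#> truth   FALSE TRUE
#>   FALSE    29    1
#>   TRUE      0   10
head(calls[calls$significant, c("event_id", "kind", "psi_a", "psi_b",
                                "delta_psi", "bayes_factor")], 4)
#>   event_id kind psi_a psi_b delta_psi bayes_factor
#> 1 G0001.SE   SE 0.556 0.209    -0.348     6.31e+06
#> 2 G0002.SE   SE 0.633 0.246    -0.386     8.29e+08
#> 3 G0003.SE   SE 0.618 0.316    -0.302     6.04e+04
#> 4 G0004.SE   SE 0.613 0.325    -0.288     2.43e+04
```

All 10 truly shifted events are recovered (one false call among the 30
null events at these depths, consistent with the ~2% null rate of the
joint criteria). The matching qPCR side — a knockdown programmed at 40% of
control U2 — reads back from the simulated Ct panel as:

```r
qp <- simulate_qpcr_panel(c("ctrl", "kd"),
  rel_abundance = matrix(c(1, 0.4), 2, 1,
                         dimnames = list(c("ctrl", "kd"), "U2")),
  noise_sd = 0.1, seed = 3)
dd <- delta_delta_ct(delta_ct(qp$ct), calibrator = "ctrl")
dd[dd$assay == "U2", ]
#>    sample assay mean_ct delta_ct delta_delta_ct rel_abundance
#> 5    ctrl    U2    12.0   0.0112            0.0         1.000
#> 13     kd    U2    13.3   1.3093            1.3         0.407
```

ΔΔCt of 1.3 cycles corresponds to 2^−1.3 ≈ 0.41 of the control level —
the programmed 0.4 within replicate noise.

## The analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
study's computational arc on synthetic data; each writes its tables under
`results/`:

| script | stage |
|---|---|
| `01_simulate_data.R` | genome, gene models, events, branchpoints, counts, qPCR panel, coverage |
| `02_snrna_panel.R` | ΔCt/ΔΔCt quantification, efficiencies, BRR intervals, Ward.D2 clustering |
| `03_differential_splicing.R` | PSI, differential calls, intron retention, dose response, overlaps, Canberra MDS |
| `04_feature_analysis.R` | splice-site scores, GC/length/region, branchpoints, TPM, Pol II, k-mers, metagene |
| `05_cohort_analysis.R` | cohort filtering, per-patient missplicing, frequent-missplicing rule, KS enrichment |

Run them in order with `Rscript analysis/01_simulate_data.R` etc.

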