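---
title: "Methods: snRNA abundance and alternative splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snRNA abundance and alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snsplice)
```

# The scientific question

The five spliceosomal snRNAs (U1, U2, U4, U5, U6) sit in equal stoichiometry
inside the assembled spliceosome, yet their cellular abundances vary several
fold across tissues, development, and tumors. If that variation is
regulatory rather than inert, depleting an individual snRNA should shift
splice-site choice at specific, sensitive events — not collapse splicing
globally — and events sensitive to snRNA dosage in a cell-line model should
be preferentially misspliced in patient tumors with dysregulated snRNA
levels. `snsplice` implements the quantitative machinery to ask exactly
that, end to end, with a synthetic-data module standing in for the wet-lab
inputs so every stage can be exercised and tested offline.

# snRNA quantification from qPCR panels

Cycle thresholds follow the exponential amplification model
$Ct = \mathrm{base} - \log_\alpha(\text{abundance})$, with per-assay
efficiency $\alpha \in (1, 2]$ (fold amplification per cycle).

* **Delta-Ct.** Technical replicates are averaged first; the pseudoreference
  is the mean Ct of the 7SK, 7SL and 5S rRNA assays within each sample, so
  $\Delta Ct$ is invariant to the amount of RNA input (adding a constant to
  every Ct of a sample cancels).
* **Delta-delta-Ct.** Calibration is either against the per-assay median
  across all samples (tissue/cohort mode; the calibrated values then have
  median 0 per assay by construction) or against a named calibrator sample
  (knockdown mode, scrambled-control transfection). Relative abundance is
  $2^{-\Delta\Delta Ct}$, or $\alpha^{-\Delta\Delta Ct}$ when efficiencies
  estimated from the four-point ten-fold dilution series are supplied
  ($\alpha = 10^{-1/m}$ from the least-squares slope $m$ of Ct on
  $\log_{10}$ dilution). Whether the tissue-scale panel used efficiency
  correction or assumed perfect doubling is not decidable from the study
  design we emulate, so both modes are exposed; they coincide at
  $\alpha = 2$.
* **Replicate intervals.** Confidence intervals come from balanced repeated
  replication over half-samples. Triplicates admit no balanced half-sample
  design, so odd replicate counts use leave-one-out subsets. A subset of
  size $m$ of $n$ carries only $(1/m - 1/n)$ of the estimator variance, so
  the mean squared deviation of subset means is rescaled by $m/(n-m)$ —
  the identity for genuine half-samples, the jackknife factor $n-1$ for
  leave-one-out. Intervals use Student-t quantiles on $n-1$ degrees of
  freedom rather than normal quantiles: with three replicates the variance
  estimate has 2 degrees of freedom and a z-interval would cover the truth
  only ~81% of the time; the t-interval restores nominal-level coverage,
  which the test suite verifies on noisy simulated panels.
* **Clustering.** Panel profiles are clustered with Ward.D2 on Euclidean
  distances of the calibrated values (the delta-delta-Ct definition already
  centers each assay, so no further scaling is applied). Rows are sorted by
  sample identifier and exact distance ties are broken by an infinitesimal
  lexicographic inflation, making dendrograms reproducible byte for byte.

# PSI from junction and boundary reads

All coordinates are 0-based half-open; a junction is keyed by (chromosome,
intron left end, intron right end, strand). A read supports a junction when
a gap in its alignment block structure matches the junction exactly with at
least 6 nt of aligned sequence on each side (mirroring a 6-nt minimum
anchor at the mapping stage); it supports a retained-intron boundary when a
single block covers 6 nt on each side of the exon-intron edge. Non-primary
records and mapping quality 0 are dropped; the protocol is strand-specific.

Per event, with inclusion support $I$ and exclusion support $E$:
$\Psi = I/(I+E)$, undefined when $n = I + E = 0$, and an event is reportable
as alternatively spliced only at $n \ge 20$. For cassette exons and retained
introns the two inclusion supports (two junctions, or two boundaries) are
averaged rather than summed, which keeps $I$ and $E$ on a per-isoform scale
and makes the complementary event's estimate satisfy
$\Psi_{\mathrm{incl}} + \Psi_{\mathrm{excl}} = 1$ on identical counts
(summing is available by argument). Competing-splice-site events orient
$\Psi$ as usage of the extension-containing isoform. Constitutive junctions
— junctions present in every transcript and untouched by any event — get
$\Psi$ = annotated-junction reads over all reads sharing either splice
site; this formula is the package's own operationalization, as is the
catalog's enumeration of annotated donors × acceptors as candidate novel
junctions.

# Differential splicing

Two samples are compared per event under three joint criteria: at least 20
informative reads on both sides, an isoform-ratio change of at least 10%,
and a Bayes factor of at least 1. The Bayes factor uses the BIC
approximation for binomial proportions: $H_0$ one shared proportion (1 free
parameter), $H_1$ two proportions (2 parameters),
$\mathrm{BIC}_m = -2\log\hat L_m + p_m \log(n_1+n_2)$ and
$BF_{10} = \exp((\mathrm{BIC}_0 - \mathrm{BIC}_1)/2)$, so equal observed
proportions give exactly $(n_1+n_2)^{-1/2}$. Fractional supports produced
by junction averaging are rounded half-to-even before the likelihoods
(bounded effect of less than one read). A conjugate beta-binomial marginal
likelihood ratio was evaluated as an alternative realization; it is *less*
conservative than the BIC form at these depths and was not adopted.

Calibration under the simulator's study conditions (base $\Psi = 0.5$,
Poisson depth, binomial split) — each measured by the test suite, not
asserted from theory: the null rate at depth 100/side is ≈2.2% (the BF
threshold, not the 10% filter, is binding there: $BF \ge 1$ corresponds to
a likelihood-ratio statistic of $\ln(n_1+n_2)$); recall at a true 0.3 shift
and depth 200 exceeds 90%; a sub-threshold true shift of 0.05 is called in
≈7% of events — the Bayes factor tightens the naive 10%-filter rate (~16%)
but does not eliminate shifts adjacent to the threshold. These rates are
reproducible to within one percentage point across seeds.

Downstream summaries: per-gene counts of significantly retained introns
(direction-aware: only increased retention counts), ordered-pair overlap
fractions of significant event sets across knockdown conditions, monotone
trend classification of dose series ($\Psi$ monotone within a tolerance of
0.02, with Spearman's $\rho$), and classical multidimensional scaling of
samples on Canberra distances $\sum_i |x_i-y_i|/|x_i+y_i|$ over the
most-variable events (terms with zero denominator contribute 0 — base R's
`dist` instead rescales them as missing, so the distance is computed
directly). MDS axes are centered and sign-fixed (first sample non-negative)
to remove the reflection indeterminacy.

# Features of snRNA-responsive events

* **Splice-site strength.** A supplied per-position score table (as exported
  by maximum-entropy models; donor window 9 nt spanning −3..+6, acceptor
  23 nt spanning −20..+3) is consumed directly; otherwise a first-order
  log-odds model is trained on the annotation at hand
  ($\log_2 p_{\mathrm{site}}/p_{\mathrm{bg}}$ per position, pseudocount
  0.5). Group comparisons are within-scorer contrasts, so either scorer
  supports them. Position weight matrices for motif display default to the
  −2..+6 (donor) and −8..+2 (acceptor) windows.
* **Branchpoints.** For each event the branchpoints of the intron directly
  upstream (transcript orientation) of the alternative region are collected,
  keeping distances to the 3' splice site of at most 200 nt — the bound is
  inclusive.
* **Expression and occupancy.** TPM is computed from counts and effective
  lengths; exon-level polymerase occupancy is the mean per-nucleotide
  coverage over the exon with zeros for uncovered positions, after removing
  genes below 1 TPM. Coverage is used as given — the per-million scaling
  applies only to the metagene computation.
* **Metagene.** Each gene body is cut into 50 bins; bin means are scaled to
  per-million mapped reads; genes whose best bin does not exceed 0.1 are
  dropped; remaining genes are normalized to their median bin (so global
  coverage rescaling cancels), and the profile is the per-bin median across
  genes, with minus-strand genes reversed to 5'→3'.
* **k-mers.** Motifs of length 4-6 are compared between sequence groups via
  per-sequence occurrence densities (count over available positions; raw
  counts by flag), a two-sample Kolmogorov-Smirnov test per motif, and
  log2 enrichment of mean densities with a pseudodensity of one over the
  total positions; reported at p < 0.01 and |log2 enrichment| > 1.5.
* **Tests.** Group differences use two-sided two-sample Wilcoxon rank-sum
  tests (features are generally not normal); medians carry percentile
  bootstrap 95% intervals.

# Cohort analysis

Events are filtered to at least 20 informative reads in a designated
reference sample (the cell-line anchor) and in at least 20% of patients.
For each patient-matched tumor/normal pair the differential-splicing
criteria above are applied unchanged (the cohort emulation states no
separate thresholds), giving a per-event count of misspliced patients.
Events misspliced in at least 10 patients (inclusive) are "frequently
misspliced"; the sensitive/insensitive ratio of those proportions is the
headline stratum contrast. Enrichment uses a one-sided Kolmogorov-Smirnov
statistic $D^+ = \max(F_{\mathrm{insens}} - F_{\mathrm{sens}})$ on the CDF
grid $\{0, 1/N, \ldots, 1\}$ implied by the cohort size ($N = 107$ steps),
with asymptotic $p = \exp(-2 m_{\mathrm{eff}} {D^+}^2)$,
$m_{\mathrm{eff}} = m_1 m_2/(m_1+m_2)$; an exact full-enumeration
permutation mode exists for small groups and anchors the oracle tests.
Heterogeneous cohort splicing is summarized as intermediate-$\Psi$ mass,
the fraction of pooled $\Psi$ values inside [0.2, 0.8] (band configurable).
Sample ties at the boundary of the top/bottom-$n$ snRNA-level groups are
included in full and flagged.

# The synthetic-data generator

The generator *defines* the study conditions; it is not tuned per test.

* Read counts: informative reads per event $n \sim$ Poisson(depth), split
  $I \sim$ Binomial$(n, \Psi_{\mathrm{true}})$ — the simplest model with
  junction-count sufficiency. Counts land on the event's physical junction
  and boundary keys; optional SAM-text emission writes single-end 67-nt
  records with M/N block structure (no sequence realism: no error model, no
  quality strings, no fragment-length model).
* Gene models: one alternative unit per gene on alternating strands along a
  single synthetic chromosome; exon GC 0.50, intron GC 0.40 by default,
  exon lengths 80-200 nt, introns 250-450 nt (long enough to host the
  200-nt branchpoint window); 0-3 branchpoints per intron at 15-100 nt from
  the 3' splice site (distal variants at 101-200 nt on request), with
  synthetic pairing energies around −25.
* Dose response: the true $\Delta\Psi$ is linear in dose, or — for the
  saturating shape — a ramp reaching the full effect at twice the half-max
  dose, hence saturating before the top dose of the 50-250 pmol series.
  Michaelis-Menten and exponential-saturation forms were considered but
  reach only 2/3 and 3/4 of the full effect at twice half-max, too slow for
  the early-saturation behavior being emulated.
* Cohort: 107 patients, 500 events, 20% sensitive, per-patient missplicing
  probability 0.30 (sensitive) vs 0.05 (insensitive) as a two-rate
  Bernoulli mixture, tumor shift $\Delta\Psi = 0.3$, depth 200 — the
  configuration the recovery tests and acceptance script run at.
* Determinism: every generator takes a seed, derives independent
  sub-streams, and restores the caller's RNG state; identical
  configurations produce byte-identical output files.

What passing on these data does **not** show: robustness to overdispersed
counts, mapping bias, isoform complexity beyond one event per gene, batch
effects between library protocols, or real snRNA-target biology. The
generator emulates the statistical skeleton the methods assume, nothing
more.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use 2,000 events for estimator
calibration (depth 500), 2,000 events × 3 seeds for call calibration, a
107 × 500 cohort with 100 null replicates, and ≤50-read SAM fixtures for
the counting oracle — sizes at which every stochastic assertion is stable
across seeds while the whole suite stays interactive. Other conventions:
$0\log 0 = 0$ in likelihoods; fractional supports rounded half-to-even;
Canberra zero-denominator terms contribute 0; MDS reflections fixed by
convention; missing panel cells imputed with the assay median and flagged;
GC denominators exclude ambiguity codes.
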