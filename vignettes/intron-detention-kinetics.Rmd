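---
title: "Modelling co-transcriptional splicing kinetics and post-transcriptional intron detention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling co-transcriptional splicing kinetics and post-transcriptional intron detention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicewave)
library(dplyr)
```

## The problem

Most introns are excised while RNA polymerase II is still transcribing the
gene. An intron that is *not* spliced before the transcript is cleaved at
the 3' end can still appear in poly(A) RNA as a retained intron (RI), and a
subset of these — detained introns — stay nuclear and are spliced or
degraded post-transcriptionally. Perturbations of protein arginine
methyltransferases (PRMTs) shift this balance in opposite directions
depending on which enzyme class is inhibited, and the question of whether
the shift is co-transcriptional (splicing rates) or post-transcriptional
(nuclear decay of the retained intron) is quantitative: it needs kinetic
rates, not just inclusion levels.

`splicewave` implements the computational layer of that analysis as
reusable, tested functions: a forward kinetic model of synchronized
nascent transcription, rate inference from coverage time courses, the
derived per-intron statistics, RI quantification from junction counts, a
transcription-block decay statistic, and the set/overlap/resampling
statistics used to compare conditions. A synthetic-data generator with
known ground truth stands in for the deposited sequencing data, so every
stage of the pipeline is verifiable end to end.

## The forward model

After a DRB block is washed out, polymerases initiate and release into
productive elongation ("spawn") as a Poisson process with rate
$\sigma$ (events/min) and move at a constant rate $v$ (nt/min). In the
transcript-relative frame (TSS = 0, TES = $L$), a molecule spawned at
$\tau$ has front $v(t-\tau)$ at collection time $t$. Three first-order
clocks act on it:

* intron $i$ is spliced at rate $s_i$ once its 3' splice site ($e3_i$) has
  been transcribed (intron-definition assumption);
* the transcript is cleaved at rate $c$ once the polymerase passes the
  TES; cleaved molecules leave the chromatin fraction entirely (the
  1 M urea wash retains only polymerase-engaged RNA);
* synchronization is ideal: no molecule is downstream of the TSS at
  $t = 0$.

Expected coverage at position $x$ is the spawn-time integral of the
survival function,

$$\mathrm{cov}(x,t) = \sigma \int_0^{\max(0,\,t - x/v)}
  S(x, t, \tau)\, d\tau,$$

where $S$ carries the factor $e^{-s_i \max(0,\,t-\tau-e3_i/v)}$ when $x$
lies in intron $i$ and $e^{-c \max(0,\,t-\tau-L/v)}$ everywhere. Because
$S$ depends on $\tau$ only through the molecule age $u = t - \tau$, one
cumulative trapezoidal integral over an age grid (step 0.05 min, kink
points included) serves all positions and time points; coverage follows by
interpolation. `simulate_molecules()` is the independent stochastic oracle
for this expectation; its optional Latin-hypercube mode stratifies the
underlying uniforms, which (the coverage indicator being monotone in each
coordinate) strictly reduces Monte-Carlo variance without changing the
estimand, and is used whenever the oracle comparison needs to be tight.

```{r forward}
m <- gene_model("demo", exon_starts = c(0, 3000), exon_ends = c(2000, 5000))
r <- rate_set(sigma = 2, v = 1000, s = 0.3, c = 0.5)
expected_coverage(m, r, t = 5, bins = c(0, 1000, 2500, 4000))
```

## Derived statistics

*Time to transcribe* an intron is `length / v`. The *probability that the
transcript is cleaved before intron* $i$ *is spliced* uses the
competing-exponentials closed form with a deterministic head start
$d = (L - e3_i)/v$ for splicing:

$$P = e^{-s_i d}\, \frac{c}{c + s_i}.$$

The *predicted poly(A) cassette-exon* $\Psi$ treats inclusion as a
commitment race: the upstream intron's clock ($s_u$) starts $\Delta t =
(e3_\text{down} - e3_\text{up})/v$ before the downstream ($s_d$) and skip
($s_\text{skip}$) clocks, and inclusion is committed if either flanking
intron splices first:

$$\Psi = 1 - e^{-s_u \Delta t}\,
  \frac{s_\text{skip}}{s_u + s_d + s_\text{skip}}.$$

Cleavage deliberately does not censor this race: splicing can complete
post-transcriptionally, which is the phenomenon under study. Both closed
forms ship with explicit Monte-Carlo race simulators used as oracles in
the test suite.

```{r derived}
cleavage_before_splicing_prob(s = 0.2, c = 1, d = 1)
predicted_cassette_psi(s_u = 1, s_d = 1, s_skip = 1, delta_t = log(2))
```

## Rate inference

`fit_rates()` minimizes the residual between observed and expected
coverage over $(\log\sigma, \log v, \log s_1..s_k, \log c)$ with box
constraints ($\sigma \in [10^{-3},10^3]$, $v \in [10^2,10^5]$,
$s_i \in [10^{-4},10^2]$, $c \in [10^{-3},10^2]$), L-BFGS-B from five
jittered starts (ties by loss, then smallest parameter norm). The default
loss is least squares on raw coverage; `loss = "poisson"` switches to the
Poisson deviance, the natural choice when the data are counts. Starting
values matter more than the optimizer: $v$ comes from the least-squares
slope of the coverage wavefront across time points
(`estimate_elongation_wavefront()`, falling back to a prior median when
the wave has already passed the gene end), $\sigma$ from the early-time
linear ramp near the TSS, and each $s_i$ from the intron/exon coverage
ratio at the last time point. Bins with zero coverage at every time point
are excluded.

Identifiability is a property of the design, not the optimizer: $v$ needs
the wavefront inside the gene at two or more collection times, and $c$
needs the wave to cross the TES well before the last time point. With
collections every 5 min to 35 min this bounds the usable gene-traversal
time $L/v$ to roughly 6–20 min, and the recovery studies in the test
suite draw their genes from that band — the same filtering any real
rate-fitting analysis applies. Within it, noiseless seven-point time
courses return every rate to well under 5 % relative error, and Poisson
noise at deep coverage (mean expressed-bin coverage ≈ 500; deep
nascent-RNA libraries put tens of reads per nucleotide on expressed
genes) keeps $\sigma, v$ within 10 % and $s_i, c$ within 25 % for
$s_i \in [0.05, 2]\ \text{min}^{-1}$. One caveat is itself a finding of
the kinetic analysis: an intron that mostly escapes co-transcriptional
splicing (cleavage-before-splicing probability above one half — slow,
TES-adjacent) leaves almost no splicing signal in nascent coverage, so its
$s_i$ is unidentifiable from this experiment by construction, and its fit
is maximum-likelihood but high-variance. The recovery studies therefore
state their splicing tolerance over introns with escape probability below
0.5, which is the population the co-transcriptional rate is meaningful
for.

## The synthetic study

`sim_config()` fixes the study conditions; defaults were chosen once to
mirror the statistical structure of the real experiments:

* collections every 5 min to 35 min after release; Poisson count noise;
  two replicates;
* log-normal rate priors centred on $\sigma = 0.5$/min, $v = 1500$ nt/min,
  $s = 0.7$/min (ordinary introns), $c = 0.5$/min, and an intron decay
  rate $k$ centred on $\ln 2 / 60$ (a 60-min half-life);
* a fraction (default 0.2) of introns planted as *detained*: drawn
  shorter (median 0.4 kb vs 1.5 kb), placed TES-proximal, and given slow
  splicing ($s$ median 0.08/min);
* three arms: `control`; `type2i`, emulating a symmetric-methylation
  (Type II PRMT) inhibitor by slowing detained-intron splicing and decay
  ($s \times 0.4$, $k \times 0.4$); and `type1i`, emulating a Type I
  inhibitor by accelerating detained-intron decay ($k \times 2.5$).
  Effects touch detained introns only, so all other introns are honest
  nulls for calibration tests.

The planted poly(A) retention ties the count tables to the kinetics: an
intron's true $\Psi$ is the probability it escapes co-transcriptional
splicing times its post-transcriptional survival over a nuclear residence
window (default 60 min),
$\Psi = e^{-s d}\,\tfrac{c}{c+s}\, e^{-k T_\text{res}}$. Slower splicing
and slower decay (type2i) therefore raise retention; faster decay
(type1i) lowers it — the two-direction asymmetry the downstream modules
must recover. Junction counts are Poisson with effective lengths
$l_I = 2$ (two exon–intron junctions) and $l_S = 1$; the
transcription-block experiment draws intron counts before/after a 60-min
block with stable flanking exons by default.

What the generator does *not* emulate: overdispersion beyond Poisson,
spike-in normalization (coverage is generated depth-normalized), mappability
and GC structure, isoform complexity beyond one transcript per gene, and
read-level artefacts. Passing tests therefore demonstrate correctness of
the estimators under the stated model, not robustness to every failure
mode of real libraries.

```{r study}
study <- simulate_study(sim_config(n_genes = 30, seed = 101, tc_genes = 2))
rec <- delta_psi_test(study$polya_counts, control = "control",
                      treatment = "type2i")
call_ri(rec) %>% count(direction)
```

## Quantification and statistics

$\Psi$ is the length-normalized inclusion ratio
$(I/l_I) / (I/l_I + S/l_S)$, pooled across replicates by count summation
(variance-stable at low counts). Differential inclusion uses a
two-proportion z-test on the length-normalized pooled counts with BH
correction; events with pooled $I+S < 10$ in either condition are
excluded from the FDR family. This is a transparent, calibrated substitute
for event-level likelihood-ratio machinery, conservative rather than
anti-conservative on null events (the length weights understate the
information in inclusion counts), and not numerically equivalent to any
rMATS version. An effect-size threshold on $|\Delta\Psi|$ is not applied
by default.

The transcription-block decay statistic is
$\delta = \log_2\frac{(I_{+} + \varepsilon)/(E_{+} + \varepsilon)}
{(I_{-} + \varepsilon)/(E_{-} + \varepsilon)}$ with pseudocount
$\varepsilon = 0.5$ and the flanking-exon normalizer summed over both
exons (either alone is accepted). For first-order decay it estimates
$-k t / \ln 2$; replicates are pooled.

Overlap statistics report the sample odds ratio with a Haldane–Anscombe
+0.5 on zero cells (closed-form and oracle-checkable, unlike a
conditional-MLE OR, from which small discrepancies are expected) and a
two-sided Fisher exact p; the BH family is the call's pair list, and the
universe is an explicit argument because the published ORs depend on an
expression filter that is not fully specified. The size-matched
resampling test draws, without replacement, subsets of the global
population equal in size to the RI set, rank-sum tests each draw, and
reports the median p over (conventionally) 1000 repetitions. Proteomics
enrichment log2-transforms intensities, centres each sample by its mean
(the most literal reading of normalizing "by the average of the data
distribution"; median-centring is a flag), and applies a per-protein
Welch two-tailed t-test.

## Numerical and design choices

* Coordinates are 0-based, half-open, transcript-relative with strand
  resolved at parse time; one representative transcript per gene (largest
  exonic span, ties by transcript id).
* Splice-site windows default to $-3..+6$ (donor) and $-20..+3$
  (acceptor), offsets counted without a zero; profiles are unweighted
  counts, with `N` and out-of-range positions dropped per column.
* Quadrature step 0.05 min and 50-nt bins are accuracy knobs, both
  configurable.
* Degenerate inputs fail loudly: all-zero coverage, a single usable
  wavefront, constant vectors in correlations, single-replicate ANOVA.
* The subsampled-Wilcoxon p-values within one call share the subset and
  are therefore dependent; calibration claims are about the marginal
  distribution across independent subsets, which is how the test suite
  evaluates them. A second caveat is inherited from the procedure itself:
  when the tested subset is literally contained in a small global pool,
  each size-matched draw shares elements with it, and those exact ties
  make the rank-sum p-values detectably non-uniform. At the scale the
  procedure is meant for (a genome-wide pool, hundreds of retained
  introns) the expected overlap is a handful of elements and the effect
  is negligible; the calibration suite therefore measures the test's
  marginal calibration with an independent null subset.
* `run_pipeline()` is the orchestration surface (hash-stamped manifest,
  stage skipping, deterministic outputs under a fixed seed); shell
  wrappers would add nothing for an analysis package, so the exported
  functions and this vignette are the interface.
* Problem sizes in the test suite (tens of genes for recovery studies,
  hundreds for count studies, $10^5$–$10^6$ Monte-Carlo draws) were
  chosen as the smallest designs at which the estimators' statistical
  error is comfortably inside the documented tolerances.

## Known limitations

The forward model omits pausing sites, piecewise elongation rates,
recursive splicing and lariat kinetics; the fit assumes one isoform and
independent genes; the decay experiment is a single-interval design (no
half-life curve fitting); and the cleavage-before-splicing probability
treats the post-3'SS delay as deterministic. Real-data quantities that
depend on deposited libraries (genome-wide medians, published ORs) are
outside what a synthetic study can reproduce; the package's claims are
about the correctness and calibration of the methods themselves.
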