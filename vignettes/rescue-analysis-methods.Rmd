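---
title: "Validating kinase substrates with triple-SILAC rescue experiments"
author: "silacrescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating kinase substrates with triple-SILAC rescue experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silacrescue)
```

## The experimental design

ATP-competitive kinase inhibitors are never perfectly selective, so a
phosphosite that loses phosphorylation under inhibitor treatment is not
necessarily a direct substrate of the targeted kinase. The chemical-genetic
rescue design resolves this with three metabolically labeled cell states
quantified in one MS run:

* **L** — cells expressing the wild-type kinase, treated with vehicle;
* **M** — wild-type kinase, treated with the inhibitor;
* **H** — an engineered inhibitor-resistant kinase mutant, treated with the
  inhibitor.

A direct substrate is *inhibited* in M relative to L, and *rescued* in H: the
resistant mutant keeps phosphorylating it despite the drug. An off-target
effect of the inhibitor is inhibited in both M and H — the mutant cannot
rescue a site the kinase never phosphorylated. The package implements this
inference for MaxQuant-style normalized ratio tables (M/L, H/L, H/M per
biological replicate; five replicates by default).

## The statistical procedure

For each record the per-channel replicate log2 ratios are summarized by a
one-sample t test against zero, `t = mean / (sd / sqrt(n))` with `n - 1`
degrees of freedom and two-sided p values, followed by Benjamini–Hochberg
FDR adjustment. Classification then applies, with defaults `alpha = 0.05`
and `fc_threshold = 0.585` (= log2 of 1.5-fold regulation, to three
decimals; both inequalities strict):

1. **Direction and relevance** (M/L): significantly downregulated
   (inhibited) when `q < alpha` with mean log2 M/L `< 0`; biologically
   relevant when `|mean| > fc_threshold`.
2. **Rescue** (H/L interval + H/M test): a downregulated record is
   *rescued* when `-fc_threshold < mean(H/L) < fc_threshold` and the H/M
   test has `q < alpha`; *partially rescued* when not rescued but
   `mean(H/M) > 0` with `q < alpha`; otherwise *not rescued*. Upregulated
   records use the mirrored criteria. Because the rescue interval forces
   `mean(H/L) - mean(M/L) > 0`, every rescued record also satisfies the
   partial-rescue criteria — the partial list nests the rescued list.
3. **Proteome cross-reference**: a rescued phosphopeptide is only evidence
   of kinase activity if its parent protein's abundance did not change the
   same way; sites whose protein (any shared accession) is significantly and
   relevantly regulated in the same direction are flagged
   `protein_confounded` (flagged, not removed, so funnel counts stay
   comparable).

### Design choices in the statistics

* **Sidedness.** Tests are two-sided; direction is imposed separately by the
  sign of the mean. This reproduces the published pairing of a signed mean
  condition with a q-value condition without double-counting direction.
* **FDR family.** BH runs per channel across all records that survive QC,
  with sites and proteins as separate families — the behavior of a
  column-wise test in Perseus-style workflows. The family choice matters:
  q values of true effects grow when the family is dominated by nulls.
* **Missing values.** A channel is tested only with `min_valid` (default 3
  of 5) non-missing replicates; below that the statistics are undefined and
  the record can never be called significant. No imputation is performed.
* **Zero variance.** With identical replicate values the t statistic is
  formally undefined. We take the limiting case: zero variance around a
  nonzero mean is infinitely strong evidence (`t = ±Inf`, `p = 0`), zero
  variance around zero stays undefined. Any calibrated alternative (e.g.
  variance moderation) would behave identically in the limit; without this
  convention noise-free data — where every planted effect is exact — could
  never be called significant, which is the wrong answer for the one case
  where the truth is known with certainty.
* **Undefined rescue inputs.** Records eligible for rescue whose H/L or H/M
  statistics are undefined default to *not rescued* (conservative), with the
  reason recorded.
* **Upregulated rescue.** The mirrored criteria (same symmetric H/L
  interval, significantly negative H/M) are the only symmetric reading
  consistent with the down-direction bounds; the H/M significance
  requirement is kept for symmetry.

### Distinctness conventions

Counts in the funnel summary use: *distinct phosphopeptide* = unique
(sequence window, multiplicity) pair; *distinct phosphosite* = unique
(leading accession, position); *distinct protein* = unique leading
accession. For real MaxQuant tables a multiply-phosphorylated peptide maps
to several site rows with different windows; the peptide-level key here
treats each site row with its multiplicity as the peptide proxy, which is
exact for the simulated data (one site per peptide) and a documented
approximation otherwise. MaxQuant's wide per-multiplicity ratio columns
(`___1`/`___2`/`___3`) are expanded to one record per site × multiplicity
state with any observed ratio, so statistics are computed per multiplicity
state.

## Motif analysis

Adherence to the minimal acidophilic recognition motif `[S/T]-x-x-[D/E]` is
decided by exactly two positions: an S/T phosphoacceptor at the center and
D/E at +3. Proline at +1 — a known negative determinant — is reported
faithfully in the frequency profile but never penalized in the adherence
call; tyrosine-centered windows are non-adherent. Position frequency
matrices and per-position information content (`log2(20) - H` bits, uniform
background, no small-sample correction — the common logo-rendering default)
are produced for the nested record sets: all input windows, inhibited,
partially rescued, rescued.

## The synthetic-data generator

`simulate_silac()` emulates the study design so every stage is testable with
known ground truth. Per site and replicate, log2 *intensities* are simulated
as `L = b + e_L`, `M = b + delta_M + e_M`, `H = b + delta_H + e_H`, with
`e ~ N(0, sigma^2)` independent per channel; ratios are differences of these
intensities. Placing noise on intensities rather than on ratios makes the
three ratio channels mutually consistent and correlated exactly as in a real
triple-labeling design (`log2(H/M) = log2(H/L) - log2(M/L)` elementwise),
which is what gives the H/M test its meaning. Masking a simulated intensity
voids both ratios that involve that channel.

Five effect classes are planted (`Delta = 1.5` log2 units by default):

| class | delta_M | delta_H | expected call |
|---|---|---|---|
| substrate_rescued | −Δ | 0 | rescued |
| substrate_partial | −Δ | −Δ/2 | partially rescued |
| off_target | −Δ | −Δ | not rescued |
| unaffected | 0 | 0 | not applicable |
| compensatory_up_rescued | +Δ | 0 | rescued (up) |

Default conditions, chosen once as the study conditions the generator
emulates: 2,000 sites, 5 replicates, `sigma = 0.3` per intensity channel (so
each log2 ratio has SD ≈ 0.42), 5% rescued substrates, 10% partial, 5%
off-target, 2% compensatory, 78% unaffected — about the proportion of
regulated phosphopeptides a kinase-inhibitor phosphoproteome shows — with 5%
missing intensities, Beta(8, 1) localization probabilities (≈10% of sites
below the 0.75 class-I cutoff), and 1% reverse/contaminant rows each.
Substrate-class windows carry D/E at +3 with probability 0.83 (the adherence
proportion reported for validated substrate sites; compensatorily
upregulated sites are included since those largely carried the motif too),
background windows with probability 0.12 (≈ the background D+E frequency);
flanking residues come from a fixed built-in human-proteome-like
composition. A configurable subset of rescued sites is planted on dedicated
proteins that carry the same regulation, to exercise the proteome
cross-reference. Replicates are modeled as independent beyond the shared
channel structure; the generator does not model spectrum-level effects,
peptide digestion, or label-conversion artifacts.

## What the benchmarks do and do not show

With `sigma = 0` every planted class is recovered exactly and the funnel
equals the planted counts — the thresholds themselves are verified. At
`sigma = 0.3` the picture is asymmetric and worth understanding:

* **Specificity** of the rescued call is high (≈ 0.99): the joint criterion
  (significant relevant inhibition, H/L interval, significant H/M) almost
  never fires spuriously.
* **Sensitivity** is moderate (≈ 0.55–0.6 per record). With five replicates
  the t test has four degrees of freedom, so even a 1.5 log2-unit effect at
  ratio SD 0.42 yields p values near 10^-3; BH correction across a family
  that is ~80% null then places the effective significance cutoff near
  p ≈ 0.005, and a substantial fraction of true substrates miss the strict
  `q < 0.05` requirement in one of the two tested channels. This mirrors the
  real workflow's character: the rescued list is deliberately conservative
  (few false positives, many false negatives), and the partially rescued
  list is the more sensitive catalogue.

Passing tests on synthetic data show the pipeline's logic and calibration
under the generative model; they do not certify recovery rates on real data,
where effect sizes, variance structure, missingness and peptide-to-site
mapping are all more complex.

## Problem sizes

The bundled checks run the generator at 2,000 sites and 5 replicates (the
emulated study scale), 100 seeded datasets for the nesting property, 20
seeds for the noise benchmark, 10,000 null vectors for t-test calibration,
and 1,000 random families for the FDR oracle comparison.

```{r example, eval = FALSE}
sim <- simulate_silac(silac_config(n_sites = 2000, seed = 1))
fit <- rescue_analysis(sim$sites, sim$proteins)
summary(fit)
evaluate_recovery(fit$sites, sim$truth)$confusion
plot(fit)  # volcano: gold = regulated, purple = rescued
```
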