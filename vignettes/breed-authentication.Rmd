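---
title: "Breed authentication with SNP panels: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breed authentication with SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedassign)
```

## Scope

`breedassign` covers the statistical workflow behind a breed-authentication
assay: quality control of breed-labelled SNP genotypes, delta-based marker
ranking and panel selection, partial-Bayesian individual assignment with
leave-one-out validation, exclusion-simulation testing, forensic pairwise
log-likelihood-ratio power analysis, and the population-genetic summaries
(F_ST, Reynolds distance, bootstrapped NJ trees, LD screening) used to
characterise a panel. A Balding–Nichols simulator supplies breed-structured
synthetic data so every stage is testable without access to proprietary chip
genotypes. Bayesian genotypic *clustering* (admixture/K inference) and
mixed-ancestry decomposition are deliberately out of scope.

## The assignment model

### Dirichlet-posterior predictive ("partial Bayesian") likelihood

For a biallelic locus where a reference breed shows $n_a$ alternate alleles
among $n$ observed, the probability of a query genotype is the predictive
probability of drawing its two alleles sequentially from the Dirichlet
posterior with uniform prior $1/k$ per allele ($k = 2$):

$$P(\text{hom alt}) = \frac{n_a + \tfrac12}{n+1}\cdot\frac{n_a + \tfrac32}{n+2},
\qquad
P(\text{het}) = 2\,\frac{n_a + \tfrac12}{n+1}\cdot\frac{n - n_a + \tfrac12}{n+2},$$

and symmetrically for the reference homozygote. These probabilities sum to
one for any counts and are strictly positive even for alleles never seen in
the reference, so multilocus log10 likelihoods are always finite — the
property that makes the method robust for forensic casework where a query may
carry a private allele. The package works in log10 throughout (the
convention of the assignment software this method is usually run in), and
per-individual likelihoods sum over non-missing loci only: a missing call is
marginalised, never penalised, so a degraded assay (e.g. 90 of 96 markers
readable) remains scorable with `n_loci_used` recording how many loci
contributed.

Reference animals scored against their own breed use leave-one-out counts
(both allele copies removed at their observed loci); all other breeds use
full counts. Assignment goes to the highest-likelihood breed; exact ties go
to the lexicographically first tied breed and are flagged — the tie rule
never favours the true breed.

### Exclusion-simulation test

Per reference breed, `n_sim` (default 10,000) genotypes are simulated
locus-independently under Hardy–Weinberg from the breed's *observed* point
frequencies and scored with the same predictive likelihood. The critical
value is the $\lceil \alpha \cdot n_\text{sim}\rceil$-th lowest simulated
log10 likelihood, and a query is excluded iff its likelihood is *strictly*
below it (a tie is not excluded). Two deliberate consequences:

- Queries drawn from the same observed frequencies are excluded at rate
  $\approx \alpha$ by construction — the calibration property the acceptance
  suite verifies.
- Queries from the *population* the reference was sampled from (rather than
  from the reference's estimated frequencies) are excluded slightly more
  often than $\alpha$, because the null distribution is built on point
  estimates that the simulated genotypes fit better than genuinely new
  individuals do. With 30-animal references and 96 loci this inflation is
  roughly 5–10× the nominal rate — visibly the same order as the reference
  study's own exclusion tally. This is a property of the published method
  (point-frequency null, predictive scoring), not an artifact of this
  implementation; we document it rather than "correct" it.

### Forensic pairwise power

For a claimed breed A against alternative B, every reference animal of A and
of B contributes $\log(LR) = \log_{10} L(A) - \log_{10} L(B)$ (leave-one-out
applied in the animal's own breed). Error rates at a test value $t$ come
from a normal approximation fitted to the observed means and SDs:
$\alpha = \Phi\!\left(\frac{m_B - t}{s_B}\right)$ evaluated as an upper tail,
$1-\beta$ analogously for A. The posterior probability of correct
assignment under equal priors is
$\frac{(1-\beta)/\alpha}{(1-\beta)/\alpha + 1}$.

Two numerical choices matter here. First, the *normal* tail is the default
because ~30 animals per breed cannot empirically resolve false-positive
rates of $10^{-7}$; an empirical exceedance-counting mode is available
(`method = "empirical"`) for diagnostics. Second, $\alpha$ is floored at
$10^{-12}$ before forming odds, so reported posteriors of `1` are a
6-decimal rounding convention, never literal certainty. Zero log(LR)
variance raises an error pointing to the empirical mode rather than
returning a fabricated tail.

## Marker ranking and panel selection

Delta for a biallelic locus is $|p_A - p_B|$; the locus score is the mean
over all unordered breed pairs where both frequencies are defined. Pairs
with no observed alleles are *excluded from the mean*, not scored zero —
absence of data is not evidence of similarity — and the number of usable
pairs is reported. Ranking is deterministic: descending score, ties broken
by ascending locus id, undefined scores last. `assignment_curve()` then
traces leave-one-out self-assignment accuracy against cumulative panel size,
the plot used to decide how many markers an assay needs; `select_panel()`
takes a rank prefix, so smaller panels are always nested in larger ones.

The LD screen (`panel_ld_screen()`) computes EM-based $r^2$ for every
same-chromosome pair of mapped panel loci within every breed and reports
pairs exceeding the threshold (default 0.4) in at least one breed.
Informative-marker selection tends to co-opt clustered selected regions, so
a post-hoc redundancy check belongs to the workflow; following the source
workflow, selection itself is purely by delta rank — no LD pruning.

## Population-genetic summaries

- **F_ST**: the Weir–Cockerham (1984) variance-component estimator;
  multi-locus values are ratio-of-sums (the FSTAT convention), monomorphic
  loci contribute zero to both sums, per-locus sample sizes shrink with
  missingness, and loci with fewer than two genotyped individuals in a breed
  are skipped. Small negative estimates are preserved.
- **Reynolds distance**: the frequency-only coancestry form with
  locus-summed aggregation,
  $d = \sum_l (p_{1l}-p_{2l})^2 \big/ \sum_l (1 - p_{1l}p_{2l} -
  q_{1l}q_{2l})$, matching the PHYLIP `gendist` convention and reported
  without the $-\ln(1-\theta)$ transform. The exact variant used upstream of
  the reference study's tree cannot be pinned down from its text; this
  choice is isolated in one function (`reynolds_from_freqs`) so an
  alternative can be swapped.
- **Neighbour joining** is implemented directly (Saitou–Nei with the
  Studier–Keppler update) so that the tie-break (Q-minimum with the lowest
  index pair) and negative-branch handling (clamped to zero at output, with
  the clamped total recorded) are documented and deterministic; trees are
  returned as `ape::phylo` objects. Bootstrap support resamples *loci* — the
  only exchangeable unit in this design — recomputes the Reynolds matrix and
  tree, and maps bipartition frequencies onto the full-data tree rather than
  building a consensus topology.
- **$r^2$** is estimated from unphased genotypes by EM over the four
  haplotype frequencies (only the double heterozygote is phase-ambiguous);
  convergence at $|\Delta \log L| < 10^{-8}$, 1000-iteration cap, flagged if
  unmet; monomorphic loci give an undefined sentinel.

## The synthetic-data generator

`sim_scenario()` describes a Balding–Nichols world: per locus an ancestral
frequency $p \sim U(0.05, 0.95)$, then per breed
$p_b \sim \text{Beta}\!\left(p\frac{1-F_b}{F_b},\,(1-p)\frac{1-F_b}{F_b}\right)$.
A *close pair* shares an intermediate ancestor (drawn with the pair's shared
F) from which both members diverge with a small `F_pair` — emulating a
recently split breed pair. Genotypes are binomial(2, p) within breeds
(exact Hardy–Weinberg), missing calls are masked independently, and optional
admixed individuals draw each allele copy from a partner breed with
probability $1 - m$. One master seed drives deterministic per-stage child
seeds, so every output is bit-reproducible.

The frozen `british_pigs_like` benchmark emulates the reference study's
structure: 14 breeds with its sample sizes (21–73, 446 total), 5000 loci, 2%
missingness, one weakly diverged pair and one strong outgroup. Divergence
parameters were tuned once during development and then frozen: realized mean
pairwise $\theta \approx 0.52$ (target band 0.4–0.6), close-pair
$\theta \approx 0.10$, outgroup mean $\theta \approx 0.68$ — reproducing the
qualitative differentiation structure (grand mean 0.54, Landrace–Welsh 0.10,
Meishan average 0.71) of the study's Table of pairwise F_ST. Empirically,
realized pairwise $\theta$ between two simulated breeds is close to the mean
of their generating F values, which is what the tuning exploits.

What the generator does *not* emulate — and therefore what a green test does
not establish: linkage (loci are independent except for explicitly injected
correlated pairs, so LD-screen behaviour on real clustered selection signals
is only exercised synthetically); the sibling-pair sampling structure of the
real reference panels (individuals are unrelated, so estimator *efficiency*
on related samples is untested); ascertainment bias of chip SNPs; and
genotyping error. Relatedness and ascertainment affect efficiency and
calibration margins, not the correctness of the estimators, which is what
the oracle tests establish.

## QC semantics

The call-rate filter screens loci (default ≥ 0.80) before samples (default
≥ 0.85). "Call rate across all breeds" is ambiguous between an overall rate
and a per-breed minimum; the default is the stricter `per_breed` scope —
preventing breed-specific missingness from masquerading as allele-frequency
divergence in delta — with `overall` available. Because dropping a sample
can retroactively push a locus back under the threshold, the two screens
iterate to a fixed point; the filter is therefore idempotent and the
returned dataset satisfies both thresholds simultaneously. Missing
genotypes are never imputed. The two X-linked panel loci of the motivating
assay are treated as autosomal diploid (sex is not modelled), and
unmapped loci ("Undetermined" chromosome) are allowed but excluded from the
same-chromosome LD screen.

## Design decisions where the design was genuinely open

- **Queries vs reference in exclusion**: null genotypes are simulated from
  *observed* (not leave-one-out) frequencies; leave-one-out applies only to
  the tested individual's own likelihood when it is a reference member.
- **Exclusion calibration target**: the acceptance target draws query
  individuals from the breeds' observed frequencies — the distribution the
  null is built on — which is the reading under which the documented
  "retention ≈ 1 − α" expectation holds; drawing them from the true
  generating frequencies instead yields retention around 99.2% for
  30-animal references (the inflation discussed above).
- **Missing data in likelihoods**: skipped, not penalised (the upstream
  method's handling is undocumented; skipping keeps degraded assays
  scorable and is the conservative choice for log-likelihood ratios).
- **Double cross-validation of held-out samples**: treated as plain queries
  against the full reference (no leave-one-out), since the original
  procedure is not defined precisely enough to reproduce.
- **Config files**: JSON rather than YAML (no YAML parser in the supported
  dependency set); the schema mirrors `pipeline_config()` one-to-one.
- **Multiallelic generalisation**: `delta_locus()` accepts only biallelic
  frequencies in this release; the $\tfrac12\sum_a |p_{Aa} - p_{Ba}|$
  generalisation reduces to $|p_A - p_B|$ for two alleles, which is the only
  case the data model admits.

## Tunable parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `min_locus_call_rate` | 0.80 | within-breed (or overall) locus call-rate floor |
| `min_sample_call_rate` | 0.85 | per-sample call-rate floor |
| `panel_size` | 96 | markers selected by delta rank (one multiplex) |
| `n_sim` | 10,000 | simulated genotypes per breed for the exclusion null |
| `alpha` | 0.001 | exclusion rejection region |
| `thresholds` | 0, 2 | log(LR) test values for the contrast matrices |
| `alpha_floor` | 1e-12 | false-positive floor before posterior odds |
| `bootstrap_reps` | 1000 | locus-bootstrap replicates for tree support |
| `r2_threshold` | 0.4 | LD-screen reporting threshold |

## Known limitations

- Two-hypothesis contrasts only: no composite or multi-breed likelihood
  ratios, no unequal priors, and no mixed-ancestry (crossbred) modelling.
- The normal tail approximation extrapolates far beyond the observed
  log(LR) range; the posterior entries near 1 inherit that model
  assumption (which is why the empirical mode exists for diagnostics).
- Tree supports below ~50% on star-like radiations are expected and
  reproduce the reference study's behaviour, not a defect of the bootstrap.
- The simulator's independence assumptions (loci, individuals) understate
  the variance a real chip panel would show; calibration margins on real
  data will be somewhat wider than the synthetic tests suggest.
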