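---
title: "Demographic inference with gp4pg: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic inference with gp4pg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model space

A demographic model in `gp4pg` is a set of *ecodemes* — named population
units placed on a one-dimensional lattice — plus a time-ordered list of
demographic events.  Each ecodeme is internally structured as a
nearest-neighbour stepping-stone chain of *topodemes* of equal diploid
size, the atomic units that exchange migrants.  This two-level
organisation lets a model express within-population substructure
(several topodemes, internal migration `m_internal`) without introducing
explicit "ghost" populations, while between-population history is
carried by the events:

* **soft splits** — backward in time, two child ecodemes merge into a
  parent at time `T`; forward in time, migration between the children
  decays exponentially after the split,
  \deqn{m(t) = m_{max}\, e^{-\lambda (T - t)/L} +
        m_{min}\,(1 - e^{-\lambda (T - t)/L}),}
  equal to `m_max` at the split and approaching `m_min` as the
  divergence ages.  A hard split is the special case
  `m_max = m_min = 0`.
* **admixture pulses** — an instantaneous transfer of a stated ancestry
  proportion between two coexisting ecodemes;
* **size, deme-count and migration-rate changes** — piecewise-constant
  regime changes on one ecodeme or one pair.

All times are in generations before present.  The exponent of the decay
is expressed per *epoch* of `L` generations with a decay constant
`lambda_decay` (default 1); `L` defaults to 200 generations because the
migration matrix is updated at that interval, so one epoch is the
natural time unit of the decay.  The split tree is validated
structurally (exactly one root, every non-root ecodeme created by
exactly one split, split times decreasing from root to leaves, events
touching only ecodemes alive at their time); `validate_model()` returns
the full list of violations rather than failing on the first.

Because "the distance between adjacent populations is zero", lattice
adjacency alone gates between-ecodeme migration: the decay rate of a
split pair is applied between the facing edge topodemes of the two
ecodemes.  Two-dimensional geography, explicit barriers and selection
are out of scope.

## Simulation

`epoch_schedule()` discretizes a model into piecewise-constant epochs:
boundaries at every event time plus the regular `L`-grid, decay
evaluated at each epoch start, a final open-ended ancestral epoch.  The
compiled structured coalescent (`simulate_dataset()`) simulates each
genomic block as an independent non-recombining genealogy of the sampled
chromosomes over this epoch schedule — migration as lineage jumps at the
backward rates, splits as deterministic slot remaps, pulses as
probabilistic remaps — and drops infinite-sites mutations at the model's
per-bp rate (default 1.61e-8 per generation; generation time 29 years is
used only to convert reported times).  Samples are drawn from the
lattice-central topodeme of each sampled ecodeme, a deterministic
convention.  Within-block recombination is not simulated; blocks stand
in for the quasi-independent genomic fragments left after masking, which
is also the resolution at which the block bootstrap operates.  The
backend is deliberately behind a small surface (model + genome spec +
seed in, site table out) so a different coalescent engine can be
substituted.

Simulator correctness is checked against analytic oracles in the test
suite: the neutral single-population spectrum E[xi_i] = theta/i, the
independence of anciently separated populations, the linearity of
segregating sites in the mutation rate, and the excess shared variation
under migration decay relative to a hard split.

## The summary statistic and fitness

Each population contributes a derived-allele count on exactly two
chromosomes (three states), matching one diploid genome per population.
For n >= 4 populations the summary vector concatenates, over all C(n,4)
population quadruples in lexicographic order, the 79-cell joint spectrum
(3^4 cells minus the two quadruple-monomorphic ones, excluded per
quadruple).  This grows polynomially instead of the 3^n - 2 cells of the
full multidimensional spectrum; for n < 4 (toy fixtures) the full
spectrum is used directly.  Cell order is the base-3 code
`27 c1 + 9 c2 + 3 c3 + c4`; since codes 0 and 80 are dropped, the
retained codes 1..79 index the segment directly.

The fitness of a candidate is the standardized squared error summed over
cells, with per-cell standard errors estimated by resampling the
observed genomic blocks with replacement (1000 replicates by default)
and floored at `epsilon` = 1 count-equivalent so that zero-variance
cells cannot produce infinite errors.

**Comparison scale.**  Simulated and observed spectra are compared as
genome-length-scaled *counts*: simulated cell counts are multiplied by
the ratio of observed to simulated callable length.  Per-segment
proportions are also available, but they are invariant to a joint
rescaling of all sizes, times and inverse migration rates (the
coalescent is scale-free once the total polymorphism level is
discarded), so under proportions absolute split times and Ne are
identified only up to that common factor.  Scaled counts keep the theta
information and make absolute parameters estimable; this is the package
default.

## The evolutionary search

Each iteration, every candidate produces offspring in inverse linear
proportion to its error — the best `s_max` = 8, the worst `s_min` = 2,
rounded half-to-even, everyone `s_max` when the population is
error-degenerate — children are mutated copies, parents and children are
pooled (elitism) and the pool is truncated by rank to the population
size (default 20).  Elitism makes the best-error trace monotone
non-increasing by construction, which the tests assert on every run.
Mutation never alters the split topology: competing topologies enter
through the mixed initial population (round-robin over the supplied
variants) and are resolved by replicate runs and the support table,
because a metaheuristic of this kind is routinely trapped in local
optima.

Mutation operators and their default probabilities: event-time
perturbation (0.6) — mostly local log-normal steps (sd 0.4 on the log
scale) around the current value with occasional global log-uniform jumps
(probability 0.3) across the event's validity bracket, always strictly
inside the bracket (a pure log-uniform over a bracket whose lower end is
near zero spends half its mass at implausibly recent times and stalls
the search); log-normal Ne perturbation (0.4, sd 0.5, clamped to
[100, 1e5]); migration-parameter perturbation (0.3) on `m_max`/`m_min`
or the internal topodeme rate; logit-normal admixture-proportion
perturbation (0.2); addition (0.1) and removal (0.1) of a random
non-split event.  An operator draw that yields an invalid model is
resampled up to 20 times, then the parent is returned unchanged.  The
canonical invasive-weed dispersion schedule (shrinking mutation
magnitudes) is not used; magnitudes are constant within a run.

**Evaluation noise.**  A fitness evaluation simulates the candidate
(`sim_replicates` simulations averaged, default 1 for speed, 2 in the
recovery scenario) and compares against the observed vector.  All
evaluations in a run share one simulation seed (common random numbers):
fitness is then a deterministic function of the model, rankings are
consistent, and elitism cannot freeze a lucky draw.  The residual cost
is a mild overfit to that seed's realization, bounded by roughly one
sigma-unit per cell, which shrinks relative to parameter signal as the
simulated genome grows.

## Identifiability and the recovery scenario

With two chromosomes per population there is almost no within-population
frequency information, so the time of a *young* split is identified only
jointly with the child deme's size (the coalescent depends on t/2Ne;
only the mutational clock on absolute branch lengths breaks the ridge,
weakly at this sample size).  Free post-split migration trades off
against split time in the same direction — a recent split with strong
decaying migration mimics an older, cleaner split.  Deep divergences, by
contrast, are pinned by the total polymorphism level and the
between-group spectrum and recover well.  The built-in
`scenario_recovery3()` therefore declares the deepest split its
recovery-target parameter, starts the competitors at wrong times (400
and 5000 vs true 1200 and 3000 generations) and sizes (1500 vs 5000),
shares the decay parameters with the truth, and disables the
structural add/remove and migration operators so the test measures
parameter recovery within the identifiable class.  At this scale the
true topology wins essentially every replicate and the deep split is
recovered within a factor 2 in >= 80% of seeded runs.

Problem sizes were chosen for single-CPU work: the recovery scenario
simulates a 25 Mb observed genome (500 blocks of 50 kb) and evaluates
fitness on the same genome size with 2 replicate simulations, population
10, 30 iterations, 10 seeds; the trace-monotonicity run uses 4
populations on 4 Mb; the goodness-of-fit checks use 2 populations on
0.6 Mb with 100 simulated replicates.  These are reduced-scale study
conditions; the statistic's behaviour at full scale (eight populations,
tens of Mb, 200 iterations, 40 replicates) is the same algorithm with
more constraints per parameter.

## Observed-data pipeline

`observed_4jsfs()` runs, in order: site-level filters — per-sample depth
>= 5 reads, QUAL >= 20, FILTER == PASS, exclusion of indels and of SNPs
within a 6-bp indel flank, biallelic SNPs only, each drop attributed to
the first failing criterion; region masks — repeats, CNVs, CpG islands
as supplied, genes extended by 20 kb on both sides (strand-agnostic; a
record exactly 20,000 bp past a gene edge is masked, 20,001 bp is
retained); ancestral polarization from the `AA` INFO annotation (counts
flip when the ancestral equals the ALT; sites whose ancestral matches
neither allele are dropped and counted); a callable mask built from
10-kb sliding windows at 2,500-bp steps keeping windows whose
callable-position density exceeds 90% (merged into maximal intervals) —
"density" is the fraction of window positions outside the masks, since a
window cannot be >90% SNPs; and block assignment, by default one block
per maximal callable interval, optionally fixed-width tiles.  VCF
coordinates are 1-based, BED and all internal intervals 0-based
half-open.

The toy fixture (`make_toy_vcf()`) encodes every filter class exactly
once with a sidecar recording the expected survivor set, so the whole
pipeline is checked end-to-end against its construction.

## Goodness of fit

`gof_pca()` simulates replicate datasets from a fitted model, fits
principal components on the simulated spectra only, projects the
observed data (the mean of 40 block-bootstrap replicate spectra of the
observed genome, which stand in for an independent replication set), and
scores it by Mahalanobis distance in the components covering >= 90% of
simulated variance.  "Outlier" is operationalized as the observed
distance exceeding the 99th percentile of the simulated distances — the
visual notion of the observed point falling outside the simulated cloud
made reproducible.  Under the null (observed generated by the same
model at the same genome size) the flag rate is near the nominal 1%; a
tenfold Ne misspecification is flagged in every repeat.

## Known limitations

* No within-block recombination; blocks are fully independent.
* Two chromosomes per population by design of the statistic; young-split
  times are reported but should be read jointly with the child Ne.
* The IWO dispersion schedule is not implemented; mutation magnitudes
  are fixed per run.
* Haplotype-based summaries are not implemented.
* The demes-style YAML export discretizes the decay per epoch; importing
  tools will see stepwise migration.
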