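---
title: "Inferring tumor-initiation dynamics from segregating DNA lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tumor-initiation dynamics from segregating DNA lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionlad)
```

## The observable: Lesion-to-Ancestor Divisions

A pulse of a DNA-damaging mutagen (diethylnitrosamine in mouse liver,
platinum or alkylating chemotherapy in patients) deposits lesions on both
strands of every chromosome of an exposed stem cell. Many such lesions
escape repair for several cell cycles. Because each cell division
segregates the two strands of every chromosome into different daughters,
the number of lesion-bearing chromosome strands in any single descendant
halves, on average, with every division.

When one of those descendants founds a clone — because a lesion at a
driver locus was converted into a driver mutation — the clone's most
recent common ancestor (MRCA, the first cell whose two daughters both
found surviving lineages of the final clone) carries a frozen snapshot of
that dilution. Persistent lesions in the MRCA are replicated
independently in its two daughter lineages, and error-prone translesion
synthesis can install *different* alternate alleles at the same site:
multiallelic variants (MAVs). The fraction of the genome carrying MAVs is
therefore proportional to $2^{-n}$, where $n$ is the number of divisions
between the pulse and the MRCA. We call $n$ the LAD
(Lesion-to-Ancestor Divisions); it is the package's central observable.

The LAD distribution across a cohort of tumors is informative about the
initial growth rate of the nascent clones: a clone whose driver confers a
high selection coefficient tends to fix its MRCA within the first one or
two divisions, while weak drivers wander longer before producing two
jointly surviving daughter lineages.

## The branching-process model

Per generation a stem cell divides into two stem daughters (probability
$b$), one stem and one differentiated daughter ($1 - b - d$), or two
differentiated daughters ($d$). Before driver acquisition the population
is homeostatic, $b = d$; after, the clone grows at rate $1 + s$ with
$s = b - d$ the selection coefficient. The driver locus is tracked as a
duplex with strands in {wildtype, lesion, mutant}, giving the closed
state set {WW, LW, LL, LM, MM}. Per generation a lesion undergoes full
repair (probability $r - u$), mutagenic repair ($u$, writing a mutant
base opposite the lesion and creating a lesion–mutation heteroduplex), or
no repair ($1 - r$); an unrepaired lesion is then replicated error-free
(probability $\epsilon$) or erroneously ($1 - \epsilon$). The
heteroduplex confers full driver fitness by default
(`heteroduplex_fit = TRUE`); requiring a double-strand mutant is
available as a robustness toggle.

`simulate_tumor()` starts from one fully mutagenized cell (LL at every
driver locus), applies repair before the first division — the only path
to LAD $= 0$ — and tracks the genealogy to a horizon. A tumor forms when
driver-carrying cells are present at the horizon. Cells are grouped into
clones by their earliest driver-competent ancestor; the largest clone
wins (ties broken by the seeded RNG), and the LAD is the generation of
the deepest common ancestor of the winning clone's horizon cells. The
winner-takes-the-tumor rule is our reading of "clonal expansion and
competition"; its main visible consequence is quantified below.

Defaults: pre-driver $b = d = 0.25$; post-driver $(b, d) = (s, 0)$;
horizon 25 generations, population cap 4000, at most 1000 initiation
attempts per tumor. Conditional on $s$, the LAD distribution is
essentially independent of how $b - d$ is split (the invariance is
verified by a chi-square homogeneity test at $10^4$ tumors per split);
the residual second-order dependence enters only through clone-size
fluctuations during competition.

## The analytic LAD distribution

For a single driver, `lad_pmf()` computes the LAD distribution without
simulation, by dynamic programming on the duplex-state chain coupled to
the branching process:

* per-state extinction probabilities solve the multitype fixed-point
  equation; the post-driver single-lineage extinction probability is
  $q = d/b$ (`extinction_prob()`);
* conditional on a driver-competent lineage surviving, each division is
  the both-daughters-survive split with probability
  $b(1-q)^2/(1-q) = s$, so the per-clone MRCA wait is geometric,
  $P(k) = s(1-s)^{k-1}$ (`mrca_wait_pmf()`). We re-derived and
  simulation-verified this before relying on it — on the single-clone
  stratum, where it actually applies;
* survival is evaluated at the same finite tracking horizon the
  simulator uses ("driver cells present at the horizon"), not in the
  eternal limit: at small $s$ the difference is visible in the tail,
  because lineages that still carry an unconverted lesion at the horizon
  have not yet formed a tumor;
* a both-surviving split at a *non-driver* cell founds two competing
  clones rather than fixing the MRCA. About 20% of formed tumors at the
  reference parameters contain two such clones. The winner is the larger
  clone at the horizon; we model the win probability through the
  almost-sure limit $W$ of the normalised clone size, approximated as a
  Gamma variable with the exact branching-process variance
  $\mathrm{Var}(W) = (4b + 1 - b - d - (1+s)^2)/((1+s)^2 - (1+s))$,
  which gives a closed-form (regularised beta) win probability as a
  function of the founding-time gap. A naive version that ignored
  competition and used eternal survival disagreed with the simulator
  detectably at $s = 0.3$; the present form matches it within
  Monte-Carlo error across the tested parameter grid.

Truncation mass beyond `n_max` is reported and either renormalized or
lumped into the top bin (`tail = "lump"`), the latter matching empirical
distributions whose LAD values are capped.

## Estimating LAD from mutation tables

`build_segments()` bins a mutation table (TSV or VCF; multiallelic ALT
records split with shared positions; 0-based half-open coordinates
internally) into 1 Mb windows, counting MAV sites once. A three-state
hidden Markov model (`decode_lesion_states()`) labels each bin with 0, 1
or 2 lesion-bearing homologs: MAV counts are Poisson with mean
$\lambda \times \text{copies} \times \text{bin-width exposure}$, and
transitions between adjacent copy numbers model mitotic-recombination
breakpoints with per-bin probability $1 - e^{-\rho \cdot \text{bin}}$.
$\lambda$, $\rho$ and the stationary prior are estimated by EM
(10 rounds by default; 2 rounds proved under-converged). Chromosome
boundaries reset the chain to the prior.

Two numerical choices matter. First, the emission mean scales with the
actual bin width, otherwise the short terminal bin of every chromosome
biases the fit. Second, a homogeneous genome cannot distinguish "all
bins one copy at rate $2\lambda$" from "all bins two copies at rate
$\lambda$": the EM is therefore run from three bracketing $\lambda$
starts, solutions are compared by likelihood, and ties (within 2 log
units) are broken toward the solution consistent with binomial homolog
retention — occupancy $(1-q)^2, 2q(1-q), q^2$ has no all-state-2
member, so the all-state-3 reading is the physical one.

`estimate_lad()` converts the length-weighted posterior occupancies
$(p_1, p_2, p_3)$ into the lesion-strand fraction
$\hat f = (p_2 + 2 p_3)/4$ (retained lesion strands out of the four
strands of a homolog pair) and $\hat n = \mathrm{round}(-\log_2 \hat f)$,
clamped to $[0, n_\max]$. LAD 0 and LAD 1 both give $p_3 \approx 1$;
they are separated by the chromosome-scale Watson–Crick asymmetry of
non-MAV mutations (each homolog's mutations polarize to the strand it
inherited at the first division, so LAD $\geq 1$ genomes are asymmetric,
LAD 0 genomes are not; threshold 0.25 on the count-weighted mean
absolute pyrimidine/purine asymmetry) and by the per-copy MAV density,
both logged in the result. A chromosome bootstrap supplies an interval.

What the estimator cannot do: the realized retained fraction at true
LAD $n$ is a binomial draw over 40 homologs, with $\log_2$ spread
$\approx 0.4$ at $n = 3$ and $\approx 0.9$ at $n = 5$. No estimator of
the $2^{-n}$ observable can recover $n = 5$ exactly much more than half
the time on a 20-chromosome karyotype; the estimator tracks the realized
fraction essentially perfectly, and cohort-level accuracy is high
because realistic LAD distributions concentrate at 0–2.

## Fitting the LAD distribution and the minimum selection coefficient

`lad_distribution()` tabulates per-tumor LADs with exact Garwood Poisson
intervals (`poisson_ci()`: $\chi^2$-quantile inversion). `fit_grid()`
accepts a parameter combination iff the model-expected count
$N \cdot \mathrm{pmf}(n)$ lies inside the Poisson band of the observed
count for *every* bin $n \leq n_\max$, and reports `min_s`, the smallest
selection coefficient among accepted combinations. Because the
acceptance is a simultaneous statement over $k = n_\max + 1$ bins,
per-bin 95% intervals would cover the generating model jointly only
~81% of the time at $N = 371$; the default band is therefore Bonferroni
adjusted (per-bin level $1 - 0.05/k$), which restores $\geq 95\%$ joint
truth coverage while remaining a conservative acceptance rule
(`ci_adjust = "none"` recovers the per-bin-95% variant). Default grids:
$s \in \{0.05, \ldots, 0.95\}$ (step 0.05), $r \in \{0, \ldots, 0.8\}$
(step 0.1), $u \in \{0, \ldots, \min(r, 0.55)\}$ (step 0.05),
$\epsilon \in \{0, \ldots, 0.9\}$ (step 0.15). Multi-driver fits use the
simulation model (no analytic multi-driver pmf is attempted) and are
intended for one or two drivers.

## Sparse samples: the chromosome-count bound

Post-chemotherapy metastatic samples and phylogeny nodes carry few MAVs
(often 1–15), too few for the HMM. `simulate_chrom_counts()` models the
number of distinct chromosomes hit by $M$ lesion-marked sites as a
function of LAD: after the first post-pulse division every homolog
carries one lesion strand, each further division retains it with
probability 1/2 (segment-wise under mitotic recombination, which can
only spread retention), and sites land on retained segments with
probability proportional to chromosome weights (length by default;
measured mutability should be supplied for real data).
`lad_bound()` declares a candidate LAD consistent when the observed
chromosome count falls in the central 95% of its simulated distribution
— our concrete version of a comparison the source analyses made
visually — and reports the best-supported LAD and the upper bound.
Counting is per chromosome, not per homolog (a flag switches).

## MAV statistics in bulk tumors

`expected_independent_mavs()` computes the birthday-problem expectation
for sites hit twice independently with distinct alternates — per-context
Poisson opportunities when a context column is available, the uniform
closed form $\binom{N}{2}/G \cdot P(\text{distinct})$ as cross-check —
and flags samples with more than tenfold excess.
`mav_spectrum_similarity()` compares the observed MAV-pair profile (96
unordered alternate-pair channels: 32 pyrimidine-centered contexts
$\times$ 3 pairs) against a mutagen signature's pair profile and against
the independent co-occurrence expectation (the product measure of the
sample's own spectrum), by cosine similarity.
`phasing_trend_test()` is the Cochran–Armitage trend test
(`stats::prop.trend.test`, integer scores) on the proportion of phased
MAVs whose two alternates sit on the same parental allele across ordered
enrichment categories; phasing requires a germline heterozygous SNP
within 300 bp, which is also why independently co-occurring same-allele
pairs are *under*-detected.

## Lesion footprints on single-cell phylogenies

`read_tree()` couples an `ape` tree with a branch-mutation table (each
mutation assigned to one branch by its child node). `detect_footprints()`
finds MAVs (distinct alternates at one site on distinct branches; the
lesion node is the MRCA of the event branches' parents) and PVVs
(identical alternate on branches inconsistent with a single origin;
ancestor–descendant pairs are flagged ambiguous rather than guessed; the
repair node is the deeper event node). `wc_anticorrelation()` tests the
single-division-sister footprint: complementary lesion strands inherited
from a pulsed parent polarize the two subtrees' mutations oppositely,
chromosome by chromosome, giving a negative Spearman correlation of the
per-chromosome strand asymmetries (one-sided).
`lesion_node_statistics()` compares expansion below lesion nodes with
controls matched on root distance (±10% in mutations, excluding
relatives of lesion nodes) and PVV lesion-to-repair distances with
topology-matched control pairs.

## The synthetic-data generators

All tests run on generated data with a serialized truth bundle.

* `gen_tumor_cohort()` emulates the mutagenized mouse cohort at desk
  scale: 20 chromosomes, 200 Mb, 5000 mutations per tumor (the real
  system carries ~59,000 on a 2.7 Gb genome; load and karyotype are
  parameters), a DEN-like stand-in spectrum (60% T>N, 25% C>T, 15%
  other — the published trinucleotide profile is not reproduced),
  MAVs at 3 per Mb of retained lesion strand, and mitotic recombination
  at 0.05 per chromosome per division. True LADs come from the
  simulator at the single-driver reference parameters
  $(s, r, u, \epsilon) = (0.6, 0.2, 0.05, 0.15)$.
* `gen_metastatic_sample()` plants 1–15 signature-shaped MAVs on
  LAD-retained chromosomes over an unpolarized background, with
  germline het SNPs and a distance-decaying same-allele detection bias.
* `gen_pulsed_phylogeny()` builds a colony phylogeny from a clone plan
  (default: two mutagen pulses two divisions apart above a nested pair
  of expansions, plus an unexposed control clade) and propagates each
  lesion through the division-resolved genealogy: strands co-segregate
  per chromosome, an unrepaired lesion survives each division with
  probability 1/2 per lineage, and an error-prone replication fixes its
  mutation one division later in the sister lineage of the lesion path —
  which is exactly how one lesion paints different branches with MAVs
  and PVVs. Chromosomes are represented as single duplexes by default;
  the diploid option roughly halves the sister-branch anticorrelation
  signal because the two homologs segregate independently.

What the generators do not emulate: sequencing error and read-level
artifacts, copy-number change and purity, chromosome-specific mutability
(weights are length-proportional), signature mixtures within one tumor,
and phylogeny reconstruction error. Passing tests therefore validate the
inference logic, not robustness to those nuisances.

## Problem sizes and reproducibility

The shipped tests use the desk-scale study conditions throughout:
tracking horizon 15 with cap 1500 for simulator/analytic comparisons
($10^4$ formed tumors per grid point), 120–371 tumors per synthetic
cohort, $10^4$ replicates for chromosome-count distributions, and 1000
null replicates for test-size calibration. Every generator is
deterministic given its seed; `scripts/acceptance.R --seed N --out f`
re-runs the full pipeline from scratch and writes the headline numbers
as JSON.
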