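---
title: "Simulating tumor evolution, metastasis and DNA-seq data with oncosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating tumor evolution, metastasis and DNA-seq data with oncosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncosim)
```

## Scope and design

`oncosim` forward-simulates the somatic evolution of cancer cell
populations distributed over anatomical sites, then resolves sampled cells
into a fully annotated single-cell lineage and emits DNA-seq-style data.
Its purpose is ground truth: every output (trees, migration graph,
profiles, counts, sequences) is generated by an explicit stochastic model
whose state is fully recorded, so method benchmarks can score against the
exact history that produced the data.

Two properties shape the design. First, selection is *genotype-driven*:
fitness is a deterministic function of a cell's copy-number profile and
SNVs under a site-specific landscape, so selective sweeps, parallel
evolution across sites, and genotype-biased seeding arise mechanistically
rather than by construction. Second, agents are *clones*, not cells: all
cells sharing an identical driver sequence have identical division,
death, mutation, and migration probabilities, so the population can be
advanced with a handful of binomial draws per clone per generation. This
is what makes simulating millions of cells tractable; the price is that
passenger mutations and cell-level variability cannot exist during the
forward pass and are reintroduced afterwards (see *Stage 2*).

## The forward model

### Genome representation

A genome is a multiset of chromosome strands; a strand is an ordered
vector of region identifiers plus the SNVs it carries. Regions are
fixed-length bins (default 1 Mb, 10 per arm, 10 chromosomes — 200 regions)
and are the resolution of the copy-number profile; breakpoints finer than
a region, structural variants, indels, and breakage–fusion–bridge cycles
are out of scope. Each region carries one gene-class label: oncogene (OG,
default 10% of regions), tumor suppressor (TSG, 10%), essential (5%), or
neutral.

Five mutation mechanisms act on strands:

* **SNV** — a single base substitution at a uniform position; phased to
  the strand (and strand position) it lands on.
* **Segmental gain/loss** — a contiguous slice of regions is duplicated
  *in tandem* (inserted immediately after the original) or deleted. Slice
  lengths are geometric with configurable mean (default 5 regions),
  breakpoints uniform along the strand. Multi-copy amplifications arise
  from repeated events.
* **Arm missegregation** — a new strand is created carrying one arm's
  regions of the target strand, or those regions are lost.
* **Chromosome missegregation** — a whole strand is duplicated (with a
  fresh strand identity) or lost.
* **WGD** — every strand is duplicated.

SNVs have physical copying semantics: an SNV inside a duplicated slice (or
on a duplicated strand) is co-duplicated, an SNV inside a deleted slice is
dropped. Internally SNVs are keyed to their position slot on the strand,
which keeps these semantics exact even after repeated overlapping events;
the external key remains (region, offset, strand).

Every event is appended to the genome's log with the coordinates actually
used, and strand identifiers are assigned deterministically, so replaying
a log on a fresh diploid founder reproduces the genome exactly. This
replay identity is the package's central internal oracle and is enforced
by property tests over random event sequences.

Mutant daughters face viability checkpoints and die immediately on
failure: homozygous deletion of any essential region, mean total copy
number above 8, any region above 10 copies, or more than 2 WGDs. These
bounds are configurable; they are modeling choices that keep profiles in
the biologically observed range, not measured constants.

### Selection

Each site has a multiplicative landscape of per-region coefficients
$\delta_r$: OG coefficients are drawn $U(1, 1+s_{\max})$, TSG
$U(1-s_{\max}, 1)$ (default $s_{\max} = 0.1$), neutral and essential
regions have $\delta = 1$. A stored coefficient of 0 is interpreted as the
no-effect sentinel and mapped to 1, since a literal multiplicative zero
would contradict the intended "neutral" meaning. Three models convert a
genome to fitness:

* **region**: $f = \prod_r \delta_r^{\,c_r - 2}$ with $c_r$ the total copy
  number — diploid fitness is exactly 1, OG gains and TSG losses raise
  fitness, their converses lower it.
* **arm**: $f = \prod_A \delta_A^{\,\bar c_A - 2}$ with $\bar c_A$ the
  *mean* copy number over the arm (so sub-arm events contribute
  fractionally). We define the arm coefficient as the **product** of the
  arm's per-region coefficients, $\delta_A = \prod_{r \in A} \delta_r$.
  This is the unique choice under which the arm model agrees exactly with
  the region model whenever events are whole-arm (if all regions of an arm
  share $\delta$, a whole-arm gain gives $\delta^{n_A}$ under both
  models), and it makes $\delta_A$ reflect the OG/TSG balance of the arm:
  an arm dominated by oncogenes has $\delta_A > 1$. An arm-mean
  (geometric-mean) definition was considered and rejected because it
  breaks that consistency identity.
* **hybrid**: the region model times one multiplier per region holding at
  least one driver SNV — $\delta_r$ if $\delta_r > 1$ (oncogene
  activation), $1/\delta_r$ if $\delta_r < 1$ (tumor-suppressor
  inactivation, i.e. an SNV knockout acts like losing the remaining
  effect), and a penalty $\varepsilon$ (default 0.95) for essential-class
  regions. Multiple SNVs in a region count once. Setting
  $\varepsilon = 1$ removes the model's only coefficient-independent
  effect.

Site-to-site divergence is controlled by one parameter $d \in [0, 2/3)$:
per site each non-neutral effect is rescaled,
$\delta^{(s)} - 1 = (\delta - 1)(1 + \tfrac{3}{2} d\, z)$ with
$z \sim U(-1, 1)$. The $\tfrac32$ factor calibrates the generator so that
the expected absolute difference of a coefficient between two sites equals
$d\,|\delta - 1|$ — i.e. sites differ in their selection coefficients by
$d$ (default 20%) relative to the effect size — while the OG/TSG direction
is preserved at every site (hence the $2/3$ bound). The calibration is
itself checked by a Monte-Carlo test against the generator.

### Growth and the division probability

Cells live in discrete generations. A cell completes its lifespan in a
generation with probability $\tau$ (the turnover rate; $\tau = 1$ is a
fixed one-generation lifespan, $\tau < 1$ the memoryless discretization of
exponential lifespans with mean $1/\tau$). A completing cell divides with
probability

$$p = \operatorname{clamp}\!\left(\frac{f}{\bar f}\cdot
\frac{1 + r(1 - N/K)}{2},\; 0,\; 1\right)$$

and dies otherwise. $\bar f$ is the exact population mean fitness at the
site, recomputed each generation from clone sizes; $N$ and $K$ are the
site's population and carrying capacity, each site running its own
logistic clock from first colonization. The functional form is chosen so
that a neutral population satisfies the logistic recursion
$E[N'] = N(1 + r(1 - N/K))$ exactly, capacity is a stationary point
($p = 1/2$ at $N = K$, for $\tau < 1$ growth scales as $\tau r$), and
selection is proportional: a clone's expected per-generation growth
advantage equals its relative fitness. With $K = \infty$ and fixed $f$
this reduces to a classic branching process with survival probability
$(2p-1)/p$, which is one of the calibration checks.

Defaults $r = 0.4$ per generation and $K = 10^5$ cells give tumors that
reach the default detection threshold of $5\times 10^4$ cells in tens of
generations; these are deliberately desk-scale populations (real tumors
reach $10^6$–$10^9$ cells) chosen so that complete multi-site simulations
run in seconds — the dynamics, not the absolute cell count, are the object
of study, and both $K$ and the threshold scale up if needed.

### Mutation during the forward pass

Driver rates are per division, per daughter, and constant across lineages
(defaults: SNV $10^{-4}$, segmental $10^{-4}$, arm missegregation
$5\times10^{-5}$, chromosome missegregation $5\times10^{-5}$, WGD
$10^{-5}$). A mutant daughter immediately founds a singleton clone — the
clone definition (identical driver sequence) forces this — with the
mechanism drawn proportional to the rates and coordinates uniform over
valid targets (strands weighted by length for SNV/segmental draws). At
most one driver per division is allowed; at these rates the probability of
two is second-order. Inviable daughters are rejected and counted as dead.

### Migration

Each surviving cell migrates from site $a$ to $b$ with probability
$\min(1, p_{\text{base}}/d_{\text{eff}}(a,b))$ per generation. The
*static* model uses a fixed distance matrix (drawn $U(1, d_{\max})$ when
not supplied) — an organotropism prior. The *genotype* model sets
$d_{\text{eff}} = d(a,b)\cdot\max(\phi,\, 1/f_b(G))$ where $f_b(G)$ is the
cell's fitness under the *target* landscape and $\phi$ (default 0.1) a
floor: the minimal form that is per-cell, monotone decreasing in
target-site advantage, and reduces to the static model for the diploid
founder ($f_b = 1$). Clone-level migration is binomial thinning, applied
target-by-target from the post-birth counts so that at most a clone's
snapshot count can leave a site in one generation; migrating cells carry
their genome unchanged and are re-evaluated under the destination
landscape. Cell counts are conserved by construction, and with one site or
$p_{\text{base}} = 0$ the machinery is provably inert.

### Termination, restarts, determinism

The run terminates when every site simultaneously holds the detection
threshold (with migration disabled, only colonized sites count — otherwise
a no-migration multi-site run could never finish). Exceeding
`max_generations` is an error naming the lagging sites. Total extinction —
likely when starting from a single founder cell, since the extinction
probability of the supercritical process is $(1-p)/p$ — triggers a restart
with seed `seed + attempt − 1`, keeping runs reproducible. All randomness
flows through R's RNG from explicit seeds; the pipeline derives one
substream seed per stage from the master seed, so enabling or disabling a
late stage never perturbs earlier ones, and two runs with the same seed
produce byte-identical outputs (checked file-by-file in the tests).

## Stage 2: sampling, coalescent resolution, passengers

Cells are sampled per site at the final generation, multinomially with
probabilities proportional to final clone sizes. The clone tree is the
union of the observed clones' root paths with unobserved non-branching
clones contracted into edges (their founding events concatenated in birth
order); if the founder itself is unobserved and non-branching it is
contracted too, so a single observed clone yields a single-node tree
carrying its full driver history.

Within each clone of that tree, entering lineages — the clone's sampled
cells (entering at the final generation) and the founder lineages of its
child clones (entering at the child's birth generation, the founding
division) — are resolved by a discrete-generation coalescent over the
clone's *recorded* total size $N_c(t)$: walking backwards, $j$ active
lineages merge with probability $\binom{j}{2}/N_c(t)$ per generation, at
most one merger per generation, with forced mergers whenever
$N_c(t) < j$; lineages reaching the clone's birth generation merge at the
founding cell (producing zero-length internal edges — the tie-break for
simultaneous merges is a uniformly random pair). Size history is recorded
every generation, which makes this coalescent exact with respect to the
forward pass at the cost of memory linear in generations × live clones.
A clone resident at several sites uses its total size across sites; the
within-clone coalescent does not distinguish site substructure. With
constant $N$ and two lineages the pairwise coalescence time is
Geometric($1/N$), which the calibration suite verifies by simulation
(mean and Kolmogorov–Smirnov).

Passenger mutations are then added top-down. Per edge of length $\ell$
generations, $\mathrm{Poisson}(\nu\ell)$ passenger events are drawn
(defaults: SNV $\nu = 0.02$, segmental $0.002$ per generation — passenger
point mutations dominate, and large-scale passengers such as WGD or
missegregations are excluded by default because they would be
fitness-relevant in any plausible landscape). Passenger times are uniform
on the edge and *interleaved chronologically* with the edge's inherited
driver events; all events are applied to the running genome so every
node's genome equals its parent's genome plus the edge's events. Because a
passenger deletion can remove a strand that a later driver event (recorded
during stage 1, without passengers) references, driver replay in this pass
is tolerant — an event whose target no longer exists is skipped, and SNV
occurrences are re-resolved against the current state — and each edge then
stores the events *as actually applied*. Leaf-genome realization is
therefore an exact, strict replay of the stored edge lists from a diploid
founder, and the tests assert bit-identity between replayed and stored
genomes. Passenger events never feed back into fitness or the stage-1
record, and they bypass viability checkpoints (a knowingly simplified
choice: rare lethal passengers are not culled).

## Data generation

Profiles are emitted as allele-specific copy-number matrices
(cells × regions) and an SNV matrix of mutated-copy multiplicities over
the union of loci. Read counts follow the standard single-cell CNV noise
model: cell $i$, region $j$ has rate
$\lambda_{ij} = R_i\, c_{ij} b_j / \sum_k c_{ik} b_k$ with a shared
lognormal bin bias $b_j \sim \text{lognormal}(0, \sigma)$ (default
$\sigma = 0.1$) and negative-binomial dispersion (default $\infty$, i.e.
Poisson). Bulk mode forms the pseudobulk profile
$(1-\rho)\,\overline{c}_j + 2\rho$ with a diploid normal fraction $\rho$
and draws one row of counts at the configured depth; variant-allele read
counts per SNV locus are available as binomial draws at the locus's
average multiplicity over copy number. Expected counts are linear in copy
number at fixed cell — the calibration suite recovers the regression slope
$R/\sum_k c_k$.

For sequence realization each region maps to a contiguous interval of its
chromosome's reference (unused tail ignored); a strand's sequence is the
concatenation of its regions' reference substrings with SNVs applied as
deterministic transitions (A↔G, C↔T), so sequences are reproducible
without storing alternate alleles. The package writes per-cell FASTA and a
coverage manifest (total cell coverage apportioned over strands by
length) and can shell out to any short-read simulator via a command
template; read simulation itself — error models, quality strings — is
deliberately not reimplemented, and without a configured tool the
interface degrades to manifest-only mode with a warning.

## What the simulation does and does not emulate

The generator produces realistic *clonal structure*: selective sweeps,
site-specific adaptation, seeding and re-seeding patterns, copy-number
profiles with WGD/missegregation signatures, and coalescent-correct
within-clone genealogies. It does **not** model the tumor
microenvironment (resources, immunity, hypoxia), intra-tumor spatial
structure, treatment, epistasis or interactions between mutations,
lineage-varying mutation rates, or sub-region breakpoints. Passing tests
therefore certify the implemented stochastic models and their
calibrations — not that any particular parameterization reproduces a given
real cohort; parameters are exposed precisely so users can fit them to
their setting.

## Numerical and degenerate-case choices

* Coordinates are 0-based with half-open slices `[start, start+length)`;
  segmental events truncate at the strand end; fully emptied strands are
  removed from the genome.
* A duplicate SNV site raises a typed condition and the caller re-draws
  (bounded retries, then the daughter is rejected).
* Fitness is computed in log space ($\exp\sum (c_r - 2)\log\delta_r$), so
  products over hundreds of regions neither underflow nor lose precision.
* Nonpositive fitness reaching the division step is an internal error —
  viability must cull such genomes first.
* Empty samples, single-clone trees (written as degenerate Newick), zero
  passenger rates, all-zero count profiles, and single-site networks are
  all defined, tested paths.
* The neutral-growth calibration starts replicates from 100 founder cells
  rather than one: with a single founder, conditioning on non-extinction
  (the engine restarts) inflates the early conditional mean well above the
  unconditional logistic recursion, whereas at 100 cells the extinction
  probability is negligible ($\approx (3/7)^{100}$) and the recursion is
  the correct oracle. Problem sizes in the calibration suite ($10^4$
  branching lineages, 20 logistic replicates, 2000 coalescent replicates,
  100 replay sequences, 200 read-count cells, three-site pipeline runs at
  the default $5\times10^4$-cell threshold) were chosen to make
  Monte-Carlo error small relative to each tolerance while keeping the
  whole suite fast.

## Known limitations

Clone-level bookkeeping cannot represent within-clone fitness variance by
construction. The within-clone coalescent ignores site substructure of
multi-site clones and enters child-founder lineages at the child's birth
generation (residence in contracted singleton intermediate clones is
absorbed into the nearest kept ancestor's coalescent). Passenger CNAs can,
rarely, erase the substrate of a recorded driver event, which is then
skipped on that lineage — the stored per-edge event lists remain exact.
SNV multiplicities after a tandem duplication count physical copies; an
SNV arising *after* the duplication on one copy is distinguishable
internally but collapses to its (region, offset) key in exported
profiles.
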