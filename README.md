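# oncosim

Agent-based simulation of tumor evolution, metastasis, and single-cell
DNA-seq data under genotype-driven selection.

Benchmarking methods that reconstruct tumor evolutionary histories —
copy-number callers, single-cell phylogeny methods, migration-history
inference — requires simulated data with known ground truth. Most
simulators generate cell lineages under a neutral coalescent or a simple
birth–death process, which cannot express the clonal selection that drives
real tumor progression and metastasis. `oncosim` instead simulates tumor
populations forward in time as an agent-based branching process in which a
cell's division probability depends on its genotype, its anatomical site,
and the local population density, and cells migrate between sites at
genotype- and organotropism-dependent rates. The package is aimed at
developers of tumor-phylogenetics and CNV-analysis methods who need
realistic, fully ground-truthed single-cell or bulk DNA-seq datasets.

## Model

**Genome.** A cell genome *G* is a multiset of chromosome strands, each an
ordered list of fixed-length regions, plus a set of phased SNVs. Five
mutation mechanisms act on it: SNVs, tandem segmental amplifications and
deletions, chromosome-arm missegregation, whole-chromosome missegregation,
and whole-genome duplication (WGD); the latter three create or remove whole
chromosomal strands. Mutant cells pass viability checkpoints (no
homozygous loss of an essential region, bounded mean and per-region copy
number, bounded WGD count) and die immediately on failure.

**Selection.** Each anatomical site *a* carries a multiplicative fitness
landscape assigning a selection coefficient δ to every region (δ > 1:
oncogene, δ < 1: tumor suppressor, δ = 1: neutral). Under the *region*
model a cell with total copy numbers *c<sub>r</sub>* has fitness

  *f* = ∏<sub>r</sub> δ<sub>r</sub><sup>(c<sub>r</sub> − 2)</sup>

The *chromosome-arm* model works on arm-level coefficients
δ<sub>A</sub> = ∏<sub>r∈A</sub> δ<sub>r</sub> with mean arm copy number as
the exponent, and the *hybrid* model adds per-region SNV multipliers
(δ<sub>r</sub> for an oncogene hit, 1/δ<sub>r</sub> for a tumor-suppressor
hit, a penalty ε for essential regions). The per-generation division
probability couples relative fitness to logistic growth:

  *p* = clamp( (f / f̄) · (1 + r(1 − N/K)) / 2, 0, 1 )

so a neutral population follows the logistic recursion
N′ = N(1 + r(1 − N/K)) in expectation, and the stationary value at
carrying capacity is 1/2.

**Migration.** A cell migrates from site *a* to *b* with probability
p<sub>base</sub> / d(a,b). In the *static* model d is a fixed organotropism
distance matrix; in the *genotype* model d shrinks (down to a floor) in
proportion to the cell's fitness under the *target* site's landscape, so
cells pre-adapted to a site seed it preferentially.

**Two-stage resolution ("down–up–down").** Stage 1 simulates agents at the
clone level (a clone = cells sharing an identical driver sequence),
recording per-generation clone sizes, until every site holds the detection
threshold. Stage 2 samples cells per site, traces the clone tree backwards,
resolves multifurcations with a discrete-generation coalescent whose rate
at generation *t* is C(j,2)/N<sub>c</sub>(t) over the recorded clone sizes,
and finally adds passenger mutations in a top-down traversal of the
resolved single-cell lineage.

**Outputs.** Clone tree and cell lineage tree (Newick, branch lengths in
generations), migration graph and event log, allele-specific copy-number
and SNV profiles, single-cell or pseudobulk read counts (negative binomial
with shared lognormal bin bias; Poisson as the no-overdispersion limit),
and per-cell mutated reference FASTA plus a coverage manifest for any
external short-read simulator.

## Worked example

A three-site metastatic simulation at the default 50,000-cell detection
threshold, sampling 100 cells per site:

```r
library(oncosim)
cfg <- default_config()
cfg$migration$n_sites <- 3L
run_pipeline(cfg, seed = 7, outdir = "example_out")
```

`example_out/record.json` from this exact call:

```json
{
  "seed": 7,
  "generations": 80,
  "attempts": 1,
  "n_clones": 1760,
  "final_cells_per_site": [100345, 55652, 94441],
  "observed_clones": 5,
  "n_leaves": 300,
  "n_snv_loci": 372,
  "migration_events": 22
}
```

The run took 80 generations; 1,760 clones were ever created, of which 5
are ancestors of the 300 sampled cells; the sampled cells segregate 372
SNV loci. `migration_graph.tsv` summarizes the 22 realized migrations:

```
source  target  n_events  n_cells  clone_ids
1       2       8         9        1,96
1       3       9         10       1,96
2       1       1         1        1
3       1       3         4        1
3       2       1         1        1
```

Site 1 (the primary) seeded sites 2 and 3, with some re-seeding back —
the migration pattern a migration-history inference method would be asked
to recover. `cnp.tsv` holds one row per sampled cell of allele-specific
copy numbers (`maternal|paternal` per region), `cell_lineage.nwk` the
binary single-cell tree with branch lengths in generations, and
`counts.tsv` the simulated per-region read counts.

The same pipeline is available from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("exec","oncosim",package="oncosim"))') \
    run --config my_config.yaml --seed 7 --outdir example_out
```

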