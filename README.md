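# vhnet

Mining immunization time courses for antigen-reactive antibody lineages.

When an animal is immunized, B cells carrying antigen-reactive receptors
proliferate preferentially and diversify their immunoglobulin genes by
somatic hypermutation and (in chicken) gene conversion. Both signatures are
visible in bulk repertoire sequencing of the heavy-chain variable domain
(V<sub>H</sub>): an antigen-reactive clonal lineage gains **new unique
V<sub>H</sub> sequences** and **read share** over successive bleeds. `vhnet`
implements the computational side of that screen for R users working with
AIRR-seq style amplicon data:

1. **Preprocess** merged amplicon reads: primer annotation/trimming
   (sliding Hamming match at both read ends), `qXpY` quality filtering
   (default `q20p100`: every base ≥ Q20), and greedy abundance-ranked error
   correction, yielding unique V<sub>H</sub> sequences with per-time-point
   read counts.
2. **Cluster** the pooled sequences into homology *components*: vertices are
   unique V<sub>H</sub> sequences, edges connect pairs whose Levenshtein
   distance LD(u, v) ≤ t, and components are the connected subgraphs —
   putative clonal lineages. Pairs are enumerated with length bucketing, a
   q-gram lower-bound screen and banded early-exit dynamic programming, so
   the full distance matrix is never materialized.
3. **Select the threshold t** with the HCDR3 ratio
   r(C) = |unique HCDR3 peptides in C| / |vertices in C|,
   where HCDR3 is the heavy-chain CDR3 peptide between the conserved second
   cysteine and the W-G-x-G junction tryptophan. Coherent lineages have low
   r; unrelated sequences lumped together push r toward 1. The selected t
   maximizes the number of vertices in components with r < 0.3.
4. **Rank candidates** by clonal dynamics. With clonal frequency
   f(v, t) = reads(v, t) / total reads(t) and a component's average
   frequency ā(C, t) = mean over members, candidates must grow by at least
   `min_delta_vertices` active vertices and a ≥ `min_fold_freq`-fold change
   in smoothed ā from the first to the last time point, ranked by the
   rank-sum of the two changes.

A seeded simulator (`simulate_repertoire()`) generates complete synthetic
immunization time courses — germline-derived founder lineages, point-mutation
daughters biased away from the CDR3, clonal expansion, per-base sequencing
error, FASTQ output — together with per-read ground truth, so the whole
pipeline is testable without external data.

## Worked example

```r
library(vhnet)

# a synthetic immunization time course: 20 lineages, 3 of them expanding
# 10-fold by week 5, ~20,000 reads over 4 bleeds
cfg <- sim_config(seed = 1)
sim <- simulate_repertoire(cfg, "sim_out")

run <- run_pipeline(run_config(fastq = sim$fastq, outdir = "run_out"))
print(run)
#> VH repertoire pipeline run
#>   unique sequences: 2545
#>   selected LD threshold: 4 (31047 edges)
#>   components: 20 (0 singletons excluded, 20 retained)
#>   candidate components: 3, 2, 1

# against the simulator's ground truth
rec <- lineage_recovery(run$components, run$repertoire, sim$truth)
rec$ari
#> [1] 1
```

The run found 2,545 unique V<sub>H</sub> sequences, chose the smallest
distance threshold that maximizes vertex mass in HCDR3-coherent components,
reconstructed exactly the 20 planted lineages (adjusted Rand index 1 against
the per-read truth labels), and ranked the three expanded lineages —
components 3, 2 and 1 — as the top candidates. `run_out/` holds the
AIRR-style sequence table, the edge list and GraphML graph, component
membership, the threshold sweep, the per-component dynamics and candidate
tables, and a JSON run report; `plot(run$sweep)` and `plot(run$dynamics)`
draw the threshold heatmap and the expansion scatter.

A thin command-line front end is installed with the package
(`exec/vhnet`): `vhnet simulate|preprocess|sweep|cluster|dynamics|run`.

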