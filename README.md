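# tunnelslicer

Divide-and-conquer analysis of protein transport tunnels in long
molecular-dynamics ensembles, for structural bioinformaticians who need
trajectory-scale tunnel statistics without trajectory-scale RAM.

Analysing tens of thousands of frames for tunnels in one pass is expensive:
every frame contributes many tunnels and the all-against-all pathway
clustering dominates memory and runtime. `tunnelslicer` instead cuts the
trajectory into contiguous slices with **globally continuous frame
numbering**, detects and clusters tunnels per slice, filters the per-slice
clusters by their **presence** (fraction of slice frames in which the
cluster has a tunnel; default threshold 2%), renumbers the survivors by
**priority**

    P_i = (1/n) * sum_{j=1..n} T_j

(the mean over frames of the cluster's per-frame tunnel throughput
`T_j = exp(-cost)`, zero in frames where the cluster is absent), and merges
the kept clusters from all slices into **superclusters** with Ward-linkage
hierarchical clustering cut at 1.0 Å. The headline property — verified by
the test suite on synthetic ensembles with exact ground truth — is that the
sliced analysis reproduces the full-trajectory analysis: same clusters,
same ranking, matching per-cluster frame counts.

Tunnel detection itself is a self-contained geometric dialect: a cubic
void lattice (0.5 Å) with exact per-node clearance (distance to the nearest
atom surface), Dijkstra minimum-cost pathways with edge cost
`len / r_mean^wc` (weighting coefficient 2), a 0.7 Å probe, greedy
best-throughput extraction of one tunnel per exit, and sub-grid bottleneck
refinement. See the methods vignette
(`vignettes/divide-and-conquer-tunnels.Rmd`) for the full model,
parameters and design rationale.

## Worked example

A synthetic 2,000-frame pseudo-protein with three designed channels
(bottlenecks 1.5 / 1.2 / 1.0 Å; always open / open 50% / open 10% of
frames), analysed both in one piece and as 8 slices of 250 frames:

```r
library(tunnelslicer)

spec <- shell_spec(n_frames = 2000, seed = 1)   # exact ground truth known
ens  <- build_ensemble(spec)
sel  <- default_start_selectors()

full   <- run_pipeline(ens, analysis_config(start_selectors = sel))
sliced <- run_pipeline(ens, analysis_config(start_selectors = sel,
                                            slice_size = 250))
full$summary
#>   cluster_id frames avg_bottleneck avg_length max_bottleneck
#> 1          1   2000       1.386980   21.13235      1.4293140
#> 2          2   1000       1.087304   20.89316      1.1320885
#> 3          3    200       0.907857   20.50359      0.9398445
sliced$summary
#>   cluster_id frames avg_bottleneck avg_length max_bottleneck
#> 1          1   2000       1.386980   21.13235      1.4293140
#> 2          2   1000       1.087304   20.89316      1.1320885
#> 3          3    200       0.907857   20.50359      0.9398445

cmp <- compare_runs(full, sliced)
cmp$matches[, c("ref_id", "other_id", "jaccard")]
#>   ref_id other_id jaccard
#> 1      1        1       1
#> 2      2        2       1
#> 3      3        3       1
cmp$rank_agreement
#> [1] 3
```

Reading the output: each supercluster is one physical channel. `frames` is
the number of trajectory frames in which the channel is open (2000, 1000
and 200 match the designed presences 100%, 50% and 10%); `max_bottleneck`
recovers the designed radii (1.5, 1.2, 1.0 Å) to better than 0.1 Å, while
`avg_bottleneck` sits slightly lower because thermal jitter biases each
frame's minimum clearance downward (on noiseless fixtures the detector's
bottleneck error is bounded at 0.15 Å by the test suite); the two analyses
agree cluster for cluster (Jaccard 1 on frame sets) and rank for rank. `run_pipeline(..., out_dir =)`
additionally writes per-slice cluster files, filtered files with old→new
id maps, merged supercluster files in the package's CAVER-dialect CSV
format, and a summary TSV. Real multi-model PDB trajectories are read with
`read_ensemble()`, with the starting point given by active-site atom
selectors, e.g. `data.frame(resno = c(106, 107, 168, 246),
name = c("CG", "CD2", "N", "N"))`.

A thin command-line front-end with `simulate`, `run`, `detect`, `filter`,
`merge`, `convert` and `compare` subcommands is installed as
`exec/tunnelslicer`.

## File formats

- Input: multi-model PDB (`MODEL`/`ENDMDL`), or a single-model topology
  PDB plus a `frame,serial,x,y,z` coordinate table.
- Output: per-cluster profile CSVs plus a run summary CSV
  (`# caver-dialect v1` header, 6-decimal fixed point, byte-stable round
  trip), TSV sidecars for id maps and supercluster provenance. See
  `?caver_dialect`.
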