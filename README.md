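# abdocktools

Post-docking analytics for antibody-antigen complex prediction.

Physics-based antibody-antigen docking produces hundreds of candidate
poses whose native scoring functions rank them poorly, while AI structure
predictors attach confidence estimates (pLDDT, pTM, aligned-error
probabilities) that *do* carry signal about model quality. This package is
for structural bioinformaticians who sit between the two: it takes docked
poses plus their confidence evidence and physics scores, and provides the
statistics needed to re-rank poses, judge them against native complexes,
characterize their interfaces, and benchmark selection strategies.

## What it computes

**Composite rescoring.** Each pose's four raw metrics are standardized
across the pose population of a system (z-scores, population sd) and summed
with equal weights:

    composite = Z_pLDDT + Z_pTM + Z_ipTM + Z_phys

ipTM is derived from the binned aligned-error probabilities when the
predictor does not emit it: for residues *i*, *j* and bin centers *b_k*,

    pTM-type score = max_i mean_{j in mask} sum_k p_ijk / (1 + (b_k/d0(N))^2)

with the interchain mask giving ipTM and d0 the standard TM-score
normalization. Physics scores are oriented per engine (lower-is-better
energies vs higher-is-better shape scores) before standardization.

**Model certainty.** Tool-reported predicted errors are z-scored against
the pooled per-tool population and sign-flipped, so higher certainty means
lower predicted error; `certainty_filter()` / `threshold_sweep()` implement
confidence-guided model selection with system-retention accounting.

**DockQ.** `dockq_score()` computes fnat, interface RMSD and ligand RMSD
with the published constants and combines them into DockQ, with the
application classes used throughout: acceptable (DockQ >= 0.23, epitope
mapping) and medium (DockQ >= 0.49, antibody design).

**Interface panel.** Shrake-Rupley SASA (deterministic quadrature),
relative accessibility against Gly-X-Gly references, the
interior/surface/support/rim/core classification from rSA transitions on
binding, per-region stickiness sums (Levy scale), global atom density of
the interface cloud, and a normals-based surface complementarity index.

**Benchmark machinery.** Run-manifest enumeration, naive (random) and
certainty-guided selection, top-N success rates, 200-iteration bootstrap
percentile intervals, and Welch-t success/failure discriminants with
standardized differences and significance stars.

**Synthetic fixtures.** Deterministic toy complexes, graded pose decoys
with recorded true DockQ, and confidence bundles whose correlation with
true quality is controlled by a fidelity parameter — the whole pipeline
runs offline.

## Worked example

```r
library(abdocktools)

# a toy native complex and 20 graded decoys with known true DockQ
toy <- make_toy_complex(toy_complex_spec(seed = 1))
dec <- make_pose_decoys(toy$model, 20, seed = 1)
dec$summary[c(1, 5, 10, 20), c("decoy_id", "translation_A", "fnat",
                               "dockq", "quality_class")]
#>    decoy_id translation_A fnat      dockq quality_class
#> 1  decoy001      0.000000    1 1.00000000          high
#> 5  decoy005      2.414902    0 0.45979037    acceptable
#> 10 decoy010      8.150296    0 0.20293077     incorrect
#> 20 decoy020     25.000000    0 0.03465505     incorrect

# confidence bundles at fidelity 0.8, composite re-ranking
bundles <- lapply(1:20, function(i)
  make_confidence_bundle(dec$summary$dockq[i], 0.8, seed = 100 + i,
                         pose_id = dec$summary$decoy_id[i]))
rk <- rescore_poses(bundles)
head(as.data.frame(rk)[, c("rank", "pose_id", "z_plddt", "z_ptm",
                           "z_iptm", "z_phys", "total")], 3)
#>   rank  pose_id z_plddt z_ptm z_iptm z_phys total
#> 1    1 decoy002    2.43  2.27  3.221   2.20 10.12
#> 2    2 decoy001    2.28  1.93  2.756   2.31  9.27
#> 3    3 decoy003    1.47  1.28 -0.136   1.52  4.14

mean(dec$summary$dockq[match(rk$pose_id[1:5], dec$summary$decoy_id)])
#> [1] 0.759   # top-5 mean true DockQ; a random top-5 averages ~0.29

dockq_score(dec$models[[5]], toy$model)
#> pose_quality: fnat 0.000 | irms 1.51 A | lrms 3.09 A | DockQ 0.460 (acceptable)
```

The composite total of the top pose decomposes into its four standardized
components (each ~2-3 sd above the pose population because this decoy is
near-native on every metric); re-ranking by the total concentrates
high-DockQ poses in the top 5.

A thin command-line front end wraps the same functions:

```sh
inst/exec/abdock dockq --pose pose.pdb --native native.pdb
inst/exec/abdock panel --complex complex.pdb --out panel.tsv
inst/exec/abdock manifest --systems 81 --tools igfold,abb2,equifold \
    --models 4 --engines propose,zdock --poses 100
```

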