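# tdtract

Muscle fascicle lengths from diffusion-tensor MRI, with automatic
tract-density-based segmentation of tendinous tissue.

## The problem

Muscle architecture — fascicle length, pennation angle, physiological
cross-sectional area — determines what a muscle-tendon unit can do, and
changes with age, training, disease and surgery. DT-MRI fibre tractography
can reconstruct fascicles in 3D over a whole muscle, but conventional
stopping rules corrupt the length estimates: streamlines run on along
tendons, aponeuroses and fasciae (partial-volume voxels average muscle and
tendon diffusion, tilting the principal direction toward the tendon), while
halting at segmented muscle boundaries truncates fibres wherever the
segmentation is imperfect.

This package implements a tract-density (TD) approach for users of
skeletal-muscle DT-MRI. Fascicles have well-defined origins and insertions
and nearly constant density in the muscle belly, so after dense whole-volume
seeding the number of distinct streamlines crossing a voxel — the tract
density — is roughly constant in muscle and systematically elevated in
tendinous voxels, which collect the elongation artifact from every fascicle
inserting on them.

## The method

1. **Tensor fit.** Per voxel, weighted linear least squares on
   `ln S = ln S0 − b gᵀ D g` (one OLS pass, one pass re-weighted by the
   squared predicted signals); FA and MD from tensor invariants.
2. **Whole-volume pass.** Deterministic bidirectional Euler tracking from a
   1 mm seed lattice (FA 0.1–0.7, ≤ 20°/step, ≥ 2 mm).
3. **TD map.** Per streamline, each *distinct* voxel crossed (exact 3D voxel
   walk) counts once; counts are normalized by the foreground mean, putting
   muscle at TD ≈ 1. Voxels with TD > 1.5 are segmented as tendinous.
4. **Per-muscle pass.** Seeds inside the muscle mask eroded to ~90 % of its
   volume (0.3 mm steps, ≤ 10°/step, ≥ 20 mm); propagation halts where
   TD > 1.5.
5. **Length estimate.** After excluding tracts that terminate at the
   field-of-view z-faces, a skew-normal distribution (ξ, ω, α) is fitted to
   the lengths by maximum likelihood; the reported mean fascicle length is
   the fitted distribution's mean, ξ + ω·δ·√(2/π) with δ = α/√(1+α²).
6. **Repeatability.** Bland–Altman bias and limits of agreement,
   CV = 100·SD(d)/mean, and MDD = 1.96·SD(d) for paired sessions.

Because no scanner data ship with the method, the package includes a
synthetic unipennate-muscle phantom (planar aponeurosis, two pennate
compartments, bounding fasciae, Rician noise, known ground-truth fascicle
length L = W/sin θ) that exercises every stage, plus the two conventional
comparators (FA-window-only stopping, muscle-boundary stopping).

## Worked example

A reduced phantom (40 × 12 × 30 voxels, ground truth L = 50 mm) through the
full pipeline:

```r
library(tdtract)
cfg <- run_config(seed = 42)
attr(cfg, "phantom_args") <- list(grid_shape = c(40L, 12L, 30L))
res <- run_pipeline(cfg)
print(res)
#> <td_pipeline_result> SNR 40.0, 87318 streamlines in pass 1, 866 tendinous voxels
#>   muscle_1: mean fascicle length 46.5 mm (n = 1646 tracts)
#>   muscle_2: mean fascicle length 47.3 mm (n = 1500 tracts)
print(res$fascicle$muscle_1)
#> <fascicle_length_result> muscle 1 n = 1646 tracts (1508 FOV-excluded)
#>   skew-normal fit: xi = 52.21 mm, omega = 7.35 mm, alpha = -3.64
#>   mean fascicle length = 46.55 mm (4.65 cm)
```

Reading the output: the simulated acquisition came out at SNR 40; the
whole-volume pass reconstructed ~87 000 streamlines whose density map
flagged 866 voxels as tendinous (the aponeurosis and fasciae); TD-stopped
tracking in each pennate compartment then yields mean fascicle lengths of
46.5 and 47.3 mm against a ground truth of 50 mm (a 5–7 % underestimate:
the TD ridge extends roughly one voxel into the muscle on each side). On
the full-size default phantom (`run_config(seed = 42)` with no override,
~10⁵ seeds per pass) the TD estimate lands within ~5 % of truth while the
FA-window comparator overshoots by ~50 % and the boundary comparator comes
out short with negative skew.

A command-line interface wraps the same functions:

```sh
exec/tdtract phantom --out phantom/ --seed 42
exec/tdtract run --seed 42 --out results/
exec/tdtract repeatability --in results.csv --out summary.csv
```

See `vignettes/td-fascicle-length.Rmd` for the model, all parameters,
numerical choices, and known limitations of the phantom.

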