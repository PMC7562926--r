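# lanternimg

Single-pixel computational imaging through a multicore-fibre photonic
lantern, end to end in R.

A photonic lantern converts each single-mode core of a multicore fibre into
a fixed multimode intensity pattern at its output facet. Because the cores
barely couple, the patterns survive fibre bending — which makes them usable
as the structured illumination of a single-pixel camera at the tip of a
microendoscope: project pattern *p*, record one bucket-detector reading
*y_p*, repeat for all *N_p* cores, then reconstruct the object
computationally. `lanternimg` simulates this pipeline and implements its
reconstruction algorithms:

* **Waveguide modes** — the lowest-order eigenmodes of a circular
  ideal-mirror waveguide, `u ∝ J_m(j_mq · r/R)·{cos mθ, sin mθ}`, ordered by
  the Bessel zero `j_mq`, plus the step-index design arithmetic
  (`V = π·d·NA/λ`, mode count `V²/4`, Rayleigh limit `0.61·λ/NA`).
* **Pattern synthesis** — random orthonormal coherent superpositions of the
  modes, squared modulus, optional rotation augmentation; or measured
  pattern images loaded from PNG/TIFF.
* **Forward model** — `y = Φx + e` with pattern rows in Φ, Gaussian noise at
  a prescribed input SNR (dB), and a chi-squared fidelity bound ε.
* **Reconstruction** — the constrained sparsity-averaging reweighted-ℓ1
  programme

  ```
  minimise ‖Ω Ψ x‖₁  subject to  x ≥ 0  and  ‖y − Φx‖₂ ≤ ε
  ```

  over the 9-basis tight frame Ψ (Dirac + Daubechies db1–db8), solved by a
  primal-dual forward-backward (Condat–Vũ) algorithm with Candès
  reweighting; and the classical ghost-imaging covariance estimator
  `x̂ = (1/N_p) Σ (y_p − ȳ)·pattern_p` as a prior-free baseline.
* **Phantoms and metrics** — knife edge, off-centre cross, elliptical dots,
  three-bar resolution groups, procedural blobs; the pattern-stability
  overlap integral `(Σ I_A·I_B)² / (Σ I_A² · Σ I_B²)` and reconstruction
  SNR.

## Worked example

121 patterns, a 125×125 grid, an off-centre cross, noiseless measurements —
then both reconstructions:

```r
library(lanternimg)

g     <- grid_spec(125)
basis <- build_mode_basis(121, g)              # 121 lowest disk modes
stack <- synthesize_patterns(basis, random_unitary(121, seed = 1))
cross <- make_offset_cross(g, arm_width = 5, centre_offset = c(-12, 8),
                           arm_length = 55)
op    <- build_operator(stack)
ms    <- simulate_measurements(op, cross)      # noiseless overlaps

ghost <- solve_ghost(ms, stack)
sara  <- solve_sara(ms, op, build_sparsity_model(g),
                    solver_config(n_reweights = 4, max_iter = 500))

reconstruction_snr(ghost, cross)
#> [1] 1.244198
reconstruction_snr(sara, cross)
#> [1] 10.58979
```

The prior-free covariance image barely rises above the speckle background
(~1.2 dB), while the constrained reweighted-ℓ1 estimate recovers the cross
at ~10.6 dB — the resolution/contrast gap the constrained approach exists
for. `plot(sara)` displays the image; `display_normalize()` maps images to
[0, 1] for export.

Design arithmetic for a future high-mode-count lantern:

```r
step_index_mode_count(fiber_spec(63, 0.22, 0.488))  # 1990 modes
rayleigh_resolution(0.488, 0.22)                    # 1.353 um
feature_spacing(63, 2000)                           # 1.248 um
```

A thin command-line driver wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "lantern.R", package = "lanternimg"))')" \
    simulate --config run.yaml --out runs/demo
```

with subcommands `modes`, `patterns`, `phantom`, `simulate`/`measure`,
`reconstruct` (`--method sara|ghost`) and `evaluate`.

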