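# spvflock

Simulation and statistics for serum-induced collective migration in
confluent epithelial monolayers.

When quiescent keratinocyte sheets are re-exposed to serum they switch from
a static state to long-range coordinated locomotion, followed by globally
polarized cell divisions with asymmetric organelle inheritance. `spvflock`
provides, as one tested R package, the computational machinery needed to
study this system quantitatively:

* **A hybrid active-Voronoi / Vicsek tissue simulator.** Cells are Voronoi
  regions of `N` centres in a periodic box with the shape energy
  `E = Σ_j K_A (A_j − A0)² + K_p (p_j − p0)²`, overdamped dynamics
  `r_i(t+Δt) = r_i(t) + [μ F_i(t) + v0 n_i(t+Δt)] Δt` with `F_i = −∇_i E`
  computed analytically, and Vicsek-type alignment of the polarization angle
  `θ_i(t+Δt) = θ_i(t) + (Δt/τ_V) ⟨φ_j − θ_i⟩_{|r_j−r_i| ≤ R_V} + η_i` with
  rotational noise of variance `2 D_r Δt`. The Vicsek radius `R_V` models
  calcium-dependent cell–cell connectivity.
* **Velocity-field (PIV) statistics**: temporal/spatial median filters,
  speed maps, the instantaneous order parameter (IOP), the angle–distance
  correlation curve, and the 5-σ velocity correlation length
  `C_vv = max r : θ̄(r) + 5·SEM(θ(r)) < 90°`.
* **Track statistics**: fixed-lag (5 h) mean square displacement with track
  filtering, the migration persistency index (MPI), per-track motility
  summaries, circular order statistics of division/polarity directions
  (`||⟨d⟩|| = sqrt(⟨x⟩² + ⟨y⟩²)`), unity-normalized rose histograms, and the
  relative nuclear position `p = |c − x| / |y − x|`.
* **A binomial organelle-inheritance model**: complete asymmetry has
  probability `p_sym^n + (1 − p_sym)^n` for a division with `n` bodies;
  maximum-likelihood fitting of `p_sym` and a Monte-Carlo test for excess
  asymmetry.
* **Seeded synthetic-data generators** for every input class (gridded
  flows, Vicsek particle fields, tracks, division angles, daughter-pair
  counts, pre-mitotic nuclear series), so the entire pipeline runs and is
  tested without microscopy data.

Intended users: quantitative cell biologists and physicists of active
matter who analyse collective-migration imaging or want a compact, tested
reference implementation of these estimators and of the confluent
flocking model.

## Worked example

```r
library(spvflock)

# --- simulate a small active sheet at the published parameter set ---
p <- model_params(N = 64)           # K_A = K_p = 1, v0 = 0.5, D_r = 1.5, p0 = 4
s <- simulate_sheet(p, n_equil = 2000, n_prod = 4000, seed = 42)
s
#> Voronoi-Vicsek run: N = 64, R_V = 0, v0 = 0.5
#>   2000 equilibration + 4000 production steps (dt = 0.001)
#>   steady-state mean speed = 0.3293 r0/tau0, mean IOP = 0.1606
```

With activity on (`v0 = 0.5`) the steady mean speed is ~0.3 length units
per time unit; the IOP near `1/sqrt(N)` says the motion is uncoordinated,
as expected for disconnected cells (`R_V = 0`).

```r
# --- 5-sigma correlation length of a synthetic PIV field ---
fl <- gen_gridded_flow(flow_spec(grid_shape = c(48, 48),
                                 angular_noise_sd = 360,
                                 correlation_scale = 3,
                                 window_spacing = 90, seed = 42))[[1]]
cl <- correlation_length(fl)        # 5-sigma criterion by default
cl$c_vv_windows; cl$c_vv_um
#> [1] 5
#> [1] 450
```

A disordered angle field smoothed over ~3 windows yields a correlation
length of 5 windows (450 µm at 90 µm PIV window spacing): vectors closer
than that still point the same way with 5-σ confidence, farther ones do
not.

```r
# --- asymmetric organelle inheritance ---
law <- stats::setNames(rep(0.2, 5), 2:6)     # 2..6 bodies per division
d <- gen_inheritance_counts(partition_spec(n_divisions = 469,
                                           body_count_law = law,
                                           p_sym = 0.2, seed = 42))
observed_asym_fraction(d)$fraction
#> [1] 0.4690832
fit_psym(d)
#> Binomial partition model: p_sym = 0.1853 (n = 469 divisions)
asym_excess_test(d, p_null = 0.5, n_mc = 9999, seed = 42)$p_value
#> [1] 1e-04
```

The fit recovers the generating partition bias (`p_sym = 0.19` vs the true
0.2), and the Monte-Carlo test rejects unbiased partitioning
(`p_sym = 0.5`) for these data at its resolution floor.

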