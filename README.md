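# vesicoat

Quantification of fluorescent protein coats on intracellular vesicles, and
of the trafficking kinetics around them. The package is written for
cell biologists analysing confocal images of lysosomes and post-lysosomes
decorated by coat proteins (for example the WASH complex and its
partners), where three questions recur:

* **Coat distribution.** A circumferential band around the vesicle is
  divided into angular sectors (24 sectors of 15° by default) and each
  channel's signal is summed per sector, giving the radial "radar" profile
  of the coat. Profiles can be aligned on their maxima and averaged across
  vesicles. Scalar summaries: the polarization index
  `PI = |Σ s_k e^{iθ_k}| / Σ s_k` (0 = even coat, 1 = single focus), the
  vesicle-to-cytosol signal ratio, and masked Pearson colocalization.
* **Radial displacement between two coats.** Per-channel peak-to-peak
  diameters are measured along opposite-ray pairs with subpixel precision
  (bilinear sampling at 0.25 px, least-squares parabolic refinement;
  ~0.03 px accuracy on noise-free rings) and the diameter difference is
  converted to nanometres: `across = Δd · pixel_size`, per side half of
  that. Spherical geometry links cross-sectional area to diameter
  (`d = 2√(A/π)`), surface area (∝ A) and volume (∝ A^{3/2}).
* **Kinetics.** FRAP recoveries are fitted to
  `Intensity(t) = A + B·exp(−C·t)` by nonlinear least squares; half-time
  `ln2/C`, immobile fraction
  `1 − (A − I_bleach)/(I_pre − I_bleach)`, geometric-mean group summaries
  with log-scale 95% CIs and Shapiro–Wilk reporting, Welch/Student
  comparisons. Exocytosis retention curves are normalized to t = 0,
  yielding interpolated t50, trapezoidal AUC per replicate, and one-way
  ANOVA with Tukey HSD across strains.

A synthetic-data module generates two-channel ring images with patchy or
focal von Mises coats (and optional per-channel radial offset), FRAP
traces, retention curves and vesicle-area samples — all with recorded
ground truth — so every estimator is validated by recovery tests.

## Worked example

```r
library(vesicoat)

# a synthetic two-channel vesicle: patchy coat, 1 px per-side radial offset
spec <- vesicle_spec(peak_radius_px = c(21, 20), ring_sigma_px = 2,
                     angular = list(angular_patchy(), angular_patchy()),
                     noise_sd = 0.02)
ves  <- render_vesicle_image(spec, c(64L, 64L), seed = 1)

# sector profile and polarization
band <- annulus_band(ves$truth$center_xy, 13, 28)
prof <- sector_profile(ves$stack, band, n_sectors = 24)
polarization_index(prof, 1)
#> [1] 0.018      # low: a patchy coat spread around the circumference

# peak-to-peak diameters and displacement at 46.3 nm/px
ptp  <- peak_to_peak_diameter(ves$stack, ves$truth$center_xy,
                              r_range = c(10, 30))
round(ptp$diameter_px, 2)
#>   ch0   ch1
#> 41.96 39.93
disp <- channel_displacement(ptp$diameter_px[1], ptp$diameter_px[2], 46.3)
round(disp$diameter_difference_px, 2)    #> 2.04  (truth: 2 px)
round(disp$displacement_across_nm, 1)    #> 94.2  nm across the vesicle
round(disp$displacement_per_side_nm, 1)  #> 47.1  nm per side

# FRAP: fit a noisy simulated recovery
sim <- simulate_frap_trace(frap_sim_spec(A = 100, B = -80, C = 0.2,
                                         noise_sd = 4), seed = 2)
fit <- fit_recovery(sim$trace)
round(c(C = fit$C, half_time_s = fit$half_time_s), 3)
#>           C half_time_s
#>       0.188       3.690   # truth: C = 0.2, half-time 3.466 s

# spherical geometry: two vesicle populations with mean cross-sections
# 3.4 and 5.5 square microns
r <- spherical_ratios(3.4, 5.5)
sprintf("diameter +%.1f%%, surface +%.1f%%, volume %.2fx",
        r$diameter_increase_pct, r$surface_increase_pct, r$volume_fold)
#> "diameter +27.2%, surface +61.8%, volume 2.06x"
```

A command-line interface wraps the same functions
(`inst/cli/vesicoat`, or `run_cli()` from R) with subcommands
`simulate`, `profile`, `displace`, `frap` and `exo`; every run writes a
`run_log.json` with the seed, configuration hash and package version.

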