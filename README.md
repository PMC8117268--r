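# flumen

**False-lumen hemodynamics from 4D flow cardiovascular MRI.**

Chronic type B aortic dissection splits the descending aorta into a true
lumen (TL) and a false lumen (FL) separated by a septal flap with an entry
tear. Pressurization of the FL drives aortic growth and rupture risk, but
FL pressure cannot be measured non-invasively — it has to be inferred from
the time-resolved, three-component velocity field that 4D flow CMR
provides. `flumen` implements the three velocity-derived metrics of FL
pressurization used for this inference, a synthetic dissected-vessel
phantom generator that provides analytic ground truth for every stage, and
the cohort-level statistical layer that relates the metrics to aortic
growth.

## The three metrics

**FLEF — false lumen ejection fraction (%).** Flow is integrated through a
plane at the dominant entry tear with a region of interest restricted to
the tear:

    FLEF = 100 · (retrograde flow volume at the tear during diastole)
                / (antegrade flow volume)

Diastolic reversal at the tear happens when FL diastolic pressure exceeds
TL pressure, so a high FLEF marks a pressurized FL.

**MSDR — maximum systolic deceleration rate (cm/s³).** Over a proximal FL
subsection (tear → distal landmark, or a 5 cm window around the tear), the
mean velocity magnitude `s(t)` is differentiated in time (cyclic central
differences) and

    MSDR = |a_max − a_min| / |t(a_min) − t(a_max)|

over systole. A pressurized, high-resistance FL decelerates systolic
inflow more abruptly.

**vWERP — virtual work-energy relative pressure (mmHg, reported per metre
of vessel).** A divergence-free, no-slip, unit-net-flow *virtual* field `w`
is computed over the segmented lumen by a staggered-grid Stokes solve.
Dotting the Navier–Stokes equations with `w` and integrating over the lumen
turns the unknown pressure gradient into a pure boundary term, giving the
inlet→outlet relative pressure from measured velocities alone:

    ΔP(t) = (1/Q_v) [ d/dt ∫ρ v·w dV + ∫ρ (v·∇v)·w dV + ∫μ ∇v:∇w dV ]

with `ΔP = p_inlet − p_outlet` (positive while flow accelerates down the
segment). Traces are normalized by centerline length; `ΔP_max`/`ΔP_min`
are the cycle extrema, and the transseptal trace (TL − FL) is the load on
the dissection flap.

## Worked example

```r
library(flumen)

# a dissected-vessel phantom with known tear volumes (10 ml antegrade,
# 4.9 ml diastolic retrograde -> true FLEF 49%), acquisition-regime noise
geom  <- phantom_geometry(grid_shape = c(64, 48, 48), lumen_radius_tl = 8,
                          lumen_radius_fl = 10, tear_diameter = 10)
wf    <- waveform_spec(n_frames = 21, peak_flow_ml_s = 300,
                       antegrade_tear_volume_ml = 10,
                       diastolic_retrograde_volume_ml = 4.9)
field <- add_velocity_noise(make_pulsatile_field(geom, wf), vnr = 40, seed = 1)
tear  <- attr(field, "ground_truth")$tear_plane

compute_flef(field, tear)
#> FLEF = 47.6%  (antegrade 10.35 ml, diastolic retrograde 4.92 ml)

mask  <- make_dissection_mask(geom)
sub   <- extract_fl_subsection(mask, tear_axial_position_mm = 60)
trace <- differentiate_trace(mean_speed_trace(field, sub))
compute_msdr(trace, cardiac_phases(1:8, 21))
#> MSDR = 229 cm/s^3  (a_max 27.1 at 0.048 s, a_min -27.5 at 0.286 s)

# vWERP against its analytic oracle: steady Poiseuille tube, R = 10 mm,
# L = 100 mm, Q = 83.3 ml/s, mu = 4 mPa s
tube <- make_poiseuille_field(
  phantom_geometry(grid_shape = c(20, 20, 40), lumen_radius_tl = 10), 83.3)
res <- vwerp(tube$field, tube$mask, "TL",
             analysis_plane(c(0, 0, 0),    c(0, 0, 1), 10),
             analysis_plane(c(0, 0, 97.5), c(0, 0, 1), 10))
#> vWERP dP = 0.0630 mmHg (Hagen-Poiseuille: 0.0636 mmHg)  [-1.1%]
res$virtual
#> <virtual_field> 5600 cells, div residual 4.39e-11, CG iters 31
#>   station flux: 1.0000 1.0000 1.0000 1.0000 1.0000

# cohort layer: group comparison, correlations, robust-SE regression
report <- analyze_cohort(simulate_cohort(cohort_spec(seed = 1)))
report$regressions$flef_pct
#> robust OLS (HC1), n = 12, adj R^2 = 0.86
#>   growth_rate_mm_yr ~ flef_pct + baseline_diameter_mm
#>              term estimate robust_se     t  p_value  ci_lo  ci_hi
#>       (Intercept)  -26.208    6.3621 -4.12 0.002600 -40.60 -11.82
#>          flef_pct    0.258    0.0417  6.19 0.000161   0.16   0.35
#>  baseline_diam...    0.616    0.1583  3.89 0.003657   0.26   0.97
```

The FLEF printed above is the pipeline's plane-integrated estimate under
noise (truth: 49%); the vWERP estimate sits 1.1% from the closed-form
pressure drop at clinical (1.5 mm in-plane) resolution; the simulated
cohort (n = 4 stable vs 8 enlarging, group means/SDs as observed clinically)
recovers its generating FLEF coefficient 0.23 inside the robust CI.

## Command line

```sh
FLUMEN=$(Rscript -e 'cat(system.file("exec", "flumen", package = "flumen"))')
Rscript $FLUMEN phantom make --config phantom.json --seed 1 --out out/
Rscript $FLUMEN metrics flef  --in out/phantom --plane out/phantom_tear_plane.json --out out/
Rscript $FLUMEN metrics vwerp --in out/phantom --mask out/phantom_mask.nii \
        --lumen FL --inlet inlet.json --outlet outlet.json --out out/
Rscript $FLUMEN cohort analyze --table cohort.csv --out out/
Rscript $FLUMEN repro perturb --mask out/phantom_mask.nii --mode smaller --out out/
```

Velocity volumes are NIfTI (one 4-D file per component) with a JSON
sidecar `{venc_cm_s, frame_interval_ms, voxel_size_mm}`; masks are
integer-label NIfTI (0 background, 1 TL, 2 FL); planes are JSON; traces and
cohort tables are CSV. Every CLI run writes a JSON provenance record.

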