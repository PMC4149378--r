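# stainkinetics

Iodine potassium iodide (I2KI, Lugol's iodine) is the workhorse contrast
agent for imaging soft tissue — hearts in particular — with X-ray computed
tomography. The practical question every staining protocol has to answer is
*how long to incubate*: too short and the core of the sample is still
unstained, too long and the tissue over-stains and shrinks. `stainkinetics`
quantifies stain penetration from a time series of reconstructed CT slices
and turns it into a staining-time rule you can plan protocols with.

## The model

Intensity in a stained voxel rises with incubation time `t` toward a
saturated ceiling. At transmural depth `d` (mm from the outer, epicardial
surface) the package fits the three-parameter saturation law

    I(t) = Imax − (Imax − I0) · exp(−t / τ)

per 0.1 mm depth segment, where `I0` is the native (unstained) intensity,
`Imax` the saturated intensity and `τ` the time constant. Because beam
hardening makes `Imax` depend on depth, saturation is judged on the ratio
`I / Imax` (levels 90%, 95%, 99%), which cancels the ceiling bias. The time
`T` for each depth to reach a saturation level follows the exponential
depth rule

    T(d) = A · exp(B · d)

— a straight line on a semi-log plot — whose coefficients `A` (hours at the
surface) and `B` (per mm) are obtained by ordinary least squares of
`log T` on `d`. Staining from both surfaces halves the effective depth, so
dual-sided staining of a sample of thickness `x` needs only `T(x/2)`.

The pipeline stages are: width-averaged intensity line profile across the
tissue wall → Gaussian-smoothed gradient detection of the epicardial edge →
twenty 0.1 mm depth segments → per-depth saturation fits (Nelder–Mead least
squares) → saturation-time table → per-level `(A, B)` models. A synthetic
phantom generator (annular wall, depth-graded time constant, beam-hardening
ceiling, Gaussian detector noise, 16-bit multi-page TIFF I/O) provides
ground truth for every stage.

## Worked example

Planning with the published reference coefficients for I2KI-stained mouse
ventricle (90% saturation: `A = 5.72` h, `B = 1.04` per mm):

```r
library(stainkinetics)
models <- reference_stain_models()
plan_staining(models[["0.90"]], thickness = 2, dual_sided = FALSE)
#> <stain_plan> 2 mm sample, 90% saturation, single-sided: stain for 45.8 h (effective depth 2 mm)
plan_staining(models[["0.90"]], thickness = 2, dual_sided = TRUE)
#> <stain_plan> 2 mm sample, 90% saturation, dual-sided: stain for 16.2 h (effective depth 1 mm)
```

A 2 mm wall needs almost two days single-sided but only 16 hours when
stained from both surfaces — the dual-sided rule halves the depth the stain
must diffuse, and the exponential turns that into a near-threefold saving.

An end-to-end run on a simulated noiseless stack (staining times 0–58 h,
11 µm voxels, time constant growing as `exp(1.0 · d)` with depth):

```r
cfg <- default_run_config(phantom = list(noise_sd = 0))
rep <- run_pipeline(cfg)
rep
#> <run_report> 6 timepoints, 20 depths, edge at 0.044 mm
#> <stain_time_model> 90% saturation: T(d) = 9.699 * exp(0.9887 * d)  [n = 20, R2(log) = 1.0000]
#> <stain_time_model> 95% saturation: T(d) = 13.24 * exp(0.9913 * d)  [n = 20, R2(log) = 1.0000]
#> <stain_time_model> 99% saturation: T(d) = 21.47 * exp(0.994 * d)  [n = 20, R2(log) = 1.0000]
```

The recovered depth rates (0.989–0.994 per mm) sit within 1.5% of the
generating value 1.0, and the fitted times are ordered 90% < 95% < 99% at
every depth, as they must be. `run_pipeline(cfg, output_dir = "out")`
additionally writes `profile.csv`, `grid.csv`, `fits.csv`,
`saturation_times.csv`, `coefficients.csv`, `report.json` and a run log;
identical configurations produce byte-identical CSVs.

A thin command-line wrapper ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","stainkinetics.R",package="stainkinetics"))')" \
    calc --level 0.90 --thickness-mm 2 --dual-sided
```

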