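# condquant

Quantification of optogenetic mRNA condensates in fluorescence microscopy.

Light-activatable phase-separation systems (optoDroplet-style Cry2 fusions
carrying an RNA-binding module) let experimenters pull specific mRNAs into
biomolecular condensates on demand and ask what that does to translation,
molecular mobility and downstream cell biology. `condquant` is the analysis
side of such experiments, built for people who have the images but not a
pipeline: smFISH z-stacks of mRNAs and condensates, two-colour live movies
at 20 Hz, FRAP series, translation-reporter time courses, per-cell
expression scans around a saturation concentration, and dendritic-spine
z-stacks around chemically induced LTP.

The quantities at its core, in the field's standard notation:

* **Recruitment fraction** — Σ amplitudes of recruited mRNA puncta /
  Σ amplitudes of all puncta in the cell, where a punctum is *recruited*
  iff its planar distance to the nearest condensate is < 330 nm (~3 px)
  and its z separation ≤ 2 z-steps. Spots are localized sub-pixel by 2D
  Gaussian least squares; amplitudes use the max − min of a σ=1-blurred
  9×9 window.
* **Diffusion coefficient** — D = slope/4 of an OLS line through the
  2nd–4th points of the time-averaged MSD, free intercept (2D imaging).
* **Mobile fraction** — plateau M of M·(1 − e^(−t/τ)) fitted to the
  FRAP recovery normalized to the pre-bleach mean; 1 − M is the immobile
  fraction, a proxy for liquid- vs solid-like material state.
* **Saturation concentration c_sat** — the concentration at
  P(clustered) = 0.5 of a logistic fit in log concentration over many
  cells.
* **Ternary regular solution** — f = Σᵢ (φᵢ/Nᵢ) ln φᵢ + φ_s ln φ_s +
  Σ χᵢⱼ φᵢφⱼ per lattice site; coexisting phases from the lower convex
  hull of f on the composition simplex, with lever-rule fractions.
* **Reporter kinetics** — P(t)/P(0) = (1−α) + α e^(−t ln2/T½): the
  synthesis fraction α lost upon mRNA sequestration decays away with the
  reporter half-life (~6 h).

Because such datasets are rarely public, the package ships a synthetic
scene generator (`make_fish_scene()`, `make_live_movie()`,
`make_frap_trace()`, `make_reporter_traces()`, `make_phase_scan()`,
`make_spine_series()`, `make_bead_pair()`, `make_telegraph_trace()`) whose
ground truth drives every recovery test.

## Worked example

Generate an smFISH scene with known 84.5% recruitment, then recover it:

```r
library(condquant)

sc <- make_fish_scene(n_condensates = 120, n_mrnas = 200,
                      recruitment_p = 0.83, seed = 42,
                      img_size = c(256, 256))

cond <- condensates_3d(sc$stack, channel = 1)          # mCherry channel
planes <- lapply(1:7, function(z) {                    # FISH channel, per z
  img  <- stack_plane(sc$stack, channel = 2, z = z)
  cand <- detect_spots(img)
  data.frame(x_px = cand$x, y_px = cand$y,
             amplitude = as.numeric(amplitude_maxmin(img, cand$x, cand$y)))
})
spots <- assign_z(planes)                              # 3D deduplication
rec <- classify_recruited(
  nearest_condensate(spots, cond, pixel_size_nm = 110))
recruitment_summary("cell_1", spots, rec)
#>   cell_id n_spots n_recruited frac_count frac_amplitude
#> 1  cell_1     113          82  0.7256637      0.8327635
```

113 detected puncta from 200 mRNAs: recruited mRNAs co-localize inside
condensates and merge into brighter puncta, which is why the count-based
fraction (0.726) underestimates while the amplitude-weighted fraction
(0.833) recovers the generator truth of 0.845.

FRAP and phase behaviour:

```r
f <- frap_analyze(make_frap_trace(0.6, tau_s = 20, noise_sd = 0.02, seed = 7))
#> mobile 0.596, immobile 0.404, tau 20.1 s   (truth M = 0.6, tau = 20)

rs_coexistence(rs_params(chi12 = -1, chi1s = 3, chi2s = 3), c(0.15, 0.15),
               grid_n = 121)
#> Regular-solution coexistence: 2 phase(s)
#>   phi1  phi2  fraction
#>  0.475 0.475 0.2777778
#>  0.025 0.025 0.7222222
```

Two components that each avoid the solvent but attract one another form a
*single* dense phase enriched in both (co-condensation) — the regime that
lets condensate composition, and with it material properties, be tuned by
co-expression.

## Command line

```sh
Rscript inst/cli/condquant.R simulate fish --condensates 120 --mrnas 200 --p 0.83 --seed 1 --out out/
Rscript inst/cli/condquant.R detect --in out/fish.tif --channel 2 --out out/
```

Images travel as multi-page 32-bit float TIFF with a JSON metadata sidecar;
tables as CSV.
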