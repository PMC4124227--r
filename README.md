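# markalign

Fiducial-mark detection and automated stage realignment for parallel
multi-chamber microscopy.

Time-lapse monitoring of a multichamber microfluidic device (4 × 8
culture chambers here) means a motorized xy stage revisits every chamber
over days. Preset chamber-to-chamber distances are imperfect and the
device creeps on its mount, so the position error E — the pixel distance
between the detected and target position of a fiducial mark fabricated
next to each chamber — accumulates to tens of micrometers within a few
scans unless corrected. `markalign` implements the image-based
correction loop and everything needed to characterize it in silico:

* **Detection pipeline** — Gaussian lowpass filtering
  (`G(i,j) = 1/(2Nπσ²)·e^{−(i²+j²)/2σ²}`, renormalized to unit sum),
  Sobel gradients with magnitude `|Sx|+|Sy|`, non-maximum suppression
  along the 45°-quantized gradient direction, Zhang–Suen thinning, and
  tri-valued circle-template matching on the edge image
  `C(x,y) = Σ S_E(x+i, y+j) I_T(i,j) / Σ I_T(i,j)`
  (white ring weight 1, gray guard rings weight 0.5, black pixels
  excluded). The three strongest well-separated peaks of C are the mark
  circles; the upper-left circle is the reference position and the mark
  orientation is `θ_m = [atan2(Δy₂,Δx₂) + atan2(Δy₃,Δx₃) − 90°]/2`.
* **Closed-loop realignment** — capture → detect → move by the measured
  displacement, repeated until E ≤ 3 px (~3 µm at 0.94 µm/px), with
  chamber-distance updating from arrival residuals.
* **Virtual stage + synthetic renderer** — a noise/bias/drift stage
  model and an anti-aliased renderer of the three-circle mark with exact
  sub-pixel ground truth, driving serpentine-scan drift experiments and
  the four-condition error characterization.
* **Liquid-replacement tracing** — normalized chamber-intensity traces
  and first-order time-constant recovery.

See `vignettes/chamber-alignment.Rmd` for the model, parameter
rationale, and limitations.

## Worked example

```r
library(markalign)
set.seed(42)

## render a chamber view with the mark displaced (truth known); detect it
r <- render_mark_image(render_spec(offset = c(23.4, -11.2), alpha = 4,
                                   noise_sd = 10, seed = 42, well_radius = 45))
pose <- detect_mark(r$image)
pose
#> <mark_pose ref=(173.40, 138.89), theta=3.98 deg>
position_error(pose, r$truth$ref)
#> <alignment_error E = 0.09 px (0.09 um)>

## closed-loop realignment from a ~70 px initial offset
geom <- device_geometry()
stage <- stage_state(position = mark_position(geom, c(0, 0)) - c(55, -42) * 0.94)
res <- realign_chamber(stage, geom, c(0, 0), alignment_config())
sprintf("E: %.1f -> %.2f px in %d iteration(s)",
        res$record$E_pre, res$record$E, res$record$iterations)
#> "E: 69.2 -> 0.78 px in 1 iteration(s)"

## five serpentine scans over the 32 chambers, aligned vs unaligned
ali <- run_scans(5, with_alignment = TRUE, seed = 1)
una <- run_scans(5, with_alignment = FALSE, seed = 1)
round(rbind(aligned = tapply(ali$E, ali$scan, mean),
            unaligned = tapply(una$E, una$scan, mean)), 2)
#>               1     2      3      4      5
#> aligned    1.19  1.40   1.26   1.46   1.09
#> unaligned 45.22 84.16 112.64 145.75 179.35
```

The detector recovers the rendered pose to a fraction of a pixel and a
few hundredths of a degree; a single corrective move collapses a ~70 px
misalignment to below one pixel; and over five scans the aligned error
stays near 1 px (never above the 3 px tolerance) while the uncorrected
error grows every scan.

There is also a command-line front end (subcommands `render`, `detect`,
`align`, `scan`, `characterize`, `trace`):

```sh
Rscript inst/cli/markalign scan --scans 5 --seed 1 --out records.csv
```

(after installation, use
`$(Rscript -e 'cat(system.file("cli/markalign", package="markalign"))')`).

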