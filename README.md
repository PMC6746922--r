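# dgmap — directed graph mapping of cardiac excitation

Cardiac arrhythmias are diagnosed from activation maps: local
activation times (LATs, ms) measured at discrete electrode positions.
Deciding from such a map whether a tachycardia is driven by **reentry**
(a wave circulating around a rotor core or an anatomical obstacle) or
by a **focal source** — and where to ablate — is difficult and
operator-dependent. `dgmap` implements directed graph (DG) mapping,
which makes that decision algorithmic: excitation is reconstructed as a
directed network whose nodes are electrodes and whose edge
`u → v` exists for neighboring electrodes iff the implied conduction
velocity is physiological,

```
CV_min < ‖x_v − x_u‖ / (LAT_v − LAT_u) < CV_max ,
```

(defaults 0.2–2.0 mm/ms ventricular, 0.08–2.0 mm/ms atrial). Reentry
is then a **directed cycle** in this network — found by breadth-first
search, bundled by center proximity (1 cm), and localized as the
bundle's center — while a focal source is a connected region of nodes
with only outgoing edges. Because a single activation window can never
contain a cycle (edges increase LAT), a second window at `t + δt`
(δt = 40 ms) is merged in: its edges are added only when the origin
electrode has not re-fired, which is exactly what closes reentrant
loops.

The package is intended for researchers working on activation-map
analysis: it contains the full diagnosis pipeline (`dgmap()`),
network-derived features (region of influence, wave averaging), an
LAT-based phase-mapping baseline (sawtooth phase + Sobel singularity
detection at a 95% threshold), synthetic activation-field generators
(rotor, multi-rotor, anatomical reentry, focal, target wave) with
exact ground truth, forward unipolar-electrogram computation with
steepest-negative-slope LAT annotation, and a Monte-Carlo LAT-noise
robustness benchmark with cluster-robust confidence intervals.

## Worked example

A stable spiral-wave rotor on a 16 × 16 electrode grid (8 mm spacing,
cycle length 260 ms), perturbed with 10 ms Gaussian LAT noise, then
diagnosed:

```r
library(dgmap)
field <- make_rotor_field(grid_shape = c(16, 16), spacing = 8,
                          cycle_length = 260, n_cycles = 4)
noisy <- add_lat_noise(field, sigma = 10, seed = 42)
dx <- dgmap(noisy, bounds = "ventricular")
dx
#> Directed graph mapping diagnosis
#>   mechanism: reentry
#>   network: 256 nodes, 736 edges
#>   core 1: center (57.3, 58.1) mm, 22 cycle(s)
```

The mechanism is identified as reentry, supported by 22 distinct
smallest cycles whose bundle center (57.3, 58.1) mm lies within one
electrode spacing of the true core at (60, 60) mm — despite the noise.
The median cycle center, which the benchmark uses for localization, is

```r
dominant_core(dx$cores)$center_median
#> [1] 57.4 59.4  0.0
```

The phase-mapping baseline on the same noisy frame finds the matching
singularity (negative response = clockwise phase winding):

```r
fr  <- lat_to_phase(noisy, t = min(unlist(noisy$lats)) - 1e-6)
detect_singularities(fr)
#>    x  y   response
#> 1 64 48 -0.8863832
```

— a detection 13 mm off the true core: already at this noise level
phase mapping localizes worse than DG mapping, the gap the
noise-robustness benchmark quantifies. On a focal field, `dgmap()`
instead reports `mechanism: focal` with one source region per stimulus
site, and `plot(dx)` draws the activation map, network arrows,
detected cycles and sources.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/dgmap simulate --kind rotor --grid 16x16 --spacing 8 --out field.csv
Rscript inst/scripts/dgmap diagnose field.csv --preset ventricular --out report.json
Rscript inst/scripts/dgmap benchmark --grid 16x16 --sigmas 0,10,20 --reps 10 --seed 1 --out bench.csv
```

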