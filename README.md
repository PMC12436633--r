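# flow4d

Hemodynamic post-processing of 4D flow MRI velocity fields in R.

4D flow MRI measures all three velocity components of a fluid over a 3-D
volume, time-resolved across the cardiac cycle. It is increasingly used to
characterise the flow inside pulsatile blood pumps (ventricular assist
devices, total artificial hearts) and cardiac chambers, where disturbed
flow — stasis, recirculation, turbulence, elevated shear — relates to
thrombosis and hemolysis risk. flow4d is for engineers and imaging
scientists doing that kind of bench or in vivo analysis: it takes
time-resolved velocity volumes (NIfTI-1 + JSON sidecar) and computes the
standard derived quantities, with every stage verifiable against analytic
phantoms.

## What it computes

With density ρ, viscosity μ, velocity u and strain-rate tensor
S_ij = ½(∂v_i/∂x_j + ∂v_j/∂x_i):

- kinetic energy density `KE = (ρ/2)(u_x² + u_y² + u_z²)` [J/m³]
- viscous dissipation
  `φ_v = ½ Σ_i Σ_j [(∂v_i/∂x_j + ∂v_j/∂x_i) − (2/3)(∇·u)δ_ij]²` [s⁻²]
  and viscous energy loss `E_L' = μ Σ φ_v V_i` [W]
- scalar shear stress `τ = μ √(2 S_ij S_ij)` [Pa]
- turbulent kinetic energy `TKE = (ρ/2)(σ_xx² + σ_yy² + σ_zz²)` [J/m³]
  from intravoxel velocity variances estimated from magnitude attenuation,
  `σ_i² = (2/k_v²) ln(|S_ref|/|S_venc,i|)`, `k_v = π/VENC`
- relative stasis `r_stasis = 100 · n_stasis/N_tot` [%] (default
  threshold 0.1 m/s)
- flow rate `q = Σ u_N ΔA`, stroke volume, Reynolds number
  `Re = ρ q_max d/(μ A)`, regional time series, maximum-intensity
  projections, shear histograms (0.02 Pa bins), quartiles, line profiles
- recirculation-zone height and length per frame from the
  zero-axial-velocity isosurface in a declared duct

Background phase offsets are corrected by fitting a 2nd-order 3-D
polynomial to a static (zero-flow) acquisition and subtracting its
extrapolation; segmentation is by magnitude threshold with
largest-component cleanup.

## Worked example

Every pipeline stage runs on analytic phantoms bundled as code, so there
is nothing to download:

```r
library(flow4d)
r <- makeDemo("demo_out", seed = 1)
cat(r$report, sep = "\n")
```

```
flow4d synthetic demonstration study
seed: 1

steady Poiseuille pipe (R = 11 mm, U = 0.5 m/s, 2 mm grid):
  flow rate: 0.000190711 m^3/s (closed form pi R^2 U = 0.000190066; error +0.34%)
  viscous energy loss: 0.000516655 W (closed form 8 pi mu L U^2 = 0.000557947; error -7.40%)
  stasis in the fast core (|u| >= 0.1 m/s all frames): 0.0% of 1068 voxels

separation duct (sinusoidal zero-crossing curve):
  detected height 0.02397 m (truth 0.024), length 0.0584 m (truth 0.05999)

turbulence layer (VENC 0.70 m/s, Gaussian intravoxel model):
  max |TKE - (rho/2) sum sigma^2| after encode->estimate: 2.84e-14 J/m^3
  peak TKE: 92.94 J/m^3 over 1800 voxel-frames
```

Reading the numbers: the voxel-summed flow rate through a 2 mm-gridded
11 mm pipe lands within 0.34% of the exact πR²U; the viscous energy loss
integral sits 7.4% below the exact 8πμLU² because one-sided wall stencils
under-resolve the near-wall shear (the error shrinks under refinement —
see the methods vignette); the recirculation detector recovers the
constructed zone size to sub-voxel accuracy; and the turbulence pipeline
(encode magnitudes → estimate variances → TKE) is an exact inverse pair.

The same stages run on data from disk:

```r
d <- readDataset("my_acquisition/")        # vel_x/y/z.nii.gz + sidecar.json
cfg <- analysisConfig(d, staticData = "my_static/",
                      outDir = "results_run1")
runPipeline(cfg)                           # maps, series, manifest.json
```

A thin command-line wrapper with the same stages ships in
`inst/scripts/flow4d`.

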