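# ventmech

Finite-element analysis of ependymal cell loading on the lateral-ventricle
wall, and its relation to periventricular white matter hyperintensities
(pvWMH).

## The scientific problem

Periventricular white matter lesions — bright regions on T2-FLAIR MRI —
consistently first appear as *caps* in the anterior and posterior horns of
the lateral ventricles. One candidate explanation is mechanical: every
heartbeat pressurizes the ventricles, and the ependymal cell monolayer
lining the wall is *stretched thin* where the wall curves most sharply,
i.e. at the horns. Chronic cyclic overstretch of the intercellular
junctions would let CSF leak into the periventricular white matter exactly
where lesions are observed to start.

`ventmech` implements that analysis as a reproducible pipeline on
synthetic 2D subjects:

1. **Subject synthesis** — a parametric axial slice: a butterfly-shaped
   ventricular cavity whose four horn tips are circular arcs of
   controllable radius, nested in white matter, a gray matter rim, and a
   subarachnoid CSF layer; plus a FLAIR-like image with planted lesions
   and a septum-like bright structure.
2. **Meshing** — graded, region-tagged triangulation with named boundary
   sets (ventricular wall, gray/white interface, gray/CSF interface,
   fixed skull).
3. **Quasistatic mechanics** — plane-strain equilibrium under follower
   pressures (ventricular pressure 20 Pa = 0.15 mmHg on the wall,
   subarachnoid pressure 1 Pa on the cortex) with a one-term Ogden
   hyperelastic energy

   Ψ = μ/2 (λ̄₁² + λ̄₂² + λ̄₃² − 3) + κ/4 (J² − 1 − 2 log J),

   with μ = 0.68, κ = 6.6 kPa for white matter, μ = 0.34, κ = 3.3 kPa for
   gray matter (white/gray stiffness ratio 2, Poisson ratio 0.45), and an
   ultrasoft compressible CSF surrogate (E = 0.1 kPa, ν = 0.3).
4. **Mechanomarkers** — reference wall frames (n₀, t₀) from a Laplace
   problem (wall = 1, gray/white interface = 0.2, gray/CSF interface = 0);
   ependymal tension λ_t = √(t₀·C t₀) and compression λ_c = √(n₀·C n₀);
   maximum principal Green–Lagrange strain; horn radius from the exact
   circle through the tension peak and its two 10 %-of-peak-excess flanks;
   and the fraction of the wall under elevated stretch.
5. **WMH segmentation** — threshold s(v) > μ + 2.5 σ inside the brain
   mask, then removal of connected components with > 50 % of their
   boundary adjacent to CSF.
6. **Statistics** — Pearson correlations, linear and reciprocal
   least-squares fits with R², and a Welch t-test of stretch at 30
   equidistant wall points split by lesion adjacency; plus the embedded
   eight-subject reference table (age, vCSF, vLV, vWMH, Fazekas score).

## Worked example

```r
library(ventmech)

run <- run_subject(run_config())   # ~10 s
print(run)
#> <vent_run> synthetic subject (seed 1)
#>   mesh: 4872 nodes, 9171 triangles (h = 2.20 mm)
#>   peak lambda_t = 1.0425, min lambda_c = 0.9650
#>   horn radii (mm): 7.54, 7.1, 7.18, 8.22; elevated wall fraction 0.250
#>   segmentation: 272 lesion pixels in 9 kept component(s)
#>   wall Welch test: t(4.4) = 22.30, p = 9.8e-06 (n+ = 4, n- = 26)
#>   fingerprint: d0940bb9

plot(run, "profile")   # lambda_t / lambda_c along the wall, peaks A-D
```

Reading the output: the ventricular wall is stretched tangentially by up
to 4.3 % (λ_t = 1.0425) at the four horns and compressed normally by up
to 3.5 % (λ_c = 0.965) there, while the lateral wall sections carry
negligible load — the four tension peaks A–D coincide with the horn tips,
and the Welch test confirms that wall points abutting the planted
periventricular lesions carry significantly higher stretch than
lesion-free points. A radius sweep (see `sensitivity_sweep()` and the
vignette) shows peak tension falling and the elevated-wall fraction
growing as horn radius increases — sharp horns in young brains load a
small wall section hard; enlarged ventricles load a long wall section
moderately.

Key statistics of the embedded subject table:

```r
s <- summarize_table1()
s$cor_vLV_FS$r    # 0.77  (p = 0.026): larger ventricles, higher Fazekas
s$cor_vWMH_FS$r   # 0.95  (p < 0.001)
s$vLV$mean        # 45.7 cm^3 (sd 16.2)
```

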