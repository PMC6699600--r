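# porescope

Structural and functional annotation of ion channel pores in R.

Ion channel structures are conventionally annotated as open or closed from
the steric dimensions of the pore alone. That criterion misses *hydrophobic
gates*: pore segments wide enough to pass a hydrated ion but lined by
hydrophobic residues, from which water spontaneously evaporates — the
desolvation penalty then blocks conduction without any physical occlusion.
`porescope` is for structural biologists and simulators who want to go
beyond a radius profile: it computes, along the permeation pathway of a
channel structure (or a solvated multi-model trajectory), the pore radius,
the hydrophobicity of the pore-facing residues, and — when waters are
present — the water density and the free-energy profile of pore hydration.

## Method

1. **Probe sweep.** The protein is a set of van der Waals spheres; the probe
   radius at a point is R(**P**) = min_j (‖**Q**_j − **P**‖ − r_j). The
   probe is stepped by Δv along the channel axis **e**_v and its position is
   optimized in each normal plane with a 2-D Nelder–Mead search, until the
   radius exceeds a stop threshold (probe left the pore); the sweep then
   repeats in −**e**_v.
2. **Centerline.** The probe centres are interpolated by an exact cubic
   spline **S**(s), reparameterized to arc length; probe radii interpolated
   along it give the continuous radius profile R(s).
3. **Pathway coordinates.** Any particle maps to (s, ρ, φ): arc length of
   its closest curve point (zero at the initial probe point's projection),
   distance to the curve, and angle about it.
4. **Solvent.** The 1-D water density P(s) is a Gaussian KDE over water
   s-coordinates (default bandwidth h = 0.14 nm ≈ one water radius, or
   AMISE/Silverman); the number density is n(s) = N·P(s)/(πR(s)²) and
   Boltzmann inversion gives G(s) = −k_B T ln[P(s)/(πR(s)²)] + C, with C
   set so G averages to zero in bulk. De-wetted segments are reported as
   long runs of sub-bulk density.
5. **Hydrophobicity.** Residues with centre of geometry within
   R(s) + 0.75 nm of the centerline are pore-lining; those whose α-carbon
   lies farther out than their centre of geometry are pore-facing. Their
   scale values (Wimley–White interface by default; scales normalized
   two-sidedly to [−1, 1] preserving the natural zero) are smoothed into a
   continuous profile by a Nadaraya–Watson kernel average (span 0.225 nm).

Trajectories are processed frame by frame and summarized with pointwise
mean/sd/min/max bands plus a frames × s density matrix.

## Worked example

An hourglass pore (waist radius 0.2 nm, wall spheres r = 0.12 nm) with
20,000 waters placed under a prescribed 6 kJ/mol Gaussian barrier at the
waist:

```r
library(porescope)

fx <- make_pore("hourglass")                      # analytic ground truth attached
fr <- place_waters(fx, 20000,
                   target_G = function(z) 6 * exp(-z^2 / (2 * 0.5^2)),
                   seed = 1)
cfg <- pore_config(bulk_band = list(c(-1.9, -1.4), c(1.4, 1.9)))
b <- analyze_frame(fr, cfg)
b
#> <PoreAnalysis> t = 0 ps, min radius 0.080 nm, 18 pore-facing residues, 20000 waters

min(b$radius$value)                               # waist: 0.2 - 0.12 = 0.08 nm
#> [1] 0.08003736
max(b$solvent$free_energy$value[abs(b$solvent$free_energy$s) < 1.5])
#> [1] 4.58        # kJ/mol; the 6 kJ/mol barrier, attenuated by kernel smoothing
b$hydrophobicity$value[which.min(abs(b$hydrophobicity$s))]
#> [1] 0.30        # leucine ring at the waist: hydrophobic (+)
b$solvent$dewetted
#> [[1]] -3.0 -2.2   # unsolvated flared mouth of the synthetic pore
#> [[2]] -0.2  0.1   # the de-wetted gate at the waist
#> [[3]]  2.2  3.0   # unsolvated mouth
```

Reading the numbers: the radius profile alone says only that the waist is
narrow (0.08 nm). The solvent analysis shows the waist is also *dry* — a
free-energy barrier of ~4.6 kJ/mol (the prescribed 5–6 kJ/mol barrier,
slightly flattened by the 0.14 nm kernel) and a detected de-wetted segment —
and the hydrophobicity profile attributes it to the hydrophobic (leucine,
+0.30) ring at the waist versus the hydrophilic (serine, −0.06) flanks.
That combination is the signature of a hydrophobic gate.

For a full report bundle (JSON profiles, annotated PDB with pore-lining in
the occupancy and pore-facing in the B-factor column, density matrix CSV,
optional OBJ surface mesh):

```r
run_porescope(fr, "out/", cfg)            # or a path to a (multi-model) PDB
```

or from the shell:

```sh
Rscript inst/cli/porescope.R run -f channel.pdb --mode full --out out/
Rscript inst/cli/porescope.R fixtures --shape hourglass --waters 20000 --out pore.pdb
```

## Units and conventions

Lengths in nm (PDB I/O converts Å), energies in kJ/mol, temperatures in K;
s = 0 at the projection of the initial probe point; population (1/n)
standard deviation in time bands. See `vignettes/pore-annotation.Rmd` for
the full methods discussion and design rationale.
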