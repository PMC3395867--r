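---
title: "Sieve-plate hydraulics: models, numerics and design choices"
author: "sieveplate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sieve-plate hydraulics: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical picture

Phloem sap moves through files of cylindrical sieve tube elements whose
end-walls — the sieve plates — are perforated by many micrometre-scale
pores. With lumen velocities of order 280 μm/s, tube radii of order 10 μm
and a sap viscosity of about 2 mPa s, the lumen Reynolds number is about
1.4×10⁻³ and the pore Reynolds number smaller still (the pore velocity is
`u/φ`, with covering fraction φ typically near 0.5, but the pore radius is
ten times smaller). Inertia is therefore negligible and the flow obeys the
Stokes equations, which is what licenses treating the tube as a network of
hydraulic resistors: resistances add in series along the tube and combine
harmonically across parallel pores.

## The resistor model

The element resistance is `R = R_L + R_P` with the lumen term
`R_L = 8ηℓ/(π(br)⁴)`. The blockage factor `b` models parietal organelles
occluding the outer part of the lumen; it rescales only the lumen radius,
never the plate pores, and `b = 0.8` is the conventional "20% blocked"
variant. Each pore contributes a Poiseuille channel term plus the Sampson
orifice end-correction,

```
R*(r_p) = 8 η ℓ_p / (π r_p⁴) + 3 η / r_p³ ,
```

a series approximation that is excellent for thin plates and still within
about 1% in its worst regime, pores as long as their diameter
(`ℓ_p = 2 r_p`). The plate is the harmonic sum over its pores. Because the
per-pore admittance scales like `r_p³…r_p⁴`, plates with variable pore
sizes conduct better than their mean radius suggests: the large-pore tail
carries the flow.

When only the mean pore radius, its spread and the pore count are known,
the harmonic sum is replaced by `N` times the expected admittance under a
normal pore-radius law (empirically, sieve pores have
`σ_p ≈ 0.25 r̄_p`). In the re-scaled radius `ξ = r_p/r̄_p` with
`α = ℓ_p/r̄_p`, `β = σ_p/r̄_p`:

```
R_P = η / (N r̄_p³) * [ ∫₀^∞ φ_β(ξ) (8α/(πξ⁴) + 3/ξ³)⁻¹ dξ ]⁻¹ ,
```

where `φ_β` is the Normal(1, β) density. Two historical estimators are
kept for comparison: the Poiseuille-only form (drops the orifice term;
its distributional variant uses `E[r_p⁴] = r̄_p⁴ + 6r̄_p²σ_p² + 3σ_p⁴`) and
the mean-radius form (keeps both terms but ignores the spread).

### Numerical choices for the integral

* The density is used *untruncated* on (0, ∞), without renormalization:
  for β ≤ 0.4 the mass below zero is at most ~0.6% and the integrand
  vanishes like ξ⁴ near zero, so the error is far below the quadrature
  tolerance of interest.
* Adaptive quadrature is applied on a window centred on the density peak,
  `(max(0, 1−10β), 1+10β)`, plus the residual tails; a blind pass over
  (0, ∞) would miss a narrow spike when β is small. Relative tolerance
  10⁻¹⁰.
* `σ_p = 0` is handled analytically (it is exactly the mean-radius form),
  never by quadrature of a near-delta density.
* When a table gives the covering fraction instead of the pore count, the
  count is recovered as `N = round(φ r² / (r̄_p² + σ_p²))` — the
  expectation of `φ = Σ r_p,i²/r²` under the normal law — and the rounding
  is flagged on the record.

## The synthetic plate generator

`sample_pore_radii()` draws radii from Normal(r̄_p, σ_p) and rejects
non-positive draws (rejection, not clipping, so the distribution shape is
preserved; for β ≤ 0.4 rejection is rare). `place_pores()` places the
pores in the cross-section disk by random sequential addition: largest
first, uniform center proposals in the feasible disk (strict containment),
a proposal is rejected if it overlaps an already-placed pore
(surface-to-surface gap < `min_gap`, default 0). Random sequential
addition jams well below φ ≈ 0.55, so dense requests can legitimately
fail; failures name the achieved versus requested covering fraction, and
the sweep records them as failed rows rather than aborting. Placement is
seeded and byte-reproducible.

The generator emulates the *statistical* structure of real plates: normal
pore sizes and non-overlapping circular pores. It does not emulate pore
shape irregularity, the spatial correlation of pores, wall margins, or the
bone-shaped widening of real tubes near the plate, so agreement of the
estimators on generated plates shows consistency of the resistor algebra,
not anatomical fidelity. The estimator cross-comparison
(`parameter_sweep()`) covers the physiological ranges α ∈ [0.4, 1.2],
β ∈ [0.2, 0.4], γ = ℓ/r ∈ [10, 100], δ = r̄_p/r ∈ [0.05, 0.2],
φ ∈ [0.1, 0.6].

## The species analysis

`run_analysis()` computes, for every record of an anatomy table, the lumen
term and the distribution-integral plate term at η = 2 mPa s, then fits
`R_P = k R_L`. Two genuinely open conventions were decided as follows:

* **Fit in log space.** The resistances span decades, and a linear-space
  least-squares fit of a proportionality is dominated by the largest
  species. The log-space fit (`k` = geometric mean of the per-species
  ratios) weights every species equally, and has an exact internal
  consistency property: multiplying every `R_L` by a constant (which is
  precisely what a lumen blockage factor does, `b⁻⁴`) divides `k` by that
  constant and leaves the correlation unchanged. The blocked-variant
  `k(b=0.8) = 0.8⁴ k(b=1)` check in the test suite rests on this. The
  linear-space fit and linear-space Pearson correlation are also reported
  (`summary()` of the fit) so the convention is inspectable, not silent.
* **Uncertainty of k.** The standard error of the mean log-ratio mapped
  through the exponential, `k·sd(log residuals)/√n`.

The correlation quoted is the Pearson correlation of (log R_L, log R_P).

### The bundled anatomy table is synthetic

The package ships `species_anatomy_synthetic.csv`, generated once by
`synthetic_species_table(19, seed = 42)`. It is a stand-in emulating the
ranges of published sieve-tube anatomy — tube radius 5–25 μm (log-uniform),
ℓ/r 10–60, r̄_p/r 0.07–0.18, ℓ_p/r̄_p 0.4–1.2, φ 0.15–0.55, with five
records carrying a "measured" spread near 0.25 r̄_p and the rest left blank
for imputation — not a transcription of any particular measured data set.
These ranges were fixed when the generator was written and have not been
adjusted since. Analyses of real data should pass their own CSV to
`run_analysis()`; the bundled table exists so the pipeline is runnable and
testable end-to-end. On it, the open-lumen fit gives `k ≈ 2.0` with
`r_corr ≈ 0.86`: the headline *structure* — proportionality of plate and
lumen resistance with `k` of order unity, hence plates roughly doubling to
tripling the total resistance — is reproduced, while the exact values of
`k` and `r_corr` are properties of the species sample, not of the model.

## The axisymmetric Stokes solver

`solve_single_pore()` validates the closed forms against a numerical
solution of the creeping-flow equations for a single coaxial pore in a
plate inside a cylindrical tube.

* **Formulation.** Stokes streamfunction ψ with `E⁴ψ = 0`,
  `E² = ∂_zz + ∂_ss − (1/s)∂_s`, discretized by centered second-order
  differences on a uniform grid, applied twice; no-slip walls carry
  Dirichlet ψ plus mirror ghosts for `∂ψ/∂n = 0`; the axis has ψ = 0 and
  `E²ψ = 0`; fully developed Poiseuille profiles are imposed at inlet and
  outlet (flux-controlled). All boundaries lie on gridlines, so the fluid
  region is tiled exactly. The sparse system is solved directly.
* **Symmetry.** The domain is mirror-symmetric about the plate mid-plane
  and creeping flow is up/downstream symmetric, so by default unknowns
  beyond the mid-plane are folded onto their mirror image, halving the
  system; the full-domain solve remains available and the test suite
  verifies the two agree to solver precision and that the full solution's
  speed field mirrors.
* **Resistance extraction.** The resistance is obtained from the
  dissipation identity `Δp·Q = 2η∫(e:e)dV`, exact for Stokes flow between
  fully developed end sections. Pointwise pressure recovery was rejected:
  the axial pressure gradient on the axis requires the `s²` coefficient of
  the near-axis field, whose extraction amplifies O(h²) discretization
  noise by 1/h⁴ and proved unusable even on the exact-Poiseuille test.
  The strain rates are formed at cell centers from the corner velocities;
  the axial pressure profile is still computed and returned for
  inspection. The analytic Hagen–Poiseuille contribution of the lumen
  segments is subtracted to isolate the plate contribution, and the
  pore-channel Poiseuille term to isolate the Sampson-like excess.
* **Grid convergence and the rim corner.** Away from the plate the scheme
  converges at second order (the open-tube case is within 0.2% of
  Hagen–Poiseuille at 48 cells per radius). The re-entrant corner at the
  pore rim reduces the global rate to roughly h^1.4 (measured), so
  `validate_stokes()` Richardson-extrapolates the plate cases over grids
  of 16, 20 and 24 cells per pore radius with the order estimated from
  the sequence itself (Aitken); a non-monotone sequence falls back to the
  finest grid with a convergence warning.
* **Validation cases and what "agreement" means.** Poiseuille (open tube)
  agrees within 2%. The thickness-independent excess of a pore with
  `ℓ_p = r_p/2` agrees with the Sampson term `3η/r_p³` within 5% at
  `r_p = 0.1 r`; the residual ~2% is dominated by genuine confinement —
  Sampson's formula assumes an unbounded plate, and at `r_p/r = 0.25` the
  measured continuum deficit grows to ~4%. The combined formula at its
  worst aspect ratio `ℓ_p = 2r_p` agrees within 5% (observed ~1%).
  Problem sizes: lumen length 4 tube radii per side (the disturbance
  decays within ~1.5 radii), grids up to ~2.3×10⁵ unknowns.
* **Localization of the disturbance.** For a single pore the centerline
  jet is ~1/δ² faster than the mean flow and relaxes on the slowest tube
  eigenmode scale (~1.5 tube radii), not on the pore-diameter scale that
  characterizes moderate-covering-fraction plates where the velocity
  contrast is only `1/φ ≈ 2`. The tests assert sub-5% deviation from
  Poiseuille beyond two tube radii and a strong disturbance within a pore
  diameter of the face.

## Limitations

* The resistor model omits pore–pore hydrodynamic interaction (reported
  elsewhere to be below ~10% for φ ≤ 0.5) and wall-proximity corrections
  (below ~2% for r_p/r ≤ 0.2); the solver's single-pore geometry cannot
  probe the former.
* Tubes are assumed perfectly cylindrical; real sieve elements often widen
  near the plate, lowering plate resistance.
* The plate thickness is treated as single-valued per plate; only the
  pore radius is given a distribution (it enters at powers 3–4 and
  dominates the variance).
* The species pipeline imputes `σ_p = 0.25 r̄_p` where unmeasured; fitted
  `k` values on the bundled synthetic table characterize the pipeline, not
  any real flora.
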