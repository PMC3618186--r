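---
title: "Modeling coiled-coil association by sedimentation equilibrium and circular dichroism"
author: "sedeq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling coiled-coil association by sedimentation equilibrium and circular dichroism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedeq)
```

# The problem

Many cytoskeletal assemblies are held together by interactions between
homodimeric coiled coils and disordered, highly charged partner chains. The
motivating system is the dynein–dynactin interface: the monomeric,
positively charged N-terminus of the dynein intermediate chain binds across
the dimer axis of a negatively charged dynactin p150 coiled-coil fragment,
forming a 2:2 heterotetramer ("dimer of dimers"). Characterizing such a
system quantitatively requires (i) knowing the oligomeric state of each
component alone, (ii) measuring the self- and hetero-association constants,
and (iii) tracking secondary structure and thermal stability. This package
implements the full analysis chain for that workflow — forward models,
global fits, profile-likelihood error bounds, and CD reductions — together
with seeded generators that emulate every experiment.

# Sedimentation equilibrium

## Forward model

At sedimentation equilibrium an ideal species obeys

$$c_i(r) = c_i(r_0)\,\exp\!\left[\sigma_i \frac{r^2 - r_0^2}{2}\right],
\qquad
\sigma_i = \frac{M_i\,(1 - \bar v_i \rho)\,\omega^2}{RT},$$

with $M_i$ the molar mass (g/mol), $\bar v_i$ the partial specific volume
(ml/g), $\rho$ the solvent density (g/ml), $\omega$ the rotor angular
velocity and $R = 8.314\times10^{7}$ erg mol⁻¹ K⁻¹. We work in cgs units
throughout (σ in cm⁻² against radii in cm), the AUC convention. The
absorbance signal is $A(r) = \sum_i \epsilon_i\, l\, c_i(r) + b$ with one
radially constant baseline $b$ per channel (default 0, optionally floated —
real absorbance optics have offsets, so the option exists even though the
generators default to none).

Three association schemes couple the species:

* **SINGLE** — one ideal species.
* **MONOMER_DIMER** — $2A \rightleftharpoons A_2$,
  $K_d = [A]^2/[A_2]$ in mol/l.
* **HETERO_2_2** — $B_2 + 2A \rightleftharpoons B_2A_2$,
  $K_d = [A]^2[B_2]/[B_2A_2]$ in mol²/l². The squared-molar unit is a
  consequence of treating the two A chains as independent monomers, the
  natural parameterization when A is monomeric and disordered on its own.

The complex inherits its extinction as the sum of its components' and its
partial specific volume as the *mass-weighted mean*. That choice is not
cosmetic: it makes buoyant masses exactly additive,
$\sigma_{complex} = \sum_i s_i \sigma_i$, so the mass-action relation
satisfied at the reference radius automatically holds at every radius. The
test suite asserts this to machine precision; it is the internal
consistency condition of an equilibrium model of chemically coupled
exponentials.

Dissociation (rather than association) constants are stored and fitted,
log-parameterized internally; the dissociation direction matches the
convention of reporting decade bounds like "K_d < 10⁻¹⁵ M²". Solution
non-ideality (second virial coefficients), meniscus/bottom mass
conservation and velocity (Lamm-equation) effects are out of scope — this
is the conventional ideal equilibrium treatment.

## The fix/float scheme and global fitting

`fitGlobal()` minimizes the unweighted sum of squared residuals (AU) over
all scans jointly; masses and $K_d$ are shared, concentrations and
baselines are per-channel. No weighting is applied because equilibrium
absorbance noise at these optical densities is approximately homoscedastic.
Two conventional protocols are wrapped:

* **Molecular weight determination** (`fitMolecularWeight()`): $\bar v$,
  $\rho$ and $\epsilon$ fixed, per-channel concentration floated, mass
  floated.
* **Association fit** (`fitAssociation()`): everything fixed except
  $\log_{10} K_d$. Here "concentration fixed" means the *total* loading
  concentration at the reference radius is held; the free monomer
  concentration is recomputed from mass action at the current $K_d$ on
  every evaluation (`totalToFree()`). Fixing the *free* concentration
  instead would leak the answer into the constraint, since the free/total
  split itself depends on $K_d$.

Optimization is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`), masses
in linear space with bounds $[0.2, 5]\times$ the initial value,
concentrations and $K_d$ in $\log_{10}$ space ($K_d$ bounds default to
±6 decades around the initial guess). Five multi-start initializations are
run per fit — start 1 at the supplied values, the rest perturbed, with
$K_d$ drawn log-uniformly over its bounded range — under seeds derived from
the user seed, so every fit is deterministic and reruns are byte-identical.
A fit in which every reduced exponent is zero (zero rotor speed, neutral
buoyancy) raises an explicit non-identifiability error rather than
returning a silent answer. A fitted $K_d$ that lands on a bound is flagged
(`atBound`), the signature of data that carry no association signal.

The reported statistics are $\chi^2$ (the raw sum of squared residuals,
AU²) and reduced $\chi^2 = \chi^2/(N - n_{\mathrm{floated}})$. On noiseless
synthetic data the reduced $\chi^2$ reaches the optimizer floor
($<10^{-12}$); with noise of SD $s$ it estimates $s^2$.

## Chi-square profiling

Point estimates of $K_d$ from equilibrium data can be sharply bounded on
one side and soft on the other, so `profileKd()` fixes $K_d$ at each point
of a log-spaced grid (default 25 points, ±3 decades), re-fits all remaining
floated parameters, and records $\chi^2$. Bounds are read where the profile
first crosses $\chi^2_{\min} + \Delta$, by log-linear interpolation,
walking outward from the minimum. The default $\Delta = 4$ is configurable
and always reported with the result; the conservative choice of re-fitting
*all* nuisance parameters at each grid point widens the bounds slightly
compared to freezing them. When a side of the profile never rises by
$\Delta$, the result is one-sided — a lower or upper limit only — with a
warning, which is exactly how weakly constrained equilibrium datasets
should be summarized.

## Condition series

`conditionSeries()` runs independent fits across a temperature, salt or pH
series and tabulates either the apparent single-species mass (sensitive to
temperature-dependent dimerization: the apparent mass falls as the dimer
dissociates) or $-\log_{10} K_d$ (which peaks at the condition of tightest
binding, e.g. an electrostatically dominated interaction maximized at
intermediate ionic strength). Failed or non-converged conditions are
flagged in the summary table and never silently dropped.

# Circular dichroism

The reductions are the standard ones: mean residue ellipticity
$[\theta] = \theta_{obs}\,\mathrm{MRW}/(10\,l\,c)$ (deg cm² dmol⁻¹, stored
at full scale, conventionally printed in units of 10³), the
length-corrected fully helical 222-nm signal
$[\theta]_{222} = -40\times10^{3}(1 - 4.6/n)$, and percent helicity as the
experimental/theoretical ratio, clipped to $[0, 1.05]$ with a warning above
1. Helical residue counts round half-to-even. The chain length $n$ is an
explicit parameter everywhere rather than being derived from a stored
sequence, because expression-tag cleavage can leave an extra residue and
shift $n$ by one; the caller decides.

Two arithmetic notes, documented rather than hidden: the formula gives
35.91×10³ at $n=45$ (35.8 at $n=44$), and a 145-residue chain at 73%
helicity and 1.5 Å/residue spans 158.8 Å while the geometric estimate
usually quoted for that fragment is 154 Å; published figures of this kind
mix rounding paths, and the package always reports the formula value.

`meltTm()` implements "Tm from the first derivative of the data" with an
explicit noise policy, since differentiation amplifies noise: the 222-nm
trace is smoothed with a Savitzky–Golay local polynomial (order 2, window 5
points, configurable), differentiated by central differences on the actual
temperature grid (endpoints dropped), and Tm is taken at the extremum of
the absolute derivative. A transition is only called when that extremum
exceeds 3× the median absolute derivative; a linear trace has a constant
derivative (ratio 1) and reports "no transition", making the qualitative
statement "this chain is unfolded" a testable output.

# Sequence properties

Net charge is the Henderson–Hasselbalch sum over the termini and the D, E,
C, Y, H, K, R side chains; it is strictly decreasing in pH, so the
isoelectric point is found by bisection on $[0, 14]$ to $10^{-4}$ pH units
(resolution far below biological meaning, and cheap). The EMBOSS pKa set is
the default scale, with the Lehninger set selectable; computed pI values
shift by a few tenths of a unit between scales, which is why literature pI
figures are treated as scale-dependent examples rather than targets.

The windowed profile (`windowedPI()`, default 28-residue windows every 7
residues — one heptad step, four heptads per window) reports only complete
windows, with 1-based inclusive starts; trailing partial windows are
dropped so every window's pI is computed from the same number of residues.

Average masses use IUPAC average residue masses plus one water (18.02 Da);
monoisotopic masses and post-translational modifications are out of scope.
The 230-nm extinction rule (900 AU/residue) is the per-residue
quantification convention for tryptophan-free coiled-coil fragments.

# What the generators emulate — and what they do not

`simulateScans()` adds i.i.d. Gaussian noise (default SD 0.005 AU) to the
exact forward model on a default radial grid of 6.85–7.15 cm in 0.001-cm
steps (a typical 3-mm column), with the same reference-radius loading at
every speed. It does *not* simulate approach to equilibrium, meniscus
artifacts, optical aberrations, or the mass-conservation constraint of a
sealed cell — so a passing fit demonstrates estimator correctness under the
model's own assumptions, not robustness to instrument systematics.

`simulateMelt()` is van't Hoff two-state unfolding with $\Delta C_p = 0$:
$K(T) = \exp[\Delta H/R\,(1/T_m - 1/T)]$, folded fraction $1/(1+K)$
(exactly ½ at $T_m$), linear folded/unfolded baselines. Irreversible
aggregation, the reason real coiled-coil melts often fail reversibility
checks, is not modeled.

`simulateCDSpectrum()` mixes a helix basis (Gaussian bands at 208 and
222 nm plus a positive 193-nm band, normalized so the 222-nm depth equals
the theoretical helical MRE for the chain length) with a coil basis (a
small positive Gaussian shoulder at 218 nm, σ = 2 nm, amplitude 350
deg cm² dmol⁻¹, hence near-zero at 222 nm). These shapes are documented
fixtures with the right qualitative geometry, not measured basis spectra;
the closed-loop guarantee is that analyzing a noiseless simulated spectrum
recovers the generating helical fraction within 0.01.

Every generator is a pure function of its parameters and seed.

# Numerical choices and problem sizes

* Bisection tolerance $10^{-4}$ pH; fine-grid pI oracles in the tests use
  $10^{-5}$.
* Levenberg–Marquardt control: `ftol = ptol = 1e-15`, up to 400
  iterations — tight enough that noiseless recovery tests pass at $10^{-6}$
  relative error in mass.
* $\Delta\chi^2 = 4$ for profile bounds, configurable and reported.
* Rounding: integer percent helicity, half-to-even residue counts,
  theoretical MRE magnitudes printed to 0.1 in units of 10³.
* The test suite runs fits on a coarsened 61-point radial grid (0.005-cm
  step) and 2–4 speeds, which leaves the physics unchanged while keeping
  the full suite around twenty seconds; the acceptance script uses the full
  301-point grid at four speeds.
* Degenerate inputs fail loudly: zero-field fits, inverted temperature
  grids, non-monotone radii, unknown configuration keys and non-standard
  residue codes are all rejected with diagnostics naming the offence.

# Limitations

Ideal-solution equilibrium only; no sedimentation velocity; no secondary
structure deconvolution (the CD side reduces to 222-nm helicity only); no
Bayesian posteriors or F-statistic contours (the χ² profile with a stated
Δ is the uncertainty statement); pI values are pKa-scale dependent; the
synthetic data are Gaussian-homoscedastic by construction. Within those
bounds, every quantitative claim the package makes is reproduced by its
test suite or its acceptance script.
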