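---
title: "Inferring fluorescence quenching mechanisms with quenchr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring fluorescence quenching mechanisms with quenchr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchr)
```

## The problem

Synthetic crowding agents — sugars, pyrrolidones, glycols and their
polymers — are added to protein samples to mimic the crowded cell
interior. Because these cosolutes also perturb intrinsic tryptophan
fluorescence, any crowding study that reads out Trp emission must first
know *how* each crowder quenches: by transient collisions (dynamic), by
ground-state association (static), by both at once, or by the
sphere-of-action effect where a quencher merely happens to sit close
enough at the instant of excitation. quenchr implements the full
inference chain from raw emission spectra to a mechanism call and, on the
computational side, thermodynamic-cycle bookkeeping for binding free
energies of fluorophore–crowder complexes.

## Models

All quenching models relate the ratio of unquenched to quenched
fluorescence intensity, $F_0/F$, to the molar quencher concentration
$[Q]$, and all share the exact anchor $F_0/F = 1$ at $[Q] = 0$:

* **Linear:** $F_0/F = 1 + K_{SV}[Q]$, with
  $K_{SV} = k_q \tau_0$ for a collisional process. A single isotherm
  cannot distinguish a dynamic $K_D$ from a static $K_S$; only the
  temperature trend can.
* **Combined static/dynamic:**
  $F_0/F = (1 + K_D[Q])(1 + K_S[Q]) = 1 + (K_D + K_S)[Q] + K_D K_S [Q]^2$.
  We fit the quadratic coefficients $(b, c)$ by least squares and recover
  the constants as the roots of $x^2 - bx + c = 0$. The roots are
  reported **unordered** (`K_lo`, `K_hi`): deciding which is the dynamic
  one requires temperature evidence, and guessing here would poison the
  classifier downstream. A negative discriminant or a negative root means
  the combined model has *no real solution* — itself diagnostic, because
  sphere-of-action data produce exactly this failure over the
  concentration ranges used.
* **Sphere of action:** $F_0/F = (1 + K_D[Q])\,e^{V[Q]}$, where $V$
  (1/M) scales with the volume around the fluorophore within which
  quenching happens with unit probability.

Because $F_0/F$ is a ratio of intensities from the same cuvette, the
intercept is fixed at 1 in every fit; a free intercept is available as a
diagnostic (`free_intercept = TRUE`) to spot baseline problems. Fits use
the replicate-mean ratios unweighted — replicate scatter in this design is
nearly homoscedastic on the ratio scale — with optional $1/\mathrm{sd}^2$
weighting (`weights = "inverse_variance"`).

Goodness of fit is the squared Pearson correlation between observed and
fitted ratios for *all* model families, so linear and nonlinear fits are
judged on the same scale. When the fitted values are constant (a genuinely
flat series) $r^2$ is undefined and reported as `NA`.

### Numerical choices

The sphere-of-action fit uses bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`, $K_D \ge 0$, $V \ge 0$), initialised from the
through-origin linear slope with $V = 0$ plus three deterministically
perturbed restarts; the lowest-RSS solution wins, and failure of every
start is reported as `converged = FALSE` rather than an error. Quadratic
root extraction happens in closed form; root pairs satisfy
sum $= b$, product $= c$ to machine precision. Free energies are carried
at full precision and rounded to 0.1 kcal/mol only at report time.

## The lifetime convention

Converting $K_{SV}$ to the bimolecular rate constant $k_q = K_{SV}/\tau_0$
needs the unquenched lifetime. We use the literature value
$\tau_0 = 3.1$ ns for free Trp at 25 °C and adopt the working convention
that the lifetime halves when the Celsius temperature doubles
($\tau_0(T) = \tau_0^{ref}\,T_{ref}/T$), giving 1.55 ns at 50 °C. This
Celsius-ratio rule is physically odd — there is no fundamental reason for
Celsius-scale scaling — but it is the convention under which the published
rate constants we validate against were derived, so
`tau0_at_temperature()` implements it verbatim and isolates it from
everything else. The synthetic generator's own temperature scaling (below)
deliberately does *not* reuse it.

## Mechanism classification

`classify_mechanism()` consumes isotherms at two temperatures and walks a
fixed decision tree. Each step that the bench literature leaves to
eyeballing is given a reproducible numeric criterion:

1. **Curvature** (`detect_curvature`): the quadratic term is accepted only
   if it is individually significant (two-sided $t$-test, $\alpha = 0.05$)
   *and* improves $r^2$ by at least 0.01. Both thresholds are exposed as
   arguments.
2. **Negligible quenching**: both isotherms linear with the 95 % CI of
   $K_{SV}$ covering 0 or $r^2 < 0.5$ — the PEG-8-like case where the
   slope is real but the scatter says nothing is being measured.
3. **Enhancement**: both slopes significantly negative (intensity rises
   with cosolute, the ethylene-glycol behaviour).
4. **Dynamic vs static**: the $K_{SV}$ difference across temperatures must
   exceed the sum of the two slope standard errors; a rise (with
   non-decreasing $k_q$) is dynamic, a fall is static. Anything inside the
   error band is returned as *inconclusive* — never a coin flip.
5. **Curved plots**: the combined quadratic is attempted first; real
   positive roots give `combined`, otherwise a converged sphere-of-action
   fit gives `sphere_of_action`. The classifier never reports
   sphere-of-action when the combined model has a real positive solution
   on the same series.

Every fit attempted along the way is attached to the returned
`mechanism_call` under `$evidence`, so any call can be audited exactly.
Hypotheses that the fits cannot themselves support (energy transfer,
fluorophore self-aggregation) belong in free-text annotations, never in
the label set.

## The synthetic-data generator

No raw titration intensities are published for this system, so the
package carries a first-class generator emulating the bench design: a
10 μM Trp solution titrated with crowder at 0–300 mg/mL in 50 mg/mL steps
(100 mg/mL ceiling is appropriate for strong quenchers like PVP 40),
measured in triplicate, at 25 and 50 °C for the temperature contrast or
25–70 °C in 5 °C steps for ramps. Mass concentrations are converted to
molarity through the crowder registry (mg/mL ≡ g/L, so $[Q]$ = conc /
molar mass).

Noise is multiplicative mean-one lognormal on each replicate's ratio with
a default CV of 1 %, reflecting that fluorescence noise scales with
signal; on ratios of order 2–3 this reproduces the few-tenths-of-a-unit
replicate scatter typical of these measurements. The zero-concentration
point is exactly 1 because each replicate is its own $F_0$ reference. All
stochastic output is reproducible from `(config, seed)`, and a seed is
mandatory whenever noise is requested.

Temperature scaling of the generating constants is a stand-in — no
quantitative law is established for these systems — with two isolated,
documented knobs:

* collisional constants scale with the **Kelvin** temperature ratio
  (diffusion speeds up roughly with absolute temperature);
* the static association constant follows a van't Hoff factor whose
  default enthalpy (≈ −2.5 kcal/mol, computed at run time, not
  hard-coded) is calibrated to reproduce the canonical dextran-like
  reduction 160 → 115 M⁻¹ between 25 and 50 °C.

What the generator does **not** emulate: inner-filter effects,
fluorophore self-aggregation, resonance energy transfer to absorbing
polymers (PVP 40 absorbs 230–400 nm), temperature-dependent band shapes,
or instrument drift. Tests passing on synthetic data therefore
demonstrate that the estimators and the decision tree are correct and
well-conditioned under the stated noise model — not that every real
titration will classify cleanly. With the default design (7
concentrations, triplicates, 1 % noise) parameter recovery is unbiased to
better than 2 % and the classifier recovers the generating mechanism in
over 95 % of seeded trials for each of the dynamic, static,
sphere-of-action and enhancement cases; with zero noise recovery is
exact. The test suite runs those checks at 500 trials per mechanism.

## Spectra

The barycentric mean wavelength is the discrete intensity-weighted mean
$\sum \lambda I(\lambda) / \sum I(\lambda)$ over grid points in the
290–450 nm window — plain summation, not quadrature, because instrument
spectra arrive already sampled and any quadrature rule cancels from the
ratio on a uniform grid. Blank correction is pointwise subtraction on an
identical grid only (no silent interpolation); slightly negative
corrected intensities are retained with a warning rather than clipped, so
weighted means stay unbiased, and the barycentre refuses spectra whose
total intensity is not positive. Shifts below 1 nm are flagged "not
significant". We assume blank-corrected spectra are the input to every
barycentre; where a workflow computes shifts from raw spectra the common
blank offset cancels only approximately.

Note one practical caveat encoded in the tests: a Gaussian band whose
tails are clipped asymmetrically by the 290–450 nm window acquires a
small bias in its barycentre, so recovered shifts of a translated band
match the translation only for bands narrow enough (width ≲ 15 nm at
350 nm centre) to fit the window; this mirrors real truncation effects at
the red edge.

## Thermodynamic cycles

For fluorophore–crowder complexes the aqueous binding free energy is
decomposed as

$$\Delta_{bind}G^\circ(aq) = \Delta_{bind}G^\circ(g) + \Delta\Delta_{solv}G^\circ,$$

with $\Delta_{bind}G^\circ(g) = G(X\!\cdots\!L,g) - G(X,g) - G(L,g)$ and
$\Delta\Delta_{solv}G^\circ$ the solvation free energy of the complex
minus those of the free species. The package only does the cycle
arithmetic and its audit; the component energies come from an external
ledger (here, DFT results shipped as CSV) and no quantum-chemistry engine
is ever invoked.

`audit_cycle_table()` recomputes each derived row from the printed
components at a tolerance of 0.15 kcal/mol — the worst case from
0.05-rounding of three addends printed to one decimal. The solvation
difference is checked against the three solvation components; the aqueous
energy is checked against printed gas + *printed* solvation difference,
which keeps the two checks independent and localises any inconsistency.
On the packaged ledgers the indole–monomer table audits clean, while in
the Trp–polymer table exactly the ficoll, PVP and PEG solvation-difference
cells cannot be reproduced from their own components (recomputed 0.6, 6.0,
0.9 vs tabulated 1.4, 6.5, 1.1 kcal/mol) even though the aqueous row is
consistent with the tabulated differences. The audit flags; it does not
decide which value is authoritative.

`binding_energy_from_K()` converts a static quenching constant — equatable
to the association constant when the fluorophore is far more dilute than
the quencher — to $\Delta G = -RT \ln K$ with
$R = 1.987 \times 10^{-3}$ kcal mol⁻¹ K⁻¹, $K$ dimensionless against a
1 M standard state, and a default $T = 298.15$ K (room temperature
assumed where no measurement temperature is stated). A 160 M⁻¹ association
constant gives −3.0 kcal/mol.

## Worked run

```{r example}
reg <- trp_crowders()
cfg <- sim_config("sphere_of_action", list(K_D = 266, V = 137),
                  reg[["ficoll 70"]], noise_cv = 0.01, seed = 7)
pair <- simulate_temperature_pair(cfg)
sv_fit(pair$low, "combined")   # no real solutions: combined model ruled out
sv_fit(pair$low, "sphere")
classify_mechanism(pair$low, pair$high)
```

## Known limitations

* The mechanism label set is the five bench-distinguishable classes plus
  `negligible` and `inconclusive`; mixtures beyond the combined quadratic
  (e.g. static + sphere) are not deconvolved.
* Lifetime-based discrimination (time-resolved measurements) is out of
  scope; the $k_q$ criterion is the stated stand-in.
* The classifier's thresholds (curvature $\alpha = 0.05$, $\Delta r^2 \ge
  0.01$, negligibility $r^2 < 0.5$, trend > combined SEs) are
  reproducible conventions for judgements the literature makes by eye;
  they are exposed as arguments, and sensitivity to them should be checked
  on any new system.
* The temperature scalings in the generator are calibrated stand-ins, not
  measured laws; conclusions about classifier performance are conditional
  on them.
* $r^2$ as squared correlation can flatter nonlinear fits with strong
  trends; it is used here for comparability with common practice in the
  field, not as a model-selection criterion (model choice rests on the
  decision tree, not on $r^2$).
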