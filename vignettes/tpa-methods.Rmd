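---
title: "Methods: sum-over-states two-photon absorption in tpasos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sum-over-states two-photon absorption in tpasos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpasos)
```

## The model

Two-photon absorption (TPA) of two identical photons of energy $\hbar\omega$
is described here in the sum-over-states (SOS) picture. The transition
tensor between the ground state $S_0$ and a final state $S_n$ is

$$S^{\alpha\beta}_{n0} \;=\; \sum_i
\frac{\mu_{ni}^{\alpha}\mu_{i0}^{\beta} + \mu_{ni}^{\beta}\mu_{i0}^{\alpha}}
     {E_i - E_0 - \hbar\omega},$$

where $\mu_{pq}$ are the permanent ($p=q$) and transition ($p\neq q$)
electric dipole vectors and the sum runs over *all* states, including the
initial and final ones. At the resonant condition $E_n - E_0 = 2\hbar\omega$
the $i \in \{0, n\}$ terms combine into
$(\Delta\mu^{\alpha}\mu_{n0}^{\beta} +
\Delta\mu^{\beta}\mu_{n0}^{\alpha})/\hbar\omega$ with
$\Delta\mu = \mu_{nn} - \mu_{00}$, and this pair of terms is what the
package always includes; an $N$-level model (NLM) then adds the $N-2$
lowest remaining states as intermediates. `tpa_tensor_nlm()` implements
exactly this truncation; `tpa_tensor_tlm()` is the $N = 2$ special case
(the two-level model, TLM).

For isotropic samples the observable is the rotational average

$$\langle\delta\rangle = \tfrac{1}{30}(F\delta_F + G\delta_G + H\delta_H),
\qquad
\delta_F = \Big(\sum_\alpha S^{\alpha\alpha}\Big)^2,\quad
\delta_G = \delta_H = \sum_{\alpha\beta} \big(S^{\alpha\beta}\big)^2$$

(the $\delta_G = \delta_H$ identity holding for the real symmetric tensors
produced here). Only the linear-parallel polarization case $F=G=H=2$ is
built in; no other case is needed for the systems the package targets. The
macroscopic cross-section is

$$\sigma = 4\pi^3\alpha^2\,\omega^2\, g(\Gamma)\,\langle\delta\rangle$$

in atomic units, converted to GM by $a_0^4 t_0 / 10^{-50}\,\mathrm{cm^4 s}
\approx 1.897$. Because $c = 1/\alpha$ in atomic units, the conventional
$a_0^5\alpha/c$ prefactor is deliberately implemented as $\alpha^2$ times
the a.u.-to-GM factor: the speed of light never appears as a standalone SI
constant anywhere in the cross-section path, which removes a classic
unit-mixing trap.

### The two-level closed form

For collinear or angled dipoles the TLM strength reduces to

$$\langle\delta_{\mathrm{TLM}}\rangle =
\frac{8}{30}\,|\Delta\mu|^2|\mu|^2\,(2\cos^2\theta + 1)\,/\,\omega^2 .$$

The $1/30$ isotropic-averaging normalization is included in the closed
form. This choice is not typographically obvious in parts of the
literature, where the averaging factor is sometimes absorbed silently; we
validated it numerically — only the $8/30$ normalization makes the closed
form agree with the explicit tensor route (tensor, then contraction, then
$F\!=\!G\!=\!H\!=\!2$ average), and the agreement is asserted to $10^{-12}$
relative in the test suite.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `gamma_ev` | lineshape half-width at half-maximum, eV | 0.1 | the conventional damping for electronic spectra; note this is HWHM, not FWHM |
| lineshape kind | Lorentzian or Gaussian, area-normalized | Lorentzian | homogeneous broadening; the Gaussian shares the same HWHM convention |
| `theta` | angle between $\Delta\mu$ and $\mu$, degrees | 0 | published tables usually print only magnitudes; collinearity is the natural default for a charge-transfer transition and is exposed, not hard-wired |
| `final` | final state (1-based; state 2 = $S_1$) | 2 | the $S_0\to S_1$ transition of GFP-type chromophores |
| `N` | truncation order | all states | convergence is inspected with `convergence_scan()` |
| photon energy | $\hbar\omega$, Hartree | $(E_n - E_0)/2$ | resonant two-photon condition; off-resonance values are allowed and the result is flagged accordingly |

Internally everything is in Hartree atomic units; Debye, eV, nm and
cm$^{-1}$ appear only at I/O boundaries (`debye_to_au()`,
`energy_convert()`). The nm conversions use $hc = 1239.842$ eV nm fixed to
four decimals so that round trips are bit-reproducible.

## Numerical choices

* **One-photon resonance guard.** An intermediate state with
  $|E_i - E_0 - \hbar\omega| < 10^{-8}$ Hartree makes the SOS denominator
  meaningless; the tensor construction raises an error naming the state
  rather than returning a silently huge tensor.
* **Dipole-matrix symmetry tolerance** is $10^{-8}$ a.u. absolute — a real
  wavefunction property, loose enough for tables re-entered at printed
  precision. Violations report the worst offending state pair.
* **Intermediate ordering.** NLM truncations include remaining states in
  ascending energy order, the order in which intermediate manifolds
  converge in practice.
* **Gauge.** Two-level tables built from magnitudes put the whole
  permanent-dipole difference on the excited state
  ($\mu_{00} = 0$). Only $\Delta\mu$ enters the two-level strength, so any
  gauge with the same difference is equivalent; a test shifts both
  permanent dipoles by a common vector and asserts invariance.
* **Exact tensor symmetry.** The symmetrized numerator makes every term of
  the sum bitwise symmetric, so $\delta_G = \delta_H$ holds identically,
  not just to rounding.
* **State indexing.** Files and serialized results use the spectroscopic
  0-based numbering (S0 = 0); in R, tables are 1-based (state 1 = S0,
  default final state 2 = S1), the idiomatic choice for R containers.

## What the synthetic generators emulate

`random_state_table()` produces energy-ordered states in a chosen span
(minimum gap 0.05 eV, so no accidental near-degeneracies) with symmetric
zero-mean Gaussian dipole matrices. It emulates nothing about any specific
molecule — it exists so that the truncated tensor can be checked against an
independently coded brute-force sum on tables larger than two states, and
so that invariance properties (rigid rotation, $k^4$ dipole scaling) can be
exercised where every term of the sum is active.

`tlm_dominant_table()` grafts weakly coupled higher states (couplings 5% of
the transition dipole, random directions, energies above the final state)
onto a two-state system. It emulates the charge-transfer regime of GFP-type
chromophores, in which intermediate-state contributions to the
cross-section stay within a few percent; the convergence scan over
$N = 2..7$ is asserted to stay within 5%.

`random_ensemble()` draws cross-sections from a normal distribution
truncated at zero (default: 21 conformers, center 15 GM, spread 4 GM),
mimicking a conformational-sampling protocol in which ~20 snapshots of an
MD trajectory are evaluated. What it does **not** emulate: correlations
between consecutive trajectory frames, skewness from the nonlinear
dipole-to-cross-section map, or any protein-specific physics. Passing
tests therefore validate the estimator logic, not any claim about real
conformer distributions.

## Study sizes used by the test suite

Oracle comparisons run on 5–7-state tables over 20 seeds; Monte-Carlo
orientation averaging uses $10^5$ unit vectors and must agree with the
analytic contraction within three standard errors; the ensemble estimator
is characterized over 200 seeded 21-sample replicates. These sizes make
the whole suite run in seconds while leaving every statistical assertion
comfortably powered.

## Known limitations

* Only degenerate (one-color) TPA, linear-parallel polarization, and a
  single phenomenological lineshape; no vibronic structure, inhomogeneous
  broadening, or complex/damped response formalisms.
* Energy denominators are taken exactly as supplied in the state table;
  the package does not distinguish perturbed from zero-order energies —
  callers choose what they load.
* The polarizability difference $\Delta\alpha$ in the internal-field
  relation $E = \Delta\mu^{\mathrm{ind}}/\Delta\alpha$ is an input; computing
  it would require electronic-structure machinery far outside this
  package's scope.
* The ensemble mode is reported as the midpoint of the highest-count
  histogram bin (Freedman–Diaconis binning with a floor of five bins, ties
  to the lowest bin). A kernel-density peak was rejected deliberately:
  ~20-sample ensembles cannot support density estimation. The flip side,
  which the test suite measures directly, is that the histogram mode of a
  21-sample ensemble with a spread of several GM is itself a noisy
  location estimator — its bin frequently misses the generating center —
  so the mode should be read as a descriptive summary of the histogram,
  not as a reliable estimate of the distribution's peak. The sample mean
  recovers the center at the expected $\sigma/\sqrt{n}$ rate.
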