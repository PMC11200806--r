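---
title: "Springpot rheometry: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Springpot rheometry: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(springpotr)
```

## The constitutive model

The package's central object is the springpot, a fractional-order
viscoelastic element whose stress is the $\alpha$-th fractional derivative
of strain scaled by the coefficient of consistence $K_\alpha$
(Pa s$^\alpha$):

$$\sigma(t) = K_\alpha \frac{d^\alpha \varepsilon(t)}{dt^\alpha},
\qquad 0 \le \alpha \le 1.$$

It interpolates continuously between a spring ($\alpha = 0$,
$K_\alpha = G$) and a dashpot ($\alpha = 1$, $K_\alpha = \eta$). In the
frequency domain

$$G'(\omega) = K_\alpha \omega^\alpha \cos(\alpha\pi/2), \qquad
G''(\omega) = K_\alpha \omega^\alpha \sin(\alpha\pi/2),$$

so both moduli follow the same weak power law and the loss tangent
$\tan(\alpha\pi/2)$ is frequency-independent — the signature that
distinguishes a springpot from spring/dashpot networks, whose loss tangent
always varies with frequency. The step-strain response is

$$G(t) = \frac{K_\alpha\, t^{-\alpha}}{\Gamma(1-\alpha)},$$

which is the bridge the pipeline exploits: parameters estimated from
frequency sweeps predict time-domain relaxation with no additional freedom.
Classical comparators (spring, dashpot, Kelvin–Voigt, Maxwell) are provided
through `classical_moduli()` so the power-law fit can be judged against the
traditional alternatives.

Assumptions worth keeping in mind: the model is linear (valid only inside
the LVE region established from amplitude sweeps), isothermal, and
single-element — a lone springpot cannot produce a characteristic relaxation
time, which is precisely why gel-like materials (nearly flat $G(t)$, small
$\alpha \approx 0.02$) are well described while organ tissue, which relaxes
over seconds, is captured only in its storage modulus.

## The angular-frequency convention

The moduli expressions use an angular frequency $\omega$, but rheometer
exports index spectra by cyclic frequency in Hz, and fitted parameter
tables in this field are only mutually consistent under one reading of
$\omega$. Because the two readings differ by a factor $(2\pi)^\alpha$ in
$K_\alpha$ (with $\alpha$ unchanged), the package never assumes: every
spectrum records its convention (`"hz"` or `"rad_s"`), every fit inherits
it, and the pipeline accepts `convention:` in its config. The default is
`"hz"`, which makes the published-style parameter values
($K_\alpha = 1.5$ kPa s$^\alpha$, $\alpha = 0.019$ for a 0.4% gel)
reproduce the printed storage moduli at 0.1 Hz after rounding; the paired
convention run is covered by a test showing that only
$(K_\alpha, \alpha)$ change, never the assignment of organs to gels. For
$\alpha \approx 0.02$ the two conventions differ by
$(2\pi)^{0.02} \approx 1.04$ in $K_\alpha$ — small, but worth making
explicit rather than silent.

## Estimation choices

**Springpot fitting** (`fit_springpot()`) is Levenberg–Marquardt least
squares with $\alpha$ box-constrained to $[0,1]$, initialised from the
log–log slope of the storage channel. The default residual is the log of
both moduli jointly with equal per-point weights: log space stabilises the
two-decade dynamic range of gel spectra and makes the recovered $\alpha$
invariant to rescaling all moduli. A `storage_only` mode exists because
organ tissue departs from springpot phase behaviour in the loss channel;
the pipeline uses it for organs and the joint fit for gels. The reported
correlation coefficient is the Pearson correlation between observed and
fitted moduli on the fitted channels, in linear space.

**LVE limit** (`detect_lve_limit()`): the reference level is the mean
storage modulus over the lowest decade of tested strains and the limit is
the largest strain amplitude before the first departure beyond a tolerance
fraction (default 5%). The underlying plateaus are qualitative, so any
criterion is a convention; this one is simple, monotone in the tolerance,
and reduces to sensible degenerate answers (maximum tested strain when flat,
first strain when no plateau exists). With noisy sweeps it is conservative —
a single 2-sigma point ends the plateau — which errs on the safe side for
choosing a working strain.

**Inertial cutoff** (`detect_inertial_cutoff()`): high-frequency inertial
contamination appears as a collapse of the measured modulus. The rule is a
persistent drop below $(1-d)$ of the running maximum (default $d = 0.1$)
with no recovery; the cutoff returned is the last frequency before the
monotone decline that leads into that persistent drop, and a one-point dip
that recovers is ignored. (Walking back over the decline excludes the
mildly contaminated shoulder just past the true cutoff; a global
pre-collapse argmax is deliberately not used because on a near-flat noisy
spectrum it can land on an arbitrary early grid point and discard almost
the whole usable band.)
Truncation keeps every point at or below the cutoff. A dedicated test shows
that fitting contaminated points without truncation visibly biases
$\alpha$, which is why the pipeline always truncates first.

**Contact offset**: rheometer axial strains are reported relative to the
position where the contact force was established, so the true pre-strain is
offset by $\sigma/E$ with $\sigma = F/(\pi (d/2)^2)$. With the protocol
values (0.1 N, 25 mm, $E = 4.4$ kPa) this is $\approx 204$ Pa and
$\approx 4.6\%$. The pipeline computes a per-sample offset from that
sample's own Young modulus when a uniaxial record is present and falls back
to the 4.4 kPa default otherwise; records store *total* axial strain
(offset included), so the offset enters once, at generation or ingest, and
never twice.

**Pre-compression model** (`fit_precompression()`):
$K_\alpha = k_0(1 - b\,\varepsilon_A)$ fitted by ordinary least squares on
the equivalent line. $\varepsilon_A$ is expressed in **percent**; on that
scale a slope of $b \approx 0.02$ per percent produces the observed
$\sim 30\%$ decline of $K_\alpha$ over a ten-point pre-strain range, which
is how the units were fixed (the relation is stated without units in the
sources this field usually cites). $\alpha$ is fitted independently at each
pre-strain level and the model stores the median; fitting a shared
$\alpha$ would be equally defensible but would hide the spread that is
itself diagnostic of whether the material stays springpot-like under
compression. The contact-force fit of $K_\alpha$ and the value obtained by
evaluating the fitted $(k_0, b)$ line at the contact offset are two
different estimators and are deliberately not reconciled; the report keeps
both.

**Relaxation comparison** (`compare_relaxation()`): the statistic is the
signed percent difference of time-averaged means,
$100(\bar G_{pred} - \bar G_{meas})/\bar G_{meas}$, after linear
interpolation of both traces onto a common 201-point uniform grid over the
window. The default window of 1–10 s starts after the $\sim 1$ s ramp over
which the nominal step is applied and spans the decade over which
relaxation data are usually displayed. The closed form treats the step as
ideal; the Grünwald–Letnikov simulator supports a finite linear ramp, and a
test quantifies that for gel-like $\alpha$ the post-2 s difference between
ramp and ideal step is under 2%, which justifies the idealisation within
the default window.

**Matching** (`match_phantom()`): each organ gets the candidate gel
minimising $|\log(G'_{cand}/G'_{organ})|$ at the reference condition
(0.1 Hz, 0.1% strain), with ties broken toward the lower concentration.
The log-ratio metric is symmetric in relative terms and invariant to a
common rescaling of all moduli. Matching runs on the frequency-domain
storage modulus, not on relaxation tails — the loss modulus and the
relaxation behaviour of tissue are exactly where the single springpot is
weakest, so they would make a misleading matching criterion.

## The Grünwald–Letnikov reference

`gl_fractional_derivative()` discretises the fractional derivative with
binomial weights $w_0 = 1$, $w_j = w_{j-1}(j-1-\alpha)/j$ and evaluates the
causal convolution by FFT, zero-padded to a highly composite length so that
$10^4$–$10^5$-sample traces cost fractions of a second. The full history is
kept — no short-memory truncation — because desk-scale traces never exceed
$10^5$ samples. Two wrappers turn it into an oracle: `gl_step_response()`
(relaxation) and `gl_oscillatory_moduli()` (drive with a sinusoid, project
the steady-state stress on the sin/cos basis after discarding transient
cycles). At $dt = 1$ ms the oracle agrees with the closed forms within 1%
for $\alpha \in \{0.02, 0.5, 0.9\}$ over $t \in [0.1, 10]$ s; this
agreement is asserted in the test suite and recomputed by the acceptance
script. The oracle shares nothing with the closed-form code paths except
the parameter container.

$\Gamma$ is evaluated by R's `gamma()`; no series of our own. $\alpha = 1$
is excluded from the relaxation formula by contract (the $\Gamma(0)$ pole)
rather than handled as a limit.

## What the synthetic generator emulates — and what it does not

The generator (`gen_study()` and the per-record `gen_*()` functions)
reproduces the statistical structure the analysis assumes, so that every
pipeline stage can be exercised without instrument data:

* springpot spectra with $\alpha = 0.019$ and $K_\alpha$ set from the
  concentration power law $G' = 10.8\,c^{2.3}$ kPa at 1 Hz;
* amplitude sweeps with an LVE plateau and Hill-type softening
  $G'(\gamma) = G'_0/(1 + (\gamma/\gamma_c)^m)$ plus a loss-modulus bump —
  chosen for monotonicity and two-parameter control, with no claim of
  helix-network physics; at $\gamma = \gamma_c$ the noiseless storage
  modulus is exactly half the plateau, which the tests use as an anchor;
* an inertial collapse factor $\max(1 - ((f-f_c)/f_c)^2,\, 0)$ above the
  per-sample cutoff (0.8 Hz for the 0.25% gel, 1.2 Hz for 0.3% and 0.4%,
  9.5/9.5/4.2 Hz for heart/kidney/liver) — an empirical shape, not an
  instrument-inertia model;
* linear uniaxial records with $E = 4.4$ kPa for the gels;
* pre-strain series following $k_0(1 - b\,\varepsilon_A)$ with
  per-concentration slopes $b = 0.006/0.017/0.021$ per percent for
  0.25/0.3/0.4%;
* organ records parameterised by storage modulus at 0.1 Hz
  (1.4/0.6/0.2 kPa for heart/kidney/liver), a larger fractional order
  (0.1), and relaxation traces multiplied by
  $(1-\phi) + \phi e^{-t/\tau}$ with $\phi = 0.3$, $\tau = 2$ s so that
  organs relax over seconds while gels stay near-flat;
* lognormal multiplicative noise, default sd 2%, approximating the
  few-percent spreads typical of replicate moduli; strictly positive by
  construction, so log-space fitting is always well defined.

Everything is bit-reproducible under a fixed seed; `gen_study()` derives
per-record seeds deterministically from the study seed.

What passing tests on these data do **not** show: robustness to slip at the
plate interface, instrument compliance, temperature or immersion-medium
effects, sample ageing, biological variability between animals, or loss
moduli that genuinely violate springpot phase behaviour. The generator's
organ records are springpots with an exponential garnish, so organ-fit
quality on synthetic data is better than it would be on tissue; only the
gel-side conclusions (parameter recovery, truncation, pre-compression,
relaxation prediction) transfer with any force.

## Problem sizes and numerical details

The test suite and acceptance script use: 10 log-spaced frequencies in
[0.1, 1.2] Hz with 2% noise and 100 replicates for Monte-Carlo recovery;
25-point amplitude sweeps over [0.01, 10]%; 41-point relaxation grids over
[0.1, 10] s; GL oracles at $dt = 1$ ms over 10 s ($10^4$ samples). The full
synthetic study is 33 records (three gels x six pre-strain levels of
frequency sweeps, plus amplitude/uniaxial/relaxation records and three
organs). One pipeline run takes well under a second.

Degenerate inputs are contracts, not silent repairs: non-positive
frequencies or times, non-monotone grids, $\alpha$ outside $[0,1]$,
$\alpha = 1$ in the relaxation formula, empty candidate sets, fewer than
three points for any fit, and log-space fitting on non-positive moduli all
raise immediate errors naming the offending argument. The only warning (as
opposed to error) is a pre-compression model whose fitted line predicts
non-positive $K_\alpha$ inside its own strain range.

## Known limitations

A single springpot has no characteristic time, so tissue relaxation can
only be approximated in level, not shape; multi-element fractional models
(fractional Kelvin–Voigt or Maxwell chains, Mittag-Leffler relaxation) are
out of scope. The inertial cutoff is an empirical truncation rule, not a
correction. The concentration power law is fitted on three concentrations
in the default study, so its extrapolated amplitude at 1% concentration
carries the full leverage of that short baseline. And the CSV dialect is
the package's own; vendor rheometer exports must be converted by the user.
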