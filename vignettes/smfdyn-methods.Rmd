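---
title: "Models and methods in smfdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in smfdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfdyn)
```

smfdyn implements the single-molecule fluorescence toolbox used to
quantify ligand-modulated conformational dynamics of membrane receptors
such as the adenosine A2A receptor: ALEX smFRET burst analysis,
time-resolved fluorescence lifetime and anisotropy fitting, PET-FCS
(photoinduced-electron-transfer fluorescence correlation spectroscopy),
and post-processing of molecular-dynamics distance trajectories into
quenching statistics. This vignette records the models, the defaults,
and the design decisions behind them.

## smFRET burst analysis

A diffusing, doubly labelled receptor produces a photon burst as it
transits the confocal volume. Under alternating-laser excitation each
photon carries an excitation label (donor or acceptor laser) and an
emission label (donor or acceptor channel). Burst detection uses the
standard sliding-window photon-density criterion: a window of `m`
consecutive photons qualifies when it spans at most `T` microseconds
(defaults m = 10, T = 500 us); qualifying windows are merged and bursts
with fewer than a minimum number of photons (default 30) are discarded.
The often-cited burst-search algorithms differ mainly in bookkeeping;
all parameters are exposed.

Per burst, the corrected FRET efficiency is

  E = I_A / (I_A + gamma I_D),

with gamma (default 0.56, the value calibrated for the AF488/AF647 pair
on dsDNA standards) correcting the unequal detection efficiencies and
quantum yields, and the stoichiometry is

  S = I_DD / (I_DD + I_AA),

which separates donor-only (S near 1), acceptor-only (S near 0) and
dual-labelled (S in [0.2, 0.8], the retained band) molecules. Background
is removed per channel as rate times burst duration (floored at zero),
spectral leakage as a fixed fraction of the corrected donor counts, and
direct acceptor excitation (disabled by default) as a fraction of the
acceptor-excitation intensity.

Efficiency histograms (40 bins over [-0.1, 1.1]) are fitted by weighted
least squares to one or two Gaussians with Poisson weights
1/max(count, 1). The component count is chosen by AICc; we use the
corrected (small-sample) form because 40 bins against 6 parameters is
squarely the regime where plain AIC overfits, and we prefer the smaller
model whenever its AICc is within 2 units of the optimum
(the conventional "substantial support" threshold). Statistical
bootstrap errors come from resampling bursts with replacement and
refitting (default 2000 replicates).

Two reference widths put the observed broadening in context: the
shot-noise floor FWHM = 2.355 sqrt(E (1 - E) / F) for mean burst size
F (binomial counting statistics), and a user-supplied quasi-static
reference measured on a rigid scaffold such as dsDNA. Distances follow
from inverting the Foerster relation, R = R0 ((1 - E)/E)^(1/6).

### The burst generator and its boundary caveat

The synthetic generator draws burst sizes from a negative binomial
(mean 260 photons — a 2.6 ms transit at the ~10 us mean inter-photon
time — dispersion 2), per-burst state efficiencies from a truncated
Gaussian per mixture component, acceptor counts binomially at the
gamma-distorted probability p = gamma E / (1 - E + gamma E), and adds
Poisson background, leakage and optional single-labelled contaminants.
Leakage is generated additively (Poisson with mean leakage x donor
counts) so that the standard subtraction correction is exactly unbiased.
Acceptor-excitation brightness is Poisson around the same per-burst
intensity as donor excitation, because both ride the same transit; an
independent draw would spread the stoichiometry of genuine
double-labelled bursts far beyond what is observed.

One boundary effect matters when choosing per-state widths for recovery
studies. After corrections, efficiencies live in [0, 1] exactly, so a
component centered at E = 0.24 with a large width piles probability
against the E = 0 cliff that a Gaussian model cannot represent, and the
structurally empty bins below zero carry the highest Poisson weight.
With widths of ~0.11 this biases the fitted low-FRET weight downward by
more than 0.1. The default two-state recovery conditions therefore use
per-component widths of 0.08, which keep the boundary mass negligible
(< 0.2%) and are consistent with the precision of two-Gaussian
decompositions reported for this system; the histogram-level fit tests
use widths of 0.11/0.10 on unbounded Gaussian draws. Passing recovery
tests therefore demonstrate the estimator's correctness for
well-identified mixtures, not robustness to strong boundary pile-up.

## Fluorescence lifetime and anisotropy decays

The isotropic decay I_par + 2 G I_perp is fitted to a sum of up to
three exponentials, F(t) = sum B_i exp(-t / tau_i), by weighted least
squares with Poisson weights 1/max(count, 1); AICc selects the
component count. Fits start 0.5 ns after the histogram peak; no
instrument response deconvolution is attempted (the generator emulates a
delta IRF). The observed-count weighting carries the well-known small
downward (Neyman) bias, about 2% on the long lifetime at 1e6 counts in
16 ps bins over 50 ns; an iteratively reweighted variant
(`poisson = TRUE`) removes it and is provided for users who prefer the
approximate maximum-likelihood answer.

The anisotropy decay r(t) = (I_par - G I_perp)/(I_par + 2 G I_perp) is
masked below 100 total counts per bin (the estimator degenerates as the
denominator shrinks), carries delta-method Poisson uncertainties, and is
fitted to r0 sum A_i exp(-t / rho_i) with sum A_i = 1 enforced by
construction and r0 either free in (0, 0.4] or fixed; both modes exist
because fundamental anisotropies are conventionally quoted as "about
0.4". With a 5.6 ns fluorescence lifetime and 1e7 total counts, bins
beyond ~35 ns fall under the count floor, so the synthetic recovery
studies use a 50 ns window; a slow rotational time of ~58 ns is then
constrained by the first half-decay, which suffices for ~5% recovery
accuracy. Parametric bootstrap errors re-simulate Poisson noise around
the idealized fitted curve and refit (default 100 replicates).

## PET-FCS

Correlation curves are modelled as 3-D diffusion through a Gaussian
volume of ellipticity s times a blinking factor with one triplet and up
to three quenching exponentials:

  G(tau) = (1/N) (1 + tau/tau_D)^-1 (1 + tau/(s^2 tau_D))^-1/2
           (1 + K_t e^(-tau/t_t) + sum K_i e^(-tau/t_q,i)).

Fits are weighted by the per-lag uncertainty when present. Because the
three-component model is ill-conditioned, fitting uses (i) data-driven
starts — diffusion from the curve tail with the ellipticity pinned,
blinking from the short-lag excess over the diffusion-only curve, with
initial quenching lifetimes at least a factor 2 apart; (ii) five seeded
multi-start restarts; (iii) a structural identifiability guard mapping
each quenching lifetime into (0, tau_D/2) — an exponential as slow as
the diffusion time cannot be distinguished from a distortion of the
diffusion shoulder and, left free, will absorb it. Exponential terms
are mathematically exchangeable, so after fitting, the triplet label is
assigned to the component nearest (in log lifetime) the triplet prior
used at initialization; the prior defaults to 5 us, the scale
established by free-dye measurements. Quench-term count is selected by
AICc with nested refinement: each larger model is additionally started
from the smaller model's optimum grown by one weak term, so model
comparisons are never distorted by an under-converged fit.

Global fitting concatenates the weighted residuals of several curves
with the triplet lifetime shared and everything else per-curve,
mirroring how multi-condition datasets are analysed with a common dye
photophysics. Diffusion subtraction removes the pure diffusion factor
from data and fit, exposing the blinking decays for display.
Synthetic ground truth uses N = 1, s = 5 and tau_D = 1 ms; published
tables report hydrodynamic radii rather than waist or diffusion time,
so these are free scale choices that leave relative recovery
unaffected. Hydrodynamic radii follow from the Stokes-Einstein
relation omega0^2 / (4 tau_D) = k_B T / (6 pi eta R_H).

The multi-tau correlator bins photon arrivals (default 100 ns), takes
16 lags at the base resolution, then repeatedly halves the resolution
and adds 8 more lags per octave, with symmetric normalization per lag.
It agrees exactly with a direct correlator at the base-resolution lags;
coarser lags trade bandwidth for variance in the usual multi-tau way.
Uncertainties come from block-wise correlation over 8 contiguous
segments. FCS noise in the generator is additive Gaussian scaled to the
first-lag amplitude; real correlator noise is lag-dependent, so
recovery tests at 0.2% noise probe estimator correctness rather than
detector realism.

## MD quenching statistics

Distance trajectories (e.g. from a receptor residue's C-beta to the
aromatic centroid of a candidate quencher) are smoothed with a centered
20-ns running average (window forced odd; shrunken at the edges;
window sums are computed locally per position because long-range
cumulative sums leave constant plateaus oscillating in the last bit,
which a cutoff placed exactly on a level amplifies into spurious
transitions). Samples with d < d_q are "quenched"; transitions are
state changes between consecutive samples, reported per microsecond;
a hysteresis band (off by default) is available for noisy traces. The
cutoff itself is the contact quenching range plus the mean dye-cloud
extension, d_q = 1 nm + <l>; with <l> = 0.81 nm this gives 1.81 nm,
and scans over a 1-2 nm cutoff grid aggregate replicate mean and
standard deviation (unweighted, mirroring replicate simulations).

The two-state telegraph generator provides ground truth: exponential
dwells at the configured rates, sampled on a regular grid with i.i.d.
Gaussian jitter (an Ornstein-Uhlenbeck option exists but is off by
default, since uncorrelated jitter is the harsher test for transition
counting). Its analytic switching frequency 2 k1 k2/(k1 + k2) is the
oracle for the counting pipeline. These stand-ins reproduce the
statistical structure of distance traces, not the conformational
mechanics of a receptor: published transition-frequency curves from
hundreds of microseconds of all-atom MD are far outside desk scale, and
passing telegraph tests says nothing about force-field realism.

Dye-cloud geometry reduces each frame to the distance between an anchor
atom and the unweighted centroid of the dye's aromatic atoms, reporting
the mean extension and the exponential autocorrelation lifetime (fitted
on the log of the positive autocorrelation values). Ionic-lock analysis
thresholds a minimum-distance series at 5 Angstrom, reports the intact
fraction, contiguous segments, and optionally a normalized 2-D histogram
against any companion coordinate.

## Numerical choices and limitations

- All fits use Levenberg-Marquardt (minpack.lm) on unconstrained
  transformed parameters (log scales; logistic maps for bounded
  quantities). Model selection is AICc with the "within 2" parsimony
  rule throughout.
- Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; bootstrap replicate seeds derive deterministically
  from a master seed.
- Problem sizes in the test-suite recovery studies (5000 bursts, 1e6 or
  1e7 decay counts, 200-lag curves at 0.2% noise, 100-400 us telegraph
  traces) match the corresponding published analyses where stated and
  otherwise are chosen to give the estimators enough statistics that
  failure indicates a defect rather than noise.
- Not modelled: instrument response convolution, photon-by-photon
  diffusion paths, polarization-resolved FCS, lifetime-resolved burst
  analysis, and dynamic-FRET exchange-rate fitting. Exchange inside a
  burst shows up only as histogram broadening beyond the shot-noise
  floor.
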