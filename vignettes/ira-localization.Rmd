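---
title: "Methods: paper-ECG reconstruction and infarct-related-artery localization"
author: "pecgira"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paper-ECG reconstruction and infarct-related-artery localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pecgira)
```

## The problem and the model

A standard paper ECG prints each of the 12 leads for only 2.5 s — four
successive 2.5-s columns of one continuous 10-s recording (I/II/III, then
aVR/aVL/aVF, then V1–V3, then V4–V6) — plus a 10-s rhythm strip of one lead,
by default lead II. `pecgira` treats the printout as a *partially observed*
10-s multichannel record and rebuilds the unobserved 7.5 s of every lead
before extracting diagnostic features.

The reconstruction model assumes a near-periodic signal: heartbeats are
realizations of a stochastic template process. The observed 2.5-s segment is
delay-embedded (Takens), and a Poincaré section transverse to the trajectory
— placed through the R-wave upstroke — cuts it into one-beat ensembles. The
beats (resampled to a common length $T_e$) define an empirical covariance
kernel $K(t,T)$ whose eigenfunctions $\varphi_i$ are the Karhunen–Loève
basis; a beat is represented as $g(t)=\sum_{i=1}^{N}\alpha_i\varphi_i(t)$
with $N$ the smallest order explaining at least the variance threshold
(default 0.95). Missing beats are synthesised from this basis with
coefficients predicted from the rhythm lead and placed at the rhythm lead's
beat times; the observed window always passes through untouched, and residual
gaps are baseline-interpolated. Fidelity is scored per lead as
$R^2 = 1-\sum_k(\hat x_k - x_k)^2/\sum_k x_k^2$.

Downstream, the 12-lead record is mapped to the vectorcardiogram
$(X,Y,Z)$ by a $3\times 8$ linear transform of the eight independent leads
(inverse Dower by default; the matrix is injectable because
infarction-adapted transforms exist but their coefficients are not public).
The VCG trajectory is discretised into the 8 Cartesian octants
(index $1 + 4\,[X<0] + 2\,[Y<0] + [Z<0]$), yielding a random walk whose
local statistics, sojourn times, transition rates and network topology form
a 161-dimensional feature vector. A four-level binary hierarchy mimicking an
angiographic descent (healthy vs infarct; discernible vs not; left main vs
right coronary; LAD vs LCX) maps features to one of five classes.

## Design choices where the method was genuinely open

**Uncentred KL kernel.** $K(t,T)$ is the second-moment matrix of the beats,
not the mean-centred covariance. With the centred form, an ensemble of
identical beats would have a zero kernel and no usable basis; with the
uncentred form it is rank-1 with $\varphi_1$ proportional to the common beat
— which is the behaviour a template model needs.

**Beat boundaries from the rhythm lead.** A lead's own Poincaré section
(normal along the first embedding coordinate, offset at 50% of the
dominant-polarity peak) fails on leads whose QRS projection is nearly zero
(aVL or V1 can be such leads, depending on the electrical axis): the section
then latches onto T waves and the beats are phase-shifted relative to the R
peaks. Because all leads are simultaneous, the rhythm lead's section
crossings anchor the same beats in every lead; `reconstruct_lead()` therefore
cuts the target lead at the rhythm lead's crossing times. Pairing of overlap
beats becomes exact and R-peak alignment holds by construction. The
lead-local machinery (`takens_embed()`, `poincare_section()`,
`extract_ensembles()`) remains available and is used where only a single
lead exists.

**Cross-lead coefficient map.** The map from rhythm-lead coefficients
$\alpha^{(r)}$ to target-lead coefficients $\alpha^{(t)}$ is fitted by least
squares on the beats both leads observe — at most 3 beats at ordinary heart
rates. An unregularised fit through 2–3 noisy points extrapolates
catastrophically on low-amplitude leads (we observed $R^2 < -20$). The fit
is therefore centred and ridge-regularised with the penalty scaled to the
coefficient variance across *all* rhythm-lead beats: when the overlap beats
vary less than the record as a whole, the slope is not identifiable and
shrinks toward zero, degrading gracefully to the mean observed beat. For
truly proportional leads the slope survives. This keeps the estimator inside
the "linear map estimated from the same beats" family while making it
well-posed.

**Fewer than two observed beats** (heart rate below 48 bpm): the whole 2.5-s
segment, resampled to the rhythm beat length, becomes a single-beat template
($N=1$) and the result is flagged `fallback`.

**Exactly maximised modularity.** `Qmod` is defined as the maximum modularity
of the symmetrised octant network over all node partitions. Greedy
agglomeration is the usual heuristic, but with at most 8 nodes the exact
maximum (Bell(8) = 4140 partitions) is affordable and, unlike a heuristic,
has a well-defined value that an independent oracle can reproduce.

**Path metrics on a possibly disconnected graph.** Edge length is
$1/\text{weight}$; the average path length is taken over reachable ordered
pairs only; global efficiency averages $1/d$ over all ordered pairs with
unreachable pairs contributing 0; eccentricity, radius and diameter are
computed on the largest strongly connected component, all other entries
taking the fill value 0. Statistics of unvisited octants also take fill
value 0, and a zero-magnitude VCG sample keeps the previous sample's octant.

**Feature count.** The four groups contain 48 + 12 + 16 + 85 = 161 named
features; the transition-rate window statistics (Slow/Fast/Mean/VarTran) use
1-s sliding windows advanced sample by sample.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| sampling rate | 500 | Hz | half of typical digital ECG (1 kHz); halves test cost, far above signal bandwidth |
| variance threshold $N$ cutoff | 0.95 | fraction | standard KL truncation for ECG templates |
| PCA component cutoff | 0.80 | fraction of variance | feature-weight formula cutoff |
| cumulative weight mass | 0.80 | fraction | selection prefix cutoff |
| SMOTE neighbours $k$ | 5 | — | Borderline-1 default |
| SVM | RBF, $C=10$, $\gamma=1/p$ | — | $C$ chosen by cross-validation on the synthetic cohort; $C=1$ underfits the 161-dimensional space |
| KNN $k$ / NN width / trees | 5 / 8 / 50 | — | validated defaults, all overridable |
| level models | CART, SVM, SVM, SVM | — | detection by tree, localization by SVM — the configuration found optimal in validation |
| render resolution | 144 | dpi | digitization working resolution; 25 mm/s, 10 mm/mV paper standard |

Features are z-standardised before PCA because group scales differ by orders
of magnitude (mV statistics vs transition counts). Balancing is applied only
inside training folds during evaluation, never to test folds.

## What the synthetic generator emulates — and what it does not

`generate_dipole_record()` models the heart as a rotating 3-D dipole whose
trajectory is a sum of Gaussian P/Q/R/S/T deflections per beat, each along a
fixed spatial direction, with i.i.d. Gaussian RR jitter truncated at
$\pm 3$ SD. The 12-lead ECG is the Dower forward projection plus white
measurement noise; the noise-free dipole trajectory is the VCG ground truth.
Infarct classes implant (i) a frontal-plane rotation of the electrical axis
— magnitude constrained to 20–90°, the range reported for MI — (ii) an ST
segment shift, and (iii) an optional T-wave inversion; the class with
non-discernible location (E) draws one of the three artery perturbations at
half magnitude, a stand-in choice since no generative description of E
exists. Default per-class tuples: LAD (+50°, +0.20 mV, T inverted),
LCX (−40°, −0.15 mV), RCA (+80°, +0.10 mV, T inverted).

The generator produces class-separable, quasi-periodic, morphologically
plausible records — nothing more. It has no torso volume conductor, no
respiratory or baseline drift, no arrhythmia, no electrode artefacts. A green
reconstruction or classification test therefore establishes that the
algorithms are implemented correctly and behave as designed on near-periodic
signals; it does not establish clinical accuracy, which in the source
setting could only be measured on angiography-confirmed patient data.

## Numerical notes

* Eigenvalues of $K$ are clamped at 0 (they are non-negative up to roundoff);
  Parseval ($\sum\vartheta_i$ = total ensemble variance) holds to 1e-8
  relative and is tested.
* Beat resampling is linear interpolation to the median segment length.
* `rsquared()` errors on an identically zero measured signal (undefined
  denominator); `estimate_embedding()` errors on constant signals; the
  false-nearest-neighbour test excludes coincident neighbours (distance below
  1e-6 SD), otherwise exactly periodic signals produce spurious false
  neighbours at machine precision.
* The average-mutual-information curve is smoothed (width-5 moving average)
  before the first-local-minimum search, since 16-bin histogram estimates
  wiggle at small lags.
* Selection ties are broken by feature name; all stochastic steps take a
  `seed` and restore the caller's RNG state.
* At 144 dpi and 10 mm/mV, binary ink quantises amplitude to 1/56.7 mV. A
  lead with RMS amplitude below ~0.05 mV is therefore bounded below
  $R^2=0.99$ at the digitization stage no matter how good the tracer —
  full-scale signals round-trip above 0.99, near-zero-projection leads above
  0.95. The reconstruction benchmark is unaffected (it operates on signals,
  not renders).

## Known limitations

* Reconstruction assumes one full-length rhythm lead; without it the method
  degenerates to per-lead templates.
* Arrhythmic (non-quasi-periodic) records violate the beat-ensemble
  assumption and are out of scope.
* The inverse Dower default is a population transform; the
  infarction-adapted matrix referenced in the literature is not public and
  must be supplied by the user if available.
* Class E is only as separable as its (synthetic) definition makes it;
  clinically its separability is an open question.
* Multi-vessel occlusions are not modelled: the hierarchy emits exactly one
  label.
```{r session}
sessionInfo()
```
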