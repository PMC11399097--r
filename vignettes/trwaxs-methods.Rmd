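---
title: "Models and methods behind trwaxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trwaxs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `trwaxs`, the
assumptions behind them, the numerical choices, and the design decisions
taken where the methodology left room. It is the package's reference for
*why* the code does what it does; the README shows *how* to run it.

## 1. The measurement model

A MHz-repetition-rate XFEL delivers trains of X-ray pulses (default: 175
pulses at 564 kHz, so 1.77 µs spacing and a ~308 µs span; trains repeat at
10 Hz). An optical pump fires at the start of every other train, so trains
alternate light/dark. Each pulse produces a radially integrated scattering
curve; the pulse index within a light train is the pump–probe delay.

The photo-induced signal is modelled as a linear composition of
time-independent per-state *basis spectra* with time-dependent state
populations:

$$\Delta S(q, t) \;=\; c \sum_i BS_i(q)\, C_i(t),$$

where $c$ is the photoactivation yield (the fraction of molecules that
enter the photocycle). The assumptions are the usual ones for global
kinetic analysis of difference scattering: states interconvert by
first-order kinetics, each state has a fixed difference signature, and
signals add linearly (dilute, non-interacting molecules).

### State populations

For a sequential chain A → B (→ C) with rates $k_A$ (and $k_B$) in
µs$^{-1}$:

* two-state: $C_A = e^{-k_A t}$, $C_B = 1 - C_A$;
* three-state: $C_A = e^{-k_A t}$,
  $C_B = \frac{k_A}{k_B-k_A}\left(e^{-k_A t}-e^{-k_B t}\right)$,
  $C_C = 1 - C_A - C_B$.

$C_C$ is computed by conservation rather than by its own exponential
expression; this guarantees $\sum_i C_i(t) = 1$ to machine precision for
every rate pair and keeps all populations inside $[0,1]$ (the closed-form
expression for $C_C$ is algebraically equivalent but, written with the
wrong signs — a surprisingly easy typo with this formula — would diverge;
conservation is the safer invariant to build in). When
$|k_B-k_A|/k_A < 10^{-7}$ the generic $C_B$ formula loses precision to
cancellation, and the confluent limit $C_B = k_A t\, e^{-k_A t}$ is used
instead. The switch-over tolerance was chosen so that the generic formula
still carries ~9 significant digits at the boundary.

## 2. Variable projection

`fit_kinetics()` exploits the model's separable structure: for any fixed
rates, the optimal basis spectra are an exact linear least-squares solve
(QR, per q bin), so only the 1–2 rate constants need a nonlinear search.
The outer optimizer is Nelder–Mead simplex over *log*-rates (positivity by
construction), with a 3×3 multi-start grid spanning ±1 decade around the
initial guesses and best-of selection; the winner is polished with a
second simplex run. The target is the sum of squared per-$(q,t)$
residuals — the quantity the inner linear solve minimizes. (Squaring a
*summed* signed residual instead would be minimized by sign cancellation
and is not a least-squares target; the implemented form is the one
consistent with solving the basis spectra by least squares.)

Numerical settings: relative convergence tolerance $10^{-10}$ on the
target, plus an absolute floor of $10^{-14}\sum \Delta S^2$ — without the
floor, a purely relative criterion can never be met when the residual
itself approaches zero on noiseless data. Maximum 5000 simplex iterations
per start; non-convergence is reported on the fit object and warned about,
never silently ignored. Default initial rates are $k_A = 1/(2\,\mu s)$ and
$k_B = 1/(100\,\mu s)$, bracketing the window an intra-train delay grid
can resolve. Rank-deficient concentration matrices (degenerate rates
colliding, or a state that never populates on the grid) abort the inner
solve with an explicit error naming the collinear columns.

A per-q-bin weight hook is provided and left off by default. For
photon-limited data the natural choice is inverse-variance weighting,
$w(q) \propto 1/S_{dark}(q)$, since Poisson variance follows the mean
count; the noisy-recovery tests use this weighting and it markedly
improves the fast rate. $k_A$ remains the hardest parameter: a state that
decays mostly within the first one or two 1.77 µs samples is intrinsically
weakly identified, and on unlucky noise realizations the optimizer can
push $k_A$ into the "effectively instantaneous" regime where the target is
nearly flat. The median-error criterion used in the tests is robust to
those realizations; per-seed worst cases are not hidden by it.

### Model comparison

`compare_models()` reports both residuals and selects the three-state
model only when its relative improvement over the two-state fit exceeds a
threshold (default 5%). The threshold was calibrated on two-state truth:
a nested three-state fit fishing in pure noise stays below 5% improvement
in almost all runs, while genuine three-state data improves by orders of
magnitude. Time-slice overlays of data versus both reconstructions are
attached for the shape judgement that a single scalar cannot make.

## 3. Reduction

The production ordering is: **filter → average within flag class →
normalize → subtract → merge**.

*Filtering.* Each train's pulse-averaged q-profile is correlated (Pearson)
against a run reference built from trains of the same flag; trains with
$r < 0.99995$ are dropped. The reference is the per-bin **median** across
trains rather than the mean: in a small run, corrupted trains drag a mean
reference toward themselves, which both flatters the corrupted trains and
penalizes clean ones; the median reference is immune to this up to half
the run being corrupted. (With thousands of trains the two choices
coincide in practice.) Profile correlation, not a scalar intensity
comparison, is the right discriminator because jet instability changes the
*shape* of the curve; a pure intensity fluctuation has correlation exactly
1 and is handled by normalization instead.

*Normalization.* Each curve is divided by its summed intensity over the
recorded window (default 0.08–2.1 Å⁻¹; a 1.4–1.6 Å⁻¹ display variant is
supported). This cancels multiplicative common-mode factors — jet
thickness, pulse energy — exactly, at the cost of a small nonlinear
distortion proportional to the window sum of the difference signal
(≲ $10^{-3}$ of the signal itself at the default signal scale).
Normalization is applied per delay curve of the class-averaged data;
whether the original analysis normalized per pulse, per train, or per run
average is not decisive at these signal levels, and the per-averaged-curve
choice is the cheapest numerically stable one.

*Subtraction.* Default is class-mean subtraction per pulse index. An
adjacent-pair strategy (subtract each dark train from its neighbouring
light train, then average) is provided because the common-mode factor
drifts slowly across trains: adjacent pairs share nearly the same factor,
distant pairs do not. With purely linear processing the averaged result is
identical either way; the pair strategy matters when pairs are weighted,
trimmed, or inspected individually, and the per-pair variance comparison
in the tests shows the drift cancellation directly. An unpaired trailing
train is dropped with a message.

*Merging.* Two concentration series are merged by fitting a single scale
and a single scalar offset (least squares over all matrix entries) of the
low- onto the high-concentration series, then averaging with weights equal
to the numbers of light frames. The offset is a scalar, not per-q: it
models a systematic detector baseline, not a shape.

## 4. The synthetic generator

`simulate_train_series()` is the package's study-condition definition, not
a convenience fixture. Per train $i$ and pulse $j$:

$$\mathbb{E}[S_i(q, t_j)] = g_i \cdot
  \left(S_{dark}(q) + c \sum_k BS_k(q) C_k(t_j)\right)
  \quad (\text{light trains}),$$

with $g_i = 1 +$ drift, and observed counts Poisson around the
expectation (per integrated q bin; the normal limit replaces `rpois`
above $10^9$ expected counts only to stay inside integer range).

Defaults and why:

* **Dark curve** = Debye profile of a toy native fold **plus a
  solvent-dominated background**, sized so the final state's difference
  signal peaks at $10^{-3}$ of the total dark scattering. This realizes
  the 0.001%-signal regime of real protein-in-water WAXS physically: the
  signal is small because the background is large, and the basis spectra
  remain the *unscaled* physical Debye differences of the toy structure
  pairs — which keeps the downstream absolute-scale arithmetic honest.
* **Photon budget** $7\times10^{10}$/pulse, calibrated once so that the
  ΔS noise floor after averaging the default 50 train pairs sits at
  $10^{-5}$ (0.001%) of the background — the regime the method operates
  in. Absolute per-pulse detector counts are not a quantity this package
  claims to reproduce.
* **Rates** $k_A = 0.5$, $k_B = 0.01$ µs$^{-1}$: a first step complete
  within the first delay sample and a second step completing within the
  ~300 µs train span.
* **Yield** 0.15.
* **Jitter** is a train-level multiplicative factor with stationary sd
  $10^{-3}$ following an AR(1) drift (adjacent-train correlation 0.9).
  A drifting, not white, common mode is what motivates alternating
  light/dark trains and adjacent-pair subtraction in the first place.
* **Corruption**: selected trains are multiplied by
  $1 + s\,P(q)$ with $P$ a smooth random cubic in $q$, centered (a
  constant component carries no shape information) and normalized to
  $\max|P| = 1$; default strength $s = 0.1$. This emulates jet-shape
  artifacts — exactly the failure mode a correlation filter detects — and
  at the default strength injected trains fall far below the 0.99995
  threshold for any random shape while untouched trains are unaffected.

**States.** The three default basis spectra are Debye differences of
structurally distinct modes: A = a strong local rearrangement of a
central 36-residue segment of the intact fold (high-q-rich, small),
B = partial extension of the *N-terminal* 15 residues (a different part of
the chain), C = the terminal-span candidate nearest ΔRg = 6 Å
(low-q-rich, large). Early versions that built all three states from the
same C-terminal expansion mode at different amplitudes produced basis
spectra correlated at $r \approx 0.99$, which makes the rate fit
near-degenerate — a useful reminder that kinetic resolvability is a
property of spectral *shape*, not amplitude. Real photoreceptor data
resolve their states precisely because the chromophore-adduct,
intermediate, and unfolded signatures differ in shape.

**Toy structures.** `make_toy_structures()` builds the native fold as a
compact coiled Cα trace (spherical spiral, 3.8 Å per residue, protein-like
Rg for 125 residues) and candidates by re-sampling a 30-residue terminal
span as an increasingly extended coil. The candidate ΔRg ladder runs from
under 1 Å to ~15 Å and always passes through the 5–7 Å regime where
terminal-helix unfolding lands. Atoms are Cα-only with carbon form
factors; this is deliberately minimal — the package's claims are about
difference-profile *algebra and fitting*, not about absolute scattering
accuracy.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: detector gain stages and panel geometry,
per-pixel common-mode corrections, solvent heating signatures in ΔS,
q-dependent solvation-shell contrast, radiation damage, and the
non-Poisson tails of real readout noise. Conclusions about those require
real data.

## 5. Scattering computation

The Debye formula
$I(q) = \sum_{ij} f_i f_j \operatorname{sinc}(q r_{ij})$ is evaluated in
vacuum with constant effective electron counts per element (H 1, C 6, N 7,
O 8, S 16, P 15). There is **no solvation shell and no excluded-volume
term** — this is the main fidelity gap versus solvent-aware predictors,
and it is deliberate: every downstream use either fits a free scale
(absolute scaling, yield projection) or takes differences between models
computed the same way. Hydrogens are excluded by default when reading PDB
files. Two evaluation paths exist: the direct $O(N^2)$ pair sum and a
pair-distance-histogram path (bin width $10^{-4}$ Å, agreeing to better
than $10^{-6}$ relative on 200-atom models). One consequence of the
vacuum model worth knowing: a uniform dilation of a structure *conserves*
forward scattering and therefore produces a **negative** low-q difference
— the intuition "bigger particle, more low-q signal" belongs to
contrast-weighted, not vacuum, scattering.

Guinier Rg estimation fits $\ln I$ against $q^2$ over $qR_g < 1$, with one
round of window iteration from an initial low-q fit.

## 6. Structural fitting and the yield convention

The experimental dark curve is scaled onto the theoretical one by the
closed-form least-squares scalar
$c_{abs} = \sum S_{exp} S_{th} / \sum S_{exp}^2$; the same scale is
applied to the difference curves. Candidate fitting then projects a yield
over the $q < 0.16$ Å⁻¹ window (the Rg-sensitive regime):

$$\hat c = \frac{\sum_q \Delta S_{exp}\,\Delta S_{model}}
                {\sum_q \Delta S_{exp}^2},
\qquad
R^2 = 1 - \frac{\sum_q (\hat c\,\Delta S_{exp} - \Delta S_{model})^2}
              {\sum_q \Delta S_{model}^2}.$$

Two conventions deserve explicit documentation:

* **Direction of $R^2$.** The raw residual-to-signal ratio (0 = perfect)
  is also reported (`raw_eq_ratio`), but the headline score is the
  $1 - \cdot$ form so that "larger is better" and a 0.9 threshold means
  what it says. The normalizer is $\sum \Delta S_{model}^2$: normalizing
  by the experimental curve combined with the fitted $\hat c$ would
  collapse $R^2$ to a function of the correlation alone.
* **Direction of $\hat c$.** The projected yield multiplies the
  *experimental* curve. Under this convention the natural truth
  construction is $\Delta S_{exp} = \Delta S_{model}/c$ (then
  $\hat c = c$ exactly). Note the asymmetry: if instead one feeds in a
  physically generated curve $\Delta S_{exp} = c\,\Delta S_{model}$, the
  projection returns $1/c$. The physically-directed estimate — the scale
  of a *fully photoconverted reference* difference onto the pulsed-source
  difference, which is how excitation yields are actually measured — is
  implemented in `estimate_yield_from_reference()` (with residual
  bootstrap uncertainty, default 1000 resamples) and recovers the
  generator's true yield end-to-end. The pipeline therefore estimates the
  yield from a saturated companion simulation and feeds the candidate
  screen the measured final-state spectrum extrapolated to full conversion
  and expressed per projected-yield unit (division by $\hat y^2$: once to
  extrapolate, once for the projection convention). All of this is
  deterministic bookkeeping from measured quantities.

Selection keeps candidates with $R^2 > 0.9$ *and* yield in the closed
window $[0.10, 0.20]$ (15 ± 5%), ranks by $R^2$ descending with ties
broken by $|c - 0.15|$ and then lexicographically by model id — a pure,
idempotent, order-independent filter. An empty selection is a valid,
reported outcome.

## 7. Reproducibility and problem sizes

Every stochastic component takes an explicit seed; `run_pipeline()`
derives all stage seeds from one master seed and writes a manifest with
content hashes, so identical config + seed gives byte-identical outputs.
RNG state is saved and restored around internal seeding, so library calls
do not disturb a caller's stream.

The test suite and acceptance script run simulations at deliberately
moderate sizes chosen to make the tested statistics stable: noiseless
rate-recovery at the full 170 × 175 grid; noisy recovery at the
generator's default 50 train pairs over 20 seeds; noise-floor scaling over
a 4× range of train pairs with 3 seeds per point; estimator coverage at
100 seeds on profile-level constructions. These sizes are statements about
statistical sufficiency for the properties under test, and all expected
values in the tests were computed from independent oracles (closed forms,
brute-force enumeration, normal-equation solves) before being frozen.

## 8. Known limitations

* Only irreversible sequential chains with 2–3 states; no branched or
  reversible schemes, and no SVD pre-filtering of ΔS.
* Rate uncertainties are not profiled; the bootstrap hook covers only the
  reference-based yield.
* The azimuthal integrator models a single rectangular detector with a
  user mask and pixel-center q assignment (no area-weighted bin
  splitting); multi-panel geometry refinement and gain calibration are out
  of scope.
* Vacuum Debye scattering, as discussed in section 5.
* The 2D image path is exercised through the integrator only; the train
  simulator generates 1D profiles (per-bin Poisson), which is where the
  analysis operates.
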