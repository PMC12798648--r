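---
title: "Whole-brain Hopf models, latent embeddings, and in-silico perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain Hopf models, latent embeddings, and in-silico perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hopfbrain)
```

## The model

hopfbrain models resting-state whole-brain dynamics as N coupled
Stuart–Landau oscillators — the normal form of a supercritical Hopf
bifurcation — one per parcellated brain region. Writing the state of region
j as $z_j = x_j + i y_j$, the local dynamics are

$$\dot z_j = z_j\,(a_j + i\omega_j - |z_j|^2) + \beta\,\eta_j(t),$$

so each region sits in one of two regimes controlled by its bifurcation
parameter: for $a_j < 0$ a stable fixed point at the origin yields
noise-driven low-amplitude fluctuations, while for $a_j > 0$ a stable limit
cycle oscillates at $f_j = \omega_j/2\pi$ with amplitude $\sqrt{a_j}$.
Regions are coupled through the structural connectome $C$ by difference
coupling on both Cartesian components; in the real part,

$$\dot x_j = (a_j - x_j^2 - y_j^2)\,x_j - \omega_j y_j
   + g_j \sum_i C_{ij}(x_i - x_j) + F_{0}\cos(\omega_0 t)\,\mathbb{1}_{j = p}
   + \beta\,\eta_j(t),$$

with the mirrored expression (and no forcing term) for $\dot y_j$. The
additive cosine models periodic stimulation of one region $p$ at amplitude
$F_0$ and frequency $\omega_0$ and is switched off during ordinary
simulation. Noise is additive, independent Gaussian per node and component,
with standard deviation $\beta = 0.02$ in the package's defaults.

The coupling scale is grouped by resting-state network (RSN): every region
inherits the $(a, g)$ pair of its RSN, so a parcellation with R RSNs has 2R
free parameters (16 for the default 8 RSNs). When all $g_{\mathrm{rsn}}$
coincide this reduces to the classic single-global-G model; the RSN-wise
scale is what the genetic algorithm fits.

### Integration

The system is integrated by Euler–Maruyama. The default step is
$\mathrm{d}t = 0.096$ s so that the repetition time of 1.92 s is exactly 20
steps; the simulated real parts are decimated to one sample per TR after
discarding a 19.2 s transient, giving BOLD-like recordings of 240 volumes
(about 7.7 minutes of scan time) by default. Euler–Maruyama at this step is
the standard choice for this model family: the fastest timescale at the
default parameter ranges ($|a| \le 0.3$, node strengths of order one) is
well above $\mathrm{d}t$, and the scheme's bias is visible only in
closed-form checks (the stationary variance of a strongly subcritical node
exceeds the continuous-time Ornstein–Uhlenbeck value
$\beta^2/2|a|$ by $\mathcal{O}(|a|\mathrm{d}t)$, e.g. about 15% in variance
at $a = -5$, $\mathrm{d}t = 0.1$). A guard aborts integration with an
instability error if any state coordinate exceeds $10^6$. All noise draws
come from R's RNG, so a single `set.seed()` (or the `seed` arguments
threaded through every entry point) reproduces any simulation bit-exactly,
independent of threading — reductions happen in a fixed order.

## Preprocessing

Simulated (or supplied) recordings are linearly detrended, demeaned, and
band-pass filtered to 0.04–0.07 Hz, the narrowband in which resting-state
BOLD is most reliable. The filter is a zero-phase forward–backward
order-2 Butterworth (applied to odd-reflection-padded series); zero-phase
filtering is chosen because phase lag would bias the Pearson functional
connectivity (FC) toward zero. The band is the analysis constraint; the
filter family and order are this package's choice.

FC is the N×N Pearson correlation matrix of the band-passed signals;
group FCs average subject FCs entrywise with the diagonal reset to 1.
Intrinsic frequencies are estimated per region as the mean, across
subjects, of the in-band peak of the Hann-windowed periodogram, with ties
broken toward the lower frequency; $\omega = 2\pi f$ feeds the model.
FC matrices are vectorised as the strict upper triangle in row-major order
— (1,2), (1,3), …, (2,3), … — a layout that is frozen because it defines
the input ordering of the autoencoder.

## Fitting by genetic algorithm

Fitting minimises the goodness of fit

$$\mathrm{GoF} = 1 - \mathrm{corr}(\mathrm{FC}_{\mathrm{emp}},
  \mathrm{FC}_{\mathrm{sim}}),$$

the Pearson correlation taken over vectorised upper triangles. The
optimiser is an elitist genetic algorithm over the 2R-dimensional RSN
parameter vector: population 20, at most 20 generations, tournament
selection (k = 2), uniform crossover (rate 0.7), Gaussian mutation with
standard deviation 5% of each coordinate's bound range, elitism of 2, and
bounds $a_{\mathrm{rsn}} \in [-0.3, 0.3]$ (bracketing the bifurcation) and
$g_{\mathrm{rsn}} \in [0, 3]$. The run stops early when the
generation-mean GoF improves by less than $10^{-6}$ — an absolute mean GoF
of $10^{-6}$ is unattainable for noisy FC, so the tolerance is read as a
convergence criterion on the improvement. Candidate fitness is evaluated
by simulating the model and computing the band-passed FC; because a single
noisy realisation makes the fitness estimate itself noisy, the default
averages `n_realizations = 5` realisations per evaluation (exposed in
`ga_config()`).

A caution discovered while validating the fit, and worth knowing when
adapting the package: because Pearson correlation is invariant to the mean
and scale of the FC entries, fully synchronised regimes (every $a > 0$,
coherent phase-locking, FC saturated near 1) can score deceptively well —
their noise-free pattern still mirrors the connectome, while any honest
stochastic candidate pays a correlation penalty for FC sampling noise.
Realisation averaging (which lifts the honest candidates), targets that
are not perfectly expressible by RSN-level modulation (see the generator's
node-level heterogeneity below), and class-distinct target patterns keep
the fits informative; a fitted FC whose mean is near 1 should be treated
as a degenerate fit.

## The synthetic cohort

No public dataset accompanies the analysis this package implements
(patient data are request-only), so a first-class generator provides
ground-truth-known substitutes for every measured quantity:

* **Parcellation** — 115 regions, 8 RSNs, every RSN nonempty, left/right/
  midline labels; sizes configurable.
* **Structural connectome** — modular weighted graph: within-RSN edges are
  denser (probability 0.6 vs 0.25) and heavier (log-normal weights scaled
  3×), symmetrised, forced connected, normalised to unit mean node
  strength. This mimics the community structure of empirical fibre-density
  connectomes without claiming anatomy.
* **Conditions** — three labels (control, nonrelapsing, relapsing) whose
  ground-truth parameters differ by RSN-level offsets on $(a, g)$.
  Controls sit at a slightly subcritical baseline ($a$ from −0.10 to
  −0.05 across RSNs, $g = 2$) — the near-critical operating point that
  motivates this model family in the first place. The two patient
  conditions shift *disjoint RSN subsets* across the bifurcation with
  weakened coupling (+0.07 on $a$, −1.2 on $g$; odd-numbered RSNs for
  nonrelapsing, even-numbered for relapsing). Patterned involvement —
  different networks dysregulated in different conditions — is what makes
  the three classes distinguishable in FC *pattern* and not merely in
  overall FC level; a purely global shift was evaluated during design and
  rejected because the resulting group FCs correlated above 0.8 with one
  another, leaving no class structure for any downstream classifier.
  Intrinsic frequencies are drawn uniformly in 0.04–0.07 Hz, and a static
  node-level bifurcation offset map (SD 0.05, a "regional excitability
  map" below the RSN resolution) is added; both are seed-derived and
  shared across conditions. The node-level map matters: a ground truth
  perfectly expressible by the RSN-level fit family is also perfectly
  expressible by the degenerate synchronised manifold described above,
  whereas real cortex always carries sub-network heterogeneity.
* **Subjects** — default group sizes 128/37/31 (196 total). Each subject
  jitters its condition's RSN bifurcations by 5% multiplicative Gaussian
  noise and receives an independent noise realisation. Subject-level
  variability is this package's definition: the fitting stage itself only
  ever sees group averages.

What the generator does **not** emulate: head motion and physiological
nuisance structure, scanner drift, hemodynamic convolution, regional
heterogeneity of the hemodynamic response, and individual structural
connectomes (one group SC is shared). Tests passing on this cohort
therefore validate the pipeline's mechanics and statistical behaviour, not
its performance on empirical MRI.

## Data augmentation

Each condition's fitted model is turned into a surrogate-FC factory: the
genetic algorithm is restarted from the fit's final 20-individual
population, and every *accepted* individual evaluated during the restart
contributes the FC of its (fresh-noise, single-realisation) simulation to
the pool, rounds continuing until the per-class quota is met. "Accepted"
means the individual's GoF is at least as good as the worst member of the
saved population — it would qualify for the population itself. This bar
matters: without it, mutation diversity produces surrogates that drift
away from the class optimum and the between-class differences drown
(measured during design as a drop of ~0.2 in downstream holdout
accuracy). The default quota of 1,000 per class gives a balanced dataset
of 3,000 labelled surrogates; the package's scaled-down reproduction uses
300 per class. Surrogate variability thus has two sources: population
diversity maintained by mutation/crossover (filtered by the acceptance
bar), and simulation noise.

## Latent embedding and classification

The variational autoencoder maps vectorised FCs (6,555 features for
N = 115) through fully connected encoder layers 512 → 128 to a Gaussian
latent layer ($\mu$, $\log\sigma^2$), and decodes through the mirrored
stack. Training minimises squared reconstruction error plus the KL
divergence to a standard normal, with Adam (lr $10^{-3}$), 10 epochs,
batch 128. The layer widths and the optimiser are this package's choices; a
"training cycle" is one epoch with full shuffling and no gradient
accumulation.
Inference uses the latent mean (no sampling), so embeddings are
deterministic given the trained weights. Inputs are z-scored per feature
by default (`normalize = TRUE`, exposed in `vae_config()`), with
reconstructions mapped back to correlation units: on raw correlations the
variance of the overall FC level dominates the reconstruction loss and
the embedding encodes little beyond mean FC (measured during design as a
~0.2 drop in downstream holdout accuracy).

The classifier is a dense network of four sequentially linked layers —
hidden widths 64/32/32 plus the class-sized softmax output — with ReLU
activations, cross-entropy
loss, Adam at $10^{-3}$, 30 epochs, batch 32, and an internal 80/20
train/validation split. The evaluation protocol isolates a 100-sample
holdout that never enters any training fold, runs 5-fold cross-validation
on the rest, scores every fold-model on the holdout, and repeats the whole
procedure (default 100 repetitions; the scaled-down reproduction uses 10),
each repetition seeded as `master + i`. The latent-dimension sweep trains
one VAE per dimension (2–12 by default) and reports the accuracy
distribution per dimension; the "optimal" dimension is summarised as the
smallest whose mean accuracy is within one standard deviation of the best
mean — an explicit elbow rule rather than a hard-coded 8. Statistical
significance comes from scrambled-label nulls: labels are permuted
independently per repetition and the p-value is the fraction of null
accuracies at or above the observed mean.

A t-SNE baseline (`tsne_class_distance()`) embeds vectorised FCs in two
dimensions — exact $O(n^2)$ t-SNE with perplexity calibration, early
exaggeration and adaptive gains — and summarises class separation as the
mean pairwise distance between class centroids. Perplexity (30) and
iteration count (400) are exposed.

## In-silico perturbation

To probe which regions can move a condition across the learned class
boundaries, the fitted model of a condition is re-simulated with the
additive forcing $F_0\cos(\omega_0 t)$ on one node at a time, at that
node's intrinsic frequency (its resonant frequency, maximising the
stimulation's effect). The perturbed FC — averaged over 3 noise
realisations by default, to stabilise the classification — is encoded by
the VAE trained on unperturbed data and classified by the trained network.
Sweeping all nodes × a 12-point log-spaced amplitude grid in
[0.001, 0.5] (the package's default grid) yields the perturbation grid, and the perturbability map
keeps, per node and induced target class, the minimal amplitude whose
reclassification confidence exceeds 0.6 — twice the three-class chance
level. With $F_0 = 0$ and the same seed the pipeline reproduces the
unperturbed FC bit-exactly, which is asserted in the test suite.

## Numerical choices and degenerate inputs

* Zero-variance signals: `compute_fc()` refuses constant regional signals
  and names the offending region; `goodness_of_fit()` refuses
  zero-variance upper triangles.
* Spectral ties resolve to the lower frequency; t-SNE on identical inputs
  returns an all-zero embedding.
* Latent dimension must be smaller than the input dimension; classifier
  training requires at least two classes; perturbability thresholds must
  exceed chance (1/number of classes).
* The GA treats candidates whose simulation blows up as infinitely unfit
  rather than aborting the fit; a fit fails only if the entire first
  generation is unstable.
* Reported problem sizes for the bundled reproduction: 196-subject
  cohort, 115 regions, 300 surrogates per class, latent dimension 8, 10
  classifier repetitions — a deliberate scale-down of the full defaults
  (1,000 per class, 100 repetitions, dimensions 2–12) keeping every
  structural constant (cohort composition, GA settings, network
  architectures, thresholds) unchanged.

## Known limitations

* The corr-based GoF cannot distinguish FC mean levels, so fits are only
  identified up to the pattern of connectivity; see the caution above.
* Intrinsic-frequency estimation is biased toward a common frequency when
  coupling is strong (entrainment pulls every region's spectral peak
  together), so node-wise frequency heterogeneity in the generator is only
  partially recoverable from the simulated BOLD.
* The VAE and classifier are plain dense networks trained on CPU;
  they are small by deep-learning standards and make no claim of
  state-of-the-art representation learning.
* Perturbability maps on the synthetic cohort carry no anatomical meaning:
  the parcellation has no coordinates and the connectome no tractography.

## A minimal session

```{r example}
labs <- c("control", "nonrelapsing", "relapsing")
parc <- generate_parcellation(30, 4, seed = 1)
sc <- generate_sc(parc, seed = 2)
eff <- condition_effects(n_rsn = 4)
conds <- lapply(labs, generate_condition_parameters, parcellation = parc,
                effect_config = eff, seed = 3)
names(conds) <- labs
cohort <- generate_cohort(sc, conds, parc,
                          group_sizes = c(control = 10, nonrelapsing = 8,
                                          relapsing = 8),
                          sim = sim_settings(n_volumes = 120), seed = 4)

labv <- cohort_labels(cohort)
filt <- lapply(cohort$subjects, function(s) bandpass(s$bold))
gfc <- lapply(labs, function(l)
  group_average_fc(lapply(filt[labv == l], compute_fc)))
names(gfc) <- labs
frq <- estimate_frequencies(filt[labv == "relapsing"])

fit <- hopf_fit(gfc$relapsing, sc, frq$omega, parc,
                config = ga_config(max_generations = 10),
                sim = sim_settings(n_volumes = 120),
                label = "relapsing", seed = 5)
summary(fit)
plot(fit)
```

The full orchestration — cohort to perturbability maps with one config and
a manifest — is `run_pipeline(pipeline_config(...), out_dir)`, also
reachable from a shell via `inst/cli/pipeline.R`.
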