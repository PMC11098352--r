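---
title: "Methods: simulating camouflage evolution under attack-order selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating camouflage evolution under attack-order selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experimental paradigm camosim models

Artificial-prey predation experiments deploy populations of patterned
targets in front of real predators and use the order in which prey are
attacked as a detectability measure. Coupled to a genetic algorithm, the
attack order becomes a fitness signal: the last prey found in each arena
survive and reproduce, and their offspring form the next generation.
camosim implements that loop — genome, rendering, ranking, selection,
breeding, bookkeeping — together with the image-analysis metrics used to
quantify camouflage, and wraps them in a synthetic world (procedural
backgrounds plus a simulated observer) so the whole pipeline can be run
and validated without any field data.

The canonical configuration is 24 prey per population, split into six
groups (trays) of four; a trial ends once at least three of four prey in
a tray have been attacked, so the best-hidden prey is typically never
found. Ranks run 1 (first attacked) to 4 (last attacked or unattacked).

# The genetic algorithm

**Genome.** A fixed vector of 20 genes in [0, 1]: four palette colours
(three genes each, mapped affinely into a CIELAB box), two genes of
pattern scale (log-mapped to 4–64 px), three genes of coverage
proportions, orientation, elongation, and edge softness. The colour box
defaults to L 0–100, a −50–50, b −10–70, the gamut available to printed
targets. The spec'd layout assigns three softmax logits to four colour
proportions; we close the system with a fixed fourth logit of 0.5, which
keeps the genome at 20 genes while letting relative coverage of all four
colours evolve.

**Selection.** Fitness ranks come from attack order. Survivors are the
prey ranked `group_size − 1` and `group_size` in each group (ranks 3 and
4 in groups of four). A *rescue rule* adds prey ranked 1 or 2 in the
current generation that held the highest possible rank in the previous
generation: one unlucky early attack should not erase a pattern that was
previously the hardest to find.

**Survivor persistence (a deliberate design choice).** The rescue rule
compares one pattern's ranks in two *consecutive* generations, which is
only possible if surviving patterns are physically redeployed in the next
generation. camosim therefore carries survivors over unchanged
(elitism) and fills the remaining slots with offspring (uniform
crossover of two distinct survivors, then per-gene mutation). An
offspring-only scheme was considered and rejected: under it no pattern
ever holds ranks in two consecutive generations and the rescue rule is
unreachable code. Population size stays exactly constant either way
because the offspring count adapts to the survivor count.

**Operators.** The source experiments delegate operator details to their
pattern-generation toolbox, so camosim's values are explicit
configuration, not claims about that toolbox: mutation probability 0.2
per gene, Normal(0, 0.1) steps reflected into [0, 1], uniform crossover,
panmictic parent choice across trays. The new population is shuffled
across trays each generation so carried survivors and offspring mix.

**Drift control.** `selection = "random-control"` replaces ranked
selection with a uniform draw of two survivors per group, isolating the
GA's stochastic operators from observer selection.

# Colour vision and metrics

**Receptor-noise-limited distances.** Chromatic `ΔS` uses the general
n-receptor RNL form on log catch contrasts, with the dichromat and
trichromat closed forms falling out as special cases (the test-suite
oracle); achromatic `ΔL = |ln(lumA/lumB)|/ω`. Units are just-noticeable
differences; 1–3 JND is a conventional discrimination threshold.

**The stand-in observer model.** The field study estimates avian cone
catches from calibrated multispectral photographs; that pipeline is out
of scope here. camosim substitutes a configurable linear map from linear
sRGB to receptor catches (default: identity matrix, all Weber fractions
0.05, equal luminance weights, catch floor 1e-4 before logs). This
preserves the RNL mathematics exactly while staying self-contained; a
calibrated mapping can be loaded from JSON. No claim is made that the
defaults match any real predator's vision.

**Frequency-weighted colour difference.** Each palette colour's pixel
frequency on the rendered target weights its minimum ΔS to any
background colour, where background colours are k-means centroids
(k = 8, fixed seed, 10 restarts, pixel subsample capped at 20,000) of
the background pixels. This rewards patterns whose component colours
match something in the background even when the mean colour does not.

**Granularity pattern difference.** Octave bands at 2–64 px are hard
FFT annuli passing wavelengths within a factor √2 of the band centre;
band energy is the standard deviation of the band-passed luminance
image. The distance between two spectra is the L1 norm across bands —
the conventional granularity-difference form; the source names the
method but not the statistic.

**GabRat edge disruption.** Even-symmetric Gabor energy at the outline:
for each boundary pixel, the response parallel to the local outline
tangent is compared with the maximum response at clearly non-parallel
orientations, `g_false / (g_par + g_false)`, averaged over the outline.
Defaults: σ = 3 px across the edge, envelope elongated 1:3 along it,
wavelength 2σ, **four** orientations (45° step). The 4-orientation bank
is a deliberate deviation from an earlier 6-orientation draft: with a
30° step the bins adjacent to the tangent respond strongly to the
coherent outline itself, inflating the false-edge maximum so much that a
plain high-contrast disc scored ≈ 0.31–0.48 and the intended
uniform-vs-striped ordering collapsed. At a 45° step the disc scores
≈ 0.18 and striped outlines score reliably higher. Pixels with no
response at all are skipped; a target identical in colour to a uniform
background scores 0 by convention.

**Background sampling.** Metrics compare the target against the whole
background image, matching whole-tray comparison; annulus sampling could
be added as configuration but is not a default.

# The synthetic world

**Backgrounds.** Gaussian-smoothed colour noise around a mean gravel
tone (default CIELAB (55, 3, 18), grain 8 px, luminance contrast 8 L
units, chromatic contrast half that), emulating a gravel/sand substrate.
The *furrowed* variant multiplies luminance by meandering sinusoidal
ridges (phase-noise-distorted, amplitude relative, wavelength 128 px),
emulating 3D structure as pure luminance modulation — no cast-shadow
geometry, no photorealism. Deterministic per seed.

**What the generator does not emulate.** Real gravel has occlusion,
specularity, shadows that move with the sun, and spatial colour
statistics far richer than band-limited noise. A green selection-vs-
drift test on this world therefore establishes that the *algorithmic
loop* creates the expected selection differential under a colour-driven
observer — not that any particular field population would follow the
same trajectory.

**Observer.** Detectability is a weighted sum of metrics (default
weights 1, 1, 0, 0 on ΔS, ΔL, 1−GabRat, pattern difference; τ = 0.5).
Attacks are drawn sequentially without replacement with probability
∝ exp(d/τ); τ → 0 gives strictly descending detectability, large τ
approaches uniform. `max_attacks = 3` reproduces the trial truncation;
the screen task's 15-second limit maps onto the same truncation rather
than a reaction-time model. Validation experiments use τ = 0.05
("low-noise") with weight on ΔS only.

**Narrow colour space.** The screen-based replication of the field
study found that founding populations drawn from a narrow box — per
CIELAB channel, the background mean ± 2 sd, intersected with the full
box — evolve much more consistently than full-box populations. camosim
reproduces this construction (`colour_space = "narrow"`), and its
paired-run experiment (ten seeds, 16 generations, ranked vs control)
checks that ranked selection ends with lower weighted ΔS than drift in
at least 8/10 pairs and that only ranked runs consistently trend
downward in ΔS.

# Numerical choices and degenerate inputs

* Lab↔sRGB uses D65/2°, standard matrices, per-channel clipping to the
  8-bit range; out-of-gamut colours clip rather than fail, as a naive
  printing pipeline would. Rendered palettes are quantised to 8 bits
  before analysis (printed targets are too).
* Quantum catches and luminances are floored at 1e-4 so log contrasts
  are always defined; black-vs-black is distance 0, not NaN.
* Smoothing, band-pass and Gabor filtering run in the FFT domain with
  circular boundaries; images are analysed whole, so wrap-around affects
  only scales comparable to the image, which are excluded by the
  requirement that band scales not exceed the image.
* Unattacked prey share the top ranks in a seeded-random order; the
  field protocol does not prescribe a tie-break.
* Rejection sampling for arena anti-clustering retries up to 1,000
  times before erroring (infeasible separation requests fail loudly).
* All randomness flows through integer seeds derived from one run seed
  (each generation, tray, and operator draw gets its own derived seed),
  which is what makes byte-identical replay possible. The global RNG
  state of the calling session is saved and restored around every
  seeded operation.

# Known limitations

* The default visual system is an explicit stand-in, not avian vision;
  UV reflectance and spectral sensitivities are out of scope.
* The simulated observer has no learning, search images, neophobia or
  positional biases, so frequency-dependent effects (apostatic
  selection) cannot emerge.
* GabRat parameters interact with target size; comparisons are only
  meaningful within one fixed setting, which the run framework enforces.
* The trend report is an OLS slope on generation means with a pairs
  bootstrap — a direction flag, not a replacement for mixed-model
  analysis of real experiments.
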