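---
title: "Modelling memory construction and consolidation with genmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling memory construction and consolidation with genmem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`genmem` simulates systems consolidation as teacher–student learning between
two memory systems:

* a **hippocampal autoassociative store**, modelled as a continuous modern
  Hopfield network (MHN) that memorizes each event in one shot, and
* a **neocortical generative network**, a variational autoencoder (VAE) that
  is gradually trained on memories *replayed* from the store and comes to
  embody the statistical structure ("schemas") of experience.

## One-shot storage and attractor retrieval

Events are flattened images stored as rows of a pattern matrix
$X \in [0,1]^{M \times D}$. Retrieval iterates

$$ q \leftarrow X^\top \operatorname{softmax}\!\big(\beta\,(X q - \tfrac{1}{2}\lVert x_m \rVert^2)\big) $$

until the mean absolute change falls below `tol` (default $10^{-4}$, at most
10 steps; at $\beta = 20$ one step practically suffices). The softmax
argument equals, up to a cue-only constant, the negative squared Euclidean
distance between the cue and each stored pattern, so a partial cue completes
to the *closest* stored memory. We include the per-memory bias
$-\lVert x_m\rVert^2/2$ deliberately: with unnormalized `[0,1]` patterns the
raw inner product is dominated by pattern norms, and bright memories would
capture most cues and almost all replay. In the memory-unit reading of the
MHN (one memory unit per stored event, feature units shared), the bias is a
per-unit excitability term.

The inverse temperature $\beta$ (default 20) controls attractor sharpness:
high $\beta$ yields one-hot softmax weights and retrieval of individual
memories; as $\beta \to 0$ retrieval tends to the mean stored pattern.
**Replay** presents uniform random noise (per pixel and channel, over the
store's value range) as a cue; each retrieval returns a stored memory, and a
single fixed set of `n_replay` samples is drawn per consolidation run.

## The generative network

The VAE's image configuration uses a *patch* front end: the 64×64×3 image
is cut into non-overlapping 4×4 patches whose 48 values share one linear
embedding to 32 features (a strided convolution — for non-overlapping
patches the im2col step is a pure index permutation, so the whole network
stays inside dense matrix algebra), followed by a 256-unit ReLU dense core,
a 20-dimensional latent space with posterior mean and log-variance heads
(log-variance clipped to $[-20, 20]$), the reparameterization
$z = \mu + e^{\ell/2}\epsilon$, and a mirrored decoder ending in a shared
patch-decoding layer. The shared patch weights give the network
translation-shared local features; a purely dense encoder on the flat image
learns the hue structure of these scenes but leaves object geometry out of
the latents entirely, which would make semantic decoding impossible. The
bag-of-words configuration has no hidden layer (input → dropout → 300
latents → sigmoid output). Training uses minibatches of 64 with the AMSGrad
variant of Adam (learning rate 0.001) for up to 50 epochs with early
stopping on the training objective (patience 10, minimum improvement
$10^{-5}$ — long enough that slow late-stage latent improvements are not
cut off).

The displayed loss is

$$ \mathcal{L} = \underbrace{\overline{|x - \hat x|}}_{\text{recon, per unit}}
   + w_{\mathrm{KL}} \underbrace{\left(-\tfrac{1}{2}\textstyle\sum_i
   (1 + \ell_i - \mu_i^2 - e^{\ell_i})\right)}_{\text{KL, summed over latents}} $$

For optimization the KL term is divided by the input dimension $D$, putting
both terms on a per-unit scale. This calibration matters: with the KL summed
over latents but the reconstruction averaged per pixel, a weight of 1 on the
raw sum would exert $\sim 10^4$ times more pressure per unit than the
reconstruction term at $D = 12{,}288$ and collapse the posterior, leaving no
usable latent space. With the per-unit normalization, $w_{\mathrm{KL}} = 1$
(the image default) gives an informative latent space from which semantic
structure can be read out. The bag-of-words model uses
$w_{\mathrm{KL}} = 0.05$, which matches the image model's per-unit KL
pressure at its much smaller input dimension
($0.05 / 561 \approx 1 / 12{,}288$).

Image reconstructions use a linear output clipped to $[0,1]$ and a mean
absolute error; bag-of-words reconstructions use a sigmoid output with
per-unit cross-entropy against binarized counts, input dropout (rate 0.3)
and an L1 penalty ($10^{-5}$) on the output weights to promote sparse word
predictions. Inference-time recall decodes the posterior *mean* (chosen for
determinism; sampling adds variability without changing any qualitative
result).

## Consolidation and semantic readout

`consolidate()` draws `n_replay` replay samples once, trains a fresh VAE on
them, and tracks the emergence of semantic structure: at the end of every
epoch a linear support vector machine (cost 1, refitted from scratch) is
trained on the latent means of 200 labelled probe scenes and evaluated on a
fixed held-out set of 2,000. The probe sets are freshly generated labelled
scenes, fixed across epochs, rather than labelled replays — the readout
probes what the latent space supports, not the replay stream itself. The
held-out set is large because at desk scale the accuracy curve's rise is a
few percentage points: the evaluation's binomial noise must stay well below
that for the curve's rank structure to be meaningful.

## The extended model

`decompose_event()` splits an event into a *conceptual* component (the
latent mean) and an *unpredicted sensory* component: the per-pixel
prediction error is the channel-averaged absolute difference between the
input and its reconstruction, and pixels with error above a threshold are
stored veridically (all channel values), zeros elsewhere. The two components
are concatenated — latents first divided by a fixed scale, the maximum
absolute latent over a reference set, so neither slot dominates the softmax
similarity — and stored as one row of an extended MHN.

Recall from a partial cue decomposes the cue the same way, pattern-completes
the combined vector, decodes the retrieved latents into a prototypical
image, and overwrites it with the retrieved non-zero sensory features. At
threshold 0 every imperfectly predicted pixel is stored and recall is exact;
as the threshold rises, fewer pixels are stored and recall falls back on the
schema, reproducing the efficiency/accuracy trade-off that
`threshold_sweep()` quantifies (default grid 0, 0.05, 0.1, 0.2, 0.4 — the
grid end points span from exact recall to an almost purely conceptual
trace). The "non-zero means stored" convention is exact because the scene
renderer keeps all channel values strictly positive (see below).

Context at encoding (`encode_event_with_context()`) replaces the conceptual
slot with externally supplied latents (a class prototype: the mean latent of
50 rendered class examples) and computes the sensory residual against that
prototype's decoded image, reproducing context-driven distortion of
ambiguous stimuli. The ambiguous stimulus is the pixel average of the scene
rendered as each of the two classes, Gaussian-blurred with $\sigma = 2$ px.

# Synthetic stimuli

The generators emulate the structure of the datasets this class of model is
usually demonstrated on, without shipping any data.

**Scenes** (64×64×3) have six generative factors: floor, wall and object
hue; object shape (cube, cylinder, sphere, capsule — distinguished by
silhouette); scale (object height $6 + \mathrm{round}(40\,s)$ px, strictly
monotone in $s$); and a signed orientation proxy (horizontal offset). The
sampler draws hues uniformly on $[0,1)$ and scale uniformly on
$[0.45, 0.95]$, emulating the bounded object scales of factorized 3D-scene
datasets and keeping objects visible and classifiable. Hue maps to RGB
through an **isoluminant colour wheel**,
$c_k = 0.5 + 0.4\cos(2\pi(h + k/3))$: every pixel then has the same channel
sum and channel norm regardless of hue, so (i) all rendered scenes have
exactly equal vector norms and replay samples stored memories approximately
uniformly rather than favouring bright images, and (ii) all values are
strictly positive, making the extended model's non-zero convention exact.

**Glyphs** (28×28×1) are stroke-drawn digits in 10 classes from fixed
polyline skeletons, with per-sample translation, slant, scale and stroke
thickness jitter; a linear classifier on raw pixels separates the classes,
and within-class variation is non-trivial — the properties the
prototypicality experiment needs.

**Corpora** come from a mixture-of-topics unigram model: 20 topics × 25
topic words plus 100 background words, 2,000 documents of mean length 40,
70% of tokens from the document's topic. Each topic designates a *lure*
word whose within-topic probability is drawn per topic from $U(0.02, 0.4)$ —
real DRM lists vary enormously in associative strength (human lure-recall
norms span roughly 0.01–0.65), and homogeneous topics would make every list
cross the recall threshold at the same studied length and be recalled for
every list at full length. DRM study lists are
15 words drawn from a topic *excluding* its lure. Document-frequency
filtering (defaults: below 0.05% or above 10% of documents) removes
high-frequency background words, as stop-word removal does for real text.

What the generators do **not** emulate: 3D rendering (perspective, shadows,
occlusion), handwriting stroke statistics, natural-language syntax and
polysemy. Passing tests show the *mechanisms* behave as the model predicts
on data with the assumed factorized structure; they do not certify
performance on natural images or text.

# Experiment batteries

* **Prototypicality** — recall every glyph, compute per-pixel within-class
  variance before and after; the paired t-test and Cohen's
  $d = \bar d / s_d$ are taken over all (pixel, class) variance pairs.
* **Boundary extension/contraction** — zoom held-out cube scenes by ratio
  $r$ (margin $n = \mathrm{round}(32/r - 32)$ px per side; positive margins
  replicate edge pixels outwards, negative margins crop; bilinear resize
  back to 64×64), corrupt 10% of values, recall, and estimate the central
  object's midline size on the clean zoomed input and on the recall via
  k-means colour quantization (k = 4; object colour = dominant quantized
  colour of the central 16×16 window; scenes whose object colour merges
  with wall or floor are excluded). Input size is measured on the clean
  image because the cue's zeroed pixels would deflate the input estimate by
  the corruption fraction and bias every ratio upwards. Scenes are filtered
  to cubes with hue separation > 0.12 from both surfaces.
* **Carmichael-style context** — encode the same ambiguous stimulus under
  each class context; recall should sit closer (mean absolute distance) to
  the cued class's decoded prototype.
* **DRM** — train the bag-of-words VAE on the filtered corpus; encode each
  study list as an id-unit (one-hot, stored veridically in the sensory
  slot) plus the list's latent representation (conceptual slot); cue with
  the id; words whose decoded score exceeds 0.5 are recalled. Each studied
  word is encoded with an exposure weight of 1.25 corpus-token equivalents
  (studied items are attended and rehearsed, and raw unit counts under-drive
  the posterior relative to the ~40-token documents the encoder was trained
  on), keeping total evidence proportional to list length. Conceptual slots
  are normalized by the maximum latent L2 norm so that the unit-amplitude id
  cue always dominates the store's energy bias and retrieves its own trace.
  Lure-rate curves use list lengths 1–12 with 20 random subsets per list
  and length.
* **Lesions** — `memory_system()` bundles store, encoder, decoder and
  readout; `lesion()` disables one pathway, and calls through it raise a
  typed condition. Semantic recall needs only the encoder and readout, so
  it survives decoder (and MHN) lesions; episodic reconstruction of
  consolidated memories survives an MHN lesion but novel unconsolidated
  detail does not.

# Numerical choices and degenerate inputs

* Softmax with max-subtraction; no overflow at $\beta D$ magnitudes.
* Retrieval tolerance $10^{-4}$ (mean absolute change), max 10 steps.
* Log-variance clipped to $[-20, 20]$; gradients masked at the clip.
* Retrieved sensory entries with magnitude below $10^{-8}$ count as "not
  stored" during recombination (softmax weights of non-retrieved traces
  underflow to exactly zero at high $\beta$, so this margin is loose).
* `spearman_rho()` returns `NA` with a warning on constant input.
* Degenerate stores (one memory), single-class readouts, empty overlays,
  out-of-range corruption fractions and non-increasing threshold grids are
  rejected or handled explicitly; category sampling reports failure after
  its budget instead of erroring.
* Weight init is Glorot-uniform; all stochastic entry points accept a seed
  and are bit-reproducible given one.

# Problem sizes

The reference setup stores 2,000 scenes, replays 2,000 samples, and trains
for up to 50 epochs; the threshold sweep uses 100 overlay events at 5
thresholds with shared cues; boundary runs use 60–200 scenes per zoom
level; the DRM battery uses 20 lists × 20 subsets × 12 lengths. These sizes
are the package's chosen defaults for a desk-scale reproduction: large
enough for the qualitative phenomena and the rank statistics to be stable,
small enough to run on a single CPU in minutes.

# Known limitations

* The patch VAE reconstructs silhouettes more coarsely than a deep
  convolutional one; semantic decoding accuracy rises well above chance
  (roughly 0.25 → 0.35 on the four-way shape task over 50 epochs) but does
  not approach the ceiling a deep convolutional encoder would reach on the
  same stimuli. The *trend* of the curve, not its absolute level, is the
  reproduced phenomenon.
* Latent representations drift during training, so conceptual slots stored
  early would decode differently later; like the underlying model, the
  package stores latents as-is and does not simulate concept stabilization.
* No capacity limits, decay or deletion in the autoassociative store.
* Sequential structure (narratives, trajectories) is out of scope; the
  corpus model is bag-of-words by construction.
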