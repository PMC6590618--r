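---
title: "Shape-weighted contour length estimation for digitized biopolymer backbones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-weighted contour length estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapelength)
library(dplyr)
```

## The problem

Atomic force microscopy images single DNA molecules (and other biopolymers)
deposited on a surface. The contour length $l_c$ of a strand -- its arc
length along the backbone, in nanometres -- is a quantity of direct
biological interest: one DNA base pair is only 0.34 nm, so useful length
measurements must be accurate to a fraction of a percent.

Automated measurement traces the strand: the image is thresholded, cleaned,
and thinned to a single-pixel-wide *skeleton backbone*, which is encoded as
a Freeman 8-connect chain code $C = c_1 c_2 \cdots c_n$ with codes $0$--$7$,
one per pixel connection (even codes are horizontal/vertical unit steps, odd
codes diagonal $\sqrt2$ steps). The classical estimator sums connection
lengths,

$$L_F = r\,(n_e + \sqrt{2}\, n_o),$$

with $r$ the pixel resolution in nm/pixel and $n_e$, $n_o$ the even/odd code
tallies. Digitization makes $L_F$ systematically long by a few percent:
a digital staircase through pixel centres is longer than the smooth curve it
approximates. Fixed reweightings (Kulpa's $0.948\,n_e + 1.343\,n_o$, the
corner-count variant) and a global correction factor
($L_{DNA} = r\,C_f (n_e + \sqrt2\,n_o)$ with $C_f = \langle l_c\rangle /
\langle L_F \rangle$) reduce but do not remove the bias, because the right
correction depends on the *local* geometry of the curve.

## The shape-number estimator

This package implements a local-shape correction. Every interior
connection of the backbone sits inside a 4-pixel segment described by three
consecutive codes $(c_{i-1}, c_i, c_{i+1})$. Brute-force enumeration
(`enumerate_valid_segments()`) shows there are exactly 64 geometrically
distinct 4-pixel arrangements compatible with a single-width path, and that
they fall into 12 equivalence classes $k_1 \ldots k_{12}$ under rotation,
mirroring and traversal reversal.

A segment is identified by its *shape number*: the cyclic differences
$s_1 = (c_{i-1} - c_{i+1}) \bmod 8$, $s_2 = (c_i - c_{i-1}) \bmod 8$,
$s_3 = (c_{i+1} - c_i) \bmod 8$. Two reordering steps make the identifier
canonical -- complement every digit ($d \mapsto (8 - d) \bmod 8$) when
$s_1 > 4$, then order the last two digits ascending -- after which only
eight identifiers occur (000, 017, 026, 107, 116, 206, 277, 367); the pairs
sharing an identifier are resolved by the parity of the middle code
(even = direct centre connection, odd = diagonal). The estimator weights
each class with its own correction coefficient:

$$L_S = r \left( \sum_{j=1}^{12} n_{k_j}\, k_j\, l_{k_j} + l_H + l_T \right),$$

where $n_{k_j}$ are the class tallies along the chain, $l_{k_j} \in
\{1, \sqrt2\}$ is the centre connection length of class $j$, and $l_H$,
$l_T$ are the head and tail connection lengths (1 or $\sqrt2$), which have
no enclosing segment and are left uncorrected. With all $k_j = 1$ the
estimator is *exactly* $L_F$; this identity is asserted in the test suite.

## Calibration

Stacking the length equation over $m$ samples of known length gives

$$r\,N D K + B = L,$$

with $N$ the $m\times 12$ occurrence matrix, $D =
\mathrm{diag}(1,\sqrt2,1,\sqrt2,\sqrt2,1,\sqrt2,\sqrt2,\sqrt2,1,\sqrt2,\sqrt2)$,
$B$ the head+tail boundary lengths and $L$ the true lengths.
`solve_coefficients()` fits $K$ by QR least squares (no normal equations).
Shapes never observed in a corpus are excluded from the solve and fixed at
the Freeman weight $k_j = 1$, so the estimator degrades gracefully toward
$L_F$ where data are absent; this happens for the tight-turn classes at
desk-scale sample counts, and a warning reports it.

Coefficients vary almost linearly with resolution, so per-resolution
calibrations are condensed into $k_j(r) = m_j r + b_j$
(`fit_coefficient_lines()`); the package ships such a line model over
$r \in [5.1, 7.8]$ nm/pixel as its default
(`default_coefficient_model()`), and `coefficients_at(r)` warns when
extrapolating outside that range. Calibration is done per resolution and
then condensed into lines -- rather than one pooled regression with $r$ as a
covariate -- because the per-$r$ solves are cheap, independent, and make the
linearity itself inspectable (`autoplot()` on the model).

```{r coefs}
coefficients_at(6.4)
```

## The synthetic calibration corpus

Real calibrated reference strands do not exist at this accuracy, so the
coefficients are calibrated against simulated skeletons of exactly known
length. The generator (`generate_wlc()`) draws discrete 2D worm-like
chains: unit steps of 1 nm whose heading performs a Gaussian random walk
with increment variance $\mathrm{step}/l_p$, giving the in-plane tangent
correlation $\langle\cos\Delta\theta(s)\rangle = e^{-s/(2 l_p)}$ of a chain
with persistence length $l_p$, and the 2D closed form
$\langle R^2\rangle = 4 l_p l_c\,[1 - (2 l_p/l_c)(1 - e^{-l_c/(2 l_p)})]$,
which the test suite checks by Monte Carlo. Defaults mirror
double-stranded DNA imaged by AFM: $l_p = 50$ nm, contour lengths 340--1020
nm in 34 nm steps, resolutions 5.1--7.8 nm/pixel in 0.1 steps.
Self-crossing realizations are rejected and redrawn, because a self-crossing
strand cannot be skeletonized into a simple path; this mildly favours open
configurations, a bias shared by any simple-path tracing protocol.

`rasterize_contour()` digitizes a chain at sub-pixel arc-length sampling
($r/10$): the backbone is the ordered sequence of pixels the curve passes
through, with staircase corner pixels (whose two neighbours are themselves
adjacent) shortcut away so the chain satisfies the strict single-width
property that the 64-segment taxonomy assumes. We digitize the curve
directly rather than thinning a painted band because iterative thinning
smooths away the very digitization staircase the estimator corrects:
under band-thinning the Freeman estimate loses its documented positive
bias (it can even turn negative at coarse resolutions), whereas direct
digitization reproduces it (about $+2.5\%$ at $r = 5.1$ nm/pixel for
$l_c = 340$ nm under this generator). Draws whose digitized chain touches
or revisits itself -- the curve approaching within about a pixel of itself
-- are rejected and redrawn.

What the generator deliberately does not emulate: AFM height fields, tip
convolution and image noise (the corpus is skeleton-level, as a calibration
needs known truth); surface adsorption effects that make deposited DNA
deviate from ideal 2D worm-like-chain statistics; molecules that overlap or
cross. Passing tests therefore validate the estimator and its calibration
machinery on ideal digitized curves; on real images the preprocessing
chain (thresholding, island filtering, thinning, debranching;
`binarize_and_clean()`, `thin_and_debranch()`) contributes its own errors
that no coefficient can remove.

## Numerical and design choices

* **Thinning (image module).** Two-subiteration thinning with deletions
  applied sequentially, each candidate re-validated against the current
  image. The textbook parallel schedule annihilates $2\times2$ blocks and
  2-pixel-wide diagonal staircases -- precisely what rasterized diagonal
  strokes look like -- whereas sequential deletion preserves connectivity
  unconditionally.
* **Debranching.** The backbone is the path between the farthest pair of
  degree-1 skeleton endpoints (breadth-first distances; ties broken by the
  lexicographically smallest endpoint), so side branches are pruned
  deterministically. Closed loops have no endpoints and are rejected
  rather than cut at an arbitrary position.
* **Threshold.** Otsu's histogram threshold (256 bins) when none is given.
* **Eight's complement of 0 is 0** ($(8-0)\bmod 8$), consistent with the
  canonicalization 602 to 206; $s_1 = 4$ never occurs among valid segments
  (asserted by brute force), so the strict rule "complement when $s_1>4$"
  is never ambiguous.
* **Invalid segments raise.** Code triples that cannot occur on a
  single-width path (for example from malformed input paths) raise a classed
  error rather than silently classifying; the taxonomy covers valid shapes
  only.
* **Degenerate calibration inputs.** Fewer than 12 samples warns
  (ill-posed); an exactly singular system errors listing the deficient
  columns; never-observed shapes are excluded with $k_j = 1$.
* **Determinism.** All randomness flows through R's RNG;
  `generate_dataset()` derives one substream seed per $(l_c, r)$ case from
  the master seed, so corpora are byte-reproducible.
* **Convergence reporting.** `convergence_curve()` re-solves on growing
  prefixes and reports the maximum relative coefficient drift between
  checkpoints. The headline drift covers the coefficients that are
  estimable at the earlier checkpoint -- relative standard error below
  `se_limit` (default 0.5%) -- because the checkpoint-to-checkpoint
  fluctuation of a rarely observed coefficient is its own sampling error,
  not convergence of the calibration: a 1% convergence statement is only
  assessable for coefficients estimated to better than 1%. All per-shape
  values are still reported.

## Problem sizes

The package's own benchmark (the test suite and `scripts/acceptance.R`)
calibrates and evaluates on 10,000 training plus 10,000 held-out samples
per $(l_c, r)$ cell over $l_c \in \{340, 680, 1020\}$ nm and
$r \in \{5.1, 6.4, 7.7\}$ nm/pixel, and tracks coefficient convergence on a
mixed-length 40,000-sample stream at $r = 6.4$ nm/pixel. These sizes give
the mean-estimate standard errors of a few hundredths of a percent needed
to resolve the shape estimator's accuracy; the full 588-case grid at
arbitrary corpus sizes is available through `generate_dataset()`.

## A worked example

```{r example}
set.seed(7)
samples <- simulate_skeletons(n = 400, l_c = 340, r = 5.1)
feats <- skeleton_features(samples)

fit <- solve_coefficients(assemble_system(feats, 340, 5.1))
tidy(fit)

set.seed(8)
held <- skeleton_features(simulate_skeletons(n = 400, l_c = 340, r = 5.1))
evaluate_estimators(held, 340, 5.1,
                    estimators = c("shape", "dna", "freeman"),
                    k = fit, cf = estimate_cf(feats, 340, 5.1))
```

## Known limitations

* The absolute Freeman bias of the corpus (and hence the calibrated
  coefficient values) depends on the digitization recipe; different
  rasterization conventions shift it by a percentage point or so. The
  *relative* ordering -- shape-corrected $<$ globally-corrected $<$
  uncorrected -- is robust to this choice.
* Head/tail connections are uncorrected by construction, leaving a residual
  per-sample offset of a fraction of a nanometre that is most visible for
  short strands at coarse resolution.
* One strand per image; closed (circular) molecules are rejected.
* The 4-pixel window is fixed; longer windows would resolve more geometry
  at a steep cost in classes (the 5-pixel taxonomy is out of scope).
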