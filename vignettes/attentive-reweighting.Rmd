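---
title: "Spatially adaptive iteratively reweighted L1 reconstruction: models, algorithms, and design choices"
author: "safir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially adaptive iteratively reweighted L1 reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safir)
```

## The model

We reconstruct an image $x \in \mathbb{R}^N$ from linear measurements
$y = Hx + n$, where $H$ is the forward operator (the identity for denoising,
a column-undersampled unitary Fourier transform for single-coil MRI) and $n$
is white Gaussian noise. The reconstruction is a variational estimate

$$\hat x \in \arg\min_{x \in X} \tfrac12\|Hx - y\|_2^2 + \lambda R(x),$$

with a filter-bank regularizer built from $N_C$ learned zero-mean
convolution filters $W_c$. A plain L1-analysis prior
$R(x) = \sum_c \|W_c x\|_1$ penalizes *all* filter responses equally — noise
and genuine image structure alike. The idea implemented here is to make the
penalty *spatially adaptive*: a per-channel, per-pixel mask
$\Lambda_c \in [0,\infty)^N$, computed from the previous reconstruction,
rescales the penalty locally,

$$R_k(x) = \sum_{c=1}^{N_C} \langle \Lambda_c(x_k),\, |W_c x| \rangle
        = \|L_k x\|_1, \qquad L_k = [\mathrm{diag}(\Lambda_c(x_k)) W_c]_c .$$

Each refinement step solves this *convex* re-weighted problem and then
regenerates the masks from the new iterate, so the regularizer becomes
progressively attentive to the image: the masks decay on edges and texture
(damping the penalty there) while staying high in flat, noise-dominated
regions.

Two mask generators are provided.

**MMR (majorization–minimization regularization).** The masks are

$$\Lambda_c(x) = B_c^\top\, \psi_c'\!\left(B_c |W_c x|\right),$$

with a nonnegative, row-normalized mixing operator $B_c$ (simplex-constrained
depthwise convolution kernels) and learned *concave* potentials $\psi_c$ with
$\psi_c'(0) = 1$ and $0 \le \psi_c' \le 1$ non-increasing. In this case the
refinement is exactly a majorization–minimization scheme for the explicit
non-convex energy

$$f(x) = \tfrac12\|Hx-y\|^2 +
  \lambda \sum_c \langle \mathbf 1, \psi_c(B_c |W_c x|)\rangle ,$$

because the first-order (concavity) bound
$\psi_c(u) \le \psi_c(u_k) + \langle \psi_c'(u_k), u - u_k\rangle$ turns
$f$ into the convex surrogate solved at each step, tight at the current
iterate. Consequently $f(x_k)$ is non-increasing along the iterations — the
package records it in the solve trace and the test suite checks the descent
property directly ([`objectiveMMR()`], [`majorizationValue()`]).

**SAFI (solution-adaptive fixed-point iterations).** The mask generator is a
small three-layer convolutional network
$\tilde\Lambda_c(x) = \phi_{3,c}(\hat B_c\, \phi_2(\tilde B\, \phi_1(\tilde W x)))$
with learnable linear-spline activations and a sigmoid-composed output
spline, so all mask entries lie in $(0,1)$. The refinement is then a
fixed-point iteration of the update operator $x \mapsto T(x)$ defined by the
convex subproblem; for invertible $H$ the operator maps into the ball of
radius $2\|y\|_2/\sigma_{\min}(H)$ (compare the value of the subproblem
objective at its minimizer with its value at $0$), which guarantees a fixed
point exists. Convergence of the iteration itself is not guaranteed in
general; empirically the outer relative error $e_k = \|x_{k+1}-x_k\|/\|x_k\|$
decays steadily, which the tests check on synthetic denoising instances.

## The nested solvers

Each refinement solves
$\min_{x\in X} \tfrac12\|Hx-y\|^2 + \lambda\|L_k x\|_1$ by accelerated
forward–backward splitting (FBS): a gradient step on the fidelity with step
$\alpha = 1/\|H\|_2^2$, followed by the proximal map of
$\alpha\lambda\|L_k\cdot\|_1$, with inertial extrapolation weights $t_1 = 1$,
$t_{k+1} = (k+5)/3$, factor $(t_k-1)/t_{k+1}$. For denoising ($H =
\mathrm{Id}$, $\alpha = 1$) a single FBS step is exact: the gradient step
lands on $y$ regardless of the start, and the prox returns the minimizer.

The prox itself has no closed form for an analysis operator, so it is
evaluated through its dual: with the constraint $\|u\|_\infty \le \gamma$,
accelerated projected gradient iterates

$$u_{k+1} = \mathrm{clip}_{[-\gamma,\gamma]}\!\left(v_k - \tfrac{1}{\|L\|_2^2}
  L\,\Pi_X(L^\top v_k - z)\right),$$

with the same inertial rule, and the primal is recovered as
$x = \Pi_X(z - L^\top u)$. $\Pi_X$ is the identity (default, $X =
\mathbb{R}^N$) or a componentwise box clamp.

Numerical choices worth knowing:

* **Step sizes.** $\|H\|_2^2$ is exact for the built-in models (identity and
  masked Fourier are partial isometries; dense models use an SVD). $\|L\|_2^2$
  is estimated by power iteration (100 iterations, relative tolerance
  $10^{-6}$, fixed probe seed) and multiplied by a 1.01 safety factor when
  forming the step, so the step never exceeds the admissible $1/\|L\|_2^2$.
* **Tolerance schedules.** Inner solvers stop on the relative change of their
  primal iterate, with iteration-dependent tolerances: for denoising
  $\epsilon_{\mathrm{prox}} = 10^{-3}\cdot 0.01^{k_{\mathrm{out}}/5}$ for
  $k_{\mathrm{out}} \le 5$ and $10^{-5}$ beyond; for general $H$ the FBS
  tolerance follows the same form and the prox tolerance is
  $3\epsilon_{\mathrm{FBS}} (1/9)^{k_{\mathrm{FBS}}/50}$ up to
  $k_{\mathrm{FBS}} = 50$ and $\epsilon_{\mathrm{FBS}}/3$ beyond (both
  schedules are continuous at their breakpoints). Early refinements are
  solved loosely, late ones nearly exactly. The caps are
  $K_{\mathrm{out}} = 10$, $K_{\mathrm{prox}} = 500$, and $K_{\mathrm{FBS}}
  = 1$ (denoising) or $1000$ (otherwise). The sentinel mode `"off"` ($-1$)
  disables early stopping; training uses it so the unrolled graph has a fixed
  shape.
* **Warm starts.** Each FBS solve starts from the previous refinement's
  minimizer. Inside one FBS solve, consecutive prox evaluations warm-start
  the *dual* variable at the previous step's dual (a standalone
  [`proxWeightedL1()`] call starts at $u_1 = Lz$). Since each subproblem is
  convex this does not change what the prox converges to, but it removes the
  large constant cost of cold dual restarts on the MRI path, where thousands
  of prox calls occur. The dual is *not* carried across outer refinements:
  with a change-based stopping rule, a dual started at the previous
  refinement's optimum stalls before adapting to the new masks. For the same
  reason the prox requires its relative-change test to hold on two
  consecutive iterations before stopping — a single small step can be a
  momentum stall far from the optimum. Oracle-comparison tests disable early
  stopping entirely.
* **Relative-error guard.** $e_k$ is defined as $\|x_{k+1}\|$ when
  $\|x_k\| = 0$ (the zero initialization).
* **Initialization.** Refinements start at $x_1 = 0$ with the *unweighted*
  operator $L_1 = [W_c]_c$, so the first step solves the plain L1-analysis
  problem. Alternative starts (`init = "random"` or an explicit image)
  generate the first masks from the start image instead; the tests check
  that zero and random starts reach the same reconstruction on an MRI
  instance.

## Parameterizations

All linear operators are stacks of grouped "same" convolutions
(`convOperator`): group count $G = 1$ mixes all channels, $G = N_C$ is
depthwise. Constraints are enforced by projection: analysis kernels have
zero mean ($w \mapsto w - \bar w$), MMR mixing kernels are nonnegative with
unit sum ($b \mapsto |b|/\mathbf 1^\top|b|$).

The scalar nonlinearities are degree-one splines on uniform grids
(`linearSpline`, `halfLineSpline`), with linear extrapolation using the
boundary-segment slope. The MMR profile derivatives are
$\psi_c'(t) = \mathrm{clip}_{[0,1]}(\sigma_c(r_c t))$ with a non-increasing
half-line spline $\sigma_c$, $\sigma_c(0) = 1$, enforced by the cumulative
projection $P_\downarrow(d) = S\,\mathrm{clip}_{(-\infty,0]}(Dd) + \mathbf 1$
(differences clipped to be non-positive, then re-accumulated from 1), and a
positive scale $r_c$ (its magnitude is used). The antiderivative $\psi_c$
(needed only for objective evaluation) is integrated exactly from the
clipped piecewise-linear derivative — a breakpoint table with the clip
crossings added makes $\psi_c$ piecewise quadratic, nonnegative,
non-decreasing and concave, with the convention $\psi_c(0) = 0$ (the
objective is defined up to this constant; monotonicity is unaffected).
Spline grids default to $M = 20$, $\Delta = 0.05$ for MMR profiles and
$M = 10$, $\Delta = 0.1$ for SAFI activations. Evaluation exactly at a knot
returns the knot value; the interpolation formula is continuous, so no
tie-break is needed.

The SAFI output activation applies the logistic function after the spline —
mathematically the masks are strictly inside $(0,1)$, though in double
precision the logistic saturates to exactly 0/1 for arguments beyond about
$\pm 37$, which only occurs for inputs far outside the intensity range.

## Training

The denoiser $D^{n_1,1,n_3}_\theta(y)$ is the scheme run for $n_1$ outer
refinements, one FBS step and $n_3$ dual iterations each, with tolerances
disabled — a fixed, deterministic, differentiable computation. Training
minimizes $\tfrac12\sum_m \|D(y_m) - x_m\|^2$ over batches with Adam
(learning rate $10^{-3}$, dropped by $0.1$ at epochs 5 and 10, batch size
128), drawing $(n_1, n_3)$ uniformly from $\{4,5,6\}\times\{1,\dots,10\}$
per batch; the random depth regularizes the unrolling. $\lambda$ starts at
$10^{-4}$ and is learned jointly. After each epoch the model is scored by
PSNR (the deepest unrolled configuration) on held-out validation patches,
and the best epoch is returned.

Design choices specific to this implementation:

* **Gradients.** No automatic-differentiation framework is assumed; the
  package ships a small reverse-mode tape (`R/autodiff.R`) covering exactly
  the unrolled graph's operations (grouped convolutions and adjoints,
  elementwise arithmetic, clips — including the symmetric clip whose bound
  $\gamma = \alpha|\lambda|$ is itself differentiated — splines with knot
  gradients, sigmoids, channel slicing, and scalar reductions). Gradients are
  exact up to the usual subgradient conventions at kinks (pass-through on the
  closed clip interval, $\mathrm{sign}$ for $|\cdot|$), and are verified
  against central finite differences in the tests.
* **Dual step size in the unrolled graph.** The evaluation-phase solvers
  re-estimate $\|L_k\|_2^2$ by power iteration at every refinement. Inside
  the training graph this would be wasteful and would put a long iterative
  tail into every mask update, so the unrolled path instead uses the
  differentiable upper bound $\|L\|_2^2 \le \max(\Lambda)^2\,\|W\|_2^2$,
  with $\|W\|_2^2$ obtained once per pass from a fixed-depth differentiable
  power iteration. A smaller admissible step changes only the finite-depth
  trajectory, which is part of what is being trained.
* **Constraints by projection.** The zero-mean, simplex and monotone
  constraints are re-applied by projection after every optimizer step (and on
  checkpoint load), rather than through in-graph reparameterization. Both
  approaches land in the same feasible set; projection keeps the training
  graph smaller and makes the feasibility invariants directly testable after
  any number of steps. Scale and strength parameters use their magnitudes
  ($|r_c|$, $|\lambda|$) in the forward pass.
* **Fine-tuning $\lambda$.** A denoising-trained model is adapted to a new
  task (or to full-convergence evaluation, which is not what the finite
  unrolling was trained for) by re-selecting only $\lambda$ on a small
  validation set: the mean PSNR of the full fixed-point reconstruction is
  evaluated on a coarse grid, then once more on a 5-point geometric grid
  between the neighbors of the coarse argmax ([`tuneLambda()`]).

## Synthetic data

Everything runs without downloads. `makePatches()` emulates natural-image
statistics with a random piecewise-constant ellipse field (sparse gradients,
sharp edges) plus $1/f$-filtered texture, clipped to $[0,1]$ — its gradient
distribution is heavy-tailed (positive excess kurtosis), which is the
property the learned sparsity prior exploits. `makePhantom()` provides the
standard ten-ellipse head phantom, random ellipse scenes, and piecewise
polynomial tiles. `makeKspaceMask()` keeps $\lfloor W/M_{\mathrm{acc}}
\rfloor$ k-space columns — a contiguous centered low-frequency block of
about `centerFraction` of the width plus uniformly drawn remaining columns
(the randomization and center-retention rule are package choices; only the
proportionality to $1/M_{\mathrm{acc}}$ is fixed). Measurement noise is
i.i.d. Gaussian with standard deviation $2\cdot10^{-3}$ per real and
imaginary component of the sampled entries.

These generators emulate the *structure* that the schemes rely on (edges,
flat regions, textured regions, undersampling artifacts); they do not
emulate photographic texture statistics, anatomy, or coil sensitivities.
Passing tests therefore demonstrate the correctness and the qualitative
behavior of the method, not benchmark performance on natural-image or
clinical data.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen so that everything
runs comfortably on one CPU core: denoising studies on $64\times 64$
phantoms with the reduced model geometry ($N_C = 8$, one $5\times 5$ layer);
the MRI initialization study on a $32\times 32$ phantom at
$M_{\mathrm{acc}} = 4$ with the FBS cap reduced to 300 (the fixed point is
insensitive to the cap once the schedule's late-stage tolerances are
active); constraint-preservation checks over 200 optimizer steps at batch
size 32 (feasibility after projection does not depend on the batch size);
and the training-efficacy study at the reduced training protocol (2000
patches of $16\times 16$, two epochs, batch 128, $\sigma = 25/255$) with
evaluation on $32\times 32$ held-out images. The full-scale protocol
($N_C = 64$, two $7\times 7$ layers, $40\times 40$ patches, 40 epochs)
remains available through the same configuration objects.

## Known limitations

* Convergence of the SAFI iteration is only encouraged (by the randomized
  unrolling depth during training), not guaranteed; the package reports the
  outer residual trace so stalls are visible.
* The masked-Fourier model covers the single-coil setting only; multi-coil
  reconstruction with sensitivity maps and non-Cartesian sampling are out of
  scope.
* The dual prox's relative-change stopping rule is a surrogate for true
  optimality; the two-consecutive-hits requirement makes it robust in the
  refinement loop, but oracle-grade accuracy still requires disabling early
  stopping.
* Training at the full protocol is computationally heavy in this
  implementation (a CPU tape, not a GPU framework); the reduced protocol is
  the supported regime.
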