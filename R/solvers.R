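# The nested solvers: accelerated FBS on the outer data-fidelity +
# weighted-L1 problem, the dual evaluation of the weighted-L1 prox, the
# refinement loops of the MMR and SAFI schemes, the exact objective and its
# majorization, and the iteration-dependent tolerance schedules.

#' Solver configuration constructor
#'
#' @param lam regularization strength lambda.
#' @param Kout outer refinement cap (default 10).
#' @param Kfbs inner FBS cap; `NA` resolves to 1 for an identity forward model
#'   and 1000 otherwise.
#' @param Kprox dual prox iteration cap (default 500).
#' @param epsOut outer relative-change tolerance (default 1e-6; the refinement
#'   is iterated until convergence under the `Kout` cap).
#' @param schedule tolerance schedule mode; `"auto"` resolves to
#'   `"denoising"` for an identity model and `"general"` otherwise. `"off"`
#'   is the training sentinel (-1): never stop early.
#' @param X constraint set descriptor: `list(kind = "all_space")` (default) or
#'   `list(kind = "box", lo =, hi =)`.
#' @return a [SolverConfig].
#' @export
solverConfig <- function(lam, Kout = 10L, Kfbs = NA_integer_, Kprox = 500L,
                         epsOut = 1e-6,
                         schedule = c("auto", "denoising", "general", "off"),
                         X = list(kind = "all_space")) {
  schedule <- match.arg(schedule)
  new("SolverConfig", lam = as.numeric(lam), Kout = as.integer(Kout),
      Kfbs = if (is.na(Kfbs)) 1L else as.integer(Kfbs),
      Kprox = as.integer(Kprox), epsOut = as.numeric(epsOut),
      schedule = schedule, X = X)
}

# resolve "auto"/NA against the forward model
.resolveConfig <- function(config, H) {
  ident <- is(H, "IdentityModel")
  if (config@schedule == "auto")
    config@schedule <- if (ident) "denoising" else "general"
  # an unset Kfbs was stored as 1; only bump it for non-identity models
  if (config@Kfbs == 1L && !ident && config@schedule == "general")
    config@Kfbs <- 1000L
  config
}

#' Iteration-dependent inner tolerances
#'
#' Closed-form tolerance schedules for the nested solvers. In `"denoising"`
#' mode (identity forward model, one FBS step per refinement) the prox
#' tolerance is `1e-3 * 0.01^(k_out/5)` for `k_out <= 5` and `1e-5` beyond.
#' In `"general"` mode the FBS tolerance follows the same closed form and the
#' prox tolerance is `3 * eps_FBS * (1/9)^(k_FBS/50)` for `k_FBS <= 50` and
#' `eps_FBS / 3` beyond (the two branches meet at the breakpoints). Mode
#' `"off"` returns the sentinel -1, meaning "never stop early".
#'
#' @param mode `"denoising"`, `"general"`, or `"off"`.
#' @param kOut current outer iteration (>= 1).
#' @param kFbs current inner FBS iteration.
#' @param which return the prox tolerance (default) or the FBS tolerance.
#' @return a positive tolerance, or -1 in mode `"off"`.
#' @export
evalTolerance <- function(mode = c("denoising", "general", "off"), kOut,
                          kFbs = 1L, which = c("prox", "fbs")) {
  mode <- match.arg(mode)
  which <- match.arg(which)
  if (kOut < 1) stop("kOut must be >= 1")
  if (mode == "off") return(-1)
  base <- if (kOut <= 5) 1e-3 * 0.01^(kOut / 5) else 1e-5
  if (mode == "denoising" || which == "fbs") return(base)
  if (kFbs <= 50) 3 * base * (1 / 9)^(kFbs / 50) else base / 3
}

.projX <- function(X, v) {
  switch(X$kind,
    all_space = v,
    box = pmin(pmax(v, X$lo), X$hi),
    stop("unknown constraint set kind: ", X$kind))
}

.relErr <- function(xNew, x) {
  nx <- sqrt(sum(x^2))
  d <- sqrt(sum((xNew - x)^2))
  if (nx > 0) d / nx else d
}

#' Proximal operator of the weighted L1-analysis penalty
#'
#' Evaluates `prox_{gamma ||L .||_1}(z)` restricted to the constraint set X by
#' accelerated projected gradient on the dual problem: with step
#' `alpha = 1 / ||L||_2^2`, starting from `u_1 = v_1 = L z`, iterate
#' `u_{k+1} = clip_[-gamma, gamma](v_k - alpha L Proj_X(L^T v_k - z))` with
#' inertial weights `t_1 = 1`, `t_{k+1} = (k+5)/3`, and recover the primal as
#' `x = Proj_X(z - L^T u)`. Stops when the relative primal change drops below
#' `epsProx` (never, if `epsProx` is the sentinel -1) or at `Kprox` iterations.
#'
#' @param L an [AnalysisOperator] (or [ConvOperator] wrapped via
#'   [onesAnalysis()]).
#' @param z image-domain matrix (the prox argument).
#' @param gamma nonnegative prox weight (`alpha * lambda` in the outer solver).
#' @param X constraint set descriptor.
#' @param epsProx relative-change tolerance (-1 disables early stopping).
#' @param Kprox iteration cap.
#' @param uWarm optional dual warm start (defaults to `L z`); the outer FBS
#'   solver passes the previous step's dual, which leaves the converged
#'   solution unchanged (the problem is convex) but saves most dual
#'   iterations when consecutive prox arguments are close.
#' @return list with the primal `x`, the dual `u`, and `iters` used.
#' @export
proxWeightedL1 <- function(L, z, gamma, X = list(kind = "all_space"),
                           epsProx = 1e-6, Kprox = 500L, uWarm = NULL) {
  if (gamma < 0) stop("gamma must be nonnegative")
  if (gamma == 0 || sqSpectralNorm(L) == 0) {
    x <- .projX(X, z)
    return(list(x = x, u = 0 * applyOp(L, z), iters = 0L))
  }
  alpha <- 1 / (1.01 * sqSpectralNorm(L))
  u <- v <- if (is.null(uWarm)) applyOp(L, z) else
    clipInterval(uWarm, -gamma, gamma)
  x <- .projX(X, z - applyOp(L, u, adjoint = TRUE))
  t <- 1
  iters <- 0L
  hits <- 0L
  for (k in seq_len(Kprox)) {
    g <- applyOp(L, .projX(X, applyOp(L, v, adjoint = TRUE) - z))
    uNew <- clipInterval(v - alpha * g, -gamma, gamma)
    tNew <- (k + 5) / 3
    v <- uNew + (t - 1) / tNew * (uNew - u)
    xNew <- .projX(X, z - applyOp(L, uNew, adjoint = TRUE))
    if (!all(is.finite(xNew))) stop("non-finite iterates in dual prox")
    e <- .relErr(xNew, x)
    u <- uNew; x <- xNew; t <- tNew; iters <- k
    # the change-based test must hold on two consecutive iterations: a
    # single small step can be a momentum stall far from the optimum
    hits <- if (epsProx > 0 && e < epsProx) hits + 1L else 0L
    if (hits >= 2L) break
  }
  list(x = x, u = u, iters = iters)
}

#' Accelerated forward-backward splitting for one refinement step
#'
#' Solves `argmin_{x in X} 0.5 ||H x - y||^2 + lambda ||L x||_1` by FBS with
#' step `alpha = 1 / ||H||_2^2`: a gradient step on the fidelity followed by
#' the dual-evaluated weighted-L1 prox, with inertial extrapolation
#' (`t_1 = 1`, `t_{k+1} = (k+5)/3`). The iteration is warm-started at `xInit`
#' (the previous refinement's minimizer) and stops when the relative change
#' drops below the scheduled FBS tolerance or at the `Kfbs` cap. For an
#' identity forward model a single step from any start already returns the
#' exact minimizer `prox_{alpha lambda ||L .||_1}(y)`.
#'
#' @param H a [ForwardModel].
#' @param y measurements (same domain as `applyOp(H, x)`).
#' @param L an [AnalysisOperator].
#' @param lam regularization strength.
#' @param xInit starting image.
#' @param config a [SolverConfig] (must carry a resolved schedule).
#' @param kOut current outer iteration (drives the tolerance schedule).
#' @param uInit optional dual warm start carried over from the previous
#'   refinement's solve (see [proxWeightedL1()]).
#' @return list with the solution `x`, the final dual `u`, FBS iterations
#'   `iters`, and the total dual iterations `proxIters`.
#' @export
fbsSolve <- function(H, y, L, lam, xInit, config, kOut = 1L, uInit = NULL) {
  config <- .resolveConfig(config, H)
  alpha <- 1 / sqSpectralNorm(H)
  gamma <- alpha * lam
  x <- xt <- xInit
  t <- 1
  iters <- 0L
  proxIters <- 0L
  uPrev <- uInit  # dual warm start across FBS iterations (and refinements)
  epsFbs <- evalTolerance(config@schedule, kOut, which = "fbs")
  for (k in seq_len(config@Kfbs)) {
    r <- applyOp(H, xt) - y
    g <- applyOp(H, r, adjoint = TRUE)
    z <- xt - alpha * g
    epsProx <- evalTolerance(config@schedule, kOut, k, which = "prox")
    pr <- proxWeightedL1(L, z, gamma, config@X, epsProx, config@Kprox,
                         uWarm = uPrev)
    xNew <- pr$x
    uPrev <- pr$u
    proxIters <- proxIters + pr$iters
    if (!all(is.finite(xNew))) stop("non-finite iterates in FBS")
    tNew <- (k + 5) / 3
    xt <- xNew + (t - 1) / tNew * (xNew - x)
    e <- .relErr(xNew, x)
    x <- xNew; t <- tNew; iters <- k
    if (epsFbs > 0 && e < epsFbs) break
  }
  list(x = x, u = uPrev, iters = iters, proxIters = proxIters)
}

## ---- objective and majorization -------------------------------------------

.fidelity <- function(H, x, y) {
  r <- applyOp(H, x) - y
  0.5 * sum(Mod(r)^2)
}

#' Exact MMR objective
#'
#' Evaluates `f(x) = 0.5 ||H x - y||^2 + lambda sum_c <1, psi_c(B_c |W_c x|)>`
#' with the exact piecewise-quadratic potentials psi (convention psi(0) = 0).
#'
#' @param x image matrix.
#' @param H a [ForwardModel].
#' @param y measurements.
#' @param lam regularization strength.
#' @param g an [MMRMaskGenerator].
#' @return the objective value (finite for finite inputs).
#' @export
objectiveMMR <- function(x, H, y, lam, g) {
  wx <- applyOp(g@W, x)
  ba <- .convStack(g@B, abs(wx))
  reg <- 0
  for (c in seq_len(dim(ba)[3]))
    reg <- reg + sum(evalPsi(g@profiles[[c]], ba[, , c]))
  .fidelity(H, x, y) + lam * reg
}

#' Majorization of the MMR objective at an anchor point
#'
#' The surrogate
#' `g(x, x_k) = 0.5||Hx - y||^2 + lambda sum_c <1, psi_c(B_c |W_c x_k|)>
#'  + lambda sum_c <Lambda_c(x_k), |W_c x| - |W_c x_k|>`
#' obtained from the first-order concavity bound on the potentials. It is an
#' upper bound on the objective, tight at `x = x_k`; each refinement step
#' minimizes it over x.
#'
#' @param x evaluation point.
#' @param xk anchor point of the majorization.
#' @inheritParams objectiveMMR
#' @return the surrogate value.
#' @export
majorizationValue <- function(x, xk, H, y, lam, g) {
  wxk <- applyOp(g@W, xk)
  bak <- .convStack(g@B, abs(wxk))
  lamMask <- maskValues(generateMask(g, xk))
  wx <- applyOp(g@W, x)
  reg <- 0
  for (c in seq_len(dim(bak)[3]))
    reg <- reg + sum(evalPsi(g@profiles[[c]], bak[, , c]))
  reg <- reg + sum(lamMask * (abs(wx) - abs(wxk)))
  .fidelity(H, x, y) + lam * reg
}

## ---- refinement loops ------------------------------------------------------

.initImage <- function(H, init, seed) {
  shape <- H@shape
  if (is.matrix(init)) return(init)
  switch(init,
    zero = matrix(0, shape[1], shape[2]),
    random = { set.seed(seed); matrix(rnorm(prod(shape)), shape[1], shape[2]) },
    stop("unknown init: ", init))
}

# Shared refinement loop for both schemes (Algorithms differ only in the mask
# generator). Starts from the unweighted analysis operator for the zero init,
# or from the mask of the supplied/random initialization otherwise.
.refineLoop <- function(H, y, gen, config, init, seed, keepMasks,
                        keepIterates, objective) {
  config <- .resolveConfig(config, H)
  if (config@lam < 0) stop("lambda must be nonnegative")
  shape <- H@shape
  x <- .initImage(H, init, seed)
  zeroInit <- is.character(init) && identical(init, "zero")
  if (zeroInit) {
    L <- onesAnalysis(gen@W, shape)
  } else {
    L <- buildWeightedAnalysis(generateMask(gen, x), gen@W, shape)
  }
  e <- f <- numeric(0)
  fbsIters <- proxIters <- integer(0)
  masks <- list()
  iterates <- if (keepIterates) list(x) else list()
  f <- objective(x, L)
  for (k in seq_len(config@Kout)) {
    # no dual carry-over across refinements: with the change-based stopping
    # rule a dual started at the previous refinement's optimum stalls before
    # adapting to the new masks
    fb <- fbsSolve(H, y, L, config@lam, x, config, kOut = k)
    xNew <- fb$x
    mask <- generateMask(gen, xNew)
    L <- buildWeightedAnalysis(mask, gen@W, shape)
    e <- c(e, .relErr(xNew, x))
    f <- c(f, objective(xNew, L))
    fbsIters <- c(fbsIters, fb$iters)
    proxIters <- c(proxIters, fb$proxIters)
    if (keepMasks) masks <- c(masks, list(mask))
    if (keepIterates) iterates <- c(iterates, list(xNew))
    x <- xNew
    if (e[k] < config@epsOut) break
  }
  trace <- new("SolveTrace", e = e, f = f,
               iterations = list(fbs = fbsIters, prox = proxIters),
               masks = masks)
  list(x = x, trace = trace, iterates = iterates, L = L)
}

#' MMR reconstruction (iterative majorization-minimization refinement)
#'
#' Runs the outer refinement loop: starting from `x_1 = 0` and the unweighted
#' analysis operator, each step solves the convex re-weighted L1-analysis
#' problem with [fbsSolve()] (warm-started at the previous minimizer) and then
#' regenerates the masks from the new iterate. The recorded objective values
#' (the exact energy [objectiveMMR()]) are non-increasing up to the inner
#' solver tolerance.
#'
#' @param H a [ForwardModel].
#' @param y measurements.
#' @param g an [MMRMaskGenerator].
#' @param config a [SolverConfig].
#' @param init `"zero"` (default), `"random"`, or an explicit start image; for
#'   a non-zero init the first masks are generated from the start image.
#' @param seed seed for the random initialization.
#' @param keepMasks record mask snapshots in the trace.
#' @param keepIterates also return the full iterate sequence.
#' @return list with the reconstruction `x`, a [SolveTrace] (`trace`), and
#'   (optionally) `iterates`.
#' @export
mmrReconstruct <- function(H, y, g, config, init = "zero", seed = 1L,
                           keepMasks = FALSE, keepIterates = FALSE) {
  obj <- function(x, L) objectiveMMR(x, H, y, config@lam, g)
  out <- .refineLoop(H, y, g, config, init, seed, keepMasks, keepIterates,
                     obj)
  out[c("x", "trace", "iterates")]
}

#' SAFI reconstruction (solution-adaptive fixed-point iterations)
#'
#' Same refinement loop as [mmrReconstruct()] with the network mask generator:
#' each update is the minimizer of a convex weighted L1-analysis problem whose
#' weights come from the previous iterate. For an invertible forward model the
#' update operator maps into the ball of radius `2 ||y|| / sigma_min`, and the
#' iterations seek one of its fixed points. The recorded objective values are
#' those of the successive convex subproblems.
#'
#' @inheritParams mmrReconstruct
#' @param g a [SAFIMaskGenerator].
#' @return list with the reconstruction `x`, a [SolveTrace], and (optionally)
#'   `iterates`.
#' @export
safiReconstruct <- function(H, y, g, config, init = "zero", seed = 1L,
                            keepMasks = FALSE, keepIterates = FALSE) {
  obj <- function(x, L) {
    .fidelity(H, x, y) + config@lam * sum(abs(applyOp(L, x)))
  }
  out <- .refineLoop(H, y, g, config, init, seed, keepMasks, keepIterates,
                     obj)
  out[c("x", "trace", "iterates")]
}

setMethod("show", "SolveTrace", function(object) {
  k <- length(object@e)
  cat(sprintf("SolveTrace: %d outer iteration(s)\n", k))
  if (k > 0) {
    cat(sprintf("  final e_k = %.3g, objective %.6g -> %.6g\n",
                object@e[k], object@f[1], object@f[length(object@f)]))
  }
})
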