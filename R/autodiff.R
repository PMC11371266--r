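# A small reverse-mode tape covering exactly the operations that appear in
# the unrolled reconstruction graph: grouped convolutions and their adjoints,
# elementwise arithmetic, absolute value, clipping (including the symmetric
# clip whose bound is itself a differentiated scalar), linear-spline and
# sigmoid activations, channel slicing, and the scalar reductions needed for
# the differentiable step-size bound and the training loss.
#
# Tensor values are stored as 3-d arrays (H, W, C*B) with slice index
# c + C*b, matching the compiled convolution layout; scalars are length-1
# numerics. Gradients of clip/abs use the standard subgradient conventions
# (pass-through on the closed interval, sign at the kink's closure).

.tpNew <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", 256L)
  tp$ops <- vector("list", 256L)
  tp$req <- logical(256L)
  tp$n <- 0L
  tp
}

.tpNode <- function(tp, op, value, parents = integer(0), ctx = NULL) {
  # force all promises first: a nested op call passed as an argument mutates
  # the tape, so tp$n / tp$vals must only be read afterwards
  force(value); parents <- as.integer(parents); force(ctx)
  n <- tp$n + 1L
  if (n > length(tp$vals)) {  # grow geometrically
    length(tp$vals) <- 2L * length(tp$vals)
    length(tp$ops) <- length(tp$vals)
    length(tp$req) <- length(tp$vals)
  }
  # gradient bookkeeping is only needed on the parameter-reachable subgraph
  req <- op == "param" || (length(parents) > 0L && any(tp$req[parents]))
  tp$vals[[n]] <- value
  tp$ops[[n]] <- list(op = op, parents = parents, ctx = ctx)
  tp$req[n] <- req
  tp$n <- n
  n
}

.tpVal <- function(tp, id) {
  force(id)  # see .tpNode: evaluate before fetching the list
  tp$vals[[id]]
}
.tpConst <- function(tp, v) .tpNode(tp, "const", v)
.tpParam <- function(tp, v) .tpNode(tp, "param", v)

# collapse a gradient onto a (possibly scalar) parent shape
.tpCollapse <- function(g, target) {
  if (length(target) == 1L && length(g) > 1L) sum(g) else g
}

.tpAdd <- function(tp, a, b)
  .tpNode(tp, "add", .tpVal(tp, a) + .tpVal(tp, b), c(a, b))
.tpSub <- function(tp, a, b)
  .tpNode(tp, "sub", .tpVal(tp, a) - .tpVal(tp, b), c(a, b))
.tpMul <- function(tp, a, b)
  .tpNode(tp, "mul", .tpVal(tp, a) * .tpVal(tp, b), c(a, b))
.tpScale <- function(tp, a, s)
  .tpNode(tp, "scale", .tpVal(tp, a) * s, a, ctx = list(s = s))
.tpAbs <- function(tp, a)
  .tpNode(tp, "abs", abs(.tpVal(tp, a)), a)
.tpSigmoid <- function(tp, a)
  .tpNode(tp, "sigmoid", plogis(.tpVal(tp, a)), a)
.tpClip <- function(tp, a, lo, hi)
  .tpNode(tp, "clip", clipInterval(.tpVal(tp, a), lo, hi), a,
          ctx = list(lo = lo, hi = hi))
.tpClipSym <- function(tp, a, gammaId) {
  gv <- as.numeric(.tpVal(tp, gammaId))
  .tpNode(tp, "clipsym", clipInterval(.tpVal(tp, a), -gv, gv),
          c(a, gammaId))
}
.tpSqnorm <- function(tp, a)
  .tpNode(tp, "sqnorm", sum(.tpVal(tp, a)^2), a)
.tpMax <- function(tp, a)
  .tpNode(tp, "max", max(.tpVal(tp, a)), a)
.tpInv <- function(tp, a)
  .tpNode(tp, "inv", 1 / as.numeric(.tpVal(tp, a)), a)
.tpSqrt <- function(tp, a)
  .tpNode(tp, "sqrt", sqrt(as.numeric(.tpVal(tp, a))), a)

# piecewise-linear spline with knot values as a differentiated parameter
.tpSpline <- function(tp, x, dId, t0, delta) {
  xv <- .tpVal(tp, x)
  d <- .tpVal(tp, dId)
  K <- length(d)
  i <- pmin(pmax(floor((xv - t0) / delta), 0), K - 2L)
  u <- (xv - t0) / delta - i
  v <- d[i + 1L] * (1 - u) + d[i + 2L] * u
  dim(v) <- dim(xv)
  .tpNode(tp, "spline", v, c(x, dId),
          ctx = list(i = i, u = u, delta = delta, K = K))
}

# grouped stacked convolution; meta = list(ks, Cin, Cout, G, B, pad)
.tpConv <- function(tp, x, kId, meta, adjoint = FALSE) {
  v <- cpp_conv2d(.tpVal(tp, x), .tpVal(tp, kId), meta$ks, meta$Cin,
                  meta$Cout, meta$G, meta$B, meta$pad, adjoint)
  .tpNode(tp, "conv", v, c(x, kId), ctx = c(meta, list(adjoint = adjoint)))
}

# extract channel c from a batched (H, W, C*B) tensor -> (H, W, B)
.tpSliceCh <- function(tp, x, ch, C, B) {
  v <- .tpVal(tp, x)
  idx <- ch + C * (0:(B - 1L))
  .tpNode(tp, "slicech", v[, , idx, drop = FALSE], x,
          ctx = list(idx = idx, C = C, B = B))
}

# recombine per-channel (H, W, B) tensors into (H, W, C*B)
.tpCatCh <- function(tp, ids, C, B) {
  vs <- lapply(ids, .tpVal, tp = tp)
  h <- dim(vs[[1]])[1]; w <- dim(vs[[1]])[2]
  out <- array(0, dim = c(h, w, C * B))
  for (ch in seq_len(C)) out[, , ch + C * (0:(B - 1L))] <- vs[[ch]]
  .tpNode(tp, "catch", out, ids, ctx = list(C = C, B = B))
}

.tpBackward <- function(tp, lossId) {
  grads <- vector("list", tp$n)
  grads[[lossId]] <- 1
  req <- tp$req
  acc <- function(id, g) {
    if (!req[id]) return(invisible(NULL))  # no parameter below: skip
    grads[[id]] <<- if (is.null(grads[[id]])) g else grads[[id]] + g
  }
  keep <- logical(tp$n)  # parameter grads must survive the sweep
  for (id in rev(seq_len(lossId))) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tp$ops[[id]]
    p <- nd$parents
    switch(nd$op,
      const = , param = NULL,
      add = {
        if (req[p[1]]) acc(p[1], .tpCollapse(g, .tpVal(tp, p[1])))
        if (req[p[2]]) acc(p[2], .tpCollapse(g, .tpVal(tp, p[2])))
      },
      sub = {
        if (req[p[1]]) acc(p[1], .tpCollapse(g, .tpVal(tp, p[1])))
        if (req[p[2]]) acc(p[2], .tpCollapse(-g, .tpVal(tp, p[2])))
      },
      mul = {
        if (req[p[1]])
          acc(p[1], .tpCollapse(g * .tpVal(tp, p[2]), .tpVal(tp, p[1])))
        if (req[p[2]])
          acc(p[2], .tpCollapse(g * .tpVal(tp, p[1]), .tpVal(tp, p[2])))
      },
      scale = acc(p[1], g * nd$ctx$s),
      abs = acc(p[1], g * sign(.tpVal(tp, p[1]))),
      sigmoid = {
        s <- .tpVal(tp, id)
        acc(p[1], g * s * (1 - s))
      },
      clip = {
        v <- .tpVal(tp, p[1])
        acc(p[1], g * (v >= nd$ctx$lo & v <= nd$ctx$hi))
      },
      clipsym = {
        v <- .tpVal(tp, p[1])
        gv <- as.numeric(.tpVal(tp, p[2]))
        if (req[p[1]]) acc(p[1], g * (abs(v) <= gv))
        if (req[p[2]]) acc(p[2], sum(g * sign(v) * (abs(v) > gv)))
      },
      sqnorm = acc(p[1], 2 * g * .tpVal(tp, p[1])),
      max = {
        v <- .tpVal(tp, p[1])
        gi <- array(0, dim = dim(v) %||% length(v))
        gi[which.max(v)] <- g
        acc(p[1], gi)
      },
      inv = acc(p[1], -g / as.numeric(.tpVal(tp, p[1]))^2),
      sqrt = acc(p[1], g / (2 * .tpVal(tp, id))),
      spline = {
        ctx <- nd$ctx
        d <- .tpVal(tp, p[2])
        if (req[p[1]]) {
          slopes <- (d[ctx$i + 2L] - d[ctx$i + 1L]) / ctx$delta
          gx <- g * slopes
          dim(gx) <- dim(.tpVal(tp, p[1]))
          acc(p[1], gx)
        }
        if (req[p[2]]) {
          gd <- numeric(ctx$K)
          w <- c(as.numeric(g) * (1 - ctx$u), as.numeric(g) * ctx$u)
          ii <- c(ctx$i + 1L, ctx$i + 2L)
          agg <- rowsum(w, ii)
          gd[as.integer(rownames(agg))] <- agg
          acc(p[2], gd)
        }
      },
      conv = {
        ctx <- nd$ctx
        if (req[p[1]]) {
          gx <- cpp_conv2d(g, .tpVal(tp, p[2]), ctx$ks, ctx$Cin, ctx$Cout,
                           ctx$G, ctx$B, ctx$pad, !ctx$adjoint)
          acc(p[1], gx)
        }
        if (req[p[2]]) {
          gk <- cpp_conv2d_kgrad(.tpVal(tp, p[1]), g, ctx$ks, ctx$Cin,
                                 ctx$Cout, ctx$G, ctx$B, ctx$pad,
                                 ctx$adjoint)
          acc(p[2], gk)
        }
      },
      slicech = {
        v <- .tpVal(tp, p[1])
        gi <- array(0, dim = dim(v))
        gi[, , nd$ctx$idx] <- g
        acc(p[1], gi)
      },
      catch = {
        C <- nd$ctx$C; B <- nd$ctx$B
        for (ch in seq_along(p))
          acc(p[ch], g[, , ch + C * (0:(B - 1L)), drop = FALSE])
      },
      stop("unknown op in backward pass: ", nd$op)
    )
    if (nd$op == "param") keep[id] <- TRUE
    if (!keep[id]) grads[id] <- list(NULL)  # free consumed gradients early
  }
  grads
}
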