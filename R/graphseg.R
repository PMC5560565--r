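# Exact constrained multi-surface segmentation.
#
# The set of feasible surface configurations (smoothness between adjacent
# columns, min/max separation between adjacent surfaces) together with a
# column-separable cost is encoded as a minimum-closure problem and solved
# with a single minimum s-t cut. A node (s, col, z) belongs to the closed
# (source-side) set iff surface s passes at depth >= z in that column; the
# monotone constraint arcs carry infinite capacity, and the per-node weight
# is the cost difference c(z) - c(z-1). The optimal configurations form a
# lattice, so a unique pointwise-minimal optimum exists; the solver returns
# it (minimal source side, via BFS in the residual network) and the
# brute-force oracle returns the meet of all enumerated optima, making the
# tie-break rule identical on both routes.

#' Smoothness and separation constraints for a stage
#'
#' @param smooth_x maximum allowed |S(b, x) - S(b, x+1)| in voxels, per
#'   surface (recycled).
#' @param smooth_b maximum allowed |S(b, x) - S(b+1, x)| in voxels, per
#'   surface (recycled). Typically relaxed relative to `smooth_x` to absorb
#'   inter-B-scan axial motion.
#' @param min_sep,max_sep per adjacent ordered surface pair (upper, lower):
#'   minimum and maximum allowed separation `S_lower - S_upper` in voxels.
#'   Length `n_surfaces - 1`. A minimum of zero permits a vanished layer to
#'   collapse (e.g. the ONL in light-damage retinas).
#' @param n_surfaces number of surfaces these constraints apply to.
#' @return an object of class `constraint_spec`.
#' @export
constraint_spec <- function(smooth_x, smooth_b = smooth_x, min_sep = NULL,
                            max_sep = NULL, n_surfaces = 1L) {
  n <- as.integer(n_surfaces)
  stopifnot(n >= 1L)
  smooth_x <- rep_len(as.numeric(smooth_x), n)
  smooth_b <- rep_len(as.numeric(smooth_b), n)
  if (any(smooth_x < 0) || any(smooth_b < 0)) stop("smoothness bounds must be >= 0")
  if (n > 1L) {
    if (is.null(min_sep)) min_sep <- rep(0, n - 1L)
    if (is.null(max_sep)) max_sep <- rep(Inf, n - 1L)
    min_sep <- rep_len(as.numeric(min_sep), n - 1L)
    max_sep <- rep_len(as.numeric(max_sep), n - 1L)
    if (any(min_sep < 0)) stop("minimum separations must be >= 0")
    if (any(max_sep < min_sep)) stop("max_sep must be >= min_sep")
  } else {
    min_sep <- numeric(0); max_sep <- numeric(0)
  }
  structure(list(smooth_x = floor(smooth_x), smooth_b = floor(smooth_b),
                 min_sep = ceiling(min_sep), max_sep = floor(max_sep),
                 n_surfaces = n),
            class = "constraint_spec")
}

.as_cost_list <- function(costs) {
  if (is.array(costs) && length(dim(costs)) == 3L) costs <- list(costs)
  if (!is.list(costs) || !length(costs))
    stop("`costs` must be a 3-D array or a non-empty list of 3-D arrays")
  d <- dim(costs[[1L]])
  for (cv in costs) {
    if (!is.array(cv) || length(dim(cv)) != 3L || !identical(dim(cv), d))
      stop("all cost volumes must be 3-D arrays of identical shape")
    if (anyNA(cv) || any(!is.finite(cv))) stop("cost volumes must be finite")
  }
  costs
}

# Arc-consistent per-surface depth intervals for a chain of separation
# constraints; errors if the constraint system is infeasible for depth Z.
.feasible_ranges <- function(cons, Z, zmin = NULL, zmax = NULL) {
  n <- cons$n_surfaces
  lo <- if (is.null(zmin)) rep(0, n) else rep_len(as.numeric(zmin), n)
  hi <- if (is.null(zmax)) rep(Z - 1, n) else rep_len(as.numeric(zmax), n)
  lo <- pmax(lo, 0); hi <- pmin(hi, Z - 1)
  for (pass in 1:3) {
    if (n > 1L) {
      for (i in 2:n) {
        lo[i] <- max(lo[i], lo[i - 1] + cons$min_sep[i - 1])
        hi[i] <- min(hi[i], hi[i - 1] + cons$max_sep[i - 1])
      }
      for (i in (n - 1):1) {
        hi[i] <- min(hi[i], hi[i + 1] - cons$min_sep[i])
        lo[i] <- max(lo[i], lo[i + 1] - cons$max_sep[i])
      }
    }
  }
  if (any(lo > hi))
    stop("infeasible constraints: no surface configuration fits in depth ", Z)
  list(lo = floor(lo), hi = floor(hi))
}

# 1-based node id for (surface s, column col, depth z0 [0-based])
.node_id <- function(s, col, z0, n_col, Z) {
  ((s - 1) * n_col + (col - 1)) * Z + z0 + 1
}

#' Simultaneous multi-surface segmentation by minimum s-t cut
#'
#' Returns the exact global minimizer of the summed per-column costs over all
#' surface configurations satisfying the smoothness and separation
#' constraints. Among cost ties the pointwise-minimal optimum (every surface
#' as shallow as possible) is returned, which makes the result deterministic.
#'
#' @param costs a 3-D cost array `(b, x, z)` or list of such arrays, one per
#'   surface ordered inner to outer; lower cost = more boundary-like.
#' @param constraints a [constraint_spec()] for `length(costs)` surfaces.
#' @param names surface names for the result (default `S1..Sn`).
#' @param zmin,zmax optional per-surface depth bounds (0-based, inclusive),
#'   used by the staged pipeline to restrict each stage to its region of
#'   interest.
#' @return a [surface_set()] (voxel units) with attribute `"total_cost"`.
#' @export
segment_surfaces <- function(costs, constraints, names = NULL,
                             zmin = NULL, zmax = NULL) {
  costs <- .as_cost_list(costs)
  stopifnot(inherits(constraints, "constraint_spec"))
  ns <- length(costs)
  if (constraints$n_surfaces != ns)
    stop("constraint spec is for ", constraints$n_surfaces,
         " surfaces but ", ns, " cost volumes were given")
  d <- dim(costs[[1L]]); B <- d[1]; X <- d[2]; Z <- d[3]
  rng <- .feasible_ranges(constraints, Z, zmin, zmax)
  n_col <- B * X
  n_node <- ns * n_col * Z
  SRC <- n_node + 1L; SNK <- n_node + 2L

  # per-node closure weights: w(z) = c(z) - c(z-1), w(0) = c(0)
  w <- numeric(n_node)
  for (s in seq_len(ns)) {
    cv <- costs[[s]]
    wd <- cv
    wd[, , -1L] <- cv[, , -1L, drop = FALSE] - cv[, , -Z, drop = FALSE]
    # node order: z fastest, then col (b fastest within col? col = (x-1)*B + b)
    # We flatten columns as col = (x - 1) * B + b to match R array layout:
    # as.vector(cv) runs b fastest, then x, then z -> reorder to z-fastest.
    w[((s - 1) * n_col * Z) + seq_len(n_col * Z)] <-
      as.vector(aperm(wd, c(3, 1, 2)))
    # aperm(.., c(3,1,2)) runs z fastest, then b, then x => col = (x-1)*B + b
  }
  INF <- sum(abs(w)) + 1

  from <- vector("list", 16L); to <- vector("list", 16L); cap <- vector("list", 16L)
  k <- 0L
  add <- function(f, t, cp) {
    k <<- k + 1L
    from[[k]] <<- f; to[[k]] <<- t; cap[[k]] <<- cp
  }

  idx <- seq_len(n_node)
  pos <- w > 0; neg <- w < 0
  add(idx[pos], rep(SNK, sum(pos)), w[pos])
  add(rep(SRC, sum(neg)), idx[neg], -w[neg])

  # intra-column monotone chain: (z) -> (z-1)
  zpos <- rep_len(seq_len(Z) - 1L, n_node)  # 0-based z per node (z fastest)
  intra <- idx[zpos >= 1L]
  add(intra, intra - 1L, rep(INF, length(intra)))

  # depth range forcing per surface
  for (s in seq_len(ns)) {
    cols <- seq_len(n_col)
    if (rng$lo[s] > 0) {
      v <- .node_id(s, cols, rng$lo[s], n_col, Z)
      add(rep(SRC, n_col), v, rep(INF, n_col))
    } else {
      v <- .node_id(s, cols, 0L, n_col, Z)
      add(rep(SRC, n_col), v, rep(INF, n_col))
    }
    if (rng$hi[s] < Z - 1) {
      nz <- Z - 1 - rng$hi[s]
      z0 <- (rng$hi[s] + 1):(Z - 1)
      v <- .node_id(rep(s, n_col * nz), rep(cols, each = nz), rep(z0, n_col), n_col, Z)
      add(v, rep(SNK, length(v)), rep(INF, length(v)))
    }
  }

  # smoothness arcs between adjacent columns (col = (x-1)*B + b)
  colmat <- matrix(seq_len(n_col), nrow = B, ncol = X)
  smooth_arcs <- function(colA, colB, delta, s) {
    delta <- min(delta, Z - 1)
    nz <- Z - delta
    if (nz <= 0 || !length(colA)) return()
    z0 <- if (delta == 0) 0:(Z - 1) else delta:(Z - 1)
    nz <- length(z0)
    cA <- rep(colA, each = nz); cB <- rep(colB, each = nz); zz <- rep(z0, length(colA))
    add(.node_id(s, cA, zz, n_col, Z), .node_id(s, cB, zz - delta, n_col, Z),
        rep(INF, length(cA)))
  }
  if (B > 1L) {
    ba <- as.vector(colmat[-B, , drop = FALSE]); bb <- as.vector(colmat[-1, , drop = FALSE])
    for (s in seq_len(ns)) {
      smooth_arcs(ba, bb, constraints$smooth_b[s], s)
      smooth_arcs(bb, ba, constraints$smooth_b[s], s)
    }
  }
  if (X > 1L) {
    xa <- as.vector(colmat[, -X, drop = FALSE]); xb <- as.vector(colmat[, -1, drop = FALSE])
    for (s in seq_len(ns)) {
      smooth_arcs(xa, xb, constraints$smooth_x[s], s)
      smooth_arcs(xb, xa, constraints$smooth_x[s], s)
    }
  }

  # separation arcs between adjacent surfaces
  if (ns > 1L) {
    cols <- seq_len(n_col)
    for (i in seq_len(ns - 1L)) {
      l <- constraints$min_sep[i]
      if (l <= Z - 1) {
        z0 <- 0:(Z - 1 - l)
        nz <- length(z0)
        cA <- rep(cols, each = nz); zz <- rep(z0, n_col)
        add(.node_id(i, cA, zz, n_col, Z), .node_id(i + 1L, cA, zz + l, n_col, Z),
            rep(INF, length(cA)))
      }
      if (l >= 1) {  # upper surface cannot sit within l of the bottom
        z0 <- (Z - l):(Z - 1)
        z0 <- z0[z0 >= 0 & z0 <= Z - 1]
        if (length(z0)) {
          cA <- rep(cols, each = length(z0)); zz <- rep(z0, n_col)
          v <- .node_id(i, cA, zz, n_col, Z)
          add(v, rep(SNK, length(v)), rep(INF, length(v)))
        }
      }
      u <- constraints$max_sep[i]
      if (is.finite(u) && u <= Z - 1) {
        z0 <- u:(Z - 1)
        if (u == 0) z0 <- 0:(Z - 1)
        nz <- length(z0)
        cA <- rep(cols, each = nz); zz <- rep(z0, n_col)
        add(.node_id(i + 1L, cA, zz, n_col, Z), .node_id(i, cA, zz - u, n_col, Z),
            rep(INF, length(cA)))
      }
    }
  }

  from <- unlist(from[seq_len(k)], use.names = FALSE)
  to <- unlist(to[seq_len(k)], use.names = FALSE)
  cap <- unlist(cap[seq_len(k)], use.names = FALSE)

  g <- igraph::make_graph(rbind(from, to), n = n_node + 2L, directed = TRUE)
  mf <- igraph::max_flow(g, source = SRC, target = SNK, capacity = cap)

  # minimal source side = nodes reachable from SRC in the residual network
  f <- mf$flow
  eps <- 1e-9 * (1 + max(abs(w)))  # scale of the finite (terminal) capacities
  fw <- f < cap - eps
  bk <- f > eps
  rg <- igraph::make_graph(rbind(c(from[fw], to[bk]), c(to[fw], from[bk])),
                           n = n_node + 2L, directed = TRUE)
  reach <- as.integer(igraph::subcomponent(rg, SRC, mode = "out"))
  reach <- reach[reach <= n_node]

  # surface position = (#source-side nodes in the chain) - 1
  chain <- (reach - 1L) %/% Z + 1L  # 1..ns*n_col
  cnt <- tabulate(chain, nbins = ns * n_col)
  if (any(cnt < 1L)) stop("internal error: empty closure chain")
  S <- matrix(cnt - 1L, nrow = n_col, ncol = ns)  # col-major: col fastest

  out <- vector("list", ns)
  total <- 0
  for (s in seq_len(ns)) {
    m <- matrix(0, B, X)
    m[cbind(rep(seq_len(B), X), rep(seq_len(X), each = B))] <-
      S[, s][(rep(seq_len(X), each = B) - 1L) * B + rep(seq_len(B), X)]
    out[[s]] <- m
    total <- total + sum(costs[[s]][cbind(rep(seq_len(B), X), rep(seq_len(X), each = B),
                                          as.vector(m) + 1L)])
  }
  if (is.null(names)) names <- paste0("S", seq_len(ns))
  names(out) <- names
  res <- surface_set(out, units = "voxel", resolution = "working")
  .check_feasible(res, constraints)
  attr(res, "total_cost") <- total
  res
}

# post-hoc feasibility audit of a solver result (internal invariant)
.check_feasible <- function(ss, cons) {
  s <- ss$surfaces
  ns <- length(s)
  for (i in seq_len(ns)) {
    m <- s[[i]]
    if (ncol(m) > 1L && any(abs(m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]) >
                            cons$smooth_x[i] + 1e-9))
      stop("internal error: lateral smoothness constraint violated")
    if (nrow(m) > 1L && any(abs(m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE]) >
                            cons$smooth_b[i] + 1e-9))
      stop("internal error: inter-B-scan smoothness constraint violated")
  }
  if (ns > 1L) {
    for (i in seq_len(ns - 1L)) {
      gap <- s[[i + 1L]] - s[[i]]
      if (any(gap < cons$min_sep[i] - 1e-9) || any(gap > cons$max_sep[i] + 1e-9))
        stop("internal error: separation constraint violated")
    }
  }
  invisible(TRUE)
}

#' Exhaustive-enumeration oracle for [segment_surfaces()]
#'
#' Enumerates every feasible surface configuration of a (tiny) instance and
#' returns the pointwise-minimal minimum-cost one — the same tie-break rule
#' as the min-cut solver. Intended as an independent correctness oracle.
#'
#' @inheritParams segment_surfaces
#' @param max_configs refuse instances with more raw configurations than
#'   this (default `1e7`).
#' @return a [surface_set()] with attribute `"total_cost"`.
#' @export
brute_force_segment <- function(costs, constraints, names = NULL,
                                zmin = NULL, zmax = NULL, max_configs = 1e7) {
  costs <- .as_cost_list(costs)
  stopifnot(inherits(constraints, "constraint_spec"))
  ns <- length(costs)
  d <- dim(costs[[1L]]); B <- d[1]; X <- d[2]; Z <- d[3]
  rng <- .feasible_ranges(constraints, Z, zmin, zmax)
  n_col <- B * X
  sizes <- rep(rng$hi - rng$lo + 1, each = n_col)
  if (prod(sizes) > max_configs)
    stop("instance too large for brute-force enumeration (",
         format(prod(sizes), digits = 3), " configurations)")

  # variables ordered: surface-major, column (b fastest) within surface
  grids <- vector("list", ns * n_col)
  for (s in seq_len(ns)) {
    for (col in seq_len(n_col)) {
      grids[[(s - 1L) * n_col + col]] <- rng$lo[s]:rng$hi[s]
    }
  }
  M <- as.matrix(do.call(expand.grid, grids))
  keep <- rep(TRUE, nrow(M))
  colmat <- matrix(seq_len(n_col), nrow = B, ncol = X)
  for (s in seq_len(ns)) {
    off <- (s - 1L) * n_col
    if (X > 1L) {
      for (x in seq_len(X - 1L)) {
        a <- off + colmat[, x]; b <- off + colmat[, x + 1L]
        for (j in seq_along(a))
          keep <- keep & abs(M[, a[j]] - M[, b[j]]) <= constraints$smooth_x[s]
      }
    }
    if (B > 1L) {
      for (bb in seq_len(B - 1L)) {
        a <- off + colmat[bb, ]; b <- off + colmat[bb + 1L, ]
        for (j in seq_along(a))
          keep <- keep & abs(M[, a[j]] - M[, b[j]]) <= constraints$smooth_b[s]
      }
    }
  }
  if (ns > 1L) {
    for (i in seq_len(ns - 1L)) {
      for (col in seq_len(n_col)) {
        gap <- M[, i * n_col + col] - M[, (i - 1L) * n_col + col]
        keep <- keep & gap >= constraints$min_sep[i] & gap <= constraints$max_sep[i]
      }
    }
  }
  M <- M[keep, , drop = FALSE]
  if (!nrow(M)) stop("infeasible constraints: no surface configuration fits in depth ", Z)

  total <- numeric(nrow(M))
  bx <- cbind(rep(seq_len(B), X), rep(seq_len(X), each = B))  # col order: b fastest
  for (s in seq_len(ns)) {
    cv <- costs[[s]]
    for (col in seq_len(n_col)) {
      total <- total + cv[bx[col, 1L], bx[col, 2L], M[, (s - 1L) * n_col + col] + 1L]
    }
  }
  cmin <- min(total)
  opt <- M[total <= cmin + 1e-9, , drop = FALSE]
  meet <- apply(opt, 2L, min)
  # the optimal set is a lattice: the meet must itself be optimal
  stopifnot(any(apply(opt, 1L, function(r) all(r == meet))))

  out <- vector("list", ns)
  for (s in seq_len(ns)) {
    m <- matrix(0, B, X)
    m[bx] <- meet[(s - 1L) * n_col + seq_len(n_col)]
    out[[s]] <- m
  }
  if (is.null(names)) names <- paste0("S", seq_len(ns))
  names(out) <- names
  res <- surface_set(out, units = "voxel", resolution = "working")
  attr(res, "total_cost") <- cmin
  res
}
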