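# Digital flow phantom: converging vessel trees draining through an axial
# imaging slice, with a slow tissue/capillary compartment feeding the branch
# tips. Spins move by plug flow (uniform speed across the lumen) along each
# segment and inherit the parent segment's speed at junctions.
#
# Coordinate convention: RAS millimetres; the imaging slice is axial with
# normal z (superior-inferior); blood drains in -z (downwards) toward the
# slice. Source offsets are Delta r = r(tagging) - r(now), so source maps
# localize where blood CAME FROM; maps are projected along y (AP).

#' Phantom specification
#'
#' Describes a single converging vein tree (branches joining a trunk that
#' crosses the imaging plane), the slow tissue feeders at the branch tips,
#' and the spin seeding densities. Units: mm, mm/s, spins/mm^3.
#'
#' @param n_branches number of branches converging onto the trunk.
#' @param branch_length,branch_speed,branch_radius branch geometry/flow.
#' @param branch_angle polar angle of branches from the trunk axis, degrees.
#' @param trunk_top z of the branch junction (trunk upstream end), mm.
#' @param trunk_bottom z of the trunk downstream end, mm (below the slice).
#' @param trunk_speed,trunk_radius trunk flow speed and radius.
#' @param root x/y position of the trunk axis, mm.
#' @param tissue_extent length of the slow capillary feeder prolonging each
#'   branch tip, mm; 0 disables the tissue compartment.
#' @param tissue_speed,tissue_radius,tissue_density tissue feeder flow and
#'   seeding density (stands in for capillary beds and surrounding tissue).
#' @param spin_density blood spin seeding density, spins/mm^3.
#' @param inflow_scale relative longitudinal magnetization carried by each
#'   spin of this tree (1 = resting inflow); used to emulate task-induced
#'   inflow modulation.
#' @param speed_scale global multiplier on every segment speed (e.g. 0.8
#'   emulates a caffeine-style global slowdown).
#' @param pulsatility fractional amplitude of a global sinusoidal speed
#'   modulation with period `pulse_period` (default 1 s cardiac analogue);
#'   0 (default) models ideal cardiac-gated consistency.
#' @param pulse_period period of the speed modulation, seconds.
#' @param flow_profile "plug" (uniform speed across the lumen) or "laminar"
#'   (parabolic Poiseuille profile: a spin at radial fraction rho of the
#'   lumen moves at 2*(1 - rho^2) times the segment speed, so the
#'   cross-sectional speed-fraction distribution is uniform on (0, 2]).
#'   The spin's radial fraction, hence its speed factor, is kept constant
#'   through junctions.
#' @param seed RNG seed; a fixed seed makes the ensemble bit-reproducible.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_branches = 2L,
                         branch_length = 40, branch_speed = 10,
                         branch_radius = 2, branch_angle = 30,
                         trunk_top = 30, trunk_bottom = -15,
                         trunk_speed = 20, trunk_radius = 3,
                         root = c(0, 0),
                         tissue_extent = 20, tissue_speed = 0.5,
                         tissue_radius = 4, tissue_density = 0.5,
                         spin_density = 2,
                         inflow_scale = 1,
                         speed_scale = 1,
                         pulsatility = 0, pulse_period = 1,
                         flow_profile = c("plug", "laminar"),
                         seed = 1L) {
  flow_profile <- match.arg(flow_profile)
  spec <- list(n_branches = as.integer(n_branches),
               branch_length = branch_length, branch_speed = branch_speed,
               branch_radius = branch_radius, branch_angle = branch_angle,
               trunk_top = trunk_top, trunk_bottom = trunk_bottom,
               trunk_speed = trunk_speed, trunk_radius = trunk_radius,
               root = as.numeric(root),
               tissue_extent = tissue_extent, tissue_speed = tissue_speed,
               tissue_radius = tissue_radius, tissue_density = tissue_density,
               spin_density = spin_density,
               inflow_scale = inflow_scale,
               speed_scale = speed_scale,
               pulsatility = pulsatility, pulse_period = pulse_period,
               flow_profile = flow_profile,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$n_branches < 1L) stopf("phantom needs at least one branch")
  for (f in c("branch_speed", "trunk_speed", "branch_radius", "trunk_radius",
              "branch_length", "speed_scale")) {
    if (!is_num1(spec[[f]]) || spec[[f]] <= 0)
      stopf("phantom configuration error: '%s' must be > 0", f)
  }
  if (spec$tissue_extent > 0 && spec$tissue_speed <= 0)
    stopf("phantom configuration error: 'tissue_speed' must be > 0")
  if (spec$trunk_top <= spec$trunk_bottom)
    stopf("phantom configuration error: trunk_top must exceed trunk_bottom")
  if (spec$pulsatility < 0 || spec$pulsatility >= 1)
    stopf("phantom configuration error: pulsatility must be in [0, 1)")
  invisible(spec)
}

#' Build a converging vessel tree from a phantom specification
#'
#' The tree is a directed drainage graph: each tissue feeder drains into its
#' branch, each branch drains into the trunk, and the trunk crosses the
#' imaging plane. Child segments end where their parent starts (junction
#' continuity); per-segment plug-flow speeds are taken from the spec (no
#' hydrodynamic mass balance is solved).
#'
#' @param spec a [phantom_spec()].
#' @return object of class `vessel_tree`: `$segments` data frame (start/end
#'   points, radius, speed, parent id, compartment) and `$trunk_id`.
#' @export
build_vessel_tree <- function(spec) {
  validate_phantom_spec(spec)
  nb <- spec$n_branches
  junction <- c(spec$root[1], spec$root[2], spec$trunk_top)
  segs <- list()
  # trunk: id 1, vertical, crosses the imaging plane (z = slice plane)
  segs[[1]] <- data.frame(
    id = 1L, x0 = junction[1], y0 = junction[2], z0 = spec$trunk_top,
    x1 = junction[1], y1 = junction[2], z1 = spec$trunk_bottom,
    radius = spec$trunk_radius, speed = spec$trunk_speed,
    parent = NA_integer_, compartment = "vein")
  theta <- spec$branch_angle * pi / 180
  az <- 2 * pi * (seq_len(nb) - 1) / nb        # azimuths spread evenly
  id <- 1L
  for (i in seq_len(nb)) {
    u <- c(sin(theta) * cos(az[i]), sin(theta) * sin(az[i]), cos(theta))
    id <- id + 1L
    bid <- id
    start <- junction + spec$branch_length * u
    segs[[id]] <- data.frame(
      id = bid, x0 = start[1], y0 = start[2], z0 = start[3],
      x1 = junction[1], y1 = junction[2], z1 = junction[3],
      radius = spec$branch_radius, speed = spec$branch_speed,
      parent = 1L, compartment = "vein")
    if (spec$tissue_extent > 0) {
      id <- id + 1L
      tip <- start + spec$tissue_extent * u
      segs[[id]] <- data.frame(
        id = id, x0 = tip[1], y0 = tip[2], z0 = tip[3],
        x1 = start[1], y1 = start[2], z1 = start[3],
        radius = spec$tissue_radius, speed = spec$tissue_speed,
        parent = bid, compartment = "tissue")
    }
  }
  tree <- structure(list(segments = do.call(rbind, segs),
                         trunk_id = 1L, spec = spec),
                    class = "vessel_tree")
  validate_vessel_tree(tree)
  tree
}

#' @export
print.vessel_tree <- function(x, ...) {
  s <- x$segments
  cat(sprintf("<vessel_tree> %d segments (%d vein, %d tissue), trunk id %s\n",
              nrow(s), sum(s$compartment == "vein"),
              sum(s$compartment == "tissue"),
              paste(x$trunk_id, collapse = ",")))
  invisible(x)
}

#' Validate vessel-tree invariants
#'
#' Checks positivity of speeds/radii, acyclicity of the drainage graph,
#' convergence of every segment onto a trunk, and junction continuity
#' (child end == parent start, tolerance 1e-9 mm).
#' @param tree a `vessel_tree`.
#' @export
validate_vessel_tree <- function(tree) {
  s <- tree$segments
  if (any(s$speed <= 0)) stopf("vessel tree configuration error: speed <= 0")
  if (any(s$radius <= 0)) stopf("vessel tree configuration error: radius <= 0")
  trunks <- s$id[is.na(s$parent)]
  if (!length(trunks))
    stopf("vessel tree configuration error: no trunk (non-converging topology)")
  idx <- match(s$parent, s$id)
  for (i in seq_len(nrow(s))) {
    j <- i; seen <- integer(0)
    while (!is.na(s$parent[j])) {
      if (j %in% seen)
        stopf("vessel tree configuration error: drainage cycle detected")
      seen <- c(seen, j)
      j <- idx[j]
      if (is.na(j)) stopf("vessel tree configuration error: dangling parent id")
    }
    if (!(s$id[j] %in% trunks))
      stopf("vessel tree configuration error: segment %d does not converge", i)
  }
  child <- which(!is.na(s$parent))
  if (length(child)) {
    p <- idx[child]
    gap <- sqrt((s$x1[child] - s$x0[p])^2 + (s$y1[child] - s$y0[p])^2 +
                  (s$z1[child] - s$z0[p])^2)
    if (any(gap > 1e-9))
      stopf("vessel tree configuration error: junction discontinuity (%.3g mm)",
            max(gap))
  }
  invisible(tree)
}

#' Merge independent vessel trees into a forest
#'
#' Used by multi-vein fixtures (e.g. a control and an activated vein). Spins
#' keep the inflow scale of the tree they were seeded from.
#' @param ... `vessel_tree` objects.
#' @export
merge_vessel_trees <- function(...) {
  trees <- list(...)
  off <- 0L
  segs <- list(); trunks <- integer(0); specs <- list()
  for (i in seq_along(trees)) {
    s <- trees[[i]]$segments
    s$id <- s$id + off
    s$parent <- s$parent + off
    s$tree <- i
    segs[[i]] <- s
    trunks <- c(trunks, trees[[i]]$trunk_id + off)
    specs[[i]] <- trees[[i]]$spec
    off <- off + nrow(s)
  }
  structure(list(segments = do.call(rbind, segs), trunk_id = trunks,
                 spec = specs), class = "vessel_tree")
}

# per-segment geometry tables used by the advection kernel
segment_geometry <- function(tree) {
  s <- tree$segments
  d <- cbind(s$x1 - s$x0, s$y1 - s$y0, s$z1 - s$z0)
  len <- row_norm(d)
  dir <- d / len
  # orthonormal frame perpendicular to dir (for lumen cross-section offsets)
  ref <- matrix(rep(c(0, 1, 0), each = nrow(s)), ncol = 3)
  swap <- abs(dir[, 2]) > 0.9
  ref[swap, ] <- matrix(rep(c(1, 0, 0), each = sum(swap)), ncol = 3)
  e1 <- ref - dir * rowSums(ref * dir)
  e1 <- e1 / row_norm(e1)
  e2 <- cbind(dir[, 2] * e1[, 3] - dir[, 3] * e1[, 2],
              dir[, 3] * e1[, 1] - dir[, 1] * e1[, 3],
              dir[, 1] * e1[, 2] - dir[, 2] * e1[, 1])
  list(start = cbind(s$x0, s$y0, s$z0), dir = dir, e1 = e1, e2 = e2,
       len = len, speed = s$speed, parent = match(s$parent, s$id))
}

#' Seed spins into a vessel tree
#'
#' Places spins uniformly inside each segment's cylindrical lumen (count =
#' round(density * lumen volume); blood density for vein segments, tissue
#' density for capillary feeders). The tagging-time position `r0` of every
#' spin is recorded; trajectories are computable on demand via [advect()].
#'
#' @param tree a `vessel_tree` (single tree or merged forest).
#' @param spec the [phantom_spec()] providing densities and the seed. For a
#'   merged forest, per-tree specs stored in the tree are used.
#' @return object of class `spin_ensemble`.
#' @export
seed_spins <- function(tree, spec = tree$spec) {
  specs <- if (inherits(spec, "phantom_spec")) list(spec) else spec
  s <- tree$segments
  tree_of_seg <- if (!is.null(s$tree)) s$tree else rep(1L, nrow(s))
  geom <- segment_geometry(tree)
  seed0 <- specs[[1]]$seed
  spins <- with_seed(seed0, {
    out <- vector("list", nrow(s))
    for (i in seq_len(nrow(s))) {
      sp <- specs[[tree_of_seg[i]]]
      dens <- if (s$compartment[i] == "tissue") sp$tissue_density else sp$spin_density
      vol <- pi * s$radius[i]^2 * geom$len[i]
      n <- round(dens * vol)
      if (n < 1) { out[[i]] <- NULL; next }
      arc <- stats::runif(n, 0, geom$len[i])
      rho <- sqrt(stats::runif(n))
      rad <- s$radius[i] * rho
      ang <- stats::runif(n, 0, 2 * pi)
      a <- rad * cos(ang); b <- rad * sin(ang)
      # Poiseuille factor for laminar blood flow; tissue feeders creep
      # uniformly regardless of the profile choice
      vf <- if (sp$flow_profile == "laminar" && s$compartment[i] == "vein")
        2 * (1 - rho^2) else rep(1, n)
      r0 <- geom$start[i, , drop = FALSE][rep(1, n), ] +
        outer(arc, geom$dir[i, ]) + outer(a, geom$e1[i, ]) + outer(b, geom$e2[i, ])
      out[[i]] <- data.frame(seg = i, s0 = arc, a = a, b = b,
                             x0 = r0[, 1], y0 = r0[, 2], z0 = r0[, 3],
                             compartment = s$compartment[i],
                             m0 = sp$inflow_scale, vfactor = vf,
                             tree = tree_of_seg[i])
    }
    do.call(rbind, out)
  })
  if (is.null(spins) || nrow(spins) == 0)
    stopf("empty ensemble: spin density produced zero spins")
  rownames(spins) <- NULL
  structure(list(tree = tree, spec = specs, spins = spins,
                 n = nrow(spins), t0 = 0),
            class = "spin_ensemble")
}

#' @export
print.spin_ensemble <- function(x, ...) {
  cat(sprintf("<spin_ensemble> %d spins (%d vein, %d tissue), t0 = %g s\n",
              x$n, sum(x$spins$compartment == "vein"),
              sum(x$spins$compartment == "tissue"), x$t0))
  invisible(x)
}

# Pulsatile flow is a global multiplicative speed modulation, so the
# trajectory at wall time t equals the steady-flow trajectory at the warped
# time  w(t) = t + a*P/(2*pi) * (1 - cos(2*pi*t/P)).
warp_time <- function(t, amp, period) {
  if (amp == 0) return(t)
  t + amp * period / (2 * pi) * (1 - cos(2 * pi * t / period))
}

# Core chain walk. Returns list(seg, s) after flowing for effective
# duration `dt_eff` (already speed-scale/pulsatility warped); `vf` is the
# per-spin speed factor (1 for plug flow, Poiseuille factor for laminar).
flow_state <- function(geom, seg, s, dt_eff, vf = 1) {
  rem <- rep_len(dt_eff, length(seg))
  vf <- rep_len(vf, length(seg))
  for (iter in 1:100) {
    active <- rem > 0
    if (!any(active)) break
    v <- geom$speed[seg] * vf
    len <- geom$len[seg]
    par <- geom$parent[seg]
    t_exit <- (len - s) / v
    move <- active & !is.na(par) & rem > t_exit
    stay <- active & !move
    s[stay] <- s[stay] + rem[stay] * v[stay]   # trunk may overshoot its end
    rem[stay] <- 0
    if (any(move)) {
      rem[move] <- rem[move] - t_exit[move]
      seg[move] <- par[move]
      s[move] <- 0
    }
  }
  list(seg = seg, s = s)
}

#' Advect a spin ensemble
#'
#' Positions of all spins `t` seconds after the ensemble's reference time.
#' Vein spins move by plug flow along their segment, cross junctions into
#' the parent segment and inherit its speed; tissue spins creep along their
#' capillary feeder into the branch. Beyond the trunk's downstream end,
#' spins continue along the trunk axis at the trunk speed.
#'
#' @param ensemble a `spin_ensemble`.
#' @param t time since tagging, seconds (scalar, >= 0).
#' @return n x 3 matrix of positions (mm).
#' @export
advect <- function(ensemble, t) {
  if (!is_num1(t) || t < 0) stopf("domain error: advection time must be >= 0")
  sp <- ensemble$spins
  spec1 <- ensemble$spec[[1]]
  geom <- segment_geometry(ensemble$tree)
  geom$speed <- geom$speed * spec1$speed_scale
  dt_eff <- warp_time(ensemble$t0 + t, spec1$pulsatility, spec1$pulse_period) -
    warp_time(ensemble$t0, spec1$pulsatility, spec1$pulse_period)
  st <- flow_state(geom, sp$seg, sp$s0, dt_eff, spin_vfactor(ensemble))
  geom$start[st$seg, , drop = FALSE] +
    geom$dir[st$seg, , drop = FALSE] * st$s +
    geom$e1[st$seg, , drop = FALSE] * sp$a +
    geom$e2[st$seg, , drop = FALSE] * sp$b
}

#' Advance an ensemble in time
#'
#' Returns a new ensemble whose spins' segment/arc state has been advected
#' by `t` seconds; tagging positions `r0` are preserved. Composition holds:
#' `advect(advance(e, t1), t2)` equals `advect(e, t1 + t2)`.
#' @param ensemble a `spin_ensemble`; @param t seconds, >= 0.
#' @export
advance <- function(ensemble, t) {
  if (!is_num1(t) || t < 0) stopf("domain error: advection time must be >= 0")
  spec1 <- ensemble$spec[[1]]
  geom <- segment_geometry(ensemble$tree)
  geom$speed <- geom$speed * spec1$speed_scale
  dt_eff <- warp_time(ensemble$t0 + t, spec1$pulsatility, spec1$pulse_period) -
    warp_time(ensemble$t0, spec1$pulsatility, spec1$pulse_period)
  st <- flow_state(geom, ensemble$spins$seg, ensemble$spins$s0, dt_eff,
                   spin_vfactor(ensemble))
  ensemble$spins$seg <- st$seg
  ensemble$spins$s0 <- st$s
  ensemble$t0 <- ensemble$t0 + t
  ensemble
}

# per-spin speed factor, tolerant of hand-built ensembles without the column
spin_vfactor <- function(ensemble) {
  if (is.null(ensemble$spins$vfactor)) 1 else ensemble$spins$vfactor
}

#' Kinematic path time from a source point to the imaging plane
#'
#' Closed-form plug-flow travel time from a point (assigned to the nearest
#' segment axis) through the drainage chain to the given z plane on the
#' trunk. Independent of the spin simulation; used as the analytic oracle
#' for arrival-time analyses.
#' @param tree a `vessel_tree`; @param point mm 3-vector;
#' @param target_z z of the plane on the trunk (mm).
#' @return seconds (speed-scale of the spec is NOT applied).
#' @export
path_time_to_plane <- function(tree, point, target_z) {
  geom <- segment_geometry(tree)
  s <- tree$segments
  # nearest segment axis (clamped projection)
  d2 <- rep(Inf, nrow(s)); arc <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    w <- point - geom$start[i, ]
    a <- min(max(sum(w * geom$dir[i, ]), 0), geom$len[i])
    p <- geom$start[i, ] + a * geom$dir[i, ]
    d2[i] <- sum((point - p)^2); arc[i] <- a
  }
  i <- which.min(d2)
  t <- 0
  while (!(s$id[i] %in% tree$trunk_id)) {
    t <- t + (geom$len[i] - arc[i]) / geom$speed[i]
    i <- geom$parent[i]; arc[i] <- 0
  }
  # trunk: travel until z reaches target_z (trunk axis is monotone in z)
  dz <- geom$dir[i, 3]
  z_here <- geom$start[i, 3] + arc[i] * dz
  t + (z_here - target_z) / (-dz * geom$speed[i])
}

#' Ground-truth source occupancy of a target voxel
#'
#' Union, over the given mixing times, of source bins actually visited by
#' spins that are inside the voxel at that time: the spin-trajectory
#' occupancy oracle for venous-territory analyses (independent of the
#' Fourier reconstruction path).
#' @param ensemble a `spin_ensemble`; @param voxel as in
#'   [true_source_distribution()]; @param times mixing times (s);
#' @param grid source grid; @param include optional per-spin eligibility
#'   mask (e.g. unsaturated spins); @param kill_time optional per-spin
#'   consumption times (spins count at time t only while `kill_time >= t`).
#' @return logical matrix over the source grid.
#' @export
occupancy_mask <- function(ensemble, voxel, times, grid, include = NULL,
                           kill_time = NULL) {
  mask <- matrix(FALSE, length(grid$dx), length(grid$dz))
  for (t in times) {
    inc <- include
    if (!is.null(kill_time)) {
      alive <- kill_time >= t
      inc <- if (is.null(inc)) alive else inc & alive
    }
    h <- true_source_distribution(ensemble, voxel, t, grid,
                                  include = inc, normalize = FALSE)
    mask <- mask | (h > 0)
  }
  mask
}

#' Nearest vessel segment to a point
#'
#' Clamped projection of a point onto every segment axis; returns the
#' nearest segment's id, plug-flow speed, arc position and axial distance.
#' Companion to [path_time_to_plane()] for analytic arrival-time oracles.
#' @param tree a `vessel_tree`; @param point mm 3-vector.
#' @export
segment_at_point <- function(tree, point) {
  geom <- segment_geometry(tree)
  n <- nrow(tree$segments)
  d2 <- rep(Inf, n); arc <- numeric(n)
  for (i in seq_len(n)) {
    w <- point - geom$start[i, ]
    a <- min(max(sum(w * geom$dir[i, ]), 0), geom$len[i])
    p <- geom$start[i, ] + a * geom$dir[i, ]
    d2[i] <- sum((point - p)^2); arc[i] <- a
  }
  i <- which.min(d2)
  list(id = tree$segments$id[i], index = i, speed = tree$segments$speed[i],
       arc = arc[i], dist = sqrt(d2[i]))
}

#' Brute-force ground-truth source distribution
#'
#' Direct spin bookkeeping oracle for the perfusion source map: histogram,
#' over relative source offsets (Delta x, Delta z) = r(tagging) - r(t_mix)
#' projected along y, of the spins found inside a target voxel at `t_mix`.
#'
#' @param ensemble a `spin_ensemble`.
#' @param voxel list with `x`, `y` (center, mm), `z` (slice center),
#'   `size` (in-plane width mm, length 2), `thickness` (slice thickness mm).
#' @param t_mix mixing time, seconds.
#' @param grid list with `dx`, `dz` (bin-center vectors, mm) and `res`
#'   (bin width mm, length 2) — typically `source_grid(protocol)`.
#' @param include optional logical mask of spins eligible to contribute
#'   (e.g. unsaturated, not yet imaged).
#' @param weights optional per-spin weights (default spin `m0`).
#' @param wrap if TRUE, offsets outside the grid wrap around (aliasing
#'   convention of the Fourier reconstruction); if FALSE they are dropped.
#' @param normalize if TRUE (default), histogram sums to 1 when nonempty.
#' @return matrix `length(dx)` x `length(dz)`.
#' @export
true_source_distribution <- function(ensemble, voxel, t_mix, grid,
                                     include = NULL, weights = NULL,
                                     wrap = FALSE, normalize = TRUE) {
  pos <- advect(ensemble, t_mix)
  sp <- ensemble$spins
  inside <- abs(pos[, 1] - voxel$x) <= voxel$size[1] / 2 &
    abs(pos[, 2] - voxel$y) <= voxel$size[2] / 2 &
    abs(pos[, 3] - voxel$z) <= voxel$thickness / 2
  if (!is.null(include)) inside <- inside & include
  nx <- length(grid$dx); nz <- length(grid$dz)
  h <- matrix(0, nx, nz)
  if (!any(inside)) return(h)
  w <- if (is.null(weights)) sp$m0[inside] else weights[inside]
  dxo <- sp$x0[inside] - pos[inside, 1]
  dzo <- sp$z0[inside] - pos[inside, 3]
  ix <- round(dxo / grid$res[1]) + which(abs(grid$dx) < grid$res[1] / 4)
  iz <- round(dzo / grid$res[2]) + which(abs(grid$dz) < grid$res[2] / 4)
  if (wrap) {
    ix <- ((ix - 1) %% nx) + 1
    iz <- ((iz - 1) %% nz) + 1
    keep <- rep(TRUE, length(ix))
  } else {
    keep <- ix >= 1 & ix <= nx & iz >= 1 & iz <= nz
  }
  for (j in which(keep)) h[ix[j], iz[j]] <- h[ix[j], iz[j]] + w[j]
  if (normalize && sum(h) > 0) h <- h / sum(h)
  h
}
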