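# Stimulated-echo acquisition simulator.
#
# Each repetition tags the longitudinal magnetization with a cosine grating
# cos(k . r0 + phi) at one displacement-encoding wavevector k and one
# phase-cycle phase phi, then images the slice dynamically at the protocol's
# mixing times. Each acquired sample contains three echo pathways:
#   stimulated echo   ~ exp(+i k . (r0 - r)) exp(+i phi)   (phase ~ displacement)
#   conjugate echo    ~ exp(-i k . (r0 + r)) exp(-i phi)
#   FID / T1 recovery ~ independent of k and phi
# Three-point 120-degree phase cycling lets the reconstruction isolate the
# stimulated echo exactly. Encoding wavevectors live on a Cartesian grid in
# displacement-frequency space: step dk fixes the source field of view
# (FOV = 2*pi/dk) and the maximum encoding fixes the source resolution
# (res = pi/k_max).

#' Displacement-encoding grid from a source FOV and resolution
#'
#' Builds the complete rectangular encoding grid for a requested source
#' field of view and resolution. Per axis: n = round(FOV/res) encodings with
#' step dk = 2*pi/FOV, symmetric about DC (which is always on the grid),
#' reaching k_max = pi/res. Ordering is row-major over (k_x, k_z) with k_x
#' varying fastest and DC at the grid center.
#'
#' @param source_fov source field of view (mm), length-2 (x, z).
#' @param source_res source resolution (mm), length-2 (x, z).
#' @return list: `encodings` (N x 2 matrix, rad/mm), `kx`, `kz` axis values,
#'   `nx`, `nz`, `fov`, `res`.
#' @export
protocol_from_fov <- function(source_fov, source_res) {
  source_fov <- rep_len(as.numeric(source_fov), 2)
  source_res <- rep_len(as.numeric(source_res), 2)
  if (any(source_res <= 0)) stopf("source resolution must be > 0")
  if (any(source_res > source_fov + 1e-12))
    stopf("source resolution cannot exceed the source FOV")
  n <- pmax(1L, as.integer(round(source_fov / source_res)))
  axis_k <- function(n, fov) (2 * pi / fov) * (seq_len(n) - 1 - floor(n / 2))
  kx <- axis_k(n[1], source_fov[1])
  kz <- axis_k(n[2], source_fov[2])
  g <- expand.grid(kx = kx, kz = kz, KEEP.OUT.ATTRS = FALSE)  # kx fastest
  list(encodings = cbind(kx = g$kx, kz = g$kz), kx = kx, kz = kz,
       nx = n[1], nz = n[2], fov = source_fov, res = source_res)
}

#' Acquisition protocol
#'
#' Bundles the displacement-encoding grid, three-point phase cycle, mixing
#' times, relaxation, slice/saturation geometry, multi-slice schedule and
#' noise settings. Units: mm, seconds, rad/mm.
#'
#' @param source_fov,source_res source-map field of view / resolution (mm,
#'   length-2 (x, z)); the encoding grid is derived via [protocol_from_fov()].
#' @param mixing_times strictly increasing mixing times (s). The default is
#'   the 19-point series 0.1 to 2.8 s in 0.15 s increments.
#' @param phase_cycle phase-cycle phases (rad); default three-point
#'   120-degree cycling `c(0, 2*pi/3, 4*pi/3)`.
#' @param t1 longitudinal relaxation time of blood (s); default 1.584 s.
#' @param slices data frame with column `z`: slice-center positions (mm).
#'   Multi-slice protocols image the slices in order within each dynamic,
#'   with `slice_gap` seconds between consecutive slice acquisitions.
#' @param slice_thickness imaging slice thickness (mm).
#' @param sat_bands data frame (`z`, `thickness`): spatial saturation slabs
#'   applied at tagging; spins inside are nulled (m = 0). Default: a 30 mm
#'   slab centred on the first slice, suppressing static tissue around it.
#' @param voxels data frame (`x`, `y`, `slice`): target image voxels.
#' @param voxel_size in-plane voxel size (mm), default 4 x 4.
#' @param slice_gap temporal gap between consecutive slice acquisitions in
#'   multi-slice mode (s); default 0.033.
#' @param tr repetition window (s); the latest imaging event must fit in it.
#' @param fid_scale amplitude of the T1-recovery (FID) artifact term.
#' @param noise_sigma std. dev. of circularly symmetric complex Gaussian
#'   noise added per acquired sample (0 = noiseless).
#' @param consume_on_imaging if TRUE (default), the ideal 90-degree imaging
#'   excitation consumes the tagged longitudinal magnetization of spins
#'   inside the imaged slice, which thereafter contribute exactly zero; this
#'   is what suppresses tagged blood between slices in multi-slice mode.
#' @param snap_displacements validation mode: snap each spin's displacement
#'   to the nearest source-grid bin centre (with FOV wraparound) before
#'   encoding, making the Fourier model exactly consistent with the binned
#'   brute-force histogram.
#' @param seed RNG seed for the noise stream.
#' @export
acq_protocol <- function(source_fov = c(36, 132), source_res = c(6, 6),
                         mixing_times = seq(0.1, by = 0.15, length.out = 19),
                         phase_cycle = c(0, 2 * pi / 3, 4 * pi / 3),
                         t1 = 1.584,
                         slices = data.frame(z = 0), slice_thickness = 5,
                         sat_bands = NULL,
                         voxels = data.frame(x = 0, y = 0, slice = 1L),
                         voxel_size = c(4, 4),
                         slice_gap = 0.033, tr = 3,
                         fid_scale = 1, noise_sigma = 0,
                         consume_on_imaging = TRUE,
                         snap_displacements = FALSE,
                         seed = 1L) {
  grid <- protocol_from_fov(source_fov, source_res)
  if (is.null(sat_bands))
    sat_bands <- data.frame(z = slices$z[1], thickness = 30)
  p <- list(grid = grid, mixing_times = as.numeric(mixing_times),
            phase_cycle = as.numeric(phase_cycle), t1 = t1,
            slices = slices, slice_thickness = slice_thickness,
            sat_bands = sat_bands, voxels = voxels,
            voxel_size = rep_len(as.numeric(voxel_size), 2),
            slice_gap = slice_gap, tr = tr, fid_scale = fid_scale,
            noise_sigma = noise_sigma,
            consume_on_imaging = isTRUE(consume_on_imaging),
            snap_displacements = isTRUE(snap_displacements),
            seed = as.integer(seed))
  class(p) <- "acq_protocol"
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  mt <- p$mixing_times
  if (!length(mt) || any(mt <= 0) || any(diff(mt) <= 0))
    stopf("protocol error: mixing times must be strictly increasing and > 0")
  if (length(p$phase_cycle) < 3)
    stopf("protocol error: three-point phase cycling needs >= 3 phases")
  if (p$t1 <= 0) stopf("protocol error: T1 must be > 0")
  if (any(p$voxels$slice < 1) || any(p$voxels$slice > nrow(p$slices)))
    stopf("geometry error: target voxel references a slice outside the protocol")
  if (max(mt) + (nrow(p$slices) - 1) * p$slice_gap > p$tr)
    stopf("protocol error: mixing time exceeds the repetition window (tr = %g s)",
          p$tr)
  invisible(p)
}

#' @export
print.acq_protocol <- function(x, ...) {
  cat(sprintf(paste0("<acq_protocol> %d encodings (%dx%d), %d phase-cycle ",
                     "steps, %d mixing times (%.3g-%.3g s), %d slice(s), ",
                     "%d target voxel(s)\n"),
              nrow(x$grid$encodings), x$grid$nx, x$grid$nz,
              length(x$phase_cycle), length(x$mixing_times),
              min(x$mixing_times), max(x$mixing_times),
              nrow(x$slices), nrow(x$voxels)))
  invisible(x)
}

#' Source-map bin grid of a protocol
#'
#' Bin-centre coordinates of the reconstructed source maps: the Fourier-dual
#' grid of the encoding grid, spacing = source resolution, with the Delta=0
#' bin exactly at the grid centre.
#' @param protocol an `acq_protocol` (or a `protocol_from_fov()` list).
#' @export
source_grid <- function(protocol) {
  g <- if (inherits(protocol, "acq_protocol")) protocol$grid else protocol
  list(dx = g$res[1] * (seq_len(g$nx) - 1 - floor(g$nx / 2)),
       dz = g$res[2] * (seq_len(g$nz) - 1 - floor(g$nz / 2)),
       res = g$res, fov = g$fov)
}

# imaging event table: one row per (slice, dynamic) in acquisition order
imaging_events <- function(protocol) {
  ns <- nrow(protocol$slices)
  ev <- expand.grid(t_idx = seq_along(protocol$mixing_times),
                    slice = seq_len(ns), KEEP.OUT.ATTRS = FALSE)
  ev$time <- protocol$mixing_times[ev$t_idx] + (ev$slice - 1) * protocol$slice_gap
  ev[order(ev$time), , drop = FALSE]
}

# spins inside any saturation slab at tagging get m = 0
saturated_at_tagging <- function(ensemble, sat_bands) {
  z0 <- ensemble$spins$z0
  sat <- rep(FALSE, length(z0))
  for (i in seq_len(nrow(sat_bands)))
    sat <- sat | abs(z0 - sat_bands$z[i]) <= sat_bands$thickness[i] / 2
  sat
}

#' Cosine-tag an ensemble
#'
#' Per-spin longitudinal magnetization after the tagging module:
#' m = m0 * cos(k . r0 + phi), with m = 0 for spins inside a saturation slab
#' at tagging time. Only the in-plane encoding components (x, z) are used.
#'
#' @param ensemble a `spin_ensemble` at its tagging-time state.
#' @param k encoding wavevector (rad/mm), length-2 (k_x, k_z).
#' @param phi phase-cycle phase (rad).
#' @param sat_bands saturation slabs (data frame `z`, `thickness`), or NULL.
#' @return numeric vector of tagged magnetization, one per spin.
#' @export
tag <- function(ensemble, k, phi = 0, sat_bands = NULL) {
  sp <- ensemble$spins
  m <- sp$m0 * cos(k[1] * sp$x0 + k[2] * sp$z0 + phi)
  if (!is.null(sat_bands)) m[saturated_at_tagging(ensemble, sat_bands)] <- 0
  m
}

# first imaging event at which each spin is inside an imaged slice
# (Inf = never); the spin still contributes to the event that consumes it.
imaging_kill_times <- function(ensemble, protocol) {
  n <- ensemble$n
  kill <- rep(Inf, n)
  if (!protocol$consume_on_imaging) return(kill)
  ev <- imaging_events(protocol)
  half <- protocol$slice_thickness / 2
  for (e in seq_len(nrow(ev))) {
    pos <- advect(ensemble, ev$time[e])
    zs <- protocol$slices$z[ev$slice[e]]
    hit <- abs(pos[, 3] - zs) <= half & is.infinite(kill)
    kill[hit] <- ev$time[e]
  }
  kill
}

# snap displacements to source-grid bin centres, wrapping across the FOV
snap_to_grid <- function(d, res, n) {
  idx <- round(d / res)
  (((idx + floor(n / 2)) %% n) - floor(n / 2)) * res
}

#' Complex signal of one target voxel for one tagging
#'
#' Direct evaluation of the three-echo signal model for a single encoding,
#' phase-cycle phase and mixing time:
#' S = sum over unsaturated spins in the voxel of
#'     1/2 m0 e^(-t/T1) e^(i k.(r0-r)) e^(i phi)          (stimulated echo)
#'   + 1/2 m0 e^(-t/T1) e^(-i k.(r0+r)) e^(-i phi)        (conjugate echo)
#'   + fid_scale (1 - e^(-t/T1)) * (in-voxel spin weight)  (T1 recovery)
#' Spins whose tagged magnetization was consumed by an earlier imaging
#' excitation contribute exactly zero.
#'
#' @param ensemble a `spin_ensemble`.
#' @param k,phi encoding wavevector (rad/mm, length 2) and phase (rad).
#' @param t_mix mixing time (s).
#' @param voxel list/row with `x`, `y` (mm) and `slice` (index into
#'   `protocol$slices`).
#' @param protocol an `acq_protocol` (geometry, T1, saturation, FID scale).
#' @param kill_time optional per-spin consumption times from the multi-slice
#'   schedule (computed internally when omitted, i.e. no prior imaging).
#' @return complex scalar.
#' @export
voxel_signal <- function(ensemble, k, phi, t_mix, voxel, protocol,
                         kill_time = NULL) {
  if (voxel$slice < 1 || voxel$slice > nrow(protocol$slices))
    stopf("geometry error: voxel outside the protocol's slices")
  pos <- advect(ensemble, t_mix)
  sp <- ensemble$spins
  zs <- protocol$slices$z[voxel$slice]
  inside <- abs(pos[, 1] - voxel$x) <= protocol$voxel_size[1] / 2 &
    abs(pos[, 2] - voxel$y) <= protocol$voxel_size[2] / 2 &
    abs(pos[, 3] - zs) <= protocol$slice_thickness / 2
  if (!is.null(kill_time)) inside <- inside & kill_time >= t_mix
  decay <- exp(-t_mix / protocol$t1)
  fid <- protocol$fid_scale * (1 - decay) * sum(sp$m0[inside])
  sat <- saturated_at_tagging(ensemble, protocol$sat_bands)
  tagged <- inside & !sat
  if (!any(tagged)) return(complex(real = fid, imaginary = 0))
  dxo <- sp$x0[tagged] - pos[tagged, 1]
  dzo <- sp$z0[tagged] - pos[tagged, 3]
  if (protocol$snap_displacements) {
    dxo <- snap_to_grid(dxo, protocol$grid$res[1], protocol$grid$nx)
    dzo <- snap_to_grid(dzo, protocol$grid$res[2], protocol$grid$nz)
  }
  w <- sp$m0[tagged]
  stim <- 0.5 * decay * sum(w * exp(1i * (k[1] * dxo + k[2] * dzo)))
  cxo <- sp$x0[tagged] + pos[tagged, 1]
  czo <- sp$z0[tagged] + pos[tagged, 3]
  conj_echo <- 0.5 * decay * sum(w * exp(-1i * (k[1] * cxo + k[2] * czo)))
  stim * exp(1i * phi) + conj_echo * exp(-1i * phi) + fid
}

#' Simulate a full DiSpect acquisition
#'
#' For every encoding and phase-cycle step, a freshly tagged ensemble
#' realization (idealized cardiac-gated repetition) is imaged dynamically at
#' all mixing times; in multi-slice mode slices are visited in order with
#' the protocol's inter-slice gap and each imaging event consumes the tagged
#' magnetization of spins inside that slice, so blood imaged at one slice
#' contributes exactly zero to any later acquisition. Optional i.i.d.
#' circularly symmetric complex Gaussian noise is added per sample.
#'
#' @param ensemble a `spin_ensemble`, or a factory `function(rep)` returning
#'   one per repetition (e.g. to inject per-repetition physiological jitter;
#'   repetitions are numbered over phase-cycle-major order).
#' @param protocol an `acq_protocol`.
#' @return object of class `encoded_signal`: complex `values` array indexed
#'   (encoding, phase step, mixing time, voxel), per-voxel imaging `times`,
#'   and a copy of the protocol.
#' @export
acquire_series <- function(ensemble, protocol) {
  validate_protocol(protocol)
  K <- protocol$grid$encodings
  nk <- nrow(K); np <- length(protocol$phase_cycle)
  nt <- length(protocol$mixing_times); nv <- nrow(protocol$voxels)
  times <- matrix(0, nt, nv)
  for (v in seq_len(nv))
    times[, v] <- protocol$mixing_times +
      (protocol$voxels$slice[v] - 1) * protocol$slice_gap
  vals <- array(0i, dim = c(nk, np, nt, nv))
  if (is.function(ensemble)) {
    # slow path: fresh ensemble per repetition (jittered gating)
    for (m in seq_len(np)) for (n in seq_len(nk)) {
      ens <- ensemble((m - 1) * nk + n)
      kt <- imaging_kill_times(ens, protocol)
      for (v in seq_len(nv)) for (j in seq_len(nt)) {
        vals[n, m, j, v] <- voxel_signal(
          ens, K[n, ], protocol$phase_cycle[m], times[j, v],
          protocol$voxels[v, ], protocol, kill_time = kt)
      }
    }
  } else {
    # fast path: identical ensemble every repetition; geometry is computed
    # once per (voxel, mixing time) and reused across all encodings
    sat <- saturated_at_tagging(ensemble, protocol$sat_bands)
    kt <- imaging_kill_times(ensemble, protocol)
    sp <- ensemble$spins
    pos_cache <- new.env(parent = emptyenv())
    get_pos <- function(t) {
      key <- format(t, digits = 15)
      if (is.null(pos_cache[[key]])) pos_cache[[key]] <- advect(ensemble, t)
      pos_cache[[key]]
    }
    stim_arr <- array(0i, dim = c(nk, nt, nv))
    conj_arr <- array(0i, dim = c(nk, nt, nv))
    fid_arr <- matrix(0, nt, nv)
    for (v in seq_len(nv)) {
      vx <- protocol$voxels[v, ]
      zs <- protocol$slices$z[vx$slice]
      for (j in seq_len(nt)) {
        t <- times[j, v]
        pos <- get_pos(t)
        inside <- abs(pos[, 1] - vx$x) <= protocol$voxel_size[1] / 2 &
          abs(pos[, 2] - vx$y) <= protocol$voxel_size[2] / 2 &
          abs(pos[, 3] - zs) <= protocol$slice_thickness / 2 &
          kt >= t
        decay <- exp(-t / protocol$t1)
        fid_arr[j, v] <- protocol$fid_scale * (1 - decay) * sum(sp$m0[inside])
        tagged <- inside & !sat
        if (!any(tagged)) next
        w <- sp$m0[tagged]
        dxo <- sp$x0[tagged] - pos[tagged, 1]
        dzo <- sp$z0[tagged] - pos[tagged, 3]
        if (protocol$snap_displacements) {
          dxo <- snap_to_grid(dxo, protocol$grid$res[1], protocol$grid$nx)
          dzo <- snap_to_grid(dzo, protocol$grid$res[2], protocol$grid$nz)
        }
        stim_arr[, j, v] <- 0.5 * decay *
          (exp(1i * (outer(K[, 1], dxo) + outer(K[, 2], dzo))) %*% w)
        cxo <- sp$x0[tagged] + pos[tagged, 1]
        czo <- sp$z0[tagged] + pos[tagged, 3]
        conj_arr[, j, v] <- 0.5 * decay *
          (exp(-1i * (outer(K[, 1], cxo) + outer(K[, 2], czo))) %*% w)
      }
    }
    for (m in seq_len(np)) {
      phi <- protocol$phase_cycle[m]
      vals[, m, , ] <- stim_arr * exp(1i * phi) + conj_arr * exp(-1i * phi) +
        rep(fid_arr, each = nk)
    }
  }
  if (protocol$noise_sigma > 0) {
    vals <- vals + with_seed(protocol$seed, {
      n <- length(vals)
      complex(real = stats::rnorm(n, 0, protocol$noise_sigma),
              imaginary = stats::rnorm(n, 0, protocol$noise_sigma))
    })
  }
  structure(list(values = vals, times = times, protocol = protocol),
            class = "encoded_signal")
}

#' @export
print.encoded_signal <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<encoded_signal> %d encodings x %d phases x %d mixing times x %d voxels\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
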