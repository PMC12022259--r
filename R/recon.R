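# Echo separation and Fourier inversion of the displacement encodings.
#
# Each acquisition samples one point of the 2-D Fourier transform of the
# perfusion source map over relative displacements (Delta x, Delta z).
# Three-point phase cycling isolates the stimulated echo; an inverse DFT
# over the complete encoding grid then yields the dynamic source maps. The
# inverse transform carries the 1/N normalization so that the map total
# equals the DC (k = 0) sample — the total inflowing tagged magnetization.

#' Separate the stimulated echo by phase cycling
#'
#' Computes the phi-Fourier coefficient of the e^(+i phi) pathway,
#' `(1/P) * sum_m S(phi_m) e^(-i phi_m)`. For the three-point 120-degree
#' cycle the conjugate-echo (e^(-i phi)) and FID (phi-independent)
#' contributions cancel exactly.
#'
#' @param sig an `encoded_signal`.
#' @return complex array indexed (encoding, mixing time, voxel).
#' @export
separate_echoes <- function(sig) {
  phases <- sig$protocol$phase_cycle
  d <- dim(sig$values)
  if (d[2] != length(phases))
    stopf("missing phase-cycle step: signal has %d, protocol expects %d",
          d[2], length(phases))
  out <- array(0i, dim = d[c(1, 3, 4)])
  for (m in seq_along(phases)) {
    sl <- sig$values[, m, , , drop = FALSE]
    dim(sl) <- d[c(1, 3, 4)]
    out <- out + sl * exp(-1i * phases[m])
  }
  out / length(phases)
}

#' Reconstruct dynamic perfusion source maps
#'
#' Inverse 2-D DFT of the separated stimulated echo over the complete
#' encoding grid, per target voxel and mixing time:
#' `map(b) = (1/N) sum_n stim_n exp(-i k_n . Delta_b)`. The map total over
#' all bins equals the DC-encoding sample (conservation). The source grid
#' (FOV, resolution, Delta = 0 at the centre bin) follows the protocol's
#' encoding-grid conventions.
#'
#' @param stim complex array (encoding, mixing time, voxel) from
#'   [separate_echoes()].
#' @param protocol the `acq_protocol` used for the acquisition.
#' @param times optional per-voxel imaging-time matrix (mixing time, voxel);
#'   defaults to the protocol schedule.
#' @return object of class `source_map`: complex `values` array
#'   (Delta x bin, Delta z bin, mixing time, voxel), `grid`, `frame`
#'   ("relative"), `t1`, `times`, `voxels`.
#' @export
reconstruct_source_maps <- function(stim, protocol, times = NULL) {
  K <- protocol$grid$encodings
  nk <- nrow(K)
  if (length(dim(stim)) == 2) dim(stim) <- c(dim(stim), 1L)
  d <- dim(stim)
  if (d[1] != nk)
    stopf("incomplete encoding grid: %d samples for a %d-point grid (partial-Fourier reconstruction is not supported)",
          d[1], nk)
  g <- source_grid(protocol)
  bins <- expand.grid(dx = g$dx, dz = g$dz, KEEP.OUT.ATTRS = FALSE) # dx fastest
  # inverse DFT matrix, bins x encodings, with 1/N normalization
  A <- exp(-1i * (outer(bins$dx, K[, 1]) + outer(bins$dz, K[, 2]))) / nk
  nt <- d[2]; nv <- d[3]
  vals <- array(0i, dim = c(length(g$dx), length(g$dz), nt, nv))
  for (v in seq_len(nv)) {
    m <- A %*% stim[, , v]                      # bins x mixing times
    vals[, , , v] <- array(m, dim = c(length(g$dx), length(g$dz), nt))
  }
  if (is.null(times)) {
    times <- matrix(0, nt, nv)
    for (v in seq_len(nv))
      times[, v] <- protocol$mixing_times +
        (protocol$voxels$slice[v] - 1) * protocol$slice_gap
  }
  vox <- protocol$voxels
  vox$z <- protocol$slices$z[vox$slice]
  structure(list(values = vals, grid = g, frame = "relative",
                 t1 = protocol$t1, times = times, voxels = vox,
                 voxel_size = protocol$voxel_size,
                 slice_thickness = protocol$slice_thickness),
            class = "source_map")
}

#' @export
print.source_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<source_map> %dx%d bins (res %gx%g mm), %d mixing times, %d voxel(s), frame=%s\n",
              d[1], d[2], x$grid$res[1], x$grid$res[2], d[3], d[4], x$frame))
  invisible(x)
}

#' Extract a single target voxel's maps
#' @param map a `source_map`; @param voxel voxel index.
#' @export
subset_voxel <- function(map, voxel) {
  d <- dim(map$values)
  if (voxel < 1 || voxel > d[4]) stopf("voxel index out of range")
  map$values <- map$values[, , , voxel, drop = FALSE]
  map$times <- map$times[, voxel, drop = FALSE]
  map$voxels <- map$voxels[voxel, , drop = FALSE]
  map
}

#' Shift a source map into absolute scanner coordinates
#'
#' Relabels the source axes from relative offsets to absolute positions,
#' `r_source = voxel_centre + Delta r`; values are unchanged. Requires a
#' single-voxel map (use [subset_voxel()] first).
#' @param map a `source_map` with `frame = "relative"`.
#' @param voxel voxel index if the map holds several (default 1).
#' @export
to_absolute <- function(map, voxel = 1L) {
  if (map$frame == "absolute")
    stopf("map is already in the absolute frame")
  map <- subset_voxel(map, voxel)
  ctr <- c(map$voxels$x[1], map$voxels$z[1])
  map$grid$dx <- map$grid$dx + ctr[1]
  map$grid$dz <- map$grid$dz + ctr[2]
  map$origin <- ctr
  map$frame <- "absolute"
  map
}

#' Undo [to_absolute()]
#' @param map an absolute-frame `source_map`.
#' @export
to_relative <- function(map) {
  if (map$frame != "absolute") stopf("map is not in the absolute frame")
  map$grid$dx <- map$grid$dx - map$origin[1]
  map$grid$dz <- map$grid$dz - map$origin[2]
  map$origin <- NULL
  map$frame <- "relative"
  map
}

# Additively place absolute-frame maps onto the union grid. Offsets between
# maps are aligned to the nearest source-grid bin.
combine_absolute_maps <- function(maps, mode = c("complex", "magnitude")) {
  mode <- match.arg(mode)
  res <- maps[[1]]$grid$res
  nt <- dim(maps[[1]]$values)[3]
  for (m in maps) {
    if (m$frame != "absolute") stopf("all maps must be in the absolute frame")
    if (any(abs(m$grid$res - res) > 1e-9)) stopf("mismatched source grids")
    if (dim(m$values)[3] != nt) stopf("mismatched mixing-time dimensions")
  }
  x0 <- min(vapply(maps, function(m) m$grid$dx[1], 0))
  x1 <- max(vapply(maps, function(m) m$grid$dx[length(m$grid$dx)], 0))
  z0 <- min(vapply(maps, function(m) m$grid$dz[1], 0))
  z1 <- max(vapply(maps, function(m) m$grid$dz[length(m$grid$dz)], 0))
  gx <- seq(x0, x1 + res[1] / 4, by = res[1])
  gz <- seq(z0, z1 + res[2] / 4, by = res[2])
  vals <- array(if (mode == "complex") 0i else 0,
                dim = c(length(gx), length(gz), nt, 1))
  for (m in maps) {
    ox <- round((m$grid$dx[1] - x0) / res[1])
    oz <- round((m$grid$dz[1] - z0) / res[2])
    v <- if (mode == "complex") m$values else abs(m$values)
    ix <- ox + seq_along(m$grid$dx)
    iz <- oz + seq_along(m$grid$dz)
    vals[ix, iz, , 1] <- vals[ix, iz, , 1, drop = FALSE] + v
  }
  out <- maps[[1]]
  out$values <- vals
  out$grid$dx <- gx
  out$grid$dz <- gz
  out$grid$fov <- c(length(gx) * res[1], length(gz) * res[2])
  out$times <- matrix(rowMeans(vapply(maps, function(m) m$times[, 1],
                                      numeric(nt))), nt, 1)
  out$voxels <- do.call(rbind, lapply(maps, function(m) m$voxels))
  out$combined <- TRUE
  out
}

#' Combine the source maps of an ROI of target voxels
#'
#' Shifts each member voxel's map into the absolute frame and sums them on
#' the union grid, giving a single per-vessel ROI map. `mode = "complex"`
#' (default) sums the complex maps; `mode = "magnitude"` sums magnitudes.
#'
#' @param map a multi-voxel relative-frame `source_map`.
#' @param voxels indices of the member voxels.
#' @param mode "complex" or "magnitude".
#' @export
combine_roi <- function(map, voxels, mode = c("complex", "magnitude")) {
  if (!length(voxels)) stopf("empty ROI")
  combine_absolute_maps(lapply(voxels, function(v) to_absolute(map, v)),
                        mode = match.arg(mode))
}

#' Combine per-slice vein-branch maps into one global map
#'
#' Multi-slice acquisitions yield, for each labelled vein, branch ROIs in
#' several slices. Each branch map is shifted to the global (absolute)
#' coordinate frame using its own voxel/slice position and the maps are
#' summed on the union grid.
#'
#' @param maps list of absolute-frame single-ROI `source_map`s belonging to
#'   one labelled vein (any slice).
#' @param mode "complex" or "magnitude".
#' @export
combine_multislice <- function(maps, mode = c("complex", "magnitude")) {
  if (!length(maps)) stopf("empty map list")
  if (length(maps) == 1L) return(maps[[1]])
  combine_absolute_maps(maps, mode = match.arg(mode))
}
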