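# Shared test helpers: hand-built ensembles and synthetic source maps.

# Ensemble of independent point spins, each on its own long straight
# segment. `dirs` are per-spin flow directions (unit vectors), `speeds`
# per-spin plug-flow speeds; tiny default speed approximates static spins.
point_ensemble <- function(r0, dirs = NULL, speeds = 1e-9, m0 = 1) {
  r0 <- matrix(r0, ncol = 3)
  n <- nrow(r0)
  if (is.null(dirs)) dirs <- matrix(rep(c(0, 0, -1), each = n), ncol = 3)
  dirs <- matrix(dirs, ncol = 3)
  speeds <- rep_len(speeds, n)
  m0 <- rep_len(m0, n)
  L <- 1e6
  segs <- data.frame(
    id = seq_len(n),
    x0 = r0[, 1], y0 = r0[, 2], z0 = r0[, 3],
    x1 = r0[, 1] + L * dirs[, 1], y1 = r0[, 2] + L * dirs[, 2],
    z1 = r0[, 3] + L * dirs[, 3],
    radius = 1, speed = speeds, parent = NA_integer_, compartment = "vein")
  tree <- structure(list(segments = segs, trunk_id = segs$id,
                         spec = phantom_spec()), class = "vessel_tree")
  spins <- data.frame(seg = seq_len(n), s0 = 0, a = 0, b = 0,
                      x0 = r0[, 1], y0 = r0[, 2], z0 = r0[, 3],
                      compartment = "vein", m0 = m0, tree = 1L)
  structure(list(tree = tree, spec = list(phantom_spec()), spins = spins,
                 n = n, t0 = 0), class = "spin_ensemble")
}

# protocol with no saturation and no FID, convenient for point-spin tests
point_protocol <- function(source_fov = c(24, 24), source_res = c(6, 6),
                           mixing_times = 1, t1 = 1e9, voxels = NULL, ...) {
  if (is.null(voxels)) voxels <- data.frame(x = 0, y = 0, slice = 1L)
  acq_protocol(source_fov = source_fov, source_res = source_res,
               mixing_times = mixing_times, t1 = t1,
               sat_bands = data.frame(z = 1e5, thickness = 1),
               voxels = voxels, voxel_size = c(10, 10),
               slice_thickness = 10, fid_scale = 0,
               consume_on_imaging = FALSE, tr = 1e9, ...)
}

# build a source_map object directly from a complex/numeric array
synth_map <- function(values, times = NULL, res = c(6, 6),
                      voxel = data.frame(x = 0, y = 0, slice = 1L, z = 0)) {
  d <- dim(values)
  if (length(d) == 3) dim(values) <- c(d, 1)
  d <- dim(values)
  if (is.null(times)) times <- seq_len(d[3])
  g <- list(dx = res[1] * (seq_len(d[1]) - 1 - floor(d[1] / 2)),
            dz = res[2] * (seq_len(d[2]) - 1 - floor(d[2] / 2)),
            res = res, fov = res * d[1:2])
  structure(list(values = as.complex(values) |> array(dim = d),
                 grid = g, frame = "relative", t1 = 1.584,
                 times = matrix(times, d[3], d[4]),
                 voxels = voxel, voxel_size = c(4, 4),
                 slice_thickness = 5),
            class = "source_map")
}

# stimulated-echo component extracted from a full acquisition
stim_of <- function(ensemble, protocol) {
  separate_echoes(acquire_series(ensemble, protocol))
}

# brute-force O(N^2) inverse-DFT oracle over the encoding grid
dft_oracle <- function(stim_vec, protocol) {
  g <- source_grid(protocol)
  K <- protocol$grid$encodings
  out <- matrix(0i, length(g$dx), length(g$dz))
  for (i in seq_along(g$dx)) for (j in seq_along(g$dz)) {
    acc <- 0i
    for (n in seq_len(nrow(K)))
      acc <- acc + stim_vec[n] * exp(-1i * (K[n, 1] * g$dx[i] +
                                              K[n, 2] * g$dz[j]))
    out[i, j] <- acc / nrow(K)
  }
  out
}
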