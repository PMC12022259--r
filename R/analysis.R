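# Downstream analyses of dynamic perfusion source maps: T1 correction,
# voxel-energy normalization, vessel detection, venous territories,
# arrival-time/delay maps, percent-change modulation maps, paired
# t-statistic maps, and mixing-time averaging for fast multi-slice data.
# All operations are pure: same inputs give bit-identical outputs.

#' Mixing-time signal series
#'
#' A nonnegative magnitude series at one source location (or ROI) over
#' ascending mixing times.
#' @param times mixing times (s), strictly increasing.
#' @param values magnitudes, same length as `times`.
#' @export
mixing_series <- function(times, values) {
  if (length(times) != length(values))
    stopf("times and values must have equal length")
  if (length(times) >= 2 && any(diff(times) <= 0))
    stopf("mixing times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "mixing_series")
}

#' Extract the magnitude series of one source bin
#' @param map a `source_map`; @param ix,iz bin indices; @param voxel voxel index.
#' @export
bin_series <- function(map, ix, iz, voxel = 1L) {
  mixing_series(map$times[, voxel], abs(map$values[ix, iz, , voxel]))
}

#' Correct a signal series (or map) for T1 decay
#'
#' Multiplies each mixing-time sample by `exp(t_mix / T1)`, undoing the
#' longitudinal relaxation of the tagged magnetization. Default T1 is the
#' blood value of 1.584 s.
#' @param x a `mixing_series` or `source_map`.
#' @param t1 longitudinal relaxation time, seconds (> 0).
#' @export
t1_correct <- function(x, t1 = 1.584) {
  if (!is_num1(t1) || t1 <= 0) stopf("T1 must be > 0")
  if (inherits(x, "mixing_series")) {
    x$values <- x$values * exp(x$times / t1)
  } else if (inherits(x, "source_map")) {
    d <- dim(x$values)
    for (v in seq_len(d[4]))
      x$values[, , , v] <- x$values[, , , v, drop = FALSE] *
        rep(exp(x$times[, v] / t1), each = d[1] * d[2])
  } else stopf("t1_correct expects a mixing_series or source_map")
  x
}

#' Total source-map energy of a target voxel
#'
#' "Overall energy of the image voxel": by default the sum of squared
#' source-map magnitudes over all bins and mixing times of that voxel
#' (`convention = "sumsq"`); `"summag"` uses the sum of magnitudes instead.
#' @param map a `source_map`; @param voxel voxel index;
#' @param convention "sumsq" (default) or "summag".
#' @export
voxel_energy <- function(map, voxel = 1L,
                         convention = c("sumsq", "summag")) {
  convention <- match.arg(convention)
  a <- abs(map$values[, , , voxel])
  if (convention == "sumsq") sum(a^2) else sum(a)
}

#' Normalize a series or map by a voxel's overall energy
#'
#' Divides the values by the target voxel's total source-map energy (see
#' [voxel_energy()]). When `energy` is omitted it is computed from `x`
#' itself (then `x` must be a `source_map`).
#' @param x a `mixing_series` or `source_map`.
#' @param energy the voxel energy; must be > 0.
#' @param convention energy convention, see [voxel_energy()].
#' @export
normalize_energy <- function(x, energy = NULL,
                             convention = c("sumsq", "summag")) {
  convention <- match.arg(convention)
  if (is.null(energy)) {
    if (!inherits(x, "source_map"))
      stopf("energy must be supplied for non-map inputs")
    energy <- voxel_energy(x, 1L, convention)
  }
  if (!is_num1(energy) || energy <= 0)
    stopf("zero energy: cannot normalize")
  x$values <- x$values / energy
  x
}

#' Detect vessel-containing image voxels from a source-energy image
#'
#' Flags 8-connected local maxima of the per-voxel source-map energy image
#' that exceed a fraction of the global maximum. Plateaus of equal
#' neighbours are flagged in full (no tie-breaking suppression).
#' @param energy numeric matrix (target-voxel grid).
#' @param frac detection threshold as a fraction of the global maximum,
#'   default 0.2.
#' @return data frame of flagged voxel indices (`i`, `j`) and `energy`.
#' @export
detect_vessel_voxels <- function(energy, frac = 0.2) {
  if (!is.matrix(energy)) energy <- matrix(energy, ncol = 1)
  nr <- nrow(energy); nc <- ncol(energy)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- energy
  is_max <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[2:(nr + 1) + di, 2:(nc + 1) + dj, drop = FALSE]
    is_max <- is_max & energy >= nb
  }
  thr <- frac * max(energy)
  hit <- which(is_max & energy >= thr & energy > 0, arr.ind = TRUE)
  data.frame(i = hit[, 1], j = hit[, 2],
             energy = energy[hit])
}

#' Venous territory mask
#'
#' The territory drained by a vessel is the maximum extent of its perfusion
#' sources across all mixing times: the union, over mixing times, of bins
#' whose magnitude reaches `threshold_frac` of that mixing time's maximum.
#' @param map a `source_map`; @param voxel voxel index;
#' @param threshold_frac per-mixing-time threshold fraction, default 0.1.
#' @return logical matrix over the source grid.
#' @export
territory_mask <- function(map, voxel = 1L, threshold_frac = 0.1) {
  a <- abs(map$values[, , , voxel, drop = FALSE])
  d <- dim(a)
  mask <- matrix(FALSE, d[1], d[2])
  for (j in seq_len(d[3])) {
    mj <- a[, , j, 1]
    mx <- max(mj)
    if (mx > 0) mask <- mask | (mj >= threshold_frac * mx)
  }
  mask
}

#' Blood arrival time of a mixing-time series
#'
#' Linearly interpolates the series to a `step`-spaced grid (default 15 ms)
#' spanning the sampled range and returns the earliest time at which the
#' signal reaches 50% of the interpolated series' maximum; the final
#' threshold crossing is resolved exactly within its grid interval (linear
#' refinement), so closed-form ramps return their analytic 50% time. Ties
#' break to the earliest grid index.
#' @param series a `mixing_series` (>= 2 samples).
#' @param step interpolation interval, seconds (default 0.015).
#' @param frac threshold fraction of the maximum, default 0.5.
#' @return seconds, or NA if the series is all zero.
#' @export
arrival_time <- function(series, step = 0.015, frac = 0.5) {
  if (length(series$times) < 2)
    stopf("arrival_time needs at least two samples")
  if (max(series$values) <= 0) return(NA_real_)
  t_max <- series$times[length(series$times)]
  grid <- seq(series$times[1], t_max, by = step)
  if (grid[length(grid)] < t_max) grid <- c(grid, t_max)
  v <- stats::approx(series$times, series$values, xout = grid)$y
  thr <- frac * max(v)
  i <- which(v >= thr)[1]
  if (i == 1L || v[i - 1] >= thr) return(grid[i])
  # refine to the exact linear crossing within the grid interval, so that
  # closed-form ramps yield their analytic 50% time
  grid[i - 1] + (thr - v[i - 1]) / (v[i] - v[i - 1]) * (grid[i] - grid[i - 1])
}

#' Arrival-time map of one target voxel
#'
#' Per-bin [arrival_time()] over the source grid, after optional T1
#' correction. Bins whose raw peak magnitude is below `floor_frac` of the
#' voxel's map maximum are masked (NA).
#' @param map a `source_map`; @param voxel voxel index;
#' @param t1 T1 for decay correction (s); NULL skips the correction.
#' @param floor_frac detection floor, fraction of the map maximum (0.05).
#' @param step interpolation interval (s).
#' @return list: `values` (matrix, s), `detected` (logical matrix), `grid`.
#' @export
arrival_map <- function(map, voxel = 1L, t1 = 1.584, floor_frac = 0.05,
                        step = 0.015) {
  a <- abs(map$values[, , , voxel, drop = FALSE])
  d <- dim(a)
  peak <- apply(a[, , , 1, drop = FALSE], c(1, 2), max)
  detected <- peak >= floor_frac * max(peak)
  times <- map$times[, voxel]
  corr <- if (is.null(t1)) rep(1, d[3]) else exp(times / t1)
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!detected[i, j]) next
    out[i, j] <- arrival_time(mixing_series(times, a[i, j, , 1] * corr),
                              step = step)
  }
  list(values = out, detected = detected, grid = map$grid)
}

#' Arrival-delay map between two states
#'
#' Per-bin difference of arrival times, `post - baseline` (e.g.
#' post-caffeine minus baseline). Bins below the detection floor in either
#' state are masked.
#' @param baseline,post single-voxel-comparable `source_map`s on matching
#'   grids and mixing times.
#' @param voxel voxel index; @param t1,floor_frac,step see [arrival_map()].
#' @return list: `values` (matrix, s), `detected`, `grid`.
#' @export
delay_map <- function(baseline, post, voxel = 1L, t1 = 1.584,
                      floor_frac = 0.05, step = 0.015) {
  check_matching_maps(baseline, post)
  a <- arrival_map(baseline, voxel, t1, floor_frac, step)
  b <- arrival_map(post, voxel, t1, floor_frac, step)
  detected <- a$detected & b$detected
  vals <- b$values - a$values
  vals[!detected] <- NA_real_
  list(values = vals, detected = detected, grid = baseline$grid)
}

check_matching_maps <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stopf("mismatched grids: source maps have different dimensions")
  if (max(abs(a$times - b$times)) > 1e-9)
    stopf("mismatched mixing times between states")
  invisible(TRUE)
}

#' Percent signal change between baseline and task
#'
#' Elementwise `(s_task - s_baseline) / s_baseline * 100` on source-map
#' magnitudes, per bin and mixing time. Bins whose baseline magnitude is
#' below the detection floor are masked (NA).
#' @param baseline,task `source_map`s on matching grids and mixing times.
#' @param voxel voxel index.
#' @param floor_frac detection floor as a fraction of the baseline map
#'   maximum, default 0.05.
#' @return list: `values` (array bins x times, percent), `detected`, `grid`,
#'   `times`.
#' @export
percent_change <- function(baseline, task, voxel = 1L, floor_frac = 0.05) {
  check_matching_maps(baseline, task)
  b <- abs(baseline$values[, , , voxel, drop = FALSE])
  s <- abs(task$values[, , , voxel, drop = FALSE])
  dim(b) <- dim(b)[1:3]
  dim(s) <- dim(s)[1:3]
  floor_val <- floor_frac * max(b)
  vals <- (s - b) / b * 100
  vals[b < floor_val] <- NA_real_
  list(values = vals, detected = b >= floor_val, grid = baseline$grid,
       times = baseline$times[, voxel])
}

#' Paired t-statistic map between baseline and task series
#'
#' For every source bin, compares the mixing-time signal series at baseline
#' and during task with a two-sided t-test (paired across matched mixing
#' times by default, since the series are matched by design) and returns
#' the t statistic, p-value, and the significance mask at `alpha`.
#' Zero-variance differences follow the signed-infinity convention
#' (t = +/-Inf, p = 0) unless the difference is identically zero
#' (t = 0, p = 1).
#'
#' @param baseline,task single-voxel `source_map`s or 3-D magnitude arrays
#'   (Delta x, Delta z, mixing time).
#' @param alpha significance threshold, default 0.05.
#' @param paired paired (default) or independent two-sample (Welch) test.
#' @param adjust "none" (default, mirroring uncorrected voxelwise maps) or
#'   "BH" for Benjamini-Hochberg adjustment of the significance mask.
#' @param voxel voxel index when maps are `source_map`s.
#' @return list: `t`, `p` (matrices), `sig` (logical matrix at `alpha`).
#' @export
ttest_maps <- function(baseline, task, alpha = 0.05, paired = TRUE,
                       adjust = c("none", "BH"), voxel = 1L) {
  adjust <- match.arg(adjust)
  as_arr <- function(x) {
    if (inherits(x, "source_map")) {
      a <- abs(x$values[, , , voxel, drop = FALSE])
      array(a, dim = dim(a)[1:3])
    } else x
  }
  b <- as_arr(baseline); s <- as_arr(task)
  if (!identical(dim(b), dim(s))) stopf("mismatched grids or mixing times")
  n <- dim(b)[3]
  if (n < 3) stopf("ttest_maps needs at least 3 paired mixing-time samples")
  d1 <- dim(b)[1]; d2 <- dim(b)[2]
  tmat <- matrix(0, d1, d2); pmat <- matrix(1, d1, d2)
  for (i in seq_len(d1)) for (j in seq_len(d2)) {
    x <- s[i, j, ]; y <- b[i, j, ]
    if (paired) {
      dd <- x - y
      sdd <- stats::sd(dd)
      if (sdd == 0) {
        if (mean(dd) == 0) { tmat[i, j] <- 0; pmat[i, j] <- 1 }
        else { tmat[i, j] <- sign(mean(dd)) * Inf; pmat[i, j] <- 0 }
      } else {
        tv <- mean(dd) / (sdd / sqrt(n))
        tmat[i, j] <- tv
        pmat[i, j] <- 2 * stats::pt(-abs(tv), df = n - 1)
      }
    } else {
      vx <- stats::var(x); vy <- stats::var(y)
      if (vx == 0 && vy == 0) {
        if (mean(x) == mean(y)) { tmat[i, j] <- 0; pmat[i, j] <- 1 }
        else { tmat[i, j] <- sign(mean(x) - mean(y)) * Inf; pmat[i, j] <- 0 }
      } else {
        se <- sqrt(vx / n + vy / n)
        tv <- (mean(x) - mean(y)) / se
        df <- se^4 / ((vx / n)^2 / (n - 1) + (vy / n)^2 / (n - 1))
        tmat[i, j] <- tv
        pmat[i, j] <- 2 * stats::pt(-abs(tv), df = df)
      }
    }
  }
  pcrit <- if (adjust == "BH") matrix(stats::p.adjust(pmat, "BH"), d1, d2)
           else pmat
  list(t = tmat, p = pmat, sig = pcrit < alpha)
}

#' Average source maps over consecutive mixing-time pairs
#'
#' Arithmetic mean of paired maps, labelled with the mean of the pair's
#' mixing times (e.g. 400 and 500 ms average to 450 ms). With the default
#' consecutive pairing, an odd leftover mixing time is passed through
#' unpaired.
#' @param map a `source_map`.
#' @param pairs optional list of index vectors to average; default pairs
#'   consecutive mixing times (1,2), (3,4), ...
#' @export
average_mixing_pairs <- function(map, pairs = NULL) {
  d <- dim(map$values)
  nt <- d[3]
  if (is.null(pairs)) {
    pairs <- lapply(seq_len(nt %/% 2), function(k) c(2 * k - 1, 2 * k))
    if (nt %% 2 == 1) pairs <- c(pairs, list(nt))
  }
  vals <- array(0i, dim = c(d[1], d[2], length(pairs), d[4]))
  times <- matrix(0, length(pairs), d[4])
  for (p in seq_along(pairs)) {
    idx <- pairs[[p]]
    sub <- map$values[, , idx, , drop = FALSE]
    vals[, , p, ] <- apply(sub, c(1, 2, 4), mean)
    times[p, ] <- colMeans(map$times[idx, , drop = FALSE])
  }
  map$values <- vals
  map$times <- times
  map
}
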