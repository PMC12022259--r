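# Downstream analyses: T1 correction, normalization, detection, territory,
# arrival/delay, percent change, t-maps, mixing-pair averaging.

test_that("T1 correction inverts decay and defaults to 1584 ms", {
  expect_equal(formals(t1_correct)$t1, 1.584)
  s <- mixing_series(c(0.1, 0.5, 1.2), c(2, 3, 4))
  expect_equal(t1_correct(s, 1e12)$values, s$values)   # factor ~1 at t1->Inf
  decayed <- mixing_series(s$times, s$values * exp(-s$times / 1.584))
  expect_equal(t1_correct(decayed)$values, s$values, tolerance = 1e-12)
  # factor is exactly 1 at t = 0
  s0 <- mixing_series(c(0, 1), c(5, 5))
  expect_equal(t1_correct(s0, 0.7)$values[1], 5)
  expect_error(t1_correct(s, t1 = -1), "T1 must be > 0")
  # map form: elementwise along the mixing-time axis
  m <- synth_map(array(1, dim = c(2, 2, 3, 1)), times = c(0.1, 0.4, 0.9))
  mc <- t1_correct(m, 1.584)
  expect_equal(Re(mc$values[1, 1, , 1]), exp(c(0.1, 0.4, 0.9) / 1.584))
})

test_that("energy normalization follows the sum-of-squares convention", {
  m <- synth_map(array(1, dim = c(2, 2, 2, 1)))
  expect_equal(voxel_energy(m), 8)
  nm <- normalize_energy(m)
  expect_equal(Re(nm$values), array(1 / 8, dim = c(2, 2, 2, 1)))
  # sum-of-magnitudes convention is scale invariant
  m2 <- m; m2$values <- m2$values * 5
  expect_equal(normalize_energy(m2, convention = "summag")$values,
               normalize_energy(m, convention = "summag")$values)
  z <- synth_map(array(0, dim = c(2, 2, 2, 1)))
  expect_error(normalize_energy(z), "zero energy")
})

test_that("vessel detection flags local maxima, ties, and plateaus", {
  e <- matrix(0, 5, 5); e[2, 3] <- 1
  d <- detect_vessel_voxels(e)
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$i, d$j), c(2L, 3L))
  # two equal peaks, both returned
  e2 <- matrix(0, 5, 5); e2[2, 2] <- 1; e2[4, 4] <- 1
  expect_equal(nrow(detect_vessel_voxels(e2)), 2L)
  # random fields against an exhaustive neighbourhood-scan oracle
  set.seed(42)
  for (rep in 1:5) {
    e3 <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
    got <- detect_vessel_voxels(e3, frac = 0.2)
    oracle <- list()
    for (i in 1:6) for (j in 1:6) {
      if (e3[i, j] <= 0 || e3[i, j] < 0.2 * max(e3)) next
      ok <- TRUE
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= 6 && jj >= 1 && jj <= 6 &&
              e3[ii, jj] > e3[i, j]) ok <- FALSE
      }
      if (ok) oracle[[length(oracle) + 1]] <- c(i, j)
    }
    expect_equal(nrow(got), length(oracle))
    expect_setequal(paste(got$i, got$j),
                    vapply(oracle, function(x) paste(x[1], x[2]), ""))
  }
})

# helper: single mixing-time view of a map
subset_voxel_time <- function(m, j) {
  m$values <- m$values[, , j, , drop = FALSE]
  m$times <- m$times[j, , drop = FALSE]
  m
}

test_that("territory mask is the union of per-time suprathreshold sets", {
  a <- array(0, dim = c(4, 4, 2, 1))
  a[1, 1, 1, 1] <- 1; a[2, 2, 1, 1] <- 0.05      # below 10% of max at t1
  a[4, 4, 2, 1] <- 2; a[3, 3, 2, 1] <- 0.5
  m <- synth_map(a)
  single <- territory_mask(subset_voxel_time(m, 1))
  expect_true(single[1, 1] && !single[2, 2])
  both <- territory_mask(m)
  expect_true(both[1, 1] && both[4, 4] && both[3, 3])
  # union monotonicity: adding mixing times never removes bins
  expect_true(all(both[single]))
})

test_that("territory of the y-phantom trunk voxel covers both feeding branches", {
  # noiseless on-grid acquisition; territory mask vs the spin-trajectory
  # occupancy oracle (Dice >= 0.9), and both branches are represented
  fx <- make_fixture("y_tree", seed = 1, snap_displacements = TRUE)
  ens <- fixture_ensemble(fx)
  proto <- fx$protocol
  proto$voxels <- data.frame(x = 0, y = 0, slice = 1L)
  sig <- acquire_series(ens, proto)
  maps <- reconstruct_source_maps(separate_echoes(sig), proto, sig$times)
  terr <- territory_mask(maps, 1)
  g <- source_grid(proto)
  sat <- dispectr:::saturated_at_tagging(ens, proto$sat_bands)
  kt <- dispectr:::imaging_kill_times(ens, proto)
  vox <- list(x = 0, y = 0, z = 0, size = proto$voxel_size,
              thickness = proto$slice_thickness)
  occ <- occupancy_mask(ens, vox, proto$mixing_times, g,
                        include = !sat, kill_time = kt)
  dice <- 2 * sum(terr & occ) / (sum(terr) + sum(occ))
  expect_gte(dice, 0.9)
  # branch sources appear on both sides of the trunk axis
  expect_true(any(terr[g$dx < 0, ]) && any(terr[g$dx > 0, ]))
})

test_that("arrival time: 50% of interpolated max on a 15 ms grid", {
  ramp <- mixing_series(seq(0, 1, by = 0.1), seq(0, 1, by = 0.1))
  expect_equal(arrival_time(ramp), 0.5)
  delayed <- mixing_series(seq(0, 1.3, by = 0.1),
                           pmax(0, seq(0, 1.3, by = 0.1) - 0.3))
  expect_equal(arrival_time(delayed), 0.8)
  expect_equal(arrival_time(delayed) - arrival_time(ramp), 0.3)
  # dense-interpolation oracle at 1 ms
  dense <- arrival_time(delayed, step = 0.001)
  expect_lte(abs(dense - 0.8), 0.015)
  # constant positive series -> first grid point
  const <- mixing_series(c(0.2, 0.5, 0.9), c(3, 3, 3))
  expect_equal(arrival_time(const), 0.2)
  expect_true(is.na(arrival_time(mixing_series(c(0, 1), c(0, 0)))))
  expect_error(arrival_time(mixing_series(1, 2)), "at least two")
})

test_that("delay map: zeros for identical states, floor-masked bins are NA", {
  a <- array(0, dim = c(3, 3, 5, 1))
  times <- seq(0.1, 0.9, by = 0.2)
  a[2, 2, , 1] <- c(0, 0.2, 0.6, 1, 1)
  a[1, 1, , 1] <- c(0, 0, 0.01, 0.02, 0.02)   # below 5% floor
  m <- synth_map(a, times = times)
  dm <- delay_map(m, m)
  expect_equal(dm$values[2, 2], 0)
  expect_true(is.na(dm$values[1, 1]))
  expect_false(dm$detected[1, 1])
  b <- a; b2 <- synth_map(b, times = times + 0.05)
  expect_error(delay_map(m, b2), "mismatched mixing times")
})

test_that("percent change matches the elementwise formula", {
  set.seed(7)
  base <- array(runif(3 * 3 * 4, 1, 2), dim = c(3, 3, 4, 1))
  task <- array(runif(3 * 3 * 4, 1, 2), dim = c(3, 3, 4, 1))
  mb <- synth_map(base); mt <- synth_map(task)
  pc <- percent_change(mb, mt, floor_frac = 0)
  # independent elementwise loop oracle
  for (i in 1:3) for (j in 1:3) for (t in 1:4)
    expect_equal(pc$values[i, j, t],
                 (task[i, j, t, 1] - base[i, j, t, 1]) / base[i, j, t, 1] * 100)
  expect_true(all(percent_change(mb, mb)$values[!is.na(percent_change(mb, mb)$values)] == 0))
  m2 <- synth_map(2 * base)
  pc2 <- percent_change(mb, m2, floor_frac = 0)
  expect_equal(max(abs(pc2$values - 100)), 0, tolerance = 1e-12)
})

test_that("paired t maps match the textbook formula and edge conventions", {
  a <- array(0, dim = c(1, 1, 5))
  b <- a
  a[1, 1, ] <- c(1.0, 1.25, 0.875, 1.5, 1.125)   # binary-exact values
  b[1, 1, ] <- a[1, 1, ] + c(0.2, 0.25, 0.15, 0.22, 0.18)
  tt <- ttest_maps(a, b)
  d <- b[1, 1, ] - a[1, 1, ]
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(tt$t[1, 1], t_oracle, tolerance = 1e-12)
  expect_equal(tt$p[1, 1], 2 * pt(-abs(t_oracle), 4), tolerance = 1e-12)
  expect_true(tt$sig[1, 1])
  # identical series: t = 0, p = 1
  t0 <- ttest_maps(a, a)
  expect_equal(t0$t[1, 1], 0); expect_equal(t0$p[1, 1], 1)
  # zero-variance nonzero difference: signed infinity, p = 0
  shift <- a; shift[1, 1, ] <- a[1, 1, ] + 0.5
  ti <- ttest_maps(a, shift)
  expect_equal(ti$t[1, 1], Inf); expect_equal(ti$p[1, 1], 0)
  expect_error(ttest_maps(a[, , 1:2, drop = FALSE], b[, , 1:2, drop = FALSE]),
               "at least 3")
  expect_equal(formals(ttest_maps)$alpha, 0.05)
})

test_that("mixing-pair averaging labels pairs by their mean time", {
  a <- array(0i, dim = c(2, 2, 5, 1))
  for (j in 1:5) a[, , j, 1] <- j
  m <- synth_map(a, times = c(0.4, 0.5, 0.8, 0.9, 1.2))
  av <- average_mixing_pairs(m)
  expect_equal(dim(av$values)[3], 3L)
  expect_equal(av$times[, 1], c(0.45, 0.85, 1.2))   # 400&500 -> 450 ms
  expect_equal(Re(av$values[1, 1, , 1]), c(1.5, 3.5, 5))
  # pair of identical maps is unchanged at the mean time
  m2 <- synth_map(array(7, dim = c(2, 2, 2, 1)), times = c(1, 2))
  av2 <- average_mixing_pairs(m2)
  expect_equal(Re(av2$values[, , 1, 1]), matrix(7, 2, 2))
  expect_equal(av2$times[1, 1], 1.5)
})

test_that("multi-slice combination places disjoint slices without double counting", {
  vals1 <- array(1 + 0i, dim = c(2, 2, 2, 1))
  vals2 <- array(2 + 0i, dim = c(2, 2, 2, 1))
  m1 <- synth_map(vals1, voxel = data.frame(x = 0, y = 0, slice = 1L, z = 18))
  m2 <- synth_map(vals2, voxel = data.frame(x = 0, y = 0, slice = 2L, z = 0))
  a1 <- to_absolute(m1); a2 <- to_absolute(m2)
  comb <- combine_multislice(list(a1, a2))
  # offsets consistent with 18 mm slice spacing: z axes are 18 mm apart
  expect_equal(a1$grid$dz - a2$grid$dz, rep(18, 2))
  # union grid spans both, supports are disjoint, values purely additive
  expect_equal(dim(comb$values)[2], 5L)   # z bins: 0-18 mm span at 6 mm
  expect_equal(sum(Re(comb$values[, , 1, 1])), 4 * 1 + 4 * 2)
  expect_equal(combine_multislice(list(a1))$values, a1$values)
})
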