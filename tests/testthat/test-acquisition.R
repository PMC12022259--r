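# Tagging, signal model, encoding-grid arithmetic, and acquisition.

test_that("cosine tagging follows cos(k.r0 + phi) with saturation nulling", {
  ens <- point_ensemble(rbind(c(0, 0, 30), c(3, 0, 40), c(0, 0, 1)))
  expect_equal(tag(ens, c(0, 0), 0), c(1, 1, 1))
  # k.r0 = pi/2 -> m = 0: k = (pi/6, 0) on the spin at x = 3
  m <- tag(ens, c(pi / 6, 0), 0)
  expect_equal(m[2], 0)
  expect_equal(m[1], 1)
  # saturation slab around the slice nulls the near-slice spin
  m2 <- tag(ens, c(0, 0), 0, sat_bands = data.frame(z = 0, thickness = 30))
  expect_equal(m2, c(1, 1, 0))
  # default protocol phases step by 120 degrees
  expect_equal(acq_protocol()$phase_cycle, c(0, 2 * pi / 3, 4 * pi / 3))
})

test_that("voxel_signal: closed forms for static and displaced spins", {
  p <- point_protocol(mixing_times = 1)
  # single static unsaturated spin, k = 0, phi = 0, no FID, T1 -> Inf:
  # both echoes coherent, S = 1/2 + 1/2 = 1
  ens <- point_ensemble(c(0.5, 0, 0.5))
  s <- voxel_signal(ens, c(0, 0), 0, 1, list(x = 0, y = 0, slice = 1L), p)
  expect_equal(s, 1 + 0i, tolerance = 1e-8)   # T1 = 1e9 s, not infinite
  # T1 decay scales the tagged echoes by exp(-t/T1)
  p2 <- point_protocol(mixing_times = 1, t1 = 1)
  s2 <- voxel_signal(ens, c(0, 0), 0, 1, list(x = 0, y = 0, slice = 1L), p2)
  expect_equal(Re(s2), exp(-1), tolerance = 1e-12)
  # voxel referencing a nonexistent slice
  expect_error(
    voxel_signal(ens, c(0, 0), 0, 1, list(x = 0, y = 0, slice = 3L), p),
    "geometry error")
})

test_that("two spins at Delta r = +/-6 mm give stimulated term -exp(-t/T1)", {
  # spins move along -/+x at 6 mm/s; at t = 1 s displacements are +/-6 mm
  ens <- point_ensemble(rbind(c(-3, 0, 0), c(3, 0, 0)),
                        dirs = rbind(c(1, 0, 0), c(-1, 0, 0)), speeds = 6)
  t1 <- 2
  p <- point_protocol(mixing_times = 1, t1 = t1,
                      source_fov = c(24, 24))
  k <- c(pi / 6, 0)
  # separate the stimulated echo via the three-point cycle
  phis <- p$phase_cycle
  S <- vapply(phis, function(phi)
    voxel_signal(ens, k, phi, 1, list(x = 0, y = 0, slice = 1L), p), 0i)
  stim <- mean(S * exp(-1i * phis))
  expect_equal(stim, complex(real = -exp(-1 / t1)), tolerance = 1e-12)
})

test_that("protocol_from_fov reproduces the published grid arithmetic", {
  g <- protocol_from_fov(c(132, 84), c(6, 6))
  expect_equal(nrow(g$encodings), 308L)            # 22 x 14
  expect_equal(g$nx, 22L); expect_equal(g$nz, 14L)
  expect_equal(diff(g$kx)[1], 2 * pi / 132)
  expect_equal(max(abs(g$kx)), pi / 6)             # k_max = pi / res
  # degenerate grid: FOV = res -> single DC encoding
  g1 <- protocol_from_fov(c(6, 6), c(6, 6))
  expect_equal(nrow(g1$encodings), 1L)
  expect_equal(unname(g1$encodings[1, ]), c(0, 0))
  # Fourier reciprocity: doubling the step (halving FOV) halves the FOV
  g2 <- protocol_from_fov(c(66, 42), c(6, 6))
  expect_equal(diff(g2$kx)[1], 2 * diff(g$kx)[1])
  expect_error(protocol_from_fov(c(6, 6), c(12, 12)), "cannot exceed")
})

test_that("protocol invariants are enforced", {
  expect_error(acq_protocol(mixing_times = c(0.3, 0.2)), "strictly increasing")
  expect_error(acq_protocol(mixing_times = c(0, 1)), "strictly increasing")
  expect_error(acq_protocol(mixing_times = c(1, 4)), "repetition window")
  expect_error(acq_protocol(phase_cycle = c(0, pi)), "phase cycling")
  expect_error(acq_protocol(voxels = data.frame(x = 0, y = 0, slice = 2L)),
               "geometry error")
})

test_that("acquisition is deterministic and phase-cycle structure holds", {
  fx <- make_fixture("y_tree", seed = 4, noise_sigma = 0.05)
  fx$protocol$mixing_times <- c(0.4, 1.0)
  fx$protocol$voxels <- data.frame(x = 0, y = 0, slice = 1L)
  ens <- fixture_ensemble(fx)
  s1 <- acquire_series(ens, fx$protocol)
  s2 <- acquire_series(ens, fx$protocol)
  expect_identical(s1$values, s2$values)
  # phi-Fourier content: exactly the e^{+i phi}, e^{-i phi}, const terms;
  # reconstruct each and re-synthesize the three raw phase samples
  fx0 <- make_fixture("y_tree", seed = 4)
  fx0$protocol$mixing_times <- c(0.4, 1.0)
  fx0$protocol$voxels <- data.frame(x = 0, y = 0, slice = 1L)
  sig <- acquire_series(fixture_ensemble(fx0), fx0$protocol)
  phis <- fx0$protocol$phase_cycle
  for (n in c(1L, 7L)) for (j in 1:2) {
    S <- sig$values[n, , j, 1]
    a <- mean(S * exp(-1i * phis))
    b <- mean(S * exp(+1i * phis))
    cc <- mean(S)
    expect_equal(a * exp(1i * phis) + b * exp(-1i * phis) + cc, S,
                 tolerance = 1e-10)
  }
})

test_that("stimulated echo is Hermitian in k and anchored at k = 0", {
  fx <- make_fixture("y_tree", seed = 9)
  fx$protocol$mixing_times <- c(0.7)
  fx$protocol$voxels <- data.frame(x = 0, y = 0, slice = 1L)
  ens <- fixture_ensemble(fx)
  sig <- acquire_series(ens, fx$protocol)
  stim <- separate_echoes(sig)
  K <- fx$protocol$grid$encodings
  # S(-k) == conj(S(k)) for the real-tagged, noiseless stimulated echo
  for (n in sample(nrow(K), 8)) {
    mirr <- which(abs(K[, 1] + K[n, 1]) < 1e-12 &
                    abs(K[, 2] + K[n, 2]) < 1e-12)
    if (!length(mirr)) next
    expect_equal(stim[mirr, 1, 1], Conj(stim[n, 1, 1]), tolerance = 1e-9)
  }
  # k = 0 sample equals the total decayed tagged magnetization in the voxel
  dc <- which(K[, 1] == 0 & K[, 2] == 0)
  sat <- dispectr:::saturated_at_tagging(ens, fx$protocol$sat_bands)
  kt <- dispectr:::imaging_kill_times(ens, fx$protocol)
  pos <- advect(ens, 0.7)
  inside <- abs(pos[, 1]) <= 2 & abs(pos[, 2]) <= 2 & abs(pos[, 3]) <= 2.5 &
    kt >= 0.7 & !sat
  expected <- 0.5 * exp(-0.7 / fx$protocol$t1) * sum(ens$spins$m0[inside])
  expect_equal(stim[dc, 1, 1], complex(real = expected), tolerance = 1e-9)
})

test_that("saturated spins contribute exactly zero at all mixing times", {
  # all spins inside the saturation slab -> stimulated echo identically 0
  ens <- point_ensemble(rbind(c(0, 0, 1), c(1, 0, -1)), speeds = 1e-9)
  p <- acq_protocol(source_fov = c(24, 24), source_res = c(6, 6),
                    mixing_times = c(0.5, 1.5),
                    sat_bands = data.frame(z = 0, thickness = 30),
                    voxels = data.frame(x = 0, y = 0, slice = 1L),
                    voxel_size = c(10, 10), slice_thickness = 10,
                    fid_scale = 0, consume_on_imaging = FALSE)
  stim <- separate_echoes(acquire_series(ens, p))
  expect_true(all(abs(stim) < 1e-12))
})

test_that("ensemble-factory path (jittered gating) matches the fast path when static", {
  fx <- make_fixture("y_tree", seed = 6)
  fx$protocol$mixing_times <- c(0.5)
  fx$protocol <- acq_protocol(source_fov = c(12, 12), source_res = c(6, 6),
                              mixing_times = 0.5,
                              sat_bands = fx$protocol$sat_bands,
                              voxels = data.frame(x = 0, y = 0, slice = 1L))
  ens <- fixture_ensemble(fx)
  fast <- acquire_series(ens, fx$protocol)
  slow <- acquire_series(function(rep) ens, fx$protocol)
  expect_equal(fast$values, slow$values, tolerance = 1e-12)
})
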