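# Seeded fixture generator: small deterministic phantom + protocol
# configurations that exercise every pipeline stage without external data.
#
# "y_tree"      two branches converging on a trunk that crosses the slice
#               (the canonical converging superior-vein geometry).
# "two_trees"   two independent straight veins, a control and an "activated"
#               one whose task state carries 20% more inflow magnetization.
# "deep_source" one long fast vessel whose sources extend ~15 cm upstream.
# "multislice"  three imaging slices 18 mm apart, imaged cyclically every
#               100 ms with a 33 ms inter-slice gap; imaging at each slice
#               consumes tagged blood so downstream slices see a reduced
#               source FOV.

#' Deterministic test fixtures
#'
#' @param name one of "y_tree", "two_trees", "deep_source", "multislice".
#' @param seed integer seed controlling spin seeding and the noise stream.
#' @param noise_sigma per-sample complex-noise std. dev. (default 0).
#' @param task if TRUE (two_trees only), the activated tree's inflow
#'   magnetization is raised by 20% (task state); baseline otherwise.
#' @param speed_scale global flow-speed multiplier applied to all phantoms
#'   (e.g. 0.8 for a caffeine-style slowdown).
#' @param snap_displacements validation mode of [acq_protocol()].
#' @param flow_profile velocity profile of the phantoms; fixtures default
#'   to "laminar" so that per-bin mixing-time series are temporally
#'   extended (plug flow collapses each vessel's sources onto a single
#'   sweeping displacement, which starves arrival-time and t-test analyses
#'   of usable samples).
#' @return list with elements `name`, `phantoms` (list of [phantom_spec()]),
#'   and `protocol` (an [acq_protocol()]).
#' @export
make_fixture <- function(name = c("y_tree", "two_trees", "deep_source",
                                  "multislice"),
                         seed = 1L, noise_sigma = 0, task = FALSE,
                         speed_scale = 1, snap_displacements = FALSE,
                         flow_profile = "laminar") {
  name <- match.arg(name)
  seed <- as.integer(seed)
  fx <- switch(
    name,
    y_tree = list(
      phantoms = list(phantom_spec(
        n_branches = 2L, branch_length = 40, branch_speed = 10,
        branch_radius = 2, branch_angle = 30,
        trunk_top = 30, trunk_bottom = -15, trunk_speed = 20,
        trunk_radius = 3, root = c(0, 0),
        tissue_extent = 20, tissue_speed = 0.5, tissue_radius = 4,
        tissue_density = 0.5, spin_density = 2,
        speed_scale = speed_scale, flow_profile = flow_profile,
        seed = seed)),
      protocol = acq_protocol(
        source_fov = c(48, 168), source_res = c(6, 6),
        mixing_times = seq(0.1, by = 0.15, length.out = 19),
        slices = data.frame(z = 0), slice_thickness = 5,
        sat_bands = data.frame(z = 0, thickness = 30),
        voxels = transform(expand.grid(x = c(-4, 0, 4), y = c(-4, 0, 4),
                                       KEEP.OUT.ATTRS = FALSE), slice = 1L),
        voxel_size = c(4, 4),
        noise_sigma = noise_sigma,
        snap_displacements = snap_displacements, seed = seed)),
    two_trees = {
      mk <- function(x, scale) phantom_spec(
        n_branches = 1L, branch_length = 30, branch_speed = 10,
        branch_radius = 2, branch_angle = 0,
        trunk_top = 20, trunk_bottom = -10, trunk_speed = 15,
        trunk_radius = 2.5, root = c(x, 0),
        tissue_extent = 15, tissue_speed = 0.5, tissue_radius = 3,
        tissue_density = 0.5, spin_density = 2,
        inflow_scale = scale, speed_scale = speed_scale,
        flow_profile = flow_profile,
        seed = seed + if (x < 0) 0L else 1L)
      list(
        phantoms = list(activated = mk(-30, if (task) 1.2 else 1),
                        control = mk(30, 1)),
        protocol = acq_protocol(
          source_fov = c(24, 156), source_res = c(6, 6),
          mixing_times = seq(0.1, by = 0.15, length.out = 19),
          slices = data.frame(z = 0), slice_thickness = 5,
          sat_bands = data.frame(z = 0, thickness = 30),
          voxels = data.frame(x = c(-30, 30), y = 0, slice = 1L),
          voxel_size = c(4, 4),
          noise_sigma = noise_sigma,
          snap_displacements = snap_displacements, seed = seed))
    },
    deep_source = list(
      phantoms = list(phantom_spec(
        n_branches = 1L, branch_length = 130, branch_speed = 60,
        branch_radius = 2.5, branch_angle = 0,
        trunk_top = 30, trunk_bottom = -15, trunk_speed = 60,
        trunk_radius = 3, root = c(0, 0),
        tissue_extent = 20, tissue_speed = 0.5, tissue_radius = 4,
        tissue_density = 0.3, spin_density = 1.5,
        speed_scale = speed_scale, flow_profile = flow_profile,
        seed = seed)),
      protocol = acq_protocol(
        source_fov = c(12, 360), source_res = c(6, 6),
        mixing_times = seq(0.1, by = 0.15, length.out = 19),
        slices = data.frame(z = 0), slice_thickness = 5,
        sat_bands = data.frame(z = 0, thickness = 30),
        voxels = data.frame(x = 0, y = 0, slice = 1L),
        voxel_size = c(4, 4),
        noise_sigma = noise_sigma,
        snap_displacements = snap_displacements, seed = seed)),
    multislice = list(
      phantoms = list(phantom_spec(
        n_branches = 1L, branch_length = 30, branch_speed = 15,
        branch_radius = 2.5, branch_angle = 0,
        trunk_top = 60, trunk_bottom = -15, trunk_speed = 15,
        trunk_radius = 3, root = c(0, 0),
        tissue_extent = 15, tissue_speed = 0.5, tissue_radius = 4,
        tissue_density = 0.5, spin_density = 2,
        speed_scale = speed_scale, flow_profile = flow_profile,
        seed = seed)),
      protocol = acq_protocol(
        source_fov = c(36, 60), source_res = c(6, 6),
        mixing_times = seq(0.1, 1.9, by = 0.1),
        slices = data.frame(z = c(36, 18, 0)),   # 18 mm spacing, top first
        slice_thickness = 4,
        sat_bands = data.frame(z = c(36, 18, 0), thickness = 6),
        voxels = data.frame(x = 0, y = 0, slice = 1:3),
        voxel_size = c(4, 4),
        slice_gap = 0.033,
        noise_sigma = noise_sigma,
        snap_displacements = snap_displacements, seed = seed))
  )
  fx$name <- name
  fx$seed <- seed
  fx
}

#' Build the merged spin ensemble of a fixture
#' @param fixture a [make_fixture()] result.
#' @export
fixture_ensemble <- function(fixture) {
  trees <- lapply(fixture$phantoms, build_vessel_tree)
  if (length(trees) == 1L) return(seed_spins(trees[[1]]))
  forest <- do.call(merge_vessel_trees, trees)
  seed_spins(forest, lapply(fixture$phantoms, identity))
}
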