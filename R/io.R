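# Standard-format I/O.
#
# Image-like outputs are written as uncompressed NIfTI-1 (.nii, float64)
# with a JSON sidecar carrying grid metadata. No NIfTI package exists in
# the target R environment, so a minimal self-contained codec for the
# NIfTI-1 single-file format is implemented here (little-endian, float64
# data, sform affine only); it is cross-checked against nibabel in the test
# suite. Configurations are JSON (mm / ms / degrees in files; seconds and
# radians internally). Encoded signals are persisted as CSV + JSON sidecar.

NIFTI_DT_FLOAT64 <- 64L

#' Write a volume as NIfTI-1
#'
#' Writes an up-to-7-D numeric array as an uncompressed little-endian
#' single-file NIfTI-1 (.nii) with float64 data, a diagonal sform affine in
#' mm, and (optionally) a JSON sidecar next to it.
#'
#' @param vol numeric array.
#' @param path output path, extension `.nii`.
#' @param pixdim grid spacings per array dimension (mm or s), recycled.
#' @param origin spatial origin (mm), length 3.
#' @param sidecar optional named list written to `<path minus .nii>.json`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, pixdim = 1, origin = c(0, 0, 0),
                        sidecar = NULL) {
  dims <- dim(vol)
  if (is.null(dims)) dims <- length(vol)
  if (length(dims) > 7) stopf("NIfTI-1 supports at most 7 dimensions")
  dim16 <- integer(8)
  dim16[1] <- length(dims)
  dim16[1 + seq_along(dims)] <- dims
  dim16[dim16 == 0] <- 1L
  pix <- rep_len(as.numeric(pixdim), length(dims))
  pixdim8 <- c(1, pix, rep(1, 7 - length(dims)))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(n - length(raw))), con)
  }
  wi(348, 4)                       # sizeof_hdr
  wc("", 10); wc("", 18)           # data_type, db_name
  wi(0, 4); wi(0, 2); wc("r", 1); wc("", 1)  # extents/session_error/regular/dim_info
  wi(dim16, 2)                     # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)         # intent_p1..3, intent_code
  wi(NIFTI_DT_FLOAT64, 2); wi(64, 2); wi(0, 2)  # datatype, bitpix, slice_start
  wf(pixdim8)                      # pixdim[8] (qfac first)
  wf(352); wf(1); wf(0)            # vox_offset, scl_slope, scl_inter
  wi(0, 2); wc("", 1); wc("", 1)   # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0, 0), 4)                   # glmax, glmin
  wc("dispectr", 80); wc("", 24)   # descrip, aux_file
  wi(0, 2); wi(1, 2)               # qform_code, sform_code
  wf(c(0, 0, 0)); wf(c(0, 0, 0))   # quatern_b/c/d, qoffset_x/y/z
  sx <- c(pixdim8[2], 0, 0, origin[1])
  sy <- c(0, pixdim8[3], 0, origin[2])
  sz <- c(0, 0, pixdim8[4], origin[3])
  wf(sx); wf(sy); wf(sz)           # srow_x/y/z
  wc("", 16)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)            # extension flag (none)
  writeBin(as.numeric(vol), con, size = 8, endian = "little")
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a NIfTI-1 volume written by [write_nifti()]
#'
#' Minimal reader for uncompressed little-endian single-file NIfTI-1 with
#' float64 data. Returns the array, grid spacings, origin, and the parsed
#' JSON sidecar when present. If a sidecar declares `dim`, it is validated
#' against the array dimensions.
#' @param path a `.nii` file.
#' @return list: `data`, `pixdim`, `origin`, `sidecar`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", 352)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = "little")
  if (ri(0, 4) != 348) stopf("not a NIfTI-1 file (bad header size): %s", path)
  if (!identical(rawToChar(hdr[345:347]), "n+1"))
    stopf("not a single-file NIfTI-1 (magic mismatch): %s", path)
  dt <- ri(70, 2)
  if (dt != NIFTI_DT_FLOAT64)
    stopf("unsupported NIfTI datatype %d (only float64 is handled)", dt)
  dim16 <- ri(40, 2, 8)
  nd <- dim16[1]
  dims <- dim16[2:(1 + nd)]
  pixdim <- rf(76, 8)[2:(1 + nd)]
  vox_offset <- rf(108)
  seek(con, vox_offset)
  data <- readBin(con, "numeric", n = prod(dims), size = 8, endian = "little")
  dim(data) <- dims
  origin <- c(rf(280, 4)[4], rf(296, 4)[4], rf(312, 4)[4])
  sc <- sidecar_path(path)
  sidecar <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE)
             else NULL
  if (!is.null(sidecar$dim) && !identical(as.integer(sidecar$dim),
                                          as.integer(dims)))
    stopf("sidecar/array dimension mismatch for %s", path)
  list(data = data, pixdim = pixdim, origin = origin, sidecar = sidecar)
}

#' Write a source map as NIfTI + JSON sidecar
#'
#' Data layout: 5-D float64 array (Delta x, Delta z, mixing time, voxel,
#' re/im). The sidecar records the grid (FOV/res in mm), frame, T1 (ms),
#' mixing times (ms, per voxel), voxel table, and the axis convention.
#' @param map a `source_map`; @param path output `.nii` path.
#' @export
write_source_map <- function(map, path) {
  d <- dim(map$values)
  vol <- array(0, dim = c(d, 2))
  vol[, , , , 1] <- Re(map$values)
  vol[, , , , 2] <- Im(map$values)
  sc <- list(
    format = "dispectr.source_map",
    dim = c(d, 2L),
    axes = c("dx", "dz", "mixing_time", "voxel", "re_im"),
    source_fov_mm = map$grid$fov,
    source_res_mm = map$grid$res,
    dx_mm = map$grid$dx, dz_mm = map$grid$dz,
    frame = map$frame,
    origin_mm = if (!is.null(map$origin)) map$origin else NULL,
    t1_ms = map$t1 * 1000,
    mixing_times_ms = 1000 * map$times,
    voxels = map$voxels,
    voxel_size_mm = map$voxel_size,
    slice_thickness_mm = map$slice_thickness,
    encoding_order = "row-major over (k_x, k_z), k_x fastest, DC at centre")
  write_nifti(vol, path, pixdim = c(map$grid$res, 1, 1, 1), sidecar = sc)
}

#' Read a source map written by [write_source_map()]
#' @param path the `.nii` path.
#' @export
read_source_map <- function(path) {
  x <- read_nifti(path)
  sc <- x$sidecar
  if (is.null(sc) || !identical(sc$format, "dispectr.source_map"))
    stopf("%s is not a dispectr source map (missing/foreign sidecar)", path)
  d <- dim(x$data)
  vals <- array(complex(real = x$data[seq_len(prod(d[1:4]))],
                        imaginary = x$data[prod(d[1:4]) + seq_len(prod(d[1:4]))]),
                dim = d[1:4])
  times <- matrix(as.numeric(sc$mixing_times_ms) / 1000, d[3], d[4])
  structure(list(values = vals,
                 grid = list(dx = as.numeric(sc$dx_mm),
                             dz = as.numeric(sc$dz_mm),
                             res = as.numeric(sc$source_res_mm),
                             fov = as.numeric(sc$source_fov_mm)),
                 frame = sc$frame,
                 origin = if (!is.null(sc$origin_mm)) as.numeric(sc$origin_mm),
                 t1 = as.numeric(sc$t1_ms) / 1000,
                 times = times,
                 voxels = as.data.frame(sc$voxels),
                 voxel_size = as.numeric(sc$voxel_size_mm),
                 slice_thickness = as.numeric(sc$slice_thickness_mm)),
            class = "source_map")
}

#' Persist an encoded signal as CSV + JSON sidecar
#'
#' Long-format CSV (columns: encoding, phase, time_index, voxel, re, im)
#' plus a JSON sidecar holding the full protocol, so the dataset is
#' reproducible and bit-interpretable without the R session.
#' @param sig an `encoded_signal`; @param path output `.csv` path.
#' @export
write_signal <- function(sig, path) {
  d <- dim(sig$values)
  idx <- expand.grid(encoding = seq_len(d[1]), phase = seq_len(d[2]),
                     time_index = seq_len(d[3]), voxel = seq_len(d[4]),
                     KEEP.OUT.ATTRS = FALSE)
  idx$re <- Re(as.vector(sig$values))
  idx$im <- Im(as.vector(sig$values))
  utils::write.csv(idx, path, row.names = FALSE)
  jsonlite::write_json(
    c(protocol_to_list(sig$protocol),
      list(times_s = sig$times, dim = d, format = "dispectr.encoded_signal")),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an encoded signal written by [write_signal()]
#' @param path the `.csv` path.
#' @export
read_signal <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  df <- df[order(df$voxel, df$time_index, df$phase, df$encoding), ]
  vals <- array(complex(real = df$re, imaginary = df$im), dim = d)
  structure(list(values = vals,
                 times = matrix(as.numeric(meta$times_s), d[3], d[4]),
                 protocol = protocol_from_list(meta)),
            class = "encoded_signal")
}

# protocol <-> plain list with file units (mm, ms, degrees)
protocol_to_list <- function(p) {
  list(source_fov_mm = p$grid$fov, source_res_mm = p$grid$res,
       mixing_times_ms = 1000 * p$mixing_times,
       phase_cycle_deg = p$phase_cycle * 180 / pi,
       t1_ms = 1000 * p$t1,
       slices_z_mm = p$slices$z, slice_thickness_mm = p$slice_thickness,
       sat_bands = list(z_mm = p$sat_bands$z,
                        thickness_mm = p$sat_bands$thickness),
       voxels = p$voxels, voxel_size_mm = p$voxel_size,
       slice_gap_ms = 1000 * p$slice_gap, tr_ms = 1000 * p$tr,
       fid_scale = p$fid_scale, noise_sigma = p$noise_sigma,
       consume_on_imaging = p$consume_on_imaging,
       snap_displacements = p$snap_displacements, seed = p$seed)
}

protocol_from_list <- function(l) {
  acq_protocol(
    source_fov = as.numeric(l$source_fov_mm),
    source_res = as.numeric(l$source_res_mm),
    mixing_times = as.numeric(l$mixing_times_ms) / 1000,
    phase_cycle = as.numeric(l$phase_cycle_deg) * pi / 180,
    t1 = as.numeric(l$t1_ms) / 1000,
    slices = data.frame(z = as.numeric(l$slices_z_mm)),
    slice_thickness = as.numeric(l$slice_thickness_mm),
    sat_bands = data.frame(z = as.numeric(l$sat_bands$z_mm),
                           thickness = as.numeric(l$sat_bands$thickness_mm)),
    voxels = as.data.frame(l$voxels),
    voxel_size = as.numeric(l$voxel_size_mm),
    slice_gap = as.numeric(l$slice_gap_ms) / 1000,
    tr = as.numeric(l$tr_ms) / 1000,
    fid_scale = as.numeric(l$fid_scale),
    noise_sigma = as.numeric(l$noise_sigma),
    consume_on_imaging = isTRUE(l$consume_on_imaging),
    snap_displacements = isTRUE(l$snap_displacements),
    seed = as.integer(l$seed))
}

#' Save / load an acquisition protocol as JSON
#' @param protocol an `acq_protocol`; @param path a `.json` path.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(protocol_to_list(protocol), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  protocol_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Save / load a phantom specification as JSON
#' @param spec a `phantom_spec`; @param path a `.json` path.
#' @export
write_phantom_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(phantom_spec, l)
}

#' Run configuration
#'
#' Bundles everything needed to reproduce a run: phantom spec(s), protocol,
#' analysis options, output directory and master seed. Round-trips losslessly
#' through JSON.
#' @param phantoms list of `phantom_spec`s; @param protocol `acq_protocol`;
#' @param analysis named list of analysis options; @param out_dir output
#'   directory; @param seed master seed; @param verbosity 0-2.
#' @export
run_config <- function(phantoms, protocol, analysis = list(),
                       out_dir = ".", seed = 1L, verbosity = 1L) {
  if (inherits(phantoms, "phantom_spec")) phantoms <- list(phantoms)
  structure(list(phantoms = phantoms, protocol = protocol,
                 analysis = analysis, out_dir = out_dir,
                 seed = as.integer(seed), verbosity = as.integer(verbosity)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`; @param path a `.json` path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(
    list(phantoms = lapply(config$phantoms, unclass),
         protocol = protocol_to_list(config$protocol),
         analysis = config$analysis, out_dir = config$out_dir,
         seed = config$seed, verbosity = config$verbosity),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  phantoms <- lapply(l$phantoms, function(p)
    do.call(phantom_spec, lapply(p, function(x) unlist(x))))
  proto <- protocol_from_list(jsonlite::read_json(path,
                                                  simplifyVector = TRUE)$protocol)
  run_config(phantoms, proto,
             analysis = lapply(l$analysis, unlist),
             out_dir = l$out_dir[[1]], seed = l$seed[[1]],
             verbosity = l$verbosity[[1]])
}
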