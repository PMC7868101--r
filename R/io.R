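## File formats: HDF5 raw data (+ ground truth companion), NIfTI volumes,
## YAML run configuration. All angles are stored in radians, lengths in mm,
## times in seconds; units and a schema version are embedded as attributes.

.RAW_SCHEMA <- "starperf-raw-1"

#' Default run configuration
#'
#' The paper-matched default geometry and pipeline settings: 16 partitions of
#' 5 mm (12 displayed slices after discarding 4 edge slices), one frame per
#' cardiac cycle, golden-angle stack-of-stars sampling with 10 spokes per
#' frame at TR 1.175 ms (188 ms shot), 8 coils, STCR reconstruction with
#' temporally dominant TV weighting, and the artifact/defect discrimination
#' thresholds of the analysis module.
#'
#' @param seed integer seed propagated to every random component.
#' @return nested list of class `run_config`; round-trips losslessly through
#'   [write_run_config()] / [read_run_config()].
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    phantom = list(
      grid = c(64L, 64L, 16L),
      voxel_mm = c(3, 3, 5),
      lv = list(endo_mm = 17, epi_mm = 30, long_axis_mm = 80,
                center_mm = c(0, 0, 0)),
      aif = list(A = 4, t0 = 4, alpha = 2.5, beta = 1.5),
      motion = list(amplitude_mm = c(1, 2, 5), period_s = 4),
      trigger = list(rr_s = 1, jitter_sd_s = 0.01, mistrigger_prob = 0.03,
                     mistrigger_shift_mm = 6),
      sat_delay_s = 0.1,
      n_frames = 32L,
      defects = list()),
    sampling = list(n_readout = 128L, n_spokes_per_frame = 10L,
                    n_partitions = 16L, angle_mode = "continuous",
                    kz_mode = "centric", readout_oversampling = 2),
    sequence = list(tr_ms = 1.175),
    coils = list(n_coils = 8L),
    noise_sd = 0.4,
    recon = list(method = "stcr", alpha_t = 100, ratio = 0.2,
                 max_iter = 30L, tol = 1e-5, backend = "nufft"),
    analysis = list(n_edge = 4L, threshold_frac = 0.15, persist_min = 5L,
                    artifact_window = 3L)
  ), class = "run_config")
}

#' @rdname default_run_config
#' @param config a `run_config`.
#' @export
pattern_from_config <- function(config) {
  s <- config$sampling
  build_pattern(n_readout = s$n_readout,
                n_spokes_per_frame = s$n_spokes_per_frame,
                n_frames = config$phantom$n_frames,
                n_partitions = s$n_partitions,
                angle_mode = s$angle_mode, kz_mode = s$kz_mode,
                readout_oversampling = s$readout_oversampling)
}

#' @rdname default_run_config
#' @export
phantom_spec_from_config <- function(config) {
  p <- config$phantom
  defects <- lapply(p$defects, function(d)
    list(angle_deg = as.numeric(d$angle_deg),
         partitions = as.integer(d$partitions),
         transmural = d$transmural, flow_reduction = d$flow_reduction))
  args <- list(grid = as.integer(p$grid), voxel_mm = as.numeric(p$voxel_mm),
               lv = p$lv, aif = p$aif, defects = defects,
               motion = list(amplitude_mm = as.numeric(p$motion$amplitude_mm),
                             period_s = p$motion$period_s),
               trigger = p$trigger, sat_delay_s = p$sat_delay_s,
               n_frames = p$n_frames, seed = config$seed)
  if (!is.null(p$tissue)) args$tissue <- p$tissue
  do.call(phantom_spec, args)
}

#' Read and write the YAML run configuration
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `read_run_config()` returns the `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  txt <- yaml::as.yaml(unclass(config), precision = 15L)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: %s", path)
  structure(yaml::read_yaml(path), class = "run_config")
}

.h5_require <- function(path, name) {
  ls <- rhdf5::h5ls(path)
  paths <- file.path(ls$group, ls$name)
  paths <- sub("^//", "/", paths)
  if (!(name %in% paths))
    stop_format("raw-data file %s is missing dataset %s", path, name)
}

#' Write a k-space series to HDF5
#'
#' Layout: `/kspace/data_real` + `/kspace/data_imag` (complex samples
#' `[readout, spoke, partition, coil, frame]` as a real pair),
#' `/kspace/noise_sd`, `/traj/angles` (radians, `[frame, spoke]`),
#' `/traj/kz_order`, trajectory attributes (`n_readout`, `k_max`,
#' `oversampling`, counts, modes), optional `/coils/maps_real` +
#' `/coils/maps_imag`, and a root `schema_version` attribute. Writing then
#' reading is the identity on all datasets and attributes.
#'
#' @param kspace a `kspace_series`.
#' @param path output `.h5` path (overwritten).
#' @param coils optional `coil_profile` stored alongside the data.
#' @return `path`, invisibly.
#' @export
write_raw <- function(kspace, path, coils = NULL) {
  stopifnot(inherits(kspace, "kspace_series"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "kspace")
  rhdf5::h5createGroup(path, "traj")
  rhdf5::h5write(Re(kspace$data), path, "kspace/data_real")
  rhdf5::h5write(Im(kspace$data), path, "kspace/data_imag")
  rhdf5::h5write(kspace$noise_sd, path, "kspace/noise_sd")
  p <- kspace$pattern
  rhdf5::h5write(p$angle_schedule, path, "traj/angles")
  rhdf5::h5write(p$kz_order, path, "traj/kz_order")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "traj")
  rhdf5::h5writeAttribute(p$n_readout, gid, "n_readout")
  rhdf5::h5writeAttribute(p$k_max, gid, "k_max")
  rhdf5::h5writeAttribute(p$readout_oversampling, gid, "oversampling")
  rhdf5::h5writeAttribute(p$n_spokes_per_frame, gid, "n_spokes_per_frame")
  rhdf5::h5writeAttribute(p$n_frames, gid, "n_frames")
  rhdf5::h5writeAttribute(p$n_partitions, gid, "n_partitions")
  rhdf5::h5writeAttribute(p$angle_mode, gid, "angle_mode")
  rhdf5::h5writeAttribute(p$kz_mode, gid, "kz_mode")
  rhdf5::h5writeAttribute("radians", gid, "angle_units")
  rhdf5::H5Gclose(gid)
  rhdf5::h5writeAttribute(.RAW_SCHEMA, fid, "schema_version")
  rhdf5::h5writeAttribute(kspace$backend, fid, "backend")
  rhdf5::H5Fclose(fid)
  if (!is.null(coils)) {
    rhdf5::h5createGroup(path, "coils")
    rhdf5::h5write(Re(unclass(coils)), path, "coils/maps_real")
    rhdf5::h5write(Im(unclass(coils)), path, "coils/maps_imag")
  }
  invisible(path)
}

#' Read a k-space series from HDF5
#'
#' Inverse of [write_raw()]; validates the layout and names any missing
#' dataset in its error.
#'
#' @param path `.h5` file written by [write_raw()].
#' @return list with `kspace` (a `kspace_series`) and `coils` (a
#'   `coil_profile`, or NULL when the file holds none).
#' @export
read_raw <- function(path) {
  if (!file.exists(path)) stop_format("raw-data file not found: %s", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (nm in c("/kspace/data_real", "/kspace/data_imag",
               "/kspace/noise_sd", "/traj/angles", "/traj/kz_order"))
    .h5_require(path, nm)
  re <- rhdf5::h5read(path, "kspace/data_real")
  im <- rhdf5::h5read(path, "kspace/data_imag")
  dat <- array(complex(real = re, imaginary = im), dim(re))
  at <- rhdf5::h5readAttributes(path, "traj")
  angles <- rhdf5::h5read(path, "traj/angles")
  pattern <- build_pattern(
    n_readout = as.integer(at$n_readout),
    n_spokes_per_frame = as.integer(at$n_spokes_per_frame),
    n_frames = as.integer(at$n_frames),
    n_partitions = as.integer(at$n_partitions),
    angle_mode = at$angle_mode, kz_mode = at$kz_mode,
    k_max = as.numeric(at$k_max),
    readout_oversampling = as.numeric(at$oversampling))
  pattern$angle_schedule <- angles   # authoritative stored schedule
  pattern$kz_order <- as.integer(rhdf5::h5read(path, "traj/kz_order"))
  root <- rhdf5::h5readAttributes(path, "/")
  coils <- NULL
  ls <- rhdf5::h5ls(path)
  if ("coils" %in% ls$name[ls$group == "/"]) {
    cre <- rhdf5::h5read(path, "coils/maps_real")
    cim <- rhdf5::h5read(path, "coils/maps_imag")
    coils <- structure(array(complex(real = cre, imaginary = cim), dim(cre)),
                       class = "coil_profile")
  }
  ks <- structure(list(data = dat, pattern = pattern,
                       noise_sd = as.numeric(rhdf5::h5read(path,
                                                           "kspace/noise_sd")),
                       backend = root$backend %||% "nufft"),
                  class = "kspace_series")
  list(kspace = ks, coils = coils)
}

#' Write the phantom ground truth to HDF5
#'
#' Companion file to the phantom NIfTI: `/gt/labels` (per-frame region label
#' volumes), `/gt/shifts` (mm), `/gt/offsets` (s), `/gt/mistriggered`,
#' `/gt/curves` (per-region concentration, mM) and `/gt/label_levels`.
#'
#' @param truth a `ground_truth`.
#' @param path output `.h5` path.
#' @return `path`, invisibly. `read_ground_truth()` returns the
#'   `ground_truth` (without the generating spec unless `spec` is supplied).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  if (file.exists(path)) unlink(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "gt")
  rhdf5::h5write(truth$labels, path, "gt/labels")
  rhdf5::h5write(truth$shifts_mm, path, "gt/shifts")
  rhdf5::h5write(truth$trigger_offset_s, path, "gt/offsets")
  rhdf5::h5write(as.integer(truth$mistriggered), path, "gt/mistriggered")
  rhdf5::h5write(as.matrix(truth$curves), path, "gt/curves")
  rhdf5::h5write(colnames(truth$curves), path, "gt/curve_names")
  rhdf5::h5write(truth$label_levels, path, "gt/label_levels")
  invisible(path)
}

#' @rdname write_ground_truth
#' @param spec optionally re-attach the generating `phantom_spec`.
#' @export
read_ground_truth <- function(path, spec = NULL) {
  if (!file.exists(path)) stop_format("ground-truth file not found: %s", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (nm in c("/gt/labels", "/gt/shifts", "/gt/offsets", "/gt/curves"))
    .h5_require(path, nm)
  curves <- as.data.frame(rhdf5::h5read(path, "gt/curves"))
  colnames(curves) <- rhdf5::h5read(path, "gt/curve_names")
  structure(list(
    labels = rhdf5::h5read(path, "gt/labels"),
    label_levels = rhdf5::h5read(path, "gt/label_levels"),
    shifts_mm = rhdf5::h5read(path, "gt/shifts"),
    trigger_offset_s = as.numeric(rhdf5::h5read(path, "gt/offsets")),
    mistriggered = as.logical(rhdf5::h5read(path, "gt/mistriggered")),
    curves = curves,
    spec = spec
  ), class = "ground_truth")
}

#' Write a dynamic volume as NIfTI
#'
#' Magnitude is stored as a 4D NIfTI (frames along the 4th dimension) with
#' the voxel size in the header (through-plane 5 mm in the default
#' configuration) and the frame interval as the temporal pixdim. The complex
#' phase goes to a `*_phase` companion file when requested.
#'
#' @param volume a `dynamic_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param write_phase also write the phase companion.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, write_phase = FALSE) {
  stopifnot(inherits(volume, "dynamic_volume"))
  dt <- if (length(volume$frame_times) > 1) diff(volume$frame_times)[1] else 1
  hdr <- list(pixdim = c(-1, volume$voxel_mm, dt, 0, 0, 0))
  img <- RNifti::asNifti(Mod(volume$data), hdr)
  RNifti::writeNifti(img, path)
  if (write_phase) {
    ph <- RNifti::asNifti(Arg(volume$data), hdr)
    RNifti::writeNifti(ph, .phase_path(path))
  }
  invisible(path)
}

.phase_path <- function(path)
  sub("(\\.nii(\\.gz)?)$", "_phase\\1", path)

#' @rdname write_volume
#' @param source provenance tag attached on read.
#' @return `read_volume()` returns the `dynamic_volume` (complex if a phase
#'   companion exists, otherwise magnitude with zero phase).
#' @export
read_volume <- function(path, source = "file") {
  if (!file.exists(path)) stop_format("volume file not found: %s", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(as.array(img)), dim(img))   # strip header attrs
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  pd <- RNifti::pixdim(img)
  hdr <- RNifti::niftiHeader(img)
  dt <- if (length(hdr$pixdim) >= 5 && hdr$pixdim[5] > 0) hdr$pixdim[5] else 1
  pp <- .phase_path(path)
  if (file.exists(pp)) {
    ph <- array(as.vector(as.array(RNifti::readNifti(pp))), dim(arr))
    arr <- arr * exp(1i * ph)
  }
  dynamic_volume(arr, voxel_mm = pd[1:3],
                 frame_times = (seq_len(dim(arr)[4]) - 1) * dt,
                 source = source)
}

#' Write findings and segment curves
#'
#' Findings as CSV plus a JSON summary; curves as CSV (frame time, 16
#' segments, blood pool).
#'
#' @param findings a `defect_findings` frame.
#' @param curves a `segment_time_curves`.
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
write_findings <- function(findings, curves, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fcsv <- file.path(dir, "findings.csv")
  utils::write.csv(as.data.frame(findings), fcsv, row.names = FALSE)
  persistent <- findings[findings$classification == "persistent-defect", ,
                         drop = FALSE]
  summary <- list(
    n_findings = nrow(findings),
    n_persistent = nrow(persistent),
    persistent_segments = as.list(unique(persistent$segment)),
    severities = as.list(stats::setNames(persistent$severity,
                                         persistent$segment)))
  fjson <- file.path(dir, "findings.json")
  jsonlite::write_json(summary, fjson, auto_unbox = TRUE, pretty = TRUE)
  cc <- data.frame(time = curves$frame_times, curves$curves,
                   bloodpool = curves$bloodpool)
  names(cc) <- c("time", curves$segment_names, "bloodpool")
  ccsv <- file.path(dir, "curves.csv")
  utils::write.csv(cc, ccsv, row.names = FALSE)
  invisible(c(fcsv, fjson, ccsv))
}
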