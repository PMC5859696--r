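#' @importFrom stats coef lm pt quantile rnorm runif sd t.test wilcox.test
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Shared physical constants ---------------------------------------------------

#' Default density of blood
#'
#' Density used to convert pathline speed and represented volume into kinetic
#' energy, in kg/m^3. All energetics functions take `rho` as an argument with
#' this value as default, and record the value used in their output.
#' @export
VF_BLOOD_DENSITY <- 1060

# condition helpers -----------------------------------------------------------

vf_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "ventriflow_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Geometry helpers ------------------------------------------------------------

# voxel centers along one axis, mm; voxel i (1-based) is centered at (i - 1/2)*h
axis_coords <- function(n, h) (seq_len(n) - 0.5) * h

# nearest voxel index (1-based) of physical coordinate p along an axis
nearest_voxel <- function(p, h) as.integer(floor(p / h)) + 1L

#' Define an oriented valve plane
#'
#' A plane is a point plus a unit normal, both in mm on the physical grid.
#' By convention the normal points into the left ventricle.
#'
#' @param point numeric(3), a point on the plane (mm).
#' @param normal numeric(3), plane normal; normalized to unit length.
#' @return An object of class `vf_plane`.
#' @export
vf_plane <- function(point, normal) {
  stopifnot(length(point) == 3, length(normal) == 3, all(is.finite(point)),
            all(is.finite(normal)))
  nn <- sqrt(sum(normal^2))
  if (nn == 0) vf_stop("plane normal must be non-zero", "vf_config_error")
  structure(list(point = as.numeric(point), normal = as.numeric(normal) / nn),
            class = "vf_plane")
}

# signed distance of positions (N x 3 mm) to a plane; positive on the side the
# normal points to (into the LV)
plane_signed_distance <- function(plane, positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  c((positions - matrix(plane$point, nrow(positions), 3, byrow = TRUE)) %*%
      plane$normal)
}

# Domain types ----------------------------------------------------------------

#' Construct a time-resolved 3D velocity field
#'
#' Internal container for gated (periodic) phase-contrast velocity data.
#' Velocities are stored in m/s, positions in mm, times in s. The time axis is
#' periodic with period `cycle_duration`: frame `n_frames` wraps around to
#' frame 1, matching a retrospectively gated cine reconstruction.
#'
#' @param values 5-D array `[nx, ny, nz, 3, n_frames]` of velocity components
#'   (m/s); the 4th dimension orders the x, y, z components.
#' @param voxel_size isotropic voxel edge length (mm).
#' @param frame_times strictly increasing frame times (s), length `n_frames`.
#' @param cycle_duration cardiac cycle length (s); must exceed the last frame
#'   time.
#' @param venc velocity encoding limit (cm/s).
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(values, voxel_size, frame_times, cycle_duration,
                           venc) {
  d <- dim(values)
  if (length(d) != 5 || d[4] != 3)
    vf_stop("values must be an [nx, ny, nz, 3, n_frames] array",
            "vf_config_error")
  if (length(frame_times) != d[5])
    vf_stop(sprintf("frame_times has length %d but values has %d frames",
                    length(frame_times), d[5]), "vf_config_error")
  if (any(diff(frame_times) <= 0))
    vf_stop("frame_times must be strictly increasing", "vf_io_error")
  if (cycle_duration <= frame_times[length(frame_times)] - frame_times[1])
    vf_stop("cycle_duration must exceed the frame time span", "vf_config_error")
  stopifnot(voxel_size > 0, venc > 0)
  structure(list(
    values = values,
    voxel_size = as.numeric(voxel_size),
    frame_times = as.numeric(frame_times),
    cycle_duration = as.numeric(cycle_duration),
    venc = as.numeric(venc)
  ), class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "velocity_field: %d x %d x %d grid, %d frames, %.1f mm voxels, VENC %g cm/s, cycle %.3f s\n",
    d[1], d[2], d[3], d[5], x$voxel_size, x$venc, x$cycle_duration))
  invisible(x)
}

field_grid_dim <- function(field) dim(field$values)[1:3]
n_frames <- function(field) dim(field$values)[5]

# VENC in m/s (stored in cm/s for reporting, used in m/s internally)
venc_ms <- function(field) field$venc / 100

#' Construct an LV segmentation
#'
#' End-diastolic and end-systolic binary masks on the velocity grid, plus the
#' mitral and aortic valve planes.
#'
#' @param ed_mask,es_mask logical 3-D arrays on the velocity grid.
#' @param mitral_plane,aortic_plane [vf_plane()] objects (mm; normal into LV).
#' @return An object of class `lv_segmentation`.
#' @export
lv_segmentation <- function(ed_mask, es_mask, mitral_plane, aortic_plane) {
  ed_mask <- array(as.logical(ed_mask), dim(ed_mask))
  es_mask <- array(as.logical(es_mask), dim(es_mask))
  if (!identical(dim(ed_mask), dim(es_mask)))
    vf_stop("ED and ES masks must share one grid", "vf_io_error")
  if (!any(ed_mask) || !any(es_mask))
    vf_stop("ED and ES masks must be non-empty", "vf_config_error")
  stopifnot(inherits(mitral_plane, "vf_plane"), inherits(aortic_plane, "vf_plane"))
  structure(list(ed_mask = ed_mask, es_mask = es_mask,
                 mitral_plane = mitral_plane, aortic_plane = aortic_plane),
            class = "lv_segmentation")
}

#' Construct cardiac-cycle timing
#'
#' @param ed_frame,es_frame 1-based reconstructed frame indices of
#'   end-diastole and end-systole.
#' @param cycle_duration cardiac cycle length (s).
#' @param mid_diastasis_frame optional 1-based frame index of mid-diastasis
#'   (set by [find_mid_diastasis()]).
#' @return An object of class `cardiac_timing`.
#' @export
cardiac_timing <- function(ed_frame, es_frame, cycle_duration,
                           mid_diastasis_frame = NA_integer_) {
  ed_frame <- as.integer(ed_frame); es_frame <- as.integer(es_frame)
  if (ed_frame == es_frame)
    vf_stop("ED and ES frames must differ", "vf_config_error")
  stopifnot(ed_frame >= 1, es_frame >= 1, cycle_duration > 0)
  structure(list(ed_frame = ed_frame, es_frame = es_frame,
                 cycle_duration = as.numeric(cycle_duration),
                 mid_diastasis_frame = as.integer(mid_diastasis_frame)),
            class = "cardiac_timing")
}

#' Acquisition metadata
#'
#' The gradient-echo sequence parameters that determine the effective
#' temporal resolution of an interleaved three-directional phase-contrast
#' acquisition.
#'
#' @param tr_ms repetition time (ms).
#' @param n_velocity_encodings encodings per k-line set; 4 for interleaved
#'   three-directional flow encoding plus reference.
#' @param k_segmentation_factor k-space segmentation factor.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(tr_ms, n_velocity_encodings = 4L,
                             k_segmentation_factor = 3L) {
  stopifnot(tr_ms > 0, n_velocity_encodings > 0, k_segmentation_factor > 0)
  structure(list(tr_ms = tr_ms,
                 n_velocity_encodings = as.integer(n_velocity_encodings),
                 k_segmentation_factor = as.integer(k_segmentation_factor)),
            class = "acquisition_meta")
}

#' Effective temporal resolution of an interleaved acquisition
#'
#' Each reconstructed cine frame spans TR times the number of velocity
#' encodings times the k-space segmentation factor.
#'
#' @param meta an [acquisition_meta()] object.
#' @return Temporal resolution in ms.
#' @examples
#' temporal_resolution(acquisition_meta(4.4, 4, 3)) # 52.8 ms
#' @export
temporal_resolution <- function(meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  meta$tr_ms * meta$n_velocity_encodings * meta$k_segmentation_factor
}

# Dataset I/O -----------------------------------------------------------------

#' Write a 4D flow dataset to a directory
#'
#' Writes the three velocity component volumes (`vx.nii.gz`, `vy.nii.gz`,
#' `vz.nii.gz`, 4-D, m/s), the ED/ES masks (and optional static-tissue mask),
#' and a JSON sidecar with frame times, VENC, voxel size, valve planes and
#' ED/ES frame indices (0-based on disk).
#'
#' @param path output directory (created if needed).
#' @param field a [velocity_field()].
#' @param seg an [lv_segmentation()].
#' @param timing a [cardiac_timing()].
#' @param static_mask optional logical 3-D static-tissue mask.
#' @param extra optional named list merged into the sidecar (e.g. the RNG seed
#'   used to generate a phantom).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(path, field, seg, timing, static_mask = NULL,
                          extra = list()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  h <- field$voxel_size
  comp_names <- c("vx", "vy", "vz")
  for (ci in 1:3) {
    vol <- field$values[, , , ci, , drop = TRUE]
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = c(h, h, h, 1)),
                       file.path(path, paste0(comp_names[ci], ".nii.gz")))
  }
  write_mask <- function(mask, name)
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim(mask)),
                                       pixdim = c(h, h, h)),
                       file.path(path, name))
  write_mask(seg$ed_mask, "ed_mask.nii.gz")
  write_mask(seg$es_mask, "es_mask.nii.gz")
  if (!is.null(static_mask)) write_mask(static_mask, "static_mask.nii.gz")
  sidecar <- c(list(
    frame_times_s = field$frame_times,
    cycle_duration_s = field$cycle_duration,
    venc_cms = field$venc,
    voxel_size_mm = h,
    velocity_units = "m/s",
    ed_frame = timing$ed_frame - 1L,   # 0-based on disk
    es_frame = timing$es_frame - 1L,
    mitral_plane = list(point_mm = seg$mitral_plane$point,
                        normal = seg$mitral_plane$normal),
    aortic_plane = list(point_mm = seg$aortic_plane$point,
                        normal = seg$aortic_plane$normal)
  ), extra)
  if (!is.na(timing$mid_diastasis_frame))
    sidecar$mid_diastasis_frame <- timing$mid_diastasis_frame - 1L
  jsonlite::write_json(sidecar, file.path(path, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_nifti_array <- function(file) {
  if (!file.exists(file))
    vf_stop(sprintf("missing dataset file: %s", file), "vf_io_error")
  a <- RNifti::readNifti(file)
  array(as.numeric(a), dim(a))
}

#' Read a 4D flow dataset from a directory
#'
#' Inverse of [write_dataset()]: reads the three 4-D component volumes, the
#' ED/ES masks and the JSON sidecar, validates grid and timing consistency,
#' and returns the internal types (m/s, mm, s; 1-based frame indices).
#'
#' @param path dataset directory.
#' @return A list with elements `field`, `seg`, `timing`, `static_mask`
#'   (NULL if absent) and `sidecar` (the raw sidecar list).
#' @export
read_dataset <- function(path) {
  sc_file <- file.path(path, "sidecar.json")
  if (!file.exists(sc_file))
    vf_stop(sprintf("missing dataset file: %s", sc_file), "vf_io_error")
  sc <- jsonlite::read_json(sc_file, simplifyVector = TRUE)
  comps <- lapply(c("vx", "vy", "vz"), function(nm)
    read_nifti_array(file.path(path, paste0(nm, ".nii.gz"))))
  d <- dim(comps[[1]])
  if (length(d) != 4)
    vf_stop("velocity component volumes must be 4-D (x, y, z, time)",
            "vf_io_error")
  for (k in 2:3) if (!identical(dim(comps[[k]]), d))
    vf_stop("velocity component volumes disagree on grid", "vf_io_error")
  values <- array(0, c(d[1:3], 3, d[4]))
  for (ci in 1:3) values[, , , ci, ] <- comps[[ci]]
  field <- velocity_field(values, voxel_size = sc$voxel_size_mm,
                          frame_times = sc$frame_times_s,
                          cycle_duration = sc$cycle_duration_s,
                          venc = sc$venc_cms)
  ed <- read_nifti_array(file.path(path, "ed_mask.nii.gz")) > 0.5
  es <- read_nifti_array(file.path(path, "es_mask.nii.gz")) > 0.5
  if (!identical(dim(ed), d[1:3]) || !identical(dim(es), d[1:3]))
    vf_stop(sprintf(
      "mask grid (%s) does not match velocity grid (%s)",
      paste(dim(ed), collapse = "x"), paste(d[1:3], collapse = "x")),
      "vf_io_error")
  seg <- lv_segmentation(
    ed, es,
    mitral_plane = vf_plane(sc$mitral_plane$point_mm, sc$mitral_plane$normal),
    aortic_plane = vf_plane(sc$aortic_plane$point_mm, sc$aortic_plane$normal))
  timing <- cardiac_timing(
    ed_frame = sc$ed_frame + 1L, es_frame = sc$es_frame + 1L,
    cycle_duration = sc$cycle_duration_s,
    mid_diastasis_frame = if (!is.null(sc$mid_diastasis_frame))
      sc$mid_diastasis_frame + 1L else NA_integer_)
  static_file <- file.path(path, "static_mask.nii.gz")
  static_mask <- if (file.exists(static_file))
    read_nifti_array(static_file) > 0.5 else NULL
  if (any(abs(field$values) > venc_ms(field), na.rm = TRUE))
    warning("velocity samples exceed VENC; data may be phase-wrapped")
  message(sprintf(
    "read dataset %s: grid %s, %d frames, VENC %g cm/s, voxel %.2f mm",
    path, paste(d[1:3], collapse = "x"), d[4], sc$venc_cms, sc$voxel_size_mm))
  list(field = field, seg = seg, timing = timing, static_mask = static_mask,
       sidecar = sc)
}

#' Write component analysis results to CSV files
#'
#' Writes `components.csv` (one row per flow component: volume, KE at ED,
#' KE/ml at ED, empty flag), `ke_curves.csv` (tidy: component, frame, time,
#' KE in mJ), `qc.json` (the QC report) and `run_log.json` (density of blood
#' used, software version, optional config/seed entries).
#'
#' @param results output of [component_curves()].
#' @param path output directory (created if needed).
#' @param qc optional QC report from [qc_inflow_outflow()].
#' @param log_extra optional named list added to the run log.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, qc = NULL, log_extra = list()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write.csv(results$summary, file.path(path, "components.csv"),
            row.names = FALSE)
  write.csv(results$curves, file.path(path, "ke_curves.csv"),
            row.names = FALSE)
  if (!is.null(qc))
    jsonlite::write_json(qc, file.path(path, "qc.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log <- c(list(rho_kg_m3 = results$rho,
                speed_source = results$speed_source,
                package_version = as.character(packageVersion("ventriflow"))),
           log_extra)
  jsonlite::write_json(log, file.path(path, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
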