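# Four-component classification of pathlines, E/A-wave subdivision at a
# data-driven mid-diastasis frame, and the inflow-outflow QC rule.

COMPONENTS <- c("DirectFlow", "RetainedInflow", "DelayedEjectionFlow",
                "ResidualVolume")
SUBCOMPONENTS <- c("DirectFlowE", "DirectFlowA",
                   "RetainedInflowE", "RetainedInflowA")

# nearest-voxel membership of positions (N x 3 mm) in a binary mask;
# positions outside the grid are outside the mask
mask_lookup <- function(mask, positions, voxel_size) {
  d <- dim(mask)
  i <- nearest_voxel(positions[, 1], voxel_size)
  j <- nearest_voxel(positions[, 2], voxel_size)
  k <- nearest_voxel(positions[, 3], voxel_size)
  inside <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep(FALSE, nrow(positions))
  out[inside] <- mask[cbind(i[inside], j[inside], k[inside])]
  out
}

#' Classify pathlines into the four flow components
#'
#' The backward endpoint (origin, at the previous end-systole) and the
#' forward endpoint (destination, at the next end-systole) of every pathline
#' are tested for membership in the ES mask by nearest-voxel lookup:
#' origin out & destination out = Direct Flow (enters this diastole, leaves
#' this systole); origin out & destination in = Retained Inflow; origin in &
#' destination out = Delayed Ejection Flow; origin in & destination in =
#' Residual Volume (resides at least two cycles). Flagged pathlines are
#' classified by their frozen endpoints and reported separately.
#'
#' @param paths a `pathline_set` from [emit_all()].
#' @param seg an [lv_segmentation()].
#' @return A data.frame with one row per pathline: `primary` component,
#'   `wave` (NA until [split_e_a()]), `flag`, crossing bookkeeping columns.
#' @export
classify_pathlines <- function(paths, seg) {
  M <- dim(paths$positions)[3]
  origin <- paths$positions[, , 1, drop = FALSE][, , 1]
  dest <- paths$positions[, , M, drop = FALSE][, , 1]
  if (is.null(dim(origin))) { origin <- matrix(origin, ncol = 3); dest <- matrix(dest, ncol = 3) }
  h <- paths$voxel_size
  o_in <- mask_lookup(seg$es_mask, origin, h)
  d_in <- mask_lookup(seg$es_mask, dest, h)
  primary <- ifelse(!o_in & !d_in, "DirectFlow",
             ifelse(!o_in & d_in, "RetainedInflow",
             ifelse(o_in & !d_in, "DelayedEjectionFlow", "ResidualVolume")))
  data.frame(pathline = seq_len(nrow(paths$seeds)),
             primary = primary,
             wave = NA_character_,
             flag = paths$flags,
             crossing_time = NA_real_,
             crossing_detected = NA,
             stringsAsFactors = FALSE)
}

# earliest index attaining the minimum
argmin_earliest <- function(counts) which(counts == min(counts))[1]

# mitral-plane signed distances of all pathlines at the diastolic samples
# (sample 1 = previous ES .. ed_index = ED); returns n_path x n_dia matrix
diastolic_plane_distances <- function(paths, seg) {
  nd <- paths$ed_index
  N <- nrow(paths$seeds)
  D <- matrix(NA_real_, N, nd)
  for (j in seq_len(nd))
    D[, j] <- plane_signed_distance(seg$mitral_plane, paths$positions[, , j])
  D
}

# crossing = signed distance changes sign across a sample interval (reaching
# exactly zero counts as crossing at that sample)
interval_crossings <- function(Drow) {
  a <- Drow[-length(Drow)]; b <- Drow[-1]
  (a * b < 0) | (a != 0 & b == 0)
}

#' Find the mid-diastasis frame
#'
#' Counts, for every diastolic frame interval, the inflow pathlines (Direct
#' Flow + Retained Inflow) whose mitral-plane signed distance changes sign in
#' that interval, and returns the reconstructed frame starting the interval
#' with the fewest crossings (ties broken by the earliest frame). This is the
#' deterministic surrogate for visually picking the frame at which the fewest
#' pathlines cross the mitral valve plane.
#'
#' @param paths a `pathline_set`.
#' @param seg an [lv_segmentation()].
#' @param timing a [cardiac_timing()].
#' @param labels classification from [classify_pathlines()].
#' @return `timing` with `mid_diastasis_frame` set; the crossing counts are
#'   attached as attribute `crossing_counts`.
#' @export
find_mid_diastasis <- function(paths, seg, timing, labels) {
  nd <- paths$ed_index
  if (nd < 4)
    vf_stop("diastole must span at least 3 frame intervals", "vf_config_error")
  inflow <- labels$primary %in% c("DirectFlow", "RetainedInflow")
  if (!any(inflow))
    vf_stop("no inflow pathlines: dataset unusable for E/A split",
            "vf_timing_error")
  D <- diastolic_plane_distances(paths, seg)
  counts <- colSums(t(apply(D[inflow, , drop = FALSE], 1, interval_crossings)))
  if (sum(inflow) == 1)
    counts <- as.numeric(interval_crossings(D[inflow, ]))
  j_min <- argmin_earliest(counts)
  timing$mid_diastasis_frame <- paths$frame_idx[j_min]
  attr(timing, "crossing_counts") <- counts
  attr(timing, "mid_diastasis_sample") <- j_min
  timing
}

#' Split inflow components by diastolic filling wave
#'
#' For every inflow pathline (Direct Flow, Retained Inflow) the first
#' mitral-plane crossing time during diastole is found by linear
#' interpolation of the signed distance between the bracketing trajectory
#' samples. Crossings earlier than the mid-diastasis frame time are E-wave
#' inflow, crossings at or after it are A-wave inflow (the A-wave interval
#' runs from mid-diastasis until ED). Inflow pathlines with no detected
#' crossing are assigned by their time of nearest approach to the plane and
#' reported via `crossing_detected = FALSE`.
#'
#' @param paths a `pathline_set`.
#' @param labels classification from [classify_pathlines()].
#' @param seg an [lv_segmentation()].
#' @param timing a [cardiac_timing()] with `mid_diastasis_frame` set (see
#'   [find_mid_diastasis()]).
#' @return `labels` with `wave`, `crossing_time` (s, ED at 0) and
#'   `crossing_detected` filled in for inflow pathlines.
#' @export
split_e_a <- function(paths, labels, seg, timing) {
  if (is.na(timing$mid_diastasis_frame))
    vf_stop("mid_diastasis_frame not set; run find_mid_diastasis first",
            "vf_timing_error")
  nd <- paths$ed_index
  j_mid <- attr(timing, "mid_diastasis_sample")
  if (is.null(j_mid)) {
    j_mid <- which(paths$frame_idx[seq_len(nd)] == timing$mid_diastasis_frame)[1]
    if (is.na(j_mid))
      vf_stop("mid_diastasis_frame is not a diastolic frame", "vf_timing_error")
  }
  t_mid <- paths$times[j_mid]
  D <- diastolic_plane_distances(paths, seg)
  inflow <- which(labels$primary %in% c("DirectFlow", "RetainedInflow"))
  for (p in inflow) {
    cr <- interval_crossings(D[p, ])
    j <- which(cr)[1]
    if (!is.na(j)) {
      d0 <- D[p, j]; d1 <- D[p, j + 1]
      tc <- paths$times[j] + (0 - d0) / (d1 - d0) *
        (paths$times[j + 1] - paths$times[j])
      labels$crossing_detected[p] <- TRUE
    } else {
      tc <- paths$times[which.min(abs(D[p, seq_len(nd)]))]
      labels$crossing_detected[p] <- FALSE
    }
    labels$crossing_time[p] <- tc
    labels$wave[p] <- if (tc < t_mid) "E" else "A"
  }
  labels
}

#' Inflow-outflow quality control
#'
#' Inflow volume is Direct Flow + Retained Inflow; outflow volume is Direct
#' Flow + Delayed Ejection Flow. The discrepancy is their absolute difference
#' normalized by their mean, in percent; datasets exceeding the threshold
#' (default 15%) fail QC and should be excluded from further analysis.
#'
#' @param labels classification from [classify_pathlines()].
#' @param represented_volume volume represented by each pathline (ml).
#' @param max_discrepancy_pct pass/fail threshold (percent).
#' @return A list: inflow/outflow volumes (ml), `discrepancy_pct`, `pass`,
#'   flagged-pathline fractions, and the threshold used.
#' @export
qc_inflow_outflow <- function(labels, represented_volume,
                              max_discrepancy_pct = 15) {
  vol <- function(comp) sum(labels$primary == comp) * represented_volume
  inflow <- vol("DirectFlow") + vol("RetainedInflow")
  outflow <- vol("DirectFlow") + vol("DelayedEjectionFlow")
  if (inflow == 0 && outflow == 0) {
    return(list(inflow_ml = 0, outflow_ml = 0, discrepancy_pct = NA_real_,
                pass = FALSE,
                reason = "no inflow or outflow: discrepancy undefined",
                flagged_fraction = mean(labels$flag != "ok"),
                no_crossing_fraction = mean(labels$crossing_detected %in% FALSE),
                threshold_pct = max_discrepancy_pct))
  }
  disc <- abs(inflow - outflow) / mean(c(inflow, outflow)) * 100
  list(inflow_ml = inflow, outflow_ml = outflow,
       discrepancy_pct = disc, pass = disc <= max_discrepancy_pct,
       reason = NULL,
       flagged_fraction = mean(labels$flag != "ok"),
       no_crossing_fraction = mean(labels$crossing_detected %in% FALSE),
       threshold_pct = max_discrepancy_pct)
}
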