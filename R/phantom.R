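# Synthetic phantom generation with closed-form ground truth.
#
# The slab phantom uses a spatially uniform axial velocity u(t) * xhat over a
# support slab that contains every pathline excursion, so every downstream
# quantity (component membership, E/A split, KE curves) has a closed form.
# Ground truth is computed from exact displacement integrals of the sampled,
# linearly interpolated waveform -- the same continuous field the pathline
# integrator sees -- so truth and pipeline can be compared at zero tolerance.

# Waveforms --------------------------------------------------------------

#' Define a piecewise cardiac waveform
#'
#' Axial speed u(t) over one cycle as consecutive segments (systolic ejection,
#' E-wave, diastasis, A-wave). Each segment has a duration, an amplitude in
#' cm/s and a shape: `"rect"` (constant at the amplitude) or `"sine"`
#' (half-sine pulse peaking at the amplitude mid-segment).
#'
#' @param segment character vector of segment names.
#' @param duration_s segment durations (s); must sum to the cycle duration of
#'   the spec using the waveform.
#' @param amplitude_cms segment amplitudes (cm/s).
#' @param shape `"rect"` or `"sine"`, recycled.
#' @return A `vf_waveform` data.frame.
#' @export
flow_waveform <- function(segment, duration_s, amplitude_cms, shape = "rect") {
  stopifnot(length(segment) == length(duration_s),
            length(segment) == length(amplitude_cms),
            all(duration_s > 0), all(shape %in% c("rect", "sine")))
  structure(data.frame(segment = segment, duration_s = duration_s,
                       amplitude_cms = amplitude_cms,
                       shape = rep_len(shape, length(segment)),
                       stringsAsFactors = FALSE),
            class = c("vf_waveform", "data.frame"))
}

#' Evaluate a waveform at given times
#'
#' Times are wrapped into `[0, cycle_duration)`; within each segment the shape
#' is evaluated relative to the segment onset.
#'
#' @param waveform a [flow_waveform()].
#' @param times numeric vector (s).
#' @param cycle_duration cycle length (s).
#' @return Speeds in m/s.
#' @export
sample_waveform <- function(waveform, times, cycle_duration) {
  bounds <- cumsum(c(0, waveform$duration_s))
  if (abs(bounds[length(bounds)] - cycle_duration) > 1e-8 * cycle_duration)
    vf_stop("waveform segment durations must sum to cycle_duration",
            "vf_config_error")
  tt <- times %% cycle_duration
  seg <- findInterval(tt, bounds, rightmost.closed = FALSE)
  seg[seg > nrow(waveform)] <- nrow(waveform)
  amp <- waveform$amplitude_cms[seg] / 100    # m/s
  u <- ifelse(waveform$shape[seg] == "rect", amp,
              amp * sin(pi * (tt - bounds[seg]) / waveform$duration_s[seg]))
  u
}

# exact cumulative displacement (mm) of the piecewise-linear interpolant of
# the frame-sampled waveform: S[k] = integral of u from frame 1 to frame k,
# k = 1..n+1 where n+1 closes the cycle back to frame 1.
cum_displacement_mm <- function(u_frames, frame_times, cycle_duration) {
  n <- length(u_frames)
  t_ext <- c(frame_times, frame_times[1] + cycle_duration)
  u_ext <- c(u_frames, u_frames[1])
  dt <- diff(t_ext)
  c(0, cumsum((u_ext[-(n + 1)] + u_ext[-1]) / 2 * dt)) * 1000
}

# displacement (mm) between two extended frame indices a <= b (1..n+1)
disp_between <- function(S, a, b) S[b] - S[a]

# Phantom specification --------------------------------------------------

#' Specify a slab phantom
#'
#' Defines the grid, timing, waveform and geometry of a synthetic 4D flow
#' dataset with closed-form ground truth. The ED and ES masks are axial slabs
#' (full cross-section in y and z) sharing their basal (low-x) face; the
#' mitral plane sits on that shared face and the aortic plane on the apical
#' (high-x) face of the ES slab, both normals pointing into the LV.
#'
#' @param grid_shape integer(3) grid size in voxels.
#' @param voxel_size isotropic voxel size (mm).
#' @param n_frames reconstructed frames per cycle (>= 4).
#' @param cycle_duration cycle length (s).
#' @param venc velocity encoding limit (cm/s).
#' @param waveform a [flow_waveform()] whose durations sum to
#'   `cycle_duration`.
#' @param edv_slab,esv_slab numeric(2) axial extents (mm) of the ED and ES
#'   masks; voxels whose centers fall inside are in the mask.
#' @param ed_frame,es_frame 1-based frame indices of ED and ES.
#' @param corruption optional list with any of `background_coeffs` (35 x 3
#'   matrix of degree-4 polynomial coefficients in the scaled-coordinate basis
#'   of [polynomial_basis()], m/s), `wrap` (logical; alias velocities beyond
#'   VENC), `noise_sd` (Gaussian velocity noise SD, m/s) and `noise_seed`.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(72L, 6L, 6L), voxel_size = 2.8,
                         n_frames = 40L, cycle_duration = 1.0, venc = 120,
                         waveform = default_waveform(cycle_duration),
                         edv_slab = c(70, 137), esv_slab = c(70, 104),
                         ed_frame = 1L, es_frame = 15L,
                         corruption = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1), n_frames >= 4,
            voxel_size > 0, cycle_duration > 0, venc > 0,
            length(edv_slab) == 2, length(esv_slab) == 2,
            ed_frame >= 1, es_frame >= 1, ed_frame != es_frame)
  if (abs(sum(waveform$duration_s) - cycle_duration) > 1e-8 * cycle_duration)
    vf_stop("waveform segment durations must sum to cycle_duration",
            "vf_config_error")
  wrap_on <- isTRUE(corruption$wrap)
  if (!wrap_on && max(abs(waveform$amplitude_cms)) > venc)
    vf_stop("waveform amplitude exceeds VENC without wrap injection",
            "vf_config_error")
  extent_x <- grid_shape[1] * voxel_size
  for (slab in list(edv_slab, esv_slab))
    if (slab[1] >= slab[2] || slab[1] < 0 || slab[2] > extent_x)
      vf_stop("ED/ES slabs must lie inside the grid", "vf_config_error")
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 n_frames = as.integer(n_frames),
                 cycle_duration = cycle_duration, venc = venc,
                 waveform = waveform, edv_slab = edv_slab,
                 esv_slab = esv_slab, ed_frame = as.integer(ed_frame),
                 es_frame = as.integer(es_frame), corruption = corruption),
            class = "phantom_spec")
}

#' Default slab-phantom waveform
#'
#' Rectangular systolic, E-wave and A-wave pulses separated by a zero-flow
#' diastasis. Amplitudes are chosen so that, with the default geometry of
#' [phantom_spec()], inflow and outflow volumes balance, Direct Flow and its
#' E/A subvolumes are non-empty, and every pre-diastasis frame interval sees
#' at least one mitral-plane pathline crossing.
#'
#' @param cycle_duration cycle length (s).
#' @return A [flow_waveform()].
#' @export
default_waveform <- function(cycle_duration = 1.0) {
  flow_waveform(
    segment = c("systole", "e_wave", "diastasis", "a_wave"),
    duration_s = cycle_duration * c(0.35, 0.15, 0.30, 0.20),
    amplitude_cms = c(6.2, 24.0, 0.0, 10.5),
    shape = "rect")
}

# frame times: uniform grid starting at 0
phantom_frame_times <- function(spec)
  (seq_len(spec$n_frames) - 1) * spec$cycle_duration / spec$n_frames

# extended-index displacement bookkeeping for a spec:
# S over frames 1..n+1; fwd/bwd displacement relative to ED and ES frames.
phantom_kinematics <- function(spec) {
  ft <- phantom_frame_times(spec)
  u <- sample_waveform(spec$waveform, ft, spec$cycle_duration)
  S <- cum_displacement_mm(u, ft, spec$cycle_duration)
  ed <- spec$ed_frame; es <- spec$es_frame
  # extended indices going forward from ED to ES and backward from ED to ES
  es_fwd <- if (es > ed) es else es + spec$n_frames
  if (es_fwd > spec$n_frames + 1)
    vf_stop("ED/ES frame layout must fit in one cycle (ed_frame = 1 supported when es < ed wraps)",
            "vf_config_error")
  d_fwd <- disp_between(S, ed, es_fwd)                      # ED -> next ES
  d_cycle <- disp_between(S, 1, spec$n_frames + 1)          # whole cycle
  d_bwd <- d_cycle - d_fwd                                  # prev ES -> ED
  list(frame_times = ft, u = u, S = S, d_fwd_mm = d_fwd, d_bwd_mm = d_bwd,
       d_cycle_mm = d_cycle)
}

# Slab phantom -----------------------------------------------------------

#' Generate a slab phantom with closed-form ground truth
#'
#' Builds a velocity field that is uniform (`u(t)` along +x) over a support
#' slab covering every pathline excursion and zero in the far field (the far
#' region doubles as static tissue for background-correction testing), the ED
#' and ES slab masks, the valve planes, cardiac timing, and a
#' `phantom_truth` object holding exact component volumes, E/A subvolumes,
#' per-component KE curves and the mid-diastasis frame.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `field`, `seg`, `timing`, `truth`,
#'   `static_mask` and `spec`. If `spec$corruption` is set, `field` is the
#'   corrupted field and `clean_field` holds the uncorrupted one.
#' @export
generate_slab_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$voxel_size
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  kin <- phantom_kinematics(spec)
  cx <- axis_coords(nx, h)

  ed_idx <- which(cx >= spec$edv_slab[1] & cx <= spec$edv_slab[2])
  es_idx <- which(cx >= spec$esv_slab[1] & cx <= spec$esv_slab[2])
  if (!length(ed_idx) || !length(es_idx))
    vf_stop("ED/ES slabs contain no voxel centers", "vf_config_error")

  # pathline excursion range; support slab with 3-voxel margin
  x_min_excur <- cx[min(ed_idx)] - max(kin$d_bwd_mm, 0)
  x_max_excur <- cx[max(ed_idx)] + max(kin$d_fwd_mm, 0)
  if (x_min_excur < 2 * h || x_max_excur > nx * h - 2 * h)
    vf_stop("slab displaced outside grid: enlarge grid or reduce waveform amplitudes",
            "vf_config_error")
  sup_lo <- max(x_min_excur - 3 * h, 0)
  sup_hi <- min(x_max_excur + 3 * h, nx * h)
  support <- cx >= sup_lo & cx <= sup_hi

  values <- array(0, c(nx, ny, nz, 3, spec$n_frames))
  ux <- outer(ifelse(support, 1, 0), kin$u)     # nx x nt
  values[, , , 1, ] <- aperm(array(ux, c(nx, spec$n_frames, ny, nz)),
                             c(1, 3, 4, 2))
  field <- velocity_field(values, voxel_size = h,
                          frame_times = kin$frame_times,
                          cycle_duration = spec$cycle_duration,
                          venc = spec$venc)

  mask3 <- function(idx) {
    m <- array(FALSE, c(nx, ny, nz)); m[idx, , ] <- TRUE; m
  }
  ed_mask <- mask3(ed_idx); es_mask <- mask3(es_idx)
  mid_yz <- c(ny, nz) * h / 2
  x_m <- cx[min(es_idx)] - h / 2        # basal face, shared by ED/ES slabs
  x_a <- cx[max(es_idx)] + h / 2        # apical face of the ES slab
  seg <- lv_segmentation(
    ed_mask, es_mask,
    mitral_plane = vf_plane(c(x_m, mid_yz), c(1, 0, 0)),
    aortic_plane = vf_plane(c(x_a, mid_yz), c(-1, 0, 0)))
  timing <- cardiac_timing(spec$ed_frame, spec$es_frame, spec$cycle_duration)

  # static tissue: one voxel clear of the support slab on both sides
  static_mask <- array(cx < sup_lo - h | cx > sup_hi + h, c(nx, ny, nz))

  truth <- slab_phantom_truth(spec, kin, cx, ed_idx, es_idx, x_m,
                              n_yz = ny * nz)
  out <- list(field = field, seg = seg, timing = timing, truth = truth,
              static_mask = static_mask, spec = spec)
  if (!is.null(spec$corruption)) {
    out$clean_field <- field
    out$field <- corrupt_field(field, spec)
  }
  out
}

# closed-form classification and energetics for the slab phantom
slab_phantom_truth <- function(spec, kin, cx, ed_idx, es_idx, x_m, n_yz) {
  h <- spec$voxel_size
  n <- spec$n_frames
  x <- cx[ed_idx]                               # seed x per axial group
  vox_ml <- h^3 / 1000
  in_es_x <- function(p) {
    i <- nearest_voxel(p, h)
    i >= min(es_idx) & i <= max(es_idx) & i >= 1 & i <= spec$grid_shape[1]
  }
  origin <- x - kin$d_bwd_mm
  dest <- x + kin$d_fwd_mm
  o_in <- in_es_x(origin); d_in <- in_es_x(dest)
  primary <- ifelse(!o_in & !d_in, "DirectFlow",
             ifelse(!o_in & d_in, "RetainedInflow",
             ifelse(o_in & !d_in, "DelayedEjectionFlow", "ResidualVolume")))

  # diastolic sampling: extended frame indices from ES forward to ED (next cycle)
  ed <- spec$ed_frame; es <- spec$es_frame
  ed_ext <- if (ed > es) ed else ed + n
  dia_ext <- es:ed_ext                          # extended indices, ES..ED
  t_ext <- c(kin$frame_times, kin$frame_times + spec$cycle_duration)
  td <- t_ext[dia_ext]
  u_ext <- c(kin$u, kin$u)[dia_ext] * 1000      # mm/s at diastolic frames
  S_ext <- c(kin$S[-length(kin$S)],
             kin$S[-1] + kin$S[length(kin$S)] - kin$S[1])[dia_ext]
  s_rel <- S_ext - S_ext[1]                     # displacement since prev ES

  inflow <- !o_in
  nd <- length(dia_ext)
  # per-group signed distance to mitral plane at diastolic frames
  # crossing bracketing + analytic in-interval solve (position quadratic in t)
  cross_time <- rep(NA_real_, length(x))
  cross_interval <- rep(NA_integer_, length(x))
  approach_e <- rep(FALSE, length(x))           # non-crossers nearest at prev ES
  for (g in which(inflow)) {
    dgj <- (origin[g] + s_rel) - x_m
    j <- which(dgj[-nd] < 0 & dgj[-1] >= 0)[1]
    if (is.na(j)) {
      # never crosses: nearest approach is at prev ES when starting beyond the
      # plane (monotone motion away from it), at ED when never reaching it
      approach_e[g] <- dgj[1] > 0
      next
    }
    dt <- td[j + 1] - td[j]
    a <- (u_ext[j + 1] - u_ext[j]) / (2 * dt)   # half acceleration, mm/s^2
    b <- u_ext[j]
    cc <- dgj[j]
    tr <- if (abs(a) < 1e-12 * max(abs(b), 1)) {
      -cc / b
    } else {
      disc <- sqrt(max(b^2 - 4 * a * cc, 0))
      r <- c((-b + disc) / (2 * a), (-b - disc) / (2 * a))
      r <- r[r >= 0 & r <= dt * (1 + 1e-9)]
      if (length(r)) min(r) else NA_real_
    }
    cross_time[g] <- td[j] + tr
    cross_interval[g] <- j
  }

  # mid-diastasis: diastolic frame interval with fewest crossings, earliest tie
  counts <- tabulate(cross_interval[inflow], nbins = nd - 1)
  j_mid <- argmin_earliest(counts)
  mid_ext <- dia_ext[j_mid]
  mid_frame <- ((mid_ext - 1) %% n) + 1
  t_mid <- td[j_mid]

  # E/A: crossing before the mid-diastasis frame time -> E, else A;
  # inflow that never reaches the plane is closest to it at ED -> A
  wave <- rep(NA_character_, length(x))
  wave[inflow] <- ifelse(is.na(cross_time[inflow]),
                         ifelse(approach_e[inflow], "E", "A"),
                         ifelse(cross_time[inflow] < t_mid, "E", "A"))

  groups <- list(
    DirectFlow = primary == "DirectFlow",
    RetainedInflow = primary == "RetainedInflow",
    DelayedEjectionFlow = primary == "DelayedEjectionFlow",
    ResidualVolume = primary == "ResidualVolume",
    DirectFlowE = primary == "DirectFlow" & !is.na(wave) & wave == "E",
    DirectFlowA = primary == "DirectFlow" & !is.na(wave) & wave == "A",
    RetainedInflowE = primary == "RetainedInflow" & !is.na(wave) & wave == "E",
    RetainedInflowA = primary == "RetainedInflow" & !is.na(wave) & wave == "A")
  counts_vox <- vapply(groups, sum, integer(1)) * n_yz
  volumes_ml <- counts_vox * vox_ml

  # KE curves, mJ: uniform speed u(t_k) for every member pathline
  ke <- outer(volumes_ml * 1e-6, kin$u^2) * 0.5 * VF_BLOOD_DENSITY * 1000
  dimnames(ke) <- list(names(groups), NULL)

  structure(list(
    component_volumes_ml = volumes_ml[1:4],
    e_a_split_ml = volumes_ml[5:8],
    component_counts_vox = counts_vox,
    ke_curves_mJ = ke,
    mid_diastasis_frame = mid_frame,
    crossing_counts = counts,
    d_fwd_mm = kin$d_fwd_mm, d_bwd_mm = kin$d_bwd_mm,
    u_frames_ms = kin$u,
    edv_ml = length(ed_idx) * n_yz * vox_ml,
    esv_ml = length(es_idx) * n_yz * vox_ml,
    rho = VF_BLOOD_DENSITY,
    seed_groups = data.frame(x = x, origin = origin, dest = dest,
                             primary = primary, wave = wave,
                             cross_time = cross_time)),
    class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("phantom_truth (ml):\n")
  print(round(c(x$component_volumes_ml, x$e_a_split_ml), 3))
  cat(sprintf("EDV %.2f ml; D_fwd %.1f mm; D_bwd %.1f mm; mid-diastasis frame %d\n",
              x$edv_ml, x$d_fwd_mm, x$d_bwd_mm, x$mid_diastasis_frame))
  invisible(x)
}

#' Draw a randomized slab-phantom specification
#'
#' Samples waveform amplitudes, segment durations, cycle length and slab
#' geometry, then sizes the grid so every pathline excursion stays inside it.
#' Used for property-based validation of the pipeline against closed-form
#' truth over many configurations.
#'
#' @param seed integer RNG seed.
#' @param n_frames reconstructed frames per cycle.
#' @param voxel_size voxel size (mm).
#' @return A [phantom_spec()].
#' @export
random_slab_spec <- function(seed, n_frames = 40L, voxel_size = 2.8) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  h <- voxel_size
  Tc <- runif(1, 0.8, 1.2)
  fr <- c(runif(1, 0.30, 0.40), runif(1, 0.10, 0.20), runif(1, 0.20, 0.30))
  fr <- c(fr, 1 - sum(fr))
  wf <- flow_waveform(
    segment = c("systole", "e_wave", "diastasis", "a_wave"),
    duration_s = Tc * fr,
    amplitude_cms = c(runif(1, 5, 18), runif(1, 12, 30), 0, runif(1, 4, 15)),
    shape = "rect")
  es_frame <- as.integer(round(fr[1] * n_frames))
  ed_len <- sample(14:24, 1)            # ED slab length, voxels
  es_len <- sample(seq(8L, ed_len - 4L), 1)

  # displacement needed to size the grid: probe with a 1-voxel dummy grid
  ft <- (seq_len(n_frames) - 1) * Tc / n_frames
  u <- sample_waveform(wf, ft, Tc)
  S <- cum_displacement_mm(u, ft, Tc)
  d_cycle <- S[n_frames + 1]
  d_fwd <- S[es_frame + 1]
  d_bwd <- d_cycle - d_fwd
  nx <- ceiling((d_bwd + ed_len * h + d_fwd) / h) + 10L
  ed_lo <- (ceiling(d_bwd / h) + 4) * h + runif(1, 0, h)
  phantom_spec(grid_shape = c(nx, 4L, 4L), voxel_size = h,
               n_frames = n_frames, cycle_duration = Tc, venc = 120,
               waveform = wf,
               edv_slab = c(ed_lo, ed_lo + ed_len * h),
               esv_slab = c(ed_lo, ed_lo + es_len * h),
               ed_frame = 1L, es_frame = es_frame + 1L)
}

# Rotation phantom -------------------------------------------------------

#' Generate a rigid-body rotation phantom
#'
#' Velocity field v = omega x r about an axis through the grid center along
#' z, identical at every frame. Because the field is linear in position,
#' trilinear interpolation reproduces it exactly, so this phantom isolates
#' the time-integration error of the pathline tracer: a seed at radius r
#' moves on a circle of radius r at angular rate omega.
#'
#' @param omega angular speed (rad/s).
#' @param spec a [phantom_spec()] providing grid, timing and VENC.
#' @return A [velocity_field()].
#' @export
generate_rotation_phantom <- function(omega, spec) {
  stopifnot(is.finite(omega), inherits(spec, "phantom_spec"))
  h <- spec$voxel_size
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  ctr <- c(nx, ny) * h / 2
  cxm <- axis_coords(nx, h) - ctr[1]
  cym <- axis_coords(ny, h) - ctr[2]
  # v in m/s such that velocity in mm/s is omega x r(mm)
  vx <- outer(rep(1, nx), -omega * cym) / 1000      # nx x ny
  vy <- outer(omega * cxm, rep(1, ny)) / 1000
  values <- array(0, c(nx, ny, nz, 3, spec$n_frames))
  values[, , , 1, ] <- array(vx, c(nx, ny, nz, spec$n_frames))
  values[, , , 2, ] <- array(vy, c(nx, ny, nz, spec$n_frames))
  velocity_field(values, voxel_size = h,
                 frame_times = phantom_frame_times(spec),
                 cycle_duration = spec$cycle_duration, venc = spec$venc)
}

# Corruption -------------------------------------------------------------

#' Corrupt a velocity field with background offsets, wraps and noise
#'
#' Applies, in order: a degree-4 polynomial background offset per component,
#' phase-wrap aliasing (any sample beyond the VENC is folded by multiples of
#' 2 VENC back into range), and Gaussian noise. The input field is not
#' modified. This injects exactly the artifacts the preprocessing stage is
#' designed to remove.
#'
#' @param field a [velocity_field()].
#' @param spec a [phantom_spec()] whose `corruption` list is used.
#' @return A new, corrupted [velocity_field()].
#' @export
corrupt_field <- function(field, spec) {
  cor <- spec$corruption
  if (is.null(cor)) vf_stop("spec has no corruption block", "vf_config_error")
  values <- field$values
  d <- dim(values)
  if (!is.null(cor$background_coeffs)) {
    B <- polynomial_basis(grid_scaled_coords(d[1:3], field$voxel_size), 4)
    off <- B %*% cor$background_coeffs          # n_vox x 3
    for (ci in 1:3) {
      off_vol <- array(off[, ci], d[1:3])
      for (f in seq_len(d[5])) values[, , , ci, f] <- values[, , , ci, f] + off_vol
    }
  }
  if (isTRUE(cor$wrap)) {
    v <- venc_ms(field)
    w <- values
    # fold into (-venc, venc]; repeat handles multi-wrap amplitudes
    while (any(abs(w) > v)) {
      over <- abs(w) > v
      w[over] <- w[over] - 2 * v * sign(w[over])
    }
    values <- w
  }
  if (!is.null(cor$noise_sd) && cor$noise_sd > 0) {
    if (!is.null(cor$noise_seed)) set.seed(cor$noise_seed)
    values <- values + array(rnorm(length(values), sd = cor$noise_sd), d)
  }
  velocity_field(values, field$voxel_size, field$frame_times,
                 field$cycle_duration, field$venc)
}
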