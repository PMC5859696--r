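# Lagrangian pathline tracing through the periodic velocity field.
#
# Positions are in mm, velocities in m/s (converted to mm/s inside the
# integrator), times in s. Integration is fixed-step classical RK4 with steps
# aligned to the reconstructed frame grid: each frame interval is split into
# round(1 / step_fraction) equal substeps. Alignment matters: the interpolated
# field is piecewise linear in time with kinks at frame times, and RK4
# integrates a polynomial of degree <= 3 exactly, so on spatially uniform
# fields the tracer reproduces the exact displacement integral to floating
# point.

# bracketing frames and interpolation weight for (possibly wrapped) time t
frame_bracket <- function(field, t) {
  ft <- field$frame_times
  Tc <- field$cycle_duration
  n <- length(ft)
  tau <- (t - ft[1]) %% Tc + ft[1]
  k <- findInterval(tau, ft)
  if (k >= n) {
    dt <- ft[1] + Tc - ft[n]
    list(f1 = n, f2 = 1L, w = (tau - ft[n]) / dt)
  } else {
    list(f1 = k, f2 = k + 1L, w = (tau - ft[k]) / (ft[k + 1] - ft[k]))
  }
}

#' Interpolate the velocity field at arbitrary positions and time
#'
#' Trilinear in space, linear in time with periodic wrap across the cycle
#' boundary. Positions outside the grid's voxel-center bounding box return
#' `NA` rows (the caller decides how to treat out-of-field queries).
#'
#' @param field a [velocity_field()].
#' @param positions N x 3 matrix (or length-3 vector) of positions (mm).
#' @param time time (s); wrapped into the cycle.
#' @return N x 3 matrix of velocities (m/s); `NA` rows where out of field.
#' @export
interpolate_velocity <- function(field, positions, time) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  d <- dim(field$values)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  h <- field$voxel_size
  N <- nrow(positions)
  g <- positions / h - 0.5                   # corner-space coords, 0-based
  eps <- 1e-9                                # voxel-scale boundary tolerance
  inside <- g[, 1] >= -eps & g[, 1] <= nx - 1 + eps &
            g[, 2] >= -eps & g[, 2] <= ny - 1 + eps &
            g[, 3] >= -eps & g[, 3] <= nz - 1 + eps
  inside[is.na(inside)] <- FALSE
  out <- matrix(NA_real_, N, 3)
  if (!any(inside)) return(out)
  gi <- g[inside, , drop = FALSE]
  lim <- matrix(rep(c(nx, ny, nz) - 1, each = nrow(gi)), ncol = 3)
  gi <- pmin(pmax(gi, 0), lim)
  i0 <- pmin(pmax(floor(gi), 0), lim - 1)
  w <- gi - i0
  br <- frame_bracket(field, time)
  vals <- field$values
  nvox <- nx * ny * nz
  acc <- matrix(0, nrow(gi), 3)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    base <- (i0[, 1] + dx) + nx * ((i0[, 2] + dy) + ny * (i0[, 3] + dz)) + 1
    for (ci in 1:3) {
      off <- nvox * ((ci - 1) + 3 * (br$f1 - 1))
      v1 <- vals[base + off]
      if (br$w > 0) {
        off2 <- nvox * ((ci - 1) + 3 * (br$f2 - 1))
        v1 <- (1 - br$w) * v1 + br$w * vals[base + off2]
      }
      acc[, ci] <- acc[, ci] + wt * v1
    }
  }
  out[inside, ] <- acc
  out
}

# one vectorized RK4 step for active pathlines; returns updated state
rk4_step <- function(field, P, t, dt, active) {
  idx <- which(active)
  if (!length(idx)) return(list(P = P, left_fov = logical(nrow(P)),
                                unreliable = logical(nrow(P))))
  vel <- function(pos, tt) interpolate_velocity(field, pos, tt) * 1000  # mm/s
  P0 <- P[idx, , drop = FALSE]
  k1 <- vel(P0, t)
  k2 <- vel(P0 + dt / 2 * k1, t + dt / 2)
  k3 <- vel(P0 + dt / 2 * k2, t + dt / 2)
  k4 <- vel(P0 + dt * k3, t + dt)
  newP <- P0 + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  stage_na <- rowSums(is.na(k1) + is.na(k2) + is.na(k3) + is.na(k4)) > 0
  stage_nan <- rowSums(is.nan(k1) | is.nan(k2) | is.nan(k3) | is.nan(k4)) > 0
  h <- field$voxel_size
  gd <- field_grid_dim(field)
  gn <- newP / h - 0.5
  eps <- 1e-9
  end_out <- gn[, 1] < -eps | gn[, 1] > gd[1] - 1 + eps |
             gn[, 2] < -eps | gn[, 2] > gd[2] - 1 + eps |
             gn[, 3] < -eps | gn[, 3] > gd[3] - 1 + eps
  end_out[is.na(end_out)] <- TRUE
  bad <- stage_na | end_out
  ok <- !bad
  P[idx[ok], ] <- newP[ok, , drop = FALSE]
  left <- unrel <- logical(nrow(P))
  left[idx[bad & !stage_nan]] <- TRUE
  unrel[idx[stage_nan]] <- TRUE
  list(P = P, left_fov = left, unreliable = unrel)
}

# integrate a set of seeds through a sequence of times, recording positions
# at each time; n_sub RK4 substeps per interval
integrate_over_times <- function(field, seeds, times, n_sub) {
  N <- nrow(seeds)
  M <- length(times)
  pos <- array(NA_real_, c(N, 3, M))
  pos[, , 1] <- seeds
  P <- seeds
  active <- rep(TRUE, N)
  left_fov <- unreliable <- rep(FALSE, N)
  for (m in seq_len(M - 1)) {
    dt <- (times[m + 1] - times[m]) / n_sub
    for (s in seq_len(n_sub)) {
      st <- rk4_step(field, P, times[m] + (s - 1) * dt, dt, active)
      P <- st$P
      left_fov <- left_fov | st$left_fov
      unreliable <- unreliable | st$unreliable
      active <- active & !st$left_fov & !st$unreliable
    }
    pos[, , m + 1] <- P
  }
  list(positions = pos, left_fov = left_fov, unreliable = unreliable)
}

#' Trace a single pathline between two times
#'
#' Fixed-step RK4 from `t0` to `t1` (backwards when `t1 < t0`), sampling the
#' periodic field. Positions are recorded at `t0`, at every reconstructed
#' frame time strictly between `t0` and `t1`, and at `t1`. If the trajectory
#' exits the grid it freezes at the last inside position and is flagged.
#'
#' @param field a [velocity_field()].
#' @param seed length-3 start position (mm).
#' @param t0,t1 start and end times (s); `|t1 - t0|` at most one cycle.
#' @param step integration step (s); defaults to a quarter of the mean frame
#'   interval.
#' @return Matrix of positions (rows = recorded times) with attributes
#'   `times`, `left_fov`, `unreliable`.
#' @export
trace_pathline <- function(field, seed, t0, t1, step = NULL) {
  Tc <- field$cycle_duration
  if (abs(t1 - t0) > Tc + 1e-12)
    vf_stop("trace interval exceeds one cardiac cycle", "vf_config_error")
  frame_dt <- Tc / n_frames(field)
  if (is.null(step)) step <- frame_dt / 4
  stopifnot(step > 0)
  # frame times crossed, as an unwrapped increasing/decreasing sequence
  ft <- field$frame_times
  all_t <- sort(unique(c(ft - Tc, ft, ft + Tc)))
  if (t1 >= t0) inner <- all_t[all_t > t0 + 1e-12 & all_t < t1 - 1e-12]
  else inner <- rev(all_t[all_t < t0 - 1e-12 & all_t > t1 + 1e-12])
  times <- c(t0, inner, t1)
  n_sub <- max(1L, ceiling(max(abs(diff(times)), 0) / step - 1e-9))
  res <- integrate_over_times(field, matrix(seed, 1, 3), times, n_sub)
  out <- matrix(res$positions[1, , ], ncol = 3, byrow = TRUE)
  attr(out, "times") <- times
  attr(out, "left_fov") <- res$left_fov[1]
  attr(out, "unreliable") <- res$unreliable[1]
  out
}

#' Emit and trace one pathline per end-diastolic voxel
#'
#' Seeds a pathline at the center of every ED-mask voxel, traces it forwards
#' from ED to the next end-systole (through systole) and backwards from ED to
#' the previous end-systole (through diastole, wrapping the periodic time
#' axis), and assembles the sampled trajectories. Each pathline represents a
#' blood volume equal to the voxel volume.
#'
#' @param field a (preprocessed) [velocity_field()].
#' @param seg an [lv_segmentation()].
#' @param timing a [cardiac_timing()].
#' @param step_fraction RK4 step as a fraction of the frame interval
#'   (default 0.25).
#' @return A `pathline_set`: seed positions, a `[n_path, 3, n_samples]`
#'   position array sampled at every frame time from previous ES through ED
#'   to next ES, the sample times (s, ED at 0), the reconstructed frame index
#'   of each sample, per-pathline status flags, and the represented volume
#'   per pathline (ml).
#' @export
emit_all <- function(field, seg, timing, step_fraction = 0.25) {
  if (!any(seg$ed_mask))
    vf_stop("ED mask is empty", "vf_config_error")
  d <- field_grid_dim(field)
  if (!identical(as.integer(dim(seg$ed_mask)), as.integer(d)))
    vf_stop("segmentation grid does not match field grid", "vf_io_error")
  h <- field$voxel_size
  idx <- which(seg$ed_mask, arr.ind = TRUE)
  seeds <- (idx - 0.5) * h
  ft <- field$frame_times
  n <- length(ft)
  Tc <- field$cycle_duration
  ed <- timing$ed_frame; es <- timing$es_frame
  # forward frames ED+1..ES (cyclic), times unwrapped upward from t_ed
  fwd_frames <- (seq(ed, length.out = n) - 1) %% n + 1
  fwd_frames <- fwd_frames[-1][seq_len((es - ed) %% n)]
  tprev <- ft[ed]; wrap <- 0
  fwd_times <- vapply(fwd_frames, function(f) {
    tt <- ft[f] + wrap * Tc
    if (tt <= tprev) { wrap <<- wrap + 1; tt <- ft[f] + wrap * Tc }
    tprev <<- tt
    tt
  }, numeric(1))
  # backward frames ED-1..ES (cyclic), times unwrapped downward from t_ed
  bwd_frames <- (seq(ed, by = -1, length.out = n) - 1) %% n + 1
  bwd_frames <- bwd_frames[-1][seq_len((ed - es) %% n)]
  tprev <- ft[ed]; wrap <- 0
  bwd_times <- vapply(bwd_frames, function(f) {
    tt <- ft[f] - wrap * Tc
    if (tt >= tprev) { wrap <<- wrap + 1; tt <- ft[f] - wrap * Tc }
    tprev <<- tt
    tt
  }, numeric(1))

  n_sub <- max(1L, round(1 / step_fraction))
  fwd <- integrate_over_times(field, seeds, c(ft[ed], fwd_times), n_sub)
  bwd <- integrate_over_times(field, seeds, c(ft[ed], bwd_times), n_sub)

  # assemble prev ES .. ED .. next ES, times relative to ED
  nb <- length(bwd_times); nf <- length(fwd_times)
  M <- nb + 1 + nf
  positions <- array(NA_real_, c(nrow(seeds), 3, M))
  positions[, , seq_len(nb)] <- bwd$positions[, , (nb + 1):2]
  positions[, , nb + 1] <- seeds
  positions[, , nb + 1 + seq_len(nf)] <- fwd$positions[, , -1]
  times <- c(rev(bwd_times), ft[ed], fwd_times) - ft[ed]
  frame_idx <- c(rev(bwd_frames), ed, fwd_frames)
  flags <- rep("ok", nrow(seeds))
  flags[fwd$left_fov | bwd$left_fov] <- "left_fov"
  flags[fwd$unreliable | bwd$unreliable] <- "unreliable_voxel"
  n_flag <- sum(flags != "ok")
  if (n_flag > 0)
    message(sprintf("emit_all: %d of %d pathlines flagged (%s)", n_flag,
                    nrow(seeds),
                    paste(names(table(flags[flags != "ok"])), collapse = ", ")))
  structure(list(
    seeds = seeds,
    positions = positions,
    times = times,
    frame_idx = as.integer(frame_idx),
    ed_index = nb + 1L,
    flags = flags,
    voxel_size = h,
    voxel_volume_ml = h^3 / 1000,
    ed_frame = ed, es_frame = es,
    n_frames = n, cycle_duration = Tc
  ), class = "pathline_set")
}

#' @export
print.pathline_set <- function(x, ...) {
  cat(sprintf(
    "pathline_set: %d pathlines (%.3f ml each, EDV %.1f ml), %d samples/trajectory, %d flagged\n",
    nrow(x$seeds), x$voxel_volume_ml, nrow(x$seeds) * x$voxel_volume_ml,
    dim(x$positions)[3], sum(x$flags != "ok")))
  invisible(x)
}

#' Total blood volume represented by a pathline set
#'
#' @param paths a `pathline_set`.
#' @return Volume in ml (pathline count times voxel volume = segmented EDV).
#' @export
represented_volume <- function(paths) nrow(paths$seeds) * paths$voxel_volume_ml
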