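# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; nothing is read from disk.

# memoised default slab phantom + pipeline run (several files use it)
.fixtures <- new.env(parent = emptyenv())

default_phantom <- function() {
  if (is.null(.fixtures$ph)) .fixtures$ph <- generate_slab_phantom(phantom_spec())
  .fixtures$ph
}

default_run <- function() {
  if (is.null(.fixtures$run)) {
    ph <- default_phantom()
    .fixtures$run <- suppressMessages(
      run_flow_analysis(ph$field, ph$seg, ph$timing, unwrap = FALSE))
  }
  .fixtures$run
}

# a spatially uniform steady field, handy for exactness checks
uniform_field <- function(v = c(0.1, 0, 0), grid = c(60, 6, 6), h = 2.8,
                          n_frames = 8, cycle = 2.0) {
  vals <- array(0, c(grid, 3, n_frames))
  for (ci in 1:3) vals[, , , ci, ] <- v[ci]
  velocity_field(vals, h, (seq_len(n_frames) - 1) * cycle / n_frames,
                 cycle, 120)
}

# phantom whose waveform exceeds VENC so wrap injection fires; calibrated so
# true inter-frame jumps stay below VENC (recoverable) and wrapped samples
# fall where double arithmetic makes fold + unfold exact
wrap_phantom_spec <- function() {
  wf <- flow_waveform(c("systole", "e_spike", "diastasis", "a_wave"),
                      c(0.35, 0.125, 0.325, 0.2), c(10, 150, 0, 8),
                      shape = c("rect", "sine", "rect", "rect"))
  phantom_spec(grid_shape = c(100L, 4L, 4L), venc = 125, waveform = wf,
               edv_slab = c(160, 215), esv_slab = c(160, 200),
               corruption = list(wrap = TRUE))
}

# Independent brute-force classification oracle: per-seed loops, trapezoid
# displacement integrals, nearest-voxel endpoint lookup. Same arithmetic as
# the definitions, entirely separate code path from both the closed-form
# truth and the RK4 pipeline.
brute_force_counts <- function(ph) {
  spec <- ph$spec
  h <- spec$voxel_size
  ft <- ph$field$frame_times
  n <- spec$n_frames
  Tc <- spec$cycle_duration
  u <- sample_waveform(spec$waveform, ft, Tc) * 1000   # mm/s
  t_ext <- c(ft, Tc)
  u_ext <- c(u, u[1])
  # displacement integral over [t_ext[a], t_ext[b]] by explicit loop
  disp <- function(a, b) {
    s <- 0
    for (k in a:(b - 1)) s <- s + (u_ext[k] + u_ext[k + 1]) / 2 * (t_ext[k + 1] - t_ext[k])
    s
  }
  ed <- spec$ed_frame; es <- spec$es_frame
  d_fwd <- disp(ed, es)
  d_bwd <- disp(es, n + 1)
  es_mask <- ph$seg$es_mask
  seeds <- which(ph$seg$ed_mask, arr.ind = TRUE)
  counts <- c(DirectFlow = 0, RetainedInflow = 0, DelayedEjectionFlow = 0,
              ResidualVolume = 0)
  in_es <- function(p) {
    i <- floor(p / h) + 1
    if (i < 1 || i > dim(es_mask)[1]) return(FALSE)
    es_mask[i, 1, 1]   # slab masks are uniform over y, z
  }
  for (r in seq_len(nrow(seeds))) {
    x <- (seeds[r, 1] - 0.5) * h
    o <- in_es(x - d_bwd)
    d <- in_es(x + d_fwd)
    lab <- if (!o && !d) "DirectFlow" else if (!o && d) "RetainedInflow"
      else if (o && !d) "DelayedEjectionFlow" else "ResidualVolume"
    counts[lab] <- counts[lab] + 1
  }
  counts
}

# minimal hand-built pathline set (one pathline) for boundary-rule tests
tiny_pathline_set <- function(xs, times) {
  M <- length(times)
  pos <- array(0, c(1, 3, M))
  pos[1, 1, ] <- xs
  pos[1, 2, ] <- 1.4; pos[1, 3, ] <- 1.4
  structure(list(seeds = matrix(c(xs[M], 1.4, 1.4), 1, 3),
                 positions = pos, times = times,
                 frame_idx = seq_len(M), ed_index = M,
                 flags = "ok", voxel_size = 2.8,
                 voxel_volume_ml = 2.8^3 / 1000,
                 ed_frame = M, es_frame = 1L, n_frames = M,
                 cycle_duration = 1),
            class = "pathline_set")
}
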