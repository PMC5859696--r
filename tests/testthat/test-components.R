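test_that("endpoint combinations map to the four components", {
  ph <- default_phantom()
  run <- default_run()
  labels <- run$labels
  # cross-check every pathline against the truth's per-seed table via seed x
  truth_tab <- ph$truth$seed_groups
  seed_x <- run$paths$seeds[, 1]
  expected <- truth_tab$primary[match(seed_x, truth_tab$x)]
  expect_equal(labels$primary, expected)
  # and the four definitions hold by construction of the truth table:
  # origin/destination outside-ES status determines the label
  h <- ph$spec$voxel_size
  es_rng <- range(which(ph$seg$es_mask[, 1, 1]))
  in_es <- function(p) { i <- floor(p / h) + 1; i >= es_rng[1] & i <= es_rng[2] }
  M <- dim(run$paths$positions)[3]
  o_in <- in_es(run$paths$positions[, 1, 1])
  d_in <- in_es(run$paths$positions[, 1, M])
  expect_true(all(labels$primary[!o_in & !d_in] == "DirectFlow"))
  expect_true(all(labels$primary[!o_in & d_in] == "RetainedInflow"))
  expect_true(all(labels$primary[o_in & !d_in] == "DelayedEjectionFlow"))
  expect_true(all(labels$primary[o_in & d_in] == "ResidualVolume"))
})

test_that("pipeline component volumes equal phantom truth exactly", {
  ph <- default_phantom()
  run <- default_run()
  expect_equal(run$results$summary$volume_ml,
               unname(c(ph$truth$component_volumes_ml, ph$truth$e_a_split_ml)))
  expect_equal(sum(run$results$summary$volume_ml[1:4]), ph$truth$edv_ml)
})

test_that("minimum-crossing frame selection takes the earliest minimum", {
  expect_equal(ventriflow:::argmin_earliest(c(12, 3, 0, 2, 9)), 3)
  expect_equal(ventriflow:::argmin_earliest(c(5, 0, 0, 7)), 2)
  expect_equal(ventriflow:::argmin_earliest(c(4, 4, 4)), 1)
})

test_that("mid-diastasis lands in the zero-flow diastasis segment on the default phantom", {
  ph <- default_phantom()
  run <- default_run()
  # diastasis spans [0.5, 0.8) s; frames are 0.025 s apart starting at 0
  t_mid <- ph$field$frame_times[run$timing$mid_diastasis_frame]
  expect_gte(t_mid, 0.5)
  expect_lt(t_mid, 0.8)
  expect_equal(run$timing$mid_diastasis_frame, ph$truth$mid_diastasis_frame)
  # every E-wave diastolic interval (frames with flow, 0.35 <= t < 0.5, plus
  # the ramp-down into diastasis) saw at least one crossing; the first
  # purely-diastasis interval saw none
  counts <- attr(run$timing, "crossing_counts")
  n_e <- sum(ph$field$frame_times >= 0.35 & ph$field$frame_times < 0.5)
  expect_true(all(counts[seq_len(n_e)] > 0))
  expect_equal(counts[n_e + 1], 0)
})

test_that("a crossing exactly at the mid-diastasis frame time is A-wave inflow", {
  # hand-built pathline reaching the plane x = 0 exactly at the sample that
  # is declared mid-diastasis
  paths <- tiny_pathline_set(xs = c(-2, -1, 0, 1, 2),
                             times = c(-0.4, -0.3, -0.2, -0.1, 0))
  seg <- list(mitral_plane = vf_plane(c(0, 0, 0), c(1, 0, 0)))
  timing <- cardiac_timing(5L, 1L, 1.0, mid_diastasis_frame = 3L)
  attr(timing, "mid_diastasis_sample") <- 3L
  labels <- data.frame(pathline = 1L, primary = "DirectFlow",
                       wave = NA_character_, flag = "ok",
                       crossing_time = NA_real_, crossing_detected = NA)
  out <- split_e_a(paths, labels, seg, timing)
  expect_equal(out$crossing_time, -0.2)
  expect_equal(out$wave, "A")
  expect_true(out$crossing_detected)
  # one sample earlier than mid-diastasis: E
  timing2 <- cardiac_timing(5L, 1L, 1.0, mid_diastasis_frame = 4L)
  attr(timing2, "mid_diastasis_sample") <- 4L
  out2 <- split_e_a(paths, labels, seg, timing2)
  expect_equal(out2$wave, "E")
})

test_that("inflow without a detected crossing is assigned by nearest approach and reported", {
  # pathline that approaches x = 0 from below but never reaches it
  paths <- tiny_pathline_set(xs = c(-8, -5, -3, -2, -1.5),
                             times = c(-0.4, -0.3, -0.2, -0.1, 0))
  seg <- list(mitral_plane = vf_plane(c(0, 0, 0), c(1, 0, 0)))
  timing <- cardiac_timing(5L, 1L, 1.0, mid_diastasis_frame = 3L)
  attr(timing, "mid_diastasis_sample") <- 3L
  labels <- data.frame(pathline = 1L, primary = "RetainedInflow",
                       wave = NA_character_, flag = "ok",
                       crossing_time = NA_real_, crossing_detected = NA)
  out <- split_e_a(paths, labels, seg, timing)
  expect_false(out$crossing_detected)
  expect_equal(out$crossing_time, 0)   # closest at ED
  expect_equal(out$wave, "A")
})

test_that("E/A subvolumes sum to their parent components on random phantoms", {
  for (s in c(41, 42)) {
    ph <- generate_slab_phantom(random_slab_spec(s))
    run <- suppressMessages(run_flow_analysis(ph$field, ph$seg, ph$timing,
                                              unwrap = FALSE))
    v <- setNames(run$results$summary$volume_ml, run$results$summary$component)
    expect_equal(unname(v["DirectFlowE"] + v["DirectFlowA"]),
                 unname(v["DirectFlow"]))
    expect_equal(unname(v["RetainedInflowE"] + v["RetainedInflowA"]),
                 unname(v["RetainedInflow"]))
  }
})

test_that("inflow-outflow discrepancy uses the symmetric mean denominator and the 15% gate", {
  lab <- function(n_df, n_ri, n_def, n_rv) {
    data.frame(primary = rep(c("DirectFlow", "RetainedInflow",
                               "DelayedEjectionFlow", "ResidualVolume"),
                             c(n_df, n_ri, n_def, n_rv)),
               flag = "ok", crossing_detected = TRUE)
  }
  # inflow 74 ml, outflow 70 ml with 1-ml pathlines: 4/72 = 5.6%, pass
  qc <- qc_inflow_outflow(lab(10, 64, 60, 5), 1)
  expect_equal(qc$inflow_ml, 74)
  expect_equal(qc$outflow_ml, 70)
  expect_equal(round(qc$discrepancy_pct, 1), 5.6)
  expect_true(qc$pass)
  # inflow = outflow: 0%, pass
  qc0 <- qc_inflow_outflow(lab(10, 50, 50, 0), 1)
  expect_equal(qc0$discrepancy_pct, 0)
  expect_true(qc0$pass)
  # inflow 100, outflow 80: 20/90 = 22.2%, fail
  qc2 <- qc_inflow_outflow(lab(40, 60, 40, 0), 1)
  expect_equal(round(qc2$discrepancy_pct, 1), 22.2)
  expect_false(qc2$pass)
  # configurable threshold
  expect_true(qc_inflow_outflow(lab(40, 60, 40, 0), 1,
                                max_discrepancy_pct = 25)$pass)
  # degenerate: no inflow and no outflow
  qcd <- qc_inflow_outflow(lab(0, 0, 0, 10), 1)
  expect_false(qcd$pass)
  expect_true(is.na(qcd$discrepancy_pct))
  expect_match(qcd$reason, "undefined")
})
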