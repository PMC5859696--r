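test_that("zero waveform leaves all blood as Residual Volume with zero KE", {
  # with no flow the LV never changes volume, so the ED and ES masks coincide
  wf <- flow_waveform("flat", 1.0, 0, "rect")
  spec <- phantom_spec(grid_shape = c(30L, 4L, 4L), waveform = wf,
                       edv_slab = c(28, 56), esv_slab = c(28, 56))
  ph <- generate_slab_phantom(spec)
  expect_equal(unname(ph$truth$component_volumes_ml["ResidualVolume"]),
               ph$truth$edv_ml)
  expect_equal(sum(ph$truth$component_volumes_ml[1:3]), 0)
  expect_true(all(ph$truth$ke_curves_mJ == 0))
  # pipeline agrees: every pathline is a fixed point, all Residual Volume,
  # and the E/A stage correctly refuses (no inflow exists)
  paths <- emit_all(ph$field, ph$seg, ph$timing)
  expect_true(all(paths$positions[, 1, 1] == paths$seeds[, 1]))
  labels <- classify_pathlines(paths, ph$seg)
  expect_true(all(labels$primary == "ResidualVolume"))
  expect_error(find_mid_diastasis(paths, ph$seg, ph$timing, labels),
               class = "vf_timing_error")
})

test_that("symmetric waveform with ES = distal half of ED matches the slab-overlap closed form", {
  # constant speed over the whole cycle: D_fwd = D_bwd = 28 mm = half the ED
  # slab length; ES slab is the distal (high-x) half of the ED slab
  wf <- flow_waveform(c("systole", "diastole"), c(0.5, 0.5), c(5.6, 5.6),
                      "rect")
  spec <- phantom_spec(grid_shape = c(60L, 4L, 4L), waveform = wf,
                       edv_slab = c(56, 112), esv_slab = c(84, 112),
                       ed_frame = 1L, es_frame = 21L)
  ph <- generate_slab_phantom(spec)
  expect_equal(ph$truth$d_fwd_mm, 28)
  expect_equal(ph$truth$d_bwd_mm, 28)
  # independent closed form, derived by hand for this geometry: with x the
  # seed center, ES spans [s_lo, s_hi] +- h/2 by nearest-voxel lookup:
  h <- 2.8
  cx <- (seq_len(60) - 0.5) * h
  seeds_x <- cx[cx >= 56 & cx <= 112]
  es_centers <- cx[cx >= 84 & cx <= 112]
  in_es <- function(p) p >= min(es_centers) - h / 2 & p < max(es_centers) + h / 2
  df_expected <- sum(!in_es(seeds_x - 28) & !in_es(seeds_x + 28)) * 16
  expect_equal(unname(ph$truth$component_counts_vox["DirectFlow"]),
               df_expected)
  # brute-force per-voxel endpoint check over all seeds equals the closed form
  bf <- brute_force_counts(ph)
  expect_equal(unname(bf), unname(ph$truth$component_counts_vox[1:4]))
})

test_that("brute-force endpoint classification equals closed-form truth on random configurations", {
  for (s in c(11, 12, 13, 14, 15)) {
    ph <- generate_slab_phantom(random_slab_spec(s))
    bf <- brute_force_counts(ph)
    expect_equal(unname(bf), unname(ph$truth$component_counts_vox[1:4]),
                 info = sprintf("seed %d", s))
  }
})

test_that("truth volumes partition the EDV and E/A subvolumes partition their parents", {
  for (s in c(21, 22, 23)) {
    tr <- generate_slab_phantom(random_slab_spec(s))$truth
    expect_equal(sum(tr$component_volumes_ml), tr$edv_ml)
    expect_equal(unname(tr$e_a_split_ml["DirectFlowE"] +
                          tr$e_a_split_ml["DirectFlowA"]),
                 unname(tr$component_volumes_ml["DirectFlow"]))
    expect_equal(unname(tr$e_a_split_ml["RetainedInflowE"] +
                          tr$e_a_split_ml["RetainedInflowA"]),
                 unname(tr$component_volumes_ml["RetainedInflow"]))
  }
})

test_that("truth KE of the union of components is (1/2) rho EDV u(t)^2 at every frame", {
  ph <- default_phantom()
  tr <- ph$truth
  union_ke <- colSums(tr$ke_curves_mJ[1:4, ])
  expected <- 0.5 * tr$rho * (tr$edv_ml * 1e-6) * tr$u_frames_ms^2 * 1000
  expect_equal(union_ke, expected, tolerance = 1e-12)
})

test_that("doubling waveform amplitudes rescales truth KE by 4 and stays exact for the pipeline", {
  spec <- phantom_spec()
  wf2 <- spec$waveform
  wf2$amplitude_cms <- wf2$amplitude_cms * 2
  spec2 <- phantom_spec(grid_shape = c(110L, 6L, 6L), waveform = wf2,
                        edv_slab = c(150, 217), esv_slab = c(150, 184))
  ph2 <- generate_slab_phantom(spec2)
  # whole-EDV KE curve scales by exactly 4 (per unit EDV volume)
  ph1 <- default_phantom()
  ke1 <- colSums(ph1$truth$ke_curves_mJ[1:4, ]) / ph1$truth$edv_ml
  ke2 <- colSums(ph2$truth$ke_curves_mJ[1:4, ]) / ph2$truth$edv_ml
  expect_equal(ke2, 4 * ke1, tolerance = 1e-12)
  # component volumes changed per the closed form and the pipeline still
  # reproduces them exactly
  expect_false(isTRUE(all.equal(
    unname(ph2$truth$component_volumes_ml / ph2$truth$edv_ml),
    unname(ph1$truth$component_volumes_ml / ph1$truth$edv_ml))))
  res2 <- suppressMessages(run_flow_analysis(ph2$field, ph2$seg, ph2$timing,
                                             unwrap = FALSE))
  expect_equal(res2$results$summary$volume_ml,
               unname(c(ph2$truth$component_volumes_ml, ph2$truth$e_a_split_ml)))
})

test_that("classification is invariant under rigid translation of the whole dataset", {
  spec <- phantom_spec()
  h <- spec$voxel_size
  spec_shift <- phantom_spec(edv_slab = spec$edv_slab + h,
                             esv_slab = spec$esv_slab + h)
  t1 <- generate_slab_phantom(spec)$truth
  t2 <- generate_slab_phantom(spec_shift)$truth
  expect_equal(t1$component_counts_vox, t2$component_counts_vox)
  expect_equal(t1$mid_diastasis_frame, t2$mid_diastasis_frame)
})

test_that("slab spec validation rejects inconsistent configurations", {
  expect_error(phantom_spec(edv_slab = c(50, 300)), class = "vf_config_error")
  expect_error(
    phantom_spec(waveform = flow_waveform("s", 0.5, 10)),  # durations != cycle
    class = "vf_config_error")
  expect_error(
    phantom_spec(waveform = flow_waveform("s", 1.0, 200)), # > VENC, no wrap
    class = "vf_config_error")
  # slab inside the grid but displaced outside it by the waveform
  wf <- flow_waveform(c("systole", "diastole"), c(0.5, 0.5), c(30, 30), "rect")
  expect_error(
    generate_slab_phantom(phantom_spec(grid_shape = c(40L, 4L, 4L),
                                       waveform = wf, ed_frame = 1L,
                                       es_frame = 21L,
                                       edv_slab = c(28, 84),
                                       esv_slab = c(28, 60))),
    class = "vf_config_error")
})

test_that("rotation phantom is a rigid-body field: zero at omega 0, speed omega r", {
  spec <- phantom_spec(grid_shape = c(24L, 24L, 6L), edv_slab = c(10, 20),
                       esv_slab = c(10, 16))
  expect_true(all(generate_rotation_phantom(0, spec)$values == 0))
  f <- generate_rotation_phantom(2 * pi, spec)
  h <- spec$voxel_size
  ctr <- c(24, 24) * h / 2
  # speed at every voxel equals omega * radius (in mm/s)
  cx <- (seq_len(24) - 0.5) * h - ctr[1]
  cy <- (seq_len(24) - 0.5) * h - ctr[2]
  r <- sqrt(outer(cx^2, cy^2, "+"))
  sp <- sqrt(f$values[, , 1, 1, 1]^2 + f$values[, , 1, 2, 1]^2) * 1000
  expect_equal(sp, 2 * pi * r, tolerance = 1e-12)
})

test_that("corrupt_field with an empty corruption block is the identity", {
  ph <- default_phantom()
  spec <- ph$spec
  spec$corruption <- list(wrap = FALSE)
  out <- corrupt_field(ph$field, spec)
  expect_identical(out$values, ph$field$values)
})

test_that("wrap injection folds a 150 cm/s sample at VENC 120 to -90 cm/s", {
  vals <- array(0, c(2, 2, 2, 3, 4))
  vals[1, 1, 1, 1, 2] <- 1.5
  f <- velocity_field(vals, 2.8, c(0, 0.1, 0.2, 0.3), 0.4, 120)
  spec <- phantom_spec(corruption = list(wrap = TRUE))
  out <- corrupt_field(f, spec)
  expect_equal(out$values[1, 1, 1, 1, 2], -0.9, tolerance = 1e-12)
  expect_true(all(abs(out$values) <= 1.2 + 1e-12))
})
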