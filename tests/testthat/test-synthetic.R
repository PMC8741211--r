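test_that("a noiseless single MG reproduces its amplitude at the brightest pixel", {
  cfg <- noiseless(tiny_config(seed = 3, n_mg = 1L, baseline_sd_frac = 0))
  sim <- simulate_calyx_movie(cfg, fixed_layer(50))
  gt <- sim$ground_truth
  dat <- sim$movie$data
  b <- gt$baseline_img
  ## brightest-pixel trace, converted to percent change over baseline
  px <- which.max(apply(dat[, , 1, ], c(1, 2), max) - b)
  tr <- 100 * (dat[, , 1, ][cbind(rep(row(b)[px], dim(dat)[4]),
                                  rep(col(b)[px], dim(dat)[4]),
                                  seq_len(dim(dat)[4]))] - b[px]) / b[px]
  ## amplitude is defined at the MG centre: footprint < 1 off-centre and the
  ## sampled kernel peak is known; restrict to the first trial window (later
  ## peaks ride on the decaying tail of earlier transients)
  g_centre <- mgpipe:::mg_footprint_value(
    sqrt((row(b)[px] - gt$mg$y_px)^2 + (col(b)[px] - gt$mg$x_px)^2),
    cfg$mg_radius_um / cfg$pixel_size_um)
  w1 <- mgpipe:::trial_frames(sim$protocol, 1)
  expect_equal(max(tr[w1]), 50 * g_centre * gt$kernel_peak, tolerance = 1e-8)
})

test_that("identical config and seed give bit-identical movies and tables", {
  cfg <- tiny_config(seed = 42, n_mg = 5L)
  a <- simulate_calyx_movie(cfg, layer_presets()$PN_BOUTON)
  b <- simulate_calyx_movie(cfg, layer_presets()$PN_BOUTON)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$ground_truth$mg, b$ground_truth$mg)
  s1 <- simulate_synapse_table(n_pn = 20, n_kc = 30, seed = 9)
  s2 <- simulate_synapse_table(n_pn = 20, n_kc = 30, seed = 9)
  expect_identical(s1$synapses, s2$synapses)
})

test_that("MG placement respects spacing and the field boundary; overfull fields error", {
  cfg <- tiny_config(seed = 7, n_mg = 12L, field_px = c(48L, 48L))
  sim <- simulate_calyx_movie(cfg, fixed_layer(50))
  mg <- sim$ground_truth$mg
  dmin <- min(dist(cbind(mg$y_px, mg$x_px)))
  expect_gte(dmin, cfg$min_spacing_um / cfg$pixel_size_um)
  cfg_bad <- tiny_config(seed = 7, n_mg = 500L)
  expect_error(simulate_calyx_movie(cfg_bad, fixed_layer(50)),
               "configuration error|too small")
})

test_that("generated odour amplitude ratios match the layer model", {
  ## PN layer: strong odour log-mean = weak + log(1.6); pooled over seeds the
  ## empirical mean ratio must recover the 1.6-fold contrast
  amps_m <- c(); amps_o <- c()
  for (s in 1:6) {
    cfg <- tiny_config(seed = 900 + s, n_mg = 44L, field_px = c(76L, 76L))
    sim <- simulate_calyx_movie(cfg, layer_presets()$PN_BOUTON)
    mg <- sim$ground_truth$mg
    amps_m <- c(amps_m, mg$amp_Mch[mg$active_Mch])
    amps_o <- c(amps_o, mg$amp_Oct[mg$active_Oct])
  }
  expect_gte(length(amps_m) + length(amps_o), 200)
  ratio <- mean(amps_o) / mean(amps_m)
  expect_gte(ratio, 1.4); expect_lte(ratio, 1.8)
})

test_that("active flags and amplitudes respect the floor invariant", {
  cfg <- tiny_config(seed = 31, n_mg = 30L, field_px = c(64L, 64L))
  sim <- simulate_calyx_movie(cfg, layer_presets()$KC_CLAW_APL_OFF)
  mg <- sim$ground_truth$mg
  for (od in c("Mch", "Oct")) {
    amp <- mg[[paste0("amp_", od)]]; act <- mg[[paste0("active_", od)]]
    expect_true(all(amp[act] > cfg$amplitude_floor))
    expect_true(all(amp[!act] == 0))
  }
})

test_that("volumetric gradients follow their closed forms and orderings", {
  ## uniform vs uniform: constant true ratio profile
  g_uni <- gradient_spec("uniform")
  expect_equal(g_uni(5), rep(1, 5))
  ## linear rising vs uniform: strictly increasing ratio by construction
  g_lin <- gradient_spec("linear", lo = 0.4, hi = 1)
  expect_true(all(diff(g_lin(5) / g_uni(5)) > 0))
  expect_equal(g_lin(5), seq(0.4, 1, length.out = 5))
  ## logistic multipliers match the formula at slice indices
  g_log <- gradient_spec("logistic", lo = 0.4, hi = 1, midpoint = 3,
                         steepness = 1.5)
  expect_equal(g_log(5), 0.4 + 0.6 * plogis(1.5 * ((1:5) - 3)))
  ## direction reversal
  expect_equal(gradient_spec("linear", lo = 0.4, direction = "down")(5),
               rev(g_lin(5)))
})

test_that("volumetric ground truth exposes per-slice amplitudes", {
  cfg <- volumetric_config(seed = 7, n_puffs = 1L, gap_s = 6, tail_s = 3,
                           baseline_frames = 10L)
  grads <- list(PA = gradient_spec("linear", lo = 0.4),
                MP = gradient_spec("uniform"), FA = gradient_spec("uniform"))
  sim <- simulate_volumetric_movie(cfg, grads)
  gt <- sim$ground_truth
  expect_equal(dim(gt$slice_amplitude), c(3L, 5L))
  expect_equal(gt$slice_amplitude["PA", ], 100 * seq(0.4, 1, length.out = 5),
               ignore_attr = TRUE)
  expect_equal(gt$slice_amplitude["MP", ], rep(80, 5), ignore_attr = TRUE)
  expect_equal(dim(sim$movie$data)[3], 5L)
})

test_that("synapse generator ground truth is internally consistent", {
  ## zero noise, slope 1, intercept 0: recomputed r2 on the table is 1
  s0 <- simulate_synapse_table(n_pn = 40, n_kc = 10, seed = 2,
                               pn_weights = list(slope = 1, intercept = 0,
                                                 noise_sd = 0, range = c(5, 60)))
  ca <- filter_region(s0$synapses, "CA(R)")
  w <- reciprocal_weights(ca, "APL", s0$neuron_meta)
  wc <- weight_correlation(w, "PN")
  expect_equal(wc$r2, 1)
  expect_equal(wc$slope, 1)
  ## all-bouton tagging when fraction is 1 with no spread (within the calyx;
  ## decoy rows in other regions stay untagged)
  s1 <- simulate_synapse_table(n_pn = 15, n_kc = 5, seed = 3,
                               bouton_fraction = list(mean = 1, sd = 0))
  ca1 <- filter_region(s1$synapses, "CA(R)")
  pn_rows <- ca1[ca1$pre_id == "APL" & grepl("^PN0", ca1$post_id), ]
  expect_true(all(pn_rows$compartment == "bouton"))
  ## weight recovery: emitted table reproduces the generator's weights
  s2 <- simulate_synapse_table(n_pn = 50, n_kc = 20, seed = 5)
  ca2 <- filter_region(s2$synapses, "CA(R)")
  w2 <- reciprocal_weights(ca2, "APL", s2$neuron_meta)
  pn <- merge(w2[w2$class == "PN", ], s2$truth$pn, by = "neuron_id")
  expect_identical(pn$w_to_hub, pn$w_to)
  expect_identical(pn$w_from_hub, pn$w_from)
})

test_that("downstream correlation recovers the generator's true r2", {
  s <- simulate_synapse_table(n_pn = 120, n_kc = 10, seed = 3)
  ca <- filter_region(s$synapses, "CA(R)")
  w <- reciprocal_weights(ca, "APL", s$neuron_meta)
  wc <- weight_correlation(w, "PN")
  expect_lte(abs(wc$r2 - s$truth$r2_pn), 0.05)
})
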