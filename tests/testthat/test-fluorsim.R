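# Synthetic-data generator: rosette scenes, physiology truth, forward
# simulation of quenching kinetics and multicolor bands, cohorts.

test_that("generate_rosette is deterministic and respects n_leaves", {
  expect_equal(sum(generate_rosette(rosette_spec(n_leaves = 0))$mask), 0)
  a <- generate_rosette(rosette_spec(n_leaves = 10, seed = 1))
  b <- generate_rosette(rosette_spec(n_leaves = 10, seed = 1))
  expect_identical(a$mask, b$mask)
  expect_identical(a$leaf_id, b$leaf_id)
  c <- generate_rosette(rosette_spec(n_leaves = 10, seed = 2))
  expect_false(identical(a$mask, c$mask))
  expect_setequal(unique(a$leaf_id[a$mask]), 1:10)
  expect_true(all(a$edge_distance[!a$mask] == 0))
  expect_true(all(a$edge_distance >= 0 & a$edge_distance <= 1))
})

test_that("a single elliptical leaf has the analytic ellipse area", {
  spec <- rosette_spec(image_shape = c(120, 120), n_leaves = 1,
                       leaf_length_px = c(20, 20),
                       leaf_width_px = c(10, 10), seed = 3)
  sc <- generate_rosette(spec)
  area <- sum(sc$mask)
  expect_lt(abs(area - pi * 20 * 10) / (pi * 20 * 10), 0.05)
})

test_that("leaves that cannot fit raise an error", {
  spec <- rosette_spec(image_shape = c(30, 30), n_leaves = 4,
                       leaf_length_px = c(20, 20),
                       leaf_width_px = c(8, 8), seed = 1)
  expect_error(generate_rosette(spec), "fit")
})

test_that("make_truth applies preset multipliers and edge gradient", {
  sc <- fx_scene()
  # no plant random effect: control values are exact
  tr <- make_truth(sc, uniform_preset(), uniform_base(), seed = 9)
  expect_true(all(tr$fvfm_true == 0.85))
  expect_true(all(tr$npq_ss == 1.2))
  # halving phi_ss multiplier halves the map (uniform preset, no edge)
  pre <- drought_preset("halfphi", 5,
                        c(fvfm_true = 1, npq_ss = 1, phi_ss = 0.5,
                          BF = 1, GF = 1, RF = 1, IrF = 1),
                        edge_gradient = 0, between_plant_sd = 0)
  tr2 <- make_truth(sc, pre, uniform_base(), seed = 9)
  expect_equal(mean(tr2$phi_ss), 0.5 * mean(tr$phi_ss), tolerance = 1e-12)
  # edge gradient amplifies the effect toward tips/edges by the stated
  # formula: base * (1 + (mult - 1) * (1 + g * (1 - d)))
  pre_g <- drought_preset("edge", 5,
                          c(fvfm_true = 1, npq_ss = 1, phi_ss = 0.5,
                            BF = 1, GF = 1, RF = 1, IrF = 1),
                          edge_gradient = 0.3, between_plant_sd = 0)
  tr3 <- make_truth(sc, pre_g, uniform_base(), seed = 9)
  d <- sc$edge_distance[which(sc$mask)]
  expected <- 0.55 * (1 + (0.5 - 1) * (1 + 0.3 * (1 - d)))
  expect_equal(tr3$phi_ss, expected, tolerance = 1e-12)
  # invariants
  expect_true(all(tr3$phi_ss >= 0))
  expect_true(all(tr3$fvfm_true < 1))
  expect_true(all(tr3$phi0 <= tr3$phi_ss))
})

test_that("zero-noise stack realizes the kinetic model pointwise", {
  st <- fx_uniform_stack()
  sc <- fx_scene()
  dm <- dim(st$frames)
  flat <- st$frames; dim(flat) <- c(dm[1] * dm[2], dm[3])
  pix <- flat[which(sc$mask)[1], ]
  p <- fx_protocol()
  base <- uniform_base()
  Fm <- base$fm_amp; Fo <- Fm * (1 - base$fvfm_true)
  # dark-adapted Fm flash peak equals Fm exactly
  expect_equal(max(pix[st$times_s >= 5.56 & st$times_s <= 5.88]), Fm)
  # dark frames before the actinic period sit at Fo
  dark <- st$times_s < p$actinic_on_s & st$light_state == "dark"
  expect_true(all(pix[dark] == Fo))
  # light phase: Ft <= Fm' <= Fm with Fm' = Fm/(1+NPQ(t))
  light <- st$light_state == "actinic"
  tau <- st$times_s[light] - p$actinic_on_s
  fmp <- Fm / (1 + base$npq_ss * (1 - exp(-base$k_ind * tau)))
  expect_true(all(pix[light] <= fmp + 1e-9))
  expect_true(all(fmp <= Fm))
  # background pixels carry no signal at zero noise
  expect_true(all(flat[which(!sc$mask)[1:50], ] == 0))
})

test_that("steady-state Fm' converges to Fm/(1+npq_ss)", {
  sc <- fx_scene()
  base <- uniform_base()
  base$npq_ss <- 1.0
  tr <- make_truth(sc, uniform_preset(), base, seed = 1)
  st <- simulate_stack(tr, fx_protocol(), no_noise())
  dm <- dim(st$frames)
  flat <- st$frames; dim(flat) <- c(dm[1] * dm[2], dm[3])
  pix <- flat[which(sc$mask)[1], ]
  i_lss <- which(st$times_s >= 92.24 & st$times_s <= 92.56)
  expect_equal(max(pix[i_lss]), base$fm_amp / 2, tolerance = 1e-6)
})

test_that("simulate_stack rejects an empty mask", {
  empty <- make_truth(matrix(FALSE, 10, 10), uniform_preset(),
                      uniform_base())
  expect_error(simulate_stack(empty, fx_protocol(), no_noise()), "empty")
})

test_that("multicolor stack has 4 bands x 5 identical exposures", {
  tr <- fx_uniform_truth()
  mc <- simulate_multicolor(tr, no_noise())
  expect_equal(dim(mc$frames)[3], 20)
  expect_equal(mc$band, rep(c("BF", "GF", "RF", "IrF"), each = 5))
  expect_true(all(mc$light_state == "uv"))
  dm <- dim(mc$frames)
  flat <- mc$frames; dim(flat) <- c(dm[1] * dm[2], dm[3])
  pix <- flat[tr$idx[1], ]
  expect_equal(unique(pix[mc$band == "BF"]),
               unname(tr$band_em[1, "BF"]))
  # reproducible under a fixed seed
  nm <- noise_model(seed = 4)
  m1 <- simulate_multicolor(tr, nm)
  m2 <- simulate_multicolor(tr, nm)
  expect_identical(m1$frames, m2$frames)
})

test_that("cohorts are labeled 1/2 and reproducible", {
  co <- simulate_cohort(2, 3, "day3", seed = 5, materialize = "manifest")
  expect_equal(co$manifest$label, c(1L, 1L, 2L, 2L, 2L))
  expect_equal(co$manifest$preset, c(rep("control", 2), rep("day3", 3)))
  expect_equal(nrow(co$manifest), 5)
  co2 <- simulate_cohort(2, 3, "day3", seed = 5, materialize = "manifest")
  expect_identical(co$manifest, co2$manifest)
  empty <- simulate_cohort(0, 0, "day3", seed = 5)
  expect_equal(nrow(empty$manifest), 0)
  f1 <- simulate_cohort(1, 1, "day3", seed = 5)
  f2 <- simulate_cohort(1, 1, "day3", seed = 5)
  expect_identical(f1$samples[[1]]$features, f2$samples[[1]]$features)
  expect_identical(f1$samples[[2]]$features, f2$samples[[2]]$features)
})

test_that("noise scaling: canopy-mean Fv/Fm tightens with mask area", {
  base <- uniform_base()
  p <- fx_protocol()
  est_sd <- function(spec, seeds) {
    vals <- vapply(seeds, function(s) {
      sc <- generate_rosette(spec)
      tr <- make_truth(sc, uniform_preset(), base, seed = s)
      st <- simulate_stack(tr, p, noise_model(read_sd = 25,
                                              shot_scale = 0.05,
                                              seed = s))
      trace <- extract_trace(st, sc$mask)
      sig <- extract_basic_signals(trace, p)
      fv_fm(sig)
    }, numeric(1))
    stats::sd(vals)
  }
  small <- rosette_spec(image_shape = c(64, 64), n_leaves = 2,
                        leaf_length_px = c(8, 8),
                        leaf_width_px = c(3, 3), seed = 1)
  large <- rosette_spec(image_shape = c(96, 96), n_leaves = 10,
                        leaf_length_px = c(16, 16),
                        leaf_width_px = c(6, 6), seed = 1)
  expect_gt(est_sd(small, 1:8), est_sd(large, 1:8))
})
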