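# Base-signal location and the quenching parameter catalogue.

test_that("estimate_fo_prime matches the Oxborough-Baker relation", {
  expect_equal(estimate_fo_prime(150, 1000, 600), 150 / (0.85 + 0.25),
               tolerance = 1e-12)
  expect_equal(estimate_fo_prime(150, 1000, 1000), 150)
  expect_equal(estimate_fo_prime(0, 1000, 600), 0)
  expect_error(estimate_fo_prime(150, 0, 600), "> 0")
  expect_error(estimate_fo_prime(150, 1000, 0), "> 0")
})

test_that("equation-level parameter values are exact", {
  s <- toy_signals()
  expect_equal(fv_fm(s), 0.85)
  expect_equal(fv_fm(structure(list(Fo = 1000, Fm = 1000), class =
                                 "basic_signals")), 0)
  expect_equal(fv_fm(structure(list(Fo = 0, Fm = 500), class =
                                 "basic_signals")), 1)
  expect_error(fv_fm(structure(list(Fo = 0, Fm = 0), class =
                                 "basic_signals")), "Fm")
  # NPQ: (Fm - Fm')/Fm'
  s2 <- s; s2$Fm <- 1200
  expect_equal(npq(s2, "L2"), 1.0)
  s3 <- s; s3$Fm_L2 <- s3$Fm
  expect_equal(npq(s3, "L2"), 0)
  # Rfd: (Fp - Ft)/Ft
  s4 <- s; s4$Ft_L3 <- 300; s4$Fp <- 900
  expect_equal(rfd(s4, "L3"), 2.0)
  s5 <- s4; s5$Ft_L3 <- 900
  expect_equal(rfd(s5, "L3"), 0)
  s4b <- s4; s4b$Ft_L3 <- 1000
  expect_warning(rfd(s4b, "L3"), "negative")
  # PhiPSII: (Fm' - Ft)/Fm'
  s6 <- s; s6$Fm_Lss <- 800; s6$Ft_Lss <- 400
  expect_equal(phi_psii(s6, "Lss"), 0.5)
  s7 <- s6; s7$Ft_Lss <- 800
  expect_equal(phi_psii(s7, "Lss"), 0)
})

test_that("qN matches hand arithmetic and its boundary cases", {
  s <- toy_signals()
  s$Fm_D2 <- 800; s$Fo_D2 <- 100
  expect_equal(qn(s, "D2"), 200 / 900)
  s$Fm_D2 <- s$Fm
  expect_equal(qn(s, "D2"), 0)
  s$Fm_D2 <- s$Fo_D2
  expect_equal(qn(s, "D2"), 1)
  s$Fo_D2 <- s$Fm
  expect_error(qn(s, "D2"), "exceed")
})

test_that("qL printed and standard forms match hand evaluation", {
  s <- toy_signals()
  fo_p <- 150 / 1.1                       # 136.3636...
  qp_expect <- (600 - 300) / (600 - fo_p) # 0.647059...
  expect_equal(qp(s, "L2"), qp_expect, tolerance = 1e-9)
  expect_equal(ql(s, "L2", "printed"), qp_expect / (fo_p / 300),
               tolerance = 1e-9)
  expect_equal(ql(s, "L2", "printed"), 1.423529, tolerance = 1e-5)
  expect_equal(ql(s, "L2", "standard"), qp_expect * (fo_p / 300),
               tolerance = 1e-9)
  expect_equal(ql(s, "L2", "standard"), 0.294118, tolerance = 1e-5)
  # Ft = Fo' -> both forms collapse to qP
  s$Ft_L2 <- s$Fo_L2
  expect_equal(ql(s, "L2", "printed"), qp(s, "L2"))
  expect_equal(ql(s, "L2", "standard"), qp(s, "L2"))
})

test_that("catalogue has exactly 89 uniquely named entries", {
  nms <- catalogue_names()
  expect_length(nms, 89)
  expect_false(anyDuplicated(nms) > 0)
  s <- full_toy_signals()
  cat89 <- compute_catalogue(s)
  expect_length(cat89, 89)
  expect_true(all(c("qN_D2", "Fv_Lss", "qL_L4", "NPQ_L2", "Rfd_L3",
                    "PhiPSII_Lss") %in% names(cat89)))
  expect_equal(cat89[["Fv/Fm"]], fv_fm(s))
  expect_equal(cat89[["NPQ_L2"]], npq(s, "L2"))
  expect_equal(cat89[["qL_L4"]], ql(s, "L4", "printed"))
  bad <- s; bad$Fm_L3 <- NULL
  expect_error(compute_catalogue(bad), "Fm_L3")
})

test_that("multicolor parameter set has 4 means and 12 ordered ratios", {
  m <- c(BF = 200, GF = 100, RF = 400, IrF = 400)
  mp <- multicolor_parameters(m)
  expect_length(mp, 16)
  expect_equal(mp[["IrF/BF"]], 2.0)
  expect_equal(mp[["BF/IrF"]], 0.5)
  expect_false(anyDuplicated(names(mp)) > 0)
  same <- multicolor_parameters(c(BF = 3, GF = 3, RF = 3, IrF = 3))
  expect_true(all(same[5:16] == 1))
  expect_error(multicolor_parameters(c(BF = 0, GF = 1, RF = 1, IrF = 1)),
               "nonpositive")
})

test_that("parameter ranges hold for physically ordered signals", {
  set.seed(31)
  for (rep in 1:25) {
    Fm <- stats::runif(1, 500, 2000)
    Fo <- stats::runif(1, 0.1, 0.25) * Fm
    fr <- sort(stats::runif(8, Fo / Fm + 0.05, 1), decreasing = TRUE)
    s <- full_toy_signals(Fo = Fo, Fm = Fm, fm_frac = fr)
    expect_true(fv_fm(s) >= 0 && fv_fm(s) <= 1)
    for (st in c("L1", "L3", "Lss", "D2")) {
      expect_gte(npq(s, st), 0)
      expect_true(qn(s, st) >= 0 && qn(s, st) <= 1)
      expect_true(phi_psii(s, st) >= 0 && phi_psii(s, st) <= 1)
      expect_true(qp(s, st) >= 0 && qp(s, st) <= 1)
    }
  }
})

test_that("zero-noise extraction matches the forward-model oracle", {
  sig <- fx_uniform_signals()
  base <- uniform_base()
  p <- fx_protocol()
  Fm <- base$fm_amp
  Fo <- Fm * (1 - base$fvfm_true)
  expect_equal(sig$Fo, Fo, tolerance = 1e-12)
  expect_equal(sig$Fm, Fm, tolerance = 1e-12)
  # closed-form light-phase state at the Lss flash onset
  tau <- 92.24 - p$actinic_on_s
  npq_t <- base$npq_ss * (1 - exp(-base$k_ind * tau))
  fmp <- Fm / (1 + npq_t)
  expect_equal(sig$Fm_Lss, fmp, tolerance = 1e-9)
  # Ft_Lss is the last pre-flash sample (t = 92.0 on the 2 Hz grid)
  tau_ft <- 92.0 - p$actinic_on_s
  phi_t <- base$phi_ss + (base$phi0 - base$phi_ss) *
    exp(-base$k_p * tau_ft)
  fmp_ft <- Fm / (1 + base$npq_ss * (1 - exp(-base$k_ind * tau_ft)))
  expect_equal(sig$Ft_Lss, fmp_ft * (1 - phi_t), tolerance = 1e-9)
  # dark-relaxation flash D2
  tau_d <- 152.24 - p$actinic_off_s
  fmp_d <- Fm / (1 + base$npq_ss * exp(-base$k_rel * tau_d))
  expect_equal(sig$Fm_D2, fmp_d, tolerance = 1e-9)
})

test_that("truncated traces are rejected", {
  st <- fx_uniform_stack()
  sc <- fx_scene()
  tr <- extract_trace(st, sc$mask)
  keep <- tr$times_s < 92
  short <- tr
  short$times_s <- tr$times_s[keep]
  short$mean_counts <- tr$mean_counts[keep]
  short$light_state <- tr$light_state[keep]
  expect_error(extract_basic_signals(short, fx_protocol()), "before")
})

test_that("per-pixel and canopy-mean catalogues agree for uniform truth", {
  st <- fx_uniform_stack()
  sc <- fx_scene()
  p <- fx_protocol()
  canopy <- compute_catalogue(extract_basic_signals(
    extract_trace(st, sc$mask), p))
  pix_ids <- which(sc$mask)[c(1, 50, 200)]
  per_pixel <- lapply(pix_ids, function(i) {
    m <- matrix(FALSE, nrow(sc$mask), ncol(sc$mask))
    m[i] <- TRUE
    compute_catalogue(extract_basic_signals(extract_trace(st, m), p))
  })
  avg <- Reduce(`+`, per_pixel) / length(per_pixel)
  expect_equal(as.numeric(avg), as.numeric(canopy), tolerance = 1e-9)
})
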