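# Shared fixtures, memoized so expensive simulations run once per suite.

# test-local seeded evaluation (restores the caller's RNG state)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

.fx <- new.env(parent = emptyenv())

fx <- function(key, expr) {
  if (!exists(key, envir = .fx, inherits = FALSE)) {
    assign(key, force(expr), envir = .fx)
  }
  get(key, envir = .fx)
}

# a preset with no drought effect, no edge gradient and no plant random
# effect: every truth map is spatially and between-plant uniform
uniform_preset <- function() {
  drought_preset("uniform", 0,
                 c(fvfm_true = 1, npq_ss = 1, phi_ss = 1,
                   BF = 1, GF = 1, RF = 1, IrF = 1),
                 edge_gradient = 0, between_plant_sd = 0)
}

uniform_base <- function() {
  base <- base_physiology()
  base$fvfm_cv <- 0
  base
}

fx_protocol <- function() fx("protocol", default_quenching_protocol())

fx_scene <- function() fx("scene", generate_rosette(rosette_spec(seed = 2)))

fx_uniform_truth <- function() fx("uniform_truth", {
  make_truth(fx_scene(), uniform_preset(), uniform_base(), seed = 1)
})

# zero-noise stack of the uniform plant + its extracted features
fx_uniform_stack <- function() fx("uniform_stack", {
  simulate_stack(fx_uniform_truth(), fx_protocol(), no_noise())
})

fx_uniform_signals <- function() fx("uniform_signals", {
  mask <- fx_scene()$mask
  trace <- extract_trace(fx_uniform_stack(), mask)
  extract_basic_signals(trace, fx_protocol())
})

fx_uniform_features <- function() fx("uniform_features", {
  mc <- simulate_multicolor(fx_uniform_truth(), no_noise())
  extract_features(fx_uniform_stack(), mc, fx_protocol())
})

# worked basic-signals example used by the equation-level tests:
# Fo = 150, Fm = 1000, stage L2 with Fm' = 600 and Ft = 300
toy_signals <- function() {
  s <- list(Fo = 150, Fm = 1000, Fv = 850, Fp = 900)
  s$Ft_L2 <- 300
  s$Fm_L2 <- 600
  s$Fo_L2 <- estimate_fo_prime(150, 1000, 600)
  s$Fv_L2 <- s$Fm_L2 - s$Fo_L2
  structure(s, class = "basic_signals")
}

# complete synthetic basic_signals with plausible stage values
full_toy_signals <- function(Fo = 150, Fm = 1000, fm_frac = NULL) {
  stages <- c("L1", "L2", "L3", "L4", "Lss", "D1", "D2", "D3")
  if (is.null(fm_frac)) {
    fm_frac <- c(0.8, 0.7, 0.62, 0.55, 0.5, 0.6, 0.75, 0.9)
  }
  s <- list(Fo = Fo, Fm = Fm, Fv = Fm - Fo, Fp = 0.9 * Fm)
  for (i in seq_along(stages)) {
    st <- stages[i]
    fm_x <- fm_frac[i] * Fm
    fo_x <- estimate_fo_prime(Fo, Fm, fm_x)
    ft_x <- fo_x + 0.45 * (fm_x - fo_x)
    s[[paste0("Ft_", st)]] <- ft_x
    s[[paste0("Fm_", st)]] <- fm_x
    s[[paste0("Fo_", st)]] <- fo_x
    s[[paste0("Fv_", st)]] <- fm_x - fo_x
  }
  structure(s, class = "basic_signals")
}

# standard nine-trait panel used as a pre-specified input feature list
wt_selected_features <- function() {
  c("IrF/BF", "qN_D2", "Fv_Lss", "qL_L4", "qN_L2", "PhiPSII_L4",
    "qL_L1", "NPQ_L1", "Fm_D1")
}

# small simulated cohorts for module tests (shared where possible)
fx_severe_table <- function() fx("severe_table", {
  cohort_feature_table(simulate_cohort(14, 14, "day7", seed = 42))
})

fx_moderate_table <- function() fx("moderate_table", {
  cohort_feature_table(simulate_cohort(14, 14, "day3", seed = 42))
})

fx_mild_table <- function() fx("mild_table", {
  cohort_feature_table(simulate_cohort(14, 14, "day1", seed = 42))
})

# random feature table with catalogue-style names (no signal by default)
random_table <- function(n_per_class = 20, p = 105, seed = 7,
                         informative = character(),
                         shift = 3) {
  pool <- c(catalogue_names(),
            names(multicolor_parameters(c(BF = 1, GF = 1, RF = 1,
                                          IrF = 1))))
  nms <- unique(c(informative, pool))[seq_len(p)]
  with_seed(seed, {
    n <- 2 * n_per_class
    x <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, nms))
    labels <- rep(1:2, each = n_per_class)
    for (nm in informative) {
      x[labels == 2, nm] <- x[labels == 2, nm] + shift
    }
    feature_table(x, labels)
  })
}
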