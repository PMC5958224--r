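# Per-pixel physiological ground truth driving the forward model, and the
# drought presets that perturb it.

#' Baseline physiology of an unstressed plant
#'
#' Control values for the per-pixel physiology maps. Fluorescence levels are
#' camera counts; rate constants are s-1; yields are dimensionless.
#'
#' * `fm_amp` - dark-adapted maximal fluorescence Fm (counts).
#' * `fvfm_true` - maximum PSII quantum yield; sets Fo = fm_amp * (1 - Fv/Fm).
#' * `npq_ss` - steady-state non-photochemical quenching under the actinic
#'   light.
#' * `k_ind`, `k_rel` - NPQ induction and dark-relaxation rates.
#' * `phi_ss`, `phi0`, `k_p` - steady-state PSII operating efficiency, its
#'   value at light onset (low, producing the Kautsky peak), and the
#'   photochemical induction rate.
#' * `band_em` - mean UV-excited emission in the blue (440 nm), green
#'   (520 nm), red (680 nm) and far-red (740 nm) bands (counts).
#' * `fvfm_cv` - between-plant coefficient of variation of Fv/Fm (healthy
#'   plants are very uniform: ~0.85 +/- 0.002).
#'
#' @return Named list of baseline values.
#' @export
base_physiology <- function() {
  list(
    fm_amp = 1000, fvfm_true = 0.85,
    npq_ss = 1.2, k_ind = 0.25, k_rel = 0.03,
    phi_ss = 0.55, phi0 = 0.05, k_p = 0.25,
    band_em = c(BF = 300, GF = 200, RF = 650, IrF = 850),
    fvfm_cv = 0.003
  )
}

#' Construct a drought preset
#'
#' Multiplicative perturbations of the baseline physiology representing a
#' given day of withheld watering. `edge_gradient` scales extra effect at
#' leaf tips and edges (stress spreads inward from the leaf margins);
#' `between_plant_sd` is the coefficient of variation of the per-plant random
#' effect on each physiological field (except Fv/Fm, whose much smaller
#' spread is set by `fvfm_cv` in [base_physiology()]).
#'
#' @param name Preset name.
#' @param day Days after drought onset (0-8; 0 = control).
#' @param multipliers Named numeric with entries `fvfm_true`, `npq_ss`,
#'   `phi_ss`, `BF`, `GF`, `RF`, `IrF`; all > 0.
#' @param edge_gradient In \[0, 1\]: 0 = spatially uniform effect.
#' @param between_plant_sd Coefficient of variation of the plant random
#'   effect.
#' @return An object of class `drought_preset`.
#' @export
drought_preset <- function(name, day, multipliers, edge_gradient = 0,
                           between_plant_sd = 0.05) {
  need <- c("fvfm_true", "npq_ss", "phi_ss", "BF", "GF", "RF", "IrF")
  if (!all(need %in% names(multipliers))) {
    stopf("multipliers must name: %s", paste(need, collapse = ", "))
  }
  if (any(multipliers <= 0)) stopf("multipliers must be > 0")
  if (edge_gradient < 0 || edge_gradient > 1) {
    stopf("edge_gradient must be in [0, 1]")
  }
  structure(list(name = name, day = day,
                 multipliers = multipliers[need],
                 edge_gradient = edge_gradient,
                 between_plant_sd = between_plant_sd),
            class = "drought_preset")
}

#' Built-in drought severity presets
#'
#' One preset per measurement day (1, 3, 5, 7, 8 days of withheld watering)
#' plus `"control"`. Effect directions follow the drought phenomenology of
#' rosette plants: NPQ, PSII efficiency and far-red emission decrease; blue
#' and green (phenolic) emission increase; red emission rises slightly late;
#' Fv/Fm drops only at the late stage. Magnitudes are calibration choices
#' expressed as standardized between-class shifts: ~0.5 SD at day 1, ~2 SD at
#' day 3 (moderate), ~4 SD at day 5, >= 8 SD at days 7-8 (severe) on the
#' affected parameters, relative to the 5% between-plant CV.
#'
#' @param name One of `"control"`, `"day1"`, `"day3"`, `"day5"`, `"day7"`,
#'   `"day8"`; aliases `"moderate"` (= day3) and `"severe"` (= day7).
#' @return A `drought_preset`.
#' @export
preset_by_name <- function(name) {
  if (name == "moderate") name <- "day3"
  if (name == "severe") name <- "day7"
  m <- function(fvfm, npq, phi, bf, gf, rf, irf) {
    c(fvfm_true = fvfm, npq_ss = npq, phi_ss = phi,
      BF = bf, GF = gf, RF = rf, IrF = irf)
  }
  tab <- list(
    control = list(0, m(1, 1, 1, 1, 1, 1, 1), 0, 0.05),
    day1 = list(1, m(1, 0.98, 0.99, 1.03, 1.02, 1.00, 0.97), 0.02, 0.05),
    day3 = list(3, m(1, 0.90, 0.90, 1.10, 1.10, 1.00, 0.90), 0.10, 0.05),
    day5 = list(5, m(0.995, 0.82, 0.85, 1.22, 1.20, 1.02, 0.78), 0.20, 0.05),
    day7 = list(7, m(0.975, 0.55, 0.60, 1.55, 1.55, 1.10, 0.55), 0.30, 0.05),
    day8 = list(8, m(0.960, 0.50, 0.55, 1.60, 1.60, 1.12, 0.50), 0.35, 0.05)
  )
  if (!name %in% names(tab)) {
    stopf("unknown preset '%s' (have: %s)", name,
          paste(names(tab), collapse = ", "))
  }
  x <- tab[[name]]
  drought_preset(name, x[[1]], x[[2]], x[[3]], x[[4]])
}

#' Generate per-pixel physiology ground truth
#'
#' Applies a drought preset to the baseline physiology over a rosette scene.
#' For each perturbed field the per-pixel value is
#' `base * (1 + (mult - 1) * (1 + g * (1 - d)))` where `g` is the preset's
#' `edge_gradient` and `d` the normalized edge distance (1 at the midrib,
#' 0 at the leaf boundary) - i.e. the stress effect is amplified by up to
#' `(1 + g)` at tips and edges, and vanishes nowhere. A per-plant lognormal-
#' free random effect `(1 + N(0, cv))` is drawn once per field.
#'
#' @param scene Output of [generate_rosette()] (or a bare logical mask, in
#'   which case the edge gradient is taken as uniform midrib distance 1).
#' @param preset A [drought_preset()].
#' @param base Baseline physiology, see [base_physiology()].
#' @param seed RNG seed for the plant random effect.
#' @return An object of class `physiology_truth`: per-pixel numeric vectors
#'   over the mask pixels (`fm_amp`, `fvfm_true`, `npq_ss`, `k_ind`,
#'   `k_rel`, `phi_ss`, `phi0`, `k_p`, and a 4-column `band_em` matrix),
#'   plus the `mask` and pixel index.
#' @export
make_truth <- function(scene, preset, base = base_physiology(), seed = 1) {
  if (is.matrix(scene) && is.logical(scene)) {
    scene <- list(mask = scene,
                  edge_distance = matrix(1, nrow(scene), ncol(scene)))
  }
  mask <- scene$mask
  idx <- which(mask)
  n <- length(idx)
  d <- scene$edge_distance[idx]
  g <- preset$edge_gradient
  mult <- preset$multipliers
  cv <- preset$between_plant_sd

  # per-plant random multipliers, one per physiological field
  re <- with_seed(seed, {
    r <- stats::rnorm(7, 0, 1)
    names(r) <- c("fvfm_true", "npq_ss", "phi_ss", "BF", "GF", "RF", "IrF")
    r
  })
  plant_mult <- function(field) {
    cv_f <- if (field == "fvfm_true") base$fvfm_cv else cv
    max(1 + re[[field]] * cv_f, 0.01)
  }
  eff <- function(field) {
    # effect amplified toward tips/edges (small d)
    1 + (mult[[field]] - 1) * (1 + g * (1 - d))
  }
  field_map <- function(field, baseval) {
    baseval * eff(field) * plant_mult(field)
  }
  fvfm <- pmin(field_map("fvfm_true", base$fvfm_true), 0.999)
  band <- vapply(c("BF", "GF", "RF", "IrF"), function(b) {
    field_map(b, base$band_em[[b]])
  }, numeric(n))
  if (n == 0) band <- matrix(numeric(0), 0, 4,
                             dimnames = list(NULL, c("BF","GF","RF","IrF")))
  phi_ss <- pmin(field_map("phi_ss", base$phi_ss), 0.99)
  structure(list(
    mask = mask, idx = idx,
    fm_amp = rep(base$fm_amp, n),
    fvfm_true = fvfm,
    npq_ss = pmax(field_map("npq_ss", base$npq_ss), 0),
    k_ind = rep(base$k_ind, n),
    k_rel = rep(base$k_rel, n),
    phi_ss = phi_ss,
    phi0 = pmin(rep(base$phi0, n), phi_ss),
    k_p = rep(base$k_p, n),
    band_em = band,
    preset = preset$name, seed = seed
  ), class = "physiology_truth")
}
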