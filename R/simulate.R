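# Forward simulation: render timestamped fluorescence frame stacks from
# per-pixel physiology under a quenching protocol, plus the UV-excited
# multicolor band exposures.

#' Camera noise model
#'
#' Gaussian read noise plus a signal-proportional variance term (a Gaussian
#' stand-in for shot noise, kept non-Poisson so that seeded runs are simple
#' to reproduce). Background pixels carry read noise only.
#'
#' @param read_sd Read-noise SD in counts.
#' @param shot_scale Signal-proportional variance scale (variance =
#'   `shot_scale * signal`).
#' @param seed RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(read_sd = 5, shot_scale = 0.01, seed = 1) {
  if (read_sd < 0 || shot_scale < 0) stopf("noise parameters must be >= 0")
  structure(list(read_sd = read_sd, shot_scale = shot_scale, seed = seed),
            class = "noise_model")
}

#' Zero-noise model
#' @return A `noise_model` with both noise terms 0.
#' @export
no_noise <- function() noise_model(read_sd = 0, shot_scale = 0, seed = 1)

# Per-pixel fluorescence F(t) for all mask pixels at the scheduled frame
# times. Returns an npix x nt matrix. The kinetic model:
#  dark-adapted:  F = Fo (measuring) or Fm (saturating flash)
#  light phase:   NPQ(t) = npq_ss (1 - e^{-k_ind (t - t_on)})
#                 Fm'(t) = Fm / (1 + NPQ(t))
#                 Phi(t) = phi_ss + (phi0 - phi_ss) e^{-k_p (t - t_on)}
#                 Ft = Fm'(t) (1 - Phi(t));  F -> Fm'(t) under a flash
#  dark relax:    NPQ(t) = npq_ss e^{-k_rel (t - t_off)}
#                 Ft relaxes from its lights-off value toward
#                 Fo'(t) = Fo / (Fv/Fm + Fo/Fm'(t))  (all centers reopening)
# Quenching state is evaluated at the flash *start* time for frames inside
# a saturating-flash window: the 320 ms flash neither induces nor relaxes
# NPQ appreciably, and this keeps Fm' constant over each flash window (so
# the window maximum is the flash-onset value, also when a flash straddles
# the lights-off boundary).
effective_times <- function(p, times) {
  teff <- times
  for (f in p$flashes) {
    if (f$kind != "saturating") next
    inwin <- times >= f$time_s & times <= f$time_s + f$duration_ms / 1000
    teff[inwin] <- f$time_s
  }
  teff
}

pixel_kinetics <- function(truth, times, states, t_on, t_off) {
  np <- length(truth$idx)
  nt <- length(times)
  Fm <- truth$fm_amp
  Fo <- Fm * (1 - truth$fvfm_true)
  FF <- matrix(0, np, nt)
  sat <- states == "saturating"

  dark0 <- times < t_on
  if (any(dark0)) {
    FF[, dark0 & !sat] <- Fo
    FF[, dark0 & sat] <- Fm
  }

  light <- times >= t_on & times <= t_off
  if (any(light)) {
    tau <- times[light] - t_on
    npq <- truth$npq_ss * (1 - exp(-outer(truth$k_ind, tau)))
    fmp <- Fm / (1 + npq)
    phi <- truth$phi_ss + (truth$phi0 - truth$phi_ss) *
      exp(-outer(truth$k_p, tau))
    ft <- fmp * (1 - phi)
    satl <- sat[light]
    ft[, satl] <- fmp[, satl]
    FF[, light] <- ft
  }

  relax <- times > t_off
  if (any(relax)) {
    tau <- times[relax] - t_off
    npq <- truth$npq_ss * exp(-outer(truth$k_rel, tau))
    fmp <- Fm / (1 + npq)
    fop <- Fo / (truth$fvfm_true + Fo / fmp)
    # openness recovery: Phi -> Phi'max(t) = 1 - Fo'(t)/Fm'(t)
    phimax <- 1 - fop / fmp
    tau_on_off <- t_off - t_on
    phi_off <- truth$phi_ss + (truth$phi0 - truth$phi_ss) *
      exp(-truth$k_p * tau_on_off)
    phid <- phimax + (phi_off - phimax) * exp(-outer(truth$k_p, tau))
    ft <- fmp * (1 - phid)
    satr <- sat[relax]
    ft[, satr] <- fmp[, satr]
    FF[, relax] <- ft
  }
  FF
}

add_noise <- function(x, noise) {
  if (noise$read_sd == 0 && noise$shot_scale == 0) return(x)
  sd <- sqrt(noise$read_sd^2 + noise$shot_scale * pmax(x, 0))
  x + stats::rnorm(length(x), 0, sd)
}

#' Simulate a kinetic fluorescence frame stack
#'
#' Renders the frame sequence a PAM imaging camera would record for a plant
#' with the given per-pixel physiology, following the protocol's frame
#' schedule. Background pixels carry only noise.
#'
#' @param truth A [make_truth()] object.
#' @param p A `protocol_definition`.
#' @param noise A [noise_model()].
#' @return An object of class `frame_stack`: list with `frames` (3-D array
#'   rows x cols x n), `times_s`, `light_state`, and `meta`.
#' @export
simulate_stack <- function(truth, p, noise = noise_model()) {
  if (length(truth$idx) == 0) stopf("empty plant mask")
  sched <- frame_schedule(p)
  nr <- nrow(truth$mask); nc <- ncol(truth$mask)
  nt <- nrow(sched)
  FF <- pixel_kinetics(truth, effective_times(p, sched$time_s),
                       sched$light_state, p$actinic_on_s, p$actinic_off_s)
  frames <- with_seed(noise$seed, {
    arr <- if (noise$read_sd > 0) {
      array(stats::rnorm(nr * nc * nt, 0, noise$read_sd), dim = c(nr, nc, nt))
    } else {
      array(0, dim = c(nr, nc, nt))
    }
    dim(arr) <- c(nr * nc, nt)
    arr[truth$idx, ] <- add_noise(FF, noise)
    dim(arr) <- c(nr, nc, nt)
    arr
  })
  structure(list(frames = frames, times_s = sched$time_s,
                 light_state = sched$light_state,
                 meta = list(protocol = "quenching", preset = truth$preset,
                             seed = noise$seed)),
            class = "frame_stack")
}

#' Simulate UV-excited multicolor band exposures
#'
#' Renders `n_exposures` frames (default 5, 4 s each) per emission band -
#' blue 440 nm (BF), green 520 nm (GF), red 680 nm (RF), far-red 740 nm
#' (IrF) - 20 frames in total, each carrying light state `"uv"`. Pre-noise,
#' every exposure of a band equals the truth's band emission.
#'
#' @param truth A [make_truth()] object.
#' @param noise A [noise_model()].
#' @param n_exposures Exposures per band.
#' @param exposure_s Exposure time (seconds), metadata only.
#' @return A `frame_stack` with an extra `band` element (per-frame band
#'   label).
#' @export
simulate_multicolor <- function(truth, noise = noise_model(),
                                n_exposures = 5, exposure_s = 4) {
  bands <- c("BF", "GF", "RF", "IrF")
  nr <- nrow(truth$mask); nc <- ncol(truth$mask)
  nt <- length(bands) * n_exposures
  band <- rep(bands, each = n_exposures)
  frames <- with_seed(noise$seed + 1L, {
    arr <- if (noise$read_sd > 0) {
      array(stats::rnorm(nr * nc * nt, 0, noise$read_sd), dim = c(nr * nc, nt))
    } else {
      array(0, dim = c(nr * nc, nt))
    }
    for (j in seq_len(nt)) {
      arr[truth$idx, j] <- add_noise(truth$band_em[, band[j]], noise)
    }
    dim(arr) <- c(nr, nc, nt)
    arr
  })
  structure(list(frames = frames,
                 times_s = seq_len(nt) * exposure_s,
                 light_state = rep("uv", nt),
                 band = band,
                 meta = list(protocol = "multicolor", preset = truth$preset,
                             seed = noise$seed)),
            class = "frame_stack")
}

#' Simulate a labeled cohort of plants
#'
#' Draws `n_control` plants under the control preset and `n_drought` plants
#' under the given drought preset, labeling controls `1` and drought-stressed
#' plants `2`. Each plant gets its own rosette scene, physiology draw and
#' noise stream, all derived deterministically from `seed`.
#'
#' Because a full cohort of frame stacks is large, `materialize` selects what
#' is kept per plant: `"features"` (default) runs the full extraction
#' pipeline (segmentation, trace, parameter catalogue, multicolor) and keeps
#' the 105-parameter vector; `"frames"` keeps the raw stacks; `"manifest"`
#' keeps only labels and seeds.
#'
#' @param n_control,n_drought Cohort sizes (>= 0).
#' @param preset Drought preset (name or [drought_preset()]).
#' @param protocol A `protocol_definition`.
#' @param noise A [noise_model()] (its seed is re-derived per plant).
#' @param seed Master seed for the cohort.
#' @param spec A [rosette_spec()] (its seed is re-derived per plant).
#' @param base Baseline physiology, see [base_physiology()].
#' @param materialize `"features"`, `"frames"` or `"manifest"`.
#' @return An object of class `cohort`: list with `manifest` (data.frame:
#'   sample_id, label, preset, scene_seed, truth_seed, noise_seed) and
#'   `samples` (per-plant list; contents depend on `materialize`).
#' @export
simulate_cohort <- function(n_control, n_drought, preset = "day7",
                            protocol = default_quenching_protocol(),
                            noise = noise_model(), seed = 1,
                            spec = rosette_spec(), base = base_physiology(),
                            materialize = c("features", "frames",
                                            "manifest")) {
  materialize <- match.arg(materialize)
  if (n_control < 0 || n_drought < 0) stopf("cohort sizes must be >= 0")
  if (is.character(preset)) preset <- preset_by_name(preset)
  ctrl <- preset_by_name("control")
  n <- n_control + n_drought
  labels <- rep(c(1L, 2L), c(n_control, n_drought))
  manifest <- data.frame(
    sample_id = if (n) sprintf("plant_%03d", seq_len(n)) else character(),
    label = labels,
    preset = ifelse(labels == 1L, ctrl$name, preset$name),
    scene_seed = if (n) vapply(seq_len(n), function(i)
      child_seed(seed, 3L * i), integer(1)) else integer(),
    truth_seed = if (n) vapply(seq_len(n), function(i)
      child_seed(seed, 3L * i + 1L), integer(1)) else integer(),
    noise_seed = if (n) vapply(seq_len(n), function(i)
      child_seed(seed, 3L * i + 2L), integer(1)) else integer(),
    stringsAsFactors = FALSE
  )
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    pre_i <- if (labels[i] == 1L) ctrl else preset
    spec_i <- spec; spec_i$seed <- manifest$scene_seed[i]
    scene <- generate_rosette(spec_i)
    truth <- make_truth(scene, pre_i, base, seed = manifest$truth_seed[i])
    noise_i <- noise; noise_i$seed <- manifest$noise_seed[i]
    if (materialize == "manifest") {
      samples[[i]] <- list(label = labels[i])
      next
    }
    chl <- simulate_stack(truth, protocol, noise_i)
    mc <- simulate_multicolor(truth, noise_i)
    if (materialize == "frames") {
      samples[[i]] <- list(chl = chl, mc = mc, truth = truth,
                           label = labels[i])
    } else {
      samples[[i]] <- list(features = extract_features(chl, mc, protocol),
                           label = labels[i])
    }
  }
  structure(list(manifest = manifest, samples = samples,
                 preset = preset$name, seed = seed),
            class = "cohort")
}
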