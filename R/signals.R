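# Locating the base fluorescence levels on a kinetic trace.

#' Estimate Fo' from Fo, Fm and Fm'
#'
#' Light- and relaxation-phase minimal fluorescence is rarely measured
#' directly; the standard reconstruction (Oxborough & Baker 1997) is
#' `Fo' = Fo / (Fv/Fm + Fo/Fm')`. When `Fm' = Fm` this reduces to `Fo`.
#'
#' @param Fo,Fm Dark-adapted minimal and maximal fluorescence (counts).
#' @param Fm_prime Stage maximal fluorescence Fm' (counts).
#' @return Fo' in counts.
#' @export
estimate_fo_prime <- function(Fo, Fm, Fm_prime) {
  if (any(Fm <= 0) || any(Fm_prime <= 0)) {
    stopf("Fm and Fm' must be > 0")
  }
  if (any(Fo > Fm)) stopf("Fo must not exceed Fm")
  Fo / ((Fm - Fo) / Fm + Fo / Fm_prime)
}

# mean of trace values with time in [t0, t1] and a matching light state
window_mean <- function(trace, t0, t1, state = NULL) {
  sel <- trace$times_s >= t0 & trace$times_s <= t1
  if (!is.null(state)) sel <- sel & trace$light_state %in% state
  if (!any(sel)) return(NA_real_)
  mean(trace$mean_counts[sel])
}

window_max <- function(trace, t0, t1, state = NULL) {
  sel <- trace$times_s >= t0 & trace$times_s <= t1
  if (!is.null(state)) sel <- sel & trace$light_state %in% state
  if (!any(sel)) return(NA_real_)
  max(trace$mean_counts[sel])
}

#' Extract the base fluorescence signals from a kinetic trace
#'
#' Locates every measurable level of the quenching protocol on a canopy-mean
#' trace:
#' * `Fo` - mean over the dark Fo measuring window;
#' * `Fm`, `Fm_Ln`, `Fm_Lss`, `Fm_Dn` - maximum inside each saturating-flash
#'   window;
#' * `Fp` - maximum of the induction transient between actinic onset and the
#'   first light-phase flash (the Kautsky peak);
#' * `Ft_Ln`, `Ft_Dn` - mean over the 1 s window ending at each flash start;
#'   `Ft_Lss` - the last pre-flash sample before the steady-state flash;
#' * `Fo_x` - reconstructed per stage via [estimate_fo_prime()] (or taken
#'   from `measured_fo_prime` when supplied);
#' * `Fv`, `Fv_x` - variable fluorescence `Fm - Fo` per stage.
#'
#' @param trace A [extract_trace()] result acquired under protocol `p`.
#' @param p The `protocol_definition` the trace follows.
#' @param measured_fo_prime Optional named vector of measured Fo' values per
#'   stage (names `L1`..`D3`) overriding the reconstruction.
#' @return An object of class `basic_signals`: named list of counts.
#' @export
extract_basic_signals <- function(trace, p, measured_fo_prime = NULL) {
  v <- validate_protocol(p)
  if (length(v)) stopf("invalid protocol: %s", v[1])
  tmax <- max(trace$times_s)
  tab <- sat_flash_table(p)
  if (tmax < max(tab$time_s)) {
    stopf("trace ends at %.2f s, before the last flash at %.2f s",
          tmax, max(tab$time_s))
  }
  s <- list()
  s$Fo <- window_mean(trace, p$fo_window[1],
                      p$fo_window[1] + p$fo_window[2] / 1000, "dark")
  fm_fl <- Filter(function(f) identical(f$yields, "Fm"), p$flashes)[[1]]
  s$Fm <- window_max(trace, fm_fl$time_s,
                     fm_fl$time_s + fm_fl$duration_ms / 1000)
  if (is.na(s$Fo) || is.na(s$Fm)) {
    stopf("trace does not cover the Fo/Fm windows of the protocol")
  }
  s$Fv <- s$Fm - s$Fo
  first_light <- min(tab$time_s[tab$phase == "light"])
  s$Fp <- window_max(trace, p$actinic_on_s, first_light - 1e-9, "actinic")
  for (i in seq_len(nrow(tab))) {
    st <- tab$stage[i]
    t0 <- tab$time_s[i]
    fm_x <- window_max(trace, t0, t0 + tab$duration_ms[i] / 1000,
                       "saturating")
    if (st == "Lss") {
      pre <- trace$times_s < t0 & trace$light_state != "saturating"
      ft_x <- trace$mean_counts[max(which(pre))]
    } else {
      ft_x <- window_mean(trace, t0 - 1, t0 - 1e-9,
                          c("actinic", "dark"))
    }
    if (is.na(fm_x) || is.na(ft_x)) {
      stopf("trace does not cover the %s flash window", st)
    }
    s[[paste0("Ft_", st)]] <- ft_x
    s[[paste0("Fm_", st)]] <- fm_x
    fo_x <- if (!is.null(measured_fo_prime) &&
                st %in% names(measured_fo_prime)) {
      measured_fo_prime[[st]]
    } else {
      estimate_fo_prime(s$Fo, s$Fm, fm_x)
    }
    s[[paste0("Fo_", st)]] <- fo_x
    s[[paste0("Fv_", st)]] <- fm_x - fo_x
  }
  if (any(unlist(s) < 0)) warnf("negative fluorescence level extracted")
  fm_stage <- unlist(s[paste0("Fm_", STAGES)])
  if (any(fm_stage > s$Fm)) {
    warnf("stage Fm' exceeds dark-adapted Fm (physically implausible)")
  }
  structure(s, class = "basic_signals")
}
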