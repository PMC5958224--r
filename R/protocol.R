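# Quenching-kinetics acquisition protocol: the timed schedule of measuring
# and saturating flashes that the simulator renders and the extractor inverts.

#' Construct a flash event
#'
#' A single timed light event of a quenching protocol: either a weak measuring
#' flash (does not drive photochemistry) or a saturating flash (transiently
#' closes all PSII reaction centers so that fluorescence rises to Fm or Fm').
#'
#' @param time_s Event onset, seconds from protocol start.
#' @param duration_ms Event duration in milliseconds.
#' @param intensity_umol Photon flux density, umol m-2 s-1.
#' @param kind `"measuring"` or `"saturating"`.
#' @param phase Protocol phase the event belongs to: `"dark_adapted"`,
#'   `"light"` (actinic period) or `"dark_relax"`.
#' @param yields Character vector of base-signal labels this event yields
#'   (e.g. `"Fm_L1"` at the flash peak, `"Ft_L1"` in the pre-flash window).
#' @return An object of class `flash_event`.
#' @export
flash_event <- function(time_s, duration_ms, intensity_umol, kind, phase,
                        yields = character()) {
  kind <- match.arg(kind, c("measuring", "saturating"))
  phase <- match.arg(phase, c("dark_adapted", "light", "dark_relax"))
  structure(list(time_s = time_s, duration_ms = duration_ms,
                 intensity_umol = intensity_umol, kind = kind,
                 phase = phase, yields = yields),
            class = "flash_event")
}

#' Construct a quenching protocol definition
#'
#' Bundles the timing constants of a PAM quenching measurement: dark
#' adaptation, the Fo measuring window, the dark-adapted Fm saturating flash,
#' the actinic light period with its saturating-flash series, and the
#' dark-relaxation flashes. Use [default_quenching_protocol()] for the
#' standard schedule.
#'
#' @param dark_adapt_end_s End of the initial dark window (s).
#' @param fo_window Numeric `c(start_s, duration_ms)` of the Fo measuring
#'   flash.
#' @param actinic_on_s,actinic_off_s Actinic light on/off times (s).
#' @param actinic_intensity_umol Actinic photon flux, umol m-2 s-1.
#' @param fp_time_s Nominal time of the Kautsky peak Fp sample (s).
#' @param flashes List of [flash_event()] objects, strictly increasing in
#'   time.
#' @param frame_rate_hz Baseline frame sampling rate between events (Hz).
#' @param flash_frame_rate_hz Dense sampling rate inside flash windows (Hz).
#' @return An object of class `protocol_definition`.
#' @export
protocol_definition <- function(dark_adapt_end_s, fo_window, actinic_on_s,
                                actinic_off_s, actinic_intensity_umol,
                                fp_time_s, flashes, frame_rate_hz = 2,
                                flash_frame_rate_hz = 50) {
  p <- structure(list(
    dark_adapt_end_s = dark_adapt_end_s,
    fo_window = as.numeric(fo_window),
    actinic_on_s = actinic_on_s,
    actinic_off_s = actinic_off_s,
    actinic_intensity_umol = actinic_intensity_umol,
    fp_time_s = fp_time_s,
    flashes = flashes,
    frame_rate_hz = frame_rate_hz,
    flash_frame_rate_hz = flash_frame_rate_hz
  ), class = "protocol_definition")
  p
}

#' Default quenching kinetics protocol
#'
#' The standard schedule: an initial dark window with the Fo measuring flash
#' (4040 ms, placed at 1.0 s) and the dark-adapted Fm saturating flash
#' (320 ms at ~2300 umol m-2 s-1) at 5.56 s; actinic light at
#' 100 umol m-2 s-1 for 70 s (22.24-92.24 s) with the Kautsky peak Fp
#' sampled at 23.12 s and saturating flashes at 32.24, 42.24, 52.24, 72.24
#' and 92.24 s (stages L1-L4, Lss); dark relaxation flashes at 122.24,
#' 152.24 and 182.24 s (stages D1-D3).
#'
#' The actinic onset is the only timing not fixed directly by the published
#' schedule; 22.24 s is the unique choice that makes the 70 s actinic period
#' contain all five light-phase flashes (the last exactly at lights-off) and
#' the Fp sample 0.88 s after light-on, where the induction transient peaks.
#'
#' @param fo_start_s Start of the Fo measuring flash inside the dark window.
#' @param actinic_on_s Actinic light onset (s); must lie after the Fm flash
#'   and before Fp.
#' @param frame_rate_hz,flash_frame_rate_hz Frame sampling rates (see
#'   [protocol_definition()]).
#' @return A `protocol_definition`.
#' @export
default_quenching_protocol <- function(fo_start_s = 1.0,
                                       actinic_on_s = 22.24,
                                       frame_rate_hz = 2,
                                       flash_frame_rate_hz = 50) {
  sat_dur <- 320
  sat_int <- 2300
  light_t <- c(32.24, 42.24, 52.24, 72.24, 92.24)
  dark_t <- c(122.24, 152.24, 182.24)
  flashes <- list(
    flash_event(fo_start_s, 4040, 0.05, "measuring", "dark_adapted",
                yields = "Fo"),
    flash_event(5.56, sat_dur, sat_int, "saturating", "dark_adapted",
                yields = "Fm")
  )
  for (i in seq_along(light_t)) {
    st <- LIGHT_STAGES[i]
    flashes[[length(flashes) + 1L]] <-
      flash_event(light_t[i], sat_dur, sat_int, "saturating", "light",
                  yields = c(paste0("Ft_", st), paste0("Fm_", st)))
  }
  for (i in seq_along(dark_t)) {
    st <- DARK_STAGES[i]
    flashes[[length(flashes) + 1L]] <-
      flash_event(dark_t[i], sat_dur, sat_int, "saturating", "dark_relax",
                  yields = c(paste0("Ft_", st), paste0("Fm_", st)))
  }
  protocol_definition(
    dark_adapt_end_s = 17,
    fo_window = c(fo_start_s, 4040),
    actinic_on_s = actinic_on_s,
    actinic_off_s = actinic_on_s + 70,
    actinic_intensity_umol = 100,
    fp_time_s = 23.12,
    flashes = flashes,
    frame_rate_hz = frame_rate_hz,
    flash_frame_rate_hz = flash_frame_rate_hz
  )
}

#' Validate a protocol definition
#'
#' Checks the structural invariants of a protocol and returns violations as
#' data rather than raising: each violation is a string naming the field and
#' the rule it breaks. An empty character vector means the protocol is valid.
#'
#' @param p A `protocol_definition`.
#' @return Character vector of violations (possibly empty).
#' @export
validate_protocol <- function(p) {
  v <- character()
  add <- function(msg) v <<- c(v, msg)
  if (!inherits(p, "protocol_definition")) {
    return("protocol: not a protocol_definition object")
  }
  times <- vapply(p$flashes, `[[`, numeric(1), "time_s")
  durs <- vapply(p$flashes, `[[`, numeric(1), "duration_ms")
  kinds <- vapply(p$flashes, `[[`, character(1), "kind")
  phases <- vapply(p$flashes, `[[`, character(1), "phase")
  ints <- vapply(p$flashes, `[[`, numeric(1), "intensity_umol")
  if (any(times < 0)) add("flashes$time_s: must be >= 0")
  if (any(durs <= 0)) add("flashes$duration_ms: must be > 0")
  if (any(diff(times) <= 0)) {
    add("flashes$time_s: must be strictly increasing")
  }
  sat <- kinds == "saturating"
  if (any(ints[sat] <= p$actinic_intensity_umol)) {
    add("flashes$intensity_umol: saturating intensity must exceed actinic")
  }
  if (p$actinic_off_s <= p$actinic_on_s) {
    add("actinic_off_s: must exceed actinic_on_s")
  }
  # flash times must lie inside their declared phase
  for (f in p$flashes) {
    ok <- switch(f$phase,
      dark_adapted = f$time_s < p$actinic_on_s,
      light = f$time_s >= p$actinic_on_s && f$time_s <= p$actinic_off_s,
      dark_relax = f$time_s > p$actinic_off_s
    )
    if (!ok) {
      add(sprintf("flashes: event at %.2f s outside declared phase '%s'",
                  f$time_s, f$phase))
    }
  }
  labels <- unlist(lapply(p$flashes, `[[`, "yields"))
  if (anyDuplicated(labels)) add("flashes$yields: labels must be unique")
  v
}

#' Base-signal labels of a protocol
#'
#' Enumerates the fluorescence levels measurable under a protocol, in time
#' order. For the default protocol these are Fo, Fm, Fp, then Ft_x and Fm_x
#' for each light-phase stage (L1-L4, Lss) and dark-relaxation stage
#' (D1-D3) - 21 labels in total.
#'
#' @param p A valid `protocol_definition`.
#' @return Character vector of labels.
#' @export
base_signal_labels <- function(p) {
  v <- validate_protocol(p)
  if (length(v)) stopf("invalid protocol: %s", v[1])
  labels <- unlist(lapply(p$flashes, `[[`, "yields"))
  # Fp is sampled from the induction curve, not a flash yield
  append(labels, "Fp", after = match("Fm", labels, nomatch = length(labels)))
}

#' Saturating-flash table of a protocol
#'
#' The light-phase and dark-relaxation saturating flashes in time order,
#' with their stage labels.
#'
#' @param p A `protocol_definition`.
#' @return data.frame with columns `stage`, `time_s`, `duration_ms`,
#'   `phase`.
#' @export
sat_flash_table <- function(p) {
  sat <- Filter(function(f) f$kind == "saturating" &&
                  f$phase %in% c("light", "dark_relax"), p$flashes)
  data.frame(
    stage = vapply(sat, function(f) sub("^Fm_", "", f$yields[2]),
                   character(1)),
    time_s = vapply(sat, `[[`, numeric(1), "time_s"),
    duration_ms = vapply(sat, `[[`, numeric(1), "duration_ms"),
    phase = vapply(sat, `[[`, character(1), "phase"),
    stringsAsFactors = FALSE
  )
}

#' Frame acquisition schedule of a protocol
#'
#' Expands a protocol into the time stamps and light states of the frames a
#' camera following it would record: a baseline grid at `frame_rate_hz` plus
#' dense sampling at `flash_frame_rate_hz` inside every flash window (so the
#' flash peaks are resolved).
#'
#' @param p A `protocol_definition`.
#' @param end_s Last frame time; defaults to 5 s past the final flash.
#' @return A data.frame with columns `time_s` and `light_state`
#'   (`dark`, `actinic` or `saturating`).
#' @export
frame_schedule <- function(p, end_s = NULL) {
  v <- validate_protocol(p)
  if (length(v)) stopf("invalid protocol: %s", v[1])
  times <- vapply(p$flashes, `[[`, numeric(1), "time_s")
  durs <- vapply(p$flashes, `[[`, numeric(1), "duration_ms")
  if (is.null(end_s)) end_s <- max(times + durs / 1000) + 5
  grid <- seq(0, end_s, by = 1 / p$frame_rate_hz)
  dense <- unlist(lapply(seq_along(times), function(i) {
    seq(times[i], times[i] + durs[i] / 1000, by = 1 / p$flash_frame_rate_hz)
  }))
  t <- sort(unique(round(c(grid, dense), 6)))
  kinds <- vapply(p$flashes, `[[`, character(1), "kind")
  sat_i <- which(kinds == "saturating")
  in_sat <- rep(FALSE, length(t))
  for (i in sat_i) {
    in_sat <- in_sat | (t >= times[i] & t <= times[i] + durs[i] / 1000)
  }
  state <- ifelse(in_sat, "saturating",
                  ifelse(t >= p$actinic_on_s & t <= p$actinic_off_s,
                         "actinic", "dark"))
  data.frame(time_s = t, light_state = state, stringsAsFactors = FALSE)
}

#' Serialize a protocol to JSON
#'
#' @param p A `protocol_definition`.
#' @param path Output file path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_protocol <- function(p, path = NULL) {
  x <- unclass(p)
  x$flashes <- lapply(p$flashes, unclass)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a protocol from JSON
#'
#' @param path File path or JSON string produced by [write_protocol()].
#' @return A `protocol_definition`.
#' @export
read_protocol <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  flashes <- lapply(x$flashes, function(f) {
    flash_event(f$time_s, f$duration_ms, f$intensity_umol, f$kind, f$phase,
                yields = unlist(f$yields))
  })
  protocol_definition(x$dark_adapt_end_s, unlist(x$fo_window),
                      x$actinic_on_s, x$actinic_off_s,
                      x$actinic_intensity_umol, x$fp_time_s, flashes,
                      x$frame_rate_hz, x$flash_frame_rate_hz)
}

#' @export
print.protocol_definition <- function(x, ...) {
  cat("Quenching protocol:\n")
  cat(sprintf("  dark adaptation to %.2f s; Fo window %.2f s + %d ms\n",
              x$dark_adapt_end_s, x$fo_window[1], as.integer(x$fo_window[2])))
  cat(sprintf("  actinic %g umol m-2 s-1 from %.2f to %.2f s\n",
              x$actinic_intensity_umol, x$actinic_on_s, x$actinic_off_s))
  tab <- sat_flash_table(x)
  cat(sprintf("  saturating flashes: Fm @ 5.56 s; %s\n",
              paste(sprintf("%s @ %.2f", tab$stage, tab$time_s),
                    collapse = "; ")))
  invisible(x)
}
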