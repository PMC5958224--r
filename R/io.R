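# Plain-text I/O: frame stacks (CSV frames + JSON sidecar), feature tables,
# and false-color parameter-map previews.

#' Write a frame stack as plain text
#'
#' Frames are flattened column-major into a CSV (one row per frame); the
#' acquisition metadata (`times_s`, `light_state`, band labels, image
#' dimensions, protocol/preset/seed) goes to a JSON sidecar next to it.
#'
#' @param stack A `frame_stack`.
#' @param prefix Output path prefix; writes `<prefix>_frames.csv` and
#'   `<prefix>_meta.json`.
#' @return Invisibly, the two paths.
#' @export
write_frame_stack <- function(stack, prefix) {
  dm <- dim(stack$frames)
  flat <- stack$frames
  dim(flat) <- c(dm[1] * dm[2], dm[3])
  frames_path <- paste0(prefix, "_frames.csv")
  meta_path <- paste0(prefix, "_meta.json")
  utils::write.table(t(flat), frames_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(dim = dm, times_s = stack$times_s,
               light_state = stack$light_state, meta = stack$meta)
  if (!is.null(stack$band)) meta$band <- stack$band
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             meta_path)
  invisible(c(frames_path, meta_path))
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `frame_stack`.
#' @export
read_frame_stack <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, "_meta.json"))
  m <- as.matrix(utils::read.table(paste0(prefix, "_frames.csv"),
                                   sep = ",", header = FALSE))
  dm <- meta$dim
  frames <- array(t(m), dim = dm)
  out <- structure(list(frames = frames, times_s = meta$times_s,
                        light_state = meta$light_state,
                        meta = meta$meta),
                   class = "frame_stack")
  if (!is.null(meta$band)) out$band <- meta$band
  out
}

#' Write a feature table to CSV
#'
#' One row per sample: metadata columns followed by the 105 parameter
#' columns (names kept verbatim, including `/`).
#'
#' @param table A [feature_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table, check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  keep <- intersect(c("day", "genotype"), names(df))
  feats <- df[, setdiff(names(df), c("sample_id", "label", keep)),
              drop = FALSE]
  feature_table(feats, df$label, sample_id = df$sample_id,
                day = if ("day" %in% keep) df$day,
                genotype = if ("genotype" %in% keep) df$genotype)
}

#' Plot a parameter map with the black-to-red false-color ramp
#'
#' @param map Numeric matrix (NA outside the plant).
#' @param main Plot title.
#' @param zlim Value range; defaults to the finite range of `map`.
#' @return Invisibly, `NULL`.
#' @export
plot_parameter_map <- function(map, main = "", zlim = NULL) {
  ramp <- grDevices::colorRampPalette(
    c("black", "#400000", "#800000", "#C00000", "red"))(64)
  if (is.null(zlim)) zlim <- range(map, finite = TRUE)
  graphics::image(t(map[nrow(map):1, , drop = FALSE]), col = ramp,
                  zlim = zlim, axes = FALSE, main = main)
  invisible(NULL)
}

#' Save a parameter map as CSV plus a PNG false-color preview
#'
#' @param map Numeric matrix.
#' @param prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>.png`.
#' @param main Title for the preview.
#' @return Invisibly, the paths.
#' @export
write_parameter_map <- function(map, prefix, main = "") {
  csv <- paste0(prefix, ".csv")
  png <- paste0(prefix, ".png")
  utils::write.table(map, csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  grDevices::png(png, width = 480, height = 480)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot_parameter_map(map, main = main)
  invisible(c(csv, png))
}
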