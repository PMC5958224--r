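# Synthetic rosette scenes: elliptical leaves arranged around a center,
# with a per-pixel leaf id and a normalized distance-to-edge map.

#' Specify a synthetic rosette scene
#'
#' @param image_shape Integer `c(rows, cols)` of the rendered image.
#' @param n_leaves Number of leaves.
#' @param leaf_length_px Range `c(min, max)` of leaf half-lengths (pixels).
#' @param leaf_width_px Range `c(min, max)` of leaf half-widths (pixels).
#' @param center Rosette center `c(row, col)`; defaults to the image center.
#' @param seed RNG seed; identical specs render identical scenes.
#' @return An object of class `rosette_spec`.
#' @export
rosette_spec <- function(image_shape = c(80, 80), n_leaves = 8,
                         leaf_length_px = c(12, 18),
                         leaf_width_px = c(4, 7),
                         center = NULL, seed = 1) {
  if (n_leaves < 0) stopf("n_leaves must be >= 0")
  if (any(leaf_length_px <= 0) || any(leaf_width_px <= 0)) {
    stopf("leaf dimensions must be positive")
  }
  if (is.null(center)) center <- (image_shape + 1) / 2
  structure(list(image_shape = as.integer(image_shape), n_leaves = n_leaves,
                 leaf_length_px = leaf_length_px,
                 leaf_width_px = leaf_width_px,
                 center = center, seed = seed),
            class = "rosette_spec")
}

#' Render a rosette scene
#'
#' Places `n_leaves` elliptical leaves at jittered angles around the center,
#' each offset outward so the leaf base sits near the center. Returns the
#' plant mask, a leaf-id map and an edge-distance map that is 0 at the leaf
#' boundary and 1 at the midrib - the spatial coordinate the drought presets
#' use to concentrate stress effects at tips and edges.
#'
#' @param spec A [rosette_spec()].
#' @return A list with elements `mask` (logical matrix), `leaf_id` (integer
#'   matrix, 0 = background), and `edge_distance` (numeric matrix in
#'   \[0, 1\]).
#' @export
generate_rosette <- function(spec) {
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  mask <- matrix(FALSE, nr, nc)
  leaf_id <- matrix(0L, nr, nc)
  edge <- matrix(0, nr, nc)
  if (spec$n_leaves == 0) {
    return(list(mask = mask, leaf_id = leaf_id, edge_distance = edge))
  }
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  with_seed(spec$seed, {
    base_ang <- seq(0, 2 * pi, length.out = spec$n_leaves + 1)[-1]
    angs <- base_ang + stats::runif(spec$n_leaves, -0.25, 0.25)
    lens <- stats::runif(spec$n_leaves, spec$leaf_length_px[1],
                         spec$leaf_length_px[2])
    wids <- stats::runif(spec$n_leaves, spec$leaf_width_px[1],
                         spec$leaf_width_px[2])
    for (i in seq_len(spec$n_leaves)) {
      a <- lens[i]; b <- wids[i]; th <- angs[i]
      # leaf center sits one half-length outward along the leaf axis
      cy <- spec$center[1] + (a + 2) * sin(th)
      cx <- spec$center[2] + (a + 2) * cos(th)
      if (cy - a < 1 || cy + a > nr || cx - a < 1 || cx + a > nc) {
        stopf("leaf %d does not fit inside the image", i)
      }
      dx <- col - cx; dy <- row - cy
      u <- dx * cos(th) + dy * sin(th)
      w <- -dx * sin(th) + dy * cos(th)
      r2 <- (u / a)^2 + (w / b)^2
      inside <- r2 <= 1
      # 0 at the ellipse boundary, 1 at the midrib/center
      d <- pmax(0, 1 - sqrt(pmax(r2, 0)))
      newpix <- inside & !mask
      mask[inside] <- TRUE
      leaf_id[newpix] <- i
      edge[inside] <- pmax(edge[inside], d[inside])
    }
  })
  list(mask = mask, leaf_id = leaf_id, edge_distance = edge)
}
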