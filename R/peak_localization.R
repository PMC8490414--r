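# Peak-based tree localization: a cell of the final-stage confidence map is
# a candidate tree if it is a strict local maximum over its in-frame
# 4-neighbourhood and exceeds the confidence threshold tau; accepted peaks
# additionally keep a minimum Euclidean separation delta (greedy,
# highest-confidence-first suppression).

#' Peak extraction parameters
#'
#' The defaults follow the dimensionally consistent reading of the peak
#' rule: `tau` is a confidence bound in (0, 1) applied as `C(p) > tau`, and
#' `delta` is a distance in map cells.
#'
#' @param tau confidence threshold in (0, 1).
#' @param delta minimum peak separation in map cells (>= 0); a candidate
#'   within `delta` (inclusive) of an already accepted peak is suppressed.
#' @export
peak_params <- function(tau = 0.35, delta = 1) {
  stopifnot(tau > 0, tau < 1, delta >= 0)
  structure(list(tau = tau, delta = delta), class = "peak_params")
}

#' Strict 4-neighbour local maxima of a confidence map
#'
#' A cell p is a local maximum if its value strictly exceeds every existing
#' neighbour (x +/- 1, y) and (x, y +/- 1); border cells compare only
#' against in-frame neighbours, and plateau ties are not maxima.
#'
#' @param map a [confidence_map] or plain numeric matrix.
#' @return data frame with 0-based `cell_x`, `cell_y` and `value`, in
#'   row-major cell order.
#' @export
find_local_maxima <- function(map) {
  g <- as_grid(map)
  H <- nrow(g); W <- ncol(g)
  up <- rbind(g[-1, , drop = FALSE], -Inf)          # neighbour at y+1
  down <- rbind(-Inf, g[-H, , drop = FALSE])        # neighbour at y-1
  right <- cbind(g[, -1, drop = FALSE], -Inf)
  left <- cbind(-Inf, g[, -W, drop = FALSE])
  is_max <- g > up & g > down & g > left & g > right
  idx <- which(is_max, arr.ind = TRUE)
  out <- data.frame(cell_x = idx[, 2] - 1L, cell_y = idx[, 1] - 1L,
                    value = g[idx])
  out[order(out$cell_y, out$cell_x), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Extract tree detections from a confidence map
#'
#' Local maxima above `tau` are visited in descending score order (ties
#' broken by row-major cell order); a candidate within `delta` of an
#' already accepted peak is dropped.  Surviving cells are mapped to input
#' pixels with the cell-centre convention `x = cell_x * scale + scale / 2`.
#'
#' @param map a [confidence_map] (its `scale` is honoured) or a matrix
#'   (scale 1).
#' @param params a [peak_params()].
#' @return data frame of detections: `x`, `y` (input pixels), `score`.
#' @export
extract_detections <- function(map, params = peak_params()) {
  stopifnot(inherits(params, "peak_params"))
  scale <- if (inherits(map, "confidence_map")) map$scale else 1L
  cand <- find_local_maxima(map)
  cand <- cand[cand$value > params$tau, , drop = FALSE]
  if (nrow(cand) > 1L) {
    cand <- cand[order(-cand$value, cand$cell_y, cand$cell_x), , drop = FALSE]
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      acc <- which(keep)
      keep[i] <- length(acc) == 0L ||
        min(sqrt((cand$cell_x[acc] - cand$cell_x[i])^2 +
                 (cand$cell_y[acc] - cand$cell_y[i])^2)) > params$delta
    }
    cand <- cand[keep, , drop = FALSE]
  }
  out <- data.frame(x = cand$cell_x * scale + scale / 2,
                    y = cand$cell_y * scale + scale / 2,
                    score = cand$value)
  rownames(out) <- NULL
  out
}

#' Translate detections from patch to mosaic pixel coordinates
#'
#' @param detections data frame with `x`, `y` (patch pixels) and any other
#'   columns (preserved).
#' @param patch_origin `c(row, col)` 0-based top-left corner of the patch
#'   within the mosaic.
#' @export
patch_to_mosaic_coords <- function(detections, patch_origin) {
  stopifnot(length(patch_origin) == 2L, all(patch_origin >= 0))
  detections$x <- detections$x + patch_origin[2]
  detections$y <- detections$y + patch_origin[1]
  detections
}

#' Map pixel detections to geographic coordinates
#'
#' Applies a 6-term affine geotransform `c(x0, dx_col, dx_row, y0, dy_col,
#' dy_row)` (GDAL ordering): `X = x0 + x*dx_col + y*dx_row`,
#' `Y = y0 + x*dy_col + y*dy_row`, where `(x, y)` are the detections'
#' (already continuous, centre-convention) pixel coordinates.
#'
#' @param detections data frame with `x`, `y` columns.
#' @param geotransform numeric length-6 affine; must be invertible.
#' @return `detections` with `geo_x`, `geo_y` columns added.
#' @export
pixel_to_geo <- function(detections, geotransform) {
  stopifnot(length(geotransform) == 6L)
  gt <- as.numeric(geotransform)
  if (abs(gt[2] * gt[6] - gt[3] * gt[5]) < 1e-12)
    stop("geotransform is not invertible", call. = FALSE)
  detections$geo_x <- gt[1] + detections$x * gt[2] + detections$y * gt[3]
  detections$geo_y <- gt[4] + detections$x * gt[5] + detections$y * gt[6]
  detections
}

#' @rdname pixel_to_geo
#' @param geo data frame with `geo_x`, `geo_y`; the inverse mapping.
#' @export
geo_to_pixel <- function(geo, geotransform) {
  stopifnot(length(geotransform) == 6L)
  gt <- as.numeric(geotransform)
  det_a <- gt[2] * gt[6] - gt[3] * gt[5]
  if (abs(det_a) < 1e-12)
    stop("geotransform is not invertible", call. = FALSE)
  dx <- geo$geo_x - gt[1]; dy <- geo$geo_y - gt[4]
  geo$x <- (gt[6] * dx - gt[3] * dy) / det_a
  geo$y <- (-gt[5] * dx + gt[2] * dy) / det_a
  geo
}

#' Write detections to CSV or GeoJSON
#'
#' CSV columns are `image_id,x,y,score`; GeoJSON emits Point features with
#' a `score` property and requires `geo_x`/`geo_y` (see [pixel_to_geo()]).
#'
#' @param detections detection data frame.
#' @param path destination.
#' @param image_id identifier for the CSV rows.
#' @export
write_detections_csv <- function(detections, path, image_id = "image") {
  df <- data.frame(image_id = rep(image_id, nrow(detections)),
                   x = detections$x, y = detections$y,
                   score = detections$score)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
write_detections_geojson <- function(detections, path) {
  stopifnot(all(c("geo_x", "geo_y", "score") %in% names(detections)))
  feats <- lapply(seq_len(nrow(detections)), function(i) list(
    type = "Feature",
    geometry = list(type = "Point",
                    coordinates = c(detections$geo_x[i], detections$geo_y[i])),
    properties = list(score = detections$score[i])))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
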