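#' Per-stage Gaussian spread schedule
#'
#' The multi-stage module is supervised with confidence maps whose Gaussian
#' spread shrinks across stages: stage 1 uses `sigma_max`, the final stage T
#' uses `sigma_min`, and interior stages interpolate linearly between the
#' two.  A sharp final kernel pins the prediction to the tree centre while
#' the broad early kernels give the network an easier, smoother target.
#'
#' @param sigma_min final-stage spread in map cells (> 0).
#' @param sigma_max first-stage spread in map cells (>= `sigma_min`).
#' @param n_stages number of refinement stages T (>= 1).  With `n_stages = 1`
#'   the single stage is rendered at `sigma_min`.
#' @return an object of class `sigma_schedule` with elements `sigma_min`,
#'   `sigma_max`, `n_stages` and `values` (length-T vector, non-increasing).
#' @examples
#' make_sigma_schedule(1, 4, 4)$values  # 4 3 2 1
#' @export
make_sigma_schedule <- function(sigma_min = 1, sigma_max = 4, n_stages = 4) {
  if (!is.numeric(sigma_min) || length(sigma_min) != 1L || sigma_min <= 0)
    stop("invalid schedule: sigma_min must be a positive scalar", call. = FALSE)
  if (!is.numeric(sigma_max) || length(sigma_max) != 1L || sigma_max < sigma_min)
    stop("invalid schedule: need 0 < sigma_min <= sigma_max", call. = FALSE)
  n_stages <- as.integer(n_stages)
  if (is.na(n_stages) || n_stages < 1L)
    stop("invalid schedule: n_stages must be >= 1", call. = FALSE)
  values <- if (n_stages == 1L) sigma_min else
    seq(sigma_max, sigma_min, length.out = n_stages)
  structure(
    list(sigma_min = sigma_min, sigma_max = sigma_max,
         n_stages = n_stages, values = values),
    class = "sigma_schedule")
}

#' @export
print.sigma_schedule <- function(x, ...) {
  cat(sprintf("sigma schedule: T = %d, sigma_max = %g -> sigma_min = %g\n",
              x$n_stages, x$sigma_max, x$sigma_min))
  cat("  values:", paste(signif(x$values, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Confidence map container
#'
#' A confidence map is a grid of per-cell tree-presence probabilities in
#' \[0, 1\].  `scale` records how many input-image pixels one map cell
#' covers (the network predicts at scale 4 after two 2x2 poolings).
#'
#' @param grid numeric matrix with values in \[0, 1\] (rows = y, cols = x).
#' @param stage refinement stage index this map belongs to (>= 1).
#' @param scale integer input pixels per map cell (>= 1).
#' @return an object of class `confidence_map`.
#' @export
confidence_map <- function(grid, stage = 1L, scale = 1L) {
  grid <- as.matrix(grid)
  if (anyNA(grid) || min(grid) < 0 || max(grid) > 1)
    stop("confidence map values must lie in [0, 1]", call. = FALSE)
  scale <- as.integer(scale)
  if (is.na(scale) || scale < 1L)
    stop("scale must be a positive integer", call. = FALSE)
  structure(list(grid = grid, stage = as.integer(stage), scale = scale),
            class = "confidence_map")
}

#' @export
print.confidence_map <- function(x, ...) {
  cat(sprintf("confidence map: %d x %d cells, stage %d, scale %d, max %.4f\n",
              nrow(x$grid), ncol(x$grid), x$stage, x$scale, max(x$grid)))
  invisible(x)
}

as_grid <- function(map) {
  if (inherits(map, "confidence_map")) map$grid else as.matrix(map)
}

#' Render a ground-truth confidence map from point annotations
#'
#' Each annotation contributes a Gaussian kernel of spread `sigma`,
#' normalised to peak 1, centred on the map cell nearest to the annotation
#' divided by `scale`.  Overlapping kernels are combined by pointwise
#' maximum so values stay interpretable as probabilities; the cell holding
#' an annotation centre is exactly 1.
#'
#' @param annotations data frame with columns `x`, `y` in 0-based input-image
#'   pixel coordinates (x = column, y = row), or NULL/empty for a zero map.
#' @param shape map grid shape `c(H, W)` in cells.
#' @param sigma Gaussian spread in map cells (> 0).
#' @param scale input pixels per map cell; the input frame is
#'   `shape * scale`.
#' @param stage stage index stored on the result.
#' @return a [confidence_map].
#' @examples
#' m <- render_confidence_map(data.frame(x = 32, y = 32), c(64, 64), sigma = 2)
#' m$grid[33, 33]  # 1 (R indexing is 1-based; the annotation is 0-based)
#' @export
render_confidence_map <- function(annotations, shape, sigma, scale = 1L,
                                  stage = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 1), sigma > 0)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  scale <- as.integer(scale)
  grid <- matrix(0, H, W)
  ann <- as_annotations(annotations)
  if (nrow(ann)) {
    if (any(ann$x < 0 | ann$x >= W * scale | ann$y < 0 | ann$y >= H * scale))
      stop("annotation outside the input-image frame", call. = FALSE)
    cx <- pmin(round(ann$x / scale), W - 1L)  # 0-based map cells
    cy <- pmin(round(ann$y / scale), H - 1L)
    ys <- seq_len(H) - 1; xs <- seq_len(W) - 1
    for (a in seq_len(nrow(ann))) {
      k <- exp(-outer((ys - cy[a])^2, (xs - cx[a])^2, "+") / (2 * sigma^2))
      grid <- pmax(grid, k)
    }
  }
  confidence_map(grid, stage = stage, scale = scale)
}

#' Render the full stack of per-stage target maps
#'
#' @param annotations as in [render_confidence_map()].
#' @param shape input image shape `c(H, W)` in pixels; must be divisible by
#'   `scale`.
#' @param schedule a [make_sigma_schedule()] result.
#' @param scale input pixels per map cell.
#' @return list of T [confidence_map]s, broad (`sigma_max`) first, sharp
#'   (`sigma_min`) last.
#' @export
render_stage_targets <- function(annotations, shape, schedule, scale = 1L) {
  stopifnot(inherits(schedule, "sigma_schedule"))
  scale <- as.integer(scale)
  if (any(shape %% scale != 0))
    stop("input shape must be divisible by scale", call. = FALSE)
  map_shape <- as.integer(shape) %/% scale
  lapply(seq_len(schedule$n_stages), function(t)
    render_confidence_map(annotations, map_shape, schedule$values[t],
                          scale = scale, stage = t))
}

as_annotations <- function(x) {
  if (is.null(x)) return(data.frame(x = numeric(0), y = numeric(0)))
  x <- as.data.frame(x)
  if (!nrow(x)) return(data.frame(x = numeric(0), y = numeric(0)))
  if (!all(c("x", "y") %in% names(x)))
    stop("annotations need columns 'x' and 'y'", call. = FALSE)
  x
}

#' Persist / load a confidence map as 32-bit float TIFF
#'
#' For inspection and debugging; the stage index is conventionally encoded
#' in the filename (e.g. `map_stage3.tif`).
#' @param map a [confidence_map].
#' @param path output path.
#' @export
write_confidence_map <- function(map, path) {
  stopifnot(inherits(map, "confidence_map"))
  tiff::writeTIFF(map$grid, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_confidence_map
#' @param stage,scale metadata to attach on read (not stored in the TIFF).
#' @export
read_confidence_map <- function(path, stage = 1L, scale = 1L) {
  g <- tiff::readTIFF(path)
  if (length(dim(g)) == 3L) g <- g[, , 1]
  confidence_map(g, stage = stage, scale = scale)
}
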