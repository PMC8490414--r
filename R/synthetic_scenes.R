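# Synthetic aerial scenes: textured circular crowns on cluttered vegetated
# background, with exact centre-point ground truth.  These stand in for the
# real (non-public) orthomosaic patches so that every downstream stage —
# target rendering, training, peak extraction, evaluation — is testable.

#' Specification of a synthetic scene
#'
#' @param height,width patch size in pixels.
#' @param n_trees number of crowns to place (>= 0).
#' @param crown_radius_range `c(min, max)` crown radius in pixels.
#' @param min_center_separation minimum Euclidean distance between any two
#'   crown centres, pixels.
#' @param clutter_level background clutter intensity in \[0, 1\]: 0 is a
#'   nearly uniform canopy background, 1 adds strong low-frequency mottling
#'   and many non-target blobs.
#' @param allow_border_clipping if TRUE, crown centres may fall within one
#'   radius of the border so crowns are clipped (a known failure mode of
#'   point detectors); if FALSE, crowns are kept fully inside the frame.
#' @param seed integer RNG seed; scenes are byte-identical for equal
#'   (spec, seed).
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(height = 256L, width = 256L, n_trees = 8L,
                       crown_radius_range = c(6, 12),
                       min_center_separation = 12,
                       clutter_level = 0.5,
                       allow_border_clipping = TRUE,
                       seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  n_trees <- as.integer(n_trees)
  stopifnot(height > 0, width > 0, n_trees >= 0,
            length(crown_radius_range) == 2L,
            crown_radius_range[1] > 0,
            crown_radius_range[1] <= crown_radius_range[2],
            min_center_separation >= 0,
            clutter_level >= 0, clutter_level <= 1)
  if (!allow_border_clipping &&
      (height < 2 * crown_radius_range[2] || width < 2 * crown_radius_range[2]))
    stop("patch too small to hold an unclipped crown", call. = FALSE)
  structure(
    list(height = height, width = width, n_trees = n_trees,
         crown_radius_range = as.numeric(crown_radius_range),
         min_center_separation = as.numeric(min_center_separation),
         clutter_level = as.numeric(clutter_level),
         allow_border_clipping = isTRUE(allow_border_clipping),
         seed = as.integer(seed)),
    class = "scene_spec")
}

#' An easy scene configuration for controlled experiments
#'
#' High-contrast, well-separated crowns on a quiet background — the regime
#' in which a correctly implemented detector should recover essentially
#' every tree.  Used by the scaled-down end-to-end recovery experiments.
#' @param size square patch side, pixels.
#' @param n_trees crowns per scene.
#' @param seed RNG seed.
#' @export
easy_scene_spec <- function(size = 128L, n_trees = 5L, seed = 1L) {
  scene_spec(height = size, width = size, n_trees = n_trees,
             crown_radius_range = c(8, 11), min_center_separation = 26,
             clutter_level = 0.15, allow_border_clipping = FALSE, seed = seed)
}

# Evaluate code under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Low-frequency "value noise": a coarse random grid bilinearly upsampled.
value_noise <- function(H, W, cells = 8L) {
  coarse <- array(runif(cells * cells), dim = c(cells, cells, 1L))
  nn_upsample_bilinear_fwd(coarse, H, W)[, , 1]
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

place_centers <- function(spec) {
  n <- spec$n_trees
  if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  margin <- if (spec$allow_border_clipping) 0 else spec$crown_radius_range[2]
  lo_x <- margin; hi_x <- spec$width - 1 - margin
  lo_y <- margin; hi_y <- spec$height - 1 - margin
  if (hi_x < lo_x || hi_y < lo_y)
    stop("infeasible scene spec: no room for crown centres", call. = FALSE)
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L; max_attempts <- 300L * n + 300L
  while (length(xs) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(
        "infeasible scene spec: placed %d of %d crowns after %d attempts",
        length(xs), n, attempts), call. = FALSE)
    x <- runif(1, lo_x, hi_x); y <- runif(1, lo_y, hi_y)
    if (length(xs) == 0 ||
        min(sqrt((xs - x)^2 + (ys - y)^2)) >= spec$min_center_separation) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  data.frame(x = xs, y = ys)
}

render_background <- function(spec) {
  H <- spec$height; W <- spec$width; cl <- spec$clutter_level
  base <- c(0.13, 0.22, 0.11) + runif(3, -0.02, 0.02)
  img <- array(0, dim = c(H, W, 3L))
  mottle <- value_noise(H, W, 8L)
  fine <- matrix(runif(H * W, -1, 1), H, W)
  for (ch in 1:3) {
    amp <- (0.03 + 0.10 * cl) * runif(1, 0.7, 1.3)
    img[, , ch] <- base[ch] + amp * (mottle - 0.5) + (0.01 + 0.025 * cl) * fine
  }
  # non-target blobs whose hue matches the background
  n_blobs <- round(cl * 8)
  if (n_blobs > 0) {
    for (b in seq_len(n_blobs)) {
      cx <- runif(1, 0, W - 1); cy <- runif(1, 0, H - 1)
      r <- runif(1, 4, 14); gain <- runif(1, 0.75, 1.35)
      xr <- max(1L, ceiling(cx - r)):min(W, floor(cx + r) + 1L)
      yr <- max(1L, ceiling(cy - r)):min(H, floor(cy + r) + 1L)
      d2 <- outer(((yr - 1) - cy)^2, ((xr - 1) - cx)^2, "+")
      alpha <- clamp01(1 - d2 / r^2)
      for (ch in 1:3)
        img[yr, xr, ch] <- img[yr, xr, ch] * (1 + alpha * (gain - 1))
    }
  }
  clamp01(img)
}

render_crown <- function(img, cx, cy, r) {
  H <- dim(img)[1]; W <- dim(img)[2]
  # brighter, yellower rosette clearly offset in hue from the background
  col <- c(0.38, 0.55, 0.16) * runif(1, 0.9, 1.1) + runif(3, -0.02, 0.02)
  xr <- max(1L, ceiling(cx - r)):min(W, floor(cx + r) + 1L)
  yr <- max(1L, ceiling(cy - r)):min(H, floor(cy + r) + 1L)
  d <- sqrt(outer(((yr - 1) - cy)^2, ((xr - 1) - cx)^2, "+"))
  alpha <- clamp01((r - d) / 1.5)             # 1.5 px soft rim
  shade <- 1 - 0.55 * clamp01(d / r)^1.5      # radial falloff from the apex
  speck <- 1 + 0.30 * matrix(runif(length(d), -1, 1), nrow(d))
  for (ch in 1:3) {
    crown <- clamp01(col[ch] * shade * speck)
    img[yr, xr, ch] <- (1 - alpha) * img[yr, xr, ch] + alpha * crown
  }
  img
}

#' Generate one synthetic annotated scene
#'
#' Renders `spec$n_trees` radially shaded, speckle-textured crowns over a
#' cluttered background; crown centres are the ground-truth annotations.
#' Deterministic for a fixed `(spec, seed)`.
#'
#' @param spec a [scene_spec()].
#' @return an object of class `annotated_scene`: list with `image`
#'   (H x W x 3 array in \[0, 1\]), `annotations` (data frame `x`, `y`,
#'   `radius`; 0-based pixel coordinates, x = column, y = row) and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    img <- render_background(spec)
    centers <- place_centers(spec)
    radii <- if (nrow(centers))
      runif(nrow(centers), spec$crown_radius_range[1],
            spec$crown_radius_range[2]) else numeric(0)
    for (i in seq_len(nrow(centers)))
      img <- render_crown(img, centers$x[i], centers$y[i], radii[i])
    structure(
      list(image = img,
           annotations = cbind(centers, radius = radii),
           spec = spec),
      class = "annotated_scene")
  })
}

#' @export
print.annotated_scene <- function(x, ...) {
  cat(sprintf("annotated scene: %d x %d px, %d trees (seed %d)\n",
              dim(x$image)[1], dim(x$image)[2], nrow(x$annotations),
              x$spec$seed))
  invisible(x)
}

#' Largest-remainder apportionment of n items by fractions
#'
#' Each split gets `floor(n * f)` items; leftover items go to the splits
#' with the largest fractional remainders (earlier split wins ties).
#' @param n total count.
#' @param fractions positive fractions summing to 1 (tolerance 1e-6).
#' @return integer vector of split sizes summing to `n`.
#' @examples
#' split_sizes(1394, c(0.423, 0.345, 0.232))  # 590 481 323
#' @export
split_sizes <- function(n, fractions) {
  stopifnot(n >= 0, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("split fractions must sum to 1", call. = FALSE)
  quota <- n * fractions
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Deterministic per-scene seed derived from the master seed and scene index.
scene_seed <- function(master, index) {
  as.integer(((master %% 65521) * 65519 + index * 7919) %% 2147483563 + 1)
}

#' Generate a partitioned synthetic dataset
#'
#' Scenes are generated with per-scene seeds derived deterministically from
#' the master seed, then partitioned into train/validation/test by
#' largest-remainder apportionment of the split fractions (default: the
#' 42.3/34.5/23.2 split used for the real palm dataset).
#'
#' @param n_scenes number of scenes (>= 3 so every split is populated).
#' @param spec_template a [scene_spec()]; its `seed` field is ignored.
#' @param split_fractions `c(train, validation, test)`, positive, summing
#'   to 1.
#' @param seed master seed.
#' @return an object of class `scene_dataset`: lists `train`, `validation`,
#'   `test` of `annotated_scene`s plus `sizes` and `seed`.
#' @export
generate_dataset <- function(n_scenes, spec_template,
                             split_fractions = c(0.423, 0.345, 0.232),
                             seed = 1L) {
  stopifnot(inherits(spec_template, "scene_spec"))
  n_scenes <- as.integer(n_scenes)
  if (n_scenes < 3L)
    stop("need at least 3 scenes to populate train/validation/test",
         call. = FALSE)
  sizes <- split_sizes(n_scenes, split_fractions)
  scenes <- lapply(seq_len(n_scenes), function(i) {
    sp <- spec_template
    sp$seed <- scene_seed(seed, i)
    generate_scene(sp)
  })
  idx <- split(seq_len(n_scenes),
               rep(c("train", "validation", "test"), times = sizes))
  structure(
    list(train = scenes[idx$train %||% integer(0)],
         validation = scenes[idx$validation %||% integer(0)],
         test = scenes[idx$test %||% integer(0)],
         sizes = setNames(sizes, c("train", "validation", "test")),
         fractions = split_fractions, seed = seed),
    class = "scene_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scene_dataset <- function(x, ...) {
  cat(sprintf("scene dataset: %d train / %d validation / %d test (seed %d)\n",
              x$sizes[1], x$sizes[2], x$sizes[3], x$seed))
  invisible(x)
}

#' Write a scene to disk (8-bit PNG + annotation CSV)
#'
#' @param scene an `annotated_scene`.
#' @param image_path PNG destination.
#' @param annotations_path optional CSV destination (`image_id,x,y`).
#' @param image_id identifier written into the CSV.
#' @export
write_scene <- function(scene, image_path, annotations_path = NULL,
                        image_id = "scene") {
  stopifnot(inherits(scene, "annotated_scene"))
  png::writePNG(scene$image, image_path)
  if (!is.null(annotations_path)) {
    ann <- scene$annotations
    write_annotations(
      data.frame(image_id = rep(image_id, nrow(ann)), x = ann$x, y = ann$y),
      annotations_path)
  }
  invisible(image_path)
}
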