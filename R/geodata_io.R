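# Orthomosaic plumbing: tiling into nonoverlapping patches, region-based
# dataset splits, raster and annotation I/O.  Conventions used throughout
# the package: 0-based pixel indexing, (row, col) = (y, x), half-open
# intervals.

#' Tile an orthomosaic into nonoverlapping square patches
#'
#' Lays a row-major lattice of full `patch_size` x `patch_size` patches over
#' the mosaic; residual margins smaller than a patch are dropped (never
#' padded), matching the real dataset's full-patch bookkeeping.
#'
#' @param mosaic_shape `c(rows, cols)` in pixels.
#' @param patch_size square patch side in pixels (> 0).
#' @param gsd optional ground sample distance, metres per pixel.
#' @return an object of class `patch_grid`: `origins` data frame with
#'   0-based `row`, `col` top-left corners, plus `patch_size`,
#'   `mosaic_shape`, `gsd`.  A mosaic smaller than one patch yields an
#'   empty (zero-row) grid.
#' @examples
#' nrow(tile_orthomosaic(c(5619, 5946), 256)$origins)  # 21 * 23 = 483
#' @export
tile_orthomosaic <- function(mosaic_shape, patch_size, gsd = NULL) {
  stopifnot(length(mosaic_shape) == 2L, patch_size > 0)
  patch_size <- as.integer(patch_size)
  nr <- mosaic_shape[1] %/% patch_size
  nc <- mosaic_shape[2] %/% patch_size
  origins <- if (nr < 1 || nc < 1)
    data.frame(row = integer(0), col = integer(0))
  else
    expand.grid(col = (seq_len(nc) - 1L) * patch_size,
                row = (seq_len(nr) - 1L) * patch_size)[, c("row", "col")]
  rownames(origins) <- NULL
  structure(list(origins = origins, patch_size = patch_size,
                 mosaic_shape = as.integer(mosaic_shape), gsd = gsd),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("patch grid: %d patches of %d px over %d x %d mosaic\n",
              nrow(x$origins), x$patch_size,
              x$mosaic_shape[1], x$mosaic_shape[2]))
  invisible(x)
}

#' Ground extent of one patch
#'
#' @param patch_size patch side in pixels.
#' @param gsd ground sample distance, metres per pixel.
#' @return side length in metres (`patch_size * gsd`); 256 px at 0.10 m/px
#'   is 25.6 m.
#' @export
patch_ground_extent <- function(patch_size, gsd) {
  stopifnot(patch_size > 0, gsd > 0)
  patch_size * gsd
}

#' Region-based split definition
#'
#' Rectangular regions in mosaic pixel coordinates, each assigned to one of
#' train/validation/test.  Region-based (rather than random) splitting
#' avoids spatial leakage between sets.
#'
#' @param regions data frame with columns `label`, `row0`, `col0`, `row1`,
#'   `col1` (half-open rectangles: rows in `[row0, row1)`).
#' @param assignment named character vector mapping region labels to
#'   `"train"`, `"validation"` or `"test"`.
#' @return object of class `region_split`.
#' @export
region_split <- function(regions, assignment) {
  stopifnot(all(c("label", "row0", "col0", "row1", "col1") %in% names(regions)),
            all(assignment %in% c("train", "validation", "test")),
            all(regions$label %in% names(assignment)))
  structure(list(regions = regions, assignment = assignment),
            class = "region_split")
}

#' Assign patches to dataset splits by region
#'
#' Each patch goes to the split of the region containing its centre.
#'
#' @param grid a [tile_orthomosaic()] result.
#' @param regions a [region_split()].
#' @return list with integer vectors `train`, `validation`, `test` indexing
#'   `grid$origins` (an exact partition).
#' @export
assign_region_splits <- function(grid, regions) {
  stopifnot(inherits(grid, "patch_grid"), inherits(regions, "region_split"))
  half <- grid$patch_size / 2
  cy <- grid$origins$row + half
  cx <- grid$origins$col + half
  out <- list(train = integer(0), validation = integer(0), test = integer(0))
  rg <- regions$regions
  for (p in seq_along(cy)) {
    hit <- which(cy[p] >= rg$row0 & cy[p] < rg$row1 &
                 cx[p] >= rg$col0 & cx[p] < rg$col1)
    if (length(hit) == 0L)
      stop(sprintf("patch %d (centre row %.1f, col %.1f) not covered by any region",
                   p, cy[p], cx[p]), call. = FALSE)
    split <- regions$assignment[[rg$label[hit[1]]]]
    out[[split]] <- c(out[[split]], p)
  }
  out
}

#' Read / write point annotations as CSV
#'
#' The on-disk format is a CSV with header `image_id,x,y`; coordinates are
#' 0-based pixels with x = column and y = row.
#'
#' @param path CSV path.
#' @return `read_annotations`: data frame with columns `image_id`, `x`, `y`.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L || trimws(lines[1]) != "image_id,x,y")
    stop("annotation file must start with header 'image_id,x,y'",
         call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (!length(body))
    return(data.frame(image_id = character(0), x = numeric(0), y = numeric(0)))
  parts <- strsplit(body, ",", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    bad <- length(p) != 3L ||
      is.na(suppressWarnings(as.numeric(p[2]))) ||
      is.na(suppressWarnings(as.numeric(p[3])))
    if (bad)
      stop(sprintf("malformed annotation row at line %d: '%s'",
                   i + 1L, body[i]), call. = FALSE)
  }
  data.frame(image_id = vapply(parts, `[`, "", 1L),
             x = as.numeric(vapply(parts, `[`, "", 2L)),
             y = as.numeric(vapply(parts, `[`, "", 3L)))
}

#' @rdname read_annotations
#' @param annotations data frame with columns `image_id`, `x`, `y`.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(all(c("image_id", "x", "y") %in% names(annotations)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# 0-based pixel coordinates; x = column, y = row", con)
  writeLines("image_id,x,y", con)
  if (nrow(annotations))
    writeLines(sprintf("%s,%.6g,%.6g", annotations$image_id,
                       annotations$x, annotations$y), con)
  invisible(path)
}

#' Read / write an RGB raster (PNG or TIFF)
#'
#' PNG carries no georeferencing and is read with an identity geotransform;
#' for georeferenced TIFFs supply the affine geotransform explicitly (e.g.
#' from a sidecar JSON) to [pixel_to_geo()].
#'
#' @param path raster path; format chosen by extension (.png / .tif(f)).
#' @return H x W x 3 numeric array with values in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported raster format: ", ext, call. = FALSE))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3]
  img
}

#' @rdname read_image
#' @param image H x W x 3 array in \[0, 1\].
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = , tiff = tiff::writeTIFF(image, path, bits.per.sample = 8L),
    stop("unsupported raster format: ", ext, call. = FALSE))
  invisible(path)
}

#' Extract one patch (and its annotations) from a mosaic
#'
#' @param image mosaic array (H x W x 3).
#' @param origin `c(row, col)` 0-based top-left corner.
#' @param patch_size square side, pixels.
#' @param annotations optional data frame `x`, `y` in mosaic pixels; those
#'   falling inside the patch are returned translated to patch coordinates.
#' @return list `image` (patch array) and `annotations`.
#' @export
extract_patch <- function(image, origin, patch_size, annotations = NULL) {
  r0 <- origin[1]; c0 <- origin[2]
  stopifnot(r0 >= 0, c0 >= 0,
            r0 + patch_size <= dim(image)[1],
            c0 + patch_size <= dim(image)[2])
  patch <- image[(r0 + 1):(r0 + patch_size), (c0 + 1):(c0 + patch_size), ,
                 drop = FALSE]
  ann <- NULL
  if (!is.null(annotations)) {
    a <- as_annotations(annotations)
    keep <- a$x >= c0 & a$x < c0 + patch_size &
            a$y >= r0 & a$y < r0 + patch_size
    ann <- a[keep, , drop = FALSE]
    ann$x <- ann$x - c0
    ann$y <- ann$y - r0
    rownames(ann) <- NULL
  }
  list(image = patch, annotations = ann)
}
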