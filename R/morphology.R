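#' Read a grayscale cell image
#'
#' Reads a PNG or TIFF micrograph as a numeric matrix with intensities in
#' \[0, 1\]. Multi-channel images are averaged to grayscale.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric intensity matrix (rows x columns).
#' @export
read_cell_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a grayscale image to PNG
#'
#' @param image Numeric matrix with values in \[0, 1\].
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_cell_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

# Merge 4-connected labels that touch diagonally so components are
# 8-connected (EBImage::bwlabel is 4-connected).
merge_diagonal_labels <- function(lab) {
  mx <- max(lab)
  if (mx < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # \ diagonal neighbours
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # / diagonal neighbours
  pairs <- rbind(cbind(a1[a1 > 0 & b1 > 0 & a1 != b1],
                       b1[a1 > 0 & b1 > 0 & a1 != b1]),
                 cbind(a2[a2 > 0 & b2 > 0 & a2 != b2],
                       b2[a2 > 0 & b2 > 0 & a2 != b2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(mx)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(mx), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[out > 0] <- relab[out[out > 0]]
  out
}

#' Segment suspended cells in a grayscale image
#'
#' Foreground pixels are those above a global intensity threshold chosen by
#' Otsu's histogram-bimodality method (unless a numeric threshold is given).
#' Foreground is partitioned into 8-connected components; components touching
#' the image border or smaller than `min_area` are discarded. Axis lengths
#' come from second-order central moments (the ellipse-equivalent axes), and
#' each region carries its roundness R_c = 4 area / (pi major^2) together
#' with the classical circularity 4 pi area / perimeter^2 as a secondary
#' shape measure (circularity is never used for round-cell counting).
#'
#' @param image Numeric intensity matrix (values in \[0, 1\]).
#' @param min_area Minimum region area in px^2 (default 50).
#' @param threshold `NULL` for automatic Otsu thresholding, or a numeric
#'   intensity cutoff in \[0, 1\].
#' @return A data.frame of class `cell_regions`, one row per retained cell:
#'   `label`, `area` (px^2), `perimeter` (px), `major_axis`, `minor_axis`
#'   (px), `roundness`, `circularity`, `centroid_x`, `centroid_y` (px).
#'   A uniform image yields zero rows.
#' @export
segment_cells <- function(image, min_area = 50, threshold = NULL) {
  if (!is.matrix(image) || length(image) == 0L) {
    stop("image must be a non-empty numeric matrix", call. = FALSE)
  }
  empty <- data.frame(label = integer(0), area = numeric(0),
                      perimeter = numeric(0), major_axis = numeric(0),
                      minor_axis = numeric(0), roundness = numeric(0),
                      circularity = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0))
  class(empty) <- c("cell_regions", "data.frame")
  if (diff(range(image)) == 0) return(empty)
  if (is.null(threshold)) {
    threshold <- EBImage::otsu(EBImage::Image(image), range = range(image))
  }
  mask <- image > threshold
  if (!any(mask)) return(empty)
  lab <- merge_diagonal_labels(EBImage::bwlabel(mask))
  # drop border-touching components
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  if (length(border)) lab[lab %in% border] <- 0L
  if (max(lab) == 0) return(empty)
  lab <- EBImage::bwlabel(lab > 0)
  lab <- merge_diagonal_labels(lab)
  sh <- EBImage::computeFeatures.shape(lab)
  mo <- EBImage::computeFeatures.moment(lab, image)
  keep <- sh[, "s.area"] >= min_area
  if (!any(keep)) return(empty)
  sh <- sh[keep, , drop = FALSE]
  mo <- mo[keep, , drop = FALSE]
  major <- mo[, "m.majoraxis"]
  minor <- major * sqrt(1 - mo[, "m.eccentricity"]^2)
  out <- data.frame(
    label = seq_len(nrow(sh)),
    area = sh[, "s.area"],
    perimeter = sh[, "s.perimeter"],
    major_axis = major,
    minor_axis = minor,
    roundness = roundness(sh[, "s.area"], major),
    circularity = 4 * pi * sh[, "s.area"] / sh[, "s.perimeter"]^2,
    centroid_x = mo[, "m.cx"],
    centroid_y = mo[, "m.cy"],
    row.names = NULL)
  class(out) <- c("cell_regions", "data.frame")
  out
}

#' Cell roundness
#'
#' R_c = 4 area / (pi major_axis^2), the roundness definition used by common
#' image-analysis software. For an ideal ellipse it equals the minor/major
#' axis ratio; a disc gives 1. Raster discretization can push the raw value
#' slightly above 1; values up to 1.05 are clamped to 1, larger values raise
#' an error (degenerate region).
#'
#' @param area Region area in px^2 (> 0).
#' @param major_axis Ellipse-equivalent major axis length in px (> 0).
#' @return Roundness in (0, 1\].
#' @examples
#' roundness(pi * 20^2, 40)  # disc of radius 20 -> 1
#' @export
roundness <- function(area, major_axis) {
  if (any(!is.finite(area)) || any(area <= 0) ||
      any(!is.finite(major_axis)) || any(major_axis <= 0)) {
    stop("area and major_axis must be finite and positive", call. = FALSE)
  }
  rc <- 4 * area / (pi * major_axis^2)
  if (any(rc > 1.05)) {
    stop("roundness > 1.05: degenerate region measurements", call. = FALSE)
  }
  pmin(rc, 1)
}

#' Round-cell frequency
#'
#' f_r = (number of cells with R_c strictly above the threshold) / (total
#' number of cells examined). The conventional threshold separating round
#' from stretched suspension cells is R_c > 0.8.
#'
#' @param regions A `cell_regions` data.frame from [segment_cells()] (or any
#'   data.frame with a `roundness` column).
#' @param threshold Roundness threshold (default 0.8); strict inequality.
#' @return An object of class `morphology_summary`: a list with `n_cells`,
#'   `f_r`, `threshold` and the vector `roundness`.
#' @export
round_fraction <- function(regions, threshold = 0.8) {
  rc <- regions$roundness
  if (is.null(rc) || length(rc) == 0L) {
    stop("round fraction undefined for an empty region list", call. = FALSE)
  }
  structure(
    list(n_cells = length(rc),
         f_r = sum(rc > threshold) / length(rc),
         threshold = threshold,
         roundness = rc),
    class = "morphology_summary")
}

#' @export
print.morphology_summary <- function(x, ...) {
  cat(sprintf("Morphology: %d cells, f_r = %.3f (R_c > %g)\n",
              x$n_cells, x$f_r, x$threshold))
  invisible(x)
}
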