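#' Construct an IHC marker image
#'
#' A grayscale marker scan with its segmentation threshold and the viable /
#' necrotic tissue masks. The segmentation threshold corresponds to the
#' interactively set level above background staining; the necrosis mask (from
#' a consecutive HE section) is excluded from all analyses.
#'
#' @param pixels numeric matrix of grey values (rows = y, columns = x).
#' @param pixel_size pixel edge length in micrometres (default 2.59).
#' @param marker_name marker label, e.g. `"CA9"`.
#' @param threshold segmentation threshold in grey values, in
#'   `(0, dynamic_range]`.
#' @param viable_mask,necrosis_mask logical matrices congruent with `pixels`;
#'   `necrosis_mask` defaults to all-`FALSE`.
#' @param dynamic_range maximum representable grey value (default 4095).
#' @return an object of class `marker_image`.
#' @export
marker_image <- function(pixels, pixel_size = 2.59, marker_name = "marker",
                         threshold, viable_mask = NULL, necrosis_mask = NULL,
                         dynamic_range = 4095) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (is.null(viable_mask)) viable_mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  if (is.null(necrosis_mask))
    necrosis_mask <- matrix(FALSE, nrow(pixels), ncol(pixels))
  if (!identical(dim(pixels), dim(viable_mask)) ||
      !identical(dim(pixels), dim(necrosis_mask)))
    stop("mask dimensions must match the pixel grid")
  if (missing(threshold) || is.null(threshold))
    stop("segmentation 'threshold' must be set")
  stop_if_not_scalar_number(threshold, "threshold", positive = TRUE)
  if (threshold > dynamic_range)
    stop("'threshold' must be within (0, dynamic_range]")
  stop_if_not_scalar_number(pixel_size, "pixel_size", positive = TRUE)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 marker_name = marker_name, threshold = threshold,
                 viable_mask = viable_mask & !necrosis_mask,
                 necrosis_mask = necrosis_mask,
                 dynamic_range = dynamic_range),
            class = "marker_image")
}

#' Construct a binary mask
#' @param pixels logical matrix.
#' @param pixel_size pixel edge length in micrometres.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size = 2.59) {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  structure(list(pixels = pixels != 0, pixel_size = pixel_size),
            class = "binary_mask")
}

mask_pixels <- function(m) {
  if (inherits(m, "binary_mask")) m$pixels else m != 0
}

check_congruent <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks/images must have congruent pixel grids")
}

#' Segment a marker image into a binary positivity mask
#'
#' A pixel is positive iff its grey value is at or above the image's
#' segmentation threshold and it lies in the viable tumor area (necrosis
#' excluded). The inclusive `>=` convention makes the boundary deterministic.
#'
#' @param image a [marker_image()].
#' @return a [binary_mask()] of positively stained viable pixels.
#' @export
segment_marker <- function(image) {
  stopifnot(inherits(image, "marker_image"))
  binary_mask(image$pixels >= image$threshold & image$viable_mask &
                !image$necrosis_mask,
              image$pixel_size)
}

#' Positively stained fraction of the viable tumor area
#'
#' @param positive a [binary_mask()] of positive pixels (e.g. from
#'   [segment_marker()]).
#' @param viable a [binary_mask()] of the viable tumor area (non-empty).
#' @return fraction in `[0, 1]`.
#' @export
staining_fraction <- function(positive, viable) {
  p <- mask_pixels(positive); v <- mask_pixels(viable)
  check_congruent(p, v)
  nv <- sum(v)
  if (nv == 0) stop("viable mask is empty")
  sum(p & v) / nv
}

#' BrdU labeling index
#'
#' Number of positively stained nuclei divided by the total number of nuclei
#' within the viable tumor area.
#'
#' @param nuclei data.frame with columns `x`, `y` (pixel coordinates,
#'   x = column, y = row) and logical `positive`.
#' @param viable a [binary_mask()] of the viable area.
#' @return fraction in `[0, 1]`.
#' @export
labeling_index <- function(nuclei, viable) {
  v <- mask_pixels(viable)
  stopifnot(all(c("x", "y", "positive") %in% names(nuclei)))
  if (nrow(nuclei) > 0 &&
      (any(nuclei$x < 1 | nuclei$x > ncol(v)) ||
       any(nuclei$y < 1 | nuclei$y > nrow(v))))
    stop("nucleus coordinates outside image bounds")
  inside <- nrow(nuclei) > 0 & v[cbind(round(nuclei$y), round(nuclei$x))]
  n <- sum(inside)
  if (n == 0) stop("no nuclei inside the viable area")
  sum(nuclei$positive[inside]) / n
}

#' Vascular density in structures per square millimetre
#'
#' Counts 8-connected components of the vessel mask restricted to the viable
#' area and divides by the viable area in mm^2 (pixel count times pixel size
#' squared).
#'
#' @param vessel_mask a [binary_mask()] of vessel staining.
#' @param viable a [binary_mask()] of the viable area (non-empty).
#' @return structures per mm^2 (>= 0).
#' @export
vascular_density <- function(vessel_mask, viable) {
  vm <- mask_pixels(vessel_mask); v <- mask_pixels(viable)
  check_congruent(vm, v)
  nv <- sum(v)
  if (nv == 0) stop("viable mask is empty")
  lab <- .label_components_2d_cpp((vm & v) * 1L, 8L)
  px <- if (inherits(vessel_mask, "binary_mask")) vessel_mask$pixel_size
        else if (inherits(viable, "binary_mask")) viable$pixel_size else 2.59
  attr(lab, "n_components") / (nv * (px / 1000)^2)
}

#' Perfused vessel fraction
#'
#' Fraction of vascular structures (8-connected components of the vessel
#' mask) that overlap the Hoechst perfusion mask in at least one pixel.
#'
#' @param vessel_mask a [binary_mask()] of vessel staining (>= 1 structure).
#' @param perfusion_mask a [binary_mask()] of the perfusion signal.
#' @return fraction in `[0, 1]`.
#' @export
perfused_fraction <- function(vessel_mask, perfusion_mask) {
  vm <- mask_pixels(vessel_mask); pm <- mask_pixels(perfusion_mask)
  check_congruent(vm, pm)
  lab <- .label_components_2d_cpp(vm * 1L, 8L)
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0) stop("no vascular structures in vessel mask")
  perfused <- unique(lab[lab > 0 & pm])
  length(perfused) / ncomp
}

#' Quantify one marker phantom/image into its scalar IHC parameters
#'
#' Convenience wrapper producing a one-row parameter record (staining
#' fraction, and where the inputs are available labeling index, vascular
#' density and perfused fraction).
#'
#' @param image a [marker_image()].
#' @param vessel_mask,perfusion_mask optional [binary_mask()] objects.
#' @param nuclei optional nuclei data.frame (see [labeling_index()]).
#' @param sample_id sample identifier carried into the record.
#' @return one-row data.frame.
#' @export
quantify_ihc <- function(image, vessel_mask = NULL, perfusion_mask = NULL,
                         nuclei = NULL, sample_id = "sample") {
  viable <- binary_mask(image$viable_mask, image$pixel_size)
  pos <- segment_marker(image)
  out <- data.frame(sample_id = sample_id, marker = image$marker_name,
                    staining_fraction = staining_fraction(pos, viable))
  out$labeling_index <-
    if (!is.null(nuclei)) labeling_index(nuclei, viable) else NA_real_
  out$vascular_density <-
    if (!is.null(vessel_mask)) vascular_density(vessel_mask, viable)
    else NA_real_
  out$perfused_fraction <-
    if (!is.null(vessel_mask) && !is.null(perfusion_mask))
      perfused_fraction(vessel_mask, perfusion_mask) else NA_real_
  out
}
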