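#' Specify a synthetic IHC marker-image phantom
#'
#' The phantom emulates a scanned fluorescent IHC section: a 12-bit grayscale
#' image (default dynamic range 4095, pixel size 2.59 um) containing blob-like
#' positively stained areas, thin ribbon-like vascular structures, point
#' nuclei and a necrotic region to be excluded from analysis.
#'
#' @param width,height image size in pixels.
#' @param pixel_size pixel edge length in micrometres.
#' @param dynamic_range maximum grey value.
#' @param stain_fraction_target requested positive fraction of the viable
#'   area. The generator rasterizes random blobs until the realized fraction
#'   matches the target to within one pixel; the realized fraction is what is
#'   returned as ground truth.
#' @param n_vessels number of vascular structures (mutually separated by at
#'   least two pixels so they never merge).
#' @param perfused_fraction_target fraction of vessels flagged perfused;
#'   realized exactly as `round(target * n_vessels)` vessels.
#' @param n_nuclei number of non-overlapping nuclei.
#' @param labeling_index_target probability that a nucleus is positive.
#' @param necrosis_fraction fraction of the section that is necrotic.
#' @param background_level,signal_level grey levels of unstained/stained
#'   tissue (`signal_level > background_level`).
#' @param noise_sd Gaussian read-out noise SD in grey values.
#' @param marker_name marker label carried through to the image object.
#' @param seed integer seed.
#' @return an object of class `image_phantom_spec`.
#' @export
image_phantom_spec <- function(width = 400, height = 400, pixel_size = 2.59,
                               dynamic_range = 4095,
                               stain_fraction_target = 0.3, n_vessels = 20,
                               perfused_fraction_target = 0.6, n_nuclei = 200,
                               labeling_index_target = 0.2,
                               necrosis_fraction = 0.1,
                               background_level = 200, signal_level = 1500,
                               noise_sd = 0, marker_name = "marker",
                               seed = NULL) {
  stop_if_not_scalar_number(width, "width", positive = TRUE)
  stop_if_not_scalar_number(height, "height", positive = TRUE)
  stop_if_not_scalar_number(pixel_size, "pixel_size", positive = TRUE)
  check_fraction(stain_fraction_target, "stain_fraction_target")
  check_fraction(perfused_fraction_target, "perfused_fraction_target")
  check_fraction(labeling_index_target, "labeling_index_target")
  check_fraction(necrosis_fraction, "necrosis_fraction")
  if (signal_level <= background_level)
    stop("'signal_level' must exceed 'background_level'")
  if (background_level < 0 || signal_level > dynamic_range)
    stop("grey levels must lie within [0, dynamic_range]")
  if (n_vessels < 0 || n_nuclei < 0) stop("counts must be >= 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, dynamic_range = dynamic_range,
                 stain_fraction_target = stain_fraction_target,
                 n_vessels = as.integer(n_vessels),
                 perfused_fraction_target = perfused_fraction_target,
                 n_nuclei = as.integer(n_nuclei),
                 labeling_index_target = labeling_index_target,
                 necrosis_fraction = necrosis_fraction,
                 background_level = background_level,
                 signal_level = signal_level, noise_sd = noise_sd,
                 marker_name = marker_name, seed = seed),
            class = "image_phantom_spec")
}

disk_pixels <- function(cy, cx, r, nr, nc) {
  ys <- max(1L, floor(cy - r)):min(nr, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(nc, ceiling(cx + r))
  g <- expand.grid(y = ys, x = xs)
  d2 <- (g$y - cy)^2 + (g$x - cx)^2
  g <- g[d2 <= r^2, , drop = FALSE]
  cbind(g$y, g$x)
}

# 3x3 dilation of a sparse pixel set given as (row, col) coordinates
dilate_coords <- function(coords, nr, nc, times = 1L) {
  out <- matrix(FALSE, nr, nc)
  if (nrow(coords) == 0) return(out)
  for (dy in -times:times) for (dx in -times:times) {
    y <- coords[, 1] + dy
    x <- coords[, 2] + dx
    ok <- y >= 1 & y <= nr & x >= 1 & x <= nc
    out[cbind(y[ok], x[ok])] <- TRUE
  }
  out
}

random_vessel_path <- function(start, nr, nc, viable, n_steps) {
  dirs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  d <- sample.int(8, 1)
  pos <- start
  path <- matrix(pos, 1, 2)
  for (i in seq_len(n_steps)) {
    turn <- sample(c(-1L, 0L, 0L, 0L, 1L), 1)  # mostly straight: ribbon-like
    d <- ((d - 1L + turn) %% 8L) + 1L
    pos <- pos + dirs[d, ]
    if (pos[1] < 2 || pos[1] > nr - 1 || pos[2] < 2 || pos[2] > nc - 1) break
    if (!viable[pos[1], pos[2]]) break
    path <- rbind(path, pos)
  }
  path
}

#' Generate a synthetic IHC marker image with exact ground truth
#'
#' Builds the phantom described by an [image_phantom_spec()]: a necrotic
#' region (nearest `necrosis_fraction` of pixels to a random centre), blob
#' staining rasterized to the target fraction of the viable area, separated
#' ribbon vessels with an exact number flagged perfused (the Hoechst-like
#' perfusion mask is a one-pixel halo around perfused vessels), and
#' non-overlapping nuclei with Bernoulli positivity. All ground truth is the
#' realized (rasterized) quantity, so downstream quantification on the
#' noiseless phantom recovers it exactly.
#'
#' @param spec an [image_phantom_spec()].
#' @return list with elements `image` (a [marker_image()] whose threshold is
#'   midway between background and signal level), `vessel_mask`,
#'   `perfusion_mask` (both [binary_mask()]), `nuclei` (data.frame `x`, `y`,
#'   `positive`) and `truth` (realized stain fraction and mask, vessel and
#'   perfused counts, necrosis mask, nucleus counts).
#' @export
generate_marker_image <- function(spec) {
  stopifnot(inherits(spec, "image_phantom_spec"))
  with_seed(spec$seed, {
    nr <- spec$height; nc <- spec$width
    npix <- nr * nc

    # necrosis: k nearest pixels to a random centre -> realized fraction k/npix
    k_nec <- round(spec$necrosis_fraction * npix)
    necrosis <- matrix(FALSE, nr, nc)
    if (k_nec > 0) {
      cy <- stats::runif(1, 1, nr); cx <- stats::runif(1, 1, nc)
      d2 <- outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, `+`)
      necrosis[order(d2)[seq_len(k_nec)]] <- TRUE
    }
    viable <- !necrosis
    n_viable <- sum(viable)
    if (n_viable == 0) stop("necrosis_fraction leaves no viable tissue")

    # staining blobs, rasterized to floor(target * viable area) pixels
    stain <- matrix(FALSE, nr, nc)
    target_px <- floor(spec$stain_fraction_target * n_viable)
    r_max <- max(3, round(min(nr, nc) / 12))
    it <- 0
    while (sum(stain) < target_px) {
      it <- it + 1
      if (it > 20000) stop("stain_fraction_target infeasible for image size")
      cy <- stats::runif(1, 1, nr); cx <- stats::runif(1, 1, nc)
      if (!viable[round(cy), round(cx)]) next
      r <- stats::runif(1, 3, r_max)
      px <- disk_pixels(cy, cx, r, nr, nc)
      new <- px[viable[px] & !stain[px], , drop = FALSE]
      if (nrow(new) == 0) next
      need <- target_px - sum(stain)
      if (nrow(new) > need) {
        d2 <- (new[, 1] - cy)^2 + (new[, 2] - cx)^2
        new <- new[order(d2)[seq_len(need)], , drop = FALSE]
      }
      stain[new] <- TRUE
    }

    # vessels: ribbon walks, pairwise separation >= 2 px so a 1-px perfusion
    # halo can never touch a different vessel
    vessel <- matrix(FALSE, nr, nc)
    vessel_px <- vector("list", spec$n_vessels)
    blocked <- matrix(FALSE, nr, nc)
    for (v in seq_len(spec$n_vessels)) {
      placed <- FALSE
      for (att in seq_len(400)) {
        start <- c(sample.int(nr - 2, 1) + 1L, sample.int(nc - 2, 1) + 1L)
        if (!viable[start[1], start[2]] || blocked[start[1], start[2]]) next
        path <- random_vessel_path(start, nr, nc, viable,
                                   n_steps = sample(20:60, 1))
        path <- unique(path)
        if (nrow(path) < 8) next
        if (any(blocked[path])) next
        vessel[path] <- TRUE
        vessel_px[[v]] <- path
        blocked <- blocked | dilate_coords(path, nr, nc, times = 2L)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place ", spec$n_vessels,
             " separated vessels; image too small")
    }
    n_perfused <- round(spec$perfused_fraction_target * spec$n_vessels)
    perfused_flags <- rep(FALSE, spec$n_vessels)
    if (spec$n_vessels > 0 && n_perfused > 0)
      perfused_flags[sample.int(spec$n_vessels, n_perfused)] <- TRUE
    perfusion <- matrix(FALSE, nr, nc)
    for (v in which(perfused_flags))
      perfusion <- perfusion | dilate_coords(vessel_px[[v]], nr, nc, 1L)

    # nuclei: Chebyshev separation >= 3 px via an occupancy grid
    nuclei <- matrix(NA_real_, 0, 2)
    occ <- matrix(FALSE, nr, nc)
    tries <- 0
    while (nrow(nuclei) < spec$n_nuclei) {
      tries <- tries + 1
      if (tries > 200 * max(spec$n_nuclei, 1))
        stop("n_nuclei exceeds image capacity")
      y <- sample.int(nr, 1); x <- sample.int(nc, 1)
      if (!viable[y, x] || occ[y, x]) next
      nuclei <- rbind(nuclei, c(y, x))
      occ <- occ | dilate_coords(matrix(c(y, x), 1), nr, nc, 2L)
    }
    positive <- if (spec$n_nuclei > 0)
      stats::runif(spec$n_nuclei) < spec$labeling_index_target else logical(0)
    nuclei_df <- data.frame(x = nuclei[, 2], y = nuclei[, 1],
                            positive = positive)

    pixels <- matrix(spec$background_level, nr, nc)
    pixels[stain] <- spec$signal_level
    pixels[necrosis] <- spec$background_level
    if (spec$noise_sd > 0)
      pixels <- pixels + stats::rnorm(npix, 0, spec$noise_sd)
    pixels <- round(pmin(pmax(pixels, 0), spec$dynamic_range))

    img <- marker_image(pixels = pixels, pixel_size = spec$pixel_size,
                        marker_name = spec$marker_name,
                        threshold = (spec$background_level +
                                       spec$signal_level) / 2,
                        viable_mask = viable, necrosis_mask = necrosis,
                        dynamic_range = spec$dynamic_range)
    list(image = img,
         vessel_mask = binary_mask(vessel, spec$pixel_size),
         perfusion_mask = binary_mask(perfusion, spec$pixel_size),
         nuclei = nuclei_df,
         truth = list(stain_fraction = sum(stain & viable) / n_viable,
                      stain_mask = stain, necrosis_mask = necrosis,
                      necrosis_fraction = sum(necrosis) / npix,
                      n_vessels = spec$n_vessels,
                      n_perfused = sum(perfused_flags),
                      perfused_flags = perfused_flags,
                      n_nuclei_positive = sum(positive),
                      viable_area_mm2 = n_viable * (spec$pixel_size / 1000)^2))
  })
}
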