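#' Rescaled intensity sample from a marker image
#'
#' Linearly rescales grey values by the image's segmentation threshold so a
#' pixel at threshold maps to the reference level `ref` in every image,
#' making intensities comparable between images of the same marker acquired
#' at different gains, and returns the rescaled values restricted to the
#' positively stained viable area.
#'
#' @param image a [marker_image()] with a positive threshold.
#' @param ref reference level the threshold maps to (default 1000). Entropy
#'   and skewness are invariant to `ref` once the bin width is scaled
#'   accordingly; only the mean feature depends on it.
#' @return numeric vector of rescaled intensities (possibly empty when
#'   nothing stains positive).
#' @export
rescale_by_threshold <- function(image, ref = 1000) {
  stopifnot(inherits(image, "marker_image"))
  stop_if_not_scalar_number(ref, "ref", positive = TRUE)
  pos <- segment_marker(image)
  image$pixels[pos$pixels] * (ref / image$threshold)
}

#' Discretize intensities into a fixed-bin-width first-order histogram
#'
#' Values are assigned to half-open bins `[i*w, (i+1)*w)` anchored at zero
#' (`i = floor(v / w)`). Only occupied bins are retained: `N_l` is the number
#' of discrete intensity levels actually present.
#'
#' @param values numeric vector (non-empty, finite).
#' @param bin_width bin width in intensity units (> 0); the conventional
#'   defaults are 0.5 SUV for PET and 25 grey-value units for IHC.
#' @return an object of class `xen_histogram`: `bin_width`, integer `levels`,
#'   probabilities `p` (summing to 1), `n_levels`.
#' @export
discretize_intensities <- function(values, bin_width) {
  stop_if_not_scalar_number(bin_width, "bin_width", positive = TRUE)
  if (length(values) == 0 || any(!is.finite(values)))
    stop("'values' must be non-empty and finite")
  idx <- floor(values / bin_width)
  tab <- table(idx)
  structure(list(bin_width = bin_width,
                 levels = as.integer(names(tab)),
                 p = as.vector(tab) / length(values),
                 n_levels = length(tab)),
            class = "xen_histogram")
}

#' Shannon entropy of a first-order histogram, in bits
#'
#' \eqn{-\sum_{i=1}^{N_l} P(i) \log_2 P(i)} over the occupied bins, with the
#' convention \eqn{0 \log 0 = 0}. Bounded by \eqn{\log_2 N_l}.
#'
#' @param hist an `xen_histogram` from [discretize_intensities()], or a
#'   numeric probability vector.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(hist) {
  p <- if (inherits(hist, "xen_histogram")) hist$p else hist
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("probabilities must be >= 0 and sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Population skewness of an intensity sample
#'
#' Uncorrected moment estimator \eqn{m_3 / m_2^{3/2}}. Returns `NA` (the
#' undefined flag propagated as a missing value downstream) for fewer than 3
#' values or zero variance.
#'
#' @param values numeric vector.
#' @return skewness, or `NA_real_` when undefined.
#' @export
intensity_skewness <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) return(NA_real_)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((values - m)^3) / m2^1.5
}

#' Mean intensity of a sample
#' @param values numeric non-empty vector (rescaled intensities).
#' @return arithmetic mean.
#' @export
mean_intensity <- function(values) {
  if (length(values) == 0) stop("empty intensity sample")
  mean(values)
}

texture_features <- function(values, bin_width, include_mean = TRUE) {
  if (length(values) == 0)
    return(c(mean = NA_real_, entropy = NA_real_, skewness = NA_real_)
           [if (include_mean) 1:3 else 2:3])
  ent <- shannon_entropy(discretize_intensities(values, bin_width))
  out <- c(entropy = ent, skewness = intensity_skewness(values))
  if (include_mean) out <- c(mean = mean(values), out)
  out
}

#' Extract the global texture feature block for a set of samples
#'
#' For each sample, computes mean/entropy/skewness per area-stain IHC marker
#' (from rescaled intensities in the positive area) and entropy/skewness for
#' PET (from SUV within the tumor VOI). Vascular density and perfused
#' fraction have no associated intensity distribution and contribute no
#' features. A marker with an empty positive area yields missing values for
#' its three features.
#'
#' @param samples named list (names = sample ids); each element is a list
#'   with optional components `ihc` (named list: marker -> rescaled intensity
#'   vector) and `pet` (SUV vector within the tumor VOI).
#' @param markers IHC marker names defining the column block (default: the
#'   seven area-stain markers).
#' @param ihc_bin_width,pet_bin_width discretization bin widths (defaults 25
#'   grey units, 0.5 SUV).
#' @return data.frame: `sample_id`, then `<marker>_mean`, `<marker>_entropy`,
#'   `<marker>_skewness` per marker and `PET_entropy`, `PET_skewness` —
#'   exactly `3 * length(markers) + 2` feature columns.
#' @export
extract_feature_block <- function(samples,
                                  markers = c("PIMO", "BrdU", "pAKT", "EGFR",
                                              "MCT4", "CA9", "GLUT1"),
                                  ihc_bin_width = 25, pet_bin_width = 0.5) {
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("'samples' must be a named list keyed by sample id")
  cols <- c(as.vector(t(outer(markers, c("mean", "entropy", "skewness"),
                              paste, sep = "_"))),
            "PET_entropy", "PET_skewness")
  out <- data.frame(sample_id = names(samples), stringsAsFactors = FALSE)
  for (cl in cols) out[[cl]] <- NA_real_
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    for (m in markers) {
      v <- s$ihc[[m]]
      if (!is.null(v)) {
        f <- texture_features(v, ihc_bin_width, include_mean = TRUE)
        out[i, paste(m, c("mean", "entropy", "skewness"), sep = "_")] <- f
      }
    }
    if (!is.null(s$pet)) {
      f <- texture_features(s$pet, pet_bin_width, include_mean = FALSE)
      out[i, c("PET_entropy", "PET_skewness")] <- f
    }
  }
  out
}
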