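#' Construct a PET uptake volume
#'
#' A 3-D grid of activity concentration with the injection metadata needed to
#' convert it to standardized uptake values (SUV). Concentrations and the
#' injected activity are assumed decay-corrected to the scan start (pass a
#' `decay_factor` to [to_suv()] otherwise); tissue density is taken as
#' 1 g/mL so SUV is dimensionless.
#'
#' @param voxels 3-D numeric array of activity concentration, in the same
#'   activity unit per mL as `injected_activity` (e.g. MBq/mL with MBq).
#' @param voxel_size numeric length-3 voxel edge lengths in mm (default
#'   transaxial 0.43, 0.43, plane separation 0.8).
#' @param injected_activity injected activity (> 0).
#' @param body_weight body weight in grams (> 0).
#' @param sample_id sample identifier.
#' @return an object of class `uptake_volume`.
#' @export
uptake_volume <- function(voxels, voxel_size = c(0.43, 0.43, 0.8),
                          injected_activity, body_weight,
                          sample_id = "sample") {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("'voxels' must be a 3-D array")
  if (any(voxels < 0)) stop("activity concentrations must be >= 0")
  stop_if_not_scalar_number(injected_activity, "injected_activity",
                            positive = TRUE)
  stop_if_not_scalar_number(body_weight, "body_weight", positive = TRUE)
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("'voxel_size' must be three positive lengths (mm)")
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 injected_activity = injected_activity,
                 body_weight = body_weight, sample_id = sample_id),
            class = "uptake_volume")
}

#' Construct a volume of interest
#' @param mask logical 3-D array.
#' @param kind `"tumor"` or `"muscle"`.
#' @return an object of class `voi`.
#' @export
voi <- function(mask, kind = c("tumor", "muscle")) {
  kind <- match.arg(kind)
  if (!is.array(mask) || length(dim(mask)) != 3)
    stop("'mask' must be a 3-D array")
  mask <- mask != 0
  if (!any(mask)) stop("VOI mask is empty")
  structure(list(mask = mask, kind = kind), class = "voi")
}

#' Convert an uptake volume to SUV
#'
#' SUV per voxel is the activity concentration (decay-corrected to scan
#' start) divided by injected activity per gram body weight:
#' \eqn{SUV(v) = C(v) \cdot d / (A_{inj} / W)} with decay factor `d`.
#'
#' @param volume an [uptake_volume()].
#' @param decay_factor multiplicative decay correction (> 0; 1 if inputs are
#'   already corrected).
#' @return 3-D numeric array of SUV, same dimensions as the volume.
#' @export
to_suv <- function(volume, decay_factor = 1) {
  stopifnot(inherits(volume, "uptake_volume"))
  stop_if_not_scalar_number(decay_factor, "decay_factor", positive = TRUE)
  volume$voxels * decay_factor /
    (volume$injected_activity / volume$body_weight)
}

#' Auto-delineate the tumor VOI at a fraction of SUVmax
#'
#' Thresholds the SUV grid at `frac` times the maximum SUV within the search
#' region, then keeps the 26-connected component(s) containing the
#' maximum-SUV voxel(s); voxels above threshold but disconnected from the
#' maximum (e.g. bladder or heart) are excluded. Ties at the maximum all seed
#' the result. The default 40% threshold is the standard small-animal
#' auto-delineation level.
#'
#' @param suv 3-D SUV array (from [to_suv()]).
#' @param search_region optional [voi()] restricting the search (default:
#'   whole grid).
#' @param frac threshold fraction of SUVmax in `(0, 1]` (default 0.40).
#' @return a tumor [voi()].
#' @export
delineate_tumor <- function(suv, search_region = NULL, frac = 0.40) {
  if (!is.array(suv) || length(dim(suv)) != 3)
    stop("'suv' must be a 3-D array")
  if (frac <= 0 || frac > 1) stop("'frac' must be in (0, 1]")
  region <- if (is.null(search_region)) array(TRUE, dim(suv))
            else search_region$mask
  if (!identical(dim(region), dim(suv)))
    stop("search region not congruent with SUV grid")
  if (!any(region)) stop("empty search region")
  vals <- suv[region]
  suvmax <- max(vals)
  cand <- region & suv >= frac * suvmax
  lab <- .label_components_3d_cpp(as.integer(cand), dim(suv), 26L)
  dim(lab) <- dim(suv)
  seeds <- unique(lab[region & suv == suvmax])
  voi(array(lab %in% seeds[seeds > 0], dim(suv)), kind = "tumor")
}

#' SUVmax and SUVmean within a VOI
#' @param suv 3-D SUV array.
#' @param voi_obj a [voi()].
#' @return named numeric vector `c(SUVmax=, SUVmean=)`.
#' @export
suv_stats <- function(suv, voi_obj) {
  stopifnot(inherits(voi_obj, "voi"))
  if (!identical(dim(suv), dim(voi_obj$mask)))
    stop("VOI not congruent with SUV grid")
  vals <- suv[voi_obj$mask]
  if (length(vals) == 0) stop("empty VOI")
  c(SUVmax = max(vals), SUVmean = mean(vals))
}

#' Tumor-to-muscle uptake ratio
#' @param tumor_mean mean tumor SUV.
#' @param muscle_mean mean muscle SUV (> 0).
#' @return T/M ratio.
#' @export
tumor_to_muscle <- function(tumor_mean, muscle_mean) {
  stop_if_not_scalar_number(tumor_mean, "tumor_mean")
  stop_if_not_scalar_number(muscle_mean, "muscle_mean", positive = TRUE)
  tumor_mean / muscle_mean
}

#' Percentage of injected dose per gram of tissue
#'
#' \%ID/g = 100 * (tissue activity / injected activity) / tissue weight, the
#' standard gamma-well-counter biodistribution quantity.
#'
#' @param tissue_activity measured tissue activity (same unit as
#'   `injected_activity`).
#' @param injected_activity injected activity (> 0).
#' @param tissue_weight tissue weight in grams (> 0).
#' @return \%ID/g.
#' @export
percent_id_per_gram <- function(tissue_activity, injected_activity,
                                tissue_weight) {
  if (any(tissue_activity < 0)) stop("'tissue_activity' must be >= 0")
  stop_if_not_scalar_number(injected_activity, "injected_activity",
                            positive = TRUE)
  if (any(tissue_weight <= 0)) stop("'tissue_weight' must be > 0")
  100 * (tissue_activity / injected_activity) / tissue_weight
}

#' Quantify one uptake volume into its scalar PET parameters
#'
#' Converts to SUV, auto-delineates the tumor at `frac` of SUVmax, and
#' reports SUVmax, SUVmean and (when a muscle VOI is given) the
#' tumor-to-muscle ratio.
#'
#' @param volume an [uptake_volume()].
#' @param muscle_voi optional muscle [voi()] (manually drawn upstream).
#' @param search_region optional tumor search region [voi()].
#' @param frac delineation threshold fraction (default 0.40).
#' @param decay_factor decay correction passed to [to_suv()].
#' @return one-row data.frame with `sample_id`, `SUVmax`, `SUVmean`, `TM`.
#' @export
quantify_pet <- function(volume, muscle_voi = NULL, search_region = NULL,
                         frac = 0.40, decay_factor = 1) {
  suv <- to_suv(volume, decay_factor)
  tumor <- delineate_tumor(suv, search_region, frac)
  st <- suv_stats(suv, tumor)
  tm <- if (!is.null(muscle_voi))
    tumor_to_muscle(st[["SUVmean"]], mean(suv[muscle_voi$mask]))
  else NA_real_
  data.frame(sample_id = volume$sample_id, SUVmax = st[["SUVmax"]],
             SUVmean = st[["SUVmean"]], TM = tm)
}
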