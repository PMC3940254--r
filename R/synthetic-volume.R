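#' Specify a synthetic PET uptake-volume phantom
#'
#' A uniform background with one spherical hot region at a plateau SUV,
#' emulating a flank xenograft on a small-animal scanner grid (default voxel
#' 0.43 x 0.43 x 0.8 mm). Activity concentrations are computed so that
#' concentration / (injected_activity / body_weight) equals the requested
#' SUV field exactly; optional Gaussian noise is added on the SUV scale.
#'
#' @param dims integer length-3 grid size in voxels.
#' @param voxel_size voxel edge lengths in mm.
#' @param center sphere centre in voxel coordinates (default: grid centre).
#' @param radius_mm sphere radius in mm.
#' @param plateau_suv SUV inside the sphere (> background).
#' @param background_suv SUV elsewhere (> 0).
#' @param injected_activity injected activity, MBq.
#' @param body_weight body weight, g.
#' @param noise_sd Gaussian noise SD in SUV units.
#' @param seed integer seed.
#' @return an object of class `volume_phantom_spec`.
#' @export
volume_phantom_spec <- function(dims = c(48, 48, 24),
                                voxel_size = c(0.43, 0.43, 0.8),
                                center = NULL, radius_mm = 4,
                                plateau_suv = 2.0, background_suv = 0.1,
                                injected_activity = 10, body_weight = 20,
                                noise_sd = 0, seed = NULL) {
  if (length(dims) != 3 || any(dims < 4)) stop("'dims' must be 3 sizes >= 4")
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("'voxel_size' must be three positive lengths")
  stop_if_not_scalar_number(plateau_suv, "plateau_suv", positive = TRUE)
  stop_if_not_scalar_number(background_suv, "background_suv", positive = TRUE)
  if (plateau_suv <= background_suv)
    stop("'plateau_suv' must exceed 'background_suv'")
  stop_if_not_scalar_number(injected_activity, "injected_activity",
                            positive = TRUE)
  stop_if_not_scalar_number(body_weight, "body_weight", positive = TRUE)
  if (is.null(center)) center <- (dims + 1) / 2
  structure(list(dims = as.integer(dims), voxel_size = voxel_size,
                 center = center, radius_mm = radius_mm,
                 plateau_suv = plateau_suv, background_suv = background_suv,
                 injected_activity = injected_activity,
                 body_weight = body_weight, noise_sd = noise_sd, seed = seed),
            class = "volume_phantom_spec")
}

#' Generate a synthetic uptake volume with exact ground truth
#'
#' @param spec a [volume_phantom_spec()].
#' @return list with elements `volume` (an [uptake_volume()]), and `truth`
#'   (noiseless `suvmax`, `suvmean`, the hot-region `voi_mask`, and the
#'   noiseless SUV array).
#' @export
generate_uptake_volume <- function(spec) {
  stopifnot(inherits(spec, "volume_phantom_spec"))
  with_seed(spec$seed, {
    d <- spec$dims
    # physical distance from sphere centre, voxel-size aware
    dx <- (seq_len(d[1]) - spec$center[1]) * spec$voxel_size[1]
    dy <- (seq_len(d[2]) - spec$center[2]) * spec$voxel_size[2]
    dz <- (seq_len(d[3]) - spec$center[3]) * spec$voxel_size[3]
    d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
    hot <- d2 <= spec$radius_mm^2
    if (!any(hot)) stop("hot region contains no voxels; increase radius_mm")
    suv_true <- array(spec$background_suv, d)
    suv_true[hot] <- spec$plateau_suv
    suv <- suv_true
    if (spec$noise_sd > 0)
      suv <- pmax(suv + stats::rnorm(length(suv), 0, spec$noise_sd), 0)
    conc <- suv * (spec$injected_activity / spec$body_weight)
    vol <- uptake_volume(conc, voxel_size = spec$voxel_size,
                         injected_activity = spec$injected_activity,
                         body_weight = spec$body_weight)
    list(volume = vol,
         truth = list(suvmax = spec$plateau_suv,
                      suvmean = spec$plateau_suv,
                      voi_mask = hot, suv = suv_true))
  })
}
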