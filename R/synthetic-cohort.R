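#' Specify one synthetic parameter with a hierarchical variance structure
#'
#' A parameter is generated as \eqn{y_{ij} = \mu + b_i + e_{ij}} on a latent
#' Gaussian scale, with line effects \eqn{b_i \sim N(0, \sigma^2_{between})}
#' and residuals \eqn{e_{ij} \sim N(0, \sigma^2_{within})}, then optionally
#' transformed. The target heterogeneity ratio of the parameter is
#' \eqn{\sigma^2_{within} / (\sigma^2_{within} + \sigma^2_{between})}: low
#' values mean the parameter is distinctive of the tumor line.
#'
#' @param name parameter name (unique within a cohort).
#' @param grand_mean latent grand mean \eqn{\mu}.
#' @param var_between between-line variance (>= 0).
#' @param var_within within-line variance (>= 0); the two variances may not
#'   both be zero.
#' @param transform `"identity"`, `"logistic"` (maps the latent scale to the
#'   unit interval, for fraction-valued parameters) or `"exp"` (maps to
#'   positive values, for SUV-like parameters).
#' @return an object of class `parameter_spec`.
#' @export
parameter_spec <- function(name, grand_mean = 0, var_between = 1,
                           var_within = 1,
                           transform = c("identity", "logistic", "exp")) {
  transform <- match.arg(transform)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string")
  stop_if_not_scalar_number(grand_mean, "grand_mean")
  stop_if_not_scalar_number(var_between, "var_between")
  stop_if_not_scalar_number(var_within, "var_within")
  if (var_between < 0 || var_within < 0)
    stop("variances must be >= 0")
  if (var_between + var_within <= 0)
    stop("var_between + var_within must be > 0")
  structure(list(name = name, grand_mean = grand_mean,
                 var_between = var_between, var_within = var_within,
                 transform = transform),
            class = "parameter_spec")
}

#' Specify a synthetic tumor cohort
#'
#' Describes a cohort of `n_lines` tumor lines with `n_per_line` tumors each
#' (a vector gives per-line sizes) and a set of parameters, each with its own
#' within/between-line variance structure. Sporadic missingness can be
#' injected completely at random: each entry of `missingness` is a list with
#' elements `parameters` (column names blanked on the same sampled rows, so a
#' failed assay knocks out all its columns at once) and `n_missing`.
#'
#' @param n_lines number of tumor lines (>= 2).
#' @param n_per_line tumors per line (scalar or length-`n_lines` vector, all
#'   >= 2).
#' @param parameter_specs list of [parameter_spec()] objects with unique names.
#' @param missingness list of `list(parameters=, n_missing=)` entries.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_lines = 14, n_per_line = 5, parameter_specs,
                        missingness = list(), seed = NULL) {
  if (n_lines < 2) stop("'n_lines' must be >= 2")
  if (length(n_per_line) == 1L) n_per_line <- rep(n_per_line, n_lines)
  if (length(n_per_line) != n_lines)
    stop("'n_per_line' must have length 1 or n_lines")
  if (any(n_per_line < 2)) stop("'n_per_line' entries must be >= 2")
  if (!is.list(parameter_specs) || length(parameter_specs) == 0 ||
      !all(vapply(parameter_specs, inherits, TRUE, "parameter_spec")))
    stop("'parameter_specs' must be a non-empty list of parameter_spec objects")
  nms <- vapply(parameter_specs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("parameter names must be unique")
  for (m in missingness) {
    if (!all(c("parameters", "n_missing") %in% names(m)))
      stop("each missingness entry needs 'parameters' and 'n_missing'")
    bad <- setdiff(m$parameters, nms)
    if (length(bad))
      stop("missingness refers to unknown parameter(s): ",
           paste(bad, collapse = ", "))
    if (m$n_missing < 0 || m$n_missing > sum(n_per_line))
      stop("'n_missing' out of range")
  }
  structure(list(n_lines = as.integer(n_lines),
                 n_per_line = as.integer(n_per_line),
                 parameter_specs = parameter_specs,
                 missingness = missingness, seed = seed),
            class = "cohort_spec")
}

apply_transform <- function(x, transform) {
  switch(transform,
         identity = x,
         logistic = stats::plogis(x),
         exp = exp(x),
         stop("unknown transform: ", transform))
}

#' Generate a synthetic cohort feature table with known ground truth
#'
#' Draws, for every parameter, per-line effects with variance `var_between`
#' and residuals with variance `var_within` on the latent Gaussian scale,
#' applies the parameter's transform, and blanks the requested missing cells
#' completely at random. The true heterogeneity ratio
#' within/(within+between) of each parameter is returned alongside the table.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `table` (data.frame: `sample_id`, `line`, one
#'   column per parameter; missing cells are `NA`) and `truth` (list with
#'   per-parameter `ratios`, the latent `line_effects` matrix and the
#'   missingness pattern).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- sum(spec$n_per_line)
    line <- factor(rep(sprintf("line%02d", seq_len(spec$n_lines)),
                       spec$n_per_line))
    tab <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                      line = line, stringsAsFactors = FALSE)
    nms <- vapply(spec$parameter_specs, `[[`, "", "name")
    effects <- matrix(NA_real_, spec$n_lines, length(nms),
                      dimnames = list(levels(line), nms))
    ratios <- numeric(length(nms))
    names(ratios) <- nms
    for (j in seq_along(spec$parameter_specs)) {
      ps <- spec$parameter_specs[[j]]
      b <- stats::rnorm(spec$n_lines, 0, sqrt(ps$var_between))
      e <- stats::rnorm(n, 0, sqrt(ps$var_within))
      latent <- ps$grand_mean + b[as.integer(line)] + e
      tab[[ps$name]] <- apply_transform(latent, ps$transform)
      effects[, j] <- b
      ratios[j] <- ps$var_within / (ps$var_within + ps$var_between)
    }
    miss <- list()
    for (m in spec$missingness) {
      rows <- sample.int(n, m$n_missing)
      for (p in m$parameters) tab[rows, p] <- NA_real_
      miss[[length(miss) + 1L]] <- list(parameters = m$parameters, rows = rows)
    }
    list(table = tab,
         truth = list(ratios = ratios, line_effects = effects,
                      missing = miss))
  })
}

# Table-1-shaped heterogeneity targets of the study this generator emulates:
# within-line variance / total variance per parameter and texture feature.
study_ratios <- function() {
  c(SUVmax = 0.41, SUVmean = 0.33, TM = 0.70,
    PET_entropy = 0.39, PET_skewness = 0.58,
    PIMO = 0.77, BrdU_LI = 0.78, pAKT = 0.34, EGFR = 0.29, MCT4 = 0.12,
    CA9 = 0.08, GLUT1 = 0.47, VD = 0.40, PF = 0.55,
    PIMO_mean = 0.77, PIMO_entropy = 0.80, PIMO_skewness = 0.82,
    BrdU_mean = 0.52, BrdU_entropy = 0.58, BrdU_skewness = 0.63,
    pAKT_mean = 0.31, pAKT_entropy = 0.36, pAKT_skewness = 0.47,
    EGFR_mean = 0.15, EGFR_entropy = 0.16, EGFR_skewness = 0.67,
    MCT4_mean = 0.23, MCT4_entropy = 0.20, MCT4_skewness = 0.48,
    CA9_mean = 0.24, CA9_entropy = 0.28, CA9_skewness = 0.71,
    GLUT1_mean = 0.92, GLUT1_entropy = 0.83, GLUT1_skewness = 0.92)
}

#' The names of the nine IHC parameters used for combined classification
#' @return character vector: seven marker staining fractions / labeling index
#'   plus vascular density (`VD`) and perfused fraction (`PF`).
#' @export
ihc_parameter_names <- function() {
  c("PIMO", "BrdU_LI", "pAKT", "EGFR", "MCT4", "CA9", "GLUT1", "VD", "PF")
}

ihc_feature_names <- function() {
  markers <- c("PIMO", "BrdU", "pAKT", "EGFR", "MCT4", "CA9", "GLUT1")
  as.vector(t(outer(markers, c("mean", "entropy", "skewness"), paste,
                    sep = "_")))
}

pet_parameter_names <- function() c("SUVmax", "SUVmean", "TM")
pet_feature_names <- function() c("PET_entropy", "PET_skewness")

#' Cohort specification emulating the xenograft study
#'
#' 14 tumor lines, 72 tumors (two lines contribute 6, the rest 5), 9 IHC
#' parameters, 21 IHC texture features, 3 PET parameters and 2 PET features.
#' Each column's within/between variance is set so its heterogeneity ratio
#' equals the study's reported within/total value (total latent variance 1).
#' Fraction-valued parameters use the logistic transform, positive-valued
#' ones the exponential, skewness features the identity. Default missingness
#' follows the observed pattern: PET columns missing for 4 tumors, MCT4 and
#' its features for 5, BrdU and its features for 3.
#'
#' @param n_per_line optional override for tumors per line.
#' @param seed integer seed.
#' @return a [cohort_spec()].
#' @export
study_cohort_spec <- function(n_per_line = NULL, seed = NULL) {
  ratios <- study_ratios()
  fraction_cols <- c("PIMO", "BrdU_LI", "pAKT", "EGFR", "MCT4", "CA9",
                     "GLUT1", "PF")
  positive_cols <- c("SUVmax", "SUVmean", "TM", "VD", "PET_entropy",
                     grep("_(mean|entropy)$", names(ratios), value = TRUE))
  # plausible latent centres: fractions ~ 0.2, SUV ~ 1, VD ~ 50/mm^2,
  # entropies ~ 3 bits, rescaled-mean intensities ~ 1300, skewness ~ 0
  centres <- c(SUVmax = log(1.2), SUVmean = log(0.9), TM = log(2),
               VD = log(50), PET_entropy = log(3))
  specs <- lapply(names(ratios), function(nm) {
    r <- ratios[[nm]]
    tr <- if (nm %in% fraction_cols) "logistic"
          else if (nm %in% positive_cols) "exp" else "identity"
    gm <- if (nm %in% fraction_cols) stats::qlogis(0.2)
          else if (grepl("_mean$", nm)) log(1300)
          else if (grepl("_entropy$", nm)) log(3)
          else if (nm %in% names(centres)) centres[[nm]] else 0
    sd_lat <- if (tr == "identity") 1 else 0.5  # total latent variance
    parameter_spec(nm, grand_mean = gm,
                   var_between = (1 - r) * sd_lat^2,
                   var_within = r * sd_lat^2, transform = tr)
  })
  if (is.null(n_per_line)) n_per_line <- c(rep(6L, 2), rep(5L, 12))
  missingness <- list(
    list(parameters = c(pet_parameter_names(), pet_feature_names()),
         n_missing = 4L),
    list(parameters = c("MCT4", "MCT4_mean", "MCT4_entropy", "MCT4_skewness"),
         n_missing = 5L),
    list(parameters = c("BrdU_LI", "BrdU_mean", "BrdU_entropy",
                        "BrdU_skewness"),
         n_missing = 3L))
  cohort_spec(n_lines = 14, n_per_line = n_per_line,
              parameter_specs = specs, missingness = missingness, seed = seed)
}
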