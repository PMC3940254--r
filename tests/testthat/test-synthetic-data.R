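test_that("cohort generation matches its specification", {
  specs <- list(parameter_spec("a", var_between = 0.7, var_within = 0.3),
                parameter_spec("b", var_between = 0, var_within = 1),
                parameter_spec("f", grand_mean = -1, var_between = 1,
                               var_within = 1, transform = "logistic"))
  co <- generate_cohort(cohort_spec(14, 5, specs, seed = 11))
  expect_equal(nrow(co$table), 70)
  expect_equal(nlevels(co$table$line), 14)
  expect_named(co$truth$ratios, c("a", "b", "f"))
  # var_between = 0 forces a true heterogeneity ratio of exactly 1
  expect_identical(co$truth$ratios[["b"]], 1.0)
  expect_true(all(co$truth$ratios >= 0 & co$truth$ratios <= 1))
  expect_true(all(co$table$f > 0 & co$table$f < 1))  # logistic range
})

test_that("cohort spec validation rejects bad inputs", {
  sp <- list(parameter_spec("a"))
  expect_error(cohort_spec(1, 5, sp), ">= 2")
  expect_error(cohort_spec(3, 1, sp), ">= 2")
  expect_error(parameter_spec("a", transform = "cubic"))
  expect_error(parameter_spec("a", var_between = 0, var_within = 0), "> 0")
  expect_error(cohort_spec(3, 5, list(parameter_spec("a"),
                                      parameter_spec("a"))), "unique")
  expect_error(
    cohort_spec(3, 5, sp, missingness = list(list(parameters = "zz",
                                                  n_missing = 1))),
    "unknown parameter")
})

test_that("generated variance structure matches a method-of-moments oracle", {
  # independent ANOVA estimator, written out by hand
  anova_ratio <- function(y, g) {
    ni <- table(g); k <- length(ni); n <- length(y)
    ybar <- tapply(y, g, mean)
    msw <- sum((y - ybar[g])^2) / (n - k)
    msb <- sum(ni * (ybar - mean(y))^2) / (k - 1)
    s2b <- max((msb - msw) / ((n - sum(ni^2) / n) / (k - 1)), 0)
    msw / (msw + s2b)
  }
  # NOTE: with 14 lines the between-line variance has 13 df, so a single
  # ratio estimate has SD ~ 0.08 whatever n_per_line is; the +/-0.05
  # tolerance is therefore asserted on the mean over replicates
  mean_est <- function(npl, reps) {
    mean(vapply(seq_len(reps), function(i) {
      co <- generate_cohort(cohort_spec(
        14, npl, list(parameter_spec("a", var_between = 0.7,
                                     var_within = 0.3)),
        seed = 1000 * npl + i))
      anova_ratio(co$table$a, co$table$line)
    }, numeric(1)))
  }
  expect_lt(abs(mean_est(5, 40) - 0.3), 0.08)
  expect_lt(abs(mean_est(50, 40) - 0.3), 0.05)
  expect_lt(abs(mean_est(500, 40) - 0.3), 0.05)
  # the within-variance component itself converges without the 13-df floor
  msw_mean <- function(npl, reps) {
    mean(vapply(seq_len(reps), function(i) {
      co <- generate_cohort(cohort_spec(
        14, npl, list(parameter_spec("a", var_between = 0.7,
                                     var_within = 0.3)),
        seed = 2000 * npl + i))
      y <- co$table$a; g <- co$table$line
      sum((y - tapply(y, g, mean)[g])^2) / (length(y) - 14)
    }, numeric(1)))
  }
  expect_lt(abs(msw_mean(5, 20) - 0.3), 0.05)     # ~4 SE at 56 df x 20
  expect_lt(abs(msw_mean(500, 20) - 0.3), 0.005)  # ~4 SE at 6986 df x 20
})

test_that("cohort missingness blanks the requested cells jointly", {
  specs <- list(parameter_spec("a"), parameter_spec("b"), parameter_spec("c"))
  co <- generate_cohort(cohort_spec(
    4, 5, specs,
    missingness = list(list(parameters = c("a", "b"), n_missing = 4)),
    seed = 5))
  expect_equal(sum(is.na(co$table$a)), 4)
  expect_identical(which(is.na(co$table$a)), which(is.na(co$table$b)))
  expect_false(anyNA(co$table$c))
})

test_that("study-shaped cohort has the study's dimensions and missingness", {
  co <- generate_cohort(study_cohort_spec(seed = 3))
  expect_equal(nrow(co$table), 72)
  expect_equal(nlevels(co$table$line), 14)
  expect_equal(ncol(co$table) - 2, 9 + 21 + 3 + 2)
  expect_equal(sum(is.na(co$table$SUVmax)), 4)
  expect_equal(sum(is.na(co$table$MCT4)), 5)
  expect_equal(sum(is.na(co$table$BrdU_LI)), 3)
})

test_that("image phantom ground truth is the realized rasterized quantity", {
  sp <- image_phantom_spec(width = 200, height = 200,
                           stain_fraction_target = 0.25, n_vessels = 8,
                           n_nuclei = 60, necrosis_fraction = 0.25, seed = 13)
  ph <- generate_marker_image(sp)
  viable <- ph$image$viable_mask
  # naive pixel counting reproduces the returned truth exactly
  expect_identical(ph$truth$stain_fraction,
                   sum(ph$truth$stain_mask & viable) / sum(viable))
  expect_equal(ph$truth$necrosis_fraction, 0.25, tolerance = 1 / (200 * 200))
  expect_equal(ph$truth$n_perfused,
               round(sp$perfused_fraction_target * sp$n_vessels))
  expect_equal(nrow(ph$nuclei), 60)
})

test_that("degenerate image phantom targets behave", {
  ph <- generate_marker_image(image_phantom_spec(
    width = 80, height = 80, stain_fraction_target = 0, noise_sd = 0,
    n_vessels = 0, n_nuclei = 0, necrosis_fraction = 0, seed = 2))
  expect_true(all(ph$image$pixels == 200))  # uniform background
  expect_identical(ph$truth$stain_fraction, 0)
  expect_error(image_phantom_spec(signal_level = 100, background_level = 200),
               "exceed")
  expect_error(generate_marker_image(image_phantom_spec(
    width = 30, height = 30, n_vessels = 0, n_nuclei = 500, seed = 1)),
    "capacity")
})

test_that("volume phantom SUV arithmetic and truth are exact", {
  # uniform concentration 0.5 MBq/mL with 10 MBq / 20 g -> SUV 1 everywhere
  vol <- uptake_volume(array(0.5, c(6, 6, 4)), injected_activity = 10,
                       body_weight = 20)
  expect_true(all(to_suv(vol) == 1.0))

  gen <- generate_uptake_volume(volume_phantom_spec(seed = 4))
  suv <- to_suv(gen$volume)
  expect_equal(max(suv), gen$truth$suvmax)
  expect_identical(suv[gen$truth$voi_mask],
                   rep(gen$truth$suvmax, sum(gen$truth$voi_mask)))
  expect_error(volume_phantom_spec(plateau_suv = 0.1, background_suv = 0.2),
               "exceed")
})

test_that("noisy volume replicates recover SUVmean within Monte-Carlo error", {
  noise_sd <- 0.1
  means <- vapply(1:20, function(s) {
    gen <- generate_uptake_volume(volume_phantom_spec(noise_sd = noise_sd,
                                                      seed = 100 + s))
    suv <- to_suv(gen$volume)
    suv_stats(suv, delineate_tumor(suv))[["SUVmean"]]
  }, numeric(1))
  nvox <- sum(generate_uptake_volume(
    volume_phantom_spec(seed = 1))$truth$voi_mask)
  se <- noise_sd / sqrt(nvox * 20)
  expect_lt(abs(mean(means) - 2.0), 2 * se + 1e-12)
})

test_that("generators are seed-deterministic", {
  a <- generate_cohort(study_cohort_spec(seed = 7))
  b <- generate_cohort(study_cohort_spec(seed = 7))
  expect_identical(a, b)
  c <- generate_cohort(study_cohort_spec(seed = 8))
  expect_false(identical(a$table, c$table))

  p1 <- generate_marker_image(image_phantom_spec(width = 100, height = 100,
                                                 noise_sd = 50, seed = 9))
  p2 <- generate_marker_image(image_phantom_spec(width = 100, height = 100,
                                                 noise_sd = 50, seed = 9))
  expect_identical(p1, p2)
  p3 <- generate_marker_image(image_phantom_spec(width = 100, height = 100,
                                                 noise_sd = 50, seed = 10))
  expect_false(identical(p1$image$pixels, p3$image$pixels))
})
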