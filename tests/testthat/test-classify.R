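test_that("median imputation fills missing cells with column medians", {
  tab <- data.frame(sample_id = as.character(1:4),
                    line = factor(c("a", "a", "b", "b")),
                    x = c(1, 2, NA, 4), y = c(1, 3, NA, NA),
                    z = c(1, 2, 3, 4))
  out <- median_impute(tab)
  expect_equal(out$x, c(1, 2, 2, 4))
  expect_equal(out$y, c(1, 3, 2, 2))
  expect_identical(out$z, tab$z)                       # untouched
  expect_identical(median_impute(out), out)            # idempotent
  tab$w <- NA_real_
  expect_error(median_impute(tab), "fully missing")
})

test_that("cv schemes partition samples at the requested fraction", {
  line <- factor(rep(sprintf("L%02d", 1:14), c(rep(6, 2), rep(5, 12))))
  expect_equal(length(line), 72)
  sch <- make_cv_scheme(line, n_repeats = 25, train_fraction = 0.75,
                        seed = 5)
  for (sp in sch$splits) {
    expect_equal(length(sp$train), 54)   # 75% of 72
    expect_equal(length(sp$test), 18)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), 1:72)
    # stratification guarantees every line in training
    expect_equal(sort(unique(as.integer(line[sp$train]))), 1:14)
  }
  # same seed -> identical scheme; distinct repeats differ
  sch2 <- make_cv_scheme(line, n_repeats = 25, train_fraction = 0.75,
                         seed = 5)
  expect_identical(sch$splits, sch2$splits)
  expect_identical(sch$scheme_id, sch2$scheme_id)
  expect_gt(length(unique(vapply(sch$splits, function(s)
    paste(s$train, collapse = ","), ""))), 20)
  # unstratified mode still partitions at the rounded fraction
  schu <- make_cv_scheme(line, n_repeats = 5, stratify = FALSE, seed = 6)
  expect_equal(lengths(lapply(schu$splits, `[[`, "train")), rep(54L, 5))
  expect_error(make_cv_scheme(line, 5, train_fraction = 1.2), "0, 1")
})

test_that("forest input validation catches contract violations", {
  tab <- make_noise_table(3, 4, p = 3)
  expect_error(fit_forest(tab, character(0), n_trees = 10), "empty column")
  expect_error(fit_forest(tab, "nope", n_trees = 10), "unknown column")
  one <- tab[tab$line == "L01", ]
  expect_error(fit_forest(one, c("q1", "q2"), n_trees = 10), ">= 2 classes")
  tab$q1[2] <- NA
  expect_error(fit_forest(tab, "q1", n_trees = 10), "missing values")
})

test_that("forest separates a strongly line-distinct cohort", {
  co <- make_separable_cohort(seed = 127)
  cols <- param_cols(co$table)
  fit <- fit_forest(co$table, cols, n_trees = 500, seed = 2)
  expect_gt(fit$oob_accuracy, 95)
  pred <- predict(fit, co$table)
  expect_gt(mean(pred == co$table$line), 0.99)  # in-bag fit is near-perfect
})

test_that("forest OOB accuracy is near chance for pure noise", {
  tab <- make_noise_table(seed = 131)
  fit <- fit_forest(tab, param_cols(tab), n_trees = 500, seed = 3)
  # 99% binomial band around 1/14 at n = 70 samples
  band <- qbinom(c(0.005, 0.995), 70, 1 / 14) / 70 * 100
  expect_gte(fit$oob_accuracy, 0)
  expect_lte(fit$oob_accuracy, band[2])
})

test_that("duplicating a column leaves accuracy essentially unchanged", {
  co <- make_separable_cohort(p = 4, var_between = 4, var_within = 1,
                              seed = 137)
  tab <- co$table
  cols <- param_cols(tab)
  accs <- vapply(1:5, function(s)
    fit_forest(tab, cols, n_trees = 500, seed = s)$oob_accuracy, numeric(1))
  tab$dup <- tab[[cols[1]]]
  accs2 <- vapply(1:5, function(s)
    fit_forest(tab, c(cols, "dup"), n_trees = 500,
               seed = 10 + s)$oob_accuracy, numeric(1))
  expect_lt(abs(mean(accs) - mean(accs2)), 5)
})

test_that("model evaluation is deterministic and scheme-consistent", {
  tab <- make_noise_table(5, 5, p = 4, seed = 139)
  sch <- make_cv_scheme(tab$line, n_repeats = 10, seed = 7)
  r1 <- evaluate_model(tab, param_cols(tab), sch, n_trees = 50, seed = 9)
  r2 <- evaluate_model(tab, param_cols(tab), sch, n_trees = 50, seed = 9)
  expect_identical(r1$cv_accuracies, r2$cv_accuracies)
  expect_length(r1$cv_accuracies, 10)
  expect_true(all(r1$cv_accuracies >= 0 & r1$cv_accuracies <= 100))
  other <- make_cv_scheme(tab$line, n_repeats = 10, seed = 8)
  r3 <- evaluate_model(tab, param_cols(tab), other, n_trees = 50, seed = 9)
  expect_error(compare_models(r1, r3), "same cross-validation scheme")
})

test_that("train-only imputation evaluates tables with missing cells", {
  co <- make_separable_cohort(5, 5, p = 4, seed = 167)
  tab <- co$table
  tab$p1[c(2, 9)] <- NA
  sch <- make_cv_scheme(tab$line, n_repeats = 5, seed = 37)
  expect_error(evaluate_model(tab, param_cols(tab), sch, n_trees = 50),
               "missing values")
  r <- evaluate_model(tab, param_cols(tab), sch, n_trees = 50, seed = 39,
                      impute = "train")
  expect_length(r$cv_accuracies, 5)
  expect_false(anyNA(r$cv_accuracies))
})

test_that("paired comparison handles identity, shift and degeneracy", {
  tab <- make_noise_table(5, 5, p = 4, seed = 149)
  sch <- make_cv_scheme(tab$line, n_repeats = 20, seed = 11)
  r <- evaluate_model(tab, param_cols(tab), sch, n_trees = 50, seed = 13)
  self <- compare_models(r, r)
  expect_identical(self$mean_difference, 0)
  expect_true(self$degenerate)
  shifted <- r
  shifted$cv_accuracies <- r$cv_accuracies + 5
  shifted$mean <- r$mean + 5
  cmp <- compare_models(shifted, r)
  expect_equal(cmp$mean_difference, 5.0)
  expect_identical(cmp$p_value, 0)      # constant shift: below any floor
  expect_true(cmp$degenerate)
  # a real difference: separable columns vs noise on shared splits
  co <- make_separable_cohort(5, 5, p = 4, seed = 151)
  tab2 <- cbind(co$table, tab[paste0("q", 1:4)])
  rs <- evaluate_model(tab2, paste0("p", 1:4), sch, n_trees = 100, seed = 17)
  rn <- evaluate_model(tab2, paste0("q", 1:4), sch, n_trees = 100, seed = 19)
  cmp2 <- compare_models(rs, rn)
  expect_gt(cmp2$mean_difference, 0)
  expect_lt(cmp2$p_value, 0.01)
  expect_true(cmp2$ci95[1] <= cmp2$mean_difference &
                cmp2$mean_difference <= cmp2$ci95[2])
})

test_that("permutation importance singles out the informative column", {
  set.seed(157)
  line <- factor(rep(1:6, each = 8))
  tab <- data.frame(sample_id = as.character(1:48), line = line)
  tab$signal <- as.integer(line) + rnorm(48, 0, 0.2)
  tab$noise1 <- rnorm(48)
  tab$noise2 <- rnorm(48)
  tab$flat <- rep(1, 48)
  imp <- parameter_importance(tab, c("signal", "noise1", "noise2", "flat"),
                              n_trees = 500, seed = 23)
  expect_equal(imp$column[which.max(imp$importance)], "signal")
  expect_lt(abs(imp$importance[imp$column == "flat"]), 1e-12)
  imp2 <- parameter_importance(tab, c("signal", "noise1", "noise2", "flat"),
                               n_trees = 500, seed = 23)
  expect_identical(imp, imp2)  # reproducible under fixed seed
})

test_that("subset sweep enumerates all combinations per size", {
  co <- make_separable_cohort(5, 4, p = 5, var_between = 4, seed = 163)
  sch <- make_cv_scheme(co$table$line, n_repeats = 5, seed = 29)
  sw <- subset_sweep(co$table, param_cols(co$table), k_range = 1:3,
                     scheme = sch, n_trees = 50, seed = 31)
  expect_equal(sw$by_k$n_models, choose(5, 1:3))
  expect_equal(nrow(sw$combinations), sum(choose(5, 1:3)))
  expect_equal(sw$tests$k, 2:3)
  expect_error(subset_sweep(co$table, param_cols(co$table), k_range = 0:2,
                            scheme = sch), "k_range")
  expect_error(subset_sweep(co$table, param_cols(co$table), k_range = 5,
                            scheme = sch), "k_range")
})
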