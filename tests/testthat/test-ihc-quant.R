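make_img <- function(px, thr, viable = NULL, necrosis = NULL)
  marker_image(px, threshold = thr, viable_mask = viable,
               necrosis_mask = necrosis)

test_that("segmentation applies threshold, viability and necrosis exclusion", {
  px <- matrix(100, 10, 10)
  expect_equal(sum(segment_marker(make_img(px, 500))$pixels), 0)

  viable <- matrix(FALSE, 10, 10); viable[3:8, 3:8] <- TRUE
  img <- make_img(matrix(500, 10, 10), 500, viable)   # >= convention
  expect_identical(segment_marker(img)$pixels, viable)

  nec <- matrix(FALSE, 10, 10); nec[3:5, 3:5] <- TRUE
  img <- make_img(matrix(500, 10, 10), 500, viable, nec)
  expect_identical(segment_marker(img)$pixels, viable & !nec)

  expect_error(make_img(px, NULL), "threshold")
  expect_error(make_img(px, 500, matrix(TRUE, 5, 5)), "dimensions")
})

test_that("staining fraction follows the area ratio definition", {
  v <- matrix(TRUE, 100, 100)
  p <- matrix(FALSE, 100, 100)
  expect_equal(staining_fraction(binary_mask(p), binary_mask(v)), 0)
  p[, 1:50] <- TRUE
  expect_equal(staining_fraction(binary_mask(p), binary_mask(v)), 0.5)
  expect_equal(staining_fraction(binary_mask(v), binary_mask(v)), 1)
  expect_error(staining_fraction(binary_mask(p),
                                 binary_mask(matrix(FALSE, 100, 100))),
               "empty")
})

test_that("noiseless phantom staining fraction is recovered exactly", {
  ph <- generate_marker_image(image_phantom_spec(
    width = 250, height = 250, stain_fraction_target = 0.30, noise_sd = 0,
    n_vessels = 0, n_nuclei = 0, seed = 17))
  viable <- binary_mask(ph$image$viable_mask, ph$image$pixel_size)
  expect_identical(staining_fraction(segment_marker(ph$image), viable),
                   ph$truth$stain_fraction)
})

test_that("staining fraction is monotone non-increasing in threshold", {
  ph <- generate_marker_image(image_phantom_spec(
    width = 150, height = 150, stain_fraction_target = 0.3, noise_sd = 300,
    n_vessels = 0, n_nuclei = 0, seed = 19))
  viable <- binary_mask(ph$image$viable_mask)
  img <- ph$image
  fr <- vapply(seq(100, 2000, by = 100), function(thr) {
    img$threshold <- thr
    staining_fraction(segment_marker(img), viable)
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("fully positive necrotic tissue does not change the fraction", {
  ph <- generate_marker_image(image_phantom_spec(
    width = 150, height = 150, stain_fraction_target = 0.2,
    necrosis_fraction = 0.2, noise_sd = 0, n_vessels = 0, n_nuclei = 0,
    seed = 23))
  img <- ph$image
  before <- staining_fraction(segment_marker(img),
                              binary_mask(img$viable_mask))
  img$pixels[img$necrosis_mask] <- 4000  # saturate the necrotic area
  after <- staining_fraction(segment_marker(img),
                             binary_mask(img$viable_mask))
  expect_identical(before, after)
})

test_that("IHC outputs are invariant under whole-image flips", {
  ph <- generate_marker_image(image_phantom_spec(
    width = 120, height = 120, stain_fraction_target = 0.25, n_vessels = 6,
    n_nuclei = 0, necrosis_fraction = 0.1, seed = 29))
  flip <- function(m) m[nrow(m):1, ]
  img <- ph$image
  img2 <- img
  img2$pixels <- flip(img$pixels)
  img2$viable_mask <- flip(img$viable_mask)
  img2$necrosis_mask <- flip(img$necrosis_mask)
  v1 <- binary_mask(img$viable_mask); v2 <- binary_mask(img2$viable_mask)
  expect_identical(staining_fraction(segment_marker(img), v1),
                   staining_fraction(segment_marker(img2), v2))
  vm2 <- binary_mask(flip(ph$vessel_mask$pixels), ph$vessel_mask$pixel_size)
  expect_identical(vascular_density(ph$vessel_mask, v1),
                   vascular_density(vm2, v2))
  pm2 <- binary_mask(flip(ph$perfusion_mask$pixels))
  expect_identical(perfused_fraction(ph$vessel_mask, ph$perfusion_mask),
                   perfused_fraction(vm2, pm2))
})

test_that("labeling index counts positive nuclei in the viable area", {
  v <- binary_mask(matrix(TRUE, 50, 50))
  nuc <- data.frame(x = rep(1:12, each = 1), y = 1:12,
                    positive = c(rep(TRUE, 3), rep(FALSE, 9)))
  expect_equal(labeling_index(nuc, v), 0.25)
  nuc$positive <- TRUE
  expect_equal(labeling_index(nuc, v), 1.0)
  # nuclei outside the viable area are excluded from both counts
  v2 <- matrix(TRUE, 50, 50); v2[, 26:50] <- FALSE
  nuc2 <- data.frame(x = c(5, 5, 40), y = c(5, 6, 5),
                     positive = c(TRUE, FALSE, TRUE))
  expect_equal(labeling_index(nuc2, binary_mask(v2)), 0.5)
  expect_error(labeling_index(nuc2[3, ], binary_mask(v2)), "no nuclei")
  expect_error(labeling_index(data.frame(x = 99, y = 1, positive = TRUE), v),
               "bounds")
})

test_that("phantom labeling index equals generator ground truth exactly", {
  ph <- generate_marker_image(image_phantom_spec(
    width = 300, height = 300, n_nuclei = 500, labeling_index_target = 0.2,
    n_vessels = 0, stain_fraction_target = 0, seed = 31))
  viable <- binary_mask(ph$image$viable_mask)
  expect_identical(labeling_index(ph$nuclei, viable),
                   ph$truth$n_nuclei_positive / 500)
})

test_that("vascular density counts 8-connected structures per mm^2", {
  # 100x100 viable at 10 um pixels = exactly 1 mm^2
  v <- binary_mask(matrix(TRUE, 100, 100), pixel_size = 10)
  vm <- matrix(FALSE, 100, 100)
  vm[cbind(seq(5, 95, by = 10), seq(5, 95, by = 10))] <- TRUE  # 10 dots
  expect_equal(vascular_density(binary_mask(vm, 10), v), 10.0)
  expect_equal(vascular_density(binary_mask(matrix(FALSE, 100, 100), 10), v),
               0.0)
  # diagonal touch is one structure under 8-connectivity
  vm2 <- matrix(FALSE, 100, 100)
  vm2[10, 10] <- TRUE; vm2[11, 11] <- TRUE
  expect_equal(vascular_density(binary_mask(vm2, 10), v), 1.0)
})

test_that("phantom vascular density matches the generated vessel count", {
  ph <- generate_marker_image(image_phantom_spec(
    width = 300, height = 300, n_vessels = 25, stain_fraction_target = 0,
    n_nuclei = 0, seed = 37))
  viable <- binary_mask(ph$image$viable_mask, ph$image$pixel_size)
  expect_equal(vascular_density(ph$vessel_mask, viable),
               25 / ph$truth$viable_area_mm2)
})

test_that("perfused fraction is the overlap fraction of structures", {
  vm <- matrix(FALSE, 40, 40)
  vm[5, 1:10] <- TRUE; vm[15, 1:10] <- TRUE
  pm <- matrix(FALSE, 40, 40)
  expect_equal(perfused_fraction(binary_mask(vm), binary_mask(pm)), 0)
  pm[5, 3] <- TRUE  # one shared pixel suffices
  expect_equal(perfused_fraction(binary_mask(vm), binary_mask(pm)), 0.5)
  pm[15, 9] <- TRUE
  expect_equal(perfused_fraction(binary_mask(vm), binary_mask(pm)), 1.0)
  expect_error(perfused_fraction(binary_mask(matrix(FALSE, 40, 40)),
                                 binary_mask(pm)), "no vascular")
})

test_that("phantom perfused fraction equals the realized target", {
  ph <- generate_marker_image(image_phantom_spec(
    width = 400, height = 400, n_vessels = 20,
    perfused_fraction_target = 0.6, stain_fraction_target = 0, n_nuclei = 0,
    seed = 41))
  expect_equal(perfused_fraction(ph$vessel_mask, ph$perfusion_mask),
               ph$truth$n_perfused / 20)
})
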