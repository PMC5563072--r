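test_that("extract_stripe samples a constant image exactly and respects geometry", {
  img <- matrix(7, 120, 120)
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  contour <- cbind(x = 60 + 25 * cos(th), y = 60 + 20 * sin(th))
  st <- extract_stripe(img, contour, width = 40)
  expect_equal(max(abs(st$pixels - 7)), 0, tolerance = 1e-9)
  expect_equal(ncol(st$pixels), 40)
  # row count ~ perimeter in pixels
  perim <- sum(sqrt(diff(c(contour[, 1], contour[1, 1]))^2 +
                      diff(c(contour[, 2], contour[1, 2]))^2))
  expect_equal(nrow(st$pixels), round(perim), tolerance = 1)
  # margin violation names the offending point
  expect_error(extract_stripe(matrix(0, 50, 50),
                              cbind(25 + 20 * cos(th), 25 + 18 * sin(th)),
                              width = 30),
               "contour point")
})

test_that("reversing the contour flips the stripe but preserves its values", {
  tr <- noiseless_truth()
  emb <- gen_midsection_image(tr, noise = FALSE)
  fwd <- extract_stripe(emb$image, emb$contour, width = 20)
  # reverse traversal, keeping the same start point
  rev <- extract_stripe(emb$image,
                        emb$contour[c(1, nrow(emb$contour):2), ],
                        width = 20)
  expect_equal(dim(fwd$pixels), dim(rev$pixels))
  # same multiset of membrane values up to interpolation differences
  expect_equal(sort(round(fwd$pixels, 6)), sort(round(rev$pixels, 6)),
               tolerance = 1e-3)
  # depth still runs outside -> inside after reversal
  expect_lt(mean(rev$pixels[, 1]), mean(rev$pixels[, 20]))
})

test_that("membrane_from_stripe takes the top-k central pixels and edge bands", {
  # 1 arclength row, depth 12: central third = columns 5..8
  row <- c(1, 1, 2, 2, 0, 5, 7, 6, 3, 9, 9, 9)
  st <- structure(list(pixels = matrix(row, nrow = 1), arclength_px = 1,
                       contour = NULL, depth_order = "outside_in",
                       width = 12),
                  class = "membrane_stripe")
  prof <- membrane_from_stripe(st, top_k = 2)
  expect_equal(prof$membrane, 6.5)                  # mean of 7, 6
  expect_equal(prof$background, 1)                  # outer sixth: cols 1-2
  expect_equal(prof$cytoplasm, 9)                   # inner sixth: cols 11-12
  expect_error(membrane_from_stripe(st, top_k = 10), "top_k")
})

test_that("noiseless synthetic embryo round-trips through extraction within 2%", {
  tr <- noiseless_truth()
  emb <- gen_midsection_image(tr, noise = FALSE)
  prof <- membrane_from_stripe(extract_stripe(emb$image, emb$contour))
  ideal <- double_boundary_model(prof$x, tr$baseline_a, tr$amplitude_b,
                                 tr$slope_m, tr$boundary_c1, tr$boundary_c2)
  away <- abs(prof$x - tr$boundary_c1) > 3 / tr$slope_m &
    abs(prof$x - tr$boundary_c2) > 3 / tr$slope_m
  expect_lt(max(abs(prof$membrane - ideal)[away] / ideal[away]), 0.02)
  expect_equal(mean(prof$background), tr$background_level, tolerance = 0.01)
  expect_equal(mean(prof$cytoplasm), tr$cytoplasm_level, tolerance = 0.01)
})

test_that("normalize_profile maps cytoplasm to 1, background to 0, and peaks to closed form", {
  n <- 100
  base <- membrane_profile(x = (0:(n - 1)) / n, membrane = rep(50, n),
                           cytoplasm = rep(50, n), background = rep(10, n))
  expect_equal(normalize_profile(base)$normalized, rep(1, n))
  bg <- membrane_profile(x = (0:(n - 1)) / n, membrane = rep(10, n),
                         cytoplasm = rep(50, n), background = rep(10, n))
  expect_equal(normalize_profile(bg)$normalized, rep(0, n))

  tr <- noiseless_truth()
  emb <- gen_midsection_image(tr, noise = FALSE)
  np <- normalize_profile(membrane_from_stripe(extract_stripe(emb$image,
                                                              emb$contour)))
  closed <- (tr$baseline_a + tr$amplitude_b - tr$background_level) /
    (tr$cytoplasm_level - tr$background_level)
  expect_equal(max(np$normalized), closed, tolerance = 0.02)
})

test_that("normalization is invariant under affine intensity transforms of the image", {
  tr <- noiseless_truth()
  emb <- gen_midsection_image(tr, noise = FALSE)
  p1 <- normalize_profile(membrane_from_stripe(extract_stripe(emb$image,
                                                              emb$contour)))
  img2 <- 3.7 * emb$image + 120
  p2 <- normalize_profile(membrane_from_stripe(extract_stripe(img2,
                                                              emb$contour)))
  expect_equal(p1$normalized, p2$normalized, tolerance = 1e-9)
})

test_that("non-positive cytoplasm-background difference is masked or fatal", {
  n <- 64
  prof <- membrane_profile(x = (0:(n - 1)) / n, membrane = rep(5, n),
                           cytoplasm = rep(1, n), background = rep(2, n))
  expect_error(normalize_profile(prof), "cannot normalize")
})

test_that("circularly permuting the contour start shifts the profile without changing values", {
  tr <- noiseless_truth()
  emb <- gen_midsection_image(tr, noise = FALSE)
  k <- 200
  perm <- emb$contour[c((k + 1):nrow(emb$contour), 1:k), ]
  p1 <- membrane_from_stripe(extract_stripe(emb$image, emb$contour))
  p2 <- membrane_from_stripe(extract_stripe(emb$image, perm))
  expect_equal(sort(round(p1$membrane, 4)), sort(round(p2$membrane, 4)),
               tolerance = 1e-2)
})

test_that("anterior cortical intensity is the line mean over the ROI mean", {
  img <- matrix(4, 60, 60)
  img[20:40, 10:20] <- 8
  line <- rbind(c(12, 25), c(18, 25))        # inside the bright block
  roi <- c(30, 45, 50, 55)                   # constant 4 region
  expect_equal(anterior_cortical_intensity(img, line, roi), 2)
  # same constant everywhere: ratio 1
  expect_equal(anterior_cortical_intensity(matrix(5, 60, 60), line, roi), 1)
  expect_error(anterior_cortical_intensity(matrix(0, 60, 60), line, roi),
               "zero mean")
})

test_that("temporal mean projection averages frames and streaks a moving spot", {
  # static stack: projection equals any frame
  frame <- matrix(runif(400), 20, 20)
  stk <- array(rep(frame, 10), dim = c(20, 20, 10))
  pr <- temporal_mean_projection(stk, window_s = 10, frame_interval = 1)
  expect_equal(pr, frame)
  # mean of projection equals mean of the windowed stack
  stk2 <- array(rnorm(20 * 20 * 12), dim = c(20, 20, 12))
  pr2 <- temporal_mean_projection(stk2, window_s = 12, frame_interval = 1)
  expect_equal(mean(pr2), mean(stk2))
  # a spot moving along x leaves an elongated streak along x
  stk3 <- array(0, dim = c(21, 40, 10))
  for (t in 1:10) stk3[11, 3 * t, t] <- 100
  pr3 <- temporal_mean_projection(stk3, window_s = 10, frame_interval = 1)
  expect_gt(sum(pr3[11, ] > 0), 8)          # spread along motion axis
  expect_equal(sum(pr3[-11, ]), 0)          # none across it
  expect_error(temporal_mean_projection(stk3, window_s = 100), "shorter")
})
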