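test_that("single-boundary fit recovers noiseless parameters and mirrors correctly", {
  x <- seq(0, 1, length.out = 256)
  y <- single_boundary_model(x, 0.5, 1, 30, 0.6)
  f <- fit_single_boundary(x, y)
  expect_true(f$converged)
  expect_lt(abs(f$a - 0.5), 1e-6)
  expect_lt(abs(f$b - 1), 1e-6)
  expect_lt(abs(f$m - 30), 1e-4)
  expect_lt(abs(f$c - 0.6), 1e-6)

  # mirrored segment: c' = 1 - c, amplitude sign flips
  fm <- fit_single_boundary(1 - x, y)
  expect_equal(fm$c, 1 - f$c, tolerance = 1e-6)
  expect_equal(fm$b, -f$b, tolerance = 1e-6)
  expect_gt(fm$m, 0)

  # flat segment: unconverged, boundary undefined
  ff <- fit_single_boundary(x, rep(0.3, 256))
  expect_false(ff$converged)
  expect_true(is.na(ff$c))
})

test_that("single fit rss never exceeds the coarse grid oracle", {
  set.seed(42)
  for (i in 1:8) {
    x <- seq(0, 1, length.out = 128)
    cc <- runif(1, 0.25, 0.75)
    mm <- runif(1, 15, 60)
    y <- single_boundary_model(x, 0.5, sample(c(-1, 1), 1), mm, cc) +
      rnorm(128, 0, 0.05)
    f <- fit_single_boundary(x, y, normalize = FALSE)
    expect_lte(f$rss, grid_oracle_single(x, y) + 1e-10)
  }
})

test_that("registration aligns pairs on the reference boundary and excludes failures", {
  n <- 200
  x <- (0:(n - 1)) / n
  mk_prof <- function(c0) {
    membrane_profile(x, single_boundary_model(x, 0.5, 1, 40, c0),
                     rep(1, n), rep(0, n))
  }
  pairs <- list(list(mk_prof(0.3), mk_prof(0.35)),
                list(mk_prof(0.6), mk_prof(0.65)),
                list(mk_prof(0.5), mk_prof(0.55)))
  fits <- lapply(pairs, function(p) fit_single_boundary(p[[1]]))
  reg <- register_profiles(fits, pairs, target = 0.5)
  expect_length(reg$pairs, 3)
  # pair already at the canonical position: zero shift
  expect_equal(reg$shifts[3], 0, tolerance = 1e-9)
  # shifts place each reference boundary at the target
  expect_equal(reg$shifts, (0.5 - c(0.3, 0.6, 0.5)) %% 1, tolerance = 1e-3)
  # after registration the reference half-max crossing sits at x = 0.5
  # (sigmoid midpoint value is a = 0.5) and the second channel keeps its
  # true +0.05 offset
  for (p in reg$pairs) {
    expect_equal(p[[1]]$membrane[x == 0.5], 0.5, tolerance = 0.02)
    expect_equal(p[[2]]$membrane[x == 0.55], 0.5, tolerance = 0.02)
  }

  # registering an already-shifted input reproduces the same aligned arrays
  shifted_pair <- list(lapply(pairs[[1]], parquant:::shift_profile,
                              delta = 0.1))
  shifted_fit <- fits[[1]]
  shifted_fit$c <- fits[[1]]$c + 0.1
  reg_s <- register_profiles(list(shifted_fit), shifted_pair, target = 0.5)
  expect_equal(reg_s$pairs[[1]][[1]]$membrane, reg$pairs[[1]][[1]]$membrane)
  expect_equal(reg_s$pairs[[1]][[2]]$membrane, reg$pairs[[1]][[2]]$membrane)

  # unconverged reference excluded with a message
  badfits <- fits
  badfits[[2]]$converged <- FALSE
  expect_message(reg2 <- register_profiles(badfits, pairs), "excluded")
  expect_equal(reg2$excluded, 2L)
  expect_length(reg2$pairs, 2)
})

test_that("boundary offset converts boundary-position differences to micrometers", {
  x <- seq(0, 1, length.out = 128)
  f1 <- fit_single_boundary(x, single_boundary_model(x, 0.5, 1, 40, 0.5))
  f2 <- fit_single_boundary(x, single_boundary_model(x, 0.5, 1, 40, 0.52))
  expect_equal(boundary_offset(f1, f1, 100), 0)
  expect_equal(boundary_offset(f1, f2, 100), 2, tolerance = 1e-4)
  f1$converged <- FALSE
  expect_error(boundary_offset(f1, f2, 100), "converged")
})

test_that("double-boundary fit recovers noiseless parameters to 1e-5", {
  tr <- noiseless_truth(baseline_a = 0.2, amplitude_b = 1.5, slope_m = 40,
                        boundary_c1 = 0.35, boundary_c2 = 0.75,
                        cytoplasm_level = 1, background_level = 0)
  prof <- gen_membrane_profile(tr, 360)
  f <- fit_double_boundary(prof)
  expect_true(f$converged)
  expect_lt(abs(f$a - 0.2), 1e-5)
  expect_lt(abs(f$b - 1.5), 1e-5)
  expect_lt(abs(f$m - 40), 1e-2)
  expect_lt(abs(f$c1 - 0.35), 1e-5)
  expect_lt(abs(f$c2 - 0.75), 1e-5)

  # flat (b = 0) profile: boundaries undefined, unconverged
  f0 <- fit_double_boundary(gen_membrane_profile(
    noiseless_truth(amplitude_b = 0, baseline_a = 1), 360))
  expect_false(f0$converged)
})

test_that("double fit handles anterior markers (negative amplitude) and wrapped domains", {
  # anterior marker: depleted inside [c1, c2]
  tr <- noiseless_truth(baseline_a = 2, amplitude_b = -1.5, slope_m = 35,
                        boundary_c1 = 0.3, boundary_c2 = 0.7,
                        cytoplasm_level = 1, background_level = 0)
  f <- fit_double_boundary(gen_membrane_profile(tr, 360))
  expect_true(f$converged)
  expect_lt(f$b, 0)
  expect_equal(f$c1, 0.3, tolerance = 1e-4)
  expect_equal(f$c2, 0.7, tolerance = 1e-4)

  # circular-shift equivariance: shifting the samples by delta shifts the
  # boundaries by delta (mod 1) without changing the domain size
  tr2 <- noiseless_truth(baseline_a = 0.2, amplitude_b = 1.5, slope_m = 40,
                         boundary_c1 = 0.35, boundary_c2 = 0.75,
                         cytoplasm_level = 1, background_level = 0)
  y <- gen_membrane_profile(tr2, 360)$membrane
  for (k in c(90, 180, 290)) {
    fs <- fit_double_boundary(rotate_vec(y, k))
    delta <- k / 360
    expect_equal(fs$c2 - fs$c1, 0.4, tolerance = 1e-4)
    expect_equal((fs$c1 - delta) %% 1, 0.35, tolerance = 1e-4)
  }
})

test_that("double fit rss never exceeds the (c1, c2) grid oracle", {
  set.seed(99)
  n <- 180
  x <- (0:(n - 1)) / n
  for (i in 1:6) {
    c1 <- runif(1, 0.15, 0.45); c2 <- runif(1, c1 + 0.2, 0.9)
    m <- runif(1, 25, 60)
    y <- double_boundary_model(x, 0.3, 1.2, m, c1, c2) + rnorm(n, 0, 0.05)
    f <- fit_double_boundary(y)
    expect_lte(f$rss, grid_oracle_double(x, y, m) + 1e-10)
  }
})

test_that("domain metrics follow the boundary positions and conserve total size", {
  f <- double_boundary_fit(a = 0, b = 1, m = 40, c1 = 0.3, c2 = 0.7)
  dm <- domain_metrics(f)
  expect_equal(dm$posterior_size, 0.4)
  expect_equal(dm$anterior_size, 0.6)
  expect_equal(dm$posterior_center, 0.5)
  # degenerate domain
  dm0 <- domain_metrics(double_boundary_fit(0, 1, 40, 0.5, 0.5))
  expect_equal(dm0$posterior_size, 0)
  expect_equal(dm0$anterior_size, 1)
  # conservation holds exactly for arbitrary fits
  set.seed(3)
  for (i in 1:20) {
    c1 <- runif(1); c2 <- runif(1, c1, min(1, c1 + 1))
    d <- domain_metrics(double_boundary_fit(0, 1, 30, c1, c2))
    expect_identical(d$posterior_size + d$anterior_size, 1)
  }
})

test_that("domain change ratio and segregation efficiency read off the metrics", {
  before <- domain_metrics(double_boundary_fit(0, 1, 40, 0.2, 0.6))
  after <- domain_metrics(double_boundary_fit(0, 1, 40, 0.3, 0.5))
  expect_equal(domain_change_ratio(before, before), 1)
  expect_equal(domain_change_ratio(before, after), 0.5)
  zero <- domain_metrics(double_boundary_fit(0, 1, 40, 0.4, 0.4))
  expect_warning(r <- domain_change_ratio(zero, after), "undefined")
  expect_true(is.na(r))

  # anterior marker: efficiency = anterior size; full-perimeter marker -> 1
  f <- double_boundary_fit(a = 2, b = -1, m = 40, c1 = 0.25, c2 = 0.75)
  expect_equal(segregation_efficiency(f), 0.5)
  expect_equal(suppressWarnings(
    segregation_efficiency(double_boundary_fit(0, 1, 40, 0.5, 0.5))), 1)
  expect_warning(segregation_efficiency(double_boundary_fit(0, 1, 40, 0.3,
                                                            0.7)),
                 "anterior")
})

test_that("segregation efficiency decreases monotonically as the anterior domain shrinks", {
  sizes <- c(0.6, 0.5, 0.4, 0.3, 0.2)
  eff <- vapply(sizes, function(s) {
    tr <- noiseless_truth(baseline_a = 2, amplitude_b = -1.5, slope_m = 40,
                          boundary_c1 = 0.5 - (1 - s) / 2,
                          boundary_c2 = 0.5 + (1 - s) / 2,
                          cytoplasm_level = 1, background_level = 0)
    segregation_efficiency(fit_double_boundary(gen_membrane_profile(tr, 240)))
  }, numeric(1))
  expect_true(all(diff(eff) < 0))
  expect_equal(eff, sizes, tolerance = 1e-3)
})

test_that("retraction intersects the domain-end line with the pole axis", {
  # worked geometry: poles (0,0)-(50,0), ends (30,-10)-(30,10) -> 20 px
  expect_equal(retraction(c(0, 0), c(50, 0), c(30, -10), c(30, 10)), 20)
  # line through the posterior pole: zero retraction
  expect_equal(retraction(c(0, 0), c(50, 0), c(50, -5), c(50, 5)), 0)
  # pixel size scales the distance
  expect_equal(retraction(c(0, 0), c(50, 0), c(30, -10), c(30, 10),
                          pixel_size = 0.2), 4)
  # parallel lines are an error; outside-axis intersections are flagged
  expect_error(retraction(c(0, 0), c(50, 0), c(10, 1), c(20, 1)),
               "parallel")
  expect_warning(r <- retraction(c(0, 0), c(50, 0), c(60, -10), c(60, 10)),
                 "outside")
  expect_equal(as.numeric(r), 10)
})

test_that("boundary position recovery stays accurate at realistic noise", {
  # 100 seeded profiles at SNR 10: median |c - c_true| <= 0.005
  errs <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    x <- seq(0, 1, length.out = 256)
    cc <- runif(1, 0.3, 0.7)
    y <- single_boundary_model(x, 0.5, 1, 35, cc) + rnorm(256, 0, 0.1)
    abs(fit_single_boundary(x, y)$c - cc)
  }, numeric(1))
  expect_lt(median(errs), 0.005)
})
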