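test_that("frequency/angle maps are exact inverses away from the boundaries", {
  th <- seq(1e-6, pi - 1e-3, length.out = 2001)
  expect_lt(max(abs(freq_to_angle(angle_to_freq(th)) - th)), 1e-12)
  # within 1e-3 of pi the spacing of doubles near x = 1 caps the achievable
  # round-trip accuracy near 1e-10
  th_hi <- seq(pi - 1e-3, pi - 1e-6, length.out = 501)
  expect_lt(max(abs(freq_to_angle(angle_to_freq(th_hi)) - th_hi)), 1e-9)
  xs <- seq(1e-9, 1 - 1e-9, length.out = 2001)
  expect_lt(max(abs(angle_to_freq(freq_to_angle(xs)) - xs)), 1e-12)
})

test_that("angular map matches its defining identities", {
  expect_equal(freq_to_angle(0.5), pi / 2)
  expect_equal(freq_to_angle(c(0, 1)), c(0, pi))
  expect_equal(freq_to_angle(0.1), acos(0.8))
  expect_equal(angle_to_freq(pi / 2), 0.5)
  expect_equal(angle_to_freq(0), 0)
  expect_equal(angle_to_freq(0.6435011), 0.1, tolerance = 1e-6)
  # Jacobian dtheta/dx = 1/sqrt(x(1-x)) by central differences
  x <- c(0.1, 0.3, 0.7)
  h <- 1e-6
  fd <- (freq_to_angle(x + h) - freq_to_angle(x - h)) / (2 * h)
  expect_equal(fd, 1 / sqrt(x * (1 - x)), tolerance = 1e-7)
  expect_error(freq_to_angle(1.2), "outside")
  expect_error(angle_to_freq(-0.1), "outside")
})

test_that("effective force matches the scaled-parameter decomposition", {
  p <- wf_params(1e4, s = 1e-3)
  expect_equal(effective_force(pi / 2, p), 5e-4)        # 2N f = Ns at sin=1
  expect_equal(effective_force(pi / 2, wf_params(1e4)), 0)  # neutral fixed point
  p2 <- wf_params(1e3, s = 0, mu1 = 2.5e-3, mu2 = 2.5e-3)   # 4Nmu = 10
  expect_equal(effective_force(pi / 4, p2), (9 / 2000) * 1)  # cot(pi/4) = 1
  expect_error(effective_force(0, p), "diverges")
  expect_error(effective_force(pi, p), "diverges")
})

test_that("effective force equals the transformed x-space drift (chain rule oracle)", {
  # f(theta) = M(x) theta'(x) + D(x) theta''(x) with theta' = 1/sqrt(x(1-x));
  # theta'' differentiated by hand in x-space (trig-free), checked against a
  # central difference, so the comparison tests the trigonometric identity.
  params_list <- list(wf_params(1e3), wf_params(1e4, 1e-3),
                      wf_params(500, -0.01, 1e-4, 3e-4),
                      wf_params(1e3, 0, 2.5e-3, 2.5e-3))
  th <- seq(0.1, pi - 0.1, length.out = 201)
  x <- angle_to_freq(th)
  thp <- 1 / sqrt(x * (1 - x))
  thpp <- -0.5 * (1 - 2 * x) * (x * (1 - x))^(-1.5)
  h <- 1e-7
  thpp_fd <- (1 / sqrt((x + h) * (1 - x - h)) -
                1 / sqrt((x - h) * (1 - x + h))) / (2 * h)
  expect_equal(thpp, thpp_fd, tolerance = 1e-5)
  for (p in params_list) {
    M <- p$s * x * (1 - x) + p$mu1 * (1 - x) - p$mu2 * x
    D <- x * (1 - x) / (2 * p$N)
    oracle <- M * thp + D * thpp
    expect_equal(effective_force(th, p), oracle, tolerance = 1e-8)
  }
})

test_that("force slope is the derivative of the regularized force", {
  params_list <- list(wf_params(1e3), wf_params(1e4, 1e-3),
                      wf_params(500, -0.01, 1e-4, 3e-4))
  th <- seq(0.01, pi - 0.01, length.out = 101)
  h <- 1e-5
  for (p in params_list) {
    fd <- (wfangular:::regularized_force(th + h, p$N, p$s, p$mu1, p$mu2) -
             wfangular:::regularized_force(th - h, p$N, p$s, p$mu1, p$mu2)) / (2 * h)
    expect_equal(force_slope(th, p), fd, tolerance = 1e-6)
  }
})

test_that("force slope reproduces the drift/mutation stability structure", {
  expect_equal(force_slope(pi / 2, wf_params(1e3)), 1 / 2000)   # unstable drift
  p10 <- wf_params(1e3, 0, 2.5e-3, 2.5e-3)                      # 4Nmu = 10
  expect_equal(force_slope(pi / 2, p10), -9 / 2000)             # stable
  pbal <- wf_params(1e3, 0, 2.5e-4, 2.5e-4)                     # 4Nmu = 1
  expect_equal(force_slope(seq(0, pi, length.out = 11), pbal),
               rep(0, 11))                                       # exact balance
  # sign of lambda(pi/2) flips as 4Nmu crosses 1
  for (fourNmu in c(0, 0.5, 0.9)) {
    mu <- fourNmu / 4e3
    expect_gt(force_slope(pi / 2, wf_params(1e3, 0, mu, mu)), 0)
  }
  for (fourNmu in c(1.1, 2, 10)) {
    mu <- fourNmu / 4e3
    expect_lt(force_slope(pi / 2, wf_params(1e3, 0, mu, mu)), 0)
  }
  # total on [0, pi]
  expect_true(all(is.finite(force_slope(c(0, pi), wf_params(1e3, 1e-3)))))
})
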