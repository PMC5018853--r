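test_that("neutral discrete Wright-Fisher is a martingale", {
  x <- wf_discrete_endpoints(wf_params(100), 0.5, t = 30, n_rep = 1e4, seed = 11)
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.5), 3 * se)
})

test_that("expected heterozygosity decays as (1 - 1/N)^t", {
  N <- 100; t <- 30
  x <- wf_discrete_endpoints(wf_params(N), 0.5, t, n_rep = 1e4, seed = 12)
  H <- x * (1 - x)
  want <- 0.25 * (1 - 1 / N)^t
  expect_lt(abs(mean(H) - want), 3 * stats::sd(H) / sqrt(length(H)))
})

test_that("fixation fraction matches Kimura's diffusion formula", {
  N <- 1e3; s <- 0.01; x0 <- 0.1
  x <- wf_discrete_endpoints(wf_params(N, s), x0, t = 3000, n_rep = 1e4, seed = 13)
  expect_true(all(x %in% c(0, 1)))  # everything absorbed by 2 tau
  pfix <- mean(x == 1)
  want <- (1 - exp(-2 * N * s * x0)) / (1 - exp(-2 * N * s))
  se <- sqrt(want * (1 - want) / length(x))
  expect_lt(abs(pfix - want), 3 * se + 0.005)  # + O(s) diffusion-limit bias
})

test_that("discrete and SDE simulators agree in distribution at short times", {
  p <- wf_params(1e3)
  xd <- wf_discrete_endpoints(p, 0.5, t = 50, n_rep = 1e4, seed = 14)
  xs <- wf_sde_endpoints(p, 0.5, t = 50, dt = 0.1, n_rep = 1e4, seed = 15)
  expect_lt(abs(mean(xd) - mean(xs)),
            3 * sqrt(stats::var(xd) / 1e4 + stats::var(xs) / 1e4))
  vr <- stats::var(xd) / stats::var(xs)
  expect_lt(abs(vr - 1), 3 * sqrt(4 / 1e4))
  ks <- suppressWarnings(stats::ks.test(xd, xs))
  expect_gt(ks$p.value, 0.001)
})

test_that("trajectories are reproducible, bounded and absorbing", {
  p <- wf_params(500, 0.005)
  t1 <- wf_discrete_trajectory(p, 0.1, 400, seed = 99)
  t2 <- wf_discrete_trajectory(p, 0.1, 400, seed = 99)
  expect_identical(t1$freqs, t2$freqs)
  expect_true(all(t1$freqs >= 0 & t1$freqs <= 1))
  hit <- which(t1$freqs %in% c(0, 1))
  if (length(hit))
    expect_true(all(t1$freqs[hit[1]:length(t1$freqs)] == t1$freqs[hit[1]]))
  s1 <- wf_sde_trajectory(p, 0.1, 100, dt = 0.1, seed = 7)
  s2 <- wf_sde_trajectory(p, 0.1, 100, dt = 0.1, seed = 7)
  expect_identical(s1$freqs, s2$freqs)
  # positive selection pushes the SDE ensemble mean upward from 0.5
  xe <- wf_sde_endpoints(wf_params(1e3, 0.01), 0.5, 100, 0.1, 2000, seed = 3)
  expect_gt(mean(xe), 0.5)
  expect_error(wf_discrete_trajectory(wf_params(100.5), 0.5, 10, 1), "integer N")
  expect_error(wf_sde_trajectory(p, 0.5, 10, dt = 0, seed = 1), "dt")
})

test_that("series sampling keeps the advertised time points", {
  p <- wf_params(1e3, 1e-3)
  tr <- wf_discrete_trajectory(p, 0.5, 1e4, seed = 5)
  sr <- sample_series(tr, 100)
  expect_length(sr$times, 101)
  expect_equal(sr$times, seq(0, 1e4, by = 100))
  expect_equal(sr$freqs, tr$freqs[tr$times %in% sr$times])
  two <- sample_series(tr, 1e4)
  expect_length(two$times, 2)
  expect_error(sample_series(tr, 2e4), "degenerate")
})

test_that("site sets have the requested composition and are reproducible", {
  ps <- wf_params(200, 5e-3); pn <- wf_params(200)
  ss <- simulate_site_set(40, 0.1, ps, pn, 0.2, T = 200, delta_t = 50, seed = 77)
  expect_equal(sum(ss$labels == "selected"), 4)
  expect_equal(sum(ss$labels == "neutral"), 36)
  ss2 <- simulate_site_set(40, 0.1, ps, pn, 0.2, T = 200, delta_t = 50, seed = 77)
  expect_identical(lapply(ss$series, `[[`, "freqs"),
                   lapply(ss2$series, `[[`, "freqs"))
  ss0 <- simulate_site_set(10, 0, ps, pn, 0.2, T = 200, delta_t = 50, seed = 1)
  expect_true(all(ss0$labels == "neutral"))
  expect_error(simulate_site_set(0, 0.1, ps, pn, 0.2, 200, 50, 1), ">= 1")
})
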