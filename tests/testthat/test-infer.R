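test_that("log-likelihood is additive over transitions", {
  p <- wf_params(1e3, 1e-3)
  s3 <- make_series(c(0, 100, 200), c(0.3, 0.35, 0.42))
  a <- make_series(c(0, 100), c(0.3, 0.35))
  b <- make_series(c(100, 200), c(0.35, 0.42))
  expect_equal(log_likelihood(s3, p),
               log_likelihood(a, p) + log_likelihood(b, p))
  # two-point series is a single log-density term
  expect_equal(log_likelihood(a, p),
               log(transition_density(0.35, 0.3, 100, p)))
  # replicating every transition doubles the log-likelihood
  s6 <- make_series(c(0, 100, 200, 300, 400),
                    c(0.3, 0.35, 0.3, 0.35, 0.3))
  rep1 <- make_series(c(0, 100, 200), c(0.3, 0.35, 0.3))
  half <- log_likelihood(rep1, p) +
    log(transition_density(0.35, 0.3, 100, p))
  expect_equal(log_likelihood(s6, p), half + log(transition_density(0.3, 0.35, 100, p)))
})

test_that("likelihood is invariant to time-origin shifts and neutral mirroring", {
  p <- wf_params(2e3)
  sr <- make_series(c(0, 50, 150), c(0.4, 0.46, 0.38))
  shifted <- make_series(c(1000, 1050, 1150), c(0.4, 0.46, 0.38))
  expect_equal(log_likelihood(sr, p), log_likelihood(shifted, p))
  mirrored <- make_series(c(0, 50, 150), 1 - c(0.4, 0.46, 0.38))
  expect_equal(log_likelihood(sr, p), log_likelihood(mirrored, p))
  pm <- wf_params(2e3, 0, 1e-5, 1e-5)
  expect_equal(log_likelihood(sr, pm), log_likelihood(mirrored, pm))
  expect_error(log_likelihood(make_series(c(0, 100), c(0.1, 0.2)),
                              p, density = "nope"))
  expect_error(wf_series(c(0, 0), c(0.1, 0.2)), "strictly increasing")
})

test_that("absorbing boundary protocol: stays are free, departures impossible", {
  p <- wf_params(1e3, 1e-3)
  fixed <- make_series(c(0, 100, 200, 300), c(0.6, 1, 1, 1))
  into <- make_series(c(0, 100), c(0.6, 1))
  expect_equal(log_likelihood(fixed, p), log_likelihood(into, p))
  departed <- make_series(c(0, 100, 200), c(0.6, 1, 0.9))
  expect_identical(log_likelihood(departed, p), -Inf)
  expect_warning(log_likelihood(make_series(c(0, 100, 200), c(1, 1, 1)), p),
                 "boundary")
  # with mutation the same data get a finite density-based likelihood
  pm <- wf_params(1e3, 1e-3, 1e-5, 1e-5)
  expect_true(is.finite(log_likelihood(departed, pm)))
})

test_that("ML fit honours degenerate bounds and nests the null", {
  sr <- sim_series(wf_params(1e3, 2e-3), 0.3, 2000, 200, seed = 21)
  b <- default_bounds(N = c(500, 500), s_mag = c(1e-3, 1e-3))
  fit <- fit_ml(sr, bounds = b)
  expect_equal(fit$N_hat, 500)
  expect_true(fit$s_hat %in% c(-1e-3, 0, 1e-3))
  fit2 <- fit_ml(sr)
  expect_gte(fit2$lrt, 0)
  expect_gte(fit2$loglik, fit2$loglik_null)
  expect_true(fit2$N_hat >= 1e2 && fit2$N_hat <= 1e6)
})

test_that("LRT statistic is symmetric for mirrored series and grows with T", {
  sr <- sim_series(wf_params(1e3), 0.5, 2000, 100, seed = 31)
  mir <- make_series(sr$times, 1 - sr$freqs)
  expect_equal(lrt_selection(sr), lrt_selection(mir), tolerance = 1e-6)
  expect_gte(lrt_selection(sr), 0)
  # replicate-average LRT increases with span under true selection
  # (Ns = 10 with a slow sweep, so T = 1e3 catches only its beginning)
  p <- wf_params(1e4, 1e-3)
  lrt_short <- lrt_long <- numeric(6)
  for (i in 1:6) {
    lrt_short[i] <- lrt_selection(sim_series(p, 0.1, 1e3, 100, seed = 100 + i))
    lrt_long[i] <- lrt_selection(sim_series(p, 0.1, 1e4, 100, seed = 100 + i))
  }
  expect_gt(mean(lrt_long), mean(lrt_short))
})

test_that("likelihood surface bookkeeping is consistent", {
  sr <- sim_series(wf_params(1e3, 2e-3), 0.3, 2000, 200, seed = 41)
  surf <- likelihood_surface(sr, N_grid = 10^seq(2, 5, length.out = 13),
                             s_grid = c(-1e-3, 0, 1e-3, 3e-3))
  expect_equal(max(surf$loglik),
               surf$loglik[surf$argmax[1], surf$argmax[2]])
  expect_equal(max(surf$loglik_rel), 0)
  shifted <- make_series(sr$times + 500, sr$freqs)
  surf2 <- likelihood_surface(shifted, N_grid = 10^seq(2, 5, length.out = 13),
                              s_grid = c(-1e-3, 0, 1e-3, 3e-3))
  expect_equal(surf$loglik, surf2$loglik)
})

test_that("ROC construction is exact on hand-made statistics", {
  ss <- structure(list(series = vector("list", 10),
                       labels = rep(c("selected", "neutral"), each = 5)),
                  class = "wf_site_set")
  perfect <- roc_curve(ss, stats = c(10:6, 5:1))
  expect_equal(perfect$auc, 1)
  worst <- roc_curve(ss, stats = c(1:5, 10:6))
  expect_equal(worst$auc, 0)
  expect_true(all(diff(perfect$points$fpr) >= 0))
  single <- structure(list(series = vector("list", 3),
                           labels = rep("neutral", 3)), class = "wf_site_set")
  expect_error(roc_curve(single, stats = 1:3), "single class")
})

test_that("shuffled labels give chance-level AUC and pROC agrees", {
  n <- 1000
  set.seed(55)
  stats <- rnorm(n)
  aucs <- vapply(1:5, function(k) {
    labels <- sample(rep(c("selected", "neutral"), c(100, 900)))
    ss <- structure(list(series = vector("list", n), labels = labels),
                    class = "wf_site_set")
    roc_curve(ss, stats = stats)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  labels <- sample(rep(c("selected", "neutral"), c(100, 900)))
  ss <- structure(list(series = vector("list", n), labels = labels),
                  class = "wf_site_set")
  roc <- roc_curve(ss, stats = stats)
  # independent cross-check of the trapezoid AUC
  ref <- pROC::auc(pROC::roc(response = labels == "selected",
                             predictor = stats, quiet = TRUE,
                             direction = "<"))
  expect_equal(roc$auc, as.numeric(ref), tolerance = 1e-10)
})

test_that("a small recovery study runs end to end with finite medians", {
  rs <- recovery_study(wf_params(1e3, 5e-3), 0.1, T = 2000, delta_t = 100,
                       n_reps = 30, seed = 1)
  expect_true(all(is.finite(rs$median_rel_err)))
  expect_true(all(is.finite(rs$iqr_rel_err)))
  expect_equal(nrow(rs$errors) + rs$n_fail, 30)
  expect_error(recovery_study(wf_params(1e3), 0.1, 1e3, 100, 10, 1), ">= 30")
})
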