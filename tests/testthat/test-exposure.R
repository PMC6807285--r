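test_that("exposure latencies are measured from the most recent token onset", {
  log <- manual_task2_log(list(
    manual_task2_epoch(1, token_t = 1000, press_t = 1400, duration = 5000),
    manual_task2_epoch(2, token_t = c(1000, 3000), press_t = 3600,
                       duration = 5000, t0 = 5000),
    manual_task2_epoch(3, token_t = 2000, press_t = 500, duration = 5000,
                       t0 = 10000)))
  el <- exposure_latencies(log)
  expect_equal(sort(el$t2), c(400, 600))  # epoch 2 relative to second token
  expect_equal(el$n_pre, 1)               # epoch 3 press before any token
  expect_equal(el$n_press, 3)
})

test_that("empirical nulls are proper distributions", {
  cfg <- task_config()
  null <- build_null_distribution(cfg, "uniform_time", n_sim = 1200, seed = 2)
  binw <- diff(null$breaks[1:2])
  expect_equal(sum(null$density) * binw, 1, tolerance = 1e-8)
  grid <- seq(0, max(null$breaks), length.out = 200)
  cdf <- null_cdf(null, grid)
  expect_true(all(diff(cdf) >= 0))
  expect_equal(cdf[length(cdf)], 1)
  expect_true(all(null$samples >= 0))
  expect_warning(build_null_distribution(cfg, "uniform_time", n_sim = 50,
                                         seed = 2), "unstable")
})

test_that("the permutation null reuses observed epochs and needs them", {
  cfg <- task_config(exposure_epochs_per_block = 60)
  logs <- lapply(1:4, function(b)
    simulate_task2_block(cfg, exposure_policy(w = 1, presses_per_epoch_mean = 5),
                         seed = 70 + b))
  el <- exposure_latencies(logs)
  null <- suppressWarnings(
    build_null_distribution(cfg, "permutation", n_sim = 3000, seed = 3,
                            exposure = el))
  expect_s3_class(null, "exposure_null")
  expect_gt(length(null$samples), 1000)
  # token-unrelated presses look like their own permutation null
  ks <- suppressWarnings(stats::ks.test(el$t2, function(q) null_cdf(null, q)))
  expect_gt(ks$p.value, 0.01)
  expect_error(build_null_distribution(cfg, "permutation", n_sim = 10,
                                       seed = 1), "observed")
})

test_that("exGauss density and distribution match independent numerics", {
  mu <- 300; sigma <- 80; lam <- 1 / 200
  # brute-force convolution oracle: Gaussian (*) exponential by quadrature
  conv <- function(x) {
    vapply(x, function(xi) {
      # finite upper limit containing both the Gaussian bump and the
      # exponential scale, where quadrature is reliable
      up <- max(xi - mu, 0) + 12 * sigma + 10 / lam
      stats::integrate(function(e) stats::dnorm(xi - e, mu, sigma) *
                         lam * exp(-lam * e),
                       0, up, rel.tol = 1e-12)$value
    }, numeric(1))
  }
  xs <- seq(-200, 2000, length.out = 100)
  expect_equal(dexgauss(xs, mu, sigma, lam), conv(xs), tolerance = 1e-8)
  expect_equal(stats::integrate(dexgauss, -Inf, Inf, mu = mu, sigma = sigma,
                                lam = lam, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-6)
  # CDF against quadrature of the density
  for (q in c(100, 400, 1200)) {
    expect_equal(pexgauss(q, mu, sigma, lam),
                 stats::integrate(dexgauss, -Inf, q, mu = mu, sigma = sigma,
                                  lam = lam, rel.tol = 1e-10)$value,
                 tolerance = 1e-7)
  }
  # sigma -> 0 limit: shifted exponential (away from the x = mu step)
  x <- c(250, 350, 500, 900)
  expect_equal(dexgauss(x, mu, 0, lam),
               ifelse(x >= mu, lam * exp(-lam * (x - mu)), 0))
  expect_equal(dexgauss(x, mu, 1e-4, lam),
               ifelse(x >= mu, lam * exp(-lam * (x - mu)), 0),
               tolerance = 1e-6)
  # stability where the naive log-density formula loses all precision
  expect_true(is.finite(dexgauss(500, 0, 1e8, 0.05, log = TRUE)))
  expect_lt(dexgauss(500, 0, 1e8, 0.05), 1e-6)
  set.seed(10)
  draws <- rexgauss(20000, mu, sigma, lam)
  expect_equal(mean(draws), mu + 1 / lam, tolerance = 10)
})

test_that("KS helpers behave on identical, null and concentrated samples", {
  cfg <- task_config()
  null <- build_null_distribution(cfg, "uniform_time", n_sim = 1200, seed = 4)
  set.seed(11)
  mk <- function(x, id = "s") structure(list(subject_id = id, t2 = x,
                                             n_pre = 0, n_press = length(x),
                                             epochs = list()),
                                        class = "exposure_latencies")
  a <- mk(sample(null$samples, 400))
  ident <- suppressWarnings(stats::ks.test(a$t2, a$t2))
  expect_equal(unname(ident$statistic), 0)
  res <- ks_exposure_tests(list(a), NULL, null)
  expect_gt(res$one_sample$a$p.value, 0.01)
  conc <- mk(rexgauss(500, 300, 50, 1 / 150), "c")
  res2 <- ks_exposure_tests(list(a, mk(sample(null$samples, 400), "s2")),
                            list(conc), null)
  expect_lt(res2$one_sample$b$p.value, 0.001)
  expect_lt(res2$two_sample_ks$p.value, 0.001)
  expect_error(ks_exposure_tests(list(mk(1:3)), NULL, null), ">= 5")
})

test_that("mixture likelihood respects nesting and flags the pure-null boundary", {
  cfg <- task_config()
  null <- suppressWarnings(
    build_null_distribution(cfg, "uniform_time", n_sim = 1000, seed = 5))
  set.seed(12)
  gen <- function(n, w, lam) {
    k <- rbinom(1, n, w)
    x <- c(sample(null$samples, k, replace = TRUE),
           rexgauss(n - k, 300, 80, lam))
    x[x >= 0 & x <= max(null$breaks)]
  }
  t2 <- list(control = gen(900, 0.4, 1 / 200), patient = gen(900, 0.4, 1 / 550))
  combined <- fit_exposure_mixture(t2, null, "combined", n_starts = 4,
                                   seed = 6)
  split_l <- fit_exposure_mixture(t2, null, "split_lambda", n_starts = 4,
                                  seed = 6)
  expect_gte(split_l$log_likelihood, combined$log_likelihood - 1e-6)
  expect_equal(split_l$n_params, 5)
  cmp <- compare_exposure_models(list(combined, split_l))
  expect_equal(attr(cmp, "best"), "split_lambda")
  expect_gt(cmp$lbf[cmp$variant == "split_lambda"], 3)
  # pure-null data: w driven to its upper bound and flagged
  pure <- list(all = sample(null$samples, 1500, replace = TRUE))
  fit0 <- fit_exposure_mixture(pure, null, "combined", n_starts = 4, seed = 7)
  expect_gt(fit0$parameters$w, 0.95)
  expect_true(any(grepl("unidentifiable", fit0$flags)) ||
                fit0$parameters$w <= 0.99)
  # reproducibility of the fit under a fixed seed
  fit0b <- fit_exposure_mixture(pure, null, "combined", n_starts = 4, seed = 7)
  expect_equal(fit0$parameters, fit0b$parameters)
  expect_error(fit_exposure_mixture(list(a = c(-1, 2)), null, "combined"),
               ">= 0")
})

test_that("LBF arithmetic follows the BIC formula", {
  fake <- function(variant, bic) structure(
    list(variant = variant, bic = bic, log_likelihood = -bic / 2,
         n_params = 4, n_obs = 100), class = "exposure_mixture_fit")
  cmp <- compare_exposure_models(list(fake("combined", 210),
                                      fake("split_lambda", 200)))
  expect_equal(cmp$lbf[cmp$variant == "split_lambda"], 5)
  expect_equal(cmp$lbf[cmp$variant == "combined"], 0)
  expect_true(attr(cmp, "decisive"))
  expect_error(compare_exposure_models(list(fake("split_w", 10))),
               "reference")
})
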