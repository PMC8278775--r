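test_that("intercept calibration matches closed forms and Monte Carlo", {
  # no markers: beta0 is just the probit of the event rate
  expect_equal(solve_beta0(0, 0, 0, 0.2), qnorm(0.2), tolerance = 1e-8)
  # no interaction: E[Phi(b0 + b'Z)] = Phi(b0 / sqrt(1 + |b|^2))
  expect_equal(solve_beta0(1, 0.8, 0, 0.05),
               qnorm(0.05) * sqrt(1 + 1 + 0.8^2), tolerance = 1e-8)
  expect_equal(solve_beta0(0.4, 0.9, 0, 0.01),
               qnorm(0.01) * sqrt(1 + 0.4^2 + 0.9^2), tolerance = 1e-8)

  # with interaction: achieved event rate checked by simulation
  spec <- true_model_spec(1, 0.8, -0.5, 0.01)
  set.seed(416)
  n <- 1e7
  x <- rnorm(n); y <- rnorm(n)
  mc <- mean(true_risk(spec, x, y))
  expect_lt(abs(mc - 0.01), 3 * sqrt(0.01 * 0.99 / n))
  expect_error(true_model_spec(1, 1, 1, 0), "pi")
})

test_that("population coefficients recover the truth when it is reachable", {
  # no interaction, both markers: the working class contains the true model
  spec <- true_model_spec(0.7, 0.5, 0, 0.1)
  w <- population_coefficients(spec, c("x", "y"))
  expect_equal(unname(w$gamma), c(spec$beta0, 0.7, 0.5), tolerance = 1e-7)
  # single informative marker
  spec1 <- true_model_spec(0.9, 0, 0, 0.05)
  w1 <- population_coefficients(spec1, "x")
  expect_equal(unname(w1$gamma), c(spec1$beta0, 0.9), tolerance = 1e-7)
  expect_identical(w$provenance, "population-limit")
})

test_that("population coefficients are the large-sample probit limit", {
  spec <- true_model_spec(1, 0.8, 0.2, 0.05)
  w <- population_coefficients(spec, c("x", "y"))
  s <- sample_true_model(spec, 2e6, seed = 417)
  fit <- fit_probit(s, c("x", "y"))
  se <- sqrt(diag(attr(fit, "vcov")))
  expect_true(all(abs(fit$gamma - w$gamma) < 3 * se))
})

test_that("conditional score CDFs satisfy exact identities and match MC", {
  spec <- true_model_spec(1, 0.8, 0.2, 0.01)
  two <- population_coefficients(spec, c("x", "y"))
  ev <- score_distribution_pair(spec, two)
  expect_equal(ev$event_rate_quadrature, 0.01, tolerance = 1e-7)

  # mixture identity: eta is a linear combination of independent normals, so
  # pi F1 + (1 - pi) F0 must equal the normal marginal CDF of eta
  pr <- ev$pair
  g <- two$gamma
  sd_eta <- sqrt(g[["gamma1"]]^2 + g[["gamma2"]]^2)
  mix <- ev$event_rate_quadrature * pr$f1_values +
    (1 - ev$event_rate_quadrature) * pr$f0_values
  expect_lt(max(abs(mix - pnorm(pr$thresholds, g[["gamma0"]], sd_eta))),
            1e-6)

  # conditional CDFs at a few thresholds against simulation
  set.seed(418)
  n <- 1e6
  x <- rnorm(n); y <- rnorm(n)
  d <- rbinom(n, 1, true_risk(spec, x, y))
  eta <- g[["gamma0"]] + g[["gamma1"]] * x + g[["gamma2"]] * y
  for (q in quantile(eta, c(0.1, 0.5, 0.9, 0.99))) {
    for (cls in 0:1) {
      sel <- d == cls
      mc <- mean(eta[sel] <= q)
      analytic <- if (cls == 1) cdf_events(pr, q) else cdf_nonevents(pr, q)
      se <- sqrt(analytic * (1 - analytic) / sum(sel))
      expect_lt(abs(analytic - mc), 3 * se + 1e-4)
    }
  }
})

test_that("the strictly proper score prefers the true model", {
  # with beta3 = 0 the two-marker working model IS the true model, so its
  # sBrS must strictly exceed the one-marker model's
  for (p in c(0.01, 0.1, 0.5)) {
    spec <- true_model_spec(0.6, 0.8, 0, p)
    sb2 <- sbrs_from_mspe(score_distribution_pair(
      spec, population_coefficients(spec, c("x", "y")))$brier)
    sb1 <- sbrs_from_mspe(score_distribution_pair(
      spec, population_coefficients(spec, "x"))$brier)
    expect_gt(sb2, sb1)
  }
})

test_that("scenario results have coherent structure and metric domains", {
  row <- scenario_incv(0.5, 0.5, -0.3, 0.1)
  expect_equal(row$d_auc, row$auc_2m - row$auc_1m)
  expect_equal(row$d_ap, row$ap_2m - row$ap_1m)
  expect_equal(row$d_sbrs, row$sbrs_2m - row$sbrs_1m)
  expect_true(row$d_auc >= -0.5 && row$d_auc <= 0.5)
  expect_true(row$d_ap >= row$pi - 1 && row$d_ap <= 1 - row$pi)
  expect_true(row$d_sbrs >= -1 && row$d_sbrs <= 1)
  expect_true(all(c(row$auc_1m, row$auc_2m) > 0.5))
})

test_that("a single-cell sweep reproduces scenario_incv and caching resumes", {
  grid <- data.frame(beta1 = 0.5, beta2 = 0.5, beta3 = -0.3, pi = 0.1)
  expect_equal(run_sweep(grid), scenario_incv(0.5, 0.5, -0.3, 0.1))

  grid3 <- default_scenario_grid(beta1 = 0.5, beta2 = c(0.4, 0.8),
                                 beta3 = -0.2, pi = c(0.05, 0.2))
  cache <- withr::local_tempfile(fileext = ".csv")
  full <- run_sweep(grid3)
  run_sweep(grid3[1:2, ], cache_file = cache)   # partial run leaves a cache
  resumed <- run_sweep(grid3, cache_file = cache)
  expect_equal(resumed, full, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("all IncVs are positive when the added marker closes the model", {
  grid <- default_scenario_grid(beta1 = c(0.3, 1.0), beta2 = c(0.3, 1.0),
                                beta3 = 0, pi = c(0.01, 0.5))
  tab <- run_sweep(grid)
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$d_auc > 0))
  expect_true(all(tab$d_ap > 0))
  expect_true(all(tab$d_sbrs > 0))
})

test_that("IncVs are stable when the quadrature resolution doubles", {
  set.seed(419)
  for (rep in 1:6) {
    b1 <- sample(seq(0.3, 1, 0.1), 1)
    b2 <- sample(seq(0.3, 1, 0.1), 1)
    b3 <- sample(setdiff(seq(-0.5, 0.5, 0.1), 0), 1)
    p <- sample(c(0.01, 0.1, 0.5), 1)
    lo <- scenario_incv(b1, b2, b3, p)
    hi <- scenario_incv(b1, b2, b3, p, n_grid = 8001L, nodes = 160L,
                        alpha_points = 40001L)
    expect_lt(abs(lo$d_auc - hi$d_auc), 5e-4)
    expect_lt(abs(lo$d_ap - hi$d_ap), 5e-4)
    expect_lt(abs(lo$d_sbrs - hi$d_sbrs), 5e-4)
  }
})

test_that("sweep summaries and agreement measures behave", {
  grid <- default_scenario_grid(beta1 = c(0.4, 0.9), beta2 = c(0.4, 0.9),
                                beta3 = c(-0.3, 0.3), pi = 0.1)
  tab <- run_sweep(grid)
  s <- summarize_sweep(tab)
  expect_equal(nrow(s), 3)          # one pi, three metrics
  expect_true(all(s$min <= s$q1 & s$q1 <= s$median & s$median <= s$q3 &
                    s$q3 <= s$max))
  expect_equal(s$n_scenarios, rep(8, 3))

  # all-positive columns are perfectly concordant
  pos <- tab
  pos$d_auc <- abs(pos$d_auc) + 0.01
  pos$d_ap <- abs(pos$d_ap) + 0.01
  cc <- correlation_and_concordance(pos, c("d_auc", "d_ap"), 0.1)
  expect_equal(cc$concordance, 1)
  # zero-variance column
  degen <- tab
  degen$d_auc <- 0.1
  expect_error(correlation_and_concordance(degen, c("d_auc", "d_ap"), 0.1),
               "zero variance")
  at <- incv_agreement_table(tab)
  expect_equal(nrow(at), 3)
  expect_true(all(at$concordance >= -1 & at$concordance <= 1))
})
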