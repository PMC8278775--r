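test_that("auc agrees with the binormal closed form", {
  same <- make_binormal_pair(binormal_spec(0, 1, 0, 1))
  expect_equal(auc(same), 0.5, tolerance = 1e-6)
  expect_equal(auc(r3_pair), pnorm(3 / sqrt(3.25)), tolerance = 1e-5)
  set.seed(404)
  for (rep in 1:8) {
    spec <- random_binormal_spec()
    expect_equal(auc(make_binormal_pair(spec)), binormal_auc(spec),
                 tolerance = 1e-5)
  }
})

test_that("ap has the right endpoints and both routes agree", {
  # useless score: AP equals the event rate; near-complete separation: AP -> 1
  same <- make_binormal_pair(binormal_spec(0, 1, 0, 1))
  sep <- make_binormal_pair(binormal_spec(60, 1, 0, 1))
  for (p in c(0.01, 0.05, 0.2, 0.5)) {
    expect_equal(ap(same, p), p, tolerance = 1e-5)
    expect_equal(ap(sep, p), 1, tolerance = 1e-6)
  }
  expect_error(ap(r1_pair, 0), "pi")
  expect_error(ap(r1_pair, 1.2), "pi")

  # quantile-grid route vs integral of PPV over TPR
  set.seed(405)
  for (rep in 1:8) {
    pair <- make_binormal_pair(random_binormal_spec())
    for (p in c(0.01, 0.05, 0.2)) {
      expect_lt(abs(ap(pair, p) - incvalue:::ap_threshold(pair, p)), 1e-4)
      expect_silent(ap(pair, p, check = TRUE))
    }
  }
})

test_that("informative scores have AP above the event rate", {
  set.seed(406)
  for (rep in 1:10) {
    spec <- random_binormal_spec()
    pair <- make_binormal_pair(spec)
    if (binormal_auc(spec) > 0.5 + 1e-3) {
      for (p in c(0.01, 0.1, 0.5)) expect_gt(ap(pair, p), p)
    }
  }
})

test_that("curve_points matches definitions and a Monte-Carlo PPV", {
  same <- make_binormal_pair(binormal_spec(0, 1, 0, 1))
  cp <- curve_points(same, 0.05, c(-30, -1, 0, 1))
  expect_equal(cp$tpr[1], 1, tolerance = 1e-12)  # c -> -inf
  expect_equal(cp$fpr[1], 1, tolerance = 1e-12)
  expect_equal(cp$ppv, rep(0.05, 4), tolerance = 1e-12)
  expect_equal(cp$npv[-1], rep(0.95, 3), tolerance = 1e-9)
  expect_true(all(diff(cp$tpr) <= 0) && all(diff(cp$fpr) <= 0))

  set.seed(407)
  n <- 1e6
  d <- rbinom(n, 1, 0.05)
  score <- ifelse(d == 1, rnorm(n, 1.8, 2), rnorm(n))
  pos <- score > 2
  mc_ppv <- mean(d[pos])
  se <- sqrt(mc_ppv * (1 - mc_ppv) / sum(pos))
  analytic <- curve_points(r1_pair, 0.05, 2)$ppv
  expect_lt(abs(analytic - mc_ppv), 3 * se)
})

test_that("delta(alpha) captures where the new model separates better", {
  a <- seq(0.01, 0.99, length.out = 99)
  expect_equal(delta_alpha(r1_pair, r1_pair, a), rep(0, 99),
               tolerance = 1e-12)
  # r1 (new) vs r2 (old): better separation at upper quantiles only
  d <- delta_alpha(r2_pair, r1_pair, a)
  expect_gt(d[which.min(abs(a - 0.95))], 0)
  expect_lt(d[which.min(abs(a - 0.05))], 0)
  # pointwise dominance gives a nonnegative curve
  expect_true(all(delta_alpha(r1_pair, r3_pair, a) >= 0))
})

test_that("the AP weight grows with alpha and reshapes with the event rate", {
  a <- seq(0.05, 0.95, length.out = 19)
  for (p in c(0.01, 0.05, 0.2)) {
    w <- ap_weight(r2_pair, r1_pair, a, p)
    expect_true(all(w > 0))
    expect_true(all(diff(w) > 0))
  }
  # rarer outcomes upweight the top and downweight the bottom
  expect_gt(ap_weight(r2_pair, r1_pair, 0.99, 0.01),
            ap_weight(r2_pair, r1_pair, 0.99, 0.2))
  expect_lt(ap_weight(r2_pair, r1_pair, 0.01, 0.01),
            ap_weight(r2_pair, r1_pair, 0.01, 0.2))

  # both models useless: S0(q_alpha) = 1 - alpha, so the weight collapses to
  # pi (1 - pi) / (1 - alpha) -- direct substitution into the definition
  useless <- make_binormal_pair(binormal_spec(0, 1, 0, 1))
  for (p in c(0.05, 0.3)) {
    expect_equal(ap_weight(useless, useless, a, p), p * (1 - p) / (1 - a),
                 tolerance = 1e-9)
  }
})

test_that("incv matches its weighted-integral identity on random pairs", {
  alpha <- incvalue:::default_alpha_grid()
  set.seed(408)
  for (rep in 1:12) {
    old <- make_binormal_pair(random_binormal_spec())
    new <- make_binormal_pair(random_binormal_spec())
    for (p in c(0.01, 0.05, 0.2, 0.5)) {
      for (metric in c("AUC", "AP")) {
        direct <- incv(old, new, p, metric)  # errors internally beyond 1e-4
        if (metric == "AUC") {
          weighted <- incvalue:::integrate_alpha(
            delta_alpha(old, new, alpha), alpha)
        } else {
          weighted <- incvalue:::integrate_alpha(
            ap_weight(old, new, alpha, p) * delta_alpha(old, new, alpha),
            alpha)
        }
        expect_lt(abs(direct - weighted), 1e-4)
      }
    }
  }
})

test_that("incv trivials and event-rate behaviour for the r1/r2 contrast", {
  expect_equal(incv(r1_pair, r1_pair, 0.1, "AUC"), 0, tolerance = 1e-12)
  expect_equal(incv(r1_pair, r1_pair, 0.1, "AP"), 0, tolerance = 1e-12)
  # Delta AUC does not involve pi at all
  vals <- vapply(c(0.2, 0.05, 0.01), function(p) incv(r2_pair, r1_pair, p,
                                                      "AUC"), 0)
  expect_equal(max(vals) - min(vals), 0)
  # Delta AP favours r1 more the rarer the outcome
  aps <- vapply(c(0.2, 0.05, 0.01), function(p) incv(r2_pair, r1_pair, p,
                                                     "AP"), 0)
  expect_true(all(aps > 0))
  expect_true(all(diff(aps) > 0))
})

test_that("Brier components and sBrS follow the decomposition", {
  perfect <- brier_components(0, 0, 0.1)
  expect_equal(perfect$sbrs, 1)
  # non-informative model p == pi
  for (p in c(0.05, 0.3)) {
    noninf <- brier_components((1 - p)^2, p^2, p)
    expect_equal(noninf$brier, p * (1 - p), tolerance = 1e-12)
    expect_equal(sbrs_from_mspe(noninf), 0, tolerance = 1e-12)
  }
  # ovarian-dose style split: MSPE 0.367 events / 0.0064 non-events at 50/875
  bc <- brier_components(0.367, 0.0064, 50 / 875)
  expect_equal(bc$brier, 0.367 * 50 / 875 + 0.0064 * 825 / 875,
               tolerance = 1e-12)
  expect_lt(abs(bc$brier - 0.027), 5e-4)
  expect_equal(bc$brier, bc$mspe1 * bc$event_rate +
                 bc$mspe0 * (1 - bc$event_rate))
})

test_that("average NPV has the right endpoints and matches Monte Carlo", {
  same <- make_binormal_pair(binormal_spec(0, 1, 0, 1))
  sep <- make_binormal_pair(binormal_spec(60, 1, 0, 1))
  for (p in c(0.05, 0.3)) {
    expect_equal(average_npv(same, p), 1 - p, tolerance = 1e-5)
    expect_equal(average_npv(sep, p), 1, tolerance = 1e-6)
  }
  # E[NPV(r0)] by simulation over non-event scores
  set.seed(409)
  n <- 1e6
  r0 <- rnorm(n)
  np <- curve_points(r1_pair, 0.05, sort(r0))$npv
  mc <- mean(np)
  se <- sd(np) / sqrt(n)
  expect_lt(abs(average_npv(r1_pair, 0.05) - mc), 3 * se)
})

test_that("net benefit follows its definition", {
  expect_equal(net_benefit(1, 0, 0.1, 0.3), 0.1)
  expect_equal(net_benefit(0.7, 0.2, 0.1, 0), 0.1 * 0.7)
  expect_equal(net_benefit(0.3, 0.3, 0.1, 0.2), 0.03 - 0.9 * 0.3 * 0.25)
  expect_error(net_benefit(0.5, 0.5, 0.1, 1), "p_t")
})
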