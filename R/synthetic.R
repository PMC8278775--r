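## Seeded generators matching the analytic machinery's assumptions, plus a
## self-contained probit MLE used as the large-sample oracle for the
## population coefficients.

# evaluate code under a temporary RNG state so generators are reproducible
# and leave the caller's stream untouched
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Sample from the true probit model
#'
#' Draws `X, Y` i.i.d. standard normal and
#' `D ~ Bernoulli(Phi(beta0 + beta1 X + beta2 Y + beta3 X Y))`. The `score`
#' column is the true-model linear predictor and the `risk` column the true
#' conditional risk `pi(X, Y)`.
#'
#' @param spec A [true_model_spec()].
#' @param n Sample size.
#' @param seed Integer seed; the same seed always yields the same sample and
#'   the caller's RNG state is left untouched.
#' @return A [risk_sample()] with columns `id, d, score, risk, x, y`.
#' @export
sample_true_model <- function(spec, n, seed) {
  stopifnot(inherits(spec, "true_model_spec"), n >= 1L)
  with_local_seed(seed, {
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    risk <- true_risk(spec, x, y)
    d <- stats::rbinom(n, 1L, risk)
    eta <- spec$beta0 + spec$beta1 * x + spec$beta2 * y + spec$beta3 * x * y
    risk_sample(d = d, score = eta, risk = risk, x = x, y = y)
  })
}

#' Sample from a binormal score model
#'
#' `D ~ Bernoulli(pi)`; scores are `N(mu1, sd1)` for events and
#' `N(mu0, sd0)` for non-events.
#'
#' @param spec A [binormal_spec()].
#' @param pi Event rate in (0, 1).
#' @param n Sample size.
#' @param seed Integer seed (see [sample_true_model()]).
#' @return A [risk_sample()] with columns `id, d, score`.
#' @export
sample_binormal <- function(spec, pi, n, seed) {
  stopifnot(inherits(spec, "binormal_spec"), n >= 1L)
  check_pi(pi)
  with_local_seed(seed, {
    d <- stats::rbinom(n, 1L, pi)
    score <- ifelse(d == 1L,
                    stats::rnorm(n, spec$mu1, spec$sd1),
                    stats::rnorm(n, spec$mu0, spec$sd0))
    risk_sample(d = d, score = score)
  })
}

#' Probit maximum-likelihood fit
#'
#' Self-contained Newton solver for the probit regression of `d` on the
#' chosen markers. Serves as the finite-sample counterpart (and, at large
#' `n`, the Monte-Carlo oracle) of [population_coefficients()]: the fitted
#' coefficients converge to the population working-model coefficients.
#'
#' @param sample A [risk_sample()] with marker columns for the requested
#'   `markers`.
#' @param markers `"x"` or `c("x", "y")`.
#' @return A `working_model_spec` with `provenance = "sample-estimate"` and a
#'   `vcov` attribute (inverse negative Hessian).
#' @export
fit_probit <- function(sample, markers = c("x", "y")) {
  sample <- check_sample(sample)
  markers <- match.arg(markers, choices = c("x", "y"), several.ok = TRUE)
  d <- sample$d
  if (all(d == d[1L]))
    stop("probit fit is undefined when all outcomes are identical",
         call. = FALSE)
  cols <- lapply(markers, function(m) {
    v <- sample[[m]]
    if (is.null(v)) stop(sprintf("sample lacks marker column '%s'", m),
                         call. = FALSE)
    v
  })
  Z <- cbind(1, do.call(cbind, cols))
  if (qr(Z)$rank < ncol(Z))
    stop("design matrix is rank deficient", call. = FALSE)
  g <- tryCatch(
    probit_population_fit(Z, t = d, w = rep(1 / nrow(Z), nrow(Z)),
                          start = numeric(ncol(Z))),
    error = function(e)
      stop(sprintf("probit fit failed (separation or non-convergence): %s",
                   conditionMessage(e)), call. = FALSE))
  nm <- c("gamma0",
          vapply(markers, function(m) if (m == "x") "gamma1" else "gamma2",
                 ""))
  names(g) <- nm
  eta <- as.vector(Z %*% g)
  lam <- probit_lambda(eta)
  info <- crossprod(Z, (stats::dnorm(eta) * lam) * Z)  # expected information
  out <- structure(list(markers = markers, gamma = g, link = "probit",
                        provenance = "sample-estimate"),
                   class = "working_model_spec")
  attr(out, "vcov") <- solve(info)
  out
}

#' Working risk and score of a fitted model on new data
#'
#' Applies a `working_model_spec` to marker columns of a sample: the linear
#' predictor `eta` (the risk score) and the probit working risk `Phi(eta)`.
#'
#' @param working A `working_model_spec`.
#' @param sample A [risk_sample()] with the needed marker columns.
#' @return A data frame with columns `score` and `risk`.
#' @export
predict_working <- function(working, sample) {
  stopifnot(inherits(working, "working_model_spec"))
  sample <- check_sample(sample)
  ld <- working_loadings(working)
  xv <- if (ld$g1 != 0) sample$x else 0
  yv <- if (ld$g2 != 0) sample$y else 0
  if ((ld$g1 != 0 && is.null(sample$x)) || (ld$g2 != 0 && is.null(sample$y)))
    stop("sample lacks the marker columns this model needs", call. = FALSE)
  eta <- ld$g0 + ld$g1 * xv + ld$g2 * yv
  data.frame(score = eta, risk = stats::pnorm(eta))
}
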