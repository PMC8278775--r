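#' Binormal risk-score specification
#'
#' Describes a risk score whose conditional distributions are normal:
#' `N(mu1, sd1)` among events (`D = 1`) and `N(mu0, sd0)` among non-events
#' (`D = 0`).
#'
#' The second parameter of each normal is the **standard deviation**, not the
#' variance. This convention matters: reading `N(1.8, 2)` as variance 2 flips
#' the sign of the AUC comparison between the canonical hypothetical scores
#' used throughout this package (events `N(1.8, sd 2)` versus `N(1.5, sd 1.5)`
#' against standard-normal non-events).
#'
#' @param mu1,sd1 Mean and standard deviation of the score among events.
#' @param mu0,sd0 Mean and standard deviation among non-events (defaults:
#'   standard normal).
#' @return An object of class `binormal_spec`.
#' @examples
#' r1 <- binormal_spec(1.8, 2)
#' binormal_auc(r1)
#' @export
binormal_spec <- function(mu1, sd1, mu0 = 0, sd0 = 1) {
  stopifnot(is.numeric(mu1), is.numeric(sd1), is.numeric(mu0), is.numeric(sd0),
            length(mu1) == 1L, length(sd1) == 1L, length(mu0) == 1L,
            length(sd0) == 1L, is.finite(mu1), is.finite(sd1), is.finite(mu0),
            is.finite(sd0))
  if (sd1 <= 0 || sd0 <= 0)
    stop("invalid binormal specification: standard deviations must be > 0",
         call. = FALSE)
  structure(list(mu1 = mu1, sd1 = sd1, mu0 = mu0, sd0 = sd0),
            class = "binormal_spec")
}

#' @export
print.binormal_spec <- function(x, ...) {
  cat(sprintf("binormal score: events N(%g, sd %g), non-events N(%g, sd %g)\n",
              x$mu1, x$sd1, x$mu0, x$sd0))
  invisible(x)
}

#' Closed-form AUC of a binormal risk score
#'
#' `Phi((mu1 - mu0) / sqrt(sd1^2 + sd0^2))`. Serves as the exact reference for
#' the quadrature-based [auc()] on the corresponding score pair.
#'
#' @param spec A [binormal_spec()].
#' @return AUC in `[0, 1]`.
#' @export
binormal_auc <- function(spec) {
  stopifnot(inherits(spec, "binormal_spec"))
  stats::pnorm((spec$mu1 - spec$mu0) / sqrt(spec$sd1^2 + spec$sd0^2))
}

#' Build a score-distribution pair
#'
#' A *score pair* holds the conditional CDFs of a risk score: `F1` among
#' events and `F0` among non-events. All rank-based quantities (AUC, AP,
#' delta(alpha), the AP weight) derive from the pair alone; the event rate
#' enters only through the measures that need it.
#'
#' `make_binormal_pair()` builds the closed-form representation from a
#' [binormal_spec()]; CDFs and quantiles are evaluated exactly via the normal
#' distribution functions.
#'
#' @param spec A [binormal_spec()].
#' @return An object of class `c("binormal_pair", "score_pair")`.
#' @seealso [grid_pair()], [empirical_pair()], [auc()], [ap()]
#' @export
make_binormal_pair <- function(spec) {
  stopifnot(inherits(spec, "binormal_spec"))
  structure(list(representation = "closed-form", spec = spec),
            class = c("binormal_pair", "score_pair"))
}

#' Grid representation of a score-distribution pair
#'
#' Tabulated CDF values on an ascending threshold grid, interpolated
#' piecewise-linearly in between. Quantiles are obtained by interpolating the
#' inverse on the strictly increasing portion of the CDF. Optional survival
#' values may be supplied when the tails are known more accurately than
#' `1 - cdf` (the population-study engine does this); otherwise `1 - f1`,
#' `1 - f0` are used.
#'
#' @param thresholds Ascending numeric thresholds `c`.
#' @param f1 Values of `F1(c)`, nondecreasing in `[0, 1]`.
#' @param f0 Values of `F0(c)`, nondecreasing in `[0, 1]`.
#' @param s1,s0 Optional survival values `1 - F1(c)`, `1 - F0(c)`.
#' @return An object of class `c("grid_pair", "score_pair")`.
#' @export
grid_pair <- function(thresholds, f1, f0, s1 = NULL, s0 = NULL) {
  stopifnot(is.numeric(thresholds), is.numeric(f1), is.numeric(f0),
            length(thresholds) == length(f1), length(f1) == length(f0),
            length(thresholds) >= 2L)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending", call. = FALSE)
  tol <- 1e-9
  for (v in list(f1, f0)) {
    if (any(v < -tol) || any(v > 1 + tol))
      stop("CDF values must lie in [0, 1]", call. = FALSE)
    if (any(diff(v) < -tol))
      stop("CDF values must be nondecreasing", call. = FALSE)
  }
  f1 <- pmin(pmax(f1, 0), 1)
  f0 <- pmin(pmax(f0, 0), 1)
  if (is.null(s1)) s1 <- 1 - f1
  if (is.null(s0)) s0 <- 1 - f0
  structure(list(representation = "grid", thresholds = thresholds,
                 f1_values = f1, f0_values = f0,
                 s1_values = pmax(s1, 0), s0_values = pmax(s0, 0)),
            class = c("grid_pair", "score_pair"))
}

#' @export
print.score_pair <- function(x, ...) {
  cat(sprintf("score-distribution pair (%s representation)\n",
              x$representation))
  if (x$representation == "closed-form") print(x$spec)
  if (x$representation == "grid")
    cat(sprintf("  %d thresholds on [%g, %g]\n", length(x$thresholds),
                min(x$thresholds), max(x$thresholds)))
  if (x$representation == "empirical")
    cat(sprintf("  %d events, %d non-events\n", length(x$events),
                length(x$nonevents)))
  invisible(x)
}

#' Convert a closed-form pair to a grid representation
#'
#' Evaluates the CDFs on `n` thresholds spanning `mu +/- width * sd` of the
#' wider component. Mainly used to validate the grid machinery against the
#' closed form.
#'
#' @param pair A closed-form `score_pair`.
#' @param n Number of grid thresholds.
#' @param width Half-width of the grid in standard deviations.
#' @return A `grid_pair`.
#' @export
as_grid_pair <- function(pair, n = 10001L, width = 8) {
  stopifnot(inherits(pair, "binormal_pair"))
  s <- pair$spec
  lo <- min(s$mu1 - width * s$sd1, s$mu0 - width * s$sd0)
  hi <- max(s$mu1 + width * s$sd1, s$mu0 + width * s$sd0)
  th <- seq(lo, hi, length.out = n)
  grid_pair(th,
            f1 = stats::pnorm(th, s$mu1, s$sd1),
            f0 = stats::pnorm(th, s$mu0, s$sd0),
            s1 = stats::pnorm(th, s$mu1, s$sd1, lower.tail = FALSE),
            s0 = stats::pnorm(th, s$mu0, s$sd0, lower.tail = FALSE))
}

## ---- CDF / quantile evaluation generics -----------------------------------

#' Evaluate the conditional CDFs and quantiles of a score pair
#'
#' `cdf_events()` returns `F1(q)`, `cdf_nonevents()` returns `F0(q)`;
#' `quantile_events()` returns `q_alpha = F1^{-1}(alpha)` and
#' `quantile_nonevents()` the analogue for `F0`. For empirical pairs the
#' quantile is the left-continuous ECDF inverse
#' `inf{c : F(c) >= alpha}`.
#'
#' @param pair A `score_pair`.
#' @param q Numeric vector of thresholds.
#' @param alpha Numeric vector of probabilities in (0, 1).
#' @return Numeric vector.
#' @name pair-evaluation
NULL

#' @rdname pair-evaluation
#' @export
cdf_events <- function(pair, q) UseMethod("cdf_events")

#' @rdname pair-evaluation
#' @export
cdf_nonevents <- function(pair, q) UseMethod("cdf_nonevents")

#' @rdname pair-evaluation
#' @export
quantile_events <- function(pair, alpha) UseMethod("quantile_events")

#' @rdname pair-evaluation
#' @export
quantile_nonevents <- function(pair, alpha) UseMethod("quantile_nonevents")

# survival functions: kept internal; tails matter for the AP integrand
surv_events <- function(pair, q) UseMethod("surv_events")
surv_nonevents <- function(pair, q) UseMethod("surv_nonevents")
# S0(q_alpha), computed without catastrophic cancellation near alpha -> 1
surv_nonevents_at_event_quantile <- function(pair, alpha)
  UseMethod("surv_nonevents_at_event_quantile")

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) ||
      any(alpha <= 0) || any(alpha >= 1))
    stop("alpha must lie strictly inside (0, 1)", call. = FALSE)
  alpha
}

## closed-form methods

#' @export
cdf_events.binormal_pair <- function(pair, q)
  stats::pnorm(q, pair$spec$mu1, pair$spec$sd1)

#' @export
cdf_nonevents.binormal_pair <- function(pair, q)
  stats::pnorm(q, pair$spec$mu0, pair$spec$sd0)

#' @export
quantile_events.binormal_pair <- function(pair, alpha)
  stats::qnorm(check_alpha(alpha), pair$spec$mu1, pair$spec$sd1)

#' @export
quantile_nonevents.binormal_pair <- function(pair, alpha)
  stats::qnorm(check_alpha(alpha), pair$spec$mu0, pair$spec$sd0)

#' @export
surv_events.binormal_pair <- function(pair, q)
  stats::pnorm(q, pair$spec$mu1, pair$spec$sd1, lower.tail = FALSE)

#' @export
surv_nonevents.binormal_pair <- function(pair, q)
  stats::pnorm(q, pair$spec$mu0, pair$spec$sd0, lower.tail = FALSE)

#' @export
surv_nonevents_at_event_quantile.binormal_pair <- function(pair, alpha) {
  q <- quantile_events(pair, alpha)
  exp(stats::pnorm(q, pair$spec$mu0, pair$spec$sd0,
                   lower.tail = FALSE, log.p = TRUE))
}

## grid methods (piecewise-linear CDF between tabulated thresholds)

interp_cdf <- function(th, vals, q, left, right) {
  stats::approx(th, vals, xout = q, rule = 2, yleft = left,
                yright = right)$y
}

#' @export
cdf_events.grid_pair <- function(pair, q)
  interp_cdf(pair$thresholds, pair$f1_values, q, 0, 1)

#' @export
cdf_nonevents.grid_pair <- function(pair, q)
  interp_cdf(pair$thresholds, pair$f0_values, q, 0, 1)

#' @export
surv_events.grid_pair <- function(pair, q)
  interp_cdf(pair$thresholds, pair$s1_values, q, 1, 0)

#' @export
surv_nonevents.grid_pair <- function(pair, q)
  interp_cdf(pair$thresholds, pair$s0_values, q, 1, 0)

# inverse of a tabulated nondecreasing CDF by interpolation on its strictly
# increasing part; flat stretches resolve to their left edge
grid_quantile <- function(th, vals, alpha) {
  keep <- c(TRUE, diff(vals) > 0)
  if (sum(keep) < 2L)
    stop("degenerate distribution: CDF has no increasing part", call. = FALSE)
  stats::approx(vals[keep], th[keep], xout = alpha, rule = 2,
                ties = "ordered")$y
}

#' @export
quantile_events.grid_pair <- function(pair, alpha)
  grid_quantile(pair$thresholds, pair$f1_values, check_alpha(alpha))

#' @export
quantile_nonevents.grid_pair <- function(pair, alpha)
  grid_quantile(pair$thresholds, pair$f0_values, check_alpha(alpha))

#' @export
surv_nonevents_at_event_quantile.grid_pair <- function(pair, alpha) {
  q <- quantile_events(pair, alpha)
  # log-linear interpolation of the survival values keeps relative accuracy
  # in the upper tail, where S0 spans many orders of magnitude
  s <- pair$s0_values
  pos <- s > 0
  if (all(pos)) {
    ls <- stats::approx(pair$thresholds, log(s), xout = q, rule = 2)$y
    exp(ls)
  } else {
    surv_nonevents(pair, q)
  }
}

## ---- derived quantity ------------------------------------------------------

#' Separation curve: F0 at the event-score quantile
#'
#' `F0(q_alpha)` is the proportion of non-events whose scores fall below the
#' `alpha`-th quantile of the event score distribution. It fully determines
#' AUC and AP and is the common currency in which two models are compared
#' (their difference is `delta(alpha)`, see [delta_alpha()]).
#'
#' @param pair A `score_pair`.
#' @param alpha Probabilities in (0, 1); may be a vector.
#' @return `F0(q_alpha)`, nondecreasing in `alpha`.
#' @export
f0_at_f1_quantile <- function(pair, alpha) {
  check_alpha(alpha)
  cdf_nonevents(pair, quantile_events(pair, alpha))
}
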