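## Analytic accuracy measures and incremental values on score pairs.
##
## AUC and AP are both integrals over alpha in (0,1) of functions of
## F0(q_alpha); the default integration device is a composite trapezoid on a
## uniform 20,001-point alpha grid over [1e-6, 1 - 1e-6], with the (bounded)
## integrand extended constantly onto the clipped end strips. Documented
## accuracy ~1e-5, set by the grid rather than by the representation for
## closed-form pairs.

default_alpha_grid <- function(n = 20001L) {
  seq(1e-6, 1 - 1e-6, length.out = n)
}

# trapezoid on a uniform alpha grid + constant extension to alpha = 0 and 1
integrate_alpha <- function(values, alpha) {
  h <- alpha[2L] - alpha[1L]
  n <- length(values)
  core <- sum(values) * h - (values[1L] + values[n]) * h / 2
  core + values[1L] * alpha[1L] + values[n] * (1 - alpha[n])
}

check_pi <- function(pi) {
  if (!is.numeric(pi) || length(pi) != 1L || !is.finite(pi) ||
      pi <= 0 || pi >= 1)
    stop("event rate pi must lie strictly inside (0, 1)", call. = FALSE)
  pi
}

#' Area under the ROC curve of a score pair
#'
#' Computed as `integral_0^1 F0(q_alpha) d alpha`: the average, over event
#' quantiles, of the proportion of non-events scoring below them. Free of the
#' event rate. Empirical pairs use the exact finite sum over event scores
#' instead of the quadrature grid.
#'
#' @param pair A `score_pair`.
#' @param alpha Integration grid (uniform, strictly inside (0, 1)); defaults
#'   to 20,001 points on `[1e-6, 1 - 1e-6]`.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pair, alpha = NULL) UseMethod("auc")

#' @export
auc.score_pair <- function(pair, alpha = NULL) {
  if (is.null(alpha)) alpha <- default_alpha_grid()
  integrate_alpha(f0_at_f1_quantile(pair, alpha), alpha)
}

#' @export
auc.empirical_pair <- function(pair, alpha = NULL) {
  # exact: the alpha-integral of a step function F0(q_alpha) collapses to the
  # mean of F0 over the observed event scores
  mean(cdf_nonevents(pair, pair$events))
}

#' Average precision (area under the precision-recall curve)
#'
#' Computed from the quantile representation
#' `AP = integral_0^1 [1 + (1/pi - 1) * S0(q_alpha) / (1 - alpha)]^{-1} d alpha`
#' where `S0 = 1 - F0`. The survival ratio is evaluated in log-survival form
#' near `alpha -> 1` so the upper tail does not suffer 0/0 cancellation.
#' `AP = E[PPV at an event's score]`, so a useless score has `AP = pi` and a
#' perfectly separating one has `AP = 1`.
#'
#' @param pair A `score_pair`.
#' @param pi Event rate in (0, 1).
#' @param alpha Integration grid, as in [auc()].
#' @param check If `TRUE`, cross-check against the threshold-space integral
#'   `integral PPV dTPR` and error if they disagree by more than `1e-4`.
#' @return AP in `(0, 1]`.
#' @export
ap <- function(pair, pi, alpha = NULL, check = FALSE) {
  check_pi(pi)
  if (is.null(alpha)) alpha <- default_alpha_grid()
  ratio <- surv_nonevents_at_event_quantile(pair, alpha) / (1 - alpha)
  value <- integrate_alpha(1 / (1 + (1 / pi - 1) * ratio), alpha)
  if (isTRUE(check)) {
    alt <- ap_threshold(pair, pi)
    if (abs(value - alt) > 1e-4)
      stop(sprintf(paste0("internal consistency failure: AP by quantile grid ",
                          "(%.6f) and by threshold integration (%.6f) ",
                          "disagree"), value, alt), call. = FALSE)
  }
  value
}

# independent route: AP = integral PPV dTPR on a threshold grid
ap_threshold <- function(pair, pi, n = 20001L) {
  check_pi(pi)
  if (inherits(pair, "binormal_pair")) {
    s <- pair$spec
    lo <- min(s$mu1 - 9 * s$sd1, s$mu0 - 9 * s$sd0)
    hi <- max(s$mu1 + 9 * s$sd1, s$mu0 + 9 * s$sd0)
    th <- seq(lo, hi, length.out = n)
  } else if (inherits(pair, "grid_pair")) {
    th <- pair$thresholds
  } else {
    th <- sort(unique(c(pair$events, pair$nonevents)))
  }
  s1 <- surv_events(pair, th)
  s0 <- surv_nonevents(pair, th)
  den <- pi * s1 + (1 - pi) * s0
  ppv <- ifelse(den > 0, pi * s1 / den, 1)
  mid <- (ppv[-1] + ppv[-length(ppv)]) / 2
  sum(mid * (-diff(s1)))
}

#' TPR, FPR, PPV, and NPV along a threshold grid
#'
#' The classification operating characteristics of a risk score at each
#' cut-off `c`: `TPR = 1 - F1(c)`, `FPR = 1 - F0(c)`,
#' `PPV = pi TPR / [pi TPR + (1 - pi) FPR]`,
#' `NPV = (1 - pi) F0 / [pi F1 + (1 - pi) F0]`. Where a ratio is 0/0 (beyond
#' the score support) the limiting value from the interior is carried over.
#'
#' @param pair A `score_pair`.
#' @param pi Event rate in (0, 1).
#' @param thresholds Ascending numeric cut-offs.
#' @return A data frame with columns `c, tpr, fpr, ppv, npv`.
#' @export
curve_points <- function(pair, pi, thresholds) {
  check_pi(pi)
  stopifnot(is.numeric(thresholds), !is.unsorted(thresholds))
  s1 <- surv_events(pair, thresholds)
  s0 <- surv_nonevents(pair, thresholds)
  f1 <- cdf_events(pair, thresholds)
  f0 <- cdf_nonevents(pair, thresholds)
  pden <- pi * s1 + (1 - pi) * s0
  ppv <- pi * s1 / pden
  nden <- pi * f1 + (1 - pi) * f0
  npv <- (1 - pi) * f0 / nden
  carry <- function(v, from_last) {
    bad <- !is.finite(v)
    if (any(bad) && !all(bad)) {
      idx <- which(!bad)
      fill <- if (from_last) v[max(idx)] else v[min(idx)]
      v[bad] <- fill
    }
    v
  }
  ppv <- carry(ppv, from_last = TRUE)   # limit from below the top threshold
  npv <- carry(npv, from_last = FALSE)  # limit from above the bottom
  data.frame(c = thresholds, tpr = s1, fpr = s0, ppv = ppv, npv = npv)
}

#' Change in separation between two score pairs
#'
#' `delta(alpha) = F_new,0(q_new,alpha) - F_old,0(q_old,alpha)`: how much the
#' new model changes the proportion of non-events below the `alpha`-th event
#' quantile. Both `Delta AUC` and `Delta AP` are weighted averages of this one
#' curve; it does not depend on the event rate.
#'
#' @param old,new `score_pair` objects for the existing and new models.
#' @param alpha Probabilities in (0, 1).
#' @return Numeric vector of `delta(alpha)` values in `[-1, 1]`.
#' @export
delta_alpha <- function(old, new, alpha) {
  f0_at_f1_quantile(new, alpha) - f0_at_f1_quantile(old, alpha)
}

#' AP weight function
#'
#' The weight `w_AP(alpha)` that makes `Delta AP` a weighted average of
#' `delta(alpha)`:
#' `w_AP = k / {[1 + (1/pi - 1) S_new,0(q_new,alpha)/(1-alpha)] *
#'             [1 + (1/pi - 1) S_old,0(q_old,alpha)/(1-alpha)]}`
#' with `k = (1/pi - 1)/(1 - alpha)`. Strictly positive, increasing in
#' `alpha` for informative models, and inflated at upper quantiles when the
#' event rate is small — the analytic reason AP rewards improvements among
#' high-risk subjects. (`w_AUC` is identically 1.)
#'
#' @param old,new `score_pair` objects.
#' @param alpha Probabilities in (0, 1).
#' @param pi Event rate in (0, 1).
#' @return Positive numeric vector.
#' @export
ap_weight <- function(old, new, alpha, pi) {
  check_alpha(alpha)
  check_pi(pi)
  k <- (1 / pi - 1) / (1 - alpha)
  rn <- surv_nonevents_at_event_quantile(new, alpha) / (1 - alpha)
  ro <- surv_nonevents_at_event_quantile(old, alpha) / (1 - alpha)
  k / ((1 + (1 / pi - 1) * rn) * (1 + (1 / pi - 1) * ro))
}

#' Delta(alpha) / weight table for two models
#'
#' Convenience table for plotting or CSV export: `delta(alpha)`, `w_AP(alpha)`
#' and their product on a grid of `alpha` values.
#'
#' @inheritParams ap_weight
#' @return Data frame with columns `alpha, delta, w_ap, w_ap_times_delta`.
#' @export
delta_curve <- function(old, new, pi, alpha = NULL) {
  if (is.null(alpha)) alpha <- seq(0.001, 0.999, length.out = 999)
  d <- delta_alpha(old, new, alpha)
  w <- ap_weight(old, new, alpha, pi)
  data.frame(alpha = alpha, delta = d, w_ap = w, w_ap_times_delta = w * d)
}

#' Incremental value of AUC or AP between two models
#'
#' Returns `Psi_new - Psi_old`. The value is computed twice: directly as the
#' difference of the two measures, and through the weighted-integral identity
#' `Delta Psi = integral w_Psi(alpha) delta(alpha) d alpha` (with `w_AUC == 1`
#' and `w_AP` from [ap_weight()]). The identity is algebraically exact, so the
#' two routes must agree; a discrepancy beyond `tol` signals a numerical
#' defect and raises an error rather than returning a silently wrong value.
#'
#' @param old,new `score_pair` objects for the existing and new models.
#' @param pi Event rate in (0, 1). `Delta AUC` does not depend on it, but it
#'   is still required so both metrics share one signature.
#' @param metric `"AUC"` or `"AP"`.
#' @param alpha Integration grid, as in [auc()].
#' @param tol Agreement tolerance between the two computation routes.
#' @return The incremental value (a single number).
#' @export
incv <- function(old, new, pi, metric = c("AUC", "AP"), alpha = NULL,
                 tol = 1e-4) {
  metric <- match.arg(metric)
  check_pi(pi)
  if (is.null(alpha)) alpha <- default_alpha_grid()
  if (metric == "AUC") {
    direct <- auc(new, alpha) - auc(old, alpha)
    weighted <- integrate_alpha(delta_alpha(old, new, alpha), alpha)
  } else {
    direct <- ap(new, pi, alpha) - ap(old, pi, alpha)
    weighted <- integrate_alpha(
      ap_weight(old, new, alpha, pi) * delta_alpha(old, new, alpha), alpha)
  }
  if (abs(direct - weighted) > tol)
    stop(sprintf(paste0("internal consistency failure for Delta %s: direct ",
                        "difference %.6f vs weighted integral %.6f"),
                 metric, direct, weighted), call. = FALSE)
  direct
}

#' Brier score components and the scaled Brier score
#'
#' The Brier score decomposes by outcome status into mean squared prediction
#' errors: `BrS = MSPE1 * pi + MSPE0 * (1 - pi)` with
#' `MSPE1 = E{[1 - p(X)]^2 | D = 1}` and `MSPE0 = E{p(X)^2 | D = 0}`. The
#' scaled Brier score rescales against the non-informative model `p == pi`
#' (whose Brier score is `pi (1 - pi)`, the maximum among calibrated-mean
#' models): `sBrS = 1 - BrS / [pi (1 - pi)]`, so 0 means no better than
#' reporting the event rate and 1 means perfect prediction. Unlike AUC and AP,
#' the Brier score is strictly proper: among all working models it is uniquely
#' minimized by the true risk.
#'
#' @param mspe1 Mean squared prediction error among events.
#' @param mspe0 Mean squared prediction error among non-events.
#' @param pi Event rate in (0, 1).
#' @return An object of class `brier_components` with fields `mspe1`, `mspe0`,
#'   `event_rate`, `brier`, `sbrs`.
#' @export
brier_components <- function(mspe1, mspe0, pi) {
  check_pi(pi)
  stopifnot(is.numeric(mspe1), is.numeric(mspe0), length(mspe1) == 1L,
            length(mspe0) == 1L, mspe1 >= 0, mspe0 >= 0)
  brier <- mspe1 * pi + mspe0 * (1 - pi)
  structure(list(mspe1 = mspe1, mspe0 = mspe0, event_rate = pi,
                 brier = brier, sbrs = 1 - brier / (pi * (1 - pi))),
            class = "brier_components")
}

#' @export
print.brier_components <- function(x, ...) {
  cat(sprintf(paste0("Brier components: MSPE events %.4g, MSPE non-events ",
                     "%.4g, pi %.4g\n  BrS = %.4g, sBrS = %.4g\n"),
              x$mspe1, x$mspe0, x$event_rate, x$brier, x$sbrs))
  invisible(x)
}

#' @rdname brier_components
#' @param components A `brier_components` object.
#' @return `sbrs_from_mspe()` returns the scaled Brier score as a number.
#' @export
sbrs_from_mspe <- function(components) {
  stopifnot(inherits(components, "brier_components"))
  components$sbrs
}

#' Average negative predictive value
#'
#' `E[NPV(r0(X))]`, the expectation of the NPV evaluated at a random
#' non-event's score — the area under the NPV-versus-specificity curve, and
#' the mirror image of AP: it weights performance in *lower*-risk regions.
#' Computed as `integral_0^1 NPV(F0^{-1}(beta)) d beta`.
#'
#' @param pair A `score_pair`.
#' @param pi Event rate in (0, 1).
#' @param alpha Integration grid over the non-event quantile axis.
#' @return Value in `[0, 1]`; equals `1 - pi` for a useless score and 1 under
#'   complete separation.
#' @export
average_npv <- function(pair, pi, alpha = NULL) {
  check_pi(pi)
  if (is.null(alpha)) alpha <- default_alpha_grid()
  q0 <- quantile_nonevents(pair, alpha)
  f1 <- cdf_events(pair, q0)
  # NPV = (1-pi) beta / [pi F1(q0_beta) + (1-pi) beta]; ratio form is stable
  # because beta is known exactly on the grid
  npv <- (1 - pi) / ((1 - pi) + pi * f1 / alpha)
  integrate_alpha(npv, alpha)
}

#' Net benefit of a treat-above-threshold rule
#'
#' `NB(p_t) = pi * TPR - (1 - pi) * FPR * p_t / (1 - p_t)` for the rule that
#' treats subjects whose predicted risk exceeds `p_t`. Takes the operating
#' point `(TPR, FPR)` directly so it serves both analytic pairs (via
#' [curve_points()]) and empirical estimates.
#'
#' @param tpr,fpr True- and false-positive rates at the chosen threshold.
#' @param pi Event rate in (0, 1).
#' @param p_t Risk threshold in `[0, 1)`.
#' @return Net benefit (can be negative).
#' @export
net_benefit <- function(tpr, fpr, pi, p_t) {
  check_pi(pi)
  stopifnot(is.numeric(tpr), is.numeric(fpr), all(tpr >= 0 & tpr <= 1),
            all(fpr >= 0 & fpr <= 1), is.numeric(p_t), all(p_t >= 0))
  if (any(p_t >= 1))
    stop("p_t must be < 1", call. = FALSE)
  pi * tpr - (1 - pi) * fpr * p_t / (1 - p_t)
}
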