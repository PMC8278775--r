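## Nonparametric estimators of AUC, AP, BrS/sBrS and empirical score pairs
## from individual-level samples.

#' Individual-level sample for the empirical estimators
#'
#' Bundles a binary outcome vector with a risk score and (optionally) a
#' predicted risk and raw markers. Stored as a data frame of class
#' `risk_sample`.
#'
#' @param d Binary outcome vector (0/1).
#' @param score Numeric risk-score vector; rank metrics depend only on its
#'   ordering.
#' @param risk Optional predicted risks in `[0, 1]` (required by
#'   [estimate_brier_sbrs()]).
#' @param x,y Optional marker vectors.
#' @param id Optional identifiers; defaults to `1:n`.
#' @return A `risk_sample` data frame with columns `id, d, score` and any of
#'   `risk, x, y` supplied.
#' @export
risk_sample <- function(d, score, risk = NULL, x = NULL, y = NULL, id = NULL) {
  n <- length(d)
  if (n < 2L) stop("a risk sample needs at least 2 records", call. = FALSE)
  if (!is.numeric(d) && !is.logical(d))
    stop("d must be numeric 0/1", call. = FALSE)
  d <- as.integer(d)
  if (any(is.na(d)) || !all(d %in% c(0L, 1L)))
    stop("d must contain only 0 and 1", call. = FALSE)
  stopifnot(is.numeric(score), length(score) == n, all(is.finite(score)))
  out <- data.frame(id = if (is.null(id)) seq_len(n) else id,
                    d = d, score = score)
  if (!is.null(risk)) {
    stopifnot(is.numeric(risk), length(risk) == n)
    if (any(!is.finite(risk)) || any(risk < 0 | risk > 1))
      stop("risk values must lie in [0, 1]", call. = FALSE)
    out$risk <- risk
  }
  if (!is.null(x)) { stopifnot(is.numeric(x), length(x) == n); out$x <- x }
  if (!is.null(y)) { stopifnot(is.numeric(y), length(y) == n); out$y <- y }
  class(out) <- c("risk_sample", "data.frame")
  out
}

as_risk_sample <- function(df) {
  risk_sample(d = df$d, score = df$score, risk = df$risk, x = df$x, y = df$y,
              id = df$id)
}

check_sample <- function(sample) {
  if (!inherits(sample, "risk_sample")) sample <- as_risk_sample(sample)
  sample
}

#' Nonparametric AUC estimator
#'
#' The Mann-Whitney double sum: the proportion of event/non-event pairs in
#' which the event has the strictly higher score. Under the default
#' `ties = "zero"` tied pairs contribute nothing, matching the indicator
#' `I(r_i > r_j)`; `ties = "midrank"` credits ties 1/2. Computed in
#' `O(n log n)` via sorted-count lookups, identical to the `O(n^2)` double
#' sum.
#'
#' @param sample A [risk_sample()] (or data frame with `d` and `score`).
#' @param ties `"zero"` (default) or `"midrank"`.
#' @return Estimated AUC.
#' @export
estimate_auc <- function(sample, ties = c("zero", "midrank")) {
  ties <- match.arg(ties)
  sample <- check_sample(sample)
  ev <- sample$score[sample$d == 1L]
  ne <- sample$score[sample$d == 0L]
  if (length(ev) == 0L || length(ne) == 0L)
    stop("AUC is undefined without at least one event and one non-event",
         call. = FALSE)
  sne <- sort(ne)
  n_pairs <- as.numeric(length(ev)) * length(ne)  # avoid integer overflow
  n_less <- findInterval(ev, sne, left.open = TRUE)   # #{non-events <  r_i}
  if (ties == "zero") {
    sum(as.numeric(n_less)) / n_pairs
  } else {
    n_leq <- findInterval(ev, sne)                    # #{non-events <= r_i}
    sum(n_less + (n_leq - n_less) / 2) / n_pairs
  }
}

#' Nonparametric AP estimator
#'
#' Averages, over events, the precision of the classifier that calls positive
#' everyone scoring at least as high as that event:
#' `AP-hat = mean_i [ #events with r_j >= r_i / #subjects with r_j >= r_i ]`.
#'
#' With the default `comparison = "geq"` each event's own record is counted in
#' both sums, so every term is well defined (denominator >= 1) even with
#' ties; this estimates `E[PPV(r)]` with `PPV(c) = Pr(D = 1 | r >= c)`.
#' `comparison = "strict"` uses `>` in both sums, in which case the
#' top-ranked event yields a 0/0 term that is dropped (the mean is taken over
#' the remaining events). Both conventions converge to the same population AP
#' for continuous scores.
#'
#' @param sample A [risk_sample()].
#' @param comparison `"geq"` (default) or `"strict"`.
#' @return Estimated AP in `(0, 1]`.
#' @export
estimate_ap <- function(sample, comparison = c("geq", "strict")) {
  comparison <- match.arg(comparison)
  sample <- check_sample(sample)
  ev <- sample$score[sample$d == 1L]
  if (length(ev) == 0L)
    stop("AP is undefined without at least one event", call. = FALSE)
  all_sorted <- sort(sample$score)
  ev_sorted <- sort(ev)
  n <- length(all_sorted)
  n1 <- length(ev_sorted)
  if (comparison == "geq") {
    num <- n1 - findInterval(ev, ev_sorted, left.open = TRUE)  # events >= r_i
    den <- n - findInterval(ev, all_sorted, left.open = TRUE)  # subjects >= r_i
    mean(num / den)
  } else {
    num <- n1 - findInterval(ev, ev_sorted)                    # events > r_i
    den <- n - findInterval(ev, all_sorted)                    # subjects > r_i
    keep <- den > 0L
    if (!any(keep))
      stop("AP (strict) is undefined: no event has a higher-scoring subject",
           call. = FALSE)
    mean(num[keep] / den[keep])
  }
}

#' Brier score and scaled Brier score from a sample
#'
#' `BrS-hat = mean((d - risk)^2)`, `pi-hat = mean(d)`,
#' `sBrS-hat = 1 - BrS-hat / [pi-hat (1 - pi-hat)]`, plus the event and
#' non-event MSPE split.
#'
#' @param sample A [risk_sample()] with a `risk` column.
#' @return A [brier_components()] object (with `pi-hat` as the event rate).
#' @export
estimate_brier_sbrs <- function(sample) {
  sample <- check_sample(sample)
  if (is.null(sample$risk))
    stop("Brier estimation needs a risk column", call. = FALSE)
  d <- sample$d
  pihat <- mean(d)
  if (pihat == 0 || pihat == 1)
    stop("sBrS is undefined when all outcomes are identical", call. = FALSE)
  mspe1 <- mean((1 - sample$risk[d == 1L])^2)
  mspe0 <- mean(sample$risk[d == 0L]^2)
  brier_components(mspe1, mspe0, pihat)
}

#' Empirical score-distribution pair
#'
#' Stepwise ECDF representation of the event and non-event score
#' distributions. Quantiles use the left-continuous ECDF inverse
#' `q_alpha = inf{c : F1(c) >= alpha}`. Feeding the result to [auc()]
#' reproduces [estimate_auc()] exactly for tie-free scores (ECDF evaluation
#' uses `<=`, so ties between an event and a non-event count fully rather
#' than zero).
#'
#' @param sample A [risk_sample()] with at least 2 events and 2 non-events.
#' @return An object of class `c("empirical_pair", "score_pair")`.
#' @export
empirical_pair <- function(sample) {
  sample <- check_sample(sample)
  ev <- sort(sample$score[sample$d == 1L])
  ne <- sort(sample$score[sample$d == 0L])
  if (length(ev) < 2L || length(ne) < 2L)
    stop("empirical pair needs at least 2 events and 2 non-events",
         call. = FALSE)
  structure(list(representation = "empirical", events = ev, nonevents = ne),
            class = c("empirical_pair", "score_pair"))
}

#' @export
cdf_events.empirical_pair <- function(pair, q)
  findInterval(q, pair$events) / length(pair$events)

#' @export
cdf_nonevents.empirical_pair <- function(pair, q)
  findInterval(q, pair$nonevents) / length(pair$nonevents)

#' @export
surv_events.empirical_pair <- function(pair, q)
  1 - cdf_events.empirical_pair(pair, q)

#' @export
surv_nonevents.empirical_pair <- function(pair, q)
  1 - cdf_nonevents.empirical_pair(pair, q)

ecdf_inverse <- function(sorted, alpha) {
  n <- length(sorted)
  sorted[pmin(pmax(ceiling(alpha * n), 1L), n)]
}

#' @export
quantile_events.empirical_pair <- function(pair, alpha)
  ecdf_inverse(pair$events, check_alpha(alpha))

#' @export
quantile_nonevents.empirical_pair <- function(pair, alpha)
  ecdf_inverse(pair$nonevents, check_alpha(alpha))

#' @export
surv_nonevents_at_event_quantile.empirical_pair <- function(pair, alpha)
  surv_nonevents(pair, quantile_events(pair, alpha))

## ---- CSV interfaces --------------------------------------------------------

#' Read / write risk samples as CSV
#'
#' The CSV dialect has a header with columns `id, d, score` and optionally
#' `risk, x, y`. `d` is parsed strictly as 0/1.
#'
#' @param path File path.
#' @return `read_sample_csv()` returns a [risk_sample()].
#' @export
read_sample_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("sample CSV '%s' does not exist", path), call. = FALSE)
  df <- utils::read.csv(path, header = TRUE)
  need <- c("id", "d", "score")
  if (!all(need %in% names(df)))
    stop(sprintf("sample CSV must contain columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  if (!is.numeric(df$d) || !all(df$d %in% c(0, 1)))
    stop("column d must contain only 0 and 1", call. = FALSE)
  risk_sample(d = df$d, score = df$score, risk = df$risk, x = df$x, y = df$y,
              id = df$id)
}

#' @rdname read_sample_csv
#' @param sample A [risk_sample()].
#' @export
write_sample_csv <- function(sample, path) {
  sample <- check_sample(sample)
  utils::write.csv(as.data.frame(sample), path, row.names = FALSE)
  invisible(path)
}
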