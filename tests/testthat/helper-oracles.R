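# Shared fixtures and independent brute-force oracles.

# the three hypothetical binormal risk scores used throughout
r1_spec <- binormal_spec(1.8, 2)
r2_spec <- binormal_spec(1.5, 1.5)
r3_spec <- binormal_spec(3, 1.5)
r1_pair <- make_binormal_pair(r1_spec)
r2_pair <- make_binormal_pair(r2_spec)
r3_pair <- make_binormal_pair(r3_spec)

random_binormal_spec <- function() {
  binormal_spec(mu1 = runif(1, 0.2, 3), sd1 = runif(1, 0.5, 2.5),
                mu0 = runif(1, -1, 1), sd0 = runif(1, 0.5, 2))
}

# O(n^2) Mann-Whitney double sum, the reference for estimate_auc
brute_auc <- function(d, score, ties = c("zero", "midrank")) {
  ties <- match.arg(ties)
  ev <- score[d == 1]
  ne <- score[d == 0]
  cmp <- outer(ev, ne, ">")
  if (ties == "midrank")
    mean(cmp + 0.5 * outer(ev, ne, "==")) else mean(cmp)
}

# direct double-loop AP under the ">=" convention
brute_ap_geq <- function(d, score) {
  ev_idx <- which(d == 1)
  mean(vapply(ev_idx, function(i) {
    sum(d == 1 & score >= score[i]) / sum(score >= score[i])
  }, 0))
}

# random small sample with a controllable amount of ties
random_tied_sample <- function(n = 40) {
  d <- c(1, 0, rbinom(n - 2, 1, 0.4))          # force both classes
  score <- sample(seq_len(max(2, n %/% 3)), n, replace = TRUE) +
    rnorm(n, sd = 0.01 * rbinom(n, 1, 0.5))    # mix of tied and untied
  list(d = d, score = score)
}
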