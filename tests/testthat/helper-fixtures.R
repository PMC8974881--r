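# Shared fixtures, built once per test run and cached. Everything is
# generated in code; EEG/EMG run at 250 Hz here to keep the suite fast
# (window definitions are in seconds, so results are rate-invariant up to
# discretisation).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

fast_cohort_config <- function(...) {
  cohort_config(fs_eeg_hz = 250, fs_emg_hz = 250, ...)
}

small_cohort <- function() {
  memo("small_cohort", simulate_cohort(
    fast_cohort_config(n_subjects = 16, seed = 101)))
}

small_features <- function() {
  memo("small_features", extract_features(small_cohort()))
}

template_250 <- function() memo("template_250", make_template(250))
template_500 <- function() memo("template_500", make_template(500))

# a perfectly separable paired cohort for forest tests: one feature with
# disjoint class supports, plus a noise feature
separable_data <- function(n_subjects = 60, seed = 7) {
  set.seed(seed)
  n <- 2 * n_subjects
  cls <- rep(c("control", "noxious"), n_subjects)
  x <- data.frame(sep = ifelse(cls == "noxious", 3, 0) + runif(n, -1, 1),
                  noise = rnorm(n))
  list(x = x,
       y = factor(cls, c("control", "noxious")),
       subjects = rep(seq_len(n_subjects), each = 2))
}

# independent split-search oracle: exhaustive loop over every (feature,
# midpoint) pair, same impurity formula and tie-breaks as the contract
oracle_best_split <- function(x, y01) {
  gini <- function(c0, c1) {
    n <- c0 + c1
    if (n == 0) return(0)
    1 - (c0 / n)^2 - (c1 / n)^2
  }
  n <- nrow(x)
  parent <- gini(sum(y01 == 0), sum(y01 == 1))
  best <- NULL
  best_dec <- 0
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    for (thr in midpoints(v)) {
      l <- v <= thr
      dec <- parent -
        (sum(l) / n) * gini(sum(y01[l] == 0), sum(y01[l] == 1)) -
        (sum(!l) / n) * gini(sum(y01[!l] == 0), sum(y01[!l] == 1))
      if (dec > best_dec) {
        best_dec <- dec
        best <- list(feature = j, threshold = thr, decrease = dec)
      }
    }
  }
  best
}

midpoints <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2) return(numeric(0))
  u[-length(u)] + diff(u) / 2
}

# independent AUC oracle: direct count over all positive-negative pairs
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}
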