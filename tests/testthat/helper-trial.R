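# Shared fixtures: simulated trials are cached per test run so the
# noise-free default trial is integrated once.

.fixture_cache <- new.env(parent = emptyenv())

noisefree_trial <- function() {
  if (is.null(.fixture_cache$trial)) {
    .fixture_cache$scenario <- default_trial(assay_cv = 0, seed = 42)
    .fixture_cache$trial <- simulate_trial(.fixture_cache$scenario)
  }
  .fixture_cache$trial
}

noisefree_run <- function() {
  if (is.null(.fixture_cache$run)) {
    .fixture_cache$run <- suppressWarnings(run_pipeline(tables = noisefree_trial()))
  }
  .fixture_cache$run
}

# first-order metabolism limit: same intrinsic clearance, Km and Vmax
# scaled far beyond any simulated concentration
linear_parameters <- function(scale = 1e5) {
  lapply(c(RM = "RM", NM = "NM", RM_PM = "RM_PM", IM = "IM"),
         default_pk_parameters, vmax_scale = scale)
}

linear_run <- function() {
  if (is.null(.fixture_cache$linear_run)) {
    sc <- default_trial(assay_cv = 0, seed = 42, parameters = linear_parameters())
    .fixture_cache$linear_run <- suppressWarnings(run_pipeline(tables = simulate_trial(sc)))
  }
  .fixture_cache$linear_run
}

# AUC of a profile's rich cell against simulator ground truth
auc_errors_vs_truth <- function(run, trial) {
  gt <- trial$ground_truth$auc
  m <- run$metrics
  m <- m[m$interval_index %in% c(1, 5, 7) & m$n_points >= 8 &
           is.finite(m$auc_last), ]
  key <- function(d) paste(d$subject_id, d$analyte, d$matrix, d$interval_index)
  m$auc_true <- gt$auc_support[match(key(m), key(gt))]
  m$rel_err <- (m$auc_last - m$auc_true) / m$auc_true
  m
}

# Riemann-sum oracle for the linear-up/log-down rule: integrate the
# piecewise interpolant (linear on rises/flats, exponential on declines)
# on a fine uniform grid per segment.
riemann_auc <- function(time, conc, n_total = 1e5) {
  stopifnot(length(time) >= 2)
  pos <- which(conc > 0)
  i_last <- pos[length(pos)]
  time <- time[seq_len(i_last)]; conc <- conc[seq_len(i_last)]
  total <- 0
  n_seg <- max(10L, ceiling(n_total / (length(time) - 1)))
  for (i in seq_len(length(time) - 1L)) {
    t1 <- time[i]; t2 <- time[i + 1]; c1 <- conc[i]; c2 <- conc[i + 1]
    tt <- seq(t1, t2, length.out = n_seg)
    if (c2 < c1 && c2 > 0 && c1 > 0) {
      k <- log(c1 / c2) / (t2 - t1)
      cc <- c1 * exp(-k * (tt - t1))
    } else {
      cc <- c1 + (c2 - c1) * (tt - t1) / (t2 - t1)
    }
    total <- total + sum((cc[-1] + cc[-n_seg]) / 2 * diff(tt))
  }
  total
}
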