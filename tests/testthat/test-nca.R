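test_that("midpoint assignment is the arithmetic interval centre", {
  expect_equal(assign_midpoints(0, 0.5), 0.25)
  expect_equal(assign_midpoints(11, 12), 11.5)
  mids <- assign_midpoints(c(0, 0.5), c(0.5, 1))
  expect_equal(mids, c(0.25, 0.75))
  expect_true(all(diff(mids) > 0))
  expect_error(assign_midpoints(1, 1), "t_end > t_start")
})

test_that("linear-up/log-down rule matches hand-computed segments", {
  expect_equal(auc_linuplogdown(c(0, 1), c(0, 10))$auc_last, 5)        # rise
  expect_equal(auc_linuplogdown(c(0, 1), c(10, 5))$auc_last, 5 / log(2))  # fall
  expect_equal(auc_linuplogdown(c(0, 1), c(10, 10))$auc_last, 10)     # tie
  # integration stops at the last positive concentration
  r <- auc_linuplogdown(c(0, 1, 2, 3), c(0, 10, 5, 0))
  expect_equal(r$auc_last, 5 + 5 / log(2))
  expect_equal(r$t_last, 2)
  # anchors are prepended
  expect_equal(auc_linuplogdown(c(1, 2), c(4, 4), anchor = c(0, 4))$auc_last, 8)
  expect_error(auc_linuplogdown(c(1, 2), c(4, 4), anchor = c(1.5, 4)), "anchor")
  # fewer than two usable points -> undefined
  expect_null(auc_linuplogdown(2, 5))
  expect_null(auc_linuplogdown(c(0, 1), c(0, 0)))
})

test_that("log-down rule is exact for mono-exponential decline", {
  set.seed(11)
  for (i in 1:50) {
    c0 <- stats::runif(1, 0.5, 50)
    k <- stats::runif(1, 0.05, 2)
    tt <- sort(c(0, stats::runif(sample(3:20, 1), 0, 24), 24))
    cc <- c0 * exp(-k * tt)
    analytic <- c0 * (1 - exp(-k * max(tt))) / k
    expect_equal(auc_linuplogdown(tt, cc)$auc_last, analytic,
                 tolerance = 1e-12)
  }
})

test_that("rule agrees with a fine Riemann sum on simulated profiles", {
  run <- noisefree_run()
  prof <- run$metrics[run$metrics$n_points >= 8 & run$metrics$matrix == "plasma", ]
  trial <- noisefree_trial()
  pl <- trial$plasma
  checked <- 0
  for (i in sample(seq_len(nrow(prof)), 6)) {
    g <- pl[pl$subject_id == prof$subject_id[i] & pl$analyte == prof$analyte[i] &
            pl$interval_index == prof$interval_index[i] & !pl$below_lloq, ]
    g <- g[order(g$time), ]
    if (nrow(g) < 3) next
    ours <- auc_linuplogdown(g$time, g$concentration)$auc_last
    expect_equal(ours, riemann_auc(g$time, g$concentration), tolerance = 1e-6)
    checked <- checked + 1
  }
  expect_gt(checked, 0)
  # and on random sawtooth profiles
  set.seed(3)
  for (i in 1:10) {
    tt <- sort(stats::runif(12, 0, 12))
    cc <- stats::runif(12, 0.1, 20)
    expect_equal(auc_linuplogdown(tt, cc)$auc_last, riemann_auc(tt, cc),
                 tolerance = 1e-6)
  }
})

test_that("segment split additivity and log<=linear inequalities hold", {
  set.seed(5)
  for (i in 1:1000) {
    t1 <- stats::runif(1, 0, 10); t2 <- t1 + stats::runif(1, 0.1, 5)
    c1 <- stats::runif(1, 0.1, 30); c2 <- stats::runif(1, 0.1, 30)
    whole <- auc_linuplogdown(c(t1, t2), c(c1, c2))$auc_last
    if (c2 < c1) {
      # log-mean trapezoid never exceeds the arithmetic trapezoid
      lin <- (c1 + c2) / 2 * (t2 - t1)
      expect_lt(whole, lin)
      # splitting at a point on the exponential through the endpoints
      # leaves the total unchanged
      tm <- stats::runif(1, t1, t2)
      k <- log(c1 / c2) / (t2 - t1)
      cm <- c1 * exp(-k * (tm - t1))
      split <- auc_linuplogdown(c(t1, tm, t2), c(c1, cm, c2))$auc_last
      expect_equal(split, whole, tolerance = 1e-12)
    } else {
      # linear branch: additivity is exact for any interior point on the chord
      tm <- stats::runif(1, t1, t2)
      cm <- c1 + (c2 - c1) * (tm - t1) / (t2 - t1)
      split <- auc_linuplogdown(c(t1, tm, t2), c(c1, cm, c2))$auc_last
      expect_equal(split, whole, tolerance = 1e-12)
    }
  }
})

test_that("appending a positive point never decreases the AUC", {
  set.seed(9)
  tt <- sort(stats::runif(8, 0, 10)); cc <- stats::runif(8, 0.5, 10)
  base <- auc_linuplogdown(tt, cc)$auc_last
  for (i in 1:20) {
    ext <- auc_linuplogdown(c(tt, 10 + i), c(cc, stats::runif(1, 1e-3, 10)))$auc_last
    expect_gte(ext, base)
  }
})

test_that("cmax ties break to the earliest time", {
  r <- cmax_tmax(c(0, 1, 2, 3), c(0, 8, 8, 4))
  expect_equal(r$c_max, 8); expect_equal(r$t_max, 1)
  r1 <- cmax_tmax(2, 5)
  expect_equal(r1$c_max, 5); expect_equal(r1$t_max, 2)
  expect_error(cmax_tmax(numeric(0), numeric(0)), "empty")
})

test_that("trough extraction honours the matching tolerance", {
  expect_equal(cmin_12h(c(0, 6, 12), c(5, 4, 3.1)), 3.1)
  expect_equal(cmin_12h(c(0.25, 11.5), c(2, 1.9)), 1.9)   # ISF midpoint grid
  expect_null(cmin_12h(c(0, 4, 8), c(5, 4, 3)))           # truncated profile
  expect_null(cmin_12h(c(0, 11.3), c(5, 4), tolerance = 0.5))
})

test_that("window classification uses the permissive upper band reading", {
  expect_equal(classify_window(2.22)$class, "below")
  expect_equal(classify_window(2.86)$class, "within")   # inclusive boundary
  w12 <- classify_window(12.0)
  expect_equal(w12$class, "within")
  expect_false(w12$borderline_high)
  w15 <- classify_window(15)
  expect_equal(w15$class, "within")
  expect_true(w15$borderline_high)
  expect_equal(classify_window(18)$class, "above")
  expect_error(classify_window(-1), "invalid")
})

test_that("profile NCA applies the ISF anchoring policy", {
  mids <- assign_midpoints(c(0, 0.5, 1), c(0.5, 1, 1.5))
  p1 <- conc_profile("S", "VRC", "isf", 1, mids, c(1, 2, 3))
  m1 <- nca_profile(p1, warn = FALSE)
  expect_equal(m1$anchor_policy, "zero")
  expect_equal(m1$auc_last,
               auc_linuplogdown(mids, c(1, 2, 3), anchor = c(0, 0))$auc_last)

  p5 <- conc_profile("S", "VRC", "isf", 5, mids, c(3, 2.5, 2))
  m5 <- nca_profile(p5, isf_anchor = "carry_back", warn = FALSE)
  expect_equal(m5$anchor_policy, "carry_back")
  expect_equal(m5$auc_last,
               auc_linuplogdown(mids, c(3, 2.5, 2), anchor = c(0, 3))$auc_last)
  m5n <- nca_profile(p5, isf_anchor = "none", warn = FALSE)
  expect_equal(m5n$auc_last, auc_linuplogdown(mids, c(3, 2.5, 2))$auc_last)

  # window class is attached only to VRC plasma profiles with a trough
  pp <- conc_profile("S", "VRC", "plasma", 5, c(0, 6, 12), c(5, 8, 3))
  expect_equal(nca_profile(pp, warn = FALSE)$window_class, "within")
  pn <- conc_profile("S", "NO", "plasma", 5, c(0, 6, 12), c(5, 8, 3))
  expect_equal(nca_profile(pn, warn = FALSE)$window_class, "not_applicable")
})
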