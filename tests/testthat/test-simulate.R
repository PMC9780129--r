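test_that("default trial reproduces the clinical dosing and sampling design", {
  sc <- default_trial()
  doses <- sc$dose_plan(65)
  expect_equal(nrow(doses), 7)                       # seven doses over 4 days
  expect_equal(doses$amount[1], 390)                 # 6 mg/kg at 65 kg
  expect_equal(doses$amount[3], 260)                 # 4 mg/kg on day two
  expect_equal(doses$duration[1:4], c(2, 2, 1.3, 1.3))
  expect_equal(doses$route[5:7], rep("oral", 3))
  expect_equal(doses$start_time, 12 * (0:6))

  rich <- names(Filter(function(x) length(x) == 16, sc$plasma_schedule))
  expect_equal(rich, c("1", "5", "7"))
  expect_equal(nrow(sc$dial_schedule[["1"]]), 16)
  expect_null(sc$dial_schedule[["6"]])
  expect_equal(sc$retro_perfusate_ugml, 200)
  expect_equal(nrow(sc$retro_occasions), 2)

  # day-one i.v. doses of all default subjects fall in the printed range
  w <- vapply(sc$subjects, `[[`, 0, "body_weight")
  expect_true(all(6 * w >= 390 & 6 * w <= 461))
  expect_true(all(4 * w >= 260 & 4 * w <= 307))

  # the factory enforces the phenotype ordering of oxidation capacity
  vmax <- vapply(c("RM", "NM", "RM_PM", "IM"),
                 function(ph) default_pk_parameters(ph)$Vmax, 0)
  expect_true(all(diff(vmax) < 0))
})

test_that("linear-limit infusion kinetics match the closed-form two-compartment solution", {
  pk <- default_pk_parameters("RM", vmax_scale = 1e6)  # first-order limit
  sc <- default_trial(assay_cv = 0, seed = 1)
  sc$subjects <- sc$subjects["RM"]
  sc$subjects$RM$pk <- pk
  amount_mg <- 400; dur <- 2
  sc$dose_plan <- function(weight) {
    data.frame(subject_id = "x", interval_index = 1, start_time = 0,
               amount = amount_mg, route = "iv_infusion", duration = dur,
               stringsAsFactors = FALSE)
  }
  check_t <- c(0.5, 1, 2, 3, 6, 12, 24, 48, 84)
  traj <- simulate_true_concentrations(sc, extra_times = check_t)[[1]]

  # independent oracle: eigen decomposition of the linear system
  cl_lin <- pk$CL_other + pk$fu * pk$Vmax / pk$Km
  A <- matrix(c(-(cl_lin + pk$Q) / pk$V1, pk$Q / pk$V2,
                pk$Q / pk$V1, -pk$Q / pk$V2), 2, 2, byrow = TRUE)
  rate <- amount_mg * 1000 / default_analytes()$VRC$molar_mass / dur
  b <- c(rate, 0)
  eg <- eigen(A)
  expAt <- function(t) eg$vectors %*% diag(exp(eg$values * t)) %*% solve(eg$vectors)
  y_inf <- function(t) solve(A, (expAt(t) - diag(2)) %*% b)   # during infusion
  yD <- y_inf(dur)
  oracle <- vapply(check_t, function(t) {
    y <- if (t <= dur) y_inf(t) else expAt(t - dur) %*% yD
    y[1] / pk$V1
  }, 0)
  got <- traj$cp_vrc[match(check_t, traj$time)]
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("zero dosing leaves every state at zero", {
  sc <- default_trial(assay_cv = 0, seed = 1)
  sc$subjects <- sc$subjects["NM"]
  sc$dose_plan <- function(weight) {
    data.frame(subject_id = character(0), interval_index = integer(0),
               start_time = numeric(0), amount = numeric(0),
               route = character(0), duration = numeric(0),
               stringsAsFactors = FALSE)
  }
  traj <- simulate_true_concentrations(sc)[[1]]
  expect_true(all(abs(as.matrix(traj[, -1])) == 0))
})

test_that("mass balance closes over the full trial", {
  sc <- default_trial(assay_cv = 0, seed = 42)
  trajs <- simulate_true_concentrations(sc)
  M <- default_analytes()$VRC$molar_mass
  for (s in sc$subjects) {
    doses <- sc$dose_plan(s$body_weight)
    administered <- sum(doses$amount) * 1000 / M
    traj <- trajs[[s$subject_id]]
    fin <- traj[nrow(traj), ]
    recovered <- fin$Ag + fin$Ac + fin$Ap + fin$Eunabs + fin$Eother + fin$cumNO
    expect_equal(recovered, administered, tolerance = 1e-6)
    # every mole of formed metabolite is either circulating or eliminated
    expect_equal(fin$cumNO, fin$Am + fin$Emet, tolerance = 1e-6)
  }
})

test_that("observation flags the pre-dose baseline below LLOQ", {
  trial <- noisefree_trial()
  base <- trial$plasma[trial$plasma$interval_index == 1 & trial$plasma$time == 0, ]
  expect_true(all(base$below_lloq))
  expect_true(all(trial$plasma$concentration >= 0))
  # dialysate concentrations are recovery-diluted, never above true ISF level
  expect_true(all(trial$dialysate$concentration >= 0))
})

test_that("a fixed seed makes the simulated trial bit-reproducible", {
  sc1 <- default_trial(assay_cv = 10, seed = 7)
  sc2 <- default_trial(assay_cv = 10, seed = 7)
  t1 <- simulate_trial(sc1); t2 <- simulate_trial(sc2)
  for (nm in c("plasma", "dialysate", "retrodialysis", "doses", "subjects")) {
    expect_identical(t1[[nm]], t2[[nm]])
  }
  t3 <- simulate_trial(default_trial(assay_cv = 10, seed = 8))
  expect_false(identical(t1$plasma$concentration, t3$plasma$concentration))
})

test_that("metabolite exposure lags the parent in the first interval", {
  run <- noisefree_run()
  m <- run$metrics[run$metrics$matrix == "plasma" & run$metrics$interval_index == 1, ]
  for (s in unique(m$subject_id)) {
    expect_gte(m$t_max[m$subject_id == s & m$analyte == "NO"],
               m$t_max[m$subject_id == s & m$analyte == "VRC"])
  }
})

test_that("catheter replacement produces a per-catheter calibration path", {
  sc <- default_trial(assay_cv = 0, seed = 42, catheter_replacement = TRUE,
                      replacement_rr = 88)
  trial <- simulate_trial(sc)
  d <- trial$dialysate[trial$dialysate$subject_id == "S3_RM_PM", ]
  expect_setequal(unique(d$catheter_id), c("C1", "C2"))
  # three mid-interval collections are lost per analyte in interval 5
  expect_equal(sum(d$interval_index == 5 & d$analyte == "VRC"), 13)
  r <- trial$retrodialysis[trial$retrodialysis$subject_id == "S3_RM_PM", ]
  expect_equal(unique(r$catheter_id[r$occasion == 1]), "C1")
  expect_equal(unique(r$catheter_id[r$occasion == 2]), "C2")

  # each catheter is calibrated from its own occasion and recovers its RR
  cal <- aggregate_calibration(r)
  expect_equal(cal$rd_percent[cal$catheter_id == "C1"],
               sc$true_rr[["RM_PM"]], tolerance = 1e-12)
  expect_equal(cal$rd_percent[cal$catheter_id == "C2"], 88, tolerance = 1e-12)
  expect_equal(cal$n_occasions, c(1, 1))
})
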