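#' Per-subject PK parameters for the synthetic trial
#'
#' Mechanistic stand-in model: two-compartment disposition of the parent
#' (central volume `V1`, peripheral `V2`, inter-compartment clearance `Q`),
#' first-order non-oxidative clearance `CL_other`, saturable
#' (Michaelis-Menten) N-oxidation of unbound parent (`Vmax`, `Km`),
#' first-order oral absorption (`ka`, bioavailability `F_oral`),
#' one-compartment metabolite (`Vm`, `CLm`), and first-order plasma-ISF
#' equilibration (`isf_lag_rate`) towards a steady-state unbound partition
#' (`isf_partition_vrc`, `isf_partition_no`). `inhibition_strength`
#' optionally reduces Vmax with cumulative metabolite formation
#' (auto-inhibition; off by default).
#'
#' @param V1,V2 Central/peripheral distribution volumes (L).
#' @param Q Inter-compartment clearance (L/h).
#' @param CL_other Non-oxidative parent clearance (L/h).
#' @param Vmax Maximal N-oxidation rate (\eqn{\mu}mol/h).
#' @param Km Saturation constant on unbound parent concentration
#'   (\eqn{\mu}mol/L).
#' @param ka Oral absorption rate constant (1/h).
#' @param F_oral Oral bioavailability, (0, 1].
#' @param Vm Metabolite distribution volume (L).
#' @param CLm Total metabolite clearance (L/h).
#' @param fu,fu_no Plasma fraction unbound of parent / metabolite, (0, 1].
#' @param isf_lag_rate Plasma-ISF equilibration rate (1/h).
#' @param isf_partition_vrc,isf_partition_no Steady-state ISF:unbound-plasma
#'   partition coefficients, (0, 1].
#' @param inhibition_strength Dimensionless auto-inhibition gain, >= 0.
#' @return Object of class `pk_parameters`.
#' @export
pk_parameters <- function(V1, V2, Q, CL_other, Vmax, Km, ka, F_oral,
                          Vm, CLm, fu, fu_no = fu, isf_lag_rate,
                          isf_partition_vrc, isf_partition_no,
                          inhibition_strength = 0) {
  p <- list(V1 = V1, V2 = V2, Q = Q, CL_other = CL_other, Vmax = Vmax,
            Km = Km, ka = ka, F_oral = F_oral, Vm = Vm, CLm = CLm,
            fu = fu, fu_no = fu_no, isf_lag_rate = isf_lag_rate,
            isf_partition_vrc = isf_partition_vrc,
            isf_partition_no = isf_partition_no,
            inhibition_strength = inhibition_strength)
  pos <- c("V1", "V2", "Q", "CL_other", "Vmax", "Km", "ka", "Vm", "CLm",
           "isf_lag_rate")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      stop(sprintf("pk_parameters: %s must be positive", nm), call. = FALSE)
    }
  }
  for (nm in c("F_oral", "fu", "fu_no", "isf_partition_vrc", "isf_partition_no")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0 || p[[nm]] > 1) {
      stop(sprintf("pk_parameters: %s must lie in (0, 1]", nm), call. = FALSE)
    }
  }
  if (p$inhibition_strength < 0) {
    stop("pk_parameters: inhibition_strength must be >= 0", call. = FALSE)
  }
  structure(p, class = "pk_parameters")
}

#' Default parameter factory by CYP2C19 phenotype
#'
#' Returns the study-condition parameter set of the synthetic trial. The
#' N-oxidation capacity is ordered RM > NM > RM_PM > IM (rapid, normal,
#' rapid/poor, intermediate metabolizer), which reverses into the exposure
#' ordering IM > RM_PM > NM > RM for the parent and restores it for the
#' metabolite. The intermediate metabolizer additionally carries a low
#' metabolite ISF partition, echoing the distinctly poor metabolite tissue
#' penetration seen clinically in that phenotype.
#'
#' @param phenotype One of `"RM"`, `"NM"`, `"RM_PM"`, `"IM"`.
#' @param vmax_scale,km Tuning constants of the factory: a common scale on
#'   the phenotype Vmax grid (\eqn{\mu}mol/h) and the saturation constant on
#'   unbound concentration (\eqn{\mu}mol/L). Scaling both by the same large
#'   factor yields the first-order (linear-metabolism) limit at unchanged
#'   intrinsic clearance Vmax/Km.
#' @return A [pk_parameters()] object.
#' @export
default_pk_parameters <- function(phenotype = c("RM", "NM", "RM_PM", "IM"),
                                  vmax_scale = 1, km = 8.0 * vmax_scale) {
  phenotype <- match.arg(phenotype)
  vmax <- c(RM = 128, NM = 96, RM_PM = 69, IM = 56)[[phenotype]] * vmax_scale
  part_no <- if (phenotype == "IM") 0.12 else 0.50
  pk_parameters(
    V1 = 70, V2 = 250, Q = 15, CL_other = 3,
    Vmax = vmax, Km = km, ka = 1.0, F_oral = 0.9,
    Vm = 0.4, CLm = 3,
    fu = 0.50, fu_no = 0.50,
    isf_lag_rate = 2.0,
    isf_partition_vrc = 0.95, isf_partition_no = part_no,
    inhibition_strength = 0
  )
}

#' Sampling schedules of the trial design
#'
#' Rich dosing intervals take 16 plasma samples
#' (0, 0.5, 1, 1.5, 1.75, 2, 2.25, 2.5, 3.25, 4.5, 6, 8, 9, 10, 11, 12 h)
#' and 16 microdialysate collection intervals (half-hourly to 4 h, hourly to
#' 12 h). Sparse intervals take plasma at the end of infusion and at 12 h,
#' with 0.33 h microdialysate collections until the end of the infusion; the
#' sixth (oral) interval has a 12 h plasma sample only.
#'
#' @name trial-schedules
#' @keywords internal
NULL

.rich_plasma_times <- c(0, 0.5, 1, 1.5, 1.75, 2, 2.25, 2.5, 3.25, 4.5,
                        6, 8, 9, 10, 11, 12)
.rich_dialysate_windows <- function() {
  st <- c(seq(0, 3.5, by = 0.5), 4:11)
  en <- c(seq(0.5, 4, by = 0.5), 5:12)
  data.frame(t_start = st, t_end = en)
}
.sparse_dialysate_windows <- function(infusion_duration) {
  n <- ceiling(infusion_duration / 0.33 - 1e-9)
  data.frame(t_start = 0.33 * (seq_len(n) - 1), t_end = 0.33 * seq_len(n))
}

#' Default synthetic trial scenario
#'
#' Builds the full specification of a synthetic four-day microdialysis
#' trial in four healthy subjects, one per CYP2C19 phenotype: twice-daily
#' dosing with 6 mg/kg i.v. 2 h infusions on day one, 4 mg/kg i.v. 1.3 h
#' infusions on day two and 200 mg oral doses on days three and four
#' (seven doses in total, 12 h dosing intervals); rich sampling in dosing
#' intervals 1, 5 and 7 and sparse sampling otherwise; retrodialysis
#' calibration (retroperfusate 200 ug/mL, two replicate retrodialysate
#' samples per occasion) after the third and the seventh dosing interval.
#'
#' @param assay_cv Multiplicative lognormal assay noise, percent CV
#'   (default 10; set 0 for noise-free ground-truth studies).
#' @param seed Random seed of the scenario (default 42).
#' @param catheter_replacement Emulate a mid-trial catheter replacement in
#'   the RM_PM subject during dosing interval 5: three mid-interval
#'   dialysate collections are lost and the two retrodialysis occasions fall
#'   on different catheters.
#' @param body_weights Named numeric vector of body weights (kg) per
#'   phenotype; defaults lie in 65-71 kg so the weight-based i.v. doses
#'   fall within 390-426 mg on day one and 260-284 mg on day two.
#' @param true_rr Named numeric vector, true relative recovery (%) per
#'   phenotype (catheter C1).
#' @param replacement_rr True relative recovery (%) of the replacement
#'   catheter (C2) when `catheter_replacement` is on.
#' @param parameters Optional named list of [pk_parameters()] per phenotype,
#'   overriding [default_pk_parameters()].
#' @param analytes Analyte set, see [default_analytes()].
#' @return Object of class `sim_scenario`.
#' @export
default_trial <- function(assay_cv = 10, seed = 42,
                          catheter_replacement = FALSE,
                          body_weights = c(RM = 65, NM = 70, RM_PM = 68, IM = 71),
                          true_rr = c(RM = 92.4, NM = 85.0, RM_PM = 78.6, IM = 96.0),
                          replacement_rr = 88.0,
                          parameters = NULL,
                          analytes = default_analytes()) {
  phenos <- c("RM", "NM", "RM_PM", "IM")
  subjects <- lapply(phenos, function(ph) {
    pk <- if (!is.null(parameters)) parameters[[ph]] else default_pk_parameters(ph)
    list(subject_id = paste0("S", match(ph, phenos), "_", ph),
         phenotype = ph, body_weight = body_weights[[ph]], pk = pk)
  })
  names(subjects) <- phenos

  ## dose plan: interval k starts at 12*(k-1) h of trial time
  dose_plan <- function(weight) {
    data.frame(
      interval_index = 1:7,
      start_time = 12 * (0:6),
      amount = c(rep(6 * weight, 2), rep(4 * weight, 2), rep(200, 3)),
      route = c(rep("iv_infusion", 4), rep("oral", 3)),
      duration = c(2, 2, 1.3, 1.3, 0, 0, 0),
      stringsAsFactors = FALSE
    )
  }

  plasma_schedule <- list(
    `1` = .rich_plasma_times, `2` = c(2, 12), `3` = c(1.3, 12),
    `4` = c(1.3, 12), `5` = .rich_plasma_times, `6` = 12,
    `7` = .rich_plasma_times
  )
  dial_schedule <- list(
    `1` = .rich_dialysate_windows(), `2` = .sparse_dialysate_windows(2),
    `3` = .sparse_dialysate_windows(1.3), `4` = .sparse_dialysate_windows(1.3),
    `5` = .rich_dialysate_windows(), `6` = NULL,
    `7` = .rich_dialysate_windows()
  )

  structure(
    list(subjects = subjects, dose_plan = dose_plan,
         plasma_schedule = plasma_schedule, dial_schedule = dial_schedule,
         retro_occasions = data.frame(occasion = 1:2, after_interval = c(3, 7)),
         retro_perfusate_ugml = 200, retro_replicates = 2,
         true_rr = true_rr, replacement_rr = replacement_rr,
         catheter_replacement = catheter_replacement,
         assay_cv = assay_cv, seed = seed, analytes = analytes,
         horizon = 84, n_intervals = 7),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario> %d subjects, %d dosing intervals, assay CV %g%%, seed %s%s\n",
              length(x$subjects), x$n_intervals, x$assay_cv, x$seed,
              if (x$catheter_replacement) ", with catheter replacement" else ""))
  invisible(x)
}

## Right-hand side of the PK system. Amounts in umol, concentrations umol/L,
## time in hours. `rate` is the (piecewise-constant) i.v. infusion rate.
.pk_derivs <- function(t, y, parms) {
  p <- parms$p
  rate <- parms$rate
  with(as.list(y), {
    cu <- p$fu * Ac / p$V1
    vmax_eff <- p$Vmax / (1 + p$inhibition_strength * cumNO / p$Vm)
    met <- vmax_eff * cu / (p$Km + cu)
    dAg <- -p$ka * Ag
    input <- rate + p$ka * p$F_oral * Ag
    dAc <- input - (p$CL_other / p$V1) * Ac - met -
      (p$Q / p$V1) * Ac + (p$Q / p$V2) * Ap
    dAp <- (p$Q / p$V1) * Ac - (p$Q / p$V2) * Ap
    dAm <- met - (p$CLm / p$Vm) * Am
    dCiv <- p$isf_lag_rate * (p$isf_partition_vrc * p$fu * Ac / p$V1 - Civ)
    dCin <- p$isf_lag_rate * (p$isf_partition_no * p$fu_no * Am / p$Vm - Cin)
    list(c(dAg, dAc, dAp, dAm, dCiv, dCin,
           met,                      # cumNO: cumulative metabolite formed
           Ac / p$V1, Am / p$Vm,     # integrals of total plasma conc
           Civ, Cin,                 # integrals of ISF conc
           (p$CL_other / p$V1) * Ac, # eliminated unchanged-ish (non-oxidative)
           (p$CLm / p$Vm) * Am,      # metabolite eliminated
           p$ka * (1 - p$F_oral) * Ag))  # oral dose never absorbed
  })
}

.state_names <- c("Ag", "Ac", "Ap", "Am", "Civ", "Cin", "cumNO",
                  "Icp_v", "Icp_n", "Iisf_v", "Iisf_n",
                  "Eother", "Emet", "Eunabs")

## Integrate one subject over the trial horizon, splitting at every dosing
## discontinuity so the solver never steps across a rate jump.
.solve_subject <- function(pk, doses, out_times, horizon, molar_mass_vrc,
                           rtol = 1e-10, atol = 1e-10) {
  amt_umol <- doses$amount * 1000 / molar_mass_vrc
  iv <- doses$route == "iv_infusion"
  bounds <- sort(unique(c(0, doses$start_time,
                          doses$start_time[iv] + doses$duration[iv],
                          horizon)))
  bounds <- bounds[bounds <= horizon + 1e-9]
  out_times <- sort(unique(c(out_times, bounds)))
  y <- stats::setNames(numeric(length(.state_names)), .state_names)
  rows <- vector("list", length(bounds) - 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1L]
    oral_now <- which(!iv & abs(doses$start_time - t0) < 1e-9)
    if (length(oral_now)) y[["Ag"]] <- y[["Ag"]] + sum(amt_umol[oral_now])
    active <- iv & doses$start_time <= t0 + 1e-9 &
      (doses$start_time + doses$duration) >= t1 - 1e-9
    rate <- sum(amt_umol[active] / doses$duration[active])
    times <- unique(c(t0, out_times[out_times > t0 + 1e-12 & out_times < t1 - 1e-12], t1))
    sol <- deSolve::lsoda(y, times, .pk_derivs,
                          parms = list(p = pk, rate = rate),
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (any(!is.finite(sol))) {
      stop("parameter-domain error: non-finite state in PK integration", call. = FALSE)
    }
    y <- sol[nrow(sol), -1]
    rows[[i]] <- sol[if (i == 1) seq_len(nrow(sol)) else -1, , drop = FALSE]
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("time", .state_names)
  out$cp_vrc <- out$Ac / pk$V1
  out$cp_no <- out$Am / pk$Vm
  out$cisf_vrc <- out$Civ
  out$cisf_no <- out$Cin
  out
}

## All absolute time points the observation stage will need for a scenario.
.needed_times <- function(scenario) {
  tt <- numeric(0)
  for (k in seq_len(scenario$n_intervals)) {
    t0 <- 12 * (k - 1)
    tt <- c(tt, t0 + scenario$plasma_schedule[[as.character(k)]])
    w <- scenario$dial_schedule[[as.character(k)]]
    if (!is.null(w)) tt <- c(tt, t0 + w$t_start, t0 + w$t_end)
    tt <- c(tt, t0, t0 + 11.5, t0 + 12)
  }
  sort(unique(round(tt, 9)))
}

#' Solve the deterministic PK system for every subject
#'
#' Integrates the parent-metabolite-ISF system of each subject over the
#' trial horizon with tight tolerances (lsoda, rtol = 1e-10), splitting the
#' integration at every infusion start/stop and oral dose. The returned
#' trajectories carry, besides the state concentrations, running integrals
#' of every plasma and ISF concentration (used for exact interval averages
#' and ground-truth AUCs) and cumulative elimination fluxes (used for mass
#' balance).
#'
#' @param scenario A `sim_scenario`, see [default_trial()].
#' @param extra_times Additional absolute time points (h) to include in the
#'   output grid.
#' @return Named list (by subject id) of trajectory data frames.
#' @export
simulate_true_concentrations <- function(scenario, extra_times = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  out_times <- unique(sort(c(.needed_times(scenario), extra_times)))
  M <- scenario$analytes$VRC$molar_mass
  res <- lapply(scenario$subjects, function(s) {
    doses <- scenario$dose_plan(s$body_weight)
    .solve_subject(s$pk, doses, out_times, scenario$horizon, M)
  })
  names(res) <- vapply(scenario$subjects, `[[`, "", "subject_id")
  res
}

.lognormal_factor <- function(n, cv_percent) {
  if (cv_percent == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + (cv_percent / 100)^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))  # unit mean
}

.traj_at <- function(traj, times, col) {
  idx <- match(round(times, 9), round(traj$time, 9))
  if (anyNA(idx)) stop("internal: trajectory missing required time point", call. = FALSE)
  traj[[col]][idx]
}

## catheter id and retained flag per dialysate window of one subject
.catheter_assignment <- function(scenario, phenotype, interval_index, windows) {
  cath <- rep("C1", nrow(windows))
  keep <- rep(TRUE, nrow(windows))
  if (isTRUE(scenario$catheter_replacement) && phenotype == "RM_PM") {
    if (interval_index == 5) {
      ## replacement during mid interval 5: the 4-5, 5-6 and 6-7 h
      ## collections are lost, later collections run on the new catheter
      lost <- windows$t_start >= 4 - 1e-9 & windows$t_end <= 7 + 1e-9
      keep[lost] <- FALSE
      cath[windows$t_start >= 7 - 1e-9] <- "C2"
    } else if (interval_index > 5) {
      cath[] <- "C2"
    }
  }
  list(catheter = cath, keep = keep)
}

#' Observe a synthetic trial: emit the five input tables plus ground truth
#'
#' Applies the observation model to deterministic trajectories: plasma
#' samples are the total plasma concentration at the nominal times; each
#' microdialysate sample is the relative recovery times the exact time
#' average of the ISF concentration over its collection window;
#' retrodialysate samples are `retroperfusate * (1 - RR/100)`. All
#' measurements receive multiplicative unit-mean lognormal noise with the
#' scenario's CV and are flagged below-LLOQ against the assay limits. The
#' returned ground truth holds quadrature-exact AUCs (full dosing interval
#' and matched to the rich-sampling support), the true recoveries and the
#' true parameters.
#'
#' @param scenario A `sim_scenario`.
#' @param trajectories Result of [simulate_true_concentrations()].
#' @return List of class `sim_trial`: `plasma`, `dialysate`,
#'   `retrodialysis`, `doses`, `subjects` (validated tables) and
#'   `ground_truth` (list with `auc`, `rr`, `parameters`).
#' @export
observe <- function(scenario, trajectories) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  analytes <- scenario$analytes
  plasma <- list(); dial <- list(); retro <- list()
  doses <- list(); subj <- list(); gt_auc <- list(); gt_rr <- list()
  rr_for <- function(phenotype, catheter) {
    if (isTRUE(scenario$catheter_replacement) && phenotype == "RM_PM" &&
        catheter == "C2") scenario$replacement_rr
    else scenario$true_rr[[phenotype]]
  }

  for (s in scenario$subjects) {
    sid <- s$subject_id
    traj <- trajectories[[sid]]
    dtab <- scenario$dose_plan(s$body_weight)
    dtab$subject_id <- sid
    doses[[sid]] <- dtab[, c("subject_id", "interval_index", "start_time",
                             "amount", "route", "duration")]
    subj[[sid]] <- data.frame(subject_id = sid, phenotype = s$phenotype,
                              body_weight = s$body_weight,
                              stringsAsFactors = FALSE)
    catheters <- "C1"

    for (k in seq_len(scenario$n_intervals)) {
      t0 <- 12 * (k - 1)
      ## plasma, both analytes
      pt <- scenario$plasma_schedule[[as.character(k)]]
      for (a in c("VRC", "NO")) {
        col <- if (a == "VRC") "cp_vrc" else "cp_no"
        conc <- .traj_at(traj, t0 + pt, col) * .lognormal_factor(length(pt), scenario$assay_cv)
        plasma[[length(plasma) + 1L]] <- data.frame(
          subject_id = sid, analyte = a, interval_index = k, time = pt,
          concentration = conc, stringsAsFactors = FALSE)
      }
      ## dialysate, both analytes
      w <- scenario$dial_schedule[[as.character(k)]]
      if (!is.null(w)) {
        ca <- .catheter_assignment(scenario, s$phenotype, k, w)
        catheters <- unique(c(catheters, ca$catheter))
        rr_w <- vapply(ca$catheter, function(cc) rr_for(s$phenotype, cc), 0)
        for (a in c("VRC", "NO")) {
          icol <- if (a == "VRC") "Iisf_v" else "Iisf_n"
          avg <- (.traj_at(traj, t0 + w$t_end, icol) -
                  .traj_at(traj, t0 + w$t_start, icol)) / (w$t_end - w$t_start)
          conc <- rr_w / 100 * avg * .lognormal_factor(nrow(w), scenario$assay_cv)
          d <- data.frame(subject_id = sid, analyte = a,
                          catheter_id = ca$catheter, interval_index = k,
                          t_start = w$t_start, t_end = w$t_end,
                          concentration = conc, stringsAsFactors = FALSE)
          dial[[length(dial) + 1L]] <- d[ca$keep, , drop = FALSE]
        }
      }
      ## ground-truth AUCs per analyte and matrix for this interval
      for (a in c("VRC", "NO")) {
        cols <- if (a == "VRC") c("Icp_v", "Iisf_v") else c("Icp_n", "Iisf_n")
        full_p <- .traj_at(traj, t0 + 12, cols[1]) - .traj_at(traj, t0, cols[1])
        full_i <- .traj_at(traj, t0 + 12, cols[2]) - .traj_at(traj, t0, cols[2])
        supp_i <- .traj_at(traj, t0 + 11.5, cols[2]) - .traj_at(traj, t0, cols[2])
        gt_auc[[length(gt_auc) + 1L]] <- data.frame(
          subject_id = sid, analyte = a, interval_index = k,
          matrix = c("plasma", "isf"),
          auc_full = c(full_p, full_i),
          auc_support = c(full_p, supp_i),  # rich plasma support is 0-12 h
          stringsAsFactors = FALSE)
      }
    }

    ## retrodialysis: per occasion, on the catheter in use at that time
    for (o in seq_len(nrow(scenario$retro_occasions))) {
      occ <- scenario$retro_occasions$occasion[o]
      cath <- if (isTRUE(scenario$catheter_replacement) &&
                  s$phenotype == "RM_PM" &&
                  scenario$retro_occasions$after_interval[o] > 5) "C2" else "C1"
      nrep <- scenario$retro_replicates
      rdial <- scenario$retro_perfusate_ugml *
        (1 - rr_for(s$phenotype, cath) / 100) *
        .lognormal_factor(nrep, scenario$assay_cv)
      retro[[length(retro) + 1L]] <- data.frame(
        subject_id = sid, catheter_id = cath, occasion = occ,
        replicate = seq_len(nrep),
        retroperfusate_conc = scenario$retro_perfusate_ugml,
        retrodialysate_conc = rdial, stringsAsFactors = FALSE)
    }
    for (cath in catheters) {
      gt_rr[[length(gt_rr) + 1L]] <- data.frame(
        subject_id = sid, catheter_id = cath,
        rr_true = rr_for(s$phenotype, cath), stringsAsFactors = FALSE)
    }
  }

  params <- do.call(rbind, lapply(scenario$subjects, function(s) {
    cbind(data.frame(subject_id = s$subject_id, phenotype = s$phenotype,
                     stringsAsFactors = FALSE),
          as.data.frame(unclass(s$pk)))
  }))
  rownames(params) <- NULL

  out <- list(
    plasma = validate_table(do.call(rbind, plasma), "plasma", analytes),
    dialysate = validate_table(do.call(rbind, dial), "dialysate", analytes),
    retrodialysis = validate_table(do.call(rbind, retro), "retrodialysis", analytes),
    doses = validate_table(do.call(rbind, doses), "doses", analytes),
    subjects = validate_table(do.call(rbind, subj), "subjects", analytes),
    ground_truth = list(auc = do.call(rbind, gt_auc),
                        rr = do.call(rbind, gt_rr),
                        parameters = params)
  )
  for (nm in c("plasma", "dialysate", "retrodialysis", "doses", "subjects")) {
    rownames(out[[nm]]) <- NULL
  }
  class(out) <- "sim_trial"
  out
}

#' Simulate a complete synthetic trial
#'
#' Convenience wrapper: [simulate_true_concentrations()] followed by
#' [observe()].
#'
#' @param scenario A `sim_scenario`, see [default_trial()].
#' @return A `sim_trial` list (five tables + ground truth).
#' @export
simulate_trial <- function(scenario = default_trial()) {
  observe(scenario, simulate_true_concentrations(scenario))
}

#' @export
print.sim_trial <- function(x, ...) {
  cat(sprintf("<sim_trial> %d plasma, %d dialysate, %d retrodialysis records; %d subjects\n",
              nrow(x$plasma), nrow(x$dialysate), nrow(x$retrodialysis),
              nrow(x$subjects)))
  invisible(x)
}

#' Write the simulated tables of a trial to CSV files
#'
#' Emits `plasma.csv`, `dialysate.csv`, `retrodialysis.csv`, `doses.csv`,
#' `subjects.csv` and `ground_truth.csv` (the true AUC table) into a
#' directory.
#'
#' @param trial A `sim_trial`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_trial_csv <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("plasma", "dialysate", "retrodialysis", "doses", "subjects")) {
    write_table_csv(trial[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  utils::write.csv(trial$ground_truth$auc, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
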