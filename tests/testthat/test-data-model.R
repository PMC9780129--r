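make_plasma_df <- function() {
  data.frame(subject_id = "S1", analyte = "VRC", interval_index = 1,
             time = c(0, 1, 2), concentration = c(0, 5, 3),
             stringsAsFactors = FALSE)
}

test_that("well-formed tables validate and round trip through CSV", {
  df <- make_plasma_df()
  v <- validate_table(df, "plasma")
  expect_equal(nrow(v), 3)
  expect_equal(v$below_lloq, c(TRUE, FALSE, FALSE))  # 0 is below LLOQ

  path <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(v, path)
  back <- read_samples(path, "plasma")
  expect_equal(back$concentration, v$concentration)
  expect_equal(back$below_lloq, v$below_lloq)

  # simulated tables also round trip exactly
  trial <- noisefree_trial()
  for (nm in c("dialysate", "retrodialysis", "doses", "subjects")) {
    p <- withr::local_tempfile(fileext = ".csv")
    write_table_csv(trial[[nm]], p)
    back <- read_samples(p, nm)
    expect_equal(back[setdiff(names(back), "row")],
                 trial[[nm]][setdiff(names(trial[[nm]]), "row")],
                 tolerance = 1e-12)
  }
})

test_that("unit-declared files are converted on ingestion", {
  df <- make_plasma_df()
  df$concentration <- c(0, 1, 2)  # ug/mL
  v <- validate_table(df, "plasma", unit = "ug/mL")
  expect_equal(v$concentration,
               ugml_to_umolL(c(0, 1, 2), default_analytes()$VRC))
})

test_that("schema violations are rejected with the offending row", {
  df <- make_plasma_df()
  expect_error(validate_table(df[, -4], "plasma"), "missing column")

  bad <- data.frame(subject_id = "S1", analyte = "VRC", catheter_id = "C1",
                    interval_index = 1, t_start = c(0, 1), t_end = c(0.5, 0.9),
                    concentration = c(1, 1))
  expect_error(validate_table(bad, "dialysate"), "row 2")

  overlap <- data.frame(subject_id = "S1", analyte = "VRC", catheter_id = "C1",
                        interval_index = 1, t_start = c(0, 0.4),
                        t_end = c(0.5, 1), concentration = c(1, 1))
  expect_error(validate_table(overlap, "dialysate"), "overlapping")

  neg <- make_plasma_df(); neg$concentration[2] <- -1
  expect_error(validate_table(neg, "plasma"), "row 2")

  subj <- data.frame(subject_id = "S1", phenotype = "XX", body_weight = 70)
  expect_error(validate_table(subj, "subjects"), "phenotype")

  dose <- data.frame(subject_id = "S1", interval_index = 1, start_time = 0,
                     amount = 400, route = "oral", duration = 2)
  expect_error(validate_table(dose, "doses"), "duration")
})

test_that("LLOQ flagging compares against the matrix-specific assay limit", {
  an <- default_analytes()
  df <- data.frame(subject_id = "S1", analyte = "VRC", catheter_id = "C1",
                   interval_index = 1, t_start = 0, t_end = 0.5,
                   concentration = lloq_umolL(an$VRC, "dialysate") * c(0.99))
  v <- validate_table(df, "dialysate", analytes = an)
  expect_true(v$below_lloq)
  df$concentration <- lloq_umolL(an$VRC, "dialysate") * 1.01
  expect_false(validate_table(df, "dialysate", analytes = an)$below_lloq)
})

test_that("drop_blq removes censored records and anchors the first interval", {
  rec <- data.frame(time = c(0, seq_len(15)),
                    concentration = c(0, 15:1),
                    below_lloq = c(TRUE, rep(FALSE, 15)))
  p <- drop_blq(rec, "S1", "VRC", "plasma", 1)
  expect_s3_class(p, "conc_profile")
  expect_equal(length(p$time), 16)          # BLQ baseline became the 0 anchor
  expect_equal(p$concentration[1], 0)

  # 16 samples with 1 interior BLQ -> 15-point profile (interval > 1)
  rec5 <- data.frame(time = 0:15, concentration = c(3, 15:1),
                     below_lloq = c(FALSE, FALSE, TRUE, rep(FALSE, 13)))
  p5 <- drop_blq(rec5, "S1", "VRC", "plasma", 5)
  expect_equal(length(p5$time), 15)

  # no BLQ -> unchanged
  p0 <- drop_blq(data.frame(time = 1:3, concentration = 3:1,
                            below_lloq = rep(FALSE, 3)), "S1", "NO", "isf", 5)
  expect_equal(p0$concentration, 3:1)

  # all BLQ -> empty-profile signal
  expect_warning(
    out <- drop_blq(data.frame(time = 1:3, concentration = rep(0, 3),
                               below_lloq = rep(TRUE, 3)), "S1", "NO", "isf", 5),
    "empty profile")
  expect_null(out)
})

test_that("profiles enforce ordering and positivity", {
  expect_error(conc_profile("S", "VRC", "plasma", 1, c(1, 1), c(2, 3)),
               "strictly increasing")
  expect_error(conc_profile("S", "VRC", "plasma", 1, c(1, 2), c(2, 0)),
               "positive")
  expect_error(conc_profile("S", "VRC", "plasma", 1, numeric(0), numeric(0)),
               "empty")
})
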