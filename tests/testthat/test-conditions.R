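test_that("condition configs validate their protocol sweeps", {
  expect_s3_class(condition_config("MR", 4), "condition_config")
  expect_error(condition_config("MR", 5), "out of range")
  expect_error(condition_config("HFpEF", 4), "out of range")
  expect_error(condition_config("nonsense"), "unknown condition")
  expect_error(condition_config(co_target = 20), "co_target")
})

test_that("exercise heart rate interpolates linearly between the endpoints", {
  expect_equal(exercise_hr(5), 70)
  expect_equal(exercise_hr(14), 130)
  expect_equal(exercise_hr(8), 90)
  expect_equal(exercise_hr(11), 110)
})

test_that("reference condition leaves the parameter set unchanged", {
  p <- reference_params()
  expect_identical(apply_condition(condition_config(), p), p)
})

test_that("regurgitation and stenosis sweeps set the stated valve fractions", {
  p <- reference_params()
  for (s in 1:4) {
    mr <- apply_condition(condition_config("MR", s), p)
    expect_equal(mr$valves$mv[["leak"]], 0.06 + 0.02 * s)
    ts <- apply_condition(condition_config("TS", s), p)
    expect_equal(ts$valves$tv[["sten"]], 0.40 + 0.10 * s)
  }
  expect_equal(apply_condition(condition_config("MR", 1), p)$valves$mv[["leak"]],
               0.08)
  expect_equal(apply_condition(condition_config("MS", 4), p)$valves$mv[["sten"]],
               0.80)
})

test_that("septal defect sweeps open the stated orifice diameters", {
  p <- reference_params()
  for (s in 1:4) {
    d <- 4 + 2 * s
    asd <- apply_condition(condition_config("ASD", s), p)
    expect_equal(asd$shunt[["loc"]], 1)
    expect_equal(asd$shunt[["area"]], pi * (d / 20)^2)
    vsd <- apply_condition(condition_config("VSD", s), p)
    expect_equal(vsd$shunt[["loc"]], 2)
  }
})

test_that("aging scales ventricular stiffness and relaxation by 2-12 %", {
  p <- reference_params()
  for (s in 1:6) {
    a <- apply_condition(condition_config("aging", s), p)
    f <- 1 + 0.02 * s
    expect_equal(a$chambers$lv[["eed"]], p$chambers$lv[["eed"]] * f)
    expect_equal(a$chambers$rv[["tau"]], p$chambers$rv[["tau"]] * f)
    # atria untouched
    expect_equal(a$chambers$la[["eed"]], p$chambers$la[["eed"]])
  }
})

test_that("HFpEF grades apply the graded diastolic abnormality to the LV", {
  p <- reference_params()
  eed_mult <- c(1.00, 1.75, 2.30)
  for (g in 1:3) {
    h <- apply_condition(condition_config("HFpEF", g), p)
    expect_equal(h$chambers$lv[["eed"]], p$chambers$lv[["eed"]] * eed_mult[g])
    expect_equal(h$chambers$lv[["tau"]], p$chambers$lv[["tau"]] * 1.80)
    # right ventricle untouched
    expect_equal(h$chambers$rv[["eed"]], p$chambers$rv[["eed"]])
  }
})

test_that("exercise engages sympathetic inotropy and lusitropy", {
  p <- reference_params()
  e <- apply_condition(condition_config(co_target = 14), p)
  expect_equal(e$chambers$lv[["emax"]], p$chambers$lv[["emax"]] * 2)
  expect_equal(e$chambers$lv[["tau"]], p$chambers$lv[["tau"]] / 2)
  # disease modification composes with the exercise scaling
  me <- apply_condition(condition_config("MR", 2, co_target = 8), p)
  expect_equal(me$valves$mv[["leak"]], 0.10)
  expect_equal(me$chambers$rv[["emax"]],
               p$chambers$rv[["emax"]] * (1 + 20 / 60))
})

test_that("shunt specification validates its geometry", {
  expect_error(shunt_spec("atrial", 0), "diameter")
  expect_error(shunt_spec("none", 6), "without a location")
  expect_equal(shunt_spec("atrial", 10)[["area"]], pi * 0.25,
               tolerance = 1e-12)
})
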