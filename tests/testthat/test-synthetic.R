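test_that("fixtures carry the registered generating values", {
  fx <- fixture("AA-C3")
  expect_equal(fx$params$S_I, 3.2e-4)
  expect_equal(fx$params$G_b, 136.4)
  expect_equal(fx$params$A_lipo, 2)
  expect_equal(fx$ra_glucose$sigma, 0.66)
  expect_equal(fx$ra_glucose$Delta, 67.9)
  wh <- fixture("WH-C4")
  expect_equal(wh$ra_glucose$tau, 33.1)
  expect_equal(wh$ra_glucose$phi, 58.1)
  expect_equal(wh$params$S_I, 5.5e-4)
  expect_error(fixture("nope"), "unknown fixture")
  expect_true(all(fixture_names() %in% c("AA-C3", "WH-C4")))
})

test_that("reference means are registered per model, combination and group", {
  expect_equal(unname(reference_means("MOD1", "C1", "AA")["S_I"]), 4.1e-4)
  expect_equal(unname(reference_means("MOD2", "C2", "white")["Delta_F"]),
               0.68)
  expect_equal(unname(reference_means("MOD3", "C1", "AA")["h_Rem"]), 5.3)
  # single-protocol combinations reuse the matching joint columns
  expect_identical(reference_means("MOD1", "S2", "AA"),
                   reference_means("MOD1", "C3", "AA"))
  expect_error(reference_means("MOD3", "C3"), "no reference")
})

test_that("synthetic insulin shapes honour the protocol conventions", {
  fs <- protocol("FSIGT")
  ins <- synth_insulin(fs)
  expect_equal(ins$value[ins$time %in% c(-10, -1)], c(5, 5))
  # first-phase peak within 0-10 min, exogenous spike after 20 min
  early <- ins$value[ins$time > 0 & ins$time <= 10]
  expect_gt(max(early), 40)
  late <- ins$value[ins$time > 20 & ins$time <= 40]
  expect_gt(max(late), max(early))
  # flat shape collapses to basal
  flat <- insulin_shape(basal = 7, fsigt_peak1 = 0, fsigt_peak2 = 0,
                        mt_peak = 0)
  expect_equal(synth_insulin(fs, flat)$value, rep(7, 32))
  expect_equal(synth_insulin(protocol("MT"), flat)$value, rep(7, 13))
  # deterministic
  expect_identical(synth_insulin(fs), synth_insulin(fs))
  # meal excursion is monophasic, peaking between 30 and 60 min
  mt <- synth_insulin(protocol("MT"))
  expect_equal(mt$value[1], 5)
  pk <- mt$time[which.max(mt$value)]
  expect_true(pk >= 30 && pk <= 60)
  expect_lt(mt$value[13], 1.05 * 5)
})

test_that("noiseless subjects reproduce the model exactly at sample times", {
  subj <- aa_c3_subject()
  fix <- attr(subj, "truth")
  expect_equal(fix$name, "AA-C3")
  # refitting machinery reads zero residuals at the generating values
  obj <- fit_objective(fix$params, subj, "C3", sigma2 = "unit",
                       ra_glucose = fix$ra_glucose)
  expect_lt(obj, 1e-8)
  # unit variances attached for noiseless data
  expect_equal(unname(subj$sigma2$MT["glucose"]), 1)
})

test_that("synthetic subjects are reproducible given a seed", {
  a <- synth_subject("AA-C3", noise_cv = 0.05, seed = 11)
  b <- synth_subject("AA-C3", noise_cv = 0.05, seed = 11)
  expect_identical(a$MT$glucose$value, b$MT$glucose$value)
  expect_identical(a$FSIGT$ffa$value, b$FSIGT$ffa$value)
  c <- synth_subject("AA-C3", noise_cv = 0.05, seed = 12)
  expect_false(identical(a$MT$glucose$value, c$MT$glucose$value))
  # insulin input is noiseless
  expect_identical(a$MT$insulin$value, c$MT$insulin$value)
})

test_that("multiplicative noise has the requested coefficient of variation", {
  clean <- aa_c3_subject()$MT$glucose$value
  reps <- sapply(1:200, function(i)
    synth_subject("AA-C3", noise_cv = 0.05, seed = 5000 + i)$MT$glucose$value)
  cv <- apply(reps, 1, sd) / clean
  expect_gt(mean(cv), 0.05 * 0.8)
  expect_lt(mean(cv), 0.05 * 1.2)
  # sigma2 records the true mean noise variance per channel
  s <- synth_subject("AA-C3", noise_cv = 0.05, seed = 1)
  expect_equal(unname(s$sigma2$MT["glucose"]),
               mean((0.05 * clean)^2), tolerance = 1e-12)
})
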