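test_that("combination registry encodes the study design", {
  c1 <- combination("C1")
  expect_equal(c1$protocols, c("FSIGT", "MT"))
  expect_equal(c1$ra_glucose, "none")
  expect_equal(combination("C2")$ra_ffa, "type1")
  expect_equal(combination("C3")$ra_glucose, "type1")
  expect_equal(combination("C4")$ra_glucose, "type2")
  expect_equal(combination("S1")$protocols, "FSIGT")
  expect_equal(combination("S2")$protocols, "MT")
  expect_equal(combination("S3")$ra_glucose, "type2")
  expect_error(combination("C9"), "unknown")
})

test_that("free parameter counts respect the fixing conventions", {
  expect_length(ffamm:::free_param_names("MOD1", "C3"), 13)
  expect_length(ffamm:::free_param_names("MOD1", "C4"), 12)
  expect_length(ffamm:::free_param_names("MOD1", "C1"), 10)
  # C2 adds Delta_F and sigma_F but not the fixed m_F / t_0F
  nm <- ffamm:::free_param_names("MOD1", "C2")
  expect_length(nm, 15)
  expect_false(any(c("m_F", "t_0F", "A_lipo", "A_Cl") %in% nm))
  # freeing the exponents adds them back
  nm_free <- ffamm:::free_param_names("MOD1", "C1",
                                      fixed = list(m_F = 300, t_0F = 60))
  expect_true(all(c("A_lipo", "A_Cl") %in% nm_free))
  expect_length(ffamm:::free_param_names("MOD2", "C3"), 13)
  expect_length(ffamm:::free_param_names("MOD3", "C2"), 11)
})

test_that("objective is zero at truth and scales inversely with sigma2", {
  fix <- fixture("AA-C3")
  subj <- aa_c3_subject()
  o0 <- fit_objective(fix$params, subj, "C3", sigma2 = "unit",
                      ra_glucose = fix$ra_glucose)
  expect_lt(o0, 1e-8)
  # perturbed parameters give a positive objective
  p2 <- fix$params; p2$S_I <- p2$S_I * 2
  o1 <- fit_objective(p2, subj, "C3", sigma2 = "unit",
                      ra_glucose = fix$ra_glucose)
  expect_gt(o1, 1)
  s2 <- list(FSIGT = c(glucose = 2, ffa = 2), MT = c(glucose = 2, ffa = 2))
  o2 <- fit_objective(p2, subj, "C3", sigma2 = s2,
                      ra_glucose = fix$ra_glucose)
  expect_equal(o2, o1 / 2, tolerance = 1e-10)
})

test_that("default bounds follow the five-times-the-mean convention", {
  b <- default_bounds("MOD1", "C1", group = "AA")
  expect_equal(unname(b$upper["S_I"]), 5 * 4.1e-4)
  # magnitude parameters are bounded below by exactly zero
  expect_equal(unname(b$lower[c("S_G", "S_I", "l_0", "l_2", "I_bx")]),
               rep(0, 5))
  # scale parameters carry a small positive guard
  expect_gt(b$lower[["X_2"]], 0)
  b3 <- default_bounds("MOD3", "C1", group = "white")
  expect_lte(b3$upper[["t_DelayLip"]], 180)
  expect_error(default_bounds("MOD1", "C9"), "unknown")
})

test_that("fitting an exact-start subject is idempotent", {
  fix <- fixture("WH-C4")
  subj <- wh_c4_subject()
  cfg <- fit_config(sigma2 = "unit", group = "white",
                    start_values = fix$theta,
                    check_identifiability = FALSE)
  fit1 <- fit_subject(subj, "MOD1", "C4", cfg)
  expect_lt(fit1$objective, 1e-8)
  expect_true(fit1$converged)
  cfg2 <- fit_config(sigma2 = "unit", group = "white",
                     start_values = fit1$theta,
                     check_identifiability = FALSE)
  fit2 <- fit_subject(subj, "MOD1", "C4", cfg2)
  expect_equal(fit2$theta, fit1$theta, tolerance = 1e-6)
  # accepted Levenberg-Marquardt iterations never increase the objective
  # (up to floating noise near the zero-residual floor)
  expect_true(all(diff(fit1$rsstrace) <= 1e-8 * max(fit1$rsstrace[1], 1)))
  # bookkeeping: 21 FSIGT + 13 MT samples for two channels
  expect_equal(fit1$n_data, 68)
  expect_equal(fit1$k_free, 12)
})

test_that("fits are reproducible and respect combination contracts", {
  fix <- fixture("WH-C4")
  subj <- wh_c4_subject()
  cfg <- fit_config(sigma2 = "unit", group = "white",
                    start_values = 1.25 * fix$theta,
                    check_identifiability = FALSE)
  f1 <- fit_subject(subj, "MOD1", "C4", cfg)
  f2 <- fit_subject(subj, "MOD1", "C4", cfg)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$objective, f2$objective)
  # a combination needing both protocols rejects an MT-only subject
  mt_only <- subject_data(mt = subj$MT)
  expect_error(fit_subject(mt_only, "MOD1", "C1"), "requires FSIGT")
})

test_that("MT-only combination fits run on MT-only data", {
  fix <- fixture("AA-C3")
  subj <- aa_c3_subject()
  mt_only <- subject_data(mt = subj$MT, sigma2 = subj$sigma2["MT"])
  cfg <- fit_config(sigma2 = "unit",
                    start_values = 1.2 * fix$theta,
                    check_identifiability = FALSE, maxiter = 200)
  fit <- fit_subject(mt_only, "MOD1", "S2", cfg)
  expect_equal(unique(fit$residuals$protocol), "MT")
  expect_equal(fit$n_data, 26)
  expect_lt(fit$objective, 1)
})
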