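test_that("insulin input interpolates linearly and clamps outside the record", {
  ins <- sampled_series(c(0, 10), c(10, 20))
  expect_equal(insulin_input(0, ins), 10)
  expect_equal(insulin_input(10, ins), 20)
  expect_equal(insulin_input(5, ins), 15)
  # clamping before the first and after the last sample
  expect_equal(insulin_input(-50, ins), 10)
  expect_equal(insulin_input(100, ins), 20)
  # delayed lookup shifts the query time
  expect_equal(insulin_input(12, ins, delay = 7), 15)
  expect_equal(insulin_input(0, ins, delay = 30), 10)
})

test_that("degenerate insulin records are rejected", {
  expect_error(sampled_series(c(0, 0, 10), c(1, 2, 3)), "increasing")
  expect_error(insulin_input(0, sampled_series(5, 12)), "two samples")
  ins <- sampled_series(c(0, 10), c(10, 20))
  expect_error(insulin_input(0, ins, delay = -1), "non-negative")
})

test_that("MOD 1 derivatives satisfy the basal balances", {
  fix <- fixture("AA-C3")
  p <- fix$params
  ins <- constant_insulin(p$I_bx + 20)
  # glucose at target with no action: production balances disposal
  d <- rhs_mod1(0, c(G = p$G_b, X = 0, F = 1), p,
                constant_insulin(p$I_bx))
  expect_equal(unname(d["G"]), 0, tolerance = 1e-12)
  # action steady state X = I - I_bx
  I <- p$I_bx + 20
  d <- rhs_mod1(0, c(G = 100, X = 20, F = 1), p, ins)
  expect_equal(unname(d["X"]), 0, tolerance = 1e-12)
  # FFA steady state at zero action
  Fss <- (p$l_0 + p$l_2) / p$C_f
  d <- rhs_mod1(0, c(G = p$G_b, X = 0, F = Fss), p,
                constant_insulin(p$I_bx))
  expect_equal(unname(d["F"]), 0, tolerance = 1e-12)
})

test_that("MOD 1 fluxes respond monotonically to insulin action", {
  p <- fixture("AA-C3")$params
  ins <- constant_insulin(p$I_bx)
  xs <- c(0, 1, 5, 20, 80, 300)
  dG <- vapply(xs, function(x)
    rhs_mod1(0, c(G = 150, X = x, F = 1), p, ins)[["G"]], numeric(1))
  expect_true(all(diff(dG) <= 0))
  # lipolysis non-increasing, clearance factor within [C_f, 2 C_f]:
  # probe through dF at l_0 = 0 and F = 0 / F = 1 decompositions
  lip <- vapply(xs, function(x)
    rhs_mod1(0, c(G = 150, X = x, F = 0), p, ins)[["F"]], numeric(1))
  expect_true(all(diff(lip) <= 0))
  clr <- vapply(xs, function(x)
    lip[match(x, xs)] -
      rhs_mod1(0, c(G = 150, X = x, F = 1), p, ins)[["F"]], numeric(1))
  expect_true(all(diff(clr) >= 0))
  expect_true(all(clr >= p$C_f - 1e-12 & clr <= 2 * p$C_f + 1e-12))
})

test_that("MOD 2 shares the glucose equation and has constant clearance", {
  p1 <- fixture("AA-C3")$params
  p2 <- mod2_params(S_G = p1$S_G, G_b = p1$G_b, S_I = p1$S_I,
                    C_x = p1$C_x, I_bx = p1$I_bx, l_0 = p1$l_0,
                    l_2 = p1$l_2, X_2 = p1$X_2, A_l = p1$A_lipo,
                    C_f0 = p1$C_f)
  ins <- constant_insulin(30)
  st <- c(G = 180, X = 12, F = 0.8)
  d1 <- rhs_mod1(5, st, p1, ins)
  d2 <- rhs_mod2(5, st, p2, ins)
  expect_equal(d1[["G"]], d2[["G"]], tolerance = 1e-12)
  expect_equal(d1[["X"]], d2[["X"]], tolerance = 1e-12)
  # at X = 0 the clearance terms coincide (hill factor is 1)
  st0 <- c(G = 180, X = 0, F = 0.8)
  expect_equal(rhs_mod1(5, st0, p1, ins)[["F"]],
               rhs_mod2(5, st0, p2, ins)[["F"]], tolerance = 1e-12)
  # saturating action drives lipolysis to l_0
  lip_inf <- rhs_mod2(5, c(G = 1, X = 1e9, F = 0), p2, ins)[["F"]]
  expect_equal(lip_inf, p2$l_0, tolerance = 1e-6)
})

test_that("MOD 3 clearance follows the saturating Hill form", {
  p <- test_mod3()
  # constant insulin equal to K_Rem: insulin-stimulated clearance at
  # half maximum, readable from dF/dt at unit FFA with zero lipolysis
  ins <- constant_insulin(p$K_Rem)
  d <- rhs_mod3(100, c(F = 1), p, ins)
  lip <- p$V_m_Lip / (1 + (p$K_Rem / p$K_Lip)^p$h_lip)
  expect_equal(unname(d), lip - (p$k_Rem + p$V_m_Rem / 2),
               tolerance = 1e-12)
  # saturating insulin: lipolysis off, clearance at k_Rem + V_m_Rem
  dinf <- rhs_mod3(100, c(F = 1), p, constant_insulin(1e9))
  expect_equal(unname(dinf), -(p$k_Rem + p$V_m_Rem), tolerance = 1e-6)
  # zero insulin: steady state at V_m_Lip / k_Rem
  Fss <- p$V_m_Lip / p$k_Rem
  d0 <- rhs_mod3(100, c(F = Fss), p, constant_insulin(0))
  expect_equal(unname(d0), 0, tolerance = 1e-12)
})

test_that("steady states zero the right-hand sides under basal input", {
  fix <- fixture("AA-C3")
  ss1 <- steady_state(fix$params)
  expect_equal(unname(ss1),
               c(fix$params$G_b, 0,
                 (fix$params$l_0 + fix$params$l_2) / fix$params$C_f))
  d <- rhs_mod1(0, ss1, fix$params, constant_insulin(fix$params$I_bx))
  expect_lt(max(abs(d)), 1e-12)

  p2 <- test_mod2()
  ss2 <- steady_state(p2)
  expect_equal(unname(ss2["F"]), (p2$l_0 + p2$l_2) / p2$C_f0)
  d2 <- rhs_mod2(0, ss2, p2, constant_insulin(p2$I_bx))
  expect_lt(max(abs(d2)), 1e-12)

  p3 <- test_mod3()
  basal <- 5
  ss3 <- steady_state(p3, insulin_basal = basal)
  d3 <- rhs_mod3(0, ss3, p3, constant_insulin(basal))
  expect_lt(max(abs(d3)), 1e-12)
})

test_that("parameter validation rejects inconsistent sets", {
  expect_error(mod1_params(S_G = -0.01, G_b = 140, S_I = 3e-4,
                           C_x = 0.1, I_bx = 5, l_0 = 0.006,
                           l_2 = 0.12, X_2 = 12, C_f = 0.05,
                           K_Cl = 20), "non-negative")
  expect_error(mod1_params(S_G = 0.01, G_b = 140, S_I = 3e-4,
                           C_x = 0.1, I_bx = 5, l_0 = 0.006,
                           l_2 = 0.12, X_2 = 0, C_f = 0.05,
                           K_Cl = 20), "X_2")
  expect_error(mod3_params(V_m_Lip = 1, t_DelayLip = 10, K_Lip = 0,
                           h_lip = 2, k_Rem = 0.2, V_m_Rem = 0.2,
                           t_DelayRem = 10, K_Rem = 40, h_Rem = 5),
               "K_Lip")
  expect_error(steady_state(mod1_params(S_G = 0.01, G_b = 140,
                                        S_I = 3e-4, C_x = 0.1,
                                        I_bx = 5, l_0 = 0.006,
                                        l_2 = 0, X_2 = 12, C_f = 0,
                                        K_Cl = 20)), "C_f")
})
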