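# shared helpers for the test suite

# constant insulin record spanning both protocol windows
constant_insulin <- function(level, from = -10, to = 400) {
  sampled_series(c(from, to), c(level, level))
}

# small, well-behaved MOD 2 / MOD 3 parameter sets for unit tests
test_mod2 <- function() {
  mod2_params(S_G = 0.012, G_b = 140, S_I = 5e-4, C_x = 0.05,
              I_bx = 5, l_0 = 0.004, l_2 = 0.15, X_2 = 13,
              A_l = 2.4, C_f0 = 0.18)
}

test_mod3 <- function() {
  mod3_params(V_m_Lip = 2.0, t_DelayLip = 25, K_Lip = 10.4,
              h_lip = 2, k_Rem = 0.16, V_m_Rem = 0.25,
              t_DelayRem = 12.6, K_Rem = 38.4, h_Rem = 6.38)
}

# noiseless synthetic subjects are deterministic; build once per run
aa_c3_subject <- local({
  subj <- NULL
  function() {
    if (is.null(subj)) subj <<- synth_subject("AA-C3")
    subj
  }
})

wh_c4_subject <- local({
  subj <- NULL
  function() {
    if (is.null(subj)) subj <<- synth_subject("WH-C4")
    subj
  }
})
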