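boltz <- function(v, vh, k) 1 / (1 + exp(-(v - vh) / k))

test_that("a variant identical to its reference has ratio exactly 1", {
  v <- seq(200, -40, by = -10)
  model <- 2 * boltz(v, 120, 15) * v / 100
  iv_ref <- manual_iv(v, cbind(model, model * 1.3, model * 0.8),
                      batch = c(1, 1, 2), construct = "REF")
  iv_var <- manual_iv(v, cbind(model * 1.1, model * 0.9, model),
                      batch = c(1, 1, 2), construct = "VAR")
  # same batch means on both sides: build variant from the reference cells
  rc <- normalize_to_reference(iv_ref, iv_ref)
  expect_equal(rc$mean[!rc$masked], rep(1, sum(!rc$masked)))
  expect_true(all(rc$masked[v == 0])) # zero reference current is masked

  # homogeneity: half the current everywhere gives a flat 0.5
  iv_half <- manual_iv(v, iv_ref$values * 0.5, batch = iv_ref$cells$batch,
                       construct = "HALF")
  rc5 <- normalize_to_reference(iv_half, iv_ref)
  expect_equal(rc5$mean[!rc5$masked], rep(0.5, sum(!rc5$masked)))
})

test_that("shifted-Boltzmann ratios match the closed form and classify as a shift", {
  v <- seq(200, -40, by = -10)
  ref <- boltz(v, 120, 40) * v
  var <- boltz(v, 160, 40) * v
  iv_ref <- manual_iv(v, cbind(ref, ref), batch = c(1, 2), construct = "REF")
  iv_var <- manual_iv(v, cbind(var, var), batch = c(1, 2), construct = "VAR")
  rc <- normalize_to_reference(iv_var, iv_ref)

  # independent oracle: direct evaluation of the Boltzmann ratio
  expect_equal(rc$mean[v == 60], boltz(60, 160, 40) / boltz(60, 120, 40),
               tolerance = 1e-12)
  expect_equal(rc$mean[v == 60], 0.4158, tolerance = 1e-3)
  expect_equal(rc$mean[v == 200], boltz(200, 160, 40) / boltz(200, 120, 40),
               tolerance = 1e-12)
  expect_equal(rc$mean[v == 200], 0.830, tolerance = 1e-3)

  # the analytic derivative of this ratio is positive, so the call is a
  # depolarizing shift
  expect_equal(classify_ratio(rc)$label, "positive_shift")
})

test_that("noise-free pooled ratios equal elementwise model division", {
  gate <- test_gate()
  lib <- variant_library()
  v <- seq(200, 10, by = -10)
  m_ref <- model_iv(gate, wt_pop(), lib$WT, v)
  m_var <- model_iv(gate, wt_pop(), lib$G545S, v)
  iv_ref <- manual_iv(v, cbind(m_ref, 2 * m_ref), batch = 1:2, construct = "R")
  iv_var <- manual_iv(v, cbind(3 * m_var, 0.5 * m_var), batch = 1:2,
                      construct = "V")
  rc <- normalize_to_reference(iv_var, iv_ref)
  keep <- !rc$masked
  expect_equal(rc$ratio[keep, 1], 3 * (m_var / m_ref)[keep], tolerance = 1e-13)
  expect_equal(rc$ratio[keep, 2], 0.25 * (m_var / m_ref)[keep], tolerance = 1e-13)
})

test_that("normalization is invariant to global current scaling", {
  lib <- variant_library()
  spec <- session_spec(constructs = list(construct_spec("REF", "WT"),
                                         construct_spec("VAR", "G545S")),
                       n_batches = 3, cells_per_batch = c(6, 8), seed = 5)
  ivs <- simulate_iv_study(spec, test_gate(), lib)
  rc1 <- normalize_to_reference(ivs$VAR, ivs$REF)
  for (c_scale in c(0.2, 7)) {
    iv_v <- ivs$VAR
    iv_r <- ivs$REF
    iv_v$values <- iv_v$values * c_scale
    iv_r$values <- iv_r$values * c_scale
    iv_v$se_ss <- iv_v$se_ss * c_scale
    iv_r$se_ss <- iv_r$se_ss * c_scale
    rc2 <- normalize_to_reference(iv_v, iv_r)
    expect_equal(rc2$mean, rc1$mean, tolerance = 1e-12)
    expect_equal(rc2$masked, rc1$masked)
  }
})

test_that("batch pairing is by identifier, never by order", {
  v <- seq(200, 100, by = -20)
  m <- boltz(v, 120, 15) * v
  iv_ref <- manual_iv(v, cbind(m, 2 * m), batch = c(1, 2), construct = "R")
  iv_var <- manual_iv(v, cbind(4 * m, 0.5 * m), batch = c(2, 1), construct = "V")
  rc <- normalize_to_reference(iv_var, iv_ref)
  # batch 1: 0.5m / m = 0.5; batch 2: 4m / 2m = 2 -- mean 1.25 at all voltages
  expect_equal(rc$mean, rep(1.25, length(v)))

  iv_far <- manual_iv(v, cbind(m), batch = 9, construct = "V")
  expect_error(normalize_to_reference(iv_far, iv_ref), "no common batches")
})

test_that("degenerate ratio curves are rejected with clear errors", {
  v <- seq(200, 140, by = -20)
  tiny <- rep(1e-12, length(v))
  iv_ref <- manual_iv(v, cbind(tiny, tiny), batch = 1:2, construct = "R",
                      se_ss = 1)
  iv_var <- manual_iv(v, cbind(tiny, tiny), batch = 1:2, construct = "V")
  expect_error(normalize_to_reference(iv_var, iv_ref), "masked")

  m <- boltz(v, 120, 15) * v
  iv_ref2 <- manual_iv(v, cbind(m, m), batch = 1:2, construct = "R")
  rc <- normalize_to_reference(iv_ref2, iv_ref2)
  rc$masked[1] <- TRUE # only 3 unmasked left
  expect_error(classify_ratio(rc), "fewer than 4")
})

test_that("flat ratio levels map to wild-type-like and uniform-reduction calls", {
  v <- seq(200, 80, by = -10)
  m <- boltz(v, 120, 15) * v
  iv_ref <- manual_iv(v, cbind(m, 1.5 * m, 0.7 * m), batch = 1:3,
                      construct = "R")
  rc1 <- normalize_to_reference(iv_ref, iv_ref)
  call1 <- classify_ratio(rc1)
  expect_equal(call1$label, "wt_like")
  expect_equal(call1$mean_ratio, 1)

  iv_half <- manual_iv(v, iv_ref$values * 0.5, batch = 1:3, construct = "H")
  call2 <- classify_ratio(normalize_to_reference(iv_half, iv_ref))
  expect_equal(call2$label, "uniform_reduction")

  iv_tenth <- manual_iv(v, iv_ref$values * 0.1, batch = 1:3, construct = "T")
  call3 <- classify_ratio(normalize_to_reference(iv_tenth, iv_ref))
  expect_equal(call3$label, "below_reference_control")
  expect_true(length(call3$trace) >= 1)
})

test_that("batch-mean division and per-cell averaging agree on balanced data", {
  v <- seq(200, 100, by = -20)
  m <- boltz(v, 120, 15) * v
  iv_ref <- manual_iv(v, cbind(m, m), batch = c(1, 1), construct = "R")
  iv_var <- manual_iv(v, cbind(0.4 * m, 0.8 * m), batch = c(1, 1),
                      construct = "V")
  rc_a <- normalize_to_reference(iv_var, iv_ref)
  rc_b <- normalize_to_reference(iv_var, iv_ref, per_cell_ratio = TRUE)
  expect_equal(rc_a$mean, rc_b$mean, tolerance = 1e-12)
})
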