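test_that("protocol validation enforces ladder divisibility and P/N scale", {
  expect_error(voltage_protocol(step_start_mV = 200, step_end_mV = -45),
               "divisible")
  expect_error(voltage_protocol(pn_scale = 0), "pn_scale")
  expect_error(voltage_protocol(pn_scale = 1), "pn_scale")
  expect_equal(protocol_voltages(voltage_protocol())[c(1, 25)], c(200, -40))
})

test_that("steady state averages the last third of the step segment", {
  # 6-sample step: last third is the final 2 samples
  proto <- voltage_protocol(step_duration_ms = 6, pre_ms = 0, post_ms = 0,
                            sampling_hz = 1000, step_start_mV = 100,
                            step_end_mV = 100)
  ss <- clchet:::new_sweep_set(
    time = (0:5) / 1000, current = matrix(1:6, ncol = 1), protocol = proto,
    meta = list(units = "uA"), corrected = TRUE
  )
  expect_equal(as.numeric(steady_state(ss)), 5.5)

  # identity on a constant segment, homogeneity under scaling
  ss$current <- matrix(rep(3.2, 6), ncol = 1)
  expect_equal(as.numeric(steady_state(ss)), 3.2)
  ss2 <- ss
  ss2$current <- ss$current * -7.5
  expect_equal(as.numeric(steady_state(ss2)), as.numeric(steady_state(ss)) * -7.5)
})

test_that("steady state reaches an exponentially settled plateau within 0.1%", {
  proto <- voltage_protocol(pre_ms = 0, post_ms = 0, sampling_hz = 20000,
                            step_start_mV = 100, step_end_mV = 100)
  t <- (0:(protocol_segments(proto)$n_step - 1)) / proto$sampling_hz
  tau <- proto$step_duration_ms * 1e-3 / 10 # tau = segment/10 << window
  plateau <- 2.5
  ss <- clchet:::new_sweep_set(
    time = t, current = matrix(plateau * (1 - exp(-t / tau)), ncol = 1),
    protocol = proto, meta = list(units = "uA"), corrected = TRUE
  )
  expect_equal(as.numeric(steady_state(ss)), plateau, tolerance = 1e-3)
})

test_that("steady state refuses raw sweeps and too-short segments", {
  proto <- voltage_protocol(step_duration_ms = 0.1, pre_ms = 0, post_ms = 0,
                            sampling_hz = 10000, step_start_mV = 100,
                            step_end_mV = 100)
  ss <- clchet:::new_sweep_set((0:0) / 1, matrix(1, 1, 1), proto,
                               list(units = "uA"), corrected = TRUE)
  expect_error(steady_state(ss), "fewer than 3")
  expect_error(steady_state(clchet:::new_sweep_set(
    (0:5) / 1000, matrix(1:6, ncol = 1),
    voltage_protocol(step_duration_ms = 6, pre_ms = 0, post_ms = 0,
                     sampling_hz = 1000, step_start_mV = 100,
                     step_end_mV = 100),
    list(units = "uA"), corrected = FALSE
  )), "not P/N-corrected")
})

test_that("P/N subtraction removes linear components exactly", {
  proto <- quick_protocol()
  # leak-only cell: corrected trace vanishes
  ses <- simulate_session(clean_spec(list(construct_spec("dead", "R360S",
                                                         expr_ratio = 0))),
                          test_gate(), variant_library(), protocol = proto)
  cell <- ses$cells[[1]]
  corr <- pn_subtract(cell$raw, cell$pn)
  expect_lt(max(abs(corr$current)) / max(abs(cell$raw$current)), 1e-9)
  expect_true(corr$corrected)

  # transport + leak + capacitive: corrected steady state equals the model
  ses <- simulate_session(clean_spec(), test_gate(), variant_library(),
                          protocol = proto)
  cell <- ses$cells[[1]]
  ssv <- steady_state(pn_subtract(cell$raw, cell$pn))
  model <- model_iv(test_gate(), wt_pop(), variant_library()$WT,
                    protocol_voltages(proto)) * cell$expr_factor
  expect_equal(as.numeric(ssv), model, tolerance = 1e-9)
})

test_that("P/N subtraction applies the documented formula and validates inputs", {
  proto <- quick_protocol()
  ses <- simulate_session(clean_spec(), test_gate(), variant_library(),
                          protocol = proto)
  cell <- ses$cells[[1]]
  corr <- pn_subtract(cell$raw, cell$pn)
  # the contract is corrected = raw - pn / pn_scale, no more, no less: a P/N
  # family with a wrongly declared scale biases the result by a known factor
  expect_equal(corr$current,
               cell$raw$current - cell$pn$current / proto$pn_scale)
  wrong <- cell$pn
  wrong$protocol$pn_scale <- 0.5
  corr2 <- pn_subtract(cell$raw, wrong)
  expect_equal(corr2$current, cell$raw$current - cell$pn$current / 0.5)

  short <- cell$pn
  short$current <- short$current[, -1]
  expect_error(pn_subtract(cell$raw, short), "mismatched")
  slow <- cell$pn
  slow$protocol$sampling_hz <- 1000
  expect_error(pn_subtract(cell$raw, slow), "sampling rates")
})

test_that("re-subtracting a null P/N family changes corrected data by nothing", {
  proto <- quick_protocol()
  ses <- simulate_session(clean_spec(leak_mean = 1e-12), test_gate(),
                          variant_library(), protocol = proto)
  cell <- ses$cells[[1]]
  corr <- pn_subtract(cell$raw, cell$pn)
  null_pn <- cell$pn
  null_pn$current[] <- 0
  expect_equal(pn_subtract(corr, null_pn)$current, corr$current)
})

test_that("group IV construction stacks cells and is order-invariant", {
  proto <- quick_protocol()
  ses <- simulate_session(clean_spec(), test_gate(), variant_library(),
                          protocol = proto)
  cells <- lapply(ses$cells, function(cc) pn_subtract(cc$raw, cc$pn))

  one <- build_iv(cells[1])
  expect_equal(one$n, 1)
  expect_equal(one$sd, rep(0, length(one$voltages)))
  expect_equal(one$mean, as.numeric(steady_state(cells[[1]])))

  two <- build_iv(cells[c(1, 1)])
  expect_equal(two$n, 2)
  expect_equal(two$sd, rep(0, length(two$voltages)))

  all3 <- build_iv(cells)
  perm <- build_iv(cells[c(3, 1, 2)])
  expect_equal(all3$mean, perm$mean)

  # simulator round trip: noise-free IV equals model x expression factors
  model <- model_iv(test_gate(), wt_pop(), variant_library()$WT,
                    protocol_voltages(proto))
  expr_f <- vapply(ses$cells, `[[`, numeric(1), "expr_factor")
  expect_equal(unname(all3$values), outer(model, unname(expr_f)),
               tolerance = 1e-9)

  mixed <- cells
  mixed[[2]]$meta$construct <- "other"
  expect_error(build_iv(mixed), "mix constructs")
})

test_that("current density divides by per-cell capacitance in patch mode", {
  iv <- manual_iv(c(100, 50), cbind(c(100, 50), c(200, 100)), units = "pA")
  cd <- current_density(iv, c(10, 20))
  expect_equal(unname(cd$values), cbind(c(10, 5), c(10, 5)))
  expect_equal(cd$units, "pA/pF")
  expect_error(current_density(iv, c(10, 0)), "positive")
  expect_error(current_density(iv, 10), "one capacitance per cell")
  oo <- manual_iv(c(100, 50), cbind(c(1, 2)), units = "uA")
  expect_error(current_density(oo, 10), "pA")
})

test_that("sweep and IV CSV round trips preserve data and metadata", {
  proto <- quick_protocol()
  ses <- simulate_session(clean_spec(), test_gate(), variant_library(),
                          protocol = proto)
  cell <- ses$cells[[1]]
  path <- file.path(tempdir(), "sweep_rt.csv")
  write_sweep_csv(cell$raw, path)
  back <- read_sweep_csv(path)
  expect_equal(unname(back$current), unname(cell$raw$current), tolerance = 1e-12)
  expect_equal(back$meta$construct, cell$raw$meta$construct)
  expect_equal(back$protocol$sampling_hz, proto$sampling_hz)
  expect_false(back$is_pn)

  iv <- build_iv(lapply(ses$cells, function(cc) pn_subtract(cc$raw, cc$pn)))
  ipath <- file.path(tempdir(), "iv_rt.csv")
  write_iv_csv(iv, ipath)
  iback <- read_iv_csv(ipath)
  expect_equal(iback$values, iv$values, tolerance = 1e-12)
  expect_equal(iback$cells$batch, iv$cells$batch)
  expect_equal(iback$construct, iv$construct)
})

test_that("a session directory processes end-to-end through the manifest", {
  dir <- file.path(tempdir(), "ses_e2e")
  unlink(dir, recursive = TRUE)
  proto <- quick_protocol()
  simulate_session(clean_spec(), test_gate(), variant_library(),
                   protocol = proto, out_dir = dir)
  ivs <- process_session(file.path(dir, "manifest.json"))
  expect_named(ivs, "C3_C4.WT")
  model <- model_iv(test_gate(), wt_pop(), variant_library()$WT,
                    protocol_voltages(proto))
  expect_equal(ivs[[1]]$mean, model, tolerance = 1e-6)

  # a missing P/N companion is a hard error
  file.remove(list.files(dir, pattern = "_pn\\.csv$", full.names = TRUE)[1])
  expect_error(process_session(file.path(dir, "manifest.json")), "P/N")
})
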