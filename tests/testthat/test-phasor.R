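test_that("limiting decays map to the canonical phasor points", {
  # all photons in the first bin (zero-lifetime limit) -> (1, 0)
  n_bins <- 4096
  counts <- array(0, c(1, 1, n_bins))
  counts[1, 1, 1] <- 1000
  st <- clchet:::new_decay_stack(counts, 80)
  ps <- phasor_transform(st, photon_floor = 0)
  expect_equal(unname(ps$pooled["G"]), 1, tolerance = 1e-6)
  expect_equal(unname(ps$pooled["S"]), 0, tolerance = 1e-3)

  # uniform decay over the full period -> (0, 0)
  st2 <- clchet:::new_decay_stack(array(1, c(1, 1, n_bins)), 80)
  ps2 <- phasor_transform(st2, photon_floor = 0)
  expect_equal(unname(ps2$pooled), c(0, 0), tolerance = 1e-9)
})

test_that("noise-free monoexponentials match the analytic phasor", {
  for (tau in c(0.5, 1, 2.22, 2.5, 5)) {
    ps <- phasor_transform(mono_stack(tau), photon_floor = 0)
    cf <- phasor_closed_form(tau)
    expect_lt(abs(ps$pooled[["G"]] - cf[["G"]]), 1e-6)
    expect_lt(abs(ps$pooled[["S"]] - cf[["S"]]), 1e-6)
    # and the estimated lifetime inverts the transform
    expect_lt(abs(lifetime_from_phasor(ps) / tau - 1), 1e-5)
  }
})

test_that("monoexponential phasors lie on the universal semicircle", {
  for (tau in c(0.3, 0.9, 1.7, 3.1, 6.4, 10)) {
    cf <- phasor_closed_form(tau)
    expect_equal((cf[["G"]] - 0.5)^2 + cf[["S"]]^2, 0.25, tolerance = 1e-12)
    ps <- phasor_transform(mono_stack(tau, n_bins = 1024), photon_floor = 0)
    expect_lt(abs((ps$pooled[["G"]] - 0.5)^2 + ps$pooled[["S"]]^2 - 0.25),
              1e-4)
  }
})

test_that("lifetime recovery from phasor coordinates is exact", {
  # at w*tau = 1 the phasor sits at (0.5, 0.5) and tau = 1/(2 pi f)
  f <- 0.08 # cycles/ns
  expect_equal(lifetime_from_phasor(c(0.5, 0.5), 80), 1 / (2 * pi * f),
               tolerance = 1e-12)
  expect_equal(lifetime_from_phasor(c(0.5, 0.5), 80), 1.98944,
               tolerance = 1e-5)

  # analytic semicircle coordinates invert to the generating lifetime
  cf <- phasor_closed_form(2.5)
  expect_equal(lifetime_from_phasor(unname(cf), 80), 2.5, tolerance = 1e-9)

  expect_equal(lifetime_from_phasor(c(1, 0), 80), 0)
  expect_error(lifetime_from_phasor(c(0, 0.5), 80), "G <= 0")
})

test_that("pixels below the photon floor are dropped, not propagated", {
  counts <- array(0, c(2, 1, 256))
  counts[1, 1, ] <- 50 * decay_profile(2, 80, 256)
  # pixel 2 stays all-zero
  st <- clchet:::new_decay_stack(counts, 80)
  ps <- phasor_transform(st, photon_floor = 20)
  expect_equal(nrow(ps$pixels), 1)
  expect_false(anyNA(ps$pixels$G))
  expect_error(phasor_transform(st, roi = matrix(FALSE, 2, 1)), "empty ROI")
  expect_error(phasor_transform(st, roi = "nope"), "unknown ROI")
})

test_that("cluster fitting finds the predominant mode", {
  # all points identical: centroid is that point
  pts <- data.frame(G = rep(0.37, 60), S = rep(0.41, 60), photons = 100)
  cl <- cluster_fit(pts)
  expect_equal(unname(cl$centroid), c(0.37, 0.41), tolerance = 1e-9)

  # a single Gaussian cloud is located within 0.002
  set.seed(2)
  n <- 4000
  pts2 <- data.frame(G = rnorm(n, 0.445, 0.01), S = rnorm(n, 0.497, 0.01),
                     photons = 100)
  cl2 <- cluster_fit(pts2)
  expect_lt(abs(cl2$centroid[["G"]] - 0.445), 0.002)
  expect_lt(abs(cl2$centroid[["S"]] - 0.497), 0.002)

  # 70/30 mixture of separated clouds: the majority cloud wins
  set.seed(3)
  pts3 <- data.frame(
    G = c(rnorm(1400, 0.3, 0.01), rnorm(600, 0.7, 0.01)),
    S = c(rnorm(1400, 0.45, 0.01), rnorm(600, 0.45, 0.01)),
    photons = 100
  )
  cl3 <- cluster_fit(pts3)
  expect_lt(abs(cl3$centroid[["G"]] - 0.3), 0.01)

  expect_error(cluster_fit(pts[1:10, ]), "at least 50")
})

test_that("per-pixel lifetimes are unbiased at realistic photon budgets", {
  # Poisson decays at 1e4 photons/pixel: mean lifetime over >= 1e3 pixels
  # within 1% of truth
  tau <- 2.3
  spec <- flim_spec(image_shape = c(32, 32), n_bins = 256,
                    tau_map = c(a = tau), photons_per_pixel = 1e4, seed = 17)
  st <- simulate_flim(spec)
  ps <- phasor_transform(st)
  taus <- (ps$pixels$S / ps$pixels$G) / (2 * pi * 0.08)
  expect_gte(length(taus), 1000)
  expect_equal(mean(taus), tau, tolerance = 0.01)
})

test_that("FRET efficiency follows the donor-quenching definition", {
  expect_equal(fret_efficiency(2.5, 2.5)$efficiency, 0)
  expect_equal(fret_efficiency(2.5, 1.25)$efficiency, 0.5)
  # arithmetic on the reported donor/acceptor lifetimes
  e <- fret_efficiency(2.22, 1.89)
  expect_equal(e$efficiency, 1 - 1.89 / 2.22, tolerance = 1e-12)
  expect_equal(e$efficiency, 0.1486, tolerance = 1e-3)
  expect_false(e$flagged)

  lengthened <- fret_efficiency(2.0, 2.2)
  expect_true(lengthened$flagged)
  expect_lt(lengthened$efficiency, 0)
  expect_error(fret_efficiency(0, 1), "positive")
})

test_that("the full FLIM pipeline recovers a generating FRET efficiency", {
  tau_d <- 2.5
  e_true <- 0.15
  spec <- flim_spec(
    image_shape = c(24, 24), n_bins = 256,
    tau_map = c(donor_only = tau_d, donor_acceptor = tau_d * (1 - e_true)),
    photons_per_pixel = 1e4, seed = 29
  )
  st <- simulate_flim(spec)
  tau_hat <- vapply(c("donor_only", "donor_acceptor"), function(roi) {
    lifetime_from_phasor(cluster_fit(phasor_transform(st, roi = roi)),
                         spec$rep_rate_mhz)
  }, numeric(1))
  res <- fret_efficiency(tau_hat[["donor_only"]], tau_hat[["donor_acceptor"]])
  expect_equal(res$efficiency, e_true, tolerance = 0.02)
})
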