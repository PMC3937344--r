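# Bell-bond construction, the competing-hazards probability, and the
# kinetic Monte Carlo, checked against independent closed-form and
# trapezoid-quadrature oracles.

test_that("bond constructors validate their physical parameters", {
  expect_error(bell_bond(0, 10), "k0")
  expect_error(bell_bond(1e-3, -1), "f_beta")
  expect_error(duplex_spec(0), "n_bp")
  expect_error(duplex_spec(20, "hairpin"), "zipper|arg")
  expect_error(ramp_protocol(0), "loading_rate")
  expect_error(ramp_protocol(100, f_max = -5), "f_max")
  b <- bell_bond(1e-3, 10)
  expect_true(all(diff(bond_hazard(b, 0:50)) > 0))  # hazard increasing in F
})

test_that("per-bp rule maps duplex length monotonically onto Bell bonds", {
  b20 <- bond_from_duplex(duplex_spec(20))
  b40 <- bond_from_duplex(duplex_spec(40))
  expect_lt(b40$k0, b20$k0)
  expect_gte(b40$f_beta, b20$f_beta)
  # documented rule applied by hand
  p <- default_per_bp_params()
  expect_equal(b20$k0, p$k0_1 * exp(-p$dg_per_bp * 20))
  expect_equal(b20$f_beta, p$f_beta_1)
  # base case and error paths
  b1 <- bond_from_duplex(duplex_spec(1))
  expect_equal(b1$k0, p$k0_1 * exp(-p$dg_per_bp))
  expect_error(bond_from_duplex(duplex_spec(20, "zipper")),
               "unsupported geometry")
})

test_that("identical competing bonds rupture the reference exactly half the time", {
  b <- bell_bond(1e-4, 10)
  expect_equal(reference_rupture_probability(b, b, ramp_protocol(100)), 0.5,
               tolerance = 1e-6)
})

test_that("a vastly weaker reference almost always ruptures first", {
  s <- bell_bond(1e-5, 10)
  r <- bell_bond(1e-2, 10)  # 1000x the off-rate
  expect_gt(reference_rupture_probability(s, r, ramp_protocol(100)), 0.99)
})

test_that("quadrature matches an independent trapezoid oracle and the equal-f_beta closed form", {
  s <- bell_bond(1e-4, 10)
  r <- bell_bond(1e-3, 10)
  ramp <- ramp_protocol(100)
  p <- reference_rupture_probability(s, r, ramp)
  # closed form: with equal force scales the hazard ratio is constant,
  # so P(ref first) = k0_ref / (k0_ref + k0_sample)
  expect_equal(p, 1e-3 / (1e-3 + 1e-4), tolerance = 1e-6)
  expect_equal(p, trapezoid_ref_probability(1e-4, 10, 1e-3, 10, 100, 130),
               tolerance = 1e-4)
  # unequal force scales: trapezoid oracle only
  s2 <- bell_bond(5e-3, 7)
  r2 <- bell_bond(2e-3, 14)
  p2 <- reference_rupture_probability(s2, r2, ramp)
  expect_equal(p2, trapezoid_ref_probability(5e-3, 7, 2e-3, 14, 100, 120),
               tolerance = 1e-4)
})

test_that("rupture probability is symmetric, normalized, and monotone", {
  ramp <- ramp_protocol(100)
  set.seed(42)
  for (i in 1:5) {
    s <- bell_bond(10^stats::runif(1, -4, -1), stats::runif(1, 5, 20))
    r <- bell_bond(10^stats::runif(1, -4, -1), stats::runif(1, 5, 20))
    p_sr <- reference_rupture_probability(s, r, ramp)
    p_rs <- reference_rupture_probability(r, s, ramp)
    expect_gte(p_sr, 0); expect_lte(p_sr, 1)
    expect_equal(p_sr + p_rs, 1, tolerance = 1e-6)  # outcomes exhaust
  }
  # a longer (stronger) reference ruptures less often; a weaker sample
  # bond (larger k0) pre-empts the reference, also lowering P(ref first)
  s <- bell_bond(2e-3, 10)
  p_len <- vapply(c(10, 20, 30, 40), function(n)
    reference_rupture_probability(s, bond_from_duplex(duplex_spec(n)), ramp),
    numeric(1))
  expect_true(all(diff(p_len) < 0))
  r <- bond_from_duplex(duplex_spec(20))
  p_k0 <- vapply(c(1e-4, 1e-3, 1e-2), function(k)
    reference_rupture_probability(bell_bond(k, 10), r, ramp), numeric(1))
  expect_true(all(diff(p_k0) < 0))
  # closed form confirms the direction: P = k0_ref / (k0_ref + k0_sample)
  expect_equal(p_k0, r$k0 / (r$k0 + c(1e-4, 1e-3, 1e-2)), tolerance = 1e-6)
})

test_that("a force cap removes probability mass from both outcomes", {
  s <- bell_bond(1e-4, 10)
  r <- bell_bond(1e-3, 10)
  p_capped <- reference_rupture_probability(s, r, ramp_protocol(100, f_max = 30))
  p_open <- reference_rupture_probability(s, r, ramp_protocol(100))
  expect_lt(p_capped, p_open)
  out <- simulate_rupture(s, r, ramp_protocol(100, f_max = 30), 5000, seed = 3)
  survived <- !out$reference_ruptured & !out$sample_ruptured
  expect_gt(sum(survived), 0)
  expect_true(all(is.na(out$rupture_force_pN[survived])))
  expect_true(all(out$rupture_force_pN[!survived] <= 30))
})

test_that("kinetic Monte Carlo is reproducible and converges to the analytic probability", {
  b <- bell_bond(1e-4, 10)
  ramp <- ramp_protocol(100)
  expect_identical(nrow(simulate_rupture(b, b, ramp, 0, seed = 1)), 0L)
  expect_error(simulate_rupture(b, b, ramp, -1, seed = 1), "invalid input")
  out1 <- simulate_rupture(b, b, ramp, 2000, seed = 9)
  out2 <- simulate_rupture(b, b, ramp, 2000, seed = 9)
  expect_identical(out1, out2)
  # symmetry: reference fraction near 1/2
  big <- simulate_rupture(b, b, ramp, 1e5, seed = 1)
  expect_true(all(big$reference_ruptured + big$sample_ruptured == 1))
  expect_lt(abs(mean(big$reference_ruptured) - 0.5), 3 * sqrt(0.25 / 1e5))
  # asymmetric pair against the analytic value
  s <- bell_bond(1e-4, 10); r <- bell_bond(1e-3, 10)
  p <- reference_rupture_probability(s, r, ramp)
  sim <- simulate_rupture(s, r, ramp, 2e5, seed = 2)
  se <- sqrt(p * (1 - p) / 2e5)
  expect_lt(abs(mean(sim$reference_ruptured) - p), 3 * se)
})

test_that("empirical fractions track the quadrature over randomized parameter sets", {
  ramp <- ramp_protocol(100)
  set.seed(7)
  n <- 2e4
  for (i in 1:6) {
    s <- bell_bond(10^stats::runif(1, -4, -1), stats::runif(1, 5, 20))
    r <- bell_bond(10^stats::runif(1, -4, -1), stats::runif(1, 5, 20))
    p <- reference_rupture_probability(s, r, ramp)
    sim <- simulate_rupture(s, r, ramp, n, seed = 100 + i)
    se <- sqrt(max(p * (1 - p), 1e-6) / n)
    expect_lt(abs(mean(sim$reference_ruptured) - p), 4 * se)
  }
})

test_that("sample-bond calibration inverts the competition model", {
  targets <- data.frame(reference_n_bp = c(20, 40), nf_mean = c(0.5, 0.25))
  cal <- calibrate_sample_bond(targets)
  expect_lt(cal$rmse, 1e-4)
  expect_equal(cal$achieved, targets$nf_mean, tolerance = 1e-3)
  # the packaged default sample bonds hit the default condition table
  cfg <- default_config()
  bonds <- lapply(cfg$rupture$sample_bonds, function(b)
    bell_bond(b$k0, b$f_beta))
  ramp <- ramp_protocol(cfg$rupture$loading_rate)
  probe <- function(bond, n) reference_rupture_probability(
    bond, bond_from_duplex(duplex_spec(n), cfg$rupture$per_bp), ramp)
  expect_equal(probe(bonds$high, 20), 0.65, tolerance = 1e-3)
  expect_equal(probe(bonds$high, 40), 0.32, tolerance = 1e-3)
  expect_equal(probe(bonds$low, 20), 0.39, tolerance = 1e-3)
  expect_equal(probe(bonds$low, 40), 0.20, tolerance = 1e-3)
})
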