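test_that("closed form reproduces hand-solved and half-time cases", {
  # t = 0: nothing has reacted
  expect_equal(monomer_remaining(0, oligomer_params(5, 3, 0.2)), 5)
  expect_equal(oligomer_mass(0, oligomer_params(5, 3, 0.2)), 0)

  # n = 3 half-time: t_half = 1/(2 k M0^2) = 12.5 h for M0 = 2, k = 0.01
  p3 <- oligomer_params(2, 3, 0.01)
  expect_equal(monomer_remaining(12.5, p3), 1)
  expect_equal(oligomer_mass(12.5, p3), 1)

  # n = 2 hand solution: m = M0 / (1 + 2 k M0 t)
  p2 <- oligomer_params(1, 2, 0.5)
  expect_equal(monomer_remaining(1, p2), 0.5)

  # asymptotic conservation (m ~ (6 k t)^(-1/2) for n = 3 at large t)
  expect_equal(oligomer_mass(1e8, p3), 2, tolerance = 1e-3)

  # k = 0: no conversion at any time
  p0 <- oligomer_params(4, 3, 0)
  expect_equal(monomer_remaining(c(0, 1, 100), p0), c(4, 4, 4))
})

test_that("ThT signal is the affine image of the oligomer mass", {
  p <- oligomer_params(2, 3, 0.01, c = 200, F0 = 50)
  expect_equal(tht_signal(12.5, p), 50 + 200 * 1.0)
  p_id <- oligomer_params(2, 3, 0.01, c = 1, F0 = 0)
  tt <- c(0, 1, 5, 12.5, 40)
  expect_equal(tht_signal(tt, p_id), oligomer_mass(tt, p_id))
  p_flat <- oligomer_params(2, 3, 0, c = 200, F0 = 50)
  expect_equal(tht_signal(c(0, 10, 100), p_flat), rep(50, 3))
})

test_that("invalid parameters and domains are rejected", {
  expect_error(oligomer_params(2, 1, 0.1), "n > 1")
  expect_error(oligomer_params(2, 0.5, 0.1), "n > 1")
  expect_error(oligomer_params(-1, 3, 0.1), "M0")
  expect_error(oligomer_params(2, 3, -0.1), "k")
  expect_error(monomer_remaining(-1, oligomer_params(2, 3, 0.1)),
               "negative time")
  expect_error(integrate_rate_law(c(0, 1), oligomer_params(2, 3, 0.1),
                                  rtol = 1), "rtol")
})

test_that("numerical integration oracle agrees with the closed form", {
  # hand-solved n = 2 case through the integrator
  p2 <- oligomer_params(1, 2, 0.5)
  expect_equal(integrate_rate_law(c(0, 1), p2)[2], 0.5, tolerance = 1e-6)

  # k = 0 gives identically zero oligomer mass
  expect_equal(integrate_rate_law(seq(0, 10, 1), oligomer_params(2, 3, 0)),
               rep(0, 11))

  # randomized equivalence across the parameter regimes
  set.seed(101)
  grid <- seq(0, 50, length.out = 21)
  for (i in 1:100) {
    p <- random_params()
    ref <- oligomer_mass(grid, p)
    num <- integrate_rate_law(grid, p, rtol = 1e-10)
    expect_lt(max(abs(num - ref) / pmax(abs(ref), 1e-9 * p$M0)), 1e-6)
  }
})

test_that("mass conservation holds to machine precision", {
  set.seed(202)
  for (i in 1:1000) {
    p <- random_params()
    t <- stats::runif(3, 0, 100)
    total <- monomer_remaining(t, p) + oligomer_mass(t, p)
    expect_lt(max(abs(total - p$M0)) / p$M0, 1e-12)
  }
})

test_that("oligomer mass is nondecreasing in t, k and M0", {
  set.seed(303)
  for (i in 1:1000) {
    p <- random_params()
    t <- sort(stats::runif(2, 0, 50))
    expect_gte(oligomer_mass(t[2], p), oligomer_mass(t[1], p))
    p_hik <- oligomer_params(p$M0, p$n, p$k * 1.7, p$c, p$F0)
    expect_gte(oligomer_mass(t[2], p_hik), oligomer_mass(t[2], p))
    p_him <- oligomer_params(p$M0 * 1.3, p$n, p$k, p$c, p$F0)
    expect_gte(oligomer_mass(t[2], p_him), oligomer_mass(t[2], p))
  }
})

test_that("the oligomer fraction depends only on k * M0^(n-1) * t", {
  set.seed(404)
  for (i in 1:200) {
    p <- random_params()
    t <- stats::runif(1, 0.1, 50)
    tau <- p$k * p$M0^(p$n - 1) * t
    # a different (M0, k, t) triple with the same scaled time and order
    M0b <- p$M0 * stats::runif(1, 0.5, 2)
    kb <- 10^stats::runif(1, -3, 0)
    tb <- tau / (kb * M0b^(p$n - 1))
    fa <- oligomer_mass(t, p) / p$M0
    fb <- oligomer_mass(tb, oligomer_params(M0b, p$n, kb)) / M0b
    expect_equal(fa, fb, tolerance = 1e-9)
  }
})

test_that("kinetic traces validate their contract", {
  expect_error(kinetic_trace(c(0, 1, 1), c(1, 2, 3), 2, 7),
               "strictly increasing")
  expect_error(kinetic_trace(c(0, 1), c(1, NA), 2, 7), "non-finite")
  expect_error(kinetic_trace(c(0, 1), c(1, 2), 2, 13), "pH")
  tr <- kinetic_trace(0:5, rep(1, 6), 2, 7)
  expect_s3_class(tr, "kinetic_trace")
})
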