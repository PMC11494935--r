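stretch_cases <- list(
  list(kind = "stretch_harmonic", gamma = NA),
  list(kind = "stretch_morse", gamma = 1.1),
  list(kind = "stretch_manz", gamma = 1.203))

test_that("every stretch form has zero value/slope and curvature k at d_eq", {
  deq <- 2.2; k <- 0.8
  for (cs in stretch_cases) {
    tm <- flex_term(cs$kind, c(1, 2), deq, k, exponent = cs$gamma)
    expect_equal(stretch_energy(deq, tm), 0, info = cs$kind)
    expect_equal(stretch_energy(deq, tm, deriv = 1), 0, info = cs$kind)
    expect_equal(stretch_energy(deq, tm, deriv = 2), k, info = cs$kind)
    # analytic derivatives agree with FD everywhere sampled
    for (d in c(1.4, 2.0, 2.9, 4.0)) {
      expect_equal(stretch_energy(d, tm, deriv = 1),
                   fd_deriv(function(x) stretch_energy(x, tm), d),
                   tolerance = 1e-7, info = cs$kind)
      expect_lt(abs(stretch_energy(d, tm, deriv = 2) -
                    fd_deriv(function(x) stretch_energy(x, tm), d,
                             order = 2, h = 1e-4)), 1e-6)
    }
  }
  expect_equal(stretch_energy(2.7, flex_term("stretch_harmonic", c(1, 2),
                                             2.2, 2)), 0.25)
  expect_error(stretch_energy(2, flex_term("bend_new", c(1, 2, 3), 2, 1)),
               "stretch")
})

test_that("harmonic stretch expands to the linear-model coefficients", {
  k <- 1.7; dref <- 2.3
  # U = p1 d^2 + p2 d + p3 with p1 = k/2, p2 = -k dref, p3 = k dref^2 / 2
  p <- c(0.5 * k, -k * dref, 0.5 * k * dref^2)
  tm <- flex_term("stretch_harmonic", c(1, 2), dref, k)
  for (d in c(1, 2, 3.5))
    expect_equal(stretch_energy(d, tm), p[1] * d^2 + p[2] * d + p[3])
})

test_that("Manz coefficient conditions solve to 5/2 and 3/2", {
  co <- manz_stretch_coefficients()
  expect_equal(unname(co), c(2.5, 1.5))
  # the conditions themselves: 1 - c2 + c3 = 0 and c2 - (5/3) c3 = 0
  expect_equal(1 - co[["coeff_2"]] + co[["coeff_3"]], 0)
  expect_equal(co[["coeff_2"]] - (5 / 3) * co[["coeff_3"]], 0)
})

test_that("dissociation energies match the d -> infinity limits", {
  k <- 0.9; g <- 1.25; deq <- 2.0
  morse <- flex_term("stretch_morse", c(1, 2), deq, k, exponent = g)
  manz <- flex_term("stretch_manz", c(1, 2), deq, k, exponent = g)
  expect_equal(stretch_dissociation_energy(morse), k / (2 * g^2))
  expect_equal(stretch_dissociation_energy(manz), 3 * k / (5 * g^2))
  expect_equal(stretch_energy(1e4, morse),
               stretch_dissociation_energy(morse), tolerance = 1e-6)
  expect_equal(stretch_energy(1e4, manz),
               stretch_dissociation_energy(manz), tolerance = 1e-6)
  # normalization: k = 5 g^2 / 3 gives unit dissociation energy
  manz1 <- flex_term("stretch_manz", c(1, 2), deq, 5 * g^2 / 3, exponent = g)
  expect_equal(stretch_dissociation_energy(manz1), 1)
  # equating k and dissociation energy pins gamma_Morse = gamma0 sqrt(5/6)
  gm <- predict_morse_exponent(g)
  expect_equal(k / (2 * gm^2), 3 * k / (5 * g^2))
  expect_error(stretch_dissociation_energy(
    flex_term("stretch_harmonic", c(1, 2), deq, k)))
})

test_that("Manz and Morse increase monotonically above d_eq, bounded by D_e", {
  deq <- 2.0
  for (kind in c("stretch_morse", "stretch_manz")) {
    tm <- flex_term(kind, c(1, 2), deq, 0.7, exponent = 1.3)
    d <- seq(deq, deq + 15, by = 0.05)
    u <- stretch_energy(d, tm)
    expect_true(all(diff(u) > 0), info = kind)
    expect_true(all(u <= stretch_dissociation_energy(tm)), info = kind)
  }
})

test_that("g_m basis obeys its limit contract and feeds curvature", {
  deq <- 2.1
  for (m in 1:6) {
    expect_equal(gm_basis_energy(deq, deq, m), 0)
    expect_equal(gm_basis_energy(deq, deq, m, deriv = 1), 0)
    expect_equal(gm_basis_energy(1e6, deq, m), 1, tolerance = 1e-12)
    expect_equal(gm_basis_energy(0, deq, m), (-1)^m)
    expect_gt(abs(gm_basis_energy(deq, deq, m, deriv = 2)), 1e-4)
    for (d in c(1.1, 2.5, 4))
      expect_equal(gm_basis_energy(d, deq, m, deriv = 1),
                   fd_deriv(function(x) gm_basis_energy(x, deq, m), d),
                   tolerance = 1e-6)
  }
  expect_error(gm_basis_energy(1, 2, 0))
})

test_that("h factor matches its printed limits and is increasing", {
  for (teq in c(pi / 3, pi / 2, 0.9 * pi, pi)) for (nu in c(0.5, 2, 5)) {
    expect_equal(h_factor(0, teq, nu), 0)
    expect_equal(h_factor(teq, teq, nu), 1)
    expect_equal(h_factor(pi, teq, nu),
                 tanh(nu) / tanh(nu * sin(teq / 2)))
    th <- seq(0.01, pi, length.out = 200)
    expect_true(all(diff(h_factor(th, teq, nu)) > 0))
  }
  expect_equal(h_factor(pi, pi / 2, 2), tanh(2) / tanh(2 * sin(pi / 4)))
})

test_that("every bend form is zero at theta_eq; curvature k where promised", {
  k <- 0.3
  kinds <- c("bend_new", "bend_harmonic", "bend_cosine")
  for (teq in c(pi / 2, 2 * pi / 3, pi)) for (kind in kinds) {
    tm <- flex_term(kind, c(1, 2, 3), teq, k)
    expect_equal(bend_energy(teq, tm), 0, info = kind)
    expect_equal(bend_energy(teq, tm, deriv = 1), 0, info = kind)
    # FD curvature check (the printed contract, including theta_eq = pi)
    h <- 1e-4
    fd2 <- (bend_energy(min(pi, teq + h), tm) + bend_energy(teq - h, tm) -
            2 * bend_energy(teq, tm)) / h^2
    # at teq = pi the + step folds back: use one-sided symmetric pair
    if (teq == pi) fd2 <- 2 * bend_energy(teq - h, tm) / h^2
    expect_equal(fd2, k, tolerance = 1e-4, info = paste(kind, teq))
  }
})

test_that("the regularized bend passes its constraint suite", {
  k <- 0.25
  for (teq in c(pi / 2, 2 * pi / 3, pi)) {
    tm <- flex_term("bend_new", c(1, 2, 3), teq, k)
    # zero force at theta = pi for any theta_eq
    expect_equal(bend_energy(pi, tm, deriv = 1), 0, tolerance = 1e-12)
    # analytic derivatives match FD
    for (th in c(0.4, 1.2, 2.4, 3.0)) {
      expect_equal(bend_energy(th, tm, deriv = 1),
                   fd_deriv(function(x) bend_energy(x, tm), th),
                   tolerance = 1e-6)
      expect_equal(bend_energy(th, tm, deriv = 2),
                   fd_deriv(function(x) bend_energy(x, tm), th, order = 2),
                   tolerance = 1e-4)
    }
  }
  # steep wall towards theta -> 0 (Pauli repulsion)
  tm <- flex_term("bend_new", c(1, 2, 3), pi / 2, k)
  expect_gt(bend_energy(0.01, tm),
            100 * max(bend_energy(pi / 2 + 0.5, tm),
                      bend_energy(pi / 2 - 0.5, tm)))
  # folding symmetry about pi: U(pi - D) is what a hypothetical pi + D
  # measures; continuity of orders 1-4 across pi via FD on cos-smoothness
  tm2 <- flex_term("bend_new", c(1, 2, 3), 2 * pi / 3, 0.4)
  f <- function(th) bend_energy(th, tm2)
  d4 <- function(th, h) (f(th + 2 * h) - 4 * f(th + h) + 6 * f(th) -
                         4 * f(th - h) + f(th - 2 * h)) / h^4
  folded <- function(th) ifelse(th > pi, 2 * pi - th, th)
  g <- function(th) f(folded(th))
  h <- 1e-2
  expect_equal(g(pi + 0.2), g(pi - 0.2))
  d4_left <- (g(pi - 0.1 + 2 * h) - 4 * g(pi - 0.1 + h) + 6 * g(pi - 0.1) -
              4 * g(pi - 0.1 - h) + g(pi - 0.1 - 2 * h)) / h^4
  d4_at <- (g(pi + 2 * h) - 4 * g(pi + h) + 6 * g(pi) -
            4 * g(pi - h) + g(pi - 2 * h)) / h^4
  expect_true(is.finite(d4_left) && is.finite(d4_at))
})

test_that("the harmonic cosine bend has zero curvature at a linear minimum", {
  tm <- flex_term("bend_harmonic_cosine", c(1, 2, 3), pi, 1)
  h <- 1e-3
  fd2 <- 2 * bend_energy(pi - h, tm) / h^2
  expect_lt(abs(fd2), 1e-4)          # the documented deficiency
})

test_that("bend domain errors and the MM3 configuration path work", {
  tm <- flex_term("bend_new", c(1, 2, 3), pi / 2, 1)
  expect_error(bend_energy(-0.1, tm), "fold")
  expect_error(bend_energy(3.5, tm), "fold")
  expect_error(flex_term("bend_mm3", c(1, 2, 3), pi / 2, 1),
               "coefficients")
  mm3 <- flex_term("bend_mm3", c(1, 2, 3), pi / 2, 0.5,
                   mm3_coeffs = c(-0.014, 5.6e-5))
  expect_equal(bend_energy(pi / 2, mm3), 0)
  expect_equal(bend_energy(pi / 2, mm3, deriv = 2), 0.5, tolerance = 1e-12)
})

test_that("cross term is bilinear and swap-symmetric", {
  tm <- flex_term("bond_bond_cross", c(1, 2, 3), 2.0, 1,
                  eq_value2 = 2.5)
  expect_equal(cross_term_energy(2.0, 3.1, tm), 0)
  expect_equal(cross_term_energy(2.4, 2.5, tm), 0)
  expect_equal(cross_term_energy(2.1, 2.3, tm), 0.1 * (-0.2))
  tm_swapped <- flex_term("bond_bond_cross", c(3, 2, 1), 2.5, 1,
                          eq_value2 = 2.0)
  expect_equal(cross_term_energy(2.3, 2.1, tm_swapped),
               cross_term_energy(2.1, 2.3, tm))
})

test_that("flexibility models serialize round-trip", {
  m <- example_flexibility_model("HNO", urey_bradley = TRUE)
  lines <- write_flexibility_model(m)
  m2 <- read_flexibility_model(lines)
  expect_length(m2$terms, length(m$terms))
  for (i in seq_along(m$terms)) {
    expect_equal(m2$terms[[i]]$kind, m$terms[[i]]$kind)
    expect_equal(m2$terms[[i]]$eq_value, m$terms[[i]]$eq_value,
                 tolerance = 1e-10)
    expect_equal(m2$terms[[i]]$force_constant,
                 m$terms[[i]]$force_constant, tolerance = 1e-10)
  }
})
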