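test_that("the displacement protocol yields 14 (symmetric) or 24 geometries", {
  disp5 <- c(-0.14, -0.07, 0, 0.07, 0.14)
  h2o <- example_molecule("H2O")
  b <- detect_bonds(h2o, test_radii)
  ro <- build_displacement_training_set(h2o, b, disp5)
  expect_equal(sum(ro$info$type == "bond_grid"), 14)
  hno <- example_molecule("HNO")
  ro2 <- build_displacement_training_set(hno, detect_bonds(hno, test_radii),
                                         disp5)
  expect_equal(sum(ro2$info$type == "bond_grid"), 24)
  # single-bond four-point protocol
  di <- molecular_system(c("C", "F"), rbind(c(0, 0, 0), c(1.332, 0, 0)))
  di$ref_coords <- di$coords
  ro3 <- build_displacement_training_set(di, cbind(1, 2),
                                         c(-0.14, -0.07, 0.07, 0.14))
  expect_equal(nrow(ro3$info), 4)
  expect_error(build_displacement_training_set(di, cbind(1, 2), c(-2)),
               "non-positive")
})

test_that("displaced geometries change only the intended bond lengths", {
  h2o <- example_molecule("H2O")
  b <- detect_bonds(h2o, test_radii)
  ro <- build_displacement_training_set(h2o, b, c(-0.07, 0, 0.07))
  teq <- bond_angle(h2o, 1, 2, 3, use_ref = TRUE)
  for (g in ro$geometries)
    expect_equal(angle_from_coords(g$coords, 1, 2, 3), teq,
                 tolerance = 1e-10)
  lens <- sort(unique(round(unlist(lapply(ro$geometries, function(g)
    c(dist_pair(g$coords, 1, 2), dist_pair(g$coords, 3, 2)))), 6)))
  expect_length(lens, 3)
})

test_that("angle-scan points are filtered to the +/- 30 degree band", {
  h2o <- example_molecule("H2O")
  b <- detect_bonds(h2o, test_radii)
  scan <- data.frame(theta = c(60, 80, 104.7, 130, 140),
                     energy = c(0.05, 0.01, 0, 0.01, 0.03))
  ro <- build_displacement_training_set(h2o, b, c(0), angle_scan = scan)
  kept <- ro$info[ro$info$type == "angle_scan", ]
  expect_equal(nrow(kept), 3)       # 80, 104.7, 130 within 104.7 +/- 30
  th <- vapply(ro$geometries[ro$info$type == "angle_scan"], function(g)
    angle_from_coords(g$coords, 1, 2, 3) * 180 / pi, numeric(1))
  expect_equal(sort(th), c(80, 104.7, 130), tolerance = 1e-8)
})

test_that("validation geometries are reproducible and inside the windows", {
  h2o <- example_molecule("H2O")
  b <- detect_bonds(h2o, test_radii)
  v1 <- generate_validation_geometries(h2o, b, n = 9, seed = 42)
  v2 <- generate_validation_geometries(h2o, b, n = 9, seed = 42)
  expect_length(v1, 9)
  expect_identical(lapply(v1, `[[`, "coords"), lapply(v2, `[[`, "coords"))
  # property: several hundred draws all stay inside the stated intervals
  deq <- 0.962 * ang2bohr; teq <- 104.7 * pi / 180
  vmany <- generate_validation_geometries(h2o, b, n = 350, seed = 7)
  for (g in vmany) {
    expect_lt(abs(dist_pair(g$coords, 1, 2) - deq), 0.0701 * ang2bohr)
    expect_lt(abs(dist_pair(g$coords, 3, 2) - deq), 0.0701 * ang2bohr)
    expect_lt(abs(angle_from_coords(g$coords, 1, 2, 3) - teq),
              30.01 * pi / 180)
  }
})

test_that("design-matrix features are unit-force-constant energies", {
  di <- molecular_system(c("C", "F"), rbind(c(0, 0, 0), c(1.4, 0, 0)),
                         units = "bohr")
  di$ref_coords <- di$coords
  m <- flexibility_model(list(
    flex_term("stretch_harmonic", c(1, 2), 1.4, 99)))   # k ignored
  g1 <- di; g1$coords[2, 1] <- 1.5                       # Dd = 0.1
  X <- design_matrix(m, list(g1, di))
  expect_equal(unname(X[1, 1]), 0.5 * 0.1^2, tolerance = 1e-12)
  expect_equal(unname(X[2, 1]), 0)                       # reference row
  # force rows are negative FD gradients of the energy features
  Xf <- design_matrix(m, list(g1), include_forces = TRUE)
  h <- 1e-6
  gp <- g1; gp$coords[2, 1] <- gp$coords[2, 1] + h
  gm <- g1; gm$coords[2, 1] <- gm$coords[2, 1] - h
  fd <- -(design_matrix(m, list(gp))[1, 1] -
          design_matrix(m, list(gm))[1, 1]) / (2 * h)
  expect_equal(Xf[1 + 3 + 1, 1], fd, tolerance = 1e-6)   # atom 2, x row
})

test_that("exact linear systems are recovered to 1e-10 and LASSO shrinks", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  colnames(X) <- c("stretch_manz_1.2", "bend_new_1.2.3",
                   "bond_bond_cross_1.2.3")
  k_true <- c(0.8, 0.3, -0.1)
  y <- as.vector(X %*% k_true)
  fit <- fit_linear(abs(X), abs(y))  # keep positives for the bound demo
  fit0 <- fit_linear(X, y)
  expect_equal(unname(fit0$force_constants), k_true, tolerance = 1e-10)
  expect_equal(fit0$r_squared_train, 1, tolerance = 1e-12)
  # huge lambda shrinks everything to zero
  fit_big <- fit_linear(X, y, fit_config(lasso_lambda = 1e6))
  expect_equal(unname(fit_big$force_constants), c(0, 0, 0))
  # all-zero column is reported, not dropped
  Xbad <- cbind(X, stretch_manz_9.9 = 0)
  expect_error(fit_linear(Xbad, y), "unidentifiable")
})

test_that("duplicated columns stay finite under L1 and sparsify with lambda", {
  set.seed(4)
  x <- rnorm(30)
  X <- cbind(a = x, b = x, c = rnorm(30))    # exact multicollinearity
  y <- 2 * x + 0.5 * X[, "c"]
  cfg <- function(l) fit_config(lasso_lambda = l, lower = rep(-Inf, 3))
  fits <- lapply(c(1e-4, 1e-2, 1), function(l) fit_linear(X, y, cfg(l)))
  for (f in fits) expect_true(all(is.finite(f$force_constants)))
  nz <- vapply(fits, `[[`, numeric(1), "n_nonzero")
  expect_true(all(diff(nz) <= 0))            # fewer terms as lambda grows
})

test_that("the LASSO path is monotone in RMSE and total magnitude", {
  set.seed(5)
  deq <- 1.4
  d <- deq + seq(-0.3, 0.9, length.out = 18)
  X <- vapply(1:6, function(m) gm_basis_energy(d, deq, m), numeric(18))
  colnames(X) <- paste0("stretch_gm_basis_", 1:6)
  k_true <- c(0.3, 0.15, 0.05, 0.02, 0.01, 0.005)
  y <- as.vector(X %*% k_true) + rnorm(18, 0, 1e-5)
  lambdas <- 10^seq(-3, -8)                  # decreasing
  rmse <- l1 <- numeric(length(lambdas))
  for (i in seq_along(lambdas)) {
    f <- fit_linear(X, y, fit_config(lasso_lambda = lambdas[i],
                                     lower = rep(-Inf, 6)))
    rmse[i] <- sqrt(mean((y - X %*% f$force_constants)^2))
    l1[i] <- sum(abs(f$force_constants))
  }
  expect_true(all(diff(rmse) <= 1e-12))      # non-increasing
  expect_true(all(diff(l1) >= -1e-12))       # non-decreasing
})

test_that("every term kind is recovered from simulated data, with noise", {
  h2o <- example_molecule("H2O")
  b <- detect_bonds(h2o, test_radii)
  deq <- 0.962 * ang2bohr
  teq <- 104.7 * pi / 180
  dub <- dist_pair(h2o$ref_coords, 1, 3)
  truth <- flexibility_model(list(
    flex_term("stretch_manz", c(1, 2), deq, 0.55, exponent = 1.276),
    flex_term("stretch_manz", c(3, 2), deq, 0.55, exponent = 1.276),
    flex_term("bend_new", c(1, 2, 3), teq, 0.15),
    flex_term("urey_bradley", c(1, 3), dub, 0.02, exponent = 1.129),
    flex_term("bond_bond_cross", c(1, 2, 3), deq, -0.03, eq_value2 = deq)))
  k_true <- vapply(truth$terms, `[[`, numeric(1), "force_constant")
  geoms <- c(
    build_displacement_training_set(h2o, b, c(-0.14, -0.07, 0, 0.07, 0.14),
                                    symmetric = FALSE)$geometries,
    generate_validation_geometries(h2o, b, n = 12, seed = 9))
  u_ref <- model_energy(truth, h2o$ref_coords)
  y <- vapply(geoms, function(g) model_energy(truth, g$coords) - u_ref,
              numeric(1))
  X <- design_matrix(truth, geoms)
  fit <- fit_linear(X, y)
  expect_equal(unname(fit$force_constants), k_true, tolerance = 1e-9)
  # with sigma = 1e-4 hartree noise the recovery degrades gracefully
  set.seed(21)
  fitn <- fit_linear(X, y + rnorm(length(y), 0, 1e-4))
  expect_equal(unname(fitn$force_constants), k_true, tolerance = 0.15)
})

test_that("with all pairs excluded the old scheme collapses onto the new", {
  h2o <- example_molecule("H2O")
  top <- bonded_topology(h2o, test_radii)     # triatomic: everything excluded
  deq <- 0.962 * ang2bohr; teq <- 104.7 * pi / 180
  truth <- flexibility_model(list(
    flex_term("stretch_manz", c(1, 2), deq, 0.55, exponent = 1.276),
    flex_term("stretch_manz", c(3, 2), deq, 0.55, exponent = 1.276),
    flex_term("bend_new", c(1, 2, 3), teq, 0.15)))
  geoms <- c(
    build_displacement_training_set(h2o, top$bonds, c(-0.07, 0, 0.07),
                                    symmetric = FALSE)$geometries,
    generate_validation_geometries(h2o, top$bonds, n = 6, seed = 2))
  u_ref <- model_energy(truth, h2o$ref_coords)
  y <- vapply(geoms, function(g) model_energy(truth, g$coords) - u_ref,
              numeric(1))
  train <- training_set(geoms, y)
  nb <- nonbonded_model(c(0.4, -0.8, 0.4), rep(3.0, 3), rep(0.05, 3),
                        scheme = "old")       # excluded pairs: no effect
  fit_new <- fit_linear(design_matrix(truth, geoms), y)
  fit_old <- fit_old_scheme(truth, train, nb, h2o, top)
  k_true <- vapply(truth$terms, `[[`, numeric(1), "force_constant")
  expect_equal(unname(fit_new$force_constants), k_true, tolerance = 1e-9)
  expect_equal(unname(fit_old$force_constants), k_true, tolerance = 1e-4)
  # resting values equal the equilibrium internals
  expect_equal(unname(fit_old$resting_values), c(deq, deq, teq),
               tolerance = 1e-4)
})

test_that("R^2 behaves for perfect, mean, and worse-than-mean predictors", {
  ref <- c(1, 2, 3, 4)
  expect_equal(r_squared(ref, ref), 1)
  expect_equal(r_squared(rep(mean(ref), 4), ref), 0)
  expect_lt(r_squared(rev(ref), ref), 0)
  expect_warning(r_squared(c(1, 2), c(3, 3)), "undefined")
})
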