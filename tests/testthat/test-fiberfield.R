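test_that("discrete Laplace solution is linear on a 1D strip", {
  # 1D Laplace with the end cells pinned to 0 and 1: the interior 5-point
  # stencil reduces to second differences, so the solution is linear in the
  # cell index (solved with the same machinery the weight solve uses)
  dom <- strip_domain(11, h = 1)
  ends <- c(dom$cells[1], dom$cells[11])
  sys <- assemble_pressure_system(dom, 1,
                                  bc = list(type = "cells", cells = ends,
                                            values = c(0, 1)))
  sol <- solve_pressure(sys, method = "jacobi")
  expect_equal(sol$p, seq(0, 1, length.out = 11), tolerance = 1e-7)
  expect_true(all(sol$p >= 0 & sol$p <= 1))
})

test_that("one-cell-thick walls get the midway transmural weight", {
  lab <- matrix(1L, 4, 1); lab[4, 1] <- 2L
  dom <- segmented_domain(lab, 1)     # every myo cell touches OUTSIDE
  w <- solve_transmural_weight(dom, method = "direct")
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(w[3], 0.5)             # in gamma_o and gamma_i at once
})

test_that("transmural weight approaches the annular Laplace solution", {
  err <- sapply(c(1, 0.5), function(h) {
    dom <- make_annulus_phantom(phantom_spec(h = h))
    w <- solve_transmural_weight(dom, method = "direct")
    cc <- cell_centers(dom)
    r <- sqrt((cc[, 1] - dom$center[1])^2 + (cc[, 2] - dom$center[2])^2)
    wex <- pmin(pmax(log(r / 34) / log(19 / 34), 0), 1)
    max(abs(w - wex))
  })
  expect_lt(err[2], err[1])        # error shrinks under refinement
  expect_lt(err[2], 0.08)          # dominated by O(h) rim rasterization
})

test_that("weight solve requires both boundary sets", {
  dom <- rect_domain(5)            # no CAVITY anywhere -> empty gamma_i
  expect_error(solve_transmural_weight(dom), "configuration error")
})

test_that("fiber directions are orthonormal, radial/tangential on the annulus", {
  dom <- make_annulus_phantom(phantom_spec(h = 1))
  w <- solve_transmural_weight(dom, method = "direct")
  dirs <- fiber_directions(dom, w)
  dot <- rowSums(dirs$e_l * dirs$e_t)
  expect_lt(max(abs(dot)), 1e-12)
  expect_equal(rowSums(dirs$e_l^2), rep(1, length(w)), tolerance = 1e-12)
  expect_equal(rowSums(dirs$e_t^2), rep(1, length(w)), tolerance = 1e-12)
  # away from the rasterized rims e_t is radial (pointing inward: w grows
  # toward the endocardium)
  cc <- cell_centers(dom)
  rx <- cc[, 1] - dom$center[1]; ry <- cc[, 2] - dom$center[2]
  r <- sqrt(rx^2 + ry^2)
  rim <- dom$cells %in% c(dom$gamma_o, dom$gamma_i)
  interior <- !rim & r > 21 & r < 32
  align <- abs(dirs$e_t[interior, 1] * rx[interior] / r[interior] +
               dirs$e_t[interior, 2] * ry[interior] / r[interior])
  expect_gt(min(align), 0.99)
})

test_that("1D strip directions are axis-aligned up to sign", {
  dom <- strip_domain(8, h = 1)
  w <- seq(0, 1, length.out = 8)
  dirs <- fiber_directions(dom, w)
  expect_equal(abs(dirs$e_t[, 1]), rep(1, 8), tolerance = 1e-12)
  expect_equal(abs(dirs$e_l[, 2]), rep(1, 8), tolerance = 1e-12)
})

test_that("degenerate gradient cells copy the nearest non-degenerate direction", {
  # w varies along x on the left half, constant on the right half
  dom <- rect_domain(8, 3, h = 1)
  cc <- cell_centers(dom)
  w <- pmin(cc[, 1], 4) / 4
  dirs <- fiber_directions(dom, w)
  right <- cc[, 1] > 5.6            # columns 7..8: zero gradient
  expect_true(any(dirs$degenerate))
  expect_true(all(dirs$degenerate[right]))
  # copied from the varying region: e_t = (1, 0) up to sign
  expect_equal(abs(dirs$e_t[right, 1]), rep(1, sum(right)), tolerance = 1e-12)
  # an all-constant field falls back with a warning
  expect_warning(fiber_directions(dom, rep(0.3, length(dom$cells))),
                 "degenerate")
})

test_that("permeability blending follows the transmural weight", {
  dom <- rect_domain(4)
  n <- length(dom$cells)
  dirs <- list(e_l = cbind(rep(1, n), 0), e_t = cbind(rep(0, n), 1))
  K0 <- assemble_tensor(dom, rep(0, n), dirs)
  K1 <- assemble_tensor(dom, rep(1, n), dirs)
  expect_equal(K0$Kl, rep(1.5, n))       # epicardial value = K1
  expect_equal(K0$Kt, rep(0.75, n))
  expect_equal(K1$Kl, rep(3.0, n))       # endocardial value = 2 K1
  expect_equal(K1$Kt, rep(1.5, n))
  expect_equal(K1$Kl / K0$Kl, rep(2, n)) # endo/epi ratio exactly 2
  expect_equal(K1$Kt / K0$Kt, rep(2, n))
  expect_error(assemble_tensor(dom, rep(0, n), dirs, K1 = -1), "positive")
})

test_that("tensor eigenvalues are {Kl, Kt} for any unit e_l, both forms", {
  set.seed(7)
  dom <- rect_domain(3)
  n <- length(dom$cells)
  th <- runif(n, 0, 2 * pi)
  dirs <- list(e_l = cbind(cos(th), sin(th)),
               e_t = cbind(-sin(th), cos(th)))
  w <- runif(n)
  for (form in c("stated", "literal")) {
    K <- assemble_tensor(dom, w, dirs, form = form)
    for (i in seq_len(n)) {
      M <- matrix(c(K$Kxx[i], K$Kxy[i], K$Kxy[i], K$Kyy[i]), 2, 2)
      ev <- sort(eigen(M, symmetric = TRUE)$values)
      expect_equal(ev, sort(c(K$Kl[i], K$Kt[i])), tolerance = 1e-12)
      expect_gt(ev[1], 0)              # SPD everywhere
      # anisotropy ratio Kl/Kt = K1/K2 = 2, uniformly in w
      expect_equal(K$Kl[i] / K$Kt[i], 2, tolerance = 1e-12)
    }
    # eigenvector assignment: stated puts Kl along e_l, literal swaps
    M1 <- matrix(c(K$Kxx[1], K$Kxy[1], K$Kxy[1], K$Kyy[1]), 2, 2)
    along_el <- drop(dirs$e_l[1, ] %*% M1 %*% dirs$e_l[1, ])
    expect_equal(along_el,
                 if (form == "stated") K$Kl[1] else K$Kt[1],
                 tolerance = 1e-12)
  }
})

test_that("e_l sign convention does not change the tensor", {
  dom <- rect_domain(3)
  n <- length(dom$cells)
  dirs <- list(e_l = cbind(rep(sqrt(0.5), n), sqrt(0.5)),
               e_t = cbind(rep(-sqrt(0.5), n), sqrt(0.5)))
  flip <- list(e_l = -dirs$e_l, e_t = -dirs$e_t)
  w <- rep(0.4, n)
  Ka <- assemble_tensor(dom, w, dirs)
  Kb <- assemble_tensor(dom, w, flip)
  expect_equal(Ka$Kxx, Kb$Kxx)
  expect_equal(Ka$Kxy, Kb$Kxy)
  expect_equal(Ka$Kyy, Kb$Kyy)
})
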