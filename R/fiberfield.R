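# Anisotropic permeability of the intravascular domain.
#
# A transmural weight w solves the Laplace equation with w = 0 on the
# epicardial contact cells and w = 1 on the endocardial ones, so w grades
# smoothly across the wall.  The second preferential direction e_t is the
# normalized gradient of w (transmural); the first, e_l, is its 90-degree
# counter-clockwise rotation (parallel to the surfaces, the direction the
# micro-vasculature preferentially follows).  Permeabilities blend linearly in
# w so the subendocardium is twice as permeable as the subepicardium:
#   K_l = K1 (1 - w) + 2 K1 w,   K_t = K2 (1 - w) + 2 K2 w.

#' Solve the transmural weight field
#'
#' Discrete Laplace equation on the myocardium (5-point stencil, reusing the
#' finite-volume machinery of the pressure solver with unit isotropic
#' coefficient): `w = 0` on epicardial contact cells, `w = 1` on endocardial
#' contact cells, zero flux across remaining external faces.
#'
#' @param domain a [segmented_domain()] with nonempty `gamma_o` and `gamma_i`.
#' @param method,tol,max_iter passed to [solve_pressure()].
#' @return numeric vector `w` in `[0, 1]` per myocardial cell (compact order).
#' @export
solve_transmural_weight <- function(domain, method = c("jacobi", "direct"),
                                    tol = 1e-8, max_iter = 1e6) {
  fail_if(length(domain$gamma_o) == 0L || length(domain$gamma_i) == 0L,
          "configuration error: empty epicardial or endocardial boundary set")
  # a cell touching both OUTSIDE and CAVITY (wall one cell thick there) sits
  # midway through the wall: w = 1/2
  both <- intersect(domain$gamma_o, domain$gamma_i)
  go <- setdiff(domain$gamma_o, both)
  gi <- setdiff(domain$gamma_i, both)
  bc <- list(type = "cells",
             cells = c(go, gi, both),
             values = c(rep(0, length(go)), rep(1, length(gi)),
                        rep(0.5, length(both))))
  sys <- assemble_pressure_system(domain, Kfield = 1, bc = bc)
  sol <- solve_pressure(sys, method = match.arg(method), tol = tol,
                        max_iter = max_iter)
  w <- sol$p
  # clip rounding residue; the discrete maximum principle bounds w in [0, 1]
  pmin(pmax(w, 0), 1)
}

#' Preferential permeability directions from the transmural weight
#'
#' `e_t` is the normalized central-difference gradient of `w` (one-sided at
#' rasterized edges); `e_l` its 90-degree counter-clockwise rotation.  Where
#' the gradient is degenerate (`|grad w| < eps`, e.g. inside a constant
#' patch), both directions are copied from the nearest non-degenerate cell
#' (Euclidean distance, ties by cell order).  If every cell is degenerate the
#' field defaults to `e_t = (1, 0)` with a warning.
#'
#' @param domain a [segmented_domain()].
#' @param w transmural weight per cell, from [solve_transmural_weight()].
#' @param eps degeneracy threshold on `|grad w|`.
#' @return list with `e_l`, `e_t` (n-by-2 unit-vector matrices) and
#'   `degenerate` (logical vector marking filled-in cells).
#' @export
fiber_directions <- function(domain, w, eps = 1e-12) {
  n <- length(domain$cells)
  fail_if(length(w) != n, "w has wrong length")
  Gx <- .gradient_operator(domain, "x")
  Gy <- .gradient_operator(domain, "y")
  gx <- as.vector(Gx %*% w)
  gy <- as.vector(Gy %*% w)
  nrm <- sqrt(gx^2 + gy^2)
  degen <- nrm < eps
  if (all(degen)) {
    warning("gradient of w degenerate everywhere; using e_t = (1, 0)")
    e_t <- cbind(rep(1, n), rep(0, n))
  } else {
    e_t <- cbind(gx / pmax(nrm, eps), gy / pmax(nrm, eps))
    if (any(degen)) {
      cc <- cell_centers(domain)
      good <- which(!degen)
      for (i in which(degen)) {
        d2 <- (cc[good, 1] - cc[i, 1])^2 + (cc[good, 2] - cc[i, 2])^2
        e_t[i, ] <- e_t[good[which.min(d2)], ]
      }
    }
  }
  e_l <- cbind(-e_t[, 2], e_t[, 1])   # 90 degrees counter-clockwise
  list(e_l = e_l, e_t = e_t, degenerate = degen)
}

#' Assemble the anisotropic permeability tensor field
#'
#' Permeability magnitudes blend linearly in the transmural weight,
#' `K_l = K1 (1 + w)` and `K_t = K2 (1 + w)`, so the endocardial values are
#' twice the epicardial ones.  Two tensor forms are available:
#' \describe{
#'   \item{`"stated"` (default)}{`K = K_l e_l e_l' + K_t e_t e_t'` — `K_l` is
#'     the permeability along the first preferential direction `e_l`, as the
#'     symbols are defined.}
#'   \item{`"literal"`}{`K = K_l I + (K_t - K_l) e_l e_l'` — the printed
#'     formula, which places eigenvalue `K_t` on `e_l` and `K_l` on `e_t`
#'     (the axes are swapped relative to the stated meaning).}
#' }
#' Both forms are symmetric positive definite with eigenvalues
#' `{K_l, K_t}`; `K` is quadratic in `e_l`, so the sign convention of the
#' rotation is immaterial.
#'
#' @param domain a [segmented_domain()].
#' @param w transmural weight per cell.
#' @param dirs directions from [fiber_directions()]; computed from `w` when
#'   `NULL`.
#' @param K1,K2 epicardial permeabilities along `e_l` and `e_t`,
#'   mm^2 kPa^-1 s^-1.
#' @param form `"stated"` or `"literal"`, see Details.
#' @return an object of class `permeability_field` with per-cell tensor
#'   components `Kxx`, `Kxy`, `Kyy`, the magnitudes `Kl`, `Kt`, the weight `w`
#'   and the direction fields.
#' @export
assemble_tensor <- function(domain, w, dirs = NULL, K1 = 1.5, K2 = 0.75,
                            form = c("stated", "literal")) {
  form <- match.arg(form)
  fail_if(K1 <= 0 || K2 <= 0, "K1 and K2 must be positive")
  if (is.null(dirs)) dirs <- fiber_directions(domain, w)
  Kl <- K1 * (1 - w) + 2 * K1 * w
  Kt <- K2 * (1 - w) + 2 * K2 * w
  elx <- dirs$e_l[, 1]; ely <- dirs$e_l[, 2]
  if (form == "stated") {
    # K = Kl el el' + Kt et et'  with et = rot(el) => et et' = I - el el'
    Kxx <- Kt + (Kl - Kt) * elx * elx
    Kxy <- (Kl - Kt) * elx * ely
    Kyy <- Kt + (Kl - Kt) * ely * ely
  } else {
    Kxx <- Kl + (Kt - Kl) * elx * elx
    Kxy <- (Kt - Kl) * elx * ely
    Kyy <- Kl + (Kt - Kl) * ely * ely
  }
  structure(list(Kxx = Kxx, Kxy = Kxy, Kyy = Kyy, Kl = Kl, Kt = Kt,
                 w = w, e_l = dirs$e_l, e_t = dirs$e_t,
                 K1 = K1, K2 = K2, form = form),
            class = "permeability_field")
}

#' @export
print.permeability_field <- function(x, ...) {
  cat("permeability_field:", length(x$Kxx), "cells;",
      sprintf("K1 = %g, K2 = %g (%s form);", x$K1, x$K2, x$form),
      sprintf("Kl in [%.3g, %.3g], Kt in [%.3g, %.3g] mm^2/kPa/s\n",
              min(x$Kl), max(x$Kl), min(x$Kt), max(x$Kt)))
  invisible(x)
}

#' Build the full permeability field of a domain in one call
#'
#' Convenience wrapper: transmural weight, directions, tensor.
#'
#' @inheritParams assemble_tensor
#' @inheritParams solve_transmural_weight
#' @return a `permeability_field`.
#' @export
permeability_field <- function(domain, K1 = 1.5, K2 = 0.75,
                               form = c("stated", "literal"),
                               method = "direct", tol = 1e-8) {
  w <- solve_transmural_weight(domain, method = method, tol = tol)
  assemble_tensor(domain, w, K1 = K1, K2 = K2, form = form)
}
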