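# Incompressible Darcy flow on the segmented grid:
#   div(v) = 0,  v = -K grad(p)
# discretized with a cell-centered finite-volume method.  Face
# transmissibilities use the harmonic mean of the normal tensor component;
# tensor cross-terms are discretized with centered tangential differences and
# moved to the right-hand side (deferred correction), so the core matrix stays
# an M-matrix and the Jacobi iteration of the reference method applies.

#' Pressure boundary condition on the epicardial and endocardial rims
#'
#' Dirichlet pressures are imposed at boundary faces (half-cell distance from
#' the adjacent cell center): `p_epi` on epicardial faces, optionally reduced
#' to `p_sten` on a stenosis arc, and `p_endo` on endocardial faces.  All
#' remaining external faces are zero-flux.
#'
#' @param p_epi epicardial pressure, kPa.
#' @param p_endo endocardial pressure, kPa.
#' @param p_sten pressure on the stenosis arc, kPa, or `NULL` for no stenosis.
#' @param stenosis_center_angle,stenosis_half_width stenosis arc, radians.
#' @param taper `"abrupt"` (constant `p_sten` on the arc) or `"cosine"`
#'   (smooth blend from `p_sten` at the arc center to `p_epi` at its edges).
#' @return an object of class `pressure_bc`.
#' @export
pressure_bc <- function(p_epi = 2.0, p_endo = 0.0, p_sten = NULL,
                        stenosis_center_angle = 0,
                        stenosis_half_width = 15 * pi / 180,
                        taper = c("abrupt", "cosine")) {
  taper <- match.arg(taper)
  fail_if(!all(is.finite(c(p_epi, p_endo, p_sten %||% 0))),
          "boundary pressures must be finite")
  structure(list(type = "ring", p_epi = p_epi, p_endo = p_endo,
                 p_sten = p_sten,
                 stenosis_center_angle = stenosis_center_angle,
                 stenosis_half_width = stenosis_half_width, taper = taper),
            class = "pressure_bc")
}

# Dirichlet value of a ring bc at epicardial boundary-face centers (x, y),
# relative to the domain center.
.bc_value_o <- function(bc, x, y, center) {
  p <- rep(bc$p_epi, length(x))
  if (!is.null(bc$p_sten)) {
    fail_if(is.null(center), "stenosis bc needs a domain with a center")
    ang <- atan2(y - center[2], x - center[1])
    d <- abs((ang - bc$stenosis_center_angle + pi) %% (2 * pi) - pi)
    inarc <- d <= bc$stenosis_half_width
    if (bc$taper == "abrupt") {
      p[inarc] <- bc$p_sten
    } else {
      blend <- 0.5 * (1 + cos(pi * d[inarc] / bc$stenosis_half_width))
      p[inarc] <- bc$p_epi + (bc$p_sten - bc$p_epi) * blend
    }
  }
  p
}

# Normal tensor components per compact cell for a permeability field that can
# be a scalar (isotropic) or a permeability_field object.
.k_components <- function(Kfield, n) {
  if (is.numeric(Kfield) && length(Kfield) == 1L)
    return(list(Kxx = rep(Kfield, n), Kxy = rep(0, n), Kyy = rep(Kfield, n)))
  fail_if(!inherits(Kfield, "permeability_field"),
          "Kfield must be a permeability_field or a scalar")
  fail_if(length(Kfield$Kxx) != n, "Kfield defined on a different domain")
  Kfield[c("Kxx", "Kxy", "Kyy")]
}

#' Assemble the finite-volume pressure system
#'
#' Builds one conservation equation per myocardial cell.  Dirichlet conditions
#' can be imposed either at boundary faces (`pressure_bc`, or a function
#' `p(x, y)` applied on every external face for manufactured-solution tests)
#' or at cell centers (`bc = list(type = "cells", cells = , values = )`, used
#' by the transmural Laplace solve).  An optional volumetric source `s(x, y)`
#' (or per-cell vector) is added to the right-hand side, enabling the method
#' of manufactured solutions.
#'
#' @param domain a [segmented_domain()].
#' @param Kfield a [permeability_field] or a positive scalar (isotropic).
#' @param bc a [pressure_bc()], a function `function(x, y)`, or a
#'   `list(type = "cells", cells = <grid indices>, values = <numeric>)`.
#' @param source optional source term: function `s(x, y)` or per-cell vector
#'   (units of flux per area, i.e. divergence of velocity).
#' @return an object of class `pressure_system` (sparse operator, right-hand
#'   side, deferred-correction closure and face topology).
#' @export
assemble_pressure_system <- function(domain, Kfield, bc, source = NULL) {
  n <- length(domain$cells)
  h <- domain$h
  id <- domain$cell_id
  nx <- domain$nx; ny <- domain$ny
  K <- .k_components(Kfield, n)

  gi <- ((domain$cells - 1L) %% nx) + 1L
  gj <- ((domain$cells - 1L) %/% nx) + 1L

  # compact id of the neighbour of every myocardial cell in each direction
  nb <- function(di, dj) {
    ii <- gi + di; jj <- gj + dj
    ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
    out <- rep(NA_integer_, n)
    out[ok] <- id[cbind(ii[ok], jj[ok])]
    out
  }
  nE <- nb(1L, 0L); nW <- nb(-1L, 0L); nN <- nb(0L, 1L); nS <- nb(0L, -1L)

  # internal faces, enumerated once from the lower/left cell
  fx_L <- which(!is.na(nE)); fx_R <- nE[fx_L]
  fy_L <- which(!is.na(nN)); fy_R <- nN[fy_L]

  harm <- function(a, b) 2 * a * b / (a + b)
  Tx <- harm(K$Kxx[fx_L], K$Kxx[fx_R])   # area h / distance h cancels
  Ty <- harm(K$Kyy[fy_L], K$Kyy[fy_R])

  ii <- c(fx_L, fx_L, fx_R, fx_R, fy_L, fy_L, fy_R, fy_R)
  jj <- c(fx_L, fx_R, fx_R, fx_L, fy_L, fy_R, fy_R, fy_L)
  vv <- c(Tx, -Tx, Tx, -Tx, Ty, -Ty, Ty, -Ty)

  b <- numeric(n)
  # external faces: every (cell, side) whose neighbour is not myocardium
  side_di <- c(E = 1L, W = -1L, N = 0L, S = 0L)
  side_dj <- c(E = 0L, W = 0L, N = 1L, S = -1L)
  bnd_cell <- integer(0); bnd_type <- character(0)
  bnd_x <- numeric(0); bnd_y <- numeric(0); bnd_T <- numeric(0)
  bnd_side <- character(0); bnd_val <- numeric(0)

  cells_dirichlet <- is.list(bc) && identical(bc$type, "cells")

  for (s in c("E", "W", "N", "S")) {
    nbr <- switch(s, E = nE, W = nW, N = nN, S = nS)
    ext <- which(is.na(nbr))
    if (!length(ext)) next
    ii_g <- gi[ext] + side_di[[s]]; jj_g <- gj[ext] + side_dj[[s]]
    inside <- ii_g >= 1L & ii_g <= nx & jj_g >= 1L & jj_g <= ny
    lab <- rep(LBL_OUTSIDE, length(ext))
    lab[inside] <- domain$labels[cbind(ii_g[inside], jj_g[inside])]
    type <- ifelse(lab == LBL_CAVITY, "i", "o")
    # face-center coordinates
    fxc <- (gi[ext] - 0.5 + 0.5 * side_di[[s]]) * h
    fyc <- (gj[ext] - 0.5 + 0.5 * side_dj[[s]]) * h
    Knn <- if (s %in% c("E", "W")) K$Kxx[ext] else K$Kyy[ext]
    bnd_cell <- c(bnd_cell, ext); bnd_type <- c(bnd_type, type)
    bnd_x <- c(bnd_x, fxc); bnd_y <- c(bnd_y, fyc)
    bnd_T <- c(bnd_T, 2 * Knn)   # Knn * h / (h/2) / h
    bnd_side <- c(bnd_side, rep(s, length(ext)))
  }

  if (!cells_dirichlet) {
    if (inherits(bc, "pressure_bc")) {
      bnd_val <- numeric(length(bnd_cell))
      is_o <- bnd_type == "o"
      bnd_val[is_o] <- .bc_value_o(bc, bnd_x[is_o], bnd_y[is_o], domain$center)
      bnd_val[!is_o] <- bc$p_endo
    } else if (is.function(bc)) {
      bnd_val <- bc(bnd_x, bnd_y)
    } else stop("unsupported bc", call. = FALSE)
    ii <- c(ii, bnd_cell); jj <- c(jj, bnd_cell); vv <- c(vv, bnd_T)
    b <- b + as.vector(tapply_add(bnd_T * bnd_val, bnd_cell, n))
  } else {
    bnd_val <- rep(NA_real_, length(bnd_cell))  # zero-flux external faces
  }

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))

  if (!is.null(source)) {
    sv <- if (is.function(source)) {
      cc <- cell_centers(domain)
      source(cc[, 1], cc[, 2])
    } else source
    fail_if(length(sv) != n, "source vector has wrong length")
    b <- b + sv * h^2
  }

  fixed <- NULL
  if (cells_dirichlet) {
    fixed_ids <- id[bc$cells]
    fail_if(anyNA(fixed_ids), "Dirichlet cells must be myocardial")
    # overwrite the rows of fixed cells with identity equations
    A <- Matrix::t(A)
    A[, fixed_ids] <- 0            # column access on dgCMatrix is cheap
    A <- Matrix::t(A)
    A <- A + Matrix::sparseMatrix(i = fixed_ids, j = fixed_ids,
                                  x = rep(1, length(fixed_ids)),
                                  dims = c(n, n))
    b[fixed_ids] <- bc$values
    fixed <- fixed_ids
  }

  diagA <- Matrix::diag(A)
  fail_if(any(diagA <= 0), "geometry error: isolated cell with no equations")

  # deferred-correction closure for tensor cross-terms
  cross <- NULL
  if (any(K$Kxy != 0)) {
    Gy <- .gradient_operator(domain, "y")
    Gx <- .gradient_operator(domain, "x")
    Kxy_fx <- 0.5 * (K$Kxy[fx_L] + K$Kxy[fx_R])
    Kxy_fy <- 0.5 * (K$Kxy[fy_L] + K$Kxy[fy_R])
    cross <- function(p) {
      dpdy <- as.vector(Gy %*% p)
      dpdx <- as.vector(Gx %*% p)
      # cross flux across x-faces (+x direction) and y-faces (+y direction)
      Fx <- -Kxy_fx * 0.5 * (dpdy[fx_L] + dpdy[fx_R]) * h
      Fy <- -Kxy_fy * 0.5 * (dpdx[fy_L] + dpdx[fy_R]) * h
      out <- numeric(n)
      out <- out - as.vector(tapply_add(Fx, fx_L, n)) +
                   as.vector(tapply_add(Fx, fx_R, n)) -
                   as.vector(tapply_add(Fy, fy_L, n)) +
                   as.vector(tapply_add(Fy, fy_R, n))
      if (!is.null(fixed)) out[fixed] <- 0
      list(rhs = out, Fx = Fx, Fy = Fy)
    }
  }

  structure(list(A = A, b = b, n = n, h = h, cross = cross,
                 domain = domain, K = K, fixed = fixed,
                 fx_L = fx_L, fx_R = fx_R, Tx = Tx,
                 fy_L = fy_L, fy_R = fy_R, Ty = Ty,
                 bnd = list(cell = bnd_cell, type = bnd_type, side = bnd_side,
                            x = bnd_x, y = bnd_y, T = bnd_T, value = bnd_val)),
            class = "pressure_system")
}

# sum values into n bins by index (vectorized scatter-add)
tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  if (length(vals)) {
    s <- rowsum(vals, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

# sparse central-difference gradient over myocardial cells (one-sided at
# domain edges, zero where no neighbour exists)
.gradient_operator <- function(domain, dir = c("x", "y")) {
  dir <- match.arg(dir)
  n <- length(domain$cells)
  id <- domain$cell_id; nx <- domain$nx; ny <- domain$ny
  gi <- ((domain$cells - 1L) %% nx) + 1L
  gj <- ((domain$cells - 1L) %/% nx) + 1L
  di <- if (dir == "x") 1L else 0L
  dj <- if (dir == "x") 0L else 1L
  get_nb <- function(sgn) {
    ii <- gi + sgn * di; jj <- gj + sgn * dj
    ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
    out <- rep(NA_integer_, n)
    out[ok] <- id[cbind(ii[ok], jj[ok])]
    out
  }
  fw <- get_nb(1L); bw <- get_nb(-1L)
  h <- domain$h
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  both <- !is.na(fw) & !is.na(bw)
  fo <- !is.na(fw) & is.na(bw)
  bo <- is.na(fw) & !is.na(bw)
  ii <- c(which(both), which(both), which(fo), which(fo),
          which(bo), which(bo))
  jj <- c(fw[both], bw[both], fw[fo], which(fo), which(bo), bw[bo])
  vv <- c(rep(1 / (2 * h), sum(both)), rep(-1 / (2 * h), sum(both)),
          rep(1 / h, sum(fo)), rep(-1 / h, sum(fo)),
          rep(1 / h, sum(bo)), rep(-1 / h, sum(bo)))
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
}

#' Solve the assembled pressure system
#'
#' The reference method is the Jacobi iteration with stop criterion
#' `max|A p - b - cross(p)| / max|b| <= tol` (default `1e-8`).  Tensor
#' cross-terms are refreshed from the current iterate every sweep (deferred
#' correction).  `method = "direct"` is a permitted substitute meeting the
#' same residual contract: a sparse direct solve wrapped in a Picard loop over
#' the deferred correction.
#'
#' @param system a `pressure_system`.
#' @param method `"jacobi"` (reference) or `"direct"`.
#' @param tol relative residual tolerance (max norm).
#' @param max_iter iteration cap; non-convergence raises an error carrying the
#'   residual history.
#' @return an object of class `flow_solution`: cell pressures `p` (kPa, in
#'   compact cell order), face-normal Darcy velocities (mm/s, see
#'   [face_velocities()]), `residual` and `iterations`.
#' @export
solve_pressure <- function(system, method = c("jacobi", "direct"),
                           tol = 1e-8, max_iter = 1e6) {
  method <- match.arg(method)
  A <- system$A; b <- system$b; n <- system$n
  d <- Matrix::diag(A)
  bscale <- max(abs(b)); if (bscale == 0) bscale <- 1
  cross <- system$cross
  p <- numeric(n)
  res_hist <- numeric(0)
  resid <- Inf; it <- 0L

  residual_of <- function(p, crhs) {
    max(abs(as.vector(A %*% p) - b - crhs)) / bscale
  }

  if (method == "jacobi") {
    R <- A - Matrix::Diagonal(x = d)
    check_every <- 10L
    while (it < max_iter) {
      crhs <- if (is.null(cross)) numeric(n) else cross(p)$rhs
      p_new <- (b + crhs - as.vector(R %*% p)) / d
      it <- it + 1L
      p <- p_new
      if (it %% check_every == 0L || it == max_iter) {
        crhs <- if (is.null(cross)) numeric(n) else cross(p)$rhs
        resid <- residual_of(p, crhs)
        res_hist <- c(res_hist, resid)
        if (resid <= tol) break
      }
    }
  } else {
    # cells-Dirichlet systems are asymmetric (identity rows); use LU there
    fac <- if (is.null(system$fixed))
      Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
    else Matrix::lu(A)
    for (outer in seq_len(200L)) {
      crhs <- if (is.null(cross)) numeric(n) else cross(p)$rhs
      p <- as.vector(Matrix::solve(fac, b + crhs))
      it <- it + 1L
      crhs2 <- if (is.null(cross)) numeric(n) else cross(p)$rhs
      resid <- residual_of(p, crhs2)
      res_hist <- c(res_hist, resid)
      if (resid <= tol) break
    }
  }
  if (resid > tol) {
    stop(sprintf(
      "pressure solver did not converge: residual %.3e after %d iterations (history tail: %s)",
      resid, it, paste(signif(utils::tail(res_hist, 5), 3), collapse = ", ")),
      call. = FALSE)
  }
  sol <- structure(list(p = p, residual = resid, iterations = it,
                        method = method, system = system),
                   class = "flow_solution")
  sol$faces <- face_velocities(p, system)
  sol
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("flow_solution:", length(x$p), "cells;",
      sprintf("p in [%.4g, %.4g] kPa;", min(x$p), max(x$p)),
      x$iterations, "iterations, residual", format(x$residual, digits = 3),
      sprintf("(%s)\n", x$method))
  invisible(x)
}

#' Face-normal Darcy velocities from a converged pressure field
#'
#' Velocities are fluxes per unit face area (mm/s): on internal faces,
#' `u = T (p_L - p_R) / h` plus the tensor cross-term evaluated at the face;
#' on epicardial/endocardial boundary faces, the half-cell Dirichlet flux,
#' signed positive into the cell.
#'
#' @param p per-cell pressure vector (compact order).
#' @param system the `pressure_system` the pressure was solved on.
#' @return a list with `ux`, `uy` (internal x-/y-face velocities in the +x/+y
#'   direction, aligned with `system$fx_L` etc.) and `u_bnd` (boundary-face
#'   velocity, positive inward, aligned with `system$bnd`).
#' @export
face_velocities <- function(p, system) {
  h <- system$h
  Fx <- system$Tx * (p[system$fx_L] - p[system$fx_R])
  Fy <- system$Ty * (p[system$fy_L] - p[system$fy_R])
  if (!is.null(system$cross)) {
    cr <- system$cross(p)
    Fx <- Fx + cr$Fx
    Fy <- Fy + cr$Fy
  }
  bnd <- system$bnd
  Fb <- rep(0, length(bnd$cell))
  if (length(bnd$cell) && !all(is.na(bnd$value))) {
    has <- !is.na(bnd$value)
    Fb[has] <- bnd$T[has] * (bnd$value[has] - p[bnd$cell[has]])
  }
  list(ux = Fx / h, uy = Fy / h, u_bnd = Fb / h)
}

#' Per-cell discrete divergence of the face fluxes
#'
#' After convergence this is the local mass-conservation defect; it should be
#' below `tol_mass` times the largest face flux for every cell.
#'
#' @param flow a `flow_solution`.
#' @return numeric vector, net outward volumetric flux per cell (mm^2/s per
#'   unit depth).
#' @export
flux_divergence <- function(flow) {
  sys <- flow$system
  n <- sys$n; h <- sys$h
  f <- flow$faces
  div <- tapply_add(f$ux * h, sys$fx_L, n) - tapply_add(f$ux * h, sys$fx_R, n) +
         tapply_add(f$uy * h, sys$fy_L, n) - tapply_add(f$uy * h, sys$fy_R, n) -
         tapply_add(f$u_bnd * h, sys$bnd$cell, n)
  div
}

#' Map a compact per-cell vector onto the raster grid
#'
#' @param values per-cell vector in compact order.
#' @param domain the matching `segmented_domain`.
#' @return an `nx` by `ny` matrix with `NA` outside the myocardium.
#' @export
field_grid <- function(values, domain) {
  g <- matrix(NA_real_, domain$nx, domain$ny)
  g[domain$cells] <- values
  g
}
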