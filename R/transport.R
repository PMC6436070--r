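# Three-domain contrast-agent transport:
#   intravascular C_i  — advected by the Darcy velocity (superficial, as
#                        printed), diffusing with coefficient phi*D_i, losing
#                        f to the interstitium;
#   interstitial  C_e  — diffusing with (1-phi)*lambda*D_e, gaining f, losing
#                        (1-phi)*lambda*k_e*C_e to the venous system and g to
#                        the fibrotic network;
#   fibrotic      C_f  — gaining g, losing (1-phi)*lambda*lambda_f*k_f*C_f.
# The time derivatives carry the porosity / fraction factors exactly as the
# model states them, advection uses the bounded TOPUS scheme, diffusion
# central differences, and time integration is explicit Euler.

#' Transport parameters (per-scenario tracer-kinetic constants)
#'
#' Defaults are the healthy/ischemic parameter set; see
#' [scenario_config()] for the infarct overrides.
#'
#' @param phi porosity (intravascular volume fraction), in (0, 1).
#' @param lambda interstitial fraction of the extravascular space, in [0, 1].
#' @param lambda_f fibrotic fraction of the interstitium, in [0, 1].
#' @param P endothelial transfer rate (one-way, intravascular to
#'   interstitium), 1/s.
#' @param k_e interstitium-to-venous washout rate, 1/s.
#' @param k_f fibrosis-to-venous washout rate, 1/s.
#' @param k_ef interstitium-to-fibrosis sortion rate, 1/s.
#' @param D_i,D_e diffusivities, mm^2/s.
#' @param sigma,t_peak epicardial influx Gaussian: standard deviation and
#'   peak time, s.
#' @details `lambda`, `lambda_f`, `P`, `k_e` and `k_f` may be per-cell
#'   vectors (compact cell order) to describe regionally varying tissue, as
#'   in the sensitivity analyses where a parameter is changed inside the
#'   diseased region only.
#' @return an object of class `transport_params`.
#' @export
transport_params <- function(phi = 0.10, lambda = 0.25, lambda_f = 0,
                             P = 0.03, k_e = 0.002, k_f = 0, k_ef = 0,
                             D_i = 1e-3, D_e = 1e-3,
                             sigma = 7, t_peak = 25) {
  fail_if(phi <= 0 || phi >= 1, "phi must be in (0, 1)")
  fail_if(any(lambda < 0) || any(lambda > 1) ||
          any(lambda_f < 0) || any(lambda_f > 1),
          "lambda and lambda_f must be in [0, 1]")
  fail_if(any(c(P, k_e, k_f, k_ef, D_i, D_e) < 0), "rates must be >= 0")
  fail_if(sigma <= 0, "sigma must be positive")
  structure(list(phi = phi, lambda = lambda, lambda_f = lambda_f,
                 P = P, k_e = k_e, k_f = k_f, k_ef = k_ef,
                 D_i = D_i, D_e = D_e, sigma = sigma, t_peak = t_peak),
            class = "transport_params")
}

#' One-way endothelial exchange rate
#'
#' `f = P (C_i - C_e)` when `C_i > C_e`, zero otherwise: the contrast agent
#' only leaks from the intravascular to the interstitial space.
#'
#' @param C_i,C_e concentrations (a.u.), vectorized.
#' @param P endothelial transfer rate, 1/s.
#' @return exchange rate, a.u./s (always >= 0).
#' @export
exchange_rate_f <- function(C_i, C_e, P) {
  fail_if(any(P < 0), "P must be >= 0")
  P * pmax(C_i - C_e, 0)
}

#' Sortion rate into the fibrotic network
#'
#' `g = (1 - phi) lambda lambda_f k_ef C_e`: trapping of interstitial
#' contrast agent by fibrosis.
#'
#' @param C_e interstitial concentration (a.u.), vectorized.
#' @param phi,lambda,lambda_f,k_ef see [transport_params()].
#' @return sortion rate, a.u./s.
#' @export
sortion_rate_g <- function(C_e, phi, lambda, lambda_f, k_ef) {
  (1 - phi) * lambda * lambda_f * k_ef * C_e
}

#' Prescribed influx concentration at the epicardium
#'
#' A Gaussian bolus
#' `Q(t) = exp(-((t - t_peak) / sigma)^2 / 2) / (sigma sqrt(2 pi)) + X`,
#' where `X` is the recirculation feedback (the outlet value of the 1D
#' recirculation line), applied uniformly over the epicardial boundary.
#'
#' @param t time, s (vectorized).
#' @param sigma,t_peak Gaussian parameters, s.
#' @param X recirculation term (a.u.), default 0.
#' @return influx concentration, a.u.
#' @export
influx_concentration_Q <- function(t, sigma = 7, t_peak = 25, X = 0) {
  fail_if(sigma <= 0, "sigma must be positive")
  exp(-0.5 * ((t - t_peak) / sigma)^2) / (sigma * sqrt(2 * pi)) + X
}

# TOPUS bounded polynomial in normalized variables (alpha = 2):
#   p(x) = 2 x^4 - 3 x^3 + 2 x   on [0, 1]
.topus_poly <- function(x) ((2 * x - 3) * x^2 + 2) * x

#' TOPUS face value from an upwind-biased three-cell stencil
#'
#' Normalized-variable formulation of the third-order polynomial upwind
#' scheme: with far-upwind `c_R`, upwind `c_U` and downwind `c_D` values, the
#' normalized upwind variable is `(c_U - c_R) / (c_D - c_R)`; inside `[0, 1]`
#' the face value is `c_R + (c_D - c_R) p(x)` with
#' `p(x) = 2 x^4 - 3 x^3 + 2 x`, which satisfies the convection-boundedness
#' criterion; outside `[0, 1]` (or when `c_R` is `NA`, e.g. at boundary
#' cells) the scheme falls back to first-order upwind.
#'
#' @param c_R far-upwind cell value (`NA` where the stencil is truncated).
#' @param c_U upwind cell value.
#' @param c_D downwind cell value.
#' @return face value (vectorized).
#' @export
topus_face_value <- function(c_R, c_U, c_D) {
  denom <- c_D - c_R
  xhat <- (c_U - c_R) / denom
  use <- is.finite(xhat) & xhat >= 0 & xhat <= 1
  out <- c_U                      # first-order upwind fallback
  idx <- which(use)
  out[idx] <- c_R[idx] + denom[idx] * .topus_poly(xhat[idx])
  out
}

#' Stable explicit-Euler step size
#'
#' `dt = safety * min(phi h / max|u|, h^2 / (4 max(D_i, D_e)),
#' 1 / max(P/phi, k_e, k_f, k_ef))`.  The porosity factor in the advective
#' bound reflects that the intravascular balance carries `phi` on the time
#' derivative but the superficial Darcy velocity on the advection term, so
#' the concentration front travels at `|u| / phi`; likewise the exchange term
#' acts on `C_i` at rate `P / phi`.  Inactive guards (zero velocity, zero
#' diffusivity, zero rates) drop out; a NaN/zero velocity field leaves the
#' diffusive and reactive bounds in charge.
#'
#' @param u a `flow_solution`, or the scalar maximum face speed, mm/s.
#' @param params a [transport_params()].
#' @param h cell size, mm.
#' @param safety safety factor, default 0.25.
#' @return step size, s.
#' @export
stable_dt <- function(u, params, h, safety = 0.25) {
  umax <- if (inherits(u, "flow_solution")) {
    f <- u$faces
    suppressWarnings(max(abs(c(f$ux, f$uy, f$u_bnd)), na.rm = TRUE))
  } else as.numeric(u)
  if (!is.finite(umax)) umax <- 0
  rate <- max(params$P / params$phi, params$k_e, params$k_f, params$k_ef)
  bounds <- c(if (umax > 0) params$phi * h / umax,
              if (max(params$D_i, params$D_e) > 0)
                h^2 / (4 * max(params$D_i, params$D_e)),
              if (rate > 0) 1 / rate)
  fail_if(length(bounds) == 0L, "no finite stability bound (all terms zero)")
  safety * min(bounds)
}

#' Initial concentration state
#'
#' All three fields start at zero by default (contrast-free tissue).
#'
#' @param domain a [segmented_domain()].
#' @param C_i,C_e,C_f initial fields, scalar or per-cell vectors (a.u.).
#'   `C_f` support is restricted to the fibrosis mask.
#' @return an object of class `concentration_state` with fields `C_i`, `C_e`,
#'   `C_f` (compact cell order), time `t` and running mass-budget
#'   accumulators.
#' @export
concentration_state <- function(domain, C_i = 0, C_e = 0, C_f = 0) {
  n <- length(domain$cells)
  expand <- function(v) if (length(v) == 1L) rep(as.numeric(v), n) else {
    fail_if(length(v) != n, "initial field has wrong length"); as.numeric(v)
  }
  C_f <- expand(C_f)
  mask <- rep(FALSE, n)
  mask[domain$cell_id[domain$fibrosis_mask]] <- TRUE
  C_f[!mask] <- 0
  structure(list(C_i = expand(C_i), C_e = expand(C_e), C_f = C_f, t = 0,
                 influx = 0, outflow = 0, sink = 0),
            class = "concentration_state")
}

#' @export
print.concentration_state <- function(x, ...) {
  cat(sprintf(
    "concentration_state at t = %.2f s: max C_i %.4g, C_e %.4g, C_f %.4g\n",
    x$t, max(x$C_i), max(x$C_e), max(x$C_f)))
  invisible(x)
}

#' Precompute the transport stencils for a flow solution
#'
#' Face stencils (including far-upwind neighbours for TOPUS), sparse
#' incidence and diffusion operators, frozen face fluxes and boundary-face
#' bookkeeping.  Built once per scenario; [step_explicit()] accepts it via
#' `workspace` to avoid rebuilding.
#'
#' @param domain a [segmented_domain()].
#' @param flow a converged [solve_pressure()] result on the same domain.
#' @return an object of class `transport_workspace`.
#' @export
transport_workspace <- function(domain, flow) {
  sys <- flow$system
  fail_if(!identical(sys$domain$cells, domain$cells),
          "flow was solved on a different domain")
  n <- sys$n; h <- sys$h
  id <- domain$cell_id; nx <- domain$nx; ny <- domain$ny
  gi <- ((domain$cells - 1L) %% nx) + 1L
  gj <- ((domain$cells - 1L) %/% nx) + 1L
  safe_id <- function(ii, jj) {
    ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
    out <- rep(NA_integer_, length(ii))
    out[ok] <- id[cbind(ii[ok], jj[ok])]
    out
  }
  # far-upwind neighbours of each internal face
  fxL <- sys$fx_L; fxR <- sys$fx_R
  fyL <- sys$fy_L; fyR <- sys$fy_R
  fx_LL <- safe_id(gi[fxL] - 1L, gj[fxL])
  fx_RR <- safe_id(gi[fxR] + 1L, gj[fxR])
  fy_LL <- safe_id(gi[fyL], gj[fyL] - 1L)
  fy_RR <- safe_id(gi[fyR], gj[fyR] + 1L)

  inc <- function(L, R) {
    nf <- length(L)
    Matrix::sparseMatrix(i = c(R, L), j = c(seq_len(nf), seq_len(nf)),
                         x = c(rep(1, nf), rep(-1, nf)), dims = c(n, nf))
  }
  IncX <- inc(fxL, fxR)   # net inflow = IncX %*% F_x  (F in +x direction)
  IncY <- inc(fyL, fyR)

  # graph Laplacian over internal faces: (Ldiff %*% C)[c] = sum_nb (C_nb - C_c)
  nfx <- length(fxL); nfy <- length(fyL)
  Ldiff <- Matrix::sparseMatrix(
    i = c(fxL, fxR, fxL, fxR, fyL, fyR, fyL, fyR),
    j = c(fxR, fxL, fxL, fxR, fyR, fyL, fyL, fyR),
    x = c(rep(1, 2 * nfx), rep(-1, 2 * nfx),
          rep(1, 2 * nfy), rep(-1, 2 * nfy)),
    dims = c(n, n))

  qx <- flow$faces$ux * h
  qy <- flow$faces$uy * h
  qb <- flow$faces$u_bnd * h      # positive into the cell
  bnd <- sys$bnd

  fibc <- id[domain$fibrosis_mask]
  structure(list(n = n, h = h,
                 fx_L = fxL, fx_R = fxR, fx_LL = fx_LL, fx_RR = fx_RR,
                 fy_L = fyL, fy_R = fyR, fy_LL = fy_LL, fy_RR = fy_RR,
                 IncX = IncX, IncY = IncY, Ldiff = Ldiff,
                 qx = qx, qy = qy, qb = qb,
                 bnd_cell = bnd$cell, bnd_is_epi = bnd$type == "o",
                 fib = fibc),
            class = "transport_workspace")
}

# TOPUS face values for one face family given the flux sign
.face_conc <- function(C, q, L, R, LL, RR) {
  pos <- q >= 0
  c_U <- ifelse(pos, C[L], C[R])
  c_D <- ifelse(pos, C[R], C[L])
  far <- ifelse(pos, LL, RR)
  c_Rv <- rep(NA_real_, length(q))
  hasfar <- !is.na(far)
  c_Rv[hasfar] <- C[far[hasfar]]
  topus_face_value(c_Rv, c_U, c_D)
}

#' Advance the concentration state one explicit-Euler step
#'
#' Updates the three fields over `dt` with TOPUS advection of `C_i` by the
#' frozen Darcy face velocities, central diffusion, the one-way exchange `f`,
#' the venous sinks and the sortion coupling `g`.  Boundary conditions:
#' advective influx `u Q(t)` across inflow epicardial faces, upwind advective
#' outflow across outflow faces (endocardial drain), zero diffusive flux on
#' every external face.  The running mass-budget accumulators (`influx`,
#' `outflow`, `sink`) are advanced with the same discrete fluxes.
#'
#' @param state a [concentration_state()].
#' @param flow a [solve_pressure()] result (used when `workspace` is `NULL`).
#' @param params a [transport_params()].
#' @param domain the [segmented_domain()].
#' @param dt step size, s; must satisfy [stable_dt()].
#' @param Q influx concentration for this step (a.u.), i.e.
#'   [influx_concentration_Q()] evaluated at the current time including the
#'   recirculation term.
#' @param workspace optional [transport_workspace()].
#' @return the updated `concentration_state` at `t + dt`.
#' @export
step_explicit <- function(state, flow, params, domain, dt, Q,
                          workspace = NULL) {
  ws <- workspace %||% transport_workspace(domain, flow)
  n <- ws$n; h <- ws$h; h2 <- h * h
  Ci <- state$C_i; Ce <- state$C_e; Cf <- state$C_f
  p <- params

  # advective fluxes through internal faces (mass per unit depth per time)
  Fx <- ws$qx * .face_conc(Ci, ws$qx, ws$fx_L, ws$fx_R, ws$fx_LL, ws$fx_RR)
  Fy <- ws$qy * .face_conc(Ci, ws$qy, ws$fy_L, ws$fy_R, ws$fy_LL, ws$fy_RR)
  adv_in <- as.vector(ws$IncX %*% Fx) + as.vector(ws$IncY %*% Fy)

  # boundary faces: inflow carries Q(t) at the epicardium and 0 (venous
  # blood) at the endocardium; outflow carries the upwind cell value
  qb <- ws$qb
  inflow <- qb > 0
  carried_in <- ifelse(ws$bnd_is_epi, Q, 0)
  Fb <- ifelse(inflow, qb * carried_in, qb * Ci[ws$bnd_cell])
  adv_in <- adv_in + tapply_add(Fb, ws$bnd_cell, n)

  # regional parameters may be per-cell vectors; sub() restricts to a subset
  sub <- function(x, idx) if (length(x) > 1L) x[idx] else x
  f <- exchange_rate_f(Ci, Ce, p$P)
  lap_i <- as.vector(ws$Ldiff %*% Ci) / h2
  lap_e <- as.vector(ws$Ldiff %*% Ce) / h2

  dCi <- adv_in / (p$phi * h2) + p$D_i * lap_i - f / p$phi
  dCe <- p$D_e * lap_e + f / ((1 - p$phi) * p$lambda) - p$k_e * Ce
  sink_rate <- sum((1 - p$phi) * p$lambda * p$k_e * Ce) * h2
  fib <- ws$fib
  if (length(fib) && any(sub(p$lambda_f, fib) > 0)) {
    lam_fib <- sub(p$lambda, fib); lamf_fib <- sub(p$lambda_f, fib)
    g <- sortion_rate_g(Ce[fib], p$phi, lam_fib, lamf_fib, p$k_ef)
    dCe[fib] <- dCe[fib] - g / ((1 - p$phi) * lam_fib)
    dCf <- p$k_ef * Ce[fib] - sub(p$k_f, fib) * Cf[fib]
    sink_rate <- sink_rate +
      sum((1 - p$phi) * lam_fib * lamf_fib * sub(p$k_f, fib) * Cf[fib]) * h2
    Cf[fib] <- Cf[fib] + dt * dCf
  }
  Ci <- Ci + dt * dCi
  Ce <- Ce + dt * dCe

  if (min(Ci, Ce, Cf) < -1e-12)
    stop(sprintf(
      "stability failure: negative concentration %.3e at t = %.3f s (dt = %.4g)",
      min(Ci, Ce, Cf), state$t, dt), call. = FALSE)

  state$C_i <- Ci; state$C_e <- Ce; state$C_f <- Cf
  state$t <- state$t + dt
  state$influx  <- state$influx  + dt * sum(Fb[inflow])
  state$outflow <- state$outflow - dt * sum(Fb[!inflow])
  state$sink    <- state$sink    + dt * sink_rate
  state
}

#' Total contrast-agent mass of a state
#'
#' Volume-fraction weighted integral
#' `sum(phi C_i + (1 - phi) lambda C_e + (1 - phi) lambda lambda_f C_f) h^2`,
#' the quantity conserved by the transport step up to boundary fluxes and
#' venous sinks.
#'
#' @param state a [concentration_state()].
#' @param params a [transport_params()].
#' @param domain the [segmented_domain()].
#' @return total mass (a.u. times mm^2).
#' @export
total_mass <- function(state, params, domain) {
  h2 <- domain$h^2
  p <- params
  sum(p$phi * state$C_i + (1 - p$phi) * p$lambda * state$C_e +
      (1 - p$phi) * p$lambda * p$lambda_f * state$C_f) * h2
}
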