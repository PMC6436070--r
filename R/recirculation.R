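# 1D recirculation line closing the circulatory loop: the intravascular
# average concentration C_L enters at the left boundary, travels down a line
# of length L with advection, diffusion and first-order elimination
# (kidneys), and the outlet value C_R feeds back into the epicardial influx
# as the recirculation term X(t).

#' Initialize the recirculation line
#'
#' First-order upwind advection, central diffusion and explicit decay on a
#' uniform 1D grid.  The default length and velocity give a loop transit time
#' of `L / v_out = 25 s`, consistent with the inter-pass spacing of clinical
#' first-pass curves.
#'
#' @param L line length, mm.
#' @param h_out grid spacing, mm.
#' @param v_out advection velocity, mm/s (> 0).
#' @param D_out diffusivity, mm^2/s.
#' @param k elimination rate, 1/s.
#' @return an object of class `recirc_state` with the concentration profile
#'   `C_out`, the inlet/outlet scalars `C_L`, `C_R` and mass-budget
#'   accumulators.
#' @export
recirc_state <- function(L = 25, h_out = 0.5, v_out = 1.0, D_out = 0.05,
                         k = 0.02) {
  fail_if(L <= 0 || h_out <= 0 || h_out > L, "invalid recirculation grid")
  fail_if(v_out <= 0, "v_out must be positive")
  fail_if(D_out < 0 || k < 0, "D_out and k must be >= 0")
  ncell <- max(2L, round(L / h_out))
  structure(list(C_out = numeric(ncell), n = ncell, L = L, h = L / ncell,
                 v = v_out, D = D_out, k = k, C_L = 0, C_R = 0,
                 injected = 0, decayed = 0, delivered = 0),
            class = "recirc_state")
}

#' @export
print.recirc_state <- function(x, ...) {
  cat(sprintf(
    "recirc_state: L = %g mm (%d cells), v = %g mm/s, D = %g mm^2/s, k = %g 1/s; C_L = %.4g, C_R = %.4g\n",
    x$L, x$n, x$v, x$D, x$k, x$C_L, x$C_R))
  invisible(x)
}

#' Largest stable explicit step for the recirculation line
#'
#' @param rstate a [recirc_state()].
#' @param safety safety factor.
#' @return step size, s.
#' @export
recirc_stable_dt <- function(rstate, safety = 0.5) {
  safety / (rstate$v / rstate$h + 2 * rstate$D / rstate$h^2 + rstate$k)
}

#' Average intravascular concentration (loop inlet)
#'
#' The arithmetic mean of `C_i` over all myocardial cells (the finite volumes
#' share one area, so the mean equals the domain integral divided by the
#' domain measure).
#'
#' @param state a [concentration_state()].
#' @param domain the matching [segmented_domain()].
#' @return scalar `C_L`, a.u.
#' @export
average_intravascular <- function(state, domain) {
  fail_if(length(domain$cells) == 0L, "empty domain")
  mean(state$C_i)
}

#' Advance the recirculation line one explicit step
#'
#' Dirichlet inlet `C_L` at the left boundary (ghost value), advective
#' outflow with zero diffusive flux at the right; the outlet value `C_R`
#' (rightmost cell) is the recirculation feedback `X(t)`.
#'
#' @param rstate a [recirc_state()].
#' @param C_L inlet concentration for this step, a.u.
#' @param dt step size, s; must satisfy the 1D stability bound.
#' @return the updated `recirc_state` with new `C_R`.
#' @export
step_recirculation <- function(rstate, C_L, dt) {
  h <- rstate$h; v <- rstate$v; D <- rstate$D; k <- rstate$k
  if (dt * (v / h + 2 * D / h^2 + k) > 1)
    stop(sprintf(
      "stability failure: recirculation dt = %.4g exceeds the explicit bound %.4g s",
      dt, 1 / (v / h + 2 * D / h^2 + k)), call. = FALSE)
  C <- rstate$C_out
  n <- rstate$n
  left <- c(C_L, C[-n])             # upwind / diffusion ghost at the inlet
  right <- c(C[-1L], C[n])          # zero-gradient ghost at the outlet
  adv <- v * (left - C) / h
  dif <- D * (left - 2 * C + right) / h^2
  # the outlet face is purely advective: drop its diffusive contribution
  dif[n] <- D * (left[n] - C[n]) / h^2
  Cn <- C + dt * (adv + dif - k * C)
  if (min(Cn) < -1e-12)
    stop("stability failure: negative recirculation concentration",
         call. = FALSE)
  rstate$injected <- rstate$injected +
    dt * (v * C_L + D * (C_L - C[1L]) / h)
  rstate$decayed <- rstate$decayed + dt * k * sum(C) * h
  rstate$delivered <- rstate$delivered + dt * v * C[n]
  rstate$C_out <- Cn
  rstate$C_L <- C_L
  rstate$C_R <- Cn[n]
  rstate
}
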