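# Shared fixture builders: all constructed in code at test time.

# horizontal strip of n myocardial cells (1 cell high), padded by OUTSIDE;
# ends touch the grid edge so both end faces are epicardial-type contacts
strip_domain <- function(n, h = 0.5) {
  segmented_domain(matrix(1L, n, 1L), h)
}

# full rectangle of myocardium on [0, Lx] x [0, Ly] (grid edges = OUTSIDE)
rect_domain <- function(nx, ny = nx, h = 1 / nx) {
  segmented_domain(matrix(1L, nx, ny), h)
}

# diagonal (axis-aligned) permeability field on a domain
diag_kfield <- function(domain, Kxx = 1.5, Kyy = 0.75) {
  n <- length(domain$cells)
  structure(list(Kxx = rep(Kxx, n), Kxy = rep(0, n), Kyy = rep(Kyy, n),
                 Kl = rep(Kxx, n), Kt = rep(Kyy, n), K1 = Kxx, K2 = Kyy,
                 form = "stated"),
            class = "permeability_field")
}

# uniform-velocity flow on a strip by solving a linear pressure drop
strip_flow <- function(domain, K = 1.5, p_left = 2, p_right = 0,
                       method = "direct") {
  L <- domain$nx * domain$h
  pfun <- function(x, y) p_left + (p_right - p_left) * x / L
  sys <- assemble_pressure_system(domain, K, bc = pfun)
  solve_pressure(sys, method = method)
}

# brute-force 4-neighbour boundary scan (independent oracle)
oracle_boundaries <- function(labels) {
  nx <- nrow(labels); ny <- ncol(labels)
  at <- function(i, j) {
    if (i < 1 || i > nx || j < 1 || j > ny) return(0L)
    labels[i, j]
  }
  go <- integer(0); gi <- integer(0)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (labels[i, j] != 1L) next
    nbrs <- c(at(i - 1, j), at(i + 1, j), at(i, j - 1), at(i, j + 1))
    idx <- i + (j - 1L) * nx
    if (any(nbrs == 0L)) go <- c(go, idx)
    if (any(nbrs == 2L)) gi <- c(gi, idx)
  }
  list(gamma_o = go, gamma_i = gi)
}
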