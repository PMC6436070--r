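# Segmented simulation domain: raster grid of cell labels with derived
# boundary sets, fibrosis support and regions of interest.

#' Construct a segmented simulation domain
#'
#' A domain is a cell-centered raster of square finite volumes of edge `h`
#' (mm).  Each cell is `OUTSIDE` (0), `MYOCARDIUM` (1) or `CAVITY` (2).
#' The epicardial boundary set \eqn{\Gamma_o} is the set of myocardial cells
#' with at least one face adjacent to an OUTSIDE cell (or the grid edge), and
#' the endocardial set \eqn{\Gamma_i} the myocardial cells adjacent to CAVITY.
#'
#' Cell centers sit at \eqn{x = (i - 1/2)h}, \eqn{y = (j - 1/2)h} for 1-based
#' column/row indices; the label matrix is indexed `labels[i, j]`.
#'
#' @param labels integer matrix (`nx` by `ny`) of cell labels 0/1/2.
#' @param h cell edge length, mm.
#' @param fibrosis_mask integer vector of linear grid indices of fibrotic
#'   cells (must be myocardial), or `NULL`.
#' @param roi_remote,roi_diseased integer vectors of linear grid indices of
#'   the two regions of interest (disjoint, myocardial), or `NULL`.
#' @return an object of class `segmented_domain` with fields `nx`, `ny`, `h`,
#'   `labels`, `cells` (linear indices of myocardial cells), `cell_id`
#'   (grid-shaped map to 1..n_cells, NA elsewhere), `gamma_o`, `gamma_i`,
#'   `fibrosis_mask`, `roi_remote`, `roi_diseased`.
#' @export
segmented_domain <- function(labels, h, fibrosis_mask = NULL,
                             roi_remote = NULL, roi_diseased = NULL) {
  fail_if(!is.matrix(labels), "labels must be a matrix")
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  bad <- setdiff(unique(as.vector(labels)), c(LBL_OUTSIDE, LBL_MYO, LBL_CAVITY))
  fail_if(length(bad) > 0L,
          paste0("unknown label value(s): ", paste(bad, collapse = ", ")))
  fail_if(!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0,
          "h must be a positive scalar")
  cells <- which(labels == LBL_MYO)
  fail_if(length(cells) == 0L, "empty domain: no myocardial cells")

  nx <- nrow(labels); ny <- ncol(labels)
  cell_id <- matrix(NA_integer_, nx, ny)
  cell_id[cells] <- seq_along(cells)

  bnd <- .boundary_sets(labels)

  chk_subset <- function(idx, what) {
    if (is.null(idx)) return(integer(0))
    idx <- sort(unique(as.integer(idx)))
    fail_if(any(labels[idx] != LBL_MYO),
            paste0(what, " contains non-myocardial cells"))
    idx
  }
  fibrosis_mask <- chk_subset(fibrosis_mask, "fibrosis_mask")
  roi_remote    <- chk_subset(roi_remote, "roi_remote")
  roi_diseased  <- chk_subset(roi_diseased, "roi_diseased")
  fail_if(length(intersect(roi_remote, roi_diseased)) > 0L,
          "roi_remote and roi_diseased overlap")

  structure(list(nx = nx, ny = ny, h = h, labels = labels,
                 cells = cells, cell_id = cell_id,
                 gamma_o = bnd$gamma_o, gamma_i = bnd$gamma_i,
                 fibrosis_mask = fibrosis_mask,
                 roi_remote = roi_remote, roi_diseased = roi_diseased),
            class = "segmented_domain")
}

# Epicardial / endocardial contact sets by 4-neighbour face adjacency.
# Grid edges count as OUTSIDE contact.
.boundary_sets <- function(labels) {
  nx <- nrow(labels); ny <- ncol(labels)
  pad <- matrix(LBL_OUTSIDE, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- labels
  core <- pad[2:(nx + 1L), 2:(ny + 1L)]
  nb_out <- (pad[1:nx, 2:(ny + 1L)] == LBL_OUTSIDE) |
            (pad[3:(nx + 2L), 2:(ny + 1L)] == LBL_OUTSIDE) |
            (pad[2:(nx + 1L), 1:ny] == LBL_OUTSIDE) |
            (pad[2:(nx + 1L), 3:(ny + 2L)] == LBL_OUTSIDE)
  nb_cav <- (pad[1:nx, 2:(ny + 1L)] == LBL_CAVITY) |
            (pad[3:(nx + 2L), 2:(ny + 1L)] == LBL_CAVITY) |
            (pad[2:(nx + 1L), 1:ny] == LBL_CAVITY) |
            (pad[2:(nx + 1L), 3:(ny + 2L)] == LBL_CAVITY)
  myo <- core == LBL_MYO
  list(gamma_o = which(myo & nb_out), gamma_i = which(myo & nb_cav))
}

#' @export
print.segmented_domain <- function(x, ...) {
  cat("segmented_domain:", x$nx, "x", x$ny, "grid, h =", x$h, "mm\n")
  cat("  myocardial cells:", length(x$cells),
      sprintf("(area %.1f mm^2)", length(x$cells) * x$h^2), "\n")
  cat("  gamma_o:", length(x$gamma_o), "cells; gamma_i:",
      length(x$gamma_i), "cells\n")
  if (length(x$fibrosis_mask))
    cat("  fibrosis:", length(x$fibrosis_mask), "cells\n")
  if (length(x$roi_remote) || length(x$roi_diseased))
    cat("  ROIs: remote", length(x$roi_remote), "cells, diseased",
        length(x$roi_diseased), "cells\n")
  invisible(x)
}

#' Cell area of a domain
#'
#' @param domain a `segmented_domain`.
#' @return the area of one finite volume, `h^2`, in mm^2.
#' @export
cell_area <- function(domain) domain$h^2

#' Cell-center coordinates
#'
#' @param domain a `segmented_domain`.
#' @param idx linear grid indices (default: all myocardial cells).
#' @return two-column matrix of `(x, y)` coordinates in mm.
#' @export
cell_centers <- function(domain, idx = domain$cells) {
  i <- ((idx - 1L) %% domain$nx) + 1L
  j <- ((idx - 1L) %/% domain$nx) + 1L
  cbind(x = (i - 0.5) * domain$h, y = (j - 0.5) * domain$h)
}

#' Specification of the synthetic annulus phantom
#'
#' The phantom stands in for a segmented short-axis MRI slice: an annular
#' myocardium between two radii, a reduced-pressure stenosis arc on the
#' epicardium, a subendocardial fibrosis patch facing the stenosis, and two
#' subendocardial regions of interest (remote and diseased).  Angles are
#' measured counter-clockwise from the +x axis; the stenosis sits on the
#' right-hand side (angle 0) by default.
#'
#' Defaults give a myocardial area of about 2,500 mm^2 (about 10,000 cells at
#' `h = 0.5` mm) and ROI areas of exactly 70 mm^2 (remote) and 55 mm^2
#' (diseased) at `h = 0.5` mm.
#'
#' @param outer_radius,inner_radius annulus radii, mm.
#' @param h cell edge length, mm.
#' @param center annulus center `(x, y)` in mm; default places the annulus
#'   centrally on an automatically sized grid.
#' @param stenosis_center_angle,stenosis_half_width stenosis arc, radians.
#' @param fibrosis_center_angle center of the fibrosis sector, radians
#'   (default: the stenosis angle).
#' @param fibrosis_half_width angular half-width of the fibrosis sector,
#'   radians.
#' @param fibrosis_band radial extent of the fibrosis patch as fractions of
#'   wall depth measured from the endocardium, length-2 vector in `[0, 1]`.
#' @param roi_cell_counts target cell counts `c(remote, diseased)`; defaults
#'   scale with `h` so the ROI areas stay 70 and 55 mm^2.
#' @param roi_seed_depth radial position of the ROI seed points as a fraction
#'   of wall depth from the endocardium.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_radius = 34, inner_radius = 19, h = 0.5,
                         center = NULL,
                         stenosis_center_angle = 0,
                         stenosis_half_width = 15 * pi / 180,
                         fibrosis_center_angle = NULL,
                         fibrosis_half_width = 25 * pi / 180,
                         fibrosis_band = c(0, 0.45),
                         roi_cell_counts = NULL,
                         roi_seed_depth = 0.2) {
  fail_if(inner_radius >= outer_radius,
          "geometry error: inner_radius must be smaller than outer_radius")
  fail_if(inner_radius <= 0 || h <= 0, "radii and h must be positive")
  if (is.null(roi_cell_counts))
    roi_cell_counts <- c(remote = round(70 / h^2), diseased = round(55 / h^2))
  fail_if(any(roi_cell_counts < 1), "ROI target counts must be >= 1")
  structure(list(outer_radius = outer_radius, inner_radius = inner_radius,
                 h = h, center = center,
                 stenosis_center_angle = stenosis_center_angle,
                 stenosis_half_width = stenosis_half_width,
                 fibrosis_center_angle = fibrosis_center_angle %||%
                   stenosis_center_angle,
                 fibrosis_half_width = fibrosis_half_width,
                 fibrosis_band = fibrosis_band,
                 roi_cell_counts = roi_cell_counts,
                 roi_seed_depth = roi_seed_depth),
            class = "phantom_spec")
}

#' Generate the synthetic annulus phantom
#'
#' Rasterizes the annulus of a [phantom_spec()] onto a square grid: cells with
#' center radius in `(inner, outer]` are myocardium, cells inside the inner
#' radius are ventricular cavity, the rest outside.  The fibrosis patch is a
#' subendocardial sector centered on the stenosis angle.  Each ROI is built as
#' the N nearest myocardial cells to a subendocardial seed point (diseased at
#' the stenosis angle, remote diametrically opposite), ties in distance broken
#' by linear index order, so the printed ROI areas are met exactly.
#'
#' @param spec a `phantom_spec`.
#' @return a [segmented_domain()].
#' @export
make_annulus_phantom <- function(spec = phantom_spec()) {
  fail_if(!inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  h <- spec$h
  R <- spec$outer_radius; r <- spec$inner_radius
  n_half <- ceiling(R / h) + 2L
  nx <- ny <- 2L * n_half
  cx <- spec$center[1] %||% (n_half * h)
  cy <- if (length(spec$center) >= 2) spec$center[2] else n_half * h
  fail_if(cx - R < 0 || cx + R > nx * h || cy - R < 0 || cy + R > ny * h,
          "geometry error: annulus does not fit on the grid")

  xs <- (seq_len(nx) - 0.5) * h - cx
  ys <- (seq_len(ny) - 0.5) * h - cy
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  rad <- sqrt(X^2 + Y^2)
  labels <- matrix(LBL_OUTSIDE, nx, ny)
  labels[rad <= r] <- LBL_CAVITY
  labels[rad > r & rad <= R] <- LBL_MYO

  ang <- atan2(Y, X)
  wall <- (rad - r) / (R - r)  # 0 at endo, 1 at epi

  ang_dist <- function(a, b) {
    d <- abs((a - b + pi) %% (2 * pi) - pi)
    d
  }

  myo <- labels == LBL_MYO
  fib <- which(myo &
               ang_dist(ang, spec$fibrosis_center_angle) <= spec$fibrosis_half_width &
               wall >= spec$fibrosis_band[1] & wall <= spec$fibrosis_band[2])

  seed_r <- r + spec$roi_seed_depth * (R - r)
  nearest_n <- function(angle, n) {
    sx <- seed_r * cos(angle); sy <- seed_r * sin(angle)
    d2 <- (X - sx)^2 + (Y - sy)^2
    cand <- which(myo)
    cand[order(d2[cand], cand)][seq_len(n)]
  }
  n_rem <- spec$roi_cell_counts[1]; n_dis <- spec$roi_cell_counts[2]
  fail_if(n_rem + n_dis > sum(myo), "geometry error: ROIs larger than myocardium")
  roi_dis <- nearest_n(spec$stenosis_center_angle, n_dis)
  roi_rem <- nearest_n(spec$stenosis_center_angle + pi, n_rem)
  fail_if(length(intersect(roi_rem, roi_dis)) > 0L,
          "geometry error: ROI seeds too close, ROIs overlap")

  dom <- segmented_domain(labels, h, fibrosis_mask = fib,
                          roi_remote = roi_rem, roi_diseased = roi_dis)
  dom$center <- c(cx, cy)
  dom$spec <- spec
  dom
}

#' Angle of myocardial cells around the phantom center
#'
#' @param domain a `segmented_domain` produced by [make_annulus_phantom()] or
#'   any domain with a `center` field.
#' @param idx linear grid indices (default all myocardial cells).
#' @return angles in `(-pi, pi]`, radians, counter-clockwise from +x.
#' @export
cell_angles <- function(domain, idx = domain$cells) {
  fail_if(is.null(domain$center), "domain has no center (not a phantom)")
  cc <- cell_centers(domain, idx)
  atan2(cc[, 2] - domain$center[2], cc[, 1] - domain$center[1])
}

# ---------------------------------------------------------------------------
# Mask I/O.  Canonical interchange format is a plain-text label grid:
#   line 1:  nx ny h
#   then ny rows of nx integers: 0 OUTSIDE, 1 MYOCARDIUM, 2 CAVITY,
#   3 MYOCARDIUM with fibrosis.
# Row j of the file is grid row j (y increasing down the file).
# ROI masks travel as a separate same-shaped grid: 0 none, 1 remote,
# 2 diseased.  PGM (P2/P5) grayscale rasters are accepted for convenience.

#' Write a domain to the plain-text mask dialect
#'
#' @param domain a `segmented_domain`.
#' @param path output file for the label grid.
#' @param roi_path optional output file for the ROI grid (`0` none, `1`
#'   remote, `2` diseased); default `paste0(path, ".roi")` when the domain has
#'   ROIs, skipped otherwise.
#' @return `path`, invisibly.
#' @export
write_mask <- function(domain, path, roi_path = NULL) {
  lab <- domain$labels
  if (length(domain$fibrosis_mask)) lab[domain$fibrosis_mask] <- LBL_FIBROSIS
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(domain$nx, domain$ny, format(domain$h, digits = 15)), con)
  for (j in seq_len(domain$ny))
    writeLines(paste(lab[, j], collapse = " "), con)
  has_roi <- length(domain$roi_remote) || length(domain$roi_diseased)
  if (is.null(roi_path) && has_roi) roi_path <- paste0(path, ".roi")
  if (!is.null(roi_path) && has_roi) {
    rg <- matrix(0L, domain$nx, domain$ny)
    rg[domain$roi_remote] <- 1L
    rg[domain$roi_diseased] <- 2L
    con2 <- file(roi_path, "w")
    writeLines(paste(domain$nx, domain$ny, format(domain$h, digits = 15)), con2)
    for (j in seq_len(domain$ny))
      writeLines(paste(rg[, j], collapse = " "), con2)
    close(con2)
  }
  invisible(path)
}

.read_text_grid <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fail_if(length(lines) < 2L, "missing header: empty mask file")
  hdr <- scan(text = lines[1L], quiet = TRUE)
  fail_if(length(hdr) != 3L || any(!is.finite(hdr)),
          "missing header: expected 'nx ny h' on line 1")
  nx <- as.integer(hdr[1]); ny <- as.integer(hdr[2]); h <- hdr[3]
  fail_if(length(lines) < 1L + ny, "mask file truncated")
  vals <- scan(text = paste(lines[2:(1L + ny)], collapse = "\n"), quiet = TRUE)
  fail_if(length(vals) != nx * ny, "mask grid has wrong number of values")
  g <- matrix(as.integer(vals), nx, ny)  # value k of row j -> g[k, j]
  list(nx = nx, ny = ny, h = h, grid = g)
}

#' Read a segmented domain from a mask file
#'
#' Accepts the plain-text label-grid dialect written by [write_mask()]
#' (round-trips bit-exactly) or a PGM (P2/P5) grayscale raster.  For PGM input
#' the gray value `v` with maximum `m` is thresholded: `v/m < 0.25` OUTSIDE,
#' `< 0.5` MYOCARDIUM, `< 0.75` CAVITY, else MYOCARDIUM with fibrosis; `h`
#' must then be supplied.
#'
#' @param path label-grid or PGM file.
#' @param roi_path optional ROI grid file (text dialect); defaults to
#'   `paste0(path, ".roi")` when that file exists.
#' @param h cell size, mm; required for PGM input (no header), ignored for the
#'   text dialect.
#' @return a [segmented_domain()].
#' @export
read_mask <- function(path, roi_path = NULL, h = NULL) {
  magic <- readBin(path, "raw", 2L)
  if (identical(rawToChar(magic), "P2") || identical(rawToChar(magic), "P5")) {
    fail_if(is.null(h), "missing header: h must be supplied for PGM input")
    g <- .read_pgm(path)
    lab <- matrix(LBL_OUTSIDE, nrow(g$grid), ncol(g$grid))
    frac <- g$grid / g$maxval
    lab[frac >= 0.25 & frac < 0.5] <- LBL_MYO
    lab[frac >= 0.5 & frac < 0.75] <- LBL_CAVITY
    fibg <- frac >= 0.75
    lab[fibg] <- LBL_MYO
    return(segmented_domain(lab, h, fibrosis_mask = which(fibg)))
  }
  tg <- .read_text_grid(path)
  g <- tg$grid
  bad <- setdiff(unique(as.vector(g)),
                 c(LBL_OUTSIDE, LBL_MYO, LBL_CAVITY, LBL_FIBROSIS))
  fail_if(length(bad) > 0L,
          paste0("unknown label value(s): ", paste(bad, collapse = ", ")))
  fib <- which(g == LBL_FIBROSIS)
  g[fib] <- LBL_MYO
  roi_remote <- roi_diseased <- NULL
  if (is.null(roi_path)) {
    cand <- paste0(path, ".roi")
    if (file.exists(cand)) roi_path <- cand
  }
  if (!is.null(roi_path)) {
    rg <- .read_text_grid(roi_path)
    fail_if(rg$nx != tg$nx || rg$ny != tg$ny, "ROI grid shape mismatch")
    roi_remote <- which(rg$grid == 1L)
    roi_diseased <- which(rg$grid == 2L)
  }
  segmented_domain(g, tg$h, fibrosis_mask = fib,
                   roi_remote = roi_remote, roi_diseased = roi_diseased)
}

# PGM P2 (ASCII) / P5 (binary) reader; returns grid[i, j] with i the column
# (x) index, matching the text dialect orientation.
.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  # read header tokens, skipping comments
  while (length(tok) < 4L) {
    line <- readLines(con, 1L)
    fail_if(length(line) == 0L, "missing header: truncated PGM")
    line <- sub("#.*$", "", line)
    tok <- c(tok, strsplit(trimws(line), "\\s+")[[1]])
    tok <- tok[nzchar(tok)]
  }
  magic <- tok[1]
  w <- as.integer(tok[2]); hgt <- as.integer(tok[3]); maxval <- as.integer(tok[4])
  fail_if(any(is.na(c(w, hgt, maxval))), "missing header: bad PGM header")
  npix <- w * hgt
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = npix, quiet = TRUE)
  } else if (magic == "P5") {
    sz <- if (maxval > 255L) 2L else 1L
    vals <- readBin(con, "integer", n = npix, size = sz, signed = FALSE,
                    endian = "big")
  } else stop("not a PGM file", call. = FALSE)
  fail_if(length(vals) != npix, "PGM pixel data truncated")
  # PGM stores row-major, top row first
  list(grid = matrix(vals, nrow = w, ncol = hgt), maxval = maxval)
}
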