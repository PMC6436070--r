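# Field snapshot writers: CSV grids and VTK legacy STRUCTURED_POINTS, both
# plain text, readable by ParaView and spreadsheet tools.

#' Write a raster field as a CSV grid
#'
#' One CSV row per grid row `j` (y increasing down the file), `NA` outside
#' the myocardium.
#'
#' @param values per-cell vector (compact order) or a grid matrix from
#'   [field_grid()].
#' @param domain the matching [segmented_domain()] (needed for vectors).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(values, domain, path) {
  g <- if (is.matrix(values)) values else field_grid(values, domain)
  utils::write.table(t(g), path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

#' Write raster fields as a legacy VTK STRUCTURED_POINTS file
#'
#' Cell-centered scalars are written as POINT_DATA on a grid with spacing
#' `h`; values outside the myocardium are written as -9999.
#'
#' @param fields named list of per-cell vectors (compact order) or grid
#'   matrices.
#' @param domain the matching [segmented_domain()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(fields, domain, path) {
  fail_if(is.null(names(fields)) || any(!nzchar(names(fields))),
          "fields must be a named list")
  con <- file(path, "w")
  on.exit(close(con))
  nx <- domain$nx; ny <- domain$ny
  writeLines(c("# vtk DataFile Version 3.0",
               "perfusim field snapshot",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               sprintf("ORIGIN %g %g 0", domain$h / 2, domain$h / 2),
               sprintf("SPACING %g %g 1", domain$h, domain$h),
               sprintf("POINT_DATA %d", nx * ny)), con)
  for (nm in names(fields)) {
    g <- fields[[nm]]
    if (!is.matrix(g)) g <- field_grid(g, domain)
    v <- as.vector(g)           # column-major = x fastest, matching VTK
    v[is.na(v)] <- -9999
    writeLines(c(sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(format(v, trim = TRUE, digits = 7), collapse = " "), con)
  }
  invisible(path)
}
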