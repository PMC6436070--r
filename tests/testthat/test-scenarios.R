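# Scenario-level tests run on a coarsened phantom (h = 1.5 mm) and short
# horizons so the whole file stays fast; figure-level behaviour at the
# published horizons is exercised in test-acceptance.R.

test_that("scenario presets carry the published parameter columns", {
  ch <- scenario_config("healthy")
  expect_null(ch$bc$p_sten)
  expect_equal(ch$params$k_e, 0.002)
  expect_equal(ch$params$P, 0.03)
  expect_equal(ch$params$lambda, 0.25)
  expect_equal(ch$params$D_i, 1e-3)
  expect_equal(ch$params$t_peak, 25)
  expect_equal(ch$recirc$v_out, 1.0)
  expect_equal(ch$recirc$k, 0.02)
  ci <- scenario_config("ischemia")
  expect_equal(ci$bc$p_sten, 1.4)
  cf <- scenario_config("infarct")
  expect_equal(cf$bc$p_sten, 0.4)
  expect_equal(cf$params$lambda, 1.0)
  expect_equal(cf$params$lambda_f, 0.5)
  expect_equal(cf$params$k_f, 7e-4)
  expect_equal(cf$params$k_ef, 1.0)
  expect_equal(cf$params$k_e, 9e-4)
  expect_equal(cf$params$P, 0.025)
  expect_equal(cf$params$D_i, 1e-7)
  expect_equal(cf$t_end, 600)
})

test_that("roi_signal is the volume-fraction weighted sum with additive parts", {
  dom <- make_annulus_phantom(phantom_spec(h = 0.5))
  params <- transport_params(phi = 0.10)
  st <- concentration_state(dom, C_i = 1)
  si <- roi_signal(st, dom$roi_diseased, params, dom)
  expect_equal(si[["total"]], 0.10 * 220 * 0.25)   # = 5.5
  expect_equal(si[["intra"]], si[["total"]])
  st0 <- concentration_state(dom)
  expect_equal(unname(roi_signal(st0, dom$roi_remote, params, dom)),
               rep(0, 4))
  # additivity for random fields, fibrosis weighting included
  set.seed(3)
  n <- length(dom$cells)
  pf <- transport_params(phi = 0.1, lambda = 0.8, lambda_f = 0.5, k_ef = 1)
  stR <- concentration_state(dom, C_i = runif(n), C_e = runif(n),
                             C_f = runif(n))
  roi_fib <- intersect(dom$fibrosis_mask, dom$cells)
  siR <- roi_signal(stR, roi_fib, pf, dom)
  expect_equal(siR[["total"]],
               siR[["intra"]] + siR[["extra"]] + siR[["fibrosis"]])
  expect_gt(siR[["fibrosis"]], 0)
  expect_error(roi_signal(stR, integer(0), pf, dom), "empty ROI")
})

test_that("scenario config round-trips through the flat YAML dialect", {
  cfg <- scenario_config("infarct", h = 1.5, t_end = 42,
                         solver_method = "direct",
                         recirc = list(v_out = 1.2))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(cfg, path)
  back <- read_scenario_config(path)
  expect_identical(back$name, "infarct")
  expect_equal(back$params, cfg$params)
  expect_equal(back$bc, cfg$bc)
  expect_equal(back$recirc, cfg$recirc)
  expect_equal(back$t_end, 42)
  expect_equal(back$phantom$h, 1.5)
})

test_that("installed scenario presets load and match the in-code presets", {
  for (nm in c("healthy", "ischemia", "infarct")) {
    path <- system.file("extdata", "scenarios", paste0(nm, ".yaml"),
                        package = "perfusim")
    expect_true(nzchar(path))
    cfg <- read_scenario_config(path)
    ref <- scenario_config(nm)
    expect_equal(cfg$params, ref$params)
    expect_equal(cfg$bc, ref$bc)
  }
})

run_fast <- function(name, ...) {
  run_scenario(scenario_config(name, h = 1.5, solver_method = "direct", ...))
}

test_that("run_scenario produces a consistent, nonnegative series", {
  res <- run_fast("ischemia", t_end = 30)
  s <- res$series
  expect_true(all(c("t", "SI_remote", "SI_diseased", "C_L", "C_R") %in%
                  names(s)))
  expect_true(all(s$SI_remote >= 0 & s$SI_diseased >= 0))
  expect_equal(s$SI_remote,
               s$SI_intra_remote + s$SI_extra_remote + s$SI_fibrosis_remote)
  expect_equal(max(s$t), 30)
  expect_lt(res$mass_balance$closure, 0.005)
  expect_lte(res$flow$residual, 1e-8)
})

test_that("run_scenario writes series, snapshots and a run log", {
  out <- withr::local_tempdir()
  res <- run_scenario(scenario_config("ischemia", h = 1.5, t_end = 12,
                                      solver_method = "direct",
                                      snapshot_times = 10),
                      out_dir = out)
  expect_true(file.exists(file.path(out, "series.csv")))
  expect_true(file.exists(file.path(out, "pressure.vtk")))
  expect_true(file.exists(file.path(out, "run_log.txt")))
  expect_true(file.exists(file.path(out, "t10_C_i.csv")))
  back <- utils::read.csv(file.path(out, "series.csv"))
  expect_equal(back$SI_remote, res$series$SI_remote, tolerance = 1e-12)
  vtk <- readLines(file.path(out, "pressure.vtk"), n = 4)
  expect_identical(vtk[4], "DATASET STRUCTURED_POINTS")
})

test_that("stage-labelled diagnostics propagate from failing stages", {
  bad <- scenario_config("healthy", phantom = phantom_spec(
    outer_radius = 4, inner_radius = 2, h = 1, roi_cell_counts = c(500, 500)))
  expect_error(run_scenario(bad), "^\\[geometry\\]")
})

test_that("a single-value global sweep reproduces run_scenario exactly", {
  cfg <- scenario_config("infarct", h = 1.5, t_end = 15,
                         solver_method = "direct")
  sw <- sweep_parameter(cfg, "k_f", 7e-4, where = "global")
  ref <- run_scenario(cfg)
  expect_identical(sw$results[[1]]$series, ref$series)
})

test_that("sweep varies the parameter in the diseased ROI only by default", {
  cfg <- scenario_config("infarct", h = 1.5, t_end = 15,
                         solver_method = "direct")
  sw <- sweep_parameter(cfg, "lambda", c(0.25, 1.0))
  p2 <- sw$results[[2]]$config$params
  expect_length(p2$lambda, length(sw$results[[2]]$domain$cells))
  ids <- sw$results[[2]]$domain$cell_id[sw$results[[2]]$domain$roi_diseased]
  expect_true(all(p2$lambda[ids] == 1.0))
  expect_true(all(p2$lambda[-ids] == cfg$params$lambda))
  expect_error(sweep_parameter(cfg, "sigma", 1), "arg")
})
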