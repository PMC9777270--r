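test_that("named scenarios expand to their documented settings", {
  cfg <- scenario_config("robin_immune", rp = rp1, rings = 4, t_end = 1)
  expect_equal(cfg$bc$kind, "robin")
  expect_equal(which(cfg$bc$alpha != 0), immune_influx_species())
  expect_equal(unique(cfg$bc$alpha[cfg$bc$alpha != 0]), 100)
  # alpha * Xhat = 1 for the influx species
  expect_equal(unique(cfg$bc$alpha * cfg$bc$Xhat)[2], 1)
  cfg2 <- scenario_config("source_M_center", rp = rp1)
  expect_equal(species_catalog()$symbol[cfg2$src$species], "M")
  expect_equal(cfg2$src$region, "center")
  d_M <- poroTME:::.reaction_split(matrix(1, 14, 1), rp1)$d[2, 1]
  expect_equal(unname(cfg2$src$magnitude), unname(2 * d_M))
  expect_error(scenario_config("no_such_case"), "unknown scenario")
})

test_that("reference run stays uniform, at equilibrium, and at size d0", {
  cfg <- scenario_config("reference", rp = rp1, rings = 6, t_end = 5,
                         dt = 0.5, output_every = 2.5)
  res <- run_scenario(cfg)
  expect_equal(res$ratios[1], 1)
  expect_lt(max(abs(res$ratios - 1)), 1e-10)
  expect_lt(max(res$spread), 1e-10)
  expect_equal(res$diameter[1], measure_diameter(res$mesh))
  expect_lt(max(abs(res$diameter - 0.01)), 1e-10)
})

test_that("initial center profile elevates M and Tc 11-fold and fades", {
  cfg <- scenario_config("center_MTc_x11", rp = rp1, rings = 6, t_end = 30,
                         dt = 0.5, output_every = 30)
  res <- run_scenario(cfg)
  s0 <- res$summaries[[1]]
  expect_equal(s0$max[2], 11, tolerance = 1e-6)
  expect_equal(s0$max[6], 11, tolerance = 1e-6)
  expect_equal(s0$min[2], 1, tolerance = 1e-6)
  # other species start uniform at the base state
  expect_equal(s0$max[9], 1, tolerance = 1e-12)
  # the elevation decays toward the homeostatic state
  send <- res$summaries[[length(res$summaries)]]
  expect_lt(send$max[2], 11)
  expect_lt(send$max[6], s0$max[6])
})

test_that("outputs are written completely and deterministically", {
  cfg <- scenario_config("reference", rp = rp1, rings = 4, t_end = 2,
                         dt = 0.5, output_every = 1)
  res <- run_scenario(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  write_outputs(res, d1)
  write_outputs(run_scenario(cfg), d2)
  for (f in c("growth_table.csv", "summary.csv", "config_resolved.yaml",
              "final_state.vtk", "run.log"))
    expect_true(file.exists(file.path(d1, f)), info = f)
  tab <- read.csv(file.path(d1, "growth_table.csv"))
  expect_identical(names(tab), c("t", "V", "n", "crude", "linear", "simulated"))
  expect_equal(tab$n[1], 1)
  # reruns are byte-identical
  expect_identical(readLines(file.path(d1, "growth_table.csv")),
                   readLines(file.path(d2, "growth_table.csv")))
  expect_identical(readLines(file.path(d1, "summary.csv")),
                   readLines(file.path(d2, "summary.csv")))
  # summary.csv is a faithful export of the recorded summaries
  summ <- read.csv(file.path(d1, "summary.csv"))
  expect_equal(subset(summ, t == 0)$max, res$summaries[[1]]$max)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("command line interface runs, reports, and rejects bad input", {
  out <- tempfile()
  expect_equal(porotme_cli(c("ode", "--seed", "1", "--t-end", "50",
                             "--growth-table", "--out", out)), 0L)
  tab <- read.csv(out)
  expect_equal(tab$n[1], 1)
  unlink(out)
  mf <- tempfile(fileext = ".vtk")
  expect_equal(suppressMessages(porotme_cli(c("mesh", "--rings", "4",
                                              "--out", mf))), 0L)
  expect_true(file.exists(mf))
  unlink(mf)
  expect_equal(suppressMessages(porotme_cli(c("frobnicate"))), 1L)
  expect_equal(suppressMessages(porotme_cli(c("run", "--scenario", "bogus"))), 1L)
})
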