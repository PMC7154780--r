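test_that("compiled and reference engines agree to float round-off", {
  site <- fixture_site()
  cli <- fixture_climate(1980:1983)
  st <- fixture_state()
  ev <- management_schedule(31.5, 900)
  for (sp in c("picea", "fagus")) {
    p <- default_parameters(sp)
    a <- run_simulation(site, cli, p, st, ev, engine = "cpp")
    b <- run_simulation(site, cli, p, st, ev, engine = "r")
    expect_lt(max(abs(as.matrix(a) - as.matrix(b)) /
                    (abs(as.matrix(b)) + 1e-12)), 1e-10)
  }
})

test_that("a 12-month trajectory matches the independent stage-chain oracle", {
  site <- fixture_site()
  cli <- fixture_climate(1981:1981)
  for (sp in c("picea", "fagus")) {
    p <- default_parameters(sp)
    st <- fixture_state(n = 3000, ws = 170) # overstocked: mortality active
    out <- run_simulation(site, cli, p, st)
    ref <- oracle_run(site, cli, p, st)
    for (col in c("n_trees", "ws", "wf", "wr", "asw", "lai", "dbh", "gpp",
                  "npp", "transpiration", "soil_evap", "interception")) {
      expect_lt(max(abs(out[[col]] - ref[[col]]) /
                      (abs(ref[[col]]) + 1e-12)), 1e-10,
                label = paste(sp, col, "relative error"))
    }
  }
})

test_that("deciduous stands are dormant outside the leaf period", {
  p <- default_parameters("fagus")
  site <- fixture_site()
  cli <- fixture_climate(1980:1981)
  st <- fixture_state()
  out <- run_simulation(site, cli, p, st)
  dormant <- out$month %in% c(12, 1:4)
  expect_true(all(out$gpp[out$year == 1981 & dormant] == 0))
  growing <- out$year == 1981 & out$month %in% 6:9
  expect_true(all(out$gpp[growing] > 0))
  # foliage is restored in the leaf-on month
  expect_gt(out$wf[out$year == 1981 & out$month == 5],
            out$wf[out$year == 1981 & out$month == 4])
})

test_that("an evergreen stand under benign climate grows every month", {
  p <- default_parameters("picea")
  site <- fixture_site(elevation = 600)
  # constant mild climate, always inside the cardinal temperatures
  cli <- data.frame(
    year = rep(1980:1985, each = 12), month = rep(1:12, 6),
    tmin = 8, tmax = 18, prcp = 80, srad = 12, frost_days = 0, co2 = 380
  )
  out <- run_simulation(site, cli, p, fixture_state())
  expect_true(all(out$npp > 0))
})

test_that("horizon 0 returns an empty table and gaps are rejected", {
  p <- default_parameters("picea")
  site <- fixture_site()
  cli <- fixture_climate()
  out <- run_simulation(site, cli, p, fixture_state(), horizon = 0)
  expect_equal(nrow(out), 0)
  gap <- cli[-3, ]
  expect_error(run_simulation(site, gap, p, fixture_state()),
               "climate gap after 1980-02")
})

test_that("restarting from a mid-run snapshot reproduces the trajectory", {
  p <- default_parameters("picea")
  site <- fixture_site()
  cli <- fixture_climate(1980:1981)
  full <- run_simulation(site, cli, p, fixture_state())
  half <- full[12, ]
  st2 <- new_stand_state(half$age, half$n_trees, half$ws, half$wf, half$wr,
                         half$asw)
  tail12 <- run_simulation(site, cli[13:24, ], p, st2)
  expect_equal(as.matrix(tail12), as.matrix(full[13:24, ]),
               ignore_attr = TRUE)
})

test_that("simulation output is bit-reproducible", {
  p <- default_parameters("picea")
  site <- fixture_site()
  cli <- fixture_climate()
  a <- run_simulation(site, cli, p, fixture_state())
  b <- run_simulation(site, cli, p, fixture_state())
  expect_identical(a, b)
})

test_that("monthly water balance closes over a full run", {
  p <- default_parameters("picea")
  site <- fixture_site()
  cli <- fixture_climate(1980:1984)
  st <- fixture_state()
  out <- run_simulation(site, cli, p, st)
  asw_prev <- c(st$asw, out$asw[-nrow(out)])
  residual <- cli$prcp[seq_len(nrow(out))] -
    ((out$asw - asw_prev) + out$interception + out$transpiration +
       out$soil_evap + out$runoff - out$clip)
  expect_lt(max(abs(residual)), 1e-9)
})

test_that("management events trigger in the month their age is reached", {
  p <- default_parameters("picea")
  site <- fixture_site()
  cli <- fixture_climate(1980:1983)
  ev <- management_schedule(31, 800)
  out <- run_simulation(site, cli, p, fixture_state(age = 30, n = 1500), ev)
  # age 31 is reached after 12 months
  expect_equal(out$n_trees[12], 800)
  expect_equal(out$n_trees[11], 1500)
})

test_that("annual aggregation sums fluxes and keeps year-end states", {
  p <- default_parameters("picea")
  site <- fixture_site()
  cli <- fixture_climate(1980:1982)
  out <- run_simulation(site, cli, p, fixture_state())
  ann <- annual_aggregate(out)
  expect_equal(ann$npp[1], sum(out$npp[out$year == 1980]))
  expect_equal(ann$npp_c, ann$npp * 0.5)
  expect_equal(ann$ws[2], out$ws[out$year == 1981 & out$month == 12])
})
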