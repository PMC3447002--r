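test_that("a run is reproducible bit-for-bit under a fixed seed", {
  cfg <- simulation_config(N0 = 800, duration_days = 0.3)
  set.seed(601)
  s1 <- run_simulation(cfg)
  set.seed(601)
  s2 <- run_simulation(cfg)
  expect_identical(s1$transits, s2$transits)
  expect_identical(s1$population, s2$population)
  expect_identical(s1$portals, s2$portals)
})

test_that("zero duration returns the initial state", {
  set.seed(602)
  sim <- run_simulation(simulation_config(N0 = 300, duration_days = 0))
  expect_equal(nrow(sim$population), 1L)
  expect_equal(sim$population$n_cells, 300L)
  expect_equal(sum(is.na(sim$transits$exit_min)), 300L)
})

test_that("cell accounting is conserved every step", {
  set.seed(603)
  sim <- run_simulation(simulation_config(N0 = 1500, duration_days = 0.5,
                                          record_every_min = 0.25))
  p <- sim$population
  # entries - exits = delta N, reconstructed per recording step from the
  # log (entrants are the cells with ids beyond the initial packing)
  entrant <- sim$transits$cell_id > 1500L
  entries <- vapply(p$t_min, function(t)
    sum(entrant & sim$transits$entry_min <= t), integer(1))
  exits <- vapply(p$t_min, function(t)
    sum(!is.na(sim$transits$exit_min) & sim$transits$exit_min <= t),
    integer(1))
  expect_equal(p$n_cells, 1500L + entries - exits)
  # totals agree with the counters
  expect_equal(as.integer(sim$counters$total_entries), entries[length(entries)])
  expect_equal(as.integer(sim$counters$total_exits), exits[length(exits)])
})

test_that("double occupancy resolves within a step except rare crowding", {
  set.seed(604)
  sim <- run_simulation(simulation_config(N0 = 2000, duration_days = 0.5))
  steps <- 0.5 * 1440 / 0.25
  cell_steps <- 2000 * steps
  expect_lt(sim$counters$crowding_exceptions / cell_steps, 0.01)
})

test_that("transit statistics compute means, histograms and censoring", {
  tr <- tibble::tibble(cell_id = 1:200,
                       entry_min = rep(c(100, 2000), 100),
                       exit_min = rep(c(100, 2000), 100) + 720,
                       tagged = FALSE, K_E = 0)
  ts <- transit_statistics(tr, burn_in_h = 0, min_records = 10)
  expect_equal(ts$mean_min, 720)
  expect_equal(ts$mean_h, 12)
  # burn-in excludes the early entries
  ts2 <- transit_statistics(tr, burn_in_h = 10, min_records = 10)
  expect_equal(ts2$n_closed, 100L)
  expect_equal(sum(ts$histogram$probability), 1)
  expect_error(transit_statistics(tr[1:5, ], burn_in_h = 0), "insufficient")
})

test_that("single-portal scenario: retention declines faster with stronger chemotaxis", {
  set.seed(605)
  r0 <- single_portal_scenario(0, n_tagged = 60, D = 6, duration_h = 1.5,
                               N0 = 2500)
  set.seed(605)
  r4 <- single_portal_scenario(4, n_tagged = 60, D = 6, duration_h = 1.5,
                               N0 = 2500)
  expect_true(all(diff(r0$tagged_remaining) <= 0))
  expect_true(all(diff(r4$tagged_remaining) <= 0))
  # without chemotaxis only a slight decline; with K_E = 4 a marked one
  expect_gte(r0$tagged_remaining[nrow(r0)], 40)
  expect_lt(r4$tagged_remaining[nrow(r4)],
            r0$tagged_remaining[nrow(r0)])
})

test_that("tidiers and autoplot return well-formed objects", {
  set.seed(606)
  sim <- run_simulation(simulation_config(N0 = 400, duration_days = 0.1))
  expect_s3_class(tidy(sim), "tbl_df")
  g <- glance(sim)
  expect_equal(g$N0, 400L)
  expect_s3_class(autoplot(sim), "ggplot")
  df <- blob_sites(build_blob(50))
  expect_named(df, c("x", "y", "z", "state", "occupancy"))
  f <- tempfile(fileext = ".tsv")
  write_transit_log(sim, f)
  expect_true(file.exists(f))
  re <- utils::read.delim(f)
  expect_equal(nrow(re), nrow(sim$transits))
  unlink(f)
})
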