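test_that("beam specification validates its physics inputs", {
  s <- beam_spec(nominal_LET = 20)
  expect_s3_class(s, "beam_spec")
  expect_equal(s$events, 1000L)
  expect_error(beam_spec(nominal_LET = 0), "positive")
  expect_error(beam_spec(nominal_LET = 10, mean_energy_per_deposit = -1),
               "positive")
})

test_that("event generation is seeded and dimensionally sound", {
  s <- beam_spec(nominal_LET = 60, events = 300L, seed = 4)
  e1 <- generate_events(s, 100)
  e2 <- generate_events(s, 100)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_equal(attr(e1, "n_events"), 300L)
  expect_true(all(e1$energy > 0))
  expect_true(all(e1$event_id >= 1 & e1$event_id <= 300))
  # deposits lie near the sphere (chord +/- lateral spread)
  r <- sqrt(e1$x^2 + e1$y^2 + e1$z^2)
  expect_lt(max(r), 100 + 6 * s$radial_sigma + 1)
})

test_that("deposit count and energy follow LET and the mean chord", {
  s <- beam_spec(nominal_LET = 100, mean_energy_per_deposit = 40,
                 events = 4000L, seed = 9)
  ev <- generate_events(s, 50)
  # E[deposits per primary] = (LET / E_dep) * mean chord (4r/3)
  expected <- (100 / 40) * (4 * 50 / 3)
  expect_equal(nrow(ev) / 4000, expected, tolerance = 0.05)
  expect_equal(mean(ev$energy), 40, tolerance = 0.05)
})

test_that("event TSV round-trips and rejects malformed rows", {
  s <- beam_spec(nominal_LET = 30, events = 50L, seed = 2)
  ev <- generate_events(s, 60)
  f <- tempfile(fileext = ".tsv")
  write_events(ev, f)
  ev2 <- read_events(f)
  expect_equal(ev2$event_id, ev$event_id)
  expect_equal(ev2$energy, ev$energy, tolerance = 1e-9)
  expect_equal(ev2$x, ev$x, tolerance = 1e-9)
  writeLines(c("event_id\tx_nm\ty_nm\tz_nm\tenergy_eV",
               "1\t0\t0\t0\t10", "2\t1\t1\t1\t-5"), f)
  expect_error(read_events(f), "malformed event row")
  writeLines("a\tb", f)
  expect_error(read_events(f), "must have columns")
  unlink(f)
})

test_that("scoring conserves energy and respects scoring spheres", {
  beads <- data.frame(bead_id = 0:2, x = c(0, 5, 10), y = 0, z = 0,
                      scoring_radius_nm = 1)
  ev <- data.frame(event_id = c(1L, 1L, 2L),
                   x = c(0.2, 4.8, 20), y = 0, z = 0,
                   energy = c(10, 20, 30))
  st <- score_events(ev, beads)
  expect_s3_class(st, "score_table")
  expect_equal(st$total_energy, 60)
  expect_equal(st$assigned_energy, 30)    # third deposit is out of reach
  expect_equal(st$unassigned_energy, 30)
  expect_equal(st$assigned_energy + st$unassigned_energy,
               st$total_energy)
  got <- as.data.frame(st$scores[order(st$scores$bead_id), ])
  expect_equal(got$bead_id, c(0L, 1L))
  expect_equal(got$energy, c(10, 20))
})

test_that("ties go to the lowest bead id and scores reset across events", {
  beads <- data.frame(bead_id = c(7L, 3L), x = c(-1, 1), y = 0, z = 0,
                      scoring_radius_nm = 2)
  ev <- data.frame(event_id = c(1L, 2L), x = 0, y = 0, z = 0,
                   energy = c(5, 6))
  st <- score_events(ev, beads)
  expect_equal(st$scores$bead_id, c(3L, 3L))  # equidistant -> lower id
  expect_equal(nrow(st$scores), 2)            # one row per event
  expect_equal(st$scores$energy, c(5, 6))
})

test_that("scoring accumulates within an event", {
  beads <- data.frame(bead_id = 0L, x = 0, y = 0, z = 0,
                      scoring_radius_nm = 3)
  ev <- data.frame(event_id = 1L, x = c(0, 1, -1), y = 0, z = 0,
                   energy = c(1, 2, 4))
  st <- score_events(ev, beads)
  expect_equal(nrow(st$scores), 1)
  expect_equal(st$scores$energy, 7)
})

test_that("scoring handles empty inputs and does not mutate arguments", {
  beads <- fixture_cg(4, "linear")
  beads_nm <- data.frame(bead_id = beads$bead_id, x = beads$x / 10,
                         y = beads$y / 10, z = beads$z / 10,
                         scoring_radius_nm = beads$scoring_radius / 10)
  empty <- data.frame(event_id = integer(), x = numeric(),
                      y = numeric(), z = numeric(), energy = numeric())
  st <- score_events(empty, beads_nm)
  expect_equal(st$total_energy, 0)
  before <- data.table::copy(beads_nm)
  ev <- data.frame(event_id = 1L, x = 0, y = 0, z = 0, energy = 1)
  invisible(score_events(ev, beads_nm))
  expect_identical(as.data.frame(before), as.data.frame(beads_nm))
})

test_that("absorbed dose follows E/m for a water sphere", {
  # manual computation: E(J) / (rho * 4/3 pi r^3)
  r_m <- 500e-9
  manual <- 2e5 * 1.602176634e-19 / (1000 * 4 / 3 * pi * r_m^3)
  expect_equal(absorbed_dose(c(1e5, 1e5), 500), manual,
               tolerance = 1e-12)
  expect_equal(absorbed_dose(data.frame(energy = c(1e5, 1e5)), 500),
               manual, tolerance = 1e-12)
  # linear in energy
  expect_equal(absorbed_dose(2e5, 500), 2 * absorbed_dose(1e5, 500))
})
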