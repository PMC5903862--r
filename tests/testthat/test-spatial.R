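test_that("centering puts the first-frame centroid at the origin", {
  cells <- data.frame(lineage = 1:2, node = 1, t0 = 4, t1 = 10,
                      x = c(30, 10), y = c(5, 5), class = "S")
  cent <- center_tracks(make_tracks(cells))
  f0 <- cent[cent$time_hpi == 4, ]
  expect_equal(sort(f0$x_um), c(-10, 10))
  expect_equal(mean(f0$x_um), 0)
  expect_equal(mean(f0$y_um), 0)
  # idempotence
  expect_equal(as.data.frame(center_tracks(cent)), as.data.frame(cent))
})

test_that("axis convention flips are applied when centering", {
  man <- experiment_manifest("exp1", duration_h = 10, founder_count = 1L,
                             axis_posterior = "-x", axis_dorsal = "-y")
  df <- data.frame(experiment_id = "exp1", lineage_id = c(1, 2),
                   node_index = 1, time_hpi = 4, x_um = c(2, -2),
                   y_um = c(3, -3), z_um = 0, cell_class = "S")
  cent <- center_tracks(track_table(df, man))
  expect_equal(sort(cent$x_um), c(-2, 2))
  expect_equal(attr(cent, "manifest")$axis_posterior, "+x")
  # the cell at +2 anterior becomes -2 posterior after the flip
  expect_equal(cent$x_um[cent$lineage_id == 1], -2)
})

test_that("polar angle matches an atan2 oracle on random points", {
  expect_equal(polar_angle(5, 0), 0)
  expect_equal(polar_angle(0, 3), 90)
  expect_equal(polar_angle(-2, -2), 225)
  expect_error(polar_angle(0, 0), "origin")
  set.seed(1)
  x <- stats::rnorm(1000); y <- stats::rnorm(1000)
  oracle <- (atan2(y, x) * 180 / pi + 360) %% 360
  expect_equal(polar_angle(x, y), oracle, tolerance = 1e-9)
  expect_true(all(polar_angle(x, y) >= 0 & polar_angle(x, y) < 360))
})

test_that("quadrants are half-open 90-degree sectors centered on the axes", {
  expect_equal(quadrant_of(0, 10), "dorsal")
  expect_equal(quadrant_of(10, 0), "posterior")
  expect_equal(quadrant_of(-10, 0), "anterior")
  expect_equal(quadrant_of(0, -10), "ventral")
  expect_equal(quadrant_of(1, 1), "dorsal")      # exactly 45 degrees
  expect_equal(quadrant_of(1, -1), "posterior")  # exactly 315 degrees
  set.seed(2)
  x <- stats::rnorm(500); y <- stats::rnorm(500)
  expect_true(all(quadrant_of(x, y) %in%
                    c("anterior", "posterior", "dorsal", "ventral")))
})

test_that("quadrant distribution fractions sum to one and flag empties", {
  ev <- data.frame(time_hpi = c(10, 10, 10, 10),
                   x_um = c(5, -5, 0, 0), y_um = c(0, 0, 5, -5))
  q <- division_quadrant_distribution(ev, c(0, 60))
  expect_equal(unname(q$fractions), rep(0.25, 4))
  expect_equal(q$polar_fraction, 0.5)
  only_d <- division_quadrant_distribution(
    data.frame(time_hpi = 10, x_um = 0, y_um = 7), c(0, 60))
  expect_equal(unname(only_d$fractions["dorsal"]), 1)
  empty <- division_quadrant_distribution(ev, c(90, 100))
  expect_true(empty$empty)
  expect_equal(empty$n, 0L)
})

test_that("laterality counts ipsilateral progeny by hand-checkable fractions", {
  # one anterior founder (x < 0); the 5 progeny alive at 60 hpi sit at
  # x = -1, +1, +2, -3, -2 -> ipsilateral fraction 3/5
  cells <- data.frame(
    lineage = 1, node = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
    t0 = c(4, 10.25, 10.25, 20.25, 20.25, 20.25, 20.25, 30.25, 30.25),
    t1 = c(10, 20, 20, 30, 60, 60, 60, 60, 60),
    x = c(-2, -1, -2, -3, -1, 1, 2, -3, -2), y = 1, class = "S")
  man <- default_manifest(founder_count = 1L)
  f <- build_forest(make_tracks(cells, man))
  lat <- progeny_laterality(f, axis = "AP", t_assess = 60)
  ant <- lat[lat$side == "anterior", ]
  expect_equal(ant$n_progeny, 5L)
  # x is already the anterior side coordinate (negative = anterior)
  expect_equal(ant$ipsilateral_fraction, 0.6)

  # progeny frozen at the founder position are fully ipsilateral
  stay <- build_forest(simple_division_tracks())
  l2 <- progeny_laterality(stay, axis = "DV", t_assess = 40)
  expect_equal(l2$ipsilateral_fraction[l2$side == "dorsal"], 1)
})

test_that("clone cohesion keeps simulated progeny mostly ipsilateral", {
  fs <- small_cohort_forests()
  lat <- do.call(rbind, c(
    lapply(fs, progeny_laterality, axis = "AP", t_assess = 60),
    lapply(fs, progeny_laterality, axis = "DV", t_assess = 60)))
  pooled <- sum(lat$ipsilateral_fraction * lat$n_progeny, na.rm = TRUE) /
    sum(lat$n_progeny[!is.na(lat$ipsilateral_fraction)])
  expect_gt(pooled, 0.55)
  expect_lt(pooled, 0.85)
})

test_that("division radii by category order SM/MM outside HH", {
  fs <- small_cohort_forests()
  d <- division_table(fs)
  d <- d[d$parent_class == "S", ]
  map <- division_location_map(d)
  r_hh <- map$median[map$category == "HH"]
  r_per <- stats::median(sqrt(d$x_um^2 + d$y_um^2)[d$category %in%
                                                     c("SM", "MM")])
  expect_gt(r_per, r_hh)
  one <- division_location_map(data.frame(category = "HH", x_um = 0.5,
                                          y_um = 0, time_hpi = 50))
  expect_equal(one$median, 0.5)
})

test_that("late divisions concentrate in the polar sectors", {
  fs <- small_cohort_forests()
  d <- division_table(fs)
  d <- d[d$parent_class == "S", ]
  late <- division_quadrant_distribution(d, c(60, Inf))
  expect_gt(late$polar_fraction, 0.5)
  # the hair-cell-producing divisions carry the dorsoventral bias
  late_hh <- division_quadrant_distribution(d[d$category == "HH", ],
                                            c(60, Inf))
  expect_gt(late_hh$polar_fraction, 0.55)
})
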