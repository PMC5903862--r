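test_that("toy-state features match printed hand values", {
  # founder at (0,10), one M at (0,-2), one H at (3,10): center (0,0)
  cells <- data.frame(lineage = 1:3, node = 1, t0 = 4, t1 = 10,
                      x = c(0, 0, 3), y = c(10, -2, 10),
                      class = c("S", "M", "H"))
  man <- default_manifest(founder_count = 3L)
  f <- build_forest(make_tracks(cells, man))
  v <- extract_features(f, 1, 1, 6)
  expect_equal(v$absolute_distance_to_center, 10)
  expect_equal(v$polar_angle, 90)
  expect_equal(v$minimum_distance_to_m, 12)
  expect_equal(v$minimum_distance_to_h, 3)
  expect_equal(v$number_of_total_cells, 3)
  expect_equal(v$number_of_h_cells_10um, 1)
  expect_equal(v$number_of_m_cells_10um, 0)
  expect_equal(v$number_of_m_cells_20um, 1)
  expect_equal(v$cell_generation, 0)
  expect_equal(v$time_to_last_division, 2)          # founder: since start
  expect_equal(v$movement_distance_since_last_division, 0)
  expect_equal(v$movement_angle_to_last_division, 0)
  expect_equal(v$founder_cell_type, "S")
  # subject is not the furthest cell? furthest is H at sqrt(109) > 10
  expect_equal(v$normalized_distance_to_center, 10 / sqrt(109))
  # when the subject is furthest, the normalized distance is 1
  v3 <- extract_features(f, 3, 1, 6)
  expect_equal(v3$normalized_distance_to_center, 1)
})

test_that("class-absence sentinels are applied and flagged", {
  cells <- data.frame(lineage = 1:2, node = 1, t0 = 4, t1 = 10,
                      x = c(0, 5), y = 0, class = c("S", "S"))
  f <- build_forest(make_tracks(cells, default_manifest(founder_count = 2L)))
  v <- extract_features(f, 2, 1, 6)
  expect_equal(v$minimum_distance_to_h, 100)
  expect_equal(v$average_distance_to_m, 100)
  expect_true(v$sentinel_used)
  expect_equal(v$minimum_distance_to_s, 5)
  v2 <- extract_features(f, 2, 1, 6,
                         feature_config(sentinel_distance = 60))
  expect_equal(v2$minimum_distance_to_h, 60)
})

test_that("configuration switches move the center and the angle vertex", {
  cells <- data.frame(lineage = 1:2, node = 1, t0 = 4, t1 = 10,
                      x = c(0, 6), y = 0, class = "S")
  f <- build_forest(make_tracks(cells, default_manifest(founder_count = 2L)))
  # fixed center: distances measured from the organ-frame origin
  v_fix <- extract_features(f, 2, 1, 6)
  expect_equal(v_fix$absolute_distance_to_center, 6)
  # per-frame centroid sits at (3, 0): both cells are 3 um from it
  v_cen <- extract_features(f, 2, 1, 6,
                            feature_config(center = "frame_centroid"))
  expect_equal(v_cen$absolute_distance_to_center, 3)

  # vertex at the last-division site: angle between the displacement since
  # the anchor and the anchor-to-center direction
  tab <- simple_division_tracks()   # daughter 2 at (-3, 1), parent end (0, 1)
  fd <- build_forest(tab)
  v <- extract_features(fd, 1, 2, 30,
                        feature_config(angle_vertex = "last_division"))
  u <- c(-3, 0); w <- c(0, -1)      # displacement; anchor to origin
  expect_equal(v$movement_angle_to_last_division,
               acos(sum(u * w) / (sqrt(sum(u^2)) * 1)) * 180 / pi)
})

test_that("features equal an independent brute-force oracle on random states", {
  fs <- small_cohort_forests()
  set.seed(9)
  checked <- 0
  for (rep in 1:100) {
    f <- fs[[sample(length(fs), 1)]]
    tr <- as.data.frame(f$tracks)
    t_pick <- sample(unique(tr$time_hpi), 1)
    state <- neuromast_state(f, t_pick)
    i <- sample(nrow(state), 1)
    v <- extract_features(f, state$lineage_id[i], state$node_index[i],
                          t_pick)
    anchor <- nmregen:::last_division_anchor(f, state$lineage_id[i],
                                             state$node_index[i])
    o <- brute_force_features(
      state, i, anchor$x, anchor$y, anchor$time,
      unname(f$founder_class[as.character(state$lineage_id[i])]),
      f$manifest$founder_count, t_pick, state$node_index[i])
    for (nm in FEATURE_NAMES) {
      if (is.numeric(o[[nm]])) {
        expect_equal(v[[nm]], o[[nm]], tolerance = 1e-9,
                     info = paste(nm, "at", t_pick))
      } else {
        expect_identical(v[[nm]], o[[nm]])
      }
    }
    checked <- checked + 1
  }
  expect_equal(checked, 100)
})

test_that("radius counts are monotone and tables carry labels and entities", {
  fs <- small_cohort_forests()
  ft <- build_feature_table(fs, task = "division")
  for (cl in c("h", "m", "s")) {
    c10 <- ft[[paste0("number_of_", cl, "_cells_10um")]]
    c20 <- ft[[paste0("number_of_", cl, "_cells_20um")]]
    c30 <- ft[[paste0("number_of_", cl, "_cells_30um")]]
    expect_true(all(c10 <= c20 & c20 <= c30))
    expect_true(all(c30 <= ft[[paste0("number_of_", cl, "_cells")]]))
  }
  num_cols <- FEATURE_NAMES[FEATURE_NAMES != "founder_cell_type"]
  expect_false(any(!is.finite(as.matrix(ft[num_cols]))))
  expect_true(all(ft$label %in% c("SS", "HH", "MM", "SM")))
  # one row per division at the default window
  d <- division_table(fs)
  expect_equal(nrow(ft), sum(d$parent_class == "S"))
  expect_equal(length(unique(ft$entity)), nrow(ft))
})

test_that("clone-task rows span recording start to first division", {
  tab <- simple_division_tracks()
  f <- build_forest(tab)
  ft <- build_feature_table(list(f), task = "clone")
  one <- ft[ft$entity == "exp1/1", ]
  expect_equal(nrow(one), length(seq(4, 19, by = 0.25)))
  expect_equal(unique(one$label), "S")
  expect_no_error(build_feature_table(list(f), task = "division",
                                      config = feature_config()))
})

test_that("rotation leaves invariant features unchanged and rotates angles", {
  fs <- small_cohort_forests()
  f <- fs[[1]]
  theta <- 30 * pi / 180
  tr <- as.data.frame(f$tracks)
  rot <- tr
  rot$x_um <- cos(theta) * tr$x_um - sin(theta) * tr$y_um
  rot$y_um <- sin(theta) * tr$x_um + cos(theta) * tr$y_um
  f2 <- build_forest(track_table(rot, f$manifest))
  t_pick <- sort(unique(tr$time_hpi))[100]
  state <- neuromast_state(f, t_pick)
  i <- which.max(state$node_index)
  v1 <- extract_features(f, state$lineage_id[i], state$node_index[i], t_pick)
  v2 <- extract_features(f2, state$lineage_id[i], state$node_index[i], t_pick)
  invariant <- setdiff(FEATURE_NAMES,
                       c("polar_angle", "x_coordinate", "y_coordinate",
                         "founder_cell_type"))
  for (nm in invariant)
    expect_equal(v2[[nm]], v1[[nm]], tolerance = 1e-6, info = nm)
  expect_equal((v1$polar_angle + 30) %% 360, v2$polar_angle,
               tolerance = 1e-6)
})
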