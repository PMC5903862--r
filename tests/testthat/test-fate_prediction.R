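test_that("mcc matches the closed-form on anchors and random matrices", {
  expect_equal(mcc(10, 10, 0, 0), 1)
  expect_equal(mcc(0, 0, 10, 10), -1)
  expect_equal(mcc(3, 2, 1, 1), 5 / 12)
  # zero-denominator convention
  expect_equal(mcc(5, 0, 0, 0), 0)
  expect_equal(mcc(0, 7, 0, 0), 0)
  set.seed(10)
  for (i in 1:10000) {
    cm <- as.list(stats::rpois(4, 5))
    names(cm) <- c("tp", "tn", "fp", "fn")
    if (sum(unlist(cm)) == 0) cm$tp <- 1
    den <- with(cm, (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    oracle <- if (den == 0) 0 else
      with(cm, (tp * tn - fp * fn) / sqrt(den))
    expect_equal(mcc(cm), oracle)
  }
})

test_that("training is deterministic, separable data fit perfectly, and a
           single-class set errors", {
  set.seed(11)
  n <- 120
  x <- as.data.frame(matrix(stats::rnorm(n * 4), n, 4))
  y <- ifelse(x[[1]] > 0, "a", "b")
  m1 <- train_forest(x, y, seed = 3)
  m2 <- train_forest(x, y, seed = 3)
  p1 <- stats::predict(m1, data = x, num.threads = 1)$predictions
  p2 <- stats::predict(m2, data = x, num.threads = 1)$predictions
  expect_identical(p1, p2)
  expect_equal(mean(p1 == y), 1)
  expect_error(train_forest(x, rep("a", n)), "single class")
  expect_error(train_forest(x, y, n_trees = 0), "n_trees")
})

test_that("label-shuffled training gives out-of-bag accuracy near chance", {
  set.seed(12)
  n <- 300
  x <- as.data.frame(matrix(stats::rnorm(n * 5), n, 5))
  y <- factor(rep(c("a", "b"), each = n / 2))
  m <- train_forest(x, sample(y), seed = 4)
  oob_acc <- 1 - m$prediction.error
  expect_lt(abs(oob_acc - 0.5), 0.12)
})

test_that("round-robin evaluation has no leakage and nails separable tasks", {
  # synthetic feature table: 6 experiments, label fully determined by one
  # feature; all other features noise
  set.seed(13)
  rows <- do.call(rbind, lapply(1:6, function(e) {
    n <- 40
    lab <- rep(c("HH", "SM"), n / 2)
    ft <- as.data.frame(matrix(stats::rnorm(n * 32), n, 32))
    names(ft) <- FEATURE_NAMES[FEATURE_NAMES != "founder_cell_type"][1:31]
    ft$normalized_distance_to_center <-
      ifelse(lab == "HH", stats::runif(n, 0, 0.4), stats::runif(n, 0.6, 1))
    ft$founder_cell_type <- "S"
    cbind(data.frame(experiment_id = paste0("e", e),
                     entity = paste0("e", e, "_", seq_len(n)),
                     label = lab, stringsAsFactors = FALSE), ft)
  }))
  task <- prediction_task("division", "HH", c("SM", "MM"))
  ev <- round_robin_evaluate(rows, task, n_trees = 100, seed = 5)
  expect_equal(length(ev$folds), 6L)
  expect_equal(ev$mcc, 1)
  expect_equal(ev$n_correct, ev$n_entities)
  # every entity is predicted in exactly one fold
  expect_equal(sort(ev$entities$entity), sort(rows$entity))
  # the informative feature dominates the importance ranking
  expect_equal(names(ev$importance)[1], "normalized_distance_to_center")
  expect_lt(ev$importance[["absolute_time_hpi"]],
            ev$importance[[1]] / 10)
})

test_that("bootstrap over identical test sets has zero sd and is reproducible", {
  fe <- list(
    a = data.frame(entity = c("x", "y"), truth = c("HH", "SM/MM"),
                   pred = c("HH", "SM/MM"), stringsAsFactors = FALSE),
    b = data.frame(entity = c("u", "v"), truth = c("HH", "SM/MM"),
                   pred = c("HH", "SM/MM"), stringsAsFactors = FALSE))
  b1 <- bootstrap_mcc(fe, "HH", B = 10, sample_size = 10, seed = 2)
  expect_equal(b1$sd, 0)
  expect_equal(b1$mean, 1)
  fe$b$pred <- c("SM/MM", "HH")
  b2 <- bootstrap_mcc(fe, "HH", B = 15, sample_size = 15, seed = 2)
  b3 <- bootstrap_mcc(fe, "HH", B = 15, sample_size = 15, seed = 2)
  expect_identical(b2, b3)
  expect_true(all(b2$replicates >= -1 & b2$replicates <= 1))
})

test_that("ties at entity aggregation are scored as incorrect", {
  ents <- nmregen:::aggregate_entities(
    entity = c("e1", "e1", "e2"),
    truth = c("HH", "HH", "SM/MM"),
    pred_rows = c("HH", "SM/MM", "SM/MM"),
    positive_label = "HH", negative_label = "SM/MM")
  expect_true(is.na(ents$pred[ents$entity == "e1"]))
  cm <- nmregen:::confusion_counts(ents$truth, ents$pred, "HH")
  expect_equal(cm$fn, 1)  # the tied HH entity counts against the positive
  expect_equal(cm$tn, 1)
})

test_that("folds with single-class training are skipped with a warning", {
  set.seed(14)
  rows <- do.call(rbind, lapply(1:3, function(e) {
    n <- 10
    lab <- if (e == 1) rep("SM", n) else rep(c("HH", "SM"), n / 2)
    ft <- as.data.frame(matrix(stats::rnorm(n * 31), n, 31))
    names(ft) <- FEATURE_NAMES[FEATURE_NAMES != "founder_cell_type"][1:31]
    ft$founder_cell_type <- "S"
    cbind(data.frame(experiment_id = paste0("e", e),
                     entity = paste0("e", e, "_", seq_len(n)),
                     label = lab, stringsAsFactors = FALSE), ft)
  }))
  # held-out folds 2 and 3 train on data including fold 1 (all SM), fine;
  # fold 1's training set has both classes too, so force the failure by
  # making folds 2 and 3 single-class as well
  rows$label[rows$experiment_id != "e1"] <- "HH"
  task <- prediction_task("division", "HH", "SM")
  expect_warning(ev <- round_robin_evaluate(rows, task, n_trees = 20,
                                            seed = 1),
                 "single-class")
  expect_true("e1" %in% ev$skipped_folds || length(ev$skipped_folds) > 0)
})
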