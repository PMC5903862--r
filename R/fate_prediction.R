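# Random-forest fate prediction: Matthews correlation, bagged-tree
# training (via ranger), leave-one-experiment-out (round-robin)
# cross-validation with entity-level majority voting, bootstrapped MCC,
# and out-of-bag permutation feature importance.

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the
#' balanced binary-classification score in `[-1, 1]`: +1 for a perfect
#' prediction, 0 for a random one, -1 for a completely incorrect one. If
#' any factor of the denominator is zero the score is 0 by the standard
#' convention.
#'
#' @param tp,tn,fp,fn Confusion-matrix counts; alternatively pass a list
#'   or named vector with those elements as `tp`.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn) && (is.list(tp) || length(tp) == 4L)) {
    cm <- tp
    tp <- cm[["tp"]]; tn <- cm[["tn"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]
  }
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn >= 1)
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# ties/NA predictions are scored as incorrect (conservative)
confusion_counts <- function(truth, pred, positive) {
  list(tp = sum(truth == positive & !is.na(pred) & pred == positive),
       tn = sum(truth != positive & !is.na(pred) & pred != positive),
       fp = sum(truth != positive & (is.na(pred) | pred == positive)),
       fn = sum(truth == positive & (is.na(pred) | pred != positive)))
}

#' Define a binary prediction task
#'
#' The clone-level tasks compare clone types (SH vs SM, S vs SH, S vs SM);
#' the division-level tasks compare division categories with SM and MM
#' merged (HH vs SM/MM, SS vs HH, SS vs SM/MM).
#'
#' @param level `"clone"` or `"division"`.
#' @param positive Label(s) forming the positive class.
#' @param negative Label(s) forming the negative class (several labels are
#'   merged, e.g. `c("SM", "MM")`).
#' @return A list of class `nm_task`.
#' @export
prediction_task <- function(level = c("clone", "division"),
                            positive, negative) {
  level <- match.arg(level)
  if (length(intersect(positive, negative)))
    stop("positive and negative classes overlap", call. = FALSE)
  structure(list(level = level, positive = positive, negative = negative,
                 positive_label = paste(positive, collapse = "/"),
                 negative_label = paste(negative, collapse = "/")),
            class = "nm_task")
}

#' The six prediction tasks of the fate analysis
#'
#' @return Named list of `nm_task` objects: `SH_vs_SM`, `S_vs_SH`,
#'   `S_vs_SM` (clone level), `HH_vs_SMMM`, `SS_vs_HH`, `SS_vs_SMMM`
#'   (division level).
#' @export
standard_tasks <- function() {
  list(
    SH_vs_SM = prediction_task("clone", "SH", "SM"),
    S_vs_SH = prediction_task("clone", "S", "SH"),
    S_vs_SM = prediction_task("clone", "S", "SM"),
    HH_vs_SMMM = prediction_task("division", "HH", c("SM", "MM")),
    SS_vs_HH = prediction_task("division", "SS", "HH"),
    SS_vs_SMMM = prediction_task("division", "SS", c("SM", "MM"))
  )
}

task_rows <- function(feature_table, task) {
  ft <- feature_table[feature_table$label %in% c(task$positive,
                                                 task$negative), ,
                      drop = FALSE]
  ft$y <- ifelse(ft$label %in% task$positive, task$positive_label,
                 task$negative_label)
  ft
}

feature_frame <- function(ft) {
  x <- ft[FEATURE_NAMES]
  x$founder_cell_type <- factor(x$founder_cell_type, levels = c("S", "M"))
  x
}

#' Train the bagged-tree random forest
#'
#' A bagged ensemble of decision trees on the 32 features (200 trees,
#' `sqrt(32)` candidate features per split, unlimited depth), reproducible
#' for a fixed seed.
#'
#' @param x Data.frame of the 32 features (see [FEATURE_NAMES]).
#' @param y Class labels (coerced to factor; at least two classes).
#' @param n_trees Number of trees.
#' @param seed RNG seed for the ensemble.
#' @param importance `"none"` or `"permutation"` (out-of-bag permutation
#'   importance).
#' @return A fitted `ranger` model.
#' @export
train_forest <- function(x, y, n_trees = 200, seed = 1,
                         importance = "none") {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("training set contains a single class", call. = FALSE)
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  ranger::ranger(x = x, y = y, num.trees = n_trees,
                 mtry = floor(sqrt(ncol(x))),
                 importance = importance,
                 seed = seed, num.threads = 1,
                 respect.unordered.factors = "order")
}

# majority vote over a cell's row predictions; exact ties are counted as
# incorrect (prediction set to NA, scored against the truth)
aggregate_entities <- function(entity, truth, pred_rows, positive_label,
                               negative_label) {
  out <- do.call(rbind, lapply(split(seq_along(entity), entity), function(ix) {
    votes <- table(factor(pred_rows[ix],
                          levels = c(positive_label, negative_label)))
    pred <- if (votes[1] == votes[2]) NA_character_ else
      names(votes)[which.max(votes)]
    data.frame(entity = entity[ix[1]], truth = truth[ix[1]],
               pred = pred, n_rows = length(ix), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Round-robin (leave-one-experiment-out) evaluation
#'
#' For each of the N experiments, trains the forest on the other N-1 and
#' predicts the held-out experiment's rows; row predictions are aggregated
#' to entities (clones or divisions) by majority vote, pooled into an
#' entity-level confusion matrix, and scored by MCC with a bootstrap over
#' experiment-level test sets. Folds whose training data contain a single
#' class are skipped with a warning and recorded.
#'
#' @param feature_table An `nm_feature_table` from [build_feature_table()].
#' @param task An `nm_task`.
#' @param n_trees,seed Forest parameters.
#' @param bootstrap_B,bootstrap_size Bootstrap replicates and experiments
#'   per replicate.
#' @return A list of class `nm_evaluation`: `entities` (pooled entity
#'   predictions), `confusion`, `mcc`, `n_correct`, `n_entities`,
#'   `bootstrap` (mean, sd, replicates), `importance`, `folds`,
#'   `skipped_folds`.
#' @export
round_robin_evaluate <- function(feature_table, task, n_trees = 200,
                                 seed = 1, bootstrap_B = 15,
                                 bootstrap_size = 15) {
  ft <- task_rows(feature_table, task)
  experiments <- unique(ft$experiment_id)
  if (length(experiments) < 3L)
    stop("round-robin evaluation needs at least 3 experiments",
         call. = FALSE)

  fold_entities <- list()
  skipped <- character()
  for (ex in experiments) {
    train <- ft[ft$experiment_id != ex, , drop = FALSE]
    test <- ft[ft$experiment_id == ex, , drop = FALSE]
    if (!nrow(test)) next
    if (length(unique(train$y)) < 2L) {
      warning("fold ", ex, " skipped: single-class training set",
              call. = FALSE)
      skipped <- c(skipped, ex)
      next
    }
    stopifnot(!any(test$entity %in% train$entity))  # leakage guard
    model <- train_forest(feature_frame(train), train$y, n_trees = n_trees,
                          seed = seed)
    pred <- stats::predict(model, data = feature_frame(test),
                           num.threads = 1)$predictions
    fold_entities[[ex]] <- aggregate_entities(
      test$entity, test$y, as.character(pred),
      task$positive_label, task$negative_label)
  }
  if (!length(fold_entities))
    stop("no evaluable folds", call. = FALSE)

  entities <- do.call(rbind, fold_entities)
  rownames(entities) <- NULL
  cm <- confusion_counts(entities$truth, entities$pred, task$positive_label)
  boot <- bootstrap_mcc(fold_entities, task$positive_label,
                        B = bootstrap_B, sample_size = bootstrap_size,
                        seed = seed)
  imp_model <- train_forest(feature_frame(ft), ft$y, n_trees = n_trees,
                            seed = seed, importance = "permutation")
  imp <- sort(ranger::importance(imp_model), decreasing = TRUE)

  structure(list(task = task, entities = entities, confusion = cm,
                 mcc = mcc(cm),
                 n_correct = sum(entities$truth == entities$pred,
                                 na.rm = TRUE),
                 n_entities = nrow(entities),
                 bootstrap = boot,
                 importance = imp,
                 folds = names(fold_entities),
                 skipped_folds = skipped),
            class = "nm_evaluation")
}

#' Bootstrapped MCC over experiment-level test sets
#'
#' Each replicate draws `sample_size` experiment-level test sets with
#' replacement, pools their entity-level predictions and computes the MCC;
#' the mean and standard deviation over `B` replicates are returned.
#'
#' @param fold_entities List (one element per experiment) of entity
#'   prediction data.frames with columns `truth`, `pred`.
#' @param positive_label The positive class label.
#' @param B Number of bootstrap replicates.
#' @param sample_size Experiments drawn per replicate.
#' @param seed RNG seed.
#' @return List with `mean`, `sd`, `replicates`.
#' @export
bootstrap_mcc <- function(fold_entities, positive_label, B = 15,
                          sample_size = 15, seed = 1) {
  fold_entities <- fold_entities[vapply(fold_entities, nrow,
                                        integer(1)) > 0]
  if (!length(fold_entities))
    stop("all test sets are empty", call. = FALSE)
  reps <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    vapply(seq_len(B), function(b) {
      pick <- sample(length(fold_entities), sample_size, replace = TRUE)
      pooled <- do.call(rbind, fold_entities[pick])
      mcc(confusion_counts(pooled$truth, pooled$pred, positive_label))
    }, numeric(1))
  })
  list(mean = mean(reps), sd = stats::sd(reps), replicates = reps)
}

#' Out-of-bag permutation feature importance
#'
#' @param model A `ranger` model fitted with `importance = "permutation"`
#'   (e.g. from [train_forest()]); alternatively an `nm_evaluation`, whose
#'   stored importance is returned.
#' @return Named numeric vector, descending.
#' @export
feature_importance <- function(model) {
  if (inherits(model, "nm_evaluation")) return(model$importance)
  sort(ranger::importance(model), decreasing = TRUE)
}

#' @export
print.nm_evaluation <- function(x, ...) {
  cat(sprintf(paste0("<nm_evaluation> %s vs %s (%s level): MCC %.3f ",
                     "(bootstrap %.3f +/- %.3f), %d/%d entities correct\n"),
              x$task$positive_label, x$task$negative_label, x$task$level,
              x$mcc, x$bootstrap$mean, x$bootstrap$sd,
              x$n_correct, x$n_entities))
  invisible(x)
}
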