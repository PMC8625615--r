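test_that("50 subjects split 30/10/10 per fold with the partition properties", {
  subjects <- sprintf("P%02d", 1:50)
  folds <- make_subject_folds(subjects, k = 5, seed = 3)
  expect_length(folds, 5)
  tests <- list()
  for (f in folds) {
    expect_length(f$train_subjects, 30)
    expect_length(f$val_subjects, 10)
    expect_length(f$test_subjects, 10)
    # no subject in two sets of one fold
    expect_length(intersect(f$train_subjects, f$val_subjects), 0)
    expect_length(intersect(f$train_subjects, f$test_subjects), 0)
    expect_length(intersect(f$val_subjects, f$test_subjects), 0)
    expect_setequal(c(f$train_subjects, f$val_subjects, f$test_subjects),
                    subjects)
    tests[[length(tests) + 1]] <- f$test_subjects
  }
  # the 5 test sets partition the subjects
  all_test <- unlist(tests)
  expect_length(all_test, 50)
  expect_setequal(all_test, subjects)
  expect_error(make_subject_folds(subjects, k = 1), "at least 2")
})

test_that("the 45-epoch learning-rate sequence is 1e-3/1e-4/1e-5 in 15s", {
  expect_equal(lr_schedule(45), rep(c(1e-3, 1e-4, 1e-5), each = 15))
  expect_equal(lr_schedule(5, initial = 0.1, drop = 0.5, every = 2),
               c(0.1, 0.1, 0.05, 0.05, 0.025))
})

test_that("confusion metrics: perfect and chance classifiers", {
  perfect <- diag(c(10, 12, 8))
  rep_p <- confusion_metrics(perfect)
  expect_equal(rep_p$clip_accuracy, 100)
  expect_equal(unname(rep_p$per_class_accuracy), rep(100, 3))
  expect_equal(rep_p$sensitivity, 100)
  expect_equal(rep_p$specificity, 100)
  # constant single-class predictor on a balanced set
  constant <- matrix(0, 3, 3)
  constant[, 1] <- 10
  rep_c <- confusion_metrics(constant)
  expect_equal(rep_c$clip_accuracy, 100 / 3, tolerance = 1e-10)
})

test_that("macro sensitivity/specificity match a one-vs-rest oracle", {
  conf <- matrix(c(42, 7, 3,
                   9, 31, 12,
                   4, 10, 38), 3, 3, byrow = TRUE)
  got <- confusion_metrics(conf)
  want <- oracle_macro_sens_spec(conf)
  expect_equal(got$sensitivity, want[["sensitivity"]], tolerance = 1e-12)
  expect_equal(got$specificity, want[["specificity"]], tolerance = 1e-12)
  expect_equal(got$clip_accuracy, 100 * sum(diag(conf)) / sum(conf),
               tolerance = 1e-12)
  expect_equal(rowSums(got$confusion), rowSums(conf), ignore_attr = TRUE)
})

test_that("video voting uses a strict threshold", {
  mk_video <- function(id, label, n_correct, n_total) {
    data.frame(video_id = id, label = label,
               pred = c(rep(label, n_correct),
                        rep(setdiff(c("neutral", "low", "high"), label)[1],
                            n_total - n_correct)))
  }
  # 6 of 10 correct at threshold 0.5: correct
  v <- mk_video("v1", "low", 6, 10)
  expect_equal(evaluate_videos(v, 0.5)$total, 100)
  # exactly 50% at threshold 0.5: NOT correct (strict inequality)
  v2 <- mk_video("v2", "high", 5, 10)
  expect_equal(evaluate_videos(v2, 0.5)$total, 0)
})

test_that("video voting totals match a hand-computed enumeration", {
  fracs <- c(v1 = 0.3, v2 = 0.45, v3 = 0.5, v4 = 0.55, v5 = 0.8, v6 = 1.0)
  labels <- c("neutral", "neutral", "low", "low", "high", "high")
  preds <- do.call(rbind, lapply(seq_along(fracs), function(i) {
    n <- 20
    nc <- round(fracs[i] * n)
    data.frame(video_id = names(fracs)[i], label = labels[i],
               pred = c(rep(labels[i], nc), rep("none", n - nc)))
  }))
  out <- evaluate_videos(preds, thresholds = c(0.4, 0.5, 0.6))
  # > 0.4: v2 v3 v4 v5 v6 -> 5/6; > 0.5: v4 v5 v6 -> 3/6; > 0.6: v5 v6 -> 2/6
  expect_equal(out$total, 100 * c(5, 3, 2) / 6, tolerance = 1e-12)
  expect_equal(out$neutral, 100 * c(1, 0, 0) / 2, tolerance = 1e-12)
  expect_equal(out$low, 100 * c(2, 1, 0) / 2, tolerance = 1e-12)
  expect_equal(out$high, 100 * c(2, 2, 2) / 2, tolerance = 1e-12)
})

test_that("zero training epochs leave the parameters untouched", {
  ds <- make_worked_fixture()
  model <- build_stress_model(model_config(frames_per_clip = 8L, seed = 11L))
  before <- stressclip:::params_snapshot(stressclip:::model_params(model))
  fit <- train_model(model, ds$clips, ds$manifest,
                     fold = list(train_subjects = c("S01", "S02", "S03")),
                     epochs = 0L, schedule = numeric(0), seed = 1)
  after <- stressclip:::params_snapshot(stressclip:::model_params(fit$model))
  expect_identical(before, after)
  expect_equal(nrow(fit$history), 0)
})

test_that("one training step on the fixture runs end to end and is finite", {
  ds <- make_worked_fixture()
  model <- build_stress_model(model_config(frames_per_clip = 8L, seed = 12L))
  sub <- which(ds$manifest$subject_id %in% c("S01", "S02") &
               ds$manifest$clip %% 2 == 1)
  t0 <- proc.time()
  fit <- train_model(model, ds$clips[sub],
                     ds$manifest[sub, , drop = FALSE],
                     fold = list(train_subjects = c("S01", "S02")),
                     epochs = 1L, schedule = 1e-3, batch_clips = 3L,
                     seed = 5)
  elapsed <- (proc.time() - t0)[["elapsed"]]
  expect_true(all(is.finite(fit$history$total)))
  expect_gt(fit$history$total[1], 0)
  expect_lt(elapsed, 60)
  # an empty training partition is an error
  expect_error(train_model(model, ds$clips, ds$manifest,
                           fold = list(train_subjects = "nobody"),
                           epochs = 1L),
               "empty training partition")
})

test_that("evaluation refuses an empty test set", {
  model <- build_stress_model(model_config(frames_per_clip = 2L, seed = 13L))
  expect_error(evaluate_clips(model, list()), "empty test set")
})
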