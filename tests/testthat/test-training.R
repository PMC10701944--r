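# Objective arithmetic, the early-stopping / LR-decay controller,
# distillation and finetuning mechanics, and the TPE search.

test_that("weighted binary cross-entropy matches its closed forms", {
  y <- c(rep(0, 99), 1)
  expect_equal(pos_weight_from_labels(y), 99)
  # p = y exactly: clamped loss is ~1e-7-scale
  expect_lt(weighted_bce(y, y, 99), 1e-4)
  # single case at p = 0.5 with weight 2
  expect_equal(weighted_bce(0.5, 1, 2), 2 * log(2))
  # pos_weight 1 equals the unweighted loss on random batches
  set.seed(8)
  for (i in 1:20) {
    p <- runif(50); yy <- rbinom(50, 1, 0.5)
    plain <- mean(-(yy * log(p) + (1 - yy) * log(1 - p)))
    expect_equal(weighted_bce(p, yy, 1), plain, tolerance = 1e-12)
  }
  expect_error(weighted_bce(0.5, 1, 0), "positive")
})

test_that("stopping and decay traces follow the patience rules exactly", {
  # improvement at 1,2 then three stagnant epochs: stop after 5, best is 2
  tr <- schedule_trace(c(1.0, 0.9, 0.95, 0.96, 0.97), lr = 1e-3)
  expect_equal(tr$stopped_after, 5L)
  expect_equal(tr$best_epoch, 2L)
  # the decay takes effect the epoch after each stagnant one (patience 1)
  expect_equal(tr$lr_used, c(1e-3, 1e-3, 1e-3, 1e-4, 1e-5))
  # strictly decreasing losses: never stops, never decays
  tr2 <- schedule_trace(seq(1, 0.1, by = -0.1), lr = 1e-2)
  expect_equal(tr2$stopped_after, 10L)
  expect_equal(tr2$lr_used, rep(1e-2, 10))
  expect_equal(tr2$best_epoch, 10L)
  # monotone increase from the start: stop after 3 stagnant epochs
  tr3 <- schedule_trace(c(1.0, 1.1, 1.2, 1.3, 1.4), lr = 1)
  expect_equal(tr3$stopped_after, 4L)
  expect_equal(tr3$lr_used, c(1, 1, 0.1, 0.01))
  expect_equal(tr3$best_epoch, 1L)
})

test_that("the live training loop reproduces the controller bookkeeping", {
  sim <- small_sim(80)
  sq <- build_sequences(sim$events, sim$cohort, max_visits = 6)
  ids <- names(sq$sequences)
  m <- fit_retain(sq, ids[1:50], ids[51:80], retain_config(4, 4),
                  train_config(batch_size = 25, max_epochs = 12, lr = 1e-2,
                               seed = 3))
  h <- m$history
  replay <- schedule_trace(h$val_loss, lr = 1e-2)
  expect_equal(h$lr, replay$lr_used)
  expect_equal(m$best_epoch, replay$best_epoch)
  expect_equal(nrow(h), replay$stopped_after)
})

test_that("distillation pulls the student onto the teacher", {
  sim <- generate_ehr(sim_config(n_persons = 64, n_concepts = 20,
                                 visits_per_person = 4, concepts_per_visit = 2,
                                 beta = c(C0001 = 2, C0002 = -1.5), seed = 19))
  sq <- build_sequences(sim$events, sim$cohort, max_visits = 10)
  ids <- names(sq$sequences)
  fm <- scale_numeric(binarize_windows(sim$events, sim$cohort, windows = 365))
  teacher_model <- suppressWarnings(
    fit_lasso(fm$matrix, sim$cohort$outcome, lambda = 0.01, seed = 1))
  teacher <- predict(teacher_model, fm$matrix)
  names(teacher) <- fm$row_ids

  stu0 <- fit_transformer(sq, ids, NULL,
                          transformer_config(8, 2, 1, 16,
                                             conv_channels = c(8, 8)),
                          train_config(batch_size = 64, max_epochs = 1,
                                       lr = 1e-3, seed = 2))
  # zero epochs: unchanged
  same <- distill(stu0, teacher, sq, ids, epochs = 0)
  expect_identical(same$params, stu0$params)

  stu <- distill(stu0, teacher, sq, ids, epochs = 220, lr = 5e-3,
                 batch_size = 64, seed = 3)
  r <- cor(predict(stu, sq, ids, type = "link"),
           qlogis(pmin(pmax(teacher[ids], 1e-7), 1 - 1e-7)),
           method = "spearman")
  expect_gt(r, 0.95)

  # constant teacher: student logit variance shrinks
  const <- setNames(rep(0.3, length(ids)), ids)
  stu_c <- distill(stu0, const, sq, ids, epochs = 150, lr = 5e-3,
                   batch_size = 64, seed = 4)
  expect_lt(var(predict(stu_c, sq, ids, type = "link")),
            var(predict(stu0, sq, ids, type = "link")))
})

test_that("finetuning loss is linear in alpha and hits its endpoints", {
  sim <- small_sim(60)
  sq <- build_sequences(sim$events, sim$cohort, max_visits = 6)
  ids <- names(sq$sequences)
  stu <- fit_transformer(sq, ids, NULL,
                         transformer_config(6, 2, 1, 8,
                                            conv_channels = c(4, 4)),
                         train_config(batch_size = 60, max_epochs = 1,
                                      lr = 1e-3, seed = 5))
  teacher <- setNames(runif(length(ids), 0.05, 0.9), ids)
  l <- vapply(c(0, 0.25, 0.5, 1), function(a)
    finetune_loss(stu, sq, ids, teacher, a), numeric(1))
  # endpoints: alpha 0 is the weighted label loss alone
  expect_equal(l[1], weighted_bce(predict(stu, sq, ids), sq$outcome[ids],
                                  stu$pos_weight), tolerance = 1e-10)
  # linearity
  expect_equal(l[2], 0.75 * l[1] + 0.25 * l[4], tolerance = 1e-10)
  expect_equal(l[3], 0.5 * l[1] + 0.5 * l[4], tolerance = 1e-10)
  expect_error(finetune(stu, sq, ids, teacher, alpha = 1.5), "alpha")
})

test_that("alpha = 1 finetuning converges to the teacher", {
  sim <- small_sim(60, seed = 23)
  sq <- build_sequences(sim$events, sim$cohort, max_visits = 6)
  ids <- names(sq$sequences)
  stu <- fit_transformer(sq, ids, NULL,
                         transformer_config(8, 2, 1, 16,
                                            conv_channels = c(8, 8)),
                         train_config(batch_size = 60, max_epochs = 1,
                                      lr = 1e-3, seed = 6))
  fm <- scale_numeric(binarize_windows(sim$events, sim$cohort, windows = 365))
  tm <- suppressWarnings(
    fit_lasso(fm$matrix, sim$cohort$outcome, lambda = 0.01, seed = 1))
  teacher <- predict(tm, fm$matrix); names(teacher) <- fm$row_ids
  ft <- finetune(stu, sq, ids, teacher[ids], alpha = 1, epochs = 250,
                 lr = 5e-3, batch_size = 60, seed = 7)
  r <- cor(predict(ft, sq, ids), teacher[ids], method = "spearman")
  expect_gt(r, 0.95)
})

test_that("refit replays the recorded schedule on combined data", {
  sim <- small_sim(100)
  sq <- build_sequences(sim$events, sim$cohort, max_visits = 6)
  ids <- names(sq$sequences)
  m <- fit_retain(sq, ids[1:60], ids[61:100], retain_config(4, 4),
                  train_config(batch_size = 30, max_epochs = 8, lr = 5e-3,
                               seed = 9))
  rf <- refit_final(m, sq, ids)
  expect_equal(nrow(rf$history), m$best_epoch)
  expect_equal(rf$history$lr,
               m$history$lr[seq_len(m$best_epoch)])
  # deterministic under the stored seed
  rf2 <- refit_final(m, sq, ids)
  expect_identical(predict(rf, sq, ids), predict(rf2, sq, ids))
  # training reduced the loss relative to the initial model state
  init <- fit_retain(sq, ids, NULL, retain_config(4, 4),
                     train_config(batch_size = 30, max_epochs = 1, lr = 1e-12,
                                  seed = 9))
  expect_lte(weighted_bce(predict(rf, sq, ids), sq$outcome[ids], rf$pos_weight),
             weighted_bce(predict(init, sq, ids), sq$outcome[ids],
                          init$pos_weight))
})

test_that("tpe search returns the best trial and survives failures", {
  # one-point space
  one <- list(x = hp_choice(list(3)))
  res <- tpe_search(one, function(cfg) cfg$x, n_iter = 1, seed = 1)
  expect_equal(res$best$x, 3)
  expect_equal(nrow(res$trials), 1L)

  # best equals the max over the log
  space <- list(x = hp_uniform(-2, 2))
  res2 <- tpe_search(space, function(cfg) -(cfg$x - 1)^2, n_iter = 25, seed = 2)
  expect_equal(res2$best_value, max(res2$trials$validation_auc, na.rm = TRUE))

  # beats random guessing: within the top decile of a dense scan
  scan <- -(seq(-2, 2, length.out = 1000) - 1)^2
  expect_gte(res2$best_value, quantile(scan, 0.9))

  # deterministic under seed
  res3 <- tpe_search(space, function(cfg) -(cfg$x - 1)^2, n_iter = 25, seed = 2)
  expect_identical(res2$trials$x, res3$trials$x)

  # failing objective marks the trial and continues
  flaky <- function(cfg) if (cfg$x < 0) stop("boom") else cfg$x
  res4 <- suppressWarnings(tpe_search(space, flaky, n_iter = 15, seed = 3))
  expect_true(any(res4$trials$status == "failed"))
  expect_true(res4$best$x >= 0)

  # random backend works and respects mixed spaces
  mixed <- list(lr = hp_loguniform(1e-4, 1e-1), k = hp_quniform(1, 5),
                act = hp_choice(c("a", "b")))
  res5 <- tpe_search(mixed, function(cfg) log10(cfg$lr) + cfg$k, n_iter = 10,
                     seed = 4, backend = "random")
  expect_true(all(res5$trials$lr >= 1e-4 & res5$trials$lr <= 1e-1))
  expect_true(all(res5$trials$k == round(res5$trials$k)))
})
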