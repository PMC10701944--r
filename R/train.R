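## Training machinery shared by both attention architectures: class-weighted
## objective, Adam, early stopping (patience 3 on validation loss) with
## learning-rate decay (factor 10, patience 1), reverse distillation from a
## linear teacher, mixed-loss finetuning, and schedule replay for the final
## refit on train+validation.

#' Training configuration
#'
#' @param batch_size minibatch size (default 512).
#' @param max_epochs maximum epochs.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (default 3).
#' @param lr initial learning rate (Adam).
#' @param lr_reduce_factor divide the learning rate by this after a stagnant
#'   epoch (default 10).
#' @param lr_reduce_patience stagnant epochs before each reduction
#'   (default 1).
#' @param weight_decay decoupled L2 decay applied to weight matrices
#'   (embeddings included; biases and gains exempt).
#' @param seed seed controlling initialization order, shuffling and dropout.
#' @return a `train_config`.
#' @export
train_config <- function(batch_size = 512L, max_epochs = 20L,
                         early_stop_patience = 3L, lr = 1e-2,
                         lr_reduce_factor = 10, lr_reduce_patience = 1L,
                         weight_decay = 0, seed = 1L) {
  stopifnot(batch_size > 0, max_epochs > 0, early_stop_patience >= 1,
            lr > 0, lr_reduce_factor > 1, lr_reduce_patience >= 1,
            weight_decay >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr = lr, lr_reduce_factor = lr_reduce_factor,
                 lr_reduce_patience = as.integer(lr_reduce_patience),
                 weight_decay = weight_decay,
                 seed = as.integer(seed)), class = "train_config")
}

## ---- early-stopping / LR-decay controller ---------------------------------

controller_init <- function(lr0, es_patience, lr_patience, factor) {
  list(lr = lr0, best = Inf, best_epoch = 0L, stall_es = 0L, stall_lr = 0L,
       es_patience = es_patience, lr_patience = lr_patience, factor = factor,
       stop = FALSE, epoch = 0L)
}

## One validation observation; returns the state with the LR to use NEXT
## epoch, whether to stop, and whether the current weights are the new best.
controller_update <- function(st, val_loss) {
  st$epoch <- st$epoch + 1L
  if (val_loss < st$best) {
    st$best <- val_loss
    st$best_epoch <- st$epoch
    st$stall_es <- 0L
    st$stall_lr <- 0L
    st$improved <- TRUE
  } else {
    st$improved <- FALSE
    st$stall_es <- st$stall_es + 1L
    st$stall_lr <- st$stall_lr + 1L
    if (st$stall_lr >= st$lr_patience) {
      st$lr <- st$lr / st$factor
      st$stall_lr <- 0L
    }
    if (st$stall_es >= st$es_patience) st$stop <- TRUE
  }
  st
}

#' Replay the early-stopping and LR-decay rules on a scripted loss sequence
#'
#' Pure bookkeeping used by the training loop, exposed so the stopping rule
#' (patience 3) and the decay rule (factor 10 after 1 stagnant epoch) can be
#' verified on hand-written validation-loss traces.
#'
#' @param val_losses validation losses per epoch.
#' @param lr initial learning rate.
#' @param early_stop_patience,lr_reduce_patience,lr_reduce_factor the rules.
#' @return list: `lr_used` (LR in effect during each executed epoch),
#'   `stopped_after` (last executed epoch), `best_epoch` (weights restored
#'   from).
#' @export
schedule_trace <- function(val_losses, lr = 1e-3, early_stop_patience = 3L,
                           lr_reduce_patience = 1L, lr_reduce_factor = 10) {
  st <- controller_init(lr, early_stop_patience, lr_reduce_patience,
                        lr_reduce_factor)
  lr_used <- numeric(0)
  for (v in val_losses) {
    lr_used <- c(lr_used, st$lr)
    st <- controller_update(st, v)
    if (st$stop) break
  }
  list(lr_used = lr_used, stopped_after = st$epoch, best_epoch = st$best_epoch)
}

## ---- losses ----------------------------------------------------------------

## loss spec: list(kind = "wbce"|"distill"|"mixed", pos_weight, alpha,
## teacher = named logit vector)
nn_loss_grad <- function(out, batch, loss) {
  y <- batch$y
  n <- length(y)
  if (loss$kind == "wbce") {
    l <- weighted_bce(out$p, y, loss$pos_weight)
    dlogit <- d_wbce_dlogit(clamp_prob(out$p), y, loss$pos_weight)
  } else if (loss$kind == "distill") {
    lt <- loss$teacher[batch$ids]
    l <- mean((out$logit - lt)^2)
    dlogit <- 2 * (out$logit - lt) / n
  } else {  # mixed
    lt <- loss$teacher[batch$ids]
    l_t <- mean((out$logit - lt)^2)
    l_y <- weighted_bce(out$p, y, loss$pos_weight)
    l <- loss$alpha * l_t + (1 - loss$alpha) * l_y
    dlogit <- loss$alpha * 2 * (out$logit - lt) / n +
      (1 - loss$alpha) * d_wbce_dlogit(clamp_prob(out$p), y, loss$pos_weight)
  }
  list(loss = l, dlogit = dlogit)
}

nn_forward_by_type <- function(type, params, batch, config, train_mode) {
  if (type == "retain") retain_forward_pass(params, batch, config, train_mode)
  else transformer_forward_pass(params, batch, config, train_mode)
}

nn_backward_by_type <- function(type, params, batch, config, cache, dlogit) {
  if (type == "retain") retain_backward_pass(params, batch, config, cache, dlogit)
  else transformer_backward_pass(params, batch, config, cache, dlogit)
}

eval_loss <- function(type, params, config, batches, loss) {
  tot <- 0; n <- 0
  for (batch in batches) {
    out <- nn_forward_by_type(type, params, batch, config, FALSE)
    lg <- nn_loss_grad(out, batch, loss)
    tot <- tot + lg$loss * batch$B
    n <- n + batch$B
  }
  tot / n
}

## Core loop. lr_schedule (vector) overrides the controller: run exactly
## length(lr_schedule) epochs at those rates with no validation monitoring.
train_nn <- function(type, params, config, seqs, train_ids, val_ids,
                     tc, loss, age_max, lr_schedule = NULL) {
  set.seed(tc$seed)
  adam <- adam_init(params)
  val_batches <- if (length(val_ids))
    make_batches(seqs, val_ids, tc$batch_size, age_max) else NULL
  st <- controller_init(tc$lr, tc$early_stop_patience, tc$lr_reduce_patience,
                        tc$lr_reduce_factor)
  best_params <- params
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  n_epochs <- if (!is.null(lr_schedule)) length(lr_schedule) else tc$max_epochs
  for (epoch in seq_len(n_epochs)) {
    lr_now <- if (!is.null(lr_schedule)) lr_schedule[epoch] else st$lr
    batches <- make_batches(seqs, train_ids, tc$batch_size, age_max,
                            shuffle = TRUE)
    tot <- 0; n <- 0
    for (batch in batches) {
      out <- nn_forward_by_type(type, params, batch, config, TRUE)
      lg <- nn_loss_grad(out, batch, loss)
      if (!is.finite(lg$loss))
        stop_arg("non-finite training loss at epoch ", epoch,
                 "; reduce the learning rate")
      grads <- nn_backward_by_type(type, params, batch, config, out$cache,
                                   lg$dlogit)
      upd <- adam_step(params, grads, adam, lr_now,
                       weight_decay = tc$weight_decay %||% 0)
      params <- upd$params; adam <- upd$state
      tot <- tot + lg$loss * batch$B; n <- n + batch$B
    }
    train_loss <- tot / n
    val_loss <- NA_real_
    if (!is.null(val_batches)) {
      val_loss <- eval_loss(type, params, config, val_batches, loss)
      st <- controller_update(st, val_loss)
      if (st$improved) best_params <- params
    }
    history <- rbind(history, data.frame(epoch = epoch, train_loss = train_loss,
                                         val_loss = val_loss, lr = lr_now))
    if (!is.null(val_batches) && st$stop) break
  }
  if (is.null(val_batches)) best_params <- params
  list(params = best_params, history = history,
       best_epoch = if (is.null(val_batches)) n_epochs else st$best_epoch)
}

new_nn_model <- function(type, params, config, seqs, pos_weight, tc, history,
                         age_max, best_epoch) {
  structure(list(type = type, params = params, config = config,
                 concept_map = seqs$concept_map, pos_weight = pos_weight,
                 train_config = tc, history = history, age_max = age_max,
                 best_epoch = best_epoch),
            class = c(paste0(type, "_model"), "ehr_nn_model"))
}

#' @export
print.ehr_nn_model <- function(x, ...) {
  cat(sprintf("<%s> %d concepts, %d epochs trained (best %d), pos_weight %.2f\n",
              class(x)[1], nrow(x$concept_map), nrow(x$history),
              x$best_epoch, x$pos_weight))
  invisible(x)
}

#' Predict risk scores from a fitted attention model
#'
#' @param object a fitted `retain_model`, `transformer_model` or
#'   `sard_model`.
#' @param seqs a `visit_sequences` built with the same concept map.
#' @param ids observation ids to score (default: all).
#' @param type `"response"` for probabilities, `"link"` for logits.
#' @param batch_size scoring batch size.
#' @param ... unused.
#' @return named score vector.
#' @export
predict.ehr_nn_model <- function(object, seqs, ids = NULL,
                                 type = c("response", "link"),
                                 batch_size = 512L, ...) {
  type <- match.arg(type)
  ids <- ids %||% names(seqs$sequences)
  batches <- make_batches(seqs, ids, batch_size, object$age_max)
  out <- do.call(c, unname(lapply(batches, function(batch) {
    o <- nn_forward_by_type(object$type, object$params, batch, object$config,
                            FALSE)
    setNames(if (type == "link") o$logit else o$p, batch$ids)
  })))
  out[ids]
}

#' Fit the two-level-attention recurrent model
#'
#' Class-weighted training with early stopping on the validation fold; the
#' positive-class weight is the negative:positive ratio of the training
#' labels.
#'
#' @param seqs a `visit_sequences`.
#' @param train_ids,val_ids observation ids for training and validation
#'   monitoring (`val_ids = NULL` disables early stopping).
#' @param config a [retain_config()].
#' @param tc a [train_config()].
#' @return a `retain_model`.
#' @export
fit_retain <- function(seqs, train_ids, val_ids = NULL,
                       config = retain_config(), tc = train_config()) {
  fit_nn("retain", seqs, train_ids, val_ids, config, tc)
}

#' Fit the transformer risk model
#'
#' @inheritParams fit_retain
#' @param config a [transformer_config()].
#' @return a `transformer_model`.
#' @export
fit_transformer <- function(seqs, train_ids, val_ids = NULL,
                            config = transformer_config(), tc = train_config()) {
  fit_nn("transformer", seqs, train_ids, val_ids, config, tc)
}

fit_nn <- function(type, seqs, train_ids, val_ids, config, tc,
                   lr_schedule = NULL) {
  y <- seqs$outcome[train_ids]
  pw <- pos_weight_from_labels(y)
  age_max <- max(seqs$static[train_ids, "age_years"])
  set.seed(tc$seed)
  params <- if (type == "retain")
    retain_init(nrow(seqs$concept_map), config, tc$seed)
  else transformer_init(nrow(seqs$concept_map), config, tc$seed)
  res <- train_nn(type, params, config, seqs, train_ids, val_ids, tc,
                  list(kind = "wbce", pos_weight = pw), age_max, lr_schedule)
  res$history$phase <- "train"
  new_nn_model(type, res$params, config, seqs, pw, tc, res$history, age_max,
               res$best_epoch)
}

#' Reverse distillation: train a student to match a linear teacher
#'
#' Minimizes the mean squared error between student and teacher logits on
#' the training rows. Teacher scores of exactly 0 or 1 are clamped before
#' the logit.
#'
#' @param student a fitted or freshly initialized `ehr_nn_model`.
#' @param teacher_scores named probability vector from the teacher (e.g.
#'   [predict.lasso_model()]) covering `train_ids`.
#' @param seqs a `visit_sequences`.
#' @param train_ids observation ids to distill on.
#' @param epochs distillation epochs (0 returns the student unchanged).
#' @param lr learning rate.
#' @param batch_size minibatch size.
#' @param seed seed.
#' @return the distilled student model.
#' @export
distill <- function(student, teacher_scores, seqs, train_ids, epochs = 10L,
                    lr = 1e-2, batch_size = 512L, seed = 1L) {
  if (epochs == 0L) return(student)
  teacher_logit <- logit(clamp_prob(teacher_scores))
  tc <- train_config(batch_size = batch_size, max_epochs = epochs, lr = lr,
                     seed = seed)
  res <- train_nn(student$type, student$params, student$config, seqs,
                  train_ids, NULL, tc,
                  list(kind = "distill", teacher = teacher_logit),
                  student$age_max)
  student$params <- res$params
  res$history$phase <- "distill"
  student$history <- rbind(student$history, res$history)
  student
}

#' Finetune a distilled student on labels plus teacher predictions
#'
#' Loss is `alpha * MSE(student logit, teacher logit) + (1 - alpha) *
#' weighted_bce(labels)`: `alpha = 0` is pure label training, `alpha = 1`
#' pure distillation; high alpha constrains the student to stay near the
#' linear teacher.
#'
#' @inheritParams distill
#' @param ids observation ids to finetune on (the validation fold in the
#'   reverse-distillation recipe).
#' @param alpha mixing factor in `[0, 1]`.
#' @return the finetuned model.
#' @export
finetune <- function(student, seqs, ids, teacher_scores, alpha = 0.5,
                     epochs = 10L, lr = 1e-3, batch_size = 512L, seed = 1L) {
  if (alpha < 0 || alpha > 1) stop_arg("alpha must lie in [0, 1]")
  if (epochs == 0L) return(student)
  teacher_logit <- logit(clamp_prob(teacher_scores))
  tc <- train_config(batch_size = batch_size, max_epochs = epochs, lr = lr,
                     seed = seed)
  res <- train_nn(student$type, student$params, student$config, seqs, ids,
                  NULL, tc,
                  list(kind = "mixed", teacher = teacher_logit, alpha = alpha,
                       pos_weight = student$pos_weight),
                  student$age_max)
  student$params <- res$params
  res$history$phase <- "finetune"
  student$history <- rbind(student$history, res$history)
  student$finetune_settings <- list(alpha = alpha, epochs = epochs, lr = lr)
  student
}

#' Evaluate the finetuning loss at fixed parameters
#'
#' @inheritParams finetune
#' @return scalar mixed loss over `ids`.
#' @export
finetune_loss <- function(student, seqs, ids, teacher_scores, alpha) {
  teacher_logit <- logit(clamp_prob(teacher_scores))
  batches <- make_batches(seqs, ids, 512L, student$age_max)
  eval_loss(student$type, student$params, student$config, batches,
            list(kind = "mixed", teacher = teacher_logit, alpha = alpha,
                 pos_weight = student$pos_weight))
}

#' Fit a reverse-distilled transformer (SARD recipe)
#'
#' Distills a transformer student toward a linear teacher's predictions on
#' the training fold, then finetunes on the validation fold with the mixed
#' label/teacher loss.
#'
#' @param seqs a `visit_sequences`.
#' @param train_ids,val_ids fold observation ids.
#' @param teacher_scores named teacher probabilities covering both folds.
#' @param config a [transformer_config()].
#' @param tc a [train_config()] (its seed and batch size drive both phases).
#' @param alpha finetuning mixing factor.
#' @param distill_epochs,finetune_epochs phase lengths.
#' @param finetune_lr finetuning learning rate.
#' @return a `sard_model` (a `transformer_model` with distillation history).
#' @export
fit_sard <- function(seqs, train_ids, val_ids, teacher_scores,
                     config = transformer_config(), tc = train_config(),
                     alpha = 0.5, distill_epochs = 10L, finetune_epochs = 10L,
                     finetune_lr = NULL) {
  y <- seqs$outcome[train_ids]
  pw <- pos_weight_from_labels(y)
  age_max <- max(seqs$static[train_ids, "age_years"])
  set.seed(tc$seed)
  params <- transformer_init(nrow(seqs$concept_map), config, tc$seed)
  student <- new_nn_model("transformer", params, config, seqs, pw, tc,
                          data.frame(epoch = integer(), train_loss = numeric(),
                                     val_loss = numeric(), lr = numeric(),
                                     phase = character()),
                          age_max, 0L)
  student <- distill(student, teacher_scores[train_ids], seqs, train_ids,
                     epochs = distill_epochs, lr = tc$lr,
                     batch_size = tc$batch_size, seed = tc$seed)
  student <- finetune(student, seqs, val_ids, teacher_scores[val_ids],
                      alpha = alpha, epochs = finetune_epochs,
                      lr = finetune_lr %||% (tc$lr / 10),
                      batch_size = tc$batch_size, seed = tc$seed + 1L)
  class(student) <- c("sard_model", class(student))
  student$alpha <- alpha
  student$teacher_scores <- teacher_scores
  student
}

#' Refit a model on train+validation with the recorded schedule
#'
#' Replays the learning-rate schedule (and epoch count) that the fitted
#' model's training run used, on the union of training and validation rows,
#' without validation monitoring.
#'
#' @param model a fitted `ehr_nn_model`.
#' @param seqs a `visit_sequences`.
#' @param ids observation ids of the combined training data.
#' @return a refitted model of the same class.
#' @export
refit_final <- function(model, seqs, ids) {
  if (inherits(model, "sard_model")) {
    # replay both phases on the combined rows with the recorded settings
    n_dist <- sum(model$history$phase == "distill")
    fs <- model$finetune_settings
    teacher <- model$teacher_scores %||%
      stop_arg("sard model carries no teacher scores; refit via fit_sard")
    refit <- fit_sard(seqs, ids, ids, teacher, model$config,
                      model$train_config, alpha = fs$alpha,
                      distill_epochs = n_dist, finetune_epochs = fs$epochs,
                      finetune_lr = fs$lr)
    return(refit)
  }
  hist <- model$history[model$history$phase == "train", ]
  n_ep <- if (model$best_epoch > 0) model$best_epoch else nrow(hist)
  schedule <- hist$lr[seq_len(max(n_ep, 1L))]
  refit <- fit_nn(model$type, seqs, ids, NULL, model$config,
                  model$train_config, lr_schedule = schedule)
  class(refit) <- class(model)
  refit$refit_schedule <- schedule
  refit
}
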