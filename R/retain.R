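## RETAIN-style two-level attention: visit embeddings feed two bidirectional
## LSTMs; one yields a scalar (softmax) visit attention, the other a
## per-coordinate tanh gate; the attended context drives a logistic output.
## Age, sex and the scaled visit time are concatenated to each visit
## embedding.

#' Configuration for the two-level-attention recurrent model
#'
#' @param embedding_dim concept embedding width.
#' @param lstm_hidden_dim hidden width of each LSTM direction.
#' @param dropout dropout rate on visit embeddings during training.
#' @param include_static concatenate scaled age/sex (and visit time) to each
#'   visit embedding.
#' @return a `retain_config`.
#' @export
retain_config <- function(embedding_dim = 16L, lstm_hidden_dim = 16L,
                          dropout = 0, include_static = TRUE) {
  if (embedding_dim <= 0 || lstm_hidden_dim <= 0) stop_arg("dims must be positive")
  structure(list(embedding_dim = as.integer(embedding_dim),
                 lstm_hidden_dim = as.integer(lstm_hidden_dim),
                 dropout = dropout, include_static = include_static),
            class = "retain_config")
}

retain_dim_in <- function(config) {
  config$embedding_dim + if (config$include_static) 3L else 1L
}

retain_init <- function(n_concepts, config, seed = 1L) {
  set.seed(seed)
  d <- config$embedding_dim
  h <- config$lstm_hidden_dim
  D <- retain_dim_in(config)
  p <- list(E = matrix(rnorm(n_concepts * d, sd = 0.1), n_concepts, d),
            null = rnorm(d, sd = 0.1))
  for (pref in c("la", "lb")) {
    for (dir in c("f", "b")) {
      p[[paste0(pref, "_Wx_", dir)]] <- glorot(D, 4L * h)
      p[[paste0(pref, "_Wh_", dir)]] <- glorot(h, 4L * h)
      p[[paste0(pref, "_b_", dir)]] <- numeric(4L * h)
    }
  }
  p$w_alpha <- glorot(2L * h, 1L)
  p$b_alpha <- 0
  p$W_beta <- glorot(2L * h, D)
  p$b_beta <- numeric(D)
  p$w_out <- glorot(D, 1L)
  p$b_out <- 0
  p
}

## time-major input: visit embedding (+ null token) with statics concatenated
retain_inputs <- function(p, batch, config, train_mode = FALSE) {
  B <- batch$B; Tm <- batch$T
  V <- as.matrix(batch$S %*% p$E)
  null_rows <- which(as.vector(batch$is_null))
  if (length(null_rows))
    V[null_rows, ] <- V[null_rows, , drop = FALSE] +
      matrix(p$null, length(null_rows), length(p$null), byrow = TRUE)
  drop_mask <- NULL
  if (train_mode && config$dropout > 0) {
    drop_mask <- matrix(rbinom(length(V), 1L, 1 - config$dropout) /
                          (1 - config$dropout), nrow(V), ncol(V))
    V <- V * drop_mask
  }
  tvec <- as.vector(batch$days) / 365
  X <- if (config$include_static) {
    cbind(V, rep(batch$static[, "age"], Tm), rep(batch$static[, "sex"], Tm), tvec)
  } else cbind(V, tvec)
  list(X = X, null_rows = null_rows, drop_mask = drop_mask)
}

retain_forward_pass <- function(p, batch, config, train_mode = FALSE) {
  B <- batch$B; Tm <- batch$T
  inp <- retain_inputs(p, batch, config, train_mode)
  X <- inp$X
  la <- bilstm_forward(X, batch$mask, p, "la", B, Tm)
  e_mat <- matrix(la$H %*% p$w_alpha + p$b_alpha, B, Tm)
  alpha <- softmax_rows(e_mat, batch$mask)
  lb <- bilstm_forward(X, batch$mask, p, "lb", B, Tm)
  beta <- tanh(sweep(lb$H %*% p$W_beta, 2L, p$b_beta, `+`))
  wv <- beta * X
  context <- matrix(0, B, ncol(X))
  for (t in seq_len(Tm)) {
    rows <- (t - 1L) * B + seq_len(B)
    context <- context + wv[rows, , drop = FALSE] * alpha[, t]
  }
  logit <- as.numeric(context %*% p$w_out) + p$b_out
  list(logit = logit, p = sigmoid(logit), alpha = alpha, beta = beta,
       cache = list(inp = inp, X = X, la = la, lb = lb, alpha = alpha,
                    beta = beta, wv = wv, context = context))
}

retain_backward_pass <- function(p, batch, config, cache, dlogit) {
  B <- batch$B; Tm <- batch$T
  X <- cache$X
  g <- list()
  g$w_out <- crossprod(cache$context, dlogit)
  g$b_out <- sum(dlogit)
  dcontext <- outer(dlogit, p$w_out[, 1L])
  dalpha <- matrix(0, B, Tm)
  dwv <- matrix(0, nrow(X), ncol(X))
  for (t in seq_len(Tm)) {
    rows <- (t - 1L) * B + seq_len(B)
    dalpha[, t] <- rowSums(dcontext * cache$wv[rows, , drop = FALSE])
    dwv[rows, ] <- dcontext * cache$alpha[, t]
  }
  de <- cache$alpha * (dalpha - rowSums(dalpha * cache$alpha))
  g$w_alpha <- crossprod(cache$la$H, as.vector(de))
  g$b_alpha <- sum(de)
  dHa <- as.vector(de) %o% p$w_alpha[, 1L]
  dbeta <- dwv * X
  dX <- dwv * cache$beta
  dz <- dbeta * (1 - cache$beta^2)
  g$W_beta <- crossprod(cache$lb$H, dz)
  g$b_beta <- colSums(dz)
  dHb <- dz %*% t(p$W_beta)
  ba <- bilstm_backward(dHa, X, cache$la, p, "la", B, Tm)
  bb <- bilstm_backward(dHb, X, cache$lb, p, "lb", B, Tm)
  g <- c(g, ba$grads, bb$grads)
  dX <- dX + ba$dX + bb$dX
  d <- config$embedding_dim
  dV <- dX[, seq_len(d), drop = FALSE]
  if (!is.null(cache$inp$drop_mask)) dV <- dV * cache$inp$drop_mask
  g$E <- as.matrix(Matrix::crossprod(batch$S, dV))
  g$null <- if (length(cache$inp$null_rows))
    colSums(dV[cache$inp$null_rows, , drop = FALSE]) else numeric(d)
  g
}

#' Forward pass of the two-level-attention recurrent model
#'
#' Exposed for inspection: returns risk scores together with the visit-level
#' attention and the per-coordinate gates. Attention over real visits sums
#' to one per observation; padded visits carry exactly zero weight.
#'
#' @param params parameter list from a fitted `retain_model` (or
#'   `retain_init`).
#' @param batch a batch from `make_batches()`.
#' @param config the `retain_config`.
#' @return list with `scores`, `visit_attention` (B x T), and
#'   `coordinate_attention` (time-major (B*T) x D gates).
#' @export
retain_forward <- function(params, batch, config) {
  out <- retain_forward_pass(params, batch, config, train_mode = FALSE)
  list(scores = out$p, visit_attention = out$alpha * batch$mask,
       coordinate_attention = out$beta)
}
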