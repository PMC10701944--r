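## Minimal neural-network core: batching of visit sequences, parameter
## initialization helpers, LSTM forward/backward (BPTT), layer norm, Adam,
## and the weighted binary cross-entropy objective. All matrices are dense
## base-R matrices except the concept multi-hot, which stays sparse.
##
## Batch layout is time-major: a quantity defined per (observation, visit)
## is a (B*T) x d matrix whose row (t-1)*B + b is observation b at visit t.

#' Class weight for the positive class
#'
#' The ratio of negative to positive observations in the training labels,
#' used as the positive-class weight of the binary cross-entropy.
#'
#' @param labels binary training labels.
#' @return `n_negative / n_positive`.
#' @export
pos_weight_from_labels <- function(labels) {
  if (!is_binary01(labels)) stop_arg("labels must be binary 0/1")
  sum(labels == 0) / sum(labels == 1)
}

#' Class-weighted binary cross-entropy
#'
#' Mean over the batch of `-(w * y * log(p) + (1 - y) * log(1 - p))` with
#' `w` the positive-class weight. Scores exactly 0 or 1 are clamped at 1e-7.
#'
#' @param scores predicted probabilities.
#' @param labels binary outcomes.
#' @param pos_weight positive-class weight (> 0); `1` gives the unweighted
#'   loss.
#' @return scalar loss.
#' @export
weighted_bce <- function(scores, labels, pos_weight = 1) {
  if (pos_weight <= 0) stop_arg("pos_weight must be positive")
  if (length(scores) != length(labels)) stop_arg("length mismatch")
  p <- clamp_prob(scores)
  mean(-(pos_weight * labels * log(p) + (1 - labels) * log(1 - p)))
}

## gradient of weighted BCE w.r.t. the logit (pre-sigmoid), averaged
d_wbce_dlogit <- function(p, y, w) {
  (p * (w * y + 1 - y) - w * y) / length(y)
}

#' Sinusoidal positional embedding of day offsets
#'
#' The standard interleaved sin/cos encoding evaluated at the day offset:
#' column pair `2i-1, 2i` is `sin(t / base^(2(i-1)/dim))`,
#' `cos(t / base^(2(i-1)/dim))`.
#'
#' @param days_before_index integer vector of offsets.
#' @param dim embedding dimension (must be even).
#' @param base frequency base (default 10000).
#' @return a `length(days) x dim` matrix with entries in `[-1, 1]`.
#' @export
sinusoidal_time_embedding <- function(days_before_index, dim, base = 10000) {
  if (dim %% 2L != 0L) stop_arg("dim must be even")
  i <- seq_len(dim / 2L)
  freq <- base^(-2 * (i - 1) / dim)
  ang <- outer(days_before_index, freq)
  out <- matrix(0, length(days_before_index), dim)
  out[, 2L * i - 1L] <- sin(ang)
  out[, 2L * i] <- cos(ang)
  out
}

## ---- batching --------------------------------------------------------------

## Turn a visit_sequences subset into padded time-major batches.
## Empty sequences get a single "null visit" (no concepts, offset 0) so the
## learned null token and the static covariates still drive a prediction.
make_batches <- function(seqs, ids, batch_size = 512L, age_max = NULL,
                         shuffle = FALSE) {
  stopifnot(inherits(seqs, "visit_sequences"))
  ids <- ids[ids %in% names(seqs$sequences)]
  if (shuffle) ids <- sample(ids)
  age_max <- age_max %||% max(seqs$static[, "age_years"])
  chunks <- split(ids, ceiling(seq_along(ids) / batch_size))
  lapply(chunks, function(chunk) {
    ss <- seqs$sequences[chunk]
    lens <- vapply(ss, function(s) max(1L, length(s$days_before_index)), integer(1))
    B <- length(chunk); Tm <- max(lens)
    mask <- matrix(FALSE, B, Tm)
    days <- matrix(0, B, Tm)
    is_null <- matrix(FALSE, B, Tm)
    ii <- integer(0); jj <- integer(0)
    for (b in seq_len(B)) {
      s <- ss[[b]]
      L <- length(s$days_before_index)
      if (L == 0L) { mask[b, 1L] <- TRUE; is_null[b, 1L] <- TRUE; next }
      mask[b, seq_len(L)] <- TRUE
      days[b, seq_len(L)] <- s$days_before_index
      for (t in seq_len(L)) {
        cs <- s$concept_indices[[t]]
        ii <- c(ii, rep.int((t - 1L) * B + b, length(cs)))
        jj <- c(jj, cs)
      }
    }
    S <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                              dims = c(B * Tm, nrow(seqs$concept_map)))
    static <- cbind(age = seqs$static[chunk, "age_years"] / age_max,
                    sex = seqs$static[chunk, "sex_male"])
    list(ids = chunk, B = B, T = Tm, S = S, mask = mask, days = days,
         is_null = is_null, static = static,
         y = unname(seqs$outcome[chunk]), age_max = age_max)
  })
}

## ---- parameter initialization ---------------------------------------------

glorot <- function(nin, nout) {
  matrix(runif(nin * nout, -sqrt(6 / (nin + nout)), sqrt(6 / (nin + nout))),
         nin, nout)
}

## ---- LSTM ------------------------------------------------------------------

## X: (B*T) x D time-major; returns H (B*T) x h plus caches for BPTT.
lstm_forward <- function(X, mask_rows, Wx, Wh, b, B, Tm) {
  h <- nrow(Wh)
  H <- matrix(0, B * Tm, h)
  Ct <- matrix(0, B, h); Ht <- matrix(0, B, h)
  caches <- vector("list", Tm)
  XW <- X %*% Wx  # precompute input projections for all steps
  for (t in seq_len(Tm)) {
    rows <- (t - 1L) * B + seq_len(B)
    z <- XW[rows, , drop = FALSE] + Ht %*% Wh +
      matrix(b, B, 4L * h, byrow = TRUE)
    i_g <- sigmoid(z[, seq_len(h), drop = FALSE])
    f_g <- sigmoid(z[, h + seq_len(h), drop = FALSE])
    g_g <- tanh(z[, 2L * h + seq_len(h), drop = FALSE])
    o_g <- sigmoid(z[, 3L * h + seq_len(h), drop = FALSE])
    C_new <- f_g * Ct + i_g * g_g
    H_new <- o_g * tanh(C_new)
    caches[[t]] <- list(i = i_g, f = f_g, g = g_g, o = o_g,
                        C_prev = Ct, H_prev = Ht, C = C_new)
    Ct <- C_new; Ht <- H_new
    H[rows, ] <- H_new
  }
  list(H = H, caches = caches)
}

lstm_backward <- function(dH, X, fwd, Wx, Wh, B, Tm) {
  h <- nrow(Wh)
  dX <- matrix(0, nrow(X), ncol(X))
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, h, 4L * h)
  db <- numeric(4L * h)
  dH_next <- matrix(0, B, h); dC_next <- matrix(0, B, h)
  for (t in rev(seq_len(Tm))) {
    rows <- (t - 1L) * B + seq_len(B)
    cc <- fwd$caches[[t]]
    dHt <- dH[rows, , drop = FALSE] + dH_next
    tC <- tanh(cc$C)
    dO <- dHt * tC
    dC <- dHt * cc$o * (1 - tC^2) + dC_next
    dF <- dC * cc$C_prev
    dI <- dC * cc$g
    dG <- dC * cc$i
    dz <- cbind(dI * cc$i * (1 - cc$i),
                dF * cc$f * (1 - cc$f),
                dG * (1 - cc$g^2),
                dO * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(X[rows, , drop = FALSE], dz)
    dWh <- dWh + crossprod(cc$H_prev, dz)
    db <- db + colSums(dz)
    dX[rows, ] <- dz %*% t(Wx)
    dH_next <- dz %*% t(Wh)
    dC_next <- dC * cc$f
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

## Per-sequence time reversal within real lengths, as an index involution on
## time-major rows; applying it twice restores the original order.
reverse_index <- function(mask, B, Tm) {
  lens <- rowSums(mask)
  idx <- integer(B * Tm)
  for (b in seq_len(B)) {
    for (t in seq_len(Tm)) {
      src_t <- if (t <= lens[b]) lens[b] - t + 1L else t
      idx[(t - 1L) * B + b] <- (src_t - 1L) * B + b
    }
  }
  idx
}

## Bidirectional LSTM: concatenated forward and (per-sequence) reversed
## hidden states, both in original time order.
bilstm_forward <- function(X, mask, p, prefix, B, Tm) {
  fw <- lstm_forward(X, NULL, p[[paste0(prefix, "_Wx_f")]],
                     p[[paste0(prefix, "_Wh_f")]], p[[paste0(prefix, "_b_f")]],
                     B, Tm)
  ridx <- reverse_index(mask, B, Tm)
  Xr <- X[ridx, , drop = FALSE]
  bw <- lstm_forward(Xr, NULL, p[[paste0(prefix, "_Wx_b")]],
                     p[[paste0(prefix, "_Wh_b")]], p[[paste0(prefix, "_b_b")]],
                     B, Tm)
  Hb <- bw$H[ridx, , drop = FALSE]  # back to original time order
  list(H = cbind(fw$H, Hb), fw = fw, bw = bw, Xr = Xr, ridx = ridx)
}

bilstm_backward <- function(dH, X, cache, p, prefix, B, Tm) {
  h <- ncol(cache$fw$H)
  d_fw <- lstm_backward(dH[, seq_len(h), drop = FALSE], X, cache$fw,
                        p[[paste0(prefix, "_Wx_f")]],
                        p[[paste0(prefix, "_Wh_f")]], B, Tm)
  dHb <- dH[, h + seq_len(h), drop = FALSE][cache$ridx, , drop = FALSE]
  d_bw <- lstm_backward(dHb, cache$Xr, cache$bw,
                        p[[paste0(prefix, "_Wx_b")]],
                        p[[paste0(prefix, "_Wh_b")]], B, Tm)
  dX <- d_fw$dX + d_bw$dX[cache$ridx, , drop = FALSE]
  grads <- list()
  grads[[paste0(prefix, "_Wx_f")]] <- d_fw$dWx
  grads[[paste0(prefix, "_Wh_f")]] <- d_fw$dWh
  grads[[paste0(prefix, "_b_f")]] <- d_fw$db
  grads[[paste0(prefix, "_Wx_b")]] <- d_bw$dWx
  grads[[paste0(prefix, "_Wh_b")]] <- d_bw$dWh
  grads[[paste0(prefix, "_b_b")]] <- d_bw$db
  list(dX = dX, grads = grads)
}

## ---- layer norm ------------------------------------------------------------

layernorm_forward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  Y <- sweep(xhat, 2L, gamma, `*`)
  Y <- sweep(Y, 2L, beta, `+`)
  list(Y = Y, xhat = xhat, istd = istd)
}

layernorm_backward <- function(dY, cache, gamma) {
  d <- ncol(dY)
  dxhat <- sweep(dY, 2L, gamma, `*`)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dX <- (dxhat - rowMeans(dxhat) -
           cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$istd
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

## decoupled weight decay (AdamW); decay skips biases, gains and scalars
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && is.matrix(params[[nm]]))
      params[[nm]] <- params[[nm]] * (1 - lr * weight_decay)
  }
  list(params = params, state = state)
}
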