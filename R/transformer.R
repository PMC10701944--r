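## Self-attention transformer over visit sequences: summed concept
## embeddings per visit with age/sex concatenated, projected to model width,
## plus a sinusoidal embedding of days-before-index; a pre-norm multi-head
## attention stack; and a 1-D convolutional prediction head (two kernel-3
## convolutions, masked max-pool over visits, linear output). A diagnostic
## mean-pool head is available for permutation checks.

#' Configuration for the transformer risk model
#'
#' @param embedding_dim model width (must be divisible by `num_heads`).
#' @param num_heads attention heads.
#' @param attn_depth number of attention blocks.
#' @param num_hidden feed-forward width inside each block.
#' @param dropout dropout rate on residual branches during training.
#' @param conv_channels widths of the two convolutional head layers.
#' @param head `"conv"` (default) or `"mean"` for the diagnostic
#'   mean-pooling head.
#' @return a `transformer_config`.
#' @export
transformer_config <- function(embedding_dim = 16L, num_heads = 2L,
                               attn_depth = 1L, num_hidden = 32L,
                               dropout = 0, conv_channels = c(16L, 16L),
                               head = c("conv", "mean")) {
  if (embedding_dim %% num_heads != 0L)
    stop_arg("embedding_dim must be divisible by num_heads")
  structure(list(embedding_dim = as.integer(embedding_dim),
                 num_heads = as.integer(num_heads),
                 attn_depth = as.integer(attn_depth),
                 num_hidden = as.integer(num_hidden), dropout = dropout,
                 conv_channels = as.integer(conv_channels),
                 head = match.arg(head)),
            class = "transformer_config")
}

transformer_init <- function(n_concepts, config, seed = 1L) {
  set.seed(seed)
  dm <- config$embedding_dim
  p <- list(E = matrix(rnorm(n_concepts * dm, sd = 0.1), n_concepts, dm),
            null = rnorm(dm, sd = 0.1),
            W_in = glorot(dm + 2L, dm), b_in = numeric(dm))
  for (l in seq_len(config$attn_depth)) {
    pre <- sprintf("blk%d_", l)
    for (w in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, w)]] <- glorot(dm, dm)
    for (b in c("bq", "bk", "bv", "bo")) p[[paste0(pre, b)]] <- numeric(dm)
    p[[paste0(pre, "ln1_g")]] <- rep(1, dm); p[[paste0(pre, "ln1_b")]] <- numeric(dm)
    p[[paste0(pre, "ln2_g")]] <- rep(1, dm); p[[paste0(pre, "ln2_b")]] <- numeric(dm)
    p[[paste0(pre, "W1")]] <- glorot(dm, config$num_hidden)
    p[[paste0(pre, "b1")]] <- numeric(config$num_hidden)
    p[[paste0(pre, "W2")]] <- glorot(config$num_hidden, dm)
    p[[paste0(pre, "b2")]] <- numeric(dm)
  }
  c1 <- config$conv_channels[1]; c2 <- config$conv_channels[2]
  for (k in 1:3) p[[paste0("conv1_W", k)]] <- glorot(dm, c1) / 3
  p$conv1_b <- numeric(c1)
  for (k in 1:3) p[[paste0("conv2_W", k)]] <- glorot(c1, c2) / 3
  p$conv2_b <- numeric(c2)
  p$w_head <- glorot(c2, 1L); p$b_head <- 0
  p$w_mean <- glorot(dm, 1L); p$b_mean <- 0
  p
}

## shift time-major rows by o visits (rows of visit t take values from t+o)
shift_time <- function(M, o, B, Tm) {
  out <- matrix(0, nrow(M), ncol(M))
  for (t in seq_len(Tm)) {
    src <- t + o
    if (src >= 1L && src <= Tm)
      out[(t - 1L) * B + seq_len(B), ] <- M[(src - 1L) * B + seq_len(B), , drop = FALSE]
  }
  out
}

conv1d_forward <- function(X, p, pre, B, Tm) {
  Y <- matrix(p[[paste0(pre, "_b")]], nrow(X), length(p[[paste0(pre, "_b")]]),
              byrow = TRUE)
  for (k in 1:3) Y <- Y + shift_time(X, k - 2L, B, Tm) %*% p[[paste0(pre, "_W", k)]]
  Y
}

conv1d_backward <- function(dY, X, p, pre, B, Tm) {
  g <- list()
  dX <- matrix(0, nrow(X), ncol(X))
  for (k in 1:3) {
    o <- k - 2L
    g[[paste0(pre, "_W", k)]] <- crossprod(shift_time(X, o, B, Tm), dY)
    dX <- dX + shift_time(dY, -o, B, Tm) %*% t(p[[paste0(pre, "_W", k)]])
  }
  g[[paste0(pre, "_b")]] <- colSums(dY)
  list(dX = dX, grads = g)
}

transformer_forward_pass <- function(p, batch, config, train_mode = FALSE) {
  B <- batch$B; Tm <- batch$T
  dm <- config$embedding_dim
  nh <- config$num_heads; dh <- dm %/% nh
  valid <- as.vector(batch$mask)  # time-major row validity

  V <- as.matrix(batch$S %*% p$E)
  null_rows <- which(as.vector(batch$is_null))
  if (length(null_rows))
    V[null_rows, ] <- V[null_rows, , drop = FALSE] +
      matrix(p$null, length(null_rows), dm, byrow = TRUE)
  Xin <- cbind(V, rep(batch$static[, "age"], Tm), rep(batch$static[, "sex"], Tm))
  X <- Xin %*% p$W_in + matrix(p$b_in, nrow(Xin), dm, byrow = TRUE)
  TE <- sinusoidal_time_embedding(as.vector(batch$days), dm)
  X <- X + TE

  blocks <- vector("list", config$attn_depth)
  attn_all <- vector("list", config$attn_depth)
  for (l in seq_len(config$attn_depth)) {
    pre <- sprintf("blk%d_", l)
    ln1 <- layernorm_forward(X, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    XN <- ln1$Y
    Q <- XN %*% p[[paste0(pre, "Wq")]] + matrix(p[[paste0(pre, "bq")]], nrow(XN), dm, byrow = TRUE)
    K <- XN %*% p[[paste0(pre, "Wk")]] + matrix(p[[paste0(pre, "bk")]], nrow(XN), dm, byrow = TRUE)
    Vv <- XN %*% p[[paste0(pre, "Wv")]] + matrix(p[[paste0(pre, "bv")]], nrow(XN), dm, byrow = TRUE)
    O <- matrix(0, nrow(XN), dm)
    A_list <- vector("list", B)
    for (b in seq_len(B)) {
      rows <- (seq_len(Tm) - 1L) * B + b
      kmask <- batch$mask[b, ]
      Ab <- array(0, dim = c(nh, Tm, Tm))
      for (hd in seq_len(nh)) {
        cols <- (hd - 1L) * dh + seq_len(dh)
        Qh <- Q[rows, cols, drop = FALSE]
        Kh <- K[rows, cols, drop = FALSE]
        S <- Qh %*% t(Kh) / sqrt(dh)
        S[, !kmask] <- -Inf
        A <- softmax_rows(S)
        Ab[hd, , ] <- A
        O[rows, cols] <- A %*% Vv[rows, cols, drop = FALSE]
      }
      A_list[[b]] <- Ab
    }
    attn_out <- O %*% p[[paste0(pre, "Wo")]] +
      matrix(p[[paste0(pre, "bo")]], nrow(O), dm, byrow = TRUE)
    drop1 <- NULL
    if (train_mode && config$dropout > 0) {
      drop1 <- matrix(rbinom(length(attn_out), 1L, 1 - config$dropout) /
                        (1 - config$dropout), nrow(attn_out), dm)
      attn_out <- attn_out * drop1
    }
    X1 <- X + attn_out
    ln2 <- layernorm_forward(X1, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    H1 <- ln2$Y %*% p[[paste0(pre, "W1")]] +
      matrix(p[[paste0(pre, "b1")]], nrow(X1), config$num_hidden, byrow = TRUE)
    R1 <- pmax(H1, 0)
    F2 <- R1 %*% p[[paste0(pre, "W2")]] +
      matrix(p[[paste0(pre, "b2")]], nrow(X1), dm, byrow = TRUE)
    drop2 <- NULL
    if (train_mode && config$dropout > 0) {
      drop2 <- matrix(rbinom(length(F2), 1L, 1 - config$dropout) /
                        (1 - config$dropout), nrow(F2), dm)
      F2 <- F2 * drop2
    }
    X2 <- X1 + F2
    blocks[[l]] <- list(X_in = X, ln1 = ln1, XN = XN, Q = Q, K = K, Vv = Vv,
                        O = O, A_list = A_list, drop1 = drop1, X1 = X1,
                        ln2 = ln2, H1 = H1, R1 = R1, drop2 = drop2)
    attn_all[[l]] <- A_list
    X <- X2
  }

  Xm <- X * valid
  if (config$head == "mean") {
    lens <- rowSums(batch$mask)
    ctx <- matrix(0, B, dm)
    for (t in seq_len(Tm)) ctx <- ctx + Xm[(t - 1L) * B + seq_len(B), , drop = FALSE]
    ctx <- ctx / lens
    logit <- as.numeric(ctx %*% p$w_mean) + p$b_mean
    cache <- list(blocks = blocks, Xm = Xm, ctx = ctx, valid = valid,
                  Xin = Xin, TE = TE, null_rows = null_rows, X_final = X)
    return(list(logit = logit, p = sigmoid(logit), attention = attn_all,
                cache = cache))
  }
  Y1 <- conv1d_forward(Xm, p, "conv1", B, Tm)
  R1c <- pmax(Y1, 0) * valid  # keep padding silent between conv layers
  Y2 <- conv1d_forward(R1c, p, "conv2", B, Tm)
  R2c <- pmax(Y2, 0)
  c2 <- ncol(R2c)
  P <- matrix(0, B, c2)
  argm <- matrix(0L, B, c2)
  for (b in seq_len(B)) {
    tv <- which(batch$mask[b, ])
    rows <- (tv - 1L) * B + b
    blockm <- R2c[rows, , drop = FALSE]
    am <- max.col(t(blockm), ties.method = "first")
    P[b, ] <- blockm[cbind(am, seq_len(c2))]
    argm[b, ] <- rows[am]
  }
  logit <- as.numeric(P %*% p$w_head) + p$b_head
  cache <- list(blocks = blocks, Xm = Xm, Y1 = Y1, R1c = R1c, Y2 = Y2,
                R2c = R2c, P = P, argm = argm, valid = valid, Xin = Xin,
                TE = TE, null_rows = null_rows, X_final = X)
  list(logit = logit, p = sigmoid(logit), attention = attn_all, cache = cache)
}

transformer_backward_pass <- function(p, batch, config, cache, dlogit) {
  B <- batch$B; Tm <- batch$T
  dm <- config$embedding_dim
  nh <- config$num_heads; dh <- dm %/% nh
  g <- list()
  if (config$head == "mean") {
    g$w_mean <- crossprod(cache$ctx, dlogit)
    g$b_mean <- sum(dlogit)
    dctx <- outer(dlogit, p$w_mean[, 1L]) / rowSums(batch$mask)
    dXm <- matrix(0, nrow(cache$Xm), dm)
    for (t in seq_len(Tm)) dXm[(t - 1L) * B + seq_len(B), ] <- dctx
    g$w_head <- p$w_head * 0; g$b_head <- 0
    g$conv1_b <- p$conv1_b * 0; g$conv2_b <- p$conv2_b * 0
    for (k in 1:3) {
      g[[paste0("conv1_W", k)]] <- p[[paste0("conv1_W", k)]] * 0
      g[[paste0("conv2_W", k)]] <- p[[paste0("conv2_W", k)]] * 0
    }
  } else {
    g$w_head <- crossprod(cache$P, dlogit)
    g$b_head <- sum(dlogit)
    dP <- outer(dlogit, p$w_head[, 1L])
    dR2 <- matrix(0, nrow(cache$R2c), ncol(cache$R2c))
    for (b in seq_len(B))
      dR2[cbind(cache$argm[b, ], seq_len(ncol(dR2)))] <-
        dR2[cbind(cache$argm[b, ], seq_len(ncol(dR2)))] + dP[b, ]
    dY2 <- dR2 * (cache$Y2 > 0)
    c2b <- conv1d_backward(dY2, cache$R1c, p, "conv2", B, Tm)
    g <- c(g, c2b$grads)
    dY1 <- c2b$dX * cache$valid * (cache$Y1 > 0)
    c1b <- conv1d_backward(dY1, cache$Xm, p, "conv1", B, Tm)
    g <- c(g, c1b$grads)
    dXm <- c1b$dX
    g$w_mean <- p$w_mean * 0; g$b_mean <- 0
  }
  dX <- dXm * cache$valid

  for (l in rev(seq_len(config$attn_depth))) {
    pre <- sprintf("blk%d_", l)
    blk <- cache$blocks[[l]]
    dF2 <- dX
    if (!is.null(blk$drop2)) dF2 <- dF2 * blk$drop2
    g[[paste0(pre, "W2")]] <- crossprod(blk$R1, dF2)
    g[[paste0(pre, "b2")]] <- colSums(dF2)
    dR1 <- dF2 %*% t(p[[paste0(pre, "W2")]])
    dH1 <- dR1 * (blk$H1 > 0)
    g[[paste0(pre, "W1")]] <- crossprod(blk$ln2$Y, dH1)
    g[[paste0(pre, "b1")]] <- colSums(dH1)
    dXN2 <- dH1 %*% t(p[[paste0(pre, "W1")]])
    lb2 <- layernorm_backward(dXN2, blk$ln2, p[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- lb2$dgamma
    g[[paste0(pre, "ln2_b")]] <- lb2$dbeta
    dX1 <- dX + lb2$dX

    dattn <- dX1
    if (!is.null(blk$drop1)) dattn <- dattn * blk$drop1
    g[[paste0(pre, "Wo")]] <- crossprod(blk$O, dattn)
    g[[paste0(pre, "bo")]] <- colSums(dattn)
    dO <- dattn %*% t(p[[paste0(pre, "Wo")]])
    dQ <- matrix(0, nrow(dO), dm); dK <- matrix(0, nrow(dO), dm)
    dVv <- matrix(0, nrow(dO), dm)
    for (b in seq_len(B)) {
      rows <- (seq_len(Tm) - 1L) * B + b
      for (hd in seq_len(nh)) {
        cols <- (hd - 1L) * dh + seq_len(dh)
        A <- blk$A_list[[b]][hd, , , drop = TRUE]
        if (Tm == 1L) A <- matrix(A, 1L, 1L)
        dOh <- dO[rows, cols, drop = FALSE]
        Vh <- blk$Vv[rows, cols, drop = FALSE]
        dA <- dOh %*% t(Vh)
        dVv[rows, cols] <- dVv[rows, cols, drop = FALSE] + crossprod(A, dOh)
        dS <- A * (dA - rowSums(dA * A))
        Qh <- blk$Q[rows, cols, drop = FALSE]
        Kh <- blk$K[rows, cols, drop = FALSE]
        dQ[rows, cols] <- dQ[rows, cols, drop = FALSE] + dS %*% Kh / sqrt(dh)
        dK[rows, cols] <- dK[rows, cols, drop = FALSE] + crossprod(dS, Qh) / sqrt(dh)
      }
    }
    g[[paste0(pre, "Wq")]] <- crossprod(blk$XN, dQ)
    g[[paste0(pre, "bq")]] <- colSums(dQ)
    g[[paste0(pre, "Wk")]] <- crossprod(blk$XN, dK)
    g[[paste0(pre, "bk")]] <- colSums(dK)
    g[[paste0(pre, "Wv")]] <- crossprod(blk$XN, dVv)
    g[[paste0(pre, "bv")]] <- colSums(dVv)
    dXN <- dQ %*% t(p[[paste0(pre, "Wq")]]) + dK %*% t(p[[paste0(pre, "Wk")]]) +
      dVv %*% t(p[[paste0(pre, "Wv")]])
    lb1 <- layernorm_backward(dXN, blk$ln1, p[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- lb1$dgamma
    g[[paste0(pre, "ln1_b")]] <- lb1$dbeta
    dX <- dX1 + lb1$dX
  }

  g$W_in <- crossprod(cache$Xin, dX)
  g$b_in <- colSums(dX)
  dXin <- dX %*% t(p$W_in)
  dV <- dXin[, seq_len(dm), drop = FALSE]
  g$E <- as.matrix(Matrix::crossprod(batch$S, dV))
  g$null <- if (length(cache$null_rows))
    colSums(dV[cache$null_rows, , drop = FALSE]) else numeric(dm)
  g
}

#' Forward pass of the transformer risk model
#'
#' Exposed for inspection: risk scores plus per-block attention weights
#' (per observation, an array heads x visits x visits; rows over unmasked
#' keys sum to one).
#'
#' @param params transformer parameter list.
#' @param batch a batch from `make_batches()`.
#' @param config the `transformer_config`.
#' @return list with `scores` and `attention`.
#' @export
transformer_forward <- function(params, batch, config) {
  out <- transformer_forward_pass(params, batch, config, train_mode = FALSE)
  list(scores = out$p, attention = out$attention)
}
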