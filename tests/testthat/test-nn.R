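# Attention architectures: embedding arithmetic, attention normalization,
# masking, analytic gradients against finite differences, and the
# memorization sanity check.

test_that("sinusoidal time embedding matches its closed form", {
  e0 <- sinusoidal_time_embedding(0L, 6)
  expect_equal(e0[1, c(1, 3, 5)], c(0, 0, 0))
  expect_equal(e0[1, c(2, 4, 6)], c(1, 1, 1))
  e1 <- sinusoidal_time_embedding(1L, 4)
  expect_equal(e1[1, ], c(sin(1), cos(1), sin(10000^(-2 / 4)),
                          cos(10000^(-2 / 4))))
  em <- sinusoidal_time_embedding(0:365, 16)
  expect_true(all(em >= -1 & em <= 1))
  expect_error(sinusoidal_time_embedding(3L, 5), "even")
})

test_that("visit embeddings are sums of concept embedding rows", {
  batch <- manual_batch(list(list(1L), list(c(2L, 3L))), days = list(0, 10))
  cfg <- retain_config(embedding_dim = 4, lstm_hidden_dim = 3)
  p <- ns$retain_init(3, cfg, seed = 1)
  inp <- ns$retain_inputs(p, batch, cfg)
  expect_equal(unname(inp$X[1, 1:4]), unname(p$E[1, ]))       # single concept
  expect_equal(unname(inp$X[2, 1:4]), unname(p$E[2, ] + p$E[3, ]))  # sum of two
  p$E[] <- 0; p$null[] <- 0
  inp0 <- ns$retain_inputs(p, batch, cfg)
  expect_equal(max(abs(inp0$X[, 1:4])), 0)            # zero table -> zero emb
})

test_that("visit attention is a masked softmax with the forced edge cases", {
  cfg <- retain_config(embedding_dim = 4, lstm_hidden_dim = 3)
  p <- ns$retain_init(5, cfg, seed = 2)
  # single visit: weight exactly 1
  b1 <- manual_batch(list(list(c(1L, 2L))), days = list(5), n_concepts = 5)
  out1 <- retain_forward(p, b1, cfg)
  expect_equal(unname(out1$visit_attention[1, 1]), 1.0)
  # two identical visits with the attention LSTM ablated (all-zero
  # parameters give position-independent hidden states): exactly uniform
  b2 <- manual_batch(list(list(c(1L, 2L), c(1L, 2L))), days = list(c(7, 7)),
                     n_concepts = 5)
  p0 <- p
  for (nm in grep("^la_", names(p0), value = TRUE)) p0[[nm]][] <- 0
  out2 <- retain_forward(p0, b2, cfg)
  expect_equal(unname(out2$visit_attention[1, ]), c(0.5, 0.5))
  # padded batch: weights on real visits sum to 1, padding gets exactly 0
  b3 <- manual_batch(list(list(1L, 2L, 3L), list(4L)),
                     days = list(c(30, 20, 10), 3), n_concepts = 5)
  out3 <- retain_forward(p, b3, cfg)
  expect_equal(unname(rowSums(out3$visit_attention)), c(1, 1))
  expect_identical(unname(out3$visit_attention[2, 2:3]), c(0, 0))
})

test_that("transformer attention rows sum to one over unmasked keys", {
  cfg <- transformer_config(embedding_dim = 8, num_heads = 2, attn_depth = 2,
                            num_hidden = 8, conv_channels = c(4, 4))
  p <- ns$transformer_init(6, cfg, seed = 3)
  batch <- manual_batch(list(list(1L, c(2L, 3L), 4L), list(5L)),
                        days = list(c(40, 20, 5), 8), n_concepts = 6)
  out <- transformer_forward(p, batch, cfg)
  expect_true(all(out$scores > 0 & out$scores < 1))
  for (l in seq_along(out$attention)) {
    for (b in 1:2) {
      A <- out$attention[[l]][[b]]
      valid <- batch$mask[b, ]
      for (hd in seq_len(dim(A)[1])) {
        M <- matrix(A[hd, , ], nrow = dim(A)[2])
        expect_equal(unname(rowSums(M[valid, , drop = FALSE])),
                     rep(1, sum(valid)))
        if (any(!valid))  # padded keys get exactly zero weight
          expect_equal(max(M[, !valid]), 0)
      }
    }
  }
})

test_that("mean-pool head is invariant to joint visit permutations", {
  cfg <- transformer_config(embedding_dim = 8, num_heads = 2, attn_depth = 1,
                            num_hidden = 8, head = "mean")
  p <- ns$transformer_init(6, cfg, seed = 4)
  b_a <- manual_batch(list(list(1L, c(2L, 3L), 4L)), days = list(c(40, 20, 5)),
                      n_concepts = 6)
  b_b <- manual_batch(list(list(4L, c(2L, 3L), 1L)), days = list(c(5, 20, 40)),
                      n_concepts = 6)
  s_a <- transformer_forward(p, b_a, cfg)$scores
  s_b <- transformer_forward(p, b_b, cfg)$scores
  expect_equal(s_a, s_b, tolerance = 1e-10)
})

test_that("padded batched scoring equals per-sequence scoring", {
  sim <- small_sim(40)
  sq <- build_sequences(sim$events, sim$cohort, max_visits = 8)
  ids <- names(sq$sequences)[1:20]
  for (maker in list(
    function() fit_retain(sq, ids, NULL, retain_config(6, 5),
                          train_config(batch_size = 20, max_epochs = 1,
                                       lr = 1e-3, seed = 1)),
    function() fit_transformer(sq, ids, NULL,
                               transformer_config(6, 2, 1, 8,
                                                  conv_channels = c(4, 4)),
                               train_config(batch_size = 20, max_epochs = 1,
                                            lr = 1e-3, seed = 1)))) {
    m <- maker()
    batched <- predict(m, sq, ids, batch_size = 20)
    looped <- predict(m, sq, ids, batch_size = 1)
    expect_equal(batched, looped, tolerance = 1e-5)
  }
})

test_that("analytic gradients match central finite differences", {
  # fixture chosen so no pre-activation sits within the step of a ReLU kink
  sim <- small_sim(6, seed = 5)
  sq <- build_sequences(sim$events, sim$cohort, max_visits = 4)
  batch <- ns$make_batches(sq, names(sq$sequences), batch_size = 6)[[1]]
  pw <- 3
  loss_of <- function(type, params, config) {
    out <- ns$nn_forward_by_type(type, params, batch, config, FALSE)
    weighted_bce(out$p, batch$y, pw)
  }
  check <- function(type, config) {
    nC <- nrow(sq$concept_map)
    params <- if (type == "retain") ns$retain_init(nC, config, 2)
              else ns$transformer_init(nC, config, 2)
    out <- ns$nn_forward_by_type(type, params, batch, config, FALSE)
    dlogit <- ns$d_wbce_dlogit(out$p, batch$y, pw)
    g <- ns$nn_backward_by_type(type, params, batch, config, out$cache, dlogit)
    expect_true(all(vapply(g, function(x) all(is.finite(x)), logical(1))))
    eps <- 1e-6
    set.seed(7)
    for (nm in names(g)) {
      for (i in sample(seq_len(length(params[[nm]])),
                       min(3, length(params[[nm]])))) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (loss_of(type, pp, config) - loss_of(type, pm, config)) / (2 * eps)
        ana <- g[[nm]][i]
        err <- min(abs(num - ana),
                   abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
        expect_lt(err, 1e-6)
      }
    }
  }
  check("retain", retain_config(embedding_dim = 4, lstm_hidden_dim = 3))
  check("transformer",
        transformer_config(embedding_dim = 4, num_heads = 2, attn_depth = 2,
                           num_hidden = 5, conv_channels = c(3, 3)))
})

test_that("each architecture can memorize a 64-row fixture", {
  sim <- generate_ehr(sim_config(n_persons = 64, n_concepts = 20,
                                 visits_per_person = 4, concepts_per_visit = 2,
                                 beta = c(C0001 = 2), seed = 11))
  sq <- build_sequences(sim$events, sim$cohort, max_visits = 10)
  ids <- names(sq$sequences)
  ret <- fit_retain(sq, ids, NULL, retain_config(8, 8),
                    train_config(batch_size = 64, max_epochs = 300, lr = 5e-3,
                                 seed = 1))
  expect_lt(weighted_bce(predict(ret, sq, ids), sq$outcome[ids],
                         ret$pos_weight), 0.05)
  trf <- fit_transformer(sq, ids, NULL,
                         transformer_config(8, 2, 1, 16,
                                            conv_channels = c(8, 8)),
                         train_config(batch_size = 64, max_epochs = 300,
                                      lr = 5e-3, seed = 1))
  expect_lt(weighted_bce(predict(trf, sq, ids), sq$outcome[ids],
                         trf$pos_weight), 0.05)
})

test_that("empty sequences are scored through the null-visit token", {
  f <- write_tiny_files()
  ev <- read_events(f$events)
  co <- read_cohort(f$cohort)
  sq <- build_sequences(ev, co)  # p2 and p3 have no qualifying events
  m <- fit_retain(sq, names(sq$sequences), NULL, retain_config(4, 3),
                  train_config(batch_size = 3, max_epochs = 2, lr = 1e-3,
                               seed = 1))
  p <- predict(m, sq)
  expect_true(all(is.finite(p)) && all(p > 0 & p < 1))
})
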