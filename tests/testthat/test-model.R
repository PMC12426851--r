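test_that("initialization is deterministic with the right shapes", {
  cfg <- model_config("independent", seed = 4)
  p1 <- init_params(cfg, 40)
  p2 <- init_params(cfg, 40)
  expect_identical(p1$par, p2$par)
  # 40 branches: (3h + 3h^2 + 3h) + (kh + 2k + 1) each, plus 40 + 1 combining
  h <- cfg$hidden; k <- cfg$head
  expect_equal(length(p1$par),
               40 * (6 * h + 3 * h^2 + k * h + 2 * k + 1) + 41)
  p3 <- init_params(model_config("independent", seed = 5), 40)
  expect_false(identical(p1$par, p3$par))
  pp <- init_params(model_config("pooled_gru", seed = 4), 40)
  hp <- 32; kp <- 16
  expect_equal(length(pp$par),
               3 * hp * 40 + 3 * hp^2 + 3 * hp + kp * hp + 2 * kp + 1)
})

test_that("the zero model scores 0.5 and simple arithmetic cases hold", {
  cfg <- model_config("independent", seed = 1)
  p <- init_params(cfg, 3)
  p$par[] <- 0
  x <- array(runif(2 * 24 * 3), c(2, 24, 3))
  out <- forward(p, x)
  expect_equal(out$logit, c(0, 0))
  expect_equal(out$score, c(0.5, 0.5))
  expect_equal(unname(out$effects), matrix(0, 2, 3))
  # b = -1 and one branch contributing +1 => z = 0
  P <- length(p$par)
  p$par[P] <- -1                     # combining bias
  p$par[P - 3] <- 1                  # w_1
  # force u_1 = 1 via the head bias of branch 1 (head b2 is the last branch
  # scalar); branch block length:
  h <- cfg$hidden; k <- cfg$head
  blk <- 6 * h + 3 * h^2 + k * h + 2 * k + 1
  p$par[blk] <- 1                    # b2 of branch 1
  out2 <- forward(p, x)
  expect_equal(out2$logit, c(0, 0), tolerance = 1e-12)
  expect_equal(out2$effects[, 1], c(1, 1), tolerance = 1e-12)
  expect_equal(out2$score, c(0.5, 0.5))
})

test_that("predictions are additive, batch-invariant and duplicate-stable", {
  cfg <- model_config("independent", seed = 7)
  p <- init_params(cfg, 10)
  fx <- rand_risk_output(p, 12, seed = 31)
  b <- p$par[length(p$par)]
  expect_lt(max(abs(fx$out$logit - b - rowSums(fx$out$effects))), 1e-5)
  # permuting patients permutes outputs
  perm <- c(4, 1, 12, 3, 2, 11, 5, 7, 6, 10, 9, 8)
  out_p <- forward(p, fx$x[perm, , ])
  expect_equal(out_p$score, fx$out$score[perm], tolerance = 1e-12)
  # duplicated patient scores identically
  out_d <- forward(p, fx$x[c(1, 1, 2), , ])
  expect_equal(out_d$score[1], out_d$score[2])
  expect_error(forward(p, array(0, c(2, 24, 9))), "dimension error")
})

test_that("perturbing one feature moves only its own effect", {
  cfg <- model_config("independent", seed = 13)
  p <- init_params(cfg, 8)
  fx <- rand_risk_output(p, 5, seed = 99)
  for (jj in c(1, 4, 8)) {
    x2 <- fx$x
    x2[, , jj] <- x2[, , jj] + 0.7
    out2 <- forward(p, x2)
    expect_false(any(out2$effects[, jj] == fx$out$effects[, jj]))
    expect_identical(out2$effects[, -jj], fx$out$effects[, -jj])
  }
})

test_that("composite loss matches its closed forms", {
  out <- list(logit = 0, branch = matrix(0, 1, 40),
              effects = matrix(0, 1, 40))
  class(out) <- "risk_output"
  expect_equal(composite_loss(out, 1, lambda = 0), log(2), tolerance = 1e-9)
  expect_equal(composite_loss(out, 1, lambda = 0.1), log(2) * 1.1,
               tolerance = 1e-9)
  out2 <- list(logit = 50, branch = NULL, effects = NULL)
  expect_lt(composite_loss(out2, 1, lambda = 0), 1e-9)
  expect_error(composite_loss(out, 2, 0.1), "labels")
  # R reference and the C++ training loss agree on random data
  cfg <- model_config("independent", seed = 3)
  p <- init_params(cfg, 6)
  fx <- rand_risk_output(p, 20, seed = 8)
  y <- rep(c(0, 1), 10)
  cpp <- foresiin:::fsn_apply(p$par, as.numeric(aperm(fx$x, c(2, 3, 1))),
                              c(24L, 6L, 20L), 0L, cfg$hidden, cfg$head,
                              as.numeric(y), cfg$lambda, FALSE)
  expect_equal(cpp$loss, composite_loss(fx$out, y, cfg$lambda),
               tolerance = 1e-10)
})

test_that("analytic gradients match finite differences for all variants", {
  for (variant in c("independent", "shared_head", "pooled_gru")) {
    cfg <- model_config(variant, hidden = 3, head = 2, lambda = 0.3,
                        seed = 17)
    m <- 4; Tn <- 6; n <- 5
    p <- init_params(cfg, m)
    vc <- foresiin:::variant_code(variant)
    withr::with_seed(55, {
      tx <- array(rnorm(Tn * m * n), c(Tn, m, n))
      y <- rbinom(n, 1, 0.5)
      idx <- sample(length(p$par), 40)
    })
    res <- foresiin:::fsn_apply(p$par, as.numeric(tx), c(Tn, m, n), vc,
                                3L, 2L, as.numeric(y), cfg$lambda, TRUE)
    eps <- 1e-6
    for (i in idx) {
      pp <- p$par; pp[i] <- pp[i] + eps
      lp <- foresiin:::fsn_apply(pp, as.numeric(tx), c(Tn, m, n), vc, 3L, 2L,
                                 as.numeric(y), cfg$lambda, FALSE)$loss
      pp[i] <- pp[i] - 2 * eps
      lm <- foresiin:::fsn_apply(pp, as.numeric(tx), c(Tn, m, n), vc, 3L, 2L,
                                 as.numeric(y), cfg$lambda, FALSE)$loss
      expect_equal(res$grad[i], (lp - lm) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("a single-feature independent model spans the pooled family", {
  # with m = 1 the independent logit b + w * (w2'v + b2) reparameterizes
  # exactly as a pooled head w2*'v + b2*; mapped parameters give identical
  # predictions
  cfg_i <- model_config("independent", hidden = 4, head = 3, lambda = 0,
                        seed = 2)
  p_i <- init_params(cfg_i, 1)
  h <- 4; k <- 3
  gru_len <- 6 * h + 3 * h^2
  head_len <- k * h + 2 * k + 1
  par <- p_i$par
  w <- par[gru_len + head_len + 1]
  b <- par[gru_len + head_len + 2]
  pooled <- par[1:(gru_len + head_len)]
  w2_idx <- gru_len + k * h + k + seq_len(k)
  pooled[w2_idx] <- pooled[w2_idx] * w              # w2* = w * w2
  pooled[gru_len + head_len] <- pooled[gru_len + head_len] * w + b
  cfg_p <- model_config("pooled_gru", hidden = 4, head = 3, seed = 2)
  p_p <- init_params(cfg_p, 1)
  p_p$par <- pooled
  x <- array(runif(7 * 24 * 1), c(7, 24, 1))
  expect_equal(forward(p_p, x)$logit, forward(p_i, x)$logit,
               tolerance = 1e-10)
})

test_that("training learns a separable rule, stops early and reproduces", {
  # one feature fully determines the label
  withr::with_seed(21, {
    n <- 160
    y <- rep(c(0, 1), each = n / 2)
    x <- array(-1, c(n, 24, 3))
    x[, , 2] <- rep(ifelse(y == 1, 0.9, 0.1), 24) |> matrix(n, 24)
    x <- x + array(runif(n * 24 * 3, 0, 0.05), c(n, 24, 3))
  })
  iv <- c(1:20, 141:160)
  cfg <- model_config("independent", max_epochs = 60, patience = 10,
                      seed = 5)
  fit <- train_model(init_params(cfg, 3), x, y, x[iv, , ], y[iv], cfg)
  out <- forward(fit$params, x)
  expect_gte(roc_auc(out$score, y), 0.99)
  # best-epoch bookkeeping: returned parameters achieve the recorded minimum
  h <- fit$history
  expect_equal(h$best_epoch, which.min(h$val_loss))
  expect_lte(h$stopped_after, h$best_epoch + cfg$patience)
  vres <- forward(fit$params, x[iv, , ])
  expect_equal(composite_loss(vres, y[iv], lambda = 0),
               min(h$val_loss), tolerance = 1e-9)
  # identical seeds reproduce the history
  fit2 <- train_model(init_params(cfg, 3), x, y, x[iv, , ], y[iv], cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params$par, fit2$params$par)
})

test_that("parameter archives round-trip", {
  p <- init_params(model_config("independent", seed = 1), 5)
  f <- withr::local_tempfile(fileext = ".rds")
  save_params(p, f)
  p2 <- load_params(f)
  expect_identical(p2$par, p$par)
  expect_s3_class(p2, "foresiin_params")
})
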