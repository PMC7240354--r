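toy_params <- function(K = 2, V = 6, seed = 51, ...) {
  withr::with_seed(seed, {
    W <- matrix(rnorm(K * V), K, V)
    phi <- exp(W) / rowSums(exp(W))
    pc_slda_params(phi, rnorm(K), 0.2, ...)
  })
}

test_that("parameter constructor validates the simplex and shapes", {
  p <- toy_params()
  expect_s3_class(p, "pc_slda_params")
  expect_error(pc_slda_params(matrix(c(0.5, 0.6, 0.6, 0.4), 2), c(0, 0), 0))
  expect_error(pc_slda_params(p$topics, c(0, 0, 0), 0), "length")
  expect_error(pc_slda_params(p$topics, c(0, 0), 0, alpha = -1))
})

test_that("MAP inference returns simplex rows and is deterministic", {
  p <- toy_params()
  X <- matrix(c(4, 0, 1, 0, 2, 0,
                0, 3, 0, 2, 0, 1), 2, byrow = TRUE)
  a <- estimate_doc_topics(X, p)
  b <- estimate_doc_topics(X, p)
  expect_identical(a, b)
  expect_equal(rowSums(a$proportions), c(1, 1), tolerance = 1e-12)
  expect_true(all(a$proportions >= 0))
  # a vector input is treated as a single document
  one <- estimate_doc_topics(X[1, ], p)
  expect_equal(one$proportions, a$proportions[1, , drop = FALSE])
})

test_that("all-zero counts with a flat prior give uniform proportions", {
  p <- toy_params(alpha = 1)
  z <- estimate_doc_topics(rep(0, 6), p)
  expect_equal(drop(z$proportions), rep(0.5, 2), tolerance = 1e-12)
})

test_that("inference matches the dense grid-search oracle", {
  withr::with_seed(52, {
    for (r in 1:20) {
      V <- sample(4:12, 1)
      W <- matrix(rnorm(2 * V), 2, V)
      phi <- exp(W) / rowSums(exp(W))
      x <- rmultinom(1, sample(c(5, 30, 120), 1), colMeans(phi))[, 1]
      p <- pc_slda_params(phi, c(0, 0), 0)
      est <- estimate_doc_topics(x, p)$proportions[1, 1]
      expect_lt(abs(est - oracle_doc_topics_k2(x, phi)), 1e-3)
    }
  })
})

test_that("the inference objective is the value the oracle maximizes", {
  p <- toy_params()
  x <- c(3, 1, 0, 2, 0, 1)
  out <- estimate_doc_topics(x, p)
  expect_equal(out$objective,
               data_loglik(x, out$proportions[1, ], p$topics),
               tolerance = 1e-9)
})

test_that("training objective decomposes into data, label and penalty terms", {
  p <- toy_params(lambda_pc = 2)
  X <- matrix(c(4, 0, 1, 0, 2, 0,
                0, 3, 0, 2, 0, 1), 2, byrow = TRUE)
  y <- c(1, 0)
  pi_hat <- estimate_doc_topics(X, p)$proportions
  expected <- -data_loglik(X, pi_hat, p$topics) -
    2 * label_loglik(y, pi_hat, p$eta, p$bias) -
    0.01 * sum(log(p$topics)) + 0.1 * sum(p$eta^2)
  expect_equal(pc_objective(X, y, p, tau = 0.01, l2_eta = 0.1), expected,
               tolerance = 1e-8)
})

test_that("unrolled gradients match central finite differences", {
  withr::with_seed(53, {
    K <- 2; V <- 5
    X <- matrix(rpois(3 * V, 3) + 1, 3, V)
    y <- c(1, 0, 1)
    W <- matrix(rnorm(K * V, 0, 0.7), K, V)
    eta <- rnorm(K); bias <- 0.3
  })
  args <- list(X = X, y = y, alpha = 0.8, lambda = 2.5, n_iters = 7L,
               step = 2, eps = 1e-9, tau = 0.01, l2_eta = 0.1)
  g <- do.call(stablerx:::pc_loss_grad_free, c(list(W, eta, bias), args))
  f <- function(Wv, etav, bv) do.call(stablerx:::pc_loss_grad_free,
                                      c(list(matrix(Wv, K, V), etav, bv), args))$loss
  h <- 1e-6
  num_W <- matrix(NA_real_, K, V)
  for (i in seq_len(K * V)) {
    up <- c(W); dn <- c(W); up[i] <- up[i] + h; dn[i] <- dn[i] - h
    num_W[i] <- (f(up, eta, bias) - f(dn, eta, bias)) / (2 * h)
  }
  num_eta <- vapply(seq_len(K), function(i) {
    up <- eta; dn <- eta; up[i] <- up[i] + h; dn[i] <- dn[i] - h
    (f(c(W), up, bias) - f(c(W), dn, bias)) / (2 * h)
  }, numeric(1))
  num_b <- (f(c(W), eta, bias + h) - f(c(W), eta, bias - h)) / (2 * h)
  expect_lt(max(abs(num_W - g$grad_W) / pmax(abs(num_W), 1e-8)), 1e-4)
  expect_lt(max(abs(num_eta - g$grad_eta) / pmax(abs(num_eta), 1e-8)), 1e-4)
  expect_lt(abs(num_b - g$grad_bias) / max(abs(num_b), 1e-8), 1e-4)
})

test_that("training is deterministic given the seed and reduces the loss", {
  withr::with_seed(54, {
    phi <- rbind(c(0.7, 0.1, 0.1, 0.05, 0.05),
                 c(0.05, 0.05, 0.1, 0.1, 0.7))
    Pi <- cbind(runif(120), 0); Pi[, 2] <- 1 - Pi[, 1]
    X <- t(vapply(seq_len(120), function(i)
      rmultinom(1, 25, Pi[i, ] %*% phi)[, 1], numeric(5)))
    y <- rbinom(120, 1, plogis(4 * Pi[, 1] - 2))
  })
  fit1 <- train_pc_slda(X[1:80, ], y[1:80], X[81:120, ], y[81:120], K = 2,
                        lambda_grid = 1, seed = 9, n_restarts = 1,
                        max_epochs = 60, eval_every = 10, patience = 3)
  fit2 <- train_pc_slda(X[1:80, ], y[1:80], X[81:120, ], y[81:120], K = 2,
                        lambda_grid = 1, seed = 9, n_restarts = 1,
                        max_epochs = 60, eval_every = 10, patience = 3)
  expect_identical(fit1$topics, fit2$topics)
  expect_identical(fit1$val_auc, fit2$val_auc)
  expect_lt(fit1$trace$loss[nrow(fit1$trace)], fit1$trace$loss[1])
  expect_gt(fit1$val_auc, 0.6)
  expect_s3_class(fit1$selection, "data.frame")
})

test_that("predicted probabilities respond to the label weights", {
  p <- toy_params()
  X <- matrix(c(9, 0, 1, 0, 1, 0,
                0, 9, 0, 1, 0, 1), 2, byrow = TRUE)
  pr <- predict_stability_prob(X, p)
  expect_length(pr, 2)
  expect_true(all(pr > 0 & pr < 1))
  flipped <- p; flipped$eta <- -p$eta; flipped$bias <- -p$bias
  expect_equal(predict_stability_prob(X, flipped), 1 - pr, tolerance = 1e-9)
})

test_that("topic summaries rank words and round the label coefficient", {
  p <- toy_params()
  words <- sprintf("w%02d", 1:6)
  tw <- top_words_per_topic(p, words, n = 3)
  expect_equal(nrow(tw), 6)
  first <- tw[tw$topic == 1, ]
  expect_identical(first$word[1],
                   words[which.max(p$topics[1, ])])
  expect_true(all(diff(first$probability) <= 0))
  expect_equal(tw$coefficient, rep(round(p$eta, 1), each = 3))
})

test_that("model parameters round-trip through the text bundle", {
  p <- toy_params(lambda_pc = 3)
  d <- withr::local_tempdir()
  write_pc_slda(p, d, vocab_hash = "abc123")
  q <- read_pc_slda(d)
  expect_equal(q$topics, p$topics, tolerance = 1e-12)
  expect_equal(q$eta, p$eta, tolerance = 1e-12)
  expect_equal(q$bias, p$bias, tolerance = 1e-12)
  expect_equal(q$lambda_pc, 3, ignore_attr = TRUE)
  expect_identical(q$vocab_hash, "abc123")
})
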