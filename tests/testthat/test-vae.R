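test_that("encoding is deterministic with the contracted shapes", {
  a <- build_alphabet(c("CCO", "CCN", "c1ccccc1"))
  m <- vae_init(micro_gen_config(), a, seed = 3)
  tm <- denovomol:::tokenize_matrix(c("CCO", "c1ccccc1", "CN"), a)
  e1 <- vae_encode(m, tm$ids)
  e2 <- vae_encode(m, tm$ids)
  expect_identical(e1, e2)
  expect_equal(dim(e1$mu), c(3L, 4L))
  expect_equal(dim(e1$log_sigma), c(3L, 4L))
  expect_true(all(is.finite(e1$mu)) && all(is.finite(e1$log_sigma)))
  long <- matrix(0L, 1, 100)
  expect_error(vae_encode(m, long), "max_len")
})

test_that("reparameterization follows z = mu + exp(log_sigma) * eps", {
  mu <- c(1, -2, 0.5); ls <- c(0, 0, 0)
  expect_equal(reparameterize(mu, ls, c(0, 0, 0)), mu)
  expect_equal(reparameterize(mu, ls, c(1, 1, 1)), mu + 1)
  expect_error(reparameterize(mu, ls, c(1, 1)), "dimension")
  set.seed(1)
  draws <- replicate(10000, reparameterize(0, log(2), rnorm(1)))
  expect_equal(stats::var(draws), 4, tolerance = 0.1 * 4)
})

test_that("FPC scores form a probability vector; zero weights give uniform", {
  a <- build_alphabet("CCO")
  m <- vae_init(micro_gen_config(), a, seed = 5)
  z <- matrix(rnorm(8), 2, 4)
  s <- fpc_scores(m, z, c(0.2, 0.9))
  expect_true(all(s >= 0))
  expect_equal(rowSums(s), c(1, 1), tolerance = 1e-6)
  m0 <- m
  for (nm in grep("^fpc_", names(m0$params), value = TRUE))
    m0$params[[nm]] <- m0$params[[nm]] * 0
  s0 <- fpc_scores(m0, z, c(0.2, 0.9))
  expect_equal(unname(as.vector(s0)), rep(1 / 4, 8), tolerance = 1e-12)
})

test_that("softmax normalization matches the closed form", {
  s <- denovomol:::softmax_rows(matrix(c(0, log(3)), 1, 2))
  expect_equal(as.vector(s), c(0.25, 0.75), tolerance = 1e-12)
})

test_that("applying FPC scores rescales as documented", {
  z <- matrix(c(1, 2, 3, 4), 1, 4)
  uniform <- matrix(1 / 4, 1, 4)
  expect_equal(apply_fpc(z, uniform, rescale = FALSE), z / 4)
  expect_equal(apply_fpc(z, uniform, rescale = TRUE), z)
  onehot <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_equal(as.vector(apply_fpc(z, onehot)), c(1, 0, 0, 0))
})

test_that("decoder logits have the contracted shape and softmax rows", {
  a <- build_alphabet(c("CCO", "CCN"))
  m <- vae_init(micro_gen_config(), a, seed = 9)
  tm <- denovomol:::tokenize_matrix(c("CCO", "CN"), a)
  teacher <- tm$ids[, -ncol(tm$ids), drop = FALSE]
  zc <- matrix(rnorm(2 * 4), 2, 4)
  lg <- vae_decode_logits(m, zc, c(0.5, 0.7), teacher)
  expect_equal(dim(lg), c(2L, ncol(teacher), length(a$tokens)))
  pr <- denovomol:::softmax_rows(matrix(lg[1, 1, ], 1))
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  bad <- teacher; bad[, 1] <- 0L
  expect_error(vae_decode_logits(m, zc, c(0.5, 0.7), bad), "start token")
})

test_that("loss components match their closed forms", {
  # KL of a standard-normal posterior is zero; one dim with mu=1 gives 1/2
  expect_equal(denovomol:::vae_loss_kl(matrix(0, 1, 3), matrix(0, 1, 3)), 0)
  expect_equal(denovomol:::vae_loss_kl(matrix(1, 1, 1), matrix(0, 1, 1)), 0.5)
  # probability-1 logits give zero reconstruction loss
  a <- build_alphabet("CCO")
  ids <- matrix(tokenize("CCO", a), nrow = 1)
  target <- ids[, -1, drop = FALSE]
  V <- length(a$tokens)
  logits <- array(-1e4, c(1, ncol(target), V))
  for (t in seq_len(ncol(target))) logits[1, t, target[1, t] + 1] <- 1e4
  l <- vae_loss(logits, target, matrix(0, 1, 2), matrix(0, 1, 2),
                kl_weight = 1, pad_id = 0L)
  expect_equal(l$reconstruction, 0, tolerance = 1e-9)
  expect_equal(l$total, 0, tolerance = 1e-9)
  expect_equal(l$accuracy, 1)
})

test_that("KL is nonnegative across random posteriors", {
  set.seed(8)
  for (i in 1:50) {
    mu <- matrix(rnorm(6), 2, 3); ls <- matrix(rnorm(6, sd = 0.7), 2, 3)
    expect_gte(denovomol:::vae_loss_kl(mu, ls), 0)
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  a <- build_alphabet(c("CCO", "CCN", "OCC"))
  cfg <- gen_config(embedding_dim = 4, encoder_rnn_dim = 5,
                    encoder_rnn_layers = 2, latent_dim = 3,
                    fpc_hidden_dims = c(4, 3), decoder_rnn_dim = 6,
                    decoder_rnn_layers = 2, kl_weight = 0.7,
                    fpc_rescale = TRUE, max_len = 20)
  m <- vae_init(cfg, a, seed = 7)
  tm <- denovomol:::tokenize_matrix(c("CCO", "CN", "C"), a)
  cond <- c(0.3, 0.6, 0.9)
  eps <- matrix(rnorm(9), 3, 3)
  fb <- denovomol:::vae_forward_backward(m, tm$ids, cond, eps)
  h <- 1e-5
  for (nm in names(m$params)) {
    P <- m$params[[nm]]
    for (k in sample(length(P), min(4, length(P)))) {
      m2 <- m; m2$params[[nm]][k] <- P[k] + h
      lp <- denovomol:::vae_forward_backward(m2, tm$ids, cond, eps)$total
      m2$params[[nm]][k] <- P[k] - h
      lm <- denovomol:::vae_forward_backward(m2, tm$ids, cond, eps)$total
      num <- (lp - lm) / (2 * h)
      ana <- fb$grads[[nm]][k]
      expect_equal(ana, num, tolerance = 1e-3,
                   label = paste("grad", nm, "entry", k))
    }
  }
})
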