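test_that("accuracy early stop fires after exactly the window length", {
  corpus <- rep("CCO", 64)  # one batch per epoch
  res <- vae_train(corpus, config = micro_gen_config(),
                   train = train_config(batch_size = 64, max_epochs = 20,
                                        acc_threshold_delta = 0.95,
                                        acc_window_steps = 6, seed = 1),
                   cond = rep(0.5, 64),
                   step_override = function(step) 0.96)
  expect_equal(res$stopped_by, "accuracy")
  expect_equal(nrow(res$log), 6L)
})

test_that("below-threshold accuracy runs to the epoch cap", {
  corpus <- rep("CCO", 64)
  res <- vae_train(corpus, config = micro_gen_config(),
                   train = train_config(batch_size = 64, max_epochs = 8,
                                        acc_window_steps = 5, seed = 1),
                   cond = rep(0.5, 64),
                   step_override = function(step) 0.5)
  expect_equal(res$stopped_by, "max_epochs")
  expect_equal(max(res$log$epoch), 8)
})

test_that("an interrupted above-threshold streak resets the counter", {
  corpus <- rep("CCO", 64)
  stream <- c(0.96, 0.96, 0.5, rep(0.96, 4))
  res <- vae_train(corpus, config = micro_gen_config(),
                   train = train_config(batch_size = 64, max_epochs = 10,
                                        acc_window_steps = 4, seed = 1),
                   cond = rep(0.5, 64),
                   step_override = function(step) stream[min(step, length(stream))])
  expect_equal(res$stopped_by, "accuracy")
  expect_equal(nrow(res$log), 7L)  # 2 hot + 1 reset + 4 hot
})

test_that("learning rate decays multiplicatively on the stated schedule", {
  lr <- denovomol:::lr_at_step(5e-4, 0:2999, 0.03, 1000)
  expect_equal(unique(lr), 5e-4 * (1 - 0.03)^(0:2))
  expect_equal(sum(lr == 5e-4), 1000L)
})

test_that("training is reproducible under a fixed seed", {
  corpus <- generate_smiles_corpus(40, seed = 3)
  run <- function() {
    suppressWarnings(vae_train(corpus, config = micro_gen_config(),
              train = train_config(batch_size = 20, max_epochs = 2,
                                   base_lr = 1e-3, seed = 13),
              cond = rep(0.5, 40)))
  }
  r1 <- run(); r2 <- run()
  expect_identical(tail(r1$log$total, 1), tail(r2$log$total, 1))
  expect_identical(r1$model$params$out_W, r2$model$params$out_W)
})

test_that("training loss trends downward over the first steps", {
  corpus <- generate_smiles_corpus(120, seed = 6)
  res <- suppressWarnings(vae_train(corpus, config = micro_gen_config(),
                   train = train_config(batch_size = 24, max_epochs = 10,
                                        base_lr = 3e-3, seed = 2),
                   cond = rep(0.5, 120)))
  chunk <- function(v, i) mean(v[((i - 1) * 10 + 1):(i * 10)])
  means <- vapply(1:5, function(i) chunk(res$log$total, i), numeric(1))
  expect_lt(means[5], means[1])
})

test_that("finetune plateau stop restores the best epoch", {
  a <- build_alphabet("CCO")
  m <- vae_init(micro_gen_config(), a, seed = 1)
  mock <- c(3, 2, 2, 2, 2, 2, 2, 1.5)  # would improve at epoch 8 if reached
  res <- vae_finetune(m, "CCO", impatience_n = 5, epoch_cap = 50,
                      epoch_loss_override = function(e) mock[min(e, length(mock))])
  expect_equal(res$stopped_by, "plateau")
  expect_equal(length(res$epoch_losses), 7L)  # stopped after epoch 7
  expect_equal(res$best_epoch, 2L)
})

test_that("strictly decreasing losses run to the epoch cap", {
  a <- build_alphabet("CCO")
  m <- vae_init(micro_gen_config(), a, seed = 1)
  res <- vae_finetune(m, "CCO", impatience_n = 3, epoch_cap = 12,
                      epoch_loss_override = function(e) 10 - e)
  expect_equal(res$stopped_by, "epoch_cap")
  expect_equal(length(res$epoch_losses), 12L)
  expect_equal(res$best_epoch, 12L)
})

test_that("finetuning rejects corpora outside the model alphabet", {
  a <- build_alphabet("CCO")
  m <- vae_init(micro_gen_config(), a, seed = 1)
  expect_error(vae_finetune(m, c("CCO", "CCS")), "outside the model alphabet")
})

test_that("checkpoints round-trip through disk", {
  a <- build_alphabet(c("CCO", "CCN"))
  m <- vae_init(micro_gen_config(), a, seed = 4)
  tf <- withr::local_tempfile(fileext = ".rds")
  vae_save(m, tf)
  m2 <- vae_load(tf)
  expect_equal(m2$params, m$params)
  expect_equal(m2$alphabet$tokens, m$alphabet$tokens)
})
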