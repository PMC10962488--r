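# Mock pieces: a finetuner that leaves the model untouched, and samplers
# with scripted behaviour. The "model" can be any object because the mocks
# never look inside it.
noop_finetuner <- function(model, domain) model

always_active <- function(smiles) rep(TRUE, length(smiles))

test_that("qualification applies the five criteria in input order", {
  train_ref <- canonicalize_smiles("c1ccccc1CCN")
  samples <- c("C((",                 # unparseable
               "c1ccccc1CCN",         # in training set
               "Oc1ccc(CCc2ccccc2)cc1",  # qualifies
               "NCCc1ccccc1",         # duplicate of the training molecule
               "Oc1ccc(CCc2ccccc2)cc1",  # duplicate of a kept sample
               "CCO")                 # QED below threshold
  q <- qualify_generated(samples, training_set = train_ref,
                         qed_threshold = 0.6, activity_model = always_active)
  expect_equal(q$canonical_smiles,
               canonicalize_smiles("Oc1ccc(CCc2ccccc2)cc1"))
  expect_true(all(q$qed > 0.6))
})

test_that("qualification without an activity model warns and skips it", {
  expect_warning(
    q <- qualify_generated("Oc1ccc(CCc2ccccc2)cc1", qed_threshold = 0.6),
    "skips the activity criterion")
  expect_equal(nrow(q), 1L)
})

test_that("a never-novel sampler stops PRTL at recurrence one", {
  sampler <- function(model, config, recurrence) list("c1ccccc1CCN")
  res <- prtl_run(model = structure(list(), class = "vae_fpc"),
                  initial_domain = "c1ccccc1CCN",
                  config = transfer_config(max_recurrences = 50, seed = 1),
                  activity_model = always_active,
                  training_set = canonicalize_smiles("c1ccccc1CCN"),
                  sampler = sampler, finetuner = noop_finetuner)
  expect_equal(res$recurrence_count, 1L)
  expect_equal(nrow(res$novel_molecules), 0L)
})

test_that("an always-novel sampler runs to the recurrence cap", {
  pool <- generate_smiles_corpus(400, seed = 77)
  i <- 0
  sampler <- function(model, config, recurrence) {
    i <<- i + 1
    list(pool[((i - 1) * 5 + 1):(i * 5)])
  }
  res <- prtl_run(model = structure(list(), class = "vae_fpc"),
                  initial_domain = "c1ccccc1CCN",
                  config = transfer_config(max_recurrences = 50,
                                           qed_threshold = 0, seed = 1),
                  activity_model = always_active,
                  sampler = sampler, finetuner = noop_finetuner)
  expect_equal(res$recurrence_count, 50L)
  expect_gt(nrow(res$novel_molecules), 0L)
})

test_that("novel molecules never intersect the reference sets and the domain grows", {
  pool <- generate_smiles_corpus(120, seed = 78)
  train_ref <- canonicalize_smiles(pool[1:40])
  fine_ref <- canonicalize_smiles(pool[41:60])
  i <- 0
  sizes <- integer(0)
  sampler <- function(model, config, recurrence) {
    i <<- i + 1
    list(pool[((i - 1) * 20 + 1):(i * 20 + 20)])
  }
  domains <- list()
  finetuner <- function(model, domain) {
    domains[[length(domains) + 1]] <<- domain
    model
  }
  res <- prtl_run(model = structure(list(), class = "vae_fpc"),
                  initial_domain = pool[1:10],
                  config = transfer_config(max_recurrences = 4,
                                           qed_threshold = 0,
                                           domain_update_mode = "append",
                                           seed = 1),
                  activity_model = always_active,
                  training_set = train_ref, finetune_set = fine_ref,
                  sampler = sampler, finetuner = finetuner)
  nov <- res$novel_molecules$canonical_smiles
  expect_equal(anyDuplicated(nov), 0L)
  expect_length(intersect(nov, c(train_ref, fine_ref)), 0L)
  lens <- vapply(domains, length, integer(1))
  expect_true(all(diff(lens) >= 0))
})

test_that("staged PTL requires nonempty domains and runs stage by stage", {
  a <- build_alphabet(c("CCO", "CCN"))
  m <- vae_init(micro_gen_config(), a, seed = 2)
  expect_error(ptl_finetune(m, list(character(0))), "empty")
  res <- ptl_finetune(m, list(c("CCO", "CCN"), "CCO"),
                      config = transfer_config(impatience_n = 2, epoch_cap = 3,
                                               seed = 1),
                      train = train_config(batch_size = 2, max_epochs = 3,
                                           seed = 1))
  expect_length(res$stages, 2L)
  expect_s3_class(res$model, "vae_fpc")
})
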