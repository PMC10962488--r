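test_that("generated corpora are valid, deterministic and constraint-true", {
  c1 <- generate_smiles_corpus(300, seed = 15)
  c2 <- generate_smiles_corpus(300, seed = 15)
  expect_identical(c1, c2)
  res <- filter_corpus(c1)
  expect_equal(sum(res$rejections), 0L)
  expect_true(all(res$records$n_heavy >= 5 & res$records$n_heavy <= 70))
  expect_true(all(nchar(c1) <= 120))
  c3 <- generate_smiles_corpus(300, seed = 16)
  expect_false(identical(c1, c3))
})

test_that("a required fragment appears in every molecule", {
  marked <- generate_smiles_corpus(50, seed = 17, required_fragment = "c1ccsc1")
  expect_true(all(grepl("s", marked, fixed = TRUE)))
  expect_true(all(is_valid_smiles(marked)))
})

test_that("capacity exhaustion falls back to duplicates with a warning", {
  expect_warning(
    out <- generate_smiles_corpus(60, seed = 18, max_middle = 0L,
                                  required_fragment = "c1ccsc1"),
    "duplicates")
  expect_length(out, 60L)
})

test_that("activity datasets carry the generating rule and derived fields", {
  ds <- generate_activity_dataset(100, seed = 19, noise_sigma = 0.3)
  rec <- ds$records
  expect_equal(rec$pic50, -log10(rec$ic50 * 1e-6), tolerance = 1e-9)
  expect_equal(rec$active_label, as.integer(rec$ic50 < 10))
  expect_equal(colnames(ds$counts), names(ds$rule$weights))
  ds2 <- generate_activity_dataset(100, seed = 19, noise_sigma = 0.3)
  expect_identical(ds$records, ds2$records)
})

test_that("noiseless pIC50 is an exact function of structure", {
  ds <- generate_activity_dataset(50, seed = 20, noise_sigma = 0)
  expected <- ds$rule$base + as.vector(ds$counts %*% ds$rule$weights)
  expect_equal(ds$records$pic50, expected, tolerance = 1e-12)
})

test_that("default-rule datasets populate all four sub-domains", {
  ds <- generate_activity_dataset(400, seed = 21, noise_sigma = 0.5)
  p <- partition_target_domain(ds$records, partition_thresholds())
  expect_true(all(vapply(p[c("A", "B", "C", "D")], nrow, integer(1)) > 0))
})

test_that("label balance matches the Gaussian flip probability oracle", {
  sigma <- 0.3
  ds <- generate_activity_dataset(1000, seed = 22, noise_sigma = sigma)
  frac <- mean(ds$records$active_label)
  # same seed draws the same molecules; the noiseless pIC50 plus threshold
  # noise gives the exact expected active fraction
  clean <- generate_activity_dataset(1000, seed = 22, noise_sigma = 0)
  implied <- mean(stats::pnorm((clean$records$pic50 - 5) / sigma))
  expect_lt(abs(frac - implied), 0.05)
})
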