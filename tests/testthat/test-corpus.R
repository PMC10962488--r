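test_that("filter applies the stated rules, counting by first failure", {
  res <- filter_corpus(c("CCO",            # 2 heavy atoms: below range
                         "CP(=O)(O)O",     # phosphorus not allowed
                         "c1ccccc1CCN",    # retained
                         "C((",            # unparseable
                         "c1ccccc1CCO"),   # retained
                       filter_criteria())
  expect_equal(nrow(res$records), 2L)
  expect_equal(unname(res$rejections["heavy_atom_range"]), 1L)
  expect_equal(unname(res$rejections["allowed_atomic_numbers"]), 1L)
  expect_equal(unname(res$rejections["parse"]), 1L)
  expect_error(filter_corpus(character(0)), "empty")
})

test_that("raw length and exclusion-set rules apply", {
  long <- paste(rep("C", 130), collapse = "")
  res <- filter_corpus(c(long, "c1ccccc1CCN"),
                       filter_criteria(exclude_set =
                         canonicalize_smiles("c1ccccc1CCN")))
  expect_equal(nrow(res$records), 0L)
  expect_equal(unname(res$rejections["max_smiles_length"]), 1L)
  expect_equal(unname(res$rejections["exclude_set"]), 1L)
})

test_that("filtering is idempotent on the retained set", {
  smiles <- generate_smiles_corpus(60, seed = 2)
  first <- filter_corpus(smiles)
  second <- filter_corpus(first$records$raw_smiles)
  expect_equal(nrow(second$records), nrow(first$records))
  expect_equal(sum(second$rejections), 0L)
})

test_that("molecule records keep ic50 and pic50 consistent", {
  rec <- molecule_records(c("c1ccccc1CCN", "c1ccccc1CCO"), ic50 = c(1, 0.5))
  expect_equal(rec$pic50, -log10(rec$ic50 * 1e-6), tolerance = 1e-6)
  expect_equal(rec$pic50[1], 6)
  expect_true(all(rec$qed >= 0 & rec$qed <= 1))
  expect_error(molecule_records("C(("), "invalid")
})
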