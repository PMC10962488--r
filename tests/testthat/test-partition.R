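fake_records <- function(qed, ic50) {
  data.frame(canonical_smiles = sprintf("mol%02d", seq_along(qed)),
             qed = qed, ic50 = ic50)
}

test_that("sub-domain boundary semantics follow the inequality signs", {
  t_crc <- partition_thresholds(qed_split = 0.6, ic50_min = 0,
                                ic50_split = 1, ic50_max = 10)
  rec <- fake_records(qed = c(0.7, 0.7, 0.3, 0.3, 0.6, 0.7, 0.7),
                      ic50 = c(0.5, 5, 0.5, 5, 1.0, 1.0, 12))
  p <- partition_target_domain(rec, t_crc)
  expect_equal(p$A$canonical_smiles, "mol01")  # drug-like, high activity
  expect_equal(p$B$canonical_smiles, c("mol02", "mol06"))  # ic50 = split -> B
  expect_equal(p$C$canonical_smiles, "mol03")
  expect_equal(p$D$canonical_smiles, c("mol04", "mol05"))  # qed = split -> non-drug-like
  expect_equal(p$out_of_range$canonical_smiles, "mol07")
})

test_that("partition is disjoint and covers the in-range records", {
  ds <- generate_activity_dataset(1000, seed = 9, noise_sigma = 0.5)
  rec <- ds$records
  rec$row_id <- seq_len(nrow(rec))
  p <- partition_target_domain(rec, partition_thresholds())
  all_ids <- unlist(lapply(p[c("A", "B", "C", "D")], function(d) d$row_id))
  expect_equal(anyDuplicated(all_ids), 0L)
  n_in <- sum(rec$ic50 > 0 & rec$ic50 <= 10)
  expect_equal(length(all_ids), n_in)
  expect_equal(nrow(p$out_of_range), nrow(rec) - n_in)
})

test_that("empty input and missing values behave as documented", {
  empty <- fake_records(numeric(0), numeric(0))
  p <- partition_target_domain(empty)
  expect_true(all(vapply(p, nrow, integer(1)) == 0))
  bad <- fake_records(c(0.5, NA), c(1, 2))
  expect_error(partition_target_domain(bad), "missing qed/ic50")
})

test_that("threshold invariants are enforced", {
  expect_error(partition_thresholds(ic50_split = 0, ic50_min = 1))
  expect_error(partition_thresholds(qed_split = 1.2))
})
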