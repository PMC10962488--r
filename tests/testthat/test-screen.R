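test_that("novelty filter partitions by canonical identity", {
  cands <- c("Oc1ccc(CCc2ccccc2)cc1", "OCC", "CCCC")
  refs <- list(c("CCO"), c("c1ccccc1"))
  nf <- novelty_filter(cands, refs)
  expect_equal(nf$known, "OCC")  # canonical match against CCO
  expect_equal(nf$novel, cands[c(1, 3)])
  expect_equal(sort(c(nf$novel, nf$known)), sort(cands))
  all_novel <- novelty_filter(cands, list())
  expect_equal(all_novel$novel, cands)
})

test_that("ranking is directional, stable and tie-broken canonically", {
  r <- rank_candidates(c("CCO", "CCN", "CCC"), c(7, 9, 8), "activity_desc")
  expect_equal(r$smiles, c("CCN", "CCC", "CCO"))
  expect_equal(r$rank, 1:3)
  d <- rank_candidates(c("CCO", "CCN"), c(-7.049, -6.679), "docking_asc")
  expect_equal(d$score, c(-7.049, -6.679))
  expect_equal(d$smiles[1], "CCO")
  t1 <- rank_candidates(c("CCN", "CCO"), c(5, 5), "activity_desc")
  t2 <- rank_candidates(c("CCO", "CCN"), c(5, 5), "activity_desc")
  expect_equal(t1$smiles, t2$smiles)  # order independent of input order
  expect_error(rank_candidates(c("CCO"), setNames(1, "CCN")), "missing score")
})

test_that("SA picks take the per-window minimum with truncation", {
  cands <- generate_smiles_corpus(20, seed = 81)
  ranked <- rank_candidates(cands, seq(20, 1), "activity_desc")
  picks <- pick_by_sa(ranked)
  sa <- sa_score(ranked$smiles)
  expect_equal(picks$rank[1], which.min(sa[1:10]))
  expect_equal(picks$rank[2], 10 + which.min(sa[11:20]))
  short <- ranked[1:12, ]
  expect_warning(p2 <- pick_by_sa(short), "truncated")
  expect_equal(p2$window[2], "[11,12]")
  w <- capture_warnings(p3 <- pick_by_sa(ranked[1:5, ]))
  expect_true(any(grepl("skipped", w)))
  expect_equal(nrow(p3), 1L)
})

test_that("the full screen is deterministic end to end", {
  cands <- generate_smiles_corpus(25, seed = 82)
  scores <- seq(9, by = -0.1, length.out = 25)
  run <- function() screen_candidates(cands, scores, mode = "activity_desc",
                                      reference_sets = list(cands[21:25]))
  r1 <- run(); r2 <- run()
  expect_identical(r1$ranked, r2$ranked)
  expect_identical(r1$picks, r2$picks)
  expect_equal(nrow(r1$ranked), 20L)
})
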