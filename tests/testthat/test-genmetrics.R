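# A scripted activity predicate keyed by canonical SMILES.
predicate_for <- function(active_set) {
  function(smiles) smiles %in% active_set
}

test_that("metric suite reproduces the worked example exactly", {
  # 10 samples: 8 valid, 6 unique, 3 drug-like, 2 active, 1 novel
  uniq6 <- c("Oc1ccc(CCc2ccccc2)cc1",      # QED .80, active, novel
             "Oc1ccc(CCc2ccccc2)cc1C",     # QED high, active, in training set
             "CCOc1ccc(CN(C)CC)cc1",       # QED high, inactive
             "CCO", "CCN", "CCCC")         # below the QED threshold
  dup2 <- c("OCC", "NCC")                  # duplicates of CCO/CCN
  invalid2 <- c("C((", "F=F")
  samples <- c(uniq6, dup2, invalid2)
  can <- canonicalize_smiles(uniq6[1:3])
  active <- predicate_for(can[1:2])
  training <- can[2]
  rpt <- evaluate_generation(list(samples), training_set = training,
                             qed_threshold = 0.6, activity_model = active)
  s <- rpt$summary
  expect_equal(unname(s["validity"]), 80)
  expect_equal(unname(s["uniqueness"]), 75)
  expect_equal(unname(s["qed_request"]), 50)
  expect_equal(unname(s["num_qed_request"]), 3)
  expect_equal(unname(s["lead_request"]), 200 / 3, tolerance = 1e-9)
  expect_equal(unname(s["num_lead"]), 2)
  expect_equal(unname(s["novelty"]), 50)
  expect_equal(unname(s["num_novel_lead"]), 1)
})

test_that("count identities hold per repetition and averaging is arithmetic", {
  reps <- list(generate_smiles_corpus(12, seed = 51),
               generate_smiles_corpus(12, seed = 52))
  rpt <- evaluate_generation(reps, qed_threshold = 0.6,
                             activity_model = function(s) rep(TRUE, length(s)))
  pr <- rpt$per_repetition
  for (i in 1:2) {
    direct <- pr$n_sample[i] * (pr$validity[i] / 100) *
      (pr$uniqueness[i] / 100) * (pr$qed_request[i] / 100)
    expect_equal(pr$num_qed_request[i], direct, tolerance = 1e-9)
  }
  expect_equal(unname(rpt$summary["validity"]), mean(pr$validity))
})

test_that("all-invalid repetitions degrade to zero with a warning", {
  w <- capture_warnings(
    rpt <- evaluate_generation(list(c("C((", "F=F")),
                               activity_model = function(s) rep(TRUE, length(s))))
  expect_true(any(grepl("degenerate", w)))
  expect_equal(unname(rpt$summary["validity"]), 0)
  expect_equal(unname(rpt$summary["uniqueness"]), 0)
})

test_that("metrics are invariant to sample order", {
  samples <- generate_smiles_corpus(20, seed = 53)
  r1 <- evaluate_generation(list(samples),
                            activity_model = function(s) rep(TRUE, length(s)))
  r2 <- evaluate_generation(list(rev(samples)),
                            activity_model = function(s) rep(TRUE, length(s)))
  expect_equal(r1$summary, r2$summary)
})

test_that("chemical-space embedding is seeded and separates scaffold families", {
  fam1 <- generate_smiles_corpus(20, seed = 61, required_fragment = "c1ccsc1")
  fam2 <- paste0(strrep("C", 5:19), "O")  # homologous alcohols, no rings
  smiles <- c(fam1, fam2)
  grp <- c(rep("thio", length(fam1)), rep("oxo", length(fam2)))
  emb1 <- embed_chemical_space(smiles, group = grp, seed = 3, perplexity = 5)
  emb2 <- embed_chemical_space(smiles, group = grp, seed = 3, perplexity = 5)
  expect_equal(nrow(emb1), length(smiles))
  expect_identical(emb1$x, emb2$x)
  xy <- as.matrix(emb1[, c("x", "y")])
  d <- as.matrix(dist(xy))
  same <- outer(grp, grp, "==")
  diag(same) <- NA
  expect_gt(mean(d[!same & !is.na(same)]), mean(d[same & !is.na(same)]))
  expect_error(embed_chemical_space(smiles[1:4]), "at least 5")
  expect_error(embed_chemical_space(smiles, perplexity = 30), "perplexity")
})
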