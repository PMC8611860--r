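test_that("synth_spec rejects invalid parameter combinations", {
  expect_error(synth_spec(n_pairs = -1), "non-negative")
  expect_error(synth_spec(noise_sd = -0.1), "noise_sd")
  expect_error(synth_spec(hazard_ratio = 0), "hazard_ratio")
  expect_error(synth_spec(censor_rate = 1), "censor_rate")
  expect_error(
    synth_spec(n_lnc = 2, planted_de = data.frame(feature = "LNC9999", log2fc = 1)),
    "undeclared")
  expect_error(
    synth_spec(planted_triplets = data.frame(lncRNA = "LNC0001", miRNA = "MIRX",
                                             mRNA = "MRNA0001", beta = 1)),
    "undeclared")
  expect_error(generate_expression(synth_spec(n_pairs = 0)), "pair")
  expect_error(generate_cerna_system(synth_spec(seq_len = 5)), "seq_len")
})

test_that("zero-noise planted fold change is recovered exactly in every pair", {
  spec <- synth_spec(n_pairs = 4, n_lnc = 5, n_mrna = 5, noise_sd = 0,
                     planted_de = data.frame(feature = "LNC0001", log2fc = 1))
  g <- generate_expression(spec)
  d <- 2^(cernet:::pair_differences(g$expr))
  expect_equal(unname(d["LNC0001", ]), rep(2, 4))
  expect_equal(unname(d["LNC0002", ]), rep(1, 4))
})

test_that("generators are bit-identical for identical specs", {
  spec <- synth_spec(n_pairs = 3, n_lnc = 10, n_mrna = 10, n_mirna = 4,
                     planted_triplets = data.frame(lncRNA = "LNC0001", miRNA = "MIR0001",
                                                   mRNA = "MRNA0001", beta = 0.8),
                     seed = 42)
  expect_identical(generate_expression(spec), generate_expression(spec))
  expect_identical(generate_cerna_system(spec), generate_cerna_system(spec))
  g <- rep(c("a", "b"), each = 10)
  expect_identical(generate_survival(spec, g), generate_survival(spec, g))
  expect_identical(generate_clinical(spec, 50), generate_clinical(spec, 50))
})

test_that("estimated log2 fold change tracks the planted value under noise", {
  # Monte-Carlo contract: mean of per-pair differences has sd
  # noise_sd * sqrt(2 / n_pairs); the estimate must fall within 3 sd.
  spec <- synth_spec(n_pairs = 50, n_lnc = 5, n_mrna = 5, noise_sd = 0.5,
                     planted_de = data.frame(feature = "LNC0001", log2fc = 2),
                     seed = 11)
  g <- generate_expression(spec)
  est <- mean(cernet:::pair_differences(g$expr)["LNC0001", ])
  expect_lt(abs(est - 2), 3 * 0.5 * sqrt(2 / 50))
})

test_that("planted ceRNA structure: correlation, degeneracy, seed sites", {
  trip <- data.frame(lncRNA = "LNC0001", miRNA = "MIR0001", mRNA = "MRNA0001", beta = 1)
  spec <- synth_spec(n_pairs = 10, n_lnc = 3, n_mrna = 3, n_mirna = 2,
                     planted_triplets = trip, noise_sd = 0, seq_len = 60, seed = 5)
  sys <- generate_cerna_system(spec)
  x <- condition_matrix(sys$lnc, "tumor")["LNC0001", ]
  y <- condition_matrix(sys$mrna, "tumor")["MRNA0001", ]
  z <- condition_matrix(sys$mirna, "tumor")["MIR0001", ]
  expect_equal(cor(x, y), 1)
  expect_equal(cor(x, z), -1)
  # noiseless triplet is degenerate for the partial correlation and must be
  # reported as such, not silently dropped
  pairs <- data.frame(lncRNA = "LNC0001", mRNA = "MRNA0001",
                      r_tumor = 1, r_normal = 1, stringsAsFactors = FALSE)
  asm <- assemble_triplets(pairs, sys$lnc, sys$mrna, sys$mirna,
                           sys$lnc_seq, sys$mrna_seq, sys$mirna_seq)
  expect_equal(nrow(asm$triplets), 0)
  expect_true(any(grepl("degenerate|undefined", asm$excluded$reason)))
  # planted seed sites are present at the recorded 0-based positions
  sites <- sys$truth$true_seed_sites
  for (i in seq_len(nrow(sites))) {
    target_seq <- c(sys$lnc_seq, sys$mrna_seq)[[sites$target[i]]]
    hit <- find_seed_matches(sys$mirna_seq[[sites$mirna[i]]], target_seq)
    expect_true(sites$position[i] %in% hit$positions)
  }
})

test_that("ground truth is conserved and references declared features only", {
  spec <- cerna_recovery_spec(seed = 3)
  sys <- generate_cerna_system(spec)
  truth <- sys$truth$true_triplets
  expect_equal(nrow(truth), 20)
  expect_equal(anyDuplicated(truth[c("lncRNA", "miRNA", "mRNA")]), 0)
  expect_true(all(truth$lncRNA %in% rownames(sys$lnc$values)))
  expect_true(all(truth$mRNA %in% rownames(sys$mrna$values)))
  expect_true(all(truth$miRNA %in% rownames(sys$mirna$values)))
  expect_equal(nrow(sys$truth$true_seed_sites), 40)
})

test_that("survival generator honors censoring, grouping and errors", {
  spec <- synth_spec(n_pairs = 4, hazard_ratio = 3, censor_rate = 0, seed = 9)
  g <- rep(c("low", "high"), each = 100)
  rec <- generate_survival(spec, g)
  expect_true(all(rec$event))
  expect_equal(nrow(rec), 200)
  # reference group (first label seen) has the baseline hazard; the other
  # group dies hazard_ratio times faster
  expect_gt(mean(rec$time[rec$group == "low"]), mean(rec$time[rec$group == "high"]))
  expect_error(generate_survival(spec, rep("low", 10)), "two")
  spec2 <- synth_spec(censor_rate = 0.5, seed = 2)
  rec2 <- generate_survival(spec2, g)
  expect_gt(mean(!rec2$event), 0.3) # about half censored
})

test_that("clinical tables conserve subject counts and track proportions", {
  spec <- synth_spec(seed = 21)
  cl <- generate_clinical(spec, 514)
  expect_equal(nrow(cl), 514)
  for (v in c("age_group", "sex", "stage"))
    expect_equal(sum(table(cl[[v]])), 514)
  # binomial 3-sigma check on the seeded sex draw
  p <- 0.467
  expect_lt(abs(sum(cl$sex == "Male") - 514 * p), 3 * sqrt(514 * p * (1 - p)))
  one <- generate_clinical(spec, 20, proportions = list(grp = c(only = 1)))
  expect_true(all(one$grp == "only"))
})
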