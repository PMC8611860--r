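test_that("pairwise correlation is Pearson per condition with undefined flags", {
  set.seed(2)
  x <- matrix(rnorm(30), 3, 10, dimnames = list(c("L1", "L2", "L3"), NULL))
  x["L3", ] <- 5                        # constant lncRNA
  y <- rbind(M1 = x["L1", ], M2 = rnorm(10))
  es_l <- make_two_condition_es(x, matrix(rnorm(30), 3, 10, dimnames = dimnames(x)))
  es_m <- make_two_condition_es(y, matrix(rnorm(20), 2, 10, dimnames = dimnames(y)))
  ct <- pairwise_correlation(es_l, es_m, "tumor")
  expect_equal(ct$r[ct$lncRNA == "L1" & ct$mRNA == "M1"], 1)
  expect_false(ct$defined[ct$lncRNA == "L3" & ct$mRNA == "M1"])
  # independence bound: |r| < 3/sqrt(n) at n = 1000
  set.seed(5)
  big_a <- matrix(rnorm(1000), 1, 1000, dimnames = list("L1", NULL))
  big_b <- matrix(rnorm(1000), 1, 1000, dimnames = list("M1", NULL))
  es_a <- make_two_condition_es(big_a, big_a)
  es_b <- make_two_condition_es(big_b, big_b)
  expect_lt(abs(pairwise_correlation(es_a, es_b, "tumor")$r), 0.1)
  # fewer than 3 samples is an error
  tiny <- make_two_condition_es(matrix(1:2, 1, 2, dimnames = list("L1", NULL)),
                                matrix(3:4, 1, 2, dimnames = list("L1", NULL)))
  expect_error(pairwise_correlation(tiny, tiny, "tumor"), "3 samples")
})

test_that("nearest-rank percentile threshold with strict exceedance", {
  v <- seq(0, 1, by = 0.01)                       # 101 values
  pt <- percentile_threshold(v, 99)
  expect_equal(pt$threshold, 0.99)
  expect_equal(v[pt$selected], 1.00)
  # degenerate all-equal distribution selects nothing
  pt2 <- percentile_threshold(rep(0.5, 50), 99)
  expect_equal(sum(pt2$selected), 0)
  expect_error(percentile_threshold(rep(NA_real_, 5), 99), "defined")
  expect_error(percentile_threshold(v, 100), "\\(0, 100\\)")
})

test_that("pair selection demands exceedance in both conditions", {
  pairs <- expand.grid(lncRNA = sprintf("L%02d", 1:10), mRNA = sprintf("M%02d", 1:10),
                       stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$mRNA, pairs$lncRNA), ]
  set.seed(8)
  ct <- cbind(pairs, r = runif(100, -0.2, 0.2))
  cn <- cbind(pairs, r = runif(100, -0.2, 0.2))
  ct$r[1] <- 0.95; cn$r[1] <- 0.9     # exceeds in both
  ct$r[2] <- 0.99; cn$r[2] <- -0.5    # tumor only
  ct$defined <- cn$defined <- TRUE
  sel <- select_cerna_pairs(ct, cn, q = 90, rule = "both")
  expect_true(paste(ct$lncRNA[1], ct$mRNA[1]) %in% paste(sel$pairs$lncRNA, sel$pairs$mRNA))
  expect_false(paste(ct$lncRNA[2], ct$mRNA[2]) %in% paste(sel$pairs$lncRNA, sel$pairs$mRNA))
  sel_e <- select_cerna_pairs(ct, cn, q = 90, rule = "either")
  expect_true(paste(ct$lncRNA[2], ct$mRNA[2]) %in% paste(sel_e$pairs$lncRNA, sel_e$pairs$mRNA))
  # raising q never adds a selected pair
  sel99 <- select_cerna_pairs(ct, cn, q = 99, rule = "both")
  expect_true(all(paste(sel99$pairs$lncRNA, sel99$pairs$mRNA) %in%
                  paste(sel$pairs$lncRNA, sel$pairs$mRNA)))
})

test_that("partial correlation follows the formula and flags degeneracy", {
  expect_equal(partial_correlation(0.5, 0, 0), 0.5)
  expect_equal(partial_correlation(0.48, 0.8, 0.6), 0)          # fully mediated
  expect_equal(partial_correlation(0.6, 0.5, 0.5), 0.35 / 0.75)
  expect_error(partial_correlation(0.5, 1, 0.2), "degenerate")
  expect_error(partial_correlation(1.2, 0.1, 0.1), "\\[-1, 1\\]")
})

test_that("partial correlation equals the residual-correlation oracle", {
  # the two regression models reading: correlate the residuals of X ~ Z
  # and Y ~ Z and compare with the closed form on the sample correlations
  set.seed(13)
  for (rep in 1:25) {
    n <- 40
    z <- rnorm(n)
    x <- 0.7 * z + rnorm(n)
    y <- -0.4 * z + rnorm(n)
    closed <- partial_correlation(cor(x, y), cor(x, z), cor(z, y))
    oracle <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
    expect_equal(as.numeric(closed), oracle, tolerance = 1e-10)
  }
})

test_that("triplet assembly enforces seed restriction and sensitivity threshold", {
  set.seed(17)
  n <- 40
  z <- rnorm(n)
  tumor_l <- rbind(L1 = 8 - 0.9 * z + rnorm(n, sd = 0.3))
  tumor_m <- rbind(M1 = 8 - 0.9 * z + rnorm(n, sd = 0.3))
  tumor_z <- rbind(Z1 = 8 + z + rnorm(n, sd = 0.3), Z2 = 8 + rnorm(n))
  mk <- function(m) make_two_condition_es(m, m + rnorm(length(m), sd = 0.1))
  es_l <- mk(tumor_l); es_m <- mk(tumor_m); es_z <- mk(tumor_z)
  r_t <- cor(tumor_l["L1", ], tumor_m["M1", ])
  pairs <- data.frame(lncRNA = "L1", mRNA = "M1", r_tumor = r_t, r_normal = r_t,
                      stringsAsFactors = FALSE)
  mir_seq <- c(Z1 = "AUGGCUAAGCGAAUUCCGGAUA", Z2 = "ACCGGUUAACCGGAAUUGGCCA")
  site1 <- rna_reverse_complement(seed_of(mir_seq["Z1"]))
  base <- paste(rep("G", 30), collapse = "")
  with_site <- function(s) paste0(base, s, base)
  # Z1 has a site in both transcripts; Z2 lacks one in the lncRNA
  lnc_seq <- c(L1 = with_site(site1))
  mrna_seq <- c(M1 = paste0(with_site(site1),
                            rna_reverse_complement(seed_of(mir_seq["Z2"]))))
  asm <- assemble_triplets(pairs, es_l, es_m, es_z, lnc_seq, mrna_seq, mir_seq,
                           delta = 0.2)
  expect_equal(asm$triplets$miRNA, "Z1")              # Z2 fails the seed restriction
  # conditioning on the (noisily measured) miRNA collapses most of rho_xy:
  # with beta = 0.9 and measurement sd 0.3 the theory value is about 0.43
  expect_lt(abs(asm$triplets$rho_xy_given_z), 0.65)
  expect_lt(abs(asm$triplets$rho_xy_given_z), asm$triplets$rho_xy_tumor)
  expect_gte(asm$triplets$sensitivity, 0.2)
  # raising delta never adds a triplet
  asm_hi <- assemble_triplets(pairs, es_l, es_m, es_z, lnc_seq, mrna_seq, mir_seq,
                              delta = 1.9)
  expect_true(all(asm_hi$triplets$miRNA %in% asm$triplets$miRNA))
  expect_true("sensitivity below delta" %in% asm_hi$excluded$reason)
  # missing sequence errors name the feature
  expect_error(assemble_triplets(pairs, es_l, es_m, es_z, lnc_seq["x"],
                                 mrna_seq, mir_seq), "L1")
})

test_that("MMI network aggregates mediators per pair deterministically", {
  trip <- data.frame(lncRNA = c("L1", "L1", "L2"), miRNA = c("Z1", "Z2", "Z1"),
                     mRNA = c("M1", "M1", "M2"),
                     rho_xy_normal = 0.8, rho_xy_tumor = 0.8, rho_xz = -0.7,
                     rho_zy = -0.7, rho_xy_given_z = 0.1,
                     sensitivity = c(0.7, 0.6, 0.5), stringsAsFactors = FALSE)
  net <- build_network(trip)
  expect_equal(nrow(net$nodes), 4)
  expect_equal(nrow(net$edges), 2)                    # distinct pairs = edges
  e1 <- net$edges[net$edges$lncRNA == "L1", ]
  expect_equal(e1$mediators, "Z1,Z2")
  expect_equal(e1$n_mediators, 2L)
  expect_equal(e1$max_sensitivity, 0.7)
  expect_true(all(net$edges$lncRNA != net$edges$mRNA))
  single <- build_network(trip[1, ])
  expect_equal(nrow(single$nodes), 2)
  expect_equal(nrow(single$edges), 1)
  empty <- build_network(trip[0, ])
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("network export: SIF lines, GraphML round trip, empty documents", {
  trip <- data.frame(lncRNA = "L1", miRNA = "Z9", mRNA = "M1",
                     rho_xy_normal = 0.8, rho_xy_tumor = 0.9, rho_xz = -0.7,
                     rho_zy = -0.7, rho_xy_given_z = 0.1, sensitivity = 0.8,
                     stringsAsFactors = FALSE)
  net <- build_network(trip)
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_equal(readLines(sif), "L1 mediates:Z9 M1")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- read_network_graphml(gml)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  # byte-determinism of the export
  gml2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml2, "graphml")
  expect_identical(readLines(gml), readLines(gml2))
  # empty network still writes a valid (re-readable) document
  empty <- build_network(trip[0, ])
  export_network(empty, gml, "graphml")
  expect_equal(nrow(read_network_graphml(gml)$edges), 0)
  export_network(empty, sif, "sif")
  expect_equal(length(readLines(sif)), 0)
  expect_error(export_network(net, sif, "dot"), "arg")
})
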