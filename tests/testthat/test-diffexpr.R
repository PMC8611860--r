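test_that("quantile normalization matches the sorted row-means definition", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  rownames(m) <- paste0("F", 1:3)
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))
  # ranks within a column are preserved even when input columns disagree
  m2 <- cbind(a = c(3, 1, 2), b = c(10, 30, 20))
  rownames(m2) <- paste0("F", 1:3)
  out2 <- quantile_normalize(m2)
  expect_equal(order(out2[, "a"]), order(m2[, "a"]))
  expect_equal(order(out2[, "b"]), order(m2[, "b"]))
})

test_that("quantile normalization fixed points and errors", {
  m <- matrix(c(1, 5, 9), 3, 4, dimnames = list(paste0("F", 1:3), paste0("S", 1:4)))
  expect_equal(quantile_normalize(m), m)            # identical columns
  single <- m[, 1, drop = FALSE]
  expect_equal(quantile_normalize(single), single)  # single column
  bad <- m; bad[1, 1] <- NA
  expect_error(quantile_normalize(bad), "missing")
  expect_error(quantile_normalize(matrix(numeric(0), 0, 0)), "empty|matrix")
})

test_that("quantile normalization is idempotent and agrees with limma", {
  set.seed(1)
  m <- matrix(rnorm(200), 40, 5,
              dimnames = list(sprintf("F%02d", 1:40), paste0("S", 1:5)))
  once <- quantile_normalize(m)
  expect_equal(quantile_normalize(once), once)
  ref <- as.matrix(limma::normalizeQuantiles(m))
  expect_equal(unname(once), unname(ref), tolerance = 1e-12)
})

test_that("paired t-test matches the t-distribution oracle and handles degeneracy", {
  d <- c(0.8, 1.2, 0.9, 1.1)
  es <- make_paired_es(matrix(d, 1, 4))
  res <- paired_t_test(es)
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  p_oracle <- 2 * pt(abs(t_oracle), df = 3, lower.tail = FALSE)
  expect_equal(res$p_value, p_oracle)
  expect_equal(res$p_value, t.test(d)$p.value)
  # no signal: all differences zero
  es0 <- make_paired_es(matrix(0, 1, 4))
  expect_equal(paired_t_test(es0)$p_value, 1)
  # zero variance, nonzero mean: documented limiting p = 0 with a flag
  es1 <- make_paired_es(matrix(1, 1, 4))
  expect_warning(r1 <- paired_t_test(es1), "zero-variance")
  expect_equal(r1$p_value, 0)
  expect_true(r1$degenerate)
  expect_error(paired_t_test(make_paired_es(matrix(1, 1, 1))), "2")
})

test_that("fold change is the geometric-mean ratio", {
  es <- make_paired_es(rbind(A = c(1, 1, 1), B = c(-1, -1, -1), C = c(1.5, 1.5, 1.5)))
  fc <- fold_change(es)
  expect_equal(fc$fc, c(2, 0.5, 2^1.5))
  expect_equal(fc$log2fc, c(1, -1, 1.5))
  expect_true(all(fc$fc > 0))
})

test_that("BH adjustment follows the step-up rule and rejects bad input", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation equivariance
  set.seed(3)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("screen_de applies the fold-change and p thresholds with inclusive FC boundary", {
  # three features engineered to land on the decision boundaries:
  # fc exactly 2 with small p -> up; fc 0.5 -> down; fc 3 but noisy p -> ns
  diffs <- rbind(UP = c(0.9, 1.1, 0.95, 1.05),
                 DOWN = c(-0.9, -1.1, -0.95, -1.05),
                 NS = c(6, -2, 4, -1.6))
  diffs["UP", ] <- diffs["UP", ] - mean(diffs["UP", ]) + 1      # mean exactly 1
  diffs["DOWN", ] <- diffs["DOWN", ] - mean(diffs["DOWN", ]) - 1
  res <- screen_de(make_paired_es(diffs))
  tab <- res$table
  expect_equal(tab$fc[tab$accession == "UP"], 2)
  expect_equal(tab$regulation[tab$accession == "UP"], "up")
  expect_equal(tab$regulation[tab$accession == "DOWN"], "down")
  expect_gt(tab$fc[tab$accession == "NS"], 2)
  expect_equal(tab$regulation[tab$accession == "NS"], "ns")   # p >= alpha
  # the up/down/ns partition is exhaustive and exclusive
  expect_setequal(tab$regulation, c("up", "down", "ns"))
  expect_equal(sort(c(res$up, res$down, tab$accession[tab$regulation == "ns"])),
               sort(tab$accession))
})

test_that("intersect_sets is an exact sorted intersection", {
  expect_equal(intersect_sets(c("A", "B", "C"), c("B", "C", "D")), c("B", "C"))
  expect_equal(intersect_sets(c("A"), c("B")), character(0))
  expect_equal(intersect_sets(c("B", "A", "A"), c("A", "B")), c("A", "B"))
})

test_that("candidate filter applies the five screening principles in order", {
  de <- data.frame(
    accession = c("KEEP", "DIM", "SEXCHR", "LONG", "EXONIC"),
    fc = c(0.2, 0.2, 4, 4, 4),
    log2fc = c(-2.3, -2.4, 2, 2, 2),
    p_value = 0.01, q_value = 0.05,
    regulation = c("down", "down", "up", "up", "up"),
    mean_log2_tumor = c(5, 5, 9, 9, 9),
    mean_log2_normal = c(7.5, 6.9, 7, 7, 7),
    stringsAsFactors = FALSE)
  ann <- data.frame(
    accession = de$accession,
    chromosome = c("chr3", "chr3", "chrX", "chr1", "chr2"),
    feature_class = "lncRNA",
    length_nt = c(1500, 1500, 1500, 2500, 1000),
    lnc_category = c("intergenic", "intergenic", "intergenic", "intergenic", "exonic-sense"),
    stringsAsFactors = FALSE)
  res <- candidate_filter(de, ann)
  expect_equal(res$candidates$accession, "KEEP")
  removed <- setNames(res$removed$rule, res$removed$accession)
  expect_equal(removed[["DIM"]], "intensity")       # normal <= 7 for a down gene
  expect_equal(removed[["SEXCHR"]], "sex_chromosome")
  expect_equal(removed[["LONG"]], "length")          # >= 2 kb
  expect_equal(removed[["EXONIC"]], "exonic_sense")
  # candidates are ranked by |log2fc| descending
  expect_equal(res$candidates$accession[order(-abs(res$candidates$log2fc))],
               res$candidates$accession)
  expect_error(candidate_filter(de, ann[-1, ]), "KEEP")
})

test_that("DE screen recovers planted features and keeps null calls rare", {
  g <- generate_expression(de_recovery_spec(seed = 4))
  de <- screen_de(quantile_normalize(g$expr))
  called <- c(de$up, de$down)
  planted <- g$truth$true_de$feature
  expect_gte(mean(planted %in% called), 0.9)
  nulls <- setdiff(de$table$accession, planted)
  # false calls additionally need |log2fc| >= 1, so their rate sits well
  # below the nominal 0.05 of the p threshold alone
  false_rate <- mean(nulls %in% called)
  expect_lte(false_rate, 0.05 + 3 * sqrt(0.05 * 0.95 / length(nulls)))
})
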