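## Quantile normalization, paired DE screening at the fold-change /
## p-value thresholds, BH adjustment, set intersection and the five
## candidate-lncRNA filter rules.

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column to share one distribution: each column is
#' replaced, rank for rank, by the vector of row means of the
#' column-sorted matrix. Ranks within a column are preserved; ties are
#' broken by row order so that all columns end up with exactly the same
#' multiset of values.
#'
#' @param es an [expr_set] (or bare numeric matrix) with no missing values.
#' @return an object of the same type with normalized values.
#' @export
quantile_normalize <- function(es) {
  m <- if (inherits(es, "expr_set")) es$values else es
  stop_if(!is.matrix(m) || !is.numeric(m), "need a numeric matrix or expr_set")
  stop_if(nrow(m) < 1L || ncol(m) < 1L, "empty matrix")
  stop_if(anyNA(m), "missing values are not allowed")
  ord <- apply(m, 2, order)
  sorted <- vapply(seq_len(ncol(m)), function(j) m[ord[, j], j], numeric(nrow(m)))
  target <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) out[ord[, j], j] <- target
  if (inherits(es, "expr_set")) { es$values <- out; es } else out
}

#' Row-wise paired two-tailed t-test
#'
#' For every feature, tests whether the per-pair tumor - normal log2
#' differences have mean zero, against the t distribution with
#' `n_pairs - 1` degrees of freedom. Two degenerate cases are resolved
#' explicitly: all differences zero gives p = 1 (no signal), and zero
#' variance with nonzero mean gives the limiting p = 0 with a `degenerate`
#' flag.
#'
#' @param es an [expr_set] with at least two complete tumor/normal pairs.
#' @return data.frame with `accession`, `mean_diff`, `t`, `p_value`,
#'   `degenerate`.
#' @export
paired_t_test <- function(es) {
  d <- pair_differences(es)
  stop_if(ncol(d) < 2L, "paired t-test needs at least 2 complete pairs")
  n <- ncol(d)
  mu <- rowMeans(d)
  s <- sqrt(rowSums((d - mu)^2) / (n - 1))
  tstat <- mu / (s / sqrt(n))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  degenerate <- s == 0 & mu != 0
  p[s == 0 & mu == 0] <- 1          # no signal at all
  p[degenerate] <- 0                # limiting value; flagged
  if (any(degenerate))
    warning(sum(degenerate), " feature(s) with zero-variance nonzero differences; p set to 0")
  data.frame(accession = rownames(d), mean_diff = mu, t = tstat,
             p_value = p, degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-feature fold change of a paired design
#'
#' The geometric-mean ratio `2^(mean log2 tumor - mean log2 normal)`,
#' the natural fold change for log2 intensity data.
#'
#' @param es an [expr_set] with pairing metadata.
#' @return data.frame with `accession`, `mean_log2_tumor`,
#'   `mean_log2_normal`, `log2fc`, `fc`.
#' @export
fold_change <- function(es) {
  paired_pairs(es)
  mt <- rowMeans(condition_matrix(es, "tumor"))
  mn <- rowMeans(condition_matrix(es, "normal"))
  l2 <- mt - mn
  data.frame(accession = rownames(es$values), mean_log2_tumor = mt,
             mean_log2_normal = mn, log2fc = l2, fc = 2^l2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order (monotone in rank, capped at 1).
#' @export
bh_adjust <- function(p) {
  stop_if(!is.numeric(p), "p must be numeric")
  stop_if(any(!is.finite(p)) || any(p < 0 | p > 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen differentially expressed features of a paired cohort
#'
#' Calls a feature up if `fc >= fc_up` and `p < alpha`, down if
#' `fc <= fc_down` and `p < alpha`, otherwise non-significant. The two
#' published threshold presets — `"microarray"` (FC >= 2 or <= 0.5,
#' P < 0.05) and `"validation"` (|log2 FC| > 1, P < 0.05) — are the same
#' rule up to boundary inclusivity and are kept as named presets. BH
#' q-values are reported but not used for the call.
#'
#' @param es a (normalized) [expr_set].
#' @param mode `"microarray"` (boundary fold changes inclusive) or
#'   `"validation"` (strict `|log2fc| > 1`).
#' @param alpha p-value threshold (strict `<`).
#' @return list with `table` (all features: `accession`, `fc`, `log2fc`,
#'   `p_value`, `q_value`, `regulation`, mean intensities), `up` and `down`
#'   (sorted id vectors).
#' @export
screen_de <- function(es, mode = c("microarray", "validation"), alpha = 0.05) {
  mode <- match.arg(mode)
  fcres <- fold_change(es)
  tres <- paired_t_test(es)
  stopifnot(identical(fcres$accession, tres$accession))
  q <- bh_adjust(tres$p_value)
  sig <- tres$p_value < alpha
  if (mode == "microarray") {
    up <- sig & fcres$fc >= 2
    down <- sig & fcres$fc <= 0.5
  } else {
    up <- sig & fcres$log2fc > 1
    down <- sig & fcres$log2fc < -1
  }
  tab <- data.frame(accession = fcres$accession, fc = fcres$fc,
                    log2fc = fcres$log2fc, p_value = tres$p_value, q_value = q,
                    regulation = ifelse(up, "up", ifelse(down, "down", "ns")),
                    mean_log2_tumor = fcres$mean_log2_tumor,
                    mean_log2_normal = fcres$mean_log2_normal,
                    degenerate = tres$degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, up = sort(tab$accession[up]), down = sort(tab$accession[down]))
}

#' Exact intersection of two id sets
#'
#' @param a,b character vectors of feature ids.
#' @return the sorted intersection, duplicates removed.
#' @export
intersect_sets <- function(a, b) {
  sort(intersect(unique(a), unique(b)))
}

#' Candidate lncRNA filter
#'
#' Applies, in order, the five screening principles used to pick candidate
#' lncRNAs from a DE table: (1) sort by `|log2fc|` descending (ties by
#' ascending p, then accession); (2) intensity rule — downregulated features
#' must have mean log2 intensity > `intensity_min` in normal tissue,
#' upregulated in tumor; (3) drop features on chrX/chrY; (4) drop features
#' of length >= `max_length_nt`; (5) drop exonic-sense lncRNAs.
#'
#' @param de the `table` element of a [screen_de()] result (only `up`/`down`
#'   calls are considered).
#' @param ann a [feature_annotation] data.frame covering every DE feature.
#' @param intensity_min log2 intensity floor for the expressed condition.
#' @param max_length_nt features at or above this length are removed.
#' @param drop_chr chromosomes to exclude.
#' @param drop_category lncRNA positional category to exclude.
#' @return list with `candidates` (surviving rows, annotated and ranked)
#'   and `removed` (data.frame `accession`, `rule` naming the rule that
#'   removed each casualty).
#' @export
candidate_filter <- function(de, ann, intensity_min = 7, max_length_nt = 2000,
                             drop_chr = c("chrX", "chrY"),
                             drop_category = "exonic-sense") {
  ann <- feature_annotation(ann)
  de <- de[de$regulation %in% c("up", "down"), , drop = FALSE]
  missing <- setdiff(de$accession, ann$accession)
  stop_if(length(missing) > 0, "no annotation for feature(s): %s",
          paste(utils::head(missing, 5), collapse = ", "))
  de <- de[order(-abs(de$log2fc), de$p_value, de$accession), , drop = FALSE]
  a <- ann[match(de$accession, ann$accession), , drop = FALSE]
  de$chromosome <- a$chromosome
  de$length_nt <- a$length_nt
  de$lnc_category <- a$lnc_category

  intensity_ok <- ifelse(de$regulation == "down",
                         de$mean_log2_normal > intensity_min,
                         de$mean_log2_tumor > intensity_min)
  rule <- rep(NA_character_, nrow(de))
  rule[!intensity_ok] <- "intensity"
  rule[is.na(rule) & de$chromosome %in% drop_chr] <- "sex_chromosome"
  rule[is.na(rule) & de$length_nt >= max_length_nt] <- "length"
  rule[is.na(rule) & !is.na(de$lnc_category) & de$lnc_category %in% drop_category] <- "exonic_sense"

  list(candidates = de[is.na(rule), , drop = FALSE],
       removed = data.frame(accession = de$accession[!is.na(rule)],
                            rule = rule[!is.na(rule)],
                            row.names = NULL, stringsAsFactors = FALSE))
}
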