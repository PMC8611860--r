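## ceRNA core: condition-wise lncRNA-mRNA correlation, 99th-percentile pair
## selection, partial correlation given each shared miRNA, seed-match
## restriction, and MMI network assembly/export.

#' Pearson correlation of every lncRNA-mRNA pair in one condition
#'
#' @param lnc_es,mrna_es [expr_set]s sharing the sample set of the
#'   requested condition (at least 3 samples).
#' @param condition `"tumor"` or `"normal"`.
#' @return data.frame with `lncRNA`, `mRNA`, `r`, `defined` (`FALSE` for
#'   pairs involving a constant feature, where the correlation is
#'   undefined).
#' @export
pairwise_correlation <- function(lnc_es, mrna_es, condition = c("tumor", "normal")) {
  condition <- match.arg(condition)
  a <- condition_matrix(lnc_es, condition)
  b <- condition_matrix(mrna_es, condition)
  stop_if(!identical(colnames(a), colnames(b)),
          "lncRNA and mRNA matrices must share the %s samples", condition)
  stop_if(ncol(a) < 3L, "need at least 3 samples per condition")
  r <- suppressWarnings(stats::cor(t(a), t(b)))
  out <- data.frame(lncRNA = rep(rownames(a), times = ncol(r)),
                    mRNA = rep(colnames(r), each = nrow(r)),
                    r = as.vector(r), stringsAsFactors = FALSE)
  out$defined <- !is.na(out$r)
  out
}

#' Nearest-rank percentile threshold with strict exceedance
#'
#' The threshold is the `ceiling(q/100 * n)`-th order statistic of the
#' defined values; an element is selected iff it strictly exceeds the
#' threshold (so a degenerate all-equal distribution selects nothing).
#'
#' @param values numeric vector (NAs treated as undefined and never
#'   selected; all-undefined input is an error).
#' @param q percentile in (0, 100).
#' @return list with `threshold` and `selected` (logical vector along
#'   `values`).
#' @export
percentile_threshold <- function(values, q = 99) {
  stop_if(!is.numeric(q) || q <= 0 || q >= 100, "q must be in (0, 100)")
  ok <- !is.na(values)
  stop_if(!any(ok), "no defined values")
  s <- sort(values[ok])
  thr <- s[ceiling(q / 100 * length(s))]
  sel <- !is.na(values) & values > thr
  list(threshold = thr, selected = sel)
}

#' Select top-correlated lncRNA-mRNA pairs across conditions
#'
#' Applies the nearest-rank percentile rule to each condition's full
#' correlation distribution and keeps a pair iff it exceeds the threshold
#' in both conditions (`rule = "both"`, the default reading) or in at
#' least one (`rule = "either"`, exploratory).
#'
#' @param cor_tumor,cor_normal [pairwise_correlation()] tables over the
#'   same pair universe.
#' @param q percentile (default 99).
#' @param rule `"both"` or `"either"`.
#' @return list with `threshold_tumor`, `threshold_normal` and `pairs`
#'   (selected pairs with `r_tumor`, `r_normal`).
#' @export
select_cerna_pairs <- function(cor_tumor, cor_normal, q = 99,
                               rule = c("both", "either")) {
  rule <- match.arg(rule)
  stop_if(!identical(cor_tumor[c("lncRNA", "mRNA")], cor_normal[c("lncRNA", "mRNA")]),
          "correlation tables must cover the same pairs in the same order")
  pt <- percentile_threshold(cor_tumor$r, q)
  pn <- percentile_threshold(cor_normal$r, q)
  sel <- if (rule == "both") pt$selected & pn$selected else pt$selected | pn$selected
  pairs <- data.frame(lncRNA = cor_tumor$lncRNA[sel], mRNA = cor_tumor$mRNA[sel],
                      r_tumor = cor_tumor$r[sel], r_normal = cor_normal$r[sel],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$lncRNA, pairs$mRNA), , drop = FALSE]
  rownames(pairs) <- NULL
  list(threshold_tumor = pt$threshold, threshold_normal = pn$threshold,
       pairs = pairs)
}

#' First-order partial correlation
#'
#' \deqn{\rho_{XY|Z} = \frac{\rho_{XY} - \rho_{XZ}\rho_{ZY}}
#'   {\sqrt{1-\rho_{XZ}^2}\,\sqrt{1-\rho_{ZY}^2}},}
#' the correlation of X and Y after removing the linear effect of Z
#' (identical to the correlation of the residuals of the regressions of X
#' on Z and Y on Z). Values outside `[-1, 1]` by more than 1e-12 are
#' flagged via the `"out_of_range"` attribute before clamping.
#'
#' @param rho_xy,rho_xz,rho_zy pairwise Pearson correlations (vectorized);
#'   `|rho_xz| = 1` or `|rho_zy| = 1` is a degeneracy error (zero
#'   denominator).
#' @return partial correlation(s) in `[-1, 1]`.
#' @export
#' @examples
#' partial_correlation(0.48, 0.8, 0.6) # fully mediated: 0
partial_correlation <- function(rho_xy, rho_xz, rho_zy) {
  for (r in list(rho_xy, rho_xz, rho_zy))
    stop_if(any(!is.finite(r)) || any(abs(r) > 1), "correlations must lie in [-1, 1]")
  stop_if(any(abs(rho_xz) == 1) || any(abs(rho_zy) == 1),
          "degenerate partial correlation: |rho_xz| or |rho_zy| equals 1")
  v <- (rho_xy - rho_xz * rho_zy) / (sqrt(1 - rho_xz^2) * sqrt(1 - rho_zy^2))
  oor <- abs(v) > 1 + 1e-12
  v <- pmin(1, pmax(-1, v))
  if (any(oor)) attr(v, "out_of_range") <- which(oor)
  v
}

## Pearson correlation of two numeric vectors; NA when either is constant.
safe_cor <- function(x, y) suppressWarnings(stats::cor(x, y))

#' Assemble ceRNA triplets from selected pairs
#'
#' For every selected (lncRNA X, mRNA Y) pair and every miRNA Z whose 6-mer
#' seed has a perfect match in both transcripts, computes `rho_xz`,
#' `rho_zy` and the partial correlation `rho_xy_given_z` on the sensitivity
#' condition's samples, and retains the triplet iff the sensitivity
#' correlation `rho_xy - rho_xy_given_z` is at least `delta`. Degenerate
#' triplets (a constant profile, or `|rho_xz|` / `|rho_zy|` at 1 so the
#' partial correlation is undefined) are excluded with a logged reason
#' rather than silently dropped.
#'
#' @param pairs selected pairs ([select_cerna_pairs()]`$pairs`).
#' @param lnc_es,mrna_es,mirna_es [expr_set]s with both conditions.
#' @param lnc_seq,mrna_seq,mirna_seq named sequence vectors (RNA/DNA
#'   alphabet); every pair member and candidate miRNA must be present.
#' @param delta sensitivity retention threshold in `[0, 2]` (default 0.2).
#' @param sensitivity_condition condition whose `rho_xy` enters the
#'   sensitivity (default `"tumor"`, the cancer network).
#' @return list with `triplets` (data.frame: `lncRNA`, `miRNA`, `mRNA`,
#'   `rho_xy_normal`, `rho_xy_tumor`, `rho_xz`, `rho_zy`,
#'   `rho_xy_given_z`, `sensitivity`) and `excluded` (data.frame with a
#'   `reason` per candidate triplet that was dropped for degeneracy).
#' @export
assemble_triplets <- function(pairs, lnc_es, mrna_es, mirna_es,
                              lnc_seq, mrna_seq, mirna_seq,
                              delta = 0.2,
                              sensitivity_condition = c("tumor", "normal")) {
  sensitivity_condition <- match.arg(sensitivity_condition)
  stop_if(!is.numeric(delta) || delta < 0 || delta > 2, "delta must be in [0, 2]")
  miss <- setdiff(pairs$lncRNA, names(lnc_seq))
  stop_if(length(miss) > 0, "missing lncRNA sequence: %s", miss[1])
  miss <- setdiff(pairs$mRNA, names(mrna_seq))
  stop_if(length(miss) > 0, "missing mRNA sequence: %s", miss[1])
  miss <- setdiff(pairs$lncRNA, rownames(lnc_es$values))
  stop_if(length(miss) > 0, "missing lncRNA expression profile: %s", miss[1])
  miss <- setdiff(pairs$mRNA, rownames(mrna_es$values))
  stop_if(length(miss) > 0, "missing mRNA expression profile: %s", miss[1])
  mirnas <- intersect(names(mirna_seq), rownames(mirna_es$values))

  lt <- condition_matrix(lnc_es, "tumor"); ln <- condition_matrix(lnc_es, "normal")
  mt <- condition_matrix(mrna_es, "tumor"); mn <- condition_matrix(mrna_es, "normal")
  zt <- condition_matrix(mirna_es, "tumor"); zn <- condition_matrix(mirna_es, "normal")
  pick <- function(tum, nor) if (sensitivity_condition == "tumor") tum else nor

  ## seed-match cache over the features actually involved
  match_cache <- new.env(parent = emptyenv())
  matched <- function(mir, target_id, seqs) {
    key <- paste0(mir, "\r", target_id)
    hit <- match_cache[[key]]
    if (is.null(hit)) {
      hit <- has_seed_match(mirna_seq[[mir]], seqs[[target_id]])
      match_cache[[key]] <- hit
    }
    hit
  }

  kept <- list(); dropped <- list()
  for (i in seq_len(nrow(pairs))) {
    X <- pairs$lncRNA[i]; Y <- pairs$mRNA[i]
    rho_xy <- if (sensitivity_condition == "tumor") pairs$r_tumor[i] else pairs$r_normal[i]
    for (Z in mirnas) {
      if (!matched(Z, X, lnc_seq) || !matched(Z, Y, mrna_seq)) next
      rho_xz <- safe_cor(pick(lt, ln)[X, ], pick(zt, zn)[Z, ])
      rho_zy <- safe_cor(pick(zt, zn)[Z, ], pick(mt, mn)[Y, ])
      row <- data.frame(lncRNA = X, miRNA = Z, mRNA = Y,
                        rho_xy_normal = pairs$r_normal[i],
                        rho_xy_tumor = pairs$r_tumor[i],
                        rho_xz = rho_xz, rho_zy = rho_zy,
                        rho_xy_given_z = NA_real_, sensitivity = NA_real_,
                        stringsAsFactors = FALSE)
      if (is.na(rho_xz) || is.na(rho_zy) || is.na(rho_xy)) {
        row$reason <- "undefined correlation (constant profile)"
        dropped[[length(dropped) + 1L]] <- row
        next
      }
      if (abs(rho_xz) >= 1 || abs(rho_zy) >= 1) {
        row$reason <- "degenerate partial correlation (|rho| = 1)"
        dropped[[length(dropped) + 1L]] <- row
        next
      }
      pc <- as.numeric(partial_correlation(rho_xy, rho_xz, rho_zy))
      row$rho_xy_given_z <- pc
      row$sensitivity <- rho_xy - pc
      if (row$sensitivity >= delta) {
        kept[[length(kept) + 1L]] <- row
      } else {
        row$reason <- "sensitivity below delta"
        dropped[[length(dropped) + 1L]] <- row
      }
    }
  }
  empty <- data.frame(lncRNA = character(), miRNA = character(), mRNA = character(),
                      rho_xy_normal = numeric(), rho_xy_tumor = numeric(),
                      rho_xz = numeric(), rho_zy = numeric(),
                      rho_xy_given_z = numeric(), sensitivity = numeric(),
                      stringsAsFactors = FALSE)
  triplets <- if (length(kept)) do.call(rbind, kept) else empty
  excluded <- if (length(dropped)) do.call(rbind, dropped) else cbind(empty, reason = character())
  rownames(triplets) <- NULL; rownames(excluded) <- NULL
  list(triplets = triplets, excluded = excluded)
}

#' Build the miRNA-mediated interaction (MMI) network
#'
#' One node per distinct lncRNA or mRNA among the retained triplets; one
#' edge per distinct (lncRNA, mRNA) pair, carrying the union of its
#' mediating miRNAs and the strongest sensitivity observed. Node and edge
#' order are deterministic (lexicographic).
#'
#' @param triplets the `triplets` table of [assemble_triplets()].
#' @return an object of class `mmi_network`: list with `nodes` (`id`,
#'   `type`) and `edges` (`lncRNA`, `mRNA`, `mediators`, `n_mediators`,
#'   `max_sensitivity`).
#' @export
build_network <- function(triplets) {
  if (nrow(triplets) == 0) {
    return(structure(list(
      nodes = data.frame(id = character(), type = character(), stringsAsFactors = FALSE),
      edges = data.frame(lncRNA = character(), mRNA = character(),
                         mediators = character(), n_mediators = integer(),
                         max_sensitivity = numeric(), stringsAsFactors = FALSE)),
      class = "mmi_network"))
  }
  key <- paste(triplets$lncRNA, triplets$mRNA, sep = "\r")
  agg <- lapply(split(seq_len(nrow(triplets)), key), function(ix) {
    data.frame(lncRNA = triplets$lncRNA[ix[1]], mRNA = triplets$mRNA[ix[1]],
               mediators = paste(sort(unique(triplets$miRNA[ix])), collapse = ","),
               n_mediators = length(unique(triplets$miRNA[ix])),
               max_sensitivity = max(triplets$sensitivity[ix]),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, agg)
  edges <- edges[order(edges$lncRNA, edges$mRNA), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- rbind(
    data.frame(id = sort(unique(edges$lncRNA)), type = "lncRNA", stringsAsFactors = FALSE),
    data.frame(id = sort(unique(edges$mRNA)), type = "mRNA", stringsAsFactors = FALSE))
  structure(list(nodes = nodes, edges = edges), class = "mmi_network")
}

#' @export
print.mmi_network <- function(x, ...) {
  cat(sprintf("mmi_network: %d nodes (%d lncRNA, %d mRNA), %d edges\n",
              nrow(x$nodes), sum(x$nodes$type == "lncRNA"),
              sum(x$nodes$type == "mRNA"), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    d = net$edges[, c("lncRNA", "mRNA", "mediators", "n_mediators", "max_sensitivity")],
    directed = FALSE, vertices = net$nodes)
}

#' Export an MMI network
#'
#' `"sif"` writes one line per edge, `lncRNA <mediates:miR[,miR...]> mRNA`;
#' `"graphml"` writes GraphML (via igraph) with a `type` node attribute and
#' `mediators` edge attribute. Output bytes are deterministic for a given
#' network.
#'
#' @param net an `mmi_network`.
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  stopifnot(inherits(net, "mmi_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- if (nrow(net$edges) == 0) character(0) else
      paste(net$edges$lncRNA, paste0("mediates:", net$edges$mediators), net$edges$mRNA)
    writeLines(lines, path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read an MMI network back from GraphML
#'
#' @param path GraphML file written by [export_network()].
#' @return an `mmi_network`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name,
                      type = if (igraph::gorder(g)) igraph::V(g)$type else character(),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$type != "lncRNA", nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  if (igraph::gsize(g) == 0) {
    edges <- data.frame(lncRNA = character(), mRNA = character(),
                        mediators = character(), n_mediators = integer(),
                        max_sensitivity = numeric(), stringsAsFactors = FALSE)
  } else {
    ends <- igraph::as_edgelist(g)
    type1 <- nodes$type[match(ends[, 1], nodes$id)]
    edges <- data.frame(
      lncRNA = ifelse(type1 == "lncRNA", ends[, 1], ends[, 2]),
      mRNA = ifelse(type1 == "lncRNA", ends[, 2], ends[, 1]),
      mediators = igraph::E(g)$mediators,
      n_mediators = as.integer(igraph::E(g)$n_mediators),
      max_sensitivity = as.numeric(igraph::E(g)$max_sensitivity),
      stringsAsFactors = FALSE)
    edges <- edges[order(edges$lncRNA, edges$mRNA), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "mmi_network")
}
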