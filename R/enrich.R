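## Hypergeometric over-representation analysis against user-supplied gene
## sets (GMT), with BH adjustment per category and fold-enrichment ranking.

#' Read a GMT gene-set file
#'
#' One set per line: term id, description, then one member id per field.
#' Duplicate members within a line are dropped.
#'
#' @param path GMT file path.
#' @param category category label attached to every set in the file
#'   (`BP`, `CC`, `MF`, `KEGG` or `custom`); BH adjustment in [enrich()] is
#'   applied within category.
#' @return data.frame with `term_id`, `term_name`, `category`, `members`
#'   (comma-joined id string).
#' @export
read_gmt <- function(path, category = "custom") {
  stop_if(!file.exists(path), "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  stop_if(length(bad) > 0, "malformed GMT line %d: fewer than 3 fields", bad[1])
  data.frame(
    term_id = vapply(fields, `[[`, character(1), 1L),
    term_name = vapply(fields, `[[`, character(1), 2L),
    category = category,
    members = vapply(fields, function(f) paste(unique(f[-(1:2)]), collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE)
}

#' Write gene sets to GMT
#'
#' @param sets gene-set data.frame as returned by [read_gmt()].
#' @param path output path.
#' @export
#' @rdname read_gmt
write_gmt <- function(sets, path) {
  lines <- paste(sets$term_id, sets$term_name,
                 gsub(",", "\t", sets$members, fixed = TRUE), sep = "\t")
  writeLines(lines, path)
  invisible(NULL)
}

gmt_member_list <- function(sets) {
  stats::setNames(strsplit(sets$members, ",", fixed = TRUE), sets$term_id)
}

#' Upper-tail hypergeometric probability
#'
#' The over-representation p-value
#' \deqn{P = 1 - \sum_{i=0}^{m-1} \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}},}
#' i.e. the probability of drawing at least `m` annotated genes when `n`
#' genes are drawn without replacement from a background of `N` genes of
#' which `M` are annotated to the term. Computed by direct summation of the
#' upper tail in log space, so it is stable for backgrounds up to about
#' 1e5 genes.
#'
#' @param N background size.
#' @param M background genes annotated to the term, `M <= N`.
#' @param n query size, `n <= N`.
#' @param m observed overlap; may be a vector, each element in
#'   `[0, min(M, n)]`.
#' @return p-value(s) in `(0, 1]`.
#' @export
#' @examples
#' hypergeom_p(20, 5, 5, 5) # 1 / choose(20, 5)
hypergeom_p <- function(N, M, n, m) {
  stop_if(!is_count(N) || !is_count(M) || !is_count(n), "N, M, n must be non-negative integers")
  stop_if(M > N || n > N, "need M <= N and n <= N")
  stop_if(any(!vapply(m, is_count, logical(1))), "m must be non-negative integer(s)")
  stop_if(any(m > pmin(M, n)), "m cannot exceed min(M, n)")
  hi <- min(M, n)
  lo <- max(0L, n - (N - M))
  i <- lo:hi
  logpmf <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  pmf <- exp(logpmf)
  ## reversed cumulative sum: tail[k] = P(X >= i[k])
  tail <- rev(cumsum(rev(pmf)))
  vapply(m, function(mm) {
    if (mm <= lo) 1 else min(1, tail[mm - lo + 1L])
  }, numeric(1))
}

#' Over-representation analysis of a query set
#'
#' For every gene set: restricts members and query to the background,
#' computes the overlap `m`, the hypergeometric p ([hypergeom_p()]), the BH
#' q within each category, and the fold enrichment
#' `(m/n) / (M/N)`. Terms with fewer than `min_hits` query hits are
#' excluded before adjustment. Results are sorted by enrichment factor
#' descending, ties by ascending p then term id.
#'
#' @param query character vector of query ids; ids outside the background
#'   are dropped with a message.
#' @param sets gene-set data.frame ([read_gmt()]).
#' @param background character vector of background ids (non-empty).
#' @param min_hits minimum query hits per term (default 2).
#' @return data.frame with `term_id`, `term_name`, `category`, `N`, `M`,
#'   `n`, `m`, `enrichment_factor`, `p_value`, `q_value`, `member_hits`.
#' @export
enrich <- function(query, sets, background, min_hits = 2) {
  background <- unique(background)
  stop_if(length(background) == 0, "empty background")
  query0 <- unique(query)
  query <- intersect(query0, background)
  dropped <- length(query0) - length(query)
  if (dropped > 0)
    message(dropped, " query id(s) outside the background were dropped")
  if (length(query) == 0) {
    warning("empty query after background restriction")
    return(data.frame(term_id = character(), term_name = character(),
                      category = character(), N = integer(), M = integer(),
                      n = integer(), m = integer(), enrichment_factor = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      member_hits = character(), stringsAsFactors = FALSE))
  }
  N <- length(background)
  n <- length(query)
  members <- lapply(gmt_member_list(sets), intersect, background)
  M <- lengths(members)
  hits <- lapply(members, intersect, query)
  m <- lengths(hits)
  res <- data.frame(term_id = sets$term_id, term_name = sets$term_name,
                    category = sets$category, N = N, M = as.integer(M),
                    n = n, m = as.integer(m),
                    enrichment_factor = ifelse(M > 0, (m / n) / (M / N), 0),
                    p_value = NA_real_, q_value = NA_real_,
                    member_hits = vapply(hits, function(h) paste(sort(h), collapse = ","),
                                         character(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[res$m >= min_hits, , drop = FALSE]
  if (nrow(res) > 0) {
    res$p_value <- vapply(seq_len(nrow(res)), function(i)
      hypergeom_p(N, res$M[i], n, res$m[i]), numeric(1))
    for (cat in unique(res$category)) {
      sel <- res$category == cat
      res$q_value[sel] <- bh_adjust(res$p_value[sel])
    }
  }
  res <- res[order(-res$enrichment_factor, res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Top enriched terms by enrichment factor
#'
#' @param res an [enrich()] result.
#' @param k number of terms to keep (default 30, the usual report size).
#' @return the first `k` rows of `res` (already ranked by enrichment
#'   factor).
#' @export
top_terms <- function(res, k = 30) {
  utils::head(res, k)
}
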