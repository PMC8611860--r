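#' Expression set container
#'
#' A lightweight container for a log2 intensity matrix (features x samples)
#' together with per-sample metadata. Paired designs carry a `condition`
#' column (`"tumor"` or `"normal"`) and a `pair_id` column mapping each pair
#' id to exactly one tumor and one normal sample.
#'
#' @param values numeric matrix of log2 intensities, rownames = feature ids,
#'   colnames = sample ids. No missing values are allowed.
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (`"tumor"`/`"normal"`) and `pair_id`; one row per column of `values`.
#' @return an object of class `expr_set`: a list with elements `values` and
#'   `samples`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' s <- data.frame(sample_id = paste0("S", 1:4),
#'   condition = rep(c("tumor", "normal"), 2), pair_id = rep(c("P1", "P2"), each = 2))
#' es <- expr_set(m, s)
expr_set <- function(values, samples) {
  stop_if(!is.matrix(values) || !is.numeric(values), "values must be a numeric matrix")
  stop_if(nrow(values) < 1L || ncol(values) < 1L, "expression matrix is empty")
  stop_if(anyNA(values), "expression matrix contains missing values")
  stop_if(is.null(rownames(values)) || anyDuplicated(rownames(values)) > 0,
          "feature ids must be present and unique")
  stop_if(is.null(colnames(values)) || anyDuplicated(colnames(values)) > 0,
          "sample ids must be present and unique")
  stop_if(!is.data.frame(samples) || !all(c("sample_id", "condition", "pair_id") %in% names(samples)),
          "samples must be a data.frame with sample_id, condition, pair_id")
  stop_if(!setequal(samples$sample_id, colnames(values)) ||
            nrow(samples) != ncol(values),
          "sample metadata does not match matrix columns")
  stop_if(!all(samples$condition %in% c("tumor", "normal")),
          "condition must be 'tumor' or 'normal'")
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d features x %d samples (%d tumor / %d normal, %d pairs)\n",
              nrow(x$values), ncol(x$values),
              sum(x$samples$condition == "tumor"),
              sum(x$samples$condition == "normal"),
              length(unique(x$samples$pair_id))))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

## Checks the one-tumor/one-normal-per-pair invariant; returns ordered pair ids.
paired_pairs <- function(es) {
  tab <- table(es$samples$pair_id, es$samples$condition)
  ok <- all(tab[, "tumor"] == 1L) && all(tab[, "normal"] == 1L)
  stop_if(!ok, "each pair_id must map to exactly one tumor and one normal sample")
  sort(rownames(tab))
}

## Matrix of per-pair log2 differences (tumor - normal), features x pairs.
pair_differences <- function(es) {
  pairs <- paired_pairs(es)
  ts <- es$samples$sample_id[match(paste0(pairs, ".tumor"),
                                   paste0(es$samples$pair_id, ".", es$samples$condition))]
  ns <- es$samples$sample_id[match(paste0(pairs, ".normal"),
                                   paste0(es$samples$pair_id, ".", es$samples$condition))]
  d <- es$values[, ts, drop = FALSE] - es$values[, ns, drop = FALSE]
  colnames(d) <- pairs
  d
}

#' Subset an expression set to one condition
#'
#' @param es an [expr_set].
#' @param condition `"tumor"` or `"normal"`.
#' @return the feature x sample submatrix for that condition, columns ordered
#'   by pair id so tumor and normal submatrices align sample-wise.
#' @export
condition_matrix <- function(es, condition = c("tumor", "normal")) {
  condition <- match.arg(condition)
  s <- es$samples[es$samples$condition == condition, , drop = FALSE]
  s <- s[order(s$pair_id), , drop = FALSE]
  es$values[, s$sample_id, drop = FALSE]
}

#' Read / write expression sets as TSV
#'
#' The matrix TSV has the feature id in the first column (`feature_id`) and
#' one column per sample; the metadata TSV has columns `sample_id`,
#' `condition`, `pair_id`.
#'
#' @param path matrix TSV path.
#' @param meta_path sample metadata TSV path.
#' @return `read_expr_set` returns an [expr_set]; `write_expr_set` returns
#'   `invisible(NULL)`.
#' @export
read_expr_set <- function(path, meta_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if(names(tab)[1] != "feature_id", "matrix TSV must start with a feature_id column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$feature_id
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  expr_set(m, meta)
}

#' @param es an [expr_set] to write.
#' @rdname read_expr_set
#' @export
write_expr_set <- function(es, path, meta_path) {
  tab <- data.frame(feature_id = rownames(es$values), es$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(es$samples, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Feature annotation table
#'
#' Validates an annotation data.frame with columns `accession`, `symbol`,
#' `chromosome`, `feature_class` (`lncRNA`/`mRNA`/`miRNA`), `length_nt` and
#' optional `lnc_category` (e.g. `intergenic`, `antisense`, `exonic-sense`).
#'
#' @param ann data.frame of annotations.
#' @return the validated data.frame.
#' @export
feature_annotation <- function(ann) {
  req <- c("accession", "chromosome", "feature_class", "length_nt")
  stop_if(!is.data.frame(ann) || !all(req %in% names(ann)),
          "annotation needs columns: %s", paste(req, collapse = ", "))
  stop_if(anyDuplicated(ann$accession) > 0, "duplicate accessions in annotation")
  stop_if(!all(ann$feature_class %in% c("lncRNA", "mRNA", "miRNA")),
          "feature_class must be lncRNA, mRNA or miRNA")
  stop_if(!all(ann$length_nt > 0), "length_nt must be positive")
  stop_if(any(!nzchar(ann$chromosome)), "chromosome strings must be non-empty")
  if (is.null(ann$symbol)) ann$symbol <- NA_character_
  if (is.null(ann$lnc_category)) ann$lnc_category <- NA_character_
  ann
}
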