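# Fixtures built in code: small paired expression sets with known
# tumor - normal differences.

# Paired expr_set whose per-pair tumor - normal log2 differences equal the
# rows of `diffs` (features x pairs); normal values come from `base`.
make_paired_es <- function(diffs, base = 8) {
  if (is.null(rownames(diffs)))
    rownames(diffs) <- sprintf("F%03d", seq_len(nrow(diffs)))
  n <- ncol(diffs)
  pid <- sprintf("P%02d", seq_len(n))
  normal <- matrix(base, nrow(diffs), n, dimnames = list(rownames(diffs), paste0(pid, "_N")))
  tumor <- normal + diffs
  colnames(tumor) <- paste0(pid, "_T")
  meta <- data.frame(sample_id = c(colnames(tumor), colnames(normal)),
                     condition = rep(c("tumor", "normal"), each = n),
                     pair_id = rep(pid, 2), stringsAsFactors = FALSE)
  expr_set(cbind(tumor, normal), meta)
}

# expr_set from explicit tumor and normal matrices with aligned columns.
make_two_condition_es <- function(tumor, normal) {
  n <- ncol(tumor)
  pid <- sprintf("P%02d", seq_len(n))
  colnames(tumor) <- paste0(pid, "_T")
  colnames(normal) <- paste0(pid, "_N")
  meta <- data.frame(sample_id = c(colnames(tumor), colnames(normal)),
                     condition = rep(c("tumor", "normal"), each = n),
                     pair_id = rep(pid, 2), stringsAsFactors = FALSE)
  expr_set(cbind(tumor, normal), meta)
}

random_rna_string <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# compact but complete pipeline configuration for fast end-to-end runs
small_config <- function(outdir, seed = 5) {
  cfg <- default_pipeline_config(seed = seed, outdir = outdir)
  cfg$simulate$n_lnc <- 30L; cfg$simulate$n_mrna <- 30L; cfg$simulate$n_mirna <- 6L
  cfg$simulate$n_pairs_validation <- 12L; cfg$simulate$n_pairs_cerna <- 15L
  cfg$simulate$n_planted_de <- 10L; cfg$simulate$n_triplets <- 3L
  cfg$simulate$seq_len <- 120L; cfg$simulate$n_subjects_survival <- 60L
  cfg$simulate$n_gene_sets <- 8L
  cfg
}
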