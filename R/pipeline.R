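## End-to-end orchestration: simulate -> normalize -> DE -> intersect ->
## enrich -> candidates -> ceRNA -> survival, from one config with a single
## fanned-out seed and a checksum manifest.

#' Default pipeline configuration
#'
#' A complete nested configuration for a fully synthetic run: a discovery
#' cohort of four tumor/normal pairs and a larger validation cohort share
#' the planted DE features; a separate correlation cohort carries the
#' planted ceRNA triplets. Every effective parameter is echoed in the run
#' manifest.
#'
#' @param seed global integer seed; per-stage seeds are derived from it
#'   with [stage_seed()].
#' @param outdir output directory for all stage artifacts.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1, outdir = "cernet_run") {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    simulate = list(
      enabled = TRUE,
      n_pairs_discovery = 4L, n_pairs_validation = 30L, n_pairs_cerna = 30L,
      n_lnc = 60L, n_mrna = 60L, n_mirna = 10L,
      n_planted_de = 20L, de_log2fc = 2,
      n_triplets = 5L, beta = 0.8,
      noise_sd_de = 0.3, noise_sd_cerna = 0.5,
      baseline_mean = 8, seq_len = 300L,
      n_subjects_survival = 120L, hazard_ratio = 2, censor_rate = 0.3,
      n_gene_sets = 20L),
    inputs = list(),
    de = list(alpha = 0.05, mode = "microarray"),
    candidate = list(intensity_min = 7, max_length_nt = 2000),
    enrich = list(min_hits = 2L, top_k = 30L),
    cerna = list(percentile = 99, delta = 0.2,
                 condition_rule = "both", sensitivity_condition = "tumor"),
    survival = list(split = "median", time_unit = "years"))
}

## Recursively reject keys absent from the default schema (no silent typos).
check_config_keys <- function(config, defaults, path = "") {
  unknown <- setdiff(names(config), names(defaults))
  stop_if(length(unknown) > 0, "unknown config key%s: %s",
          if (length(unknown) > 1) "s" else "",
          paste0(path, unknown, collapse = ", "))
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) && k != "inputs")
      check_config_keys(config[[k]], defaults[[k]], paste0(path, k, "."))
  }
  invisible(TRUE)
}

merge_config <- function(config, defaults) {
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && is.list(config[[k]]) && k != "inputs") {
      defaults[[k]] <- merge_config(config[[k]], defaults[[k]])
    } else {
      defaults[[k]] <- config[[k]]
    }
  }
  defaults
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML configuration, merges it over [default_pipeline_config()]
#' and rejects unknown keys; basic numeric invariants (percentile in
#' (0, 100), delta in `[0, 2]`, positive thresholds) are enforced here,
#' before any stage runs.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param config an already-built list (alternative to `path`).
#' @return validated configuration list.
#' @export
read_pipeline_config <- function(path = NULL, config = NULL) {
  defaults <- default_pipeline_config()
  if (!is.null(path)) {
    stop_if(!file.exists(path), "no such config file: %s", path)
    config <- yaml::read_yaml(path)
  }
  if (is.null(config)) config <- list()
  check_config_keys(config, defaults)
  cfg <- merge_config(config, defaults)
  stop_if(cfg$cerna$percentile <= 0 || cfg$cerna$percentile >= 100,
          "cerna.percentile must be in (0, 100)")
  stop_if(cfg$cerna$delta < 0 || cfg$cerna$delta > 2, "cerna.delta must be in [0, 2]")
  stop_if(cfg$de$alpha <= 0 || cfg$de$alpha >= 1, "de.alpha must be in (0, 1)")
  stop_if(!cfg$cerna$condition_rule %in% c("both", "either"),
          "cerna.condition_rule must be 'both' or 'either'")
  stop_if(!cfg$cerna$sensitivity_condition %in% c("tumor", "normal"),
          "cerna.sensitivity_condition must be 'tumor' or 'normal'")
  cfg
}

#' Validate pipeline input files
#'
#' Checks declared input files (expression TSV headers and pairing
#' completeness, FASTA alphabet, GMT shape) and returns violations as
#' data, not exceptions. With simulation enabled there is nothing to
#' check.
#'
#' @param config pipeline configuration ([read_pipeline_config()]).
#' @return data.frame with `check`, `object`, `message`; zero rows when
#'   everything is valid.
#' @export
validate_inputs <- function(config) {
  config <- read_pipeline_config(config = config)
  v <- list()
  note <- function(check, object, message)
    v[[length(v) + 1L]] <<- data.frame(check = check, object = object,
                                       message = message, stringsAsFactors = FALSE)
  ins <- config$inputs
  if (!config$simulate$enabled) {
    req <- c("expr", "meta")
    for (k in req)
      if (is.null(ins[[k]])) note("missing_input", k, "required input path not configured")
  }
  for (k in names(ins)) {
    p <- ins[[k]]
    if (!file.exists(p)) { note("missing_file", p, "file does not exist"); next }
    if (grepl("\\.(fa|fasta)$", p)) {
      seqs <- tryCatch(Biostrings::readBStringSet(p), error = function(e) NULL)
      if (is.null(seqs)) { note("fasta_parse", p, "unparseable FASTA"); next }
      ok <- !grepl("[^ACGUTacgut]", as.character(seqs))
      for (bad in names(seqs)[!ok]) note("fasta_alphabet", bad, "illegal characters in record")
    } else if (grepl("\\.gmt$", p)) {
      err <- tryCatch({ read_gmt(p); NULL }, error = function(e) conditionMessage(e))
      if (!is.null(err)) note("gmt_shape", p, err)
    }
  }
  if (!is.null(ins$expr) && !is.null(ins$meta) &&
      file.exists(ins$expr) && file.exists(ins$meta)) {
    tab <- utils::read.delim(ins$expr, check.names = FALSE, nrows = 1)
    meta <- tryCatch(utils::read.delim(ins$meta, stringsAsFactors = FALSE),
                     error = function(e) NULL)
    if (names(tab)[1] != "feature_id")
      note("tsv_header", ins$expr, "first column must be feature_id")
    if (is.null(meta) || !all(c("sample_id", "condition", "pair_id") %in% names(meta))) {
      note("tsv_header", ins$meta, "need columns sample_id, condition, pair_id")
    } else {
      samples <- setdiff(names(tab), "feature_id")
      for (s in setdiff(samples, meta$sample_id))
        note("unpaired_sample", s, "sample present in matrix but absent from metadata")
      tab2 <- table(meta$pair_id, factor(meta$condition, c("tumor", "normal")))
      for (p in rownames(tab2)[tab2[, "tumor"] != 1 | tab2[, "normal"] != 1])
        note("incomplete_pair", p, "pair lacks one tumor and one normal sample")
    }
  }
  if (length(v) == 0)
    return(data.frame(check = character(), object = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

out_path <- function(config, ...) file.path(config$outdir, ...)

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## ---- stages ---------------------------------------------------------------

planted_de_default <- function(sim) {
  k <- min(sim$n_planted_de, sim$n_lnc + sim$n_mrna)
  kl <- min(k %/% 2, sim$n_lnc); km <- min(k - kl, sim$n_mrna)
  feats <- c(sprintf("LNC%04d", seq_len(kl)), sprintf("MRNA%04d", seq_len(km)))
  data.frame(feature = feats,
             log2fc = rep_len(c(sim$de_log2fc, -sim$de_log2fc), length(feats)),
             stringsAsFactors = FALSE)
}

planted_triplets_default <- function(sim) {
  k <- min(sim$n_triplets, sim$n_lnc, sim$n_mrna, sim$n_mirna)
  data.frame(lncRNA = sprintf("LNC%04d", seq_len(k)),
             miRNA = sprintf("MIR%04d", seq_len(k)),
             mRNA = sprintf("MRNA%04d", seq_len(k)),
             beta = sim$beta, stringsAsFactors = FALSE)
}

#' Pipeline stages
#'
#' Each stage reads its inputs from `config$outdir` (written by the
#' previous stage), writes its artifacts there, and returns the vector of
#' files written, so stages can be run standalone in order or through
#' [run_pipeline()].
#'
#' @param config validated configuration ([read_pipeline_config()]).
#' @return character vector of files written.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config) {
  sim <- config$simulate
  planted <- planted_de_default(sim)
  spec_disc <- synth_spec(n_pairs = sim$n_pairs_discovery, n_lnc = sim$n_lnc,
                          n_mrna = sim$n_mrna, n_mirna = sim$n_mirna,
                          planted_de = planted, noise_sd = sim$noise_sd_de,
                          baseline_mean = sim$baseline_mean,
                          hazard_ratio = sim$hazard_ratio,
                          censor_rate = sim$censor_rate,
                          seed = stage_seed(config$seed, "sim-discovery"))
  spec_val <- synth_spec(n_pairs = sim$n_pairs_validation, n_lnc = sim$n_lnc,
                         n_mrna = sim$n_mrna, planted_de = planted,
                         noise_sd = sim$noise_sd_de, baseline_mean = sim$baseline_mean,
                         seed = stage_seed(config$seed, "sim-validation"))
  trip <- planted_triplets_default(sim)
  spec_cer <- synth_spec(n_pairs = sim$n_pairs_cerna, n_lnc = sim$n_lnc,
                         n_mrna = sim$n_mrna, n_mirna = sim$n_mirna,
                         planted_triplets = trip, noise_sd = sim$noise_sd_cerna,
                         baseline_mean = sim$baseline_mean, seq_len = sim$seq_len,
                         seed = stage_seed(config$seed, "sim-cerna"))

  disc <- generate_expression(spec_disc)
  val <- generate_expression(spec_val)
  cer <- generate_cerna_system(spec_cer)
  gmt <- generate_gene_sets(spec_cer, n_sets = sim$n_gene_sets,
                            size_range = c(5L, max(6L, sim$n_mrna %/% 3)))
  clinical <- generate_clinical(spec_disc, n = sim$n_subjects_survival)

  files <- c(
    write_expr_set(disc$expr, out_path(config, "discovery_expr.tsv"),
                   out_path(config, "discovery_meta.tsv")),
    out_path(config, c("discovery_expr.tsv", "discovery_meta.tsv")),
    write_tsv(disc$annotation, out_path(config, "annotation.tsv")),
    {write_expr_set(val$expr, out_path(config, "validation_expr.tsv"),
                    out_path(config, "validation_meta.tsv"))
     out_path(config, c("validation_expr.tsv", "validation_meta.tsv"))},
    {write_expr_set(cer$lnc, out_path(config, "cerna_lnc.tsv"),
                    out_path(config, "cerna_meta.tsv"))
     write_expr_set(cer$mrna, out_path(config, "cerna_mrna.tsv"),
                    out_path(config, "cerna_meta.tsv"))
     write_expr_set(cer$mirna, out_path(config, "cerna_mirna.tsv"),
                    out_path(config, "cerna_meta.tsv"))
     out_path(config, c("cerna_lnc.tsv", "cerna_mrna.tsv", "cerna_mirna.tsv",
                        "cerna_meta.tsv"))},
    {write_fasta(cer$lnc_seq, out_path(config, "lnc.fasta"))
     write_fasta(cer$mrna_seq, out_path(config, "mrna.fasta"))
     write_fasta(cer$mirna_seq, out_path(config, "mirna.fasta"))
     out_path(config, c("lnc.fasta", "mrna.fasta", "mirna.fasta"))},
    {write_gmt(gmt, out_path(config, "genesets.gmt"))
     out_path(config, "genesets.gmt")},
    write_tsv(clinical, out_path(config, "clinical.tsv")))
  truth <- list(true_de = disc$truth$true_de,
                true_triplets = cer$truth$true_triplets,
                true_seed_sites = cer$truth$true_seed_sites)
  jsonlite::write_json(truth, out_path(config, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  unique(c(files, out_path(config, "truth.json")))
}

#' @rdname pipeline_stages
#' @export
stage_normalize <- function(config) {
  files <- character(0)
  for (cohort in c("discovery", "validation")) {
    es <- read_expr_set(out_path(config, paste0(cohort, "_expr.tsv")),
                        out_path(config, paste0(cohort, "_meta.tsv")))
    es <- quantile_normalize(es)
    write_expr_set(es, out_path(config, paste0(cohort, "_norm.tsv")),
                   out_path(config, paste0(cohort, "_meta.tsv")))
    files <- c(files, out_path(config, paste0(cohort, "_norm.tsv")))
  }
  files
}

#' @rdname pipeline_stages
#' @export
stage_de <- function(config) {
  files <- character(0)
  for (cohort in c("discovery", "validation")) {
    es <- read_expr_set(out_path(config, paste0(cohort, "_norm.tsv")),
                        out_path(config, paste0(cohort, "_meta.tsv")))
    mode <- if (cohort == "discovery") config$de$mode else "validation"
    de <- screen_de(es, mode = mode, alpha = config$de$alpha)
    files <- c(files,
               write_tsv(de$table, out_path(config, paste0("de_", cohort, ".tsv"))))
    writeLines(de$up, out_path(config, paste0("de_", cohort, "_up.txt")))
    writeLines(de$down, out_path(config, paste0("de_", cohort, "_down.txt")))
    files <- c(files, out_path(config, paste0("de_", cohort, c("_up.txt", "_down.txt"))))
  }
  files
}

read_de_ids <- function(config, cohort) {
  c(readLines(out_path(config, paste0("de_", cohort, "_up.txt"))),
    readLines(out_path(config, paste0("de_", cohort, "_down.txt"))))
}

#' @rdname pipeline_stages
#' @export
stage_intersect <- function(config) {
  common <- intersect_sets(read_de_ids(config, "discovery"),
                           read_de_ids(config, "validation"))
  writeLines(common, out_path(config, "de_intersection.txt"))
  out_path(config, "de_intersection.txt")
}

#' @rdname pipeline_stages
#' @export
stage_enrich <- function(config) {
  ann <- utils::read.delim(out_path(config, "annotation.tsv"), stringsAsFactors = FALSE)
  background <- ann$accession[ann$feature_class == "mRNA"]
  common <- readLines(out_path(config, "de_intersection.txt"))
  query <- intersect(common, background)
  sets <- read_gmt(out_path(config, "genesets.gmt"))
  res <- if (length(query) == 0) suppressWarnings(enrich(character(0), sets, background)) else
    enrich(query, sets, background, min_hits = config$enrich$min_hits)
  write_tsv(top_terms(res, config$enrich$top_k), out_path(config, "enrichment.tsv"))
  out_path(config, "enrichment.tsv")
}

#' @rdname pipeline_stages
#' @export
stage_candidates <- function(config) {
  de <- utils::read.delim(out_path(config, "de_discovery.tsv"), stringsAsFactors = FALSE)
  ann <- feature_annotation(
    utils::read.delim(out_path(config, "annotation.tsv"), stringsAsFactors = FALSE))
  common <- readLines(out_path(config, "de_intersection.txt"))
  lnc_ids <- ann$accession[ann$feature_class == "lncRNA"]
  de <- de[de$accession %in% intersect(common, lnc_ids), , drop = FALSE]
  res <- candidate_filter(de, ann, intensity_min = config$candidate$intensity_min,
                          max_length_nt = config$candidate$max_length_nt)
  c(write_tsv(res$candidates, out_path(config, "candidates.tsv")),
    write_tsv(res$removed, out_path(config, "candidates_removed.tsv")))
}

#' @rdname pipeline_stages
#' @export
stage_cerna <- function(config) {
  for (f in c("mirna.fasta", "lnc.fasta", "mrna.fasta"))
    stop_if(!file.exists(out_path(config, f)),
            "ceRNA stage input missing: %s", out_path(config, f))
  lnc <- read_expr_set(out_path(config, "cerna_lnc.tsv"), out_path(config, "cerna_meta.tsv"))
  mrna <- read_expr_set(out_path(config, "cerna_mrna.tsv"), out_path(config, "cerna_meta.tsv"))
  mirna <- read_expr_set(out_path(config, "cerna_mirna.tsv"), out_path(config, "cerna_meta.tsv"))
  lseq <- read_fasta(out_path(config, "lnc.fasta"))
  mseq <- read_fasta(out_path(config, "mrna.fasta"))
  zseq <- read_fasta(out_path(config, "mirna.fasta"))
  ct <- pairwise_correlation(lnc, mrna, "tumor")
  cn <- pairwise_correlation(lnc, mrna, "normal")
  sel <- select_cerna_pairs(ct, cn, q = config$cerna$percentile,
                            rule = config$cerna$condition_rule)
  asm <- assemble_triplets(sel$pairs, lnc, mrna, mirna, lseq, mseq, zseq,
                           delta = config$cerna$delta,
                           sensitivity_condition = config$cerna$sensitivity_condition)
  net <- build_network(asm$triplets)
  jsonlite::write_json(list(threshold_tumor = sel$threshold_tumor,
                            threshold_normal = sel$threshold_normal,
                            n_selected_pairs = nrow(sel$pairs)),
                       out_path(config, "cerna_thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  c(write_tsv(sel$pairs, out_path(config, "selected_pairs.tsv")),
    write_tsv(asm$triplets, out_path(config, "triplets.tsv")),
    write_tsv(asm$excluded, out_path(config, "triplets_excluded.tsv")),
    export_network(net, out_path(config, "network.sif"), "sif"),
    export_network(net, out_path(config, "network.graphml"), "graphml"),
    out_path(config, "cerna_thresholds.json"))
}

#' @rdname pipeline_stages
#' @export
stage_survival <- function(config) {
  sim <- config$simulate
  spec <- synth_spec(n_pairs = sim$n_pairs_discovery,
                     hazard_ratio = sim$hazard_ratio, censor_rate = sim$censor_rate,
                     seed = stage_seed(config$seed, "survival-groups"))
  expr <- with_seed(stage_seed(config$seed, "survival-expression"),
                    stats::rnorm(sim$n_subjects_survival))
  groups <- median_split(expr)
  rec <- generate_survival(spec, groups)
  km <- do.call(rbind, lapply(split(rec, rec$group), function(r)
    cbind(group = r$group[1], km_estimate(r), stringsAsFactors = FALSE)))
  rownames(km) <- NULL
  lr <- logrank_test(rec)
  jsonlite::write_json(lr, out_path(config, "logrank.json"),
                       auto_unbox = TRUE, digits = NA)
  c(write_tsv(rec, out_path(config, "survival_records.tsv")),
    write_tsv(km, out_path(config, "km_curves.tsv")),
    out_path(config, "logrank.json"))
}

#' Run the full screening pipeline
#'
#' Executes simulate (optional) -> normalize -> DE -> intersect -> enrich
#' -> candidates -> ceRNA -> survival. Every stage writes its artifacts
#' into `config$outdir`; the returned manifest records the effective
#' configuration, the per-stage output files and their MD5 checksums. A
#' fixed config and seed reproduce byte-identical artifacts.
#'
#' @param config a configuration list, or path to a YAML config; merged
#'   over [default_pipeline_config()].
#' @param seed optional override of the config's global seed.
#' @return the run manifest (list), invisibly; also written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config = NULL, seed = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(path = config)
         else read_pipeline_config(config = config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  viol <- validate_inputs(cfg)
  stop_if(nrow(viol) > 0, "invalid inputs: %s",
          paste(viol$check, viol$object, sep = ":", collapse = "; "))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- list(simulate = stage_simulate, normalize = stage_normalize,
                 de = stage_de, intersect = stage_intersect,
                 enrich = stage_enrich, candidates = stage_candidates,
                 cerna = stage_cerna, survival = stage_survival)
  if (!cfg$simulate$enabled) stages$simulate <- NULL
  manifest <- list(config = cfg, seed = cfg$seed, stages = list(),
                   package_version = as.character(utils::packageVersion("cernet")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  for (nm in names(stages)) {
    message("[", nm, "] running")
    files <- tryCatch(stages[[nm]](cfg), error = function(e)
      stop(sprintf("stage '%s' failed: %s", nm, conditionMessage(e)), call. = FALSE))
    manifest$stages[[nm]] <- list(outputs = basename(files),
                                  checksums = as.list(file_checksums(files)))
  }
  jsonlite::write_json(manifest, out_path(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
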