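## Synthetic cohorts with planted truth: differential expression, ceRNA
## triplets driven by latent miRNA activity, seed sites, survival hazards.

#' Specification of a synthetic paired cohort
#'
#' Bundles every parameter of the synthetic-data generators. The default
#' design mirrors a small paired tumor/normal microarray cohort of four
#' pairs; correlation-based experiments use larger cohorts (four pairs
#' cannot support correlation inference) via e.g. [cerna_recovery_spec()].
#'
#' @param n_pairs number of tumor/normal sample pairs.
#' @param n_lnc,n_mrna,n_mirna feature counts per molecule class.
#' @param planted_de `NULL` or data.frame with columns `feature`, `log2fc`:
#'   features whose tumor - normal log2 difference is shifted by `log2fc`.
#' @param planted_triplets `NULL` or data.frame with columns `lncRNA`,
#'   `miRNA`, `mRNA`, `beta`: ceRNA triplets in which a latent miRNA
#'   activity `z` represses both targets with slope `beta` (log2 units per
#'   unit activity).
#' @param noise_sd log2-scale Gaussian measurement noise (sd).
#' @param baseline_mean log2 baseline intensity.
#' @param baseline_feature_sd sd of the per-feature baseline around
#'   `baseline_mean` (constant across samples). Emulates the wide dynamic
#'   range of array intensities; it cancels from every tumor - normal
#'   difference but keeps planted features in the interior of the intensity
#'   distribution, where quantile normalization is rank-faithful.
#' @param seq_len transcript length in nt for generated lncRNA/mRNA
#'   sequences.
#' @param hazard_ratio survival hazard ratio between expression groups.
#' @param baseline_hazard events per year in the reference group.
#' @param censor_rate expected fraction of censored subjects, in `[0, 1)`.
#' @param seed integer RNG seed; identical specs give bit-identical outputs.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_pairs = 4, n_lnc = 200, n_mrna = 200, n_mirna = 20,
                       planted_de = NULL, planted_triplets = NULL,
                       noise_sd = 0.3, baseline_mean = 8, baseline_feature_sd = 2,
                       seq_len = 500,
                       hazard_ratio = 1, baseline_hazard = 0.2,
                       censor_rate = 0.3, seed = 1) {
  for (nm in c("n_pairs", "n_lnc", "n_mrna", "n_mirna"))
    stop_if(!is_count(get(nm)), "%s must be a non-negative integer", nm)
  stop_if(!is.numeric(noise_sd) || noise_sd < 0, "noise_sd must be >= 0")
  stop_if(!is.numeric(hazard_ratio) || hazard_ratio <= 0, "hazard_ratio must be > 0")
  stop_if(!is.numeric(baseline_hazard) || baseline_hazard <= 0, "baseline_hazard must be > 0")
  stop_if(!is.numeric(censor_rate) || censor_rate < 0 || censor_rate >= 1,
          "censor_rate must be in [0, 1)")
  stop_if(!is.numeric(baseline_feature_sd) || baseline_feature_sd < 0,
          "baseline_feature_sd must be >= 0")
  stop_if(!is_count(seq_len), "seq_len must be a non-negative integer")
  stop_if(!is_count(abs(seed)), "seed must be a single integer")
  spec <- structure(list(
    n_pairs = as.integer(n_pairs), n_lnc = as.integer(n_lnc),
    n_mrna = as.integer(n_mrna), n_mirna = as.integer(n_mirna),
    planted_de = planted_de, planted_triplets = planted_triplets,
    noise_sd = noise_sd, baseline_mean = baseline_mean,
    baseline_feature_sd = baseline_feature_sd,
    seq_len = as.integer(seq_len), hazard_ratio = hazard_ratio,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    seed = as.integer(seed)), class = "synth_spec")
  feats <- unlist(synth_feature_ids(spec), use.names = FALSE)
  if (!is.null(planted_de)) {
    stop_if(!is.data.frame(planted_de) || !all(c("feature", "log2fc") %in% names(planted_de)),
            "planted_de needs columns feature, log2fc")
    bad <- setdiff(planted_de$feature, feats)
    stop_if(length(bad) > 0, "planted_de references undeclared features: %s",
            paste(utils::head(bad, 3), collapse = ", "))
    stop_if(anyDuplicated(planted_de$feature) > 0, "duplicate planted_de features")
  }
  if (!is.null(planted_triplets)) {
    req <- c("lncRNA", "miRNA", "mRNA", "beta")
    stop_if(!is.data.frame(planted_triplets) || !all(req %in% names(planted_triplets)),
            "planted_triplets needs columns lncRNA, miRNA, mRNA, beta")
    bad <- setdiff(c(planted_triplets$lncRNA, planted_triplets$miRNA, planted_triplets$mRNA), feats)
    stop_if(length(bad) > 0, "planted_triplets references undeclared features: %s",
            paste(utils::head(bad, 3), collapse = ", "))
  }
  spec
}

## Declared feature ids, deterministic by class and index.
synth_feature_ids <- function(spec) {
  list(lnc = sprintf("LNC%04d", seq_len(spec$n_lnc)),
       mrna = sprintf("MRNA%04d", seq_len(spec$n_mrna)),
       mirna = sprintf("MIR%04d", seq_len(spec$n_mirna)))
}

synth_sample_meta <- function(n_pairs) {
  pid <- sprintf("P%03d", seq_len(n_pairs))
  data.frame(sample_id = c(paste0(pid, "_T"), paste0(pid, "_N")),
             condition = rep(c("tumor", "normal"), each = n_pairs),
             pair_id = rep(pid, 2), stringsAsFactors = FALSE)
}

#' Generate a paired expression matrix with planted differential expression
#'
#' Each feature's log2 intensity is `baseline_mean` plus Gaussian noise;
#' planted features additionally get their planted log2 fold change added to
#' every tumor sample, so the expected tumor - normal log2 difference equals
#' the planted value and is 0 for all other features.
#'
#' @param spec a [synth_spec]; `n_pairs >= 1` and at least one feature.
#' @return a list with elements `expr` (an [expr_set] over the lncRNA and
#'   mRNA features), `annotation` (a [feature_annotation] data.frame) and
#'   `truth` (list with `true_de`).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  stop_if(spec$n_pairs < 1, "need at least one tumor/normal pair")
  ids <- synth_feature_ids(spec)
  feats <- c(ids$lnc, ids$mrna)
  stop_if(length(feats) == 0, "spec declares zero lncRNA/mRNA features")
  meta <- synth_sample_meta(spec$n_pairs)
  with_seed(stage_seed(spec$seed, "expression"), {
    baseline <- spec$baseline_mean +
      stats::rnorm(length(feats), sd = spec$baseline_feature_sd)
    m <- matrix(baseline +
                  stats::rnorm(length(feats) * nrow(meta), sd = spec$noise_sd),
                nrow = length(feats), ncol = nrow(meta),
                dimnames = list(feats, meta$sample_id))
    if (!is.null(spec$planted_de)) {
      idx <- match(spec$planted_de$feature, feats)
      tum <- meta$sample_id[meta$condition == "tumor"]
      m[idx, tum] <- m[idx, tum] + spec$planted_de$log2fc
    }
    ann <- data.frame(
      accession = feats,
      symbol = NA_character_,
      chromosome = sample(paste0("chr", c(1:22, "X", "Y")), length(feats),
                          replace = TRUE,
                          prob = c(rep(0.9 / 22, 22), 0.05, 0.05)),
      feature_class = rep(c("lncRNA", "mRNA"), c(length(ids$lnc), length(ids$mrna))),
      length_nt = sample(200:3000, length(feats), replace = TRUE),
      lnc_category = NA_character_,
      stringsAsFactors = FALSE)
    ann$lnc_category[ann$feature_class == "lncRNA"] <-
      sample(c("intergenic", "antisense", "exonic-sense"),
             length(ids$lnc), replace = TRUE)
    list(expr = expr_set(m, meta), annotation = feature_annotation(ann),
         truth = list(true_de = spec$planted_de))
  })
}

rand_rna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a synthetic ceRNA system with planted triplets
#'
#' For every planted triplet a per-sample latent miRNA activity `z ~ N(0,1)`
#' is drawn independently in each condition; the lncRNA and mRNA read
#' `baseline - beta * z + noise` and the miRNA expression reads
#' `baseline + z + noise`, so the lncRNA and mRNA are positively correlated
#' and conditioning on the miRNA removes that correlation. Decoy features
#' are independent `baseline + N(0, 1) + noise`. The reverse complement of
#' each planted miRNA's 6-mer seed is inserted at a recorded (0-based)
#' position into both target transcripts; decoy sequences carry no planted
#' site.
#'
#' @param spec a [synth_spec] with `planted_triplets` referencing declared
#'   features and `seq_len >= 6`.
#' @return list with `lnc`, `mrna`, `mirna` ([expr_set]s over both
#'   conditions), `lnc_seq`, `mrna_seq`, `mirna_seq` (named character
#'   vectors, RNA alphabet 5'->3') and `truth` (list with `true_triplets`
#'   and `true_seed_sites`).
#' @export
generate_cerna_system <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  stop_if(spec$seq_len < 6, "seq_len must be at least 6 to carry a seed site")
  stop_if(spec$n_pairs < 1, "need at least one tumor/normal pair")
  ids <- synth_feature_ids(spec)
  stop_if(anyDuplicated(c(ids$lnc, ids$mrna, ids$mirna)) > 0, "duplicate feature names")
  trip <- spec$planted_triplets
  meta <- synth_sample_meta(spec$n_pairs)
  n <- spec$n_pairs

  with_seed(stage_seed(spec$seed, "cerna"), {
    gen_cond <- function() {
      base <- function(k) matrix(stats::rnorm(k * n), k, n)
      lnc <- spec$baseline_mean + base(spec$n_lnc)
      mrna <- spec$baseline_mean + base(spec$n_mrna)
      mirna <- spec$baseline_mean + base(spec$n_mirna)
      rownames(lnc) <- ids$lnc; rownames(mrna) <- ids$mrna; rownames(mirna) <- ids$mirna
      if (!is.null(trip) && nrow(trip) > 0) {
        z <- matrix(stats::rnorm(length(unique(trip$miRNA)) * n), ncol = n,
                    dimnames = list(unique(trip$miRNA), NULL))
        ## planted miRNAs report their latent activity (plus noise)
        mirna[rownames(z), ] <- spec$baseline_mean + z
        for (i in seq_len(nrow(trip))) {
          zi <- z[trip$miRNA[i], ]
          lnc[trip$lncRNA[i], ] <- spec$baseline_mean - trip$beta[i] * zi
          mrna[trip$mRNA[i], ] <- spec$baseline_mean - trip$beta[i] * zi
        }
      }
      noise <- function(m) m + matrix(stats::rnorm(length(m), sd = spec$noise_sd),
                                      nrow(m), ncol(m))
      list(lnc = noise(lnc), mrna = noise(mrna), mirna = noise(mirna))
    }
    tum <- gen_cond()
    nor <- gen_cond()
    bind <- function(cls) {
      m <- cbind(tum[[cls]], nor[[cls]])
      colnames(m) <- meta$sample_id
      expr_set(m, meta)
    }

    lnc_seq <- stats::setNames(rand_rna(spec$n_lnc, spec$seq_len), ids$lnc)
    mrna_seq <- stats::setNames(rand_rna(spec$n_mrna, spec$seq_len), ids$mrna)
    mirna_seq <- stats::setNames(rand_rna(spec$n_mirna, 22L), ids$mirna)

    sites <- NULL
    if (!is.null(trip) && nrow(trip) > 0) {
      plant <- function(seqs, target, site) {
        pos <- sample.int(spec$seq_len - 6L + 1L, 1L) - 1L   # 0-based
        substr(seqs[target], pos + 1L, pos + 6L) <- site
        list(seqs = seqs, pos = pos)
      }
      rows <- vector("list", 2L * nrow(trip))
      for (i in seq_len(nrow(trip))) {
        site <- rna_reverse_complement(seed_of(mirna_seq[trip$miRNA[i]]))
        p1 <- plant(lnc_seq, trip$lncRNA[i], site); lnc_seq <- p1$seqs
        p2 <- plant(mrna_seq, trip$mRNA[i], site); mrna_seq <- p2$seqs
        rows[[2L * i - 1L]] <- data.frame(target = trip$lncRNA[i], mirna = trip$miRNA[i],
                                          position = p1$pos, stringsAsFactors = FALSE)
        rows[[2L * i]] <- data.frame(target = trip$mRNA[i], mirna = trip$miRNA[i],
                                     position = p2$pos, stringsAsFactors = FALSE)
      }
      sites <- do.call(rbind, rows)
    }
    list(lnc = bind("lnc"), mrna = bind("mrna"), mirna = bind("mirna"),
         lnc_seq = lnc_seq, mrna_seq = mrna_seq, mirna_seq = mirna_seq,
         truth = list(true_triplets = trip, true_seed_sites = sites))
  })
}

#' Generate survival records with a group-dependent hazard
#'
#' Event times are exponential: the reference group (first label in order of
#' appearance) has rate `baseline_hazard`, the other group
#' `baseline_hazard * hazard_ratio`. Censoring times are drawn independently
#' from an exponential whose rate is chosen so the expected censored
#' fraction equals `censor_rate`.
#'
#' @param spec a [synth_spec].
#' @param groups character vector of group labels, one per subject; exactly
#'   two distinct non-empty labels.
#' @return data.frame with `subject_id`, `time` (years), `event` (logical),
#'   `group`.
#' @export
generate_survival <- function(spec, groups) {
  stopifnot(inherits(spec, "synth_spec"))
  lev <- unique(groups)
  stop_if(length(lev) != 2L || any(!nzchar(lev)), "need exactly two non-empty group labels")
  stop_if(any(table(groups) == 0), "empty groups")
  h <- ifelse(groups == lev[1], spec$baseline_hazard,
              spec$baseline_hazard * spec$hazard_ratio)
  with_seed(stage_seed(spec$seed, "survival"), {
    t_event <- stats::rexp(length(groups), rate = h)
    if (spec$censor_rate > 0) {
      c_rate <- h * spec$censor_rate / (1 - spec$censor_rate)
      t_cens <- stats::rexp(length(groups), rate = c_rate)
    } else {
      t_cens <- rep(Inf, length(groups))
    }
    data.frame(subject_id = sprintf("S%04d", seq_along(groups)),
               time = pmin(t_event, t_cens),
               event = t_event <= t_cens,
               group = groups, stringsAsFactors = FALSE)
  })
}

#' Generate a categorical clinical covariate table
#'
#' Each subject's category for every variable is an independent draw from
#' the stated proportions (normalized internally), so per-variable counts
#' always sum to `n` and fluctuate binomially around `n * p`.
#'
#' @param spec a [synth_spec] (supplies the seed).
#' @param n number of subjects, `>= 1`.
#' @param proportions named list of named numeric vectors: one entry per
#'   clinical variable giving category proportions.
#' @return data.frame with `subject_id` and one column per variable.
#' @export
generate_clinical <- function(spec, n,
                              proportions = list(
                                age_group = c("<68" = 0.545, ">=68" = 0.455),
                                sex = c(Male = 0.467, Female = 0.533),
                                stage = c(I = 0.543, II = 0.237, III = 0.152, IV = 0.068))) {
  stopifnot(inherits(spec, "synth_spec"))
  stop_if(!is_count(n) || n < 1, "n must be a positive integer")
  stop_if(length(proportions) == 0, "need at least one clinical variable")
  with_seed(stage_seed(spec$seed, "clinical"), {
    out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (v in names(proportions)) {
      p <- proportions[[v]]
      stop_if(any(p < 0) || sum(p) <= 0, "invalid proportions for %s", v)
      out[[v]] <- sample(names(p), n, replace = TRUE, prob = p / sum(p))
    }
    out
  })
}

#' Generate random gene sets over the synthetic mRNA features
#'
#' Plumbing for exercising the enrichment stage on synthetic cohorts: draws
#' seeded random subsets of the declared mRNA features as a gene-set
#' collection.
#'
#' @param spec a [synth_spec].
#' @param n_sets number of sets.
#' @param size_range integer range of set sizes.
#' @return a data.frame of gene sets as returned by [read_gmt()].
#' @export
generate_gene_sets <- function(spec, n_sets = 20, size_range = c(10, 40)) {
  stopifnot(inherits(spec, "synth_spec"))
  ids <- synth_feature_ids(spec)$mrna
  stop_if(length(ids) < max(size_range), "fewer mRNA features than max set size")
  with_seed(stage_seed(spec$seed, "genesets"), {
    sets <- lapply(seq_len(n_sets), function(i)
      sort(sample(ids, sample(size_range[1]:size_range[2], 1L))))
    data.frame(term_id = sprintf("SET%03d", seq_len(n_sets)),
               term_name = sprintf("synthetic set %d", seq_len(n_sets)),
               category = "custom",
               members = vapply(sets, paste, character(1), collapse = ","),
               stringsAsFactors = FALSE)
  })
}

#' Study conditions for the planted ceRNA recovery experiment
#'
#' Twenty planted lncRNA--miRNA--mRNA triplets (latent-activity slope
#' `beta = 0.8`, noise sd 0.5) among 200 decoy lncRNAs and 200 decoy mRNAs,
#' in a cohort of 50 tumor/normal pairs, so the pair universe holds 220 x
#' 220 candidate pairs of which the planted 20 are the strongly correlated
#' minority screened out by the 99th-percentile rule.
#'
#' @param seed integer RNG seed.
#' @return a [synth_spec].
#' @export
cerna_recovery_spec <- function(seed = 1) {
  trip <- data.frame(lncRNA = sprintf("LNC%04d", 1:20),
                     miRNA = sprintf("MIR%04d", 1:20),
                     mRNA = sprintf("MRNA%04d", 1:20),
                     beta = 0.8, stringsAsFactors = FALSE)
  synth_spec(n_pairs = 50, n_lnc = 220, n_mrna = 220, n_mirna = 20,
             planted_triplets = trip, noise_sd = 0.5, seq_len = 500,
             seed = seed)
}

#' Study conditions for the planted differential-expression recovery
#'
#' Four tumor/normal pairs (the microarray design emulated throughout),
#' noise sd 0.3, and 40 planted features at log2 fold change +2 or -2 among
#' 400 features.
#'
#' @param seed integer RNG seed.
#' @return a [synth_spec].
#' @export
de_recovery_spec <- function(seed = 1) {
  feats <- c(sprintf("LNC%04d", 1:20), sprintf("MRNA%04d", 1:20))
  planted <- data.frame(feature = feats,
                        log2fc = rep(c(2, -2), 20), stringsAsFactors = FALSE)
  synth_spec(n_pairs = 4, n_lnc = 200, n_mrna = 200, planted_de = planted,
             noise_sd = 0.3, seed = seed)
}
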