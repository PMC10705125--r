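#' Pipeline configuration
#'
#' One object holding the stage list, thresholds and the global seed for an
#' end-to-end run on synthetic data. Threshold defaults are the pipeline's
#' canonical values (QC ratio 0.10, junction reads 4, coverage 0.20/0.70,
#' median depth 3, whitelist 0.08, retained 0.1, DIR p 0.05 and delta 0.1,
#' missing rates 0.30/0.20, eligibility 0.50/0.05). The global seed fans
#' out to per-stage child seeds as `seed * 100 + stage index`, so any stage
#' can be reproduced in isolation.
#'
#' @param sim A [sim_config()] for the simulate stage.
#' @param stages Character vector of stages to run, a prefix-closed subset
#'   of `c("simulate", "quantify", "whitelist", "dir", "features",
#'   "diagnose", "prognosis")`.
#' @param seed Global integer seed.
#' @param thresholds Named list overriding threshold defaults.
#' @param diagnostic Named list: `repeats`, `folds` for the diagnose stage.
#' @param survival Named list: `h0`, `censor_frac`, `beta` (planted
#'   log-hazard), `n_prognostic` (introns given the planted hazard).
#' @param planted_dirs Number of introns given a planted tumor-normal
#'   retention shift, and `delta` its size.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("simulate", "quantify", "whitelist",
                                       "dir", "features", "diagnose",
                                       "prognosis"),
                            seed = 1L,
                            thresholds = list(),
                            diagnostic = list(repeats = 5L, folds = 4L),
                            survival = list(h0 = 0.002, censor_frac = 0.3,
                                            beta = 1, n_prognostic = 3L),
                            planted_dirs = list(n = 20L, delta = 0.3)) {
  all_stages <- c("simulate", "quantify", "whitelist", "dir", "features",
                  "diagnose", "prognosis")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop_fmt("unknown stage: %s", bad[1L])
  defaults <- list(qc_ratio = 0.10, min_junctions = 4L, cov_low = 0.20,
                   cov_high = 0.70, min_median_depth = 3,
                   whitelist = 0.08, retained = 0.1, dir_alpha = 0.05,
                   dir_delta = 0.1, max_missing = 0.30,
                   irr_max_missing = 0.20, elig_valid = 0.50,
                   elig_above = 0.05)
  thr <- utils::modifyList(defaults, thresholds)
  structure(list(sim = sim, stages = stages, seed = as.integer(seed),
                 thresholds = thr, diagnostic = diagnostic,
                 survival = survival, planted_dirs = planted_dirs),
            class = "pipeline_config")
}

stage_seed <- function(config, stage) {
  all_stages <- c("simulate", "quantify", "whitelist", "dir", "features",
                  "diagnose", "prognosis")
  config$seed * 100L + match(stage, all_stages)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate -> quantify -> whitelist -> dir -> features -> diagnose ->
#' prognosis), writing each stage's outputs as TSV/JSON under `dir`. The
#' serialized configuration is written first and its MD5 hash is stamped
#' as a `#config=` header line into every TSV output, so artifacts are
#' traceable to the exact configuration; re-running with an identical
#' configuration and seed reproduces every file bit for bit.
#'
#' @param config A [pipeline_config()].
#' @param dir Run directory (created if needed).
#' @return Invisibly, a manifest list of the in-memory stage results;
#'   files are under `dir`.
#' @export
run_pipeline <- function(config, dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(config_to_list(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  hash <- unname(tools::md5sum(cfg_path))
  res <- list(config = config, hash = hash, dir = dir)
  thr <- config$thresholds

  need <- function(what, stage) {
    if (is.null(res[[what]])) {
      stop_fmt("stage '%s' requires output of an earlier stage ('%s') that has not run",
               stage, what)
    }
    res[[what]]
  }

  for (stage in config$stages) {
    if (stage == "simulate") {
      genome <- make_genome(config$sim, stage_seed(config, stage),
                            file.path(dir, "genome"))
      introns <- extract_introns(genome$models)
      usable <- introns[!introns$known_exon_overlap, , drop = FALSE]
      n_planted <- min(config$planted_dirs$n, nrow(usable))
      planted <- data.frame(
        intron_id = usable$intron_id[seq_len(n_planted)],
        delta = config$planted_dirs$delta)
      cohort <- simulate_cohort(usable, config$sim, planted,
                                seed = stage_seed(config, stage) + 1L)
      write_intron_bed(introns, file.path(dir, "introns.bed"))
      write_tsv_hashed(cohort$truth, file.path(dir, "truth.tsv"), hash)
      write_tsv_hashed(cohort$samples, file.path(dir, "samples.tsv"), hash)
      res$simulate <- list(genome = genome, introns = introns,
                           cohort = cohort, planted = planted)
    } else if (stage == "quantify") {
      sim <- need("simulate", stage)
      mat <- build_ir_matrix(sim$cohort$summaries, sim$introns,
                             samples = sim$cohort$samples)
      write_ir_matrix_hashed(mat$ir, file.path(dir, "ir_matrix.tsv"), hash)
      res$quantify <- mat
    } else if (stage == "whitelist") {
      mat <- need("quantify", stage)
      wl <- build_whitelist(mat, threshold = thr$whitelist)
      writeLines(c(sprintf("#config=%s", hash), wl),
                 file.path(dir, "whitelist.txt"))
      res$whitelist <- wl
    } else if (stage == "dir") {
      mat <- need("quantify", stage)
      wl <- need("whitelist", stage)
      dirs <- call_dirs(mat, whitelist = wl, alpha = thr$dir_alpha,
                        min_delta = thr$dir_delta, cancer_type = "SIM")
      write_tsv_hashed(dirs, file.path(dir, "dirs.tsv"), hash)
      res$dir <- dirs
    } else if (stage == "features") {
      sim <- need("simulate", stage)
      mat <- need("quantify", stage)
      dirs <- need("dir", stage)
      feats <- feature_table(sim, mat, dirs)
      write_tsv_hashed(feats, file.path(dir, "features.tsv"), hash)
      res$features <- feats
    } else if (stage == "diagnose") {
      mat <- need("quantify", stage)
      dirs <- need("dir", stage)
      feat_ids <- merge_dirs_pan_cancer(dirs, mat,
                                        max_missing = thr$max_missing)
      if (nrow(feat_ids) < 2L) {
        stop_fmt("stage 'diagnose': fewer than 2 merged DIR features")
      }
      dense <- matrix_prep(mat, max_missing = thr$max_missing)
      keep <- intersect(feat_ids$intron_id, rownames(dense))
      paired <- !is.na(mat$samples$pair_id)
      x <- t(dense[keep, mat$samples$sample_id[paired], drop = FALSE])
      run <- train_eval_cv(x, mat$samples$condition[paired],
                           pairs = mat$samples$pair_id[paired],
                           repeats = config$diagnostic$repeats,
                           folds = config$diagnostic$folds,
                           seed = stage_seed(config, stage))
      metrics <- list(pooled_auc = run$pooled_auc,
                      n_features = length(keep),
                      repeats = config$diagnostic$repeats)
      jsonlite::write_json(metrics, file.path(dir, "diagnostic.json"),
                           auto_unbox = TRUE, digits = NA)
      res$diagnose <- run
    } else if (stage == "prognosis") {
      mat <- need("quantify", stage)
      wl <- need("whitelist", stage)
      tumors <- mat$samples$sample_id[mat$samples$condition == "tumor" &
                                        !is.na(mat$samples$pair_id)]
      tm <- mat$ir[intersect(rownames(mat$ir), wl), tumors, drop = FALSE]
      sseed <- stage_seed(config, stage)
      # plant hazards on the first prognostic introns that qualify
      elig <- rownames(tm)[apply(tm, 1L, prognostic_eligibility,
                                 min_valid = thr$elig_valid,
                                 min_above = thr$elig_above,
                                 threshold = thr$retained)]
      npro <- min(config$survival$n_prognostic, length(elig))
      beta_map <- stats::setNames(rep(config$survival$beta, npro),
                                  elig[seq_len(npro)])
      surv <- simulate_survival(tm, beta_map, h0 = config$survival$h0,
                                censor_frac = config$survival$censor_frac,
                                seed = sseed)
      model <- fit_irr(tm, surv, lambda_rule = "min",
                       max_missing = thr$irr_max_missing, seed = sseed + 1L)
      # an empty model (no introns selected) cannot stratify patients
      stratifies <- length(model$intron_ids) > 0L &&
        nlevels(droplevels(model$groups)) == 2L
      km <- if (stratifies) km_logrank(model$groups, surv) else NULL
      write_tsv_hashed(surv, file.path(dir, "survival.tsv"), hash)
      jsonlite::write_json(
        list(introns = model$intron_ids,
             coefficients = model$coefficients,
             lambda = model$lambda, cutoff = model$cutoff,
             logrank_p = if (is.null(km)) NA else km$logrank_p,
             hr = if (is.null(km)) NA else km$hr),
        file.path(dir, "irr_model.json"), auto_unbox = TRUE, digits = NA)
      res$prognosis <- list(model = model, km = km, surv = surv,
                            beta_map = beta_map)
    }
  }
  invisible(res)
}

# Strip function-valued/simulation-heavy parts for serialization.
config_to_list <- function(config) {
  list(sim = unclass(config$sim), stages = config$stages,
       seed = config$seed, thresholds = config$thresholds,
       diagnostic = config$diagnostic, survival = config$survival,
       planted_dirs = config$planted_dirs)
}

write_tsv_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#config=%s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

write_ir_matrix_hashed <- function(mat, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#config=%s", hash), con)
  df <- data.frame(intron_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# Per-intron feature table for the features stage.
feature_table <- function(sim, mat, dirs) {
  introns <- sim$introns[!sim$introns$known_exon_overlap, , drop = FALSE]
  introns <- introns[match(rownames(mat$ir), introns$intron_id), ,
                     drop = FALSE]
  genome <- Biostrings::readDNAStringSet(sim$genome$fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqs <- vapply(seq_len(nrow(introns)), function(i) {
    fetch_seq(genome, introns$chrom[i], introns$start[i], introns$end[i],
              introns$strand[i] == "-")
  }, character(1))
  smp <- mat$samples
  med_t <- apply(mat$ir[, smp$sample_id[smp$condition == "tumor"],
                        drop = FALSE], 1L, stats::median, na.rm = TRUE)
  med_n <- apply(mat$ir[, smp$sample_id[smp$condition == "normal"],
                        drop = FALSE], 1L, stats::median, na.rm = TRUE)
  medians <- cbind(SIM_tumor = med_t, SIM_normal = med_n)
  medians[is.nan(medians)] <- NA_real_
  cls <- classify_introns(medians, dirs)
  nmd <- vapply(seq_len(nrow(introns)), function(i) {
    if (introns$region[i] == "noncoding") return(NA_character_)
    call <- tryCatch(predict_nmd(sim$genome$models, introns[i, ], genome),
                     error = function(e) NULL)
    if (is.null(call)) NA_character_ else call$verdict
  }, character(1))
  data.frame(intron_id = introns$intron_id, class = as.character(cls),
             gc = round(gc_content(seqs), 4L),
             length = intron_length(introns),
             rel_pos = round(relative_gene_position(
               introns$ordinal, introns$n_introns_in_gene), 4L),
             region = introns$region, nmd = nmd,
             stringsAsFactors = FALSE)
}

#' Build the demo dataset and its expected-results manifest
#'
#' Runs a small fully seeded pipeline and records headline results
#' (intron count, DIR count and recall against the planted truth, pooled
#' diagnostic AUC, IRR selection and log-rank p) as a manifest, which
#' regenerates identically for the same seed.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return List with `dir` and `manifest` (also written to
#'   `manifest.json`).
#' @export
make_demo <- function(seed = 42L, dir = tempfile("demo")) {
  config <- pipeline_config(
    sim = sim_config(n_genes = 25L, n_pairs = 20L, depth = 80),
    seed = seed)
  res <- run_pipeline(config, dir)
  planted <- res$simulate$planted$intron_id
  manifest <- list(
    seed = seed,
    n_introns = nrow(res$simulate$introns),
    n_quantified = nrow(res$quantify$ir),
    n_whitelist = length(res$whitelist),
    n_dirs = nrow(res$dir),
    dir_recall = mean(planted %in% res$dir$intron_id),
    pooled_auc = res$diagnose$pooled_auc,
    n_irr_introns = length(res$prognosis$model$intron_ids),
    logrank_p = if (is.null(res$prognosis$km)) NA
                else res$prognosis$km$logrank_p)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, manifest = manifest))
}
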