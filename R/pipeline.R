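#' Default pipeline configuration
#'
#' Returns the full nested configuration with the study-scale defaults;
#' any supplied overrides are merged block-wise. The configuration
#' round-trips losslessly through YAML.
#'
#' @param ... named blocks (`simulate`, `preprocess`, `microstates`,
#'   `spectral`, `stats`, `classify`) or scalars (`seed`, `out_dir`)
#'   overriding the defaults.
#' @return a nested list configuration.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    out_dir = NULL,
    simulate = list(n_hc = 54, n_adhd_c = 53, n_adhd_i = 54,
                    n_channels = 91, fs = 250, duration_s = 120,
                    noise_sd = 2, amplitude = 100),
    preprocess = list(band = c(1, 45), fs_target = 250, epoch_s = 2,
                      reject_uV = 100, keep_s = NULL),
    microstates = list(K = 4, n_restarts = 100),
    spectral = list(report_m = list(delta = 9, tbr = 8, gamma = 6)),
    stats = list(alpha = 0.05),
    classify = list(n_folds = 5, cost = 1)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the blocks of [default_config()].
#' @return the merged configuration.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

.required_blocks <- c("simulate", "preprocess", "microstates", "spectral",
                      "stats", "classify")

validate_config <- function(config) {
  missing <- setdiff(.required_blocks, names(config))
  if (length(missing)) {
    stop("configuration is missing required block(s): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(config$seed)) stop("configuration is missing `seed`")
  invisible(config)
}

.stage_log <- function(stage, seed, shape, t0) {
  message(sprintf("[%s] seed=%s shape=%s elapsed=%.1fs", stage,
                  seed, shape, as.numeric(proc.time()[3]) - t0))
}

# One microstate analysis pass over a set of subjects: individual models,
# per-group pooled models, A-D labelling, back-fit, features, statistics.
.microstate_stage <- function(recordings, group_labels, subject_ids, cfg,
                              seed, alpha) {
  K <- cfg$K
  n_restarts <- cfg$n_restarts
  individual <- lapply(seq_along(recordings), function(i) {
    subject_model(recordings[[i]], K = K, n_restarts = n_restarts,
                  seed = seed + i)
  })
  g <- as.factor(group_labels)
  group_models <- lapply(levels(g), function(lev) {
    group_level_model(individual[g == lev], K = K, n_restarts = n_restarts,
                      seed = seed + 10000L)
  })
  names(group_models) <- levels(g)
  reo <- reorient_to_ABCD(group_models)
  labeled <- reo$models
  feats <- microstate_feature_table(
    recordings,
    lapply(as.character(g), function(lev) labeled[[lev]]),
    subject_ids = subject_ids
  )
  fam <- list(duration = paste0("dur_", LETTERS[1:4]),
              occurrence = paste0("occ_", LETTERS[1:4]),
              coverage = paste0("cov_", LETTERS[1:4]),
              transitions = grep("^tp_", names(feats), value = TRUE))
  anova <- lapply(fam, function(cols) {
    anova_interaction(as.matrix(feats[cols]), g, alpha = alpha)
  })
  posthoc <- posthoc_t_tests(feats, g, alpha = alpha, n_comparisons = 24)
  sim <- topography_similarity(individual, reo$mean_model)
  kw <- kruskal_wallis_topography(sim, g, alpha = alpha)
  gev <- vapply(levels(g), function(lev) labeled[[lev]]$gev, numeric(1))
  list(features = feats, individual_models = individual,
       group_models = labeled, mean_model = reo$mean_model,
       anova = anova, posthoc = posthoc, kruskal_wallis = kw,
       group_gev = gev)
}

# ICA + loading tests for one band at the configured component count.
.spectral_stage <- function(pm, group_labels, m, seed, alpha, reference) {
  m <- min(m, nrow(pm) - 1L, ncol(pm))
  ica <- ica_decompose(pm, m, seed = seed)
  ica <- orient_and_zscore(ica, group_labels, reference_group = reference)
  tests <- test_components(ica, group_labels, alpha = alpha)
  list(ica = ica, tests = tests, m = m)
}

.sig_loadings <- function(stage, prefix) {
  sig <- stage$tests$tests$component[stage$tests$tests$significant]
  L <- stage$ica$loadings[, sig, drop = FALSE]
  if (ncol(L)) colnames(L) <- paste0(prefix, "_", sig)
  L
}

#' Run the full two-stage analysis pipeline
#'
#' simulate -> preprocess -> stage-1 microstates (all subjects, HC vs
#' patients) -> spectral ICA -> statistics -> classification, then the
#' stage-2 pass re-clustered on the two patient subtypes only. Writes
#' feature tables, power matrices, reports and a manifest (with content
#' hashes) to `config$out_dir` when set; every artifact is reproducible
#' from the configuration and seed.
#'
#' @param config configuration from [default_config()] or [read_config()].
#' @return list with `stage1`, `stage2`, `spectral`, `classification`,
#'   `meta` and `manifest`.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  t0 <- as.numeric(proc.time()[3])
  seed <- as.integer(config$seed)
  alpha <- config$stats$alpha %||% 0.05

  sim <- config$simulate
  spec <- cohort_spec(n_hc = sim$n_hc, n_adhd_c = sim$n_adhd_c,
                      n_adhd_i = sim$n_adhd_i, n_channels = sim$n_channels,
                      fs = sim$fs, duration_s = sim$duration_s,
                      noise_sd = sim$noise_sd, amplitude = sim$amplitude,
                      seed = seed)
  cohort <- simulate_cohort(spec)
  meta <- cohort$meta
  .stage_log("simulate", seed, sprintf("%dx%dch", nrow(meta), sim$n_channels), t0)

  pp <- config$preprocess
  pcfg <- preprocess_config(band = pp$band, fs_target = pp$fs_target,
                            epoch_s = pp$epoch_s, reject_uV = pp$reject_uV,
                            keep_s = pp$keep_s %||% sim$duration_s)
  recs <- lapply(cohort$recordings, preprocess, cfg = pcfg)
  .stage_log("preprocess", seed, sprintf("%d recs", length(recs)), t0)

  stage1 <- .microstate_stage(recs, meta$group, meta$subject_id,
                              config$microstates, seed + 1L, alpha)
  .stage_log("microstates-stage1", seed + 1L, "HC/ADHD", t0)

  pms <- build_power_matrices(recs, subject_ids = meta$subject_id)
  rep_m <- config$spectral$report_m
  spectral1 <- list(
    delta = .spectral_stage(pms$delta, meta$group, rep_m$delta %||% 9,
                            seed + 2L, alpha, "HC"),
    tbr = .spectral_stage(pms$tbr, meta$group, rep_m$tbr %||% 8,
                          seed + 3L, alpha, "HC")
  )
  .stage_log("spectral-stage1", seed + 2L, "delta+tbr", t0)

  clf_in1 <- assemble_inputs(
    stage1$features,
    cbind(.sig_loadings(spectral1$delta, "delta"),
          .sig_loadings(spectral1$tbr, "tbr")) |>
      (\(L) data.frame(subject_id = meta$subject_id, as.data.frame(L),
                       check.names = FALSE))()
  )
  clf1 <- svm_rfe_cv(clf_in1, meta$group,
                     n_folds = config$classify$n_folds %||% 5,
                     seed = seed + 4L, cost = config$classify$cost %||% 1,
                     positive = "ADHD")
  .stage_log("classify-stage1", seed + 4L, sprintf("%d feats", ncol(clf_in1) - 1), t0)

  sub <- !is.na(meta$subtype)
  stage2 <- .microstate_stage(recs[sub], meta$subtype[sub],
                              meta$subject_id[sub], config$microstates,
                              seed + 5L, alpha)
  spectral2 <- list(
    gamma = .spectral_stage(pms$gamma[sub, , drop = FALSE], meta$subtype[sub],
                            rep_m$gamma %||% 6, seed + 6L, alpha, "ADHD-C")
  )
  clf_in2 <- assemble_inputs(
    stage2$features,
    data.frame(subject_id = meta$subject_id[sub],
               as.data.frame(.sig_loadings(spectral2$gamma, "gamma")),
               check.names = FALSE)
  )
  clf2 <- svm_rfe_cv(clf_in2, meta$subtype[sub],
                     n_folds = config$classify$n_folds %||% 5,
                     seed = seed + 7L, cost = config$classify$cost %||% 1,
                     positive = "ADHD-C")
  .stage_log("stage2", seed + 5L, "ADHD-C/ADHD-I", t0)

  out <- list(stage1 = stage1, stage2 = stage2,
              spectral = list(stage1 = spectral1, stage2 = spectral2),
              classification = list(stage1 = clf1, stage2 = clf2),
              meta = meta, power_matrices = pms, truth = cohort$truth)
  out$manifest <- .write_outputs(out, config)
  out
}

.write_outputs <- function(out, config) {
  manifest <- list(
    package = as.character(utils::packageVersion("microdyn")),
    seed = config$seed,
    n_subjects = nrow(out$meta),
    n_subtype = sum(!is.na(out$meta$subtype)),
    group_counts = as.list(table(out$meta$group)),
    subtype_counts = as.list(table(out$meta$subtype)),
    files = list()
  )
  dir <- config$out_dir
  if (is.null(dir)) return(manifest)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(obj, name) {
    path <- file.path(dir, name)
    if (is.data.frame(obj)) {
      utils::write.csv(obj, path, row.names = FALSE)
    } else {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
    }
    path
  }
  files <- c(
    wr(out$meta, "meta.csv"),
    wr(out$stage1$features, "features_stage1.csv"),
    wr(out$stage2$features, "features_stage2.csv"),
    vapply(names(out$power_matrices), function(bn) {
      wr(data.frame(subject_id = rownames(out$power_matrices[[bn]]),
                    as.data.frame(out$power_matrices[[bn]]),
                    check.names = FALSE),
         sprintf("power_%s.csv", bn))
    }, character(1)),
    wr(.stats_report(out), "report.json")
  )
  manifest$files <- lapply(files, function(f) {
    list(path = basename(f), md5 = unname(tools::md5sum(f)))
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

.stat_to_list <- function(s) {
  s[c("test", "statistic", "df", "p", "correction", "n_comparisons",
      "significant")]
}

.stats_report <- function(out) {
  list(
    stage1 = list(
      group_gev = as.list(out$stage1$group_gev),
      anova_interaction = lapply(out$stage1$anova, .stat_to_list),
      posthoc = out$stage1$posthoc,
      kruskal_wallis = lapply(out$stage1$kruskal_wallis, .stat_to_list),
      ica = lapply(out$spectral$stage1, function(s) {
        list(m = s$m, tests = s$tests$tests,
             selected_channels = s$tests$selected_channels)
      }),
      classification = out$classification$stage1[
        c("accuracy", "sensitivity", "specificity", "selection_counts")]
    ),
    stage2 = list(
      group_gev = as.list(out$stage2$group_gev),
      anova_interaction = lapply(out$stage2$anova, .stat_to_list),
      posthoc = out$stage2$posthoc,
      kruskal_wallis = lapply(out$stage2$kruskal_wallis, .stat_to_list),
      ica = lapply(out$spectral$stage2, function(s) {
        list(m = s$m, tests = s$tests$tests,
             selected_channels = s$tests$selected_channels)
      }),
      classification = out$classification$stage2[
        c("accuracy", "sensitivity", "specificity", "selection_counts")]
    )
  )
}

#' Write a cohort's metadata table as CSV
#'
#' @param meta metadata data.frame from [simulate_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort metadata table
#'
#' @param path CSV with columns subject_id, group, subtype, sex, age,
#'   hand, inatt_score, hyper_score, total_score.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
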