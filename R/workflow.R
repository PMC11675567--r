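# End-to-end study orchestration: synthesize (or ingest) -> extract ->
# group + demographics -> classify -> explain, driven by one TOML-style
# config file, with a digest manifest for reproducibility.

#' Parse a study config file
#'
#' Minimal TOML-style key-value format: `[section]` headers,
#' `key = value` lines, `#` comments. Values are parsed as numbers,
#' logicals, or (comma-separated lists of) strings. The blocks
#' `[synthesis]`, `[features]`, `[classification]` and `[explain]` and a
#' top-level `seed` are required.
#'
#' @param path Path to the config file.
#' @return Nested named list of class `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- parse_config_value(trimws(paste(kv[-1], collapse = "=")))
      if (is.null(section)) cfg[[key]] <- val else cfg[[section]][[key]] <- val
    } else {
      stop("cannot parse config line: ", ln, call. = FALSE)
    }
  }
  validate_study_config(cfg)
}

parse_config_value <- function(v) {
  v <- gsub('^"|"$', "", v)
  if (grepl(",", v)) return(vapply(strsplit(v, ",")[[1]],
                                   function(x) trimws(x), character(1),
                                   USE.NAMES = FALSE))
  if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(toupper(v)))
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}

validate_study_config <- function(cfg) {
  for (block in c("synthesis", "features", "classification", "explain")) {
    if (is.null(cfg[[block]])) {
      stop("config error: missing [", block, "] block", call. = FALSE)
    }
  }
  if (is.null(cfg$seed)) stop("config error: missing global seed",
                              call. = FALSE)
  defaults <- list(
    out_dir = "voicecog_run",
    synthesis = list(mode = "waveform", n_severe = 10, n_mild = 8,
                     n_normal = 12, sample_rate_hz = 16000,
                     vowel_duration_s = 1.2, ddk_syllables = 8,
                     ddk_rate_hz = 5, gap_fraction = 0.4,
                     base_correlation = 0.2, n_features = 184,
                     effect_size = 1.0, n_effect_features = 10),
    features = list(f0_min = 60, f0_max = 400),
    classification = list(families = "linear_logistic", budget = 5,
                          test_fraction = 0.2, n_folds = 5),
    explain = list(background_size = 100, n_permutations = 100,
                   top_k = 20))
  merged <- utils::modifyList(defaults, cfg)
  structure(merged, class = c("study_config", "list"))
}

stage_seed <- function(seed, stage) {
  h <- strtoi(substr(digest::digest(stage, algo = "crc32"), 1, 6), 16L)
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

# group-dependent synthesis parameters for waveform mode: impairment
# raises jitter/shimmer and lowers the harmonics-to-noise ratio.
group_voice_profile <- function(group) {
  switch(as.character(group),
    severe = list(jitter_pct = 2.0, shimmer_pct = 6.0, noise_snr_db = 12),
    mild   = list(jitter_pct = 1.2, shimmer_pct = 4.0, noise_snr_db = 18),
    normal = list(jitter_pct = 0.6, shimmer_pct = 2.5, noise_snr_db = 25))
}

task_params_for <- function(task, profile, syn, subject_f0) {
  base <- voice_params(
    f0_hz = subject_f0, duration_s = syn$vowel_duration_s,
    sample_rate_hz = syn$sample_rate_hz,
    jitter_pct = profile$jitter_pct, shimmer_pct = profile$shimmer_pct,
    noise_snr_db = profile$noise_snr_db,
    formants_hz = switch(task,
      a = c(700, 1200, 2600, 3400), i = c(300, 2300, 3000, 3700),
      u = c(350, 800, 2400, 3300), c(600, 1100, 2500, 3400)),
    formant_bw_hz = c(80, 100, 160, 200))
  if (task %in% ddk_task_ids()) {
    ddk_params(base = base, syllable_rate_hz = syn$ddk_rate_hz,
               n_syllables = syn$ddk_syllables,
               gap_fraction = syn$gap_fraction)
  } else {
    if (task == "a_prolonged") base$duration_s <- base$duration_s * 2
    base
  }
}

run_stage_synth <- function(cfg, paths) {
  syn <- cfg$synthesis
  seed <- stage_seed(cfg$seed, "synth")
  cp <- cohort_params(
    group_sizes = c(severe = syn$n_severe, mild = syn$n_mild,
                    normal = syn$n_normal),
    effect_map = default_effect_map(syn), n_features = syn$n_features,
    base_correlation = syn$base_correlation, seed = seed)
  cohort <- generate_cohort(cp)
  utils::write.csv(cohort$roster, paths$roster, row.names = FALSE)
  if (identical(syn$mode, "waveform")) {
    dir.create(paths$wav_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nrow(cohort$roster))) {
      subj <- cohort$roster$subject_id[i]
      profile <- group_voice_profile(cohort$roster$group[i])
      f0 <- withr_seed(seed + 7L * i, stats::runif(1, 90, 220))
      for (task in task_ids()) {
        p <- task_params_for(task, profile, syn, f0)
        w <- if (inherits(p, "ddk_params")) {
          synthesize_ddk(p, seed = seed + 100L * i + match(task, task_ids()))
        } else {
          synthesize_vowel(p, seed = seed + 100L * i + match(task, task_ids()))
        }
        write_wav(w, file.path(paths$wav_dir,
                               sprintf("%s__%s.wav", subj, task)))
      }
    }
  } else {
    write_feature_csv(cohort$features, paths$features)
  }
  invisible(cohort)
}

# table-mode ground-truth effects: shifts on the first n_effect_features
# indicators for the impaired groups, scaled by effect_size (SD units).
default_effect_map <- function(syn) {
  nm <- indicator_names(syn$n_features)[seq_len(min(syn$n_effect_features,
                                                    syn$n_features))]
  stats::setNames(lapply(nm, function(x) {
    c(severe = syn$effect_size, mild = syn$effect_size / 2)
  }), nm)
}

run_stage_extract <- function(cfg, paths) {
  wavs <- list.files(paths$wav_dir, pattern = "\\.wav$", full.names = TRUE)
  if (!length(wavs)) stop("no WAV files found in ", paths$wav_dir,
                          call. = FALSE)
  recs <- lapply(wavs, function(f) {
    parts <- strsplit(sub("\\.wav$", "", basename(f)), "__")[[1]]
    task_recording(parts[2], read_wav(f), subject_id = parts[1])
  })
  tab <- build_feature_table(recs, f0_min = cfg$features$f0_min,
                             f0_max = cfg$features$f0_max)
  write_feature_csv(tab, paths$features)
  invisible(tab)
}

run_stage_demographics <- function(cfg, paths) {
  roster <- utils::read.csv(paths$roster, stringsAsFactors = FALSE)
  rep <- demographic_report(roster)
  utils::write.csv(rep$omnibus, paths$demographics, row.names = FALSE)
  txt <- utils::capture.output(print(rep))
  writeLines(txt, sub("\\.csv$", ".txt", paths$demographics))
  invisible(rep)
}

run_stage_classify <- function(cfg, paths) {
  roster <- utils::read.csv(paths$roster, stringsAsFactors = FALSE)
  features <- read_feature_csv(paths$features)
  stopifnot(identical(roster$subject_id, features$subject_id))
  X_all <- as.matrix(features[, -1])
  tasks <- make_tasks(roster)
  if (!length(tasks)) {
    stop("no classification task has both classes present", call. = FALSE)
  }
  seed <- stage_seed(cfg$seed, "classify")
  cls <- cfg$classification
  rows <- list(); models <- list()
  for (tk in tasks) {
    X <- X_all[tk$subject_index, , drop = FALSE]
    y <- tk$labels
    sc <- split_config(test_fraction = cls$test_fraction,
                       n_folds = cls$n_folds, seed = seed)
    sp <- stratified_split(y, sc)
    best <- NULL
    for (fam in cls$families) {
      spec <- model_spec(fam, search_budget = cls$budget,
                         seed = seed + nchar(tk$name))
      model <- tune_and_train(X[sp$train, , drop = FALSE], y[sp$train],
                              spec, sc)
      rep <- evaluate_model(model, X[sp$test, , drop = FALSE], y[sp$test],
                            counts = tk$counts)
      rows[[length(rows) + 1L]] <- data.frame(
        task = tk$name, family = fam, pr_auc = rep$pr_auc, auc = rep$auc,
        accuracy = rep$accuracy, f1 = rep$f1, precision = rep$precision,
        recall = rep$recall, baseline_pr_auc = rep$baseline_pr_auc,
        improvement_pct = rep$improvement_pct,
        cv_pr_auc = model$best_cv_pr_auc)
      if (is.null(best) || rep$pr_auc > best$report$pr_auc) {
        best <- list(model = model, report = rep, split = sp, task = tk)
      }
    }
    models[[tk$name]] <- best
  }
  res <- do.call(rbind, rows)
  utils::write.csv(res, paths$classification, row.names = FALSE)
  invisible(list(results = res, best_models = models,
                 features = features, roster = roster))
}

run_stage_explain <- function(cfg, paths, classify_out) {
  ex <- cfg$explain
  seed <- stage_seed(cfg$seed, "explain")
  X_all <- as.matrix(classify_out$features[, -1])
  for (nm in names(classify_out$best_models)) {
    b <- classify_out$best_models[[nm]]
    X <- X_all[b$task$subject_index, , drop = FALSE]
    bg_idx <- b$split$train
    if (length(bg_idx) > ex$background_size) {
      bg_idx <- withr_seed(seed, sample(bg_idx, ex$background_size))
    }
    pp <- b$model$preproc
    bg <- preproc_apply(pp, X[bg_idx, , drop = FALSE])
    test <- preproc_apply(pp, X[b$split$test, , drop = FALSE])
    prob <- shapley_problem(function(m) predict_family(b$model$fit, m), bg)
    expl <- explain_instances(prob, test,
                              n_permutations = ex$n_permutations,
                              seed = seed)
    ranking <- rank_features(expl, top_k = ex$top_k)
    utils::write.csv(ranking,
                     file.path(paths$out_dir,
                               sprintf("shap_ranking_%s.csv", nm)),
                     row.names = FALSE)
    phi <- as.data.frame(expl$phi)
    phi <- cbind(subject_id = classify_out$features$subject_id[
      b$task$subject_index][b$split$test], phi)
    utils::write.csv(phi,
                     file.path(paths$out_dir,
                               sprintf("shap_values_%s.csv", nm)),
                     row.names = FALSE)
  }
  invisible(NULL)
}

study_paths <- function(cfg) {
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  list(out_dir = out,
       wav_dir = file.path(out, "wav"),
       roster = file.path(out, "roster.csv"),
       features = file.path(out, "features.csv"),
       demographics = file.path(out, "demographics.csv"),
       classification = file.path(out, "classification_results.csv"),
       manifest = file.path(out, "manifest.json"))
}

#' Run the full study pipeline
#'
#' Executes synth -> extract -> demographics -> classify -> explain and
#' writes all artifacts plus a manifest (config hash, seed, per-artifact
#' digests, timestamps) under the config's `out_dir`. Re-running with the
#' same config and seed reproduces identical artifact digests.
#'
#' @param config Path to a config file or a parsed `study_config`.
#' @return The manifest, invisibly.
#' @export
run_study <- function(config) {
  cfg <- if (inherits(config, "study_config")) config
         else read_study_config(config)
  paths <- study_paths(cfg)
  stages <- character(0)
  run <- function(name, fun) {
    message("[voicecog] stage: ", name)
    out <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    out
  }
  run("synth", function() run_stage_synth(cfg, paths))
  if (identical(cfg$synthesis$mode, "waveform")) {
    run("extract", function() run_stage_extract(cfg, paths))
  } else {
    stages <- c(stages, "extract")  # table mode wrote features directly
  }
  run("demographics", function() run_stage_demographics(cfg, paths))
  cls_out <- run("classify", function() run_stage_classify(cfg, paths))
  run("explain", function() run_stage_explain(cfg, paths, cls_out))
  artifacts <- list.files(paths$out_dir, pattern = "\\.csv$",
                          full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("voicecog")),
    seed = cfg$seed,
    config_digest = digest::digest(unclass(cfg)),
    stages = stages,
    artifacts = stats::setNames(
      lapply(artifacts, function(f) digest::digest(file = f)),
      basename(artifacts)),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline), `synth`, `extract`,
#' `demographics`, `classify` (each one stage on existing artifacts).
#' Usage: `voicecog <subcommand> --config study.toml`.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly: 0 ok, 1 stage failure,
#'   2 config error.
#' @export
voicecog_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0("usage: voicecog run|synth|extract|demographics|",
                  "classify --config <file>")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  ci <- which(args == "--config")
  if (!length(ci) || ci == length(args)) {
    message("config error: --config <file> is required")
    return(invisible(2L))
  }
  cfg <- tryCatch(read_study_config(args[ci + 1L]), error = function(e) {
    message(conditionMessage(e)); NULL
  })
  if (is.null(cfg)) return(invisible(2L))
  paths <- study_paths(cfg)
  status <- tryCatch({
    switch(cmd,
      run = run_study(cfg),
      synth = run_stage_synth(cfg, paths),
      extract = run_stage_extract(cfg, paths),
      demographics = run_stage_demographics(cfg, paths),
      classify = run_stage_classify(cfg, paths),
      stop("unknown subcommand: ", cmd, call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
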