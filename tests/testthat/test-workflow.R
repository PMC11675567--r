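write_config <- function(path, lines) {
  writeLines(lines, path)
  path
}

table_config_lines <- function(out_dir, seed = 7) c(
  paste0("seed = ", seed),
  paste0('out_dir = "', out_dir, '"'),
  "[synthesis]",
  'mode = "table"',
  "n_severe = 16", "n_mild = 12", "n_normal = 20",
  "effect_size = 1.5", "n_effect_features = 10",
  "[features]",
  "[classification]",
  "families = linear_logistic", "budget = 2",
  "[explain]",
  "background_size = 20", "n_permutations = 8", "top_k = 20")

test_that("config parsing applies defaults and rejects missing blocks", {
  f <- withr::local_tempfile(fileext = ".toml")
  write_config(f, c("seed = 3", "[synthesis]", "[features]",
                    "[classification]", "budget = 9", "[explain]"))
  cfg <- read_study_config(f)
  expect_equal(cfg$seed, 3)
  expect_equal(cfg$classification$budget, 9)
  expect_equal(cfg$classification$test_fraction, 0.2)  # default
  expect_equal(cfg$synthesis$mode, "waveform")         # default

  f2 <- withr::local_tempfile(fileext = ".toml")
  write_config(f2, c("seed = 3", "[synthesis]", "[classification]",
                     "[explain]"))
  expect_error(read_study_config(f2), "\\[features\\]")
  f3 <- withr::local_tempfile(fileext = ".toml")
  write_config(f3, c("[synthesis]", "[features]", "[classification]",
                     "[explain]"))
  expect_error(read_study_config(f3), "seed")
  expect_error(read_study_config("no/such/file.toml"), "not found")
})

test_that("stage seeds derive deterministically from the global seed", {
  expect_equal(voicecog:::stage_seed(7, "synth"),
               voicecog:::stage_seed(7, "synth"))
  expect_false(voicecog:::stage_seed(7, "synth") ==
               voicecog:::stage_seed(7, "classify"))
  expect_false(voicecog:::stage_seed(7, "synth") ==
               voicecog:::stage_seed(8, "synth"))
  expect_true(voicecog:::stage_seed(2^30, "explain") < 2^31)
})

test_that("run_study produces all stage artifacts and a stable manifest", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  f1 <- write_config(withr::local_tempfile(fileext = ".toml"),
                     table_config_lines(file.path(dir1, "out")))
  f2 <- write_config(withr::local_tempfile(fileext = ".toml"),
                     table_config_lines(file.path(dir2, "out")))
  m1 <- suppressMessages(run_study(f1))
  expect_equal(sort(m1$stages),
               sort(c("synth", "extract", "demographics", "classify",
                      "explain")))
  out <- file.path(dir1, "out")
  for (art in c("roster.csv", "features.csv", "demographics.csv",
                "classification_results.csv",
                "shap_ranking_severe_vs_normal.csv", "manifest.json")) {
    expect_true(file.exists(file.path(out, art)), info = art)
  }
  res <- read.csv(file.path(out, "classification_results.csv"))
  expect_true(all(c("pr_auc", "baseline_pr_auc", "improvement_pct")
                  %in% names(res)))
  rk <- read.csv(file.path(out, "shap_ranking_severe_vs_normal.csv"))
  expect_lte(nrow(rk), 20)

  # identical config + seed => identical artifact digests
  m2 <- suppressMessages(run_study(f2))
  expect_identical(m1$artifacts, m2$artifacts)
})

test_that("waveform mode synthesizes, writes WAVs and extracts 184 columns", {
  dir <- withr::local_tempdir()
  f <- write_config(withr::local_tempfile(fileext = ".toml"), c(
    "seed = 5", paste0('out_dir = "', file.path(dir, "out"), '"'),
    "[synthesis]", 'mode = "waveform"',
    "n_severe = 1", "n_mild = 0", "n_normal = 1",
    "sample_rate_hz = 16000", "vowel_duration_s = 0.6",
    "ddk_syllables = 5",
    "[features]", "[classification]", "[explain]"))
  cfg <- read_study_config(f)
  paths <- voicecog:::study_paths(cfg)
  voicecog:::run_stage_synth(cfg, paths)
  wavs <- list.files(paths$wav_dir, pattern = "\\.wav$")
  expect_length(wavs, 16)  # 2 subjects x 8 tasks
  tab <- voicecog:::run_stage_extract(cfg, paths)
  expect_equal(dim(tab), c(2, 185))
  expect_false(anyNA(tab[, paste0("a__", c("jitter_local", "hnr",
                                           "mean_f0"))]))
})

test_that("CLI returns the documented exit codes", {
  expect_equal(voicecog_cli(character(0)), 2L)
  expect_equal(voicecog_cli(c("run")), 2L)
  suppressMessages(
    expect_equal(voicecog_cli(c("run", "--config", "missing.toml")), 2L))

  # stage failure: classify on a single-class roster surfaces as status 1
  dir <- withr::local_tempdir()
  out <- file.path(dir, "out")
  f <- write_config(withr::local_tempfile(fileext = ".toml"), c(
    "seed = 2", paste0('out_dir = "', out, '"'),
    "[synthesis]", 'mode = "table"',
    "n_severe = 0", "n_mild = 0", "n_normal = 8",
    "[features]", "[classification]", "[explain]"))
  cfg <- read_study_config(f)
  paths <- voicecog:::study_paths(cfg)
  voicecog:::run_stage_synth(cfg, paths)
  suppressMessages(suppressWarnings(
    expect_equal(voicecog_cli(c("classify", "--config", f)), 1L)))
})
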