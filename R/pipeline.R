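# End-to-end orchestration: configuration, report assembly, provenance.

# Small deterministic content hash (polynomial rolling hash over the
# serialized config, mod a Mersenne prime); embedded in every output for
# provenance.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                 digits = NA, force = TRUE)))
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

default_run_config <- function() {
  list(
    lexicon = NULL,          # path, or NULL for the packaged toy lexicon
    corpus = NULL,           # path to JSON Lines sessions, or NULL to simulate
    n_sessions = 2000,       # simulated corpus size when corpus is NULL
    out_dir = NULL,          # output directory, or NULL to skip writing
    seed = 1L,
    stratifications = c("gender", "age"),
    fractions = srf_fractions,
    normalize = FALSE,
    presence = FALSE,
    alpha = 0.05,
    p_adjust = "none",
    univariable = FALSE,
    test_fraction = 0.2,
    threshold = 0.5,
    hl_groups = 10,
    explanations = FALSE     # per-chat match explanation report (can be large)
  )
}

#' Run the full analysis pipeline
#'
#' Stages: load (or simulate) the corpus; compile the lexicon; extract
#' features at every configured fraction; fit stratified models; trace
#' temporal trajectories; evaluate held-out classification; assess
#' calibration; assemble the sample-accounting table. Deterministic given
#' `config$seed`. When `config$out_dir` is set, every table is written as TSV
#' with a provenance header (config hash + seed).
#'
#' @param config Named list overriding the defaults: `lexicon` (path or NULL
#'   for the packaged toy lexicon), `corpus` (JSON Lines path or NULL to
#'   simulate `n_sessions` sessions from [default_config()]), `out_dir`,
#'   `seed`, `stratifications`, `fractions`, `normalize`, `presence`,
#'   `alpha`, `p_adjust`, `univariable`, `test_fraction`, `threshold`,
#'   `hl_groups`, `explanations`. A path to a YAML/JSON config file is also
#'   accepted.
#' @return List with `effects` (per stratification), `trajectories`,
#'   `metrics`, `calibration`, `accounting`, `features`, `config` (resolved,
#'   with hash), invisibly written to `out_dir` if set.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) {
      if (!requireNamespace("yaml", quietly = TRUE)) stop("'yaml' package required")
      yaml::read_yaml(config)
    } else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  cfg <- modifyList(default_run_config(), config)
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), "hash")])

  lexicon <- if (is.null(cfg$lexicon)) toy_lexicon() else
    compile_lexicon(load_lexicon(cfg$lexicon))

  ground_truth <- NULL
  if (is.null(cfg$corpus)) {
    gen <- generate_corpus(default_config(lexicon, n_sessions = cfg$n_sessions),
                           lexicon, seed = cfg$seed)
    sessions <- gen$sessions
    ground_truth <- gen$ground_truth
  } else {
    sessions <- read_sessions(cfg$corpus)
  }

  feats <- lapply(cfg$fractions, function(f) {
    featurize_sessions(sessions, lexicon, fraction = f,
                       normalize = cfg$normalize, presence = cfg$presence)
  })
  names(feats) <- format(cfg$fractions)
  i_full <- which(abs(cfg$fractions - 1) < 1e-9)
  full <- if (length(i_full)) feats[[i_full[1]]] else
    featurize_sessions(sessions, lexicon, normalize = cfg$normalize,
                       presence = cfg$presence)

  effects <- list(); accounting <- list()
  for (st in cfg$stratifications) {
    res <- fit_by_stratum(full, st, alpha = cfg$alpha, p_adjust = cfg$p_adjust)
    eff <- if (cfg$univariable) {
      do.call(rbind, lapply(names(res$fits), function(lev) {
        sl <- strata_levels(st)
        fit_univariable(design_for_stratum(full, sl$var, lev),
                        alpha = cfg$alpha, p_adjust = cfg$p_adjust)
      }))
    } else res$effects
    eff$stratification <- st
    acc <- res$accounting
    acc$stratification <- st
    effects[[st]] <- eff
    accounting[[st]] <- acc
  }

  trajectories <- temporal_trajectories(feats,
                                        stratification = cfg$stratifications[1],
                                        alpha = cfg$alpha)

  design_all <- build_design(full)
  metrics <- evaluate_holdout(design_all, test_fraction = cfg$test_fraction,
                              seed = cfg$seed, threshold = cfg$threshold)
  fit_all <- fit_logistic(design_all)
  calibration <- hosmer_lemeshow(fit_all, design_all, groups = cfg$hl_groups)

  out <- list(effects = do.call(rbind, effects),
              trajectories = trajectories,
              metrics = metrics[c("precision", "recall", "f1", "f2", "roc_auc",
                                  "threshold", "n_train", "n_test")],
              calibration = calibration,
              accounting = do.call(rbind, accounting),
              features = full,
              ground_truth = ground_truth,
              config = cfg)

  if (!is.null(cfg$out_dir)) {
    write_report(out, sessions, lexicon, cfg)
  }
  out
}

provenance_line <- function(cfg) {
  sprintf("# srflex config_hash=%s seed=%s", cfg$hash, cfg$seed)
}

write_tsv_report <- function(df, path, cfg) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_line(cfg), con)
  utils::write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_report <- function(out, sessions, lexicon, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  write_tsv_report(out$effects, p("effects.tsv"), cfg)
  write_tsv_report(out$trajectories, p("trajectories.tsv"), cfg)
  write_tsv_report(out$accounting, p("sample_accounting.tsv"), cfg)
  write_tsv_report(tibble::tibble(metric = names(unlist(out$metrics)),
                                  value = unlist(out$metrics)),
                   p("metrics.tsv"), cfg)
  write_tsv_report(tibble::tibble(chi2 = out$calibration$chi2,
                                  df = out$calibration$df,
                                  p_value = out$calibration$p_value),
                   p("calibration.tsv"), cfg)
  if (isTRUE(cfg$explanations)) {
    expl <- do.call(rbind, lapply(sessions, function(s) {
      df <- explain_matches(lexicon, helpseeker_text(s))
      if (nrow(df)) cbind(session_id = s$session_id, df) else NULL
    }))
    if (!is.null(expl)) write_tsv_report(expl, p("explanations.tsv"), cfg)
  }
  jsonlite::write_json(cfg, p("run_config.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(cfg$out_dir)
}
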