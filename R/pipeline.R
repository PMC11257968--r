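#' Load and validate a run configuration
#'
#' YAML with blocks `generator`, `splits`, `model`, `evaluation`,
#' `fairness`, `explain`, plus `seed` and `out_dir`. Missing blocks fall
#' back to package defaults; the generator and split blocks are validated
#' before any work starts. The global seed fans out to per-stage seeds via
#' [derive_seed()].
#'
#' @param path YAML file path, or a list already parsed.
#' @return list of class `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  gen <- do.call(generator_config, raw$generator %||% list())
  sp_args <- raw$splits %||% list()
  if (!is.null(sp_args$fractions)) {
    sp_args$fractions <- unlist(sp_args$fractions)
  }
  spec <- do.call(split_spec, sp_args)
  model <- raw$model %||% list()
  rnn <- do.call(recurrent_spec, model$rnn %||% list())
  cfg <- list(
    generator = gen,
    splits = spec,
    rnn = rnn,
    comparators = model$comparators %||% character(),
    evaluation = utils::modifyList(list(bootstrap = 1000L, bins = 10L),
                                   raw$evaluation %||% list()),
    fairness = utils::modifyList(list(permutations = 1000L),
                                 raw$fairness %||% list()),
    explain = utils::modifyList(list(mode = "sampled", fraction = 0.065,
                                     n_permutations = 30L),
                                raw$explain %||% list()),
    seed = as.integer(raw$seed %||% 1L),
    out_dir = raw$out_dir %||% "mortclock_run"
  )
  class(cfg) <- "run_config"
  cfg
}

#' @keywords internal
stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full experiment from one configuration
#'
#' simulate -> cohort -> encode -> train -> evaluate -> fairness -> explain,
#' every stage consuming and producing files under `out_dir` so stages are
#' individually re-runnable, with a manifest recording seeds, package
#' version and file hashes. Deterministic stages reproduce their hashes on
#' rerun.
#'
#' @param config a `run_config` (or path to YAML).
#' @param stages subset of stages to run (default: all, in order).
#' @param verbose log stage progress.
#' @return the manifest list, invisibly.
#' @export
run_experiment <- function(config,
                           stages = c("simulate", "cohort", "encode",
                                      "train", "evaluate", "fairness",
                                      "explain"),
                           verbose = TRUE) {
  if (is.character(config) || !inherits(config, "run_config")) {
    config <- load_run_config(config)
  }
  out <- config$out_dir
  dirs <- file.path(out, c("registry", "cohort", "models", "reports"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  seed_of <- function(stage) derive_seed(config$seed, stage)
  say <- function(...) if (verbose) stage_log(...)
  t0 <- Sys.time()

  run_stage <- function(name, fn) {
    if (!(name %in% stages)) return(invisible(NULL))
    say(name, "start")
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s (partial outputs kept under %s)",
                   name, conditionMessage(e), out), call. = FALSE)
    })
    say(name, "done")
  }

  run_stage("simulate", function() {
    gen <- config$generator
    reg <- generate_population(gen, seed = seed_of("simulate_pop"))
    reg <- simulate_events(reg, gen, end_year = 2020L,
                           seed = seed_of("simulate_events"))
    reg <- simulate_mortality(reg, gen, horizon = 2018:2020,
                              seed = seed_of("simulate_mortality"))
    dis <- disadvantage_flags(reg$persons)
    reg <- apply_observation_bias(reg, gen, dis$any,
                                  seed = seed_of("simulate_bias"))
    write_registry(reg, file.path(out, "registry"))
  })

  reg <- NULL
  get_reg <- function() {
    if (is.null(reg)) reg <<- read_registry(file.path(out, "registry"))
    reg
  }

  run_stage("cohort", function() {
    bc <- build_cohort(get_reg(), config$splits, seed = seed_of("cohort"))
    fwrite(bc$cohort, file.path(out, "cohort", "cohort.csv"))
    jsonlite::write_json(bc$tallies,
                         file.path(out, "cohort", "exclusions.json"),
                         auto_unbox = TRUE)
  })

  enc_of <- function(split) {
    readRDS(file.path(out, "cohort", paste0("encoded_", split, ".rds")))
  }

  run_stage("encode", function() {
    r <- get_reg()
    co <- fread(file.path(out, "cohort", "cohort.csv"),
                colClasses = list(character = "person_id"))
    tr <- co[split == "train"]
    ivs <- config$splits$splits
    stats <- fit_preprocessor(r, tr$person_id, ivs$train$feature_cutoff,
                              ivs$train$interval_start)
    saveRDS(stats, file.path(out, "cohort", "preprocessor.rds"))
    vocab <- data.table(code = names(stats$code_index),
                        index = unname(stats$code_index),
                        prevalence = unname(stats$code_prevalence))
    fwrite(vocab, file.path(out, "cohort", "codes.tsv"), sep = "\t")
    for (s in c("train", "valid", "test")) {
      enc <- encode_cohort(r, co[split == s], stats,
                           ivs[[s]]$feature_cutoff, ivs[[s]]$interval_start,
                           seed = seed_of("encode"))
      saveRDS(enc, file.path(out, "cohort", paste0("encoded_", s, ".rds")))
    }
  })

  run_stage("train", function() {
    r <- get_reg()
    tr <- enc_of("train"); va <- enc_of("valid")
    rnn <- train_recurrent(tr, va, config$rnn, seed = seed_of("train_rnn"))
    saveRDS(rnn, file.path(out, "models", "rnn.rds"))
    fwrite(as.data.table(rnn$log),
           file.path(out, "models", "training_log.tsv"), sep = "\t")
    iv <- config$splits$splits$train$interval_start
    ptr <- r$persons[match(tr$person_id, person_id)]
    base <- train_baseline(age_years(ptr$birth_date, iv), ptr$sex, tr$label)
    saveRDS(base, file.path(out, "models", "baseline.rds"))
    for (cmp in config$comparators) {
      stats <- readRDS(file.path(out, "cohort", "preprocessor.rds"))
      X <- binarize(r, tr$person_id, stats,
                    config$splits$splits$train$feature_cutoff, iv)
      m <- train_comparator(cmp, X, tr$label,
                            seed = seed_of(paste0("train_", cmp)))
      saveRDS(m, file.path(out, "models", paste0(cmp, ".rds")))
    }
  })

  make_pred <- function() {
    r <- get_reg()
    te <- enc_of("test")
    rnn <- readRDS(file.path(out, "models", "rnn.rds"))
    iv <- config$splits$splits$test$interval_start
    pte <- r$persons[match(te$person_id, person_id)]
    fl <- disadvantage_flags(r$persons)
    fl <- fl[match(te$person_id, person_id)]
    prediction_set(
      te$person_id, te$label, predict(rnn, te), te$event_week,
      attributes = data.table(
        age = age_years(pte$birth_date, iv), sex = pte$sex,
        region = pte$region, pension = pte$pension_level,
        unmarried = fl$unmarried, immigrant = fl$immigrant,
        mental_health_dx = fl$mental_health_dx))
  }

  run_stage("evaluate", function() {
    pred <- make_pred()
    fwrite(pred, file.path(out, "reports", "pred_test.csv"))
    rep <- evaluate_predictions(pred, B = config$evaluation$bootstrap,
                                n_bins = config$evaluation$bins,
                                seed = seed_of("evaluate"))
    jsonlite::write_json(
      list(n = rep$n, n_cases = rep$n_cases, auc = rep$auc,
           auc_ci = as.numeric(rep$auc_ci), auprc = rep$auprc,
           brier = rep$brier, c_index = rep$c_index),
      file.path(out, "reports", "evaluation.json"), auto_unbox = TRUE,
      digits = NA)
    fwrite(rep$calibration, file.path(out, "reports", "calibration.tsv"),
           sep = "\t")
    fwrite(rep$td_auc, file.path(out, "reports", "td_auc.tsv"), sep = "\t")
    fwrite(rep$km, file.path(out, "reports", "km.tsv"), sep = "\t")
  })

  run_stage("fairness", function() {
    pred <- make_pred()
    rep <- disadvantage_report(pred, B = config$fairness$permutations,
                               seed = seed_of("fairness"))
    fwrite(rep$attributes, file.path(out, "reports", "fairness_attributes.tsv"),
           sep = "\t")
    fwrite(rep$by_count, file.path(out, "reports", "fairness_by_count.tsv"),
           sep = "\t")
    fwrite(rep$intersections,
           file.path(out, "reports", "fairness_intersections.tsv"),
           sep = "\t")
  })

  run_stage("explain", function() {
    te <- enc_of("test")
    stats <- readRDS(file.path(out, "cohort", "preprocessor.rds"))
    rnn <- readRDS(file.path(out, "models", "rnn.rds"))
    n <- length(te$person_id)
    k <- max(1L, round(config$explain$fraction * n))
    idx <- with_seed(seed_of("explain"), sample.int(n, k))
    r <- get_reg()
    by <- as.integer(format(
      r$persons[match(te$person_id[idx], person_id), birth_date], "%Y"))
    sets <- lapply(idx, function(i) {
      p <- as_shap_person(te, i)
      np <- length(unique(unlist(p$rows)))
      if (np == 0) return(NULL)
      if (config$explain$mode == "exact" && np <= 12) {
        exact_shapley(rnn, p, stats)
      } else {
        sampled_shapley(rnn, p, config$explain$n_permutations,
                        seed = seed_of("explain_mc"), stats = stats)
      }
    })
    keep <- !vapply(sets, is.null, logical(1))
    sets <- sets[keep]
    agg_cat <- aggregate_attributions(sets, "category")
    agg_yr <- aggregate_attributions(
      sets, "years_before_index", birth_years = by[keep],
      index_year = as.integer(format(
        config$splits$splits$test$interval_start, "%Y")))
    agg_prev <- aggregate_attributions(sets, "prevalence_bin")
    fwrite(agg_cat, file.path(out, "reports", "shapley_category.tsv"),
           sep = "\t")
    fwrite(agg_yr, file.path(out, "reports", "shapley_years.tsv"),
           sep = "\t")
    fwrite(agg_prev, file.path(out, "reports", "shapley_prevalence.tsv"),
           sep = "\t")
  })

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest[.]json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("mortclock")),
    global_seed = config$seed,
    stage_seeds = setNames(lapply(stages, seed_of), stages),
    wall_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    hashes = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
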