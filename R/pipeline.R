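#' Run the full split / train / stats / predict workflow
#'
#' Drives the whole modelling pipeline from one configuration (a YAML/JSON
#' file or an equivalent list) and writes five artifacts into `outDir`:
#' `split.csv` (record-to-subset assignment), `model.json` (the serialized
#' model), `stats.tsv` (per-subset criteria table), `predictions.csv`
#' (predicted values with an `inDomain` column; out-of-domain molecules are
#' flagged but still predicted — the domain is advisory), and `run.log`
#' (configuration echo, seeds and config hash).
#'
#' Recognized configuration fields: `data` (dataset path) *or* `synth`
#' (list of [syntheticDataset()] arguments); `task`; `seed`; `epochs`;
#' `threshold`; `delta`; `target` (list: `variant`, `f1`, `f2`, `f3`);
#' `split` (list: either `file`, or `fractions` + `seed`, or `lasvegas` =
#' list(`nTests`, `probeEpochs`)); `attr` (list of [attrConfig()]
#' arguments); `outDir`.
#'
#' @param config list or path to a YAML/JSON configuration file.
#' @return Invisibly, a list with the fitted model, the split, the stats
#'   table and the artifact paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- config
  out_dir <- cfg$outDir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  task <- cfg$task %||% "regression"
  seed <- as.integer(cfg$seed %||% 1L)
  epochs <- as.integer(cfg$epochs %||% 30L)
  threshold <- as.integer(cfg$threshold %||% 1L)
  delta <- cfg$delta %||% 0.1
  attr_cfg <- do.call(attrConfig, as.list(cfg$attr %||% list()))
  tgt_args <- as.list(cfg$target %||% list())
  target <- do.call(targetConfig, tgt_args)

  dataset <- if (!is.null(cfg$data)) {
    readDataset(cfg$data, task = task,
                dropDuplicates = isTRUE(cfg$dropDuplicates))
  } else if (!is.null(cfg$synth)) {
    args <- as.list(cfg$synth)
    args$task <- task
    if (is.null(args$seed)) args$seed <- seed
    do.call(syntheticDataset, args)
  } else {
    stop_typed("config_error", "config needs 'data' or 'synth'")
  }

  scfg <- cfg$split %||% list()
  lv_trace <- NULL
  split <- if (!is.null(scfg$file)) {
    readSplit(scfg$file)[compoundIds(dataset)]
  } else if (!is.null(scfg$lasvegas)) {
    lv <- lasVegas(dataset,
                   nTests = as.integer(scfg$lasvegas$nTests %||% 10L),
                   probeEpochs =
                     as.integer(scfg$lasvegas$probeEpochs %||% 5L),
                   target = target, threshold = threshold,
                   seed = as.integer(scfg$seed %||% seed),
                   attr = attr_cfg)
    lv_trace <- lv$trace
    lv$split
  } else {
    randomSplit(compoundIds(dataset),
                fractions = as.numeric(scfg$fractions %||% rep(0.25, 4)),
                seed = as.integer(scfg$seed %||% seed))
  }
  splitLabels(dataset) <- split

  run <- mcOptimize(dataset, target = target, epochs = epochs,
                    threshold = threshold, seed = seed, attr = attr_cfg,
                    delta = delta)

  bags <- extractAttributes(smilesStrings(dataset), attr_cfg)
  defects <- defectTable(bags, splitLabels(dataset), threshold)
  pred <- predict(run$model, dataset)

  paths <- list(
    split = file.path(out_dir, "split.csv"),
    model = file.path(out_dir, "model.json"),
    stats = file.path(out_dir, "stats.tsv"),
    predictions = file.path(out_dir, "predictions.csv"),
    log = file.path(out_dir, "run.log")
  )
  sp <- structure(splitLabels(dataset), names = compoundIds(dataset))
  writeSplit(sp, paths$split)
  writeModel(run$model, paths$model)
  stats <- subsetStats(dataset, run$model, attr_cfg)
  writeStatsReport(stats, paths$stats)
  pred_df <- data.frame(
    id = compoundIds(dataset),
    smiles = smilesStrings(dataset),
    endpoint = endpoints(dataset),
    predicted = pred,
    inDomain = defects$inDomain,
    stringsAsFactors = FALSE)
  if (task == "classification") {
    pred_df$class <- as.integer(pred >= 0.5)
  }
  utils::write.csv(pred_df, paths$predictions, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(lv_trace)) {
    paths$lasvegas <- file.path(out_dir, "lasvegas.tsv")
    utils::write.table(lv_trace, paths$lasvegas, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  hash <- config_hash(cfg)
  writeLines(c(
    paste("cwqsar pipeline", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("config_hash:", hash),
    paste("seed:", seed),
    paste("task:", task),
    paste("target:", target$variant,
          sprintf("(f1=%g f2=%g f3=%g)", target$f1, target$f2, target$f3)),
    paste("epochs:", epochs, " threshold:", threshold, " delta:", delta),
    paste("n:", length(dataset)),
    "config:",
    utils::capture.output(utils::str(cfg))
  ), paths$log)

  invisible(list(model = run$model, trace = run$trace, split = sp,
                 stats = stats, defects = defects, paths = paths,
                 configHash = hash))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
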