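# Pipeline orchestration: synth -> fit -> damage -> simulate, with a run
# manifest.  The exported functions are the interface; a thin Rscript
# wrapper lives under inst/scripts/run_pipeline.R.

#' Read and validate a pipeline run configuration
#'
#' The configuration is YAML with (all optional) keys: \code{scenario}
#' (preset name: vacuum/N2/H2O), \code{seed}, \code{out_dir}, \code{rsf}
#' (path to a sensitivity-factor TSV), \code{regions}, \code{model_files}
#' (named map region -> RegionModel YAML), \code{transport} (\code{n},
#' \code{conditions}), \code{snr}, \code{verbosity}.  Every referenced
#' file must exist at validation time; validation happens before any
#' compute.
#'
#' @param path YAML file path.
#' @return validated config list for \code{\link{runPipeline}}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validateRunConfig(yaml::read_yaml(path))
}

#' @rdname readRunConfig
#' @param config a (possibly partial) config list.
#' @export
validateRunConfig <- function(config = list()) {
  defaults <- list(scenario = "H2O", seed = 1L, out_dir = "xpsdamage-run",
                   rsf = NULL, regions = c("C1s", "N1s", "O1s", "P2p"),
                   model_files = NULL, snr = 100,
                   transport = list(n = 1e5,
                                    conditions = c("vacuum", "N2", "H2O")),
                   verbosity = 1L)
  cfg <- utils::modifyList(defaults, config)
  if (is.character(cfg$scenario) &&
      !(cfg$scenario %in% c("vacuum", "N2", "H2O")))
    stop("validation error: unknown scenario preset: ", cfg$scenario)
  if (!is.null(cfg$rsf) && !file.exists(cfg$rsf))
    stop("validation error: rsf file not found: ", cfg$rsf)
  for (mf in cfg$model_files %||% list())
    if (!file.exists(mf))
      stop("validation error: model file not found: ", mf)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    stop("validation error: seed must be a single number")
  if (!is.numeric(cfg$transport$n) || cfg$transport$n < 1)
    stop("validation error: transport n must be >= 1")
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: \emph{synth} (generate the scenario's
#' spectrum series and write it out), \emph{fit} (deconvolute every region
#' at every timepoint, warm-started along the time axis), \emph{damage}
#' (normalized series, damage indices, report files) and \emph{simulate}
#' (transport comparison across atmospheres).  A failing stage aborts with
#' the stage name; outputs of completed stages are preserved.  Rerunning
#' with an identical config reproduces identical analysis outputs.
#'
#' @param config config list (see \code{\link{validateRunConfig}}, applied
#'   automatically).
#' @return invisibly, a list with the manifest, the damage report and the
#'   transport comparison.
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateRunConfig(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log1 <- function(...) if (cfg$verbosity > 0)
    message(sprintf("[xpsdamage] %s", sprintf(...)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  sc <- stage("synth", {
    if (is(cfg$scenario, "DamageScenario")) cfg$scenario else
      presetScenarios(snr = cfg$snr)[[cfg$scenario]]
  })
  gen <- stage("synth", generateSeries(sc, seed = cfg$seed))
  specDir <- file.path(cfg$out_dir, "spectra")
  dir.create(specDir, showWarnings = FALSE)
  stage("synth", {
    for (i in seq_len(length(gen$series))) {
      s <- gen$series[[i]]
      writeSpectrum(s, file.path(specDir,
        sprintf("%s_t%06d.tsv", s@region, round(s@timepoint))),
        overwrite = TRUE)
    }
    jsonlite::write_json(
      list(scenario = gen$truth@scenario, seed = gen$truth@seed,
           scale = gen$truth@scale, areas = gen$truth@areas),
      file.path(specDir, "truth_record.json"),
      auto_unbox = TRUE, digits = NA)
  })
  log1("synth: %d spectra from scenario '%s'", length(gen$series), sc@name)

  models <- sc@regionModels
  for (r in names(cfg$model_files %||% list()))
    models[[r]] <- readRegionModel(cfg$model_files[[r]])
  fits <- stage("fit", {
    out <- list()
    for (r in intersect(cfg$regions, names(models)))
      out <- c(out, fitRegionSeries(gen$series, models[[r]]))
    out
  })
  log1("fit: %d region fits, %d converged", length(fits),
       sum(vapply(fits, converged, logical(1))))

  rsf <- if (is.null(cfg$rsf)) defaultRsf() else readRsf(cfg$rsf)
  rep <- stage("damage", {
    series <- normalizeSeries(fits)
    regs <- vapply(fits, .fitRegionOf, character(1))
    tps <- vapply(fits, .fitTimeOf, numeric(1))
    o1s <- fits[regs == "O1s" & tps == min(tps)]
    p2p <- fits[regs == "P2p" & tps == min(tps)]
    report <- damageReport(series,
      o1sFit = if (length(o1s)) o1s[[1]] else NULL,
      p2pFit = if (length(p2p)) p2p[[1]] else NULL,
      rsf = rsf, condition = c(sc@condition, list(scenario = sc@name)))
    writeReport(series, report, cfg$out_dir, overwrite = TRUE)
    report
  })
  log1("damage: strand-break %.3f, base-damage %.3f",
       rep@strandBreak[1], rep@baseDamage[1])

  trans <- stage("simulate", {
    geoms <- lapply(setNames(nm = cfg$transport$conditions), defaultGeometry)
    cmp <- compareAtmospheres(geoms, n = cfg$transport$n, seed = cfg$seed)
    jsonlite::write_json(
      list(maxRelDiff = as.list(cmp$maxRelDiff),
           tallies = lapply(cmp$results, function(tr) list(
             meanDeposit = tr@meanDeposit, meanDepositSE = tr@meanDepositSE,
             ionizationFraction = tr@ionizationFraction,
             thermalizedElectrons = tr@thermalizedElectrons))),
      file.path(cfg$out_dir, "transport.json"), auto_unbox = TRUE,
      digits = NA)
    cmp
  })
  log1("simulate: max atmosphere contrast of mean deposit %.3g%%",
       100 * trans$maxRelDiff[["meanDeposit"]])

  manifest <- list(
    package = as.character(utils::packageVersion("xpsdamage")),
    r_version = R.version.string,
    seed = cfg$seed,
    scenario = sc@name,
    config = cfg[setdiff(names(cfg), "scenario")],
    input_digests = {
      ins <- as.character(unlist(c(cfg$rsf, cfg$model_files)))
      ins <- ins[file.exists(ins)]
      if (length(ins)) as.list(tools::md5sum(ins)) else list()
    },
    outputs = list.files(cfg$out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(manifest = manifest, report = rep, transport = trans))
}
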