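## End-to-end orchestration: simulate -> covariates -> fit -> vp ->
## scenarios -> diversity -> report, with per-stage seeds, cached stage
## state and a run manifest. The exported functions are the package's
## command surface; each stage is also callable on its own through the
## module functions it wraps.

.pipelineStages <- c("simulate", "covariates", "fit", "vp", "scenarios",
                     "diversity", "report")

#' Build a validated pipeline configuration
#'
#' Presets fix the study dimensions and MCMC effort: `demo` is a small
#' configuration that runs end-to-end in minutes (8 species, 40 sites,
#' 8 years, 150 grid cells, 2 x 400 iterations); `full` is the package's
#' reference desk-scale study (15 species, 80 sites, 12 years, 500 grid
#' cells, 2 x 2000 iterations). Every stochastic stage has its own seed
#' derived from `seed`. The configuration round-trips through YAML
#' unchanged.
#'
#' @param preset `"demo"` or `"full"`.
#' @param seed master seed.
#' @param outdir output directory.
#' @param overrides named list merged over the preset (nested lists
#'   merged shallowly).
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(preset = c("demo", "full"), seed = 1,
                           outdir = file.path(tempdir(), "jsdmVP-run"),
                           overrides = list()) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    seed = as.integer(seed),
    outdir = outdir,
    study = if (preset == "demo")
      list(nSpecies = 8, nSites = 40, nYears = 8, nGridCells = 150)
    else list(nSpecies = 15, nSites = 80, nYears = 12, nGridCells = 500),
    prevalenceThreshold = 0.10,
    mcmc = if (preset == "demo")
      list(chains = 2, iterations = 400, burnin = 0.5, thin = 2)
    else list(chains = 2, iterations = 2000, burnin = 0.5, thin = 2),
    nFactors = c(site = 2, year = 1, zone = 1),
    kmeansK = 4,
    scenarioBaselineYears = 5,
    diversityDraws = 100
  )
  cfg <- modifyList(base, overrides)
  cfg$seeds <- list(generator = cfg$seed, sampler = cfg$seed + 10L,
                    kmeans = cfg$seed + 20L, split = cfg$seed + 30L)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipelineConfig()] list.
#' @param path YAML path.
#' @return `readPipelineConfig` returns the configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  cfg <- unclass(config)
  cfg$nFactors <- as.list(cfg$nFactors)  # keep level names through YAML
  yaml::write_yaml(cfg, path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$nFactors <- unlist(cfg$nFactors)
  class(cfg) <- "pipelineConfig"
  cfg
}

.stateFile <- function(outdir, stage) file.path(outdir, "state",
                                                paste0(stage, ".rds"))

#' Run the full analysis pipeline
#'
#' Executes the stages in order; a stage whose cached state exists is
#' skipped unless an earlier stage was recomputed in this call, so
#' deleting one stage's outputs recomputes that stage and everything
#' after it. All CSV outputs are deterministic given the configuration
#' seeds. A manifest (`manifest.yaml`) records the configuration, its
#' content hash, per-stage timings and output file hashes.
#'
#' @param config a [pipelineConfig()] list.
#' @param stages subset of stages to consider (default all, in order).
#' @return invisibly, the output directory.
#' @export
runPipeline <- function(config, stages = .pipelineStages) {
  stopifnot(inherits(config, "pipelineConfig"))
  stages <- match.arg(stages, .pipelineStages, several.ok = TRUE)
  outdir <- config$outdir
  dir.create(file.path(outdir, "state"), recursive = TRUE,
             showWarnings = FALSE)
  timings <- list()
  dirty <- FALSE
  state <- list()
  for (stage in .pipelineStages) {
    sf <- .stateFile(outdir, stage)
    if (!stage %in% stages && !dirty && file.exists(sf)) {
      state[[stage]] <- readRDS(sf)
      next
    }
    if (!dirty && file.exists(sf) && !identical(
      readRDS(sf)$configHash, .contentHash(unclass(config)))) {
      dirty <- TRUE  # config changed: recompute from here on
    }
    if (!dirty && file.exists(sf)) {
      state[[stage]] <- readRDS(sf)
      next
    }
    t0 <- proc.time()[["elapsed"]]
    state[[stage]] <- tryCatch(
      .runStage(stage, config, state, outdir),
      error = function(e) stop("pipeline stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    state[[stage]]$configHash <- .contentHash(unclass(config))
    saveRDS(state[[stage]], sf)
    timings[[stage]] <- round(proc.time()[["elapsed"]] - t0, 2)
    dirty <- TRUE
  }
  manifest <- list(
    configHash = .contentHash(unclass(config)),
    config = unclass(config),
    stageTimings = timings,
    rVersion = as.character(getRversion()),
    outputs = local({
      files <- sort(list.files(outdir, pattern = "\\.csv$",
                               recursive = TRUE, full.names = TRUE))
      setNames(lapply(files, .fileHash),
               sub(paste0("^", outdir, "/?"), "", files))
    }))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}

.runStage <- function(stage, config, state, outdir) {
  switch(stage,
    simulate = {
      st <- config$study
      study <- simulateStudy(config$seeds$generator,
                             nSpecies = st$nSpecies, nSites = st$nSites,
                             nYears = st$nYears,
                             nGridCells = st$nGridCells)
      writeCommunityCSV(study@community,
                        file.path(outdir, "community.csv"))
      write.csv(study@traits, file.path(outdir, "traits.csv"),
                row.names = FALSE)
      list(study = study)
    },
    covariates = {
      study <- state$simulate$study
      write.csv(study@covariates, file.path(outdir, "covariates.csv"),
                row.names = FALSE)
      write.csv(study@gridCovariates,
                file.path(outdir, "grid_covariates.csv"),
                row.names = FALSE)
      list(done = TRUE)
    },
    fit = {
      study <- state$simulate$study
      community <- prevalenceFilter(study@community,
                                    config$prevalenceThreshold)
      traits <- study@traits[study@traits$species %in%
                               rownames(community), ]
      design <- buildDesignMatrix(study@covariates)
      spec <- hurdleModelSpec(nFactors = config$nFactors,
                              chains = config$mcmc$chains,
                              iterations = config$mcmc$iterations,
                              burnin = config$mcmc$burnin,
                              thin = config$mcmc$thin,
                              seed = config$seeds$sampler)
      pa <- fitPA(community, design, traits, spec)
      ab <- fitAB(community, design, traits, spec)
      pred <- predictHurdle(pa, ab, design,
                            units = as.data.frame(colData(community)))
      metrics <- evaluateHurdle(pred, community)
      write.csv(metrics$perSpecies, file.path(outdir, "fit_metrics.csv"),
                row.names = FALSE)
      list(community = community, traits = traits, design = design,
           pa = pa, ab = ab, metrics = metrics)
    },
    vp = {
      study <- state$simulate$study
      fit <- state$fit
      gridDesign <- buildDesignMatrix(study@gridCovariates,
                                      stats = fit$design@stats)
      vpPA <- variancePartition(fit$pa, gridDesign)
      vpAB <- variancePartition(fit$ab, gridDesign)
      writeVPResult(vpPA, summaryPath = file.path(outdir,
                                                  "vp_pa_summary.csv"))
      writeVPResult(vpAB, summaryPath = file.path(outdir,
                                                  "vp_ab_summary.csv"))
      compCols <- grep("^comp_", names(study@gridCovariates), value = TRUE)
      comp <- aggregate(study@gridCovariates[compCols],
                        by = list(cell = study@gridCovariates$cell), mean)
      km <- kmeansProfiles(as.matrix(comp[compCols]), k = config$kmeansK,
                           seed = config$seeds$kmeans)
      cellProfile <- setNames(km$labels, comp$cell)
      ctx <- conditionalVPEnvironmental(
        fit$pa, gridDesign,
        cellProfile[as.character(study@gridCovariates$cell)])
      hostG <- setNames(fit$traits$host_group, fit$traits$species)
      fun <- conditionalVPFunctional(vpPA, hostG)
      ddc <- dominantDriverCounts(vpPA)
      write.csv(data.frame(cell = comp$cell, profile = km$labels),
                file.path(outdir, "habitat_profiles.csv"),
                row.names = FALSE)
      write.csv(data.frame(statistic = c("median", "q2.5", "q97.5"),
                           habitat_dominant_species =
                             c(ddc$median, ddc$ci[1], ddc$ci[2])),
                file.path(outdir, "dominant_driver.csv"),
                row.names = FALSE)
      list(gridDesign = gridDesign, vpPA = vpPA, vpAB = vpAB,
           profiles = cellProfile, contextVP = ctx, functionalVP = fun,
           dominant = ddc)
    },
    scenarios = {
      study <- state$simulate$study
      base <- config$scenarioBaselineYears
      scen <- list(
        full = buildScenario(study@gridCovariates, "full", base),
        climate_only = buildScenario(study@gridCovariates,
                                     "climate_only", base),
        habitat_only = buildScenario(study@gridCovariates,
                                     "habitat_only", base))
      list(scenarios = scen)
    },
    diversity = {
      fit <- state$fit
      scen <- state$scenarios$scenarios
      nd <- nDraws(fit$pa)
      di <- unique(round(seq(1, nd,
                             length.out = min(config$diversityDraws, nd))))
      surfaces <- lapply(names(scen), function(s)
        diversitySurface(fit$pa, fit$ab, scen[[s]], fit$design@stats,
                         scenario = s, drawIndices = di))
      names(surfaces) <- names(scen)
      for (s in names(surfaces))
        writeDiversityCSV(surfaces[[s]],
                          file.path(outdir, paste0("diversity_", s, ".csv")),
                          file.path(outdir, paste0("trends_", s, ".csv")))
      comparison <- scenarioComparison(surfaces$full,
                                       surfaces$climate_only,
                                       surfaces$habitat_only)
      write.csv(comparison$slopeCor,
                file.path(outdir, "scenario_slope_cor.csv"),
                row.names = FALSE)
      list(surfaces = surfaces, comparison = comparison)
    },
    report = {
      .writeReport(state, outdir)
      list(done = TRUE)
    })
}

.writeReport <- function(state, outdir) {
  if (is.null(state$vp) || is.null(state$diversity))
    stop("report requires completed vp and diversity stages")
  vps <- vpSummary(state$vp$vpPA)
  vps$part <- "PA"
  vpsAB <- vpSummary(state$vp$vpAB)
  vpsAB$part <- "AB"
  write.csv(rbind(vps, vpsAB), file.path(outdir, "report_vp_species.csv"),
            row.names = FALSE)
  ctx <- state$vp$contextVP
  ctxTab <- do.call(rbind, lapply(names(ctx@results), function(cl) {
    s <- vpSummary(ctx@results[[cl]])
    s$context <- cl
    s
  }))
  write.csv(ctxTab, file.path(outdir, "report_vp_context.csv"),
            row.names = FALSE)
  funTab <- do.call(rbind, lapply(names(state$vp$functionalVP), function(g) {
    q <- state$vp$functionalVP[[g]]$quantiles
    data.frame(group = g,
               habitat_median = q["50%", "habitat"],
               habitat_q2.5 = q["2.5%", "habitat"],
               habitat_q97.5 = q["97.5%", "habitat"],
               climate_median = q["50%", "climate"],
               climate_q2.5 = q["2.5%", "climate"],
               climate_q97.5 = q["97.5%", "climate"])
  }))
  write.csv(funTab, file.path(outdir, "report_vp_functional.csv"),
            row.names = FALSE)
  trends <- do.call(rbind, lapply(state$diversity$surfaces, function(s)
    cbind(scenario = s@scenario, s@trends)))
  write.csv(trends, file.path(outdir, "report_diversity_trends.csv"),
            row.names = FALSE)
  invisible(NULL)
}

#' Regenerate the report tables of a completed run
#'
#' Re-reads the cached stage state of a pipeline run and rewrites the
#' report CSVs; idempotent, and an error if the required stages have not
#' completed.
#'
#' @param outdir the pipeline output directory.
#' @return invisibly, `outdir`.
#' @export
pipelineReport <- function(outdir) {
  state <- list()
  for (stage in c("simulate", "fit", "vp", "diversity")) {
    sf <- .stateFile(outdir, stage)
    if (file.exists(sf)) state[[stage]] <- readRDS(sf)
  }
  if (!length(state)) stop("no completed pipeline stages under ", outdir)
  .writeReport(state, outdir)
  invisible(outdir)
}
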