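## Presets, configuration and end-to-end workflow orchestration:
## calibrate -> dose-response -> inflammation -> PN profiles -> ABM.

.PRESETS <- list(
  optimal           = list(glucose = 5,      pH = 7.1),
  borderline        = list(glucose = 1.0293, pH = 6.9531),
  early_degenerated = list(glucose = 0.8901, pH = 6.9349)
)

#' Nutrient-environment presets
#'
#' Three physiologically motivated glucose/pH combinations: an optimal
#' nutritional environment (5 mM, pH 7.1) and two adverse mid-transverse
#' plane environments derived from mechanotransport finite-element
#' predictions: borderline (1.0293 mM, pH 6.9531, non-degenerated
#' endplate) and early degenerated (0.8901 mM, pH 6.9349).
#'
#' @param name preset name.
#' @return A [NutrientEnvironment-class].
#' @examples
#' nutrientPreset("borderline")
#' @export
nutrientPreset <- function(name = c("optimal", "borderline",
                                    "early_degenerated")) {
  name <- match.arg(name)
  p <- .PRESETS[[name]]
  nutrientEnvironment(p$glucose, p$pH, label = name)
}

## resolve an environment from preset or custom glucose/pH (validated)
.resolveEnvironment <- function(preset = NULL, glucose = NULL, ph = NULL) {
  if (!is.null(preset)) return(nutrientPreset(preset))
  if (is.null(glucose) || is.null(ph))
    stop("either a preset or both glucose and pH must be given", call. = FALSE)
  nutrientEnvironment(glucose, ph, label = "custom")
}

#' Run the full modelling pipeline
#'
#' Calibrates the weighting factors from the relationship tables, fits the
#' dose-response curves, computes the inflammation state of the chosen
#' nutrient environment, evaluates the PN-activity profiles for all four
#' cell states, runs the replicate agent-based simulations, and writes all
#' outputs plus a manifest to \code{outDir}.
#'
#' Output files: \code{theta_table.csv} (derived weighting factors),
#' \code{profiles.csv} (PN-activities), \code{inflammation.json},
#' \code{abm_runs.csv}, \code{abm_summary.csv}, \code{world_seed<seed>.csv}
#' (snapshot of the first run) and \code{manifest.json}.
#'
#' @param preset preset name, or NULL with explicit \code{glucose}/\code{ph}.
#' @param glucose,ph custom nutrient values (validated against the
#'   physiological ranges before any computation).
#' @param thetaMode \code{"individual"} or \code{"invariant_0.01"}.
#' @param nAgents,nRuns agent-based model size and replicate count.
#' @param nIl1b,nTnfa nucleation points per cytokine.
#' @param seed root seed; the ABM replicate seeds are derived from it.
#' @param outDir output directory (created if missing); NULL returns the
#'   results without writing files.
#' @param config optional path to a YAML file whose keys (preset, glucose,
#'   ph, theta_mode, n_agents, n_runs, seed, tables: pn / inflammation,
#'   anchors) override the corresponding arguments.
#' @return Invisibly, a list with the calibrated system, curves,
#'   environment, inflammation state, profiles, ABM runs and summary, and
#'   the manifest.
#' @export
runPipeline <- function(preset = "optimal", glucose = NULL, ph = NULL,
                        thetaMode = c("individual", "invariant_0.01"),
                        nAgents = 4000, nRuns = 10, nIl1b = 15L, nTnfa = 15L,
                        seed = 1L, outDir = NULL, config = NULL) {
  thetaMode <- match.arg(thetaMode)
  pnPath <- defaultTablePath("table1_pn")
  inflPath <- defaultTablePath("table3_inflammation")
  anchorPath <- defaultTablePath("anchors_default")
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg$preset)) preset <- cfg$preset
    if (!is.null(cfg$glucose)) { glucose <- cfg$glucose; preset <- NULL }
    if (!is.null(cfg$ph)) { ph <- cfg$ph; preset <- NULL }
    if (!is.null(cfg$theta_mode)) thetaMode <- cfg$theta_mode
    if (!is.null(cfg$n_agents)) nAgents <- cfg$n_agents
    if (!is.null(cfg$n_runs)) nRuns <- cfg$n_runs
    if (!is.null(cfg$seed)) seed <- cfg$seed
    if (!is.null(cfg$tables$pn)) pnPath <- cfg$tables$pn
    if (!is.null(cfg$tables$inflammation)) inflPath <- cfg$tables$inflammation
    if (!is.null(cfg$anchors)) anchorPath <- cfg$anchors
  }
  env <- .resolveEnvironment(preset, glucose, ph)  # validates ranges first

  system <- calibrateSystem(loadRelationshipTable(pnPath),
                            loadRelationshipTable(inflPath))
  curves <- fitCurveSet(loadAnchorTable(anchorPath))
  message(sprintf("scaling factor %.4g (%s)", system@scalingFactor,
                  system@scalingSource))

  infl <- inflammationState(system, env, curves, thetaMode = thetaMode)
  pct <- pctImmunopositiveCells(infl)
  message(sprintf("immunopositivity targets: IL1B %.2f%% TNFA %.2f%%",
                  pct[["IL1B"]], pct[["TNFA"]]))
  profiles <- profileAll(system, env, curves,
                         cytokineXValues = cytokineX(infl),
                         thetaMode = thetaMode)
  runs <- replicateRuns(pct[["IL1B"]], pct[["TNFA"]], n = nAgents,
                        nRuns = nRuns, baseSeed = seed, nIl1b = nIl1b,
                        nTnfa = nTnfa, keepWorlds = TRUE)
  worlds <- attr(runs, "worlds")
  summary <- summarizeReplicates(runs)

  cfgRecord <- list(environment = list(label = env@label,
                                       glucose = env@glucose, pH = env@pH),
                    theta_mode = thetaMode, n_agents = nAgents,
                    n_runs = nRuns, n_nucleation = c(nIl1b, nTnfa),
                    seed = seed)
  manifest <- list(config = cfgRecord,
                   config_hash = rlang::hash(cfgRecord),
                   scaling_factor = system@scalingFactor,
                   scaling_source = system@scalingSource,
                   abm_seeds = seed + seq_len(nRuns) - 1,
                   timestamp = format(Sys.time(), tz = "UTC"))

  result <- list(system = system, curves = curves, environment = env,
                 inflammation = infl, profiles = profiles, runs = runs,
                 summary = summary, worlds = worlds, manifest = manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    exportThetaTable(system, file.path(outDir, "theta_table.csv"))
    utils::write.csv(profiles, file.path(outDir, "profiles.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(environment = env@label,
           omega_mRNA = as.list(omegaMRNA(infl)),
           protein = as.list(infl@protein),
           pct_immunopositive = as.list(pct),
           cytokine_x = as.list(cytokineX(infl))),
      file.path(outDir, "inflammation.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(runs, file.path(outDir, "abm_runs.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(summary, file.path(outDir, "abm_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(worldSnapshot(worlds[[1]]),
                     file.path(outDir, sprintf("world_seed%d.csv", seed)),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
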