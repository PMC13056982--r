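# End-to-end pipeline: synthetic (or file-based) ingestion -> trophic
# layers -> sea-ice masks -> index -> summary tables, with a
# provenance record. Deterministic under fixed seeds.

#' Build a pipeline configuration
#'
#' All thresholds of the analysis in one validated list: the seasonal
#' sea-ice zone SIC threshold (15%), the polynya threshold (0.4 m SIT
#' for model fields; 0.85 SIC for satellite-style fields), the
#' typical-polynya frequency cutoff (10%, strict), the demersal-fish
#' bottom-temperature habitability bound (1 degC), the valid SST range
#' of the krill growth model, and the percentile bin cutoffs (5/10/25).
#'
#' @param scenario a [ScenarioConfig-class] for synthetic input, or
#'   `NULL` to read fields from `fieldDir`
#' @param fieldDir directory of `.aevf` field files (used when
#'   `scenario` is NULL)
#' @param gridLatRange,gridLonStep,gridLatStep grid geometry for
#'   synthetic runs
#' @param sicZoneThreshold SIC fraction defining the seasonal ice zone
#' @param polynyaVariable "SIT" (model default) or "SIC"
#' @param polynyaThreshold threshold for `polynyaVariable`
#' @param freqCutoff typical-polynya frequency cutoff (strict)
#' @param connectivity polynya component connectivity, 4 or 8
#' @param dfpMaxTbot bottom-temperature habitability bound, degC
#' @param kgpSstRange valid SST range for the krill model, degC
#' @param binCutoffs percentile cutoffs for the index bins
#' @param mode "regional" or "hemispheric" index scaling
#' @param nEmperor,nAdelie synthetic colony counts
#' @param mpaSectors longitude sectors of a synthetic protected-area
#'   mask (list of c(start, end)); NULL for no protected areas
#' @param boundaries region boundary spec (see [regionMasks()])
#' @param seed master seed for colony placement
#' @return validated config list (class "aevPipelineConfig")
#' @export
pipelineConfig <- function(scenario = scenarioConfig(years = 2000:2019,
                                                     nMembers = 2),
                           fieldDir = NULL,
                           gridLatRange = c(-78, -50),
                           gridLonStep = 2, gridLatStep = 2,
                           sicZoneThreshold = 0.15,
                           polynyaVariable = c("SIT", "SIC"),
                           polynyaThreshold = NULL,
                           freqCutoff = 0.10,
                           connectivity = 4,
                           dfpMaxTbot = 1,
                           kgpSstRange = c(-1, 5),
                           binCutoffs = c(5, 10, 25),
                           mode = c("regional", "hemispheric"),
                           nEmperor = 12, nAdelie = 30,
                           mpaSectors = list(c(150, 230), c(300, 30)),
                           boundaries = defaultRegionBoundaries(),
                           seed = 7) {
  polynyaVariable <- match.arg(polynyaVariable)
  mode <- match.arg(mode)
  if (is.null(polynyaThreshold))
    polynyaThreshold <- if (polynyaVariable == "SIT") 0.4 else 0.85
  cfg <- list(scenario = scenario, fieldDir = fieldDir,
              gridLatRange = gridLatRange, gridLonStep = gridLonStep,
              gridLatStep = gridLatStep,
              sicZoneThreshold = sicZoneThreshold,
              polynyaVariable = polynyaVariable,
              polynyaThreshold = polynyaThreshold,
              freqCutoff = freqCutoff,
              connectivity = as.integer(connectivity),
              dfpMaxTbot = dfpMaxTbot, kgpSstRange = kgpSstRange,
              binCutoffs = binCutoffs, mode = mode,
              nEmperor = nEmperor, nAdelie = nAdelie,
              mpaSectors = mpaSectors, boundaries = boundaries,
              seed = as.integer(seed))
  errs <- .validatePipelineConfig(cfg)
  if (length(errs))
    stop("invalid pipeline configuration:\n  - ",
         paste(errs, collapse = "\n  - "))
  class(cfg) <- "aevPipelineConfig"
  cfg
}

.validatePipelineConfig <- function(cfg) {
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(cfg$sicZoneThreshold > 0 && cfg$sicZoneThreshold < 1,
      "sicZoneThreshold must lie in (0, 1)")
  chk(cfg$polynyaThreshold > 0, "polynyaThreshold must be positive")
  chk(!(cfg$polynyaVariable == "SIC" && cfg$polynyaThreshold > 1),
      "SIC polynya threshold must be a fraction <= 1")
  chk(cfg$freqCutoff >= 0 && cfg$freqCutoff < 1,
      "freqCutoff must lie in [0, 1)")
  chk(cfg$connectivity %in% c(4L, 8L), "connectivity must be 4 or 8")
  chk(length(cfg$binCutoffs) == 3 && all(diff(cfg$binCutoffs) > 0) &&
        all(cfg$binCutoffs > 0 & cfg$binCutoffs < 100),
      "binCutoffs must be three increasing percentages in (0, 100)")
  chk(length(cfg$kgpSstRange) == 2 && cfg$kgpSstRange[1] < cfg$kgpSstRange[2],
      "kgpSstRange must be an increasing pair")
  chk(cfg$nEmperor >= 1 && cfg$nAdelie >= 1,
      "colony counts must be >= 1")
  if (is.null(cfg$scenario)) {
    chk(!is.null(cfg$fieldDir) && dir.exists(cfg$fieldDir),
        "fieldDir must exist when no synthetic scenario is given")
  }
  errs
}

#' Run the full pipeline
#'
#' Synthetic-or-file ingestion, five trophic layers, seasonal sea-ice
#' zone and typical polynyas, the regional AEV index with percentile
#' bins, and the polynya / protected-area / layer-contribution summary
#' tables. With an `outputDir`, writes the index field, the three
#' tables as csv, and a provenance record (config, seeds, package
#' version, config hash); repeated runs with the same config are
#' byte-identical.
#'
#' @param config an `aevPipelineConfig` from [pipelineConfig()]
#' @param outputDir optional directory for output files
#' @return list: `result` ([AevResult-class]), `stack`
#'   ([LayerStack-class]), `polynyas` ([PolynyaMap-class]), `grid`,
#'   `regions`, `tables` (polynyaStats, mpaOverlap, contributions),
#'   `colonies`, `provenance`
#' @export
runPipeline <- function(config = pipelineConfig(), outputDir = NULL) {
  stopifnot(inherits(config, "aevPipelineConfig"))
  grid <- makeGrid(config$gridLatRange, config$gridLonStep,
                   config$gridLatStep)
  landMask(grid) <- syntheticLandMask(grid)
  if (!is.null(config$scenario)) {
    env <- generateEnvironment(grid, config$scenario)
  } else {
    env <- readFields(config$fieldDir)
    need <- c("SIC", "SIT", "SST", "TBOT", "CHL", "NPP", "DFP_raw")
    miss <- setdiff(need, names(env))
    if (length(miss))
      stop("missing input fields: ", paste(miss, collapse = ", "))
  }
  land <- landMask(grid)

  zone <- seasonalIceZone(env$SIC, threshold = config$sicZoneThreshold,
                          land = land)
  polyField <- if (config$polynyaVariable == "SIT") env$SIT else env$SIC
  polynyas <- polynyaSeries(polyField,
                            threshold = config$polynyaThreshold,
                            land = land,
                            connectivity = config$connectivity,
                            cutoff = config$freqCutoff)

  nppL <- growingSeasonNpp(env$NPP)
  chlClim <- .growingSeasonMean(env$CHL)
  sstClim <- .growingSeasonMean(env$SST)
  kgpL <- kgp(chlClim, sstClim, sstRange = config$kgpSstRange)
  dfpL <- dfp(.annualMean(env$DFP_raw), .annualMean(env$TBOT),
              maxTbot = config$dfpMaxTbot)
  emperor <- generateColonies(grid, config$nEmperor,
                              abundanceRange = c(2e3, 5e4),
                              seed = config$seed, species = "emperor")
  adelie <- generateColonies(grid, config$nAdelie,
                             abundanceRange = c(1e3, 2e5),
                             seed = config$seed + 1L, species = "adelie")
  eppL <- accessibility(emperor, grid, EPP_CALIBRATION)
  appL <- accessibility(adelie, grid, APP_CALIBRATION)

  stack <- layerStack(nppL, kgpL, dfpL, eppL, appL, zone)
  regions <- regionMasks(grid, config$boundaries)
  result <- regionalIndex(scaleAndSum(stack), regions, config$mode)
  result <- binPercentiles(result, config$binCutoffs)

  mpaMask <- .sectorMask(grid, config$mpaSectors)
  tables <- list(
    polynyaStats = polynyaRegionStats(result, typicalMask(polynyas),
                                      grid),
    mpaOverlap = mpaOverlap(result, mpaMask, grid),
    contributions = layerContributions(
      result,
      masks = list(inside_polynya = typicalMask(polynyas),
                   outside_polynya = !typicalMask(polynyas) & zone,
                   valuable = !is.na(aevBins(result)) &
                     aevBins(result) != "other"),
      grid)$table
  )

  provenance <- list(
    package = "AEVIndex",
    version = as.character(utils::packageVersion("AEVIndex")),
    seed = config$seed,
    scenarioSeed = if (!is.null(config$scenario))
      config$scenario@seed else NA,
    thresholds = config[c("sicZoneThreshold", "polynyaVariable",
                          "polynyaThreshold", "freqCutoff",
                          "connectivity", "dfpMaxTbot", "kgpSstRange",
                          "binCutoffs")]
  )

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    d <- dim(aevValues(result))
    aevField <- new("GriddedField", name = "AEV", units = "1",
                    data = array(aevValues(result), c(1, 1, d)),
                    years = max(fieldYears(env$SIC)), months = 1L)
    writeFields(list(AEV = aevField), outputDir)
    utils::write.csv(tables$polynyaStats,
                     file.path(outputDir, "polynya_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(tables$mpaOverlap,
                     file.path(outputDir, "mpa_overlap.csv"),
                     row.names = FALSE)
    utils::write.csv(tables$contributions,
                     file.path(outputDir, "layer_contributions.csv"),
                     row.names = FALSE)
    cfgPath <- file.path(outputDir, "provenance.json")
    prov <- provenance
    prov$configHash <- .configHash(config)
    jsonlite::write_json(prov, cfgPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }

  list(result = result, stack = stack, polynyas = polynyas,
       grid = grid, regions = regions, tables = tables,
       colonies = rbind(emperor, adelie), provenance = provenance)
}

# md5 of the canonical JSON serialisation of the config.
.configHash <- function(config) {
  cfg <- config
  cfg$scenario <- if (!is.null(cfg$scenario))
    list(years = cfg$scenario@years, nMembers = cfg$scenario@nMembers,
         warmingRate = cfg$scenario@warmingRate,
         iceDeclineRate = cfg$scenario@iceDeclineRate,
         polynyas = cfg$scenario@polynyas,
         bloomAmplification = cfg$scenario@bloomAmplification,
         noiseSd = as.list(cfg$scenario@noiseSd),
         seed = cfg$scenario@seed)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

# Growing-season (ONDJFM) mean over members, years and season months.
.growingSeasonMean <- function(field) {
  sel <- which(.inGrowingSeason(fieldMonths(field)))
  if (!length(sel)) stop("no growing-season months in field ", field@name)
  d <- dim(field@data)
  apply(field@data[, sel, , , drop = FALSE], c(3, 4), mean, na.rm = TRUE)
}

.annualMean <- function(field) {
  apply(field@data, c(3, 4), mean, na.rm = TRUE)
}

# Boolean mask from longitude sectors (wrap-aware), all latitudes.
.sectorMask <- function(grid, sectors) {
  nlat <- length(latCenters(grid))
  nlon <- length(lonCenters(grid))
  if (is.null(sectors) || !length(sectors))
    return(matrix(FALSE, nlat, nlon))
  lon <- lonCenters(grid)
  inLon <- rep(FALSE, nlon)
  for (sec in sectors)
    inLon <- inLon | .inSector(lon, sec[1] %% 360, sec[2] %% 360)
  matrix(inLon, nlat, nlon, byrow = TRUE) & !landMask(grid)
}
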