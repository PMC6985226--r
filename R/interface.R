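## Thin command-line layer tying the stages together:
## simulate | invariance | growth | voxelmap | report.
## Flags override YAML config values; the fully resolved configuration
## (plus package version and seed) is embedded in every artifact, so a
## fixed seed and config give bit-identical outputs. Wall-clock provenance
## goes to a side log, not into the artifacts.

.cliDefaults <- list(
  simulate = list(seed = 1L, out = "sim", n_participants = 400L, drift = 0.3,
                  coupling = 0.5, volumes = 0L, grid = 20L,
                  mask_radius = 8.5, config = NULL),
  invariance = list(seed = 1L, panel = NULL, out = "invariance",
                    robust = FALSE, config = NULL),
  growth = list(seed = 1L, panel = NULL, out = "growth",
                covariates = "", latent_basis = FALSE, config = NULL),
  voxelmap = list(seed = 1L, panel = NULL, volumes = NULL, out = "voxelmap",
                  target = "slope", mode = "fixed_measurement",
                  p_thresh = 0.001, min_extent = 50L,
                  connectivity = "faces_edges", config = NULL),
  report = list(dir = ".", out = "report.json", config = NULL)
)

.parseArgs <- function(args, defaults) {
  cfg <- defaults
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("malformed argument: ", a)
    key <- gsub("-", "_", substring(a, 3))
    if (!key %in% names(defaults)) stop("unknown option: --", substring(a, 3))
    if (is.logical(defaults[[key]]) &&
        (i == length(args) || startsWith(args[i + 1L], "--"))) {
      cfg[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) stop("missing value for option: --", substring(a, 3))
      val <- args[i + 1L]
      proto <- defaults[[key]]
      cfg[[key]] <- if (is.integer(proto)) as.integer(val)
        else if (is.numeric(proto)) as.numeric(val)
        else if (is.logical(proto)) as.logical(val)
        else val
      i <- i + 2L
    }
  }
  ## YAML config file values fill in under explicit flags
  if (!is.null(cfg$config)) {
    y <- yaml::read_yaml(cfg$config)
    bad <- setdiff(names(y), names(defaults))
    if (length(bad)) stop("unknown config field: ", paste(bad, collapse = ", "))
    given <- gsub("-", "_", sub("^--", "", grep("^--", args, value = TRUE)))
    for (k in names(y)) if (!k %in% given) cfg[[k]] <- y[[k]]
  }
  cfg
}

.provenance <- function(cfg) {
  list(package = "longsem",
       version = as.character(utils::packageVersion("longsem")),
       seed = cfg$seed %||% NA,
       config = cfg[setdiff(names(cfg), c("config", "out", "panel",
                                          "volumes", "dir"))])
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (synthetic panel + optional volumes with truth
#' record), `invariance` (configural/weak/strong ladder + partial search),
#' `growth` (second-order LGCM estimates), `voxelmap` (voxel-wise slope or
#' intercept maps + cluster table), `report` (merge stage outputs into one
#' summary). Options may come from `--config file.yaml`; explicit flags
#' win. On failure all artifacts created by the run are removed and a
#' non-zero status is returned.
#'
#' @param args character vector, e.g.
#'   `c("simulate", "--seed", "7", "--out", "simdir")`.
#' @return exit status, invisibly (0 on success).
#' @export
runCLI <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || !args[1] %in% names(.cliDefaults)) {
    message("usage: longsem <simulate|invariance|growth|voxelmap|report> [--options]")
    return(invisible(1L))
  }
  sub <- args[1]
  created <- character()
  status <- tryCatch({
    cfg <- .parseArgs(args[-1], .cliDefaults[[sub]])
    created <- switch(sub,
      simulate = .cliSimulate(cfg),
      invariance = .cliInvariance(cfg),
      growth = .cliGrowth(cfg),
      voxelmap = .cliVoxelmap(cfg),
      report = .cliReport(cfg))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    unlink(created, recursive = TRUE)
    1L
  })
  invisible(status)
}

.logLine <- function(dir, ...) {
  cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), sprintf(...), "\n",
      file = file.path(dir, "cli.log"), append = TRUE)
}

.cliSimulate <- function(cfg) {
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  n <- cfg$n_participants
  sc <- simConfig(n = n, occasionCounts = .scaledCounts(n),
                  intermittentReturn = .scaledIntermittent(n),
                  driftMagnitude = cfg$drift, coupling = cfg$coupling,
                  grid = rep(cfg$grid, 3),
                  maskRadiusVox = cfg$mask_radius,
                  effectCenter = rep((cfg$grid + 1) / 2, 3),
                  effectRadiusVox = min(4, cfg$grid / 4),
                  seed = cfg$seed)
  panel <- genItemPanel(sc)
  writeItemPanel(panel, file.path(cfg$out, "panel.csv"))
  truth <- panel@meta$truth
  truth$provenance <- .provenance(cfg)
  jsonlite::write_json(truth, file.path(cfg$out, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (cfg$volumes > 0) {
    nv <- min(cfg$volumes, length(truth$slope))
    gen <- genVolumes(sc, truth$slope[seq_len(nv)])
    writeVolumes(gen, file.path(cfg$out, "volumes"),
                 ids = panel@ids[seq_len(nv)])
  }
  .logLine(cfg$out, "simulate seed=%d n=%d", cfg$seed, n)
  cfg$out
}

## scale the canonical dropout profile 1808/1414/1282 (with 100 intermittent
## returners) to a smaller n
.scaledCounts <- function(n) {
  ref <- c(1808, 1414, 1282)
  cnt <- round(ref / ref[1] * n)
  cnt[1] <- n
  as.integer(cnt)
}

.scaledIntermittent <- function(n) max(0L, as.integer(round(100 / 1808 * n)))

.cliInvariance <- function(cfg) {
  if (is.null(cfg$panel)) stop("missing required option: --panel")
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  panel <- readItemPanel(cfg$panel)
  rep <- runLadder(panel, robust = cfg$robust, seed = cfg$seed)
  out <- list(provenance = .provenance(cfg),
              levels = lapply(rep$levels, unclass),
              decisions = rep$decisions,
              freedItems = rep$freedItems, finalLevel = rep$finalLevel)
  jsonlite::write_json(out, file.path(cfg$out, "invariance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tab <- do.call(rbind, lapply(names(rep$levels), function(lv) {
    s <- rep$levels[[lv]]
    data.frame(model = lv, T = s$T, df = s$df, c = s$c, rmsea = s$rmsea,
               ci_lo = s$rmsea.ci[1], ci_hi = s$rmsea.ci[2], cfi = s$cfi)
  }))
  utils::write.table(tab, file.path(cfg$out, "invariance.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  .logLine(cfg$out, "invariance final=%s", rep$finalLevel)
  cfg$out
}

.cliGrowth <- function(cfg) {
  if (is.null(cfg$panel)) stop("missing required option: --panel")
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  panel <- readItemPanel(cfg$panel)
  rep <- runLadder(panel, seed = cfg$seed)
  if (is.null(rep$finalSpec)) stop("no accepted measurement model")
  covs <- if (nzchar(cfg$covariates)) {
    if (cfg$covariates == "auto") colnames(covariateDesign(panel))
    else strsplit(cfg$covariates, ",", fixed = TRUE)[[1]]
  } else character()
  spec <- buildLGCM(rep$finalSpec, growthSpec(latentBasis = cfg$latent_basis),
                    covariates = covs, panel = panel)
  est <- estimateGrowth(spec, panel, seed = cfg$seed)
  writeGrowthTSV(est, file.path(cfg$out, "growth.tsv"))
  out <- list(provenance = .provenance(cfg),
              growth = est$growth, correlation = est$correlation,
              covariatePaths = est$covariatePaths,
              fitStatistics = unclass(fitStatistics(est$fit)),
              measurementLevel = rep$finalLevel,
              freedItems = rep$freedItems)
  jsonlite::write_json(out, file.path(cfg$out, "growth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  .logLine(cfg$out, "growth done")
  cfg$out
}

.cliVoxelmap <- function(cfg) {
  for (req in c("panel", "volumes"))
    if (is.null(cfg[[req]])) stop("missing required option: --", req)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  panel <- readItemPanel(cfg$panel)
  vols <- readVolumes(cfg$volumes)
  nv <- dim(vols$volumes)[4]
  if (!identical(vols$ids, panel@ids[seq_len(nv)]))
    stop("ID mismatch between volumes sidecar and panel")
  panelSub <- ItemPanel(responses(panel)[seq_len(nv), , drop = FALSE],
                        nItems = nItems(panel), nOccasions = nOccasions(panel),
                        ids = panel@ids[seq_len(nv)])
  rep <- runLadder(panelSub, seed = cfg$seed)
  if (is.null(rep$finalSpec)) stop("no accepted measurement model")
  base <- buildLGCM(rep$finalSpec, growthSpec(), panel = panelSub)
  map <- mapVoxelPredictor(panelSub, vols$volumes, vols$mask, base,
                           target = cfg$target, mode = cfg$mode,
                           affine = vols$affine, seed = cfg$seed)
  writeStatMap(map, cfg$out, prefix = cfg$target)
  cl <- thresholdCluster(map, pThresh = cfg$p_thresh,
                         minExtent = cfg$min_extent,
                         connectivity = cfg$connectivity)
  writeClusterTSV(cl, file.path(cfg$out, "clusters.tsv"))
  meta <- c(.provenance(cfg), map@meta,
            list(clusters = nrow(cl),
                 thresholds = list(p = cfg$p_thresh, extent = cfg$min_extent,
                                   connectivity = cfg$connectivity)))
  jsonlite::write_json(meta, file.path(cfg$out, "voxelmap.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .logLine(cfg$out, "voxelmap clusters=%d", nrow(cl))
  cfg$out
}

.cliReport <- function(cfg) {
  pieces <- list(provenance = .provenance(cfg))
  for (nm in c("invariance", "growth", "voxelmap")) {
    f <- file.path(cfg$dir, nm, paste0(nm, ".json"))
    if (file.exists(f)) pieces[[nm]] <- jsonlite::read_json(f)
  }
  jsonlite::write_json(pieces, cfg$out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfg$out
}
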