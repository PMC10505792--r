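#' Build a run configuration
#'
#' Returns the default configuration for [runActivin()] /
#' [runNeuruloid()] with any number of named overrides. Unknown keys are
#' rejected, and every parameter that affects results is emitted in the
#' run's provenance record.
#'
#' @param assay `"activin"` or `"neuruloid"`.
#' @param ... named overrides of default fields.
#' @return a named list of class `mpRunConfig`.
#' @examples
#' cfg <- runConfig("activin", nColonies = 5, seed = 7,
#'                  outputDir = tempfile())
#' @export
runConfig <- function(assay = c("activin", "neuruloid"), ...) {
  assay <- match.arg(assay)
  common <- list(
    assay = assay,
    mode = "synth",                  # "synth" or "dir"
    inputDir = NULL,                 # for mode = "dir": <dir>/<group>/*.tif
    phenotypes = c("WT", "HET", "HD", "KO"),
    control = "WT",
    pixelSize = 1,
    seed = 1,
    outputDir = "mpq_out",
    statsMethod = "dunnett",
    writeImages = FALSE,
    writePlots = FALSE)
  spec <- if (assay == "activin") c(common, list(
    nColonies = 15,
    colonyRadius = 250, targetCount = 1800, minSeparation = 8,
    channelMap = c("DAPI", "SMAD23"),
    expectedDiameter = 500, areaTolerance = 0.35, cropMargin = 5,
    minNucleusArea = 30, maxNucleusArea = 300,
    binWidth = 10, maxRadius = 250,
    centerBand = c(10, 25), edgeBand = c(175, 225),
    thresholdMode = "otsu",
    classifyIntensity = "mean_SMAD23",
    profileIntensity = "median_SMAD23"))
  else c(common, list(
    nColonies = 20,
    channelMap = c("DAPI", "PAX6", "NCAD", "SOX10"),
    jitterSd = 0.03,
    noise = list(background = 10, backgroundSd = 4, blurSigma = 0.8,
                 poisson = FALSE),
    fractionMode = "clip"))
  over <- list(...)
  bad <- setdiff(names(over), names(spec))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- modifyList(spec, over, keep.null = TRUE)
  class(cfg) <- "mpRunConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; must contain an `assay` key, all other keys are
#'   validated against [runConfig()] defaults.
#' @return a validated config list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$assay)) stop("config must name an assay")
  assay <- y$assay
  y$assay <- NULL
  do.call(runConfig, c(list(assay = assay), y))
}

# small deterministic seed stream: all derived seeds stay below 2^31 - 1
.deriveSeed <- function(seed, ...) {
  ix <- c(...)
  as.integer((seed + sum(ix * (7919 + 104729 * seq_along(ix)))) %% 2147483646 + 1)
}

.writeProvenance <- function(cfg, dir) {
  cfgPlain <- unclass(cfg)
  yamlPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfgPlain, yamlPath)
  jsonlite::write_json(
    list(config = cfgPlain,
         config_md5 = unname(tools::md5sum(yamlPath)),
         seed = cfg$seed,
         package = "micropattern",
         version = as.character(utils::packageVersion("micropattern"))),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
}

.statsRows <- function(groups, control, method, readout) {
  summ <- data.frame(readout = readout, group = names(groups),
                     n = lengths(groups),
                     mean = vapply(groups, mean, numeric(1)),
                     sd = vapply(groups, sd, numeric(1)),
                     comparison = NA_character_, p_adj = NA_real_,
                     stars = NA_character_, method = method,
                     row.names = NULL)
  cmpObj <- if (method == "dunnett") dunnettTest(groups, control)
            else tukeyTest(groups)
  cmp <- cmpObj@comparisons
  cmpRows <- data.frame(readout = readout, group = NA_character_,
                        n = NA_integer_, mean = NA_real_, sd = NA_real_,
                        comparison = cmp$comparison, p_adj = cmp$p_adj,
                        stars = cmp$stars, method = method, row.names = NULL)
  rbind(summ, cmpRows)
}

# process one colony image: detect -> crop -> segment -> measure
.quantifyColonyImage <- function(img, cfg, colonyId) {
  regs <- detectColonies(img, expectedDiameter = cfg$expectedDiameter,
                         tau = cfg$areaTolerance, sourceId = colonyId)
  acc <- acceptedRegions(regs)
  colonyRows <- do.call(rbind, lapply(regs, function(r) data.frame(
    colony_id = colonyId, center_x_um = r@centerUm[1],
    center_y_um = r@centerUm[2], area_um2 = r@areaUm2,
    accepted = r@accepted, reject_reason = r@rejectReason)))
  if (length(acc) == 0)
    return(list(colonies = colonyRows, records = NULL))
  ex <- extractColony(img, acc[[1]], margin = cfg$cropMargin)
  labels <- segmentNuclei(getChannel(ex$image, "DAPI"),
                          pixelSize = pixelSize(ex$image))
  filt <- filterNuclei(labels, cfg$minNucleusArea, cfg$maxNucleusArea,
                       pixelSize = pixelSize(ex$image))
  rec <- measureNuclei(filt$labels, ex$image,
                       colonyCenter = ex$region@centerUm,
                       colonyId = colonyId)
  list(colonies = colonyRows, records = rec)
}

#' Run the activin A assay pipeline
#'
#' End-to-end deterministic run: synthesize (or ingest) colony images,
#' detect colonies, segment and measure nuclei, compute radial profiles,
#' center/edge band summaries and positive-nucleus fractions, and compare
#' groups against the control. All outputs are CSV plus a JSON provenance
#' record; identical config and seed reproduce every CSV byte-identically.
#'
#' @param cfg config from [runConfig()] (`assay = "activin"`), or a YAML
#'   path accepted by [readRunConfig()].
#' @return invisibly, a list with the output tables (`colonies`, `nuclei`,
#'   `profiles`, `groupProfiles`, `bands`, `positives`, `stats`,
#'   `threshold`) and `notices`.
#' @export
runActivin <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  stopifnot(cfg$assay == "activin")
  if (!all(c("DAPI", "SMAD23") %in% cfg$channelMap))
    stop("channelMap must provide DAPI and SMAD23 channels")
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  notices <- character()

  inputs <- .activinInputs(cfg)   # list of (group, colonyId, image)
  allColonies <- list(); allRecords <- list()
  for (inp in inputs) {
    q <- .quantifyColonyImage(inp$image, cfg, inp$colonyId)
    q$colonies$group <- inp$group
    allColonies[[inp$colonyId]] <- q$colonies
    if (is.null(q$records)) {
      notices <- c(notices, paste0("no accepted colony in ", inp$colonyId))
    } else {
      q$records$group <- inp$group
      allRecords[[inp$colonyId]] <- q$records
    }
  }
  colonies <- do.call(rbind, allColonies)
  if (length(allRecords) == 0) stop("no colonies detected in any condition")
  nuclei <- do.call(rbind, allRecords)
  grpOf <- vapply(allRecords, function(r) r$group[1], character(1))
  missing <- setdiff(unique(vapply(inputs, `[[`, character(1), "group")),
                     unique(grpOf))
  if (length(missing))
    stop("no colonies detected in condition(s): ",
         paste(missing, collapse = ", "))

  # radial profiles (per-colony normalization is the statistics default)
  profiles <- lapply(allRecords, radialProfile, binWidth = cfg$binWidth,
                     maxRadius = cfg$maxRadius,
                     intensity = cfg$profileIntensity)
  profRows <- do.call(rbind, lapply(profiles, function(p) {
    np <- normalizeProfile(p)
    data.frame(colony_id = p@colonyId,
               bin_lo = p@binEdges[-length(p@binEdges)],
               bin_hi = p@binEdges[-1], mean = p@binMeans,
               mean_norm = np@binMeans, n = p@binCounts)
  }))
  byGrp <- split(profiles, grpOf)
  groupProfiles <- do.call(rbind, lapply(names(byGrp), function(g) {
    agg <- aggregateProfiles(lapply(byGrp[[g]], normalizeProfile))
    agg$group <- g
    agg
  }))

  bands <- do.call(rbind, lapply(allRecords, bandSummary,
                                 centerBand = cfg$centerBand,
                                 edgeBand = cfg$edgeBand,
                                 intensity = cfg$profileIntensity))
  bands$group <- grpOf[bands$colony_id]

  # one global threshold from the pooled control records (batch-wide)
  controlRecs <- nuclei[nuclei$group == cfg$control, , drop = FALSE]
  thrRecs <- if (nrow(controlRecs)) controlRecs else nuclei
  thr <- suggestThreshold(thrRecs, mode = cfg$thresholdMode,
                          intensity = cfg$classifyIntensity)
  positives <- do.call(rbind, lapply(allRecords, function(r) {
    cl <- classifyPositive(r, thr$threshold, intensity = cfg$classifyIntensity)
    data.frame(colony_id = r$colony_id[1], group = r$group[1],
               n_total = nrow(r), n_positive = sum(cl$calls$positive),
               pct_positive = cl$fraction, threshold = thr$threshold,
               threshold_mode = thr$mode)
  }))

  statsTab <- NULL
  grpLevels <- unique(grpOf)
  if (length(grpLevels) < 2) {
    notices <- c(notices, "single group: statistics skipped")
  } else {
    bandGroups <- split(bands$center_mean, bands$group)[grpLevels]
    posGroups <- split(positives$pct_positive, positives$group)[grpLevels]
    statsTab <- rbind(
      .statsRows(bandGroups, cfg$control, cfg$statsMethod, "center_mean"),
      .statsRows(split(bands$edge_mean, bands$group)[grpLevels],
                 cfg$control, cfg$statsMethod, "edge_mean"),
      .statsRows(posGroups, cfg$control, cfg$statsMethod, "pct_positive"))
  }

  out <- cfg$outputDir
  write.csv(colonies, file.path(out, "colonies.csv"), row.names = FALSE)
  write.csv(nuclei, file.path(out, "nuclei.csv"), row.names = FALSE)
  write.csv(profRows, file.path(out, "profiles.csv"), row.names = FALSE)
  write.csv(groupProfiles, file.path(out, "profiles_group.csv"),
            row.names = FALSE)
  write.csv(bands, file.path(out, "bands.csv"), row.names = FALSE)
  write.csv(positives, file.path(out, "positives.csv"), row.names = FALSE)
  if (!is.null(statsTab))
    write.csv(statsTab, file.path(out, "stats.csv"), row.names = FALSE)
  .writeProvenance(cfg, out)
  if (isTRUE(cfg$writePlots)) .activinPlots(out, groupProfiles, bands)
  if (length(notices)) writeLines(notices, file.path(out, "notices.txt"))

  invisible(list(colonies = colonies, nuclei = nuclei, profiles = profRows,
                 groupProfiles = groupProfiles, bands = bands,
                 positives = positives, stats = statsTab,
                 threshold = thr, notices = notices))
}

.activinInputs <- function(cfg) {
  if (cfg$mode == "synth") {
    inputs <- list()
    for (gi in seq_along(cfg$phenotypes)) {
      g <- cfg$phenotypes[gi]
      ph <- phenotypeParams(g)
      for (ci in seq_len(cfg$nColonies)) {
        lay <- generateColonyLayout(cfg$colonyRadius, cfg$targetCount,
                                    cfg$minSeparation,
                                    seed = .deriveSeed(cfg$seed, gi, ci, 1))
        act <- assignActivation(lay, ph, seed = .deriveSeed(cfg$seed, gi, ci, 2))
        smp <- renderColonyImage(lay, act, ph, pixelSize = cfg$pixelSize,
                                 seed = .deriveSeed(cfg$seed, gi, ci, 3))
        id <- sprintf("%s_%03d", g, ci)
        if (isTRUE(cfg$writeImages))
          writeSyntheticSample(smp, file.path(cfg$outputDir, "images", g), id)
        inputs[[id]] <- list(group = g, colonyId = id, image = smp@image)
      }
    }
    inputs
  } else if (cfg$mode == "dir") {
    .dirInputs(cfg)
  } else stop("unknown mode '", cfg$mode, "'")
}

.dirInputs <- function(cfg) {
  stopifnot(!is.null(cfg$inputDir), dir.exists(cfg$inputDir))
  groups <- list.dirs(cfg$inputDir, recursive = FALSE)
  if (length(groups) == 0) stop("inputDir has no condition subdirectories")
  inputs <- list()
  for (gdir in groups) {
    g <- basename(gdir)
    for (tif in sort(list.files(gdir, pattern = "\\.tif$", full.names = TRUE))) {
      img <- readMultiChannelTIFF(tif, channelNames = cfg$channelMap,
                                  pixelSize = cfg$pixelSize)
      id <- sub("\\.tif$", "", basename(tif))
      inputs[[id]] <- list(group = g, colonyId = id, image = img)
    }
  }
  inputs
}

#' Run the neuruloid assay pipeline
#'
#' Synthesizes (or ingests) neuruloid images, segments the area occupied by
#' each marker and the total DAPI area, computes per-colony marker area
#' fractions, and compares groups. Outputs `domains.csv`, `stats.csv` and a
#' provenance record; fully deterministic given config and seed.
#'
#' @param cfg config from [runConfig()] (`assay = "neuruloid"`), or a YAML
#'   path.
#' @return invisibly, a list with `domains`, `stats`, `notices`.
#' @export
runNeuruloid <- function(cfg) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  stopifnot(cfg$assay == "neuruloid")
  markers <- c("PAX6", "NCAD", "SOX10")
  if (!all(c("DAPI", markers) %in% cfg$channelMap))
    stop("channelMap must provide DAPI, PAX6, NCAD and SOX10 channels")
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  notices <- character()

  inputs <- if (cfg$mode == "synth") {
    res <- list()
    for (gi in seq_along(cfg$phenotypes)) {
      g <- cfg$phenotypes[gi]
      for (ci in seq_len(cfg$nColonies)) {
        geom <- jitterNeuruloidGeometry(neuruloidPreset(g), cfg$jitterSd,
                                        seed = .deriveSeed(cfg$seed, gi, ci, 1))
        smp <- renderNeuruloidImage(geom, pixelSize = cfg$pixelSize,
                                    noise = cfg$noise,
                                    seed = .deriveSeed(cfg$seed, gi, ci, 2))
        id <- sprintf("%s_%03d", g, ci)
        if (isTRUE(cfg$writeImages))
          writeSyntheticSample(smp, file.path(cfg$outputDir, "images", g), id)
        res[[id]] <- list(group = g, colonyId = id, image = smp@image,
                          truth = smp@truth)
      }
    }
    res
  } else .dirInputs(cfg)

  rows <- list()
  for (inp in inputs) {
    img <- inp$image
    dapiMask <- segmentMarkerArea(getChannel(img, "DAPI"),
                                  pixelSize = pixelSize(img))
    if (!any(dapiMask)) {
      notices <- c(notices, paste0("empty DAPI area in ", inp$colonyId))
      next
    }
    masks <- lapply(setNames(markers, markers), function(m)
      segmentMarkerArea(getChannel(img, m), pixelSize = pixelSize(img)))
    row <- domainFractions(masks, dapiMask, pixelSize = pixelSize(img),
                           mode = cfg$fractionMode, colonyId = inp$colonyId)
    row$group <- inp$group
    if (!is.null(inp$truth)) {
      tf <- setNames(inp$truth$true_fraction, inp$truth$marker)
      row$true_PAX6 <- tf[["PAX6"]]; row$true_NCAD <- tf[["NCAD"]]
      row$true_SOX10 <- tf[["SOX10"]]
    }
    rows[[inp$colonyId]] <- row
  }
  if (length(rows) == 0) stop("no neuruloids quantified in any condition")
  domains <- do.call(rbind, rows)
  missing <- setdiff(unique(vapply(inputs, `[[`, character(1), "group")),
                     unique(domains$group))
  if (length(missing))
    stop("no neuruloids quantified in condition(s): ",
         paste(missing, collapse = ", "))

  statsTab <- NULL
  grpLevels <- unique(domains$group)
  if (length(grpLevels) < 2) {
    notices <- c(notices, "single group: statistics skipped")
  } else {
    statsTab <- do.call(rbind, lapply(markers, function(m)
      .statsRows(split(domains[[paste0(m, "_frac")]], domains$group)[grpLevels],
                 cfg$control, cfg$statsMethod, paste0(m, "_frac"))))
  }

  out <- cfg$outputDir
  write.csv(domains, file.path(out, "domains.csv"), row.names = FALSE)
  if (!is.null(statsTab))
    write.csv(statsTab, file.path(out, "stats.csv"), row.names = FALSE)
  .writeProvenance(cfg, out)
  if (isTRUE(cfg$writePlots)) .neuruloidPlots(out, domains)
  if (length(notices)) writeLines(notices, file.path(out, "notices.txt"))
  invisible(list(domains = domains, stats = statsTab, notices = notices))
}
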