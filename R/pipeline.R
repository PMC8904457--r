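#' Pipeline configuration
#'
#' Assembles the configuration for [runPipeline()], with every analysis
#' threshold surfaced here rather than hard-coded: the hydrogen-bond
#' classification window (2.5-3.8 Angstrom) and histogram range (2.5-4.0),
#' the polar-contact cutoff (3.5), the initial-rate window (5 min), and
#' the representative selections (10 lowest-energy; 3 RMSD groups of 5).
#'
#' @param sizes deletion-window sizes.
#' @param nPoses poses per variant ensemble.
#' @param sigmaTorsion,closureTol,energySlope,energySigma synthetic
#'   ensemble parameters (see [syntheticEnsembleSpec()]).
#' @param kinetics list: \code{noiseSigma} (multiplicative noise),
#'   \code{foldSigma} (SD of per-variant log fold changes around the
#'   reference parameters).
#' @param hbondWindow,histRange,contactCutoff,rateWindow analysis
#'   thresholds.
#' @param lowEnergyN,rmsdGroups,perGroup representative selections.
#' @param makeHeatmap also render a PNG heatmap.
#' @param seed master seed; all stage seeds derive from it.
#' @return Config list.
#' @export
pipelineConfig <- function(sizes = 1:6, nPoses = 250, sigmaTorsion = 20,
                           closureTol = 0.1, energySlope = 1,
                           energySigma = 0.2,
                           kinetics = list(noiseSigma = 0.02,
                                           foldSigma = 0.4),
                           hbondWindow = c(2.5, 3.8),
                           histRange = c(2.5, 4.0), contactCutoff = 3.5,
                           rateWindow = 5, lowEnergyN = 10,
                           rmsdGroups = 3, perGroup = 5,
                           makeHeatmap = FALSE, seed = 1) {
  list(sizes = sizes, nPoses = nPoses, sigmaTorsion = sigmaTorsion,
       closureTol = closureTol, energySlope = energySlope,
       energySigma = energySigma, kinetics = kinetics,
       hbondWindow = hbondWindow, histRange = histRange,
       contactCutoff = contactCutoff, rateWindow = rateWindow,
       lowEnergyN = lowEnergyN, rmsdGroups = rmsdGroups,
       perGroup = perGroup, makeHeatmap = makeHeatmap, seed = seed)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full deletion-scan pipeline on synthetic inputs
#'
#' Orchestrates enumerate -> simulate -> analyze -> fit -> report: the
#' deletion library is enumerated, a closed-loop conformer ensemble is
#' generated per variant, the geometry statistics (average RMSF, funnel
#' shape, slot-resolved hydrogen-bond summary, contact frequency, helix
#' angle) are computed, per-variant kinetic datasets with seeded fold
#' changes are generated and fitted, and the reference-normalised activity
#' table is assembled. All outputs are written to \code{outDir} together
#' with a manifest (package version, seed, config, md5 checksums of every
#' output). The pipeline is a pure function of (config, seed): rerunning
#' with the same seed reproduces every file byte for byte.
#'
#' @param config list from [pipelineConfig()], or a path to a YAML file
#'   with the same fields (missing fields take the defaults).
#' @param outDir output directory, created if absent.
#' @param seed master seed (defaults to the config's).
#' @return Invisibly, a list with the geometry table, activity table and
#'   manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, seed = NULL) {
  if (is.character(config)) {
    user <- yaml::read_yaml(config)
    config <- utils::modifyList(pipelineConfig(), user)
  }
  if (is.null(seed)) seed <- config$seed
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  warningsSeen <- character()
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warningsSeen <<- c(warningsSeen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  loopDef <- fviiaLoopDefinition()
  map <- fviiaNumberingMap()
  lib <- .stage("enumerate", enumerateDeletions(loopDef, config$sizes))
  paths <- .stage("enumerate", writeVariantOutputs(lib, outDir, map))
  v <- variants(lib)

  espec <- syntheticEnsembleSpec(nPoses = config$nPoses,
                                 sigmaTorsion = config$sigmaTorsion,
                                 closureTol = config$closureTol,
                                 energySlope = config$energySlope,
                                 energySigma = config$energySigma)

  geo <- .stage("analyze", do.call(rbind, lapply(seq_len(nrow(v)), function(i) {
    ens <- collect(sampleLoopEnsemble(
      fviiaLoopGeometry(v$start[i], v$size[i]), espec,
      seed = seed + 1000L * i))
    rp <- rmsfProfile(ens)
    fun <- funnelTable(ens)
    slotRes <- collect(resolveSlotResidue(loopDef, 315L, v$start[i],
                                          v$size[i]))
    series <- atomDistanceSeries(ens, atomSpec(slotRes, "N"),
                                 atomSpec(372L, "O"))
    hb <- hbondSummary(series, window = config$hbondWindow,
                       histRange = config$histRange)
    ha <- helixAngle(ens, pose = 1L,
                     helixSelection = list(resno = c(306L, 310L),
                                           elety = "CA"),
                     baseSelection = list(
                       from = list(resno = setdiff(311:321,
                                                   v$start[i]:v$end[i]),
                                   elety = "CA"),
                       to = list(resno = c(306L, 307L), elety = "CA")))
    data.frame(index = v$index[i], size = v$size[i], start = v$start[i],
               end = v$end[i], loop_length = v$loop_length[i],
               avg_rmsf = attr(rp, "average"),
               funnel_spearman = suppressWarnings(
                 cor(fun$score, fun$rmsd, method = "spearman")),
               min_score = min(fun$score),
               rmsd_range = diff(range(fun$rmsd)),
               slot315_residue = slotRes,
               hbond_mean = hb$mean, hbond_sd = hb$sd,
               hbond_stable = hb$stable,
               hbond_in_range = hb$inRangeFrequency,
               contact_freq = contactFrequency(series,
                                               config$contactCutoff),
               helix_angle = ha$angle)
  })))

  kin <- .stage("fit", do.call(rbind, lapply(c("WT", v$index), function(id) {
    i <- if (identical(id, "WT")) 0L else as.integer(id)
    set.seed(seed + 77000L + i)
    fold <- if (i == 0L) rep(1, 4) else
      exp(rnorm(4, 0, config$kinetics$foldSigma))
    ks <- syntheticKineticsSpec(KM = 7.2 * fold[1], kcat = 0.3 * fold[2],
                                Ki = 2.0 * fold[3], Kd = 0.09 * fold[4],
                                noiseSigma = config$kinetics$noiseSigma)
    dat <- genKinetics(ks, seed = seed + 88000L + i)
    mm <- fitMichaelisMenten(averageReplicates(dat$mm)$conc,
                             averageReplicates(dat$mm)$rate,
                             enzymeConc = ks$enzymeConc)
    ki <- fitCompetitiveKi(averageReplicates(dat$ki)$conc,
                           averageReplicates(dat$ki)$rate,
                           S = 1, KM = mm$KM)
    kd <- collect(fitBindingKd(averageReplicates(dat$kd)$conc,
                               averageReplicates(dat$kd)$rate))
    pr <- averageReplicates(dat$progress, "time", "signal")
    fx <- initialRate(pr$time, pr$signal, window = config$rateWindow)
    data.frame(variant = as.character(id), KM = mm$KM, kcat = mm$kcat,
               Ki = ki$Ki, Kd = kd$Kd, fx_rate = fx$slope,
               true_KM = ks$KM, true_kcat = ks$kcat, true_Ki = ks$Ki,
               true_Kd = ks$Kd)
  })))
  act <- .stage("fit", normalizeToReference(kin, reference = "WT"))
  heat <- .stage("report", buildHeatmapTable(
    act, lib, file = if (isTRUE(config$makeHeatmap))
      file.path(outDir, "heatmap.png") else NULL))

  .stage("report", {
    wr <- function(df, f) {
      write.table(df, file.path(outDir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      f
    }
    files <- c(paths["fasta"], paths["tsv"],
               wr(geo, "geometry.tsv"), wr(act, "activity.tsv"),
               wr(heat$table, "heatmap_table.tsv"),
               wr(aggregate(avg_rmsf ~ loop_length, geo, mean),
                  "rmsf_vs_loop_length.tsv"),
               wr(geo[, c("index", "loop_length", "hbond_mean", "hbond_sd",
                          "hbond_stable")], "hbond_mean_sd.tsv"),
               wr(geo[, c("index", "loop_length", "contact_freq")],
                  "contact_frequency.tsv"))
    jsonlite::write_json(geo, file.path(outDir, "geometry.json"),
                         dataframe = "rows", digits = 10, pretty = TRUE)
    files <- c(files, "geometry.json")
    files <- basename(unname(files))
    manifest <- list(package = "LoopScanR",
                     version = as.character(packageVersion("LoopScanR")),
                     seed = seed,
                     config = config[setdiff(names(config), "seed")],
                     n_variants = nrow(v),
                     warnings = warningsSeen,
                     checksums = as.list(tools::md5sum(
                       file.path(outDir, sort(files)))) |>
                       setNames(sort(files)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
    manifest
  }) -> manifest

  invisible(list(geometry = geo, activity = act, heatmap = heat,
                 manifest = manifest, library = lib))
}

#' Fixture variant groups from the functional characterisation
#'
#' The two high-activity groups of the packaged deletion scan: group 1,
#' the 2-3 residue truncations at 315-319 (variants 12-14 and 20-22);
#' group 2, the 6-7 residue truncations at 313-320 (variants 36, 37, 39).
#'
#' @return Named list of variant-index vectors.
#' @export
fviiaVariantGroups <- function() {
  list(group1 = c(12L, 13L, 14L, 20L, 21L, 22L),
       group2 = c(36L, 37L, 39L))
}

#' Aggregate a per-variant report over variant groups
#'
#' @param report data.frame with an \code{index} column (e.g. the
#'   pipeline's geometry table).
#' @param groups named list of variant-index vectors; default
#'   [fviiaVariantGroups()].
#' @param metrics metric column names to aggregate (default: all numeric
#'   columns except the variant metadata).
#' @return data.frame with one row per (group, metric): n, mean, sd.
#' @export
reportGroupSummary <- function(report, groups = fviiaVariantGroups(),
                               metrics = NULL) {
  if (is.null(metrics))
    metrics <- setdiff(names(report)[vapply(report, is.numeric, logical(1))],
                       c("index", "size", "start", "end", "loop_length"))
  do.call(rbind, lapply(names(groups), function(g) {
    idx <- groups[[g]]
    m <- match(idx, report$index)
    if (anyNA(m))
      stop("unknown variant index in group '", g, "': ",
           paste(idx[is.na(m)], collapse = ", "))
    do.call(rbind, lapply(metrics, function(col)
      data.frame(group = g, metric = col, n = length(m),
                 mean = mean(report[[col]][m]),
                 sd = sd(report[[col]][m]))))
  }))
}
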