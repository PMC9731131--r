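#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. The defaults are the
#' study conditions: 1 mm isotropic voxels, 30 mm^3 minimum lesion volume,
#' 250-voxel size cutoff, volume normalization to 80 voxels in a 36^3 cube
#' (small group, Zernike order 100) and 1500 voxels in a 90^3 cube (large
#' group, order 250), screening at order 150 in 150^3 cubes, PCA retaining
#' 99.8% variance, 1000 K-means restarts, gap statistic with N = 20 and
#' B = 30, ten texture bins with 1% low-tail discard, and PGI with
#' gamma = 2.5 over 5 layers. Reduced orders/cubes ("desk mode") are
#' ordinary overrides of the same fields.
#'
#' @param minVolumeMm3 minimum lesion volume (mm^3).
#' @param cutoffVoxels small/large size cutoff (voxels, inclusive for small).
#' @param smallTarget,largeTarget per-group normalization settings: lists
#'   with `volume`, `cube` and `order`.
#' @param screening list with `enabled`, `order`, `cube`: whole-cohort
#'   size-screening clustering on unnormalized shapes.
#' @param pcaVariance cumulative variance retained by PCA.
#' @param kmeansTrials K-means restarts for the final fits.
#' @param gapN,gapB,gapTrials,gapRefTrials gap-statistic settings.
#' @param textureBins,discardFraction texture settings.
#' @param gamma,pgiLayers PGI settings.
#' @param connectivity lesion/dilation connectivity (6, 18, 26).
#' @param interpolation `"tricubic"` or `"trilinear"`.
#' @param kOverride optional named list forcing cluster counts, e.g.
#'   `list(shape_small = 5, shape_large = 4, texture = 4)`; `NULL` entries
#'   use the gap-statistic choice.
#' @param seed master seed; every random stage derives its sub-stream from
#'   it.
#' @return a validated configuration list.
#' @export
pipelineConfig <- function(minVolumeMm3 = 30, cutoffVoxels = 250L,
                           smallTarget = list(volume = 80L, cube = 36L, order = 100L),
                           largeTarget = list(volume = 1500L, cube = 90L, order = 250L),
                           screening = list(enabled = FALSE, order = 150L, cube = 150L),
                           pcaVariance = 0.998,
                           kmeansTrials = 1000L,
                           gapN = 20L, gapB = 30L,
                           gapTrials = 100L, gapRefTrials = gapTrials,
                           textureBins = 10L, discardFraction = 0.01,
                           gamma = 2.5, pgiLayers = 5L,
                           connectivity = 26L,
                           interpolation = "tricubic",
                           kOverride = list(),
                           seed = 1L) {
  cfg <- list(minVolumeMm3 = minVolumeMm3, cutoffVoxels = as.integer(cutoffVoxels),
              smallTarget = smallTarget, largeTarget = largeTarget,
              screening = screening, pcaVariance = pcaVariance,
              kmeansTrials = as.integer(kmeansTrials),
              gapN = as.integer(gapN), gapB = as.integer(gapB),
              gapTrials = as.integer(gapTrials),
              gapRefTrials = as.integer(gapRefTrials),
              textureBins = as.integer(textureBins),
              discardFraction = discardFraction,
              gamma = gamma, pgiLayers = as.integer(pgiLayers),
              connectivity = as.integer(connectivity),
              interpolation = interpolation, kOverride = kOverride,
              seed = as.integer(seed))
  num <- c(cfg$minVolumeMm3, cfg$cutoffVoxels, cfg$pcaVariance,
           cfg$kmeansTrials, cfg$gapN, cfg$gapB, cfg$textureBins,
           cfg$gamma, cfg$pgiLayers,
           unlist(cfg$smallTarget), unlist(cfg$largeTarget))
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all numeric configuration fields must be positive")
  cfg
}

# shape features -> clusters for one lesion group
clusterShapeGroup <- function(lesions, target, cfg, seedTag, kForce = NULL) {
  ids <- vapply(lesions, function(x) paste0(x@subjectId, ".", x@lesionId),
                character(1))
  desc <- matrix(NA_real_, length(lesions), descriptorDimension(target$order))
  rownames(desc) <- ids
  for (i in seq_along(lesions)) {
    shape <- rescaleToTargetVolume(lesions[[i]], target$volume,
                                   cfg$interpolation)
    cube <- embedInCube(shape, target$cube)
    desc[i, ] <- zernikeDescriptor(zernikeMoments(cube, target$order))@values
  }
  scores <- pcaReduce(desc, cfg$pcaVariance)
  gapCurve <- gapStatistic(scores, N = cfg$gapN, B = cfg$gapB,
                           seed = subSeed(cfg$seed, seedTag),
                           trialsPerFit = cfg$gapTrials,
                           refTrials = cfg$gapRefTrials)
  k <- if (!is.null(kForce)) as.integer(kForce) else gapCurve@kHat
  k <- min(k, nrow(scores))
  model <- kmeansBestOf(scores, k, cfg$kmeansTrials,
                        subSeed(cfg$seed, seedTag + 1L))
  list(ids = ids, descriptors = desc, scores = scores, gap = gapCurve,
       model = model, k = k,
       assignments = data.frame(lesion = ids,
                                cluster = model@assignments),
       representatives = representatives(model, scores))
}

#' Run the end-to-end WMH characterization pipeline
#'
#' Executes extraction, size grouping, optional size-screening clustering,
#' per-group shape normalization + Zernike descriptors + PCA + gap/K-means
#' shape clustering, fuzzy-texture clustering, per-lesion PGI, and one-way
#' ANOVAs of PGI (and lesion size) across the shape and texture clusters.
#' Deterministic for a fixed manifest, configuration and seed.
#'
#' @param manifest subjects to analyze: a data.frame with columns `subject`,
#'   `volume`, `mask` (NIfTI paths), or a list of entries
#'   `list(subject =, volume =, mask =)` where `volume`/`mask` may be
#'   in-memory arrays. An empty manifest yields an empty report.
#' @param config a [pipelineConfig()].
#' @param outputDir if non-NULL, [writeReport()] is called on the result.
#' @return an `AnalysisReport`: list with elements `lesions`, `screening`,
#'   `shape` (per group: descriptors, gap curve, cluster model,
#'   assignments, representatives), `texture`, `pgi`, `anova`, `config`.
#' @export
runPipeline <- function(manifest, config = pipelineConfig(), outputDir = NULL) {
  entries <- normalizeManifest(manifest)
  lesions <- list(); volumes <- list()
  for (e in entries) {
    vol <- if (is.character(e$volume)) readVolume(e$volume) else e$volume
    msk <- if (is.character(e$mask)) readVolume(e$mask) else e$mask
    volumes[[e$subject]] <- vol
    lesions <- c(lesions,
                 extractLesions(vol, msk, config$minVolumeMm3,
                                connectivity = config$connectivity,
                                subjectId = e$subject))
  }
  report <- list(lesions = lesionTable(lesions, config$cutoffVoxels),
                 screening = NULL,
                 shape = list(small = NULL, large = NULL),
                 texture = NULL, pgi = data.frame(), anova = list(),
                 config = config)
  class(report) <- "AnalysisReport"
  if (!length(lesions)) return(finishReport(report, outputDir))

  if (isTRUE(config$screening$enabled) && length(lesions) >= 4L) {
    scr <- config$screening
    ids <- vapply(lesions, function(x) paste0(x@subjectId, ".", x@lesionId),
                  character(1))
    desc <- t(vapply(lesions, function(x) {
      cube <- embedInCube(lesionToArray(x), scr$cube)
      zernikeDescriptor(zernikeMoments(cube, scr$order))@values
    }, numeric(descriptorDimension(scr$order))))
    rownames(desc) <- ids
    scores <- pcaReduce(desc, config$pcaVariance)
    gapCurve <- gapStatistic(scores, N = config$gapN, B = config$gapB,
                             seed = subSeed(config$seed, 77L),
                             trialsPerFit = config$gapTrials,
                             refTrials = config$gapRefTrials)
    model <- kmeansBestOf(scores, gapCurve@kHat, config$kmeansTrials,
                          subSeed(config$seed, 78L))
    report$screening <- list(gap = gapCurve, model = model,
                             assignments = data.frame(lesion = ids,
                                                      cluster = model@assignments))
  }

  groups <- splitBySize(lesions, config$cutoffVoxels)
  if (length(groups$small) >= 4L)
    report$shape$small <- clusterShapeGroup(groups$small, config$smallTarget,
                                            config, 100L,
                                            config$kOverride$shape_small)
  if (length(groups$large) >= 4L)
    report$shape$large <- clusterShapeGroup(groups$large, config$largeTarget,
                                            config, 200L,
                                            config$kOverride$shape_large)

  tex <- textureFeatures(lesions, config$textureBins, config$discardFraction)
  if (nrow(tex) >= 4L) {
    gapCurve <- gapStatistic(tex, N = config$gapN, B = config$gapB,
                             seed = subSeed(config$seed, 300L),
                             trialsPerFit = config$gapTrials,
                             refTrials = config$gapRefTrials)
    k <- config$kOverride$texture
    k <- if (is.null(k)) gapCurve@kHat else as.integer(k)
    model <- kmeansBestOf(tex, min(k, nrow(tex)), config$kmeansTrials,
                          subSeed(config$seed, 301L))
    report$texture <- list(features = tex, gap = gapCurve, model = model,
                           assignments = data.frame(lesion = rownames(tex),
                                                    cluster = model@assignments))
  }

  bySubject <- split(lesions, vapply(lesions, function(x) x@subjectId,
                                     character(1)))
  pgiRows <- lapply(names(bySubject), function(s)
    subjectPGI(volumes[[s]], bySubject[[s]], config$pgiLayers, config$gamma,
               config$connectivity))
  report$pgi <- do.call(rbind, pgiRows)

  report$anova <- reportAnovas(report)
  finishReport(report, outputDir)
}

# ANOVAs of PGI and lesion size across the clusterings present in a report
reportAnovas <- function(report) {
  out <- list()
  if (is.null(report$pgi) || !nrow(report$pgi)) return(out)
  key <- paste0(report$pgi$subject_id, ".", report$pgi$lesion_id)
  pgi <- stats::setNames(report$pgi$PGI, key)
  vol <- stats::setNames(report$lesions$volume_mm3,
                         paste0(report$lesions$subject_id, ".",
                                report$lesions$lesion_id))
  addOne <- function(assign, label) {
    g <- stats::setNames(assign$cluster, assign$lesion)
    if (length(unique(g)) < 2L) return(NULL)
    list(pgi = tryCatch(anovaByCluster(pgi[names(g)], g),
                        error = function(e) NULL),
         volume = tryCatch(anovaByCluster(vol[names(g)], g),
                           error = function(e) NULL))
  }
  for (grp in c("small", "large")) {
    sh <- report$shape[[grp]]
    if (!is.null(sh))
      out[[paste0("shape_", grp)]] <- addOne(sh$assignments, grp)
  }
  if (!is.null(report$texture))
    out$texture <- addOne(report$texture$assignments, "texture")
  out
}

normalizeManifest <- function(manifest) {
  if (is.data.frame(manifest)) {
    if (!nrow(manifest)) return(list())
    return(lapply(seq_len(nrow(manifest)), function(i)
      list(subject = as.character(manifest$subject[i]),
           volume = manifest$volume[i], mask = manifest$mask[i])))
  }
  if (is.list(manifest)) return(manifest)
  stop("manifest must be a data.frame or a list")
}

finishReport <- function(report, outputDir) {
  if (!is.null(outputDir)) writeReport(report, outputDir)
  report
}

#' One-way ANOVA with pairwise F tests and Bonferroni thresholds
#'
#' Overall one-way ANOVA of `values` across `groups`, plus all pairwise
#' two-group F tests. Raw p-values are reported together with the
#' Bonferroni-corrected significance thresholds `alpha / npairs`
#' ("significant") and `alphaHigh / npairs` ("highly significant"), and with
#' Bonferroni-adjusted p-values for convenience. Groups with fewer than two
#' members are excluded with a warning.
#'
#' @param values numeric response per observation.
#' @param groups cluster labels.
#' @param alpha,alphaHigh family-wise significance levels (defaults 0.05 and
#'   0.01); with 5 groups the pairwise thresholds are 0.05/10 = 5.0e-3 and
#'   0.01/10 = 1.0e-3.
#' @return list with `F`, `p`, `nGroups`, `pairs` (data.frame: groups, F,
#'   p, pBonferroni, significant, highlySignificant), and `thresholds`.
#' @export
anovaByCluster <- function(values, groups, alpha = 0.05, alphaHigh = 0.01) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.vector(groups)[ok]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding groups with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
  }
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stop("at least 2 groups with >= 2 members required")
  fit <- stats::anova(stats::lm(values ~ factor(groups)))
  npairs <- choose(length(lev), 2L)
  thrSig <- alpha / npairs; thrHigh <- alphaHigh / npairs
  cmb <- utils::combn(lev, 2L)
  pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1, i]; b <- cmb[2, i]
    sel <- groups %in% c(a, b)
    pf <- stats::anova(stats::lm(values[sel] ~ factor(groups[sel])))
    data.frame(group1 = a, group2 = b,
               F = pf$`F value`[1], p = pf$`Pr(>F)`[1])
  }))
  pairs$pBonferroni <- pmin(1, pairs$p * npairs)
  pairs$significant <- pairs$p < thrSig
  pairs$highlySignificant <- pairs$p < thrHigh
  list(F = fit$`F value`[1], p = fit$`Pr(>F)`[1], nGroups = length(lev),
       pairs = pairs,
       thresholds = list(alpha = alpha, alphaHigh = alphaHigh,
                         nPairs = npairs, significant = thrSig,
                         highlySignificant = thrHigh))
}

#' Write an analysis report to disk
#'
#' Serializes the tables of a [runPipeline()] report as CSV and the run
#' metadata (configuration, seed, gap curves, cluster dispersions) as JSON
#' under `dir`. Output is deterministic for a fixed report.
#'
#' @param report an `AnalysisReport`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) if (!is.null(x) && NROW(x))
    utils::write.csv(x, file.path(dir, name), row.names = FALSE)
  wcsv(report$lesions, "lesions.csv")
  wcsv(report$pgi, "pgi.csv")
  gapAsList <- function(g) list(k = g@k, Wk = g@Wk, gap = g@gap, sdk = g@sdk,
                                sk = g@sk, kHat = g@kHat, B = g@B, N = g@N)
  meta <- list(config = report$config[setdiff(names(report$config),
                                              "kOverride")],
               clusterings = list())
  for (grp in c("small", "large")) {
    sh <- report$shape[[grp]]
    if (is.null(sh)) next
    wcsv(sh$assignments, paste0("shape_clusters_", grp, ".csv"))
    meta$clusterings[[paste0("shape_", grp)]] <-
      list(k = sh$k, Wk = sh$model@Wk, gap = gapAsList(sh$gap),
           nComponents = attr(sh$scores, "nComponents"),
           representatives = sh$representatives)
  }
  if (!is.null(report$texture)) {
    wcsv(report$texture$assignments, "texture_clusters.csv")
    wcsv(cbind(lesion = rownames(report$texture$features),
               as.data.frame(report$texture$features)),
         "texture_features.csv")
    meta$clusterings$texture <- list(k = report$texture$model@k,
                                     Wk = report$texture$model@Wk,
                                     gap = gapAsList(report$texture$gap))
  }
  if (length(report$anova)) {
    meta$anova <- lapply(report$anova, function(a) lapply(a, function(b) {
      if (is.null(b)) return(NULL)
      list(F = b$F, p = b$p, thresholds = b$thresholds, pairs = b$pairs)
    }))
  }
  jsonlite::write_json(meta, file.path(dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
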