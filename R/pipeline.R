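## End-to-end orchestration: phantom -> parametric maps -> classifications
## -> recovery, mask-time-course, shell, edema and behaviour reports.

.studyGroups <- function(study) names(study@spect)

.studyDays <- function(study) study@spec@timepointsDays

#' Per-animal region rCBF means across a study
#'
#' Runs the parametric-map and region-averaging path for every animal and
#' requested timepoint, producing the long table that
#' [classifyRecovery()] consumes.
#'
#' @param study a \linkS4class{StudyDataset}.
#' @param days timepoints to analyse (default: all).
#' @param alpha Lassen parameter.
#' @return data.frame (region_id, hemisphere, group, day, animal, rcbf).
#' @export
studyRegionMeans <- function(study, days = .studyDays(study), alpha = 0.5) {
  out <- list()
  for (g in .studyGroups(study)) {
    for (an in names(study@spect[[g]])) {
      for (t in days) {
        vol <- study@spect[[g]][[an]][[paste0("d", t)]]
        pm <- parametricMap(vol, study@labels, alpha = alpha)
        rr <- regionRcbf(pm, study@labels, study@regionTable)
        rr$group <- g; rr$day <- t; rr$animal <- an
        out[[length(out) + 1L]] <- rr
      }
    }
  }
  do.call(rbind, out)
}

#' Per-animal perfusion classifications for selected timepoints
#'
#' @param study a \linkS4class{StudyDataset}.
#' @param days timepoints to classify.
#' @param alpha Lassen parameter.
#' @return nested list \code{[[group]][[animal]][[paste0("d", day)]]} of
#'   \linkS4class{PerfusionClassification}s.
#' @export
studyClassifications <- function(study, days = c(0, 7), alpha = 0.5) {
  res <- list()
  for (g in .studyGroups(study)) {
    arm <- list()
    for (an in names(study@spect[[g]])) {
      cls <- list()
      for (t in days) {
        vol <- study@spect[[g]][[an]][[paste0("d", t)]]
        pm <- parametricMap(vol, study@labels, alpha = alpha)
        cls[[paste0("d", t)]] <- classifyPerfusion(pm, study@healthyRef,
                                                   study@labels)
      }
      arm[[an]] <- cls
    }
    res[[g]] <- arm
  }
  res
}

#' Ipsilesional hypoperfused volumes per animal and timepoint
#'
#' @param classifications output of [studyClassifications()].
#' @return data.frame (group, animal, day, hypo_mm3).
#' @export
studyHypoVolumes <- function(classifications) {
  out <- list()
  for (g in names(classifications))
    for (an in names(classifications[[g]]))
      for (dn in names(classifications[[g]][[an]]))
        out[[length(out) + 1L]] <- data.frame(
          group = g, animal = an,
          day = as.numeric(sub("^d", "", dn)),
          hypo_mm3 = hypoperfusedVolume(classifications[[g]][[an]][[dn]],
                                        "left"))
  do.call(rbind, out)
}

#' Group-mean percent shrink of the hypoperfused volume between two days
#'
#' 100 * (V_day0 - V_day1) / V_day0 on the group-mean ipsilesional
#' hypoperfused volumes.
#'
#' @param hypoVolumes output of [studyHypoVolumes()].
#' @param from,to the two days (default 0 and 7).
#' @return named numeric, one entry per group.
#' @export
hypoVolumeShrink <- function(hypoVolumes, from = 0, to = 7) {
  sapply(split(hypoVolumes, hypoVolumes$group), function(d) {
    v0 <- mean(d$hypo_mm3[d$day == from])
    v1 <- mean(d$hypo_mm3[d$day == to])
    100 * (v0 - v1) / v0
  })
}

#' Day-0-mask mean rCBF contrast between arms
#'
#' Fixes each animal's day-0 ipsilesional hypoperfused volume (the
#' stroke-affected region) as a 3-D mask, computes the voxel-wise mean rCBF
#' inside the mask at the target day, averages per group, and reports
#' 100 * (treated - control) / control.
#'
#' @param study a \linkS4class{StudyDataset}.
#' @param classifications output of [studyClassifications()] containing
#'   day 0.
#' @param day target day (default 7).
#' @param alpha Lassen parameter.
#' @return list with the per-animal table, per-group means and
#'   \code{contrastPct}.
#' @export
maskMeanContrast <- function(study, classifications, day = 7, alpha = 0.5) {
  rows <- list()
  for (g in .studyGroups(study)) {
    for (an in names(study@spect[[g]])) {
      cl0 <- classifications[[g]][[an]][["d0"]]
      mask <- hypoMask(cl0) & cl0@hemispheres == 1L
      vol <- study@spect[[g]][[an]][[paste0("d", day)]]
      pm <- parametricMap(vol, study@labels, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, animal = an, day = day,
        mask_mean = mean(pm@values[mask & is.finite(pm@values)]))
    }
  }
  tab <- do.call(rbind, rows)
  gm <- tapply(tab$mask_mean, tab$group, mean)
  list(perAnimal = tab, groupMeans = gm,
       contrastPct = 100 * (gm[["treated"]] - gm[["control"]]) /
         gm[["control"]])
}

#' Day-0-mask time courses for every animal of a study
#'
#' Applies [trackDay0Mask()] per animal, with the ipsilesional day-0
#' hypoperfused volume as the mask, over all study timepoints.
#'
#' @param study a \linkS4class{StudyDataset}.
#' @param classifications output of [studyClassifications()] containing
#'   day 0.
#' @param alpha Lassen parameter.
#' @return nested list \code{[[group]][[animal]]} of
#'   \linkS4class{MaskTimeCourse}s.
#' @export
studyMaskTimeCourses <- function(study, classifications, alpha = 0.5) {
  days <- .studyDays(study)
  res <- list()
  for (g in .studyGroups(study)) {
    arm <- list()
    for (an in names(study@spect[[g]])) {
      series <- study@spect[[g]][[an]][paste0("d", days)]
      maps <- lapply(series, parametricMap, labels = study@labels,
                     alpha = alpha)
      cl0 <- classifications[[g]][[an]][["d0"]]
      mask <- hypoMask(cl0) & cl0@hemispheres == 1L
      arm[[an]] <- trackDay0Mask(maps, series, mask, study@labels, days)
    }
    res[[g]] <- arm
  }
  res
}

#' Group-averaged shell profile at one timepoint
#'
#' Averages the per-animal affected and total per-shell volumes of one
#' study arm.
#'
#' @param classifications output of [studyClassifications()].
#' @param group arm name.
#' @param day timepoint.
#' @param siteMM injection site (world mm).
#' @param binWidthMM shell width.
#' @return a \linkS4class{ShellProfile}.
#' @export
groupShellProfile <- function(classifications, group, day, siteMM,
                              binWidthMM = 1) {
  profs <- lapply(classifications[[group]], function(a)
    shellProfile(a[[paste0("d", day)]], siteMM, binWidthMM))
  nsh <- max(vapply(profs, function(p) length(p@affected), integer(1)))
  pad <- function(x, n) c(x, rep(0, n - length(x)))
  aff <- rowMeans(vapply(profs, function(p) pad(p@affected, nsh),
                         numeric(nsh)))
  tot <- rowMeans(vapply(profs, function(p) pad(p@total, nsh), numeric(nsh)))
  new("ShellProfile", edges = seq(0, nsh * binWidthMM, by = binWidthMM),
      affected = aff, total = tot, site = as.numeric(siteMM))
}

## tiny FNV-1a hash over the serialised configuration, for bundle
## self-validation without external digest dependencies
.configHash <- function(text) {
  bytes <- utf8ToInt(paste(text, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    ## xor only touches the low byte (b < 256); keep h as a double
    h <- (h %/% 256) * 256 + bitwXor(as.integer(h %% 256), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31) + 0L)  # printable, stable
}

.configYAML <- function(cfg)
  yaml::as.yaml(cfg[!vapply(cfg, is.null, logical(1))])

#' Run the full phantom-to-report pipeline
#'
#' Generates a phantom study, builds parametric maps, classifies perfusion,
#' tracks the day-0 mask, classifies region recovery, profiles recovery by
#' distance shell, quantifies edema, and aggregates behavioural scores.
#' When \code{config$outDir} is set, the bundle is serialised (TSV/JSON)
#' together with the configuration and its hash.
#'
#' @param config named list: \code{scenario} (default "reference_mcao"),
#'   \code{seed}, \code{alpha} (0.5), \code{sigLevel} (0.05),
#'   \code{shellBinWidthMM} (1), \code{classifyDays} (c(0, 7)),
#'   \code{outDir} (NULL = in-memory only), \code{spec} (optional list of
#'   [phantomSpec()] overrides).
#' @return invisible list with every stage's result.
#' @export
runFullStudy <- function(config = list()) {
  cfg <- utils::modifyList(
    list(scenario = "reference_mcao", seed = 1L, alpha = 0.5,
         sigLevel = 0.05, shellBinWidthMM = 1, classifyDays = c(0, 7),
         outDir = NULL, spec = list()),
    config)
  spec <- do.call(phantomSpec, c(list(seed = cfg$seed), cfg$spec))
  study <- generateStudy(spec, cfg$scenario)

  rmeans <- studyRegionMeans(study, alpha = cfg$alpha)
  recovery <- classifyRecovery(
    rmeans[, c("region_id", "hemisphere", "group", "day", "animal", "rcbf")],
    study@healthyRef, sigLevel = cfg$sigLevel)
  counts <- recoveryCounts(recovery, day = 7)

  cls <- studyClassifications(study, days = cfg$classifyDays,
                              alpha = cfg$alpha)
  hypo <- studyHypoVolumes(cls)
  shrink <- hypoVolumeShrink(hypo)
  maskC <- maskMeanContrast(study, cls, day = 7, alpha = cfg$alpha)
  timeCourses <- studyMaskTimeCourses(study, cls, alpha = cfg$alpha)

  shells <- list(
    treated = groupShellProfile(cls, "treated", 7, spec@injectionSiteMM,
                                cfg$shellBinWidthMM),
    control = groupShellProfile(cls, "control", 7, spec@injectionSiteMM,
                                cfg$shellBinWidthMM))
  shells$difference <- shellRecoveryDifference(shells$treated,
                                               shells$control)

  ## edema at the last timepoint with developed edema (day 7), one result
  ## per animal; day-0 anatomy has neither edema nor swelling
  edema <- list()
  for (g in .studyGroups(study)) {
    for (an in names(study@mri[[g]])) {
      mriVol <- study@mri[[g]][[an]][["d7"]]
      fit <- fitBackgroundGaussian(mriVol, study@mriLabels)
      edema[[paste(g, an, sep = ".")]] <-
        suppressWarnings(quantifyEdema(mriVol, study@mriLabels, fit))
    }
  }

  genScores <- cumulativeGeneral(study@scores)
  focScores <- cumulativeFocal(study@scores)
  cylinder <- suppressWarnings(cylinderAsymmetry(study@cylinder))
  behCompare <- lapply(sort(unique(genScores$day)), function(d) {
    g <- genScores[genScores$day == d, ]
    f <- focScores[focScores$day == d, ]
    cy <- cylinder[cylinder$day == d, ]
    list(day = d,
         general = groupCompare(g$general[g$group == "treated"],
                                g$general[g$group == "control"]),
         focal = groupCompare(f$focal[f$group == "treated"],
                              f$focal[f$group == "control"]),
         cylinder = groupCompare(cy$asymmetry[cy$group == "treated"],
                                 cy$asymmetry[cy$group == "control"]))
  })

  bundle <- list(config = cfg,
                 configHash = .configHash(trimws(.configYAML(cfg))),
                 spec = spec,
                 study = study, regionMeans = rmeans, recovery = recovery,
                 counts = counts, hypoVolumes = hypo, shrinkPct = shrink,
                 maskContrast = maskC, timeCourses = timeCourses,
                 shells = shells, edema = edema,
                 scores = list(general = genScores, focal = focScores,
                               cylinder = cylinder, compare = behCompare))
  if (!is.null(cfg$outDir)) .writeBundle(bundle, cfg$outDir)
  invisible(bundle)
}

.writeBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  writeLines(.configYAML(cfg), file.path(outDir, "config.yaml"))
  writeLines(bundle$configHash, file.path(outDir, "config.hash"))
  utils::write.table(bundle$recovery@table,
                     file.path(outDir, "recovery.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(bundle$hypoVolumes,
                     file.path(outDir, "hypo_volumes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeHealthyReference(bundle$study@healthyRef,
                        file.path(outDir, "healthy_reference.tsv"))
  writeRegionTable(bundle$study@regionTable,
                   file.path(outDir, "region_table.tsv"))
  edemaTab <- do.call(rbind, lapply(names(bundle$edema), function(k) {
    e <- bundle$edema[[k]]
    data.frame(id = k, threshold = e@threshold, raw_mm3 = e@rawEdemaVolume,
               ventricle_mm3 = e@ventricleVolume,
               corrected_mm3 = e@correctedInfarctVolume)
  }))
  utils::write.table(edemaTab, file.path(outDir, "edema.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  summaryJSON <- list(
    scenario = bundle$config$scenario, seed = bundle$config$seed,
    counts = list(
      affected = lapply(bundle$counts$groups, `[[`, "affected"),
      recovered = lapply(bundle$counts$groups, `[[`, "recovered"),
      shared = bundle$counts$shared,
      exclusive = as.list(bundle$counts$exclusive)),
    shrinkPct = as.list(bundle$shrinkPct),
    maskContrastPct = bundle$maskContrast$contrastPct)
  jsonlite::write_json(summaryJSON, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' Re-validate a written bundle against its stored configuration hash
#'
#' @param outDir a directory written by [runFullStudy()].
#' @return TRUE if the stored configuration re-hashes to the stored hash.
#' @export
validateBundle <- function(outDir) {
  cfgText <- trimws(paste(readLines(file.path(outDir, "config.yaml")),
                          collapse = "\n"))
  stored <- readLines(file.path(outDir, "config.hash"))[1]
  identical(.configHash(cfgText), stored)
}
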