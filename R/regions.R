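## Atlas-region statistics: exclusions, per-region rCBF, the
## regenerated/non-regenerated classification, and distance-shell profiles.

#' Mark atlas regions as excluded from analysis
#'
#' Exclusions are explicit flags, never silent deletions: the rows stay in
#' the table, carrying the reason, and every downstream operation skips
#' flagged regions. Typical use mirrors real atlas bookkeeping where some
#' regions hold no measurement data and others incomplete data.
#'
#' @param tb a region table (see [readRegionTable()]).
#' @param noData region ids without measurement data.
#' @param incomplete region ids with incomplete data.
#' @return the table with \code{excluded} and \code{exclusion_reason} set.
#' @examples
#' tb <- data.frame(region_id = 1:77, name = paste0("r", 1:77),
#'                  hemisphere = "both", cortical = TRUE, excluded = FALSE)
#' tb <- applyRegionExclusions(tb, noData = c(4, 13, 75),
#'                             incomplete = c(56, 71))
#' activeRegionCount(tb)  # 72
#' @export
applyRegionExclusions <- function(tb, noData = integer(), incomplete = integer()) {
  ids <- c(noData, incomplete)
  unknown <- setdiff(ids, tb$region_id)
  if (length(unknown))
    stop("unknown region id(s): ", paste(unknown, collapse = ", "))
  if (!"exclusion_reason" %in% names(tb)) tb$exclusion_reason <- ""
  tb$excluded[tb$region_id %in% ids] <- TRUE
  tb$exclusion_reason[tb$region_id %in% noData] <- "no_data"
  tb$exclusion_reason[tb$region_id %in% incomplete] <- "incomplete"
  tb
}

#' Per-region mean rCBF from a parametric map
#'
#' Averages the parametric-map voxels over each active (non-excluded)
#' region, separately per hemisphere. NaN voxels are excluded; a region with
#' no finite voxels in a hemisphere is reported with \code{NA} mean and
#' flagged missing. Excluded regions never appear in the output.
#'
#' @param map a \linkS4class{ParametricMap}.
#' @param labels a congruent \linkS4class{LabelVolume}.
#' @param tb a region table; only non-excluded rows are measured.
#' @return data.frame (region_id, hemisphere, rcbf, n_voxels, missing).
#' @export
regionRcbf <- function(map, labels, tb) {
  .stopIfNotCongruent(map, labels, "map and labels")
  active <- tb$region_id[!tb$excluded]
  v <- map@values
  sel <- labels@regions %in% active & labels@hemispheres %in% c(1L, 2L) &
    is.finite(v)
  fk <- paste(labels@regions[sel], labels@hemispheres[sel], sep = ":")
  mn <- tapply(v[sel], fk, mean)
  nv <- tapply(v[sel], fk, length)
  parts <- strsplit(names(mn), ":", fixed = TRUE)
  got <- data.frame(
    region_id = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    hemisphere = ifelse(vapply(parts, function(p) p[2], "") == "1",
                        "left", "right"),
    rcbf = as.numeric(mn), n_voxels = as.integer(nv))
  full <- expand.grid(region_id = active, hemisphere = c("left", "right"),
                      stringsAsFactors = FALSE)
  out <- merge(full, got, all.x = TRUE, sort = FALSE)
  out$n_voxels[is.na(out$n_voxels)] <- 0L
  out$missing <- !is.finite(out$rcbf)
  out[order(out$region_id, out$hemisphere), ]
}

## Welch two-sample t-test from summary statistics (the healthy reference
## stores only mean/sd/n). Degenerate zero-variance cases compare means with
## an absolute tolerance so that noise-free designs classify exactly.
.welchSummary <- function(m1, s1, n1, m2, s2, n2, tol = 1e-8) {
  se2 <- s1^2 / n1 + s2^2 / n2
  if (se2 <= 0)
    return(list(t = 0, df = NA_real_, p = if (abs(m1 - m2) <= tol) 1 else 0))
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Classify regions as regenerated or non-regenerated
#'
#' A region is \emph{affected at day 0} when its group day-0 mean rCBF lies
#' outside the healthy mean +/- 2 SD band. At each later timepoint an
#' affected region is \emph{recovered} when its group values are no longer
#' significantly below the healthy cohort (Welch two-sample t-test against
#' the cohort's summary statistics at \code{sigLevel}); a recovered region
#' whose mean exceeds the upper band is flagged
#' \code{hyper_after_recovery} (and still counts as recovered). With
#' \code{method = "band"} the significance test is replaced by the pure
#' +/- 2 SD band criterion. No multiple-testing correction is applied by
#' default; \code{adjust = "BH"} enables Benjamini-Hochberg across regions
#' within each group x timepoint.
#'
#' @param regionMeans long data.frame with columns \code{region_id},
#'   \code{group}, \code{day}, \code{animal}, \code{rcbf} (one row per
#'   animal x region x day; ipsilesional means). A \code{hemisphere} column,
#'   if present, is filtered to \code{"left"}.
#' @param healthy a \linkS4class{HealthyReference}; its \code{"left"} rows
#'   provide the bands and the cohort summary.
#' @param sigLevel significance level (default 0.05).
#' @param method \code{"ttest"} (default) or \code{"band"}.
#' @param adjust p-value adjustment method (default \code{"none"}).
#' @return a \linkS4class{RecoveryReport}.
#' @export
classifyRecovery <- function(regionMeans, healthy, sigLevel = 0.05,
                             method = c("ttest", "band"), adjust = "none") {
  method <- match.arg(method)
  rm <- regionMeans
  if ("hemisphere" %in% names(rm)) rm <- rm[rm$hemisphere == "left", ]
  rm <- rm[is.finite(rm$rcbf), ]
  ref <- healthy@table[healthy@table$hemisphere == "left", ]

  agg <- stats::aggregate(rcbf ~ region_id + group + day, rm,
                          function(x) c(mean(x), stats::sd(x), length(x)))
  out <- data.frame(region_id = agg$region_id, group = agg$group,
                    day = agg$day, mean = agg$rcbf[, 1], sd = agg$rcbf[, 2],
                    n = as.integer(agg$rcbf[, 3]))
  if (any(out$n < 2))
    stop("degenerate group size: every region x group x day needs >= 2 animals")
  out$se <- out$sd / sqrt(out$n)
  ri <- match(out$region_id, ref$region_id)
  if (any(is.na(ri)))
    stop("no healthy reference row for region(s): ",
         paste(unique(out$region_id[is.na(ri)]), collapse = ", "))
  hm <- ref$mean[ri]; hs <- ref$sd[ri]; hn <- ref$n[ri]
  if (any(hn < 2)) stop("healthy cohort must have n >= 2")
  tol <- 1e-8   # keeps degenerate zero-SD bands well defined
  lo <- hm - 2 * hs - tol; hi <- hm + 2 * hs + tol

  w <- mapply(function(m1, s1, n1, m2, s2, n2)
    unlist(.welchSummary(m1, s1, n1, m2, s2, n2)),
    out$mean, out$sd, out$n, hm, hs, hn)
  out$t <- w["t", ]; out$p_value <- w["p", ]
  if (adjust != "none")
    out$p_value <- stats::ave(out$p_value,
                              paste(out$group, out$day),
                              FUN = function(p) stats::p.adjust(p, adjust))

  ## affected at day 0: group day-0 mean outside the 95% band
  d0 <- out[out$day == min(out$day), ]
  affKey <- paste(d0$region_id, d0$group)
  d0lo <- ref$mean[match(d0$region_id, ref$region_id)] -
    2 * ref$sd[match(d0$region_id, ref$region_id)] - tol
  d0hi <- ref$mean[match(d0$region_id, ref$region_id)] +
    2 * ref$sd[match(d0$region_id, ref$region_id)] + tol
  affected <- d0$mean < d0lo | d0$mean > d0hi
  out$affected_day0 <- affected[match(paste(out$region_id, out$group),
                                      affKey)]

  sigBelow <- if (method == "ttest") out$p_value < sigLevel & out$mean < hm
              else out$mean < lo
  out$status <- ifelse(!out$affected_day0, "unaffected",
                ifelse(sigBelow, "non_regenerated",
                ifelse(out$mean > hi, "hyper_after_recovery", "recovered")))
  out <- out[order(out$group, out$day, out$region_id), ]
  rownames(out) <- NULL
  new("RecoveryReport", table = out, sigLevel = sigLevel, method = method)
}

#' Summary counts of a recovery report at one timepoint
#'
#' Recovered regions are those with status \code{recovered} or
#' \code{hyper_after_recovery}; counts of regions recovered exclusively in
#' one group and shared between groups satisfy
#' recovered = exclusive + shared for each group.
#'
#' @param report a \linkS4class{RecoveryReport}.
#' @param day the timepoint to summarise (default 7).
#' @param groups the two groups to compare (default treated vs control).
#' @return list with per-group affected and recovered counts, recovered
#'   region id sets, shared and exclusive counts.
#' @export
recoveryCounts <- function(report, day = 7,
                           groups = c("treated", "control")) {
  tb <- report@table
  recStat <- c("recovered", "hyper_after_recovery")
  res <- lapply(groups, function(g) {
    d0 <- tb[tb$group == g & tb$day == min(tb$day), ]
    dt <- tb[tb$group == g & tb$day == day, ]
    list(affected = sum(d0$affected_day0),
         affectedIDs = sort(d0$region_id[d0$affected_day0]),
         recovered = sum(dt$status %in% recStat),
         recoveredIDs = sort(dt$region_id[dt$status %in% recStat]),
         hyperAfterRecovery = sum(dt$status == "hyper_after_recovery"))
  })
  names(res) <- groups
  shared <- intersect(res[[1]]$recoveredIDs, res[[2]]$recoveredIDs)
  list(groups = res, day = day, shared = length(shared), sharedIDs = shared,
       exclusive = stats::setNames(
         c(length(setdiff(res[[1]]$recoveredIDs, res[[2]]$recoveredIDs)),
           length(setdiff(res[[2]]$recoveredIDs, res[[1]]$recoveredIDs))),
         groups))
}

#' Affected volume as a function of distance from the injection site
#'
#' Bins every classified brain voxel by the Euclidean distance of its centre
#' from the injection site and reports per-shell affected
#' (hypoperfused or hyperperfused) and total brain volumes. Shells partition
#' the brain: per-shell totals sum to the brain volume and per-shell
#' affected volumes sum to the total affected volume.
#'
#' @param classification a \linkS4class{PerfusionClassification}.
#' @param siteMM injection site in world coordinates (mm); must lie inside
#'   the volume's world bounds.
#' @param binWidthMM shell width (default 1 mm).
#' @return a \linkS4class{ShellProfile}.
#' @export
shellProfile <- function(classification, siteMM, binWidthMM = 1) {
  g <- .gridGeom(classification)
  loB <- g$origin; hiB <- g$origin + g$dim * g$spacing
  if (any(siteMM < loB) || any(siteMM > hiB))
    stop("injection site lies outside the volume's world bounds")
  cls <- as.vector(classification@classes)
  inBrain <- cls > 0L
  ctr <- .voxelCentres(classification)[inBrain, , drop = FALSE]
  d <- sqrt((ctr[, 1] - siteMM[1])^2 + (ctr[, 2] - siteMM[2])^2 +
              (ctr[, 3] - siteMM[3])^2)
  edges <- seq(0, (floor(max(d) / binWidthMM) + 1) * binWidthMM,
               by = binWidthMM)
  bin <- findInterval(d, edges, rightmost.closed = FALSE)
  vv <- prod(g$spacing)
  nsh <- length(edges) - 1L
  affected <- cls[inBrain] %in% c(1L, 3L)
  new("ShellProfile", edges = edges,
      affected = vv * tabulate(bin[affected], nsh),
      total = vv * tabulate(bin, nsh), site = as.numeric(siteMM))
}

#' Per-shell recovery difference between two arms
#'
#' Per shell, control affected volume minus treated affected volume: the
#' tissue volume recovered over the control level; may be negative. The
#' profiles must share identical shell edges.
#'
#' @param treated,control \linkS4class{ShellProfile}s with identical edges.
#' @return a \linkS4class{ShellProfile} whose \code{affected} slot holds the
#'   difference (control - treated) and whose \code{total} is the control
#'   per-shell total.
#' @export
shellRecoveryDifference <- function(treated, control) {
  if (length(treated@edges) != length(control@edges) ||
      any(abs(treated@edges - control@edges) > 1e-9))
    stop("mismatched shell edges")
  new("ShellProfile", edges = control@edges,
      affected = control@affected - treated@affected,
      total = control@total, site = control@site)
}
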