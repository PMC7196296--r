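## Neurological deficit scoring and cylinder-test aggregation.

.generalItems <- c(posture = 4L, activity = 4L, hair = 2L, eyes = 4L)
.focalItems <- c(body_symmetry = 4L, gait = 4L, limb_symmetry = 4L,
                 circling = 4L, whisker = 4L)
.scoreDays <- c(4, 8, 11, 15, 18, 21)

#' Validate a behavioural score sheet
#'
#' One row per animal x day with the general items posture (0-4),
#' activity (0-4), hair (0-2), eyes (0-4) and the focal items
#' body_symmetry, gait, limb_symmetry, circling, whisker (each 0-4), plus
#' \code{animal}, \code{group} and \code{day}. An out-of-range or missing
#' component raises an error naming it. Epileptic-behaviour,
#' circling-behaviour and climbing items are structurally absent from the
#' scheme.
#'
#' @param sheet data.frame candidate.
#' @return the validated sheet.
#' @export
validateScoreSheet <- function(sheet) {
  items <- c(.generalItems, .focalItems)
  need <- c("animal", "group", "day", names(items))
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("score sheet is missing column(s): ",
                         paste(miss, collapse = ", "))
  for (it in names(items)) {
    x <- sheet[[it]]
    if (any(is.na(x))) stop("missing ", it, " entry")
    if (any(x < 0 | x > items[[it]] | x != round(x)))
      stop(it, " out of range 0-", items[[it]])
  }
  if (!all(sheet$day %in% .scoreDays))
    warning("score days outside the usual schedule (",
            paste(.scoreDays, collapse = ","), ")")
  sheet
}

#' Cumulative general deficit score
#'
#' posture + activity + hair, range 0-10. The eyes item is never included:
#' eye condition recovers almost completely by day 8 in both arms, so it is
#' excluded from the cumulative general score.
#'
#' @param sheet a validated score sheet (see [validateScoreSheet()]).
#' @return data.frame (animal, group, day, general) per animal x day.
#' @examples
#' s <- data.frame(animal = "a1", group = "treated", day = 4, posture = 4,
#'                 activity = 4, hair = 2, eyes = 4, body_symmetry = 0,
#'                 gait = 0, limb_symmetry = 0, circling = 0, whisker = 0)
#' cumulativeGeneral(s)$general  # 10; eyes ignored
#' @export
cumulativeGeneral <- function(sheet) {
  sheet <- validateScoreSheet(sheet)
  data.frame(animal = sheet$animal, group = sheet$group, day = sheet$day,
             general = sheet$posture + sheet$activity + sheet$hair)
}

#' Cumulative focal deficit score
#'
#' Sum of the five focal items (body symmetry, gait, limb symmetry,
#' compulsory circling, whisker response), range 0-20.
#'
#' @param sheet a validated score sheet.
#' @return data.frame (animal, group, day, focal) per animal x day.
#' @export
cumulativeFocal <- function(sheet) {
  sheet <- validateScoreSheet(sheet)
  data.frame(animal = sheet$animal, group = sheet$group, day = sheet$day,
             focal = sheet$body_symmetry + sheet$gait + sheet$limb_symmetry +
               sheet$circling + sheet$whisker)
}

#' Cylinder-test forelimb asymmetry
#'
#' From impaired- and unimpaired-forelimb wall-touch counts (2-minute
#' sessions), reports the unimpaired-use fraction
#' unimpaired / (impaired + unimpaired); 0.5 is symmetric use, 1 is complete
#' neglect of the impaired forelimb. Sessions with zero total touches are
#' undefined and flagged, not dropped; raw counts are preserved so any other
#' index remains recomputable.
#'
#' @param rec data.frame with columns \code{animal}, \code{group},
#'   \code{day}, \code{impaired}, \code{unimpaired} (counts >= 0).
#' @return the record with added \code{asymmetry} (NA where undefined) and
#'   \code{undefined} flag.
#' @export
cylinderAsymmetry <- function(rec) {
  need <- c("animal", "group", "day", "impaired", "unimpaired")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("cylinder record is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(rec$impaired < 0 | rec$unimpaired < 0))
    stop("touch counts must be non-negative")
  total <- rec$impaired + rec$unimpaired
  rec$asymmetry <- ifelse(total > 0, rec$unimpaired / total, NA_real_)
  rec$undefined <- total == 0
  if (any(rec$undefined))
    warning(sum(rec$undefined), " session(s) with zero total touches: ",
            "asymmetry undefined")
  rec
}

#' Compare two groups with Welch's t-test and normality checks
#'
#' Unpaired two-sample (Welch) t-test with per-group mean +/- SEM and
#' Shapiro-Wilk normality p-values, the summary used for behavioural and
#' volumetric group contrasts.
#'
#' @param a,b numeric vectors of per-animal values (>= 3 each for the
#'   normality test; >= 2 for the t-test).
#' @return list with \code{t}, \code{df}, \code{p}, per-group \code{mean},
#'   \code{sem}, \code{n} and \code{shapiro_p}.
#' @export
groupCompare <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 finite values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    ## degenerate zero-variance case: equal means are indistinguishable
    tt <- list(statistic = c(t = if (mean(a) == mean(b)) 0 else Inf),
               parameter = c(df = length(a) + length(b) - 2),
               p.value = if (mean(a) == mean(b)) 1 else 0)
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
  }
  sw <- function(x) if (length(x) >= 3 && stats::sd(x) > 0)
    stats::shapiro.test(x)$p.value else NA_real_
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       mean = c(a = mean(a), b = mean(b)),
       sem = c(a = stats::sd(a) / sqrt(length(a)),
               b = stats::sd(b) / sqrt(length(b))),
       n = c(a = length(a), b = length(b)),
       shapiro_p = c(a = sw(a), b = sw(b)))
}
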