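#' Lassen's linearization correction for HMPAO uptake
#'
#' Converts the retained-tracer uptake ratio R (voxel activity over the
#' reference-region mean) into a relative flow ratio, compensating the
#' nonlinear retention-versus-flow relationship of lipophilic perfusion
#' tracers:
#' \deqn{F = \frac{\alpha R}{1 + (\alpha - 1) R}}
#' The transform fixes the reference anchor, F(1) = 1 for every alpha, is
#' strictly increasing in R on its domain, and reduces to the identity at
#' alpha = 1. For alpha < 1 it diverges at R = 1/(1 - alpha); ratios at or
#' beyond the pole are clamped just below it (ratio \code{poleMargin} of the
#' pole) and counted in the \code{"nClamped"} attribute.
#'
#' @param uptakeRatio non-negative scalar, vector or array of uptake ratios.
#' @param alpha Lassen parameter in (0, 1]; 0.5 is the conventional value
#'   for [99mTc]-HMPAO.
#' @param poleMargin clamp ratio relative to the pole (default 0.995).
#' @return relative rCBF values, same shape as \code{uptakeRatio}, with
#'   attribute \code{nClamped}.
#' @examples
#' lassenCorrect(1, 0.5)        # reference identity: 1
#' lassenCorrect(0.5, 0.5)      # 0.25 / 0.75 = 1/3
#' lassenCorrect(c(0.2, 0.8), 1)  # alpha = 1 is the identity
#' @export
lassenCorrect <- function(uptakeRatio, alpha = 0.5, poleMargin = 0.995) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  if (any(uptakeRatio < 0, na.rm = TRUE))
    stop("uptake ratios must be non-negative")
  r <- uptakeRatio
  nClamped <- 0L
  if (alpha < 1) {
    pole <- 1 / (1 - alpha)
    bad <- !is.na(r) & r >= pole * poleMargin
    nClamped <- sum(bad)
    if (nClamped > 0L) {
      warning(sprintf("%d uptake ratio(s) at or beyond the Lassen pole (R = %g) were clamped",
                      nClamped, pole))
      r[bad] <- pole * poleMargin
    }
  }
  f <- alpha * r / (1 + (alpha - 1) * r)
  attr(f, "nClamped") <- nClamped
  f
}

#' Inverse of Lassen's correction
#'
#' Maps a relative flow ratio back to the uptake ratio that produces it:
#' \code{R = F / (alpha + (1 - alpha) * F)}. Used by the phantom generator to
#' synthesise SPECT activity with designed rCBF.
#'
#' @param rcbf relative flow values (non-negative).
#' @param alpha Lassen parameter in (0, 1].
#' @return uptake ratios, same shape.
#' @export
lassenInvert <- function(rcbf, alpha = 0.5) {
  if (length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  rcbf / (alpha + (1 - alpha) * rcbf)
}
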