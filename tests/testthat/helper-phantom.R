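## Shared fixtures, built in code. The small grid keeps module tests fast;
## acceptance checks use the generator defaults.

.fixtureEnv <- new.env(parent = emptyenv())

smallSpec <- function(...) {
  base <- list(gridShape = c(32L, 36L, 24L), mriShape = c(24L, 28L, 16L),
               injectionSiteMM = c(-2.5, 0.3, 3), nHealthy = 4L,
               nPerGroup = 3L, timepointsDays = c(0, 3, 7), seed = 11L)
  do.call(phantomSpec, utils::modifyList(base, list(...)))
}

## one small reference_mcao study, generated once per test run
smallStudy <- function() {
  if (is.null(.fixtureEnv$study))
    .fixtureEnv$study <- generateStudy(smallSpec(), "reference_mcao")
  .fixtureEnv$study
}

smallCohort <- function() {
  if (is.null(.fixtureEnv$cohort))
    .fixtureEnv$cohort <- generateHealthyCohort(smallSpec())
  .fixtureEnv$cohort
}

## a synthetic two-hemisphere MRI: left = ipsilesional (first half of the
## x axis), right = contralesional
makeHemiMRI <- function(dm = c(40L, 40L, 40L), vox = 0.4,
                        intensities = function(n) rnorm(n, 100, 10)) {
  vals <- array(intensities(prod(dm)), dm)
  hemi <- array(2L, dm)
  hemi[seq_len(dm[1] %/% 2), , ] <- 1L
  list(mri = VolumeGrid(vals, spacing = vox, modality = "MRI"),
       labels = LabelVolume(array(0L, dm), hemi, spacing = vox))
}

## a valid one-row score sheet with overridable items
scoreRow <- function(...) {
  base <- list(animal = "a1", group = "treated", day = 4, posture = 0L,
               activity = 0L, hair = 0L, eyes = 0L, body_symmetry = 0L,
               gait = 0L, limb_symmetry = 0L, circling = 0L, whisker = 0L)
  as.data.frame(utils::modifyList(base, list(...)))
}
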