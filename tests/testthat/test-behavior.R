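test_that("cumulative scores hit the printed ranges with eyes excluded", {
  zero <- scoreRow()
  expect_equal(cumulativeGeneral(zero)$general, 0)
  expect_equal(cumulativeFocal(zero)$focal, 0)
  maxed <- scoreRow(posture = 4L, activity = 4L, hair = 2L, eyes = 4L,
                    body_symmetry = 4L, gait = 4L, limb_symmetry = 4L,
                    circling = 4L, whisker = 4L)
  expect_equal(cumulativeGeneral(maxed)$general, 10)  # eyes never included
  expect_equal(cumulativeFocal(maxed)$focal, 20)
})

test_that("out-of-range or missing score items are rejected by name", {
  expect_error(cumulativeGeneral(scoreRow(posture = 5L)), "posture")
  expect_error(cumulativeGeneral(scoreRow(hair = 3L)), "hair")
  bad <- scoreRow(); bad$whisker <- NULL
  expect_error(cumulativeFocal(bad), "whisker")
  na <- scoreRow(); na$whisker <- NA_integer_
  expect_error(cumulativeFocal(na), "whisker")
})

test_that("cumulative scores are monotone in every component", {
  base <- scoreRow(posture = 1L, activity = 1L, hair = 1L)
  for (item in c("posture", "activity", "hair")) {
    up <- base; up[[item]] <- up[[item]] + 1L
    expect_gt(cumulativeGeneral(up)$general, cumulativeGeneral(base)$general)
  }
})

test_that("cylinder asymmetry is the unimpaired-use fraction", {
  rec <- data.frame(animal = c("a", "b", "c"), group = "g", day = 4,
                    impaired = c(10, 0, 0), unimpaired = c(10, 20, 0))
  expect_warning(out <- cylinderAsymmetry(rec), "zero total")
  expect_equal(out$asymmetry[1:2], c(0.5, 1.0))
  expect_true(is.na(out$asymmetry[3]) && out$undefined[3])
  neg <- rec; neg$impaired[1] <- -1
  expect_error(cylinderAsymmetry(neg), "non-negative")
})

test_that("group comparison is calibrated and powered", {
  x <- c(1, 2, 3, 4)
  same <- groupCompare(x, x)
  expect_equal(same$p, 1)
  expect_equal(same$t, 0)

  set.seed(41)
  rej <- mean(replicate(1000, groupCompare(rnorm(8), rnorm(8))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.02)

  set.seed(42)
  strong <- groupCompare(rnorm(16, 0, 1), rnorm(15, 5, 1))
  expect_lt(strong$p, 0.01)
  expect_equal(unname(strong$n), c(16, 15))
  expect_true(all(strong$shapiro_p > 0, na.rm = TRUE))
  expect_error(groupCompare(1, c(1, 2)), "at least 2")
})
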