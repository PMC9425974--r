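mkProfile <- function(h, id = "p") {
  new("HomogeneityProfile", familyId = id, h = h,
      mask = rep("scored", length(h)), nSequences = 10L)
}

test_that("clade mean homogeneity pools scored columns and rejects degenerate means", {
  ctx <- cladeMeanHomogeneity(list(mkProfile(c(0.4, 0.6), "a"),
                                   mkProfile(c(0.8, 0.8), "b")))
  expect_equal(ctx@hT, 0.65)
  expect_equal(ctx@nColumnsTotal, 4L)

  # single profile: its own column mean
  solo <- cladeMeanHomogeneity(mkProfile(c(0.2, 0.4)))
  expect_equal(solo@hT, 0.3)

  # all-invariant clade is degenerate (h_T must stay below 1)
  expect_error(cladeMeanHomogeneity(mkProfile(c(1, 1, 1))), "degenerate")

  # pooled vs mean-of-means differ when profile lengths differ
  p1 <- mkProfile(c(0.2, 0.2, 0.2, 0.2), "a")
  p2 <- mkProfile(0.8, "b")
  expect_equal(cladeMeanHomogeneity(list(p1, p2))@hT, 0.32)
  expect_equal(cladeMeanHomogeneity(list(p1, p2),
                                    method = "mean-of-means")@hT, 0.5)
})

test_that("relative variability follows the clade-normalized formula", {
  expect_equal(relativeVariability(0.7, 0.7), 1)
  expect_equal(relativeVariability(1.0, 0.8), 0)
  expect_equal(relativeVariability(0.6, 0.8), (0.4 * 0.8) / (0.2 * 0.6),
               tolerance = 1e-12)
  # identity v(h, h) = 1 across the whole open interval
  for (h in seq(0.05, 0.95, by = 0.05))
    expect_equal(relativeVariability(h, h), 1, tolerance = 1e-12)
  expect_error(relativeVariability(0.5, 1.0), "strictly inside")
  expect_error(relativeVariability(0, 0.7), "zeroCap")
  expect_equal(relativeVariability(0, 0.7, zeroCap = 1e6), 1e6)
})

test_that("v is strictly decreasing in h_C for fixed h_T", {
  hC <- seq(0.05, 1, by = 0.05)
  for (hT in c(0.3, 0.6, 0.9)) {
    v <- relativeVariability(hC, hT)
    expect_true(all(diff(v) < 0))
  }
})

test_that("variability classes honor the printed thresholds with closed middle band", {
  expect_identical(classifyVariability(c(0.3, 1.0, 2.5)),
                   c("conserved", "intermediate", "variable"))
  # boundary values land in the intermediate band (outer classes are open)
  expect_identical(classifyVariability(c(0.5, 2.0)),
                   c("intermediate", "intermediate"))
  expect_identical(classifyVariability(0.499999), "conserved")
  expect_identical(classifyVariability(2.000001), "variable")
  expect_error(classifyVariability(-0.1), "negative")
})

test_that("position variability maps columns through the same transform", {
  ctx <- cladeMeanHomogeneity(mkProfile(c(0.7, 0.5, 0.9)))
  hT <- ctx@hT
  prof <- mkProfile(c(hT, 1, 0, 0.4))
  pos <- positionVariability(prof, ctx)
  expect_equal(pos$v[1], 1)
  expect_identical(pos$varClass[1], "intermediate")
  expect_equal(pos$v[2], 0)
  expect_identical(pos$varClass[2], "conserved")
  expect_equal(pos$v[3], 1e6)          # sentinel for h = 0
  expect_true(pos$sentinel[3])
  expect_identical(pos$varClass[3], "variable")
  expect_equal(pos$column, 0:3)        # 0-based indexing
})

test_that("position class fractions count scored positions only and sum to 1", {
  expect_equal(positionClassFractions(rep("intermediate", 5)),
               c(conserved = 0, intermediate = 1, variable = 0))
  expect_equal(positionClassFractions(c(rep("conserved", 3), "variable")),
               c(conserved = 0.75, intermediate = 0, variable = 0.25))
  # masked columns never reach the denominator: profile with NA columns
  prof <- new("HomogeneityProfile", familyId = "m",
              h = c(0.9, NA, 0.9), mask = c("scored", "skipped-singular",
                                            "scored"),
              nSequences = 5L)
  pos <- positionVariability(prof, cladeMeanHomogeneity(mkProfile(c(0.5, 0.7))))
  expect_equal(nrow(pos), 2)
  expect_equal(sum(positionClassFractions(pos$varClass)), 1)
})

test_that("family variability records are internally consistent", {
  profs <- lapply(1:4, function(i) {
    sim <- simulateFamilyAlignment(10, 80, theta = 0.1 * i,
                                   familyId = paste0("f", i),
                                   seed = 500 + i)
    homogeneityProfile(sim$alignment, bl62)
  })
  ctx <- cladeMeanHomogeneity(profs)
  tab <- do.call(rbind, lapply(profs, familyVariability, ctx = ctx))
  expect_equal(tab$vC,
               relativeVariability(tab$hC, ctx@hT), tolerance = 1e-12)
  expect_identical(tab$varClass, classifyVariability(tab$vC))
  expect_equal(tab$fConserved + tab$fIntermediate + tab$fVariable,
               rep(1, 4), tolerance = 1e-12)
})

test_that("mean variability rises with simulated divergence", {
  meanV <- vapply(c(0.05, 0.25, 0.5), function(theta) {
    profs <- lapply(1:5, function(i) {
      sim <- simulateFamilyAlignment(10, 60, theta = theta,
                                     seed = round(1e4 * theta) + i)
      homogeneityProfile(sim$alignment, bl62)
    })
    hT <- 0.6   # fixed external context so levels are comparable
    mean(vapply(profs, function(p)
      relativeVariability(meanHomogeneity(p), hT), 1))
  }, 1)
  expect_true(all(diff(meanV) > 0))
})

test_that("feature bins follow the printed edges and the one-third rule", {
  b <- binFeatures(paralogy = c(1.0, 2.0, 5.0), gainRate = c(0.4, 1.0, 3.0))
  expect_identical(as.character(b$paralogyBin), c("low", "medium", "high"))
  expect_identical(as.character(b$gainRateBin), c("low", "medium", "high"))
  # half-open edges: 1.25 and 3 go up, 0.5 and 2 go up
  b2 <- binFeatures(paralogy = c(1.25, 3), gainRate = c(0.5, 2))
  expect_identical(as.character(b2$paralogyBin), c("medium", "high"))
  expect_identical(as.character(b2$gainRateBin), c("medium", "high"))
  expect_false(binFeatures(1, 0, fracTM = 0.333)$membrane)
  expect_true(binFeatures(1, 0, fracTM = 0.34)$membrane)
  expect_true(binFeatures(1, 0, fracSignal = 1 / 3)$secreted)
  expect_error(binFeatures(0.9, 0), "paralogy")
})
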