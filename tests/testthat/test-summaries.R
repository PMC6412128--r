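trip <- fixtureTriplet()

test_that("licencing summaries use interpolated quartiles and handle degeneracy", {
  s <- sampleMatrix(4)
  s[, "q1"] <- c(0.1, 0.2, 0.3, 0.4)
  s[, "q2"] <- 1
  s[, "q3"] <- 0.7
  cs <- fakeChainSet(list(s))
  lic <- summarizeLicencing(cs)
  expect_equal(lic$median[1], 0.25)
  expect_equal(lic$lower[1], 0.175)  # type-7 quartile of {0.1..0.4}
  expect_equal(lic$upper[1], 0.325)
  # degenerate posterior collapses to the constant
  expect_equal(unlist(lic[2, c("lower", "median", "upper")]),
               c(lower = 1, median = 1, upper = 1))
  one <- fakeChainSet(list(sampleMatrix(1, q = c(0.4, 0.5, 0.6))))
  lic1 <- summarizeLicencing(one)
  expect_equal(lic1$median, lic1$lower)
  expect_equal(lic1$median, lic1$upper)
})

test_that("obscuring summaries report quartiles and Gaussian significance", {
  n <- 2000
  d <- matrix(0, n, 9)
  colnames(d) <- c("real1", "real2", "real3", "obsc12", "obsc13", "obsc21",
                   "obsc23", "obsc31", "obsc32")
  set.seed(6)
  d[, "obsc21"] <- rnorm(n, 0.14, 0.01)   # clearly non-zero obscuring
  cs <- fakeChainSet(list(sampleMatrix(n)), derived = list(d))
  ob <- summarizeObscuring(cs)
  expect_equal(nrow(ob), 6)
  row <- ob[ob$obscured == 2 & ob$by == 1, ]
  expect_lt(abs(row$median - 0.14), 0.002)
  expect_lt(row$p_zero, 1e-10)
  # all-zero rows are exactly zero with p_zero = 1
  zero <- ob[ob$obscured == 1 & ob$by == 2, ]
  expect_equal(zero$median, 0)
  expect_equal(zero$p_zero, 1)
  expect_true(all(ob$lower <= ob$median & ob$median <= ob$upper))
})

test_that("firing-order plug-in probability matches the Gaussian model", {
  expect_equal(round(probFiresEarlier(4667, 10873), 2), 0.33)
  expect_equal(round(probFiresEarlier(-12205, 15050), 2), 0.79)
  expect_equal(round(probFiresEarlier(-11582, 15138), 2), 0.78)
  expect_equal(probFiresEarlier(0, 10), 0.5)
  # exact complement symmetry
  for (d in c(-500, 0, 1234))
    expect_equal(probFiresEarlier(-d, 321) + probFiresEarlier(d, 321), 1)
  expect_error(probFiresEarlier(100, 0), "positive")
})

test_that("collision and firing-difference summaries read the latent snapshots", {
  # data generated with an unlicensable middle origin: only O1-O3 collisions
  truth <- firingParams(c(0, 0, 0), c(120, 120, 120), q = c(1, 0, 1))
  prof <- averageProfile(truth, trip, simConfig(M = 128, seed = 71))
  cnt <- generateCounts(prof, noiseParams(0.05, 15), seed = 72)
  cfg <- mcmcConfig(nChains = 1, M = 128, nSweeps = 6000, burnIn = 2500,
                    thin = 5, snapEvery = 5, nSub = 64, seed = 73,
                    quiet = TRUE)
  fit <- suppressWarnings(samplePosterior(cnt, trip, cfg))
  cd13 <- collisionDensity(fit, c(1, 3))
  # the dominant termination event is the direct O1-O3 collision
  expect_gt(cd13$realizedFraction, 0.5)
  expect_gt(length(cd13$points), 100)
  # collision positions live strictly inside the region
  expect_true(all(cd13$points > 200 & cd13$points < 2800))
  # the O1-O2 collision is correspondingly rare
  cd12 <- collisionDensity(fit, c(1, 2))
  expect_lt(cd12$realizedFraction, 0.5)
  expect_gt(cd13$realizedFraction, cd12$realizedFraction)
  fd <- firingDiffDensity(fit, c(1, 3))
  expect_false(fd$empty)
  expect_equal(fd$thresholds, c(-2600, 2600))
  # t3 - t1 roughly centred, spread ~ sqrt(2) * 120
  expect_lt(abs(mean(fd$diffs)), 150)
})

test_that("firing-difference density flags an empty conditioning set", {
  snap <- list(times = array(NA_real_, c(2, 4, 3)),
               licenced = array(0L, c(2, 4, 3)),
               realized = array(0L, c(2, 4, 3)), sample_index = 1:2)
  snap$licenced[, , 2] <- 1L   # only the middle origin ever licenced
  snap$times[, , 2] <- 0
  snap$realized[, , 2] <- 1L
  cs <- fakeChainSet(list(sampleMatrix(2)), snapshots = list(snap))
  fd <- firingDiffDensity(cs, c(1, 2))
  expect_true(fd$empty)
  expect_null(fd$density)
})

test_that("collision mass cannot extend beyond an obscured origin", {
  # strong obscuring of O2 from the left: O1-O2 collisions (when realized)
  # are truncated at x2
  set.seed(81)
  cells <- simulateCells(paramsObscured(), trip, 4000)
  coll <- collisionPoints(cells, trip)
  p12 <- coll$position[!is.na(coll$pair) & coll$pair == 12]
  expect_gt(length(p12), 100)
  expect_true(all(p12 <= 1500))
  # and the collision fractions match a brute-force recount from the same draws
  frac12 <- mean(apply(coll$pair == 12, 1, any, na.rm = TRUE))
  both <- cells$realized[, 1] == 1 & cells$realized[, 2] == 1
  expect_equal(frac12, mean(both))
})

test_that("firing-difference mass beyond +N equals the obscuring fraction", {
  set.seed(91)
  cells <- simulateCells(paramsObscured(), trip, 4000)
  both <- cells$licenced[, 1] == 1 & cells$licenced[, 2] == 1
  diffs <- cells$times[both, 2] - cells$times[both, 1]
  # t2 - t1 > N1 <=> O1's fork reaches O2 before it fires
  expect_equal(mean(diffs > 1300),
               mean(cells$obscured_by[both, 2] == 1), tolerance = 0.02)
})

test_that("replication-time reconstruction gives the exact sawtooth limit", {
  p <- firingParams(c(0, 0, 0), rep(1e-9, 3))
  nu <- 1.6  # budding-yeast fork velocity, kb/min
  rt <- medianReplicationTime(p, trip, nu = nu, anchor = 10, K = 200,
                              seed = 3)
  x <- rt@position
  nearest <- pmin(abs(x - 200), abs(x - 1500), abs(x - 2800))
  expect_equal(rt@median, nearest / (1000 * nu) + 10, tolerance = 1e-6)
  expect_equal(rt@p05, rt@p95, tolerance = 1e-6)
  # stochastic case: percentile ordering everywhere and origin-located minima
  rt2 <- medianReplicationTime(paramsStaggered(), trip, nu = 1.6, K = 500,
                               seed = 4)
  expect_true(all(rt2@p05 <= rt2@median & rt2@median <= rt2@p95))
  expect_error(medianReplicationTime(p, trip, nu = 0), "positive")
  expect_error(medianReplicationTime(p, trip, nu = 1, K = 10), "100")
})

test_that("summary report writes machine-readable JSON", {
  s1 <- sampleMatrix(50, mu = c(-100, 0, 100), q = c(0.9, 0.8, 1))
  set.seed(7)
  s1[, "q2"] <- runif(50, 0.7, 0.9)
  cs <- fakeChainSet(list(s1))
  f <- tempfile(fileext = ".json")
  rt <- medianReplicationTime(paramsSharp(), trip, nu = 1.6, K = 200,
                              seed = 5)
  writeSummaryReport(cs, f, replicationTime = rt)
  rep <- jsonlite::read_json(f)
  expect_true(all(c("licencing", "obscuring", "firing_order") %in% names(rep)))
  expect_equal(rep$firing_order$plug_in$pi_t2_lt_t1,
               probFiresEarlier(100, sqrt(2) * 100), tolerance = 1e-6)
  tsv <- read.delim(sub("\\.json$", "_reptime.tsv", f))
  expect_true(all(tsv$p05 <= tsv$median & tsv$median <= tsv$p95))
})
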