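trip <- fixtureTriplet()

test_that("fork collisions of a fully fired triplet land at the stated points", {
  # t = (0, 300, 200): x12 = (200+1500+300)/2 = 1000, x23 = (1500+2800-100)/2 = 2100
  st <- resolveCell(c(0, 300, 200), rep(TRUE, 3), trip)
  expect_false(st@prohibited)
  expect_true(all(st@realized))
  expect_equal(st@collisions$position, c(1000, 2100))
  # simultaneous firing: collisions at the midpoints, no obscuring
  st2 <- resolveCell(c(0, 0, 0), rep(TRUE, 3), trip)
  expect_equal(st2@collisions$position, c(850, 2150))
  expect_equal(st2@obscuredBy, rep(0L, 3))
})

test_that("a late middle origin is obscured by the earliest-arriving fork", {
  # O1 fork reaches x2 at 0 + 1300 < t2 = 2000; O3 fork arrives at 100 + 1300
  st <- resolveCell(c(0, 2000, 100), rep(TRUE, 3), trip)
  expect_equal(st@obscuredBy, c(0L, 1L, 0L))
  expect_equal(st@realized, c(TRUE, FALSE, TRUE))
  expect_equal(st@collisions$position, (200 + 2800 + 100 - 0) / 2)  # 1550
})

test_that("prohibited states are flagged: overrun end origins and empty cells", {
  expect_true(resolveCell(c(0, 0, 0), c(TRUE, FALSE, FALSE), trip)@prohibited)
  expect_true(resolveCell(c(0, 0, 0), c(FALSE, FALSE, TRUE), trip)@prohibited)
  expect_true(resolveCell(c(0, 0, 0), rep(FALSE, 3), trip)@prohibited)
  # a lone middle origin is admissible (profile steps at x2)
  expect_false(resolveCell(c(0, 0, 0), c(FALSE, TRUE, FALSE), trip)@prohibited)
  # a degenerate regime errors out of the generator
  expect_error(
    simulateCell(firingParams(c(0, 0, 0), rep(1, 3), q = c(1, 0, 0)), trip,
                 maxResample = 50),
    "degenerate")
})

test_that("single-cell profile follows the origin/collision breakpoints", {
  st <- resolveCell(c(0, 300, 200), rep(TRUE, 3), trip)
  p <- cellProfile(st, trip, sBox = 50)
  mid <- attr(p, "boxStart") + 25
  expect_equal(as.vector(p),
               as.integer(mid < 1000 | (mid >= 1500 & mid < 2100)))
  # flipping the strand convention flips the profile
  expect_equal(as.vector(cellProfile(st, trip, 50, strandConvention = FALSE)),
               as.vector(1L - p))
  # O2 unlicenced, t1 = t3: single breakpoint at the region midpoint
  st2 <- resolveCell(c(50, 0, 50), c(TRUE, FALSE, TRUE), trip)
  p2 <- cellProfile(st2, trip, 50)
  expect_equal(as.vector(p2), as.integer(mid < 1500))
  st3 <- resolveCell(c(0, 0, 0), c(TRUE, FALSE, FALSE), trip)
  expect_error(cellProfile(st3, trip), "prohibited")
})

test_that("averaged profiles satisfy the structural invariants", {
  scenarios <- list(paramsSharp(), paramsStaggered(), paramsObscured(),
                    firingParams(c(100, 100, 100), rep(100, 3),
                                 q = c(1, 0.3, 1)))
  for (s in seq_along(scenarios)) {
    cfg <- simConfig(M = 400, seed = 40 + s)
    prof <- averageProfile(scenarios[[s]], trip, cfg)
    v <- profileValues(prof)
    expect_true(all(v >= 0 & v <= 1))
    # every value a multiple of 1/M
    expect_equal(round(v * cfg@M), v * cfg@M, tolerance = 1e-9)
    # non-increasing strictly between origins, non-negative jumps at origins
    mids <- boxMids(prof)
    pos <- originPositions(trip)
    seg <- findInterval(mids, pos)
    for (k in 1:2) {
      inside <- which(seg == k)
      dif <- diff(v[inside])
      expect_true(all(dif <= 1e-12))
    }
    # the jump at the middle origin is non-negative (the last box lies left
    # of x3, so only the interior origin's jump is observable)
    before <- max(which(mids < pos[2]))
    expect_gte(v[before + 1] - v[before], 0)
  }
})

test_that("deterministic firing gives the ideal step profile", {
  p <- firingParams(c(0, 0, 0), rep(1e-9, 3))
  prof <- averageProfile(p, trip, simConfig(M = 16, seed = 1))
  v <- profileValues(prof)
  mid <- boxMids(prof)
  expect_equal(v, as.numeric(mid < 850 | (mid >= 1500 & mid < 2150)))
})

test_that("recentring makes the profile invariant to mu translation", {
  a <- firingParams(c(0, 700, 1000), c(100, 100, 264))
  b <- firingParams(c(500, 1200, 1500), c(100, 100, 264))
  expect_equal(a@mu, b@mu)
  pa <- averageProfile(a, trip, simConfig(M = 200, seed = 9))
  pb <- averageProfile(b, trip, simConfig(M = 200, seed = 9))
  expect_identical(profileValues(pa), profileValues(pb))
})

test_that("two-origin closed form matches its stated values and limits", {
  # midpoint shifted by the mean difference -> exactly 1/2
  expect_equal(twoOriginProfile((200 + 1500 + 700) / 2, 200, 1500, 0, 700,
                                100, 100), 0.5)
  # x at 1100: Phi((700 + 1700 - 2200)/sqrt(2e4)) = Phi(1.414) = 0.921
  expect_equal(twoOriginProfile(1100, 200, 1500, 0, 700, 100, 100),
               pnorm(200 / sqrt(2e4)), tolerance = 1e-12)
  expect_equal(round(twoOriginProfile(1100, 200, 1500, 0, 700, 100, 100), 3),
               0.921)
  # near the left origin with a much later right origin -> 1
  expect_gt(twoOriginProfile(201, 200, 1500, 0, 5000, 100, 100), 0.999999)
  expect_error(twoOriginProfile(500, 200, 1500, 0, 0, -1, 100), "positive")
})

test_that("simulated two-origin profile tracks the closed form box by box", {
  p <- firingParams(c(0, 0, 700), c(100, 1, 100), q = c(1, 0, 1))
  M <- 2000
  prof <- averageProfile(p, trip, simConfig(M = M, seed = 12))
  expected <- twoOriginProfile(boxMids(prof), 200, 2800, p@mu[1], p@mu[3],
                               100, 100)
  tol <- 3 * sqrt(expected * (1 - expected) / M) + 0.5 / M
  expect_true(all(abs(profileValues(prof) - expected) <= tol))
})

test_that("one-sided obscuring probability matches the fork-arrival law", {
  # obscured-middle scenario: Phi(102/219.9) = 0.679
  expect_equal(obscuringProbability(-602, 196, 800, 100, 1300),
               pnorm((800 + 602 - 1300) / sqrt(196^2 + 100^2)))
  expect_equal(round(obscuringProbability(-602, 196, 800, 100, 1300), 3), 0.679)
  # delay equal to the distance -> 1/2
  expect_equal(obscuringProbability(0, 50, 1300, 50, 1300), 0.5)
  # tight firing with delay below the distance -> 0
  expect_lt(obscuringProbability(0, 1e-3, 1000, 1e-3, 1300), 1e-12)
  expect_error(obscuringProbability(0, 50, 0, 50, -5), "positive")
})

test_that("middle-origin obscuring frequency matches the closed form", {
  # O1 fires ~N1 rbp earlier than O2 (so ~50% left-obscuring) while O3 fires
  # early enough that its forks essentially never interfere at O2 and no
  # prohibited states arise
  p <- firingParams(c(-650, 650, 0), c(150, 150, 150))
  n <- 4000
  set.seed(77)
  cells <- simulateCells(p, trip, n)
  obs <- mean(cells$obscured_by[, 2] == 1)
  expected <- obscuringProbability(p@mu[1], 150, p@mu[2], 150, 1300)
  expect_lt(abs(obs - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("collision points are Normal about the displaced midpoint", {
  p <- paramsSharp()  # no obscuring at these spacings
  set.seed(5)
  cells <- simulateCells(p, trip, 5000)
  coll <- collisionPoints(cells, trip)
  pts <- coll$position[!is.na(coll$pair) & coll$pair == 12]
  ks <- suppressWarnings(
    ks.test(pts, "pnorm", mean = (200 + 1500) / 2, sd = sqrt(2 * 100^2) / 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("averaged profiles export to bedGraph and tables faithfully", {
  prof <- averageProfile(paramsSharp(), trip, simConfig(M = 64, seed = 2))
  bg <- tempfile(fileext = ".bedGraph")
  exportProfile(prof, bg, format = "bedGraph")
  gr <- rtracklayer::import(bg, format = "bedGraph")
  expect_equal(GenomicRanges::start(gr) - 1, boxStarts(prof))
  expect_equal(gr$score, profileValues(prof))
  tb <- tempfile(fileext = ".tsv")
  exportProfile(prof, tb, format = "table")
  tab <- read.delim(tb)
  expect_equal(tab$F_ave, profileValues(prof))
})

test_that("cell batches flatten to a debuggable table", {
  set.seed(3)
  cells <- simulateCells(paramsStaggered(), trip, 10)
  tab <- cellTable(cells)
  expect_equal(nrow(tab), 30)
  expect_true(all(tab$realized[tab$realized] %in% tab$licenced[tab$realized]))
  expect_true(all(is.na(tab$time[!tab$licenced])))
})
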