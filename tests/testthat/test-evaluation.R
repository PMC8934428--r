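# exhaustive oracles, independent of the implementation under test
oracleRocAuc <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}
oraclePrAuc <- function(p, y) {
  th <- sort(unique(p), decreasing = TRUE)
  prevR <- 0; area <- 0
  for (t in th) {
    tp <- sum(p >= t & y == 1); fp <- sum(p >= t & y == 0)
    prec <- tp / (tp + fp); rec <- tp / sum(y == 1)
    area <- area + prec * (rec - prevR)
    prevR <- rec
  }
  area
}
# greedy earliest-first suppression: keep t unless within win of the last
# kept event
oracleDedup <- function(times, win = 5) {
  times <- sort(times)
  kept <- numeric(0)
  for (t in times) {
    if (!length(kept) || t > kept[length(kept)] + win) kept <- c(kept, t)
  }
  kept
}

test_that("AUC matches exhaustive oracles on 500 random small instances", {
  set.seed(123)
  for (i in 1:500) {
    n <- sample(4:20, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))  # both classes present
    p <- round(runif(n), sample(c(1, 2, 7), 1))       # induce ties sometimes
    expect_equal(aucScore(p, y, "roc"), oracleRocAuc(p, y))
    expect_equal(aucScore(p, y, "pr"), oraclePrAuc(p, y))
  }
})

test_that("AUC endpoints: perfect separation and exchangeable labels", {
  y <- rep(c(0, 1), each = 20)
  p <- c(runif(20, 0, 0.4), runif(20, 0.6, 1))
  expect_equal(aucScore(p, y, "roc"), 1)

  set.seed(99)
  nulls <- vapply(1:100, function(i) {
    yy <- sample(rep(0:1, each = 25))
    aucScore(runif(50), yy, "roc")
  }, numeric(1))
  expect_lt(abs(mean(nulls) - 0.5), 0.05)

  expect_error(aucScore(runif(5), rep(1, 5)), "both classes")
})

test_that("thresholding emits one event per qualifying second", {
  p <- c(0.2, 0.7, 0.4)
  ev <- thresholdDetections(p, 0.5)
  expect_equal(ev$time, 1)          # second index 1 (0-based start times)
  expect_equal(nrow(thresholdDetections(p, 0)), 3)
  expect_equal(nrow(thresholdDetections(p, 0.9)), 0)
})

test_that("event metrics implement greedy 5 s deduplication and delay", {
  ann <- seizureAnnotations(1000, 1010)
  ev <- data.frame(time = c(100, 102, 104, 110), insideSeizure = FALSE)
  m <- eventMetrics(ev, ann, recordHours = 1)
  expect_equal(m$falseEvents, 2)    # 100 suppresses 102 and 104; 110 counted
  expect_equal(m$fdrPerHour, 2)
  expect_equal(m$sensitivity, 0)

  ev2 <- data.frame(time = c(1003), insideSeizure = TRUE)
  m2 <- eventMetrics(ev2, ann, recordHours = 1)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$meanDelay, 3)
  expect_equal(m2$fdrPerHour, 0)

  expect_error(eventMetrics(ev, ann, recordHours = 0), "positive")
})

test_that("deduplication matches a brute-force oracle on 200 random sets", {
  set.seed(7)
  ann <- seizureAnnotations(10000, 10010)   # events below are all false
  for (i in 1:200) {
    times <- sort(sample(seq(0, 120, by = 0.5), sample(1:40, 1)))
    ev <- data.frame(time = times, insideSeizure = FALSE)
    m <- eventMetrics(ev, ann, recordHours = 2)
    expect_equal(m$falseEvents, length(oracleDedup(times)))
    # dedup never exceeds the raw count
    expect_lte(m$falseEvents, length(times))
  }
})

test_that("event metrics are invariant to adding suppressed duplicates", {
  ann <- seizureAnnotations(500, 510)
  base <- data.frame(time = c(20, 40, 503), insideSeizure = c(FALSE, FALSE, TRUE))
  dup <- rbind(base, data.frame(time = c(21, 23, 41), insideSeizure = FALSE))
  m1 <- eventMetrics(base, ann, 1)
  m2 <- eventMetrics(dup, ann, 1)
  expect_equal(m1$falseEvents, m2$falseEvents)
  expect_equal(m1$sensitivity, m2$sensitivity)
  expect_equal(m1$meanDelay, m2$meanDelay)
})

test_that("F1-optimal threshold maximizes F1 with ties toward higher theta", {
  r <- f1OptimalThreshold(c(.1, .2, .6, .7, .8, .9), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$threshold, 0.7)
  expect_equal(r$f1, 1)

  # all-identical probabilities: the single candidate wins
  r2 <- f1OptimalThreshold(rep(0.5, 6), c(0, 0, 1, 1, 1, 1))
  expect_equal(r2$threshold, 0.5)
  expect_equal(r2$f1, 2 * 4 / (2 * 4 + 2 + 0))

  expect_error(f1OptimalThreshold(runif(4), rep(0, 4)), "both classes")
})

test_that("early labels are a subset of the standard ictal labels", {
  ann <- seizureAnnotations(c(30, 100), c(60, 104))
  starts <- 0:119
  full <- windowLabels(starts, ann)
  early <- earlyLabels(starts, ann)
  pos <- which(!is.na(early) & early == 1)
  expect_true(all(full[pos] == 1))          # early positives are ictal
  expect_true(all(is.na(early[full == 1 & starts >= 40 & starts < 60])))
  # short seizure (< 10 s) is entirely early-detectable
  expect_true(all(early[starts >= 100 & starts < 104] == 1, na.rm = TRUE))
})
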