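# Block-maxima deviance summaries, FDR maps and tail correlations.

test_that("constant Z rows give their common value in every mode", {
  z <- matrix(2.5, 3, 120)
  d <- summarizeDeviance(z)
  expect_equal(d$positive, rep(2.5, 3))
  expect_equal(d$absolute, rep(2.5, 3))
  # the bottom tail of an all-positive map is still the constant itself
  expect_equal(d$negative, rep(2.5, 3))
  dn <- summarizeDeviance(-z)
  expect_equal(dn$negative, rep(-2.5, 3))
})

test_that("tail and trim arithmetic matches direct enumeration", {
  z <- matrix(seq_len(1000) / 1000, 1, 1000)
  # untrimmed mean of the 10 largest values
  d0 <- summarizeDeviance(z, modes = "positive", tailFraction = 0.01,
                          trimTotal = 0)
  expect_equal(d0$positive, mean(seq(0.991, 1, by = 0.001)))
  expect_equal(d0$positive, 0.9955)
  # 90% trim keeps the central survivors of the sorted tail block
  d9 <- summarizeDeviance(z, modes = "positive", tailFraction = 0.01,
                          trimTotal = 0.90)
  expect_equal(d9$positive, oracleTailTrim(z[1, ], 0.01, 0.90))
  expect_equal(d9$positive, mean(c(0.995, 0.996)))
})

test_that("trimmed tail mean agrees with enumeration across random cases", {
  set.seed(31)
  for (rep in 1:20) {
    v <- rnorm(sample(50:400, 1))
    tf <- sample(c(0.01, 0.05, 0.1), 1)
    tt <- sample(c(0, 0.5, 0.9), 1)
    got <- summarizeDeviance(matrix(v, 1), modes = "absolute",
                             tailFraction = tf, trimTotal = tt)$absolute
    expect_equal(got, oracleTailTrim(abs(v), tf, tt))
  }
})

test_that("signed modes respond only to their own tail", {
  set.seed(77)
  z0 <- matrix(rnorm(40 * 500), 40, 500)
  z1 <- z0
  z1[1:10, 1:5] <- z1[1:10, 1:5] - 6  # plant negative deviations only
  d0 <- summarizeDeviance(z0)
  d1 <- summarizeDeviance(z1)
  expect_true(all(d1$negative[1:10] < d0$negative[1:10]))
  expect_true(all(d1$absolute[1:10] > d0$absolute[1:10]))
  # positive deviance of planted subjects stays within the null spread
  spread <- range(d0$positive)
  expect_true(all(d1$positive[1:10] >= spread[1] - 0.5 &
                  d1$positive[1:10] <= spread[2] + 0.5))
})

test_that("raising a retained tail value never lowers absolute deviance", {
  set.seed(13)
  for (rep in 1:10) {
    v <- rnorm(200)
    base <- summarizeDeviance(matrix(v, 1), modes = "absolute",
                              tailFraction = 0.05)$absolute
    j <- which.max(abs(v))
    v2 <- v
    v2[j] <- sign(v[j]) * (abs(v[j]) + runif(1, 0, 3))
    bumped <- summarizeDeviance(matrix(v2, 1), modes = "absolute",
                                tailFraction = 0.05)$absolute
    expect_gte(bumped, base - 1e-12)
  }
})

test_that("all-NA subjects are reported by name", {
  z <- matrix(rnorm(200), 2, 100, dimnames = list(c("good", "bad"), NULL))
  z["bad", ] <- NA
  expect_error(summarizeDeviance(z), "bad")
})

test_that("BH step-up matches the enumeration oracle", {
  # worked example: first three rejected, last retained
  p <- c(0.001, 0.02, 0.03, 0.5)
  z <- qnorm(p / 2)  # two-sided p recovers these exactly
  res <- fdrMap(z, q = 0.05)
  expect_equal(res$p, p, tolerance = 1e-12)
  expect_equal(res$mask, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$mask, oracleBHReject(p, 0.05))
  set.seed(19)
  for (rep in 1:25) {
    zz <- rnorm(sample(5:200, 1), sd = sample(1:3, 1))
    got <- fdrMap(zz, q = 0.05)
    expect_equal(got$mask, oracleBHReject(got$p, 0.05))
  }
})

test_that("zero Z scores are never rejected and NAs pass through", {
  res <- fdrMap(rep(0, 50))
  expect_false(any(res$mask))
  res2 <- fdrMap(c(NA, 5, 0.1, NA))
  expect_true(is.na(res2$mask[1]) && res2$mask[2])
  expect_error(fdrMap(numeric(0)), "empty")
})

test_that("deviant location counts aggregate FDR masks per location", {
  z <- matrix(0, 4, 6)
  z[1, 2] <- z[2, 2] <- z[3, 2] <- 8
  z[1, 5] <- -8
  res <- fdrMap(z)
  expect_equal(unname(deviantLocationCounts(res$mask)), c(0, 3, 0, 0, 1, 0))
})

test_that("tail correlation is exact under linearity and reduces to Pearson at fraction 1", {
  set.seed(23)
  dev <- sort(rnorm(60), decreasing = TRUE)
  sym <- 2 * dev + 5
  tc <- tailCorrelation(dev, sym, topFractions = c(0.1, 1))
  expect_equal(tc$r, c(1, 1), tolerance = 1e-12)
  sym2 <- sym + rnorm(60)
  tc2 <- tailCorrelation(dev, sym2, topFractions = 1)
  ct <- cor.test(dev, sym2)
  expect_equal(tc2$r, unname(ct$estimate))
  expect_equal(tc2$p, ct$p.value)
  expect_equal(tc2$n, 60)
})

test_that("negative-mode ranking uses deviance magnitude", {
  dev <- c(-5, -1, -3, -0.5)       # negative deviances
  sym <- c(10, 1, 6, 0.2)          # grows with magnitude
  tc <- tailCorrelation(dev, sym, topFractions = 0.75, mode = "negative")
  expect_equal(tc$n, 3)
  expect_gt(tc$r, 0.9)             # computed on magnitudes
  expect_error(tailCorrelation(dev, sym, topFractions = 0.25), "need >= 3")
  expect_true(is.na(tailCorrelation(dev, rep(1, 4), topFractions = 1)$r))
})

test_that("planted deviance-symptom links are strongest in the extreme tail", {
  # outliers whose symptom is a monotone function of the planted deviation
  # plus noise, against a null bulk that overlaps the weaker outliers: the
  # extreme tail isolates the tightly linked subjects, wider fractions
  # dilute the correlation with unlinked subjects
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 500
    dev <- abs(rnorm(n, 2.2, 0.6))         # null deviance bulk
    sym <- rgamma(n, 2, scale = 1.2)       # unlinked symptoms
    out <- sample(n, 15)
    mag <- 2.6 + rexp(15, 1 / 2)           # heavy-tailed planted deviations
    dev[out] <- mag + rnorm(15, sd = 0.3)
    sym[out] <- 2 + 2.5 * (mag - 2.6) + rnorm(15, sd = 0.3)
    tc <- tailCorrelation(dev, sym, topFractions = c(0.01, 0.2))
    tc$r[1] > tc$r[2] && all(tc$r > 0)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
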