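test_that("dilution ladders enforce the two-fold structure", {
  lad <- dilution_ladder(c(78, 156, 312, 625, 1250))
  expect_s3_class(lad, "dilution_ladder")
  expect_error(dilution_ladder(c(78, 100)), "1.9")
  expect_error(dilution_ladder(c(156, 78)), "increasing")
  expect_error(dilution_ladder(c(-1, 2)), "positive")
})

test_that("ladder validation flags off-ladder cells and nothing else", {
  lad <- dilution_ladder(c(78, 156, 312, 625, 1250))
  mic <- bp_mic()
  expect_equal(nrow(validate_mic_series(mic, lad)), 0)
  bad <- mic
  bad$mic[bad$organism == "E. coli" & bad$compound == "2a"] <- 100
  v <- validate_mic_series(bad, lad)
  expect_equal(nrow(v), 1)
  expect_equal(v$organism, "E. coli")
  expect_equal(v$compound, "2a")
  expect_equal(v$mic, 100)
  empty <- mic
  empty$mic <- NA_real_
  expect_equal(nrow(validate_mic_series(empty, lad)), 0)
})

test_that("MIC summaries find best compounds per organism", {
  s <- mic_summary(bp_mic())
  alb <- s$best_by_organism[s$best_by_organism$organism == "C. albicans", ]
  expect_equal(alb$best_mic, 78)
  expect_equal(alb$compounds, "2d,2f")
  one <- mic_summary(tibble::tibble(organism = "o", compound = "c", mic = 312))
  expect_equal(one$best_by_organism$compounds, "c")
  tiedm <- tidyr::expand_grid(organism = "o", compound = c("a", "b", "c"))
  tiedm$mic <- 625
  expect_equal(mic_summary(tiedm)$best_by_organism$compounds, "a,b,c")
  expect_error(mic_summary(tibble::tibble(organism = "o", compound = "c",
                                          mic = NA_real_)), "tested")
})

test_that("the ANOVA decomposition matches hand and brute-force oracles", {
  d <- tibble::tibble(y = c(1, 2, 3, 2, 3, 4), g = rep(c("a", "b"), each = 3))
  fit <- one_way_anova(d, y, g)
  expect_equal(fit$F, 1.5)
  expect_equal(c(fit$df_between, fit$df_within), c(1, 4))
  expect_equal(fit$ss_between, 1.5)
  expect_equal(fit$ss_within, 4)
  # identical groups: F = 0, p = 1
  d0 <- tibble::tibble(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  fit0 <- one_way_anova(d0, y, g)
  expect_equal(fit0$F, 0)
  expect_equal(fit0$p, 1)
  # two groups: F equals the squared pooled t statistic
  set.seed(21)
  d2 <- tibble::tibble(y = c(rnorm(6), rnorm(8, 1)),
                       g = rep(c("a", "b"), c(6, 8)))
  tt <- stats::t.test(y ~ g, data = d2, var.equal = TRUE)
  f2 <- one_way_anova(d2, y, g)
  expect_equal(f2$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(f2$p, tt$p.value, tolerance = 1e-12)
  # random layouts against base aov() as the independent route
  for (i in 1:20) {
    k <- sample(2:5, 1)
    ns <- sample(2:7, k, replace = TRUE)
    dd <- tibble::tibble(g = rep(letters[1:k], ns),
                         y = rnorm(sum(ns), rep(rnorm(k, sd = 2), ns)))
    fit <- one_way_anova(dd, y, g)
    ref <- summary(stats::aov(y ~ g, data = dd))[[1]]
    expect_equal(fit$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(fit$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(fit$ss_between, ref$`Sum Sq`[1], tolerance = 1e-10)
    expect_equal(fit$ss_within, ref$`Sum Sq`[2], tolerance = 1e-10)
  }
  expect_error(one_way_anova(d[1:3, ], y, g), "two groups")
})

test_that("ANOVA holds its nominal type-I error under the null", {
  set.seed(99)
  n_rep <- 10000; k <- 3; n <- 5
  y <- matrix(rnorm(n_rep * k * n), nrow = k * n)
  g <- rep(1:k, each = n)
  gm <- rowsum(y, g) / n
  grand <- colMeans(y)
  ssb <- n * colSums((gm - matrix(grand, k, n_rep, byrow = TRUE))^2)
  ssw <- colSums((y - gm[g, ])^2)
  f <- (ssb / (k - 1)) / (ssw / (k * n - k))
  rej <- mean(f > qf(0.95, k - 1, k * n - k))
  expect_lt(abs(rej - 0.05), 0.01)
  # spot-check the vectorized oracle against the package implementation
  dd <- tibble::tibble(y = y[, 1], g = rep(letters[1:k], each = n))
  expect_equal(one_way_anova(dd, y, g)$F, f[1], tolerance = 1e-10)
})

test_that("Tukey HSD matches the base TukeyHSD reference on random layouts", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    ns <- sample(3:8, k, replace = TRUE)
    dd <- data.frame(g = factor(rep(letters[1:k], ns)),
                     y = rnorm(sum(ns), rep(rnorm(k, sd = 1.5), ns)))
    got <- tukey_hsd(dd, y, g)
    ref <- stats::TukeyHSD(stats::aov(y ~ g, data = dd))$g
    pair_ref <- rownames(ref)
    for (j in seq_len(nrow(got))) {
      key <- paste0(got$group2[j], "-", got$group1[j])
      r <- ref[match(key, pair_ref), ]
      expect_equal(got$mean_diff[j], unname(r["diff"]), tolerance = 1e-10)
      expect_equal(got$adj_p[j], unname(r["p adj"]), tolerance = 1e-8)
    }
  }
})

test_that("Tukey HSD degenerate and two-group behavior", {
  # identical groups: all adjusted p = 1, nothing significant
  d0 <- tibble::tibble(y = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  t0 <- tukey_hsd(d0, y, g)
  expect_equal(t0$adj_p, rep(1, 3), tolerance = 1e-12)
  expect_false(any(t0$significant))
  # k = 2 reduces to the two-sample t test decision at the same level
  set.seed(41)
  for (i in 1:20) {
    d2 <- tibble::tibble(y = c(rnorm(5), rnorm(5, runif(1, 0, 2))),
                         g = rep(c("a", "b"), each = 5))
    t2 <- tukey_hsd(d2, y, g)
    tt <- stats::t.test(y ~ g, data = d2, var.equal = TRUE)
    # ptukey's tail accuracy is ~1e-8 absolute, so compare absolutely
    expect_lt(abs(t2$adj_p - tt$p.value), 1e-7)
    expect_equal(t2$significant, tt$p.value < 0.05)
  }
})

test_that("Tukey adjusted p decreases with separation at fixed spread", {
  base <- c(-1, -0.5, 0, 0.5, 1)
  ps <- vapply(c(0.5, 1, 2, 4, 8), function(delta) {
    d <- tibble::tibble(y = c(base, base + delta),
                        g = rep(c("a", "b"), each = 5))
    tukey_hsd(d, y, g)$adj_p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("three separated groups: the shifted pairs are flagged, the null pair is not", {
  set.seed(51)
  d <- tibble::tibble(
    y = c(rnorm(5, 0), rnorm(5, 0), rnorm(5, 10)),
    g = rep(c("a", "b", "c"), each = 5)
  )
  tk <- tukey_hsd(d, y, g)
  sig <- tk$significant
  names(sig) <- paste(tk$group1, tk$group2)
  expect_false(sig[["a b"]])
  expect_true(sig[["a c"]])
  expect_true(sig[["b c"]])
})

test_that("the MIC comparison pipeline excludes untested cells and supports both scales", {
  mic <- bp_mic()
  cmp <- mic_compare(mic, scale = "log2")
  expect_s3_class(cmp$anova, "oneway_anova")
  expect_equal(cmp$anova$df_between, 5)
  expect_equal(cmp$anova$df_within, 54 - 6)
  expect_lt(cmp$anova$p, 0.05)
  raw <- mic_compare(mic, scale = "raw")
  expect_false(identical(raw$anova$F, cmp$anova$F))
  # untested cells drop out
  mic_nt <- mic
  mic_nt$mic[1:5] <- NA
  cmp_nt <- mic_compare(mic_nt)
  expect_equal(cmp_nt$anova$n, sum(!is.na(mic_nt$mic)))
})

test_that("tidy() and glance() expose the ANOVA fit", {
  d <- tibble::tibble(y = c(1, 2, 3, 2, 3, 4), g = rep(c("a", "b"), each = 3))
  fit <- one_way_anova(d, y, g)
  td <- tidy(fit)
  expect_equal(td$term, c("between", "within"))
  expect_equal(td$statistic[1], 1.5)
  expect_equal(td$sumsq, c(1.5, 4))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 6)
  expect_equal(gl$statistic, 1.5)
})
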