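test_that("the omnibus normality statistic matches reference values", {
  ## frozen reference values computed independently with
  ## scipy.stats.normaltest / skewtest / kurtosistest
  x <- c(0.5, 1.2, -0.3, 0.8, 2.1, -1.4, 0.2, 0.9, -0.7, 1.1, 0.4, -0.2,
         1.8, -1.1, 0.6)
  r <- dagostino_pearson(x)
  expect_equal(r$statistic, 0.169769315771, tolerance = 1e-9)
  expect_equal(r$p, 0.918618233661, tolerance = 1e-9)
  expect_equal(r$z_skew, -0.316181033275, tolerance = 1e-9)
  expect_equal(r$z_kurt, -0.264194757647, tolerance = 1e-9)
  y <- c(0.1, 0.2, 0.15, 0.3, 0.25, 0.18, 0.22, 5.0, 4.2, 0.12, 0.28, 0.19)
  ry <- dagostino_pearson(y)
  expect_equal(ry$statistic, 12.7334223658, tolerance = 1e-9)
  expect_equal(ry$p, 0.0017177994739, tolerance = 1e-9)
  z <- c(2.3, 1.1, 4.5, 3.3, 2.8, 1.9, 5.2, 2.2, 3.7, 2.9, 1.5, 4.1, 3.0, 2.6)
  rz <- dagostino_pearson(z)
  expect_equal(rz$statistic, 0.457051094816, tolerance = 1e-9)
  expect_equal(rz$p, 0.79570596872, tolerance = 1e-9)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
})

test_that("paired_compare gates on normality and flags degenerate input", {
  a <- c(10, 12, 14, 11, 13, 12, 10, 15, 11, 12)
  expect_equal(paired_compare(a, a)$p, 1)
  expect_true(paired_compare(a, a)$degenerate)
  r <- paired_compare(a + 10, a)
  expect_true(r$degenerate)
  expect_true(is.na(r$p))
  ## near-normal differences select the paired t-test and match the closed
  ## form p = 2 * pt(-|t|, n - 1) with t = mean(d) / (sd(d) / sqrt(n))
  set.seed(7)
  b <- a + rnorm(10, 1, 0.8)
  r2 <- paired_compare(b, a)
  expect_equal(r2$test, "paired t-test")
  d <- b - a
  tstat <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(r2$statistic, tstat, tolerance = 1e-10)
  expect_equal(r2$p, 2 * pt(-abs(tstat), 9), tolerance = 1e-10)
  ## heavily skewed differences fall back to the signed-rank test
  set.seed(8)
  skew <- a + c(0.01, 0.02, 0.01, 0.03, 0.02, 0.01, 0.02, 9, 8, 0.01)
  r3 <- paired_compare(skew, a)
  expect_equal(r3$test, "Wilcoxon matched-pairs")
})

test_that("ks_compare equals the hand-computed ECDF supremum", {
  x <- c(1, 2, 3); y <- c(11, 12, 13)
  expect_equal(ks_compare(x, y)$D, 1)
  expect_equal(ks_compare(x, x)$D, 0)
  set.seed(4)
  a <- rlnorm(40, log(40), 0.5); b <- rlnorm(55, log(64), 0.5)
  grid <- sort(c(a, b))
  d_oracle <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  expect_equal(ks_compare(a, b)$D, d_oracle, tolerance = 1e-12)
  ## invariance under strictly monotone transforms
  r1 <- ks_compare(a, b)
  r2 <- ks_compare(log(a), log(b))
  expect_equal(r1$D, r2$D)
  expect_equal(r1$p, r2$p)
})

test_that("ks_compare detects a 1.6-fold shift reliably at n = 300", {
  ## power check over seeded replicates
  hits <- 0
  for (s in 1:40) {
    set.seed(1000 + s)
    a <- rlnorm(300, log(40), 0.5)
    b <- rlnorm(300, log(40) + log(1.6), 0.5)
    if (ks_compare(a, b)$p < 0.001) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("response distances and their comparison behave as defined", {
  pf <- data.frame(fly = rep(1:4, each = 2),
                   odour = rep(c("Mch", "Oct"), 4),
                   value = c(100, 145, 90, 120, 110, 150, 95, 140))
  d <- response_distance(pf, "Mch", "Oct")
  expect_equal(d$per_fly$delta, c(45, 30, 40, 45))
  expect_equal(d$mean, 40)
  ## identical responses give zero distance
  pf0 <- pf; pf0$value <- rep(c(100, 100), 4)
  expect_equal(response_distance(pf0, "Mch", "Oct")$mean, 0)
  ## incomplete fly is dropped and reported
  pf_miss <- pf[-8, ]
  d2 <- response_distance(pf_miss, "Mch", "Oct")
  expect_equal(d2$n, 3)
  expect_equal(d2$excluded, 4)
  ## Welch comparison matches t.test
  set.seed(2)
  dA <- response_distance(pf, "Mch", "Oct")
  pfB <- pf; pfB$value <- pfB$value + rnorm(8, 0, 5)
  dB <- response_distance(pfB, "Mch", "Oct")
  cc <- compare_distances(dA, dB)
  tt <- t.test(dA$per_fly$delta, dB$per_fly$delta)
  expect_equal(cc$p, tt$p.value)
})

test_that("two-factor ANOVA matches hand-computed sums of squares", {
  ## balanced 2x2 with two observations per cell
  df <- data.frame(value = c(10, 12, 20, 22, 11, 13, 30, 34),
                   condition = rep(c("ON", "OFF"), each = 4),
                   odour = rep(c("Mch", "Mch", "Oct", "Oct"), 2))
  r <- two_factor_compare(df)
  ## hand computation: cell means 11,21,12,32; grand mean 19
  ## SS_condition = 2*2*((16-19)^2 + (22-19)^2) = 72
  ## SS_odour     = 2*2*((11.5-19)^2 + (26.5-19)^2) = 450
  ## SS_inter     = 8 * ... = 50 ; SS_resid = sum within-cell = 2+2+2+8 = 14
  an <- r$anova
  expect_equal(an["condition", "Sum Sq"], 72)
  expect_equal(an["odour", "Sum Sq"], 450)
  expect_equal(an["condition:odour", "Sum Sq"], 50)
  expect_equal(an["Residuals", "Sum Sq"], 14)
  expect_equal(an["odour", "F value"], 450 / (14 / 4))
  expect_equal(nrow(r$contrasts), 2)
  ## all-constant cells: degenerate, adjusted p = 1
  df0 <- df; df0$value <- 5
  r0 <- two_factor_compare(df0)
  expect_true(r0$degenerate)
  expect_true(all(r0$contrasts$p_adj == 1))
  ## empty cell errors with the cell name
  expect_error(two_factor_compare(df[df$condition == "ON" | df$odour == "Mch", ]),
               "empty cell")
})

test_that("two-factor contrasts separate a blocked-inhibition effect", {
  ## ON cells equal; OFF cells differ strongly: the OFF contrast must be
  ## significant and the ON contrast not, across seeds
  hits_on <- 0; hits_off <- 0; n_rep <- 25
  for (s in 1:n_rep) {
    set.seed(2100 + s)
    df <- data.frame(
      value = c(rnorm(10, 40, 3), rnorm(10, 40, 3),
                rnorm(10, 40, 3), rnorm(10, 64, 3)),
      condition = rep(c("ON", "OFF"), each = 20),
      odour = rep(rep(c("Mch", "Oct"), each = 10), 2))
    r <- two_factor_compare(df)
    p_on <- r$contrasts$p_adj[r$contrasts$condition == "ON"]
    p_off <- r$contrasts$p_adj[r$contrasts$condition == "OFF"]
    if (p_on > 0.05) hits_on <- hits_on + 1
    if (p_off < 0.05) hits_off <- hits_off + 1
  }
  expect_gte(hits_on / n_rep, 0.9)
  expect_gte(hits_off / n_rep, 0.95)
})

test_that("subtype localization ANOVA matches a hand-computed F", {
  fr <- data.frame(neuron_id = 1:9,
                   subtype = rep(c("gamma", "alpha_beta", "apbp"), each = 3),
                   fraction = c(0.9, 0.8, 0.85, 0.6, 0.65, 0.7, 0.88, 0.8, 0.84))
  r <- subtype_localization_compare(fr, n_per_group = 3, seed = 1)
  g <- split(fr$fraction, fr$subtype)
  gm <- mean(fr$fraction)
  ss_b <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, 0))
  ss_w <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  f_hand <- (ss_b / 2) / (ss_w / 6)
  expect_equal(r$anova["subtype", "F value"], f_hand, tolerance = 1e-10)
  expect_equal(nrow(r$tukey), 3)
})
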