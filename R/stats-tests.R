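## Group-level statistics: normality-gated paired tests, two-sample KS on
## pooled peak distributions, response-distance metrics and the two-factor
## (inhibition x odour) comparison.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino) and kurtosis
#' (Anscombe-Glynn) into the omnibus statistic `K2 = Zs^2 + Zk^2`, referred
#' to a chi-squared distribution with 2 df. Requires `n >= 8` for the
#' skewness transformation to be defined.
#'
#' @param x numeric vector.
#' @return list `statistic` (K2), `p`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("dagostino_pearson: need n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  ## skewness: D'Agostino (1970) Z
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  ## kurtosis: Anscombe & Glynn (1983) Z
  g2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  sb2 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb2 * (2 / sb2 + sqrt(1 + 4 / sb2^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p = stats::pchisq(k2, 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Normality-gated paired comparison
#'
#' Tests paired per-fly values under two odours. The within-pair differences
#' are first screened with the D'Agostino-Pearson normality test (Shapiro-
#' Wilk below `n = 8`, where the omnibus test is undefined): if they pass at
#' `alpha_norm`, a paired t-test is used, otherwise the Wilcoxon
#' matched-pairs signed-rank test. Zero-variance differences are degenerate:
#' all-zero differences give `p = 1`, a non-zero constant difference is
#' flagged with `p = NA`.
#'
#' @param a,b paired numeric vectors (same flies, two odours).
#' @param alpha_norm normality-screen level.
#' @return list `test`, `statistic`, `p`, `n`, `normality_test`,
#'   `normality_p`, `degenerate`.
#' @export
paired_compare <- function(a, b, alpha_norm = 0.05) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stop("paired_compare: need at least 3 complete pairs")
  d <- a - b
  if (all(d == 0))
    return(list(test = "degenerate (all differences zero)", statistic = NA_real_,
                p = 1, n = n, normality_test = NA_character_,
                normality_p = NA_real_, degenerate = TRUE))
  if (stats::sd(d) == 0)
    return(list(test = "degenerate (constant non-zero difference)",
                statistic = NA_real_, p = NA_real_, n = n,
                normality_test = NA_character_, normality_p = NA_real_,
                degenerate = TRUE))
  if (n >= 8) {
    norm_name <- "D'Agostino-Pearson"
    norm_p <- dagostino_pearson(d)$p
  } else {
    norm_name <- "Shapiro-Wilk"
    norm_p <- stats::shapiro.test(d)$p.value
  }
  if (norm_p > alpha_norm) {
    tt <- stats::t.test(a, b, paired = TRUE)
    list(test = "paired t-test", statistic = unname(tt$statistic),
         p = tt$p.value, n = n, normality_test = norm_name,
         normality_p = norm_p, degenerate = FALSE)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE))
    list(test = "Wilcoxon matched-pairs", statistic = unname(wt$statistic),
         p = wt$p.value, n = n, normality_test = norm_name,
         normality_p = norm_p, degenerate = FALSE)
  }
}

#' Two-sample Kolmogorov-Smirnov comparison of peak distributions
#'
#' Computed on the raw pooled values, never on binned histograms (binning is
#' presentation-only and loses power). `D` is the supremum distance between
#' the two empirical CDFs.
#'
#' @param a,b numeric vectors of pooled `dF/F0%MAX` values.
#' @return list `D`, `p`, `n_a`, `n_b`.
#' @export
ks_compare <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("ks_compare: empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Per-fly response distance between two odours
#'
#' `Delta_fly = mean_peak(odour_b) - mean_peak(odour_a)` in dF/F0% points,
#' with the group mean and SD. Flies missing either odour are excluded.
#'
#' @param per_fly data.frame with columns `fly`, `odour`, `value`.
#' @param odour_a,odour_b odour labels (the distance is `b - a`).
#' @return list `per_fly` (data.frame `fly`, `delta`), `mean`, `sd`, `n`,
#'   `excluded` (fly ids lacking a complete pair).
#' @export
response_distance <- function(per_fly, odour_a, odour_b) {
  va <- per_fly[per_fly$odour == odour_a, c("fly", "value")]
  vb <- per_fly[per_fly$odour == odour_b, c("fly", "value")]
  m <- merge(va, vb, by = "fly", suffixes = c("_a", "_b"))
  m <- m[is.finite(m$value_a) & is.finite(m$value_b), , drop = FALSE]
  excluded <- setdiff(unique(per_fly$fly), m$fly)
  delta <- m$value_b - m$value_a
  list(per_fly = data.frame(fly = m$fly, delta = delta),
       mean = mean(delta), sd = stats::sd(delta), n = nrow(m),
       excluded = excluded)
}

#' Compare response distances of two groups (Welch t-test)
#'
#' Unpaired comparison of per-fly distance values with unequal-variance
#' correction.
#'
#' @param d1,d2 results of [response_distance()].
#' @return list `statistic`, `p`, `df`.
#' @export
compare_distances <- function(d1, d2) {
  tt <- stats::t.test(d1$per_fly$delta, d2$per_fly$delta, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Two-factor comparison for the inhibition-intact / inhibition-blocked design
#'
#' Two-way ANOVA of a per-fly response measure on condition (e.g. APL ON /
#' OFF) crossed with odour, followed by Tukey-adjusted pairwise contrasts;
#' the within-condition odour contrasts are extracted for reporting. If the
#' residual variance is (numerically) zero -- e.g. all cells equal constants
#' -- the report is flagged degenerate with all adjusted p = 1.
#'
#' @param summaries data.frame with columns `value`, `condition`, `odour`
#'   (and optionally `fly`).
#' @return list `anova` (data.frame), `contrasts` (data.frame `condition`,
#'   `contrast`, `diff`, `p_adj`), `degenerate`.
#' @export
two_factor_compare <- function(summaries) {
  summaries$condition <- factor(summaries$condition)
  summaries$odour <- factor(summaries$odour)
  cells <- table(summaries$condition, summaries$odour)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("two_factor_compare: empty cell %s:%s",
                 rownames(cells)[bad[1]], colnames(cells)[bad[2]]))
  }
  if (any(cells < 2)) stop("two_factor_compare: need >= 2 flies per cell")
  fit <- stats::aov(value ~ condition * odour, data = summaries)
  an <- as.data.frame(summary(fit)[[1]])
  rownames(an) <- trimws(rownames(an))
  ms_resid <- an["Residuals", "Mean Sq"]
  scale2 <- stats::var(summaries$value)
  degenerate <- is.na(ms_resid) ||
    ms_resid <= 1e-12 * max(scale2, .Machine$double.eps)
  conds <- levels(summaries$condition)
  if (degenerate) {
    contrasts <- data.frame(condition = conds,
                            contrast = paste(levels(summaries$odour)[1],
                                             levels(summaries$odour)[2],
                                             sep = "-"),
                            diff = vapply(conds, function(cc) {
                              m <- tapply(summaries$value[summaries$condition == cc],
                                          summaries$odour[summaries$condition == cc],
                                          mean)
                              unname(m[1] - m[2])
                            }, numeric(1)),
                            p_adj = 1)
    return(list(anova = an, contrasts = contrasts, degenerate = TRUE))
  }
  tk <- stats::TukeyHSD(fit, "condition:odour")$`condition:odour`
  rn <- rownames(tk)
  rows <- list()
  for (cc in conds) {
    ods <- levels(summaries$odour)
    k1 <- paste0(cc, ":", ods[1]); k2 <- paste0(cc, ":", ods[2])
    hit <- which(rn == paste(k1, k2, sep = "-") | rn == paste(k2, k1, sep = "-"))
    rows[[cc]] <- data.frame(condition = cc,
                             contrast = rn[hit],
                             diff = tk[hit, "diff"],
                             p_adj = tk[hit, "p adj"])
  }
  list(anova = an, contrasts = do.call(rbind, rows), degenerate = FALSE)
}
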