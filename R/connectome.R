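## Connectome analysis of hub-neuron (APL) synapse tables: region filtering,
## reciprocal weights, weight correlation, compartment-localization
## fractions and the KC-subtype comparison.

#' Filter a synapse table to one region
#'
#' Keeps rows whose region label matches `region_label` exactly (e.g.
#' `"CA(R)"`, the right-hemisphere calyx). Retained/dropped counts are
#' attached as the `"filter_log"` attribute.
#'
#' @param table synapse data.frame (see [read_synapse_table()]).
#' @param region_label label to keep.
#' @return filtered data.frame.
#' @export
filter_region <- function(table, region_label = "CA(R)") {
  keep <- table$region == region_label
  out <- table[keep, , drop = FALSE]
  if (!nrow(out)) warning("filter_region: no rows with region '", region_label, "'")
  attr(out, "filter_log") <- c(retained = sum(keep), dropped = sum(!keep))
  out
}

#' Reciprocal synapse weights with a hub neuron
#'
#' Per partner neuron, counts the synapses it makes onto the hub
#' (`w_to_hub`) and receives from it (`w_from_hub`). A neuron "interacts"
#' with the hub when both directions are non-zero (the made-and-received
#' criterion); one-directional partners remain in the list with
#' `interacting = FALSE`.
#'
#' @param table region-filtered synapse data.frame.
#' @param hub_id hub neuron id (default `"APL"`).
#' @param meta optional neuron metadata data.frame (`neuron_id`, `class`,
#'   `subtype`); partners absent from it get class `"other"`.
#' @return data.frame `neuron_id`, `class`, `subtype`, `w_to_hub`,
#'   `w_from_hub`, `interacting`.
#' @export
reciprocal_weights <- function(table, hub_id = "APL", meta = NULL) {
  to_hub <- table[table$post_id == hub_id & table$pre_id != hub_id, "pre_id"]
  from_hub <- table[table$pre_id == hub_id & table$post_id != hub_id, "post_id"]
  ids <- sort(unique(c(to_hub, from_hub)))
  w_to <- as.integer(table(factor(to_hub, levels = ids)))
  w_from <- as.integer(table(factor(from_hub, levels = ids)))
  out <- data.frame(neuron_id = ids, class = "other", subtype = "unknown",
                    w_to_hub = w_to, w_from_hub = w_from,
                    interacting = w_to > 0L & w_from > 0L)
  if (!is.null(meta)) {
    hit <- match(out$neuron_id, meta$neuron_id)
    miss <- sum(is.na(hit))
    if (miss) message(miss, " partner(s) absent from metadata; class 'other'")
    out$class[!is.na(hit)] <- meta$class[hit[!is.na(hit)]]
    if ("subtype" %in% names(meta))
      out$subtype[!is.na(hit)] <- meta$subtype[hit[!is.na(hit)]]
  }
  out
}

#' Correlation of reciprocal weights
#'
#' Ordinary least squares of `w_from_hub` on `w_to_hub` over the interacting
#' neurons of one class; `r2` is the squared Pearson correlation, which for
#' simple linear regression coincides with the OLS R-squared.
#'
#' @param weights data.frame from [reciprocal_weights()].
#' @param class_filter neuron class to keep (`NULL` = all).
#' @param interacting_only restrict to made-and-received partners (default).
#' @return list `r2`, `slope`, `intercept`, `n`.
#' @export
weight_correlation <- function(weights, class_filter = NULL,
                               interacting_only = TRUE) {
  w <- weights
  if (!is.null(class_filter)) w <- w[w$class %in% class_filter, , drop = FALSE]
  if (interacting_only) w <- w[w$interacting, , drop = FALSE]
  if (nrow(w) < 3) stop("weight_correlation: need n >= 3 after filtering")
  if (stats::sd(w$w_to_hub) == 0)
    stop("weight_correlation: zero variance in predictor")
  fit <- stats::lm(w_from_hub ~ w_to_hub, data = w)
  list(r2 = unname(stats::cor(w$w_to_hub, w$w_from_hub)^2),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = nrow(w))
}

#' Compartment localization fractions
#'
#' For synapses in one direction (default hub-to-neuron, i.e. inhibitory
#' inputs received), the per-neuron fraction carrying a given compartment
#' tag (`"bouton"` for PNs, `"claw"` for KCs), with group mean and SEM across
#' neurons. Rows tagged `"unknown"` are uninformative and excluded from the
#' denominator; neurons with only unknown tags are dropped and reported.
#'
#' @param table region-filtered synapse data.frame.
#' @param hub_id hub neuron id.
#' @param direction `"from_hub"` (hub presynaptic) or `"to_hub"`.
#' @param tag compartment tag counted in the numerator.
#' @param neurons optional neuron ids to restrict to (e.g. one class).
#' @return list `per_neuron` (data.frame `neuron_id`, `n_tagged`, `n_total`,
#'   `fraction`), `mean`, `sem`, `n`, `excluded`.
#' @export
compartment_fractions <- function(table, hub_id = "APL",
                                  direction = c("from_hub", "to_hub"),
                                  tag = "bouton", neurons = NULL) {
  direction <- match.arg(direction)
  rows <- if (direction == "from_hub")
    table[table$pre_id == hub_id & table$post_id != hub_id, ]
  else table[table$post_id == hub_id & table$pre_id != hub_id, ]
  partner <- if (direction == "from_hub") rows$post_id else rows$pre_id
  if (!is.null(neurons)) {
    keep <- partner %in% neurons
    rows <- rows[keep, , drop = FALSE]; partner <- partner[keep]
  }
  known <- rows$compartment != "unknown"
  all_ids <- unique(partner)
  partner <- partner[known]; rows <- rows[known, , drop = FALSE]
  n_total <- table(partner)
  n_tag <- table(factor(partner, levels = names(n_total))[rows$compartment == tag])
  per <- data.frame(neuron_id = names(n_total),
                    n_tagged = as.integer(n_tag),
                    n_total = as.integer(n_total))
  per$fraction <- per$n_tagged / per$n_total
  excluded <- setdiff(all_ids, per$neuron_id)
  if (length(excluded))
    message(length(excluded), " neuron(s) with only unknown tags excluded")
  list(per_neuron = per, mean = mean(per$fraction),
       sem = stats::sd(per$fraction) / sqrt(nrow(per)),
       n = nrow(per), excluded = excluded)
}

#' Compare compartment localization across KC subtypes
#'
#' One-way ANOVA of per-neuron claw-localization fractions across KC
#' subtypes, on a balanced random subsample of `n_per_group` neurons per
#' subtype (seeded), with Tukey-adjusted pairwise comparisons. Groups
#' smaller than `n_per_group` are used whole, with a warning.
#'
#' @param fractions data.frame `neuron_id`, `subtype`, `fraction`.
#' @param n_per_group subsample size per subtype.
#' @param seed RNG seed for the subsample.
#' @return list `anova`, `p`, `tukey` (data.frame), `n_used` (per group).
#' @export
subtype_localization_compare <- function(fractions, n_per_group = 70L, seed = 1L) {
  groups <- split(fractions, fractions$subtype)
  groups <- groups[vapply(groups, nrow, 0L) >= 3L]
  if (length(groups) < 2) stop("subtype_localization_compare: need >= 2 groups of >= 3")
  set.seed(seed)
  sub <- do.call(rbind, lapply(groups, function(g) {
    if (nrow(g) < n_per_group) {
      warning("group ", g$subtype[1], " smaller than n_per_group; using all ",
              nrow(g))
      g
    } else g[sample(nrow(g), n_per_group), ]
  }))
  sub$subtype <- factor(sub$subtype)
  fit <- stats::aov(fraction ~ subtype, data = sub)
  an <- as.data.frame(summary(fit)[[1]])
  rownames(an) <- trimws(rownames(an))
  tk <- stats::TukeyHSD(fit)$subtype
  list(anova = an, p = an[["Pr(>F)"]][1],
       tukey = data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL),
       n_used = vapply(split(sub, sub$subtype), nrow, 0L))
}
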