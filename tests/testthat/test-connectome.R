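## small hand-built synapse table
hand_table <- function() {
  data.frame(
    pre_id = c("APL", "APL", "APL", "n1", "n1", "n1", "n1", "n1",
               "n2", "APL", "x1", "APL"),
    post_id = c("n1", "n1", "n1", "APL", "APL", "APL", "APL", "APL",
                "APL", "n2", "APL", "x1"),
    x = 1:12, y = 1:12, z = 1:12,
    region = c(rep("CA(R)", 9), "CA(R)", "LH(R)", "LH(R)"),
    compartment = c("bouton", "bouton", "dendrite", rep("unknown", 5),
                    "unknown", "claw", "unknown", "unknown"))
}

test_that("region filtering keeps exact label matches and logs counts", {
  tb <- hand_table()
  ca <- filter_region(tb, "CA(R)")
  expect_equal(nrow(ca), 10)
  expect_equal(unname(attr(ca, "filter_log")["dropped"]), 2)
  expect_warning(none <- filter_region(tb, "AL(R)"), "no rows")
  expect_equal(nrow(none), 0)
})

test_that("reciprocal weights count both directions and flag interaction", {
  ca <- filter_region(hand_table(), "CA(R)")
  w <- reciprocal_weights(ca, "APL")
  w1 <- w[w$neuron_id == "n1", ]
  expect_equal(w1$w_from_hub, 3L)   # APL -> n1 three times
  expect_equal(w1$w_to_hub, 5L)     # n1 -> APL five times
  expect_true(w1$interacting)
  ## n2 makes one synapse and receives one: interacting
  expect_true(w$interacting[w$neuron_id == "n2"])
  ## one-directional partner stays in the list, not in the interacting set
  tb2 <- rbind(ca, data.frame(pre_id = "APL", post_id = "n3", x = 0, y = 0,
                              z = 0, region = "CA(R)", compartment = "unknown"))
  w2 <- reciprocal_weights(tb2, "APL")
  expect_false(w2$interacting[w2$neuron_id == "n3"])
  expect_equal(w2$w_to_hub[w2$neuron_id == "n3"], 0L)
  ## counting is exact: per-neuron sums equal the row counts
  expect_equal(sum(w$w_from_hub), sum(ca$pre_id == "APL"))
  expect_equal(sum(w$w_to_hub), sum(ca$post_id == "APL"))
})

test_that("weight correlation equals hand-computed Pearson r2 and is symmetric", {
  w <- data.frame(neuron_id = c("a", "b", "c"), class = "PN",
                  subtype = "none", w_to_hub = c(1, 2, 3),
                  w_from_hub = c(1, 2, 4), interacting = TRUE)
  ## hand computation: r = 9 / sqrt(6 * 14), so r2 = 81/84 = 27/28
  r <- weight_correlation(w, "PN")
  expect_equal(r$r2, 27 / 28, tolerance = 1e-12)
  ## r2 is symmetric under axis exchange, the slope is not
  w_swap <- w
  w_swap$w_to_hub <- w$w_from_hub; w_swap$w_from_hub <- w$w_to_hub
  r_swap <- weight_correlation(w_swap, "PN")
  expect_equal(r_swap$r2, r$r2)
  expect_false(isTRUE(all.equal(r_swap$slope, r$slope)))
  ## degenerate predictor errors
  w0 <- w; w0$w_to_hub <- 2
  expect_error(weight_correlation(w0, "PN"), "zero variance")
})

test_that("compartment fractions follow their definition", {
  ca <- filter_region(hand_table(), "CA(R)")
  fr <- compartment_fractions(ca, "APL", "from_hub", "bouton",
                              neurons = c("n1"))
  ## n1 receives 3 tagged rows: 2 bouton, 1 dendrite
  expect_equal(fr$per_neuron$fraction, 2 / 3)
  ## all-bouton table gives fraction 1 and SEM 0 across neurons
  tb <- data.frame(pre_id = "APL", post_id = rep(c("p1", "p2"), each = 3),
                   x = 0, y = 0, z = 0, region = "CA(R)",
                   compartment = "bouton")
  fr2 <- compartment_fractions(tb, "APL")
  expect_equal(fr2$mean, 1)
  expect_equal(fr2$sem, 0)
  ## 3 bouton + 1 dendrite = 0.75
  tb3 <- data.frame(pre_id = "APL", post_id = "p1", x = 0, y = 0, z = 0,
                    region = "CA(R)",
                    compartment = c("bouton", "bouton", "bouton", "dendrite"))
  expect_equal(compartment_fractions(tb3, "APL")$per_neuron$fraction, 0.75)
  ## neurons with only unknown tags are excluded and reported
  tb4 <- rbind(tb3, data.frame(pre_id = "APL", post_id = "p9", x = 0, y = 0,
                               z = 0, region = "CA(R)", compartment = "unknown"))
  expect_message(fr4 <- compartment_fractions(tb4, "APL"), "unknown tags excluded")
  expect_equal(fr4$excluded, "p9")
})

test_that("generator fractions are recovered at scale", {
  s <- simulate_synapse_table(n_pn = 120, n_kc = 40, seed = 3)
  ca <- filter_region(s$synapses, "CA(R)")
  w <- reciprocal_weights(ca, "APL", s$neuron_meta)
  fr <- compartment_fractions(ca, "APL", "from_hub", "bouton",
                              neurons = w$neuron_id[w$class == "PN"])
  expect_lte(abs(fr$mean - s$truth$mean_bouton_fraction), 0.02)
})

test_that("subtype comparison distinguishes a shifted claw-localization mean", {
  hits <- 0; n_rep <- 12
  for (s in 1:n_rep) {
    tab <- simulate_synapse_table(n_pn = 10, n_kc = 240, seed = 4000 + s)
    ca <- filter_region(tab$synapses, "CA(R)")
    w <- reciprocal_weights(ca, "APL", tab$neuron_meta)
    fr <- compartment_fractions(ca, "APL", "from_hub", "claw",
                                neurons = w$neuron_id[w$class == "KC"])
    kc <- merge(fr$per_neuron,
                tab$neuron_meta[, c("neuron_id", "subtype")], by = "neuron_id")
    ## some subtype draws fall short of 70 neurons; the documented fallback
    ## (use the whole group, with a warning) is expected here
    r <- suppressWarnings(subtype_localization_compare(kc, n_per_group = 70,
                                                       seed = s))
    if (r$p < 1e-4) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("interacting census reflects silent neurons", {
  s <- simulate_synapse_table(n_pn = 30, n_kc = 20, n_pn_silent = 6,
                              n_kc_silent = 4, seed = 11)
  ca <- filter_region(s$synapses, "CA(R)")
  w <- reciprocal_weights(ca, "APL", s$neuron_meta)
  ## silent neurons never appear in calyx rows
  expect_false(any(grepl("^PNs|^KCs", w$neuron_id)))
  expect_equal(sum(s$neuron_meta$class == "PN"), 36)
})
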