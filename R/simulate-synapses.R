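## Synthetic hub-neuron (APL) synapse tables with known ground truth,
## emulating the statistical structure of calyx connectivity exports:
## reciprocal weights linearly related with noise, compartment tags drawn to
## per-neuron localization fractions, a region label with decoy regions, and
## a few non-interacting neurons.

#' Simulate an APL-hub synapse table
#'
#' For each interacting partner neuron, the synapse count made onto the hub
#' (`w_to`) is drawn uniformly from `weight_range`, and the count received
#' from the hub follows `w_from = round(slope * w_to + intercept + eps)`,
#' clipped at zero (clips are counted in the ground truth). One row is
#' emitted per synapse with 3D coordinates (nm, hemibrain convention), the
#' region label `"CA(R)"`, and a compartment tag: hub-to-PN rows are tagged
#' `"bouton"` with the neuron's localization fraction (truncated-normal
#' across neurons), hub-to-KC rows `"claw"` likewise with subtype-specific
#' means. Decoy rows in other regions and silent (non-interacting) neurons
#' are included so region filtering and the made-and-received criterion have
#' something to reject. The noise defaults are calibrated so the realized
#' weight correlations sit near the values reported for calyx PN and KC
#' populations (r2 ~ 0.63 and ~ 0.60).
#'
#' @param n_pn,n_kc numbers of interacting PN / KC partners (defaults 126 and
#'   300: the PN count matches the reported calyx census at full scale, the
#'   KC population is scaled down for desk use).
#' @param n_pn_silent,n_kc_silent partners with no calyx APL contact.
#' @param pn_weights,kc_weights lists `slope`, `intercept`, `noise_sd`,
#'   `range` of the reciprocal-weight model.
#' @param bouton_fraction list `mean`, `sd`: per-PN on-bouton localization.
#' @param claw_fraction named list of `c(mean, sd)` per KC subtype.
#' @param decoy_regions labels used for out-of-region decoy rows.
#' @param decoy_fraction decoy rows as a fraction of real rows.
#' @param hub_id hub neuron id.
#' @param seed RNG seed.
#' @return list `synapses` (data.frame `pre_id`, `post_id`, `x`, `y`, `z`,
#'   `region`, `compartment`), `neuron_meta` (`neuron_id`, `class`,
#'   `subtype`), `truth` (model + realized ground truth: weights per neuron,
#'   continuous-model `r2`, per-neuron fractions, counts).
#' @export
simulate_synapse_table <- function(n_pn = 126L, n_kc = 300L,
                                   n_pn_silent = 10L, n_kc_silent = 8L,
                                   pn_weights = list(slope = 0.9, intercept = 25,
                                                     noise_sd = 19, range = c(5, 100)),
                                   kc_weights = list(slope = 0.9, intercept = 12,
                                                     noise_sd = 8.3, range = c(2, 40)),
                                   bouton_fraction = list(mean = 0.84, sd = 0.15),
                                   claw_fraction = list(
                                     gamma = c(0.85, 0.08),
                                     alpha_beta = c(0.65, 0.08),
                                     alpha_prime_beta_prime = c(0.82, 0.08)),
                                   decoy_regions = c("LH(R)", "PED(R)"),
                                   decoy_fraction = 0.05,
                                   hub_id = "APL", seed = 1L) {
  set.seed(seed)
  rtrunc01 <- function(n, mean, sd) pmin(pmax(stats::rnorm(n, mean, sd), 0), 1)
  draw_weights <- function(n, wm) {
    w_to <- sample(seq.int(wm$range[1], wm$range[2]), n, replace = TRUE)
    w_from_cont <- wm$slope * w_to + wm$intercept + stats::rnorm(n, 0, wm$noise_sd)
    w_from <- as.integer(round(pmax(w_from_cont, 0)))
    list(w_to = w_to, w_from = w_from, w_from_cont = w_from_cont,
         n_clipped = sum(w_from_cont < 0))
  }
  pn_ids <- sprintf("PN%03d", seq_len(n_pn))
  kc_ids <- sprintf("KC%04d", seq_len(n_kc))
  subtypes <- sample(names(claw_fraction), n_kc, replace = TRUE)
  pw <- draw_weights(n_pn, pn_weights)
  kw <- draw_weights(n_kc, kc_weights)
  pn_frac <- rtrunc01(n_pn, bouton_fraction$mean, bouton_fraction$sd)
  kc_frac <- vapply(seq_len(n_kc), function(i) {
    p <- claw_fraction[[subtypes[i]]]
    rtrunc01(1, p[1], p[2])
  }, numeric(1))

  coords <- function(n) data.frame(x = round(stats::runif(n, 1e5, 5e5)),
                                   y = round(stats::runif(n, 1e5, 5e5)),
                                   z = round(stats::runif(n, 1e5, 3e5)))
  rows_for <- function(ids, w, frac, tag_on, tag_off, region) {
    to_n <- rep(w$w_to, times = 1L)
    pre_to <- rep(ids, to_n)
    n_to <- length(pre_to)
    from_n <- w$w_from
    post_from <- rep(ids, from_n)
    n_from <- length(post_from)
    on_tag <- unlist(lapply(seq_along(ids), function(i) {
      if (from_n[i] == 0L) return(character(0))
      ifelse(stats::runif(from_n[i]) < frac[i], tag_on,
             sample(tag_off, from_n[i], replace = TRUE))
    }))
    rbind(
      cbind(data.frame(pre_id = pre_to, post_id = hub_id), coords(n_to),
            data.frame(region = region, compartment = "unknown")),
      cbind(data.frame(pre_id = hub_id, post_id = post_from), coords(n_from),
            data.frame(region = region, compartment = on_tag)))
  }
  syn <- rbind(
    rows_for(pn_ids, pw, pn_frac, "bouton", c("dendrite", "other"), "CA(R)"),
    rows_for(kc_ids, kw, kc_frac, "claw", c("dendrite", "other"), "CA(R)"))
  n_real <- nrow(syn)
  ## decoy rows outside the calyx (and the only contacts of silent neurons)
  silent_ids <- c(sprintf("PNs%02d", seq_len(n_pn_silent)),
                  sprintf("KCs%02d", seq_len(n_kc_silent)))
  n_decoy <- ceiling(decoy_fraction * n_real)
  decoy_partner <- sample(c(pn_ids, kc_ids, silent_ids), n_decoy, replace = TRUE)
  decoy_dir <- stats::runif(n_decoy) < 0.5
  decoy <- cbind(data.frame(pre_id = ifelse(decoy_dir, hub_id, decoy_partner),
                            post_id = ifelse(decoy_dir, decoy_partner, hub_id)),
                 coords(n_decoy),
                 data.frame(region = sample(decoy_regions, n_decoy, replace = TRUE),
                            compartment = "unknown"))
  syn <- rbind(syn, decoy)
  meta <- data.frame(
    neuron_id = c(pn_ids, kc_ids, silent_ids),
    class = c(rep("PN", n_pn), rep("KC", n_kc),
              rep("PN", n_pn_silent), rep("KC", n_kc_silent)),
    subtype = c(rep("none", n_pn), subtypes,
                rep("none", n_pn_silent + n_kc_silent)))
  truth <- list(
    pn = data.frame(neuron_id = pn_ids, w_to = pw$w_to, w_from = pw$w_from,
                    bouton_fraction = pn_frac),
    kc = data.frame(neuron_id = kc_ids, subtype = subtypes, w_to = kw$w_to,
                    w_from = kw$w_from, claw_fraction = kc_frac),
    r2_pn = stats::cor(pw$w_to, pw$w_from_cont)^2,
    r2_kc = stats::cor(kw$w_to, kw$w_from_cont)^2,
    slope_pn = pn_weights$slope, slope_kc = kc_weights$slope,
    mean_bouton_fraction = mean(pn_frac),
    n_clipped = pw$n_clipped + kw$n_clipped,
    n_ca_rows = n_real, n_decoy_rows = n_decoy)
  list(synapses = syn, neuron_meta = meta, truth = truth)
}
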