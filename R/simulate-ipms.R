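#' Configuration for a simulated label-free IP-MS experiment
#'
#' Emulates a proteinGroups-style log2 LFQ intensity matrix from an
#' affinity-purification experiment: proteins span a wide baseline
#' abundance range, replicates add Gaussian noise, planted prey proteins
#' are enriched or depleted in a target condition, the bait protein carries
#' per-condition level offsets (it is essentially absent from uninduced
#' controls), and low-abundance observations drop out preferentially
#' (missing not at random): the detection probability is a logistic
#' function of the true intensity centered at a detection-limit quantile,
#' which is the left-censoring structure that downshifted imputation
#' assumes.
#'
#' @param n_proteins number of protein rows (bait included).
#' @param conditions named integer vector of replicates per condition (>= 2
#'   each); the first condition is the reference.
#' @param target_condition condition carrying the planted effects (default:
#'   the second condition).
#' @param baseline_mean,baseline_sd log2 baseline abundance distribution
#'   across proteins.
#' @param rep_sd replicate-to-replicate SD of log2 intensity.
#' @param n_enriched,n_depleted planted differential proteins.
#' @param effect_lfc planted |log2 fold change|.
#' @param bait name of the bait row (default `"CENPA"`).
#' @param bait_offsets named per-condition log2 offsets of the bait; any
#'   condition not named gets 0. An uninduced control should carry a large
#'   negative offset.
#' @param bait_base bait baseline log2 intensity (baits are captured at high
#'   level).
#' @param dropout_quantile detection-limit quantile in `[0, 1)`; 0 disables
#'   dropout entirely.
#' @param dropout_width logistic width (log2 units) of the detection curve.
#' @param on_bait_dropout `"force"` keeps the bait detected in every
#'   condition without a negative offset; `"error"` fails instead.
#' @param rng_seed integer seed.
#' @return object of class `ipms_sim_config`.
#' @export
ipms_sim_config <- function(n_proteins = 1500L,
                            conditions = c(siCTRL = 5L, siDNAJC9 = 4L),
                            target_condition = NULL,
                            baseline_mean = 26, baseline_sd = 2.5,
                            rep_sd = 0.4,
                            n_enriched = 0L, n_depleted = 0L,
                            effect_lfc = 1.5,
                            bait = "CENPA",
                            bait_offsets = c(),
                            bait_base = 32,
                            dropout_quantile = 0.2, dropout_width = 0.6,
                            on_bait_dropout = c("force", "error"),
                            rng_seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              conditions = conditions,
              target_condition = if (is.null(target_condition))
                names(conditions)[2] else target_condition,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              rep_sd = rep_sd, n_enriched = as.integer(n_enriched),
              n_depleted = as.integer(n_depleted), effect_lfc = effect_lfc,
              bait = bait, bait_offsets = bait_offsets, bait_base = bait_base,
              dropout_quantile = dropout_quantile,
              dropout_width = dropout_width,
              on_bait_dropout = match.arg(on_bait_dropout),
              rng_seed = as.integer(rng_seed))
  if (is.null(names(cfg$conditions)) || any(cfg$conditions < 2L))
    stop("conditions must be a named vector of group sizes >= 2")
  if (cfg$dropout_quantile < 0 || cfg$dropout_quantile >= 1)
    stop("dropout_quantile must be in [0, 1)")
  if (cfg$n_enriched + cfg$n_depleted >= cfg$n_proteins)
    stop("more planted effects than proteins")
  if (!cfg$target_condition %in% names(cfg$conditions))
    stop("target_condition not among conditions")
  class(cfg) <- "ipms_sim_config"
  cfg
}

#' Simulate a label-free IP-MS intensity matrix with known truth
#'
#' @param config an [ipms_sim_config()].
#' @return list with class `ipms_sim`: `matrix` (an [intensity_matrix()]
#'   with `NA` for undetected cells), and `truth` (`enriched` / `depleted`
#'   protein ids with planted log2 effects, `bait_offsets`, the complete
#'   `true_values` matrix and the logical `detected` mask).
#' @export
simulate_ipms <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "ipms_sim_config"))
  set.seed(cfg$rng_seed)

  conds <- rep(names(cfg$conditions), times = cfg$conditions)
  reps <- unlist(lapply(cfg$conditions, seq_len), use.names = FALSE)
  samples <- paste0(conds, "_", reps)
  n_s <- length(samples)

  prot <- sprintf("P%05d", seq_len(cfg$n_proteins - 1L))
  proteins <- c(cfg$bait, prot)
  baseline <- c(cfg$bait_base,
                stats::rnorm(cfg$n_proteins - 1L, cfg$baseline_mean,
                             cfg$baseline_sd))

  planted <- sample(prot, cfg$n_enriched + cfg$n_depleted)
  enriched <- planted[seq_len(cfg$n_enriched)]
  depleted <- planted[cfg$n_enriched + seq_len(cfg$n_depleted)]

  true_mean <- matrix(baseline, cfg$n_proteins, n_s,
                      dimnames = list(proteins, samples))
  tgt <- conds == cfg$target_condition
  true_mean[enriched, tgt] <- true_mean[enriched, tgt] + cfg$effect_lfc
  true_mean[depleted, tgt] <- true_mean[depleted, tgt] - cfg$effect_lfc
  bait_off <- vapply(names(cfg$conditions), function(cn) {
    if (cn %in% names(cfg$bait_offsets)) cfg$bait_offsets[[cn]] else 0
  }, numeric(1))
  true_mean[cfg$bait, ] <- cfg$bait_base + bait_off[conds]

  values <- true_mean + stats::rnorm(length(true_mean), 0, cfg$rep_sd)

  detected <- matrix(TRUE, cfg$n_proteins, n_s,
                     dimnames = list(proteins, samples))
  if (cfg$dropout_quantile > 0) {
    limit <- stats::quantile(values, cfg$dropout_quantile, names = FALSE)
    p_det <- stats::plogis((values - limit) / cfg$dropout_width)
    detected[] <- stats::runif(length(values)) < p_det
    induced <- bait_off[conds] >= 0
    if (any(!detected[cfg$bait, induced])) {
      if (cfg$on_bait_dropout == "error")
        stop("bait dropped out of an induced sample; rerun with a new seed ",
             "or on_bait_dropout = 'force'")
      detected[cfg$bait, induced] <- TRUE
    }
  }
  observed <- values
  observed[!detected] <- NA_real_

  meta <- data.frame(sample = samples, condition = conds,
                     replicate = reps, stringsAsFactors = FALSE)
  structure(list(
    matrix = intensity_matrix(observed, meta),
    truth = list(
      enriched = data.frame(protein = enriched, lfc = rep(cfg$effect_lfc,
                            length(enriched)), stringsAsFactors = FALSE),
      depleted = data.frame(protein = depleted, lfc = rep(-cfg$effect_lfc,
                            length(depleted)), stringsAsFactors = FALSE),
      bait_offsets = bait_off, true_values = values, detected = detected),
    config = cfg), class = "ipms_sim")
}
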