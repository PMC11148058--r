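#' Summarize single-cell intensities for one well
#'
#' The per-well readout of the screen is the median nuclear reporter
#' intensity across all imaged cells of the well.
#'
#' @param cell_values numeric vector of per-cell nuclear intensities (> 0).
#' @return list with `median` and `n_cells`.
#' @export
summarize_well <- function(cell_values) {
  if (length(cell_values) == 0L) stop("empty well: no cell intensities")
  if (!is.numeric(cell_values) || any(!is.finite(cell_values)))
    stop("cell intensities must be finite numbers")
  if (any(cell_values <= 0)) stop("cell intensities must be positive")
  list(median = stats::median(cell_values), n_cells = length(cell_values))
}

#' Z'-factor plate quality statistic
#'
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`, computed from the
#' positive- and negative-control wells of one plate (sample SDs). Values
#' near 1 indicate a large assay window; plates below a cutoff
#' (conventionally 0.3--0.5) are excluded.
#'
#' @param pos_values,neg_values numeric vectors of control well values
#'   (>= 2 each).
#' @return the Z'-factor (a dimensionless number <= 1).
#' @seealso [zprime_from_moments()] for the closed form on known moments.
#' @export
compute_zprime <- function(pos_values, neg_values) {
  if (length(pos_values) < 2L || length(neg_values) < 2L)
    stop("need >= 2 values per control group for Z'")
  zprime_from_moments(mean(pos_values), stats::sd(pos_values),
                      mean(neg_values), stats::sd(neg_values))
}

#' Z'-factor from group moments
#'
#' @param mu_pos,sd_pos,mu_neg,sd_neg control means and SDs.
#' @return `1 - 3 (sd_pos + sd_neg) / |mu_pos - mu_neg|`.
#' @export
zprime_from_moments <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  sep <- abs(mu_pos - mu_neg)
  if (sep == 0)
    stop("undefined separation: control means are equal, plate has no dynamic range")
  1 - 3 * (sd_pos + sd_neg) / sep
}

#' Normalize one plate against its negative controls
#'
#' Computes, for every well of a single plate, the fold of the
#' negative-control median (`norm_value`) and the Z-score relative to the
#' negative-control distribution (`raw_z`). With `robust = TRUE` the Z-score
#' basis is median / (1.4826 * MAD) instead of mean / SD.
#'
#' @param wells data.frame of well records for one plate (columns `role`,
#'   `value` at minimum).
#' @param min_neg minimum number of negative-control wells required.
#' @param robust use median/MAD instead of mean/SD for the Z-score.
#' @return the input data.frame with `norm_value` and `raw_z` columns added.
#' @export
normalize_plate <- function(wells, min_neg = 4L, robust = FALSE) {
  if (length(unique(wells$plate_id)) > 1L)
    stop("normalize_plate() expects wells from a single plate")
  neg <- wells$value[wells$role == "neg_ctrl"]
  if (length(neg) < min_neg)
    stop("plate has fewer than ", min_neg, " negative-control wells")
  if (any(!is.finite(wells$value)) || any(wells$value <= 0))
    stop("well values must be positive and finite")
  med <- stats::median(neg)
  if (robust) {
    ctr <- stats::median(neg)
    scl <- stats::mad(neg)
  } else {
    ctr <- mean(neg)
    scl <- stats::sd(neg)
  }
  if (scl == 0) stop("degenerate negative controls: zero spread")
  wells$norm_value <- wells$value / med
  wells$raw_z <- (wells$value - ctr) / scl
  wells
}

#' Build a seed index for an siRNA library
#'
#' Maps every guide-strand 7-mer seed (positions 2--8 of the guide, the
#' determinant of microRNA-like off-target activity) to the siRNAs carrying
#' it. siRNAs sharing a seed form a "seed family" whose common phenotype is
#' interpreted as off-target signal.
#'
#' @param library data.frame with columns `sirna_id`, `gene_id`, `seed`.
#' @return data.frame (`seed`, `sirna_id`, `gene_id`) ordered by seed, with
#'   attribute `n_families`.
#' @export
build_seed_index <- function(library) {
  need <- c("sirna_id", "gene_id", "seed")
  if (!all(need %in% names(library)))
    stop("library must have columns sirna_id, gene_id, seed")
  if (anyDuplicated(library$sirna_id))
    stop("duplicate sirna_id in library")
  bad <- !grepl("^[ACGU]{7}$", library$seed)
  if (any(bad))
    stop("malformed seed (need 7-mer over A/C/G/U): ",
         paste(utils::head(library$seed[bad], 3), collapse = ", "))
  idx <- library[order(library$seed, library$sirna_id),
                 c("seed", "sirna_id", "gene_id")]
  rownames(idx) <- NULL
  attr(idx, "n_families") <- length(unique(idx$seed))
  idx
}

## Aggregate a family's member Z-scores into one off-target effect.
family_aggregate <- function(z, aggregator = c("median", "trimmed")) {
  aggregator <- match.arg(aggregator)
  if (length(z) == 0L) return(0)
  if (aggregator == "median") stats::median(z) else mean(z, trim = 0.2)
}

#' Estimate per-seed off-target family effects
#'
#' For every seed the family effect is the aggregate (default: median) of
#' the raw Z-scores of its member siRNAs, optionally leaving out all
#' members belonging to one gene (used when scoring that gene's siRNAs so a
#' gene cannot vouch for itself). Seeds whose leave-out set is empty
#' (singleton seeds) contribute an effect of 0.
#'
#' @param scores data.frame with columns `sirna_id`, `gene_id`, `seed`,
#'   `raw_z`.
#' @param exclude_gene optional gene id whose siRNAs are dropped before
#'   aggregation.
#' @param aggregator `"median"` (default) or `"trimmed"` (20% trimmed mean).
#' @return data.frame (`seed`, `effect`, `n_members`).
#' @export
estimate_offtarget_effects <- function(scores, exclude_gene = NULL,
                                       aggregator = c("median", "trimmed")) {
  aggregator <- match.arg(aggregator)
  keep <- if (is.null(exclude_gene)) rep(TRUE, nrow(scores))
          else scores$gene_id != exclude_gene
  sub <- scores[keep, , drop = FALSE]
  eff <- vapply(split(sub$raw_z, sub$seed), family_aggregate,
                numeric(1), aggregator = aggregator)
  n <- vapply(split(sub$raw_z, sub$seed), length, integer(1))
  ## a family observed only once carries no cross-gene evidence
  eff[n < 2L] <- 0
  data.frame(seed = names(eff), effect = unname(eff),
             n_members = unname(n), stringsAsFactors = FALSE)
}

#' Subtract seed-driven off-target signal from raw Z-scores
#'
#' The gross off-target contribution of an siRNA is the weighted sum of the
#' estimated effects of the off-target families (seeds) it belongs to; by
#' default a single guide-seed term with weight 1. The family effect for a
#' given siRNA is recomputed leaving out all siRNAs of that siRNA's own gene,
#' so a phenotype shared only within one gene is never treated as
#' off-target. The on-target Z-score is `raw_z - gross_offtarget`, an exact
#' identity preserved in the output.
#'
#' @param scores data.frame with columns `sirna_id`, `gene_id`, `seed`,
#'   `raw_z` (and optionally `norm_value`).
#' @param weights named numeric vector of per-seed weights, or a single
#'   number applied to every seed (default 1).
#' @param aggregator family effect aggregator, see
#'   [estimate_offtarget_effects()].
#' @return the input with `gross_offtarget` and `ontarget_z` columns added.
#' @export
correct_ontarget <- function(scores, weights = 1,
                             aggregator = c("median", "trimmed")) {
  aggregator <- match.arg(aggregator)
  if (!is.null(names(weights))) {
    unknown <- setdiff(names(weights), scores$seed)
    if (length(unknown))
      stop("weight given for unknown seed: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    w <- ifelse(scores$seed %in% names(weights), weights[scores$seed], 1)
  } else {
    if (length(weights) != 1L)
      stop("weights must be a single number or a named vector")
    w <- rep(weights, nrow(scores))
  }

  gross <- numeric(nrow(scores))
  fam <- split(seq_len(nrow(scores)), scores$seed)
  for (members in fam) {
    if (length(members) < 2L) next # singleton seed: no shared evidence
    for (i in members) {
      others <- members[scores$gene_id[members] != scores$gene_id[i]]
      gross[i] <- w[i] * family_aggregate(scores$raw_z[others], aggregator)
    }
  }
  scores$gross_offtarget <- gross
  scores$ontarget_z <- scores$raw_z - gross
  scores
}

#' Aggregate siRNA scores to gene level
#'
#' The gene-level Z-score is the median of the member on-target Z-scores;
#' even-sized medians are midpoints. The median normalized fold is carried
#' along for the fold-change hit filter.
#'
#' @param sirna_scores data.frame with `gene_id`, `ontarget_z` and
#'   optionally `norm_value`.
#' @return data.frame (`gene_id`, `gene_z`, `median_fold`, `n_sirnas`).
#' @export
aggregate_gene <- function(sirna_scores) {
  if (is.numeric(sirna_scores)) { # convenience: bare vector of member scores
    return(stats::median(sirna_scores))
  }
  if (nrow(sirna_scores) == 0L)
    return(data.frame(gene_id = character(), gene_z = numeric(),
                      median_fold = numeric(), n_sirnas = integer(),
                      stringsAsFactors = FALSE))
  sp <- split(sirna_scores, sirna_scores$gene_id)
  out <- data.frame(
    gene_id = names(sp),
    gene_z = vapply(sp, function(d) stats::median(d$ontarget_z), numeric(1)),
    median_fold = vapply(sp, function(d)
      if ("norm_value" %in% names(d)) stats::median(d$norm_value) else NA_real_,
      numeric(1)),
    n_sirnas = vapply(sp, nrow, integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call screen hits from gene-level scores
#'
#' A gene is an `up` hit when `gene_z > z_threshold` and a `down` hit when
#' `gene_z < -z_threshold` (strict inequalities; a score exactly at the
#' boundary is not a hit). When `fold_threshold` is given, hits must
#' additionally change the normalized median fold by more than that factor
#' (`median_fold > fold_threshold` for up, `< 1/fold_threshold` for down).
#'
#' @param gene_scores data.frame from [aggregate_gene()].
#' @param z_threshold gene-level |Z| cutoff (default 2).
#' @param fold_threshold optional fold-change cutoff (e.g. 2); `NULL`
#'   disables the fold filter.
#' @return the input with a `hit` column (`"up"`, `"down"`, `"none"`).
#' @export
call_hits <- function(gene_scores, z_threshold = 2, fold_threshold = NULL) {
  if (z_threshold <= 0) stop("z_threshold must be positive")
  if (!is.null(fold_threshold) && fold_threshold <= 0)
    stop("fold_threshold must be positive")
  hit <- ifelse(gene_scores$gene_z > z_threshold, "up",
                ifelse(gene_scores$gene_z < -z_threshold, "down", "none"))
  if (!is.null(fold_threshold)) {
    pass <- ifelse(hit == "up", gene_scores$median_fold > fold_threshold,
                   ifelse(hit == "down",
                          gene_scores$median_fold < 1 / fold_threshold, TRUE))
    pass[is.na(pass)] <- FALSE
    hit[hit != "none" & !pass] <- "none"
  }
  gene_scores$hit <- hit
  gene_scores
}

#' Score a screen end to end
#'
#' Runs the full primary-screen scoring workflow on a well table: per-plate
#' Z'-factor QC (failed or manually excluded plates are dropped and their
#' genes reported as untested), normalization to the plate negative
#' controls, seed-based off-target correction, gene-level aggregation and
#' hit calling.
#'
#' @param wells data.frame of well records (`plate_id`, `well`, `role`,
#'   `gene_id`, `sirna_id`, `seed`, `value`).
#' @param zprime_min minimum Z' for a plate to pass QC (default 0.3).
#' @param z_threshold gene-level hit threshold.
#' @param fold_threshold optional fold-change filter, see [call_hits()].
#' @param correct apply the seed off-target correction (disable to obtain
#'   uncorrected scores for comparison).
#' @param robust use median/MAD plate normalization.
#' @param exclude_plates plate ids excluded after visual inspection.
#' @param min_neg minimum negative-control wells per plate.
#' @return list with `plate_qc`, `sirna_scores`, `gene_scores` (with `hit`),
#'   and `untested_genes` (genes whose every plate failed QC).
#' @export
score_screen <- function(wells, zprime_min = 0.3, z_threshold = 2,
                         fold_threshold = NULL, correct = TRUE,
                         robust = FALSE, exclude_plates = character(),
                         min_neg = 4L) {
  plates <- split(wells, wells$plate_id)
  qc <- do.call(rbind, lapply(plates, function(p) {
    pos <- p$value[p$role == "pos_ctrl"]
    neg <- p$value[p$role == "neg_ctrl"]
    zp <- tryCatch(compute_zprime(pos, neg), error = function(e) NA_real_)
    data.frame(plate_id = p$plate_id[1], z_prime = zp,
               n_neg = length(neg), n_pos = length(pos),
               stringsAsFactors = FALSE)
  }))
  rownames(qc) <- NULL
  qc$passed <- !is.na(qc$z_prime) & qc$z_prime >= zprime_min &
    qc$n_neg >= min_neg & !(qc$plate_id %in% exclude_plates)

  passing <- qc$plate_id[qc$passed]
  if (length(passing) == 0L) {
    warning("no plate passed QC; all genes untested")
    sirna <- cbind(wells[0, , drop = FALSE], norm_value = numeric(),
                   raw_z = numeric())
  } else {
    scored <- do.call(rbind, lapply(plates[passing], normalize_plate,
                                    min_neg = min_neg, robust = robust))
    sirna <- scored[scored$role == "sample", , drop = FALSE]
    rownames(sirna) <- NULL
  }

  if (nrow(sirna) > 0L) {
    if (correct) {
      sirna <- correct_ontarget(sirna)
    } else {
      sirna$gross_offtarget <- 0
      sirna$ontarget_z <- sirna$raw_z
    }
  }

  genes <- call_hits(aggregate_gene(sirna), z_threshold = z_threshold,
                     fold_threshold = fold_threshold)
  all_genes <- unique(stats::na.omit(wells$gene_id[wells$role == "sample"]))
  untested <- setdiff(all_genes, genes$gene_id)

  list(plate_qc = qc, sirna_scores = sirna, gene_scores = genes,
       untested_genes = untested)
}

#' Concordance between a primary and a validation screen
#'
#' A primary hit is `validated` when the validation screen (independent
#' siRNAs, same workflow) calls the same direction, `discordant` when it
#' calls a different direction or none, and `untested` when the gene was not
#' scored in the validation screen.
#'
#' @param primary_hits data.frame with `gene_id` and `hit` from the primary
#'   screen (only rows with `hit != "none"` are assessed).
#' @param validation_scores gene-level data.frame with `gene_id` and `hit`
#'   from the validation screen.
#' @return list with `table` (per-gene status) and `summary` counts.
#' @export
validation_concordance <- function(primary_hits, validation_scores) {
  ph <- primary_hits[primary_hits$hit != "none", , drop = FALSE]
  if (nrow(ph) > 0L && !any(ph$gene_id %in% validation_scores$gene_id))
    warning("no gene overlap between primary hits and validation screen")
  m <- match(ph$gene_id, validation_scores$gene_id)
  vhit <- validation_scores$hit[m]
  status <- ifelse(is.na(vhit), "untested",
                   ifelse(vhit == ph$hit, "validated", "discordant"))
  tab <- data.frame(gene_id = ph$gene_id, primary_hit = ph$hit,
                    validation_hit = ifelse(is.na(vhit), NA_character_, vhit),
                    status = status, stringsAsFactors = FALSE)
  list(table = tab,
       summary = c(validated = sum(status == "validated"),
                   discordant = sum(status == "discordant"),
                   untested = sum(status == "untested")))
}

#' Relative expression by the 2^-dCt method
#'
#' Normalizes a target gene's qPCR threshold cycle against a reference gene
#' (e.g. GAPDH): `2^-(Ct_target - Ct_reference)`. Vectorized over replicates.
#'
#' @param ct_target,ct_reference threshold cycles (finite).
#' @return relative expression values.
#' @examples
#' ddct(25, 20) # 2^-5 = 0.03125
#' @export
ddct <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite")
  2^-(ct_target - ct_reference)
}
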