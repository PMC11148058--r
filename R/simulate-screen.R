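#' Configuration for a simulated high-content siRNA screen
#'
#' Describes one synthetic genome-scale (or smaller) image-based RNAi screen
#' laid out on 384-well plates: three (by default) unique siRNAs per gene
#' stamped into columns 1--22, with columns 23--24 reserved for negative,
#' positive and cell-death transfection controls. Per-cell reporter
#' intensities are log-normal; the per-well readout is the median cell
#' intensity, so the well-to-well spread among negative controls is the
#' sampling error of a median. Planted gene effects and seed-family
#' off-target effects are expressed in units of that control SD, which is
#' the scale on which plate Z-scores are later computed.
#'
#' Seed families model microRNA-like off-target activity: a set of siRNAs
#' targeting unrelated genes but sharing one 7-mer guide seed, all shifted
#' by `seed_effect` control SDs. Family members are drawn from dedicated
#' "confounded" genes, each contributing `confounded_per_gene` of its
#' siRNAs to different families, so that the gene-level median is moved by
#' the off-target signal (the failure mode the on-target correction is
#' designed to remove). Hit genes and confounded genes are disjoint.
#'
#' @param n_genes number of library genes (>= 1).
#' @param sirnas_per_gene unique non-pooled siRNAs per gene (default 3).
#' @param plate_format wells per plate; only 384 (16 x 24) is supported.
#' @param n_hit_genes_up,n_hit_genes_down planted true hit genes per direction.
#' @param hit_effect planted on-target effect, in negative-control SD units.
#' @param n_seed_families number of shared-seed off-target families.
#' @param seed_family_size member siRNAs per family.
#' @param confounded_per_gene how many siRNAs of one confounded gene carry a
#'   family seed (each goes to a different family when possible).
#' @param seed_effect per-family off-target shift in control SD units.
#' @param plate_shift_sd SD (log scale) of the multiplicative between-plate
#'   intensity shift.
#' @param cells_per_well mean number of imaged cells per well (Poisson).
#' @param cell_cv coefficient of variation of single-cell intensity.
#' @param n_neg_ctrl,n_pos_ctrl,n_death_ctrl control wells per plate; all
#'   controls must fit in the two reserved columns.
#' @param pos_ctrl_fold multiplicative intensity effect of the biological
#'   positive control.
#' @param death_ctrl_cell_frac fraction of cells surviving in the
#'   transfection (cell-death) control wells.
#' @param base_intensity baseline median single-cell intensity (AU).
#' @param rng_seed integer seed; identical config + seed is bit-reproducible.
#'
#' @return An object of class `screen_sim_config` (a validated list).
#' @seealso [simulate_screen()]
#' @export
screen_sim_config <- function(n_genes,
                              sirnas_per_gene = 3L,
                              plate_format = 384L,
                              n_hit_genes_up = 0L,
                              n_hit_genes_down = 0L,
                              hit_effect = 4,
                              n_seed_families = 0L,
                              seed_family_size = 20L,
                              confounded_per_gene = 2L,
                              seed_effect = 0,
                              plate_shift_sd = 0.05,
                              cells_per_well = 1500,
                              cell_cv = 0.3,
                              n_neg_ctrl = 16L,
                              n_pos_ctrl = 8L,
                              n_death_ctrl = 8L,
                              pos_ctrl_fold = 2.5,
                              death_ctrl_cell_frac = 0.1,
                              base_intensity = 1000,
                              rng_seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), sirnas_per_gene = as.integer(sirnas_per_gene),
    plate_format = as.integer(plate_format),
    n_hit_genes_up = as.integer(n_hit_genes_up),
    n_hit_genes_down = as.integer(n_hit_genes_down),
    hit_effect = hit_effect,
    n_seed_families = as.integer(n_seed_families),
    seed_family_size = as.integer(seed_family_size),
    confounded_per_gene = as.integer(confounded_per_gene),
    seed_effect = seed_effect,
    plate_shift_sd = plate_shift_sd,
    cells_per_well = cells_per_well, cell_cv = cell_cv,
    n_neg_ctrl = as.integer(n_neg_ctrl), n_pos_ctrl = as.integer(n_pos_ctrl),
    n_death_ctrl = as.integer(n_death_ctrl),
    pos_ctrl_fold = pos_ctrl_fold,
    death_ctrl_cell_frac = death_ctrl_cell_frac,
    base_intensity = base_intensity,
    rng_seed = as.integer(rng_seed))
  class(cfg) <- "screen_sim_config"
  validate_screen_sim_config(cfg)
}

validate_screen_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  if (cfg$n_genes < 1L)
    stop("invalid config: n_genes must be >= 1 (no sample well would be filled)")
  if (cfg$sirnas_per_gene < 1L) stop("invalid config: sirnas_per_gene must be >= 1")
  if (cfg$plate_format != 384L)
    stop("invalid config: only the 384-well plate format is supported")
  if (cfg$cells_per_well <= 0 || cfg$cell_cv <= 0)
    stop("invalid config: cells_per_well and cell_cv must be positive")
  if (cfg$base_intensity <= 0) stop("invalid config: base_intensity must be > 0")
  if (cfg$n_neg_ctrl < 2L)
    stop("invalid config: at least 2 negative-control wells per plate required")
  n_ctrl <- cfg$n_neg_ctrl + cfg$n_pos_ctrl + cfg$n_death_ctrl
  if (n_ctrl > 2L * 16L)
    stop("invalid config: control wells do not fit in the two reserved columns (23-24)")
  if (cfg$n_hit_genes_up < 0L || cfg$n_hit_genes_down < 0L ||
      cfg$n_seed_families < 0L)
    stop("invalid config: counts must be non-negative")
  if (cfg$n_seed_families > 0L) {
    if (cfg$seed_family_size < 2L)
      stop("invalid config: seed families need >= 2 members")
    if (cfg$confounded_per_gene < 1L ||
        cfg$confounded_per_gene > cfg$sirnas_per_gene)
      stop("invalid config: confounded_per_gene must be in 1..sirnas_per_gene")
    n_fam_sirnas <- cfg$n_seed_families * cfg$seed_family_size
    if (n_fam_sirnas %% cfg$confounded_per_gene != 0L)
      stop("invalid config: family slots (n_seed_families * seed_family_size) ",
           "must be divisible by confounded_per_gene")
    n_conf_genes <- n_fam_sirnas %/% cfg$confounded_per_gene
    if (cfg$n_hit_genes_up + cfg$n_hit_genes_down + n_conf_genes > cfg$n_genes)
      stop("invalid config: hit genes plus seed-family (confounded) genes ",
           "exceed n_genes; they must be disjoint")
  } else if (cfg$n_hit_genes_up + cfg$n_hit_genes_down > cfg$n_genes) {
    stop("invalid config: more hit genes than genes")
  }
  cfg
}

## 7-mer seeds over {A,C,G,U}; unique by construction (sampled without
## replacement from the 4^7 = 16384 possible seeds).
make_seed_strings <- function(idx) {
  alphabet <- c("A", "C", "G", "U")
  out <- character(length(idx))
  v <- idx - 1L
  for (p in 1:7) {
    out <- paste0(out, alphabet[v %% 4L + 1L])
    v <- v %/% 4L
  }
  out
}

well_label <- function(row, col) sprintf("%s%02d", LETTERS[row], col)

## Relative (log-scale) SD of the per-well median across cells: asymptotic
## SE of the sample median of a normal, 1.2533 * sigma / sqrt(n).
well_median_rel_sd <- function(cell_cv, cells_per_well) {
  sdlog <- sqrt(log(1 + cell_cv^2))
  sqrt(pi / 2) * sdlog / sqrt(cells_per_well)
}

#' Simulate a 384-well image-based siRNA screen
#'
#' Generates per-well median reporter intensities for a full screen together
#' with a ground-truth object listing every planted effect. Sample siRNAs are
#' stamped row-wise into columns 1--22; column 23 holds negative controls and
#' column 24 positive and cell-death controls. Each well draws a Poisson
#' number of cells with log-normal single-cell intensities; the reported
#' value is the median cell intensity. Plate-level multiplicative shifts
#' model batch effects and cancel under within-plate normalization.
#'
#' @param config a [screen_sim_config()].
#' @return A list with class `screen_sim`:
#' \describe{
#'   \item{wells}{data.frame, one row per well: `plate_id`, `well`, `role`
#'     (`sample`/`neg_ctrl`/`pos_ctrl`/`death_ctrl`), `gene_id`, `sirna_id`,
#'     `seed`, `value` (median nuclear intensity, AU), `n_cells`.}
#'   \item{truth}{list of data.frames: `genes` (`gene_id`, `direction`,
#'     `effect`, `confounded`), `seeds` (`seed`, `family`, `effect`,
#'     `n_members`), `sirnas` (`sirna_id`, `gene_id`, `seed`, `family`).}
#'   \item{config}{the input configuration.}
#' }
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 24, rng_seed = 7))
#' head(sim$wells)
#' @export
simulate_screen <- function(config) {
  cfg <- validate_screen_sim_config(config)
  set.seed(cfg$rng_seed)

  n_sirnas <- cfg$n_genes * cfg$sirnas_per_gene
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  sirna_gene <- rep(seq_len(cfg$n_genes), each = cfg$sirnas_per_gene)
  sirna_ids <- sprintf("%s_s%d", gene_ids[sirna_gene],
                       rep(seq_len(cfg$sirnas_per_gene), times = cfg$n_genes))

  ## --- planted gene effects (disjoint role assignment) ------------------
  n_fam_sirnas <- cfg$n_seed_families * cfg$seed_family_size
  n_conf_genes <- if (cfg$n_seed_families > 0L)
    n_fam_sirnas %/% cfg$confounded_per_gene else 0L
  roles_needed <- cfg$n_hit_genes_up + cfg$n_hit_genes_down + n_conf_genes
  special <- sample.int(cfg$n_genes, roles_needed)
  up_genes <- special[seq_len(cfg$n_hit_genes_up)]
  down_genes <- special[cfg$n_hit_genes_up + seq_len(cfg$n_hit_genes_down)]
  conf_genes <- special[cfg$n_hit_genes_up + cfg$n_hit_genes_down +
                          seq_len(n_conf_genes)]

  gene_effect <- numeric(cfg$n_genes)
  gene_effect[up_genes] <- cfg$hit_effect
  gene_effect[down_genes] <- -cfg$hit_effect
  gene_dir <- rep("none", cfg$n_genes)
  gene_dir[up_genes] <- "up"
  gene_dir[down_genes] <- "down"

  ## --- seed assignment --------------------------------------------------
  ## Family seeds first, then unique singleton seeds for everyone else.
  n_seeds_needed <- cfg$n_seed_families + (n_sirnas - n_fam_sirnas)
  if (n_seeds_needed > 4^7)
    stop("invalid config: more distinct 7-mer seeds required than exist")
  seed_pool <- make_seed_strings(sample.int(4^7, n_seeds_needed))
  family_seed <- seed_pool[seq_len(cfg$n_seed_families)]

  sirna_seed <- character(n_sirnas)
  sirna_family <- integer(n_sirnas) # 0 = no family
  if (cfg$n_seed_families > 0L) {
    ## Confounded gene j contributes its first `confounded_per_gene` siRNAs;
    ## consecutive slots cycle through families so one gene's siRNAs land in
    ## different families while each family spans many genes.
    fam_cycle <- rep_len(seq_len(cfg$n_seed_families), n_fam_sirnas)
    slot <- 0L
    for (g in conf_genes) {
      idx <- which(sirna_gene == g)[seq_len(cfg$confounded_per_gene)]
      for (i in idx) {
        slot <- slot + 1L
        sirna_family[i] <- fam_cycle[slot]
        sirna_seed[i] <- family_seed[fam_cycle[slot]]
      }
    }
  }
  singles <- which(sirna_seed == "")
  sirna_seed[singles] <-
    seed_pool[cfg$n_seed_families + seq_along(singles)]

  ## --- plate layout -----------------------------------------------------
  n_rows <- 16L; sample_cols <- 22L
  wells_per_plate <- n_rows * sample_cols
  n_plates <- ceiling(n_sirnas / wells_per_plate)

  sample_order <- expand.grid(row = seq_len(n_rows), col = seq_len(sample_cols))
  sample_order <- sample_order[order(sample_order$row, sample_order$col), ]

  ctrl_rows <- c(seq_len(cfg$n_neg_ctrl), seq_len(cfg$n_pos_ctrl),
                 seq_len(cfg$n_death_ctrl))
  ctrl_cols <- c(rep(23L, cfg$n_neg_ctrl),
                 rep(24L, cfg$n_pos_ctrl),
                 rep(24L, cfg$n_death_ctrl))
  ## overflow wraps: if a role does not fit its preferred column the well
  ## labels continue in the other reserved column
  overflow <- which(ctrl_cols == 24L)
  if (length(overflow)) {
    pos_death_rows <- c(seq_len(cfg$n_pos_ctrl),
                        cfg$n_pos_ctrl + seq_len(cfg$n_death_ctrl))
    ctrl_rows[overflow] <- pos_death_rows
  }
  ctrl_roles <- c(rep("neg_ctrl", cfg$n_neg_ctrl),
                  rep("pos_ctrl", cfg$n_pos_ctrl),
                  rep("death_ctrl", cfg$n_death_ctrl))

  ## --- well table -------------------------------------------------------
  rows <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    first <- (p - 1L) * wells_per_plate + 1L
    last <- min(p * wells_per_plate, n_sirnas)
    k <- last - first + 1L
    sm <- data.frame(
      plate_id = sprintf("P%03d", p),
      well = well_label(sample_order$row[seq_len(k)],
                        sample_order$col[seq_len(k)]),
      role = "sample",
      gene_id = gene_ids[sirna_gene[first:last]],
      sirna_id = sirna_ids[first:last],
      seed = sirna_seed[first:last],
      effect = gene_effect[sirna_gene[first:last]] +
        ifelse(sirna_family[first:last] > 0L, cfg$seed_effect, 0),
      stringsAsFactors = FALSE)
    cm <- data.frame(
      plate_id = sprintf("P%03d", p),
      well = well_label(ctrl_rows, ctrl_cols),
      role = ctrl_roles,
      gene_id = NA_character_, sirna_id = NA_character_,
      seed = NA_character_, effect = 0,
      stringsAsFactors = FALSE)
    rows[[p]] <- rbind(sm, cm)
  }
  wells <- do.call(rbind, rows)
  rownames(wells) <- NULL

  ## --- intensities ------------------------------------------------------
  sdlog_cell <- sqrt(log(1 + cfg$cell_cv^2))
  s_well <- well_median_rel_sd(cfg$cell_cv, cfg$cells_per_well)
  plate_shift <- stats::rnorm(n_plates, 0, cfg$plate_shift_sd)
  names(plate_shift) <- sprintf("P%03d", seq_len(n_plates))

  mu_cells <- ifelse(wells$role == "death_ctrl",
                     cfg$cells_per_well * cfg$death_ctrl_cell_frac,
                     cfg$cells_per_well)
  n_cells <- stats::rpois(nrow(wells), mu_cells)
  n_cells[n_cells < 1L] <- 1L

  meanlog <- log(cfg$base_intensity) + plate_shift[wells$plate_id] +
    wells$effect * s_well +
    ifelse(wells$role == "pos_ctrl", log(cfg$pos_ctrl_fold), 0)

  value <- numeric(nrow(wells))
  for (i in seq_len(nrow(wells))) {
    value[i] <- exp(stats::median(stats::rnorm(n_cells[i], meanlog[i],
                                               sdlog_cell)))
  }
  wells$value <- value
  wells$n_cells <- n_cells
  wells$effect <- NULL

  truth <- list(
    genes = data.frame(gene_id = gene_ids, direction = gene_dir,
                       effect = gene_effect,
                       confounded = seq_len(cfg$n_genes) %in% conf_genes,
                       stringsAsFactors = FALSE),
    seeds = if (cfg$n_seed_families > 0L) data.frame(
      seed = family_seed, family = seq_len(cfg$n_seed_families),
      effect = cfg$seed_effect,
      n_members = as.integer(table(factor(sirna_family[sirna_family > 0L],
                                          levels = seq_len(cfg$n_seed_families)))),
      stringsAsFactors = FALSE)
    else data.frame(seed = character(), family = integer(), effect = numeric(),
                    n_members = integer(), stringsAsFactors = FALSE),
    sirnas = data.frame(sirna_id = sirna_ids, gene_id = gene_ids[sirna_gene],
                        seed = sirna_seed, family = sirna_family,
                        stringsAsFactors = FALSE))

  structure(list(wells = wells, truth = truth, config = cfg),
            class = "screen_sim")
}
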