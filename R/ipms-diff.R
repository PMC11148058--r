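#' Log2 intensity matrix with sample metadata
#'
#' The working container for label-free IP-MS data: a proteins x samples
#' matrix of log2 LFQ intensities with `NA` marking undetected cells
#' (missingness is explicit, never encoded as 0), plus a sample metadata
#' table carrying at least `sample` and `condition`.
#'
#' @param values numeric matrix, proteins in rows (rownames required),
#'   samples in columns (colnames required), log2 scale, `NA` = missing.
#' @param meta data.frame with columns `sample` (matching the column names)
#'   and `condition`; additional columns (`fraction`, `replicate`, ...) are
#'   carried along.
#' @return object of class `intensity_matrix` (list with `values`, `meta`).
#' @export
intensity_matrix <- function(values, meta) {
  if (!is.matrix(values) || is.null(colnames(values)) ||
      (nrow(values) > 0 && is.null(rownames(values))))
    stop("values must be a matrix with protein rownames and sample colnames")
  if (!all(c("sample", "condition") %in% names(meta)))
    stop("meta must have 'sample' and 'condition' columns")
  if (!setequal(meta$sample, colnames(values)) ||
      nrow(meta) != ncol(values))
    stop("metadata does not cover exactly the sample columns")
  meta <- meta[match(colnames(values), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  if (any(is.infinite(values)))
    stop("intensities must be finite where present")
  structure(list(values = values, meta = meta), class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d samples (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  cat("conditions:", paste(sprintf("%s (n=%d)",
      names(table(x$meta$condition)), table(x$meta$condition)),
      collapse = ", "), "\n")
  invisible(x)
}

#' Filter proteins by complete detection in at least one condition
#'
#' Keeps a protein only if, in some condition (excluded conditions -- e.g.
#' an uninduced/beads-only control -- do not count), it is detected in at
#' least `min_detect_frac` of the replicates (default 1.0: every replicate).
#'
#' @param mat an [intensity_matrix()].
#' @param min_detect_frac required detection fraction within a qualifying
#'   condition, in `(0, 1]`.
#' @param exclude_conditions condition names that cannot qualify a protein.
#' @return the filtered [intensity_matrix()]; attribute `n_removed` records
#'   the number of dropped proteins. Warns when nothing survives.
#' @export
filter_valid <- function(mat, min_detect_frac = 1.0,
                         exclude_conditions = character()) {
  stopifnot(inherits(mat, "intensity_matrix"))
  if (min_detect_frac <= 0 || min_detect_frac > 1)
    stop("min_detect_frac must be in (0, 1]")
  bad <- setdiff(exclude_conditions, mat$meta$condition)
  if (length(bad))
    stop("excluded condition not present: ", paste(bad, collapse = ", "))
  conds <- setdiff(unique(mat$meta$condition), exclude_conditions)
  det <- !is.na(mat$values)
  keep <- rep(FALSE, nrow(mat$values))
  for (cn in conds) {
    cols <- mat$meta$sample[mat$meta$condition == cn]
    frac <- rowMeans(det[, cols, drop = FALSE])
    keep <- keep | frac >= min_detect_frac
  }
  if (!any(keep)) warning("filter removed every protein")
  out <- intensity_matrix(mat$values[keep, , drop = FALSE], mat$meta)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Impute missing values from a downshifted normal distribution
#'
#' Standard left-censored (missing-not-at-random) imputation for label-free
#' proteomics: for each sample column with observed mean `mu` and SD
#' `sigma`, missing cells are drawn from
#' `Normal(mu - downshift * sigma, (width * sigma)^2)` -- by default a
#' downshift of 1.8 and a width of 0.3 column SDs, i.e. imputed values sit
#' in the low tail where undetected proteins are expected. With
#' `per_column = FALSE` the moments are taken from the whole matrix.
#'
#' @param mat an [intensity_matrix()] (typically filtered first).
#' @param downshift imputed-mean downshift in column-SD units.
#' @param width imputed-SD as a fraction of the column SD (> 0).
#' @param rng_seed integer seed; imputation is deterministic given the seed.
#' @param per_column compute moments per sample column (default) or from
#'   the total matrix.
#' @return list: `matrix` (complete [intensity_matrix()]) and `mask`
#'   (logical matrix marking imputed cells).
#' @export
impute_downshift <- function(mat, downshift = 1.8, width = 0.3,
                             rng_seed = 1L, per_column = TRUE) {
  stopifnot(inherits(mat, "intensity_matrix"))
  if (width <= 0) stop("width must be > 0")
  v <- mat$values
  mask <- is.na(v)
  if (!any(mask))
    return(list(matrix = mat, mask = mask))
  set.seed(as.integer(rng_seed))
  if (per_column) {
    for (j in seq_len(ncol(v))) {
      obs <- v[!mask[, j], j]
      n_miss <- sum(mask[, j])
      if (n_miss == 0L) next
      if (length(obs) < 2L)
        stop("cannot impute column '", colnames(v)[j],
             "': fewer than 2 observed values")
      mu <- mean(obs); sg <- stats::sd(obs)
      v[mask[, j], j] <- stats::rnorm(n_miss, mu - downshift * sg,
                                      width * sg)
    }
  } else {
    obs <- v[!mask]
    if (length(obs) < 2L) stop("cannot impute: fewer than 2 observed values")
    mu <- mean(obs); sg <- stats::sd(obs)
    v[mask] <- stats::rnorm(sum(mask), mu - downshift * sg, width * sg)
  }
  list(matrix = intensity_matrix(v, mat$meta), mask = mask)
}

#' Normalize all intensities to the bait protein
#'
#' Subtracts the bait's log2 intensity from every protein within each
#' sample (equivalently, divides linear intensities by the bait's), so
#' prey abundance is expressed relative to the amount of captured bait --
#' the LFQ_B.N. transformation that removes differences in bait expression
#' or pulldown efficiency between conditions. The bait row becomes 0
#' everywhere; multiplying a sample's linear intensities by any constant
#' leaves its bait-normalized values unchanged.
#'
#' @param mat an [intensity_matrix()]; the bait must be present (observed
#'   or imputed) in every sample.
#' @param bait_protein bait row name.
#' @return the bait-normalized [intensity_matrix()].
#' @export
bait_normalize <- function(mat, bait_protein) {
  stopifnot(inherits(mat, "intensity_matrix"))
  if (!bait_protein %in% rownames(mat$values))
    stop("bait '", bait_protein, "' not found in the matrix")
  bait <- mat$values[bait_protein, ]
  if (any(is.na(bait)))
    stop("bait is missing in ", sum(is.na(bait)),
         " sample(s); filter/impute before bait normalization")
  intensity_matrix(sweep(mat$values, 2L, bait, "-"), mat$meta)
}

#' s0-moderated two-sample statistic
#'
#' The SAM-style test statistic: the pooled-variance Student t denominator
#' is inflated by the constant `s0`, damping the significance of tiny fold
#' changes measured with tiny variance. At `s0 = 0` this is exactly the
#' two-sample pooled-variance Student t statistic. |stat| is non-increasing
#' in `s0` for fixed data.
#'
#' @param group_a,group_b numeric vectors (>= 2 values each).
#' @param s0 non-negative fudge constant (same units as the values).
#' @return list: `log2fc` (`mean(a) - mean(b)`), `stat`, `df`. A zero
#'   denominator with nonzero fold change yields `Inf` with a warning;
#'   identical constant groups yield `stat = 0`.
#' @export
moderated_stat <- function(group_a, group_b, s0 = 0) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("need >= 2 values per group")
  if (s0 < 0) stop("s0 must be >= 0")
  lfc <- mean(group_a) - mean(group_b)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  denom <- sqrt(sp2) * sqrt(1 / na + 1 / nb) + s0
  if (denom == 0) {
    if (lfc == 0) return(list(log2fc = 0, stat = 0, df = na + nb - 2L))
    warning("zero within-group variance with s0 = 0: infinite statistic")
    return(list(log2fc = lfc, stat = sign(lfc) * Inf, df = na + nb - 2L))
  }
  list(log2fc = lfc, stat = lfc / denom, df = na + nb - 2L)
}

## Vectorized s0-moderated stats for all proteins at once.
## X: proteins x samples, ia/ib: column indices of the two groups.
row_moderated_stat <- function(X, ia, ib, s0) {
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(X[, ia, drop = FALSE])
  mb <- rowMeans(X[, ib, drop = FALSE])
  ssa <- rowSums((X[, ia, drop = FALSE] - ma)^2)
  ssb <- rowSums((X[, ib, drop = FALSE] - mb)^2)
  sp <- sqrt((ssa + ssb) / (na + nb - 2))
  denom <- sp * sqrt(1 / na + 1 / nb) + s0
  lfc <- ma - mb
  stat <- ifelse(denom == 0, ifelse(lfc == 0, 0, sign(lfc) * Inf),
                 lfc / denom)
  list(log2fc = lfc, stat = stat)
}

## All distinct assignments of `na` out of `n` columns to group A, as a
## matrix with one assignment per column; NULL if there are more than cap.
exhaustive_assignments <- function(n, na, cap) {
  if (choose(n, na) > cap) return(NULL)
  utils::combn(n, na)
}

#' Permutation-based FDR for the s0-moderated test
#'
#' Computes the observed |stat| for every protein, re-computes all |stat|
#' under permutations of the sample labels, and estimates for every
#' threshold `t` the false discovery rate
#' `FDR(t) = mean permuted count(|stat*| >= t) / observed count(|stat| >= t)`.
#' Each protein's q-value is the minimum estimated FDR over all thresholds
#' at or below its own |stat| (monotone in |stat| by construction, capped
#' at 1). All distinct label assignments are enumerated exhaustively when
#' their number is at most `exhaustive_cap`; otherwise `n_permutations`
#' random assignments are drawn (deterministic given `rng_seed`).
#'
#' @param X numeric matrix, proteins x samples (complete, log2 scale).
#' @param labels vector of two group labels, one per column; the first
#'   label in `unique(labels)` is group A (log2fc = mean A - mean B).
#' @param s0 moderation constant.
#' @param n_permutations number of random assignments when exhaustive
#'   enumeration is infeasible.
#' @param exhaustive_cap maximum number of assignments to enumerate.
#' @param rng_seed integer seed for the randomized mode.
#' @return data.frame, one row per protein: `protein`, `log2fc`, `stat`,
#'   `q`; attributes `n_assignments` and `exhaustive`.
#' @export
permutation_fdr <- function(X, labels, s0 = 0, n_permutations = 250L,
                            exhaustive_cap = 10000L, rng_seed = 1L) {
  if (length(labels) != ncol(X)) stop("one label per sample column required")
  lev <- unique(labels)
  if (length(lev) != 2L) stop("exactly two groups required")
  ia <- which(labels == lev[1]); ib <- which(labels == lev[2])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("need >= 2 samples per group")
  if (anyNA(X)) stop("matrix contains missing values; impute first")
  n <- ncol(X); na <- length(ia)
  obs <- row_moderated_stat(X, ia, ib, s0)
  abs_obs <- abs(obs$stat)

  asg <- exhaustive_assignments(n, na, exhaustive_cap)
  if (is.null(asg)) {
    set.seed(as.integer(rng_seed))
    asg <- replicate(n_permutations, sample.int(n, na))
    exhaustive <- FALSE
  } else exhaustive <- TRUE
  n_asg <- ncol(asg)

  perm_pool <- numeric(n_asg * nrow(X))
  cols <- seq_len(n)
  for (k in seq_len(n_asg)) {
    pa <- asg[, k]; pb <- cols[-pa]
    st <- row_moderated_stat(X, pa, pb, s0)$stat
    perm_pool[((k - 1L) * nrow(X) + 1L):(k * nrow(X))] <- abs(st)
  }
  perm_pool <- sort(perm_pool[is.finite(perm_pool)])
  n_inf_perm <- n_asg * nrow(X) - length(perm_pool)

  sorted_obs <- sort(abs_obs)
  count_ge <- function(pool, t) length(pool) - findInterval(t, pool,
                                                            left.open = TRUE)
  ## infinite permuted stats exceed every threshold; infinite observed
  ## stats are handled by findInterval directly
  fdr_at <- vapply(abs_obs, function(t) {
    nobs <- count_ge(sorted_obs, t)
    nperm <- count_ge(perm_pool, t) + n_inf_perm
    min(1, (nperm / n_asg) / max(1L, nobs))
  }, numeric(1))

  ## q = min FDR over thresholds at or below own |stat|
  ord <- order(abs_obs)
  q <- numeric(length(abs_obs))
  q[ord] <- cummin(fdr_at[ord])

  out <- data.frame(protein = if (is.null(rownames(X)))
    sprintf("row%04d", seq_len(nrow(X))) else rownames(X),
    log2fc = obs$log2fc, stat = obs$stat, q = q,
    stringsAsFactors = FALSE)
  attr(out, "n_assignments") <- n_asg
  attr(out, "exhaustive") <- exhaustive
  out
}

#' Call enriched and depleted proteins
#'
#' A protein is `enriched` when `q <= fdr_threshold` and
#' `log2fc >= min_lfc`; `depleted` symmetrically. `min_lfc = 0` disables
#' the fold filter (then significance alone decides, with direction from
#' the sign of the fold change).
#'
#' @param results data.frame from [permutation_fdr()].
#' @param fdr_threshold q-value cutoff.
#' @param min_lfc minimum |log2 fold change| (>= comparison).
#' @return list: `results` with `significant` and `direction` columns, and
#'   `sets` (`enriched`, `depleted` protein id vectors).
#' @export
call_enrichment <- function(results, fdr_threshold, min_lfc = 0) {
  sig <- results$q <= fdr_threshold & abs(results$log2fc) >= min_lfc &
    results$log2fc != 0
  dir <- ifelse(sig & results$log2fc > 0, "enriched",
                ifelse(sig & results$log2fc < 0, "depleted", "none"))
  results$significant <- dir != "none"
  results$direction <- dir
  list(results = results,
       sets = list(enriched = results$protein[dir == "enriched"],
                   depleted = results$protein[dir == "depleted"]))
}

#' Overlap of two protein sets
#'
#' @param set_a,set_b character vectors of protein identifiers.
#' @return list: memberships `only_a`, `only_b`, `both` and a named
#'   `counts` vector (the counts always sum to the union size).
#' @export
overlap_sets <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  both <- intersect(set_a, set_b)
  only_a <- setdiff(set_a, set_b)
  only_b <- setdiff(set_b, set_a)
  list(only_a = only_a, only_b = only_b, both = both,
       counts = c(only_a = length(only_a), only_b = length(only_b),
                  both = length(both)))
}

#' Differential interactome analysis, end to end
#'
#' Runs the label-free differential enrichment workflow in the canonical
#' order: detection filter, downshifted imputation, optional bait
#' normalization, then the s0-moderated permutation-FDR two-sample test
#' between two conditions, and enrichment calls. Deterministic given
#' `rng_seed`.
#'
#' @param mat an [intensity_matrix()].
#' @param condition_a,condition_b the two conditions to compare (log2fc is
#'   `mean(condition_a) - mean(condition_b)`).
#' @param s0 moderation constant.
#' @param fdr_threshold,min_lfc enrichment-call parameters (e.g. `0.01`
#'   and `1.5`, or `0.05` and `0` for the bait-normalized comparison).
#' @param bait bait protein for normalization, or `NULL` to skip.
#' @param impute impute missing values before testing (default); when
#'   `FALSE`, proteins with any missing value in the compared samples are
#'   dropped.
#' @param exclude_conditions conditions that cannot qualify a protein in
#'   the detection filter (e.g. the uninduced control).
#' @param min_detect_frac see [filter_valid()].
#' @param n_permutations,exhaustive_cap,rng_seed see [permutation_fdr()].
#' @return list: `results` (per-protein data.frame with calls), `sets`,
#'   `imputed` (count of imputed cells), `n_filtered` (proteins removed by
#'   the detection filter).
#' @export
ipms_diff <- function(mat, condition_a, condition_b, s0 = 0.1,
                      fdr_threshold = 0.05, min_lfc = 0, bait = NULL,
                      impute = TRUE, exclude_conditions = character(),
                      min_detect_frac = 1.0, n_permutations = 250L,
                      exhaustive_cap = 10000L, rng_seed = 1L) {
  stopifnot(inherits(mat, "intensity_matrix"))
  for (cn in c(condition_a, condition_b))
    if (!cn %in% mat$meta$condition) stop("condition not found: ", cn)
  flt <- filter_valid(mat, min_detect_frac = min_detect_frac,
                      exclude_conditions = exclude_conditions)
  n_filtered <- attr(flt, "n_removed")
  if (impute) {
    imp <- impute_downshift(flt, rng_seed = rng_seed)
    work <- imp$matrix
    n_imputed <- sum(imp$mask)
  } else {
    work <- flt
    n_imputed <- 0L
  }
  if (!is.null(bait)) work <- bait_normalize(work, bait)

  cols <- work$meta$condition %in% c(condition_a, condition_b)
  X <- work$values[, cols, drop = FALSE]
  labels <- work$meta$condition[cols]
  ## put condition_a first so log2fc = mean(a) - mean(b)
  ord <- order(labels != condition_a)
  X <- X[, ord, drop = FALSE]; labels <- labels[ord]
  if (!impute) {
    complete <- rowSums(is.na(X)) == 0L
    X <- X[complete, , drop = FALSE]
  }
  res <- permutation_fdr(X, labels, s0 = s0,
                         n_permutations = n_permutations,
                         exhaustive_cap = exhaustive_cap,
                         rng_seed = rng_seed)
  called <- call_enrichment(res, fdr_threshold = fdr_threshold,
                            min_lfc = min_lfc)
  list(results = called$results, sets = called$sets,
       imputed = n_imputed, n_filtered = n_filtered)
}
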