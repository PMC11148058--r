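## Quantification of nuclear and metaphase-spread fluorescence signals.
## Interphase nuclei are defined on the DAPI channel (global Otsu threshold
## after smoothing); mitotic figures and border-touching cells are filtered
## out; mean per-channel nuclear intensities and integrated DAPI feed the
## EdU/DAPI cell-cycle gate. Spread images are partitioned into centromeric
## (CENP-C focus) and noncentromeric (arm) regions with a robust
## outside-mask background correction.

#' Otsu threshold for a numeric vector
#'
#' Histogram-based two-class Otsu threshold (maximum between-class
#' variance), used for 1-D gating of log-intensities. The threshold is a
#' bin boundary on the range of the data, so the assignment of points to
#' classes is invariant to adding a constant (and hence, on log scale, to
#' rescaling the raw intensities).
#'
#' @param x numeric vector (finite values).
#' @param n_bins number of histogram bins.
#' @return the threshold (scalar); values `> threshold` form the upper class.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0)
    stop("cannot compute Otsu threshold: fewer than 2 distinct values")
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  h <- as.numeric(tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                           nbins = n_bins))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(n_bins))
  n <- w[n_bins]; mtot <- mu[n_bins]
  wf <- n - w
  between <- (mtot * w - mu * n)^2 / (w * wf * n^2)
  between[w == 0 | wf == 0] <- 0
  ## empty bins between the modes tie exactly; split mid-valley
  ties <- which(between == max(between))
  breaks[floor(mean(ties)) + 1L]
}

#' Segment interphase nuclei from a DAPI image
#'
#' Smooths the DAPI plane, applies a global Otsu threshold (recomputed per
#' image, so segmentation is invariant to global intensity scaling), fills
#' holes and labels connected components. Components smaller than
#' `min_area`, touching the border margin, or flagged as mitotic figures
#' (see [flag_mitotic()]) are excluded; measurements are returned for the
#' surviving nuclei along with the excluded objects and their reasons.
#'
#' Intensities are measured over a slightly eroded core of each component
#' so that the dim, blurred boundary ring does not dilute the mean -- the
#' usual edge-effect guard in intensity quantification.
#'
#' @param stack a [channel_stack()] containing a `DAPI` plane; every other
#'   plane is measured per nucleus as `mean_<lowercased channel>`.
#' @param min_area minimum component (core) area (px^2).
#' @param border_margin components whose full extent comes within this many
#'   pixels of the image edge are excluded as border cells.
#' @param smooth_sigma Gaussian smoothing sigma (px) before thresholding.
#' @param erode_radius radius (px) of the erosion applied before labeling
#'   and measurement.
#' @param mitotic_k,mitotic_area_frac parameters of the mitotic filter.
#' @return list: `labels` (integer label matrix), `measurements`
#'   (data.frame per surviving nucleus: `label`, 0-based centroid `y`,`x`,
#'   `area`, `mean_dapi`, `integrated_dapi`, `mean_*` per channel,
#'   `on_border`, `mitotic`, `phase = "unassigned"`), and `excluded`
#'   (same columns plus `reason`).
#' @export
segment_nuclei <- function(stack, min_area = 50, border_margin = 2,
                           smooth_sigma = 2, erode_radius = 4,
                           mitotic_k = 2, mitotic_area_frac = 0.5) {
  dapi <- get_plane(stack, "DAPI")
  empty <- data.frame(label = integer(), y = numeric(), x = numeric(),
                      area = integer(), mean_dapi = numeric(),
                      integrated_dapi = numeric(), on_border = logical(),
                      mitotic = logical(), phase = character(),
                      stringsAsFactors = FALSE)
  if (max(dapi) <= 0)
    return(list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                measurements = empty, excluded = cbind(empty,
                  reason = character())))

  sm <- as.matrix(EBImage::gblur(EBImage::Image(dapi / max(dapi)),
                                 sigma = smooth_sigma))
  ## Otsu on log intensity: compresses very bright (mitotic) pixels so the
  ## threshold separates background from nuclei rather than nuclei from
  ## mitotic figures; max-normalization keeps it scale invariant
  thr <- otsu_threshold(log(pmax(sm, 0) + 1e-3))
  mask <- EBImage::fillHull(log(pmax(sm, 0) + 1e-3) > thr)
  if (erode_radius > 0) {
    brush <- EBImage::makeBrush(2L * erode_radius + 1L, shape = "disc")
    mask <- EBImage::erode(mask, brush)
  }
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  n_obj <- max(lab)
  if (n_obj == 0L)
    return(list(labels = lab, measurements = empty,
                excluded = cbind(empty, reason = character())))

  idx <- which(lab > 0L)
  li <- lab[idx]
  rr <- (idx - 1L) %% nrow(lab) + 1L
  cc <- (idx - 1L) %/% nrow(lab) + 1L
  area <- tabulate(li, n_obj)
  fl <- factor(li, levels = seq_len(n_obj))
  cy <- as.numeric(tapply(rr, fl, mean)) - 1
  cx <- as.numeric(tapply(cc, fl, mean)) - 1
  rmin <- as.numeric(tapply(rr, fl, min)); rmax <- as.numeric(tapply(rr, fl, max))
  cmin <- as.numeric(tapply(cc, fl, min)); cmax <- as.numeric(tapply(cc, fl, max))
  ## the full (pre-erosion) component reaches `erode_radius` further out
  reach <- border_margin + erode_radius
  on_border <- rmin <= reach | cmin <= reach |
    rmax > nrow(lab) - reach | cmax > ncol(lab) - reach

  meas <- data.frame(label = seq_len(n_obj), y = cy, x = cx,
                     area = as.integer(area), stringsAsFactors = FALSE)
  dsum <- as.numeric(tapply(dapi[idx], fl, sum))
  meas$mean_dapi <- dsum / area
  meas$integrated_dapi <- dsum
  for (ch in setdiff(names(stack), "DAPI")) {
    meas[[paste0("mean_", tolower(ch))]] <-
      as.numeric(tapply(stack[[ch]][idx], fl, sum)) / area
  }
  meas$on_border <- on_border

  small <- meas$area < min_area
  meas <- flag_mitotic(meas[!small, , drop = FALSE], k = mitotic_k,
                       area_frac = mitotic_area_frac)
  meas$phase <- "unassigned"

  drop <- meas$on_border | meas$mitotic
  excluded <- meas[drop, , drop = FALSE]
  excluded$reason <- ifelse(excluded$mitotic & excluded$on_border,
                            "border+mitotic",
                            ifelse(excluded$mitotic, "mitotic", "border"))
  keep <- meas[!drop, , drop = FALSE]
  rownames(keep) <- rownames(excluded) <- NULL
  list(labels = lab, measurements = keep, excluded = excluded)
}

#' Flag condensed mitotic figures among segmented objects
#'
#' A component is flagged mitotic when its mean DAPI intensity exceeds the
#' population center by more than `k` population spreads *and* its area is
#' below `area_frac` of the median area -- the signature of condensed
#' mitotic chromatin. The center and spread are the median and
#' MAD-estimated SD (1.4826 * MAD): the mitotic figures being detected are
#' themselves extreme DAPI outliers, so moment estimates of the population
#' would be contaminated by exactly the objects the filter must catch.
#' With fewer than 3 objects the population statistics are meaningless and
#' all flags are left `FALSE` with a warning.
#'
#' @param measurements data.frame with `mean_dapi` and `area` columns.
#' @param k DAPI outlier threshold in population spreads.
#' @param area_frac area cutoff as a fraction of the median area.
#' @return the input with a logical `mitotic` column.
#' @export
flag_mitotic <- function(measurements, k = 2, area_frac = 0.5) {
  if (nrow(measurements) < 3L) {
    if (nrow(measurements) > 0L)
      warning("fewer than 3 nuclei: mitotic flags left FALSE")
    measurements$mitotic <- rep(FALSE, nrow(measurements))
    return(measurements)
  }
  ctr <- stats::median(measurements$mean_dapi)
  spr <- stats::mad(measurements$mean_dapi)
  if (spr == 0) spr <- stats::sd(measurements$mean_dapi)
  med_area <- stats::median(measurements$area)
  measurements$mitotic <- measurements$mean_dapi > ctr + k * spr &
    measurements$area < area_frac * med_area
  measurements
}

#' Gate nuclei into cell-cycle phases from EdU and DAPI intensities
#'
#' Reproduces image-cytometry gating: nuclei positive for EdU (threshold by
#' Otsu on log mean EdU) are in S phase; EdU-negative nuclei are split on
#' log integrated DAPI by a second Otsu threshold into G1 (2N, lower mode)
#' and G2 (4N, upper mode). Because both gates act on log intensities with
#' data-derived thresholds, phase assignments are invariant to global gain
#' changes of either channel. If the EdU-negative DAPI distribution does not
#' show two modes (mode ratio below `min_separation`, the signature of a
#' failed stain or a collapsed gate) the function stops rather than assign
#' phases silently.
#'
#' @param measurements data.frame with `mean_edu` and `integrated_dapi`.
#' @param min_nuclei minimum number of nuclei required to fit the gate.
#' @param min_separation minimum G2/G1 integrated-DAPI mode ratio for the
#'   split to be considered bimodal (a true 4N/2N ratio is close to 2).
#' @return list: `model` (`edu_threshold`, `dapi_g1_mode`, `dapi_g2_mode`,
#'   `dapi_split`, `separation` -- a gate-quality metric), and
#'   `measurements` with the `phase` column filled with `G1`/`S`/`G2`.
#' @export
gate_cell_cycle <- function(measurements, min_nuclei = 30L,
                            min_separation = 1.4) {
  need <- c("mean_edu", "integrated_dapi")
  if (!all(need %in% names(measurements)))
    stop("measurements must have mean_edu and integrated_dapi")
  if (nrow(measurements) < min_nuclei)
    stop("too few nuclei to gate (", nrow(measurements), " < ",
         min_nuclei, ")")
  eps <- .Machine$double.eps
  log_edu <- log(pmax(measurements$mean_edu, eps))
  edu_thr <- otsu_threshold(log_edu)
  s_phase <- log_edu > edu_thr

  neg <- which(!s_phase)
  if (length(neg) < 4L)
    stop("gate failure: almost no EdU-negative nuclei to split into G1/G2")
  log_dapi <- log(pmax(measurements$integrated_dapi[neg], eps))
  split <- otsu_threshold(log_dapi)
  lower <- log_dapi <= split
  if (!any(lower) || all(lower))
    stop("gate failure: DAPI split produced an empty class")
  g1_mode <- stats::median(exp(log_dapi[lower]))
  g2_mode <- stats::median(exp(log_dapi[!lower]))
  separation <- g2_mode / g1_mode
  if (separation < min_separation)
    stop("gate failure: EdU-negative DAPI distribution is unimodal ",
         sprintf("(mode ratio %.2f < %.2f); cannot separate G1 from G2",
                 separation, min_separation))

  phase <- rep("S", nrow(measurements))
  phase[neg[lower]] <- "G1"
  phase[neg[!lower]] <- "G2"
  measurements$phase <- phase
  list(model = list(edu_threshold = exp(edu_thr), dapi_g1_mode = g1_mode,
                    dapi_g2_mode = g2_mode, dapi_split = exp(split),
                    separation = separation),
       measurements = measurements)
}

#' Summarize nuclear intensity per cell-cycle phase and condition
#'
#' @param measurements phased measurements (a `phase` column, plus the value
#'   column).
#' @param condition character vector of per-nucleus condition labels
#'   (recycled if length 1).
#' @param value_col which intensity column to summarize (default
#'   `"mean_yfp"`).
#' @return data.frame with one row per phase x condition: `n`, `mean`, `sd`
#'   (0 for singletons). Empty cells are absent from the output.
#' @export
compare_phase_intensity <- function(measurements, condition,
                                    value_col = "mean_yfp") {
  if (!value_col %in% names(measurements))
    stop("no column '", value_col, "' in measurements")
  condition <- rep_len(as.character(condition), nrow(measurements))
  v <- measurements[[value_col]]
  key <- interaction(measurements$phase, condition, drop = TRUE, sep = "\r")
  sp <- split(v, key)
  parts <- strsplit(names(sp), "\r", fixed = TRUE)
  out <- data.frame(
    phase = vapply(parts, `[`, "", 1),
    condition = vapply(parts, `[`, "", 2),
    n = vapply(sp, length, integer(1)),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(x) if (length(x) > 1L) stats::sd(x) else 0,
                numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$condition, out$phase), ]
}

## Laplacian-of-Gaussian kernel (normalized so blob response scales with
## sigma^2, the standard scale normalization).
log_kernel <- function(sigma) {
  r <- ceiling(3.5 * sigma)
  d <- outer((-r:r)^2, (-r:r)^2, "+")
  k <- (d - 2 * sigma^2) / (2 * pi * sigma^6) * exp(-d / (2 * sigma^2))
  k - mean(k) # zero-sum: flat regions give zero response
}

#' Detect centromeric foci by Laplacian-of-Gaussian blob detection
#'
#' Convolves the CENP-C (centromere marker) plane with scale-normalized LoG
#' kernels over `sigma_range`, takes the maximum response across scales and
#' keeps local maxima inside the chromosome mask that rise above a robust
#' (median + `threshold_k` * MAD) in-mask response threshold. Detected
#' centers are dilated to `dilate_radius` to form the centromeric region,
#' clipped to the chromosome mask.
#'
#' @param cenpc numeric matrix, centromere marker plane.
#' @param chrom_mask logical matrix, chromosome (DAPI) mask.
#' @param sigma_range blob scale range in px (two values; three scales are
#'   sampled across it).
#' @param threshold_k robust threshold multiplier.
#' @param dilate_radius radius (px) of the centromeric region grown around
#'   each detected focus.
#' @return logical foci mask with attributes `n_foci` and `centers`
#'   (data.frame of 0-based `y`, `x`). Empty (with a warning) when nothing
#'   is detected.
#' @export
detect_centromere_foci <- function(cenpc, chrom_mask, sigma_range = c(1, 2),
                                   threshold_k = 8, dilate_radius = 4) {
  if (!all(dim(cenpc) == dim(chrom_mask)))
    stop("cenpc plane and chromosome mask differ in shape")
  chrom_mask <- chrom_mask > 0
  sigmas <- seq(sigma_range[1], sigma_range[2], length.out = 3)
  resp <- NULL
  for (s in sigmas) {
    r <- -as.matrix(EBImage::filter2(EBImage::Image(cenpc), log_kernel(s)))
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  empty <- function() {
    warning("no centromeric foci detected")
    structure(matrix(FALSE, nrow(cenpc), ncol(cenpc)), n_foci = 0L,
              centers = data.frame(y = numeric(), x = numeric()))
  }
  rin <- resp[chrom_mask]
  if (length(rin) == 0L) return(empty())
  thr <- stats::median(rin) + threshold_k * stats::mad(rin)

  ## strict local maxima in the 8-neighborhood
  nr <- nrow(resp); nc <- ncol(resp)
  is_max <- matrix(TRUE, nr, nc)
  core_r <- 2:(nr - 1); core_c <- 2:(nc - 1)
  center <- resp[core_r, core_c]
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max[core_r, core_c] <- is_max[core_r, core_c] &
      center >= resp[core_r + dr, core_c + dc]
  }
  is_max[c(1, nr), ] <- FALSE
  is_max[, c(1, nc)] <- FALSE
  peaks <- is_max & chrom_mask & resp > thr
  if (!any(peaks)) return(empty())

  pk <- which(peaks)
  centers <- data.frame(y = (pk - 1L) %% nr, x = (pk - 1L) %/% nr)
  brush <- EBImage::makeBrush(2L * dilate_radius + 1L, shape = "disc")
  foci <- EBImage::imageData(EBImage::dilate(EBImage::Image(peaks * 1),
                                             brush)) > 0
  foci <- foci & chrom_mask
  structure(foci, n_foci = nrow(centers), centers = centers)
}

#' Quantify centromeric vs noncentromeric signal on a spread
#'
#' Background is the median intensity outside the chromosome mask (robust
#' to bright debris). The centromeric mean is the background-corrected mean
#' over the foci region; the noncentromeric (arm) mean is over the
#' chromosome mask minus the foci. Negative corrected means are clamped to
#' 0 and flagged.
#'
#' @param cenpa numeric matrix, the quantified (e.g. CENP-A) plane.
#' @param foci_mask logical centromeric-region mask (must be a subset of
#'   `chrom_mask`).
#' @param chrom_mask logical chromosome mask.
#' @return one-row data.frame: `centromeric_mean`, `noncentromeric_mean`,
#'   `background`, `n_foci` (from the mask attribute when available),
#'   `chrom_area`, `clamped`.
#' @export
quantify_spread <- function(cenpa, foci_mask, chrom_mask) {
  if (!all(dim(cenpa) == dim(chrom_mask)) ||
      !all(dim(cenpa) == dim(foci_mask)))
    stop("masks and plane differ in shape")
  chrom_mask <- chrom_mask > 0; fm <- foci_mask > 0
  if (any(fm & !chrom_mask))
    stop("foci mask is not a subset of the chromosome mask")
  outside <- !chrom_mask
  background <- if (any(outside)) stats::median(cenpa[outside]) else 0
  cent <- if (any(fm)) mean(cenpa[fm]) - background else NA_real_
  arm_px <- chrom_mask & !fm
  noncent <- if (any(arm_px)) mean(cenpa[arm_px]) - background else NA_real_
  clamped <- isTRUE(cent < 0) || isTRUE(noncent < 0)
  if (isTRUE(cent < 0)) cent <- 0
  if (isTRUE(noncent < 0)) noncent <- 0
  nf <- attr(foci_mask, "n_foci")
  data.frame(centromeric_mean = cent, noncentromeric_mean = noncent,
             background = background,
             n_foci = if (is.null(nf)) NA_integer_ else nf,
             chrom_area = sum(chrom_mask), clamped = clamped)
}

#' Fold change of group medians
#'
#' The summary used to compare spread intensity distributions between
#' conditions: `median(b) / median(a)`, reported with group sizes.
#'
#' @param values_a,values_b numeric vectors (nonempty).
#' @return one-row data.frame: `fold`, `median_a`, `median_b`, `n_a`, `n_b`.
#' @export
fold_change_medians <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both groups must be nonempty")
  ma <- stats::median(values_a); mb <- stats::median(values_b)
  if (ma == 0) stop("undefined ratio: median of the reference group is 0")
  data.frame(fold = mb / ma, median_a = ma, median_b = mb,
             n_a = length(values_a), n_b = length(values_b))
}
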