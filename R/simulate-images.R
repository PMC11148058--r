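## Synthetic fluorescence microscopy: interphase nuclei fields (DAPI / YFP /
## EdU) and metaphase chromosome spreads (DAPI / CENP-A / CENP-C), rendered
## as filled ellipses and Gaussian foci with known per-object ground truth.
## The geometry is deliberately minimal: just enough structure to exercise
## segmentation, QC filters, cell-cycle gating and the centromeric/arm
## signal partition.

#' Configuration for a simulated nuclei field
#'
#' @param width,height image size in pixels.
#' @param n_nuclei number of objects to place (0 gives blank channels).
#' @param radius_range nucleus semi-axis range in px (>= 3).
#' @param phase_fractions named fractions for `G1`, `S`, `G2`; must sum to 1.
#' @param dapi_g1_total mean integrated DAPI intensity of a G1 (2N) nucleus;
#'   G2 nuclei average twice this, S-phase nuclei fall in between.
#' @param dapi_cv cell-to-cell CV of integrated DAPI within a phase.
#' @param edu_s_mean,edu_neg_mean mean EdU intensity for S-phase and
#'   non-S-phase nuclei.
#' @param yfp_mean mean nuclear YFP-CENP-A intensity for this condition.
#' @param yfp_cv cell-to-cell CV of the true mean YFP.
#' @param noise_frac additive Gaussian noise SD as a fraction of the mean
#'   foreground signal of each channel (in `[0, 1)`).
#' @param border_prob probability a nucleus is placed overlapping the image
#'   border.
#' @param mitotic_prob probability an object is a condensed mitotic figure
#'   (small, DAPI-bright) instead of an interphase nucleus.
#' @param edge_sigma Gaussian blur applied to object edges (px).
#' @param rng_seed integer seed.
#' @return object of class `image_sim_config`.
#' @export
image_sim_config <- function(width = 512L, height = 512L, n_nuclei = 80L,
                             radius_range = c(12, 18),
                             phase_fractions = c(G1 = 0.5, S = 0.3, G2 = 0.2),
                             dapi_g1_total = 5e4, dapi_cv = 0.07,
                             edu_s_mean = 200, edu_neg_mean = 20,
                             yfp_mean = 100, yfp_cv = 0.2,
                             noise_frac = 0.05,
                             border_prob = 0.05, mitotic_prob = 0.03,
                             edge_sigma = 1, rng_seed = 1L) {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              n_nuclei = as.integer(n_nuclei), radius_range = radius_range,
              phase_fractions = phase_fractions,
              dapi_g1_total = dapi_g1_total, dapi_cv = dapi_cv,
              edu_s_mean = edu_s_mean, edu_neg_mean = edu_neg_mean,
              yfp_mean = yfp_mean, yfp_cv = yfp_cv, noise_frac = noise_frac,
              border_prob = border_prob, mitotic_prob = mitotic_prob,
              edge_sigma = edge_sigma, rng_seed = as.integer(rng_seed))
  if (abs(sum(cfg$phase_fractions) - 1) > 1e-8)
    stop("phase fractions must sum to 1")
  if (!all(c("G1", "S", "G2") %in% names(cfg$phase_fractions)))
    stop("phase_fractions must name G1, S and G2")
  if (min(cfg$radius_range) < 3) stop("nucleus radii must be >= 3 px")
  if (cfg$noise_frac < 0 || cfg$noise_frac >= 1)
    stop("noise_frac must be in [0, 1)")
  if (cfg$n_nuclei < 0L) stop("n_nuclei must be >= 0")
  class(cfg) <- "image_sim_config"
  cfg
}

## Add a filled, rotated ellipse to `plane`; returns list(plane, area).
## (y0, x0) are 0-based pixel coordinates.
add_ellipse <- function(plane, y0, x0, a, b, theta, value) {
  nr <- nrow(plane); nc <- ncol(plane)
  rmax <- max(a, b)
  rows <- max(1L, floor(y0 - rmax)):min(nr, ceiling(y0 + rmax + 2))
  cols <- max(1L, floor(x0 - rmax)):min(nc, ceiling(x0 + rmax + 2))
  dy <- outer(rows - 1 - y0, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - 1 - x0)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- (u^2 + v^2) <= 1
  plane[rows, cols][inside] <- plane[rows, cols][inside] + value
  list(plane = plane, area = sum(inside))
}

## Pixel area of an ellipse clipped to the image (for per-pixel intensity).
ellipse_pixels <- function(nr, nc, y0, x0, a, b, theta) {
  rmax <- max(a, b)
  rows <- max(1L, floor(y0 - rmax)):min(nr, ceiling(y0 + rmax + 2))
  cols <- max(1L, floor(x0 - rmax)):min(nc, ceiling(x0 + rmax + 2))
  dy <- outer(rows - 1 - y0, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - 1 - x0)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  sum((u^2 + v^2) <= 1)
}

blur_plane <- function(plane, sigma) {
  if (sigma <= 0) return(plane)
  as.matrix(EBImage::gblur(EBImage::Image(plane), sigma = sigma))
}

add_noise <- function(plane, sd) {
  if (sd <= 0) return(plane)
  out <- plane + stats::rnorm(length(plane), 0, sd)
  out[out < 0] <- 0
  out
}

#' Simulate a nuclei field with cell-cycle ground truth
#'
#' Renders interphase nuclei (filled ellipses, Gaussian-smoothed edges) with
#' per-phase DAPI content (G2 integrated DAPI is about twice G1), EdU
#' incorporation restricted to S phase, and a condition-level nuclear YFP
#' reporter signal; optionally plants border-overlapping nuclei and
#' condensed mitotic figures to exercise the segmentation QC filters.
#'
#' @param config an [image_sim_config()].
#' @return list with class `nuclei_sim`: `stack` (a [channel_stack()] with
#'   `DAPI`, `YFP`, `EdU`) and `truth` (one row per object: 0-based centroid
#'   `y`,`x`, semi-axes, `area`, `phase` (`G1`/`S`/`G2`/`M`),
#'   `true_total_dapi`, `true_mean_yfp`, `true_mean_edu`, `on_border`,
#'   `mitotic`).
#' @export
simulate_nuclei_image <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "image_sim_config"))
  set.seed(cfg$rng_seed)
  nr <- cfg$height; nc <- cfg$width
  blank <- matrix(0, nr, nc)
  empty_truth <- data.frame(
    nucleus_id = integer(), y = numeric(), x = numeric(), a = numeric(),
    b = numeric(), theta = numeric(), area = integer(), phase = character(),
    true_total_dapi = numeric(), true_mean_yfp = numeric(),
    true_mean_edu = numeric(), on_border = logical(), mitotic = logical(),
    stringsAsFactors = FALSE)
  if (cfg$n_nuclei == 0L)
    return(structure(list(
      stack = channel_stack(DAPI = blank, YFP = blank, EdU = blank),
      truth = empty_truth, config = cfg), class = "nuclei_sim"))

  ## ---- geometry: placement with bounded retries ------------------------
  n <- cfg$n_nuclei
  r_mean <- mean(cfg$radius_range)
  ys <- xs <- as_ <- bs <- th <- numeric(n)
  border <- logical(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:200) {
      a <- stats::runif(1, cfg$radius_range[1], cfg$radius_range[2])
      b <- a * stats::runif(1, 0.8, 1)
      r <- max(a, b)
      on_b <- stats::runif(1) < cfg$border_prob
      if (on_b) {
        edge <- sample(4, 1)
        d <- stats::runif(1, 0, 0.7 * r) # center this close to the edge
        y0 <- switch(edge, d, nr - 1 - d,
                     stats::runif(1, r, nr - 1 - r),
                     stats::runif(1, r, nr - 1 - r))
        x0 <- switch(edge, stats::runif(1, r, nc - 1 - r),
                     stats::runif(1, r, nc - 1 - r), d, nc - 1 - d)
      } else {
        y0 <- stats::runif(1, r + 2, nr - 3 - r)
        x0 <- stats::runif(1, r + 2, nc - 3 - r)
      }
      if (i == 1L ||
          all(sqrt((ys[seq_len(i - 1)] - y0)^2 +
                   (xs[seq_len(i - 1)] - x0)^2) >
              r + pmax(as_[seq_len(i - 1)], bs[seq_len(i - 1)]) + 6)) {
        ys[i] <- y0; xs[i] <- x0; as_[i] <- a; bs[i] <- b
        th[i] <- stats::runif(1, 0, pi); border[i] <- on_b
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("placement error: could not fit ", n, " nuclei of radius ~",
           round(r_mean), " px into a ", nc, " x ", nr, " image")
  }

  ## ---- biology: phase, intensities ------------------------------------
  mitotic <- stats::runif(n) < cfg$mitotic_prob
  phase <- sample(names(cfg$phase_fractions), n, replace = TRUE,
                  prob = cfg$phase_fractions)
  phase[mitotic] <- "M"
  ## mitotic figures: condensed (small) 4N objects
  as_[mitotic] <- pmax(3.2, as_[mitotic] * 0.4)
  bs[mitotic] <- pmax(3, bs[mitotic] * 0.4)

  dapi_mult <- c(G1 = 1, S = NA, G2 = 2, M = 2)[phase]
  dapi_mult[phase == "S"] <- stats::runif(sum(phase == "S"), 1.15, 1.85)
  total_dapi <- cfg$dapi_g1_total * dapi_mult *
    exp(stats::rnorm(n, 0, cfg$dapi_cv))
  mean_yfp <- cfg$yfp_mean * exp(stats::rnorm(n, 0, cfg$yfp_cv))
  mean_edu <- ifelse(phase == "S", cfg$edu_s_mean, cfg$edu_neg_mean) *
    exp(stats::rnorm(n, 0, 0.1))

  dapi <- yfp <- edu <- blank
  area <- integer(n)
  for (i in seq_len(n)) {
    full_area <- max(1L, ellipse_pixels(nr, nc, ys[i], xs[i], as_[i], bs[i],
                                        th[i]))
    per_px <- total_dapi[i] / full_area
    res <- add_ellipse(dapi, ys[i], xs[i], as_[i], bs[i], th[i], per_px)
    dapi <- res$plane; area[i] <- res$area
    yfp <- add_ellipse(yfp, ys[i], xs[i], as_[i], bs[i], th[i],
                       mean_yfp[i])$plane
    edu <- add_ellipse(edu, ys[i], xs[i], as_[i], bs[i], th[i],
                       mean_edu[i])$plane
  }

  fg_noise <- function(plane) {
    fg <- plane[plane > 0]
    if (length(fg) == 0L) 0 else cfg$noise_frac * mean(fg)
  }
  dapi <- add_noise(blur_plane(dapi, cfg$edge_sigma), fg_noise(dapi))
  yfp <- add_noise(blur_plane(yfp, cfg$edge_sigma), fg_noise(yfp))
  edu <- add_noise(blur_plane(edu, cfg$edge_sigma), fg_noise(edu))

  truth <- data.frame(
    nucleus_id = seq_len(n), y = ys, x = xs, a = as_, b = bs, theta = th,
    area = area, phase = phase, true_total_dapi = total_dapi,
    true_mean_yfp = mean_yfp, true_mean_edu = mean_edu,
    on_border = border, mitotic = mitotic, stringsAsFactors = FALSE)

  structure(list(stack = channel_stack(DAPI = dapi, YFP = yfp, EdU = edu),
                 truth = truth, config = cfg),
            class = "nuclei_sim")
}

#' Configuration for a simulated metaphase chromosome spread
#'
#' @param width,height image size in pixels.
#' @param n_chromosomes chromosomes per spread (46 for a human cell).
#' @param chr_length_range chromosome long-axis length range (px).
#' @param chr_width chromosome short-axis width (px).
#' @param total_cenpa mean total CENP-A signal per chromosome (AU); a
#'   fraction `mislocalization_fraction` of it is spread uniformly over the
#'   chromosome arms, the remainder concentrated in the two sister
#'   centromeric foci.
#' @param mislocalization_fraction fraction of total CENP-A on the arms
#'   (in `[0, 1]`).
#' @param sister_sep distance between sister centromere foci (px).
#' @param focus_sigma Gaussian sigma of a centromeric focus (px).
#' @param cenpc_amp peak CENP-C intensity of a focus (AU).
#' @param dapi_level per-pixel chromosome DAPI intensity (AU).
#' @param background additive background level on the CENP-A channel (AU).
#' @param noise_sd additive Gaussian noise SD on every channel (AU).
#' @param rng_seed integer seed.
#' @return object of class `spread_sim_config`.
#' @export
spread_sim_config <- function(width = 640L, height = 640L,
                              n_chromosomes = 46L,
                              chr_length_range = c(36, 64), chr_width = 14,
                              total_cenpa = 3000,
                              mislocalization_fraction = 0.1,
                              sister_sep = 6, focus_sigma = 1.2,
                              cenpc_amp = 300, dapi_level = 100,
                              background = 10, noise_sd = 2,
                              rng_seed = 1L) {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              n_chromosomes = as.integer(n_chromosomes),
              chr_length_range = chr_length_range, chr_width = chr_width,
              total_cenpa = total_cenpa,
              mislocalization_fraction = mislocalization_fraction,
              sister_sep = sister_sep, focus_sigma = focus_sigma,
              cenpc_amp = cenpc_amp, dapi_level = dapi_level,
              background = background, noise_sd = noise_sd,
              rng_seed = as.integer(rng_seed))
  if (cfg$mislocalization_fraction < 0 || cfg$mislocalization_fraction > 1)
    stop("mislocalization_fraction must be in [0, 1]")
  if (cfg$n_chromosomes < 1L) stop("need at least one chromosome")
  if (cfg$sister_sep / 2 + 3 * cfg$focus_sigma > cfg$chr_width / 2 + 3)
    stop("sister foci would not fit inside the chromosome width")
  class(cfg) <- "spread_sim_config"
  cfg
}

## Add an integrated-intensity `total` Gaussian spot at 0-based (y0, x0).
add_gaussian_spot <- function(plane, y0, x0, sigma, total) {
  nr <- nrow(plane); nc <- ncol(plane)
  r <- ceiling(4 * sigma)
  rows <- max(1L, floor(y0 - r)):min(nr, ceiling(y0 + r + 2))
  cols <- max(1L, floor(x0 - r)):min(nc, ceiling(x0 + r + 2))
  dy <- outer(rows - 1 - y0, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - 1 - x0)
  g <- exp(-(dx^2 + dy^2) / (2 * sigma^2)) * total / (2 * pi * sigma^2)
  plane[rows, cols] <- plane[rows, cols] + g
  plane
}

#' Simulate a metaphase chromosome spread
#'
#' Renders chromosomes as elongated ellipses (DAPI), plants two sister
#' centromeric foci per chromosome (CENP-C marker channel) and distributes
#' each chromosome's total CENP-A signal between the centromeric foci and a
#' uniform arm component according to `mislocalization_fraction`.
#'
#' @param config a [spread_sim_config()].
#' @return list with class `spread_sim`: `stack` ([channel_stack()] with
#'   `DAPI`, `CENPA`, `CENPC`), and `truth` with `chromosomes` (per
#'   chromosome: geometry, `total_cenpa`, `arm_mean` above background),
#'   `foci` (0-based focus coordinates and per-focus centromeric signal)
#'   and the planted `mislocalization_fraction`.
#' @export
simulate_spread_image <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "spread_sim_config"))
  set.seed(cfg$rng_seed)
  nr <- cfg$height; nc <- cfg$width
  dapi <- cenpa <- cenpc <- matrix(0, nr, nc)
  n <- cfg$n_chromosomes
  f <- cfg$mislocalization_fraction

  ys <- xs <- as_ <- th <- numeric(n)
  b <- cfg$chr_width / 2
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:400) {
      a <- stats::runif(1, cfg$chr_length_range[1], cfg$chr_length_range[2]) / 2
      y0 <- stats::runif(1, a + 4, nr - 5 - a)
      x0 <- stats::runif(1, a + 4, nc - 5 - a)
      if (i == 1L ||
          all(sqrt((ys[seq_len(i - 1)] - y0)^2 +
                   (xs[seq_len(i - 1)] - x0)^2) >
              0.85 * (a + as_[seq_len(i - 1)]) + 3)) {
        ys[i] <- y0; xs[i] <- x0; as_[i] <- a
        th[i] <- stats::runif(1, 0, pi)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("placement error: could not fit ", n,
           " chromosomes into the field")
  }

  total <- cfg$total_cenpa * exp(stats::rnorm(n, 0, 0.1))
  chrom_rows <- vector("list", n)
  foci_rows <- vector("list", n)
  area <- integer(n)
  for (i in seq_len(n)) {
    area[i] <- max(1L, ellipse_pixels(nr, nc, ys[i], xs[i], as_[i], b, th[i]))
    dapi <- add_ellipse(dapi, ys[i], xs[i], as_[i], b, th[i],
                        cfg$dapi_level)$plane
    arm_per_px <- f * total[i] / area[i]
    if (arm_per_px > 0)
      cenpa <- add_ellipse(cenpa, ys[i], xs[i], as_[i], b, th[i],
                           arm_per_px)$plane
    ## centromere at a roughly central position along the long axis,
    ## sister foci offset perpendicular to it
    tpos <- (stats::runif(1, -0.25, 0.25)) * as_[i]
    ux <- cos(th[i]); uy <- sin(th[i])     # long-axis direction
    px <- -uy; py <- ux                    # perpendicular
    cy <- ys[i] + tpos * uy; cx <- xs[i] + tpos * ux
    off <- cfg$sister_sep / 2
    fy <- c(cy + off * py, cy - off * py)
    fx <- c(cx + off * px, cx - off * px)
    cent_total <- (1 - f) * total[i] / 2
    for (k in 1:2) {
      cenpa <- add_gaussian_spot(cenpa, fy[k], fx[k], cfg$focus_sigma,
                                 cent_total)
      cenpc <- add_gaussian_spot(cenpc, fy[k], fx[k], cfg$focus_sigma,
                                 cfg$cenpc_amp * 2 * pi * cfg$focus_sigma^2)
      ## consistency: the focus center must lie on the chromosome body
      du <- ((fx[k] - xs[i]) * ux + (fy[k] - ys[i]) * uy) / as_[i]
      dv <- (-(fx[k] - xs[i]) * uy + (fy[k] - ys[i]) * ux) / b
      if (du^2 + dv^2 > 1)
        stop("internal consistency error: centromeric focus outside ",
             "chromosome mask")
    }
    chrom_rows[[i]] <- data.frame(
      chrom_id = i, y = ys[i], x = xs[i], a = as_[i], b = b, theta = th[i],
      area = area[i], total_cenpa = total[i],
      arm_mean = f * total[i] / area[i], stringsAsFactors = FALSE)
    foci_rows[[i]] <- data.frame(
      chrom_id = i, focus = 1:2, y = fy, x = fx,
      cent_total = cent_total, stringsAsFactors = FALSE)
  }

  cenpa <- cenpa + cfg$background
  dapi <- add_noise(dapi, cfg$noise_sd)
  cenpa <- add_noise(cenpa, cfg$noise_sd)
  cenpc <- add_noise(cenpc, cfg$noise_sd)

  structure(list(
    stack = channel_stack(DAPI = dapi, CENPA = cenpa, CENPC = cenpc),
    truth = list(chromosomes = do.call(rbind, chrom_rows),
                 foci = do.call(rbind, foci_rows),
                 mislocalization_fraction = f),
    config = cfg), class = "spread_sim")
}
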