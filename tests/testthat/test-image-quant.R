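test_that("vector Otsu splits a bimodal sample and shifts with the data", {
  set.seed(4)
  x <- c(rnorm(300, 0, 0.3), rnorm(200, 4, 0.3))
  thr <- otsu_threshold(x)
  expect_gt(thr, 1); expect_lt(thr, 3)
  ## class assignment is invariant to adding a constant
  expect_equal(x > thr, (x + 13.7) > otsu_threshold(x + 13.7))
  expect_error(otsu_threshold(rep(1, 10)), "distinct")
})

test_that("blank or channel-less stacks are handled", {
  blank <- channel_stack(DAPI = matrix(0, 32, 32), YFP = matrix(0, 32, 32))
  seg <- segment_nuclei(blank)
  expect_equal(nrow(seg$measurements), 0)
  expect_error(segment_nuclei(channel_stack(YFP = matrix(1, 8, 8))),
               "DAPI")
  expect_error(channel_stack(DAPI = matrix(1, 4, 4), Y = matrix(1, 5, 5)),
               "identical dimensions")
  expect_error(channel_stack(DAPI = matrix(-1, 4, 4)), ">= 0")
})

test_that("segmentation recovers planted nuclei and excludes border cells", {
  sim <- simulate_nuclei_image(image_sim_config(
    n_nuclei = 40, width = 420, height = 420, border_prob = 0.15,
    mitotic_prob = 0, rng_seed = 21))
  seg <- segment_nuclei(sim$stack)
  tt <- sim$truth
  n_border <- sum(tt$on_border)
  ## interior nuclei are kept, border nuclei are not
  expect_gt(nrow(seg$measurements), 0.85 * (nrow(tt) - n_border))
  kept_match <- vapply(seq_len(nrow(seg$measurements)), function(i) {
    which.min((tt$y - seg$measurements$y[i])^2 +
                (tt$x - seg$measurements$x[i])^2)
  }, integer(1))
  expect_false(any(tt$on_border[kept_match]))
  ## per-nucleus mean YFP matches generator truth closely
  err <- abs(seg$measurements$mean_yfp - tt$true_mean_yfp[kept_match]) /
    tt$true_mean_yfp[kept_match]
  expect_lt(mean(err), 0.05)
  ## integrated DAPI is mean x area within rounding
  expect_equal(seg$measurements$integrated_dapi,
               seg$measurements$mean_dapi * seg$measurements$area,
               tolerance = 1e-9)
})

test_that("segmentation is invariant to global DAPI scaling", {
  sim <- simulate_nuclei_image(image_sim_config(
    n_nuclei = 15, width = 300, height = 300, rng_seed = 5))
  st2 <- channel_stack(DAPI = sim$stack$DAPI * 7.3, YFP = sim$stack$YFP,
                       EdU = sim$stack$EdU)
  a <- segment_nuclei(sim$stack)
  b <- segment_nuclei(st2)
  expect_identical(a$labels, b$labels)
  expect_equal(b$measurements$mean_dapi, a$measurements$mean_dapi * 7.3)
  expect_equal(a$measurements$mean_yfp, b$measurements$mean_yfp)
})

test_that("mitotic flagging isolates condensed DAPI-bright objects", {
  pop <- data.frame(mean_dapi = c(rep(100, 12), 320),
                    area = c(rep(700, 12), 200))
  out <- flag_mitotic(pop)
  expect_equal(out$mitotic, c(rep(FALSE, 12), TRUE))
  none <- flag_mitotic(data.frame(mean_dapi = rep(100, 8),
                                  area = rep(650, 8)))
  expect_false(any(none$mitotic))
  expect_warning(two <- flag_mitotic(pop[1:2, ]), "fewer than 3")
  expect_false(any(two$mitotic))
})

test_that("planted mitotic figures are excluded during segmentation", {
  sims <- lapply(31:33, function(s) simulate_nuclei_image(image_sim_config(
    n_nuclei = 50, width = 512, height = 512, border_prob = 0,
    mitotic_prob = 0.1, rng_seed = s)))
  flagged <- total <- 0
  for (sim in sims) {
    seg <- segment_nuclei(sim$stack)
    tt <- sim$truth
    kept <- vapply(seq_len(nrow(seg$measurements)), function(i)
      which.min((tt$y - seg$measurements$y[i])^2 +
                  (tt$x - seg$measurements$x[i])^2), integer(1))
    total <- total + sum(tt$mitotic)
    flagged <- flagged + sum(!(which(tt$mitotic) %in% kept))
  }
  expect_gte(flagged / total, 0.9)
})

test_that("cell-cycle gating assigns phases and fails on unimodal DAPI", {
  set.seed(11)
  n <- 120
  phase <- sample(c("G1", "S", "G2"), n, TRUE, prob = c(0.5, 0.3, 0.2))
  m <- data.frame(
    mean_edu = ifelse(phase == "S", 200, 20) * exp(rnorm(n, 0, 0.1)),
    integrated_dapi = c(G1 = 5e4, S = 7.5e4, G2 = 1e5)[phase] *
      exp(rnorm(n, 0, 0.05)))
  g <- gate_cell_cycle(m)
  expect_gte(mean(g$measurements$phase == phase), 0.95)
  expect_lt(g$model$dapi_g1_mode, g$model$dapi_split)
  expect_gt(g$model$dapi_g2_mode, g$model$dapi_split)

  ## doubling either channel (a gain change) leaves assignments unchanged
  m2 <- transform(m, integrated_dapi = integrated_dapi * 2,
                  mean_edu = mean_edu * 3)
  g2 <- gate_cell_cycle(m2)
  expect_identical(g$measurements$phase, g2$measurements$phase)

  ## all EdU-negative with a single 2N mode: refuse to gate
  uni <- data.frame(mean_edu = rep(20, 80) * exp(rnorm(80, 0, 0.05)),
                    integrated_dapi = 5e4 * exp(rnorm(80, 0, 0.03)))
  expect_error(gate_cell_cycle(uni), "gate failure")
  expect_error(gate_cell_cycle(m[1:5, ]), "too few")
})

test_that("phase summaries are order-invariant with singleton SDs of 0", {
  m <- data.frame(phase = c("G1", "G1", "S"), mean_yfp = c(10, 14, 30))
  s <- compare_phase_intensity(m, condition = "ctrl")
  expect_equal(s$sd[s$phase == "S"], 0)
  expect_equal(s$mean[s$phase == "G1"], 12)
  perm <- m[c(3, 1, 2), ]
  expect_equal(compare_phase_intensity(perm, "ctrl"), s)
})

test_that("foci detection respects the chromosome mask", {
  blank <- matrix(0, 64, 64)
  mask <- matrix(FALSE, 64, 64); mask[20:40, 20:40] <- TRUE
  expect_warning(f <- detect_centromere_foci(blank, mask), "no centromeric")
  expect_equal(attr(f, "n_foci"), 0L)

  sim <- simulate_spread_image(spread_sim_config(
    n_chromosomes = 20, width = 480, height = 480, rng_seed = 4))
  dapi <- sim$stack$DAPI
  sm <- dapi / max(dapi)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  chrom <- EBImage::imageData(EBImage::fillHull(sm > thr)) > 0
  foci <- detect_centromere_foci(sim$stack$CENPC, chrom)
  expect_true(all(chrom[foci]))                 # masking contract
  expect_lt(abs(attr(foci, "n_foci") - 40) / 40, 0.05)
})

test_that("spread quantification partitions signal with background correction", {
  u <- matrix(5, 40, 40)
  mask <- matrix(FALSE, 40, 40); mask[10:20, 10:20] <- TRUE
  foci <- matrix(FALSE, 40, 40); foci[14:16, 14:16] <- TRUE
  q <- quantify_spread(u, foci, mask)
  expect_equal(q$centromeric_mean, 0)
  expect_equal(q$noncentromeric_mean, 0)
  expect_equal(q$background, 5)
  ## foci outside the chromosome mask are rejected
  bad <- matrix(FALSE, 40, 40); bad[1:3, 1:3] <- TRUE
  expect_error(quantify_spread(u, bad, mask), "subset")
  ## negative corrected means are clamped and flagged
  dim_img <- matrix(10, 40, 40); dim_img[mask] <- 4
  q2 <- quantify_spread(dim_img, foci, mask)
  expect_true(q2$clamped)
  expect_equal(q2$centromeric_mean, 0)
})

test_that("zero mislocalization leaves arms at background level", {
  sim <- simulate_spread_image(spread_sim_config(
    mislocalization_fraction = 0, n_chromosomes = 15, width = 420,
    height = 420, rng_seed = 9))
  dapi <- sim$stack$DAPI
  sm <- dapi / max(dapi)
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  chrom <- EBImage::imageData(EBImage::fillHull(sm > thr)) > 0
  foci <- detect_centromere_foci(sim$stack$CENPC, chrom)
  q <- quantify_spread(sim$stack$CENPA, foci, chrom)
  expect_gt(q$centromeric_mean, 10)
  expect_lt(q$noncentromeric_mean, 0.5)
})

test_that("fold change of medians", {
  fc <- fold_change_medians(c(1, 2, 3), c(2, 4, 6))
  expect_equal(fc$fold, 2)
  expect_equal(fc$n_a, 3); expect_equal(fc$n_b, 3)
  expect_equal(fold_change_medians(c(4, 5), c(4, 5))$fold, 1)
  expect_error(fold_change_medians(c(-1, 0, 1), c(1, 2)), "undefined")
  expect_error(fold_change_medians(numeric(), 1), "nonempty")
})
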