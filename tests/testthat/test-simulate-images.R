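test_that("empty nuclei field gives blank channels and empty truth", {
  sim <- simulate_nuclei_image(image_sim_config(n_nuclei = 0, width = 64,
                                                height = 64))
  expect_true(all(sim$stack$DAPI == 0))
  expect_true(all(sim$stack$YFP == 0))
  expect_equal(nrow(sim$truth), 0)
})

test_that("nuclei simulation is deterministic and respects its invariants", {
  cfg <- image_sim_config(n_nuclei = 20, width = 320, height = 320,
                          rng_seed = 8)
  s1 <- simulate_nuclei_image(cfg)
  s2 <- simulate_nuclei_image(cfg)
  expect_identical(s1$stack, s2$stack)
  expect_identical(s1$truth, s2$truth)
  expect_true(all(vapply(s1$stack, function(p) all(p >= 0), logical(1))))
  expect_error(image_sim_config(phase_fractions = c(G1 = 0.5, S = 0.5,
                                                    G2 = 0.2)), "sum to 1")
  expect_error(image_sim_config(radius_range = c(2, 5)), ">= 3")
  expect_error(image_sim_config(noise_frac = 1.2), "noise_frac")
})

test_that("G2 nuclei carry about twice the integrated DAPI of G1", {
  cfg <- image_sim_config(n_nuclei = 120, width = 768, height = 768,
                          mitotic_prob = 0, border_prob = 0, rng_seed = 2)
  tt <- simulate_nuclei_image(cfg)$truth
  r <- mean(tt$true_total_dapi[tt$phase == "G2"]) /
    mean(tt$true_total_dapi[tt$phase == "G1"])
  expect_lt(abs(r - 2), 0.15)
  ## S phase sits strictly between the 2N and 4N means
  s_mean <- mean(tt$true_total_dapi[tt$phase == "S"])
  expect_gt(s_mean, mean(tt$true_total_dapi[tt$phase == "G1"]))
  expect_lt(s_mean, mean(tt$true_total_dapi[tt$phase == "G2"]))
})

test_that("infeasible nucleus placement raises a placement error", {
  expect_error(
    simulate_nuclei_image(image_sim_config(n_nuclei = 60, width = 96,
                                           height = 96, rng_seed = 1)),
    "placement")
})

test_that("spread simulation plants the requested CENP-A partition", {
  cfg0 <- spread_sim_config(mislocalization_fraction = 0,
                            n_chromosomes = 12, width = 360, height = 360,
                            rng_seed = 3)
  s0 <- simulate_spread_image(cfg0)
  expect_true(all(s0$truth$chromosomes$arm_mean == 0))

  cfg5 <- spread_sim_config(mislocalization_fraction = 0.5,
                            n_chromosomes = 12, width = 360, height = 360,
                            rng_seed = 3)
  s5 <- simulate_spread_image(cfg5)
  ch <- s5$truth$chromosomes
  fo <- s5$truth$foci
  ## arm-assigned and centromere-assigned totals are equal at f = 0.5
  arm_total <- sum(ch$arm_mean * ch$area)
  cent_total <- sum(fo$cent_total)
  expect_equal(arm_total, cent_total, tolerance = 1e-9)
  expect_equal(s5$truth$mislocalization_fraction, 0.5)
  ## two sister foci per chromosome
  expect_equal(nrow(fo), 2 * 12)
  expect_error(spread_sim_config(mislocalization_fraction = 1.2),
               "\\[0, 1\\]")
})

test_that("planted foci lie on their chromosome bodies", {
  sim <- simulate_spread_image(spread_sim_config(n_chromosomes = 15,
                                                 width = 420, height = 420,
                                                 rng_seed = 6))
  ch <- sim$truth$chromosomes
  fo <- sim$truth$foci
  for (i in seq_len(nrow(fo))) {
    c_i <- ch[ch$chrom_id == fo$chrom_id[i], ]
    ux <- cos(c_i$theta); uy <- sin(c_i$theta)
    du <- ((fo$x[i] - c_i$x) * ux + (fo$y[i] - c_i$y) * uy) / c_i$a
    dv <- (-(fo$x[i] - c_i$x) * uy + (fo$y[i] - c_i$y) * ux) / c_i$b
    expect_lte(du^2 + dv^2, 1)
  }
})
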