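test_that("detection filter keeps proteins complete in one condition", {
  v <- matrix(NA_real_, 3, 11,
              dimnames = list(c("kept", "partial", "ctrl_only"),
                              c(paste0("siCTRL_", 1:3),
                                paste0("siDNAJC9_", 1:3),
                                paste0("noDOX_", 1:5))))
  v["kept", 1:3] <- 25            # 3/3 in siCTRL, 1/3 elsewhere
  v["kept", 4] <- 24
  v["partial", c(1, 2, 4, 5, 7, 8)] <- 25   # 2/3 or 2/5 everywhere
  v["ctrl_only", 7:11] <- 25      # 5/5 only in the excluded control
  meta <- data.frame(sample = colnames(v),
                     condition = rep(c("siCTRL", "siDNAJC9", "noDOX"),
                                     c(3, 3, 5)))
  flt <- filter_valid(intensity_matrix(v, meta),
                      exclude_conditions = "noDOX")
  expect_equal(rownames(flt$values), "kept")
  expect_equal(attr(flt, "n_removed"), 2L)
  expect_warning(
    filter_valid(intensity_matrix(v["partial", , drop = FALSE], meta)),
    "every protein")
})

test_that("downshifted imputation hits the prescribed moments", {
  ## a column whose observed values have exact mean 25 and SD 2
  obs <- with_moments(400, 25, 2, seed = 2)
  v <- matrix(NA_real_, 1000, 2,
              dimnames = list(sprintf("p%04d", 1:1000), c("a_1", "a_2")))
  v[, 1] <- rnorm(1000, 25, 2)
  v[1:400, 2] <- obs
  mat <- intensity_matrix(v, data.frame(sample = c("a_1", "a_2"),
                                        condition = "a"))
  imp <- impute_downshift(mat, rng_seed = 9)
  drawn <- imp$matrix$values[imp$mask[, 2], 2]
  expect_equal(length(drawn), 600)
  expect_lt(abs(mean(drawn) - (25 - 1.8 * 2)), 0.15)
  expect_lt(abs(sd(drawn) - 0.3 * 2), 0.08)
  ## deterministic and identity on complete data
  imp2 <- impute_downshift(mat, rng_seed = 9)
  expect_identical(imp$matrix$values, imp2$matrix$values)
  full <- impute_downshift(make_lfq(), rng_seed = 1)
  expect_identical(full$matrix$values, make_lfq()$values)
  expect_false(any(full$mask))
  ## refuse a column with almost no observations
  v2 <- v; v2[2:1000, 1] <- NA
  expect_error(impute_downshift(intensity_matrix(v2, mat$meta)),
               "fewer than 2 observed")
})

test_that("bait normalization subtracts the bait per sample", {
  m <- make_lfq(n_prot = 5)
  rownames(m$values)[1] <- "CENPA"
  m$values["CENPA", ] <- 25
  m$values[2, 1] <- 20
  bn <- bait_normalize(m, "CENPA")
  expect_equal(bn$values[2, 1], -5)
  expect_true(all(bn$values["CENPA", ] == 0))
  ## adding a constant to one sample column cancels exactly
  shifted <- m
  shifted$values[, 3] <- shifted$values[, 3] + log2(10)
  bns <- bait_normalize(shifted, "CENPA")
  expect_equal(bns$values, bn$values, tolerance = 1e-12)
  expect_error(bait_normalize(m, "NOPE"), "not found")
})

test_that("the moderated statistic reduces to Student's t at s0 = 0", {
  set.seed(7)
  for (i in 1:200) {
    a <- rnorm(3, 25, 1); b <- rnorm(3, 25, 1)
    ours <- moderated_stat(a, b, s0 = 0)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_lt(abs(ours$stat - unname(ref$statistic)), 1e-12)
    expect_equal(ours$log2fc, mean(a) - mean(b))
  }
  expect_equal(moderated_stat(c(1, 2, 3), c(1, 2, 3), s0 = 0.1)$stat, 0)
  expect_equal(moderated_stat(c(4, 4), c(2, 2), s0 = 1)$stat, 2)
  expect_warning(st <- moderated_stat(c(4, 4), c(2, 2), s0 = 0), "infinite")
  expect_identical(st$stat, Inf)
  expect_error(moderated_stat(1, c(1, 2)), ">= 2")
})

test_that("|stat| is non-increasing in s0", {
  set.seed(3)
  for (i in 1:50) {
    a <- rnorm(4, 25, 1); b <- rnorm(4, 24, 1)
    s <- vapply(c(0, 0.1, 0.5, 1, 2), function(s0)
      abs(moderated_stat(a, b, s0)$stat), numeric(1))
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("exhaustive permutation FDR matches a brute-force oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(40 * 6, 25, 1), 40,
                dimnames = list(sprintf("P%03d", 1:40), paste0("s", 1:6)))
    X[1:4, 1:3] <- X[1:4, 1:3] + 3 # a few real effects
    res <- permutation_fdr(X, rep(c("A", "B"), each = 3), s0 = 0.1)
    expect_true(attr(res, "exhaustive"))
    expect_equal(attr(res, "n_assignments"), choose(6, 3))
    oracle <- brute_force_perm_q(X, na = 3, s0 = 0.1)
    expect_equal(res$q, oracle, tolerance = 1e-12)
  }
})

test_that("permutation FDR handles degenerate inputs", {
  X <- matrix(25, 30, 6, dimnames = list(sprintf("P%02d", 1:30),
                                         paste0("s", 1:6)))
  res <- permutation_fdr(X, rep(c("A", "B"), each = 3))
  expect_true(all(res$q == 1))
  expect_true(all(res$stat == 0))
  expect_error(permutation_fdr(X, rep("A", 6)), "two groups")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(permutation_fdr(Xna, rep(c("A", "B"), each = 3)), "missing")
})

test_that("randomized permutation mode is deterministic given the seed", {
  set.seed(2)
  X <- matrix(rnorm(50 * 12, 25, 1), 50,
              dimnames = list(sprintf("P%03d", 1:50), paste0("s", 1:12)))
  lab <- rep(c("A", "B"), each = 6)
  r1 <- permutation_fdr(X, lab, n_permutations = 100, exhaustive_cap = 50,
                        rng_seed = 7)
  r2 <- permutation_fdr(X, lab, n_permutations = 100, exhaustive_cap = 50,
                        rng_seed = 7)
  expect_false(attr(r1, "exhaustive"))
  expect_identical(r1, r2)
})

test_that("enrichment calls combine q-value and fold thresholds", {
  res <- data.frame(protein = c("a", "b", "c", "d"),
                    log2fc = c(2, 1, -2, 0.2), stat = c(5, 4, -5, 1),
                    q = c(0.005, 0.005, 0.004, 0.2))
  called <- call_enrichment(res, fdr_threshold = 0.01, min_lfc = 1.5)
  expect_equal(called$results$direction,
               c("enriched", "none", "depleted", "none"))
  ## Fig 5C-style mode: no fold filter
  c2 <- call_enrichment(res, fdr_threshold = 0.05, min_lfc = 0)
  expect_equal(c2$results$direction,
               c("enriched", "enriched", "depleted", "none"))
})

test_that("set overlap partitions exactly", {
  ov <- overlap_sets(c("P1", "P2", "P3"), c("P2", "P3", "P4"))
  expect_equal(unname(ov$counts), c(1L, 1L, 2L))
  expect_equal(sum(ov$counts), length(union(c("P1", "P2", "P3"),
                                            c("P2", "P3", "P4"))))
  same <- overlap_sets(c("a", "b"), c("b", "a"))
  expect_equal(unname(same$counts["both"]), 2L)
  expect_equal(unname(overlap_sets("x", "y")$counts["both"]), 0L)
})

test_that("the end-to-end differential pipeline is reproducible and calls
           planted effects", {
  sim <- simulate_ipms(ipms_sim_config(
    n_proteins = 300, n_enriched = 10, effect_lfc = 3,
    dropout_quantile = 0.15, rng_seed = 6))
  d1 <- ipms_diff(sim$matrix, "siDNAJC9", "siCTRL", s0 = 0.1,
                  fdr_threshold = 0.05, bait = "CENPA", rng_seed = 4)
  d2 <- ipms_diff(sim$matrix, "siDNAJC9", "siCTRL", s0 = 0.1,
                  fdr_threshold = 0.05, bait = "CENPA", rng_seed = 4)
  expect_identical(d1$results, d2$results)
  recovered <- mean(sim$truth$enriched$protein %in% d1$sets$enriched)
  expect_gt(recovered, 0.6)
  ## bait row itself is never called (log2fc identically 0)
  expect_false("CENPA" %in% c(d1$sets$enriched, d1$sets$depleted))
})
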