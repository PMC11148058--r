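test_that("well summaries are medians with validation", {
  expect_equal(summarize_well(c(10, 20, 30)),
               list(median = 20, n_cells = 3L))
  expect_equal(summarize_well(c(5, 5, 5, 5))$median, 5)
  expect_equal(summarize_well(c(30, 10, 20))$median, 20)
  expect_error(summarize_well(numeric()), "empty")
  expect_error(summarize_well(c(1, -2)), "positive")

  set.seed(1)
  x <- rlnorm(10000, log(100), 0.5) # distribution median = 100
  expect_lt(abs(summarize_well(x)$median / 100 - 1), 0.02)
})

test_that("Z'-factor matches its closed form", {
  expect_equal(zprime_from_moments(10, 5, 100, 5), 1 - 30 / 90)
  expect_equal(zprime_from_moments(10, 0, 100, 0), 1)
  expect_error(zprime_from_moments(50, 5, 50, 5), "separation")
  pos <- c(10, 14); neg <- c(98, 102)
  expect_equal(compute_zprime(pos, neg),
               1 - 3 * (sd(pos) + sd(neg)) / abs(mean(pos) - mean(neg)))
  expect_error(compute_zprime(c(5, 5), c(5, 5)), "separation")
  expect_error(compute_zprime(1, c(1, 2)), ">= 2")
})

test_that("plate normalization yields fold and Z against negative controls", {
  neg <- with_moments(6, 100, 10)          # exact mean 100, SD 10
  plate <- make_plate(neg = neg, sample_values = c(120, median(neg)))
  out <- normalize_plate(plate)
  s <- out[out$role == "sample", ]
  expect_equal(s$raw_z[1], 2)
  expect_equal(s$norm_value[2], 1)
  ## negative wells have mean raw_z 0 by construction
  expect_equal(mean(out$raw_z[out$role == "neg_ctrl"]), 0)
  ## degenerate controls
  bad <- make_plate(neg = c(10, 10, 10, 10))
  expect_error(normalize_plate(bad), "zero spread")
  expect_error(normalize_plate(make_plate(neg = c(100, 101))), "fewer than")
})

test_that("seed index is complete and validated", {
  lib <- data.frame(sirna_id = c("s1", "s2", "s3"),
                    gene_id = c("g1", "g2", "g3"),
                    seed = c("GGAAUGU", "GGAAUGU", "ACGUACG"),
                    stringsAsFactors = FALSE)
  idx <- build_seed_index(lib)
  expect_equal(nrow(idx), 3)
  expect_equal(attr(idx, "n_families"), 2L)
  expect_equal(sum(idx$seed == "GGAAUGU"), 2)
  expect_error(build_seed_index(transform(lib, seed = "ACGT")), "malformed")
  expect_error(build_seed_index(lib[c(1, 1), ]), "duplicate")
})

test_that("off-target family effects use leave-own-gene-out medians", {
  scores <- data.frame(
    sirna_id = paste0("s", 1:5),
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    seed = c(rep("AAAAAAA", 4), "CCCCCCC"),
    raw_z = c(1, 3, 2, 10, 4),
    stringsAsFactors = FALSE)
  eff <- estimate_offtarget_effects(scores)
  expect_equal(eff$effect[eff$seed == "AAAAAAA"], median(c(1, 3, 2, 10)))
  expect_equal(eff$effect[eff$seed == "CCCCCCC"], 0) # singleton
  ## leaving out gD: the family effect seen by s4 is median(1, 3, 2) = 2
  eff_d <- estimate_offtarget_effects(scores, exclude_gene = "gD")
  expect_equal(eff_d$effect[eff_d$seed == "AAAAAAA"], 2)

  corr <- correct_ontarget(scores)
  expect_equal(corr$gross_offtarget[4], 2)
  expect_equal(corr$ontarget_z[4], 8)
  expect_equal(corr$gross_offtarget[5], 0)          # unshared seed
  expect_equal(corr$ontarget_z[5], corr$raw_z[5])
  expect_equal(corr$gross_offtarget[1], median(c(3, 2, 10)))
  ## the identity holds exactly
  expect_equal(corr$ontarget_z + corr$gross_offtarget, corr$raw_z)
  expect_error(correct_ontarget(scores, weights = c(ZZZZZZZ = 1)),
               "unknown seed")
})

test_that("off-target estimation recovers a planted family shift", {
  cfg <- screen_sim_config(n_genes = 300, n_seed_families = 2,
                           seed_family_size = 20, seed_effect = 3,
                           confounded_per_gene = 2, rng_seed = 7)
  sim <- simulate_screen(cfg)
  sc <- score_screen(sim$wells)
  s <- sc$sirna_scores
  fam_seeds <- sim$truth$seeds$seed
  eff <- estimate_offtarget_effects(s)
  est <- eff$effect[match(fam_seeds, eff$seed)]
  expect_true(all(abs(est - 3) < 0.5))
  ## correction shrinks family member scores toward zero
  fam <- s$seed %in% fam_seeds
  expect_lt(mean(abs(s$ontarget_z[fam])), mean(abs(s$raw_z[fam])))
})

test_that("gene aggregation is the median of member on-target scores", {
  expect_equal(aggregate_gene(c(1, 2, 3)), 2)
  expect_equal(aggregate_gene(c(-3, -2.5, 0.5)), -2.5)
  expect_equal(aggregate_gene(c(1, 3)), 2) # even-count midpoint
  df <- data.frame(gene_id = c("g1", "g1", "g1", "g2"),
                   ontarget_z = c(1, 2, 3, -4),
                   norm_value = c(1.5, 2, 2.5, 0.4))
  g <- aggregate_gene(df)
  expect_equal(g$gene_z, c(2, -4))
  expect_equal(g$median_fold, c(2, 0.4))
  expect_equal(g$n_sirnas, c(3L, 1L))
})

test_that("hit calls use strict thresholds and optional fold filter", {
  g <- data.frame(gene_id = c("a", "b", "c", "d"),
                  gene_z = c(2.1, -2.0, 0, -2.5),
                  median_fold = c(2.5, 0.9, 1, 0.9))
  h <- call_hits(g)
  expect_equal(h$hit, c("up", "none", "none", "down"))
  hf <- call_hits(g, fold_threshold = 2)
  expect_equal(hf$hit, c("up", "none", "none", "none"))
  expect_error(call_hits(g, z_threshold = 0), "positive")
})

test_that("gene scores equal a brute-force recomputation", {
  cfg <- screen_sim_config(n_genes = 90, n_hit_genes_up = 10,
                           n_seed_families = 2, seed_family_size = 10,
                           seed_effect = 2, rng_seed = 13)
  sim <- simulate_screen(cfg)
  sc <- score_screen(sim$wells)
  s <- sc$sirna_scores
  ## independent recomputation: sort-based median, explicit loops
  sort_median <- function(x) {
    x <- sort(x); n <- length(x)
    if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  }
  oracle_gene_z <- vapply(unique(s$gene_id), function(g) {
    members <- which(s$gene_id == g)
    onz <- vapply(members, function(i) {
      others <- which(s$seed == s$seed[i] & s$gene_id != g)
      gross <- if (length(others) == 0) 0 else sort_median(s$raw_z[others])
      s$raw_z[i] - gross
    }, numeric(1))
    sort_median(onz)
  }, numeric(1))
  got <- sc$gene_scores$gene_z[match(unique(s$gene_id),
                                     sc$gene_scores$gene_id)]
  expect_equal(unname(got), unname(oracle_gene_z), tolerance = 1e-12)
})

test_that("failed plates leave their genes untested, not scored zero", {
  sim <- simulate_screen(screen_sim_config(n_genes = 240, rng_seed = 5))
  w <- sim$wells
  ## sabotage plate 2: positive controls identical to negatives
  p2neg <- w$role == "neg_ctrl" & w$plate_id == "P002"
  p2pos <- w$role == "pos_ctrl" & w$plate_id == "P002"
  w$value[p2pos] <- mean(w$value[p2neg])
  sc <- score_screen(w)
  expect_false(sc$plate_qc$passed[sc$plate_qc$plate_id == "P002"])
  p2genes <- unique(na.omit(w$gene_id[w$plate_id == "P002" &
                                        w$role == "sample"]))
  p1only <- setdiff(p2genes, sc$gene_scores$gene_id)
  expect_true(all(setdiff(p2genes, sc$gene_scores$gene_id) %in%
                    sc$untested_genes))
  expect_false(any(sc$gene_scores$gene_id %in% sc$untested_genes))
  ## explicit exclusion list behaves like QC failure
  sc2 <- score_screen(sim$wells, exclude_plates = "P001")
  expect_false(sc2$plate_qc$passed[sc2$plate_qc$plate_id == "P001"])
})

test_that("validation concordance classifies per-gene outcomes", {
  prim <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     hit = c("up", "up", "down", "none"))
  val <- data.frame(gene_id = c("g1", "g2", "g3"),
                    hit = c("up", "none", "up"))
  vc <- validation_concordance(prim, val)
  expect_equal(unname(vc$summary),
               c(1L, 2L, 0L))
  expect_equal(vc$table$status, c("validated", "discordant", "discordant"))
  disjoint <- data.frame(gene_id = "g9", hit = "up")
  expect_warning(vc2 <- validation_concordance(disjoint, val), "overlap")
  expect_equal(unname(vc2$summary["untested"]), 1L)
})

test_that("relative expression follows 2^-dCt", {
  expect_equal(ddct(25, 20), 0.03125)
  expect_equal(ddct(20, 20), 1)
  expect_equal(ddct(19, 20), 2)
  expect_equal(ddct(c(25, 19), c(20, 20)), c(0.03125, 2))
  expect_error(ddct(NA, 20), "finite")
})
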