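# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A minimal single-plate well table with exact negative-control moments.
make_plate <- function(plate_id = "P001", neg = c(90, 110, 95, 105),
                       pos = c(8, 12), sample_values = c(120, 100),
                       genes = sprintf("g%03d", seq_along(sample_values))) {
  n <- length(sample_values)
  data.frame(
    plate_id = plate_id,
    well = c(sprintf("A%02d", seq_len(n)),
             paste0(LETTERS[seq_along(neg)], "23"),
             paste0(LETTERS[seq_along(pos)], "24")),
    role = c(rep("sample", n), rep("neg_ctrl", length(neg)),
             rep("pos_ctrl", length(pos))),
    gene_id = c(genes, rep(NA, length(neg) + length(pos))),
    sirna_id = c(paste0(genes, "_s1"), rep(NA, length(neg) + length(pos))),
    seed = c(make_test_seeds(n), rep(NA, length(neg) + length(pos))),
    value = c(sample_values, neg, pos),
    stringsAsFactors = FALSE)
}

# Distinct deterministic 7-mers over the siRNA seed alphabet.
make_test_seeds <- function(n) {
  alphabet <- c("A", "C", "G", "U")
  vapply(seq_len(n), function(i) {
    v <- i - 1
    paste(vapply(1:7, function(p) {
      d <- v %% 4; v <<- v %/% 4; alphabet[d + 1]
    }, ""), collapse = "")
  }, "")
}

# A vector with exact sample mean and SD (for moment-sensitive tests).
with_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  (x - base::mean(x)) / stats::sd(x) * sd + mean
}

# A small complete intensity matrix with two conditions.
make_lfq <- function(n_prot = 30, na = 3, nb = 3, mean = 25, sd = 1,
                     seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rnorm(n_prot * (na + nb), mean, sd), n_prot,
              dimnames = list(sprintf("P%03d", seq_len(n_prot)),
                              c(paste0("A_", seq_len(na)),
                                paste0("B_", seq_len(nb)))))
  intensity_matrix(v, data.frame(
    sample = colnames(v),
    condition = rep(c("A", "B"), c(na, nb)),
    stringsAsFactors = FALSE))
}

# Independent brute-force oracle for the permutation-FDR estimator:
# plain loops, no shared code with the package implementation.
brute_force_perm_q <- function(X, na, s0) {
  n <- ncol(X)
  pooled_stat <- function(x, ia) {
    a <- x[ia]; b <- x[-ia]
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(a) + length(b) - 2)
    d <- sqrt(sp2) * sqrt(1 / length(a) + 1 / length(b)) + s0
    if (d == 0) { if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf }
    else (mean(a) - mean(b)) / d
  }
  asg <- utils::combn(n, na)
  obs <- abs(apply(X, 1, pooled_stat, ia = seq_len(na)))
  perm <- matrix(0, nrow(X), ncol(asg))
  for (k in seq_len(ncol(asg)))
    perm[, k] <- abs(apply(X, 1, pooled_stat, ia = asg[, k]))
  fdr_at <- function(t) {
    n_obs <- sum(obs >= t)
    mean_perm <- mean(colSums(perm >= t))
    min(1, mean_perm / max(1, n_obs))
  }
  q <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    cand <- obs[obs <= obs[i]]
    q[i] <- min(vapply(cand, fdr_at, numeric(1)))
  }
  q
}
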