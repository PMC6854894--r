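# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths.

# Monte-Carlo droplet partitioning: k molecules land independently and
# uniformly in N droplets; returns the number of occupied droplets.
# (Uses runif/ceiling, not the sample.int route the simulator takes.)
oracle_partition <- function(k, n_droplets) {
  if (k == 0) return(0L)
  length(unique(ceiling(stats::runif(k) * n_droplets)))
}

# Exhaustive enumeration of the two-of-three false-positive rate for
# independent per-marker rates p = c(p1, p2, p3).
oracle_two_of_three <- function(p) {
  g <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  pr <- apply(g, 1, function(x)
    prod(ifelse(x == 1, p, 1 - p)))
  sum(pr[rowSums(g) >= 2])
}

# Mann-Whitney AUC by exhaustive pairwise comparison (ties count 1/2).
oracle_auc_pairs <- function(case_scores, control_scores) {
  cmp <- outer(case_scores, control_scores,
               function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Direct per-CpG fraction computation for the discovery filter.
oracle_cpg_fractions <- function(bm, beta_hyper = 0.35,
                                 pbl_beta_max = 0.05) {
  g <- bm$groups
  list(crc_sens = rowMeans(bm$values[, g == "CRC", drop = FALSE] >
                             beta_hyper),
       pbl_pos = rowMeans(bm$values[, g == "PBL", drop = FALSE] >
                            pbl_beta_max))
}

# Synthetic bimodal control well for caller tests.
make_control <- function(n = 8000, neg = 2000, pos = 8000,
                         spread = 300, occupancy = 0.5,
                         well_id = "CTRL", channel = "ch1") {
  n_pos <- round(n * occupancy)
  amp <- c(stats::rnorm(n - n_pos, neg, spread),
           stats::rnorm(n_pos, pos, spread))
  new_droplet_well(well_id, channel, amp, role = "positive_control")
}

count_density_maxima <- function(x, bw, n_grid = 512L) {
  y <- stats::density(x, bw = bw, n = n_grid)$y
  s <- sign(diff(y))
  s <- s[s != 0]
  sum(s[-length(s)] > 0 & s[-1L] < 0)
}
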