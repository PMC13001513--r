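# fixtures are built in code at test time; nothing is read from disk

# small snp_table with explicit counts; samples default to one founder set
toy_table <- function(minor, coverage, chrom = NULL, samples = NULL) {
  minor <- as.matrix(minor); coverage <- as.matrix(coverage)
  L <- nrow(minor); ns <- ncol(minor)
  if (is.null(chrom)) chrom <- rep("2L", L)
  loci <- data.frame(chrom = chrom, pos = seq_len(L) * 10L,
                     minor_base = rep("A", L), major_base = rep("G", L))
  if (is.null(samples)) samples <- founder_samples(ns)
  snp_table(loci, samples, minor, coverage)
}

founder_samples <- function(ns, group = "FOUNDER_A") {
  data.frame(sample_id = paste0("s", seq_len(ns)), group = group,
             replicate = seq_len(ns), generation = 0,
             timepoint = "T1", stringsAsFactors = FALSE)
}

# two-trajectory design for direct GLMM fits: n_rep replicates per
# trajectory, each sampled at the given generations
two_traj_design <- function(n_rep = 10, gens = c(0, 30, 65)) {
  g <- expand.grid(generation = gens, replicate = seq_len(2 * n_rep))
  data.frame(treatment = as.numeric(g$replicate > n_rep),
             generation = g$generation,
             replicate = paste0("pop", g$replicate))
}

# draw beta-binomial GLMM counts for one locus given true parameters
sim_bb_locus <- function(design, beta, phi, sigma_u, coverage = 90) {
  reps <- sort(unique(design$replicate))
  u <- stats::setNames(rnorm(length(reps), 0, sigma_u), reps)
  eta <- beta[1] + beta[2] * design$treatment + beta[3] * design$generation +
    beta[4] * design$treatment * design$generation +
    u[as.character(design$replicate)]
  p <- plogis(eta)
  n <- rpois(nrow(design), coverage) + 1L
  if (phi > 0) {
    cc <- (1 - phi) / phi
    p <- rbeta(length(p), p * cc, (1 - p) * cc)
  }
  list(minor = rbinom(length(p), n, p), coverage = n)
}

# brute-force beta-binomial log pmf, independent of lbeta: ascending
# factorial products on the log scale
bb_lpmf_bruteforce <- function(y, n, p, phi) {
  cc <- (1 - phi) / phi
  a <- p * cc; b <- (1 - p) * cc
  lg <- function(x, k) if (k == 0) 0 else sum(log(x + 0:(k - 1)))
  lchoose(n, y) + lg(a, y) + lg(b, n - y) - lg(a + b, n)
}

# mean silhouette width between two groups on a score matrix (Euclidean)
silhouette_2group <- function(scores, grp) {
  d <- as.matrix(dist(scores))
  vapply(seq_along(grp), function(i) {
    own <- grp == grp[i]; own[i] <- FALSE
    a <- mean(d[i, own]); b <- mean(d[i, !own & seq_along(grp) != i])
    (b - a) / max(a, b)
  }, numeric(1))
}
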