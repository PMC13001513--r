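#' Simulator configuration
#'
#' Parameterizes the forward Wright-Fisher Pool-seq simulator. The defaults
#' describe the reciprocal selection-shift design the package's analyses
#' target: two antiparallel regimes ("A-like": early-reproduction pressure;
#' "C-like": that pressure relaxed) applied to replicate populations that
#' share ancestral standing variation, censused on the order of a thousand,
#' pooled at ~200 individuals, sequenced at per-sample mean depths in the
#' 62-113x range, with an 800x deep-sequencing mode.
#'
#' Locus classes: `neutral` loci drift; `directional` loci carry an
#' antiparallel additive fitness effect (favoured homozygote `1 + s`), with
#' the favoured allele in one regime disfavoured in the other; `balanced`
#' loci have a heterozygote net-fitness advantage `h_balance` and, under the
#' A-like regime only, an additional multiplicative penalty per minor-allele
#' copy chosen so the internal equilibrium sits at `balanced_low_eq` — a
#' low-frequency reservoir that is often invisible at standard depth and
#' rebounds when the A-like pressure is removed.
#'
#' @param n_loci total loci simulated.
#' @param n_selected number of directional loci.
#' @param n_balanced number of balanced loci (the rest are neutral).
#' @param N diploid census size (default 1000).
#' @param n_replicates replicate populations per trajectory (default 10).
#' @param sampled_generations named list with numeric vectors `A2C` and
#'   `C2A`: generations (under the new regime) at which Pool-seq samples are
#'   taken; 0 = the founder state.
#' @param s selection coefficient magnitude for directional loci.
#' @param h_balance heterozygote net-fitness advantage at balanced loci
#'   (default 1: strong net balancing; at this census size a weak advantage
#'   cannot hold a low-frequency reservoir against drift for hundreds of
#'   generations).
#' @param balanced_low_eq target equilibrium minor-allele frequency of
#'   balanced loci under the A-like regime (default 0.015).
#' @param neutral_range,directional_range uniform ranges for ancestral
#'   frequencies of neutral and directional loci.
#' @param pool_size individuals pooled per sample (default 200).
#' @param coverage_range range from which each sample's mean depth is drawn
#'   uniformly (default `c(62, 113)`).
#' @param mean_coverage if non-`NULL`, a fixed mean depth for every sample
#'   (overrides `coverage_range`).
#' @param deep_coverage mean depth of the deep-sequencing mode (default 800).
#' @param deep_sample also emit a deep-sequenced table for the first A-type
#'   founder replicate? (default `FALSE`).
#' @param founder_drift_gens generations of per-replicate drift used to
#'   individualize founder replicates around the regime state (default 20).
#' @param seed integer seed; the full run is reproducible from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_loci = 1000, n_selected = 100, n_balanced = 100,
                       N = 1000, n_replicates = 10,
                       sampled_generations = list(A2C = c(0, 12, 33, 65),
                                                  C2A = c(0, 33, 143, 182)),
                       s = 0.05, h_balance = 1, balanced_low_eq = 0.015,
                       neutral_range = c(0.05, 0.95),
                       directional_range = c(0.2, 0.8),
                       pool_size = 200, coverage_range = c(62, 113),
                       mean_coverage = NULL, deep_coverage = 800,
                       deep_sample = FALSE, founder_drift_gens = 20,
                       seed = 1) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  stopifnot(cfg$n_selected + cfg$n_balanced <= cfg$n_loci,
            cfg$s > 0, cfg$s < 1, cfg$N >= 2, cfg$pool_size <= cfg$N,
            cfg$pool_size >= 1, cfg$h_balance >= 0,
            cfg$balanced_low_eq > 0, cfg$balanced_low_eq < 0.5,
            all(c("A2C", "C2A") %in% names(cfg$sampled_generations)))
  cfg
}

#' One Wright-Fisher generation with viability selection
#'
#' Deterministic selection update under random mating,
#' `f' = (f^2 wAA + f(1-f) wAa) / (f^2 wAA + 2 f(1-f) wAa + (1-f)^2 waa)`,
#' followed by binomial drift sampling of `2N` gametes. Vectorized over loci;
#' fitness arguments recycle.
#'
#' @param freq current frequency (vector) of the focal allele "A".
#' @param N diploid population size.
#' @param w_AA,w_Aa,w_aa relative genotype fitnesses (focal-homozygote,
#'   heterozygote, other-homozygote); must be positive.
#' @return sampled next-generation frequency vector.
#' @export
wright_fisher_step <- function(freq, N, w_AA = 1, w_Aa = 1, w_aa = 1) {
  stopifnot(all(freq >= 0), all(freq <= 1),
            all(w_AA > 0), all(w_Aa > 0), all(w_aa > 0), N >= 1)
  num <- freq^2 * w_AA + freq * (1 - freq) * w_Aa
  den <- freq^2 * w_AA + 2 * freq * (1 - freq) * w_Aa + (1 - freq)^2 * w_aa
  fprime <- ifelse(den > 0, num / den, 0)
  stats::rbinom(length(freq), 2 * N, fprime) / (2 * N)
}

# Poisson truncated below at 1, by inverse CDF
rtpois1 <- function(n, lambda) {
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  pmax(1L, stats::qpois(u, lambda))
}

#' Two-stage Pool-seq sampling of one sample
#'
#' Pool stage: the pooled-individuals allele frequency `q` is drawn as
#' `Binomial(2 * pool_size, true_freq) / (2 * pool_size)`. Read stage:
#' coverage is Poisson(`depth_mean`) truncated at 1, and the minor count is
#' `Binomial(coverage, q)`. The pool stage adds overdispersion relative to
#' pure binomial read sampling. Vectorized over loci.
#'
#' @param true_freq population frequency vector of the focal allele.
#' @param pool_size individuals in the pool.
#' @param depth_mean mean sequencing depth (scalar or per-locus vector).
#' @param pool_freq optionally, an already-drawn pool frequency vector to
#'   resequence (used by the deep mode so standard and deep counts share the
#'   same pool draw).
#' @return list with integer vectors `minor` and `coverage`, plus the pool
#'   frequency `q`.
#' @export
pool_seq_sample <- function(true_freq, pool_size, depth_mean,
                            pool_freq = NULL) {
  stopifnot(all(true_freq >= 0), all(true_freq <= 1), pool_size >= 1)
  n <- length(true_freq)
  q <- if (is.null(pool_freq))
    stats::rbinom(n, 2 * pool_size, true_freq) / (2 * pool_size)
  else pool_freq
  coverage <- rtpois1(n, depth_mean)
  minor <- stats::rbinom(n, coverage, q)
  list(minor = as.integer(minor), coverage = as.integer(coverage), q = q)
}

# penalty d per minor-allele copy giving internal equilibrium f* for
# genotype fitnesses ((1-d)^2, (1+h)(1-d), 1)
solve_balance_pressure <- function(h, f_star) {
  a <- f_star
  b <- (1 + h) * (1 - 2 * f_star)
  cc <- -(1 - f_star)
  x <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  d <- 1 - x
  stopifnot(d > 0, d < 1)
  d
}

# genotype fitnesses (w_minor_hom, w_het, w_major_hom) per locus for a regime
regime_fitness <- function(class, sign_in_regime, regime, s, h, d) {
  n <- length(class)
  w2 <- rep(1, n); w1 <- rep(1, n); w0 <- rep(1, n)
  dir_plus <- class == "directional" & sign_in_regime > 0   # minor favoured
  dir_minus <- class == "directional" & sign_in_regime < 0  # minor disfavoured
  w2[dir_plus] <- 1 + s; w1[dir_plus] <- 1 + s / 2
  w0[dir_minus] <- 1 + s; w1[dir_minus] <- 1 + s / 2
  bal <- class == "balanced"
  if (regime == "A") {
    w2[bal] <- (1 - d)^2
    w1[bal] <- (1 + h) * (1 - d)
    w0[bal] <- 1
  } else {
    w2[bal] <- 1; w1[bal] <- 1 + h; w0[bal] <- 1
  }
  list(w2 = w2, w1 = w1, w0 = w0)
}

evolve_path <- function(freq0, gens_needed, N, w) {
  # returns matrix loci x length(gens_needed); gens_needed sorted, may start 0
  n <- length(freq0)
  out <- matrix(NA_real_, n, length(gens_needed))
  f <- freq0
  g <- 0
  for (k in seq_along(gens_needed)) {
    while (g < gens_needed[k]) {
      f <- wright_fisher_step(f, N, w$w2, w$w1, w$w0)
      g <- g + 1
    }
    out[, k] <- f
  }
  out
}

#' Simulate a reciprocal selection-shift Pool-seq experiment
#'
#' Generates founder A-type and C-type replicate populations from shared
#' ancestral standing variation, shifts them to the opposite regime (A2C,
#' C2A), evolves each replicate forward under Wright-Fisher dynamics with
#' viability selection, and Pool-seq samples every replicate at the
#' configured generations. Returns the standard-depth [snp_table()], a truth
#' table with per-locus class and antiparallel effect signs, and (optionally)
#' a deep-sequenced table for the first A-type founder replicate that shares
#' the standard table's pool draws.
#'
#' Loci evolve independently (no linkage); generations are discrete and
#' non-overlapping; census size is constant. Minor alleles in the emitted
#' table follow the global convention: if a focal allele ends up globally
#' more common than 0.5, its counts, truth paths and signs are flipped so
#' the table's minor allele is the globally rarer one.
#'
#' @param config a [sim_config()].
#' @return list with elements `table` (`snp_table`), `truth` (class
#'   `truth_table`: `$loci` data frame with `class`, `sign_A2C`, `sign_C2A`;
#'   `$paths` true frequencies at sampled generations, loci x replicates x
#'   generations per trajectory; `$founder_freq` per-replicate founder
#'   states) and `deep` (`snp_table` or `NULL`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_loci; R <- config$n_replicates; N <- config$N
  cls <- rep("neutral", L)
  if (config$n_selected > 0) cls[seq_len(config$n_selected)] <- "directional"
  if (config$n_balanced > 0)
    cls[config$n_selected + seq_len(config$n_balanced)] <- "balanced"
  # sign of the focal allele's effect under the A-like regime; antiparallel
  sign_A <- integer(L)
  dir_idx <- which(cls == "directional")
  sign_A[dir_idx] <- sample(c(-1L, 1L), length(dir_idx), replace = TRUE)
  d_bal <- if (config$n_balanced > 0)
    solve_balance_pressure(config$h_balance, config$balanced_low_eq) else 0

  # ancestral / founder starting frequencies of the focal allele
  anc <- stats::runif(L, config$neutral_range[1], config$neutral_range[2])
  anc[dir_idx] <- stats::runif(length(dir_idx), config$directional_range[1],
                               config$directional_range[2])
  f_A <- anc; f_C <- anc
  # founders sit near their regime's long-term state
  f_A[dir_idx] <- ifelse(sign_A[dir_idx] > 0, 0.9, 0.1)
  f_C[dir_idx] <- ifelse(sign_A[dir_idx] > 0, 0.1, 0.9)
  bal_idx <- which(cls == "balanced")
  f_A[bal_idx] <- config$balanced_low_eq
  f_C[bal_idx] <- 0.5

  w_regA <- regime_fitness(cls, sign_A, "A", config$s, config$h_balance, d_bal)
  w_regC <- regime_fitness(cls, -sign_A, "C", config$s, config$h_balance, d_bal)

  # per-replicate founder states: short independent drift under home regime
  founder_A <- matrix(NA_real_, L, R); founder_C <- matrix(NA_real_, L, R)
  for (r in seq_len(R)) {
    fa <- f_A; fc <- f_C
    for (g in seq_len(config$founder_drift_gens)) {
      fa <- wright_fisher_step(fa, N, w_regA$w2, w_regA$w1, w_regA$w0)
      fc <- wright_fisher_step(fc, N, w_regC$w2, w_regC$w1, w_regC$w0)
    }
    founder_A[, r] <- fa; founder_C[, r] <- fc
  }

  gens <- lapply(config$sampled_generations, function(g) sort(unique(g)))
  paths <- list(
    A2C = array(NA_real_, c(L, R, length(gens$A2C))),  # A founders under C regime
    C2A = array(NA_real_, c(L, R, length(gens$C2A)))   # C founders under A regime
  )
  for (r in seq_len(R)) {
    paths$A2C[, r, ] <- evolve_path(founder_A[, r], gens$A2C, N, w_regC)
    paths$C2A[, r, ] <- evolve_path(founder_C[, r], gens$C2A, N, w_regA)
  }

  # assemble sample layout: founders (gen 0) + trajectory samples
  layout <- list()
  for (r in seq_len(R)) {
    layout[[length(layout) + 1]] <- list(group = "FOUNDER_A", rep = r,
                                         gen = 0, tp = "T1",
                                         freq = founder_A[, r])
    layout[[length(layout) + 1]] <- list(group = "FOUNDER_C", rep = r,
                                         gen = 0, tp = "T1",
                                         freq = founder_C[, r])
  }
  for (traj in c("A2C", "C2A")) {
    gg <- gens[[traj]]
    for (r in seq_len(R)) for (k in seq_along(gg)) {
      layout[[length(layout) + 1]] <- list(group = traj, rep = r,
                                           gen = gg[k],
                                           tp = paste0("G", gg[k]),
                                           freq = paths[[traj]][, r, k])
    }
  }
  ns <- length(layout)
  depth_means <- if (is.null(config$mean_coverage))
    stats::runif(ns, config$coverage_range[1], config$coverage_range[2])
  else rep(config$mean_coverage, ns)

  minor <- matrix(0L, L, ns); coverage <- matrix(0L, L, ns)
  pool_q_focal <- NULL
  for (j in seq_len(ns)) {
    draw <- pool_seq_sample(layout[[j]]$freq, config$pool_size, depth_means[j])
    minor[, j] <- draw$minor; coverage[, j] <- draw$coverage
    if (layout[[j]]$group == "FOUNDER_A" && layout[[j]]$rep == 1)
      pool_q_focal <- draw$q
  }

  samples <- data.frame(
    sample_id = vapply(layout, function(x)
      paste0(x$group, "_r", x$rep, "_", x$tp), character(1)),
    group = vapply(layout, `[[`, character(1), "group"),
    replicate = vapply(layout, function(x) as.integer(x$rep), integer(1)),
    generation = vapply(layout, function(x) as.numeric(x$gen), numeric(1)),
    timepoint = vapply(layout, `[[`, character(1), "tp"),
    stringsAsFactors = FALSE
  )

  # global minor-allele convention: flip loci whose focal allele is majority
  pooled <- rowSums(minor) / pmax(1, rowSums(coverage))
  flip <- pooled > 0.5
  minor[flip, ] <- coverage[flip, ] - minor[flip, ]
  sign_A[flip] <- -sign_A[flip]
  for (traj in c("A2C", "C2A"))
    paths[[traj]][flip, , ] <- 1 - paths[[traj]][flip, , ]
  founder_A[flip, ] <- 1 - founder_A[flip, ]
  founder_C[flip, ] <- 1 - founder_C[flip, ]
  if (!is.null(pool_q_focal)) pool_q_focal[flip] <- 1 - pool_q_focal[flip]

  arms <- c("2L", "2R", "3L", "3R", "X")
  chrom <- arms[(seq_len(L) - 1L) %% length(arms) + 1L]
  pos <- 100L * (((seq_len(L) - 1L) %/% length(arms)) + 1L)
  base_pair <- t(vapply(seq_len(L), function(i)
    sample(NUCLEOTIDES, 2), character(2)))
  loci <- data.frame(chrom = chrom, pos = pos,
                     minor_base = base_pair[, 1], major_base = base_pair[, 2],
                     stringsAsFactors = FALSE)
  tab <- snp_table(loci, samples, minor, coverage)

  deep <- NULL
  if (isTRUE(config$deep_sample)) {
    dd <- pool_seq_sample(founder_A[, 1], config$pool_size,
                          config$deep_coverage, pool_freq = pool_q_focal)
    deep_samples <- data.frame(sample_id = "FOUNDER_A_r1_T1_deep",
                               group = "FOUNDER_A", replicate = 1L,
                               generation = 0, timepoint = "T1_deep",
                               stringsAsFactors = FALSE)
    deep <- snp_table(loci, deep_samples,
                      matrix(dd$minor, ncol = 1), matrix(dd$coverage, ncol = 1))
  }

  truth <- structure(
    list(loci = data.frame(locus = seq_len(L), chrom = chrom, pos = pos,
                           class = cls,
                           sign_A2C = -sign_A,  # effect of table's minor allele under C regime
                           sign_C2A = sign_A,
                           stringsAsFactors = FALSE),
         paths = paths, sampled_generations = gens,
         founder_freq = list(A = founder_A, C = founder_C)),
    class = "truth_table")
  list(table = tab, truth = truth, deep = deep)
}
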