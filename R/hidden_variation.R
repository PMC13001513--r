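#' Identify pseudo-fixed sites in a focal sample
#'
#' Among a set of scan-significant loci, returns those whose minor-allele
#' count in the focal sample is 0 or equals coverage — sites that look fixed
#' at standard sequencing depth but may segregate at frequencies below the
#' detection threshold.
#'
#' @param table a `snp_table`.
#' @param focal_sample sample_id of the focal (standard-depth) sample.
#' @param significant_loci integer indices (or logical vector) of
#'   scan-significant loci; an empty set returns an empty result.
#' @return integer locus indices of the pseudo-fixed subset.
#' @export
find_pseudo_fixed <- function(table, focal_sample, significant_loci) {
  stopifnot(inherits(table, "snp_table"))
  j <- match(focal_sample, table$samples$sample_id)
  if (is.na(j)) stop("focal sample '", focal_sample, "' not in table")
  if (is.logical(significant_loci)) significant_loci <- which(significant_loci)
  if (length(significant_loci) == 0) return(integer(0))
  mi <- table$minor[significant_loci, j]
  cv <- table$coverage[significant_loci, j]
  significant_loci[mi == 0 | mi == cv]
}

#' Folded minor-allele frequencies from a deep-sequenced sample
#'
#' Frequencies of the (globally defined) minor allele in a deep table,
#' folded to `min(f, 1 - f)` so sites fixed *for* the minor nucleotide still
#' contribute their rare-allele frequency.
#'
#' @param deep a single-sample `snp_table` from the deep-sequencing mode.
#' @param min_cov minimum deep coverage for a site to count as "available"
#'   (default 1).
#' @return data frame: locus index (into `deep`), chrom, pos, coverage, maf
#'   (folded); sites below `min_cov` are excluded.
#' @export
deep_maf <- function(deep, min_cov = 1) {
  stopifnot(inherits(deep, "snp_table"), nrow(deep$samples) == 1)
  cv <- deep$coverage[, 1]
  keep <- which(cv >= min_cov)
  f <- deep$minor[keep, 1] / cv[keep]
  data.frame(locus = keep, chrom = deep$loci$chrom[keep],
             pos = deep$loci$pos[keep], coverage = cv[keep],
             maf = pmin(f, 1 - f))
}

#' Permutation test for depleted mean minor-allele frequency
#'
#' Tests whether the observed mean MAF of a focal SNP set (e.g. deep-coverage
#' MAFs at pseudo-fixed sites) is lower than expected for a random set of the
#' same size: the null distribution is the mean MAF of equal-size subsets
#' drawn without replacement from the background, independently across
#' permutations. The empirical p-value uses the +1 smoothing convention,
#' `p = (1 + #\{null <= observed\}) / (1 + n_perm)`, so it is never exactly
#' zero; the raw count is also reported.
#'
#' @param pseudo_fixed_mafs MAFs of the focal set (nonempty).
#' @param background_mafs background MAF pool, at least as large as the
#'   focal set.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for reproducible draws.
#' @return object of class `pseudo_fixed_report`: observed mean, null mean
#'   and SD, z-score, empirical p, raw count, `n_perm`, `seed`, set sizes.
#' @export
permutation_test_mean_maf <- function(pseudo_fixed_mafs, background_mafs,
                                      n_perm = 10000, seed = 1) {
  k <- length(pseudo_fixed_mafs)
  if (k == 0) stop("pseudo-fixed set is empty")
  if (length(background_mafs) < k)
    stop("background (", length(background_mafs),
         ") smaller than the focal set (", k, ")")
  set.seed(seed)
  # sorting makes the draws, hence p, invariant to background ordering
  background_mafs <- sort(background_mafs)
  observed <- mean(pseudo_fixed_mafs)
  null_means <- vapply(seq_len(n_perm), function(i)
    mean(background_mafs[sample.int(length(background_mafs), k)]),
    numeric(1))
  n_le <- sum(null_means <= observed)
  null_sd <- stats::sd(null_means)
  structure(list(
    observed_mean = observed,
    null_mean = mean(null_means), null_sd = null_sd,
    z = if (null_sd > 0) (observed - mean(null_means)) / null_sd else 0,
    p = (1 + n_le) / (1 + n_perm), n_le = n_le,
    n_perm = n_perm, seed = seed, n_set = k,
    n_background = length(background_mafs)),
    class = "pseudo_fixed_report")
}

#' @export
print.pseudo_fixed_report <- function(x, ...) {
  cat(sprintf(
    "pseudo_fixed_report: %d sites vs background of %d\n", x$n_set,
    x$n_background))
  cat(sprintf("  observed mean MAF %.4g; null %.4g (SD %.3g); Z = %.2f; p = %.3g\n",
              x$observed_mean, x$null_mean, x$null_sd, x$z, x$p))
  invisible(x)
}

#' Full hidden-variation analysis
#'
#' Convenience wrapper chaining the pieces: find pseudo-fixed sites among
#' scan-significant loci in the focal standard-depth sample, merge with the
#' deep-sequenced table by (chrom, pos), restrict to sites with deep
#' coverage at least `deep_min_cov`, and run the permutation test of the
#' pseudo-fixed sites' mean folded MAF against the full deep background.
#'
#' @param standard a `snp_table` at standard depth containing `focal_sample`.
#' @param deep the single-sample deep `snp_table`.
#' @param focal_sample sample_id of the focal sample in `standard`.
#' @param significant_loci indices (or logical) of scan-significant loci in
#'   `standard`.
#' @param n_perm,seed passed to [permutation_test_mean_maf()].
#' @param deep_min_cov minimum deep coverage for availability (default 1).
#' @return a `pseudo_fixed_report` with additional elements `sites` (data
#'   frame of pseudo-fixed sites with deep MAFs) and `n_pseudo_fixed_total`
#'   (before the deep-availability restriction).
#' @export
hidden_variation_report <- function(standard, deep, focal_sample,
                                    significant_loci, n_perm = 10000,
                                    seed = 1, deep_min_cov = 1) {
  pf <- find_pseudo_fixed(standard, focal_sample, significant_loci)
  dm <- deep_maf(deep, min_cov = deep_min_cov)
  key_std <- paste(standard$loci$chrom, standard$loci$pos)
  key_deep <- paste(dm$chrom, dm$pos)
  hit <- match(key_std[pf], key_deep)
  avail <- !is.na(hit)
  sites <- data.frame(locus = pf[avail],
                      chrom = standard$loci$chrom[pf[avail]],
                      pos = standard$loci$pos[pf[avail]],
                      deep_maf = dm$maf[hit[avail]])
  if (nrow(sites) == 0)
    stop("no pseudo-fixed site has deep coverage >= ", deep_min_cov)
  rep <- permutation_test_mean_maf(sites$deep_maf, dm$maf,
                                   n_perm = n_perm, seed = seed)
  rep$sites <- sites
  rep$n_pseudo_fixed_total <- length(pf)
  rep
}
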