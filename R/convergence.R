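#' Evolved-versus-founder convergence scan
#'
#' Per-SNP test of whether newly derived populations differ from the
#' long-established founder populations of the regime they evolved into
#' (C2A vs FOUNDER_A, or A2C vs FOUNDER_C). Few differentiated loci indicate
#' repeatable convergence on the founder genomic state. Counts are modelled
#' with an overdispersed binomial: the default `"quasi"` mode compares the
#' population-type model against the intercept-only null with a
#' quasi-likelihood F-test (deviance difference scaled by the Pearson
#' dispersion, which also absorbs replicate-level variation); the `"bb"`
#' mode fits beta-binomial models with an explicit replicate random
#' intercept and uses a likelihood-ratio chi-square.
#'
#' Chromosome 4 is excluded, as are loci monomorphic across all used
#' samples; excluded loci do not enter the Bonferroni denominator.
#'
#' @param table a `snp_table` containing the evolved and founder groups.
#' @param contrast `"C2A-vs-FOUNDER_A"` or `"A2C-vs-FOUNDER_C"`.
#' @param alpha level on Bonferroni-adjusted p-values (default 0.05).
#' @param mode `"quasi"` (default) or `"bb"`.
#' @return object of class `convergence_result`: `results` (per-locus
#'   statistic, raw and adjusted p, `differentiated`, `tested`), `m`
#'   (tested-locus count), `contrast`, `alpha`, `mode`.
#' @export
convergence_scan <- function(table, contrast = c("C2A-vs-FOUNDER_A",
                                                 "A2C-vs-FOUNDER_C"),
                             alpha = 0.05, mode = c("quasi", "bb")) {
  contrast <- match.arg(contrast)
  mode <- match.arg(mode)
  stopifnot(inherits(table, "snp_table"))
  parts <- strsplit(contrast, "-vs-")[[1]]
  evolved <- parts[1]; founder <- parts[2]
  s <- table$samples
  if (!any(s$group == evolved)) stop("group ", evolved, " absent from table")
  if (!any(s$group == founder)) stop("group ", founder, " absent from table")
  # evolved populations at their final sampled generation; all founder samples
  ev_gen <- max(s$generation[s$group == evolved])
  use <- which((s$group == evolved & s$generation == ev_gen) |
                 s$group == founder)
  su <- s[use, ]
  if (length(unique(su$replicate[su$group == evolved])) < 2 ||
      length(unique(su$replicate[su$group == founder])) < 2)
    stop("need >= 2 replicates in each group")
  type <- as.numeric(su$group == evolved)
  pop <- paste0(su$group, "_", su$replicate)

  L <- nrow(table$loci)
  mi <- table$minor[, use, drop = FALSE]
  cv <- table$coverage[, use, drop = FALSE]
  tested <- table$loci$chrom != "4" &
    !(rowSums(mi) == 0 | rowSums(mi) == rowSums(cv))
  stat <- p <- rep(NA_real_, L)
  X1 <- cbind(1, type)
  for (i in which(tested)) {
    y <- mi[i, ]; n <- cv[i, ]
    if (mode == "quasi") {
      r <- tryCatch(quasi_f_test(y, n, X1), error = function(e) NULL)
    } else {
      r <- tryCatch(bb_type_lrt(y, n, type, pop), error = function(e) NULL)
    }
    if (is.null(r)) { tested[i] <- FALSE; next }
    stat[i] <- r$stat; p[i] <- r$p
  }
  m <- sum(tested)
  padj <- pmin(1, p * m)
  res <- data.frame(table$loci[, c("chrom", "pos")], locus = seq_len(L),
                    statistic = stat, p = p, padj = padj,
                    differentiated = !is.na(padj) & padj < alpha,
                    tested = tested)
  structure(list(results = res, m = m, contrast = contrast, alpha = alpha,
                 mode = mode),
            class = "convergence_result")
}

# quasi-likelihood F test of the second column of X against intercept-only
quasi_f_test <- function(y, n, X) {
  prop <- y / n
  full <- suppressWarnings(stats::glm.fit(X, prop, weights = n,
                                          family = stats::binomial()))
  null <- suppressWarnings(stats::glm.fit(X[, 1, drop = FALSE], prop,
                                          weights = n,
                                          family = stats::binomial()))
  mu <- full$fitted.values
  df_res <- length(y) - full$rank
  disp <- sum((prop - mu)^2 * n / pmax(mu * (1 - mu), 1e-12)) / df_res
  disp <- max(disp, 1e-8)
  fstat <- (null$deviance - full$deviance) / disp
  list(stat = fstat,
       p = stats::pf(fstat, 1, df_res, lower.tail = FALSE))
}

# beta-binomial LRT with replicate random intercept (sensitivity mode)
bb_type_lrt <- function(y, n, type, pop) {
  design <- data.frame(treatment = type, generation = 0, replicate = pop)
  full <- fit_bb_constrained(y, n, cbind(1, type, 0, 0), pop,
                             free = c(TRUE, TRUE, FALSE, FALSE))
  red <- fit_bb_constrained(y, n, cbind(1, 0 * type, 0, 0), pop,
                            free = c(TRUE, FALSE, FALSE, FALSE))
  stat <- 2 * (full - red)
  list(stat = stat,
       p = stats::pchisq(pmax(stat, 0), 1, lower.tail = FALSE))
}

# maximize the marginal beta-binomial likelihood with some beta columns
# pinned at zero; returns the log-likelihood
fit_bb_constrained <- function(y, n, X, pop, free) {
  ji <- match(pop, sort(unique(pop)))
  J <- length(unique(ji))
  lower <- c(ifelse(free, -25, -1e-9), stats::qlogis(1e-8), log(1e-4))
  upper <- c(ifelse(free, 25, 1e-9), stats::qlogis(0.9), log(10))
  st <- c(stats::qlogis(pmin(pmax(mean(y / n), 0.001), 0.999)), 0, 0, 0,
          stats::qlogis(0.05), log(0.2))
  st <- pmin(pmax(st, lower + 1e-10), upper - 1e-10)
  fit <- stats::optim(st, bb_marginal_nll, y = as.numeric(y),
                      n = as.numeric(n), X = X, ji = ji, J = J,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = 300, factr = 1e8))
  -fit$value
}

#' @export
print.convergence_result <- function(x, ...) {
  cat(sprintf("convergence_result (%s, %s mode): %d/%d loci tested, %d differentiated at Bonferroni %g\n",
              x$contrast, x$mode, x$m, nrow(x$results),
              sum(x$results$differentiated), x$alpha))
  invisible(x)
}
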