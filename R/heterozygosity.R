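#' Site-level expected heterozygosity
#'
#' `H = 2 f (1 - f)` with `f = minor / coverage` (no pseudocount: a site
#' sampled as invariant genuinely contributes 0). Vectorized; `H(f)` is
#' symmetric in minor/major relabeling.
#'
#' @param minor,coverage count vectors or matrices; coverage must be > 0.
#' @return expected heterozygosity, same shape as the input.
#' @export
site_het <- function(minor, coverage) {
  if (any(coverage == 0))
    stop("heterozygosity undefined at ", sum(coverage == 0),
         " cell(s) with coverage 0")
  f <- minor / coverage
  2 * f * (1 - f)
}

#' Genome-wide heterozygosity trend over a trajectory
#'
#' Computes the per-sample mean expected heterozygosity over all loci, then,
#' within each trajectory present, compares replicate-level means at the
#' first versus last sampled generation with a Welch two-sample t-test
#' (replicate populations as independent units). The direction of change
#' (+1 rising, -1 falling) is reported per trajectory.
#'
#' @param table a `snp_table`.
#' @param groups which sample groups to treat as trajectories
#'   (default `c("A2C", "C2A")`).
#' @return object of class `het_summary`: `per_sample` (data frame with
#'   sample metadata and `mean_het`) and `tests` (per trajectory: first/last
#'   generation, replicate-mean heterozygosities, Welch statistic, p,
#'   direction).
#' @export
het_trend <- function(table, groups = c("A2C", "C2A")) {
  stopifnot(inherits(table, "snp_table"))
  H <- site_het(table$minor, table$coverage)
  per_sample <- cbind(table$samples, mean_het = colMeans(H))
  tests <- list()
  for (g in intersect(groups, unique(table$samples$group))) {
    s <- per_sample[per_sample$group == g, ]
    gens <- sort(unique(s$generation))
    if (length(gens) < 2) {
      warning("het_trend: <2 generations for ", g, "; test skipped")
      next
    }
    first <- s$mean_het[s$generation == gens[1]]
    last <- s$mean_het[s$generation == gens[length(gens)]]
    if (length(first) < 2 || length(last) < 2) {
      warning("het_trend: single replicate in ", g, "; test skipped")
      tt <- list(statistic = NA_real_, p.value = NA_real_)
    } else if (isTRUE(all.equal(first, last))) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      w <- stats::t.test(last, first)
      tt <- list(statistic = unname(w$statistic), p.value = w$p.value)
    }
    tests[[g]] <- data.frame(
      group = g, gen_first = gens[1], gen_last = gens[length(gens)],
      mean_first = mean(first), mean_last = mean(last),
      direction = sign(mean(last) - mean(first)),
      statistic = tt$statistic, p = tt$p.value)
  }
  structure(list(per_sample = per_sample,
                 tests = if (length(tests)) do.call(rbind, tests) else NULL),
            class = "het_summary")
}

#' @export
print.het_summary <- function(x, ...) {
  cat("het_summary:", nrow(x$per_sample), "samples\n")
  if (!is.null(x$tests)) print(x$tests, row.names = FALSE)
  invisible(x)
}
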