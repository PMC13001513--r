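#' Quasibinomial generation scan within one trajectory
#'
#' Baseline per-SNP scan of allele-frequency change through time for one
#' trajectory: `(minor, major) ~ generation + replicate` with replicate
#' fixed-effect intercepts, quasibinomial dispersion estimated from Pearson
#' residuals, t-based p-value for the generation coefficient, and
#' Benjamini-Hochberg adjustment across estimable loci (inestimable loci are
#' recorded and excluded from the BH denominator). A locus with exactly
#' constant counts yields estimate 0 and p = 1.
#'
#' @param table a `snp_table` restricted to (or containing only) one
#'   trajectory's samples; pass `group` to subset internally.
#' @param group optional sample group to restrict to (e.g. `"A2C"`).
#' @return data frame, one row per locus: `estimate` (logit slope per
#'   generation), `p`, `padj` (BH), `estimable`.
#' @export
qb_generation_scan <- function(table, group = NULL) {
  stopifnot(inherits(table, "snp_table"))
  if (!is.null(group)) table <- table[, table$samples$group == group]
  s <- table$samples
  if (length(unique(s$generation)) < 2) stop("need >= 2 generations")
  if (length(unique(s$replicate)) < 2) stop("need >= 2 replicates")
  X <- stats::model.matrix(~ generation + factor(replicate), data = s)
  gen_col <- 2L
  L <- nrow(table$loci)
  est <- pval <- rep(NA_real_, L)
  rk <- qr(X)$rank
  df_res <- nrow(X) - rk
  for (i in seq_len(L)) {
    y <- table$minor[i, ]; n <- table$coverage[i, ]
    prop <- y / n
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, prop, weights = n,
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients[gen_col])) next
    mu <- fit$fitted.values
    disp <- sum((prop - mu)^2 * n / pmax(mu * (1 - mu), 1e-12)) /
      max(df_res, 1)
    disp <- max(disp, 1e-8)
    covu <- tryCatch(chol2inv(fit$qr$qr[seq_len(rk), seq_len(rk),
                                        drop = FALSE]),
                     error = function(e) NULL)
    if (is.null(covu)) next
    se <- sqrt(disp * covu[gen_col, gen_col])
    est[i] <- fit$coefficients[gen_col]
    tt <- est[i] / se
    pval[i] <- 2 * stats::pt(-abs(tt), df_res)
  }
  estimable <- !is.na(pval) & is.finite(pval)
  padj <- rep(NA_real_, L)
  padj[estimable] <- stats::p.adjust(pval[estimable], method = "BH")
  data.frame(locus = seq_len(L), chrom = table$loci$chrom,
             pos = table$loci$pos, estimate = est, p = pval, padj = padj,
             estimable = estimable)
}

#' Net allele-frequency change between first and last sampled generations
#'
#' Pools minor and total counts over the selected replicates within each
#' generation, then returns `delta_p = f_last - f_first` per locus, where
#' `f_gen` is the pooled minor-allele frequency at that generation.
#'
#' @param table a `snp_table` (restrict with `group` for one trajectory).
#' @param replicates replicate numbers to pool over; `NULL` = all.
#' @param group optional sample group to restrict to first.
#' @param gen_first,gen_last generations to difference; default the minimum
#'   and maximum present in the subset. An explicitly requested generation
#'   that is absent raises an error naming it.
#' @return numeric vector of signed frequency changes, one per locus.
#' @export
delta_p <- function(table, replicates = NULL, group = NULL,
                    gen_first = NULL, gen_last = NULL) {
  stopifnot(inherits(table, "snp_table"))
  if (!is.null(group)) table <- table[, table$samples$group == group]
  if (!is.null(replicates))
    table <- table[, table$samples$replicate %in% replicates]
  gens <- sort(unique(table$samples$generation))
  if (is.null(gen_first)) gen_first <- gens[1]
  if (is.null(gen_last)) gen_last <- gens[length(gens)]
  for (g in c(gen_first, gen_last))
    if (!g %in% gens) stop("generation ", g, " absent from the subset")
  if (gen_first == gen_last)
    stop("need two distinct generations; only generation ", gen_first,
         " present")
  pooled_freq <- function(g) {
    j <- table$samples$generation == g
    rowSums(table$minor[, j, drop = FALSE]) /
      rowSums(table$coverage[, j, drop = FALSE])
  }
  pooled_freq(gen_last) - pooled_freq(gen_first)
}

#' Leave-one-out parallelism analysis
#'
#' Tests whether allele-frequency change is replicate-independent. For each
#' replicate r of a trajectory: (i) re-run the quasibinomial generation scan
#' on the remaining ("training") replicates; (ii) define target SNPs as
#' estimable loci with BH-adjusted p below `fdr` and training-pool
#' `|delta_p| >= min_abs_dp`; (iii) draw an equal-size control set uniformly
#' (without replacement, per-iteration derived seed) from estimable
#' non-target loci; (iv) measure `delta_p` in the held-out replicate alone
#' and summarize it as the median over targets and over controls,
#' genome-wide and per chromosome arm. Finally, replicate-level target and
#' control medians are compared per region with a two-sample two-tailed
#' t-test. Iterations with zero targets are recorded empty and excluded
#' from the t-tests with a warning.
#'
#' @param table a `snp_table`.
#' @param trajectory `"A2C"` or `"C2A"`.
#' @param fdr BH threshold for targets (default 0.05).
#' @param min_abs_dp minimum training-pool `|delta_p|` for targets
#'   (default 0.02).
#' @param seed integer seed driving the control draws.
#' @param arms chromosome arms summarized separately
#'   (default 2L, 2R, 3L, 3R, X).
#' @return object of class `loo_summary`: `iterations` (replicate x region
#'   medians and target counts), `tests` (per region: t statistic, p, df),
#'   `fdr`, `min_abs_dp`, `seed`, `trajectory`.
#' @export
loo_parallelism <- function(table, trajectory = c("A2C", "C2A"), fdr = 0.05,
                            min_abs_dp = 0.02, seed = 1,
                            arms = c("2L", "2R", "3L", "3R", "X")) {
  trajectory <- match.arg(trajectory)
  stopifnot(fdr > 0, fdr < 1, min_abs_dp >= 0, min_abs_dp <= 1)
  tb <- table[, table$samples$group == trajectory]
  reps <- sort(unique(tb$samples$replicate))
  if (length(reps) < 3) stop("LOO needs >= 3 replicates, got ", length(reps))
  regions <- c("genome", intersect(arms, unique(tb$loci$chrom)))
  iters <- list()
  for (idx in seq_along(reps)) {
    r <- reps[idx]
    train <- tb[, tb$samples$replicate != r]
    scan <- qb_generation_scan(train)
    dp_train <- delta_p(train)
    target <- scan$estimable & !is.na(scan$padj) & scan$padj < fdr &
      abs(dp_train) >= min_abs_dp
    eligible <- scan$estimable & !target
    n_t <- sum(target)
    set.seed(seed + 7919L * idx)
    control_idx <- if (n_t > 0 && sum(eligible) > 0)
      sample(which(eligible), min(n_t, sum(eligible)))
    else integer(0)
    dp_held <- delta_p(tb, replicates = r)
    for (reg in regions) {
      in_reg <- if (reg == "genome") rep(TRUE, nrow(tb$loci))
      else tb$loci$chrom == reg
      ti <- which(target & in_reg)
      ci <- intersect(control_idx, which(in_reg))
      iters[[length(iters) + 1]] <- data.frame(
        replicate = r, region = reg, n_targets = length(ti),
        target_median = if (length(ti)) stats::median(dp_held[ti]) else NA_real_,
        control_median = if (length(ci)) stats::median(dp_held[ci]) else NA_real_)
    }
  }
  iterations <- do.call(rbind, iters)
  tests <- list()
  for (reg in regions) {
    d <- iterations[iterations$region == reg, ]
    ok <- !is.na(d$target_median) & !is.na(d$control_median)
    if (sum(!ok) > 0)
      warning("loo_parallelism: ", sum(!ok), " empty iteration(s) excluded ",
              "from the ", reg, " t-test")
    if (sum(ok) >= 2 &&
        stats::sd(c(d$target_median[ok], d$control_median[ok])) > 0) {
      tt <- stats::t.test(d$target_median[ok], d$control_median[ok])
      tests[[reg]] <- data.frame(region = reg, statistic = unname(tt$statistic),
                                 df = unname(tt$parameter), p = tt$p.value,
                                 n = sum(ok))
    } else {
      tests[[reg]] <- data.frame(region = reg, statistic = NA_real_,
                                 df = NA_real_, p = NA_real_, n = sum(ok))
    }
  }
  structure(list(iterations = iterations, tests = do.call(rbind, tests),
                 fdr = fdr, min_abs_dp = min_abs_dp, seed = seed,
                 trajectory = trajectory),
            class = "loo_summary")
}

#' @export
print.loo_summary <- function(x, ...) {
  cat(sprintf("loo_summary (%s): fdr %g, |dp| >= %g\n", x$trajectory,
              x$fdr, x$min_abs_dp))
  gw <- x$iterations[x$iterations$region == "genome", ]
  cat(sprintf("  genome-wide median target dp: %.4f; control: %.4f\n",
              stats::median(gw$target_median, na.rm = TRUE),
              stats::median(gw$control_median, na.rm = TRUE)))
  print(x$tests, row.names = FALSE)
  invisible(x)
}
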