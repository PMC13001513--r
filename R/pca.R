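#' Scaled-uncentered PCA of SNP frequencies
#'
#' Singular-value decomposition of the samples x loci frequency matrix after
#' dividing each locus column by its standard deviation *without* mean
#' subtraction. Because the matrix is not centered, component scores retain
#' absolute frequency information (founder groups separate along early
#' components). Zero-variance loci are dropped with a message. When given a
#' `snp_table`, frequencies are computed with a pseudocount of 1 so that
#' monomorphic-sampled sites neither divide by zero nor carry zero variance
#' spuriously.
#'
#' @param x a [snp_table()] or a numeric samples x loci frequency matrix.
#' @param pseudocount pseudocount used when `x` is a `snp_table` (default 1).
#' @param fix_signs if sample metadata are available, flip each PC so the
#'   mean FOUNDER_A score does not exceed the mean FOUNDER_C score
#'   (reproducible orientation; default `TRUE`).
#' @return object of class `pca_result`: `scores` (samples x components),
#'   `variance_explained`, `loadings`, `dropped` (indices of zero-variance
#'   loci), `samples` (metadata or `NULL`).
#' @export
run_pca <- function(x, pseudocount = 1, fix_signs = TRUE) {
  samples <- NULL
  if (inherits(x, "snp_table")) {
    samples <- x$samples
    m <- t(frequencies(x, pseudocount = pseudocount))
  } else {
    m <- as.matrix(x)
  }
  if (nrow(m) < 2) stop("PCA needs at least 2 samples")
  sds <- apply(m, 2, stats::sd)
  dropped <- which(sds == 0 | !is.finite(sds))
  if (length(dropped) > 0) {
    message("run_pca: dropping ", length(dropped), " zero-variance loci")
    m <- m[, -dropped, drop = FALSE]
    sds <- sds[-dropped]
  }
  if (ncol(m) == 0) stop("no loci with nonzero variance")
  ms <- sweep(m, 2, sds, "/")
  sv <- svd(ms)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  ve <- sv$d^2 / sum(sv$d^2)
  loadings <- sv$v
  if (fix_signs && !is.null(samples) &&
      all(c("FOUNDER_A", "FOUNDER_C") %in% samples$group)) {
    ia <- samples$group == "FOUNDER_A"; ic <- samples$group == "FOUNDER_C"
    for (k in seq_len(ncol(scores))) {
      if (mean(scores[ia, k]) > mean(scores[ic, k])) {
        scores[, k] <- -scores[, k]
        loadings[, k] <- -loadings[, k]
      }
    }
  }
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores, variance_explained = ve,
                 loadings = loadings, dropped = dropped, samples = samples),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5, length(x$variance_explained))
  cat("pca_result:", nrow(x$scores), "samples;",
      "variance explained (first", k, "PCs):",
      paste0(sprintf("%.1f%%", 100 * x$variance_explained[seq_len(k)]),
             collapse = " "), "\n")
  invisible(x)
}

#' Per-component trajectory x generation mixed models
#'
#' For each of the first `n_pcs` principal components, fits
#' `score ~ trajectory * generation + (1 | population)` by REML over the
#' trajectory samples (A2C, C2A) and tests the fixed effects with
#' Satterthwaite-approximation t-tests (lmerTest). P-values are
#' Bonferroni-adjusted across all PCs x terms. Singular fits are flagged,
#' not fatal.
#'
#' @param pca a `pca_result` carrying sample metadata, or a scores matrix
#'   (then `samples` must be supplied).
#' @param samples sample metadata data frame (needed when `pca` is a matrix).
#' @param n_pcs number of leading components to model (default 10).
#' @param alpha significance level applied to adjusted p-values
#'   (default 0.005).
#' @return object of class `pc_lmm_result`: data frame with one row per
#'   PC x term (`estimate`, `p`, `padj`, `significant`, `singular`), plus
#'   `alpha` and `n_tests`.
#' @export
fit_pc_lmm <- function(pca, samples = NULL, n_pcs = 10, alpha = 0.005) {
  if (inherits(pca, "pca_result")) {
    scores <- pca$scores
    if (is.null(samples)) samples <- pca$samples
  } else scores <- as.matrix(pca)
  if (is.null(samples)) stop("sample metadata required")
  keep <- samples$group %in% c("A2C", "C2A")
  if (!any(keep)) stop("no trajectory samples for the mixed model")
  s <- samples[keep, ]
  one_traj <- length(unique(s$group)) < 2
  if (one_traj)
    warning("only one trajectory present; treatment terms inestimable")
  n_pcs <- min(n_pcs, ncol(scores))
  terms <- c("trajectory", "generation", "interaction")
  out <- list()
  for (k in seq_len(n_pcs)) {
    df <- data.frame(score = scores[keep, k],
                     trajectory = factor(s$group, levels = c("A2C", "C2A")),
                     generation = s$generation,
                     population = paste0(s$group, "_", s$replicate))
    row <- data.frame(pc = k, term = terms, estimate = NA_real_,
                      p = NA_real_, singular = FALSE)
    fit <- if (one_traj) NULL else
      tryCatch(suppressMessages(suppressWarnings(
        lmerTest::lmer(score ~ trajectory * generation + (1 | population),
                       data = df))), error = function(e) NULL)
    if (!is.null(fit)) {
      co <- stats::coef(summary(fit))
      idx <- c("trajectoryC2A", "generation", "trajectoryC2A:generation")
      pres <- idx %in% rownames(co)
      row$estimate[pres] <- co[idx[pres], "Estimate"]
      row$p[pres] <- co[idx[pres], "Pr(>|t|)"]
      row$singular <- lme4::isSingular(fit)
    }
    out[[k]] <- row
  }
  res <- do.call(rbind, out)
  n_tests <- sum(!is.na(res$p))
  res$padj <- pmin(1, res$p * n_tests)
  res$significant <- !is.na(res$padj) & res$padj < alpha
  structure(list(results = res, alpha = alpha, n_tests = n_tests),
            class = "pc_lmm_result")
}

#' Endpoint group linear models per principal component
#'
#' The endpoint-only analysis: ordinary linear models `score ~ group` per
#' component (generation dropped), used to ask whether trajectory/founder
#' group identity predicts genomic state at the final timepoint. P-values
#' (model F-test) are Bonferroni-adjusted across PCs.
#'
#' @param pca a `pca_result` with sample metadata (typically computed on
#'   endpoint + founder samples only).
#' @param samples optional metadata override.
#' @param n_pcs components to test (default 10).
#' @param alpha level on adjusted p-values (default 0.05).
#' @return data frame: pc, max |group effect| estimate, F statistic, p,
#'   padj, significant.
#' @export
endpoint_group_lm <- function(pca, samples = NULL, n_pcs = 10, alpha = 0.05) {
  scores <- pca$scores
  if (is.null(samples)) samples <- pca$samples
  n_pcs <- min(n_pcs, ncol(scores))
  out <- lapply(seq_len(n_pcs), function(k) {
    fit <- stats::lm(scores[, k] ~ factor(samples$group))
    fs <- summary(fit)$fstatistic
    p <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
    est <- stats::coef(fit)[-1]
    data.frame(pc = k, estimate = est[which.max(abs(est))],
               f_statistic = unname(fs[1]), p = unname(p))
  })
  res <- do.call(rbind, out)
  res$padj <- pmin(1, res$p * n_pcs)
  res$significant <- res$padj < alpha
  rownames(res) <- NULL
  res
}
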