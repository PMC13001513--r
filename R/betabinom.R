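#' Beta-binomial log probability mass
#'
#' Beta-binomial pmf in the intra-class correlation parameterization used
#' throughout the package: `BetaBinomial(n, p, phi)` has beta shape
#' parameters `a = p (1 - phi) / phi`, `b = (1 - p)(1 - phi) / phi`, so
#' `phi` in `[0, 1)` is the correlation between reads drawn from the same
#' pool and `phi -> 0` recovers the binomial. Vectorized over all arguments.
#'
#' @param y observed minor-allele counts.
#' @param n total counts (coverage).
#' @param p mean allele frequency in (0,1).
#' @param phi overdispersion (intra-class correlation) in `[0, 1)`.
#' @param log return log pmf? (default `TRUE`).
#' @return (log) pmf values.
#' @export
dbetabinom <- function(y, n, p, phi, log = TRUE) {
  stopifnot(all(phi >= 0), all(phi < 1))
  # below ~1e-8 the beta-binomial is numerically indistinguishable from the
  # binomial while the lgamma route starts losing precision to cancellation
  if (all(phi < 1e-8)) {
    ll <- stats::dbinom(y, n, p, log = TRUE)
  } else {
    cc <- (1 - phi) / phi
    a <- p * cc
    b <- (1 - p) * cc
    ll <- lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b)
  }
  if (log) ll else exp(ll)
}

#' Beta-binomial GLMM log-likelihood at fixed random effects
#'
#' Conditional log-likelihood of minor-allele counts given fixed effects and
#' replicate random-intercept values: the sum over observations of the
#' beta-binomial log pmf with mean `p = plogis(b0 + b1 T + b2 G +
#' b3 T G + u[replicate])`.
#'
#' @param beta numeric length 4: intercept, treatment, generation,
#'   interaction coefficients on the logit scale.
#' @param phi overdispersion in `[0, 1)`; 0 gives the binomial likelihood.
#' @param u named vector of random-intercept values, one per replicate
#'   population level in `design$replicate`.
#' @param minor,coverage integer vectors of per-sample counts for one locus.
#' @param design data frame with columns `treatment` (0/1), `generation`
#'   (numeric) and `replicate` (population label).
#' @return the summed log-likelihood.
#' @export
bb_loglik <- function(beta, phi, u, minor, coverage, design) {
  stopifnot(length(beta) == 4, all(minor >= 0), all(minor <= coverage))
  ji <- as.character(design$replicate)
  if (!all(ji %in% names(u)))
    stop("u must be named with every replicate level")
  eta <- beta[1] + beta[2] * design$treatment + beta[3] * design$generation +
    beta[4] * design$treatment * design$generation + u[ji]
  if (any(!is.finite(eta)))
    stop("non-finite linear predictor at observation ",
         which(!is.finite(eta))[1])
  sum(dbetabinom(minor, coverage, stats::plogis(eta), phi, log = TRUE))
}

# first/second derivatives of the BB log pmf wrt the linear predictor.
# With a+b = cc constant in p, dl/dp = cc [psi(y+a) - psi(a) - psi(n-y+b)
# + psi(b)]; chain rule through p = plogis(eta).
bb_eta_derivs <- function(y, n, p, cc) {
  a <- p * cc; b <- (1 - p) * cc
  d1p <- cc * (digamma(y + a) - digamma(a) - digamma(n - y + b) + digamma(b))
  d2p <- cc^2 * (trigamma(y + a) - trigamma(a) + trigamma(n - y + b) - trigamma(b))
  w <- p * (1 - p)
  list(d1 = d1p * w, d2 = d2p * w^2 + d1p * w * (1 - 2 * p))
}

# Gauss-Hermite nodes/weights (Golub-Welsch on the Jacobi matrix)
gauss_hermite <- function(k) {
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- sqrt(pi) * e$vectors[1, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

# marginal negative log-likelihood with the replicate intercept integrated
# out by Laplace (nagq = 1) or adaptive Gauss-Hermite quadrature (nagq > 1).
# par = (b0c, b1c, b2, b3, qlogis(phi), log(sigma_u)); ji is an integer
# replicate index 1..J (rowsum order matches u's order).
bb_marginal_nll <- function(par, y, n, X, ji, J, nagq = 1, gh = NULL,
                            cache = NULL) {
  if (nagq <= 1) {
    u0 <- if (!is.null(cache) && !is.null(cache$u)) cache$u else numeric(0)
    r <- .bb_nll_laplace(par, y, n, X, as.integer(ji), as.integer(J), u0)
    if (!is.null(cache)) cache$u <- r$u
    return(r$value)
  }
  bb_marginal_nll_r(par, y, n, X, ji, J, nagq = nagq, gh = gh, cache = cache)
}

# reference R implementation: Laplace (nagq = 1) or adaptive Gauss-Hermite
bb_marginal_nll_r <- function(par, y, n, X, ji, J, nagq = 1, gh = NULL,
                              cache = NULL) {
  beta <- par[1:4]
  phi <- stats::plogis(par[5])
  sig2 <- exp(2 * par[6])
  cc <- (1 - phi) / phi
  eta0 <- drop(X %*% beta)
  # warm-start the conditional modes from the previous evaluation
  u <- if (!is.null(cache) && !is.null(cache$u)) cache$u else numeric(J)
  # vectorized Newton for the per-replicate conditional modes
  clamp <- function(p) pmin(pmax(p, 1e-9), 1 - 1e-9)
  for (it in 1:25) {
    p <- clamp(stats::plogis(eta0 + u[ji]))
    dv <- bb_eta_derivs(y, n, p, cc)
    g1 <- rowsum(dv$d1, ji, reorder = TRUE)[, 1] - u / sig2
    g2 <- rowsum(dv$d2, ji, reorder = TRUE)[, 1] - 1 / sig2
    g2 <- pmin(g2, -1e-8)
    step <- -g1 / g2
    step <- pmax(pmin(step, 3), -3)
    u <- u + step
    if (max(abs(step)) < 1e-7) break
  }
  if (!is.null(cache)) cache$u <- u
  p <- clamp(stats::plogis(eta0 + u[ji]))
  ll_obs <- dbetabinom(y, n, p, phi, log = TRUE)
  ll_j <- rowsum(ll_obs, ji, reorder = TRUE)[, 1]
  dv <- bb_eta_derivs(y, n, p, cc)
  H <- pmax(-(rowsum(dv$d2, ji, reorder = TRUE)[, 1] - 1 / sig2), 1e-10)
  if (nagq <= 1) {
    lmarg <- ll_j - u^2 / (2 * sig2) - 0.5 * log(sig2) - 0.5 * log(H)
  } else {
    if (is.null(gh)) gh <- gauss_hermite(nagq)
    sc <- sqrt(2 / H)
    lmarg <- numeric(J)
    for (jj in seq_len(J)) {
      uk <- u[jj] + sc[jj] * gh$x
      sel <- ji == jj
      lk <- vapply(uk, function(uu) {
        pp <- clamp(stats::plogis(eta0[sel] + uu))
        sum(dbetabinom(y[sel], n[sel], pp, phi, log = TRUE)) -
          uu^2 / (2 * sig2)
      }, numeric(1))
      m <- max(lk + gh$x^2 + log(gh$w))
      lmarg[jj] <- m + log(sum(exp(lk + gh$x^2 + log(gh$w) - m))) +
        log(sc[jj]) - 0.5 * log(2 * pi * sig2)
    }
  }
  val <- -sum(lmarg)
  if (!is.finite(val)) 1e10 else val
}

bb_result_na <- function(reason) {
  structure(list(beta = rep(NA_real_, 4), se = rep(NA_real_, 4),
                 p = rep(NA_real_, 4), phi = NA_real_, sigma_u2 = NA_real_,
                 loglik = NA_real_, converged = FALSE, reason = reason),
            class = "bb_fit")
}

#' Fit the per-locus beta-binomial GLMM
#'
#' Maximum-likelihood fit of
#' `logit(p) = b0 + b1 T + b2 G + b3 (T x G) + u_j`,
#' `Y ~ BetaBinomial(n, p, phi)`, `u_j ~ N(0, sigma_u^2)` with the replicate
#' random intercept integrated out by a Laplace approximation (adaptive
#' Gauss-Hermite quadrature available as a validation mode via `nagq`).
#' Generation is centered internally to decorrelate intercept and slope;
#' estimates and standard errors are reported on the original scale.
#' Per-term Wald tests use a t reference with `J - 2` degrees of freedom
#' (J = replicate populations): replicates are the independent units behind
#' the treatment and interaction contrasts, and a normal reference is
#' anticonservative at typical replicate counts. Optimizer failure or
#' degenerate input yields `converged = FALSE`, never an exception.
#'
#' @param minor,coverage per-sample counts for the locus.
#' @param design data frame with columns `treatment` (0/1 trajectory
#'   indicator), `generation` (numeric) and `replicate` (population label;
#'   coerced to factor).
#' @param nagq 1 for Laplace (default); >1 for adaptive Gauss-Hermite with
#'   that many nodes.
#' @return object of class `bb_fit`: `beta`, `se`, `p` (length-4, order
#'   intercept/treatment/generation/interaction), `phi`, `sigma_u2`,
#'   `loglik`, `converged`, `reason`, `df` (Wald reference df).
#' @export
fit_bb_glmm <- function(minor, coverage, design, nagq = 1) {
  y <- as.numeric(minor); n <- as.numeric(coverage)
  if (all(y == 0) || all(y == n)) return(bb_result_na("no variation"))
  jchar <- as.character(design$replicate)
  ji <- match(jchar, sort(unique(jchar)))
  J <- length(unique(ji))
  # center and scale generation so all coefficients are O(1) for the
  # optimizer; estimates are mapped back to the original scale below
  gbar <- mean(design$generation)
  sdg <- stats::sd(design$generation)
  if (!is.finite(sdg) || sdg == 0) sdg <- 1
  Gc <- (design$generation - gbar) / sdg
  X <- cbind(1, design$treatment, Gc, design$treatment * Gc)
  gh <- if (nagq > 1) gauss_hermite(nagq) else NULL
  cache <- new.env(parent = emptyenv())

  # starting values: weighted binomial GLM + Pearson moment overdispersion
  start_beta <- tryCatch({
    f0 <- suppressWarnings(stats::glm.fit(X, y / n, weights = n,
                                          family = stats::binomial()))
    b <- f0$coefficients
    b[!is.finite(b)] <- 0
    pmin(pmax(b, -10), 10)
  }, error = function(e) c(stats::qlogis(pmin(pmax(mean(y / n), 0.01), 0.99)),
                           0, 0, 0))
  phat <- stats::plogis(drop(X %*% start_beta))
  chi2 <- sum((y - n * phat)^2 / pmax(n * phat * (1 - phat), 1e-8))
  infl <- max(chi2 / max(length(y) - 4, 1), 1.001)
  rho0 <- min(max((infl - 1) / max(mean(n) - 1, 1), 1e-4), 0.3)

  starts <- list(c(start_beta, stats::qlogis(rho0), log(0.1)),
                 c(start_beta, stats::qlogis(0.01), log(0.3)),
                 c(0, 0, 0, 0, stats::qlogis(0.05), log(0.2)))
  lower <- c(rep(-25, 4), stats::qlogis(1e-8), log(1e-4))
  upper <- c(rep(25, 4), stats::qlogis(0.9), log(10))
  fit <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower + 1e-6), upper - 1e-6)
    cache$u <- NULL
    fit <- tryCatch(
      stats::optim(st, bb_marginal_nll, y = y, n = n, X = X, ji = ji, J = J,
                   nagq = nagq, gh = gh, cache = cache, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) && fit$value < 1e9) break
    fit <- NULL
  }
  if (is.null(fit)) return(bb_result_na("optimizer failure"))

  par <- fit$par
  Hn <- tryCatch(
    stats::optimHess(par, bb_marginal_nll, y = y, n = n, X = X, ji = ji,
                     J = J, nagq = nagq, gh = gh, cache = cache),
    error = function(e) NULL)
  covb <- NULL
  if (!is.null(Hn)) {
    covb <- tryCatch(solve(Hn[1:4, 1:4]), error = function(e) NULL)
    if (!is.null(covb) && any(diag(covb) <= 0)) covb <- NULL
  }
  # back-transform centered/scaled-generation parametrization
  A <- diag(4)
  A[1, 3] <- -gbar / sdg; A[2, 4] <- -gbar / sdg
  A[3, 3] <- 1 / sdg; A[4, 4] <- 1 / sdg
  beta <- drop(A %*% par[1:4])
  se <- rep(NA_real_, 4)
  if (!is.null(covb)) se <- sqrt(diag(A %*% covb %*% t(A)))
  z <- beta / se
  # Wald t with between-replicate degrees of freedom: the replicate
  # populations are the independent units behind the treatment and
  # interaction contrasts, and a normal reference is anticonservative at
  # this many groups
  dfree <- max(J - 2, 1)
  pv <- 2 * stats::pt(-abs(z), dfree)
  structure(list(beta = beta, se = se, p = pv, df = dfree,
                 phi = stats::plogis(par[5]), sigma_u2 = exp(2 * par[6]),
                 loglik = -fit$value,
                 converged = fit$convergence == 0 && !is.null(covb),
                 reason = if (fit$convergence == 0) "" else "optim code != 0"),
            class = "bb_fit")
}

#' Likelihood-ratio test for one fixed effect (validation mode)
#'
#' Refits the beta-binomial GLMM without one fixed-effect column and returns
#' the chi-square LRT p-value; a slower alternative to the default Wald test.
#'
#' @inheritParams fit_bb_glmm
#' @param term one of "treatment", "generation", "interaction".
#' @return list with `stat`, `p`, and both fits' log-likelihoods.
#' @export
bb_lrt <- function(minor, coverage, design, term = "interaction", nagq = 1) {
  term <- match.arg(term, c("treatment", "generation", "interaction"))
  full <- fit_bb_glmm(minor, coverage, design, nagq = nagq)
  d0 <- design
  # drop the term by zeroing its column through a constrained design
  if (term == "treatment") d0$treatment <- 0
  if (term == "generation") d0$generation <- d0$generation * 0
  red <- if (term == "interaction") {
    # refit with interaction column removed: absorb via treatment-only design
    fit_bb_glmm_reduced(minor, coverage, design)
  } else fit_bb_glmm(minor, coverage, d0, nagq = nagq)
  stat <- 2 * (full$loglik - red$loglik)
  list(stat = stat, p = stats::pchisq(pmax(stat, 0), 1, lower.tail = FALSE),
       loglik_full = full$loglik, loglik_reduced = red$loglik)
}

# additive model (no interaction) used by the LRT validation mode
fit_bb_glmm_reduced <- function(minor, coverage, design) {
  y <- as.numeric(minor); n <- as.numeric(coverage)
  if (all(y == 0) || all(y == n)) return(bb_result_na("no variation"))
  jchar <- as.character(design$replicate)
  ji <- match(jchar, sort(unique(jchar)))
  J <- length(unique(ji))
  sdg <- stats::sd(design$generation)
  if (!is.finite(sdg) || sdg == 0) sdg <- 1
  Gc <- (design$generation - mean(design$generation)) / sdg
  X <- cbind(1, design$treatment, Gc, 0 * Gc)
  st <- c(stats::qlogis(pmin(pmax(mean(y / n), 0.01), 0.99)), 0, 0, 0,
          stats::qlogis(0.05), log(0.2))
  lower <- c(rep(-25, 3), -1e-8, stats::qlogis(1e-8), log(1e-4))
  upper <- c(rep(25, 3), 1e-8, stats::qlogis(0.9), log(10))
  fit <- tryCatch(
    stats::optim(pmin(pmax(st, lower + 1e-9), upper - 1e-9), bb_marginal_nll,
                 y = y, n = n, X = X, ji = ji, J = J, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = 300, factr = 1e8)),
    error = function(e) NULL)
  if (is.null(fit)) return(bb_result_na("optimizer failure"))
  structure(list(beta = fit$par[1:4], se = rep(NA_real_, 4),
                 p = rep(NA_real_, 4), phi = stats::plogis(fit$par[5]),
                 sigma_u2 = exp(2 * fit$par[6]), loglik = -fit$value,
                 converged = fit$convergence == 0, reason = ""),
            class = "bb_fit")
}

#' Build the trajectory-scan design from sample metadata
#'
#' Restricts to trajectory samples (groups A2C and C2A), codes treatment
#' 0 = A2C, 1 = C2A, and keys the random intercept by population
#' (group x replicate).
#'
#' @param samples the `samples` data frame of a [snp_table()].
#' @return list with `design` data frame and `keep` (column index into the
#'   table's samples).
#' @export
scan_design <- function(samples) {
  keep <- which(samples$group %in% c("A2C", "C2A"))
  if (length(keep) == 0) stop("no trajectory (A2C/C2A) samples present")
  s <- samples[keep, ]
  list(design = data.frame(
    treatment = as.numeric(s$group == "C2A"),
    generation = s$generation,
    replicate = paste0(s$group, "_", s$replicate),
    stringsAsFactors = FALSE), keep = keep)
}

#' Genome-wide beta-binomial GLMM scan
#'
#' Fits [fit_bb_glmm()] at every locus of a filtered SNP table, applies a
#' Bonferroni correction per model term across tested loci, and tallies the
#' exclusive significance classes (treatment / generation / interaction and
#' their overlaps). Loci whose fit fails are recorded and, by default, still
#' count in the multiplicity denominator.
#'
#' @param table a filtered `snp_table` containing A2C and C2A samples.
#' @param alpha genome-wide significance level on Bonferroni-adjusted
#'   p-values (default 0.05).
#' @param exclude_failures_from_m drop failed fits from the Bonferroni
#'   denominator? (default `FALSE`).
#' @param nagq passed to [fit_bb_glmm()].
#' @return object of class `bb_scan`: `results` data frame (one row per
#'   locus: estimates, SEs, raw and adjusted p per term, `phi`, `sigma_u2`,
#'   significance flags), `m` (Bonferroni denominator), `alpha`,
#'   `class_counts` (named vector over exclusive term combinations).
#' @export
scan_genome <- function(table, alpha = 0.05, exclude_failures_from_m = FALSE,
                        nagq = 1) {
  stopifnot(inherits(table, "snp_table"))
  sd <- scan_design(table$samples)
  L <- nrow(table$loci)
  cols <- c("treatment", "generation", "interaction")
  res <- data.frame(table$loci[, c("chrom", "pos")],
                    b0 = NA_real_, b_treatment = NA_real_,
                    b_generation = NA_real_, b_interaction = NA_real_,
                    se_treatment = NA_real_, se_generation = NA_real_,
                    se_interaction = NA_real_,
                    p_treatment = NA_real_, p_generation = NA_real_,
                    p_interaction = NA_real_,
                    phi = NA_real_, sigma_u2 = NA_real_, converged = FALSE)
  for (i in seq_len(L)) {
    f <- fit_bb_glmm(table$minor[i, sd$keep], table$coverage[i, sd$keep],
                     sd$design, nagq = nagq)
    res$converged[i] <- f$converged
    if (!any(is.na(f$beta))) {
      res[i, c("b0", "b_treatment", "b_generation", "b_interaction")] <- f$beta
      res[i, c("se_treatment", "se_generation", "se_interaction")] <- f$se[2:4]
      res[i, c("p_treatment", "p_generation", "p_interaction")] <- f$p[2:4]
      res$phi[i] <- f$phi; res$sigma_u2[i] <- f$sigma_u2
    }
  }
  m <- if (exclude_failures_from_m) sum(res$converged) else L
  for (t in cols) {
    res[[paste0("padj_", t)]] <- pmin(1, res[[paste0("p_", t)]] * m)
    res[[paste0("sig_", t)]] <- !is.na(res[[paste0("padj_", t)]]) &
      res[[paste0("padj_", t)]] < alpha
  }
  class_counts <- table(factor(paste0(ifelse(res$sig_treatment, "T", ""),
                                      ifelse(res$sig_generation, "G", ""),
                                      ifelse(res$sig_interaction, "I", "")),
                               levels = c("", "T", "G", "I", "TG", "TI",
                                          "GI", "TGI")))
  structure(list(results = res, m = m, alpha = alpha,
                 class_counts = class_counts),
            class = "bb_scan")
}

#' @export
print.bb_scan <- function(x, ...) {
  cat(sprintf("bb_scan: %d loci (m = %d), alpha = %g\n",
              nrow(x$results), x$m, x$alpha))
  cat("significance classes (T=treatment, G=generation, I=interaction):\n")
  print(x$class_counts)
  invisible(x)
}
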