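#' Pooled allele probability
#'
#' MLE of the binomial probability under the biallelic null: the pooled
#' haplotype-A fraction over all tissues of a gene, `sum(X) / sum(N)`.
#'
#' @param X integer vector of haplotype-A counts per tissue.
#' @param N integer vector of total phased counts per tissue.
#' @return `sum(X) / sum(N)`.
#' @export
pooled_probability <- function(X, N) {
  stopifnot(length(X) == length(N), length(X) >= 1)
  tot <- sum(N)
  if (tot == 0) stop("undefined probability: sum(N) is zero")
  sum(X) / tot
}

#' Binomial log-likelihood over tissues
#'
#' Sum of log binomial pmfs with a shared success probability `p`.
#' Data inconsistent with a degenerate `p` (0 or 1) yield `-Inf`.
#'
#' @inheritParams pooled_probability
#' @param p success probability in \[0, 1\].
#' @return log-likelihood (scalar).
#' @export
binomial_loglik <- function(X, N, p) {
  stopifnot(p >= 0, p <= 1, all(X <= N))
  sum(stats::dbinom(X, N, p, log = TRUE))
}

#' Beta-binomial log-likelihood in the (mu, rho) parameterization
#'
#' The beta-binomial is parameterized by its mean allele fraction `mu` and
#' intra-class correlation `rho`, with shape parameters
#' `alpha = mu (1 - rho) / rho`, `beta = (1 - mu)(1 - rho) / rho`.
#' As `rho -> 0` it converges to `binomial_loglik(X, N, mu)`; `rho = 0` is
#' evaluated as that binomial limit. Log-gamma (via `lbeta`) evaluation
#' keeps the pmf stable at large counts.
#'
#' @inheritParams pooled_probability
#' @param mu mean allele fraction in (0, 1).
#' @param rho intra-class correlation (overdispersion) in \[0, 1).
#' @return log-likelihood (scalar).
#' @export
betabinomial_loglik <- function(X, N, mu, rho) {
  stopifnot(mu > 0, mu < 1, rho >= 0, rho < 1, all(X <= N))
  if (rho < 1e-12) return(binomial_loglik(X, N, mu))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  sum(lchoose(N, X) + lbeta(X + a, N - X + b) - lbeta(a, b))
}

# negative beta-binomial log-likelihood closure with the combinatorial
# term precomputed (it does not depend on mu, rho)
.bb_nll <- function(X, N) {
  lch <- sum(lchoose(N, X))
  k <- length(X)
  function(par) {
    mu <- par[1]; rho <- par[2]
    if (rho < 1e-12) return(-sum(stats::dbinom(X, N, mu, log = TRUE)))
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    -(lch + sum(lbeta(X + a, N - X + b)) - k * lbeta(a, b))
  }
}

#' Maximum-likelihood beta-binomial fit
#'
#' Maximizes the beta-binomial log-likelihood over
#' `(mu, rho) in (eps, 1 - eps) x [0, 1 - eps)` with a bounded
#' quasi-Newton optimizer (`L-BFGS-B`), multi-started at the pooled
#' probability and `rho0 in {1e-4, 0.05, 0.3}`. The returned likelihood is
#' clamped to be at least the nested binomial likelihood at the pooled
#' probability (within 1e-8).
#'
#' @inheritParams pooled_probability
#' @return list with `mu_hat`, `rho_hat`, `ll_bb`, and `converged`.
#' @export
fit_betabinomial <- function(X, N) {
  stopifnot(length(X) >= 1, all(N >= 0), all(X <= N))
  eps <- 1e-8
  p <- pooled_probability(X, N)
  ll_bin <- binomial_loglik(X, N, p)
  mu0 <- min(max(p, 1e-3), 1 - 1e-3)
  nll <- .bb_nll(X, N)
  best <- NULL; conv <- FALSE
  for (rho0 in c(1e-4, 0.05, 0.3)) {
    o <- tryCatch(
      stats::optim(c(mu0, rho0), nll, method = "L-BFGS-B",
                   lower = c(eps, 0), upper = c(1 - eps, 1 - eps)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
    if (o$convergence == 0) conv <- TRUE
  }
  if (is.null(best))
    return(list(mu_hat = mu0, rho_hat = 0, ll_bb = ll_bin, converged = FALSE))
  ll_bb <- -best$value
  # nested models: the alternative cannot fit worse than the null
  if (ll_bb < ll_bin) ll_bb <- ll_bin
  list(mu_hat = best$par[1], rho_hat = best$par[2], ll_bb = ll_bb,
       converged = conv)
}

#' Per-gene overdispersion likelihood-ratio test
#'
#' Tests the biallelic binomial null `X_i ~ Binomial(N_i, p)` (with `p`
#' the pooled MLE) against the overdispersed beta-binomial alternative
#' `X_i ~ BetaBinomial(N_i, mu, rho)`. The statistic
#' `LRT = 2 (ll_bb - ll_bin)` (clamped at 0) is referred to the upper tail
#' of the chi-squared distribution with 1 degree of freedom (two free
#' parameters minus one). Because the null value `rho = 0` sits on the
#' boundary of the parameter space, the plain df = 1 reference is
#' conservative.
#'
#' Degenerate cases return a null result (`lrt = 0`, `p = 1`): a single
#' informative tissue (no between-tissue variance information), and
#' perfectly consistent monoallelic data with pooled `p` of 0 or 1
#' (an imprinting-like pattern, which is consistent allelic bias, not
#' random allelic expression).
#'
#' @inheritParams pooled_probability
#' @param gene_id optional label stored in the result.
#' @return one-row data.frame: `gene_id`, `n_tissues`, `p_hat`, `mu_hat`,
#'   `rho_hat`, `ll_bin`, `ll_bb`, `lrt`, `p_value`, `q_value` (NA until
#'   [bh_adjust()] is applied by the caller).
#' @export
lrt_overdispersion <- function(X, N, gene_id = NA_character_) {
  stopifnot(length(X) == length(N))
  if (sum(N) == 0) stop("degenerate gene: all-zero N (filter upstream)")
  p <- pooled_probability(X, N)
  k <- length(X)
  res <- function(mu, rho, llb, llbb, lrt, pv)
    data.frame(gene_id = gene_id, n_tissues = k, p_hat = p,
               mu_hat = mu, rho_hat = rho, ll_bin = llb, ll_bb = llbb,
               lrt = lrt, p_value = pv, q_value = NA_real_,
               stringsAsFactors = FALSE)
  if (p == 0 || p == 1) {
    # consistent monoallelic data: both models fit perfectly
    return(res(p, 0, 0, 0, 0, 1))
  }
  ll_bin <- binomial_loglik(X, N, p)
  if (k == 1L) {
    # rho unidentifiable from a single tissue given the pooled p
    return(res(p, 0, ll_bin, ll_bin, 0, 1))
  }
  fit <- fit_betabinomial(X, N)
  lrt <- max(0, 2 * (fit$ll_bb - ll_bin))
  # floor against double underflow so p stays in (0, 1]
  pv <- max(stats::pchisq(lrt, df = 1, lower.tail = FALSE),
            .Machine$double.xmin)
  res(fit$mu_hat, fit$rho_hat, ll_bin, fit$ll_bb, lrt, pv)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Applied per individual, over that individual's tested genes only.
#'
#' @param p_values numeric vector of raw p-values in (0, 1\].
#' @return vector of adjusted values (monotone, capped at 1).
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Test every gene of one individual and flag significant RAE
#'
#' Runs [lrt_overdispersion()] on each gene of a filtered table over its
#' non-missing tissues, applies [bh_adjust()] across the individual's
#' genes, and flags genes with `q_value < fdr` as significant RAE.
#'
#' @param table a filtered `AlleleCountTable` (see [apply_filters()]).
#' @param fdr false discovery rate for the significance flag (default 0.10).
#' @return data.frame of per-gene results with a logical `significant`
#'   column; attribute `individual_id` and `sex` copied from the table.
#' @export
call_individual <- function(table, fdr = 0.10) {
  stopifnot(inherits(table, "AlleleCountTable"))
  ng <- length(table$genes)
  if (ng == 0L) {
    warning("no genes after filtering for individual ", table$individual_id)
    out <- data.frame(gene_id = character(), n_tissues = integer(),
                      p_hat = numeric(), mu_hat = numeric(),
                      rho_hat = numeric(), ll_bin = numeric(),
                      ll_bb = numeric(), lrt = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      significant = logical())
  } else {
    rows <- vector("list", ng)
    for (i in seq_len(ng)) {
      obs <- !table$missing[i, ]
      rows[[i]] <- lrt_overdispersion(table$X[i, obs], table$N[i, obs],
                                      gene_id = table$genes[i])
    }
    out <- do.call(rbind, rows)
    out$q_value <- bh_adjust(out$p_value)
    out$significant <- out$q_value < fdr
  }
  attr(out, "individual_id") <- table$individual_id
  attr(out, "sex") <- table$sex
  out
}
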