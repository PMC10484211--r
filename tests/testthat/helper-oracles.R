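# Independent oracles. These deliberately avoid the code paths they check:
# the beta-binomial pmf is evaluated through rising factorials instead of
# log-beta differences, the ML fit through grid refinement instead of
# quasi-Newton, BH through the literal step-up definition instead of
# p.adjust, and the chi-squared statistic through direct (O-E)^2/E sums.

# beta-binomial log pmf via rising factorials:
# P(x) = C(n,x) * prod_{j<x}(a+j) * prod_{j<n-x}(b+j) / prod_{j<n}(a+b+j)
oracle_bb_logpmf <- function(x, n, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  rising <- function(z, k) if (k == 0) 0 else sum(log(z + 0:(k - 1)))
  lchoose(n, x) + rising(a, x) + rising(b, n - x) - rising(a + b, n)
}

oracle_bb_loglik <- function(X, N, mu, rho) {
  sum(mapply(oracle_bb_logpmf, X, N, MoreArgs = list(mu = mu, rho = rho)))
}

# dense grid search with iterative zoom; returns the maximized
# beta-binomial log-likelihood and the arg max
oracle_grid_fit <- function(X, N, stages = 4, pts = 41) {
  lch <- sum(lchoose(N, X))
  ll <- function(mu, rho) {
    if (rho < 1e-12) return(sum(dbinom(X, N, mu, log = TRUE)))
    a <- mu * (1 - rho) / rho; b <- (1 - mu) * (1 - rho) / rho
    lch + sum(lbeta(X + a, N - X + b)) - length(X) * lbeta(a, b)
  }
  mu_lo <- 1e-6; mu_hi <- 1 - 1e-6; rho_lo <- 0; rho_hi <- 0.999
  best <- c(ll = -Inf, mu = NA, rho = NA)
  for (s in seq_len(stages)) {
    mus <- seq(mu_lo, mu_hi, length.out = pts)
    rhos <- seq(rho_lo, rho_hi, length.out = pts)
    vals <- outer(mus, rhos, Vectorize(ll))
    i <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    best <- c(ll = max(vals), mu = mus[i[1]], rho = rhos[i[2]])
    dm <- (mu_hi - mu_lo) / (pts - 1); dr <- (rho_hi - rho_lo) / (pts - 1)
    mu_lo <- max(1e-6, best["mu"] - dm); mu_hi <- min(1 - 1e-6, best["mu"] + dm)
    rho_lo <- max(0, best["rho"] - dr); rho_hi <- min(0.999, best["rho"] + dr)
  }
  as.list(best)
}

# literal BH step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# shared small fixture: the five-tissue example with pooled p = 0.5
example_X <- c(7, 8, 46, 32, 17)
example_N <- c(14, 16, 90, 65, 35)

write_fixture_matrix <- function(path, genes, tissues, cells) {
  # cells: character matrix (genes x tissues) of "a|b" or "NA"
  lines <- c(paste(c("gene_id", tissues), collapse = "\t"),
             vapply(seq_along(genes), function(i)
               paste(c(genes[i], cells[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  path
}

# quick beta-binomial sampler for test data
rbetabinom <- function(k, n, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  rbinom(k, n, rbeta(k, a, b))
}
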