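# distribution specs are small serializable lists so a cohort spec can be
# round-tripped through a config file
.draw <- function(dist, n) {
  switch(dist$type,
    uniform_int = sample(seq.int(dist$min, dist$max), n, replace = TRUE),
    uniform     = stats::runif(n, dist$min, dist$max),
    lognormal   = pmax(dist$min,
                       as.integer(round(stats::rlnorm(n, dist$meanlog,
                                                      dist$sdlog)))),
    fixed       = rep(dist$value, n),
    stop("unknown distribution type: ", dist$type))
}

#' Specify a synthetic cohort
#'
#' Describes the generative world for [generate_cohort()]: per-gene tissue
#' support and sequencing depth, the mixture of allelic classes, and an
#' optional XCI-like positive-control stratum present only in females.
#'
#' Defaults describe a bulk multi-tissue cohort: 3-30 informative tissues
#' per gene per individual; total phased depth log-normal around 100 reads
#' truncated at 10 (so the depth filter is exercised but not dominant);
#' 70% balanced biallelic genes, 15% cis-skewed (binomial with a gene-fixed
#' `p` drawn from `skew_p_range`, consistent across tissues and
#' individuals), 5% imprinted-like (`p` of 0.02 or 0.98, consistent
#' direction), 10% RAE (beta-binomial, `mu = 0.5`, gene-level `rho` drawn
#' from `rae_rho_distribution`, independent draws per tissue). RAE and
#' XCI-like genes are overdispersed only in a penetrant subset of
#' individuals (gene-level penetrance drawn uniformly from \[0.5, 1\]);
#' elsewhere they behave biallelically.
#'
#' @param n_individuals,n_genes cohort dimensions (autosomal genes).
#' @param tissue_count_distribution,depth_distribution,rae_rho_distribution,
#'   rae_penetrance_distribution distribution specs: lists with a `type`
#'   of `"uniform_int"`, `"uniform"`, `"lognormal"`, or `"fixed"`.
#' @param class_proportions named numeric summing to 1 over
#'   `biallelic_balanced`, `biallelic_skewed`, `imprinted_like`, `rae`.
#' @param skew_p_range length-2 numeric inside (0, 1).
#' @param xci_like optional stratum: list with `count`, `rho` (dist spec),
#'   `penetrance` (dist spec). `count = 0` disables it.
#' @param sexes character vector of length `n_individuals` (values
#'   `"female"`, `"male"`, `"unknown"`); XCI-like genes are emitted only
#'   for females.
#' @param seed integer RNG seed.
#' @return list of class `SyntheticCohortSpec`.
#' @export
cohort_spec <- function(n_individuals = 20L, n_genes = 500L,
                        tissue_count_distribution =
                          list(type = "uniform_int", min = 3, max = 30),
                        depth_distribution =
                          list(type = "lognormal", meanlog = log(100),
                               sdlog = 0.5, min = 10),
                        class_proportions =
                          c(biallelic_balanced = 0.70,
                            biallelic_skewed = 0.15,
                            imprinted_like = 0.05,
                            rae = 0.10),
                        skew_p_range = c(0.2, 0.8),
                        rae_rho_distribution =
                          list(type = "uniform", min = 0.3, max = 0.7),
                        rae_penetrance_distribution =
                          list(type = "uniform", min = 0.5, max = 1),
                        xci_like = list(count = 0L,
                                        rho = list(type = "uniform",
                                                   min = 0.4, max = 0.7),
                                        penetrance = list(type = "uniform",
                                                          min = 0.5, max = 1)),
                        sexes = rep("unknown", n_individuals),
                        seed = 1L) {
  need <- c("biallelic_balanced", "biallelic_skewed", "imprinted_like", "rae")
  if (!all(need %in% names(class_proportions)))
    stop("class_proportions must name: ", paste(need, collapse = ", "))
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  if (any(class_proportions < 0)) stop("negative class proportion")
  stopifnot(n_individuals >= 1, n_genes >= 1,
            length(sexes) == n_individuals,
            all(sexes %in% c("female", "male", "unknown")),
            length(skew_p_range) == 2,
            skew_p_range[1] > 0, skew_p_range[2] < 1)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_genes = as.integer(n_genes),
                 tissue_count_distribution = tissue_count_distribution,
                 depth_distribution = depth_distribution,
                 class_proportions = class_proportions[need],
                 skew_p_range = skew_p_range,
                 rae_rho_distribution = rae_rho_distribution,
                 rae_penetrance_distribution = rae_penetrance_distribution,
                 xci_like = xci_like,
                 sexes = sexes, seed = as.integer(seed)),
            class = "SyntheticCohortSpec")
}

#' Generate a synthetic cohort with ground truth
#'
#' Emulates the allelic subtypes observable in phased multi-tissue counts:
#' balanced biallelic (binomial, p = 0.5), cis-skewed (binomial, gene-fixed
#' p != 0.5 — consistent across tissues, so it fits the binomial and is
#' *not* RAE), imprinted-like (binomial, p near 0 or 1, consistent
#' direction), RAE (beta-binomial with gene-level intra-class correlation
#' rho, independent per-tissue draws), and an XCI-like positive-control
#' stratum (females only, high rho, high penetrance).
#'
#' RNG streams are seeded hierarchically (cohort seed for gene-level
#' parameters, a derived per-individual seed for count draws, consumed
#' gene-by-gene in order), so the same spec reproduces byte-identical
#' cohorts and appending genes does not perturb earlier draws.
#'
#' @param spec a [cohort_spec()].
#' @return list with `tables` (named list of `AlleleCountTable`), `truth`
#'   (data.frame: `gene_id`, `class`, `param` (skew/imprint p or rho),
#'   `penetrance`), and `penetrant` (gene x individual logical matrix of
#'   which individuals carry the overdispersed state).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "SyntheticCohortSpec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  classes <- sample(rep(names(spec$class_proportions),
                        times = stats::rmultinom(1, ng,
                                                 spec$class_proportions)[, 1]))
  genes <- sprintf("GENE%05d", seq_len(ng))
  param <- rep(NA_real_, ng)
  penet <- rep(1, ng)
  param[classes == "biallelic_balanced"] <- 0.5
  sk <- classes == "biallelic_skewed"
  param[sk] <- stats::runif(sum(sk), spec$skew_p_range[1], spec$skew_p_range[2])
  im <- classes == "imprinted_like"
  param[im] <- sample(c(0.02, 0.98), sum(im), replace = TRUE)
  ra <- classes == "rae"
  param[ra] <- .draw(spec$rae_rho_distribution, sum(ra))
  penet[ra] <- .draw(spec$rae_penetrance_distribution, sum(ra))

  nx <- spec$xci_like$count
  if (nx > 0) {
    genes <- c(genes, sprintf("XCI%04d", seq_len(nx)))
    classes <- c(classes, rep("xci", nx))
    param <- c(param, .draw(spec$xci_like$rho, nx))
    penet <- c(penet, .draw(spec$xci_like$penetrance, nx))
  }
  ntot <- length(genes)
  tmax <- if (spec$tissue_count_distribution$type == "uniform_int")
    spec$tissue_count_distribution$max else 30L
  tissues <- sprintf("tissue%02d", seq_len(tmax))

  nind <- spec$n_individuals
  ind_ids <- sprintf("IND%03d", seq_len(nind))
  penetrant <- matrix(FALSE, ntot, nind, dimnames = list(genes, ind_ids))
  od <- classes %in% c("rae", "xci")
  tables <- vector("list", nind); names(tables) <- ind_ids

  for (j in seq_len(nind)) {
    # derived per-individual stream, kept below 2^31
    set.seed((spec$seed + 7919L * j) %% .Machine$integer.max)
    sex <- spec$sexes[j]
    penetrant[od, j] <- stats::runif(sum(od)) < penet[od]
    X <- matrix(NA_integer_, ntot, tmax, dimnames = list(genes, tissues))
    N <- X
    for (g in seq_len(ntot)) {
      if (classes[g] == "xci" && sex != "female") next
      k <- .draw(spec$tissue_count_distribution, 1)
      k <- min(k, tmax)
      cols <- sample.int(tmax, k)
      n <- .draw(spec$depth_distribution, k)
      x <- if (od[g] && penetrant[g, j]) {
        rho <- param[g]
        a <- 0.5 * (1 - rho) / rho
        stats::rbinom(k, n, stats::rbeta(k, a, a))
      } else {
        p <- if (od[g]) 0.5 else param[g]
        stats::rbinom(k, n, p)
      }
      N[g, cols] <- as.integer(n)
      X[g, cols] <- as.integer(x)
    }
    tables[[j]] <- allele_count_table(X, N, individual_id = ind_ids[j],
                                      sex = sex)
  }
  truth <- data.frame(gene_id = genes, class = classes, param = param,
                      penetrance = penet, stringsAsFactors = FALSE)
  list(tables = tables, truth = truth, penetrant = penetrant)
}

#' Simulate biallelic null counts matching an observed table
#'
#' For every observed (non-missing) cell, keeps the observed total `N` and
#' redraws the haplotype-A count from `Binomial(N, p)` with the biallelic
#' probability `p = 0.5`; the second haplotype gets `N - X`. With
#' `use_observed_p = TRUE`, each gene instead uses its own pooled observed
#' probability, giving a sharper per-gene null.
#'
#' @param observed a filtered `AlleleCountTable`.
#' @param seed integer seed; identical seeds give identical simulations.
#' @param use_observed_p use each gene's pooled p-hat instead of 0.5.
#' @return An `AlleleCountTable` with the same genes, tissues, `N`, and
#'   missingness as `observed` and simulated `X`.
#' @export
simulate_null_counts <- function(observed, seed = 1L,
                                 use_observed_p = FALSE) {
  stopifnot(inherits(observed, "AlleleCountTable"))
  set.seed(seed)
  X <- observed$X
  obs <- !observed$missing
  if (use_observed_p) {
    for (i in seq_len(nrow(X))) {
      o <- obs[i, ]
      if (!any(o)) next
      p <- sum(observed$X[i, o]) / max(1, sum(observed$N[i, o]))
      X[i, o] <- stats::rbinom(sum(o), observed$N[i, o], p)
    }
  } else {
    X[obs] <- stats::rbinom(sum(obs), observed$N[obs], 0.5)
  }
  out <- observed
  out$X <- X
  out
}

#' Empirical false-discovery estimate from biallelic null simulation
#'
#' For each individual (and replicate), simulates a biallelic null cohort
#' with [simulate_null_counts()], re-runs the per-individual test, and
#' records the fraction of genes falsely significant at each q-value
#' cutoff in `fdr_grid`, plus the raw `p < 0.05` fraction. If
#' `observed_calls` are supplied, the observed significant fraction is
#' reported for contrast.
#'
#' @param tables named list of filtered `AlleleCountTable`s.
#' @param n_reps simulated replicates per individual (default 1).
#' @param fdr_grid q-value cutoffs to evaluate (default 0.05 and 0.10).
#' @param seed integer seed.
#' @param observed_calls optional named list of [call_individual()] results
#'   for the observed data, reused for the contrast.
#' @return list of class `FdrEstimate`: `per_run` (data.frame of
#'   individual, rep, raw p<0.05 rate, one false-rate column per grid
#'   value), `mean`/`sd` per grid value, `raw_p05_mean`, `n_reps`,
#'   `observed_fraction` (NA when no observed calls given).
#' @export
estimate_fdr <- function(tables, n_reps = 1L, fdr_grid = c(0.05, 0.10),
                         seed = 1L, observed_calls = NULL) {
  stopifnot(n_reps >= 1, length(tables) >= 1)
  rows <- list()
  for (j in seq_along(tables)) {
    for (r in seq_len(n_reps)) {
      s <- (seed + 104729L * j + 7L * r) %% .Machine$integer.max
      sim <- simulate_null_counts(tables[[j]], seed = s)
      res <- call_individual(sim, fdr = max(fdr_grid))
      rates <- vapply(fdr_grid, function(q) mean(res$q_value < q), numeric(1))
      rows[[length(rows) + 1L]] <- c(individual = j, rep = r,
                                     raw_p05 = mean(res$p_value < 0.05),
                                     stats::setNames(rates,
                                                     paste0("q", fdr_grid)))
    }
  }
  per_run <- as.data.frame(do.call(rbind, rows))
  qcols <- paste0("q", fdr_grid)
  obs_frac <- NA_real_
  if (!is.null(observed_calls))
    obs_frac <- mean(vapply(observed_calls,
                            function(x) mean(x$significant), numeric(1)))
  structure(list(per_run = per_run,
                 mean = colMeans(per_run[qcols]),
                 sd = vapply(per_run[qcols], stats::sd, numeric(1)),
                 raw_p05_mean = mean(per_run$raw_p05),
                 n_reps = n_reps,
                 observed_fraction = obs_frac),
            class = "FdrEstimate")
}

#' @export
print.FdrEstimate <- function(x, ...) {
  cat("Biallelic null simulation FDR estimate (", nrow(x$per_run),
      " runs):\n", sep = "")
  for (nm in names(x$mean))
    cat(sprintf("  false significant fraction at %s: %.4f (SD %.4f)\n",
                sub("^q", "q < ", nm), x$mean[[nm]], x$sd[[nm]]))
  cat(sprintf("  raw p < 0.05 fraction: %.4f\n", x$raw_p05_mean))
  if (!is.na(x$observed_fraction))
    cat(sprintf("  observed significant fraction: %.4f\n",
                x$observed_fraction))
  invisible(x)
}
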