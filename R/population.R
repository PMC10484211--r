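#' Aggregate per-individual calls into population summaries
#'
#' For each gene, counts the individuals in which it was tested (present
#' in that individual's result table) and those in which it was flagged
#' significant, and computes the population frequency of significant RAE,
#' `f = n_significant / n_tested`. Genes tested in fewer than
#' `min_individuals` people are labeled `Untested`.
#'
#' @param calls named list of per-individual result data.frames from
#'   [call_individual()]; names are individual IDs and must be unique.
#' @param min_individuals minimum number of tested individuals for a gene
#'   to be classifiable (default 10).
#' @return data.frame with columns `gene_id`, `n_tested`, `n_significant`,
#'   `frequency`, `z` (NA until [z_scores()]), `class_label`.
#' @export
summarize_population <- function(calls, min_individuals = 10L) {
  stopifnot(length(calls) >= 1)
  ids <- names(calls)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(calls, function(x) {
      id <- attr(x, "individual_id"); if (is.null(id)) NA_character_ else id
    }, character(1))
  if (anyDuplicated(ids)) stop("duplicate individual IDs in calls")
  gene <- unlist(lapply(calls, `[[`, "gene_id"), use.names = FALSE)
  sig <- unlist(lapply(calls, `[[`, "significant"), use.names = FALSE)
  n_tested <- table(gene)
  n_sig <- tapply(sig, gene, sum)[names(n_tested)]
  out <- data.frame(gene_id = names(n_tested),
                    n_tested = as.integer(n_tested),
                    n_significant = as.integer(n_sig),
                    frequency = as.numeric(n_sig) / as.numeric(n_tested),
                    z = NA_real_,
                    class_label = ifelse(as.integer(n_tested) < min_individuals,
                                         "Untested", "NotCategorized"),
                    stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Standardize population frequencies into Z scores
#'
#' Each gene's frequency is standardized against the mean and population
#' (divide-by-n) standard deviation of the frequency distribution over
#' `combined_set` — the autosomal genes and XCI positive controls taken
#' together. Genes outside the combined set still receive a Z on the same
#' scale, so a gene with above-average RAE frequency has `z > 0`.
#'
#' @param summaries data.frame from [summarize_population()].
#' @param combined_set gene IDs defining the standardization set; defaults
#'   to all classifiable (non-`Untested`) genes.
#' @return `summaries` with the `z` column filled.
#' @export
z_scores <- function(summaries, combined_set = NULL) {
  use <- summaries$class_label != "Untested"
  if (!is.null(combined_set)) use <- use & summaries$gene_id %in% combined_set
  f <- summaries$frequency[use]
  if (length(f) < 2) stop("need >= 2 genes to standardize")
  m <- mean(f)
  s <- sqrt(mean((f - m)^2))   # population SD
  if (s == 0) stop("degenerate frequency distribution: zero variance")
  summaries$z <- (summaries$frequency - m) / s
  summaries$z[summaries$class_label == "Untested"] <- NA_real_
  summaries
}

#' Derive the RAE Z-score threshold from positive and negative controls
#'
#' Scans candidate thresholds (every observed Z among the controls) and,
#' at each z, computes sensitivity (fraction of XCI positives with
#' `Z >= z`) and specificity (fraction of autosomal negatives with
#' `Z < z`). The empirical RAE threshold is where the two curves converge:
#' the z minimizing `|sensitivity - specificity|`, taking the smallest z on
#' ties so the RAE class is maximal at equal separability. The biallelic
#' threshold is fixed at `z = 0`.
#'
#' @param summaries data.frame with `z` filled (see [z_scores()]).
#' @param positives gene IDs of the positive-control stratum (XCI genes).
#' @param negatives gene IDs of presumed true negatives (autosomal genes).
#' @return list of class `ThresholdResult`: `z_rae`, `z_biallelic` (0),
#'   `sensitivity`, `specificity` at `z_rae`, and a `curve` data.frame of
#'   (z, sensitivity, specificity).
#' @export
derive_threshold <- function(summaries, positives, negatives) {
  zp <- summaries$z[summaries$gene_id %in% positives & !is.na(summaries$z)]
  zn <- summaries$z[summaries$gene_id %in% negatives & !is.na(summaries$z)]
  if (length(zp) == 0 || length(zn) == 0)
    stop("both positive and negative control sets must be non-empty and scored")
  grid <- sort(unique(c(zp, zn)))
  sens <- vapply(grid, function(z) mean(zp >= z), numeric(1))
  spec <- vapply(grid, function(z) mean(zn < z), numeric(1))
  gap <- abs(sens - spec)
  i <- which(gap == min(gap))[1L]   # smallest z on ties
  if (sens[i] + spec[i] < 1.2)
    warning("positive and negative Z distributions barely separable; ",
            "threshold may not be meaningful")
  structure(list(z_rae = grid[i], z_biallelic = 0,
                 sensitivity = sens[i], specificity = spec[i],
                 curve = data.frame(z = grid, sensitivity = sens,
                                    specificity = spec)),
            class = "ThresholdResult")
}

#' @export
print.ThresholdResult <- function(x, ...) {
  cat(sprintf("RAE threshold Z >= %.4g (sensitivity %.3f, specificity %.3f); biallelic Z <= %g\n",
              x$z_rae, x$sensitivity, x$specificity, x$z_biallelic))
  invisible(x)
}

#' Classify genes by population Z score
#'
#' RAE if `Z >= z_rae`; biallelic if `Z <= 0` (boundary inclusive by
#' default; set `biallelic_inclusive = FALSE` for strict `Z < 0`);
#' otherwise `NotCategorized`. `Untested` genes keep their label.
#'
#' @param summaries data.frame with `z` filled.
#' @param thresholds a `ThresholdResult` from [derive_threshold()], or a
#'   numeric RAE threshold.
#' @param biallelic_inclusive include `Z == 0` in the biallelic class.
#' @return `summaries` with `class_label` set.
#' @export
classify_genes <- function(summaries, thresholds,
                           biallelic_inclusive = TRUE) {
  z_rae <- if (inherits(thresholds, "ThresholdResult")) thresholds$z_rae
           else as.numeric(thresholds)
  tested <- summaries$class_label != "Untested"
  z <- summaries$z
  lab <- summaries$class_label
  bi <- if (biallelic_inclusive) z <= 0 else z < 0
  lab[tested] <- ifelse(z[tested] >= z_rae, "RAE",
                        ifelse(bi[tested], "Biallelic", "NotCategorized"))
  summaries$class_label <- lab
  summaries
}

#' High-confidence catalogs by male/female replication
#'
#' A gene is high-confidence RAE (hc-RAE) if classified RAE in both the
#' female and the male cohort, and hc-Biallelic if classified biallelic in
#' both. Genes tested in only one sex cannot replicate and are excluded.
#' A chi-squared test of class agreement over the common classified genes
#' quantifies reproducibility between the sexes.
#'
#' @param female_classes,male_classes classified summaries (one per sex)
#'   from [classify_genes()], produced with the same threshold.
#' @return list: `hc_rae`, `hc_biallelic` (character vectors),
#'   `agreement_table` (female x male class contingency), `chisq_p`.
#' @export
replicate_hc <- function(female_classes, male_classes) {
  fe <- female_classes[female_classes$class_label != "Untested", ]
  ma <- male_classes[male_classes$class_label != "Untested", ]
  common <- intersect(fe$gene_id, ma$gene_id)
  if (length(common) == 0) stop("no genes tested in both sexes")
  fl <- fe$class_label[match(common, fe$gene_id)]
  ml <- ma$class_label[match(common, ma$gene_id)]
  tab <- table(female = fl, male = ml)
  p <- if (nrow(tab) > 1 && ncol(tab) > 1)
    suppressWarnings(stats::chisq.test(tab)$p.value) else NA_real_
  list(hc_rae = sort(common[fl == "RAE" & ml == "RAE"]),
       hc_biallelic = sort(common[fl == "Biallelic" & ml == "Biallelic"]),
       agreement_table = tab, chisq_p = p)
}

#' Technical-factor regression QC
#'
#' Ordinary least-squares simple regression of per-gene scores (q-values
#' at the individual level, Z scores at the population level) on a
#' candidate technical factor; the fit R-squared measures how much of the
#' score variance the factor explains.
#'
#' @param gene_scores numeric response vector.
#' @param factor numeric explanatory vector, same length, `>= 3` finite
#'   points, non-constant.
#' @return list with `r_squared` and `p` (slope p-value).
#' @export
factor_regression <- function(gene_scores, factor) {
  stopifnot(length(gene_scores) == length(factor), length(factor) >= 3,
            all(is.finite(gene_scores)), all(is.finite(factor)))
  if (stats::var(factor) == 0) stop("zero-variance factor")
  fit <- stats::lm(gene_scores ~ factor)
  s <- summary(fit)
  list(r_squared = s$r.squared,
       p = unname(s$coefficients["factor", "Pr(>|t|)"]))
}
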