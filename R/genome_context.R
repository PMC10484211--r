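# intervals are 0-based half-open data.frames (chrom/start/end/strand/id);
# IRanges is 1-based closed, so [start, end) maps to IRanges(start+1, end)
.as_iranges <- function(intervals) {
  IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
}

#' Map genes to overlapping domains
#'
#' A gene is assigned to every domain it overlaps by at least 1 bp on the
#' same chromosome (so a gene spanning two adjacent domains counts in
#' both); genes overlapping no domain are unmapped. Coordinates are
#' 0-based half-open, so abutting intervals do not overlap.
#'
#' @param genes,domains interval data.frames (see [read_intervals()]).
#' @param largest_only assign each gene only to the domain with the
#'   largest overlap (default `FALSE`, matching intersect semantics).
#' @return data.frame with columns `gene_id`, `domain_id`.
#' @export
assign_genes_to_domains <- function(genes, domains, largest_only = FALSE) {
  out <- list()
  for (chr in unique(genes$chrom)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    d <- domains[domains$chrom == chr, , drop = FALSE]
    if (nrow(d) == 0) next
    hits <- IRanges::findOverlaps(.as_iranges(g), .as_iranges(d),
                                  minoverlap = 1L)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    if (largest_only && anyDuplicated(qi)) {
      ow <- IRanges::width(IRanges::pintersect(
        .as_iranges(g)[qi], .as_iranges(d)[si]))
      keep <- unlist(lapply(split(seq_along(qi), qi),
                            function(ix) ix[which.max(ow[ix])]))
      qi <- qi[keep]; si <- si[keep]
    }
    out[[chr]] <- data.frame(gene_id = g$id[qi], domain_id = d$id[si],
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(), domain_id = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# 2x2 Pearson chi-squared machinery shared by the enrichment operations
.chisq2x2 <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    empty <- c(rownames(tab)[rowSums(tab) == 0],
               colnames(tab)[colSums(tab) == 0])
    stop("zero margin in contingency table for category: ",
         paste(empty, collapse = ", "))
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E < 5))
    warning("expected count < 5 in a cell; an exact test may be preferable")
  chi2 <- sum((tab - E)^2 / E)
  list(chi2 = chi2,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       residuals = (tab - E) / sqrt(E),
       odds_ratio = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
}

#' Per-domain enrichment of RAE vs biallelic genes
#'
#' For every domain with at least one classified gene, forms the 2x2 table
#' of (inside vs outside the domain) x (RAE vs Biallelic), computes the
#' odds ratio and Pearson chi-squared p-value (no continuity correction),
#' adjusts p-values across domains with Benjamini-Hochberg, and flags
#' domains with `q < fdr` and `OR >= min_or`. Significant domains are
#' merged by interval union per chromosome. Labels are expected to already
#' exclude X-linked, imprinted, and HLA genes.
#'
#' @param mapping gene-to-domain data.frame from
#'   [assign_genes_to_domains()].
#' @param labels named character vector: gene_id -> `"RAE"`/`"Biallelic"`.
#' @param domains interval data.frame of the domains (used for merging).
#' @param fdr BH q-value cutoff (default 0.10).
#' @param min_or minimum odds ratio for a significant call (default 1.5).
#' @return list: `results` (per-domain data.frame with counts, OR, p, q,
#'   significance), `merged` (interval data.frame of unioned significant
#'   domains), `skipped` (domain IDs with no classified genes).
#' @export
domain_enrichment <- function(mapping, labels, domains,
                              fdr = 0.10, min_or = 1.5) {
  labels <- labels[labels %in% c("RAE", "Biallelic")]
  n_rae <- sum(labels == "RAE"); n_bi <- sum(labels == "Biallelic")
  if (n_rae == 0 || n_bi == 0)
    stop("need at least one RAE and one Biallelic gene")
  mapping <- mapping[mapping$gene_id %in% names(labels), , drop = FALSE]
  dom_ids <- unique(domains$id)
  skipped <- setdiff(dom_ids, unique(mapping$domain_id))
  rows <- list()
  for (d in setdiff(dom_ids, skipped)) {
    inside <- unique(mapping$gene_id[mapping$domain_id == d])
    in_rae <- sum(labels[inside] == "RAE")
    in_bi <- sum(labels[inside] == "Biallelic")
    tab <- matrix(c(in_rae, in_bi, n_rae - in_rae, n_bi - in_bi), 2, 2,
                  dimnames = list(c("RAE", "Biallelic"),
                                  c("inside", "outside")))
    ct <- suppressWarnings(.chisq2x2(t(tab)))
    rows[[d]] <- data.frame(domain_id = d, rae_in = in_rae, bi_in = in_bi,
                            rae_out = n_rae - in_rae, bi_out = n_bi - in_bi,
                            odds_ratio = ct$odds_ratio, p_value = ct$p,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value < fdr & res$odds_ratio >= min_or
  sig <- domains[domains$id %in% res$domain_id[res$significant], ,
                 drop = FALSE]
  merged <- .merge_intervals(sig)
  list(results = res, merged = merged, skipped = skipped)
}

.merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      id = character(), stringsAsFactors = FALSE))
  out <- list()
  for (chr in sort(unique(intervals$chrom))) {
    x <- intervals[intervals$chrom == chr, , drop = FALSE]
    red <- IRanges::reduce(.as_iranges(x))
    out[[chr]] <- data.frame(chrom = chr,
                             start = IRanges::start(red) - 1L,
                             end = IRanges::end(red), strand = ".",
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$id <- sprintf("%s:%d-%d", res$chrom, res$start, res$end)
  rownames(res) <- NULL
  res
}

#' Flag sense-antisense and same-strand gene overlaps
#'
#' For every stranded gene, reports whether it overlaps (by >= 1 bp,
#' half-open coordinates, self excluded) any other gene on the opposite
#' strand and any on the same strand. Genes with strand `"."` are excluded
#' with a warning.
#'
#' @param genes interval data.frame with known strands.
#' @return data.frame: `gene_id`, `opposite_overlap`, `same_overlap`.
#' @export
strand_overlap_flags <- function(genes) {
  unk <- genes$strand == "."
  if (any(unk)) {
    warning(sum(unk), " gene(s) with unknown strand excluded")
    genes <- genes[!unk, , drop = FALSE]
  }
  n <- nrow(genes)
  opp <- logical(n); same <- logical(n)
  for (chr in unique(genes$chrom)) {
    ix <- which(genes$chrom == chr)
    g <- genes[ix, , drop = FALSE]
    hits <- IRanges::findOverlaps(.as_iranges(g), minoverlap = 1L,
                                  drop.self = TRUE)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    sme <- g$strand[qi] == g$strand[si]
    opp[ix] <- tabulate(qi[!sme], length(ix)) > 0
    same[ix] <- tabulate(qi[sme], length(ix)) > 0
  }
  data.frame(gene_id = genes$id, opposite_overlap = opp,
             same_overlap = same, stringsAsFactors = FALSE)
}

#' 2x2 enrichment of a boolean gene feature in RAE vs biallelic genes
#'
#' Pearson chi-squared test of independence (no continuity correction)
#' between class label and feature flag, with Pearson residuals
#' `(O - E) / sqrt(E)` giving the signed direction and magnitude of each
#' cell's enrichment or depletion.
#'
#' @param flags named logical vector: gene_id -> feature present.
#' @param labels named character vector: gene_id -> `"RAE"`/`"Biallelic"`.
#' @return list of class `EnrichmentResult`: `table`, `chi2`, `p_value`,
#'   `odds_ratio`, `pearson_residuals`.
#' @export
contingency_enrichment <- function(flags, labels) {
  common <- intersect(names(flags), names(labels))
  labels <- labels[common]; flags <- flags[common]
  keep <- labels %in% c("RAE", "Biallelic")
  labels <- labels[keep]; flags <- flags[keep]
  tab <- table(class = factor(labels, c("RAE", "Biallelic")),
               flag = factor(flags, c(TRUE, FALSE)))
  ct <- .chisq2x2(unclass(tab))
  structure(list(table = tab, chi2 = ct$chi2, p_value = ct$p,
                 odds_ratio = ct$odds_ratio,
                 pearson_residuals = ct$residuals),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("2x2 enrichment: chi2 = %.4g, p = %.3g, OR = %.3g\n",
              x$chi2, x$p_value, x$odds_ratio))
  print(x$table)
  invisible(x)
}

#' Split genes at the genome-wide median of a per-bp density
#'
#' Genes below the median are "low", above are "high"; genes exactly at
#' the median fold into "low" (the split is defined by strict
#' inequalities, so ties are otherwise unassigned). Densities should be
#' length-normalized (count / gene length) by the caller.
#'
#' @param values named numeric vector: gene_id -> per-bp density.
#' @return named character vector of `"high"`/`"low"`.
#' @export
density_split <- function(values) {
  stopifnot(length(values) >= 2)
  if (length(unique(values)) == 1)
    stop("all densities identical: no split possible")
  med <- stats::median(values)
  out <- ifelse(values > med, "high", "low")
  names(out) <- names(values)
  out
}

#' Regulatory complexity score
#'
#' Summarizes per-gene regulatory input metrics (typically: number of
#' intragenic chromatin-state kinds, per-bp chromatin-state density, mean
#' promoter-contact count per tissue, and enhancer count) into one score:
#' each metric column is converted to a percentile rank across genes
#' (average rank on ties, scaled to \[0, 1\]), and the score is the median
#' of the per-metric percentiles. Rank-based, so any strictly monotone
#' transform of a metric leaves scores unchanged. Genes with a missing
#' metric are excluded.
#'
#' @param metrics numeric matrix or data.frame, genes in rows (rownames =
#'   gene IDs), metrics in columns.
#' @return named numeric vector of scores in \[0, 1\].
#' @export
regulatory_complexity <- function(metrics) {
  m <- as.matrix(metrics)
  stopifnot(nrow(m) >= 2)
  complete <- stats::complete.cases(m)
  if (!all(complete)) {
    message(sum(!complete), " gene(s) with missing metrics excluded")
    m <- m[complete, , drop = FALSE]
  }
  n <- nrow(m)
  pct <- apply(m, 2, function(col) (rank(col, ties.method = "average") - 1) /
                                   (n - 1))
  scores <- apply(pct, 1, stats::median)
  names(scores) <- rownames(m)
  scores
}

#' Compare chromosome-arm positioning of two domain sets
#'
#' Positions each domain by its midpoint's normalized distance to the
#' nearest chromosome end, `min(mid, size - mid) / size` in \[0, 0.5\]
#' (0 = telomere-proximal, 0.5 = chromosome center), and compares the two
#' sets with a Kruskal-Wallis rank test.
#'
#' @param domains_a,domains_b interval data.frames.
#' @param chrom_sizes named numeric vector: chromosome -> length in bp.
#' @return list: `positions_a`, `positions_b`, `p_value`.
#' @export
arm_position_compare <- function(domains_a, domains_b, chrom_sizes) {
  pos <- function(d) {
    if (!all(d$chrom %in% names(chrom_sizes)))
      stop("chromosome(s) missing from chrom_sizes: ",
           paste(setdiff(d$chrom, names(chrom_sizes)), collapse = ", "))
    size <- chrom_sizes[d$chrom]
    if (any(d$end > size)) stop("domain extends past chromosome end")
    mid <- (d$start + d$end) / 2
    unname(pmin(mid, size - mid) / size)
  }
  a <- pos(domains_a); b <- pos(domains_b)
  kt <- stats::kruskal.test(list(a, b))
  list(positions_a = a, positions_b = b, p_value = kt$p.value)
}
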