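test_that("gene-domain assignment uses >= 1 bp overlap, half-open", {
  genes <- genomic_intervals("chr1", c(100, 100, 300), c(200, 150, 500),
                             id = c("gA", "gB", "gC"))
  domains <- genomic_intervals("chr1", c(150, 450), c(400, 600),
                               id = c("d1", "d2"))
  m <- assign_genes_to_domains(genes, domains)
  expect_true(any(m$gene_id == "gA" & m$domain_id == "d1"))
  expect_false("gB" %in% m$gene_id)              # [100,150) abuts [150,400)
  # gC spans both domains and is counted in each
  expect_setequal(m$domain_id[m$gene_id == "gC"], c("d1", "d2"))
  m1 <- assign_genes_to_domains(genes, domains, largest_only = TRUE)
  expect_identical(m1$domain_id[m1$gene_id == "gC"], "d1")  # 100 bp vs 50 bp
})

test_that("domain_enrichment flags the planted domain and merges intervals", {
  # 1000 classified genes; planted domain holds 8 RAE + 2 biallelic
  labels <- c(rep("RAE", 100), rep("Biallelic", 900))
  names(labels) <- paste0("g", 1:1000)
  genes <- genomic_intervals("chr1", seq(0, by = 1000, length.out = 1000),
                             seq(900, by = 1000, length.out = 1000),
                             id = paste0("g", sample(1:1000)))
  inside <- c(paste0("g", 1:8), paste0("g", 101:102))
  background <- setdiff(names(labels), inside)
  mapping <- rbind(
    data.frame(gene_id = inside, domain_id = "planted"),
    data.frame(gene_id = background[1:100], domain_id = "balanced"))
  # a balanced domain mirroring the 92/898 background ratio: 10 RAE, 98 Bi
  mapping$domain_id[mapping$gene_id %in% paste0("g", 9:18)] <- "balanced"
  mapping <- rbind(mapping[mapping$domain_id == "planted", ],
                   data.frame(gene_id = c(paste0("g", 9:18),
                                          paste0("g", 103:200)),
                              domain_id = "balanced"))
  domains <- genomic_intervals("chr1", c(0, 50, 5000), c(100, 150, 6000),
                               id = c("planted", "overlap2", "balanced"))
  enr <- domain_enrichment(mapping, labels, domains, fdr = 0.10,
                           min_or = 1.5)
  res <- enr$results
  planted <- res[res$domain_id == "planted", ]
  expect_equal(planted$odds_ratio, (8 * 898) / (2 * 92), tolerance = 1e-9)
  expect_true(planted$significant)
  bal <- res[res$domain_id == "balanced", ]
  expect_lt(abs(bal$odds_ratio - 1), 0.2)
  expect_false(bal$significant)
  expect_true("overlap2" %in% enr$skipped)
  # merged union of overlapping significant domains
  doms2 <- genomic_intervals("chr1", c(0, 50), c(100, 150),
                             id = c("planted", "p2"))
  map2 <- rbind(mapping[mapping$domain_id == "planted", ],
                transform(mapping[mapping$domain_id == "planted", ],
                          domain_id = "p2"))
  enr2 <- domain_enrichment(map2, labels, doms2)
  expect_true(all(enr2$results$significant))
  expect_identical(enr2$merged$start, 0L)
  expect_identical(enr2$merged$end, 150L)
})

test_that("strand overlap flags distinguish opposite and same strand", {
  genes <- genomic_intervals("chr1",
                             c(100, 150, 300, 400, 600),
                             c(200, 250, 380, 500, 700),
                             strand = c("+", "-", "+", "+", "."),
                             id = c("gA", "gB", "gC", "gD", "gE"))
  # gA(+) overlaps gB(-); gC(+)[300,380) does NOT touch gD(+)[400,500)
  expect_warning(fl <- strand_overlap_flags(genes), "unknown strand")
  expect_false("gE" %in% fl$gene_id)
  expect_true(fl$opposite_overlap[fl$gene_id == "gA"])
  expect_false(fl$same_overlap[fl$gene_id == "gA"])
  expect_true(fl$opposite_overlap[fl$gene_id == "gB"])
  expect_false(fl$opposite_overlap[fl$gene_id == "gC"])
  # same-strand abutting at the half-open boundary does not overlap
  genes2 <- genomic_intervals("chr1", c(100, 200), c(200, 300),
                              strand = c("+", "-"), id = c("a", "b"))
  fl2 <- strand_overlap_flags(genes2)
  expect_false(any(fl2$opposite_overlap))
  # same-strand case
  genes3 <- genomic_intervals("chr1", c(100, 150), c(200, 250),
                              strand = c("+", "+"), id = c("a", "b"))
  fl3 <- strand_overlap_flags(genes3)
  expect_true(all(fl3$same_overlap))
  expect_false(any(fl3$opposite_overlap))
})

test_that("contingency_enrichment matches the hand chi-squared oracle", {
  labels <- c(rep("RAE", 50), rep("Biallelic", 50))
  names(labels) <- paste0("g", 1:100)
  flags <- rep(c(TRUE, FALSE), 50)
  names(flags) <- names(labels)
  bal <- contingency_enrichment(flags, labels)
  expect_equal(bal$chi2, 0)
  expect_true(all(abs(bal$pearson_residuals) < 1e-9))

  flags2 <- c(rep(TRUE, 30), rep(FALSE, 20), rep(TRUE, 10), rep(FALSE, 40))
  names(flags2) <- names(labels)
  enr <- contingency_enrichment(flags2, labels)
  tab <- matrix(c(30, 20, 10, 40), 2, byrow = TRUE)
  expect_equal(enr$chi2, oracle_chisq(tab), tolerance = 1e-12)
  # residual signs: positive iff observed > expected
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_identical(as.vector(sign(unclass(enr$pearson_residuals))),
                   as.vector(sign(tab - E)))
  # zero margin errors with the category named
  expect_error(contingency_enrichment(
    stats::setNames(rep(TRUE, 100), names(labels)), labels), "zero margin")
})

test_that("OR and residuals are invariant under simultaneous row+column swap", {
  labels <- stats::setNames(c(rep("RAE", 40), rep("Biallelic", 60)),
                            paste0("g", 1:100))
  set.seed(41)
  flags <- stats::setNames(runif(100) < 0.4, names(labels))
  a <- contingency_enrichment(flags, labels)
  swapped <- unclass(a$table)[2:1, 2:1]
  E <- outer(rowSums(swapped), colSums(swapped)) / sum(swapped)
  or_swapped <- swapped[1, 1] * swapped[2, 2] / (swapped[1, 2] * swapped[2, 1])
  expect_equal(a$odds_ratio, or_swapped)
  expect_equal(unclass(a$pearson_residuals)[1, 1],
               ((swapped - E) / sqrt(E))[2, 2])
})

test_that("density_split folds exact-median ties into low", {
  v <- c(a = 1, b = 2, c = 3, d = 4)
  s <- density_split(v)
  expect_identical(s, c(a = "low", b = "low", c = "high", d = "high"))
  v2 <- c(a = 1, b = 2, c = 3)      # odd n: b sits at the median
  expect_identical(density_split(v2)[["b"]], "low")
  expect_error(density_split(c(a = 2, b = 2)), "identical")
})

test_that("regulatory_complexity is a median of percentile ranks", {
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(10, 20, 30, 40, 50),
             c = c(5, 4, 3, 2, 1), d = c(2, 4, 6, 8, 10))
  rownames(m) <- paste0("g", 1:5)
  sc <- regulatory_complexity(m)
  expect_equal(unname(sc["g3"]), 0.5)    # median gene in every metric
  m2 <- m; m2[, 3] <- m[, 1]             # maximal gene in all four metrics
  expect_equal(unname(regulatory_complexity(m2)["g5"]), 1)
  # invariance to strictly monotone transforms
  m3 <- m; m3[, 1] <- exp(m[, 1]); m3[, 2] <- log(m[, 2])
  expect_equal(regulatory_complexity(m3), sc)
  # permuting gene order leaves scores unchanged
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(regulatory_complexity(m[perm, ])[rownames(m)], sc)
  # a gene with missing metrics is excluded
  m4 <- m; m4[2, 2] <- NA
  expect_message(sc4 <- regulatory_complexity(m4), "excluded")
  expect_false("g2" %in% names(sc4))
})

test_that("arm positions are normalized end distances; rank test separates", {
  sizes <- c(chr1 = 1000)
  d0 <- genomic_intervals("chr1", 0, 2, id = "t")       # midpoint ~ 0
  dc <- genomic_intervals("chr1", 499, 501, id = "c")   # exact center
  r <- arm_position_compare(d0, dc, sizes)
  expect_equal(r$positions_a, 0.001)
  expect_equal(r$positions_b, 0.5)
  set.seed(42)
  telo <- genomic_intervals("chr1", sample(0:50, 20, TRUE),
                            sample(60:100, 20, TRUE) + 50, id = paste0("t", 1:20))
  cent <- genomic_intervals("chr1", sample(400:450, 20, TRUE),
                            sample(460:500, 20, TRUE) + 50, id = paste0("c", 1:20))
  r2 <- arm_position_compare(telo, cent, sizes)
  expect_lt(r2$p_value, 0.01)
  bad <- genomic_intervals("chr1", 900, 1100, id = "x")
  expect_error(arm_position_compare(bad, cent, sizes), "past chromosome end")
  expect_error(arm_position_compare(genomic_intervals("chrZ", 1, 5, id = "z"),
                                    cent, sizes), "missing from chrom_sizes")
})
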