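#' Construct an allele-count table
#'
#' An `AlleleCountTable` holds one individual's haplotype-phased allele
#' counts as two gene x tissue integer matrices: `X` (haplotype-A reads) and
#' `N` (total phased reads), plus a logical `missing` mask. Because counts
#' are genome-wide phased, haplotype A refers to the same parental
#' chromosome in every gene and tissue of the individual.
#'
#' Missingness is a mask, not a sentinel: an observed `0|0` cell carries
#' X = 0, N = 0 and is *not* missing (the depth filter removes it later),
#' whereas an empty/NA cell in the source file is missing.
#'
#' @param X integer matrix of haplotype-A counts (genes x tissues).
#' @param N integer matrix of total phased counts, same shape as `X`.
#' @param individual_id character scalar identifying the subject.
#' @param sex one of `"female"`, `"male"`, `"unknown"`. Carried on the
#'   table because the high-confidence catalog step replicates calls across
#'   male and female cohorts.
#' @param missing optional logical matrix marking absent cells; defaults to
#'   cells where `N` is `NA`.
#' @return An object of class `AlleleCountTable`: a list with elements
#'   `individual_id`, `sex`, `genes`, `tissues`, `X`, `N`, `missing`.
#' @export
allele_count_table <- function(X, N, individual_id = "unknown",
                               sex = c("unknown", "female", "male"),
                               missing = NULL) {
  sex <- match.arg(sex)
  X <- as.matrix(X); N <- as.matrix(N)
  if (!identical(dim(X), dim(N)))
    stop("X and N must have identical dimensions")
  if (is.null(rownames(X))) rownames(X) <- paste0("gene", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("tissue", seq_len(ncol(X)))
  if (anyDuplicated(rownames(X)))
    stop("duplicate gene IDs in allele-count table")
  if (is.null(missing)) missing <- is.na(N)
  missing <- missing | is.na(N) | is.na(X)
  obs <- !missing
  if (any(obs & (X < 0 | N < 0), na.rm = TRUE))
    stop("negative counts in allele-count table")
  if (any(obs & (X > N), na.rm = TRUE))
    stop("X exceeds N in allele-count table")
  if (any(obs & (X != floor(X) | N != floor(N)), na.rm = TRUE))
    stop("non-integer counts in allele-count table")
  dimnames(N) <- dimnames(X); dimnames(missing) <- dimnames(X)
  structure(list(individual_id = individual_id, sex = sex,
                 genes = rownames(X), tissues = colnames(X),
                 X = X, N = N, missing = missing),
            class = "AlleleCountTable")
}

#' @export
print.AlleleCountTable <- function(x, ...) {
  cat(sprintf("AlleleCountTable: individual %s (%s), %d genes x %d tissues, %d observed cells\n",
              x$individual_id, x$sex, length(x$genes), length(x$tissues),
              sum(!x$missing)))
  invisible(x)
}

#' @export
dim.AlleleCountTable <- function(x) dim(x$X)

#' Read a phased gene x tissue allele-count matrix
#'
#' Reads the phASER-style gene-level dialect: a tab-separated file whose
#' header row lists tissue labels, whose first column holds gene IDs, and
#' whose data cells are `"a|b"` pairs of non-negative integers
#' (HAP_A_COUNT|HAP_B_COUNT). Empty cells and NA tokens are marked missing.
#'
#' @param path path to the TSV file.
#' @param individual_id subject identifier stored on the table.
#' @param sex subject sex (`"female"`, `"male"`, `"unknown"`).
#' @return An [allele_count_table()] with X = haplotype-A count and
#'   N = a + b per cell.
#' @export
read_phased_matrix <- function(path, individual_id = "unknown",
                               sex = c("unknown", "female", "male")) {
  sex <- match.arg(sex)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  tissues <- header[-1L]
  ncol_expect <- length(header)
  body <- fields[-1L]
  if (length(body) == 0L) stop("no gene rows in ", path)
  nf <- lengths(body)
  if (any(nf != ncol_expect))
    stop(sprintf("ragged rows in %s: row(s) %s have field counts %s, expected %d",
                 path,
                 paste(which(nf != ncol_expect) + 1L, collapse = ","),
                 paste(unique(nf[nf != ncol_expect]), collapse = ","),
                 ncol_expect))
  genes <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene ID(s) in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  ng <- length(genes); nt <- length(tissues)
  X <- matrix(NA_integer_, ng, nt, dimnames = list(genes, tissues))
  N <- X
  na_tokens <- c("", "NA", "na", "NaN", ".")
  cellmat <- do.call(rbind, lapply(body, function(f) f[-1L]))
  cells <- as.vector(cellmat)
  is_na <- cells %in% na_tokens
  parts <- strsplit(cells[!is_na], "|", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  a <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1L)))
  b <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2L)))
  nonint <- vapply(parts, function(p)
    any(!grepl("^[0-9]+$", p)), logical(1))
  bad <- sort(unique(c(bad, which(is.na(a) | is.na(b) | nonint))))
  if (length(bad)) {
    idx <- which(!is_na)[bad[1L]]
    row <- ((idx - 1L) %% ng) + 1L
    col <- ((idx - 1L) %/% ng) + 1L
    stop(sprintf("malformed count cell '%s' at gene '%s', tissue '%s' in %s",
                 cells[idx], genes[row], tissues[col], path))
  }
  Xv <- rep(NA_integer_, length(cells)); Nv <- Xv
  Xv[!is_na] <- a
  Nv[!is_na] <- a + b
  X[] <- Xv; N[] <- Nv
  allele_count_table(X, N, individual_id = individual_id, sex = sex)
}

#' Write an allele-count table in the phased-matrix dialect
#'
#' Inverse of [read_phased_matrix()]: cells are written as `"a|b"` with
#' `a = X` and `b = N - X`; missing cells are written as `NA`.
#'
#' @param table an `AlleleCountTable`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phased_matrix <- function(table, path) {
  stopifnot(inherits(table, "AlleleCountTable"))
  cells <- matrix(NA_character_, nrow(table$X), ncol(table$X))
  obs <- !table$missing
  cells[obs] <- paste0(table$X[obs], "|", table$N[obs] - table$X[obs])
  cells[!obs] <- "NA"
  out <- cbind(gene_id = table$genes, cells)
  colnames(out) <- c("gene_id", table$tissues)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundle gene sets used for exclusion and calibration
#'
#' @param xci_controls IDs of X-inactivated positive-control genes.
#' @param imprinted IDs of known imprinted genes.
#' @param hla IDs of HLA-locus genes.
#' @param excluded_loci IDs flagged for mapping bias / low mappability;
#'   removed at the filtering step.
#' @return A list of class `GeneSets`. Membership tests are exact,
#'   case-sensitive matches.
#' @export
gene_sets <- function(xci_controls = character(), imprinted = character(),
                      hla = character(), excluded_loci = character()) {
  structure(list(xci_controls = unique(as.character(xci_controls)),
                 imprinted = unique(as.character(imprinted)),
                 hla = unique(as.character(hla)),
                 excluded_loci = unique(as.character(excluded_loci))),
            class = "GeneSets")
}

#' Read a plain-text gene ID list (one ID per line)
#' @param path file path; blank lines and `#` comment lines are skipped.
#' @return character vector of IDs.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Filter an allele-count table for depth, tissue support, and flagged loci
#'
#' Applies the pre-test filters: cells with total phased depth below
#' `min_depth` become missing; genes observed in fewer than `min_tissues`
#' surviving tissues are dropped; genes in `excluded$excluded_loci` are
#' dropped. The attrition at each step is recorded in the `filter_log`
#' attribute. The operation is idempotent.
#'
#' @param table an `AlleleCountTable`.
#' @param min_depth minimum total reads per cell (default 10).
#' @param min_tissues minimum surviving tissues per gene (default 3).
#' @param excluded optional [gene_sets()] whose `excluded_loci` are removed.
#' @return The filtered `AlleleCountTable`, with attribute `filter_log`
#'   (a data.frame of step, genes_removed, cells_removed).
#' @export
apply_filters <- function(table, min_depth = 10L, min_tissues = 3L,
                          excluded = NULL) {
  stopifnot(inherits(table, "AlleleCountTable"))
  if (min_depth < 1 || min_tissues < 1)
    stop("min_depth and min_tissues must be >= 1")
  log <- list()
  n0 <- length(table$genes)

  excl <- if (is.null(excluded)) character() else excluded$excluded_loci
  keep <- !(table$genes %in% excl)
  log[[1]] <- data.frame(step = "excluded_loci",
                         genes_removed = sum(!keep), cells_removed = NA_integer_)
  tab <- .subset_genes(table, keep)

  low <- !tab$missing & tab$N < min_depth
  tab$missing <- tab$missing | low
  log[[2]] <- data.frame(step = "min_depth",
                         genes_removed = 0L, cells_removed = sum(low))

  support <- rowSums(!tab$missing)
  keep <- support >= min_tissues
  log[[3]] <- data.frame(step = "min_tissues",
                         genes_removed = sum(!keep), cells_removed = NA_integer_)
  tab <- .subset_genes(tab, keep)
  attr(tab, "filter_log") <- do.call(rbind, log)
  tab
}

.subset_genes <- function(table, keep) {
  table$X <- table$X[keep, , drop = FALSE]
  table$N <- table$N[keep, , drop = FALSE]
  table$missing <- table$missing[keep, , drop = FALSE]
  table$genes <- table$genes[keep]
  table
}

#' Read gene/domain intervals from BED or GTF
#'
#' Intervals are returned in the package's internal convention: 0-based,
#' half-open `[start, end)`. BED is consumed natively; GTF's 1-based closed
#' coordinates are converted at this boundary. For GTF, only records with
#' feature type `gene` are used (an isoform-collapsed annotation is
#' expected); the `gene_id` attribute becomes the interval ID.
#'
#' @param path file path.
#' @param format `"BED"` or `"GTF"` (default: guessed from the extension).
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `id`. Unknown strand symbols map to `"."`; records with
#'   `end <= start` after conversion are dropped with a warning.
#' @export
read_intervals <- function(path, format = c("auto", "BED", "GTF")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff[23]?)(\\.gz)?$", path, ignore.case = TRUE))
      "GTF" else "BED"
  }
  gr <- if (format == "GTF") {
    g <- rtracklayer::import(path, format = "gtf")
    if ("type" %in% names(S4Vectors::mcols(g)) &&
        any(S4Vectors::mcols(g)$type == "gene"))
      g <- g[S4Vectors::mcols(g)$type == "gene"]
    g
  } else {
    rtracklayer::import(path, format = "bed")
  }
  mc <- S4Vectors::mcols(gr)
  id <- if (format == "GTF" && "gene_id" %in% names(mc)) {
    as.character(mc$gene_id)
  } else if ("name" %in% names(mc) && !all(is.na(mc$name))) {
    as.character(mc$name)
  } else {
    paste0("interval", seq_along(gr))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[!strand %in% c("+", "-")] <- "."
  # GRanges is 1-based closed; internal convention is 0-based half-open
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = strand, id = id,
                    stringsAsFactors = FALSE)
  bad <- out$end <= out$start
  if (any(bad)) {
    warning(sum(bad), " interval(s) with end <= start dropped from ", path)
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Construct an interval table directly
#'
#' Convenience constructor for the internal 0-based half-open interval
#' data.frame used by the genome-context statistics.
#'
#' @param chrom,start,end,strand,id vectors of equal length; `strand`
#'   defaults to `"."`.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`, `id`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".",
                              id = NULL) {
  n <- length(start)
  stopifnot(length(end) == n)
  if (is.null(id)) id <- paste0("interval", seq_len(n))
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  strand[!strand %in% c("+", "-")] <- "."
  if (any(end <= start)) stop("intervals require start < end")
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand,
             id = as.character(id), stringsAsFactors = FALSE)
}

#' Write a result table as TSV with a stable column order
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
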