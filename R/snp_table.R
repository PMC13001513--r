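#' @keywords internal
#' @useDynLib evoltraj, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

CHROM_LEVELS <- c("2L", "2R", "3L", "3R", "X", "4")
NUCLEOTIDES <- c("A", "T", "C", "G")
GROUP_LEVELS <- c("A2C", "C2A", "FOUNDER_A", "FOUNDER_C")

#' Construct a Pool-seq SNP table
#'
#' The central exchange object of the package: minor-allele counts and total
#' coverages for a set of loci (rows) across a set of pooled samples
#' (columns), together with locus and sample metadata. The minor allele is
#' defined *globally*: at each locus it is the nucleotide that is less common
#' summed over all samples.
#'
#' @param loci data frame with columns `chrom` (one of 2L, 2R, 3L, 3R, X, 4),
#'   `pos` (1-based), `minor_base`, `major_base`.
#' @param samples data frame with columns `sample_id`, `group` (one of
#'   `A2C`, `C2A`, `FOUNDER_A`, `FOUNDER_C`), `replicate` (integer),
#'   `generation` (non-negative; generations under the current regime),
#'   `timepoint` (label).
#' @param minor integer matrix, loci x samples, minor-allele read counts.
#' @param coverage integer matrix, loci x samples, total read counts.
#' @return An object of class `snp_table`.
#' @export
snp_table <- function(loci, samples, minor, coverage) {
  minor <- as.matrix(minor)
  coverage <- as.matrix(coverage)
  storage.mode(minor) <- "integer"
  storage.mode(coverage) <- "integer"
  obj <- structure(
    list(loci = as.data.frame(loci), samples = as.data.frame(samples),
         minor = minor, coverage = coverage),
    class = "snp_table"
  )
  validate_snp_table(obj)
  obj
}

#' Validate a `snp_table`
#'
#' Checks the structural invariants: matching dimensions, counts within
#' coverage, distinct minor/major bases, allowed chromosome labels and unique
#' (group, replicate, timepoint) sample keys.
#'
#' @param x a `snp_table`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_snp_table <- function(x) {
  stopifnot(inherits(x, "snp_table"))
  nl <- nrow(x$loci); ns <- nrow(x$samples)
  if (!all(dim(x$minor) == c(nl, ns)) || !all(dim(x$coverage) == c(nl, ns)))
    stop("matrix dimensions do not match loci/samples metadata")
  req_l <- c("chrom", "pos", "minor_base", "major_base")
  if (!all(req_l %in% names(x$loci)))
    stop("loci metadata must have columns: ", paste(req_l, collapse = ", "))
  req_s <- c("sample_id", "group", "replicate", "generation", "timepoint")
  if (!all(req_s %in% names(x$samples)))
    stop("sample metadata must have columns: ", paste(req_s, collapse = ", "))
  if (nl > 0) {
    if (!all(x$loci$chrom %in% CHROM_LEVELS))
      stop("chrom labels must be in {", paste(CHROM_LEVELS, collapse = ", "), "}")
    if (any(x$loci$pos < 1)) stop("positions must be >= 1 (1-based)")
    if (any(x$loci$minor_base == x$loci$major_base))
      stop("minor_base must differ from major_base")
  }
  if (ns > 0) {
    if (!all(x$samples$group %in% GROUP_LEVELS))
      stop("sample group must be in {", paste(GROUP_LEVELS, collapse = ", "), "}")
    if (any(x$samples$generation < 0)) stop("generation must be >= 0")
    key <- paste(x$samples$group, x$samples$replicate, x$samples$timepoint)
    if (anyDuplicated(key))
      stop("(group, replicate, timepoint) must be unique across samples")
  }
  if (nl > 0 && ns > 0) {
    if (any(x$minor < 0) || any(x$coverage < 0))
      stop("counts must be non-negative")
    if (any(x$minor > x$coverage))
      stop("minor count exceeds coverage at ",
           sum(x$minor > x$coverage), " cell(s)")
  }
  invisible(x)
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d loci x %d samples\n", nrow(x$loci), nrow(x$samples)))
  if (nrow(x$loci) > 0)
    cat("  chromosomes:", paste(sort(unique(x$loci$chrom)), collapse = " "), "\n")
  if (nrow(x$samples) > 0)
    cat("  groups:", paste(sort(unique(x$samples$group)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.snp_table <- function(x) c(nrow(x$loci), nrow(x$samples))

#' Subset a SNP table by loci and/or samples
#'
#' @param x a `snp_table`.
#' @param i locus index (logical, integer or negative integer).
#' @param j sample index.
#' @param ... unused.
#' @return a `snp_table` restricted to the selected loci/samples.
#' @export
`[.snp_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$loci))
  if (missing(j)) j <- seq_len(nrow(x$samples))
  structure(
    list(loci = x$loci[i, , drop = FALSE],
         samples = x$samples[j, , drop = FALSE],
         minor = x$minor[i, j, drop = FALSE],
         coverage = x$coverage[i, j, drop = FALSE]),
    class = "snp_table"
  )
}

#' Minor-allele frequencies
#'
#' Per-cell minor-allele frequency, optionally with a symmetric pseudocount
#' (as used before PCA to avoid division by zero and zero-variance loci):
#' `f = (minor + pc) / (coverage + 2 pc)`.
#'
#' @param table a `snp_table`.
#' @param pseudocount non-negative integer added to the minor count (and twice
#'   to coverage). With 0 (default) exact ratios are returned.
#' @return numeric matrix, loci x samples.
#' @export
frequencies <- function(table, pseudocount = 0) {
  stopifnot(inherits(table, "snp_table"), pseudocount >= 0)
  if (pseudocount == 0 && any(table$coverage == 0)) {
    bad <- which(table$coverage == 0, arr.ind = TRUE)
    stop("frequency undefined (coverage 0, pseudocount 0) at e.g. locus ",
         bad[1, 1], " sample ", bad[1, 2], "; ", nrow(bad), " cell(s) affected")
  }
  f <- (table$minor + pseudocount) / (table$coverage + 2 * pseudocount)
  dimnames(f) <- list(NULL, table$samples$sample_id)
  f
}

#' Filter SNPs on coverage and pooled minor-allele frequency
#'
#' Retains loci where every sample reaches `min_cov` coverage and the pooled
#' minor-allele frequency (summed minor counts over summed coverage across all
#' samples) is at least `min_maf`; both bounds inclusive. Optionally drops the
#' small dot chromosome (4), whose atypical recombination and heterochromatin
#' content make per-locus models there unreliable.
#'
#' @param table a `snp_table`.
#' @param min_cov minimum per-sample coverage (default 20).
#' @param min_maf minimum pooled minor-allele frequency in `[0, 0.5]`
#'   (default 0.02).
#' @param exclude_chrom4 drop loci on chromosome 4? (default `FALSE`).
#' @return the filtered `snp_table`, locus order preserved.
#' @export
filter_snps <- function(table, min_cov = 20, min_maf = 0.02,
                        exclude_chrom4 = FALSE) {
  stopifnot(inherits(table, "snp_table"))
  if (min_maf < 0 || min_maf > 0.5)
    stop("min_maf must lie in [0, 0.5], got ", min_maf)
  if (nrow(table$loci) == 0) return(table)
  cov_ok <- apply(table$coverage >= min_cov, 1, all)
  tot_cov <- rowSums(table$coverage)
  pooled <- ifelse(tot_cov > 0, rowSums(table$minor) / tot_cov, 0)
  keep <- cov_ok & pooled >= min_maf
  if (exclude_chrom4) keep <- keep & table$loci$chrom != "4"
  table[keep, ]
}

parse_sync_counts <- function(strings, lineno) {
  parts <- strsplit(strings, ":", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields != 6 & n_fields != 4))
    stop("malformed count string on sync line ", lineno, ": '",
         strings[which(n_fields != 6 & n_fields != 4)[1]], "'")
  cnt <- suppressWarnings(
    vapply(parts, function(p) as.integer(p[1:4]), integer(4))
  )
  if (any(is.na(cnt)))
    stop("malformed count string on sync line ", lineno,
         ": non-integer field")
  cnt  # 4 x n_samples, rows A,T,C,G
}

#' Read a PoPoolation2 sync file into a SNP table
#'
#' Parses the tab-separated sync format (chrom, pos, ref, then one
#' `A:T:C:G:N:del` count string per sample), keeps only biallelic sites
#' (exactly two nucleotides with nonzero count summed over all samples),
#' and defines the minor allele as the globally less common of the two
#' (lexicographic tie-break, A<C<G<T, toward the minor). Sites with more than
#' two segregating nucleotides are dropped with a message; N and deletion
#' counts are ignored.
#'
#' @param path sync file path.
#' @param sample_metas data frame of sample metadata (see [snp_table()]);
#'   row order must match the sync sample columns.
#' @return a `snp_table`.
#' @export
read_sync <- function(path, sample_metas) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ns <- nrow(sample_metas)
  if (length(lines) == 0) {
    return(snp_table(
      data.frame(chrom = character(), pos = integer(),
                 minor_base = character(), major_base = character()),
      sample_metas,
      matrix(integer(), 0, ns), matrix(integer(), 0, ns)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3 + ns))
    stop("sync line ", which(nf != 3 + ns)[1], " has ", nf[nf != 3 + ns][1],
         " fields; expected ", 3 + ns, " for ", ns, " samples")
  chrom <- vapply(fields, `[[`, character(1), 1)
  pos <- as.integer(vapply(fields, `[[`, character(1), 2))
  n_dropped <- 0L
  keep <- logical(length(lines))
  minor_base <- major_base <- character(length(lines))
  minor_m <- matrix(0L, length(lines), ns)
  cov_m <- matrix(0L, length(lines), ns)
  for (k in seq_along(fields)) {
    cnt <- parse_sync_counts(fields[[k]][-(1:3)], k)
    tot <- rowSums(cnt)
    seg <- which(tot > 0)
    if (length(seg) != 2) {
      if (length(seg) > 2) n_dropped <- n_dropped + 1L
      next
    }
    # global minor = smaller summed count; lexicographic tie-break (A<C<G<T)
    b <- NUCLEOTIDES[seg]
    ord <- order(tot[seg], b)
    mi <- seg[ord[1]]; ma <- seg[ord[2]]
    keep[k] <- TRUE
    minor_base[k] <- NUCLEOTIDES[mi]
    major_base[k] <- NUCLEOTIDES[ma]
    minor_m[k, ] <- cnt[mi, ]
    cov_m[k, ] <- cnt[mi, ] + cnt[ma, ]
  }
  if (n_dropped > 0)
    message("read_sync: dropped ", n_dropped, " site(s) with >2 segregating nucleotides")
  snp_table(
    data.frame(chrom = chrom[keep], pos = pos[keep],
               minor_base = minor_base[keep], major_base = major_base[keep]),
    sample_metas, minor_m[keep, , drop = FALSE], cov_m[keep, , drop = FALSE])
}

#' Write a SNP table as a sync file
#'
#' Inverse of [read_sync()]: emits one `A:T:C:G:N:del` count string per
#' sample with the minor/major counts in their nucleotide slots (reference
#' column = major base). `read_sync(write_sync(x))` reproduces the minor and
#' coverage matrices exactly.
#'
#' @param table a `snp_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(table, path) {
  stopifnot(inherits(table, "snp_table"))
  nl <- nrow(table$loci); ns <- nrow(table$samples)
  if (nl == 0) { writeLines(character(0), path); return(invisible(path)) }
  mi_idx <- match(table$loci$minor_base, NUCLEOTIDES)
  ma_idx <- match(table$loci$major_base, NUCLEOTIDES)
  lines <- character(nl)
  for (k in seq_len(nl)) {
    cnt <- matrix(0L, 4, ns)
    cnt[mi_idx[k], ] <- table$minor[k, ]
    cnt[ma_idx[k], ] <- table$coverage[k, ] - table$minor[k, ]
    strs <- apply(cnt, 2, function(v) paste(c(v, 0L, 0L), collapse = ":"))
    lines[k] <- paste(c(table$loci$chrom[k], table$loci$pos[k],
                        table$loci$major_base[k], strs), collapse = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a SNP table in the tabular dialect (plus sample sidecar)
#'
#' One row per locus: chrom, pos, minor_base, major_base, then a
#' `<sample>.minor` / `<sample>.cov` column pair per sample. Sample metadata
#' go to a sidecar TSV.
#'
#' @param table a `snp_table`.
#' @param path output TSV path for the count table.
#' @param design_path output TSV path for the sample metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(table, path, design_path) {
  stopifnot(inherits(table, "snp_table"))
  ids <- table$samples$sample_id
  out <- table$loci[, c("chrom", "pos", "minor_base", "major_base")]
  for (j in seq_along(ids)) {
    out[[paste0(ids[j], ".minor")]] <- table$minor[, j]
    out[[paste0(ids[j], ".cov")]] <- table$coverage[, j]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$samples, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a SNP table from the tabular dialect
#'
#' @param path count-table TSV written by [write_snp_table()].
#' @param design_path sample-metadata sidecar TSV.
#' @return a `snp_table`.
#' @export
read_snp_table <- function(path, design_path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(chrom = "character"),
                           check.names = FALSE)
  samples <- utils::read.table(design_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  ids <- samples$sample_id
  minor <- as.matrix(tab[, paste0(ids, ".minor"), drop = FALSE])
  cov <- as.matrix(tab[, paste0(ids, ".cov"), drop = FALSE])
  dimnames(minor) <- dimnames(cov) <- NULL
  snp_table(tab[, c("chrom", "pos", "minor_base", "major_base")],
            samples, minor, cov)
}
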