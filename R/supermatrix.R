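# Gene selection by cohort-wide presence, concatenation into a partitioned
# supermatrix, and the alignment statistics (length, variable sites,
# missing data).

#' Construct a gene alignment object
#'
#' @param gene_name Gene name.
#' @param rows Named character vector of aligned sequences (names are
#'   sample ids); all rows must have equal length.
#' @return A `gene_alignment`.
#' @export
gene_alignment <- function(gene_name, rows) {
  if (!length(rows)) stop("alignment has no rows")
  if (is.null(names(rows)) || anyNA(names(rows)) || !all(nzchar(names(rows))))
    stop("alignment rows must be named by sample id")
  if (anyDuplicated(names(rows)))
    stop("duplicate sample id in alignment for gene ", gene_name)
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("rows of gene ", gene_name, " differ in length")
  structure(list(gene_name = gene_name, sample_ids = names(rows),
                 rows = toupper(unname(rows)), width = w),
            class = "gene_alignment")
}

#' Read one aligned FASTA file as a gene alignment
#'
#' @param path Aligned FASTA path.
#' @param gene_name Gene name; defaults to the file stem.
#' @return A `gene_alignment`.
#' @export
read_alignment <- function(path, gene_name = NULL) {
  if (is.null(gene_name))
    gene_name <- sub("\\.(fa|fasta|fna|aln)(\\.gz)?$", "", basename(path))
  ss <- Biostrings::readDNAStringSet(path)
  gene_alignment(gene_name, stats::setNames(as.character(ss), names(ss)))
}

#' Select genes by cohort-wide presence
#'
#' Keeps genes whose presence fraction is at least `threshold` (bound
#' inclusive: a gene present in exactly 90\% of samples passes the default)
#' and returns them sorted by name.
#'
#' @param presence Named numeric vector, gene name -> fraction of samples
#'   in which the gene is present, values in \[0, 1\].
#' @param threshold Minimum presence fraction, default 0.90.
#' @return Sorted character vector of gene names.
#' @export
#' @examples
#' select_genes(c(ndhA = 0.9, ndhB = 0.8), threshold = 0.9)
select_genes <- function(presence, threshold = 0.90) {
  if (!length(presence)) return(character(0))
  stopifnot(!is.null(names(presence)), all(presence >= 0 & presence <= 1))
  sort(names(presence)[presence >= threshold - 1e-12])
}

#' Concatenate gene alignments into a partitioned supermatrix
#'
#' Rows follow `sample_universe`; a sample absent from a gene's alignment
#' is padded with `"-"` across that gene's partition. Partition
#' coordinates are 1-based inclusive and tile the matrix without gaps.
#'
#' @param alignments Non-empty list of `gene_alignment` objects.
#' @param sample_universe Ordered character vector of sample ids; defaults
#'   to the union of all alignment samples in first-seen order.
#' @return A `supermatrix`: list with `sample_ids`, `matrix_rows` (named
#'   character vector) and `partitions` (data frame `gene`, `start`,
#'   `end`).
#' @export
concatenate <- function(alignments, sample_universe = NULL) {
  if (!length(alignments)) stop("no alignments to concatenate")
  stopifnot(all(vapply(alignments, inherits, TRUE, "gene_alignment")))
  if (is.null(sample_universe)) {
    sample_universe <- unique(unlist(lapply(alignments, `[[`, "sample_ids")))
  }
  rows <- stats::setNames(rep("", length(sample_universe)), sample_universe)
  parts <- list()
  at <- 0L
  for (aln in alignments) {
    pad <- strrep("-", aln$width)
    block <- stats::setNames(rep(pad, length(sample_universe)),
                             sample_universe)
    hit <- intersect(aln$sample_ids, sample_universe)
    block[hit] <- aln$rows[match(hit, aln$sample_ids)]
    rows <- paste0(rows, block)
    names(rows) <- sample_universe
    parts[[length(parts) + 1L]] <- df(gene = aln$gene_name, start = at + 1L,
                                      end = at + aln$width)
    at <- at + aln$width
  }
  structure(list(sample_ids = sample_universe, matrix_rows = rows,
                 partitions = do.call(rbind, parts)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d sample(s), %d bp, %d partition(s)\n",
              length(x$sample_ids), max(x$partitions$end),
              nrow(x$partitions)))
  invisible(x)
}

#' Alignment statistics: length, variable sites, missing data
#'
#' A column is \emph{variable} (a SNP column) when it contains at least two
#' distinct unambiguous bases (A/C/G/T) across rows; gaps, N and IUPAC
#' ambiguity letters are ignored in the variability test. \emph{Missing}
#' cells are `-` and `N` only.
#'
#' @param x A `supermatrix` or `gene_alignment`.
#' @return An `alignment_stats`: list with `length_bp`,
#'   `n_variable_sites`, `pct_variable` and `pct_missing` (both on the
#'   0--100 scale).
#' @export
#' @examples
#' aln <- gene_alignment("g", c(s1 = "ACGT", s2 = "ACGA"))
#' alignment_statistics(aln)  # 1 variable site (25%)
alignment_statistics <- function(x) {
  rows <- if (inherits(x, "supermatrix")) x$matrix_rows
          else if (inherits(x, "gene_alignment")) x$rows
          else stop("`x` must be a supermatrix or gene_alignment")
  if (!length(rows)) stop("empty alignment")
  w <- unique(nchar(rows))
  stopifnot(length(w) == 1L)
  if (w == 0L) stop("alignment has zero columns")
  m <- matrix(unlist(strsplit(toupper(rows), "", fixed = TRUE), use.names =
                       FALSE),
              nrow = length(rows), byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  n_var <- sum(apply(m, 2L, function(col) {
    length(unique(col[col %in% bases])) >= 2L
  }))
  n_missing <- sum(m == "-" | m == "N")
  structure(list(length_bp = w, n_variable_sites = n_var,
                 pct_variable = 100 * n_var / w,
                 pct_missing = 100 * n_missing / (length(rows) * w)),
            class = "alignment_stats")
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat(sprintf(
    "<alignment_stats> %d bp, %d variable sites (%.2f%%), %.2f%% missing\n",
    x$length_bp, x$n_variable_sites, x$pct_variable, x$pct_missing))
  invisible(x)
}

#' Write a supermatrix and its partition file
#'
#' The alignment is written as FASTA; the partition table in plain RAxML
#' dialect, one `DNA, gene = start-end` line per partition.
#'
#' @param sm A `supermatrix`.
#' @param fasta_path Output FASTA path.
#' @param partition_path Output partition-file path (optional).
#' @return Invisibly, `fasta_path`.
#' @export
write_supermatrix <- function(sm, fasta_path, partition_path = NULL) {
  stopifnot(inherits(sm, "supermatrix"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sm$matrix_rows), fasta_path, width = 70L)
  if (!is.null(partition_path)) {
    writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$gene,
                       sm$partitions$start, sm$partitions$end),
               partition_path)
  }
  invisible(fasta_path)
}
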