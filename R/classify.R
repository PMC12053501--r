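# Four-state classification of ndh genes: functional / truncated /
# pseudogenized / lost.

GENE_STATES <- c("functional", "truncated", "pseudogenized", "lost")

#' Detect a premature (internal) stop codon
#'
#' Translates the coding sequence from position 1 in frame 0 and returns
#' the 1-based codon index of the first stop codon that is not the final
#' complete codon. A stop in the last complete codon is the normal
#' terminator and does not count; a trailing remainder of 1--2 nt is
#' ignored. Codons containing non-ACGT letters never match a stop.
#'
#' @param cds Nucleotide string, length at least 3.
#' @param translation_table Genetic code identifier passed to
#'   [Biostrings::getGeneticCode()]; default `"11"`, the bacterial/plastid
#'   code.
#' @return Integer codon index, or `NULL` when no internal stop exists.
#' @export
#' @examples
#' detect_premature_stop("ATGAAATAA")     # NULL: TAA is the terminator
#' detect_premature_stop("ATGTAAAAATAA")  # 2
detect_premature_stop <- function(cds, translation_table = "11") {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 3L) stop("`cds` must be at least 3 nt long")
  code <- Biostrings::getGeneticCode(translation_table)
  stops <- names(code)[code == "*"]
  n_codons <- n %/% 3L
  starts <- 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(cds, starts, starts + 2L)
  hit <- which(codons %in% stops)
  hit <- hit[hit < n_codons]
  if (length(hit)) hit[1] else NULL
}

#' Classify one gene in one sample
#'
#' Applies the four-state rule to the longest annotated copy of a gene
#' (or to its absence). Precedence:
#' \enumerate{
#'   \item absent, or length ratio strictly below `lost_fraction` -> lost;
#'   \item else, if `check_stops` and an internal stop codon is found ->
#'     truncated;
#'   \item else, if the ratio is strictly below `pseudo_lower` or strictly
#'     above `pseudo_upper` -> pseudogenized;
#'   \item else -> functional.
#' }
#' The bounds are strict ("below 80\% or above 120\%", "below 20\%"):
#' a ratio of exactly 0.20 is pseudogenized, exactly 0.80 or 1.20 is
#' functional (absent an internal stop).
#'
#' By default the stop-codon test is applied to every non-lost copy, so an
#' internal stop dominates a length violation; set
#' `truncation_scope = "pseudogenized_only"` to test stops only on copies
#' already outside the length window.
#'
#' @param observations List of `gene_observation` for this gene in this
#'   sample (possibly empty), e.g. from [extract_gene()].
#' @param reference_length_bp Positive reference length in bp.
#' @param thresholds An [audit_thresholds()] object.
#' @param check_stops Apply the premature-stop test? Disable to reproduce
#'   an annotation-only assessment (lengths trusted, frames unexamined).
#' @param truncation_scope `"any"` (default) or `"pseudogenized_only"`.
#' @param translation_table Genetic code id for the stop test.
#' @return A `gene_status`: list with `sample_id`, `gene_name`, `state`,
#'   `observed_length_bp`, `length_ratio`,
#'   `premature_stop_codon_index` (NULL when none or untested).
#' @export
classify_gene <- function(observations, reference_length_bp,
                          thresholds = audit_thresholds(),
                          check_stops = TRUE,
                          truncation_scope = c("any", "pseudogenized_only"),
                          translation_table = "11") {
  if (!is.numeric(reference_length_bp) || length(reference_length_bp) != 1L ||
      is.na(reference_length_bp) || reference_length_bp <= 0) {
    stop("`reference_length_bp` must be a single positive number")
  }
  truncation_scope <- match.arg(truncation_scope)
  stopifnot(inherits(thresholds, "audit_thresholds"))

  if (!length(observations)) {
    return(new_gene_status(NA_character_, NA_character_, "lost", 0L, 0))
  }
  lens <- vapply(observations, `[[`, 1L, "length_bp")
  obs <- observations[[which.max(lens)]]
  ratio <- obs$length_bp / reference_length_bp
  stop_idx <- if (check_stops && obs$length_bp >= 3L) {
    detect_premature_stop(obs$sequence, translation_table)
  } else NULL

  in_window <- ratio >= thresholds$pseudo_lower &
    ratio <= thresholds$pseudo_upper
  state <-
    if (ratio < thresholds$lost_fraction) "lost"
    else if (!is.null(stop_idx) &&
             (truncation_scope == "any" || !in_window)) "truncated"
    else if (!in_window) "pseudogenized"
    else "functional"

  new_gene_status(obs$sample_id, obs$gene_name, state, obs$length_bp, ratio,
                  stop_idx)
}

new_gene_status <- function(sample_id, gene_name, state, observed_length_bp,
                            length_ratio, premature_stop_codon_index = NULL) {
  structure(list(sample_id = sample_id, gene_name = gene_name, state = state,
                 observed_length_bp = observed_length_bp,
                 length_ratio = length_ratio,
                 premature_stop_codon_index = premature_stop_codon_index),
            class = "gene_status")
}

#' @export
print.gene_status <- function(x, ...) {
  cat(sprintf("<gene_status> %s %s: %s (%d bp, ratio %.3f%s)\n",
              x$sample_id, x$gene_name, x$state, x$observed_length_bp,
              x$length_ratio,
              if (!is.null(x$premature_stop_codon_index))
                sprintf(", stop at codon %d", x$premature_stop_codon_index)
              else ""))
  invisible(x)
}

#' Build the samples-by-genes status matrix
#'
#' Classifies every (sample, gene) pair; absence is recorded as `lost`, so
#' the matrix has no empty cells.
#'
#' @param cohort List of `plastome_record` objects (named or carrying
#'   `sample_id` fields).
#' @param genes Character vector of gene names.
#' @param refs A `reference_length_set` from
#'   [determine_reference_lengths()]; must cover every requested gene.
#' @inheritParams classify_gene
#' @return A `status_matrix`: list with `samples`, `genes`, `status`
#'   (character matrix of the four states), `ratio` and `stop_index`
#'   numeric matrices, and `cells`, a long data frame.
#' @export
build_status_matrix <- function(cohort, genes = ndh_genes(), refs,
                                thresholds = audit_thresholds(),
                                check_stops = TRUE,
                                truncation_scope = c("any",
                                                     "pseudogenized_only"),
                                translation_table = "11") {
  stopifnot(inherits(refs, "reference_length_set"))
  truncation_scope <- match.arg(truncation_scope)
  missing_ref <- setdiff(genes, refs$gene)
  if (length(missing_ref)) {
    stop("no reference length for gene(s): ",
         paste(missing_ref, collapse = ", "))
  }
  samples <- vapply(cohort, `[[`, "", "sample_id")
  status <- matrix(NA_character_, length(samples), length(genes),
                   dimnames = list(samples, genes))
  ratio <- matrix(NA_real_, length(samples), length(genes),
                  dimnames = list(samples, genes))
  stop_idx <- matrix(NA_integer_, length(samples), length(genes),
                     dimnames = list(samples, genes))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    for (g in genes) {
      ref <- refs$reference_length_bp[refs$gene == g]
      st <- classify_gene(extract_gene(rec, g), ref, thresholds,
                          check_stops, truncation_scope, translation_table)
      status[i, g] <- st$state
      ratio[i, g] <- st$length_ratio
      stop_idx[i, g] <- if (is.null(st$premature_stop_codon_index))
        NA_integer_ else st$premature_stop_codon_index
    }
  }
  cells <- df(sample_id = rep(samples, times = length(genes)),
              gene_name = rep(genes, each = length(samples)),
              state = as.vector(status),
              observed_ratio = as.vector(ratio),
              premature_stop_codon_index = as.vector(stop_idx))
  structure(list(samples = samples, genes = genes, status = status,
                 ratio = ratio, stop_index = stop_idx, cells = cells),
            class = "status_matrix")
}

#' @export
print.status_matrix <- function(x, ...) {
  cat(sprintf("<status_matrix> %d sample(s) x %d gene(s)\n",
              length(x$samples), length(x$genes)))
  print(summary(x))
  invisible(x)
}

#' Per-gene state counts of a status matrix
#'
#' @param object A `status_matrix`.
#' @param ... Unused.
#' @return Data frame with one row per gene and one count column per state.
#' @method summary status_matrix
#' @export
summary.status_matrix <- function(object, ...) {
  counts <- t(vapply(object$genes, function(g)
    table(factor(object$status[, g], levels = GENE_STATES)),
    stats::setNames(integer(4), GENE_STATES)))
  cbind(df(gene = object$genes), as.data.frame(counts))
}

#' Write a status matrix to TSV
#'
#' Two layouts: `"wide"`, samples in rows and genes in columns with the
#' state initials F/T/P/L as values, and `"long"`, one row per cell with
#' the observed length ratio and stop-codon index.
#'
#' @param matrix A `status_matrix`.
#' @param path Output path.
#' @param layout `"wide"` or `"long"`.
#' @return Invisibly, `path`.
#' @export
write_status_matrix <- function(matrix, path, layout = c("wide", "long")) {
  stopifnot(inherits(matrix, "status_matrix"))
  layout <- match.arg(layout)
  if (layout == "wide") {
    letters_ <- matrix(toupper(substr(matrix$status, 1, 1)),
                       nrow = length(matrix$samples),
                       dimnames = dimnames(matrix$status))
    utils::write.table(cbind(df(sample_id = matrix$samples),
                             as.data.frame(letters_)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(matrix$cells, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
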