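# Per-gene reference length inference: exact-length consensus first, then
# a two-pass outlier-excluding mean as fallback.

#' Classification and selection thresholds
#'
#' Bundles the tunable proportions used across the pipeline. All defaults
#' follow the audit procedure: a length value becomes the reference by
#' consensus when at least 50\% of annotated samples share it exactly;
#' copies deviating by 30\% or more from the first-pass mean are excluded
#' from the second pass; genes outside 80--120\% of the reference are
#' pseudogenized; genes below 20\% (or absent) are lost; genes present in
#' at least 90\% of samples enter the supermatrix.
#'
#' @param consensus_fraction Minimum fraction of samples that must share an
#'   exact length for the consensus path (default 0.50).
#' @param outlier_fraction Relative deviation at or above which a copy is
#'   excluded from the second-pass mean (default 0.30; the bound is
#'   closed, "at least 30\%" is excluded).
#' @param pseudo_lower,pseudo_upper Lower/upper bounds of the functional
#'   length window as fractions of the reference (defaults 0.80, 1.20;
#'   strict inequalities -- exactly 80\% or 120\% is not pseudogenized).
#' @param lost_fraction Copies strictly below this fraction of the
#'   reference are lost (default 0.20).
#' @param supermatrix_presence Minimum fraction of samples a gene must be
#'   present in to enter the supermatrix (default 0.90; bound inclusive).
#' @return An object of class `audit_thresholds`.
#' @export
#' @examples
#' audit_thresholds()
audit_thresholds <- function(consensus_fraction = 0.50,
                             outlier_fraction = 0.30,
                             pseudo_lower = 0.80,
                             pseudo_upper = 1.20,
                             lost_fraction = 0.20,
                             supermatrix_presence = 0.90) {
  stopifnot_scalar_fraction(consensus_fraction, "consensus_fraction")
  stopifnot_scalar_fraction(outlier_fraction, "outlier_fraction",
                            allow_one = FALSE)
  stopifnot_scalar_fraction(supermatrix_presence, "supermatrix_presence")
  if (!(0 < lost_fraction && lost_fraction < pseudo_lower &&
        pseudo_lower < 1 && 1 < pseudo_upper)) {
    stop("thresholds must satisfy 0 < lost_fraction < pseudo_lower < 1 < ",
         "pseudo_upper", call. = FALSE)
  }
  structure(list(consensus_fraction = consensus_fraction,
                 outlier_fraction = outlier_fraction,
                 pseudo_lower = pseudo_lower,
                 pseudo_upper = pseudo_upper,
                 lost_fraction = lost_fraction,
                 supermatrix_presence = supermatrix_presence),
            class = "audit_thresholds")
}

#' @export
print.audit_thresholds <- function(x, ...) {
  cat("<audit_thresholds>\n")
  for (n in names(x)) cat(sprintf("  %-22s %.2f\n", n, x[[n]]))
  invisible(x)
}

#' Exact-length consensus reference
#'
#' Returns the length value carried by at least `consensus_fraction` of the
#' input lengths, or `NULL` when no value qualifies. When two values tie
#' (only possible at exactly the consensus fraction) the consensus is
#' ambiguous and `NULL` is returned, letting the caller fall through to the
#' two-pass mean.
#'
#' @param lengths Non-empty vector of positive integer lengths (bp), one
#'   per sample.
#' @param consensus_fraction Required exact-match fraction, default 0.50.
#' @return A single integer, or `NULL` when no unique consensus exists.
#' @export
#' @examples
#' consensus_reference_length(c(477, 477, 480, 477))  # 477
#' consensus_reference_length(c(100, 200, 300))       # NULL
consensus_reference_length <- function(lengths, consensus_fraction = 0.50) {
  if (!length(lengths)) stop("`lengths` must be non-empty")
  stopifnot(all(lengths > 0))
  tab <- table(lengths)
  # tolerance guard: n * fraction can land a hair above an integer count
  need <- consensus_fraction * length(lengths) - 1e-9
  qual <- as.integer(names(tab))[as.vector(tab) >= need]
  if (length(qual) == 1L) qual else NULL
}

#' Two-pass mean reference length
#'
#' First pass: arithmetic mean `m1` of all lengths. Second pass: the mean of
#' the lengths whose relative deviation from `m1` is strictly below
#' `outlier_fraction` (a deviation of at least the fraction is excluded),
#' rounded half-up to the nearest integer.
#'
#' @inheritParams consensus_reference_length
#' @param outlier_fraction Exclusion bound on `|l - m1| / m1` (closed),
#'   default 0.30.
#' @return A positive integer.
#' @export
#' @examples
#' two_pass_mean_reference_length(c(1000, 1000, 500))  # 1000
#' two_pass_mean_reference_length(c(100, 101))         # 101 (100.5 rounds up)
two_pass_mean_reference_length <- function(lengths, outlier_fraction = 0.30) {
  if (!length(lengths)) stop("`lengths` must be non-empty")
  stopifnot(all(lengths > 0))
  m1 <- mean(lengths)
  keep <- abs(lengths - m1) / m1 < outlier_fraction
  if (!any(keep)) {
    stop(sprintf(
      "all %d lengths deviate >= %.0f%% from the first-pass mean (%.2f bp); ",
      length(lengths), 100 * outlier_fraction, m1),
      "cannot infer a reference length")
  }
  as.integer(round_half_up(mean(lengths[keep])))
}

#' Infer per-gene reference lengths for a cohort
#'
#' For each gene, the per-sample length is the longest annotated copy
#' (inverted-repeat fragments must not drag the mean down); only samples in
#' which the gene is annotated contribute. The exact-length consensus is
#' tried first; when no unique length reaches the consensus fraction, the
#' two-pass outlier-excluding mean is used instead. A gene annotated in no
#' sample is omitted with a warning.
#'
#' @param cohort List of `plastome_record` objects, or a named list mapping
#'   sample id to a list of `gene_observation`.
#' @param genes Character vector of gene names to process (default the
#'   eleven ndh genes).
#' @param thresholds An [audit_thresholds()] object.
#' @return A `reference_length_set`: data frame with columns `gene`,
#'   `reference_length_bp`, `method` (`"consensus"` or `"two_pass_mean"`),
#'   `n_used`, `n_excluded`.
#' @export
determine_reference_lengths <- function(cohort, genes = ndh_genes(),
                                        thresholds = audit_thresholds()) {
  if (!length(cohort)) stop("`cohort` must be non-empty")
  stopifnot(inherits(thresholds, "audit_thresholds"))
  lengths_by_gene <- cohort_gene_lengths(cohort, genes)
  rows <- list()
  for (g in genes) {
    lens <- lengths_by_gene[[g]]
    if (!length(lens)) {
      warning(sprintf("gene '%s' annotated in no sample; no reference length",
                      g), call. = FALSE)
      next
    }
    cons <- consensus_reference_length(lens, thresholds$consensus_fraction)
    if (!is.null(cons)) {
      rows[[g]] <- df(gene = g, reference_length_bp = cons,
                      method = "consensus", n_used = length(lens),
                      n_excluded = 0L)
    } else {
      m1 <- mean(lens)
      keep <- abs(lens - m1) / m1 < thresholds$outlier_fraction
      ref <- two_pass_mean_reference_length(lens, thresholds$outlier_fraction)
      rows[[g]] <- df(gene = g, reference_length_bp = ref,
                      method = "two_pass_mean", n_used = sum(keep),
                      n_excluded = sum(!keep))
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("reference_length_set", "data.frame")
  out
}

# Per-gene vector of per-sample representative lengths (longest copy).
cohort_gene_lengths <- function(cohort, genes) {
  out <- stats::setNames(vector("list", length(genes)), genes)
  for (g in genes) out[[g]] <- integer(0)
  for (sample in cohort) {
    obs_list <- if (inherits(sample, "plastome_record")) sample$features
                else sample
    nm <- vapply(obs_list, `[[`, "", "gene_name")
    for (g in genes) {
      hits <- obs_list[nm == g]
      if (length(hits)) {
        out[[g]] <- c(out[[g]],
                      max(vapply(hits, `[[`, 1L, "length_bp")))
      }
    }
  }
  out
}

#' Write a reference-length table to TSV
#'
#' @param refs A `reference_length_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reference_lengths <- function(refs, path) {
  stopifnot(inherits(refs, "reference_length_set"))
  utils::write.table(refs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
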