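# GenBank flat-file input and per-gene FASTA output.
#
# Coordinates are stored 0-based half-open internally; the 1-based inclusive
# GenBank convention is converted exactly once, at the parse boundary.

# ---- gene-name normalization -------------------------------------------

# canonical spellings matched case-insensitively; anything else falls
# through to the synonym table, then is returned trimmed but unchanged.
.canonical_genes <- c(
  paste0("ndh", LETTERS[1:11]),
  "rbcL", "matK", "accD", "ccsA", "cemA", "clpP", "infA",
  paste0("atp", c("A", "B", "E", "F", "H", "I")),
  paste0("pet", c("A", "B", "D", "G", "L", "N")),
  paste0("psa", c("A", "B", "C", "I", "J")),
  paste0("psb", c("A", "B", "C", "D", "E", "F", "H", "I", "J", "K",
                  "L", "M", "N", "T", "Z")),
  paste0("rpo", c("A", "B", "C1", "C2")),
  "ycf1", "ycf2", "ycf3", "ycf4"
)

.synonym_env <- new.env(parent = emptyenv())

.gene_synonyms <- function() {
  if (is.null(.synonym_env$tab)) {
    path <- system.file("extdata", "gene_synonyms.tsv", package = "ndhaudit")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    .synonym_env$tab <- stats::setNames(tab$canonical, tab$synonym)
  }
  .synonym_env$tab
}

#' Normalize a gene name to its canonical spelling
#'
#' Strips surrounding whitespace, matches case-insensitively against the
#' canonical plastid gene names (ndhA...ndhK and the common photosynthesis
#' and housekeeping genes), and finally consults an editable synonym table
#' (`inst/extdata/gene_synonyms.tsv`) that maps long product descriptions
#' such as `"NADH dehydrogenase subunit 2"` to gene symbols. Unknown names
#' are returned trimmed but otherwise unchanged, so non-focal genes survive
#' parsing.
#'
#' @param name Character vector of raw gene names or product descriptions.
#' @return Character vector of the same length with canonical names where
#'   recognized.
#' @export
#' @examples
#' normalize_gene_name(c("NDHB", " ndhe", "NADH dehydrogenase subunit 2"))
normalize_gene_name <- function(name) {
  out <- trimws(name)
  low <- tolower(out)
  hit <- match(low, tolower(.canonical_genes))
  out[!is.na(hit)] <- .canonical_genes[hit[!is.na(hit)]]
  syn <- .gene_synonyms()
  rest <- is.na(hit)
  if (any(rest)) {
    shit <- match(low[rest], names(syn))
    out[rest][!is.na(shit)] <- unname(syn[shit[!is.na(shit)]])
  }
  out
}

# ---- location strings ---------------------------------------------------

# Parse a GenBank location string into strand and a list of 1-based
# inclusive (start, end) pairs in annotation order. Returns NULL for
# locations this parser cannot resolve (the caller skips the feature with
# a warning, per the module contract).
.parse_location <- function(loc) {
  loc <- gsub("[[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    if (!endsWith(loc, ")")) return(NULL)
    loc <- substr(loc, 12L, nchar(loc) - 1L)
    strand <- "-"
  }
  if (grepl("^(join|order)\\(", loc)) {
    if (!endsWith(loc, ")")) return(NULL)
    loc <- sub("^(join|order)\\(", "", loc)
    loc <- substr(loc, 1L, nchar(loc) - 1L)
  }
  # inner complement() (trans-spliced, mixed strands) is out of contract
  if (grepl("complement|join|order|\\(", loc)) return(NULL)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  if (!length(parts)) return(NULL)
  segs <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- gsub("[<>]", "", parts[i])
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", p)) {
      ab <- rep(as.integer(p), 2L)
    } else {
      return(NULL)
    }
    if (is.na(ab[1]) || is.na(ab[2]) || ab[1] < 1L) return(NULL)
    segs[[i]] <- ab
  }
  list(strand = strand, segments = segs)
}

# Convert 1-based inclusive segments to 0-based half-open, splitting
# origin-spanning segments (end > sequence length) on circular records.
.normalize_segments <- function(segs, seq_len, is_circular) {
  out <- list()
  for (ab in segs) {
    a <- ab[1]; b <- ab[2]
    if (b <= seq_len) {
      out[[length(out) + 1L]] <- c(a - 1L, b)
    } else if (is_circular && a <= seq_len && b - seq_len < a) {
      out[[length(out) + 1L]] <- c(a - 1L, seq_len)
      out[[length(out) + 1L]] <- c(0L, b - seq_len)
    } else {
      return(NULL)
    }
  }
  out
}

# ---- gene observations --------------------------------------------------

new_gene_observation <- function(gene_name, sample_id, segments, strand,
                                 sequence, copy_index = 1L) {
  structure(
    list(gene_name = gene_name, sample_id = sample_id,
         segments = segments, strand = strand, sequence = sequence,
         length_bp = nchar(sequence), copy_index = as.integer(copy_index)),
    class = "gene_observation")
}

#' @export
print.gene_observation <- function(x, ...) {
  cat(sprintf("<gene_observation> %s | %s | copy %d | %d bp | strand %s\n",
              x$sample_id, x$gene_name, x$copy_index, x$length_bp, x$strand))
  invisible(x)
}

# ---- plastome records ---------------------------------------------------

#' Parse an annotated plastome from a GenBank flat file
#'
#' Reads a GenBank flat file (plain or gzip-compressed), extracts the
#' sequence and the annotated features of the requested kinds, and resolves
#' each feature's location into one strand-corrected gene observation.
#' `join(...)` and `complement(...)` locations are handled; on circular
#' records a segment running past the end of the sequence is split at the
#' origin into two segments that are concatenated in annotation order.
#' Features whose location cannot be resolved (e.g. trans-spliced
#' mixed-strand joins) are skipped with a warning rather than aborting the
#' parse.
#'
#' When a gene carries both a `gene` and a `CDS` annotation, the CDS is
#' preferred for sequence extraction because it carries the reading frame
#' needed by the premature-stop test; the `gene` feature is the fallback.
#' Inverted-repeat duplicates are all retained and distinguished by
#' `copy_index` in annotation order.
#'
#' @param path Path to a GenBank flat file (`.gb`, `.gbk`, optionally
#'   `.gz`).
#' @param feature_kinds Feature table kinds to harvest. Default
#'   `c("gene", "CDS")`.
#' @return A `plastome_record`: list with `sample_id`, `taxon_name`,
#'   `sequence`, `length_bp`, `is_circular` and `features` (a list of
#'   `gene_observation`).
#' @export
#' @examples
#' cohort <- simulate_cohort(simulate_tree(2, seed = 1),
#'                           simulation_config(n_samples = 2),
#'                           dir = tempfile())
#' rec <- parse_plastome(cohort$files[[1]])
#' rec
parse_plastome <- function(path, feature_kinds = c("gene", "CDS")) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines)) stop("empty GenBank file: ", path)

  locus <- grep("^LOCUS", lines, value = TRUE)
  is_circular <- length(locus) > 0 && grepl("circular", locus[1],
                                            ignore.case = TRUE)
  locus_name <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])),
                                            "\\s+")[[1]][1] else NA_character_

  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line)) {
    strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  } else NA_character_
  sample_id <- if (!is.na(accession) && nzchar(accession)) accession
               else if (!is.na(locus_name)) locus_name
               else sub("\\.(gb|gbk|genbank)(\\.gz)?$", "", basename(path))

  org_line <- grep("^ {2}ORGANISM", lines, value = TRUE)
  taxon_name <- if (length(org_line)) trimws(sub("^ {2}ORGANISM", "",
                                                 org_line[1])) else NA_character_

  origin_at <- grep("^ORIGIN", lines)
  if (!length(origin_at)) stop("GenBank file has no ORIGIN sequence section: ",
                               path)
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at)) end_at[end_at > origin_at[1]][1] else
    length(lines) + 1L
  if (is.na(end_at)) end_at <- length(lines) + 1L
  seq_lines <- lines[seq(origin_at[1] + 1L, end_at - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("GenBank ORIGIN section contains no sequence: ",
                             path)
  seq_len <- nchar(sequence)

  feat_at <- grep("^FEATURES", lines)
  features <- list()
  if (length(feat_at)) {
    block <- lines[seq(feat_at[1] + 1L, origin_at[1] - 1L)]
    starts <- grep("^ {5}\\S", block)
    for (i in seq_along(starts)) {
      from <- starts[i]
      to <- if (i < length(starts)) starts[i + 1L] - 1L else length(block)
      flines <- block[from:to]
      kind <- sub("^ {5}(\\S+).*$", "\\1", flines[1])
      if (!(kind %in% feature_kinds)) next
      body <- c(sub("^ {5}\\S+\\s*", "", flines[1]),
                trimws(flines[-1]))
      qual_at <- grep("^/", body)
      loc <- paste(body[seq_len(if (length(qual_at)) qual_at[1] - 1L
                                else length(body))], collapse = "")
      quals <- if (length(qual_at)) {
        .parse_qualifiers(body[qual_at[1]:length(body)])
      } else list()
      gene <- quals[["gene"]]
      if (is.null(gene)) gene <- quals[["product"]]
      if (is.null(gene) || !nzchar(gene)) next
      gene <- normalize_gene_name(gene)

      parsed <- .parse_location(loc)
      if (is.null(parsed)) {
        warning(sprintf("skipping feature '%s' (%s): unresolvable location '%s'",
                        gene, kind, loc), call. = FALSE)
        next
      }
      segs <- .normalize_segments(parsed$segments, seq_len, is_circular)
      if (is.null(segs)) {
        warning(sprintf("skipping feature '%s' (%s): coordinates outside sequence",
                        gene, kind), call. = FALSE)
        next
      }
      fwd <- paste(vapply(segs, function(s)
        substr(sequence, s[1] + 1L, s[2]), ""), collapse = "")
      obs_seq <- if (parsed$strand == "-") revcomp(fwd) else fwd
      features[[length(features) + 1L]] <- list(
        kind = kind,
        obs = new_gene_observation(gene, sample_id, segs, parsed$strand,
                                   obs_seq))
    }
  }

  # CDS-preference: when a gene has any CDS feature, drop its gene-kind
  # features; then assign copy_index per gene in annotation order.
  kinds <- vapply(features, `[[`, "", "kind")
  names_ <- vapply(features, function(f) f$obs$gene_name, "")
  has_cds <- unique(names_[kinds == "CDS"])
  keep <- !(kinds == "gene" & names_ %in% has_cds)
  obs <- lapply(features[keep], `[[`, "obs")
  nm <- names_[keep]
  for (g in unique(nm)) {
    idx <- which(nm == g)
    for (j in seq_along(idx)) obs[[idx[j]]]$copy_index <- j
  }

  structure(
    list(sample_id = sample_id, taxon_name = taxon_name, sequence = sequence,
         length_bp = seq_len, is_circular = is_circular, features = obs),
    class = "plastome_record")
}

# split qualifier lines (each starting "/") into a named list; multi-line
# quoted values are re-joined before splitting.
.parse_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  # re-group: a new qualifier starts with "/", continuations do not
  starts <- grep("^/", lines)
  if (!length(starts)) return(list())
  out <- list()
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    q <- paste(lines[from:to], collapse = " ")
    m <- regmatches(q, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?', q))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- m[3]
  }
  out
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s (%s)\n  %d bp, %s, %d gene feature(s)\n",
              x$sample_id, x$taxon_name, x$length_bp,
              if (x$is_circular) "circular" else "linear", length(x$features)))
  invisible(x)
}

#' Extract all observations of one gene from a parsed record
#'
#' @param record A `plastome_record` from [parse_plastome()].
#' @param gene_name Gene name; normalized before matching.
#' @return List of `gene_observation`, ordered by `copy_index`. Empty list
#'   when the gene is not annotated -- absence is a meaningful result that
#'   feeds the "lost" state downstream.
#' @export
extract_gene <- function(record, gene_name) {
  stopifnot(inherits(record, "plastome_record"))
  g <- normalize_gene_name(gene_name)
  hits <- Filter(function(o) o$gene_name == g, record$features)
  hits[order(vapply(hits, `[[`, 1L, "copy_index"))]
}

#' Write gene observations to a FASTA file
#'
#' One record per observation with header `sample_id|gene_name|copy_index`,
#' wrapped at 70 columns.
#'
#' @param observations Non-empty list of `gene_observation`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_fasta <- function(observations, path) {
  if (!length(observations)) stop("no observations to write")
  seqs <- vapply(observations, `[[`, "", "sequence")
  names(seqs) <- vapply(observations, function(o)
    paste(o$sample_id, o$gene_name, o$copy_index, sep = "|"), "")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 70L)
  invisible(path)
}
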