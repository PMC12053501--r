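# Synthetic annotated plastome cohorts with planted gene states.
#
# The generator's purpose is to hit the classifier's decision boundaries
# exactly, not to model molecular evolution: functional genes are stop-free
# ORFs of the true length, truncated genes carry one substituted internal
# stop, pseudogenized genes are shortened to a fixed fraction of the true
# length, lost genes are deleted (or left as sub-20% fragments), and
# background substitutions are rejection-sampled so they can never create
# or destroy a planted stop codon.

#' Default true gene lengths for the simulator
#'
#' The eleven ndh genes at their cohort reference lengths rounded to the
#' nearest multiple of three (coding sequences are codon-aligned).
#'
#' @return Named integer vector, gene -> length in bp.
#' @export
default_gene_lengths <- function() {
  c(ndhA = 2262L, ndhB = 2241L, ndhC = 363L, ndhD = 1512L, ndhE = 306L,
    ndhF = 2118L, ndhG = 531L, ndhH = 1182L, ndhI = 495L, ndhJ = 477L,
    ndhK = 765L)
}

#' Simulation configuration
#'
#' Describes one synthetic cohort: which genes exist and how long their
#' intact copies are, where along the tree each non-functional state is
#' planted, and the effect sizes of the planted states. Defaults keep the
#' planted states well clear of the classification boundaries:
#' pseudogenized copies at 50\% of the true length (inside the 20--80\%
#' pseudogene band), lost fragments at 10\% (below the 20\% lost bound),
#' and planted stops at mid-gene.
#'
#' @param n_samples Number of samples (tree tips).
#' @param genes Named integer vector of true gene lengths in bp; every
#'   length must be a multiple of 3. Default [default_gene_lengths()].
#' @param tree_seed,mutation_seed Integer seeds for the tree shape and for
#'   the sequence-level randomness.
#' @param state_scenario Data frame with columns `gene`, `tips`
#'   (one tip label, or several joined by `";"` -- the state is applied to
#'   the whole clade spanned by their most recent common ancestor) and
#'   `state` (one of functional/truncated/pseudogenized/lost). Unlisted
#'   (tip, gene) pairs are functional. `NULL` means all functional.
#' @param pseudo_length_factor Planted pseudogene length as a fraction of
#'   the true length; must lie outside the functional window and above the
#'   lost bound. Default 0.5.
#' @param lost_fragment_factor Planted lost-fragment length fraction; must
#'   be below the lost bound. Default 0.1.
#' @param stop_position_fraction Relative codon position of the planted
#'   internal stop in truncated genes. Default 0.5.
#' @param background_substitution_rate Per-site substitution probability
#'   applied on top of the planted states. Default 0.01.
#' @param lost_mode `"deleted"` (gene removed and unannotated, the
#'   default) or `"fragment"` (annotated fragment below the lost bound).
#' @param ir_genes Genes to duplicate, emulating the inverted repeat
#'   (second identical annotated copy). Default none.
#' @param span_origin When `TRUE` the circular genome is rotated so the
#'   first gene spans the origin and must be annotated as a two-segment
#'   join. Default `FALSE`.
#' @param spacer_bp Length of the random intergenic spacers. Default 200.
#' @param thresholds Thresholds used only to validate that the planted
#'   effect sizes respect the classification boundaries.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(n_samples,
                              genes = default_gene_lengths(),
                              tree_seed = 1L, mutation_seed = 2L,
                              state_scenario = NULL,
                              pseudo_length_factor = 0.5,
                              lost_fragment_factor = 0.1,
                              stop_position_fraction = 0.5,
                              background_substitution_rate = 0.01,
                              lost_mode = c("deleted", "fragment"),
                              ir_genes = character(0),
                              span_origin = FALSE,
                              spacer_bp = 200L,
                              thresholds = audit_thresholds()) {
  lost_mode <- match.arg(lost_mode)
  stopifnot(is.numeric(genes), !is.null(names(genes)), all(genes > 0))
  if (any(genes %% 3L != 0L))
    stop("every true gene length must be a multiple of 3")
  if (pseudo_length_factor >= thresholds$pseudo_lower &&
      pseudo_length_factor <= thresholds$pseudo_upper)
    stop("pseudo_length_factor must lie outside the functional window")
  if (pseudo_length_factor <= thresholds$lost_fraction)
    stop("pseudo_length_factor must exceed lost_fraction")
  if (lost_fragment_factor >= thresholds$lost_fraction)
    stop("lost_fragment_factor must be below lost_fraction")
  if (stop_position_fraction <= 0 || stop_position_fraction >= 1)
    stop("stop_position_fraction must be in (0, 1)")
  if (!is.null(state_scenario)) {
    stopifnot(is.data.frame(state_scenario),
              all(c("gene", "tips", "state") %in% names(state_scenario)))
    bad <- setdiff(state_scenario$state, GENE_STATES)
    if (length(bad)) stop("unknown state(s) in scenario: ",
                          paste(bad, collapse = ", "))
    bad <- setdiff(state_scenario$gene, names(genes))
    if (length(bad)) stop("scenario names unknown gene(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(list(n_samples = as.integer(n_samples),
                 genes = stats::setNames(as.integer(genes), names(genes)),
                 tree_seed = as.integer(tree_seed),
                 mutation_seed = as.integer(mutation_seed),
                 state_scenario = state_scenario,
                 pseudo_length_factor = pseudo_length_factor,
                 lost_fragment_factor = lost_fragment_factor,
                 stop_position_fraction = stop_position_fraction,
                 background_substitution_rate = background_substitution_rate,
                 lost_mode = lost_mode, ir_genes = ir_genes,
                 span_origin = span_origin,
                 spacer_bp = as.integer(spacer_bp)),
            class = "simulation_config")
}

#' Simulate a random rooted bifurcating tree
#'
#' Random topology with exponential branch lengths and tips labeled
#' `s01, s02, ...`. Identical seeds give byte-identical Newick strings.
#'
#' @param n_samples Number of tips, at least 2.
#' @param seed Integer seed.
#' @return An [ape::phylo] tree.
#' @export
simulate_tree <- function(n_samples, seed = 1L) {
  if (n_samples < 2L) stop("`n_samples` must be at least 2")
  set.seed(seed)
  tree <- ape::rtree(n_samples, rooted = TRUE, br = stats::rexp)
  tree$tip.label <- sprintf("s%02d", seq_len(n_samples))
  tree
}

# ---- sequence construction ---------------------------------------------

.STOPS <- c("TAA", "TAG", "TGA")
.ALL_CODONS <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 c("A", "C", "G", "T")), 1, paste,
                     collapse = "")
.SENSE_CODONS <- setdiff(.ALL_CODONS, .STOPS)

random_sense_codons <- function(n) {
  if (n <= 0L) return(character(0))
  sample(.SENSE_CODONS, n, replace = TRUE)
}

# intact ORF: ATG, sense codons, one terminal stop
functional_orf <- function(length_bp) {
  n_codons <- length_bp %/% 3L
  stopifnot(n_codons >= 2L)
  paste0("ATG", paste(random_sense_codons(n_codons - 2L), collapse = ""),
         "TAA")
}

# stop-free coding-frame fragment of an arbitrary length
stop_free_fragment <- function(length_bp) {
  if (length_bp <= 0L) return("")
  n_codons <- ceiling(length_bp / 3)
  s <- paste(c("ATG", random_sense_codons(n_codons - 1L))[seq_len(n_codons)],
             collapse = "")
  substr(s, 1L, length_bp)
}

# one planted gene copy for a given state; returns sequence, the length to
# record in the truth table, and the planted stop index (or NA)
plant_gene <- function(state, true_length, config) {
  if (state == "functional") {
    list(seq = functional_orf(true_length), length = true_length,
         stop_index = NA_integer_)
  } else if (state == "truncated") {
    s <- functional_orf(true_length)
    n_codons <- true_length %/% 3L
    k <- max(2L, min(n_codons - 1L,
                     floor(config$stop_position_fraction * n_codons)))
    substr(s, 3L * (k - 1L) + 1L, 3L * k) <- "TAA"
    list(seq = s, length = true_length, stop_index = k)
  } else if (state == "pseudogenized") {
    len <- as.integer(round_half_up(config$pseudo_length_factor *
                                      true_length))
    list(seq = stop_free_fragment(len), length = len,
         stop_index = NA_integer_)
  } else {  # lost
    if (config$lost_mode == "deleted") {
      list(seq = NULL, length = 0L, stop_index = NA_integer_)
    } else {
      len <- as.integer(round_half_up(config$lost_fragment_factor *
                                        true_length))
      list(seq = stop_free_fragment(len), length = len,
           stop_index = NA_integer_)
    }
  }
}

# Background substitutions on a coding sequence. Protected codons (the
# start, the planted internal stop, the terminal stop) are untouched; in
# every other codon a proposed substitution is rejected if it would create
# a stop, so planted states survive mutation exactly.
mutate_coding <- function(seq, rate, protected_codons = integer(0)) {
  if (rate <= 0 || !nzchar(seq)) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    codon_idx <- (i - 1L) %/% 3L + 1L
    if (codon_idx %in% protected_codons) next
    alt <- setdiff(c("A", "C", "G", "T"), chars[i])
    new <- sample(alt, 1L)
    start <- 3L * (codon_idx - 1L) + 1L
    if (start + 2L <= length(chars)) {
      codon <- chars[start:(start + 2L)]
      codon[i - start + 1L] <- new
      if (paste(codon, collapse = "") %in% .STOPS) next
    }
    chars[i] <- new
  }
  paste(chars, collapse = "")
}

random_spacer <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- scenario expansion -------------------------------------------------

# tip -> state for one gene, with Dollo-consistency (conflict) checking
expand_scenario <- function(tree, config) {
  tips <- tree$tip.label
  states <- matrix("functional", length(tips), length(config$genes),
                   dimnames = list(tips, names(config$genes)))
  sc <- config$state_scenario
  if (is.null(sc)) return(states)
  assigned <- matrix(FALSE, length(tips), length(config$genes),
                     dimnames = dimnames(states))
  for (r in seq_len(nrow(sc))) {
    anchor <- strsplit(sc$tips[r], ";", fixed = TRUE)[[1]]
    bad <- setdiff(anchor, tips)
    if (length(bad)) stop("scenario names unknown tip(s): ",
                          paste(bad, collapse = ", "))
    clade <- if (length(anchor) == 1L) anchor else {
      ape::extract.clade(tree, ape::getMRCA(tree, anchor))$tip.label
    }
    g <- sc$gene[r]
    conflict <- assigned[clade, g] & states[clade, g] != sc$state[r]
    if (any(conflict)) {
      stop(sprintf(
        "scenario violates Dollo consistency: tip(s) %s get conflicting states for %s",
        paste(clade[conflict], collapse = ", "), g))
    }
    states[clade, g] <- sc$state[r]
    assigned[clade, g] <- TRUE
  }
  states
}

# ---- GenBank writing ----------------------------------------------------

format_location <- function(segments, strand, seq_len) {
  # segments are 1-based inclusive (start, end) pairs in annotation order
  parts <- vapply(segments, function(s) sprintf("%d..%d", s[1], s[2]), "")
  loc <- if (length(parts) > 1L) sprintf("join(%s)",
                                         paste(parts, collapse = ","))
         else parts
  if (strand == "-") sprintf("complement(%s)", loc) else loc
}

write_genbank <- function(path, sample_id, taxon, sequence, features,
                          circular = TRUE) {
  L <- nchar(sequence)
  con <- file(path, "wt")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LOCUS       %s %d bp    DNA     %s PLN 01-JAN-2026",
    sample_id, L, if (circular) "circular" else "linear")
  w("DEFINITION  %s plastid, synthetic cohort member.", taxon)
  w("ACCESSION   %s", sample_id)
  w("SOURCE      %s", taxon)
  w("  ORGANISM  %s", taxon)
  w("FEATURES             Location/Qualifiers")
  w("     source          1..%d", L)
  w("                     /organism=\"%s\"", taxon)
  for (f in features) {
    loc <- format_location(f$segments, f$strand, L)
    for (kind in c("gene", "CDS")) {
      w("     %-16s%s", kind, loc)
      w("                     /gene=\"%s\"", f$gene)
      if (kind == "CDS") {
        w("                     /codon_start=1")
        w("                     /transl_table=11")
      }
    }
  }
  w("ORIGIN")
  low <- tolower(sequence)
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(low, p, min(p + 59L, L))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    w("%9d %s", p, paste(blocks, collapse = " "))
  }
  w("//")
  invisible(path)
}

# ---- cohort simulation --------------------------------------------------

#' Simulate an annotated plastome cohort with planted gene states
#'
#' Builds, for every tip of `tree`, a circular "plastome" consisting of
#' random intergenic spacers and one planted copy of each configured gene
#' in the state the scenario assigns to that tip, writes each sample as a
#' GenBank flat file, and emits the truth table alongside. The planted
#' states are constructed to be exactly recoverable by the classifier:
#' see [simulation_config()] for the effect sizes.
#'
#' Output files (all plain text): one `<tip>.gb` per sample, `tree.nwk`,
#' `truth.tsv` and `config.json` under `dir`.
#'
#' @param tree A rooted [ape::phylo] tree, e.g. from [simulate_tree()].
#' @param config A [simulation_config()]. Its `n_samples` must match the
#'   number of tips.
#' @param dir Output directory (created if needed).
#' @return List with `files` (named character vector of GenBank paths),
#'   `truth` (the truth table data frame), `tree`, `states` (tip x gene
#'   matrix of planted states), `sequences` (per tip, the post-mutation
#'   coding-strand sequence of every non-deleted gene copy), `strands`
#'   (per-gene genomic strand) and `dir`.
#' @export
simulate_cohort <- function(tree, config, dir = tempfile("cohort")) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "simulation_config"))
  if (length(tree$tip.label) != config$n_samples)
    stop("config$n_samples does not match the number of tree tips")
  states <- expand_scenario(tree, config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$mutation_seed)

  gene_names <- names(config$genes)
  # fixed strand assignment: every other gene on the minus strand
  strands <- stats::setNames(rep(c("+", "-"), length.out =
                                   length(gene_names)), gene_names)
  files <- character(0)
  truth <- list()
  sequences <- list()
  for (tip in tree$tip.label) {
    sequences[[tip]] <- character(0)
    seq_parts <- character(0)
    feats <- list()
    at <- 0L
    add_spacer <- function() {
      sp <- random_spacer(config$spacer_bp)
      seq_parts[[length(seq_parts) + 1L]] <<- sp
      at <<- at + nchar(sp)
    }
    add_spacer()
    for (g in gene_names) {
      st <- states[tip, g]
      planted <- plant_gene(st, config$genes[[g]], config)
      protected <- if (st == "truncated") {
        c(1L, planted$stop_index, nchar(planted$seq) %/% 3L)
      } else if (st == "functional") {
        c(1L, nchar(planted$seq) %/% 3L)
      } else 1L
      truth[[length(truth) + 1L]] <- df(
        sample_id = tip, gene_name = g, planted_state = st,
        planted_length_bp = planted$length,
        planted_stop_codon_index = planted$stop_index)
      if (is.null(planted$seq)) next  # deleted: no sequence, no feature
      gs <- mutate_coding(planted$seq, config$background_substitution_rate,
                          protected)
      sequences[[tip]][[g]] <- gs
      n_copies <- if (g %in% config$ir_genes) 2L else 1L
      for (copy in seq_len(n_copies)) {
        genomic <- if (strands[[g]] == "-") revcomp(gs) else gs
        seq_parts[[length(seq_parts) + 1L]] <- genomic
        feats[[length(feats) + 1L]] <- list(
          gene = g, strand = strands[[g]],
          segments = list(c(at + 1L, at + nchar(genomic))))
        at <- at + nchar(genomic)
        add_spacer()
      }
    }
    genome <- paste(seq_parts, collapse = "")
    L <- nchar(genome)

    if (config$span_origin && length(feats)) {
      # rotate so the first gene wraps around the origin
      f1 <- feats[[1]]$segments[[1]]
      r <- f1[1] + (f1[2] - f1[1] + 1L) %/% 2L  # cut point inside gene 1
      genome <- paste0(substr(genome, r + 1L, L), substr(genome, 1L, r))
      shift <- function(p) {
        q <- p - r
        if (q < 1L) q + L else q
      }
      for (i in seq_along(feats)) {
        ab <- feats[[i]]$segments[[1]]
        a <- shift(ab[1]); b <- shift(ab[2])
        feats[[i]]$segments <- if (a <= b) list(c(a, b))
                               else list(c(a, L), c(1L, b))
      }
    }

    path <- file.path(dir, paste0(tip, ".gb"))
    write_genbank(path, tip, paste("Synthetica", tip), genome, feats)
    files[[tip]] <- path
  }
  truth <- do.call(rbind, truth)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  cfg <- config
  cfg$state_scenario <- if (is.null(cfg$state_scenario)) NULL else
    as.list(cfg$state_scenario)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  list(files = files, truth = truth, tree = tree, states = states,
       sequences = sequences, strands = strands, dir = dir)
}

#' Simulate an alignment with exact statistics
#'
#' Constructs an alignment with exactly `n_variable` variable columns and
#' exactly `floor(pct_missing * n_rows * n_cols)` gap cells, so that
#' [alignment_statistics()] round-trips the request exactly. Variable
#' columns keep one protected `A` and one protected `C` cell that the gap
#' placement may not overwrite.
#'
#' @param n_rows,n_cols Alignment dimensions; `n_rows >= 2` whenever
#'   `n_variable > 0`.
#' @param n_variable Number of variable (SNP) columns, at most `n_cols`.
#' @param pct_missing Fraction of cells to gap, in \[0, 1).
#' @param seed Integer seed.
#' @return A `gene_alignment` with rows `r001, r002, ...`.
#' @export
simulate_alignment <- function(n_rows, n_cols, n_variable, pct_missing,
                               seed = 1L) {
  if (n_variable > n_cols) stop("n_variable exceeds n_cols")
  if (n_variable > 0 && n_rows < 2L)
    stop("variable columns need at least 2 rows")
  if (pct_missing < 0 || pct_missing >= 1) stop("pct_missing must be in [0,1)")
  n_missing <- floor(pct_missing * n_rows * n_cols)
  set.seed(seed)
  m <- matrix("A", n_rows, n_cols)
  var_cols <- sort(sample.int(n_cols, n_variable))
  protected <- matrix(FALSE, n_rows, n_cols)
  for (j in var_cols) {
    rr <- sample.int(n_rows, 2L)
    m[rr[2], j] <- "C"
    protected[rr, j] <- TRUE
  }
  free <- which(!protected)
  if (n_missing > length(free))
    stop(sprintf("infeasible: %d gap cells requested but only %d cells free",
                 n_missing, length(free)))
  if (n_missing > 0) m[sample(free, n_missing)] <- "-"
  rows <- apply(m, 1L, paste, collapse = "")
  gene_alignment("sim", stats::setNames(rows,
                                        sprintf("r%03d", seq_len(n_rows))))
}
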