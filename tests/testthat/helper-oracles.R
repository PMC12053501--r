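# Shared fixtures and independent oracles.

# A bare gene observation for tests that do not need a full GenBank parse.
make_obs <- function(gene, length_bp = NULL, sequence = NULL,
                     sample_id = "sX", copy_index = 1L, strand = "+") {
  if (is.null(sequence)) sequence <- strrep("A", length_bp)
  ndhaudit:::new_gene_observation(gene, sample_id,
                                  list(c(0L, nchar(sequence))), strand,
                                  sequence, copy_index)
}

# Hand-assembled GenBank flat-file text. `features` is a list of lists with
# fields kind, location, quals (named character vector).
make_genbank <- function(sequence, features, locus = "TEST01",
                         circular = TRUE, organism = "Testus testus") {
  L <- nchar(sequence)
  out <- c(
    sprintf("LOCUS       %s %d bp    DNA     %s PLN 01-JAN-2026",
            locus, L, if (circular) "circular" else "linear"),
    sprintf("DEFINITION  %s synthetic test record.", organism),
    sprintf("ACCESSION   %s", locus),
    sprintf("SOURCE      %s", organism),
    sprintf("  ORGANISM  %s", organism),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L),
    sprintf("                     /organism=\"%s\"", organism))
  for (f in features) {
    out <- c(out, sprintf("     %-16s%s", f$kind, f$location))
    for (q in names(f$quals)) {
      out <- c(out, sprintf("                     /%s=\"%s\"", q,
                            f$quals[[q]]))
    }
  }
  out <- c(out, "ORIGIN")
  low <- tolower(sequence)
  for (p in seq(1L, L, by = 60L)) {
    chunk <- substr(low, p, min(p + 59L, L))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L),
                             nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(blocks, collapse = " ")))
  }
  c(out, "//")
}

write_genbank_fixture <- function(sequence, features, ...) {
  path <- tempfile(fileext = ".gb")
  writeLines(make_genbank(sequence, features, ...), path)
  path
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Exhaustive small-parsimony oracle: minimize the number of changes over
# all assignments of states to internal nodes. Exact for any rooted tree;
# only feasible for small tip counts.
brute_force_parsimony <- function(tree, tip_states, root_state = NULL) {
  states <- sort(unique(c(as.character(tip_states), as.character(root_state))))
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  node_state <- character(n_tip + n_node)
  node_state[seq_len(n_tip)] <- as.character(tip_states[tree$tip.label])
  internal <- n_tip + seq_len(n_node)
  grid <- expand.grid(rep(list(states), n_node), stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    node_state[internal] <- unlist(grid[r, ], use.names = FALSE)
    if (!is.null(root_state) &&
        node_state[n_tip + 1L] != root_state) next
    changes <- sum(node_state[tree$edge[, 1]] != node_state[tree$edge[, 2]])
    best <- min(best, changes)
  }
  as.integer(best)
}

# k disjoint clades (tip-label sets) of a rooted binary tree, smallest
# first, such that no two chosen clades merge into a larger clade (sister
# pairs would collapse two planted loss events into one). Deterministic.
pick_disjoint_clades <- function(tree, k, min_size = 2L, max_size = 3L) {
  n_tip <- length(tree$tip.label)
  nodes <- n_tip + seq_len(tree$Nnode)
  all_clades <- lapply(nodes, function(nd)
    sort(ape::extract.clade(tree, nd)$tip.label))
  clade_keys <- vapply(all_clades, paste, "", collapse = "|")
  cand <- Filter(function(x) length(x) >= min_size &
                   length(x) <= max_size & length(x) < n_tip, all_clades)
  cand <- cand[order(vapply(cand, length, 1L))]
  chosen <- list()
  used <- character(0)
  for (cl in cand) {
    if (length(intersect(cl, used))) next
    merges <- any(vapply(chosen, function(ch)
      paste(sort(c(ch, cl)), collapse = "|") %in% clade_keys, TRUE))
    if (merges) next
    chosen[[length(chosen) + 1L]] <- cl
    used <- c(used, cl)
    if (length(chosen) == k) break
  }
  if (length(chosen) < k) stop("could not find ", k, " disjoint clades")
  chosen
}

# Count palette-colored cell elements in a cairo SVG (cells are emitted as
# filled <path> elements; black/white/none fills are text and frame).
count_svg_colored_fills <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  fills <- regmatches(txt, gregexpr('fill="rgb\\([^)]*\\)"', txt))[[1]]
  keep <- !grepl("0%, 0%, 0%|100%, 100%, 100%", fills)
  list(n = sum(keep), distinct = length(unique(fills[keep])))
}
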