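# Mapping gene status onto a phylogeny: parsimony loss counting and the
# matrix-beside-tree figure. Trees are ape "phylo" objects throughout.

#' Read a rooted tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that first checks the file is
#' non-empty and its parentheses balance, reporting the character offset of
#' the first imbalance (ape itself does not).
#'
#' @param path Newick file path.
#' @return An [ape::phylo] object. Node labels (e.g. bootstrap supports)
#'   and branch lengths are kept when present; polytomies are permitted.
#' @export
read_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(trimws(txt))) stop("empty Newick file: ", path)
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop(sprintf("malformed Newick: unmatched ')' at character %d", i))
  }
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' at end of input (%d characters)",
                 depth, length(chars)))
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL)
  if (is.null(tree)) stop("malformed Newick in ", path)
  tree
}

#' Minimum number of state changes on a tree (Fitch parsimony)
#'
#' Computes the small-parsimony minimum number of unweighted state changes
#' required to explain the tip states on a rooted tree. The implementation
#' is a unit-cost dynamic program over the observed state alphabet, which
#' coincides with classic Fitch counting on bifurcating trees and remains
#' exact on polytomies.
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param tip_states Named vector (names = tip labels) of states from a
#'   finite alphabet; every tip must have a state.
#' @param root_state Optional state to anchor at the root. Used by
#'   [loss_summary()] to assert that the common ancestor retained the gene
#'   (the Dollo view); `NULL` (default) leaves the root free, matching
#'   plain parsimony.
#' @return Integer minimum number of changes.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch_min_transitions(tr, c(A = "lost", B = "lost",
#'                             C = "retained", D = "retained"))  # 1
fitch_min_transitions <- function(tree, tip_states, root_state = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  missing <- setdiff(tips, names(tip_states))
  if (length(missing))
    stop("tip(s) without a state: ", paste(missing, collapse = ", "))
  states <- sort(unique(c(as.character(tip_states[tips]),
                          as.character(root_state))))
  if (!is.null(root_state) && !(root_state %in% states))
    states <- sort(c(states, root_state))
  S <- length(states)
  if (S == 1L) return(0L)

  n_tip <- length(tips)
  n_node <- tree$Nnode
  cost <- matrix(0, n_tip + n_node, S)
  cost[seq_len(n_tip), ] <- Inf
  for (i in seq_len(n_tip)) {
    cost[i, match(as.character(tip_states[tips[i]]), states)] <- 0
  }
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]
    child <- po$edge[e, 2]
    child_cost <- cost[child, ]
    best <- min(child_cost)
    cost[parent, ] <- cost[parent, ] + pmin(child_cost, best + 1)
  }
  root <- n_tip + 1L
  res <- if (is.null(root_state)) min(cost[root, ])
         else cost[root, match(root_state, states)]
  as.integer(res)
}

#' Per-gene minimal loss events on a phylogeny
#'
#' Binarizes each gene's column of the status matrix and counts the minimal
#' number of state changes on the tree with the root anchored to the
#' ancestral "retained" state (the gene was present in the common
#' ancestor, and what is counted are losses of it). Two encodings are
#' available: the default treats pseudogenized and truncated copies as
#' retained-but-decaying (`lost` alone is the derived state); the
#' alternative counts loss of \emph{function}, deriving every non-functional
#' state.
#'
#' @param tree A rooted [ape::phylo] tree whose tip labels cover the
#'   matrix samples; extra tips are pruned with a warning.
#' @param matrix A `status_matrix` from [build_status_matrix()].
#' @param encoding `"lost_vs_retained"` (default) or
#'   `"functional_vs_nonfunctional"`.
#' @return A `loss_event_summary`: data frame with one row per gene
#'   (`gene_name`, `n_min_losses`, `n_tips_lost_state`, `encoding`) and an
#'   attribute `n_genes_lost_at_least_twice`.
#' @export
loss_summary <- function(tree, matrix,
                         encoding = c("lost_vs_retained",
                                      "functional_vs_nonfunctional")) {
  stopifnot(inherits(tree, "phylo"), inherits(matrix, "status_matrix"))
  encoding <- match.arg(encoding)
  overlap <- intersect(tree$tip.label, matrix$samples)
  if (!length(overlap))
    stop("no overlap between tree tips and status-matrix samples")
  extra <- setdiff(tree$tip.label, matrix$samples)
  if (length(extra)) {
    warning(sprintf("pruning %d tip(s) absent from the status matrix: %s",
                    length(extra), paste(utils::head(extra, 5),
                                         collapse = ", ")), call. = FALSE)
    tree <- ape::keep.tip(tree, overlap)
  }
  derived <- if (encoding == "lost_vs_retained") "lost"
             else c("lost", "pseudogenized", "truncated")
  rows <- lapply(matrix$genes, function(g) {
    st <- matrix$status[overlap, g]
    bin <- stats::setNames(ifelse(st %in% derived, "lost", "retained"),
                           overlap)
    df(gene_name = g,
       n_min_losses = fitch_min_transitions(tree, bin,
                                            root_state = "retained"),
       n_tips_lost_state = sum(bin == "lost"),
       encoding = encoding)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_genes_lost_at_least_twice") <- sum(out$n_min_losses >= 2L)
  class(out) <- c("loss_event_summary", "data.frame")
  out
}

#' @export
print.loss_event_summary <- function(x, ...) {
  NextMethod()
  cat(sprintf("# %d of %d gene(s) lost at least twice\n",
              attr(x, "n_genes_lost_at_least_twice"), nrow(x)))
  invisible(x)
}

#' Default state palette for status figures
#'
#' @return Named character vector of colors for the four states.
#' @export
state_palette <- function() {
  c(functional = "#4daf4a", truncated = "#ffd92f",
    pseudogenized = "#ff7f00", lost = "#999999")
}

#' Draw the status matrix beside the phylogeny
#'
#' Renders the tree on the left and, aligned with its tips, a colored grid
#' with one column per gene and one row per tip, plus a four-state legend.
#' Both an SVG and a PNG are written (`<out>.svg`, `<out>.png`).
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param matrix A `status_matrix`; samples must overlap the tree tips.
#' @param out Output path base; any `.svg`/`.png` extension is stripped.
#' @param palette Named state -> color vector, default [state_palette()].
#' @param show_support Draw node labels (e.g. bootstrap values) above
#'   branches when the tree carries them.
#' @param node_ages Optional numeric vector of ages (one per internal
#'   node, in Ma) drawn below branches; accepted as annotation only, never
#'   computed.
#' @return Invisibly, the character vector of the two files written.
#' @export
render_matrix_tree <- function(tree, matrix, out, palette = state_palette(),
                               show_support = TRUE, node_ages = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(matrix, "status_matrix"))
  if (!length(matrix$samples) || !length(matrix$genes))
    stop("empty status matrix")
  overlap <- intersect(tree$tip.label, matrix$samples)
  if (!length(overlap))
    stop("no overlap between tree tips and status-matrix samples")
  if (length(overlap) < length(tree$tip.label))
    tree <- ape::keep.tip(tree, overlap)
  base <- sub("\\.(svg|png)$", "", out)
  paths <- c(svg = paste0(base, ".svg"), png = paste0(base, ".png"))
  n_tip <- length(tree$tip.label)
  n_gene <- length(matrix$genes)
  h_in <- max(3, 0.24 * n_tip + 1.2)
  w_in <- max(6, 4 + 0.28 * n_gene)

  for (fmt in names(paths)) {
    if (fmt == "svg") grDevices::svg(paths[["svg"]], width = w_in,
                                     height = h_in)
    else grDevices::png(paths[["png"]], width = w_in, height = h_in,
                        units = "in", res = 150)
    graphics::par(mar = c(1, 1, 1, 1), xpd = NA)
    if (is.null(tree$edge.length)) {
      # cladogram: unit branch lengths for drawing only
      tree$edge.length <- rep(1, nrow(tree$edge))
    }
    depth <- max(ape::node.depth.edgelength(tree))
    if (depth <= 0) depth <- 1
    grid_w <- 0.65 * depth
    ape::plot.phylo(tree, show.tip.label = TRUE, label.offset = 0.01 * depth,
                    x.lim = c(0, 1.85 * depth + grid_w), cex = 0.7,
                    no.margin = FALSE)
    lastPP <- get("last_plot.phylo", envir = ape::.PlotPhyloEnv)
    tip_y <- lastPP$yy[seq_len(n_tip)]
    x0 <- max(lastPP$xx[seq_len(n_tip)]) + 0.55 * depth
    cell_w <- grid_w / n_gene
    for (j in seq_len(n_gene)) {
      g <- matrix$genes[j]
      for (i in seq_len(n_tip)) {
        st <- matrix$status[tree$tip.label[i], g]
        graphics::rect(x0 + (j - 1) * cell_w, tip_y[i] - 0.4,
                       x0 + j * cell_w, tip_y[i] + 0.4,
                       col = palette[[st]], border = "white", lwd = 0.4)
      }
      graphics::text(x0 + (j - 0.5) * cell_w, max(tip_y) + 0.9, g,
                     srt = 90, adj = 0, cex = 0.55)
    }
    if (show_support && !is.null(tree$node.label)) {
      lab <- tree$node.label
      lab[is.na(lab)] <- ""
      ape::nodelabels(lab, frame = "none", adj = c(1.1, -0.4), cex = 0.5)
    }
    if (!is.null(node_ages)) {
      ape::nodelabels(format(node_ages, digits = 3), frame = "none",
                      adj = c(1.1, 1.4), cex = 0.5, col = "grey30")
    }
    graphics::legend("bottomright", legend = names(palette),
                     fill = unname(palette), bty = "n", cex = 0.7,
                     title = "gene state")
    grDevices::dev.off()
  }
  invisible(unname(paths))
}
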