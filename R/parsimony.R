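#' Read a rooted tree and character matrix from NEXUS
#'
#' Trees are read with [ape::read.nexus()] (translate tables honored; newick
#' files are accepted via [ape::read.tree()] as a fallback) and STANDARD
#' character matrices with [ape::read.nexus.data()]. Taxa are cross-checked
#' between the two sources and mismatches reported by name.
#'
#' @param tree_path NEXUS (or newick) tree file.
#' @param matrix_path NEXUS file holding the DATA/CHARACTERS block; may be
#'   the same file as `tree_path`.
#' @return list with `tree` (an [ape] `phylo`, polytomies preserved) and
#'   `matrix` (character matrix of symbols, rows = taxa).
#' @export
read_nexus_inputs <- function(tree_path, matrix_path) {
  tree <- tryCatch(ape::read.nexus(tree_path), error = function(e) NULL)
  if (is.null(tree)) tree <- ape::read.tree(tree_path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (ape::Ntip(tree) < 2) stop("read_nexus_inputs: tree has < 2 tips")

  dat <- ape::read.nexus.data(matrix_path)
  mat <- do.call(rbind, lapply(dat, toupper))
  rownames(mat) <- names(dat)

  only_tree <- setdiff(tree$tip.label, rownames(mat))
  only_mat <- setdiff(rownames(mat), tree$tip.label)
  if (length(only_tree) || length(only_mat)) {
    stop("read_nexus_inputs: taxa mismatch; only in tree: [",
         paste(only_tree, collapse = ", "), "]; only in matrix: [",
         paste(only_mat, collapse = ", "), "]")
  }
  list(tree = tree, matrix = mat)
}

#' Unordered-parsimony ancestral-state reconstruction (Sankoff)
#'
#' Dynamic programming over the rooted tree with uniform unit cost between
#' distinct states (equivalent to Fitch parsimony on binary trees, and
#' well-defined on hard multifurcations). Missing tips (`"?"`) contribute
#' zero cost to every state. A down-pass gives the minimum number of state
#' changes; a second (up) pass gives, for every node, the full MPR set: the
#' states attainable under at least one most-parsimonious assignment.
#'
#' @param tree rooted `phylo` object; polytomies allowed; branch lengths
#'   ignored.
#' @param states named character vector mapping every tip label to a state
#'   symbol or `"?"`.
#' @param symbols the character's symbol set; defaults to the sorted distinct
#'   observed states.
#' @param label optional character label carried into the result.
#' @return object of class `parsimony_reconstruction`: list with `score`
#'   (minimum changes), `mpr` (list of state sets, indexed tips first then
#'   internal nodes in `phylo` numbering), `resolved` (state when the MPR set
#'   is a singleton, else NA), `symbols`, `label`.
#' @export
parsimony_reconstruct <- function(tree, states, symbols = NULL,
                                  label = NA_character_) {
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) {
    stop("parsimony_reconstruct: no state for tips: ",
         paste(miss, collapse = ", "))
  }
  obs <- unname(states[tree$tip.label])
  if (is.null(symbols)) symbols <- sort(unique(obs[obs != "?"]))
  bad <- setdiff(unique(obs), c(symbols, "?"))
  if (length(bad)) {
    stop("parsimony_reconstruct: unknown state symbol(s): ",
         paste(bad, collapse = ", "))
  }
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  S <- length(symbols)
  if (S == 0) {                      # all tips missing
    full <- replicate(ntip + nnode, "?", simplify = FALSE)
    return(structure(list(score = 0L, mpr = full,
                          resolved = rep(NA_character_, ntip + nnode),
                          symbols = character(), label = label),
                     class = "parsimony_reconstruction"))
  }
  tre <- ape::reorder.phylo(tree, "postorder")
  edge <- tre$edge
  root <- ntip + 1L

  down <- matrix(0, ntip + nnode, S)
  for (i in seq_len(ntip)) {
    if (obs[i] != "?") {
      down[i, ] <- Inf
      down[i, match(obs[i], symbols)] <- 0
    }
  }
  contrib <- matrix(NA_real_, ntip + nnode, S)  # child's term in its parent
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    contrib[ch, ] <- pmin(down[ch, ], min(down[ch, ]) + 1)
    down[p, ] <- down[p, ] + contrib[ch, ]
  }
  score <- min(down[root, ])

  up <- matrix(0, ntip + nnode, S)
  for (e in rev(seq_len(nrow(edge)))) {          # preorder
    p <- edge[e, 1]; ch <- edge[e, 2]
    v <- up[p, ] + down[p, ] - contrib[ch, ]
    up[ch, ] <- pmin(v, min(v) + 1)
  }

  total <- down + up
  mpr <- lapply(seq_len(ntip + nnode), function(i) {
    symbols[abs(total[i, ] - score) < 1e-9]
  })
  resolved <- vapply(mpr, function(s) {
    if (length(s) == 1) s else NA_character_
  }, character(1))
  structure(list(score = as.integer(round(score)), mpr = mpr,
                 resolved = resolved, symbols = symbols, label = label),
            class = "parsimony_reconstruction")
}

#' @export
print.parsimony_reconstruction <- function(x, ...) {
  cat("<parsimony_reconstruction>",
      if (!is.na(x$label)) paste0(" ", x$label), "\n", sep = "")
  cat("  score: ", x$score, " (symbols: ",
      paste(x$symbols, collapse = ""), ")\n", sep = "")
  invisible(x)
}

#' Reconstruct every character of a matrix on a tree
#'
#' @param tree rooted `phylo`.
#' @param cm a [build_character_matrix()] result, or a plain symbol matrix
#'   (rows = taxa) as returned by [read_nexus_inputs()].
#' @return named list of [parsimony_reconstruct()] results, one per
#'   character, each carrying its parsimony score and MPR sets.
#' @export
reconstruct_all <- function(tree, cm) {
  if (inherits(cm, "character_matrix")) {
    sym <- symbol_matrix(cm)
    symbol_sets <- strsplit(cm$characters$symbols, "")
  } else {
    sym <- cm
    symbol_sets <- replicate(ncol(sym), NULL, simplify = FALSE)
  }
  if (is.null(colnames(sym))) {
    colnames(sym) <- sprintf("char%02d", seq_len(ncol(sym)))
  }
  out <- lapply(seq_len(ncol(sym)), function(j) {
    st <- sym[, j]
    names(st) <- rownames(sym)
    obs <- unique(st[st != "?"])
    symbols <- symbol_sets[[j]]
    if (!is.null(symbols)) symbols <- union(symbols, obs)
    parsimony_reconstruct(tree, st, symbols = symbols,
                          label = colnames(sym)[j])
  })
  names(out) <- colnames(sym)
  out
}

#' Tabulate reconstructions at named nodes
#'
#' Builds the per-axis report behind the mapped trees: one row per
#' (character, node) with the MPR state set and, when unique, the resolved
#' state.
#'
#' @param recons list from [reconstruct_all()].
#' @param tree the tree the reconstructions were computed on.
#' @param nodes named integer vector of node numbers (phylo numbering), or
#'   NULL for all internal nodes (named `node_<k>`, or by `tree$node.label`
#'   when present). Unknown node names are an error.
#' @return data frame with `character`, `node`, `node_number`, `states`
#'   (states collapsed with "|"), `resolved`.
#' @export
summarize_mapping <- function(recons, tree, nodes = NULL) {
  ntip <- ape::Ntip(tree)
  if (is.null(nodes)) {
    nodes <- seq_len(tree$Nnode) + ntip
    names(nodes) <- if (!is.null(tree$node.label) &&
                        all(nzchar(tree$node.label))) {
      tree$node.label
    } else {
      sprintf("node_%d", nodes)
    }
  } else {
    if (is.character(nodes)) {
      if (is.null(tree$node.label)) {
        stop("summarize_mapping: tree has no node labels")
      }
      num <- match(nodes, tree$node.label) + ntip
      if (anyNA(num)) {
        stop("summarize_mapping: unknown node name(s): ",
             paste(nodes[is.na(num)], collapse = ", "))
      }
      names(num) <- nodes
      nodes <- num
    }
    if (any(nodes < 1 | nodes > ntip + tree$Nnode)) {
      stop("summarize_mapping: node number out of range")
    }
    if (is.null(names(nodes))) names(nodes) <- sprintf("node_%d", nodes)
  }
  if (!length(recons)) {
    return(data.frame(character = character(), node = character(),
                      node_number = integer(), states = character(),
                      resolved = character()))
  }
  rows <- lapply(names(recons), function(chname) {
    rec <- recons[[chname]]
    data.frame(
      character = chname,
      node = names(nodes),
      node_number = unname(nodes),
      states = vapply(nodes, function(nd) {
        s <- rec$mpr[[nd]]
        if (!length(s)) "?" else paste(s, collapse = "|")
      }, character(1)),
      resolved = unname(rec$resolved[nodes])
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Eight-tip synthetic demonstration phylogeny
#'
#' A rooted tree over the bundled fixture archetypes and their variants:
#' the two calibration objects as a sister pair, then a long-tailed grade
#' and a short-tailed clade containing one polytomy, mimicking the shape of
#' a consensus tree with unresolved nodes. Purely synthetic; tip names match
#' the demo pipeline's taxa.
#'
#' @return rooted `phylo` with 8 tips and a polytomy.
#' @export
fixture_tree <- function() {
  ape::read.tree(text = paste0(
    "((sphere,weathervane),((longtail_a,longtail_b),",
    "(shorttail_a,(shorttail_b,shorttail_c,shorttail_d))));"))
}
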