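#' @importFrom ape read.tree read.nexus write.tree keep.tip reorder.phylo
NULL

# Validate a rooted tree for use in the CTM machinery: unique labelled tips,
# a branch length on every edge, non-negative lengths. Newick/NEXUS input is
# treated as rooted at its basal node; polytomies (including a basal one) are
# legal because classification-derived language trees are non-binary.
validate_tree <- function(tree, where = "tree") {
  if (!inherits(tree, "phylo")) stop(where, ": not a phylo object")
  if (is.null(tree$tip.label) || !length(tree$tip.label))
    stop(where, ": tree has no tips")
  if (anyDuplicated(tree$tip.label))
    stop(where, ": duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (any(!nzchar(tree$tip.label)) || anyNA(tree$tip.label))
    stop(where, ": unlabelled tip present")
  if (is.null(tree$edge.length))
    stop(where, ": branch lengths missing on every edge")
  if (anyNA(tree$edge.length)) {
    bad <- tree$edge[which(is.na(tree$edge.length))[1], 2]
    stop(where, ": missing branch length on the edge to node ", bad)
  }
  if (any(tree$edge.length < 0))
    stop(where, ": negative branch length")
  # exactly one root: one node that never appears as a child
  kids <- tree$edge[, 2]
  parents <- unique(tree$edge[, 1])
  roots <- setdiff(parents, kids)
  if (length(roots) != 1L) stop(where, ": tree must have exactly one root")
  invisible(tree)
}

#' Parse a rooted Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The tree must carry a
#' branch length on every edge and unique tip labels; polytomies are allowed.
#'
#' @param text a Newick string.
#' @return a rooted \code{phylo} object.
#' @examples
#' parse_newick("(A:1,(B:0.5,C:0.5):0.5);")
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: could not read tree")
  validate_tree(tree, "parse_newick")
}

#' Read trees from a file (Newick or NEXUS)
#'
#' \code{read_tree_file} dispatches on content: a NEXUS file (with optional
#' Translate table) yields all trees of its TREES block, a Newick file all
#' semicolon-terminated trees, in file order. Both return a [tree_set].
#'
#' @param path file path.
#' @return a [tree_set].
#' @export
read_tree_file <- function(path) {
  first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
  trees <- if (startsWith(first, "#NEXUS")) ape::read.nexus(path)
           else ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  tree_set(lapply(trees, identity))
}

#' Parse a NEXUS TREES block from text
#'
#' @param text NEXUS file contents as a single string or character vector.
#' @return a [tree_set] with the trees in file order.
#' @export
parse_nexus <- function(text) {
  tf <- tempfile(fileext = ".nex")
  on.exit(unlink(tf))
  writeLines(text, tf)
  read_tree_file(tf)
}

#' Bundle trees into an equally weighted tree set
#'
#' A tree set represents a posterior sample of phylogenies (or a single
#' tree). All member trees must share a tip set; when they do not, every tree
#' is pruned to the common intersection of tips, with a warning.
#'
#' @param trees a list of \code{phylo} objects (or a single one).
#' @return an object of class \code{tree_set}: a list with \code{trees} and
#'   \code{n_trees}; weights are implicitly uniform.
#' @export
tree_set <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("tree set must contain at least one tree")
  trees <- lapply(seq_along(trees), function(i)
    validate_tree(trees[[i]], paste0("tree ", i)))
  tip_sets <- lapply(trees, `[[`, "tip.label")
  common <- Reduce(intersect, tip_sets)
  if (!all(vapply(tip_sets, function(s) setequal(s, common), TRUE))) {
    if (!length(common)) stop("trees in the set share no tips")
    warning("trees differ in tip sets; pruning all to the ",
            length(common), " shared tips")
    trees <- lapply(trees, prune_to_taxa, keep = common)
  }
  structure(list(trees = trees, n_trees = length(trees)), class = "tree_set")
}

#' @export
print.tree_set <- function(x, ...) {
  cat("Tree set:", x$n_trees, "tree(s),",
      length(x$trees[[1]]$tip.label), "tips\n")
  invisible(x)
}

as_tree_set <- function(x) {
  if (inherits(x, "tree_set")) x else tree_set(x)
}

#' Prune a tree to a set of taxa
#'
#' Drops all tips outside \code{keep} and collapses the resulting
#' unifurcations, summing branch lengths, so that root-to-tip path lengths
#' (and all patristic distances among kept tips) are preserved exactly.
#'
#' @param tree a \code{phylo}.
#' @param keep character vector of tip labels to retain.
#' @return a \code{phylo} (a minimal one-edge tree if a single tip is kept).
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_tree(tree, "prune_to_taxa")
  keep <- intersect(tree$tip.label, keep)
  if (!length(keep)) stop("prune_to_taxa: no requested taxa present in tree")
  if (setequal(keep, tree$tip.label)) return(tree)
  if (length(keep) == 1L) {
    # ape cannot drop to one tip; build the single-edge tree at full depth
    depth <- node_depths(tree)[match(keep, tree$tip.label)]
    out <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = keep,
                edge.length = depth, Nnode = 1L)
    class(out) <- "phylo"
    attr(out, "order") <- "cladewise"
    return(out)
  }
  ape::keep.tip(tree, keep)
}

# root-to-node path lengths, indexed by node id
node_depths <- function(tree) {
  n <- length(tree$tip.label)
  depth <- numeric(n + tree$Nnode)
  ord <- ape::reorder.phylo(tree, "postorder")
  # preorder = reversed postorder edge list
  for (e in rev(seq_len(nrow(ord$edge)))) {
    depth[ord$edge[e, 2]] <- depth[ord$edge[e, 1]] + ord$edge.length[e]
  }
  depth
}

#' Report the match between tree tips and trait records
#'
#' @param tree a \code{phylo}.
#' @param matrix a [trait_matrix].
#' @return a list with \code{tips_without_data} and \code{data_without_tips}
#'   (both empty exactly when tree and data match perfectly).
#' @export
match_taxa <- function(tree, matrix) {
  stopifnot(inherits(matrix, "trait_matrix"))
  list(tips_without_data = setdiff(tree$tip.label, matrix$taxa),
       data_without_tips = setdiff(matrix$taxa, tree$tip.label))
}

#' Rescale a tree to a target mean branch length
#'
#' Multiplies every branch length by one constant so that the mean branch
#' length equals \code{target}. Rescaling is a pure reparameterization:
#' likelihoods are unchanged if all transition rates are divided by the same
#' factor, so it only serves numerical conditioning of rate estimates.
#'
#' @param tree a \code{phylo}.
#' @param target positive target mean branch length.
#' @return the rescaled \code{phylo}.
#' @export
scale_tree <- function(tree, target) {
  validate_tree(tree, "scale_tree")
  stopifnot(target > 0)
  m <- mean(tree$edge.length)
  if (m == 0) stop("scale_tree: tree has zero total length")
  tree$edge.length <- tree$edge.length * (target / m)
  tree
}

#' Rescale a tree to a target root-to-tip depth
#'
#' Scales all branch lengths so the maximum root-to-tip path length equals
#' \code{target}. With unit depth, transition rates read as expected numbers
#' of changes per total tree depth — the convention used throughout the
#' package's simulation studies.
#'
#' @param tree a \code{phylo}.
#' @param target positive target depth.
#' @return the rescaled \code{phylo}.
#' @export
scale_tree_depth <- function(tree, target = 1) {
  validate_tree(tree, "scale_tree_depth")
  stopifnot(target > 0)
  h <- max(node_depths(tree))
  if (h == 0) stop("scale_tree_depth: tree has zero depth")
  tree$edge.length <- tree$edge.length * (target / h)
  tree
}

#' Write a tree as Newick
#'
#' @param tree a \code{phylo}.
#' @param path optional file path; if omitted the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = path); invisible(path) }
}
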