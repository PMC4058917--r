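# Rooted binary trees, indexed for the reconciliation dynamic program.
#
# Internally a tree is a set of integer node ids 1..n_node with parent and
# children arrays, a post-order, and a precomputed ancestry matrix.  Newick
# parsing is delegated to ape; this module only validates the contracts the
# reconciliation model needs (rooted, strictly binary, unique tip labels)
# and converts to the indexed form.

new_rb_tree <- function(parent, children, labels, root) {
  n_node <- length(parent)
  is_tip <- is.na(children[, 1])
  # post-order: children before parents
  post <- integer(0)
  stack <- c(root)
  visit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    visit <- c(visit, v)
    if (!is_tip[v]) stack <- c(stack, children[v, ])
  }
  post <- rev(visit)
  depth <- integer(n_node)
  for (v in visit) depth[v] <- if (is.na(parent[v])) 0L else depth[parent[v]] + 1L
  # anc[x, y] TRUE iff y is an ancestor of x (inclusive)
  anc <- matrix(FALSE, n_node, n_node)
  for (v in visit) {
    anc[v, v] <- TRUE
    if (!is.na(parent[v])) anc[v, ] <- anc[v, ] | anc[parent[v], ]
    anc[v, v] <- TRUE
  }
  structure(list(
    n_node = n_node, n_tip = sum(is_tip), root = root,
    parent = parent, children = children, labels = labels,
    is_tip = is_tip, postorder = post, preorder = visit,
    depth = depth, anc = anc
  ), class = "rb_tree")
}

#' Parse a rooted binary tree from a Newick string
#'
#' Branch lengths and internal node labels are accepted and discarded: the
#' reconciliation model is purely topological.  Redundant outer parentheses
#' (a unary "root wrapper") are collapsed; any other unary node, any
#' polytomy, and duplicate tip labels are errors.
#'
#' @param text a single Newick string terminated by `;`.
#' @return an object of class `rb_tree`.
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' tr$n_tip            # 3
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string")
  if (!grepl(";", text, fixed = TRUE)) stop("Newick string must end with ';'")
  # single-leaf tree: "A;" (ape does not accept a leaf-only Newick)
  if (!grepl("(", text, fixed = TRUE)) {
    lab <- sub(";.*$", "", text)
    lab <- sub(":.*$", "", lab)
    lab <- trimws(lab)
    if (!nzchar(lab) || grepl("[(),]", lab)) stop("malformed Newick string")
    return(new_rb_tree(parent = NA_integer_,
                       children = matrix(NA_integer_, 1, 2),
                       labels = lab, root = 1L))
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("malformed Newick string: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("malformed Newick string")
  as_rb_tree(phy)
}

#' Convert an ape `phylo` object to the internal rooted binary tree
#'
#' @param phy a rooted `phylo` object.
#' @return an object of class `rb_tree`.
#' @export
as_rb_tree <- function(phy) {
  edge <- phy$edge
  n_tip <- length(phy$tip.label)
  n_all <- n_tip + phy$Nnode
  kids <- vector("list", n_all)
  for (i in seq_len(nrow(edge))) kids[[edge[i, 1]]] <- c(kids[[edge[i, 1]]], edge[i, 2])
  parent <- rep(NA_integer_, n_all)
  parent[edge[, 2]] <- edge[, 1]
  root <- setdiff(edge[, 1], edge[, 2])
  if (length(root) != 1) stop("tree is not singly rooted")
  # collapse a unary chain at the root (redundant outer parentheses)
  while (length(kids[[root]]) == 1) {
    old <- root
    root <- kids[[root]][1]
    kids[old] <- list(NULL)
    parent[root] <- NA_integer_
  }
  deg <- vapply(seq_len(n_all), function(v) length(kids[[v]]), integer(1))
  live <- which(deg > 0 | seq_len(n_all) <= n_tip)
  live <- union(live, root)
  bad <- live[deg[live] == 1 & live != root]
  if (length(bad))
    stop("unary (single-child) node at internal node id ", bad[1])
  poly <- live[deg[live] > 2]
  if (length(poly))
    stop("polytomy: node id ", poly[1], " has ", deg[poly[1]], " children")
  labs <- phy$tip.label
  if (anyDuplicated(labs))
    stop("duplicate leaf labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  # re-index live nodes 1..m
  idx <- match(seq_len(n_all), sort(live))
  m <- length(live)
  parent2 <- rep(NA_integer_, m)
  children2 <- matrix(NA_integer_, m, 2)
  labels2 <- rep(NA_character_, m)
  for (v in sort(live)) {
    nv <- idx[v]
    if (v <= n_tip) labels2[nv] <- labs[v]
    if (!is.na(parent[v]) && v != root) parent2[nv] <- idx[parent[v]]
    if (deg[v] == 2) children2[nv, ] <- idx[kids[[v]]]
  }
  tr <- new_rb_tree(parent2, children2, labels2, idx[root])
  if (tr$n_node != 2L * tr$n_tip - 1L)
    stop("tree is not strictly binary")
  tr
}

#' @export
print.rb_tree <- function(x, ...) {
  cat("Rooted binary tree:", x$n_tip, "tips,", x$n_node - x$n_tip,
      "internal nodes\n")
  cat("  ", write_newick(x), "\n", sep = "")
  invisible(x)
}

#' Serialize a tree back to Newick (topology only)
#'
#' @param tree an `rb_tree`.
#' @return a Newick string.
#' @export
write_newick <- function(tree) {
  rec <- function(v) {
    if (tree$is_tip[v]) return(tree$labels[v])
    ch <- tree$children[v, ]
    paste0("(", rec(ch[1]), ",", rec(ch[2]), ")")
  }
  paste0(rec(tree$root), ";")
}

#' Last common ancestor of a set of nodes
#'
#' Every node is an ancestor of itself, so `lca_node(tree, x)` is `x`.
#'
#' @param tree an `rb_tree`.
#' @param nodes non-empty vector of node ids.
#' @return the node id of the LCA.
#' @export
lca_node <- function(tree, nodes) {
  nodes <- as.integer(nodes)
  if (!length(nodes)) stop("lca of empty node set")
  if (any(nodes < 1 | nodes > tree$n_node)) stop("node not in tree")
  common <- tree$anc[nodes[1], ]
  for (v in nodes[-1]) common <- common & tree$anc[v, ]
  cand <- which(common)
  cand[which.max(tree$depth[cand])]
}

#' Number of edges on the path between two nodes
#'
#' @param tree an `rb_tree`.
#' @param x,y node ids.
#' @return non-negative integer; `path_distance(tree, x, x)` is 0.
#' @export
path_distance <- function(tree, x, y) {
  x <- as.integer(x); y <- as.integer(y)
  if (any(c(x, y) < 1 | c(x, y) > tree$n_node)) stop("node not in tree")
  a <- lca_node(tree, c(x, y))
  (tree$depth[x] - tree$depth[a]) + (tree$depth[y] - tree$depth[a])
}

# ancestor-or-equal / comparability helpers used throughout the model
is_anc <- function(tree, anc, desc) tree$anc[desc, anc]   # anc >= desc
incomparable <- function(tree, x, y) !tree$anc[x, y] && !tree$anc[y, x]

tip_ids <- function(tree) which(tree$is_tip)

tip_id <- function(tree, label) {
  i <- match(label, tree$labels)
  if (is.na(i)) stop("no tip labelled '", label, "'")
  i
}

# Deterministic readable name for any node: tips by label, internal nodes by
# the pair of extreme descendant tip labels.
node_name <- function(tree, v) {
  if (tree$is_tip[v]) return(tree$labels[v])
  tips <- tree$labels[tree$is_tip & tree$anc[, v]]
  tips <- sort(tips)
  paste0("lca(", tips[1], ",", tips[length(tips)], ")")
}

# sibling species node (NA at root)
sibling <- function(tree, v) {
  p <- tree$parent[v]
  if (is.na(p)) return(NA_integer_)
  ch <- tree$children[p, ]
  ch[ch != v]
}

# subtree node ids (inclusive)
subtree_nodes <- function(tree, v) which(tree$anc[, v])
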