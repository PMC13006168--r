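## Backbone-tree reduction -----------------------------------------------
##
## A reticulation node is resolved either as a transfer event (keep only the
## designated acceptor edge) or as a combining event (replace all incoming
## edges by a single edge from its lowest stable ancestor).  Applying this
## to every reticulation node turns the network into its backbone tree
## B(N), over exactly the same node set; B may contain unlabeled leaves and
## through nodes and is kept as-is.

## Dominator sets of all nodes, as an n x n logical matrix (row v = nodes on
## every root -> v path).  Single pass in topological order suffices on a DAG.
dominator_matrix <- function(net) {
  ord <- topo_order(net)
  if (is.null(ord)) stop("network is cyclic")
  n <- net$n
  dom <- matrix(FALSE, n, n)
  for (v in ord) {
    ps <- unique(net$parents[[v]])
    if (length(ps) == 0L) {
      dom[v, v] <- TRUE
    } else {
      acc <- dom[ps[1L], ]
      for (p in ps[-1L]) acc <- acc & dom[p, ]
      acc[v] <- TRUE
      dom[v, ] <- acc
    }
  }
  dom
}

## LSA of every node (NA for the root): the dominator closest to v, i.e. the
## dominator other than v with the largest dominator set of its own.
lsa_all <- function(net) {
  dom <- dominator_matrix(net)
  sizes <- rowSums(dom)
  out <- rep(NA_integer_, net$n)
  for (v in seq_len(net$n)) {
    if (v == net$root) next
    cand <- which(dom[v, ])
    cand <- cand[cand != v]
    out[v] <- cand[which.max(sizes[cand])]
  }
  out
}

#' Lowest stable ancestor
#'
#' The LSA of a node `v` is the node closest to `v` (other than `v` itself)
#' that lies on every directed path from the root to `v`.  For a node with a
#' single parent this is that parent.
#'
#' @param net a `phylo_network`.
#' @param v a node id, not the root.
#' @return the node id of the LSA.
#' @export
lsa <- function(net, v) {
  if (v == net$root) stop("the root has no lowest stable ancestor")
  lsa_all(net)[v]
}

#' Reticulate edges of a network
#'
#' Returns R: all incoming edges of combining reticulation nodes, plus all
#' non-acceptor incoming edges of transfer reticulation nodes.  For a tree,
#' R is empty.  Parallel edges are kept with multiplicity.
#'
#' @param net a `phylo_network`.
#' @return a 2-column integer matrix with columns `from`, `to`.
#' @export
reticulate_edges <- function(net) {
  from <- integer(0)
  to <- integer(0)
  indeg <- in_degree(net)
  for (p in seq_len(net$n)) {
    ch <- net$children[[p]]
    acc <- net$child_acceptor[[p]]
    for (j in seq_along(ch)) {
      w <- ch[j]
      if (indeg[w] >= 2L && !acc[j]) {
        from <- c(from, p)
        to <- c(to, w)
      }
    }
  }
  cbind(from = from, to = to)
}

#' Backbone tree of a rooted phylogenetic network
#'
#' For each reticulation node `v`: if `v` has a transfer-acceptor edge, all
#' its other incoming edges are deleted; otherwise all incoming edges of `v`
#' are replaced by the single edge (LSA(v), v), appended after the existing
#' children of the LSA node.  A tree input is returned unchanged (as a
#' backbone).  The result keeps every node of the network, including any
#' through nodes or unlabeled leaves that the reduction produces.
#'
#' @param net a `phylo_network`.
#' @return a `backbone_tree`: list with `n`, `children`, `parent` (integer,
#'   `NA` at the root), `root`, `label`, `replacement_edges` (2-column
#'   matrix of LSA edges added for combining nodes), and `lsa` (the cached
#'   LSA of every node of the network).
#' @export
backbone_tree <- function(net) {
  acc <- acceptor_parent(net)
  indeg <- in_degree(net)
  rets <- which(indeg >= 2L)
  lsa_v <- if (net$n > 1L) lsa_all(net) else rep(NA_integer_, net$n)
  children <- net$children
  repl_from <- integer(0)
  repl_to <- integer(0)
  for (v in rets) {
    if (!is.na(acc[v])) {
      ## transfer event: keep exactly the flagged acceptor occurrence
      for (p in unique(net$parents[[v]])) {
        hit <- which(children[[p]] == v)
        if (p == acc[v]) {
          flagged <- hit[net$child_acceptor[[p]][hit]][1L]
          drop <- setdiff(hit, flagged)
        } else drop <- hit
        if (length(drop) > 0L) children[[p]] <- children[[p]][-drop]
      }
    } else {
      ## combining event: single replacement edge from the LSA
      for (p in unique(net$parents[[v]])) {
        hit <- which(children[[p]] == v)
        if (length(hit) > 0L) children[[p]] <- children[[p]][-hit]
      }
      u <- lsa_v[v]
      children[[u]] <- c(children[[u]], v)
      repl_from <- c(repl_from, u)
      repl_to <- c(repl_to, v)
    }
  }
  parent <- rep(NA_integer_, net$n)
  for (p in seq_len(net$n)) {
    for (w in children[[p]]) {
      if (!is.na(parent[w])) stop("internal error: backbone node with two parents")
      parent[w] <- p
    }
  }
  n_edges <- sum(lengths(children))
  if (n_edges != net$n - 1L) {
    stop("internal error: backbone is not a tree (|E| != |V| - 1)")
  }
  if (sum(is.na(parent)) != 1L || is.na(parent[net$root]) == FALSE) {
    stop("internal error: backbone root mismatch")
  }
  structure(
    list(
      n = net$n,
      children = children,
      parent = parent,
      root = net$root,
      label = net$label,
      replacement_edges = cbind(from = repl_from, to = repl_to),
      lsa = lsa_v
    ),
    class = "backbone_tree"
  )
}

#' @export
print.backbone_tree <- function(x, ...) {
  cat(sprintf(
    "Backbone tree: %d nodes, %d leaf slots, %d replacement edge%s\n",
    x$n, sum(lengths(x$children) == 0L), nrow(x$replacement_edges),
    if (nrow(x$replacement_edges) == 1L) "" else "s"
  ))
  invisible(x)
}

#' Initial child ordering of a backbone tree
#'
#' The ordering object used throughout the package: a list with one integer
#' vector per node giving the current left-to-right order of its backbone
#' children (input text order, with LSA replacement edges appended last).
#'
#' @param bb a `backbone_tree`.
#' @return a list of integer vectors, indexed by node id.
#' @export
initial_ordering <- function(bb) bb$children
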