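## NN-presorting ----------------------------------------------------------
##
## Build the hardwired-cluster distance D over the shared taxa, run the
## agglomerative phase of neighbor-net on D to obtain a circular order, and
## presort both backbone trees by increasing average rank of the taxa in
## each child's subtree.

#' Hardwired clusters of a network, restricted to shared taxa
#'
#' Every tree node (in-degree at most 1) of a rooted phylogenetic network
#' induces a cluster: the shared taxa labeling the leaves reachable from
#' it.  Clusters of size < 2 after restriction are dropped and duplicates
#' collapse.
#'
#' @param network a `phylo_network`.
#' @param shared character vector of shared taxon labels.
#' @return list of clusters, each a sorted character vector.
#' @export
hardwired_clusters <- function(network, shared) {
  ord <- topo_order(network)
  n <- network$n
  ns <- length(shared)
  desc <- matrix(FALSE, n, ns)
  leaves <- leaf_nodes(network)
  hit <- match(network$label[leaves], shared)
  ok <- !is.na(hit)
  desc[cbind(leaves[ok], hit[ok])] <- TRUE
  for (v in rev(ord)) {
    for (w in network$children[[v]]) desc[v, ] <- desc[v, ] | desc[w, ]
  }
  tree_nodes <- which(in_degree(network) <= 1L)
  out <- list()
  keys <- character(0)
  for (v in tree_nodes) {
    cl <- shared[desc[v, ]]
    if (length(cl) < 2L) next
    key <- paste(cl, collapse = "\r")
    if (!(key %in% keys)) {
      keys <- c(keys, key)
      out[[length(out) + 1L]] <- cl
    }
  }
  out
}

#' Hardwired-cluster distance matrix
#'
#' `D(i, j)` = number of clusters containing exactly one of taxa `i`, `j`
#' (the L1 distance between cluster-membership indicator vectors).
#'
#' @param clusters list of clusters (character vectors), e.g. from
#'   [hardwired_clusters()] of both networks concatenated.
#' @param shared character vector of shared taxon labels.
#' @return symmetric numeric matrix with dimnames `shared`.
#' @export
cluster_distance <- function(clusters, shared) {
  ns <- length(shared)
  if (ns < 2L) stop("need at least two shared taxa")
  M <- matrix(0, nrow = length(clusters), ncol = ns,
              dimnames = list(NULL, shared))
  for (i in seq_along(clusters)) M[i, clusters[[i]]] <- 1
  if (length(clusters) == 0L) {
    return(matrix(0, ns, ns, dimnames = list(shared, shared)))
  }
  D <- crossprod(M, 1 - M)
  D <- D + t(D)
  dimnames(D) <- list(shared, shared)
  D
}

#' Circular taxon order by the neighbor-net agglomerative phase
#'
#' Maintains active clusters (initially singletons, each a path of linked
#' nodes).  Repeatedly the cluster pair minimizing the neighbor-joining
#' style criterion `Q(A, B) = (m - 2) d(A, B) - sum_C d(A, C) - sum_C
#' d(B, C)` (cluster distances as means over member nodes) is chosen; among
#' the endpoint nodes of the chosen clusters, the node pair minimizing the
#' analogous node-level criterion is linked; whenever a cluster path
#' reaches three consecutive linked nodes x-y-z they are replaced by two
#' nodes u, v with reduced distances `d(u,w) = 2/3 d(x,w) + 1/3 d(y,w)`,
#' `d(v,w) = 1/3 d(y,w) + 2/3 d(z,w)`, `d(u,v) = (d(x,y) + d(y,z) +
#' d(x,z)) / 3`.  When at most three clusters remain the circular order is
#' read off by expanding the reductions in reverse.  Ties are broken by
#' lowest represented taxon index.
#'
#' @param d symmetric, non-negative distance matrix with zero diagonal and
#'   taxon dimnames.
#' @return character vector: a permutation of the taxa, read cyclically.
#' @export
neighbornet_order <- function(d) {
  taxa <- rownames(d)
  n <- length(taxa)
  stopifnot(!is.null(taxa), nrow(d) == ncol(d))
  if (n <= 3L) return(taxa)

  cap <- 3L * n + 3L
  Dn <- matrix(0, cap, cap)
  Dn[seq_len(n), seq_len(n)] <- d
  nodemin <- c(seq_len(n), rep(NA_integer_, cap - n))
  n_nodes <- n
  clusters <- lapply(seq_len(n), function(i) i)
  reductions <- list()

  cluster_dist <- function(A, B) mean(Dn[A, B, drop = FALSE])

  while (length(clusters) > 3L) {
    m <- length(clusters)
    ## mean distances between clusters
    dC <- matrix(0, m, m)
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        dC[i, j] <- dC[j, i] <- cluster_dist(clusters[[i]], clusters[[j]])
      }
    }
    rowsum_dC <- rowSums(dC)
    cmin <- vapply(clusters, function(cl) min(nodemin[cl]), integer(1))
    best <- NULL
    best_key <- c(Inf, Inf, Inf)
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * dC[i, j] - rowsum_dC[i] - rowsum_dC[j]
        key <- c(q, min(cmin[i], cmin[j]), max(cmin[i], cmin[j]))
        if (key[1L] < best_key[1L] - 1e-12 ||
            (abs(key[1L] - best_key[1L]) <= 1e-12 &&
             (key[2L] < best_key[2L] ||
              (key[2L] == best_key[2L] && key[3L] < best_key[3L])))) {
          best_key <- key
          best <- c(i, j)
        }
      }
    }
    ai <- best[1L]; bi <- best[2L]
    A <- clusters[[ai]]; B <- clusters[[bi]]
    ends_A <- unique(c(A[1L], A[length(A)]))
    ends_B <- unique(c(B[1L], B[length(B)]))
    others <- clusters[-c(ai, bi)]
    node_clusterdist <- function(x) {
      vapply(others, function(cl) mean(Dn[x, cl]), numeric(1))
    }
    best_nodes <- NULL
    best_nkey <- c(Inf, Inf, Inf)
    for (x in ends_A) {
      sx <- sum(node_clusterdist(x))
      for (y in ends_B) {
        sy <- sum(node_clusterdist(y))
        q <- (m - 2) * Dn[x, y] - sx - sy
        key <- c(q, nodemin[x], nodemin[y])
        if (key[1L] < best_nkey[1L] - 1e-12 ||
            (abs(key[1L] - best_nkey[1L]) <= 1e-12 &&
             (key[2L] < best_nkey[2L] ||
              (key[2L] == best_nkey[2L] && key[3L] < best_nkey[3L])))) {
          best_nkey <- key
          best_nodes <- c(x, y)
        }
      }
    }
    x <- best_nodes[1L]; y <- best_nodes[2L]
    ## orient A to end at x, B to start at y, then link
    if (A[length(A)] != x) A <- rev(A)
    if (B[1L] != y) B <- rev(B)
    path <- c(A, B)
    ## reduce to a 2-node cluster
    while (length(path) > 2L) {
      x0 <- path[1L]; y0 <- path[2L]; z0 <- path[3L]
      u <- n_nodes + 1L
      v <- n_nodes + 2L
      n_nodes <- n_nodes + 2L
      active <- c(unlist(others), path[-(1:3)])
      for (w in active) {
        Dn[u, w] <- Dn[w, u] <- (2 * Dn[x0, w] + Dn[y0, w]) / 3
        Dn[v, w] <- Dn[w, v] <- (Dn[y0, w] + 2 * Dn[z0, w]) / 3
      }
      Dn[u, v] <- Dn[v, u] <- (Dn[x0, y0] + Dn[y0, z0] + Dn[x0, z0]) / 3
      nodemin[u] <- min(nodemin[c(x0, y0)])
      nodemin[v] <- min(nodemin[c(y0, z0)])
      reductions[[length(reductions) + 1L]] <- c(u, v, x0, y0, z0)
      path <- c(u, v, path[-(1:3)])
    }
    clusters[[ai]] <- path
    clusters <- clusters[-bi]
  }

  cycle <- unlist(clusters)
  ## expand reductions in reverse; rotate so the reduced pair sits first
  rot <- function(vec, k) {
    if (k == 1L) vec else c(vec[k:length(vec)], vec[seq_len(k - 1L)])
  }
  for (k in rev(seq_along(reductions))) {
    r <- reductions[[k]]
    u <- r[1L]; v <- r[2L]
    nc <- length(cycle)
    iu <- which(cycle == u)
    if (cycle[if (iu == nc) 1L else iu + 1L] == v) {
      cycle <- rot(cycle, iu)            # (u, v, ...)
      cycle <- c(r[3:5], cycle[-(1:2)])
    } else {
      iv <- which(cycle == v)
      if (cycle[if (iv == nc) 1L else iv + 1L] != u) {
        stop("internal error: reduced pair not adjacent in cycle")
      }
      cycle <- rot(cycle, iv)            # (v, u, ...)
      cycle <- c(rev(r[3:5]), cycle[-(1:2)])
    }
  }
  stopifnot(all(sort(cycle) == seq_len(n)))
  taxa[cycle]
}

## Deterministic linearization of a circular order: cut immediately before
## the lexicographically smallest taxon; traverse in the direction whose
## second element is the lexicographically smaller neighbor.
linearize_circular <- function(cyc) {
  n <- length(cyc)
  if (n <= 2L) return(sort(cyc, method = "radix"))
  i <- which(cyc == sort(cyc, method = "radix")[1L])[1L]
  nxt <- cyc[if (i == n) 1L else i + 1L]
  prv <- cyc[if (i == 1L) n else i - 1L]
  fwd <- c(cyc[i:n], cyc[seq_len(i - 1L)])
  if (sort(c(nxt, prv), method = "radix")[1L] == nxt) fwd else
    c(fwd[1L], rev(fwd[-1L]))
}

## Reorder `items`: entries with a non-NA key are sorted ascending by key
## (stable) and placed back into the keyed slots; NA-keyed entries keep
## their slots.
reorder_keep_unkeyed <- function(items, keys) {
  keyed <- which(!is.na(keys))
  if (length(keyed) < 2L) return(items)
  items[keyed] <- items[keyed][order(keys[keyed])]
  items
}

## Mean (and min) rank of shared taxa below every backbone node.
subtree_rank_stats <- function(bb, ordering, rank_by_taxon) {
  lay <- bb_layout(bb, ordering)
  n <- bb$n
  rsum <- numeric(n)
  rcnt <- integer(n)
  rmin <- rep(Inf, n)
  for (v in lay$leaf_seq) {
    lab <- bb$label[v]
    if (!is.na(lab) && lab %in% names(rank_by_taxon)) {
      r <- rank_by_taxon[[lab]]
      rsum[v] <- r
      rcnt[v] <- 1L
      rmin[v] <- r
    }
  }
  for (v in rev(lay$preorder)) {
    p <- bb$parent[v]
    if (!is.na(p)) {
      rsum[p] <- rsum[p] + rsum[v]
      rcnt[p] <- rcnt[p] + rcnt[v]
      rmin[p] <- min(rmin[p], rmin[v])
    }
  }
  list(mean = ifelse(rcnt > 0L, rsum / pmax(rcnt, 1L), NA_real_),
       min = ifelse(is.finite(rmin), rmin, NA_real_))
}

#' Presort a backbone tree by a taxon order
#'
#' Taxa are ranked by their position in `order`; at every internal node the
#' children are sorted by increasing average rank of the shared taxa in
#' their backbone subtrees.  Children whose subtrees contain no shared
#' taxon keep their slots.  A circular order from [neighbornet_order()]
#' should be linearized first (both sides with the same cut); the pairwise
#' presorting helpers do this with a deterministic cut before the
#' lexicographically smallest taxon.
#'
#' @param backbone a `backbone_tree`.
#' @param order a linear taxon order (character vector); position = rank.
#' @return a child ordering (see [initial_ordering()]).
#' @export
presort <- function(backbone, order) {
  rk <- stats::setNames(seq_along(order), order)
  ord <- initial_ordering(backbone)
  stats_v <- subtree_rank_stats(backbone, ord, rk)
  for (v in seq_len(backbone$n)) {
    ch <- ord[[v]]
    if (length(ch) >= 2L) {
      ord[[v]] <- reorder_keep_unkeyed(ch, stats_v$mean[ch])
    }
  }
  ord
}

## Full NN-presorting of a tanglegram pair.
nn_presort_pair <- function(n1, b1, n2, b2) {
  shared <- shared_taxa(n1, n2)
  if (length(shared) < 2L) {
    return(list(o1 = initial_ordering(b1), o2 = initial_ordering(b2),
                circular = shared))
  }
  cl <- c(hardwired_clusters(n1, shared), hardwired_clusters(n2, shared))
  ## collapse duplicates across the two sides
  keys <- vapply(cl, paste, character(1), collapse = "\r")
  cl <- cl[!duplicated(keys)]
  D <- cluster_distance(cl, shared)
  cyc <- neighbornet_order(D)
  lin <- linearize_circular(cyc)
  list(o1 = presort(b1, lin), o2 = presort(b2, lin), circular = cyc)
}
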