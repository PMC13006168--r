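## Synthetic benchmark generation ----------------------------------------
##
## Emulates the benchmark construction: a 500-taxon random background tree,
## induced subtrees of size n, r*n random rooted-SPR perturbations per
## copy, random deletion of a proportion m of taxa, random contraction of a
## proportion c of internal edges, and random insertion of k combining
## reticulation edges.

round_half_up <- function(x) as.integer(floor(x + 0.5))

## deterministic sub-seed derivation, kept below 2^31
subseed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + i * 9973) %% 2147483629)
}

## mutable-ish working state for tree surgery
compact_network <- function(children, label, root,
                            child_acceptor = NULL) {
  n <- length(children)
  visited <- rep(FALSE, n)
  stack <- root
  while (length(stack) > 0L) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (visited[v]) next
    visited[v] <- TRUE
    stack <- c(children[[v]], stack)
  }
  keep <- which(visited)
  map <- rep(NA_integer_, n)
  map[keep] <- seq_along(keep)
  ch2 <- lapply(keep, function(v) map[children[[v]]])
  acc2 <- if (is.null(child_acceptor)) NULL else child_acceptor[keep]
  new_phylo_network(ch2, label[keep], child_acceptor = acc2)
}

#' Random binary background tree
#'
#' Grows a rooted binary tree by successive attachment of each new leaf to
#' a uniformly chosen edge of the current tree.  Leaves are labeled
#' `t001`, `t002`, ...
#'
#' @param size number of taxa (at least 2).
#' @param seed random seed.
#' @return a binary `phylo_network` tree.
#' @export
random_background_tree <- function(size, seed = 1L) {
  stopifnot(size >= 2L)
  lab_fmt <- paste0("t%0", max(3L, nchar(as.character(size))), "d")
  with_seed(seed, {
    children <- list(c(2L, 3L), integer(0), integer(0))
    label <- c(NA, sprintf(lab_fmt, 1:2))
    for (i in seq_len(size - 2L) + 2L) {
      edges <- do.call(rbind, lapply(seq_along(children), function(p) {
        if (length(children[[p]]) > 0L) cbind(p, children[[p]]) else NULL
      }))
      e <- edges[sample.int(nrow(edges), 1L), ]
      p <- e[1L]; v <- e[2L]
      u <- length(children) + 1L
      l <- length(children) + 2L
      children[[p]][which(children[[p]] == v)[1L]] <- u
      children[[u]] <- c(v, l)
      children[[l]] <- integer(0)
      label <- c(label, NA, sprintf(lab_fmt, i))
    }
    new_phylo_network(children, label)
  })
}

## Restriction of a tree to a subset of its taxa (induced subtree with
## through nodes suppressed).
restrict_tree <- function(net, keep_labels) {
  if (!is_tree_network(net)) stop("restrict_tree expects a tree")
  n <- net$n
  cnt <- integer(n)
  ord <- topo_order(net)
  for (v in rev(ord)) {
    if (length(net$children[[v]]) == 0L) {
      cnt[v] <- as.integer(!is.na(net$label[v]) && net$label[v] %in% keep_labels)
    } else {
      cnt[v] <- sum(cnt[net$children[[v]]])
    }
  }
  if (cnt[net$root] < 2L) stop("restriction would leave fewer than 2 taxa")
  children <- list()
  label <- character(0)
  add_node <- function(lab) {
    children[[length(children) + 1L]] <<- integer(0)
    label[length(label) + 1L] <<- lab
    length(children)
  }
  build <- function(v) {
    ch <- net$children[[v]]
    ch <- ch[cnt[ch] > 0L]
    if (length(net$children[[v]]) == 0L) return(add_node(net$label[v]))
    if (length(ch) == 1L) return(build(ch))
    id <- add_node(NA_character_)
    kids <- vapply(ch, build, integer(1))
    children[[id]] <<- kids
    id
  }
  ## descend past a unary root stretch
  r <- net$root
  repeat {
    ch <- net$children[[r]]
    ch <- ch[cnt[ch] > 0L]
    if (length(ch) == 1L && cnt[r] == cnt[ch]) r <- ch else break
  }
  build(r)
  compact_network(children, label, root = 1L)
}

#' Extract a random induced subtree
#'
#' Restricts the tree to `n` uniformly sampled taxa, suppressing the
#' resulting through nodes.
#'
#' @param tree a `phylo_network` tree.
#' @param n number of taxa to keep.
#' @param seed random seed.
#' @return a `phylo_network` tree on `n` taxa.
#' @export
extract_subtree <- function(tree, n, seed = 1L) {
  taxa <- network_taxa(tree)
  if (n > length(taxa)) stop("cannot extract more taxa than the tree has")
  keep <- with_seed(seed, sample(taxa, n))
  restrict_tree(tree, keep)
}

#' Random rooted subtree prune-and-regraft perturbation
#'
#' Applies `count` successive rooted SPR moves to a binary tree: a random
#' non-root edge's subtree is pruned (the resulting unary node is
#' suppressed) and regrafted onto a random edge of the remaining tree.
#'
#' @param tree a binary `phylo_network` tree with at least 3 leaves.
#' @param count number of moves.
#' @param seed random seed.
#' @return a binary `phylo_network` tree on the same taxa.
#' @export
apply_rspr <- function(tree, count, seed = 1L) {
  if (count == 0L) return(tree)
  if (length(leaf_nodes(tree)) < 3L) stop("need at least 3 leaves for rSPR")
  with_seed(seed, {
    children <- tree$children
    label <- tree$label
    root <- tree$root
    parent <- rep(NA_integer_, length(children))
    for (p in seq_along(children)) for (w in children[[p]]) parent[w] <- p

    live_edges <- function() {
      out <- do.call(rbind, lapply(seq_along(children), function(p) {
        if (length(children[[p]]) > 0L) cbind(p, children[[p]]) else NULL
      }))
      ## restrict to nodes reachable from root
      reach <- rep(FALSE, length(children))
      stack <- root
      while (length(stack) > 0L) {
        v <- stack[[1L]]; stack <- stack[-1L]
        reach[v] <- TRUE
        stack <- c(children[[v]], stack)
      }
      out[reach[out[, 1L]], , drop = FALSE]
    }

    for (mv in seq_len(count)) {
      moved <- FALSE
      for (try in 1:100) {
        edges <- live_edges()
        e <- edges[sample.int(nrow(edges), 1L), ]
        p <- e[1L]; v <- e[2L]
        ## prune subtree at v; suppress p
        sib <- setdiff(children[[p]], v)
        if (length(sib) != 1L) next  # should not happen on a binary tree
        if (p == root) {
          new_root <- sib
          parent[sib] <- NA_integer_
        } else {
          g <- parent[p]
          children[[g]][children[[g]] == p] <- sib
          parent[sib] <- g
          new_root <- root
        }
        children[[p]] <- integer(0)
        ## remaining edges (pruned subtree is unreachable from new_root)
        saved_root <- root
        root <- new_root
        rem <- live_edges()
        if (nrow(rem) == 0L) {  # remaining tree is a single leaf: undo
          root <- saved_root
          if (p == saved_root) {
            children[[p]] <- c(v, sib)
            parent[sib] <- p
          } else {
            g <- parent[sib]
            children[[g]][children[[g]] == sib] <- p
            children[[p]] <- c(v, sib)
            parent[p] <- g
            parent[sib] <- p
          }
          next
        }
        t <- rem[sample.int(nrow(rem), 1L), ]
        a <- t[1L]; b <- t[2L]
        ## regraft: reuse p as the subdivision node
        children[[a]][children[[a]] == b] <- p
        children[[p]] <- c(b, v)
        parent[p] <- a
        parent[b] <- p
        parent[v] <- p
        moved <- TRUE
        break
      }
      if (!moved) stop("rSPR: no valid move found")
    }
    compact_network(children, label, root)
  })
}

#' Randomly delete a proportion of taxa
#'
#' Removes `round(m * |X|)` uniformly chosen taxa (round half up) and
#' suppresses the resulting through nodes.
#'
#' @param tree a `phylo_network` tree.
#' @param m proportion of taxa to remove, in `[0, 1]`.
#' @param seed random seed.
#' @return a `phylo_network` tree.
#' @export
delete_taxa <- function(tree, m, seed = 1L) {
  stopifnot(m >= 0, m <= 1)
  taxa <- network_taxa(tree)
  nrem <- round_half_up(m * length(taxa))
  if (nrem == 0L) return(tree)
  if (length(taxa) - nrem < 2L) stop("deletion would leave fewer than 2 taxa")
  drop <- with_seed(seed, sample(taxa, nrem))
  restrict_tree(tree, setdiff(taxa, drop))
}

#' Randomly contract internal edges
#'
#' Contracts `round(c * I)` uniformly chosen internal edges (edges whose
#' both endpoints are internal nodes), merging each contracted child into
#' its parent and yielding multifurcations.
#'
#' @param tree a `phylo_network` tree.
#' @param c proportion of internal edges to contract, in `[0, 1]`.
#' @param seed random seed.
#' @return a `phylo_network` tree on the same taxa.
#' @export
contract_edges <- function(tree, c = 0, seed = 1L) {
  stopifnot(c >= 0, c <= 1)
  if (!is_tree_network(tree)) stop("contract_edges expects a tree")
  outdeg <- out_degree(tree)
  internal_children <- unlist(lapply(seq_len(tree$n), function(p) {
    ch <- tree$children[[p]]
    ch[outdeg[ch] > 0L]
  }))
  I <- length(internal_children)
  ncon <- round_half_up(c * I)
  if (ncon == 0L) return(tree)
  vs <- with_seed(seed, internal_children[sample.int(I, ncon)])
  ## process in preorder so a contracted node's parent is already final
  pre <- bb_preorder_tree(tree)
  vs <- vs[order(match(vs, pre))]
  children <- tree$children
  parent <- rep(NA_integer_, tree$n)
  for (p in seq_len(tree$n)) for (w in children[[p]]) parent[w] <- p
  for (v in vs) {
    p <- parent[v]
    idx <- match(v, children[[p]])
    children[[p]] <- append(children[[p]][-idx], children[[v]], after = idx - 1L)
    for (w in children[[v]]) parent[w] <- p
    children[[v]] <- integer(0)
  }
  compact_network(children, tree$label, tree$root)
}

## preorder of a tree stored as a phylo_network
bb_preorder_tree <- function(net) {
  pre <- integer(net$n)
  stack <- net$root
  np <- 0L
  while (length(stack) > 0L) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    np <- np + 1L
    pre[np] <- v
    stack <- c(net$children[[v]], stack)
  }
  pre[seq_len(np)]
}

#' Randomly insert combining reticulation edges
#'
#' `k` times: two edges `(u1, v1)` and `(u2, v2)` are chosen such that
#' `v2` is not an ancestor (or equal) of `u1`; both are subdivided and an
#' edge from the first subdivision node to the second is added, making the
#' second a combining reticulation node.  The result is a valid acyclic
#' network.
#'
#' @param tree a `phylo_network` tree with at least 3 leaves.
#' @param k number of reticulation edges to add.
#' @param seed random seed.
#' @return a `phylo_network`.
#' @export
add_reticulations <- function(tree, k, seed = 1L) {
  if (k == 0L) return(tree)
  if (length(leaf_nodes(tree)) < 3L) stop("need at least 3 leaves")
  with_seed(seed, {
    children <- tree$children
    label <- tree$label
    root <- tree$root
    desc_or_self <- function(v) {
      seen <- rep(FALSE, length(children))
      stack <- v
      while (length(stack) > 0L) {
        u <- stack[[1L]]; stack <- stack[-1L]
        if (seen[u]) next
        seen[u] <- TRUE
        stack <- c(children[[u]], stack)
      }
      seen
    }
    for (i in seq_len(k)) {
      edges <- do.call(rbind, lapply(seq_along(children), function(p) {
        if (length(children[[p]]) > 0L) cbind(p, children[[p]]) else NULL
      }))
      placed <- FALSE
      for (try in 1:200) {
        ee <- sample.int(nrow(edges), 2L)
        u1 <- edges[ee[1L], 1L]; v1 <- edges[ee[1L], 2L]
        u2 <- edges[ee[2L], 1L]; v2 <- edges[ee[2L], 2L]
        if (desc_or_self(v2)[u1]) next
        s1 <- length(children) + 1L
        s2 <- length(children) + 2L
        children[[u1]][which(children[[u1]] == v1)[1L]] <- s1
        children[[u2]][which(children[[u2]] == v2)[1L]] <- s2
        children[[s1]] <- c(v1, s2)
        children[[s2]] <- v2
        label <- c(label, NA_character_, NA_character_)
        placed <- TRUE
        break
      }
      if (!placed) stop("add_reticulations: no valid edge pair found")
    }
    compact_network(children, label, root)
  })
}

#' Configuration for synthetic tanglegram benchmarks
#'
#' @param n subtree size (number of taxa extracted from the background
#'   tree).
#' @param r rooted-SPR rate; `round(r * n)` moves are applied per copy
#'   (tree mode).
#' @param m proportion of taxa deleted per copy, in `[0, 1]`.
#' @param c proportion of internal edges contracted per copy, in `[0, 1]`.
#' @param k number of reticulation edges added per copy (network mode).
#' @param background_size size of the random background tree.
#' @param seed base seed; all sub-steps derive their own seeds from it.
#' @param mode `"tree"`, `"network"`, or `"auto"` (network iff `k > 0`).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n, r = 0, m = 0, c = 0, k = 0L,
                             background_size = 500L, seed = 1L,
                             mode = c("auto", "tree", "network")) {
  mode <- match.arg(mode)
  stopifnot(n >= 2L, n <= background_size, m >= 0, m <= 1, c >= 0, c <= 1,
            k >= 0L, r >= 0)
  if (mode == "auto") mode <- if (k > 0L) "network" else "tree"
  structure(
    list(n = as.integer(n), r = r, m = m, c = c, k = as.integer(k),
         background_size = as.integer(background_size),
         seed = as.integer(seed), mode = mode),
    class = "synthetic_config"
  )
}

#' Generate a synthetic tanglegram input pair
#'
#' Tree mode: one induced subtree of the background tree, two copies
#' independently perturbed by `round(r * n)` rooted SPR moves, then
#' per-copy taxon deletion and edge contraction.  Network mode: two
#' identical induced subtrees, per-copy deletion and contraction, then `k`
#' random reticulation edges each.  All sub-seeds derive deterministically
#' from `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `n1`, `n2` (`phylo_network`s) and `cfg`.
#' @export
generate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  s <- function(i) subseed(cfg$seed, i)
  bg <- random_background_tree(cfg$background_size, seed = s(1L))
  sub <- extract_subtree(bg, cfg$n, seed = s(2L))
  if (cfg$mode == "tree") {
    nmoves <- round_half_up(cfg$r * cfg$n)
    t1 <- apply_rspr(sub, nmoves, seed = s(3L))
    t2 <- apply_rspr(sub, nmoves, seed = s(4L))
  } else {
    t1 <- sub
    t2 <- sub
  }
  if (cfg$m > 0) {
    t1 <- delete_taxa(t1, cfg$m, seed = s(5L))
    t2 <- delete_taxa(t2, cfg$m, seed = s(6L))
  }
  if (cfg$c > 0) {
    t1 <- contract_edges(t1, cfg$c, seed = s(7L))
    t2 <- contract_edges(t2, cfg$c, seed = s(8L))
  }
  if (cfg$mode == "network" && cfg$k > 0L) {
    t1 <- add_reticulations(t1, cfg$k, seed = s(9L))
    t2 <- add_reticulations(t2, cfg$k, seed = s(10L))
  }
  list(n1 = t1, n2 = t2, cfg = cfg)
}
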