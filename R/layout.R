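## Layout and displacement metrics ---------------------------------------

## Fast internal layout of a backbone tree under a child ordering:
## preorder DFS, leaf slots 1..L in encounter order, internal y = mean of
## descendant leaf slots, x = edge count from the root.
bb_layout <- function(bb, ordering) {
  n <- bb$n
  pre <- integer(n)
  stack <- integer(n + 1L)
  sp <- 1L
  stack[1L] <- bb$root
  np <- 0L
  while (sp > 0L) {
    v <- stack[sp]
    sp <- sp - 1L
    np <- np + 1L
    pre[np] <- v
    ch <- ordering[[v]]
    if (is.null(ch)) stop("ordering does not cover node ", v)
    nc <- length(ch)
    if (nc > 0L) {
      stack[(sp + 1L):(sp + nc)] <- ch[nc:1L]
      sp <- sp + nc
    }
  }
  if (np != n) stop("ordering does not span the backbone tree")
  x <- integer(n)
  for (i in seq_len(n)) {
    v <- pre[i]
    p <- bb$parent[v]
    x[v] <- if (is.na(p)) 0L else x[p] + 1L
  }
  is_leaf <- lengths(ordering[seq_len(n)]) == 0L
  leaf_seq <- pre[is_leaf[pre]]
  ysum <- numeric(n)
  cnt <- integer(n)
  ysum[leaf_seq] <- seq_along(leaf_seq)
  cnt[leaf_seq] <- 1L
  for (i in n:1L) {
    v <- pre[i]
    p <- bb$parent[v]
    if (!is.na(p)) {
      ysum[p] <- ysum[p] + ysum[v]
      cnt[p] <- cnt[p] + cnt[v]
    }
  }
  list(x = x, y = ysum / pmax(cnt, 1L), leaf_seq = leaf_seq, preorder = pre)
}

#' Coordinates of a backbone tree under a child ordering
#'
#' Leaves (labeled or not) receive y-coordinates 1..L in the order they are
#' encountered by a depth-first traversal that visits children in the given
#' order; an internal node's y is the arithmetic mean of the y values of
#' its leaf descendants; x is the number of edges from the root.
#'
#' @param backbone a `backbone_tree`.
#' @param ordering a child ordering (see [initial_ordering()]).
#' @return list with numeric `x`, `y` (per node) and `leaf_seq`, the node
#'   ids of the leaves in left-to-right order.
#' @export
assign_coordinates <- function(backbone, ordering) {
  lay <- bb_layout(backbone, ordering)
  list(x = lay$x, y = lay$y, leaf_seq = lay$leaf_seq)
}

#' Ranking of the shared taxa under an ordering
#'
#' Traverses the backbone tree depth-first under `ordering` and records the
#' order in which leaves labeled by shared taxa are visited; those leaves
#' receive ranks 1..n.  Unlabeled leaves and leaves whose taxon is not
#' shared consume no rank.
#'
#' @param backbone a `backbone_tree`.
#' @param ordering a child ordering.
#' @param shared character vector of shared taxon labels.
#' @return named integer vector mapping each shared taxon to its rank.
#' @export
ranking_of <- function(backbone, ordering, shared) {
  lay <- bb_layout(backbone, ordering)
  lab <- backbone$label[lay$leaf_seq]
  keep <- !is.na(lab) & lab %in% shared
  lab <- lab[keep]
  stats::setNames(seq_along(lab), lab)
}

check_same_taxa <- function(r1, r2) {
  if (length(r1) != length(r2) || !setequal(names(r1), names(r2))) {
    stop("rankings are not over the same taxon set")
  }
}

#' Taxon displacement (Spearman footrule) between two rankings
#'
#' `TD = sum over shared taxa of |rank1(t) - rank2(t)|`.
#'
#' @param r1,r2 rankings over the same taxon set, as from [ranking_of()].
#' @return non-negative integer.
#' @export
taxon_displacement <- function(r1, r2) {
  check_same_taxa(r1, r2)
  sum(abs(r1 - r2[names(r1)]))
}

## merge-sort inversion counting
count_inversions <- function(v) {
  n <- length(v)
  if (n < 2L) return(0)
  mid <- n %/% 2L
  left <- v[seq_len(mid)]
  right <- v[(mid + 1L):n]
  cnt <- count_inversions(left) + count_inversions(right)
  left <- sort(left)
  right <- sort(right)
  i <- 1L
  nl <- length(left)
  for (j in seq_along(right)) {
    while (i <= nl && left[i] <= right[j]) i <- i + 1L
    cnt <- cnt + (nl - i + 1L)
  }
  cnt
}

#' Number of intertaxon edge crossings between two rankings
#'
#' Counts unordered taxon pairs whose relative order differs between the
#' two rankings, by inversion counting in O(n log n).
#'
#' @inheritParams taxon_displacement
#' @return non-negative integer.
#' @export
count_crossings <- function(r1, r2) {
  check_same_taxa(r1, r2)
  s <- r2[names(sort(r1))]
  count_inversions(unname(s))
}

#' Reticulate displacement of a network layout
#'
#' `RD = sum over reticulate edges (v, w) of |y(v) - y(w)|`, with the y
#' coordinates taken from the backbone layout under `ordering`.
#'
#' @param network a `phylo_network`.
#' @param backbone its `backbone_tree`.
#' @param ordering a child ordering of the backbone.
#' @return non-negative number; 0 for any tree.
#' @export
reticulate_displacement <- function(network, backbone, ordering) {
  R <- reticulate_edges(network)
  if (nrow(R) == 0L) return(0)
  y <- bb_layout(backbone, ordering)$y
  sum(abs(y[R[, 1L]] - y[R[, 2L]]))
}

#' Score weights for displacement optimization
#'
#' @param alpha weight (0 or 1) of the first network's reticulate
#'   displacement.
#' @param beta weight (0 or 1) of the taxon displacement between the sides.
#' @param gamma weight (0 or 1) of the second network's reticulate
#'   displacement (two-sided only).
#' @return list of class `score_config`.
#' @export
score_config <- function(alpha = 1, beta = 1, gamma = 1) {
  stopifnot(alpha %in% c(0, 1), beta %in% c(0, 1), gamma %in% c(0, 1))
  if (alpha + beta + gamma == 0) stop("at least one score weight must be 1")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "score_config")
}

#' One-sided tanglegram score
#'
#' `OSTS = alpha * RD(N2, B2, O2) + beta * TD(O1, O2)` where the first
#' side's ranking `r1_fixed` is held fixed.
#'
#' @param n2 the free-side `phylo_network`.
#' @param b2 its `backbone_tree`.
#' @param o2 a child ordering of `b2`.
#' @param r1_fixed the fixed side's ranking of the shared taxa.
#' @param cfg a [score_config()] (its `gamma` is ignored).
#' @return non-negative number.
#' @export
one_sided_score <- function(n2, b2, o2, r1_fixed, cfg = score_config()) {
  rd <- if (cfg$alpha > 0) reticulate_displacement(n2, b2, o2) else 0
  td <- if (cfg$beta > 0) {
    taxon_displacement(r1_fixed, ranking_of(b2, o2, names(r1_fixed)))
  } else 0
  cfg$alpha * rd + cfg$beta * td
}

#' Two-sided tanglegram score
#'
#' `TSTS = alpha * RD1 + beta * TD + gamma * RD2`.
#'
#' @param side1,side2 lists with components `net`, `bb`, `ord`.
#' @param cfg a [score_config()].
#' @return non-negative number.
#' @export
two_sided_score <- function(side1, side2, cfg = score_config()) {
  shared <- shared_taxa(side1$net, side2$net)
  rd1 <- if (cfg$alpha > 0) {
    reticulate_displacement(side1$net, side1$bb, side1$ord)
  } else 0
  rd2 <- if (cfg$gamma > 0) {
    reticulate_displacement(side2$net, side2$bb, side2$ord)
  } else 0
  td <- if (cfg$beta > 0) {
    taxon_displacement(ranking_of(side1$bb, side1$ord, shared),
                       ranking_of(side2$bb, side2$ord, shared))
  } else 0
  cfg$alpha * rd1 + cfg$beta * td + cfg$gamma * rd2
}

## All metrics of a tanglegram state, recomputed from scratch.
tanglegram_metrics <- function(n1, b1, o1, n2, b2, o2, cfg = score_config()) {
  shared <- shared_taxa(n1, n2)
  r1 <- ranking_of(b1, o1, shared)
  r2 <- ranking_of(b2, o2, shared)
  td <- taxon_displacement(r1, r2)
  rd1 <- reticulate_displacement(n1, b1, o1)
  rd2 <- reticulate_displacement(n2, b2, o2)
  list(
    td = td,
    crossings = count_crossings(r1, r2),
    rd1 = rd1,
    rd2 = rd2,
    score = cfg$alpha * rd1 + cfg$beta * td + cfg$gamma * rd2,
    n_shared = length(shared)
  )
}
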