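## DO-tanglegram heuristics ----------------------------------------------

#' Simulated annealing / search configuration
#'
#' Defaults follow the method's advanced settings: start temperature 1000,
#' end temperature 0.01, 1000 iterations per temperature step, cooling rate
#' 0.95, exhaustive search for nodes with at most 8 children, and 32
#' parallel restart jobs.
#'
#' @param start_temperature,end_temperature,iterations_per_step,cooling_rate
#'   Metropolis schedule: `T <- T * cooling_rate` after each block of
#'   `iterations_per_step` proposals, from start until `T <
#'   end_temperature`.
#' @param exhaustive_threshold maximum number of children for which all
#'   permutations are enumerated instead of annealed.
#' @param jobs number of independent seeded restarts in
#'   [optimize_with_restarts()].
#' @param seed base random seed; job `i` uses `seed + i`.
#' @param max_rounds maximum number of two-sided alternation rounds.
#' @return list of class `sa_config`.
#' @export
sa_config <- function(start_temperature = 1000, end_temperature = 0.01,
                      iterations_per_step = 1000, cooling_rate = 0.95,
                      exhaustive_threshold = 8L, jobs = 32L, seed = 42L,
                      max_rounds = 10L) {
  stopifnot(
    cooling_rate > 0, cooling_rate < 1,
    end_temperature < start_temperature,
    exhaustive_threshold >= 1L, jobs >= 1L, max_rounds >= 1L
  )
  structure(
    list(
      start_temperature = start_temperature,
      end_temperature = end_temperature,
      iterations_per_step = iterations_per_step,
      cooling_rate = cooling_rate,
      exhaustive_threshold = as.integer(exhaustive_threshold),
      jobs = as.integer(jobs),
      seed = as.integer(seed),
      max_rounds = as.integer(max_rounds)
    ),
    class = "sa_config"
  )
}

## Evaluate code under a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

## All permutations of 1..k in lexicographic order (cached).
.perm_cache <- new.env(parent = emptyenv())
perms_lex <- function(k) {
  key <- as.character(k)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  res <- if (k == 1L) {
    matrix(1L, 1L, 1L)
  } else {
    sub <- perms_lex(k - 1L)
    blocks <- vector("list", k)
    for (i in seq_len(k)) {
      rest <- setdiff(seq_len(k), i)
      blocks[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
    }
    do.call(rbind, blocks)
  }
  if (k <= 8L) .perm_cache[[key]] <- res
  res
}

#' Optimize the order of one node's children against an objective
#'
#' With at most `cfg$exhaustive_threshold` children, all permutations are
#' evaluated and the exact argmin is returned (ties: first in lexicographic
#' generation order).  With more children, simulated annealing over random
#' pair-swap moves is used (Metropolis acceptance `exp(-delta / T)` for
#' worsening moves); the best state ever seen is returned.  If
#' `rank_candidate` is given it is evaluated first and, when at least as
#' good as the current order, seeds the search.
#'
#' @param children current child order (any vector).
#' @param objective function mapping a child order to a numeric score to be
#'   minimized; must be evaluable for any permutation of `children`.
#' @param cfg a [sa_config()].
#' @param rank_candidate optional alternative child order to try first.
#' @return the best child order found.
#' @export
optimize_children <- function(children, objective, cfg = sa_config(),
                              rank_candidate = NULL) {
  k <- length(children)
  if (k <= 1L) return(children)
  if (k <= cfg$exhaustive_threshold) {
    P <- perms_lex(k)
    best <- NULL
    best_val <- Inf
    for (r in seq_len(nrow(P))) {
      cand <- children[P[r, ]]
      val <- objective(cand)
      if (val < best_val) {
        best_val <- val
        best <- cand
      }
    }
    return(best)
  }
  ## simulated annealing over pair swaps
  cur <- children
  cur_val <- objective(cur)
  if (!is.null(rank_candidate)) {
    cand_val <- objective(rank_candidate)
    if (cand_val <= cur_val) {
      cur <- rank_candidate
      cur_val <- cand_val
    }
  }
  best <- cur
  best_val <- cur_val
  temp <- cfg$start_temperature
  while (temp >= cfg$end_temperature) {
    for (it in seq_len(cfg$iterations_per_step)) {
      ij <- sample.int(k, 2L)
      prop <- cur
      prop[ij] <- prop[rev(ij)]
      val <- objective(prop)
      delta <- val - cur_val
      if (delta <= 0 || stats::runif(1L) < exp(-delta / temp)) {
        cur <- prop
        cur_val <- val
        if (val < best_val) {
          best_val <- val
          best <- cur
        }
      }
    }
    temp <- temp * cfg$cooling_rate
  }
  best
}

## Minimum reference rank of the shared taxa below every backbone node
## (order-independent).
subtree_min_refrank <- function(bb, ref_rank) {
  lay <- bb_layout(bb, bb$children)
  rmin <- rep(Inf, bb$n)
  for (v in lay$leaf_seq) {
    lab <- bb$label[v]
    if (!is.na(lab)) {
      r <- ref_rank[lab]
      if (!is.na(r)) rmin[v] <- r
    }
  }
  for (v in rev(lay$preorder)) {
    p <- bb$parent[v]
    if (!is.na(p)) rmin[p] <- min(rmin[p], rmin[v])
  }
  ifelse(is.finite(rmin), rmin, NA_real_)
}

#' Smallest-rank child order candidate
#'
#' Orders the children of a node by the smallest reference rank among the
#' shared taxa in their backbone subtrees; children without any shared
#' taxon keep their slots.
#'
#' @param backbone a `backbone_tree`.
#' @param node an internal node id.
#' @param reference_rank the fixed side's ranking of the shared taxa.
#' @param ordering current child ordering (default: as stored).
#' @return reordered integer vector of the node's children.
#' @export
smallest_rank_candidate <- function(backbone, node, reference_rank,
                                    ordering = initial_ordering(backbone)) {
  ch <- ordering[[node]]
  rmin <- subtree_min_refrank(backbone, reference_rank)
  reorder_keep_unkeyed(ch, rmin[ch])
}

## Local objective around node v: permuting v's children only shifts the
## contiguous leaf blocks of their subtrees, so both TD and RD decompose
## into a constant part (everything outside the subtree of v) and a cheap
## block-offset part.  The returned eval(perm) equals the full global
## OSTS = alpha * RD + beta * TD for the ordering with ord[[v]] permuted.
make_local_objective <- function(net, bb, ord, v, ref_rank, alpha, beta,
                                 ret_edges, lay = NULL) {
  if (is.null(lay)) lay <- bb_layout(bb, ord)
  ch <- ord[[v]]
  k <- length(ch)
  n <- bb$n
  memb <- rep(0L, n)
  stack <- integer(n)
  for (j in seq_len(k)) {
    sp <- 1L
    stack[1L] <- ch[j]
    while (sp > 0L) {
      u <- stack[sp]
      sp <- sp - 1L
      memb[u] <- j
      cc <- ord[[u]]
      nc <- length(cc)
      if (nc > 0L) {
        stack[(sp + 1L):(sp + nc)] <- cc
        sp <- sp + nc
      }
    }
  }
  leaf_seq <- lay$leaf_seq
  leaf_child <- memb[leaf_seq]
  in_block <- leaf_child > 0L
  s <- if (any(in_block)) which(in_block)[1L] - 1L else 0L
  b <- tabulate(leaf_child, nbins = k)

  lab <- bb$label[leaf_seq]
  refs_all <- rep(NA_real_, length(leaf_seq))
  ok <- !is.na(lab)
  refs_all[ok] <- ref_rank[lab[ok]]
  is_sh <- !is.na(refs_all)
  sh_pos <- which(is_sh)
  sh_child <- leaf_child[sh_pos]
  sh_ref <- refs_all[sh_pos]
  cur_rank <- seq_along(sh_pos)
  S <- sum(sh_pos <= s)
  const_td <- sum(abs(sh_ref[sh_child == 0L] - cur_rank[sh_child == 0L]))
  q <- tabulate(sh_child, nbins = k)
  sr <- lapply(seq_len(k), function(j) sh_ref[sh_child == j])
  idx <- lapply(seq_len(k), function(j) seq_len(q[j]))

  use_rd <- alpha > 0 && nrow(ret_edges) > 0L
  const_rd <- 0
  var_edges <- NULL
  if (use_rd) {
    y <- lay$y
    t_cur <- cumsum(c(0, b))[seq_len(k)]
    ca <- memb[ret_edges[, 1L]]
    cb <- memb[ret_edges[, 2L]]
    for (e in seq_len(nrow(ret_edges))) {
      a <- ret_edges[e, 1L]
      w <- ret_edges[e, 2L]
      if (ca[e] == 0L && cb[e] == 0L) {
        const_rd <- const_rd + abs(y[a] - y[w])
      } else if (ca[e] == cb[e]) {
        const_rd <- const_rd + abs(y[a] - y[w])
      } else {
        va <- if (ca[e] > 0L) y[a] - (s + t_cur[ca[e]]) else y[a]
        vb <- if (cb[e] > 0L) y[w] - (s + t_cur[cb[e]]) else y[w]
        var_edges <- rbind(var_edges, c(ca[e], cb[e], va, vb))
      }
    }
  }

  eval_perm <- function(perm) {
    td <- const_td
    if (beta > 0) {
      o <- S + cumsum(c(0, q[perm]))[seq_len(k)]
      o_of <- numeric(k)
      o_of[perm] <- o
      for (j in seq_len(k)) {
        if (q[j] > 0L) td <- td + sum(abs(sr[[j]] - (o_of[j] + idx[[j]])))
      }
    }
    rd <- const_rd
    if (use_rd && !is.null(var_edges)) {
      t_new <- cumsum(c(0, b[perm]))[seq_len(k)]
      t_of <- numeric(k)
      t_of[perm] <- t_new
      for (e in seq_len(nrow(var_edges))) {
        cae <- var_edges[e, 1L]
        cbe <- var_edges[e, 2L]
        ya <- if (cae > 0L) var_edges[e, 3L] + s + t_of[cae] else var_edges[e, 3L]
        yb <- if (cbe > 0L) var_edges[e, 4L] + s + t_of[cbe] else var_edges[e, 4L]
        rd <- rd + abs(ya - yb)
      }
    }
    alpha * rd + beta * td
  }
  list(eval = eval_perm, k = k)
}

## Nodes at which the local objective includes RD: LSA of some reticulate
## node, or source of a transfer edge.
osts_nodes <- function(net, bb) {
  rets <- reticulation_nodes(net)
  if (length(rets) == 0L) return(integer(0))
  acc <- acceptor_parent(net)
  lsa_part <- bb$lsa[rets]
  R <- reticulate_edges(net)
  transfer_sources <- R[!is.na(acc[R[, 2L]]), 1L]
  unique(c(lsa_part, transfer_sources))
}

#' One-sided DO-tanglegram optimization
#'
#' Optimizes the child ordering of the free side's backbone tree against a
#' fixed reference ranking, by a preorder traversal: at each node that is
#' the LSA of a reticulate node or the source of a transfer edge the local
#' objective is the one-sided score `alpha * RD + beta * TD`; at all other
#' internal nodes it is the taxon displacement alone.  Each node is
#' optimized with [optimize_children()], seeding the search with the
#' smallest-rank candidate derived from the reference ranking.  The result
#' never scores worse than `initial`.
#'
#' @param free list with components `net` (a `phylo_network`) and `bb` (its
#'   `backbone_tree`).
#' @param fixed_rank the fixed side's ranking of the shared taxa (see
#'   [ranking_of()]).
#' @param cfg a [score_config()]; `alpha` weighs the free side's RD, `beta`
#'   the TD.
#' @param sa a [sa_config()].
#' @param initial starting child ordering (default: as stored).
#' @return the optimized child ordering.
#' @export
one_sided_optimize <- function(free, fixed_rank, cfg = score_config(),
                               sa = sa_config(),
                               initial = initial_ordering(free$bb)) {
  net <- free$net
  bb <- free$bb
  ord <- initial
  alpha <- cfg$alpha
  beta <- cfg$beta
  ret_edges <- reticulate_edges(net)
  rd_nodes <- osts_nodes(net, bb)
  rmin <- subtree_min_refrank(bb, fixed_rank)

  one_pass <- function(ord) {
    lay <- NULL
    stack <- bb$root
    while (length(stack) > 0L) {
      v <- stack[[1L]]
      stack <- stack[-1L]
      ch <- ord[[v]]
      if (length(ch) >= 2L) {
        is_rd <- alpha > 0 && v %in% rd_nodes
        if (is_rd || beta > 0) {
          if (is.null(lay)) lay <- bb_layout(bb, ord)
          loc <- make_local_objective(
            net, bb, ord, v, fixed_rank,
            alpha = if (is_rd) alpha else 0,
            beta = beta, ret_edges = ret_edges, lay = lay
          )
          obj <- function(cand) loc$eval(match(cand, ch))
          cand0 <- reorder_keep_unkeyed(ch, rmin[ch])
          new_ch <- optimize_children(ch, obj, sa, rank_candidate = cand0)
          if (!identical(new_ch, ch)) {
            ord[[v]] <- new_ch
            lay <- NULL
          }
        }
      }
      stack <- c(as.list(ord[[v]]), stack)
    }
    ord
  }

  ## preorder pass plus verification sweeps until no local gain remains
  cur <- one_sided_score(net, bb, ord, fixed_rank,
                         score_config(max(alpha, 0), beta, 1))
  for (sweep in 1:20) {
    ord <- one_pass(ord)
    new <- one_sided_score(net, bb, ord, fixed_rank,
                           score_config(max(alpha, 0), beta, 1))
    if (new >= cur) break
    cur <- new
  }
  ord
}

#' Two-sided DO-tanglegram optimization
#'
#' Optionally NN-presorts both sides, then alternates one-sided
#' optimization (starting with side 2 against side 1) until a full round
#' brings no improvement of the two-sided score, or `sa$max_rounds` rounds
#' have run.  The two-sided score is non-increasing across rounds.
#'
#' @param n1,n2 `phylo_network` objects sharing at least one taxon.
#' @param cfg a [score_config()].
#' @param sa a [sa_config()]; its `seed` drives all randomness.
#' @param presort apply the NN-presorting heuristic before optimizing?
#' @param initial1,initial2 optional starting child orderings (override
#'   presorting).
#' @return a `tanglegram_result`: list with `ordering1`, `ordering2`,
#'   `layout1`, `layout2`, `metrics` (td, crossings, rd1, rd2, score,
#'   n_shared) and `round_scores` (two-sided score after each alternation
#'   round, preceded by the initial score).
#' @export
two_sided_optimize <- function(n1, n2, cfg = score_config(),
                               sa = sa_config(), presort = TRUE,
                               initial1 = NULL, initial2 = NULL) {
  b1 <- backbone_tree(n1)
  b2 <- backbone_tree(n2)
  shared <- shared_taxa(n1, n2)
  if (presort && (is.null(initial1) || is.null(initial2))) {
    ps <- nn_presort_pair(n1, b1, n2, b2)
    o1 <- if (is.null(initial1)) ps$o1 else initial1
    o2 <- if (is.null(initial2)) ps$o2 else initial2
  } else {
    o1 <- if (is.null(initial1)) initial_ordering(b1) else initial1
    o2 <- if (is.null(initial2)) initial_ordering(b2) else initial2
  }
  score <- function(oo1, oo2) {
    two_sided_score(list(net = n1, bb = b1, ord = oo1),
                    list(net = n2, bb = b2, ord = oo2), cfg)
  }
  with_seed(sa$seed, {
    cur <- score(o1, o2)
    round_scores <- cur
    for (round in seq_len(sa$max_rounds)) {
      o2 <- one_sided_optimize(
        list(net = n2, bb = b2), ranking_of(b1, o1, shared),
        score_config(
          alpha = if (cfg$gamma > 0) 1 else 0,
          beta = cfg$beta,
          gamma = 0
        ),
        sa, initial = o2
      )
      o1 <- one_sided_optimize(
        list(net = n1, bb = b1), ranking_of(b2, o2, shared),
        score_config(alpha = cfg$alpha, beta = cfg$beta, gamma = 0),
        sa, initial = o1
      )
      new <- score(o1, o2)
      round_scores <- c(round_scores, new)
      if (new >= cur) break
      cur <- new
    }
  })
  structure(
    list(
      ordering1 = o1,
      ordering2 = o2,
      layout1 = assign_coordinates(b1, o1),
      layout2 = assign_coordinates(b2, o2),
      backbone1 = b1,
      backbone2 = b2,
      net1 = n1,
      net2 = n2,
      metrics = tanglegram_metrics(n1, b1, o1, n2, b2, o2, cfg),
      round_scores = round_scores,
      shared = shared
    ),
    class = "tanglegram_result"
  )
}

#' @export
print.tanglegram_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "DO-tanglegram: %d shared taxa | TD = %g, crossings = %d, RD1 = %g, RD2 = %g, score = %g\n",
    m$n_shared, m$td, m$crossings, m$rd1, m$rd2, m$score
  ))
  invisible(x)
}

## Random re-shuffle of child orders used for restart jobs: all internal
## nodes for a tree, only LSA nodes for a network.
randomize_ordering <- function(net, bb) {
  ord <- initial_ordering(bb)
  nodes <- if (is_tree_network(net)) {
    which(lengths(ord) >= 2L)
  } else {
    intersect(osts_nodes(net, bb), which(lengths(ord) >= 2L))
  }
  for (v in nodes) ord[[v]] <- sample(ord[[v]])
  ord
}

#' Two-sided optimization with seeded independent restarts
#'
#' Runs `sa$jobs` independent two-sided optimizations; job 0 starts from
#' the presorted (or as-input) initialization, jobs >= 1 from random child
#' orders (all internal nodes for trees, LSA nodes for networks).  Job `i`
#' is seeded with `sa$seed + i`; results are merged deterministically by
#' minimal two-sided score, ties broken by crossings, then job index.
#'
#' @inheritParams two_sided_optimize
#' @return the winning `tanglegram_result`, with a `job` element appended.
#' @export
optimize_with_restarts <- function(n1, n2, cfg = score_config(),
                                   sa = sa_config(), presort = TRUE) {
  b1 <- backbone_tree(n1)
  b2 <- backbone_tree(n2)
  best <- NULL
  for (i in seq_len(sa$jobs) - 1L) {
    sa_i <- sa
    sa_i$seed <- sa$seed + i
    res <- if (i == 0L) {
      two_sided_optimize(n1, n2, cfg, sa_i, presort = presort)
    } else {
      inits <- with_seed(sa_i$seed, {
        list(o1 = randomize_ordering(n1, b1), o2 = randomize_ordering(n2, b2))
      })
      two_sided_optimize(n1, n2, cfg, sa_i, presort = FALSE,
                         initial1 = inits$o1, initial2 = inits$o2)
    }
    res$job <- i
    if (is.null(best) ||
        res$metrics$score < best$metrics$score ||
        (res$metrics$score == best$metrics$score &&
         res$metrics$crossings < best$metrics$crossings)) {
      best <- res
    }
  }
  best
}
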