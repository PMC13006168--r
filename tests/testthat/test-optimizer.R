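test_that("exhaustive child optimization is exact brute force", {
  expect_equal(optimize_children(5L, function(o) 0), 5L)
  # 3 children, footrule against a fixed target position
  target <- c(a = 3, b = 1, c = 2)
  obj <- function(ord) sum(abs(match(names(target), ord) - target))
  best <- optimize_children(c("a", "b", "c"), obj, sa_fast())
  P <- dotangle:::perms_lex(3L)
  vals <- apply(P, 1L, function(p) obj(c("a", "b", "c")[p]))
  expect_equal(obj(best), min(vals))
  expect_equal(best, c("b", "c", "a"))
  # constant objective: ties resolve to the first (identity) permutation
  expect_equal(optimize_children(c("x", "y", "z"), function(o) 1, sa_fast()),
               c("x", "y", "z"))
})

test_that("simulated annealing solves a separable 12-child assignment", {
  k <- 12L
  hits <- 0L
  runs <- 20L
  for (i in seq_len(runs)) {
    set.seed(1000L + i)
    target <- sample(k)
    obj <- function(ord) sum((match(seq_len(k), ord) - target)^2)
    res <- dotangle:::with_seed(2000L + i, {
      optimize_children(seq_len(k), obj, sa_fast())
    })
    if (obj(res) == 0) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * runs))
})

test_that("smallest-rank candidate follows subtree minimum ranks", {
  star <- parse_phylogeny("(a,b,c);")
  bbs <- backbone_tree(star)
  ref <- c(c = 1L, a = 2L, b = 3L)
  cand <- smallest_rank_candidate(bbs, star$root, ref)
  expect_equal(star$label[cand], c("c", "a", "b"))

  # subtree min-ranks {5, 2, none, 9} in slots 1..4
  t <- parse_phylogeny("((a1,a2),(b1,b2),(z1,z2),(c1,c2));")
  bbt <- backbone_tree(t)
  ref2 <- c(a1 = 5L, a2 = 6L, b1 = 2L, b2 = 11L, c1 = 9L, c2 = 12L)
  cand2 <- smallest_rank_candidate(bbt, t$root, ref2)
  lab_first <- vapply(cand2, function(v) t$label[bbt$children[[v]][1L]],
                      character(1))
  expect_equal(lab_first, c("b1", "a1", "z1", "c1"))

  # all children unranked: unchanged
  cand3 <- smallest_rank_candidate(bbt, t$root, c(q = 1L))
  expect_equal(cand3, initial_ordering(bbt)[[t$root]])
})

test_that("one-sided optimization recovers perfect alignments", {
  # star free side: rank candidate gives zero TD even past the threshold
  n_leaves <- 12L
  star_txt <- paste0("(", paste(paste0("s", 1:n_leaves), collapse = ","), ");")
  star <- parse_phylogeny(star_txt)
  ref_tree <- shuffled_copy(star, 5L)
  bref <- backbone_tree(ref_tree)
  bstar <- backbone_tree(star)
  sh <- shared_taxa(star, ref_tree)
  ref <- ranking_of(bref, initial_ordering(bref), sh)
  o <- dotangle:::with_seed(1L, one_sided_optimize(
    list(net = star, bb = bstar), ref, score_config(0, 1, 0), sa_fast()
  ))
  expect_equal(taxon_displacement(ref, ranking_of(bstar, o, sh)), 0)

  # free side identical to the fixed side
  tr <- random_background_tree(25L, seed = 14L)
  free <- shuffled_copy(tr, 15L)
  bfix <- backbone_tree(tr)
  bfree <- backbone_tree(free)
  sh <- shared_taxa(tr, free)
  ref <- ranking_of(bfix, initial_ordering(bfix), sh)
  o <- dotangle:::with_seed(2L, one_sided_optimize(
    list(net = free, bb = bfree), ref, score_config(0, 1, 0), sa_fast()
  ))
  r2 <- ranking_of(bfree, o, sh)
  expect_equal(taxon_displacement(ref, r2), 0)
  expect_equal(count_crossings(ref, r2), 0L)
})

test_that("the local objective equals a from-scratch recomputation", {
  nw <- random_network(12L, 3L, 77L)
  bb <- backbone_tree(nw)
  o <- initial_ordering(bb)
  shared <- sort(network_taxa(nw))
  set.seed(9)
  ref <- stats::setNames(sample(length(shared)), shared)
  re <- reticulate_edges(nw)
  for (v in which(lengths(o) >= 2L)) {
    loc <- dotangle:::make_local_objective(nw, bb, o, v, ref,
                                           alpha = 1, beta = 1,
                                           ret_edges = re)
    ch <- o[[v]]
    P <- dotangle:::perms_lex(length(ch))
    for (r in seq_len(nrow(P))) {
      oo <- o
      oo[[v]] <- ch[P[r, ]]
      expect_equal(
        loc$eval(P[r, ]),
        one_sided_score(nw, bb, oo, ref, score_config(1, 1, 1))
      )
    }
  }
})

test_that("two-sided optimization matches exhaustive oracles on toys", {
  a <- parse_phylogeny("((a,b),c);")
  b <- parse_phylogeny("((b,a),c);")
  res <- two_sided_optimize(a, b, score_config(1, 1, 1), sa_fast(seed = 3L))
  expect_equal(res$metrics$td, 0)
  expect_equal(res$metrics$crossings, 0L)

  # network vs tree toy: achieved TSTS equals full enumeration
  nw <- parse_phylogeny("((l1,(l3)#H1)a,(#H1,l2)b);")
  tr <- parse_phylogeny("((l1,l3),l2);")
  res <- two_sided_optimize(nw, tr, score_config(1, 1, 1), sa_fast(seed = 4L))
  b1 <- backbone_tree(nw)
  b2 <- backbone_tree(tr)
  sh <- shared_taxa(nw, tr)
  best <- local({
    opt <- Inf
    f1 <- function(o1) {
      enumerate_min(b2, function(o2) {
        two_sided_score(list(net = nw, bb = b1, ord = o1),
                        list(net = tr, bb = b2, ord = o2),
                        score_config(1, 1, 1))
      })
    }
    o <- initial_ordering(b1)
    internal <- which(lengths(o) >= 2L)
    rec <- function(i, o) {
      if (i > length(internal)) {
        opt <<- min(opt, f1(o))
        return(invisible())
      }
      v <- internal[i]
      ch <- o[[v]]
      P <- dotangle:::perms_lex(length(ch))
      for (r in seq_len(nrow(P))) {
        o[[v]] <- ch[P[r, ]]
        rec(i + 1L, o)
      }
    }
    rec(1L, o)
    opt
  })
  expect_equal(res$metrics$score, best)
})

test_that("alternation is monotone and results are self-consistent", {
  cfg <- synthetic_config(n = 30L, m = 0.05, c = 0.05, k = 5L, seed = 99L)
  pair <- generate_pair(cfg)
  res <- two_sided_optimize(pair$n1, pair$n2, score_config(1, 1, 1),
                            sa_fast(seed = 8L))
  expect_true(all(diff(res$round_scores) <= 1e-9))
  m2 <- dotangle:::tanglegram_metrics(
    pair$n1, res$backbone1, res$ordering1,
    pair$n2, res$backbone2, res$ordering2, score_config(1, 1, 1)
  )
  expect_equal(res$metrics, m2)
})

test_that("restarts are deterministic and merge by score", {
  tr <- random_background_tree(50L, seed = 33L)
  a <- shuffled_copy(tr, 34L)
  b <- shuffled_copy(tr, 35L)
  res <- optimize_with_restarts(a, b, score_config(1, 1, 1),
                                sa_fast(seed = 5L, jobs = 4L))
  expect_equal(res$metrics$score, 0)
  expect_equal(res$metrics$crossings, 0L)

  cfg <- synthetic_config(n = 25L, r = 0.2, seed = 7L)
  pair <- generate_pair(cfg)
  r1 <- optimize_with_restarts(pair$n1, pair$n2, score_config(1, 1, 1),
                               sa_fast(seed = 11L, jobs = 3L))
  r2 <- optimize_with_restarts(pair$n1, pair$n2, score_config(1, 1, 1),
                               sa_fast(seed = 11L, jobs = 3L))
  expect_identical(r1$ordering1, r2$ordering1)
  expect_identical(r1$ordering2, r2$ordering2)
  expect_identical(r1$metrics, r2$metrics)
  # jobs = 1 equals a plain two-sided run with the same seed
  single <- optimize_with_restarts(pair$n1, pair$n2, score_config(1, 1, 1),
                                   sa_fast(seed = 11L, jobs = 1L))
  plain <- two_sided_optimize(pair$n1, pair$n2, score_config(1, 1, 1),
                              sa_fast(seed = 11L))
  expect_identical(single$metrics, plain$metrics)
  expect_identical(single$ordering2, plain$ordering2)
})
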