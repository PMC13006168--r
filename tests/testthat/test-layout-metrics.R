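test_that("coordinates follow the postorder-leaf / mean-y rule", {
  one <- parse_phylogeny("(a);")
  bb1 <- backbone_tree(one)
  lay <- assign_coordinates(bb1, initial_ordering(bb1))
  expect_equal(lay$x[one$root], 0L)
  expect_equal(unname(lay$y), c(1, 1))

  t <- parse_phylogeny("((a,b),c);")
  bb <- backbone_tree(t)
  lay <- assign_coordinates(bb, initial_ordering(bb))
  lab <- t$label
  y_of <- function(l) lay$y[which(!is.na(lab) & lab == l)]
  expect_equal(y_of("a"), 1)
  expect_equal(y_of("b"), 2)
  expect_equal(y_of("c"), 3)
  inner <- setdiff(which(lengths(t$children) > 0L), t$root)
  expect_equal(unname(lay$y[inner]), 1.5)
  expect_equal(unname(lay$y[t$root]), 2)
})

test_that("internal y equals the mean over descendant leaves (oracle)", {
  tr <- random_background_tree(20L, seed = 4L)
  bb <- backbone_tree(tr)
  o <- initial_ordering(bb)
  lay <- assign_coordinates(bb, o)
  desc_leaves <- function(v) {
    ch <- bb$children[[v]]
    if (length(ch) == 0L) return(v)
    unlist(lapply(ch, desc_leaves))
  }
  for (v in seq_len(bb$n)) {
    expect_equal(lay$y[v], mean(lay$y[desc_leaves(v)]))
  }
  expect_equal(sort(lay$y[lay$leaf_seq]), seq_along(lay$leaf_seq))
})

test_that("rankings skip unshared leaves and stay bijective", {
  t <- parse_phylogeny("((a,b),c);")
  bb <- backbone_tree(t)
  r <- ranking_of(bb, initial_ordering(bb), c("a", "b", "c"))
  expect_equal(r, c(a = 1L, b = 2L, c = 3L))

  t2 <- parse_phylogeny("((a,z),b);")
  bb2 <- backbone_tree(t2)
  r2 <- ranking_of(bb2, initial_ordering(bb2), c("a", "b"))
  expect_equal(r2, c(a = 1L, b = 2L))

  tr <- random_background_tree(30L, seed = 8L)
  shared <- sort(sample(network_taxa(tr), 20L))
  bbr <- backbone_tree(tr)
  rr <- ranking_of(bbr, initial_ordering(bbr), shared)
  expect_setequal(names(rr), shared)
  expect_setequal(unname(rr), 1:20)
})

test_that("taxon displacement is the Spearman footrule", {
  r1 <- c(a = 1L, b = 2L, c = 3L)
  expect_equal(taxon_displacement(r1, r1), 0)
  r2 <- c(c = 1L, b = 2L, a = 3L)
  expect_equal(taxon_displacement(r1, r2), 4)
  expect_equal(taxon_displacement(r2, r1), 4)       # symmetric
  expect_error(taxon_displacement(r1, c(a = 1L, b = 2L, d = 3L)),
               "same taxon set")
  # relabeling invariance
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:40, 1L)
    taxa <- paste0("x", seq_len(n))
    p1 <- stats::setNames(sample(n), taxa)
    p2 <- stats::setNames(sample(n), taxa)
    relab <- stats::setNames(paste0("y", sample(n)), taxa)
    q1 <- stats::setNames(unname(p1), relab[names(p1)])
    q2 <- stats::setNames(unname(p2), relab[names(p2)])
    expect_equal(taxon_displacement(p1, p2), taxon_displacement(q1, q2))
    expect_equal(count_crossings(p1, p2), count_crossings(q1, q2))
    expect_equal(taxon_displacement(p1, p2) == 0, all(p1 == p2[names(p1)]))
  }
})

test_that("crossing counts match the quadratic oracle", {
  r1 <- c(a = 1L, b = 2L, c = 3L)
  expect_equal(count_crossings(r1, r1), 0L)
  expect_equal(count_crossings(r1, c(a = 3L, b = 2L, c = 1L)), 3L)
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(2:60, 1L)
    taxa <- paste0("t", seq_len(n))
    p1 <- stats::setNames(sample(n), taxa)
    p2 <- stats::setNames(sample(n), taxa)
    expect_equal(count_crossings(p1, p2), crossings_oracle(p1, p2))
  }
})

test_that("reticulate displacement matches hand layouts", {
  t <- parse_phylogeny("((a,b),c);")
  expect_equal(
    reticulate_displacement(t, backbone_tree(t),
                            initial_ordering(backbone_tree(t))),
    0
  )
  nw <- parse_phylogeny("((l1,(l3)#H1)a,(#H1,l2)b);")
  bb <- backbone_tree(nw)
  o <- initial_ordering(bb)
  ret <- which(lengths(nw$parents) >= 2L)
  ch <- o[[bb$root]]
  # root children (a, h, b): RD = 2; (a, b, h): RD = 3
  o[[bb$root]] <- c(ch[1L], ret, setdiff(ch, c(ch[1L], ret)))
  expect_equal(reticulate_displacement(nw, bb, o), 2)
  o[[bb$root]] <- c(setdiff(ch, ret), ret)
  expect_equal(reticulate_displacement(nw, bb, o), 3)
  # brute force over the 3! root orders: the minimum is 2
  vals <- apply(dotangle:::perms_lex(3L), 1L, function(p) {
    oo <- initial_ordering(bb)
    oo[[bb$root]] <- ch[p]
    reticulate_displacement(nw, bb, oo)
  })
  expect_equal(min(vals), 2)
})

test_that("one- and two-sided scores are additive in their terms", {
  nw <- parse_phylogeny("((l1,(l3)#H1)a,(#H1,l2)b);")
  bb <- backbone_tree(nw)
  o <- initial_ordering(bb)
  shared <- c("l1", "l2", "l3")
  ref <- c(l2 = 1L, l1 = 2L, l3 = 3L)
  rd <- reticulate_displacement(nw, bb, o)
  td <- taxon_displacement(ref, ranking_of(bb, o, shared))
  expect_equal(one_sided_score(nw, bb, o, ref, score_config(0, 1, 1)), td)
  expect_equal(one_sided_score(nw, bb, o, ref, score_config(1, 0, 1)), rd)
  expect_equal(one_sided_score(nw, bb, o, ref, score_config(1, 1, 1)), rd + td)

  t <- parse_phylogeny("((l1,l3),l2);")
  bt <- backbone_tree(t)
  s1 <- list(net = nw, bb = bb, ord = o)
  s2 <- list(net = t, bb = bt, ord = initial_ordering(bt))
  td2 <- taxon_displacement(ranking_of(bb, o, shared),
                            ranking_of(bt, s2$ord, shared))
  expect_equal(two_sided_score(s1, s2, score_config(1, 1, 1)), rd + td2)
  expect_equal(two_sided_score(s2, s1, score_config(0, 1, 1)), td2 + rd)
  expect_equal(two_sided_score(s2, s2, score_config(1, 1, 1)), 0)
})

test_that("TD attains its reversal bound and never exceeds it", {
  for (n in 2:8) {
    taxa <- paste0("t", seq_len(n))
    id <- stats::setNames(seq_len(n), taxa)
    rev_r <- stats::setNames(rev(seq_len(n)), taxa)
    expect_equal(taxon_displacement(id, rev_r), floor(n^2 / 2))
  }
  # exhaustive maximum for small n
  for (n in 2:6) {
    taxa <- paste0("t", seq_len(n))
    id <- stats::setNames(seq_len(n), taxa)
    P <- dotangle:::perms_lex(n)
    vals <- apply(P, 1L, function(p) {
      taxon_displacement(id, stats::setNames(p, taxa))
    })
    expect_equal(max(vals), floor(n^2 / 2))
  }
})
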