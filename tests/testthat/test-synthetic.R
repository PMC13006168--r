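test_that("background trees are binary, labeled, and reproducible", {
  t2 <- random_background_tree(2L, seed = 1L)
  expect_equal(length(leaf_nodes(t2)), 2L)
  expect_equal(write_phylogeny(t2), "(t001,t002);")

  t50 <- random_background_tree(50L, seed = 2L)
  expect_equal(length(leaf_nodes(t50)), 50L)
  expect_equal(t50$n, 99L)                     # binary: n leaves - 1 internal
  expect_true(all(lengths(t50$children) %in% c(0L, 2L)))
  expect_identical(write_phylogeny(random_background_tree(50L, seed = 2L)),
                   write_phylogeny(t50))
  expect_false(identical(write_phylogeny(random_background_tree(50L, 3L)),
                         write_phylogeny(t50)))
})

test_that("subtree extraction is the induced restriction", {
  t4 <- parse_phylogeny("((a,b),(c,d));")
  r <- dotangle:::restrict_tree(t4, c("a", "c"))
  expect_equal(write_phylogeny(r), "(a,c);")

  tr <- random_background_tree(10L, seed = 6L)
  full <- extract_subtree(tr, 10L, seed = 1L)
  expect_equal(net_signature(full), net_signature(tr))

  # restriction preserves rooted triplets of the kept taxa
  for (seed in c(4L, 9L)) {
    tr <- random_background_tree(10L, seed = seed)
    sub <- extract_subtree(tr, 6L, seed = seed + 1L)
    keep <- network_taxa(sub)
    set.seed(seed)
    for (rep in 1:15) {
      xyz <- sort(sample(keep, 3L))
      expect_equal(triplet_of(sub, xyz), triplet_of(tr, xyz))
    }
  }
})

test_that("rSPR moves keep valid binary trees and usually change topology", {
  tr <- random_background_tree(20L, seed = 10L)
  expect_identical(apply_rspr(tr, 0L, seed = 1L), tr)
  cluster_key <- function(t) {
    sort(vapply(hardwired_clusters(t, sort(network_taxa(t))),
                paste, character(1), collapse = ","))
  }
  changed <- 0L
  for (seed in 1:100) {
    out <- apply_rspr(tr, 1L, seed = seed)
    expect_setequal(network_taxa(out), network_taxa(tr))
    expect_true(all(lengths(out$children) %in% c(0L, 2L)))
    validate_network(out)
    if (!identical(cluster_key(out), cluster_key(tr))) changed <- changed + 1L
  }
  expect_gte(changed, 95L)
})

test_that("taxon deletion removes the requested count and stays valid", {
  tr <- random_background_tree(100L, seed = 12L)
  expect_identical(delete_taxa(tr, 0, seed = 1L), tr)
  d <- delete_taxa(tr, 0.1, seed = 3L)
  expect_equal(length(leaf_nodes(d)), 90L)
  for (seed in 1:10) {
    d <- delete_taxa(tr, 0.25, seed = seed)
    validate_network(d)
    expect_equal(length(leaf_nodes(d)), 75L)
  }
  small <- random_background_tree(3L, seed = 1L)
  expect_error(delete_taxa(small, 0.9, seed = 1L), "fewer than 2")
})

test_that("edge contraction produces the requested multifurcations", {
  tr <- random_background_tree(10L, seed = 20L)
  expect_identical(contract_edges(tr, 0, seed = 1L), tr)
  star <- contract_edges(tr, 1, seed = 1L)
  expect_setequal(network_taxa(star), network_taxa(tr))
  expect_equal(length(star$children[[star$root]]), length(leaf_nodes(tr)))
  mid <- contract_edges(tr, 0.5, seed = 2L)
  validate_network(mid)
  expect_setequal(network_taxa(mid), network_taxa(tr))
})

test_that("reticulation insertion stays acyclic and counts structure", {
  tr <- random_background_tree(20L, seed = 30L)
  expect_identical(add_reticulations(tr, 0L, seed = 1L), tr)
  one <- add_reticulations(tr, 1L, seed = 2L)
  expect_equal(one$n, tr$n + 2L)
  expect_equal(sum(lengths(one$children)), sum(lengths(tr$children)) + 3L)
  expect_equal(sum(lengths(one$parents) == 2L), 1L)
  for (seed in 1:30) {
    nw <- add_reticulations(random_background_tree(50L, seed = seed), 10L,
                            seed = seed)
    validate_network(nw)   # includes the acyclicity check
    expect_equal(sum(lengths(nw$parents) >= 2L), 10L)
  }
})

test_that("generate_pair follows the tree and network recipes", {
  id <- generate_pair(synthetic_config(n = 40L, seed = 5L))
  expect_identical(write_phylogeny(id$n1), write_phylogeny(id$n2))

  cfg <- synthetic_config(n = 100L, r = 0.2, m = 0.1, seed = 6L)
  pair <- generate_pair(cfg)
  expect_equal(length(leaf_nodes(pair$n1)), 90L)
  expect_equal(length(leaf_nodes(pair$n2)), 90L)
  sh <- shared_taxa(pair$n1, pair$n2)
  expect_gte(length(sh), 80L)
  expect_lte(length(sh), 90L)

  nets <- generate_pair(synthetic_config(n = 40L, m = 0.05, c = 0.05,
                                         k = 10L, seed = 7L))
  expect_equal(sum(lengths(nets$n1$parents) >= 2L), 10L)
  expect_equal(sum(lengths(nets$n2$parents) >= 2L), 10L)
  validate_network(nets$n1)
  validate_network(nets$n2)

  again <- generate_pair(cfg)
  expect_identical(write_phylogeny(again$n1), write_phylogeny(pair$n1))
  expect_identical(write_phylogeny(again$n2), write_phylogeny(pair$n2))
})
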