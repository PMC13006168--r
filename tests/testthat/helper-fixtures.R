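# Shared helpers: all fixtures are generated in code.

# Scaled-down annealing schedule so suite runtime stays small; the search
# structure (Metropolis pair swaps, exhaustive <= 8 children) is unchanged.
sa_fast <- function(seed = 1L, ...) {
  sa_config(start_temperature = 100, end_temperature = 0.1,
            iterations_per_step = 200, cooling_rate = 0.9, seed = seed, ...)
}

# A copy of `net` re-serialized with uniformly shuffled child orders.
shuffled_copy <- function(net, seed) {
  set.seed(seed)
  bb <- backbone_tree(net)
  o <- initial_ordering(bb)
  for (v in which(lengths(o) >= 2L)) o[[v]] <- sample(o[[v]])
  parse_phylogeny(write_phylogeny(net, o))
}

# Canonical signature of a labeled rooted DAG: per-node strings built from
# sorted child signatures (leaves contribute their unique labels, internal
# nodes their in-degree), compared as the multiset of signed edges plus the
# root signature.  Equal signatures on uniquely leaf-labeled networks imply
# isomorphism for the instances used here.
net_signature <- function(net) {
  n <- net$n
  indeg <- lengths(net$parents)
  canon <- rep(NA_character_, n)
  visit <- function(v) {
    if (!is.na(canon[v])) return(canon[v])
    ch <- net$children[[v]]
    canon[v] <<- if (length(ch) == 0L) {
      paste0("L<", net$label[v], ">")
    } else {
      paste0("[", indeg[v], "](",
             paste(sort(vapply(ch, visit, character(1))), collapse = ","), ")")
    }
    canon[v]
  }
  visit(net$root)
  for (v in seq_len(n)) visit(v)
  edges <- character(0)
  for (p in seq_len(n)) {
    for (w in net$children[[p]]) {
      edges <- c(edges, paste0(canon[p], " -> ", canon[w]))
    }
  }
  list(root = canon[net$root], edges = sort(edges))
}

# Random network fixture: background tree restricted to `ntaxa`, plus `k`
# random combining reticulations.
random_network <- function(ntaxa, k, seed) {
  bg <- random_background_tree(max(ntaxa, 20L), seed = seed)
  t0 <- extract_subtree(bg, ntaxa, seed = seed + 1L)
  add_reticulations(t0, k, seed = seed + 2L)
}

# Enumerate all complete child orderings of a backbone tree and report the
# minimum of `fn(ordering)` (exhaustive oracle for small instances).
enumerate_min <- function(bb, fn) {
  o <- initial_ordering(bb)
  internal <- which(lengths(o) >= 2L)
  best <- Inf
  rec <- function(i) {
    if (i > length(internal)) {
      best <<- min(best, fn(o))
      return(invisible())
    }
    v <- internal[i]
    ch <- o[[v]]
    P <- dotangle:::perms_lex(length(ch))
    for (r in seq_len(nrow(P))) {
      o[[v]] <<- ch[P[r, ]]
      rec(i + 1L)
    }
    o[[v]] <<- ch
  }
  rec(1L)
  best
}

# Brute-force LSA oracle: enumerate every root -> v path, intersect the
# node sets, return the common node closest to v.
lsa_oracle <- function(net, v) {
  paths <- list()
  walk <- function(u, acc) {
    acc <- c(u, acc)
    if (u == net$root) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible())
    }
    for (p in net$parents[[u]]) walk(p, acc)
  }
  walk(v, integer(0))
  common <- Reduce(intersect, paths)
  common <- setdiff(common, v)
  ref <- paths[[1L]]                 # dominators appear in path order
  ref[ref %in% common][sum(ref %in% common)]
}

# O(n^2) crossing-count oracle.
crossings_oracle <- function(r1, r2) {
  taxa <- names(r1)
  n <- length(taxa)
  cnt <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- taxa[i]; t <- taxa[j]
      if ((r1[s] - r1[t]) * (r2[s] - r2[t]) < 0) cnt <- cnt + 1L
    }
  }
  cnt
}

# Rooted-triplet topology of three taxa in a tree: the cherry pair, or ""
# for an unresolved triplet.
triplet_of <- function(tree, xyz) {
  cl <- hardwired_clusters(tree, xyz)
  two <- Filter(function(C) length(C) == 2L, cl)
  if (length(two) == 0L) "" else paste(sort(two[[1L]]), collapse = "|")
}
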