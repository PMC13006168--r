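#' @keywords internal
"_PACKAGE"

## Rooted phylogenetic networks ------------------------------------------
##
## A network N = (V, E, rho, lambda) is stored as an S3 list of parallel,
## node-indexed structures.  Children lists are authoritative for edge order
## (the order in which subtrees appeared in the input text); per-edge
## attributes (branch length, transfer-acceptor flag) are kept aligned with
## the children lists.

new_phylo_network <- function(children, label,
                              child_length = NULL, child_acceptor = NULL,
                              validate = TRUE) {
  n <- length(children)
  children <- lapply(children, as.integer)
  if (length(label) != n) stop("label vector must have one entry per node")
  if (is.null(child_length)) {
    child_length <- lapply(children, function(ch) rep(NA_real_, length(ch)))
  }
  if (is.null(child_acceptor)) {
    child_acceptor <- lapply(children, function(ch) rep(FALSE, length(ch)))
  }
  parents <- vector("list", n)
  for (v in seq_len(n)) parents[[v]] <- integer(0)
  for (v in seq_len(n)) {
    for (w in children[[v]]) parents[[w]] <- c(parents[[w]], v)
  }
  indeg <- lengths(parents)
  roots <- which(indeg == 0L)
  net <- structure(
    list(
      n = n,
      children = children,
      parents = parents,
      root = if (length(roots) == 1L) roots else NA_integer_,
      label = as.character(label),
      child_length = child_length,
      child_acceptor = child_acceptor
    ),
    class = "phylo_network"
  )
  if (validate) validate_network(net)
  net
}

out_degree <- function(net) lengths(net$children)
in_degree <- function(net) lengths(net$parents)

#' Leaf nodes and taxa of a network
#'
#' Leaves are the nodes of out-degree zero; the taxa of a network are the
#' labels carried by its leaves.
#'
#' @param net a `phylo_network`.
#' @return `leaf_nodes()`: integer node ids; `network_taxa()`: character
#'   vector of taxon labels in node-id order.
#' @export
leaf_nodes <- function(net) which(out_degree(net) == 0L)

#' @rdname leaf_nodes
#' @export
network_taxa <- function(net) net$label[leaf_nodes(net)]

#' @export
print.phylo_network <- function(x, ...) {
  nret <- sum(in_degree(x) >= 2L)
  cat(sprintf(
    "Rooted phylogenetic %s: %d taxa, %d nodes, %d reticulation node%s\n",
    if (nret == 0L) "tree" else "network",
    length(leaf_nodes(x)), x$n, nret, if (nret == 1L) "" else "s"
  ))
  invisible(x)
}

is_tree_network <- function(net) all(in_degree(net) <= 1L)

reticulation_nodes <- function(net) which(in_degree(net) >= 2L)

## The designated transfer-acceptor parent of each node (NA if none).
acceptor_parent <- function(net) {
  out <- rep(NA_integer_, net$n)
  for (v in seq_len(net$n)) {
    acc <- net$child_acceptor[[v]]
    if (any(acc)) {
      for (w in net$children[[v]][acc]) {
        if (!is.na(out[w])) {
          stop("validation error: node has more than one transfer-acceptor edge")
        }
        out[w] <- v
      }
    }
  }
  out
}

## Topological order (parents before children); NULL if the graph is cyclic.
topo_order <- function(net) {
  indeg <- lengths(net$parents)
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    ord <- c(ord, v)
    for (w in net$children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(ord) != net$n) NULL else ord
}

#' Validate the structural conditions of a rooted phylogenetic network
#'
#' Checks the five definitional conditions: (1) the directed graph is
#' acyclic, (2) there is a unique in-degree-0 node, the root, (3) taxon
#' labels are in bijection with the out-degree-0 nodes, (4) no node has both
#' in-degree 1 and out-degree 1, and (5) every leaf has in-degree at most 1.
#' Additionally every transfer-acceptor edge must end at a node of in-degree
#' at least 2, with at most one acceptor edge per node.
#'
#' @param net a `phylo_network`.
#' @return `net`, invisibly; stops with a message naming the violated
#'   condition otherwise.
#' @export
validate_network <- function(net) {
  indeg <- in_degree(net)
  outdeg <- out_degree(net)
  roots <- which(indeg == 0L)
  if (length(roots) != 1L) {
    stop(sprintf(
      "validation error (condition 2): expected a unique in-degree-0 root, found %d",
      length(roots)
    ))
  }
  if (is.null(topo_order(net))) {
    stop("validation error (condition 1): directed graph contains a cycle")
  }
  leaves <- which(outdeg == 0L)
  lab <- net$label[leaves]
  if (anyNA(lab) || any(!nzchar(lab))) {
    stop("validation error (condition 3): unlabeled leaf (lambda must be a bijection)")
  }
  if (anyDuplicated(lab)) {
    stop(sprintf(
      "validation error (condition 3): duplicate taxon label '%s'",
      lab[duplicated(lab)][1L]
    ))
  }
  if (any(indeg == 1L & outdeg == 1L)) {
    stop("validation error (condition 4): node with in-degree 1 and out-degree 1")
  }
  if (any(indeg[leaves] > 1L)) {
    stop("validation error (condition 5): leaf with in-degree > 1")
  }
  acc <- acceptor_parent(net)  # errors if a node has two acceptor edges
  bad <- which(!is.na(acc) & indeg < 2L)
  if (length(bad) > 0L) {
    stop("validation error: transfer-acceptor edge ends at a node of in-degree < 2")
  }
  invisible(net)
}

## eNewick parsing --------------------------------------------------------

#' Parse a Newick or extended-Newick (eNewick) phylogeny
#'
#' Reticulations are encoded by repeated `#H<id>` labels (eNewick
#' convention): all occurrences sharing a tag are merged into a single
#' reticulation node, and the occurrence carrying a subtree contributes its
#' children.  A bracketed comment containing the token `&acceptor` on an
#' occurrence (e.g. `#H1[&acceptor]`) marks the corresponding incoming edge
#' as the transfer-acceptor edge of that reticulation node.  Branch lengths
#' and internal node labels are parsed and retained but ignored by all
#' layout computations.
#'
#' @param text a single Newick/eNewick statement terminated by `";"`.
#' @return a validated `phylo_network`.
#' @export
#' @examples
#' parse_phylogeny("((a,b),c);")
#' parse_phylogeny("((a,(h)#H1),(#H1,b));")
parse_phylogeny <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  nch <- length(chars)
  pos <- 1L

  peek <- function() if (pos <= nch) chars[pos] else ""
  adv <- function() pos <<- pos + 1L
  perr <- function(msg) stop(sprintf("parse error at position %d: %s", pos, msg))
  skip_ws <- function() while (pos <= nch && grepl("^\\s$", chars[pos])) adv()

  ## occurrence records
  o_parent <- integer(0)
  o_name <- character(0)
  o_tag <- character(0)
  o_acc <- logical(0)
  o_len <- numeric(0)
  o_haschild <- logical(0)
  new_occ <- function(parent) {
    o_parent[length(o_parent) + 1L] <<- parent
    o_name[length(o_name) + 1L] <<- ""
    o_tag[length(o_tag) + 1L] <<- NA_character_
    o_acc[length(o_acc) + 1L] <<- FALSE
    o_len[length(o_len) + 1L] <<- NA_real_
    o_haschild[length(o_haschild) + 1L] <<- FALSE
    length(o_parent)
  }

  read_comment <- function() {
    # positioned on "["
    adv()
    buf <- character(0)
    while (pos <= nch && chars[pos] != "]") {
      buf <- c(buf, chars[pos])
      adv()
    }
    if (pos > nch) perr("unterminated comment")
    adv()
    paste(buf, collapse = "")
  }

  read_name <- function() {
    skip_ws()
    if (peek() == "'") {
      adv()
      buf <- character(0)
      repeat {
        if (pos > nch) perr("unterminated quoted label")
        ch <- chars[pos]
        adv()
        if (ch == "'") {
          if (peek() == "'") { buf <- c(buf, "'"); adv() } else break
        } else buf <- c(buf, ch)
      }
      paste(buf, collapse = "")
    } else {
      buf <- character(0)
      while (pos <= nch && !(chars[pos] %in% c("(", ")", ",", ";", ":", "["))) {
        buf <- c(buf, chars[pos])
        adv()
      }
      trimws(paste(buf, collapse = ""))
    }
  }

  parse_subtree <- function(parent) {
    skip_ws()
    id <- new_occ(parent)
    if (peek() == "(") {
      adv()
      o_haschild[id] <<- TRUE
      repeat {
        parse_subtree(id)
        skip_ws()
        if (peek() == ",") { adv(); next }
        if (peek() == ")") { adv(); break }
        perr("expected ',' or ')'")
      }
    }
    nm <- read_name()
    if (grepl("#", nm, fixed = TRUE)) {
      tag <- sub("^[^#]*#", "", nm)
      if (!nzchar(tag)) perr("empty reticulation tag after '#'")
      o_tag[id] <<- tag
      o_name[id] <<- sub("#.*$", "", nm)
    } else {
      o_name[id] <<- nm
    }
    repeat {
      skip_ws()
      if (peek() == "[") {
        cm <- read_comment()
        if (grepl("&acceptor", cm, fixed = TRUE)) o_acc[id] <<- TRUE
      } else if (peek() == ":") {
        adv()
        skip_ws()
        numbuf <- character(0)
        while (pos <= nch && grepl("^[-+0-9.eE]$", chars[pos])) {
          numbuf <- c(numbuf, chars[pos])
          adv()
        }
        val <- suppressWarnings(as.numeric(paste(numbuf, collapse = "")))
        if (is.na(val)) perr("malformed branch length")
        o_len[id] <<- val
      } else break
    }
    id
  }

  skip_ws()
  if (pos > nch) perr("empty input")
  parse_subtree(NA_integer_)
  skip_ws()
  if (peek() != ";") perr("expected ';'")
  adv()
  skip_ws()
  if (pos <= nch) perr("trailing text after ';'")

  ## merge occurrences sharing a reticulation tag into single nodes
  nocc <- length(o_parent)
  tags <- unique(o_tag[!is.na(o_tag)])
  for (tg in tags) {
    grp <- which(o_tag == tg)
    if (length(grp) < 2L) {
      stop(sprintf(
        "validation error: reticulation tag '#%s' used as child of only one parent", tg
      ))
    }
    if (sum(o_haschild[grp]) > 1L) {
      stop(sprintf(
        "parse error: reticulation tag '#%s' carries more than one subtree", tg
      ))
    }
  }
  node_of <- integer(nocc)
  nxt <- 0L
  tag_node <- stats::setNames(rep(NA_integer_, length(tags)), tags)
  for (i in seq_len(nocc)) {
    if (!is.na(o_tag[i])) {
      if (is.na(tag_node[[o_tag[i]]])) {
        nxt <- nxt + 1L
        tag_node[[o_tag[i]]] <- nxt
      }
      node_of[i] <- tag_node[[o_tag[i]]]
    } else {
      nxt <- nxt + 1L
      node_of[i] <- nxt
    }
  }
  n <- nxt
  children <- rep(list(integer(0)), n)
  child_length <- rep(list(numeric(0)), n)
  child_acceptor <- rep(list(logical(0)), n)
  label <- rep(NA_character_, n)
  for (i in seq_len(nocc)) {
    v <- node_of[i]
    if (nzchar(o_name[i]) && is.na(label[v])) label[v] <- o_name[i]
    if (!is.na(o_parent[i])) {
      p <- node_of[o_parent[i]]
      children[[p]] <- c(children[[p]], v)
      child_length[[p]] <- c(child_length[[p]], o_len[i])
      child_acceptor[[p]] <- c(child_acceptor[[p]], o_acc[i])
    }
  }
  new_phylo_network(children, label, child_length, child_acceptor)
}

#' Read one phylogeny per statement from a file
#'
#' @param path path to a UTF-8 text file containing a single Newick/eNewick
#'   statement (anything after the first `";"` is ignored).
#' @return a `phylo_network`.
#' @export
read_phylogeny <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  semi <- regexpr(";", txt, fixed = TRUE)
  if (semi < 0L) stop("parse error: no ';' found in file ", path)
  parse_phylogeny(substr(txt, 1L, semi))
}

## eNewick writing --------------------------------------------------------

quote_label <- function(x) {
  if (grepl("[](),;:#'[[:space:]\\[]", x)) {
    paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
  } else x
}

#' Write a network as Newick/eNewick
#'
#' Children of each node are emitted in the order given by `ordering` (a
#' backbone child ordering, see [backbone_tree()]); network children not
#' covered by the ordering (e.g. reticulation children whose backbone parent
#' is elsewhere) keep their stored relative order and follow the ordered
#' ones.  Reticulation nodes are split into occurrences sharing a fresh
#' `#H<i>` tag; transfer-acceptor edges carry an `[&acceptor]` comment.
#'
#' @param net a `phylo_network`.
#' @param ordering optional child ordering as produced by [initial_ordering()]
#'   or the optimizers; default: stored order.
#' @param with_lengths emit stored branch lengths?
#' @return a single eNewick string terminated by `";"`.
#' @export
write_phylogeny <- function(net, ordering = NULL, with_lengths = TRUE) {
  if (!is.null(ordering)) {
    need <- which(lengths(net$children) >= 2L)
    covered <- vapply(need, function(v) {
      v <= length(ordering) && !is.null(ordering[[v]])
    }, logical(1))
    miss <- need[!covered]
    if (length(miss) > 0L) {
      stop("ordering does not cover internal node ", miss[1L])
    }
  }
  ret <- reticulation_nodes(net)
  tag_of <- rep(NA_character_, net$n)
  seen <- rep(FALSE, net$n)
  tag_count <- 0L
  acc_parent <- acceptor_parent(net)

  order_children <- function(v) {
    ch <- net$children[[v]]
    if (length(ch) <= 1L) return(seq_along(ch))
    if (!is.null(ordering) && v <= length(ordering) && !is.null(ordering[[v]])) {
      key <- match(ch, ordering[[v]])
      key[is.na(key)] <- net$n + seq_len(sum(is.na(key)))
      order(key)
    } else seq_along(ch)
  }

  emit <- function(v, via_parent, len) {
    out <- ""
    is_ret <- v %in% ret
    show_subtree <- TRUE
    if (is_ret) {
      if (!seen[v]) {
        seen[v] <<- TRUE
        tag_count <<- tag_count + 1L
        tag_of[v] <<- sprintf("H%d", tag_count)
      } else show_subtree <- FALSE
    }
    if (show_subtree && length(net$children[[v]]) > 0L) {
      idx <- order_children(v)
      parts <- vapply(idx, function(j) {
        w <- net$children[[v]][j]
        emit(w, v, if (with_lengths) net$child_length[[v]][j] else NA_real_)
      }, character(1))
      out <- paste0("(", paste(parts, collapse = ","), ")")
    }
    if (show_subtree && !is.na(net$label[v])) out <- paste0(out, quote_label(net$label[v]))
    if (is_ret) {
      out <- paste0(out, "#", tag_of[v])
      if (!is.na(acc_parent[v]) && !is.na(via_parent) && acc_parent[v] == via_parent) {
        out <- paste0(out, "[&acceptor]")
      }
    }
    if (!is.na(len)) out <- paste0(out, ":", format(len, digits = 10))
    out
  }
  paste0(emit(net$root, NA_integer_, NA_real_), ";")
}

#' Taxa shared by two phylogenies
#'
#' Taxa are matched by exact label equality; the result is returned in
#' lexicographic order.
#'
#' @param n1,n2 `phylo_network` objects.
#' @return character vector of shared taxon labels (sorted).
#' @export
shared_taxa <- function(n1, n2) {
  x <- sort(intersect(network_taxa(n1), network_taxa(n2)), method = "radix")
  if (length(x) == 0L) {
    stop("the two phylogenies share no taxa; no tanglegram is possible")
  }
  x
}
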