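## Front end: file-to-file tanglegram computation ------------------------

report_lines <- function(res) {
  m <- res$metrics
  lo1 <- leaf_order_labels(res$backbone1, res$ordering1)
  lo2 <- leaf_order_labels(res$backbone2, res$ordering2)
  c(
    sprintf("n_shared: %d", m$n_shared),
    sprintf("td: %g", m$td),
    sprintf("crossings: %d", m$crossings),
    sprintf("rd1: %g", m$rd1),
    sprintf("rd2: %g", m$rd2),
    sprintf("score: %g", m$score),
    sprintf("leaf_order1: %s", paste(lo1, collapse = ",")),
    sprintf("leaf_order2: %s", paste(lo2, collapse = ","))
  )
}

leaf_order_labels <- function(bb, ord) {
  seq <- bb_layout(bb, ord)$leaf_seq
  lab <- bb$label[seq]
  lab[!is.na(lab)]
}

#' Compute a displacement-optimized tanglegram from two phylogeny files
#'
#' Reads two Newick/eNewick files, runs one- or two-sided displacement
#' optimization, and optionally writes ordered Newick output, a JSON
#' metrics report, and an SVG drawing.
#'
#' @param file1,file2 paths to Newick/eNewick files (side 1 and side 2).
#' @param mode `"two-sided"` (both sides reordered) or `"one-sided"`
#'   (side 1's child order is kept exactly as in the input file).
#' @param alpha,beta,gamma score weights in `{0, 1}`; `gamma` is ignored in
#'   one-sided mode.
#' @param presort apply the NN-presorting heuristic?
#' @param jobs,seed,max_rounds search settings, see [sa_config()].
#' @param sa optional full [sa_config()] overriding the previous three.
#' @param out1,out2 optional paths for the ordered Newick/eNewick outputs.
#' @param report optional path for the JSON metrics report.
#' @param svg optional path for an SVG tanglegram drawing.
#' @param quiet suppress the key/value metrics block on the console?
#' @return a `tanglegram_result`, invisibly.
#' @export
run_tanglegram <- function(file1, file2, mode = c("two-sided", "one-sided"),
                           alpha = 1, beta = 1, gamma = 1, presort = TRUE,
                           jobs = 32L, seed = 42L, max_rounds = 10L,
                           sa = NULL, out1 = NULL, out2 = NULL,
                           report = NULL, svg = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  n1 <- read_phylogeny(file1)
  n2 <- read_phylogeny(file2)
  shared_taxa(n1, n2)  # errors early if no overlap
  if (is.null(sa)) {
    sa <- sa_config(jobs = jobs, seed = seed, max_rounds = max_rounds)
  }
  cfg <- score_config(alpha, beta, if (mode == "one-sided") 0 else gamma)

  if (mode == "one-sided") {
    b1 <- backbone_tree(n1)
    b2 <- backbone_tree(n2)
    shared <- shared_taxa(n1, n2)
    o1 <- initial_ordering(b1)
    o2 <- if (presort) {
      nn_presort_pair(n1, b1, n2, b2)$o2
    } else {
      initial_ordering(b2)
    }
    o2 <- with_seed(sa$seed, one_sided_optimize(
      list(net = n2, bb = b2), ranking_of(b1, o1, shared),
      score_config(alpha = alpha, beta = beta, gamma = 0), sa, initial = o2
    ))
    res <- structure(
      list(
        ordering1 = o1, ordering2 = o2,
        layout1 = assign_coordinates(b1, o1),
        layout2 = assign_coordinates(b2, o2),
        backbone1 = b1, backbone2 = b2, net1 = n1, net2 = n2,
        metrics = tanglegram_metrics(n1, b1, o1, n2, b2, o2,
                                     score_config(alpha, beta, 1)),
        round_scores = NULL, shared = shared
      ),
      class = "tanglegram_result"
    )
  } else {
    res <- optimize_with_restarts(n1, n2, cfg, sa, presort = presort)
  }

  if (!is.null(out1)) {
    writeLines(write_phylogeny(n1, res$ordering1), out1)
  }
  if (!is.null(out2)) {
    writeLines(write_phylogeny(n2, res$ordering2), out2)
  }
  if (!is.null(report)) {
    m <- res$metrics
    jsonlite::write_json(
      list(
        mode = mode, td = m$td, crossings = m$crossings, rd1 = m$rd1,
        rd2 = m$rd2, score = m$score, n_shared = m$n_shared,
        leaf_order1 = leaf_order_labels(res$backbone1, res$ordering1),
        leaf_order2 = leaf_order_labels(res$backbone2, res$ordering2)
      ),
      report, auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(svg)) write_tanglegram_svg(res, svg)
  if (!quiet) writeLines(report_lines(res))
  invisible(res)
}

## SVG rendering ---------------------------------------------------------

svg_side <- function(net, bb, ord, lay, xmap, ymap, label_anchor, lab_x) {
  out <- character(0)
  seg <- function(x1, y1, x2, y2, cls) {
    sprintf(
      '<path d="M %.1f %.1f L %.1f %.1f" class="%s"/>',
      x1, y1, x2, y2, cls
    )
  }
  for (p in seq_len(bb$n)) {
    for (w in ord[[p]]) {
      out <- c(out, seg(xmap(lay$x[p]), ymap(lay$y[p]),
                        xmap(lay$x[w]), ymap(lay$y[w]), "tree"))
    }
  }
  R <- reticulate_edges(net)
  for (e in seq_len(nrow(R))) {
    out <- c(out, seg(xmap(lay$x[R[e, 1L]]), ymap(lay$y[R[e, 1L]]),
                      xmap(lay$x[R[e, 2L]]), ymap(lay$y[R[e, 2L]]), "ret"))
  }
  for (v in lay$leaf_seq) {
    if (!is.na(bb$label[v])) {
      out <- c(out, sprintf(
        '<text x="%.1f" y="%.1f" text-anchor="%s" class="lab">%s</text>',
        lab_x, ymap(lay$y[v]) + 3, label_anchor, bb$label[v]
      ))
    }
  }
  out
}

#' Write a minimal SVG drawing of a tanglegram
#'
#' Side 1 is drawn left-to-right, side 2 right-to-left, with straight
#' lines connecting leaves labeled by shared taxa.
#'
#' @param res a `tanglegram_result`.
#' @param path output file path.
#' @param width,row_height drawing dimensions in pixels.
#' @return `path`, invisibly.
#' @export
write_tanglegram_svg <- function(res, path, width = 1000, row_height = 14) {
  l1 <- res$layout1
  l2 <- res$layout2
  nrow_max <- max(length(l1$leaf_seq), length(l2$leaf_seq))
  height <- row_height * (nrow_max + 2)
  panel <- width * 0.32
  gap <- width - 2 * panel
  sc1 <- (panel - 100) / max(1, max(l1$x))
  sc2 <- (panel - 100) / max(1, max(l2$x))
  y1 <- function(y) row_height * y
  y2 <- function(y) row_height * y
  x1 <- function(x) 10 + x * sc1
  x2 <- function(x) width - 10 - x * sc2
  body <- c(
    svg_side(res$net1, res$backbone1, res$ordering1, l1, x1, y1,
             "start", panel - 80 + 10),
    svg_side(res$net2, res$backbone2, res$ordering2, l2, x2, y2,
             "end", width - panel + 80 - 10)
  )
  ## intertaxon lines
  lab1 <- res$backbone1$label[l1$leaf_seq]
  lab2 <- res$backbone2$label[l2$leaf_seq]
  for (t in res$shared) {
    i <- which(!is.na(lab1) & lab1 == t)
    j <- which(!is.na(lab2) & lab2 == t)
    body <- c(body, sprintf(
      '<path d="M %.1f %.1f L %.1f %.1f" class="inter"/>',
      panel - 60 + 10, y1(i), width - panel + 60 - 10, y2(j)
    ))
  }
  doc <- c(
    sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
      width, height, width, height
    ),
    "<style>",
    ".tree { stroke: #333; fill: none; stroke-width: 1.2; }",
    ".ret { stroke: #2166ac; fill: none; stroke-width: 1; stroke-dasharray: 4 2; }",
    ".inter { stroke: #b2182b; fill: none; stroke-width: 0.8; opacity: 0.7; }",
    ".lab { font: 10px sans-serif; fill: #000; }",
    "</style>",
    body,
    "</svg>"
  )
  writeLines(doc, path)
  invisible(path)
}

## Command-line entry point (used by inst/cli/dotangle.R) ----------------

cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE)) {
    stop("the command-line interface requires the 'optparse' package")
  }
  if (length(args) >= 1L && args[[1L]] == "synth") {
    return(cli_synth(args[-1L]))
  }
  if (length(args) >= 1L && args[[1L]] == "tangle") args <- args[-1L]
  op <- optparse::OptionParser(
    usage = "dotangle.R [tangle] [options] tree1.nwk tree2.nwk",
    option_list = list(
      optparse::make_option("--mode", default = "two-sided",
                            help = "one-sided or two-sided [%default]"),
      optparse::make_option("--alpha", type = "integer", default = 1L),
      optparse::make_option("--beta", type = "integer", default = 1L),
      optparse::make_option("--gamma", type = "integer", default = 1L),
      optparse::make_option("--no-presort", action = "store_true",
                            dest = "no_presort", default = FALSE),
      optparse::make_option("--jobs", type = "integer", default = 32L),
      optparse::make_option("--seed", type = "integer", default = 42L),
      optparse::make_option("--max-rounds", type = "integer", default = 10L,
                            dest = "max_rounds"),
      optparse::make_option("--out1", default = NULL),
      optparse::make_option("--out2", default = NULL),
      optparse::make_option("--report", default = NULL),
      optparse::make_option("--svg", default = NULL)
    )
  )
  parsed <- optparse::parse_args2(op, args)
  if (length(parsed$args) != 2L) {
    stop("expected exactly two input files")
  }
  run_tanglegram(
    parsed$args[[1L]], parsed$args[[2L]],
    mode = parsed$options$mode,
    alpha = parsed$options$alpha, beta = parsed$options$beta,
    gamma = parsed$options$gamma,
    presort = !parsed$options$no_presort,
    jobs = parsed$options$jobs, seed = parsed$options$seed,
    max_rounds = parsed$options$max_rounds,
    out1 = parsed$options$out1, out2 = parsed$options$out2,
    report = parsed$options$report, svg = parsed$options$svg
  )
  invisible(0L)
}

cli_synth <- function(args) {
  op <- optparse::OptionParser(
    usage = "dotangle.R synth [options]",
    option_list = list(
      optparse::make_option("--n", type = "integer", default = 50L),
      optparse::make_option("--r", type = "double", default = 0),
      optparse::make_option("--m", type = "double", default = 0),
      optparse::make_option("--c", type = "double", default = 0),
      optparse::make_option("--k", type = "integer", default = 0L),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--background-size", type = "integer",
                            default = 500L, dest = "background_size"),
      optparse::make_option("--out-prefix", default = "pair",
                            dest = "out_prefix")
    )
  )
  o <- optparse::parse_args2(op, args)$options
  cfg <- synthetic_config(n = o$n, r = o$r, m = o$m, c = o$c, k = o$k,
                          background_size = o$background_size, seed = o$seed)
  pair <- generate_pair(cfg)
  f1 <- paste0(o$out_prefix, ".side1.", if (cfg$k > 0) "enwk" else "nwk")
  f2 <- paste0(o$out_prefix, ".side2.", if (cfg$k > 0) "enwk" else "nwk")
  writeLines(write_phylogeny(pair$n1), f1)
  writeLines(write_phylogeny(pair$n2), f2)
  jsonlite::write_json(
    c(unclass(cfg), list(side1 = f1, side2 = f2)),
    paste0(o$out_prefix, ".json"), auto_unbox = TRUE
  )
  invisible(0L)
}
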