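#' Compressed RNA graph
#'
#' Runs of consecutive unpaired nucleotides lying between two retained nodes
#' of the same chain are replaced by one weighted super-edge whose labels are
#' the collapsed residues in chain order; the weight is the run length.
#' Chain-terminal unpaired runs (dangling ends) have no retained flank on one
#' side and are deliberately left uncompressed, so motif patterns can never
#' reach into them. All indices refer to the source graph's ordinal node
#' numbering, which makes decompression exact.
#'
#' @name rna_cgraph
NULL

new_rna_cgraph <- function(all_nodes, retained, edges, super) {
  structure(list(all_nodes = all_nodes, retained = as.integer(retained),
                 nodes = all_nodes[retained, , drop = FALSE],
                 edges = edges, super = super),
            class = "rna_cgraph")
}

#' @export
print.rna_cgraph <- function(x, ...) {
  cat(sprintf("compressed rna_graph: %d/%d nodes retained, %d plain edges, %d super-edges\n",
              length(x$retained), nrow(x$all_nodes), nrow(x$edges),
              length(x$super)))
  invisible(x)
}

#' Compress runs of unpaired nucleotides into super-edges
#'
#' @param g an `rna_graph` in the without-non-WC view (non-WC edges present
#'   would silently change pairing context, so they are rejected)
#' @return an `rna_cgraph`
#' @export
compress_graph <- function(g) {
  if (any(g$edges$nonwc == 1L)) {
    stop("compress_graph expects the without-non-WC view")
  }
  p <- wc_partner(g)
  n <- nrow(g$nodes)
  paired <- !is.na(p)
  chain <- g$nodes$chain
  collapsed <- rep(FALSE, n)
  super <- list()
  i <- 1L
  while (i <= n) {
    if (!paired[[i]]) {
      j <- i
      while (j < n && !paired[[j + 1L]] && chain[[j + 1L]] == chain[[i]]) {
        j <- j + 1L
      }
      left_ok <- i > 1L && chain[[i - 1L]] == chain[[i]] && paired[[i - 1L]]
      right_ok <- j < n && chain[[j + 1L]] == chain[[i]] && paired[[j + 1L]]
      if (left_ok && right_ok) {
        collapsed[i:j] <- TRUE
        super[[length(super) + 1L]] <-
          list(a = i - 1L, b = j + 1L, labels = i:j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  retained <- which(!collapsed)
  edges <- g$edges[!(g$edges$a %in% which(collapsed)) &
                     !(g$edges$b %in% which(collapsed)), , drop = FALSE]
  rownames(edges) <- NULL
  new_rna_cgraph(g$nodes, retained, edges, super)
}

#' Restore the original graph from its compression
#'
#' Total inverse: `decompress_graph(compress_graph(g))` is node- and
#' edge-identical to `g` for every without-non-WC graph `g`.
#'
#' @param c an `rna_cgraph`
#' @return an `rna_graph`
#' @export
decompress_graph <- function(c) {
  edges <- c$edges
  for (se in c$super) {
    run <- c(se$a, se$labels, se$b)
    edges <- rbind(edges,
                   data.frame(a = run[-length(run)], b = run[-1L],
                              cov = 1L, wc = 0L, nonwc = 0L))
  }
  rna_graph(c$all_nodes, edges)
}
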