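#' Attributed nucleotide-level RNA graph
#'
#' Nodes are residues (ordinal index along concatenated chains, chain file
#' order, no covalent edge across chain breaks); edges carry a 3-component
#' indicator attribute over (covalent, Watson-Crick, non-Watson-Crick). A pair
#' of residues with several interaction types yields one multi-hot edge.
#'
#' @param nodes data.frame with columns `key`, `chain`, `resno`, `icode`,
#'   `base` (row order = ordinal order)
#' @param edges data.frame with columns `a`, `b` (node indices, `a < b`) and
#'   indicator columns `cov`, `wc`, `nonwc`
#' @return an `rna_graph`
#' @export
rna_graph <- function(nodes, edges) {
  if (anyDuplicated(nodes$key)) {
    stop("duplicate residue keys in graph nodes")
  }
  edges <- canonical_edges(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(edges$a >= 1), all(edges$b <= nrow(nodes)),
              all(edges$a != edges$b),
              all(edges$cov + edges$wc + edges$nonwc > 0))
  }
  wc_deg <- tabulate(c(edges$a[edges$wc == 1L], edges$b[edges$wc == 1L]),
                     nbins = nrow(nodes))
  structure(list(nodes = nodes, edges = edges,
                 wc_matching = all(wc_deg <= 1L)),
            class = "rna_graph")
}

canonical_edges <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L) {
    return(data.frame(a = integer(), b = integer(), cov = integer(),
                      wc = integer(), nonwc = integer()))
  }
  swap <- edges$a > edges$b
  tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]; edges$b[swap] <- tmp
  id <- paste(edges$a, edges$b)
  if (anyDuplicated(id)) {
    u <- !duplicated(id)
    for (cl in c("cov", "wc", "nonwc")) {
      edges[[cl]] <- as.integer(edges[[cl]] > 0)
      mx <- tapply(edges[[cl]], id, max)
      edges[[cl]][u] <- as.integer(mx[match(id[u], names(mx))])
    }
    edges <- edges[u, , drop = FALSE]
  }
  edges <- edges[order(edges$a, edges$b), c("a", "b", "cov", "wc", "nonwc")]
  rownames(edges) <- NULL
  for (cl in c("a", "b", "cov", "wc", "nonwc")) {
    edges[[cl]] <- as.integer(edges[[cl]])
  }
  edges
}

#' @export
print.rna_graph <- function(x, ...) {
  e <- x$edges
  cat(sprintf("rna_graph: %d nodes, %d edges (cov %d, WC %d, non-WC %d)\n",
              nrow(x$nodes), nrow(e), sum(e$cov), sum(e$wc), sum(e$nonwc)))
  invisible(x)
}

#' Build the graph of a structure from its interactions
#'
#' One node per residue (file order); the edge attribute is the indicator
#' union over the pair's interaction types.
#'
#' @param s an `rna_structure`
#' @param ia an `interaction_set` whose keys all resolve in `s`
#' @return an `rna_graph`
#' @export
build_graph <- function(s, ia) {
  nodes <- s$residues[, c("key", "chain", "resno", "icode", "base")]
  rownames(nodes) <- NULL
  df <- ia$interactions
  miss <- setdiff(c(df$key_a, df$key_b), nodes$key)
  if (length(miss) > 0L) {
    stop("interaction references unknown residue key(s): ",
         paste(miss, collapse = ", "))
  }
  edges <- data.frame(a = match(df$key_a, nodes$key),
                      b = match(df$key_b, nodes$key),
                      cov = df$cov, wc = df$wc, nonwc = df$nonwc)
  rna_graph(nodes, edges)
}

#' Drop non-Watson-Crick components
#'
#' Zeroes the non-WC indicator on every edge and removes edges whose
#' attribute becomes all-zero; the node set is unchanged. Idempotent. Motif
#' search always operates on this view.
#'
#' @param g an `rna_graph`
#' @return an `rna_graph`
#' @export
without_nonwc <- function(g) {
  e <- g$edges
  e$nonwc <- 0L
  e <- e[e$cov + e$wc > 0L, , drop = FALSE]
  rna_graph(g$nodes, e)
}

wc_partner <- function(g) {
  # partner index per node under the WC matching; NA when unpaired
  e <- g$edges[g$edges$wc == 1L, , drop = FALSE]
  p <- rep(NA_integer_, nrow(g$nodes))
  if (nrow(e) > 0L) {
    if (!g$wc_matching) stop("WC edges do not form a matching")
    p[e$a] <- e$b
    p[e$b] <- e$a
  }
  p
}

PAGE_OPEN <- c("(", "[", "{", "<")
PAGE_CLOSE <- c(")", "]", "}", ">")

#' Convert a graph to (extended) dot-bracket text
#'
#' Operates on the without-non-WC view; WC pairs must form a matching. Pairs
#' are assigned to bracket pages by first-fit interval coloring in order of
#' left endpoint: `()`, then `[]`, `{}`, `<>` for successive crossing
#' families. More than 4 pages raises a capacity error naming the pair.
#'
#' @param g an `rna_graph`
#' @return single character string, one symbol per node in ordinal order
#' @export
to_dot_bracket <- function(g) {
  g <- without_nonwc(g)
  p <- wc_partner(g)
  n <- length(p)
  out <- rep(".", n)
  left <- which(!is.na(p) & p > seq_len(n))
  left <- left[order(left)]
  pages <- vector("list", length(PAGE_OPEN))
  for (i in left) {
    j <- p[[i]]
    placed <- FALSE
    for (pg in seq_along(pages)) {
      ok <- TRUE
      for (pr in pages[[pg]]) {
        k <- pr[[1L]]; l <- pr[[2L]]
        if ((k < i && i < l && l < j) || (i < k && k < j && j < l)) {
          ok <- FALSE; break
        }
      }
      if (ok) {
        pages[[pg]] <- c(pages[[pg]], list(c(i, j)))
        out[[i]] <- PAGE_OPEN[[pg]]; out[[j]] <- PAGE_CLOSE[[pg]]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("dot-bracket page capacity exceeded (>4 crossing families) at pair (",
           i, ",", j, ")")
    }
  }
  paste(out, collapse = "")
}

#' Parse (extended) dot-bracket text into a WC-only graph
#'
#' Inverse of [to_dot_bracket()] on WC-only graphs; a covalent backbone is
#' added along the string (single chain `A`, residues numbered from 1).
#'
#' @param t dot-bracket string over `. ( ) [ ] { } < >`
#' @param seq optional nucleotide sequence (same length) for node bases
#' @return an `rna_graph`
#' @export
from_dot_bracket <- function(t, seq = NULL) {
  ch <- strsplit(t, "")[[1L]]
  n <- length(ch)
  bad <- which(!ch %in% c(".", PAGE_OPEN, PAGE_CLOSE))
  if (length(bad) > 0L) {
    stop("invalid dot-bracket character '", ch[[bad[[1L]]]],
         "' at position ", bad[[1L]])
  }
  stacks <- rep(list(integer()), length(PAGE_OPEN))
  pairs <- NULL
  for (i in seq_len(n)) {
    pg <- match(ch[[i]], PAGE_OPEN)
    if (!is.na(pg)) {
      stacks[[pg]] <- c(stacks[[pg]], i)
    } else {
      pg <- match(ch[[i]], PAGE_CLOSE)
      if (!is.na(pg)) {
        if (length(stacks[[pg]]) == 0L) {
          stop("unbalanced '", ch[[i]], "' at position ", i)
        }
        j <- stacks[[pg]][[length(stacks[[pg]])]]
        stacks[[pg]] <- stacks[[pg]][-length(stacks[[pg]])]
        pairs <- rbind(pairs, c(j, i))
      }
    }
  }
  for (pg in seq_along(stacks)) {
    if (length(stacks[[pg]]) > 0L) {
      stop("unbalanced '", PAGE_OPEN[[pg]], "' at position ",
           stacks[[pg]][[1L]])
    }
  }
  base <- if (is.null(seq)) rep("OTHER", n) else {
    s <- toupper(strsplit(seq, "")[[1L]])
    stopifnot(length(s) == n)
    ifelse(s %in% RNA_BASES, s, "OTHER")
  }
  nodes <- data.frame(key = res_key("A", seq_len(n)), chain = "A",
                      resno = seq_len(n), icode = "", base = base,
                      stringsAsFactors = FALSE)
  edges <- data.frame(a = integer(), b = integer(), cov = integer(),
                      wc = integer(), nonwc = integer())
  if (n > 1L) {
    edges <- data.frame(a = seq_len(n - 1L), b = seq_len(n - 1L) + 1L,
                        cov = 1L, wc = 0L, nonwc = 0L)
  }
  if (!is.null(pairs)) {
    edges <- rbind(edges, data.frame(a = pairs[, 1L], b = pairs[, 2L],
                                     cov = 0L, wc = 1L, nonwc = 0L))
  }
  rna_graph(nodes, edges)
}

#' Exact label-preserving graph equality
#'
#' Node keys, order and attributed edge sets must match exactly (not mere
#' isomorphism); the equality used by compression round-trip checks.
#'
#' @param g1,g2 `rna_graph` objects
#' @return logical
#' @export
graph_equal <- function(g1, g2) {
  identical(g1$nodes$key, g2$nodes$key) &&
    identical(g1$nodes$base, g2$nodes$base) &&
    identical(canonical_edges(g1$edges), canonical_edges(g2$edges))
}

induced_subgraph_keys <- function(g, keys) {
  idx <- match(keys, g$nodes$key)
  stopifnot(!anyNA(idx))
  idx <- sort(idx)
  e <- g$edges[g$edges$a %in% idx & g$edges$b %in% idx, , drop = FALSE]
  nodes <- g$nodes[idx, , drop = FALSE]
  rownames(nodes) <- NULL
  e$a <- match(e$a, idx); e$b <- match(e$b, idx)
  rna_graph(nodes, e)
}

#' Serialize a graph to JSON
#'
#' Documented payload shape shared with the custom-search interface: `nodes`
#' (key, chain, resno, icode, base), `edges` (a, b, cov, wc, nonwc) and, for
#' compressed graphs, `super_edges` (a, b, labels, weight).
#'
#' @param g an `rna_graph` or compressed graph
#' @return JSON string
#' @export
graph_to_json <- function(g) {
  if (inherits(g, "rna_cgraph")) {
    payload <- list(
      compressed = TRUE,
      retained = g$retained, edges = g$edges,
      super_edges = lapply(g$super, function(se) {
        list(a = se$a, b = se$b, labels = se$labels, weight = length(se$labels))
      }),
      all_nodes = g$all_nodes
    )
  } else {
    payload <- list(compressed = FALSE, nodes = g$nodes, edges = g$edges)
  }
  jsonlite::toJSON(payload, dataframe = "columns", auto_unbox = TRUE,
                   digits = NA)
}

#' @rdname graph_to_json
#' @param json JSON string produced by [graph_to_json()]
#' @export
graph_from_json <- function(json) {
  p <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  as_node_df <- function(x) {
    data.frame(key = as.character(x$key), chain = as.character(x$chain),
               resno = as.integer(x$resno), icode = as.character(x$icode),
               base = as.character(x$base), stringsAsFactors = FALSE)
  }
  as_edge_df <- function(x) {
    if (length(x) == 0L || length(x$a) == 0L) {
      return(data.frame(a = integer(), b = integer(), cov = integer(),
                        wc = integer(), nonwc = integer()))
    }
    data.frame(a = as.integer(x$a), b = as.integer(x$b),
               cov = as.integer(x$cov), wc = as.integer(x$wc),
               nonwc = as.integer(x$nonwc))
  }
  if (isTRUE(p$compressed)) {
    super <- p$super_edges
    if (is.data.frame(super)) {
      super <- lapply(seq_len(nrow(super)), function(i) {
        list(a = super$a[[i]], b = super$b[[i]],
             labels = as.integer(unlist(super$labels[i])))
      })
    } else {
      super <- lapply(super, function(se) {
        list(a = as.integer(se$a), b = as.integer(se$b),
             labels = as.integer(se$labels))
      })
    }
    new_rna_cgraph(all_nodes = as_node_df(p$all_nodes),
                   retained = as.integer(p$retained),
                   edges = as_edge_df(p$edges), super = super)
  } else {
    rna_graph(as_node_df(p$nodes), as_edge_df(p$edges))
  }
}
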