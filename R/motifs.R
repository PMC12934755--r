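#' Compressed motif search patterns
#'
#' Each pattern is a small cycle of template nodes alternating closing
#' Watson-Crick pairs and loop strands. A strand with range `[lo, hi]`
#' matches a super-edge of weight `w` iff `lo <= w <= hi`; a strand with
#' `lo = 0` additionally matches a plain covalent backbone edge between the
#' two retained nodes (an empty strand, as in coaxially stacked junctions).
#' Compression makes per-size enumeration unnecessary: one ranged pattern per
#' motif class (plus one per junction way count) covers all loop sizes.
#'
#' Defaults: hairpin loop 1-20 unpaired nucleotides (larger loops are
#' thermodynamically unstable and excluded by construction), internal-loop
#' and bulge strands up to 20, junctions 3- to 8-way with per-strand range
#' 0-20.
#'
#' @param hairpin_range integer `c(lo, hi)`, `1 <= lo <= hi <= 20` by default
#' @param junction_ways integer `c(lo, hi)` within `[3, 8]`
#' @param strand_max maximal unpaired run per internal/bulge/junction strand
#' @return list of `motif_pattern` objects (3 + number of junction way
#'   values with the defaults)
#' @export
make_patterns <- function(hairpin_range = c(1L, 20L),
                          junction_ways = c(3L, 8L),
                          strand_max = 20L) {
  hairpin_range <- as.integer(hairpin_range)
  junction_ways <- as.integer(junction_ways)
  if (length(hairpin_range) != 2L || hairpin_range[[1L]] < 1L ||
      hairpin_range[[1L]] > hairpin_range[[2L]]) {
    stop("invalid hairpin range")
  }
  if (length(junction_ways) != 2L || junction_ways[[1L]] < 3L ||
      junction_ways[[2L]] > 8L || junction_ways[[1L]] > junction_ways[[2L]]) {
    stop("invalid junction ways range")
  }
  if (strand_max < 1L) stop("invalid strand_max")
  pats <- list(
    motif_pattern("HAIRPIN", ways = 1L,
                  strands = list(c(hairpin_range[[1L]], hairpin_range[[2L]]))),
    motif_pattern("INTERNAL", ways = 2L,
                  strands = list(c(1L, strand_max), c(1L, strand_max))),
    motif_pattern("BULGE", ways = 2L,
                  strands = list(c(1L, strand_max), c(0L, 0L)))
  )
  for (w in junction_ways[[1L]]:junction_ways[[2L]]) {
    pats[[length(pats) + 1L]] <-
      motif_pattern("JUNCTION", ways = w,
                    strands = rep(list(c(0L, strand_max)), w))
  }
  pats
}

#' @rdname make_patterns
#' @param motif_class one of `"HAIRPIN"`, `"INTERNAL"`, `"BULGE"`,
#'   `"JUNCTION"`
#' @param ways number of closing pairs (1 hairpin, 2 internal/bulge, 3-8
#'   junction)
#' @param strands list of `c(lo, hi)` ranges, one per loop strand
#' @export
motif_pattern <- function(motif_class, ways, strands) {
  stopifnot(length(strands) == ways)
  # cycle template: WC pairs (1,2),(3,4),... and strand t from node 2t to
  # node (2t+1) mod 2*ways; for hairpins the single strand closes (2,1).
  wc_edges <- lapply(seq_len(ways), function(t) c(2L * t - 1L, 2L * t))
  strand_edges <- lapply(seq_len(ways), function(t) {
    to <- if (t == ways) 1L else 2L * t + 1L
    c(2L * t, to, strands[[t]])
  })
  structure(list(motif_class = motif_class, ways = as.integer(ways),
                 n_nodes = 2L * ways, wc_edges = wc_edges,
                 strand_edges = strand_edges, strands = strands),
            class = "motif_pattern")
}

cgraph_adjacency <- function(cg) {
  n <- nrow(cg$all_nodes)
  wc <- rep(list(integer()), n)
  cov <- rep(list(integer()), n)
  sup <- rep(list(list()), n)
  e <- cg$edges
  for (i in seq_len(nrow(e))) {
    a <- e$a[[i]]; b <- e$b[[i]]
    if (e$wc[[i]] == 1L) {
      wc[[a]] <- c(wc[[a]], b); wc[[b]] <- c(wc[[b]], a)
    }
    if (e$cov[[i]] == 1L) {
      cov[[a]] <- c(cov[[a]], b); cov[[b]] <- c(cov[[b]], a)
    }
  }
  for (k in seq_along(cg$super)) {
    se <- cg$super[[k]]
    sup[[se$a]] <- c(sup[[se$a]], list(list(to = se$b, id = k)))
    sup[[se$b]] <- c(sup[[se$b]], list(list(to = se$a, id = k)))
  }
  list(wc = wc, cov = cov, sup = sup,
       weight = vapply(cg$super, function(se) length(se$labels), 1L))
}

# strand candidates from a mapped node: list of (to, super_id or 0)
strand_candidates <- function(adj, from, lo, hi) {
  out <- list()
  for (s in adj$sup[[from]]) {
    w <- adj$weight[[s$id]]
    if (w >= lo && w <= hi) out <- c(out, list(list(to = s$to, id = s$id)))
  }
  if (lo == 0L) {
    for (to in adj$cov[[from]]) {
      out <- c(out, list(list(to = to, id = 0L)))
    }
  }
  out
}

#' Match one motif pattern against a compressed graph
#'
#' Enumerates every attribute-constrained embedding of the pattern template,
#' decompresses each into its full member set (closing-pair nodes plus the
#' collapsed loop residues) and removes automorphic duplicates by unique
#' (class, member-set).
#'
#' @param p a `motif_pattern`
#' @param cg an `rna_cgraph` built from a without-non-WC view
#' @return list of `motif_match` objects with fields `motif_class`, `ways`,
#'   `size` (number of unpaired nucleotides), `members` (ordered residue
#'   keys), `member_idx` (ordinal node indices), `closing_idx`
#' @export
match_pattern <- function(p, cg) {
  adj <- cgraph_adjacency(cg)
  nmap <- rep(NA_integer_, p$n_nodes)
  used <- logical(nrow(cg$all_nodes))
  strand_by_from <- list()
  for (se in p$strand_edges) strand_by_from[[as.character(se[[1L]])]] <- se
  results <- list()
  seen <- character()

  emit <- function(nmap, super_ids) {
    loop_idx <- integer()
    for (id in super_ids) if (id > 0L) {
      loop_idx <- c(loop_idx, cg$super[[id]]$labels)
    }
    members_idx <- sort(c(nmap, loop_idx))
    key <- paste(p$motif_class, paste(members_idx, collapse = ","))
    if (key %in% seen) return()
    seen <<- c(seen, key)
    results[[length(results) + 1L]] <<- structure(
      list(motif_class = p$motif_class, ways = p$ways,
           size = length(loop_idx),
           members = cg$all_nodes$key[members_idx],
           member_idx = members_idx,
           closing_idx = sort(nmap)),
      class = "motif_match")
  }

  # pattern nodes are visited in cycle order 1..2w; node 2t+1 is reached from
  # node 2t through a strand edge, node 2t from 2t-1 through its WC pair.
  extend <- function(k, super_ids) {
    if (k > p$n_nodes) {
      se <- p$strand_edges[[p$ways]]
      cands <- strand_candidates(adj, nmap[[p$n_nodes]], se[[3L]], se[[4L]])
      for (cand in cands) {
        if (cand$to == nmap[[1L]]) emit(nmap, c(super_ids, cand$id))
      }
      return()
    }
    if (k %% 2L == 0L) {
      for (to in adj$wc[[nmap[[k - 1L]]]]) {
        if (!used[[to]]) {
          nmap[[k]] <<- to; used[[to]] <<- TRUE
          extend(k + 1L, super_ids)
          used[[to]] <<- FALSE; nmap[[k]] <<- NA_integer_
        }
      }
    } else {
      se <- p$strand_edges[[(k - 1L) %/% 2L]]
      cands <- strand_candidates(adj, nmap[[k - 1L]], se[[3L]], se[[4L]])
      for (cand in cands) {
        if (!used[[cand$to]]) {
          nmap[[k]] <<- cand$to; used[[cand$to]] <<- TRUE
          extend(k + 1L, c(super_ids, cand$id))
          used[[cand$to]] <<- FALSE; nmap[[k]] <<- NA_integer_
        }
      }
    }
  }

  if (p$motif_class == "HAIRPIN") {
    # single pair closed by its own strand
    lo <- p$strands[[1L]][[1L]]; hi <- p$strands[[1L]][[2L]]
    for (i in seq_len(nrow(cg$all_nodes))) {
      for (j in adj$wc[[i]]) {
        if (j <= i) next
        for (cand in strand_candidates(adj, i, lo, hi)) {
          if (cand$to == j) {
            nmap <- c(i, j)
            emit(nmap, cand$id)
          }
        }
      }
    }
  } else {
    for (i in seq_len(nrow(cg$all_nodes))) {
      if (length(adj$wc[[i]]) == 0L) next
      nmap[[1L]] <- i; used[[i]] <- TRUE
      extend(2L, integer())
      used[[i]] <- FALSE; nmap[[1L]] <- NA_integer_
    }
  }
  results
}

#' Extract all motif occurrences from a graph
#'
#' Full pipeline: drop non-WC edges, compress unpaired runs, match every
#' pattern, decompress matches and enrich each with both graph views over its
#' members (with and without non-WC edges).
#'
#' @param g an `rna_graph` (non-WC edges allowed; they are excluded from the
#'   search but kept in the returned with-non-WC views)
#' @param patterns list from [make_patterns()]
#' @return list of `motif_match` objects, each additionally carrying
#'   `graph_with_nonwc` and `graph_without_nonwc` (induced member subgraphs)
#' @export
extract_motifs <- function(g, patterns = make_patterns()) {
  gw <- without_nonwc(g)
  cg <- compress_graph(gw)
  out <- list()
  for (p in patterns) {
    out <- c(out, match_pattern(p, cg))
  }
  for (i in seq_along(out)) {
    out[[i]]$graph_with_nonwc <- induced_subgraph_keys(g, out[[i]]$members)
    out[[i]]$graph_without_nonwc <- induced_subgraph_keys(gw, out[[i]]$members)
  }
  out
}

#' @export
print.motif_match <- function(x, ...) {
  cat(sprintf("%s motif (%d-way), size %d: %s\n", x$motif_class, x$ways,
              x$size, paste(x$members, collapse = " ")))
  invisible(x)
}

#' Search a user-defined query graph in a target graph
#'
#' Attribute-constrained subgraph monomorphism at full node resolution (no
#' compression): every query edge must map onto a target edge with an
#' identical (covalent, WC, non-WC) attribute vector, so non-WC edges are
#' respected. Results are deduplicated by member-set.
#'
#' @param query connected `rna_graph` with at most `max_query` nodes
#' @param target `rna_graph`
#' @param max_query capacity guard on query size
#' @return list of character vectors of target residue keys
#' @export
custom_search <- function(query, target, max_query = 30L) {
  nq <- nrow(query$nodes)
  if (nq == 0L) stop("empty query graph")
  if (nq > max_query) {
    stop("query too large: ", nq, " nodes (limit ", max_query, ")")
  }
  qadj <- rep(list(integer()), nq)
  for (i in seq_len(nrow(query$edges))) {
    a <- query$edges$a[[i]]; b <- query$edges$b[[i]]
    qadj[[a]] <- c(qadj[[a]], b); qadj[[b]] <- c(qadj[[b]], a)
  }
  # connectivity check + BFS visit order so each new node attaches to a
  # mapped one
  order <- integer(); seen <- logical(nq)
  queue <- 1L; seen[[1L]] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, v)
    for (w in qadj[[v]]) if (!seen[[w]]) { seen[[w]] <- TRUE; queue <- c(queue, w) }
  }
  if (length(order) < nq) stop("query graph must be connected")

  nt <- nrow(target$nodes)
  eattr <- function(g) paste(g$edges$a, g$edges$b)
  tkey <- eattr(target)
  tattr <- paste(target$edges$cov, target$edges$wc, target$edges$nonwc)
  names(tattr) <- tkey
  tadj <- rep(list(integer()), nt)
  for (i in seq_len(nrow(target$edges))) {
    a <- target$edges$a[[i]]; b <- target$edges$b[[i]]
    tadj[[a]] <- c(tadj[[a]], b); tadj[[b]] <- c(tadj[[b]], a)
  }
  qattr_of <- function(a, b) {
    e <- query$edges
    r <- which((e$a == a & e$b == b) | (e$a == b & e$b == a))
    paste(e$cov[r], e$wc[r], e$nonwc[r])
  }
  edge_ok <- function(ta, tb, attr) {
    k <- if (ta < tb) paste(ta, tb) else paste(tb, ta)
    !is.na(tattr[k]) && tattr[k] == attr
  }
  mapping <- rep(NA_integer_, nq)
  used <- logical(nt)
  seen_sets <- character()
  results <- list()
  bt <- function(pos) {
    if (pos > nq) {
      idx <- sort(mapping)
      key <- paste(idx, collapse = ",")
      if (!key %in% seen_sets) {
        seen_sets <<- c(seen_sets, key)
        results[[length(results) + 1L]] <<- target$nodes$key[idx]
      }
      return()
    }
    v <- order[[pos]]
    anchors <- qadj[[v]][!is.na(mapping[qadj[[v]]])]
    cands <- if (length(anchors) == 0L) seq_len(nt) else tadj[[mapping[[anchors[[1L]]]]]]
    for (t in cands) {
      if (used[[t]]) next
      ok <- TRUE
      for (u in qadj[[v]]) {
        if (!is.na(mapping[[u]]) &&
            !edge_ok(t, mapping[[u]], qattr_of(v, u))) { ok <- FALSE; break }
      }
      if (ok) {
        mapping[[v]] <<- t; used[[t]] <<- TRUE
        bt(pos + 1L)
        used[[t]] <<- FALSE; mapping[[v]] <<- NA_integer_
      }
    }
  }
  bt(1L)
  results
}
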