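# Independent brute-force motif enumerator working on the UNCOMPRESSED
# graph: explicit per-size patterns (the enumeration that compression makes
# unnecessary), implemented directly on WC-pair and backbone adjacency with
# no use of the package's compression or matcher machinery.

oracle_inventory <- function(g, hairpin_max = 20L, strand_max = 20L,
                             ways_range = c(3L, 8L)) {
  gw <- without_nonwc(g)
  n <- nrow(gw$nodes)
  e <- gw$edges
  partner <- rep(NA_integer_, n)
  wc <- e[e$wc == 1L, , drop = FALSE]
  partner[wc$a] <- wc$b
  partner[wc$b] <- wc$a
  cov <- e[e$cov == 1L, , drop = FALSE]
  nbr <- rep(list(integer()), n)
  for (r in seq_len(nrow(cov))) {
    nbr[[cov$a[r]]] <- c(nbr[[cov$a[r]]], cov$b[r])
    nbr[[cov$b[r]]] <- c(nbr[[cov$b[r]]], cov$a[r])
  }
  paired <- !is.na(partner)
  # strand walks: from a paired node, follow backbone through unpaired
  # nodes (in every direction) until the next paired node
  strand_walks <- function(from) {
    out <- list()
    for (first in nbr[[from]]) {
      run <- integer()
      prev <- from; cur <- first
      ok <- TRUE
      while (!paired[[cur]]) {
        run <- c(run, cur)
        nxt <- setdiff(nbr[[cur]], prev)
        if (length(nxt) != 1L) { ok <- FALSE; break }
        prev <- cur; cur <- nxt
      }
      if (ok) out <- c(out, list(list(to = cur, run = run)))
    }
    out
  }
  res <- list()
  seen <- character()
  emit <- function(class, ways, members, size) {
    members <- sort(members)
    key <- paste(class, paste(members, collapse = ","))
    if (key %in% seen) return()
    seen <<- c(seen, key)
    res[[length(res) + 1L]] <<- list(motif_class = class, ways = ways,
                                     size = size,
                                     members = gw$nodes$key[members])
  }
  # hairpins
  for (i in which(paired)) {
    j <- partner[[i]]
    if (j < i) next
    for (wlk in strand_walks(i)) {
      if (wlk$to == j && length(wlk$run) >= 1L &&
          length(wlk$run) <= hairpin_max) {
        emit("HAIRPIN", 1L, c(i, j, wlk$run), length(wlk$run))
      }
    }
  }
  # cycles of k WC pairs connected by strands (internal/bulge/junction)
  max_ways <- ways_range[[2L]]
  search_cycle <- function(start_pair, chain, runs, used) {
    cur <- chain[[length(chain)]]  # current pair as c(opened_at, far_end)
    for (wlk in strand_walks(cur[[2L]])) {
      to <- wlk$to
      if (length(wlk$run) > strand_max) next
      if (to == start_pair[[1L]]) {
        k <- length(chain)
        nodes <- unlist(chain)
        size <- length(unlist(c(runs, list(wlk$run))))
        members <- c(nodes, unlist(runs), wlk$run)
        if (k == 2L) {
          r1 <- length(runs[[2L]]); r2 <- length(wlk$run)
          if (r1 >= 1L && r2 >= 1L) emit("INTERNAL", 2L, members, size)
          else if (r1 + r2 >= 1L) emit("BULGE", 2L, members, size)
        } else if (k >= ways_range[[1L]] && k <= max_ways) {
          emit("JUNCTION", k, members, size)
        }
        next
      }
      if (length(chain) >= max_ways) next
      p <- partner[[to]]
      if (is.na(p)) next
      if (to %in% used || p %in% used) next
      search_cycle(start_pair, c(chain, list(c(to, p))),
                   c(runs, list(wlk$run)), c(used, to, p))
    }
  }
  for (i in which(paired)) {
    j <- partner[[i]]
    search_cycle(c(i, j), list(c(i, j)), list(integer()), c(i, j))
  }
  res
}

inventory_signature <- function(inv) {
  sort(vapply(inv, function(r) {
    paste(r$motif_class, r$size, paste(sort(r$members), collapse = ","))
  }, character(1)))
}
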