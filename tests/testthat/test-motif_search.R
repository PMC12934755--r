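test_that("default pattern set covers the motif classes and junction ways", {
  pats <- make_patterns()
  expect_length(pats, 9L)
  expect_setequal(vapply(pats, `[[`, "", "motif_class"),
                  c("HAIRPIN", "INTERNAL", "BULGE", "JUNCTION"))
  jw <- vapply(Filter(function(p) p$motif_class == "JUNCTION", pats),
               `[[`, 1L, "ways")
  expect_equal(sort(jw), 3:8)
  expect_length(make_patterns(junction_ways = c(3, 3)), 4L)
  expect_error(make_patterns(hairpin_range = c(5, 2)), "range")
  expect_error(make_patterns(junction_ways = c(2, 9)), "ways")
})

test_that("hairpin pattern matches loops within the 1-20 bound only", {
  cg <- compress_graph(from_dot_bracket("(((....)))"))
  hp <- make_patterns()[[1]]
  m <- match_pattern(hp, cg)
  expect_length(m, 1L)
  expect_equal(m[[1]]$size, 4L)
  expect_equal(m[[1]]$members, res_key("A", 3:8))

  # tetraloop-only range
  m44 <- match_pattern(motif_pattern("HAIRPIN", 1L, list(c(4L, 4L))), cg)
  expect_length(m44, 1L)
  m55 <- match_pattern(motif_pattern("HAIRPIN", 1L, list(c(5L, 5L))), cg)
  expect_length(m55, 0L)

  # a 21-nucleotide loop is beyond the thermodynamic-stability bound
  big <- from_dot_bracket(paste0("(((", strrep(".", 21), ")))"))
  expect_length(match_pattern(hp, compress_graph(big)), 0L)
})

test_that("internal, bulge and junction patterns recover planted loops", {
  g <- from_dot_bracket("((.((....)).))")
  ms <- extract_motifs(g)
  cls <- vapply(ms, `[[`, "", "motif_class")
  expect_setequal(cls, c("HAIRPIN", "INTERNAL"))
  int <- ms[[which(cls == "INTERNAL")]]
  expect_equal(int$size, 2L)
  expect_equal(int$members, res_key("A", c(2, 3, 4, 11, 12, 13)))

  gb <- from_dot_bracket("((.((....))))")
  msb <- extract_motifs(gb)
  clsb <- vapply(msb, `[[`, "", "motif_class")
  expect_true("BULGE" %in% clsb)
  expect_equal(msb[[which(clsb == "BULGE")]]$size, 1L)

  st <- generate_structure(structure_spec(
    list(list(class = "JUNCTION", ways = 3, strands = c(2, 3, 3))),
    seed = 17))
  msj <- extract_motifs(st$graph)
  j <- Filter(function(m) m$motif_class == "JUNCTION", msj)
  expect_length(j, 1L)
  expect_equal(j[[1]]$size, 8L)
  expect_equal(j[[1]]$ways, 3L)

  expect_length(extract_motifs(from_dot_bracket("......")), 0L)
})

test_that("motif members never reach into dangling ends", {
  g <- from_dot_bracket("...(((....)))..")
  ms <- extract_motifs(g)
  dang <- res_key("A", c(1:3, 14:15))
  for (m in ms) expect_length(intersect(m$members, dang), 0L)
})

test_that("compressed matching equals brute-force enumeration on random fixtures", {
  suite <- random_suite(60, seed = 19)
  for (st in suite) {
    expect_equal(match_signature(extract_motifs(st$graph)),
                 inventory_signature(oracle_inventory(st$graph)))
  }
})

test_that("custom search respects edge attributes including non-WC", {
  target <- from_dot_bracket("((....))")
  # query: a lone WC edge (no covalent backbone between its two nodes)
  q_wc <- rna_graph(
    data.frame(key = res_key("A", 1:2), chain = "A", resno = 1:2,
               icode = "", base = "OTHER", stringsAsFactors = FALSE),
    data.frame(a = 1L, b = 2L, cov = 0L, wc = 1L, nonwc = 0L))
  hits <- custom_search(q_wc, target)
  expect_length(hits, 2L)

  # triangle covalent-covalent-nonWC planted exactly once
  t2 <- graph_from_pairs(8, nonwc = cbind(3, 5))
  q_tri <- rna_graph(
    data.frame(key = res_key("A", 1:3), chain = "A", resno = 1:3,
               icode = "", base = "OTHER", stringsAsFactors = FALSE),
    data.frame(a = c(1L, 2L, 1L), b = c(2L, 3L, 3L),
               cov = c(1L, 1L, 0L), wc = 0L, nonwc = c(0L, 0L, 1L)))
  hits2 <- custom_search(q_tri, t2)
  expect_length(hits2, 1L)
  expect_setequal(hits2[[1]], res_key("A", 3:5))

  # identity embedding always present
  expect_gte(length(custom_search(target, target)), 1L)

  expect_error(custom_search(graph_from_pairs(31), graph_from_pairs(31)),
               "query too large")
  disc <- graph_from_pairs(2)
  disc$edges <- disc$edges[0, ]
  disc <- rna_graph(disc$nodes, disc$edges)
  expect_error(custom_search(disc, target), "connected")
})

test_that("custom search agrees with a brute-force injective-map oracle", {
  brute <- function(query, target) {
    nq <- nrow(query$nodes); nt <- nrow(target$nodes)
    tattr <- paste(target$edges$a, target$edges$b)
    tval <- paste(target$edges$cov, target$edges$wc, target$edges$nonwc)
    names(tval) <- tattr
    ok <- function(map) {
      for (r in seq_len(nrow(query$edges))) {
        a <- map[query$edges$a[r]]; b <- map[query$edges$b[r]]
        k <- paste(min(a, b), max(a, b))
        want <- paste(query$edges$cov[r], query$edges$wc[r],
                      query$edges$nonwc[r])
        if (is.na(tval[k]) || tval[k] != want) return(FALSE)
      }
      TRUE
    }
    res <- character()
    perm <- function(map, left) {
      if (length(map) == nq) {
        if (ok(map)) res <<- c(res, paste(sort(map), collapse = ","))
        return()
      }
      for (t in left) perm(c(map, t), setdiff(left, t))
    }
    perm(integer(), seq_len(nt))
    sort(unique(res))
  }
  set.seed(23)
  for (rep in 1:8) {
    st <- generate_structure(structure_spec(
      list(list(class = "HAIRPIN", loop = sample(1:3, 1))),
      nonwc = sample(0:1, 1), seed = 400 + rep, stem = 1))
    target <- st$graph
    qsize <- sample(2:3, 1)
    start <- sample(seq_len(nrow(target$nodes) - qsize + 1L), 1)
    query <- rnamotifs:::induced_subgraph_keys(target,
                                   target$nodes$key[start:(start + qsize - 1L)])
    got <- sort(vapply(custom_search(query, target), function(k) {
      paste(sort(match(k, target$nodes$key)), collapse = ",")
    }, ""))
    expect_equal(got, brute(query, target))
  }
})
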