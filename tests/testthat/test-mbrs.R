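tetraloop_features <- function(seed = 101, nonwc = 0) {
  st <- generate_structure(structure_spec(
    list(list(class = "HAIRPIN", loop = 4)), nonwc = nonwc, seed = seed))
  motif_features(extract_motifs(st$graph))
}

test_that("motif weights combine length and non-WC count", {
  f <- tetraloop_features()
  expect_equal(f[[1]]$L, 6L)
  expect_equal(f[[1]]$NC, 0L)
  expect_equal(f[[1]]$W, 6)
  fd <- tetraloop_features(nonwc = 2)
  expect_equal(fd[[1]]$NC, 2L)
  expect_equal(fd[[1]]$W, 6 * 3)
})

test_that("WL kernel similarity is 1 on identity, symmetric, relabel-invariant", {
  f <- tetraloop_features()
  g <- f[[1]]$graph
  expect_equal(wl_similarity(g, g), 1.0)

  gd <- tetraloop_features(nonwc = 1)[[1]]$graph
  s <- wl_similarity(g, gd)
  expect_gt(s, 0); expect_lt(s, 1)

  set.seed(7)
  for (rep in 1:30) {
    st <- generate_structure(structure_spec(
      list(list(class = sample(c("HAIRPIN", "INTERNAL", "BULGE"), 1))),
      nonwc = sample(0:2, 1), seed = 2000 + rep))
    ms <- motif_features(extract_motifs(st$graph))
    g1 <- ms[[1]]$graph
    g2 <- ms[[length(ms)]]$graph
    expect_equal(wl_similarity(g1, g2), wl_similarity(g2, g1),
                 tolerance = 1e-12)
    expect_equal(wl_similarity(random_relabel(g1), g2),
                 wl_similarity(g1, g2), tolerance = 1e-12)
  }
  expect_error(wl_similarity(rna_graph(tetraloop_features()[[1]]$graph$nodes[0, ],
                                       NULL), g), "nonempty")
})

test_that("assignment is optimal against permutation brute force", {
  # 2x2 worked case
  S <- matrix(c(0.9, 0.3, 0.2, 0.8), 2, 2)
  expect_equal(unname(best_match(S)), cbind(1:2, 1:2))

  brute_cost <- function(C) {
    n <- nrow(C); m <- ncol(C)
    perm <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perm(v[-i]), function(p) c(v[[i]], p))))
    best <- Inf
    if (n <= m) {
      for (p in perm(seq_len(m)))
        best <- min(best, sum(C[cbind(seq_len(n), p[seq_len(n)])]))
    } else {
      for (p in perm(seq_len(n)))
        best <- min(best, sum(C[cbind(p[seq_len(m)], seq_len(m))]))
    }
    best
  }
  set.seed(13)
  for (rep in 1:300) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    C <- matrix(runif(n * m), n, m)
    asg <- best_match(cost = C)
    expect_equal(nrow(asg), min(n, m))
    expect_equal(sum(C[asg]), brute_cost(C), tolerance = 1e-12)
  }
  # rectangular: 3 motifs against 1 gives exactly one matched pair
  expect_equal(nrow(best_match(matrix(runif(3), 3, 1))), 1L)
})

test_that("RNA similarity follows the weighted matched-pair formula", {
  f6 <- tetraloop_features(seed = 103)          # W = 6
  expect_equal(rna_similarity(f6, f6)$score, 1.0)

  # hand evaluation: A = {W=6}, B = {same motif, plus one with W=4}
  extra <- tetraloop_features(seed = 104)[[1]]
  extra$graph <- rnamotifs:::induced_subgraph_keys(
    extra$graph, extra$graph$nodes$key[1:4])
  extra$L <- 4L; extra$NC <- 0L; extra$W <- 4
  A <- f6
  B <- c(f6, list(extra))
  rs <- rna_similarity(A, B)
  expect_equal(rs$score, 2 * 6 / (6 + 10), tolerance = 1e-9)

  expect_error(rna_similarity(list(), list()), "empty")
  expect_equal(rna_similarity(f6, list())$score, 0)
})

test_that("RNA similarity is symmetric, bounded, monotone under shared motifs", {
  set.seed(17)
  pool <- random_suite(12, seed = 37)
  feats <- lapply(pool, function(st) motif_features(extract_motifs(st$graph)))
  feats <- Filter(function(f) length(f) > 0, feats)
  for (rep in 1:15) {
    ij <- sample(length(feats), 2)
    a <- feats[[ij[[1]]]]; b <- feats[[ij[[2]]]]
    rab <- rna_similarity(a, b)$score
    expect_equal(rab, rna_similarity(b, a)$score, tolerance = 1e-9)
    expect_gte(rab, 0); expect_lte(rab, 1)
    expect_equal(rna_similarity(a, a)$score, 1.0, tolerance = 1e-9)
    # adding one identical motif to both sides never decreases RS
    shared <- tetraloop_features(seed = 3000 + rep)[[1]]
    r2 <- rna_similarity(c(a, list(shared)), c(b, list(shared)))$score
    expect_gte(r2 + 1e-9, rab)
  }
})

test_that("Leiden recovers planted similarity blocks and builds the meta-graph", {
  set.seed(19)
  n <- 30
  M <- matrix(0.1, n, n)
  M[1:15, 1:15] <- 0.9
  M[16:30, 16:30] <- 0.9
  M <- M + matrix(rnorm(n * n, 0, 0.01), n)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  cl <- cluster_rnas(M)
  expect_length(unique(cl$membership), 2L)
  expect_length(unique(cl$membership[1:15]), 1L)
  expect_length(unique(cl$membership[16:30]), 1L)
  expect_equal(nrow(cl$meta_nodes), 2L)  # both blocks exceed 10 members
  expect_equal(nrow(cl$meta_edges), 1L)

  # all-identical RNAs collapse to one cluster
  M1 <- matrix(1, 12, 12)
  expect_length(unique(cluster_rnas(M1)$membership), 1L)

  # clusters of sizes 12/15/5: only two meta-nodes
  m2 <- c(rep(1, 12), rep(2, 15), rep(3, 5))
  M2 <- outer(m2, m2, function(x, y) ifelse(x == y, 0.9, 0.05))
  diag(M2) <- 1
  cl2 <- cluster_rnas(M2)
  expect_equal(nrow(cl2$meta_nodes), 2L)
})

test_that("Mann-Whitney comparison flags a shifted intra-family sample", {
  set.seed(23)
  inter <- runif(50, 0.1, 0.5)
  intra <- inter + 0.3
  fc <- family_comparison(intra, inter)
  expect_lt(fc$p, 0.05)
  expect_true(is.finite(fc$U))

  same <- family_comparison(inter, inter)
  expect_gt(same$p, 0.9)

  tiny <- family_comparison(0.8, 0.3)
  expect_true(is.finite(tiny$U) && tiny$p > 0 && tiny$p <= 1)
})
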