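#' Motif features for similarity scoring
#'
#' For each motif: `L` = number of member nucleotides (closing pairs
#' included), `NC` = number of edges carrying the non-WC component (each
#' edge counted once even when multi-type), weight `W = L * (1 + NC)`.
#' Non-WC-rich motifs therefore dominate the weighted similarity, mirroring
#' their structural information content.
#'
#' @param matches list of `motif_match` from [extract_motifs()]
#' @return list of `motif_feature` (fields `graph`, `L`, `NC`, `W`)
#' @export
motif_features <- function(matches) {
  lapply(matches, function(m) {
    g <- m$graph_with_nonwc
    NC <- sum(g$edges$nonwc == 1L)
    L <- nrow(g$nodes)
    structure(list(graph = g, L = L, NC = NC, W = L * (1 + NC),
                   motif_class = m$motif_class),
              class = "motif_feature")
  })
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a
}

#' Weisfeiler-Lehman subtree kernel similarity of two motif graphs
#'
#' Edge-attribute-aware WL refinement: the initial node label is the sorted
#' multiset of incident edge-attribute vectors, and neighbour messages carry
#' the connecting edge attribute, so covalent, WC and non-WC context all
#' enter the subtree features. The score is the feature-count inner product
#' under cosine normalization, hence in \[0, 1\], 1 for identical graphs and
#' symmetric; it is invariant under node relabeling.
#'
#' @param g1,g2 nonempty `rna_graph`s
#' @param iterations WL refinement rounds (default 3)
#' @return similarity in \[0, 1\]
#' @export
wl_similarity <- function(g1, g2, iterations = 3L) {
  if (nrow(g1$nodes) == 0L || nrow(g2$nodes) == 0L) {
    stop("wl_similarity requires nonempty graphs")
  }
  dict <- new.env(parent = emptyenv())
  dict$map <- new.env(parent = emptyenv(), hash = TRUE)
  dict$n <- 0L
  f1 <- wl_feature_counts(g1, iterations, dict)
  f2 <- wl_feature_counts(g2, iterations, dict)
  keys <- union(names(f1), names(f2))
  v1 <- vapply(keys, function(k) f1[k][[1]] %||% 0, numeric(1))
  v2 <- vapply(keys, function(k) f2[k][[1]] %||% 0, numeric(1))
  denom <- sqrt(sum(v1^2)) * sqrt(sum(v2^2))
  if (denom == 0) return(0)
  sum(v1 * v2) / denom
}

wl_feature_counts <- function(g, iterations, dict) {
  n <- nrow(g$nodes)
  e <- g$edges
  attr <- edge_attr_str(e)
  nb <- rep(list(list()), n)
  for (r in seq_len(nrow(e))) {
    nb[[e$a[[r]]]] <- c(nb[[e$a[[r]]]], list(c(e$b[[r]], r)))
    nb[[e$b[[r]]]] <- c(nb[[e$b[[r]]]], list(c(e$a[[r]], r)))
  }
  intern <- function(s) {
    id <- dict$map[[s]]
    if (is.null(id)) {
      dict$n <- dict$n + 1L
      id <- dict$n
      assign(s, id, envir = dict$map)
    }
    id
  }
  lab <- vapply(seq_len(n), function(v) {
    inc <- sort(vapply(nb[[v]], function(p) attr[[p[[2L]]]], character(1)))
    intern(paste0("0:", paste(inc, collapse = "|")))
  }, integer(1))
  feats <- numeric(0)
  accumulate <- function(feats, lab) {
    counts <- table(lab)
    for (k in names(counts)) {
      feats[k] <- (feats[k][[1]] %||% 0) + as.numeric(counts[[k]])
    }
    feats
  }
  feats <- accumulate(feats, lab)
  for (it in seq_len(iterations)) {
    lab <- vapply(seq_len(n), function(v) {
      msg <- sort(vapply(nb[[v]], function(p) {
        paste0(lab[[p[[1L]]]], "@", attr[[p[[2L]]]])
      }, character(1)))
      intern(paste0(lab[[v]], ">", paste(msg, collapse = "|")))
    }, integer(1))
    feats <- accumulate(feats, lab)
  }
  feats
}

#' Optimal one-to-one motif assignment
#'
#' Solves the rectangular linear sum assignment problem minimizing the total
#' cost `sum(1 - S)` over matched pairs with a Hungarian
#' (potential/augmenting-path) solver; `min(|A|, |B|)` pairs are matched,
#' the rest left out.
#'
#' @param S similarity matrix (rows = motifs of A, cols = motifs of B), or
#'   pass `cost` directly
#' @param cost optional cost matrix overriding `1 - S`
#' @return two-column matrix of matched (row, col) index pairs
#' @export
best_match <- function(S = NULL, cost = NULL) {
  if (is.null(cost)) cost <- 1 - S
  n <- nrow(cost); m <- ncol(cost)
  if (is.null(n) || n == 0L || m == 0L) {
    return(matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("a", "b"))))
  }
  transposed <- FALSE
  if (n > m) { cost <- t(cost); transposed <- TRUE; tmp <- n; n <- m; m <- tmp }
  assignment <- hungarian(cost)
  out <- cbind(seq_len(n), assignment)
  if (transposed) out <- out[, c(2L, 1L), drop = FALSE]
  colnames(out) <- c("a", "b")
  out[order(out[, 1L]), , drop = FALSE]
}

hungarian <- function(a) {
  # potentials u, v; p[j] = row matched to column j (0-based sentinel row 0)
  n <- nrow(a); m <- ncol(a)
  stopifnot(n <= m)
  INF <- Inf
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L); way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[[1L]] <- i
    j0 <- 1L
    minv <- rep(INF, m + 1L)
    used <- logical(m + 1L)
    repeat {
      used[[j0]] <- TRUE
      i0 <- p[[j0]]; delta <- INF; j1 <- 0L
      for (j in seq_len(m) + 1L) {
        if (!used[[j]]) {
          cur <- a[i0, j - 1L] - u[[i0 + 1L]] - v[[j]]
          if (cur < minv[[j]]) { minv[[j]] <- cur; way[[j]] <- j0 }
          if (minv[[j]] < delta) { delta <- minv[[j]]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1L)) {
        if (used[[j]]) {
          u[[p[[j]] + 1L]] <- u[[p[[j]] + 1L]] + delta
          v[[j]] <- v[[j]] - delta
        } else {
          minv[[j]] <- minv[[j]] - delta
        }
      }
      j0 <- j1
      if (p[[j0]] == 0L) break
    }
    repeat {
      j1 <- way[[j0]]
      p[[j0]] <- p[[j1]]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m) + 1L) {
    if (p[[j]] > 0L) ans[[p[[j]]]] <- j - 1L
  }
  ans
}

#' Motif-based RNA similarity
#'
#' Weighted aggregation of matched motif-motif similarities:
#' `RS = 2 * sum((W_m + W_sigma(m))/2 * S_m,sigma(m)) / (sum W_A + sum W_B)`
#' where the optimal matching `sigma` minimizes total cost `1 - S` via
#' [best_match()]. `RS` is symmetric, lies in \[0, 1\] and equals 1 for
#' identical motif inventories.
#'
#' @param A,B lists of `motif_feature` (see [motif_features()])
#' @param iterations WL iterations for the pairwise motif similarities
#' @return list with `score`, `assignment` (matched index pairs) and
#'   `per_pair` motif similarities
#' @export
rna_similarity <- function(A, B, iterations = 3L) {
  if (length(A) == 0L && length(B) == 0L) {
    stop("similarity undefined: both motif inventories are empty")
  }
  WA <- sum(vapply(A, `[[`, numeric(1), "W"))
  WB <- sum(vapply(B, `[[`, numeric(1), "W"))
  if (length(A) == 0L || length(B) == 0L) {
    return(list(score = 0,
                assignment = matrix(integer(), ncol = 2L,
                                    dimnames = list(NULL, c("a", "b"))),
                per_pair = numeric()))
  }
  S <- matrix(0, length(A), length(B))
  for (i in seq_along(A)) {
    for (j in seq_along(B)) {
      S[i, j] <- wl_similarity(A[[i]]$graph, B[[j]]$graph, iterations)
    }
  }
  asg <- best_match(S)
  per <- S[asg]
  wsum <- vapply(seq_len(nrow(asg)), function(r) {
    (A[[asg[r, 1L]]]$W + B[[asg[r, 2L]]]$W) / 2
  }, numeric(1))
  score <- 2 * sum(wsum * per) / (WA + WB)
  list(score = score, assignment = asg, per_pair = per)
}

#' Pairwise RNA similarity matrix
#'
#' @param rnas named list; each element a list of `motif_feature`
#' @param iterations WL iterations
#' @return symmetric matrix with unit diagonal
#' @export
pairwise_similarity <- function(rnas, iterations = 3L) {
  n <- length(rnas)
  stopifnot(n >= 2L)
  M <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      M[i, j] <- M[j, i] <- rna_similarity(rnas[[i]], rnas[[j]],
                                           iterations)$score
    }
  }
  dimnames(M) <- list(names(rnas), names(rnas))
  M
}

#' Leiden clustering of the RNA similarity network
#'
#' Community detection on the dense weighted similarity graph (no
#' thresholding); the meta-graph keeps clusters with more than
#' `meta_min_size` members as nodes, edges weighted by the mean
#' inter-cluster similarity.
#'
#' @param M similarity matrix from [pairwise_similarity()]
#' @param resolution Leiden resolution parameter
#' @param meta_min_size minimal cluster size for a meta-graph node
#' @return list with `membership` (integer labels), `meta_nodes`
#'   (data.frame cluster/size), `meta_edges` (data.frame a/b/weight)
#' @export
cluster_rnas <- function(M, resolution = 1.0, meta_min_size = 10L) {
  g <- igraph::graph_from_adjacency_matrix(M, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10L)
  membership <- igraph::membership(cl)
  sizes <- table(membership)
  big <- as.integer(names(sizes)[sizes > meta_min_size])
  meta_nodes <- data.frame(cluster = big,
                           size = as.integer(sizes[as.character(big)]))
  meta_edges <- data.frame(a = integer(), b = integer(), weight = numeric())
  if (length(big) > 1L) {
    for (i in seq_len(length(big) - 1L)) {
      for (j in (i + 1L):length(big)) {
        mi <- membership == big[[i]]; mj <- membership == big[[j]]
        meta_edges <- rbind(meta_edges,
                            data.frame(a = big[[i]], b = big[[j]],
                                       weight = mean(M[mi, mj])))
      }
    }
  }
  list(membership = as.integer(membership), meta_nodes = meta_nodes,
       meta_edges = meta_edges)
}

#' Compare intra- and inter-family similarity distributions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test; a significant shift
#' supports higher within-family than between-family motif-based similarity.
#'
#' @param intra_scores,inter_scores numeric similarity samples
#' @return list with the `U` statistic and `p` value
#' @export
family_comparison <- function(intra_scores, inter_scores) {
  stopifnot(length(intra_scores) > 0L, length(inter_scores) > 0L)
  w <- wilcox.test(intra_scores, inter_scores, alternative = "two.sided")
  list(U = unname(w$statistic), p = w$p.value)
}
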