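#' Seeded synthetic RNA structures with known motif inventories
#'
#' The generator plants hairpins, internal loops, bulges, multiway junctions
#' and pseudoknots of six topologies into dot-bracket scaffolds, assigns
#' complementary sequences to planted pairs, optionally decorates loops with
#' non-WC edges, and lays out schematic 3D coordinates (paired C1' atoms at
#' 10.4 angstrom, everything else far apart) so that the geometric annotator
#' recovers exactly the planted pairs. Coordinates are a ladder layout,
#' sufficient for distance-based pairing and PDB round-trips, not physically
#' realistic geometry.
#'
#' @param motifs list of planted motif specs, e.g.
#'   `list(class = "HAIRPIN", loop = 4)`,
#'   `list(class = "INTERNAL", a = 1, b = 1)`,
#'   `list(class = "BULGE", a = 2)`,
#'   `list(class = "JUNCTION", ways = 3, strands = c(2, 3, 3))`,
#'   `list(class = "PSEUDOKNOT", pk_class = "H")`
#' @param nonwc number of random non-WC decorations between loop nucleotides
#' @param seed RNG seed; identical seeds give identical output
#' @param stem helix depth used for planted stems
#' @param structure_id id stamped on the generated structure
#' @return `structure_spec` for [generate_structure()]
#' @export
structure_spec <- function(motifs, nonwc = 0L, seed = 1L, stem = 2L,
                           structure_id = NULL) {
  stopifnot(stem >= 1L, nonwc >= 0L)
  structure(list(motifs = motifs, nonwc = nonwc, seed = seed, stem = stem,
                 structure_id = structure_id %||% sprintf("SYN%04d", seed %% 10000L)),
            class = "structure_spec")
}

# element builders: return list(db, records, extra_pairs) with 1-based
# positions relative to the element start; records carry class, size and
# relative member positions

el_hairpin <- function(loop, stem) {
  n <- 2L * stem + loop
  rec <- if (loop >= 1L && loop <= 20L) {
    list(list(class = "HAIRPIN", size = loop,
              members = stem:(stem + loop + 1L)))
  } else list()
  list(db = paste0(strrep("(", stem), strrep(".", loop), strrep(")", stem)),
       n = n, records = rec)
}

el_wrap_loop <- function(a, b, inner, stem) {
  # internal loop (a,b >= 1) or bulge (one of a,b zero) around `inner`
  n <- 2L * stem + a + b + inner$n
  db <- paste0(strrep("(", stem), strrep(".", a), inner$db,
               strrep(".", b), strrep(")", stem))
  shift <- stem + a
  recs <- lapply(inner$records, shift_record, shift)
  outer_close <- c(stem, stem + a + inner$n + b + 1L)
  inner_outer <- c(stem + a + 1L, stem + a + inner$n)
  cls <- if (a >= 1L && b >= 1L) "INTERNAL" else
    if (a + b >= 1L) "BULGE" else NA_character_
  if (!is.na(cls) && a <= 20L && b <= 20L) {
    dots <- c(if (a > 0L) (stem + 1L):(stem + a),
              if (b > 0L) (stem + a + inner$n + 1L):(stem + a + inner$n + b))
    recs <- c(recs, list(list(class = cls, size = a + b,
                              members = sort(c(outer_close, inner_outer,
                                               dots)))))
  }
  list(db = db, n = n, records = recs)
}

el_junction <- function(strands, branches, stem) {
  ways <- length(strands)
  stopifnot(length(branches) == ways - 1L)
  db <- strrep("(", stem)
  pos <- stem
  members <- c(stem)  # innermost closing pair left; right added later
  recs <- list()
  for (t in seq_len(ways - 1L)) {
    if (strands[[t]] > 0L) {
      members <- c(members, (pos + 1L):(pos + strands[[t]]))
      db <- paste0(db, strrep(".", strands[[t]]))
      pos <- pos + strands[[t]]
    }
    br <- branches[[t]]
    recs <- c(recs, lapply(br$records, shift_record, pos))
    members <- c(members, pos + 1L, pos + br$n)  # branch outermost pair
    db <- paste0(db, br$db)
    pos <- pos + br$n
  }
  if (strands[[ways]] > 0L) {
    members <- c(members, (pos + 1L):(pos + strands[[ways]]))
    db <- paste0(db, strrep(".", strands[[ways]]))
    pos <- pos + strands[[ways]]
  }
  members <- c(members, pos + 1L)  # innermost closing pair right
  db <- paste0(db, strrep(")", stem))
  n <- pos + stem
  if (ways >= 3L && ways <= 8L && all(strands <= 20L)) {
    recs <- c(recs, list(list(class = "JUNCTION", ways = ways,
                              size = sum(strands),
                              members = sort(members))))
  }
  list(db = db, n = n, records = recs)
}

shift_record <- function(r, by) {
  r$members <- r$members + by
  r
}

# Six pseudoknot scaffolds. Their motif inventories (crossing pairs create
# incidental junction-shaped cycles, e.g. a kissing hairpin contains a
# 4-way-junction cycle) were enumerated once with the uncompressed
# brute-force matcher and are frozen here.
PK_TEMPLATES <- list(
  H     = "((((....[[[[))))....]]]]",
  HHH   = "((((..[[[..))))....((((..]]]..))))",
  HLOUT = "((((....[[[[))))..((((....))))..]]]]",
  HLIN  = "((((..[[[[..((((....))))..))))....]]]]",
  LL    = "((..[[..((((....))))..))..((((..]]..))))",
  LR    = "((..[[..{{..))..]]..}}"
)

PK_MOTIF_RECORDS <- list(
  H = list(
    list(class = "JUNCTION", ways = 5L, size = 4L,
         members = c(1L, 2L, 3L, 4L, 12L, 13L, 14L, 15L, 16L, 17L, 18L, 19L, 20L, 21L)),
    list(class = "JUNCTION", ways = 5L, size = 4L,
         members = c(4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 21L, 22L, 23L, 24L))),
  HHH = list(
    list(class = "JUNCTION", ways = 4L, size = 8L,
         members = c(4L, 5L, 6L, 7L, 9L, 10L, 11L, 12L, 23L, 24L, 25L, 26L, 28L, 29L, 30L, 31L))),
  HLOUT = list(
    list(class = "HAIRPIN", ways = 1L, size = 4L,
         members = c(22L, 23L, 24L, 25L, 26L, 27L)),
    list(class = "JUNCTION", ways = 6L, size = 4L,
         members = c(1L, 2L, 3L, 4L, 12L, 13L, 14L, 15L, 16L, 17L, 18L, 19L, 30L, 31L, 32L, 33L)),
    list(class = "JUNCTION", ways = 5L, size = 4L,
         members = c(4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 33L, 34L, 35L, 36L))),
  HLIN = list(
    list(class = "HAIRPIN", ways = 1L, size = 4L,
         members = c(16L, 17L, 18L, 19L, 20L, 21L)),
    list(class = "JUNCTION", ways = 6L, size = 8L,
         members = c(1L, 2L, 3L, 4L, 10L, 11L, 12L, 13L, 24L, 25L, 26L, 27L, 28L, 29L, 30L, 31L, 32L, 33L, 34L, 35L)),
    list(class = "JUNCTION", ways = 6L, size = 6L,
         members = c(4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 24L, 25L, 26L, 27L, 35L, 36L, 37L, 38L))),
  LL = list(
    list(class = "HAIRPIN", ways = 1L, size = 4L,
         members = c(12L, 13L, 14L, 15L, 16L, 17L)),
    list(class = "JUNCTION", ways = 8L, size = 8L,
         members = c(1L, 2L, 6L, 7L, 8L, 9L, 20L, 21L, 22L, 23L, 24L, 25L, 26L, 27L, 28L, 29L, 30L, 31L, 32L, 33L, 37L, 38L, 39L, 40L)),
    list(class = "JUNCTION", ways = 5L, size = 10L,
         members = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 20L, 21L, 22L, 23L, 30L, 31L, 32L, 33L, 34L, 35L, 36L, 37L)),
    list(class = "JUNCTION", ways = 4L, size = 6L,
         members = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 20L, 21L, 22L, 23L, 33L, 34L)),
    list(class = "JUNCTION", ways = 3L, size = 4L,
         members = c(5L, 6L, 30L, 31L, 32L, 33L, 34L, 35L, 36L, 37L))),
  LR = list(
    list(class = "JUNCTION", ways = 5L, size = 6L,
         members = c(1L, 2L, 5L, 6L, 10L, 11L, 12L, 13L, 14L, 15L, 16L, 17L, 18L, 19L, 20L, 21L)),
    list(class = "JUNCTION", ways = 5L, size = 6L,
         members = c(1L, 2L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 14L, 15L, 16L, 17L, 21L, 22L)),
    list(class = "JUNCTION", ways = 3L, size = 6L,
         members = c(2L, 3L, 4L, 5L, 10L, 11L, 12L, 13L, 18L, 19L, 20L, 21L)),
    list(class = "JUNCTION", ways = 5L, size = 6L,
         members = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 17L, 18L, 21L, 22L))) 
)

el_pseudoknot <- function(pk_class) {
  db <- PK_TEMPLATES[[pk_class]]
  if (is.null(db)) stop("unknown pseudoknot class '", pk_class, "'")
  list(db = db, n = nchar(db), records = PK_MOTIF_RECORDS[[pk_class]],
       pk_class = pk_class)
}

build_element <- function(m, stem) {
  cls <- toupper(m$class)
  switch(cls,
    HAIRPIN = el_hairpin(m$loop %||% 4L, stem),
    INTERNAL = {
      stopifnot((m$a %||% 1L) >= 1L, (m$b %||% 1L) >= 1L)
      el_wrap_loop(m$a %||% 1L, m$b %||% 1L,
                   el_hairpin(m$inner_loop %||% 4L, stem), stem)
    },
    BULGE = el_wrap_loop(m$a %||% 1L, 0L, el_hairpin(m$inner_loop %||% 4L, stem),
                         stem),
    JUNCTION = {
      ways <- m$ways %||% 3L
      strands <- m$strands %||% rep(2L, ways)
      stopifnot(length(strands) == ways)
      branches <- rep(list(el_hairpin(m$branch_loop %||% 4L, stem)), ways - 1L)
      el_junction(as.integer(strands), branches, stem)
    },
    PSEUDOKNOT = el_pseudoknot(m$pk_class %||% "H"),
    stop("unknown motif class '", m$class, "'")
  )
}

#' Generate a synthetic structure from a spec
#'
#' @param spec a `structure_spec`
#' @return list with `dot_bracket`, `graph` (with any non-WC decorations),
#'   `structure` (toy 3D coordinates), `interactions`, `annotation` (text in
#'   the [read_annotation()] dialect), `inventory` (expected motif records:
#'   class, size, member keys), `pk_classes` (expected pseudoknot classes),
#'   `seq`
#' @export
generate_structure <- function(spec) {
  set.seed(spec$seed)
  spacer <- 2L
  db <- ""
  records <- list()
  pk_classes <- character()
  pos <- 0L
  for (k in seq_along(spec$motifs)) {
    el <- build_element(spec$motifs[[k]], spec$stem)
    if (k > 1L) {
      db <- paste0(db, strrep(".", spacer))
      pos <- pos + spacer
    }
    records <- c(records, lapply(el$records, shift_record, pos))
    if (!is.null(el$pk_class)) pk_classes <- c(pk_classes, el$pk_class)
    db <- paste0(db, el$db)
    pos <- pos + el$n
  }
  n <- nchar(db)
  pr <- db_pairs(db)

  # sequence: complementary planted pairs, random elsewhere
  seqv <- sample(RNA_BASES, n, replace = TRUE)
  pair_choices <- matrix(c("A", "U", "U", "A", "G", "C", "C", "G",
                           "G", "U", "U", "G"), ncol = 2L, byrow = TRUE)
  for (r in seq_len(nrow(pr))) {
    pick <- pair_choices[sample.int(6L, 1L), ]
    seqv[[pr[r, "i"]]] <- pick[[1L]]
    seqv[[pr[r, "j"]]] <- pick[[2L]]
  }

  g <- from_dot_bracket(db, seq = paste(seqv, collapse = ""))

  # non-WC decorations between unpaired loop nucleotides
  paired <- rep(FALSE, n)
  paired[c(pr[, "i"], pr[, "j"])] <- TRUE
  unpaired <- which(!paired)
  nonwc_edges <- NULL
  if (spec$nonwc > 0L && length(unpaired) >= 2L) {
    tries <- 0L
    while (tries < 200L &&
           (is.null(nonwc_edges) || nrow(nonwc_edges) < spec$nonwc)) {
      tries <- tries + 1L
      cand <- sort(sample(unpaired, 2L))
      if (cand[[2L]] - cand[[1L]] < 2L) next
      if (!is.null(nonwc_edges) &&
          any(nonwc_edges[, 1L] == cand[[1L]] &
                nonwc_edges[, 2L] == cand[[2L]])) next
      nonwc_edges <- rbind(nonwc_edges, cand)
    }
  }
  if (!is.null(nonwc_edges)) {
    extra <- data.frame(a = nonwc_edges[, 1L], b = nonwc_edges[, 2L],
                        cov = 0L, wc = 0L, nonwc = 1L)
    g <- rna_graph(g$nodes, rbind(g$edges, extra))
  }

  s <- toy_structure(spec$structure_id, seqv, pr)

  ann <- c(sprintf("A%d-A%d : WC", pr[, "i"], pr[, "j"]),
           if (!is.null(nonwc_edges))
             sprintf("A%d-A%d : NONWC", nonwc_edges[, 1L], nonwc_edges[, 2L]))
  inventory <- lapply(records, function(r) {
    list(motif_class = r$class, size = as.integer(r$size),
         members = res_key("A", sort(r$members)))
  })
  list(dot_bracket = db, graph = g, structure = s,
       interactions = read_annotation(ann, s), annotation = ann,
       inventory = inventory, pk_classes = pk_classes,
       seq = paste(seqv, collapse = ""))
}

toy_structure <- function(structure_id, seqv, pr) {
  n <- length(seqv)
  x <- y <- z <- numeric(n)
  placed <- rep(FALSE, n)
  for (r in seq_len(nrow(pr))) {
    i <- pr[r, "i"]; j <- pr[r, "j"]
    x[[i]] <- 0; y[[i]] <- 6.5 * r; z[[i]] <- 0
    x[[j]] <- 10.4; y[[j]] <- 6.5 * r; z[[j]] <- 0
    placed[c(i, j)] <- TRUE
  }
  m <- 0L
  for (i in which(!placed)) {
    m <- m + 1L
    x[[i]] <- 1000 + 20 * m; y[[i]] <- 0; z[[i]] <- 0
  }
  atoms <- data.frame(
    chain = "A", resno = rep(seq_len(n), each = 2L), icode = "",
    resname = rep(seqv, each = 2L),
    atom = rep(c("P", "C1'"), n),
    x = as.vector(rbind(x + 0.5, x)),
    y = as.vector(rbind(y + 0.5, y)),
    z = as.vector(rbind(z + 0.5, z)), stringsAsFactors = FALSE)
  residues <- data.frame(chain = "A", resno = seq_len(n), icode = "",
                         base = seqv, stringsAsFactors = FALSE)
  new_rna_structure(structure_id, residues, atoms, "PDB")
}

#' Reproducible suite of synthetic structures
#'
#' Deterministic coverage block first (hairpin loops 1-20, internal loops,
#' bulges, 3- to 8-way junctions, all six pseudoknot classes, with and
#' without non-WC decorations), then random specs up to `n`. Identical
#' seeds give identical suites.
#'
#' @param n number of structures (>= 1)
#' @param seed suite seed
#' @return list of results from [generate_structure()]; each element also
#'   carries its `spec`
#' @export
random_suite <- function(n, seed = 7L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  specs <- list()
  add <- function(motifs, nonwc = 0L) {
    specs[[length(specs) + 1L]] <<- list(motifs = motifs, nonwc = nonwc)
  }
  for (loop in 1:20) add(list(list(class = "HAIRPIN", loop = loop)))
  for (ab in list(c(1L, 1L), c(2L, 3L), c(1L, 4L), c(3L, 1L), c(2L, 2L))) {
    add(list(list(class = "INTERNAL", a = ab[[1L]], b = ab[[2L]])))
  }
  for (a in 1:5) add(list(list(class = "BULGE", a = a)))
  for (w in 3:8) {
    add(list(list(class = "JUNCTION", ways = w,
                  strands = sample(0:4, w, replace = TRUE))))
  }
  for (pk in names(PK_TEMPLATES)) {
    add(list(list(class = "PSEUDOKNOT", pk_class = pk)))
  }
  add(list(list(class = "HAIRPIN", loop = 4L)), nonwc = 2L)
  add(list(list(class = "INTERNAL", a = 2L, b = 2L)), nonwc = 1L)
  while (length(specs) < n) {
    cls <- sample(c("HAIRPIN", "INTERNAL", "BULGE", "JUNCTION",
                    "PSEUDOKNOT"), 1L)
    m <- switch(cls,
      HAIRPIN = list(class = "HAIRPIN", loop = sample(1:20, 1L)),
      INTERNAL = list(class = "INTERNAL", a = sample(1:6, 1L),
                      b = sample(1:6, 1L)),
      BULGE = list(class = "BULGE", a = sample(1:6, 1L)),
      JUNCTION = list(class = "JUNCTION", ways = sample(3:8, 1L),
                      strands = NULL),
      PSEUDOKNOT = list(class = "PSEUDOKNOT",
                        pk_class = sample(names(PK_TEMPLATES), 1L)))
    if (cls == "JUNCTION") {
      m$strands <- sample(0:4, m$ways, replace = TRUE)
    }
    extra <- if (sample.int(3L, 1L) == 1L && cls != "PSEUDOKNOT") {
      list(m, list(class = "HAIRPIN", loop = sample(1:8, 1L)))
    } else list(m)
    add(extra, nonwc = sample(0:2, 1L))
  }
  specs <- specs[seq_len(n)]
  seeds <- sample.int(2147483646L, n)
  lapply(seq_len(n), function(i) {
    sp <- structure_spec(specs[[i]]$motifs, nonwc = specs[[i]]$nonwc,
                         seed = seeds[[i]],
                         structure_id = sprintf("SYN%04d", i))
    out <- generate_structure(sp)
    out$spec <- sp
    out
  })
}
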