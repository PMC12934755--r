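#' Motif store
#'
#' A single-file relational-style motif store. Rows carry the unique motif
#' id, motif class, source structure (PDB) id, size (number of unpaired
#' nucleotides), member residue keys, both graph views as JSON and the motif
#' coordinates as PDB text. The store lives in memory and is persisted as one
#' versioned JSON file via [save_store()] / [load_store()].
#'
#' @return an empty `motif_store`
#' @export
motif_store <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- empty_store_rows()
  env$next_id <- 1L
  env$schema_version <- 1L
  structure(env, class = "motif_store")
}

empty_store_rows <- function() {
  data.frame(motif_id = integer(), motif_class = character(),
             pdb_id = character(), size = integer(), n_members = integer(),
             members = character(), graph_with_nonwc = character(),
             graph_without_nonwc = character(), pdb_text = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.motif_store <- function(x, ...) {
  cat(sprintf("motif_store: %d motifs (%s)\n", nrow(x$rows),
              paste(names(table(x$rows$motif_class)), collapse = ", ")))
  invisible(x)
}

#' Add motif occurrences to a store
#'
#' @param store a `motif_store`
#' @param matches list of `motif_match` from [extract_motifs()]
#' @param pdb_id source structure identifier
#' @param s optional `rna_structure`; when given, each motif's member
#'   coordinates are stored as PDB text for ZIP export
#' @param motif_ids optional explicit ids (must be unused)
#' @return number of rows inserted
#' @export
store_motifs <- function(store, matches, pdb_id, s = NULL, motif_ids = NULL) {
  if (length(matches) == 0L) return(0L)
  if (is.null(motif_ids)) {
    motif_ids <- seq.int(store$next_id, length.out = length(matches))
  }
  if (any(motif_ids %in% store$rows$motif_id) || anyDuplicated(motif_ids)) {
    stop("duplicate motif_id on insert")
  }
  rows <- do.call(rbind, lapply(seq_along(matches), function(i) {
    m <- matches[[i]]
    data.frame(
      motif_id = as.integer(motif_ids[[i]]),
      motif_class = m$motif_class, pdb_id = pdb_id,
      size = m$size, n_members = length(m$members),
      members = paste(m$members, collapse = ";"),
      graph_with_nonwc = as.character(graph_to_json(m$graph_with_nonwc)),
      graph_without_nonwc = as.character(graph_to_json(m$graph_without_nonwc)),
      pdb_text = if (is.null(s)) NA_character_ else
        paste(write_motif_pdb(s, m$members), collapse = "\n"),
      stringsAsFactors = FALSE)
  }))
  store$rows <- rbind(store$rows, rows)
  store$next_id <- max(store$rows$motif_id) + 1L
  nrow(rows)
}

#' Query motifs by class and size
#'
#' @param store a `motif_store`
#' @param motif_class optional class filter
#' @param size optional size filter (unpaired nucleotide count)
#' @return data.frame of matching rows
#' @export
query_motifs <- function(store, motif_class = NULL, size = NULL) {
  rows <- store$rows
  if (!is.null(motif_class)) rows <- rows[rows$motif_class %in% motif_class, ]
  if (!is.null(size)) rows <- rows[rows$size %in% size, ]
  rownames(rows) <- NULL
  rows
}

#' Persist / restore a motif store
#'
#' @param store a `motif_store`
#' @param path file path for the single-file store
#' @export
save_store <- function(store, path) {
  jsonlite::write_json(
    list(schema_version = store$schema_version, next_id = store$next_id,
         rows = store$rows),
    path, dataframe = "columns", auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  store <- motif_store()
  if (length(p$rows) > 0L && length(p$rows$motif_id) > 0L) {
    rows <- as.data.frame(p$rows, stringsAsFactors = FALSE)
    rows$motif_id <- as.integer(rows$motif_id)
    rows$size <- as.integer(rows$size)
    rows$n_members <- as.integer(rows$n_members)
    store$rows <- rows
  }
  store$next_id <- as.integer(p$next_id)
  store$schema_version <- as.integer(p$schema_version)
  store
}

#' Export motif rows as CSV
#'
#' Column contract, in this order: `ID`, `motif type`, `PDB ID`,
#' `nucleotide number` (the motif size, i.e. unpaired nucleotide count).
#'
#' @param rows data.frame from [query_motifs()]
#' @param path optional file to write
#' @return the CSV text lines
#' @export
export_csv <- function(rows, path = NULL) {
  header <- "ID,motif type,PDB ID,nucleotide number"
  body <- if (nrow(rows) == 0L) character() else {
    sprintf("%d,%s,%s,%d", rows$motif_id, rows$motif_class, rows$pdb_id,
            rows$size)
  }
  lines <- c(header, body)
  if (!is.null(path)) writeLines(lines, path)
  lines
}

# --- minimal ZIP (method STORE) writer -------------------------------------

crc32 <- function(bytes) {
  # table-driven CRC-32 (IEEE 802.3) on a raw vector, done in double
  # arithmetic to dodge R's signed 32-bit integers
  tab <- get_crc_table()
  crc <- 4294967295
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(as.integer(crc %% 256), 255L)
    idx <- bitwXor(idx, b) + 1L
    crc <- floor(crc / 256) %% 16777216
    crc <- bitwXor64(crc, tab[[idx]])
  }
  bitwXor64(crc, 4294967295)
}

bitwXor64 <- function(x, y) {
  # xor of two non-negative doubles < 2^32
  hi <- bitwXor(as.integer(x %/% 65536), as.integer(y %/% 65536))
  lo <- bitwXor(as.integer(x %% 65536), as.integer(y %% 65536))
  (hi %% 65536) * 65536 + (lo %% 65536)
}

crc_tab_env <- new.env(parent = emptyenv())
get_crc_table <- function() {
  if (is.null(crc_tab_env$tab)) {
    tab <- numeric(256)
    for (n in 0:255) {
      c <- as.numeric(n)
      for (k in 1:8) {
        odd <- c %% 2 == 1
        c <- floor(c / 2)
        if (odd) c <- bitwXor64(c, 3988292384)  # 0xEDB88320
      }
      tab[[n + 1L]] <- c
    }
    crc_tab_env$tab <- tab
  }
  crc_tab_env$tab
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) {
  c(u16(x %% 65536), u16(x %/% 65536))
}
u16r <- function(x) u16(x)

zip_write <- function(path, names, contents) {
  stopifnot(length(names) == length(contents))
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(names))
  central <- raw()
  offset <- 0
  locals <- raw()
  for (i in seq_along(names)) {
    data <- if (is.raw(contents[[i]])) contents[[i]] else
      charToRaw(paste0(paste(contents[[i]], collapse = "\n"), "\n"))
    nm <- charToRaw(names[[i]])
    crc <- crc32(data)
    local <- c(u32(67324752),            # local file header signature
               u16(20), u16(0), u16(0),  # version, flags, method STORE
               u16(0), u16(0),           # mod time/date
               u32(crc), u32(length(data)), u32(length(data)),
               u16(length(nm)), u16(0), nm, data)
    offsets[[i]] <- offset
    offset <- offset + length(local)
    locals <- c(locals, local)
    central <- c(central,
                 u32(33639248), u16(20), u16(20), u16(0), u16(0),
                 u16(0), u16(0), u32(crc), u32(length(data)),
                 u32(length(data)), u16(length(nm)), u16(0), u16(0),
                 u16(0), u16(0), u32(0), u32(offsets[[i]]), nm)
  }
  eocd <- c(u32(101010256), u16(0), u16(0), u16(length(names)),
            u16(length(names)), u32(length(central)), u32(offset), u16(0))
  writeBin(c(locals, central, eocd), con)
  invisible(path)
}

#' Export motif coordinates as a ZIP archive
#'
#' One `"<motif_id>.pdb"` entry per row (method STORE). Rows without stored
#' coordinates are skipped with a warning. Zero rows produce a valid empty
#' archive.
#'
#' @param rows data.frame from [query_motifs()]
#' @param path output `.zip` path
#' @return `path`, invisibly
#' @export
export_zip <- function(rows, path) {
  has <- !is.na(rows$pdb_text)
  if (any(!has)) warning(sum(!has), " motif(s) without stored coordinates skipped")
  rows <- rows[has, , drop = FALSE]
  if (nrow(rows) == 0L) return(zip_write(path, character(), list()))
  zip_write(path, paste0(rows$motif_id, ".pdb"), as.list(rows$pdb_text))
}

# --- conformation classification (graph-topology uniqueness) ----------------

edge_attr_str <- function(e) paste(e$cov, e$wc, e$nonwc, sep = "")

refine_labels <- function(g, max_rounds = nrow(g$nodes)) {
  n <- nrow(g$nodes)
  e <- g$edges
  attr <- edge_attr_str(e)
  inc <- rep(list(character()), n)
  nb <- rep(list(integer()), n)
  for (r in seq_len(nrow(e))) {
    inc[[e$a[[r]]]] <- c(inc[[e$a[[r]]]], attr[[r]])
    inc[[e$b[[r]]]] <- c(inc[[e$b[[r]]]], attr[[r]])
    nb[[e$a[[r]]]] <- c(nb[[e$a[[r]]]], e$b[[r]])
    nb[[e$b[[r]]]] <- c(nb[[e$b[[r]]]], e$a[[r]])
  }
  eattr_of <- function(a, b) {
    attr[[which((e$a == pmin(a, b)) & (e$b == pmax(a, b)))[[1L]]]]
  }
  lab <- vapply(inc, function(x) paste(sort(x), collapse = "|"), character(1))
  lab <- as.integer(factor(lab, levels = sort(unique(lab))))
  for (round in seq_len(max_rounds)) {
    sig <- vapply(seq_len(n), function(v) {
      ne <- nb[[v]]
      msg <- sort(vapply(ne, function(w) paste0(lab[[w]], ":", eattr_of(v, w)),
                         character(1)))
      paste(lab[[v]], paste(msg, collapse = "|"))
    }, character(1))
    new <- as.integer(factor(sig, levels = sort(unique(sig))))
    if (length(unique(new)) == length(unique(lab))) { lab <- new; break }
    lab <- new
  }
  lab
}

graph_signature <- function(g) {
  lab <- refine_labels(g)
  e <- g$edges
  paste(nrow(g$nodes),
        paste(sort(lab), collapse = ","),
        paste(sort(paste0(pmin(lab[e$a], lab[e$b]), "-",
                          pmax(lab[e$a], lab[e$b]), ":", edge_attr_str(e))),
              collapse = ","),
        sep = ";")
}

graphs_isomorphic_attr <- function(g1, g2) {
  # exact attribute-preserving isomorphism by backtracking, refinement-pruned
  n <- nrow(g1$nodes)
  if (n != nrow(g2$nodes) || nrow(g1$edges) != nrow(g2$edges)) return(FALSE)
  l1 <- refine_labels(g1); l2 <- refine_labels(g2)
  if (!identical(sort(l1), sort(l2))) return(FALSE)
  adj_of <- function(g) {
    m <- matrix("", n, n)
    e <- g$edges
    a <- edge_attr_str(e)
    for (r in seq_len(nrow(e))) {
      m[e$a[[r]], e$b[[r]]] <- a[[r]]
      m[e$b[[r]], e$a[[r]]] <- a[[r]]
    }
    m
  }
  m1 <- adj_of(g1); m2 <- adj_of(g2)
  mapping <- rep(NA_integer_, n)
  used <- logical(n)
  bt <- function(v) {
    if (v > n) return(TRUE)
    for (w in which(l2 == l1[[v]])) {
      if (used[[w]]) next
      ok <- TRUE
      for (u in seq_len(v - 1L)) {
        if (m1[v, u] != m2[w, mapping[[u]]]) { ok <- FALSE; break }
      }
      if (ok) {
        mapping[[v]] <<- w; used[[w]] <<- TRUE
        if (bt(v + 1L)) return(TRUE)
        used[[w]] <<- FALSE; mapping[[v]] <<- NA_integer_
      }
    }
    FALSE
  }
  bt(1L)
}

canonical_key <- function(g, perm_cap = 5000L) {
  # lexicographically minimal adjacency serialization over orderings
  # compatible with the refinement partition; falls back to the refinement
  # signature when the cell permutation count exceeds perm_cap
  n <- nrow(g$nodes)
  lab <- refine_labels(g)
  cells <- split(seq_len(n), lab)
  n_perm <- prod(vapply(cells, function(cl) factorial(length(cl)), 1))
  sig <- graph_signature(g)
  if (!is.finite(n_perm) || n_perm > perm_cap) return(sig)
  e <- g$edges
  a <- edge_attr_str(e)
  serialize <- function(ord) {
    pos <- integer(n); pos[ord] <- seq_len(n)
    paste(sort(paste0(pmin(pos[e$a], pos[e$b]), "-",
                      pmax(pos[e$a], pos[e$b]), ":", a)), collapse = ",")
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[[i]], p)
    }
    out
  }
  cell_perms <- lapply(cells, perms)
  best <- NULL
  idx <- rep(1L, length(cells))
  repeat {
    ord <- unlist(lapply(seq_along(cells), function(k) cell_perms[[k]][[idx[[k]]]]))
    ser <- serialize(ord)
    if (is.null(best) || ser < best) best <- ser
    k <- length(cells)
    while (k >= 1L) {
      idx[[k]] <- idx[[k]] + 1L
      if (idx[[k]] <= length(cell_perms[[k]])) break
      idx[[k]] <- 1L; k <- k - 1L
    }
    if (k < 1L) break
  }
  paste0(sig, "#", best)
}

#' Classify stored motifs into conformation classes
#'
#' Fetches motifs of the given class and size and partitions their graphs
#' (with non-WC edges by default: non-WC interactions are what makes
#' conformations of one WC-defined motif distinct) into
#' attribute-isomorphism classes. Frequencies sum to the number fetched;
#' output is sorted by frequency descending, ties by canonical key. The
#' partition is independent of insertion order.
#'
#' @param store a `motif_store`
#' @param motif_class motif class to fetch
#' @param size motif size to fetch
#' @param use_nonwc classify on the with-non-WC view (default) or WC-only
#' @return data.frame with `canonical_key`, `frequency`, `representative`
#'   (graph JSON of the first member in canonical-key order)
#' @export
classify_conformations <- function(store, motif_class, size,
                                   use_nonwc = TRUE) {
  rows <- query_motifs(store, motif_class, size)
  if (nrow(rows) == 0L) {
    return(data.frame(canonical_key = character(), frequency = integer(),
                      representative = character(), stringsAsFactors = FALSE))
  }
  col <- if (use_nonwc) "graph_with_nonwc" else "graph_without_nonwc"
  graphs <- lapply(rows[[col]], graph_from_json)
  keys <- vapply(graphs, canonical_key, character(1))
  classes <- list()
  for (i in order(keys)) {
    placed <- FALSE
    for (k in seq_along(classes)) {
      cl <- classes[[k]]
      if (keys[[i]] == cl$key &&
          graphs_isomorphic_attr(graphs[[i]], cl$graph)) {
        classes[[k]]$freq <- cl$freq + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      classes[[length(classes) + 1L]] <-
        list(key = keys[[i]], graph = graphs[[i]], freq = 1L,
             json = rows[[col]][[i]])
    }
  }
  out <- data.frame(
    canonical_key = vapply(classes, `[[`, character(1), "key"),
    frequency = vapply(classes, `[[`, integer(1), "freq"),
    representative = vapply(classes, `[[`, character(1), "json"),
    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$canonical_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif class shares and size histograms
#'
#' @param store a `motif_store`
#' @return list with `shares` (class, count, share_pct summing to 100) and
#'   `histograms` (per class, a table of size counts)
#' @export
motif_distributions <- function(store) {
  rows <- store$rows
  if (nrow(rows) == 0L) {
    return(list(shares = data.frame(motif_class = character(),
                                    count = integer(), share_pct = numeric()),
                histograms = list()))
  }
  tab <- table(rows$motif_class)
  shares <- data.frame(motif_class = names(tab),
                       count = as.integer(tab),
                       share_pct = 100 * as.integer(tab) / nrow(rows),
                       stringsAsFactors = FALSE)
  shares <- shares[order(-shares$count), , drop = FALSE]
  rownames(shares) <- NULL
  hists <- lapply(split(rows$size, rows$motif_class), table)
  list(shares = shares, histograms = hists)
}
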