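#' @useDynLib rnamotifs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef quantile sd wilcox.test rnorm runif setNames
#' @importFrom utils head tail
NULL

CHAIN_ALPHABET <- c(LETTERS, letters, as.character(0:9))
RNA_BASES <- c("A", "U", "G", "C")

#' Residue key
#'
#' Residues are identified throughout the package by the author chain id,
#' author residue number and insertion code, concatenated as e.g. `"A12"` or
#' `"A12a"`. Motif membership and sizes are always computed on keys, never on
#' coordinates.
#'
#' @param chain single-character chain id
#' @param resno integer author residue number
#' @param icode insertion code, `""` if absent
#' @return character key
#' @export
res_key <- function(chain, resno, icode = "") {
  paste0(chain, resno, icode)
}

new_rna_structure <- function(structure_id, residues, atoms, source_format,
                              model_used = 1L, chain_remap = character()) {
  residues$key <- res_key(residues$chain, residues$resno, residues$icode)
  if (anyDuplicated(residues$key)) {
    stop("duplicate residue keys: ",
         paste(residues$key[duplicated(residues$key)], collapse = ", "))
  }
  structure(
    list(structure_id = structure_id, residues = residues, atoms = atoms,
         source_format = source_format, model_used = model_used,
         chain_remap = chain_remap),
    class = "rna_structure"
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  ch <- unique(x$residues$chain)
  cat(sprintf("RNA structure '%s' (%s, model %d): %d chain(s), %d residues, %d atoms\n",
              x$structure_id, x$source_format, x$model_used,
              length(ch), nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

structure_chains <- function(s) unique(s$residues$chain)

normalize_base <- function(resname) {
  b <- toupper(trimws(resname))
  ifelse(b %in% RNA_BASES, b, "OTHER")
}

# Deterministic remap of chain identifiers: any id longer than one character
# (or colliding after truncation) takes the first unused symbol from A-Z, a-z,
# 0-9 in encounter order.
remap_chains <- function(chain_ids) {
  seen <- unique(chain_ids)
  ok <- nchar(seen) == 1L
  used <- seen[ok]
  map <- setNames(seen, seen)
  for (cid in seen[!ok]) {
    free <- setdiff(CHAIN_ALPHABET, used)
    if (length(free) == 0L) {
      stop("chain capacity exceeded: more than ", length(CHAIN_ALPHABET),
           " chains after normalization")
    }
    map[[cid]] <- free[[1L]]
    used <- c(used, free[[1L]])
  }
  if (length(unique(map)) > length(CHAIN_ALPHABET)) {
    stop("chain capacity exceeded")
  }
  map
}

parse_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  out <- vector("list", length(lines))
  model <- 1L
  n_models <- 1L
  keep <- rep(TRUE, length(lines))
  for (i in seq_along(lines)) {
    r <- trimws(rec[[i]])
    if (r == "MODEL") {
      mn <- suppressWarnings(as.integer(trimws(substr(lines[[i]], 7, 80))))
      if (!is.na(mn)) model <- mn
      n_models <- max(n_models, model)
    } else if (r == "ENDMDL") {
      model <- model + 1L
    }
    keep[[i]] <- r %in% c("ATOM", "HETATM") && model == 1L
  }
  atom_lines <- lines[keep]
  atom_idx <- which(keep)
  if (length(atom_lines) == 0L) {
    return(list(atoms = empty_atom_df(), multi_model = n_models > 1L))
  }
  fixed <- function(l, a, b) substr(l, a, b)
  name <- trimws(fixed(atom_lines, 13, 16))
  resname <- trimws(fixed(atom_lines, 18, 20))
  chain <- trimws(fixed(atom_lines, 21, 22))
  resno <- suppressWarnings(as.integer(trimws(fixed(atom_lines, 23, 26))))
  icode <- trimws(fixed(atom_lines, 27, 27))
  x <- suppressWarnings(as.numeric(fixed(atom_lines, 31, 38)))
  y <- suppressWarnings(as.numeric(fixed(atom_lines, 39, 46)))
  z <- suppressWarnings(as.numeric(fixed(atom_lines, 47, 54)))
  bad <- is.na(x) | is.na(y) | is.na(z) | is.na(resno) | name == ""
  if (any(bad)) {
    # Atom-serial overflow dialect: serials >= 100000 widen the serial field
    # and shift the record right; fall back to whitespace tokenization.
    for (j in which(bad)) {
      tok <- strsplit(trimws(atom_lines[[j]]), "\\s+")[[1L]]
      if (length(tok) < 9L) {
        stop("unreadable PDB record at line ", atom_idx[[j]], ": ",
             atom_lines[[j]])
      }
      name[[j]] <- tok[[3L]]
      resname[[j]] <- tok[[4L]]
      chain[[j]] <- tok[[5L]]
      resno[[j]] <- suppressWarnings(as.integer(tok[[6L]]))
      icode[[j]] <- ""
      x[[j]] <- suppressWarnings(as.numeric(tok[[7L]]))
      y[[j]] <- suppressWarnings(as.numeric(tok[[8L]]))
      z[[j]] <- suppressWarnings(as.numeric(tok[[9L]]))
      if (is.na(x[[j]]) || is.na(y[[j]]) || is.na(z[[j]]) || is.na(resno[[j]])) {
        stop("unreadable PDB record at line ", atom_idx[[j]], ": ",
             atom_lines[[j]])
      }
    }
  }
  list(atoms = data.frame(chain = chain, resno = resno, icode = icode,
                          resname = resname, atom = name,
                          x = x, y = y, z = z, stringsAsFactors = FALSE),
       multi_model = n_models > 1L)
}

empty_atom_df <- function() {
  data.frame(chain = character(), resno = integer(), icode = character(),
             resname = character(), atom = character(),
             x = numeric(), y = numeric(), z = numeric(),
             stringsAsFactors = FALSE)
}

parse_cif_atoms <- function(lines) {
  # Minimal atom_site loop reader: header tags then whitespace-separated rows.
  tag_idx <- grep("^_atom_site\\.", lines)
  if (length(tag_idx) == 0L) stop("unreadable mmCIF: no _atom_site loop found")
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  start <- max(tag_idx) + 1L
  rows <- character()
  for (i in start:length(lines)) {
    l <- trimws(lines[[i]])
    if (l == "" || startsWith(l, "#") || startsWith(l, "loop_") ||
        startsWith(l, "_")) break
    rows <- c(rows, l)
  }
  if (length(rows) == 0L) stop("unreadable mmCIF: empty _atom_site loop")
  tok <- strsplit(rows, "\\s+")
  bad <- which(vapply(tok, length, 1L) != length(tags))
  if (length(bad) > 0L) {
    stop("unreadable mmCIF record at line ", start + bad[[1L]] - 1L)
  }
  m <- do.call(rbind, tok)
  colnames(m) <- tags
  get <- function(a, b = NULL) {
    if (a %in% tags) m[, a]
    else if (!is.null(b) && b %in% tags) m[, b]
    else rep(NA_character_, nrow(m))
  }
  model <- get("pdbx_PDB_model_num")
  if (!all(is.na(model))) {
    first <- model[[1L]]
    sel <- model == first
  } else sel <- rep(TRUE, nrow(m))
  icode <- get("pdbx_PDB_ins_code")
  icode[is.na(icode) | icode %in% c("?", ".")] <- ""
  atoms <- data.frame(
    chain = get("auth_asym_id", "label_asym_id"),
    resno = as.integer(get("auth_seq_id", "label_seq_id")),
    icode = icode,
    resname = get("auth_comp_id", "label_comp_id"),
    atom = get("auth_atom_id", "label_atom_id"),
    x = as.numeric(get("Cartn_x")),
    y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    stringsAsFactors = FALSE
  )[sel, , drop = FALSE]
  if (anyNA(atoms$x) || anyNA(atoms$resno)) stop("unreadable mmCIF coordinates")
  list(atoms = atoms,
       multi_model = length(unique(model[!is.na(model)])) > 1L)
}

#' Read an RNA structure from PDB or mmCIF
#'
#' Normalizations applied: only the first model of multi-model (NMR-style)
#' files is retained; chain identifiers longer than one character are remapped
#' deterministically to the first unused symbol in `A-Z a-z 0-9` (encounter
#' order); atom serial overflow records (serial >= 100000) are accepted and all
#' atoms are re-sequenced from 1.
#'
#' @param path file path, or a character vector of lines via `text`
#' @param format `"PDB"`, `"mmCIF"` or `"auto"` (by file extension)
#' @param text optional character vector of file lines (overrides `path`)
#' @param structure_id id recorded on the structure; defaults to the file stem
#' @return an `rna_structure` with residues in file order; the applied chain
#'   remap table is in `$chain_remap`
#' @export
read_structure <- function(path = NULL, format = c("auto", "PDB", "mmCIF"),
                           text = NULL, structure_id = NULL) {
  format <- match.arg(format)
  if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path)
    text <- readLines(path, warn = FALSE)
    if (is.null(structure_id)) {
      structure_id <- sub("\\.(pdb|cif|mmcif|ent)$", "",
                          basename(path), ignore.case = TRUE)
    }
  }
  if (is.null(structure_id)) structure_id <- "UNKNOWN"
  if (format == "auto") {
    format <- if (!is.null(path) && grepl("\\.(cif|mmcif)$", path,
                                          ignore.case = TRUE)) "mmCIF"
              else if (any(grepl("^_atom_site\\.", text))) "mmCIF"
              else "PDB"
  }
  parsed <- if (format == "PDB") parse_pdb_lines(text) else parse_cif_atoms(text)
  atoms <- parsed$atoms
  map <- remap_chains(atoms$chain)
  atoms$chain <- unname(map[atoms$chain])
  if (anyDuplicated(unname(map))) stop("chain id collision after remap")
  rid <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  first <- !duplicated(rid)
  residues <- data.frame(chain = atoms$chain[first],
                         resno = atoms$resno[first],
                         icode = atoms$icode[first],
                         base = normalize_base(atoms$resname[first]),
                         stringsAsFactors = FALSE)
  remap <- map[names(map) != unname(map)]
  new_rna_structure(structure_id, residues, atoms, format,
                    model_used = 1L, chain_remap = remap)
}

#' Keep only RNA chains
#'
#' A chain qualifies when it contains at least one residue with base A, U, G
#' or C; modified (`OTHER`) residues inside qualifying chains are retained.
#' Idempotent; the result may have zero chains.
#'
#' @param s an `rna_structure`
#' @return filtered `rna_structure`
#' @export
filter_rna_chains <- function(s) {
  keep_chain <- vapply(structure_chains(s), function(ch) {
    any(s$residues$base[s$residues$chain == ch] %in% RNA_BASES)
  }, logical(1))
  chains <- structure_chains(s)[keep_chain]
  s$residues <- s$residues[s$residues$chain %in% chains, , drop = FALSE]
  s$atoms <- s$atoms[s$atoms$chain %in% chains, , drop = FALSE]
  rownames(s$residues) <- rownames(s$atoms) <- NULL
  s
}

new_interaction_set <- function(df) {
  if (nrow(df) > 0) {
    stopifnot(all(df$key_a != df$key_b))
    df <- df[order(df$key_a, df$key_b), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(list(interactions = df), class = "interaction_set")
}

empty_interactions <- function() {
  data.frame(key_a = character(), key_b = character(),
             cov = integer(), wc = integer(), nonwc = integer(),
             stringsAsFactors = FALSE)
}

backbone_interactions <- function(s) {
  res <- s$residues
  out <- empty_interactions()
  for (ch in structure_chains(s)) {
    k <- res$key[res$chain == ch]
    if (length(k) > 1L) {
      out <- rbind(out, data.frame(key_a = k[-length(k)], key_b = k[-1L],
                                   cov = 1L, wc = 0L, nonwc = 0L,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

merge_interactions <- function(df) {
  if (nrow(df) == 0L) return(df)
  swap <- df$key_a > df$key_b
  tmp <- df$key_a[swap]; df$key_a[swap] <- df$key_b[swap]; df$key_b[swap] <- tmp
  id <- paste(df$key_a, df$key_b, sep = "\r")
  agg <- function(v) as.integer(tapply(v, id, max))
  u <- !duplicated(id)
  out <- data.frame(key_a = df$key_a[u], key_b = df$key_b[u],
                    stringsAsFactors = FALSE)
  ord <- match(unique(id), sort(unique(id)))
  out$cov <- agg(df$cov)[ord]; out$wc <- agg(df$wc)[ord]
  out$nonwc <- agg(df$nonwc)[ord]
  out
}

#' Parse a base-pair annotation text
#'
#' One pair per line in the dialect
#' `"<chain><number>[icode]-<chain><number>[icode] : <WC|NONWC>"`, e.g.
#' `"A1-A8 : WC"`. The same residue pair may appear on several lines with
#' different types; the resulting interaction then carries the union of types.
#' Covalent interactions between chain-adjacent residues are always added,
#' regardless of the pairing lines. This is the adapter seam for external
#' annotation tools: convert their output to this dialect and feed it here.
#'
#' @param text annotation text (single string or character vector of lines)
#' @param s the annotated `rna_structure`; every referenced key must resolve
#' @return an `interaction_set`
#' @export
read_annotation <- function(text, s) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  pat <- "^([A-Za-z0-9])(-?[0-9]+)([A-Za-z]?)-([A-Za-z0-9])(-?[0-9]+)([A-Za-z]?)\\s*:\\s*(WC|NONWC)$"
  df <- empty_interactions()
  for (l in lines) {
    m <- regmatches(l, regexec(pat, l))[[1L]]
    if (length(m) == 0L) stop("unparseable annotation line: '", l, "'")
    ka <- res_key(m[[2L]], as.integer(m[[3L]]), m[[4L]])
    kb <- res_key(m[[5L]], as.integer(m[[6L]]), m[[7L]])
    for (k in c(ka, kb)) {
      if (!k %in% s$residues$key) {
        stop("annotation references unknown residue key '", k, "'")
      }
    }
    if (ka == kb) stop("self-interaction in annotation: '", l, "'")
    df <- rbind(df, data.frame(key_a = ka, key_b = kb,
                               cov = 0L,
                               wc = as.integer(m[[8L]] == "WC"),
                               nonwc = as.integer(m[[8L]] == "NONWC"),
                               stringsAsFactors = FALSE))
  }
  new_interaction_set(merge_interactions(rbind(df, backbone_interactions(s))))
}

c1_coords <- function(s) {
  a <- s$atoms[s$atoms$atom == "C1'", , drop = FALSE]
  key <- res_key(a$chain, a$resno, a$icode)
  a <- a[!duplicated(key), , drop = FALSE]
  rownames(a) <- NULL
  a$key <- key[!duplicated(key)]
  a
}

complementary <- function(b1, b2) {
  paste0(b1, b2) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

#' Fixture-grade geometric base-pair annotation
#'
#' Emits a WC interaction for complementary bases (A-U, G-C, G-U) whose
#' C1'-C1' distance falls in \[8.5, 12.0\] angstrom, assigning greedily by
#' increasing distance so each residue joins at most one WC pair, plus the
#' covalent backbone. Never emits non-WC interactions. This is a schematic
#' annotator for generated fixtures, not a production base-pair caller: it
#' knows nothing about base planes, edges or glycosidic orientation.
#'
#' @param s an `rna_structure` whose residues carry C1' atoms
#' @param d_min,d_max distance window in angstrom
#' @return an `interaction_set`
#' @export
naive_annotate <- function(s, d_min = 8.5, d_max = 12.0) {
  c1 <- c1_coords(s)
  missing <- setdiff(s$residues$key, c1$key)
  if (length(missing) > 0L) {
    warning("residues without C1' skipped: ", paste(missing, collapse = ", "))
  }
  base <- s$residues$base[match(c1$key, s$residues$key)]
  n <- nrow(c1)
  cand <- NULL
  if (n > 1L) {
    xyz <- as.matrix(c1[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    idx <- which(upper.tri(d) & d >= d_min & d <= d_max, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      comp <- complementary(base[idx[, 1L]], base[idx[, 2L]])
      idx <- idx[comp, , drop = FALSE]
      if (nrow(idx) > 0L) {
        cand <- data.frame(i = idx[, 1L], j = idx[, 2L],
                           d = d[idx])
        cand <- cand[order(cand$d), , drop = FALSE]
      }
    }
  }
  used <- rep(FALSE, n)
  df <- empty_interactions()
  if (!is.null(cand)) {
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[[r]]; j <- cand$j[[r]]
      if (!used[[i]] && !used[[j]]) {
        used[[i]] <- used[[j]] <- TRUE
        df <- rbind(df, data.frame(key_a = c1$key[[i]], key_b = c1$key[[j]],
                                   cov = 0L, wc = 1L, nonwc = 0L,
                                   stringsAsFactors = FALSE))
      }
    }
  }
  new_interaction_set(merge_interactions(rbind(df, backbone_interactions(s))))
}

format_pdb_atom <- function(serial, name, resname, chain, resno, icode, x, y, z) {
  nm <- if (nchar(name) < 4L) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00",
          serial %% 100000L, substr(nm, 1, 4), substr(resname, 1, 3),
          chain, resno, ifelse(icode == "", " ", icode), x, y, z)
}

#' Write selected residues as PDB text
#'
#' Emits ATOM records for exactly the member residues (in structure order),
#' keeping original chain/residue identifiers and re-numbering atom serials
#' from 1. An empty member list produces a header-only file with a warning.
#'
#' @param s an `rna_structure`
#' @param members character vector of residue keys; default all residues
#' @param path optional file to write
#' @return the PDB text lines, invisibly when `path` is given
#' @export
write_motif_pdb <- function(s, members = s$residues$key, path = NULL) {
  unknown <- setdiff(members, s$residues$key)
  if (length(unknown) > 0L) {
    stop("unknown member residue key(s): ", paste(unknown, collapse = ", "))
  }
  akey <- res_key(s$atoms$chain, s$atoms$resno, s$atoms$icode)
  sel <- s$atoms[akey %in% members, , drop = FALSE]
  header <- sprintf("REMARK   1 %s residues=%d", s$structure_id, length(members))
  if (length(members) == 0L) {
    warning("empty member list: writing header-only PDB")
    lines <- c(header, "END")
  } else {
    body <- vapply(seq_len(nrow(sel)), function(i) {
      format_pdb_atom(i, sel$atom[[i]], sel$resname[[i]], sel$chain[[i]],
                      sel$resno[[i]], sel$icode[[i]],
                      sel$x[[i]], sel$y[[i]], sel$z[[i]])
    }, character(1))
    lines <- c(header, body, "END")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
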