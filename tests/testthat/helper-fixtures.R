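# Programmatic text fixtures (built in code; nothing stored on disk).

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          icode = "") {
  nm <- if (nchar(name) < 4L) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00",
          serial, substr(nm, 1, 4), resname, chain, resno,
          ifelse(icode == "", " ", icode), x, y, z)
}

# one C1' atom per residue
pdb_chain_lines <- function(chain, bases, start_serial = 1L, resno = NULL,
                            y = 0) {
  if (is.null(resno)) resno <- seq_along(bases)
  vapply(seq_along(bases), function(i) {
    pdb_atom_line(start_serial + i - 1L, "C1'", bases[[i]], chain,
                  resno[[i]], 4 * i, y, 0)
  }, character(1))
}

fixture_simple_pdb <- function() {
  c(pdb_chain_lines("A", c("A", "U", "G")), "END")
}

fixture_nmr_pdb <- function() {
  c("MODEL     1",
    pdb_chain_lines("A", c("A", "U", "G", "C")),
    "ENDMDL",
    "MODEL     2",
    pdb_chain_lines("A", c("A", "U", "G", "C"), y = 50),
    "ENDMDL",
    "END")
}

fixture_overflow_pdb <- function() {
  # serial numbers >= 100000 widen the field (overflow dialect)
  l1 <- pdb_chain_lines("A", c("A", "U"))
  l2 <- sub("^ATOM  [ 0-9]{5}", "ATOM  100000", pdb_atom_line(
    99999, "C1'", "G", "A", 3L, 12, 0, 0))
  c(l1, l2, "END")
}

fixture_rna_protein_pdb <- function() {
  c(pdb_chain_lines("A", c("A", "U", "G", "C")),
    pdb_chain_lines("B", c("ALA", "GLY", "SER"), start_serial = 5L, y = 30),
    "END")
}

fixture_mmcif_two_letter <- function() {
  header <- c("data_test", "#", "loop_",
              paste0("_atom_site.", c("group_PDB", "id", "auth_atom_id",
                                      "auth_comp_id", "auth_asym_id",
                                      "auth_seq_id", "Cartn_x", "Cartn_y",
                                      "Cartn_z", "pdbx_PDB_model_num")))
  row <- function(id, atom, comp, asym, seq, x) {
    sprintf("ATOM %d %s %s %s %d %.3f 0.000 0.000 1", id, atom, comp, asym,
            seq, x)
  }
  c(header,
    row(1, "C1'", "A", "A", 1, 1),
    row(2, "C1'", "U", "A", 2, 5),
    row(3, "C1'", "G", "AB", 1, 40),
    row(4, "C1'", "C", "AB", 2, 44),
    "#")
}

# graph built directly from explicit WC pairs on an n-mer single chain
graph_from_pairs <- function(n, wc = NULL, nonwc = NULL, seq = NULL) {
  db <- rep(".", n)
  g <- from_dot_bracket(paste(db, collapse = ""), seq = seq)
  edges <- g$edges
  if (!is.null(wc)) {
    edges <- rbind(edges, data.frame(a = wc[, 1], b = wc[, 2], cov = 0L,
                                     wc = 1L, nonwc = 0L))
  }
  if (!is.null(nonwc)) {
    edges <- rbind(edges, data.frame(a = nonwc[, 1], b = nonwc[, 2],
                                     cov = 0L, wc = 0L, nonwc = 1L))
  }
  rna_graph(g$nodes, edges)
}

match_signature <- function(ms) {
  inventory_signature(lapply(ms, function(m) {
    list(motif_class = m$motif_class, size = m$size, members = m$members)
  }))
}

# independent crossing-pair check: does the WC pair set contain (i,k,j,l)
# with i < k < j < l?
has_crossing_pairs <- function(g) {
  e <- without_nonwc(g)$edges
  wc <- e[e$wc == 1L, , drop = FALSE]
  if (nrow(wc) < 2L) return(FALSE)
  for (r in seq_len(nrow(wc) - 1L)) {
    for (q in (r + 1L):nrow(wc)) {
      i <- wc$a[r]; j <- wc$b[r]; k <- wc$a[q]; l <- wc$b[q]
      if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

random_relabel <- function(g) {
  # random node permutation preserving structure (keys regenerated)
  n <- nrow(g$nodes)
  perm <- sample.int(n)
  nodes <- g$nodes[order(perm), , drop = FALSE]
  rownames(nodes) <- NULL
  pos <- integer(n); pos[order(perm)] <- seq_len(n)
  e <- g$edges
  e$a <- pos[e$a]; e$b <- pos[e$b]
  rna_graph(nodes, e)
}
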