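test_that("PDB parsing keeps file order and identity on a simple chain", {
  s <- read_structure(text = fixture_simple_pdb(), format = "PDB",
                      structure_id = "FX1")
  expect_s3_class(s, "rna_structure")
  expect_equal(nrow(s$residues), 3L)
  expect_equal(s$residues$base, c("A", "U", "G"))
  expect_equal(unique(s$residues$chain), "A")
})

test_that("only the first model of a multi-model file is retained", {
  s <- read_structure(text = fixture_nmr_pdb(), format = "PDB")
  expect_equal(s$model_used, 1L)
  expect_equal(nrow(s$residues), 4L)
  # model-1 coordinates (y = 0), not model-2 (y = 50)
  expect_true(all(s$atoms$y == 0))
})

test_that("two-letter chain ids remap to the first unused symbol", {
  s <- read_structure(text = fixture_mmcif_two_letter(), format = "mmCIF")
  expect_setequal(unique(s$residues$chain), c("A", "B"))
  expect_equal(unname(s$chain_remap["AB"]), "B")
  expect_true(all(nchar(s$residues$chain) == 1L))
})

test_that("atom serial overflow records are accepted and re-sequenced", {
  s <- read_structure(text = fixture_overflow_pdb(), format = "PDB")
  expect_equal(nrow(s$residues), 3L)
  expect_equal(s$residues$resno, 1:3)
  out <- write_motif_pdb(s)
  serials <- as.integer(substr(grep("^ATOM", out, value = TRUE), 7, 11))
  expect_equal(serials, 1:3)
})

test_that("unreadable records raise errors naming the line", {
  bad <- c(pdb_chain_lines("A", "A"), "ATOM  garbage", "END")
  expect_error(read_structure(text = bad, format = "PDB"), "line")
})

test_that("RNA-chain filter keeps ribonucleotide chains and is idempotent", {
  prot <- read_structure(text = c(pdb_chain_lines("B", c("ALA", "GLY")),
                                  "END"), format = "PDB")
  expect_equal(nrow(filter_rna_chains(prot)$residues), 0L)

  mix <- read_structure(text = fixture_rna_protein_pdb(), format = "PDB")
  f <- filter_rna_chains(mix)
  expect_equal(unique(f$residues$chain), "A")
  expect_equal(nrow(f$residues), 4L)
  expect_identical(filter_rna_chains(f)$residues, f$residues)

  # modified residues are retained inside qualifying chains
  modi <- read_structure(text = c(pdb_chain_lines("A", c("A", "PSU", "G")),
                                  "END"), format = "PDB")
  fm <- filter_rna_chains(modi)
  expect_equal(nrow(fm$residues), 3L)
  expect_equal(fm$residues$base, c("A", "OTHER", "G"))
})

test_that("annotation dialect parses pairs and always adds the backbone", {
  s <- read_structure(text = c(pdb_chain_lines("A", rep("A", 8)), "END"),
                      format = "PDB")
  ia <- read_annotation("A1-A8 : WC", s)
  df <- ia$interactions
  expect_equal(sum(df$cov), 7L)
  expect_equal(sum(df$wc), 1L)
  wcrow <- df[df$wc == 1L, ]
  expect_setequal(c(wcrow$key_a, wcrow$key_b), c("A1", "A8"))

  # empty annotation: backbone only
  ia0 <- read_annotation("", s)
  expect_equal(nrow(ia0$interactions), 7L)
  expect_true(all(ia0$interactions$cov == 1L))

  # multiple types on one pair merge into one multi-type interaction
  ia2 <- read_annotation(c("A2-A7 : WC", "A2-A7 : NONWC"), s)
  df2 <- ia2$interactions
  both <- df2[df2$wc == 1L & df2$nonwc == 1L, ]
  expect_equal(nrow(both), 1L)

  expect_error(read_annotation("A1-A99 : WC", s), "A99")
})

test_that("backbone covalent count is sum over chains of (len - 1)", {
  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    lines <- c(pdb_chain_lines("A", sample(c("A", "U", "G", "C"), n1, TRUE)),
               pdb_chain_lines("B", sample(c("A", "U", "G", "C"), n2, TRUE),
                               start_serial = n1 + 1L, y = 40),
               "END")
    s <- read_structure(text = lines, format = "PDB")
    ia <- read_annotation("", s)
    expect_equal(sum(ia$interactions$cov), (n1 - 1L) + (n2 - 1L))
  }
})

test_that("geometric annotator recovers planted helices and skips mismatches", {
  st <- generate_structure(structure_spec(
    list(list(class = "HAIRPIN", loop = 4)), seed = 21, stem = 6))
  ia <- naive_annotate(st$structure)
  wc <- ia$interactions[ia$interactions$wc == 1L, ]
  expect_equal(nrow(wc), 6L)

  # single strand: no pairs
  ss <- generate_structure(structure_spec(
    list(list(class = "HAIRPIN", loop = 21)), seed = 3, stem = 1))
  # strip the lone planted pair by keeping only loop residues
  keys <- ss$structure$residues$key[2:22]
  sub <- ss$structure
  sub$residues <- sub$residues[2:22, ]
  sub$atoms <- sub$atoms[sub$atoms$resno %in% 2:22, ]
  ia2 <- naive_annotate(sub)
  expect_equal(sum(ia2$interactions$wc), 0L)

  # non-complementary ladder position stays unpaired
  s3 <- st$structure
  planted <- st$interactions$interactions
  wcp <- planted[planted$wc == 1L, ][1, ]
  i <- match(wcp$key_a, s3$residues$key); j <- match(wcp$key_b, s3$residues$key)
  s3$residues$base[c(i, j)] <- c("A", "A")
  s3$atoms$resname[s3$atoms$resno %in% c(i, j)] <- "A"
  ia3 <- naive_annotate(s3)
  wc3 <- ia3$interactions[ia3$interactions$wc == 1L, ]
  expect_equal(nrow(wc3), 5L)
  expect_false(wcp$key_a %in% c(wc3$key_a, wc3$key_b))
})

test_that("motif PDB writer extracts subsets with original numbering", {
  st <- generate_structure(structure_spec(
    list(list(class = "HAIRPIN", loop = 4)), seed = 5, stem = 7))
  s <- st$structure
  all_out <- write_motif_pdb(s)
  expect_equal(sum(grepl("^ATOM", all_out)), nrow(s$atoms))

  members <- res_key("A", 7:12)
  out <- write_motif_pdb(s, members)
  atom_lines <- grep("^ATOM", out, value = TRUE)
  resnos <- unique(as.integer(substr(atom_lines, 23, 26)))
  expect_setequal(resnos, 7:12)

  expect_warning(empty <- write_motif_pdb(s, character()), "header-only")
  expect_false(any(grepl("^ATOM", empty)))
  expect_error(write_motif_pdb(s, "Z9"), "Z9")
})

test_that("write/read round trip preserves keys, bases and coordinates", {
  st <- generate_structure(structure_spec(
    list(list(class = "INTERNAL", a = 2, b = 1)), seed = 9))
  s <- st$structure
  tmp <- tempfile(fileext = ".pdb")
  write_motif_pdb(s, path = tmp)
  back <- read_structure(tmp, format = "PDB")
  expect_equal(back$residues$key, s$residues$key)
  expect_equal(back$residues$base, s$residues$base)
  expect_equal(back$atoms$x, s$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$y, s$atoms$y, tolerance = 1e-3)
  # independent reader agrees on the written file
  b3 <- bio3d::read.pdb(tmp)
  expect_equal(nrow(b3$atom), nrow(s$atoms))
  expect_equal(b3$atom$x, s$atoms$x, tolerance = 1e-3)
  unlink(tmp)
})
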