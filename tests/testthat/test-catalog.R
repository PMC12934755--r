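make_filled_store <- function(specs, seed0 = 600) {
  store <- motif_store()
  for (k in seq_along(specs)) {
    st <- generate_structure(specs[[k]])
    store_motifs(store, extract_motifs(st$graph),
                 pdb_id = st$structure$structure_id, s = st$structure)
  }
  store
}

test_that("store insert, query and CSV column contract", {
  st <- generate_structure(structure_spec(
    list(list(class = "HAIRPIN", loop = 4),
         list(class = "INTERNAL", a = 1, b = 1)), seed = 61))
  store <- motif_store()
  n <- store_motifs(store, extract_motifs(st$graph), "TEST1",
                    s = st$structure)
  expect_equal(n, nrow(store$rows))
  expect_gte(n, 3L)

  hp4 <- query_motifs(store, "HAIRPIN", 4L)
  expect_true(all(hp4$motif_class == "HAIRPIN" & hp4$size == 4L))

  csv <- export_csv(query_motifs(store, "HAIRPIN"))
  expect_equal(csv[[1]], "ID,motif type,PDB ID,nucleotide number")
  expect_equal(length(csv) - 1L, nrow(query_motifs(store, "HAIRPIN")))
  fields <- strsplit(csv[[2]], ",")[[1]]
  expect_length(fields, 4L)
  expect_equal(fields[[2]], "HAIRPIN")
  expect_equal(fields[[3]], "TEST1")

  expect_error(store_motifs(store, extract_motifs(st$graph), "TEST1",
                            motif_ids = store$rows$motif_id), "duplicate")
})

test_that("store persists and round-trips graph JSON bit-identically", {
  st <- generate_structure(structure_spec(
    list(list(class = "HAIRPIN", loop = 5)), nonwc = 1, seed = 67))
  store <- motif_store()
  store_motifs(store, extract_motifs(st$graph), "TEST2", s = st$structure)
  tmp <- tempfile(fileext = ".json")
  save_store(store, tmp)
  back <- load_store(tmp)
  expect_identical(back$rows$graph_with_nonwc, store$rows$graph_with_nonwc)
  expect_identical(back$rows$members, store$rows$members)
  unlink(tmp)
})

test_that("ZIP export writes one readable PDB entry per motif", {
  st <- generate_structure(structure_spec(
    list(list(class = "HAIRPIN", loop = 4)), seed = 71))
  store <- motif_store()
  store_motifs(store, extract_motifs(st$graph), "TEST3", s = st$structure)
  zf <- tempfile(fileext = ".zip")
  export_zip(query_motifs(store), zf)
  lst <- utils::unzip(zf, list = TRUE)
  expect_equal(sort(lst$Name), sort(paste0(store$rows$motif_id, ".pdb")))
  ex <- tempfile()
  utils::unzip(zf, exdir = ex)
  one <- readLines(file.path(ex, lst$Name[[1]]))
  expect_true(any(grepl("^ATOM", one)))

  # zero rows: valid empty archive (bare end-of-central-directory record;
  # R's unzip refuses 0-entry archives, so check the record directly)
  zf0 <- tempfile(fileext = ".zip")
  export_zip(query_motifs(store, "JUNCTION", 99L), zf0)
  expect_equal(file.size(zf0), 22)
  eocd <- readBin(zf0, "raw", 4)
  expect_equal(as.integer(eocd), c(0x50, 0x4b, 0x05, 0x06))
  unlink(c(zf, zf0))
})

test_that("conformation classes count attribute-distinct graphs", {
  # 5 copies of one tetraloop + 2 copies of a non-WC-decorated variant
  base_spec <- structure_spec(list(list(class = "HAIRPIN", loop = 4)),
                              seed = 81)
  deco_spec <- structure_spec(list(list(class = "HAIRPIN", loop = 4)),
                              nonwc = 1, seed = 81)
  store <- motif_store()
  for (k in 1:5) {
    st <- generate_structure(base_spec)
    store_motifs(store, extract_motifs(st$graph), sprintf("P%d", k))
  }
  for (k in 1:2) {
    st <- generate_structure(deco_spec)
    store_motifs(store, extract_motifs(st$graph), sprintf("Q%d", k))
  }
  cls <- classify_conformations(store, "HAIRPIN", 4L)
  expect_equal(cls$frequency, c(5L, 2L))
  expect_equal(sum(cls$frequency), 7L)

  # WC-only view merges the two conformations
  cls_wc <- classify_conformations(store, "HAIRPIN", 4L, use_nonwc = FALSE)
  expect_equal(cls_wc$frequency, 7L)

  # single motif: one class of frequency 1
  one <- motif_store()
  st <- generate_structure(base_spec)
  store_motifs(one, extract_motifs(st$graph), "S1")
  expect_equal(classify_conformations(one, "HAIRPIN", 4L)$frequency, 1L)

  # empty fetch
  expect_equal(nrow(classify_conformations(store, "JUNCTION", 8L)), 0L)
})

test_that("conformation partition is insertion-order independent", {
  specs <- c(rep(list(structure_spec(list(list(class = "HAIRPIN", loop = 4)),
                                     seed = 83)), 3),
             rep(list(structure_spec(list(list(class = "HAIRPIN", loop = 4)),
                                     nonwc = 2, seed = 83)), 2))
  s1 <- make_filled_store(specs)
  s2 <- make_filled_store(rev(specs))
  c1 <- classify_conformations(s1, "HAIRPIN", 4L)
  c2 <- classify_conformations(s2, "HAIRPIN", 4L)
  expect_equal(c1$frequency, c2$frequency)
  expect_equal(c1$canonical_key, c2$canonical_key)
})

test_that("canonical keys are invariant under node relabeling", {
  st <- generate_structure(structure_spec(
    list(list(class = "HAIRPIN", loop = 4)), nonwc = 2, seed = 89))
  m <- extract_motifs(st$graph)[[1]]
  g <- m$graph_with_nonwc
  key0 <- rnamotifs:::canonical_key(g)
  set.seed(97)
  for (rep in 1:100) {
    expect_equal(rnamotifs:::canonical_key(random_relabel(g)), key0)
  }
})

test_that("distribution shares sum to 100 and histograms track planted sizes", {
  store <- motif_store()
  for (k in 1:10) {
    st <- generate_structure(structure_spec(
      list(list(class = "HAIRPIN", loop = 4)), seed = 900 + k, stem = 3))
    store_motifs(store, extract_motifs(st$graph), sprintf("H%d", k))
  }
  for (k in 1:10) {
    st <- generate_structure(structure_spec(
      list(list(class = "INTERNAL", a = 1, b = 1)), seed = 950 + k, stem = 3))
    ms <- extract_motifs(st$graph)
    ms <- Filter(function(m) m$motif_class == "INTERNAL", ms)
    store_motifs(store, ms, sprintf("I%d", k))
  }
  d <- motif_distributions(store)
  expect_equal(sum(d$shares$share_pct), 100)
  expect_equal(sort(d$shares$share_pct), c(50, 50))
  expect_equal(names(which.max(d$histograms$HAIRPIN)), "4")
  expect_equal(names(which.max(d$histograms$INTERNAL)), "2")

  empty <- motif_distributions(motif_store())
  expect_equal(nrow(empty$shares), 0L)
  expect_length(empty$histograms, 0L)
})
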