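test_that("gene windows reproduce the printed tile counts and the closed form", {
  expect_equal(make_gene_window(tiny_gene(11703L))$n_tiles, 1024L)
  expect_equal(make_gene_window(tiny_gene(140502L))$n_tiles, 1282L)
  expect_equal(make_gene_window(tiny_gene(500L))$n_tiles, 1001L)

  # oracle: explicit interval construction for random gene lengths
  set.seed(1)
  for (len in sample.int(300000L, 50)) {
    w <- make_gene_window(tiny_gene(len), flank = 10000L, tile_size = 500L)
    tc <- tile_coords(w)
    expect_equal(nrow(tc), 2L * 20L + as.integer(ceiling(len / 500)))
    expect_true(all(tc$end - tc$start == 500L))
    expect_true(all(diff(tc$start) == 500L))  # contiguous, non-overlapping
    expect_equal(tc$start[1], 1000000L - 10000L)
    expect_true(tc$end[nrow(tc)] >= 1000000L + len)
  }

  expect_error(make_gene_window(tiny_gene(), flank = 250100L),
               "divisible")
  expect_error(make_gene_window(tiny_gene(), tile_size = -5L), "positive")
})

test_that("fragments yield insertions at start and end-1, unknown barcodes skipped", {
  cells <- tibble::tibble(barcode = c("AAAC", "GGGT"), cell_type = "T")
  frags <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L,
                          barcode = "AAAC", count = 1L)
  ins <- fragments_to_insertions(frags, cells)
  expect_equal(ins$pos, c(100L, 199L))

  # count column replicates the fragment
  frags$count <- 3L
  expect_equal(nrow(fragments_to_insertions(frags, cells)), 6L)

  frags2 <- tibble::tibble(chrom = "chr1", start = 1L, end = 10L,
                           barcode = "ZZZZ", count = 1L)
  expect_message(ins2 <- fragments_to_insertions(frags2, cells), "skipped")
  expect_equal(nrow(ins2), 0L)
})

test_that("fragments TSV round-trips and malformed lines are reported", {
  cells <- tibble::tibble(barcode = "AAAC", cell_type = "T")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t200\tAAAC\t2", "chr1\t50\t70\tAAAC\t1"), path)
  ins <- read_fragments(path, cells)
  expect_equal(sort(ins$pos), c(50L, 69L, 100L, 100L, 199L, 199L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100\t200\tAAAC\t1", "chr1\t100\t200"), bad)
  expect_error(suppressWarnings(read_fragments(bad, cells)), "line 2")
})

test_that("tile matrix counts insertions, respects half-open tiles and blacklist", {
  gene <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 2000L,
                         end = 3000L, strand = "+")
  w <- make_gene_window(gene, flank = 1000L, tile_size = 500L)  # window 1000-4000
  cells <- tibble::tibble(barcode = c("A", "B"), cell_type = "T")

  ins <- tibble::tibble(
    barcode = c("A", "A", "A", "B", "B", "A"),
    chrom = "chr1",
    pos = c(1001L, 1002L, 1003L,  # three in tile 1 for cell A
            1500L,                # boundary: first position of tile 2
            3999L,                # last in-window position (tile 6)
            4000L))               # outside the window: ignored
  m <- build_tile_matrix(ins, w, cells)
  expect_equal(dim(m), c(2L, 6L))
  expect_equal(unname(m["A", 1]), 3)
  expect_equal(unname(m["B", 2]), 1)   # boundary insertion in the tile starting there
  expect_equal(unname(m["B", 6]), 1)
  expect_equal(sum(m), 5)      # conservation: in-window insertions only

  # blacklist overlapping tile 2 by 1 bp zeroes the whole column
  bl <- tibble::tibble(chrom = "chr1", start = 1999L, end = 2001L)
  mb <- build_tile_matrix(ins, w, cells, blacklist = bl)
  expect_equal(sum(mb[, 2]), 0)
  expect_equal(sum(mb[, 3]), 0)  # 2000-2500 tile also touched
  expect_equal(unname(mb["A", 1]), 3)
})

test_that("tile matrix conserves insertions on simulated data", {
  sim <- small_sim()
  fr <- sim_fragments(sim, "gene01", seed = 3L)
  w <- sim$windows$gene01
  m <- build_tile_matrix(fr$insertions, w, sim$cells)
  expect_equal(sum(m), nrow(fr$insertions))
  expect_equal(unname(as.matrix(m)), unname(as.matrix(sim$atac$gene01)))
})

test_that("reads-in-TSS counting floors at 1 and collapses overlapping windows", {
  cells <- tibble::tibble(barcode = c("A", "B"), cell_type = "T")
  tss <- tibble::tibble(chrom = "chr1", pos = c(5000L, 6000L))  # overlapping +-2kb
  ins <- tibble::tibble(barcode = c("A", "A", "A"), chrom = "chr1",
                        pos = c(5000L,   # exactly at a TSS
                                5500L,   # in the overlap of both windows
                                20000L)) # far away
  rit <- compute_reads_in_tss(ins, tss, cells)
  expect_equal(unname(rit["A"]), 2)  # overlap counted once
  expect_equal(unname(rit["B"]), 1)  # floored

  # brute-force interval-union oracle on random data
  set.seed(2)
  pos <- sample.int(50000L, 300)
  ins2 <- tibble::tibble(barcode = "A", chrom = "chr1", pos = pos)
  centers <- sort(sample.int(50000L, 5))
  oracle <- sum(vapply(pos, function(p) any(abs(p - centers) <= 2000),
                       logical(1)))
  rit2 <- compute_reads_in_tss(ins2, tibble::tibble(chrom = "chr1",
                                                    pos = centers),
                               cells)
  expect_equal(unname(rit2["A"]), max(oracle, 1))
})

test_that("model store round-trips fitted models bit-exactly", {
  fit <- small_fit()
  dir <- withr::local_tempdir()
  save_model_store(list(gene01 = fit$m), dir)
  back <- load_model_store(dir)
  expect_identical(back$gene01, fit$m)
  expect_error(load_model_store(dir, genes = "nope"), "not in store")
})

test_that("MTX matrices round-trip with sidecars", {
  sim <- small_sim()
  m <- Matrix::Matrix(sim$rna[1:20, 1:10], sparse = TRUE)
  dir <- withr::local_tempdir()
  write_mtx_matrix(m, dir)
  back <- read_mtx_matrix(file.path(dir, "matrix.mtx"))
  expect_equal(as.matrix(back), as.matrix(m))
})

test_that("annotation, metadata and BED readers validate their inputs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tiny_gene(), path)
  expect_equal(read_gene_annotation(path)$gene_id, "g1")

  bad <- tiny_gene(); bad$end <- bad$start
  readr::write_tsv(bad, path)
  expect_error(read_gene_annotation(path), "end <= start")

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tblockA", "chr2\t50\t80\tblockB"), bed)
  b <- read_bed(bed)
  expect_equal(b$name, c("blockA", "blockB"))

  meta <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(barcode = c("A", "B"), cell_type = "T",
                                  reads_in_tss = c(5, 3)), meta)
  cells <- read_cell_metadata(meta)
  expect_true(all(cells$include_flag))
})
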