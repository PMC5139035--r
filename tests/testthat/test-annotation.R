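test_that("bin indexing follows the 1-based floor convention", {
  expect_identical(bin_index(1L), 0L)
  expect_identical(bin_index(200L), 0L)
  expect_identical(bin_index(201L), 1L)
  expect_error(bin_index(0L), ">= 1")
  # interval-membership oracle over enumerated bins
  set.seed(5)
  pos <- sample.int(5e4, 1000)
  starts <- seq(1L, 5e4, by = 200L)
  oracle <- vapply(pos, function(p) which(p >= starts & p <= starts + 199L) - 1L,
                   integer(1))
  expect_identical(bin_index(pos), oracle)
})

test_that("read replicates merge by per-bin addition", {
  g <- toy_genome(2000, chroms = "chrA")
  a <- toy_read_track(list(chrA = c(3, 0, 1, 0, 0, 0, 0, 0, 0, 0)))
  b <- toy_read_track(list(chrA = c(4, 2, 0, 0, 0, 0, 0, 0, 0, 0)), id = "t2")
  m <- merge_read_replicates(list(a, b))
  expect_equal(m$payload$chrA[1:3], c(7, 2, 1))
  expect_equal(m$total_reads, a$total_reads + b$total_reads)
  expect_identical(merge_read_replicates(list(a)), a)

  set.seed(8)
  tracks <- lapply(1:3, function(i)
    toy_read_track(list(chrA = rpois(10, 1), chrB = rpois(10, 1)), id = paste0("r", i)))
  m3 <- merge_read_replicates(tracks)
  dense <- Reduce(`+`, lapply(tracks, function(t) c(t$payload$chrA, t$payload$chrB)))
  expect_equal(c(m3$payload$chrA, m3$payload$chrB), dense)

  other <- toy_read_track(list(chrA = c(1, rep(0, 9))), id = "x", factor = "H3K4me1")
  expect_error(merge_read_replicates(list(a, other)), "mismatch")
})

test_that("peak replicates merge to a sorted non-overlapping union", {
  a <- toy_peak_track("chrA", 100L, 300L)
  b <- toy_peak_track("chrA", 200L, 400L, id = "p2")
  m <- merge_peak_replicates(list(a, b))
  expect_equal(GenomicRanges::start(m$payload), 101L)
  expect_equal(GenomicRanges::end(m$payload), 400L)

  d1 <- toy_peak_track("chrA", 0L, 100L)
  d2 <- toy_peak_track("chrA", 500L, 600L, id = "p2")
  md <- merge_peak_replicates(list(d2, d1))
  expect_equal(GenomicRanges::start(md$payload), c(1L, 501L))

  # per-base boolean-OR oracle on a 10-kb toy chromosome
  set.seed(9)
  mk <- function(id) {
    s <- sort(sample.int(9900, 8)); e <- pmin(s + sample.int(300, 8), 10000L)
    toy_peak_track(rep("chrA", 8), s, e, id = id)
  }
  reps <- lapply(c("a", "b", "c"), mk)
  mu <- merge_peak_replicates(reps)
  covered <- logical(10000)
  for (t in reps) for (i in seq_along(t$payload))
    covered[GenomicRanges::start(t$payload)[i]:GenomicRanges::end(t$payload)[i]] <- TRUE
  oracle <- logical(10000)
  for (i in seq_along(mu$payload))
    oracle[GenomicRanges::start(mu$payload)[i]:GenomicRanges::end(mu$payload)[i]] <- TRUE
  expect_identical(oracle, covered)
  expect_false(is.unsorted(GenomicRanges::start(mu$payload)))
})

test_that("input subtraction scales control to ChIP depth and floors at zero", {
  chip <- toy_read_track(list(chrA = c(10, 1, 5)), total = 1e6)
  ctl <- toy_read_track(list(chrA = c(4, 6, 5)), id = "inp", total = 2e6)
  norm <- normalize_chip_vs_input(chip, ctl)
  expect_equal(norm$payload$chrA, c(10 - 4 * 0.5, 0, 5 - 2.5))
  raw <- normalize_chip_vs_input(chip, ctl, floor_negative = FALSE)
  expect_equal(raw$payload$chrA[2], 1 - 3)
  selfn <- normalize_chip_vs_input(chip, toy_read_track(list(chrA = c(10, 1, 5)), id = "i2", total = 1e6))
  expect_true(all(selfn$payload$chrA == 0))
  bad <- toy_read_track(list(chrA = c(1, 1, 1)), id = "i3", total = 1)
  bad$total_reads <- 0
  expect_error(normalize_chip_vs_input(chip, bad), "depth")
})

test_that("annotation matrix holds bin counts, peak hits and scores per cell", {
  g <- toy_genome(2000, chroms = "chrA")
  counts <- list(chrA = c(7, 0, 2, 0, 0, 0, 0, 0, 0, 0))
  tr <- toy_read_track(counts)
  # peak [400, 600) 0-based: first base inside is 401, first outside is 601
  pk <- toy_peak_track("chrA", 400L, 600L)
  v <- variant_table("chrA", c(100L, 401L, 601L), c("a", "b", "c"), "risk")
  am <- build_annotation_matrix(v, list(tr, pk), g)
  expect_equal(unname(am$values[, "t1"]), c(7, 2, 0))
  expect_equal(unname(am$values[, "p1"]), c(0, 1, 0))

  far <- variant_table("chrA", 5000L, "far", "risk")
  expect_error(build_annotation_matrix(far, list(tr), g), "far")
})

test_that("matrix construction equals per-cell recomputation and is order-invariant", {
  g <- toy_genome(20000, chroms = c("chrA", "chrB"))
  set.seed(13)
  tracks <- c(
    lapply(1:12, function(i) toy_read_track(
      list(chrA = rpois(100, 3), chrB = rpois(100, 3)), id = sprintf("rd%02d", i))),
    lapply(1:8, function(i) {
      s <- sort(sample.int(19000, 5)); e <- pmin(s + 400L, 20000L)
      toy_peak_track(rep(sample(c("chrA", "chrB"), 1), 5), s, e, id = sprintf("pk%02d", i))
    }))
  v <- random_variants(50, g, seed = 14)
  am <- build_annotation_matrix(v, tracks, g)
  for (i in sample(50, 10)) for (j in sample(20, 10)) {
    tr <- tracks[[j]]
    cell <- if (tr$representation == "read") {
      tr$payload[[v$chrom[i]]][bin_index(v$pos[i]) + 1L]
    } else {
      s <- GenomicRanges::start(tr$payload); e <- GenomicRanges::end(tr$payload)
      ch <- as.character(GenomicRanges::seqnames(tr$payload))
      as.numeric(any(ch == v$chrom[i] & s <= v$pos[i] & e >= v$pos[i]))
    }
    expect_equal(unname(am$values[i, j]), cell)
  }
  pv <- sample(50); pt <- sample(20)
  am2 <- build_annotation_matrix(v[pv, ], tracks[pt], g)
  expect_equal(am2$values, am$values[pv, pt])
})

test_that("bedGraph and peak tracks round-trip; misaligned intervals error", {
  g <- toy_genome(4000, chroms = "chrA")
  set.seed(17)
  tr <- toy_read_track(list(chrA = as.numeric(rpois(20, 2))))
  f <- tempfile(fileext = ".bedgraph")
  write_bedgraph_track(tr, f, g)
  back <- read_bedgraph_track(f, g, "t1", "H3K9me3", "cellX", "REMC", "histone",
                              total_reads = tr$total_reads)
  expect_equal(back$payload$chrA, tr$payload$chrA)

  badf <- tempfile(fileext = ".bedgraph")
  writeLines("chrA\t100\t300\t5", badf)
  expect_error(read_bedgraph_track(badf, g, "t", "x", "c"), "chrA:100-300")

  pk <- toy_peak_track("chrA", c(100L, 900L), c(300L, 1000L))
  pf <- tempfile(fileext = ".bed")
  write_peak_track(pk, pf)
  back2 <- read_peak_track(pf, "p1", "CTCF", "cellX")
  expect_equal(GenomicRanges::start(back2$payload), GenomicRanges::start(pk$payload))
})

test_that("manifest and annotation-matrix TSVs round-trip", {
  g <- toy_genome(4000, chroms = "chrA")
  dir <- tempfile(); dir.create(dir)
  set.seed(19)
  tr <- toy_read_track(list(chrA = as.numeric(rpois(20, 2))))
  write_bedgraph_track(tr, file.path(dir, "t1.bedgraph"), g)
  man <- data.frame(track_id = "t1", factor = "H3K9me3", cell_line = "cellX",
                    source = "REMC", category = "histone", representation = "read",
                    path = "t1.bedgraph", total_reads = tr$total_reads,
                    stringsAsFactors = FALSE)
  write_manifest(man, file.path(dir, "manifest.tsv"))
  man2 <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(man2$track_id, "t1")
  tracks <- load_tracks(man2, g, dir)
  expect_equal(tracks[[1]]$payload$chrA, tr$payload$chrA)

  v <- random_variants(10, toy_genome(4000, chroms = "chrA"), seed = 21)
  am <- build_annotation_matrix(v, tracks, g)
  mf <- file.path(dir, "annot.tsv")
  write_annotation_matrix(am, mf)
  am2 <- read_annotation_matrix(mf)
  expect_equal(am2$values, am$values)
  expect_equal(am2$col_meta$factor, am$col_meta$factor)
})
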