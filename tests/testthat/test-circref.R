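test_that("circular references rotate and pad as specified", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAACCCGGGTTT"))
  ref <- build_circular_reference(genome, list(chrom = "chr1", start = 0, end = 12),
                                  rotation = 6, pad = 2)
  expect_equal(ref$seq, "NNGGGTTTAAACCCNN")
  expect_equal(ref$size, 12L)

  ident <- build_circular_reference(genome, list(chrom = "chr1", start = 0, end = 12),
                                    rotation = 0, pad = 0)
  expect_equal(ident$seq, "AAACCCGGGTTT")

  expect_error(build_circular_reference(genome,
                                        list(chrom = "chr1", start = 5, end = 20)),
               "out of bounds")
  expect_error(build_circular_reference(genome,
                                        list(chrom = "chr1", start = 0, end = 12),
                                        rotation = 12), "rotation")
})

test_that("liftover maps core positions and rejects pads", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAACCCGGGTTT"))
  ref <- build_circular_reference(genome, list(chrom = "chr1", start = 0, end = 12),
                                  rotation = 6, pad = 2)
  # first core base is the 'G' at genome position 6
  expect_equal(liftover_to_genome(ref, 2)$genome_pos, 6L)
  expect_true(is.na(liftover_to_genome(ref, 0)$genome_pos))
  expect_error(liftover_to_genome(ref, 16), "out of range")

  # round-trip identity over all core positions
  core <- ref$pad + 0:(ref$size - 1L)
  g <- liftover_to_genome(ref, core)
  back <- liftover_from_genome(ref, g$chrom, g$genome_pos)
  expect_equal(back, core)
})

test_that("liftover round-trip holds for randomized size/rotation/pad", {
  set.seed(11)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")))
  for (i in 1:25) {
    size <- sample(10:2000, 1)
    start <- sample(0:(5000 - size), 1)
    rot <- sample(0:(size - 1), 1)
    pad <- sample(0:500, 1)
    ref <- build_circular_reference(genome,
                                    list(chrom = "chr1", start = start,
                                         end = start + size),
                                    rotation = rot, pad = pad)
    core <- ref$pad + 0:(size - 1L)
    g <- liftover_to_genome(ref, core)
    expect_false(anyNA(g$genome_pos))
    expect_equal(liftover_from_genome(ref, g$chrom, g$genome_pos), core)
    # the lifted sequence letters match the genome
    expect_equal(substring(ref$seq, core + 1L, core + 1L),
                 substring(as.character(genome[[1]]), g$genome_pos + 1L,
                           g$genome_pos + 1L))
  }
})

test_that("junction distance is signed circular distance from the junction", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("ACGT", 1500), collapse = "")))
  ref <- build_circular_reference(genome,
                                  list(chrom = "chr1", start = 0, end = 6000),
                                  rotation = 3000, pad = 100)
  j <- ref$pad + (ref$size - ref$rotation)   # junction sequence position
  expect_equal(junction_distance(ref, j), 0L)
  expect_equal(junction_distance(ref, j + 1L), 1L)
  expect_equal(junction_distance(ref, j - 1L), -1L)
  # antipode (positive by convention)
  expect_equal(abs(junction_distance(ref, ref$pad)), 3000L)
  expect_error(junction_distance(ref, 0), "core")
})

test_that("a circle track lifted to the genome matches the direct genome track", {
  set.seed(21)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = "")))
  ref <- build_circular_reference(genome,
                                  list(chrom = "chr1", start = 1000, end = 3000),
                                  rotation = 0, pad = 0)
  # reads inside the circle that do not span the junction
  apos <- as.integer(gregexpr("A", as.character(genome[[1]]))[[1]]) - 1L
  apos <- apos[apos >= 1000 & apos < 3000]
  calls <- data.frame(read_id = "r1", ref = "chr1", pos = apos, strand = "+",
                      prob = 0.9,
                      methylated = runif(length(apos)) > 0.5)
  tg <- methylation_ratio_track(calls, 4000)
  circ_calls <- calls
  circ_calls$pos <- liftover_from_genome(ref, calls$ref, calls$pos)
  circ_calls$ref <- ref$name
  tc <- methylation_ratio_track(circ_calls, ref$size)
  # with rotation 0 circle coordinate = genome coordinate - 1000
  shift <- 1000 %/% tg$step
  for (i in seq_len(nrow(tc$bins))) {
    expect_equal(tc$bins$total_A[i], tg$bins$total_A[i + shift])
    expect_equal(tc$bins$meth_A[i], tg$bins$meth_A[i + shift])
  }
})
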