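small_cfg <- function(...) {
  args <- list(seed = 7, genome_len = 30000L, n_genes = 4L, n_ecdna = 2L,
               ecdna_size_range = c(3000L, 5000L),
               read_len_range = c(3000L, 10000L), coverage = 10)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("simulation is fully deterministic under a fixed seed", {
  s1 <- simulate_ccda(small_cfg())
  s2 <- simulate_ccda(small_cfg())
  expect_identical(as.character(s1$genome[[1]]), as.character(s2$genome[[1]]))
  expect_identical(s1$segments, s2$segments)
  expect_identical(s1$modcalls, s2$modcalls)
  expect_identical(s1$ecdna, s2$ecdna)
  s3 <- simulate_ccda(small_cfg(seed = 8))
  expect_false(identical(as.character(s1$genome[[1]]),
                         as.character(s3$genome[[1]])))
})

test_that("mod calls fall only on template-strand adenines", {
  sim <- simulate_ccda(small_cfg())
  expect_true(validate_modcall_bases(sim$modcalls, sim$genome))
})

test_that("the chromatin array tiles nucleosomes and carves NDRs", {
  cfg <- sim_config(seed = 1, genome_len = 100000L, ndr_at_tss = FALSE)
  gen <- simulate_genome(cfg)
  # complete 147/50 units fitting in the genome
  expect_equal(length(gen$dyads$chr1), 100000L %/% (147L + 50L))
  # linkers open, nucleosome cores closed
  expect_true(all(gen$mask$chr1[1:50]))
  expect_true(all(!gen$mask$chr1[51:197]))

  cfg2 <- sim_config(seed = 1, ndr_width = 300L)
  gen2 <- simulate_genome(cfg2)
  for (i in seq_len(nrow(gen2$genes))) {
    tss <- gen2$genes$tss[i]
    expect_true(all(gen2$mask$chr1[(tss - 149):(tss + 150)]))
  }
  # truth dyads avoid NDR-disrupted nucleosomes (mask is 1-based over
  # 0-based positions d-73 .. d+73)
  closed_at_dyads <- vapply(gen2$dyads$chr1, function(d) {
    all(!gen2$mask$chr1[(d - 72):(d + 74)])
  }, logical(1))
  expect_true(all(closed_at_dyads))
})

test_that("circle truth respects size range and non-overlap", {
  cfg <- small_cfg()
  gen <- simulate_genome(cfg)
  ec <- simulate_ecdna_events(cfg, gen$genome)
  expect_equal(nrow(ec), 2L)
  expect_true(all(ec$size >= 3000 & ec$size <= 5000))
  expect_true(all(ec$end[-nrow(ec)] <= ec$start[-1]))
  cfg0 <- small_cfg(n_ecdna = 0L)
  expect_equal(nrow(simulate_ecdna_events(cfg0, gen$genome)), 0L)
})

test_that("junction-crossing circle reads emit outward same-strand pairs", {
  sim <- simulate_ccda(small_cfg())
  crossing <- sim$reads$read_id[sim$reads$crosses_junction]
  expect_gt(length(crossing), 0L)
  for (rid in crossing) {
    segs <- as.data.frame(sim$segments[sim$segments$read_id == rid, ])
    expect_equal(nrow(segs), 2L)
    expect_equal(segs$strand[1], segs$strand[2])
    a <- segs[1, ]; b <- segs[2, ]
    if (a$strand == "+") expect_lte(b$ref_end, a$ref_start)
    else expect_gte(b$ref_start, a$ref_end)
    # the pair reconstructs the generating circle
    ci <- sim$reads$circle[sim$reads$read_id == rid]
    expect_equal(min(segs$ref_start), sim$ecdna$start[ci])
    expect_equal(max(segs$ref_end), sim$ecdna$end[ci])
  }
})

test_that("fraction sampling reproduces the configured circular read share", {
  cfg <- small_cfg(ecdna_sampling = "fraction", ecdna_read_frac = 0)
  sim <- simulate_ccda(cfg)
  expect_equal(sum(sim$reads$source == "ecdna"), 0L)
  expect_true(all(table(sim$segments$read_id) == 1L))

  cfg2 <- small_cfg(ecdna_sampling = "fraction", ecdna_read_frac = 0.2)
  sim2 <- simulate_ccda(cfg2)
  frac <- mean(sim2$reads$source == "ecdna")
  expect_equal(frac, 0.2, tolerance = 0.05)
})

test_that("open-region methylated fraction matches the normal tail integral", {
  sim <- simulate_ccda(small_cfg())
  mask <- simulate_genome(sim$config)$mask$chr1
  open_calls <- sim$modcalls[mask[sim$modcalls$pos + 1L], ]
  cutoff <- 0.53
  observed <- mean(open_calls$prob > cutoff)
  expected <- 1 - pnorm((cutoff - sim$config$signal_mean) / sim$config$signal_sd)
  expect_equal(observed, expected, tolerance = 3 * sqrt(expected * (1 - expected) /
                                                          nrow(open_calls)) + 1e-4)
  closed_calls <- sim$modcalls[!mask[sim$modcalls$pos + 1L], ]
  expected_noise <- 1 - pnorm((cutoff - sim$config$noise_mean) / sim$config$noise_sd)
  expect_lt(abs(mean(closed_calls$prob > cutoff) - expected_noise),
            3 * sqrt(expected_noise * (1 - expected_noise) / nrow(closed_calls)) +
              1e-3)
})

test_that("a written simulation reloads through the package readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_ccda(small_cfg())
  write_simulation(sim, dir)
  genome <- read_genome_fasta(file.path(dir, "genome.fasta"))
  expect_equal(as.character(genome[[1]]), as.character(sim$genome[[1]]))
  segs <- read_alignment_table(file.path(dir, "alignments.tsv"))
  expect_equal(nrow(segs), nrow(sim$segments))
  calls <- read_modcall_table(file.path(dir, "modcalls.tsv"), genome = genome)
  expect_equal(nrow(calls), nrow(sim$modcalls))
  genes <- read_gene_bed(file.path(dir, "genes.bed"), score_as_expression = TRUE)
  expect_equal(genes$tss, sim$genes$tss)
  expect_equal(genes$expression, sim$genes$expression)
})
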