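test_that("methylation ratio pools counts over all covered reads", {
  # two reads over one bin: 2/5 and 3/5 methylated -> pooled 5/10
  calls <- rbind(toy_calls(c(1, 1, 0, 0, 0), read_id = "r1"),
                 toy_calls(c(1, 1, 1, 0, 0), read_id = "r2"))
  tr <- methylation_ratio_track(calls, ref_length = 50)
  expect_equal(tr$bins$ratio[1], 0.5)
  expect_equal(tr$bins$total_A[1], 10L)

  all_m <- binarize_calls(transform(calls, prob = 0.99), 0.53)
  tr2 <- methylation_ratio_track(all_m, 50)
  covered <- tr2$bins$total_A > 0
  expect_true(all(tr2$bins$ratio[covered] == 1))
})

test_that("track counts equal a brute-force per-position recount", {
  set.seed(31)
  calls <- data.frame(read_id = sprintf("r%d", sample(1:5, 300, TRUE)),
                      ref = "chr1", pos = sample(0:1999, 300, TRUE),
                      strand = sample(c("+", "-"), 300, TRUE), prob = 0.5,
                      methylated = runif(300) > 0.6)
  tr <- methylation_ratio_track(calls, 2000)
  want <- oracle_track_counts(calls, 2000)
  expect_equal(tr$bins$start, want$start)
  expect_equal(tr$bins$total_A, want$total_A)
  expect_equal(tr$bins$meth_A, want$meth_A)
})

test_that("strand-restricted counts decompose the pooled track bin by bin", {
  set.seed(32)
  calls <- data.frame(read_id = "r1", ref = "chr1",
                      pos = sample(0:999, 400, TRUE),
                      strand = sample(c("+", "-"), 400, TRUE), prob = 0.5,
                      methylated = runif(400) > 0.5)
  both <- methylation_ratio_track(calls, 1000, strand_mode = "both")
  plus <- methylation_ratio_track(calls, 1000, strand_mode = "plus")
  minus <- methylation_ratio_track(calls, 1000, strand_mode = "minus")
  expect_equal(both$bins$total_A, plus$bins$total_A + minus$bins$total_A)
  expect_equal(both$bins$meth_A, plus$bins$meth_A + minus$bins$meth_A)
})

test_that("a minus-strand gene's metagene profile mirrors the plus-strand one", {
  set.seed(33)
  calls <- data.frame(read_id = "r1", ref = "chr1",
                      pos = sample(0:2999, 2000, TRUE), strand = "+",
                      prob = 0.5, methylated = runif(2000) > 0.5)
  tr <- methylation_ratio_track(calls, 3000)
  gp <- data.frame(gene_id = "g+", chrom = "chr1", strand = "+",
                   tss = 1500L, tes = 2500L, expression = NA_real_)
  gm <- transform(gp, gene_id = "g-", strand = "-")
  pp <- metagene_profile(tr, gp, flank = 500)
  pm <- metagene_profile(tr, gm, flank = 500)
  expect_equal(pm$value, rev(pp$value))
})

test_that("depth normalization makes profiles invariant to read duplication", {
  set.seed(34)
  calls <- data.frame(read_id = "r1", ref = "chr1",
                      pos = sample(0:2999, 1500, TRUE), strand = "+",
                      prob = 0.5, methylated = runif(1500) > 0.4)
  dup <- rbind(calls, transform(calls, read_id = "r1_copy"))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 1500L, tes = 2500L, expression = NA_real_)
  tr1 <- methylation_ratio_track(calls, 3000)
  tr2 <- methylation_ratio_track(dup, 3000)
  p1 <- metagene_profile(list(tr1, tr1), genes)
  p2 <- metagene_profile(list(tr1, tr2), genes)
  expect_equal(p1$value, p2$value)
})

test_that("expression strata follow the 25/75 rank rule with tie promotion", {
  g <- function(e) data.frame(gene_id = sprintf("g%d", seq_along(e)),
                              chrom = "chr1", strand = "+", tss = 0L,
                              tes = 10L, expression = e)
  expect_equal(expression_strata(g(c(10, 7, 3, 1))),
               c("high", "medium", "medium", "low"))
  expect_equal(expression_strata(g(rep(5, 6))), rep("high", 6))
  expect_error(expression_strata(g(c(1, 2, 3))), "at least 4")
  expect_warning(s <- expression_strata(g(c(4, 3, 2, 1, NA))), "excluded")
  expect_true(is.na(s[5]))
})

test_that("single-molecule window posteriors behave as a Bayesian aggregate", {
  fit <- circaccess:::.mixture_fit(c(0.5, 0.5), c(0.45, 0.85), c(0.05, 0.08),
                                   0.65, 0, 1L, TRUE, NA_character_, 1000L)
  mk <- function(probs, start = 0L) {
    data.frame(read_id = "r1", ref = "chr1",
               pos = start + 5L * (seq_along(probs) - 1L), strand = "+",
               prob = probs)
  }
  # all probabilities at the signal mean -> decisively open
  w <- single_molecule_windows(mk(rep(0.85, 10)), fit)
  expect_equal(w$state, "open")
  expect_gt(w$posterior, 0.99)
  # all at the noise mean -> closed
  w2 <- single_molecule_windows(mk(rep(0.45, 10)), fit)
  expect_equal(w2$state, "closed")
  # below min_A -> no_call with undefined posterior
  w3 <- single_molecule_windows(mk(0.85), fit, min_A = 2)
  expect_equal(w3$state, "no_call")
  expect_true(is.na(w3$posterior))
  expect_error(single_molecule_windows(mk(rep(0.85, 5)), NULL), "mixture_fit")
})

test_that("the tied posterior resolves to closed and is monotone in any p_i", {
  # symmetric components: a probability midway gives equal densities
  fit <- circaccess:::.mixture_fit(c(0.5, 0.5), c(0.4, 0.8), c(0.06, 0.06),
                                   0.6, 0, 1L, TRUE, NA_character_, 1000L)
  mk <- function(probs) data.frame(read_id = "r1", ref = "chr1",
                                   pos = 5L * (seq_along(probs) - 1L),
                                   strand = "+", prob = probs)
  w <- single_molecule_windows(mk(rep(0.6, 5)), fit)
  expect_equal(w$posterior, 0.5)
  expect_equal(w$state, "closed")
  # raising any single probability never decreases the open posterior
  base <- c(0.5, 0.55, 0.6, 0.65, 0.7)
  p0 <- single_molecule_windows(mk(base), fit)$posterior
  for (i in seq_along(base)) {
    for (delta in c(0.05, 0.15, 0.25)) {
      p <- base; p[i] <- p[i] + delta
      expect_gte(single_molecule_windows(mk(p), fit)$posterior, p0)
    }
  }
})

test_that("regional accessibility is count-weighted, not a mean of bins", {
  calls <- rbind(toy_calls(rep(1, 4), start = 0L, spacing = 10L),
                 toy_calls(c(rep(0, 11), 1), start = 100L, spacing = 10L,
                           read_id = "r2"))
  expect_equal(mean_accessibility(calls), 5 / 16)
  expect_equal(mean_accessibility(calls, start = 0, end = 40), 1.0)
  # differs from the unweighted mean of bin ratios in general
  tr <- methylation_ratio_track(calls, 250, bin = 50, step = 50)
  bin_mean <- mean(tr$bins$ratio[tr$bins$total_A > 0])
  expect_false(isTRUE(all.equal(bin_mean, 5 / 16)))
  expect_warning(v <- mean_accessibility(calls, start = 5000, end = 6000),
                 "no adenosine")
  expect_true(is.na(v))
})

test_that("junction profiles report elevated openness at the junction", {
  set.seed(36)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 8000, replace = TRUE), collapse = "")))
  ref <- build_circular_reference(genome,
                                  list(chrom = "chr1", start = 1000, end = 7000),
                                  pad = 100)
  apos <- as.integer(gregexpr("A", as.character(genome[[1]]))[[1]]) - 1L
  apos <- apos[apos >= 1000 & apos < 7000]
  cpos <- liftover_from_genome(ref, "chr1", apos)
  d <- junction_distance(ref, cpos)
  # open within 200 bp of the junction, closed elsewhere
  calls <- data.frame(read_id = "r1", ref = ref$name, pos = cpos, strand = "+",
                      prob = 0.5, methylated = abs(d) <= 200)
  prof <- junction_profile(calls, list(ref), flank = 1000)
  expect_equal(sort(names(prof)), c("n", "offset", "value"))
  expect_lt(abs(profile_peak_position(prof)), 100)
  expect_error(junction_profile(calls[0, ], list(ref)), "no calls")
})
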