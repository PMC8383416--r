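# Synthetic data generator with known ground truth.
#
# Emulates a methyltransferase-footprinting long-read experiment at desk
# scale: a random genome with genes, an alternating nucleosome/linker
# chromatin landscape with optional nucleosome-depleted regions (NDRs) at
# TSSs, simple single-locus excision circles, long reads (junction-spanning
# reads emit head-to-tail outward split alignments), and per-base m6A
# probabilities drawn from distinct open/closed distributions. Every module
# downstream is testable against the returned truth.

#' Simulation configuration
#'
#' Defaults describe the scaled-down study conditions: a 100 kb genome at
#' 30x depth with 5-50 kb reads, five excision circles, a 147/50 bp
#' nucleosome/linker array with 300 bp NDRs at TSSs, a noise probability
#' peak at mean 0.49 and a signal peak at mean 0.85.
#'
#' Two circle-sampling modes are provided. `"coverage"` (default) sequences
#' every circle to the same target depth as the genome, emulating the
#' exonuclease enrichment of circular molecules; `"fraction"` draws each
#' read from a circle with probability `ecdna_read_frac` (default 0.009,
#' the circular share of reads observed after enrichment), reproducing the
#' published read split directly.
#'
#' @param seed Integer seed driving all randomness.
#' @param genome_len Genome length in bp (default 100000, one chromosome).
#' @param n_genes Number of non-overlapping genes (default 10).
#' @param gene_len Gene length in bp (default 2000).
#' @param nucleosome_len,linker_len Chromatin array unit in bp (defaults
#'   147 and 50).
#' @param chromatin `"array"` (default) for the nucleosome/linker tiling,
#'   `"uniform_open"` or `"uniform_closed"` for featureless landscapes.
#' @param ndr_at_tss Carve an open NDR at each TSS (default `TRUE`).
#' @param ndr_width NDR width in bp (default 300).
#' @param n_ecdna Number of excision circles (default 5).
#' @param ecdna_size_range Circle sizes in bp (default `c(3000, 10000)`).
#' @param ecdna_sampling `"coverage"` or `"fraction"` (see above).
#' @param ecdna_read_frac Circle read fraction for `"fraction"` sampling
#'   (default 0.009).
#' @param read_len_range Read lengths in bp (default `c(5000, 50000)`;
#'   circle reads are capped at the circle size).
#' @param coverage Mean sequencing depth (default 30).
#' @param noise_mean,noise_sd Closed-chromatin probability distribution
#'   (defaults 0.49 and 0.05).
#' @param signal_mean,signal_sd Open-chromatin probability distribution
#'   (defaults 0.85 and 0.08).
#' @param strand_asymmetry Offset subtracted from the minus-strand signal
#'   mean (default 0).
#' @param breakpoint_jitter Uniform +/- jitter in bp applied to emitted
#'   alignment breakpoints (default 0).
#' @param prob_model `"gaussian"` (default, matches the analysis model) or
#'   `"beta"` (moment-matched Beta draws, for mis-specification checks).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 7L, genome_len = 100000L, n_genes = 10L,
                       gene_len = 2000L, nucleosome_len = 147L,
                       linker_len = 50L,
                       chromatin = c("array", "uniform_open", "uniform_closed"),
                       ndr_at_tss = TRUE, ndr_width = 300L,
                       n_ecdna = 5L, ecdna_size_range = c(3000L, 10000L),
                       ecdna_sampling = c("coverage", "fraction"),
                       ecdna_read_frac = 0.009,
                       read_len_range = c(5000L, 50000L), coverage = 30,
                       noise_mean = 0.49, noise_sd = 0.05,
                       signal_mean = 0.85, signal_sd = 0.08,
                       strand_asymmetry = 0, breakpoint_jitter = 0L,
                       prob_model = c("gaussian", "beta")) {
  chromatin <- match.arg(chromatin)
  ecdna_sampling <- match.arg(ecdna_sampling)
  prob_model <- match.arg(prob_model)
  stopifnot(genome_len > 0, n_genes >= 0, gene_len > 0,
            nucleosome_len > 0, linker_len > 0, ndr_width > 0,
            n_ecdna >= 0, ecdna_size_range[1] <= ecdna_size_range[2],
            ecdna_read_frac >= 0, ecdna_read_frac <= 1,
            read_len_range[1] <= read_len_range[2], coverage > 0,
            signal_mean > noise_mean, noise_sd > 0, signal_sd > 0,
            breakpoint_jitter >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a genome, genes and a chromatin truth landscape
#'
#' The sequence is i.i.d. uniform ACGT on one chromosome (`chr1`). Genes
#' are placed non-overlapping in equal slots with alternating strands and
#' log-normal expression. The chromatin mask alternates open linkers and
#' closed nucleosomes from coordinate 0; NDRs of `ndr_width` centered at
#' each TSS override the tiling. Truth dyads are reported only for
#' nucleosomes untouched by an NDR.
#'
#' @param config A [sim_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `genes`
#'   (data.frame), `mask` (named list of per-position logical open masks),
#'   `dyads` (named list of integer dyad positions), `ndr` (data.frame of
#'   NDR intervals).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  L <- config$genome_len
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(seq, "chr1"))

  genes <- NULL
  if (config$n_genes > 0) {
    margin <- 600L
    slot <- (L - 2L * margin) %/% config$n_genes
    if (slot <= config$gene_len) stop("genes cannot be placed: genome too small")
    starts <- vapply(seq_len(config$n_genes), function(i) {
      lo <- margin + (i - 1L) * slot
      lo + sample.int(slot - config$gene_len, 1L)
    }, integer(1))
    strand <- rep(c("+", "-"), length.out = config$n_genes)
    genes <- data.frame(
      gene_id = sprintf("gene_%02d", seq_len(config$n_genes)),
      chrom = "chr1", strand = strand,
      tss = ifelse(strand == "+", starts, starts + config$gene_len),
      tes = ifelse(strand == "+", starts + config$gene_len, starts),
      expression = round(stats::rlnorm(config$n_genes, meanlog = 2, sdlog = 1), 3),
      stringsAsFactors = FALSE)
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), tss = integer(), tes = integer(),
                        expression = numeric(), stringsAsFactors = FALSE)
  }

  unit <- config$linker_len + config$nucleosome_len
  mask <- rep(TRUE, L)   # open
  dyads <- integer(0)
  if (config$chromatin == "array") {
    nuc_starts <- seq(config$linker_len, L - 1L, by = unit)
    nuc_starts <- nuc_starts[nuc_starts + config$nucleosome_len <= L]
    for (s in nuc_starts) mask[(s + 1L):(s + config$nucleosome_len)] <- FALSE
    dyads <- as.integer(nuc_starts + config$nucleosome_len %/% 2)
  } else if (config$chromatin == "uniform_closed") {
    mask[] <- FALSE
  }
  ndr <- data.frame(chrom = character(), start = integer(), end = integer())
  if (config$ndr_at_tss && nrow(genes) > 0 && config$chromatin == "array") {
    half <- config$ndr_width %/% 2L
    ndr <- data.frame(chrom = "chr1",
                      start = pmax(0L, genes$tss - half),
                      end = pmin(L, genes$tss + half))
    for (i in seq_len(nrow(ndr))) {
      mask[(ndr$start[i] + 1L):ndr$end[i]] <- TRUE
    }
    # a dyad whose nucleosome intersects an NDR is no longer a truth dyad
    half_nuc <- config$nucleosome_len %/% 2L
    keep <- vapply(dyads, function(d) {
      !any(d + half_nuc > ndr$start & d - half_nuc < ndr$end)
    }, logical(1))
    dyads <- dyads[keep]
  }
  list(genome = genome, genes = genes,
       mask = list(chr1 = mask), dyads = list(chr1 = dyads), ndr = ndr)
}

#' Simulate excision-circle truth records
#'
#' Places `n_ecdna` non-overlapping circles with uniform random loci and
#' sizes in `ecdna_size_range`, away from the genome ends.
#'
#' @param config A [sim_config()].
#' @param genome The simulated genome (for bounds).
#' @return Data.frame with `chrom`, `start`, `end`, `size`.
#' @export
simulate_ecdna_events <- function(config, genome) {
  set.seed(config$seed + 1L)
  L <- length(genome[[1]])
  chrom <- names(genome)[1]
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    size = integer(), stringsAsFactors = FALSE)
  if (config$n_ecdna == 0L) return(out)
  placed <- 0L; tries <- 0L
  while (placed < config$n_ecdna) {
    if ((tries <- tries + 1L) > 1000L * config$n_ecdna) {
      stop("simulate_ecdna_events: cannot place circles (genome too crowded)")
    }
    size <- as.integer(round(runif(1, config$ecdna_size_range[1],
                                   config$ecdna_size_range[2])))
    if (size >= L) next
    start <- as.integer(floor(runif(1, 0, L - size)))
    end <- start + size
    if (nrow(out) == 0L || all(end <= out$start | start >= out$end)) {
      out <- rbind(out, data.frame(chrom = chrom, start = start, end = end,
                                   size = size, stringsAsFactors = FALSE))
      placed <- placed + 1L
    }
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Moment-matched probability draws for one read's positions.
.draw_probs <- function(n, mu, sdev, model) {
  if (model == "gaussian") {
    p <- rnorm(n, mu, sdev)
  } else {
    v <- sdev^2
    a <- mu * (mu * (1 - mu) / v - 1)
    b <- (1 - mu) * (mu * (1 - mu) / v - 1)
    p <- stats::rbeta(n, pmax(a, 0.01), pmax(b, 0.01))
  }
  pmin(pmax(p, 0), 1)
}

#' Simulate long reads, split alignments and per-base m6A probabilities
#'
#' Linear reads emit one alignment segment; circle reads enter at a uniform
#' point and, when they cross the head-to-tail junction, emit two segments
#' in same-strand outward orientation. At every adenosine of the read's
#' template strand (reference `A` for `+` reads, `T` for `-` reads) a
#' probability is drawn from the signal distribution if the chromatin mask
#' is open there, else from the noise distribution, clamped to \[0, 1\].
#' `strand_asymmetry` lowers the minus-strand signal mean. Breakpoint
#' jitter (if configured) perturbs only the emitted alignment coordinates,
#' emulating alignment wobble.
#'
#' @param config A [sim_config()].
#' @param genome The simulated genome.
#' @param truth Output of [simulate_genome()] (chromatin mask) — only the
#'   `mask` element is used.
#' @param ecdna Circle truth from [simulate_ecdna_events()].
#' @return List with `segments` (alignment table), `modcalls` (per-read
#'   call table) and `reads` (per-read truth: source, circle, entry,
#'   length, strand, crosses_junction).
#' @export
simulate_reads <- function(config, genome, truth, ecdna) {
  set.seed(config$seed + 2L)
  chrom <- names(genome)[1]
  L <- length(genome[[1]])
  seqstr <- as.character(genome[[1]])
  apos <- as.integer(gregexpr("A", seqstr, fixed = TRUE)[[1]]) - 1L
  tpos <- as.integer(gregexpr("T", seqstr, fixed = TRUE)[[1]]) - 1L
  mask <- truth$mask[[chrom]]

  mean_len <- mean(config$read_len_range)
  n_linear <- max(1L, as.integer(round(config$coverage * L / mean_len)))
  n_circ <- integer(nrow(ecdna))
  if (nrow(ecdna) > 0) {
    if (config$ecdna_sampling == "coverage") {
      for (i in seq_len(nrow(ecdna))) {
        cap <- mean(pmin(seq(config$read_len_range[1], config$read_len_range[2],
                             length.out = 101), ecdna$size[i]))
        n_circ[i] <- max(1L, as.integer(ceiling(config$coverage * ecdna$size[i] / cap)))
      }
    } else {
      n_total <- as.integer(round(n_linear / (1 - config$ecdna_read_frac)))
      n_ec <- n_total - n_linear
      if (n_ec > 0) {
        alloc <- sample.int(nrow(ecdna), n_ec, replace = TRUE)
        n_circ <- tabulate(alloc, nbins = nrow(ecdna))
      }
    }
  }

  segs <- list(); calls <- list(); reads <- list()
  rid <- 0L
  emit_calls <- function(read_id, s, e, strand) {
    pos <- if (strand == "+") {
      apos[apos >= s & apos < e]
    } else {
      tpos[tpos >= s & tpos < e]
    }
    if (length(pos) == 0L) return(NULL)
    open <- mask[pos + 1L]
    smean <- config$signal_mean -
      if (strand == "-") config$strand_asymmetry else 0
    mu <- ifelse(open, smean, config$noise_mean)
    sdev <- ifelse(open, config$signal_sd, config$noise_sd)
    data.table::data.table(read_id = read_id, ref = chrom, pos = pos,
                           strand = strand,
                           prob = .draw_probs(length(pos), mu, sdev,
                                              config$prob_model))
  }

  for (i in seq_len(n_linear)) {
    rid <- rid + 1L
    read_id <- sprintf("read_%05d", rid)
    len <- as.integer(round(runif(1, config$read_len_range[1],
                                  config$read_len_range[2])))
    len <- min(len, L)
    start <- as.integer(floor(runif(1, 0, L - len + 1)))
    strand <- sample(c("+", "-"), 1L)
    segs[[length(segs) + 1L]] <- data.table::data.table(
      read_id = read_id, read_start = 0L, read_end = len,
      chrom = chrom, ref_start = start, ref_end = start + len,
      strand = strand)
    calls[[length(calls) + 1L]] <- emit_calls(read_id, start, start + len, strand)
    reads[[length(reads) + 1L]] <- data.table::data.table(
      read_id = read_id, source = "linear", circle = NA_integer_,
      entry = start, length = len, strand = strand,
      crosses_junction = FALSE)
  }

  # Genome intervals covered by a circle read, in read order. In circle
  # coordinates a + read covers [entry, entry+len) mod size; a - read walks
  # backwards and covers [entry-len, entry) mod size, higher offsets first.
  circle_read_intervals <- function(cs, size, entry, len, strand) {
    if (strand == "+") {
      p1 <- c(entry, min(entry + len, size))
      pieces <- if (entry + len > size) rbind(p1, c(0L, entry + len - size)) else rbind(p1)
    } else {
      p1 <- c(max(entry - len, 0L), entry)
      pieces <- if (entry - len < 0L) rbind(p1, c(size - (len - entry), size)) else rbind(p1)
    }
    pieces <- pieces[pieces[, 2] > pieces[, 1], , drop = FALSE]
    pieces + cs
  }

  for (ci in seq_len(nrow(ecdna))) {
    cs <- ecdna$start[ci]; size <- ecdna$size[ci]
    for (i in seq_len(n_circ[ci])) {
      rid <- rid + 1L
      read_id <- sprintf("read_%05d", rid)
      len <- as.integer(round(runif(1, config$read_len_range[1],
                                    config$read_len_range[2])))
      len <- min(len, size)   # at most one junction crossing
      entry <- as.integer(floor(runif(1, 0, size)))
      strand <- sample(c("+", "-"), 1L)
      iv <- circle_read_intervals(cs, size, entry, len, strand)
      widths <- iv[, 2] - iv[, 1]
      ends <- cumsum(widths)
      segs[[length(segs) + 1L]] <- data.table::data.table(
        read_id = read_id,
        read_start = as.integer(ends - widths), read_end = as.integer(ends),
        chrom = chrom,
        ref_start = as.integer(iv[, 1]), ref_end = as.integer(iv[, 2]),
        strand = strand)
      for (p in seq_len(nrow(iv))) {
        calls[[length(calls) + 1L]] <- emit_calls(read_id, iv[p, 1], iv[p, 2],
                                                  strand)
      }
      reads[[length(reads) + 1L]] <- data.table::data.table(
        read_id = read_id, source = "ecdna", circle = ci,
        entry = entry, length = len, strand = strand,
        crosses_junction = nrow(iv) == 2L)
    }
  }

  segments <- data.table::rbindlist(segs)
  if (config$breakpoint_jitter > 0) {
    j <- config$breakpoint_jitter
    segments$ref_start <- pmax(0L, segments$ref_start +
                                 sample(-j:j, nrow(segments), replace = TRUE))
    segments$ref_end <- pmin(L, segments$ref_end +
                               sample(-j:j, nrow(segments), replace = TRUE))
    segments <- segments[segments$ref_end > segments$ref_start, ]
  }
  list(segments = segments[],
       modcalls = data.table::rbindlist(calls)[],
       reads = data.table::rbindlist(reads)[])
}

#' Simulate a control (untreated) probability sample
#'
#' Draws pure-noise probabilities — the background an unmethylated control
#' produces — for specificity evaluation.
#'
#' @param config A [sim_config()].
#' @param n Number of values (default 50000).
#' @return Numeric vector of probabilities.
#' @export
simulate_control_probs <- function(config, n = 50000L) {
  set.seed(config$seed + 3L)
  .draw_probs(n, config$noise_mean, config$noise_sd, config$prob_model)
}

#' Run the full simulation
#'
#' Genome + genes + chromatin truth, circle truth, then reads, alignments
#' and mod calls; deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `config`, `genome`, `genes`, `mask`, `dyads`, `ndr`,
#'   `ecdna`, `segments`, `modcalls`, `reads`.
#' @export
simulate_ccda <- function(config = sim_config()) {
  gen <- simulate_genome(config)
  ecdna <- simulate_ecdna_events(config, gen$genome)
  rds <- simulate_reads(config, gen$genome, gen, ecdna)
  c(list(config = config), gen, list(ecdna = ecdna), rds)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' FASTA genome, alignment TSV, mod-call TSV, gene BED (score = expression)
#' and a truth JSON.
#'
#' @param sim Output of [simulate_ccda()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fasta"))
  write_alignment_table(sim$segments, file.path(dir, "alignments.tsv"))
  write_modcall_table(sim$modcalls, file.path(dir, "modcalls.tsv"))
  g <- sim$genes
  if (nrow(g) > 0) {
    bed <- data.frame(chrom = g$chrom, start = pmin(g$tss, g$tes),
                      end = pmax(g$tss, g$tes), name = g$gene_id,
                      score = g$expression, strand = g$strand)
    data.table::fwrite(bed, file.path(dir, "genes.bed"), sep = "\t",
                       col.names = FALSE)
  }
  write_json_report(list(
    seed = sim$config$seed,
    ecdna = sim$ecdna,
    dyads = sim$dyads,
    n_reads = nrow(sim$reads)), file.path(dir, "truth.json"))
  invisible(dir)
}
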