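# Shared simulated datasets, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

# The default study conditions: 100 kb genome, 5 circles, 30x, seed 7.
default_sim <- function() cached("default", simulate_ccda(sim_config(seed = 7)))

default_fit <- function() {
  cached("default_fit", fit_probability_mixture(default_sim()$modcalls$prob))
}

# A small simulated dataset written to disk in the pipeline's input
# formats, plus a matching control sample.
pipeline_inputs <- function() {
  cached("pipeline_inputs", {
    dir <- file.path(tempdir(), "circaccess-pipeline-sim")
    sim <- simulate_ccda(sim_config(
      seed = 7, genome_len = 30000L, n_genes = 4L, n_ecdna = 2L,
      ecdna_size_range = c(3000L, 5000L), read_len_range = c(3000L, 10000L),
      coverage = 10))
    write_simulation(sim, dir)
    ctl <- data.frame(read_id = "ctl", ref = "chr1",
                      pos = sim$modcalls$pos[seq_len(5000)], strand = "+",
                      prob = simulate_control_probs(sim$config, 5000))
    write_modcall_table(ctl, file.path(dir, "control.tsv"))
    list(dir = dir, sim = sim)
  })
}

pipeline_cfg <- function(dir, ...) {
  run_config(genome_fasta = file.path(dir, "genome.fasta"),
             alignments = file.path(dir, "alignments.tsv"),
             modcalls = file.path(dir, "modcalls.tsv"),
             control_modcalls = file.path(dir, "control.tsv"),
             genes_bed = file.path(dir, "genes.bed"),
             cutoff = "fit", min_reads = 3, ...)
}

# Small deterministic mod-call table: n adenosine calls on one read,
# evenly spaced, with the given methylated flags.
toy_calls <- function(flags, start = 0L, spacing = 5L, read_id = "r1",
                      ref = "chr1", strand = "+") {
  n <- length(flags)
  data.frame(read_id = read_id, ref = ref,
             pos = start + spacing * (seq_len(n) - 1L),
             strand = strand, prob = ifelse(flags, 0.9, 0.1),
             methylated = as.logical(flags), stringsAsFactors = FALSE)
}
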