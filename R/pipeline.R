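# End-to-end pipeline: detect -> cluster -> circular references -> cutoff ->
# binarize -> tracks -> metagene -> molecule windows -> COA, with a
# deterministic JSON manifest.

#' Pipeline run configuration
#'
#' Collects input paths and the analysis parameters with their standard
#' defaults. `cutoff = "fit"` derives the threshold from the mixture fit;
#' a numeric value (e.g. the canonical 0.53) bypasses the fit.
#'
#' @param genome_fasta,alignments,modcalls Paths to the three mandatory
#'   inputs.
#' @param control_modcalls Optional control mod-call table (enables
#'   sensitivity/specificity reporting, and is required when
#'   `cutoff = "fit"` only for that evaluation).
#' @param genes_bed Optional BED6 gene annotation (enables metagene
#'   profiles); column 5 is taken as expression.
#' @param min_seg_len,size_range,cluster_tol Junction-calling parameters
#'   (defaults 1000 bp, `c(50, 100000)` bp, 50 bp).
#' @param pad,rotation Circular-reference parameters (defaults 10000 bp and
#'   `NULL` = junction centered).
#' @param cutoff `"fit"` or a numeric probability (default 0.53).
#' @param bin,step Track bin width and step (defaults 50 and 5 bp).
#' @param flank Metagene half-width (default 500 bp).
#' @param window,min_reads Single-molecule window size and COA coverage
#'   minimum (defaults 200 bp and 5).
#' @param seed Seed for any stochastic step (default 1).
#' @return A `run_config` list.
#' @export
run_config <- function(genome_fasta, alignments, modcalls,
                       control_modcalls = NULL, genes_bed = NULL,
                       min_seg_len = 1000, size_range = c(50, 100000),
                       cluster_tol = 50, pad = 10000, rotation = NULL,
                       cutoff = 0.53, bin = 50, step = 5, flank = 500,
                       window = 200, min_reads = 5, seed = 1L) {
  if (identical(cutoff, "fit")) {
    if (is.null(control_modcalls)) {
      stop("run_config: cutoff = \"fit\" requires a control mod-call table ",
           "(the background-noise sample)")
    }
  } else {
    stopifnot(is.numeric(cutoff), cutoff > 0, cutoff < 1)
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage on file inputs and writes results plus a manifest
#' (`manifest.json`: parameters, per-stage record counts, md5 checksums of
#' outputs) to `out_dir`. Reruns with identical inputs and config produce
#' byte-identical outputs. A stage failure writes a `FAILED` marker naming
#' the stage, keeps partial outputs, and raises an error.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "circaccess",
                   version = as.character(utils::packageVersion("circaccess")),
                   parameters = config[!vapply(config, is.null, logical(1))],
                   stages = list())
  state <- new.env(parent = emptyenv())
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      writeLines(sprintf("stage %s: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      .write_manifest(manifest, out_dir)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(status = "ok"), res$report)
    res$value
  }

  state$genome <- stage("read_inputs", function() {
    g <- read_genome_fasta(config$genome_fasta)
    state$segments <- read_alignment_table(config$alignments)
    state$calls <- read_modcall_table(config$modcalls)
    state$control <- if (!is.null(config$control_modcalls))
      read_modcall_table(config$control_modcalls) else NULL
    state$genes <- if (!is.null(config$genes_bed))
      read_gene_bed(config$genes_bed, score_as_expression = TRUE) else NULL
    list(value = g,
         report = list(n_segments = nrow(state$segments),
                       n_modcalls = nrow(state$calls),
                       n_genes = if (is.null(state$genes)) 0L else nrow(state$genes)))
  })

  state$records <- stage("detect_ecdna", function() {
    cand <- detect_junctions(state$segments, min_seg_len = config$min_seg_len,
                             size_range = config$size_range)
    recs <- cluster_junctions(cand, tolerance = config$cluster_tol)
    write_ecdna_bed(recs, file.path(out_dir, "ecdna.bed"))
    write_json_report(
      lapply(seq_len(nrow(recs)), function(i) {
        list(name = sprintf("ecdna_%d", i), chrom = recs$chrom[i],
             start = recs$start[i], end = recs$end[i],
             support = recs$support[i], read_ids = recs$read_ids[[i]])
      }), file.path(out_dir, "ecdna_records.json"))
    list(value = recs,
         report = list(n_candidates = nrow(cand), n_records = nrow(recs)))
  })

  state$refs <- stage("build_references", function() {
    refs <- if (nrow(state$records) > 0) {
      build_circular_references(state$genome, state$records,
                                rotation = config$rotation, pad = config$pad)
    } else list()
    if (length(refs)) {
      write_circular_references(refs, file.path(out_dir, "circular_refs.fasta"),
                                file.path(out_dir, "circular_refs.json"))
    }
    list(value = refs, report = list(n_references = length(refs)))
  })

  state$fit <- stage("fit_cutoff", function() {
    fit <- fit_probability_mixture(state$calls$prob, seed = config$seed)
    cutoff <- if (identical(config$cutoff, "fit")) {
      if (!fit$converged) stop("mixture fit did not converge: ", fit$diagnostic)
      fit$cutoff
    } else config$cutoff
    evaluation <- if (!is.null(state$control) && fit$converged) {
      evaluate_cutoff(fit, state$calls$prob, state$control$prob, cutoff)
    } else NULL
    write_mixture_report(fit, file.path(out_dir, "mixture.json"),
                         evaluation = evaluation)
    state$cutoff <- cutoff
    list(value = fit,
         report = c(list(cutoff = cutoff, converged = fit$converged),
                    evaluation))
  })

  state$bcalls <- stage("binarize", function() {
    b <- binarize_calls(state$calls, cutoff = state$cutoff)
    list(value = b, report = list(n_methylated = sum(b$methylated)))
  })

  stage("tracks", function() {
    chrom <- names(state$genome)[1]
    ccalls <- state$bcalls[state$bcalls$ref == chrom, ]
    n <- 0L
    for (sm in c("both", "plus", "minus")) {
      tr <- methylation_ratio_track(ccalls, length(state$genome[[chrom]]),
                                    bin = config$bin, step = config$step,
                                    strand_mode = sm)
      write_bedgraph(tr, file.path(out_dir, sprintf("track_%s_%s.bedgraph",
                                                    chrom, sm)))
      if (sm == "both") state$track <- tr
      n <- n + sum(tr$bins$total_A > 0)
    }
    list(value = NULL, report = list(n_covered_bins = n))
  })

  stage("metagene", function() {
    if (is.null(state$genes) || nrow(state$genes) == 0L) {
      return(list(value = NULL, report = list(skipped = "no gene annotation")))
    }
    for (anchor in c("TSS", "TES")) {
      prof <- metagene_profile(state$track, state$genes, anchor = anchor,
                               flank = config$flank)
      data.table::fwrite(prof, file.path(out_dir, sprintf("metagene_%s.tsv",
                                                          tolower(anchor))),
                         sep = "\t")
    }
    list(value = NULL, report = list(n_genes = nrow(state$genes)))
  })

  stage("junction_profile", function() {
    if (length(state$refs) == 0L) {
      return(list(value = NULL, report = list(skipped = "no ecDNA records")))
    }
    ecreads <- unique(unlist(lapply(seq_len(nrow(state$records)),
                                    function(i) state$records$read_ids[[i]])))
    jc <- as.data.frame(state$bcalls)
    jc <- jc[jc$read_id %in% ecreads, , drop = FALSE]
    parts <- list()
    for (rn in names(state$refs)) {
      cref <- state$refs[[rn]]
      sub <- jc[jc$ref == cref$origin_chrom & jc$pos >= cref$origin_start &
                  jc$pos < cref$origin_end, , drop = FALSE]
      if (nrow(sub) == 0L) next
      sub$pos <- liftover_from_genome(cref, sub$ref, sub$pos)
      sub$ref <- rn
      parts[[rn]] <- sub
    }
    if (length(parts) == 0L) {
      return(list(value = NULL, report = list(skipped = "no junction coverage")))
    }
    jprof <- junction_profile(data.table::rbindlist(parts), state$refs,
                              flank = 2000, bin = config$bin,
                              step = config$step)
    data.table::fwrite(jprof, file.path(out_dir, "junction_profile.tsv"),
                       sep = "\t")
    list(value = NULL, report = list(n_offsets = nrow(jprof)))
  })

  stage("coaccessibility", function() {
    if (!state$fit$converged) {
      return(list(value = NULL, report = list(skipped = "no converged fit")))
    }
    chrom <- names(state$genome)[1]
    mc <- molecule_windows(state$calls[state$calls$ref == chrom, ], state$fit,
                           window = config$window)
    data.table::fwrite(mc, file.path(out_dir, "molecule_windows.tsv"),
                       sep = "\t")
    mat <- coaccessibility_matrix(mc, w = config$window, N = config$min_reads)
    write_coa_table(mat, file.path(out_dir, "coa.tsv"))
    list(value = NULL,
         report = list(n_windows = length(mat$window_starts),
                       n_defined = sum(is.finite(mat$values))))
  })

  .write_manifest(manifest, out_dir)
  invisible(manifest)
}

.write_manifest <- function(manifest, out_dir) {
  outs <- sort(setdiff(list.files(out_dir), c("manifest.json", "FAILED")))
  sums <- tools::md5sum(file.path(out_dir, outs))
  manifest$outputs <- as.list(setNames(unname(sums), outs))
  write_json_report(manifest, file.path(out_dir, "manifest.json"))
}
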