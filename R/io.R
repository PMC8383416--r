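# Readers/writers for the package's external representations.
# Conventions: every table is TSV with a header; all coordinates 0-based
# half-open; probabilities serialized at 4 decimals.

MODCALL_COLS   <- c("read_id", "ref", "pos", "strand", "prob")
ALIGNMENT_COLS <- c("read_id", "read_start", "read_end",
                    "chrom", "ref_start", "ref_end", "strand")

#' Read a genome (or circular-reference) FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that truncates
#' sequence names at the first whitespace, as aligners do.
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write sequences to FASTA
#'
#' @param seqs A named [Biostrings::DNAStringSet], or a named character
#'   vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read a per-read modified-base call table
#'
#' Expects a TSV with header `read_id  ref  pos  strand  prob`: one row per
#' adenosine on one read, `pos` a 0-based reference coordinate and `prob`
#' the caller's m6A probability in \[0, 1\]. When a genome is supplied,
#' every call is checked to sit on an adenine of its strand (reference base
#' `A` for `+` calls, `T` for `-` calls).
#'
#' @param path Path to the TSV.
#' @param genome Optional [Biostrings::DNAStringSet] for base validation.
#' @return A `data.table` with columns `read_id`, `ref`, `pos`, `strand`,
#'   `prob`.
#' @export
read_modcall_table <- function(path, genome = NULL) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!identical(names(dt), MODCALL_COLS)) {
    stop("mod-call table header must be: ", paste(MODCALL_COLS, collapse = "\t"),
         " (got: ", paste(names(dt), collapse = "\t"), ")")
  }
  for (col in c("read_id", "ref", "strand")) dt[[col]] <- as.character(dt[[col]])
  if (nrow(dt) == 0L) return(dt)
  if (!is.numeric(dt$pos) || !is.numeric(dt$prob)) {
    stop("mod-call table: 'pos' and 'prob' must be numeric")
  }
  .check_rows(!is.finite(dt$prob) | dt$prob < 0 | dt$prob > 1,
              "prob outside [0,1]")
  .check_rows(dt$pos < 0 | dt$pos != floor(dt$pos), "pos must be a non-negative integer")
  .check_rows(!dt$strand %in% c("+", "-"), "strand must be '+' or '-'")
  dt$pos <- as.integer(dt$pos)
  if (!is.null(genome)) validate_modcall_bases(dt, genome)
  dt[]
}

# Raise a line-numbered parse error (line 1 is the header).
.check_rows <- function(bad, what) {
  if (any(bad)) {
    stop(sprintf("%s at line %d", what, which(bad)[1] + 1L))
  }
}

validate_modcall_bases <- function(calls, genome) {
  for (r in unique(calls$ref)) {
    if (!r %in% names(genome)) stop("reference '", r, "' absent from genome")
    sub <- calls[calls$ref == r, ]
    if (any(sub$pos >= length(genome[[r]]))) {
      stop("mod call beyond end of reference '", r, "'")
    }
    seqstr <- as.character(genome[[r]])
    base <- substring(seqstr, sub$pos + 1L, sub$pos + 1L)
    want <- ifelse(sub$strand == "+", "A", "T")
    if (any(base != want & base != "N")) {
      i <- which(base != want & base != "N")[1]
      stop(sprintf("call at %s:%d (%s) is not on an adenine of its strand",
                   r, sub$pos[i], sub$strand[i]))
    }
  }
  invisible(TRUE)
}

#' Write a per-read modified-base call table
#'
#' Probabilities are serialized at 4 decimal places, so a write/read
#' round-trip reproduces the collection to that precision.
#'
#' @param calls A data.frame with the mod-call columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modcall_table <- function(calls, path) {
  calls <- data.table::as.data.table(calls)[, MODCALL_COLS, with = FALSE]
  calls$prob <- sprintf("%.4f", calls$prob)
  data.table::fwrite(calls, path, sep = "\t")
  invisible(path)
}

#' Read a split-alignment segment table
#'
#' TSV with header `read_id  read_start  read_end  chrom  ref_start
#' ref_end  strand`: one row per mapped block of a long read. Read and
#' reference intervals are 0-based half-open; each must have length >= 1.
#'
#' @param path Path to the TSV.
#' @return A `data.table` of segments.
#' @export
read_alignment_table <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!identical(names(dt), ALIGNMENT_COLS)) {
    stop("alignment table header must be: ", paste(ALIGNMENT_COLS, collapse = "\t"))
  }
  for (col in c("read_id", "chrom", "strand")) dt[[col]] <- as.character(dt[[col]])
  if (nrow(dt) == 0L) return(dt)
  .check_rows(dt$read_start >= dt$read_end, "read_start must be < read_end")
  .check_rows(dt$ref_start >= dt$ref_end, "ref_start must be < ref_end")
  .check_rows(!dt$strand %in% c("+", "-"), "strand must be '+' or '-'")
  for (col in c("read_start", "read_end", "ref_start", "ref_end")) {
    dt[[col]] <- as.integer(dt[[col]])
  }
  dt[]
}

#' @rdname read_alignment_table
#' @param segments A data.frame of segments to write.
#' @export
write_alignment_table <- function(segments, path) {
  segments <- data.table::as.data.table(segments)[, ALIGNMENT_COLS, with = FALSE]
  data.table::fwrite(segments, path, sep = "\t")
  invisible(path)
}

#' Read gene annotations from BED6 or GFF
#'
#' BED input must carry at least 6 columns (strand is required). The TSS is
#' always the transcription start: for `+` genes `tss = start`, `tes = end`;
#' for `-` genes `tss = end`, `tes = start` (0-based half-open convention,
#' so a `-` TSS is the exclusive end coordinate). GFF input (1-based,
#' inclusive) is converted to the same convention; the feature `ID`/`Name`
#' attribute, or the raw attribute string, becomes the gene id.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` (default) or `"gff"`.
#' @param score_as_expression For BED input, treat column 5 as a per-gene
#'   expression value (default `FALSE`, expression left `NA`).
#' @return A `data.table` with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `tes`, `expression`.
#' @export
read_gene_bed <- function(path, format = c("bed", "gff"),
                          score_as_expression = FALSE) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(gene_id = character(), chrom = character(),
                                  strand = character(), tss = integer(),
                                  tes = integer(), expression = numeric()))
  }
  if (format == "bed") {
    if (ncol(dt) < 6L) stop("BED input needs >= 6 columns (strand required)")
    out <- data.table::data.table(
      gene_id = as.character(dt[[4]]), chrom = as.character(dt[[1]]),
      strand = as.character(dt[[6]]),
      start = as.integer(dt[[2]]), end = as.integer(dt[[3]]),
      expression = if (score_as_expression) as.numeric(dt[[5]]) else NA_real_)
  } else {
    if (ncol(dt) < 9L) stop("GFF input needs 9 columns")
    attr_id <- sub(";.*$", "", sub("^.*(ID|Name|gene_id)[=\" ]+([^;\"]+).*$", "\\2",
                                   as.character(dt[[9]])))
    out <- data.table::data.table(
      gene_id = attr_id, chrom = as.character(dt[[1]]),
      strand = as.character(dt[[7]]),
      start = as.integer(dt[[4]]) - 1L, end = as.integer(dt[[5]]),
      expression = NA_real_)
  }
  if (any(!out$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-' (line ",
         which(!out$strand %in% c("+", "-"))[1], ")")
  }
  out$tss <- ifelse(out$strand == "+", out$start, out$end)
  out$tes <- ifelse(out$strand == "+", out$end, out$start)
  out[, c("gene_id", "chrom", "strand", "tss", "tes", "expression"), with = FALSE]
}

#' Write an accessibility track as bedGraph
#'
#' Emits 4 columns (chrom, start, end, value), 0-based half-open. Bins with
#' undefined ratio (no covered adenosines) are omitted. Input bins must be
#' sorted by (chrom, start) with each chromosome contiguous.
#'
#' @param track A `binned_track` (see [methylation_ratio_track()]) or a
#'   data.frame with columns `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  if (inherits(track, "binned_track")) {
    df <- data.frame(chrom = track$ref, start = track$bins$start,
                     end = track$bins$end, value = track$bins$ratio)
  } else {
    df <- as.data.frame(track)[, c("chrom", "start", "end", "value")]
  }
  runs <- rle(df$chrom)
  if (anyDuplicated(runs$values)) stop("bedGraph bins: chromosomes interleaved")
  unsorted <- tapply(df$start, factor(df$chrom, levels = runs$values), is.unsorted)
  if (any(unlist(unsorted))) {
    stop("bedGraph bins must be sorted by start within each chromosome")
  }
  keep <- is.finite(df$value)
  df <- df[keep, , drop = FALSE]
  df$value <- sprintf("%.6g", df$value)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write an ecDNA record catalog as BED
#'
#' One line per clustered circle: `chrom start end ecdna_<k> support strand`
#' (strand reported as `.`; a circle has no strand of its own).
#'
#' @param records ecDNA records from [cluster_junctions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecdna_bed <- function(records, path) {
  if (nrow(records) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  df <- data.frame(chrom = records$chrom, start = records$start,
                   end = records$end,
                   name = sprintf("ecdna_%d", seq_len(nrow(records))),
                   score = records$support, strand = ".")
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a JSON report
#'
#' Deterministic (no timestamps), `auto_unbox`ed JSON used for mixture fits,
#' pipeline manifests and QC summaries.
#'
#' @param x A list to serialize.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
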