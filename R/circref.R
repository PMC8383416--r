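# Circular reference construction and coordinate liftover.
#
# Aligning junction-spanning reads to the linear genome loses methylation
# calls near the head-to-tail junction. Each detected circle therefore gets
# its own reference: the genomic interval rotated so the junction sits
# mid-sequence, with a run of N appended to both ends to keep long reads
# mappable. All coordinates are 0-based.

#' Build a rotated, padded reference sequence for one circle
#'
#' The core sequence is `rotate(genome[start:end], rotation)` where `rotate`
#' moves the first `rotation` bases to the end; the head-to-tail junction
#' therefore sits at core offset `size - rotation`. `pad` N characters are
#' appended to each end. The default rotation centers the junction
#' (`floor(size/2)`), so windowed scoring has full context on both sides.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param rec A list or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open genome interval of the circle).
#' @param rotation Offset of the sequence start relative to `start`, in
#'   `[0, size)`. Default `floor(size/2)`.
#' @param pad Number of N bases appended to each end (default 10000).
#' @param name Reference name (default `"<chrom>_<start>_<end>"` prefixed
#'   with `"circ_"`).
#' @return A `circular_reference`: list with `name`, `origin_chrom`,
#'   `origin_start`, `origin_end`, `size`, `rotation`, `pad`, `seq`.
#' @export
build_circular_reference <- function(genome, rec, rotation = NULL,
                                     pad = 10000, name = NULL) {
  chrom <- as.character(rec$chrom)
  start <- as.integer(rec$start); end <- as.integer(rec$end)
  if (!chrom %in% names(genome)) stop("chromosome '", chrom, "' not in genome")
  clen <- length(genome[[chrom]])
  if (start < 0 || end > clen || start >= end) {
    stop(sprintf("circle interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, clen))
  }
  size <- end - start
  if (is.null(rotation)) rotation <- size %/% 2L
  rotation <- as.integer(rotation)
  if (rotation < 0 || rotation >= size) stop("rotation must lie in [0, size)")
  stopifnot(pad >= 0)
  core <- as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
  rotated <- if (rotation == 0L) core else
    paste0(substr(core, rotation + 1L, size), substr(core, 1L, rotation))
  structure(list(name = if (is.null(name)) sprintf("circ_%s_%d_%d", chrom, start, end) else name,
                 origin_chrom = chrom, origin_start = start, origin_end = end,
                 size = size, rotation = rotation, pad = as.integer(pad),
                 seq = paste0(strrep("N", pad), rotated, strrep("N", pad))),
            class = "circular_reference")
}

#' @export
print.circular_reference <- function(x, ...) {
  cat(sprintf("<circular_reference> %s: %s:%d-%d (size %d bp, rotation %d, pad %d)\n",
              x$name, x$origin_chrom, x$origin_start, x$origin_end,
              x$size, x$rotation, x$pad))
  invisible(x)
}

#' Map circular-reference positions back to the genome
#'
#' Vectorized. Positions inside the N pads map to `NA`; core positions map
#' through the inverse rotation. Positions outside `[0, len(seq))` raise an
#' error.
#'
#' @param ref A `circular_reference`.
#' @param pos 0-based positions on the padded, rotated sequence.
#' @return A data.frame with columns `chrom` and `genome_pos` (`NA` rows for
#'   pad positions).
#' @export
liftover_to_genome <- function(ref, pos) {
  len <- 2L * ref$pad + ref$size
  if (any(pos < 0 | pos >= len)) stop("position out of range [0, ", len, ")")
  core <- pos - ref$pad
  in_core <- core >= 0 & core < ref$size
  gpos <- rep(NA_integer_, length(pos))
  gpos[in_core] <- ref$origin_start +
    as.integer((core[in_core] + ref$rotation) %% ref$size)
  data.frame(chrom = ifelse(in_core, ref$origin_chrom, NA_character_),
             genome_pos = gpos, stringsAsFactors = FALSE)
}

#' Map genome positions onto a circular reference
#'
#' Inverse of [liftover_to_genome()]: genome positions inside the circle's
#' origin interval map to core positions of the padded, rotated sequence;
#' positions outside map to `NA`.
#'
#' @param ref A `circular_reference`.
#' @param chrom Chromosome name(s) of the genome positions.
#' @param genome_pos 0-based genome coordinates.
#' @return Integer vector of sequence positions (`NA` where unmappable).
#' @export
liftover_from_genome <- function(ref, chrom, genome_pos) {
  inside <- chrom == ref$origin_chrom &
    genome_pos >= ref$origin_start & genome_pos < ref$origin_end
  out <- rep(NA_integer_, length(genome_pos))
  rel <- genome_pos[inside] - ref$origin_start
  out[inside] <- ref$pad + as.integer((rel - ref$rotation) %% ref$size)
  out
}

#' Signed circular distance to the head-to-tail junction
#'
#' For a core position of a circular reference, returns the signed distance
#' in bp to the junction point along the circle, in
#' `(-size/2, size/2]`; positive values are downstream of the junction in
#' the direction of increasing sequence coordinate (the antipode reports
#' `+size/2`). Pad positions raise an error.
#'
#' @param ref A `circular_reference`.
#' @param pos 0-based sequence positions (vectorized).
#' @return Integer vector of signed distances.
#' @export
junction_distance <- function(ref, pos) {
  core <- pos - ref$pad
  if (any(core < 0 | core >= ref$size)) {
    stop("junction_distance: position outside the circle core")
  }
  j <- (ref$size - ref$rotation) %% ref$size
  d <- (core - j) %% ref$size
  over <- d > ref$size / 2
  d[over] <- d[over] - ref$size
  as.integer(d)
}

#' Build references for a whole ecDNA catalog
#'
#' Convenience wrapper: one [build_circular_reference()] per record, named
#' `circ_1 ... circ_k` in catalog order.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param records ecDNA catalog from [cluster_junctions()].
#' @inheritParams build_circular_reference
#' @return Named list of `circular_reference` objects.
#' @export
build_circular_references <- function(genome, records, rotation = NULL,
                                      pad = 10000) {
  refs <- lapply(seq_len(nrow(records)), function(i) {
    build_circular_reference(genome, records[i, ], rotation = rotation,
                             pad = pad, name = sprintf("circ_%d", i))
  })
  setNames(refs, vapply(refs, `[[`, character(1), "name"))
}

#' Write circular references as FASTA plus a JSON liftover sidecar
#'
#' @param refs Named list of `circular_reference` objects.
#' @param fasta_path,json_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_circular_references <- function(refs, fasta_path, json_path) {
  seqs <- setNames(vapply(refs, `[[`, character(1), "seq"),
                   vapply(refs, `[[`, character(1), "name"))
  write_genome_fasta(seqs, fasta_path)
  meta <- lapply(refs, function(r) {
    r[c("name", "origin_chrom", "origin_start", "origin_end",
        "size", "rotation", "pad")]
  })
  write_json_report(unname(meta), json_path)
  invisible(fasta_path)
}
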