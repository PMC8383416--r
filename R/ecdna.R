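# ecDNA calling from split long-read alignments.
#
# A read that traverses the head-to-tail junction of a circle aligns as two
# same-chromosome, same-strand segments in *outward* orientation: the
# segment later in read order maps upstream (+ strand) / downstream
# (- strand) of the earlier one, because the read runs off the circle's
# reference end and re-enters at its reference start.

#' Classify one ordered segment pair as a circle junction
#'
#' Applies the four junction criteria to a pair of mapped blocks of the same
#' read: (1) both segments longer than `min_seg_len` (strict, on both the
#' read and the reference span); (2) same chromosome; (3) same strand;
#' (4) outward orientation. The segment earlier on the read is identified by
#' `read_start`; pairs overlapping on the read by more than
#' `max_read_overlap` bp are rejected (supplementary-alignment trimming can
#' produce small overlaps, which are tolerated).
#'
#' @param a,b Single segments (one-row data.frames or lists) with fields
#'   `read_id`, `read_start`, `read_end`, `chrom`, `ref_start`, `ref_end`,
#'   `strand`. They must share `read_id`.
#' @param min_seg_len Minimum segment length in bp, strict (default 1000).
#' @param max_read_overlap Tolerated overlap of the two segments on the read
#'   in bp (default 100).
#' @return A one-row data.frame (`read_id`, `chrom`, `strand`,
#'   `circle_start`, `circle_end`, `size`) or `NULL` if any criterion fails.
#' @export
classify_pair <- function(a, b, min_seg_len = 1000, max_read_overlap = 100) {
  if (!identical(as.character(a$read_id), as.character(b$read_id))) {
    stop("classify_pair: segments belong to different reads")
  }
  if (a$read_start > b$read_start) { tmp <- a; a <- b; b <- tmp }
  # overlap on the read beyond slack -> not a usable split
  if (a$read_end - b$read_start > max_read_overlap) return(NULL)
  seg_ok <- function(s) {
    (s$read_end - s$read_start) > min_seg_len &&
      (s$ref_end - s$ref_start) > min_seg_len
  }
  if (!seg_ok(a) || !seg_ok(b)) return(NULL)
  if (!identical(as.character(a$chrom), as.character(b$chrom))) return(NULL)
  if (!identical(as.character(a$strand), as.character(b$strand))) return(NULL)
  outward <- if (a$strand == "+") b$ref_end <= a$ref_start
             else                 b$ref_start >= a$ref_end
  if (!outward) return(NULL)
  cs <- min(a$ref_start, b$ref_start)
  ce <- max(a$ref_end, b$ref_end)
  data.frame(read_id = as.character(a$read_id), chrom = as.character(a$chrom),
             strand = as.character(a$strand),
             circle_start = as.integer(cs), circle_end = as.integer(ce),
             size = as.integer(ce - cs), stringsAsFactors = FALSE)
}

#' Detect per-read circle-junction candidates
#'
#' Groups segments by read, orders them along the read, evaluates every
#' consecutive pair with [classify_pair()], and keeps at most one candidate
#' per read: the qualifying pair with the largest combined read-segment
#' length (ties broken by smaller `circle_start`). Candidates whose implied
#' circle size falls outside `size_range` are dropped.
#'
#' @param segments Segment table (see [read_alignment_table()]).
#' @param min_seg_len Minimum segment length, strict (default 1000 bp).
#' @param size_range Allowed circle sizes in bp (default `c(50, 100000)`).
#' @param max_read_overlap Passed to [classify_pair()].
#' @return A data.frame of junction candidates (possibly empty) with columns
#'   `read_id`, `chrom`, `strand`, `circle_start`, `circle_end`, `size`.
#' @export
detect_junctions <- function(segments, min_seg_len = 1000,
                             size_range = c(50, 100000),
                             max_read_overlap = 100) {
  empty <- data.frame(read_id = character(), chrom = character(),
                      strand = character(), circle_start = integer(),
                      circle_end = integer(), size = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(segments) || nrow(segments) < 2L) return(empty)
  segments <- as.data.frame(segments)
  out <- vector("list", 0L)
  for (rid in unique(segments$read_id)) {
    segs <- segments[segments$read_id == rid, , drop = FALSE]
    if (nrow(segs) < 2L) next
    segs <- segs[order(segs$read_start, segs$read_end), , drop = FALSE]
    best <- NULL; best_len <- -1L
    for (i in seq_len(nrow(segs) - 1L)) {
      a <- segs[i, ]; b <- segs[i + 1L, ]
      cand <- classify_pair(a, b, min_seg_len, max_read_overlap)
      if (is.null(cand)) next
      comb <- (a$read_end - a$read_start) + (b$read_end - b$read_start)
      if (comb > best_len ||
          (comb == best_len && cand$circle_start < best$circle_start)) {
        best <- cand; best_len <- comb
      }
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  if (length(out) == 0L) return(empty)
  cand <- do.call(rbind, out)
  cand <- cand[cand$size >= size_range[1] & cand$size <= size_range[2], ,
               drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Cluster junction candidates into an ecDNA catalog
#'
#' Single-linkage clustering of candidates on the same chromosome: two
#' candidates are linked when both breakpoints differ by at most
#' `tolerance` bp. Each cluster becomes one record with breakpoints at the
#' lower median of member breakpoints and support equal to the number of
#' distinct reads.
#'
#' @param candidates Output of [detect_junctions()].
#' @param tolerance Breakpoint matching tolerance in bp (default 50).
#' @return A data.frame with columns `chrom`, `start`, `end`, `support` and
#'   a list-column `read_ids`, sorted by (chrom, start).
#' @export
cluster_junctions <- function(candidates, tolerance = 50) {
  stopifnot(tolerance >= 0)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      support = integer(), stringsAsFactors = FALSE)
  empty$read_ids <- list()
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty)
  candidates <- as.data.frame(candidates)
  recs <- list()
  for (chr in unique(candidates$chrom)) {
    cc <- candidates[candidates$chrom == chr, , drop = FALSE]
    cc <- cc[order(cc$circle_start, cc$circle_end), , drop = FALSE]
    n <- nrow(cc)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) {
      j <- i + 1L
      # sorted by start, so linkage partners lie within tolerance ahead
      while (j <= n && cc$circle_start[j] - cc$circle_start[i] <= tolerance) {
        if (abs(cc$circle_end[j] - cc$circle_end[i]) <= tolerance) {
          parent[find(j)] <- find(i)
        }
        j <- j + 1L
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (k in unique(comp)) {
      m <- cc[comp == k, , drop = FALSE]
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = chr,
        start = lower_median(m$circle_start),
        end = lower_median(m$circle_end),
        support = length(unique(m$read_id)),
        stringsAsFactors = FALSE)
      recs[[length(recs)]]$read_ids <- list(unique(m$read_id))
    }
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Lower median: middle element of the sorted vector, taking the lower of the
# two central values for even lengths.
lower_median <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}

#' Match detected ecDNA records against a truth catalog
#'
#' Utility used in validation: a detected record matches a truth record when
#' both lie on the same chromosome and both breakpoints agree within
#' `tolerance` bp. Returns recall and precision over 1:1 greedy matches.
#'
#' @param detected,truth Data.frames with `chrom`, `start`, `end`.
#' @param tolerance Breakpoint tolerance in bp (default 50).
#' @return A list with `recall`, `precision`, `n_matched`.
#' @export
match_ecdna_records <- function(detected, truth, tolerance = 50) {
  if (nrow(truth) == 0L) {
    return(list(recall = NA_real_,
                precision = if (nrow(detected)) 0 else NA_real_,
                n_matched = 0L))
  }
  used <- rep(FALSE, nrow(detected))
  matched <- 0L
  for (i in seq_len(nrow(truth))) {
    hit <- which(!used &
                 detected$chrom == truth$chrom[i] &
                 abs(detected$start - truth$start[i]) <= tolerance &
                 abs(detected$end - truth$end[i]) <= tolerance)
    if (length(hit)) { used[hit[1]] <- TRUE; matched <- matched + 1L }
  }
  list(recall = matched / nrow(truth),
       precision = if (nrow(detected)) sum(used) / nrow(detected) else NA_real_,
       n_matched = matched)
}
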