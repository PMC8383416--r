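# Bulk and single-molecule accessibility profiles.
#
# The bulk accessibility score of a bin is the pooled methylation ratio:
# m6A bases in all covered reads in the bin over adenosine bases in all
# covered reads in the bin. Bins are 50 bp wide and slide by 5 bp, tiled
# from coordinate 0. Single-molecule states come from a Bayesian
# aggregation of raw per-base probabilities under the fitted mixture.

#' Methylation-ratio accessibility track
#'
#' Counts, per sliding bin, the methylated and total adenosine calls pooled
#' over all covered reads, and reports their ratio. A call at position `x`
#' belongs to every bin with start `s` such that `s <= x < s + bin`; bins
#' are tiled from coordinate 0 with the given step. Bins without covered
#' adenosines carry an undefined (`NaN`) ratio.
#'
#' @param calls Binarized mod-call table (needs columns `ref`, `pos`,
#'   `strand`, `methylated`) on a single reference.
#' @param ref_length Length of the reference in bp.
#' @param bin Bin width in bp (default 50).
#' @param step Bin step in bp (default 5); `bin` must be a multiple of
#'   `step`.
#' @param strand_mode `"both"` (default) pools the strands, `"plus"`/
#'   `"minus"` restrict to calls on that strand.
#' @return A `binned_track`: list with `ref`, `bin`, `step`, `strand_mode`
#'   and a data.frame `bins` (`start`, `end`, `meth_A`, `total_A`, `ratio`).
#' @export
methylation_ratio_track <- function(calls, ref_length, bin = 50, step = 5,
                                    strand_mode = c("both", "plus", "minus")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(step > 0, bin >= step, bin %% step == 0, ref_length > 0)
  calls <- as.data.frame(calls)
  if (nrow(calls) > 0) {
    refs <- unique(calls$ref)
    if (length(refs) > 1L) {
      stop("methylation_ratio_track: calls span several references: ",
           paste(refs, collapse = ", "))
    }
    ref <- refs
  } else {
    ref <- NA_character_
  }
  if (strand_mode == "plus")  calls <- calls[calls$strand == "+", , drop = FALSE]
  if (strand_mode == "minus") calls <- calls[calls$strand == "-", , drop = FALSE]
  n_bins <- as.integer((ref_length - 1) %/% step + 1)
  starts <- (seq_len(n_bins) - 1L) * as.integer(step)
  k <- bin %/% step
  total <- integer(n_bins); meth <- integer(n_bins)
  if (nrow(calls) > 0) {
    if (!is.logical(calls$methylated)) {
      stop("calls must be binarized first (see binarize_calls)")
    }
    idx0 <- calls$pos %/% step
    for (j in 0:(k - 1L)) {
      idx <- idx0 - j
      keep <- idx >= 0L & idx < n_bins
      total <- total + tabulate(idx[keep] + 1L, nbins = n_bins)
      meth <- meth + tabulate(idx[keep & calls$methylated] + 1L, nbins = n_bins)
    }
  }
  bins <- data.frame(start = starts,
                     end = pmin(starts + as.integer(bin), as.integer(ref_length)),
                     meth_A = meth, total_A = total,
                     ratio = ifelse(total > 0, meth / total, NaN))
  structure(list(ref = ref, bin = as.integer(bin), step = as.integer(step),
                 strand_mode = strand_mode, bins = bins),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cov <- sum(x$bins$total_A > 0)
  cat(sprintf("<binned_track> %s: %d bins (%d/%d bp, strand=%s), %d covered, mean ratio %.3f\n",
              x$ref, nrow(x$bins), x$bin, x$step, x$strand_mode, cov,
              mean(x$bins$ratio[x$bins$total_A > 0])))
  invisible(x)
}

# Pool count vectors of several tracks sharing one reference grid,
# optionally rescaling each track's counts by its mean covered-bin depth so
# sources sequenced at different depths contribute equally.
pool_tracks <- function(tracks, depth_norm = TRUE) {
  stopifnot(length(tracks) >= 1L)
  t1 <- tracks[[1]]
  n <- nrow(t1$bins)
  meth <- numeric(n); total <- numeric(n)
  for (tr in tracks) {
    stopifnot(nrow(tr$bins) == n, tr$step == t1$step, tr$bin == t1$bin)
    scale <- 1
    if (depth_norm && length(tracks) > 1L) {
      d <- mean(tr$bins$total_A[tr$bins$total_A > 0])
      if (is.finite(d) && d > 0) scale <- 1 / d
    }
    meth <- meth + scale * tr$bins$meth_A
    total <- total + scale * tr$bins$total_A
  }
  list(start = t1$bins$start, meth = meth, total = total,
       step = t1$step, bin = t1$bin)
}

#' Metagene accessibility profile around TSS or TES
#'
#' For each gene, samples the track's methylation ratio on a `step`-spaced
#' offset grid spanning `anchor +/- flank`, flipping minus-strand genes so
#' negative offsets are always transcription-upstream. The profile value at
#' each offset is the mean of per-gene ratios over genes with a defined
#' ratio there. The value at a position is taken from the sliding bin whose
#' center is nearest to it.
#'
#' When several tracks are given (e.g. an ecDNA pool and a linear pool on
#' the same reference grid) their counts are pooled after per-source depth
#' normalization: each source's counts are divided by its mean covered-bin
#' depth, so duplicating every read of a source leaves the profile
#' unchanged.
#'
#' @param track A `binned_track` or a list of them on one reference grid.
#' @param genes Gene table (see [read_gene_bed()]); only genes on the
#'   track's reference are used.
#' @param anchor `"TSS"` (default) or `"TES"`.
#' @param flank Half-width of the profile in bp (default 500); must be a
#'   multiple of the track step.
#' @param depth_norm Depth-normalize multiple sources (default `TRUE`).
#' @return A data.frame (`offset`, `value`, `n_genes`, `meth_A`, `total_A`)
#'   with attributes `anchor` and `stratum`; `meth_A`/`total_A` are the
#'   pooled (depth-scaled) counts behind each offset, whose ratio is the
#'   count-weighted alternative to the gene-mean `value`.
#' @export
metagene_profile <- function(track, genes, anchor = c("TSS", "TES"),
                             flank = 500, depth_norm = TRUE) {
  anchor <- match.arg(anchor)
  if (inherits(track, "binned_track")) track <- list(track)
  pooled <- pool_tracks(track, depth_norm = depth_norm)
  step <- pooled$step; bin <- pooled$bin
  stopifnot(flank %% step == 0)
  ref <- track[[1]]$ref
  genes <- as.data.frame(genes)
  genes <- genes[genes$chrom == ref, , drop = FALSE]
  if (nrow(genes) == 0L) stop("metagene_profile: no usable genes on ", ref)
  offsets <- seq(-flank, flank, by = step)
  acc <- matrix(NA_real_, nrow = nrow(genes), ncol = length(offsets))
  cnt <- matrix(0, nrow = nrow(genes), ncol = length(offsets))
  mcnt <- matrix(0, nrow = nrow(genes), ncol = length(offsets))
  n_bins <- length(pooled$start)
  for (g in seq_len(nrow(genes))) {
    a <- if (anchor == "TSS") genes$tss[g] else genes$tes[g]
    p <- if (genes$strand[g] == "+") a + offsets else a - offsets
    # nearest bin center: centers sit at s + bin/2, s a multiple of step
    s <- as.integer(round((p - bin / 2) / step)) * step
    idx <- s %/% step + 1L
    ok <- idx >= 1L & idx <= n_bins
    tot <- rep(NA_real_, length(offsets)); met <- tot
    tot[ok] <- pooled$total[idx[ok]]; met[ok] <- pooled$meth[idx[ok]]
    acc[g, ] <- ifelse(!is.na(tot) & tot > 0, met / tot, NA_real_)
    cnt[g, ok] <- pooled$total[idx[ok]]
    met[is.na(met)] <- 0
    mcnt[g, ] <- met
  }
  value <- colMeans(acc, na.rm = TRUE)
  n_genes <- colSums(!is.na(acc))
  value[n_genes == 0L] <- NA_real_
  if (all(n_genes == 0L)) stop("metagene_profile: no gene has covered bins")
  structure(data.frame(offset = offsets, value = value, n_genes = n_genes,
                       meth_A = colSums(mcnt), total_A = colSums(cnt)),
            anchor = anchor, stratum = "all")
}

#' Accessibility profile by distance to the circle junction
#'
#' Pools binarized calls on circular references by their signed distance to
#' the head-to-tail junction and reports the pooled methylation ratio in
#' sliding bins on a `step`-spaced distance grid.
#'
#' @param calls Binarized calls in circular-reference coordinates (column
#'   `ref` naming entries of `refs`).
#' @param refs Named list of `circular_reference` objects.
#' @param flank Maximum |distance| in bp (default 2000).
#' @param bin,step Bin width and grid spacing in bp (defaults 50 and 5).
#' @return A data.frame (`offset`, `value`, `n`) with attribute
#'   `anchor = "junction"`; `n` is the pooled adenosine count.
#' @export
junction_profile <- function(calls, refs, flank = 2000, bin = 50, step = 5) {
  if (inherits(refs, "circular_reference")) refs <- list(refs)
  if (is.null(names(refs))) {
    names(refs) <- vapply(refs, `[[`, character(1), "name")
  }
  calls <- as.data.frame(calls)
  calls <- calls[calls$ref %in% names(refs), , drop = FALSE]
  if (nrow(calls) == 0L) stop("junction_profile: no calls on the given references")
  d <- integer(nrow(calls))
  for (r in unique(calls$ref)) {
    i <- calls$ref == r
    d[i] <- junction_distance(refs[[r]], calls$pos[i])
  }
  keep <- abs(d) <= flank + bin
  d <- d[keep]; methylated <- calls$methylated[keep]
  if (length(d) == 0L) stop("junction_profile: no junction-proximal coverage")
  offsets <- seq(-flank, flank, by = step)
  value <- numeric(length(offsets)); n <- integer(length(offsets))
  for (o in seq_along(offsets)) {
    inbin <- d >= offsets[o] - bin %/% 2 & d < offsets[o] + bin %/% 2
    n[o] <- sum(inbin)
    value[o] <- if (n[o] > 0) mean(methylated[inbin]) else NA_real_
  }
  structure(data.frame(offset = offsets, value = value, n = n),
            anchor = "junction")
}

#' Stratify genes by expression rank
#'
#' Ranks genes by descending expression: the top 25% are `high`, ranks
#' 25–75% `medium`, the remainder `low`, with boundaries at
#' `ceiling(n * 0.25)` and `ceiling(n * 0.75)`. Tied expression values all
#' take the better stratum. Genes with missing expression are excluded with
#' a warning and return `NA`.
#'
#' @param genes Gene table with an `expression` column.
#' @return A character vector (`"high"`, `"medium"`, `"low"` or `NA`)
#'   aligned with the rows of `genes`.
#' @export
expression_strata <- function(genes) {
  genes <- as.data.frame(genes)
  expr <- genes$expression
  if (any(is.na(expr))) {
    warning(sum(is.na(expr)), " gene(s) without expression excluded from strata")
  }
  usable <- which(!is.na(expr))
  if (length(usable) < 4L) {
    stop("expression_strata: need at least 4 genes with expression values")
  }
  e <- expr[usable]
  ord <- order(-e)
  n <- length(e)
  k1 <- ceiling(n * 0.25); k2 <- ceiling(n * 0.75)
  base <- character(n)
  base[ord[seq_len(k1)]] <- "high"
  if (k2 > k1) base[ord[(k1 + 1):k2]] <- "medium"
  if (n > k2) base[ord[(k2 + 1):n]] <- "low"
  # ties share the better stratum
  rank_of <- c(high = 1L, medium = 2L, low = 3L)
  best <- tapply(rank_of[base], e, min)
  strat <- names(rank_of)[best[as.character(e)]]
  out <- rep(NA_character_, nrow(genes))
  out[usable] <- strat
  out
}

#' Single-molecule accessibility states over windows
#'
#' Bayesian aggregation of one read's raw m6A probabilities: within each
#' window the posterior that the window is open is
#' `prior * prod(f_open(p_i)) / (prior * prod(f_open(p_i)) +
#' (1 - prior) * prod(f_closed(p_i)))`, with `f_open`/`f_closed` the signal
#' and noise component densities of the fitted mixture, positions treated
#' as independent. A window is `open` iff the posterior exceeds 0.5 (a
#' posterior of exactly 0.5 is `closed`); windows where the read covers
#' fewer than `min_A` adenosines are `no_call`. Windows tile the reference
#' from coordinate 0 with width `window`.
#'
#' @param calls Mod-call table of a single read (raw probabilities).
#' @param fit A converged `mixture_fit`.
#' @param window Window width in bp (default 200, >= 50).
#' @param min_A Minimum adenosines per window for a call (default 2).
#' @param prior_open Prior probability that a window is open (default 0.5).
#' @return A data.frame with `read_id`, `ref`, `start`, `end`, `n_A`,
#'   `posterior`, `state`.
#' @export
single_molecule_windows <- function(calls, fit, window = 200, min_A = 2,
                                    prior_open = 0.5) {
  stopifnot(window >= 50, min_A >= 2, prior_open > 0, prior_open < 1)
  if (is.null(fit) || !inherits(fit, "mixture_fit")) {
    stop("single_molecule_windows: a mixture_fit is required")
  }
  calls <- as.data.frame(calls)
  stopifnot(length(unique(calls$read_id)) == 1L,
            length(unique(calls$ref)) == 1L)
  win <- as.integer(calls$pos %/% window)
  lo <- dnorm(calls$prob, fit$means[2], fit$sds[2], log = TRUE)
  lc <- dnorm(calls$prob, fit$means[1], fit$sds[1], log = TRUE)
  agg <- rowsum(cbind(lo, lc, 1), group = win)
  starts <- as.integer(rownames(agg)) * as.integer(window)
  n_A <- as.integer(agg[, 3])
  lpost_open <- log(prior_open) + agg[, 1]
  lpost_closed <- log(1 - prior_open) + agg[, 2]
  posterior <- 1 / (1 + exp(lpost_closed - lpost_open))
  state <- ifelse(posterior > 0.5, "open", "closed")
  no_call <- n_A < min_A
  state[no_call] <- "no_call"
  posterior[no_call] <- NA_real_
  out <- data.frame(read_id = calls$read_id[1], ref = calls$ref[1],
                    start = starts, end = starts + as.integer(window),
                    n_A = n_A, posterior = unname(posterior), state = state,
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Single-molecule window states for many reads
#'
#' Applies [single_molecule_windows()] per read on a common absolute window
#' grid and binds the results.
#'
#' @inheritParams single_molecule_windows
#' @param calls Mod-call table of one reference, many reads.
#' @return A data.frame of window calls for all reads.
#' @export
molecule_windows <- function(calls, fit, window = 200, min_A = 2,
                             prior_open = 0.5) {
  calls <- as.data.frame(calls)
  parts <- lapply(split(calls, calls$read_id), single_molecule_windows,
                  fit = fit, window = window, min_A = min_A,
                  prior_open = prior_open)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Pooled mean accessibility of a region
#'
#' The pooled methylated-over-total adenosine ratio of all calls in
#' `[start, end)` — a count-weighted average, which in general differs from
#' the unweighted mean of bin ratios.
#'
#' @param calls Binarized calls.
#' @param ref Reference to restrict to (default: all).
#' @param start,end Region bounds, 0-based half-open (defaults: all
#'   positions).
#' @return Ratio in \[0, 1\], or `NA` (with a warning) when the region
#'   contains no adenosine calls.
#' @export
mean_accessibility <- function(calls, ref = NULL, start = -Inf, end = Inf) {
  calls <- as.data.frame(calls)
  if (!is.null(ref)) calls <- calls[calls$ref == ref, , drop = FALSE]
  calls <- calls[calls$pos >= start & calls$pos < end, , drop = FALSE]
  if (nrow(calls) == 0L) {
    warning("mean_accessibility: region contains no adenosine calls")
    return(NA_real_)
  }
  mean(calls$methylated)
}

#' Position of a profile's maximum (plateau-aware)
#'
#' Accessibility profiles over a nucleosome-depleted region saturate, so
#' the literal argmax of a plateau is decided by sampling noise. The peak
#' position is therefore reported as the mean offset of all points within
#' `tol` (relative) of the maximum — the center of the maximal plateau,
#' which degenerates to the argmax for a sharp peak.
#'
#' @param profile A profile data.frame (`offset`, `value`).
#' @param tol Relative tolerance defining the plateau (default 1e-3).
#' @return The peak offset in bp.
#' @export
profile_peak_position <- function(profile, tol = 1e-3) {
  v <- profile$value
  top <- max(v, na.rm = TRUE)
  mean(profile$offset[!is.na(v) & v >= top * (1 - tol)])
}

#' Locate occupancy footprints as smoothed track minima
#'
#' Smooths the ratio with a centered running mean over `smooth_bp` and
#' returns the bin-center coordinates of local minima separated by at least
#' `min_separation` bp — nucleosome dyad candidates on a protection
#' landscape.
#'
#' @param track A `binned_track`.
#' @param smooth_bp Smoothing window in bp (default 100).
#' @param min_separation Minimum distance between reported minima in bp
#'   (default 120, just under a nucleosome footprint).
#' @return Integer vector of minima centers (bp).
#' @export
locate_track_minima <- function(track, smooth_bp = 100, min_separation = 120) {
  bins <- track$bins
  centers <- bins$start + track$bin / 2
  y <- bins$ratio
  hw <- max(1L, as.integer(round(smooth_bp / 2 / track$step)))
  n <- length(y)
  sm <- vapply(seq_len(n), function(i) {
    w <- y[max(1L, i - hw):min(n, i + hw)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  r <- max(1L, as.integer(round(min_separation / track$step)))
  is_min <- vapply(seq_len(n), function(i) {
    if (is.na(sm[i])) return(FALSE)
    w <- sm[max(1L, i - r):min(n, i + r)]
    sm[i] <= min(w, na.rm = TRUE)
  }, logical(1))
  # collapse runs of tied minima to their midpoint
  runs <- rle(is_min)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  mids <- floor((starts[runs$values] + ends[runs$values]) / 2)
  as.integer(centers[mids])
}
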