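# Single-molecule co-accessibility (COA).
#
# For two windows i and j and a molecule k spanning both with accessibility
# scores A_i, A_j, the per-molecule term is 1 - |A_i - A_j| / (A_i + A_j);
# COA(i,j) is the mean over the >= N spanning molecules. With binary A the
# term is an agreement indicator once the 0/0 case (both closed) is defined
# as 1 — the only convention under which COA(i,i) = 1 holds for closed
# windows.

#' Single-molecule co-accessibility matrix
#'
#' Computes COA between all window pairs on one reference from per-molecule
#' window calls (see [molecule_windows()]). An entry is defined only where
#' at least `N` molecules carry a defined (non-`no_call`) state in both
#' windows. With `mode = "binary"` (default) the accessibility score is the
#' 0/1 window state; with `mode = "continuous"` it is the open posterior.
#'
#' @param molecule_calls Window-call table for one reference; all calls
#'   must share one window grid (width `w`, phase 0).
#' @param w Window size in bp (default 200); must match the grid.
#' @param N Minimum number of spanning molecules per pair (default 5).
#' @param mode `"binary"` or `"continuous"`.
#' @return A `coa_matrix`: list with `ref`, `w`, `N`, `mode`,
#'   `window_starts`, `values` (symmetric matrix, `NA` where undefined)
#'   and `n_spanning` (matrix of spanning-molecule counts).
#' @export
coaccessibility_matrix <- function(molecule_calls, w = 200, N = 5,
                                   mode = c("binary", "continuous")) {
  mode <- match.arg(mode)
  stopifnot(N >= 1)
  mc <- as.data.frame(molecule_calls)
  stopifnot(length(unique(mc$ref)) == 1L)
  if (any(mc$end - mc$start != w) || any(mc$start %% w != 0)) {
    stop("coaccessibility_matrix: window grid does not match (w, phase 0)")
  }
  starts <- sort(unique(mc$start))
  reads <- unique(mc$read_id)
  A <- matrix(NA_real_, nrow = length(reads), ncol = length(starts),
              dimnames = list(reads, as.character(starts)))
  defined <- mc$state != "no_call"
  score <- if (mode == "binary") as.numeric(mc$state == "open") else mc$posterior
  A[cbind(match(mc$read_id, reads), match(mc$start, starts))[defined, ,
                                                             drop = FALSE]] <-
    score[defined]
  nw <- length(starts)
  values <- matrix(NA_real_, nw, nw)
  n_spanning <- matrix(0L, nw, nw)
  for (i in seq_len(nw)) {
    for (j in i:nw) {
      ok <- !is.na(A[, i]) & !is.na(A[, j])
      n <- sum(ok)
      n_spanning[i, j] <- n_spanning[j, i] <- n
      if (n >= N) {
        ai <- A[ok, i]; aj <- A[ok, j]
        denom <- ai + aj
        term <- ifelse(denom == 0, 1, 1 - abs(ai - aj) / denom)
        values[i, j] <- values[j, i] <- mean(term)
      }
    }
  }
  structure(list(ref = mc$ref[1], w = as.integer(w), N = as.integer(N),
                 mode = mode, window_starts = starts, values = values,
                 n_spanning = n_spanning),
            class = "coa_matrix")
}

#' @export
print.coa_matrix <- function(x, ...) {
  def <- sum(is.finite(x$values))
  cat(sprintf("<coa_matrix> %s: %d windows of %d bp (N>=%d, %s), %d defined entries\n",
              x$ref, length(x$window_starts), x$w, x$N, x$mode, def))
  invisible(x)
}

#' Mean co-accessibility by window separation
#'
#' Averages the defined off-diagonal entries of a COA matrix at each window
#' separation `d = |i - j|` (in windows). Also reports the background level
#' (mean COA at the largest available separation) and the largest
#' separation whose mean COA exceeds that background — the apparent range
#' of nucleosome-positioning correlation.
#'
#' @param mat A `coa_matrix`.
#' @return A data.frame (`separation`, `distance_bp`, `mean_coa`,
#'   `n_pairs`) with attributes `background` and `range_windows`.
#' @export
coa_summary_by_distance <- function(mat) {
  v <- mat$values
  nw <- length(mat$window_starts)
  off <- v[upper.tri(v)]
  if (sum(is.finite(off)) < 2L) {
    stop("coa_summary_by_distance: need at least 2 defined off-diagonal entries")
  }
  seps <- seq_len(nw - 1L)
  mean_coa <- rep(NA_real_, length(seps))
  n_pairs <- integer(length(seps))
  for (d in seps) {
    idx <- cbind(seq_len(nw - d), seq_len(nw - d) + d)
    vals <- v[idx]
    n_pairs[d] <- sum(is.finite(vals))
    if (n_pairs[d] > 0) mean_coa[d] <- mean(vals, na.rm = TRUE)
  }
  defined <- which(n_pairs > 0)
  background <- mean_coa[max(defined)]
  above <- defined[mean_coa[defined] > background]
  range_windows <- if (length(above)) max(above) else 0L
  structure(data.frame(separation = seps,
                       distance_bp = seps * mat$w,
                       mean_coa = mean_coa, n_pairs = n_pairs),
            background = background, range_windows = range_windows)
}

#' Write a COA matrix in long form
#'
#' TSV with columns `ref`, `start_i`, `start_j`, `coa`, `n` (defined
#' entries only, upper triangle including the diagonal).
#'
#' @param mat A `coa_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coa_table <- function(mat, path) {
  nw <- length(mat$window_starts)
  idx <- which(upper.tri(mat$values, diag = TRUE) & is.finite(mat$values),
               arr.ind = TRUE)
  df <- data.frame(ref = mat$ref,
                   start_i = mat$window_starts[idx[, 1]],
                   start_j = mat$window_starts[idx[, 2]],
                   coa = mat$values[idx],
                   n = mat$n_spanning[idx])
  df <- df[order(df$start_i, df$start_j), , drop = FALSE]
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
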