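# Independent oracles used to cross-check the implementation.

# Circular-traversal oracle for junction classification: a segment pair is
# a junction candidate iff a read walking around the circle defined by the
# union of the two reference intervals reproduces exactly segment a's
# positions followed by segment b's positions, AND the walk wraps across
# the circle's end (a non-wrapping walk is an ordinary colinear split).
oracle_classify_pair <- function(a, b, min_seg_len = 1000) {
  if (a$read_start > b$read_start) { tmp <- a; a <- b; b <- tmp }
  la_read <- a$read_end - a$read_start; lb_read <- b$read_end - b$read_start
  la <- a$ref_end - a$ref_start; lb <- b$ref_end - b$ref_start
  if (!(la > min_seg_len && lb > min_seg_len &&
        la_read > min_seg_len && lb_read > min_seg_len)) return(NULL)
  if (a$chrom != b$chrom || a$strand != b$strand) return(NULL)
  cs <- min(a$ref_start, b$ref_start); ce <- max(a$ref_end, b$ref_end)
  size <- ce - cs
  seq_of <- function(s) {
    if (s$strand == "+") s$ref_start:(s$ref_end - 1L) else (s$ref_end - 1L):s$ref_start
  }
  target <- c(seq_of(a), seq_of(b))
  # a two-segment junction read covers each circle position at most once
  if (length(target) > size) return(NULL)
  dir <- if (a$strand == "+") 1L else -1L
  o0 <- target[1] - cs
  walk <- ((o0 + dir * (seq_along(target) - 1L)) %% size) + cs
  if (!all(walk == target)) return(NULL)
  wrapped <- if (dir == 1L) o0 + length(target) > size else o0 - (length(target) - 1L) < 0L
  if (!wrapped) return(NULL)
  data.frame(chrom = a$chrom, strand = a$strand, circle_start = cs,
             circle_end = ce, size = size, stringsAsFactors = FALSE)
}

make_segment <- function(read_id, read_start, read_end, chrom,
                         ref_start, ref_end, strand) {
  data.frame(read_id = read_id, read_start = read_start, read_end = read_end,
             chrom = chrom, ref_start = ref_start, ref_end = ref_end,
             strand = strand, stringsAsFactors = FALSE)
}

# Closed-form crossover: equality of the weighted log-densities is a
# quadratic in x; return the smallest root in (m1, m2) at which the signal
# component overtakes the noise component, or NA when none exists.
oracle_crossover <- function(w, m, s) {
  A <- 1 / s[1]^2 - 1 / s[2]^2
  B <- -2 * (m[1] / s[1]^2 - m[2] / s[2]^2)
  C <- m[1]^2 / s[1]^2 - m[2]^2 / s[2]^2 + 2 * log((w[2] * s[1]) / (w[1] * s[2]))
  roots <- if (abs(A) < 1e-12) {
    if (abs(B) < 1e-12) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0) else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  g <- function(x) {
    (log(w[2]) + dnorm(x, m[2], s[2], log = TRUE)) -
      (log(w[1]) + dnorm(x, m[1], s[1], log = TRUE))
  }
  roots <- sort(roots[roots > m[1] & roots < m[2]])
  for (r in roots) {
    if (g(r - 1e-6) < 0 && g(r + 1e-6) > 0) return(r)
  }
  NA_real_
}

# Brute-force per-position bin recount for tracks.
oracle_track_counts <- function(calls, ref_length, bin = 50, step = 5) {
  starts <- seq(0L, ref_length - 1L, by = step)
  total <- integer(length(starts)); meth <- integer(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    inbin <- calls$pos >= s & calls$pos < s + bin
    total[i] <- sum(inbin)
    meth[i] <- sum(inbin & calls$methylated)
  }
  data.frame(start = starts, meth_A = meth, total_A = total)
}

# Exhaustive COA recomputation from a molecules x windows state matrix
# (values 0, 1 or NA).
oracle_coa <- function(A, N) {
  nw <- ncol(A)
  out <- matrix(NA_real_, nw, nw)
  for (i in seq_len(nw)) {
    for (j in seq_len(nw)) {
      terms <- c()
      for (k in seq_len(nrow(A))) {
        ai <- A[k, i]; aj <- A[k, j]
        if (is.na(ai) || is.na(aj)) next
        terms <- c(terms, if (ai + aj == 0) 1 else 1 - abs(ai - aj) / (ai + aj))
      }
      if (length(terms) >= N) out[i, j] <- mean(terms)
    }
  }
  out
}

# Turn a molecules x windows 0/1/NA state matrix into a molecule-call table.
states_to_calls <- function(A, w = 200, ref = "chr1") {
  starts <- (seq_len(ncol(A)) - 1L) * w
  rows <- list()
  for (k in seq_len(nrow(A))) {
    rows[[k]] <- data.frame(
      read_id = sprintf("m%02d", k), ref = ref,
      start = starts, end = starts + w, n_A = 10L,
      posterior = ifelse(is.na(A[k, ]), NA_real_, A[k, ]),
      state = ifelse(is.na(A[k, ]), "no_call",
                     ifelse(A[k, ] == 1, "open", "closed")),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
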