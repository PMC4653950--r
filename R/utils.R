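#' Centred running average
#'
#' Box smoothing over an odd window, the operation used throughout for
#' dyad-score tracks (21 bp) and incidence profiles (41 bp).  Windows are
#' truncated at the ends of the vector, so a constant input is returned
#' unchanged.  With `na.rm = TRUE`, `NA` entries are dropped from both the
#' numerator and the denominator, which is how masked offsets (for example
#' the MNase-biased stretch upstream of dyads) are imputed from their
#' neighbourhood.
#'
#' @param x numeric vector.
#' @param window odd integer window width in positions.
#' @param na.rm drop `NA`s from each window instead of propagating them.
#' @return numeric vector of `length(x)`.
#' @export
running_mean <- function(x, window = 21L, na.rm = FALSE) {
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  h <- (window - 1L) %/% 2L
  ok <- !is.na(x)
  vals <- x
  vals[!ok] <- 0
  cs <- c(0, cumsum(vals))
  cn <- c(0, cumsum(as.numeric(ok)))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  if (!na.rm) {
    # propagate NA wherever the window touched one
    full <- (hi - lo + 1L)
    out <- tot / full
    out[cnt < full] <- NA_real_
  } else {
    out <- tot / cnt
    out[cnt == 0] <- NA_real_
  }
  out
}

#' Rolling maximum over a centred window
#'
#' Doubling-trick sliding maximum; used by the stable-dyad peak caller, where
#' a peak must dominate every score within +/- `h` positions.
#'
#' @param x numeric vector.
#' @param h half-width of the window in positions.
#' @return vector `m` with `m[i] = max(x[max(1,i-h):min(n,i+h)])`.
#' @keywords internal
roll_max <- function(x, h) {
  n <- length(x)
  w <- 2L * as.integer(h) + 1L
  if (n == 0L || w <= 1L) return(x)
  # left-aligned maxima over the largest power of two <= w
  p <- 1L
  m <- x
  while (2L * p <= w) {
    shifted <- c(m[(p + 1L):n], rep(-Inf, p))
    m <- pmax(m, shifted)
    p <- 2L * p
  }
  # m[i] = max over [i, i+p-1]; combine two overlapping runs to cover width w
  lead <- function(v, k) if (k == 0L) v else c(v[(k + 1L):n], rep(-Inf, k))
  left_max <- pmax(m, lead(m, w - p))          # max over [i, i+w-1]
  # centre: window [i-h, i+h] = left-aligned window starting at i-h
  idx <- seq_len(n) - h
  res <- numeric(n)
  inside <- idx >= 1L
  res[inside] <- left_max[idx[inside]]
  if (any(!inside)) {
    # truncated leading windows
    for (i in which(!inside)) res[i] <- max(x[1:min(n, i + h)])
  }
  # truncated trailing windows are handled by the -Inf padding only if the
  # true maximum lies inside the vector, which it always does
  res
}

# deterministic per-module seed derivation: one user seed fans out to
# independent, reproducible streams for each generator stage
derive_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((as.numeric(seed) %% 65521 * 31013 + h * 1009 + 17) %% 2147483587)
}

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# complement of a character vector of bases (non-ACGT left untouched)
complement_bases <- function(b) {
  out <- DNA_COMPLEMENT[b]
  out[is.na(out)] <- b[is.na(out)]
  unname(out)
}

# genome string -> character vector of single bases
genome_chars <- function(genome) {
  if (length(genome) == 1L && nchar(genome) > 1L) {
    strsplit(genome, "", fixed = TRUE)[[1]]
  } else {
    genome
  }
}

strand_sign <- function(strand) ifelse(strand == "-", -1L, 1L)

# distance from each x to its nearest value in ref (ref need not be sorted);
# Inf when ref is empty
nearest_distance <- function(x, ref) {
  if (length(ref) == 0L) return(rep(Inf, length(x)))
  ref <- sort(ref)
  i <- findInterval(x, ref)
  lo <- ifelse(i >= 1L, ref[pmax(i, 1L)], -Inf)
  hi <- ifelse(i < length(ref), ref[pmin(i + 1L, length(ref))], Inf)
  pmin(abs(x - lo), abs(hi - x))
}
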