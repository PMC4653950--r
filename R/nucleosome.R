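# Nucleosome map: dyad-score tracks, mean core fragment length, stable
# dyads, first downstream dyads.

#' Build smoothed dyad-score tracks from nucleosome read anchors
#'
#' A forward read anchored at x marks a putative dyad at
#' x + floor((L-1)/2); a reverse read anchored at y (the fragment's other
#' cleavage end) marks y - floor((L-1)/2).  Raw per-strand dyad counts are
#' smoothed with a 21-bp running average; a combined track (forward +
#' reverse raw counts, then smoothed) is kept alongside the per-strand
#' tracks.
#'
#' @param reads data frame with columns `pos` (anchor) and `strand`.
#' @param genome_length track length in bp.
#' @param core_length assumed core length L (default 147, so the dyad
#'   offset is 73).
#' @param smooth_window running-average window in bp (odd; default 21).
#' @return object of class `dyad_track` with elements `raw` (`fwd`, `rev`
#'   integer vectors), `smooth` (`fwd`, `rev`, `all`), `core_length`,
#'   `window`, `genome_length`.
#' @export
compute_dyad_scores <- function(reads, genome_length, core_length = 147L,
                                smooth_window = 21L) {
  offset <- (as.integer(core_length) - 1L) %/% 2L
  fwd_pos <- reads$pos[reads$strand == "+"] + offset
  rev_pos <- reads$pos[reads$strand == "-"] - offset
  fwd_pos <- fwd_pos[fwd_pos >= 1L & fwd_pos <= genome_length]
  rev_pos <- rev_pos[rev_pos >= 1L & rev_pos <= genome_length]
  raw_fwd <- tabulate(fwd_pos, nbins = genome_length)
  raw_rev <- tabulate(rev_pos, nbins = genome_length)
  structure(list(
    raw = list(fwd = raw_fwd, rev = raw_rev),
    smooth = list(fwd = running_mean(raw_fwd, smooth_window),
                  rev = running_mean(raw_rev, smooth_window),
                  all = running_mean(raw_fwd + raw_rev, smooth_window)),
    core_length = as.integer(core_length),
    window = as.integer(smooth_window),
    genome_length = as.integer(genome_length)),
    class = "dyad_track")
}

#' @export
print.dyad_track <- function(x, ...) {
  cat("dyad_track:", x$genome_length, "bp,",
      sum(x$raw$fwd), "forward and", sum(x$raw$rev),
      "reverse dyad counts, core length", x$core_length, "\n")
  invisible(x)
}

#' Estimate the mean nucleosome core fragment length
#'
#' For each candidate length L, the fragment of a forward read anchored at
#' x spans \[x, x+L-1\] and that of a reverse read anchored at y spans
#' \[y-L+1, y\].  Excluding 30 bp at both fragment ends (where MNase
#' cleavage skews composition), the mean A/T-indicator vector over the
#' fragment interior is computed for each strand in fragment-left-to-right
#' orientation — for reverse reads the interior is read from the start
#' inferred under the candidate L, so the candidate aligns the two strands'
#' distributions.  The discrepancy is the mean squared difference of the
#' two vectors over the L-60 interior offsets; the optimal L minimizes it
#' (ties broken toward the smaller L).
#'
#' @param reads data frame with columns `pos` and `strand`; both strands
#'   must be represented.
#' @param genome genome string.
#' @param lengths candidate lengths (default 137:157, one helical turn
#'   around the canonical 147).
#' @param end_exclusion bases excluded at each fragment end (default 30).
#' @return object of class `fragment_length_result`: `optimal`,
#'   `discrepancy` (named by L), `v_plus`/`v_minus` at the optimum,
#'   `n_reads`, `n_skipped` (reads whose window ran off the genome).
#' @export
estimate_fragment_length <- function(reads, genome, lengths = 137:157,
                                     end_exclusion = 30L) {
  g <- genome_chars(genome)
  n <- length(g)
  at01 <- as.numeric(g %in% c("A", "T"))
  ex <- as.integer(end_exclusion)
  Lmax <- max(lengths)
  if (min(lengths) <= 2L * ex) stop("candidate lengths must exceed twice the ",
                                    "end exclusion")
  fx <- reads$pos[reads$strand == "+"]
  ry <- reads$pos[reads$strand == "-"]
  if (length(fx) == 0L || length(ry) == 0L) {
    stop("both strands must have at least one read")
  }
  # forward interiors reach x + Lmax - ex - 1; reverse reach y - Lmax + ex + 1
  keep_f <- fx + Lmax - ex - 1L <= n & fx >= 1L
  keep_r <- ry - Lmax + ex + 1L >= 1L & ry <= n
  n_skipped <- c(fwd = sum(!keep_f), rev = sum(!keep_r))
  fx <- fx[keep_f]
  ry <- ry[keep_r]
  if (length(fx) == 0L || length(ry) == 0L) {
    stop("no reads remain after removing those running off the genome")
  }
  # mean A/T incidence at each offset from the anchors
  f_off <- ex:(Lmax - ex - 1L)                       # from forward start
  r_off <- (-(Lmax - ex - 1L)):(-ex)                 # from reverse end
  m_fwd <- vapply(f_off, function(k) mean(at01[fx + k]), numeric(1))
  m_rev <- vapply(r_off, function(k) mean(at01[ry + k]), numeric(1))
  names(m_fwd) <- f_off
  names(m_rev) <- r_off
  disc <- vapply(lengths, function(L) {
    i <- 0:(L - 2L * ex - 1L)
    vp <- m_fwd[as.character(ex + i)]
    vm <- m_rev[as.character(-(L - ex - 1L) + i)]   # interior from inferred start
    mean((vp - vm)^2)
  }, numeric(1))
  names(disc) <- lengths
  opt <- lengths[which.min(disc)]   # which.min takes the first = smallest L
  i <- 0:(opt - 2L * ex - 1L)
  structure(list(
    optimal = opt,
    discrepancy = disc,
    v_plus = unname(m_fwd[as.character(ex + i)]),
    v_minus = unname(m_rev[as.character(-(opt - ex - 1L) + i)]),
    n_reads = c(fwd = length(fx), rev = length(ry)),
    n_skipped = n_skipped),
    class = "fragment_length_result")
}

#' @export
print.fragment_length_result <- function(x, ...) {
  cat("optimal core fragment length:", x$optimal, "bp (searched",
      names(x$discrepancy)[1], "-",
      names(x$discrepancy)[length(x$discrepancy)], "bp)\n")
  invisible(x)
}

# local maxima of s within +/- (win-1) bp, restricted to positions with
# positive score.  Box smoothing of discrete counts produces exactly tied
# plateaus (every 21-bp window catching the same reads has the same
# score); the peak of such a plateau is its centre — the position the
# direct convolution of the reads with the smoothing kernel peaks at —
# so tied runs collapse to their central position (leftmost between
# distinct runs).
call_score_peaks <- function(s, win = 147L) {
  h <- as.integer(win) - 1L
  rm_ <- roll_max(s, h)
  cand <- which(s > 0 & s == rm_)
  if (length(cand) <= 1L) return(cand)
  # a plateau is a maximal *contiguous* run of tied values; it collapses to
  # its centre.  Equal-valued maxima further apart are distinct peaks and
  # are left for the isolation rule to arbitrate.
  new_run <- c(TRUE, diff(cand) > 1L | s[cand[-1L]] != s[cand[-length(cand)]])
  run_id <- cumsum(new_run)
  as.integer(vapply(split(cand, run_id), function(r) {
    r[(length(r) + 1L) %/% 2L]
  }, numeric(1)))
}

# positions (kmer start coordinates) whose k-mer occurs >= 2 times in the
# genome; returns a logical vector over start positions 1..n-k+1.
# k-mers are encoded as a pair of base-4 integers (first ceil(k/2), last
# floor(k/2) bases) and duplicates found by radix ordering, which keeps the
# catalogue a few numeric vectors instead of millions of strings.
duplicated_kmer_starts <- function(genome, k = 25L) {
  g <- genome_chars(genome)
  n <- length(g)
  if (n < k) return(logical(0))
  b <- match(g, DNA_BASES) - 1
  b[is.na(b)] <- 0
  k1 <- (k + 1L) %/% 2L
  k2 <- k - k1
  m <- n - k + 1L
  roll_code <- function(offset, len) {
    code <- numeric(m)
    for (i in seq_len(len)) {
      code <- code + b[(offset + i):(offset + i + m - 1L)] * 4^(i - 1)
    }
    code
  }
  c1 <- roll_code(0L, k1)
  c2 <- roll_code(k1, k2)
  o <- order(c1, c2, method = "radix")
  s1 <- c1[o]
  s2 <- c2[o]
  same <- c(FALSE, s1[-1L] == s1[-m] & s2[-1L] == s2[-m])
  dup_sorted <- same | c(same[-1L], FALSE)
  dup <- logical(m)
  dup[o] <- dup_sorted
  dup
}

#' Select stable nucleosome dyads across three tissues
#'
#' Works from the forward-strand smoothed dyad scores and applies, in
#' order: (1) peak calling — positions maximizing the score within
#' `peak_window` bp; (2) isolation — a peak is dropped when any other peak
#' lies within `isolation` bp (both members of such a pair are dropped);
#' (3) uniqueness — a peak is dropped when any 25-mer within `isolation` bp
#' of it occurs elsewhere in the genome; (4) cross-tissue stability — a
#' peak is kept only when both other tissues have a retained peak within
#' `proximal` bp.  Each elimination is recorded.
#'
#' @param tracks named list of three `dyad_track` objects (one per tissue).
#' @param genome genome string (for the uniqueness filter).
#' @param peak_window peak dominance window, bp (default 147).
#' @param isolation isolation / uniqueness radius, bp (default 165, the
#'   average neighbouring-dyad distance).
#' @param kmer uniqueness k-mer size (default 25).
#' @param proximal cross-tissue partner distance, bp (default 10).
#' @return object of class `stable_dyads`: per tissue a list with `dyads`
#'   (final positions) and `candidates` (data frame `pos`, `eliminated_by`).
#' @export
select_stable_dyads <- function(tracks, genome, peak_window = 147L,
                                isolation = 165L, kmer = 25L,
                                proximal = 10L) {
  if (length(tracks) < 3L) stop("stable-dyad selection needs three tissues")
  tissues <- names(tracks)
  dup <- duplicated_kmer_starts(genome, kmer)
  dup_cum <- c(0, cumsum(as.numeric(dup)))
  n_km <- length(dup)
  per <- list()
  for (t in tissues) {
    peaks <- call_score_peaks(tracks[[t]]$smooth$fwd, peak_window)
    elim <- rep(NA_character_, length(peaks))
    # isolation: both members of a close pair are removed
    if (length(peaks) > 1L) {
      gap_prev <- c(Inf, diff(peaks))
      gap_next <- c(diff(peaks), Inf)
      bad <- gap_prev <= isolation | gap_next <= isolation
      elim[bad & is.na(elim)] <- "isolation"
    }
    # uniqueness: any duplicated k-mer starting within +/- isolation
    alive <- which(is.na(elim))
    if (length(alive) > 0L && n_km > 0L) {
      lo <- pmax(peaks[alive] - isolation, 1L)
      hi <- pmin(peaks[alive] + isolation - kmer + 1L, n_km)
      has_dup <- hi >= lo & (dup_cum[pmin(hi, n_km) + 1L] - dup_cum[lo]) > 0
      elim[alive[has_dup]] <- "uniqueness"
    }
    per[[t]] <- list(peaks = peaks, elim = elim)
  }
  # cross-tissue stability on the survivors of the first three filters
  survivors <- lapply(per, function(x) x$peaks[is.na(x$elim)])
  for (t in tissues) {
    others <- setdiff(tissues, t)
    alive <- which(is.na(per[[t]]$elim))
    pos <- per[[t]]$peaks[alive]
    ok <- nearest_distance(pos, survivors[[others[1]]]) <= proximal &
      nearest_distance(pos, survivors[[others[2]]]) <= proximal
    per[[t]]$elim[alive[!ok]] <- "cross_tissue"
  }
  out <- lapply(per, function(x) {
    list(dyads = x$peaks[is.na(x$elim)],
         candidates = data.frame(pos = x$peaks, eliminated_by = x$elim,
                                 stringsAsFactors = FALSE))
  })
  structure(out, class = "stable_dyads",
            params = list(peak_window = peak_window, isolation = isolation,
                          kmer = kmer, proximal = proximal))
}

#' Locate the first nucleosome dyad downstream of each representative TSS
#'
#' The first dyad is the position with the maximal smoothed dyad score in
#' the strand-oriented window `window` bp downstream of the TSS (default
#' \[+50, +150\]); it is undefined when every score in the window is zero.
#' A dyad shared by several TSSs is reported once in the unique dyad list.
#'
#' @param reps representative TSS data frame (`pos`, `strand`).
#' @param track a `dyad_track`.
#' @param window two-element downstream offset range.
#' @param score which smoothed track to scan: `"all"` (default) or `"fwd"`.
#' @return list with `first_dyads` (per-TSS data frame `id`, `pos`,
#'   `strand`, `dyad`, `offset`; `dyad` is `NA` when undefined) and `dyads`
#'   (unique defined dyad positions).
#' @export
locate_first_dyads <- function(reps, track, window = c(50L, 150L),
                               score = c("all", "fwd")) {
  score <- match.arg(score)
  s <- track$smooth[[score]]
  n <- track$genome_length
  offs <- window[1]:window[2]
  dyad <- rep(NA_integer_, nrow(reps))
  offset <- rep(NA_integer_, nrow(reps))
  for (i in seq_len(nrow(reps))) {
    idx <- reps$pos[i] + strand_sign(reps$strand[i]) * offs
    ok <- idx >= 1L & idx <= n
    if (!any(ok)) next
    vals <- s[idx[ok]]
    if (all(vals == 0)) next
    top <- which(vals == max(vals))
    # a tied plateau (box-smoothed counts) peaks at its centre; between
    # separate tied maxima the first (smallest offset) run wins
    run <- top[seq_len(match(TRUE, diff(top) > 1L, nomatch = length(top)))]
    j <- run[(length(run) + 1L) %/% 2L]
    dyad[i] <- idx[ok][j]
    offset[i] <- offs[ok][j]
  }
  fd <- data.frame(id = seq_len(nrow(reps)), pos = reps$pos,
                   strand = reps$strand, dyad = dyad, offset = offset,
                   stringsAsFactors = FALSE)
  list(first_dyads = fd, dyads = sort(unique(dyad[!is.na(dyad)])))
}
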