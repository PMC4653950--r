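# Sequence composition around TSSs and dyads: windowed base counts and
# asymmetry, the two-sample incidence z-test, smoothed incidence profiles
# with the MNase-biased offsets masked, and the dyad-versus-linker
# rank-sum contrast.

#' Base and dinucleotide counts upstream/downstream of representative TSSs
#'
#' Counts A, C, G, T and the overlapping dinucleotides AA+TT and CC+GG in
#' the strand-oriented 500-bp windows upstream (\[-500, -1\]) and
#' downstream (\[+1, +500\]) of each TSS (the TSS base itself belongs to
#' neither window).  The asymmetry of each feature is upstream minus
#' downstream, so a negative value means the count is higher downstream.
#'
#' @param genome genome string.
#' @param reps representative TSS data frame (`pos`, `strand`).
#' @param window window width in bp (default 500).
#' @return data frame with, per TSS, `<base>_up`, `<base>_dn`, `asym_<base>`
#'   for A, C, G, T, AA_TT and CC_GG, plus a `missing` flag for windows
#'   truncated by the contig edge.
#' @export
window_base_counts <- function(genome, reps, window = 500L) {
  g <- genome_chars(genome)
  n <- length(g)
  w <- as.integer(window)
  nr <- nrow(reps)
  feats <- c("A", "C", "G", "T", "AA_TT", "CC_GG")
  up <- matrix(NA_real_, nr, length(feats), dimnames = list(NULL, feats))
  dn <- up
  missing <- logical(nr)
  count_feats <- function(seq_chars) {
    a <- seq_chars[-length(seq_chars)]
    b <- seq_chars[-1L]
    c(A = sum(seq_chars == "A"), C = sum(seq_chars == "C"),
      G = sum(seq_chars == "G"), T = sum(seq_chars == "T"),
      AA_TT = sum((a == "A" & b == "A") | (a == "T" & b == "T")),
      CC_GG = sum((a == "C" & b == "C") | (a == "G" & b == "G")))
  }
  for (i in seq_len(nr)) {
    p <- reps$pos[i]
    if (p - w < 1L || p + w > n) {
      missing[i] <- TRUE
      next
    }
    if (reps$strand[i] == "+") {
      up_seq <- g[(p - w):(p - 1L)]
      dn_seq <- g[(p + 1L):(p + w)]
    } else {
      up_seq <- complement_bases(g[(p + w):(p + 1L)])
      dn_seq <- complement_bases(g[(p - 1L):(p - w)])
    }
    up[i, ] <- count_feats(up_seq)
    dn[i, ] <- count_feats(dn_seq)
  }
  out <- data.frame(id = seq_len(nr), pos = reps$pos, strand = reps$strand,
                    stringsAsFactors = FALSE)
  for (f in feats) {
    out[[paste0(f, "_up")]] <- up[, f]
    out[[paste0(f, "_dn")]] <- dn[, f]
    out[[paste0("asym_", f)]] <- up[, f] - dn[, f]
  }
  out$missing <- missing
  out
}

#' Two-sample z-test for asymmetry of base incidence
#'
#' Tests the null hypothesis that the average incidence of a focal base is
#' equal upstream and downstream.  With focal-base counts n1 (up), n2
#' (down) and total base counts m1, m2, the pooled incidence is
#' mu = (n1+n2)/(m1+m2) and
#' Z = (n1/m1 - n2/m2) / sqrt(mu (1-mu) (1/n1 + 1/n2)).
#' The denominator above uses the focal-base counts; the statistically
#' conventional two-proportion form with 1/m1 + 1/m2 is available via
#' `corrected = TRUE`.  Two-sided p from the standard normal.
#'
#' @param n1,n2 focal-base counts upstream and downstream.
#' @param m1,m2 total base counts upstream and downstream.
#' @param corrected use the 1/m1 + 1/m2 denominator.
#' @return list with `z`, `p.value`, `mu`, `corrected`; `z` is `NA` under
#'   the default formula when n1 or n2 is 0 (division by zero).
#' @export
asymmetry_ztest <- function(n1, n2, m1, m2, corrected = FALSE) {
  stopifnot(n1 >= 0, n2 >= 0, n1 <= m1, n2 <= m2, m1 > 0, m2 > 0)
  mu <- (n1 + n2) / (m1 + m2)
  inv <- if (corrected) 1 / m1 + 1 / m2 else {
    if (n1 == 0 || n2 == 0) {
      return(list(z = NA_real_, p.value = NA_real_, mu = mu,
                  corrected = corrected))
    }
    1 / n1 + 1 / n2
  }
  den <- sqrt(mu * (1 - mu) * inv)
  z <- if (den == 0) NA_real_ else (n1 / m1 - n2 / m2) / den
  p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  list(z = z, p.value = p, mu = mu, corrected = corrected)
}

# offsets to mask around dyads for MNase cleavage bias: the 70-74 bp
# stretch upstream of dyads, where rates depart sharply from their
# neighbourhood; masked values are rendered by the running average.  The
# downstream linker window (+70..+130) is deliberately untouched.
mnase_excluded_offsets <- function(mode) {
  -74:-70
}

#' Mean base-incidence profile around a set of anchors
#'
#' Per-offset mean A/C/G/T indicator across anchors, within
#' `half_width` bp.  In `"transcribed"` mode windows are oriented by the
#' anchor strand (minus-strand anchors contribute their reverse
#' complement).  In `"both"` mode (genome-wide dyads, no meaningful strand)
#' the profile is averaged with its reverse complement, so the incidence of
#' a base at +d equals that of its complement at -d exactly.  Offsets
#' listed in `exclude` are masked before smoothing and rendered by the
#' 41-bp running average of the remaining offsets.
#'
#' @param genome genome string.
#' @param anchors data frame with `pos` (and `strand` for transcribed
#'   mode), or an integer vector of positions.
#' @param half_width window half-width in bp (default 500).
#' @param smooth running-average window (default 41).
#' @param mode `"transcribed"` or `"both"`.
#' @param exclude integer offsets to mask, or `NULL`; defaults to the MNase
#'   range via [mnase_excluded_offsets()] when `anchors_are_dyads = TRUE`.
#' @param anchors_are_dyads apply the MNase mask by default.
#' @return object of class `incidence_profile`: list with `offsets`, `raw`
#'   and `smoothed` (4 x width matrices, rows A/C/G/T), `n_anchors`, `mode`.
#' @export
incidence_profile <- function(genome, anchors, half_width = 500L,
                              smooth = 41L,
                              mode = c("transcribed", "both"),
                              exclude = NULL, anchors_are_dyads = FALSE) {
  mode <- match.arg(mode)
  g <- genome_chars(genome)
  n <- length(g)
  if (is.data.frame(anchors)) {
    pos <- anchors$pos
    strand <- if ("strand" %in% names(anchors)) anchors$strand
              else rep("+", length(pos))
  } else {
    pos <- anchors
    strand <- rep("+", length(pos))
  }
  keep <- pos - half_width >= 1L & pos + half_width <= n
  pos <- pos[keep]
  strand <- strand[keep]
  if (length(pos) == 0L) stop("no anchors with complete windows")
  if (is.null(exclude) && anchors_are_dyads) {
    exclude <- mnase_excluded_offsets(mode)
  }
  offs <- (-half_width):half_width
  width <- length(offs)
  counts <- matrix(0, 4L, width, dimnames = list(DNA_BASES, offs))
  sgn <- strand_sign(strand)
  for (dir in c(1L, -1L)) {
    ii <- which(sgn == dir)
    if (length(ii) == 0L) next
    idx <- outer(pos[ii], dir * offs, `+`)
    bm <- matrix(g[idx], nrow = length(ii))
    for (b in DNA_BASES) {
      bb <- if (dir == 1L) b else DNA_COMPLEMENT[[b]]
      counts[b, ] <- counts[b, ] + colSums(bm == bb)
    }
  }
  raw <- counts / length(pos)
  if (mode == "both") {
    rawm <- raw
    for (b in DNA_BASES) {
      raw[b, ] <- (rawm[b, ] + rev(rawm[DNA_COMPLEMENT[[b]], ])) / 2
    }
  }
  if (!is.null(exclude)) {
    raw[, as.character(intersect(exclude, offs))] <- NA_real_
  }
  smoothed <- t(apply(raw, 1L, running_mean, window = smooth, na.rm = TRUE))
  dimnames(smoothed) <- dimnames(raw)
  structure(list(offsets = offs, raw = raw, smoothed = smoothed,
                 n_anchors = length(pos), n_excluded_anchors = sum(!keep),
                 mode = mode, excluded_offsets = exclude),
            class = "incidence_profile")
}

#' Dyad-versus-linker contrast of two incidence profiles
#'
#' Collects the per-offset difference (first profile minus second) over
#' the dyad window (default \[-30, +30\]) and the linker window (default
#' \[+70, +130\], centred 100 bp downstream of the dyad), and compares the
#' two 61-value difference samples with a one-tailed Wilcoxon rank-sum
#' test.
#'
#' @param profile_first `incidence_profile` around first downstream dyads.
#' @param profile_genome `incidence_profile` around genome-wide dyads.
#' @param base which base row to contrast.
#' @param dyad_window,linker_window offset ranges.
#' @param alternative `"greater"` tests whether the difference is larger
#'   around dyads than around linkers.
#' @param use which profile component to difference (`"raw"` default).
#' @return [rank_sum_test()] result, augmented with the two median
#'   differences.
#' @export
dyad_vs_linker_test <- function(profile_first, profile_genome, base,
                                dyad_window = c(-30L, 30L),
                                linker_window = c(70L, 130L),
                                alternative = c("greater", "less"),
                                use = c("raw", "smoothed")) {
  alternative <- match.arg(alternative)
  use <- match.arg(use)
  stopifnot(base %in% DNA_BASES)
  d1 <- profile_first[[use]][base, ]
  d2 <- profile_genome[[use]][base, ]
  offs <- profile_first$offsets
  if (!identical(offs, profile_genome$offsets)) {
    stop("profiles must share offsets")
  }
  diffs <- d1 - d2
  in_win <- function(wn) {
    sel <- offs >= wn[1] & offs <= wn[2]
    v <- diffs[sel]
    if (anyNA(v)) stop("missing offsets inside a comparison window")
    v
  }
  dy <- in_win(dyad_window)
  li <- in_win(linker_window)
  res <- rank_sum_test(dy, li, alternative = alternative)
  res$median_dyad <- stats::median(dy)
  res$median_linker <- stats::median(li)
  res
}
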