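# Nucleosome phasing: autocorrelation of smoothed dyad scores within the
# 500-bp windows flanking each representative TSS, and stratification of
# TSSs into three consistency groups (Group 1 = "nucleocyclic").

#' Normalized autocorrelation of a dyad-score window
#'
#' R(L) = sum_x (s(x)-sbar)(s(x-L)-sbar) / sum_x (s(x)-sbar)^2 over the
#' valid x, the standard sample autocorrelation (mean-centred, full-window
#' variance in the denominator, so |R| <= 1).  The lag maximizing R over
#' the nucleosome-repeat search range is the periodicity; R at that lag is
#' the consistency.
#'
#' @param s numeric score window (typically 501 or 1001 positions).
#' @param lags lags to evaluate (default 150:220 bp).
#' @return named numeric vector of R(L); all `NA` when the window has zero
#'   variance (degenerate).
#' @export
autocorrelation_profile <- function(s, lags = 150:220) {
  n <- length(s)
  if (max(lags) >= n) stop("lags must be smaller than the window length")
  sc <- s - mean(s)
  den <- sum(sc^2)
  if (den == 0) {
    return(stats::setNames(rep(NA_real_, length(lags)), lags))
  }
  r <- vapply(lags, function(L) {
    sum(sc[(L + 1L):n] * sc[1:(n - L)]) / den
  }, numeric(1))
  stats::setNames(r, lags)
}

#' Periodicity and consistency around representative TSSs
#'
#' For every representative TSS, tissue, and side (upstream \[-500, 0\] and
#' downstream \[0, +500\], oriented by the TSS strand), computes the
#' autocorrelation of the smoothed dyad score over lags 150-220 bp and
#' reports the maximizing lag (periodicity, ties toward the smaller lag)
#' and the maximum (consistency).  Metrics are missing when the window
#' leaves the track or has zero variance.
#'
#' @param reps representative TSS data frame (`pos`, `strand`).
#' @param tracks named list of `dyad_track` objects, one per tissue.
#' @param window flank size in bp (default 500).
#' @param lags lag search range (default 150:220).
#' @param score smoothed component to use: `"all"` (default) or `"fwd"`.
#' @return data frame `id`, `pos`, `strand`, `tissue`, `side`,
#'   `periodicity`, `consistency`, `missing`.
#' @export
phasing_metrics <- function(reps, tracks, window = 500L, lags = 150:220,
                            score = c("all", "fwd")) {
  score <- match.arg(score)
  res <- list()
  for (t in names(tracks)) {
    s_all <- tracks[[t]]$smooth[[score]]
    n <- tracks[[t]]$genome_length
    for (side in c("upstream", "downstream")) {
      per <- rep(NA_integer_, nrow(reps))
      con <- rep(NA_real_, nrow(reps))
      for (i in seq_len(nrow(reps))) {
        sg <- strand_sign(reps$strand[i])
        offs <- if (side == "downstream") 0:window else -(window:0)
        idx <- reps$pos[i] + sg * offs
        if (min(idx) < 1L || max(idx) > n) next
        prof <- autocorrelation_profile(s_all[idx], lags)
        if (all(is.na(prof))) next
        j <- which.max(prof)
        per[i] <- lags[j]
        con[i] <- prof[j]
      }
      res[[paste(t, side)]] <- data.frame(
        id = seq_len(nrow(reps)), pos = reps$pos, strand = reps$strand,
        tissue = t, side = side, periodicity = per, consistency = con,
        missing = is.na(con), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Stratify TSSs into three downstream-consistency groups
#'
#' Group 1 contains the highest-consistency stratum ("nucleocyclic" TSSs),
#' Group 3 the lowest.  The default stratification is rank tertiles (group
#' sizes differing by at most one; ties and the degenerate all-equal case
#' are resolved by input order, so the assignment is deterministic);
#' `method = "kmeans"` instead clusters the consistency values into three
#' groups relabelled by decreasing centre.
#'
#' @param consistency numeric vector of downstream consistency values;
#'   `NA`s are excluded and labelled `NA`.
#' @param method `"tertile"` (default) or `"kmeans"`.
#' @return integer vector of labels in \{1, 2, 3\} (`NA` where the input was
#'   missing).
#' @export
group_tss_by_consistency <- function(consistency,
                                     method = c("tertile", "kmeans")) {
  method <- match.arg(method)
  ok <- which(!is.na(consistency))
  if (length(ok) < 3L) stop("need at least 3 TSSs with consistency values")
  labels <- rep(NA_integer_, length(consistency))
  v <- consistency[ok]
  if (method == "tertile") {
    ord <- order(-v, seq_along(v))
    n <- length(v)
    sizes <- rep(n %/% 3L, 3L)
    extra <- n %% 3L
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    grp <- rep(1:3, times = sizes)
    labels[ok[ord]] <- grp
  } else {
    centers <- stats::quantile(v, c(0.17, 0.5, 0.83), names = FALSE)
    if (length(unique(centers)) < 3L) {
      centers <- centers + c(-1e-9, 0, 1e-9)
    }
    km <- stats::kmeans(v, centers = matrix(centers, ncol = 1))
    relabel <- rank(-km$centers[, 1], ties.method = "first")
    labels[ok] <- relabel[km$cluster]
  }
  labels
}
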