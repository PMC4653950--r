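# Tag libraries and MNase nucleosome-core reads sampled from the planted
# ground truth.

#' Simulate per-tissue 5'-end tag libraries
#'
#' Distributes each tissue's library over the planted TSSs in proportion to
#' their true expression (with optional per-strain log-normal noise), then
#' spreads each promoter's tags over +/-10 bp of the TSS with a two-sided
#' geometric decay.  Totals are exactly the configured library size
#' (multinomial allocation).
#'
#' @param truth `ground_truth` from [simulate_ancestor_genome()].
#' @param config the [sim_config()] used to build `truth`.
#' @param strain `"focal"` or `"sister"`; selects an independent sampling
#'   stream and per-strain expression noise.
#' @return object of class `tag_library`: per-tissue data frames with
#'   columns `pos`, `strand`, `count`, plus the library size.
#' @export
simulate_tag_library <- function(truth, config, strain = c("focal", "sister")) {
  strain <- match.arg(strain)
  tss <- truth$tss
  np <- nrow(tss)
  if (np == 0L) stop("no planted TSSs: cannot simulate a tag library")
  set.seed(derive_seed(config$seed, paste0("tags_", strain)))
  offs <- -10:10
  offw <- 0.5^abs(offs)
  sgn <- strand_sign(tss$strand)
  tissues <- config$tissues
  out <- list()
  for (t in tissues) {
    expr <- tss[[paste0("expr_", t)]]
    wgt <- expr * 10^stats::rnorm(np, 0, config$strain_log_sd)
    wgt[expr == 0] <- 0
    if (sum(wgt) == 0) {
      out[[t]] <- data.frame(pos = integer(0), strand = character(0),
                             count = integer(0))
      next
    }
    pmat <- outer(wgt, offw)
    counts <- stats::rmultinom(1L, config$library_size, as.vector(pmat))
    counts <- matrix(counts, nrow = np)
    keep <- which(counts > 0, arr.ind = TRUE)
    df <- data.frame(
      pos = tss$pos[keep[, 1L]] + sgn[keep[, 1L]] * offs[keep[, 2L]],
      strand = tss$strand[keep[, 1L]],
      count = counts[keep],
      stringsAsFactors = FALSE)
    df <- df[order(df$pos, df$strand), , drop = FALSE]
    rownames(df) <- NULL
    out[[t]] <- df
  }
  structure(list(tissues = out, library_size = config$library_size,
                 strain = strain),
            class = "tag_library")
}

# choose a +/-2 bp shift for each position, weighted w^(A/T at candidate);
# vectorised across positions
at_biased_shift <- function(pos, at01, w, n) {
  if (w == 1) return(pos)
  deltas <- -2:2
  wt <- matrix(0, nrow = length(pos), ncol = length(deltas))
  for (j in seq_along(deltas)) {
    idx <- pos + deltas[j]
    ok <- idx >= 1L & idx <= n
    wt[ok, j] <- w^at01[idx[ok]]
  }
  c1 <- wt[, 1L]
  c2 <- c1 + wt[, 2L]
  c3 <- c2 + wt[, 3L]
  c4 <- c3 + wt[, 4L]
  c5 <- c4 + wt[, 5L]
  u <- stats::runif(length(pos)) * c5
  pick <- 1L + (u >= c1) + (u >= c2) + (u >= c3) + (u >= c4)
  pos + deltas[pick]
}

#' Simulate strand-balanced nucleosome core reads
#'
#' For each planted dyad of each tissue, draws a Poisson number of
#' fragments whose midpoints are Normal around the dyad and whose lengths
#' are Normal around the true core length; both cleavage ends are then
#' locally re-placed with an A/T preference (weight `end_bias_weight`),
#' emulating MNase cleavage bias.  Each fragment is reported as its 5'
#' anchor: the start for forward-anchored reads, the end for
#' reverse-anchored reads, with probability 1/2 each.
#'
#' @param truth `ground_truth` with planted dyads.
#' @param config the [sim_config()] used to build `truth`.
#' @param genome genome string the reads are cut from (per strain).
#' @param strain `"focal"` or `"sister"`; selects the sampling stream.
#' @return object of class `nucleosome_reads`: per-tissue data frames with
#'   columns `pos` (anchor) and `strand`.
#' @export
simulate_nucleosome_reads <- function(truth, config, genome,
                                      strain = c("focal", "sister")) {
  strain <- match.arg(strain)
  g <- genome_chars(genome)
  n <- length(g)
  at01 <- as.integer(g %in% c("A", "T"))
  out <- list()
  for (t in config$tissues) {
    set.seed(derive_seed(config$seed, paste0("reads_", strain, "_", t)))
    dy <- truth$dyads[[t]]$pos
    nr <- stats::rpois(length(dy), config$coverage)
    d <- rep(dy, nr)
    N <- length(d)
    if (N == 0L) {
      out[[t]] <- data.frame(pos = integer(0), strand = character(0))
      next
    }
    Lf <- pmin(pmax(round(stats::rnorm(N, config$core_length_true,
                                       config$fragment_length_sd)), 100L),
               250L)
    mid <- round(stats::rnorm(N, d, config$dyad_jitter_sd))
    start <- as.integer(mid - (Lf - 1L) %/% 2L)
    end <- as.integer(start + Lf - 1L)
    start <- at_biased_shift(start, at01, config$end_bias_weight, n)
    end <- at_biased_shift(end, at01, config$end_bias_weight, n)
    keep <- start >= 1L & end <= n & start < end
    start <- start[keep]
    end <- end[keep]
    fwd <- stats::runif(length(start)) < 0.5
    df <- data.frame(pos = ifelse(fwd, start, end),
                     strand = ifelse(fwd, "+", "-"),
                     stringsAsFactors = FALSE)
    df <- df[order(df$pos, df$strand), , drop = FALSE]
    rownames(df) <- NULL
    out[[t]] <- df
  }
  structure(list(tissues = out, strain = strain,
                 core_length_true = config$core_length_true),
            class = "nucleosome_reads")
}
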