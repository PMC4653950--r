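# Evolution: outgroup-parsimony ancestral inference, per-offset mutation
# rates around anchors, mutational-flux summaries, and the directional
# dyad-versus-linker and C>T-versus-G>A contrasts.

MUTATION_CATEGORIES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                         "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

# complementary category of each ordered base change (A>C <-> T>G, ...)
complement_category <- function(cat) {
  from <- substr(cat, 1L, 1L)
  to <- substr(cat, 3L, 3L)
  paste0(DNA_COMPLEMENT[from], ">", DNA_COMPLEMENT[to])
}

#' Infer ancestral bases by outgroup parsimony
#'
#' For each aligned site of (focal, sister, outgroup), the ancestor of the
#' focal/sister pair is the outgroup base whenever the outgroup agrees
#' with at least one of the two strains; three-way disagreements are
#' undetermined, and sites with a gap or ambiguous base in any strain are
#' excluded.  A site is a (focal-branch) mutation when the ancestor is
#' determined and differs from the focal base.
#'
#' @param focal,sister,outgroup character vectors of aligned bases (equal
#'   length), or genome strings.
#' @return object of class `ancestral_calls`: list with `ancestor`
#'   (character), `focal` (character), `status` (factor with levels
#'   `no_mutation`, `mutated`, `undetermined`, `excluded`) and `category`
#'   (e.g. `"C>T"` at mutated sites, `NA` elsewhere), all per site.
#' @export
infer_ancestral_bases <- function(focal, sister, outgroup) {
  f <- genome_chars(focal)
  s <- genome_chars(sister)
  o <- genome_chars(outgroup)
  n <- length(f)
  if (length(s) != n || length(o) != n) {
    stop("the three strains must have equal aligned length")
  }
  valid <- f %in% DNA_BASES & s %in% DNA_BASES & o %in% DNA_BASES
  determined <- valid & (o == f | o == s)
  ancestor <- rep(NA_character_, n)
  ancestor[determined] <- o[determined]
  status <- rep("excluded", n)
  status[valid & !determined] <- "undetermined"
  mutated <- determined & ancestor != f
  status[determined] <- ifelse(mutated[determined], "mutated", "no_mutation")
  category <- rep(NA_character_, n)
  category[mutated] <- paste0(ancestor[mutated], ">", f[mutated])
  structure(list(ancestor = ancestor, focal = f,
                 status = factor(status, levels = c("no_mutation", "mutated",
                                                    "undetermined",
                                                    "excluded")),
                 category = category, n_sites = n),
            class = "ancestral_calls")
}

#' @export
print.ancestral_calls <- function(x, ...) {
  tb <- table(x$status)
  cat("ancestral_calls:", x$n_sites, "sites;",
      paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Estimate per-branch substitution probabilities from ancestral calls
#'
#' Classical matrix recovery: count(X -> Y) / count(ancestor X determined),
#' for the focal branch.  Used for parameter-recovery checks against the
#' generator's planted matrices.
#'
#' @param calls `ancestral_calls`.
#' @return 4x4 matrix of estimated substitution probabilities (diagonal =
#'   identity fraction).
#' @export
substitution_rate_estimate <- function(calls) {
  det <- calls$status %in% c("no_mutation", "mutated")
  anc <- calls$ancestor[det]
  foc <- calls$focal[det]
  m <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  tb <- table(factor(anc, DNA_BASES), factor(foc, DNA_BASES))
  m[] <- tb
  sweep(m, 1L, pmax(rowSums(m), 1), "/")
}

#' Per-offset mutation rates around anchors
#'
#' For each offset within `half_width` bp of the anchors, the rate of each
#' ordered base change X>Y is the count of focal-branch X>Y mutations at
#' that offset divided by the total number of ancestor-determined sites at
#' that offset (so rates of a change and its reverse are directly
#' comparable).  In `"stranded"` mode (TSS or first-dyad anchors) windows
#' are oriented by anchor strand and categories on minus-strand anchors
#' are complemented, giving transcribed-strand changes.  In `"both"` mode
#' (genome-wide dyads) each rate is averaged with its complementary
#' category mirrored around the dyad.  Offsets in `exclude` are masked and
#' rendered by the 41-bp running average.
#'
#' @param calls `ancestral_calls` on the focal strain's coordinates.
#' @param anchors data frame with `pos` (and `strand` in stranded mode), or
#'   integer positions.
#' @param half_width window half-width (default 500).
#' @param mode `"stranded"` or `"both"`.
#' @param exclude offsets to mask (`NULL` = none; dyad anchors convention
#'   via `anchors_are_dyads`).
#' @param anchors_are_dyads apply the MNase mask by default.
#' @param smooth running-average window for the smoothed rates.
#' @return object of class `mutation_rate_track`: `offsets`, `totals`
#'   (determined sites per offset), `counts` (12 x width), `rate`,
#'   `smoothed`, `mode`, `n_anchors`.
#' @export
positional_mutation_rates <- function(calls, anchors, half_width = 500L,
                                      mode = c("stranded", "both"),
                                      exclude = NULL,
                                      anchors_are_dyads = FALSE,
                                      smooth = 41L) {
  mode <- match.arg(mode)
  n <- calls$n_sites
  if (is.data.frame(anchors)) {
    pos <- anchors$pos
    strand <- if ("strand" %in% names(anchors) && mode == "stranded") {
      anchors$strand
    } else rep("+", length(pos))
  } else {
    pos <- anchors
    strand <- rep("+", length(pos))
  }
  keep <- pos - half_width >= 1L & pos + half_width <= n
  pos <- pos[keep]
  strand <- strand[keep]
  if (length(pos) == 0L) stop("no anchors with complete windows")
  if (is.null(exclude) && anchors_are_dyads) {
    exclude <- mnase_excluded_offsets(if (mode == "both") "both"
                                      else "transcribed")
  }
  offs <- (-half_width):half_width
  width <- length(offs)
  det01 <- as.numeric(calls$status %in% c("no_mutation", "mutated"))
  cat_id <- match(calls$category, MUTATION_CATEGORIES)
  cat_id[is.na(cat_id)] <- 0L
  totals <- numeric(width)
  counts <- matrix(0, 12L, width,
                   dimnames = list(MUTATION_CATEGORIES, offs))
  sgn <- strand_sign(strand)
  for (dir in c(1L, -1L)) {
    ii <- which(sgn == dir)
    if (length(ii) == 0L) next
    idx <- outer(pos[ii], dir * offs, `+`)
    totals <- totals + colSums(matrix(det01[idx], nrow = length(ii)))
    cm <- matrix(cat_id[idx], nrow = length(ii))
    for (k in seq_along(MUTATION_CATEGORIES)) {
      kk <- if (dir == 1L) k else {
        match(complement_category(MUTATION_CATEGORIES[k]),
              MUTATION_CATEGORIES)
      }
      counts[kk, ] <- counts[kk, ] + colSums(cm == k)
    }
  }
  rate <- sweep(counts, 2L, pmax(totals, 1), "/")
  rate[, totals == 0] <- NA_real_
  if (mode == "both") {
    rr <- rate
    tt <- totals
    for (k in seq_along(MUTATION_CATEGORIES)) {
      kk <- match(complement_category(MUTATION_CATEGORIES[k]),
                  MUTATION_CATEGORIES)
      rate[k, ] <- (rr[k, ] + rev(rr[kk, ])) / 2
    }
    totals <- (tt + rev(tt)) / 2
  }
  if (!is.null(exclude)) {
    rate[, as.character(intersect(exclude, offs))] <- NA_real_
  }
  smoothed <- t(apply(rate, 1L, running_mean, window = smooth, na.rm = TRUE))
  dimnames(smoothed) <- dimnames(rate)
  totals <- stats::setNames(as.numeric(totals), offs)
  structure(list(offsets = offs, totals = totals, counts = counts,
                 rate = rate, smoothed = smoothed, mode = mode,
                 n_anchors = length(pos), n_excluded_anchors = sum(!keep),
                 excluded_offsets = exclude),
            class = "mutation_rate_track")
}

#' Region-level mutational-flux summary
#'
#' Pools counts over each region's offsets to give the mean rate of every
#' ordered base change, then the flow into each base Z (sum of X>Z rates),
#' the flow out of Z (sum of Z>X rates), and the net incidence change
#' (flow in minus flow out = (current count - ancestral count)/total).
#' The net changes sum to zero over the four bases by construction.
#'
#' @param track `mutation_rate_track`.
#' @param regions named list of offset ranges, default upstream
#'   \[-500, -1\] and downstream \[+1, +500\].
#' @return list per region: `rates` (named 12-vector), `flow_in`,
#'   `flow_out`, `net` (named 4-vectors), `total_sites`.
#' @export
mutational_flux_summary <- function(track,
                                    regions = list(upstream = c(-500L, -1L),
                                                   downstream = c(1L, 500L))) {
  out <- list()
  for (rn in names(regions)) {
    rg <- regions[[rn]]
    sel <- track$offsets >= rg[1] & track$offsets <= rg[2]
    tot <- sum(track$totals[sel])
    cnt <- rowSums(track$counts[, sel, drop = FALSE])
    rates <- cnt / max(tot, 1)
    from <- substr(MUTATION_CATEGORIES, 1L, 1L)
    to <- substr(MUTATION_CATEGORIES, 3L, 3L)
    flow_in <- vapply(DNA_BASES, function(z) sum(rates[to == z]), numeric(1))
    flow_out <- vapply(DNA_BASES, function(z) sum(rates[from == z]),
                       numeric(1))
    out[[rn]] <- list(rates = rates, flow_in = flow_in,
                      flow_out = flow_out, net = flow_in - flow_out,
                      total_sites = tot)
  }
  out
}

#' Dyad-versus-linker contrast of mutation rates
#'
#' The machinery of [dyad_vs_linker_test()] applied to one mutation
#' category: per-offset rate differences (first-dyad track minus
#' genome-wide track) over the dyad window are compared with those over
#' the linker window by a one-tailed rank-sum test.
#'
#' @param track_first `mutation_rate_track` around first downstream dyads.
#' @param track_genome `mutation_rate_track` around genome-wide dyads.
#' @param category ordered base change, e.g. `"C>T"`.
#' @param dyad_window,linker_window offset ranges.
#' @param alternative `"greater"`: the dyad-window difference exceeds the
#'   linker-window difference (first dyads peak where genome-wide dyads
#'   dip).
#' @return [rank_sum_test()] result with median differences.
#' @export
mutation_dyad_vs_linker_test <- function(track_first, track_genome, category,
                                         dyad_window = c(-30L, 30L),
                                         linker_window = c(70L, 130L),
                                         alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (!category %in% MUTATION_CATEGORIES) {
    stop("category must be one of the 12 ordered base changes")
  }
  offs <- track_first$offsets
  if (!identical(offs, track_genome$offsets)) {
    stop("tracks must share offsets")
  }
  diffs <- track_first$rate[category, ] - track_genome$rate[category, ]
  in_win <- function(wn) {
    v <- diffs[offs >= wn[1] & offs <= wn[2]]
    v[!is.na(v)]
  }
  dy <- in_win(dyad_window)
  li <- in_win(linker_window)
  res <- rank_sum_test(dy, li, alternative = alternative)
  res$median_dyad <- stats::median(dy)
  res$median_linker <- stats::median(li)
  res
}

#' Compare C>T and G>A mutation rates upstream versus downstream
#'
#' Forms d(x) = rate(C>T)(x) - rate(G>A)(x) at each offset and tests, by
#' one-tailed rank-sum, whether the upstream differences are smaller than
#' the downstream ones — the signature expected from transcription-coupled
#' repair acting on the transcribed strand downstream of active TSSs.
#'
#' @param track `mutation_rate_track` around (nucleocyclic) TSSs in
#'   stranded mode.
#' @return [rank_sum_test()] result (alternative: upstream less than
#'   downstream), with the two median differences.
#' @export
ct_vs_ga_test <- function(track) {
  offs <- track$offsets
  d <- track$rate["C>T", ] - track$rate["G>A", ]
  up <- d[offs < 0]
  dn <- d[offs > 0]
  up <- up[!is.na(up)]
  dn <- dn[!is.na(dn)]
  res <- rank_sum_test(up, dn, alternative = "less")
  res$median_upstream <- stats::median(up)
  res$median_downstream <- stats::median(dn)
  res
}
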