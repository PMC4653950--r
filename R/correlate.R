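# The 48-parameter table per representative TSS and its Spearman
# rank-correlation matrix with Bonferroni-corrected significance.

#' Assemble the per-TSS parameter table
#'
#' One row per representative TSS with the 48 parameters: for each strain
#' and tissue, log10 expression (pseudocount 0.01) and breadth (12
#' columns); for each strain, tissue and side, nucleosome periodicity Np
#' and consistency Na (24 columns); for the focal strain only, A/C/G/T
#' counts upstream and downstream and their asymmetries Sa (12 columns).
#' Expression is missing where a tissue had no tags; rows with any missing
#' value are dropped and the removal is reported.
#'
#' @param tss_tables named list (per strain) of [representative_tss_table()]
#'   outputs, rows aligned across strains (same TSS order).
#' @param phasing_tables named list (per strain) of [phasing_metrics()]
#'   outputs for the same TSSs.
#' @param composition [window_base_counts()] output for the focal strain
#'   (first strain in `tss_tables`).
#' @param tissues tissue names.
#' @param strain_labels short labels used in column names (default `"Hd"`,
#'   `"HN"` in order of `tss_tables`).
#' @param pseudocount added to expression before log10.
#' @return list with `table` (complete rows only, first column `id`),
#'   `n_input`, `n_complete`, `n_dropped`.
#' @export
assemble_parameter_table <- function(tss_tables, phasing_tables, composition,
                                     tissues, strain_labels = c("Hd", "HN"),
                                     pseudocount = 0.01) {
  strains <- names(tss_tables)
  if (length(strains) < 2L) stop("need at least two strains")
  n <- nrow(tss_tables[[1L]])
  out <- data.frame(id = tss_tables[[1L]]$id)
  for (si in seq_along(strains)) {
    st <- strains[si]
    lab <- strain_labels[si]
    tt <- tss_tables[[st]]
    if (nrow(tt) != n) stop("strain TSS tables must be row-aligned")
    for (ti in tissues) {
      e <- tt[[paste0("expr_", ti)]]
      e[e <= 0] <- NA_real_   # no tags in this tissue: undefined
      out[[paste(lab, "Exp", ti, sep = "_")]] <- log10(e + pseudocount)
      out[[paste(lab, "Br", ti, sep = "_")]] <- ifelse(is.na(e), NA_real_,
        tt[[paste0("breadth_", ti)]])
    }
    ph <- phasing_tables[[st]]
    for (ti in tissues) {
      for (side in c("upstream", "downstream")) {
        sel <- ph$tissue == ti & ph$side == side
        sub <- ph[sel, , drop = FALSE]
        sub <- sub[order(sub$id), , drop = FALSE]
        if (nrow(sub) != n) stop("phasing table must cover every TSS")
        sd_lab <- if (side == "upstream") "Up" else "Dw"
        out[[paste(lab, "Np", ti, sd_lab, sep = "_")]] <- sub$periodicity
        out[[paste(lab, "Na", ti, sd_lab, sep = "_")]] <- sub$consistency
      }
    }
  }
  lab <- strain_labels[1L]
  if (nrow(composition) != n) stop("composition table must be row-aligned")
  for (b in DNA_BASES) {
    up <- composition[[paste0(b, "_up")]]
    dn <- composition[[paste0(b, "_dn")]]
    up[composition$missing] <- NA_real_
    dn[composition$missing] <- NA_real_
    out[[paste(lab, b, "Up", sep = "_")]] <- up
    out[[paste(lab, b, "Dw", sep = "_")]] <- dn
    out[[paste(lab, "Sa", b, sep = "_")]] <- up - dn
  }
  # roster size: strains x tissues x {Exp, Br} + strains x tissues x sides x
  # {Np, Na} + focal 4 bases x {Up, Dw, Sa}; 48 for 2 strains and 3 tissues
  expected <- 2L * length(strains) * length(tissues) +
    4L * length(strains) * length(tissues) + 12L
  if (ncol(out) - 1L != expected) {
    stop("parameter roster incomplete: got ", ncol(out) - 1L,
         " columns, expected ", expected)
  }
  complete <- stats::complete.cases(out)
  if (sum(complete) == 0L) stop("no TSS has complete information")
  list(table = out[complete, , drop = FALSE],
       n_input = n, n_complete = sum(complete),
       n_dropped = n - sum(complete))
}

#' Spearman rank-correlation matrix with p-values
#'
#' Pairwise Spearman correlation (average ranks on ties) with the
#' t-approximation p-value for each pair.  Constant columns yield `NA`
#' correlations and are flagged.
#'
#' @param table parameter table (the `table` element of
#'   [assemble_parameter_table()]; an `id` column, if present, is
#'   dropped).
#' @return object of class `correlation_matrix`: `r`, `p`, `n`,
#'   `constant_columns`.
#' @export
spearman_matrix <- function(table) {
  if ("id" %in% names(table)) table$id <- NULL
  x <- as.matrix(table)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 complete rows")
  const <- apply(x, 2L, function(v) length(unique(v)) == 1L)
  r <- suppressWarnings(stats::cor(x, method = "spearman"))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  structure(list(r = r, p = p, n = n,
                 constant_columns = names(which(const))),
            class = "correlation_matrix")
}

#' Bonferroni significance threshold and mask
#'
#' @param alpha family-wise significance level.
#' @param n_tests number of hypotheses (1128 for all pairs of 48
#'   parameters).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1L, alpha > 0)
  alpha / n_tests
}

#' Significance mask for a correlation matrix
#' @param cm `correlation_matrix`.
#' @param alpha family-wise level (default 0.05).
#' @return logical matrix: `p < alpha / n_offdiag_pairs`.
#' @export
significant_correlations <- function(cm, alpha = 0.05) {
  k <- ncol(cm$r)
  thr <- bonferroni_threshold(alpha, k * (k - 1L) / 2L)
  mask <- cm$p < thr
  diag(mask) <- FALSE
  mask
}
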