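# Synthetic genomes with planted promoters and nucleosome arrays.
#
# The generator plants the phenomena the analysis is designed to detect:
# A/T-rich upstream and C/G-rich downstream promoter windows, phased
# downstream dyad arrays in a tissue-specific subset of promoters, an
# irregularly spaced genome-wide background of nucleosomes shared across
# tissues, and a graded A/T profile rising from each background dyad to its
# linkers (the canonical GC-rich core / AT-rich linker organisation) which
# gives the fragment-length estimator its alignment signal.

# sample one base per entry of `at_prob`, the per-position A+T probability
# (A/T and C/G equiprobable within their class)
sample_at_profile <- function(at_prob) {
  n <- length(at_prob)
  u <- stats::runif(n)
  at <- u < at_prob
  half <- stats::runif(n) < 0.5
  out <- character(n)
  out[at & half] <- "A"
  out[at & !half] <- "T"
  out[!at & half] <- "C"
  out[!at & !half] <- "G"
  out
}

#' Simulate the ancestral genome with planted promoters and nucleosomes
#'
#' Builds a uniform-background genome, plants `n_promoters` TSSs spaced more
#' than 1000 bp apart with A/T-rich upstream and C/G-rich downstream 500-bp
#' windows (transcribed-strand orientation), lays down an irregular
#' genome-wide array of background dyads shared by all tissues, writes a
#' graded A/T ramp (lowest at the dyad, rising to the linker) around each
#' background dyad, and draws per-promoter, per-tissue expression, activity
#' and phasing states.
#'
#' @param config a [sim_config()].
#' @return list with `sequence` (genome string) and `truth` (a
#'   `ground_truth` object holding planted TSSs, per-tissue dyads, and the
#'   identity strain coordinate map).
#' @export
simulate_ancestor_genome <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "genome"))
  n <- config$genome_length
  np <- config$n_promoters
  w <- config$promoter_window
  tissues <- config$tissues

  if (np > 0L) {
    slot <- (n - 1400L) %/% np
    if (slot < 1150L) {
      stop("genome too short: ", np, " promoters need at least ",
           np * 1150L + 1400L, " bp, got ", n)
    }
  }

  genome <- sample(DNA_BASES, n, replace = TRUE)

  # -- promoters -------------------------------------------------------------
  if (np > 0L) {
    jmax <- slot - 1101L
    pos <- 700L + (seq_len(np) - 1L) * slot +
      sample.int(jmax + 1L, np, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), np, replace = TRUE)
    sgn <- strand_sign(strand)
    up_prob <- c(A = config$upstream_AT_fraction / 2,
                 C = (1 - config$upstream_AT_fraction) / 2,
                 G = (1 - config$upstream_AT_fraction) / 2,
                 T = config$upstream_AT_fraction / 2)
    dn_prob <- c(A = (1 - config$downstream_CG_fraction) / 2,
                 C = config$downstream_CG_fraction / 2,
                 G = config$downstream_CG_fraction / 2,
                 T = (1 - config$downstream_CG_fraction) / 2)
    for (i in seq_len(np)) {
      up_seq <- sample(DNA_BASES, w, replace = TRUE, prob = up_prob)
      dn_seq <- sample(DNA_BASES, w, replace = TRUE, prob = dn_prob)
      if (strand[i] == "+") {
        genome[(pos[i] - w):(pos[i] - 1L)] <- up_seq
        genome[(pos[i] + 1L):(pos[i] + w)] <- dn_seq
      } else {
        # oriented 5'->3' on the minus strand; written reverse-complemented
        genome[(pos[i] + w):(pos[i] + 1L)] <- complement_bases(up_seq)
        genome[(pos[i] - 1L):(pos[i] - w)] <- complement_bases(dn_seq)
      }
    }
  } else {
    pos <- integer(0)
    strand <- character(0)
    sgn <- integer(0)
  }

  # -- background dyads (common to all tissues) ------------------------------
  gaps_lo <- config$background_gap_range[1]
  gaps_hi <- config$background_gap_range[2]
  approx_n <- ceiling((n - 1400L) / gaps_lo) + 1L
  gaps <- round(stats::runif(approx_n, gaps_lo, gaps_hi))
  bg <- 700L + cumsum(gaps)
  bg <- bg[bg <= n - 700L]
  if (np > 0L) {
    # keep the promoter neighbourhood free of background nucleosomes
    bg <- bg[nearest_distance(bg, pos) > 1050L]
  }

  # graded A/T ramp around each background dyad: core_AT at the dyad rising
  # linearly to linker_AT at +/-73, then linker_AT out to +/-110
  if (length(bg) > 0L) {
    offs <- -110:110
    at_prof <- ifelse(abs(offs) <= 73,
                      config$core_AT +
                        (config$linker_AT - config$core_AT) * abs(offs) / 73,
                      config$linker_AT)
    for (d in bg) {
      idx <- d + offs
      keep <- idx >= 1L & idx <= n
      genome[idx[keep]] <- sample_at_profile(at_prof[keep])
    }
  }

  # -- per-tissue promoter dyads --------------------------------------------
  phased <- matrix(stats::runif(np * length(tissues)) < config$phased_fraction,
                   nrow = np, ncol = length(tissues),
                   dimnames = list(NULL, tissues))
  active <- matrix(stats::runif(np * length(tissues)) < config$active_fraction,
                   nrow = np, ncol = length(tissues),
                   dimnames = list(NULL, tissues))
  log_expr <- matrix(stats::rnorm(np * length(tissues),
                                  mean = config$expression_log_mean,
                                  sd = config$expression_log_sd),
                     nrow = np, ncol = length(tissues),
                     dimnames = list(NULL, tissues))
  log_expr <- log_expr + config$phasing_expression_shift * phased
  expr <- 10^log_expr * active

  n_array <- 5L
  n_upstream <- 3L
  dyads <- list()
  for (t in tissues) {
    dlist <- list(data.frame(pos = bg, type = "background",
                             promoter = NA_integer_))
    for (i in seq_len(np)) {
      if (phased[i, t]) {
        off <- config$first_dyad_offset +
          (seq_len(n_array) - 1L) * config$nucleosome_spacing
      } else {
        # disordered but present: a +1 nucleosome near the TSS plus
        # randomly placed downstream nucleosomes, tissue-specific
        off <- sort(c(sample(50:450, 1L), sample(50:950, n_array - 1L)))
      }
      # upstream of the depleted region every promoter keeps a -1
      # nucleosome plus disordered tissue-specific nucleosomes
      up_off <- sort(c(max(150L, round(stats::rnorm(1, 200, 15))),
                       sample(350:900, n_upstream - 1L)))
      dpos <- c(pos[i] - sgn[i] * up_off, pos[i] + sgn[i] * off)
      dlist[[length(dlist) + 1L]] <-
        data.frame(pos = dpos,
                   type = c(rep("promoter_upstream", n_upstream),
                            rep(if (phased[i, t]) "promoter_phased"
                                else "promoter_fuzzy", n_array)),
                   promoter = i)
    }
    dd <- do.call(rbind, dlist)
    dd <- dd[dd$pos >= 1L & dd$pos <= n, , drop = FALSE]
    dd <- dd[order(dd$pos), , drop = FALSE]
    rownames(dd) <- NULL
    dyads[[t]] <- dd
  }

  tss <- data.frame(id = seq_len(np), pos = pos, strand = strand,
                    stringsAsFactors = FALSE)
  for (t in tissues) {
    tss[[paste0("expr_", t)]] <- if (np > 0L) expr[, t] else numeric(0)
    tss[[paste0("phased_", t)]] <- if (np > 0L) phased[, t] else logical(0)
    tss[[paste0("active_", t)]] <- if (np > 0L) active[, t] else logical(0)
  }

  truth <- structure(
    list(tss = tss, dyads = dyads, background_dyads = bg,
         substitutions = NULL, coord_map = "identity",
         genome_length = n, tissues = tissues),
    class = "ground_truth")

  list(sequence = paste(genome, collapse = ""), truth = truth)
}

#' Evolve two descendant strains and an outgroup from an ancestor
#'
#' Applies the three per-branch substitution matrices site-independently to
#' the ancestral sequence, producing the focal strain, its sister strain and
#' the outgroup, with every substitution recorded.  Optional
#' position-dependent modulations multiply a chosen substitution probability
#' at chosen sites (used to plant dyad- or linker-localised mutational
#' biases).
#'
#' @param ancestor ancestral genome string (or character vector of bases).
#' @param config a [sim_config()]; `branch_rate_matrices` and
#'   `rate_modulation` drive the process.
#' @return list with genome strings `focal`, `sister`, `outgroup` and a
#'   `substitutions` data frame (`pos`, `ancestral`, `derived`, `branch`).
#' @export
evolve_strains <- function(ancestor, config) {
  validate_sim_config(config)
  anc <- genome_chars(ancestor)
  n <- length(anc)
  out <- list()
  subs <- list()
  for (branch in c("focal", "sister", "outgroup")) {
    set.seed(derive_seed(config$seed, paste0("evolve_", branch)))
    m <- config$branch_rate_matrices[[branch]]
    derived <- anc
    for (b in DNA_BASES) {
      idx <- which(anc == b)
      if (length(idx) == 0L) next
      targets <- setdiff(DNA_BASES, b)
      p <- matrix(rep(m[b, targets], each = length(idx)), ncol = 3L)
      for (mod in config$rate_modulation) {
        if (!identical(mod$branch, branch) || !identical(mod$from, b)) next
        j <- match(mod$to, targets)
        if (is.na(j)) stop("rate modulation target must differ from source")
        hit <- idx %in% mod$pos
        p[hit, j] <- p[hit, j] * mod$factor
      }
      if (any(rowSums(p) > 1)) {
        stop("modulated substitution probabilities exceed 1 on branch ",
             branch)
      }
      u <- stats::runif(length(idx))
      c1 <- p[, 1L]
      c2 <- c1 + p[, 2L]
      c3 <- c2 + p[, 3L]
      k <- ifelse(u < c1, 1L, ifelse(u < c2, 2L, ifelse(u < c3, 3L, 0L)))
      ch <- which(k > 0L)
      if (length(ch) > 0L) {
        derived[idx[ch]] <- targets[k[ch]]
      }
    }
    changed <- which(derived != anc)
    subs[[branch]] <- data.frame(pos = changed,
                                 ancestral = anc[changed],
                                 derived = derived[changed],
                                 branch = rep(branch, length(changed)),
                                 stringsAsFactors = FALSE)
    out[[branch]] <- paste(derived, collapse = "")
  }
  substitutions <- do.call(rbind, subs)
  rownames(substitutions) <- NULL
  list(focal = out$focal, sister = out$sister, outgroup = out$outgroup,
       substitutions = substitutions)
}
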