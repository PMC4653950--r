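#' Default per-branch substitution probability matrices
#'
#' Row = ancestral base, column = derived base (order A, C, G, T); entries
#' are per-site substitution probabilities along one branch of the
#' two-strain + outgroup tree, with the diagonal holding the no-change
#' probability.  The defaults carry a 2:1 transition bias and an off-diagonal
#' row sum of about 1.7 % per branch, matching the divergence scale of a pair
#' of strains with a ~3.4 % SNP rate.
#'
#' @param transition per-site transition probability (A<->G, C<->T).
#' @param transversion per-site probability of each transversion.
#' @return named list of three 4x4 matrices: `focal`, `sister`, `outgroup`.
#' @export
default_rate_matrices <- function(transition = 0.009, transversion = 0.004) {
  one <- matrix(transversion, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  one["A", "G"] <- one["G", "A"] <- transition
  one["C", "T"] <- one["T", "C"] <- transition
  diag(one) <- 0
  diag(one) <- 1 - rowSums(one)
  list(focal = one, sister = one, outgroup = one)
}

#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the simulation: genome size and promoter count,
#' the A/T-rich-upstream / C/G-rich-downstream promoter composition, phased
#' downstream nucleosome arrays and irregular genome-wide background
#' nucleosomes, MNase fragment geometry and A/T end bias, log-scale
#' expression variation across three tissues, and the two-branch + outgroup
#' substitution history.  All randomness downstream is derived
#' deterministically from `seed`, so an identical configuration reproduces
#' bit-identical outputs.
#'
#' @param genome_length ancestral genome length in bp.
#' @param n_promoters number of planted promoters (TSSs); may be 0 for
#'   nucleosome-only genomes.
#' @param upstream_AT_fraction expected A+T fraction of the 500-bp window
#'   upstream of each planted TSS (transcribed-strand orientation).
#' @param downstream_CG_fraction expected C+G fraction of the 500-bp
#'   downstream window.
#' @param promoter_window width of the composition windows, bp.
#' @param nucleosome_spacing centre-to-centre spacing of phased downstream
#'   dyads, bp.
#' @param dyad_jitter_sd standard deviation of fragment midpoints around
#'   their planted dyad, bp.
#' @param core_length_true mean nucleosome core fragment length, bp
#'   (must lie in \[100, 250\]).
#' @param fragment_length_sd standard deviation of fragment lengths, bp.
#' @param coverage mean reads per planted dyad (Poisson).
#' @param end_bias_weight multiplicative weight (>= 1) favouring A/T bases
#'   when placing fragment ends, emulating MNase cleavage preference.
#' @param background_gap_range range of uniform gaps between genome-wide
#'   background dyads, bp; irregular spacing keeps background arrays
#'   unphased.
#' @param core_AT,linker_AT expected A+T fraction written into the core
#'   (+/- 73 bp) and flanking linker of each background dyad; the contrast
#'   gives the fragment-length estimator its signal.
#' @param expression_log_mean,expression_log_sd mean and sd of log10
#'   expression (cell-copy units) across promoters.
#' @param phasing_expression_shift additive log10-expression shift for
#'   promoters with a phased downstream array in a tissue (couples phasing
#'   to expression; set 0 to decouple).
#' @param phased_fraction probability that a promoter carries a phased
#'   downstream array in a given tissue.
#' @param active_fraction probability that a promoter is expressed at all in
#'   a given tissue.
#' @param library_size 5'-tag count per tissue library.
#' @param tissues tissue names (three are expected by downstream stages).
#' @param branch_rate_matrices list of 4x4 substitution matrices for the
#'   `focal`, `sister` and `outgroup` branches (see
#'   [default_rate_matrices()]).
#' @param rate_modulation optional list of position-dependent rate
#'   modulations, each a list with fields `branch`, `from`, `to`, `pos`
#'   (integer positions) and `factor` (scalar multiplier applied to that
#'   substitution probability at those positions).
#' @param strain_log_sd per-strain log10 noise added to tissue expression
#'   when sampling each strain's tag library.
#' @param first_dyad_offset distance from a TSS to its first downstream
#'   dyad, bp.
#' @param seed integer seed; every generator stage derives its own stream
#'   from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1200000L,
                       n_promoters = 300L,
                       upstream_AT_fraction = 0.6,
                       downstream_CG_fraction = 0.6,
                       promoter_window = 500L,
                       nucleosome_spacing = 180L,
                       dyad_jitter_sd = 2,
                       core_length_true = 147L,
                       fragment_length_sd = 4,
                       coverage = 50,
                       end_bias_weight = 2,
                       background_gap_range = c(170L, 230L),
                       core_AT = 0.35,
                       linker_AT = 0.7,
                       expression_log_mean = 0.5,
                       expression_log_sd = 1,
                       phasing_expression_shift = 1,
                       phased_fraction = 1 / 3,
                       active_fraction = 0.9,
                       library_size = 1000000L,
                       tissues = c("testes", "blastulae", "liver"),
                       branch_rate_matrices = default_rate_matrices(),
                       rate_modulation = NULL,
                       strain_log_sd = 0.2,
                       first_dyad_offset = 100L,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_promoters = as.integer(n_promoters),
    upstream_AT_fraction = upstream_AT_fraction,
    downstream_CG_fraction = downstream_CG_fraction,
    promoter_window = as.integer(promoter_window),
    nucleosome_spacing = as.integer(nucleosome_spacing),
    dyad_jitter_sd = dyad_jitter_sd,
    core_length_true = as.integer(core_length_true),
    fragment_length_sd = fragment_length_sd,
    coverage = coverage,
    end_bias_weight = end_bias_weight,
    background_gap_range = as.integer(background_gap_range),
    core_AT = core_AT,
    linker_AT = linker_AT,
    expression_log_mean = expression_log_mean,
    expression_log_sd = expression_log_sd,
    phasing_expression_shift = phasing_expression_shift,
    phased_fraction = phased_fraction,
    active_fraction = active_fraction,
    library_size = as.integer(library_size),
    tissues = tissues,
    branch_rate_matrices = branch_rate_matrices,
    rate_modulation = rate_modulation,
    strain_log_sd = strain_log_sd,
    first_dyad_offset = as.integer(first_dyad_offset),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$upstream_AT_fraction, cfg$downstream_CG_fraction,
             cfg$core_AT, cfg$linker_AT, cfg$phased_fraction,
             cfg$active_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("all probability parameters must lie in [0, 1]")
  }
  if (cfg$core_length_true < 100L || cfg$core_length_true > 250L) {
    stop("core_length_true must lie in [100, 250]")
  }
  if (cfg$end_bias_weight < 1) stop("end_bias_weight must be >= 1")
  mats <- cfg$branch_rate_matrices
  if (!all(c("focal", "sister", "outgroup") %in% names(mats))) {
    stop("branch_rate_matrices must name focal, sister and outgroup branches")
  }
  for (nm in c("focal", "sister", "outgroup")) {
    m <- mats[[nm]]
    if (!is.matrix(m) || !all(dim(m) == c(4, 4))) {
      stop("each branch rate matrix must be 4x4")
    }
    off <- m
    diag(off) <- 0
    if (any(off < 0) || any(rowSums(off) > 1)) {
      stop("off-diagonal substitution probabilities must be non-negative ",
           "with row sums <= 1")
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$genome_length, "bp genome,", x$n_promoters,
      "promoters,", length(x$tissues), "tissues, seed", x$seed, "\n")
  invisible(x)
}
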