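# End-to-end orchestration: simulate -> TSS -> nucleosome map -> phasing ->
# sequence composition -> evolution -> correlation -> group comparisons,
# with optional on-disk outputs and a checksummed manifest.

# pair focal representatives with their nearest same-strand sister
# representative (identity coordinate map, substitution-only evolution)
align_representatives <- function(reps_focal, reps_sister, max_dist = 50L) {
  match_idx <- rep(NA_integer_, nrow(reps_focal))
  for (str in c("+", "-")) {
    fi <- which(reps_focal$strand == str)
    si <- which(reps_sister$strand == str)
    if (length(fi) == 0L || length(si) == 0L) next
    sp <- reps_sister$pos[si]
    ord <- order(sp)
    sp_sorted <- sp[ord]
    j <- findInterval(reps_focal$pos[fi], sp_sorted)
    lo <- pmax(j, 1L)
    hi <- pmin(j + 1L, length(sp_sorted))
    d_lo <- abs(reps_focal$pos[fi] - sp_sorted[lo])
    d_hi <- abs(sp_sorted[hi] - reps_focal$pos[fi])
    pick <- ifelse(d_lo <= d_hi, lo, hi)
    d <- pmin(d_lo, d_hi)
    ok <- d <= max_dist
    match_idx[fi[ok]] <- si[ord][pick[ok]]
  }
  match_idx
}

# one strain's TSS stage: normalize, merge, cluster, select representatives
tss_stage <- function(tags, target_total, min_expr, gap, min_dist) {
  norm <- lapply(tags$tissues, normalize_tags, target_total = target_total)
  merged <- merge_tissue_expression(norm)
  clusters <- call_tss_clusters(merged, min_expr = min_expr, gap = gap)
  reps <- select_representative_tss(clusters, min_dist = min_dist)
  table <- representative_tss_table(reps, clusters, norm, min_expr = min_expr)
  list(normalized = norm, merged = merged, clusters = clusters,
       reps = reps, table = table)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates an ancestral genome with planted promoters and nucleosome
#' arrays, evolves the two strains and the outgroup, samples per-tissue
#' tag libraries and nucleosome reads for both strains, and then runs
#' every analysis stage: TSS calling, dyad-score tracks and fragment-length
#' estimation, stable and first dyads, phasing metrics and consistency
#' groups, composition asymmetry with z-tests and incidence profiles,
#' ancestral inference with mutational-flux tracks and directional tests,
#' the 48-parameter Spearman matrix, and the group comparisons.  Given the
#' same configuration the run is fully reproducible; with `outdir` set,
#' stage outputs are written (FASTA/BED/TSV/JSON) together with a
#' checksummed manifest.
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory.
#' @param target_total tag normalization target (default 300,000).
#' @param min_expr expression cutoff for clustering/activity (default 0.1).
#' @param gap TSS cluster gap (default 20 bp).
#' @param min_dist representative spacing (default 500 bp).
#' @param core_length assumed core length for dyad scoring (default 147).
#' @param grouping_tissue tissue whose downstream consistency defines the
#'   groups (default the first configured tissue).
#' @param dyad_half_width window half-width for dyad-centred profiles
#'   (default 200 bp).
#' @return object of class `nucleocyclic_run` (a list of stage results).
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         target_total = 300000, min_expr = 0.1, gap = 20L,
                         min_dist = 500L, core_length = 147L,
                         grouping_tissue = NULL, dyad_half_width = 200L) {
  tissues <- config$tissues
  if (is.null(grouping_tissue)) grouping_tissue <- tissues[1L]

  # -- simulation -----------------------------------------------------------
  sim <- simulate_ancestor_genome(config)
  evo <- evolve_strains(sim$sequence, config)
  truth <- sim$truth
  truth$substitutions <- evo$substitutions
  genomes <- list(focal = evo$focal, sister = evo$sister,
                  outgroup = evo$outgroup)
  tags <- list(focal = simulate_tag_library(truth, config, "focal"),
               sister = simulate_tag_library(truth, config, "sister"))
  reads <- list(
    focal = simulate_nucleosome_reads(truth, config, genomes$focal, "focal"),
    sister = simulate_nucleosome_reads(truth, config, genomes$sister,
                                       "sister"))

  # -- TSS model ------------------------------------------------------------
  tss <- list(
    focal = tss_stage(tags$focal, target_total, min_expr, gap, min_dist),
    sister = tss_stage(tags$sister, target_total, min_expr, gap, min_dist))
  pair <- align_representatives(tss$focal$reps, tss$sister$reps)
  aligned <- !is.na(pair)
  reps_f <- tss$focal$reps[aligned, , drop = FALSE]
  reps_s <- tss$sister$reps[pair[aligned], , drop = FALSE]
  rownames(reps_f) <- rownames(reps_s) <- NULL
  table_f <- tss$focal$table[aligned, , drop = FALSE]
  table_s <- tss$sister$table[pair[aligned], , drop = FALSE]
  table_f$id <- table_s$id <- seq_len(nrow(table_f))
  rownames(table_f) <- rownames(table_s) <- NULL

  activity <- active_tss_sets(
    as.matrix(table_f[, paste0("expr_", tissues), drop = FALSE]),
    min_expr = min_expr)

  # -- nucleosome map -------------------------------------------------------
  n <- config$genome_length
  # the pipeline only consumes the combined smoothed score (phasing, first
  # dyads) and the focal forward-strand smoothed score (stable dyads);
  # dropping the other components keeps large runs within memory
  slim <- function(track, keep_fwd) {
    track$raw <- NULL
    track$smooth$rev <- NULL
    if (!keep_fwd) track$smooth$fwd <- NULL
    track
  }
  tracks <- list(
    focal = lapply(reads$focal$tissues, function(r) {
      slim(compute_dyad_scores(r, n, core_length), keep_fwd = TRUE)
    }),
    sister = lapply(reads$sister$tissues, function(r) {
      slim(compute_dyad_scores(r, n, core_length), keep_fwd = FALSE)
    }))
  gc(verbose = FALSE)
  fragment_length <- estimate_fragment_length(
    reads$focal$tissues[[grouping_tissue]], genomes$focal)
  stable <- select_stable_dyads(tracks$focal, genomes$focal)
  first <- locate_first_dyads(reps_f, tracks$focal[[grouping_tissue]])

  # -- phasing and groups ---------------------------------------------------
  phasing <- list(
    focal = phasing_metrics(reps_f, tracks$focal),
    sister = phasing_metrics(reps_s, tracks$sister))
  dw <- phasing$focal[phasing$focal$tissue == grouping_tissue &
                        phasing$focal$side == "downstream", ]
  dw <- dw[order(dw$id), ]
  groups <- group_tss_by_consistency(dw$consistency)
  nucleocyclic <- which(groups == 1L)

  # -- sequence composition -------------------------------------------------
  composition <- window_base_counts(genomes$focal, reps_f)
  g1 <- intersect(nucleocyclic, which(!composition$missing))
  ztests <- list()
  for (b in DNA_BASES) {
    n1 <- sum(composition[[paste0(b, "_up")]][g1])
    n2 <- sum(composition[[paste0(b, "_dn")]][g1])
    m <- 500 * length(g1)
    ztests[[b]] <- list(
      printed = asymmetry_ztest(n1, n2, m, m, corrected = FALSE),
      corrected = asymmetry_ztest(n1, n2, m, m, corrected = TRUE))
  }
  tss_profile <- incidence_profile(genomes$focal, reps_f[g1, ],
                                   half_width = 500L, mode = "transcribed")
  fd <- first$first_dyads
  fd_anchors <- fd[fd$id %in% nucleocyclic & !is.na(fd$dyad), ]
  fd_anchors <- fd_anchors[!duplicated(fd_anchors$dyad), ]
  first_profile <- NULL
  genome_profile <- NULL
  seq_dyad_tests <- NULL
  gw_dyads <- stable[[grouping_tissue]]$dyads
  if (nrow(fd_anchors) >= 3L && length(gw_dyads) >= 3L) {
    first_profile <- incidence_profile(
      genomes$focal, data.frame(pos = fd_anchors$dyad,
                                strand = fd_anchors$strand),
      half_width = dyad_half_width, mode = "transcribed",
      anchors_are_dyads = TRUE)
    genome_profile <- incidence_profile(
      genomes$focal, gw_dyads, half_width = dyad_half_width, mode = "both",
      anchors_are_dyads = TRUE)
    seq_dyad_tests <- lapply(stats::setNames(nm = DNA_BASES), function(b) {
      dyad_vs_linker_test(first_profile, genome_profile, b,
                          alternative = "greater")
    })
  }

  # -- evolution ------------------------------------------------------------
  calls <- infer_ancestral_bases(genomes$focal, genomes$sister,
                                 genomes$outgroup)
  tss_rates <- positional_mutation_rates(
    calls, reps_f[nucleocyclic, , drop = FALSE], half_width = 500L,
    mode = "stranded")
  flux <- mutational_flux_summary(tss_rates)
  ctga <- ct_vs_ga_test(tss_rates)
  first_rates <- NULL
  genome_rates <- NULL
  mut_dyad_tests <- NULL
  if (!is.null(first_profile)) {
    first_rates <- positional_mutation_rates(
      calls, data.frame(pos = fd_anchors$dyad, strand = fd_anchors$strand),
      half_width = dyad_half_width, mode = "stranded",
      anchors_are_dyads = TRUE)
    genome_rates <- positional_mutation_rates(
      calls, gw_dyads, half_width = dyad_half_width, mode = "both",
      anchors_are_dyads = TRUE)
    mut_dyad_tests <- lapply(
      stats::setNames(nm = c("C>T", "T>C")), function(ct) {
        mutation_dyad_vs_linker_test(first_rates, genome_rates, ct,
                                     alternative = "greater")
      })
  }

  # -- correlation and group comparisons ------------------------------------
  params <- assemble_parameter_table(
    list(focal = table_f, sister = table_s),
    phasing, composition, tissues)
  correlation <- spearman_matrix(params$table)

  expr_g <- table_f[[paste0("expr_", grouping_tissue)]]
  comparisons <- list(
    expression = compare_groups(log10(expr_g + 0.01), groups, "greater"),
    breadth = compare_groups(table_f[[paste0("breadth_", grouping_tissue)]],
                             groups, "greater"))
  conservation <- compare_strain_tss_distance(
    reps_f$pos, tss$sister$reps$pos, groups = groups)

  run <- structure(list(
    config = config, truth = truth, genomes = genomes,
    tags = tags, reads = reads, tss = tss,
    aligned = list(reps_focal = reps_f, reps_sister = reps_s,
                   table_focal = table_f, table_sister = table_s),
    activity = activity, tracks = tracks,
    fragment_length = fragment_length, stable_dyads = stable,
    first_dyads = first, phasing = phasing, groups = groups,
    composition = composition, ztests = ztests,
    profiles = list(tss = tss_profile, first_dyads = first_profile,
                    genome_dyads = genome_profile),
    seq_dyad_tests = seq_dyad_tests,
    ancestral_calls = calls,
    mutation = list(tss = tss_rates, first_dyads = first_rates,
                    genome_dyads = genome_rates),
    flux = flux, ct_vs_ga = ctga, mut_dyad_tests = mut_dyad_tests,
    parameters = params, correlation = correlation,
    comparisons = comparisons, conservation = conservation),
    class = "nucleocyclic_run")

  if (!is.null(outdir)) {
    run$manifest <- write_run_outputs(run, outdir)
  }
  run
}

#' @export
print.nucleocyclic_run <- function(x, ...) {
  cat("nucleocyclic_run:", nrow(x$aligned$reps_focal),
      "aligned representative TSSs,",
      sum(x$groups == 1L, na.rm = TRUE), "nucleocyclic (Group 1)\n")
  cat("  fragment length:", x$fragment_length$optimal, "bp;",
      "stable dyads:", length(x$stable_dyads[[1]]$dyads), "\n")
  cat("  Group-1 expression p:",
      format(x$comparisons$expression$p.value, digits = 3), "\n")
  invisible(x)
}

# write stage outputs and return a manifest (paths + md5 checksums)
write_run_outputs <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- run$config
  paths <- character(0)
  put <- function(p) {
    paths[[length(paths) + 1L]] <<- p
    p
  }
  for (st in c("focal", "sister", "outgroup")) {
    write_genome_fasta(run$genomes[[st]],
                       put(file.path(outdir, paste0(st, ".fa"))), st)
  }
  for (st in c("focal", "sister")) {
    for (t in cfg$tissues) {
      write_bed6(run$tags[[st]]$tissues[[t]],
                 put(file.path(outdir, paste0("tags_", st, "_", t, ".bed"))))
      write_bed6(run$reads[[st]]$tissues[[t]],
                 put(file.path(outdir, paste0("reads_", st, "_", t, ".bed"))))
    }
    reps <- run$aligned[[paste0("table_", st)]]
    reps0 <- reps
    reps0$pos <- reps0$pos - 1L   # 0-based on disk
    write_tsv(reps0, put(file.path(outdir, paste0("representative_tss_",
                                                  st, ".tsv"))))
    write_tsv(run$phasing[[st]],
              put(file.path(outdir, paste0("phasing_", st, ".tsv"))))
  }
  write_tsv(data.frame(id = run$aligned$table_focal$id, group = run$groups),
            put(file.path(outdir, "groups.tsv")))
  write_tsv(run$composition, put(file.path(outdir, "composition.tsv")))
  write_tsv(run$parameters$table, put(file.path(outdir, "parameters.tsv")))
  rmat <- as.data.frame(run$correlation$r)
  write_tsv(cbind(parameter = rownames(run$correlation$r), rmat),
            put(file.path(outdir, "spearman_r.tsv")))
  for (t in cfg$tissues) {
    write_tsv(data.frame(pos = run$stable_dyads[[t]]$dyads - 1L),
              put(file.path(outdir, paste0("stable_dyads_", t, ".tsv"))))
  }
  rates <- run$mutation$tss
  write_tsv(data.frame(offset = rep(rates$offsets, each = 12L),
                       category = rep(rownames(rates$rate),
                                      times = length(rates$offsets)),
                       rate = as.vector(rates$rate),
                       n = rep(rates$totals, each = 12L)),
            put(file.path(outdir, "mutation_rates_tss.tsv")))
  report <- list(
    seed = cfg$seed,
    n_promoters = cfg$n_promoters,
    n_representative = nrow(run$aligned$reps_focal),
    n_group1 = sum(run$groups == 1L, na.rm = TRUE),
    fragment_length = run$fragment_length$optimal,
    n_stable_dyads = vapply(cfg$tissues, function(t)
      length(run$stable_dyads[[t]]$dyads), integer(1)),
    expression_p = run$comparisons$expression$p.value,
    ct_vs_ga_p = run$ct_vs_ga$p.value,
    parameters_complete = run$parameters$n_complete,
    parameters_dropped = run$parameters$n_dropped)
  report_path <- put(file.path(outdir, "report.json"))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = cfg$seed,
    files = data.frame(path = basename(unlist(paths)),
                       md5 = unname(tools::md5sum(unlist(paths))),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
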