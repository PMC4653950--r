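test_that("degenerate composition makes upstream windows pure A/T", {
  cfg <- small_config(upstream_AT_fraction = 1)
  sim <- simulate_ancestor_genome(cfg)
  g <- strsplit(sim$sequence, "")[[1]]
  tss <- sim$truth$tss
  for (i in seq_len(nrow(tss))) {
    win <- if (tss$strand[i] == "+") {
      g[(tss$pos[i] - 500):(tss$pos[i] - 1)]
    } else {
      g[(tss$pos[i] + 1):(tss$pos[i] + 500)]
    }
    expect_true(all(win %in% c("A", "T")))
  }
})

test_that("the generator is deterministic and spaces promoters apart", {
  cfg <- small_config()
  a <- simulate_ancestor_genome(cfg)
  b <- simulate_ancestor_genome(cfg)
  expect_identical(a, b)
  expect_true(all(diff(sort(a$truth$tss$pos)) > 1000))
  expect_error(simulate_ancestor_genome(
    sim_config(genome_length = 20000L, n_promoters = 50L)),
    "genome too short")
})

test_that("window composition hits its target within binomial error", {
  cfg <- sim_config(genome_length = 100000L, n_promoters = 20L, seed = 5L,
                    upstream_AT_fraction = 0.6)
  sim <- simulate_ancestor_genome(cfg)
  g <- strsplit(sim$sequence, "")[[1]]
  tss <- sim$truth$tss
  at <- 0
  for (i in seq_len(nrow(tss))) {
    win <- if (tss$strand[i] == "+") {
      g[(tss$pos[i] - 500):(tss$pos[i] - 1)]
    } else {
      g[(tss$pos[i] + 1):(tss$pos[i] + 500)]
    }
    at <- at + sum(win %in% c("A", "T"))
  }
  n <- 500 * nrow(tss)
  # binomial oracle: 3 SDs around the configured fraction
  expect_lt(abs(at / n - 0.6), 3 * sqrt(0.6 * 0.4 / n))
})

test_that("zero-rate evolution returns the ancestor unchanged", {
  zero <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"),
                                          c("A","C","G","T")))
  diag(zero) <- 1
  cfg <- small_config(branch_rate_matrices = list(focal = zero, sister = zero,
                                                  outgroup = zero))
  anc <- random_genome(5000, seed = 2)
  evo <- evolve_strains(anc, cfg)
  expect_identical(evo$focal, anc)
  expect_identical(evo$sister, anc)
  expect_identical(evo$outgroup, anc)
  expect_equal(nrow(evo$substitutions), 0L)
})

test_that("a single nonzero rate produces only that substitution", {
  m <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"),
                                       c("A","C","G","T")))
  diag(m) <- 1
  focal <- m
  focal["C", "T"] <- 0.1
  focal["C", "C"] <- 0.9
  cfg <- small_config(branch_rate_matrices = list(focal = focal, sister = m,
                                                  outgroup = m))
  anc <- random_genome(20000, seed = 3)
  evo <- evolve_strains(anc, cfg)
  av <- strsplit(anc, "")[[1]]
  fv <- strsplit(evo$focal, "")[[1]]
  ch <- which(av != fv)
  expect_gt(length(ch), 0)
  expect_true(all(av[ch] == "C" & fv[ch] == "T"))
})

test_that("substitution counts land within 3 binomial SDs of expectation", {
  m <- matrix(0.01, 4, 4, dimnames = list(c("A","C","G","T"),
                                          c("A","C","G","T")))
  diag(m) <- 0
  diag(m) <- 1 - rowSums(m)
  cfg <- sim_config(genome_length = 100000L, n_promoters = 0L, seed = 4L,
                    branch_rate_matrices = list(focal = m, sister = m,
                                                outgroup = m))
  anc <- random_genome(1000000, seed = 4)
  evo <- evolve_strains(anc, cfg)
  for (br in c("focal", "sister", "outgroup")) {
    k <- sum(evo$substitutions$branch == br)
    expected <- 1e6 * 0.03
    expect_lt(abs(k - expected), 3 * sqrt(1e6 * 0.03 * 0.97))
  }
})

test_that("substitution records reconstruct each descendant exactly", {
  cfg <- small_config()
  sim <- simulate_ancestor_genome(cfg)
  evo <- evolve_strains(sim$sequence, cfg)
  av <- strsplit(sim$sequence, "")[[1]]
  for (br in c("focal", "sister", "outgroup")) {
    rebuilt <- av
    sub <- evo$substitutions[evo$substitutions$branch == br, ]
    expect_true(all(rebuilt[sub$pos] == sub$ancestral))
    rebuilt[sub$pos] <- sub$derived
    expect_identical(paste(rebuilt, collapse = ""), evo[[br]])
  }
})

test_that("tag libraries concentrate at planted TSSs with exact totals", {
  cfg <- sim_config(genome_length = 25000L, n_promoters = 1L,
                    library_size = 1000L, active_fraction = 1, seed = 6L)
  sim <- simulate_ancestor_genome(cfg)
  lib <- simulate_tag_library(sim$truth, cfg)
  for (t in cfg$tissues) {
    d <- lib$tissues[[t]]
    expect_equal(sum(d$count), 1000)
    expect_true(all(abs(d$pos - sim$truth$tss$pos) <= 10))
  }
})

test_that("log-normal expression variance is recovered across promoters", {
  cfg <- sim_config(genome_length = 150000L, n_promoters = 50L,
                    expression_log_sd = 1, phasing_expression_shift = 0,
                    active_fraction = 1, library_size = 2000000L, seed = 8L)
  sim <- simulate_ancestor_genome(cfg)
  lib <- simulate_tag_library(sim$truth, cfg)
  d <- lib$tissues[[1]]
  tot <- tapply(d$count, findInterval(d$pos, sim$truth$tss$pos - 11), sum)
  # log-normal sampling oracle: sample variance of log mass within 40% of 1
  v <- stats::var(log10(as.numeric(tot)))
  expect_lt(abs(v - 1), 0.4)
})

test_that("nucleosome reads obey midpoint arithmetic without noise", {
  cfg <- sim_config(genome_length = 50000L, n_promoters = 0L,
                    dyad_jitter_sd = 0, fragment_length_sd = 0,
                    core_length_true = 147L, end_bias_weight = 1,
                    coverage = 20, seed = 10L)
  sim <- simulate_ancestor_genome(cfg)
  reads <- simulate_nucleosome_reads(sim$truth, cfg, sim$sequence)
  r <- reads$tissues[[1]]
  dy <- sim$truth$dyads[[1]]$pos
  fwd <- r$pos[r$strand == "+"]
  rev_ <- r$pos[r$strand == "-"]
  expect_true(all((fwd + 73) %in% dy))
  expect_true(all((rev_ - 73) %in% dy))
})

test_that("read strands are balanced and coverage matches its mean", {
  cfg <- sim_config(genome_length = 120000L, n_promoters = 0L,
                    coverage = 50, seed = 12L)
  sim <- simulate_ancestor_genome(cfg)
  reads <- simulate_nucleosome_reads(sim$truth, cfg, sim$sequence)
  r <- reads$tissues[[1]]
  n <- nrow(r)
  expect_gt(n, 10000)
  # binomial oracle on the strand split
  expect_lt(abs(mean(r$strand == "+") - 0.5), 3 * sqrt(0.25 / n))
  expect_lt(abs(n / length(sim$truth$dyads[[1]]$pos) - 50), 5)
})
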