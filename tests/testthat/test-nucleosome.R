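test_that("dyad scores place read midpoints correctly", {
  reads <- data.frame(pos = 1000L, strand = "+")
  tr <- compute_dyad_scores(reads, genome_length = 2000L)
  expect_equal(which(tr$raw$fwd == 1L), 1073L)  # 1000 + floor(146/2)
  expect_equal(sum(tr$raw$fwd), 1L)
  rev_ <- compute_dyad_scores(data.frame(pos = 1073L, strand = "-"), 2000L)
  expect_equal(which(rev_$raw$rev == 1L), 1000L)
})

test_that("dyad scoring is strand-symmetric under reflection", {
  set.seed(41)
  n <- 4000L
  reads <- data.frame(pos = sample(200:3800, 300, replace = TRUE),
                      strand = sample(c("+", "-"), 300, replace = TRUE))
  tr <- compute_dyad_scores(reads, n)
  mirrored <- data.frame(pos = n + 1L - reads$pos,
                         strand = ifelse(reads$strand == "+", "-", "+"))
  tr2 <- compute_dyad_scores(mirrored, n)
  expect_equal(rev(tr2$raw$rev), tr$raw$fwd)
  expect_equal(rev(tr2$raw$fwd), tr$raw$rev)
  expect_equal(rev(tr2$smooth$all), tr$smooth$all)
})

test_that("noiseless reads give a smoothed peak exactly at the dyad", {
  # direct convolution oracle: a point mass box-smoothed is a plateau whose
  # peak is its centre, the dyad itself
  d <- 1500L
  reads <- rbind(data.frame(pos = rep(d - 73L, 25), strand = "+"),
                 data.frame(pos = rep(d + 73L, 25), strand = "-"))
  tr <- compute_dyad_scores(reads, 3000L)
  peaks <- nucleocyclic:::call_score_peaks(tr$smooth$fwd)
  expect_equal(peaks, d)
})

test_that("fragment-length discrepancy is zero (and tie-broken low) on a
           structureless genome", {
  g <- paste(rep("A", 3000), collapse = "")
  reads <- data.frame(pos = c(500L, 1000L, 2400L, 2500L),
                      strand = c("+", "+", "-", "-"))
  fl <- estimate_fragment_length(reads, g)
  expect_true(all(fl$discrepancy == 0))
  expect_equal(fl$optimal, 137L)    # exact tie: smaller L wins
  expect_true(all(fl$v_plus == 1))
})

test_that("fragment-length estimator recovers the true length", {
  cfg <- sim_config(genome_length = 100000L, n_promoters = 0L, coverage = 40,
                    core_length_true = 150L, seed = 13L)
  sim <- simulate_ancestor_genome(cfg)
  reads <- simulate_nucleosome_reads(sim$truth, cfg, sim$sequence)
  fl <- estimate_fragment_length(reads$tissues[[1]], sim$sequence)
  # brute-force check over all 21 candidates is what the function returns
  expect_equal(length(fl$discrepancy), 21L)
  expect_lte(abs(fl$optimal - 150L), 1L)
})

test_that("fragment-length discrepancy is invariant under reflection", {
  cfg <- sim_config(genome_length = 60000L, n_promoters = 0L, coverage = 20,
                    seed = 14L)
  sim <- simulate_ancestor_genome(cfg)
  reads <- simulate_nucleosome_reads(sim$truth, cfg, sim$sequence)$tissues[[1]]
  fl <- estimate_fragment_length(reads, sim$sequence)
  n <- cfg$genome_length
  g_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sim$sequence)))
  mirrored <- data.frame(pos = n + 1L - reads$pos,
                         strand = ifelse(reads$strand == "+", "-", "+"))
  fl2 <- estimate_fragment_length(mirrored, g_rc)
  expect_equal(fl2$discrepancy, fl$discrepancy)
  expect_equal(fl2$optimal, fl$optimal)
})

test_that("isolation filter removes both members of a close peak pair", {
  n <- 8000L
  raw <- rep(0L, n)
  raw[c(1000L, 1150L)] <- 40L   # 150 bp apart: both must go
  raw[4000L] <- 40L             # isolated control
  tr <- fake_track(raw)
  tracks <- list(testes = tr, blastulae = tr, liver = tr)
  st <- select_stable_dyads(tracks, random_genome(n, 51))
  expect_equal(st$testes$dyads, 4000L)
  cand <- st$testes$candidates
  expect_equal(cand$eliminated_by[cand$pos %in% c(1000L, 1150L)],
               rep("isolation", 2))
})

test_that("uniqueness filter removes dyads flanked by repeated 25-mers", {
  set.seed(52)
  g <- sample(c("A", "C", "G", "T"), 8000, replace = TRUE)
  # duplicate a 25-mer from the flank of the dyad at 1000 to position 6000
  g[6000:6024] <- g[1050:1074]
  n <- length(g)
  raw <- rep(0L, n)
  raw[c(1000L, 4000L)] <- 40L
  tr <- fake_track(raw)
  tracks <- list(testes = tr, blastulae = tr, liver = tr)
  st <- select_stable_dyads(tracks, paste(g, collapse = ""))
  cand <- st$testes$candidates
  expect_equal(cand$eliminated_by[cand$pos == 1000L], "uniqueness")
  expect_true(4000L %in% st$testes$dyads)
})

test_that("cross-tissue filter requires partners within 10 bp", {
  n <- 8000L
  raw1 <- rep(0L, n); raw1[c(1000L, 4000L)] <- 40L
  raw2 <- rep(0L, n); raw2[c(1008L, 4000L)] <- 40L   # partner at 8 bp
  raw3 <- rep(0L, n); raw3[c(1030L, 4000L)] <- 40L   # partner at 30 bp
  tracks <- list(testes = fake_track(raw1), blastulae = fake_track(raw2),
                 liver = fake_track(raw3))
  st <- select_stable_dyads(tracks, random_genome(n, 53))
  expect_equal(st$testes$dyads, 4000L)
  cand <- st$testes$candidates
  expect_equal(cand$eliminated_by[cand$pos == 1000L], "cross_tissue")
  expect_error(select_stable_dyads(tracks[1:2], random_genome(n, 53)),
               "three tissues")
})

test_that("stable dyads recover planted positions on 3-tissue simulations", {
  cfg <- sim_config(genome_length = 200000L, n_promoters = 0L, coverage = 50,
                    dyad_jitter_sd = 2, seed = 15L)
  sim <- simulate_ancestor_genome(cfg)
  reads <- simulate_nucleosome_reads(sim$truth, cfg, sim$sequence)
  tracks <- lapply(reads$tissues, compute_dyad_scores,
                   genome_length = cfg$genome_length)
  st <- select_stable_dyads(tracks, sim$sequence)
  bg <- sim$truth$background_dyads
  for (t in names(st)) {
    recall <- mean(nucleocyclic:::nearest_distance(bg, st[[t]]$dyads) <= 5)
    expect_gt(recall, 0.9)
    # every filter only removes: final set is a subset of the candidates
    expect_true(all(st[[t]]$dyads %in% st[[t]]$candidates$pos))
  }
})

test_that("first dyads take the downstream score maximum or stay undefined", {
  n <- 3000L
  raw <- rep(0L, n)
  raw[1100L] <- 5L
  tr <- fake_track(raw, raw)
  reps <- data.frame(pos = c(1000L, 2000L), strand = "+")
  fd <- locate_first_dyads(reps, tr)
  expect_equal(fd$first_dyads$dyad[1], 1100L)
  expect_equal(fd$first_dyads$offset[1], 100L)
  expect_true(is.na(fd$first_dyads$dyad[2]))   # all-zero window
  # two TSSs sharing one dyad: a single occurrence in the unique list
  reps2 <- data.frame(pos = c(1000L, 990L), strand = "+")
  fd2 <- locate_first_dyads(reps2, tr)
  expect_equal(fd2$dyads, 1100L)
  # minus-strand windows run upstream in genome coordinates
  repm <- data.frame(pos = 1200L, strand = "-")
  fdm <- locate_first_dyads(repm, tr)
  expect_equal(fdm$first_dyads$dyad, 1100L)
})
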