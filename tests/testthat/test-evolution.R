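fitch_oracle <- function(f, s, o) {
  # exhaustive parsimony over the ((focal, sister), outgroup) tree: choose
  # internal-node states minimizing changes; the focal/sister ancestor is
  # reported only when unambiguous
  bases <- c("A", "C", "G", "T")
  best <- Inf
  anc_set <- character(0)
  for (anc in bases) for (root in bases) {
    cost <- (anc != f) + (anc != s) + (root != anc) + (root != o)
    if (cost < best) {
      best <- cost
      anc_set <- anc
    } else if (cost == best) {
      anc_set <- union(anc_set, anc)
    }
  }
  if (length(anc_set) == 1L) anc_set else NA_character_
}

test_that("ancestral inference agrees with the exhaustive parsimony oracle", {
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(f = bases, s = bases, o = bases,
                        stringsAsFactors = FALSE)
  calls <- infer_ancestral_bases(combos$f, combos$s, combos$o)
  for (i in seq_len(nrow(combos))) {
    oracle <- fitch_oracle(combos$f[i], combos$s[i], combos$o[i])
    if (!is.na(oracle) && (combos$o[i] == combos$f[i] ||
                           combos$o[i] == combos$s[i])) {
      expect_equal(calls$ancestor[i], oracle,
                   info = paste(combos[i, ], collapse = ","))
    } else {
      # outgroup matching neither descendant: undetermined by the rule
      expect_equal(as.character(calls$status[i]), "undetermined")
    }
  }
  # the three canonical cases
  one <- infer_ancestral_bases(c("A", "G", "A"), c("A", "A", "C"),
                               c("A", "A", "G"))
  expect_equal(as.character(one$status), c("no_mutation", "mutated",
                                           "undetermined"))
  expect_equal(one$category[2], "A>G")
})

test_that("gaps and ambiguity codes exclude sites; statuses partition", {
  calls <- infer_ancestral_bases(c("A", "N", "-"), c("A", "A", "A"),
                                 c("A", "A", "A"))
  expect_equal(as.character(calls$status), c("no_mutation", "excluded",
                                             "excluded"))
  set.seed(81)
  f <- sample(c("A", "C", "G", "T", "N"), 500, replace = TRUE)
  s <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
  o <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
  calls2 <- infer_ancestral_bases(f, s, o)
  expect_equal(sum(table(calls2$status)), 500L)
  expect_true(all(!is.na(calls2$category[calls2$status == "mutated"])))
})

test_that("positional rates are exact count ratios at each offset", {
  n <- 2000L
  # 100 anchors; at offset +5, exactly 2 of them carry a C>T mutation
  anchors <- seq(505L, by = 10L, length.out = 100L)
  mut <- data.frame(pos = anchors[c(10, 60)] + 5L, from = "C", to = "T")
  calls <- constructed_calls(n, mut, seed = 82)
  tr <- positional_mutation_rates(calls, anchors, half_width = 5L,
                                  mode = "stranded", smooth = 3L)
  expect_equal(tr$rate["C>T", "5"], 0.02)
  expect_equal(sum(tr$counts[, "5"]), 2)
  expect_equal(tr$totals[["5"]], 100)
  # zero-rate history: all rates zero
  none <- positional_mutation_rates(constructed_calls(n, NULL, 82), anchors,
                                    half_width = 5L, smooth = 3L)
  expect_true(all(none$rate == 0))
})

test_that("minus-strand anchors complement the mutation category", {
  n <- 1000L
  mut <- data.frame(pos = 505L, from = "C", to = "T")
  calls <- constructed_calls(n, mut, seed = 83)
  plus <- positional_mutation_rates(
    calls, data.frame(pos = 500L, strand = "+"), half_width = 10L,
    smooth = 3L)
  minus <- positional_mutation_rates(
    calls, data.frame(pos = 510L, strand = "-"), half_width = 10L,
    smooth = 3L)
  expect_equal(plus$rate["C>T", "5"], 1)
  # on the transcribed strand of the minus anchor the same site is G>A at +5
  expect_equal(minus$rate["G>A", "5"], 1)
})

test_that("planted branch matrices are recovered within 3 binomial SDs", {
  m <- default_rate_matrices()$focal
  cfg <- sim_config(genome_length = 100000L, n_promoters = 0L, seed = 16L)
  anc <- random_genome(100000, seed = 16)
  evo <- evolve_strains(anc, cfg)
  calls <- infer_ancestral_bases(evo$focal, evo$sister, evo$outgroup)
  est <- substitution_rate_estimate(calls)
  det <- calls$status %in% c("no_mutation", "mutated")
  for (x in rownames(m)) for (y in colnames(m)) {
    if (x == y) next
    n_x <- sum(calls$ancestor[det] == x)
    tol <- 3 * sqrt(m[x, y] * (1 - m[x, y]) / n_x)
    expect_lt(abs(est[x, y] - m[x, y]), tol + 0.1 * m[x, y])
  }
})

test_that("flux summaries respect definitions and conservation", {
  n <- 3000L
  anchors <- data.frame(pos = c(1000L, 2000L), strand = "+")
  mut <- data.frame(pos = c(1010L, 2020L), from = "C", to = "A")
  calls <- constructed_calls(n, mut, seed = 84)
  tr <- positional_mutation_rates(calls, anchors, half_width = 100L,
                                  smooth = 3L)
  fx <- mutational_flux_summary(tr, regions = list(all = c(-100L, 100L)))
  expect_equal(unname(fx$all$flow_in["A"]), unname(fx$all$rates["C>A"]))
  expect_equal(unname(fx$all$flow_out["C"]), unname(fx$all$rates["C>A"]))
  expect_equal(sum(fx$all$net), 0)
  # symmetric rates: every net flow vanishes
  mut2 <- data.frame(pos = c(1010L, 2020L), from = c("C", "T"),
                     to = c("T", "C"))
  fx2 <- mutational_flux_summary(
    positional_mutation_rates(constructed_calls(n, mut2, 84), anchors,
                              half_width = 100L, smooth = 3L),
    regions = list(all = c(-100L, 100L)))
  expect_equal(unname(fx2$all$net), rep(0, 4))
  # conservation on arbitrary random histories
  set.seed(85)
  mut3 <- data.frame(pos = sample(900:2100, 40),
                     from = sample(c("A", "C", "G", "T"), 40, TRUE),
                     to = sample(c("A", "C", "G", "T"), 40, TRUE))
  mut3 <- mut3[mut3$from != mut3$to, ]
  fx3 <- mutational_flux_summary(
    positional_mutation_rates(constructed_calls(n, mut3, 85), anchors,
                              half_width = 100L, smooth = 3L),
    regions = list(all = c(-100L, 100L)))
  expect_equal(sum(fx3$all$net), 0)
})

test_that("opposite dyad/linker rate modulation is detected one-tailed", {
  set.seed(86)
  n <- 60000L
  first_dyads <- seq(2000L, 28000L, by = 400L)
  gw_dyads <- seq(32000L, 58000L, by = 400L)
  near <- function(centers, lo, hi) {
    unique(as.vector(outer(centers, lo:hi, `+`)))
  }
  # C>T boosted at first-dyad cores and at genome-wide linkers
  anc <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  foc <- anc
  boost <- c(near(first_dyads, -30L, 30L), near(gw_dyads, 70L, 130L))
  base_sites <- which(anc == "C")
  hit <- base_sites[runif(length(base_sites)) <
                      ifelse(base_sites %in% boost, 0.25, 0.02)]
  foc[hit] <- "T"
  calls <- infer_ancestral_bases(foc, anc, anc)
  tr_first <- positional_mutation_rates(
    calls, data.frame(pos = first_dyads, strand = "+"), half_width = 200L,
    mode = "stranded", anchors_are_dyads = TRUE)
  tr_gw <- positional_mutation_rates(calls, gw_dyads, half_width = 200L,
                                     mode = "both", anchors_are_dyads = TRUE)
  res <- mutation_dyad_vs_linker_test(tr_first, tr_gw, "C>T",
                                      alternative = "greater")
  expect_lt(res$p.value, 0.05)
  # doubling both tracks scales every difference, leaving ranks (and p)
  # unchanged
  tr_first2 <- tr_first
  tr_gw2 <- tr_gw
  tr_first2$rate <- 2 * tr_first$rate
  tr_gw2$rate <- 2 * tr_gw$rate
  expect_equal(mutation_dyad_vs_linker_test(tr_first2, tr_gw2, "C>T",
                                            alternative = "greater")$p.value,
               res$p.value)
  expect_error(mutation_dyad_vs_linker_test(tr_first, tr_gw, "C>X"),
               "ordered base changes")
})

test_that("downstream-only C>T excess drives the strand-bias test", {
  n <- 30000L
  anchors <- data.frame(pos = seq(2000L, 28000L, by = 1200L), strand = "+")
  set.seed(87)
  anc <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  foc <- anc
  dn_sites <- unique(as.vector(outer(anchors$pos, 1:500, `+`)))
  hit <- intersect(which(anc == "C"), dn_sites)
  hit <- hit[runif(length(hit)) < 0.1]
  foc[hit] <- "T"
  calls <- infer_ancestral_bases(foc, anc, anc)
  tr <- positional_mutation_rates(calls, anchors, half_width = 500L)
  res <- ct_vs_ga_test(tr)
  expect_lt(res$p.value, 0.01)
  # no mutations at all: every difference ties at zero, boundary p
  null_tr <- positional_mutation_rates(constructed_calls(n, NULL, 87),
                                       anchors, half_width = 500L)
  null_res <- ct_vs_ga_test(null_tr)
  expect_true(null_res$degenerate)
  expect_equal(null_res$p.value, 0.5)
})

test_that("a strand-symmetric history rejects at roughly the nominal rate", {
  set.seed(88)
  n <- 20000L
  anchors <- data.frame(pos = seq(1000L, 19000L, by = 1500L), strand = "+")
  rej <- 0
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    anc <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    foc <- anc
    sites <- which(runif(n) < 0.02)
    foc[sites] <- vapply(anc[sites], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    calls <- infer_ancestral_bases(foc, anc, anc)
    tr <- positional_mutation_rates(calls, anchors, half_width = 500L)
    rej <- rej + (ct_vs_ga_test(tr)$p.value < 0.05)
  }
  expect_lte(rej / n_rep, 0.15)
})
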