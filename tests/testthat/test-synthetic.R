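test_that("scenario validation rejects impossible parameters", {
  expect_error(simulation_scenario(concordance = 1.2), "probabilities")
  expect_error(simulation_scenario(subtype_probs = c(g1 = 0.5, g2 = 0.5,
                                                     g3 = 0.5, g4 = 0.5)),
               "sum to 1")
  expect_error(simulation_scenario(linked_loci = list(
    list(chrom = 1, cm = 10, subtype = "g1", lambda_s = 0.5))), "lambda_s")
  expect_error(simulation_scenario(linked_loci = list(
    list(chrom = 1, cm = 10, subtype = "g9", lambda_s = 2))), "subtype")
})

test_that("the lambda_s sharing triple follows the no-dominance identity", {
  expect_equal(asp_sharing_triple(1), c(0.25, 0.5, 0.25))
  expect_equal(asp_sharing_triple(2), c(0.125, 0.5, 0.375))
  z <- asp_sharing_triple(4)
  expect_equal(sum(z), 1)
  expect_equal(z[1], 0.0625)
})

test_that("a fixed seed gives byte-identical PED/MAP/subtype files", {
  sc <- simulation_scenario(n_families = 8, n_chrom = 2, markers_per_chrom = 6,
                            spacing_cm = 10, missing_rate = 0.02)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(sc, seed = 99), d1)
  write_cohort(simulate_cohort(sc, seed = 99), d2)
  for (f in c("cohort.ped", "cohort.map", "cohort.subtypes.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  ## different seed differs
  write_cohort(simulate_cohort(sc, seed = 100), d2)
  expect_false(identical(readLines(file.path(d1, "cohort.ped")),
                         readLines(file.path(d2, "cohort.ped"))))
})

test_that("null loci give the uniform affected-pair IBD triple", {
  ## lambda_s = 1 locus: sharing at the locus must match (0.25, 0.5, 0.25)
  sc <- simulation_scenario(n_families = 1000, n_chrom = 1,
                            markers_per_chrom = 3, spacing_cm = 20,
                            concordance = 1,
                            subtype_probs = c(g1 = 1, g2 = 0, g3 = 0, g4 = 0),
                            sibship_probs = c("2" = 1),
                            n_affected_probs = c("2" = 1),
                            linked_loci = list(list(chrom = 1, cm = 20,
                                                    subtype = "g1",
                                                    lambda_s = 1)),
                            keep_inheritance = TRUE)
  sim <- simulate_cohort(sc, seed = 31)
  ibd <- vapply(sim$truth$inheritance, function(fam) {
    b <- fam[["1"]]
    sum(b$pat[1, 2] == b$pat[2, 2], b$mat[1, 2] == b$mat[2, 2])
  }, numeric(1))
  counts <- tabulate(ibd + 1, 3)
  expect_gt(stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value, 0.001)
})

test_that("a lambda_s = 2 locus inflates sharing per the ASP triple", {
  sc <- simulation_scenario(n_families = 1500, n_chrom = 1,
                            markers_per_chrom = 3, spacing_cm = 20,
                            concordance = 1,
                            subtype_probs = c(g1 = 1, g2 = 0, g3 = 0, g4 = 0),
                            sibship_probs = c("2" = 1),
                            n_affected_probs = c("2" = 1),
                            linked_loci = list(list(chrom = 1, cm = 20,
                                                    subtype = "g1",
                                                    lambda_s = 2)),
                            keep_inheritance = TRUE)
  sim <- simulate_cohort(sc, seed = 32)
  ibd <- vapply(sim$truth$inheritance, function(fam) {
    b <- fam[["1"]]
    sum(b$pat[1, 2] == b$pat[2, 2], b$mat[1, 2] == b$mat[2, 2])
  }, numeric(1))
  counts <- tabulate(ibd + 1, 3)
  expect_gt(stats::chisq.test(counts, p = asp_sharing_triple(2))$p.value, 0.001)
  ## and clearly not null sharing
  expect_lt(stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value, 1e-6)
})

test_that("inject_noise masks and corrupts at the requested rates", {
  sc <- simulation_scenario(n_families = 25, n_chrom = 1, markers_per_chrom = 20,
                            spacing_cm = 5)
  sim <- simulate_cohort(sc, seed = 44)
  ## identity at zero rates
  same <- inject_noise(sim, 0, 0, seed = 1)
  expect_equal(same$cohort, sim$cohort)
  ## masked fraction within binomial bounds at rate 0.5
  noisy <- inject_noise(sim, 0.5, 0, seed = 2)
  calls <- do.call(rbind, lapply(noisy$cohort, function(p) p$genotypes))
  n_calls <- nrow(calls) * ncol(calls) / 2
  frac <- mean(calls[, seq(1, ncol(calls), by = 2)] == 0L)
  half <- qnorm(0.995) * sqrt(0.25 / n_calls)
  expect_lt(abs(frac - 0.5), half)
  ## injected Mendelian errors: detected inconsistencies agree with the
  ## exhaustive trio oracle and occur only at recorded injection sites
  err <- inject_noise(sim, 0, 0.02, seed = 3)
  counts <- mendelian_check(err$cohort)
  hits <- err$truth$noise$errors
  expect_gt(length(hits), 0)
  for (fam in names(err$cohort))
    expect_equal(unname(counts[, fam]), oracle_mendel_family(err$cohort[[fam]]))
  flagged <- which(counts > 0, arr.ind = TRUE)
  expect_gt(nrow(flagged), 0)
  for (r in seq_len(nrow(flagged))) {
    fam <- colnames(counts)[flagged[r, 2]]
    expect_true(flagged[r, 1] %in% hits[[fam]]$marker)
  }
})

test_that("stratified linkage uncovers a subgroup-private locus (scaled demo)", {
  ## small-scale version of the central claim: a g1-private locus yields a
  ## higher LOD in G1s than in the undivided cohort
  sc <- simulation_scenario(n_families = 60, n_chrom = 1, markers_per_chrom = 13,
                            spacing_cm = 10, concordance = 0.5,
                            linked_loci = list(list(chrom = 1, cm = 60,
                                                    subtype = "g1",
                                                    lambda_s = 8)))
  diffs <- vapply(1:5, function(s) {
    sim <- simulate_cohort(sc, seed = 500 + s)
    cache <- linkage_cache(sim$cohort, sim$map)
    g1s <- stratify_catalogue(sim$cohort, sim$subtypes, stage = "n2")$G1s
    all_curve <- scan_genome(sim$cohort, sim$map, cache = cache)
    g1s_curve <- scan_genome(sim$cohort, sim$map, strat = g1s, cache = cache)
    max(g1s_curve$lod) - max(all_curve$lod)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
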