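test_that("Haldane map function behaves at its limits and closed form", {
  expect_equal(haldane_theta(0), 0)
  expect_equal(haldane_theta(1e9), 0.5, tolerance = 1e-12)
  expect_equal(haldane_theta(50), 0.5 * (1 - exp(-1)))
  expect_error(haldane_theta(-1), "negative")
})

test_that("fully informative sib pair gives posterior IBD2 of 1", {
  mem <- data.frame(indiv_id = c("P1", "P2", "K1", "K2"),
                    father_id = c(NA, NA, "P1", "P1"),
                    mother_id = c(NA, NA, "P2", "P2"),
                    sex = c("male", "female", "male", "male"),
                    affection = c("unknown", "unknown", "affected", "affected"))
  ## parents 1/2 x 3/4, both sibs 1/3
  ped <- pedigree("F1", mem, rbind(c(1L, 2L), c(3L, 4L),
                                   c(1L, 3L), c(1L, 3L)))
  map <- toy_map(0)
  freqs <- list(c("1" = 0.25, "2" = 0.25, "3" = 0.25, "4" = 0.25))
  dist <- lander_green_ibd(ped, map, freqs)
  npl <- npl_pairs(ped, dist, c("K1", "K2"))
  expect_equal(npl$score, 2, tolerance = 1e-12)       # IBD2 certain
  expect_equal(npl$Z, sqrt(2), tolerance = 1e-12)     # (2-1)/sqrt(1/2)
  expect_equal(attr(npl, "z_min"), -sqrt(2), tolerance = 1e-12)
})

test_that("single-marker posterior equals founder-genotype enumeration", {
  ## parents untyped, both sibs 1/1 at allele-1 frequency 0.5
  ped <- rand_nuclear(2, cm = 0, freq1 = 0.5)
  ped$genotypes[1:2, ] <- 0L
  ped$genotypes[3:4, ] <- 1L
  freqs <- uniform_freqs(1)
  dist <- lander_green_ibd(ped, toy_map(0), freqs)
  oracle <- oracle_posterior(ped, 0, freqs)
  expect_equal(dist$posterior[1, ], oracle[1, ], tolerance = 1e-12)
})

test_that("multipoint HMM equals joint enumeration on random small families", {
  set.seed(101)
  for (rep in 1:12) {
    nk <- sample(1:3, 1)
    Tn <- sample(1:3, 1)
    cm <- sort(runif(Tn, 0, 60))
    p1 <- runif(1, 0.2, 0.8)
    ped <- rand_nuclear(nk, cm, freq1 = p1, missing_prob = 0.2,
                        parents_typed = runif(1) < 0.7)
    freqs <- uniform_freqs(Tn, p1)
    dist <- lander_green_ibd(ped, toy_map(cm), freqs)
    oracle <- oracle_posterior(ped, cm, freqs)
    expect_equal(dist$posterior, oracle, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("far from any marker the posterior relaxes to the uniform prior", {
  set.seed(55)
  ped <- rand_nuclear(2, cm = c(0, 5), freq1 = 0.5)
  pos <- data.frame(chrom = 1L, cm = c(0, 5, 500))
  dist <- lander_green_ibd(ped, toy_map(c(0, 5)), uniform_freqs(2), positions = pos)
  expect_equal(dist$posterior[3, ], rep(1 / 16, 16), tolerance = 1e-3)
  npl <- npl_pairs(ped, dist, c("K01", "K02"))
  expect_equal(npl$Z[3], 0, tolerance = 1e-2)
})

test_that("S_pairs over three affected sibs equals the pairwise sum", {
  set.seed(7)
  ped <- rand_nuclear(3, cm = c(0, 10), freq1 = 0.4)
  freqs <- uniform_freqs(2, 0.4)
  dist <- lander_green_ibd(ped, toy_map(c(0, 10)), freqs)
  all3 <- npl_pairs(ped, dist, c("K01", "K02", "K03"))
  ## brute force: sum expected pairwise sharing from the posterior
  lay <- dist$layout
  pair_share <- function(i, j)
    (lay$patbit[[i]] == lay$patbit[[j]]) + (lay$matbit[[i]] == lay$matbit[[j]])
  S <- pair_share(1, 2) + pair_share(1, 3) + pair_share(2, 3)
  expect_equal(all3$score, as.numeric(dist$posterior %*% S), tolerance = 1e-12)
  ## null moments for 3 sibs: mean 3, sd sqrt(3/2)
  expect_equal(all3$mu0[1], 3)
  expect_equal(all3$sd0[1], sqrt(1.5), tolerance = 1e-12)
})

test_that("uninformative families are flagged", {
  ped <- rand_nuclear(2, cm = 0, freq1 = 0.5)
  dist <- lander_green_ibd(ped, toy_map(0), uniform_freqs(1))
  expect_warning(res <- npl_pairs(ped, dist, "K01"), "uninformative")
  expect_null(res)
})

test_that("Kong-Cox maximization handles the canonical cases", {
  expect_equal(kong_cox_lod(c(0, 0, 0))$lod, 0)
  expect_equal(kong_cox_lod(c(0, 0, 0))$delta_hat, 0)
  expect_equal(kong_cox_lod(c(1, -1))$lod, 0)
  res <- kong_cox_lod(c(2, -0.5))
  expect_equal(res$delta_hat, 0.75, tolerance = 1e-6)
  expect_equal(res$lod, log10((1 + 2 * 0.75) * (1 - 0.5 * 0.75)),
               tolerance = 1e-9)
  ## sib-pair attainable-minimum constraint reproduces the 1/sqrt(2) cap
  res <- kong_cox_lod(c(2, 1.5), z_min = rep(-sqrt(2), 2))
  expect_equal(res$delta_hat, 1 / sqrt(2), tolerance = 1e-6)
})

test_that("Kong-Cox equals the dense grid-search oracle", {
  set.seed(202)
  for (i in 1:60) {
    n <- sample(2:20, 1)
    z <- rnorm(n, sd = runif(1, 0.5, 2))
    res <- kong_cox_lod(z)
    orc <- oracle_kc_grid(z)
    expect_equal(res$lod, orc$lod, tolerance = 1e-4)
  }
})

test_that("LOD to pointwise p-value reproduces the published arithmetic", {
  expect_equal(round(lod_to_pvalue(1.41), 3), 0.005)
  expect_equal(lod_to_pvalue(0), 0.5)
  expect_equal(round(lod_to_pvalue(3.50), 5), 0.00003)
  expect_error(lod_to_pvalue(-0.1), "negative")
  lods <- seq(0, 6, by = 0.01)
  p <- lod_to_pvalue(lods)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p <= 0.5))
})

test_that("a one-family scan equals that family's own LOD curve", {
  set.seed(77)
  ped <- rand_nuclear(2, cm = seq(0, 40, by = 10), freq1 = 0.5)
  cohort <- list(FX = ped)
  map <- toy_map(seq(0, 40, by = 10))
  curve <- scan_genome(cohort, map, allele_freqs = uniform_freqs(5))
  dist <- lander_green_ibd(ped, map, uniform_freqs(5))
  npl <- npl_pairs(ped, dist, c("K01", "K02"))
  for (i in seq_len(nrow(curve))) {
    single <- kong_cox_lod(npl$Z[i], z_min = attr(npl, "z_min"))
    expect_equal(curve$lod[i], single$lod, tolerance = 1e-9)
  }
  expect_equal(attr(curve, "n_families"), 1L)
})

test_that("scan is invariant under allele relabeling and family order", {
  set.seed(88)
  sim <- simulate_cohort(simulation_scenario(n_families = 12, n_chrom = 1,
                                             markers_per_chrom = 6,
                                             spacing_cm = 10), seed = 88)
  base <- scan_genome(sim$cohort, sim$map)
  ## swap allele codes 1 <-> 2 everywhere
  swapped <- lapply(sim$cohort, function(ped) {
    g <- ped$genotypes
    g[g == 1L] <- 99L; g[g == 2L] <- 1L; g[g == 99L] <- 2L
    ped$genotypes <- g
    ped
  })
  sw <- scan_genome(swapped, sim$map)
  expect_equal(sw$lod, base$lod, tolerance = 1e-9)
  ## reverse the family order
  rev_curve <- scan_genome(rev(sim$cohort), sim$map)
  expect_equal(rev_curve$lod, base$lod, tolerance = 1e-9)
})

test_that("zero-likelihood genotypes name the offending family", {
  fix <- scripted_cohort(list(c("g1", "g1")))
  ped <- fix$cohort$F001
  ## parents 1/1 x 1/1 with a 2/2 child: impossible at marker 1
  ped$genotypes[1:2, ] <- 1L
  ped$genotypes[3, 1:2] <- 2L
  ped$genotypes[4, ] <- 1L
  freqs <- uniform_freqs(2)
  expect_error(lander_green_ibd(ped, toy_map(c(0, 10)), freqs),
               "F001.*zero likelihood|zero likelihood.*F001")
})

test_that("oversized and non-nuclear families are skipped with a warning", {
  big <- rand_nuclear(5, cm = 0, freq1 = 0.5)
  expect_warning(res <- lander_green_ibd(big, toy_map(0), uniform_freqs(1),
                                         meiosis_budget = 8L),
                 "budget")
  expect_null(res)
})
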