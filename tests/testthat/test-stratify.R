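test_that("G-level assignment keeps discordant siblings, Gs removes them", {
  fix <- scripted_cohort(list(c("g1", "g2"),          # F001: in G1 and G2
                              c("g3", "g3"),          # F002: G3 only
                              c("g1", "g1", "g2")))   # F003: G1 and G2
  g1 <- assign_G_level(fix$cohort, fix$subtypes, 1)
  g2 <- assign_G_level(fix$cohort, fix$subtypes, 2)
  g3 <- assign_G_level(fix$cohort, fix$subtypes, 3)
  expect_setequal(g1$family_ids, c("F001", "F003"))
  expect_setequal(g2$family_ids, c("F001", "F003"))
  expect_equal(g3$family_ids, "F002")
  ## all affected siblings retained at G level, regardless of subtype
  expect_equal(g1$retained$F003, c("K01", "K02", "K03"))

  g1s <- assign_Gs_level(g1, fix$cohort, fix$subtypes)
  ## F001 has one concordant g1 affected -> no longer multiplex -> dropped
  expect_equal(g1s$family_ids, "F003")
  expect_equal(g1s$retained$F003, c("K01", "K02"))
  g3s <- assign_Gs_level(g3, fix$cohort, fix$subtypes)
  expect_equal(g3s$family_ids, "F002")
})

test_that("gender split partitions Gs by retained affecteds' sex", {
  fix <- scripted_cohort(list(c("g1", "g1"), c("g1", "g1"), c("g1", "g1")),
                         sexes = list(c("male", "male"),
                                      c("male", "female"),
                                      c("male", "unknown")))
  g1s <- assign_Gs_level(assign_G_level(fix$cohort, fix$subtypes, 1),
                         fix$cohort, fix$subtypes)
  expect_warning(gd <- split_gender(g1s, fix$cohort), "unknown sex")
  expect_equal(gd$GM$family_ids, "F001")
  expect_equal(gd$GFc$family_ids, "F002")
  expect_setequal(c(gd$GM$family_ids, gd$GFc$family_ids, "F003"),
                  g1s$family_ids)
})

test_that("subgroup merging is a strict set union and commutes", {
  set.seed(4)
  ## fixture with the Table-3 subgroup sizes: 15 + 8 disjoint -> 23
  sets <- c(replicate(15, c("g1", "g1"), simplify = FALSE),
            replicate(8, c("g2", "g2"), simplify = FALSE))
  sexes <- replicate(23, c("male", "female"), simplify = FALSE)
  fix <- scripted_cohort(sets, sexes = sexes)
  cat16 <- stratify_catalogue(fix$cohort, fix$subtypes, stage = "n1")
  expect_equal(length(cat16$G1Fc$family_ids), 15L)
  expect_equal(length(cat16$G2Fc$family_ids), 8L)
  merged <- merge_subgroups(cat16$G1Fc, cat16$G2Fc)
  expect_equal(merged$label, "G1Fc&G2Fc")
  expect_equal(length(merged$family_ids), 23L)
  ## commutativity and idempotence
  ba <- merge_subgroups(cat16$G2Fc, cat16$G1Fc)
  expect_setequal(merged$family_ids, ba$family_ids)
  expect_equal(merged$retained, ba$retained)
  self <- merge_subgroups(cat16$G1Fc, cat16$G1Fc)
  expect_equal(self$family_ids, cat16$G1Fc$family_ids)
  expect_equal(self$retained, cat16$G1Fc$retained)
  ## overlap arithmetic: |A u B| = |A| + |B| - |A n B|
  g1 <- assign_G_level(fix$cohort, fix$subtypes, 1)
  g2 <- assign_G_level(fix$cohort, fix$subtypes, 2)
  u <- merge_subgroups(g1, g2)
  ov <- length(intersect(g1$family_ids, g2$family_ids))
  expect_equal(length(u$family_ids),
               length(g1$family_ids) + length(g2$family_ids) - ov)
})

test_that("stratification identities hold on a simulated cohort", {
  sim <- simulate_cohort(simulation_scenario(n_families = 50, n_chrom = 1,
                                             markers_per_chrom = 4,
                                             spacing_cm = 10), seed = 12)
  at_n2 <- stratify_catalogue(sim$cohort, sim$subtypes, stage = "n2",
                              include_all = TRUE)
  for (k in 1:4) {
    g <- at_n2[[paste0("G", k)]]
    gs <- at_n2[[paste0("G", k, "s")]]
    gm <- at_n2[[paste0("G", k, "M")]]
    gfc <- at_n2[[paste0("G", k, "Fc")]]
    expect_true(all(gs$family_ids %in% g$family_ids))
    expect_true(all(g$family_ids %in% at_n2$ALL$family_ids))
    ## GM and GFc partition Gs
    expect_setequal(c(gm$family_ids, gfc$family_ids), gs$family_ids)
    expect_length(intersect(gm$family_ids, gfc$family_ids), 0L)
    ## Gs retains subsets of the G-level retained affecteds
    for (fam in gs$family_ids)
      expect_true(all(gs$retained[[fam]] %in% g$retained[[fam]]))
  }
  ## discordant families appear in several G subgroups, so subgroup family
  ## counts sum to at least the undivided multiplex cohort size
  n_g <- sum(vapply(1:4, function(k)
    length(at_n2[[paste0("G", k)]]$family_ids), integer(1)))
  expect_gte(n_g, length(at_n2$ALL$family_ids))
})

test_that("n1 subgroups expand monotonically into n2", {
  sim <- simulate_cohort(simulation_scenario(n_families = 60, n_chrom = 1,
                                             markers_per_chrom = 4,
                                             spacing_cm = 10,
                                             broad_fraction = 0.3), seed = 19)
  cat_n1 <- stratify_catalogue(sim$cohort, sim$subtypes, stage = "n1",
                               include_all = TRUE)
  for (s1 in cat_n1) {
    s2 <- expand_cohort(s1, sim$cohort, sim$subtypes)
    expect_equal(s2$stage, "n2")
    expect_true(all(s1$family_ids %in% s2$family_ids))
    expect_gte(length(s2$family_ids), length(s1$family_ids))
  }
  ## no broad-spectrum subjects -> n2 identical to n1
  sim0 <- simulate_cohort(simulation_scenario(n_families = 20, n_chrom = 1,
                                              markers_per_chrom = 4,
                                              spacing_cm = 10,
                                              broad_fraction = 0), seed = 19)
  g1_n1 <- assign_G_level(sim0$cohort, sim0$subtypes, 1, stage = "n1")
  g1_n2 <- expand_cohort(g1_n1, sim0$cohort, sim0$subtypes)
  expect_equal(g1_n1$family_ids, g1_n2$family_ids)
  expect_equal(g1_n1$retained, g1_n2$retained)
})

test_that("full concordance makes Gs counts equal G counts", {
  sim <- simulate_cohort(simulation_scenario(n_families = 40, n_chrom = 1,
                                             markers_per_chrom = 4,
                                             spacing_cm = 10,
                                             concordance = 1), seed = 8)
  cat2 <- stratify_catalogue(sim$cohort, sim$subtypes, stage = "n2")
  for (k in 1:4) {
    expect_equal(cat2[[paste0("G", k, "s")]]$family_ids,
                 cat2[[paste0("G", k)]]$family_ids)
  }
})
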