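## Gene-dropping simulator of multiplex nuclear-family cohorts with subtype
## labels, controllable intra-family concordance, gender effects and
## subgroup-specific linked risk loci.

#' Define a simulation scenario
#'
#' Defaults emulate an AGRE-style multiplex cohort: 392 nuclear families,
#' mostly two affected siblings, a roughly 4:1 male:female ratio among
#' affecteds, four sub-phenotype labels with moderate intra-family
#' concordance, and a SNP panel of 200 markers per chromosome at 1 cM
#' spacing with founder minor allele frequencies uniform on (0.1, 0.5).
#'
#' @param n_families Number of nuclear families.
#' @param n_chrom Number of autosomes simulated.
#' @param markers_per_chrom Markers per chromosome.
#' @param spacing_cm Inter-marker spacing in cM.
#' @param maf_range Range of founder minor allele frequencies.
#' @param sibship_probs Named probabilities of sibship sizes.
#' @param n_affected_probs Named probabilities of affected counts per family
#'   (capped at the sibship size, floor 2: families are ascertained
#'   multiplex).
#' @param subtype_probs Probability simplex over subtypes g1-g4 for the
#'   proband.
#' @param concordance Probability that each further affected sibling shares
#'   the proband's subtype (otherwise drawn from the renormalized others).
#' @param linked_loci List of risk loci, each
#'   `list(chrom, cm, subtype, lambda_s)`: at that position, affected
#'   siblings of families concordant for `subtype` share alleles in excess,
#'   following the no-dominance affected-sib-pair IBD triple
#'   `z = (0.25/lambda_s, 0.5, 0.5 - 0.25/lambda_s)`.
#' @param broad_fraction Probability an affected is `dx_class = "broad"`.
#' @param female_affected_prob Probability an affected sibling is female.
#' @param missing_rate,mendel_error_rate Noise rates applied by
#'   [inject_noise] when nonzero.
#' @param keep_inheritance Store the latent meiosis bit chains in the truth
#'   record (memory-heavy; used by tests).
#' @return A validated `sim_scenario` list.
#' @export
simulation_scenario <- function(n_families = 392L, n_chrom = 22L,
                                markers_per_chrom = 200L, spacing_cm = 1,
                                maf_range = c(0.1, 0.5),
                                sibship_probs = c("2" = 0.65, "3" = 0.25, "4" = 0.10),
                                n_affected_probs = c("2" = 0.85, "3" = 0.15),
                                subtype_probs = c(g1 = 0.25, g2 = 0.25,
                                                  g3 = 0.25, g4 = 0.25),
                                concordance = 0.3,
                                linked_loci = list(),
                                broad_fraction = 0.15,
                                female_affected_prob = 0.2,
                                missing_rate = 0, mendel_error_rate = 0,
                                keep_inheritance = FALSE) {
  sc <- list(n_families = as.integer(n_families), n_chrom = as.integer(n_chrom),
             markers_per_chrom = as.integer(markers_per_chrom),
             spacing_cm = spacing_cm, maf_range = maf_range,
             sibship_probs = sibship_probs, n_affected_probs = n_affected_probs,
             subtype_probs = subtype_probs, concordance = concordance,
             linked_loci = linked_loci, broad_fraction = broad_fraction,
             female_affected_prob = female_affected_prob,
             missing_rate = missing_rate, mendel_error_rate = mendel_error_rate,
             keep_inheritance = isTRUE(keep_inheritance))
  probs <- c(sc$concordance, sc$broad_fraction, sc$female_affected_prob,
             sc$missing_rate, sc$mendel_error_rate, sc$subtype_probs,
             sc$sibship_probs, sc$n_affected_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(sc$subtype_probs) - 1) > 1e-9) stop("subtype_probs must sum to 1")
  for (lc in sc$linked_loci) {
    if (lc$lambda_s < 1) stop("lambda_s must be >= 1")
    z <- asp_sharing_triple(lc$lambda_s)
    if (any(z < -1e-12) || abs(sum(z) - 1) > 1e-9)
      stop("lambda_s yields an invalid IBD sharing triple")
    if (!lc$subtype %in% c("g1", "g2", "g3", "g4"))
      stop("linked locus subtype must be g1-g4")
  }
  structure(sc, class = "sim_scenario")
}

#' No-dominance affected-sib-pair IBD sharing triple for a locus of effect
#' lambda_s: z = (0.25/lambda_s, 0.5, 0.5 - 0.25/lambda_s).
#' @param lambda_s Sibling relative risk attributable to the locus.
#' @return Numeric vector `c(z0, z1, z2)`.
#' @export
asp_sharing_triple <- function(lambda_s) {
  c(0.25 / lambda_s, 0.5, 0.5 - 0.25 / lambda_s)
}

#' Simulate a multiplex-family cohort
#'
#' Founder haplotypes are drawn from the marker allele frequencies;
#' offspring genotypes by gene-dropping with Haldane recombination along
#' each chromosome. Sub-phenotype labels, diagnosis classes, sexes and
#' affection are assigned per scenario. At each risk locus, in families
#' whose affecteds are all concordant for the locus subtype, every affected
#' sibling after the first shares the first affected's paternal meiosis bit
#' with probability `1 - 0.5/lambda_s` (maternal bit neutral), which
#' realizes the no-dominance sharing triple for each pair with the first
#' affected; meiosis chains are then extended outward from the locus.
#'
#' @param scenario A `sim_scenario` from [simulation_scenario].
#' @param seed Integer RNG seed; fixed seed gives byte-identical outputs.
#' @return List with `cohort` (named list of [pedigree]), `map`
#'   (`marker_map`), `subtypes` (assignment table) and `truth` (latent
#'   record: per-family labels, affecteds, risk-locus target flags, and the
#'   meiosis chains when `keep_inheritance`).
#' @export
simulate_cohort <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(as.integer(seed))
  sc <- scenario
  ## marker map
  map <- do.call(rbind, lapply(seq_len(sc$n_chrom), function(ch) {
    data.frame(marker_id = sprintf("mk%d_%03d", ch, seq_len(sc$markers_per_chrom)),
               chrom = ch,
               cm = (seq_len(sc$markers_per_chrom) - 1L) * sc$spacing_cm,
               bp = as.integer((seq_len(sc$markers_per_chrom) - 1L) * 1e6 + 1e6),
               band = NA_character_, stringsAsFactors = FALSE)
  }))
  class(map) <- c("marker_map", "data.frame")
  m_total <- nrow(map)
  maf <- stats::runif(m_total, sc$maf_range[1L], sc$maf_range[2L])
  freq1 <- ifelse(stats::runif(m_total) < 0.5, maf, 1 - maf)
  ## "copy the first affected's paternal bit with prob q, else redraw" gives
  ## a pairwise share probability (1+q)/2; q = 1 - 1/lambda_s makes that
  ## 1 - 0.5/lambda_s, the paternal share of the no-dominance ASP triple
  loci <- lapply(sc$linked_loci, function(lc) {
    lc$p_copy <- 1 - 1 / lc$lambda_s
    lc
  })
  cohort <- list()
  sub_rows <- list()
  truth_fam <- list()
  inh_store <- if (sc$keep_inheritance) list() else NULL
  for (f in seq_len(sc$n_families)) {
    fam <- sprintf("F%04d", f)
    s <- as.integer(sample(names(sc$sibship_probs), 1L, prob = sc$sibship_probs))
    n_aff <- min(s, as.integer(sample(names(sc$n_affected_probs), 1L,
                                      prob = sc$n_affected_probs)))
    aff <- c(rep(TRUE, n_aff), rep(FALSE, s - n_aff))
    sex <- ifelse(aff, ifelse(stats::runif(s) < sc$female_affected_prob, "female", "male"),
                  ifelse(stats::runif(s) < 0.5, "female", "male"))
    proband_sub <- sample(names(sc$subtype_probs), 1L, prob = sc$subtype_probs)
    subs <- rep(NA_character_, s)
    subs[1L] <- proband_sub
    if (n_aff > 1L) for (j in 2:n_aff) {
      subs[j] <- if (stats::runif(1) < sc$concordance) proband_sub else {
        others <- setdiff(names(sc$subtype_probs), proband_sub)
        sample(others, 1L, prob = sc$subtype_probs[others])
      }
    }
    dx <- ifelse(aff, ifelse(stats::runif(s) < sc$broad_fraction, "broad", "strict"),
                 NA_character_)
    concordant_set <- unique(subs[aff])
    kid_ids <- sprintf("K%02d", seq_len(s))
    ## genotypes chromosome by chromosome
    geno <- matrix(0L, nrow = 2L + s, ncol = 2L * m_total)
    inh_fam <- if (sc$keep_inheritance) list() else NULL
    for (ch in seq_len(sc$n_chrom)) {
      mk <- which(map$chrom == ch)
      Tn <- length(mk)
      p1 <- rep(freq1[mk], each = 2L)
      fh <- matrix(as.integer(stats::runif(2L * Tn) < p1), nrow = 2L)
      mh <- matrix(as.integer(stats::runif(2L * Tn) < p1), nrow = 2L)
      fh <- 2L - fh; mh <- 2L - mh  # allele 1 with prob freq1
      lc <- Filter(function(l) l$chrom == ch &&
                     length(concordant_set) == 1L && l$subtype == concordant_set &&
                     n_aff >= 2L, loci)
      lc <- if (length(lc)) lc[[1L]] else NULL
      bits <- sim_meioses(s, map$cm[mk], lc, aff, sc)
      ## bits: list(pat, mat), each s x Tn 0/1 matrices
      cols <- as.vector(rbind(2L * mk - 1L, 2L * mk))
      geno[1L, cols] <- as.vector(rbind(fh[1L, ], fh[2L, ]))
      geno[2L, cols] <- as.vector(rbind(mh[1L, ], mh[2L, ]))
      for (j in seq_len(s)) {
        pat <- fh[cbind(bits$pat[j, ] + 1L, seq_len(Tn))]
        mat <- mh[cbind(bits$mat[j, ] + 1L, seq_len(Tn))]
        geno[2L + j, cols] <- as.vector(rbind(pat, mat))
      }
      if (sc$keep_inheritance) inh_fam[[as.character(ch)]] <- bits
    }
    mem <- data.frame(indiv_id = c("P1", "P2", kid_ids),
                      father_id = c(NA, NA, rep("P1", s)),
                      mother_id = c(NA, NA, rep("P2", s)),
                      sex = c("male", "female", sex),
                      affection = c("unknown", "unknown",
                                    ifelse(aff, "affected", "unaffected")),
                      stringsAsFactors = FALSE)
    cohort[[fam]] <- pedigree(fam, mem, geno)
    sub_rows[[fam]] <- data.frame(family_id = fam, indiv_id = kid_ids[aff],
                                  subtype = subs[aff], dx_class = dx[aff],
                                  stringsAsFactors = FALSE)
    truth_fam[[fam]] <- list(affected = kid_ids[aff], subtypes = subs[aff],
                             dx = dx[aff], sexes = sex,
                             concordant = length(concordant_set) == 1L,
                             concordant_subtype = if (length(concordant_set) == 1L)
                               concordant_set else NA_character_)
    if (sc$keep_inheritance) inh_store[[fam]] <- inh_fam
  }
  subtypes <- do.call(rbind, sub_rows)
  rownames(subtypes) <- NULL
  truth <- list(scenario = sc, seed = as.integer(seed), freq1 = freq1,
                families = truth_fam,
                target_families = lapply(sc$linked_loci, function(lc)
                  names(Filter(function(tf) tf$concordant &&
                                 identical(tf$concordant_subtype, lc$subtype),
                               truth_fam))),
                inheritance = inh_store, noise = NULL)
  sim <- list(cohort = cohort, map = map, subtypes = subtypes, truth = truth)
  if (sc$missing_rate > 0 || sc$mendel_error_rate > 0)
    sim <- inject_noise(sim, sc$missing_rate, sc$mendel_error_rate,
                        seed = as.integer(seed) + 1L)
  sim
}

## simulate paternal/maternal meiosis bit chains for s siblings along one
## chromosome; `locus` (if non-NULL) imposes excess sharing among affecteds
sim_meioses <- function(s, cm, locus, aff, sc) {
  Tn <- length(cm)
  pat <- matrix(0L, s, Tn); mat <- matrix(0L, s, Tn)
  if (is.null(locus)) {
    for (j in seq_len(s)) {
      pat[j, ] <- walk_bits(stats::rbinom(1L, 1L, 0.5), cm, anchor = 1L)
      mat[j, ] <- walk_bits(stats::rbinom(1L, 1L, 0.5), cm, anchor = 1L)
    }
    return(list(pat = pat, mat = mat))
  }
  aidx <- which(aff)
  anchor <- findInterval(locus$cm, cm)
  anchor <- max(1L, anchor)
  ## distance from locus to anchor marker folded into the first step
  b1_pat <- stats::rbinom(1L, 1L, 0.5)
  b1_mat <- stats::rbinom(1L, 1L, 0.5)
  for (j in seq_len(s)) {
    if (j %in% aidx && j != aidx[1L]) {
      bp <- if (stats::runif(1) < locus$p_copy) b1_pat else stats::rbinom(1L, 1L, 0.5)
      bm <- stats::rbinom(1L, 1L, 0.5)
    } else if (j == aidx[1L]) {
      bp <- b1_pat; bm <- b1_mat
    } else {
      bp <- stats::rbinom(1L, 1L, 0.5); bm <- stats::rbinom(1L, 1L, 0.5)
    }
    ## propagate from the locus position to the anchor marker, then outward
    d_anchor <- abs(cm[anchor] - locus$cm)
    bp_a <- flip_bit(bp, d_anchor); bm_a <- flip_bit(bm, d_anchor)
    pat[j, ] <- walk_bits(bp_a, cm, anchor = anchor)
    mat[j, ] <- walk_bits(bm_a, cm, anchor = anchor)
  }
  list(pat = pat, mat = mat)
}

flip_bit <- function(b, d) {
  if (d <= 0) return(b)
  if (stats::runif(1) < haldane_theta(d)) 1L - b else b
}

## Markov bit chain over marker positions, anchored at index `anchor`
walk_bits <- function(b0, cm, anchor) {
  Tn <- length(cm)
  out <- integer(Tn)
  out[anchor] <- b0
  if (anchor < Tn) for (t in (anchor + 1L):Tn)
    out[t] <- flip_bit(out[t - 1L], cm[t] - cm[t - 1L])
  if (anchor > 1L) for (t in (anchor - 1L):1L)
    out[t] <- flip_bit(out[t + 1L], cm[t + 1L] - cm[t])
  out
}

#' Inject genotype noise into a simulated cohort
#'
#' Masks genotypes (both alleles set to 0) at `missing_rate` and flips one
#' allele of a genotype to the other code at `mendel_error_rate`,
#' per individual-marker call; injected positions are recorded in
#' `truth$noise`.
#'
#' @param sim Result of [simulate_cohort].
#' @param missing_rate,mendel_error_rate Per-call rates in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return The modified simulation list.
#' @export
inject_noise <- function(sim, missing_rate, mendel_error_rate, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            mendel_error_rate >= 0, mendel_error_rate <= 1)
  set.seed(as.integer(seed))
  m <- nrow(sim$map)
  noise <- list(missing = list(), errors = list())
  for (fam in names(sim$cohort)) {
    ped <- sim$cohort[[fam]]
    n <- nrow(ped$members)
    if (mendel_error_rate > 0) {
      hit <- which(matrix(stats::runif(n * m) < mendel_error_rate, n, m), arr.ind = TRUE)
      for (r in seq_len(nrow(hit))) {
        i <- hit[r, 1L]; t <- hit[r, 2L]
        col <- 2L * t - 1L + stats::rbinom(1L, 1L, 0.5)
        old <- ped$genotypes[i, col]
        if (old == 0L) next
        ped$genotypes[i, col] <- if (old == 1L) 2L else 1L
      }
      if (nrow(hit)) noise$errors[[fam]] <-
        data.frame(indiv_id = ped$members$indiv_id[hit[, 1L]], marker = hit[, 2L])
    }
    if (missing_rate > 0) {
      hit <- which(matrix(stats::runif(n * m) < missing_rate, n, m), arr.ind = TRUE)
      for (r in seq_len(nrow(hit))) {
        i <- hit[r, 1L]; t <- hit[r, 2L]
        ped$genotypes[i, c(2L * t - 1L, 2L * t)] <- 0L
      }
      if (nrow(hit)) noise$missing[[fam]] <-
        data.frame(indiv_id = ped$members$indiv_id[hit[, 1L]], marker = hit[, 2L])
    }
    sim$cohort[[fam]] <- ped
  }
  sim$truth$noise <- noise
  sim
}

#' Write a simulated cohort as PED/MAP/subtype files
#' @param sim Result of [simulate_cohort].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(sim, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".ped", ".map", ".subtypes.tsv")))
  write_ped(sim$cohort, paths[1L])
  write_map(sim$map, paths[2L])
  write_subtypes(sim$subtypes, paths[3L])
  invisible(paths)
}
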