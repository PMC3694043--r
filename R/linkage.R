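## Multipoint nonparametric allele-sharing linkage: inheritance-vector HMM
## over nuclear families, S_pairs scoring, Kong-Cox one-parameter LOD and the
## LOD -> pointwise-p conversion.

#' Haldane map function
#'
#' Converts a genetic distance in centimorgans to a recombination fraction
#' under Haldane's no-interference model, theta = (1 - exp(-2d/100)) / 2.
#'
#' @param d Distance in cM (non-negative).
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane_theta <- function(d) {
  if (any(d < 0)) stop("negative genetic distance")
  0.5 * (1 - exp(-2 * d / 100))
}

#' Estimate founder allele frequencies per marker
#'
#' Frequencies are estimated from founder chromosomes of the supplied cohort
#' (offspring would count transmitted alleles twice). Markers where no founder
#' is typed fall back to a uniform distribution over the alleles observed in
#' the whole cohort.
#'
#' @param cohort Named list of [pedigree] objects.
#' @param marker_map A `marker_map` (used only for the marker count/names).
#' @return List, one named numeric simplex per marker (names = allele codes).
#' @export
estimate_allele_freqs <- function(cohort, marker_map) {
  m <- nrow(marker_map)
  out <- vector("list", m)
  for (t in seq_len(m)) {
    al <- founder_alleles(cohort, t)
    if (!length(al)) {
      all_al <- unlist(lapply(cohort, function(p) marker_geno(p, t)), use.names = FALSE)
      al <- all_al[all_al != 0L]
      if (!length(al)) al <- c(1L, 2L)
    }
    tab <- table(al)
    out[[t]] <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  }
  names(out) <- marker_map$marker_id
  out
}

## ---- nuclear-family layout -------------------------------------------------

## Identify the founder couple and the sibship; NULL with a warning when the
## family is not a (within-budget) two-founder nuclear family.
nuclear_layout <- function(ped, meiosis_budget = 16L) {
  mem <- ped$members
  fo <- ped_founders(ped)
  kids <- ped_offspring(ped)
  if (length(fo) != 2L || !length(kids)) {
    warning(sprintf("family %s: not a two-founder nuclear family, skipped", ped$family_id))
    return(NULL)
  }
  fa <- fo[mem$sex[match(fo, mem$indiv_id)] == "male"]
  mo <- fo[mem$sex[match(fo, mem$indiv_id)] == "female"]
  kid_rows <- match(kids, mem$indiv_id)
  if (length(fa) != 1L || length(mo) != 1L ||
      !all(mem$father_id[kid_rows] == fa & mem$mother_id[kid_rows] == mo)) {
    warning(sprintf("family %s: offspring do not share the founder couple, skipped",
                    ped$family_id))
    return(NULL)
  }
  m <- 2L * length(kids)
  if (m > meiosis_budget) {
    warning(sprintf("family %s: %d meioses exceed budget %d, skipped",
                    ped$family_id, m, meiosis_budget))
    return(NULL)
  }
  nstates <- 2L^m
  states <- 0:(nstates - 1L)
  ## child j: paternal bit 2j-1, maternal bit 2j (0 = founder's first allele)
  bit <- function(k) bitwAnd(states, bitwShiftL(1L, k - 1L)) > 0L
  idx4 <- lapply(seq_along(kids), function(j)
    1L + 2L * bit(2L * j - 1L) + bit(2L * j))
  flips <- lapply(seq_len(m), function(k)
    bitwXor(states, bitwShiftL(1L, k - 1L)) + 1L)
  patbit <- lapply(seq_along(kids), function(j) bit(2L * j - 1L))
  matbit <- lapply(seq_along(kids), function(j) bit(2L * j))
  list(father = fa, mother = mo, children = kids, m = m, nstates = nstates,
       idx4 = idx4, flips = flips, patbit = patbit, matbit = matbit)
}

## ordered founder allele pairs consistent with an observed genotype,
## weighted by population frequency
founder_pair_table <- function(g, freq) {
  codes <- as.integer(names(freq))
  if (g[1L] != 0L) {
    prs <- matrix(c(g[1L], g[2L]), 1L)
    if (g[1L] != g[2L]) prs <- rbind(prs, c(g[2L], g[1L]))
  } else {
    prs <- as.matrix(expand.grid(a1 = codes, a2 = codes, KEEP.OUT.ATTRS = FALSE))
  }
  w <- freq[as.character(prs[, 1L])] * freq[as.character(prs[, 2L])]
  ok <- !is.na(w) & w > 0
  list(pairs = prs[ok, , drop = FALSE], w = unname(w[ok]))
}

## emission vector over inheritance states at one marker: founder-allele
## peeling by summation over weighted ordered founder genotypes
emission_states <- function(lay, gf, gm, kidg, freq) {
  fp <- founder_pair_table(gf, freq)
  mp <- founder_pair_table(gm, freq)
  e <- numeric(lay$nstates)
  if (!nrow(fp$pairs) || !nrow(mp$pairs)) return(e)
  nk <- length(lay$children)
  for (i in seq_len(nrow(fp$pairs))) {
    for (j in seq_len(nrow(mp$pairs))) {
      w <- fp$w[i] * mp$w[j]
      contrib <- rep(w, lay$nstates)
      for (k in seq_len(nk)) {
        c1 <- kidg[k, 1L]; c2 <- kidg[k, 2L]
        if (c1 == 0L) next  # untyped child: summed over
        ## value for (paternal bit, maternal bit) in {00,01,10,11}
        val4 <- numeric(4L)
        for (bpm in 0:3) {
          a <- fp$pairs[i, (bpm %/% 2L) + 1L]
          b <- mp$pairs[j, (bpm %% 2L) + 1L]
          val4[bpm + 1L] <- as.numeric((c1 == a && c2 == b) || (c1 == b && c2 == a))
        }
        contrib <- contrib * val4[lay$idx4[[k]]]
      }
      e <- e + contrib
    }
  }
  e
}

## spread an inheritance-state distribution across a distance of d cM:
## each meiosis bit flips independently with probability haldane_theta(d)
spread_dist <- function(p, d, flips) {
  th <- haldane_theta(d)
  if (th == 0) return(p)
  for (f in flips) p <- (1 - th) * p + th * p[f]
  p
}

#' Multipoint inheritance-vector distribution for one family
#'
#' Runs the Lander-Green forward-backward algorithm over the markers of each
#' chromosome: hidden state = inheritance vector (one bit per meiosis of the
#' sibship), emission = probability of the observed genotypes given the
#' vector with founder-allele peeling, transitions flip each bit
#' independently with the Haldane recombination fraction of the inter-marker
#' distance. The returned distribution at every evaluation position is
#' conditional on all markers of the chromosome (multipoint). Missing
#' genotypes are summed over, not imputed.
#'
#' @param ped A [pedigree] (two-founder nuclear family).
#' @param marker_map `marker_map` for the markers in `ped` (any number of
#'   chromosomes).
#' @param allele_freqs Per-marker allele frequency list, as from
#'   [estimate_allele_freqs].
#' @param positions Optional data frame (`chrom`, `cm`) of evaluation
#'   positions; defaults to the marker positions.
#' @param meiosis_budget Maximum meioses (bits) for the exact HMM; larger
#'   families are skipped with a warning (returns `NULL`).
#' @return An `inheritance_dist`: list with `family_id`, `children`,
#'   `positions` (data frame `chrom`, `cm`, `marker_id` of nearest marker),
#'   `posterior` (positions x 2^m matrix, rows summing to 1), and the
#'   sibship layout.
#' @export
lander_green_ibd <- function(ped, marker_map, allele_freqs, positions = NULL,
                             meiosis_budget = 16L) {
  lay <- nuclear_layout(ped, meiosis_budget)
  if (is.null(lay)) return(NULL)
  if (is.null(positions))
    positions <- data.frame(chrom = marker_map$chrom, cm = marker_map$cm)
  positions <- positions[order(positions$chrom, positions$cm, method = "radix"), ,
                         drop = FALSE]
  mem_idx <- match(c(lay$father, lay$mother, lay$children), ped$members$indiv_id)
  post <- matrix(NA_real_, nrow(positions), lay$nstates)
  nearest <- character(nrow(positions))
  for (ch in unique(positions$chrom)) {
    mk <- which(marker_map$chrom == ch)
    px <- which(positions$chrom == ch)
    if (!length(mk))
      stop(sprintf("no markers on chromosome %s for requested positions", ch))
    res <- lg_chromosome(ped, lay, mem_idx, mk, marker_map$cm[mk],
                         allele_freqs[mk], positions$cm[px])
    post[px, ] <- res
    nearest[px] <- marker_map$marker_id[mk][
      vapply(positions$cm[px], function(x) which.min(abs(marker_map$cm[mk] - x)),
             integer(1L))]
  }
  positions$marker_id <- nearest
  rownames(positions) <- NULL
  structure(list(family_id = ped$family_id, children = lay$children,
                 positions = positions, posterior = post, layout = lay),
            class = "inheritance_dist")
}

## forward-backward on one chromosome; returns posterior at `at_cm` positions
lg_chromosome <- function(ped, lay, mem_idx, mk, cm, freqs, at_cm) {
  g <- ped$genotypes
  Tn <- length(mk)
  ns <- lay$nstates
  E <- matrix(0, ns, Tn)
  for (t in seq_len(Tn)) {
    cols <- c(2L * mk[t] - 1L, 2L * mk[t])
    gg <- g[mem_idx, cols, drop = FALSE]
    E[, t] <- emission_states(lay, gg[1L, ], gg[2L, ],
                              gg[-(1:2), , drop = FALSE], freqs[[t]])
  }
  A <- matrix(0, ns, Tn)   # scaled forward, includes emission at t
  B <- matrix(0, ns, Tn)   # scaled backward (emissions t+1..Tn only)
  a <- E[, 1L] / ns
  s <- sum(a)
  if (s <= 0) stop(sprintf("family %s: zero likelihood at marker index %d (unfixed Mendelian error?)",
                           ped$family_id, mk[1L]))
  A[, 1L] <- a / s
  if (Tn > 1L) for (t in 2:Tn) {
    a <- spread_dist(A[, t - 1L], cm[t] - cm[t - 1L], lay$flips) * E[, t]
    s <- sum(a)
    if (s <= 0) stop(sprintf("family %s: zero likelihood at marker index %d (unfixed Mendelian error?)",
                             ped$family_id, mk[t]))
    A[, t] <- a / s
  }
  B[, Tn] <- 1 / ns
  if (Tn > 1L) for (t in (Tn - 1L):1L) {
    b <- spread_dist(B[, t + 1L] * E[, t + 1L], cm[t + 1L] - cm[t], lay$flips)
    B[, t] <- b / sum(b)
  }
  BE <- B * E  # backward including own emission, for off-marker evaluation
  out <- matrix(0, length(at_cm), ns)
  for (i in seq_along(at_cm)) {
    x <- at_cm[i]
    j <- findInterval(x, cm)
    p <- if (j >= 1L && j <= Tn && x == cm[j]) {
      A[, j] * B[, j]
    } else if (j == 0L) {
      spread_dist(BE[, 1L], cm[1L] - x, lay$flips)
    } else if (j == Tn) {
      spread_dist(A[, Tn], x - cm[Tn], lay$flips)
    } else {
      spread_dist(A[, j], x - cm[j], lay$flips) *
        spread_dist(BE[, j + 1L], cm[j + 1L] - x, lay$flips)
    }
    p[!is.finite(p)] <- 0
    out[i, ] <- p / sum(p)
  }
  out
}

## ---- S_pairs scoring -------------------------------------------------------

## S_pairs over a subset of children as a function of the inheritance state
spairs_state_vector <- function(lay, subset_idx) {
  S <- numeric(lay$nstates)
  n <- length(subset_idx)
  if (n < 2L) return(S)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- subset_idx[i]; b <- subset_idx[j]
    S <- S + (lay$patbit[[a]] == lay$patbit[[b]]) + (lay$matbit[[a]] == lay$matbit[[b]])
  }
  S
}

#' Per-family nonparametric linkage score (S_pairs)
#'
#' S_pairs sums, over all pairs of retained affected siblings, the expected
#' number of alleles shared identical-by-descent under the multipoint
#' inheritance distribution. The null mean and standard deviation are taken
#' over the uniform inheritance-vector distribution, giving the standardized
#' per-family score Z = (S - mu0) / sd0.
#'
#' @param ped The [pedigree] scored.
#' @param inheritance_dist Result of [lander_green_ibd] for `ped`.
#' @param retained_affecteds Ids of the affected individuals to score
#'   (must be >= 2 offspring of the family).
#' @return A `family_npl` data frame: per position `score`, `mu0`, `sd0`,
#'   `Z`; the minimum attainable standardized score is in `attr(, "z_min")`.
#'   Families with `sd0 = 0` (fewer than two scoreable affecteds) return
#'   `NULL` with a warning (uninformative).
#' @export
npl_pairs <- function(ped, inheritance_dist, retained_affecteds) {
  lay <- inheritance_dist$layout
  idx <- match(retained_affecteds, lay$children)
  idx <- idx[!is.na(idx)]
  if (length(idx) < 2L) {
    warning(sprintf("family %s: fewer than two scoreable affected siblings, uninformative",
                    ped$family_id))
    return(NULL)
  }
  S <- spairs_state_vector(lay, idx)
  mu <- mean(S)
  sig <- sqrt(mean(S^2) - mu^2)
  if (sig <= 0) {
    warning(sprintf("family %s: degenerate null sharing distribution", ped$family_id))
    return(NULL)
  }
  score <- as.numeric(inheritance_dist$posterior %*% S)
  out <- data.frame(inheritance_dist$positions,
                    score = score, mu0 = mu, sd0 = sig,
                    Z = (score - mu) / sig)
  attr(out, "z_min") <- (min(S) - mu) / sig
  class(out) <- c("family_npl", "data.frame")
  out
}

## ---- Kong-Cox combination --------------------------------------------------

## vectorized constrained Newton ascent of sum_i log10(1 + delta * Z_i)
## Z: positions x families; zmin: per-family minimum attainable Z (< 0)
kc_maximize <- function(Z, zmin) {
  if (!length(zmin)) stop("no informative families")
  dmax <- (1 - 1e-9) * min(-1 / zmin)
  P <- nrow(Z)
  delta <- numeric(P)
  for (it in 1:100) {
    W <- 1 + Z * delta
    R <- Z / W
    g1 <- rowSums(R)
    g2 <- rowSums(R^2)
    step <- ifelse(g2 > 0, g1 / g2, 0)
    dn <- pmin(pmax(delta + step, 0), dmax)
    if (max(abs(dn - delta)) < 1e-12) { delta <- dn; break }
    delta <- dn
  }
  lod <- pmax(rowSums(log10(1 + Z * delta)), 0)
  list(delta = delta, lod = lod)
}

#' Kong-Cox one-parameter allele-sharing LOD at one position
#'
#' Maximizes `sum_i log10(1 + delta * Z_i)` over `delta >= 0` (one-sided, so
#' the LOD is truncated at 0). `delta` is constrained so every per-family
#' likelihood ratio `1 + delta * Z_i` stays positive: the bound is
#' `min_i(-1/Z_min,i)` from the minimum attainable family scores when
#' supplied (the linear-model constraint), otherwise from the observed
#' negative scores, otherwise `delta_max` (default 1). For a cohort of
#' affected sib pairs the attainable-score bound equals 1/sqrt(2) = 0.707.
#'
#' @param family_scores Standardized family scores Z_i at one position.
#' @param z_min Optional per-family minimum attainable standardized scores.
#' @param delta_max Optional explicit upper bound for delta.
#' @return List with `delta_hat` and `lod`.
#' @export
kong_cox_lod <- function(family_scores, z_min = NULL, delta_max = NULL) {
  z <- family_scores[!is.na(family_scores)]
  if (!length(z)) stop("no informative families")
  bound <- Inf
  if (!is.null(z_min)) {
    if (any(z_min >= 0)) stop("z_min must be negative")
    bound <- min(-1 / z_min)
  } else if (any(z < 0)) {
    bound <- min(-1 / z[z < 0])
  }
  if (!is.null(delta_max)) bound <- min(bound, delta_max / (1 - 1e-9))
  if (!is.finite(bound)) bound <- 1 / (1 - 1e-9)
  res <- kc_maximize(matrix(z, nrow = 1L), -1 / bound)
  list(delta_hat = res$delta, lod = res$lod)
}

#' Pointwise p-value of a Kong-Cox LOD score
#'
#' `p = 1 - Phi(sqrt(2 ln(10) LOD))`, the standard one-sided normal
#' conversion for the one-parameter allele-sharing LOD; a LOD of 0 maps to
#' 0.5. Strictly decreasing in LOD, with values in (0, 0.5].
#'
#' @param lod Non-negative LOD score(s).
#' @return Pointwise probability, same length as `lod`.
#' @export
lod_to_pvalue <- function(lod) {
  if (any(lod < 0)) stop("negative LOD")
  ifelse(lod == 0, 0.5,
         stats::pnorm(sqrt(2 * log(10) * lod), lower.tail = FALSE))
}

## ---- genome scan -----------------------------------------------------------

#' Genome-wide multipoint allele-sharing scan for a stratified cohort
#'
#' For every informative family (a two-founder nuclear family within the
#' meiosis budget with at least two retained affected siblings) the
#' multipoint inheritance distribution and standardized S_pairs score are
#' computed at each evaluation position, then combined across families with
#' the Kong-Cox one-parameter LOD, with the pointwise p attached.
#'
#' @param cohort Named list of [pedigree] objects.
#' @param marker_map QC-filtered `marker_map`.
#' @param strat Optional `strat_cohort` restricting families and retained
#'   affecteds; default scans all families with all their affecteds.
#' @param allele_freqs Optional per-marker frequency list; estimated from the
#'   cohort founders when `NULL`.
#' @param grid_cm Optional uniform evaluation grid spacing in cM added to the
#'   marker positions.
#' @param meiosis_budget Exact-HMM size limit (bits).
#' @param cache Optional [linkage_cache] to reuse across scans.
#' @return A `lod_curve` data frame: `label`, `chrom`, `cm`, `marker_id`,
#'   `Z` (equal-weight combined score), `delta`, `lod`, `p`; the number of
#'   informative families is in `attr(, "n_families")`.
#' @export
scan_genome <- function(cohort, marker_map, strat = NULL, allele_freqs = NULL,
                        grid_cm = NULL, meiosis_budget = 16L, cache = NULL) {
  if (is.null(cache))
    cache <- linkage_cache(cohort, marker_map, allele_freqs = allele_freqs,
                           grid_cm = grid_cm, meiosis_budget = meiosis_budget)
  if (is.null(strat)) strat <- strat_all_affected(cohort)
  scan_strat(cache, strat)
}

## default "scan everything" stratum
strat_all_affected <- function(cohort) {
  retained <- lapply(cohort, ped_affected)
  keep <- lengths(retained) >= 2L
  new_strat_cohort("ALL", names(cohort)[keep], retained[keep],
                   provenance = "all multiplex families, all affecteds",
                   level = "ALL", k = NA_integer_, stage = "n2")
}

#' Precompute per-family inheritance distributions for repeated scans
#'
#' The HMM posterior depends only on genotypes and the map, not on subtype
#' labels, so one cache serves every stratified subgroup and every
#' permutation replicate. Standardized score curves per retained-affected
#' subset are derived lazily and memoized.
#'
#' @inheritParams scan_genome
#' @return A `linkage_cache` environment.
#' @export
linkage_cache <- function(cohort, marker_map, allele_freqs = NULL,
                          grid_cm = NULL, meiosis_budget = 16L) {
  if (is.null(allele_freqs)) allele_freqs <- estimate_allele_freqs(cohort, marker_map)
  positions <- data.frame(chrom = marker_map$chrom, cm = marker_map$cm)
  if (!is.null(grid_cm)) {
    extra <- do.call(rbind, lapply(unique(marker_map$chrom), function(ch) {
      x <- marker_map$cm[marker_map$chrom == ch]
      data.frame(chrom = ch, cm = seq(min(x), max(x), by = grid_cm))
    }))
    positions <- unique(rbind(positions, extra))
  }
  positions <- positions[order(positions$chrom, positions$cm, method = "radix"), ,
                         drop = FALSE]
  rownames(positions) <- NULL
  cc <- new.env(parent = emptyenv())
  cc$cohort <- cohort
  cc$map <- marker_map
  cc$freqs <- allele_freqs
  cc$positions <- positions
  cc$budget <- meiosis_budget
  cc$ibd <- new.env(parent = emptyenv())    # family_id -> inheritance_dist | "skipped"
  cc$zcurves <- new.env(parent = emptyenv()) # family_id|subset -> list(Z, zmin)
  class(cc) <- "linkage_cache"
  cc
}

cache_ibd <- function(cache, fam) {
  got <- get0(fam, envir = cache$ibd)
  if (!is.null(got)) return(if (identical(got, "skipped")) NULL else got)
  dist <- lander_green_ibd(cache$cohort[[fam]], cache$map, cache$freqs,
                           positions = cache$positions,
                           meiosis_budget = cache$budget)
  assign(fam, if (is.null(dist)) "skipped" else dist, envir = cache$ibd)
  dist
}

cache_zcurve <- function(cache, fam, retained) {
  key <- paste0(fam, "|", paste(sort(retained), collapse = ","))
  got <- get0(key, envir = cache$zcurves)
  if (!is.null(got)) return(if (identical(got, "uninf")) NULL else got)
  dist <- cache_ibd(cache, fam)
  out <- NULL
  if (!is.null(dist)) {
    npl <- suppressWarnings(npl_pairs(cache$cohort[[fam]], dist, retained))
    if (!is.null(npl)) out <- list(Z = npl$Z, zmin = attr(npl, "z_min"))
  }
  assign(key, if (is.null(out)) "uninf" else out, envir = cache$zcurves)
  out
}

## gather the per-family standardized score matrix for one subgroup
strat_zmat <- function(cache, strat) {
  curves <- list(); zmins <- numeric(0)
  for (fam in strat$family_ids) {
    zc <- cache_zcurve(cache, fam, strat$retained[[fam]])
    if (!is.null(zc)) {
      curves[[fam]] <- zc$Z
      zmins <- c(zmins, zc$zmin)
    }
  }
  if (!length(curves)) return(NULL)
  list(Z = do.call(cbind, curves), zmins = zmins)
}

## combine cached per-family curves for one stratified subgroup
scan_strat <- function(cache, strat) {
  zm <- strat_zmat(cache, strat)
  if (is.null(zm))
    stop(sprintf("subgroup %s: no informative families", strat$label))
  Z <- zm$Z
  res <- kc_maximize(Z, zm$zmins)
  pos <- cache$positions
  nearest <- character(nrow(pos))
  for (ch in unique(pos$chrom)) {
    mk <- cache$map[cache$map$chrom == ch, ]
    px <- which(pos$chrom == ch)
    nearest[px] <- mk$marker_id[vapply(pos$cm[px],
      function(x) which.min(abs(mk$cm - x)), integer(1L))]
  }
  out <- data.frame(label = strat$label, chrom = pos$chrom, cm = pos$cm,
                    marker_id = nearest,
                    Z = rowSums(Z) / sqrt(ncol(Z)),
                    delta = res$delta, lod = res$lod,
                    p = lod_to_pvalue(res$lod),
                    stringsAsFactors = FALSE)
  attr(out, "n_families") <- ncol(Z)
  class(out) <- c("lod_curve", "data.frame")
  out
}

#' Write LOD curves as TSV
#' @param curve A `lod_curve` (or data frame of stacked curves).
#' @param path Output path.
#' @export
write_lod_curve <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
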