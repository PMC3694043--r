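## Marker-level quality control: founder MAF, missingness, exact
## Hardy-Weinberg, Mendelian-error filters.

#' Founder minor allele frequency
#'
#' Allele frequencies are computed on founder chromosomes only, to avoid the
#' inflation that related offspring would introduce; the MAF is the frequency
#' of the second most common allele (ties at 0.5 return 0.5).
#'
#' @param cohort Named list of [pedigree] objects.
#' @param marker Marker index (1-based).
#' @return Minor allele frequency in `[0, 0.5]`, or `NA` with an
#'   undefined-marker warning when every founder is untyped.
#' @export
compute_maf <- function(cohort, marker) {
  al <- founder_alleles(cohort, marker)
  if (!length(al)) {
    warning(sprintf("marker %d: all founders missing, MAF undefined", marker))
    return(NA_real_)
  }
  fr <- sort(tabulate(al) / length(al), decreasing = TRUE)
  if (length(fr) < 2L) 0 else fr[2L]
}

founder_alleles <- function(cohort, marker) {
  al <- unlist(lapply(cohort, function(ped) {
    f <- match(ped_founders(ped), ped$members$indiv_id)
    marker_geno(ped, marker)[f, ]
  }), use.names = FALSE)
  al[al != 0L]
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test for a biallelic marker: conditional on the observed
#' allele counts, the probability of every heterozygote configuration is
#' enumerated and those no more probable than the observed one are summed.
#' Intended for founder genotype counts. Monomorphic input returns 1.
#'
#' @param genotype_counts Integer vector `c(AA, Aa, aa)` (names optional).
#' @return Exact test probability.
#' @export
hwe_exact_test <- function(genotype_counts) {
  x <- as.integer(round(genotype_counts))
  if (length(x) != 3L || any(x < 0L)) stop("need counts c(AA, Aa, aa) >= 0")
  n <- sum(x)
  if (n < 1L) stop("at least one genotype required")
  nA <- 2L * x[1L] + x[2L]
  na <- 2L * x[3L] + x[2L]
  if (nA == 0L || na == 0L) return(1)
  rare <- min(nA, na)
  hets <- seq(rare %% 2L, rare, by = 2L)
  ## log P(nAa = h | allele counts) up to a shared constant
  lp <- vapply(hets, function(h) {
    hom_r <- (rare - h) %/% 2L
    hom_c <- n - h - hom_r
    h * log(2) - lfactorial(hom_c) - lfactorial(h) - lfactorial(hom_r)
  }, numeric(1L))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(x[2L], hets)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  sum(pr[pr <= obs * (1 + 1e-12)])
}

#' Apply marker-level QC filters
#'
#' Removes markers failing any of: founder MAF below `maf_min`, missingness
#' above `missing_max`, exact Hardy-Weinberg p (founders) below `hwe_alpha`,
#' or more than `mendel_max` Mendelian errors summed over families. Filters
#' are independent, so the surviving set does not depend on the order in
#' which rules are applied; the report tags every exclusion with its
#' reason(s).
#'
#' @param cohort Named list of [pedigree] objects.
#' @param marker_map A `marker_map` covering the cohort's markers.
#' @param thresholds List with `maf_min`, `missing_max`, `hwe_alpha`,
#'   `mendel_max` (defaults 0.05, 0.10, 0.001, 1).
#' @return List with `map` (surviving `marker_map`) and `report` (per-marker
#'   data frame: `maf`, `missing_rate`, `hwe_p`, `mendel_errors`,
#'   `excluded_by`).
#' @export
apply_filters <- function(cohort, marker_map,
                          thresholds = list(maf_min = 0.05, missing_max = 0.10,
                                            hwe_alpha = 0.001, mendel_max = 1)) {
  thr <- utils::modifyList(list(maf_min = 0.05, missing_max = 0.10,
                                hwe_alpha = 0.001, mendel_max = 1), thresholds)
  m <- nrow(marker_map)
  if (ncol(cohort[[1L]]$genotypes) %/% 2L != m)
    stop("marker_map does not match cohort marker count")
  n_ind <- sum(vapply(cohort, function(p) nrow(p$members), integer(1L)))
  mendel <- rowSums(mendelian_check(cohort))
  maf <- numeric(m); miss <- numeric(m); hwe <- numeric(m)
  for (t in seq_len(m)) {
    al <- founder_alleles(cohort, t)
    maf[t] <- if (length(al)) {
      fr <- sort(tabulate(al) / length(al), decreasing = TRUE)
      if (length(fr) < 2L) 0 else fr[2L]
    } else NA_real_
    miss[t] <- 1 - sum(vapply(cohort, function(p) sum(marker_geno(p, t)[, 1L] != 0L),
                              numeric(1L))) / n_ind
    hwe[t] <- hwe_founder_p(cohort, t)
  }
  fail <- cbind(MAF = !is.na(maf) & maf < thr$maf_min,
                MISSING = miss > thr$missing_max,
                HWE = !is.na(hwe) & hwe < thr$hwe_alpha,
                MENDEL = mendel > thr$mendel_max)
  fail[is.na(maf), "MAF"] <- TRUE  # undefined markers cannot be scored
  excluded_by <- apply(fail, 1L, function(r) paste(colnames(fail)[r], collapse = ","))
  report <- data.frame(marker_id = marker_map$marker_id, maf = maf,
                       missing_rate = miss, hwe_p = hwe, mendel_errors = mendel,
                       excluded_by = excluded_by, stringsAsFactors = FALSE)
  keep <- excluded_by == ""
  if (!any(keep)) stop("no markers survive QC filters")
  out_map <- marker_map[keep, , drop = FALSE]
  rownames(out_map) <- NULL
  attr(out_map, "kept_index") <- which(keep)
  list(map = out_map, report = report)
}

hwe_founder_p <- function(cohort, marker) {
  gt <- do.call(rbind, lapply(cohort, function(ped) {
    f <- match(ped_founders(ped), ped$members$indiv_id)
    marker_geno(ped, marker)[f, , drop = FALSE]
  }))
  gt <- gt[gt[, 1L] != 0L, , drop = FALSE]
  if (!nrow(gt)) return(NA_real_)
  al <- sort(unique(c(gt)))
  if (length(al) < 2L) return(1)
  ## biallelic in scope; with rare extra codes, test the two most common
  fr <- tabulate(c(gt))
  top <- order(fr, decreasing = TRUE)[1:2]
  a <- min(top); b <- max(top)
  use <- (gt[, 1L] %in% c(a, b)) & (gt[, 2L] %in% c(a, b))
  gt <- gt[use, , drop = FALSE]
  if (!nrow(gt)) return(1)
  het <- gt[, 1L] != gt[, 2L]
  hwe_exact_test(c(sum(!het & gt[, 1L] == a), sum(het), sum(!het & gt[, 1L] == b)))
}

#' Write a QC report as TSV
#' @param report Report data frame from [apply_filters].
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
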