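## Transmission disequilibrium test on trios drawn from stratified cohorts.

#' Count transmissions of a target allele to affected children
#'
#' For each family one affected child (the proband: the first retained
#' affected in canonical order, or every affected with
#' `one_per_family = FALSE`) is paired with its two parents; trios with an
#' untyped parent are dropped. Every heterozygous parent contributes one
#' transmission (b) or non-transmission (c) of the target allele when the
#' transmission is unambiguous given both parental genotypes; configurations
#' whose consistent phase assignments disagree are skipped and counted in
#' `attr(, "ambiguous")`.
#'
#' @param cohort Named list of [pedigree] objects.
#' @param marker Marker index (1-based).
#' @param target_allele Allele code whose transmissions are counted.
#' @param strat Optional `strat_cohort` restricting families/affecteds.
#' @param one_per_family Use only the proband of each family.
#' @return A `transmission_counts` list: `marker`, `b`, `c`,
#'   `n_trios`; skipped ambiguous parent-child pairs in `attr(, "ambiguous")`.
#' @export
count_transmissions <- function(cohort, marker, target_allele, strat = NULL,
                                one_per_family = FALSE) {
  if (!one_per_family && is.null(strat)) one_per_family <- TRUE
  fams <- if (is.null(strat)) names(cohort) else strat$family_ids
  b <- 0L; c_ <- 0L; amb <- 0L; n_trios <- 0L
  for (fam in fams) {
    ped <- cohort[[fam]]
    mem <- ped$members
    aff <- if (is.null(strat)) ped_affected(ped) else strat$retained[[fam]]
    aff <- intersect(aff, ped_offspring(ped))
    if (!length(aff)) next
    kids <- if (one_per_family) sort(aff, method = "radix")[1L] else aff
    g <- marker_geno(ped, marker)
    for (kid in kids) {
      ki <- match(kid, mem$indiv_id)
      fi <- match(mem$father_id[ki], mem$indiv_id)
      mi <- match(mem$mother_id[ki], mem$indiv_id)
      if (is.na(fi) || is.na(mi)) next
      cg <- g[ki, ]; fg <- g[fi, ]; mg <- g[mi, ]
      if (any(cg == 0L) || any(fg == 0L) || any(mg == 0L)) next
      n_trios <- n_trios + 1L
      ## consistent ordered (paternal, maternal) transmissions
      asg <- list(c(cg[1L], cg[2L]), c(cg[2L], cg[1L]))
      ok <- Filter(function(a) (a[1L] %in% fg) && (a[2L] %in% mg), asg)
      if (!length(ok)) next  # Mendelian inconsistency: no valid phase
      contrib <- unique(lapply(ok, function(a) {
        cc <- c(0L, 0L)  # (b, c) increments
        if (fg[1L] != fg[2L]) {  # father heterozygous
          if (a[1L] == target_allele) cc[1L] <- cc[1L] + 1L
          else if (target_allele %in% fg) cc[2L] <- cc[2L] + 1L
        }
        if (mg[1L] != mg[2L]) {
          if (a[2L] == target_allele) cc[1L] <- cc[1L] + 1L
          else if (target_allele %in% mg) cc[2L] <- cc[2L] + 1L
        }
        cc
      }))
      if (length(contrib) == 1L) {
        b <- b + contrib[[1L]][1L]
        c_ <- c_ + contrib[[1L]][2L]
      } else {
        amb <- amb + 1L
      }
    }
  }
  structure(list(marker = marker, b = b, c = c_, n_trios = n_trios),
            ambiguous = amb, class = "transmission_counts")
}

#' McNemar-form TDT statistic
#'
#' `chi2 = (b - c)^2 / (b + c)` with a 1-df chi-square p-value; invariant
#' under swapping which allele of a biallelic marker is the target.
#'
#' @param counts A `transmission_counts` object or a list with `b` and `c`.
#' @return List with `chi_square` and `p`; markers with `b + c = 0` are
#'   undefined (`NA` with a warning).
#' @export
tdt_statistic <- function(counts) {
  b <- counts$b; c_ <- counts$c
  if (b + c_ < 1L) {
    warning("no informative transmissions; TDT undefined")
    return(list(chi_square = NA_real_, p = NA_real_))
  }
  chi2 <- (b - c_)^2 / (b + c_)
  list(chi_square = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' TDT over a set of markers for one stratified cohort
#'
#' @param cohort Named list of [pedigree] objects.
#' @param marker_map A `marker_map`.
#' @param markers Marker ids (or indices) to test.
#' @param strat Optional `strat_cohort`.
#' @param target_allele Allele code counted (default 2).
#' @param one_per_family Use only the proband of each family.
#' @return Data frame: `marker_id`, `label`, `b`, `c`, `chi2`, `p`.
#' @export
tdt_scan <- function(cohort, marker_map, markers, strat = NULL,
                     target_allele = 2L, one_per_family = TRUE) {
  idx <- if (is.character(markers)) match(markers, marker_map$marker_id)
         else as.integer(markers)
  if (anyNA(idx)) stop("unknown marker id(s)")
  rows <- lapply(idx, function(t) {
    cts <- count_transmissions(cohort, t, target_allele, strat = strat,
                               one_per_family = one_per_family)
    st <- suppressWarnings(tdt_statistic(cts))
    data.frame(marker_id = marker_map$marker_id[t],
               label = if (is.null(strat)) "ALL" else strat$label,
               b = cts$b, c = cts$c, chi2 = st$chi_square, p = st$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
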