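## Three-step stratification of multiplex pedigrees by proband sub-phenotype
## (G level), sibling concordance (Gs level) and gender (GM / GFc), plus
## subgroup merging and the strict-to-broad (n1 -> n2) cohort expansion.

new_strat_cohort <- function(label, family_ids, retained, provenance,
                             level, k, stage, components = NULL) {
  structure(list(label = label, family_ids = family_ids,
                 retained = retained, provenance = provenance,
                 level = level, k = k, stage = stage, components = components),
            class = "strat_cohort")
}

#' @export
print.strat_cohort <- function(x, ...) {
  cat(sprintf("<subgroup %s (%s): %d families, %d retained affecteds>\n",
              x$label, x$stage, length(x$family_ids),
              sum(lengths(x$retained))))
  invisible(x)
}

## one row per affected individual, joined with its subtype assignment;
## affecteds without an assignment get subtype "none", dx "strict"
affected_table <- function(cohort, subtypes) {
  rows <- do.call(rbind, lapply(cohort, function(ped) {
    mem <- ped$members
    aff <- mem$affection == "affected"
    if (!any(aff)) return(NULL)
    data.frame(family_id = ped$family_id, indiv_id = mem$indiv_id[aff],
               sex = mem$sex[aff], stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  key <- paste(rows$family_id, rows$indiv_id)
  skey <- paste(subtypes$family_id, subtypes$indiv_id)
  idx <- match(key, skey)
  rows$subtype <- ifelse(is.na(idx), "none", subtypes$subtype[idx])
  rows$dx_class <- ifelse(is.na(idx), "strict", subtypes$dx_class[idx])
  rows
}

## diagnosis-eligible affecteds for a cohort stage
eligible_rows <- function(at, stage) {
  if (stage == "n1") at[at$dx_class == "strict", , drop = FALSE] else at
}

strat_from_rows <- function(rows, label, provenance, level, k, stage,
                            min_affected = 2L) {
  spl <- split(rows$indiv_id, rows$family_id)
  spl <- spl[lengths(spl) >= min_affected]
  fams <- sort(names(spl), method = "radix")
  new_strat_cohort(label, fams, lapply(spl[fams], sort, method = "radix"),
                   provenance, level, k, stage)
}

#' Step 1: G-level subgroup for one sub-phenotype
#'
#' A family enters subgroup `Gk` when at least one of its
#' diagnosis-eligible affected individuals carries subtype `gk`; all
#' eligible affected siblings are retained regardless of their own subtype,
#' so a family with discordant siblings appears in several G-level
#' subgroups. Families left with fewer than two eligible affecteds are not
#' multiplex and are excluded.
#'
#' @param cohort Named list of [pedigree] objects.
#' @param subtypes Sub-phenotype table ([read_subtypes] layout).
#' @param k Subgroup index 1-4.
#' @param stage `"n1"` (strict diagnoses only) or `"n2"` (strict + broad).
#' @param at Precomputed affected table (internal fast path).
#' @return A `strat_cohort` labelled `G<k>`.
#' @export
assign_G_level <- function(cohort, subtypes, k, stage = "n1", at = NULL) {
  stage <- match.arg(stage, c("n1", "n2"))
  if (is.null(at)) at <- affected_table(cohort, subtypes)
  at <- eligible_rows(at, stage)
  tag <- paste0("g", k)
  fams <- unique(at$family_id[at$subtype == tag])
  rows <- at[at$family_id %in% fams, , drop = FALSE]
  strat_from_rows(rows, paste0("G", k),
                  c(sprintf("stage %s: %s-eligible affecteds", stage,
                            if (stage == "n1") "strict" else "strict+broad"),
                    sprintf("G level: families with >=1 affected of subtype %s; all affecteds retained", tag)),
                  level = "G", k = k, stage = stage)
}

#' Step 2: Gs-level subgroup (concordant siblings only)
#'
#' Discordant affected siblings (those not in subtype `gk`, including
#' affecteds without a subtype label) are removed from a G-level subgroup;
#' families left with fewer than two concordant affecteds are no longer
#' multiplex and are dropped. Removed siblings are recorded in the
#' provenance and treated as unknown phenotype downstream.
#'
#' @param g_cohort A G-level `strat_cohort` from [assign_G_level].
#' @param cohort Named list of [pedigree] objects.
#' @param subtypes Sub-phenotype table.
#' @param at Precomputed affected table (internal fast path).
#' @return A `strat_cohort` labelled `G<k>s`.
#' @export
assign_Gs_level <- function(g_cohort, cohort, subtypes, at = NULL) {
  k <- g_cohort$k
  if (is.null(at)) at <- affected_table(cohort, subtypes)
  at <- eligible_rows(at, g_cohort$stage)
  tag <- paste0("g", k)
  rows <- at[at$family_id %in% g_cohort$family_ids & at$subtype == tag, , drop = FALSE]
  strat_from_rows(rows, paste0("G", k, "s"),
                  c(g_cohort$provenance,
                    sprintf("Gs level: discordant affecteds removed (retained subtype %s only); non-multiplex families dropped", tag)),
                  level = "Gs", k = k, stage = g_cohort$stage)
}

#' Step 3: gender split of a Gs-level subgroup
#'
#' A family goes to the female-containing side (`GFc`) when at least one of
#' its retained concordant affecteds is female, otherwise to the male-only
#' side (`GM`); the two sides partition the Gs subgroup. Families with a
#' retained affected of unknown sex are excluded from both with a warning.
#'
#' @param gs_cohort A Gs-level `strat_cohort`.
#' @param cohort Named list of [pedigree] objects.
#' @return List with elements `GM` and `GFc` (two `strat_cohort`s).
#' @export
split_gender <- function(gs_cohort, cohort) {
  sexes <- lapply(gs_cohort$family_ids, function(fam) {
    mem <- cohort[[fam]]$members
    mem$sex[match(gs_cohort$retained[[fam]], mem$indiv_id)]
  })
  unknown <- vapply(sexes, function(s) any(s == "unknown"), logical(1L))
  if (any(unknown))
    warning(sprintf("%d family(ies) with retained affected of unknown sex excluded from gender split",
                    sum(unknown)))
  has_f <- vapply(sexes, function(s) any(s == "female"), logical(1L))
  pick <- function(sel, side, lab) {
    fams <- gs_cohort$family_ids[sel & !unknown]
    new_strat_cohort(lab, fams, gs_cohort$retained[fams],
                     c(gs_cohort$provenance,
                       sprintf("gender split: %s pedigrees (by retained concordant affecteds)", side)),
                     level = lab_level(side), k = gs_cohort$k, stage = gs_cohort$stage)
  }
  lab_level <- function(side) if (side == "male-only") "GM" else "GFc"
  list(GM = pick(!has_f, "male-only", paste0("G", gs_cohort$k, "M")),
       GFc = pick(has_f, "female-containing", paste0("G", gs_cohort$k, "Fc")))
}

#' Merge two stratified subgroups
#'
#' Set union of the families; a family present in both contributes once,
#' with the union of its retained affecteds. Commutative; merging a cohort
#' with itself returns the identical family set.
#'
#' @param a,b `strat_cohort` objects at the same stage.
#' @return A `strat_cohort` labelled `"<a>&<b>"`.
#' @export
merge_subgroups <- function(a, b) {
  fams <- sort(union(a$family_ids, b$family_ids), method = "radix")
  retained <- lapply(stats::setNames(fams, fams), function(fam)
    sort(union(if (fam %in% a$family_ids) a$retained[[fam]] else character(0),
               if (fam %in% b$family_ids) b$retained[[fam]] else character(0)),
         method = "radix"))
  lab <- if (identical(a$label, b$label)) a$label else paste0(a$label, "&", b$label)
  new_strat_cohort(lab, fams, retained,
                   c(sprintf("merge of %s and %s (strict set union)", a$label, b$label)),
                   level = "merge", k = NA_integer_, stage = a$stage,
                   components = list(a, b))
}

#' Expand a strict-diagnosis (n1) subgroup with broad-spectrum subjects (n2)
#'
#' Rebuilds the same subgroup definition with `dx_class = "broad"`
#' individuals also eligible; the n1 family set is always a subset of the
#' rebuilt n2 set.
#'
#' @param n1_cohort A `strat_cohort` built at stage `"n1"`.
#' @param cohort Named list of [pedigree] objects.
#' @param subtypes Sub-phenotype table.
#' @return The corresponding stage-`"n2"` `strat_cohort`.
#' @export
expand_cohort <- function(n1_cohort, cohort, subtypes) {
  rebuild_strat(n1_cohort, cohort, subtypes, stage = "n2")
}

## rebuild a subgroup recipe at a given stage (used by n2 expansion and by
## the permutation machinery after label randomization)
rebuild_strat <- function(strat, cohort, subtypes, stage = strat$stage) {
  switch(strat$level,
    ALL = {
      at <- eligible_rows(affected_table(cohort, subtypes), stage)
      strat_from_rows(at, "ALL", sprintf("stage %s: all multiplex families", stage),
                      level = "ALL", k = NA_integer_, stage = stage)
    },
    G = assign_G_level(cohort, subtypes, strat$k, stage),
    Gs = assign_Gs_level(assign_G_level(cohort, subtypes, strat$k, stage),
                         cohort, subtypes),
    GM = split_gender(assign_Gs_level(assign_G_level(cohort, subtypes, strat$k, stage),
                                      cohort, subtypes), cohort)$GM,
    GFc = split_gender(assign_Gs_level(assign_G_level(cohort, subtypes, strat$k, stage),
                                       cohort, subtypes), cohort)$GFc,
    merge = merge_subgroups(rebuild_strat(strat$components[[1L]], cohort, subtypes, stage),
                            rebuild_strat(strat$components[[2L]], cohort, subtypes, stage)),
    stop("unknown subgroup level: ", strat$level))
}

#' Build the full 16-subgroup stratification catalogue
#'
#' One driver call producing, for each sub-phenotype k in 1-4, the `Gk`,
#' `Gks`, `GkM` and `GkFc` subgroups (plus optionally the unstratified
#' `ALL` cohort). Deterministic given its inputs.
#'
#' @param cohort Named list of [pedigree] objects.
#' @param subtypes Sub-phenotype table.
#' @param stage `"n1"` or `"n2"`.
#' @param include_all Prepend the unstratified `ALL` cohort.
#' @return Named list of `strat_cohort` objects.
#' @export
stratify_catalogue <- function(cohort, subtypes, stage = "n1", include_all = FALSE) {
  out <- list()
  at <- affected_table(cohort, subtypes)
  if (include_all) {
    out$ALL <- strat_from_rows(eligible_rows(at, stage), "ALL",
                               sprintf("stage %s: all multiplex families", stage),
                               level = "ALL", k = NA_integer_, stage = stage)
  }
  for (k in 1:4) {
    g <- assign_G_level(cohort, subtypes, k, stage, at = at)
    gs <- assign_Gs_level(g, cohort, subtypes, at = at)
    gd <- suppressWarnings(split_gender(gs, cohort))
    out[[g$label]] <- g
    out[[gs$label]] <- gs
    out[[paste0("G", k, "M")]] <- gd$GM
    out[[paste0("G", k, "Fc")]] <- gd$GFc
  }
  out
}

#' Write cohort manifests as TSV
#' @param strats List of `strat_cohort` objects (or a single one).
#' @param path Output path.
#' @export
write_cohort_manifest <- function(strats, path) {
  if (inherits(strats, "strat_cohort")) strats <- list(strats)
  rows <- do.call(rbind, lapply(strats, function(s)
    data.frame(label = s$label, stage = s$stage, family_id = s$family_ids,
               retained = vapply(s$retained, paste, "", collapse = ","),
               provenance = paste(s$provenance, collapse = "; "),
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
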