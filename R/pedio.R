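## Canonical data model: pedigrees, marker maps, sub-phenotype tables, and the
## PED/MAP readers and writers shared by every downstream stage.

SEX_CODES <- c("1" = "male", "2" = "female", "0" = "unknown")
AFF_CODES <- c("2" = "affected", "1" = "unaffected", "0" = "unknown", "-9" = "unknown")
SUBTYPES <- c("g1", "g2", "g3", "g4", "none")
DX_CLASSES <- c("strict", "broad")

#' Construct a pedigree
#'
#' A pedigree holds one family: a member table (parent pointers, sex,
#' affection) and a genotype matrix with two integer allele columns per
#' marker (0 = missing). Founders are members with no parents in the family;
#' individuals with exactly one known parent are rejected.
#'
#' @param family_id Family identifier (scalar character).
#' @param members Data frame with columns `indiv_id`, `father_id`, `mother_id`
#'   (`NA` for founders), `sex` (`"male"`, `"female"`, `"unknown"`) and
#'   `affection` (`"affected"`, `"unaffected"`, `"unknown"`).
#' @param genotypes Integer matrix, one row per member (rownames = `indiv_id`),
#'   `2 * n_markers` columns; allele codes are small positive integers, 0 for
#'   missing. Both alleles of a genotype must be missing or both present.
#' @return An object of class `pedigree`.
#' @export
pedigree <- function(family_id, members, genotypes) {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  members$indiv_id <- as.character(members$indiv_id)
  members$father_id <- as.character(members$father_id)
  members$mother_id <- as.character(members$mother_id)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  rownames(genotypes) <- members$indiv_id
  ped <- structure(list(family_id = as.character(family_id),
                        members = members, genotypes = genotypes),
                   class = "pedigree")
  validate_pedigree(ped)
  canonicalize_pedigree(ped)
}

validate_pedigree <- function(ped) {
  mem <- ped$members
  fam <- ped$family_id
  has_f <- !is.na(mem$father_id)
  has_m <- !is.na(mem$mother_id)
  if (any(has_f != has_m))
    stop(sprintf("family %s: individual(s) %s have exactly one known parent (both or neither required)",
                 fam, paste(mem$indiv_id[has_f != has_m], collapse = ", ")))
  dangling <- c(setdiff(mem$father_id[has_f], mem$indiv_id),
                setdiff(mem$mother_id[has_m], mem$indiv_id))
  if (length(dangling))
    stop(sprintf("family %s: parent reference(s) not found in family: %s",
                 fam, paste(unique(dangling), collapse = ", ")))
  idx <- match(mem$father_id[has_f], mem$indiv_id)
  if (any(mem$sex[idx] != "male"))
    stop(sprintf("family %s: father(s) %s not recorded as male",
                 fam, paste(unique(mem$indiv_id[idx][mem$sex[idx] != "male"]), collapse = ", ")))
  idx <- match(mem$mother_id[has_m], mem$indiv_id)
  if (any(mem$sex[idx] != "female"))
    stop(sprintf("family %s: mother(s) %s not recorded as female",
                 fam, paste(unique(mem$indiv_id[idx][mem$sex[idx] != "female"]), collapse = ", ")))
  ## cycle check: repeatedly strip founders; leftovers are in a loop
  ids <- mem$indiv_id
  parent <- cbind(match(mem$father_id, ids), match(mem$mother_id, ids))
  depth <- rep(NA_integer_, length(ids))
  depth[!has_f] <- 0L
  repeat {
    ready <- is.na(depth) & apply(parent, 1L, function(p) all(!is.na(depth[p])))
    if (!any(ready)) break
    depth[ready] <- apply(parent[ready, , drop = FALSE], 1L,
                          function(p) max(depth[p]) + 1L)
  }
  if (anyNA(depth))
    stop(sprintf("family %s: pedigree loop involving %s", fam,
                 paste(ids[is.na(depth)], collapse = ", ")))
  g <- ped$genotypes
  if (nrow(g) != nrow(mem))
    stop(sprintf("family %s: genotype rows != member count", fam))
  if (ncol(g) %% 2L != 0L)
    stop(sprintf("family %s: odd genotype column count", fam))
  a1 <- g[, seq(1L, ncol(g), by = 2L), drop = FALSE]
  a2 <- g[, seq(2L, ncol(g), by = 2L), drop = FALSE]
  if (any((a1 == 0L) != (a2 == 0L)))
    stop(sprintf("family %s: half-called genotype (one allele missing)", fam))
  invisible(ped)
}

canonicalize_pedigree <- function(ped) {
  mem <- ped$members
  ord <- order(!is.na(mem$father_id), mem$indiv_id, method = "radix")
  ped$members <- mem[ord, , drop = FALSE]
  rownames(ped$members) <- NULL
  ped$genotypes <- ped$genotypes[ord, , drop = FALSE]
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree %s: %d members (%d founders, %d affected), %d markers>\n",
              x$family_id, nrow(x$members), length(ped_founders(x)),
              length(ped_affected(x)), ncol(x$genotypes) %/% 2L))
  invisible(x)
}

#' Founder / affected / offspring accessors
#'
#' @param ped A `pedigree`.
#' @return Character vector of individual ids.
#' @export
ped_founders <- function(ped) ped$members$indiv_id[is.na(ped$members$father_id)]

#' @rdname ped_founders
#' @export
ped_offspring <- function(ped) ped$members$indiv_id[!is.na(ped$members$father_id)]

#' @rdname ped_founders
#' @export
ped_affected <- function(ped) ped$members$indiv_id[ped$members$affection == "affected"]

#' Extract the two allele columns of one marker
#' @param ped A `pedigree`.
#' @param marker Marker index (1-based).
#' @return Integer matrix, members x 2.
#' @keywords internal
marker_geno <- function(ped, marker) {
  ped$genotypes[, c(2L * marker - 1L, 2L * marker), drop = FALSE]
}

#' Read a PED pedigree file
#'
#' Whitespace-delimited PED dialect: six leading columns
#' (family, individual, father, mother, sex, affection) followed by two
#' integer allele columns per marker; `0` codes a missing parent, allele or
#' sex, affection `2` = affected, `1` = unaffected, `0`/`-9` = unknown.
#' Gzipped files are read transparently. Families and members are returned
#' canonically sorted, so the result does not depend on input row order.
#'
#' @param path PED file path (plain or `.gz`).
#' @param marker_count Expected marker count; inferred from the first line
#'   when `NULL`.
#' @return Named list of [pedigree] objects (a cohort), sorted by family id.
#' @export
read_ped <- function(path, marker_count = NULL) {
  lines <- read_text_lines(path)
  if (!length(lines)) stop("empty PED file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 8L) || any((ncols - 6L) %% 2L != 0L))
    stop(sprintf("malformed PED line %d: %d fields",
                 which(ncols < 8L | (ncols - 6L) %% 2L != 0L)[1L],
                 ncols[which(ncols < 8L | (ncols - 6L) %% 2L != 0L)[1L]]))
  if (length(unique(ncols)) != 1L)
    stop(sprintf("PED line %d: genotype column count differs from line 1",
                 which(ncols != ncols[1L])[1L]))
  m <- (ncols[1L] - 6L) %/% 2L
  if (!is.null(marker_count) && m != marker_count)
    stop(sprintf("PED has %d markers, expected %d", m, marker_count))
  tab <- do.call(rbind, fields)
  alleles <- suppressWarnings(matrix(as.integer(tab[, -(1:6), drop = FALSE]),
                                     nrow = nrow(tab)))
  if (anyNA(alleles))
    stop(sprintf("non-numeric allele code at PED line %d",
                 which(rowSums(is.na(alleles)) > 0L)[1L]))
  sex <- unname(SEX_CODES[tab[, 5L]])
  aff <- unname(AFF_CODES[tab[, 6L]])
  if (anyNA(sex)) stop(sprintf("bad sex code at PED line %d", which(is.na(sex))[1L]))
  if (anyNA(aff)) stop(sprintf("bad affection code at PED line %d", which(is.na(aff))[1L]))
  fam <- tab[, 1L]
  peds <- lapply(split(seq_along(fam), fam), function(i) {
    mem <- data.frame(indiv_id = tab[i, 2L],
                      father_id = ifelse(tab[i, 3L] == "0", NA_character_, tab[i, 3L]),
                      mother_id = ifelse(tab[i, 4L] == "0", NA_character_, tab[i, 4L]),
                      sex = sex[i], affection = aff[i],
                      stringsAsFactors = FALSE)
    pedigree(fam[i[1L]], mem, alleles[i, , drop = FALSE])
  })
  peds[order(names(peds), method = "radix")]
}

#' Write a cohort to a PED file
#' @param cohort Named list of [pedigree] objects.
#' @param path Output path (`.gz` for gzip).
#' @export
write_ped <- function(cohort, path) {
  sex_inv <- c(male = "1", female = "2", unknown = "0")
  aff_inv <- c(affected = "2", unaffected = "1", unknown = "0")
  rows <- unlist(lapply(cohort, function(ped) {
    mem <- ped$members
    paste(ped$family_id, mem$indiv_id,
          ifelse(is.na(mem$father_id), "0", mem$father_id),
          ifelse(is.na(mem$mother_id), "0", mem$mother_id),
          sex_inv[mem$sex], aff_inv[mem$affection],
          apply(ped$genotypes, 1L, paste, collapse = " "))
  }), use.names = FALSE)
  write_text_lines(rows, path)
}

#' Read a MAP marker file
#'
#' Four-column MAP dialect (chromosome, marker id, genetic position in cM,
#' physical bp) with an optional fifth cytogenetic-band column. Markers are
#' grouped and sorted by chromosome and genetic position; duplicated
#' positions within a chromosome are jittered upward by `epsilon` (stable
#' order by marker id) so inter-marker distances are strictly positive.
#' Non-autosomal rows (chromosome outside 1-22) are dropped with a warning.
#'
#' @param path MAP file path (plain or `.gz`).
#' @param epsilon Jitter added to duplicated cM positions.
#' @return A `marker_map` data frame with columns `marker_id`, `chrom`,
#'   `cm`, `bp`, `band`; the number of dropped non-autosomal rows is in
#'   `attr(, "dropped")`.
#' @export
read_map <- function(path, epsilon = 1e-6) {
  lines <- read_text_lines(path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 4L))
    stop(sprintf("malformed MAP line %d: %d fields", which(ncols < 4L)[1L], ncols[which(ncols < 4L)[1L]]))
  tab <- t(vapply(fields, function(f) f[1:5], character(5L)))
  chrom <- suppressWarnings(as.integer(tab[, 1L]))
  cm <- suppressWarnings(as.numeric(tab[, 3L]))
  if (anyNA(cm)) stop(sprintf("non-numeric cM at MAP line %d", which(is.na(cm))[1L]))
  if (any(cm < 0, na.rm = TRUE)) stop("negative genetic position in MAP")
  bp <- suppressWarnings(as.integer(tab[, 4L]))
  keep <- !is.na(chrom) & chrom >= 1L & chrom <= 22L
  if (any(!keep))
    warning(sprintf("dropped %d non-autosomal MAP row(s)", sum(!keep)))
  map <- data.frame(marker_id = tab[keep, 2L], chrom = chrom[keep],
                    cm = cm[keep], bp = bp[keep],
                    band = ifelse(is.na(tab[keep, 5L]), NA_character_, tab[keep, 5L]),
                    stringsAsFactors = FALSE)
  map <- map[order(map$chrom, map$cm, map$marker_id, method = "radix"), , drop = FALSE]
  ## strictly increasing cM within chromosome
  jittered <- FALSE
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    pos <- map$cm[i]
    for (j in seq_along(pos)[-1L]) {
      if (pos[j] <= pos[j - 1L]) {
        pos[j] <- pos[j - 1L] + epsilon
        jittered <- TRUE
      }
    }
    map$cm[i] <- pos
  }
  if (jittered) warning("duplicate genetic positions jittered by epsilon")
  rownames(map) <- NULL
  structure(map, dropped = sum(!keep), class = c("marker_map", "data.frame"))
}

#' Write a MAP file
#' @param map A `marker_map` data frame.
#' @param path Output path (`.gz` for gzip).
#' @export
write_map <- function(map, path) {
  rows <- paste(map$chrom, map$marker_id, format(map$cm, trim = TRUE, scientific = FALSE),
                ifelse(is.na(map$bp), 0L, map$bp))
  band <- if ("band" %in% names(map)) map$band else NA_character_
  rows <- ifelse(is.na(band), rows, paste(rows, band))
  write_text_lines(rows, path)
}

#' Read a sub-phenotype assignment table
#'
#' Tab- or whitespace-separated table with header
#' `family_id indiv_id subtype dx_class`; `subtype` is one of `g1`-`g4` or
#' `none`, `dx_class` is `strict` or `broad`. When a cohort is supplied,
#' assignments for individuals absent from the pedigrees are flagged (kept in
#' `attr(, "absent")` with a warning), as are subtype labels attached to
#' non-affected individuals (`attr(, "nonaffected_labelled")`).
#'
#' @param path Table path (plain or `.gz`).
#' @param cohort Optional named list of [pedigree] objects to validate against.
#' @return Data frame of validated assignments.
#' @export
read_subtypes <- function(path, cohort = NULL) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("family_id", "indiv_id", "subtype", "dx_class")
  if (!all(need %in% names(df)))
    stop("subtype table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  bad <- setdiff(unique(df$subtype), SUBTYPES)
  if (length(bad)) stop("unknown subtype token(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$dx_class), DX_CLASSES)
  if (length(bad)) stop("unknown dx_class token(s): ", paste(bad, collapse = ", "))
  df <- df[order(df$family_id, df$indiv_id, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(cohort)) {
    known <- unlist(lapply(cohort, function(p) paste(p$family_id, p$members$indiv_id)),
                    use.names = FALSE)
    aff <- unlist(lapply(cohort, function(p) paste(p$family_id, ped_affected(p))),
                  use.names = FALSE)
    key <- paste(df$family_id, df$indiv_id)
    absent <- !(key %in% known)
    if (any(absent))
      warning(sprintf("%d subtype assignment(s) for individuals absent from the cohort",
                      sum(absent)))
    mislab <- df$subtype != "none" & (key %in% known) & !(key %in% aff)
    if (any(mislab))
      warning(sprintf("%d non-affected individual(s) carry a subtype label: %s",
                      sum(mislab), paste(utils::head(key[mislab], 5L), collapse = "; ")))
    attr(df, "absent") <- df[absent, , drop = FALSE]
    attr(df, "nonaffected_labelled") <- df[mislab, , drop = FALSE]
  }
  df
}

#' Write a sub-phenotype table
#' @param subtypes Data frame with the four standard columns.
#' @param path Output path (`.gz` for gzip).
#' @export
write_subtypes <- function(subtypes, path) {
  rows <- c(paste("family_id", "indiv_id", "subtype", "dx_class", sep = "\t"),
            paste(subtypes$family_id, subtypes$indiv_id, subtypes$subtype,
                  subtypes$dx_class, sep = "\t"))
  write_text_lines(rows, path)
}

#' Count Mendelian inconsistencies per marker
#'
#' Scans each non-founder against its (typed) parents at every marker and
#' counts child-marker combinations whose genotype cannot be produced by any
#' allele split of the parents. With one typed parent the check degrades to
#' allele compatibility with that parent. Deterministic pure scan.
#'
#' @param x A [pedigree] or a cohort (named list of pedigrees).
#' @param marker_map Optional `marker_map` supplying marker names.
#' @return For a pedigree, a named integer vector of per-marker error counts;
#'   for a cohort, a markers x families integer matrix.
#' @export
mendelian_check <- function(x, marker_map = NULL) {
  if (inherits(x, "pedigree")) {
    counts <- mendel_counts_ped(x)
  } else {
    counts <- vapply(x, mendel_counts_ped, integer(ncol(x[[1L]]$genotypes) %/% 2L))
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                               dimnames = list(NULL, names(x)))
  }
  if (!is.null(marker_map)) {
    if (NROW(counts) != nrow(marker_map))
      stop("marker_map length does not match genotype marker count")
    if (is.matrix(counts)) rownames(counts) <- marker_map$marker_id
    else names(counts) <- marker_map$marker_id
  }
  counts
}

mendel_counts_ped <- function(ped) {
  g <- ped$genotypes
  m <- ncol(g) %/% 2L
  mem <- ped$members
  kid <- which(!is.na(mem$father_id))
  out <- integer(m)
  if (!length(kid)) return(out)
  fi <- match(mem$father_id[kid], mem$indiv_id)
  mi <- match(mem$mother_id[kid], mem$indiv_id)
  for (t in seq_len(m)) {
    c1 <- g[kid, 2L * t - 1L]; c2 <- g[kid, 2L * t]
    f1 <- g[fi, 2L * t - 1L]; f2 <- g[fi, 2L * t]
    m1 <- g[mi, 2L * t - 1L]; m2 <- g[mi, 2L * t]
    typed <- c1 != 0L
    bad <- logical(length(kid))
    both <- typed & f1 != 0L & m1 != 0L
    if (any(both)) {
      ok <- (compat2(c1, c2, f1, m1) | compat2(c1, c2, f1, m2) |
             compat2(c1, c2, f2, m1) | compat2(c1, c2, f2, m2))
      bad[both] <- !ok[both]
    }
    fonly <- typed & f1 != 0L & m1 == 0L
    if (any(fonly))
      bad[fonly] <- !(c1 == f1 | c1 == f2 | c2 == f1 | c2 == f2)[fonly]
    monly <- typed & f1 == 0L & m1 != 0L
    if (any(monly))
      bad[monly] <- !(c1 == m1 | c1 == m2 | c2 == m1 | c2 == m2)[monly]
    out[t] <- sum(bad)
  }
  out
}

## child unordered genotype (c1,c2) compatible with paternal allele a, maternal b
compat2 <- function(c1, c2, a, b) (c1 == a & c2 == b) | (c1 == b & c2 == a)

read_text_lines <- function(path) {
  con <- if (grepl("[.]gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

write_text_lines <- function(lines, path) {
  con <- if (grepl("[.]gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
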