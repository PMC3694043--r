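## Cross-subgroup comparison surfaces: the LOD matrix behind the heat map
## and ranked per-subgroup peak tables.

#' Assemble a positions x subgroups LOD matrix
#'
#' Curves must share one evaluation grid (same chromosome/position rows).
#' Rows are kept when the row maximum across subgroups reaches the display
#' cut-off; ordering is genomic, columns follow the order of `curves`.
#'
#' @param curves Named list of `lod_curve` data frames from [scan_genome].
#' @param cutoff Display cut-off (default 2.0).
#' @return A `lod_matrix` list: `positions` (data frame `chrom`, `cm`,
#'   `marker_id`) and `lod` (numeric matrix). Empty (all cells below the
#'   cut-off) gives a 0-row matrix with a warning.
#' @export
build_matrix <- function(curves, cutoff = 2.0) {
  if (is.null(names(curves)))
    names(curves) <- vapply(curves, function(cv) cv$label[1L], "")
  ref <- curves[[1L]][, c("chrom", "cm", "marker_id")]
  for (cv in curves[-1L]) {
    if (nrow(cv) != nrow(ref) ||
        any(cv$chrom != ref$chrom) || any(cv$cm != ref$cm))
      stop("curves evaluated on mismatched maps")
  }
  lod <- do.call(cbind, lapply(curves, function(cv) cv$lod))
  colnames(lod) <- names(curves)
  keep <- apply(lod, 1L, max) >= cutoff
  if (!any(keep)) warning("no position reaches the display cut-off")
  structure(list(positions = ref[keep, , drop = FALSE],
                 lod = lod[keep, , drop = FALSE], cutoff = cutoff),
            class = "lod_matrix")
}

#' Heat-map display of a LOD matrix
#' @param x A `lod_matrix`.
#' @param ... Passed to [graphics::image].
#' @export
plot.lod_matrix <- function(x, ...) {
  if (!nrow(x$lod)) stop("empty LOD matrix")
  z <- x$lod[rev(seq_len(nrow(x$lod))), , drop = FALSE]
  graphics::image(x = seq_len(ncol(z)), y = seq_len(nrow(z)), z = t(z),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1L, at = seq_len(ncol(z)), labels = colnames(z), las = 2L,
                 cex.axis = 0.7)
  graphics::axis(2L, at = seq_len(nrow(z)),
                 labels = rev(x$positions$marker_id), las = 1L, cex.axis = 0.5)
  invisible(x)
}

#' Ranked linkage peaks per subgroup
#'
#' Local maxima of each curve, greedily selected in descending LOD order;
#' a candidate within `min_sep_cm` of an already-kept peak on the same
#' chromosome is only kept when the curve dips by at least `lod_drop`
#' between them.
#'
#' @param curves Named list (or single) `lod_curve`.
#' @param top_k Peaks per subgroup.
#' @param min_sep_cm Minimum separation between peaks (cM).
#' @param lod_drop Valley depth that lets two nearby peaks coexist.
#' @return Data frame: `label`, `chrom`, `cm`, `marker_id`, `lod`, `p`,
#'   `n_families`; zero rows for flat-zero curves.
#' @export
peak_table <- function(curves, top_k = 5L, min_sep_cm = 30, lod_drop = 1) {
  if (inherits(curves, "lod_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    nfam <- attr(cv, "n_families")
    peaks <- find_peaks(cv, top_k, min_sep_cm, lod_drop)
    if (!nrow(peaks)) return(NULL)
    data.frame(label = cv$label[1L], peaks,
               p = lod_to_pvalue(peaks$lod),
               n_families = if (is.null(nfam)) NA_integer_ else nfam,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- data.frame(label = character(0), chrom = integer(0), cm = numeric(0),
                      marker_id = character(0), lod = numeric(0), p = numeric(0),
                      n_families = integer(0))
  rownames(out) <- NULL
  out
}

find_peaks <- function(cv, top_k, min_sep_cm, lod_drop) {
  cand <- integer(0)
  for (ch in unique(cv$chrom)) {
    i <- which(cv$chrom == ch)
    v <- cv$lod[i]
    loc <- which(v > 0 &
                 v >= c(-Inf, v[-length(v)]) &
                 v >= c(v[-1L], -Inf))
    cand <- c(cand, i[loc])
  }
  cand <- cand[order(cv$lod[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (j in cand) {
    ok <- TRUE
    for (kp in kept) {
      if (cv$chrom[j] != cv$chrom[kp]) next
      if (abs(cv$cm[j] - cv$cm[kp]) >= min_sep_cm) next
      between <- which(cv$chrom == cv$chrom[j] &
                       cv$cm >= min(cv$cm[j], cv$cm[kp]) &
                       cv$cm <= max(cv$cm[j], cv$cm[kp]))
      if (min(cv$lod[between]) <= min(cv$lod[j], cv$lod[kp]) - lod_drop) next
      ok <- FALSE; break
    }
    if (ok) kept <- c(kept, j)
    if (length(kept) >= top_k) break
  }
  kept <- kept[order(cv$lod[kept], decreasing = TRUE)]
  cv[kept, c("chrom", "cm", "marker_id", "lod"), drop = FALSE]
}

#' Write a LOD matrix as TSV
#' @param x A `lod_matrix`.
#' @param path Output path.
#' @export
write_lod_matrix <- function(x, path) {
  df <- cbind(x$positions, as.data.frame(x$lod))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
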