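# Independent brute-force oracles and tiny fixture builders used across the
# suite. Everything here is deliberately written as plain enumeration loops,
# separate from the package's vectorized implementations.

# -- fixture: random two-founder nuclear family on one chromosome ------------

rand_nuclear <- function(n_kids, cm, freq1 = 0.5, missing_prob = 0,
                         parents_typed = TRUE) {
  Tn <- length(cm)
  draw_hap <- function() ifelse(runif(Tn) < freq1, 1L, 2L)
  fh <- list(draw_hap(), draw_hap())
  mh <- list(draw_hap(), draw_hap())
  drop_chain <- function() {
    b <- integer(Tn)
    b[1] <- rbinom(1, 1, 0.5)
    if (Tn > 1) for (t in 2:Tn) {
      th <- 0.5 * (1 - exp(-2 * (cm[t] - cm[t - 1]) / 100))
      b[t] <- if (runif(1) < th) 1L - b[t - 1] else b[t - 1]
    }
    b
  }
  geno <- matrix(0L, 2 + n_kids, 2 * Tn)
  geno[1, ] <- as.vector(rbind(fh[[1]], fh[[2]]))
  geno[2, ] <- as.vector(rbind(mh[[1]], mh[[2]]))
  for (j in seq_len(n_kids)) {
    bp <- drop_chain(); bm <- drop_chain()
    pat <- ifelse(bp == 0L, fh[[1]], fh[[2]])
    mat <- ifelse(bm == 0L, mh[[1]], mh[[2]])
    geno[2 + j, ] <- as.vector(rbind(pat, mat))
  }
  if (!parents_typed) geno[1:2, ] <- 0L
  if (missing_prob > 0) {
    for (i in seq_len(nrow(geno))) for (t in seq_len(Tn)) {
      if (runif(1) < missing_prob) geno[i, c(2 * t - 1, 2 * t)] <- 0L
    }
  }
  mem <- data.frame(
    indiv_id = c("P1", "P2", sprintf("K%02d", seq_len(n_kids))),
    father_id = c(NA, NA, rep("P1", n_kids)),
    mother_id = c(NA, NA, rep("P2", n_kids)),
    sex = c("male", "female", rep("male", n_kids)),
    affection = c("unknown", "unknown", rep("affected", n_kids)),
    stringsAsFactors = FALSE)
  pedigree("FX", mem, geno)
}

toy_map <- function(cm, chrom = 1L) {
  structure(data.frame(marker_id = sprintf("m%02d", seq_along(cm)),
                       chrom = chrom, cm = cm, bp = seq_along(cm) * 1000L,
                       band = NA_character_, stringsAsFactors = FALSE),
            class = c("marker_map", "data.frame"))
}

uniform_freqs <- function(n, p1 = 0.5) {
  rep(list(c("1" = p1, "2" = 1 - p1)), n)
}

# -- oracle: emission by explicit enumeration over founder genotypes ---------

oracle_emission <- function(ped, marker, freq) {
  mem <- ped$members
  fo <- mem$indiv_id[is.na(mem$father_id)]
  fa <- fo[mem$sex[match(fo, mem$indiv_id)] == "male"]
  mo <- fo[mem$sex[match(fo, mem$indiv_id)] == "female"]
  kids <- mem$indiv_id[!is.na(mem$father_id)]
  g <- ped$genotypes[, c(2 * marker - 1, 2 * marker)]
  codes <- as.integer(names(freq))
  m <- 2 * length(kids)
  e <- numeric(2^m)
  for (a1 in codes) for (a2 in codes) for (a3 in codes) for (a4 in codes) {
    w <- freq[as.character(a1)] * freq[as.character(a2)] *
         freq[as.character(a3)] * freq[as.character(a4)]
    gf <- g[match(fa, mem$indiv_id), ]
    if (gf[1] != 0 && !setequal_pair(gf, c(a1, a2))) next
    gm <- g[match(mo, mem$indiv_id), ]
    if (gm[1] != 0 && !setequal_pair(gm, c(a3, a4))) next
    for (s in 0:(2^m - 1)) {
      okv <- 1
      for (j in seq_along(kids)) {
        ck <- g[match(kids[j], mem$indiv_id), ]
        if (ck[1] == 0) next
        bp <- bitwAnd(bitwShiftR(s, 2 * j - 2), 1L)
        bm <- bitwAnd(bitwShiftR(s, 2 * j - 1), 1L)
        pa <- if (bp == 0) a1 else a2
        ma <- if (bm == 0) a3 else a4
        if (!setequal_pair(ck, c(pa, ma))) { okv <- 0; break }
      }
      e[s + 1] <- e[s + 1] + w * okv
    }
  }
  unname(e)
}

setequal_pair <- function(a, b) {
  (a[1] == b[1] && a[2] == b[2]) || (a[1] == b[2] && a[2] == b[1])
}

# -- oracle: multipoint posterior by direct summation over the joint ---------
# handles 1-3 markers; dense transition matrices built from Hamming distances

oracle_transition <- function(m, theta) {
  ns <- 2^m
  H <- outer(0:(ns - 1), 0:(ns - 1), function(a, b) {
    x <- bitwXor(a, b)
    cnt <- 0
    for (k in 0:(m - 1)) cnt <- cnt + bitwAnd(bitwShiftR(x, k), 1L)
    cnt
  })
  theta^H * (1 - theta)^(m - H)
}

oracle_posterior <- function(ped, cm, freqs) {
  kids <- sum(!is.na(ped$members$father_id))
  m <- 2 * kids
  ns <- 2^m
  Tn <- length(cm)
  E <- sapply(seq_len(Tn), function(t) oracle_emission(ped, t, freqs[[t]]))
  th <- function(d) 0.5 * (1 - exp(-2 * d / 100))
  if (Tn == 1) {
    j <- E[, 1] / ns
    return(matrix(j / sum(j), nrow = 1))
  }
  T12 <- oracle_transition(m, th(cm[2] - cm[1]))
  if (Tn == 2) {
    joint <- (E[, 1] / ns) * T12 * rep(E[, 2], each = ns)  # [v1, v2]
    joint <- matrix(joint, ns, ns)
    tot <- sum(joint)
    return(rbind(rowSums(joint) / tot, colSums(joint) / tot))
  }
  T23 <- oracle_transition(m, th(cm[3] - cm[2]))
  m1 <- numeric(ns); m2 <- numeric(ns); m3 <- numeric(ns); tot <- 0
  for (v1 in 1:ns) for (v2 in 1:ns) {
    base <- (E[v1, 1] / ns) * T12[v1, v2] * E[v2, 2]
    if (base == 0) next
    contrib <- base * T23[v2, ] * E[, 3]
    s <- sum(contrib)
    m1[v1] <- m1[v1] + s
    m2[v2] <- m2[v2] + s
    m3 <- m3 + contrib
    tot <- tot + s
  }
  rbind(m1 / tot, m2 / tot, m3 / tot)
}

# -- oracle: exact HWE probability by direct factorial enumeration -----------

oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- sapply(hets, function(h) {
    homA <- (nA - h) / 2
    homa <- (na - h) / 2
    exp(lfactorial(n) - lfactorial(homA) - lfactorial(h) - lfactorial(homa) +
        h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  })
  pr <- pr / sum(pr)
  obs <- pr[hets == nAa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# -- oracle: Kong-Cox LOD by dense delta-grid search (step 1e-5) -------------
# the objective is concave in delta, so coarse-then-fine refinement visits
# the same optimum as a flat 1e-5 grid

oracle_kc_grid <- function(z, dmax = NULL, step = 1e-5) {
  if (is.null(dmax)) {
    dmax <- if (any(z < 0)) (1 - 1e-9) * min(-1 / z[z < 0]) else 1
  }
  f <- function(d) sum(log10(1 + d * z))
  coarse <- seq(0, dmax, length.out = 2001)
  fc <- vapply(coarse, f, 0)
  i <- which.max(fc)
  lo <- coarse[max(1, i - 1)]; hi <- coarse[min(length(coarse), i + 1)]
  fine <- seq(lo, hi, by = step)
  fv <- vapply(fine, f, 0)
  j <- which.max(fv)
  list(delta = fine[j], lod = max(fv[j], 0))
}

# -- oracle: per-trio Mendelian compatibility by exhaustive allele splits ----

oracle_mendel_family <- function(ped) {
  mem <- ped$members
  g <- ped$genotypes
  m <- ncol(g) / 2
  out <- integer(m)
  for (t in seq_len(m)) {
    for (i in which(!is.na(mem$father_id))) {
      ck <- g[i, c(2 * t - 1, 2 * t)]
      if (ck[1] == 0) next
      fg <- g[match(mem$father_id[i], mem$indiv_id), c(2 * t - 1, 2 * t)]
      mg <- g[match(mem$mother_id[i], mem$indiv_id), c(2 * t - 1, 2 * t)]
      ok <- FALSE
      pat_opts <- if (fg[1] == 0) unique(c(ck, fg[fg != 0], 1:2)) else fg
      mat_opts <- if (mg[1] == 0) unique(c(ck, mg[mg != 0], 1:2)) else mg
      for (pa in pat_opts) for (ma in mat_opts) {
        if (setequal_pair(ck, c(pa, ma))) ok <- TRUE
      }
      if (!ok) out[t] <- out[t] + 1
    }
  }
  out
}

# -- fixture: cohort with scripted subtype structure -------------------------
# spec: list of per-family character vectors of affected subtypes, optionally
# with attributes for sexes and dx classes

scripted_cohort <- function(subtype_sets, sexes = NULL, dx = NULL, n_markers = 2) {
  cohort <- list()
  rows <- list()
  for (f in seq_along(subtype_sets)) {
    subs <- subtype_sets[[f]]
    s <- length(subs)
    fam <- sprintf("F%03d", f)
    sx <- if (is.null(sexes)) rep("male", s) else sexes[[f]]
    dd <- if (is.null(dx)) rep("strict", s) else dx[[f]]
    kid_ids <- sprintf("K%02d", seq_len(s))
    geno <- matrix(rep(c(1L, 2L), (2 + s) * n_markers), nrow = 2 + s, byrow = TRUE)
    mem <- data.frame(indiv_id = c("P1", "P2", kid_ids),
                      father_id = c(NA, NA, rep("P1", s)),
                      mother_id = c(NA, NA, rep("P2", s)),
                      sex = c("male", "female", sx),
                      affection = c("unknown", "unknown", rep("affected", s)),
                      stringsAsFactors = FALSE)
    cohort[[fam]] <- pedigree(fam, mem, geno)
    rows[[fam]] <- data.frame(family_id = fam, indiv_id = kid_ids,
                              subtype = subs, dx_class = dd,
                              stringsAsFactors = FALSE)
  }
  list(cohort = cohort, subtypes = do.call(rbind, rows))
}
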