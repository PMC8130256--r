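# Allele frequencies, heterozygosity, pairwise Fst, hierarchical AMOVA and
# individual genetic distances.

#' Per-group allele frequencies
#'
#' Alternate-allele frequency per group per locus,
#' \eqn{p = \sum dosage / (2 n_{called})}, with missing entries excluded.
#' Loci with no called genotype in a group get \code{NaN}.
#'
#' @param g A \code{genotype_matrix}.
#' @param grouping Metadata column name or a vector of group labels.
#' @return List with matrices \code{p} (groups x loci) and \code{n_called}.
#' @export
allele_frequencies <- function(g, grouping) {
  labels <- resolve_grouping(g, grouping)
  groups <- sort(unique(labels))
  L <- ncol(g$dosage)
  p <- n_called <- matrix(NA_real_, length(groups), L,
                          dimnames = list(groups, colnames(g$dosage)))
  for (grp in groups) {
    d <- g$dosage[labels == grp, , drop = FALSE]
    nc <- colSums(!is.na(d))
    n_called[grp, ] <- nc
    p[grp, ] <- colSums(d, na.rm = TRUE) / (2 * nc)   # NaN where nc == 0
  }
  list(p = p, n_called = n_called)
}

#' Observed and expected heterozygosity per group
#'
#' \eqn{H_o} is the mean over loci of the heterozygote fraction among called
#' genotypes; \eqn{H_e} is the mean over loci of \eqn{2p(1-p)}. A group with
#' \eqn{H_o < H_e} is flagged as inbreeding-like (isolation); the converse
#' suggests isolate-breaking admixture.
#'
#' @inheritParams allele_frequencies
#' @return A \code{"het_result"}: data frame \code{summary} (group, Ho, He,
#'   flag) and matrices \code{per_locus_ho}, \code{per_locus_he}.
#' @export
heterozygosity <- function(g, grouping) {
  labels <- resolve_grouping(g, grouping)
  groups <- sort(unique(labels))
  af <- allele_frequencies(g, labels)
  ho <- matrix(NA_real_, length(groups), ncol(g$dosage),
               dimnames = dimnames(af$p))
  for (grp in groups) {
    d <- g$dosage[labels == grp, , drop = FALSE]
    ho[grp, ] <- colSums(d == 1L, na.rm = TRUE) / colSums(!is.na(d))
  }
  he <- 2 * af$p * (1 - af$p)
  s <- data.frame(group = groups,
                  Ho = rowMeans(ho, na.rm = TRUE),
                  He = rowMeans(he, na.rm = TRUE),
                  stringsAsFactors = FALSE, row.names = NULL)
  s$flag <- ifelse(s$Ho < s$He, "inbreeding-like", "isolate-breaking")
  structure(list(summary = s, per_locus_ho = ho, per_locus_he = he),
            class = "het_result")
}

#' @export
print.het_result <- function(x, digits = 4, ...) {
  cat("Heterozygosity per group:\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

# --- allele-level variance components --------------------------------------
# Two-level AMOVA at the allele (haplotype) level, locus by locus. For a
# biallelic locus the within-group sum of squares over the 2n alleles equals
# m * p * (1 - p), so everything reduces to allele counts; summing variance
# components over loci gives the multi-locus Phi_ST (the treatment Arlequin
# applies to genotypic SNP data).
fst_components_two <- function(dos1, dos2) {
  m1 <- 2 * colSums(!is.na(dos1)); a1 <- colSums(dos1, na.rm = TRUE)
  m2 <- 2 * colSums(!is.na(dos2)); a2 <- colSums(dos2, na.rm = TRUE)
  M <- m1 + m2
  ok <- m1 > 0 & m2 > 0 & M > 2
  if (!any(ok)) return(c(sigma_a = NA_real_, sigma_w = NA_real_))
  m1 <- m1[ok]; m2 <- m2[ok]; a1 <- a1[ok]; a2 <- a2[ok]; M <- M[ok]
  p1 <- a1 / m1; p2 <- a2 / m2; pbar <- (a1 + a2) / M
  ss_t <- M * pbar * (1 - pbar)
  ss_w <- m1 * p1 * (1 - p1) + m2 * p2 * (1 - p2)
  ss_a <- ss_t - ss_w
  ms_a <- ss_a                       # df_a = 1
  ms_w <- ss_w / (M - 2)
  n_c <- (M - (m1^2 + m2^2) / M)    # / (P - 1) with P = 2
  sigma_a <- (ms_a - ms_w) / n_c
  c(sigma_a = sum(sigma_a), sigma_w = sum(ms_w))
}

phi_st_two <- function(dos1, dos2) {
  comp <- fst_components_two(dos1, dos2)
  unname(comp[1] / (comp[1] + comp[2]))
}

# Weir & Cockerham (1984) theta across r groups, summed over loci.
wc_theta <- function(g, labels) {
  groups <- sort(unique(labels))
  r <- length(groups)
  n <- vapply(groups, function(grp)
    colSums(!is.na(g$dosage[labels == grp, , drop = FALSE])),
    numeric(ncol(g$dosage)))
  p <- vapply(groups, function(grp) {
    d <- g$dosage[labels == grp, , drop = FALSE]
    colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
  }, numeric(ncol(g$dosage)))
  h <- vapply(groups, function(grp) {
    d <- g$dosage[labels == grp, , drop = FALSE]
    colSums(d == 1L, na.rm = TRUE) / colSums(!is.na(d))
  }, numeric(ncol(g$dosage)))
  # n, p, h are loci x groups
  ok <- rowSums(n > 0) == r & rowSums(n) > r
  n <- n[ok, , drop = FALSE]; p <- p[ok, , drop = FALSE]
  h <- h[ok, , drop = FALSE]
  nbar <- rowMeans(n)
  nc <- (r * nbar - rowSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n * p) / (r * nbar)
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  sum(a) / sum(a + b + cc)
}

#' Pairwise Fst between groups with permutation tests
#'
#' For every pair of groups, Fst is the among-group fraction of allele-level
#' variance from a two-level AMOVA (the Phi_ST Arlequin reports for
#' genotypic SNP data); \code{method = "wc"} gives the Weir-Cockerham (1984)
#' theta instead. Significance comes from permuting individuals between the
#' two groups: \eqn{p = (1 + \#\{F^{perm} \ge F^{obs}\}) / (B + 1)}.
#' Negative estimates are reported as-is.
#'
#' @inheritParams allele_frequencies
#' @param permutations Number of label permutations B per pair.
#' @param seed RNG seed governing all permutation draws.
#' @param method \code{"amova"} (Phi_ST, default) or \code{"wc"}.
#' @return A \code{"fst_result"}: \code{fst} and \code{p_value} symmetric
#'   matrices, \code{groups}, \code{permutations}, \code{method}.
#' @export
pairwise_fst <- function(g, grouping, permutations = 999, seed = 1L,
                         method = c("amova", "wc")) {
  method <- match.arg(method)
  labels <- resolve_grouping(g, grouping)
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    stop("group(s) with fewer than 2 individuals: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  K <- length(groups)
  fst <- pv <- matrix(0, K, K, dimnames = list(groups, groups))
  stat_fun <- if (method == "amova") {
    function(d1, d2) phi_st_two(d1, d2)
  } else {
    function(d1, d2) {
      lab <- rep(c("a", "b"), c(nrow(d1), nrow(d2)))
      wc_theta(list(dosage = rbind(d1, d2)), lab)
    }
  }
  local_rng(seed, {
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      d1 <- g$dosage[labels == groups[i], , drop = FALSE]
      d2 <- g$dosage[labels == groups[j], , drop = FALSE]
      obs <- stat_fun(d1, d2)
      fst[i, j] <- fst[j, i] <- obs
      if (permutations > 0) {
        pool <- rbind(d1, d2)
        n1 <- nrow(d1); n <- nrow(pool)
        hits <- 0L
        for (b in seq_len(permutations)) {
          idx <- sample.int(n, n1)
          perm <- stat_fun(pool[idx, , drop = FALSE],
                           pool[-idx, , drop = FALSE])
          if (!is.na(perm) && perm >= obs) hits <- hits + 1L
        }
        pv[i, j] <- pv[j, i] <- (1 + hits) / (permutations + 1)
      } else {
        pv[i, j] <- pv[j, i] <- NA_real_
      }
    }
  })
  diag(pv) <- NA_real_
  structure(list(fst = fst, p_value = pv, groups = groups,
                 permutations = permutations, method = method),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, digits = 4, alpha = 0.05, ...) {
  cat(sprintf("Pairwise Fst (%s), %d permutations\n", x$method,
              x$permutations))
  m <- format(round(x$fst, digits))
  ns <- !is.na(x$p_value) & x$p_value > alpha
  m[ns] <- paste0(m[ns], "*")
  print(m, quote = FALSE)
  if (any(ns)) cat("* not significant at alpha =", alpha, "\n")
  invisible(x)
}

#' Individual-level genetic distance
#'
#' Allele-mismatch dissimilarity between individuals:
#' \eqn{d(i,j) = \sum_l |g_{il} - g_{jl}| / 2} over loci called in both,
#' divided by the number of such loci (pairwise-complete), so identical
#' genotypes give 0 and opposite homozygotes at every locus give 1.
#'
#' @param g A \code{genotype_matrix}.
#' @param metric Distance definition; only \code{"allele_mismatch"}.
#' @return A \code{stats::dist} object with attribute
#'   \code{method = "allele_mismatch"}.
#' @export
individual_distance <- function(g, metric = "allele_mismatch") {
  metric <- match.arg(metric, "allele_mismatch")
  d <- g$dosage
  if (nrow(d) < 2L) stop("need at least 2 individuals", call. = FALSE)
  # |a - b| over {0,1,2} decomposes into mismatches of the indicators
  # (a >= 1) and (a == 2), which are crossprod-friendly
  V <- !is.na(d)
  h1 <- (d >= 1L) & V; h2 <- (d == 2L) & V
  mism <- function(h) {
    hm <- h * 1; vm <- V * 1
    A <- tcrossprod(hm)              # sum x_i x_j over jointly called loci
    S <- tcrossprod(hm, vm)          # sum x_i over loci called in both
    S + t(S) - 2 * A
  }
  shared <- tcrossprod(V * 1)
  off <- shared[upper.tri(shared)]
  if (any(off == 0)) {
    idx <- which(upper.tri(shared) & shared == 0, arr.ind = TRUE)
    pairs <- apply(idx, 1, function(r)
      paste(rownames(d)[r[1]], rownames(d)[r[2]], sep = "/"))
    stop("pair(s) with no shared called loci: ",
         paste(utils::head(pairs, 5), collapse = ", "), call. = FALSE)
  }
  m <- (mism(h1) + mism(h2)) / (2 * shared)
  diag(m) <- 0
  rownames(m) <- colnames(m) <- rownames(d)
  out <- stats::as.dist(m)
  attr(out, "method") <- metric
  out
}

# --- hierarchical AMOVA ----------------------------------------------------

# Expand dosages into 2N pseudo-haplotype indicator rows; per-locus sums of
# squares at the allele level equal those of the mismatch-distance AMOVA, so
# phase (which is arbitrary here) never matters.
haplotype_matrix <- function(g) {
  d <- g$dosage
  h1 <- (d >= 1L) * 1; h2 <- (d == 2L) * 1
  h1[is.na(d)] <- NA; h2[is.na(d)] <- NA
  H <- matrix(NA_real_, 2 * nrow(d), ncol(d))
  H[seq(1, 2 * nrow(d), by = 2), ] <- h1
  H[seq(2, 2 * nrow(d), by = 2), ] <- h2
  rownames(H) <- paste0(rep(rownames(d), each = 2), c(".1", ".2"))
  H
}

# Squared mismatch distances between rows of a 0/1 matrix with missing
# entries, scaled to the full locus count (pairwise-complete).
hap_sq_distance <- function(H) {
  V <- (!is.na(H)) * 1
  Hm <- H; Hm[is.na(Hm)] <- 0
  A <- tcrossprod(Hm)
  S <- tcrossprod(Hm, V)
  shared <- tcrossprod(V)
  if (any(shared[upper.tri(shared)] == 0)) {
    stop("haplotype pair(s) share no called loci", call. = FALSE)
  }
  m <- (S + t(S) - 2 * A) * (ncol(H) / shared)
  diag(m) <- 0
  m
}

# Variance-component decomposition of a squared-distance matrix over units
# grouped as populations (and optionally populations into groups).
amova_decompose <- function(D2, pop, grp = NULL) {
  N <- nrow(D2)
  pop <- as.character(pop)
  pops <- sort(unique(pop))
  P <- length(pops)
  ss_among_units <- function(idx) sum(D2[idx, idx]) / (2 * length(idx))
  ss_t <- ss_among_units(seq_len(N))
  ss_wp <- sum(vapply(pops, function(p) ss_among_units(which(pop == p)),
                      numeric(1)))
  n_p <- as.numeric(table(pop)[pops])
  if (is.null(grp)) {                      # two-level decomposition
    df_a <- P - 1; df_w <- N - P
    ss_a <- ss_t - ss_wp
    ms_a <- ss_a / df_a; ms_w <- ss_wp / df_w
    n_c <- (N - sum(n_p^2) / N) / (P - 1)
    sigma_w <- ms_w
    sigma_a <- (ms_a - ms_w) / n_c
    tot <- sigma_a + sigma_w
    return(list(
      table = data.frame(
        source = c("Among populations", "Within populations", "Total"),
        df = c(df_a, df_w, N - 1),
        SS = c(ss_a, ss_wp, ss_t),
        sigma2 = c(sigma_a, sigma_w, tot),
        pct = 100 * c(sigma_a, sigma_w, tot) / tot,
        stringsAsFactors = FALSE),
      phi = c(Phi_ST = sigma_a / tot)))
  }
  grp <- as.character(grp)
  pop2grp <- tapply(grp, pop, function(x) unique(x))
  if (any(lengths(pop2grp) != 1L)) {
    stop("every population must belong to exactly one group", call. = FALSE)
  }
  groups <- sort(unique(grp))
  G <- length(groups)
  if (G < 2L) stop("need at least 2 groups for a three-level AMOVA",
                   call. = FALSE)
  singles <- names(which(table(unlist(pop2grp)) == 1L))
  if (length(singles)) {
    warning("group(s) with a single population contribute no ",
            "among-population d.f.: ", paste(singles, collapse = ", "))
  }
  ss_wg <- sum(vapply(groups, function(gg) ss_among_units(which(grp == gg)),
                      numeric(1)))
  ss_ap <- ss_wg - ss_wp
  ss_ag <- ss_t - ss_wg
  N_g <- as.numeric(table(grp)[groups])
  df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
  sum_np2_by_grp <- vapply(groups, function(gg) {
    pg <- pops[vapply(pops, function(p) pop2grp[[p]] == gg, logical(1))]
    sum(n_p[match(pg, pops)]^2)
  }, numeric(1))
  n_coef  <- (N - sum(sum_np2_by_grp / N_g)) / df_ap
  np_coef <- (sum(sum_np2_by_grp / N_g) - sum(n_p^2) / N) / df_ag
  npp_coef <- (N - sum(N_g^2) / N) / df_ag
  ms_wp <- ss_wp / df_wp
  ms_ap <- if (df_ap > 0) ss_ap / df_ap else NA_real_
  ms_ag <- ss_ag / df_ag
  sigma_c <- ms_wp
  sigma_b <- if (df_ap > 0) (ms_ap - sigma_c) / n_coef else 0
  sigma_a <- (ms_ag - sigma_c - np_coef * sigma_b) / npp_coef
  tot <- sigma_a + sigma_b + sigma_c
  list(
    table = data.frame(
      source = c("Among groups", "Among populations within groups",
                 "Within populations", "Total"),
      df = c(df_ag, df_ap, df_wp, N - 1),
      SS = c(ss_ag, ss_ap, ss_wp, ss_t),
      sigma2 = c(sigma_a, sigma_b, sigma_c, tot),
      pct = 100 * c(sigma_a, sigma_b, sigma_c, tot) / tot,
      stringsAsFactors = FALSE),
    phi = c(Phi_CT = sigma_a / tot,
            Phi_SC = sigma_b / (sigma_b + sigma_c),
            Phi_ST = (sigma_a + sigma_b) / tot))
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions allele-level squared mismatch distances (each diploid
#' individual contributes two haplotypes) into variance components: among
#' groups, among populations within groups, and within populations, with
#' Phi statistics and permutation p-values. With \code{groups = NULL} a
#' two-level decomposition (among / within populations) is returned.
#'
#' Permutation schemes follow the standard design: Phi_ST permutes
#' individuals across everything; Phi_SC permutes individuals across
#' populations within their group; Phi_CT permutes whole populations across
#' groups.
#'
#' @param g A \code{genotype_matrix}.
#' @param populations Metadata column name or label vector: population of
#'   each individual.
#' @param groups Optional metadata column name or label vector: group of
#'   each individual (must be constant within population).
#' @param permutations Number of permutations for each Phi statistic.
#' @param seed RNG seed.
#' @return An \code{"amova_result"}: \code{table} (source, df, SS, variance
#'   component, % variation), \code{phi}, \code{p_value}, \code{permutations}.
#' @export
hierarchical_amova <- function(g, populations, groups = NULL,
                               permutations = 999, seed = 1L) {
  pop_i <- resolve_grouping(g, populations)
  grp_i <- if (is.null(groups)) NULL else resolve_grouping(g, groups)
  H <- haplotype_matrix(g)
  D2 <- hap_sq_distance(H)
  n_ind <- nrow(g$dosage)
  pop_u <- rep(pop_i, each = 2)
  grp_u <- if (is.null(grp_i)) NULL else rep(grp_i, each = 2)
  obs <- amova_decompose(D2, pop_u, grp_u)
  pvals <- rep(NA_real_, length(obs$phi))
  names(pvals) <- names(obs$phi)
  if (permutations > 0) local_rng(seed, {
    hits <- stats::setNames(integer(length(obs$phi)), names(obs$phi))
    unit_idx <- function(ind_perm) {       # individual -> its 2 haplotypes
      as.vector(rbind(2 * ind_perm - 1, 2 * ind_perm))
    }
    for (b in seq_len(permutations)) {
      # Phi_ST: individuals across everything
      perm <- sample.int(n_ind)
      dec <- suppressWarnings(
        amova_decompose(D2[unit_idx(perm), unit_idx(perm)], pop_u, grp_u))
      if (isTRUE(dec$phi[["Phi_ST"]] >= obs$phi[["Phi_ST"]])) {
        hits["Phi_ST"] <- hits["Phi_ST"] + 1L
      }
      if (!is.null(grp_i)) {
        # Phi_SC: individuals across populations within groups
        perm2 <- seq_len(n_ind)
        for (gg in unique(grp_i)) {
          w <- which(grp_i == gg)
          perm2[w] <- w[sample.int(length(w))]
        }
        dec2 <- suppressWarnings(
          amova_decompose(D2[unit_idx(perm2), unit_idx(perm2)], pop_u, grp_u))
        if (isTRUE(dec2$phi[["Phi_SC"]] >= obs$phi[["Phi_SC"]])) {
          hits["Phi_SC"] <- hits["Phi_SC"] + 1L
        }
        # Phi_CT: whole populations across groups
        pops <- unique(pop_i)
        grp_of_pop <- vapply(pops, function(p)
          grp_i[match(p, pop_i)], character(1))
        shuffled <- sample(grp_of_pop)
        grp_perm <- rep(shuffled[match(pop_i, pops)], each = 2)
        dec3 <- suppressWarnings(
          tryCatch(amova_decompose(D2, pop_u, grp_perm),
                   error = function(e) NULL))
        if (!is.null(dec3) && isTRUE(dec3$phi[["Phi_CT"]] >= obs$phi[["Phi_CT"]])) {
          hits["Phi_CT"] <- hits["Phi_CT"] + 1L
        }
      }
    }
    pvals <- (1 + hits) / (permutations + 1)
  })
  structure(list(table = obs$table, phi = obs$phi, p_value = pvals,
                 permutations = permutations),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, digits = 4, ...) {
  cat("Analysis of molecular variance\n")
  tab <- x$table
  tab$SS <- round(tab$SS, 2); tab$sigma2 <- round(tab$sigma2, digits)
  tab$pct <- round(tab$pct, 2)
  names(tab) <- c("Source of variation", "d.f.", "SS",
                  "Variance component", "% variation")
  print(tab, row.names = FALSE)
  cat("\nPhi statistics:\n")
  for (nm in names(x$phi)) {
    cat(sprintf("  %s = %.4f (p = %s)\n", nm, x$phi[nm],
                ifelse(is.na(x$p_value[nm]), "NA",
                       format(x$p_value[nm], digits = 3))))
  }
  invisible(x)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d A \code{dist} or symmetric matrix.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_phylip_dist <- function(d, path) {
  m <- as_distance_matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(formatC(rownames(m)[i], width = -10),
                     paste(sprintf("%.6f", m[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
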