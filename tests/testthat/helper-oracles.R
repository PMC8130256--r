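# Independent brute-force implementations used as oracles. These are written
# from first principles with plain loops, deliberately sharing no code with
# the package internals.

# All 0-based cut positions of an enzyme on a sequence, by sliding-window
# IUPAC comparison. Non-ACGT genome characters never match.
naive_cut_sites <- function(seq_chr, enzyme) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  chars <- strsplit(toupper(seq_chr), "")[[1]]
  motif <- strsplit(enzyme$site, "")[[1]]
  w <- length(motif)
  hits <- integer(0)
  if (length(chars) >= w) {
    for (s in 0:(length(chars) - w)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        cc <- chars[s + j]
        if (!(cc %in% c("A", "C", "G", "T")) ||
            !(cc %in% iupac[[motif[j]]])) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, s + enzyme$cut_offset)
    }
  }
  sort(unique(hits))
}

# Allele-mismatch distance between two dosage vectors, pairwise-complete.
naive_pair_distance <- function(a, b) {
  both <- !is.na(a) & !is.na(b)
  sum(abs(a[both] - b[both])) / (2 * sum(both))
}

# Two- or three-level AMOVA variance components recomputed from a squared
# distance matrix with explicit double sums (Excoffier-style).
naive_amova <- function(D2, pop, grp = NULL) {
  N <- nrow(D2)
  ss <- function(idx) {
    acc <- 0
    for (i in idx) for (j in idx) acc <- acc + D2[i, j]
    acc / (2 * length(idx))
  }
  pops <- sort(unique(pop))
  P <- length(pops)
  n_p <- sapply(pops, function(p) sum(pop == p))
  ss_t <- ss(seq_len(N))
  ss_wp <- sum(sapply(pops, function(p) ss(which(pop == p))))
  if (is.null(grp)) {
    ss_a <- ss_t - ss_wp
    ms_a <- ss_a / (P - 1); ms_w <- ss_wp / (N - P)
    n_c <- (N - sum(n_p^2) / N) / (P - 1)
    sigma_w <- ms_w
    sigma_a <- (ms_a - ms_w) / n_c
    return(c(sigma_a = sigma_a, sigma_w = sigma_w))
  }
  groups <- sort(unique(grp))
  G <- length(groups)
  grp_of_pop <- sapply(pops, function(p) unique(grp[pop == p]))
  N_g <- sapply(groups, function(gg) sum(grp == gg))
  ss_wg <- sum(sapply(groups, function(gg) ss(which(grp == gg))))
  ss_ap <- ss_wg - ss_wp
  ss_ag <- ss_t - ss_wg
  sum_np2_over_Ng <- sum(sapply(groups, function(gg) {
    sum(n_p[grp_of_pop == gg]^2) / N_g[groups == gg]
  }))
  n_coef <- (N - sum_np2_over_Ng) / (P - G)
  np_coef <- (sum_np2_over_Ng - sum(n_p^2) / N) / (G - 1)
  npp_coef <- (N - sum(N_g^2) / N) / (G - 1)
  ms_wp <- ss_wp / (N - P)
  ms_ap <- ss_ap / (P - G)
  ms_ag <- ss_ag / (G - 1)
  sigma_c <- ms_wp
  sigma_b <- (ms_ap - sigma_c) / n_coef
  sigma_a <- (ms_ag - sigma_c - np_coef * sigma_b) / npp_coef
  c(sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c)
}

# An edge (u, v) of weight w belongs to some minimum spanning tree iff u and
# v lie in different components of the graph restricted to strictly lighter
# edges (cycle/cut property). The union over all edges is the minimum
# spanning network.
naive_msn_edges <- function(m) {
  n <- nrow(m)
  comp_lighter <- function(w) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (m[i, j] < w) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
    sapply(seq_len(n), find)
  }
  out <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cc <- comp_lighter(m[i, j])
    if (cc[i] != cc[j]) {
      out <- rbind(out, data.frame(from = rownames(m)[i],
                                   to = rownames(m)[j],
                                   weight = m[i, j],
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$from, out$to), , drop = FALSE]
}

# Canonical string form of an edge set for comparison.
edge_key <- function(edges) {
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  sort(paste(a, b, sep = "|"))
}

# Canonical string form of a split (side not containing taxon 1).
split_key <- function(split, n) {
  s <- sort(split)
  if (1 %in% s) s <- sort(setdiff(seq_len(n), s))
  paste(s, collapse = ",")
}

# Root-mean-square error between an estimated and a true Q matrix, minimised
# over column permutations (cluster labels are arbitrary).
q_rmse <- function(Q_hat, Q_true) {
  K <- ncol(Q_true)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(K))) {
    err <- sqrt(mean((Q_hat[, p, drop = FALSE] - Q_true)^2))
    if (err < best) best <- err
  }
  best
}

# Small deterministic genotype matrix used across the QC tests.
toy_genotypes <- function() {
  dos <- rbind(
    s1 = c(0L, 1L, 2L, 0L, 1L, NA),
    s2 = c(0L, 0L, 2L, 1L, NA, 1L),
    s3 = c(1L, 0L, 1L, 2L, 0L, 0L),
    s4 = c(2L, NA, 0L, 1L, 0L, 0L)
  )
  loci <- data.frame(scaffold = c("c1", "c1", "c2", "c2", "c3", "c3"),
                     pos = c(10L, 90L, 5L, 55L, 7L, 70L),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = rownames(dos),
                     country = c("x", "x", "y", "y"),
                     stringsAsFactors = FALSE)
  genotype_matrix(dos, loci, meta)
}
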