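# Genotype PCA and maximum-likelihood admixture clustering.

#' Genotype principal component analysis
#'
#' Monomorphic loci are dropped (with a warning), missing entries are
#' mean-imputed per locus, columns are centred by \eqn{2\hat p} and scaled
#' by \eqn{\sqrt{2\hat p(1-\hat p)}} (Patterson normalisation), and sample
#' coordinates come from the singular value decomposition of the normalised
#' matrix. Variance explained is each squared singular value's share of the
#' total.
#'
#' @param g A \code{genotype_matrix}.
#' @param m Number of components to keep.
#' @return A \code{"pca_result"}: \code{scores} (samples x m),
#'   \code{var_explained} (percent, non-increasing), \code{loci_used}.
#' @export
snp_pca <- function(g, m = 10) {
  X <- g$dosage
  storage.mode(X) <- "double"
  p_hat <- colMeans(X, na.rm = TRUE) / 2
  poly <- !is.na(p_hat) & p_hat > 0 & p_hat < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic or all-missing locus/loci dropped")
    X <- X[, poly, drop = FALSE]
    p_hat <- p_hat[poly]
  }
  if (ncol(X) == 0L) stop("no polymorphic loci for PCA", call. = FALSE)
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- 2 * p_hat[j]
  }
  Z <- sweep(X, 2, 2 * p_hat, "-")
  Z <- sweep(Z, 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  max_m <- min(dim(Z)) - 1L
  if (m > max_m) {
    warning("m truncated to ", max_m)
    m <- max_m
  }
  s <- svd(Z, nu = m, nv = 0)
  scores <- s$u %*% diag(s$d[seq_len(m)], m, m)
  rownames(scores) <- rownames(g$dosage)
  colnames(scores) <- paste0("PC", seq_len(m))
  structure(list(scores = scores,
                 var_explained = 100 * s$d[seq_len(m)]^2 / sum(s$d^2),
                 loci_used = colnames(g$dosage)[poly]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("Genotype PCA: %d samples, %d loci, %d components\n",
              nrow(x$scores), length(x$loci_used), ncol(x$scores)))
  cat("variance explained (%):",
      paste(sprintf("%.1f", utils::head(x$var_explained, 5)),
            collapse = ", "),
      if (length(x$var_explained) > 5) "..." else "", "\n")
  invisible(x)
}

#' @export
plot.pca_result <- function(x, components = c(1, 2), labels = NULL, ...) {
  xy <- x$scores[, components, drop = FALSE]
  col <- if (is.null(labels)) 1 else as.integer(factor(labels))
  plot(xy, col = col, pch = 19,
       xlab = sprintf("PC%d (%.1f%%)", components[1],
                      x$var_explained[components[1]]),
       ylab = sprintf("PC%d (%.1f%%)", components[2],
                      x$var_explained[components[2]]), ...)
  invisible(x)
}

# Log-likelihood of dosages under the admixture model (binomial kernel
# without the constant choose(2, g) term); missing entries contribute 0.
admix_loglik <- function(G, Theta) {
  ll <- G * log(Theta) + (2 - G) * log1p(-Theta)
  sum(ll[!is.na(G)])
}

P_EPS <- 1e-6

em_once <- function(G, K, q0, p0, tol, max_iter) {
  N <- nrow(G); L <- ncol(G)
  Q <- q0; P <- p0
  M <- !is.na(G)
  G0 <- G; G0[!M] <- 0
  G2 <- 2 - G; G2[!M] <- 0
  n_called2 <- 2 * rowSums(M)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    Theta <- Q %*% P
    Theta <- pmin(pmax(Theta, P_EPS), 1 - P_EPS)
    RA <- G0 / Theta          # alt-allele responsibility scale
    RB <- G2 / (1 - Theta)    # ref-allele responsibility scale
    Anum_q <- matrix(0, N, K)
    Asum_p <- Bsum_p <- matrix(0, K, L)
    for (k in seq_len(K)) {
      a_k <- RA * (Q[, k] %o% P[k, ])        # expected alt copies from k
      b_k <- RB * (Q[, k] %o% (1 - P[k, ]))  # expected ref copies from k
      Anum_q[, k] <- rowSums(a_k) + rowSums(b_k)
      Asum_p[k, ] <- colSums(a_k)
      Bsum_p[k, ] <- colSums(b_k)
    }
    Q <- Anum_q / n_called2
    Q <- Q / rowSums(Q)
    denom <- Asum_p + Bsum_p
    P <- ifelse(denom > 0, Asum_p / denom, P)
    P <- pmin(pmax(P, P_EPS), 1 - P_EPS)
    Theta <- pmin(pmax(Q %*% P, P_EPS), 1 - P_EPS)
    ll <- admix_loglik(G, Theta)
    ll_trace <- c(ll_trace, ll)
    if (!is.finite(ll)) {
      bad <- which(colSums(!is.finite(log(Theta))) > 0)[1]
      stop("non-finite likelihood at locus ", colnames(G)[bad],
           call. = FALSE)
    }
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) break
    ll_old <- ll
  }
  list(Q = Q, P = P, loglik = ll, iterations = length(ll_trace),
       loglik_trace = ll_trace)
}

#' Fit the admixture model by expectation-maximisation
#'
#' Maximum-likelihood estimation of ancestry proportions Q (samples x K)
#' and cluster allele frequencies P (K x loci) under the standard admixture
#' model: dosage \eqn{g_{il} \sim Binomial(2, \theta_{il})} with
#' \eqn{\theta_{il} = \sum_k q_{ik} p_{kl}}. EM on the complete-data
#' decomposition; missing genotypes contribute nothing to the likelihood.
#' The best of \code{restarts} random initialisations is returned.
#'
#' @param g A \code{genotype_matrix}.
#' @param K Number of ancestral clusters (>= 1).
#' @param seed RNG seed for the restarts.
#' @param tol Relative log-likelihood change at which EM stops.
#' @param max_iter Iteration cap per restart.
#' @param restarts Number of random initialisations.
#' @return An \code{"admixture_fit"}: \code{K}, \code{Q}, \code{P},
#'   \code{loglik}, \code{loglik_trace}, \code{iterations}, \code{seed}.
#' @export
admixture_em_fit <- function(g, K, seed = 1L, tol = 1e-6, max_iter = 2000,
                             restarts = 10) {
  stopifnot(K >= 1)
  G <- g$dosage
  storage.mode(G) <- "double"
  fully_missing <- colSums(!is.na(G)) == 0
  if (any(fully_missing)) {
    stop("locus/loci fully missing: ",
         paste(utils::head(colnames(G)[fully_missing], 5), collapse = ", "),
         call. = FALSE)
  }
  N <- nrow(G); L <- ncol(G)
  p_hat <- pmin(pmax(colMeans(G, na.rm = TRUE) / 2, P_EPS), 1 - P_EPS)
  if (K == 1L) {
    # analytic optimum: q == 1, p = overall allele frequencies
    Q <- matrix(1, N, 1, dimnames = list(rownames(G), "K1"))
    P <- matrix(p_hat, 1, L, dimnames = list("K1", colnames(G)))
    Theta <- pmin(pmax(Q %*% P, P_EPS), 1 - P_EPS)
    return(structure(list(K = 1L, Q = Q, P = P,
                          loglik = admix_loglik(G, Theta),
                          loglik_trace = admix_loglik(G, Theta),
                          iterations = 0L, seed = seed),
                     class = "admixture_fit"))
  }
  best <- NULL
  local_rng(seed, {
    for (r in seq_len(restarts)) {
      q0 <- matrix(stats::rgamma(N * K, 1), N, K)
      q0 <- q0 / rowSums(q0)
      p0 <- matrix(pmin(pmax(
        rep(p_hat, each = K) + stats::rnorm(K * L, 0, 0.1),
        P_EPS), 1 - P_EPS), K, L)
      fit <- em_once(G, K, q0, p0, tol, max_iter)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  dimnames(best$Q) <- list(rownames(G), paste0("K", seq_len(K)))
  dimnames(best$P) <- list(paste0("K", seq_len(K)), colnames(G))
  structure(c(best[c("Q", "P", "loglik", "loglik_trace", "iterations")],
              list(K = as.integer(K), seed = seed)),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("Admixture model fit: K = %d, %d samples, %d loci\n",
              x$K, nrow(x$Q), ncol(x$P)))
  cat(sprintf("log-likelihood %.2f after %d EM iteration(s)\n",
              x$loglik, x$iterations))
  invisible(x)
}

#' @export
plot.admixture_fit <- function(x, labels = NULL, ...) {
  o <- if (is.null(labels)) seq_len(nrow(x$Q)) else order(labels)
  graphics::barplot(t(x$Q[o, , drop = FALSE]), col = seq_len(x$K) + 1,
                    border = NA, space = 0, las = 2,
                    ylab = "ancestry proportion", ...)
  invisible(x)
}

#' Choose the number of clusters by held-out cross-validation
#'
#' Randomly partitions the non-missing genotype entries into \code{folds}
#' folds; for each fold and each candidate K, the fold is masked, the
#' admixture model is fitted to the rest, and the binomial deviance
#' \eqn{-2\sum [g \log\hat\theta + (2-g)\log(1-\hat\theta)]} is scored on
#' the held-out entries. The chosen K minimises the mean held-out deviance;
#' ties break toward smaller K.
#'
#' @param g A \code{genotype_matrix}.
#' @param K_range Candidate K values.
#' @param folds Number of cross-validation folds.
#' @param seed RNG seed (masking and EM restarts).
#' @param restarts,tol,max_iter EM settings for the fold fits.
#' @return A \code{"k_selection"}: data frame \code{criterion}
#'   (K, mean_deviance), \code{chosen_k}.
#' @export
choose_k <- function(g, K_range = 1:5, folds = 3, seed = 1L,
                     restarts = 3, tol = 1e-5, max_iter = 500) {
  stopifnot(length(K_range) >= 1)
  G <- g$dosage
  obs_idx <- which(!is.na(G))
  dev <- matrix(NA_real_, length(K_range), folds)
  local_rng(seed, {
    for (f in seq_len(folds)) {
      # draw a mask that leaves no locus (or sample) empty; bounded retries
      for (try in 1:20) {
        fold_idx <- sample(obs_idx, length(obs_idx) %/% folds)
        Gtrain <- G
        Gtrain[fold_idx] <- NA
        if (all(colSums(!is.na(Gtrain)) > 0) &&
            all(rowSums(!is.na(Gtrain)) > 0)) break
        if (try == 20) stop("could not draw a valid cross-validation mask",
                            call. = FALSE)
      }
      gtrain <- g
      gtrain$dosage <- Gtrain
      for (ki in seq_along(K_range)) {
        fit <- admixture_em_fit(gtrain, K_range[ki],
                                seed = sample.int(1e6, 1), tol = tol,
                                max_iter = max_iter, restarts = restarts)
        Theta <- pmin(pmax(fit$Q %*% fit$P, P_EPS), 1 - P_EPS)
        gh <- G[fold_idx]; th <- Theta[fold_idx]
        dev[ki, f] <- -2 * sum(gh * log(th) + (2 - gh) * log1p(-th))
      }
    }
  })
  crit <- data.frame(K = K_range, mean_deviance = rowMeans(dev))
  chosen <- crit$K[which.min(crit$mean_deviance)]  # first min: smallest K
  structure(list(criterion = crit, chosen_k = chosen, folds = folds,
                 seed = seed),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Cross-validated choice of K (held-out binomial deviance):\n")
  print(x$criterion, row.names = FALSE)
  cat("chosen K =", x$chosen_k, "\n")
  invisible(x)
}

#' Summarise admixture ancestry by group
#'
#' @param fit An \code{admixture_fit}.
#' @param grouping Vector of group labels over the fitted samples (or a
#'   metadata column name if \code{g} is given).
#' @param g Optional \code{genotype_matrix} to resolve \code{grouping}.
#' @return Data frame: one row per group with mean ancestry per cluster,
#'   the modal cluster, and a \code{tie} flag when the modal ancestry is
#'   not unique.
#' @export
cluster_memberships <- function(fit, grouping, g = NULL) {
  labels <- if (!is.null(g)) resolve_grouping(g, grouping)
  else as.character(grouping)
  if (length(labels) != nrow(fit$Q)) {
    stop("grouping must give one label per fitted sample", call. = FALSE)
  }
  groups <- sort(unique(labels))
  meanq <- do.call(rbind, lapply(groups, function(grp)
    colMeans(fit$Q[labels == grp, , drop = FALSE])))
  modal <- lapply(seq_len(nrow(meanq)), function(i)
    which(meanq[i, ] == max(meanq[i, ])))
  tie <- vapply(modal, length, integer(1)) > 1
  out <- data.frame(group = groups, meanq,
                    modal_cluster = vapply(modal, `[`, integer(1), 1),
                    tie = tie, stringsAsFactors = FALSE, row.names = NULL)
  names(out)[seq_len(fit$K) + 1] <- paste0("mean_Q", seq_len(fit$K))
  out
}
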