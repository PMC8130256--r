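# Synthetic data with exposed ground truth: Balding-Nichols genotype
# matrices and genomes with planted restriction sites.

#' Simulate structured genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn Uniform(0.05, 0.95) (avoiding
#' near-fixed loci that destabilise the Beta sampling); population
#' frequencies follow the Balding-Nichols distribution
#' \eqn{p_{kl} \sim Beta(p_l(1-F_k)/F_k, (1-p_l)(1-F_k)/F_k)}, whose
#' divergence parameter F equals the expected Fst against the ancestral
#' pool. Individual dosages are Binomial(2, \eqn{\sum_k q_{ik} p_{kl}})
#' given the admixture proportions Q, and entries are masked missing
#' completely at random.
#'
#' @param n_pops Number of ancestral populations K.
#' @param fst Divergence F per population, recycled to length K; each in
#'   (0, 1).
#' @param n_per_pop Diploid sample size per population (recycled). Ignored
#'   when \code{Q} is supplied.
#' @param n_loci Number of biallelic loci.
#' @param Q Optional true admixture matrix (individuals x K, rows summing
#'   to 1); by default individuals are unadmixed members of their
#'   population.
#' @param missing_rate Fraction of entries masked missing, in [0, 1).
#' @param seed RNG seed; same seed, same output.
#' @return A list: \code{genotypes} (a \code{genotype_matrix} whose
#'   metadata carries the source population as \code{country} and
#'   \code{population}) and \code{truth} (\code{p_ancestral}, \code{p_pop}
#'   K x loci, \code{Q}, \code{fst}).
#' @export
sim_genotypes <- function(n_pops = 2, fst = 0.1, n_per_pop = 50,
                          n_loci = 1000, Q = NULL, missing_rate = 0,
                          seed = 1L) {
  stopifnot(n_pops >= 1, n_loci >= 1)
  fst <- rep_len(fst, n_pops)
  if (any(fst <= 0 | fst >= 1)) stop("fst values must lie in (0, 1)",
                                     call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(Q)) {
    n_per_pop <- rep_len(n_per_pop, n_pops)
    Q <- matrix(0, sum(n_per_pop), n_pops)
    pop_of <- rep(seq_len(n_pops), n_per_pop)
    Q[cbind(seq_len(nrow(Q)), pop_of)] <- 1
  } else {
    Q <- as.matrix(Q)
    if (ncol(Q) != n_pops) stop("Q must have n_pops columns", call. = FALSE)
    if (max(abs(rowSums(Q) - 1)) > 1e-8) {
      stop("Q rows must sum to 1", call. = FALSE)
    }
    pop_of <- apply(Q, 1, which.max)
  }
  N <- nrow(Q)
  local_rng(seed, {
    p_anc <- stats::runif(n_loci, 0.05, 0.95)
    p_pop <- matrix(NA_real_, n_pops, n_loci)
    for (k in seq_len(n_pops)) {
      shape_scale <- (1 - fst[k]) / fst[k]
      p_pop[k, ] <- stats::rbeta(n_loci, p_anc * shape_scale,
                                 (1 - p_anc) * shape_scale)
    }
    theta <- Q %*% p_pop
    dosage <- matrix(stats::rbinom(N * n_loci, 2, as.vector(theta)),
                     N, n_loci)
    if (missing_rate > 0) {
      dosage[stats::runif(N * n_loci) < missing_rate] <- NA_integer_
    }
    rownames(dosage) <- sprintf("ind%03d", seq_len(N))
    loci <- data.frame(scaffold = paste0("scf",
                                         rep(seq_len(max(1, n_loci %/% 4 + 1)),
                                             each = 4, length.out = n_loci)),
                       pos = rep_len(seq(100, by = 150, length.out = 4),
                                     n_loci) +
                         1000 * (seq_len(n_loci) - 1) %/% 4,
                       ref = "A", alt = "T", stringsAsFactors = FALSE)
    meta <- data.frame(sample_id = rownames(dosage),
                       country = paste0("pop", pop_of),
                       population = paste0("pop", pop_of),
                       locality = paste0("loc", pop_of),
                       stringsAsFactors = FALSE)
    g <- genotype_matrix(dosage, loci, meta)
    rownames(Q) <- rownames(dosage)
    list(genotypes = g,
         truth = list(p_ancestral = p_anc, p_pop = p_pop, Q = Q, fst = fst))
  })
}

#' Simulate a genome with planted restriction sites
#'
#' Background sequence is drawn from the given base composition; any
#' accidental occurrence of a target enzyme's motif is rewritten until the
#' planted positions are the only occurrences. The returned truth bundle
#' lists, for any pair of the involved enzymes, the exact cut positions and
#' fragment lengths the digest must produce.
#'
#' @param scaffold_lengths Integer vector of scaffold lengths (bp).
#' @param sites Named list: for each enzyme name (looked up in
#'   \code{catalogue}), a list with one integer vector of planted 0-based
#'   motif start positions per scaffold. Motifs must fit inside their
#'   scaffold and must not overlap each other.
#' @param gc Background GC content in (0, 1).
#' @param catalogue Enzyme catalogue; defaults to [enzyme_catalogue()].
#' @param seed RNG seed.
#' @return A list: \code{genome} (\code{Biostrings::DNAStringSet}),
#'   \code{truth} with \code{site_starts}, \code{cut_positions} (per enzyme
#'   per scaffold) and \code{fragments(e1, e2)} — a function returning the
#'   ground-truth fragment-length vector per scaffold for an enzyme pair.
#' @export
sim_genome <- function(scaffold_lengths = 10000, sites,
                       gc = 0.42, catalogue = enzyme_catalogue(),
                       seed = 1L) {
  stopifnot(all(scaffold_lengths >= 10), gc > 0, gc < 1)
  enz_names <- names(sites)
  if (is.null(enz_names) || any(!nzchar(enz_names))) {
    stop("sites must be a named list keyed by enzyme name", call. = FALSE)
  }
  missing <- setdiff(enz_names, names(catalogue))
  if (length(missing)) stop("unknown enzyme(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  enz <- catalogue[enz_names]
  n_scf <- length(scaffold_lengths)
  sites <- lapply(sites, function(s) {
    if (!is.list(s)) s <- list(s)
    if (length(s) != n_scf) s <- rep_len(s, n_scf)
    lapply(s, as.integer)
  })
  # occupancy check: planted motifs must not overlap and must fit
  for (i in seq_len(n_scf)) {
    iv <- do.call(rbind, lapply(enz_names, function(nm) {
      st <- sites[[nm]][[i]]
      if (length(st) == 0) return(NULL)
      w <- nchar(enz[[nm]]$site)
      if (any(st < 0 | st + w > scaffold_lengths[i])) {
        stop("planted site outside scaffold ", i, " for ", nm,
             call. = FALSE)
      }
      cbind(start = st, end = st + w)
    }))
    if (!is.null(iv) && nrow(iv) > 1) {
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] < iv[-nrow(iv), 2])) {
        stop("planted sites overlap on scaffold ", i, call. = FALSE)
      }
    }
  }
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  local_rng(seed, {
    seqs <- character(n_scf)
    for (i in seq_len(n_scf)) {
      len <- scaffold_lengths[i]
      chars <- sample(names(probs), len, replace = TRUE, prob = probs)
      planted <- lapply(enz_names, function(nm) sites[[nm]][[i]])
      names(planted) <- enz_names
      protected <- unlist(lapply(enz_names, function(nm) {
        st <- planted[[nm]]
        if (!length(st)) return(integer(0))
        w <- nchar(enz[[nm]]$site)
        unlist(lapply(st, function(s) (s + 1):(s + w)))
      }))
      # write the planted motifs (ambiguity codes resolved at random)
      for (nm in enz_names) {
        motif <- strsplit(enz[[nm]]$site, "")[[1]]
        concrete <- vapply(motif, function(cc) {
          opts <- switch(cc, A = "A", C = "C", G = "G", T = "T",
                         W = c("A", "T"), S = c("C", "G"),
                         R = c("A", "G"), Y = c("C", "T"),
                         K = c("G", "T"), M = c("A", "C"),
                         c("A", "C", "G", "T"))
          if (length(opts) == 1) opts else sample(opts, 1)
        }, character(1))
        for (s in planted[[nm]]) chars[(s + 1):(s + length(motif))] <- concrete
      }
      # scrub accidental motif occurrences outside the planted windows
      for (pass in 1:50) {
        seq_chr <- paste(chars, collapse = "")
        dirty <- FALSE
        for (nm in enz_names) {
          w <- nchar(enz[[nm]]$site)
          hits <- Biostrings::start(Biostrings::matchPattern(
            enz[[nm]]$site, Biostrings::DNAString(seq_chr),
            fixed = "subject")) - 1L
          rogue <- setdiff(hits, planted[[nm]])
          for (s in rogue) {
            pos <- setdiff((s + 1):(s + w), protected)
            if (!length(pos)) {
              stop("planted layout too dense to scrub accidental sites",
                   call. = FALSE)
            }
            j <- pos[sample.int(length(pos), 1)]
            chars[j] <- sample(setdiff(names(probs), chars[j]), 1)
            dirty <- TRUE
          }
        }
        if (!dirty) break
        if (pass == 50) stop("failed to scrub accidental sites",
                             call. = FALSE)
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- sprintf("scaffold%02d", seq_len(n_scf))
    cut_positions <- lapply(enz_names, function(nm) {
      lapply(seq_len(n_scf), function(i)
        sort(sites[[nm]][[i]] + enz[[nm]]$cut_offset))
    })
    names(cut_positions) <- enz_names
    fragments <- function(e1, e2) {
      lapply(seq_len(n_scf), function(i) {
        cuts <- sort(unique(c(cut_positions[[e1]][[i]],
                              cut_positions[[e2]][[i]])))
        cuts <- cuts[cuts > 0 & cuts < scaffold_lengths[i]]
        diff(c(0L, cuts, scaffold_lengths[i]))
      })
    }
    list(genome = genome,
         truth = list(site_starts = sites, cut_positions = cut_positions,
                      fragments = fragments))
  })
}
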