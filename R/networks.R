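# Minimum spanning networks, NeighborNet split networks and neighbor joining.

#' Minimum spanning network over a distance matrix
#'
#' Kruskal-style construction that, at each distance level, adds *every*
#' edge of that weight joining two previously disconnected components.
#' Retaining all tie edges makes the result the union of all minimum
#' spanning trees, so reticulations caused by equal distances are kept.
#'
#' @param d A \code{dist} or symmetric non-negative matrix.
#' @return An \code{"msn_graph"}: \code{labels} and an edge data frame
#'   (\code{from}, \code{to}, \code{weight}); every edge belongs to at
#'   least one minimum spanning tree.
#' @export
minimum_spanning_network <- function(d) {
  m <- as_distance_matrix(d)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  iu <- which(upper.tri(m), arr.ind = TRUE)
  edges <- data.frame(from = iu[, 1], to = iu[, 2],
                      weight = m[upper.tri(m)])
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  keep <- logical(nrow(edges))
  for (w in sort(unique(edges$weight))) {
    lev <- which(edges$weight == w)
    # decide against the components as they stood before this level
    roots_from <- vapply(edges$from[lev], find, integer(1))
    roots_to <- vapply(edges$to[lev], find, integer(1))
    keep[lev] <- roots_from != roots_to
    for (e in lev[keep[lev]]) {
      ra <- find(edges$from[e]); rb <- find(edges$to[e])
      if (ra != rb) parent[ra] <- rb
    }
  }
  out <- edges[keep, , drop = FALSE]
  out$from <- rownames(m)[out$from]
  out$to <- rownames(m)[out$to]
  rownames(out) <- NULL
  structure(list(labels = rownames(m), edges = out),
            class = "msn_graph")
}

#' @export
print.msn_graph <- function(x, ...) {
  cat(sprintf("Minimum spanning network: %d nodes, %d edges (MST needs %d)\n",
              length(x$labels), nrow(x$edges), length(x$labels) - 1))
  invisible(x)
}

#' Write a minimum spanning network as GraphML
#'
#' @param x An \code{msn_graph}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_msn_graphml <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
               '<key id="w" for="edge" attr.name="weight" attr.type="double"/>',
               '<graph edgedefault="undirected">'), con)
  for (lab in x$labels) {
    writeLines(sprintf('  <node id="%s"/>', lab), con)
  }
  for (i in seq_len(nrow(x$edges))) {
    writeLines(sprintf(
      '  <edge source="%s" target="%s"><data key="w">%.10g</data></edge>',
      x$edges$from[i], x$edges$to[i], x$edges$weight[i]), con)
  }
  writeLines(c("</graph>", "</graphml>"), con)
  invisible(path)
}

# --- NeighborNet ------------------------------------------------------------

# Agglomerative construction of a circular taxon ordering (Bryant-Moulton).
# Every partially assembled cluster is a linear chain of taxa; only its two
# end taxa stay "active" and carry reduced distances. Picking a pair of
# clusters uses the net-divergence-corrected average distance; picking which
# ends to link uses the analogous criterion over the member nodes; linking
# triggers the 3-point reduction that collapses a path x-y-z onto its outer
# nodes. The surviving chain, closed up, is the circular ordering.
nnet_ordering <- function(m) {
  n <- nrow(m)
  if (n <= 3L) return(seq_len(n))
  d <- unname(m)                 # working node distances (original indices)
  reduc3 <- function(d, x, y, z) {
    u <- (2 / 3) * d[x, ] + (1 / 3) * d[y, ]
    v <- (2 / 3) * d[z, ] + (1 / 3) * d[y, ]
    uv <- (d[x, y] + d[x, z] + d[y, z]) / 3
    d[x, ] <- d[, x] <- u
    d[z, ] <- d[, z] <- v
    d[y, ] <- d[, y] <- 0
    d[x, z] <- d[z, x] <- uv
    d[x, x] <- d[z, z] <- 0
    d
  }
  CL <- as.list(seq_len(n))      # active end-node ids (1 or 2 per cluster)
  ORD <- as.list(seq_len(n))     # ordered taxa of each chain
  while (length(CL) > 1L) {
    l <- length(CL)
    DM <- matrix(0, l, l)
    for (i in seq_len(l - 1)) for (j in (i + 1):l) {
      DM[i, j] <- DM[j, i] <- mean(d[CL[[i]], CL[[j]]])
    }
    if (l > 3L) {
      r <- rowSums(DM) / (l - 2)
      Qm <- DM - outer(r, r, "+")
      diag(Qm) <- Inf
      pick <- arrayInd(which.min(Qm), dim(Qm))
      e1 <- min(pick); e2 <- max(pick)
    } else {
      # with three clusters the adjusted criterion is the same constant,
      # -(D12 + D13 + D23), for every pair; with two there is no choice.
      # Use a fixed convention instead of letting round-off break the tie.
      e1 <- 1L; e2 <- 2L
    }
    A <- CL[[e1]]; B <- CL[[e2]]
    n1 <- length(A); n2 <- length(B)
    if (n1 == 1L && n2 == 1L) {
      CL[[e1]] <- c(A, B)
      ORD[[e1]] <- c(ORD[[e1]], ORD[[e2]])
    } else {
      # node-level selection: members of A and B individually, every other
      # cluster as an averaged unit
      others <- CL[-c(e1, e2)]
      nodes <- c(A, B)
      mhat <- length(nodes) + length(others)
      R <- vapply(nodes, function(x) {
        sum(d[x, setdiff(nodes, x)]) +
          sum(vapply(others, function(C) mean(d[x, C]), numeric(1)))
      }, numeric(1))
      score <- d[A, B, drop = FALSE] -
        outer(R[seq_len(n1)], R[n1 + seq_len(n2)], "+") / (mhat - 2)
      hit <- arrayInd(which.min(score), dim(score))
      ia <- hit[1]; ib <- hit[2]
      ordA <- ORD[[e1]]; if (n1 == 2L && ia == 1L) ordA <- rev(ordA)
      ordB <- ORD[[e2]]; if (n2 == 2L && ib == 2L) ordB <- rev(ordB)
      if (n1 == 2L && n2 == 1L) {
        xa <- A[3L - ia]
        d <- reduc3(d, xa, A[ia], B[1])
        CL[[e1]] <- c(xa, B[1])
      } else if (n1 == 1L && n2 == 2L) {
        zb <- B[3L - ib]
        d <- reduc3(d, A[1], B[ib], zb)
        CL[[e1]] <- c(A[1], zb)
      } else {
        xa <- A[3L - ia]; zb <- B[3L - ib]
        d <- reduc3(d, xa, A[ia], B[ib])
        d <- reduc3(d, xa, B[ib], zb)
        CL[[e1]] <- c(xa, zb)
      }
      ORD[[e1]] <- c(ordA, ordB)
    }
    CL <- CL[-e2]; ORD <- ORD[-e2]
  }
  ORD[[1]]
}

# All splits compatible with a circular ordering: contiguous arcs of the
# cycle that do not contain the first cycle position.
circular_splits <- function(cycle) {
  n <- length(cycle)
  out <- list()
  for (i in 2:n) for (j in i:n) {
    out[[length(out) + 1L]] <- sort(cycle[i:j])
  }
  out
}

#' NeighborNet split network
#'
#' Bryant-Moulton NeighborNet: an agglomerative pass with net-divergence
#' selection and 3-point reductions produces a circular ordering of the
#' taxa; the weights of all splits compatible with that ordering are then
#' estimated by non-negative least squares (active-set NNLS) against the
#' input distances, and splits whose weight falls below \code{prune} are
#' dropped.
#'
#' @param d A \code{dist} or symmetric non-negative matrix.
#' @param prune Weight threshold below which splits are removed.
#' @return A \code{"split_system"}: \code{taxa}, \code{cycle} (taxon index
#'   permutation), \code{splits} (list of integer vectors, one side of each
#'   bipartition), \code{weights}, and \code{residual} (Euclidean norm of
#'   the distance misfit).
#' @export
neighbor_net <- function(d, prune = 1e-8) {
  m <- as_distance_matrix(d)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  cycle <- if (n <= 3L) seq_len(n) else nnet_ordering(m)
  splits <- circular_splits(if (n >= 2) cycle else seq_len(n))
  npair <- n * (n - 1) / 2
  iu <- which(upper.tri(m), arr.ind = TRUE)
  A <- matrix(0, npair, length(splits))
  for (s in seq_along(splits)) {
    side <- logical(n)
    side[splits[[s]]] <- TRUE
    A[, s] <- side[iu[, 1]] != side[iu[, 2]]
  }
  dvec <- m[upper.tri(m)]
  w <- pracma::lsqnonneg(A, dvec)$x
  resid <- sqrt(sum((A %*% w - dvec)^2))
  keep <- w >= prune
  structure(list(taxa = rownames(m), cycle = cycle,
                 splits = splits[keep], weights = unname(w[keep]),
                 residual = resid),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  cat(sprintf("Split system on %d taxa: %d weighted splits, residual %.3g\n",
              length(x$taxa), length(x$splits), x$residual))
  cat("circular ordering:", paste(x$taxa[x$cycle], collapse = " "), "\n")
  invisible(x)
}

#' Pairwise distances induced by a split system
#'
#' Sum of weights of the splits separating each pair of taxa.
#'
#' @param s A \code{split_system}.
#' @return Symmetric matrix of induced distances.
#' @export
split_distances <- function(s) {
  n <- length(s$taxa)
  m <- matrix(0, n, n, dimnames = list(s$taxa, s$taxa))
  for (k in seq_along(s$splits)) {
    side <- logical(n)
    side[s$splits[[k]]] <- TRUE
    sep <- outer(side, side, "!=")
    m <- m + s$weights[k] * sep
  }
  m
}

# weight of the terminal (singleton) split of each taxon, 0 if absent
terminal_split_weights <- function(s) {
  w <- stats::setNames(numeric(length(s$taxa)), s$taxa)
  for (k in seq_along(s$splits)) {
    sp <- s$splits[[k]]
    n <- length(s$taxa)
    if (length(sp) == 1L) w[sp] <- w[sp] + s$weights[k]
    if (length(sp) == n - 1L) w[setdiff(seq_len(n), sp)] <-
        w[setdiff(seq_len(n), sp)] + s$weights[k]
  }
  w
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via \code{ape::nj}); serves as the
#' tree-based cross-check for [neighbor_net()] on tree-like distances.
#'
#' @param d A \code{dist} or symmetric matrix.
#' @param path Optional path: when given, the tree is also written in
#'   Newick format.
#' @return An \code{ape::phylo} tree.
#' @export
neighbor_joining <- function(d, path = NULL) {
  m <- as_distance_matrix(d)
  if (nrow(m) < 3L) stop("need at least 3 taxa", call. = FALSE)
  tr <- ape::nj(stats::as.dist(m))
  if (!is.null(path)) ape::write.tree(tr, path)
  tr
}

# Splits (as sorted taxon-index sides) of an unrooted ape tree, with branch
# lengths; trivial splits included.
tree_splits <- function(tr) {
  n <- length(tr$tip.label)
  desc <- function(node) {
    if (node <= n) return(node)
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    sort(unlist(lapply(kids, desc)))
  }
  out <- lapply(tr$edge[, 2], desc)
  # canonical side: the one not containing taxon 1
  canon <- lapply(out, function(s)
    if (1 %in% s) sort(setdiff(seq_len(n), s)) else sort(s))
  keep <- vapply(canon, function(s)
    length(s) >= 1 && length(s) <= n - 1, logical(1))
  list(splits = canon[keep], weights = tr$edge.length[keep])
}

# --- Nexus SPLITS IO --------------------------------------------------------

#' Write a split system as a Nexus SPLITS file
#'
#' Emits TAXA and SPLITS blocks (cycle plus weighted split lines) in the
#' format used by splits-graph viewers; [read_splits_nexus()] round-trips
#' the file.
#'
#' @param s A \code{split_system}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_splits_nexus <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(s$taxa)
  writeLines("#NEXUS", con)
  writeLines(c("", "BEGIN TAXA;",
               sprintf("DIMENSIONS NTAX=%d;", n), "TAXLABELS"), con)
  writeLines(sprintf("[%d] '%s'", seq_len(n), s$taxa), con)
  writeLines(c(";", "END;", "", "BEGIN SPLITS;",
               sprintf("DIMENSIONS NTAX=%d NSPLITS=%d;", n,
                       length(s$splits)),
               "FORMAT LABELS=NO WEIGHTS=YES;",
               paste("CYCLE", paste(s$cycle, collapse = " "), ";"),
               "MATRIX"), con)
  for (k in seq_along(s$splits)) {
    writeLines(sprintf("[%d, size=%d]\t%.10g\t%s,", k,
                       length(s$splits[[k]]), s$weights[k],
                       paste(s$splits[[k]], collapse = " ")), con)
  }
  writeLines(c(";", "END;"), con)
  invisible(path)
}

#' Read a split system from a Nexus SPLITS file
#'
#' @param path A file written by [write_splits_nexus()] (or an equivalent
#'   TAXA + SPLITS Nexus file using numeric split lines).
#' @return A \code{split_system}.
#' @export
read_splits_nexus <- function(path) {
  lines <- readLines(path)
  if (!grepl("#NEXUS", lines[1], ignore.case = TRUE)) {
    stop("not a Nexus file: ", path, call. = FALSE)
  }
  taxa <- sub("^\\[\\d+\\]\\s*'(.*)'\\s*$", "\\1",
              grep("^\\[\\d+\\] '", lines, value = TRUE))
  cyc_line <- grep("^\\s*CYCLE", lines, value = TRUE)[1]
  cycle <- as.integer(strsplit(gsub("CYCLE|;", "", cyc_line), "\\s+")[[1]]
                      [nzchar(strsplit(gsub("CYCLE|;", "", cyc_line),
                                       "\\s+")[[1]])])
  split_lines <- grep("^\\[\\d+, size=", lines, value = TRUE)
  splits <- list(); weights <- numeric(0)
  for (ln in split_lines) {
    body <- sub("^\\[[^]]*\\]\\s*", "", ln)
    body <- sub(",\\s*$", "", body)
    parts <- strsplit(body, "\\s+")[[1]]
    weights <- c(weights, as.numeric(parts[1]))
    splits[[length(splits) + 1L]] <- sort(as.integer(parts[-1]))
  }
  structure(list(taxa = taxa, cycle = cycle, splits = splits,
                 weights = weights, residual = NA_real_),
            class = "split_system")
}
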