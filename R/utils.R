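# Internal helpers.

# Evaluate expr under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
local_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Resolve a grouping spec (metadata column name or explicit label vector)
# into a character vector aligned with the samples of g.
resolve_grouping <- function(g, grouping) {
  if (is.character(grouping) && length(grouping) == 1L &&
      grouping %in% names(g$meta)) {
    labels <- as.character(g$meta[[grouping]])
  } else {
    if (length(grouping) != nrow(g$dosage)) {
      stop("grouping must name a metadata column or give one label per sample",
           call. = FALSE)
    }
    labels <- as.character(grouping)
  }
  if (anyNA(labels)) stop("grouping labels contain NA", call. = FALSE)
  labels
}

# Coerce a dist or matrix into a validated symmetric distance matrix.
as_distance_matrix <- function(d, require_finite = TRUE) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square", call. = FALSE)
  if (require_finite && any(!is.finite(m))) {
    stop("distance matrix contains non-finite entries", call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(m < -1e-12)) stop("distance matrix must be non-negative",
                            call. = FALSE)
  m[m < 0] <- 0
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  }
  diag(m) <- 0
  m
}
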