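# In-silico double digestion and size-selection yield counting.

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    g <- genome
  } else if (is.character(genome) && length(genome) == 1L &&
             file.exists(genome)) {
    g <- Biostrings::readDNAStringSet(genome)
  } else if (is.character(genome)) {
    g <- Biostrings::DNAStringSet(toupper(genome))
    if (is.null(names(g))) names(g) <- paste0("seq", seq_along(g))
  } else {
    stop("genome must be a FASTA path, character vector or DNAStringSet",
         call. = FALSE)
  }
  if (length(g) == 0L) stop("genome contains no sequences", call. = FALSE)
  if (is.null(names(g)) || anyNA(names(g)) || any(!nzchar(names(g)))) {
    names(g) <- paste0("seq", seq_along(g))
  }
  # FASTA headers: keep the first whitespace-delimited token as the id
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Double digestion of a genome by a pair of restriction enzymes
#'
#' Scans every record of the genome for cut sites of both enzymes, merges the
#' cut positions, and reports the resulting fragments. Fragment intervals are
#' 0-based half-open; within a scaffold they partition it exactly, so their
#' lengths sum to the scaffold length. Each fragment records which enzyme
#' produced its left and right boundary; scaffold ends are labelled
#' \code{"terminus"}.
#'
#' @param genome FASTA path (gzip transparent), character vector of
#'   sequences, or a \code{Biostrings::DNAStringSet}.
#' @param pair List or character vector of length 2: two
#'   \code{restriction_enzyme} objects, or two names looked up in
#'   \code{enzyme_catalogue()}.
#' @return A \code{"digest_table"}: data frame with columns
#'   \code{scaffold}, \code{start}, \code{end}, \code{left}, \code{right},
#'   \code{length}, plus attributes \code{enzymes} (the pair's names) and
#'   \code{scaffold_lengths}.
#' @examples
#' dt <- double_digest(c(chr = "AAGAATTCAAACCGGAA"), c("EcoRI", "MspI"))
#' dt
#' @export
double_digest <- function(genome, pair) {
  pair <- resolve_pair(pair)
  g <- as_genome(genome)
  rows <- lapply(seq_along(g), function(i) {
    seq_i <- g[[i]]
    len <- length(seq_i)
    cuts1 <- scan_cut_sites(seq_i, pair[[1]])
    cuts2 <- scan_cut_sites(seq_i, pair[[2]])
    # if both enzymes cut at the same between-base position, the boundary is
    # attributed to the first enzyme of the pair
    cuts <- c(cuts1, setdiff(cuts2, cuts1))
    who  <- c(rep(pair[[1]]$name, length(cuts1)),
              rep(pair[[2]]$name, length(setdiff(cuts2, cuts1))))
    # drop degenerate cuts at the very ends (offset 0 site at position 0 etc.)
    keep <- cuts > 0L & cuts < len
    cuts <- cuts[keep]; who <- who[keep]
    o <- order(cuts); cuts <- cuts[o]; who <- who[o]
    bounds <- c(0L, cuts, len)
    labs   <- c("terminus", who, "terminus")
    k <- length(bounds) - 1L
    data.frame(scaffold = names(g)[i],
               start = bounds[-length(bounds)],
               end   = bounds[-1],
               left  = labs[seq_len(k)],
               right = labs[seq_len(k) + 1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$length <- out$end - out$start
  rownames(out) <- NULL
  structure(out,
            enzymes = c(pair[[1]]$name, pair[[2]]$name),
            scaffold_lengths = stats::setNames(Biostrings::width(g), names(g)),
            class = c("digest_table", "data.frame"))
}

resolve_pair <- function(pair) {
  if (inherits(pair, "restriction_enzyme")) {
    stop("pair must contain two enzymes", call. = FALSE)
  }
  if (is.character(pair)) pair <- enzyme_catalogue(pair)
  pair <- unname(as.list(pair))
  if (length(pair) != 2L ||
      !all(vapply(pair, inherits, logical(1), "restriction_enzyme"))) {
    stop("pair must be two restriction_enzyme objects or two catalogue names",
         call. = FALSE)
  }
  pair
}

#' Count size-selectable fragments of a double digest
#'
#' In mode \code{"both_enzymes"} (the ddRAD-selectable class) a fragment is
#' counted when its two flanks are cut sites of the two different enzymes of
#' the pair and its length falls in \code{[min_len, max_len]} (inclusive).
#' Mode \code{"any_fragment"} counts every fragment in the window regardless
#' of flanks. Both counts are always reported.
#'
#' @param table A \code{digest_table} from [double_digest()].
#' @param min_len,max_len Inclusive fragment-length window in bp.
#' @param mode Which count to use as the headline \code{selected} figure.
#' @return A \code{"pair_yield"} list: \code{pair}, \code{total},
#'   \code{in_window}, \code{selectable}, \code{selected}, \code{mode},
#'   \code{window}, and \code{histogram} (table of in-window lengths).
#' @export
count_selectable <- function(table, min_len, max_len,
                             mode = c("both_enzymes", "any_fragment")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "digest_table"))
  if (!(min_len > 0 && min_len <= max_len)) {
    stop("need 0 < min_len <= max_len", call. = FALSE)
  }
  enz <- attr(table, "enzymes")
  in_win <- table$length >= min_len & table$length <= max_len
  both <- in_win &
    table$left != "terminus" & table$right != "terminus" &
    ((table$left == enz[1] & table$right == enz[2]) |
     (table$left == enz[2] & table$right == enz[1]) |
     (enz[1] == enz[2] & table$left == enz[1] & table$right == enz[1]))
  structure(list(
    pair = paste(enz, collapse = "-"),
    total = nrow(table),
    in_window = sum(in_win),
    selectable = sum(both),
    selected = if (mode == "both_enzymes") sum(both) else sum(in_win),
    mode = mode,
    window = c(min_len, max_len),
    histogram = table(table$length[in_win])
  ), class = "pair_yield")
}

#' @export
print.pair_yield <- function(x, ...) {
  cat(sprintf("%s: %d fragments, %d in [%d, %d] bp, %d flanked by both enzymes\n",
              x$pair, x$total, x$in_window, x$window[1], x$window[2],
              x$selectable))
  invisible(x)
}

#' Rank enzyme pairs by in-silico size-selectable yield
#'
#' Digests the genome with every requested pair and returns one summary row
#' per pair, sorted by decreasing in-window fragment count. Duplicate pair
#' entries (in either orientation) are collapsed with a warning.
#'
#' @param genome As in [double_digest()].
#' @param pairs List of 2-element character vectors of enzyme names, or a
#'   character vector like \code{"EcoRI-MspI"}.
#' @param min_len,max_len Inclusive size-selection window in bp.
#' @param catalogue Named list of enzymes; defaults to [enzyme_catalogue()].
#' @param mode Counting mode passed to [count_selectable()].
#' @return Data frame (class \code{"pair_ranking"}) with columns
#'   \code{pair}, \code{total}, \code{in_window}, \code{selectable},
#'   \code{selected}, sorted by \code{in_window} descending.
#' @export
rank_enzyme_pairs <- function(genome, pairs, min_len = 300, max_len = 500,
                              catalogue = enzyme_catalogue(),
                              mode = c("both_enzymes", "any_fragment")) {
  mode <- match.arg(mode)
  if (is.character(pairs)) pairs <- strsplit(pairs, "-", fixed = TRUE)
  pairs <- lapply(pairs, function(p) {
    if (is.character(p)) {
      missing <- setdiff(p, names(catalogue))
      if (length(missing))
        stop("pair member(s) not in catalogue: ",
             paste(missing, collapse = ", "), call. = FALSE)
      catalogue[p]
    } else p
  })
  key <- vapply(pairs, function(p)
    paste(sort(vapply(p, function(e) e$name, character(1))), collapse = "-"),
    character(1))
  if (anyDuplicated(key)) {
    warning("duplicate enzyme pair(s) collapsed: ",
            paste(unique(key[duplicated(key)]), collapse = ", "))
    pairs <- pairs[!duplicated(key)]
  }
  g <- as_genome(genome)
  summaries <- lapply(pairs, function(p) {
    y <- count_selectable(double_digest(g, p), min_len, max_len, mode)
    data.frame(pair = y$pair, total = y$total, in_window = y$in_window,
               selectable = y$selectable, selected = y$selected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, summaries)
  out <- out[order(-out$in_window, out$pair), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, window = c(min_len, max_len), mode = mode,
            class = c("pair_ranking", "data.frame"))
}

#' Write selectable fragments of a digest as BED
#'
#' @param table A \code{digest_table}.
#' @param path Output path.
#' @param min_len,max_len Window; only both-enzyme-flanked in-window
#'   fragments are written.
#' @return Invisibly, the number of records written.
#' @export
write_selectable_bed <- function(table, path, min_len = 300, max_len = 500) {
  enz <- attr(table, "enzymes")
  keep <- table$length >= min_len & table$length <= max_len &
    table$left != "terminus" & table$right != "terminus" &
    table$left != table$right
  bed <- table[keep, c("scaffold", "start", "end"), drop = FALSE]
  bed$name <- paste(table$left[keep], table$right[keep], sep = "-")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(bed))
}
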