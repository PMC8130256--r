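# Genotype matrix container, VCF input/output and quality-control filters.

#' Construct a genotype matrix
#'
#' The central container for downstream analyses: an individuals x loci
#' matrix of alternate-allele dosages (0, 1, 2 or NA) plus locus coordinates
#' and per-sample metadata.
#'
#' @param dosage Numeric/integer matrix, samples in rows, loci in columns;
#'   entries in \{0, 1, 2, NA\}. Row names are sample ids.
#' @param loci Data frame with one row per locus: columns \code{scaffold},
#'   \code{pos}, and optionally \code{ref}, \code{alt}, \code{id}.
#' @param meta Data frame with one row per sample: columns \code{sample_id}
#'   and any grouping columns (e.g. \code{country}, \code{locality},
#'   \code{cluster}).
#' @return An object of class \code{"genotype_matrix"}.
#' @export
genotype_matrix <- function(dosage, loci, meta) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- if (!missing(meta) && !is.null(meta$sample_id))
      as.character(meta$sample_id) else paste0("S", seq_len(nrow(dosage)))
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (nrow(loci) != ncol(dosage)) {
    stop("loci table rows must equal dosage columns", call. = FALSE)
  }
  if (!all(c("scaffold", "pos") %in% names(loci))) {
    stop("loci must have columns 'scaffold' and 'pos'", call. = FALSE)
  }
  if (is.null(loci$id)) loci$id <- paste(loci$scaffold, loci$pos, sep = ":")
  if (anyDuplicated(loci$id)) stop("locus ids must be unique", call. = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (is.null(meta$sample_id)) stop("meta must have column 'sample_id'",
                                    call. = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    stop("sample ids must be unique", call. = FALSE)
  }
  missing_meta <- setdiff(rownames(dosage), meta$sample_id)
  if (length(missing_meta)) {
    stop("samples missing from metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(rownames(dosage), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  colnames(dosage) <- loci$id
  structure(list(dosage = dosage, loci = loci, meta = meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d biallelic loci (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  grp <- setdiff(names(x$meta), "sample_id")
  if (length(grp)) cat("metadata columns:", paste(grp, collapse = ", "), "\n")
  rep <- attr(x, "filter_report")
  if (!is.null(rep)) cat(sprintf("%d filter step(s) applied\n", nrow(rep)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Retrieve the accumulated filter ledger of a genotype matrix
#'
#' @param g A \code{genotype_matrix}.
#' @return Data frame with columns \code{filter}, \code{parameter},
#'   \code{loci_before}, \code{loci_after}, \code{samples_before},
#'   \code{samples_after}, or \code{NULL} if no filter was applied.
#' @export
filter_report <- function(g) attr(g, "filter_report")

add_report <- function(g, prev, filter, parameter, before, after) {
  entry <- data.frame(filter = filter, parameter = parameter,
                      loci_before = before[2], loci_after = after[2],
                      samples_before = before[1], samples_after = after[1],
                      stringsAsFactors = FALSE)
  attr(g, "filter_report") <- rbind(prev, entry)
  g
}

subset_genotypes <- function(g, samples = NULL, loci = NULL) {
  rep <- attr(g, "filter_report")
  d <- g$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  lt <- g$loci
  if (!is.null(loci)) {
    d <- d[, loci, drop = FALSE]
    lt <- lt[loci, , drop = FALSE]
    rownames(lt) <- NULL
  }
  mt <- g$meta[match(rownames(d), g$meta$sample_id), , drop = FALSE]
  rownames(mt) <- NULL
  out <- genotype_matrix(d, lt, mt)
  attr(out, "filter_report") <- rep
  out
}

#' Read a VCF into a genotype matrix
#'
#' Keeps biallelic SNP records only (multi-allelic and indel records are
#' dropped with a message); dosage is the count of alternate alleles in the
#' GT field, with any half-missing genotype (\code{./1} etc.) treated as
#' missing.
#'
#' @param path VCF file (plain or bgzipped).
#' @param metadata Data frame or TSV path with columns \code{sample_id},
#'   plus grouping columns; must cover every sample in the VCF.
#' @return A \code{genotype_matrix}.
#' @export
read_vcf <- function(path, metadata) {
  if (is.character(metadata)) {
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  is_snp <- !is.na(fix[, "REF"]) & !is.na(fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1L & !grepl(",", fix[, "ALT"]) &
    nchar(fix[, "ALT"]) == 1L &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_drop <- sum(!is_snp)
  if (n_drop > 0) {
    message(n_drop, " multi-allelic or non-SNP record(s) dropped")
  }
  gt <- v@gt[is_snp, -1, drop = FALSE]
  samples <- colnames(gt)
  absent <- setdiff(samples, as.character(metadata$sample_id))
  if (length(absent)) {
    stop("VCF sample(s) absent from metadata: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  # GT is the leading colon-separated field
  gtc <- sub(":.*$", "", gt)
  gtc <- gsub("\\|", "/", gtc)
  dos <- matrix(NA_integer_, nrow = nrow(gtc), ncol = ncol(gtc))
  dos[gtc == "0/0"] <- 0L
  dos[gtc == "0/1" | gtc == "1/0"] <- 1L
  dos[gtc == "1/1"] <- 2L
  dosage <- t(dos)
  rownames(dosage) <- samples
  loci <- data.frame(scaffold = fix[is_snp, "CHROM"],
                     pos = as.integer(fix[is_snp, "POS"]),
                     ref = fix[is_snp, "REF"], alt = fix[is_snp, "ALT"],
                     stringsAsFactors = FALSE)
  ids <- fix[is_snp, "ID"]
  if (!all(is.na(ids) | ids == ".")) loci$id <- ids
  genotype_matrix(dosage, loci, metadata)
}

#' Write a genotype matrix as VCF
#'
#' @param g A \code{genotype_matrix}.
#' @param path Output path; \code{vcfR} writes gzip-compressed VCF, so a
#'   \code{.vcf.gz} suffix is conventional.
#' @return Invisibly, \code{path}.
#' @export
write_vcf <- function(g, path) {
  L <- nrow(g$loci)
  ref <- if (!is.null(g$loci$ref)) g$loci$ref else rep("A", L)
  alt <- if (!is.null(g$loci$alt)) g$loci$alt else rep("T", L)
  fix <- cbind(CHROM = as.character(g$loci$scaffold),
               POS = as.character(g$loci$pos),
               ID = g$loci$id, REF = ref, ALT = alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  gt_chr <- matrix(c("0/0", "0/1", "1/1")[g$dosage + 1L],
                   nrow = nrow(g$dosage))
  gt_chr[is.na(g$dosage)] <- "./."
  gt <- cbind(FORMAT = "GT", t(gt_chr))
  colnames(gt) <- c("FORMAT", rownames(g$dosage))
  cls <- methods::getClass("vcfR", where = asNamespace("vcfR"))
  v <- methods::new(cls,
                    meta = c("##fileformat=VCFv4.2",
                             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
                    fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

sample_call_rate <- function(g) rowMeans(!is.na(g$dosage))
locus_call_rate <- function(g) colMeans(!is.na(g$dosage))

#' Drop samples with a low genotype call rate
#'
#' @param g A \code{genotype_matrix}.
#' @param min_rate Minimum fraction of non-missing loci per sample kept.
#' @return Filtered \code{genotype_matrix}; the removal is appended to the
#'   object's [filter_report()].
#' @export
filter_samples_by_call_rate <- function(g, min_rate) {
  stopifnot(min_rate >= 0, min_rate <= 1)
  keep <- sample_call_rate(g) >= min_rate
  if (!any(keep)) stop("sample call-rate filter removed every sample",
                       call. = FALSE)
  before <- dim(g)
  out <- subset_genotypes(g, samples = which(keep))
  add_report(out, attr(g, "filter_report"), "sample_call_rate",
             sprintf("min_rate=%g", min_rate), before, dim(out))
}

#' Drop loci by call rate and minor allele frequency
#'
#' First removes loci whose per-locus call rate is below
#' \code{min_call_rate} (a threshold of 1 keeps only loci typed in every
#' sample), then removes loci whose minor allele frequency, computed from
#' allele counts among called genotypes of the remaining samples, is below
#' \code{min_maf}.
#'
#' @param g A \code{genotype_matrix}.
#' @param min_call_rate Minimum per-locus call rate in \code{[0, 1]}.
#' @param min_maf Minimum minor allele frequency \code{min(p, 1 - p)}.
#' @return Filtered \code{genotype_matrix} with two [filter_report()]
#'   entries.
#' @export
filter_loci <- function(g, min_call_rate = 1, min_maf = 0.03) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  before <- dim(g)
  keep_cr <- locus_call_rate(g) >= min_call_rate
  g1 <- subset_genotypes(g, loci = which(keep_cr))
  g1 <- add_report(g1, attr(g, "filter_report"), "locus_call_rate",
                   sprintf("min_rate=%g", min_call_rate), before, dim(g1))
  if (ncol(g1$dosage) == 0L) {
    stop("no loci survive the call-rate filter (min_call_rate = ",
         min_call_rate, ")", call. = FALSE)
  }
  n_called <- colSums(!is.na(g1$dosage))
  p <- colSums(g1$dosage, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(p, 1 - p)
  keep_maf <- !is.na(maf) & maf >= min_maf
  mid <- dim(g1)
  g2 <- subset_genotypes(g1, loci = which(keep_maf))
  g2 <- add_report(g2, attr(g1, "filter_report"), "maf",
                   sprintf("min_maf=%g", min_maf), mid, dim(g2))
  if (ncol(g2$dosage) == 0L) {
    stop("no loci survive the MAF filter (min_maf = ", min_maf, ")",
         call. = FALSE)
  }
  g2
}

#' Per-scaffold SNP counts
#'
#' @param g A \code{genotype_matrix}.
#' @return A list of class \code{"scaffold_summary"}: \code{counts} (data
#'   frame scaffold / n_snps), \code{n_scaffolds}, \code{min}, \code{max},
#'   and \code{mean} (1 decimal).
#' @export
summarize_by_scaffold <- function(g) {
  tab <- table(g$loci$scaffold)
  counts <- data.frame(scaffold = names(tab), n_snps = as.integer(tab),
                       stringsAsFactors = FALSE)
  structure(list(counts = counts,
                 n_scaffolds = nrow(counts),
                 min = min(counts$n_snps), max = max(counts$n_snps),
                 mean = round(sum(counts$n_snps) / nrow(counts), 1)),
            class = "scaffold_summary")
}

#' @export
print.scaffold_summary <- function(x, ...) {
  cat(sprintf("%d SNPs on %d scaffolds (range %d-%d, mean %.1f per scaffold)\n",
              sum(x$counts$n_snps), x$n_scaffolds, x$min, x$max, x$mean))
  invisible(x)
}

#' Keep one SNP per scaffold
#'
#' @param g A \code{genotype_matrix}.
#' @param rule \code{"first"} keeps the lowest-position SNP of each scaffold
#'   (deterministic); \code{"random"} draws one uniformly per scaffold.
#' @param seed RNG seed, used only for \code{rule = "random"}.
#' @return Thinned \code{genotype_matrix} with exactly one locus per
#'   scaffold.
#' @export
thin_one_per_scaffold <- function(g, rule = c("first", "random"), seed = 1L) {
  rule <- match.arg(rule)
  if (ncol(g$dosage) == 0L) stop("empty genotype matrix", call. = FALSE)
  idx <- split(seq_len(nrow(g$loci)), g$loci$scaffold)
  pick <- if (rule == "first") {
    vapply(idx, function(i) i[which.min(g$loci$pos[i])], integer(1))
  } else {
    local_rng(seed, vapply(idx, function(i)
      if (length(i) == 1L) i else sample(i, 1L), integer(1)))
  }
  subset_genotypes(g, loci = sort(unname(pick)))
}
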