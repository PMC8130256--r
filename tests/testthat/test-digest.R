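test_that("enzyme constructor enforces IUPAC palindromes and cut bounds", {
  e <- restriction_enzyme("EcoRI", "gaattc", 1)
  expect_s3_class(e, "restriction_enzyme")
  expect_identical(e$site, "GAATTC")
  expect_error(restriction_enzyme("bad", "GATC1", 1), "IUPAC")
  expect_error(restriction_enzyme("bad", "ACG", 1), "IUPAC")
  expect_error(restriction_enzyme("bad", "GAATTC", 7), "cut_offset")
  expect_error(restriction_enzyme("BamHI-like", "GGATCA", 1),
               "non-palindromic")
})

test_that("the built-in catalogue matches the published cut geometries", {
  cat9 <- enzyme_catalogue()
  expect_setequal(names(cat9),
                  c("AvaII", "EcoRI", "MseI", "MspI", "NlaIII", "PstI",
                    "SbfI", "SphI", "MluCI"))
  expect_equal(cat9$EcoRI$cut_offset, 1L)
  expect_equal(cat9$NlaIII$cut_offset, 4L)   # cuts after its motif: CATG^
  expect_equal(cat9$MluCI$cut_offset, 0L)    # cuts before its motif: ^AATT
  expect_equal(cat9$SbfI$site, "CCTGCAGG")
  expect_error(enzyme_catalogue("NoSuchEnzyme"), "unknown enzyme")
  sub <- enzyme_catalogue(c("MspI", "EcoRI"))
  expect_identical(names(sub), c("MspI", "EcoRI"))
})

test_that("cut positions equal a sliding-window IUPAC oracle on random sequence", {
  set.seed(11)
  cat9 <- enzyme_catalogue()
  for (rep in 1:3) {
    seq_chr <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE,
                            prob = c(0.29, 0.21, 0.21, 0.29)),
                     collapse = "")
    for (e in cat9) {
      expect_identical(scan_cut_sites(seq_chr, e),
                       naive_cut_sites(seq_chr, e),
                       info = e$name)
    }
  }
})

test_that("ambiguity codes match in the motif but N in the genome never matches", {
  avaII <- enzyme_catalogue("AvaII")[[1]]      # GGWCC, W = A or T
  expect_equal(scan_cut_sites("AAGGACCAA", avaII), 3)
  expect_equal(scan_cut_sites("AAGGTCCAA", avaII), 3)
  expect_equal(scan_cut_sites("AAGGCCCAA", avaII), integer(0))
  # genomic N sits where W would allow A/T: must not match
  expect_equal(scan_cut_sites("AAGGNCCAA", avaII), integer(0))
  eco <- enzyme_catalogue("EcoRI")[[1]]
  expect_equal(scan_cut_sites("GANTTC", eco), integer(0))
})

test_that("cut position arithmetic places the cut between the right bases", {
  eco <- enzyme_catalogue("EcoRI")[[1]]
  # G^AATTC starting at 0-based 2 cuts at 3
  expect_equal(scan_cut_sites("AAGAATTCAA", eco), 3)
  nla <- enzyme_catalogue("NlaIII")[[1]]
  # CATG^ starting at 0-based 1 cuts at 5
  expect_equal(scan_cut_sites("ACATGA", nla), 5)
  mlu <- enzyme_catalogue("MluCI")[[1]]
  # ^AATT starting at 0-based 2 cuts at 2
  expect_equal(scan_cut_sites("GGAATTGG", mlu), 2)
})

test_that("digest fragments partition every scaffold exactly", {
  set.seed(21)
  seqs <- sapply(c(400, 1000), function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
  names(seqs) <- c("sA", "sB")
  dt <- double_digest(seqs, c("MseI", "MspI"))
  expect_s3_class(dt, "digest_table")
  for (sc in names(seqs)) {
    rows <- dt[dt$scaffold == sc, ]
    expect_equal(rows$start[1], 0)
    expect_equal(rows$end[nrow(rows)], nchar(seqs[[sc]]))
    # half-open intervals must abut: next start == previous end
    expect_equal(rows$start[-1], rows$end[-nrow(rows)])
    expect_equal(sum(rows$length), nchar(seqs[[sc]]))
  }
  # flank labels at the termini
  first <- dt[dt$start == 0, ]
  expect_true(all(first$left == "terminus"))
})

test_that("digest is invariant to the order of the enzyme pair", {
  set.seed(22)
  s <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
             collapse = "")
  d1 <- double_digest(s, c("EcoRI", "MspI"))
  d2 <- double_digest(s, c("MspI", "EcoRI"))
  expect_equal(d1[c("scaffold", "start", "end", "length")],
               d2[c("scaffold", "start", "end", "length")])
  y1 <- count_selectable(d1, 100, 400)
  y2 <- count_selectable(d2, 100, 400)
  expect_equal(y1$in_window, y2$in_window)
  expect_equal(y1$selectable, y2$selectable)
})

test_that("fragment boundaries carry the enzyme that produced each cut", {
  # EcoRI cuts at 3, MspI at 10 and 16: fragments 0-3, 3-10, 10-16, 16-20
  s <- c(chr = "AAGAATTCACCGGAACCGGA")
  dt <- double_digest(s, c("EcoRI", "MspI"))
  expect_equal(dt$start, c(0, 3, 10, 16))
  expect_equal(dt$end, c(3, 10, 16, 20))
  expect_equal(dt$left, c("terminus", "EcoRI", "MspI", "MspI"))
  expect_equal(dt$right, c("EcoRI", "MspI", "MspI", "terminus"))
  y <- count_selectable(dt, 1, 50)
  # only the EcoRI|MspI fragment has mixed flanks
  expect_equal(y$selectable, 1)
  expect_equal(y$in_window, 4)
})

test_that("widening the size window never lowers the in-window count", {
  set.seed(23)
  s <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
             collapse = "")
  dt <- double_digest(s, c("MseI", "NlaIII"))
  wins <- list(c(300, 400), c(300, 500), c(200, 500), c(100, 600))
  counts <- sapply(wins, function(w)
    count_selectable(dt, w[1], w[2])$in_window)
  expect_true(all(diff(counts) >= 0))
  sel <- sapply(wins, function(w)
    count_selectable(dt, w[1], w[2])$selectable)
  expect_true(all(diff(sel) >= 0))
  expect_true(all(sel <= counts))
})

test_that("pair ranking sorts by yield and collapses duplicate pairs", {
  set.seed(24)
  s <- paste(sample(c("A", "C", "G", "T"), 30000, replace = TRUE),
             collapse = "")
  rk <- rank_enzyme_pairs(s, list(c("EcoRI", "MspI"), c("MseI", "NlaIII"),
                                  c("SbfI", "SphI")),
                          min_len = 100, max_len = 400)
  expect_s3_class(rk, "pair_ranking")
  expect_equal(nrow(rk), 3)
  expect_true(all(diff(rk$in_window) <= 0))
  # rare 8-bp cutter pairs should fall behind frequent 4-bp cutter pairs
  expect_equal(rk$pair[1], "MseI-NlaIII")
  expect_warning(
    rk2 <- rank_enzyme_pairs(s, list(c("EcoRI", "MspI"), c("MspI", "EcoRI")),
                             min_len = 100, max_len = 400),
    "duplicate")
  expect_equal(nrow(rk2), 1)
})

test_that("an enzyme catalogue round-trips through its TSV representation", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(name = c("EcoRI", "MspI"),
                   site = c("GAATTC", "CCGG"),
                   cut_offset = c(1L, 1L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat2 <- read_enzyme_table(path)
  expect_identical(names(cat2), c("EcoRI", "MspI"))
  expect_equal(cat2$EcoRI$site, "GAATTC")
  expect_equal(cat2$MspI$cut_offset, 1L)
  unlink(path)
})

test_that("selectable fragments are exported as valid BED records", {
  s <- c(chr = "AAGAATTCACCGGAACCGGA")
  dt <- double_digest(s, c("EcoRI", "MspI"))
  path <- tempfile(fileext = ".bed")
  n <- write_selectable_bed(dt, path, min_len = 1, max_len = 50)
  expect_equal(n, 1)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, 3)    # 0-based start
  expect_equal(bed$V3, 10)
  unlink(path)
})

test_that("FASTA input keeps only the first header token as scaffold id", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">scaf_1 assembly=demo", "AAGAATTCAA"), fa)
  dt <- double_digest(fa, c("EcoRI", "MspI"))
  expect_true(all(dt$scaffold == "scaf_1"))
  unlink(fa)
})
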