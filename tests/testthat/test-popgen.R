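test_that("allele frequencies match hand counts with missing data excluded", {
  g <- toy_genotypes()
  af <- allele_frequencies(g, "country")
  # group x: s1, s2. locus 1: dosages 0,0 over 4 alleles -> 0
  expect_equal(af$p["x", 1], 0)
  # locus 5: s1 = 1, s2 = NA -> 1 alt / 2 alleles = 0.5
  expect_equal(af$p["x", 5], 0.5)
  expect_equal(af$n_called["x", 5], 1)
  # group y: s3, s4. locus 2: s3 = 0, s4 = NA -> 0
  expect_equal(af$p["y", 2], 0)
  # all groups, all loci: p within [0, 1]
  expect_true(all(af$p >= 0 & af$p <= 1, na.rm = TRUE))
})

test_that("heterozygosity flags reflect the Ho versus He comparison", {
  # fully inbred population: only homozygotes, so Ho = 0 < He
  dos <- rbind(a = c(0L, 2L, 0L, 2L), b = c(2L, 0L, 0L, 2L),
               c = c(0L, 0L, 2L, 2L), d = c(2L, 2L, 2L, 0L))
  g <- genotype_matrix(dos,
                       data.frame(scaffold = "c", pos = 1:4),
                       data.frame(sample_id = rownames(dos),
                                  pop = "p1"))
  h <- heterozygosity(g, "pop")
  expect_equal(h$summary$Ho, 0)
  expect_true(h$summary$He > 0)
  expect_equal(h$summary$flag, "inbreeding-like")
})

test_that("two-population Fst matches a direct allele-count computation", {
  # Arlequin-style allele-level components, worked by hand for one locus:
  # pop1 = {0,1} (p1 = 1/4, m1 = 4), pop2 = {2,2} (p2 = 1, m2 = 4)
  dos <- rbind(a = 0L, b = 1L, c = 2L, d = 2L)
  g <- genotype_matrix(matrix(dos, 4, 1, dimnames = list(rownames(dos), NULL)),
                       data.frame(scaffold = "c", pos = 1),
                       data.frame(sample_id = rownames(dos),
                                  pop = c("p1", "p1", "p2", "p2")))
  M <- 8; pbar <- 3 / 8
  ss_t <- M * pbar * (1 - pbar)
  ss_w <- 4 * (1 / 4) * (3 / 4) + 4 * 1 * 0
  ms_w <- ss_w / (M - 2)
  n_c <- M - (16 + 16) / M
  sigma_a <- ((ss_t - ss_w) - ms_w) / n_c
  fst_hand <- sigma_a / (sigma_a + ms_w)
  r <- pairwise_fst(g, "pop", permutations = 0)
  expect_equal(r$fst["p1", "p2"], fst_hand, tolerance = 1e-12)
})

test_that("pairwise Fst is symmetric and invariant to group label names", {
  set.seed(41)
  sim <- sim_genotypes(n_pops = 3, fst = 0.15, n_per_pop = 15, n_loci = 300,
                       seed = 5)
  g <- sim$genotypes
  r1 <- pairwise_fst(g, "population", permutations = 0)
  expect_equal(r1$fst, t(r1$fst))
  # renaming the groups must permute, not change, the estimates
  relabel <- c(pop1 = "zebra", pop2 = "apple", pop3 = "mango")
  labs2 <- unname(relabel[g$meta$population])
  r2 <- pairwise_fst(g, labs2, permutations = 0)
  expect_equal(r2$fst["zebra", "apple"], r1$fst["pop1", "pop2"])
  expect_equal(r2$fst["mango", "zebra"], r1$fst["pop3", "pop1"])
})

test_that("the Weir-Cockerham estimator agrees with the variance-component Fst", {
  sim <- sim_genotypes(n_pops = 2, fst = 0.1, n_per_pop = 50, n_loci = 1000,
                       seed = 7)
  a <- pairwise_fst(sim$genotypes, "population", permutations = 0,
                    method = "amova")$fst[1, 2]
  w <- pairwise_fst(sim$genotypes, "population", permutations = 0,
                    method = "wc")$fst[1, 2]
  expect_equal(a, w, tolerance = 0.005)
})

test_that("groups below two individuals or two groups are rejected", {
  g <- toy_genotypes()
  expect_error(pairwise_fst(g, rep("one", 4), permutations = 0),
               "at least 2 groups")
  expect_error(pairwise_fst(g, c("a", "a", "a", "b"), permutations = 0),
               "fewer than 2")
})

test_that("individual distances equal the naive pairwise-complete mismatch", {
  set.seed(42)
  dos <- matrix(sample(c(0:2, NA), 8 * 60, replace = TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)), 8, 60)
  # ensure no all-missing pair
  dos[, 1] <- 1L
  rownames(dos) <- letters[1:8]
  g <- genotype_matrix(dos,
                       data.frame(scaffold = "c", pos = 1:60),
                       data.frame(sample_id = rownames(dos)))
  D <- as.matrix(individual_distance(g))
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(D[i, j], naive_pair_distance(dos[i, ], dos[j, ]),
                 tolerance = 1e-12)
  }
  # identical individuals sit at distance zero
  dos2 <- rbind(dos, z = dos["a", ])
  g2 <- genotype_matrix(dos2,
                        data.frame(scaffold = "c", pos = 1:60),
                        data.frame(sample_id = rownames(dos2)))
  expect_equal(as.matrix(individual_distance(g2))["a", "z"], 0)
})

test_that("a pair sharing no called locus is an error, not a silent zero", {
  dos <- rbind(a = c(1L, NA), b = c(NA, 1L), c = c(1L, 1L))
  g <- genotype_matrix(dos,
                       data.frame(scaffold = "c", pos = 1:2),
                       data.frame(sample_id = rownames(dos)))
  expect_error(individual_distance(g), "no shared called loci")
})

test_that("two-level AMOVA Phi_ST equals the pairwise Fst on the same data", {
  sim <- sim_genotypes(n_pops = 2, fst = 0.1, n_per_pop = 20, n_loci = 400,
                       seed = 11)
  g <- sim$genotypes
  fst <- pairwise_fst(g, "population", permutations = 0)$fst[1, 2]
  am <- hierarchical_amova(g, "population", permutations = 0)
  expect_equal(unname(am$phi[["Phi_ST"]]), fst, tolerance = 1e-10)
})

test_that("three-level AMOVA percentages sum to 100 and components stay consistent", {
  sim <- sim_genotypes(n_pops = 4, fst = 0.1, n_per_pop = 12, n_loci = 300,
                       seed = 13)
  g <- sim$genotypes
  grp <- ifelse(g$meta$population %in% c("pop1", "pop2"), "west", "east")
  am <- hierarchical_amova(g, "population", grp, permutations = 0)
  tab <- am$table
  expect_equal(sum(tab$pct[1:3]), 100, tolerance = 1e-9)
  expect_equal(tab$pct[4], 100, tolerance = 1e-9)
  expect_equal(sum(tab$SS[1:3]), tab$SS[4], tolerance = 1e-8)
  expect_equal(tab$df[4], sum(tab$df[1:3]))
  # Phi identities
  s <- tab$sigma2
  expect_equal(unname(am$phi[["Phi_ST"]]), (s[1] + s[2]) / s[4],
               tolerance = 1e-12)
})

test_that("permuting population labels leaves a true null Fst non-significant on average", {
  # one panmictic population split arbitrarily in two: Fst should hover
  # around zero and the permutation p-value should not be extreme
  sim <- sim_genotypes(n_pops = 1, fst = 0.2, n_per_pop = 30, n_loci = 300,
                       seed = 17)
  g <- sim$genotypes
  labs <- rep(c("u", "v"), 15)
  r <- pairwise_fst(g, labs, permutations = 99, seed = 3)
  expect_true(abs(r$fst["u", "v"]) < 0.02)
  expect_true(r$p_value["u", "v"] > 0.01)
})

test_that("strong structure yields a significant permutation p-value", {
  sim <- sim_genotypes(n_pops = 2, fst = 0.2, n_per_pop = 25, n_loci = 400,
                       seed = 19)
  r <- pairwise_fst(sim$genotypes, "population", permutations = 99, seed = 3)
  expect_equal(unname(r$p_value[1, 2]), 1 / 100)
})

test_that("distance matrices are exported in PHYLIP square format", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(c("t1", "t2", "t3"), c("t1", "t2", "t3")))
  path <- tempfile()
  write_phylip_dist(m, path)
  lines <- readLines(path)
  expect_equal(as.integer(trimws(lines[1])), 3)
  expect_equal(length(lines), 4)
  expect_match(lines[2], "^t1")
  unlink(path)
})
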