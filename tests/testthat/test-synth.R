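test_that("locus and simulation configs reject invalid parameters", {
  expect_error(locus_spec("bad", n_codons = 20), "30 codons")
  expect_error(locus_spec("bad", lof_rate = 1.5))
  expect_error(simulation_config(n_species = 0))
  expect_error(simulation_config(migration_rate = 2))
  expect_error(simulate_allele_pool(
    structure(list(name = "x", n_codons = 10L, n_alleles = 2L,
                   mutations_per_allele = 1, lof_rate = 0,
                   selection = "neutral", min_pairwise_diff = 0L),
              class = "locus_spec")), "30 codons")
})

test_that("loss-of-function flags are forced by the lof_rate extremes", {
  pool0 <- simulate_allele_pool(locus_spec("L", lof_rate = 0), seed = 1)
  expect_true(all(pool0$functional))
  # and no LoF lesion is visible against the ancestor
  for (s in pool0$sequences) {
    ann <- scan_orf(s, pool0$ancestor)
    expect_true(ann$is_functional_cds)
  }
  pool1 <- simulate_allele_pool(
    locus_spec("L", n_alleles = 10, lof_rate = 1), seed = 2)
  expect_length(pool1$functional, 10)
  expect_true(all(!pool1$functional))
  for (s in pool1$sequences) {
    ann <- scan_orf(s, pool1$ancestor)
    expect_false(ann$is_functional_cds)
    expect_true(any(ann$events$kind %in% c("premature_stop",
                                           "frameshift_indel")))
  }
})

test_that("mean pairwise allele differences match a brute-force
           expectation (100 codons, mutation count 5, 8 alleles)", {
  spec <- locus_spec("L", n_codons = 100, n_alleles = 8,
                     mutations_per_allele = 5, lof_rate = 0)
  means <- vapply(seq_len(200), function(s) {
    pool <- simulate_allele_pool(spec, seed = 1000 + s)
    seqs <- pool$sequences
    pairs <- combn(length(seqs), 2)
    mean(apply(pairs, 2, function(ix)
      pairwise_nt_diff(seqs[[ix[1]]], seqs[[ix[2]]])))
  }, numeric(1))
  expected <- withr::with_seed(42,
    oracle_pairdiff_expectation(L = 3 * 100 - 6, mu = 5, nsim = 20000))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expected), 3 * se)
})

test_that("identical configs give byte-identical datasets and the read
           count conserves 2 x clones_per_allele per individual-locus", {
  cfg <- simulation_config(n_species = 2, populations_per_species = 2,
                           individuals_per_population = 4, seed = 77)
  d1 <- simulate_metapopulation(cfg)
  d2 <- simulate_metapopulation(cfg)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$phenotype, d2$phenotype)
  expect_identical(d1$truth$fst_parametric, d2$truth$fst_parametric)
  r1 <- dataset_clone_reads(d1)
  r2 <- dataset_clone_reads(d2)
  expect_identical(r1, r2)
  n_ind <- 2 * 2 * 4
  expect_equal(nrow(r1),
               n_ind * length(cfg$loci) * 2 * cfg$clones_per_allele)
  # every read maps to exactly one true allele of its individual
  g <- d1$genotypes
  key <- paste(g$individual, g$locus)
  for (i in sample(nrow(r1), 25)) {
    row <- r1[i, ]
    alleles <- unlist(g[match(paste(row$individual, row$locus), key),
                        c("allele1", "allele2")])
    expect_true(row$true_allele %in% alleles)
  }
  # files are byte-identical across reruns
  t1 <- withr::local_tempdir(); t2 <- withr::local_tempdir()
  write_dataset(d1, t1, r1)
  write_dataset(d2, t2, r2)
  for (f in list.files(t1)) {
    expect_identical(readLines(file.path(t1, f)),
                     readLines(file.path(t2, f)), label = f)
  }
})

test_that("parametric F_ST fixed points: disjoint fixation gives 1,
           panmixia gives ~0", {
  # two species fixed for disjoint alleles
  f <- rbind(sp1 = c(1, 0), sp2 = c(0, 1))
  expect_equal(popallele:::parametric_fst(f), 1)
  expect_equal(popallele:::parametric_fst(rbind(a = c(.3, .7),
                                                b = c(.3, .7))), 0)
  # full migration: realized species F_ST below 0.02 in >= 95% of seeds
  small <- vapply(seq_len(100), function(s) {
    cfg <- simulation_config(n_species = 3, populations_per_species = 2,
                             individuals_per_population = 50,
                             loci = list(locus_spec("L", n_alleles = 6)),
                             migration_rate = 1, seed = 3000 + s)
    ds <- simulate_metapopulation(cfg)
    ds$truth$fst_parametric$L$species
  }, numeric(1))
  expect_gte(mean(small < 0.02), 0.95)
})

test_that("ledger F_ST decreases with migration (rank correlation)", {
  grid <- rep(c(0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 0.95), each = 6)
  fst <- vapply(seq_along(grid), function(i) {
    cfg <- simulation_config(n_species = 3, populations_per_species = 2,
                             individuals_per_population = 12,
                             loci = list(locus_spec("L", n_alleles = 6)),
                             migration_rate = grid[i], seed = 4000 + i)
    simulate_metapopulation(cfg)$truth$fst_parametric$L$species
  }, numeric(1))
  ct <- suppressWarnings(cor.test(grid, fst, method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("noise-free phenotypes are exactly linear in causal functional
           expression", {
  cfg <- simulation_config(n_species = 2, populations_per_species = 2,
                           individuals_per_population = 8,
                           loci = list(locus_spec("L1")),
                           noise_sd = 0, expression_effect = 2.5,
                           seed = 5)
  ds <- simulate_metapopulation(cfg)
  fun_ids <- names(ds$pools$L1$functional)[ds$pools$L1$functional]
  ex <- ds$expression[ds$expression$allele_group %in% fun_ids, ]
  x <- tapply(ex$normalized_intensity, ex$individual, sum)
  v <- setNames(rep(0, nrow(ds$individuals)), ds$individuals$individual)
  v[names(x)] <- x
  y <- setNames(ds$phenotype$amount_ug, ds$phenotype$individual)[names(v)]
  fit <- lm(y ~ v)
  expect_equal(unname(coef(fit)["v"]), 2.5, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["(Intercept)"]), 0, tolerance = 1e-8)
})

test_that("clone reads reproduce their source exactly at zero error and
           at the configured error rate otherwise", {
  pool <- simulate_allele_pool(locus_spec("L", n_codons = 267,
                                          lof_rate = 0), seed = 3)
  al <- pool$sequences[c(1, 2)]
  r0 <- generate_clone_reads(al, "ind1", "p1", "sp1", "L",
                             clones_per_allele = 3, error_rate = 0,
                             seed = 4)
  expect_equal(nrow(r0), 6)  # heterozygote, 3 clones per copy
  expect_identical(r0$sequence, unname(al[r0$true_allele]))
  # binomial counting oracle: empirical error within 3 SE of 1e-3
  hom <- pool$sequences[c(1, 1)]
  rr <- generate_clone_reads(hom, "ind2", "p1", "sp1", "L",
                             clones_per_allele = 5000, error_rate = 1e-3,
                             seed = 9)
  src <- strsplit(unname(al[1]), "")[[1]]
  errs <- vapply(rr$sequence, function(s)
    sum(strsplit(s, "")[[1]] != src), numeric(1))
  n_sites <- length(src) * nrow(rr)
  phat <- sum(errs) / n_sites
  se <- sqrt(1e-3 * (1 - 1e-3) / n_sites)
  expect_lt(abs(phat - 1e-3), 3 * se)
})
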