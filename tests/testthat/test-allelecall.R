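test_that("pairwise_nt_diff counts substitutions and indel events", {
  expect_equal(pairwise_nt_diff("ACGT", "ACGT"), 0)
  expect_equal(pairwise_nt_diff("ACGT", "ACGA"), 1)
  # a 2-column gap run is one event under indel_as_diff
  expect_equal(pairwise_nt_diff("AC--GT", "ACTTGT",
                                gap_policy = "indel_as_diff"), 1)
  expect_equal(pairwise_nt_diff("AC--GT", "ACTTGT",
                                gap_policy = "ignore_gaps"), 0)
  # substitutions + separate gap runs accumulate
  expect_equal(pairwise_nt_diff("A-CA-G", "ATCTTG"), 3)
  expect_equal(pairwise_nt_diff("ANGT", "ACGT"), 0)  # N never scored
  expect_error(pairwise_nt_diff("ACG", "ACGT"), "alignment")
})

test_that("merge_clones follows the merge rule, single linkage, and is
           order invariant", {
  reads <- data.frame(
    id = c("r1", "r2", "r3"),
    sequence = c("ACGTACGT", "ACGTACGA", "ACCTACGA"),
    locus = "L", stringsAsFactors = FALSE)
  # r1-r2 differ by 1 (merged); r3 is 1 from r2, 2 from r1: chain merges
  chain <- merge_clones(reads, d_merge = 1)
  expect_equal(nrow(chain$alleles), 1)
  expect_equal(chain$alleles$n_reads, 3)
  # pairwise >= 3 differences: all singletons
  far <- data.frame(id = c("r1", "r2", "r3"),
                    sequence = c("AAAAAAAA", "CCCAAAAA", "GGGGGGAA"),
                    locus = "L", stringsAsFactors = FALSE)
  singles <- merge_clones(far, d_merge = 1)
  expect_equal(nrow(singles$alleles), 3)
  expect_true(all(singles$alleles$is_singleton))
  # two reads 1 apart: consensus by majority over members
  two <- merge_clones(reads[1:2, ], d_merge = 1)
  expect_equal(nrow(two$alleles), 1)
  # shuffling input changes nothing
  shuf <- merge_clones(reads[c(3, 1, 2), ], d_merge = 1)
  expect_identical(chain$alleles, shuf$alleles)
  expect_identical(merge_clones(reads[0, ], 1)$alleles$allele_id,
                   character(0))
})

test_that("consensus majority and its smallest-id tie-break", {
  expect_equal(build_consensus(c(a = "AAG", b = "AAG", c = "GAG")), "AAG")
  # tie column: read with smaller id carries A
  expect_equal(build_consensus(c(r1 = "AT", r2 = "GT")), "AT")
  expect_equal(build_consensus(c(r2 = "GT", r1 = "AT")), "AT")
  expect_equal(build_consensus(c(x = "ACGT", y = "ACGT")), "ACGT")
})

test_that("p-distance uses pairwise deletion of gaps", {
  d1 <- p_distance_matrix(c(a = "AAAA", b = "AAAA"))
  expect_equal(d1$values["a", "b"], 0)
  d2 <- p_distance_matrix(c(a = "AAAA", b = "AATT"))
  expect_equal(d2$values["a", "b"], 0.5)
  d3 <- p_distance_matrix(c(a = "AA-A", b = "AATA"))
  expect_equal(d3$values["a", "b"], 0)
  expect_equal(d3$overlap["a", "b"], 3)
  expect_error(p_distance_matrix(c(a = "--AA", b = "TT--")),
               "no co-scored sites.*a.*b")
})

test_that("upgma reproduces the textbook 3-taxon case and stays
           ultrametric", {
  D <- matrix(c(0, .1, .4, .1, 0, .4, .4, .4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(D)
  expect_equal(length(tr$nodes), 2)
  expect_equal(tr$nodes[[1]]$members, c("A", "B"))
  expect_equal(tr$nodes[[1]]$height, 0.05)
  expect_equal(tr$nodes[[2]]$height, 0.2)
  # ultrametric: equal root-to-tip path lengths via ape
  withr::with_seed(11, {
    for (case in 1:25) {
      n <- sample(4:7, 1)
      M <- matrix(runif(n * n), n)
      M <- (M + t(M)) / 2
      diag(M) <- 0
      dimnames(M) <- list(paste0("t", 1:n), paste0("t", 1:n))
      tree <- upgma(M)
      ph <- ape::read.tree(text = upgma_newick(tree))
      depth <- ape::node.depth.edgelength(ph)[seq_len(n)]
      expect_lt(diff(range(depth)), 1e-12 * max(depth))
    }
  })
})

test_that("upgma agrees with the original-distance averaging oracle", {
  withr::with_seed(202, {
    for (case in 1:40) {
      n <- 6
      M <- matrix(runif(n * n), n)
      M <- (M + t(M)) / 2
      diag(M) <- 0
      dimnames(M) <- list(paste0("t", 1:n), paste0("t", 1:n))
      got <- upgma(M)$nodes
      want <- oracle_upgma(M)
      for (k in seq_along(want)) {
        expect_identical(got[[k]]$members, want[[k]]$members)
        expect_equal(got[[k]]$height, want[[k]]$height,
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("bootstrap support: clean separation gives 1, one replicate
           gives {0,1}, seeds make it reproducible", {
  seqs <- c(a1 = strrep("A", 20), a2 = strrep("A", 20),
            b1 = paste0(strrep("A", 14), strrep("G", 6)),
            b2 = paste0(strrep("A", 14), strrep("G", 6)))
  tr <- bootstrap_support(seqs, n_reps = 50, seed = 1)
  sup <- attr(tr, "support")
  # every internal clade is perfectly supported here
  expect_true(all(sup == 1))
  tr1 <- bootstrap_support(seqs, n_reps = 1, seed = 3)
  expect_true(all(attr(tr1, "support") %in% c(0, 1)))
  tr2a <- bootstrap_support(seqs, n_reps = 25, seed = 9)
  tr2b <- bootstrap_support(seqs, n_reps = 25, seed = 9)
  expect_identical(attr(tr2a, "support"), attr(tr2b, "support"))
})

test_that("allele group assignment cuts the tree as specified", {
  seqs <- c(a1 = strrep("A", 100), a2 = strrep("A", 100),
            b1 = paste0(strrep("A", 98), "GG"),
            b2 = paste0(strrep("A", 98), "GG"))
  tr <- bootstrap_support(seqs, n_reps = 100, seed = 2)
  # everything within max_within_distance: one group, root support moot
  g1 <- assign_allele_groups(tr, min_support = 0.7,
                             max_within_distance = 0.5, locus = "L")
  expect_equal(unique(g1$group_label), "A")
  # tight cut: the two 2-allele clades become groups A and B
  g2 <- assign_allele_groups(tr, min_support = 0.7,
                             max_within_distance = 0.005, locus = "L")
  expect_equal(sort(unique(g2$group_label)), c("A", "B"))
  expect_equal(g2$group_label[match(c("a1", "a2"), g2$allele_id)],
               c("A", "A"))
  # support below min_support everywhere (tall tree): all singletons
  far <- c(x = strrep("A", 10), y = strrep("C", 10), z = strrep("G", 10))
  tr3 <- upgma(p_distance_matrix(far))  # supports all NA
  g3 <- assign_allele_groups(tr3, min_support = 0.7,
                             max_within_distance = 0.03, locus = "L")
  expect_true(all(g3$is_singleton))
  expect_equal(nrow(g3), 3)
})

test_that("merge_clones is idempotent on called alleles in the synthetic
           world", {
  for (s in c(21, 22, 23)) {
    ds <- simulate_metapopulation(recovery_config(s))
    reads <- dataset_clone_reads(ds)
    a1 <- merge_clones(reads[, c("id", "sequence", "locus")])
    again <- data.frame(id = a1$alleles$allele_id,
                        sequence = a1$alleles$consensus,
                        locus = "LX", stringsAsFactors = FALSE)
    a2 <- merge_clones(again)
    expect_equal(nrow(a2$alleles), nrow(a1$alleles))
    expect_setequal(a2$alleles$consensus, a1$alleles$consensus)
  }
})

test_that("zero clone error recovers every true allele sequence exactly", {
  cfg <- recovery_config(31)
  cfg$clone_error_rate <- 0
  ds <- simulate_metapopulation(cfg)
  reads <- dataset_clone_reads(ds)
  aset <- merge_clones(reads[, c("id", "sequence", "locus")])
  carried <- unique(c(ds$genotypes$allele1, ds$genotypes$allele2))
  expect_setequal(aset$alleles$consensus,
                  unname(ds$pools$LX$sequences[carried]))
})
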