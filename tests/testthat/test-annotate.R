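ref_cds <- paste0("ATG", strrep("GGTACC", 18), "TAA")  # 38 codons, intact

test_that("scan_orf finds stops, frameshifts and start loss", {
  expect_true(scan_orf(ref_cds, ref_cds)$is_functional_cds)
  # TGG-free here, so plant a premature stop by codon replacement
  chars <- strsplit(ref_cds, "")[[1]]
  chars[28:30] <- c("T", "G", "A")
  stopped <- paste0(chars, collapse = "")
  ann <- scan_orf(stopped, ref_cds)
  expect_false(ann$is_functional_cds)
  expect_equal(ann$events$kind, "premature_stop")
  expect_equal(ann$events$position, 10)  # codon index
  # single 1-bp deletion at codon 10: frameshift at that alignment column
  del <- chars0 <- strsplit(ref_cds, "")[[1]]
  del[28] <- "-"
  ann2 <- scan_orf(paste0(del, collapse = ""), ref_cds)
  expect_true("frameshift_indel" %in% ann2$events$kind)
  expect_equal(ann2$events$position[ann2$events$kind == "frameshift_indel"],
               28)
  expect_false(ann2$is_functional_cds)
  # 3-bp deletion is in-frame: no frameshift event
  del3 <- chars0
  del3[28:30] <- "-"
  expect_true(scan_orf(paste0(del3, collapse = ""), ref_cds)
              $is_functional_cds)
  # start loss
  lost <- chars0
  lost[1] <- "C"
  expect_equal(scan_orf(paste0(lost, collapse = ""), ref_cds)$events$kind,
               "start_loss")
  # broken reference is a configuration error
  expect_error(scan_orf(ref_cds, stopped), "configuration error")
})

test_that("reference selection takes the longest intact ORF, smallest id
           on ties", {
  seqs <- c(b = ref_cds, a = ref_cds,
            broken = sub("ATG", "CTG", ref_cds))
  expect_equal(choose_reference_cds(seqs), "a")
  expect_error(choose_reference_cds(seqs["broken"]), "intact ORF")
})

test_that("lof_enrichment matches hypergeometric closed forms", {
  none <- data.frame(group = c("A", "B"), nonfunctional = c(0, 0),
                     total = c(5, 20))
  expect_equal(lof_enrichment(none)$p_value, c(1, 1))
  allg <- data.frame(group = c("A", "B"), nonfunctional = c(5, 0),
                     total = c(5, 20))
  expect_equal(lof_enrichment(allg)$p_value[1], 1 / choose(25, 5),
               tolerance = 1e-12)
  # group at the background rate is never 'significant': p >= 0.5
  same <- data.frame(group = c("A", "B"), nonfunctional = c(2, 8),
                     total = c(5, 20))
  expect_gte(lof_enrichment(same)$p_value[1], 0.5)
  expect_warning(lof_enrichment(
    data.frame(group = c("A", "B"), nonfunctional = c(1, 0),
               total = c(4, 0))), "zero total")
})

test_that("classification follows expression floor, majority
           functionality, and the external override", {
  group_map <- data.frame(allele_id = c("x1", "x2", "y1"),
                          group_label = c("A", "A", "B"))
  func <- c(x1 = TRUE, x2 = TRUE, y1 = FALSE)
  expression <- data.frame(
    individual = c("i1", "i2", "i2"),
    allele_group = c("A", "A", "B"),
    normalized_intensity = c(1.2, 0.9, 0.4))
  individuals <- data.frame(individual = c("i1", "i2"),
                            species = c("sp1", "sp2"))
  cats <- classify_alleles(group_map, func, expression, individuals)
  get <- function(g, sp) cats$category[cats$group_label == g &
                                         cats$species == sp]
  expect_equal(get("A", "sp1"), "functional_expressed")
  expect_equal(get("B", "sp1"), "non_expressed")   # only sp2 expresses B
  expect_equal(get("B", "sp2"), "nonfunctional_expressed")
  # external biochemical evidence overrides the ORF scan
  over <- classify_alleles(group_map, func, expression, individuals,
                           nonfunctional_override = "A")
  expect_equal(over$category[over$group_label == "A" &
                               over$species == "sp1"],
               "nonfunctional_expressed")
  expect_error(classify_alleles(group_map, func,
                                transform(expression,
                                          allele_group = "Z"),
                                individuals), "unknown allele group")
})

test_that("ORF scan reproduces the generator's functionality flags", {
  for (s in 1:20) {
    pool <- simulate_allele_pool(
      locus_spec("L", n_codons = 60, n_alleles = 8, lof_rate = 0.4),
      seed = 600 + s)
    ann <- annotate_alleles(c(anc = pool$ancestor, pool$sequences),
                            reference = "anc")
    got <- ann$table$is_functional_cds[match(names(pool$functional),
                                             ann$table$allele_id)]
    expect_identical(got, unname(pool$functional))
  }
})

test_that("NG86 fixed points and symmetry", {
  a <- paste0(rep("ATGTTTGGTCAA", 8), collapse = "")  # 32 codons
  same <- ng86_dnds(a, a)
  expect_equal(same$dN, 0)
  expect_equal(same$dS, 0)
  # one synonymous third-position change: dN = 0, dS > 0
  b <- sub("TTT", "TTC", a)
  r <- ng86_dnds(a, b)
  expect_equal(r$Nd, 0)
  expect_equal(r$Sd, 1)
  expect_equal(r$dN, 0)
  expect_gt(r$dS, 0)
  # symmetry in the arguments
  withr::with_seed(5, {
    for (i in 1:10) {
      s1 <- paste0(replicate(12, random_codon()), collapse = "")
      s2 <- paste0(replicate(12, random_codon()), collapse = "")
      r12 <- ng86_dnds(s1, s2)
      r21 <- ng86_dnds(s2, s1)
      expect_equal(r12$Sd, r21$Sd)
      expect_equal(r12$Nd, r21$Nd)
      expect_equal(r12$S, r21$S)
    }
  })
  # gap codons are removed pairwise
  g <- ng86_dnds(paste0("ATG", "---", "GGT"), paste0("ATG", "AAA", "GGT"))
  expect_equal(g$codons_used, 2)
  expect_error(ng86_dnds("ACGT", "ACGT"), "multiple of 3")
})
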