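# Shared synthetic "worlds": fixed configurations used by the property
# and acceptance tests.  Parameter choices are explained in the methods
# vignette ("The synthetic world behind the acceptance tests").

# Allele-calling recovery world: 800 bp CDS (267 codons), clone error
# 5e-4/base, 3 clones per allele copy, alleles pairwise >= 5 differences
# apart (realised separation ~60 nt so that allele groups are
# identifiable genotyping units at the default group cut).
recovery_config <- function(seed) {
  simulation_config(
    n_species = 3, populations_per_species = 1,
    individuals_per_population = 4,
    loci = list(locus_spec("LX", n_codons = 267, n_alleles = 6,
                           mutations_per_allele = 30, lof_rate = 0.15,
                           min_pairwise_diff = 5)),
    migration_rate = 0.2, clones_per_allele = 3, clone_error_rate = 5e-4,
    seed = seed)
}

# Runs merge -> consensus -> group on one simulated locus and checks that
# every individual's set of genotyping units (allele groups) matches the
# ground truth mapped through the same truth-allele -> group table.
allele_recovery_run <- function(seed, n_boot = 200) {
  ds <- simulate_metapopulation(recovery_config(seed))
  reads <- dataset_clone_reads(ds)
  aset <- merge_clones(reads[, c("id", "sequence", "locus")])
  seqs <- setNames(aset$alleles$consensus, aset$alleles$allele_id)
  if (length(seqs) >= 2) {
    tree <- bootstrap_support(seqs, n_reps = n_boot,
                              seed = derive_seed(seed, 1))
    groups <- assign_allele_groups(tree, locus = "LX")
  } else {
    groups <- data.frame(allele_id = names(seqs), group_label = "A")
  }
  g_of_allele <- setNames(groups$group_label, groups$allele_id)
  read_group <- unname(g_of_allele[aset$membership$allele_id])
  names(read_group) <- aset$membership$read_id
  tag <- reads$true_allele[match(aset$membership$read_id, reads$id)]
  map <- vapply(split(read_group, tag), function(g)
    names(which.max(table(g))), character(1))
  ok <- vapply(split(reads, reads$individual), function(rr) {
    called <- sort(unique(unname(read_group[rr$id])))
    truthg <- sort(unique(unname(map[unique(rr$true_allele)])))
    identical(called, truthg)
  }, logical(1))
  all(ok)
}

# F_ST calibration world: one neutral locus, 3 species x 2 populations x
# 30 diploids, migration 0.2 (expected species-level F_ST 1/(1+c) = 0.25
# under the Dirichlet island device with c = 12 m / (1 - m) = 3).
fst_calibration_config <- function(seed) {
  simulation_config(
    n_species = 3, populations_per_species = 2,
    individuals_per_population = 30,
    loci = list(locus_spec("N1", n_alleles = 6)),
    migration_rate = 0.2, seed = seed)
}

# F_ST contrast world: three neutral loci and one divergently selected
# locus (compact pool of 4 alleles, LoF rate 0.5 so functional and
# nonfunctional sets are both populated).
fst_contrast_config <- function(seed) {
  simulation_config(
    n_species = 3, populations_per_species = 2,
    individuals_per_population = 30,
    loci = list(locus_spec("N1", n_alleles = 6),
                locus_spec("N2", n_alleles = 6),
                locus_spec("N3", n_alleles = 6),
                locus_spec("D1", n_alleles = 4, lof_rate = 0.5,
                           selection = "divergent")),
    migration_rate = 0.2, seed = seed)
}

# Association world: n = 60 individuals (3 species x 2 populations x 10),
# four loci each driving its own compound at the default effect size.
assoc_config <- function(seed) {
  simulation_config(
    n_species = 3, populations_per_species = 2,
    individuals_per_population = 10,
    loci = list(locus_spec("L1"), locus_spec("L2"),
                locus_spec("L3"), locus_spec("L4")),
    migration_rate = 0.2, seed = seed)
}

# Response (ln-shift amounts for one compound) and predictors
# (sqrt summed functional expression per locus, truth functionality) for
# the association tests.
assoc_variables <- function(ds, compound = "alkene_L1") {
  inds <- ds$individuals$individual
  preds <- lapply(names(ds$config$loci), function(l) {
    fun_ids <- names(ds$pools[[l]]$functional)[ds$pools[[l]]$functional]
    ex <- ds$expression[ds$expression$locus == l &
                          ds$expression$allele_group %in% fun_ids, ]
    sums <- tapply(ex$normalized_intensity, ex$individual, sum)
    v <- setNames(rep(0, length(inds)), inds)
    v[names(sums)] <- sums
    apply_transform(unname(v), "sqrt", name = paste0("expr_", l))
  })
  names(preds) <- paste0("expr_", names(ds$config$loci))
  # a locus whose functional alleles are absent or never expressed gives
  # a constant (all-zero) predictor that cannot enter a regression
  keep <- vapply(preds, function(p) var(p$values) > 0, logical(1))
  ph <- ds$phenotype[ds$phenotype$compound == compound, ]
  amt <- setNames(ph$amount_ug, ph$individual)[inds]
  list(response = apply_transform(unname(amt), "ln_shift", name = compound),
       predictors = preds[keep],
       population = ds$individuals$population)
}
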