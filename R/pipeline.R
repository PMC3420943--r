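CANONICAL_TRANSFORMS <- list(amount = "ln_shift",
                             proportion = "arcsin_sqrt",
                             expression = "sqrt")

#' Read a clone FASTA with pipe-separated provenance headers
#'
#' Headers follow `>id|individual|population|species|locus`; sequences use
#' `-` for gaps and `N` for ambiguity.
#'
#' @param path FASTA file.
#' @return data frame `id`, `locus`, `individual`, `population`,
#'   `species`, `sequence`.
#' @export
read_clone_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  bad <- lengths(parts) != 5
  if (any(bad)) {
    stop("malformed FASTA header (need 5 pipe-separated fields): ",
         names(ss)[bad][1])
  }
  m <- do.call(rbind, parts)
  data.frame(id = m[, 1], individual = m[, 2], population = m[, 3],
             species = m[, 4], locus = m[, 5],
             sequence = as.character(ss), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Assemble a pipeline run configuration
#'
#' Validates every threshold before any computation; in particular the
#' dataset-kind-to-transform mapping is enforced (absolute amounts in
#' micrograms must use `ln_shift`, relative proportions `arcsin_sqrt`,
#' expression `sqrt`), so e.g. requesting `arcsin_sqrt` for amounts is a
#' configuration error, not a silent reinterpretation.
#'
#' @param synth optional [simulation_config()]; when given, the pipeline
#'   starts by simulating and writing a dataset.
#' @param input_dir directory holding `clones_<locus>.fasta`,
#'   `expression.tsv` and `phenotype.tsv` when `synth` is `NULL`.
#' @param out_dir output directory.
#' @param d_merge clone merge threshold (nucleotide differences).
#' @param gap_policy gap handling for the merge rule.
#' @param min_support,max_within_distance allele-group cut parameters
#'   (see [assign_allele_groups()]).
#' @param detection_floor expression detection floor.
#' @param n_boot bootstrap pseudo-replicates for group support.
#' @param n_fst_reps diploid-resampling replicates for F_ST.
#' @param fst_grouping `"species"` or `"population"`.
#' @param transforms dataset-kind to transform mapping (must equal the
#'   canonical mapping; present so misconfiguration fails loudly).
#' @param reference optional named list `locus = allele_id` overriding the
#'   automatic reference CDS choice.
#' @param nonfunctional_override character vector of group labels forced
#'   nonfunctional by external evidence.
#' @param seed master seed for every stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(synth = NULL, input_dir = NULL, out_dir,
                       d_merge = 1, gap_policy = "indel_as_diff",
                       min_support = 0.70, max_within_distance = 0.03,
                       detection_floor = 0.05, n_boot = 1000,
                       n_fst_reps = 100, fst_grouping = "species",
                       transforms = CANONICAL_TRANSFORMS,
                       reference = NULL,
                       nonfunctional_override = character(0), seed = 1) {
  if (is.null(synth) && is.null(input_dir)) {
    stop("either a synth simulation_config or an input_dir is required")
  }
  if (!is.null(synth)) stopifnot(inherits(synth, "simulation_config"))
  stopifnot(d_merge >= 0, min_support >= 0, min_support <= 1,
            max_within_distance >= 0, detection_floor >= 0,
            n_boot >= 1, n_fst_reps >= 1)
  fst_grouping <- match.arg(fst_grouping, c("species", "population"))
  for (kind in names(CANONICAL_TRANSFORMS)) {
    got <- transforms[[kind]]
    want <- CANONICAL_TRANSFORMS[[kind]]
    if (is.null(got) || !identical(got, want)) {
      stop("invalid transform for ", kind, " data: got '", got,
           "', the analysis prescribes '", want, "'")
    }
  }
  structure(list(synth = synth, input_dir = input_dir, out_dir = out_dir,
                 d_merge = d_merge, gap_policy = gap_policy,
                 min_support = min_support,
                 max_within_distance = max_within_distance,
                 detection_floor = detection_floor,
                 n_boot = as.integer(n_boot),
                 n_fst_reps = as.integer(n_fst_reps),
                 fst_grouping = fst_grouping, transforms = transforms,
                 reference = reference,
                 nonfunctional_override = nonfunctional_override,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the analysis pipeline
#'
#' Stages execute in order synth (optional) -> allele calling -> LoF
#' annotation -> population genetics -> association, writing every
#' declared table to `config$out_dir` and returning the in-memory results
#' plus a JSON run report.  Identical configurations produce identical
#' outputs.
#'
#' @param config a [run_config()].
#' @param upto last stage to run: one of `"synth"`, `"allelecall"`,
#'   `"annotate"`, `"popgen"`, `"assoc"` (default: the full chain).
#' @return invisibly, a list with per-stage results and the report.
#' @export
run_pipeline <- function(config, upto = "assoc") {
  stopifnot(inherits(config, "run_config"))
  stages <- c("synth", "allelecall", "annotate", "popgen", "assoc")
  upto <- match.arg(upto, stages)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  report <- list(package = "popallele",
                 version = as.character(packageVersion("popallele")),
                 seed = seed, stages = character(0), warnings = character(0))
  note_warning <- function(w) {
    report$warnings <<- c(report$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  results <- list()

  # --- synth ---------------------------------------------------------
  data_dir <- if (!is.null(config$synth)) out else config$input_dir
  if (!is.null(config$synth)) {
    ds <- simulate_metapopulation(config$synth)
    reads <- dataset_clone_reads(ds)
    write_dataset(ds, out, reads)
    results$synth <- ds
    report$stages <- c(report$stages, "synth")
  }
  if (upto == "synth") {
    jsonlite::write_json(report, file.path(out, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(results))
  }

  fasta_files <- sort(list.files(data_dir, pattern = "^clones_.*\\.fasta$",
                                 full.names = TRUE))
  if (length(fasta_files) == 0) {
    stop("stage allelecall: no clones_<locus>.fasta found in ", data_dir)
  }
  reads <- do.call(rbind, lapply(fasta_files, read_clone_fasta))
  expression <- read.delim(file.path(data_dir, "expression.tsv"),
                           stringsAsFactors = FALSE)
  phenotype <- read.delim(file.path(data_dir, "phenotype.tsv"),
                          stringsAsFactors = FALSE)
  individuals <- unique(reads[, c("individual", "population", "species")])

  # --- allelecall ----------------------------------------------------
  loci <- sort(unique(reads$locus))
  calls <- list()
  group_rows <- list()
  for (l in seq_along(loci)) {
    locus <- loci[l]
    sub <- reads[reads$locus == locus, ]
    aset <- merge_clones(sub[, c("id", "sequence", "locus")],
                         d_merge = config$d_merge,
                         gap_policy = config$gap_policy)
    seqs <- setNames(aset$alleles$consensus, aset$alleles$allele_id)
    if (length(seqs) >= 2) {
      tree <- withCallingHandlers(
        bootstrap_support(seqs, n_reps = config$n_boot,
                          seed = derive_seed(seed, 1000 + l)),
        warning = note_warning)
      groups <- assign_allele_groups(tree, config$min_support,
                                     config$max_within_distance,
                                     locus = locus)
      writeLines(upgma_newick(tree),
                 file.path(out, paste0("tree_", locus, ".nwk")))
    } else {
      tree <- NULL
      groups <- data.frame(locus = locus,
                           allele_id = aset$alleles$allele_id,
                           group_label = "A", support = NA_real_,
                           is_singleton = TRUE, stringsAsFactors = FALSE)
    }
    writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))),
               file.path(out, paste0("alleles_", locus, ".fasta")))
    calls[[locus]] <- list(allele_set = aset, tree = tree, groups = groups)
    group_rows[[locus]] <- groups
  }
  allele_groups <- do.call(rbind, group_rows)
  rownames(allele_groups) <- NULL
  write_tsv(allele_groups, file.path(out, "allele_groups.tsv"))
  results$allelecall <- calls
  report$stages <- c(report$stages, "allelecall")

  # map each assay tag (second "__"-field of a read id, the product of
  # allele-specific RT-PCR) to the called group carrying most of its reads
  tag_to_group <- function(locus) {
    aset <- calls[[locus]]$allele_set
    groups <- calls[[locus]]$groups
    mem <- aset$membership
    tags <- vapply(strsplit(mem$read_id, "__", fixed = TRUE), function(p)
      if (length(p) >= 2) p[2] else p[1], character(1))
    grp <- groups$group_label[match(mem$allele_id, groups$allele_id)]
    vapply(split(grp, tags), function(g)
      names(sort(table(g), decreasing = TRUE))[1], character(1))
  }
  map_expression <- function(locus) {
    ex <- expression[expression$locus == locus, ]
    map <- tag_to_group(locus)
    hit <- ex$allele_group %in% names(map)
    ex$allele_group[hit] <- unname(map[ex$allele_group[hit]])
    ex  # rows not in the map are assumed to carry group labels already
  }
  expr_by_group <- do.call(rbind, lapply(loci, map_expression))

  if (upto == "allelecall") {
    jsonlite::write_json(report, file.path(out, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(results))
  }

  # --- annotate ------------------------------------------------------
  lof_rows <- list()
  enr_rows <- list()
  cat_rows <- list()
  dnds_rows <- list()
  functional_groups <- list()
  for (locus in loci) {
    aset <- calls[[locus]]$allele_set
    groups <- calls[[locus]]$groups
    seqs <- setNames(aset$alleles$consensus, aset$alleles$allele_id)
    ref <- config$reference[[locus]] %||% NULL
    ann <- annotate_alleles(seqs, reference = ref)
    lof_rows[[locus]] <- cbind(locus = locus, ann$table,
                               reference = ann$reference)
    func <- setNames(ann$table$is_functional_cds, ann$table$allele_id)
    counts <- aggregate(list(nonfunctional = !func[groups$allele_id]),
                        by = list(group = groups$group_label), FUN = sum)
    counts$total <- as.vector(table(groups$group_label)[counts$group])
    if (nrow(counts) >= 2) {
      enr <- withCallingHandlers(lof_enrichment(counts),
                                 warning = note_warning)
      enr_rows[[locus]] <- cbind(locus = locus, enr)
    }
    cats <- classify_alleles(groups, func,
                             expr_by_group[expr_by_group$locus == locus, ],
                             individuals,
                             detection_floor = config$detection_floor,
                             nonfunctional_override =
                               config$nonfunctional_override)
    cat_rows[[locus]] <- cbind(locus = locus, cats)
    # group-level functionality used by the association stage
    gmaj <- vapply(split(func[groups$allele_id], groups$group_label),
                   function(fl) sum(fl) > sum(!fl), logical(1))
    functional_groups[[locus]] <- names(gmaj)[gmaj &
      !(names(gmaj) %in% config$nonfunctional_override)]
    # pairwise NG86 screen over called alleles
    ids <- names(seqs)
    if (length(ids) >= 2) {
      for (i in seq_len(length(ids) - 1)) {
        for (j in (i + 1):length(ids)) {
          dd <- ng86_dnds(seqs[[ids[i]]], seqs[[ids[j]]])
          dnds_rows[[length(dnds_rows) + 1]] <- data.frame(
            locus = locus, allele_a = ids[i], allele_b = ids[j],
            dN = dd$dN, dS = dd$dS, ratio = dd$ratio,
            flags = paste(dd$flags, collapse = ";"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  lof_tab <- do.call(rbind, lof_rows); rownames(lof_tab) <- NULL
  write_tsv(lof_tab, file.path(out, "lof_annotations.tsv"))
  cat_tab <- do.call(rbind, cat_rows); rownames(cat_tab) <- NULL
  write_tsv(cat_tab, file.path(out, "allele_categories.tsv"))
  if (length(enr_rows) > 0) {
    enr_tab <- do.call(rbind, enr_rows); rownames(enr_tab) <- NULL
    write_tsv(enr_tab, file.path(out, "lof_enrichment.tsv"))
  }
  if (length(dnds_rows) > 0) {
    write_tsv(do.call(rbind, dnds_rows), file.path(out, "dnds_pairs.tsv"))
  }
  results$annotate <- list(lof = lof_tab, categories = cat_tab,
                           functional_groups = functional_groups)
  report$stages <- c(report$stages, "annotate")
  if (upto == "annotate") {
    jsonlite::write_json(report, file.path(out, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(results))
  }

  # --- popgen --------------------------------------------------------
  records <- expressed_groups(expr_by_group, individuals,
                              config$detection_floor)
  fst_rows <- list()
  rep_rows <- list()
  chisq_rows <- list()
  for (l in seq_along(loci)) {
    locus <- loci[l]
    fe <- resampled_fst(records, locus, grouping = config$fst_grouping,
                        n_reps = config$n_fst_reps,
                        seed = derive_seed(seed, 2000 + l))
    fst_rows[[locus]] <- data.frame(
      locus = locus, grouping = fe$grouping, mean = fe$mean, se = fe$se,
      mean_clamped = if (is.na(fe$mean)) NA_real_ else max(fe$mean, 0),
      n_reps = fe$n_reps, n_individuals = fe$n_individuals,
      flags = paste(fe$flags, collapse = ";"), stringsAsFactors = FALSE)
    rep_rows[[locus]] <- data.frame(locus = locus,
                                    replicate = seq_along(fe$replicates),
                                    theta = fe$replicates)
    cats <- cat_rows[[locus]]
    tab <- table(cats$species, cats$category)
    chi <- tryCatch(
      suppressWarnings(category_chisq(tab)),
      error = function(e) NULL)
    if (!is.null(chi)) {
      chisq_rows[[locus]] <- data.frame(locus = locus, chi2 = chi$chi2,
                                        df = chi$df, p = chi$p,
                                        stringsAsFactors = FALSE)
    }
  }
  fst_tab <- do.call(rbind, fst_rows); rownames(fst_tab) <- NULL
  write_tsv(fst_tab, file.path(out, "fst.tsv"))
  write_tsv(do.call(rbind, rep_rows), file.path(out, "fst_replicates.tsv"))
  if (length(chisq_rows) > 0) {
    write_tsv(do.call(rbind, chisq_rows),
              file.path(out, "category_chisq.tsv"))
  }
  results$popgen <- list(fst = fst_tab, records = records)
  report$stages <- c(report$stages, "popgen")
  if (upto == "popgen") {
    jsonlite::write_json(report, file.path(out, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(results))
  }

  # --- assoc ---------------------------------------------------------
  inds <- individuals$individual
  locus_expr <- function(locus) {
    keep <- expr_by_group$locus == locus &
      expr_by_group$allele_group %in% functional_groups[[locus]]
    ex <- expr_by_group[keep, ]
    sums <- tapply(ex$normalized_intensity, ex$individual, sum)
    out <- setNames(rep(0, length(inds)), inds)
    out[names(sums)] <- sums
    out
  }
  predictors <- lapply(setNames(loci, paste0("expr_", loci)), function(l)
    apply_transform(locus_expr(l), "sqrt", name = paste0("expr_", l)))
  assoc_rows <- list()
  step_lines <- character(0)
  for (cmp in sort(unique(phenotype$compound))) {
    ph <- phenotype[phenotype$compound == cmp, ]
    amt <- setNames(ph$amount_ug, ph$individual)[inds]
    y <- apply_transform(unname(amt), config$transforms$amount, name = cmp)
    pop <- individuals$population
    for (kind in c("fixed_only", "random_intercept_population")) {
      fit <- tryCatch(
        if (kind == "fixed_only") fit_association(y, predictors)
        else fit_association(y, predictors, population = pop),
        error = function(e) NULL)
      if (is.null(fit)) next
      assoc_rows[[length(assoc_rows) + 1]] <- data.frame(
        response = cmp, term = fit$term, estimate = fit$estimate,
        p = fit$p, adj_R2 = attr(fit, "adj_r2"), model_kind = kind,
        AIC = attr(fit, "aic"), n = attr(fit, "n"),
        stringsAsFactors = FALSE)
    }
    st <- tryCatch(stepwise_aic(y, predictors), error = function(e) NULL)
    if (!is.null(st)) {
      step_lines <- c(step_lines, paste0("== ", cmp, " (fixed_only) =="),
                      attr(st, "elimination_log"))
      assoc_rows[[length(assoc_rows) + 1]] <- data.frame(
        response = cmp, term = st$term, estimate = st$estimate, p = st$p,
        adj_R2 = attr(st, "adj_r2"), model_kind = "fixed_only_stepwise",
        AIC = attr(st, "aic"), n = attr(st, "n"), stringsAsFactors = FALSE)
    }
  }
  assoc_tab <- do.call(rbind, assoc_rows)
  rownames(assoc_tab) <- NULL
  write_tsv(assoc_tab, file.path(out, "associations.tsv"))
  writeLines(step_lines, file.path(out, "stepwise_log.txt"))
  results$assoc <- assoc_tab
  report$stages <- c(report$stages, "assoc")

  report$headline <- list(
    n_loci = length(loci),
    n_alleles = nrow(allele_groups),
    n_groups = length(unique(paste(allele_groups$locus,
                                   allele_groups$group_label))),
    fst = fst_tab[, c("locus", "mean", "se")])
  jsonlite::write_json(report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  results$report <- report
  invisible(results)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `call-alleles`, `annotate`, `fst`,
#' `associate`, `run-all`.  Each reads a declarative JSON configuration
#' (`--config`), optionally overridden by `--seed` and `--out`, and runs
#' the chain up to the requested stage.  Logs go to stderr.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return invisibly, the [run_pipeline()] result.
#' @export
pa_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: popallele <simulate|call-alleles|annotate|fst|associate|run-all>",
    "--config FILE [--out DIR] [--seed INT]")
  if (length(args) < 1) stop(usage, call. = FALSE)
  sub <- args[1]
  upto <- switch(sub, simulate = "synth", `call-alleles` = "allelecall",
                 annotate = "annotate", fst = "popgen",
                 associate = "assoc", `run-all` = "assoc",
                 stop(usage, call. = FALSE))
  opt <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% c("config", "out", "seed")) stop(usage, call. = FALSE)
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  if (is.null(opt$config)) stop(usage, call. = FALSE)
  cfg_json <- jsonlite::read_json(opt$config, simplifyVector = TRUE)
  synth <- NULL
  if (!is.null(cfg_json$synth)) {
    s <- cfg_json$synth
    loci <- lapply(seq_len(nrow(s$loci)), function(i)
      do.call(locus_spec, as.list(s$loci[i, ])))
    s$loci <- NULL
    synth <- do.call(simulation_config, c(s, list(loci = loci)))
  }
  cfg_json$synth <- NULL
  if (!is.null(opt$out)) cfg_json$out_dir <- opt$out
  if (!is.null(opt$seed)) {
    cfg_json$seed <- as.integer(opt$seed)
    if (!is.null(synth)) synth$seed <- as.integer(opt$seed)
  }
  config <- do.call(run_config, c(cfg_json, list(synth = synth)))
  message("popallele: running up to stage '", upto, "' into ",
          config$out_dir)
  invisible(run_pipeline(config, upto = upto))
}
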