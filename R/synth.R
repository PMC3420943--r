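#' Specify one simulated locus
#'
#' A locus is described by the length of its ancestral coding sequence, the
#' expected number of point mutations separating each allele from the
#' ancestor (a per-lineage scaled mutation count; the realised number is
#' Poisson), a per-allele loss-of-function rate, and a selection mode.
#' Under `"divergent"` selection the functional-allele frequency differs
#' between species lineages; under `"neutral"` allele frequencies follow
#' the island model controlled by the metapopulation migration rate.
#'
#' @param name locus name (used in file names and ids).
#' @param n_codons ancestral CDS length in codons (incl. start and stop);
#'   must be >= 30.
#' @param n_alleles number of alleles in the species-wide pool.
#' @param mutations_per_allele expected point mutations per allele lineage.
#' @param lof_rate probability that an allele carries an injected
#'   loss-of-function lesion (premature stop or frame-shifting deletion).
#' @param selection `"neutral"` or `"divergent"`.
#' @param min_pairwise_diff minimum nucleotide difference enforced between
#'   any two alleles of the pool (0 = no floor).
#' @return a `locus_spec` list.
#' @export
locus_spec <- function(name, n_codons = 100, n_alleles = 6,
                       mutations_per_allele = 5, lof_rate = 0.15,
                       selection = c("neutral", "divergent"),
                       min_pairwise_diff = 0) {
  selection <- match.arg(selection)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (n_codons < 30) {
    stop("locus '", name, "': CDS length must be at least 30 codons")
  }
  stopifnot(n_alleles >= 1, mutations_per_allele >= 0,
            lof_rate >= 0, lof_rate <= 1, min_pairwise_diff >= 0)
  structure(list(name = name, n_codons = as.integer(n_codons),
                 n_alleles = as.integer(n_alleles),
                 mutations_per_allele = mutations_per_allele,
                 lof_rate = lof_rate, selection = selection,
                 min_pairwise_diff = as.integer(min_pairwise_diff)),
            class = "locus_spec")
}

#' Configure a synthetic metapopulation
#'
#' The generator emulates diploid individuals sampled from an island-model
#' metapopulation of several species, each with several populations.
#' Species allele frequencies are drawn from a Dirichlet centred on global
#' base frequencies with concentration controlled by `migration_rate`
#' (a Balding-Nichols-style device: concentration `c = 12 m / (1 - m)`, so
#' the expected species-level F_ST is `1 / (1 + c)`); population
#' frequencies are a mild Dirichlet perturbation of their species'
#' frequencies.  Expression of a carried allele is a non-negative
#' lognormal "normalized band intensity" gated by a per-species x per-locus
#' regulatory on/off state; the compound amount for the compound driven by
#' a locus is `expression_effect` times the summed expression of the
#' individual's functional alleles at that locus plus Gaussian noise
#' (truncated at zero, amounts being mass in micrograms).
#'
#' @param n_species number of species lineages (>= 1).
#' @param populations_per_species populations sampled per species.
#' @param individuals_per_population diploid individuals per population.
#' @param loci list of [locus_spec()] objects.
#' @param migration_rate per-generation migrant proportion in `[0, 1]`;
#'   1 means panmixia among species lineages, 0 fixes each lineage.
#' @param clones_per_allele cloned reads sequenced per allele copy.
#' @param clone_error_rate per-base substitution probability of a clone
#'   read.
#' @param expression_effect slope of compound amount (ug) per unit summed
#'   functional expression.
#' @param noise_sd standard deviation (ug) of phenotype noise.
#' @param regulation optional data frame `(species, locus, on)` switching
#'   expression of a locus off (`on = 0`) in a species; default all on.
#' @param seed master seed fixing every downstream draw.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_species = 3, populations_per_species = 2,
                              individuals_per_population = 8,
                              loci = list(locus_spec("L1"), locus_spec("L2")),
                              migration_rate = 0.2, clones_per_allele = 3,
                              clone_error_rate = 5e-4,
                              expression_effect = 2, noise_sd = 0.5,
                              regulation = NULL, seed = 1) {
  stopifnot(n_species >= 1, populations_per_species >= 1,
            individuals_per_population >= 1, clones_per_allele >= 1)
  stopifnot(migration_rate >= 0, migration_rate <= 1,
            clone_error_rate >= 0, clone_error_rate <= 1, noise_sd >= 0)
  stopifnot(length(loci) >= 1,
            all(vapply(loci, inherits, logical(1), "locus_spec")))
  lnames <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(lnames)) stop("duplicate locus names")
  names(loci) <- lnames
  structure(list(n_species = as.integer(n_species),
                 populations_per_species = as.integer(populations_per_species),
                 individuals_per_population = as.integer(individuals_per_population),
                 loci = loci, migration_rate = migration_rate,
                 clones_per_allele = as.integer(clones_per_allele),
                 clone_error_rate = clone_error_rate,
                 expression_effect = expression_effect, noise_sd = noise_sd,
                 regulation = regulation, seed = as.integer(seed)),
            class = "simulation_config")
}

random_cds <- function(n_codons) {
  non_stop <- setdiff(apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES),
                            1, paste0, collapse = ""), STOP_CODONS)
  body <- sample(non_stop, n_codons - 2, replace = TRUE)
  paste0("ATG", paste0(body, collapse = ""), sample(STOP_CODONS, 1))
}

# Internal stop scan on the degapped sequence (terminal codon excluded).
has_internal_stop <- function(chars) {
  s <- chars[chars != "-"]
  n <- floor(length(s) / 3)
  if (n < 2) return(FALSE)
  starts <- seq(1, by = 3, length.out = n - 1)
  cods <- vapply(starts, function(i) paste0(s[i:(i + 2)], collapse = ""),
                 character(1))
  any(cods %in% STOP_CODONS)
}

count_diff <- function(a, b) {
  sum((a %in% DNA_BASES | a == "-") & (b %in% DNA_BASES | b == "-") & a != b)
}

#' Simulate the allele pool of one locus
#'
#' Alleles are derived from a random ancestral CDS by Poisson numbers of
#' point mutations at internal sites (start and terminal stop codons are
#' kept intact; mutation sets that create an internal stop in a functional
#' allele are redrawn).  With probability `lof_rate` an allele additionally
#' receives a loss-of-function lesion: either an internal stop codon
#' substitution or a 1-2 bp deletion (a frame-shifting indel, encoded as
#' `-` in the ancestor-aligned sequence).  Functional alleles contain
#' neither lesion.
#'
#' @param spec a [locus_spec()].
#' @param seed integer seed.
#' @return an `allele_pool` list with elements `locus`, `ancestor`,
#'   `sequences` (named, ancestor-aligned) and `functional` (named logical).
#' @export
simulate_allele_pool <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "locus_spec"))
  if (spec$n_codons < 30) {
    stop("locus '", spec$name, "': CDS length must be at least 30 codons")
  }
  with_seed(seed, {
    anc <- seq_chars(random_cds(spec$n_codons))
    L <- length(anc)
    mutable <- 4:(L - 3)  # spare start codon and terminal stop
    seqs <- character(spec$n_alleles)
    func <- logical(spec$n_alleles)
    kept <- list()
    for (i in seq_len(spec$n_alleles)) {
      # draw the mutation count once so rejection (below) does not thin
      # the Poisson toward smaller counts; rejections redraw positions
      # and target bases only (escape hatch after many tries)
      k <- min(rpois(1, spec$mutations_per_allele), length(mutable))
      for (try in seq_len(500)) {
        if (try %% 250 == 0) {
          k <- min(rpois(1, spec$mutations_per_allele), length(mutable))
        }
        s <- anc
        if (k > 0) {
          pos <- sample(mutable, k)
          s[pos] <- vapply(s[pos], function(old)
            sample(setdiff(DNA_BASES, old), 1), character(1))
        }
        if (has_internal_stop(s)) next
        is_func <- runif(1) >= spec$lof_rate
        if (!is_func) {
          if (runif(1) < 0.5) {  # premature stop substitution
            cod <- sample(2:(spec$n_codons - 1), 1)
            s[(3 * cod - 2):(3 * cod)] <- seq_chars(sample(STOP_CODONS, 1))
          } else {               # frame-shifting deletion of 1 or 2 bp
            len <- sample(1:2, 1)
            at <- sample(4:(L - 3 - len), 1)
            s[at:(at + len - 1)] <- "-"
          }
        }
        if (spec$min_pairwise_diff > 0 && length(kept) > 0) {
          d <- vapply(kept, count_diff, integer(1), b = s)
          if (any(d < spec$min_pairwise_diff)) next
        }
        kept[[i]] <- s
        seqs[i] <- paste0(s, collapse = "")
        func[i] <- is_func
        break
      }
      if (seqs[i] == "") {
        stop("locus '", spec$name, "': could not generate allele ", i,
             " satisfying min_pairwise_diff = ", spec$min_pairwise_diff)
      }
    }
    ids <- sprintf("%s.a%02d", spec$name, seq_len(spec$n_alleles))
    structure(list(locus = spec$name,
                   ancestor = paste0(anc, collapse = ""),
                   sequences = setNames(seqs, ids),
                   functional = setNames(func, ids), spec = spec),
              class = "allele_pool")
  })
}

# Parametric F_ST from realized per-group allele frequencies: the
# large-sample limit of the Weir-Cockerham estimand,
#   sum_a s2_a / sum_a (pbar_a (1 - pbar_a) + s2_a / r),
# with s2_a the (r - 1)-divisor among-group variance (equal group
# weights).  Equals 1 for groups fixed for disjoint alleles and 0 for
# identical frequencies, and is what the genotype-level theta estimator
# converges to as per-group sample size grows.
parametric_fst <- function(freq_by_group) {
  stopifnot(is.matrix(freq_by_group), nrow(freq_by_group) >= 2)
  r <- nrow(freq_by_group)
  pbar <- colMeans(freq_by_group)
  s2 <- colSums(sweep(freq_by_group, 2, pbar)^2) / (r - 1)
  den <- sum(pbar * (1 - pbar) + s2 / r)
  if (den == 0) return(NA_real_)
  max(0, min(1, sum(s2) / den))
}

# Realized allele frequencies of one locus per grouping level.
realized_freqs <- function(genotypes, individuals, locus_name, by) {
  g <- genotypes[genotypes$locus == locus_name, ]
  g$grp <- individuals[[by]][match(g$individual, individuals$individual)]
  alleles <- sort(unique(c(g$allele1, g$allele2)))
  lev <- sort(unique(g$grp))
  f <- matrix(0, length(lev), length(alleles),
              dimnames = list(lev, alleles))
  for (s in lev) {
    x <- c(g$allele1[g$grp == s], g$allele2[g$grp == s])
    f[s, ] <- tabulate(factor(x, levels = alleles),
                       nbins = length(alleles)) / length(x)
  }
  f
}

#' Simulate a complete synthetic dataset
#'
#' Runs the island-model metapopulation simulation described in
#' [simulation_config()] and returns the in-memory dataset together with a
#' ground-truth ledger (true diploid genotypes, true allele functionality,
#' realized parametric F_ST per locus at species and population level, and
#' the true expression-to-phenotype slope).  Identical configurations
#' (including the seed) yield byte-identical outputs.
#'
#' @param config a [simulation_config()].
#' @return a `synthetic_metapop` list with elements `individuals`, `pools`,
#'   `genotypes`, `expression`, `phenotype`, `truth`, `config`.
#' @export
simulate_metapopulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- config$seed
  sp_names <- sprintf("sp%d", seq_len(config$n_species))
  individuals <- do.call(rbind, lapply(seq_len(config$n_species), function(s) {
    do.call(rbind, lapply(seq_len(config$populations_per_species), function(p) {
      data.frame(
        individual = sprintf("%s_p%d_i%02d", sp_names[s], p,
                             seq_len(config$individuals_per_population)),
        population = sprintf("%s_p%d", sp_names[s], p),
        species = sp_names[s], stringsAsFactors = FALSE)
    }))
  }))

  pools <- list()
  genotypes <- list()
  fst_truth <- list()
  m <- config$migration_rate
  conc <- if (m >= 1) Inf else 12 * m / (1 - m)
  within_conc <- 300  # mild within-species population perturbation

  for (l in seq_along(config$loci)) {
    spec <- config$loci[[l]]
    pool <- simulate_allele_pool(spec, derive_seed(seed, 100 + l))
    pools[[spec$name]] <- pool
    K <- spec$n_alleles
    ids <- names(pool$sequences)

    gl <- with_seed(derive_seed(seed, 200 + l), {
      p_global <- rdirichlet1(rep(2, K))
      p_species <- matrix(0, config$n_species, K,
                          dimnames = list(sp_names, ids))
      for (s in seq_len(config$n_species)) {
        if (spec$selection == "divergent") {
          fun_set <- which(pool$functional)
          nul_set <- which(!pool$functional)
          if (length(fun_set) == 0 || length(nul_set) == 0) {
            fun_set <- seq_len(ceiling(K / 2))   # fallback: first half
            nul_set <- setdiff(seq_len(K), fun_set)
          }
          w <- if (s %% 2 == 1) 0.95 else 0.05  # alternating species mass
          # selection overwhelms migration at the selected locus: each
          # lineage sweeps toward its locally favoured variant, so
          # within-set frequencies are drawn sweep-like (concentration 1)
          # rather than at the neutral island concentration
          conc_sel <- 1
          draw_set <- function(set, mass) {
            base <- p_global[set] / sum(p_global[set])
            q <- rdirichlet1(conc_sel * base)
            mass * q
          }
          p_species[s, fun_set] <- draw_set(fun_set, w)
          p_species[s, nul_set] <- draw_set(nul_set, 1 - w)
        } else {
          p_species[s, ] <- if (is.infinite(conc)) p_global else if (conc == 0) {
            v <- numeric(K); v[sample.int(K, 1, prob = p_global)] <- 1; v
          } else rdirichlet1(conc * p_global)
        }
      }
      g <- vector("list", nrow(individuals))
      pops <- unique(individuals[, c("population", "species")])
      p_pop <- matrix(0, nrow(pops), K, dimnames = list(pops$population, ids))
      for (q in seq_len(nrow(pops))) {
        ps <- p_species[pops$species[q], ]
        p_pop[q, ] <- if (all(ps %in% c(0, 1))) ps else
          rdirichlet1(within_conc * ps)
      }
      for (i in seq_len(nrow(individuals))) {
        pr <- p_pop[individuals$population[i], ]
        a <- sample(ids, 2, replace = TRUE, prob = pr)
        g[[i]] <- sort(a)
      }
      gmat <- do.call(rbind, g)
      data.frame(individual = individuals$individual, locus = spec$name,
                 allele1 = gmat[, 1], allele2 = gmat[, 2],
                 stringsAsFactors = FALSE)
    })
    genotypes[[spec$name]] <- gl
    fst_truth[[spec$name]] <- list(
      species = parametric_fst(realized_freqs(gl, individuals, spec$name,
                                              "species")),
      population = parametric_fst(realized_freqs(gl, individuals, spec$name,
                                                 "population")))
  }
  genotypes <- do.call(rbind, genotypes)
  rownames(genotypes) <- NULL

  reg_on <- function(sp, locus) {
    if (is.null(config$regulation)) return(1)
    hit <- config$regulation$species == sp & config$regulation$locus == locus
    if (!any(hit)) 1 else as.numeric(config$regulation$on[hit][1])
  }

  expression <- with_seed(derive_seed(seed, 400), {
    rows <- lapply(names(config$loci), function(l) {
      gl <- genotypes[genotypes$locus == l, ]
      long <- data.frame(individual = rep(gl$individual, 2),
                         allele_group = c(gl$allele1, gl$allele2),
                         stringsAsFactors = FALSE)
      key <- paste(long$individual, long$allele_group, sep = "\r")
      copies <- table(key)
      uniq <- long[!duplicated(key), ]
      uniq <- uniq[order(uniq$individual, uniq$allele_group), ]
      ukey <- paste(uniq$individual, uniq$allele_group, sep = "\r")
      sp <- individuals$species[match(uniq$individual,
                                      individuals$individual)]
      on <- vapply(sp, reg_on, numeric(1), locus = l)
      data.frame(individual = uniq$individual, locus = l,
                 allele_group = uniq$allele_group,
                 normalized_intensity =
                   on * as.integer(copies[ukey]) *
                   rlnorm(nrow(uniq), 0, 0.25),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rownames(expression) <- NULL

  phenotype <- with_seed(derive_seed(seed, 500), {
    rows <- lapply(names(config$loci), function(l) {
      pool <- pools[[l]]
      ex <- expression[expression$locus == l, ]
      fun_ids <- names(pool$functional)[pool$functional]
      ex <- ex[ex$allele_group %in% fun_ids, ]
      sums <- tapply(ex$normalized_intensity, ex$individual, sum)
      per_ind <- setNames(rep(0, nrow(individuals)),
                          individuals$individual)
      per_ind[names(sums)] <- sums
      amount <- pmax(0, config$expression_effect * per_ind +
                        rnorm(nrow(individuals), 0, config$noise_sd))
      data.frame(individual = individuals$individual,
                 compound = paste0("alkene_", l),
                 amount_ug = unname(amount), stringsAsFactors = FALSE)
    })
    ph <- do.call(rbind, rows)
    tot <- tapply(ph$amount_ug, ph$individual, sum)
    ph$relative_proportion <- ifelse(tot[ph$individual] > 0,
                                     ph$amount_ug / tot[ph$individual], 0)
    ph
  })
  rownames(phenotype) <- NULL

  truth <- list(
    genotypes = genotypes,
    functional = lapply(pools, function(p) as.list(p$functional)),
    fst_parametric = fst_truth,
    expression_effect = config$expression_effect,
    causal_map = setNames(paste0("alkene_", names(config$loci)),
                          names(config$loci)))

  structure(list(individuals = individuals, pools = pools,
                 genotypes = genotypes, expression = expression,
                 phenotype = phenotype, truth = truth, config = config),
            class = "synthetic_metapop")
}

#' Generate clone reads for one individual at one locus
#'
#' Each of the two allele copies yields `clones_per_allele` reads; each
#' read is the allele sequence with independent per-base substitution
#' errors at `error_rate` (gap positions are never mutated).  Read ids
#' encode individual and source-allele assay tag as
#' `<individual>__<allele>__c<k>`; FASTA headers additionally carry
#' population, species and locus (pipe-separated).
#'
#' @param allele_seqs named character vector of the two allele-copy
#'   sequences (names repeated for homozygotes).
#' @param individual,population,species,locus provenance strings.
#' @param clones_per_allele reads per allele copy.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return data frame of clone reads (`id`, `locus`, `individual`,
#'   `population`, `species`, `sequence`, `true_allele`).
#' @export
generate_clone_reads <- function(allele_seqs, individual, population,
                                 species, locus, clones_per_allele = 3,
                                 error_rate = 5e-4, seed = 1) {
  stopifnot(length(allele_seqs) == 2, !is.null(names(allele_seqs)))
  with_seed(seed, {
    out <- list()
    k <- 0
    for (copy in 1:2) {
      chars <- seq_chars(allele_seqs[[copy]])
      mutable <- which(chars %in% DNA_BASES)
      for (cl in seq_len(clones_per_allele)) {
        k <- k + 1
        s <- chars
        hit <- mutable[runif(length(mutable)) < error_rate]
        if (length(hit) > 0) {
          s[hit] <- vapply(s[hit], function(old)
            sample(setdiff(DNA_BASES, old), 1), character(1))
        }
        out[[k]] <- data.frame(
          id = sprintf("%s__%s__c%d", individual, names(allele_seqs)[copy], k),
          locus = locus, individual = individual, population = population,
          species = species, sequence = paste0(s, collapse = ""),
          true_allele = names(allele_seqs)[copy], stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Generate clone reads for a whole synthetic dataset
#'
#' @param ds a `synthetic_metapop` from [simulate_metapopulation()].
#' @return data frame of clone reads for every individual and locus.
#' @export
dataset_clone_reads <- function(ds) {
  stopifnot(inherits(ds, "synthetic_metapop"))
  cfg <- ds$config
  out <- list()
  for (l in seq_along(cfg$loci)) {
    locus <- names(cfg$loci)[l]
    pool <- ds$pools[[locus]]
    gl <- ds$genotypes[ds$genotypes$locus == locus, ]
    for (i in seq_len(nrow(gl))) {
      ind <- gl$individual[i]
      row <- ds$individuals[match(ind, ds$individuals$individual), ]
      pair <- c(gl$allele1[i], gl$allele2[i])
      out[[length(out) + 1]] <- generate_clone_reads(
        setNames(pool$sequences[pair], pair), ind, row$population,
        row$species, locus, cfg$clones_per_allele, cfg$clone_error_rate,
        derive_seed(cfg$seed, 600 + l * 10000 + i))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a synthetic dataset to disk
#'
#' Emits one clone FASTA per locus (headers
#' `>id|individual|population|species|locus`), `expression.tsv`,
#' `phenotype.tsv` and `truth.json`.
#'
#' @param ds a `synthetic_metapop`.
#' @param dir output directory (created if needed).
#' @param reads optional precomputed read table from
#'   [dataset_clone_reads()]; generated on the fly when `NULL`.
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(ds, dir, reads = NULL) {
  stopifnot(inherits(ds, "synthetic_metapop"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reads <- reads %||% dataset_clone_reads(ds)
  files <- character(0)
  for (locus in names(ds$config$loci)) {
    sub <- reads[reads$locus == locus, ]
    hdr <- sprintf("%s|%s|%s|%s|%s", sub$id, sub$individual,
                   sub$population, sub$species, sub$locus)
    path <- file.path(dir, paste0("clones_", locus, ".fasta"))
    writeLines(as.vector(rbind(paste0(">", hdr), sub$sequence)), path)
    files <- c(files, path)
  }
  f1 <- file.path(dir, "expression.tsv")
  write_tsv(ds$expression, f1)
  f2 <- file.path(dir, "phenotype.tsv")
  write_tsv(ds$phenotype, f2)
  f3 <- file.path(dir, "truth.json")
  jsonlite::write_json(ds$truth, f3, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(files, f1, f2, f3))
}
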