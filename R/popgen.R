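#' Multiallelic Weir-Cockerham F_ST (theta)
#'
#' Variance-components estimator of Weir & Cockerham (1984) for diploid
#' genotypic data at one multiallelic locus: per-allele components `a`
#' (among populations), `b` (among individuals within populations) and
#' `c` (within individuals) are summed over alleles and
#' `theta = sum(a) / sum(a + b + c)`.  The estimate is not truncated at
#' zero (negative estimates are informative for calibration); a
#' monomorphic locus yields `NaN` with a `"monomorphic"` flag.
#'
#' @param population vector of population labels, one per individual.
#' @param allele1,allele2 vectors of allele labels (the two copies of each
#'   diploid individual).
#' @return a `wc_fst` list: `theta`, component sums `a`, `b`, `c`,
#'   `n_pops`, `n_alleles`, `flag` (`NULL` when estimable).
#' @export
wc_fst <- function(population, allele1, allele2) {
  stopifnot(length(population) == length(allele1),
            length(allele1) == length(allele2))
  pop <- factor(population)
  r <- nlevels(pop)
  if (r < 2) stop("need at least 2 populations")
  alleles <- sort(unique(c(as.character(allele1), as.character(allele2))))
  res <- function(theta, a = NA_real_, b = NA_real_, cc = NA_real_,
                  flag = NULL) {
    structure(list(theta = theta, a = a, b = b, c = cc, n_pops = r,
                   n_alleles = length(alleles), flag = flag),
              class = "wc_fst")
  }
  if (length(alleles) < 2) return(res(NaN, flag = "monomorphic"))
  n_i <- as.vector(table(pop))
  if (any(n_i < 1)) stop("every population needs at least one individual")
  N <- sum(n_i)
  nbar <- N / r
  if (nbar <= 1) return(res(NaN, flag = "insufficient_sample"))
  n_c <- (N - sum(n_i^2) / N) / (r - 1)
  a1 <- as.character(allele1)
  a2 <- as.character(allele2)
  suma <- sumb <- sumc <- 0
  for (A in alleles) {
    x_i <- tapply((a1 == A) + (a2 == A), pop, sum)          # allele copies
    h_i <- tapply((a1 == A) + (a2 == A) == 1, pop, mean)    # het. proportion
    p_i <- x_i / (2 * n_i)
    pbar <- sum(n_i * p_i) / N
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / N
    a <- (nbar / n_c) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    suma <- suma + a
    sumb <- sumb + b
    sumc <- sumc + cc
  }
  den <- suma + sumb + sumc
  if (den == 0) return(res(NaN, suma, sumb, sumc, flag = "zero_variance"))
  res(suma / den, suma, sumb, sumc)
}

#' @export
print.wc_fst <- function(x, ...) {
  cat(sprintf("Weir-Cockerham theta = %s (%d populations, %d alleles)%s\n",
              format(x$theta, digits = 4), x$n_pops, x$n_alleles,
              if (is.null(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' Resample one diploid genotype from an expressed allele-group set
#'
#' One expressed group makes the individual homozygous; two give one copy
#' of each; more than two expressed groups (possible under gel
#' misassignment) are resolved by drawing two uniformly without
#' replacement.  Uses the current RNG state; seed the caller for
#' determinism.
#'
#' @param expressed character vector of expressed allele-group labels.
#' @return sorted character vector of length 2, or `NULL` (with a
#'   message-level log) for an empty set.
#' @export
resample_diploid_genotype <- function(expressed) {
  expressed <- unique(expressed)
  n <- length(expressed)
  if (n == 0) return(NULL)
  if (n == 1) return(c(expressed, expressed))
  if (n == 2) return(sort(expressed))
  sort(sample(expressed, 2, replace = FALSE))
}

#' Build the expressed-genotype table from expression data
#'
#' One row per (individual, locus, expressed group): the groups whose
#' normalized intensity exceeds the detection floor.
#'
#' @param expression data frame `individual`, `locus`, `allele_group`,
#'   `normalized_intensity`.
#' @param individuals data frame `individual`, `population`, `species`.
#' @param detection_floor expression detection floor (default 0.05).
#' @return data frame `individual`, `population`, `species`, `locus`,
#'   `group`.
#' @export
expressed_groups <- function(expression, individuals,
                             detection_floor = 0.05) {
  keep <- expression$normalized_intensity > detection_floor
  ex <- unique(expression[keep, c("individual", "locus", "allele_group")])
  ix <- match(ex$individual, individuals$individual)
  data.frame(individual = ex$individual,
             population = individuals$population[ix],
             species = individuals$species[ix],
             locus = ex$locus, group = ex$allele_group,
             stringsAsFactors = FALSE)
}

#' Resampled F_ST for one locus
#'
#' Implements the in-silico diploid resampling scheme: in each replicate
#' every genotypable individual's diploid genotype is redrawn from its
#' expressed allele-group set ([resample_diploid_genotype()]) and
#' Weir-Cockerham theta is computed; the replicate list, mean and standard
#' error (`sd / sqrt(n_reps)`) are reported.  Individuals with an empty
#' expressed set are excluded for the locus (logged, not an error); a
#' locus expressed in fewer than two groups of the chosen grouping is
#' reported inestimable.
#'
#' @param records expressed-genotype table from [expressed_groups()].
#' @param locus locus to analyse.
#' @param grouping `"species"` or `"population"`.
#' @param n_reps number of resampling replicates (default 100).
#' @param seed master seed; replicate r uses the derived stream
#'   `derive_seed(seed, r)`.
#' @return an `fst_estimate`: `locus`, `grouping`, `replicates`, `mean`,
#'   `se`, `n_reps`, `n_individuals`, `flags`.
#' @export
resampled_fst <- function(records, locus, grouping = c("species",
                                                       "population"),
                          n_reps = 100, seed = 1) {
  grouping <- match.arg(grouping)
  stopifnot(n_reps >= 1)
  sub <- records[records$locus == locus, ]
  est <- function(replicates, flags = character(0), n_ind = 0L) {
    fin <- replicates[is.finite(replicates)]
    structure(list(locus = locus, grouping = grouping,
                   replicates = replicates,
                   mean = if (length(fin)) mean(fin) else NA_real_,
                   se = if (length(fin) > 1) sd(fin) / sqrt(length(fin))
                        else if (length(fin) == 1) 0 else NA_real_,
                   n_reps = n_reps, n_individuals = n_ind, flags = flags),
              class = "fst_estimate")
  }
  if (nrow(sub) == 0) {
    return(est(rep(NA_real_, n_reps), flags = "inestimable"))
  }
  sets <- split(sub$group, sub$individual)
  grp_of <- vapply(names(sets), function(id)
    sub[[grouping]][match(id, sub$individual)], character(1))
  if (length(unique(grp_of)) < 2) {
    return(est(rep(NA_real_, n_reps), flags = "inestimable",
               n_ind = length(sets)))
  }
  ambiguous <- vapply(sets, function(s) length(unique(s)) > 2, logical(1))
  fixed <- lapply(sets[!ambiguous], resample_diploid_genotype)
  reps <- numeric(n_reps)
  flags <- character(0)
  for (rep in seq_len(n_reps)) {
    drawn <- if (any(ambiguous)) {
      with_seed(derive_seed(seed, rep),
                lapply(sets[ambiguous], resample_diploid_genotype))
    } else list()
    g <- c(fixed, drawn)
    a1 <- vapply(g, `[`, character(1), 1)
    a2 <- vapply(g, `[`, character(1), 2)
    th <- wc_fst(grp_of[names(g)], a1, a2)
    reps[rep] <- th$theta
    if (!is.null(th$flag)) flags <- unique(c(flags, th$flag))
  }
  est(reps, flags = flags, n_ind = length(sets))
}

#' @export
print.fst_estimate <- function(x, ...) {
  if ("inestimable" %in% x$flags) {
    cat(sprintf("F_ST[%s by %s]: inestimable\n", x$locus, x$grouping))
  } else {
    cat(sprintf("F_ST[%s by %s] = %.4f +/- %.4f (SE, %d replicates)%s\n",
                x$locus, x$grouping, x$mean, x$se, x$n_reps,
                if (length(x$flags)) paste0(" [",
                  paste(x$flags, collapse = ","), "]") else ""))
  }
  invisible(x)
}

#' Chi-squared test of a species x category contingency table
#'
#' Pearson chi-squared with `df = (r - 1)(c - 1)`.  Rows or columns with a
#' zero marginal are dropped with a warning; expected counts below 5
#' trigger a small-sample warning and, when `monte_carlo = TRUE`, a seeded
#' Monte-Carlo p-value from tables drawn with fixed margins.
#'
#' @param counts contingency matrix (>= 2 rows and columns after
#'   dropping zero margins).
#' @param monte_carlo also compute a Monte-Carlo p-value.
#' @param n_sim Monte-Carlo table draws (default 10000).
#' @param seed seed for the Monte-Carlo draw.
#' @return list `chi2`, `df`, `p`, `expected`, `p_mc` (NULL unless
#'   requested), `warnings`.
#' @export
category_chisq <- function(counts, monte_carlo = FALSE, n_sim = 10000,
                           seed = 1) {
  counts <- as.matrix(counts)
  warnings <- character(0)
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warnings <- c(warnings, "zero-margin rows/columns dropped")
    warning("zero-margin rows/columns dropped")
    counts <- counts[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("need a table with at least 2 rows and 2 columns")
  }
  n <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  chi2 <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  p <- pchisq(chi2, df, lower.tail = FALSE)
  if (any(expected < 5)) {
    warnings <- c(warnings, "expected counts < 5")
    warning("expected counts < 5; consider the Monte-Carlo p-value")
  }
  p_mc <- NULL
  if (monte_carlo) {
    p_mc <- with_seed(seed, {
      sims <- r2dtable(n_sim, rowSums(counts), colSums(counts))
      stat <- vapply(sims, function(tb)
        sum((tb - expected)^2 / expected), numeric(1))
      (1 + sum(stat >= chi2 - 1e-9)) / (n_sim + 1)
    })
  }
  list(chi2 = chi2, df = df, p = p, expected = expected, p_mc = p_mc,
       warnings = warnings)
}
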