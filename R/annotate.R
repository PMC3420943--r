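#' Scan an allele CDS for loss-of-function lesions
#'
#' The allele must be aligned to a designated functional reference CDS of
#' the same locus.  Three lesion kinds are recorded:
#'
#' * `frameshift_indel`: any gap run (in either sequence) whose length is
#'   not a multiple of 3, at the 1-based alignment column of the run start;
#' * `premature_stop`: an in-frame stop codon of the allele strictly
#'   upstream of the reference stop (the reading frame is tracked through
#'   prior indels because codons are read off the degapped allele);
#' * `start_loss`: the allele's first codon is not `ATG`.
#'
#' @param allele_cds aligned allele sequence (string).
#' @param reference_cds aligned reference sequence (string); must have an
#'   intact start and no internal stop, else a configuration error.
#' @param allele_id optional id recorded on the result.
#' @return a `lof_annotation`: list with `allele_id`, `events` (data frame
#'   `kind`, `position`) and `is_functional_cds` (TRUE iff no events).
#' @export
scan_orf <- function(allele_cds, reference_cds, allele_id = NA_character_) {
  a <- seq_chars(allele_cds)
  r <- seq_chars(reference_cds)
  if (length(a) != length(r)) {
    stop("alignment error: allele and reference have different lengths")
  }
  rg <- r[r != "-"]
  if (paste0(rg[1:3], collapse = "") != "ATG") {
    stop("configuration error: reference CDS does not start with ATG")
  }
  if (has_internal_stop(r)) {
    stop("configuration error: reference CDS contains an internal stop")
  }
  events <- list()
  add <- function(kind, pos) {
    events[[length(events) + 1]] <<- data.frame(kind = kind,
                                                position = as.integer(pos),
                                                stringsAsFactors = FALSE)
  }
  # frame-shifting gap runs, in either sequence
  state <- (a == "-") + 2L * (r == "-")
  run <- rle(state)
  at <- cumsum(c(1L, run$lengths))[seq_along(run$lengths)]
  for (k in seq_along(run$values)) {
    if (run$values[k] %in% c(1L, 2L) && run$lengths[k] %% 3 != 0) {
      add("frameshift_indel", at[k])
    }
  }
  # start codon
  ag <- a[a != "-"]
  if (length(ag) < 3 || paste0(ag[1:3], collapse = "") != "ATG") {
    add("start_loss", 1L)
  }
  # premature stops: read the degapped allele in its own running frame
  ref_stop_col <- which(cumsum(r != "-") == length(rg) - 2 & r != "-")[1]
  a_cols <- which(a != "-")
  ncod <- floor(length(ag) / 3)
  if (ncod >= 1) {
    for (j in seq_len(ncod)) {
      cod <- paste0(ag[(3 * j - 2):(3 * j)], collapse = "")
      if (cod %in% STOP_CODONS && a_cols[3 * j - 2] < ref_stop_col) {
        add("premature_stop", j)
      }
    }
  }
  events <- if (length(events) == 0) {
    data.frame(kind = character(0), position = integer(0))
  } else do.call(rbind, events)
  structure(list(allele_id = allele_id, events = events,
                 is_functional_cds = nrow(events) == 0),
            class = "lof_annotation")
}

#' @export
print.lof_annotation <- function(x, ...) {
  cat("allele", x$allele_id, "-",
      if (x$is_functional_cds) "intact ORF" else
        paste(nrow(x$events), "LoF event(s):",
              paste(x$events$kind, collapse = ", ")), "\n")
  invisible(x)
}

#' Pick the reference CDS for a locus
#'
#' The longest allele with an intact open reading frame (ATG start, length
#' a multiple of 3, terminal stop, no internal stop); ties broken by
#' smallest id.  Overridable in pipeline configuration.
#'
#' @param sequences named aligned allele sequences.
#' @return the name of the chosen reference allele.
#' @export
choose_reference_cds <- function(sequences) {
  ok <- vapply(names(sequences), function(id) {
    s <- seq_chars(sequences[[id]])
    g <- s[s != "-"]
    n <- length(g)
    n >= 6 && n %% 3 == 0 &&
      paste0(g[1:3], collapse = "") == "ATG" &&
      paste0(g[(n - 2):n], collapse = "") %in% STOP_CODONS &&
      !has_internal_stop(s)
  }, logical(1))
  if (!any(ok)) {
    stop("no allele with an intact ORF; supply an explicit reference CDS")
  }
  cand <- names(sequences)[ok]
  lens <- vapply(sequences[cand], function(s) sum(seq_chars(s) != "-"),
                 numeric(1))
  cand[order(-lens, cand)][1]
}

#' Annotate every allele of a locus against a reference
#'
#' @param sequences named aligned allele sequences.
#' @param reference name of the reference allele, or `NULL` to use
#'   [choose_reference_cds()].
#' @return list with `reference`, `annotations` (list of
#'   `lof_annotation`) and `table` (data frame `allele_id`, `n_events`,
#'   `kinds`, `is_functional_cds`).
#' @export
annotate_alleles <- function(sequences, reference = NULL) {
  reference <- reference %||% choose_reference_cds(sequences)
  stopifnot(reference %in% names(sequences))
  ann <- lapply(names(sequences), function(id) {
    scan_orf(sequences[[id]], sequences[[reference]], allele_id = id)
  })
  names(ann) <- names(sequences)
  tab <- data.frame(
    allele_id = names(sequences),
    n_events = vapply(ann, function(x) nrow(x$events), integer(1)),
    kinds = vapply(ann, function(x)
      paste(unique(x$events$kind), collapse = ";"), character(1)),
    is_functional_cds = vapply(ann, `[[`, logical(1), "is_functional_cds"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(reference = reference, annotations = ann, table = tab)
}

#' Loss-of-function enrichment per allele group
#'
#' For each group, a one-sided (greater) Fisher exact test of the 2x2
#' table {this group vs all other groups} x {nonfunctional vs functional},
#' i.e. the upper hypergeometric tail probability of observing at least
#' the group's nonfunctional count.
#'
#' @param group_counts data frame with columns `group`, `nonfunctional`,
#'   `total`.
#' @return the input with a `p_value` column appended; groups with
#'   `total == 0` are skipped with a warning.
#' @export
lof_enrichment <- function(group_counts) {
  stopifnot(all(c("group", "nonfunctional", "total") %in%
                  names(group_counts)))
  stopifnot(all(group_counts$nonfunctional <= group_counts$total))
  if (any(group_counts$total == 0)) {
    warning("skipping group(s) with zero total: ",
            paste(group_counts$group[group_counts$total == 0],
                  collapse = ", "))
    group_counts <- group_counts[group_counts$total > 0, ]
  }
  N <- sum(group_counts$total)
  K <- sum(group_counts$nonfunctional)
  group_counts$p_value <- vapply(seq_len(nrow(group_counts)), function(i) {
    x <- group_counts$nonfunctional[i]
    n <- group_counts$total[i]
    phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  }, numeric(1))
  group_counts
}

#' Classify allele groups into the three expression/functionality
#' categories
#'
#' For a given species a group is `non_expressed` when no individual of
#' that species shows intensity above the detection floor; otherwise it is
#' `functional_expressed` or `nonfunctional_expressed` according to the
#' majority functionality of its member alleles (ties are conservatively
#' nonfunctional).  A group can also be forced nonfunctional by an
#' external-evidence flag (e.g. a biochemical assay showing an expressed
#' allele encodes an inactive enzyme, or a repetitive insertion at the
#' start of the CDS that sequence heuristics do not see).
#'
#' @param group_map data frame `allele_id`, `group_label` (from
#'   [assign_allele_groups()]).
#' @param functional named logical vector of per-allele functionality
#'   (e.g. from [annotate_alleles()] or a truth ledger).
#' @param expression data frame `individual`, `allele_group` (group
#'   label), `normalized_intensity` for one locus.
#' @param individuals data frame `individual`, `species`.
#' @param detection_floor intensity above which a band counts as
#'   expressed (default 0.05).
#' @param nonfunctional_override character vector of group labels forced
#'   nonfunctional by external evidence.
#' @return data frame `group_label`, `species`, `category`.
#' @export
classify_alleles <- function(group_map, functional, expression, individuals,
                             detection_floor = 0.05,
                             nonfunctional_override = character(0)) {
  groups <- sort(unique(group_map$group_label))
  unknown <- setdiff(unique(expression$allele_group), groups)
  if (length(unknown) > 0) {
    stop("unknown allele group(s) in expression table: ",
         paste(unknown, collapse = ", "))
  }
  expression$species <-
    individuals$species[match(expression$individual,
                              individuals$individual)]
  species <- sort(unique(individuals$species))
  out <- expand.grid(group_label = groups, species = species,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$category <- vapply(seq_len(nrow(out)), function(i) {
    g <- out$group_label[i]
    sp <- out$species[i]
    inten <- expression$normalized_intensity[
      expression$allele_group == g & expression$species == sp]
    if (length(inten) == 0 || !any(inten > detection_floor)) {
      return("non_expressed")
    }
    if (g %in% nonfunctional_override) return("nonfunctional_expressed")
    members <- group_map$allele_id[group_map$group_label == g]
    fl <- functional[members]
    if (sum(fl, na.rm = TRUE) > sum(!fl, na.rm = TRUE)) {
      "functional_expressed"
    } else {
      "nonfunctional_expressed"  # tie -> conservative
    }
  }, character(1))
  out
}
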