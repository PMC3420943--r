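#' Count nucleotide differences between two aligned sequences
#'
#' Columns where both characters are in `{A,C,G,T}` and differ count one
#' substitution each.  Under `gap_policy = "indel_as_diff"` a gap-vs-base
#' column additionally counts as a difference, with a run of k contiguous
#' gap columns (gap on the same side) counting as a single indel event.
#' `N` is never counted.
#'
#' @param seq_a,seq_b aligned sequences (strings or character vectors) of
#'   equal length.
#' @param gap_policy `"ignore_gaps"` (substitutions only) or
#'   `"indel_as_diff"`.
#' @return integer difference count.
#' @export
pairwise_nt_diff <- function(seq_a, seq_b,
                             gap_policy = c("indel_as_diff", "ignore_gaps")) {
  gap_policy <- match.arg(gap_policy)
  a <- if (length(seq_a) == 1) seq_chars(seq_a) else toupper(seq_a)
  b <- if (length(seq_b) == 1) seq_chars(seq_b) else toupper(seq_b)
  if (length(a) != length(b)) {
    stop("alignment error: sequences of length ", length(a), " and ",
         length(b))
  }
  subs <- sum(a %in% DNA_BASES & b %in% DNA_BASES & a != b)
  if (gap_policy == "ignore_gaps") return(as.integer(subs))
  state <- (a == "-") + 2L * (b == "-")  # 1: gap in a, 2: gap in b, 3: both
  r <- rle(state)
  as.integer(subs + sum(r$values %in% c(1L, 2L)))
}

# Pairwise difference matrix over rows of a character matrix.
diff_matrix <- function(mat, gap_policy = "indel_as_diff") {
  n <- nrow(mat)
  d <- matrix(0L, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- pairwise_nt_diff(mat[i, ], mat[j, ], gap_policy)
    }
  }
  d
}

#' Build a majority-rule consensus from aligned reads
#'
#' Per-column majority character; ties are broken by the character of the
#' member read with the lexicographically smallest id, making the result
#' deterministic and independent of input order.
#'
#' @param seqs named character vector of aligned sequences (names = read
#'   ids), or a character matrix with row names.
#' @return the consensus as a single string.
#' @export
build_consensus <- function(seqs) {
  mat <- if (is.matrix(seqs)) seqs else seqs_to_matrix(seqs)
  if (is.null(rownames(mat))) stop("reads must carry ids")
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  cons <- apply(mat, 2, function(col) {
    tab <- table(col)
    best <- names(tab)[tab == max(tab)]
    if (length(best) == 1) return(best)
    col[match(TRUE, col %in% best)]  # char of smallest-id read among ties
  })
  paste0(cons, collapse = "")
}

#' Merge clone reads into alleles
#'
#' Reads whose pairwise difference is at most `d_merge` are considered the
#' same allele with PCR or sequencing errors: single-linkage clustering
#' (connected components of the `<= d_merge` graph) guarantees invariance
#' to input order.  Clusters of two or more reads yield a majority-rule
#' consensus allele; singletons become singleton alleles.  The default
#' `d_merge = 1` is the literal reading of a "less than two differences"
#' merge rule.
#'
#' @param reads data frame with columns `id` and `sequence` (aligned to a
#'   common length); an optional `locus` column names the output alleles.
#' @param d_merge maximum difference merged (default 1).
#' @param gap_policy passed to [pairwise_nt_diff()].
#' @return an `allele_set`: list with `alleles` (data frame `allele_id`,
#'   `locus`, `consensus`, `n_reads`, `is_singleton`) and `membership`
#'   (data frame `read_id`, `allele_id`).
#' @export
merge_clones <- function(reads, d_merge = 1, gap_policy = "indel_as_diff") {
  if (is.null(reads) || nrow(reads) == 0) {
    return(structure(list(
      alleles = data.frame(allele_id = character(0), locus = character(0),
                           consensus = character(0), n_reads = integer(0),
                           is_singleton = logical(0)),
      membership = data.frame(read_id = character(0),
                              allele_id = character(0))),
      class = "allele_set"))
  }
  stopifnot(all(c("id", "sequence") %in% names(reads)))
  locus <- if ("locus" %in% names(reads)) reads$locus[1] else "locus"
  reads <- reads[order(reads$id), ]
  mat <- seqs_to_matrix(setNames(reads$sequence, reads$id))
  d <- diff_matrix(mat, gap_policy)
  n <- nrow(mat)
  # connected components of the <= d_merge adjacency graph
  comp <- rep(NA_integer_, n)
  nc <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    nc <- nc + 1
    queue <- i
    comp[i] <- nc
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(d[v, ] <= d_merge & is.na(comp))
      comp[nb] <- nc
      queue <- c(queue, nb)
    }
  }
  clusters <- split(seq_len(n), comp)
  sizes <- lengths(clusters)
  first_id <- vapply(clusters, function(ix) min(rownames(mat)[ix]),
                     character(1))
  ord <- order(-sizes, first_id)
  clusters <- clusters[ord]
  alleles <- data.frame(
    allele_id = sprintf("%s_al%02d", locus, seq_along(clusters)),
    locus = locus,
    consensus = vapply(clusters, function(ix) {
      if (length(ix) == 1) paste0(mat[ix, ], collapse = "")
      else build_consensus(mat[ix, , drop = FALSE])
    }, character(1)),
    n_reads = lengths(clusters),
    is_singleton = lengths(clusters) == 1,
    stringsAsFactors = FALSE)
  membership <- do.call(rbind, lapply(seq_along(clusters), function(k) {
    data.frame(read_id = rownames(mat)[clusters[[k]]],
               allele_id = alleles$allele_id[k], stringsAsFactors = FALSE)
  }))
  rownames(membership) <- NULL
  structure(list(alleles = alleles, membership = membership),
            class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat("allele_set:", nrow(x$alleles), "alleles from",
      nrow(x$membership), "reads (",
      sum(x$alleles$is_singleton), "singletons )\n")
  invisible(x)
}

#' p-distance matrix with pairwise deletion of gaps
#'
#' `d[i, j]` is the proportion of differing sites among columns where both
#' sequences have a non-gap, non-N character (pairwise deletion).  A pair
#' with zero co-scored sites is an error naming the pair.
#'
#' @param seqs named character vector of aligned sequences (>= 2).
#' @return a `p_dist` list: `labels`, `values` (symmetric matrix, zero
#'   diagonal), `overlap` (co-scored site counts).
#' @export
p_distance_matrix <- function(seqs) {
  mat <- if (is.matrix(seqs)) seqs else seqs_to_matrix(seqs)
  if (nrow(mat) < 2) stop("need at least 2 sequences")
  if (is.null(rownames(mat))) stop("sequences must be named")
  scored <- matrix(mat %in% DNA_BASES, nrow(mat))
  n <- nrow(mat)
  values <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  overlap <- matrix(0L, n, n, dimnames = dimnames(values))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      co <- scored[i, ] & scored[j, ]
      ov <- sum(co)
      if (ov == 0) {
        stop("no co-scored sites between '", rownames(mat)[i], "' and '",
             rownames(mat)[j], "'")
      }
      nd <- sum(mat[i, co] != mat[j, co])
      values[i, j] <- values[j, i] <- nd / ov
      overlap[i, j] <- overlap[j, i] <- ov
    }
  }
  diag(overlap) <- as.integer(rowSums(scored))
  structure(list(labels = rownames(mat), values = values, overlap = overlap),
            class = "p_dist")
}
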