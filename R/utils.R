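DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages draw their seeds from one master seed through this
#' fixed scheme, so that every draw in a run is attributable to the master
#' seed.  Results stay below 2^31 - 1 (R integers are 32-bit).
#'
#' @param master integer master seed.
#' @param offset integer stage/replicate offset (>= 0).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, offset) {
  m <- as.double(master) %% 2147483647
  s <- (m * 48271 + as.double(offset) * 8191 + 1) %% 2147483646
  as.integer(s + 1)
}

# Run `code` under a local RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# String <-> character-vector helpers.  Sequences are stored as plain
# uppercase strings over {A,C,G,T,-,N}; most column-wise work happens on
# character matrices (rows = sequences).
seq_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

seqs_to_matrix <- function(seqs) {
  stopifnot(length(seqs) >= 1)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    stop("alignment error: sequences have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")")
  }
  mat <- do.call(rbind, strsplit(toupper(unname(seqs)), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  mat
}

matrix_to_seqs <- function(mat) {
  setNames(apply(mat, 1, paste0, collapse = ""), rownames(mat))
}

# One draw from a Dirichlet(alpha).  Zero components of alpha yield exact
# zeros.  An all-zero alpha is a degenerate request and is rejected.
rdirichlet1 <- function(alpha) {
  stopifnot(all(alpha >= 0))
  if (all(alpha == 0)) stop("Dirichlet draw with all-zero concentration")
  g <- ifelse(alpha > 0, rgamma(length(alpha), shape = alpha, rate = 1), 0)
  if (sum(g) == 0) {
    # numerically underflowed draw: fall back to the mean
    g <- alpha
  }
  g / sum(g)
}

# "A", "B", ..., "Z", "AA", "AB", ... labels for allele groups.
group_labels <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(n)]
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
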