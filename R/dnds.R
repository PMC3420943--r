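# Nei & Gojobori (1986) pairwise dN/dS with Jukes-Cantor correction.
# Conventions (documented in the methods vignette):
#  * codon columns containing a gap in either sequence are removed;
#  * codon columns where either codon is a stop are excluded from both
#    site and difference counts;
#  * mutational pathways passing through a stop codon are excluded from
#    the pathway average (if every pathway is blocked, all are used, with
#    steps into/out of stops counted as nonsynonymous);
#  * changes into stop codons count as nonsynonymous in site counting.

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# Fraction of synonymous sites of one codon (NG86 site counting).
ng86_sites <- function(codon) {
  chars <- seq_chars(codon)
  aa <- translate_codon(codon)
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(DNA_BASES, chars[pos])) {
      mut <- chars
      mut[pos] <- alt
      mcod <- paste0(mut, collapse = "")
      if (!(mcod %in% STOP_CODONS) && translate_codon(mcod) == aa) {
        s <- s + 1 / 3
      }
    }
  }
  c(syn = s, nonsyn = 3 - s)
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in all_permutations(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
  }
  out
}

# Average synonymous/nonsynonymous differences between two codons over
# all orderings of the mutational pathway.
ng86_codon_diff <- function(cod_a, cod_b) {
  a <- seq_chars(cod_a)
  b <- seq_chars(cod_b)
  pos <- which(a != b)
  if (length(pos) == 0) return(c(syn = 0, nonsyn = 0))
  paths <- all_permutations(pos)
  step_counts <- function(path, allow_stops) {
    cur <- a
    syn <- 0
    for (p in path) {
      nxt <- cur
      nxt[p] <- b[p]
      c1 <- paste0(cur, collapse = "")
      c2 <- paste0(nxt, collapse = "")
      if (!allow_stops && (c2 %in% STOP_CODONS || c1 %in% STOP_CODONS)) {
        return(NULL)  # blocked pathway
      }
      same_aa <- !(c1 %in% STOP_CODONS) && !(c2 %in% STOP_CODONS) &&
        translate_codon(c1) == translate_codon(c2)
      if (same_aa) syn <- syn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = length(path) - syn)
  }
  counted <- Filter(Negate(is.null),
                    lapply(paths, step_counts, allow_stops = FALSE))
  if (length(counted) == 0) {
    counted <- lapply(paths, step_counts, allow_stops = TRUE)
  }
  Reduce(`+`, counted) / length(counted)
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) method
#'
#' Per-codon synonymous and nonsynonymous site counts are averaged over
#' both sequences; differences within multi-hit codons are averaged over
#' all orderings of the mutational pathway; proportions are corrected
#' with the Jukes-Cantor formula `d = -3/4 ln(1 - 4p/3)`.  The ratio is
#' undefined (`NA`) when `dS = 0`; a proportion `p >= 3/4` makes the
#' correction undefined and is flagged.
#'
#' @param cds_a,cds_b aligned coding sequences; alignment length must be a
#'   multiple of 3 (gap-containing codon columns are removed before
#'   analysis).
#' @return a `dnds` list: `dN`, `dS`, `ratio`, `pN`, `pS`, site counts
#'   `N`, `S`, difference counts `Nd`, `Sd`, `codons_used`, `flags`.
#' @export
ng86_dnds <- function(cds_a, cds_b) {
  a <- seq_chars(cds_a)
  b <- seq_chars(cds_b)
  if (length(a) != length(b)) stop("alignment error: unequal lengths")
  if (length(a) %% 3 != 0) {
    stop("alignment length must be a multiple of 3")
  }
  ncod <- length(a) / 3
  Sa <- Sb <- Na <- Nb <- Sd <- Nd <- 0
  used <- 0
  flags <- character(0)
  for (j in seq_len(ncod)) {
    ix <- (3 * j - 2):(3 * j)
    cod_a <- paste0(a[ix], collapse = "")
    cod_b <- paste0(b[ix], collapse = "")
    if (grepl("[^ACGT]", cod_a) || grepl("[^ACGT]", cod_b)) next
    if (cod_a %in% STOP_CODONS || cod_b %in% STOP_CODONS) next
    used <- used + 1
    sa <- ng86_sites(cod_a)
    sb <- ng86_sites(cod_b)
    Sa <- Sa + sa["syn"];    Na <- Na + sa["nonsyn"]
    Sb <- Sb + sb["syn"];    Nb <- Nb + sb["nonsyn"]
    d <- ng86_codon_diff(cod_a, cod_b)
    Sd <- Sd + d["syn"];     Nd <- Nd + d["nonsyn"]
  }
  S <- (Sa + Sb) / 2
  N <- (Na + Nb) / 2
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 3 / 4) {
      flags <<- c(flags, "jc_undefined")
      return(NA_real_)
    }
    d <- -3 / 4 * log(1 - 4 * p / 3)
    if (d == 0) 0 else d  # normalise -0
  }
  dS <- jc(pS)
  dN <- jc(pN)
  ratio <- if (is.na(dS) || dS == 0) {
    if (!is.na(dS) && dS == 0) flags <- c(flags, "dS_zero")
    NA_real_
  } else dN / dS
  structure(list(dN = unname(dN), dS = unname(dS), ratio = unname(ratio),
                 pN = unname(pN), pS = unname(pS), N = unname(N),
                 S = unname(S), Nd = unname(Nd), Sd = unname(Sd),
                 codons_used = used, flags = unique(flags)),
            class = "dnds")
}

#' @export
print.dnds <- function(x, ...) {
  cat(sprintf("NG86: dN = %.4f, dS = %.4f, dN/dS = %s (%d codons)\n",
              x$dN, x$dS,
              if (is.na(x$ratio)) "undefined" else sprintf("%.3f", x$ratio),
              x$codons_used))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
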