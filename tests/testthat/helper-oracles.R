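# Independent oracles.  Each recomputes a quantity from first principles,
# by enumeration or explicit sums, without reusing the package's code
# paths.

perms_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in perms_of(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
  }
  out
}

# --- Weir-Cockerham theta via the indicator-variable ANOVA ---------------
# Method-of-moments from explicit sums of squares of allele indicators
# x_ijk (population i, individual j, gene copy k):
#   E[MSG] = c;  E[MSI] = c + 2b;  E[MSP] = c + 2b + 2 n_c a.
oracle_wc_theta <- function(pop, a1, a2) {
  pop <- as.character(pop)
  pops <- sort(unique(pop))
  r <- length(pops)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2) return(NaN)
  n_i <- vapply(pops, function(p) sum(pop == p), numeric(1))
  N <- sum(n_i)
  n_c <- (N - sum(n_i^2) / N) / (r - 1)
  suma <- sumb <- sumc <- 0
  for (A in alleles) {
    SSG <- SSI <- SSP <- 0
    xbar_all <- mean(c(a1 == A, a2 == A))
    for (p in pops) {
      rows <- which(pop == p)
      x <- cbind(as.numeric(a1[rows] == A), as.numeric(a2[rows] == A))
      xbar_ij <- rowMeans(x)
      xbar_i <- mean(x)
      for (j in seq_len(nrow(x))) {
        SSG <- SSG + sum((x[j, ] - xbar_ij[j])^2)
        SSI <- SSI + 2 * (xbar_ij[j] - xbar_i)^2
      }
      SSP <- SSP + 2 * n_i[[p]] * (xbar_i - xbar_all)^2
    }
    MSG <- SSG / N
    MSI <- SSI / (N - r)
    MSP <- SSP / (r - 1)
    cc <- MSG
    b <- (MSI - MSG) / 2
    a <- (MSP - MSI) / (2 * n_c)
    suma <- suma + a; sumb <- sumb + b; sumc <- sumc + cc
  }
  if (suma + sumb + sumc == 0) return(NaN)
  suma / (suma + sumb + sumc)
}

random_wc_instance <- function() {
  r <- sample(2:4, 1)
  K <- sample(2:5, 1)
  alleles <- paste0("g", seq_len(K))
  pop <- character(0); a1 <- character(0); a2 <- character(0)
  for (p in seq_len(r)) {
    n <- sample(5:20, 1)
    freq <- rdirichlet_oracle(rep(1, K))
    pop <- c(pop, rep(paste0("pop", p), n))
    a1 <- c(a1, sample(alleles, n, replace = TRUE, prob = freq))
    a2 <- c(a2, sample(alleles, n, replace = TRUE, prob = freq))
  }
  list(pop = pop, a1 = a1, a2 = a2)
}

rdirichlet_oracle <- function(alpha) {
  g <- rgamma(length(alpha), alpha)
  g / sum(g)
}

# --- UPGMA by repeated averaging over the ORIGINAL distance matrix -------
# UPGMA inter-cluster distance equals the mean over all original leaf
# pairs, which this oracle recomputes at every step instead of using the
# weighted recurrence.  Same tie-break: smallest label pair, a cluster
# labelled by its smallest member.
oracle_upgma <- function(D) {
  labels <- rownames(D)
  clusters <- lapply(labels, identity)
  names(clusters) <- labels
  nodes <- list()
  while (length(clusters) > 1) {
    labs <- names(clusters)
    best <- NULL
    for (i in seq_len(length(labs) - 1)) {
      for (j in (i + 1):length(labs)) {
        mi <- clusters[[labs[i]]]; mj <- clusters[[labs[j]]]
        d <- mean(D[mi, mj])
        pair <- sort(c(labs[i], labs[j]))
        better <- is.null(best) || d < best$d - 1e-15 ||
          (abs(d - best$d) <= 1e-15 &&
             (pair[1] < best$pair[1] ||
                (pair[1] == best$pair[1] && pair[2] < best$pair[2])))
        if (better) best <- list(d = d, pair = pair)
      }
    }
    members <- sort(c(clusters[[best$pair[1]]], clusters[[best$pair[2]]]))
    nodes[[length(nodes) + 1]] <- list(members = members,
                                       height = best$d / 2)
    clusters[[best$pair[2]]] <- NULL
    clusters[[best$pair[1]]] <- members
  }
  nodes
}

# --- NG86 codon-pair counts by explicit pathway enumeration --------------
GC <- Biostrings::GENETIC_CODE
ORACLE_STOPS <- names(GC)[GC == "*"]

oracle_ng86_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), ch[pos])) {
      mut <- ch; mut[pos] <- alt
      mc <- paste0(mut, collapse = "")
      if (!(mc %in% ORACLE_STOPS) && GC[[mc]] == GC[[codon]]) {
        syn <- syn + 1 / 3
      }
    }
  }
  syn
}

oracle_ng86_diff <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  if (length(pos) == 0) return(c(syn = 0, nonsyn = 0))
  count_path <- function(order, strict) {
    cur <- a; syn <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- b[p]
      c1 <- paste0(cur, collapse = ""); c2 <- paste0(nxt, collapse = "")
      if (strict && (c1 %in% ORACLE_STOPS || c2 %in% ORACLE_STOPS)) {
        return(NULL)
      }
      if (!(c1 %in% ORACLE_STOPS) && !(c2 %in% ORACLE_STOPS) &&
          GC[[c1]] == GC[[c2]]) syn <- syn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = length(order) - syn)
  }
  paths <- perms_of(pos)
  res <- Filter(Negate(is.null), lapply(paths, count_path, strict = TRUE))
  if (length(res) == 0) res <- lapply(paths, count_path, strict = FALSE)
  Reduce(`+`, res) / length(res)
}

random_codon <- function() {
  repeat {
    cod <- paste0(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                  collapse = "")
    if (!(cod %in% ORACLE_STOPS)) return(cod)
  }
}

# --- expected pairwise difference of two mutated allele lineages ---------
# Brute-force mini-simulator of the generator's mutation placement:
# Poisson mutation counts, positions without replacement, random
# different target bases (two hits at one site coincide w.p. 1/3).
oracle_pairdiff_expectation <- function(L, mu, nsim = 20000) {
  diffs <- numeric(nsim)
  for (i in seq_len(nsim)) {
    ka <- min(rpois(1, mu), L)
    kb <- min(rpois(1, mu), L)
    pa <- sample.int(L, ka)
    pb <- sample.int(L, kb)
    ov <- length(intersect(pa, pb))
    diffs[i] <- (ka - ov) + (kb - ov) + rbinom(1, ov, 2 / 3)
  }
  mean(diffs)
}

# --- exact Monte-Carlo reference for the chi-squared test ----------------
# Exhaustive enumeration of all 2x2 tables with the observed margins,
# weighted by the hypergeometric probability.
oracle_chisq_exact_p <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  expected <- outer(rs, cs) / n
  stat <- function(tb) sum((tb - expected)^2 / expected)
  obs <- stat(tab)
  p <- 0
  for (x in max(0, cs[1] - rs[2]):min(rs[1], cs[1])) {
    tb <- matrix(c(x, cs[1] - x, rs[1] - x, rs[2] - cs[1] + x), 2, 2)
    prob <- exp(lchoose(rs[1], x) + lchoose(rs[2], cs[1] - x) -
                  lchoose(n, cs[1]))
    if (stat(tb) >= obs - 1e-9) p <- p + prob
  }
  p
}
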