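# Independent brute-force oracles. These re-derive every checked quantity
# from first principles, sharing no code with the implementation paths they
# verify.

# genetic code bookkeeping used by the oracles
.ogc <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})
.ostops <- names(.ogc)[.ogc == "*"]

split_codons_oracle <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n - 2, 3), seq(3, n, 3))
}

# codons that the package's exclusion rules keep (terminal stop, N codons,
# internal stops dropped)
kept_codons_oracle <- function(seq) {
  cods <- split_codons_oracle(toupper(seq))
  if (cods[length(cods)] %in% .ostops) cods <- cods[-length(cods)]
  cods[!grepl("N", cods) & !(cods %in% .ostops)]
}

# CAI as a direct product (not log-domain)
oracle_cai <- function(seq, weights) {
  cods <- kept_codons_oracle(seq)
  cods <- cods[!(cods %in% weights$excluded)]
  prod(weights$w[cods])^(1 / length(cods))
}

# Nc applied symbol by symbol from the definition, with the degeneracy
# classes written out explicitly
oracle_nc <- function(seq) {
  cods <- kept_codons_oracle(seq)
  aa_of <- .ogc[cods]
  two <- c("F", "Y", "H", "Q", "N", "K", "D", "E", "C")
  three <- "I"
  four <- c("V", "P", "T", "A", "G")
  six <- c("L", "S", "R")
  fhat_of <- function(aa) {
    cnt <- table(cods[aa_of == aa])
    n <- sum(cnt)
    if (n < 2) return(NA_real_)
    p <- as.numeric(cnt) / n
    (n * sum(p^2) - 1) / (n - 1)
  }
  avg_class <- function(aas) {
    f <- vapply(aas, fhat_of, numeric(1))
    f <- f[!is.na(f) & f > 0]
    if (length(f)) mean(f) else NA_real_
  }
  f2 <- avg_class(two); f3 <- avg_class(three)
  f4 <- avg_class(four); f6 <- avg_class(six)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) {
    f3 <- 1 / ((1 / f2 + 1 / f4) / 2)
  }
  if (anyNA(c(f2, f3, f4, f6))) return(NA_real_)
  min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)
}

# tie-corrected Kruskal-Wallis H from the textbook formula
oracle_kw_h <- function(groups) {
  values <- unlist(groups)
  N <- length(values)
  r <- rank(values)
  ri <- split(r, rep(seq_along(groups), lengths(groups)))
  h <- 12 / (N * (N + 1)) *
    sum(vapply(ri, function(x) sum(x)^2 / length(x), numeric(1))) -
    3 * (N + 1)
  tt <- table(values)
  h / (1 - sum(tt^3 - tt) / (N^3 - N))
}

# Holm and BH from their definitions (sorted cumulative max / min)
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- cummax(pmin(1, (m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- cummin(pmin(1, m / (m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact two-sided Mann-Whitney p by enumerating all splits
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  u_of <- function(idx) {
    xx <- pool[idx]; yy <- pool[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(combn(n1 + n2, n1), 2, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Cliff's delta by the double loop definition
oracle_cliffs_delta <- function(x, y) {
  d <- outer(x, y, "-")
  (sum(d > 0) - sum(d < 0)) / (length(x) * length(y))
}

# type-7 quantile from the interpolation formula, written out
oracle_q7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# PERMANOVA pseudo-F straight from a distance matrix (Anderson's
# definitional sums over squared inter-point distances)
oracle_pseudo_f <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- as.character(labels)
  k <- length(unique(labels))
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    dg <- d[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dg[upper.tri(dg)]^2) / length(idx)
  }
  ss_between <- ss_total - ss_within
  list(f = (ss_between / (k - 1)) / (ss_within / (n - k)),
       r2 = ss_between / ss_total)
}

# helpers to build random in-frame CDS fixtures
.sense_codons <- names(.ogc)[.ogc != "*"]

random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  body <- sample(.sense_codons, n_codons - 2, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# a complete codon usage table from a named count vector (frequencies made
# exactly consistent)
make_usage_table <- function(counts) {
  stopifnot(length(counts) == 64)
  codon_usage_table(names(counts), 1000 * counts / sum(counts), counts)
}

# uniform counts over all codons
uniform_counts <- function(value = 1000) {
  b <- c("T", "C", "A", "G")
  cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setNames(rep(value, 64), cods)
}
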