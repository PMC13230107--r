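# Combined genomic distance (CGD) over pairwise genome-similarity tables.
#
# Each unordered genome pair is summarised by the average of its reciprocal
# directional percent identity (pid) and query coverage (pcov). The distance
# combines both components Euclidean-style:
#     d = sqrt((1 - pid/100)^2 + (1 - pcov/100)^2)
# Pairs with no detectable similarity in either direction (NSS) are not
# missing data: they sit at the metric's theoretical maximum sqrt(2).

#' Combined genomic distance
#'
#' @param pid,pcov averaged percent identity and coverage in `[0, 100]`;
#'   both `NA` encodes a no-significant-similarity (NSS) pair, which is
#'   assigned the maximum distance `sqrt(2)` exactly.
#' @return numeric distance(s) in `[0, sqrt(2)]`.
#' @export
cgd <- function(pid, pcov) {
  assert_that(length(pid) == length(pcov),
              "pid and pcov must have the same length")
  both_na <- is.na(pid) & is.na(pcov)
  if (any(xor(is.na(pid), is.na(pcov)))) {
    stop("exactly one of pid/pcov is unset; NSS pairs must have both unset",
         call. = FALSE)
  }
  ok <- !both_na
  if (any(pid[ok] < 0 | pid[ok] > 100 | pcov[ok] < 0 | pcov[ok] > 100)) {
    stop("pid/pcov outside [0,100]", call. = FALSE)
  }
  out <- rep_len(sqrt(2), length(pid))
  out[ok] <- sqrt((1 - pid[ok] / 100)^2 + (1 - pcov[ok] / 100)^2)
  out
}

#' Build unordered genome pairs from directional hits
#'
#' Reciprocal directional values are averaged into a single pid/pcov per
#' unordered pair (a single available direction contributes its own value);
#' duplicate rows for the same direction are averaged with a warning. Every
#' listed pair with no hit in either direction is flagged NSS. The output
#' covers all `n(n-1)/2` pairs of the genome list.
#'
#' @param hits data frame `query_id`, `subject_id`, `pid`, `pcov` (see
#'   [read_directional_hits()]).
#' @param genomes character vector of genome ids the pair grid is built
#'   over.
#' @return data frame `genome_a`, `genome_b` (with `genome_a < genome_b`),
#'   `pid`, `pcov`, `nss`, `d`.
#' @export
pair_from_hits <- function(hits, genomes) {
  genomes <- unique(as.character(genomes))
  assert_that(length(genomes) >= 2L, "need at least two genomes")
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), genomes)
  if (length(unknown)) {
    stop(sprintf("hits reference unknown genome(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(hits)) {
    dir_key <- paste(hits$query_id, hits$subject_id, sep = "\r")
    if (anyDuplicated(dir_key)) {
      warning("duplicate directional rows averaged", call. = FALSE)
      pid <- tapply(hits$pid, dir_key, mean)
      pcov <- tapply(hits$pcov, dir_key, mean)
      parts <- strsplit(names(pid), "\r", fixed = TRUE)
      hits <- data.frame(
        query_id = vapply(parts, `[`, character(1L), 1L),
        subject_id = vapply(parts, `[`, character(1L), 2L),
        pid = as.numeric(pid), pcov = as.numeric(pcov),
        stringsAsFactors = FALSE)
    }
  }
  grid <- t(combn(sort(genomes), 2L))
  pairs <- data.frame(genome_a = grid[, 1L], genome_b = grid[, 2L],
                      stringsAsFactors = FALSE)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pair_key <- key(pairs$genome_a, pairs$genome_b)
  if (nrow(hits)) {
    hk <- key(hits$query_id, hits$subject_id)
    pid <- tapply(hits$pid, hk, mean)
    pcov <- tapply(hits$pcov, hk, mean)
    m <- match(pair_key, names(pid))
    pairs$pid <- as.numeric(pid[m])
    pairs$pcov <- as.numeric(pcov[m])
  } else {
    pairs$pid <- NA_real_
    pairs$pcov <- NA_real_
  }
  pairs$nss <- is.na(pairs$pid)
  pairs$d <- cgd(pairs$pid, pairs$pcov)
  pairs
}

#' Within-group heterogeneity summary of genome pairs
#'
#' Two complementary scopes: `"valid_only"` restricts to pairs with
#' detectable similarity and reports pid/pcov/d statistics; `"all_pairs"`
#' includes NSS pairs at `d = sqrt(2)` and reports counts, the NSS
#' proportion and d statistics. Quartiles interpolate linearly between order
#' statistics; SD uses the n-1 denominator.
#'
#' @param pairs pair data frame from [pair_from_hits()].
#' @param scope `"valid_only"` or `"all_pairs"`.
#' @return one-row data frame of summary fields.
#' @export
summarize_pairs <- function(pairs, scope = c("valid_only", "all_pairs")) {
  scope <- match.arg(scope)
  assert_that(nrow(pairs) > 0L, "empty pair collection")
  n_total <- nrow(pairs)
  n_nss <- sum(pairs$nss)
  n_valid <- n_total - n_nss
  stat5 <- function(x, prefix) {
    out <- data.frame(mean(x), median(x),
                      if (length(x) > 1L) sd(x) else NA_real_,
                      q7(x, 0.25), q7(x, 0.75), max(x))
    names(out) <- paste0(prefix, c("_mean", "_median", "_sd", "_q1", "_q3",
                                   "_max"))
    out
  }
  base <- data.frame(scope = scope, n_total = n_total, n_valid = n_valid,
                     n_nss = n_nss, prop_nss = n_nss / n_total,
                     stringsAsFactors = FALSE)
  if (scope == "valid_only") {
    if (n_valid == 0L) {
      stop("no valid pairs; valid-only summary undefined", call. = FALSE)
    }
    v <- pairs[!pairs$nss, , drop = FALSE]
    cbind(base, stat5(v$d, "d"), stat5(v$pid, "pid"), stat5(v$pcov, "pcov"))
  } else {
    cbind(base, stat5(pairs$d, "d"))
  }
}
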