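# Per-gene compositional and codon-usage metrics: gene length, overall and
# position-specific GC content, the Codon Adaptation Index (CAI, Sharp & Li)
# and Wright's effective number of codons (Nc), plus functional gene
# classification from product strings.
#
# Conventions applied uniformly (documented in the methods vignette):
#   * the terminal stop codon is excluded from GC, CAI and Nc;
#   * codons containing N and internal stop codons are excluded, and their
#     counts are carried on the result as attributes;
#   * ATG and TGG (single-codon families) do not enter CAI's geometric mean;
#   * zero-count reference codons receive a 0.5 pseudo-count before CAI
#     weight normalisation;
#   * Nc is capped at 61 and is NA when a required family average is
#     unavailable.

# Split an in-frame CDS into codons, applying the exclusion rules. With
# drop_terminal_stop = FALSE the terminal stop codon is retained as an
# ordinary codon (the GC sensitivity switch); internal stops are always
# excluded. Returns the retained codons plus bookkeeping counts.
#' @noRd
prepare_codons <- function(sequence, drop_terminal_stop = TRUE) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  assert_that(n >= 3L, "sequence shorter than one codon")
  if (n %% 3L != 0L) {
    stop(sprintf("sequence length %d is not a multiple of 3 (broken frame)",
                 n), call. = FALSE)
  }
  codons <- substring(sequence, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  stops <- stop_codons()
  had_terminal_stop <- codons[length(codons)] %in% stops
  keep_last <- had_terminal_stop && !drop_terminal_stop
  if (had_terminal_stop && drop_terminal_stop) {
    codons <- codons[-length(codons)]
  }
  with_n <- grepl("N", codons, fixed = TRUE)
  internal_stop <- !with_n & codons %in% stops
  if (keep_last) internal_stop[length(codons)] <- FALSE
  kept <- codons[!with_n & !internal_stop]
  list(codons = kept,
       n_ambiguous = sum(with_n),
       n_internal_stops = sum(internal_stop),
       had_terminal_stop = had_terminal_stop)
}

#' Overall and position-specific GC content of a CDS
#'
#' `gcK` is 100 x (number of G or C at codon position K) / (number of codons
#' counted); `gc` is the same proportion over all three positions. Codons
#' containing `N` and internal stop codons are excluded from numerator and
#' denominator; the terminal stop codon is excluded unless
#' `include_terminal_stop` is set (a sensitivity switch).
#'
#' @param sequence in-frame CDS string.
#' @param include_terminal_stop count the terminal stop codon as an ordinary
#'   codon.
#' @return named numeric vector `gc`, `gc1`, `gc2`, `gc3` (percent).
#' @export
positional_gc <- function(sequence, include_terminal_stop = FALSE) {
  pc <- prepare_codons(sequence, drop_terminal_stop = !include_terminal_stop)
  codons <- pc$codons
  if (!length(codons)) {
    stop("all codons excluded; GC content undefined", call. = FALSE)
  }
  chars <- strsplit(paste(codons, collapse = ""), "", fixed = TRUE)[[1L]]
  is_gc <- chars == "G" | chars == "C"
  pos <- rep(1:3, times = length(codons))
  k <- length(codons)
  c(gc = 100 * sum(is_gc) / (3 * k),
    gc1 = 100 * sum(is_gc[pos == 1L]) / k,
    gc2 = 100 * sum(is_gc[pos == 2L]) / k,
    gc3 = 100 * sum(is_gc[pos == 3L]) / k)
}

#' Relative adaptiveness weights for CAI
#'
#' For every synonymous family, `w(codon) = f(codon) / max f(family)` on the
#' reference counts. Codons with zero reference count receive `zero_rule`
#' pseudo-counts before normalisation so that no weight is zero. Stop codons
#' and the single-codon families (ATG, TGG) are flagged as excluded from the
#' CAI geometric mean.
#'
#' @param table a [codon_usage_table()].
#' @param zero_rule pseudo-count substituted for zero reference counts
#'   (count scale; default 0.5).
#' @return object of class `adaptiveness_weights`: list with `w` (named
#'   weights over the 61 sense codons) and `excluded` (codons not
#'   contributing to CAI).
#' @export
adaptiveness_weights <- function(table, zero_rule = 0.5) {
  stopifnot(inherits(table, "codon_usage_table"))
  counts <- setNames(table$entries$count, table$entries$codon)
  fams <- synonymous_families()
  w <- setNames(numeric(0L), character(0L))
  for (aa in names(fams)) {
    codons <- fams[[aa]]
    fc <- counts[codons]
    if (all(fc == 0)) {
      stop(sprintf(
        "reference table unusable: all codons of family %s have zero counts",
        aa), call. = FALSE)
    }
    fc[fc == 0] <- zero_rule
    w <- c(w, fc / max(fc))
  }
  structure(list(w = w,
                 excluded = c(stop_codons(), "ATG", "TGG")),
            class = "adaptiveness_weights")
}

#' Codon Adaptation Index of a CDS
#'
#' Geometric mean of the relative adaptiveness weights over the gene's
#' codons, computed in the log domain. Stop codons, single-codon families
#' (ATG, TGG) and codons containing `N` do not contribute.
#'
#' @param sequence in-frame CDS string.
#' @param weights an [adaptiveness_weights()] object.
#' @return CAI in `(0, 1]`.
#' @export
cai <- function(sequence, weights) {
  stopifnot(inherits(weights, "adaptiveness_weights"))
  pc <- prepare_codons(sequence)
  codons <- pc$codons[!(pc$codons %in% weights$excluded)]
  if (!length(codons)) {
    stop("no codons contribute to CAI (metric undefined)", call. = FALSE)
  }
  exp(mean(log(weights$w[codons])))
}

#' Effective number of codons (Nc) of a CDS
#'
#' Wright's estimator from synonymous-family homozygosities. Per family,
#' `F = (n * sum(p_i^2) - 1) / (n - 1)` with `n` the family codon count;
#' family averages are taken over families with `n >= 2` and `F > 0` within
#' each degeneracy class (9 two-fold, 1 three-fold, 5 four-fold, 3 six-fold
#' families; Met, Trp and stops excluded), and
#' `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`. A missing three-fold average (Ile
#' absent) is imputed as the harmonic mean of the two- and four-fold
#' averages; if the two-, four- or six-fold average is unavailable the
#' metric is undefined and `NA` is returned. Estimates above the theoretical
#' maximum are capped at 61.
#'
#' @param sequence in-frame CDS string.
#' @return Nc in `[20, 61]`, or `NA` when undefined.
#' @export
nc <- function(sequence) {
  pc <- prepare_codons(sequence)
  if (!length(pc$codons)) return(NA_real_)
  code <- std_genetic_code()
  deg <- family_degeneracy()
  tab <- table(pc$codons)
  aa <- code[names(tab)]
  fhat <- vapply(split(as.numeric(tab), aa), function(cnt) {
    n <- sum(cnt)
    if (n < 2) return(NA_real_)
    p <- cnt / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1L))
  fhat <- fhat[!is.na(fhat) & fhat > 0]
  fbar <- vapply(c(2, 3, 4, 6), function(k) {
    vals <- fhat[names(fhat) %in% names(deg)[deg == k]]
    if (length(vals)) mean(vals) else NA_real_
  }, numeric(1L))
  names(fbar) <- c("F2", "F3", "F4", "F6")
  if (is.na(fbar["F3"]) && !is.na(fbar["F2"]) && !is.na(fbar["F4"])) {
    fbar["F3"] <- 1 / ((1 / fbar["F2"] + 1 / fbar["F4"]) / 2)
  }
  if (anyNA(fbar)) return(NA_real_)
  out <- 2 + 9 / fbar[["F2"]] + 1 / fbar[["F3"]] + 5 / fbar[["F4"]] +
    3 / fbar[["F6"]]
  min(out, 61)
}

#' All metrics for one CDS record
#'
#' Bundles gene length (raw sequence length in nt), GC metrics, CAI and Nc.
#'
#' @param record one-row CDS record data frame.
#' @param weights an [adaptiveness_weights()] object.
#' @param include_terminal_stop GC sensitivity switch, see [positional_gc()].
#' @return one-row data frame `gene_id`, `genome_id`, `lifestyle`, `nt`,
#'   `gc`, `gc1`, `gc2`, `gc3`, `cai`, `nc`, `n_codons_used`.
#' @export
gene_metrics <- function(record, weights, include_terminal_stop = FALSE) {
  seq <- record$sequence[[1L]]
  pc <- prepare_codons(seq)
  gcs <- positional_gc(seq, include_terminal_stop = include_terminal_stop)
  data.frame(gene_id = record$gene_id[[1L]],
             genome_id = record$genome_id[[1L]] %||% NA_character_,
             lifestyle = record$lifestyle[[1L]] %||% NA_character_,
             nt = nchar(seq),
             gc = unname(gcs["gc"]), gc1 = unname(gcs["gc1"]),
             gc2 = unname(gcs["gc2"]), gc3 = unname(gcs["gc3"]),
             cai = cai(seq, weights), nc = nc(seq),
             n_codons_used = length(pc$codons),
             stringsAsFactors = FALSE)
}

#' Metrics for a batch of CDS records
#'
#' Per-gene failures (e.g. broken reading frames) are collected, reported
#' with a message and attached as the `"failures"` attribute; they are not
#' fatal to the batch.
#'
#' @param records CDS record data frame.
#' @param weights an [adaptiveness_weights()] object.
#' @param include_terminal_stop GC sensitivity switch, see [positional_gc()].
#' @return data frame of per-gene metrics (one row per successful gene).
#' @export
compute_gene_metrics <- function(records, weights,
                                 include_terminal_stop = FALSE) {
  rows <- vector("list", nrow(records))
  failures <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    rows[[i]] <- tryCatch(
      gene_metrics(rec, weights,
                   include_terminal_stop = include_terminal_stop),
      error = function(e) {
        failures[[length(failures) + 1L]] <<-
          data.frame(gene_id = rec$gene_id, error = conditionMessage(e),
                     stringsAsFactors = FALSE)
        NULL
      })
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0L))
  }
  rownames(out) <- NULL
  if (length(failures)) {
    fdf <- do.call(rbind, failures)
    message(sprintf("%d gene(s) failed metric computation", nrow(fdf)))
    attr(out, "failures") <- fdf
  }
  out
}

#' Functional category keyword lists
#'
#' Case-insensitive keyword vocabularies for the five functional gene
#' categories, in precedence order (`lysis` > `replication` > `repair` >
#' `regulatory` > `structural`); a product matching several categories gets
#' the first. The lists are configurable and are not claimed to reproduce
#' any particular annotation pipeline's exact gene counts.
#'
#' @return named list of keyword character vectors.
#' @export
functional_keywords <- function() {
  list(
    lysis = c("endolysin", "holin", "amidase", "lysin", "hemolysin"),
    replication = c("replication initiation", "polymerase", "helicase",
                    "primase", "exonuclease"),
    repair = c("methyltransferase", "methylation", "arda", "lar",
               "hydroxymethylase", "dndb"),
    regulatory = c("repressor", "antirepressor", "activator", "sigma",
                   "anti-sigma", "response regulator",
                   "transcriptional regulator"),
    structural = c("packaging", "terminase", "portal", "capsid", "head",
                   "neck", "tail", "baseplate", "adsorption")
  )
}

#' Classify genes into functional categories from product strings
#'
#' Whole-word, case-insensitive keyword matching against
#' [functional_keywords()]; products with no hit (including empty or missing
#' strings) are `"unclassified"`.
#'
#' @param product character vector of product annotations.
#' @param keywords keyword lists in precedence order.
#' @return character vector of categories.
#' @export
classify_functional_category <- function(product,
                                         keywords = functional_keywords()) {
  out <- rep("unclassified", length(product))
  txt <- tolower(ifelse(is.na(product), "", product))
  remaining <- nzchar(txt)
  for (cat in names(keywords)) {
    pat <- paste0("\\b(", paste(keywords[[cat]], collapse = "|"), ")\\b")
    hit <- remaining & grepl(pat, txt, perl = TRUE)
    out[hit] <- cat
    remaining <- remaining & !hit
  }
  out
}
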