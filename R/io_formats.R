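# Readers and writers for every external format the pipeline touches.
# Downstream modules consume only the plain data frames produced here:
#   CDS records:      gene_id, genome_id, sequence, lifestyle, product
#   codon usage:      codon_usage_table object (see codon_usage_table())
#   directional hits: query_id, subject_id, pid, pcov
#   annotations:      gene_id, genome_id, lifestyle, product, trna_count,
#                     genome_size_bp

#' Construct a CDS record collection
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param sequence nucleotide strings over `A,C,G,T,N`.
#' @param genome_id,lifestyle,product optional per-gene annotations; lifestyle,
#'   when set, must be one of `"virulent"`, `"temperate"`, `"prophage"`.
#' @return data frame with columns `gene_id`, `genome_id`, `sequence`,
#'   `lifestyle`, `product`.
#' @export
cds_records <- function(gene_id, sequence, genome_id = NA_character_,
                        lifestyle = NA_character_, product = NA_character_) {
  gene_id <- as.character(gene_id)
  sequence <- toupper(as.character(sequence))
  assert_that(length(gene_id) == length(sequence),
              "gene_id and sequence must have the same length")
  assert_that(all(nzchar(sequence)), "sequences must be non-empty")
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup)) {
    stop(sprintf("duplicate gene_id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop(sprintf("sequence for %s contains characters outside {A,C,G,T,N}",
                 paste(gene_id[bad][seq_len(min(3L, sum(bad)))],
                       collapse = ", ")), call. = FALSE)
  }
  lifestyle <- as.character(lifestyle)
  check_lifestyle(lifestyle)
  data.frame(gene_id = gene_id,
             genome_id = rep_len(as.character(genome_id), length(gene_id)),
             sequence = sequence,
             lifestyle = rep_len(lifestyle, length(gene_id)),
             product = rep_len(as.character(product), length(gene_id)),
             stringsAsFactors = FALSE)
}

#' Read coding sequences from a FASTA file
#'
#' The token before the first whitespace in each header becomes the
#' `gene_id`; the remainder of the header, when present, is retained as
#' `product`. Sequences are uppercased and IUPAC ambiguity codes other than
#' `N` are converted to `N`.
#'
#' @param path FASTA file of CDS nucleotide sequences.
#' @return CDS record data frame (see [cds_records()]).
#' @export
read_fasta_cds <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) {
                  stop(sprintf("malformed FASTA in %s: %s", path,
                               conditionMessage(e)), call. = FALSE)
                })
  if (length(x) == 0L) {
    stop(sprintf("FASTA file %s contains no records", path), call. = FALSE)
  }
  headers <- names(x)
  gene_id <- sub("\\s.*$", "", headers)
  rest <- sub("^\\S+\\s*", "", headers)
  product <- ifelse(nzchar(rest), rest, NA_character_)
  seqs <- toupper(as.character(x))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  cds_records(gene_id = gene_id, sequence = seqs, product = product)
}

#' Write CDS records to FASTA
#'
#' Inverse of [read_fasta_cds()] for the columns a FASTA file can carry
#' (`gene_id`, `product`, `sequence`).
#'
#' @param records CDS record data frame.
#' @param path output file.
#' @export
write_fasta_cds <- function(records, path) {
  headers <- ifelse(is.na(records$product), records$gene_id,
                    paste(records$gene_id, records$product))
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Construct a reference codon-usage table
#'
#' @param codon character vector of 64 DNA codons.
#' @param freq_per_1000 usage frequency per 1000 codons.
#' @param count observed codon count in the reference gene set.
#' @return object of class `codon_usage_table`: a list with `entries`
#'   (data frame codon/freq_per_1000/count), `total_codons` and
#'   `genetic_code`.
#' @export
codon_usage_table <- function(codon, freq_per_1000, count) {
  codon <- chartr("Uu", "Tt", toupper(as.character(codon)))
  dup <- unique(codon[duplicated(codon)])
  if (length(dup)) {
    stop(sprintf("duplicate codon(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(all_codons(), codon)
  if (length(missing)) {
    stop(sprintf("codon usage table is missing %d codon(s): %s",
                 length(missing), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  freq_per_1000 <- as.numeric(freq_per_1000)
  count <- as.numeric(count)
  assert_that(all(is.finite(freq_per_1000)) && all(freq_per_1000 >= 0),
              "frequencies must be non-negative")
  assert_that(all(is.finite(count)) && all(count >= 0) &&
                all(count == round(count)),
              "counts must be non-negative integers")
  o <- match(all_codons(), codon)
  entries <- data.frame(codon = codon[o], freq_per_1000 = freq_per_1000[o],
                        count = count[o], stringsAsFactors = FALSE)
  total <- sum(entries$count)
  assert_that(total > 0, "codon usage table has zero total count")
  dev <- abs(1000 * entries$count / total - entries$freq_per_1000)
  if (any(dev > 0.05 + 1e-9)) {
    bad <- entries$codon[which.max(dev)]
    stop(sprintf(
      "frequency/count mismatch (worst codon %s, deviation %.3f per 1000)",
      bad, max(dev)), call. = FALSE)
  }
  structure(list(entries = entries, total_codons = total,
                 genetic_code = std_genetic_code()),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("codon usage table: 64 codons, %s total\n",
              format(x$total_codons, big.mark = ",")))
  invisible(x)
}

#' Read a reference codon-usage table
#'
#' Two dialects are supported: `"kazusa"`, the whitespace-separated
#' `CODON freq (count)` blocks printed by the Kazusa codon-usage database
#' (RNA or DNA alphabet; `U` is normalised to `T`), and `"tsv"`, a
#' three-column tab-separated file with header
#' `codon  freq_per_1000  count`.
#'
#' @param path input file.
#' @param dialect `"kazusa"` or `"tsv"`.
#' @return a [codon_usage_table()].
#' @export
read_codon_usage_table <- function(path, dialect = c("kazusa", "tsv")) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  if (dialect == "kazusa") {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    pat <- "([ACGTUacgtu]{3})[ \t]+([0-9]+\\.?[0-9]*)[ \t]*\\([ \t]*([0-9]+)[ \t]*\\)"
    m <- gregexpr(pat, txt, perl = TRUE)
    hits <- regmatches(txt, m)[[1]]
    if (!length(hits)) {
      stop(sprintf("no Kazusa-style 'CODON freq (count)' blocks found in %s",
                   path), call. = FALSE)
    }
    parts <- regmatches(hits, regexec(pat, hits, perl = TRUE))
    codon <- vapply(parts, `[`, character(1L), 2L)
    freq <- as.numeric(vapply(parts, `[`, character(1L), 3L))
    count <- as.numeric(vapply(parts, `[`, character(1L), 4L))
    codon_usage_table(codon, freq, count)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("codon", "freq_per_1000", "count")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop(sprintf("TSV codon table is missing column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    codon_usage_table(df$codon, df$freq_per_1000, df$count)
  }
}

#' Write a codon-usage table as three-column TSV
#'
#' @param table a [codon_usage_table()].
#' @param path output file.
#' @export
write_codon_usage_table <- function(table, path) {
  stopifnot(inherits(table, "codon_usage_table"))
  write_table(table$entries, path)
}

#' Read directional genome-similarity hits (BLAST tabular style)
#'
#' Expects a tab-separated file with a header naming at least the four
#' columns below (BLAST `outfmt 6/7` custom column names). Which column of a
#' BLAST run encodes query coverage is a reporting choice, so the column
#' names are parameters rather than guesses.
#'
#' @param path input TSV.
#' @param col_query,col_subject,col_pid,col_pcov column names holding the
#'   query genome id, subject genome id, percent identity and percent query
#'   coverage. Defaults follow BLAST's `qseqid sseqid pident qcovs`.
#' @return data frame `query_id`, `subject_id`, `pid`, `pcov`; self-hits are
#'   dropped.
#' @export
read_directional_hits <- function(path, col_query = "qseqid",
                                  col_subject = "sseqid",
                                  col_pid = "pident", col_pcov = "qcovs") {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c(col_query, col_subject, col_pid, col_pcov)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("hits file is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(query_id = as.character(df[[col_query]]),
                    subject_id = as.character(df[[col_subject]]),
                    pid = as.numeric(df[[col_pid]]),
                    pcov = as.numeric(df[[col_pcov]]),
                    stringsAsFactors = FALSE)
  bad <- which(!is.finite(out$pid) | out$pid < 0 | out$pid > 100 |
                 !is.finite(out$pcov) | out$pcov < 0 | out$pcov > 100)
  if (length(bad)) {
    stop(sprintf("pid/pcov outside [0,100] at row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out[out$query_id != out$subject_id, , drop = FALSE]
}

#' Read a gene annotation table
#'
#' Tab-separated with header; required columns `gene_id`, `genome_id`,
#' `lifestyle`; optional `product`, `trna_count` (per genome) and
#' `genome_size_bp`.
#'
#' @param path input TSV.
#' @return annotation data frame with all six columns (optional ones `NA`
#'   when absent from the file).
#' @export
read_annotation_table <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "genome_id", "lifestyle")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("annotation table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  check_lifestyle(df$lifestyle)
  if (is.null(df$product)) df$product <- NA_character_
  if (is.null(df$trna_count)) {
    df$trna_count <- NA_integer_
  } else {
    tc <- df$trna_count
    assert_that(all(is.na(tc) | (tc >= 0 & tc == round(tc))),
                "trna_count must be a non-negative integer")
    df$trna_count <- as.integer(tc)
  }
  if (is.null(df$genome_size_bp)) {
    df$genome_size_bp <- NA_integer_
  } else {
    assert_that(all(is.na(df$genome_size_bp) | df$genome_size_bp > 0),
                "genome_size_bp must be positive")
    df$genome_size_bp <- as.integer(df$genome_size_bp)
  }
  df[, c("gene_id", "genome_id", "lifestyle", "product", "trna_count",
         "genome_size_bp")]
}

#' Write a record collection as tab-separated text
#'
#' Exact inverse of the corresponding reader for the supported columns.
#'
#' @param records data frame.
#' @param path output file.
#' @export
write_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
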