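# Lifestyle-structured synthetic dataset generator.
#
# Emulates the study conditions of a balanced three-lifestyle phage
# comparison: genome-size regimes per lifestyle (narrow ~43 kb temperate,
# broader ~60 kb prophage, bimodal ~17.5/135 kb virulent), per-gene CDS
# sequences with controlled third-position GC and host codon adaptation,
# functional category labels, genome-size-gated tRNA counts, and pairwise
# similarity tables with a tunable fraction of no-similarity (NSS) pairs.
# All defaults are fixed, documented study conditions (see the methods
# vignette); every sampling step is reproducible from a single mandatory
# seed.

#' Lifestyle simulation profile
#'
#' @param lifestyle one of `"virulent"`, `"temperate"`, `"prophage"`.
#' @param genome_size_model list of truncated-normal mixture components,
#'   each `list(weight, mean, sd, min, max)` in bp; weights must sum to 1.
#' @param gene_length_meanlog,gene_length_sdlog log-normal parameters on
#'   gene length in codons (minimum 21 codons).
#' @param gc3_target target third-position GC percent for the synonymous
#'   tilt draw.
#' @param host_mix_alpha probability in `[0, 1]` that a codon is drawn from
#'   host reference frequencies instead of the GC3-tilted synonymous draw.
#' @param nss_rate probability that a within-group genome pair yields no
#'   similarity hits.
#' @param pid_mean,pid_sd percent-identity distribution of valid pairs.
#' @param trna_gate_bp genome size (bp) below which tRNAs never occur
#'   (`Inf` disables tRNAs).
#' @param trna_prob probability that a genome past the gate carries tRNAs.
#' @return object of class `lifestyle_profile`.
#' @export
lifestyle_profile <- function(lifestyle, genome_size_model,
                              gene_length_meanlog = log(130),
                              gene_length_sdlog = 0.93,
                              gc3_target, host_mix_alpha, nss_rate,
                              pid_mean = 85, pid_sd = 5,
                              trna_gate_bp = Inf, trna_prob = 0) {
  check_lifestyle(lifestyle, allow_na = FALSE)
  w <- vapply(genome_size_model, `[[`, numeric(1L), "weight")
  assert_that(abs(sum(w) - 1) < 1e-8, "mixture weights must sum to 1")
  for (cmp in genome_size_model) {
    assert_that(all(c("weight", "mean", "sd", "min", "max") %in% names(cmp)),
                "each mixture component needs weight, mean, sd, min, max")
    assert_that(cmp$min < cmp$max && cmp$sd > 0,
                "invalid mixture component bounds")
  }
  assert_that(host_mix_alpha >= 0 && host_mix_alpha <= 1,
              "host_mix_alpha must lie in [0, 1]")
  assert_that(nss_rate >= 0 && nss_rate <= 1,
              "nss_rate must lie in [0, 1]")
  structure(list(lifestyle = lifestyle, genome_size_model = genome_size_model,
                 gene_length_meanlog = gene_length_meanlog,
                 gene_length_sdlog = gene_length_sdlog,
                 gc3_target = gc3_target, host_mix_alpha = host_mix_alpha,
                 nss_rate = nss_rate, pid_mean = pid_mean, pid_sd = pid_sd,
                 trna_gate_bp = trna_gate_bp, trna_prob = trna_prob),
            class = "lifestyle_profile")
}

#' Default lifestyle profiles (the study conditions)
#'
#' Genome-size models: temperate 43,297 +/- 1,423 bp; prophage 61,021 +/-
#' 15,655 bp; virulent a 14:16 mixture of 17,500 +/- 600 bp and 135,000 +/-
#' 7,000 bp components. GC3 targets 28.0 / 25.8 / 19.8 percent and
#' host-mix alpha 0.35 / 0.50 / 0.90 for temperate / prophage / virulent;
#' NSS rates 0 / 0.055 / 0.591; mean percent identity of valid pairs
#' 83.51 / 84.62 / 86.89. tRNAs occur only in virulent genomes of at least
#' 120 kb (probability 0.56).
#'
#' @return named list of three [lifestyle_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    virulent = lifestyle_profile(
      "virulent",
      genome_size_model = list(
        list(weight = 14 / 30, mean = 17500, sd = 600,
             min = 16500, max = 19000),
        list(weight = 16 / 30, mean = 135000, sd = 7000,
             min = 120000, max = 149000)),
      gc3_target = 19.8, host_mix_alpha = 0.90, nss_rate = 0.591,
      pid_mean = 86.89, pid_sd = 5,
      trna_gate_bp = 120000, trna_prob = 0.56),
    temperate = lifestyle_profile(
      "temperate",
      genome_size_model = list(
        list(weight = 1, mean = 43297, sd = 1423,
             min = 39000, max = 47000)),
      gc3_target = 28.0, host_mix_alpha = 0.35, nss_rate = 0,
      pid_mean = 83.51, pid_sd = 5),
    prophage = lifestyle_profile(
      "prophage",
      genome_size_model = list(
        list(weight = 1, mean = 61021, sd = 15655,
             min = 43000, max = 131000)),
      gc3_target = 25.8, host_mix_alpha = 0.50, nss_rate = 0.055,
      pid_mean = 84.62, pid_sd = 5)
  )
}

#' Default functional-category mixture
#'
#' @return named probability vector over the six categories.
#' @export
default_category_mix <- function() {
  c(structural = 0.40, regulatory = 0.08, lysis = 0.05,
    replication = 0.12, repair = 0.03, unclassified = 0.32)
}

# Product strings emitted per category; classify_functional_category()
# recovers the generating category for every one of them.
#' @noRd
product_vocabulary <- function() {
  list(
    structural = c("portal protein", "major capsid protein",
                   "head morphogenesis protein", "tail fiber protein",
                   "baseplate wedge protein", "terminase large subunit",
                   "neck passage structure protein",
                   "host adsorption protein"),
    regulatory = c("transcriptional regulator", "repressor protein CI",
                   "antirepressor protein", "sigma factor",
                   "anti-sigma factor", "two-component response regulator",
                   "transcriptional activator"),
    lysis = c("endolysin", "holin",
              "N-acetylmuramoyl-L-alanine amidase",
              "tail-associated lysin", "hemolysin family protein"),
    replication = c("replication initiation protein", "DNA polymerase I",
                    "replicative DNA helicase", "DNA primase",
                    "proofreading exonuclease"),
    repair = c("DNA methyltransferase", "antirestriction protein ArdA",
               "restriction alleviation protein Lar",
               "dCMP hydroxymethylase",
               "DNA sulfur modification protein DndB"),
    unclassified = c("hypothetical protein", "phage protein")
  )
}

#' Simulation configuration
#'
#' @param seed mandatory integer seed driving all randomness.
#' @param n_genomes genomes per lifestyle group (default 30).
#' @param profiles named list of [lifestyle_profile()] objects.
#' @param category_mix probability vector over functional categories
#'   (must sum to 1).
#' @param usage_table host reference [codon_usage_table()] providing both
#'   amino-acid composition and host codon frequencies.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed, n_genomes = 30L,
                       profiles = default_profiles(),
                       category_mix = default_category_mix(),
                       usage_table = host_usage_table()) {
  assert_that(!missing(seed) && is.numeric(seed) && length(seed) == 1L &&
                is.finite(seed), "an integer seed is mandatory")
  assert_that(n_genomes >= 1L, "n_genomes must be positive")
  assert_that(abs(sum(category_mix) - 1) < 1e-8,
              "category_mix must sum to 1")
  assert_that(all(names(category_mix) %in% FUNCTIONAL_CATEGORIES),
              "unknown category in category_mix")
  for (p in profiles) stopifnot(inherits(p, "lifestyle_profile"))
  stopifnot(inherits(usage_table, "codon_usage_table"))
  structure(list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
                 profiles = profiles, category_mix = category_mix,
                 usage_table = usage_table),
            class = "sim_config")
}

# Deterministic genome ids per lifestyle group.
#' @noRd
genome_ids <- function(lifestyle, n) sprintf("%s_%02d", lifestyle, seq_len(n))

# Truncated normal sampler via inverse-CDF (reproducible, no rejection).
#' @noRd
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Sample genome sizes from a lifestyle profile
#'
#' @param profile a [lifestyle_profile()].
#' @param n number of genomes.
#' @param seed integer seed (`NULL` continues the current RNG stream).
#' @return numeric vector of genome sizes in bp.
#' @export
sample_genome_sizes <- function(profile, n, seed = NULL) {
  stopifnot(inherits(profile, "lifestyle_profile"))
  assert_that(is.numeric(n) && length(n) == 1L && n >= 1L,
              "n must be a positive count")
  with_seed(seed, {
    model <- profile$genome_size_model
    w <- vapply(model, `[[`, numeric(1L), "weight")
    # stratified allocation (largest remainder): the component counts are
    # a fixed property of the emulated dataset, not a per-draw coin flip
    alloc <- floor(w * n)
    rem <- w * n - alloc
    short <- n - sum(alloc)
    if (short > 0L) {
      top <- order(rem, decreasing = TRUE)[seq_len(short)]
      alloc[top] <- alloc[top] + 1L
    }
    comp <- rep(seq_along(model), alloc)
    sizes <- vapply(seq_len(n), function(i) {
      m <- model[[comp[i]]]
      rtruncnorm(1L, m$mean, m$sd, m$min, m$max)
    }, numeric(1L))
    sizes[sample.int(n)]
  })
}

# Amino-acid sampling frequencies and per-family codon probability tables
# derived from the host usage table. Computed once per generation run.
#' @noRd
codon_sampler_tables <- function(table, gc3_target) {
  counts <- setNames(table$entries$count, table$entries$codon)
  fams <- synonymous_families()
  aa_w <- vapply(fams, function(cod) sum(counts[cod]), numeric(1L))
  gc_end <- function(cod) substr(cod, 3L, 3L) %in% c("G", "C")
  g <- min(max(gc3_target, 1), 99) / 100
  host <- lapply(fams, function(cod) {
    p <- counts[cod]
    if (sum(p) == 0) p <- rep(1, length(cod))
    p / sum(p)
  })
  tilt <- lapply(fams, function(cod) {
    p <- ifelse(gc_end(cod), g, 1 - g)
    p / sum(p)
  })
  stops <- stop_codons()
  sp <- counts[stops]
  if (sum(sp) == 0) sp <- rep(1, length(stops))
  list(aa_freq = aa_w / sum(aa_w), fams = fams, host = host, tilt = tilt,
       stop_codons = stops, stop_prob = sp / sum(sp))
}

#' Generate one synthetic CDS
#'
#' Amino acids are drawn from the host table's amino-acid frequencies. Each
#' synonymous codon comes from the host frequencies with probability
#' `host_mix_alpha`, otherwise from a GC3 tilt that weights codons ending in
#' G/C by `gc3_target/100` against `1 - gc3_target/100`. The gene starts
#' with ATG, ends with a single stop codon and contains no internal stops.
#' A `gc3_target` of 0 or 100 is clamped to 1/99 with a warning.
#'
#' @param n_codons total codon count including start and stop (`>= 21`).
#' @param gc3_target target third-position GC percent.
#' @param host_mix_alpha host adaptation mixing probability in `[0, 1]`.
#' @param table host reference [codon_usage_table()].
#' @param seed integer seed (`NULL` continues the current RNG stream).
#' @param sampler precomputed internal sampler tables (for batch use).
#' @return nucleotide string of length `3 * n_codons`.
#' @export
generate_cds <- function(n_codons, gc3_target, host_mix_alpha, table,
                         seed = NULL, sampler = NULL) {
  assert_that(n_codons >= 21L, "n_codons must be at least 21")
  if (!is.null(table)) stopifnot(inherits(table, "codon_usage_table"))
  if (gc3_target <= 0 || gc3_target >= 100) {
    warning("gc3_target clamped to [1, 99]", call. = FALSE)
  }
  if (is.null(sampler)) sampler <- codon_sampler_tables(table, gc3_target)
  with_seed(seed, {
    m <- n_codons - 2L
    aa <- sample(names(sampler$aa_freq), m, replace = TRUE,
                 prob = sampler$aa_freq)
    from_host <- runif(m) < host_mix_alpha
    codons <- character(m)
    for (a in unique(aa)) {
      fam <- sampler$fams[[a]]
      for (host_route in c(TRUE, FALSE)) {
        idx <- which(aa == a & from_host == host_route)
        if (!length(idx)) next
        if (length(fam) == 1L) {
          codons[idx] <- fam
        } else {
          p <- if (host_route) sampler$host[[a]] else sampler$tilt[[a]]
          codons[idx] <- sample(fam, length(idx), replace = TRUE, prob = p)
        }
      }
    }
    stop_codon <- sample(sampler$stop_codons, 1L,
                         prob = sampler$stop_prob)
    paste0("ATG", paste(codons, collapse = ""), stop_codon)
  })
}

#' Generate the full synthetic dataset
#'
#' For each lifestyle: genome sizes from the profile's mixture, per-genome
#' gene counts scaled so that summed CDS length is about 90 percent of the
#' genome size, gene lengths log-normal in codons (minimum 21), functional
#' categories and product strings from the category mixture, and tRNA counts
#' gated on genome size. All randomness flows from the single configured
#' seed.
#'
#' @param config a [sim_config()].
#' @return list with `cds` (CDS record data frame) and `annotation`
#'   (annotation data frame with per-genome tRNA counts and genome sizes).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  vocab <- product_vocabulary()
  cat_names <- names(config$category_mix)
  with_seed(config$seed, {
    cds_list <- list()
    ann_list <- list()
    for (profile in config$profiles) {
      ls <- profile$lifestyle
      sizes <- sample_genome_sizes(profile, config$n_genomes)
      ids <- genome_ids(ls, config$n_genomes)
      sampler <- codon_sampler_tables(config$usage_table,
                                      profile$gc3_target)
      for (gi in seq_len(config$n_genomes)) {
        target_nt <- 0.9 * sizes[gi]
        mean_len <- exp(profile$gene_length_meanlog +
                          profile$gene_length_sdlog^2 / 2)
        n_draw <- ceiling(target_nt / (3 * mean_len) * 1.6) + 10L
        lens <- pmax(21L, round(rlnorm(n_draw, profile$gene_length_meanlog,
                                       profile$gene_length_sdlog)))
        n_genes <- which(cumsum(3 * lens) >= target_nt)[1L]
        if (is.na(n_genes)) n_genes <- n_draw
        lens <- lens[seq_len(n_genes)]
        cats <- sample(cat_names, n_genes, replace = TRUE,
                       prob = config$category_mix)
        products <- vapply(cats, function(cc) {
          v <- vocab[[cc]]
          v[sample.int(length(v), 1L)]
        }, character(1L))
        seqs <- vapply(lens, function(L) {
          generate_cds(L, profile$gc3_target, profile$host_mix_alpha,
                       table = NULL, sampler = sampler)
        }, character(1L))
        trna <- 0L
        if (sizes[gi] >= profile$trna_gate_bp &&
              runif(1L) < profile$trna_prob) {
          trna <- 1L + rpois(1L, (sizes[gi] - profile$trna_gate_bp) / 5000)
        }
        gene_ids <- sprintf("%s_g%04d", ids[gi], seq_len(n_genes))
        cds_list[[length(cds_list) + 1L]] <- data.frame(
          gene_id = gene_ids, genome_id = ids[gi], sequence = seqs,
          lifestyle = ls, product = products, stringsAsFactors = FALSE)
        ann_list[[length(ann_list) + 1L]] <- data.frame(
          gene_id = gene_ids, genome_id = ids[gi], lifestyle = ls,
          product = products, trna_count = trna,
          genome_size_bp = as.integer(round(sizes[gi])),
          stringsAsFactors = FALSE)
      }
    }
    cds <- do.call(rbind, cds_list)
    rownames(cds) <- NULL
    ann <- do.call(rbind, ann_list)
    rownames(ann) <- NULL
    list(cds = cds, annotation = ann)
  })
}

#' Generate within-group pairwise similarity tables
#'
#' For every unordered within-lifestyle genome pair: with probability
#' `nss_rate` no hits are emitted; otherwise both directions are emitted
#' with percent identity near a truncated-normal pair-level value around the
#' profile's mean and a broad low-median coverage distribution, with small
#' reciprocal asymmetry. Seeded independently of [generate_dataset()] (from
#' `config$seed + 1`) but over the same deterministic genome ids.
#'
#' @param config a [sim_config()].
#' @return directional hit data frame `query_id`, `subject_id`, `pid`,
#'   `pcov`.
#' @export
generate_similarity_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    out <- list()
    for (profile in config$profiles) {
      ids <- genome_ids(profile$lifestyle, config$n_genomes)
      if (length(ids) < 2L) next
      grid <- t(combn(ids, 2L))
      n_pairs <- nrow(grid)
      is_nss <- runif(n_pairs) < profile$nss_rate
      for (j in seq_len(n_pairs)) {
        if (is_nss[j]) next
        pid0 <- rtruncnorm(1L, profile$pid_mean, profile$pid_sd, 50, 100)
        pcov0 <- 100 * rbeta(1L, 1.2, 3.5)
        pid_dir <- pmin(100, pmax(0, pid0 + rnorm(2L, 0, 1)))
        pcov_dir <- pmin(100, pmax(0, pcov0 + rnorm(2L, 0, 2)))
        out[[length(out) + 1L]] <- data.frame(
          query_id = c(grid[j, 1L], grid[j, 2L]),
          subject_id = c(grid[j, 2L], grid[j, 1L]),
          pid = round(pid_dir, 3), pcov = round(pcov_dir, 3),
          stringsAsFactors = FALSE)
      }
    }
    if (!length(out)) {
      return(data.frame(query_id = character(0L),
                        subject_id = character(0L),
                        pid = numeric(0L), pcov = numeric(0L),
                        stringsAsFactors = FALSE))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
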