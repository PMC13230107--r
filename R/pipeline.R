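# End-to-end orchestration: simulate -> per-gene metrics -> genome distances
# -> the statistical ledger. Each stage is exported on its own; run_all()
# chains them for the single-command synthetic demo. Outputs are plain data
# frames plus a JSON results bundle writer.

#' Simulate a complete input set
#'
#' @param config a [sim_config()].
#' @return list with `cds`, `annotation` and `hits`.
#' @export
run_simulate <- function(config) {
  dataset <- generate_dataset(config)
  hits <- generate_similarity_table(config)
  c(dataset, list(hits = hits))
}

#' Per-gene metrics stage
#'
#' Computes the seven metrics for every CDS, joins lifestyle/product
#' information from the annotation, assigns functional categories, and
#' summarises every metric per lifestyle (mean, SD, min, max, P10-P90
#' percentiles and IQR).
#'
#' @param cds CDS record data frame.
#' @param usage_table host reference [codon_usage_table()].
#' @param annotation optional annotation data frame overriding
#'   lifestyle/product carried on the CDS records.
#' @param include_terminal_stop GC sensitivity switch, see
#'   [positional_gc()].
#' @return list with `metrics` (per-gene rows incl. `category`) and
#'   `summary` (lifestyle x metric descriptive blocks).
#' @export
run_metrics <- function(cds, usage_table, annotation = NULL,
                        include_terminal_stop = FALSE) {
  assert_that(nrow(cds) > 0L, "no CDS records")
  if (!is.null(annotation)) {
    m <- match(cds$gene_id, annotation$gene_id)
    cds$lifestyle <- ifelse(is.na(m), cds$lifestyle, annotation$lifestyle[m])
    cds$product <- ifelse(is.na(m), cds$product, annotation$product[m])
    cds$genome_id <- ifelse(is.na(m), cds$genome_id, annotation$genome_id[m])
  }
  weights <- adaptiveness_weights(usage_table)
  metrics <- compute_gene_metrics(cds, weights,
                                  include_terminal_stop =
                                    include_terminal_stop)
  m <- match(metrics$gene_id, cds$gene_id)
  metrics$category <- classify_functional_category(cds$product[m])
  nc_missing <- sum(is.na(metrics$nc))
  if (nc_missing > 0L) {
    message(sprintf("Nc undefined for %d gene(s); excluded pairwise from Nc statistics",
                    nc_missing))
  }
  summaries <- list()
  for (ls in intersect(LIFESTYLES, unique(metrics$lifestyle))) {
    sub <- metrics[metrics$lifestyle %in% ls, , drop = FALSE]
    for (met in GENE_METRICS) {
      d <- describe_vector(sub[[met]])
      summaries[[length(summaries) + 1L]] <-
        cbind(data.frame(lifestyle = ls, metric = met,
                         stringsAsFactors = FALSE), d)
    }
  }
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  list(metrics = metrics, summary = summary)
}

#' Genome distance stage
#'
#' Builds the complete within-lifestyle pair sets from directional hits and
#' produces both heterogeneity summaries (valid-only and all-pairs) per
#' lifestyle group.
#'
#' @param hits directional hit data frame.
#' @param genomes data frame with `genome_id` and `lifestyle` (one row per
#'   genome); every genome in `hits` must appear here.
#' @return list with `pairs` (per-lifestyle pair tables, `lifestyle`
#'   column added) and `summary` (one row per lifestyle x scope).
#' @export
run_distance <- function(hits, genomes) {
  genomes <- unique(genomes[, c("genome_id", "lifestyle")])
  check_lifestyle(genomes$lifestyle)
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)),
                     genomes$genome_id)
  if (length(unknown)) {
    stop(sprintf("hits reference genome(s) absent from the annotation: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  pair_list <- list()
  sum_list <- list()
  for (ls in intersect(LIFESTYLES, unique(genomes$lifestyle))) {
    ids <- genomes$genome_id[genomes$lifestyle %in% ls]
    if (length(ids) < 2L) next
    sub_hits <- hits[hits$query_id %in% ids & hits$subject_id %in% ids, ,
                     drop = FALSE]
    pairs <- pair_from_hits(sub_hits, ids)
    pairs$lifestyle <- ls
    pair_list[[ls]] <- pairs
    for (scope in c("valid_only", "all_pairs")) {
      s <- tryCatch(summarize_pairs(pairs, scope), error = function(e) NULL)
      if (!is.null(s)) {
        s <- cbind(data.frame(lifestyle = ls, stringsAsFactors = FALSE), s)
        sum_list[[paste(ls, scope)]] <- s
      }
    }
  }
  pairs <- do.call(rbind, pair_list)
  rownames(pairs) <- NULL
  nm <- unique(unlist(lapply(sum_list, names)))
  sum_list <- lapply(sum_list, function(s) {
    s[setdiff(nm, names(s))] <- NA_real_
    s[nm]
  })
  summary <- do.call(rbind, sum_list)
  rownames(summary) <- NULL
  list(pairs = pairs, summary = summary)
}

#' @noRd
metric_groups <- function(metrics, column) {
  ls_present <- intersect(LIFESTYLES, unique(metrics$lifestyle))
  g <- lapply(ls_present, function(ls) {
    v <- metrics[[column]][metrics$lifestyle %in% ls]
    v[is.finite(v)]
  })
  names(g) <- ls_present
  g[lengths(g) > 0L]
}

#' Statistical ledger stage
#'
#' Runs every analysis block on the per-gene metrics and the genome table:
#' (a) genome-size Kruskal-Wallis + Dunn contrasts with eta2/epsilon2;
#' (b) per-metric Kruskal-Wallis with epsilon2 labels; (c) pairwise
#' Mann-Whitney + Holm + Cliff's delta for metrics with a significant
#' omnibus test; (d) per-lifestyle Spearman correlations among
#' log10-length and the compositional metrics with bootstrap CIs and BH
#' correction, plus partial Spearman controlling GC3 and overall GC;
#' (e) functional-category analyses (Scheirer-Ray-Hare category x
#' lifestyle, within-lifestyle category contrasts, within-category
#' lifestyle contrasts) on per-genome category medians (or gene-level
#' values via `category_unit`); (f) PERMANOVA + PERMDISP per lifestyle
#' pair on z-scored metric profiles with balanced subsampling;
#' (g) genome-size/tRNA correlations. Genes with undefined Nc are excluded
#' pairwise per metric. Block failures are isolated and recorded under
#' `errors`.
#'
#' @param metrics per-gene metrics data frame (from [run_metrics()]).
#' @param genomes data frame with `genome_id`, `lifestyle`,
#'   `genome_size_bp` and optionally `trna_count`.
#' @param seed integer seed for the stochastic blocks (bootstrap,
#'   subsampling, permutations).
#' @param n_perm permutations for PERMANOVA/PERMDISP (default 999).
#' @param subsample_cap per-group gene cap for PERMANOVA subsampling
#'   (default 1953; the effective size is the smaller of this and the
#'   smallest group).
#' @param boot_B bootstrap iterations for correlation CIs (default 1000).
#' @param category_unit `"genome_median"` (default) analyses per-genome
#'   medians within each functional category; `"gene"` analyses gene-level
#'   values.
#' @param alpha significance threshold gating post-hoc blocks (default
#'   0.05).
#' @return named list of result blocks plus a `meta` record of seeds and
#'   correction methods.
#' @export
run_stats <- function(metrics, genomes, seed, n_perm = 999L,
                      subsample_cap = 1953L, boot_B = 1000L,
                      category_unit = c("genome_median", "gene"),
                      alpha = 0.05) {
  category_unit <- match.arg(category_unit)
  assert_that(!missing(seed), "a seed is required for the stochastic blocks")
  errors <- list()
  res <- list()
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  # (a) genome size ----------------------------------------------------
  res$genome_size <- grab("genome_size", {
    gu <- unique(genomes[, c("genome_id", "lifestyle", "genome_size_bp")])
    groups <- split(gu$genome_size_bp,
                    factor(gu$lifestyle,
                           levels = intersect(LIFESTYLES, gu$lifestyle)))
    list(kw = kruskal_wallis(groups), dunn = dunn_posthoc(groups),
         summary = do.call(rbind, lapply(names(groups), function(ls) {
           cbind(data.frame(lifestyle = ls, stringsAsFactors = FALSE),
                 describe_vector(groups[[ls]]))
         })))
  })

  # (b) per-metric omnibus tests ---------------------------------------
  res$metric_kw <- grab("metric_kw", {
    rows <- lapply(GENE_METRICS, function(met) {
      g <- metric_groups(metrics, met)
      kw <- kruskal_wallis(g)
      data.frame(metric = met, H = kw$H, df = kw$df, p = kw$p,
                 eta2 = kw$eta2, epsilon2 = kw$epsilon2,
                 effect = epsilon2_label(kw$epsilon2), N = kw$N,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  # (c) pairwise lifestyle contrasts per significant metric ------------
  res$pairwise <- grab("pairwise", {
    sig <- res$metric_kw$metric[res$metric_kw$p < alpha]
    rows <- list()
    for (met in sig) {
      g <- metric_groups(metrics, met)
      idx <- combn(names(g), 2L)
      p_raw <- numeric(ncol(idx))
      block <- vector("list", ncol(idx))
      for (j in seq_len(ncol(idx))) {
        a <- idx[1L, j]; b <- idx[2L, j]
        mw <- mann_whitney(g[[a]], g[[b]])
        cd <- cliffs_delta(g[[a]], g[[b]])
        p_raw[j] <- mw$p
        block[[j]] <- data.frame(
          metric = met, group_1 = a, group_2 = b, U = mw$U, p_raw = mw$p,
          cliffs_delta = cd$delta, magnitude = cd$magnitude,
          direction = if (cd$delta > 0) paste(a, ">", b)
                      else if (cd$delta < 0) paste(b, ">", a)
                      else paste(a, "=", b),
          stringsAsFactors = FALSE)
      }
      block <- do.call(rbind, block)
      block$p_holm <- holm_adjust(p_raw)
      block$correction <- "holm"
      rows[[met]] <- block
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  # (d) correlation structure per lifestyle ----------------------------
  corr_vars <- c("log_nt", "gc", "gc1", "gc2", "gc3", "cai", "nc")
  res$correlations <- grab("correlations", {
    rows <- list()
    boot_seed <- seed + 11L
    for (ls in intersect(LIFESTYLES, unique(metrics$lifestyle))) {
      sub <- metrics[metrics$lifestyle %in% ls, , drop = FALSE]
      sub$log_nt <- log10(sub$nt)
      pr <- combn(corr_vars, 2L)
      p_raw <- numeric(ncol(pr))
      block <- vector("list", ncol(pr))
      for (j in seq_len(ncol(pr))) {
        v1 <- pr[1L, j]; v2 <- pr[2L, j]
        ok <- is.finite(sub[[v1]]) & is.finite(sub[[v2]])
        sp <- spearman(sub[[v1]][ok], sub[[v2]][ok])
        ci <- bootstrap_ci(sub[[v1]][ok], sub[[v2]][ok], B = boot_B,
                           seed = boot_seed + j)
        p_raw[j] <- sp$p
        block[[j]] <- data.frame(
          lifestyle = ls, var_1 = v1, var_2 = v2, rho = sp$rho,
          p_raw = sp$p, ci_low = ci[1L], ci_high = ci[2L], n = sum(ok),
          stringsAsFactors = FALSE)
      }
      block <- do.call(rbind, block)
      block$p_fdr <- bh_adjust(p_raw)
      block$correction <- "bh"
      rows[[ls]] <- block
      boot_seed <- boot_seed + 100L
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  res$partial_correlations <- grab("partial_correlations", {
    part_vars <- setdiff(corr_vars, c("gc", "gc3"))
    rows <- list()
    for (ls in intersect(LIFESTYLES, unique(metrics$lifestyle))) {
      sub <- metrics[metrics$lifestyle %in% ls, , drop = FALSE]
      sub$log_nt <- log10(sub$nt)
      pr <- combn(part_vars, 2L)
      p_raw <- numeric(ncol(pr))
      block <- vector("list", ncol(pr))
      for (j in seq_len(ncol(pr))) {
        v1 <- pr[1L, j]; v2 <- pr[2L, j]
        ok <- is.finite(sub[[v1]]) & is.finite(sub[[v2]]) &
          is.finite(sub$gc3) & is.finite(sub$gc)
        ps <- partial_spearman(sub[[v1]][ok], sub[[v2]][ok],
                               cbind(gc3 = sub$gc3[ok], gc = sub$gc[ok]))
        p_raw[j] <- ps$p
        block[[j]] <- data.frame(
          lifestyle = ls, var_1 = v1, var_2 = v2, rho = ps$rho,
          p_raw = ps$p, df = ps$df, covariates = "gc3,gc", n = sum(ok),
          stringsAsFactors = FALSE)
      }
      block <- do.call(rbind, block)
      block$p_fdr <- bh_adjust(p_raw)
      block$correction <- "bh"
      rows[[ls]] <- block
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  # (e) functional gene categories -------------------------------------
  res$functional <- grab("functional", {
    cats <- setdiff(FUNCTIONAL_CATEGORIES, "unclassified")
    sub <- metrics[metrics$category %in% cats, , drop = FALSE]
    if (category_unit == "genome_median") {
      unit <- aggregate(sub[GENE_METRICS],
                        by = list(genome_id = sub$genome_id,
                                  lifestyle = sub$lifestyle,
                                  category = sub$category),
                        FUN = function(v) median(v, na.rm = TRUE))
    } else {
      unit <- sub[, c("genome_id", "lifestyle", "category", GENE_METRICS)]
    }
    srh_rows <- list()
    within_ls <- list()
    within_cat <- list()
    for (met in GENE_METRICS) {
      v <- unit[[met]]
      ok <- is.finite(v)
      s <- tryCatch(scheirer_ray_hare(v[ok], unit$category[ok],
                                      unit$lifestyle[ok]),
                    error = function(e) NULL)
      if (!is.null(s)) {
        srh_rows[[met]] <- data.frame(
          metric = met, h_category = s$h_factor_a,
          h_lifestyle = s$h_factor_b, h_interaction = s$h_interaction,
          p_category = s$p_a, p_lifestyle = s$p_b,
          p_interaction = s$p_interaction, stringsAsFactors = FALSE)
      }
      for (ls in intersect(LIFESTYLES, unique(unit$lifestyle))) {
        uls <- unit[unit$lifestyle %in% ls, , drop = FALSE]
        g <- lapply(split(uls[[met]], uls$category),
                    function(x) x[is.finite(x)])
        g <- g[lengths(g) > 0L]
        if (length(g) < 2L) next
        kw <- kruskal_wallis(g)
        row <- data.frame(lifestyle = ls, metric = met, H = kw$H, p = kw$p,
                          epsilon2 = kw$epsilon2,
                          effect = epsilon2_label(kw$epsilon2),
                          stringsAsFactors = FALSE)
        within_ls[[paste(ls, met)]] <- row
        if (kw$p < alpha) {
          dn <- dunn_posthoc(g)
          dn <- cbind(data.frame(lifestyle = ls, metric = met,
                                 stringsAsFactors = FALSE), dn)
          within_cat[[paste(ls, met)]] <- dn
        }
      }
    }
    cat_contrasts <- list()
    for (met in GENE_METRICS) {
      for (cc in intersect(cats, unique(unit$category))) {
        ucat <- unit[unit$category %in% cc, , drop = FALSE]
        g <- lapply(split(ucat[[met]], ucat$lifestyle),
                    function(x) x[is.finite(x)])
        g <- g[lengths(g) > 1L]
        if (length(g) < 2L) next
        kw <- kruskal_wallis(g)
        if (kw$p >= alpha) next
        idx <- combn(names(g), 2L)
        p_raw <- numeric(ncol(idx))
        block <- vector("list", ncol(idx))
        for (j in seq_len(ncol(idx))) {
          a <- idx[1L, j]; b <- idx[2L, j]
          mw <- mann_whitney(g[[a]], g[[b]])
          cd <- cliffs_delta(g[[a]], g[[b]])
          p_raw[j] <- mw$p
          block[[j]] <- data.frame(
            metric = met, category = cc, group_1 = a, group_2 = b,
            U = mw$U, p_raw = mw$p, cliffs_delta = cd$delta,
            magnitude = cd$magnitude,
            direction = if (cd$delta > 0) paste(a, ">", b)
                        else if (cd$delta < 0) paste(b, ">", a)
                        else paste(a, "=", b),
            stringsAsFactors = FALSE)
        }
        block <- do.call(rbind, block)
        block$p_holm <- holm_adjust(p_raw)
        block$correction <- "holm"
        cat_contrasts[[paste(met, cc)]] <- block
      }
    }
    list(unit = category_unit,
         srh = {
           x <- do.call(rbind, srh_rows); rownames(x) <- NULL; x
         },
         within_lifestyle = {
           x <- do.call(rbind, within_ls); rownames(x) <- NULL; x
         },
         within_lifestyle_dunn = {
           x <- do.call(rbind, within_cat); rownames(x) <- NULL; x
         },
         lifestyle_contrasts = {
           x <- do.call(rbind, cat_contrasts); rownames(x) <- NULL; x
         })
  })

  # (f) multivariate separation ----------------------------------------
  res$permanova <- grab("permanova", {
    feats <- metrics[, GENE_METRICS]
    ok <- apply(is.finite(as.matrix(feats)), 1L, all)
    feats <- as.matrix(feats)[ok, , drop = FALSE]
    lab <- metrics$lifestyle[ok]
    ls_present <- intersect(LIFESTYLES, unique(lab))
    idx <- combn(ls_present, 2L)
    rows <- lapply(seq_len(ncol(idx)), function(j) {
      a <- idx[1L, j]; b <- idx[2L, j]
      keep <- lab %in% c(a, b)
      nmin <- min(table(lab[keep]))
      ss <- min(subsample_cap, nmin)
      pr <- permanova(feats[keep, , drop = FALSE], lab[keep],
                      n_perm = n_perm, subsample_n = ss,
                      seed = seed + 1000L + j)
      data.frame(group_1 = a, group_2 = b, pseudo_f = pr$pseudo_f,
                 r2 = pr$r2, p = pr$p, dispersion_f = pr$dispersion_f,
                 dispersion_p = pr$dispersion_p, subsample_n = ss,
                 n_perm = n_perm, seed = pr$seed,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  # (g) tRNA associations ----------------------------------------------
  res$trna <- grab("trna", {
    if (is.null(genomes$trna_count) || all(is.na(genomes$trna_count))) {
      stop("no tRNA counts available", call. = FALSE)
    }
    gv <- unique(genomes[genomes$lifestyle == "virulent",
                         c("genome_id", "genome_size_bp", "trna_count")])
    # no tRNA variation (e.g. no carriers at all) leaves the association
    # undefined rather than failing the block
    sp_size <- tryCatch(spearman(gv$genome_size_bp, gv$trna_count),
                        error = function(e) list(rho = NA_real_,
                                                 p = NA_real_))
    med_cai <- tapply(metrics$cai[metrics$lifestyle == "virulent"],
                      metrics$genome_id[metrics$lifestyle == "virulent"],
                      median, na.rm = TRUE)
    presence <- as.numeric(gv$trna_count[match(names(med_cai),
                                               gv$genome_id)] > 0)
    sp_cai <- tryCatch(spearman(as.numeric(med_cai), presence),
                       error = function(e) list(rho = NA_real_,
                                                p = NA_real_))
    data.frame(
      association = c("genome_size_vs_trna_count",
                      "median_cai_vs_trna_presence"),
      rho = c(sp_size$rho, sp_cai$rho), p = c(sp_size$p, sp_cai$p),
      n = c(nrow(gv), length(med_cai)), stringsAsFactors = FALSE)
  })

  res$meta <- list(seed = seed, n_perm = n_perm,
                   subsample_cap = subsample_cap, boot_B = boot_B,
                   category_unit = category_unit, alpha = alpha,
                   corrections = c(pairwise = "holm", correlations = "bh",
                                   dunn = "holm"))
  res$errors <- errors
  res
}

#' Run the full synthetic pipeline
#'
#' Simulates a dataset, computes per-gene metrics, genome distances, and
#' the complete statistical ledger. Bit-reproducible for a given
#' configuration.
#'
#' @param config a [sim_config()].
#' @param ... passed to [run_stats()] (`n_perm`, `subsample_cap`,
#'   `boot_B`, `category_unit`).
#' @return list with `data`, `metrics`, `distance` and `stats`.
#' @export
run_all <- function(config, ...) {
  stopifnot(inherits(config, "sim_config"))
  data <- run_simulate(config)
  genomes <- unique(data$annotation[, c("genome_id", "lifestyle",
                                        "genome_size_bp", "trna_count")])
  met <- run_metrics(data$cds, config$usage_table,
                     annotation = data$annotation)
  dist <- run_distance(data$hits, genomes)
  stats <- run_stats(met$metrics, genomes, seed = config$seed, ...)
  list(data = data, metrics = met, distance = dist, stats = stats)
}

#' Write pipeline outputs to disk
#'
#' Emits the per-gene metrics, summaries, pair tables and heterogeneity
#' summaries as TSV plus a `results.json` bundle holding the statistical
#' ledger (seeds and corrections included).
#'
#' @param results output of [run_all()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_results_bundle <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table(results$metrics$metrics, file.path(dir, "gene_metrics.tsv"))
  write_table(results$metrics$summary,
              file.path(dir, "metric_summary.tsv"))
  if (!is.null(results$distance)) {
    write_table(results$distance$pairs, file.path(dir, "genome_pairs.tsv"))
    write_table(results$distance$summary,
                file.path(dir, "heterogeneity_summary.tsv"))
  }
  stats <- results$stats
  stats$genome_size$kw <- unclass(stats$genome_size$kw)
  jsonlite::write_json(stats, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(dir)
}
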