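test_that("genome-size sampling hits the configured regimes", {
  profs <- default_profiles()
  sizes <- sample_genome_sizes(profs$temperate, 1000, seed = 201)
  expect_lt(abs(mean(sizes) - 43297), 200)
  expect_true(all(sizes >= 39000 & sizes <= 47000))

  # virulent sizes are bimodal: two well-separated clusters, empty middle
  vs <- sample_genome_sizes(profs$virulent, 1000, seed = 202)
  expect_gt(mean(vs < 20000), 0.35)
  expect_gt(mean(vs > 120000), 0.45)
  expect_equal(sum(vs > 20000 & vs < 120000), 0L)

  expect_identical(sample_genome_sizes(profs$prophage, 50, seed = 7),
                   sample_genome_sizes(profs$prophage, 50, seed = 7))
  expect_error(sample_genome_sizes(profs$temperate, 0), "positive")
})

test_that("generated CDS satisfy the structural contract", {
  tab <- host_usage_table()
  stops <- c("TAA", "TAG", "TGA")
  set.seed(203)
  for (i in 1:20) {
    L <- sample(21:400, 1)
    s <- generate_cds(L, gc3_target = runif(1, 5, 95),
                      host_mix_alpha = runif(1), table = tab)
    expect_equal(nchar(s), 3 * L)
    expect_equal(substr(s, 1, 3), "ATG")
    cods <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    expect_true(cods[L] %in% stops)
    expect_false(any(cods[-L] %in% stops))
  }
  expect_error(generate_cds(10, 25, 0.5, tab), "at least 21")
  expect_warning(generate_cds(30, 0, 0.5, tab), "clamped")
})

test_that("alpha = 1 reproduces host codon proportions per family", {
  tab <- host_usage_table()
  s <- generate_cds(20000, gc3_target = 50, host_mix_alpha = 1,
                    table = tab, seed = 205)
  cods <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
  cods <- cods[-c(1, length(cods))]
  counts <- setNames(tab$entries$count, tab$entries$codon)
  code <- Biostrings::GENETIC_CODE
  # chi-square goodness of fit within the largest families
  for (aa in c("L", "S", "G", "A", "K")) {
    fam <- names(code)[code == aa]
    obs <- table(factor(cods[cods %in% fam], levels = fam))
    expterm <- counts[fam] / sum(counts[fam])
    suppressWarnings(
      gof <- chisq.test(as.numeric(obs), p = as.numeric(expterm)))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("the GC3 tilt moves third-position composition as configured", {
  tab <- host_usage_table()
  mean_gc3 <- function(target, seed) {
    withr::with_seed(seed, {
      mean(vapply(rep(150, 200), function(L) {
        s <- generate_cds(L, gc3_target = target, host_mix_alpha = 0,
                         table = tab)
        positional_gc(s)[["gc3"]]
      }, numeric(1)))
    })
  }
  g20 <- mean_gc3(20, 207)
  g50 <- mean_gc3(50, 207)
  expect_gt(g50 - g20, 10)
})

test_that("dataset generation respects the configuration contract", {
  cfg <- sim_config(seed = 209, n_genomes = 6)
  ds <- generate_dataset(cfg)
  expect_equal(length(unique(ds$annotation$genome_id)), 18L)
  expect_equal(as.vector(table(unique(
    ds$annotation[, c("genome_id", "lifestyle")])$lifestyle)),
    rep(6L, 3))
  # summed CDS length tracks 90% of genome size
  per_genome <- tapply(nchar(ds$cds$sequence), ds$cds$genome_id, sum)
  gsz <- unique(ds$annotation[, c("genome_id", "genome_size_bp")])
  ratio <- per_genome[gsz$genome_id] / gsz$genome_size_bp
  expect_true(all(ratio > 0.85 & ratio < 1.0))
  # every generated CDS is a valid codon_metrics input
  w <- adaptiveness_weights(cfg$usage_table)
  m <- compute_gene_metrics(ds$cds[sample(nrow(ds$cds), 50), ], w)
  expect_equal(nrow(m), 50L)
  expect_null(attr(m, "failures"))
  # determinism
  ds2 <- generate_dataset(cfg)
  expect_identical(ds, ds2)
  expect_error(sim_config(seed = 1, category_mix = c(structural = 0.5)),
               "sum to 1")
})

test_that("tRNAs occur only in virulent genomes past the size gate", {
  cfg <- sim_config(seed = 211, n_genomes = 12)
  ds <- generate_dataset(cfg)
  g <- unique(ds$annotation[, c("genome_id", "lifestyle", "trna_count",
                                "genome_size_bp")])
  carriers <- g[g$trna_count > 0, ]
  expect_true(all(carriers$lifestyle == "virulent"))
  expect_true(all(carriers$genome_size_bp >= 120000))
  expect_gt(nrow(carriers), 0)
})

test_that("similarity tables realise the configured NSS rates", {
  cfg0 <- sim_config(seed = 213, n_genomes = 10)
  cfg0$profiles$virulent$nss_rate <- 0
  cfg0$profiles$prophage$nss_rate <- 0
  hits <- generate_similarity_table(cfg0)
  ann <- data.frame(genome_id = unlist(lapply(names(cfg0$profiles),
                                              function(l) sprintf("%s_%02d", l, 1:10))),
                    lifestyle = rep(names(cfg0$profiles), each = 10))
  rd <- run_distance(hits, ann)
  expect_true(all(rd$summary$prop_nss == 0))

  # binomial mean of the NSS proportion at the default virulent rate
  props <- vapply(1:50, function(r) {
    cfg <- sim_config(seed = 5000 + r)
    h <- generate_similarity_table(cfg)
    ids <- sprintf("virulent_%02d", 1:30)
    p <- pair_from_hits(h[h$query_id %in% ids, ], ids)
    mean(p$nss)
  }, numeric(1))
  expect_lt(abs(mean(props) - 0.591), 0.015)

  expect_identical(generate_similarity_table(cfg0),
                   generate_similarity_table(cfg0))
})

test_that("recovered group means tighten with more genes (root-n scaling)", {
  tab <- host_usage_table()
  sam <- phagecub:::codon_sampler_tables(tab, 25)
  batch_mean <- function(n, seed) {
    withr::with_seed(seed, {
      mean(vapply(rep(120, n), function(L) {
        s <- generate_cds(L, 25, 0.5, table = NULL, sampler = sam)
        positional_gc(s)[["gc3"]]
      }, numeric(1)))
    })
  }
  sd_small <- sd(vapply(1:12, function(r) batch_mean(40, 600 + r),
                        numeric(1)))
  sd_large <- sd(vapply(1:12, function(r) batch_mean(160, 700 + r),
                        numeric(1)))
  expect_lt(sd_large, sd_small)
})
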