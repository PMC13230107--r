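test_that("positional GC matches hand counts and excludes the stop codon", {
  # ATG AAA: the single G sits at codon position 3
  expect_equal(unname(positional_gc("ATGAAA")),
               c(100 * 1 / 6, 0, 0, 50))
  # GCG GCG: G and C at every position
  expect_equal(unname(positional_gc("GCGGCG")), c(100, 100, 100, 100))
  # terminal stop excluded: ATG AAA TAA reduces to ATG AAA
  expect_equal(positional_gc("ATGAAATAA"), positional_gc("ATGAAA"))
  # ATG AAA TAA with the stop counted: one G over nine bases, position 3
  # carries G,A,A
  expect_equal(unname(positional_gc("ATGAAATAA",
                                    include_terminal_stop = TRUE)),
               c(100 * 1 / 9, 0, 0, 100 * 1 / 3))
  expect_error(positional_gc("ATGAA"), "not a multiple of 3")
  expect_error(positional_gc("NNNNNN"), "excluded")
})

test_that("overall GC equals the mean of positional GC without exclusions", {
  set.seed(5)
  for (i in 1:10) {
    s <- random_cds(400 + i)
    s <- substr(s, 1, nchar(s) - 3)  # drop stop: no trimming, no N
    gcs <- positional_gc(s)
    expect_equal(gcs[["gc"]], mean(gcs[c("gc1", "gc2", "gc3")]),
                 tolerance = 1e-12)
  }
})

test_that("adaptiveness weights are family-maximal ratios with pseudo-counts", {
  counts <- uniform_counts(100)
  counts["AAA"] <- 800; counts["AAG"] <- 200
  w <- adaptiveness_weights(make_usage_table(counts))
  expect_equal(unname(w$w["AAA"]), 1)
  expect_equal(unname(w$w["AAG"]), 0.25)
  # uniform table: all weights 1
  wu <- adaptiveness_weights(make_usage_table(uniform_counts(1000)))
  expect_true(all(wu$w == 1))
  # zero-count codon gets the 0.5 pseudo-count
  cz <- uniform_counts(100)
  cz["GGG"] <- 0
  wz <- adaptiveness_weights(make_usage_table(cz))
  expect_equal(unname(wz$w["GGG"]), 0.005)
  # per-family maxima are exactly 1
  code <- Biostrings::GENETIC_CODE
  fams <- split(names(code)[code != "*"], code[code != "*"])
  wmax <- vapply(fams, function(cod) max(wz$w[cod]), numeric(1))
  expect_true(all(wmax == 1))
})

test_that("CAI corners and log-domain equivalence hold", {
  counts <- uniform_counts(100)
  counts["AAA"] <- 800; counts["AAG"] <- 200
  tab <- make_usage_table(counts)
  w <- adaptiveness_weights(tab)
  # two-codon gene with weights 0.25 and 1
  expect_equal(cai("AAGAAA", w), sqrt(0.25 * 1))
  # gene of family-maximal codons: CAI exactly 1
  wmax_codons <- vapply(
    split(names(w$w), Biostrings::GENETIC_CODE[names(w$w)]),
    function(cod) cod[which.max(w$w[cod])], character(1))
  g <- paste0("ATG", paste(rep(wmax_codons, each = 3), collapse = ""), "TAA")
  expect_equal(cai(g, w), 1)
  # log-domain computation equals the direct product oracle
  hw <- adaptiveness_weights(host_usage_table())
  set.seed(23)
  for (i in 1:10) {
    s <- random_cds(300)
    expect_equal(cai(s, hw), oracle_cai(s, hw), tolerance = 1e-12)
  }
})

test_that("Nc attains its analytic limits", {
  w <- adaptiveness_weights(make_usage_table(uniform_counts(10)))
  # one codon per family, each used three times: maximal bias, Nc = 20
  one_per_family <- vapply(
    split(names(w$w), Biostrings::GENETIC_CODE[names(w$w)]),
    `[`, character(1), 1L)
  g <- paste0(paste(rep(one_per_family, each = 3), collapse = ""))
  expect_equal(nc(g), 20)
  # asymptotically uniform synonymous usage approaches 61 (capped)
  set.seed(31)
  code <- Biostrings::GENETIC_CODE
  all_sense <- names(code)[code != "*"]
  g2 <- paste(sample(rep(all_sense, 40)), collapse = "")
  expect_equal(nc(g2), 61, tolerance = 0.02)
  # too short for the required family averages: undefined
  expect_true(is.na(nc("ATGAAA")))
})

test_that("Nc matches an independent symbol-by-symbol oracle", {
  set.seed(37)
  tab <- host_usage_table()
  for (i in 1:12) {
    s <- generate_cds(500, gc3_target = runif(1, 10, 60),
                      host_mix_alpha = runif(1), table = tab)
    expect_equal(nc(s), oracle_nc(s), tolerance = 1e-9)
  }
})

test_that("Nc is invariant under synonymous permutation; CAI is not", {
  counts <- uniform_counts(100)
  counts["GGT"] <- 900
  w <- adaptiveness_weights(make_usage_table(counts))
  # same family counts {GGT x2, GGA x1} in different codon orders
  a <- "GGTGGAGGTAAAAAGAAAATTATAATT"
  b <- "GGAGGTGGTAAAAAGAAAATTATAATT"
  expect_equal(nc(a), nc(b))
  # swapping which codon is used changes CAI but preserves counts per family
  a2 <- "GGTGGTGGAAAAAAGAAA"
  b2 <- "GGAGGAGGTAAAAAGAAA"
  expect_equal(nc(a2), nc(b2))
  expect_false(isTRUE(all.equal(cai(a2, w), cai(b2, w))))
})

test_that("gene_metrics composes the per-gene metrics and batches survive
           frame-broken genes", {
  tab <- host_usage_table()
  w <- adaptiveness_weights(tab)
  wmax_codons <- vapply(
    split(names(w$w), Biostrings::GENETIC_CODE[names(w$w)]),
    function(cod) cod[which.max(w$w[cod])], character(1))
  g <- paste0(paste(rep(wmax_codons, each = 3), collapse = ""))
  rec <- cds_records("g1", g)
  gm <- gene_metrics(rec, w)
  expect_equal(gm$cai, 1)
  expect_equal(gm$nc, 20)
  expect_equal(gm$nt, nchar(g))

  set.seed(41)
  seqs <- vapply(rep(60, 100), random_cds, character(1))
  seqs[37] <- paste0(seqs[37], "AG")  # break the frame
  batch <- cds_records(sprintf("g%03d", 1:100), seqs)
  expect_message(m <- compute_gene_metrics(batch, w), "1 gene")
  expect_equal(nrow(m), 99L)
  expect_equal(attr(m, "failures")$gene_id, "g037")
  # determinism: identical input gives identical metrics
  m2 <- suppressMessages(compute_gene_metrics(batch, w))
  attr(m, "failures") <- NULL; attr(m2, "failures") <- NULL
  expect_identical(m, m2)
})

test_that("functional classification follows keywords and precedence", {
  expect_equal(classify_functional_category("portal protein"), "structural")
  expect_equal(classify_functional_category(""), "unclassified")
  expect_equal(classify_functional_category(NA_character_), "unclassified")
  # lysis takes precedence over structural on multi-hits
  expect_equal(classify_functional_category("tail-associated lysin"),
               "lysis")
  expect_equal(classify_functional_category("replicative DNA helicase"),
               "replication")
  expect_equal(classify_functional_category("antirestriction protein ArdA"),
               "repair")
  # short keywords match whole words only
  expect_equal(classify_functional_category("terminase large subunit"),
               "structural")
  # every generator product string classifies to its generating category
  vocab <- phagecub:::product_vocabulary()
  for (category in names(vocab)) {
    expect_equal(classify_functional_category(vocab[[category]]),
                 rep(category, length(vocab[[category]])),
                 label = category)
  }
})

test_that("raising host-mix alpha increases CAI and decreases Nc", {
  tab <- host_usage_table()
  w <- adaptiveness_weights(tab)
  stats_at <- function(alpha) {
    means <- withr::with_seed(97, {
      s <- vapply(rep(150, 200), function(L) {
        generate_cds(L, gc3_target = 25, host_mix_alpha = alpha,
                     table = NULL, sampler = sam)
      }, character(1))
      c(cai = mean(vapply(s, cai, numeric(1), weights = w)),
        nc = mean(vapply(s, nc, numeric(1)), na.rm = TRUE))
    })
    means
  }
  sam <- phagecub:::codon_sampler_tables(tab, 25)
  res <- vapply(c(0.2, 0.5, 0.9), stats_at, numeric(2))
  expect_true(all(diff(res["cai", ]) > 0))
  expect_true(all(diff(res["nc", ]) < 0))
})
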