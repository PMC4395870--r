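toy_probes <- function(...) {
  rows <- list(...)
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(gene = r$gene, region_id = r$id, region_type = r$type,
                   genotype = rep(c("wt", "mut"), lengths(r[c("wt", "mut")])),
                   intensity = c(r$wt, r$mut))
  })
}

test_that("region fold changes are ratios of genotype means", {
  pr <- toy_probes(list(gene = "g1", id = "r1", type = "exon",
                        wt = c(100, 100), mut = c(160, 160)),
                   list(gene = "g1", id = "r2", type = "intron",
                        wt = c(50, 70), mut = c(50, 70)))
  folds <- region_fold_changes(pr)
  expect_equal(folds$fold[folds$region_id == "r1"], 1.6)
  expect_equal(folds$fold[folds$region_id == "r2"], 1.0)

  bad <- toy_probes(list(gene = "g2", id = "r3", type = "exon",
                         wt = c(0, 0), mut = c(10, 10)))
  expect_warning(out <- region_fold_changes(bad), "non-positive")
  expect_equal(nrow(out), 0)
  expect_error(region_fold_changes(dplyr::mutate(pr, genotype = "het")), "genotype")
})

test_that("category calls use strict thresholds, no intron-down class", {
  folds <- tibble::tibble(
    gene = "g", region_id = paste0("r", 1:5),
    region_type = c("exon", "exon", "exon", "intron", "intron"),
    mean_wt = 100, mean_mut = 100,
    fold = c(1.6, 1.5, 0.6, 1.6, 0.5))
  calls <- classify_regions(folds, threshold = 1.5)
  expect_equal(calls$category,
               c("exon_up", "none", "exon_down", "intron_up", "none"))
})

test_that("gene aggregation counts multi-category genes in every category", {
  calls <- tibble::tibble(
    gene = c("g1", "g1", "g2"),
    region_id = c("a", "b", "c"),
    region_type = c("exon", "intron", "exon"),
    fold = c(2, 2, 0.4),
    category = c("exon_up", "intron_up", "exon_down"))
  agg <- aggregate_genes(calls)
  expect_setequal(agg$genes$category[agg$genes$gene == "g1"],
                  c("exon_up", "intron_up"))
  expect_equal(agg$multi_category, "g1")
  expect_equal(agg$n_genes_total, 2)

  empty <- aggregate_genes(dplyr::mutate(calls, category = "none"))
  expect_equal(nrow(empty$counts), 0)
  expect_equal(empty$n_genes_total, 0)
})

test_that("region counts are conserved across calling and aggregation", {
  sim <- simulate_probe_table(splice_scenario(n_genes = 120, seed = 11))
  calls <- classify_regions(region_fold_changes(sim$probes))
  agg <- aggregate_genes(calls)
  expect_equal(sum(agg$counts$n_regions) + sum(calls$category == "none"),
               nrow(calls))
})

test_that("raising the threshold never increases any category count", {
  sim <- simulate_probe_table(splice_scenario(n_genes = 150, effect_size = 2,
                                              noise_sd = 0.2, seed = 12))
  folds <- region_fold_changes(sim$probes)
  n_at <- function(th) {
    cc <- dplyr::count(classify_regions(folds, th), .data$category)
    stats::setNames(cc$n, cc$category)
  }
  for (cat in c("exon_up", "exon_down", "intron_up")) {
    counts <- vapply(c(1.2, 1.5, 2, 3), function(th) {
      n <- n_at(th)[cat]
      ifelse(is.na(n), 0L, n)
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("noiseless effects are exact and sub-threshold effects invisible", {
  sim <- simulate_probe_table(splice_scenario(n_genes = 60, effect_size = 2,
                                              noise_sd = 0, seed = 3))
  folds <- region_fold_changes(sim$probes)
  planted <- dplyr::semi_join(folds, sim$truth, by = "region_id")
  up <- dplyr::semi_join(planted,
                         dplyr::filter(sim$truth, .data$category != "exon_down"),
                         by = "region_id")
  expect_true(all(abs(up$fold - 2) < 1e-12))

  # a 1.2-fold effect can never cross a 1.5-fold threshold without noise
  sim12 <- simulate_probe_table(splice_scenario(n_genes = 60, effect_size = 1.2,
                                                noise_sd = 0, seed = 3))
  calls12 <- classify_regions(region_fold_changes(sim12$probes))
  expect_equal(sum(calls12$category != "none"), 0)

  # null scenario: nothing planted, nothing called
  sim0 <- simulate_probe_table(splice_scenario(n_genes = 40, affected_fraction = 0,
                                               noise_sd = 0, seed = 4))
  calls0 <- classify_regions(region_fold_changes(sim0$probes))
  expect_equal(sum(calls0$category != "none"), 0)
})

test_that("classifier sensitivity rises with effect size", {
  sens <- vapply(c(1.2, 1.5, 2, 3), function(es) {
    sim <- simulate_probe_table(splice_scenario(n_genes = 100, effect_size = es,
                                                noise_sd = 0.05, seed = 21))
    agg <- aggregate_genes(classify_regions(region_fold_changes(sim$probes)))
    classification_recovery(agg$genes, sim$truth)$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[4], sens[1])
})

test_that("swapping genotype labels maps exon-up calls to exon-down exactly", {
  sim <- simulate_probe_table(splice_scenario(n_genes = 80, effect_size = 2,
                                              noise_sd = 0, seed = 6))
  calls <- classify_regions(region_fold_changes(sim$probes))
  swapped <- dplyr::mutate(sim$probes,
                           genotype = ifelse(.data$genotype == "wt", "mut", "wt"))
  calls_sw <- classify_regions(region_fold_changes(swapped))
  m <- dplyr::inner_join(calls, calls_sw, by = "region_id",
                         suffix = c("", "_sw"))
  expect_equal(m$category_sw[m$category == "exon_up"],
               rep("exon_down", sum(m$category == "exon_up")))
  expect_equal(m$category_sw[m$category == "exon_down"],
               rep("exon_up", sum(m$category == "exon_down")))
})

test_that("probe tables are deterministic in the seed and validate inputs", {
  s1 <- simulate_probe_table(splice_scenario(n_genes = 30, seed = 9))
  s2 <- simulate_probe_table(splice_scenario(n_genes = 30, seed = 9))
  expect_identical(s1$probes, s2$probes)
  expect_error(splice_scenario(probes_per_region = 0), "probes_per_region")
  expect_error(splice_scenario(effect_size = 1))
})

test_that("AS proportions reproduce printed worked examples", {
  expect_equal(as_proportion(135, 449)$percent_rounded, 30)
  expect_equal(as_proportion(8, 12)$percent_rounded, 67)
  expect_equal(as_proportion(75, 159)$percent_rounded, 47)
  expect_equal(as_proportion(1, 3)$percent, 100 / 3)
  expect_error(as_proportion(1, 0), "positive")
  expect_error(as_proportion(5, 3), "k")
})

test_that("enrichment tests match formula and enumeration oracles", {
  gs <- tibble::tibble(
    gene = c(sprintf("u%03d", 1:159), sprintf("d%03d", 1:286)),
    category = rep(c("exon_up", "exon_down"), c(159, 286)))
  annot <- tibble::tibble(
    gene = gs$gene,
    as_flag = c(rep(TRUE, 75), rep(FALSE, 84), rep(TRUE, 52), rep(FALSE, 234)))
  enr <- as_enrichment(gs, annot, background = 0.25)

  # chi-square with continuity correction, direct formula on the 2x2 table
  a <- 52; b <- 234; cc <- 75; d <- 84; n <- a + b + cc + d
  chi_hand <- n * (abs(a * d - b * cc) - n / 2)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(enr$pairwise$statistic, chi_hand, tolerance = 1e-12)
  expect_lt(enr$pairwise$p.value, 1e-4)

  # exact binomial against the background: brute-force minimum-likelihood sum
  gs2 <- tibble::tibble(gene = sprintf("i%02d", 1:12), category = "intron_up")
  an2 <- tibble::tibble(gene = gs2$gene, as_flag = rep(c(TRUE, FALSE), c(8, 4)))
  enr2 <- as_enrichment(gs2, an2, background = 0.25)
  dens <- dbinom(0:12, 12, 0.25)
  p_enum <- sum(dens[dens <= dbinom(8, 12, 0.25) * (1 + 1e-7)])
  expect_equal(enr2$vs_background$p.value, p_enum, tolerance = 1e-10)
  expect_lt(enr2$vs_background$p.value, 0.005)

  # a category matching the background is unremarkable
  gs3 <- tibble::tibble(gene = sprintf("n%03d", 1:200), category = "exon_up")
  an3 <- tibble::tibble(gene = gs3$gene, as_flag = rep(c(TRUE, FALSE), c(50, 150)))
  expect_gt(as_enrichment(gs3, an3)$vs_background$p.value, 0.5)
})
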