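#' Region-level fold changes between genotypes
#'
#' Averages probe intensities per region and genotype and forms the
#' mutant/wild-type ratio. Regions with a non-positive wild-type mean (or a
#' missing genotype) cannot carry a fold change and are excluded with a
#' warning.
#'
#' @param probes Probe tibble with columns `gene`, `region_id`,
#'   `region_type`, `genotype` (`"wt"` / `"mut"`) and `intensity`.
#' @return A tibble with one row per region: `gene`, `region_id`,
#'   `region_type`, `mean_wt`, `mean_mut`, `fold`.
#' @export
region_fold_changes <- function(probes) {
  need <- c("gene", "region_id", "region_type", "genotype", "intensity")
  if (!all(need %in% names(probes))) {
    abort(paste("probe table must have columns:", paste(need, collapse = ", ")))
  }
  if (!all(probes$genotype %in% c("wt", "mut"))) {
    abort("`genotype` must be 'wt' or 'mut'")
  }
  folds <- probes |>
    dplyr::group_by(.data$gene, .data$region_id, .data$region_type,
                    .data$genotype) |>
    dplyr::summarise(mean_int = mean(.data$intensity), n_probes = dplyr::n(),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "genotype",
                       values_from = c("mean_int", "n_probes")) |>
    dplyr::rename(mean_wt = "mean_int_wt", mean_mut = "mean_int_mut")
  bad <- is.na(folds$mean_wt) | is.na(folds$mean_mut) | folds$mean_wt <= 0
  if (any(bad)) {
    warn(sprintf("excluding %d region(s) with missing or non-positive wild-type signal",
                 sum(bad)))
    folds <- folds[!bad, ]
  }
  folds |>
    dplyr::mutate(fold = .data$mean_mut / .data$mean_wt) |>
    dplyr::select("gene", "region_id", "region_type",
                  "mean_wt", "mean_mut", "fold")
}

#' Classify regions by fold-change threshold
#'
#' Strict >1.5-fold rule (threshold configurable), symmetric on the log
#' scale for down-calls: an exon with `fold > threshold` is `exon_up`, an
#' exon with `fold < 1/threshold` is `exon_down`, an intron with
#' `fold > threshold` is `intron_up`; everything else (including every
#' down-regulated intron — no such category is defined) is `none`.
#'
#' @param folds Output of [region_fold_changes()].
#' @param threshold Fold-change cut-off (strict inequality).
#' @return `folds` with an added `category` column.
#' @export
classify_regions <- function(folds, threshold = 1.5) {
  stopifnot(threshold > 1)
  folds |>
    dplyr::mutate(category = dplyr::case_when(
      .data$region_type == "exon" & .data$fold > threshold ~ "exon_up",
      .data$region_type == "exon" & .data$fold < 1 / threshold ~ "exon_down",
      .data$region_type == "intron" & .data$fold > threshold ~ "intron_up",
      TRUE ~ "none"
    ))
}

#' Gene-level aggregation of region calls
#'
#' A gene enters a category when at least one of its regions carries that
#' category, so a gene can be counted in several categories; the overlap is
#' reported separately rather than double-resolved, and region counts per
#' category are conserved against the input.
#'
#' @param calls Output of [classify_regions()].
#' @return A list: `genes` (tibble `gene`, `category`, `n_regions` — one row
#'   per gene x category it enters), `counts` (tibble `category`, `n_genes`,
#'   `n_regions`), `multi_category` (character vector of genes in more than
#'   one category) and `n_genes_total` (distinct called genes).
#' @export
aggregate_genes <- function(calls) {
  called <- dplyr::filter(calls, .data$category != "none")
  genes <- called |>
    dplyr::group_by(.data$gene, .data$category) |>
    dplyr::summarise(n_regions = dplyr::n(), .groups = "drop")
  counts <- genes |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n_genes = dplyr::n(), n_regions = sum(.data$n_regions),
                     .groups = "drop")
  multi <- genes |>
    dplyr::count(.data$gene) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::pull(.data$gene)
  list(genes = genes, counts = counts, multi_category = multi,
       n_genes_total = dplyr::n_distinct(called$gene))
}

#' Alternative-splicing proportion
#'
#' The share of a gene set annotated as alternatively spliced, reported as
#' a percentage both exact and rounded to the nearest integer (the form in
#' which such proportions are usually quoted).
#'
#' @param k Number of alternatively spliced genes in the set.
#' @param n Size of the set (> 0).
#' @return A one-row tibble (`k`, `n`, `percent`, `percent_rounded`).
#' @examples
#' as_proportion(135, 449)   # 30%
#' @export
as_proportion <- function(k, n) {
  if (n <= 0) abort("`n` must be positive")
  if (k < 0 || k > n) abort("`k` must lie in [0, n]")
  p <- 100 * k / n
  tibble::tibble(k = k, n = n, percent = p, percent_rounded = round(p))
}

#' Alternative-splicing enrichment across call categories
#'
#' For each gene category, the AS proportion; pairwise category comparisons
#' by the chi-square test on the 2x2 table (with continuity correction),
#' falling back to Fisher's exact test when any expected cell drops below 5;
#' and an exact binomial test of each category against the genome-wide
#' background proportion.
#'
#' @param gene_summary The `genes` element of [aggregate_genes()], or any
#'   tibble with `gene` and `category` columns.
#' @param annotation Tibble with `gene` and logical `as_flag`.
#' @param background Genome-wide AS proportion (default 0.25).
#' @return A list of tibbles: `proportions` (per category: `k`, `n`,
#'   `percent`, `percent_rounded`), `pairwise` (category pair, test used,
#'   statistic, p.value) and `vs_background` (per category: exact binomial
#'   statistic = k, p.value).
#' @export
as_enrichment <- function(gene_summary, annotation, background = 0.25) {
  stopifnot(background > 0, background < 1)
  tab <- gene_summary |>
    dplyr::distinct(.data$gene, .data$category) |>
    dplyr::left_join(annotation, by = "gene")
  if (anyNA(tab$as_flag)) abort("some called genes are missing from the annotation")
  per_cat <- tab |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(k = sum(.data$as_flag), n = dplyr::n(), .groups = "drop")
  proportions <- per_cat |>
    dplyr::rowwise() |>
    dplyr::reframe(category = .data$category, as_proportion(.data$k, .data$n))

  cats <- per_cat$category
  pairs <- if (length(cats) >= 2) utils::combn(cats, 2, simplify = FALSE) else list()
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    a <- per_cat[per_cat$category == pr[1], ]
    b <- per_cat[per_cat$category == pr[2], ]
    m <- matrix(c(a$k, a$n - a$k, b$k, b$n - b$k), 2, byrow = TRUE)
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(expected < 5)) {
      ft <- fisher.test(m)
      tibble::tibble(category_a = pr[1], category_b = pr[2],
                     test = "Fisher exact", statistic = NA_real_,
                     p.value = ft$p.value)
    } else {
      ct <- chisq.test(m, correct = TRUE)
      tibble::tibble(category_a = pr[1], category_b = pr[2],
                     test = "chi-square (Yates)",
                     statistic = unname(ct$statistic), p.value = ct$p.value)
    }
  })

  vs_background <- per_cat |>
    dplyr::rowwise() |>
    dplyr::mutate(p.value = binom.test(.data$k, .data$n, background)$p.value,
                  background = background) |>
    dplyr::ungroup()

  list(proportions = proportions, pairwise = pairwise,
       vs_background = vs_background)
}

#' Recovery of planted effects by the classifier
#'
#' Compares gene-level category calls against the ground-truth labels of a
#' synthetic scenario, on (gene, category) pairs.
#'
#' @param called_genes The `genes` element of [aggregate_genes()].
#' @param truth The `truth` tibble of [simulate_probe_table()].
#' @return A one-row tibble (`sensitivity`, `precision`, `n_truth`,
#'   `n_called`).
#' @export
classification_recovery <- function(called_genes, truth) {
  call_pairs <- called_genes |>
    dplyr::distinct(.data$gene, .data$category)
  truth_pairs <- truth |>
    dplyr::distinct(.data$gene, .data$category)
  hits <- dplyr::inner_join(call_pairs, truth_pairs,
                            by = c("gene", "category"))
  tibble::tibble(
    sensitivity = if (nrow(truth_pairs)) nrow(hits) / nrow(truth_pairs) else NA_real_,
    precision = if (nrow(call_pairs)) nrow(hits) / nrow(call_pairs) else NA_real_,
    n_truth = nrow(truth_pairs),
    n_called = nrow(call_pairs)
  )
}
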