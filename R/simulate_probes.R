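#' Scenario for a synthetic two-genotype tiling-array experiment
#'
#' Describes a probe-level intensity experiment comparing a wild-type and a
#' splicing-factor mutant genotype: genes made of alternating exon/intron
#' regions, a fraction annotated as alternatively spliced, and a fraction
#' misregulated in the mutant with one of four effect kinds (intron
#' retention, exon up, exon down, or mixed intron+exon up).
#'
#' @param n_genes Number of genes.
#' @param regions_per_gene Integer range `c(min, max)` of regions per gene
#'   (regions alternate exon, intron, exon, ...).
#' @param as_fraction Probability that a gene is annotated alternatively
#'   spliced (the genome-wide background is about 0.25).
#' @param affected_fraction Probability that a gene is misregulated in the
#'   mutant.
#' @param effect_kinds Effect kinds sampled for affected genes.
#' @param effect_size Multiplicative fold applied to affected regions
#'   (> 1; exon-down effects use its reciprocal).
#' @param noise_sd Log-scale standard deviation of probe noise.
#' @param probes_per_region Probes per region (> 0).
#' @param seed Integer seed.
#' @return An object of class `splice_scenario`.
#' @export
splice_scenario <- function(n_genes = 200,
                            regions_per_gene = c(4, 8),
                            as_fraction = 0.25,
                            affected_fraction = 0.2,
                            effect_kinds = c("intron_up", "exon_up",
                                             "exon_down", "mixed"),
                            effect_size = 3,
                            noise_sd = 0.1,
                            probes_per_region = 4,
                            seed = 1L) {
  stopifnot(n_genes >= 1, length(regions_per_gene) == 2,
            regions_per_gene[1] >= 2,
            as_fraction >= 0, as_fraction <= 1,
            affected_fraction >= 0, affected_fraction <= 1,
            effect_size > 1, noise_sd >= 0)
  if (probes_per_region < 1) abort("`probes_per_region` must be at least 1")
  effect_kinds <- match.arg(effect_kinds, several.ok = TRUE)
  structure(list(n_genes = n_genes, regions_per_gene = regions_per_gene,
                 as_fraction = as_fraction, affected_fraction = affected_fraction,
                 effect_kinds = effect_kinds, effect_size = effect_size,
                 noise_sd = noise_sd, probes_per_region = probes_per_region,
                 seed = as.integer(seed)),
            class = "splice_scenario")
}

#' Generate a synthetic probe table with planted splicing effects
#'
#' Builds the gene models, plants the scenario's effects, and draws probe
#' intensities: `intensity = baseline * fold * exp(Normal(0, noise_sd))`,
#' where `fold` is the planted effect for affected regions in the mutant
#' genotype and 1 otherwise. Affected regions per gene: intron-retention
#' genes up-regulate one intron by `effect_size`; exon-up (-down) genes
#' scale one exon by `effect_size` (its reciprocal); mixed genes carry one
#' up-regulated intron and one up-regulated exon. Ground-truth labels are
#' returned for recovery tests.
#'
#' @param scenario A [splice_scenario()].
#' @return A list of class `splice_sim`: `probes` (tibble: `probe_id`,
#'   `gene`, `region_id`, `region_type`, `genotype`, `intensity`),
#'   `annotation` (tibble: `gene`, `as_flag`), and `truth` (tibble:
#'   `gene`, `region_id`, `region_type`, `category` of every planted
#'   region-level effect).
#' @examples
#' sim <- simulate_probe_table(splice_scenario(n_genes = 20, seed = 2))
#' head(sim$probes)
#' @export
simulate_probe_table <- function(scenario = splice_scenario()) {
  stopifnot(inherits(scenario, "splice_scenario"))
  withr::with_seed(scenario$seed, {
    genes <- sprintf("gene%04d", seq_len(scenario$n_genes))
    n_regions <- sample(seq(scenario$regions_per_gene[1],
                            scenario$regions_per_gene[2]),
                        scenario$n_genes, replace = TRUE)
    as_flag <- runif(scenario$n_genes) < scenario$as_fraction
    affected <- runif(scenario$n_genes) < scenario$affected_fraction
    kind <- rep(NA_character_, scenario$n_genes)
    kind[affected] <- sample(scenario$effect_kinds, sum(affected), replace = TRUE)

    regions <- purrr::map_dfr(seq_len(scenario$n_genes), function(i) {
      types <- rep(c("exon", "intron"), length.out = n_regions[i])
      tibble::tibble(
        gene = genes[i],
        region_id = sprintf("%s_r%02d", genes[i], seq_len(n_regions[i])),
        region_type = types,
        baseline = exp(rnorm(n_regions[i], log(500), 0.4)),
        fold = 1
      )
    })

    truth <- tibble::tibble(gene = character(), region_id = character(),
                            region_type = character(), category = character())
    for (i in which(affected)) {
      g <- genes[i]
      idx <- which(regions$gene == g)
      ex <- idx[regions$region_type[idx] == "exon"]
      it <- idx[regions$region_type[idx] == "intron"]
      pick <- function(v) v[sample.int(length(v), 1)]
      plant <- function(j, fold, category) {
        regions$fold[j] <<- fold
        truth <<- dplyr::bind_rows(truth, tibble::tibble(
          gene = g, region_id = regions$region_id[j],
          region_type = regions$region_type[j], category = category))
      }
      switch(kind[i],
        intron_up = plant(pick(it), scenario$effect_size, "intron_up"),
        exon_up = plant(pick(ex), scenario$effect_size, "exon_up"),
        exon_down = plant(pick(ex), 1 / scenario$effect_size, "exon_down"),
        mixed = {
          plant(pick(it), scenario$effect_size, "intron_up")
          plant(pick(ex), scenario$effect_size, "exon_up")
        })
    }

    ppr <- scenario$probes_per_region
    probes <- tidyr::crossing(regions,
                              genotype = c("wt", "mut"),
                              probe = seq_len(ppr)) |>
      dplyr::mutate(
        probe_id = sprintf("%s_g%s_p%d", .data$region_id, .data$genotype, .data$probe),
        intensity = .data$baseline *
          ifelse(.data$genotype == "mut", .data$fold, 1) *
          exp(rnorm(dplyr::n(), 0, scenario$noise_sd))
      ) |>
      dplyr::select("probe_id", "gene", "region_id", "region_type",
                    "genotype", "intensity")

    structure(list(
      probes = probes,
      annotation = tibble::tibble(gene = genes, as_flag = as_flag),
      truth = truth
    ), class = "splice_sim")
  })
}
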