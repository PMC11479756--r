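# Orchestration of the computational experiments: reproductive-parameter
# presets, replicate sets with identical starting conditions, the
# architecture grid, and ternary summaries of final morph frequencies.

#' Reproductive-parameter presets
#'
#' Two parameter sets chosen from the analytical sweep: one predicted to
#' collapse to a single morph (`"low_diversity"`: courter:non-courter
#' allocation ratio 2.0, c = 0.5, 2 sneakers) and one predicted to maintain
#' several morphs (`"high_diversity"`: ratio 0.70 as printed — the per-morph
#' maxima 6 and 8 imply 0.75, exposed as `"high_diversity_0.75"` — c = 0.75,
#' 2 sneakers). A further `"methods_defaults"` preset carries the
#' description-level defaults (3 sneakers, c = 0.5).
#'
#' @param name Preset name.
#' @param model `"ibm"` for a [sim_params()] object (per-morph offspring
#'   ceilings), `"analytic"` for an [analytic_params()] object.
#' @param ... Overrides passed to the underlying constructor.
#' @return A `sim_params` or `analytic_params` object.
#' @export
preset_params <- function(name = c("low_diversity", "high_diversity",
                                   "high_diversity_0.75",
                                   "methods_defaults"),
                          model = c("ibm", "analytic"), ...) {
  name <- match.arg(name)
  model <- match.arg(model)
  cfg <- switch(name,
    low_diversity = list(r = c(CP = 8, CN = 8, NP = 4, NN = 4),
                         sperm_comp = 0.5, n_sneak = 2),
    high_diversity = list(r = c(CP = 5.6, CN = 5.6, NP = 8, NN = 8),
                          sperm_comp = 0.75, n_sneak = 2),
    high_diversity_0.75 = list(r = c(CP = 6, CN = 6, NP = 8, NN = 8),
                               sperm_comp = 0.75, n_sneak = 2),
    methods_defaults = list(r = c(CP = 8, CN = 8, NP = 4, NN = 4),
                            sperm_comp = 0.5, n_sneak = 3)
  )
  if (model == "ibm") {
    # offspring ceilings are integer egg counts; the printed per-morph
    # maxima are used (6 for courters under high diversity)
    if (name == "high_diversity") cfg$r[c("CP", "CN")] <- 6
    do.call(sim_params, utils::modifyList(cfg, list(...)))
  } else {
    do.call(analytic_params, utils::modifyList(cfg, list(...)))
  }
}

#' Run schedules
#'
#' `"full"` is the complete schedule (carrying capacity 1000, 10000 burn-in plus
#' 2000 experimental generations, 4 replicates per set); `"desk"` is the
#' scaled-down schedule used by the test-bench (carrying capacity 300,
#' 600 + 150 generations, 4 replicates per set), chosen because the morph
#' frequencies of these models equilibrate within a few hundred generations
#' so replicate sets complete on a single CPU.
#'
#' @param name `"full"` or `"desk"`.
#' @return A list with `K`, `burn_in`, `experimental`, `n_replicates` and
#'   `scale` (the label recorded in summaries).
#' @export
schedule <- function(name = c("desk", "full")) {
  name <- match.arg(name)
  if (name == "full") {
    list(K = 1000L, burn_in = 10000L, experimental = 2000L,
         n_replicates = 4L, scale = "full")
  } else {
    list(K = 300L, burn_in = 600L, experimental = 150L,
         n_replicates = 4L, scale = "desk")
  }
}

#' Run a set of replicates with identical starting conditions
#'
#' One architecture (QTL positions, allelic effects), generation-0
#' population and pair of trait thresholds are drawn under `arch_seed`; each
#' replicate then runs under its own seed from an identical copy of that
#' starting state, so differences among replicates are purely demographic /
#' genetic stochasticity.
#'
#' @param arch_fn A function () -> [genome_architecture()]; called once
#'   under `arch_seed`.
#' @param params A [sim_params()].
#' @param generations Generations per replicate (burn-in + experimental).
#' @param n_replicates Number of replicates sharing the starting state.
#' @param arch_seed Seed for architecture, effects, initial genotypes and
#'   thresholds.
#' @param run_seeds Optional integer vector of per-replicate seeds
#'   (default `arch_seed * 1000 + 1:n`).
#' @param keep_pops Keep the final populations (default FALSE: summaries
#'   only).
#' @return A list of class `replicate_set`: `runs` (list of `morph_sim`),
#'   `summary` tibble (one row per replicate with final morph frequencies),
#'   `arch`, `arch_seed`.
#' @export
run_replicate_set <- function(arch_fn, params, generations,
                              n_replicates = 4, arch_seed = 1,
                              run_seeds = NULL, keep_pops = FALSE) {
  set.seed(arch_seed)
  arch <- arch_fn()
  init <- initialize_thresholds(init_population(arch, params$K))
  if (is.null(run_seeds)) {
    run_seeds <- arch_seed * 1000 + seq_len(n_replicates)
  }
  stopifnot(length(run_seeds) == n_replicates)
  runs <- purrr::map(run_seeds, function(s) {
    sim <- run_simulation(arch, params, generations, seed = s, init = init)
    if (!keep_pops) sim$pop <- NULL
    sim
  })
  smry <- purrr::map2_dfr(runs, run_seeds, function(sim, s) {
    dplyr::mutate(glance(sim), run_seed = s, .before = 1)
  })
  structure(list(runs = runs, summary = smry, arch = arch,
                 arch_seed = arch_seed),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("Replicate set (%d replicates, arch seed %s)\n",
              nrow(x$summary), format(x$arch_seed)))
  print(x$summary)
  invisible(x)
}

#' Enumerate the architecture grid
#'
#' All combinations of diversity preset, architecture type, chromosome
#' count, QTL count and (for supergenes) region proportion, with
#' capacity-infeasible combinations (a region too small for the QTLs of both
#' traits) flagged rather than silently dropped.
#'
#' @param presets Diversity presets to cross.
#' @param n_chrom,n_qtl,supergene_prop Grid values.
#' @param loci_per_chrom Loci per chromosome (default 1000).
#' @return A tibble with one row per condition and a `feasible` flag.
#' @export
architecture_grid <- function(presets = c("low_diversity", "high_diversity"),
                              n_chrom = c(2, 4, 8),
                              n_qtl = c(8, 16, 32, 64),
                              supergene_prop = c(0.05, 0.25, 0.5),
                              loci_per_chrom = 1000) {
  gw <- tidyr::expand_grid(preset = presets, architecture = "genome_wide",
                           n_chrom = n_chrom, n_qtl = n_qtl,
                           supergene_prop = NA_real_)
  sg <- tidyr::expand_grid(preset = presets, architecture = "supergene",
                           n_chrom = min(n_chrom), n_qtl = n_qtl,
                           supergene_prop = supergene_prop)
  dplyr::bind_rows(gw, sg) |>
    dplyr::mutate(feasible = ifelse(
      .data$architecture == "supergene",
      2 * .data$n_qtl <= round(.data$supergene_prop * loci_per_chrom),
      2 * .data$n_qtl <= .data$n_chrom * loci_per_chrom))
}

#' Ternary summary of final morph frequencies
#'
#' Renormalizes each run's final frequencies over the three morphs that can
#' persist (CP, NP, NN; the courter/non-parent morph is never maintained)
#' and counts identical outcomes.
#'
#' @param summary_tbl A tibble with columns `f_cp`, `f_np`, `f_nn` (e.g. a
#'   `replicate_set` summary).
#' @param digits Rounding used when counting identical outcomes.
#' @return A tibble with renormalized `cp`, `np`, `nn` and a count `n` per
#'   distinct outcome.
#' @export
summarize_ternary <- function(summary_tbl, digits = 3) {
  tot <- summary_tbl$f_cp + summary_tbl$f_np + summary_tbl$f_nn
  tibble(cp = summary_tbl$f_cp / tot, np = summary_tbl$f_np / tot,
         nn = summary_tbl$f_nn / tot) |>
    dplyr::count(cp = round(.data$cp, digits), np = round(.data$np, digits),
                 nn = round(.data$nn, digits))
}
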