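# Stochastic diploid individual-based simulator.
#
# Each generation: (1) every female searches a fixed number of males and
# mates with the first courter she encounters; (2) the chosen male sires up
# to his reproductive allocation of her eggs and up to n_sneak non-courting
# males sneak-fertilize the remainder, while gametes undergo recombination
# (Poisson crossovers; crossovers inside a supergene kill the zygote) and
# mutation; (3) the whole clutch survives only if the chosen male carries the
# parenting trait; (4) Gaussian viability selection penalizes male offspring
# expressing courting and/or parenting; (5) survivors are culled uniformly to
# the carrying capacity.

#' Parameters of the individual-based simulation
#'
#' @param K Carrying capacity (maximum adult population size, default 1000).
#' @param mate_search_n Number of males each female samples while searching
#'   for a mate (default 50).
#' @param eggs_per_female Clutch size. Defaults to `max(r)` so the chosen
#'   male can realize his allocation ceiling.
#' @param n_sneak Maximum number of sneakers per clutch.
#' @param sperm_comp Sperm-competition coefficient `c` in \[0, 1\].
#' @param r Named per-morph reproductive allocations (offspring ceilings).
#' @param omega_v Strength of viability selection; a male expressing `k`
#'   of the two costly traits survives with probability `exp(-k / omega_v)`
#'   (trait indicators are 0/1 and the optimum is at 0, so selection favours
#'   non-courting non-parents; the two trait costs multiply).
#' @param theta Viability optimum on the trait indicator scale (default 0).
#' @return An object of class `sim_params`.
#' @examples
#' sim_params(K = 500, r = c(CP = 6, CN = 6, NP = 8, NN = 8),
#'            sperm_comp = 0.75, n_sneak = 2)
#' @export
sim_params <- function(K = 1000,
                       mate_search_n = 50,
                       eggs_per_female = NULL,
                       n_sneak = 2,
                       sperm_comp = 0.5,
                       r = c(CP = 8, CN = 8, NP = 4, NN = 4),
                       omega_v = 4,
                       theta = 0) {
  r <- as_morph_vec(r, "r")
  if (is.null(eggs_per_female)) eggs_per_female <- max(r)
  stopifnot(K >= 1, mate_search_n >= 1, eggs_per_female >= 1,
            n_sneak >= 0, omega_v > 0)
  if (sperm_comp < 0 || sperm_comp > 1) {
    abort("sperm_comp must be in [0, 1]", class = "morphsim_error")
  }
  structure(list(K = as.integer(K), mate_search_n = as.integer(mate_search_n),
                 eggs_per_female = as.integer(eggs_per_female),
                 n_sneak = as.integer(n_sneak), sperm_comp = sperm_comp,
                 r = r, omega_v = omega_v, theta = theta),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "IBM parameters: K = %d, mate_search_n = %d, eggs = %d, n_sneak = %d, c = %g\n",
    x$K, x$mate_search_n, x$eggs_per_female, x$n_sneak, x$sperm_comp))
  cat(sprintf("  r = (%s); omega_v = %g, theta = %g\n",
              paste(sprintf("%s=%g", MORPHS, x$r), collapse = ", "),
              x$omega_v, x$theta))
  invisible(x)
}

#' Mate choice: each female picks the first courter she encounters
#'
#' Every female samples up to `mate_search_n` males uniformly without
#' replacement and mates with the first courting male in encounter order;
#' if she encounters none she does not mate.
#'
#' @param male_is_courter Logical vector over males.
#' @param n_females Number of searching females.
#' @param mate_search_n Males sampled per female.
#' @return Integer vector of length `n_females`: index of the chosen male
#'   (into the male vector) or `NA` for unmated females.
#' @export
mate_choice <- function(male_is_courter, n_females, mate_search_n) {
  n_males <- length(male_is_courter)
  if (n_males == 0) return(rep(NA_integer_, n_females))
  s <- min(mate_search_n, n_males)
  vapply(seq_len(n_females), function(i) {
    enc <- sample.int(n_males, s)
    hit <- which(male_is_courter[enc])
    if (length(hit) == 0) NA_integer_ else enc[hit[1]]
  }, integer(1))
}

#' Paternity shares within one clutch
#'
#' The chosen (first) male sires `min(r_chosen, E)` of the `E` eggs; each
#' sneaker, in draw order, then sires `min(round(c * r_sneaker), remaining)`.
#'
#' @param r_chosen Chosen male's reproductive allocation.
#' @param r_sneakers Allocations of the sneakers, in draw order.
#' @param eggs Clutch size `E`.
#' @param sperm_comp Sperm-competition coefficient.
#' @return Integer vector of egg counts: first the chosen male, then one
#'   entry per sneaker.
#' @examples
#' clutch_shares(r_chosen = 6, r_sneakers = 8, eggs = 8, sperm_comp = 0.5)
#' @export
clutch_shares <- function(r_chosen, r_sneakers, eggs, sperm_comp) {
  shares <- integer(1 + length(r_sneakers))
  shares[1] <- min(r_chosen, eggs)
  rem <- eggs - shares[1]
  for (i in seq_along(r_sneakers)) {
    take <- min(round(sperm_comp * r_sneakers[i]), rem)
    shares[1 + i] <- take
    rem <- rem - take
  }
  shares
}

#' Gaussian viability survival probability for a male morph
#'
#' `exp(-(I_court - theta)^2 / omega_v) * exp(-(I_parent - theta)^2 /
#' omega_v)` with trait indicators I equal to 1 when the costly trait is
#' expressed.
#'
#' @param morph Character vector of morph labels.
#' @param params A [sim_params()].
#' @return Numeric survival probabilities.
#' @export
viability_prob <- function(morph, params) {
  ic <- as.numeric(morph %in% c("CP", "CN"))
  ip <- as.numeric(morph %in% c("CP", "NP"))
  exp(-(ic - params$theta)^2 / params$omega_v) *
    exp(-(ip - params$theta)^2 / params$omega_v)
}

# Offspring genotype construction (recombination, supergene inviability,
# mutation and per-copy effect inheritance) lives in src/offspring.cpp;
# mutation counts per offspring are Poisson with mean
# 2 * mu * loci_per_chrom * n_chrom, each mutation re-draws the allele among
# the states segregating at that locus in the parental population and
# perturbs the carried effect by Normal(0, sigma_mu) when the locus is a QTL.
make_offspring <- function(pop, sires, dams) {
  arch <- pop$arch
  sg <- arch$supergene
  qidx <- arch_qtl_idx(arch)
  cpp_make_offspring(pop$state, pop$eff_c, pop$eff_p,
                     as.integer(sires - 1L), as.integer(dams - 1L),
                     arch$n_chrom, arch$loci_per_chrom,
                     as.integer(qidx$courter), as.integer(qidx$parent),
                     arch$recomb_rate,
                     if (is.null(sg)) -1L else sg$chrom - 1L,
                     if (is.null(sg)) -1L else sg$start,
                     if (is.null(sg)) -1L else sg$end,
                     arch$mu, arch$sigma_mu)
}

#' Run one generation of the individual-based model
#'
#' @param pop A `morph_pop` with thresholds set.
#' @param params A [sim_params()].
#' @return A list with the next-generation `pop` (or `NULL` on extinction)
#'   and a one-row `summary` tibble of the state of the *incoming* adult
#'   population plus the generation's bookkeeping (matings, inviable
#'   recombinants).
#' @export
run_generation <- function(pop, params) {
  arch <- pop$arch
  n <- length(pop$sex)
  males <- which(pop$sex == "M")
  females <- which(pop$sex == "F")
  ph <- phenotypes(pop)
  morph <- assign_morph(ph$courter_value, ph$parent_value, pop$thresholds)
  morph_m <- morph[males]
  smry <- generation_summary(pop, morph_m, ph)

  if (length(males) == 0 || length(females) == 0) {
    return(list(pop = NULL, summary = smry))
  }
  courter <- morph_m %in% c("CP", "CN")
  noncourt <- which(!courter)

  chosen <- mate_choice(courter, length(females), params$mate_search_n)
  mated <- which(!is.na(chosen))
  smry$matings <- length(mated)

  # Parental care acts at clutch level: clutches whose chosen male lacks the
  # parenting trait leave no survivors, so their genotypes are never built.
  sire_l <- vector("list", length(mated))
  dam_l <- vector("list", length(mated))
  for (k in seq_along(mated)) {
    i <- mated[k]
    cm <- chosen[i]
    if (morph_m[cm] != "CP") next
    sn <- if (length(noncourt) > 0 && params$n_sneak > 0) {
      noncourt[sample.int(length(noncourt), min(params$n_sneak, length(noncourt)))]
    } else integer(0)
    sh <- clutch_shares(params$r[[morph_m[cm]]], params$r[morph_m[sn]],
                        params$eggs_per_female, params$sperm_comp)
    fathers <- rep.int(c(males[cm], males[sn]), sh)
    sire_l[[k]] <- fathers
    dam_l[[k]] <- rep.int(females[i], length(fathers))
  }
  sires <- unlist(sire_l)
  if (length(sires) == 0) {
    return(list(pop = NULL, summary = smry))
  }
  raw <- make_offspring(pop, sires, unlist(dam_l))
  viable <- which(raw$viable)
  smry$inviable <- length(raw$viable) - length(viable)
  if (length(viable) == 0) return(list(pop = NULL, summary = smry))
  sex_off <- sample(c("F", "M"), length(viable), replace = TRUE)

  # Viability selection on male offspring only (phenotypes from the mutated
  # per-copy effects; inviable columns are skipped, not subset).
  sc <- colSums(raw$eff_c)
  sp <- colSums(raw$eff_p)
  pc <- sc[2 * viable - 1] + sc[2 * viable]
  pp <- sp[2 * viable - 1] + sp[2 * viable]
  omorph <- assign_morph(pc, pp, pop$thresholds)
  surv <- rep(TRUE, length(viable))
  is_m <- sex_off == "M"
  surv[is_m] <- runif(sum(is_m)) <= viability_prob(omorph[is_m], params)
  if (!any(surv)) return(list(pop = NULL, summary = smry))

  # Regulation: uniform cull to carrying capacity, then a single subset of
  # the offspring matrices.
  alive <- which(surv)
  if (length(alive) > params$K) alive <- sort(sample(alive, params$K))
  keep <- viable[alive]
  cols <- rep(keep * 2L, each = 2L) + c(-1L, 0L)
  new_pop <- structure(
    list(state = raw$state[, cols, drop = FALSE],
         eff_c = raw$eff_c[, cols, drop = FALSE],
         eff_p = raw$eff_p[, cols, drop = FALSE],
         sex = sex_off[alive], arch = arch, thresholds = pop$thresholds),
    class = "morph_pop")
  list(pop = new_pop, summary = smry)
}

generation_summary <- function(pop, morph_m, ph) {
  counts <- table(factor(morph_m, levels = MORPHS))
  nm <- length(morph_m)
  tibble(n = length(pop$sex), n_female = sum(pop$sex == "F"), n_male = nm,
         n_cp = as.integer(counts[["CP"]]), n_cn = as.integer(counts[["CN"]]),
         n_np = as.integer(counts[["NP"]]), n_nn = as.integer(counts[["NN"]]),
         f_cp = if (nm > 0) counts[["CP"]] / nm else NA_real_,
         f_cn = if (nm > 0) counts[["CN"]] / nm else NA_real_,
         f_np = if (nm > 0) counts[["NP"]] / nm else NA_real_,
         f_nn = if (nm > 0) counts[["NN"]] / nm else NA_real_,
         mean_courter_value = mean(ph$courter_value),
         mean_parent_value = mean(ph$parent_value),
         matings = 0L, inviable = 0L)
}

#' Run a full individual-based simulation
#'
#' Builds (or reuses) a generation-0 population, freezes the trait
#' thresholds, and iterates [run_generation()].
#'
#' @param arch A [genome_architecture()] (ignored when `init` is supplied).
#' @param params A [sim_params()].
#' @param generations Number of generations to run.
#' @param seed Optional integer seed for the run.
#' @param init Optional initialized `morph_pop` (with thresholds) shared by
#'   replicate runs.
#' @param summary_every Record a summary row every this many generations
#'   (generation 0 and the final generation are always recorded).
#' @return An object of class `morph_sim`: per-generation `summary` tibble,
#'   the final population (`pop`), `params`, `extinct` flag and
#'   `generations_run`.
#' @examples
#' set.seed(1)
#' arch <- genome_architecture("single_locus")
#' sim <- run_simulation(arch, sim_params(K = 200), generations = 20, seed = 1)
#' glance(sim)
#' @export
run_simulation <- function(arch, params, generations, seed = NULL,
                           init = NULL, summary_every = 10) {
  if (!is.null(seed)) set.seed(seed)
  pop <- if (is.null(init)) {
    initialize_thresholds(init_population(arch, params$K))
  } else {
    init
  }
  rows <- vector("list", generations + 1)
  extinct <- FALSE
  g_done <- 0L
  for (g in seq_len(generations)) {
    step <- run_generation(pop, params)
    if (g == 1 || g %% summary_every == 0 || is.null(step$pop) ||
        g == generations) {
      rows[[g]] <- dplyr::mutate(step$summary, generation = g - 1L, .before = 1)
    }
    if (is.null(step$pop)) {
      extinct <- TRUE
      pop <- NULL
      break
    }
    pop <- step$pop
    g_done <- g
  }
  if (!extinct) {
    ph <- phenotypes(pop)
    morph_m <- assign_morph(ph$courter_value, ph$parent_value,
                            pop$thresholds)[pop$sex == "M"]
    rows[[generations + 1]] <- dplyr::mutate(
      generation_summary(pop, morph_m, ph), generation = generations,
      .before = 1)
  }
  structure(list(summary = dplyr::bind_rows(rows), pop = pop,
                 params = params, arch = arch, seed = seed,
                 extinct = extinct, generations_run = g_done),
            class = "morph_sim")
}

#' @export
print.morph_sim <- function(x, ...) {
  cat(sprintf("IBM run: %d generation(s)%s\n", x$generations_run,
              if (x$extinct) " [EXTINCT]" else ""))
  print(glance(x))
  invisible(x)
}

#' @export
glance.morph_sim <- function(x, ...) {
  fin <- x$summary[nrow(x$summary), ]
  tibble(generations = x$generations_run, extinct = x$extinct,
         n = fin$n, f_cp = fin$f_cp, f_cn = fin$f_cn, f_np = fin$f_np,
         f_nn = fin$f_nn,
         shannon = shannon_index(c(fin$f_cp, fin$f_cn, fin$f_np, fin$f_nn)))
}

#' @export
tidy.morph_sim <- function(x, ...) {
  x$summary |>
    dplyr::select("generation", f_cp = "f_cp", f_cn = "f_cn",
                  f_np = "f_np", f_nn = "f_nn") |>
    dplyr::rename(CP = "f_cp", CN = "f_cn", NP = "f_np", NN = "f_nn") |>
    tidyr::pivot_longer(-"generation", names_to = "morph",
                        values_to = "frequency")
}

#' Plot male morph frequencies over a simulation run
#'
#' @param object A `morph_sim` from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.morph_sim <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$generation, y = .data$frequency,
                               colour = .data$morph)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "Male morph frequency",
                  colour = "Morph") +
    ggplot2::theme_minimal()
}
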