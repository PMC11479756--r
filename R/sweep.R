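# Parameter sweep of the analytical recurrence.
#
# The sweep is iterated with all parameter combinations advanced in lockstep
# as a combos x 4 frequency matrix; the scalar stage ledger in analytic.R is
# the reference implementation against which this vectorized step is tested.

#' Default sweep grid
#'
#' The grid crosses the sperm-competition coefficient `c` (5 evenly spaced
#' values on \[0, 1\]), the courter:non-courter reproductive ratio `r`
#' (21 evenly spaced values on \[0, 2\], applied as `r_CP = r_CN = r * r_base`
#' with the non-courter allocation fixed at `r_base`), and the number of
#' sneakers per clutch (1, 2, 3).
#'
#' @param sperm_comp,r_ratio,n_sneak Numeric vectors of grid values.
#' @param r_base Non-courter reproductive allocation (default 8); only the
#'   ratio affects the dynamics.
#' @return A tibble with one row per parameter combination.
#' @export
sweep_grid <- function(sperm_comp = seq(0, 1, length.out = 5),
                       r_ratio = seq(0, 2, length.out = 21),
                       n_sneak = 1:3,
                       r_base = 8) {
  stopifnot(length(sperm_comp) > 0, length(r_ratio) > 0, length(n_sneak) > 0)
  tidyr::expand_grid(sperm_comp = sperm_comp, r_ratio = r_ratio,
                     n_sneak = as.integer(n_sneak)) |>
    dplyr::mutate(r_base = r_base)
}

#' Equal-frequency starting point and simplex lattices
#'
#' `initial_equal()` is the equal-start state. `initial_simplex(step)`
#' enumerates a four-morph simplex lattice with the given spacing (all
#' non-negative combinations of multiples of `step` summing to 1).
#'
#' @param step Lattice spacing (e.g. `1/24`).
#' @return A tibble with columns `CP`, `CN`, `NP`, `NN`.
#' @export
initial_equal <- function() {
  tibble(CP = 0.25, CN = 0.25, NP = 0.25, NN = 0.25)
}

#' @rdname initial_equal
#' @export
initial_simplex <- function(step = 1 / 24) {
  k <- round(1 / step)
  grid <- tidyr::expand_grid(i = 0:k, j = 0:k, l = 0:k) |>
    dplyr::filter(.data$i + .data$j + .data$l <= k)
  tibble(CP = grid$i / k, CN = grid$j / k, NP = grid$l / k,
         NN = 1 - (grid$i + grid$j + grid$l) / k)
}

# One synchronized recurrence step for all active sweep rows.
# F: n x 4 matrix; cc, ns, r_cp, r_nc: per-row parameter vectors.
# Baseline sweep assumptions: w_s = 1, w_n = (1, 0, 1, 0), viability = 1.
# Returns the next F with rows of failed populations set to NA.
sweep_step_matrix <- function(F, cc, ns, r_cp, r_nc, n_males = 100) {
  n <- n_males * (F[, 1] + F[, 2])
  Ns <- n * cc * ns * r_nc
  e_o_cp <- F[, 1] * n_males * r_cp
  e_o_cn <- F[, 2] * n_males * r_cp
  o_cp <- e_o_cp # w_n = 1 for CP, 0 for CN
  tot_e <- e_o_cp + e_o_cn
  frac <- ifelse(tot_e > 0, o_cp / tot_e, 0)
  e_s_np <- pmin(Ns, F[, 3] * n_males * r_nc)
  e_s_nn <- pmin(Ns, F[, 4] * n_males * r_nc)
  j <- cbind(o_cp, 0, e_s_np * frac, e_s_nn * frac)
  tot <- rowSums(j)
  out <- j / tot
  out[tot <= 0, ] <- NA_real_
  out
}

#' Run the equal-start analytical sweep
#'
#' Iterates the recurrence for every parameter combination in `grid` from the
#' given initial frequencies under the baseline assumptions (`w_s = 1`,
#' clutch survival `(1, 0, 1, 0)`, no viability cost). Populations that fail
#' to reproduce are frozen at their last valid state and flagged.
#'
#' @param grid A tibble from [sweep_grid()].
#' @param initial A tibble of starting frequencies ([initial_equal()] by
#'   default); every combination of grid row and initial row is run.
#' @param generations Number of generations to iterate (default 10000).
#' @return A tibble with the grid and initial-frequency columns plus final
#'   frequencies `f_cp`..`f_nn`, `shannon`, `outcome`, `failed` and
#'   `generations_run`.
#' @examples
#' res <- run_sweep(sweep_grid(), generations = 200)
#' dplyr::count(res, outcome)
#' @export
run_sweep <- function(grid = sweep_grid(), initial = initial_equal(),
                      generations = 10000) {
  stopifnot(generations >= 1)
  combos <- tidyr::expand_grid(grid, f0 = seq_len(nrow(initial)))
  F <- as.matrix(initial[combos$f0, MORPHS])
  F0 <- F
  cc <- combos$sperm_comp
  ns <- combos$n_sneak
  r_cp <- combos$r_ratio * combos$r_base
  r_nc <- combos$r_base
  active <- rep(TRUE, nrow(F))
  gens_run <- integer(nrow(F))
  for (t in seq_len(generations)) {
    if (!any(active)) break
    nxt <- sweep_step_matrix(F[active, , drop = FALSE], cc[active],
                             ns[active], r_cp[active], r_nc[active])
    died <- is.na(nxt[, 1])
    idx <- which(active)
    if (any(died)) {
      active[idx[died]] <- FALSE
      nxt[died, ] <- F[idx[died], , drop = FALSE]
    }
    F[idx, ] <- nxt
    gens_run[idx[!died]] <- t
    # after reaching a fixed point the remaining iterations are no-ops, but
    # the loop is cheap enough (matrix ops on a few hundred rows) to keep
    # the schedule literal
  }
  combos |>
    dplyr::mutate(
      f0_cp = F0[, 1], f0_cn = F0[, 2], f0_np = F0[, 3], f0_nn = F0[, 4],
      f_cp = F[, 1], f_cn = F[, 2], f_np = F[, 3], f_nn = F[, 4],
      shannon = apply(F, 1, shannon_index),
      outcome = apply(F, 1, function(x) classify_outcome(setNames(x, MORPHS))),
      failed = !active,
      generations_run = ifelse(.data$failed, gens_run, generations)
    ) |>
    dplyr::select(-"f0")
}

#' Summarize a sweep: retention and morph proportions
#'
#' Aggregates a [run_sweep()] table the way the sweep results are reported:
#' among parameter combinations that retained a polymorphism, the share in
#' which the courter/parent morph reaches at least half the population, and
#' the mean morph proportions across the remaining (not CP-dominated)
#' polymorphic combinations.
#'
#' @param sweep_tbl Output of [run_sweep()].
#' @param retain Retention filter: `"shannon"` (default) keeps combinations
#'   whose final Shannon diversity is at least `shannon_min`, the filter used
#'   to delimit multi-morph parameter space; `"frequency"` keeps combinations
#'   with more than one morph above `freq_threshold`. Failed (reproductively
#'   collapsed) combinations are never counted as retaining polymorphism.
#' @param shannon_min Minimum Shannon index for the `"shannon"` filter.
#' @param freq_threshold Per-morph retention threshold for the `"frequency"`
#'   filter.
#' @return A one-row tibble with `n_retained`, `pct_cp_dominant`,
#'   `pct_not_cp_dominant`, and mean percentages `mean_cp`, `mean_np`,
#'   `mean_nn` over retained combos with `f_cp < 0.5`.
#' @export
summarize_sweep <- function(sweep_tbl, retain = c("shannon", "frequency"),
                            shannon_min = 1, freq_threshold = 0.01) {
  retain <- match.arg(retain)
  kept <- if (retain == "shannon") {
    dplyr::filter(sweep_tbl, !.data$failed, .data$shannon >= shannon_min)
  } else {
    dplyr::filter(
      sweep_tbl, !.data$failed,
      (.data$f_cp > freq_threshold) + (.data$f_cn > freq_threshold) +
        (.data$f_np > freq_threshold) + (.data$f_nn > freq_threshold) > 1
    )
  }
  shared <- dplyr::filter(kept, .data$f_cp < 0.5)
  tibble(
    n_retained = nrow(kept),
    pct_cp_dominant = 100 * mean(kept$f_cp >= 0.5),
    pct_not_cp_dominant = 100 * mean(kept$f_cp < 0.5),
    mean_cp = 100 * mean(shared$f_cp),
    mean_np = 100 * mean(shared$f_np),
    mean_nn = 100 * mean(shared$f_nn)
  )
}
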