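# Deterministic recurrence over the frequencies of the four male morphs.
#
# Each generation passes through five stages: mate choice (clutch count),
# fertilization (chosen males plus sneakers), parental care (clutches only
# survive under a caring male), viability selection, and maturation
# (renormalization of juvenile counts to frequencies).

#' Morph frequency vector
#'
#' Constructs and validates the four-morph frequency vector used as the state
#' of the analytical recurrence. Morphs are the combinations of two male
#' traits: courter/parent (CP), courter/non-parent (CN), non-courter/parent
#' (NP) and non-courter/non-parent (NN).
#'
#' @param cp,cn,np,nn Frequencies of the four morphs. Must be in \[0, 1\] and
#'   sum to 1 (within 1e-9).
#' @return A named numeric vector of length 4 with names `CP`, `CN`, `NP`, `NN`.
#' @examples
#' morph_freqs(0.25, 0.25, 0.25, 0.25)
#' @export
morph_freqs <- function(cp, cn, np, nn) {
  f <- c(CP = cp, CN = cn, NP = np, NN = nn)
  validate_freqs(f)
  f
}

validate_freqs <- function(f) {
  if (length(f) != 4 || anyNA(f)) {
    abort("morph frequencies must be 4 finite values", class = "morphsim_error")
  }
  if (any(f < -1e-12) || any(f > 1 + 1e-12)) {
    abort("morph frequencies must lie in [0, 1]", class = "morphsim_error")
  }
  if (abs(sum(f) - 1) > 1e-9) {
    abort("morph frequencies must sum to 1 (within 1e-9)",
          class = "morphsim_error")
  }
  invisible(f)
}

#' Parameters of the analytical morph-frequency recurrence
#'
#' Collects the coefficients of the five life-cycle stages. Defaults
#' correspond to the baseline assumptions: every female accepts a courting
#' male (`w_s = 1`), clutches survive only under a caring male
#' (`w_n = c(1, 0, 1, 0)`), and no viability cost (`v_court = v_parent = 1`).
#'
#' @param w_s Probability that a female chooses a courting male, in \[0, 1\].
#' @param n_males Number of males in the population (cancels out of the
#'   recurrence; kept for the stage-level bookkeeping).
#' @param r Named numeric vector of per-morph reproductive allocations (the
#'   maximum offspring units a male of each morph can sire). `r["NP"]` must
#'   equal `r["NN"]`.
#' @param sperm_comp Sperm-competition coefficient `c` in \[0, 1\]; scales the
#'   allocation a sneaker can realize.
#' @param n_sneak Number of sneakers per clutch (non-negative integer).
#' @param w_n Named clutch-survival coefficients per morph, each in \[0, 1\].
#' @param v_court,v_parent Per-trait viability retentions in (0, 1]. The
#'   per-morph viability coefficients are multiplicative:
#'   `w_v = c(CP = v_court * v_parent, CN = v_court, NP = v_parent, NN = 1)`.
#' @param sneak_rule Either `"min"` (default): eggs fertilized by sneaking are
#'   bounded by both the sneak capacity and the morph's population-level
#'   reproductive effort, `min(N_s, f * N_m * r)`; or `"literal"`: the
#'   difference `max(N_s - f * N_m * r, 0)`, kept for sensitivity analysis.
#' @return An object of class `analytic_params` (a validated list).
#' @examples
#' analytic_params(sperm_comp = 0.5, n_sneak = 2)
#' @export
analytic_params <- function(w_s = 1,
                            n_males = 100,
                            r = c(CP = 8, CN = 8, NP = 4, NN = 4),
                            sperm_comp = 0.5,
                            n_sneak = 2,
                            w_n = c(CP = 1, CN = 0, NP = 1, NN = 0),
                            v_court = 1,
                            v_parent = 1,
                            sneak_rule = c("min", "literal")) {
  sneak_rule <- match.arg(sneak_rule)
  r <- as_morph_vec(r, "r")
  w_n <- as_morph_vec(w_n, "w_n")
  stopifnot(length(w_s) == 1, length(sperm_comp) == 1, length(n_sneak) == 1)
  if (w_s < 0 || w_s > 1) abort("w_s must be in [0, 1]", class = "morphsim_error")
  if (sperm_comp < 0 || sperm_comp > 1) {
    abort("sperm_comp must be in [0, 1]", class = "morphsim_error")
  }
  if (any(r < 0)) abort("reproductive allocations must be >= 0", class = "morphsim_error")
  if (abs(r[["NP"]] - r[["NN"]]) > 1e-12) {
    abort("r[NP] must equal r[NN]", class = "morphsim_error")
  }
  if (n_sneak < 0 || n_sneak != round(n_sneak)) {
    abort("n_sneak must be a non-negative integer", class = "morphsim_error")
  }
  if (any(w_n < 0 | w_n > 1)) abort("w_n must be in [0, 1]", class = "morphsim_error")
  if (v_court <= 0 || v_court > 1 || v_parent <= 0 || v_parent > 1) {
    abort("viability retentions must be in (0, 1]", class = "morphsim_error")
  }
  if (n_males <= 0) abort("n_males must be positive", class = "morphsim_error")
  structure(
    list(w_s = w_s, n_males = n_males, r = r, sperm_comp = sperm_comp,
         n_sneak = n_sneak, w_n = w_n, v_court = v_court, v_parent = v_parent,
         w_v = c(CP = v_court * v_parent, CN = v_court, NP = v_parent, NN = 1),
         sneak_rule = sneak_rule),
    class = "analytic_params"
  )
}

as_morph_vec <- function(x, what) {
  if (length(x) != 4) abort(paste(what, "must have 4 entries"), class = "morphsim_error")
  if (is.null(names(x))) names(x) <- MORPHS
  if (!setequal(names(x), MORPHS)) {
    abort(paste(what, "must be named CP, CN, NP, NN"), class = "morphsim_error")
  }
  x[MORPHS]
}

#' @export
print.analytic_params <- function(x, ...) {
  cat("Analytical morph-recurrence parameters\n")
  cat(sprintf("  w_s = %g, n_males = %g, c = %g, n_sneak = %d\n",
              x$w_s, x$n_males, x$sperm_comp, as.integer(x$n_sneak)))
  cat(sprintf("  r   = (%s)\n", paste(sprintf("%s=%g", MORPHS, x$r), collapse = ", ")))
  cat(sprintf("  w_n = (%s); w_v = (%s)\n",
              paste(x$w_n, collapse = ", "), paste(round(x$w_v, 4), collapse = ", ")))
  invisible(x)
}

#' Stage 1: number of clutches
#'
#' Females mate with a courting male with probability `w_s`, otherwise with a
#' non-courting male. Each mating yields one clutch, so the clutch count is
#' `n = w_s * N_m * (f_CP + f_CN) + (1 - w_s) * N_m * (f_NP + f_NN)`.
#'
#' @param f Morph frequencies (see [morph_freqs()]).
#' @param params An [analytic_params()] object.
#' @return The clutch count (scalar, possibly 0).
#' @export
clutch_count <- function(f, params) {
  validate_freqs(f)
  params$w_s * params$n_males * (f[["CP"]] + f[["CN"]]) +
    (1 - params$w_s) * params$n_males * (f[["NP"]] + f[["NN"]])
}

#' Stage 2: population-level sneak capacity
#'
#' Maximum number of fertilizations achievable through sneaking for a given
#' non-courting morph: `N_s = n * c * n_sneak * r_NN` (clutch count times the
#' sperm-competition-discounted allocation of each of the `n_sneak` sneakers
#' per clutch).
#'
#' @param n Clutch count from [clutch_count()].
#' @param params An [analytic_params()] object.
#' @return The sneak capacity (scalar).
#' @export
sneak_capacity <- function(n, params) {
  stopifnot(n >= 0)
  n * params$sperm_comp * params$n_sneak * params$r[["NN"]]
}

#' Per-clutch share fertilized by one sneaker
#'
#' In a single clutch in which the non-courting male could fertilize `eggs`
#' eggs, a chosen male with relative allocation `r` and `n_sneak` competing
#' sneakers each discounted by `c`, one sneaker fertilizes
#' `c * E / (r * E + n_sneak * c * E)` of the offspring.
#'
#' @param eggs Number of eggs the non-courting male could fertilize (> 0).
#' @param r Chosen male's allocation relative to the sneaker's.
#' @param sperm_comp Sperm-competition coefficient in \[0, 1\].
#' @param n_sneak Number of sneakers competing in the clutch.
#' @return Proportion of the clutch fertilized by one sneaker.
#' @examples
#' sneak_share(eggs = 8, r = 0.5, sperm_comp = 0.2, n_sneak = 2) # 0.222
#' @export
sneak_share <- function(eggs, r, sperm_comp, n_sneak) {
  stopifnot(eggs > 0, r >= 0, sperm_comp >= 0, sperm_comp <= 1)
  denom <- r * eggs + n_sneak * sperm_comp * eggs
  if (denom == 0) {
    abort("empty clutch share: r = 0 and c * n_sneak = 0", class = "morphsim_empty_clutch")
  }
  sperm_comp * eggs / denom
}

#' Stage 2: eggs fertilized per morph
#'
#' Fills the fertilization entries of the stage ledger. Chosen-male
#' fertilizations are `e_o = f * N_m * r * w_sM`, where `w_sM` is `w_s` for
#' courting morphs and `1 - w_s` for non-courting morphs. Sneak
#' fertilizations `e_s` are zero for courting morphs; each non-courting morph
#' independently realizes `min(N_s, f * N_m * r)` (or the literal difference
#' rule, see [analytic_params()]).
#'
#' @inheritParams clutch_count
#' @param n Clutch count; defaults to [clutch_count()] of `f`.
#' @return A `stage_ledger` list with fields `n`, `N_s`, `e_o`, `e_s`.
#' @export
fertilization <- function(f, params, n = clutch_count(f, params)) {
  validate_freqs(f)
  Ns <- sneak_capacity(n, params)
  w_sM <- c(params$w_s, params$w_s, 1 - params$w_s, 1 - params$w_s)
  e_o <- setNames(as.numeric(f) * params$n_males * params$r * w_sM, MORPHS)
  effort <- as.numeric(f) * params$n_males * params$r
  e_s <- if (params$sneak_rule == "min") {
    pmin(Ns, effort)
  } else {
    pmax(Ns - effort, 0)
  }
  e_s <- setNames(as.numeric(e_s), MORPHS)
  e_s[c("CP", "CN")] <- 0
  structure(list(n = n, N_s = Ns, e_o = e_o, e_s = e_s),
            class = "stage_ledger")
}

#' Stage 3: offspring surviving parental care
#'
#' Chosen-male offspring survive with their morph's clutch-survival
#' coefficient, `o_o = e_o * w_n`. Sneak-sired offspring survive in
#' proportion to the clutch survival of the males that were chosen:
#' `o_s = e_s * sum(o_o) / sum(e_o)` (defined as 0 when no eggs were
#' fertilized by chosen males).
#'
#' @param ledger A `stage_ledger` from [fertilization()].
#' @param params An [analytic_params()] object.
#' @return The ledger with `o_o`, `o_s` and `o = o_o + o_s` filled in.
#' @export
care <- function(ledger, params) {
  stopifnot(inherits(ledger, "stage_ledger"))
  o_o <- ledger$e_o * params$w_n
  tot_e <- sum(ledger$e_o)
  frac <- if (tot_e > 0) sum(o_o) / tot_e else 0
  o_s <- ledger$e_s * frac
  ledger$o_o <- o_o
  ledger$o_s <- o_s
  ledger$o <- o_o + o_s
  ledger
}

#' Stage 4: viability selection on juveniles
#'
#' Juvenile counts are `j = o * w_v`, where the per-morph viability
#' coefficients multiply the per-trait retentions (`v_court` for courters,
#' `v_parent` for parents), so the courter/parent morph pays both costs.
#'
#' @inheritParams care
#' @return The ledger with `j` filled in.
#' @export
viability <- function(ledger, params) {
  stopifnot(!is.null(ledger$o))
  ledger$j <- ledger$o * params$w_v
  ledger
}

#' @export
print.stage_ledger <- function(x, ...) {
  cat(sprintf("Stage ledger: n = %g clutches, N_s = %g\n", x$n, x$N_s))
  m <- do.call(rbind, x[intersect(c("e_o", "e_s", "o_o", "o_s", "o", "j"), names(x))])
  print(round(m, 4))
  invisible(x)
}

#' Advance morph frequencies by one generation
#'
#' Runs the five stages and renormalizes the juvenile counts:
#' `f' = j / sum(j)`.
#'
#' @inheritParams clutch_count
#' @return The next-generation morph frequencies (named vector summing to 1).
#'   Signals a condition of class `morphsim_reproductive_failure` when no
#'   juveniles are produced.
#' @examples
#' p <- analytic_params(r = c(CP = 16, CN = 16, NP = 8, NN = 8),
#'                      sperm_comp = 0.5, n_sneak = 2)
#' morph_step(morph_freqs(0.25, 0.25, 0.25, 0.25), p)
#' @export
morph_step <- function(f, params) {
  ledger <- viability(care(fertilization(f, params), params), params)
  j <- ledger$j
  tot <- sum(j)
  if (tot <= 0) {
    abort("population reproductive failure: no surviving juveniles",
          class = "morphsim_reproductive_failure")
  }
  j / tot
}

#' Iterate the morph-frequency recurrence
#'
#' @inheritParams clutch_count
#' @param generations Number of generations to iterate (>= 0).
#' @return A tibble of class `morph_trajectory` with columns `generation`,
#'   `CP`, `CN`, `NP`, `NN`. If the population fails to reproduce the
#'   trajectory is truncated at the last valid state and carries the
#'   attribute `failed = TRUE`.
#' @examples
#' p <- analytic_params(r = c(CP = 4, CN = 4, NP = 8, NN = 8),
#'                      sperm_comp = 0.75, n_sneak = 2)
#' traj <- morph_iterate(morph_freqs(0.25, 0.25, 0.25, 0.25), p, 100)
#' tail(traj)
#' @export
morph_iterate <- function(f, params, generations) {
  stopifnot(generations >= 0)
  validate_freqs(f)
  out <- matrix(NA_real_, nrow = generations + 1, ncol = 4,
                dimnames = list(NULL, MORPHS))
  out[1, ] <- f
  failed <- FALSE
  t_done <- 0
  if (generations > 0) {
    for (t in seq_len(generations)) {
      f <- tryCatch(morph_step(f, params),
                    morphsim_reproductive_failure = function(e) NULL)
      if (is.null(f)) {
        failed <- TRUE
        break
      }
      out[t + 1, ] <- f
      t_done <- t
    }
  }
  traj <- as_tibble(out[seq_len(t_done + 1), , drop = FALSE])
  traj <- dplyr::mutate(traj, generation = seq_len(nrow(traj)) - 1L,
                        .before = 1)
  structure(traj, failed = failed, params = params,
            class = c("morph_trajectory", class(traj)))
}

#' Shannon diversity of a morph-frequency vector
#'
#' `H = -sum(f * log(f))` over morphs with positive frequency (natural log).
#'
#' @inheritParams clutch_count
#' @return Shannon diversity index (scalar >= 0).
#' @examples
#' shannon_index(morph_freqs(0.25, 0.25, 0.25, 0.25)) # log(4)
#' @export
shannon_index <- function(f) {
  f <- as.numeric(f)
  f <- f[f > 0]
  -sum(f * log(f))
}

#' Classify the outcome of a trajectory
#'
#' A morph is retained when its final frequency exceeds `threshold`.
#'
#' @param f Final morph frequencies.
#' @param threshold Retention threshold on a morph's frequency (default 0.01).
#' @return One of `"fixed_CP"`, `"fixed_other"`, `"two_morphs"`,
#'   `"three_morphs"` (three or more morphs retained).
#' @export
classify_outcome <- function(f, threshold = 0.01) {
  f <- as_morph_vec(f, "f")
  retained <- names(f)[f > threshold]
  n <- length(retained)
  if (n <= 1) {
    if (identical(retained, "CP")) "fixed_CP" else "fixed_other"
  } else if (n == 2) {
    "two_morphs"
  } else {
    "three_morphs"
  }
}

#' @export
glance.morph_trajectory <- function(x, ...) {
  fin <- as.numeric(x[nrow(x), MORPHS])
  tibble(
    generations = max(x$generation),
    failed = isTRUE(attr(x, "failed")),
    f_cp = fin[1], f_cn = fin[2], f_np = fin[3], f_nn = fin[4],
    shannon = shannon_index(fin),
    outcome = classify_outcome(setNames(fin, MORPHS))
  )
}

#' @export
tidy.morph_trajectory <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), cols = dplyr::all_of(MORPHS),
                      names_to = "morph", values_to = "frequency")
}

#' Plot a morph-frequency trajectory
#'
#' @param object A `morph_trajectory` from [morph_iterate()].
#' @param ... Unused.
#' @return A ggplot object showing each morph's frequency over generations.
#' @export
autoplot.morph_trajectory <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$generation, y = .data$frequency,
                               colour = .data$morph)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Generation", y = "Morph frequency", colour = "Morph") +
    ggplot2::theme_minimal()
}
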