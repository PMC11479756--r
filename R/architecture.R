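# Explicit genetic architectures for the individual-based simulator.
#
# A genome is n_chrom chromosomes of loci_per_chrom loci. Two additive
# threshold traits (courting, parenting) are each controlled by n_qtl
# quantitative trait loci, either scattered genome-wide, clustered inside a
# non-recombining supergene region, or reduced to one large-effect locus per
# trait. All other loci are neutral markers.
#
# Internal coordinates are 0-based; the supergene is a half-open interval
# [start, end) of locus indices. VCF/BED export converts (io.R).

#' Build a genetic architecture
#'
#' @param architecture One of `"genome_wide"` (QTLs drawn uniformly without
#'   replacement across all chromosomes), `"supergene"` (all QTLs of both
#'   traits drawn inside a non-recombining region of one chromosome), or
#'   `"single_locus"` (one locus per trait on separate chromosomes with fixed
#'   allelic effects -1/+1 and thresholds at 0).
#' @param n_chrom Number of chromosomes (the replicated conditions use
#'   2, 4 or 8).
#' @param loci_per_chrom Loci per chromosome, markers plus QTLs (default 1000).
#' @param n_qtl QTLs per trait (the replicated conditions use 8, 16, 32, 64).
#' @param supergene_prop Proportion of the supergene chromosome occupied by
#'   the region (0.05, 0.25 or 0.50 in the replicated conditions).
#' @param supergene_chrom Chromosome carrying the supergene (default 1).
#' @param recomb_rate Expected crossovers per chromosome per meiosis
#'   (default 0.2).
#' @param mu Per-locus mutation rate per generation (default 1e-4).
#' @param sigma_mu Standard deviation of the effect-size perturbation applied
#'   when a QTL copy mutates (default 0.05).
#' @param sigma_effect Standard deviation of the initial allelic-effect draw
#'   at QTLs (default 0.5).
#' @return An object of class `genome_arch` with the QTL map (`qtl`: tibble
#'   of trait, chromosome, 0-based locus), allelic effects (one per QTL and
#'   allele state), thresholds placeholder, and the supergene interval (or
#'   `NULL`).
#' @examples
#' set.seed(1)
#' arch <- genome_architecture("genome_wide", n_chrom = 2, n_qtl = 8)
#' arch
#' @export
genome_architecture <- function(architecture = c("genome_wide", "supergene",
                                                 "single_locus"),
                                n_chrom = 2,
                                loci_per_chrom = 1000,
                                n_qtl = 8,
                                supergene_prop = 0.25,
                                supergene_chrom = 1,
                                recomb_rate = 0.2,
                                mu = 1e-4,
                                sigma_mu = 0.05,
                                sigma_effect = 0.5) {
  architecture <- match.arg(architecture)
  stopifnot(n_chrom >= 1, loci_per_chrom >= 1, n_qtl >= 1,
            recomb_rate >= 0, mu >= 0, sigma_mu >= 0, sigma_effect >= 0)
  supergene <- NULL
  if (architecture == "single_locus") {
    n_chrom <- max(n_chrom, 2)
    loci_per_chrom <- 1L
    qtl <- tibble(trait = c("courter", "parent"),
                  chrom = c(1L, 2L), locus = c(0L, 0L))
    effects <- tibble(trait = qtl$trait[c(1, 1, 2, 2)],
                      chrom = qtl$chrom[c(1, 1, 2, 2)],
                      locus = 0L, state = c(0L, 1L, 0L, 1L),
                      effect = c(-1, 1, -1, 1))
  } else {
    n_pos <- n_chrom * loci_per_chrom
    need <- 2L * n_qtl
    if (architecture == "supergene") {
      len <- round(supergene_prop * loci_per_chrom)
      if (need > len) {
        abort(sprintf(
          "supergene region of %d loci cannot hold %d QTLs (2 traits x %d)",
          len, need, n_qtl), class = "morphsim_config_error")
      }
      start <- if (loci_per_chrom - len > 0) {
        sample.int(loci_per_chrom - len + 1L, 1L) - 1L
      } else 0L
      supergene <- list(chrom = as.integer(supergene_chrom),
                        start = as.integer(start),
                        end = as.integer(start + len),
                        proportion = supergene_prop)
      pos <- sample(start:(start + len - 1L), need)
      qtl <- tibble(trait = rep(c("courter", "parent"), each = n_qtl),
                    chrom = as.integer(supergene_chrom),
                    locus = as.integer(pos))
    } else {
      if (need > n_pos) {
        abort("more QTLs than loci in the genome", class = "morphsim_config_error")
      }
      pos <- sample.int(n_pos, need) - 1L
      qtl <- tibble(trait = rep(c("courter", "parent"), each = n_qtl),
                    chrom = as.integer(pos %/% loci_per_chrom + 1L),
                    locus = as.integer(pos %% loci_per_chrom))
    }
    qtl <- dplyr::arrange(qtl, .data$trait, .data$chrom, .data$locus)
    effects <- tidyr::expand_grid(qtl, state = 0:1) |>
      dplyr::mutate(effect = rnorm(dplyr::n(), 0, sigma_effect)) |>
      dplyr::select("trait", "chrom", "locus", "state", "effect")
  }
  structure(
    list(architecture = architecture, n_chrom = as.integer(n_chrom),
         loci_per_chrom = as.integer(loci_per_chrom),
         n_qtl = as.integer(n_qtl), qtl = qtl, effects = effects,
         supergene = supergene, recomb_rate = recomb_rate, mu = mu,
         sigma_mu = sigma_mu, sigma_effect = sigma_effect),
    class = "genome_arch"
  )
}

#' @export
print.genome_arch <- function(x, ...) {
  cat(sprintf("Genome architecture: %s\n", x$architecture))
  cat(sprintf("  %d chromosome(s) x %d loci; %d QTLs per trait\n",
              x$n_chrom, x$loci_per_chrom, x$n_qtl))
  if (!is.null(x$supergene)) {
    cat(sprintf("  supergene: chr%d loci [%d, %d) (%.0f%% of chromosome)\n",
                x$supergene$chrom, x$supergene$start, x$supergene$end,
                100 * x$supergene$proportion))
  }
  cat(sprintf("  recomb_rate = %g, mu = %g, sigma_mu = %g\n",
              x$recomb_rate, x$mu, x$sigma_mu))
  invisible(x)
}

# Global 0-based column/row index of a (chrom, locus) pair.
locus_index <- function(chrom, locus, loci_per_chrom) {
  (chrom - 1L) * loci_per_chrom + locus
}

# QTL bookkeeping in global indices, split by trait.
arch_qtl_idx <- function(arch) {
  q <- arch$qtl
  split(locus_index(q$chrom, q$locus, arch$loci_per_chrom), q$trait)
}

# Effect lookup matrices: rows = QTLs of the trait (in arch$qtl order),
# columns = allele states 0..max_state.
arch_effect_matrix <- function(arch, trait) {
  eff <- dplyr::filter(arch$effects, .data$trait == !!trait) |>
    dplyr::arrange(.data$chrom, .data$locus, .data$state)
  n_states <- max(eff$state) + 1L
  matrix(eff$effect, ncol = n_states, byrow = TRUE)
}

#' Initialize a population conforming to an architecture
#'
#' Generation-0 haplotype states are drawn independently per locus (alleles 0
#' and 1 with probability 1/2 each, maximizing initial segregation); sexes
#' are a fair binomial draw. Each QTL allele copy carries the allelic effect
#' drawn for its state.
#'
#' @param arch A [genome_architecture()].
#' @param n Number of individuals.
#' @return An object of class `morph_pop`: haplotype state matrix
#'   (`loci x 2n`, columns `2i-1`, `2i` are individual `i`'s haplotypes),
#'   per-copy QTL effect matrices, sexes, and (once set) trait thresholds.
#' @export
init_population <- function(arch, n) {
  stopifnot(n >= 1)
  Lg <- arch$n_chrom * arch$loci_per_chrom
  state <- matrix(sample(0:1, Lg * 2 * n, replace = TRUE), nrow = Lg)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  pop <- structure(list(state = state, sex = sex, arch = arch,
                        thresholds = NULL),
                   class = "morph_pop")
  pop$eff_c <- copy_effects(pop, "courter")
  pop$eff_p <- copy_effects(pop, "parent")
  pop
}

# Per-copy effect matrix (n_qtl x 2n) for a trait, looked up from the
# architecture's state-level effect table.
copy_effects <- function(pop, trait) {
  arch <- pop$arch
  idx <- arch_qtl_idx(arch)[[trait]] # 0-based global locus indices
  lut <- arch_effect_matrix(arch, trait)
  st <- pop$state[idx + 1L, , drop = FALSE]
  out <- matrix(0, nrow = length(idx), ncol = ncol(st))
  for (s in seq_len(ncol(lut)) - 1L) {
    hit <- st == s
    if (any(hit)) out[hit] <- lut[, s + 1L][row(st)[hit]]
  }
  out
}

#' Additive phenotypes of every individual
#'
#' Each trait value is the sum over both haplotypes of the effects carried by
#' the individual's QTL allele copies (mutated copies carry their perturbed
#' effects).
#'
#' @param pop A `morph_pop`.
#' @return A tibble with columns `id`, `sex`, `courter_value`, `parent_value`.
#' @export
phenotypes <- function(pop) {
  pc <- colSums(pop$eff_c)
  pp <- colSums(pop$eff_p)
  n <- length(pop$sex)
  odd <- seq(1, 2 * n, by = 2)
  tibble(id = seq_len(n), sex = pop$sex,
         courter_value = pc[odd] + pc[odd + 1],
         parent_value = pp[odd] + pp[odd + 1])
}

#' Freeze trait thresholds from the generation-0 population
#'
#' Thresholds are the mean phenotypic values over all generation-0
#' individuals, fixed for the entire run.
#'
#' @param pop A `morph_pop` (generation 0).
#' @return The population with `thresholds = c(courter =, parent =)` set.
#' @export
initialize_thresholds <- function(pop) {
  if (length(pop$sex) == 0) abort("empty population", class = "morphsim_error")
  if (pop$arch$architecture == "single_locus") {
    # fixed +/-1 allelic effects straddle a threshold of 0
    pop$thresholds <- c(courter = 0, parent = 0)
    return(pop)
  }
  ph <- phenotypes(pop)
  pop$thresholds <- c(courter = mean(ph$courter_value),
                      parent = mean(ph$parent_value))
  pop
}

#' Assign morphs from phenotypes and thresholds
#'
#' A male is a courter (respectively parent) when his trait value strictly
#' exceeds the threshold; values at or below the threshold express the
#' non-courting (non-parenting) state.
#'
#' @param courter_value,parent_value Numeric phenotype vectors.
#' @param thresholds Named vector `c(courter =, parent =)`.
#' @return Character vector of morph labels (`"CP"`, `"CN"`, `"NP"`, `"NN"`).
#' @export
assign_morph <- function(courter_value, parent_value, thresholds) {
  courter <- courter_value > thresholds[["courter"]]
  parent <- parent_value > thresholds[["parent"]]
  dplyr::case_when(courter & parent ~ "CP",
                   courter & !parent ~ "CN",
                   !courter & parent ~ "NP",
                   .default = "NN")
}

# Morphs of the males in a population (females get NA).
pop_morphs <- function(pop) {
  ph <- phenotypes(pop)
  m <- assign_morph(ph$courter_value, ph$parent_value, pop$thresholds)
  m[pop$sex != "M"] <- NA_character_
  m
}

#' @export
print.morph_pop <- function(x, ...) {
  n <- length(x$sex)
  cat(sprintf("Population: %d individuals (%d F, %d M), %s architecture\n",
              n, sum(x$sex == "F"), sum(x$sex == "M"), x$arch$architecture))
  if (!is.null(x$thresholds)) {
    m <- table(pop_morphs(x))
    cat(sprintf("  male morphs: %s\n",
                paste(sprintf("%s=%d", names(m), m), collapse = ", ")))
  }
  invisible(x)
}
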