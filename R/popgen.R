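# Per-locus and windowed population-genomic statistics on simulated
# genotypes: heterozygosity, Nei's G_ST between male morphs, a dosage score
# test of morph-trait association, Tajima's D in fixed windows, pairwise LD
# (genotype r^2), peak calling and detection of the true QTLs.

#' Genotype table
#'
#' The container consumed by the statistics layer: an integer haplotype
#' matrix (loci in rows, two columns per individual), sample metadata, and a
#' locus map carrying 1-based positions and QTL flags.
#'
#' @param geno Integer matrix, `n_loci x (2 * n_samples)`; columns `2i-1`,
#'   `2i` are individual `i`'s two allele copies (states are non-negative
#'   integers).
#' @param samples Tibble with columns `id`, `sex`, `morph` (`NA` for
#'   females).
#' @param loci Tibble with columns `chrom`, `pos` (1-based), `qtl` (logical)
#'   and `trait` (`NA` for markers).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(geno, samples, loci) {
  stopifnot(is.matrix(geno), nrow(geno) == nrow(loci),
            ncol(geno) == 2 * nrow(samples), all(geno >= 0))
  structure(list(geno = geno, samples = samples, loci = loci),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table: %d loci x %d samples (%d QTLs)\n",
              nrow(x$loci), nrow(x$samples), sum(x$loci$qtl)))
  invisible(x)
}

#' Convert a simulated population to a genotype table
#'
#' @param pop A `morph_pop` with thresholds set.
#' @return A [genotype_table()] covering every locus in the genome.
#' @export
as_genotype_table <- function(pop) {
  arch <- pop$arch
  n <- length(pop$sex)
  morph <- pop_morphs(pop)
  samples <- tibble(id = sample_ids(pop$sex, morph), sex = pop$sex,
                    morph = morph)
  loci <- tibble(
    chrom = rep(seq_len(arch$n_chrom), each = arch$loci_per_chrom),
    pos = rep(seq_len(arch$loci_per_chrom), arch$n_chrom)
  )
  key <- locus_index(loci$chrom, loci$pos - 1L, arch$loci_per_chrom)
  qkey <- locus_index(arch$qtl$chrom, arch$qtl$locus, arch$loci_per_chrom)
  hit <- match(key, qkey)
  loci$qtl <- !is.na(hit)
  loci$trait <- arch$qtl$trait[hit]
  genotype_table(pop$state, samples, loci)
}

sample_ids <- function(sex, morph) {
  code <- ifelse(is.na(morph), "NA", morph)
  sprintf("%s_%s_%04d", sex, code, seq_along(sex))
}

# Split haplotype columns into the two copies per individual.
hap_pair <- function(gt) {
  n <- nrow(gt$samples)
  odd <- seq(1, 2 * n, by = 2)
  list(a = gt$geno[, odd, drop = FALSE], b = gt$geno[, odd + 1, drop = FALSE])
}

# Per-locus allele frequency matrix over a set of haplotype columns:
# rows = loci, one column per allele state in `states`.
freq_matrix <- function(geno, states) {
  m <- vapply(states, function(s) rowMeans(geno == s), numeric(nrow(geno)))
  matrix(m, nrow = nrow(geno))
}

count_matrix <- function(geno, states) {
  m <- vapply(states, function(s) rowSums(geno == s), numeric(nrow(geno)))
  matrix(m, nrow = nrow(geno))
}

allele_freqs <- function(geno) {
  freq_matrix(geno, sort(unique(as.vector(geno))))
}

#' Observed heterozygosity per locus
#'
#' Fraction of individuals whose two allele copies differ.
#'
#' @param gt A [genotype_table()].
#' @return Numeric vector, one value per locus.
#' @export
observed_heterozygosity <- function(gt) {
  h <- hap_pair(gt)
  rowMeans(h$a != h$b)
}

#' Expected heterozygosity per locus
#'
#' `1 - sum(p_a^2)` over the allele frequencies at the locus.
#'
#' @inheritParams observed_heterozygosity
#' @return Numeric vector, one value per locus.
#' @export
expected_heterozygosity <- function(gt) {
  p <- allele_freqs(gt$geno)
  1 - rowSums(p^2)
}

#' Nei's G_ST between groups, per locus
#'
#' `(H_T - H_S) / H_T`, with `H_S` the unweighted mean within-group expected
#' heterozygosity and `H_T` the expected heterozygosity of the unweighted
#' mean allele frequencies; defined as 0 where `H_T = 0`. Groups default to
#' the male morphs.
#'
#' @inheritParams observed_heterozygosity
#' @param groups Character vector assigning each sample to a group (`NA`
#'   samples are dropped); defaults to the sample morphs.
#' @param weighted If `TRUE`, group contributions are weighted by sample
#'   size instead of equally.
#' @return Numeric vector of per-locus G_ST values in \[0, 1\].
#' @export
gst_between_groups <- function(gt, groups = gt$samples$morph,
                               weighted = FALSE) {
  keep <- !is.na(groups)
  groups <- groups[keep]
  lv <- unique(groups)
  if (length(lv) < 2) {
    abort("G_ST needs at least 2 non-empty groups", class = "morphsim_error")
  }
  states <- sort(unique(as.vector(gt$geno)))
  w <- if (weighted) table(groups)[lv] / length(groups) else rep(1 / length(lv), length(lv))
  hs <- 0
  pbar <- matrix(0, nrow(gt$geno), length(states))
  for (k in seq_along(lv)) {
    cols <- which(keep)[groups == lv[k]]
    hcols <- rep(cols * 2L, each = 2L) + c(-1L, 0L)
    p <- freq_matrix(gt$geno[, hcols, drop = FALSE], states)
    hs <- hs + w[[k]] * (1 - rowSums(p^2))
    pbar <- pbar + w[[k]] * p
  }
  ht <- 1 - rowSums(pbar^2)
  ifelse(ht > 0, (ht - hs) / ht, 0)
}

#' Dosage score test of association with a binary morph trait
#'
#' Per locus, reduces genotypes to the major-allele dosage (0/1/2) and tests
#' association with a binary trait among males using the score test of a
#' logistic regression on dosage (equivalently a 1-d.f. chi-square trend
#' test): `U = sum((y - ybar) x)`, `V = ybar (1 - ybar) sum((x - xbar)^2)`,
#' `X^2 = U^2 / V`. Monomorphic loci get p = 1.
#'
#' @inheritParams observed_heterozygosity
#' @param trait `"courter"` or `"parent"`: the male trait tested.
#' @return Numeric vector of per-locus p-values in (0, 1].
#' @export
association_scan <- function(gt, trait = c("courter", "parent")) {
  trait <- match.arg(trait)
  males <- which(gt$samples$sex == "M" & !is.na(gt$samples$morph))
  y <- if (trait == "courter") {
    as.numeric(gt$samples$morph[males] %in% c("CP", "CN"))
  } else {
    as.numeric(gt$samples$morph[males] %in% c("CP", "NP"))
  }
  if (length(unique(y)) < 2) {
    warn("single trait class present; association p-values set to 1")
    return(rep(1, nrow(gt$geno)))
  }
  x <- major_dosage(gt)[, males, drop = FALSE]
  assoc_score_p(x, y)
}

# Score-test p-values for a dosage matrix (loci x samples) vs binary y.
assoc_score_p <- function(x, y) {
  ybar <- mean(y)
  u <- as.vector(x %*% (y - ybar))
  v <- ybar * (1 - ybar) * (rowSums(x^2) - rowSums(x)^2 / length(y))
  p <- rep(1, nrow(x))
  ok <- v > 0
  p[ok] <- pchisq(u[ok]^2 / v[ok], df = 1, lower.tail = FALSE)
  pmax(p, .Machine$double.xmin)
}

# Major-allele dosage matrix (loci x individuals), reducing multi-allelic
# loci to major allele vs the rest.
major_dosage <- function(gt) {
  p <- allele_freqs(gt$geno)
  states <- sort(unique(as.vector(gt$geno)))
  major <- states[max.col(p, ties.method = "first")]
  h <- hap_pair(gt)
  (h$a == major) + (h$b == major)
}

#' Tajima's D in fixed windows of loci
#'
#' Computes the standard Tajima test statistic per non-overlapping window of
#' `window` loci along each chromosome, from the 2N pseudo-haplotypes:
#' `D = (pi - S / a1) / sqrt(e1 S + e2 S (S - 1))` where `pi` is the mean
#' number of pairwise differences in the window, `S` the number of
#' segregating loci (a locus with more than one state segregating counts
#' once), and the constants follow the published formulation. Windows with
#' `S = 0` are reported as `NA`.
#'
#' @inheritParams observed_heterozygosity
#' @param window Number of loci per window (default 50).
#' @return A tibble with one row per window: `chrom`, `start`, `end`
#'   (1-based positions), `n_loci`, `s` (segregating sites), `pi`, `d`, and
#'   `has_qtl`.
#' @export
tajimas_d <- function(gt, window = 50) {
  stopifnot(window >= 1)
  n <- 2 * nrow(gt$samples)
  # per-locus mean pairwise difference: 1 - sum_s C(k_s,2)/C(n,2)
  cnt <- count_matrix(gt$geno, sort(unique(as.vector(gt$geno))))
  pair_same <- rowSums(cnt * (cnt - 1) / 2)
  pi_locus <- 1 - pair_same / (n * (n - 1) / 2)
  seg <- rowSums(cnt > 0) > 1
  win <- dplyr::mutate(gt$loci,
                       .win = (dplyr::row_number() - 1) %/% window,
                       .by = "chrom")
  dplyr::summarise(
    dplyr::mutate(win, pi_locus = pi_locus, seg = seg),
    start = min(.data$pos), end = max(.data$pos),
    n_loci = dplyr::n(), s = sum(.data$seg), pi = sum(.data$pi_locus),
    has_qtl = any(.data$qtl),
    .by = c("chrom", ".win")
  ) |>
    dplyr::mutate(d = tajima_d_stat(.data$s, .data$pi, n)) |>
    dplyr::select("chrom", "start", "end", "n_loci", "s", "pi", "d",
                  "has_qtl")
}

# The D statistic from S, pi and the haplotype count n.
tajima_d_stat <- function(S, pi, n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  d <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  ifelse(S > 0, d, NA_real_)
}

#' Pairwise linkage disequilibrium (genotype r^2)
#'
#' Squared Pearson correlation of major-allele dosages (0/1/2) between loci.
#'
#' @inheritParams observed_heterozygosity
#' @param loci Optional integer vector of locus rows to include (default
#'   all).
#' @return A symmetric matrix of r^2 values (`NA` for monomorphic loci).
#' @export
ld_r2 <- function(gt, loci = NULL) {
  d <- major_dosage(gt)
  if (!is.null(loci)) d <- d[loci, , drop = FALSE]
  suppressWarnings(cor(t(d))^2)
}

#' Per-locus LD summaries
#'
#' Mean and maximum r^2 of each locus against all other loci.
#'
#' @inheritParams ld_r2
#' @return A tibble with `mean_r2` and `max_r2` per locus.
#' @export
ld_summary <- function(gt, loci = NULL) {
  r2 <- ld_r2(gt, loci)
  diag(r2) <- NA
  tibble(mean_r2 = rowMeans(r2, na.rm = TRUE),
         max_r2 = suppressWarnings(apply(r2, 1, max, na.rm = TRUE))) |>
    dplyr::mutate(max_r2 = ifelse(is.finite(.data$max_r2), .data$max_r2,
                                  NA_real_))
}

#' Per-locus statistics table
#'
#' Convenience wrapper assembling the locus map, observed and expected
#' heterozygosity, male-morph G_ST and the association p-values for both
#' traits.
#'
#' @inheritParams observed_heterozygosity
#' @return A tibble with one row per locus.
#' @export
locus_stats <- function(gt) {
  morphs <- gt$samples$morph
  gst <- if (length(unique(morphs[!is.na(morphs)])) >= 2) {
    gst_between_groups(gt)
  } else {
    rep(NA_real_, nrow(gt$geno))
  }
  dplyr::mutate(gt$loci,
                h_obs = observed_heterozygosity(gt),
                h_exp = expected_heterozygosity(gt),
                gst = gst,
                p_courter = quiet_assoc(gt, "courter"),
                p_parent = quiet_assoc(gt, "parent"))
}

quiet_assoc <- function(gt, trait) {
  suppressWarnings(association_scan(gt, trait))
}

#' Identify peaks in a per-locus statistic
#'
#' A locus qualifies when its value is beyond the genome-wide empirical
#' quantile (`direction = "high"`: above `threshold_quantile`;
#' `"low"`, for p-values: below `1 - threshold_quantile`). Runs of adjacent
#' qualifying loci on a chromosome merge into a single peak at their
#' extremum, and a peak must be the extremum within `window` loci on either
#' side.
#'
#' @param values Per-locus statistic.
#' @param chrom Chromosome of each locus (loci assumed position-ordered
#'   within chromosome).
#' @param pos 1-based positions matching `values`.
#' @param direction `"high"` or `"low"`.
#' @param threshold_quantile Genome-wide quantile defining outliers
#'   (default 0.99).
#' @param window Half-width (in loci) of the local-extremum check
#'   (default 25).
#' @return A tibble of peaks: `chrom`, `pos`, `value`, and the locus row
#'   `index`.
#' @export
find_peaks <- function(values, chrom, pos, direction = c("high", "low"),
                       threshold_quantile = 0.99, window = 25) {
  direction <- match.arg(direction)
  v <- if (direction == "low") -values else values
  thr <- quantile(v, threshold_quantile, na.rm = TRUE, names = FALSE)
  qual <- !is.na(v) & v > thr
  if (stats::sd(v, na.rm = TRUE) == 0 || !any(qual)) {
    return(tibble(chrom = integer(0), pos = integer(0),
                  value = numeric(0), index = integer(0)))
  }
  idx <- which(qual)
  runs <- split(idx, cumsum(c(1, diff(idx) != 1 | diff(chrom[idx]) != 0)))
  cand <- vapply(runs, function(r) r[which.max(v[r])], integer(1))
  keep <- vapply(cand, function(i) {
    nb <- seq(max(1, i - window), min(length(v), i + window))
    nb <- nb[chrom[nb] == chrom[i]]
    v[i] >= max(v[nb], na.rm = TRUE)
  }, logical(1))
  cand <- sort(cand[keep])
  tibble(chrom = chrom[cand], pos = pos[cand], value = values[cand],
         index = cand)
}

#' Proportion of peaks near true QTLs (and vice versa)
#'
#' @param peaks A tibble from [find_peaks()] (columns `chrom`, `pos`).
#' @param qtl_map A tibble of true QTL positions (columns `chrom`, `pos`).
#' @param window Two-sided detection window in positions (default 50).
#' @return A one-row tibble: `n_peaks`, `n_qtl`, `prop_peaks_near_qtl`
#'   (`NA` when there are no peaks), `prop_qtl_detected`.
#' @export
qtl_detection <- function(peaks, qtl_map, window = 50) {
  near <- function(c1, p1, c2, p2) {
    vapply(seq_along(p1), function(i) {
      any(c2 == c1[i] & abs(p2 - p1[i]) <= window)
    }, logical(1))
  }
  n_peaks <- nrow(peaks)
  n_qtl <- nrow(qtl_map)
  tibble(
    n_peaks = n_peaks, n_qtl = n_qtl,
    prop_peaks_near_qtl = if (n_peaks == 0) NA_real_ else {
      mean(near(peaks$chrom, peaks$pos, qtl_map$chrom, qtl_map$pos))
    },
    prop_qtl_detected = if (n_qtl == 0) NA_real_ else {
      mean(near(qtl_map$chrom, qtl_map$pos, peaks$chrom, peaks$pos))
    }
  )
}

#' Resampling null for a per-locus statistic at non-QTL loci
#'
#' Compares the mean of a statistic over QTL loci against means of repeated
#' draws (without replacement) of equally many non-QTL loci.
#'
#' @param values Per-locus statistic.
#' @param is_qtl Logical QTL flag per locus.
#' @param n_resamples Number of resamples (default 999).
#' @param size Loci per resample (default: the number of QTLs).
#' @return A list with `observed` (QTL mean), `null` (resample means) and
#'   `quantile` (the empirical proportion of resamples at or below the
#'   observed mean).
#' @export
resample_nonqtl <- function(values, is_qtl, n_resamples = 999, size = NULL) {
  pool <- values[!is_qtl]
  if (is.null(size)) size <- sum(is_qtl)
  if (size > length(pool)) {
    abort("resample size exceeds number of non-QTL loci",
          class = "morphsim_error")
  }
  observed <- mean(values[is_qtl])
  null <- vapply(seq_len(n_resamples),
                 function(i) mean(sample(pool, size)), numeric(1))
  list(observed = observed, null = null,
       quantile = mean(null <= observed))
}

#' Welch t-test of a statistic at QTLs versus neutral markers
#'
#' @param stats_tbl A [locus_stats()] tibble.
#' @param stat Column to compare (default `"h_obs"`).
#' @return A one-row tibble with `t`, `df`, `p` and the group means.
#' @export
qtl_vs_neutral_test <- function(stats_tbl, stat = "h_obs") {
  x <- stats_tbl[[stat]][stats_tbl$qtl]
  y <- stats_tbl[[stat]][!stats_tbl$qtl]
  if (length(x) < 2 || length(y) < 2) {
    abort("need at least 2 QTL and 2 non-QTL loci", class = "morphsim_error")
  }
  if (var(x) == 0 && var(y) == 0) {
    warn("degenerate variance in both groups")
    return(tibble(t = NA_real_, df = NA_real_, p = NA_real_,
                  mean_qtl = mean(x), mean_neutral = mean(y)))
  }
  tt <- t.test(x, y)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_qtl = mean(x), mean_neutral = mean(y))
}

#' Random genotype fixture with known group allele frequencies
#'
#' Generates a small diploid genotype table for oracle-testing the
#' statistics: each locus is biallelic (or multi-state when `n_states > 2`)
#' with independent allele draws at the given per-group frequencies.
#'
#' @param n_per_group Integer vector of male sample counts, one per group
#'   (groups are labelled with morph codes in order CP, CN, NP, NN).
#' @param n_loci Number of loci.
#' @param p Matrix (`n_loci x n_groups`) of allele-1 frequencies, or a single
#'   number recycled; ignored when `n_states > 2`, in which case states are
#'   drawn uniformly.
#' @param n_states Number of allele states (default 2).
#' @return A [genotype_table()].
#' @export
random_genotype_table <- function(n_per_group, n_loci, p = 0.5,
                                  n_states = 2) {
  n_groups <- length(n_per_group)
  n <- sum(n_per_group)
  morph <- rep(MORPHS[seq_len(n_groups)], n_per_group)
  if (n_states == 2) {
    if (!is.matrix(p)) p <- matrix(p, n_loci, n_groups)
    cols <- lapply(seq_len(n), function(i) {
      g <- match(morph[i], MORPHS)
      matrix(rbinom(2 * n_loci, 1, rep(p[, g], 2)), ncol = 2)
    })
    geno <- do.call(cbind, cols)
  } else {
    geno <- matrix(sample(0:(n_states - 1), 2 * n * n_loci, replace = TRUE),
                   nrow = n_loci)
  }
  samples <- tibble(id = sprintf("M_%s_%04d", morph, seq_len(n)),
                    sex = "M", morph = morph)
  loci <- tibble(chrom = 1L, pos = seq_len(n_loci),
                 qtl = FALSE, trait = NA_character_)
  genotype_table(geno, samples, loci)
}
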