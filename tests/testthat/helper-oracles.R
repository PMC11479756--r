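# Independent brute-force oracles. These deliberately use naive loops and
# textbook formulas, not the package's vectorized code paths.

# Scalar five-stage ledger for one recurrence step under the sweep's
# baseline assumptions (w_s = 1, w_n = (1,0,1,0), viability 1), enumerating
# each morph explicitly.
oracle_step <- function(f, r_ratio, cc, ns, r_base = 8, n_males = 100) {
  r <- c(CP = r_ratio * r_base, CN = r_ratio * r_base,
         NP = r_base, NN = r_base)
  n <- n_males * f[["CP"]] + n_males * f[["CN"]]
  Ns <- n * cc * ns * r[["NN"]]
  e_o <- c(CP = f[["CP"]] * n_males * r[["CP"]],
           CN = f[["CN"]] * n_males * r[["CN"]], NP = 0, NN = 0)
  e_s <- c(CP = 0, CN = 0,
           NP = min(Ns, f[["NP"]] * n_males * r[["NP"]]),
           NN = min(Ns, f[["NN"]] * n_males * r[["NN"]]))
  o_o <- c(e_o[["CP"]], 0, 0, 0)
  frac <- if (sum(e_o) > 0) sum(o_o) / sum(e_o) else 0
  j <- o_o + e_s * frac
  if (sum(j) <= 0) return(NULL)
  setNames(j / sum(j), c("CP", "CN", "NP", "NN"))
}

# Per-locus statistics by explicit loops over individuals / haplotypes.
oracle_hobs <- function(geno) {
  n <- ncol(geno) / 2
  vapply(seq_len(nrow(geno)), function(l) {
    het <- 0
    for (i in seq_len(n)) {
      if (geno[l, 2 * i - 1] != geno[l, 2 * i]) het <- het + 1
    }
    het / n
  }, numeric(1))
}

oracle_hexp <- function(geno) {
  vapply(seq_len(nrow(geno)), function(l) {
    p <- table(geno[l, ]) / ncol(geno)
    1 - sum(p^2)
  }, numeric(1))
}

oracle_gst <- function(geno, groups) {
  lv <- unique(groups)
  states <- sort(unique(as.vector(geno)))
  vapply(seq_len(nrow(geno)), function(l) {
    hs <- 0
    pbar <- rep(0, length(states))
    for (g in lv) {
      cols <- which(rep(groups, each = 2) == g)
      p <- vapply(states, function(s) mean(geno[l, cols] == s), numeric(1))
      hs <- hs + (1 - sum(p^2)) / length(lv)
      pbar <- pbar + p / length(lv)
    }
    ht <- 1 - sum(pbar^2)
    if (ht > 0) (ht - hs) / ht else 0
  }, numeric(1))
}

# Squared Pearson correlation of major-allele dosages, per pair, by loops.
oracle_r2 <- function(geno, l1, l2) {
  n <- ncol(geno) / 2
  dosage <- function(l) {
    states <- sort(unique(geno[l, ]))
    p <- vapply(states, function(s) mean(geno[l, ] == s), numeric(1))
    major <- states[which.max(p)]
    vapply(seq_len(n), function(i) {
      (geno[l, 2 * i - 1] == major) + (geno[l, 2 * i] == major)
    }, numeric(1))
  }
  cor(dosage(l1), dosage(l2))^2
}

# Tajima's D from the published constants, computing pi as the literal mean
# over all haplotype pairs of their per-site differences.
oracle_tajima <- function(geno) {
  n <- ncol(geno)
  diffs <- 0
  npair <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diffs <- diffs + sum(geno[, i] != geno[, j])
      npair <- npair + 1
    }
  }
  pi <- diffs / npair
  S <- sum(apply(geno, 1, function(x) length(unique(x)) > 1))
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Phenotype of one individual by looping over every QTL copy.
oracle_phenotype <- function(pop, i, trait) {
  arch <- pop$arch
  q <- arch$qtl[arch$qtl$trait == trait, ]
  eff <- arch$effects
  total <- 0
  for (k in seq_len(nrow(q))) {
    row <- (q$chrom[k] - 1) * arch$loci_per_chrom + q$locus[k] + 1
    for (h in c(2 * i - 1, 2 * i)) {
      s <- pop$state[row, h]
      e <- eff$effect[eff$trait == trait & eff$chrom == q$chrom[k] &
                        eff$locus == q$locus[k] & eff$state == s]
      total <- total + e
    }
  }
  total
}

# Small-population helper used across IBM tests.
tiny_sim_setup <- function(seed = 1, architecture = "genome_wide", n = 60,
                           n_chrom = 2, loci = 100, n_qtl = 4, ...) {
  set.seed(seed)
  arch <- genome_architecture(architecture, n_chrom = n_chrom,
                              loci_per_chrom = loci, n_qtl = n_qtl, ...)
  pop <- initialize_thresholds(init_population(arch, n))
  list(arch = arch, pop = pop)
}
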