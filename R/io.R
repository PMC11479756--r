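# Readers/writers: VCF 4.2 export of simulated genotypes (via vcfR), BED
# QTL maps, YAML run configuration and JSON run manifests.
#
# Internal locus coordinates are 0-based; VCF positions are 1-based and BED
# intervals 0-based half-open. Conversions happen only here.

#' Write simulated genotypes to VCF 4.2
#'
#' Variant (segregating) loci only; monomorphic loci are omitted and their
#' count reported. One contig per chromosome (`chr1..chrN`), allele states
#' mapped to placeholder bases in order of frequency-ranked state (REF = the
#' lowest segregating state), `GT` genotypes only, and causal loci flagged
#' with an `INFO` key `QTL=courter|parent`. Sample names encode sex and
#' morph (`M_CP_0001`; females carry `NA` as the morph code).
#'
#' @param gt A [genotype_table()] (e.g. from [as_genotype_table()]).
#' @param path Output path; vcfR appends nothing, but the file is
#'   gzip-compressed, so a `.vcf.gz` name is conventional.
#' @param loci_per_chrom Contig length recorded in the header.
#' @return Invisibly, a list with the number of variant and omitted loci.
#' @export
write_sim_vcf <- function(gt, path, loci_per_chrom = max(gt$loci$pos)) {
  geno <- gt$geno
  n_loci <- nrow(geno)
  states_by_locus <- apply(geno, 1, function(x) sort(unique(x)),
                           simplify = FALSE)
  n_states <- lengths(states_by_locus)
  variant <- which(n_states > 1)
  bases <- c("A", "C", "G", "T", "M", "R", "W", "S") # placeholder alleles
  fix <- matrix(NA_character_, length(variant), 8,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER", "INFO")))
  gtm <- matrix(NA_character_, length(variant), nrow(gt$samples) + 1)
  colnames(gtm) <- c("FORMAT", gt$samples$id)
  h <- hap_pair(gt)
  for (k in seq_along(variant)) {
    l <- variant[k]
    st <- states_by_locus[[l]]
    a <- match(h$a[l, ], st) - 1L
    b <- match(h$b[l, ], st) - 1L
    info <- if (gt$loci$qtl[l]) paste0("QTL=", gt$loci$trait[l]) else "."
    fix[k, ] <- c(paste0("chr", gt$loci$chrom[l]), gt$loci$pos[l], ".",
                  bases[1], paste(bases[1 + seq_len(length(st) - 1)],
                                  collapse = ","),
                  ".", "PASS", info)
    gtm[k, ] <- c("GT", paste0(a, "/", b))
  }
  meta <- c("##fileformat=VCFv4.2",
            "##source=morphsim",
            sprintf("##contig=<ID=chr%d,length=%d>",
                    sort(unique(gt$loci$chrom)), loci_per_chrom),
            paste0("##INFO=<ID=QTL,Number=1,Type=String,",
                   "Description=\"Causal trait of this locus\">"),
            paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                   "Description=\"Genotype\">"))
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = meta, fix = fix, gt = gtm)
  vcfR::write.vcf(v, file = path)
  invisible(list(n_variant = length(variant),
                 n_monomorphic = n_loci - length(variant)))
}

#' Read a simulated-genotype VCF back into a genotype table
#'
#' Parses GT calls into integer allele indices (REF = 0). QTL flags are
#' taken from the `INFO` field or, when `qtl_bed` is given, joined from a
#' BED file (0-based half-open intervals).
#'
#' @param path VCF path (plain or gzipped).
#' @param qtl_bed Optional BED file of true QTL positions.
#' @return A [genotype_table()] of the variant loci.
#' @export
read_sim_vcf <- function(path, qtl_bed = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gtc <- v@gt[, -1, drop = FALSE]
  if (nrow(v@gt) > 0 && !all(v@gt[, "FORMAT"] == "GT")) {
    abort("expected a GT-only FORMAT field", class = "morphsim_io_error")
  }
  split_gt <- function(x) {
    parts <- strsplit(x, "[/|]")
    if (any(lengths(parts) != 2)) {
      abort("malformed or missing GT field", class = "morphsim_io_error")
    }
    m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
    if (anyNA(m)) abort("malformed GT field", class = "morphsim_io_error")
    m
  }
  n_loci <- nrow(fix)
  n_samp <- ncol(gtc)
  geno <- matrix(0L, n_loci, 2 * n_samp)
  for (l in seq_len(n_loci)) {
    m <- split_gt(gtc[l, ])
    geno[l, seq(1, 2 * n_samp, by = 2)] <- m[, 1]
    geno[l, seq(2, 2 * n_samp, by = 2)] <- m[, 2]
  }
  ids <- colnames(gtc)
  parts <- strsplit(ids, "_")
  sex <- vapply(parts, `[`, "", 1)
  morph <- vapply(parts, `[`, "", 2)
  morph[!morph %in% MORPHS] <- NA_character_
  chrom <- as.integer(sub("^chr", "", fix[, "CHROM"]))
  pos <- as.integer(fix[, "POS"])
  info <- fix[, "INFO"]
  trait <- ifelse(grepl("QTL=", info), sub(".*QTL=([a-z]+).*", "\\1", info),
                  NA_character_)
  loci <- tibble(chrom = chrom, pos = pos, qtl = !is.na(trait),
                 trait = trait)
  if (!is.null(qtl_bed)) {
    bed <- read_qtl_bed(qtl_bed)
    key <- paste(loci$chrom, loci$pos)
    bkey <- paste(bed$chrom, bed$pos)
    hit <- match(key, bkey)
    loci$qtl <- !is.na(hit)
    loci$trait <- bed$trait[hit]
  }
  genotype_table(geno, tibble(id = ids, sex = sex, morph = morph), loci)
}

#' Write / read a QTL map as BED
#'
#' BED uses 0-based half-open intervals; a single locus at 1-based position
#' `p` is the interval `[p - 1, p)`. The name column carries the trait.
#'
#' @param arch A [genome_architecture()].
#' @param path Output file.
#' @return `write_qtl_bed()`: the path, invisibly. `read_qtl_bed()`: a
#'   tibble with `chrom`, `pos` (1-based) and `trait`.
#' @export
write_qtl_bed <- function(arch, path) {
  q <- arch$qtl
  utils::write.table(
    data.frame(chrom = paste0("chr", q$chrom), start = q$locus,
               end = q$locus + 1L, name = q$trait),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_qtl_bed
#' @export
read_qtl_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", col.names = c("chrom", "start",
                                                           "end", "trait"))
  tibble(chrom = as.integer(sub("^chr", "", bed$chrom)),
         pos = bed$start + 1L, trait = bed$trait)
}

#' Load a structured run configuration
#'
#' Reads a YAML file whose keys mirror the constructor arguments of
#' [analytic_params()], [sim_params()] and [genome_architecture()] (top-level
#' sections `analytic`, `sim`, `architecture`). Unknown keys and out-of-range
#' values are rejected with a message naming the offending parameter; an
#' empty file yields all defaults with a warning.
#'
#' @param path YAML file.
#' @return A list with elements `analytic`, `sim`, `architecture` (each
#'   `NULL` when its section is absent, except that an empty file returns
#'   default `analytic` and `sim` objects).
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg) || length(cfg) == 0) {
    warn("empty configuration; using all defaults")
    return(list(analytic = analytic_params(), sim = sim_params(),
                architecture = NULL))
  }
  bad <- setdiff(names(cfg), c("analytic", "sim", "architecture"))
  if (length(bad) > 0) {
    abort(paste0("unknown configuration section(s): ",
                 paste(bad, collapse = ", ")), class = "morphsim_config_error")
  }
  build <- function(section, fn) {
    if (is.null(cfg[[section]])) return(NULL)
    args <- cfg[[section]]
    ok <- names(formals(fn))
    bad <- setdiff(names(args), ok)
    if (length(bad) > 0) {
      abort(sprintf("unknown %s parameter(s): %s", section,
                    paste(bad, collapse = ", ")),
            class = "morphsim_config_error")
    }
    for (nm in c("r", "w_n")) {
      if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
    }
    tryCatch(do.call(fn, args), morphsim_error = function(e) {
      abort(sprintf("invalid %s configuration: %s", section,
                    conditionMessage(e)), class = "morphsim_config_error")
    })
  }
  list(analytic = build("analytic", analytic_params),
       sim = build("sim", sim_params),
       architecture = build("architecture", genome_architecture))
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: package version, seeds,
#' parameters, architecture settings, schedule and scale factor.
#'
#' @param path Output JSON file.
#' @param ... Named fields to record.
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, ...) {
  fields <- list(...)
  fields$tool <- "morphsim"
  fields$version <- as.character(utils::packageVersion("morphsim"))
  fields$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Save a simulation run as an artifact directory
#'
#' Writes `summary.csv`, `final_genotypes.vcf.gz`, `qtl_map.bed`,
#' `architecture.json` and `params.json` under `dir`.
#'
#' @param sim A `morph_sim` from [run_simulation()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_run <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  arch <- sim$arch
  jsonlite::write_json(
    list(architecture = arch$architecture, n_chrom = arch$n_chrom,
         loci_per_chrom = arch$loci_per_chrom, n_qtl = arch$n_qtl,
         qtl = arch$qtl, effects = arch$effects,
         supergene = arch$supergene, recomb_rate = arch$recomb_rate,
         mu = arch$mu, sigma_mu = arch$sigma_mu,
         sigma_effect = arch$sigma_effect),
    file.path(dir, "architecture.json"), auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE)
  p <- sim$params
  jsonlite::write_json(
    list(K = p$K, mate_search_n = p$mate_search_n,
         eggs_per_female = p$eggs_per_female, n_sneak = p$n_sneak,
         sperm_comp = p$sperm_comp, r = as.list(p$r), omega_v = p$omega_v,
         theta = p$theta, seed = sim$seed,
         generations = sim$generations_run, extinct = sim$extinct),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE)
  write_qtl_bed(arch, file.path(dir, "qtl_map.bed"))
  if (!is.null(sim$pop)) {
    write_sim_vcf(as_genotype_table(sim$pop),
                  file.path(dir, "final_genotypes.vcf.gz"),
                  loci_per_chrom = arch$loci_per_chrom)
  }
  invisible(dir)
}
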