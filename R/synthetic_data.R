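# Synthetic-data generator with full ground truth: a toy genome with
# masked low-complexity intervals, hidden (unannotated) duplications and
# homeologous blocks; structured populations (three NA aquaculture
# strains with year-classes, wild European fish, European doubled-haploid
# lines); and three emulated caller call sets with configurable
# sensitivity, false positives, genotype error, quality and missingness.
#
# The planted site classes map one-to-one onto the filtering stages:
#   clean_snp / continental_fixed  -> survive the cascade
#   indel                          -> removed as non-SNP (and the source
#                                     of proximity removals)
#   near_indel                     -> removed at the indel-proximity stage
#   masked_snp                     -> removed at the repeat-mask stage
#   deep_repeat                    -> removed at the excess-depth stage
#                                     (placed in *hidden* duplications,
#                                     absent from the BED mask)
#   psv                            -> universal heterozygosity, removed
#                                     at the doubled-haploid stage

#' Default study roster
#'
#' 115 samples mirroring the study cohort: 16 GNB (year-classes 12-13
#' and 15-16), 11 PR (12-13, 13-14), 53 SJR (13-14, 14-15, 15-16,
#' 16-17), 31 wild European, and 4 European doubled-haploid lines.
#'
#' @return sample metadata data.frame
#' @export
default_roster <- function() {
  blocks <- list(
    c("GNB", "12-13", 12), c("GNB", "15-16", 4),
    c("PR", "12-13", 6), c("PR", "13-14", 5),
    c("SJR", "13-14", 14), c("SJR", "14-15", 14),
    c("SJR", "15-16", 12), c("SJR", "16-17", 13))
  rows <- do.call(rbind, lapply(blocks, function(b) {
    n <- as.integer(b[3])
    data.frame(sample_id = sprintf("%s%s-%d", b[1], sub("-.*", "", b[2]),
                                   seq_len(n)),
               strain = b[1], year_class = b[2], continent = "NA",
               is_doubled_haploid = FALSE, stringsAsFactors = FALSE)
  }))
  eu <- data.frame(sample_id = sprintf("EUW-%d", 1:31),
                   strain = "EUR_WILD", year_class = NA_character_,
                   continent = "EU", is_doubled_haploid = FALSE,
                   stringsAsFactors = FALSE)
  dh <- data.frame(sample_id = sprintf("EUDH-%d", 1:4),
                   strain = "EUR_DH", year_class = NA_character_,
                   continent = "EU", is_doubled_haploid = TRUE,
                   stringsAsFactors = FALSE)
  validate_metadata(rbind(rows, eu, dh))
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions at desk scale: three 1 Mb
#' chromosomes, ~20,000 planted sites, the 115-sample study roster,
#' 18.5x mean per-sample coverage, and caller sensitivities ordered as
#' in the study (mpileup most sensitive, then GATK, then freebayes).
#'
#' @param seed RNG seed (mandatory; all stage seeds derive from it)
#' @param n_chromosomes,chrom_length toy genome shape
#' @param repeat_fraction genome fraction covered by masked
#'   low-complexity intervals (exported to BED)
#' @param hidden_dup_fraction genome fraction covered by unannotated
#'   duplications (host deep-repeat sites; absent from the BED)
#' @param homeolog_fraction genome fraction in homeologous blocks (host
#'   PSV sites)
#' @param n_sites named counts per planted site class
#' @param roster sample metadata (default [default_roster()])
#' @param ancestral_beta Beta(a, b) for ancestral allele frequencies
#' @param continent_fst Balding-Nichols divergence of each continent
#'   from the ancestral pool
#' @param strain_fst named per-strain divergence from the NA pool
#'   (GNB and PR drift harder than SJR, echoing their founder history)
#' @param yc_drift divergence of each year-class from its strain pool
#' @param mean_depth,depth_dispersion negative-binomial per-sample read
#'   depth (mean 18.5 as in the study); `deep_mean_depth` for
#'   deep-repeat sites
#' @param psv_depth_factor multiplier on PSV site depths (1 = off)
#' @param sensitivity named per-caller probability of emitting a true
#'   site
#' @param fp_rate per-caller false-positive sites as a fraction of true
#'   sites
#' @param genotype_error per-cell probability of a wrong genotype
#' @param missing_rate per-cell probability of a missing genotype
#' @param frac_low_qual fraction of records drawing QUAL below 30
#' @param ld_copy_prob probability that a site's genotype column copies
#'   its left neighbour (with 5\% per-sample switching) to create LD; 0
#'   disables
#' @return a `sim_config` list
#' @export
sim_config <- function(seed,
                       n_chromosomes = 3, chrom_length = 1e6,
                       repeat_fraction = 0.10,
                       hidden_dup_fraction = 0.03,
                       homeolog_fraction = 0.10,
                       n_sites = c(clean_snp = 15000,
                                   continental_fixed = 500,
                                   psv = 1000, deep_repeat = 500,
                                   indel = 2000, masked_snp = 500,
                                   near_indel = 500),
                       roster = default_roster(),
                       ancestral_beta = c(0.8, 0.8),
                       continent_fst = 0.30,
                       strain_fst = c(GNB = 0.25, PR = 0.25, SJR = 0.08),
                       yc_drift = 0.02,
                       mean_depth = 18.5, depth_dispersion = 8,
                       deep_mean_depth = 60,
                       psv_depth_factor = 1,
                       sensitivity = c(freebayes = 0.90, mpileup = 0.97,
                                       gatk = 0.93),
                       fp_rate = 0.01,
                       genotype_error = 0.002,
                       missing_rate = 0.005,
                       frac_low_qual = 0.03,
                       ld_copy_prob = 0) {
  if (missing(seed)) stop("a seed is mandatory")
  fr <- c(repeat_fraction, hidden_dup_fraction, homeolog_fraction,
          fp_rate, genotype_error, missing_rate, frac_low_qual,
          ld_copy_prob, sensitivity)
  stopifnot(all(fr >= 0), all(fr <= 1), all(n_sites >= 0),
            all(sort(names(sensitivity)) == sort(CALLER_LABELS)))
  as.list(environment())
}

#' Noiseless variant of a simulation configuration
#'
#' Sensitivity 1 for every caller, no false positives, no genotype
#' error, no missingness, and no sub-threshold QUAL draws: every caller
#' reports exactly the truth.
#'
#' @param config a [sim_config()]
#' @return the modified config
#' @export
noiseless <- function(config) {
  config$sensitivity[] <- 1
  config$fp_rate <- 0
  config$genotype_error <- 0
  config$missing_rate <- 0
  config$frac_low_qual <- 0
  config
}

# assign 2 kb genome segments to feature types; coverage of each type is
# approximately its requested fraction
SEGMENT_LEN <- 2000L

#' Simulate the genome layout
#'
#' Tiles each chromosome into 2 kb segments assigned to masked
#' low-complexity repeat, hidden duplication, homeologous block, or
#' unique sequence, then places each site class in its required region:
#' PSVs only inside homeolog blocks, deep-repeat sites only inside
#' hidden duplications, masked SNPs inside the BED mask, everything else
#' in unique sequence. Planted sites sit on a 25 bp grid (near-indel
#' SNPs offset 2-5 bp from their indel), so no two independent sites
#' interact through the 5 bp proximity rule.
#'
#' @param config a [sim_config()]
#' @return list with `chrom_lengths`, `mask` (IntervalSet of the
#'   exported BED), `hidden`, `homeolog` (IntervalSets), and `sites`
#'   (data.frame: chrom, pos, ref, alt, class, and for near-indel sites
#'   the partner indel key)
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  len <- as.integer(config$chrom_length)
  n_seg <- len %/% SEGMENT_LEN
  seg <- list()
  for (ch in chroms) {
    type <- sample(c("mask", "hidden", "homeolog", "free"), n_seg,
                   replace = TRUE,
                   prob = c(config$repeat_fraction,
                            config$hidden_dup_fraction,
                            config$homeolog_fraction,
                            1 - config$repeat_fraction -
                              config$hidden_dup_fraction -
                              config$homeolog_fraction))
    seg[[ch]] <- data.frame(chrom = ch,
                            start0 = (seq_len(n_seg) - 1L) * SEGMENT_LEN,
                            end0 = seq_len(n_seg) * SEGMENT_LEN,
                            type = type, stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, seg)
  iset_of <- function(tp) {
    s <- seg[seg$type == tp, , drop = FALSE]
    interval_set(s$chrom, s$start0, s$end0)
  }
  # candidate grid: every 25 bp, away from segment edges
  cand <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- seq(13L, len - 13L, by = 25L)
    data.frame(chrom = ch, pos = pos,
               type = seg$type[match(paste(ch, (pos - 1L) %/% SEGMENT_LEN),
                                     paste(seg$chrom,
                                           seg$start0 %/% SEGMENT_LEN))],
               stringsAsFactors = FALSE)
  }))
  ns <- config$n_sites
  need <- c(free = sum(ns[c("clean_snp", "continental_fixed", "indel",
                            "near_indel")]),
            mask = unname(ns["masked_snp"]),
            hidden = unname(ns["deep_repeat"]),
            homeolog = unname(ns["psv"]))
  avail <- table(factor(cand$type, levels = c("free", "mask", "hidden",
                                              "homeolog")))
  if (any(need > avail[names(need)])) {
    stop("site counts exceed available genome positions for class(es): ",
         paste(names(need)[need > avail[names(need)]], collapse = ", "))
  }
  take <- function(tp, n) {
    i <- sample(which(cand$type == tp), n)
    out <- cand[i, c("chrom", "pos")]
    cand$type[i] <<- "used"
    out
  }
  bases <- c("A", "C", "G", "T")
  draw_alleles <- function(n) {
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                  character(1))
    data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
  }
  mk <- function(df, class) {
    df$class <- rep(class, nrow(df))
    df$near_key <- rep(NA_character_, nrow(df))
    df
  }
  sites <- list()
  for (cl in c("clean_snp", "continental_fixed")) {
    p <- take("free", ns[[cl]])
    sites[[cl]] <- mk(cbind(p, draw_alleles(nrow(p))), cl)
  }
  p <- take("mask", ns[["masked_snp"]])
  sites$masked_snp <- mk(cbind(p, draw_alleles(nrow(p))), "masked_snp")
  p <- take("hidden", ns[["deep_repeat"]])
  sites$deep_repeat <- mk(cbind(p, draw_alleles(nrow(p))), "deep_repeat")
  p <- take("homeolog", ns[["psv"]])
  sites$psv <- mk(cbind(p, draw_alleles(nrow(p))), "psv")
  # indels: half deletions (2-base ref), half insertions (2-base alt)
  p <- take("free", ns[["indel"]])
  if (nrow(p)) {
    a <- draw_alleles(nrow(p))
    ins <- runif(nrow(p)) < 0.5
    ext <- sample(bases, nrow(p), replace = TRUE)
    a$alt[ins] <- paste0(a$ref[ins], ext[ins])
    a$ref[!ins] <- paste0(a$ref[!ins], ext[!ins])
    a$alt[!ins] <- substr(a$ref[!ins], 1, 1)
    sites$indel <- mk(cbind(p, a), "indel")
  }
  # near-indel SNPs: 2-5 bp right of a planted indel's reference span
  n_near <- ns[["near_indel"]]
  if (n_near > 0) {
    if (is.null(sites$indel) || nrow(sites$indel) < n_near) {
      stop("near_indel sites require at least as many planted indels")
    }
    host <- sites$indel[sample(nrow(sites$indel), n_near), ]
    span_end <- host$pos + nchar(host$ref) - 1L
    np <- data.frame(chrom = host$chrom,
                     pos = span_end + sample(2:5, n_near, replace = TRUE))
    near <- mk(cbind(np, draw_alleles(n_near)), "near_indel")
    near$near_key <- site_key(host$chrom, host$pos, host$ref, host$alt)
    sites$near_indel <- near
  }
  sites <- do.call(rbind, sites)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  if (anyDuplicated(paste(sites$chrom, sites$pos))) {
    stop("internal error: site placement collision")
  }
  rownames(sites) <- NULL
  sites$key <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  list(chrom_lengths = setNames(rep(len, length(chroms)), chroms),
       mask = iset_of("mask"), hidden = iset_of("hidden"),
       homeolog = iset_of("homeolog"), sites = sites)
}

# Balding-Nichols draw of daughter frequencies around p with divergence F
bn_draw <- function(p, f) {
  if (f <= 0) return(p)
  k <- (1 - f) / f
  rbeta(length(p), p * k, (1 - p) * k)
}

#' Simulate population structure and true genotypes
#'
#' Ancestral allele frequencies are Beta-distributed; each continent,
#' strain, and year-class drifts from its parent pool via a
#' Balding-Nichols model. Genotypes are Hardy-Weinberg draws within the
#' terminal group. Doubled-haploid samples are strictly homozygous at
#' every non-PSV site; PSV sites are heterozygous in every sample
#' (the duplication-collapse signature); continental fixed-difference
#' sites carry the alternate allele in all NA fish and the reference in
#' all European fish.
#'
#' @param config a [sim_config()]
#' @param layout result of [simulate_genome()]
#' @return `SimTruth` list: `sites` (with class labels), `geno` (true
#'   genotype-code matrix, sites x samples), `strain_freqs` (per-strain
#'   allele frequencies), `roster`
#' @export
simulate_populations <- function(config, layout) {
  set.seed(config$seed + 1L)
  sites <- layout$sites
  roster <- config$roster
  n <- nrow(sites)
  p0 <- rbeta(n, config$ancestral_beta[1], config$ancestral_beta[2])
  p0 <- pmin(pmax(p0, 0.02), 0.98)
  p_na <- bn_draw(p0, config$continent_fst)
  p_eu <- bn_draw(p0, config$continent_fst)
  strain_freqs <- list(EUR_WILD = p_eu, EUR_DH = p_eu)
  for (st in names(config$strain_fst)) {
    strain_freqs[[st]] <- bn_draw(p_na, config$strain_fst[[st]])
  }
  geno <- matrix(NA_integer_, n, nrow(roster),
                 dimnames = list(sites$key, roster$sample_id))
  groups <- unique(roster[, c("strain", "year_class")])
  for (gi in seq_len(nrow(groups))) {
    st <- groups$strain[gi]; yc <- groups$year_class[gi]
    in_g <- roster$strain == st &
      (is.na(yc) | (!is.na(roster$year_class) & roster$year_class == yc))
    p_g <- if (st %in% c("EUR_WILD", "EUR_DH")) strain_freqs[[st]]
    else bn_draw(strain_freqs[[st]], config$yc_drift)
    for (s in which(in_g)) {
      if (roster$is_doubled_haploid[s]) {
        geno[, s] <- 2L * rbinom(n, 1L, p_g)       # doubled single haploid
      } else {
        geno[, s] <- rbinom(n, 2L, p_g)            # Hardy-Weinberg
      }
    }
  }
  # optional LD: copy the previous site's column with 5% switching
  if (config$ld_copy_prob > 0) {
    for (i in 2:n) {
      if (sites$chrom[i] == sites$chrom[i - 1] &&
          runif(1) < config$ld_copy_prob) {
        sw <- runif(ncol(geno)) < 0.05
        geno[i, !sw] <- geno[i - 1, !sw]
      }
    }
  }
  fixed <- sites$class == "continental_fixed"
  geno[fixed, roster$continent == "NA"] <- 2L
  geno[fixed, roster$continent == "EU"] <- 0L
  geno[sites$class == "psv", ] <- 1L
  list(sites = sites, geno = geno, strain_freqs = strain_freqs,
       roster = roster)
}

# allele depths consistent with a genotype code under the re-calling
# rule (>=2 alt and >=1 ref reads => het, etc.)
consistent_ad <- function(code, depth) {
  n <- length(code)
  ref <- integer(n); alt <- integer(n)
  het <- !is.na(code) & code == 1L
  hr <- !is.na(code) & code == 0L
  ha <- !is.na(code) & code == 2L
  d <- depth
  d[het] <- pmax(d[het], 3L)
  d[hr] <- pmax(d[hr], 1L)
  d[ha] <- pmax(d[ha], 2L)
  if (any(het)) {
    a <- rbinom(sum(het), d[het], 0.5)
    alt[het] <- pmin(pmax(a, 2L), d[het] - 1L)
    ref[het] <- d[het] - alt[het]
  }
  ref[hr] <- d[hr]
  alt[ha] <- d[ha]
  list(ref = ref, alt = alt)
}

#' Emulate the three variant callers
#'
#' Each caller reports each true site with its configured sensitivity,
#' adds false-positive sites at its configured rate, perturbs genotypes
#' at the configured error rate, masks genotypes to missing, draws
#' per-sample negative-binomial depths (deep-repeat sites are scaled so
#' the summed site depth always exceeds 3,000), emits allele depths
#' consistent with the final genotype, and draws QUAL with a configured
#' fraction below 30.
#'
#' @param truth result of [simulate_populations()]
#' @param layout result of [simulate_genome()]
#' @param config a [sim_config()]
#' @return list with `callsets` (named list of three CallSets) and
#'   `fp_keys` (per-caller false-positive site keys)
#' @export
emulate_callers <- function(truth, layout, config) {
  set.seed(config$seed + 2L)
  roster <- truth$roster
  ns <- nrow(roster)
  callsets <- list()
  fp_keys <- list()
  for (caller in CALLER_LABELS) {
    called <- runif(nrow(truth$sites)) <
      config$sensitivity[[caller]]
    sites <- truth$sites[called, , drop = FALSE]
    geno <- truth$geno[called, , drop = FALSE]
    # false positives on fresh positions (offset 7 from the 25 bp grid)
    n_fp <- round(config$fp_rate * nrow(truth$sites))
    if (n_fp > 0) {
      ch <- sample(names(layout$chrom_lengths), n_fp, replace = TRUE)
      pos <- sample(seq(20L, as.integer(layout$chrom_lengths[1]) - 20L,
                        by = 25L), n_fp, replace = (n_fp > 35000)) + 7L
      ref <- sample(c("A", "C", "G", "T"), n_fp, replace = TRUE)
      alt <- vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
      fp <- data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                       class = "false_positive", near_key = NA,
                       key = site_key(ch, pos, ref, alt),
                       stringsAsFactors = FALSE)
      dup <- duplicated(paste(fp$chrom, fp$pos)) |
        paste(fp$chrom, fp$pos) %in% paste(sites$chrom, sites$pos)
      fp <- fp[!dup, , drop = FALSE]
      p_fp <- runif(nrow(fp), 0.05, 0.95)
      g_fp <- matrix(rbinom(nrow(fp) * ns, 2L, rep(p_fp, ns)),
                     nrow = nrow(fp))
      sites <- rbind(sites, fp)
      geno <- rbind(geno, g_fp)
      fp_keys[[caller]] <- fp$key
    } else {
      fp_keys[[caller]] <- character(0)
    }
    nr <- nrow(sites)
    # genotype error then missingness
    if (config$genotype_error > 0) {
      err <- which(matrix(runif(nr * ns) < config$genotype_error, nr))
      if (length(err)) {
        geno[err] <- (geno[err] + sample(1:2, length(err),
                                         replace = TRUE)) %% 3L
      }
    }
    if (config$missing_rate > 0) {
      geno[matrix(runif(nr * ns) < config$missing_rate, nr)] <- NA_integer_
    }
    # per-sample depths; deep-repeat sites draw from the inflated mean
    # and are rescaled if needed so summed depth always exceeds 3,000
    mu <- matrix(config$mean_depth, nr, ns)
    deep <- sites$class == "deep_repeat"
    mu[deep, ] <- config$deep_mean_depth
    if (config$psv_depth_factor != 1) {
      mu[sites$class == "psv", ] <- config$mean_depth *
        config$psv_depth_factor
    }
    depth <- matrix(rnbinom(nr * ns, mu = as.vector(mu),
                            size = config$depth_dispersion), nr, ns)
    depth[is.na(geno)] <- 0L
    if (any(deep)) {
      tot <- rowSums(depth[deep, , drop = FALSE])
      boost <- ceiling(3001 / pmax(tot, 1))
      scale_up <- which(boost > 1)
      if (length(scale_up)) {
        di <- which(deep)[scale_up]
        depth[di, ] <- depth[di, , drop = FALSE] * boost[scale_up]
      }
    }
    ad <- consistent_ad(as.vector(geno), as.vector(depth))
    ad_ref <- matrix(ad$ref, nr, ns)
    ad_alt <- matrix(ad$alt, nr, ns)
    qual <- ifelse(runif(nr) < config$frac_low_qual,
                   runif(nr, 1, 29.9), runif(nr, 30.1, 2000))
    qual <- round(qual, 2)
    site_depth <- rowSums(ad_ref + ad_alt)
    cs_sites <- data.frame(chrom = sites$chrom, pos = sites$pos,
                           ref = sites$ref, alt = sites$alt, qual = qual,
                           site_depth = site_depth,
                           stringsAsFactors = FALSE)
    callsets[[caller]] <- new_callset(caller, cs_sites, geno, ad_ref,
                                      ad_alt, roster)
  }
  list(callsets = callsets, fp_keys = fp_keys)
}

#' True continental fixed differences in a simulated truth set
#'
#' All planted fixed-difference sites are fixed by construction, but
#' ordinary sites can also drift to opposite fixation between the
#' continents; both are genuine diagnostic markers. This returns the
#' site keys whose *true* genotypes are opposite-fixed between the NA
#' group and the given European samples, restricted to site classes
#' that can survive the filtering cascade.
#'
#' @param truth result of [simulate_populations()]
#' @param eu_ids European comparison group (default: wild EU samples)
#' @return character vector of site keys
#' @export
truth_fixed_keys <- function(truth, eu_ids = NULL) {
  ros <- truth$roster
  if (is.null(eu_ids)) {
    eu_ids <- ros$sample_id[ros$continent == "EU" & !ros$is_doubled_haploid]
  }
  na_ids <- ros$sample_id[ros$continent == "NA"]
  survivor <- truth$sites$class %in% c("clean_snp", "continental_fixed")
  fx <- fixed_difference(truth$geno[, na_ids, drop = FALSE],
                         truth$geno[, eu_ids, drop = FALSE])
  truth$sites$key[survivor & fx]
}

#' Generate a complete simulated data set
#'
#' Runs [simulate_genome()], [simulate_populations()] and
#' [emulate_callers()]; optionally persists the three caller VCFs, the
#' repeat-mask BED, the sample metadata and the truth tables to
#' `out_dir`. Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory, or NULL for in-memory only
#' @return list with `layout`, `truth`, `callsets`, `fp_keys`, and (if
#'   written) `paths`
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  layout <- simulate_genome(config)
  truth <- simulate_populations(config, layout)
  emu <- emulate_callers(truth, layout, config)
  out <- list(layout = layout, truth = truth, callsets = emu$callsets,
              fp_keys = emu$fp_keys)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    for (caller in names(emu$callsets)) {
      paths[[caller]] <- file.path(out_dir, paste0(caller, ".vcf"))
      write_vcf(emu$callsets[[caller]], paths[[caller]])
    }
    paths$mask <- file.path(out_dir, "repeats.bed")
    gr <- layout$mask$gr
    writeLines(paste(as.character(GenomicRanges::seqnames(gr)),
                     GenomicRanges::start(gr) - 1L,
                     GenomicRanges::end(gr), sep = "\t"), paths$mask)
    paths$meta <- file.path(out_dir, "samples.tsv")
    write.table(truth$roster, paths$meta, sep = "\t", quote = FALSE,
                row.names = FALSE)
    dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
    paths$truth_sites <- file.path(out_dir, "truth", "sites.tsv")
    write.table(truth$sites, paths$truth_sites, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths$truth_geno <- file.path(out_dir, "truth", "genotypes.tsv")
    write.table(data.frame(key = truth$sites$key, truth$geno,
                           check.names = FALSE),
                paths$truth_geno, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  out
}
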