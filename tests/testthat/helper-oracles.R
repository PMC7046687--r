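# Independent oracles and fixture builders. Everything here is written
# directly from first principles (brute-force scans, naive formula
# transcriptions) and never calls the code paths it checks.

# --- Weir & Cockerham (1984) per-site estimator, naive transcription ---
# Scalar, general-r form written straight from the published moment
# equations; no vectorization and no degenerate-case guards, so it is
# only valid when every population has >= 1 genotype and n_bar > 1.
wc_oracle <- function(groups) {
  r <- length(groups)
  n <- vapply(groups, function(g) sum(!is.na(g)), numeric(1))
  p <- vapply(groups, function(g) mean(g[!is.na(g)]) / 2, numeric(1))
  h <- vapply(groups, function(g) mean(g[!is.na(g)] == 1), numeric(1))
  n_bar <- mean(n)
  n_c <- (r * n_bar - sum(n^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n * p) / (r * n_bar)
  s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n * h) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# --- brute-force genotype re-calling rule, spelled out case by case ---
recall_oracle <- function(ref_depth, alt_depth, min_alt = 2, min_ref = 1) {
  alt_present <- alt_depth >= min_alt
  ref_present <- ref_depth >= min_ref
  if (alt_present && ref_present) return("het")
  if (alt_present && !ref_present) return("hom_alt")
  if (!alt_present && ref_present) return("hom_ref")
  "missing"
}

# --- brute-force per-record filter predicates -------------------------
# Each takes a CallSet and returns the logical keep vector by looping
# over records one at a time.
keep_biallelic_oracle <- function(cs) {
  vapply(seq_len(n_records(cs)), function(i) {
    alts <- strsplit(cs$sites$alt[i], ",")[[1]]
    length(alts) == 1 && nchar(cs$sites$ref[i]) == 1 &&
      nchar(alts) == 1 && !grepl("[<>*]", alts)
  }, logical(1))
}

keep_proximity_oracle <- function(cs, indel_df, distance) {
  vapply(seq_len(n_records(cs)), function(i) {
    p <- cs$sites$pos[i]
    same <- indel_df[indel_df$chrom == cs$sites$chrom[i], , drop = FALSE]
    if (!nrow(same)) return(TRUE)
    gaps <- vapply(seq_len(nrow(same)), function(j) {
      lo <- same$pos[j]
      hi <- same$pos[j] + nchar(same$ref[j]) - 1
      if (p >= lo && p <= hi) 0 else min(abs(p - lo), abs(p - hi))
    }, numeric(1))
    min(gaps) > distance
  }, logical(1))
}

keep_mask_oracle <- function(cs, bed_df) {
  vapply(seq_len(n_records(cs)), function(i) {
    p0 <- cs$sites$pos[i] - 1   # convert 1-based to 0-based
    hit <- any(bed_df$chrom == cs$sites$chrom[i] &
                 p0 >= bed_df$start & p0 < bed_df$end)
    !hit
  }, logical(1))
}

keep_missing_oracle <- function(cs, ids, max_missing) {
  vapply(seq_len(n_records(cs)), function(i) {
    sum(is.na(cs$gt[i, ids])) <= max_missing
  }, logical(1))
}

keep_dh_oracle <- function(cs, dh_ids) {
  vapply(seq_len(n_records(cs)), function(i) {
    g <- cs$gt[i, dh_ids]
    !any(g == 1, na.rm = TRUE)
  }, logical(1))
}

# --- fixture builders -------------------------------------------------
small_roster <- function(n_na = 4, n_eu = 2, n_dh = 2) {
  df <- data.frame(
    sample_id = c(sprintf("NA-%d", seq_len(n_na)),
                  sprintf("EU-%d", seq_len(n_eu)),
                  sprintf("DH-%d", seq_len(n_dh))),
    strain = c(rep("SJR", n_na), rep("EUR_WILD", n_eu),
               rep("EUR_DH", n_dh)),
    year_class = c(rep("15-16", n_na), rep(NA, n_eu + n_dh)),
    continent = c(rep("NA", n_na), rep("EU", n_eu + n_dh)),
    is_doubled_haploid = c(rep(FALSE, n_na + n_eu), rep(TRUE, n_dh)),
    stringsAsFactors = FALSE)
  df
}

# random CallSet with a mix of SNPs, indels and multi-allelic rows
random_callset <- function(n_sites, roster = small_roster(),
                           caller = "freebayes", span = 10000L,
                           p_indel = 0.15, p_multi = 0.05) {
  ns <- nrow(roster)
  pos <- sort(sample.int(span, n_sites))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  kind <- runif(n_sites)
  ins <- kind < p_indel / 2
  del <- kind >= p_indel / 2 & kind < p_indel
  multi <- kind >= p_indel & kind < p_indel + p_multi
  alt[ins] <- paste0(ref[ins], "T")
  ref[del] <- paste0(ref[del], "A")
  alt[del] <- substr(ref[del], 1, 1)
  alt[multi] <- vapply(ref[multi], function(r)
    paste(sample(setdiff(bases, r), 2), collapse = ","), character(1))
  gt <- matrix(sample(c(0:2, NA), n_sites * ns, replace = TRUE,
                      prob = c(0.4, 0.3, 0.25, 0.05)), n_sites, ns)
  ad_ref <- matrix(sample(0:30, n_sites * ns, replace = TRUE), n_sites, ns)
  ad_alt <- matrix(sample(0:30, n_sites * ns, replace = TRUE), n_sites, ns)
  sites <- data.frame(chrom = sample(c("chr1", "chr2"), n_sites,
                                     replace = TRUE),
                      pos = pos,
                      ref = ref, alt = alt,
                      qual = round(runif(n_sites, 0, 100), 2),
                      site_depth = sample(0:5000, n_sites, replace = TRUE),
                      stringsAsFactors = FALSE)
  dup <- duplicated(paste(sites$chrom, sites$pos))
  new_callset(caller, sites[!dup, ], gt[!dup, , drop = FALSE],
              ad_ref[!dup, , drop = FALSE], ad_alt[!dup, , drop = FALSE],
              roster)
}

# GenotypeMatrix straight from raw pieces
gm_from_codes <- function(codes, chrom = NULL, pos = NULL,
                          sample_ids = NULL) {
  n <- nrow(codes)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(ncol(codes)))
  ref <- rep("A", n); alt <- rep("T", n)
  key <- site_key(chrom, pos, ref, alt)
  dimnames(codes) <- list(key, sample_ids)
  structure(list(sites = data.frame(chrom = chrom, pos = pos, ref = ref,
                                    alt = alt, key = key,
                                    stringsAsFactors = FALSE),
                 geno = codes,
                 samples = data.frame(sample_id = sample_ids,
                                      stringsAsFactors = FALSE)),
            class = "GenotypeMatrix")
}

# small simulation config used across tests
test_sim_config <- function(seed, ...) {
  sim_config(seed = seed,
             n_sites = c(clean_snp = 1500, continental_fixed = 80,
                         psv = 150, deep_repeat = 80, indel = 250,
                         masked_snp = 80, near_indel = 80),
             ...)
}
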