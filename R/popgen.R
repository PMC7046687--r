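# Population-genetic summaries over the consensus genotype matrix:
# minor-allele-frequency spectra, per-strain polymorphism tables,
# per-site Weir-Cockerham Fst, and the tiered continent-diagnostic panel.

#' Extract the genotype matrix from a CallSet
#'
#' @param callset a CallSet (genotypes normally re-called by the cascade)
#' @return object of class `GenotypeMatrix`: a site table plus a
#'   sites x samples integer matrix of codes 0 (hom ref), 1 (het),
#'   2 (hom alt), NA (missing)
#' @export
genotype_matrix <- function(callset) {
  structure(list(sites = callset$sites[, c("chrom", "pos", "ref", "alt",
                                           "key")],
                 geno = callset$gt, samples = callset$samples),
            class = "GenotypeMatrix")
}

#' @exportS3Method base::print
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", nrow(x$geno), "sites x", ncol(x$geno),
      "samples\n")
  invisible(x)
}

subset_gm <- function(gm, keep_sites) {
  gm$sites <- gm$sites[keep_sites, , drop = FALSE]
  rownames(gm$sites) <- NULL
  gm$geno <- gm$geno[keep_sites, , drop = FALSE]
  gm
}

#' Minor allele frequency of one site
#'
#' @param genotypes genotype codes (0/1/2/NA) over a subgroup
#' @return MAF in \[0, 0.5\], or NA when all genotypes are missing
#' @export
minor_allele_freq <- function(genotypes) {
  n <- sum(!is.na(genotypes))
  if (n == 0L) return(NA_real_)
  p <- sum(genotypes, na.rm = TRUE) / (2 * n)
  min(p, 1 - p)
}

# vectorized over the rows of a code matrix
site_maf <- function(g) {
  n <- rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / (2 * n)
  out <- pmin(p, 1 - p)
  out[n == 0L] <- NA_real_
  out
}

site_het <- function(g) {
  n <- rowSums(!is.na(g))
  out <- rowSums(g == 1L, na.rm = TRUE) / n
  out[n == 0L] <- NA_real_
  out
}

#' Is a site polymorphic within a subgroup?
#' @param genotypes genotype codes over the subgroup
#' @return TRUE iff both alleles are observed among non-missing
#'   genotypes (a single heterozygote suffices)
#' @export
is_polymorphic <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (!length(g)) return(FALSE)
  # ref allele observed iff any code < 2; alt allele iff any code > 0
  any(g < 2L) && any(g > 0L)
}

site_polymorphic <- function(g) {
  n <- rowSums(!is.na(g))
  ac <- rowSums(g, na.rm = TRUE)
  n > 0L & ac > 0L & ac < 2L * n
}

#' Observed heterozygosity of one site
#' @param genotypes genotype codes over the subgroup
#' @return proportion of heterozygous calls among non-missing ones; NA
#'   when all are missing
#' @export
observed_het <- function(genotypes) {
  n <- sum(!is.na(genotypes))
  if (n == 0L) return(NA_real_)
  sum(genotypes == 1L, na.rm = TRUE) / n
}

#' Minor-allele-frequency spectrum
#'
#' Histogram of per-site MAF over a subgroup, with the count and
#' fraction of sites at or above the high-MAF threshold (0.25 by
#' default, the class highlighted in the study).
#'
#' @param gm a [genotype_matrix()]
#' @param sample_ids subgroup columns (default: all samples)
#' @param bin_width histogram bin width over \[0, 0.5\], right-closed
#' @param high_maf threshold for the high-MAF class
#' @return data.frame of bins and counts, with attributes
#'   `n_high_maf`, `frac_high_maf`, and `n_sites` (sites with at least
#'   one non-missing genotype; others are excluded)
#' @export
maf_spectrum <- function(gm, sample_ids = NULL, bin_width = 0.025,
                         high_maf = 0.25) {
  if (is.null(sample_ids)) sample_ids <- colnames(gm$geno)
  maf <- site_maf(gm$geno[, sample_ids, drop = FALSE])
  maf <- maf[!is.na(maf)]
  breaks <- seq(0, 0.5, by = bin_width)
  counts <- as.integer(table(cut(maf, breaks, include.lowest = TRUE,
                                 right = TRUE)))
  out <- data.frame(bin_low = breaks[-length(breaks)],
                    bin_high = breaks[-1], count = counts)
  attr(out, "n_sites") <- length(maf)
  attr(out, "n_high_maf") <- sum(maf >= high_maf)
  attr(out, "frac_high_maf") <- if (length(maf))
    sum(maf >= high_maf) / length(maf) else NA_real_
  out
}

summary_row <- function(g, label, n_fish) {
  evaluable <- rowSums(!is.na(g)) > 0L
  poly <- site_polymorphic(g)
  gp <- g[poly, , drop = FALSE]
  data.frame(population = label, n_fish = n_fish,
             n_snp = sum(evaluable), n_polymorphic = sum(poly),
             pct_polymorphic = if (sum(evaluable)) sum(poly) /
               sum(evaluable) else NA_real_,
             avg_maf = if (sum(poly)) mean(site_maf(gp)) else NA_real_,
             avg_het = if (sum(poly)) mean(site_het(gp)) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Per-strain and per-year-class polymorphism summary
#'
#' One row per aquaculture strain and per year-class within strain:
#' number of fish, sites evaluable in the group (at least one
#' non-missing genotype), number and fraction polymorphic, and average
#' MAF and observed heterozygosity over the group's polymorphic sites
#' only.
#'
#' @param gm a [genotype_matrix()]
#' @param meta sample metadata; strains with continent `"NA"` are
#'   summarized
#' @return data.frame with one row per group
#' @export
strain_summary <- function(gm, meta = gm$samples) {
  meta <- meta[meta$continent == "NA", , drop = FALSE]
  if (!all(meta$sample_id %in% colnames(gm$geno))) {
    stop("metadata names samples absent from the genotype matrix")
  }
  rows <- list()
  for (st in unique(meta$strain)) {
    ids <- meta$sample_id[meta$strain == st]
    rows <- c(rows, list(summary_row(gm$geno[, ids, drop = FALSE], st,
                                     length(ids))))
    ycs <- meta$year_class[meta$strain == st]
    for (yc in unique(ycs[!is.na(ycs)])) {
      ids <- meta$sample_id[meta$strain == st & !is.na(meta$year_class) &
                              meta$year_class == yc]
      rows <- c(rows, list(summary_row(gm$geno[, ids, drop = FALSE],
                                       paste0(st, "_YC", yc),
                                       length(ids))))
    }
  }
  do.call(rbind, rows)
}

# guarded product: a bracket that is exactly zero annihilates its
# (possibly infinite) multiplier — needed for the n_bar = 1 limit, where
# the fixed-difference brackets vanish identically
zero_prod <- function(mult, term) {
  out <- mult * term
  out[term == 0] <- 0
  out
}

#' Per-site Weir-Cockerham Fst between two groups
#'
#' The Weir & Cockerham (1984) two-population moment estimator with the
#' observed-heterozygosity correction (the formulation used by vcftools'
#' per-site mode): variance components a (among populations), b (among
#' individuals within populations), c (within individuals), and
#' Fst = a / (a + b + c). Missing genotypes are excluded from allele
#' counts. A fixed difference (all non-missing genotypes in one group
#' one homozygote class, the other group the opposite class) yields
#' exactly 1 for any group sizes >= 1.
#'
#' @param g1,g2 genotype codes for the two groups at one site
#' @return list with `a`, `b`, `c`, `fst` (fst is NA when a+b+c = 0 or a
#'   group has no non-missing genotype)
#' @export
wc_fst <- function(g1, g2) {
  comp <- wc_components(matrix(g1, nrow = 1), matrix(g2, nrow = 1))
  lapply(comp, `[`, 1L)
}

# vectorized over sites: G1, G2 are sites x samples code matrices
wc_components <- function(G1, G2) {
  n1 <- rowSums(!is.na(G1)); n2 <- rowSums(!is.na(G2))
  p1 <- rowSums(G1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(G2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(G1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(G2 == 1L, na.rm = TRUE) / n2
  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  pq <- p_bar * (1 - p_bar)
  inner_a <- s2 - zero_prod(1 / (n_bar - 1),
                            pq - s2 * (r - 1) / r - h_bar / 4)
  a <- (n_bar / n_c) * inner_a
  b <- zero_prod(n_bar / (n_bar - 1),
                 pq - s2 * (r - 1) / r -
                   h_bar * (2 * n_bar - 1) / (4 * n_bar))
  cc <- h_bar / 2
  denom <- a + b + cc
  fst <- a / denom
  bad <- n1 == 0L | n2 == 0L | denom == 0 | !is.finite(denom)
  fst[bad] <- NA_real_
  a[n1 == 0L | n2 == 0L] <- NA_real_
  list(a = a, b = b, c = cc, fst = fst)
}

#' Per-site Fst across a genotype matrix
#' @param gm a [genotype_matrix()]
#' @param ids1,ids2 sample ids of the two groups (disjoint)
#' @return numeric vector of per-site Fst (NA where undefined)
#' @export
fst_sites <- function(gm, ids1, ids2) {
  if (length(intersect(ids1, ids2))) stop("groups overlap")
  wc_components(gm$geno[, ids1, drop = FALSE],
                gm$geno[, ids2, drop = FALSE])$fst
}

# exact fixed-difference test: every non-missing genotype in one group
# is one homozygote class and every non-missing genotype in the other is
# the opposite class (the combinatorial condition equivalent to Fst = 1)
fixed_difference <- function(G1, G2) {
  n1 <- rowSums(!is.na(G1)); n2 <- rowSums(!is.na(G2))
  ac1 <- rowSums(G1, na.rm = TRUE); ac2 <- rowSums(G2, na.rm = TRUE)
  het1 <- rowSums(G1 == 1L, na.rm = TRUE)
  het2 <- rowSums(G2 == 1L, na.rm = TRUE)
  mono1_ref <- het1 == 0L & ac1 == 0L
  mono1_alt <- het1 == 0L & ac1 == 2L * n1
  mono2_ref <- het2 == 0L & ac2 == 0L
  mono2_alt <- het2 == 0L & ac2 == 2L * n2
  n1 > 0L & n2 > 0L &
    ((mono1_ref & mono2_alt) | (mono1_alt & mono2_ref))
}

#' Select continent-diagnostic fixed-difference markers
#'
#' A candidate diagnostic site is fixed for opposite homozygous
#' genotypes between the North American and European groups (the exact
#' combinatorial condition equivalent to Fst = 1, asserted on allele
#' counts rather than floating-point equality) in at least one caller's
#' filtered call set. High-confidence sites meet the condition in all
#' three callers and are present in all three filtered sets.
#'
#' @param matrices named list of three [genotype_matrix()] objects, one
#'   per caller's filtered call set
#' @param na_ids,eu_ids sample ids of the two continental groups
#'   (disjoint)
#' @return data.frame: site key fields, each group's homozygote class,
#'   per-caller Fst columns (`fst_<caller>`, NA where the caller lacks
#'   the site), and `tier` (`high_confidence` or `candidate`)
#' @export
select_diagnostic <- function(matrices, na_ids, eu_ids) {
  if (length(intersect(na_ids, eu_ids))) stop("groups overlap")
  callers <- sort(names(matrices))
  stopifnot(length(callers) == 3L)
  per <- lapply(matrices[callers], function(gm) {
    G1 <- gm$geno[, na_ids, drop = FALSE]
    G2 <- gm$geno[, eu_ids, drop = FALSE]
    data.frame(key = gm$sites$key, chrom = gm$sites$chrom,
               pos = gm$sites$pos, ref = gm$sites$ref, alt = gm$sites$alt,
               fixed = fixed_difference(G1, G2),
               fst = wc_components(G1, G2)$fst,
               na_alt = rowSums(G1, na.rm = TRUE) > 0L,
               stringsAsFactors = FALSE)
  })
  all_keys <- unique(unlist(lapply(per, `[[`, "key"), use.names = FALSE))
  fixed_any <- rep(FALSE, length(all_keys))
  fixed_all <- rep(TRUE, length(all_keys))
  present_all <- rep(TRUE, length(all_keys))
  fst_cols <- list()
  for (cl in callers) {
    i <- match(all_keys, per[[cl]]$key)
    f <- per[[cl]]$fixed[i]
    fixed_any <- fixed_any | (!is.na(f) & f)
    fixed_all <- fixed_all & !is.na(f) & f
    present_all <- present_all & !is.na(i)
    fst_cols[[paste0("fst_", cl)]] <- per[[cl]]$fst[i]
  }
  cand <- fixed_any
  if (!any(cand)) {
    return(data.frame(key = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), na_genotype = character(0),
                      eu_genotype = character(0),
                      fst_freebayes = numeric(0), fst_gatk = numeric(0),
                      fst_mpileup = numeric(0), tier = character(0)))
  }
  # genotype classes from the first caller that carries the site
  first_i <- lapply(per, function(p) match(all_keys, p$key))
  na_alt <- rep(NA, length(all_keys))
  chrom <- pos <- ref <- alt <- rep(NA, length(all_keys))
  for (cl in callers) {
    i <- first_i[[cl]]
    take <- is.na(na_alt) & !is.na(i)
    na_alt[take] <- per[[cl]]$na_alt[i[take]]
    chrom[take] <- per[[cl]]$chrom[i[take]]
    pos[take] <- per[[cl]]$pos[i[take]]
    ref[take] <- per[[cl]]$ref[i[take]]
    alt[take] <- per[[cl]]$alt[i[take]]
  }
  out <- data.frame(key = all_keys, chrom = chrom, pos = as.integer(pos),
                    ref = ref, alt = alt,
                    na_genotype = ifelse(na_alt, "hom_alt", "hom_ref"),
                    eu_genotype = ifelse(na_alt, "hom_ref", "hom_alt"),
                    stringsAsFactors = FALSE)
  for (nm in names(fst_cols)) out[[nm]] <- fst_cols[[nm]]
  out$tier <- ifelse(fixed_all & present_all, "high_confidence",
                     "candidate")
  out <- out[cand, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
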