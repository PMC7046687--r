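# The six-step SNP filtering cascade and the three-caller consensus.
#
# Every stage is a pure set filter over a CallSet (output is a subset of
# the input, idempotent, invariant to record order) and returns the
# filtered CallSet together with a one-row stage report.

#' Filtering thresholds
#'
#' Defaults reproduce the study's stated rules: bi-allelic SNPs not
#' within 5 bases of an indel, QUAL strictly greater than 30, site depth
#' at most 3,000 reads summed over samples, at most one North American
#' sample with a missing genotype after re-calling, and genotype
#' re-calling requiring at least 2 alternate-supporting and 1
#' reference-supporting read.
#'
#' @param indel_distance maximum base gap to an indel's reference span
#'   that disqualifies a SNP
#' @param min_qual phred QUAL threshold (kept if strictly greater)
#' @param max_site_depth maximum summed read depth at a site (inclusive)
#' @param max_missing_samples maximum missing genotypes tolerated in the
#'   evaluation roster
#' @param min_alt_reads,min_ref_reads read-support thresholds for the
#'   genotype re-calling rule
#' @return a `filter_config` list
#' @export
filter_config <- function(indel_distance = 5, min_qual = 30,
                          max_site_depth = 3000, max_missing_samples = 1,
                          min_alt_reads = 2, min_ref_reads = 1) {
  cfg <- list(indel_distance = indel_distance, min_qual = min_qual,
              max_site_depth = max_site_depth,
              max_missing_samples = max_missing_samples,
              min_alt_reads = min_alt_reads, min_ref_reads = min_ref_reads)
  if (any(unlist(cfg) < 0)) stop("filter_config values must be non-negative")
  cfg
}

stage_result <- function(callset, keep, stage) {
  n_in <- length(keep)
  rep <- data.frame(stage = stage, records_in = n_in,
                    records_removed = sum(!keep),
                    records_out = sum(keep), stringsAsFactors = FALSE)
  list(callset = subset_callset(callset, keep), report = rep)
}

#' Keep bi-allelic SNPs
#'
#' Retains records whose reference and single alternate allele are both
#' one base; indels, multi-allelic rows, and symbolic alleles drop.
#'
#' @param callset a CallSet
#' @return list with elements `callset` and `report`
#' @export
filter_biallelic_snp <- function(callset) {
  keep <- callset$sites$variant_class == "snp" & callset$sites$n_alt == 1L
  stage_result(callset, keep, "biallelic_snp")
}

# reference span of an indel record: [pos, pos + nchar(ref) - 1]
indel_spans <- function(indels) {
  data.frame(chrom = indels$chrom, start = indels$pos,
             end = indels$pos + nchar(indels$ref) - 1L,
             stringsAsFactors = FALSE)
}

#' Remove SNPs close to indels
#'
#' A record at position p is removed when the gap between p and the
#' nearest indel reference span on the same chromosome is at most
#' `distance` bases (a SNP inside the span has gap 0). Indels are drawn
#' from the same caller's unfiltered call set.
#'
#' @param callset a CallSet (normally already bi-allelic SNPs)
#' @param indels data.frame with columns chrom, pos, ref (e.g. the
#'   `sites` table of the unfiltered CallSet restricted to indels), or a
#'   CallSet whose indel records will be used
#' @param distance maximum disqualifying gap in bases
#' @return list with elements `callset` and `report`
#' @export
filter_indel_proximity <- function(callset, indels, distance = 5) {
  if (distance < 0) stop("indel distance must be non-negative")
  if (inherits(indels, "CallSet")) {
    indels <- indels$sites[indels$sites$variant_class == "indel", ,
                           drop = FALSE]
  }
  if (nrow(indels) == 0L || n_records(callset) == 0L) {
    return(stage_result(callset, rep(TRUE, n_records(callset)),
                        "indel_proximity"))
  }
  sp <- indel_spans(indels)
  grown <- GenomicRanges::GRanges(
    sp$chrom, IRanges::IRanges(pmax(1L, sp$start - as.integer(distance)),
                               sp$end + as.integer(distance)))
  q <- GenomicRanges::GRanges(callset$sites$chrom,
                              IRanges::IRanges(callset$sites$pos,
                                               callset$sites$pos))
  keep <- GenomicRanges::countOverlaps(q, grown) == 0L
  stage_result(callset, keep, "indel_proximity")
}

#' Keep records with QUAL strictly above a threshold
#' @param callset a CallSet
#' @param min_qual phred threshold; records with `qual > min_qual` pass
#' @return list with elements `callset` and `report`
#' @export
filter_qual <- function(callset, min_qual = 30) {
  stage_result(callset, callset$sites$qual > min_qual, "qual")
}

#' Remove records inside a repeat mask
#' @param callset a CallSet
#' @param mask an [interval_set()], e.g. RepeatMasker low-complexity
#'   intervals loaded with [read_intervals()]
#' @return list with elements `callset` and `report`
#' @export
mask_repeats <- function(callset, mask) {
  inside <- in_intervals(mask, callset$sites$chrom, callset$sites$pos)
  stage_result(callset, !inside, "repeat_mask")
}

#' Remove records with excess summed read depth
#'
#' Sites covered by more reads than expected under unique mapping are
#' likely repeat or duplication artifacts; records with site depth
#' strictly greater than `max_site_depth` are removed.
#'
#' @param callset a CallSet
#' @param max_site_depth inclusive depth ceiling
#' @return list with elements `callset` and `report`
#' @export
filter_depth <- function(callset, max_site_depth = 3000) {
  stage_result(callset, callset$sites$site_depth <= max_site_depth, "depth")
}

#' Re-call a genotype from allele read depths
#'
#' The alternate allele is considered present when supported by at least
#' `min_alt_reads` reads, the reference allele when supported by at
#' least `min_ref_reads`. Both present gives `het`, only alternate
#' `hom_alt`, only reference `hom_ref`, neither `missing`.
#'
#' @param ref_depth,alt_depth non-negative read counts (vectorized)
#' @param config a [filter_config()]
#' @return character vector of calls in
#'   `hom_ref`/`het`/`hom_alt`/`missing`
#' @export
recall_genotype <- function(ref_depth, alt_depth, config = filter_config()) {
  code <- recall_code(ref_depth, alt_depth, config)
  out <- c("hom_ref", "het", "hom_alt")[code + 1L]
  out[is.na(out)] <- "missing"
  out
}

# integer-code version used on matrices
recall_code <- function(ref_depth, alt_depth, config = filter_config()) {
  stopifnot(all(ref_depth >= 0, na.rm = TRUE),
            all(alt_depth >= 0, na.rm = TRUE))
  ref_in <- ref_depth >= config$min_ref_reads
  alt_in <- alt_depth >= config$min_alt_reads
  out <- rep(NA_integer_, length(ref_in))
  out[ref_in & alt_in] <- 1L
  out[ref_in & !alt_in] <- 0L
  out[!ref_in & alt_in] <- 2L
  out
}

#' Replace a CallSet's genotypes by depth-based re-calls
#' @param callset a CallSet with AD matrices
#' @param config a [filter_config()]
#' @return the CallSet with its genotype matrix re-called
#' @export
apply_recall <- function(callset, config = filter_config()) {
  g <- recall_code(callset$ad_ref, callset$ad_alt, config)
  callset$gt <- matrix(g, nrow = nrow(callset$ad_ref),
                       dimnames = dimnames(callset$ad_ref))
  callset
}

#' Remove records with too many missing genotypes
#'
#' Missingness is counted over `subset_ids` (by default the North
#' American roster, matching the requirement that genotypes be available
#' for at least 79 of the 80 NA fish); genotypes are expected to have
#' been re-called first (see [apply_recall()]).
#'
#' @param callset a CallSet
#' @param max_missing_samples maximum tolerated missing calls
#' @param subset_ids sample ids over which to count (default: samples
#'   with continent `"NA"`)
#' @return list with elements `callset` and `report`
#' @export
filter_missingness <- function(callset, max_missing_samples = 1,
                               subset_ids = NULL) {
  if (is.null(subset_ids)) {
    subset_ids <- callset$samples$sample_id[callset$samples$continent == "NA"]
  }
  if (length(subset_ids) == 0L) stop("missingness roster subset is empty")
  g <- callset$gt[, subset_ids, drop = FALSE]
  n_missing <- rowSums(is.na(g))
  stage_result(callset, n_missing <= max_missing_samples, "missingness")
}

#' Remove sites heterozygous in any doubled-haploid line
#'
#' A doubled haploid is homozygous at every true locus, so a
#' heterozygous DH call flags a paralogous sequence variant (PSV) or
#' similar duplication artifact. Missing DH genotypes do not trigger
#' removal.
#'
#' @param callset a CallSet
#' @param dh_ids doubled-haploid sample ids (default: roster flag)
#' @return list with elements `callset` and `report`
#' @export
filter_dh_het <- function(callset, dh_ids = NULL) {
  if (is.null(dh_ids)) {
    dh_ids <- callset$samples$sample_id[callset$samples$is_doubled_haploid]
  }
  if (length(dh_ids) == 0L) {
    warning("no doubled-haploid samples; DH het stage is a pass-through")
    return(stage_result(callset, rep(TRUE, n_records(callset)), "dh_het"))
  }
  g <- callset$gt[, dh_ids, drop = FALSE]
  any_het <- rowSums(g == 1L, na.rm = TRUE) > 0L
  stage_result(callset, !any_het, "dh_het")
}

#' Run the full filtering cascade on one caller's call set
#'
#' Applies, in the study's narrated order: bi-allelic SNP extraction,
#' indel proximity, QUAL, repeat mask, excess depth, genotype re-calling
#' with the missingness cap, and the doubled-haploid heterozygosity
#' screen. All stages are site-local predicates, so the final set is
#' order-independent; the report preserves the narrated order.
#'
#' @param callset a CallSet
#' @param mask an [interval_set()] repeat mask (NULL for no mask)
#' @param indels indel table or CallSet for the proximity stage
#'   (default: the input call set's own indel records)
#' @param config a [filter_config()]
#' @param missing_subset_ids roster subset for the missingness count
#' @param dh_ids doubled-haploid sample ids
#' @return list with `callset` (filtered, sorted) and `report` (one row
#'   per stage; `records_in - records_removed = records_out` throughout)
#' @export
run_cascade <- function(callset, mask = NULL, indels = callset,
                        config = filter_config(),
                        missing_subset_ids = NULL, dh_ids = NULL) {
  if (is.null(mask)) mask <- interval_set(character(0), integer(0),
                                          integer(0))
  steps <- list()
  s <- filter_biallelic_snp(callset); steps <- c(steps, list(s$report))
  s <- filter_indel_proximity(s$callset, indels, config$indel_distance)
  steps <- c(steps, list(s$report))
  s <- filter_qual(s$callset, config$min_qual)
  steps <- c(steps, list(s$report))
  s <- mask_repeats(s$callset, mask)
  steps <- c(steps, list(s$report))
  s <- filter_depth(s$callset, config$max_site_depth)
  steps <- c(steps, list(s$report))
  cs <- apply_recall(s$callset, config)
  s <- filter_missingness(cs, config$max_missing_samples,
                          missing_subset_ids)
  steps <- c(steps, list(s$report))
  s <- filter_dh_het(s$callset, dh_ids)
  steps <- c(steps, list(s$report))
  list(callset = s$callset, report = do.call(rbind, steps))
}

#' Intersect three filtered call sets
#'
#' The consensus set contains the records whose site key (chrom, pos,
#' ref, alt) occurs in all three callers' filtered sets. Genotypes are
#' taken from a designated reference caller (default: first caller label
#' alphabetically); genotype discordance against the other callers is
#' counted but not reconciled. Venn counts for all 7 regions of the
#' three-set diagram are returned and sum to the union size.
#'
#' @param callsets list of exactly three CallSets with identical rosters
#' @param reference_caller caller whose genotypes populate the consensus
#' @return list with `callset` (the consensus), `venn` (named counts for
#'   the 7 regions), and `discordant_genotypes` (count of consensus
#'   cells where callers disagree)
#' @export
consensus_intersect <- function(callsets, reference_caller = NULL) {
  if (length(callsets) != 3L) stop("exactly three call sets are required")
  labels <- vapply(callsets, function(x) x$caller, character(1))
  if (anyDuplicated(labels)) stop("caller labels must be distinct")
  names(callsets) <- labels
  rosters <- lapply(callsets, function(x) x$samples$sample_id)
  if (!all(vapply(rosters[-1], identical, logical(1), rosters[[1]]))) {
    stop("sample rosters differ across call sets")
  }
  ord <- sort(labels)
  keys <- lapply(callsets[ord], function(x) x$sites$key)
  u <- unique(unlist(keys, use.names = FALSE))
  member <- vapply(keys, function(k) u %in% k,
                   logical(length(u)))
  member <- matrix(member, ncol = 3L, dimnames = list(NULL, ord))
  region <- apply(member, 1L, function(m) paste(ord[m], collapse = "_"))
  region_names <- c(ord,
                    paste(ord[1], ord[2], sep = "_"),
                    paste(ord[1], ord[3], sep = "_"),
                    paste(ord[2], ord[3], sep = "_"),
                    paste(ord, collapse = "_"))
  venn <- setNames(integer(7L), c(paste0(ord, "_only"),
                                  region_names[4:7]))
  tab <- table(region)
  lab <- c(setNames(paste0(ord, "_only"), ord),
           setNames(region_names[4:7], region_names[4:7]))
  for (r in names(tab)) venn[lab[[r]]] <- as.integer(tab[[r]])
  if (is.null(reference_caller)) reference_caller <- ord[1]
  ref <- callsets[[reference_caller]]
  shared_keys <- u[rowSums(member) == 3L]
  shared <- subset_callset(ref, ref$sites$key %in% shared_keys)
  discord <- 0L
  for (other in setdiff(labels, reference_caller)) {
    og <- callsets[[other]]
    m <- og$sites$key %in% shared_keys
    discord <- discord +
      sum(og$gt[m, , drop = FALSE][order(og$sites$key[m]), , drop = FALSE] !=
            shared$gt[order(shared$sites$key), , drop = FALSE],
          na.rm = TRUE)
  }
  list(callset = shared, venn = venn, discordant_genotypes = discord)
}
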