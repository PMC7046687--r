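# Reading/writing the standard formats (VCF, BED, sample metadata) and the
# internal CallSet / IntervalSet containers shared by every downstream stage.

VALID_STRAINS <- c("GNB", "PR", "SJR", "EUR_WILD", "EUR_DH")
CALLER_LABELS <- c("freebayes", "mpileup", "gatk")

#' Site keys
#'
#' A site key is the cross-caller identity of a variant record:
#' `chrom:pos:ref:alt`. Two records from different callers refer to the
#' same site if and only if their keys are equal.
#'
#' @param chrom chromosome name
#' @param pos 1-based position
#' @param ref reference allele
#' @param alt alternate allele (comma-joined if multi-allelic)
#' @return character vector of keys
#' @export
site_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# total order over sites: chrom, pos, ref, alt
site_order <- function(sites) {
  order(sites$chrom, sites$pos, sites$ref, sites$alt, method = "radix")
}

classify_variant <- function(ref, alt) {
  alts <- strsplit(alt, ",", fixed = TRUE)
  vapply(seq_along(ref), function(i) {
    a <- alts[[i]]
    if (any(grepl("[<>*\\[\\]]", a))) return("other")
    if (nchar(ref[i]) == 1L && all(nchar(a) == 1L)) "snp" else "indel"
  }, character(1))
}

#' Construct a CallSet
#'
#' A CallSet is one caller's collection of variant records over a fixed
#' sample roster: a site table (chrom, pos, ref, alt, qual, site_depth,
#' variant class) plus aligned genotype-code and allele-depth matrices.
#' Genotype codes are 0 = hom ref, 1 = het, 2 = hom alt, NA = missing.
#'
#' @param caller caller label, one of `freebayes`, `mpileup`, `gatk`
#' @param sites data.frame with columns chrom, pos, ref, alt, qual,
#'   site_depth (and optionally variant_class, n_alt, key; recomputed if
#'   absent)
#' @param gt integer matrix, sites x samples, codes in 0/1/2/NA
#' @param ad_ref,ad_alt integer matrices of per-sample reference / first
#'   alternate allele read depths, same shape as `gt`
#' @param samples sample metadata data.frame (see [read_metadata()])
#' @return object of class `CallSet`, records sorted by site key
#' @export
new_callset <- function(caller, sites, gt, ad_ref, ad_alt, samples) {
  stopifnot(is.data.frame(sites), is.data.frame(samples))
  caller <- match.arg(caller, CALLER_LABELS)
  n <- nrow(sites)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n)
  stopifnot(nrow(gt) == n, nrow(ad_ref) == n, nrow(ad_alt) == n,
            ncol(gt) == nrow(samples))
  sites$pos <- as.integer(sites$pos)
  if (is.null(sites$n_alt)) {
    sites$n_alt <- lengths(strsplit(sites$alt, ",", fixed = TRUE))
  }
  if (is.null(sites$variant_class)) {
    sites$variant_class <- classify_variant(sites$ref, sites$alt)
  }
  sites$key <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  o <- site_order(sites)
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL
  gt <- gt[o, , drop = FALSE]
  ad_ref <- ad_ref[o, , drop = FALSE]
  ad_alt <- ad_alt[o, , drop = FALSE]
  if (anyDuplicated(sites$key)) {
    stop("duplicate site keys in call set: ",
         sites$key[duplicated(sites$key)][1])
  }
  dimnames(gt) <- dimnames(ad_ref) <- dimnames(ad_alt) <-
    list(sites$key, samples$sample_id)
  structure(list(caller = caller, sites = sites, gt = gt,
                 ad_ref = ad_ref, ad_alt = ad_alt, samples = samples),
            class = "CallSet")
}

#' @exportS3Method base::print
print.CallSet <- function(x, ...) {
  cat("CallSet [", x$caller, "]: ", nrow(x$sites), " records x ",
      nrow(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' Number of records in a CallSet
#' @param callset a [new_callset()] object
#' @return integer record count
#' @export
n_records <- function(callset) nrow(callset$sites)

# row-subset a callset, preserving class invariants
subset_callset <- function(callset, keep) {
  callset$sites <- callset$sites[keep, , drop = FALSE]
  rownames(callset$sites) <- NULL
  callset$gt <- callset$gt[keep, , drop = FALSE]
  callset$ad_ref <- callset$ad_ref[keep, , drop = FALSE]
  callset$ad_alt <- callset$ad_alt[keep, , drop = FALSE]
  callset
}

#' Read sample metadata
#'
#' The roster mirrors the study design: three North American aquaculture
#' strains (GNB, PR, SJR) with year-classes, wild European samples, and
#' European doubled-haploid (DH) control lines. Tab- or comma-separated
#' with a header; required columns `sample_id`, `strain`, `year_class`,
#' `continent`, `is_doubled_haploid`.
#'
#' @param path metadata file path
#' @return data.frame with one validated row per sample
#' @export
read_metadata <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  meta <- read.table(path, header = TRUE, sep = sep,
                     stringsAsFactors = FALSE, na.strings = c("NA_", ""))
  validate_metadata(meta)
}

validate_metadata <- function(meta) {
  req <- c("sample_id", "strain", "year_class", "continent",
           "is_doubled_haploid")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$year_class <- as.character(meta$year_class)
  # "NA" is a continent label here, so it is not a global NA string;
  # year_class uses it (or blank) to mean absent
  meta$year_class[!is.na(meta$year_class) &
                    meta$year_class %in% c("NA", "")] <- NA_character_
  meta$is_doubled_haploid <- as.logical(meta$is_doubled_haploid)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id: ", meta$sample_id[duplicated(meta$sample_id)][1])
  }
  bad <- setdiff(unique(meta$strain), VALID_STRAINS)
  if (length(bad)) stop("unknown strain label: ", paste(bad, collapse = ", "))
  if (!all(meta$continent %in% c("NA", "EU"))) {
    stop("continent must be 'NA' or 'EU'")
  }
  if (any(meta$is_doubled_haploid & meta$continent != "EU")) {
    stop("doubled-haploid samples must be European (continent 'EU')")
  }
  if (any(startsWith(meta$strain, "EUR_") & meta$continent != "EU")) {
    stop("EUR_* strains must have continent 'EU'")
  }
  rownames(meta) <- NULL
  meta[req]
}

parse_gt_codes <- function(gt_chr) {
  out <- rep(NA_integer_, length(gt_chr))
  a <- sub("[/|].*$", "", gt_chr)
  b <- sub("^[^/|]*[/|]", "", gt_chr)
  ok <- !is.na(gt_chr) & a %in% c("0", "1") & b %in% c("0", "1")
  out[ok] <- as.integer(a[ok]) + as.integer(b[ok])
  out
}

#' Read a caller's VCF into a CallSet
#'
#' Parses a VCF 4.x file (via vcfR), requiring per-sample GT and AD
#' fields — the genotype re-calling rule is defined on allele read
#' depths, so records without AD are rejected. Sample columns are
#' reconciled to the roster by name, genotypes are coded 0/1/2/NA
#' (alleles beyond the first alternate code as NA and are removed by the
#' bi-allelic filter), and records are sorted by site key. Site depth is
#' taken from the INFO DP field when present, otherwise summed from AD.
#'
#' @param path VCF file
#' @param caller caller label
#' @param roster sample metadata (see [read_metadata()])
#' @return a [new_callset()] object
#' @export
read_vcf <- function(path, caller, roster) {
  roster <- validate_metadata(roster)
  ns <- nrow(roster)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    empty <- matrix(integer(0), nrow = 0, ncol = ns)
    return(new_callset(caller,
                       data.frame(chrom = character(0), pos = integer(0),
                                  ref = character(0), alt = character(0),
                                  qual = numeric(0), site_depth = numeric(0)),
                       empty, empty, empty, roster))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) {
    stop("malformed VCF row (non-numeric POS) at data line ",
         which(is.na(pos))[1])
  }
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)AD(:|$)", fmt))) {
    stop("VCF lacks the per-sample AD (allele depth) field, required for ",
         "genotype re-calling, at data line ",
         which(!grepl("(^|:)AD(:|$)", fmt))[1])
  }
  vcf_samples <- colnames(v@gt)[-1]
  missing_s <- setdiff(roster$sample_id, vcf_samples)
  if (length(missing_s)) {
    stop("VCF missing sample column(s): ", paste(missing_s, collapse = ", "))
  }
  GT <- vcfR::extract.gt(v, element = "GT")
  AD <- vcfR::extract.gt(v, element = "AD")
  # reconcile shuffled sample columns to roster order by name
  GT <- GT[, roster$sample_id, drop = FALSE]
  AD <- AD[, roster$sample_id, drop = FALSE]
  gt <- matrix(parse_gt_codes(GT), nrow = nrow(GT))
  ad_parts <- strsplit(ifelse(is.na(AD) | AD == ".", "0,0", AD), ",",
                       fixed = TRUE)
  ad_ref <- matrix(vapply(ad_parts, function(p) as.integer(p[1]),
                          integer(1)), nrow = nrow(AD))
  ad_alt <- matrix(vapply(ad_parts, function(p)
    if (length(p) >= 2L) as.integer(p[2]) else 0L, integer(1)),
    nrow = nrow(AD))
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  qual[is.na(qual)] <- 0
  dp <- suppressWarnings(as.numeric(sub("^.*DP=([0-9]+).*$", "\\1",
                                        fix$INFO)))
  dp[is.na(dp)] <- rowSums(ad_ref + ad_alt)[is.na(dp)]
  sites <- data.frame(chrom = fix$CHROM, pos = pos, ref = fix$REF,
                      alt = fix$ALT, qual = qual, site_depth = dp,
                      stringsAsFactors = FALSE)
  new_callset(caller, sites, gt, ad_ref, ad_alt, roster)
}

format_qual <- function(q) {
  ifelse(q == round(q), format(q, scientific = FALSE, trim = TRUE),
         sub("0+$", "", sprintf("%.6f", q)))
}

#' Write a CallSet to a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with INFO DP and per-sample GT:AD, such that
#' [read_vcf()] round-trips site keys, QUAL, genotype codes and allele
#' depths exactly.
#'
#' @param callset a [new_callset()] object (sorted by construction)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(callset, path) {
  s <- callset$sites
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=salmonsnp(", callset$caller, ")"),
    paste0("##contig=<ID=", unique(s$chrom), ">"),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth at site\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic read depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", callset$samples$sample_id), collapse = "\t"))
  writeLines(header, con)
  if (nrow(s)) {
    gt_str <- matrix(c("0/0", "0/1", "1/1")[callset$gt + 1L],
                     nrow = nrow(s))
    gt_str[is.na(gt_str)] <- "./."
    pad <- ifelse(s$n_alt > 1L,
                  vapply(s$n_alt, function(k)
                    paste(rep(",0", k - 1L), collapse = ""), character(1)),
                  "")
    cells <- matrix(paste0(gt_str, ":", callset$ad_ref, ",",
                           callset$ad_alt), nrow = nrow(s))
    cells <- matrix(paste0(cells, pad[row(cells)]), nrow = nrow(s))
    rows <- paste(s$chrom, s$pos, ".", s$ref, s$alt, format_qual(s$qual),
                  "PASS", paste0("DP=", as.integer(round(s$site_depth))),
                  "GT:AD",
                  apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a BED repeat mask into an IntervalSet
#'
#' BED intervals are 0-based half-open; internally everything is 1-based,
#' so the conversion happens here and only here. Intervals are merged
#' (overlapping or touching runs collapse) per chromosome.
#'
#' @param path BED3+ file
#' @return an `IntervalSet` wrapping a reduced [GenomicRanges::GRanges]
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) return(interval_set(character(0), integer(0),
                                          integer(0)))
  parts <- strsplit(lines, "[\t ]+")
  chrom <- vapply(parts, `[`, character(1), 1L)
  start0 <- as.integer(vapply(parts, `[`, character(1), 2L))
  end0 <- as.integer(vapply(parts, `[`, character(1), 3L))
  if (any(start0 >= end0)) {
    stop("BED interval with start >= end at line ", which(start0 >= end0)[1])
  }
  interval_set(chrom, start0, end0)
}

#' Build an IntervalSet from 0-based half-open coordinates
#' @param chrom chromosome names
#' @param start0,end0 0-based half-open interval bounds
#' @return an `IntervalSet`
#' @export
interval_set <- function(chrom, start0, end0) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L,
                                                end = end0))
  structure(list(gr = GenomicRanges::reduce(gr)), class = "IntervalSet")
}

#' @exportS3Method base::print
print.IntervalSet <- function(x, ...) {
  cat("IntervalSet:", length(x$gr), "merged intervals\n")
  invisible(x)
}

#' Interval membership for 1-based positions
#' @param iset an [interval_set()]
#' @param chrom,pos chromosome names and 1-based positions (recycled
#'   together)
#' @return logical vector, TRUE where the position is inside the set
#' @export
in_intervals <- function(iset, chrom, pos) {
  if (length(pos) == 0L) return(logical(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  # chromosomes absent from the set are legitimately outside it
  suppressWarnings(GenomicRanges::countOverlaps(q, iset$gr) > 0L)
}

#' Write the diagnostic marker panel as TSV
#'
#' One row per candidate site: site key fields, the homozygous genotype
#' class of each continental group, per-caller Fst, and confidence tier.
#'
#' @param panel data.frame from [select_diagnostic()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_panel <- function(panel, path) {
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
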