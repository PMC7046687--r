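# The six-step filtering cascade: boundary behaviour of every stage,
# genotype re-calling, oracle equivalence, set-filter properties, and
# the three-caller consensus with Venn accounting.

mini_cs <- function(sites, gt = NULL, roster = small_roster()) {
  n <- nrow(sites)
  ns <- nrow(roster)
  if (is.null(gt)) gt <- matrix(0L, n, ns)
  ad <- matrix(5L, n, ns)
  if (is.null(sites$qual)) sites$qual <- 99
  if (is.null(sites$site_depth)) sites$site_depth <- 100
  new_callset("freebayes", sites, gt, ad, ad, roster)
}

test_that("only single-alternate single-base SNPs pass the bi-allelic stage", {
  cs <- mini_cs(data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                           ref = c("A", "A", "A"),
                           alt = c("T", "T,G", "AT")))
  res <- filter_biallelic_snp(cs)
  expect_equal(res$callset$sites$key, "chr1:10:A:T")
  expect_equal(res$report$records_removed, 2)
  only_indels <- mini_cs(data.frame(chrom = "chr1", pos = c(1L, 2L),
                                    ref = c("AT", "G"), alt = c("A", "GC")))
  res2 <- filter_biallelic_snp(only_indels)
  expect_equal(n_records(res2$callset), 0)
  expect_equal(res2$report$records_removed, 2)
})

test_that("indel proximity is span-based with an inclusive 5-base boundary", {
  snps <- mini_cs(data.frame(chrom = "chr1", pos = c(100L, 200L),
                             ref = "A", alt = "T"))
  indels <- data.frame(chrom = "chr1", pos = c(105L, 206L),
                       ref = c("G", "G"), stringsAsFactors = FALSE)
  res <- filter_indel_proximity(snps, indels, 5)
  # gap(100, 105) = 5 -> removed; gap(200, 206) = 6 -> kept
  expect_equal(res$callset$sites$pos, 200L)
  # a SNP inside a deletion span has gap 0
  inside <- filter_indel_proximity(
    mini_cs(data.frame(chrom = "chr1", pos = 301L, ref = "A", alt = "T")),
    data.frame(chrom = "chr1", pos = 300L, ref = "GAT"), 0)
  expect_equal(n_records(inside$callset), 0)
  expect_error(filter_indel_proximity(snps, indels, -1), "non-negative")
})

test_that("QUAL filtering is strict and depth filtering inclusive", {
  cs <- mini_cs(data.frame(chrom = "chr1", pos = c(1L, 2L, 3L),
                           ref = "A", alt = "T",
                           qual = c(30, 30.01, 29.99),
                           site_depth = c(3000, 3001, 0)))
  expect_equal(filter_qual(cs, 30)$callset$sites$pos, 2L)
  expect_equal(filter_depth(cs, 3000)$callset$sites$pos, c(1L, 3L))
})

test_that("repeat masking converts 1-based positions to the BED frame", {
  cs <- mini_cs(data.frame(chrom = "chr1", pos = c(10L, 11L, 20L, 21L),
                           ref = "A", alt = "T"))
  mask <- interval_set("chr1", 10, 20)   # 0-based [10, 20)
  res <- mask_repeats(cs, mask)
  expect_equal(res$callset$sites$pos, c(10L, 21L))
  expect_equal(res$report$records_removed, 2)
})

test_that("genotype re-calling follows the >=2 alt / >=1 ref read rule", {
  expect_equal(recall_genotype(5, 0), "hom_ref")
  expect_equal(recall_genotype(1, 2), "het")
  expect_equal(recall_genotype(0, 2), "hom_alt")
  expect_equal(recall_genotype(0, 1), "missing")
  expect_equal(recall_genotype(0, 0), "missing")
  # exhaustive decision grid against the case-by-case oracle
  grid <- expand.grid(ref = 0:10, alt = 0:10)
  got <- recall_genotype(grid$ref, grid$alt)
  want <- mapply(recall_oracle, grid$ref, grid$alt)
  expect_equal(got, unname(want))
})

test_that("missingness is counted over the NA roster after re-calling", {
  roster <- small_roster(4, 2, 2)
  na_ids <- roster$sample_id[roster$continent == "NA"]
  gt <- rbind(c(0L, 1L, 2L, NA, NA, NA, 0L, 0L),   # 1 missing NA sample
              c(0L, NA, NA, 0L, 0L, 0L, 0L, 0L))   # 2 missing NA samples
  cs <- mini_cs(data.frame(chrom = "chr1", pos = c(1L, 2L), ref = "A",
                           alt = "T"), gt, roster)
  res <- filter_missingness(cs, 1)
  expect_equal(res$callset$sites$pos, 1L)
  expect_error(filter_missingness(cs, 1, character(0)), "empty")
})

test_that("any heterozygous doubled-haploid call removes the site", {
  roster <- small_roster(2, 2, 4)
  gt <- rbind(c(0L, 1L, 0L, 0L, 0L, 0L, 1L, 0L),  # het in 1 of 4 DH
              c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L),  # hom_alt in all DH
              c(0L, 0L, 0L, 0L, NA, NA, NA, NA))  # missing DH: no removal
  cs <- mini_cs(data.frame(chrom = "chr1", pos = 1:3, ref = "A",
                           alt = "T"), gt, roster)
  res <- filter_dh_het(cs)
  expect_equal(res$callset$sites$pos, c(2L, 3L))
  no_dh <- mini_cs(data.frame(chrom = "chr1", pos = 1L, ref = "A",
                              alt = "T"), roster = small_roster(2, 2, 0))
  expect_warning(res2 <- filter_dh_het(no_dh), "pass-through")
  expect_equal(n_records(res2$callset), 1)
})

test_that("each stage matches its brute-force predicate on random fixtures", {
  set.seed(88)
  for (rep in 1:5) {
    cs <- random_callset(150)
    indels <- cs$sites[cs$sites$variant_class == "indel", ]
    bed <- data.frame(chrom = sample(c("chr1", "chr2"), 6, replace = TRUE),
                      start = sample(0:9000, 6))
    bed$end <- bed$start + sample(50:400, 6, replace = TRUE)
    mask <- interval_set(bed$chrom, bed$start, bed$end)
    stages <- list(
      list(got = filter_biallelic_snp(cs), want = keep_biallelic_oracle(cs)),
      list(got = filter_indel_proximity(cs, indels, 5),
           want = keep_proximity_oracle(cs, indels, 5)),
      list(got = mask_repeats(cs, mask), want = keep_mask_oracle(cs, bed)),
      list(got = filter_missingness(cs, 1),
           want = keep_missing_oracle(
             cs, cs$samples$sample_id[cs$samples$continent == "NA"], 1)),
      list(got = filter_dh_het(cs),
           want = keep_dh_oracle(
             cs, cs$samples$sample_id[cs$samples$is_doubled_haploid])))
    for (st in stages) {
      expect_identical(st$got$callset$sites$key, cs$sites$key[st$want])
      rp <- st$got$report
      expect_equal(rp$records_in - rp$records_removed, rp$records_out)
    }
  }
})

test_that("stages are idempotent, order-invariant set filters", {
  set.seed(99)
  cs <- random_callset(200)
  mask <- interval_set("chr1", c(100, 4000), c(900, 6000))
  run1 <- run_cascade(cs, mask = mask)
  # idempotence of each stage
  once <- filter_qual(cs, 30)$callset
  expect_identical(filter_qual(once, 30)$callset$sites$key,
                   once$sites$key)
  # cascade conservation chains end-to-end
  rp <- run1$report
  expect_equal(rp$records_out[-nrow(rp)], rp$records_in[-1])
  expect_equal(rp$records_in - rp$records_removed, rp$records_out)
  # permuting input record order leaves the output set unchanged
  perm <- sample(n_records(cs))
  cs2 <- new_callset(cs$caller, cs$sites[perm, ],
                     cs$gt[perm, , drop = FALSE],
                     cs$ad_ref[perm, , drop = FALSE],
                     cs$ad_alt[perm, , drop = FALSE], cs$samples)
  run2 <- run_cascade(cs2, mask = mask)
  expect_identical(run2$callset$sites$key, run1$callset$sites$key)
  # stage order does not matter: apply predicates in a shuffled order
  indels <- cs$sites[cs$sites$variant_class == "indel", ]
  alt <- apply_recall(cs)
  alt <- filter_dh_het(alt)$callset
  alt <- filter_depth(alt, 3000)$callset
  alt <- mask_repeats(alt, mask)$callset
  alt <- filter_missingness(alt, 1)$callset
  alt <- filter_qual(alt, 30)$callset
  alt <- filter_indel_proximity(alt, indels, 5)$callset
  alt <- filter_biallelic_snp(alt)$callset
  expect_identical(alt$sites$key, run1$callset$sites$key)
})

test_that("a degenerate config reduces the cascade to bi-allelic SNPs", {
  set.seed(105)
  # no DH lines: with read-support thresholds at 0 every genotype
  # re-calls as het, which would otherwise trip the DH screen
  cs <- random_callset(150, roster = small_roster(4, 2, 0))
  cs$sites$qual <- cs$sites$qual + 1   # keep QUAL > 0 everywhere
  cfg <- filter_config(indel_distance = 0, min_qual = 0,
                       max_site_depth = Inf,
                       max_missing_samples = nrow(cs$samples),
                       min_alt_reads = 0, min_ref_reads = 0)
  # distance 0 still removes SNPs *inside* an indel span; pass no indels
  cs <- new_callset(cs$caller, cs$sites, cs$gt, cs$ad_ref, cs$ad_alt,
                    cs$samples)
  res <- suppressWarnings(
    run_cascade(cs, indels = cs$sites[0, ], config = cfg))
  bi <- filter_biallelic_snp(cs)$callset
  expect_identical(res$callset$sites$key, bi$sites$key)
})

test_that("three-way consensus reproduces set algebra and Venn counts", {
  roster <- small_roster()
  base <- random_callset(60, roster, span = 4000)
  keys <- base$sites$key
  pick <- function(caller, idx) {
    cs <- salmonsnp:::subset_callset(base, base$sites$key %in% keys[idx])
    cs$caller <- caller
    cs
  }
  # callsets {A,B}, {B,C}, {B} -> shared {B}
  cs1 <- pick("freebayes", 1:2)
  cs2 <- pick("mpileup", 2:3)
  cs3 <- pick("gatk", 2)
  res <- consensus_intersect(list(cs1, cs2, cs3))
  expect_equal(res$callset$sites$key, keys[2])
  # regions: (freebayes, gatk, mpileup) singles, then pairs, then triple
  expect_equal(unname(res$venn),
               c(1L, 0L, 1L, 0L, 0L, 0L, 1L))
  expect_equal(sum(res$venn), 3)   # union size
  # identical callsets: everything in the triple region
  resi <- consensus_intersect(list(pick("freebayes", 1:60),
                                   pick("mpileup", 1:60),
                                   pick("gatk", 1:60)))
  expect_equal(n_records(resi$callset), 60)
  expect_equal(sum(resi$venn[1:6]), 0)
  # random membership: Venn equals brute-force set operations,
  # symmetric in caller order
  set.seed(7)
  ia <- sample(60, 40); ib <- sample(60, 35); ic <- sample(60, 30)
  l <- list(pick("freebayes", ia), pick("mpileup", ib), pick("gatk", ic))
  r1 <- consensus_intersect(l)
  r2 <- consensus_intersect(l[c(3, 1, 2)])
  expect_identical(r1$venn, r2$venn)
  expect_identical(r1$callset$sites$key, r2$callset$sites$key)
  ka <- keys[ia]; kb <- keys[ib]; kc <- keys[ic]
  expect_equal(sort(r1$callset$sites$key),
               sort(intersect(intersect(ka, kb), kc)))
  expect_equal(unname(r1$venn["freebayes_only"]),
               length(setdiff(ka, union(kb, kc))))
  expect_equal(unname(r1$venn["freebayes_mpileup"]),
               length(setdiff(intersect(ka, kb), kc)))
  expect_error(consensus_intersect(l[1:2]), "three")
})
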