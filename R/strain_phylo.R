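# Strain phylogeny from the consensus genotype matrix: MAF pre-filter,
# greedy windowed LD pruning, allele-sharing distances, neighbor-joining,
# and site-bootstrap support. The study built its tree with SNPhylo +
# DNAML; here the documented preprocessing (MAF > 0.1, r^2 > 0.1) is kept
# and the tree method is a distance method (NJ), labelled as such in the
# outputs.

#' LD pruning configuration
#'
#' @param maf_min sites with MAF strictly above this survive the
#'   pre-filter (default 0.1)
#' @param r2_max maximum tolerated squared genotype correlation between
#'   retained sites within a window (default 0.1)
#' @param window_size window span in SNPs
#' @param window_step window advance in SNPs (must not exceed
#'   `window_size`)
#' @return an `ld_prune_config` list
#' @export
ld_prune_config <- function(maf_min = 0.1, r2_max = 0.1,
                            window_size = 50, window_step = 5) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, r2_max >= 0, r2_max <= 1,
            window_step <= window_size, window_size >= 2)
  list(maf_min = maf_min, r2_max = r2_max, window_size = window_size,
       window_step = window_step)
}

#' MAF and chromosome pre-filter for tree building
#'
#' Retains sites with minor allele frequency strictly greater than
#' `maf_min` (computed over the given samples) and, when `chromosomes`
#' is supplied, located on those named chromosome sequences (dropping
#' unplaced scaffolds).
#'
#' @param gm a [genotype_matrix()]
#' @param maf_min strict MAF threshold
#' @param sample_ids samples over which MAF is computed (default: all)
#' @param chromosomes allowed chromosome names, or NULL for all
#' @return the filtered GenotypeMatrix
#' @export
maf_prefilter <- function(gm, maf_min = 0.1, sample_ids = NULL,
                          chromosomes = NULL) {
  if (is.null(sample_ids)) sample_ids <- colnames(gm$geno)
  maf <- site_maf(gm$geno[, sample_ids, drop = FALSE])
  keep <- !is.na(maf) & maf > maf_min
  if (!is.null(chromosomes)) keep <- keep & gm$sites$chrom %in% chromosomes
  subset_gm(gm, keep)
}

#' Squared genotype correlation (LD r-squared) between two sites
#'
#' @param x,y genotype code vectors (0/1/2/NA) over the same samples
#' @return squared Pearson correlation over pairwise-complete samples;
#'   NA with fewer than 2 complete pairs or zero variance at either site
#' @export
genotype_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Greedy windowed LD pruning
#'
#' Sites are scanned left to right within each chromosome (input order =
#' position order); a site is dropped when its r-squared with any
#' already-retained site within `window_size - 1` positions (original
#' site index) exceeds `r2_max`. Ties are broken by keeping the earlier
#' site. The retained set therefore satisfies r^2 <= r2_max for every
#' within-window retained pair. An undefined r-squared (monomorphic on
#' the complete subset, or too few complete pairs) never triggers
#' removal.
#'
#' @param gm a [genotype_matrix()] with sites ordered by (chrom, pos)
#' @param config an [ld_prune_config()]
#' @return the pruned GenotypeMatrix, with attribute `prune_report`
#'   (sites in/out)
#' @export
ld_prune <- function(gm, config = ld_prune_config()) {
  n <- nrow(gm$geno)
  keep <- logical(n)
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch)
    idx <- idx[order(gm$sites$pos[idx])]
    kept <- integer(0)       # positions within idx of retained sites
    for (j in seq_along(idx)) {
      cand <- kept[j - kept < config$window_size]
      drop <- FALSE
      for (k in rev(cand)) {
        r2 <- genotype_r2(gm$geno[idx[k], ], gm$geno[idx[j], ])
        if (!is.na(r2) && r2 > config$r2_max) { drop <- TRUE; break }
      }
      if (!drop) { kept <- c(kept, j); keep[idx[j]] <- TRUE }
    }
  }
  out <- subset_gm(gm, keep)
  attr(out, "prune_report") <- list(sites_in = n, sites_out = sum(keep))
  out
}

# samples x sites numeric matrix for distance computation
geno_t <- function(gm, sample_ids = NULL) {
  g <- if (is.null(sample_ids)) gm$geno else
    gm$geno[, sample_ids, drop = FALSE]
  t(g)
}

# allele-sharing distance on a samples x sites matrix; R's dist() with
# missing values rescales the Manhattan sum by m / m_complete, so
# dividing by 2m gives exactly the mean of |code_i - code_j| / 2 over
# co-observed sites
asd_matrix <- function(X) {
  m <- ncol(X)
  if (m == 0L) stop("no sites available for distance computation")
  D <- as.matrix(stats::dist(X, method = "manhattan")) / (2 * m)
  if (any(!is.finite(D))) {
    bad <- which(!is.finite(D), arr.ind = TRUE)[1, ]
    stop("samples ", rownames(D)[bad[1]], " and ", rownames(D)[bad[2]],
         " share no co-observed sites")
  }
  D
}

#' Pairwise allele-sharing distances between samples
#'
#' d(x, y) = mean over sites non-missing in both samples of
#' |code_x - code_y| / 2; 0 for identical genotype vectors, 1 for
#' opposite homozygotes at every site.
#'
#' @param gm a [genotype_matrix()]
#' @param sample_ids samples to include (default: all)
#' @return symmetric distance matrix with zero diagonal
#' @export
pairwise_distance <- function(gm, sample_ids = NULL) {
  asd_matrix(geno_t(gm, sample_ids))
}

#' Neighbor-joining tree from a distance matrix
#'
#' @param distances symmetric distance matrix with sample names
#' @return an [ape::nj()] phylo object; a fully degenerate (all-zero)
#'   matrix yields a star tree with zero branch lengths and a warning
#' @export
build_tree <- function(distances) {
  stopifnot(nrow(distances) >= 3L)
  if (all(distances == 0)) {
    warning("degenerate distance matrix; returning a star tree")
    tips <- rownames(distances)
    txt <- paste0("(", paste0(tips, ":0", collapse = ","), ");")
    return(ape::read.tree(text = txt))
  }
  ape::nj(stats::as.dist(distances))
}

# canonical key for the bipartition induced by an internal edge: the
# lexicographically-sorted tip names of the smaller side (ties broken
# lexicographically on the joined string)
split_keys <- function(phy) {
  pp <- ape::prop.part(phy)
  tips <- attr(pp, "labels")
  keys <- vapply(pp, function(cl) {
    a <- sort(tips[cl]); b <- sort(setdiff(tips, a))
    if (length(b) == 0L) return("<all-tips>")  # trivial root "split"
    ka <- paste(a, collapse = "|"); kb <- paste(b, collapse = "|")
    if (length(a) < length(b) || (length(a) == length(b) && ka < kb))
      ka else kb
  }, character(1))
  # prop.part entry i corresponds to internal node Ntip + i
  setNames(keys, length(tips) + seq_along(pp))
}

#' Does a tree contain the bipartition separating a tip set?
#' @param phy a phylo object
#' @param tips tip labels of one side of the candidate split
#' @return TRUE iff some internal edge induces exactly this split
#' @export
has_split <- function(phy, tips) {
  all_tips <- phy$tip.label
  a <- sort(tips); b <- sort(setdiff(all_tips, a))
  ka <- paste(a, collapse = "|"); kb <- paste(b, collapse = "|")
  key <- if (length(a) < length(b) || (length(a) == length(b) && ka < kb))
    ka else kb
  key %in% split_keys(phy)
}

#' Site-bootstrap support for a neighbor-joining tree
#'
#' Resamples sites (matrix columns) with replacement `n_reps` times,
#' recomputes the allele-sharing distances and NJ tree per replicate,
#' and scores each internal edge of the reference tree by the
#' percentage of replicates containing its bipartition.
#'
#' @param gm a pruned [genotype_matrix()]
#' @param sample_ids samples in the tree (default: all)
#' @param n_reps bootstrap replicates (study setting: 1000)
#' @param seed RNG seed (mandatory for reproducibility)
#' @param tree optional precomputed reference tree
#' @return list with `tree` (reference NJ tree, `node.label` set to the
#'   support percentages, NA at the root) and `support` (named vector,
#'   one entry per internal node)
#' @export
bootstrap_support <- function(gm, sample_ids = NULL, n_reps = 1000,
                              seed, tree = NULL) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  X <- geno_t(gm, sample_ids)
  if (is.null(tree)) tree <- build_tree(asd_matrix(X))
  ref_keys <- split_keys(tree)
  counts <- setNames(numeric(length(ref_keys)), ref_keys)
  m <- ncol(X)
  set.seed(seed)
  for (i in seq_len(n_reps)) {
    idx <- sample.int(m, m, replace = TRUE)
    rep_tree <- build_tree(asd_matrix(X[, idx, drop = FALSE]))
    hit <- intersect(unique(split_keys(rep_tree)), names(counts))
    counts[hit] <- counts[hit] + 1
  }
  support <- setNames(100 * counts / n_reps, names(ref_keys))
  # root "split" (all tips) is trivial; blank its label
  node_lab <- as.character(round(unname(support), 1))
  node_lab[1] <- ""
  tree$node.label <- node_lab
  list(tree = tree, support = support)
}

#' Bootstrap support for the split isolating a set of tips
#' @param boot result of [bootstrap_support()]
#' @param tips tip labels of the candidate clade
#' @return support percentage, or NA if the reference tree lacks the
#'   split
#' @export
split_support <- function(boot, tips) {
  phy <- boot$tree
  a <- sort(tips); b <- sort(setdiff(phy$tip.label, a))
  ka <- paste(a, collapse = "|"); kb <- paste(b, collapse = "|")
  key <- if (length(a) < length(b) || (length(a) == length(b) && ka < kb))
    ka else kb
  keys <- split_keys(phy)
  i <- match(key, keys)
  if (is.na(i)) return(NA_real_)
  unname(boot$support[i])
}
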