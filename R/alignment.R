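#' Read an aligned mtDNA FASTA with cohort labels
#'
#' Reads a FASTA file of aligned mitochondrial sequences (one fragment, all
#' records the same length) and attaches a cohort label to every individual.
#' Labels are taken from `cohort_map` when supplied, otherwise parsed from the
#' sequence id as the field following the last underscore (e.g.
#' `ind007_2010` -> cohort `"2010"`).
#'
#' @param path path to a FASTA file.
#' @param cohort_map optional named character vector mapping sequence ids to
#'   cohort labels. Ids present in the file but absent from the map are an
#'   error.
#' @param ambiguity how to treat non-ACGT characters: `"error"` rejects the
#'   file (the default; a clean single-fragment alignment is expected),
#'   `"mask"` drops every alignment column containing an ambiguity or gap.
#' @return an object of class `mt_alignment`: a list with `ids`, `cohort`,
#'   `seq` (uppercase character vector) and `site_count`.
#' @export
read_alignment <- function(path, cohort_map = NULL,
                           ambiguity = c("error", "mask")) {
  ambiguity <- match.arg(ambiguity)
  xs <- Biostrings::readDNAStringSet(path)
  if (length(xs) == 0L) stop("no sequences in ", path)
  ids <- vapply(strsplit(names(xs), "[ \t]"), `[[`, "", 1L)
  seqs <- toupper(as.character(xs))
  names(seqs) <- NULL
  mt_alignment(ids, seqs, cohort_map = cohort_map, ambiguity = ambiguity)
}

#' Construct an mtDNA alignment object from vectors
#'
#' @param ids character vector of unique individual ids.
#' @param seqs character vector of equal-length upper-case DNA sequences.
#' @param cohorts optional character vector of cohort labels, recycled checks
#'   apply; if `NULL` the label is parsed from the id (text after the last
#'   underscore) or via `cohort_map`.
#' @param cohort_map optional named character vector id -> cohort.
#' @param ambiguity `"error"` or `"mask"`, see [read_alignment()].
#' @return an `mt_alignment` object.
#' @export
mt_alignment <- function(ids, seqs, cohorts = NULL, cohort_map = NULL,
                         ambiguity = c("error", "mask")) {
  ambiguity <- match.arg(ambiguity)
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (anyDuplicated(ids)) stop("duplicated sequence ids")
  if (any(!nzchar(seqs))) stop("empty sequence")
  ll <- nchar(seqs)
  if (length(unique(ll)) != 1L) {
    stop("alignment error: sequences of unequal length (",
         paste(unique(ll), collapse = ", "), ")")
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  bad_col <- apply(mat, 2L, function(x) any(!x %in% c("A", "C", "G", "T")))
  if (any(bad_col)) {
    if (ambiguity == "error") {
      stop("ambiguity codes or gaps found in ", sum(bad_col),
           " column(s); rerun with ambiguity = \"mask\" to drop them")
    }
    mat <- mat[, !bad_col, drop = FALSE]
    if (ncol(mat) == 0L) stop("all columns masked")
    seqs <- apply(mat, 1L, paste, collapse = "")
  }
  if (is.null(cohorts)) {
    if (!is.null(cohort_map)) {
      miss <- setdiff(ids, names(cohort_map))
      if (length(miss)) {
        stop("labelling error: no cohort for id(s) ",
             paste(utils::head(miss, 5L), collapse = ", "))
      }
      cohorts <- unname(cohort_map[ids])
    } else {
      cohorts <- sub("^.*_", "", ids)
    }
  }
  cohorts <- as.character(cohorts)
  if (length(cohorts) != length(ids)) stop("cohort labels differ in length")
  structure(
    list(ids = ids, cohort = cohorts, seq = seqs,
         site_count = nchar(seqs[1L])),
    class = "mt_alignment"
  )
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat("mtDNA alignment:", length(x$ids), "sequences x", x$site_count, "bp\n")
  tab <- table(x$cohort)
  cat("cohorts:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Write an alignment back to FASTA
#'
#' Ids are written as `id cohort` so that a round trip through
#' [read_alignment()] with a sidecar map reproduces the object.
#'
#' @param aln an `mt_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  x <- Biostrings::DNAStringSet(aln$seq)
  names(x) <- aln$ids
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

subset_alignment <- function(aln, keep) {
  mt_alignment(aln$ids[keep], aln$seq[keep], cohorts = aln$cohort[keep])
}

#' Collapse an alignment into a haplotype table
#'
#' Distinct sequences become haplotypes; per-cohort counts, the number of
#' segregating sites S, haplotype diversity Hd and nucleotide diversity pi
#' are computed for the selected subset.
#'
#' @param aln an `mt_alignment`.
#' @param cohorts optional character vector of cohort labels to keep
#'   (default: all individuals).
#' @return an object of class `haplotype_table`: a list with `seqs` (distinct
#'   haplotype sequences, most frequent first), `counts` (haplotype x cohort
#'   integer matrix), `total` (per-haplotype totals), `n`, `n_hap`, `s_sites`,
#'   `hd`, `pi` and `site_count`.
#' @export
collapse_haplotypes <- function(aln, cohorts = NULL) {
  keep <- if (is.null(cohorts)) rep(TRUE, length(aln$ids)) else
    aln$cohort %in% cohorts
  if (!any(keep)) stop("empty subset: no individuals in requested cohorts")
  seqs <- aln$seq[keep]
  coh <- aln$cohort[keep]
  tab <- table(factor(seqs, levels = unique(seqs)), coh)
  total <- rowSums(tab)
  ord <- order(-total, rownames(tab))
  counts <- matrix(as.integer(tab[ord, , drop = FALSE]), nrow = nrow(tab),
                   dimnames = list(NULL, colnames(tab)))
  hseq <- rownames(tab)[ord]
  total <- unname(total[ord])
  n <- length(seqs)
  s <- count_segregating(hseq)
  hd <- if (n >= 2L) haplotype_diversity_counts(total) else NA_real_
  pi <- if (n >= 2L) nucleotide_diversity_counts(hseq, total,
                                                 aln$site_count) else NA_real_
  structure(
    list(seqs = hseq, counts = counts, total = total, n = n,
         n_hap = length(hseq), s_sites = s, hd = hd, pi = pi,
         site_count = aln$site_count),
    class = "haplotype_table"
  )
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf(
    "haplotype table: n = %d, nHap = %d, S = %d, Hd = %.3f, pi = %.5f\n",
    x$n, x$n_hap, x$s_sites, x$hd, x$pi))
  invisible(x)
}

count_segregating <- function(seqs) {
  if (length(seqs) < 2L) return(0L)
  mat <- do.call(rbind, strsplit(seqs, ""))
  sum(apply(mat, 2L, function(col) length(unique(col)) > 1L))
}

haplotype_diversity_counts <- function(counts) {
  n <- sum(counts)
  if (n < 2L) stop("haplotype diversity undefined for n < 2")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Haplotype (gene) diversity
#'
#' Nei's unbiased haplotype diversity, `Hd = n/(n-1) * (1 - sum(p_i^2))`.
#'
#' @param tbl a `haplotype_table`, or a numeric vector of haplotype counts.
#' @return Hd in `[0, 1]`.
#' @export
haplotype_diversity <- function(tbl) {
  counts <- if (inherits(tbl, "haplotype_table")) tbl$total else tbl
  haplotype_diversity_counts(counts)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

nucleotide_diversity_counts <- function(seqs, counts, site_count) {
  n <- sum(counts)
  if (n < 2L) stop("nucleotide diversity undefined for n < 2")
  k <- length(seqs)
  if (k == 1L) return(0)
  mats <- strsplit(seqs, "")
  tot <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      d <- sum(mats[[i]] != mats[[j]])
      tot <- tot + d * counts[i] * counts[j]
    }
  }
  tot / (n * (n - 1) / 2) / site_count
}

#' Nucleotide diversity per site
#'
#' Mean pairwise Hamming distance over all sequence pairs in the sample,
#' divided by the alignment length.
#'
#' @param tbl a `haplotype_table`.
#' @param site_count alignment length; defaults to the value stored in `tbl`.
#' @return pi >= 0.
#' @export
nucleotide_diversity <- function(tbl, site_count = tbl$site_count) {
  nucleotide_diversity_counts(tbl$seqs, tbl$total, site_count)
}

#' Haplotype-frequency F_ST between groups of sequences
#'
#' AMOVA-style fixation index on haplotype identity (distance 0 between
#' identical haplotypes, 1 otherwise), i.e. differentiation of haplotype
#' frequencies, with a permutation test that shuffles individuals among
#' groups.
#'
#' @param aln an `mt_alignment`.
#' @param groups character vector naming the grouping: either `"cohort"` (use
#'   the stored cohort labels) or a vector of labels, one per individual.
#' @param n_perm number of permutations for the p-value.
#' @param seed optional integer seed for the permutation stream.
#' @return a list with `fst`, `p` (one-sided `(#>=obs + 1)/(n_perm + 1)`),
#'   `n_perm`, and the per-group sample sizes.
#' @export
mtdna_fst <- function(aln, groups = "cohort", n_perm = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- if (identical(groups, "cohort")) aln$cohort else as.character(groups)
  if (length(g) != length(aln$ids)) stop("groups must label every individual")
  tab <- table(g)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) stop("every group needs n >= 2")
  hap <- as.integer(factor(aln$seq, levels = unique(aln$seq)))
  obs <- hap_identity_phist(hap, g)
  more <- 0L
  for (b in seq_len(n_perm)) {
    if (hap_identity_phist(hap, sample(g)) >= obs) more <- more + 1L
  }
  list(fst = obs, p = (more + 1) / (n_perm + 1), n_perm = n_perm,
       n = as.integer(tab))
}

# AMOVA Phi_ST with identity distance: variance decomposition of the 0/1
# distance d_ij = [hap_i != hap_j] into among- and within-group components
# (Excoffier's sums of squared deviations with unequal sample sizes).
hap_identity_phist <- function(hap, g) {
  g <- as.character(g)
  n <- length(hap)
  sizes <- table(g)
  k <- length(sizes)
  # SSD(total) = sum_{i<j} d_ij / n ; SSD(within) = sum_g sum_{i<j in g} d/n_g
  ssd_tot <- pair_mismatch_sum(hap) / n
  ssd_w <- 0
  for (gg in names(sizes)) {
    idx <- g == gg
    ssd_w <- ssd_w + pair_mismatch_sum(hap[idx]) / sum(idx)
  }
  ssd_a <- ssd_tot - ssd_w
  df_a <- k - 1
  df_w <- n - k
  ms_a <- ssd_a / df_a
  ms_w <- ssd_w / df_w
  n_c <- (n - sum(sizes^2) / n) / (k - 1)
  sigma_a <- (ms_a - ms_w) / n_c
  sigma_w <- ms_w
  tot <- sigma_a + sigma_w
  if (tot <= 0) return(0)
  sigma_a / tot
}

pair_mismatch_sum <- function(hap) {
  n <- length(hap)
  tab <- table(hap)
  same <- sum(tab * (tab - 1) / 2)
  n * (n - 1) / 2 - same
}
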