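#' Nei's unbiased expected heterozygosity
#'
#' Per-locus unbiased gene diversity `n_g/(n_g - 1) * (1 - sum(p^2))`
#' (`n_g` = typed gene copies), averaged over loci.
#'
#' @param g a `genotype_matrix`.
#' @param deme optional deme label(s); default pools all individuals.
#' @param by_locus return the per-locus vector instead of the mean.
#' @return He in `[0, 1]`.
#' @export
expected_het <- function(g, deme = NULL, by_locus = FALSE) {
  he <- vapply(seq_along(g$loci), function(li) {
    af <- allele_freqs(g, li, deme)
    if (af$n_genes < 2L) return(NA_real_)
    af$n_genes / (af$n_genes - 1) * (1 - sum(af$freq^2))
  }, 0)
  names(he) <- g$loci
  if (by_locus) he else mean(he, na.rm = TRUE)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a subsample of `g_genes` gene
#' copies, `sum_a [1 - C(N - N_a, g) / C(N, g)]`, averaged over loci.
#'
#' @param g a `genotype_matrix`.
#' @param deme optional deme label(s).
#' @param g_genes rarefaction size in gene copies; must not exceed the
#'   typed gene count of any locus.
#' @param by_locus return the per-locus vector.
#' @return Ar >= 1.
#' @export
rarefied_ar <- function(g, deme = NULL, g_genes, by_locus = FALSE) {
  ar <- vapply(seq_along(g$loci), function(li) {
    af <- allele_freqs(g, li, deme)
    N <- af$n_genes
    if (g_genes > N) {
      stop("g_genes (", g_genes, ") exceeds typed genes (", N,
           ") at locus ", g$loci[li])
    }
    sum(1 - exp(lchoose(N - af$counts, g_genes) - lchoose(N, g_genes)))
  }, 0)
  names(ar) <- g$loci
  if (by_locus) ar else mean(ar)
}

# Weir & Cockerham within-population components for one locus in one deme:
# per allele, b (among individuals within deme) and c (within individuals).
wc_within_components <- function(a1, a2) {
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]
  n <- length(a1)
  if (n < 2L) return(NULL)
  alleles <- sort(unique(c(a1, a2)))
  b <- c_ <- numeric(length(alleles))
  for (ai in seq_along(alleles)) {
    al <- alleles[ai]
    p <- (sum(a1 == al) + sum(a2 == al)) / (2 * n)
    hbar <- mean((a1 == al) != (a2 == al))
    b[ai] <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
    c_[ai] <- hbar / 2
  }
  list(b = b, c = c_)
}

#' Weir & Cockerham inbreeding coefficient F_IS
#'
#' Multilocus `f = 1 - sum(c) / sum(b + c)` over loci and alleles, where
#' `b` and `c` are the among- and within-individual variance components of
#' Weir & Cockerham's estimator for a single population.
#'
#' @param g a `genotype_matrix`.
#' @param deme optional deme label(s).
#' @return F_IS (can be negative with heterozygote excess).
#' @export
fis <- function(g, deme = NULL) {
  keep <- if (is.null(deme)) rep(TRUE, length(g$ids)) else g$deme %in% deme
  sb <- sc <- 0
  for (li in seq_along(g$loci)) {
    comp <- wc_within_components(g$a1[keep, li], g$a2[keep, li])
    if (is.null(comp)) next
    sb <- sb + sum(comp$b)
    sc <- sc + sum(comp$c)
  }
  if (sb + sc == 0) return(NA_real_)
  1 - sc / (sb + sc)
}

deme_freq_table <- function(g, deme, include_self = TRUE, focal = NULL) {
  # list per locus: named allele frequency vector within the deme
  keep <- g$deme %in% deme
  if (!include_self && !is.null(focal)) keep[focal] <- FALSE
  lapply(seq_along(g$loci), function(li) {
    al <- c(g$a1[keep, li], g$a2[keep, li])
    al <- al[!is.na(al)]
    if (!length(al)) return(numeric(0))
    tab <- table(al)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
}

#' Internal relatedness (IR)
#'
#' Amos's multilocus homozygosity index
#' `IR = (2H - sum(f_i)) / (2N - sum(f_i))`, where `H` is the number of
#' homozygous loci, `N` the number of typed loci and `f_i` the deme-specific
#' frequencies of the alleles carried. The default counts every carried
#' allele copy (both alleles of every typed locus), which reproduces the
#' Rhh reference behaviour; `freq_domain = "homozygous"` restricts the sum
#' to alleles at homozygous loci.
#'
#' @param g a `genotype_matrix`.
#' @param min_typed minimum fraction of typed loci required (individuals
#'   below it get NA).
#' @param freq_domain `"carried"` (default) or `"homozygous"`.
#' @param include_self include the focal individual in the allele-frequency
#'   estimates (default TRUE).
#' @param by_deme compute allele frequencies within each individual's deme
#'   (default TRUE) rather than over the whole matrix.
#' @return named numeric vector of IR in `[-1, 1]`.
#' @export
internal_relatedness <- function(g, min_typed = 0.5,
                                 freq_domain = c("carried", "homozygous"),
                                 include_self = TRUE, by_deme = TRUE) {
  freq_domain <- match.arg(freq_domain)
  out <- stats::setNames(rep(NA_real_, length(g$ids)), g$ids)
  for (i in seq_along(g$ids)) {
    typed <- which(!is.na(g$a1[i, ]))
    if (length(typed) < min_typed * length(g$loci)) next
    dm <- if (by_deme) g$deme[i] else unique(g$deme)
    freqs <- deme_freq_table(g, dm, include_self = include_self, focal = i)
    H <- 0L; sf <- 0; N <- length(typed)
    for (li in typed) {
      x1 <- g$a1[i, li]; x2 <- g$a2[i, li]
      hom <- x1 == x2
      if (hom) H <- H + 1L
      if (freq_domain == "carried" || hom) {
        f <- freqs[[li]]
        sf <- sf + f[as.character(x1)] + f[as.character(x2)]
      }
    }
    out[i] <- (2 * H - sf) / (2 * N - sf)
  }
  out
}

#' Homozygosity by loci (HL)
#'
#' Aparicio's index `HL = sum(E_h) / (sum(E_h) + sum(E_j))`, where `E` is
#' the expected heterozygosity of a locus (within the individual's deme),
#' `h` runs over the individual's homozygous loci and `j` over its
#' heterozygous loci. 0 = fully heterozygous, 1 = fully homozygous.
#'
#' @inheritParams internal_relatedness
#' @return named numeric vector of HL in `[0, 1]`.
#' @export
homozygosity_by_loci <- function(g, min_typed = 0.5, include_self = TRUE,
                                 by_deme = TRUE) {
  out <- stats::setNames(rep(NA_real_, length(g$ids)), g$ids)
  # cache per-deme locus expected heterozygosities
  demes <- if (by_deme) unique(g$deme) else list(unique(g$deme))
  eh_cache <- lapply(demes, function(dm) {
    freqs <- deme_freq_table(g, dm)
    vapply(freqs, function(f) 1 - sum(f^2), 0)
  })
  names(eh_cache) <- vapply(demes, paste, "", collapse = "+")
  for (i in seq_along(g$ids)) {
    typed <- which(!is.na(g$a1[i, ]))
    if (length(typed) < min_typed * length(g$loci)) next
    key <- if (by_deme) g$deme[i] else paste(unique(g$deme), collapse = "+")
    eh <- eh_cache[[key]]
    hom <- g$a1[i, typed] == g$a2[i, typed]
    se_h <- sum(eh[typed[hom]])
    se_j <- sum(eh[typed[!hom]])
    out[i] <- if (se_h + se_j == 0) 0 else se_h / (se_h + se_j)
  }
  out
}

#' Per-deme diversity report
#'
#' Convenience summary feeding the R_IR/R_HL diagnostic and reporting: He,
#' rarefied Ar, F_IS, mean IR and mean HL per deme.
#'
#' @param g a `genotype_matrix`.
#' @param g_genes rarefaction size; default = smallest typed gene count
#'   over demes and loci.
#' @return data.frame with one row per deme.
#' @export
diversity_report <- function(g, g_genes = NULL) {
  demes <- sort(unique(g$deme))
  if (is.null(g_genes)) {
    g_genes <- min(vapply(demes, function(d) {
      min(vapply(seq_along(g$loci), function(li)
        allele_freqs(g, li, d)$n_genes, 0))
    }, 0))
  }
  ir <- internal_relatedness(g)
  hl <- homozygosity_by_loci(g)
  out <- do.call(rbind, lapply(demes, function(d) {
    idx <- g$deme == d
    data.frame(
      deme = d, n = sum(idx),
      he = expected_het(g, d),
      ar = rarefied_ar(g, d, g_genes),
      fis = fis(g, d),
      mean_ir = mean(ir[idx], na.rm = TRUE),
      mean_hl = mean(hl[idx], na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  attr(out, "g_genes") <- g_genes
  out
}

#' R_IR / R_HL asymmetric-gene-flow diagnostic
#'
#' Pearson correlations, across demes, of deme-mean IR and deme-mean HL
#' with deme F_IS. Under asymmetric migration that imports rare alleles,
#' HL is expected to track F_IS more closely than IR (`R_HL > R_IR`).
#'
#' @param report a data.frame from [diversity_report()] (columns `mean_ir`,
#'   `mean_hl`, `fis`).
#' @return list with `r_ir`, `r_hl`, their p-values, and `contrast`
#'   (`sign(r_hl - r_ir)`); NA with a warning when the statistics are
#'   degenerate across demes.
#' @export
rir_rhl_diagnostic <- function(report) {
  if (nrow(report) < 3L) stop("need at least three demes")
  if (stats::sd(report$fis) == 0 || stats::sd(report$mean_ir) == 0 ||
      stats::sd(report$mean_hl) == 0) {
    warning("degenerate deme statistics; correlations undefined")
    return(list(r_ir = NA_real_, r_hl = NA_real_, p_ir = NA_real_,
                p_hl = NA_real_, contrast = NA_real_))
  }
  ct_ir <- stats::cor.test(report$mean_ir, report$fis)
  ct_hl <- stats::cor.test(report$mean_hl, report$fis)
  list(r_ir = unname(ct_ir$estimate), r_hl = unname(ct_hl$estimate),
       p_ir = ct_ir$p.value, p_hl = ct_hl$p.value,
       contrast = sign(unname(ct_hl$estimate) - unname(ct_ir$estimate)))
}
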