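#' Diploid microsatellite genotype matrix
#'
#' Container for individuals x loci diploid genotypes with integer allele
#' sizes (repeat scores). Missing genotypes are NA in both allele matrices.
#'
#' @param ids character vector of individual ids.
#' @param deme character vector of deme (population) labels.
#' @param a1,a2 integer matrices (individuals x loci) of allele sizes;
#'   `NA` marks a missing genotype (both must be NA together).
#' @param loci locus names; defaults to colnames of `a1`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(ids, deme, a1, a2, loci = colnames(a1)) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!all(dim(a1) == dim(a2))) stop("allele matrices differ in shape")
  if (length(ids) != nrow(a1)) stop("ids do not match rows")
  if (length(deme) != nrow(a1)) stop("deme labels do not match rows")
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  if (any(xor(is.na(a1), is.na(a2)))) stop("half-missing genotype")
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE)) {
    stop("allele sizes must be positive integers")
  }
  # store unordered: smaller allele first
  sw <- !is.na(a1) & a1 > a2
  tmp <- a1[sw]; a1[sw] <- a2[sw]; a2[sw] <- tmp
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = as.character(ids), deme = as.character(deme),
                 loci = loci, a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype matrix:", length(x$ids), "individuals x", length(x$loci),
      "loci;", sprintf("%.1f%% missing\n", 100 * mean(is.na(x$a1))))
  tab <- table(x$deme)
  cat("demes:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype matrix by individuals and/or loci
#' @param g a `genotype_matrix`.
#' @param individuals logical/integer/character selector of individuals.
#' @param loci selector of loci.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(g, individuals = NULL, loci = NULL) {
  ii <- if (is.null(individuals)) seq_along(g$ids) else individuals
  if (is.character(ii)) ii <- match(ii, g$ids)
  ll <- if (is.null(loci)) seq_along(g$loci) else loci
  if (is.character(ll)) ll <- match(ll, g$loci)
  genotype_matrix(g$ids[ii], g$deme[ii],
                  g$a1[ii, ll, drop = FALSE], g$a2[ii, ll, drop = FALSE],
                  g$loci[ll])
}

#' Allele counts and frequencies at one locus
#'
#' @param g a `genotype_matrix`.
#' @param locus locus name or index.
#' @param deme optional deme label(s); default all individuals.
#' @return a list with `counts` (named integer vector per allele),
#'   `freq`, and `n_genes` (number of typed gene copies).
#' @export
allele_freqs <- function(g, locus, deme = NULL) {
  li <- if (is.character(locus)) match(locus, g$loci) else locus
  keep <- if (is.null(deme)) rep(TRUE, length(g$ids)) else g$deme %in% deme
  al <- c(g$a1[keep, li], g$a2[keep, li])
  al <- al[!is.na(al)]
  cnt <- table(al)
  counts <- as.integer(cnt)
  names(counts) <- names(cnt)
  list(counts = counts, freq = counts / sum(counts),
       n_genes = length(al))
}

#' Read a GenePop genotype file
#'
#' Supports the standard GenePop layout: a title line, locus names (one per
#' line or comma-separated on one line), and `POP` blocks of
#' `id , g1 g2 ...` rows with 2- or 3-digit-per-allele diploid codes
#' (`000`/`00` = missing). Pop labels are taken from the id of the first
#' individual in each block (text before any trailing digits are kept
#' as-is), or `pop1`, `pop2`, ... when ids are uninformative.
#'
#' @param path path to a GenePop file.
#' @param deme_names optional character vector of labels for the POP blocks.
#' @return a `genotype_matrix`.
#' @export
read_genepop <- function(path, deme_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("not a GenePop file: too short")
  body <- lines[-1L]
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("not a GenePop file: no POP line")
  loc_lines <- body[seq_len(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(loc_lines, ",")))
  loci <- loci[nzchar(loci)]
  ids <- character(); deme <- character()
  rows1 <- list(); rows2 <- list()
  popi <- 0L
  for (ln in body[first_pop:length(body)]) {
    if (toupper(trimws(ln)) == "POP") { popi <- popi + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2L) stop("malformed GenePop row: ", ln)
    id <- trimws(parts[1L])
    gt <- strsplit(trimws(paste(parts[-1L], collapse = " ")), "[ \t]+")[[1]]
    if (length(gt) != length(loci)) {
      stop("row has ", length(gt), " genotypes for ", length(loci),
           " loci: ", id)
    }
    w <- nchar(gt[1L]) / 2L
    if (!w %in% c(2L, 3L)) stop("allele code width must be 2 or 3 digits")
    x1 <- as.integer(substr(gt, 1L, w))
    x2 <- as.integer(substr(gt, w + 1L, 2L * w))
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    miss <- is.na(x1) | is.na(x2)
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    ids <- c(ids, id)
    deme <- c(deme, if (!is.null(deme_names)) deme_names[popi] else
      paste0("pop", popi))
    rows1[[length(rows1) + 1L]] <- x1
    rows2[[length(rows2) + 1L]] <- x2
  }
  genotype_matrix(ids, deme, do.call(rbind, rows1), do.call(rbind, rows2),
                  loci)
}

#' Write a genotype matrix as a GenePop file
#'
#' One POP block per deme (alphabetical order), 3-digit allele codes.
#'
#' @param g a `genotype_matrix`.
#' @param path output path.
#' @param title first line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, path, title = "matriflow genotypes") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(g$loci, con)
  fmt <- function(x) ifelse(is.na(x), "000", sprintf("%03d", x))
  for (d in sort(unique(g$deme))) {
    writeLines("POP", con)
    for (i in which(g$deme == d)) {
      writeLines(paste0(g$ids[i], " ,  ",
                        paste(paste0(fmt(g$a1[i, ]), fmt(g$a2[i, ])),
                              collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read genotypes from long-form TSV
#'
#' Expects columns `id`, `deme`, `locus`, `allele1`, `allele2` (0 or NA =
#' missing).
#'
#' @param path TSV path.
#' @return a `genotype_matrix`.
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("id", "deme", "locus", "allele1", "allele2")
  if (!all(need %in% names(df))) {
    stop("TSV must have columns ", paste(need, collapse = ", "))
  }
  ids <- unique(df$id)
  loci <- unique(df$locus)
  a1 <- matrix(NA_integer_, length(ids), length(loci),
               dimnames = list(ids, loci))
  a2 <- a1
  ii <- match(df$id, ids); ll <- match(df$locus, loci)
  a1[cbind(ii, ll)] <- ifelse(df$allele1 %in% 0, NA_integer_,
                              as.integer(df$allele1))
  a2[cbind(ii, ll)] <- ifelse(df$allele2 %in% 0, NA_integer_,
                              as.integer(df$allele2))
  deme <- df$deme[match(ids, df$id)]
  genotype_matrix(ids, deme, a1, a2, loci)
}
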