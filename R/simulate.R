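#' Configuration for the synthetic matriline-deme world
#'
#' Defaults reproduce the conditions the analysis assumes for the eel
#' system: three matrilines sampled over three glass-eel cohorts with the
#' published per-deme sample sizes; per-matriline mutation-scaled sizes and
#' migration derived from the published mutation-scaled estimates (the 2012
#' cohort column, the most asymmetric one: effective gene flow into the
#' large matriline ~20 migrants/generation, reverse flow < 0.4); 22
#' microsatellites under stepwise mutation; a 355-bp mtDNA fragment whose
#' three founding haplotypes sit 1-2 transition steps apart; and allometric
#' length-weight phenotypes with cohort-specific condition shifts.
#'
#' @param seed integer seed recorded in the truth record.
#' @param cohorts cohort labels.
#' @param matrilines matriline labels.
#' @param n_per_deme matrix (cohort x matriline) of sample sizes.
#' @param theta per-matriline mutation-scaled sizes.
#' @param M mutation-scaled immigration matrix (`M[j, i]` into matriline i
#'   from j).
#' @param n_loci microsatellite locus count.
#' @param msat_model `"smm"` or `"tpm"`.
#' @param p_smm,var_tpm two-phase mutation parameters (used for `"tpm"`).
#' @param mt_len mtDNA fragment length (bp).
#' @param mt_theta within-matriline mutation-scaled mtDNA diversity.
#' @param kappa mtDNA transition:transversion rate ratio.
#' @param allom_b,allom_intercept log10 allometry slope and intercept
#'   (weight in mg, length in mm).
#' @param length_mean,length_sd per-cohort length distributions (mm).
#' @param kn_shift per-cohort multiplicative condition shifts.
#' @param pheno_sigma residual sd of log10(weight).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       cohorts = c("2010", "2011", "2012"),
                       matrilines = c("A", "B", "C"),
                       n_per_deme = rbind(`2010` = c(82, 35, 33),
                                          `2011` = c(58, 35, 32),
                                          `2012` = c(62, 32, 27)),
                       theta = c(A = 2.600, B = 2.067, C = 4.600),
                       M = NULL,
                       n_loci = 22L,
                       msat_model = c("smm", "tpm"),
                       p_smm = 0.10, var_tpm = 0.10,
                       mt_len = 355L, mt_theta = 1.0, kappa = 8,
                       allom_b = 3.397, allom_intercept = -3.813,
                       length_mean = c(`2010` = 66.59, `2011` = 69.10,
                                       `2012` = 71.60),
                       length_sd = 3.5,
                       kn_shift = c(`2010` = 0.944, `2011` = 0.993,
                                    `2012` = 1.061),
                       pheno_sigma = 0.04) {
  msat_model <- match.arg(msat_model)
  k <- length(matrilines)
  if (is.null(M)) {
    # invert Nem = M * theta_receiver / 4 from the published 2011 gene-flow
    # pattern (rows = source j, cols = receiver i); this is the one column
    # whose sizes and migrant numbers are jointly consistent with the
    # reported weak nuclear differentiation (F_ST of a few per mille)
    nem <- rbind(c(0, 11.195, 21.850),
                 c(14.084, 0, 19.550),
                 c(12.350, 8.738, 0))
    M <- 4 * nem / rep(theta, each = k)
    diag(M) <- 0
  }
  stopifnot(nrow(n_per_deme) == length(cohorts),
            ncol(n_per_deme) == k, all(theta > 0), all(M >= 0))
  structure(list(seed = as.integer(seed), cohorts = cohorts,
                 matrilines = matrilines, n_per_deme = n_per_deme,
                 theta = theta, M = M, n_loci = as.integer(n_loci),
                 msat_model = msat_model, p_smm = p_smm,
                 var_tpm = var_tpm, mt_len = as.integer(mt_len),
                 mt_theta = mt_theta, kappa = kappa, allom_b = allom_b,
                 allom_intercept = allom_intercept,
                 length_mean = length_mean, length_sd = length_sd,
                 kn_shift = kn_shift, pheno_sigma = pheno_sigma),
            class = "sim_config")
}

random_seq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

apply_steps <- function(seq, n_ts, kappa) {
  # apply n_ts transition steps at distinct random sites
  v <- strsplit(seq, "")[[1]]
  sites <- sample(length(v), n_ts)
  v[sites] <- c(A = "G", G = "A", C = "T", T = "C")[v[sites]]
  paste(v, collapse = "")
}

#' Simulate a matriline-structured dataset
#'
#' Generates (1) an mtDNA alignment: each matriline's sequences coalesce
#' within the matriline (no mtDNA exchange) from a founding haplotype,
#' founders one to two transition steps apart, with satellite haplotypes
#' arising by mutation; (2) a diploid microsatellite matrix: per cohort,
#' per-locus genealogies follow the structured coalescent across the
#' matriline demes with the configured asymmetric migration, so nuclear
#' gene flow crosses matrilines while mtDNA does not; (3) allometric
#' weight/length phenotypes with cohort-specific condition shifts. The
#' returned truth record carries every generating parameter.
#'
#' @param config a [sim_config()].
#' @return list with `alignment` (`mt_alignment`), `genotypes`
#'   (`genotype_matrix`, deme = cohort x matriline), `phenotypes`
#'   (data.frame id, weight, length, cohort), `truth` (config, founder
#'   haplotypes, per-individual matriline, realised migration counts).
#' @export
simulate_structured <- function(config = sim_config()) {
  set.seed(config$seed)
  k <- length(config$matrilines)
  if (any(config$n_per_deme <= 0)) stop("infeasible config: zero samples")
  founder <- character(k)
  founder[1L] <- random_seq(config$mt_len)
  if (k >= 2L) {
    founder[2L] <- apply_steps(founder[1L], 1L, config$kappa) # 1 bp off A
  }
  if (k >= 3L) {
    founder[3L] <- apply_steps(founder[1L], 2L, config$kappa) # 2 bp off A
  }
  if (k > 3L) {
    for (i in 4:k) founder[i] <- apply_steps(founder[1L], 2L, config$kappa)
  }
  # individual bookkeeping: cohorts are contemporary samples from the SAME
  # underlying matriline process, so genealogies are shared across cohorts
  # (one per matriline for mtDNA, one per locus for the nuclear genome);
  # independent per-cohort genealogies would fabricate between-cohort
  # differentiation that the sampled system does not show.
  idx <- expand.grid(cohort = seq_along(config$cohorts),
                     matriline = seq_len(k))
  ids <- character(); cohort <- character(); deme <- character()
  matriline <- character()
  for (r in seq_len(nrow(idx))) {
    ci <- idx$cohort[r]; mi <- idx$matriline[r]
    n_i <- config$n_per_deme[ci, mi]
    co <- config$cohorts[ci]
    new_ids <- sprintf("%s%s%03d", co, config$matrilines[mi],
                       length(ids) + seq_len(n_i))
    ids <- c(ids, new_ids)
    cohort <- c(cohort, rep(co, n_i))
    matriline <- c(matriline, rep(config$matrilines[mi], n_i))
    deme <- c(deme, rep(paste0(co, config$matrilines[mi]), n_i))
  }
  n_tot <- length(ids)
  # mtDNA: one within-matriline coalescent over all cohorts
  seqs <- character(n_tot)
  for (mi in seq_len(k)) {
    rows <- which(matriline == config$matrilines[mi])
    n_i <- length(rows)
    sq <- if (n_i == 1L) founder[mi] else {
      gen <- rkingman(n_i)
      seq_mutations(gen, founder[mi],
                    rate_per_seq = config$mt_theta / 2,
                    kappa = config$kappa)
    }
    seqs[rows] <- sq
  }
  # microsatellites: one structured-coalescent genealogy per locus over
  # the pooled matriline samples
  n_mig_realised <- 0L
  n_by_matriline <- vapply(seq_len(k), function(mi)
    sum(matriline == config$matrilines[mi]), 0L)
  ord_by_matriline <- order(match(matriline, config$matrilines))
  a1 <- a2 <- matrix(NA_integer_, n_tot, config$n_loci)
  for (l in seq_len(config$n_loci)) {
    gen <- rcoal_structured(2L * n_by_matriline, config$theta, config$M)
    n_mig_realised <- n_mig_realised + gen$n_mig
    al <- ladder_mutations(gen, rate = 1, root_allele = 50L,
                           model = config$msat_model,
                           p_smm = if (config$msat_model == "smm") 1 else
                             config$p_smm,
                           var_tpm = config$var_tpm)
    a1[ord_by_matriline, l] <- al[seq(1L, length(al), 2L)]
    a2[ord_by_matriline, l] <- al[seq(2L, length(al), 2L)]
  }
  aln <- mt_alignment(ids, seqs, cohorts = cohort)
  g <- genotype_matrix(ids, deme, a1, a2,
                       loci = sprintf("msat%02d", seq_len(config$n_loci)))
  # phenotypes: lognormal noise around the allometric curve (mg/mm scale)
  L <- stats::rnorm(length(ids), config$length_mean[cohort],
                    config$length_sd)
  L <- pmax(L, 40)
  lw <- config$allom_intercept + config$allom_b * log10(L) +
    log10(config$kn_shift[cohort]) +
    stats::rnorm(length(ids), 0, config$pheno_sigma)
  phen <- data.frame(id = ids, weight = 10^lw / 1000, length = L,
                     cohort = cohort, stringsAsFactors = FALSE)
  list(alignment = aln, genotypes = g, phenotypes = phen,
       truth = list(config = config, founders = founder,
                    matriline = stats::setNames(matriline, ids),
                    n_mig_realised = n_mig_realised))
}

#' Write the deterministic miniature fixture set
#'
#' A small, fixed-seed dataset (3 matrilines x 12 individuals in each of
#' 3 cohorts is overkill for unit tests, so one cohort of 3 x 12
#' individuals, 8 loci is written) used by the test-suite: FASTA alignment,
#' GenePop genotypes, phenotype TSV and an id-to-cohort map. Repeated calls
#' are byte-identical.
#'
#' @param outdir output directory (created if needed).
#' @param seed fixed seed; change only with the fixtures' consumers.
#' @return named character vector of file paths, invisibly.
#' @export
make_fixtures <- function(outdir, seed = 4059L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(
    seed = seed, cohorts = "2010",
    n_per_deme = rbind(`2010` = c(12, 12, 12)),
    theta = c(A = 1, B = 1, C = 1),
    M = matrix(c(0, 2, 2, 20, 0, 2, 20, 2, 0), 3, 3, byrow = TRUE),
    n_loci = 8L, mt_theta = 1.5,
    length_mean = c(`2010` = 66.59), kn_shift = c(`2010` = 1))
  sim <- simulate_structured(cfg)
  paths <- c(
    fasta = file.path(outdir, "mtdna.fasta"),
    genepop = file.path(outdir, "genotypes.gen"),
    phenotypes = file.path(outdir, "phenotypes.tsv"),
    cohorts = file.path(outdir, "cohorts.tsv"))
  write_alignment(sim$alignment, paths["fasta"])
  write_genepop(sim$genotypes, paths["genepop"],
                title = "matriflow synthetic fixture")
  utils::write.table(sim$phenotypes, paths["phenotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(id = sim$alignment$ids, cohort = sim$alignment$cohort),
    paths["cohorts"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
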