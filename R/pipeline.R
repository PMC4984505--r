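#' Run the full matriline-deme analysis pipeline
#'
#' Orchestrates sequences -> haplotype network -> matriline demes ->
#' microsatellite statistics -> migration-model comparison -> skylines ->
#' condition/HFC, writing a machine-readable JSON report plus TSV tables.
#' Every stochastic stage draws its seed deterministically from `seed`, so
#' the same inputs + seed give an identical report.
#'
#' @param fasta,cohorts_tsv,genepop,phenotypes_tsv input paths: aligned
#'   mtDNA FASTA, id-to-cohort TSV (columns id, cohort), GenePop genotypes
#'   (POP blocks in deme order), phenotype TSV (id, weight, length,
#'   cohort). Alternatively pass `sim` to run on synthetic data.
#' @param sim optional [sim_config()]; when given, inputs are generated
#'   in-memory and the file arguments are ignored.
#' @param stages character subset of `c("mtdna", "network", "msat",
#'   "migration", "skyline", "condition")`.
#' @param outdir output directory for the report files (`NULL` = no files).
#' @param seed master seed.
#' @param n_perm permutation budget for the frequency tests.
#' @param epsilon,tv_weight median-joining network parameters.
#' @param kappa fixed transition:transversion ratio for HKY distances.
#' @param rate,rate_sd substitution rate (per site per Myr) used only to
#'   convert skyline time axes.
#' @param migration_budget list with `steps`, `thin`, `replicates` for
#'   [sample_posterior()].
#' @param theta_prior,m_prior priors for the migration stage.
#' @return the report (list), invisibly when writing files.
#' @export
run_pipeline <- function(fasta = NULL, cohorts_tsv = NULL, genepop = NULL,
                         phenotypes_tsv = NULL, sim = NULL,
                         stages = c("mtdna", "network", "msat",
                                    "condition"),
                         outdir = NULL, seed = 1L, n_perm = 1000L,
                         epsilon = 35, tv_weight = 8, kappa = 8,
                         rate = 0.946e-5, rate_sd = 0.196e-5,
                         migration_budget = list(steps = 200L, thin = 20L,
                                                 replicates = 2L),
                         theta_prior = c(0, 200), m_prior = c(0, 1000)) {
  stages <- match.arg(stages, c("mtdna", "network", "msat", "migration",
                                "skyline", "condition"),
                      several.ok = TRUE)
  report <- list(meta = list(seed = seed, stages = stages,
                             epsilon = epsilon, tv_weight = tv_weight,
                             kappa = kappa, rate = rate,
                             timestamp = "deterministic"))
  if (!is.null(sim)) {
    simdat <- simulate_structured(sim)
    aln <- simdat$alignment
    g <- simdat$genotypes
    phen <- simdat$phenotypes
  } else {
    aln <- NULL; g <- NULL; phen <- NULL
    if (any(c("mtdna", "network", "skyline") %in% stages)) {
      if (is.null(fasta)) stop("stage needs a FASTA input")
      cmap <- NULL
      if (!is.null(cohorts_tsv)) {
        ct <- utils::read.table(cohorts_tsv, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
        cmap <- stats::setNames(as.character(ct$cohort), ct$id)
      }
      aln <- read_alignment(fasta, cohort_map = cmap)
    }
    if (any(c("msat", "migration") %in% stages)) {
      if (is.null(genepop)) stop("stage needs a GenePop input")
      g <- read_genepop(genepop)
    }
    if ("condition" %in% stages) {
      if (is.null(phenotypes_tsv)) stop("stage needs a phenotype input")
      phen <- utils::read.table(phenotypes_tsv, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    }
  }
  assignment <- NULL
  demes_df <- NULL
  if ("mtdna" %in% stages) {
    cohorts <- sort(unique(aln$cohort))
    tabs <- lapply(cohorts, function(co) collapse_haplotypes(aln, co))
    report$mtdna <- list(
      site_count = aln$site_count,
      per_cohort = data.frame(
        cohort = cohorts,
        n = vapply(tabs, `[[`, 0L, "n"),
        n_hap = vapply(tabs, `[[`, 0L, "n_hap"),
        s = vapply(tabs, `[[`, 0L, "s_sites"),
        hd = round(vapply(tabs, `[[`, 0, "hd"), 3),
        pi = round(vapply(tabs, `[[`, 0, "pi"), 5)))
    if (length(cohorts) >= 2L) {
      pf <- list()
      for (i in seq_len(length(cohorts) - 1L)) {
        for (j in (i + 1L):length(cohorts)) {
          keep <- aln$cohort %in% cohorts[c(i, j)]
          sub <- subset_alignment(aln, keep)
          r <- mtdna_fst(sub, n_perm = n_perm, seed = seed + i * 13L + j)
          pf[[length(pf) + 1L]] <- data.frame(
            cohort1 = cohorts[i], cohort2 = cohorts[j],
            fst = r$fst, p = r$p)
        }
      }
      report$mtdna$pairwise_fst <- do.call(rbind, pf)
    }
  }
  if ("network" %in% stages) {
    tb <- collapse_haplotypes(aln)
    net <- median_joining(tb, epsilon = epsilon, tv_weight = tv_weight)
    net <- mp_prune(net)
    assignment <- assign_matrilines(net)
    demes_df <- deme_labels(assignment, aln)
    main_bp <- outer(assignment$main_seqs, assignment$main_seqs,
                     Vectorize(bp_divergence))
    report$network <- list(
      n_observed = sum(net$observed),
      n_medians = sum(!net$observed),
      n_satellites = sum(net$observed) - length(assignment$mains),
      n_shortest_trees = length(net$trees),
      trees_truncated = isTRUE(net$trees_truncated),
      tree_length = net$tree_length,
      main_bp_divergence = max(main_bp),
      matriline_counts = as.list(table(demes_df$matriline)),
      deme_counts = as.list(table(demes_df$deme)),
      assignment = assignment$table)
    # align genotype/phenotype demes with the inferred matrilines
    if (!is.null(g) && all(aln$ids %in% g$ids)) {
      m <- demes_df$deme[match(g$ids, demes_df$id)]
      g$deme[!is.na(m)] <- m[!is.na(m)]
    }
  }
  if ("msat" %in% stages) {
    rep_div <- diversity_report(g)
    diag_cor <- tryCatch(rir_rhl_diagnostic(rep_div),
                         error = function(e) NULL)
    nulls <- vapply(seq_along(g$loci), function(li)
      tryCatch(null_allele_em(g, li), error = function(e) NA_real_), 0)
    report$msat <- list(
      per_deme = rep_div,
      null_alleles = data.frame(locus = g$loci, p_null = nulls),
      global_fst = global_fst(g),
      rir_rhl = diag_cor)
    demes <- sort(unique(g$deme))
    grp <- stats::setNames(substr(demes, 1L, nchar(demes) - 1L), demes)
    if (length(unique(grp)) >= 2L && length(demes) > length(unique(grp))) {
      report$msat$amova <- amova(g, grp, n_perm = min(n_perm, 200L),
                                 seed = seed + 99L)
    }
  }
  if ("migration" %in% stages) {
    gm <- g
    # demes = matrilines pooled over cohorts (last label character)
    gm$deme <- substr(gm$deme, nchar(gm$deme), nchar(gm$deme))
    # the desk-scale sampler's genealogy moves mix reliably only for small
    # per-locus gene counts; subsample each deme (see the vignette)
    keep <- unlist(lapply(split(seq_along(gm$ids), gm$deme), function(ix)
      ix[seq_len(min(3L, length(ix)))]))
    gm <- subset_genotypes(gm, sort(keep))
    mI <- deme_model("panmixia", theta_prior = theta_prior,
                     m_prior = m_prior)
    mII <- deme_model("island", k = length(unique(gm$deme)),
                      theta_prior = theta_prior, m_prior = m_prior)
    rI <- sample_posterior(gm, mI, steps = migration_budget$steps,
                           thin = migration_budget$thin,
                           replicates = migration_budget$replicates,
                           seed = seed + 1000L)
    rII <- sample_posterior(gm, mII, steps = migration_budget$steps,
                            thin = migration_budget$thin,
                            replicates = migration_budget$replicates,
                            seed = seed + 2000L)
    cmp <- compare_models(rI, rII)
    report$migration <- list(
      mlog_panmixia = rI$mlog, mlog_island = rII$mlog,
      lbf = cmp$lbf, support = cmp$support,
      theta_mode = rII$theta_mode,
      nem = effective_migrants(rII))
  }
  if ("skyline" %in% stages) {
    src <- if (!is.null(demes_df)) demes_df$matriline else {
      if (!is.null(sim)) unname(simdat$truth$matriline[aln$ids]) else NULL
    }
    if (is.null(src)) stop("skyline stage needs the network stage (or sim)")
    sks <- list()
    for (m in sort(unique(stats::na.omit(src)))) {
      sub <- subset_alignment(aln, which(src == m))
      if (length(sub$ids) < 5L) next
      prof <- tryCatch(
        matriline_skyline(sub, kappa = kappa, epsilon = "aicc",
                          rate = rate, rate_sd = rate_sd),
        error = function(e) NULL)
      if (!is.null(prof)) sks[[m]] <- as.data.frame(prof)
    }
    report$skyline <- sks
  }
  if ("condition" %in% stages) {
    fit <- allometry_fit(phen)
    kn <- condition_index(phen$weight, phen$length, fit$a, fit$b)
    kn_by <- tapply(kn, phen$cohort, function(x)
      c(mean = mean(x), sd = stats::sd(x)))
    report$condition <- list(
      a = fit$a, b = fit$b, r = fit$r,
      by_group = fit$by_group,
      ancova_t = if (!is.null(fit$ancova)) data.frame(
        term = rownames(fit$ancova),
        t = fit$ancova[["t value"]],
        p = fit$ancova[["Pr(>|t|)"]]),
      kn_by_cohort = data.frame(
        cohort = names(kn_by),
        mean = vapply(kn_by, `[[`, 0, "mean"),
        sd = vapply(kn_by, `[[`, 0, "sd")))
    src <- if (!is.null(demes_df)) demes_df else if (!is.null(sim)) {
      data.frame(id = names(simdat$truth$matriline),
                 matriline = unname(simdat$truth$matriline),
                 stringsAsFactors = FALSE)
    } else NULL
    if (!is.null(src) && !is.null(g)) {
      ir <- internal_relatedness(g)
      hl <- homozygosity_by_loci(g)
      df <- data.frame(id = phen$id, kn = kn, cohort = phen$cohort,
                       stringsAsFactors = FALSE)
      df$ir <- ir[df$id]
      df$hl <- hl[df$id]
      df$matriline <- src$matriline[match(df$id, src$id)]
      h <- tryCatch(hfc_model(df), error = function(e) NULL)
      if (!is.null(h)) {
        report$condition$hfc <- data.frame(
          term = rownames(h$anova), df = h$anova$Df,
          f = h$anova[["F value"]], p = h$anova[["Pr(>F)"]])
      }
    }
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "rows", force = TRUE)
    if (!is.null(demes_df)) {
      utils::write.table(demes_df, file.path(outdir, "demes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(report))
  }
  report
}
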