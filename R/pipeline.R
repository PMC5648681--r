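#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline]: input
#' sources (files or simulation specs), per-stage Monte-Carlo settings, the
#' global seed every stochastic stage derives its own seed from, and the
#' output directory.  Genotypes may come from a GENEPOP file
#' (`genotype_path`) or a [genotype_sim_spec]; experiment records from CSV
#' files (`clutch_path`/`brood_path`) or an [experiment_sim_spec]; climate
#' series from a CSV (`climate_path`, columns `site`, `year`, `month`,
#' variables) or a list of per-site [climate_sim_spec]s.  Site descriptors
#' (`flow`, `deep_water`, `altitude` per site) are required for the
#' environmental ordination.
#'
#' The Monte-Carlo defaults here are desk-scale so a full bundle builds in
#' minutes; the single-test defaults of [hwe_exact_test] and [ld_test]
#' retain the classic heavyweight settings.
#'
#' @param genotype_spec,genotype_path genotype source (exactly one).
#' @param experiment_spec,clutch_path,brood_path experiment source.
#' @param climate_specs,climate_path climate source.
#' @param site_info data.frame with columns `site`, `flow`, `deep_water`,
#'   `altitude` (and optionally `habitat` for the habitat contrast).
#' @param seed global integer seed.
#' @param out_dir output directory (created if absent).
#' @param n_perm permutations for the Q_ST-F_ST comparison.
#' @param hwe_steps,hwe_dememorization HWE chain settings.
#' @param ld_batches,ld_iterations,ld_dememorization LD test settings.
#' @param n_bins Colwell state bins.
#' @param growth_filter inclusive brood-size window for growth analyses.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotype_spec = NULL, genotype_path = NULL,
                            experiment_spec = NULL, clutch_path = NULL,
                            brood_path = NULL,
                            climate_specs = NULL, climate_path = NULL,
                            site_info = NULL,
                            seed = 1L, out_dir = tempfile("qstfst_run_"),
                            n_perm = 999L,
                            hwe_steps = 2e4, hwe_dememorization = 2e3,
                            ld_batches = 10L, ld_iterations = 100L,
                            ld_dememorization = 100L,
                            n_bins = 10L, growth_filter = c(5L, 19L)) {
  if (is.null(genotype_spec) && is.null(genotype_path))
    stop("config gap: no genotype input file and no genotype simulation spec")
  if (is.null(experiment_spec) && (is.null(clutch_path) || is.null(brood_path)))
    stop("config gap: no experiment input files and no experiment simulation spec")
  if (is.null(climate_specs) && is.null(climate_path))
    stop("config gap: no climate input file and no climate simulation specs")
  seed <- .assert_scalar_count(seed, "seed", min = 0L)
  structure(list(
    genotype_spec = genotype_spec, genotype_path = genotype_path,
    experiment_spec = experiment_spec, clutch_path = clutch_path,
    brood_path = brood_path,
    climate_specs = climate_specs, climate_path = climate_path,
    site_info = site_info,
    seed = seed, out_dir = out_dir, n_perm = as.integer(n_perm),
    hwe_steps = hwe_steps, hwe_dememorization = hwe_dememorization,
    ld_batches = as.integer(ld_batches),
    ld_iterations = as.integer(ld_iterations),
    ld_dememorization = as.integer(ld_dememorization),
    n_bins = as.integer(n_bins), growth_filter = growth_filter
  ), class = "pipeline_config")
}

#' Default fully synthetic pipeline configuration
#'
#' An 8-population study: Balding-Nichols genotypes at 7 loci, the
#' 8 x 4 x 4 half-sib breeding design, and one 15-year monthly climate
#' series per population with half the sites lake-like (non-flowing, close
#' to deep water, low altitude, damped seasonal temperature swing) and half
#' peripheral (flowing, distant from deep water, higher altitude, stronger
#' seasonality).
#'
#' @param seed global seed.
#' @param out_dir output directory.
#' @param ... further arguments passed to [pipeline_config].
#' @return A `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L,
                                    out_dir = tempfile("qstfst_run_"),
                                    ...) {
  K <- 8L
  sites <- paste0("Pop", seq_len(K))
  lake <- seq_len(K) <= 4L
  cspecs <- lapply(seq_len(K), function(i) {
    amp <- if (lake[i]) 2.5 else 5.5
    base <- if (lake[i]) 24 else 20
    climate_sim_spec(
      n_years = 15L,
      monthly_profile = list(
        temperature = base + amp * sin(2 * pi * (seq_len(12) - 4) / 12),
        precipitation = pmax(0, 150 + (if (lake[i]) 120 else 160) *
                               cos(2 * pi * (seq_len(12) - 1) / 12))),
      noise_sd = c(temperature = 0.8, precipitation = 40),
      site = sites[i],
      seed = derive_seed(seed, paste0("climate:", sites[i])))
  })
  site_info <- data.frame(
    site = sites,
    flow = !lake,
    deep_water = lake,
    altitude = ifelse(lake, 480 + 10 * seq_len(K), 900 + 60 * seq_len(K)),
    habitat = ifelse(lake, "lake", "peripheral"),
    stringsAsFactors = FALSE)
  pipeline_config(
    genotype_spec = genotype_sim_spec(
      n_populations = K, n_per_pop = 20L, n_loci = 7L,
      alleles_per_locus = 10L, divergence_f = 0.10,
      seed = derive_seed(seed, "genotypes")),
    experiment_spec = experiment_sim_spec(
      n_populations = K, seed = derive_seed(seed, "experiment")),
    climate_specs = cspecs, site_info = site_info,
    seed = seed, out_dir = out_dir, ...)
}

#' Run the full divergence-analysis pipeline
#'
#' Executes simulate (where specs are configured) -> population genetics ->
#' life-history statistics -> variance components / Q_ST -> environmental
#' predictability -> Q_ST-F_ST comparison, writing every stage output as a
#' plain file (CSV/TSV/JSON) under `config$out_dir` plus a machine-readable
#' `summary.json` and a `run_log.txt`.  The bundle is byte-identical across
#' runs with an identical configuration and seed.  A stage failure halts
#' the run with the stage name and cause; outputs of completed stages are
#' retained alongside a `FAILED_<stage>` marker file.
#'
#' @param config a [pipeline_config].
#' @return Invisibly, a list with the main results (`global_fst`,
#'   `fst_matrix`, `het`, `ld`, `qst_matrices`, `anova`, `tukey`,
#'   `lsmeans`, `tradeoff`, `colwell`, `comparisons`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run_log.txt")
  cat("qstfst pipeline run\n", file = logf)
  logmsg <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = logf, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    logmsg("stage %s ...", name)
    tryCatch(expr, error = function(e) {
      file.create(file.path(out, paste0("FAILED_", name)))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  logmsg("seed: %d", config$seed)

  ## ---- inputs ----------------------------------------------------------
  gt <- stage("genotypes", {
    if (!is.null(config$genotype_path)) read_genepop(config$genotype_path)
    else {
      g <- simulate_genotypes(config$genotype_spec)
      write_genepop(g, file.path(out, "genotypes.gen"))
      g
    }
  })
  expd <- stage("experiment", {
    if (!is.null(config$experiment_spec)) {
      e <- simulate_experiment(config$experiment_spec)
      write.csv(e$clutches, file.path(out, "clutches.csv"), row.names = FALSE)
      write.csv(e$broods, file.path(out, "broods.csv"), row.names = FALSE)
      e
    } else {
      list(clutches = read.csv(config$clutch_path),
           broods = read.csv(config$brood_path))
    }
  })
  climate <- stage("climate", {
    if (!is.null(config$climate_specs)) {
      cl <- do.call(rbind, lapply(config$climate_specs, simulate_climate))
      write.csv(cl, file.path(out, "climate.csv"), row.names = FALSE)
      cl
    } else read.csv(config$climate_path)
  })
  # JSON sidecar of the specs actually used
  specs <- list(seed = config$seed,
                genotype_spec = config$genotype_spec,
                experiment_spec = config$experiment_spec,
                climate_specs = config$climate_specs)
  jsonlite::write_json(.despec(specs), file.path(out, "specs_used.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  ## ---- population genetics ---------------------------------------------
  pg <- stage("popgen", {
    het <- het_stats(gt, hwe = TRUE, chain_steps = config$hwe_steps,
                     dememorization = config$hwe_dememorization,
                     seed = derive_seed(config$seed, "hwe"))
    write.csv(het, file.path(out, "het_stats.csv"), row.names = FALSE)
    fstm <- pairwise_fst(gt)
    write_dist_matrix(fstm, file.path(out, "fst_pairwise.tsv"))
    gfst <- global_fst(gt)
    lp <- combn(length(gt$loci), 2)
    ld <- lapply(seq_len(ncol(lp)), function(i) {
      lt <- ld_test(gt, gt$loci[lp[, i]], batches = config$ld_batches,
                    iterations_per_batch = config$ld_iterations,
                    dememorization = config$ld_dememorization,
                    seed = derive_seed(config$seed, paste0("ld:", i)))
      data.frame(locus1 = gt$loci[lp[1, i]], locus2 = gt$loci[lp[2, i]],
                 fisher_chisq = lt$fisher_chisq, fisher_df = lt$fisher_df,
                 fisher_p = lt$fisher_p)
    })
    ld <- do.call(rbind, ld)
    write.csv(ld, file.path(out, "ld_tests.csv"), row.names = FALSE)
    pca <- genotype_pca(gt)
    write.csv(data.frame(id = rownames(pca$scores),
                         population = as.character(pca$population),
                         pca$scores[, seq_len(min(4, ncol(pca$scores))),
                                    drop = FALSE]),
              file.path(out, "genotype_pca_scores.csv"), row.names = FALSE)
    list(het = het, fst_matrix = fstm, global_fst = gfst, ld = ld, pca = pca)
  })

  ## ---- life-history statistics -----------------------------------------
  lh <- stage("lifehist", {
    cl <- expd$clutches; br <- expd$broods
    br$growth35 <- brood_growth(br, 0, 35)
    br$growth70 <- brood_growth(br, 0, 70)
    br$log10_density_0_35 <- log10(br$density_0_35)
    br$log10_density_0_70 <- log10((br$density_0_35 + br$density_35_70) / 2)
    grow <- filter_growth_broods(br, config$growth_filter[1],
                                 config$growth_filter[2])
    models <- list(
      clutch_size = fit_trait_glm(cl, "clutch_size", "female_tl",
                                  include_interaction = TRUE),
      mean_egg_mass = fit_trait_glm(cl, "mean_egg_mass", "female_tl",
                                    include_interaction = TRUE),
      total_egg_mass = fit_trait_glm(cl, "total_egg_mass", "female_tl",
                                     include_interaction = TRUE),
      brood_size = fit_trait_glm(br, "brood_size", "female_tl",
                                 include_interaction = TRUE),
      incubation_days = fit_trait_glm(br, "incubation_days", "female_tl",
                                      include_interaction = TRUE),
      fry_len_day0 = fit_trait_glm(br, "fry_len_day0", "female_tl",
                                   include_interaction = TRUE),
      growth35 = fit_trait_glm(grow, "growth35", "log10_density_0_35"),
      growth70 = fit_trait_glm(grow, "growth70", "log10_density_0_70"))
    av <- do.call(rbind, lapply(names(models), function(nm) {
      cbind(response = nm, models[[nm]]$anova)
    }))
    write.csv(av, file.path(out, "anova_tables.csv"), row.names = FALSE)
    tk <- lapply(models, tukey_hsd)
    tkdf <- do.call(rbind, lapply(names(tk), function(nm) {
      p <- tk[[nm]]$p
      idx <- which(lower.tri(p), arr.ind = TRUE)
      data.frame(response = nm, pop1 = rownames(p)[idx[, 1]],
                 pop2 = colnames(p)[idx[, 2]], p_adj = p[idx])
    }))
    write.csv(tkdf, file.path(out, "tukey_pairwise.csv"), row.names = FALSE)
    lsm <- do.call(rbind, lapply(names(models), function(nm) {
      cbind(response = nm, lsmeans_populations(models[[nm]]))
    }))
    write.csv(lsm, file.path(out, "lsmeans.csv"), row.names = FALSE)
    # offspring size-number trade-off on size-corrected values
    sc_cs <- size_corrected(cl, "clutch_size", "female_tl")
    sc_em <- cl$mean_egg_mass
    tradeoff <- trait_correlation(sc_cs, sc_em)
    write.csv(tradeoff, file.path(out, "tradeoff.csv"), row.names = FALSE)
    # trait PCAs on residual tables
    t1 <- data.frame(
      clutch_size = sc_cs,
      egg_mass = size_corrected(cl, "mean_egg_mass", "female_tl"),
      egg_invest = size_corrected(cl, "total_egg_mass", "female_tl"))
    pca1 <- trait_pca(t1)
    t2 <- data.frame(
      incubation = grow$incubation_days,
      fry_len_release = grow$fry_len_day0,
      brood_size = size_corrected(grow, "brood_size", "female_tl"),
      growth35 = size_corrected(grow, "growth35", "log10_density_0_35"),
      growth70 = size_corrected(grow, "growth70", "log10_density_0_70"))
    pca2 <- trait_pca(t2)
    write.csv(data.frame(variable = rownames(pca1$loadings),
                         round(pca1$loadings, 6)),
              file.path(out, "trait_pca_clutch_loadings.csv"),
              row.names = FALSE)
    write.csv(data.frame(variable = rownames(pca2$loadings),
                         round(pca2$loadings, 6)),
              file.path(out, "trait_pca_brood_loadings.csv"),
              row.names = FALSE)
    list(models = models, tukey = tk, lsmeans = lsm, tradeoff = tradeoff,
         pca_clutch = pca1, pca_brood = pca2, broods_aug = br, grow = grow)
  })

  ## ---- variance components and Q_ST ------------------------------------
  qg <- stage("quantgen", {
    br <- lh$broods_aug
    grow <- lh$grow
    qtraits <- list(
      brood_size = list(data = br, cov = "female_tl"),
      incubation_days = list(data = br, cov = NULL),
      fry_len_day0 = list(data = br, cov = NULL),
      growth35 = list(data = grow, cov = "log10_density_0_35"),
      growth70 = list(data = grow, cov = "log10_density_0_70"))
    qmats <- lapply(names(qtraits), function(tr) {
      qm <- pairwise_qst(qtraits[[tr]]$data, tr, qtraits[[tr]]$cov)
      write_dist_matrix(qm, file.path(out, paste0("qst_", tr, ".tsv")))
      qm
    })
    names(qmats) <- names(qtraits)
    gvc <- lapply(names(qtraits), function(tr) {
      fit_nested_ranef(qtraits[[tr]]$data, tr, qtraits[[tr]]$cov)
    })
    names(gvc) <- names(qtraits)
    jsonlite::write_json(
      lapply(gvc, function(v) v[c("V_b", "V_male", "V_res", "V_w", "method")]),
      file.path(out, "variance_components.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(qst_matrices = qmats, components = gvc)
  })

  ## ---- environmental predictability ------------------------------------
  ev <- stage("envpred", {
    si <- config$site_info
    if (is.null(si)) stop("site_info required for the environment stage")
    feats <- lapply(seq_len(nrow(si)), function(i) {
      s <- climate[climate$site == si$site[i], , drop = FALSE]
      if (nrow(s) == 0L) stop("no climate series for site ", si$site[i])
      summarize_site(s, si$flow[i], si$deep_water[i], si$altitude[i],
                     n_bins = config$n_bins)
    })
    fm <- do.call(rbind, feats)
    rownames(fm) <- si$site
    write.csv(data.frame(site = si$site, fm), file.path(out, "site_features.csv"),
              row.names = FALSE)
    cw <- fm[, grep("_(C|M|P)$", colnames(fm)), drop = FALSE]
    write.csv(data.frame(site = si$site, cw), file.path(out, "colwell.csv"),
              row.names = FALSE)
    pca <- env_pca(fm)
    list(features = fm, colwell = cw, pca = pca)
  })

  ## ---- Q_ST vs F_ST -----------------------------------------------------
  cmp <- stage("compare", {
    res <- lapply(names(qg$qst_matrices), function(tr) {
      spearman_permutation(qg$qst_matrices[[tr]], pg$fst_matrix,
                           n_perm = config$n_perm,
                           seed = derive_seed(config$seed, paste0("cmp:", tr)),
                           trait = tr)
    })
    names(res) <- names(qg$qst_matrices)
    pairdf <- do.call(rbind, lapply(res, function(r)
      cbind(trait = r$trait, r$pairs)))
    write.csv(pairdf, file.path(out, "comparison_pairs.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      lapply(res, function(r) r[c("trait", "rho", "p", "n_perm", "unit",
                                  "n_pairs")]),
      file.path(out, "comparison.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    res
  })

  ## ---- summary ----------------------------------------------------------
  summary <- list(
    seed = config$seed,
    global_fst = pg$global_fst,
    fst_pairwise = .mat2list(pg$fst_matrix),
    mean_h_e = mean(pg$het$H_E, na.rm = TRUE),
    n_hwe_significant = sum(pg$het$p_hwe < 0.05, na.rm = TRUE),
    ld_fisher_p = setNames(pg$ld$fisher_p,
                           paste(pg$ld$locus1, pg$ld$locus2, sep = "|")),
    anova = lapply(lh$models, function(m) m$anova),
    tradeoff = lh$tradeoff,
    qst = lapply(qg$qst_matrices, .mat2list),
    variance_components = lapply(qg$components, function(v)
      v[c("V_b", "V_male", "V_res", "V_w")]),
    colwell = apply(ev$colwell, 2, unname, simplify = FALSE),
    comparison = lapply(cmp, function(r) list(rho = r$rho, p = r$p)))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logmsg("done; outputs in %s", out)
  invisible(list(global_fst = pg$global_fst, fst_matrix = pg$fst_matrix,
                 het = pg$het, ld = pg$ld, genotype_pca = pg$pca,
                 qst_matrices = qg$qst_matrices,
                 components = qg$components,
                 models = lh$models, tukey = lh$tukey, lsmeans = lh$lsmeans,
                 tradeoff = lh$tradeoff, env = ev, comparisons = cmp,
                 summary = summary, paths = out))
}

.mat2list <- function(m) {
  v <- lower_pairs(m)
  as.list(v)
}

.despec <- function(x) {
  if (inherits(x, c("genotype_sim_spec", "experiment_sim_spec",
                    "climate_sim_spec"))) {
    return(lapply(unclass(x), .despec))
  }
  if (is.list(x)) return(lapply(x, .despec))
  if (is.matrix(x)) return(apply(x, 1, as.list, simplify = FALSE))
  x
}
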