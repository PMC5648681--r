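#' Specification for a common-garden breeding experiment simulation
#'
#' Defines a two-part simulated experiment mirroring the structure the
#' analysis assumes: (1) clutch records — one spawning per female, with
#' clutch size, mean dried egg mass and total egg investment, and a
#' configurable negative correlation (`tradeoff_rho`) between size-corrected
#' clutch size and egg mass; (2) brood records — a nested half-sib design
#' (`sires_per_pop` sires each mated to `dams_per_sire` dams in every
#' population) with brood size, incubation time and fry lengths at release
#' and days 35/70, density-dependent growth, and broods truncated at
#' `brood_cap` individuals for rearing.
#'
#' Every trait value is built as population effect (variance `v_pop`) +
#' sire effect (variance `v_male`, brood traits only) + residual (variance
#' `v_res`) + `tl_slope * (TL - mean TL)`; cross-trait correlations are
#' induced by drawing the population, sire and residual deviations from
#' multivariate normals sharing one correlation matrix, so the configured
#' correlations survive any variance partition.  Female total length is
#' log-normal (positive support), and the slope acts on centred TL so
#' population means stay interpretable.
#'
#' @param n_populations populations in the design.
#' @param sires_per_pop sires per population (brood experiment).
#' @param dams_per_sire dams mated per sire.
#' @param clutches_per_pop females per population in the clutch experiment.
#' @param trait_means named numeric vector overriding grand trait means
#'   (names among `clutch_size`, `mean_egg_mass`, `brood_size`,
#'   `incubation_days`, `fry_len_release`, `growth35`, `growth70`).
#' @param population_trait_means optional matrix (populations x traits) of
#'   configured per-population means; defaults to the grand means everywhere
#'   (population divergence then comes only from the random `v_pop` draws).
#' @param v_pop,v_male,v_res variance components (trait units squared);
#'   scalar values apply to every trait, or supply named vectors for
#'   per-trait control.  Must be non-negative.
#' @param tl_slope trait units per mm of female TL; scalar or named vector.
#' @param tradeoff_rho correlation in `[-1, 0]` between size-corrected
#'   clutch size and mean egg mass.
#' @param brood_cor length-2 numeric: correlation of brood size with
#'   incubation time and with fry release length (both conventionally
#'   negative).
#' @param density_slope mm of growth per log10(individuals) of rearing
#'   density (negative: denser broods grow less).
#' @param brood_cap maximum fry retained per brood for rearing (>= 1).
#' @param female_tl_meanlog,female_tl_sdlog log-normal parameters of female
#'   total length (mm).
#' @param seed integer seed.
#' @return A list of class `experiment_sim_spec`.
#' @export
experiment_sim_spec <- function(n_populations = 8L, sires_per_pop = 4L,
                                dams_per_sire = 4L, clutches_per_pop = 16L,
                                trait_means = NULL,
                                population_trait_means = NULL,
                                v_pop = NULL, v_male = NULL, v_res = NULL,
                                tl_slope = NULL, tradeoff_rho = -0.4,
                                brood_cor = c(-0.2, -0.25),
                                density_slope = -2,
                                brood_cap = 32L,
                                female_tl_meanlog = log(85),
                                female_tl_sdlog = 0.08,
                                seed = 1L) {
  .assert_scalar_count(n_populations, "n_populations")
  .assert_scalar_count(sires_per_pop, "sires_per_pop")
  .assert_scalar_count(dams_per_sire, "dams_per_sire")
  .assert_scalar_count(clutches_per_pop, "clutches_per_pop")
  .assert_scalar_count(brood_cap, "brood_cap")
  if (abs(tradeoff_rho) > 1) stop("|tradeoff_rho| must be <= 1")
  if (tradeoff_rho > 0) stop("'tradeoff_rho' is a trade-off: must be <= 0")
  if (length(brood_cor) != 2L || any(abs(brood_cor) > 1))
    stop("'brood_cor' must be two correlations in [-1, 1]")

  traits <- c("clutch_size", "mean_egg_mass", "brood_size",
              "incubation_days", "fry_len_release", "growth35", "growth70")
  means <- c(clutch_size = 35, mean_egg_mass = 0.020, brood_size = 18,
             incubation_days = 17, fry_len_release = 10.5,
             growth35 = 5, growth70 = 12)
  vp <- c(clutch_size = 25, mean_egg_mass = 4e-6, brood_size = 6,
          incubation_days = 1.0, fry_len_release = 0.25,
          growth35 = 0.5, growth70 = 1.0)
  vm <- c(clutch_size = 0, mean_egg_mass = 0, brood_size = 2,
          incubation_days = 0.3, fry_len_release = 0.08,
          growth35 = 0.15, growth70 = 0.3)
  vr <- c(clutch_size = 49, mean_egg_mass = 9e-6, brood_size = 12,
          incubation_days = 1.5, fry_len_release = 0.3,
          growth35 = 0.6, growth70 = 1.2)
  sl <- c(clutch_size = 0.8, mean_egg_mass = 5e-5, brood_size = 0.5,
          incubation_days = 0, fry_len_release = 0,
          growth35 = 0, growth70 = 0)

  merge_par <- function(def, usr, name) {
    if (is.null(usr)) return(def)
    if (is.null(names(usr))) {
      if (length(usr) != 1L)
        stop("'", name, "' must be scalar or a named vector")
      def[] <- usr
    } else {
      bad <- setdiff(names(usr), traits)
      if (length(bad)) stop("unknown trait(s) in '", name, "': ",
                            paste(bad, collapse = ", "))
      def[names(usr)] <- usr
    }
    def
  }
  means <- merge_par(means, trait_means, "trait_means")
  vp <- merge_par(vp, v_pop, "v_pop")
  vm <- merge_par(vm, v_male, "v_male")
  vr <- merge_par(vr, v_res, "v_res")
  sl <- merge_par(sl, tl_slope, "tl_slope")
  if (any(c(vp, vm, vr) < 0)) stop("variance components must be >= 0")

  if (!is.null(population_trait_means)) {
    population_trait_means <- as.matrix(population_trait_means)
    if (nrow(population_trait_means) != n_populations ||
        is.null(colnames(population_trait_means)) ||
        !all(colnames(population_trait_means) %in% traits))
      stop("'population_trait_means' must be populations x named traits")
  }

  structure(list(
    n_populations = as.integer(n_populations),
    sires_per_pop = as.integer(sires_per_pop),
    dams_per_sire = as.integer(dams_per_sire),
    clutches_per_pop = as.integer(clutches_per_pop),
    trait_means = means, population_trait_means = population_trait_means,
    v_pop = vp, v_male = vm, v_res = vr, tl_slope = sl,
    tradeoff_rho = tradeoff_rho, brood_cor = brood_cor,
    density_slope = density_slope, brood_cap = as.integer(brood_cap),
    female_tl_meanlog = female_tl_meanlog,
    female_tl_sdlog = female_tl_sdlog, seed = as.integer(seed)
  ), class = "experiment_sim_spec")
}

# draw n rows from a zero-mean MVN with correlation matrix R (chol-based)
.rmvn_cor <- function(n, R) {
  L <- tryCatch(chol(R), error = function(e)
    stop("configured trait correlations are not positive definite"))
  z <- matrix(rnorm(n * nrow(R)), n, nrow(R))
  z %*% L
}

#' Simulate a common-garden breeding experiment
#'
#' Generates clutch records (one per female) and brood records (one per
#' sire x dam family) per the design in an [experiment_sim_spec].  The
#' default design of 8 populations x 4 sires x 4 dams yields 128 families.
#'
#' @param spec an [experiment_sim_spec].
#' @return A list of class `experiment_sim` with data.frames `clutches`
#'   (`female_id`, `population`, `female_tl`, `postspawn_mass`,
#'   `clutch_size`, `mean_egg_mass`, `total_egg_mass`) and `broods`
#'   (`female_id`, `sire_id`, `population`, `female_tl`, `brood_size`,
#'   `incubation_days`, `fry_len_day0`, `fry_len_day35`, `fry_len_day70`,
#'   `n_reared`, `density_0_35`, `density_35_70`); the spec used is
#'   attached as attribute `"sim_spec"`.
#' @export
simulate_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_sim_spec"))
  set.seed(spec$seed)
  K <- spec$n_populations
  pops <- paste0("Pop", seq_len(K))
  mu <- spec$trait_means
  pm <- spec$population_trait_means
  pop_mean <- function(trait) {
    if (!is.null(pm) && trait %in% colnames(pm)) pm[, trait] else
      rep(mu[trait], K)
  }
  tl_center <- exp(spec$female_tl_meanlog + spec$female_tl_sdlog^2 / 2)

  ## ---- Experiment 1: clutches ------------------------------------------
  nc <- spec$clutches_per_pop
  Nc <- K * nc
  popc <- factor(rep(pops, each = nc), levels = pops)
  tlc <- rlnorm(Nc, spec$female_tl_meanlog, spec$female_tl_sdlog)
  R2 <- matrix(c(1, spec$tradeoff_rho, spec$tradeoff_rho, 1), 2, 2)
  pop_dev <- .rmvn_cor(K, R2)    # shared correlation at every level
  res_dev <- .rmvn_cor(Nc, R2)
  ip <- as.integer(popc)
  cs <- pop_mean("clutch_size")[ip] +
    sqrt(spec$v_pop["clutch_size"]) * pop_dev[ip, 1] +
    sqrt(spec$v_res["clutch_size"]) * res_dev[, 1] +
    spec$tl_slope["clutch_size"] * (tlc - tl_center)
  em <- pop_mean("mean_egg_mass")[ip] +
    sqrt(spec$v_pop["mean_egg_mass"]) * pop_dev[ip, 2] +
    sqrt(spec$v_res["mean_egg_mass"]) * res_dev[, 2] +
    spec$tl_slope["mean_egg_mass"] * (tlc - tl_center)
  cs <- pmax(1, round(cs))
  em <- pmax(1e-3, em)
  mass <- 2.1e-5 * tlc^2.9 * exp(rnorm(Nc, 0, 0.05))
  clutches <- data.frame(
    female_id = paste0(popc, "_F", rep(seq_len(nc), K)),
    population = popc, female_tl = tlc, postspawn_mass = mass,
    clutch_size = cs, mean_egg_mass = em, total_egg_mass = cs * em,
    stringsAsFactors = FALSE)

  ## ---- Experiment 2: half-sib broods -----------------------------------
  S <- spec$sires_per_pop; D <- spec$dams_per_sire
  Nb <- K * S * D
  popb <- factor(rep(pops, each = S * D), levels = pops)
  sire <- paste0(popb, "_S", rep(rep(seq_len(S), each = D), K))
  dam <- paste0(sire, "_D", rep(seq_len(D), K * S))
  tlb <- rlnorm(Nb, spec$female_tl_meanlog, spec$female_tl_sdlog)
  r_bi <- spec$brood_cor[1]; r_br <- spec$brood_cor[2]
  R5 <- diag(5)
  dimnames(R5) <- list(
    c("brood_size", "incubation_days", "fry_len_release", "growth35",
      "growth70"),
    c("brood_size", "incubation_days", "fry_len_release", "growth35",
      "growth70"))
  R5["brood_size", "incubation_days"] <- R5["incubation_days", "brood_size"] <- r_bi
  R5["brood_size", "fry_len_release"] <- R5["fry_len_release", "brood_size"] <- r_br
  R5["growth35", "growth70"] <- R5["growth70", "growth35"] <- 0.5
  btraits <- rownames(R5)
  pdev <- .rmvn_cor(K, R5)
  sdev_ <- .rmvn_cor(K * S, R5)
  rdev <- .rmvn_cor(Nb, R5)
  is_ <- as.integer(factor(sire, levels = unique(sire)))
  ib <- as.integer(popb)
  val <- matrix(0, Nb, 5, dimnames = list(NULL, btraits))
  for (t in btraits) {
    tt <- if (t == "fry_len_release") "fry_len_release" else t
    val[, t] <- pop_mean(tt)[ib] +
      sqrt(spec$v_pop[tt]) * pdev[ib, t] +
      sqrt(spec$v_male[tt]) * sdev_[is_, t] +
      sqrt(spec$v_res[tt]) * rdev[, t] +
      spec$tl_slope[tt] * (tlb - tl_center)
  }
  bs <- pmax(1, round(val[, "brood_size"]))
  inc <- pmax(1, val[, "incubation_days"])
  len0 <- pmax(0.5, val[, "fry_len_release"])
  n_reared <- pmin(bs, spec$brood_cap)
  # density-dependent growth on log10 rearing density, centred at the
  # design's expected density so configured growth means stay interpretable
  d_center <- log10(min(mu["brood_size"], spec$brood_cap))
  g35 <- val[, "growth35"] +
    spec$density_slope * (log10(n_reared) - d_center)
  g70 <- val[, "growth70"] +
    spec$density_slope * (log10(n_reared) - d_center)
  g35 <- pmax(0, g35)
  g70 <- pmax(g35, g70)  # lengths non-decreasing through time
  broods <- data.frame(
    female_id = dam, sire_id = sire, population = popb, female_tl = tlb,
    brood_size = bs, incubation_days = inc,
    fry_len_day0 = len0, fry_len_day35 = len0 + g35,
    fry_len_day70 = len0 + g70,
    n_reared = n_reared, density_0_35 = n_reared, density_35_70 = n_reared,
    stringsAsFactors = FALSE)

  out <- structure(list(clutches = clutches, broods = broods),
                   class = "experiment_sim")
  attr(out, "sim_spec") <- spec
  out
}

#' @export
print.experiment_sim <- function(x, ...) {
  cat(sprintf("experiment_sim: %d clutches, %d half-sib families (%d populations)\n",
              nrow(x$clutches), nrow(x$broods),
              nlevels(x$broods$population)))
  invisible(x)
}
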