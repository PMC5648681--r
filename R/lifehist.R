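#' ANCOVA-style trait model with sequential F-tests
#'
#' Ordinary least-squares fit of
#' `response ~ covariate + population (+ covariate:population)` with
#' sequential (entry-order, Type I) F-tests, the layout conventional for
#' common-garden trait tables.  Marginal (Type II-style) tests are
#' available via `type = "marginal"` for sensitivity.
#'
#' @param records data.frame with a `population` column, the response, and
#'   the covariate if any.
#' @param response name of the response column.
#' @param covariate optional name of a numeric covariate column.
#' @param include_interaction add the `covariate:population` term.
#' @param type `"sequential"` (default) or `"marginal"`.
#' @return A list of class `trait_glm`: `fit` (the `lm` object), `anova`
#'   (data.frame: `term`, `df`, `df_res`, `F`, `p`), `response`,
#'   `covariate`.
#' @export
fit_trait_glm <- function(records, response, covariate = NULL,
                          include_interaction = FALSE,
                          type = c("sequential", "marginal")) {
  type <- match.arg(type)
  if (!"population" %in% names(records)) stop("records lack 'population'")
  if (!response %in% names(records)) stop("records lack '", response, "'")
  df <- records
  df$population <- factor(df$population)
  if (nlevels(df$population) < 2L) stop("need >= 2 populations")
  terms <- c(covariate, "population",
             if (include_interaction) {
               if (is.null(covariate))
                 stop("interaction requires a covariate")
               paste0(covariate, ":population")
             })
  if (include_interaction) {
    n_per <- table(df$population)
    if (any(n_per < 2L))
      stop("interaction model rank-deficient: population(s) with < 2 records: ",
           paste(names(n_per)[n_per < 2L], collapse = ", "))
  }
  fm <- as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  fit <- lm(fm, data = df)
  if (type == "sequential") {
    at <- anova(fit)
    resdf <- at["Residuals", "Df"]
    rows <- setdiff(rownames(at), "Residuals")
    tab <- data.frame(term = rows, df = at[rows, "Df"], df_res = resdf,
                      F = at[rows, "F value"], p = at[rows, "Pr(>F)"],
                      stringsAsFactors = FALSE)
  } else {
    tab <- do.call(rbind, lapply(seq_along(terms), function(i) {
      red <- as.formula(paste(response, "~",
                              paste(terms[-i], collapse = " + ")))
      cmp <- anova(lm(red, data = df), fit)
      data.frame(term = terms[i], df = cmp$Df[2], df_res = cmp$Res.Df[2],
                 F = cmp$F[2], p = cmp$`Pr(>F)`[2], stringsAsFactors = FALSE)
    }))
  }
  if (fit$df.residual <= 0) stop("no residual degrees of freedom")
  structure(list(fit = fit, anova = tab, response = response,
                 covariate = covariate), class = "trait_glm")
}

#' @export
print.trait_glm <- function(x, ...) {
  cat(sprintf("trait model: %s\n", deparse(formula(x$fit))))
  print(transform(x$anova, F = round(F, 3), p = signif(p, 3)))
  invisible(x)
}

#' Tukey HSD pairwise comparisons of population means
#'
#' Tukey-Kramer studentized-range comparisons of covariate-adjusted
#' population means from a fitted trait model, safe for unbalanced group
#' sizes (computed through the estimated marginal means machinery).
#'
#' @param fit a `trait_glm` from [fit_trait_glm] (or an `lm` with a
#'   `population` factor).
#' @return A list of class `tukey_hsd`: `p` (symmetric matrix of adjusted
#'   p-values, diagonal `NA`), `estimate` (matrix of mean differences,
#'   row - column), `degenerate` (`TRUE` when the residual variance is
#'   zero, in which case p-values are not meaningful and are returned as
#'   computed limits).
#' @export
tukey_hsd <- function(fit) {
  lmfit <- if (inherits(fit, "trait_glm")) fit$fit else fit
  degenerate <- sum(resid(lmfit)^2) < 1e-12
  em <- suppressMessages(emmeans::emmeans(lmfit, "population"))
  pr <- as.data.frame(
    emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  levs <- levels(factor(lmfit$model$population))
  K <- length(levs)
  p <- matrix(NA_real_, K, K, dimnames = list(levs, levs))
  est <- p
  cmp <- strsplit(as.character(pr$contrast), " - ")
  for (r in seq_len(nrow(pr))) {
    i <- match(cmp[[r]][1], levs); j <- match(cmp[[r]][2], levs)
    p[i, j] <- p[j, i] <- pr$p.value[r]
    est[i, j] <- pr$estimate[r]
    est[j, i] <- -pr$estimate[r]
  }
  structure(list(p = p, estimate = est, degenerate = degenerate),
            class = "tukey_hsd")
}

#' Least-square (covariate-adjusted) population means
#'
#' Population means evaluated at the grand mean of the covariate, with 95%
#' confidence intervals from the model's residual variance — the values
#' conventionally plotted for population comparisons.  Populations whose
#' own covariate range excludes the grand covariate mean are flagged as
#' extrapolating.
#'
#' @param fit a `trait_glm` from [fit_trait_glm].
#' @param level confidence level.
#' @return data.frame: `population`, `lsmean`, `se`, `lower`, `upper`,
#'   `extrapolated`.
#' @export
lsmeans_populations <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "trait_glm"))
  em <- as.data.frame(stats::confint(
    suppressMessages(emmeans::emmeans(fit$fit, "population")),
    level = level))
  out <- data.frame(population = em$population, lsmean = em$emmean,
                    se = em$SE, lower = em$lower.CL, upper = em$upper.CL,
                    extrapolated = FALSE, stringsAsFactors = FALSE)
  if (!is.null(fit$covariate)) {
    x <- fit$fit$model[[fit$covariate]]
    gmean <- mean(x)
    pop <- fit$fit$model$population
    rng <- tapply(x, pop, range)
    out$extrapolated <- vapply(as.character(out$population), function(p) {
      r <- rng[[p]]; gmean < r[1] || gmean > r[2]
    }, logical(1))
  }
  out
}

#' Size-corrected trait values (standardized residuals)
#'
#' Residuals of a trait regressed on a covariate (typically female total
#' length), divided by the residual standard deviation, so the result has
#' mean 0 and SD 1.  Used for trade-off analysis between e.g. clutch size
#' and egg mass.
#'
#' @param records data.frame.
#' @param trait name of the trait column.
#' @param covariate name of the covariate column.
#' @return Numeric vector of standardized residuals, with attribute
#'   `"degenerate"` `TRUE` when the residuals are all (near) zero so
#'   standardisation is not meaningful (zeros are returned).
#' @export
size_corrected <- function(records, trait, covariate) {
  y <- records[[trait]]; x <- records[[covariate]]
  if (is.null(y) || is.null(x)) stop("missing trait or covariate column")
  ok <- complete.cases(y, x)
  if (sum(ok) < 3L) stop("need >= 3 complete records")
  if (var(x[ok]) == 0) stop("constant covariate")
  r <- resid(lm(y ~ x, subset = ok))
  s <- sd(r)
  out <- rep(NA_real_, length(y))
  if (s < 1e-12) {
    out[ok] <- 0
    attr(out, "degenerate") <- TRUE
  } else {
    out[ok] <- (r - mean(r)) / s
    attr(out, "degenerate") <- FALSE
  }
  out
}

#' Pearson correlation between two trait vectors
#'
#' @param x,y numeric vectors (pairwise complete observations used).
#' @return data.frame: `r`, `n`, `t`, `df`, `p` (two-sided).
#' @export
trait_correlation <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need n >= 3")
  if (var(x) == 0 || var(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  data.frame(r = unname(ct$estimate), n = length(x),
             t = unname(ct$statistic), df = unname(ct$parameter),
             p = ct$p.value)
}

#' Restrict broods to the growth-comparison density window
#'
#' Growth comparisons are restricted to broods rearing between 5 and 19
#' individuals inclusive, limiting bias from extreme rearing densities.
#'
#' @param broods data.frame with an `n_reared` (or `brood_size`) column.
#' @param min_n,max_n inclusive bounds.
#' @param size_col column holding the reared-offspring count.
#' @return The retained subset, with attributes `"n_retained"` and
#'   `"n_excluded"`.
#' @export
filter_growth_broods <- function(broods, min_n = 5L, max_n = 19L,
                                 size_col = if ("n_reared" %in% names(broods))
                                   "n_reared" else "brood_size") {
  n <- broods[[size_col]]
  if (is.null(n) && nrow(broods) > 0L) stop("no brood-size column found")
  keep <- if (nrow(broods) == 0L) logical(0) else n >= min_n & n <= max_n
  out <- broods[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Average brood growth between two time points
#'
#' Difference in mean fry total length between two measurement days.
#'
#' @param brood one brood record (list/data.frame row) with columns
#'   `fry_len_day<t>`; or a data.frame of broods (vectorised).
#' @param t1,t2 measurement days (e.g. 0 and 35).
#' @return Growth in mm (`mean TL(t2) - mean TL(t1)`).
#' @export
brood_growth <- function(brood, t1, t2) {
  c1 <- paste0("fry_len_day", t1); c2 <- paste0("fry_len_day", t2)
  if (is.null(brood[[c1]]) || is.null(brood[[c2]]))
    stop("missing fry length at day ", if (is.null(brood[[c1]])) t1 else t2)
  brood[[c2]] - brood[[c1]]
}

#' Habitat-class contrast on population-level adjusted means
#'
#' One-way comparison of population least-square means between two habitat
#' classes (e.g. main-lake vs peripheral), with degrees of freedom
#' determined by the population count: numerator 1, denominator
#' `n_populations - 2`.
#'
#' @param population_lsmeans data.frame from [lsmeans_populations] (or any
#'   data.frame with `population` and `lsmean`).
#' @param habitat_labels named character/factor vector of habitat class per
#'   population.
#' @return data.frame: `F`, `df1`, `df2`, `p`.
#' @export
habitat_contrast <- function(population_lsmeans, habitat_labels) {
  df <- population_lsmeans
  hab <- factor(habitat_labels[as.character(df$population)])
  if (nlevels(hab) != 2L) stop("need exactly 2 habitat classes")
  if (any(table(hab) < 2L)) stop("each habitat class needs >= 2 populations")
  at <- anova(lm(df$lsmean ~ hab))
  data.frame(F = at$`F value`[1], df1 = at$Df[1], df2 = at$Df[2],
             p = at$`Pr(>F)`[1])
}
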