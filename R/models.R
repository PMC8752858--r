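#' z-transform covariate columns
#'
#' Standardizes each column to mean 0 and SD 1 (sample SD, n - 1 denominator)
#' so fitted coefficients are directly comparable; the centering and scaling
#' constants are returned for back-mapping to the natural scale.
#'
#' @param x data.frame or matrix of numeric covariates
#' @param cols columns to transform (default: all)
#' @return object of the same shape with transformed columns and attributes
#'   `center` and `scale`
#' @export
zTransform <- function(x, cols = NULL) {
  if (is.null(cols)) cols <- colnames(x) %||% seq_len(ncol(x))
  ctr <- scl <- stats::setNames(numeric(length(cols)), cols)
  for (cl in cols) {
    v <- if (is.data.frame(x)) x[[cl]] else x[, cl]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("degenerate covariate: '", cl, "' has zero SD")
    ctr[cl] <- mean(v); scl[cl] <- s
    if (is.data.frame(x)) x[[cl]] <- (v - ctr[cl]) / s
    else x[, cl] <- (v - ctr[cl]) / s
  }
  attr(x, "center") <- ctr
  attr(x, "scale") <- scl
  x
}

#' Maximum-likelihood logistic regression with Wald tests
#'
#' Fits a binomial-logit GLM (iteratively reweighted least squares), reports
#' asymptotic Wald z tests per coefficient and AIC = 2*npar - 2*logLik, and
#' flags (quasi-)complete separation, under which the estimates diverge and
#' the fit must not be interpreted.
#'
#' @param y binary response vector
#' @param X data.frame/matrix of covariates, or `NULL` for an intercept-only
#'   model
#' @param label model label
#' @return a [ModelFit-class]
#' @export
fitLogistic <- function(y, X = NULL, label = "logistic") {
  d <- data.frame(.y = y)
  form <- ".y ~ 1"
  if (!is.null(X) && NCOL(X) > 0) {
    X <- as.data.frame(X)
    d <- cbind(d, X)
    form <- paste(".y ~", paste(colnames(X), collapse = " + "))
  }
  if (nrow(d) <= NCOL(X %||% matrix(0, 1, 0)) + 1L)
    stop("more parameters than observations")
  sep <- length(unique(y)) < 2L
  fit <- suppressWarnings(stats::glm(stats::as.formula(form), data = d,
                                     family = stats::binomial()))
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))$coefficients
  mu <- stats::fitted(fit)
  sep <- sep || !fit$converged || any(abs(cf) > 15) ||
    all(mu > 1 - 1e-8 | mu < 1e-8)
  ll <- as.numeric(stats::logLik(fit))
  np <- length(cf)
  new("ModelFit", label = label, coef = cf, se = sm[, 2],
      z = sm[, 3], p = sm[, 4], logLik = ll, npar = np,
      nobs = length(y), aic = 2 * np - 2 * ll, reSD = NA_real_,
      groupVar = NA_character_, converged = fit$converged,
      separation = sep)
}

#' Mixed-effects logistic regression with a Gaussian random intercept
#'
#' Logistic fit with a per-group Gaussian random intercept; the marginal
#' likelihood is integrated by adaptive Gauss-Hermite quadrature (default 15
#' nodes). Reports fixed coefficients with asymptotic Wald z tests, the
#' random-intercept SD, log-likelihood and AIC.
#'
#' @param y binary response vector
#' @param X data.frame/matrix of covariates (or `NULL`)
#' @param group grouping factor for the random intercept
#' @param nAGQ quadrature nodes
#' @param label model label
#' @return a [ModelFit-class]
#' @export
fitMixedLogistic <- function(y, X = NULL, group, nAGQ = 15L,
                             label = "mixed logistic") {
  d <- data.frame(.y = y, .grp = factor(group))
  if (nlevels(d$.grp) < 2L) stop("need >= 2 groups for a random intercept")
  rhs <- "1"
  if (!is.null(X) && NCOL(X) > 0) {
    X <- as.data.frame(X)
    d <- cbind(d, X)
    rhs <- paste(colnames(X), collapse = " + ")
  }
  form <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .grp)"))
  fit <- suppressWarnings(suppressMessages(
    lme4::glmer(form, data = d, family = stats::binomial(), nAGQ = nAGQ)))
  cf <- lme4::fixef(fit)
  sm <- stats::coef(summary(fit))
  reSD <- sqrt(unname(lme4::VarCorr(fit)$.grp[1, 1]))
  ll <- as.numeric(stats::logLik(fit))
  np <- length(cf) + 1L
  conv <- length(fit@optinfo$conv$lme4) == 0L
  new("ModelFit", label = label, coef = cf, se = sm[, 2], z = sm[, 3],
      p = sm[, 4], logLik = ll, npar = np, nobs = length(y),
      aic = 2 * np - 2 * ll, reSD = reSD, groupVar = "group",
      converged = conv, separation = any(abs(cf) > 15))
}

#' Female mate choice as a function of heterozygosity
#'
#' Models whether females pair with males of above-average heterozygosity:
#' the binary response is 1 when the male's observed heterozygosity exceeds
#' the reference-pool mean, regressed on the female's continuous
#' heterozygosity. Fits the fixed logistic model, a mixed variant with a
#' pair-identity random intercept, and an intercept-only null, and reports
#' AIC differences versus the null.
#'
#' @param pairs data.frame with columns `female_ho`, `male_ho`, `pair_id`
#'   (one row per pair-year)
#' @param referenceHo heterozygosities of the reference pool of potential
#'   breeders (its mean defines "average"), or a single precomputed mean
#' @return list: fixed, mixed, null ([ModelFit-class]), deltaAIC (fixed and
#'   mixed vs null), referenceMean
#' @export
mateChoiceAnalysis <- function(pairs, referenceHo) {
  if (nrow(pairs) < 10L) stop("need >= 10 pair-years")
  refMean <- mean(referenceHo)
  yy <- as.integer(pairs$male_ho > refMean)
  if (length(unique(yy)) < 2L)
    stop("degenerate response: all male H_o on one side of the mean")
  if (stats::sd(pairs$female_ho) == 0)
    stop("degenerate covariate: female H_o is constant")
  X <- data.frame(female_ho = pairs$female_ho)
  fixed <- fitLogistic(yy, X, label = "mate choice (fixed)")
  nullF <- fitLogistic(yy, NULL, label = "mate choice (null)")
  mixed <- fitMixedLogistic(yy, X, pairs$pair_id,
                            label = "mate choice (mixed)")
  list(fixed = fixed, mixed = mixed, null = nullF,
       deltaAIC = c(fixed = fixed@aic - nullF@aic,
                    mixed = mixed@aic - nullF@aic),
       referenceMean = refMean)
}

#' Pup survival models on standardized covariates
#'
#' z-scores the five survival covariates (harvest rate, group adults, pair
#' heterozygosity, density, years paired), fits the fixed-effects logistic
#' model, the mixed model with a mated-pair random intercept, and an
#' intercept-only null, and tabulates AIC differences (each model vs null,
#' and mixed vs fixed).
#'
#' @param pups data.frame with columns `alive`, `pair_id` and the covariates
#'   `harvest_rate`, `n_adults`, `pair_ho`, `density`, `years_paired`
#' @param nAGQ quadrature nodes for the mixed fit
#' @return list: fixed, mixed, null ([ModelFit-class]), deltaAIC,
#'   zInfo (center/scale used)
#' @export
pupSurvivalAnalysis <- function(pups, nAGQ = 15L) {
  if (nrow(pups) < 30L) stop("need >= 30 pup records")
  covs <- c("harvest_rate", "n_adults", "pair_ho", "density", "years_paired")
  miss <- setdiff(c(covs, "alive", "pair_id"), names(pups))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  Z <- zTransform(pups[covs])
  fixed <- fitLogistic(pups$alive, Z, label = "pup survival (fixed)")
  nullF <- fitLogistic(pups$alive, NULL, label = "pup survival (null)")
  mixed <- fitMixedLogistic(pups$alive, Z, pups$pair_id, nAGQ = nAGQ,
                            label = "pup survival (mixed)")
  list(fixed = fixed, mixed = mixed, null = nullF,
       deltaAIC = c(fixed_vs_null = fixed@aic - nullF@aic,
                    mixed_vs_null = mixed@aic - nullF@aic,
                    mixed_vs_fixed = mixed@aic - fixed@aic),
       zInfo = list(center = attr(Z, "center"), scale = attr(Z, "scale")))
}

#' Two-sample t test
#'
#' Welch's unequal-variance t test (default) or the pooled-variance variant,
#' two-sided; used to compare heterozygosity between sneaker males and
#' group-living mated males.
#'
#' @param x1,x2 numeric samples (each n >= 2)
#' @param variant `"welch"` or `"pooled"`
#' @return list: t, df, p, mean1, mean2
#' @export
twoSampleT <- function(x1, x2, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(x1) < 2L || length(x2) < 2L) stop("need n >= 2 in each sample")
  if (stats::sd(x1) == 0 && stats::sd(x2) == 0)
    stop("undefined t: zero variance in both samples")
  ht <- stats::t.test(x1, x2, var.equal = (variant == "pooled"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean1 = mean(x1), mean2 = mean(x2))
}
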