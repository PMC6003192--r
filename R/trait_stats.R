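#' Lin's concordance correlation coefficient
#'
#' Measures agreement between a measured and an estimated trait vector as
#' `rho_c = 2 * s12 / (s1^2 + s2^2 + (mu1 - mu2)^2)`, using population
#' (1/n) moments by default. It factors into `rho_c = rho * C_b`, where
#' `rho` is the Pearson correlation (precision: scatter about the best-fit
#' line) and `C_b` in `(0, 1]` is the bias-correction factor (accuracy: how
#' far the best-fit line sits from the 45-degree line through the origin).
#' The coefficient is 1 exactly when every point lies on the 45-degree line.
#' The confidence interval is computed on Fisher's z scale with Lin's
#' asymptotic variance and transformed back.
#'
#' @param y1,y2 Equal-length numeric vectors (length >= 3), both with
#'   nonzero variance.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param moments `"population"` (1/n, the original definition) or
#'   `"sample"` (1/(n-1)).
#' @return A list of class `concordance` with elements `rho_c`, `rho`,
#'   `c_b`, `ci95` (lower/upper), `n`.
#' @export
lin_ccc <- function(y1, y2, conf_level = 0.95,
                    moments = c("population", "sample")) {
  moments <- match.arg(moments)
  if (length(y1) != length(y2)) stop("y1 and y2 must have equal length")
  n <- length(y1)
  if (n < 3) stop("at least 3 paired values are required")
  if (anyNA(y1) || anyNA(y2)) stop("missing values are not allowed")
  if (sd(y1) == 0 || sd(y2) == 0)
    stop("zero variance in y1 or y2; concordance is degenerate")
  mu1 <- mean(y1); mu2 <- mean(y2)
  denomN <- if (moments == "population") n else n - 1
  s1 <- sum((y1 - mu1)^2) / denomN
  s2 <- sum((y2 - mu2)^2) / denomN
  s12 <- sum((y1 - mu1) * (y2 - mu2)) / denomN
  rho <- cor(y1, y2)
  rho_c <- 2 * s12 / (s1 + s2 + (mu1 - mu2)^2)
  c_b <- rho_c / rho

  if (1 - rho_c^2 < 1e-12 || abs(rho) < 1e-12) {
    ci <- c(rho_c, rho_c)
  } else {
    u <- (mu1 - mu2) / sqrt(sqrt(s1) * sqrt(s2))
    sz2 <- ((1 - rho^2) * rho_c^2 / ((1 - rho_c^2) * rho^2) +
            2 * rho_c^3 * (1 - rho_c) * u^2 / (rho * (1 - rho_c^2)^2) -
            rho_c^4 * u^4 / (2 * rho^2 * (1 - rho_c^2)^2)) / (n - 2)
    sz2 <- max(sz2, 0)
    zq <- qnorm(1 - (1 - conf_level) / 2)
    z <- atanh(rho_c)
    ci <- tanh(z + c(-1, 1) * zq * sqrt(sz2))
  }
  structure(list(rho_c = rho_c, rho = rho, c_b = c_b,
                 ci95 = c(lower = ci[1], upper = ci[2]), n = n,
                 conf_level = conf_level),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Lin's CCC: rho_c = %.4f (precision rho = %.4f, accuracy C_b = %.4f)\n",
              x$rho_c, x$rho, x$c_b))
  cat(sprintf("%d%% CI [%.4f, %.4f], n = %d\n", round(100 * x$conf_level),
              x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' Pearson correlation of paired trait values
#'
#' @param y1,y2 Equal-length numeric vectors with nonzero variance.
#' @return Product-moment correlation in `[-1, 1]`.
#' @export
pearson_r <- function(y1, y2) {
  if (length(y1) != length(y2)) stop("y1 and y2 must have equal length")
  if (sd(y1) == 0 || sd(y2) == 0) stop("zero variance; correlation undefined")
  cor(y1, y2)
}

#' Root-mean-square error between paired trait values
#'
#' @param y1,y2 Equal-length numeric vectors.
#' @return RMSE in the units of the trait.
#' @export
rmse <- function(y1, y2) {
  if (length(y1) != length(y2)) stop("y1 and y2 must have equal length")
  sqrt(mean((y1 - y2)^2))
}

# ---- trial tables ----------------------------------------------------------

#' Read / write a tidy trial table
#'
#' A trial table records genotype-by-replicate trait values in long format
#' with columns `genotype`, `rep`, `trait`, `value`.
#'
#' @param path CSV path.
#' @return `read_trial_table`: a `data.frame`; `write_trial_table`: `path`,
#'   invisibly.
#' @export
read_trial_table <- function(path) {
  t <- read.csv(path, stringsAsFactors = FALSE)
  validate_trial_table(t)
  t
}

#' @rdname read_trial_table
#' @param t A trial-table `data.frame`.
#' @export
write_trial_table <- function(t, path) {
  validate_trial_table(t)
  write.csv(t, path, row.names = FALSE)
  invisible(path)
}

validate_trial_table <- function(t) {
  need <- c("genotype", "rep", "trait", "value")
  if (!all(need %in% names(t)))
    stop("trial table must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(t$value)) stop("trial table values must be numeric")
  invisible(t)
}

trait_matrix <- function(t, trait) {
  tt <- t[t$trait == trait, , drop = FALSE]
  if (nrow(tt) == 0) stop("trait not found in table: ", trait)
  g <- factor(tt$genotype)
  r <- factor(tt$rep)
  if (nlevels(g) < 2) stop("at least 2 genotypes are required")
  if (nlevels(r) < 2) stop("at least 2 replicates are required")
  counts <- table(g, r)
  if (any(counts != 1))
    stop("trial table must hold exactly one value per genotype x replicate")
  m <- matrix(NA_real_, nlevels(g), nlevels(r),
              dimnames = list(levels(g), levels(r)))
  m[cbind(as.integer(g), as.integer(r))] <- tt$value
  m
}

#' Variance components of a replicated trial
#'
#' Decomposes a genotype-by-replicate trial into genotypic and residual
#' variance under the model `value = mu + rep_block + G_genotype + error`
#' with the replicate as a fixed blocking term. `method = "anova"` uses the
#' balanced method of moments, `sigma_g2 = (MS_gen - MS_err) / nreps`
#' truncated at zero; `method = "reml"` fits the equivalent mixed model with
#' a random genotype effect by restricted maximum likelihood. On balanced
#' data the two agree whenever the REML estimate is interior.
#'
#' @param t A tidy trial table (columns `genotype`, `rep`, `trait`,
#'   `value`).
#' @param trait Trait name to analyze.
#' @param method `"anova"` (default) or `"reml"`.
#' @return A list of class `variance_components`: `sigma_g2`, `sigma_e2`,
#'   `nreps`, `n_geno`, `method`.
#' @export
variance_components <- function(t, trait, method = c("anova", "reml")) {
  method <- match.arg(method)
  validate_trial_table(t)
  m <- trait_matrix(t, trait)
  G <- nrow(m); R <- ncol(m)
  if (method == "anova") {
    grand <- mean(m)
    gm <- rowMeans(m)
    rm_ <- colMeans(m)
    ms_gen <- R * sum((gm - grand)^2) / (G - 1)
    resid <- m - outer(gm, rep(1, R)) - outer(rep(1, G), rm_) + grand
    ms_err <- sum(resid^2) / ((G - 1) * (R - 1))
    sigma_e2 <- ms_err
    sigma_g2 <- max((ms_gen - ms_err) / R, 0)
  } else {
    df <- data.frame(value = as.vector(m),
                     genotype = rep(rownames(m), R),
                     rep = rep(colnames(m), each = G))
    fit <- lme4::lmer(value ~ rep + (1 | genotype), data = df,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_g2 <- vc$vcov[vc$grp == "genotype"]
    sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  }
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 nreps = R, n_geno = G, method = method),
            class = "variance_components")
}

#' Broad-sense heritability
#'
#' `H^2 = sigma_g2 / (sigma_g2 + sigma_e2 / nreps)`: the fraction of the
#' phenotypic variance of genotype means attributable to genotype. Returns
#' `NA` (with a warning) when both components are zero.
#'
#' @param vc A [variance_components()] result, or any list with elements
#'   `sigma_g2` and `sigma_e2`.
#' @param nreps Number of replicates; defaults to the value stored in `vc`.
#' @return `H^2` in `[0, 1]`, or `NA` if undefined.
#' @export
heritability <- function(vc, nreps = vc$nreps) {
  if (is.null(nreps) || nreps < 1) stop("nreps must be >= 1")
  denom <- vc$sigma_g2 + vc$sigma_e2 / nreps
  if (denom <= 0) {
    warning("both variance components are zero; heritability is undefined")
    return(NA_real_)
  }
  vc$sigma_g2 / denom
}

#' Genetic correlation between two traits
#'
#' Correlation of the genotypic effects of two traits measured on the same
#' genotypes and replicates: the genotypic covariance (method-of-moments
#' cross-trait analogue of [variance_components()]) divided by the geometric
#' mean of the two genotypic variances.
#'
#' @param t A tidy trial table holding both traits.
#' @param trait_j,trait_j2 Trait names.
#' @return Estimated genetic correlation (unbounded estimator; values
#'   slightly outside `[-1, 1]` can occur by sampling error).
#' @export
genetic_correlation <- function(t, trait_j, trait_j2) {
  validate_trial_table(t)
  m1 <- trait_matrix(t, trait_j)
  m2 <- trait_matrix(t, trait_j2)
  if (!identical(dimnames(m1), dimnames(m2)))
    stop("the two traits must cover the same genotypes and replicates")
  G <- nrow(m1); R <- ncol(m1)
  comp <- function(m) {
    grand <- mean(m); gm <- rowMeans(m); rm_ <- colMeans(m)
    resid <- m - outer(gm, rep(1, R)) - outer(rep(1, G), rm_) + grand
    list(gm = gm, grand = grand, resid = resid)
  }
  c1 <- comp(m1); c2 <- comp(m2)
  ms_gen <- R * sum((c1$gm - c1$grand) * (c2$gm - c2$grand)) / (G - 1)
  ms_err <- sum(c1$resid * c2$resid) / ((G - 1) * (R - 1))
  cov_g <- (ms_gen - ms_err) / R
  var_g <- function(cc, m) {
    msg <- R * sum((cc$gm - cc$grand)^2) / (G - 1)
    mse <- sum(cc$resid^2) / ((G - 1) * (R - 1))
    max((msg - mse) / R, 0)
  }
  v1 <- var_g(c1, m1); v2 <- var_g(c2, m2)
  if (v1 <= 0 || v2 <= 0)
    stop("zero genotypic variance; genetic correlation is degenerate")
  cov_g / sqrt(v1 * v2)
}
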