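# Single-environment GBLUP genomic prediction: ridge regression on centered
# marker dosages with the shrinkage level set by restricted maximum
# likelihood on the eigendecomposition of the marker covariance.

#' Fit a GBLUP / ridge-regression genomic prediction model
#'
#' Fits `y = mu + W a + e` with marker effects `a ~ N(0, sigma_a^2 I)`, where
#' `W` is the dosage matrix centered at twice the training allele
#' frequencies. The variance-component ratio is estimated by restricted
#' maximum likelihood via the spectral decomposition of `W W'`, so the fit is
#' exactly equivalent to GBLUP with a VanRaden relationship matrix. Marker
#' effects and fitted values are returned; a degenerate REML solution falls
#' back to a small ridge floor with a warning.
#'
#' @param genotypes training dosage matrix (missing calls are centered to 0).
#' @param phenotypes named numeric vector (names matching rows of
#'   `genotypes`) or a vector in row order.
#' @param lambda optional fixed ridge parameter (ratio sigma_e^2 / sigma_a^2);
#'   default: REML estimate.
#' @param min_train minimum training size.
#' @return object of class `gblup_fit` with `mu`, `effects`, `lambda`,
#'   variance components, fitted values and the centering frequencies.
#' @export
fit_gblup <- function(genotypes, phenotypes, lambda = NULL, min_train = 30) {
  if (!is.null(names(phenotypes))) {
    phenotypes <- phenotypes[rownames(genotypes)]
  }
  y <- as.numeric(phenotypes)
  if (anyNA(y) || any(!is.finite(y))) stop("phenotypes must be finite")
  n <- nrow(genotypes)
  if (n < min_train) stop("at least ", min_train, " training individuals are required")
  freqs <- allele_frequencies(genotypes)
  w <- sweep(genotypes, 2, 2 * freqs)
  w[is.na(w)] <- 0
  wwt <- tcrossprod(w)
  eig <- eigen(wwt, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  u <- eig$vectors
  yt <- crossprod(u, y)
  xt <- crossprod(u, rep(1, n))

  reml_nll <- function(log_lambda) {
    v <- d + exp(log_lambda)
    mu <- sum(xt * yt / v) / sum(xt^2 / v)
    r <- yt - xt * mu
    s2 <- sum(r^2 / v) / (n - 1)
    0.5 * ((n - 1) * log(s2) + sum(log(v)) + log(sum(xt^2 / v)))
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(reml_nll, interval = c(-12, 25))
    lambda <- exp(opt$minimum)
    if (opt$minimum <= -11.9) {
      lambda <- max(lambda, 1e-6 * mean(d[d > 0]))
      warning("REML ridge estimate at its floor; lambda floor applied")
    }
  }
  if (lambda <= 0) stop("lambda must be positive")
  v <- d + lambda
  mu <- sum(xt * yt / v) / sum(xt^2 / v)
  r <- yt - xt * mu
  sigma2 <- sum(r^2 / v) / (n - 1) # = sigma_a^2; sigma_e^2 = lambda * sigma_a^2
  effects <- crossprod(w, u %*% (r / v))
  fitted <- as.numeric(mu + w %*% effects)
  out <- list(mu = mu, effects = stats::setNames(as.numeric(effects),
                                                 colnames(genotypes)),
              lambda = lambda,
              sigma2_a = sigma2, sigma2_e = sigma2 * lambda,
              freqs = freqs, fitted = stats::setNames(fitted, rownames(genotypes)),
              loci = colnames(genotypes), n_train = n)
  class(out) <- "gblup_fit"
  out
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("GBLUP / ridge genomic prediction fit\n")
  cat(sprintf("  training individuals: %d, loci: %d\n", x$n_train,
              length(x$effects)))
  cat(sprintf("  lambda (sigma_e^2 / sigma_a^2): %.4g; intercept: %.4g\n",
              x$lambda, x$mu))
  invisible(x)
}

#' @export
coef.gblup_fit <- function(object, ...) {
  c(`(Intercept)` = object$mu, object$effects)
}

#' Predict genome-estimated trait values
#'
#' `intercept + dosage %*% effects` on the loci shared between the model and
#' the new genotypes (a warning reports dropped loci; zero overlap is an
#' error). Missing calls are centered to zero, i.e. imputed at the training
#' mean.
#'
#' @param object a [fit_gblup()] model.
#' @param newdata dosage matrix.
#' @param ... unused.
#' @return named numeric vector of predictions.
#' @export
predict.gblup_fit <- function(object, newdata, ...) {
  shared <- intersect(object$loci, colnames(newdata))
  if (!length(shared)) stop("no loci shared between model and new genotypes")
  if (length(shared) < length(object$loci)) {
    warning(length(object$loci) - length(shared),
            " model loci absent from the new genotypes were dropped")
  }
  w <- sweep(newdata[, shared, drop = FALSE], 2, 2 * object$freqs[shared])
  w[is.na(w)] <- 0
  stats::setNames(as.numeric(object$mu + w %*% object$effects[shared]),
                  rownames(newdata))
}

#' Trait means per distance bin with protected LSD letters
#'
#' @param predictions named numeric vector of predicted trait values (names =
#'   progeny ids) or a matrix/data frame with one column per trait.
#' @param records a [build_dispersal_records()] table.
#' @param width_m distance-bin width in meters.
#' @param alpha significance level of the LSD test.
#' @return data frame with one row per (trait, bin): mean, sd, n and LSD
#'   letters; empty bins are excluded.
#' @export
per_bin_trait_table <- function(predictions, records, width_m = 3,
                                alpha = 0.05) {
  if (is.null(dim(predictions))) {
    predictions <- matrix(predictions, ncol = 1,
                          dimnames = list(names(predictions), "trait"))
  }
  bins <- bin_by_distance(records, width_m)
  idx <- match(records$progeny_id, rownames(predictions))
  if (anyNA(idx)) stop("every assigned progeny needs a prediction")
  rows <- list()
  for (tr in colnames(predictions)) {
    vals <- predictions[idx, tr]
    keep <- !is.na(bins$bin)
    lt <- lsd_test(vals[keep], bins$bin[keep], alpha = alpha)
    g <- lt$groups
    agg_sd <- tapply(vals[keep], droplevels(bins$bin[keep]), stats::sd)
    g$sd <- as.numeric(agg_sd[g$group])
    g$trait <- tr
    g$any_difference <- lt$any_difference
    rows[[tr]] <- g[, c("trait", "group", "n", "mean", "sd", "letters",
                        "any_difference")]
  }
  out <- do.call(rbind, unname(rows))
  names(out)[names(out) == "group"] <- "bin"
  rownames(out) <- NULL
  out
}
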