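# Negative-binomial differential expression.
#
# The engine is a deliberately transparent stand-in for heavyweight DE
# packages: median-of-ratios size factors, method-of-moments dispersion on
# normalized counts (no shrinkage, no independent filtering, no outlier
# refitting), and a Wald test on the contrast coefficient referred to a t
# distribution with residual degrees of freedom. Downstream threshold
# cascades also accept externally computed tables with the same columns.

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement. `NA` p-values are propagated and
#' excluded from the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and names as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop2("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald differential expression
#'
#' Per gene, a negative-binomial log-link regression with a log size-factor
#' offset. Dispersion is estimated by method of moments on size-factor
#' normalized counts around the design fit, floored at `1e-8` and capped at
#' 10. The contrast (or covariate) coefficient is tested with a Wald
#' statistic referred to a t distribution on the residual degrees of freedom;
#' two-sided p-values are BH-adjusted over the tested genes. Genes with no
#' counts in the contrast samples are reported with `NA` p-values and are
#' excluded from the adjustment.
#'
#' @param counts Count matrix (genes x samples).
#' @param metadata Sample metadata with a `sample_id` column matching the
#'   columns of `counts` (or rownames equal to the sample ids).
#' @param test Name of the metadata column to test: a two-level factor
#'   contrast or a continuous covariate (used in its raw units).
#' @param contrast For factor tests, `c(numerator, denominator)` levels;
#'   positive `log2fc` means higher in the numerator. Defaults to the two
#'   sorted levels, numerator last.
#' @param blocking Optional character vector of metadata columns entered
#'   additively in the design (e.g. cell type when testing species across
#'   pooled samples).
#' @param sf Optional size factors; computed from `counts` when missing.
#' @return data.frame of class `de_result` with columns `gene_id`,
#'   `base_mean`, `log2fc`, `se`, `stat`, `pvalue`, `padj`; the contrast is
#'   recorded in `attr(, "contrast")`.
#' @export
nb_wald_test <- function(counts, metadata, test, contrast = NULL,
                         blocking = NULL, sf = NULL) {
  validate_count_matrix(counts)
  metadata <- align_metadata(counts, metadata)
  if (!test %in% names(metadata)) stop2("no metadata column '", test, "'")
  if (is.null(sf)) sf <- size_factors(counts)
  v <- metadata[[test]]
  is_factor <- is.character(v) || is.factor(v) || is.logical(v)

  if (is_factor) {
    v <- as.character(v)
    if (is.null(contrast)) {
      lv <- sort(unique(v))
      if (length(lv) != 2)
        stop2("'", test, "' has ", length(lv),
              " levels; supply contrast = c(numerator, denominator)")
      contrast <- c(lv[2], lv[1])
    }
    keep <- v %in% contrast
    counts <- counts[, keep, drop = FALSE]
    metadata <- metadata[keep, , drop = FALSE]
    sf <- sf[keep]
    v <- v[keep]
    if (min(table(v)) < 2) stop2("need >= 2 samples per contrast level")
    tcol <- as.numeric(v == contrast[1])
  } else {
    if (stats::var(v) == 0) stop2("covariate '", test, "' is constant")
    contrast <- c(test, "slope")
    tcol <- as.numeric(v)
  }

  X0 <- design_blocking(metadata, blocking)
  X <- cbind(X0, test = tcol)
  if (qr(X)$rank < ncol(X))
    stop2("confounded design: '", test, "' is collinear with the blocking terms")
  n <- nrow(X); p <- ncol(X)
  if (n - p < 1) stop2("no residual degrees of freedom")

  z <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(z)
  tested <- rowSums(counts) > 0
  alpha <- mom_dispersion(z, X, sf)

  res <- data.frame(gene_id = rownames(counts), base_mean = base_mean,
                    log2fc = NA_real_, se = NA_real_, stat = NA_real_,
                    pvalue = NA_real_, stringsAsFactors = FALSE)
  if (any(tested)) {
    if (is_factor && ncol(X) == 2) {
      fit <- nb_two_group_fit(counts[tested, , drop = FALSE], sf,
                              tcol == 1, alpha[tested])
      res$log2fc[tested] <- fit$log2fc
      res$se[tested] <- fit$se
    } else {
      fit <- nb_glm_fit(counts[tested, , drop = FALSE], X, sf, alpha[tested])
      res$log2fc[tested] <- fit$log2fc
      res$se[tested] <- fit$se
    }
    res$stat <- res$log2fc / res$se
    res$pvalue <- 2 * stats::pt(-abs(res$stat), df = n - p)
  }
  res$padj <- bh_adjust(res$pvalue)
  rownames(res) <- NULL
  structure(res, class = c("de_result", "data.frame"),
            contrast = c(test = test, numerator = contrast[1],
                         denominator = contrast[2]),
            df = n - p, n = n)
}

align_metadata <- function(counts, metadata) {
  ids <- colnames(counts)
  if ("sample_id" %in% names(metadata)) {
    i <- match(ids, metadata$sample_id)
  } else {
    i <- match(ids, rownames(metadata))
  }
  if (anyNA(i)) stop2("metadata missing sample: ", ids[is.na(i)][1])
  metadata[i, , drop = FALSE]
}

design_blocking <- function(metadata, blocking) {
  X <- matrix(1, nrow(metadata), 1, dimnames = list(NULL, "(Intercept)"))
  for (b in blocking %||% character()) {
    if (!b %in% names(metadata)) stop2("no metadata column '", b, "'")
    v <- metadata[[b]]
    if (is.character(v) || is.factor(v)) {
      f <- factor(v)
      if (nlevels(f) > 1) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(b, levels(f)[-1])
        X <- cbind(X, mm)
      }
    } else {
      X <- cbind(X, stats::setNames(data.frame(v), b))
      X <- as.matrix(X)
    }
  }
  as.matrix(X)
}

# Method-of-moments dispersion around the OLS fit of normalized counts on the
# design: Var(z_i) ~ mu_i / s_i + alpha * mu_i^2, averaged over samples.
mom_dispersion <- function(z, X, sf) {
  n <- nrow(X); p <- ncol(X)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  fitted <- z %*% H
  s2 <- rowSums((z - fitted)^2) / (n - p)
  mu <- pmax(fitted, 0)
  pois <- rowMeans(sweep(mu, 2, sf, "/"))
  quad <- rowMeans(mu^2)
  alpha <- ifelse(quad > 0, (s2 - pois) / quad, 0)
  pmin(pmax(alpha, 1e-8), 10)
}

# Vectorized Fisher scoring for the two-group NB model with offsets:
# mu_gi = sf_i * q_g(group). Returns log2 fold change numerator/denominator
# and its standard error from the Fisher information.
nb_two_group_fit <- function(counts, sf, num, alpha) {
  fitA <- nb_group_mean(counts[, !num, drop = FALSE], sf[!num], alpha)
  fitB <- nb_group_mean(counts[, num, drop = FALSE], sf[num], alpha)
  list(log2fc = (fitB$eta - fitA$eta) / log(2),
       se = sqrt(1 / pmax(fitA$info, 1e-12) +
                 1 / pmax(fitB$info, 1e-12)) / log(2))
}

nb_group_mean <- function(y, sf, alpha, iter = 40L) {
  eta <- log(pmax(rowSums(y) / sum(sf), 1e-8))
  lo <- log(1e-8); hi <- log(1e12)
  for (k in seq_len(iter)) {
    mu <- outer(exp(eta), sf)
    w <- 1 + alpha * mu
    U <- rowSums((y - mu) / w)
    info <- rowSums(mu / w)
    step <- U / pmax(info, 1e-12)
    step <- pmin(pmax(step, -3), 3)
    eta <- pmin(pmax(eta + step, lo), hi)
    if (max(abs(step)) < 1e-10) break
  }
  mu <- outer(exp(eta), sf)
  list(eta = eta, info = rowSums(mu / (1 + alpha * mu)))
}

# Per-gene NB GLM for designs beyond the two-group case (continuous
# covariates, additive blocking). Dispersion is fixed per gene, so the
# IRLS-weight information matrix gives the Wald covariance directly.
nb_glm_fit <- function(counts, X, sf, alpha) {
  off <- log(sf)
  ti <- ncol(X)
  G <- nrow(counts)
  lfc <- se <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    fam <- MASS::negative.binomial(theta = 1 / alpha[g], link = "log")
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, counts[g, ], family = fam,
                                      offset = off,
                                      control = list(maxit = 50))),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) next
    XtWX <- crossprod(X * fit$weights, X)
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(cov)) next
    lfc[g] <- fit$coefficients[ti] / log(2)
    se[g] <- sqrt(cov[ti, ti]) / log(2)
  }
  list(log2fc = lfc, se = se)
}

#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat("Negative-binomial Wald differential expression\n")
  cat("  contrast: ", ct["test"], " (", ct["numerator"], " vs ",
      ct["denominator"], "), ", attr(x, "n"), " samples\n", sep = "")
  cat("  genes tested: ", sum(!is.na(x$pvalue)), " of ", nrow(x), "\n", sep = "")
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}
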