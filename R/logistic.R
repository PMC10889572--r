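#' Logistic regression of case/control status
#'
#' Maximum-likelihood logistic regression of case status on genotype and
#' covariate terms, used for covariate-adjusted odds ratios. The fit is the
#' standard iteratively reweighted least squares binomial GLM; a univariate
#' fit on a single binary indicator reproduces the cross-product odds ratio
#' exactly (a property asserted in the test suite).
#'
#' @param dataset a [cohort()] object.
#' @param genotypes named character vector mapping `snp_id` to an encoding:
#'   `"additive"` (dosage 0/1/2), `"dominant"` (counted-allele carrier
#'   indicator), `"recessive"` (counted-allele homozygote indicator), or
#'   `"major_carrier"` (major-allele carrier indicator).
#' @param covariates character vector of covariate column names to adjust for.
#' @param conf confidence level for the odds-ratio intervals.
#' @return A `logistic_fit` object: list with `coefficients` (data.frame of
#'   term, estimate, se, z, p_value, or, ci_low, ci_high), `n`, `converged`,
#'   and the underlying `glm` fit.
#' @export
logistic_fit <- function(dataset, genotypes = NULL, covariates = NULL,
                         conf = 0.95) {
  stopifnot(inherits(dataset, "cohort"))
  df <- dataset$subjects
  y <- as.integer(df$status == "case")
  X <- data.frame(row.names = seq_len(nrow(df)))
  if (!is.null(genotypes)) {
    if (is.null(names(genotypes)) || any(names(genotypes) == ""))
      stop("genotypes must be a named vector: c(snp_id = \"encoding\")")
    for (s in names(genotypes)) {
      if (!s %in% dataset$snps$snp_id) stop("SNP not in dataset: ", s)
      d <- df[[s]]
      enc <- match.arg(genotypes[[s]],
                       c("additive", "dominant", "recessive", "major_carrier"))
      X[[paste0(s, "_", enc)]] <- switch(enc,
        additive = d,
        dominant = as.integer(d >= 1L),
        recessive = as.integer(d == 2L),
        major_carrier = as.integer(d <= 1L))
    }
  }
  for (v in covariates %||% character()) {
    if (!v %in% names(df)) stop("covariate not in dataset: ", v)
    X[[v]] <- as.numeric(df[[v]])
  }
  if (ncol(X) == 0 && is.null(genotypes) && is.null(covariates)) {
    dat <- data.frame(y = y)
    fml <- y ~ 1
  } else {
    if (ncol(X) == 0) stop("at least one term required")
    dat <- cbind(data.frame(y = y), X)
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    const <- vapply(dat[-1], function(z) length(unique(z)) < 2, TRUE)
    if (any(const))
      stop("constant term(s): ", paste(names(dat[-1])[const], collapse = ", "))
    fml <- stats::as.formula(paste("y ~", paste(names(dat)[-1], collapse = " + ")))
  }
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  if (!fit$converged) stop("logistic regression did not converge")
  ct <- summary(fit)$coefficients
  ## separation: near-degenerate fitted probabilities with exploding slopes
  sep <- abs(ct[, "Estimate"]) > 12 & ct[, "Std. Error"] > 50
  if (any(sep))
    stop("perfect or quasi-complete separation detected for term(s): ",
         paste(rownames(ct)[sep], collapse = ", "))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  co <- data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                   se = ct[, "Std. Error"], z = ct[, "z value"],
                   p_value = ct[, "Pr(>|z|)"],
                   or = exp(ct[, "Estimate"]),
                   ci_low = exp(ct[, "Estimate"] - z * ct[, "Std. Error"]),
                   ci_high = exp(ct[, "Estimate"] + z * ct[, "Std. Error"]),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = co, n = nrow(dat), converged = fit$converged,
                 fit = fit, conf = conf), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat("Logistic regression of case status,", x$n, "subjects\n")
  y <- x$coefficients
  y[-1] <- lapply(y[-1], signif, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
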