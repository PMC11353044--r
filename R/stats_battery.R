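# Statistical layer: exact two-sided Fisher tests on 2x2 tables, Poisson
# log-linear regression of mutational load, binary logistic regression of
# acquisition events, and an outlier-exclusion refit utility.

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact p-value computed in log space from the hypergeometric density:
#' with margins fixed, the two-sided p is the sum of probabilities of all
#' tables whose probability does not exceed that of the observed table
#' (with relative numeric slack 1e-12 against ties lost to rounding).
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   (rows = groups, cols = outcome yes/no)
#' @return Two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(4, 17, 9, 3), nrow = 2))   # 0.0028
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  n <- sum(tab)
  if (n == 0) stop("all-zero table: Fisher test undefined")
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1])
  x <- max(0, c1 - (n - r1)):min(r1, c1)
  lp <- stats::dhyper(x, r1, n - r1, c1, log = TRUE)
  lobs <- stats::dhyper(tab[1, 1], r1, n - r1, c1, log = TRUE)
  min(1, sum(exp(lp[lp <= lobs + 1e-12])))
}

regression_result <- function(model, predictor, fit, excluded = NULL) {
  co <- summary(fit)$coefficients
  if (nrow(co) < 2) stop("degenerate fit: no slope estimated")
  structure(list(model = model, predictor = predictor,
                 intercept = co[1, 1], slope = co[2, 1], se = co[2, 2],
                 p = co[2, 4], n = stats::nobs(fit),
                 excluded_points = excluded, fit = fit),
            class = "stemdrift_regression")
}

#' @export
print.stemdrift_regression <- function(x, ...) {
  cat(sprintf("%s: slope(%s) = %.4f (se %.4f), p = %.4g, n = %d\n",
              x$model, x$predictor, x$slope, x$se, x$p, x$n))
  if (length(x$excluded_points))
    cat("  excluded points:", paste(x$excluded_points, collapse = ", "), "\n")
  invisible(x)
}

#' Poisson log-linear regression of mutational load
#'
#' Fits log E[count] = b0 + b1 * x by IRLS (`stats::glm`, tolerance 1e-8,
#' at most 100 iterations) and reports the two-sided Wald p-value on the
#' slope. Used for "load of acquired mutations vs sampling rank / passage".
#'
#' @param x predictor values (sample rank or passage number)
#' @param counts non-negative mutation counts
#' @param predictor label recorded in the result
#' @return A `stemdrift_regression` with slope, se, p, n.
#' @export
poisson_load_regression <- function(x, counts, predictor = "rank") {
  if (length(x) != length(counts)) stop("x and counts differ in length")
  if (length(x) < 3) stop("need at least 3 points")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("all counts zero: load regression undefined")
  fit <- stats::glm(counts ~ x, family = stats::poisson(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged)
    stop("IRLS did not converge within 100 iterations (deviance ",
         format(fit$deviance), ")")
  regression_result("poisson_loglinear", predictor, fit)
}

#' Binary logistic regression of acquisition events
#'
#' Fits logit P(event) = b0 + b1 * x by IRLS and reports the two-sided Wald
#' p-value on the slope. Used for "risk of acquiring a de novo mutation at
#' a given passage" (the rate question, as opposed to the load question).
#'
#' @param x predictor values
#' @param events 0/1 (or logical) event indicators; both classes required
#' @param predictor label recorded in the result
#' @return A `stemdrift_regression`.
#' @export
logistic_acquisition_regression <- function(x, events, predictor = "passage") {
  events <- as.integer(events)
  if (length(x) != length(events)) stop("x and events differ in length")
  if (length(x) < 3) stop("need at least 3 points")
  if (!all(events %in% 0:1)) stop("events must be 0/1")
  if (length(unique(events)) < 2)
    stop("both event classes must be present")
  fit <- suppressWarnings(
    stats::glm(events ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  if (fit$deviance < 1e-8)
    stop("perfect separation: the predictor separates the classes exactly")
  if (!fit$converged)
    stop("IRLS did not converge within 100 iterations")
  regression_result("binary_logistic", predictor, fit)
}

#' Refit a regression with points excluded as outliers
#'
#' @param x,y the full data (y = counts or 0/1 events depending on `model`)
#' @param exclude logical vector marking excluded points, or a predicate
#'   `function(x, y)` returning one
#' @param model "poisson_loglinear" or "binary_logistic"
#' @param predictor label recorded in the result
#' @return A `stemdrift_regression` on the retained points, with
#'   `excluded_points` recording the indices removed.
#' @export
refit_without_outliers <- function(x, y, exclude,
                                   model = c("poisson_loglinear",
                                             "binary_logistic"),
                                   predictor = "passage") {
  model <- match.arg(model)
  drop <- if (is.function(exclude)) exclude(x, y) else exclude
  if (!is.logical(drop) || length(drop) != length(x))
    stop("exclude must mark one logical per point")
  keep <- !drop
  if (sum(keep) < 3) stop("fewer than 3 points survive exclusion")
  res <- if (model == "poisson_loglinear")
    poisson_load_regression(x[keep], y[keep], predictor = predictor)
  else
    logistic_acquisition_regression(x[keep], y[keep], predictor = predictor)
  res$excluded_points <- which(drop)
  res$n <- sum(keep)
  res
}
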