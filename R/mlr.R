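# Multivariable linear regression validation of candidate fragments.
#
# For one fragment, every non-reference sequence contributes a row of six
# window-averaged property features; thermostability is regressed on
# those features by ordinary least squares with the thermal class as a
# 0/1 response (a linear probability model -- the dataset construction
# excludes the 40-50 degree band, so the class indicator, not the raw
# OGT, matches the bimodal design; raw OGT is available as an option).
# The multiple correlation R = sqrt(R^2) and the global F-test p-value
# summarise the fit; per-property t-tests at alpha = 0.05 name the
# significant impact factors.

#' Per-sequence property features of one fragment
#'
#' @param fm A `fragment_matrix` (or an `alignment_set` together with
#'   `table`).
#' @param fragment Fragment start column.
#' @param table Property table; only needed when `fm` is an
#'   `alignment_set`.
#' @return Data frame with one row per non-reference sequence: `id`,
#'   `group`, `ogt` and the six window features named by property label.
#' @export
fragment_features <- function(fm, fragment, table = NULL) {
  if (inherits(fm, "alignment_set")) {
    if (is.null(table)) stop("table required when passing an alignment_set")
    fm <- fragment_matrix(fm, table)
  }
  stopifnot(inherits(fm, "fragment_matrix"))
  if (fragment < 1L || fragment > fm$m) stop("Fragment out of range: ", fragment)
  pr <- fm$profiles
  rows <- which(pr$group != "reference")
  X <- vapply(pr$acc, function(acc) pr$val[[acc]][rows, fragment],
              numeric(length(rows)))
  colnames(X) <- unname(pr$labels[pr$acc])
  data.frame(id = pr$ids[rows], group = pr$group[rows],
             X, row.names = NULL, check.names = FALSE)
}

#' Fit the fragment-level multivariable linear regression
#'
#' @param features Data frame from [fragment_features()] or a numeric
#'   matrix of predictors (one column per property).
#' @param response Numeric response per row: by default the thermal class
#'   indicator (0 mesophilic, 1 thermophilic) derived from
#'   `features$group`; pass a numeric vector (e.g. raw OGT) to override.
#' @param factor_alpha Per-factor significance level (default 0.05).
#' @return Object of class `mlr_result`: list with `R` (multiple
#'   correlation), `r_squared`, `p_overall` (global F-test),
#'   `coefficients` (per-property estimate, t, p), `significant`
#'   (property names passing `factor_alpha`), `dropped` (collinear
#'   columns removed from the fit), `n`.
#' @export
mlr_fit <- function(features, response = NULL, factor_alpha = 0.05) {
  if (is.data.frame(features)) {
    num <- vapply(features, is.numeric, logical(1)) &
      !names(features) %in% c("ogt")
    X <- as.matrix(features[, num, drop = FALSE])
    if (is.null(response)) {
      if (!"group" %in% names(features)) {
        stop("response is required when features carry no group column")
      }
      response <- as.numeric(features$group == "thermophilic")
    }
  } else {
    X <- as.matrix(features)
    if (is.null(response)) stop("response is required for a matrix input")
  }
  n <- nrow(X)
  if (n < ncol(X) + 2L) {
    stop("Need more rows (", n, ") than predictors plus intercept (",
         ncol(X) + 1L, ")")
  }
  if (length(unique(response)) < 2L) {
    stop("Response is constant; both thermal classes are required")
  }
  df <- data.frame(.y = response, X, check.names = TRUE)
  fit <- stats::lm(.y ~ ., data = df)
  dropped <- character(0)
  if (anyNA(stats::coef(fit))) {
    nas <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    dropped <- colnames(X)[make.names(colnames(X)) %in% nas]
    warning("Rank-deficient design; dropped collinear column(s): ",
            paste(dropped, collapse = ", "))
  }
  sm <- summary(fit)
  r2 <- sm$r.squared
  fstat <- sm$fstatistic
  p_overall <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  ct <- sm$coefficients
  ct <- ct[rownames(ct) != "(Intercept)", , drop = FALSE]
  prop_names <- colnames(X)[match(rownames(ct), make.names(colnames(X)))]
  coefs <- data.frame(property = prop_names,
                      estimate = ct[, 1L], t = ct[, 3L], p = ct[, 4L],
                      row.names = NULL)
  significant <- coefs$property[coefs$p < factor_alpha]
  structure(list(R = sqrt(max(r2, 0)), r_squared = r2,
                 p_overall = unname(p_overall), coefficients = coefs,
                 significant = significant, dropped = dropped, n = n,
                 factor_alpha = factor_alpha, fit = fit),
            class = "mlr_result")
}

#' @export
print.mlr_result <- function(x, ...) {
  cat("MLR fit on ", x$n, " sequences: R = ", signif(x$R, 3),
      ", overall p = ", format.pval(x$p_overall, digits = 3), "\n",
      "  significant factors (alpha = ", x$factor_alpha, "): ",
      if (length(x$significant)) paste(x$significant, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Validate a set of candidate fragments by MLR
#'
#' @param fm A `fragment_matrix`.
#' @param fragments Fragment start columns to validate (e.g. the
#'   candidates from [candidate_fragments()]).
#' @param factor_alpha Per-factor significance level.
#' @return Data frame with one row per fragment: `fragment`, `R`,
#'   `p_overall`, `significant` (comma-separated property labels), plus
#'   a list-column `fitobj` of `mlr_result`s as an attribute.
#' @export
validate_candidates <- function(fm, fragments, factor_alpha = 0.05) {
  fits <- lapply(fragments, function(fr) {
    mlr_fit(fragment_features(fm, fr), factor_alpha = factor_alpha)
  })
  out <- data.frame(
    fragment = as.integer(fragments),
    R = vapply(fits, `[[`, numeric(1), "R"),
    p_overall = vapply(fits, `[[`, numeric(1), "p_overall"),
    significant = vapply(fits, function(f)
      paste(f$significant, collapse = ", "), character(1)),
    row.names = NULL)
  attr(out, "fits") <- fits
  out
}
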