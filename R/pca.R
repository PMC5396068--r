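# PCA / varimax fragment scoring.
#
# The retained rows of the difference matrix V (fragments x 6 properties)
# are column-standardized, decomposed by PCA on the correlation matrix,
# and the components with standard deviation > 1 are varimax-rotated.
# Rotated components are kept as factor loadings (FLs) until their
# cumulative variance share reaches the configured level (default 80%),
# and each fragment is scored by the variance-weighted Euclidean norm of
# its rotated component scores:
#
#     L(i) = sqrt( sum_k v'_k f_k(i)^2 )
#
# with v'_k the chosen FLs' variance shares renormalized to sum to one.
# The score is non-negative, collapses to |f_1(i)| when a single FL is
# chosen, and is invariant to the sign indeterminacy of the loadings.

#' Column-standardize a difference matrix
#'
#' Centers and scales each property column to mean 0 and sample (n-1)
#' standard deviation 1.
#'
#' @param V Numeric matrix (fragments x properties), at least two rows.
#' @return Standardized matrix `Z` with attributes `center` and `scale`.
#' @export
standardize_matrix <- function(V) {
  V <- as.matrix(V)
  if (nrow(V) < 2L) stop("Standardization needs at least 2 fragments")
  if (any(!is.finite(V))) stop("Non-finite values in difference matrix")
  ctr <- colMeans(V)
  scl <- apply(V, 2L, stats::sd)
  zero <- scl == 0
  if (any(zero)) {
    nm <- colnames(V)[zero]
    if (is.null(nm)) nm <- which(zero)
    stop("Zero-variance property column(s): ", paste(nm, collapse = ", "),
         "; PCA is undefined")
  }
  Z <- sweep(sweep(V, 2L, ctr), 2L, scl, "/")
  attr(Z, "center") <- ctr
  attr(Z, "scale") <- scl
  Z
}

#' Principal component analysis of the standardized difference matrix
#'
#' Eigen-decomposes the correlation structure of `Z` (PCA without further
#' centering or scaling).  Loadings are unit-norm coefficient vectors
#' `a_kj` (sum of squares 1 per component), scores are `Z %*% a`, and
#' variance proportions are `sdev_j^2 / sum(sdev^2)`; because `Z` is
#' standardized the proportions sum to one exactly.
#'
#' @param Z Standardized matrix from [standardize_matrix()].
#' @return List with `loadings` (K x K), `scores` (n x K), `sdev`
#'   (non-increasing) and `prop` (variance proportions).
#' @export
pca_fragments <- function(Z) {
  if (any(!is.finite(Z))) stop("Non-finite values in standardized matrix")
  p <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  list(loadings = p$rotation, scores = p$x, sdev = p$sdev,
       prop = p$sdev^2 / sum(p$sdev^2))
}

#' Retain high-variance components and varimax-rotate them
#'
#' Components with standard deviation above `sd_threshold` are retained;
#' their loading block, scaled by the component standard deviations, is
#' varimax-rotated (Kaiser normalization, convergence tolerance 1e-6).
#' Rotation is orthogonal, so the block's total squared loading (total
#' explained variance) is preserved.  Rotated components, the factor
#' loadings (FLs), are then chosen greedily by variance share until the
#' cumulative share reaches `cumvar`; if the retained components cannot
#' reach `cumvar`, all of them are chosen.  Ties are broken by original
#' component order.
#'
#' @param p Output of [pca_fragments()].
#' @param sd_threshold Retain components with `sdev >` this (default 1,
#'   the average-variance rule for standardized data).
#' @param cumvar Target cumulative variance share for FL choice
#'   (default 0.80).
#' @return Object of class `rotated_fls`: list with `retained` (component
#'   indices), `rotmat`, `loadings_rot` (scaled, rotated loadings),
#'   `scores_rot`, `var_share` (per rotated component, fraction of total
#'   variance), `chosen` (indices into the rotated block, ordered by
#'   decreasing share), `weights` (renormalized shares of the chosen
#'   FLs), plus the unrotated `sdev` and `prop`.
#' @export
retain_and_rotate <- function(p, sd_threshold = 1, cumvar = 0.80) {
  retained <- which(p$sdev > sd_threshold)
  if (length(retained) == 0L) {
    stop("No principal component has standard deviation > ", sd_threshold,
         "; review the retention threshold")
  }
  K <- length(p$sdev)
  lam <- p$loadings[, retained, drop = FALSE] %*%
    diag(p$sdev[retained], nrow = length(retained))
  if (length(retained) == 1L) {
    rotmat <- matrix(1, 1L, 1L)
    lam_rot <- lam
    scores_rot <- p$scores[, retained, drop = FALSE]
  } else {
    vm <- stats::varimax(lam, normalize = TRUE, eps = 1e-6)
    rotmat <- vm$rotmat
    lam_rot <- unclass(vm$loadings)
    scores_rot <- p$scores[, retained, drop = FALSE] %*% rotmat
  }
  var_share <- colSums(lam_rot^2) / K
  ord <- order(-var_share)            # stable: ties keep original order
  cum <- cumsum(var_share[ord])
  n_choose <- if (cum[length(cum)] < cumvar) length(ord) else
    which(cum >= cumvar)[1L]
  chosen <- ord[seq_len(n_choose)]
  weights <- var_share[chosen] / sum(var_share[chosen])
  structure(list(retained = retained, rotmat = rotmat,
                 loadings_rot = lam_rot, scores_rot = scores_rot,
                 var_share = var_share, chosen = chosen, weights = weights,
                 sdev = p$sdev, prop = p$prop,
                 sd_threshold = sd_threshold, cumvar = cumvar),
            class = "rotated_fls")
}

#' Fragment scores from chosen factor loadings
#'
#' @param fls A `rotated_fls` object.
#' @return Non-negative numeric vector of per-fragment scores
#'   `L(i) = sqrt(sum_k v'_k f_k(i)^2)`.
#' @export
fragment_scores <- function(fls) {
  stopifnot(inherits(fls, "rotated_fls"))
  f <- fls$scores_rot[, fls$chosen, drop = FALSE]
  sqrt(as.vector(f^2 %*% fls$weights))
}

# One pass of the V -> standardize -> PCA -> rotate -> score chain on an
# explicit difference matrix; returns NULL fls and zero scores when V is
# identically zero (identical groups).
score_matrix <- function(V, sd_threshold = 1, cumvar = 0.80) {
  if (nrow(V) == 0L) return(list(scores = numeric(0), fls = NULL))
  if (max(abs(V)) == 0) return(list(scores = rep(0, nrow(V)), fls = NULL))
  Z <- standardize_matrix(V)
  p <- pca_fragments(Z)
  fls <- retain_and_rotate(p, sd_threshold, cumvar)
  list(scores = fragment_scores(fls), fls = fls)
}

#' Score fragments of a fragment matrix
#'
#' Runs the standardize / PCA / varimax / score chain on either the
#' retained (gap-free) fragments — the candidate-detection track — or on
#' all fragments with complete difference rows, the unfiltered score
#' track useful for visualising how gap-rich regions would dominate
#' without the filter.
#'
#' @param fm A `fragment_matrix`.
#' @param sd_threshold,cumvar See [retain_and_rotate()].
#' @param use `"retained"` (default) or `"all"`.
#' @return Object of class `score_result`: list with `use`, `rows`
#'   (fragment indices scored), `scores`, `fls` (NULL when the
#'   difference matrix is identically zero), `sd_threshold`, `cumvar`.
#' @export
score_fragments <- function(fm, sd_threshold = 1, cumvar = 0.80,
                            use = c("retained", "all")) {
  stopifnot(inherits(fm, "fragment_matrix"))
  use <- match.arg(use)
  rows <- if (use == "retained") which(fm$retained) else
    which(stats::complete.cases(fm$D))
  V <- fm$D[rows, , drop = FALSE]
  sm <- score_matrix(V, sd_threshold, cumvar)
  structure(list(use = use, rows = rows, scores = sm$scores, fls = sm$fls,
                 sd_threshold = sd_threshold, cumvar = cumvar),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat("Fragment scores (", x$use, "): ", length(x$rows), " fragments\n",
      sep = "")
  if (!is.null(x$fls)) {
    cat("  PC sdev: ", paste(signif(x$fls$sdev, 3), collapse = ", "), "\n",
        "  retained: ", paste(x$fls$retained, collapse = ", "),
        "; chosen FLs (rotated): ", paste(x$fls$chosen, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Group-mean difference rows for an arbitrary 0/1 thermophile labelling of
# the non-reference sequences, restricted to the given fragment rows.
# Used by the permutation null; profiles are label-free, so only the
# averaging is redone.
diff_for_labels <- function(profiles, thermo_rows, meso_rows, frag_rows) {
  K <- length(profiles$acc)
  V <- matrix(NA_real_, length(frag_rows), K,
              dimnames = list(NULL, profiles$acc))
  for (k in seq_len(K)) {
    Wm <- profiles$val[[profiles$acc[k]]][, frag_rows, drop = FALSE]
    A <- Wm
    A[is.na(A)] <- 0
    Kc <- !is.na(Wm)
    st <- colSums(A[thermo_rows, , drop = FALSE])
    ct <- colSums(Kc[thermo_rows, , drop = FALSE])
    sm <- colSums(A[meso_rows, , drop = FALSE])
    cm <- colSums(Kc[meso_rows, , drop = FALSE])
    V[, k] <- st / ct - sm / cm
  }
  V
}

# Difference matrices for a batch of permuted labellings at once.  The
# window profiles do not depend on labels, so each permutation reduces to
# re-averaging: with A_k the zero-filled value matrix and K_k the
# defined-indicator, one crossprod per property gives all permutations'
# group sums in a single BLAS call.  Returns a list of per-permutation
# fragment x property matrices.
diff_for_label_batch <- function(profiles, perm_idx, nonref, frag_rows) {
  n_perm <- ncol(perm_idx)
  Zt <- matrix(0, length(nonref), n_perm)
  for (b in seq_len(n_perm)) Zt[match(perm_idx[, b], nonref), b] <- 1
  Kp <- length(profiles$acc)
  Dk <- vector("list", Kp)
  for (k in seq_len(Kp)) {
    Wm <- profiles$val[[profiles$acc[k]]][nonref, frag_rows, drop = FALSE]
    A <- Wm
    A[is.na(A)] <- 0
    Ind <- 1 * !is.na(Wm)
    St <- crossprod(A, Zt)
    Ct <- crossprod(Ind, Zt)
    Stot <- colSums(A)
    Ctot <- colSums(Ind)
    Dk[[k]] <- St / Ct - (Stot - St) / (Ctot - Ct)
  }
  lapply(seq_len(n_perm), function(b)
    vapply(Dk, function(M) M[, b], numeric(length(frag_rows))))
}

#' Detect candidate fragments with a permutation null
#'
#' Scores the retained fragments, then recomputes the whole
#' group-mean / difference / PCA / varimax / score chain `n_perm` times
#' with the thermal labels shuffled among the non-reference sequences
#' (group sizes preserved).  Each permutation contributes its maximum
#' fragment score to the null, so the per-fragment p-value
#' `p(i) = (1 + #\{max null score >= L(i)\}) / (1 + n_perm)` is
#' family-wise calibrated across fragments.  A fragment is flagged
#' candidate when it is retained, its score exceeds `threshold` and its
#' p-value is below `alpha`.
#'
#' A parametric alternative (`p_method = "normal"`: upper-tail of a
#' normal fitted to the observed score distribution) is provided for
#' speed; the permutation null is the default and the one used for
#' calibration claims.
#'
#' @param fm A `fragment_matrix`.
#' @param sd_threshold,cumvar See [retain_and_rotate()].
#' @param threshold Score threshold for the candidate rule (default 1.2).
#' @param alpha Significance level (default 0.01).
#' @param n_perm Number of label permutations (default 999).  With
#'   `n_perm < 99` the smallest attainable p-value exceeds 0.01 and a
#'   warning is emitted.
#' @param seed Integer seed for the permutation stream.
#' @param p_method `"permutation"` (default) or `"normal"`.
#' @return Object of class `candidate_result`: a data frame with one row
#'   per retained fragment (`fragment`, `start_col`, `end_col`,
#'   `ref_from`, `ref_to`, `score`, `p`, `candidate`), with attributes
#'   `null_max` (permutation maxima), `thresholds` and `seed`.
#' @export
candidate_fragments <- function(fm, sd_threshold = 1, cumvar = 0.80,
                                threshold = 1.2, alpha = 0.01,
                                n_perm = 999L, seed = NULL,
                                p_method = c("permutation", "normal")) {
  stopifnot(inherits(fm, "fragment_matrix"))
  p_method <- match.arg(p_method)
  sr <- score_fragments(fm, sd_threshold, cumvar, use = "retained")
  rows <- sr$rows
  L <- sr$scores

  null_max <- NULL
  if (length(rows) == 0L) {
    pvals <- numeric(0)
  } else if (is.null(sr$fls)) {
    # identical groups: zero scores, nothing can be a candidate
    pvals <- rep(1, length(rows))
  } else if (p_method == "normal") {
    pvals <- stats::pnorm(L, mean = mean(L), sd = stats::sd(L),
                          lower.tail = FALSE)
  } else {
    if (n_perm < 99L) {
      warning("n_perm = ", n_perm, ": the smallest attainable p-value is ",
              signif(1 / (1 + n_perm), 3),
              ", so alpha = 0.01 cannot be reached")
    }
    if (!is.null(seed)) set.seed(seed)
    profiles <- fm$profiles
    nonref <- which(profiles$group != "reference")
    n_thermo <- sum(profiles$group == "thermophilic")
    perm_idx <- vapply(seq_len(n_perm), function(b) sample(nonref, n_thermo),
                       integer(n_thermo))
    Vb_list <- diff_for_label_batch(profiles, perm_idx, nonref, rows)
    null_max <- vapply(Vb_list, function(Vb) {
      tryCatch(max(score_matrix(Vb, sd_threshold, cumvar)$scores),
               error = function(e) Inf)
    }, numeric(1))
    pvals <- vapply(L, function(li) (1 + sum(null_max >= li)) / (1 + n_perm),
                    numeric(1))
  }

  out <- data.frame(fragment = rows, start_col = rows,
                    end_col = rows + fm$w - 1L,
                    ref_from = fm$ref_from[rows], ref_to = fm$ref_to[rows],
                    score = L, p = pvals,
                    candidate = L > threshold & pvals < alpha,
                    row.names = NULL)
  structure(out, class = c("candidate_result", "data.frame"),
            null_max = null_max, seed = seed,
            thresholds = list(sd_threshold = sd_threshold, cumvar = cumvar,
                              score = threshold, alpha = alpha,
                              n_perm = n_perm, p_method = p_method),
            fls = sr$fls)
}
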