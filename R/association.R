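#' Phenotypic, genotypic and environmental correlation matrices
#'
#' Builds the three trait-pair correlation matrices of a clonal trial from
#' RBD mean (cross-)products:
#' `r_g(X,Y) = cov_g / sqrt(sigma2_g(X) * sigma2_g(Y))`, with the
#' phenotypic and environmental analogues on the corresponding
#' (co)variances.  Genotypic correlations are an indirect estimator and can
#' fall outside `[-1, 1]`; such cells are reported raw and flagged in
#' `out_of_range`, never clamped.  Cells involving a trait whose genotypic
#' variance estimate is non-positive are `NA`.
#'
#' @param x a [clonal_trial] object.
#' @param traits traits to correlate (>= 2; default all traits that year).
#' @param year year label.
#' @param alpha significance level for the correlation flags (two-tailed
#'   t-test on `n - 2` df, with `n` the number of clones).
#' @return an object of class `corr_set`: list with `traits`, matrices
#'   `r_p`, `r_g`, `r_e`, logical flag matrices `sig_p`, `sig_g`,
#'   `out_of_range`, and `n`, `alpha`.
#' @seealso [cor_significance()], [path_analysis()]
#' @export
correlation_matrices <- function(x, traits = NULL, year, alpha = 0.05) {
  stopifnot(inherits(x, "clonal_trial"))
  present <- unique(x$trait[x$year == year])
  if (is.null(traits)) {
    traits <- attr(x, "traits")$trait[attr(x, "traits")$trait %in% present]
  }
  if (length(traits) < 2) stop("need at least two traits", call. = FALSE)

  t <- length(traits)
  vcs <- lapply(traits, function(tr) {
    an <- rbd_anova(x, tr, year)
    raw_g <- (an$ms_genotype - an$ms_error) / an$r
    list(g = raw_g, e = an$ms_error, p = raw_g + an$ms_error, n = an$g)
  })
  names(vcs) <- traits
  n <- vcs[[1L]]$n

  empty <- matrix(NA_real_, t, t, dimnames = list(traits, traits))
  r_p <- r_g <- r_e <- empty
  diag(r_p) <- diag(r_g) <- diag(r_e) <- 1
  for (i in seq_len(t - 1)) {
    for (j in seq(i + 1, t)) {
      mp <- mean_products(x, traits[i], traits[j], year)
      vi <- vcs[[i]]; vj <- vcs[[j]]
      if (vi$p > 0 && vj$p > 0) {
        r_p[i, j] <- r_p[j, i] <- mp$cov_p / sqrt(vi$p * vj$p)
      }
      if (vi$g > 0 && vj$g > 0) {
        r_g[i, j] <- r_g[j, i] <- mp$cov_g / sqrt(vi$g * vj$g)
      }
      if (vi$e > 0 && vj$e > 0) {
        r_e[i, j] <- r_e[j, i] <- mp$cov_e / sqrt(vi$e * vj$e)
      }
    }
  }
  sig_p <- .sig_matrix(r_p, n, alpha)
  sig_g <- .sig_matrix(r_g, n, alpha)
  out_of_range <- abs(r_g) > 1 + 1e-12
  diag(out_of_range) <- FALSE
  structure(list(traits = traits, r_p = r_p, r_g = r_g, r_e = r_e,
                 sig_p = sig_p, sig_g = sig_g,
                 out_of_range = out_of_range, n = n, alpha = alpha,
                 year = year),
            class = "corr_set")
}

.sig_matrix <- function(r, n, alpha) {
  sig <- matrix(NA, nrow(r), ncol(r), dimnames = dimnames(r))
  idx <- which(upper.tri(r), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (!is.na(r[i, j])) {
      s <- cor_significance(r[i, j], n, alpha)$significant
      sig[i, j] <- sig[j, i] <- s
    }
  }
  diag(sig) <- NA
  sig
}

#' @export
print.corr_set <- function(x, digits = 3, ...) {
  cat("Trait correlations (", x$year, "), n = ", x$n,
      " genotypes, alpha = ", x$alpha, "\n", sep = "")
  fmt <- function(r, sig) {
    out <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
    low <- lower.tri(r, diag = TRUE)
    out[low] <- ifelse(is.na(r[low]), "NA",
                       paste0(formatC(r[low], digits = digits,
                                      format = "f"),
                              ifelse(!is.na(sig[low]) & sig[low], "*", "")))
    out
  }
  cat("\nGenotypic (lower triangle, * significant):\n")
  print(fmt(x$r_g, x$sig_g), quote = FALSE)
  cat("\nPhenotypic:\n")
  print(fmt(x$r_p, x$sig_p), quote = FALSE)
  n_oor <- sum(x$out_of_range[upper.tri(x$out_of_range)], na.rm = TRUE)
  if (n_oor) {
    cat("\n", n_oor, " genotypic correlation(s) exceed |1| ",
        "(estimator artifact; reported raw)\n", sep = "")
  }
  invisible(x)
}

#' Significance of a correlation coefficient
#'
#' Two-tailed test of `rho = 0` via `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom (equivalent to the F-test with
#' `t^2 = F(1, n - 2)`).  A degenerate input with `|r| >= 1` is flagged
#' significant with `p = 0` and a note.
#'
#' @param r correlation value.
#' @param n number of independent units behind `r` (>= 3); for genotypic
#'   correlations this is the number of clones.
#' @param alpha significance level.
#' @return a list with `t`, `p`, `significant`, `note`.
#' @export
cor_significance <- function(r, n, alpha = 0.05) {
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (is.na(r)) return(list(t = NA_real_, p = NA_real_,
                            significant = NA, note = "undefined input"))
  if (abs(r) >= 1) {
    return(list(t = Inf * sign(r), p = 0, significant = TRUE,
                note = "degenerate input: |r| >= 1"))
  }
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  list(t = tval, p = p, significant = p < alpha, note = NULL)
}

#' Critical correlation magnitude
#'
#' The smallest `|r|` declared significant by [cor_significance()] at the
#' given `n` and `alpha`.
#'
#' @inheritParams cor_significance
#' @return a positive number below 1.
#' @export
critical_r <- function(n, alpha = 0.05) {
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

#' Path-coefficient analysis
#'
#' Dewey-Lu decomposition of the correlations of a set of predictor traits
#' with a target trait: solves the normal equations `R p = r_y` for the
#' direct effects `p`, where `R` is the predictor correlation matrix and
#' `r_y` the predictor-target correlations.  The indirect effect of
#' predictor `i` via predictor `j` is `r_ij * p_j`; each row of the
#' indirect-effect matrix sums (with the direct effect on the diagonal)
#' back to `r_iy` exactly, and the residual effect satisfies
#' `residual^2 = 1 - sum(p_i * r_iy)`.
#'
#' @param x a square predictor correlation matrix (symmetric, unit
#'   diagonal), or a `corr_set`.
#' @param ... passed to methods.
#' @return an object of class `path_result` with `direct` (named vector),
#'   `indirect` (matrix, direct effects on the diagonal), `target_corr`,
#'   `reconstruction`, `residual_squared`, `residual`, `condition`.
#' @export
path_analysis <- function(x, ...) UseMethod("path_analysis")

#' @rdname path_analysis
#' @param target_corr vector of predictor-target correlations, in predictor
#'   order.
#' @param clamp logical; allow (and truncate to the nearest of -1/1)
#'   correlation entries outside `[-1, 1]`.  By default such matrices are
#'   refused, since out-of-range genotypic correlations signal estimator
#'   breakdown.
#' @param max_condition refuse matrices whose 2-norm condition number
#'   exceeds this bound (no pseudo-inverse fallback).
#' @export
path_analysis.matrix <- function(x, target_corr, clamp = FALSE,
                                 max_condition = 1e8, ...) {
  R <- x
  k <- nrow(R)
  if (ncol(R) != k) stop("predictor matrix must be square", call. = FALSE)
  if (length(target_corr) != k) {
    stop("target_corr length must match the predictor matrix", call. = FALSE)
  }
  if (anyNA(R) || anyNA(target_corr)) {
    stop("correlations contain NA", call. = FALSE)
  }
  if (max(abs(R - t(R))) > 1e-8) {
    stop("predictor matrix must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(R) - 1)) > 1e-8) {
    stop("predictor matrix must have unit diagonal", call. = FALSE)
  }
  if (any(abs(R) > 1 + 1e-12) || any(abs(target_corr) > 1 + 1e-12)) {
    if (!clamp) {
      stop("correlation magnitude exceeds 1; refusing (set clamp = TRUE ",
           "to truncate at the bound)", call. = FALSE)
    }
    R <- pmin(pmax(R, -1), 1); diag(R) <- 1
    target_corr <- pmin(pmax(target_corr, -1), 1)
  }
  kap <- kappa(R, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    stop(sprintf(
      "predictor matrix is singular or ill-conditioned (condition %.3g)",
      kap), call. = FALSE)
  }
  if (is.null(rownames(R))) {
    dimnames(R) <- list(paste0("X", seq_len(k)), paste0("X", seq_len(k)))
  }
  p <- solve(R, target_corr)
  names(p) <- rownames(R)
  indirect <- R * rep(p, each = k)   # cell (i, j) = r_ij * p_j
  recon <- rowSums(indirect)         # = direct_i + sum_{j != i} r_ij p_j
  stopifnot(max(abs(recon - target_corr)) <= 1e-9 * max(1, kap))
  res2 <- 1 - sum(p * target_corr)
  structure(list(direct = p, indirect = indirect,
                 target_corr = stats::setNames(target_corr, rownames(R)),
                 reconstruction = recon,
                 residual_squared = res2,
                 residual = sqrt(max(res2, 0)),
                 negative_residual_squared = res2 < 0,
                 condition = kap),
            class = "path_result")
}

#' @rdname path_analysis
#' @param target target trait name (a column of the correlation set).
#' @param type `"genotypic"` (default, the conventional choice) or
#'   `"phenotypic"`.
#' @export
path_analysis.corr_set <- function(x, target,
                                   type = c("genotypic", "phenotypic"),
                                   clamp = FALSE, max_condition = 1e8, ...) {
  type <- match.arg(type)
  m <- if (type == "genotypic") x$r_g else x$r_p
  if (!target %in% x$traits) stop("unknown target trait: ", target,
                                  call. = FALSE)
  preds <- setdiff(x$traits, target)
  R <- m[preds, preds, drop = FALSE]
  ry <- m[preds, target]
  if (type == "genotypic" && !clamp) {
    used <- x$out_of_range[preds, c(preds, target)]
    if (any(used, na.rm = TRUE)) {
      stop("genotypic correlations outside [-1, 1] among the predictors; ",
           "refusing (set clamp = TRUE to truncate)", call. = FALSE)
    }
  }
  path_analysis(R, target_corr = ry, clamp = clamp,
                max_condition = max_condition)
}

#' @export
print.path_result <- function(x, digits = 3, ...) {
  k <- length(x$direct)
  cat("Path-coefficient analysis (", k, " predictors)\n", sep = "")
  tab <- data.frame(direct = round(x$direct, digits),
                    indirect_total = round(x$reconstruction - x$direct,
                                           digits),
                    total_r = round(x$target_corr, digits))
  print(tab)
  cat(sprintf("Residual effect = %.4f (residual^2 = %.4f)%s\n",
              x$residual, x$residual_squared,
              if (x$negative_residual_squared)
                "  [negative; correlations inconsistent]" else ""))
  invisible(x)
}
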