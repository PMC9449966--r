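#' Coefficients of variation from variance components
#'
#' `pcv = 100 * sqrt(sigma2_p) / mean`, `gcv = 100 * sqrt(sigma2_g) / mean`,
#' `ecv = 100 * sqrt(sigma2_e) / mean`.
#'
#' @param vc a [variance_components] object.
#' @param grand_mean trait grand mean (must be positive; a CV is undefined
#'   otherwise).
#' @return a list with components `pcv`, `gcv`, `ecv` (percent).
#' @export
coefficients_of_variation <- function(vc, grand_mean) {
  stopifnot(inherits(vc, "variance_components"))
  if (!is.finite(grand_mean) || grand_mean <= 0) {
    stop("coefficient of variation undefined for non-positive grand mean",
         call. = FALSE)
  }
  list(pcv = 100 * sqrt(vc$sigma2_p) / grand_mean,
       gcv = 100 * sqrt(vc$sigma2_g) / grand_mean,
       ecv = 100 * sqrt(vc$sigma2_e) / grand_mean)
}

#' Broad-sense heritability
#'
#' `h2 = sigma2_g / sigma2_p`, the repeatability of clone performance on a
#' plot basis.  Returns `NA` (with a warning) when the phenotypic variance
#' is zero.
#'
#' @param vc a [variance_components] object.
#' @return heritability as a proportion in `[0, 1]`, or `NA`.
#' @export
broad_sense_heritability <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (vc$sigma2_p <= 0) {
    warning("phenotypic variance is zero; heritability undefined",
            call. = FALSE)
    return(NA_real_)
  }
  vc$sigma2_g / vc$sigma2_p
}

#' Heritability implied by printed coefficients of variation
#'
#' Convenience for auditing published estimate tables:
#' `h2 = (gcv / pcv)^2` (as a proportion), an algebraic identity of the
#' variance-component definitions.
#'
#' @param gcv,pcv genotypic and phenotypic coefficients of variation
#'   (percent, `pcv > 0`).
#' @return implied heritability as a proportion.
#' @export
h2_from_cv <- function(gcv, pcv) {
  stopifnot(all(pcv > 0))
  (gcv / pcv)^2
}

#' Genetic advance under truncation selection
#'
#' Expected gain from selecting the best fraction of clones:
#' `GA = k * h2 * sqrt(sigma2_p)` and
#' `GA% of mean = 100 * GA / grand_mean = k * h2 * pcv`.  The default
#' `k = 2.06` is the standardized selection differential at 5% selection
#' intensity.
#'
#' @param vc a [variance_components] object.
#' @param h2 broad-sense heritability (proportion).
#' @param k standardized selection differential (> 0).
#' @param grand_mean trait grand mean (> 0).
#' @return a list with `ga` (trait units) and `ga_percent_mean` (percent).
#' @export
genetic_advance <- function(vc, h2, k = 2.06, grand_mean) {
  stopifnot(inherits(vc, "variance_components"))
  if (k <= 0) stop("selection differential k must be positive", call. = FALSE)
  if (!is.finite(grand_mean) || grand_mean <= 0) {
    stop("grand mean must be positive", call. = FALSE)
  }
  ga <- k * h2 * sqrt(vc$sigma2_p)
  list(ga = ga, ga_percent_mean = 100 * ga / grand_mean)
}

#' Qualitative bands for genetic parameters
#'
#' Conventional cutoffs used in variability studies; all intervals are
#' left-closed at the boundary.  CV (PCV/GCV) and GA% of mean: `< 10` low,
#' `10-20` moderate, `> 20` high.  Heritability (percent): `< 30` low,
#' `30-60` moderate, `> 60` high.
#'
#' @param x numeric vector (percent scale).
#' @return character vector of `"low"`, `"moderate"`, `"high"`.
#' @export
classify_cv <- function(x) {
  ifelse(is.na(x), NA_character_,
         ifelse(x < 10, "low", ifelse(x <= 20, "moderate", "high")))
}

#' @rdname classify_cv
#' @export
classify_ga <- function(x) classify_cv(x)

#' @rdname classify_cv
#' @param percent logical; is `x` on the percent scale (default) or a
#'   proportion?
#' @export
classify_h2 <- function(x, percent = TRUE) {
  if (!percent) x <- 100 * x
  ifelse(is.na(x), NA_character_,
         ifelse(x < 30, "low", ifelse(x <= 60, "moderate", "high")))
}

#' Fit the genetic-parameter model to a clonal trial
#'
#' The package's central fit: for every trait of one trial year it runs the
#' balanced RBD ANOVA, extracts variance components, and derives the
#' standard variability summary (PCV/GCV/ECV, broad-sense heritability,
#' genetic advance and its percent of mean, qualitative bands), plus the
#' phenotypic/genotypic/environmental correlation matrices among the
#' traits.  The identity `GA% of mean = k * h2 * pcv` is asserted for every
#' row.
#'
#' @param x a [clonal_trial] object.
#' @param year year label to analyse (analyses are strictly per-year).
#' @param traits traits to include (default: all traits observed that year).
#' @param k standardized selection differential (default 2.06, the 5%
#'   selection intensity).
#' @param alpha significance level for correlation flags.
#' @param correlations logical; compute the trait-pair correlation matrices
#'   (default `TRUE`; skip for speed when only per-trait parameters are
#'   needed).
#' @return an object of class `rbd_genetics` with components `params` (one
#'   row per trait), `anovas` (list of [rbd_anova] fits), `correlations`
#'   (a `corr_set` or `NULL`), and the call metadata.  Methods: `print`,
#'   `summary`, `coef` (variance-component matrix), `residuals` (RBD plot
#'   residuals), `plot` (PCV/GCV/heritability bars).
#' @seealso [correlation_matrices()], [path_analysis()], [duncan_test()]
#' @export
#' @examples
#' sim <- simulate_trial(demo_trial_spec(seed = 7))
#' fit <- rbd_genetics(sim$dataset, year = "2020-2021")
#' fit
#' coef(fit)[1:3, ]
rbd_genetics <- function(x, year, traits = NULL, k = 2.06, alpha = 0.05,
                         correlations = TRUE) {
  stopifnot(inherits(x, "clonal_trial"))
  if (missing(year)) {
    if (length(attr(x, "years")) == 1L) year <- attr(x, "years")
    else stop("dataset has several years; specify one", call. = FALSE)
  }
  present <- unique(x$trait[x$year == year])
  if (is.null(traits)) {
    traits <- attr(x, "traits")$trait[attr(x, "traits")$trait %in% present]
  } else if (!all(traits %in% present)) {
    stop("trait(s) not observed in year '", year, "': ",
         paste(setdiff(traits, present), collapse = ", "), call. = FALSE)
  }

  anovas <- lapply(traits, function(tr) rbd_anova(x, tr, year))
  names(anovas) <- traits
  rows <- lapply(anovas, function(an) {
    vc <- variance_components(an)
    cv <- coefficients_of_variation(vc, an$grand_mean)
    h2 <- broad_sense_heritability(vc)
    ga <- genetic_advance(vc, h2, k = k, grand_mean = an$grand_mean)
    # exact identity of the chain (up to float rounding)
    stopifnot(abs(ga$ga_percent_mean - k * h2 * cv$pcv) <=
                1e-9 * max(1, abs(ga$ga_percent_mean)))
    data.frame(trait = an$trait, grand_mean = an$grand_mean,
               sigma2_g = vc$sigma2_g, sigma2_e = vc$sigma2_e,
               sigma2_p = vc$sigma2_p, truncated = vc$truncated,
               pcv = cv$pcv, gcv = cv$gcv, ecv = cv$ecv,
               h2 = h2, h2_percent = 100 * h2,
               ga = ga$ga, ga_percent_mean = ga$ga_percent_mean,
               band_pcv = classify_cv(cv$pcv),
               band_gcv = classify_cv(cv$gcv),
               band_h2 = classify_h2(100 * h2),
               band_ga = classify_ga(ga$ga_percent_mean),
               stringsAsFactors = FALSE)
  })
  params <- do.call(rbind, rows)
  rownames(params) <- NULL

  corr <- NULL
  if (correlations && length(traits) >= 2) {
    corr <- correlation_matrices(x, traits = traits, year = year,
                                 alpha = alpha)
  }
  an1 <- anovas[[1L]]
  structure(list(params = params, anovas = anovas, correlations = corr,
                 year = year, k = k, alpha = alpha, g = an1$g, r = an1$r,
                 call = match.call()),
            class = "rbd_genetics")
}

#' @export
print.rbd_genetics <- function(x, digits = 2, ...) {
  cat("Clonal-trial genetic parameters (", x$year, "): ",
      x$g, " clones x ", x$r, " replications, k = ", x$k, "\n\n", sep = "")
  tab <- x$params[, c("trait", "grand_mean", "pcv", "gcv", "ecv",
                      "h2_percent", "ga_percent_mean")]
  names(tab) <- c("trait", "mean", "PCV%", "GCV%", "ECV%", "h2%", "GA%mean")
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  if (any(x$params$truncated)) {
    cat("\nNote: negative genotypic-variance estimate truncated to 0 for:",
        paste(x$params$trait[x$params$truncated], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.rbd_genetics <- function(object, ...) {
  structure(list(fit = object), class = "summary.rbd_genetics")
}

#' @export
print.summary.rbd_genetics <- function(x, digits = 2, ...) {
  fit <- x$fit
  print(fit, digits = digits)
  tab <- fit$params[, c("trait", "band_pcv", "band_gcv", "band_h2",
                        "band_ga")]
  cat("\nQualitative bands (CV and GA%: <10 low, 10-20 moderate, >20 high;",
      "\n h2: <30% low, 30-60% moderate, >60% high):\n")
  print(tab, row.names = FALSE)
  if (!is.null(fit$correlations)) {
    oor <- fit$correlations$out_of_range
    n_oor <- sum(oor[upper.tri(oor)], na.rm = TRUE)
    cat("\nCorrelations: ", length(fit$correlations$traits),
        " traits; ", n_oor,
        " genotypic correlation(s) outside [-1, 1] (estimator artifact, ",
        "reported raw).\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.rbd_genetics <- function(object, ...) {
  m <- as.matrix(object$params[, c("sigma2_g", "sigma2_e", "sigma2_p", "h2")])
  rownames(m) <- object$params$trait
  m
}

#' @export
residuals.rbd_genetics <- function(object, data, ...) {
  if (missing(data)) {
    stop("the fit does not retain plot data; pass the clonal_trial as ",
         "'data' (or call rbd_residuals(data, fit))", call. = FALSE)
  }
  rbd_residuals(data, object)
}

#' RBD plot residuals for a fitted trial
#'
#' Residuals of the additive RBD model,
#' `e_ij = y_ij - clone mean - block mean + grand mean`, per trait.
#'
#' @param x the [clonal_trial] the fit was computed from.
#' @param fit an [rbd_genetics] fit on `x`.
#' @return a long data.frame with columns `trait`, `clone`, `replication`,
#'   `residual`.
#' @export
rbd_residuals <- function(x, fit) {
  stopifnot(inherits(x, "clonal_trial"), inherits(fit, "rbd_genetics"))
  out <- lapply(fit$params$trait, function(tr) {
    m <- .trait_matrix(x, tr, fit$year)
    e <- m - outer(rowMeans(m), rep(1, ncol(m))) -
      outer(rep(1, nrow(m)), colMeans(m)) + mean(m)
    data.frame(trait = tr,
               clone = rep(rownames(m), times = ncol(m)),
               replication = rep(as.integer(colnames(m)), each = nrow(m)),
               residual = as.vector(e), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
plot.rbd_genetics <- function(x, ...) {
  p <- x$params
  op <- graphics::par(mar = c(9, 4, 2, 1))
  on.exit(graphics::par(op))
  h <- rbind(p$pcv, p$gcv)
  graphics::barplot(h, beside = TRUE, names.arg = p$trait, las = 2,
                    cex.names = 0.7,
                    col = c("grey35", "grey70"),
                    ylab = "coefficient of variation (%)",
                    main = paste("PCV and GCV by trait,", x$year), ...)
  graphics::legend("topright", legend = c("PCV", "GCV"),
                   fill = c("grey35", "grey70"), bty = "n")
  invisible(x)
}
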