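# Balanced RBD sums of squares / cross-products engine.  Written out from
# the definitional decomposition so that the trait-pair mean cross-products
# (the ANCOVA step behind genotypic covariances) share one code path with
# the single-trait ANOVA: mean_products(X, X) reduces exactly to the
# AnovaTable mean squares.

# g x r matrix of plot values (clones in dataset order); errors on
# missing/unbalanced cells
.trait_matrix <- function(x, trait, year) {
  stopifnot(inherits(x, "clonal_trial"))
  if (!trait %in% attr(x, "traits")$trait) {
    stop("unknown trait: ", trait, call. = FALSE)
  }
  if (!year %in% attr(x, "years")) stop("unknown year: ", year, call. = FALSE)
  sub <- x[x$trait == trait & x$year == year, , drop = FALSE]
  if (!nrow(sub)) {
    stop("no observations for trait '", trait, "' in year '", year, "'",
         call. = FALSE)
  }
  clones <- attr(x, "clones")[attr(x, "clones") %in% unique(sub$clone)]
  reps <- sort(unique(sub$replication))
  m <- matrix(NA_real_, length(clones), length(reps),
              dimnames = list(clones, as.character(reps)))
  m[cbind(match(sub$clone, clones), match(sub$replication, reps))] <- sub$value
  if (anyNA(m)) {
    stop("unbalanced layout for trait '", trait, "' in year '", year,
         "': refusing to run a balanced-design analysis", call. = FALSE)
  }
  m
}

# cross-product decomposition for two g x r matrices on the same layout
.rbd_crossprod <- function(mx, my) {
  g <- nrow(mx); r <- ncol(mx)
  gx <- mean(mx); gy <- mean(my)
  sp_g <- r * sum((rowMeans(mx) - gx) * (rowMeans(my) - gy))
  sp_r <- g * sum((colMeans(mx) - gx) * (colMeans(my) - gy))
  sp_tot <- sum((mx - gx) * (my - gy))
  sp_e <- sp_tot - sp_g - sp_r
  list(g = g, r = r, sp_genotype = sp_g, sp_replication = sp_r,
       sp_error = sp_e, sp_total = sp_tot)
}

#' Randomized-block ANOVA for one trait
#'
#' Two-way balanced RBD decomposition (genotype + replication + error) of a
#' single trait in a single year.  The genotype test is
#' `F = MS_genotype / MS_error` on `(g - 1, (g - 1)(r - 1))` degrees of
#' freedom.  A one-way mode (`method = "oneway"`) pools the replication
#' stratum into the error for exact mimicry of a completely randomized
#' analysis; variance-component work should use the default RBD mode, which
#' keeps block effects out of the error mean square.
#'
#' @param x a [clonal_trial] object.
#' @param trait trait name.
#' @param year year label.
#' @param method `"rbd"` (default) or `"oneway"`.
#' @return an object of class `rbd_anova`: a list with the ANOVA `table`
#'   (df, SS, MS, F, p), `g`, `r`, `grand_mean`, per-clone `means`, and the
#'   identifiers.  With degenerate input (zero error variance) F is
#'   reported as `NA`.
#' @export
#' @examples
#' sim <- simulate_trial(demo_trial_spec(seed = 7))
#' rbd_anova(sim$dataset, "seed_yield", "2020-2021")
rbd_anova <- function(x, trait, year, method = c("rbd", "oneway")) {
  method <- match.arg(method)
  m <- .trait_matrix(x, trait, year)
  cp <- .rbd_crossprod(m, m)
  g <- cp$g; r <- cp$r
  df_g <- g - 1
  if (method == "rbd") {
    df_r <- r - 1
    df_e <- (g - 1) * (r - 1)
    ss <- c(cp$sp_genotype, cp$sp_replication, cp$sp_error)
    df <- c(df_g, df_r, df_e)
    src <- c("Genotype", "Replication", "Error")
  } else {
    df_e <- g * (r - 1)
    ss <- c(cp$sp_genotype, cp$sp_replication + cp$sp_error)
    df <- c(df_g, df_e)
    src <- c("Genotype", "Error")
  }
  ms <- ss / df
  ms_e <- ms[length(ms)]
  fstat <- rep(NA_real_, length(src))
  pval <- rep(NA_real_, length(src))
  if (is.finite(ms_e) && ms_e > 0) {
    fstat[-length(src)] <- ms[-length(src)] / ms_e
    pval[-length(src)] <- stats::pf(fstat[-length(src)],
                                    df[-length(src)], df_e,
                                    lower.tail = FALSE)
  }
  table <- data.frame(
    source = c(src, "Total"),
    df = c(df, sum(df)),
    sum_sq = c(ss, cp$sp_total),
    mean_sq = c(ms, NA_real_),
    F = c(fstat, NA_real_),
    p = c(pval, NA_real_),
    stringsAsFactors = FALSE)
  structure(list(table = table, trait = trait, year = year, g = g, r = r,
                 grand_mean = mean(m), means = rowMeans(m),
                 ms_genotype = ms[1], ms_error = ms_e,
                 df_error = df_e, method = method),
            class = "rbd_anova")
}

#' @export
print.rbd_anova <- function(x, ...) {
  cat("Randomized-block ANOVA:", x$trait, "(", x$year, "),",
      x$g, "clones x", x$r, "replications\n")
  tab <- x$table
  tab$sum_sq <- signif(tab$sum_sq, 6)
  tab$mean_sq <- signif(tab$mean_sq, 6)
  tab$F <- signif(tab$F, 5)
  tab$p <- format.pval(tab$p, digits = 4, na.form = "")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Variance components from RBD mean squares
#'
#' Expected-mean-squares extraction for a clonally replicated RBD:
#' `sigma2_g = (MS_genotype - MS_error) / r` (clamped at zero with a
#' `truncated` flag when negative), `sigma2_e = MS_error`, and the
#' phenotypic variance on a plot basis, `sigma2_p = sigma2_g + sigma2_e`
#' (Burton-DeVane convention).
#'
#' @param x an [rbd_anova] object, or the genotype mean square as a number.
#' @param ... passed to methods.
#' @return an object of class `variance_components`.
#' @export
variance_components <- function(x, ...) UseMethod("variance_components")

#' @rdname variance_components
#' @param ms_error error mean square (numeric method).
#' @param r number of replications used (>= 2).
#' @export
variance_components.numeric <- function(x, ms_error, r, ...) {
  ms_genotype <- x
  if (r < 2) stop("need r >= 2 replications", call. = FALSE)
  raw <- (ms_genotype - ms_error) / r
  truncated <- raw < 0
  sigma2_g <- max(raw, 0)
  sigma2_e <- ms_error
  structure(list(sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 sigma2_p = sigma2_g + sigma2_e, r = as.integer(r),
                 truncated = truncated, ms_genotype = ms_genotype,
                 ms_error = ms_error),
            class = "variance_components")
}

#' @rdname variance_components
#' @export
variance_components.rbd_anova <- function(x, ...) {
  if (x$method != "rbd") {
    warning("variance components from a one-way fit pool block variance ",
            "into the error term", call. = FALSE)
  }
  out <- variance_components(x$ms_genotype, ms_error = x$ms_error, r = x$r)
  out$trait <- x$trait
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components", if (!is.null(x$trait)) paste0("(", x$trait, ")"),
      "\n")
  cat(sprintf("  sigma2_g = %.6g%s\n", x$sigma2_g,
              if (x$truncated) "  [negative estimate truncated to 0]" else ""))
  cat(sprintf("  sigma2_e = %.6g\n", x$sigma2_e))
  cat(sprintf("  sigma2_p = %.6g  (plot basis, r = %d)\n", x$sigma2_p, x$r))
  invisible(x)
}

#' Mean cross-products for a trait pair
#'
#' The covariance analogue of [rbd_anova()]: decomposes the cross-products
#' of two traits measured on the same RBD layout into genotype, replication
#' and error mean products, and derives the genotypic, environmental and
#' phenotypic covariances `cov_g = (MP_genotype - MP_error) / r`,
#' `cov_e = MP_error`, `cov_p = cov_g + cov_e`.  The self-pair
#' `mean_products(x, tr, tr, year)` reproduces the ANOVA mean squares
#' exactly.  `cov_g` is reported raw (it is not clamped), since genotypic
#' covariance estimates may be incompatible with the single-trait variance
#' bounds; the association layer surfaces such cases.
#'
#' @param x a [clonal_trial] object.
#' @param trait_x,trait_y trait names on the same balanced layout.
#' @param year year label.
#' @return an object of class `mean_products`.
#' @export
mean_products <- function(x, trait_x, trait_y, year) {
  mx <- .trait_matrix(x, trait_x, year)
  my <- .trait_matrix(x, trait_y, year)
  if (!identical(dim(mx), dim(my)) ||
      !identical(dimnames(mx), dimnames(my))) {
    stop("traits '", trait_x, "' and '", trait_y,
         "' are not on the same layout", call. = FALSE)
  }
  cp <- .rbd_crossprod(mx, my)
  g <- cp$g; r <- cp$r
  mp_g <- cp$sp_genotype / (g - 1)
  mp_r <- cp$sp_replication / (r - 1)
  mp_e <- cp$sp_error / ((g - 1) * (r - 1))
  cov_g <- (mp_g - mp_e) / r
  structure(list(trait_x = trait_x, trait_y = trait_y, year = year,
                 g = g, r = r,
                 mp_genotype = mp_g, mp_replication = mp_r, mp_error = mp_e,
                 cov_g = cov_g, cov_e = mp_e, cov_p = cov_g + mp_e),
            class = "mean_products")
}

#' @export
print.mean_products <- function(x, ...) {
  cat("Mean cross-products:", x$trait_x, "x", x$trait_y, "(", x$year, ")\n")
  cat(sprintf("  MP_genotype = %.6g, MP_replication = %.6g, MP_error = %.6g\n",
              x$mp_genotype, x$mp_replication, x$mp_error))
  cat(sprintf("  cov_g = %.6g, cov_e = %.6g, cov_p = %.6g\n",
              x$cov_g, x$cov_e, x$cov_p))
  invisible(x)
}
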