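#' Specification of a simulated clonal trial
#'
#' Defines the generative model for a randomized-block clonal trial:
#' \deqn{y_{ijt} = \mu_t + g_{it} + b_{jt} + e_{ijt}}
#' where clone effects \eqn{g_i \sim N_t(0, \Sigma_g)} are drawn once per
#' clone and shared across its replications (clonal propagation), block
#' effects \eqn{b_{jt} \sim N(0, \mathrm{block\_sd}_t^2)} are independent
#' across traits, and plot errors \eqn{e_{ij} \sim N_t(0, \Sigma_e)}.
#'
#' @param g number of clones (>= 2).
#' @param r replications per clone (>= 2).
#' @param mu named numeric vector of trait population means; names define
#'   the trait list.
#' @param Sigma_g genotypic covariance matrix (t x t, positive
#'   semidefinite).  A vector is taken as a diagonal.
#' @param Sigma_e plot-error covariance matrix (t x t, positive definite).
#'   A vector is taken as a diagonal.
#' @param block_sd per-trait replication-effect standard deviation (scalar
#'   recycled, or length-t vector).
#' @param units optional character vector of trait units.
#' @param clones optional clone labels (default `C01`, `C02`, ...).
#' @param year year label attached to the generated observations.
#' @param seed integer seed stored with the spec and used by
#'   [simulate_trial()] unless overridden.
#' @return an object of class `trial_sim_spec`.
#' @seealso [simulate_trial()], [ground_truth()], [demo_trial_spec()]
#' @export
trial_sim_spec <- function(g, r, mu, Sigma_g, Sigma_e, block_sd = 0,
                           units = NULL, clones = NULL, year = "year1",
                           seed = 1L) {
  if (g < 2) stop("need at least 2 clones", call. = FALSE)
  if (r < 2) stop("need at least 2 replications", call. = FALSE)
  if (is.null(names(mu))) {
    names(mu) <- sprintf("trait%02d", seq_along(mu))
  }
  t <- length(mu)
  if (is.vector(Sigma_g) && !is.matrix(Sigma_g)) {
    Sigma_g <- diag(rep_len(Sigma_g, t), t)
  }
  if (is.vector(Sigma_e) && !is.matrix(Sigma_e)) {
    Sigma_e <- diag(rep_len(Sigma_e, t), t)
  }
  if (!all(dim(Sigma_g) == t) || !all(dim(Sigma_e) == t)) {
    stop("covariance dimensions inconsistent with trait list", call. = FALSE)
  }
  if (max(abs(Sigma_g - t(Sigma_g))) > 1e-8 ||
      max(abs(Sigma_e - t(Sigma_e))) > 1e-8) {
    stop("covariance matrices must be symmetric", call. = FALSE)
  }
  scale_g <- max(abs(diag(Sigma_g)), 1)
  ev_g <- eigen(Sigma_g, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_g) < -1e-8 * scale_g) {
    stop("Sigma_g is not positive semidefinite (min eigenvalue ",
         format(min(ev_g)), ")", call. = FALSE)
  }
  ev_e <- eigen(Sigma_e, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_e) <= 1e-10 * max(abs(diag(Sigma_e)))) {
    stop("Sigma_e must be positive definite (min eigenvalue ",
         format(min(ev_e)), ")", call. = FALSE)
  }
  block_sd <- rep_len(block_sd, t)
  if (any(block_sd < 0)) stop("block_sd must be non-negative", call. = FALSE)
  if (is.null(clones)) clones <- sprintf("C%02d", seq_len(g))
  if (length(clones) != g) stop("need one label per clone", call. = FALSE)
  if (is.null(units)) units <- rep("unspecified", t)
  dimnames(Sigma_g) <- dimnames(Sigma_e) <- list(names(mu), names(mu))
  structure(list(g = as.integer(g), r = as.integer(r), mu = mu,
                 Sigma_g = Sigma_g, Sigma_e = Sigma_e,
                 block_sd = stats::setNames(block_sd, names(mu)),
                 units = stats::setNames(rep_len(units, t), names(mu)),
                 clones = clones, year = year, seed = as.integer(seed)),
            class = "trial_sim_spec")
}

#' @export
print.trial_sim_spec <- function(x, ...) {
  cat("Clonal-trial simulation spec:", x$g, "clones x", x$r,
      "replications,", length(x$mu), "traits, seed", x$seed, "\n")
  invisible(x)
}

#' Analytic ground truth implied by a simulation spec
#'
#' @param spec a [trial_sim_spec()] object.
#' @return a list with `params` (data.frame of per-trait true
#'   `sigma2_g`, `sigma2_e`, `h2 = sigma2_g / (sigma2_g + sigma2_e)`),
#'   `corr_g` (genotypic correlation implied by `Sigma_g`; `NA` rows where
#'   the genotypic variance is zero) and `corr_e` (error correlation).
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  s2g <- diag(spec$Sigma_g)
  s2e <- diag(spec$Sigma_e)
  params <- data.frame(trait = names(spec$mu), mu = unname(spec$mu),
                       sigma2_g = unname(s2g), sigma2_e = unname(s2e),
                       h2 = unname(s2g / (s2g + s2e)),
                       stringsAsFactors = FALSE)
  corr_g <- .safe_cov2cor(spec$Sigma_g)
  corr_e <- .safe_cov2cor(spec$Sigma_e)
  list(params = params, corr_g = corr_g, corr_e = corr_e)
}

.safe_cov2cor <- function(S) {
  d <- diag(S)
  out <- matrix(NA_real_, nrow(S), ncol(S), dimnames = dimnames(S))
  ok <- d > 0
  if (any(ok)) {
    out[ok, ok] <- stats::cov2cor(S[ok, ok, drop = FALSE])
  }
  diag(out)[ok] <- 1
  out
}

#' Simulate a randomized-block clonal trial
#'
#' Draws one balanced trial-year from the model in [trial_sim_spec()].  The
#' generator is fully determined by the seed (R's default Mersenne-Twister
#' stream): identical spec and seed give identical datasets.
#'
#' @param spec a [trial_sim_spec()] object.
#' @param seed integer seed; defaults to `spec$seed`.
#' @param year year label; defaults to `spec$year`.
#' @return a list with elements `dataset` (a [clonal_trial]) and `truth`
#'   (the [ground_truth()] of the spec).  The seed actually used is stored
#'   as attribute `seed` on the dataset.
#' @export
simulate_trial <- function(spec, seed = spec$seed, year = spec$year) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  t <- length(spec$mu)
  set.seed(as.integer(seed))
  g_eff <- .rmvn(spec$g, spec$Sigma_g)              # g x t clone effects
  b_eff <- matrix(stats::rnorm(spec$r * t), spec$r, t) *
    rep(spec$block_sd, each = spec$r)               # r x t block effects
  e_eff <- .rmvn(spec$g * spec$r, spec$Sigma_e)     # (g*r) x t plot errors

  idx_clone <- rep(seq_len(spec$g), times = spec$r)
  idx_rep <- rep(seq_len(spec$r), each = spec$g)
  vals <- matrix(spec$mu, spec$g * spec$r, t, byrow = TRUE) +
    g_eff[idx_clone, , drop = FALSE] +
    b_eff[idx_rep, , drop = FALSE] + e_eff

  df <- data.frame(
    clone = rep(spec$clones[idx_clone], times = t),
    replication = rep(idx_rep, times = t),
    year = year,
    trait = rep(names(spec$mu), each = spec$g * spec$r),
    value = as.vector(vals),
    units = rep(unname(spec$units), each = spec$g * spec$r),
    stringsAsFactors = FALSE)
  ds <- clonal_trial(df)
  attr(ds, "seed") <- as.integer(seed)
  list(dataset = ds, truth = ground_truth(spec))
}

# multivariate normal draws via eigendecomposition; tolerates PSD-singular
# covariance (negative rounding eigenvalues clamped at zero)
.rmvn <- function(n, Sigma) {
  t <- nrow(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  z <- matrix(stats::rnorm(n * t), n, t)
  z %*% (t(ev$vectors) * sqrt(lam))
}

#' Demonstration spec mirroring a Jatropha backcross clonal trial
#'
#' A ready-made [trial_sim_spec()] at the scale of the reference trial: six
#' clones (five BC4F1 backcross hybrid clones plus the control variety),
#' four replications, and 22 growth, flowering, fruit, seed and oil traits.
#' Trait means sit near the reference third-year clone means; genotypic and
#' error variances are back-calculated from the reference GCV and
#' heritability estimates, so true broad-sense heritabilities span roughly
#' 0.31 to 0.99.  A genotypic correlation block links female flowers,
#' fruits per bunch and seed yield at the reference genotypic correlations.
#'
#' @param seed integer seed stored in the spec.
#' @return a `trial_sim_spec` object with `g = 6`, `r = 4`, 22 traits.
#' @export
demo_trial_spec <- function(seed = 1L) {
  ref <- data.frame(
    trait = c("plant_height", "basal_diameter", "sturdiness_quotient",
              "primary_branches", "secondary_branches", "male_flowers",
              "female_flowers", "mf_flower_ratio", "fruits_per_bunch",
              "bunches_per_branch", "seed_yield", "hundred_fruit_weight",
              "fruit_length", "fruit_width", "fruit_aspect_ratio",
              "hundred_seed_weight", "seed_length", "seed_width",
              "seed_aspect_ratio", "shelling_percent", "seed_oil_content",
              "kernel_oil_content"),
    units = c("cm", "cm", "ratio", "count", "count", "count", "count",
              "ratio", "count", "count", "g", "g", "cm", "cm", "ratio",
              "g", "cm", "cm", "ratio", "%", "%", "%"),
    mu = c(127.3, 19.85, 6.28, 8.20, 9.35, 252.8, 35.17, 7.31, 22.38,
           6.82, 940.3, 112.8, 2.13, 1.70, 1.27, 59.58, 1.72, 0.79,
           2.19, 61.50, 26.36, 47.65),
    gcv = c(5.83, 4.96, 4.64, 14.65, 14.41, 11.03, 9.09, 21.10, 10.73,
            5.48, 16.00, 2.23, 5.96, 4.80, 3.80, 4.22, 1.23, 2.57,
            3.44, 2.55, 16.39, 15.00),
    h2 = c(0.92, 0.90, 0.80, 0.99, 0.99, 0.98, 0.99, 0.99, 0.99, 0.96,
           0.99, 0.80, 0.86, 0.54, 0.31, 0.80, 0.43, 0.46, 0.80, 0.69,
           0.99, 0.95),
    stringsAsFactors = FALSE)
  sg <- (ref$gcv / 100 * ref$mu)^2
  se <- sg * (1 - ref$h2) / ref$h2
  Sigma_g <- diag(sg)
  dimnames(Sigma_g) <- list(ref$trait, ref$trait)
  # reference genotypic correlations among female flowers, fruits/bunch
  # and seed yield (a positive-definite block)
  blk <- c("female_flowers", "fruits_per_bunch", "seed_yield")
  Rb <- matrix(c(1, 0.745, 0.557,
                 0.745, 1, 0.850,
                 0.557, 0.850, 1), 3, 3, dimnames = list(blk, blk))
  sd_blk <- sqrt(sg[match(blk, ref$trait)])
  Sigma_g[blk, blk] <- Rb * tcrossprod(sd_blk)
  mu <- stats::setNames(ref$mu, ref$trait)
  trial_sim_spec(g = 6, r = 4, mu = mu, Sigma_g = Sigma_g, Sigma_e = se,
                 block_sd = 0.02 * ref$mu, units = ref$units,
                 clones = c("CJH 3", "CJH 5", "CJH 9", "CJH 12", "CJH 13",
                            "TNMC 7"),
                 year = "2020-2021", seed = seed)
}
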