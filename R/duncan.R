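#' Duncan's multiple range test
#'
#' Step-down mean separation over clone means.  For a span of `p` ordered
#' means the least significant range is
#' `LSR_p = q*(p, df_error) * SE_mean`, where `SE_mean = sqrt(MS_error/r)`
#' and `q*` is the studentized-range quantile at Duncan's protection level
#' `1 - (1 - alpha)^(p - 1)` (computed from the studentized-range
#' distribution, not table lookups).  The standard step-down rule applies:
#' a range nested inside a non-significant wider range is never declared
#' significant.  Letters come from [compact_letter_display()].
#'
#' @param x named numeric vector of per-clone means, or an [rbd_anova]
#'   object (whose clone means, error mean square and df are used).
#' @param ... passed to methods.
#' @return an object of class `duncan_test`: list with `means` (sorted
#'   descending), `letters` (aligned with `means`), `lsr` (least
#'   significant ranges for spans `2..g`), `significant` (pairwise logical
#'   matrix in sorted order), `se_mean`, `alpha`, `df_error`.
#' @export
#' @examples
#' m <- c(A = 10, B = 9.8, C = 7, D = 6.9)
#' duncan_test(m, ms_error = 0.02, df_error = 9, r = 4)
duncan_test <- function(x, ...) UseMethod("duncan_test")

#' @rdname duncan_test
#' @param ms_error error mean square from the RBD ANOVA (> 0).
#' @param df_error its degrees of freedom (>= 1).
#' @param r replications per mean.
#' @param alpha significance level (default 0.05).
#' @export
duncan_test.numeric <- function(x, ms_error, df_error, r, alpha = 0.05,
                                ...) {
  means <- x
  g <- length(means)
  if (g < 2) stop("need at least two means", call. = FALSE)
  if (!is.finite(ms_error) || ms_error <= 0) {
    stop("ms_error must be positive", call. = FALSE)
  }
  if (df_error < 1) stop("df_error must be >= 1", call. = FALSE)
  if (is.null(names(means))) names(means) <- paste0("T", seq_len(g))
  # descending means; ties broken by label for determinism
  ord <- order(-means, names(means))
  m <- means[ord]
  se_mean <- sqrt(ms_error / r)
  spans <- 2:g
  # span-p significance level is 1 - (1 - alpha)^(p - 1), so the critical
  # studentized range sits at cumulative probability (1 - alpha)^(p - 1)
  lsr <- vapply(spans, function(p) {
    stats::qtukey((1 - alpha)^(p - 1), nmeans = p, df = df_error) * se_mean
  }, numeric(1))
  names(lsr) <- paste0("p", spans)

  # step-down protection: scan spans widest-first; an interval whose range
  # falls short of its LSR protects all pairs inside it
  accepted <- list()   # non-significant intervals [a, b]
  covered <- function(i, j) {
    any(vapply(accepted, function(ab) ab[1] <= i && j <= ab[2], logical(1)))
  }
  for (p in rev(spans)) {
    for (i in seq_len(g - p + 1)) {
      j <- i + p - 1
      if (covered(i, j)) next
      if (m[i] - m[j] <= lsr[p - 1] + 1e-12 * max(1, abs(m[i]))) {
        accepted[[length(accepted) + 1L]] <- c(i, j)
      }
    }
  }
  sig <- matrix(FALSE, g, g, dimnames = list(names(m), names(m)))
  for (i in seq_len(g - 1)) {
    for (j in seq(i + 1, g)) {
      sig[i, j] <- sig[j, i] <- !covered(i, j)
    }
  }
  letters <- compact_letter_display(sig)
  structure(list(means = m, letters = letters, lsr = lsr,
                 significant = sig, se_mean = se_mean, alpha = alpha,
                 df_error = df_error, r = r, ms_error = ms_error),
            class = "duncan_test")
}

#' @rdname duncan_test
#' @export
duncan_test.rbd_anova <- function(x, alpha = 0.05, ...) {
  duncan_test(x$means, ms_error = x$ms_error, df_error = x$df_error,
              r = x$r, alpha = alpha)
}

#' @export
print.duncan_test <- function(x, digits = 2, ...) {
  cat("Duncan's multiple range test (alpha = ", x$alpha, ", df_error = ",
      x$df_error, ", SE_mean = ", signif(x$se_mean, 4), ")\n\n", sep = "")
  tab <- data.frame(mean = round(x$means, digits), group = x$letters)
  print(tab)
  cat("\nLeast significant ranges:\n")
  print(round(x$lsr, 4))
  invisible(x)
}

#' Compact letter display
#'
#' Insert-and-absorb construction of the minimal letter assignment in which
#' two treatments share at least one letter exactly when their difference
#' is non-significant.  Deterministic given the input order (rows are
#' expected in descending-mean order, so letter `a` attaches to the best
#' group).
#'
#' @param significant symmetric logical matrix of pairwise significance
#'   (in display order).
#' @param labels optional names (default the matrix dimnames).
#' @return a named character vector of letter groups, one per treatment.
#' @export
compact_letter_display <- function(significant, labels = NULL) {
  g <- nrow(significant)
  stopifnot(ncol(significant) == g)
  if (is.null(labels)) {
    labels <- rownames(significant)
    if (is.null(labels)) labels <- paste0("T", seq_len(g))
  }
  if (max(abs(significant - t(significant)), na.rm = TRUE) > 0) {
    stop("significance matrix must be symmetric", call. = FALSE)
  }
  groups <- list(seq_len(g))
  for (i in seq_len(g - 1)) {
    for (j in seq(i + 1, g)) {
      if (!isTRUE(significant[i, j])) next
      hit <- which(vapply(groups, function(grp) i %in% grp && j %in% grp,
                          logical(1)))
      if (!length(hit)) next
      for (h in hit) {
        grp <- groups[[h]]
        groups[[h]] <- setdiff(grp, i)
        groups[[length(groups) + 1L]] <- setdiff(grp, j)
      }
      # absorb: drop groups contained in another group
      keep <- rep(TRUE, length(groups))
      for (a in seq_along(groups)) {
        for (b in seq_along(groups)) {
          if (a != b && keep[a] &&
              all(groups[[a]] %in% groups[[b]]) &&
              (length(groups[[a]]) < length(groups[[b]]) ||
               (length(groups[[a]]) == length(groups[[b]]) && a > b))) {
            keep[a] <- FALSE
          }
        }
      }
      groups <- groups[keep]
    }
  }
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  letter_pool <- c(letters, as.vector(outer(letters, letters, paste0)))
  out <- vapply(seq_len(g), function(i) {
    paste0(letter_pool[which(vapply(groups, function(grp) i %in% grp,
                                    logical(1)))], collapse = "")
  }, character(1))
  stats::setNames(out, labels)
}
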