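#' Titration-based oil quality indices
#'
#' The four wet-chemistry formulas used to characterise seed oil for
#' biodiesel suitability, plus the empirical cetane prediction from the
#' saponification and iodine numbers.  Units follow the field conventions:
#' acid value in mg KOH per g oil, free fatty acid as percent oleic acid by
#' weight, saponification number in mg KOH per g, iodine value in g iodine
#' per 100 g.
#'
#' * `acid_value(V, N_koh, W) = V * N_koh * 56.1 / W`
#' * `free_fatty_acid(V, N_koh, W) = 28.2 * V * N_koh / W`
#'   (equivalently `acid_value * 28.2 / 56.1`)
#' * `saponification_number(b, a, W) = (b - a) * 0.02805 * 1000 / W`
#' * `iodine_value(B, S, N_thio, W) = (B - S) * N_thio * 12.69 / W`
#' * `cetane_number(SN, IV) = 46.3 + 5458 / SN - 0.225 * IV`
#'
#' @param V ml of KOH used in the acid titration.
#' @param N_koh normality of the KOH solution.
#' @param W sample weight in g (> 0).
#' @return the index value (vectorised over inputs).
#' @name oil_indices
NULL

#' @rdname oil_indices
#' @export
acid_value <- function(V, N_koh, W) {
  .check_weight(W)
  if (any(V < 0) || any(N_koh <= 0)) {
    stop("titration volume must be >= 0 and normality > 0", call. = FALSE)
  }
  V * N_koh * 56.1 / W
}

#' @rdname oil_indices
#' @export
free_fatty_acid <- function(V, N_koh, W) {
  .check_weight(W)
  if (any(V < 0) || any(N_koh <= 0)) {
    stop("titration volume must be >= 0 and normality > 0", call. = FALSE)
  }
  28.2 * V * N_koh / W
}

#' @rdname oil_indices
#' @param av an acid value in mg KOH/g.
#' @export
ffa_from_acid_value <- function(av) {
  if (any(av < 0)) stop("acid value must be >= 0", call. = FALSE)
  av * 28.2 / 56.1
}

#' @rdname oil_indices
#' @param b ml of 0.5 N HCl required by the blank.
#' @param a ml of 0.5 N HCl required by the sample.
#' @export
saponification_number <- function(b, a, W) {
  .check_weight(W)
  if (any(b < a)) {
    warning("blank titre below sample titre (b < a); ",
            "negative saponification number", call. = FALSE)
  }
  (b - a) * 0.02805 * 1000 / W
}

#' @rdname oil_indices
#' @param B ml of sodium thiosulfate required by the blank.
#' @param S ml of sodium thiosulfate required by the sample.
#' @param N_thio normality of the thiosulfate solution.
#' @export
iodine_value <- function(B, S, N_thio, W) {
  .check_weight(W)
  if (any(N_thio <= 0)) stop("normality must be positive", call. = FALSE)
  if (any(B < S)) {
    warning("blank titre below sample titre (B < S); negative iodine value",
            call. = FALSE)
  }
  (B - S) * N_thio * 12.69 / W
}

#' @rdname oil_indices
#' @param SN saponification number (> 0).
#' @param IV iodine value (>= 0).
#' @export
cetane_number <- function(SN, IV) {
  if (any(SN <= 0)) stop("saponification number must be positive",
                         call. = FALSE)
  if (any(IV < 0)) stop("iodine value must be >= 0", call. = FALSE)
  46.3 + 5458 / SN - 0.225 * IV
}

.check_weight <- function(W) {
  if (any(!is.finite(W)) || any(W <= 0)) {
    stop("sample weight must be positive", call. = FALSE)
  }
  invisible(W)
}

#' Oil quality profile
#'
#' Assembles the derived quality indices for one or more oil samples.  The
#' free fatty acid percent is derived from the acid value (constant factor
#' 28.2/56.1) unless supplied; the cetane number is always computed from
#' the saponification and iodine numbers.
#'
#' @param acid_value acid values (mg KOH/g).
#' @param saponification saponification numbers.
#' @param iodine iodine values.
#' @param ffa optional measured free fatty acid percents (default derived).
#' @param sample optional sample labels.
#' @return a data.frame of class `oil_quality` with columns `sample`,
#'   `acid_value`, `ffa_percent`, `saponification`, `iodine`, `cetane`.
#' @seealso [compliance_check()]
#' @export
oil_quality_profile <- function(acid_value, saponification, iodine,
                                ffa = NULL, sample = NULL) {
  n <- length(acid_value)
  stopifnot(length(saponification) == n, length(iodine) == n)
  if (is.null(sample)) sample <- paste0("sample", seq_len(n))
  if (is.null(ffa)) ffa <- ffa_from_acid_value(acid_value)
  if (any(acid_value < 0) || any(ffa < 0) || any(saponification <= 0) ||
      any(iodine < 0)) {
    stop("indices must be non-negative (saponification positive)",
         call. = FALSE)
  }
  out <- data.frame(sample = sample, acid_value = acid_value,
                    ffa_percent = ffa, saponification = saponification,
                    iodine = iodine,
                    cetane = cetane_number(saponification, iodine),
                    stringsAsFactors = FALSE)
  class(out) <- c("oil_quality", "data.frame")
  out
}

#' Biodiesel standards registry
#'
#' The compliance thresholds applied by [compliance_check()], seeded with
#' the Indian (IS 15607), American (ASTM D6751) and European (EN 14214)
#' limits for predicted cetane number, iodine value and acid value.  The
#' registry is an editable data.frame and can be loaded from a CSV with
#' columns `standard`, `property`, `limit`, `direction` (`min`/`max`).
#'
#' @param path optional CSV path overriding the packaged registry.
#' @return a data.frame with columns `standard`, `property`, `limit`,
#'   `direction`.
#' @export
biodiesel_standards <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "biodiesel_standards.csv",
                        package = "clonetrial", mustWork = TRUE)
  }
  std <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("standard", "property", "limit", "direction")
  if (!all(needed %in% names(std))) {
    stop("standards registry needs columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!all(std$direction %in% c("min", "max"))) {
    stop("direction must be 'min' or 'max'", call. = FALSE)
  }
  std
}

#' Standards compliance check
#'
#' Evaluates every registered threshold against every sample of an oil
#' quality profile.  Boundary values pass (`>=` for minima, `<=` for
#' maxima).  Each flag carries its threshold and standard name; no
#' aggregate verdict is produced — per-row arithmetic truth only.
#'
#' @param profile an [oil_quality_profile()] data.frame.
#' @param standards a standards registry (default [biodiesel_standards()]).
#' @return a long data.frame with columns `sample`, `standard`, `property`,
#'   `limit`, `direction`, `value`, `pass`.
#' @export
compliance_check <- function(profile, standards = biodiesel_standards()) {
  stopifnot(inherits(profile, "oil_quality"))
  prop_col <- c(cetane = "cetane", iodine = "iodine",
                acid_value = "acid_value", ffa_percent = "ffa_percent",
                saponification = "saponification")
  rows <- list()
  for (k in seq_len(nrow(standards))) {
    prop <- standards$property[k]
    if (!prop %in% names(prop_col)) {
      stop("unknown property in standards registry: ", prop, call. = FALSE)
    }
    val <- profile[[prop_col[prop]]]
    pass <- if (standards$direction[k] == "min") val >= standards$limit[k]
            else val <= standards$limit[k]
    rows[[k]] <- data.frame(sample = profile$sample,
                            standard = standards$standard[k],
                            property = prop,
                            limit = standards$limit[k],
                            direction = standards$direction[k],
                            value = val, pass = pass,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
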