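#' Clonal-trial dataset
#'
#' Validates and classes a long-format table of plot observations from a
#' clonally replicated randomized block design (RBD).  Each row is one
#' measurement of one trait on one clone in one replication block of one
#' trial year.  All downstream analyses (`[rbd_anova()]`, `[rbd_genetics()]`,
#' `[correlation_matrices()]`) operate on this container.
#'
#' @param data a data.frame with columns `clone`, `replication`, `year`,
#'   `trait`, `value` (an optional `units` column attaches units to traits).
#' @param strict logical; if `TRUE` an unbalanced design (a missing
#'   clone-by-replication cell for some year/trait) is an error rather than a
#'   warning.
#'
#' @return an object of class `clonal_trial` (a data.frame with attributes
#'   `clones`, `replications`, `years` and `traits`).  Clone, year and trait
#'   orderings follow first appearance in `data`.
#'
#' @details Replications must be positive integers in `1..r`; the key
#'   `(clone, replication, year, trait)` must be unique; values must be
#'   finite numbers.  Missing cells are tolerated with a warning because the
#'   ANOVA layer refuses unbalanced layouts explicitly rather than silently
#'   approximating.
#' @export
#' @examples
#' d <- expand.grid(clone = c("A", "B", "C"), replication = 1:2,
#'                  year = "y1", trait = "height", stringsAsFactors = FALSE)
#' d$value <- c(10, 14, 18, 12, 16, 20)
#' clonal_trial(d)
clonal_trial <- function(data, strict = FALSE) {
  required <- c("clone", "replication", "year", "trait", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("trial data is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$clone <- as.character(data$clone)
  data$year <- as.character(data$year)
  data$trait <- as.character(data$trait)

  rep_num <- suppressWarnings(as.numeric(data$replication))
  if (anyNA(rep_num) || any(rep_num < 1) || any(rep_num != round(rep_num))) {
    stop("'replication' must contain positive integer block indices",
         call. = FALSE)
  }
  data$replication <- as.integer(rep_num)

  val <- suppressWarnings(as.numeric(data$value))
  if (anyNA(val) || any(!is.finite(val))) {
    bad <- which(is.na(val) | !is.finite(val))[1L]
    stop("non-numeric or non-finite value in row ", bad, call. = FALSE)
  }
  data$value <- val

  key <- paste(data$clone, data$replication, data$year, data$trait, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- which(dup)[1L]
    stop(sprintf(
      "duplicated observation key (clone=%s, replication=%d, year=%s, trait=%s)",
      data$clone[first], data$replication[first], data$year[first],
      data$trait[first]), call. = FALSE)
  }

  clones <- unique(data$clone)
  years <- unique(data$year)
  trait_names <- unique(data$trait)
  if (!is.null(data$units)) {
    units <- vapply(trait_names, function(tr) {
      u <- unique(as.character(data$units[data$trait == tr]))
      u <- u[nzchar(u) & !is.na(u)]
      if (length(u)) u[1L] else "unspecified"
    }, character(1))
  } else {
    units <- rep("unspecified", length(trait_names))
  }
  traits <- data.frame(trait = trait_names, units = unname(units),
                       stringsAsFactors = FALSE)
  r <- max(data$replication)

  # balance audit: every clone x replication cell present per year/trait
  unbalanced <- character(0)
  for (yr in years) {
    for (tr in trait_names) {
      sub <- data[data$year == yr & data$trait == tr, , drop = FALSE]
      if (!nrow(sub)) next
      cl <- unique(sub$clone)
      expected <- length(cl) * max(sub$replication)
      if (nrow(sub) != expected ||
          !all(table(sub$clone) == max(sub$replication))) {
        unbalanced <- c(unbalanced, sprintf("%s/%s", yr, tr))
      }
    }
  }
  if (length(unbalanced)) {
    msg <- paste0("unbalanced design for year/trait: ",
                  paste(unbalanced, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }

  structure(data[required],
            clones = clones,
            replications = r,
            years = years,
            traits = traits,
            class = c("clonal_trial", "data.frame"))
}

#' @export
print.clonal_trial <- function(x, ...) {
  cat("Clonal trial dataset\n")
  cat("  clones:      ", length(attr(x, "clones")), " (",
      paste(utils::head(attr(x, "clones"), 6), collapse = ", "),
      if (length(attr(x, "clones")) > 6) ", ..." else "", ")\n", sep = "")
  cat("  replications:", attr(x, "replications"), "\n")
  cat("  years:       ", paste(attr(x, "years"), collapse = ", "), "\n")
  cat("  traits:      ", nrow(attr(x, "traits")), "\n")
  cat("  observations:", nrow(x), "\n")
  invisible(x)
}

#' Read a clonal-trial CSV
#'
#' Reads the canonical long interchange format: a UTF-8 comma-separated file
#' with header `clone,replication,year,trait,value` (plus optional `units`).
#'
#' @param path path to the CSV file.
#' @param strict passed to [clonal_trial()]; error (rather than warn) on an
#'   unbalanced design.
#' @return a [clonal_trial] object.
#' @seealso [write_trial_csv()]
#' @export
read_trial_csv <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("clone", "replication", "year", "trait", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("CSV header is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  clonal_trial(df, strict = strict)
}

#' Write a clonal-trial CSV
#'
#' @param x a [clonal_trial] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(x, path) {
  stopifnot(inherits(x, "clonal_trial"))
  ord <- order(match(x$year, attr(x, "years")),
               match(x$trait, attr(x, "traits")$trait),
               match(x$clone, attr(x, "clones")),
               x$replication)
  utils::write.csv(x[ord, , drop = FALSE], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Per-clone means and standard errors
#'
#' Summarises one trait in one year as the per-clone mean over replications
#' with its standard error of the mean (s / sqrt(r)), in the dataset's clone
#' order.  Letter groups are left `NA` until a mean-separation test
#' ([duncan_test()]) is run.
#'
#' @param x a [clonal_trial] object.
#' @param trait trait name present in the dataset.
#' @param year year label present in the dataset.
#' @return a data.frame with columns `clone`, `n`, `mean`, `se`, `letters`.
#' @export
summarize_means <- function(x, trait, year) {
  stopifnot(inherits(x, "clonal_trial"))
  if (!trait %in% attr(x, "traits")$trait) {
    stop("unknown trait: ", trait, call. = FALSE)
  }
  if (!year %in% attr(x, "years")) stop("unknown year: ", year, call. = FALSE)
  sub <- x[x$trait == trait & x$year == year, , drop = FALSE]
  if (!nrow(sub)) stop("no observations for ", trait, " in ", year,
                       call. = FALSE)
  clones <- attr(x, "clones")[attr(x, "clones") %in% unique(sub$clone)]
  out <- do.call(rbind, lapply(clones, function(cl) {
    v <- sub$value[sub$clone == cl]
    data.frame(clone = cl, n = length(v), mean = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               stringsAsFactors = FALSE)
  }))
  out$letters <- NA_character_
  rownames(out) <- NULL
  out
}

#' Format a mean with its standard error and letter group
#'
#' Renders `"mean ± SE^letters^"` in the style used for clonal-trial
#' report tables.
#'
#' @param mean,se numeric vectors.
#' @param letters optional character vector of letter groups.
#' @param digits decimal places (default 2).
#' @return a character vector.
#' @export
format_mean_se <- function(mean, se, letters = NULL, digits = 2) {
  out <- sprintf(paste0("%.", digits, "f ± %.", digits, "f"), mean, se)
  if (!is.null(letters)) {
    has <- !is.na(letters) & nzchar(letters)
    out[has] <- paste0(out[has], "^", letters[has], "^")
  }
  out
}
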