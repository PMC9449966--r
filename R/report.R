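#' Run the full clonal-trial analysis pipeline
#'
#' Orchestrates the complete per-year analysis of a trial: clone means with
#' Duncan letter groups for every trait, genetic parameters (the
#' PCV/GCV/heritability/genetic-advance table), correlation matrices, and
#' optionally a path-coefficient decomposition onto a target trait and an
#' oil-quality compliance report.  Every output table is returned as a
#' data.frame and, when `out_dir` is given, also written as CSV together
#' with a run-metadata sidecar.  Outputs are deterministic given the
#' inputs; any stage failure aborts with the stage and trait/pair named.
#'
#' @param x a [clonal_trial] object.
#' @param years year labels to analyse (default: all in the dataset).
#' @param traits traits to analyse (default: all).
#' @param k standardized selection differential for genetic advance.
#' @param alpha significance level for correlation flags and mean
#'   separation.
#' @param path_target optional trait name; run genotypic path analysis of
#'   the remaining traits onto it.
#' @param path_clamp logical; truncate out-of-range genotypic correlations
#'   at the `[-1, 1]` bound before the path solve (default `FALSE`: such
#'   matrices are refused, which is common at small clone counts).
#' @param oil optional [oil_quality_profile()] to append a standards
#'   compliance report.
#' @param out_dir optional output directory for CSV export.
#' @return a report bundle: named list with `means`, `genetic_params`,
#'   `correlations`, `path`, `oil_compliance`, `metadata`.
#' @export
run_full_analysis <- function(x, years = NULL, traits = NULL, k = 2.06,
                              alpha = 0.05, path_target = NULL,
                              path_clamp = FALSE, oil = NULL,
                              out_dir = NULL) {
  stopifnot(inherits(x, "clonal_trial"))
  if (is.null(years)) years <- attr(x, "years")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  means <- list(); params <- list(); corrs <- list(); paths <- list()
  for (yr in years) {
    fit <- stage(paste0("genetic_parameters/", yr),
                 rbd_genetics(x, year = yr, traits = traits, k = k,
                              alpha = alpha))
    params[[yr]] <- fit$params
    corrs[[yr]] <- fit$correlations
    mtabs <- lapply(fit$params$trait, function(tr) {
      dt <- stage(paste0("mean_separation/", yr, "/", tr),
                  duncan_test(fit$anovas[[tr]], alpha = alpha))
      sm <- summarize_means(x, tr, yr)
      sm$letters <- unname(dt$letters[sm$clone])
      sm$display <- format_mean_se(sm$mean, sm$se, sm$letters)
      sm$trait <- tr
      sm
    })
    means[[yr]] <- do.call(rbind, mtabs)
    if (!is.null(path_target)) {
      paths[[yr]] <- stage(paste0("path_analysis/", yr, "/", path_target),
                           path_analysis(fit$correlations,
                                         target = path_target,
                                         clamp = path_clamp))
    }
  }
  oil_comp <- NULL
  if (!is.null(oil)) {
    oil_comp <- stage("oil_compliance", compliance_check(oil))
  }
  metadata <- list(package = "clonetrial",
                   version = as.character(utils::packageVersion("clonetrial")),
                   k = k, alpha = alpha, years = years,
                   seed = attr(x, "seed"),
                   sigma_p_basis = "plot (sigma2_g + sigma2_e)",
                   correlation_test = "two-tailed t on n-2 df")
  bundle <- list(means = means, genetic_params = params,
                 correlations = corrs,
                 path = if (length(paths)) paths else NULL,
                 oil_compliance = oil_comp, metadata = metadata)
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
  bundle
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  for (yr in names(bundle$means)) {
    tag <- gsub("[^A-Za-z0-9_-]", "_", yr)
    wr(bundle$means[[yr]], paste0("means_", tag))
    wr(bundle$genetic_params[[yr]], paste0("genetic_params_", tag))
    cs <- bundle$correlations[[yr]]
    if (!is.null(cs)) {
      utils::write.csv(cs$r_g, file.path(out_dir,
                                         paste0("corr_genotypic_", tag,
                                                ".csv")))
      utils::write.csv(cs$r_p, file.path(out_dir,
                                         paste0("corr_phenotypic_", tag,
                                                ".csv")))
      utils::write.csv(cs$sig_g, file.path(out_dir,
                                           paste0("corr_genotypic_sig_",
                                                  tag, ".csv")))
    }
    pr <- bundle$path[[yr]]
    if (!is.null(pr)) {
      tab <- data.frame(predictor = names(pr$direct), direct = pr$direct,
                        total_r = pr$target_corr)
      wr(tab, paste0("path_", tag))
    }
  }
  if (!is.null(bundle$oil_compliance)) wr(bundle$oil_compliance,
                                          "oil_compliance")
  meta <- bundle$metadata
  writeLines(paste0(names(meta), ": ",
                    vapply(meta, function(v) paste(v, collapse = ", "),
                           character(1))),
             file.path(out_dir, "run_metadata.txt"))
  invisible(out_dir)
}

#' Verify the reference tables against the analysis chains
#'
#' Recomputes every quantity in the packaged reference tables that is
#' derivable from other printed quantities, and reports computed vs
#' printed values: the cetane chain (CN from printed SN and IV), the
#' FFA/acid-value ratio, the heritability implied by the printed PCV/GCV,
#' the genetic-advance percent implied by printed PCV/GCV at `k`, and the
#' path-analysis reconstruction identity on the printed genotypic
#' correlation matrix.  Verification failures are report rows (`status`),
#' never errors: rows whose printed heritability caps at 95.00 while the
#' implied value exceeds it are flagged `"cap"`, and rows disagreeing by
#' more than 1 point are flagged `"inconsistent"`.
#'
#' @param k standardized selection differential (default 2.06).
#' @return a data.frame with columns `chain`, `id`, `computed`, `printed`,
#'   `diff`, `status`.
#' @export
verify_reference_tables <- function(k = 2.06) {
  rows <- list()
  add <- function(chain, id, computed, printed, status) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, id = id, computed = computed, printed = printed,
      diff = computed - printed, status = status, stringsAsFactors = FALSE)
  }

  t7 <- load_fixture("T7")
  wide <- function(prop) {
    sub <- t7[t7$property == prop, ]
    stats::setNames(sub$mean, sub$clone)
  }
  sn <- wide("saponification"); iv <- wide("iodine")
  cn <- wide("cetane"); av <- wide("acid_value"); ffa <- wide("ffa_percent")
  for (cl in names(sn)) {
    comp <- cetane_number(sn[[cl]], iv[[cl]])
    add("cetane", cl, comp, cn[[cl]],
        ifelse(round(comp, 2) == cn[[cl]], "pass", "inconsistent"))
  }
  for (cl in names(av)) {
    comp <- ffa_from_acid_value(av[[cl]])
    # 0.0076 = half-ulp of the printed FFA plus the propagated half-ulp of
    # the printed acid value (0.005 * 28.2/56.1)
    add("ffa", cl, comp, ffa[[cl]],
        ifelse(abs(comp - ffa[[cl]]) <= 0.0076, "pass", "inconsistent"))
  }

  t3 <- load_fixture("T3")
  for (i in seq_len(nrow(t3))) {
    comp <- 100 * h2_from_cv(t3$gcv[i], t3$pcv[i])
    printed <- t3$heritability[i]
    status <- if (printed == 95 && comp > 95) "cap"
              else if (abs(comp - printed) <= 1) "pass"
              else "inconsistent"
    add("heritability", t3$trait[i], comp, printed, status)
    comp_ga <- k * t3$gcv[i]^2 / t3$pcv[i]
    add("genetic_advance", t3$trait[i], comp_ga, t3$ga_percent_mean[i],
        ifelse(abs(comp_ga - t3$ga_percent_mean[i]) <= 0.03, "pass",
               "inconsistent"))
  }

  t4 <- load_fixture("T4")
  preds <- setdiff(t4$traits, "seed_yield")
  pr <- path_analysis(t4$genotypic[preds, preds],
                      target_corr = t4$genotypic[preds, "seed_yield"])
  for (p in preds) {
    add("path_reconstruction", p, pr$reconstruction[[p]],
        pr$target_corr[[p]],
        ifelse(abs(pr$reconstruction[[p]] - pr$target_corr[[p]]) <= 1e-9,
               "pass", "inconsistent"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
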