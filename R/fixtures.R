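#' Packaged reference tables
#'
#' Loads one of the seven reference tables transcribed from the published
#' Jatropha BC4F1 backcross hybrid clonal trial that this package's
#' analysis chain is validated against.  Values keep the printed precision
#' (no re-rounding); compact-letter superscripts are kept verbatim as
#' display fixtures.  The raw plot data behind these tables were not
#' deposited, so the tables are inputs for chain-identity verification
#' ([verify_reference_tables()]), not recomputable outputs.
#'
#' * `T1` growth-trait clone means by year (mean, SE, letter group)
#' * `T2` fruit and seed trait clone means
#' * `T3` genetic estimates (PCV, GCV, heritability, GA% of mean)
#' * `T4` biometrical-trait correlations on seed yield (P and G triangles)
#' * `T5` fruit-trait correlations on fruit yield
#' * `T6` seed-trait correlations on seed oil content
#' * `T7` oil quality properties (acid value, FFA, SN, IV, CN)
#'
#' @param table_id one of `"T1"`..`"T7"`.
#' @return for `T1`, `T2`, `T3`, `T7`: a data.frame.  For `T4`-`T6`: a list
#'   with `traits`, full symmetric matrices `phenotypic` and `genotypic`
#'   (unit diagonal), matching logical flag matrices `phenotypic_sig` /
#'   `genotypic_sig`, and the long-form `cells` data.frame.
#' @export
#' @examples
#' t3 <- load_fixture("T3")
#' t3[t3$trait == "seed_oil_content", ]
load_fixture <- function(table_id = c("T1", "T2", "T3", "T4", "T5", "T6",
                                      "T7")) {
  table_id <- match.arg(table_id)
  files <- c(T1 = "table1_growth_means.csv",
             T2 = "table2_fruit_seed_means.csv",
             T3 = "table3_genetic_estimates.csv",
             T4 = "table4_biometrical_correlations.csv",
             T5 = "table5_fruit_correlations.csv",
             T6 = "table6_seed_correlations.csv",
             T7 = "table7_oil_properties.csv")
  path <- system.file("extdata", files[[table_id]], package = "clonetrial",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (table_id %in% c("T4", "T5", "T6")) {
    return(.corr_fixture(df))
  }
  df
}

# long triangle -> symmetric matrices with unit diagonal
.corr_fixture <- function(df) {
  traits <- unique(c(df$trait_row, df$trait_col))
  t <- length(traits)
  build <- function(level) {
    m <- matrix(NA_real_, t, t, dimnames = list(traits, traits))
    s <- matrix(FALSE, t, t, dimnames = list(traits, traits))
    diag(m) <- 1
    sub <- df[df$level == level, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      i <- sub$trait_row[k]; j <- sub$trait_col[k]
      m[i, j] <- m[j, i] <- sub$r[k]
      s[i, j] <- s[j, i] <- sub$significant[k] == 1
    }
    list(r = m, sig = s)
  }
  p <- build("P"); g <- build("G")
  list(traits = traits, phenotypic = p$r, genotypic = g$r,
       phenotypic_sig = p$sig, genotypic_sig = g$sig, cells = df)
}
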