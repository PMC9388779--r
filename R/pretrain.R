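#' Label the pre-training cohort by the CGI rule
#'
#' Healthy controls and unaffected first-degree relatives with CGI = 0 get
#' label 0; SZ and OCD patients who are at least moderately ill (CGI
#' strictly greater than 3) get label 1. Records matching neither rule are
#' dropped, with their count attached and messaged.
#'
#' @param records Data.frame with columns `group` (one of `"HC"`,
#'   `"FDR_SZ"`, `"SZ"`, `"OCD"`) and `cgi`.
#' @return The labelled subset with a new integer `label` column;
#'   `attr(, "n_excluded")` counts the dropped records.
#' @export
assign_cgi_labels <- function(records) {
  stopifnot(all(c("group", "cgi") %in% names(records)))
  lab0 <- records$group %in% c("HC", "FDR_SZ") & records$cgi == 0
  lab1 <- records$group %in% c("SZ", "OCD") & records$cgi > 3
  out <- records[lab0 | lab1, , drop = FALSE]
  out$label <- ifelse(out$group %in% c("HC", "FDR_SZ"), 0L, 1L)
  n_excluded <- nrow(records) - nrow(out)
  if (n_excluded > 0)
    message(sprintf("assign_cgi_labels: %d record(s) match neither rule; excluded",
                    n_excluded))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Oversample the minority class within sex/age strata
#'
#' Duplicates minority-class records until the classes are balanced. The
#' duplicates are drawn (seeded, with replacement) from (sex, age-decile)
#' strata sampled in proportion to the majority class's stratum composition,
#' so the balanced minority mirrors the majority's sex/age marginals. Age
#' deciles are computed on the pooled age distribution. If a required
#' stratum holds no minority record, the nearest age bin with the same sex
#' is used (any minority record as a last resort), with a message.
#' Majority-class records are never touched; an already balanced input is
#' returned unchanged.
#'
#' @param records Labelled data.frame with columns `label`, `sex`, `age`.
#' @param seed RNG seed.
#' @return The balanced data.frame of `2 * max(class count)` rows.
#' @export
oversample_balance <- function(records, seed = 1L) {
  stopifnot(all(c("label", "sex", "age") %in% names(records)))
  counts <- table(factor(records$label, levels = c(0, 1)))
  if (any(counts == 0)) stopf("both classes must be present")
  if (counts[1] == counts[2]) return(records)
  minority <- as.integer(names(which.min(counts)))
  n_extra <- abs(diff(as.vector(counts)))

  qs <- unique(stats::quantile(records$age, probs = seq(0, 1, 0.1)))
  age_bin <- cut(records$age, breaks = qs, include.lowest = TRUE,
                 labels = FALSE)
  stratum <- paste(records$sex, age_bin)
  is_min <- records$label == minority
  maj_strata <- stratum[!is_min]

  extra_idx <- with_seed(seed, {
    draws <- sample(maj_strata, n_extra, replace = TRUE)
    fallbacks <- 0L
    idx <- vapply(draws, function(s) {
      pool <- which(is_min & stratum == s)
      if (!length(pool)) {
        fallbacks <<- fallbacks + 1L
        sx <- as.integer(strsplit(s, " ")[[1]][1])
        bin <- as.integer(strsplit(s, " ")[[1]][2])
        same_sex <- which(is_min & records$sex == sx)
        pool <- if (length(same_sex)) {
          same_sex[order(abs(age_bin[same_sex] - bin))[1]]
        } else {
          which(is_min)
        }
      }
      if (length(pool) == 1) pool else sample(pool, 1)
    }, integer(1))
    if (fallbacks > 0)
      message(sprintf("oversample_balance: %d draw(s) fell back to the nearest stratum",
                      fallbacks))
    idx
  })
  rbind(records, records[extra_idx, , drop = FALSE])
}
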