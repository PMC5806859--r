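#' @title Study-level diagnostic evaluation
#' @description
#' Houses the packaged 92-sample clinical study table (pleural effusions,
#' ascitic fluids and cerebrospinal fluids screened for malignancy) and the
#' study-level computations: the cytology reference call, per-method
#' predictions, 2x2 diagnostic accuracy (sensitivity, specificity, PPV,
#' NPV), the Rule 1 / Rule 2 concordance partition, Mann-Whitney rank-sum
#' comparisons, and mean +/- SEM group summaries.
#' @name study_eval
NULL

CYTOLOGY_LEVELS <- c("Negative", "I", "II", "IIb", "III", "IIIb", "IV", "V")
EVAL_METHODS <- c("xnbf", "micro_diff", "micro_count")

#' Parse Papanicolaou-style cytology class tokens
#'
#' Accepts both ASCII ("II", "IIIb") and Unicode roman-numeral forms as
#' printed in clinical tables, and returns an ordered factor
#' `Negative < I < II < IIb < III < IIIb < IV < V`.
#'
#' @param x character vector of class tokens.
#' @return ordered factor with the full level set.
#' @export
parse_cytology_class <- function(x) {
  x <- trimws(as.character(x))
  # Unicode roman numerals (U+2160..) as found in typeset tables
  x <- gsub("\u2160", "I", x)
  x <- gsub("\u2161", "II", x)
  x <- gsub("\u2162", "III", x)
  x <- gsub("\u2163", "IV", x)
  x <- gsub("\u2164", "V", x)
  bad <- !x %in% CYTOLOGY_LEVELS
  if (any(bad)) {
    stop("unrecognized cytology class token(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = CYTOLOGY_LEVELS, ordered = TRUE)
}

#' Path to the packaged 92-sample study table
#' @return file path of the CSV shipped with the package.
#' @export
study_table_path <- function() {
  system.file("extdata", "bf_study_samples.csv", package = "xnbf",
              mustWork = TRUE)
}

#' Load and validate the study table
#'
#' Reads the CSV of per-sample records (specimen material, histology,
#' cytology class, analyzer counts, the two rule flags, and the two
#' microscopy flags) and verifies two arithmetic invariants on every row:
#' the total cell count equals WBC + HF-BF#, and the printed HF-BF% equals
#' 100 x HF-BF# / WBC rounded half away from zero to one decimal (rows with
#' WBC = 0 are exempt from the second check). A violation is a load error
#' naming the row, which doubles as a transcription-integrity regression
#' check for the packaged fixture.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return data.frame of 92 (for the packaged table) validated records with
#'   `cytology_class` as an ordered factor and the four flags as logicals.
#' @export
load_study_table <- function(path = study_table_path()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  needed <- c("sample_id", "material", "histology", "cytology_class",
              "total_cells", "wbc", "hfbf", "hfbf_percent",
              "rule1", "rule2", "micro_diff", "micro_count")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("study table is missing column(s): ", paste(missing, collapse = ", "))
  }
  flag <- function(v, col) {
    v <- trimws(v)
    v <- gsub("\u2212|\u2013", "-", v)  # unicode minus / en-dash
    bad <- !v %in% c("+", "-")
    if (any(bad)) stop("column ", col, " has values other than +/- in row(s) ",
                       paste(which(bad), collapse = ", "))
    v == "+"
  }
  rec <- data.frame(
    sample_id = as.integer(raw$sample_id),
    material = raw$material,
    histology = raw$histology,
    cytology_class = parse_cytology_class(raw$cytology_class),
    total_cells = as.numeric(raw$total_cells),
    wbc = as.numeric(raw$wbc),
    hfbf = as.numeric(raw$hfbf),
    hfbf_percent = as.numeric(raw$hfbf_percent),
    rule1 = flag(raw$rule1, "rule1"),
    rule2 = flag(raw$rule2, "rule2"),
    micro_diff = flag(raw$micro_diff, "micro_diff"),
    micro_count = flag(raw$micro_count, "micro_count"),
    stringsAsFactors = FALSE
  )
  if (!all(rec$material %in% c("PE", "AF", "CSF"))) {
    stop("material must be one of PE, AF, CSF")
  }
  bad_tot <- which(rec$total_cells != rec$wbc + rec$hfbf)
  if (length(bad_tot)) {
    stop("total_cells != wbc + hfbf in sample(s): ",
         paste(rec$sample_id[bad_tot], collapse = ", "))
  }
  has_wbc <- rec$wbc > 0
  recomputed <- round_half_up(100 * rec$hfbf[has_wbc] / rec$wbc[has_wbc], 1)
  bad_pct <- which(abs(recomputed - rec$hfbf_percent[has_wbc]) > 1e-9)
  if (length(bad_pct)) {
    stop("hfbf_percent does not match 100*hfbf/wbc in sample(s): ",
         paste(rec$sample_id[has_wbc][bad_pct], collapse = ", "))
  }
  rec
}

#' Cytology reference standard
#'
#' A record is reference-malignant when its cytology class is at or above
#' class IIIb on the Papanicolaou-style ordinal scale.
#'
#' @param records data.frame from [load_study_table()].
#' @return logical vector.
#' @export
reference_malignant <- function(records) {
  records$cytology_class >= "IIIb"
}

#' Per-method screening prediction
#'
#' @param records data.frame from [load_study_table()].
#' @param method `"xnbf"` (Rule 1 OR Rule 2), `"micro_diff"` (microscopic
#'   WBC differential), or `"micro_count"` (microscopic WBC count).
#' @return logical vector of predicted-malignant flags.
#' @export
method_prediction <- function(records, method) {
  method <- match.arg(method, EVAL_METHODS)
  switch(method,
         xnbf = records$rule1 | records$rule2,
         micro_diff = records$micro_diff,
         micro_count = records$micro_count)
}

#' Diagnostic accuracy of one method against cytology
#'
#' Builds the 2x2 confusion matrix over all records and reports
#' sensitivity = 100 TP/(TP+FN), specificity = 100 TN/(TN+FP),
#' PPV = 100 TP/(TP+FP), NPV = 100 TN/(TN+FN), each rounded half away from
#' zero to one decimal and `NA` when its denominator is zero.
#'
#' @param records data.frame from [load_study_table()].
#' @param method see [method_prediction()].
#' @return a `diagnostic_performance` list: `matrix` (tp, fp, fn, tn) and
#'   the four metrics.
#' @export
evaluate_method <- function(records, method) {
  if (nrow(records) == 0L) stop("no records to evaluate")
  ref <- reference_malignant(records)
  pred <- method_prediction(records, method)
  tp <- sum(ref & pred); fn <- sum(ref & !pred)
  fp <- sum(!ref & pred); tn <- sum(!ref & !pred)
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den, 1)
  }
  structure(
    list(method = method,
         matrix = c(tp = tp, fp = fp, fn = fn, tn = tn),
         sensitivity = pct(tp, tp + fn),
         specificity = pct(tn, tn + fp),
         ppv = pct(tp, tp + fp),
         npv = pct(tn, tn + fn)),
    class = "diagnostic_performance"
  )
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  m <- x$matrix
  cat(sprintf("<diagnostic_performance: %s>\n", x$method))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", m["tp"], m["fp"], m["fn"],
              m["tn"]))
  cat(sprintf("  sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              format(x$sensitivity), format(x$specificity),
              format(x$ppv), format(x$npv)))
  invisible(x)
}

#' Table of all three methods' accuracy
#'
#' @param records data.frame from [load_study_table()].
#' @return data.frame with one row per method and the four metrics.
#' @export
evaluate_all_methods <- function(records) {
  do.call(rbind, lapply(EVAL_METHODS, function(m) {
    p <- evaluate_method(records, m)
    data.frame(method = m,
               tp = p$matrix[["tp"]], fp = p$matrix[["fp"]],
               fn = p$matrix[["fn"]], tn = p$matrix[["tn"]],
               sensitivity = p$sensitivity, specificity = p$specificity,
               ppv = p$ppv, npv = p$npv)
  }))
}

#' Rule 1 / Rule 2 concordance among reference-malignant samples
#'
#' Partitions the cytology-positive records by their (Rule 1, Rule 2) flag
#' pair; the four counts sum to the number of reference-malignant records.
#'
#' @param records data.frame from [load_study_table()].
#' @return named integer vector `c(both, rule1_only, rule2_only, neither)`.
#' @export
concordance_breakdown <- function(records) {
  m <- records[reference_malignant(records), ]
  c(both = sum(m$rule1 & m$rule2),
    rule1_only = sum(m$rule1 & !m$rule2),
    rule2_only = sum(!m$rule1 & m$rule2),
    neither = sum(!m$rule1 & !m$rule2))
}

#' Mann-Whitney U rank-sum test
#'
#' U is computed from midranks (ties shared). `exact` mode enumerates every
#' assignment of the pooled observations to the two groups and reports the
#' two-sided tail probability of deviations of U from its null mean at
#' least as large as observed; this remains exact under ties, which the
#' usual exact algorithms refuse. `approx` mode uses the normal
#' approximation with the tie-corrected variance and a 0.5 continuity
#' correction. `auto` picks exact when n1 + n2 <= 20 and no tied value
#' spans the two groups, else approx.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param mode `"auto"`, `"exact"`, or `"approx"`.
#' @return a `rank_sum_result` list: `u_statistic` (for `x`), `p_value`
#'   (two-sided), `method`, `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty")
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)   # midranks
  u_from_ranksum <- function(rs, n1) rs - n1 * (n1 + 1) / 2
  u_obs <- u_from_ranksum(sum(r[seq_len(n1)]), n1)

  cross_ties <- any(x %in% y)
  if (mode == "auto") {
    mode <- if (N <= 20L && !cross_ties) "exact" else "approx"
  }

  if (mode == "exact") {
    combs <- utils::combn(N, n1)
    rs <- colSums(matrix(r[combs], nrow = n1))
    u_all <- u_from_ranksum(rs, n1)
    mu <- n1 * n2 / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact-enumeration"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(v)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal-approximation-with-tie-correction"
  }
  structure(
    list(u_statistic = u_obs, p_value = p, method = method,
         n1 = n1, n2 = n2),
    class = "rank_sum_result"
  )
}

#' True-positive vs false-negative group summary
#'
#' Splits the reference-malignant records (optionally minus an explicit
#' exclusion list of sample ids — exclusions are never applied silently)
#' into true positives and false negatives under one method, and reports
#' mean and SEM (sample SD / sqrt(n)) of total cell count, WBC, HF-BF# and
#' HF-BF%, with a Mann-Whitney comparison per variable. If one group is
#' empty the other group's summaries are still returned and the tests are
#' `NA`-flagged.
#'
#' @param records data.frame from [load_study_table()].
#' @param method see [method_prediction()].
#' @param exclusions integer vector of `sample_id`s to drop before
#'   splitting.
#' @return a `group_summary` list: per-variable data.frame of group n,
#'   mean, SEM, and rank-sum p, plus the group sizes.
#' @export
group_summary <- function(records, method,
                          exclusions = integer(0)) {
  method <- match.arg(method, EVAL_METHODS)
  m <- records[reference_malignant(records) &
                 !(records$sample_id %in% exclusions), ]
  pred <- method_prediction(m, method)
  vars <- c("total_cells", "wbc", "hfbf", "hfbf_percent")
  tp <- m[pred, vars]; fn <- m[!pred, vars]
  sem <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
  }
  summarise <- function(v) {
    a <- tp[[v]]; b <- fn[[v]]
    p <- if (nrow(tp) > 0 && nrow(fn) > 0) {
      mann_whitney_u(a[!is.na(a)], b[!is.na(b)])$p_value
    } else NA_real_
    data.frame(variable = v,
               tp_mean = if (nrow(tp)) mean(a, na.rm = TRUE) else NA_real_,
               tp_sem = sem(a),
               fn_mean = if (nrow(fn)) mean(b, na.rm = TRUE) else NA_real_,
               fn_sem = sem(b),
               p_value = p)
  }
  structure(
    list(method = method,
         n_tp = nrow(tp), n_fn = nrow(fn),
         excluded = exclusions,
         table = do.call(rbind, lapply(vars, summarise))),
    class = "group_summary"
  )
}
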