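#' Per-subject change from baseline
#'
#' Pairs baseline and follow-up records by subject and computes the change
#' from baseline in IMMAX, in the individual centile (when a distributional
#' model is supplied), and in EYOL and age gap for every supplied reference
#' curve. Centiles are evaluated at each visit's own age; EYOL depends only
#' on the IMMAX value. For every reference the changes obey the exact
#' identity `delta_eyol - delta_age_gap = fpl` (the follow-up period
#' length), which the function enforces algebraically.
#'
#' @param paired Cohort table containing exactly one `baseline` and one
#'   `followup` record per subject (column `visit`), with `immax` present.
#' @param lms_model Optional LMS `centile_model` for individual centiles;
#'   when `NULL` the centile columns are `NA`.
#' @param references Named list of `reference_curve` objects (for example
#'   `list(LQR_P50 = ..., LMS_P50 = ..., HYP = ...)`).
#' @return A `data.frame` (class `delta_table`) with one row per subject:
#'   `subject_id`, `sex`, `age_baseline`, `fpl`, `delta_immax`,
#'   `delta_centile`, and per reference `delta_eyol_<name>` and
#'   `delta_age_gap_<name>`.
#' @export
change_from_baseline <- function(paired, lms_model = NULL,
                                 references = list()) {
  if (!all(c("subject_id", "visit", "immax", "age_years") %in% names(paired)))
    stop("paired cohort needs subject_id, visit, age_years and immax columns",
         call. = FALSE)
  if (anyNA(paired$immax))
    stop("every record needs an IMMAX value (compute it with predict_immax ",
         "before the longitudinal analysis)", call. = FALSE)
  bl <- paired[paired$visit == "baseline", ]
  fu <- paired[paired$visit == "followup", ]
  dup <- c(bl$subject_id[duplicated(bl$subject_id)],
           fu$subject_id[duplicated(fu$subject_id)])
  if (length(dup))
    stop("subjects with duplicated visits: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  unpaired <- c(setdiff(bl$subject_id, fu$subject_id),
                setdiff(fu$subject_id, bl$subject_id))
  if (length(unpaired))
    stop("unpaired subject(s): ", paste(sort(unpaired), collapse = ", "),
         call. = FALSE)
  if (nrow(bl) == 0L) stop("no baseline/followup pairs found", call. = FALSE)
  fu <- fu[match(bl$subject_id, fu$subject_id), ]
  fpl <- fu$age_years - bl$age_years
  out <- data.frame(subject_id = bl$subject_id,
                    sex = if (is.null(bl$sex)) "unknown" else bl$sex,
                    age_baseline = bl$age_years,
                    fpl = fpl,
                    delta_immax = fu$immax - bl$immax,
                    stringsAsFactors = FALSE)
  out$delta_centile <- if (is.null(lms_model)) NA_real_ else
    individual_centile(lms_model, fu$age_years, fu$immax) -
    individual_centile(lms_model, bl$age_years, bl$immax)
  if (length(references)) {
    if (is.null(names(references)) || any(names(references) == ""))
      stop("references must be a named list of reference curves", call. = FALSE)
    for (nm in names(references)) {
      d_ey <- eyol(references[[nm]], fu$immax) - eyol(references[[nm]], bl$immax)
      out[[paste0("delta_eyol_", nm)]] <- d_ey
      out[[paste0("delta_age_gap_", nm)]] <- d_ey - fpl
    }
  }
  class(out) <- c("delta_table", "data.frame")
  out
}

#' Statistical report on longitudinal changes
#'
#' Runs the change-from-baseline comparisons: a Wilcoxon signed-rank test
#' of each delta against zero (exact for 25 or fewer non-zero differences,
#' continuity-corrected normal approximation otherwise; zero differences
#' dropped by the Wilcoxon convention, an all-zero delta is reported as
#' degenerate rather than raising), pairwise paired Wilcoxon comparisons of
#' delta-EYOL across the supplied references with Holm adjustment, Spearman
#' correlations among all delta columns, and, when both sexes have at
#' least `min_group` subjects, independent-sample Wilcoxon comparisons of
#' every delta between the sexes.
#'
#' @param deltas A `delta_table` from [change_from_baseline()].
#' @param adjust Multiplicity adjustment for the cross-reference family
#'   (default `"holm"`; any method of [stats::p.adjust()]).
#' @param min_group Minimum per-sex group size for the sex comparisons.
#' @return A `stats_report`: list with `tests` (comparison, test,
#'   statistic, p_raw, p_adj, note), `adjust_method` and `correlations`
#'   (Spearman matrix of the delta columns).
#' @export
longitudinal_report <- function(deltas, adjust = "holm", min_group = 6L) {
  stopifnot(inherits(deltas, "delta_table"))
  dcols <- grep("^delta_", names(deltas), value = TRUE)
  dcols <- dcols[colSums(!is.na(deltas[dcols])) > 0]
  rows <- list()
  add <- function(comparison, test, statistic, p, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = comparison, test = test,
      statistic = statistic, p_raw = p, p_adj = NA_real_, note = note,
      stringsAsFactors = FALSE)
  }
  for (cn in dcols) {
    x <- deltas[[cn]]
    nz <- x[x != 0]
    if (length(nz) == 0L) {
      add(paste0(cn, " vs 0"), "wilcoxon_signed_rank", NA_real_, NA_real_,
          "degenerate: all differences zero")
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(nz, exact = length(nz) <= 25, correct = TRUE))
      add(paste0(cn, " vs 0"), "wilcoxon_signed_rank",
          unname(wt$statistic), wt$p.value)
    }
  }
  ey <- grep("^delta_eyol_", dcols, value = TRUE)
  if (length(ey) >= 2L) {
    prs <- utils::combn(ey, 2L, simplify = FALSE)
    ps <- vapply(prs, function(pr) {
      d <- deltas[[pr[1]]] - deltas[[pr[2]]]
      nz <- d[d != 0]
      if (!length(nz)) return(NA_real_)
      suppressWarnings(
        stats::wilcox.test(nz, exact = length(nz) <= 25, correct = TRUE))$p.value
    }, 0)
    padj <- stats::p.adjust(ps, method = adjust)
    for (i in seq_along(prs)) {
      add(paste(prs[[i]][1], "vs", prs[[i]][2]), "wilcoxon_paired",
          NA_real_, ps[i])
      rows[[length(rows)]]$p_adj <- padj[i]
    }
  }
  sexes <- table(deltas$sex[deltas$sex %in% c("F", "M")])
  if (length(sexes) == 2L && all(sexes >= min_group)) {
    for (cn in dcols) {
      f <- deltas[[cn]][deltas$sex == "F"]
      m <- deltas[[cn]][deltas$sex == "M"]
      wt <- stats::wilcox.test(f, m, exact = FALSE, correct = TRUE)
      add(paste0(cn, ": F vs M"), "wilcoxon_independent",
          unname(wt$statistic), wt$p.value)
    }
  }
  tests <- do.call(rbind, rows)
  tests$p_adj[is.na(tests$p_adj)] <- tests$p_raw[is.na(tests$p_adj)]
  cors <- spearman_matrix(as.matrix(deltas[dcols]))
  rep <- list(tests = tests, adjust_method = adjust, correlations = cors)
  class(rep) <- "stats_report"
  rep
}

# pairwise Spearman correlations; NA (not an error) for constant columns
spearman_matrix <- function(M) {
  k <- ncol(M)
  out <- matrix(NA_real_, k, k, dimnames = list(colnames(M), colnames(M)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(M[, c(i, j)])
    if (i == j) { out[i, j] <- 1; next }
    if (sum(ok) < 3 || stats::sd(M[ok, i]) == 0 || stats::sd(M[ok, j]) == 0) next
    out[i, j] <- stats::cor(M[ok, i], M[ok, j], method = "spearman")
  }
  out
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Longitudinal change-from-baseline report\n")
  print(x$tests, row.names = FALSE, digits = 4)
  cat("\nSpearman correlations of the changes:\n")
  print(round(x$correlations, 3))
  invisible(x)
}
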