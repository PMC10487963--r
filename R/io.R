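#' Read and validate a cohort table
#'
#' Reads a cohort CSV with the canonical per-subject-visit schema
#' (`subject_id`, `study`, `sex`, `age_years`, the five biomarkers,
#' `immax`, `visit`, optionally `true_centile`), keeps any extra columns
#' with a warning, and validates every row: ages within \[18, 100\] for
#' baseline visits (follow-up visits may run to 105), IMMAX within
#' \[0, 1\] when present, strictly positive ratio biomarkers, CD28neg
#' fraction within \[0, 1\], and visit labels `baseline`/`followup`.
#' Violations are reported with their row and column.
#'
#' @param path Path to a CSV file with a header row; missing values as
#'   empty fields.
#' @return A validated cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  required <- c("subject_id", "age_years", biomarker_columns(), "visit")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("cohort file lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  known <- c("subject_id", "study", "sex", "age_years", biomarker_columns(),
             "immax", "visit", "true_centile")
  extra <- setdiff(names(x), known)
  if (length(extra))
    warning("unknown column(s) preserved as-is: ", paste(extra, collapse = ", "),
            call. = FALSE)
  if (is.null(x$study)) x$study <- "unknown"
  if (is.null(x$sex)) x$sex <- "unknown"
  x$sex[is.na(x$sex) | !(x$sex %in% c("F", "M"))] <- "unknown"
  if (is.null(x$immax)) x$immax <- NA_real_
  validate_cohort(x)
  x
}

validate_cohort <- function(x) {
  problems <- character(0)
  flag <- function(rows, col, msg) {
    if (any(rows, na.rm = TRUE))
      problems <<- c(problems,
                     sprintf("row %d, column %s: %s",
                             which(rows), col, msg))
  }
  flag(!(x$visit %in% c("baseline", "followup")), "visit",
       "must be 'baseline' or 'followup'")
  is_fu <- x$visit == "followup"
  flag(!is.na(x$age_years) & !is_fu & (x$age_years < 18 | x$age_years > 100),
       "age_years", "baseline age outside [18, 100]")
  flag(!is.na(x$age_years) & is_fu & (x$age_years < 18 | x$age_years > 105),
       "age_years", "follow-up age outside [18, 105]")
  flag(is.na(x$age_years), "age_years", "missing")
  flag(!is.na(x$immax) & (x$immax < 0 | x$immax > 1), "immax",
       "outside [0, 1]")
  for (cn in biomarker_columns()[1:4])
    flag(!is.na(x[[cn]]) & x[[cn]] <= 0, cn, "ratio must be strictly positive")
  flag(!is.na(x$cd28neg_cd8_freq) &
         (x$cd28neg_cd8_freq < 0 | x$cd28neg_cd8_freq > 1),
       "cd28neg_cd8_freq", "outside [0, 1]")
  if (length(problems))
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(x)
}

#' Write a cohort table to CSV
#'
#' @param x Cohort `data.frame`.
#' @param path Output path; missing values become empty fields.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

schema_version <- 1L

#' Serialize a fitted model or reference curve to JSON
#'
#' Centile models (all three algorithms), reference curves, IMMAX PCR
#' models and generator parameter sets round-trip through a JSON schema:
#' [load_model()] restores an object whose predictions agree with the
#' original. A version field guards against reading files written by an
#' incompatible schema.
#'
#' @param x A `centile_model`, `reference_curve`, `immax_pcr` or
#'   `generator_params` object.
#' @param path Output path.
#' @export
save_model <- function(x, path) {
  cls <- intersect(class(x), c("centile_model", "reference_curve",
                               "immax_pcr", "generator_params"))
  if (!length(cls))
    stop("don't know how to serialize an object of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  payload <- unclass(x)
  payload$diagnostics <- NULL
  obj <- list(schema_version = schema_version, class = cls[1],
              payload = payload)
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Restore a serialized model
#'
#' @param path Path written by [save_model()].
#' @return The restored object, with its class reattached.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::fromJSON(readLines(path, warn = FALSE),
                                     simplifyMatrix = TRUE),
                  error = function(e) stop("cannot parse model file ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(obj$schema_version) || obj$schema_version != schema_version)
    stop("model file schema version ", obj$schema_version,
         " is not supported by this reader (expected ", schema_version, ")",
         call. = FALSE)
  x <- obj$payload
  x <- restore_numeric_shapes(x, obj$class)
  class(x) <- obj$class
  x
}

# fromJSON leaves column-major matrices as matrices; re-coerce the few
# fields whose exact type matters downstream
restore_numeric_shapes <- function(x, cls) {
  if (cls == "centile_model") {
    for (f in c("coef", "theta", "par_grid"))
      if (!is.null(x[[f]])) x[[f]] <- as.matrix(x[[f]])
  }
  if (cls == "generator_params") {
    x$age_components <- as.matrix(x$age_components)
    x$biomarker_loadings <- unlist(x$biomarker_loadings)
    x$biomarker_noise_sd <- unlist(x$biomarker_noise_sd)
    x$seed <- as.integer(x$seed)
  }
  if (cls == "immax_pcr") {
    x$loadings <- as.matrix(x$loadings)
    x$center <- unlist(x$center)
    x$scale <- unlist(x$scale)
  }
  x
}

#' Export percentile curves as a tidy chart table
#'
#' Writes the fitted percentile curves on an age grid as a long CSV with
#' columns `age`, `tau`, `quantile` — the interface for external plotting.
#' For NQR models the grid is restricted to the fitted age range.
#'
#' @param model A `centile_model`.
#' @param path Output CSV path.
#' @param ages Age grid (default 18 to 100 by 0.5 years).
#' @return The exported `data.frame`, invisibly.
#' @export
export_centile_chart <- function(model, path,
                                 ages = seq(18, 100, by = 0.5)) {
  if (model$algorithm == "NQR")
    ages <- ages[ages >= model$age_range[1] & ages <= model$age_range[2]]
  Q <- predict_quantiles(model, ages)
  out <- data.frame(age = rep(ages, times = length(model$taus)),
                    tau = rep(model$taus, each = length(ages)),
                    quantile = as.vector(Q))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
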