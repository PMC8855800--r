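#' Body surface area
#'
#' Mosteller formula by default: \code{sqrt(height_cm x weight_kg / 3600)}.
#' Du Bois (\code{0.007184 x height^0.725 x weight^0.425}) is selectable.
#' BSA is carried as a covariate in the automated-vs-manual error model and
#' in exported phenotype tables.
#'
#' @param height height in cm, > 0 (vectorized).
#' @param weight weight in kg, > 0 (vectorized).
#' @param method "mosteller" (default) or "dubois".
#' @return BSA in m^2.
#' @export
#' @examples
#' bsa(180, 80)   # 2.0
bsa <- function(height, weight, method = c("mosteller", "dubois")) {
  method <- match.arg(method)
  if (any(!is.finite(height)) || any(!is.finite(weight)) ||
      any(height <= 0) || any(weight <= 0))
    stop("height and weight must be positive")
  switch(method,
         mosteller = sqrt(height * weight / 3600),
         dubois = 0.007184 * height^0.725 * weight^0.425)
}

#' Z-score outlier flags
#'
#' Standard-measure quality control: z = (v - mean) / SD with the sample
#' (n - 1) SD; a value is excluded iff |z| > k. When the SD is zero all
#' z-scores are 0 and nothing is excluded. The default multiplier is k = 3;
#' a stricter k = 2.5 preset is available via \code{k = 2.5}.
#'
#' @param values numeric vector (>= 2 values) of one measure across subjects.
#' @param k SD multiplier (default 3).
#' @return data.frame with columns \code{zscore} and \code{excluded}.
#' @export
zscoreFlags <- function(values, k = 3) {
  if (length(values) < 2L) stop("need at least 2 values for z-scores")
  s <- sd(values)
  z <- if (s == 0) rep(0, length(values)) else (values - mean(values)) / s
  data.frame(zscore = z, excluded = abs(z) > k)
}

#' Automated-versus-manual error model
#'
#' Summarizes automated minus manual differences and regresses the
#' percentage difference, (auto - manual) / manual, on supplied covariates
#' (e.g. age, BSA, sex, imaging-plane deviation, cardiac phase) by ordinary
#' least squares with an intercept, to detect systematic measurement error.
#'
#' @param auto,manual paired measurements in mm; \code{manual} must be > 0.
#' @param covariates optional data.frame of per-pair predictors.
#' @return list of class \code{errorModelReport}: \code{n_pairs},
#'   \code{mean_diff_mm}, \code{mean_pct_diff} (fraction), and
#'   \code{coefficients} (slope, SE, p per predictor; absent without
#'   covariates; rank-deficient designs are flagged with
#'   \code{rank_deficient = TRUE} and coefficients withheld).
#' @export
compareToManual <- function(auto, manual, covariates = NULL) {
  if (length(auto) != length(manual)) stop("auto and manual must be paired")
  if (length(auto) < 2L) stop("need at least 2 pairs")
  if (any(manual <= 0)) stop("manual values must be positive")
  pct <- (auto - manual) / manual
  out <- list(n_pairs = length(auto),
              mean_diff_mm = mean(auto - manual),
              mean_pct_diff = mean(pct),
              rank_deficient = FALSE,
              coefficients = NULL)
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), nrow(covariates) == length(auto))
    if (length(auto) < ncol(covariates) + 2L)
      stop("need at least (number of predictors + 2) pairs for regression")
    dat <- cbind(pct_diff = pct, covariates)
    fit <- lm(pct_diff ~ ., data = dat)
    if (anyNA(coef(fit))) {
      out$rank_deficient <- TRUE
    } else {
      sm <- summary(fit)$coefficients
      out$coefficients <- data.frame(
        term = rownames(sm), slope = sm[, 1], se = sm[, 2],
        p_value = sm[, 4], row.names = NULL)
    }
  }
  class(out) <- "errorModelReport"
  out
}

#' @export
print.errorModelReport <- function(x, ...) {
  cat(sprintf("Automated vs manual: n = %d pairs\n", x$n_pairs))
  cat(sprintf("  mean difference: %.3f mm, mean %% difference: %.2f%%\n",
              x$mean_diff_mm, 100 * x$mean_pct_diff))
  if (x$rank_deficient) cat("  regression design rank-deficient; coefficients withheld\n")
  if (!is.null(x$coefficients)) {
    cat("  percentage-difference regression:\n")
    print(x$coefficients, digits = 3)
  }
  invisible(x)
}

#' Export a QC'd phenotype table
#'
#' Tab-delimited table of per-subject phenotypes (systolic and diastolic
#' mitral annular diameter, plus any tricuspid/septal analogues present) and
#' covariates (sex, age, BSA), for downstream association tooling. Excluded
#' subjects are omitted. Subjects missing height or weight get an empty BSA
#' field, not zero. Column order is fixed: subject_id, the phenotype columns
#' in input order, sex, age, bsa.
#'
#' @param records data.frame with \code{subject_id}, phenotype columns ending
#'   in \code{_mm}, optional \code{sex}, \code{age}, \code{height},
#'   \code{weight} or precomputed \code{bsa}, and optional logical
#'   \code{excluded}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
exportPhenotypes <- function(records, path) {
  stopifnot(is.data.frame(records), "subject_id" %in% names(records))
  if ("excluded" %in% names(records))
    records <- records[!records$excluded %in% TRUE, , drop = FALSE]
  if (nrow(records) == 0L) stop("no non-excluded records to export")
  if (!"bsa" %in% names(records)) {
    records$bsa <- NA_real_
    if (all(c("height", "weight") %in% names(records))) {
      ok <- is.finite(records$height) & is.finite(records$weight) &
            records$height > 0 & records$weight > 0
      records$bsa[ok] <- bsa(records$height[ok], records$weight[ok])
    }
  }
  pheno <- grep("_mm$", names(records), value = TRUE)
  cols <- c("subject_id", pheno,
            intersect(c("sex", "age"), names(records)), "bsa")
  out <- records[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) ifelse(is.na(v), "",
                                                  sprintf("%.12g", v)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
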