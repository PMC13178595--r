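#' Threshold-based fluorophore detection
#'
#' A fluorophore counts as detected when its relative fraction exceeds the
#' threshold. The default 0.01 treats percent-level fractions as meaningful
#' while a zero amplitude is a non-detection; thresholds at or above 0.5
#' are rejected because they would make multi-fluorophore detection
#' impossible.
#'
#' @param fractions Named numeric vector of relative fractions (sum 1).
#' @param threshold Detection threshold in `(0, 0.5)`; default 0.01.
#' @return Named logical vector of detected flags.
#' @export
detect <- function(fractions, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 0.5)
    stop("threshold must be in (0, 0.5)")
  if (abs(sum(fractions) - 1) > 1e-5)
    stop("fractions must sum to 1 (got ", sum(fractions), ")")
  fractions > threshold
}

#' Classify detection outcomes against ground truth
#'
#' Per (sample, fluorophore) pair: TP when present and detected, FP when
#' absent and detected, TN when absent and not detected, FN when present
#' and not detected.
#'
#' @param truth_present Logical vector (or matrix), truth presence flags.
#' @param detected Logical of the same shape, detection calls.
#' @return data.frame with columns `truth_present`, `detected`, `class`.
#' @export
classify_detections <- function(truth_present, detected) {
  if (length(truth_present) != length(detected))
    stop("truth and detection vectors must have the same length")
  truth_present <- as.logical(truth_present)
  detected <- as.logical(detected)
  cls <- ifelse(truth_present & detected, "TP",
         ifelse(!truth_present & detected, "FP",
         ifelse(!truth_present & !detected, "TN", "FN")))
  data.frame(truth_present = truth_present, detected = detected,
             class = cls, stringsAsFactors = FALSE)
}

#' Tally confusion counts
#'
#' @param outcomes data.frame from [classify_detections()] (rows may be
#'   concatenated over samples); an empty data.frame yields all zeros.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(outcomes) {
  counts <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  if (NROW(outcomes) > 0) {
    tab <- table(factor(outcomes$class, levels = names(counts)))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Detection sensitivity and specificity
#'
#' Sensitivity = 100 * TP / (TP + FN); specificity = 100 * TN / (TN + FP),
#' in percent at full precision. A zero denominator makes the metric
#' undefined and is reported as `NA` (not 0).
#'
#' @param counts Named vector with TP, FP, TN, FN.
#' @return List with `sensitivity` and `specificity` (percent or NA).
#' @export
sensitivity_specificity <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  list(
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}

#' Mean absolute error of recovered fractions
#'
#' MAE = (1/N) * sum |c_measured - c_truth| over all (sample, fluorophore)
#' pairs; for the seven-phantom, three-fluorophore suite N = 21.
#'
#' @param measured Numeric vector or matrix of recovered fractions.
#' @param truth Same shape, generator/theoretical fractions.
#' @return MAE in `[0, 1]`.
#' @export
mean_absolute_error <- function(measured, truth) {
  if (length(measured) != length(truth))
    stop("measured and truth must have the same number of entries")
  mean(abs(as.numeric(measured) - as.numeric(truth)))
}

#' Optical redox ratio
#'
#' c_FAD / (c_FAD + c_NADH) from relative fluorescence fractions; values
#' toward 1 indicate an oxidized metabolic state, toward 0 a reduced one.
#' Undefined (NA) when both fractions are zero.
#'
#' @param fractions Named numeric vector containing the FAD and NADH
#'   entries.
#' @param fad,nadh Component names (defaults `"FAD"`, `"NADH"`).
#' @return Ratio in `[0, 1]`, or NA.
#' @export
redox_ratio <- function(fractions, fad = "FAD", nadh = "NADH") {
  if (!all(c(fad, nadh) %in% names(fractions)))
    stop("fractions must contain entries named '", fad, "' and '", nadh, "'")
  cf <- fractions[[fad]]; cn <- fractions[[nadh]]
  if (cf + cn <= 0) return(NA_real_)
  cf / (cf + cn)
}

#' Per-phase linear trends of a monitoring timecourse
#'
#' Ordinary least-squares line (value ~ time) per phase for each tracked
#' quantity (fluorophore fractions and the redox ratio). Phases with fewer
#' than 2 points yield intercept-only records (slope NA).
#'
#' @param timecourse data.frame with a `time_min` column and one numeric
#'   column per tracked quantity.
#' @param phases data.frame with columns `phase`, `start`, `end`
#'   (minutes); windows must not overlap.
#' @return data.frame with columns `phase`, `quantity`, `slope`
#'   (per minute), `intercept` (value at phase start), `n`.
#' @export
phase_trends <- function(timecourse, phases) {
  stopifnot(is.data.frame(timecourse), "time_min" %in% names(timecourse))
  ord <- order(phases$start)
  ph <- phases[ord, , drop = FALSE]
  if (nrow(ph) > 1 && any(ph$start[-1] < ph$end[-nrow(ph)]))
    stop("phase windows overlap")
  quantities <- setdiff(names(timecourse), c("time_min", "phase"))
  out <- list()
  for (i in seq_len(nrow(ph))) {
    inside <- timecourse$time_min >= ph$start[i] &
      timecourse$time_min <= ph$end[i]
    sub <- timecourse[inside, , drop = FALSE]
    for (q in quantities) {
      y <- sub[[q]]
      ok <- is.finite(y)
      if (sum(ok) >= 2 && stats::var(sub$time_min[ok]) > 0) {
        fit <- stats::lm(y[ok] ~ I(sub$time_min[ok] - ph$start[i]))
        slope <- unname(stats::coef(fit)[2])
        intercept <- unname(stats::coef(fit)[1])
      } else {
        slope <- NA_real_
        intercept <- if (any(ok)) mean(y[ok]) else NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        phase = ph$phase[i], quantity = q, slope = slope,
        intercept = intercept, n = sum(ok), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Evaluate a correction method over a phantom suite
#'
#' Fits every suite entry at one excitation tag with the requested method,
#' applies threshold detection, and summarizes sensitivity, specificity
#' (percent) and MAE against the generator truth.
#'
#' @param suite Output of [generate_phantom_suite()].
#' @param library Basis library (default the phantom library on the suite
#'   grid).
#' @param method One of `"new"` (adaptive alpha), `"kim"` (alpha = 1),
#'   `"valdes"` (shared calibrated alpha), `"none"` (alpha = 0, no
#'   correction).
#' @param excitation_nm Excitation tag to evaluate (375 or 405).
#' @param threshold Detection threshold (default 0.01).
#' @param valdes_alpha Calibrated alpha for `method = "valdes"`; when NULL
#'   it is calibrated on the suite itself.
#' @param options [fit_options()].
#' @return List with `counts`, `sensitivity`, `specificity`, `mae`,
#'   `n_pairs`, per-phantom `fractions` and `truth` matrices, and the
#'   alpha used per phantom.
#' @export
evaluate_suite <- function(suite, library = NULL, method = "new",
                           excitation_nm = 375, threshold = 0.01,
                           valdes_alpha = NULL, options = fit_options()) {
  method <- match.arg(method, c("new", "kim", "valdes", "none"))
  entries <- Filter(function(e) e$excitation_nm == excitation_nm, suite)
  if (!length(entries)) stop("suite has no entries at ", excitation_nm, " nm")
  if (is.null(library))
    library <- phantom_basis_library(entries[[1]]$fm$wavelength)
  if (method == "valdes" && is.null(valdes_alpha)) {
    cal <- calibrate_valdes_alpha(
      lapply(entries, function(e) list(fm = e$fm, r = e$r)),
      excitation_nm, library, options)
    valdes_alpha <- cal$alpha
  }
  nms <- component_names(library)
  meas <- truth <- matrix(NA_real_, nrow = length(entries),
                          ncol = length(nms),
                          dimnames = list(NULL, nms))
  alphas <- numeric(length(entries))
  outcomes <- list()
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    res <- switch(method,
      new = fit_adaptive(e$fm, e$r, library, options),
      kim = fit_fixed_alpha(e$fm, e$r, 1, library, options),
      valdes = fit_fixed_alpha(e$fm, e$r, valdes_alpha, library, options),
      none = fit_fixed_alpha(e$fm, e$r, 0, library, options))
    meas[i, ] <- res$fractions[nms]
    tr <- stats::setNames(rep(0, length(nms)), nms)
    tr[names(e$truth$fractions)] <- e$truth$fractions
    truth[i, ] <- tr
    alphas[i] <- res$alpha
    outcomes[[i]] <- classify_detections(tr > 0,
                                         detect(res$fractions[nms], threshold))
  }
  counts <- confusion_counts(do.call(rbind, outcomes))
  ss <- sensitivity_specificity(counts)
  list(method = method, excitation_nm = excitation_nm,
       counts = counts,
       sensitivity = ss$sensitivity, specificity = ss$specificity,
       mae = mean_absolute_error(meas, truth),
       n_pairs = length(meas),
       fractions = meas, truth = truth, alpha = alphas,
       valdes_alpha = valdes_alpha)
}
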