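#' Min-max normalization of an index series
#'
#' Subtracts the series minimum, then divides by the new maximum, so the
#' result spans exactly `[0, 1]` for non-constant input.  A constant
#' series maps to all zeros and is flagged through the `"constant"`
#' attribute.  The transformation is idempotent.
#'
#' @param x numeric series, length >= 2.
#' @return Numeric series in `[0, 1]`, attribute `constant`.
#' @export
min_max_normalize <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  if (any(!is.finite(x))) stop("series has non-finite values", call. = FALSE)
  rng <- max(x) - min(x)
  if (rng == 0) return(structure(rep(0, length(x)), constant = TRUE))
  structure((x - min(x)) / rng, constant = FALSE)
}

#' Threshold detection on a normalized index series
#'
#' Chorus is flagged where the normalized value crosses 0.5 in the
#' direction the index responds to chorusing: strictly above 0.5 for C,
#' ACI, ADI and BI, strictly below 0.5 for H (chorusing lowers
#' entropy).  A value exactly at 0.5 is never a detection under either
#' polarity.
#'
#' @param norm normalized series in `[0, 1]`.
#' @param index_name one of `"C"`, `"ACI"`, `"ADI"`, `"BI"`, `"H"`,
#'   or explicitly `polarity`.
#' @param polarity `"high"` (detect above threshold) or `"low"`;
#'   derived from `index_name` when missing.
#' @param threshold detection threshold (default 0.5).
#' @return Integer vector of 0/1 detections.
#' @export
detect_chorus <- function(norm, index_name = NULL, polarity = NULL,
                          threshold = 0.5) {
  if (is.null(polarity)) {
    if (is.null(index_name))
      stop("give `index_name` or `polarity`", call. = FALSE)
    polarity <- if (toupper(index_name) == "H") "low" else "high"
  }
  polarity <- match.arg(polarity, c("high", "low"))
  v <- as.numeric(norm)
  as.integer(if (polarity == "high") v > threshold else v < threshold)
}

#' Confusion matrix and accuracy of binary chorus detections
#'
#' Tabulates detections against annotated truth into true/false
#' positives and negatives, with
#' `accuracy = (TP + TN) / (TP + FP + TN + FN)` and
#' `error rate = (FN + FP) / (TP + FP + TN + FN)`.
#'
#' @param truth 0/1 vector, chorus present.
#' @param detected 0/1 vector of the same length.
#' @return Object of class `"detection_table"`: counts `TP`, `FP`,
#'   `TN`, `FN`, plus `accuracy` and `error_rate`.
#' @export
confusion_matrix <- function(truth, detected) {
  truth <- as.integer(truth); detected <- as.integer(detected)
  if (length(truth) != length(detected))
    stop("`truth` and `detected` lengths differ", call. = FALSE)
  if (!all(truth %in% 0:1) || !all(detected %in% 0:1))
    stop("`truth` and `detected` must be binary 0/1", call. = FALSE)
  tp <- sum(truth == 1 & detected == 1)
  fp <- sum(truth == 0 & detected == 1)
  tn <- sum(truth == 0 & detected == 0)
  fn <- sum(truth == 1 & detected == 0)
  n <- tp + fp + tn + fn
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn, n = n,
                 accuracy = (tp + tn) / n,
                 error_rate = (fn + fp) / n),
            class = "detection_table")
}

#' @export
print.detection_table <- function(x, ...) {
  cat(sprintf("detections: TP %d  FP %d  TN %d  FN %d | accuracy %.3f, error rate %.3f\n",
              x$TP, x$FP, x$TN, x$FN, x$accuracy, x$error_rate))
  invisible(x)
}

#' Mask an SPL series to the chorusing hours
#'
#' Keeps the SPL value in the fish-chorusing hours and replaces it with
#' zero elsewhere, so the masked series is a cleaner proxy of chorus
#' energy when noise leaks into the chorus band.  Default chorus hours
#' are 00:00-05:00 and 18:00-23:00.
#'
#' @param spl numeric SPL series.
#' @param clock integer clock hour (0-23) per value.
#' @param chorus_hours integer vector of chorusing hours
#'   (default `c(0:5, 18:23)`).
#' @return Numeric series: `spl` in chorus hours, 0 elsewhere.
#' @export
chorus_masked_spl <- function(spl, clock, chorus_hours = c(0:5, 18:23)) {
  if (length(spl) != length(clock))
    stop("`spl` and `clock` lengths differ", call. = FALSE)
  clock <- as.integer(clock)
  if (any(is.na(clock)) || any(clock < 0 | clock > 23))
    stop("`clock` must hold hours 0-23", call. = FALSE)
  ifelse(clock %in% as.integer(chorus_hours), spl, 0)
}

#' Diel grouping of clock hours
#'
#' The three analysis periods used for grouped correlations: Dawn
#' (00:00-05:00), Dusk (18:00-23:00) and Midday (06:00-17:00).
#'
#' @param clock integer clock hours (0-23).
#' @return Factor with levels `Dawn`, `Midday`, `Dusk`.
#' @export
time_of_day_group <- function(clock) {
  clock <- as.integer(clock)
  g <- ifelse(clock <= 5, "Dawn", ifelse(clock >= 18, "Dusk", "Midday"))
  factor(g, levels = c("Dawn", "Midday", "Dusk"))
}

#' Pearson correlation between an index and band SPL, by diel group
#'
#' Computes the Pearson coefficient and its standard two-sided p-value
#' per group and over all windows.  Groups with fewer than 3 windows or
#' with zero variance in either series yield `NA` with a note.
#'
#' @param index_series numeric index values.
#' @param spl_series paired SPL values (same length).
#' @param groups factor/vector of group labels per window; `NULL` for an
#'   overall correlation only.
#' @param index_name,band labels carried into the report.
#' @return Data frame: `index`, `group`, `r`, `p`, `n`, `note`.
#' @export
pearson_by_group <- function(index_series, spl_series, groups = NULL,
                             index_name = "index", band = NULL) {
  if (length(index_series) != length(spl_series))
    stop("series lengths differ", call. = FALSE)
  one <- function(ix, sp, label) {
    note <- ""
    if (length(ix) < 3L) {
      r <- p <- NA_real_; note <- "fewer than 3 windows"
    } else if (stats::sd(ix) == 0 || stats::sd(sp) == 0) {
      r <- p <- NA_real_; note <- "zero variance"
    } else {
      ct <- stats::cor.test(ix, sp, method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(index = index_name,
               band = if (is.null(band)) NA_character_ else
                 sprintf("%g-%g Hz", band[1], band[2]),
               group = label, r = r, p = p, n = length(ix), note = note,
               stringsAsFactors = FALSE)
  }
  out <- one(index_series, spl_series, "all")
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    for (g in levels(groups)) {
      sel <- groups == g
      out <- rbind(out, one(index_series[sel], spl_series[sel], g))
    }
  }
  rownames(out) <- NULL
  out
}
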