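#' Analyze one recording window
#'
#' Computes the full measure set for a single audio window (one "hour"
#' of a deployment): permutation entropy H and statistical complexity C
#' (Bandt-Pompe, defaults d = 6, tau = 1), the three acoustic indices
#' ACI, ADI and BI, and the calibrated band SPLs for the vessel-noise
#' band (50-200 Hz) and the chorus band (500-2500 Hz).
#'
#' @param audio a [calibrated_audio()].
#' @param d,tau ordinal embedding parameters.
#' @param aci_cluster_s ACI cluster length, s; defaults to the full
#'   window so compressed synthetic hours form one cluster.
#' @param spl_bands list of two bands, low then high.
#' @param nfft_indices,nfft_spl FFT sizes for the indices and the Welch
#'   SPL spectrogram.
#' @return One-row data frame: `H`, `C`, `ACI`, `ADI`, `BI`,
#'   `spl_50_200`, `spl_500_2500` (column names follow the bands).
#' @export
analyze_audio <- function(audio, d = 6L, tau = 1L,
                          aci_cluster_s = NULL,
                          spl_bands = list(c(50, 200), c(500, 2500)),
                          nfft_indices = 2048L, nfft_spl = 1024L) {
  stopifnot(inherits(audio, "calibrated_audio"))
  dur <- length(audio$samples) / audio$rate
  if (is.null(aci_cluster_s)) aci_cluster_s <- dur
  chp <- global_complexity(audio$samples, d = d, tau = tau)
  top <- min(3500, audio$rate / 2 * 0.999)
  v_aci <- aci(audio, f_hi = top, nfft = nfft_indices,
               cluster_s = aci_cluster_s)$value
  v_adi <- adi(audio, max_freq = top, nfft = nfft_indices)$value
  v_bi <- bi(audio, f_hi = top, nfft = nfft_indices)$value
  spec <- welch_spectrogram(audio, nfft = nfft_spl, seg_seconds = 1,
                            avg_seconds = dur)
  spl <- vapply(spl_bands, function(b)
    10 * log10(mean(10^(band_spl(spec, b) / 10))), numeric(1))
  out <- data.frame(H = chp$H, C = chp$C, ACI = v_aci, ADI = v_adi,
                    BI = v_bi)
  for (i in seq_along(spl_bands))
    out[[sprintf("spl_%g_%g", spl_bands[[i]][1], spl_bands[[i]][2])]] <- spl[i]
  out
}

#' Analyze every hour of a rendered scene
#'
#' Slices the scene into its clock hours and runs [analyze_audio()] on
#' each, yielding the per-hour measure table the detector operates on.
#'
#' @param scene a [render_scene()] result.
#' @param ... passed to [analyze_audio()].
#' @return Data frame with `hour` plus the [analyze_audio()] columns.
#' @export
analyze_scene <- function(scene, ...) {
  stopifnot(inherits(scene, "scene"))
  cfg <- scene$config
  nh <- round(cfg$seconds_per_hour * cfg$rate)
  rows <- lapply(seq_len(cfg$hours), function(h) {
    seg <- scene$audio$samples[((h - 1) * nh + 1):(h * nh)]
    a <- calibrated_audio(seg, cfg$rate, cfg$sensitivity_db)
    cbind(hour = h - 1L, analyze_audio(a, ...))
  })
  do.call(rbind, rows)
}

#' Analyze WAV files into a tidy long-format table
#'
#' Runs [analyze_audio()] on each file and appends tidy rows
#' `(window_id, measure, value)` to `out_csv`.  Files whose `window_id`
#' (the base file name) is already present in `out_csv` are skipped, so
#' an interrupted run can be resumed.  Unreadable files are logged to
#' stderr and skipped.
#'
#' @param paths WAV file paths.
#' @param out_csv output CSV path (appended to if it exists).
#' @param sensitivity_db end-to-end calibration applied to each file.
#' @param ... passed to [analyze_audio()].
#' @return Data frame of all rows in `out_csv` after the run,
#'   invisibly.  An attribute `failed` lists files that could not be
#'   read.
#' @export
analyze_files <- function(paths, out_csv, sensitivity_db = -164.5, ...) {
  if (!length(paths)) stop("no input files", call. = FALSE)
  done <- character(0)
  if (file.exists(out_csv))
    done <- unique(utils::read.csv(out_csv)$window_id)
  failed <- character(0)
  for (p in paths) {
    id <- sub("\\.wav$", "", basename(p), ignore.case = TRUE)
    if (id %in% done) next
    t0 <- proc.time()[3]
    res <- tryCatch({
      wv <- read_wav(p)
      analyze_audio(calibrated_audio(wv$samples, wv$rate, sensitivity_db), ...)
    }, error = function(e) {
      message(sprintf("SKIP %s: %s", p, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { failed <- c(failed, p); next }
    long <- data.frame(window_id = id,
                       measure = names(res),
                       value = as.numeric(res[1, ]))
    utils::write.table(long, out_csv, sep = ",", row.names = FALSE,
                       col.names = !file.exists(out_csv), append = file.exists(out_csv))
    message(sprintf("analyzed %s (%.1f s)", id, proc.time()[3] - t0))
  }
  out <- utils::read.csv(out_csv)
  attr(out, "failed") <- failed
  invisible(out)
}

#' Detect and evaluate choruses over a deployment
#'
#' The full evaluation scheme on an hourly measure table: each index
#' series is min-max normalized over the deployment, thresholded at 0.5
#' with the polarity the index responds with (above for C/ACI/ADI/BI,
#' below for H), and scored against the ground truth as a confusion
#' matrix.  A combined plane-based C-H detector flags an hour whose
#' point has moved from the noise cluster in either coordinate (C above
#' *or* H below threshold); it is reported alongside the five
#' single-index detectors.  Pearson
#' correlations are computed between each normalized index and (i) the
#' normalized chorus-band SPL masked to the chorusing hours (zero
#' elsewhere) and (ii) the normalized low-frequency noise-band SPL,
#' overall and per diel group.  Finally, every (H, C) point is checked
#' against the C-H plane boundary curves.
#'
#' @param results data frame from [analyze_scene()] (or several
#'   `rbind`-ed together): columns `hour`, `H`, `C`, `ACI`, `ADI`, `BI`,
#'   `spl_50_200`, `spl_500_2500`, and optionally `window_id`.
#' @param truth data frame with matching rows: column `chorus` (0/1)
#'   plus `hour`; `window_id` is compared when present in both.
#' @param chorus_hours clock hours treated as chorusing time for the
#'   SPL mask (default `c(0:5, 18:23)`).
#' @param d embedding dimension for the plane containment check.
#' @param containment_tol tolerance added around the boundary curves.
#' @return Object of class `"chorus_evaluation"`: list with
#'   `detections` (per-index 0/1 matrix), `confusion` (named list of
#'   [confusion_matrix()] tables for H, C, ACI, ADI, BI and CH),
#'   `correlations` (data frame), `plane` (containment summary) and
#'   `normalized` (the normalized series).
#' @export
evaluate_run <- function(results, truth, chorus_hours = c(0:5, 18:23),
                         d = 6L, containment_tol = 1e-3) {
  need <- c("hour", "H", "C", "ACI", "ADI", "BI")
  miss <- setdiff(need, names(results))
  if (length(miss))
    stop("`results` lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(results) != nrow(truth))
    stop("`results` and `truth` have different numbers of windows",
         call. = FALSE)
  if ("window_id" %in% names(results) && "window_id" %in% names(truth) &&
      !all(results$window_id == truth$window_id)) {
    bad <- which(results$window_id != truth$window_id)
    stop("window_id mismatch at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  idx_names <- c("H", "C", "ACI", "ADI", "BI")
  norm <- lapply(results[idx_names], min_max_normalize)
  det <- vapply(idx_names, function(nm)
    detect_chorus(norm[[nm]], nm), integer(nrow(results)))
  det <- cbind(det, CH = as.integer(det[, "C"] == 1L | det[, "H"] == 1L))
  confusion <- lapply(colnames(det), function(nm)
    confusion_matrix(truth$chorus, det[, nm]))
  names(confusion) <- colnames(det)

  clock <- results$hour %% 24L
  groups <- time_of_day_group(clock)
  spl_hi_col <- grep("^spl_5", names(results), value = TRUE)
  cors <- NULL
  if (all(c("spl_50_200", "spl_500_2500") %in% names(results))) {
    spl_chorus <- chorus_masked_spl(min_max_normalize(results$spl_500_2500),
                                    clock, chorus_hours)
    spl_noise <- min_max_normalize(results$spl_50_200)
    for (nm in idx_names) {
      cors <- rbind(cors,
        pearson_by_group(norm[[nm]], spl_chorus, groups, nm, c(500, 2500)),
        pearson_by_group(norm[[nm]], spl_noise, groups, nm, c(50, 200)))
    }
  }

  pr <- limit_curves(d, n_grid = 1000L)
  cmin <- boundary_complexity(pr, results$H, "min")
  cmax <- boundary_complexity(pr, results$H, "max")
  contained <- results$C >= cmin - containment_tol &
    results$C <= cmax + containment_tol
  structure(list(
    detections = det,
    confusion = confusion,
    correlations = cors,
    plane = list(d = d, n = length(contained),
                 n_contained = sum(contained),
                 all_contained = all(contained)),
    normalized = as.data.frame(norm)),
    class = "chorus_evaluation")
}

#' @export
print.chorus_evaluation <- function(x, ...) {
  cat("chorus_evaluation\n")
  for (nm in names(x$confusion)) {
    cm <- x$confusion[[nm]]
    cat(sprintf("  %-3s accuracy %.3f (TP %d FP %d TN %d FN %d)\n",
                nm, cm$accuracy, cm$TP, cm$FP, cm$TN, cm$FN))
  }
  if (!is.null(x$correlations)) {
    ov <- x$correlations[x$correlations$group == "all", ]
    hi <- ov[ov$band == "500-2500 Hz", ]
    cat("  r vs masked chorus-band SPL:",
        paste(sprintf("%s %.2f", hi$index, hi$r), collapse = ", "), "\n")
  }
  cat(sprintf("  C-H plane containment: %d/%d inside\n",
              x$plane$n_contained, x$plane$n))
  invisible(x)
}

#' Export an evaluation report
#'
#' Writes the confusion matrices and plane summary as JSON and the
#' correlation table as CSV.
#'
#' @param eval_out a [evaluate_run()] result.
#' @param dir output directory.
#' @return Named vector of files written, invisibly.
#' @export
write_evaluation <- function(eval_out, dir) {
  stopifnot(inherits(eval_out, "chorus_evaluation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- file.path(dir, "evaluation.json")
  jsonlite::write_json(list(
    confusion = lapply(eval_out$confusion, unclass),
    plane = eval_out$plane), js, auto_unbox = TRUE, digits = NA)
  files <- c(report = js)
  if (!is.null(eval_out$correlations)) {
    cc <- file.path(dir, "correlations.csv")
    utils::write.csv(eval_out$correlations, cc, row.names = FALSE)
    files <- c(files, correlations = cc)
  }
  invisible(files)
}
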