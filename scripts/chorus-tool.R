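#!/usr/bin/env Rscript
# Command-line front end over the chorusentropy package:
#
#   simulate  --preset a|b|c|d --seed N --out DIR    render a labeled scene
#   analyze   --wav 'GLOB' --out results.csv         per-file measures (tidy CSV)
#   detect    --results results.csv --out det.csv    normalized detections
#   evaluate  --results results.csv --truth truth.csv --out DIR
#   plane     --d 6 --out curves.csv                 C-H limit curves export
#
# Example:
#   Rscript scripts/chorus-tool.R simulate --preset a --seed 1 --out scenes/

suppressPackageStartupMessages({
  library(optparse)
  library(chorusentropy)
})

argv <- commandArgs(trailingOnly = TRUE)
if (!length(argv)) stop("usage: chorus-tool.R <simulate|analyze|detect|evaluate|plane> [options]")
cmd <- argv[1]
rest <- argv[-1]

parse <- function(opts) parse_args(OptionParser(option_list = opts), args = rest)

if (cmd == "simulate") {
  o <- parse(list(
    make_option("--preset", default = "a"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--out", default = "scenes")))
  cfg <- scene_presets(seed = o$seed)[[o$preset]]
  if (is.null(cfg)) stop("preset must be one of a, b, c, d")
  sc <- render_scene(cfg)
  files <- write_scene(sc, o$out, paste0("preset_", o$preset))
  message("wrote: ", paste(files, collapse = ", "))

} else if (cmd == "analyze") {
  o <- parse(list(
    make_option("--wav", default = NULL),
    make_option("--out", default = "results.csv"),
    make_option("--sensitivity", type = "double", default = -164.5),
    make_option("--d", type = "integer", default = 6L),
    make_option("--tau", type = "integer", default = 1L)))
  paths <- Sys.glob(o$wav)
  res <- analyze_files(paths, o$out, sensitivity_db = o$sensitivity,
                       d = o$d, tau = o$tau)
  if (length(attr(res, "failed"))) quit(status = 1L)

} else if (cmd == "detect") {
  o <- parse(list(
    make_option("--results", default = "results.csv"),
    make_option("--out", default = "detections.csv"),
    make_option("--threshold", type = "double", default = 0.5)))
  long <- utils::read.csv(o$results)
  wide <- stats::reshape(long, idvar = "window_id", timevar = "measure",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  out <- data.frame(window_id = wide$window_id)
  for (nm in intersect(c("H", "C", "ACI", "ADI", "BI"), names(wide))) {
    nrm <- min_max_normalize(wide[[nm]])
    out[[paste0(nm, "_norm")]] <- as.numeric(nrm)
    out[[paste0(nm, "_detected")]] <- detect_chorus(nrm, nm,
                                                    threshold = o$threshold)
  }
  utils::write.csv(out, o$out, row.names = FALSE)
  message("wrote ", o$out)

} else if (cmd == "evaluate") {
  o <- parse(list(
    make_option("--results", default = "results.csv"),
    make_option("--truth", default = "truth.csv"),
    make_option("--out", default = "evaluation")))
  long <- utils::read.csv(o$results)
  wide <- stats::reshape(long, idvar = "window_id", timevar = "measure",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide$hour <- seq_len(nrow(wide)) - 1L
  truth <- utils::read.csv(o$truth)
  ev <- evaluate_run(wide, truth)
  print(ev)
  files <- write_evaluation(ev, o$out)
  message("wrote: ", paste(files, collapse = ", "))

} else if (cmd == "plane") {
  o <- parse(list(
    make_option("--d", type = "integer", default = 6L),
    make_option("--out", default = "limit_curves.csv")))
  write_ch_csv(limit_curves(o$d), o$out)
  message("wrote ", o$out)

} else {
  stop("unknown command: ", cmd)
}
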