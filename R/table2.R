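#' Published diagnostic-performance confusion counts
#'
#' Loads the packaged fixture of published confusion counts (TP/FP/FN/TN),
#' operating cutoffs and printed integer-percent metric cells for the
#' combined model, CNN model, FIB-4, APRI and two radiologists on the three
#' testing datasets. Used to verify that [metrics_with_ci()] reproduces the
#' printed arithmetic exactly.
#'
#' @return nested list keyed dataset -> model
#' @export
published_counts <- function() {
  path <- system.file("extdata", "table2_counts.json", package = "hepascan")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$comment <- NULL
  obj
}

#' Metric table for all published models in one dataset
#'
#' @param dataset one of `"internal1"`, `"internal2"`, `"external"`
#' @return data.frame: model, metric, estimate, percent, printed
#' @export
published_metrics <- function(dataset = c("internal1", "internal2", "external")) {
  dataset <- match.arg(dataset)
  d <- published_counts()[[dataset]]
  d$n <- NULL
  out <- lapply(names(d), function(model) {
    e <- d[[model]]
    ms <- metrics_with_ci(confusion_counts(e$tp, e$fp, e$fn, e$tn),
                          cutoff = e$cutoff %||% NA)
    ms$model <- model
    ms$printed <- unlist(e$printed)[ms$metric]
    ms
  })
  do.call(rbind, out)
}
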