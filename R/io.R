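#' Write and read spike-train datasets
#'
#' Datasets are written as a two-column CSV `(train_id, spike_time_s)`
#' plus a JSON sidecar (`<file>.json`) recording per-train duration,
#' condition and latent component, and the dataset seed.
#'
#' @param dataset a list of [spike_train()] objects.
#' @param file CSV path; the sidecar goes to `paste0(file, ".json")`.
#' @return The CSV path, invisibly.
#' @export
write_spike_trains <- function(dataset, file) {
  rows <- do.call(rbind, lapply(seq_along(dataset), function(i)
    if (length(dataset[[i]]$times))
      data.frame(train_id = i, spike_time_s = dataset[[i]]$times)
    else NULL))
  write.csv(rows, file, row.names = FALSE)
  side <- list(
    n_trains = length(dataset),
    seed = attr(dataset, "seed"),
    trains = lapply(dataset, function(tr)
      list(duration = tr$duration,
           condition = if (is.na(tr$condition)) NULL else tr$condition,
           component = if (is.na(tr$component)) NULL else tr$component)))
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(file) {
  rows <- read.csv(file)
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = FALSE)
  n <- side$n_trains
  trains <- vector("list", n)
  for (i in seq_len(n)) {
    meta <- side$trains[[i]]
    trains[[i]] <- spike_train(rows$spike_time_s[rows$train_id == i],
                               duration = meta$duration,
                               condition = if (is.null(meta$condition)) NA else meta$condition,
                               component = if (is.null(meta$component)) NA_integer_
                                           else as.integer(meta$component))
  }
  structure(trains, class = "lif_dataset",
            seed = if (is.null(side$seed)) NULL else side$seed)
}
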