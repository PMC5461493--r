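#' Write a dataset to a directory
#'
#' On-disk layout: `dataset.json` (direction set, bin width, sample duration,
#' provenance), `trials.csv`, `neurons.csv` and one `rates/<neuron_id>.csv`
#' per neuron (one row per trial in `trials.csv` order, one column per time
#' bin). All CSV files carry a header row, UTF-8, '.' decimal separator.
#'
#' @param dataset A `pm_dataset`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_pm_dataset <- function(dataset, path) {
  validate_pm_dataset(dataset)
  dir.create(file.path(path, "rates"), recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    direction_set = dataset$direction_set,
    bin_ms = dataset$bin_ms,
    sample_ms = dataset$sample_ms,
    subjects = unique(dataset$neurons$subject_id),
    provenance = dataset$provenance[setdiff(names(dataset$provenance),
                                            "ground_truth")]
  )
  jsonlite::write_json(meta, file.path(path, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(dataset$trials, file.path(path, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$neurons, file.path(path, "neurons.csv"),
                   row.names = FALSE)
  if (!is.null(dataset$provenance$ground_truth)) {
    utils::write.csv(dataset$provenance$ground_truth,
                     file.path(path, "ground_truth.csv"), row.names = FALSE)
  }
  for (id in dataset$neurons$neuron_id) {
    m <- dataset$rates[[id]]
    colnames(m) <- paste0("bin", seq_len(ncol(m)) - 1L)
    utils::write.csv(as.data.frame(m), file.path(path, "rates",
                                                 paste0(id, ".csv")),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a dataset from a directory
#'
#' Inverse of [write_pm_dataset()]; `write` then `read` is the identity on
#' all fields up to floating-point text round-trip. Schema violations
#' (unknown task labels, row-count mismatches, missing files) raise
#' descriptive errors.
#'
#' @param path Dataset directory.
#' @return A `pm_dataset`.
#' @export
read_pm_dataset <- function(path) {
  jf <- file.path(path, "dataset.json")
  if (!file.exists(jf)) stop("missing dataset.json in ", path)
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  tf <- file.path(path, "trials.csv")
  nf <- file.path(path, "neurons.csv")
  if (!file.exists(tf)) stop("missing trials.csv in ", path)
  if (!file.exists(nf)) stop("missing neurons.csv in ", path)
  trials <- tibble::as_tibble(utils::read.csv(tf, stringsAsFactors = FALSE,
                                              colClasses = c(session_id = "character",
                                                             subject_id = "character")))
  neurons <- tibble::as_tibble(utils::read.csv(nf, stringsAsFactors = FALSE,
                                               colClasses = c(neuron_id = "character",
                                                              subject_id = "character")))
  rates <- lapply(neurons$neuron_id, function(id) {
    f <- file.path(path, "rates", paste0(id, ".csv"))
    if (!file.exists(f)) stop("missing rates file for neuron ", id)
    m <- as.matrix(utils::read.csv(f))
    dimnames(m) <- NULL
    m
  })
  names(rates) <- neurons$neuron_id
  gt <- file.path(path, "ground_truth.csv")
  prov <- as.list(meta$provenance %||% list())
  if (file.exists(gt)) {
    prov$ground_truth <- tibble::as_tibble(
      utils::read.csv(gt, stringsAsFactors = FALSE))
  }
  pm_dataset(trials = trials, neurons = neurons, rates = rates,
             direction_set = meta$direction_set, bin_ms = meta$bin_ms,
             sample_ms = meta$sample_ms, provenance = prov)
}
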