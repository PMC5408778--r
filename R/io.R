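# File round-tripping for characterization datasets and configuration.

#' Write / read characterization datasets
#'
#' Delimited tables matching the characterization record fields, with the
#' fluorescence column named by its calibrated unit (`fluorescence_mefl` for
#' green/sfGFP reporters, `fluorescence_mecy` for red/mCherry).
#'
#' @param dataset Characterization data.frame (see
#'   [generate_characterization()]).
#' @param path File path.
#' @param units `"mefl"` or `"mecy"`.
#' @return The path / the dataset with a plain `fluorescence` column.
#' @export
write_characterization <- function(dataset, path, units = c("mefl", "mecy")) {
  units <- match.arg(units)
  out <- dataset
  names(out)[names(out) == "fluorescence"] <- paste0("fluorescence_", units)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_characterization
#' @export
read_characterization <- function(path) {
  tab <- utils::read.csv(path)
  fcol <- grep("^fluorescence", names(tab), value = TRUE)
  if (length(fcol) != 1L) stop("expected exactly one fluorescence_* column")
  names(tab)[names(tab) == fcol] <- "fluorescence"
  attr(tab, "units") <- sub("fluorescence_?", "", fcol)
  for (col in c("bg_led", "bg_intensity"))
    if (!col %in% names(tab)) tab[[col]] <- NA
  tab
}

#' Read a run configuration
#'
#' A single human-readable YAML file holding paths, parameters, and seeds for
#' command-line runs.
#'
#' @param path Path to a YAML file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}
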