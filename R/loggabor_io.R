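#' Export / import a filter bank
#'
#' `write_bank()` stores the stacked transfer functions as a serialized
#' height x width x n_filters array and writes a JSON sidecar
#' (`<path>.json`) holding the generating parameters and grid size, so banks
#' are portable and auditable. `read_bank()` reads the pair back and verifies
#' the array shape against the sidecar.
#'
#' @param bank A [build_bank()] result.
#' @param path File path for the array container; the sidecar is written
#'   alongside as `<path>.json`.
#' @return `write_bank()` returns `path` invisibly; `read_bank()` returns a
#'   `log_gabor_bank`.
#' @export
write_bank <- function(bank, path) {
  stopifnot(inherits(bank, "log_gabor_bank"))
  arr <- array(unlist(bank$transfers, use.names = FALSE),
               dim = c(bank$height, bank$width, length(bank$transfers)))
  saveRDS(arr, path)
  sidecar <- list(
    params = unclass(bank$params),
    height = bank$height, width = bank$width,
    n_filters = length(bank$transfers)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_bank
#' @export
read_bank <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- readRDS(path)
  if (!identical(dim(arr),
                 as.integer(c(side$height, side$width, side$n_filters)))) {
    stop("bank array shape disagrees with JSON sidecar", call. = FALSE)
  }
  params <- do.call(log_gabor_params, as.list(side$params))
  bank <- build_bank(params, side$height, side$width)
  bank$transfers <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  bank
}
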