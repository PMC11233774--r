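# shared validation helpers and error classes

roles <- c("teacher", "focal_child", "peer")

abort_validation <- function(message, ...) {
  abort(message, class = "classtalk_validation_error", ...)
}

abort_format <- function(message, ...) {
  abort(message, class = "classtalk_format_error", ...)
}

abort_io <- function(message, ...) {
  abort(message, class = "classtalk_io_error", ...)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort_validation(sprintf("`%s` must be a single positive number", name))
  }
  invisible(x)
}

check_file_exists <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort_io(sprintf("file not found: %s", as.character(path)[1]))
  }
  invisible(path)
}

# normalize an unordered participant pair into lexicographic order
normalize_pair <- function(id_a, id_b) {
  lo <- pmin(id_a, id_b)
  hi <- pmax(id_a, id_b)
  tibble::tibble(id_a = lo, id_b = hi)
}

pair_key <- function(id_a, id_b) {
  paste(pmin(id_a, id_b), pmax(id_a, id_b), sep = "\r")
}
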