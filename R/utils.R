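# internal helpers

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_input <- function(...) stop(sprintf(...), call. = FALSE)

# full-precision text serialization of a numeric matrix (samples x channels);
# %.17g guarantees doubles round-trip exactly through text
#' @noRd
write_signal_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  txt <- matrix(sprintf("%.17g", mat), nrow = nrow(mat))
  lines <- do.call(paste, c(asplit(txt, 2), list(sep = "\t")))
  writeLines(c(paste(sprintf("ch%d", seq_len(ncol(mat))), collapse = "\t"), lines), path)
}

#' @noRd
read_signal_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt)
  dimnames(m) <- NULL
  m
}
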