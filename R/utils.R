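# internal helpers shared across modules

#' Evaluate an expression under a fixed RNG seed, restoring RNG state after
#' @param seed integer seed
#' @param code expression
#' @return value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# derive a reproducible child seed (kept below 2^31)
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(k) * 7919L
}

#' Construct a multi-channel image field
#'
#' A field is a named list of equal-sized intensity matrices (arbitrary
#' units on the 16-bit camera scale) plus provenance identifiers.
#'
#' @param channels named list of numeric matrices, identical dimensions
#' @param well,field optional provenance identifiers
#' @return an `image_field` object
#' @export
image_field <- function(channels, well = NA_character_, field = NA_integer_) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  d <- dim(channels[[1L]])
  for (ch in channels) {
    stopifnot(is.matrix(ch), identical(dim(ch), d))
    if (any(ch < 0 | ch > 65535, na.rm = TRUE))
      stop("channel intensities must lie in [0, 65535]")
  }
  structure(list(channels = channels, channel_names = names(channels),
                 dim = d, well = well, field = field),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf("image_field %dx%d px, channels: %s\n",
              x$dim[1L], x$dim[2L], paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

# clip-and-quantize a rendered intensity surface to the 16-bit camera scale
quantize16 <- function(x) {
  matrix(pmin(pmax(round(x), 0), 65535), nrow(x), ncol(x))
}

# edge-replicate padding of a matrix by p pixels on every side
pad_replicate <- function(x, p) {
  i <- pmin(pmax(seq_len(nrow(x) + 2L * p) - p, 1L), nrow(x))
  j <- pmin(pmax(seq_len(ncol(x) + 2L * p) - p, 1L), ncol(x))
  x[i, j, drop = FALSE]
}
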