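# file interfaces: multi-page TIFF fields and label masks

#' Write an image field as a multi-page 16-bit TIFF
#'
#' One page per channel, in the field's channel order. Requires the
#' `tiff` package.
#'
#' @param field an [image_field()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_field_tiff <- function(field, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF I/O")
  stopifnot(inherits(field, "image_field"))
  pages <- lapply(field$channels, function(ch) ch / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_field_tiff()]
#'
#' @param path TIFF file
#' @param channel_names names to assign to the pages
#' @param well,field_index provenance labels
#' @return an [image_field()]
#' @export
read_field_tiff <- function(path, channel_names = c("dapi", "hp1a", "gh2av"),
                            well = NA_character_, field_index = NA_integer_) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF I/O")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(channel_names))
    stop("TIFF has ", length(pages), " pages but ",
         length(channel_names), " channel names were given")
  chans <- lapply(pages, function(p) round(p * 65535))
  names(chans) <- channel_names
  image_field(chans, well = well, field = field_index)
}

#' Write a per-nucleus QC/shape table as CSV
#'
#' @param mask a `nucleus_mask` (after [qc_filter()] if QC flags are wanted)
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_nucleus_table <- function(mask, path) {
  stopifnot(inherits(mask, "nucleus_mask"))
  tab <- mask$shape
  if (!is.null(mask$qc) && nrow(mask$qc))
    tab <- merge(tab, mask$qc, by = "label", all.x = TRUE)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
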