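#' Write a result object as JSON
#'
#' Serialises lists/data.frames (CNV truth, benchmark results, dynamics
#' summaries, ...) with scalars unboxed and full numeric precision.
#'
#' @param x object to serialise (classed lists are unclassed first).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_json_result <- function(x, path) {
  if (is.object(x) && !is.data.frame(x)) x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
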