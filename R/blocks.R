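#' @rdname LinkedBlocks-class
#' @export
setMethod("addLocation", "LinkedBlocks", function(x, pos) {
  cpp_lb_add(x@ptr, .lbPos(x, pos))
  invisible(x)
})

#' @rdname LinkedBlocks-class
#' @export
setMethod("removeLocation", "LinkedBlocks", function(x, pos) {
  cpp_lb_remove(x@ptr, .lbPos(x, pos))
  invisible(x)
})

#' @rdname LinkedBlocks-class
#' @export
setMethod("peekLeft", "LinkedBlocks", function(x, pos) {
  p <- cpp_lb_peek_left(x@ptr, .lbPos(x, pos))
  if (p < 0) NA_integer_ else p + 1L
})

#' @rdname LinkedBlocks-class
#' @export
setMethod("peekRight", "LinkedBlocks", function(x, pos) {
  p <- cpp_lb_peek_right(x@ptr, .lbPos(x, pos))
  if (p < 0) NA_integer_ else p + 1L
})

#' @rdname LinkedBlocks-class
#' @export
setMethod("blockStats", "LinkedBlocks", function(x) cpp_lb_stats(x@ptr))

#' @rdname LinkedBlocks-class
#' @export
setMethod("selectedLocations", "LinkedBlocks", function(x) {
  sort(cpp_lb_locations(x@ptr)) + 1L
})

.lbPos <- function(x, pos) {
  pos <- as.integer(pos)
  if (length(pos) != 1L || is.na(pos) || pos < 1L || pos > x@n)
    stop("location out of range [1, ", x@n, "]")
  pos - 1L
}

setMethod("show", "LinkedBlocks", function(object) {
  st <- blockStats(object)
  cat("LinkedBlocks: n =", object@n, ", w =", object@w,
      ", block width =", max(1L, object@w %/% 2L), "\n")
  cat("  selected locations:", st$aele, " segments:", st$aseg, "\n")
  cat(sprintf("  Acov = %.0f   link energy L = %.6g\n", st$acov, st$L))
})
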