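## Structured conditions.  Every domain failure gets its own condition class
## so callers (and the batch driver) can branch on the cause.

mg_stop <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mg_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

mg_warn <- function(class, message) {
  warning(structure(
    class = c(class, "mg_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' @noRd
flat_image_error <- function(msg) mg_stop("flat_image_error", msg)
no_boundary_error <- function(msg) mg_stop("no_boundary_error", msg)
empty_mask_error <- function(msg) mg_stop("empty_mask_error", msg)
empty_roi_error <- function(msg) mg_stop("empty_roi_error", msg)
degenerate_object_error <- function(msg) mg_stop("degenerate_object_error", msg)
invalid_counts_error <- function(msg) mg_stop("invalid_counts_error", msg)
outside_roi_error <- function(msg) mg_stop("outside_roi_error", msg)
insufficient_reference_error <- function(msg) mg_stop("insufficient_reference_error", msg)
out_of_range_error <- function(msg) mg_stop("out_of_range_error", msg)
degenerate_data_error <- function(msg) mg_stop("degenerate_data_error", msg)
empty_table_error <- function(msg) mg_stop("empty_table_error", msg)
parameter_error <- function(msg) mg_stop("parameter_error", msg)
file_not_found_error <- function(msg) mg_stop("file_not_found_error", msg)
unsupported_format_error <- function(msg) mg_stop("unsupported_format_error", msg)
empty_directory_error <- function(msg) mg_stop("empty_directory_error", msg)
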