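#' Multipart chunking policy
#'
#' The two transfer settings that govern how an S3-style ETag is computed:
#' the size at which a file switches from a plain whole-content MD5 to a
#' multipart digest-of-digests, and the size of each part. The defaults match
#' the AWS CLI transfer defaults of 8 MB each, interpreted as
#' 8 x 1024 x 1024 = 8,388,608 bytes (the transfer manager's units).
#'
#' Files whose size is greater than or equal to `threshold_bytes` are treated
#' as multipart uploads; AWS's transfer manager uses the same `>=` rule.
#'
#' @param threshold_bytes Size in bytes at or above which a file is hashed as
#'   a multipart upload. Must be a positive integer.
#' @param chunk_size_bytes Size in bytes of each multipart part. Must be a
#'   positive integer.
#' @return An object of class `chunking_policy`.
#' @examples
#' chunking_policy()                 # AWS CLI defaults: 8 MiB / 8 MiB
#' chunking_policy(1024, 1024)      # kilobyte-scale policy for testing
#' @export
chunking_policy <- function(threshold_bytes = 8 * 1024 * 1024,
                            chunk_size_bytes = 8 * 1024 * 1024) {
  threshold_bytes <- as.numeric(threshold_bytes)
  chunk_size_bytes <- as.numeric(chunk_size_bytes)
  if (length(threshold_bytes) != 1 || !is.finite(threshold_bytes) ||
      threshold_bytes <= 0 || threshold_bytes != trunc(threshold_bytes)) {
    stop("`threshold_bytes` must be a single positive integer (bytes).",
         call. = FALSE)
  }
  if (length(chunk_size_bytes) != 1 || !is.finite(chunk_size_bytes) ||
      chunk_size_bytes <= 0 || chunk_size_bytes != trunc(chunk_size_bytes)) {
    stop("`chunk_size_bytes` must be a single positive integer (bytes).",
         call. = FALSE)
  }
  structure(
    list(threshold_bytes = threshold_bytes,
         chunk_size_bytes = chunk_size_bytes),
    class = "chunking_policy"
  )
}

#' @export
print.chunking_policy <- function(x, ...) {
  cat(sprintf(
    "<chunking_policy> multipart threshold: %s bytes; chunk size: %s bytes\n",
    format(x$threshold_bytes, big.mark = ","),
    format(x$chunk_size_bytes, big.mark = ",")
  ))
  invisible(x)
}
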