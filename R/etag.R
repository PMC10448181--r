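raw_to_hex <- function(r) {
  paste(sprintf("%02x", as.integer(r)), collapse = "")
}

is_hex32 <- function(x) {
  is.character(x) && length(x) == 1 && grepl("^[0-9a-f]{32}$", x)
}

#' ETag value
#'
#' A parsed S3 entity tag: a 32-character lowercase hexadecimal MD5 digest,
#' plus an optional part count. The part count is present exactly when the
#' object was stored via a multipart upload, in which case the tag renders as
#' `<digest>-<parts>`; a simple upload renders as the bare digest.
#'
#' @param digest_hex 32 lowercase hexadecimal characters. Uppercase input is
#'   normalized to lowercase.
#' @param part_count `NULL` for a simple (single PUT) tag, otherwise a
#'   positive integer number of multipart parts.
#' @return An object of class `s3_etag`.
#' @seealso [parse_etag()], [etags_equal()], [format.s3_etag()]
#' @export
etag <- function(digest_hex, part_count = NULL) {
  if (!is.character(digest_hex) || length(digest_hex) != 1 || is.na(digest_hex)) {
    stop("`digest_hex` must be a single character string.", call. = FALSE)
  }
  digest_hex <- tolower(digest_hex)
  if (!is_hex32(digest_hex)) {
    stop(sprintf("invalid MD5 digest %s: expected 32 hexadecimal characters.",
                 sQuote(digest_hex)), call. = FALSE)
  }
  if (!is.null(part_count)) {
    part_count <- as.integer(part_count)
    if (length(part_count) != 1 || is.na(part_count) || part_count < 1) {
      stop("`part_count` must be NULL or a single positive integer.",
           call. = FALSE)
    }
  }
  structure(list(digest_hex = digest_hex, part_count = part_count),
            class = "s3_etag")
}

#' Parse an ETag string
#'
#' Normalizes the `"ETag"` field of a bucket listing entry: strips one layer
#' of surrounding double quotes if present (the list-objects JSON dialect
#' embeds literal quotes in the value), lowercases the hex digest, and splits
#' a trailing `-<digits>` suffix into the part count.
#'
#' @param raw A non-empty ETag string, possibly wrapped in literal double
#'   quotes, e.g. `"\"d41d8cd98f00b204e9800998ecf8427e-3\""`.
#' @return An [etag()] object.
#' @examples
#' parse_etag("\"900150983cd24fb0d6963f7d28e17f72\"")
#' parse_etag("d41d8cd98f00b204e9800998ecf8427e-3")
#' @export
parse_etag <- function(raw) {
  if (!is.character(raw) || length(raw) != 1 || is.na(raw) || !nzchar(raw)) {
    stop("ETag value must be a single non-empty string.", call. = FALSE)
  }
  value <- raw
  if (grepl('^".*"$', value)) {
    value <- substr(value, 2, nchar(value) - 1)
  }
  value <- tolower(value)
  if (grepl("-", value, fixed = TRUE)) {
    dash <- max(gregexpr("-", value, fixed = TRUE)[[1]])
    digest <- substr(value, 1, dash - 1)
    suffix <- substr(value, dash + 1, nchar(value))
    if (!grepl("^[0-9]+$", suffix)) {
      stop(sprintf("malformed ETag %s: part-count suffix %s is not numeric.",
                   sQuote(raw), sQuote(suffix)), call. = FALSE)
    }
    parts <- suppressWarnings(as.integer(suffix))
    if (is.na(parts) || parts < 1) {
      stop(sprintf("malformed ETag %s: part count must be a positive integer.",
                   sQuote(raw)), call. = FALSE)
    }
    if (!is_hex32(digest)) {
      stop(sprintf("malformed ETag %s: digest is not 32 hex characters.",
                   sQuote(raw)), call. = FALSE)
    }
    etag(digest, parts)
  } else {
    if (!is_hex32(value)) {
      stop(sprintf("malformed ETag %s: digest is not 32 hex characters.",
                   sQuote(raw)), call. = FALSE)
    }
    etag(value)
  }
}

#' Render an ETag as a string
#'
#' The canonical rendering is the lowercase hex digest, followed by
#' `-<part count>` when the tag came from a multipart upload. No surrounding
#' quotes are added.
#'
#' @param x An [etag()] object.
#' @param ... Unused.
#' @export
format.s3_etag <- function(x, ...) {
  if (is.null(x$part_count)) x$digest_hex
  else paste0(x$digest_hex, "-", x$part_count)
}

#' @export
print.s3_etag <- function(x, ...) {
  cat("<s3_etag>", format(x), "\n")
  invisible(x)
}

#' Compare two ETags for equality
#'
#' Two tags are equal iff their digests match (comparison is
#' case-insensitive because both sides are normalized to lowercase at parse
#' time) and their part counts match structurally: both absent, or both
#' present and equal. A multipart tag never equals a single-part tag, even on
#' the same digest.
#'
#' @param a,b [etag()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
etags_equal <- function(a, b) {
  stopifnot(inherits(a, "s3_etag"), inherits(b, "s3_etag"))
  if (a$digest_hex != b$digest_hex) return(FALSE)
  if (is.null(a$part_count) != is.null(b$part_count)) return(FALSE)
  is.null(a$part_count) || a$part_count == b$part_count
}
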