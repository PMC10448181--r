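# Checksum engine: whole-content MD5 below the multipart threshold, and the
# S3 multipart digest-of-digests at or above it. All hashing goes through
# openssl's MD5 (OpenSSL's libcrypto); file content is streamed through a
# bounded buffer so memory use is independent of file size.

# Coerce a "readable byte source" (raw vector, open connection, or file
# path) to a connection, recording whether we own it and must close it.
as_byte_source <- function(stream) {
  if (is.raw(stream)) {
    list(con = rawConnection(stream), owned = TRUE)
  } else if (inherits(stream, "connection")) {
    if (!isOpen(stream)) open(stream, "rb")
    list(con = stream, owned = FALSE)
  } else if (is.character(stream) && length(stream) == 1) {
    if (!file.exists(stream)) {
      stop(sprintf("cannot read %s: no such file.", sQuote(stream)),
           call. = FALSE)
    }
    list(con = file(stream, "rb"), owned = TRUE)
  } else {
    stop("`stream` must be a raw vector, a connection, or a file path.",
         call. = FALSE)
  }
}

#' MD5 digest of a byte stream
#'
#' Computes the MD5 of the full content of `stream` — the Content-MD5 of a
#' file, in hexadecimal form — reading it once through a bounded buffer.
#'
#' @param stream A raw vector, an (openable) connection, or a file path.
#' @return A 32-character lowercase hexadecimal digest string.
#' @examples
#' md5_hex(raw(0))             # "d41d8cd98f00b204e9800998ecf8427e"
#' md5_hex(charToRaw("abc"))   # "900150983cd24fb0d6963f7d28e17f72"
#' @export
md5_hex <- function(stream) {
  src <- as_byte_source(stream)
  if (src$owned) on.exit(close(src$con), add = TRUE)
  digest <- tryCatch(
    openssl::md5(src$con),
    error = function(e) {
      stop(sprintf("I/O error while reading %s: %s",
                   sQuote(summary(src$con)$description),
                   conditionMessage(e)), call. = FALSE)
    }
  )
  raw_to_hex(digest)
}

#' Multipart (digest-of-digests) ETag of a byte stream
#'
#' Reproduces the checksum S3 assigns to a multipart upload: the content is
#' split into consecutive parts of `chunk_size_bytes` (the last part may be
#' short), each part's raw 16-byte MD5 digest is computed, the raw digests
#' are concatenated in order, and the MD5 of that concatenation becomes the
#' final digest, suffixed with the number of parts. A single pass over the
#' stream; memory is bounded by one part plus 16 bytes per part seen.
#'
#' An empty stream is treated as a single empty part, so it yields a
#' `...-1` tag (the function is total over all inputs).
#'
#' @param stream A raw vector, an (openable) connection, or a file path.
#' @param chunk_size_bytes Part size in bytes; must be positive.
#' @param buffer_size Read-buffer size in bytes. The result is independent of
#'   this value; it only bounds each read from the source.
#' @return An [etag()] with `part_count` set.
#' @examples
#' multipart_etag(charToRaw("abcdefgh"), chunk_size_bytes = 4)  # 2 parts
#' @export
multipart_etag <- function(stream, chunk_size_bytes,
                           buffer_size = 65536L) {
  chunk_size_bytes <- as.numeric(chunk_size_bytes)
  if (length(chunk_size_bytes) != 1 || !is.finite(chunk_size_bytes) ||
      chunk_size_bytes < 1) {
    stop("`chunk_size_bytes` must be a positive number of bytes.",
         call. = FALSE)
  }
  buffer_size <- max(1L, as.integer(buffer_size))
  src <- as_byte_source(stream)
  if (src$owned) on.exit(close(src$con), add = TRUE)

  part_digests <- raw(0)   # 16 raw bytes appended per completed part
  n_parts <- 0L
  carry <- raw(0)          # bytes of the part under construction

  repeat {
    block <- tryCatch(
      readBin(src$con, what = "raw", n = buffer_size),
      error = function(e) {
        stop(sprintf("I/O error while reading %s: %s",
                     sQuote(summary(src$con)$description),
                     conditionMessage(e)), call. = FALSE)
      }
    )
    if (length(block) == 0) break
    carry <- c(carry, block)
    while (length(carry) >= chunk_size_bytes) {
      part <- carry[seq_len(chunk_size_bytes)]
      carry <- carry[-seq_len(chunk_size_bytes)]
      part_digests <- c(part_digests, as.raw(openssl::md5(part)))
      n_parts <- n_parts + 1L
    }
  }
  # trailing short part; an empty stream counts as one empty part
  if (length(carry) > 0 || n_parts == 0L) {
    part_digests <- c(part_digests, as.raw(openssl::md5(carry)))
    n_parts <- n_parts + 1L
  }
  etag(raw_to_hex(openssl::md5(part_digests)), part_count = n_parts)
}

#' Compute the S3-style checksum of a local file
#'
#' Dispatches on file size exactly as the AWS CLI transfer commands do under
#' their default configuration: files smaller than the policy threshold get
#' a plain whole-content MD5 (no part suffix); files at or above it get the
#' multipart digest-of-digests via [multipart_etag()].
#'
#' @param path Path to an existing, readable, regular file.
#' @param policy A [chunking_policy()]; defaults to the AWS CLI 8 MiB values.
#' @param buffer_size Read-buffer size in bytes (result-invariant).
#' @return An object of class `s3_local_digest`: a list with fields `etag`
#'   (an [etag()]), `size_bytes`, and `path`.
#' @export
compute_etag_for_file <- function(path, policy = chunking_policy(),
                                  buffer_size = 65536L) {
  stopifnot(inherits(policy, "chunking_policy"))
  if (!is.character(path) || length(path) != 1) {
    stop("`path` must be a single file path.", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(sprintf("file %s does not exist.", sQuote(path)), call. = FALSE)
  }
  info <- file.info(path, extra_cols = FALSE)
  if (isTRUE(info$isdir)) {
    stop(sprintf("%s is a directory, not a regular file.", sQuote(path)),
         call. = FALSE)
  }
  if (file.access(path, mode = 4) != 0) {
    stop(sprintf("permission denied reading %s.", sQuote(path)),
         call. = FALSE)
  }
  size <- as.numeric(info$size)
  tag <- if (size < policy$threshold_bytes) {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    etag(md5_hex(con))
  } else {
    multipart_etag(path, policy$chunk_size_bytes, buffer_size = buffer_size)
  }
  structure(list(etag = tag, size_bytes = size, path = path),
            class = "s3_local_digest")
}

#' @export
print.s3_local_digest <- function(x, ...) {
  cat(sprintf("<s3_local_digest> %s  (%s, %s bytes)\n",
              format(x$etag), x$path, format(x$size_bytes, big.mark = ",")))
  invisible(x)
}
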