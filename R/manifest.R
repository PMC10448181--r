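# Bucket metadata: parsing the list-objects JSON dialect, and obtaining it
# either from an offline document or from a live endpoint through a
# pluggable backend. Verification only ever consumes the normalized
# BucketManifest produced here.

access_error <- function(message) {
  structure(
    class = c("s3fixity_access_error", "error", "condition"),
    list(message = message, call = NULL)
  )
}

new_remote_object <- function(key, etag, size_bytes = NULL,
                              last_modified = NULL, extra = list()) {
  if (!is.character(key) || length(key) != 1 || !nzchar(key)) {
    stop("remote object key must be a non-empty string.", call. = FALSE)
  }
  stopifnot(inherits(etag, "s3_etag"))
  structure(
    list(key = key, etag = etag,
         size_bytes = if (is.null(size_bytes)) NULL else as.numeric(size_bytes),
         last_modified = last_modified, extra = extra),
    class = "s3_remote_object"
  )
}

new_bucket_manifest <- function(bucket_name, objects) {
  structure(list(bucket_name = bucket_name, objects = objects),
            class = "s3_bucket_manifest")
}

#' @export
print.s3_bucket_manifest <- function(x, ...) {
  cat(sprintf("<s3_bucket_manifest> bucket %s: %d object(s)\n",
              sQuote(x$bucket_name), length(x$objects)))
  invisible(x)
}

#' Number of objects in a bucket manifest
#' @param x An `s3_bucket_manifest`.
#' @export
length.s3_bucket_manifest <- function(x) length(x$objects)

entries_to_manifest <- function(entries, bucket_name, source_label) {
  objects <- list()
  for (i in seq_along(entries)) {
    entry <- entries[[i]]
    if (is.null(entry$Key) || is.null(entry$ETag)) {
      stop(sprintf("%s: entry %d lacks a \"Key\" or \"ETag\" field.",
                   source_label, i), call. = FALSE)
    }
    key <- as.character(entry$Key)
    if (!is.null(objects[[key]])) {
      stop(sprintf("%s: duplicate key %s (entries must be unique).",
                   source_label, sQuote(key)), call. = FALSE)
    }
    known <- c("Key", "ETag", "Size", "LastModified")
    objects[[key]] <- new_remote_object(
      key = key,
      etag = parse_etag(as.character(entry$ETag)),
      size_bytes = entry$Size,
      last_modified = entry$LastModified,
      extra = entry[setdiff(names(entry), known)]
    )
  }
  new_bucket_manifest(bucket_name, objects)
}

#' Parse a list-objects JSON document into a bucket manifest
#'
#' Accepts the JSON shape emitted by `aws s3api list-objects` (and
#' `list-objects-v2`): either a top-level object with a `"Contents"` array,
#' or a bare array of entries. Each entry must carry `"Key"` and `"ETag"`
#' (the ETag string may embed literal double quotes, which are stripped);
#' `"Size"` and `"LastModified"` are captured when present, and any other
#' fields are preserved untouched in the object's `extra` field but play no
#' role in verification.
#'
#' @param json_text A JSON document as a single string.
#' @param bucket_name Optional bucket name to record on the manifest.
#' @return An `s3_bucket_manifest`: the bucket name plus a mapping from
#'   object key to remote object (key, parsed ETag, size, last-modified).
#' @export
parse_list_objects <- function(json_text, bucket_name = NA_character_) {
  doc <- tryCatch(
    jsonlite::fromJSON(json_text, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("invalid list-objects JSON: %s", conditionMessage(e)),
           call. = FALSE)
    }
  )
  entries <- if (is.list(doc) && !is.null(names(doc))) {
    if (is.null(doc$Contents)) list() else doc$Contents
  } else if (is.list(doc)) {
    doc
  } else {
    stop("invalid list-objects JSON: expected an object or an array.",
         call. = FALSE)
  }
  entries_to_manifest(entries, bucket_name, "list-objects document")
}

#' Read a bucket manifest from a JSON file (offline mode)
#'
#' Offline counterpart to [fetch_manifest()]: reads a previously saved
#' `list-objects` response from disk, so a verification run needs no cloud
#' credentials and no network. This mode is an extension over the original
#' command-line workflow, which always queried the live API.
#'
#' @param path Path to a JSON file in the list-objects dialect.
#' @param bucket_name Optional bucket name to record on the manifest.
#' @return An `s3_bucket_manifest`.
#' @export
read_manifest <- function(path, bucket_name = NA_character_) {
  if (!file.exists(path)) {
    stop(sprintf("manifest file %s does not exist.", sQuote(path)),
         call. = FALSE)
  }
  parse_list_objects(
    paste(readLines(path, warn = FALSE), collapse = "\n"),
    bucket_name = bucket_name
  )
}

#' Serialize a bucket manifest back to list-objects JSON
#'
#' Inverse of [parse_list_objects()] on the (key, ETag, size) triples: the
#' ETag is re-quoted the way the AWS CLI prints it (literal double quotes
#' inside the JSON string).
#'
#' @param manifest An `s3_bucket_manifest`.
#' @return A JSON string with a top-level `"Contents"` array.
#' @export
manifest_to_json <- function(manifest) {
  stopifnot(inherits(manifest, "s3_bucket_manifest"))
  contents <- lapply(unname(manifest$objects), function(obj) {
    entry <- list(Key = obj$key,
                  ETag = paste0('"', format(obj$etag), '"'))
    if (!is.null(obj$size_bytes)) entry$Size <- obj$size_bytes
    if (!is.null(obj$last_modified)) entry$LastModified <- obj$last_modified
    entry
  })
  jsonlite::toJSON(list(Contents = contents), auto_unbox = TRUE,
                   digits = NA, pretty = TRUE)
}

# ---------------------------------------------------------------------------
# Backends: how a "live" listing is actually performed. A backend is a list
# with fields `check_access(bucket_name, profile)` (TRUE or an access error)
# and `list_page(bucket_name, profile, continuation_token)` (a list with
# `entries` and an optional `next_token`).

#' In-memory mock S3 backend
#'
#' Simulates an S3-compatible endpoint for offline testing: holds named
#' buckets of entries (each a list with at least `Key` and `ETag`), serves
#' paginated listing responses, can deny access to selected buckets, and
#' counts both logical listing queries and individual page requests so tests
#' can assert that a verification run issues exactly one listing.
#'
#' @param buckets Named list: bucket name -> list of entries (each entry a
#'   list with `Key`, `ETag`, and optionally `Size`, `LastModified`).
#' @param page_size Maximum entries per listing page (S3's cap is 1,000).
#' @param denied Character vector of bucket names for which every request
#'   fails with an access error.
#' @return An object of class `s3_mock_backend`. Its environment exposes the
#'   counters `listing_calls` (logical listings begun) and `page_requests`.
#' @export
mock_s3_backend <- function(buckets, page_size = 1000L,
                            denied = character()) {
  stopifnot(is.list(buckets))
  state <- new.env(parent = emptyenv())
  state$listing_calls <- 0L
  state$page_requests <- 0L

  deny_or_missing <- function(bucket_name) {
    if (bucket_name %in% denied) {
      stop(access_error(sprintf(
        "access denied to bucket %s. Check your AWS credentials (a named profile, SSO session, or IAM role) and retry.",
        sQuote(bucket_name))))
    }
    if (is.null(buckets[[bucket_name]])) {
      stop(access_error(sprintf(
        "bucket %s does not exist or is not visible to these credentials.",
        sQuote(bucket_name))))
    }
  }

  backend <- list(
    name = "mock",
    state = state,
    check_access = function(bucket_name, profile = NULL) {
      deny_or_missing(bucket_name)
      TRUE
    },
    list_page = function(bucket_name, profile = NULL,
                         continuation_token = NULL) {
      deny_or_missing(bucket_name)
      if (is.null(continuation_token)) {
        state$listing_calls <- state$listing_calls + 1L
        start <- 1L
      } else {
        start <- as.integer(continuation_token)
      }
      state$page_requests <- state$page_requests + 1L
      entries <- buckets[[bucket_name]]
      n <- length(entries)
      end <- min(n, start + page_size - 1L)
      page <- if (start > n) list() else entries[start:end]
      list(entries = page,
           next_token = if (end < n) as.character(end + 1L) else NULL)
    }
  )
  class(backend) <- "s3_mock_backend"
  backend
}

#' AWS CLI backend
#'
#' Performs live bucket access through the `aws` command-line tool, the same
#' mechanism the original workflow used: `aws s3 ls` for the read-access
#' check and `aws s3api list-objects` for the listing. JSON output is
#' requested explicitly (`--output json`), so the run does not depend on the
#' user's configured default output format. Requires the `aws` executable on
#' the PATH and working credentials.
#'
#' @return A backend usable with [fetch_manifest()] and
#'   [check_read_access()].
#' @export
awscli_backend <- function() {
  find_aws <- function() {
    aws <- Sys.which("aws")
    if (!nzchar(aws)) {
      stop(access_error(paste(
        "the `aws` command-line tool was not found on the PATH;",
        "install the AWS CLI or use offline mode (--manifest <file.json>).")))
    }
    aws
  }
  run_aws <- function(args) {
    aws <- find_aws()
    out <- suppressWarnings(system2(aws, args, stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0) {
      stop(access_error(paste(
        paste(out, collapse = "\n"),
        "Hint: authenticate with a named profile (-p), an SSO session,",
        "or an IAM role, and confirm read access to the bucket.")))
    }
    out
  }
  list(
    name = "awscli",
    check_access = function(bucket_name, profile = NULL) {
      args <- c("s3", "ls", paste0("s3://", bucket_name))
      if (!is.null(profile)) args <- c(args, "--profile", profile)
      run_aws(args)
      TRUE
    },
    list_page = function(bucket_name, profile = NULL,
                         continuation_token = NULL) {
      args <- c("s3api", "list-objects", "--bucket", bucket_name,
                "--output", "json")
      if (!is.null(profile)) args <- c(args, "--profile", profile)
      if (!is.null(continuation_token)) {
        args <- c(args, "--starting-token", continuation_token)
      }
      out <- paste(run_aws(args), collapse = "\n")
      doc <- jsonlite::fromJSON(out, simplifyVector = FALSE)
      list(entries = if (is.null(doc$Contents)) list() else doc$Contents,
           next_token = doc$NextToken)
    }
  )
}

#' Check read access to a bucket
#'
#' Mirrors the pre-flight `aws s3 ls` check: a minimal listing must succeed
#' before any checksum work begins. On failure an access error is signalled
#' (condition class `s3fixity_access_error`) carrying the endpoint's message
#' plus authentication hints; callers are expected to stop the run. Offline
#' runs that supply a manifest file skip this check entirely.
#'
#' @param bucket_name Bucket to probe.
#' @param profile Optional named AWS profile.
#' @param backend A backend, e.g. [mock_s3_backend()] or [awscli_backend()].
#' @return `TRUE` invisibly on success.
#' @export
check_read_access <- function(bucket_name, profile = NULL,
                              backend = awscli_backend()) {
  backend$check_access(bucket_name, profile)
  invisible(TRUE)
}

#' Fetch a bucket manifest with one logical listing query
#'
#' Enumerates the whole bucket through the backend with a single logical
#' list-objects query. When the endpoint truncates the response (S3 caps
#' pages at 1,000 objects) the continuation pages are followed
#' transparently; they are part of the same logical query, so the network
#' cost stays one listing per run regardless of bucket size.
#'
#' @inheritParams check_read_access
#' @return An `s3_bucket_manifest` covering every object in the bucket.
#' @export
fetch_manifest <- function(bucket_name, profile = NULL,
                           backend = awscli_backend()) {
  entries <- list()
  token <- NULL
  repeat {
    page <- backend$list_page(bucket_name, profile,
                              continuation_token = token)
    entries <- c(entries, page$entries)
    token <- page$next_token
    if (is.null(token)) break
  }
  entries_to_manifest(entries, bucket_name,
                      sprintf("bucket %s listing", sQuote(bucket_name)))
}
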