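Package: s3fixity
Title: End-to-End Integrity Verification for Datasets on S3-Compatible Object Storage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Verifies that a local directory tree is bit-identical to its copy in
    an Amazon-S3-compatible bucket by recomputing each file's ETag exactly as S3
    assigns it (a plain MD5 digest below the multipart threshold, a
    digest-of-digests with a part-count suffix at or above it) and comparing the
    result against bucket metadata obtained from a single logical list-objects
    query. Reports a per-file verdict (verified, missing from the bucket, or
    checksum mismatch), continues past warnings, and mirrors every on-screen
    message to a timestamped log file. Includes an offline manifest mode, a
    deterministic synthetic-fixture generator with an independent checksum
    oracle, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    openssl,
    optparse,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
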