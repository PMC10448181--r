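# Checksum engine: plain MD5, multipart digest-of-digests, size dispatch.

test_that("md5_hex reproduces the RFC 1321 reference vectors", {
  expect_identical(md5_hex(raw(0)), "d41d8cd98f00b204e9800998ecf8427e")
  expect_identical(md5_hex(charToRaw("abc")),
                   "900150983cd24fb0d6963f7d28e17f72")
  expect_identical(md5_hex(charToRaw("message digest")),
                   "f96b697d7cb7938d525a2f31aaf161d0")
})

test_that("md5_hex agrees with an independent MD5 oracle on bulk input", {
  content <- raw(1024 * 1024)  # 1 MiB of 0x00
  tmp <- withr::local_tempfile()
  writeBin(content, tmp)
  expect_identical(md5_hex(content), unname(tools::md5sum(tmp)))
  # and identically when streamed from the file itself
  expect_identical(md5_hex(tmp), unname(tools::md5sum(tmp)))
})

test_that("multipart_etag implements the digest-of-digests construction", {
  # two exact chunks: md5(raw_md5(c1) || raw_md5(c2)), suffix -2
  c1 <- charToRaw("abcd"); c2 <- charToRaw("efgh")
  blob <- c(s3fixity:::hex_to_raw(md5_hex(c1)),
            s3fixity:::hex_to_raw(md5_hex(c2)))
  expected <- md5_hex(blob)
  got <- multipart_etag(c(c1, c2), chunk_size_bytes = 4)
  expect_identical(got$digest_hex, expected)
  expect_identical(got$part_count, 2L)

  # content shorter than one chunk reduces to md5hex(raw_md5(content))-1
  short <- charToRaw("xyz")
  got1 <- multipart_etag(short, chunk_size_bytes = 1024)
  expect_identical(format(got1),
                   paste0(md5_hex(s3fixity:::hex_to_raw(md5_hex(short))), "-1"))

  # empty stream: one empty part
  got0 <- multipart_etag(raw(0), chunk_size_bytes = 1024)
  expect_identical(got0$part_count, 1L)

  expect_error(multipart_etag(raw(3), chunk_size_bytes = 0), "positive")
})

test_that("multipart part count is ceil(max(size, 1) / chunk_size)", {
  set.seed(11)
  for (chunk in c(7, 64, 1000)) {
    for (size in c(0, 1, chunk - 1, chunk, chunk + 1, 2 * chunk,
                   3 * chunk + 5)) {
      got <- multipart_etag(as.raw(sample.int(256, size, replace = TRUE) - 1),
                            chunk_size_bytes = chunk)
      expect_identical(got$part_count,
                       as.integer(ceiling(max(size, 1) / chunk)),
                       info = sprintf("size=%d chunk=%d", size, chunk))
    }
  }
})

test_that("multipart and whole-file digests agree with the independent oracle", {
  set.seed(101)
  tmp_root <- withr::local_tempdir()
  for (chunk in c(1024, 4096)) {
    policy <- chunking_policy(chunk, chunk)
    for (i in 1:40) {
      size <- sample.int(3 * chunk + 1, 1) - 1  # 0 .. 3*chunk
      path <- file.path(tmp_root, sprintf("c%d_i%d.bin", chunk, i))
      writeBin(as.raw(sample.int(256, size, replace = TRUE) - 1), path)
      got <- compute_etag_for_file(path, policy)
      want <- parse_etag(s3fixity:::oracle_etag_string(path, policy))
      expect_true(etags_equal(got$etag, want),
                  info = sprintf("size=%d chunk=%d", size, chunk))
      unlink(path)
    }
  }
})

test_that("digests are independent of the read-buffer size", {
  set.seed(5)
  content <- as.raw(sample.int(256, 2500, replace = TRUE) - 1)
  tmp <- withr::local_tempfile()
  writeBin(content, tmp)
  chunk <- 1024
  tags <- lapply(c(1L, 7L, 4096L, chunk), function(buf) {
    multipart_etag(tmp, chunk_size_bytes = chunk, buffer_size = buf)
  })
  for (t in tags[-1]) expect_true(etags_equal(tags[[1]], t))
})

test_that("file-size dispatch follows the 8 MB rule (scaled policy)", {
  policy <- kb_policy(1024)
  root <- withr::local_tempdir()
  sizes <- c(a = 5, b = 1023, c = 1024, d = 1025, e = 2 * 1024 + 3)
  for (nm in names(sizes)) {
    writeBin(as.raw(rep(1L, sizes[[nm]])), file.path(root, nm))
  }
  expect_null(compute_etag_for_file(file.path(root, "a"), policy)$etag$part_count)
  expect_null(compute_etag_for_file(file.path(root, "b"), policy)$etag$part_count)
  # exactly at the threshold: multipart with one part
  expect_identical(
    compute_etag_for_file(file.path(root, "c"), policy)$etag$part_count, 1L)
  expect_identical(
    compute_etag_for_file(file.path(root, "d"), policy)$etag$part_count, 2L)
  expect_identical(
    compute_etag_for_file(file.path(root, "e"), policy)$etag$part_count, 3L)
})

test_that("default 8 MiB policy dispatches correctly at the boundary", {
  policy <- chunking_policy()
  root <- withr::local_tempdir()
  below <- file.path(root, "below"); at <- file.path(root, "at")
  writeBin(raw(8 * 1024 * 1024 - 1), below)
  writeBin(raw(8 * 1024 * 1024), at)
  expect_null(compute_etag_for_file(below, policy)$etag$part_count)
  expect_identical(compute_etag_for_file(at, policy)$etag$part_count, 1L)
})

test_that("compute_etag_for_file rejects missing files and directories", {
  root <- withr::local_tempdir()
  expect_error(compute_etag_for_file(file.path(root, "nope")),
               "does not exist")
  expect_error(compute_etag_for_file(root), "directory")
})

test_that("any single-byte flip changes the computed ETag", {
  set.seed(2024)
  root <- withr::local_tempdir()
  policy <- kb_policy(256)
  for (i in 1:100) {
    size <- sample.int(3 * 256, 1)
    path <- file.path(root, "probe.bin")
    writeBin(as.raw(sample.int(256, size, replace = TRUE) - 1), path)
    before <- compute_etag_for_file(path, policy)$etag
    corrupt_file(root, "probe.bin", "flip-byte", seed = i)
    after <- compute_etag_for_file(path, policy)$etag
    expect_false(etags_equal(before, after), info = paste("case", i))
    unlink(path)
  }
})
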