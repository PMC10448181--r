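---
title: "Verifying dataset fixity on S3: the ETag model behind s3fixity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying dataset fixity on S3: the ETag model behind s3fixity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(s3fixity)
```

## The problem

Biomedical datasets routinely span hundreds of gigabytes across hundreds
of files, and they move: sequencing cores upload to S3 buckets,
collaborators sync them back down, archives mirror them. A transfer that
completes is not a transfer that succeeded — packet loss and write faults
can alter bytes silently. The classical fixity answer is a checksum
manifest, and S3 in fact maintains one for free: every object carries an
**ETag**. `s3fixity` turns that server-side metadata into an end-to-end
integrity check: recompute each local file's ETag with the same algorithm
the server used, fetch the bucket's metadata once, and compare.

## The ETag model

For an object stored by a simple PUT, the ETag is the MD5 of its bytes.
For an object stored by a **multipart upload** the server never sees the
whole byte stream at once; each part is hashed separately, and the final
tag is

$$\mathrm{ETag} = \mathrm{MD5}\big(d_1 \,\|\, d_2 \,\|\, \cdots \,\|\, d_N\big)\texttt{-}N,$$

where $d_i$ is the raw 16-byte MD5 digest of part $i$ and $N$ the part
count. Whether a file goes multipart is decided by the transfer tool, not
the server: the AWS CLI transfer commands switch at
`multipart_threshold = 8` MB and cut `multipart_chunksize = 8` MB parts.
A local re-computation therefore reproduces the remote tag exactly as
long as the upload used those defaults — which is the regime this package
(and its verification guarantee) assumes. Two further assumptions are
inherited from the ETag mechanism itself: objects must be plaintext or
SSE-S3 encrypted (SSE-C/SSE-KMS ETags are not MD5-based), and an object
rewritten through the console may carry a suffix-less plain MD5 even when
large — such files are reported as mismatches rather than silently
re-chunked, because guessing the remote chunk geometry would dilute the
guarantee into "some chunking matches".

Comparison is structural: digests (normalized to lowercase, since JSON
dialects differ in casing) *and* part counts must match. A multipart tag
never equals a single-part tag on the same digest.

## Parameters that matter

* `threshold_bytes` (default `8 * 1024 * 1024`): size at or above which a
  file is hashed as multipart. "8 MB" is interpreted in the transfer
  manager's units as 8 MiB = 8,388,608 bytes. A file of *exactly* the
  threshold is treated as multipart (`>=`), matching AWS transfer-manager
  behaviour; the boundary is exercised explicitly in the tests.
* `chunk_size_bytes` (default 8 MiB): the part size. The command line
  exposes a single `--chunk-size` override that sets both values, because
  the upstream defaults tie them together; overriding is how the test
  suite exercises full multipart logic on kilobyte files instead of
  multi-gigabyte ones.
* `buffer_size` (64 KiB default): the read granularity of the streaming
  hasher. It never affects the digest — a property the suite checks with
  buffers of 1, 7, 4096 and one-chunk bytes — and only bounds memory.

Degenerate inputs are made total rather than erroneous: an empty file
below the threshold hashes to the well-known empty-content MD5, and an
empty stream forced through the multipart path yields one empty part and
a `-1` suffix. Part counts always equal `ceiling(max(size, 1) / chunk)`.

## One logical listing

The bucket side of the comparison comes from a single logical
`list-objects` query per run — deliberately frugal: one metadata query
regardless of dataset size, no per-file HEAD requests. Endpoints cap
listing pages at 1,000 objects, so "one query" is interpreted as one
logical enumeration whose continuation pages belong to the same query;
the mock backend counts both and the tests pin the logical count at one.
Live access goes through the `aws` CLI (with `--output json` requested
explicitly, so the user's configured output format is irrelevant); the
offline `--manifest` mode consumes a saved `list-objects` JSON document
instead and skips the credential check entirely. Both `list-objects` and
`list-objects-v2` response shapes are accepted; fields beyond
`Key`/`ETag`/`Size`/`LastModified` are carried along untouched and play
no role in verification.

## Verdicts and run semantics

Local files are mapped to bucket keys by their `/`-separated path
relative to the verification root — exactly the key a
`sync local_folder/ s3://bucket/` upload assigns. Matching is on the full
relative path, not the basename, which would be ambiguous in nested
trees. Each discovered regular file receives exactly one of three
verdicts (`VERIFIED`, `MISSING_REMOTE`, `ETAG_MISMATCH`), so the three
counts always partition the discovered-file count; warnings and
mismatches never stop the run, only broken preconditions (unreadable
root, denied bucket, bad arguments) do, before any checksum work.
Symbolic links are skipped with a warning (a sync upload would have
followed or skipped them depending on flags; verifying link targets
twice risks double counting), hidden files are included, and remote
objects with no local counterpart are reported as an informational count
only — verification is local-to-remote directed, and the reverse
direction is covered by verifying a downloaded copy, which the suite
checks gives identical verdicts. Exit codes 0/1/2 (all verified /
integrity findings / could not run) let batch callers distinguish the
three outcomes; they are this package's own convention.

Every event is printed once and appended, byte-identical and in order, to
`logs/<bucket>.S3_integrity_log.<YYYY.MM.DD-HH.MM.SS>.txt`; the folder is
created on demand and each run opens a fresh file (local time, injectable
clock for deterministic tests). The mismatch line is a fixed template —
`ERROR: local and remote ETag numbers for the file '<name>' do not
match.` — so downstream tooling can grep for it.

## What the synthetic fixtures emulate — and what they do not

The generator (`fixture_spec()`, `generate_tree()`, `oracle_manifest()`,
`corrupt_file()`) stands in for a real upload cycle. Trees are
deterministic in `(entries, seed)`, with per-file bytes derived from a
mix of the seed and the key, and sizes chosen to straddle every dispatch
boundary: 0, 1, chunk − 1, chunk, chunk + 1, and several multiples. The
manifest side is computed by an **independent oracle** that shares no
code with the verification engine — it reads each file whole, slices it
in memory, and hashes with base R's `tools::md5sum()` on temporary files,
versus the engine's streamed OpenSSL MD5. Agreement between the two
paths, across random contents and chunk sizes, is the package's core
correctness evidence; a bug in either path would have to be mirrored
exactly in the other to go unseen.

Fixtures default to a 1 KiB threshold/chunk so multipart logic runs on
kilobyte files; the genuine 8 MiB boundary is covered by a small number
of slower tests on ~8 MiB files. Problem sizes throughout are desk-scale
choices: 200 random contents for oracle equivalence, 50 randomized trees
of 5–40 files for round-trip soundness and corruption detection, 100
sampled single-byte flips for corruption sensitivity. What passing these
tests shows is that the algorithm and its plumbing are correct; what they
cannot show is behaviour against a live S3 endpoint (authentication,
eventual consistency, truncated listings beyond the mocked pagination) or
on multi-gigabyte files, where only the arithmetic, not the code path,
differs. `LastModified` in oracle manifests is a fixed constant;
verification never reads it.

## Known limitations

* Only MD5-based ETags are verifiable: console uploads with non-default
  chunking, SSE-C/SSE-KMS objects, and the newer SHA-based checksum modes
  fall outside the model (the first is reported as a mismatch, honestly).
* The log-folder name follows the observed artifact convention (`logs/`)
  where the prose description of the original workflow also mentions
  `log/`; one had to be chosen.
* Verification trusts the bucket listing: a manifest captured after a
  corrupting upload verifies the corruption as "correct". Fixity is
  evidence of faithful transfer, not of the sanity of what was sent.
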