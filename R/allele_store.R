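# Exact-match allele indexes built from VCF files.
#
# Coordinate convention: everything user-facing is 0-based (start = offset
# of the first reference base), following the GA4GH style. VCF POS (1-based)
# is converted once, at ingest/normalization time, and nowhere else.

## ---- AlleleKey ------------------------------------------------------------

#' Normalize an allele to its canonical key
#'
#' Builds the canonical identity of an allele: assembly, contig, 0-based
#' start, reference bases and alternate bases. Shared trailing bases are
#' trimmed first, then shared leading bases (advancing `start` by one per
#' trimmed leading base), so that e.g. `CAG>CTG` at 1-based position 100
#' canonicalizes to `A>T` at 0-based start 100. At least one base is always
#' retained on each side. A leading `"chr"` on the contig name is stripped
#' for dialect tolerance.
#'
#' @param chromosome Contig name (with or without a `"chr"` prefix).
#' @param pos_1based 1-based position of the first reference base, as in a
#'   VCF `POS` column.
#' @param ref Reference bases (`[ACGT]+`, case-insensitive).
#' @param alt Alternate bases (`[ACGT]+`, case-insensitive).
#' @param assembly_id Genome assembly label, e.g. `"GRCh37"`.
#' @return An object of class `allele_key`: a list with fields
#'   `assembly_id`, `chromosome`, `start` (0-based), `ref_bases`,
#'   `alt_bases`.
#' @examples
#' normalize_allele("13", 32936732, "G", "C", "GRCh37")
#' normalize_allele("1", 100, "CAG", "CTG", "GRCh37") # trims to A>T at 100
#' @export
normalize_allele <- function(chromosome, pos_1based, ref, alt, assembly_id) {
  chromosome <- strip_chr(as.character(chromosome))
  if (!nzchar(chromosome)) {
    beacon_abort("chromosome must be a nonempty contig name",
                 "beacon_unsupported_allele")
  }
  pos_1based <- as.numeric(pos_1based)
  if (length(pos_1based) != 1L || is.na(pos_1based) || pos_1based < 1) {
    beacon_abort("position must be a 1-based coordinate >= 1",
                 "beacon_unsupported_allele")
  }
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  for (b in c(ref, alt)) {
    if (!nzchar(b) || grepl("[^ACGT]", b)) {
      beacon_abort(
        sprintf("unsupported allele %s>%s: bases must match [ACGT]+ (symbolic alleles, breakends and N are not supported)",
                ref, alt),
        "beacon_unsupported_allele")
    }
  }

  # Trim shared suffix, then shared prefix; keep >= 1 base on each side.
  rb <- strsplit(ref, "")[[1]]
  ab <- strsplit(alt, "")[[1]]
  while (length(rb) > 1L && length(ab) > 1L &&
         rb[length(rb)] == ab[length(ab)]) {
    rb <- rb[-length(rb)]
    ab <- ab[-length(ab)]
  }
  start <- pos_1based - 1  # 0-based from here on
  while (length(rb) > 1L && length(ab) > 1L && rb[1L] == ab[1L]) {
    rb <- rb[-1L]
    ab <- ab[-1L]
    start <- start + 1
  }
  ref <- paste(rb, collapse = "")
  alt <- paste(ab, collapse = "")
  if (identical(ref, alt)) {
    beacon_abort(
      sprintf("degenerate allele: ref and alt are identical (%s) after trimming", ref),
      "beacon_degenerate_allele")
  }
  structure(
    list(assembly_id = as.character(assembly_id), chromosome = chromosome,
         start = start, ref_bases = ref, alt_bases = alt),
    class = "allele_key")
}

strip_chr <- function(x) sub("^chr", "", x)

# Internal string form used as the hash key inside a dataset index
# (assembly is held at index level, not per key).
key_string <- function(key) {
  paste(key$chromosome, format(key$start, scientific = FALSE, trim = TRUE),
        key$ref_bases, key$alt_bases, sep = ":")
}

#' @export
print.allele_key <- function(x, ...) {
  cat(sprintf("<allele_key> %s %s:%s %s>%s\n", x$assembly_id, x$chromosome,
              format(x$start, scientific = FALSE), x$ref_bases, x$alt_bases))
  invisible(x)
}

## ---- DatasetIndex ---------------------------------------------------------

new_dataset_index <- function(dataset_id, assembly_id, sample_total = NULL,
                              source_path = NA_character_) {
  structure(
    list(dataset_id = dataset_id, assembly_id = assembly_id,
         records = new.env(parent = emptyenv(), hash = TRUE),
         sample_total = sample_total, source_path = source_path),
    class = "dataset_index")
}

index_put <- function(index, record) {
  ks <- key_string(record$key)
  existing <- index$records[[ks]]
  if (!is.null(existing)) {
    # Duplicate normalized key: merge by summing counts.
    warning(sprintf("duplicate allele %s in dataset '%s': merging counts",
                    ks, index$dataset_id), call. = FALSE)
    record$allele_count <- existing$allele_count + record$allele_count
    record$call_count <- sum_or_null(existing$call_count, record$call_count)
    record$sample_count <- sum_or_null(existing$sample_count, record$sample_count)
    record$extra_metadata <- modifyList(existing$extra_metadata,
                                        record$extra_metadata)
  }
  assign(ks, record, envir = index$records)
  invisible(index)
}

sum_or_null <- function(a, b) {
  if (is.null(a) || is.null(b)) NULL else a + b
}

#' Number of allele records held by a dataset index
#'
#' @param index A `dataset_index`.
#' @return Integer record count.
#' @export
record_count <- function(index) {
  stopifnot(inherits(index, "dataset_index"))
  length(ls(index$records, all.names = TRUE))
}

#' @export
print.dataset_index <- function(x, ...) {
  cat(sprintf("<dataset_index> '%s' (%s): %d alleles, %s samples\n",
              x$dataset_id, x$assembly_id, record_count(x),
              if (is.null(x$sample_total)) "?" else x$sample_total))
  invisible(x)
}

# Observation records are plain lists with class "observation_record":
# key, allele_count (>= 1), call_count (NULL when unknown), sample_count
# (NULL when unknown), extra_metadata (named character list from INFO).
new_observation_record <- function(key, allele_count, call_count = NULL,
                                   sample_count = NULL,
                                   extra_metadata = list()) {
  if (allele_count < 1) {
    beacon_abort("allele_count must be >= 1", "beacon_domain_error")
  }
  if (!is.null(call_count) && call_count < allele_count) {
    beacon_abort("call_count must be >= allele_count", "beacon_domain_error")
  }
  structure(list(key = key, allele_count = allele_count,
                 call_count = call_count, sample_count = sample_count,
                 extra_metadata = extra_metadata),
            class = "observation_record")
}

## ---- VCF ingestion --------------------------------------------------------

#' Build an exact-match allele index from a VCF file
#'
#' Reads a VCF (plain or gzip/bgzip compressed), splits multi-allelic lines
#' into one record per ALT allele, normalizes each allele with
#' [normalize_allele()], and indexes the resulting observation records.
#' Alt-allele counts are taken from `INFO/AC` and `INFO/AN` when present;
#' otherwise they are recomputed from the `GT` genotype columns; otherwise
#' they are recorded as a bare presence (allele_count 1, call_count
#' unknown). Symbolic ALT alleles (`<DEL>`, breakends, `*`, alleles
#' containing `N`) are skipped with a warning, never a crash. Duplicate
#' normalized keys are merged by summing counts.
#'
#' @param path Path to a VCF v4.x file.
#' @param dataset_id Label for the dataset served from this file.
#' @param assembly_id Genome assembly the coordinates refer to.
#' @return A `dataset_index`.
#' @export
ingest_vcf <- function(path, dataset_id, assembly_id) {
  if (!file.exists(path)) {
    beacon_abort(sprintf("VCF file not found: %s", path), "beacon_ingest_error")
  }
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)),
    error = function(e) {
      beacon_abort(sprintf("cannot parse %s as VCF: %s", path,
                           conditionMessage(e)), "beacon_ingest_error")
    })
  fix <- v@fix
  gt <- v@gt
  n_samples <- if (is.null(gt) || ncol(gt) <= 1L) 0L else ncol(gt) - 1L
  index <- new_dataset_index(dataset_id, assembly_id,
                             sample_total = if (n_samples > 0L) n_samples else NULL,
                             source_path = path)
  if (nrow(fix) == 0L) return(index)

  for (i in seq_len(nrow(fix))) {
    chrom <- fix[i, "CHROM"]
    pos <- suppressWarnings(as.numeric(fix[i, "POS"]))
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (is.na(pos) || is.na(ref) || length(alts) == 0L) {
      beacon_abort(sprintf("garbled VCF record at %s line %d (site %s:%s)",
                           path, i, chrom, fix[i, "POS"]),
                   "beacon_ingest_error")
    }
    info <- parse_info(fix[i, "INFO"])
    ac <- info_numeric(info, "AC")
    an <- info_numeric(info, "AN")
    gt_counts <- NULL
    if ((is.null(ac) || is.null(an)) && n_samples > 0L) {
      gt_counts <- count_gt_alleles(gt[i, -1L], n_alt = length(alts))
    }
    extra <- info[setdiff(names(info), c("AC", "AN"))]

    for (j in seq_along(alts)) {
      key <- tryCatch(
        normalize_allele(chrom, pos, ref, alts[j], assembly_id),
        beacon_error = function(e) {
          warning(sprintf("skipping unsupported ALT '%s' at %s:%s in %s: %s",
                          alts[j], chrom, fix[i, "POS"], path,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (is.null(key)) next
      counts <- resolve_counts(ac, an, gt_counts, j)
      if (is.null(counts$allele_count) || counts$allele_count < 1) next  # ALT never observed
      index_put(index, new_observation_record(
        key, counts$allele_count, counts$call_count,
        sample_count = counts$sample_count, extra_metadata = extra))
    }
  }
  index
}

# INFO field "AC=3,5;AN=200;DB" -> named list(AC="3,5", AN="200", DB="")
parse_info <- function(info) {
  if (is.na(info) || info == "." || !nzchar(info)) return(list())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, function(p) if (length(p) > 1L) paste(p[-1L], collapse = "=") else "")
  names(out) <- vapply(kv, `[[`, "", 1L)
  out
}

info_numeric <- function(info, field) {
  if (is.null(info[[field]])) return(NULL)
  x <- suppressWarnings(as.numeric(strsplit(info[[field]], ",", fixed = TRUE)[[1]]))
  if (anyNA(x)) NULL else x
}

# Count alt-allele copies per ALT index and total called copies from GT
# strings ("0/1", "1|2", "./.", NA). "." is missing and excluded from AN.
count_gt_alleles <- function(gts, n_alt) {
  gts <- gts[!is.na(gts)]
  alleles <- unlist(strsplit(sub(":.*$", "", gts), "[/|]"))
  alleles <- alleles[alleles != "." & nzchar(alleles)]
  idx <- suppressWarnings(as.integer(alleles))
  idx <- idx[!is.na(idx)]
  # carriers per ALT: individuals with >= 1 copy of that ALT
  carrier <- integer(n_alt)
  for (j in seq_len(n_alt)) {
    carrier[j] <- sum(vapply(gts, function(g) {
      a <- strsplit(sub(":.*$", "", g), "[/|]")[[1]]
      any(a == as.character(j))
    }, logical(1L)))
  }
  list(ac = vapply(seq_len(n_alt), function(j) sum(idx == j), 0),
       an = length(idx), carriers = carrier)
}

# AC/AN from INFO take precedence over GT-derived counts (producer-asserted
# counts are respected); GT additionally yields per-ALT carrier counts.
resolve_counts <- function(ac, an, gt_counts, alt_index) {
  allele_count <- NULL
  call_count <- NULL
  sample_count <- NULL
  if (!is.null(ac) && length(ac) >= alt_index) allele_count <- ac[alt_index]
  if (!is.null(an)) call_count <- an[1L]
  if (!is.null(gt_counts)) {
    if (is.null(allele_count)) allele_count <- gt_counts$ac[alt_index]
    if (is.null(call_count)) call_count <- gt_counts$an
    sample_count <- gt_counts$carriers[alt_index]
    if (sample_count == 0L) sample_count <- NULL
  }
  if (is.null(allele_count)) allele_count <- 1  # sites-only VCF: bare presence
  if (!is.null(call_count) && call_count < allele_count) call_count <- NULL
  list(allele_count = allele_count, call_count = call_count,
       sample_count = sample_count)
}

## ---- Lookup & frequency ---------------------------------------------------

#' Look up an allele in a dataset index
#'
#' Exact-match semantics only: the key must come from [normalize_allele()].
#' An absent allele returns `NULL`, never an error. Querying an index with
#' a key from a different genome assembly raises a typed
#' `beacon_assembly_mismatch` error rather than silently answering "no".
#'
#' @param index A `dataset_index`.
#' @param key An `allele_key`.
#' @return The `observation_record`, or `NULL` when the allele is absent.
#' @export
lookup <- function(index, key) {
  stopifnot(inherits(index, "dataset_index"), inherits(key, "allele_key"))
  if (!identical(key$assembly_id, index$assembly_id)) {
    beacon_abort(
      sprintf("assembly mismatch: query is %s but dataset '%s' is %s",
              key$assembly_id, index$dataset_id, index$assembly_id),
      "beacon_assembly_mismatch")
  }
  index$records[[key_string(key)]]
}

#' Allele frequency of an observation record
#'
#' @param record An `observation_record`.
#' @return `allele_count / call_count` when the total called-allele count is
#'   known, `NULL` otherwise.
#' @export
allele_frequency <- function(record) {
  if (is.null(record) || is.null(record$call_count)) return(NULL)
  record$allele_count / record$call_count
}

# All keys currently held by an index, as allele_key objects (used by the
# linear-scan oracle in tests and by index persistence).
index_keys <- function(index) {
  lapply(ls(index$records, all.names = TRUE), function(ks) {
    index$records[[ks]]$key
  })
}
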