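# Versioned single-file JSON persistence for dataset indexes, so a beacon
# lit from large VCFs does not re-parse them on every start. The CLI
# rebuilds an index automatically when its source VCF is newer.

INDEX_FORMAT_VERSION <- 1L

#' Persist a dataset index to a JSON file
#'
#' @param index A `dataset_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
index_save <- function(index, path) {
  stopifnot(inherits(index, "dataset_index"))
  recs <- lapply(ls(index$records, all.names = TRUE), function(ks) {
    r <- index$records[[ks]]
    out <- list(chromosome = r$key$chromosome, start = r$key$start,
                ref_bases = r$key$ref_bases, alt_bases = r$key$alt_bases,
                allele_count = r$allele_count)
    if (!is.null(r$call_count)) out$call_count <- r$call_count
    if (!is.null(r$sample_count)) out$sample_count <- r$sample_count
    if (length(r$extra_metadata) > 0L) out$extra_metadata <- r$extra_metadata
    out
  })
  jsonlite::write_json(
    list(format_version = INDEX_FORMAT_VERSION,
         dataset_id = index$dataset_id, assembly_id = index$assembly_id,
         sample_total = index$sample_total, source_path = index$source_path,
         record_count = length(recs), records = recs),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a persisted dataset index
#'
#' @param path A file written by [index_save()].
#' @return A `dataset_index`.
#' @export
index_load <- function(path) {
  x <- jsonlite::read_json(path)
  if (is.null(x$format_version) || x$format_version > INDEX_FORMAT_VERSION) {
    beacon_abort(sprintf("unsupported index format in %s", path),
                 "beacon_ingest_error")
  }
  index <- new_dataset_index(x$dataset_id, x$assembly_id,
                             sample_total = x$sample_total,
                             source_path = x$source_path %||% NA_character_)
  for (r in x$records) {
    key <- structure(list(assembly_id = x$assembly_id,
                          chromosome = r$chromosome, start = r$start,
                          ref_bases = r$ref_bases, alt_bases = r$alt_bases),
                     class = "allele_key")
    index_put(index, new_observation_record(
      key, r$allele_count, r$call_count, r$sample_count,
      extra_metadata = r$extra_metadata %||% list()))
  }
  index
}
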