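## Testing units: non-overlapping consecutive windows of k post-QC variants.

#' Partition variants into non-overlapping windows of k consecutive variants
#'
#' Windows are defined on variant order, not base-pair spans: per
#' chromosome, consecutive chunks of `k` variants; a final partial chunk
#' is retained as a short window and no window spans a chromosome
#' boundary. The total window count is the sum over chromosomes of
#' `ceiling(n_chrom / k)`.
#'
#' @param variants data.frame of post-QC variants sorted by
#'   (chromosome, position) with columns `chrom`, `pos`, `ref`, `alt`.
#' @param k window size in variants (default 10).
#' @return data.frame with one row per window: `window_id`, `chrom`,
#'   `vidx_start`/`vidx_end` (column indices into the variant set),
#'   `first_snv`, `last_snv` (`chrom:pos:ref:alt`), `pos_start`,
#'   `pos_end`, `n_variants`.
#' @export
build_windows <- function(variants, k = 10) {
  stopifnot(k >= 1, is.data.frame(variants))
  if (nrow(variants) == 0L)
    return(data.frame(window_id = character(0), chrom = character(0),
                      vidx_start = integer(0), vidx_end = integer(0),
                      first_snv = character(0), last_snv = character(0),
                      pos_start = integer(0), pos_end = integer(0),
                      n_variants = integer(0)))
  co <- match(variants$chrom, unique(variants$chrom))
  if (is.unsorted(co) ||
      any(diff(variants$pos) < 0 & diff(co) == 0))
    stop("variants must be sorted by (chromosome, position)")
  key <- variant_key(variants)
  out <- lapply(split(seq_len(nrow(variants)), co), function(idx) {
    nb <- ceiling(length(idx) / k)
    starts <- (seq_len(nb) - 1L) * k + 1L
    ends <- pmin(starts + k - 1L, length(idx))
    data.frame(chrom = variants$chrom[idx[1]],
               vidx_start = idx[starts], vidx_end = idx[ends],
               stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, out)
  rownames(w) <- NULL
  data.frame(window_id = sprintf("W%05d", seq_len(nrow(w))),
             chrom = w$chrom,
             vidx_start = w$vidx_start, vidx_end = w$vidx_end,
             first_snv = key[w$vidx_start], last_snv = key[w$vidx_end],
             pos_start = variants$pos[w$vidx_start],
             pos_end = variants$pos[w$vidx_end],
             n_variants = w$vidx_end - w$vidx_start + 1L,
             stringsAsFactors = FALSE)
}

#' Write the window table as TSV
#' @param windows a [build_windows()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path) {
  write_tsv(windows[c("window_id", "chrom", "first_snv", "last_snv",
                      "n_variants")], path)
}
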