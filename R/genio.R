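## Data model and file IO: genotype matrices, pedigrees, VCF/PED/TSV.

#' Construct a genotype matrix
#'
#' The package's central container: an ALT-allele dosage matrix (samples in
#' rows, variants in columns; entries 0/1/2 or `NA` for missing) together
#' with per-variant metadata and the positions of half-called genotypes
#' (one missing allele out of two, e.g. `./1`).
#'
#' @param dosage integer matrix, samples x variants; `NA` = missing call.
#'   Row names are sample ids.
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` and optionally `id`, `multiallelic`. One row per column of
#'   `dosage`.
#' @param half_calls two-column integer matrix of (sample index, variant
#'   index) pairs flagging half-called entries; these entries must be `NA`
#'   in `dosage`.
#' @param sort sort variants by (chromosome in order of first appearance,
#'   position)? Default `TRUE`.
#' @return an object of class `genotype_matrix` with elements `dosage`,
#'   `variants`, `half_calls`.
#' @export
genotype_matrix <- function(dosage, variants, half_calls = NULL, sort = TRUE) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            nrow(variants) == ncol(dosage))
  if (is.null(rownames(dosage)))
    stop("dosage must have sample ids as row names")
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (any(variants$pos < 1L)) stop("positions must be 1-based (pos >= 1)")
  if (any(variants$ref == variants$alt))
    stop("ref and alt alleles must differ")
  if (is.null(variants$id)) variants$id <- NA_character_
  if (is.null(variants$multiallelic))
    variants$multiallelic <- grepl(",", variants$alt, fixed = TRUE)
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must lie in {0, 1, 2, NA}")
  if (is.null(half_calls))
    half_calls <- matrix(integer(0), ncol = 2)
  half_calls <- matrix(as.integer(half_calls), ncol = 2)
  if (nrow(half_calls) && any(!is.na(dosage[half_calls])))
    stop("half-called entries must have missing dosage")
  if (sort) {
    ord <- order(match(variants$chrom, unique(variants$chrom)), variants$pos)
    if (!identical(ord, seq_len(nrow(variants)))) {
      dosage <- dosage[, ord, drop = FALSE]
      variants <- variants[ord, , drop = FALSE]
      if (nrow(half_calls))
        half_calls[, 2] <- match(half_calls[, 2], ord)
    }
  }
  rownames(variants) <- NULL
  colnames(dosage) <- variant_key(variants)
  structure(list(dosage = dosage, variants = variants,
                 half_calls = half_calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d half-calls, %d chromosome%s)\n",
              nrow(x$dosage), ncol(x$dosage), nrow(x$half_calls),
              length(unique(x$variants$chrom)),
              if (length(unique(x$variants$chrom)) == 1L) "" else "s"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Canonical chrom:pos:ref:alt key for variants
#' @param variants data.frame with chrom, pos, ref, alt columns.
#' @return character vector of keys.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Subset a genotype matrix
#'
#' @param G a [genotype_matrix()].
#' @param samples sample ids or indices (optional).
#' @param variants variant column indices or logical mask (optional).
#' @return a `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(G, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(G$dosage)) else
    if (is.character(samples)) match(samples, rownames(G$dosage)) else samples
  if (anyNA(si)) stop("unknown sample id(s)")
  vi <- if (is.null(variants)) seq_len(ncol(G$dosage)) else
    which(seq_len(ncol(G$dosage)) %in% seq_len(ncol(G$dosage))[variants])
  hc <- G$half_calls
  if (nrow(hc)) {
    keep <- hc[, 1] %in% si & hc[, 2] %in% vi
    hc <- hc[keep, , drop = FALSE]
    hc[, 1] <- match(hc[, 1], si)
    hc[, 2] <- match(hc[, 2], vi)
  }
  genotype_matrix(G$dosage[si, vi, drop = FALSE],
                  G$variants[vi, , drop = FALSE], hc, sort = FALSE)
}

## ---------------------------------------------------------------- VCF ----

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses diploid GT fields only. `./.` becomes missing; genotypes with
#' exactly one missing allele (`./1`, `0/.`) become missing and are flagged
#' as half-calls; records with a comma in ALT are retained but flagged
#' multiallelic (the QC cascade removes them). Phased (`|`) and unphased
#' (`/`) separators are treated identically. Positions stay 1-based.
#'
#' @param path VCF file (plain or gzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("VCF parse error in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  nvar <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  if (nvar == 0L)
    return(genotype_matrix(
      matrix(integer(0), nrow = length(samples), ncol = 0,
             dimnames = list(samples, NULL)),
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0))))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nvar)
  # map each distinct GT string once; VCF row numbers reported on error
  parsed <- parse_gt_strings(gt)
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                     NA_character_, fix[, "ID"]),
                         stringsAsFactors = FALSE)
  dos <- t(parsed$dosage)          # to samples x variants
  rownames(dos) <- samples
  half <- which(t(parsed$half), arr.ind = TRUE)
  dimnames(half) <- NULL
  genotype_matrix(dos, variants, half)
}

parse_gt_strings <- function(gt) {
  u <- unique(as.vector(gt))
  udos <- integer(length(u)); uhalf <- logical(length(u))
  for (k in seq_along(u)) {
    s <- u[k]
    if (is.na(s)) { udos[k] <- NA_integer_; next }
    g <- sub(":.*", "", s)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2L) {
      row <- which(gt == s, arr.ind = TRUE)[1, 1]
      stop(sprintf("non-diploid GT '%s' at VCF record %d", g, row),
           call. = FALSE)
    }
    miss <- al == "."
    if (all(miss)) {
      udos[k] <- NA_integer_
    } else if (any(miss)) {
      udos[k] <- NA_integer_; uhalf[k] <- TRUE
    } else {
      a <- suppressWarnings(as.integer(al))
      if (anyNA(a)) {
        row <- which(gt == s, arr.ind = TRUE)[1, 1]
        stop(sprintf("malformed GT '%s' at VCF record %d", g, row),
             call. = FALSE)
      }
      udos[k] <- sum(a > 0L)
    }
  }
  idx <- match(as.vector(gt), u)
  list(dosage = matrix(udos[idx], nrow = nrow(gt)),
       half = matrix(uhalf[idx], nrow = nrow(gt)))
}

#' Write a genotype matrix as VCF v4.2
#'
#' GT-only records; half-calls are emitted as `./1`, missing as `./.`.
#' A path ending in `.gz` is gzip-compressed.
#'
#' @param G a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  dos <- G$dosage
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(dos), ncol = ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- code[dos[ok] + 1L]
  if (nrow(G$half_calls)) gt[G$half_calls] <- "./1"
  v <- G$variants
  recs <- paste(v$chrom, v$pos, ifelse(is.na(v$id), ".", v$id), v$ref, v$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rvscan",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(dos)), collapse = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, recs), con)
  invisible(path)
}

## ---------------------------------------------------------- pedigree ----

#' Read a 6-column PED/FAM pedigree
#'
#' Columns: family id, individual id, father id, mother id, sex, phenotype.
#' Phenotype codes follow the PED dialect: 2 = affected (1), 1 = unaffected
#' (0), 0 or -9 = missing. Parent id "0" means unknown. Duplicate individual
#' ids are an error; unknown sex codes are kept with a warning.
#'
#' @param path whitespace-delimited PED/FAM file.
#' @return data.frame of class `rv_pedigree` with columns `fid`, `iid`,
#'   `pat`, `mat`, `sex`, `affected` (0/1/NA).
#' @export
read_pedigree <- function(path) {
  d <- read.table(path, header = FALSE, colClasses = "character",
                  col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  pedigree(d$fid, d$iid, d$pat, d$mat, as.integer(d$sex),
           pheno_to_affection(d$pheno))
}

pheno_to_affection <- function(x) {
  x <- gsub("−", "-", as.character(x))   # tolerate unicode minus
  out <- rep(NA_integer_, length(x))
  out[x == "2"] <- 1L
  out[x == "1"] <- 0L
  bad <- !(x %in% c("0", "-9", "1", "2"))
  if (any(bad)) stop("unknown phenotype code(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  out
}

#' Construct a pedigree table
#'
#' @param fid,iid,pat,mat,sex per-individual fields; parent ids `"0"` or
#'   `NA` mean unknown.
#' @param affected 0/1/NA affection status.
#' @return data.frame of class `rv_pedigree`.
#' @export
pedigree <- function(fid, iid, pat, mat, sex, affected) {
  d <- data.frame(fid = as.character(fid), iid = as.character(iid),
                  pat = as.character(pat), mat = as.character(mat),
                  sex = as.integer(sex), affected = as.integer(affected),
                  stringsAsFactors = FALSE)
  d$pat[d$pat %in% "0"] <- NA_character_
  d$mat[d$mat %in% "0"] <- NA_character_
  if (anyDuplicated(d$iid))
    stop("duplicate individual id(s): ",
         paste(unique(d$iid[duplicated(d$iid)]), collapse = ", "))
  self <- !is.na(d$pat) & d$pat == d$iid | !is.na(d$mat) & d$mat == d$iid
  if (any(self)) stop("individual listed as its own parent: ",
                      paste(d$iid[self], collapse = ", "))
  if (any(!d$sex %in% c(1L, 2L)))
    warning("unknown sex code(s) kept: ",
            paste(unique(d$sex[!d$sex %in% c(1L, 2L)]), collapse = ", "))
  class(d) <- c("rv_pedigree", "data.frame")
  d
}

#' Write a pedigree as 6-column PED (PHENO 1/2, missing -9)
#' @param ped an `rv_pedigree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(ped$fid, ped$iid,
                    ifelse(is.na(ped$pat), "0", ped$pat),
                    ifelse(is.na(ped$mat), "0", ped$mat),
                    ped$sex,
                    ifelse(is.na(ped$affected), -9L, ped$affected + 1L))
  write.table(out, path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ------------------------------------------------------------- tables ----

#' Read/write simple TSV tables used by the pipeline
#'
#' `read_af_table` expects columns `chrom`, `pos`, `ref`, `alt`, `AF_all`,
#' `AF_nfe` (a local stand-in for an external allele-frequency reference).
#' `read_phenotypes` expects `iid`, `affection`; `read_covariates` expects
#' `iid` plus any covariate columns.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_af_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c(chrom = "character"), check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "AF_all", "AF_nfe")
  if (!all(need %in% names(d)))
    stop("AF table must have columns: ", paste(need, collapse = ", "))
  d
}

#' @rdname read_af_table
#' @export
read_phenotypes <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c(iid = "character"))
  if (!all(c("iid", "affection") %in% names(d)))
    stop("phenotype table must have columns iid, affection")
  d
}

#' @rdname read_af_table
#' @export
read_covariates <- function(path) {
  read.table(path, header = TRUE, sep = "\t",
             colClasses = c(iid = "character"))
}

#' @rdname read_af_table
#' @param table data.frame to write.
#' @export
write_tsv <- function(table, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else path
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Double-precision columns (p-values, statistics) are written in
#' scientific notation with 17 significant digits so that reading the file
#' back reproduces the values exactly.
#'
#' @param table data.frame of per-window results.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  out <- table
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf("%.16e", out[[j]]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
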