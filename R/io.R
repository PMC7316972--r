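# Plain-text readers/writers for every emitted format. All write/read pairs
# round-trip exactly; coordinates follow the package convention (BED-like
# files 0-based half-open, VCF/TSV positions 1-based).

#' Write / read a cells x bins count table as CSV
#'
#' First column `barcode`, remaining columns one per bin (bin ids
#' `chrom:start-end`, 1-based inclusive).
#'
#' @param counts cells x bins matrix with dimnames.
#' @param path file path.
#' @return `readCountsCsv` returns the integer matrix.
#' @export
writeCountsCsv <- function(counts, path) {
  df <- data.frame(barcode = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' @rdname writeCountsCsv
#' @export
readCountsCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$barcode
  m
}

#' Write / read counts as MatrixMarket triplets
#'
#' Writes `<prefix>.mtx` plus `<prefix>.barcodes.txt` and `<prefix>.bins.txt`
#' label files.
#'
#' @param counts cells x bins matrix.
#' @param prefix path prefix.
#' @return `readCountsMtx` returns the dense integer matrix with labels.
#' @export
writeCountsMtx <- function(counts, prefix) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), paste0(prefix, ".mtx"))
  writeLines(rownames(counts), paste0(prefix, ".barcodes.txt"))
  writeLines(colnames(counts), paste0(prefix, ".bins.txt"))
}

#' @rdname writeCountsMtx
#' @export
readCountsMtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(readLines(paste0(prefix, ".barcodes.txt")),
                      readLines(paste0(prefix, ".bins.txt")))
  m
}

#' Write / read per-cell CNV calls as 6-column BED-like text
#'
#' Columns: chrom, start, end (0-based half-open), barcode, copy number,
#' confidence. Tab-separated, no header — the per-cell CNV call dialect of
#' droplet single-cell CNV pipelines.
#'
#' @param calls data.frame with those columns (e.g. `cnvSegments()`).
#' @param path file path.
#' @return `readCnvBed` returns the data.frame.
#' @export
writeCnvBed <- function(calls, path) {
  utils::write.table(calls[, c("chrom", "start", "end", "barcode", "copy",
                               "confidence")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' @rdname writeCnvBed
#' @export
readCnvBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "barcode",
                                        "copy", "confidence"))
  df$copy <- as.integer(df$copy)
  df
}

#' Write / read anomalous read pairs as BEDPE
#'
#' Standard 10 BEDPE columns (name carries the pair id, score the minimum
#' mapq) followed by `mapq1`, `mapq2`, `class`, `barcode` extension columns.
#'
#' @param pairs data.frame as produced by [simulateReadPairs()].
#' @param path file path.
#' @return `readBedpe` returns the data.frame.
#' @export
writeBedpe <- function(pairs, path) {
  out <- data.frame(pairs$chrom1, pairs$start1, pairs$end1,
                    pairs$chrom2, pairs$start2, pairs$end2,
                    pairs$name, pmin(pairs$mapq1, pairs$mapq2),
                    pairs$strand1, pairs$strand2,
                    pairs$mapq1, pairs$mapq2, pairs$class,
                    ifelse(is.na(pairs$barcode), ".", pairs$barcode))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' @rdname writeBedpe
#' @export
readBedpe <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom1", "start1", "end1", "chrom2",
                                        "start2", "end2", "name", "score",
                                        "strand1", "strand2", "mapq1",
                                        "mapq2", "class", "barcode"),
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "numeric", "numeric",
                                         "character", "numeric", "character",
                                         "character", "numeric", "numeric",
                                         "character", "character"))
  df$barcode[df$barcode == "."] <- NA_character_
  df$score <- NULL
  df
}

#' Write / read split reads as TSV
#'
#' Columns: read id, side-1 chrom/pos, side-2 chrom/pos (1-based breakend
#' coordinates).
#'
#' @param splits data.frame (`read`, `chrom1`, `pos1`, `chrom2`, `pos2`).
#' @param path file path.
#' @return `readSplitReads` returns the data.frame.
#' @export
writeSplitReads <- function(splits, path) {
  utils::write.table(splits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' @rdname writeSplitReads
#' @export
readSplitReads <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "character", "numeric"))
}

#' Write / read SNP allele counts as TSV
#'
#' Header TSV with `chrom`, `pos` (1-based), `ref`, `alt`, `refDepth`,
#' `altDepth`, `group`, `maf`.
#'
#' @param snps data.frame from [simulateAlleleCounts()].
#' @param path file path.
#' @return `readSnpTsv` returns the data.frame.
#' @export
writeSnpTsv <- function(snps, path) {
  utils::write.table(snps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' @rdname writeSnpTsv
#' @export
readSnpTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read SNP allele counts as a minimal VCF
#'
#' Sites-only VCFv4.2 with a single sample column carrying `GT:AD` (genotype
#' fixed to 0/1; AD = ref,alt depths) and the population MAF in INFO. The
#' reader parses exactly this dialect; general-purpose VCF readers parse the
#' output too.
#'
#' @param snps data.frame with `chrom`, `pos`, `ref`, `alt`, `refDepth`,
#'   `altDepth`, `maf`.
#' @param path file path.
#' @param sampleName sample column header.
#' @return `readSnpVcf` returns the data.frame (without `group`).
#' @export
writeSnpVcf <- function(snps, path, sampleName = "sample") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Population minor allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sampleName, sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tMAF=%.6f\tGT:AD\t0/1:%d,%d",
                  snps$chrom, as.integer(snps$pos), snps$ref, snps$alt,
                  snps$maf, as.integer(snps$refDepth), as.integer(snps$altDepth))
  writeLines(c(header, body), path)
}

#' @rdname writeSnpVcf
#' @export
readSnpVcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0)
    return(data.frame(chrom = character(), pos = numeric(), ref = character(),
                      alt = character(), refDepth = integer(),
                      altDepth = integer(), maf = numeric(),
                      stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  ad <- do.call(rbind, strsplit(sub("^[^:]*:", "", f[, 10]), ",", fixed = TRUE))
  data.frame(chrom = f[, 1], pos = as.numeric(f[, 2]), ref = f[, 4],
             alt = f[, 5],
             refDepth = as.integer(ad[, 1]), altDepth = as.integer(ad[, 2]),
             maf = as.numeric(sub("MAF=", "", f[, 8])),
             stringsAsFactors = FALSE)
}

#' Write a per-bin track as bedGraph
#'
#' @param values per-bin numeric values (`NA` bins skipped).
#' @param model the [GenomeModel-class] giving bin coordinates.
#' @param path file path.
#' @param name track name for the header line.
#' @export
writeBedgraph <- function(values, model, path, name = "track") {
  b <- model@bins
  keep <- is.finite(values)
  lines <- c(sprintf("track type=bedGraph name=\"%s\"", name),
             sprintf("%s\t%d\t%d\t%g", as.character(seqnames(b))[keep],
                     start(b)[keep] - 1L, end(b)[keep], values[keep]))
  writeLines(lines, path)
}
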