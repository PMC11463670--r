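#' Construct a count matrix
#'
#' Sparse features x cells non-negative integer counts with identifier lists,
#' used for both RNA (genes) and ATAC (peaks).
#'
#' @param values matrix-like, coerced to `dgCMatrix`.
#' @param feature_ids,cell_ids unique identifier vectors matching the dims.
#' @param modality `"rna"` or `"atac"`.
#' @return A `CountMatrix` (a `dgCMatrix` with dimnames and a `modality`
#'   attribute).
#' @export
count_matrix <- function(values, feature_ids, cell_ids, modality = c("rna", "atac")) {
  modality <- match.arg(modality)
  m <- Matrix::Matrix(values, sparse = TRUE)
  m <- as(as(m * 1.0, "generalMatrix"), "CsparseMatrix")
  assert_that(nrow(m) == length(feature_ids),
              "matrix has %d rows but %d feature ids", nrow(m), length(feature_ids))
  assert_that(ncol(m) == length(cell_ids),
              "matrix has %d columns but %d cell ids", ncol(m), length(cell_ids))
  assert_that(!anyDuplicated(feature_ids), "duplicate feature identifiers")
  assert_that(!anyDuplicated(cell_ids), "duplicate cell identifiers")
  assert_that(all(m@x >= 0), "negative count entries are not allowed")
  dimnames(m) <- list(as.character(feature_ids), as.character(cell_ids))
  attr(m, "modality") <- modality
  m
}

#' Read a MatrixMarket count matrix with feature/barcode tables
#'
#' @param matrix_path `.mtx` coordinate file.
#' @param features_path,barcodes_path one identifier per line (first column of
#'   a TSV is used).
#' @param modality `"rna"` or `"atac"`.
#' @return A `CountMatrix`.
#' @export
read_count_matrix <- function(matrix_path, features_path, barcodes_path,
                              modality = c("rna", "atac")) {
  for (p in c(matrix_path, features_path, barcodes_path))
    assert_that(file.exists(p), "file not found: %s", p)
  m <- Matrix::readMM(matrix_path)
  feats <- read.table(features_path, sep = "\t", header = FALSE,
                      colClasses = "character")[[1]]
  cells <- read.table(barcodes_path, sep = "\t", header = FALSE,
                      colClasses = "character")[[1]]
  assert_that(nrow(m) == length(feats) && ncol(m) == length(cells),
              "matrix is %d x %d but %d features / %d barcodes listed",
              nrow(m), ncol(m), length(feats), length(cells))
  count_matrix(m, feats, cells, match.arg(modality))
}

#' Write a count matrix as MatrixMarket + feature/barcode tables
#'
#' @param mat `CountMatrix`.
#' @param matrix_path,features_path,barcodes_path output paths.
#' @export
write_count_matrix <- function(mat, matrix_path, features_path, barcodes_path) {
  Matrix::writeMM(mat, matrix_path)
  writeLines(rownames(mat), features_path)
  writeLines(colnames(mat), barcodes_path)
  invisible(matrix_path)
}

#' Read peaks from BED (0-based half-open)
#'
#' Columns chrom/start/end plus optional `gc` (4th) and `mean_accessibility`
#' (5th).
#'
#' @param path BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `peak_id`, and
#'   `gc` / `mean_accessibility` when present.
#' @export
read_peaks_bed <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$chrom <- as.character(df$chrom)
  assert_that(all(nzchar(df$chrom)), "empty chromosome name")
  assert_that(all(df$start < df$end), "interval with start >= end at line %d",
              which(df$start >= df$end)[1])
  out <- df[, 1:3]
  out$peak_id <- paste0(out$chrom, ":", out$start, "-", out$end)
  if (ncol(df) >= 4) {
    out$gc <- as.numeric(df[[4]])
    assert_that(all(out$gc >= 0 & out$gc <= 1), "gc content outside [0, 1]")
  }
  if (ncol(df) >= 5) out$mean_accessibility <- as.numeric(df[[5]])
  out
}

#' Write peaks to BED
#'
#' @param peaks data.frame as returned by [read_peaks_bed()].
#' @param path output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  cols <- c("chrom", "start", "end",
            intersect(c("gc", "mean_accessibility"), names(peaks)))
  write.table(format(peaks[, cols], scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read motifs in JASPAR text format
#'
#' `>ID NAME` headers followed by four base rows (`A [ 1 2 3 ]` style or bare
#' numbers), base order A, C, G, T.
#'
#' @param path JASPAR-format file.
#' @return Named list of 4 x L non-negative count matrices with rownames
#'   A/C/G/T.
#' @export
read_jaspar_pfm <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  assert_that(length(hdr) > 0, "no '>' motif headers found in %s", path)
  out <- list()
  for (i in seq_along(hdr)) {
    from <- hdr[i] + 1L
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    assert_that(length(block) == 4, "motif block with %d rows (need 4)", length(block))
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    lens <- lengths(rows)
    assert_that(length(unique(lens)) == 1, "motif rows of unequal length (%s)",
                paste(lens, collapse = ","))
    m <- do.call(rbind, rows)
    assert_that(all(is.finite(m)) && all(m >= 0), "non-numeric or negative PFM entry")
    rownames(m) <- c("A", "C", "G", "T")
    id <- strsplit(sub("^>", "", lines[hdr[i]]), "\\s+")[[1]][1]
    out[[id]] <- m
  }
  out
}

#' Write motifs in JASPAR text format
#' @param pfms named list of 4 x L matrices.
#' @param path output file.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(pfms)) {
    m <- pfms[[id]]
    writeLines(sprintf(">%s %s", id, id), con)
    for (b in 1:4)
      writeLines(sprintf("%s  [ %s ]", c("A", "C", "G", "T")[b],
                         paste(format(m[b, ], trim = TRUE), collapse = " ")), con)
  }
  invisible(path)
}

#' Read an ATAC fragments file
#'
#' 5-column TSV: chrom, start, end, barcode, duplicate count. Plain or gzipped.
#'
#' @param path fragments file.
#' @return data.frame `chrom`, `start`, `end`, `barcode`, `count` in file
#'   order; zero rows for an empty file.
#' @export
read_fragments <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      barcode = character(), count = integer())
  if (file.size(path) == 0) return(empty)
  if (grepl("\\.gz$", path)) {
    df <- tryCatch(read.table(gzfile(path), sep = "\t", header = FALSE,
                              colClasses = c("character", "numeric", "numeric",
                                             "character", "character")),
                   error = function(e) empty)
  } else {
    df <- data.table::fread(path, sep = "\t", header = FALSE,
                            colClasses = list(character = c(1, 4)),
                            data.table = FALSE, showProgress = FALSE)
  }
  if (nrow(df) == 0) return(empty)
  assert_that(ncol(df) == 5, "fragments file must have 5 columns, found %d", ncol(df))
  names(df) <- c("chrom", "start", "end", "barcode", "count")
  cnt <- suppressWarnings(as.numeric(df$count))
  assert_that(!anyNA(cnt) && all(cnt == floor(cnt)),
              "non-integer duplicate count in fragments file")
  assert_that(all(cnt >= 1), "duplicate count must be >= 1")
  assert_that(all(df$start < df$end), "fragment with start >= end")
  df$count <- as.integer(cnt)
  df
}

#' Write an ATAC fragments file
#' @param fragments data.frame as from [read_fragments()].
#' @param path output TSV (gzipped when the name ends in `.gz`).
#' @export
write_fragments <- function(fragments, path) {
  data.table::fwrite(fragments, path, sep = "\t", col.names = FALSE,
                     quote = FALSE, compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read / write a gene model table
#'
#' TSV with columns gene_id, chrom, start, end, strand, is_mitochondrial,
#' is_chrY. The TSS is derived: `start` for + strand, `end - 1` for -.
#'
#' @param path TSV file.
#' @return data.frame with a derived `tss` column.
#' @export
read_gene_model <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = c(
    gene_id = "character", chrom = "character", strand = "character"))
  validate_gene_model(df)
}

#' @rdname read_gene_model
#' @param genes gene model data.frame.
#' @export
write_gene_model <- function(genes, path) {
  write.table(genes[, c("gene_id", "chrom", "start", "end", "strand",
                        "is_mitochondrial", "is_chrY")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_gene_model <- function(df, chrY_name = "chrY") {
  assert_that(all(df$start < df$end), "gene with start >= end")
  assert_that(all(df$strand %in% c("+", "-", ".")), "invalid strand")
  df$tss <- ifelse(df$strand == "-", df$end - 1, df$start)
  df$is_mitochondrial <- as.logical(df$is_mitochondrial)
  df$is_chrY <- df$chrom == chrY_name
  df
}

# data.frame of intervals -> GRanges (0-based half-open -> 1-based closed).
as_granges <- function(df, extra = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*")
  for (nm in extra) S4Vectors::mcols(gr)[[nm]] <- df[[nm]]
  gr
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
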