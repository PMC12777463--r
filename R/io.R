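#' Read a per-cell spatial table
#'
#' Reads a TSV/CSV cell table (header row required) into a validated slide
#' tibble. The readers are deliberately strict: malformed rows are rejected
#' with a named error rather than silently coerced, because downstream
#' statistics treat 0 and missingness very differently.
#'
#' @param path Path to a TSV or CSV file (delimiter sniffed from the header
#'   line; `.csv` extension forces comma).
#' @param required_columns Columns that must be present.
#' @param type_universe Optional declared cell-type universe; defaults to
#'   the observed labels.
#' @return A slide tibble with `cell_type` as a factor over the universe.
#' @export
read_cell_table <- function(path,
                            required_columns = c("cell_id", "x", "y",
                                                 "cell_type"),
                            type_universe = NULL) {
  if (!file.exists(path)) {
    stop_validation(sprintf("file '%s' does not exist", path),
                    "rareniche_format_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  header <- readLines(path, n = 1)
  if (delim == "\t" && !grepl("\t", header) && grepl(",", header)) delim <- ","

  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)

  missing <- setdiff(required_columns, names(raw))
  if (length(missing) > 0) {
    stop_validation(
      sprintf("missing required column(s): %s",
              paste(missing, collapse = ", ")),
      "rareniche_format_error"
    )
  }
  dup <- raw$cell_id[duplicated(raw$cell_id)]
  if (length(dup) > 0) {
    stop_validation(
      sprintf("duplicate cell_id(s): %s",
              paste(unique(dup), collapse = ", ")),
      "rareniche_format_error"
    )
  }

  parse_numeric_col <- function(col, name) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0) {
      stop_validation(
        sprintf("non-numeric or non-finite value in column '%s' at row %d",
                name, bad[1]),
        "rareniche_format_error"
      )
    }
    v
  }

  out <- raw
  out$x <- parse_numeric_col(raw$x, "x")
  out$y <- parse_numeric_col(raw$y, "y")
  universe <- type_universe %||% sort(unique(raw$cell_type))
  if (!all(raw$cell_type %in% universe)) {
    bad <- setdiff(unique(raw$cell_type), universe)
    stop_validation(
      sprintf("cell_type label(s) outside the declared universe: %s",
              paste(bad, collapse = ", ")),
      "rareniche_format_error"
    )
  }
  out$cell_type <- factor(raw$cell_type, levels = universe)
  if ("positive" %in% names(out)) {
    out$positive <- as.logical(out$positive)
  }
  # remaining columns (expression / weights): numeric, no NAs permitted
  fixed <- c("cell_id", "x", "y", "cell_type", "positive")
  for (nm in setdiff(names(out), fixed)) {
    out[[nm]] <- parse_numeric_col(raw[[nm]], nm)
  }
  out <- as_tibble(out)
  attr(out, "type_universe") <- universe
  out
}

#' Write a slide tibble as TSV
#'
#' @param slide A slide tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(slide, path) {
  out <- slide
  out$cell_type <- as.character(out$cell_type)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sparse expression matrix (MatrixMarket + id lists)
#'
#' @param matrix_path MatrixMarket coordinate file (`.mtx`).
#' @param features_path One feature id per line (rows).
#' @param barcodes_path One barcode per line (columns).
#' @return A `dgCMatrix` with feature/barcode dimnames.
#' @export
read_sparse_matrix <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  features <- readLines(features_path)
  barcodes <- readLines(barcodes_path)
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    stop_validation(
      sprintf(
        "matrix is %d x %d but %d features and %d barcodes were supplied",
        nrow(m), ncol(m), length(features), length(barcodes)
      ),
      "rareniche_format_error"
    )
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(features, barcodes)
  m
}

#' Write a sparse matrix as MatrixMarket + id lists
#'
#' @param m Matrix with dimnames.
#' @param matrix_path,features_path,barcodes_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_sparse_matrix <- function(m, matrix_path, features_path,
                                barcodes_path) {
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), matrix_path)
  writeLines(rownames(m), features_path)
  writeLines(colnames(m), barcodes_path)
  invisible(matrix_path)
}

read_bed_raw <- function(path, min_cols) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(NULL)
  }
  parts <- strsplit(lines, "\t")
  ncols <- lengths(parts)
  if (any(ncols < min_cols)) {
    stop_validation(
      sprintf("BED line %d has %d field(s); at least %d required",
              which(ncols < min_cols)[1], min(ncols), min_cols),
      "rareniche_format_error"
    )
  }
  parts
}

parse_bed_int <- function(x, what, line) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v))
  if (length(bad) > 0) {
    stop_validation(
      sprintf("non-integer %s at BED line %d", what, line[bad[1]]),
      "rareniche_format_error"
    )
  }
  v
}

#' Read peak intervals from a BED file
#'
#' BED intervals are 0-based half-open. The per-peak score (here, a
#' differential-acetylation log fold-change) is taken from `score_column`.
#'
#' @param path BED3+ file (tab-separated, no header).
#' @param score_column 1-based column index of the score; `NA` entries are
#'   not permitted. Default 5, the standard BED score slot.
#' @return Tibble with `chrom`, `start`, `end`, `name` (if present),
#'   `score` (if the column exists).
#' @export
read_bed_intervals <- function(path, score_column = 5) {
  parts <- read_bed_raw(path, 3)
  if (is.null(parts)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric()))
  }
  lineno <- seq_along(parts)
  chrom <- vapply(parts, `[[`, "", 1)
  start <- parse_bed_int(vapply(parts, `[[`, "", 2), "start", lineno)
  end <- parse_bed_int(vapply(parts, `[[`, "", 3), "end", lineno)
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0) {
    stop_validation(
      sprintf("invalid interval (need 0 <= start < end) at BED line %d",
              bad[1]),
      "rareniche_format_error"
    )
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (all(lengths(parts) >= 4)) {
    out$name <- vapply(parts, `[[`, "", 4)
  }
  if (!is.null(score_column) && !is.na(score_column) &&
      all(lengths(parts) >= score_column)) {
    sc <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", score_column)))
    bad <- which(is.na(sc))
    if (length(bad) > 0) {
      stop_validation(
        sprintf("non-numeric score at BED line %d", bad[1]),
        "rareniche_format_error"
      )
    }
    out$score <- sc
  }
  out
}

#' Read transcription start sites from a BED6 file
#'
#' The TSS of a plus-strand interval is its start; for a minus-strand
#' interval it is `end - 1` (the last base of the 0-based half-open
#' interval), following genome-browser convention.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return Tibble with `chrom`, `tss`, `strand`, `gene_id`.
#' @export
read_tss_bed <- function(path) {
  parts <- read_bed_raw(path, 6)
  if (is.null(parts)) {
    return(tibble(chrom = character(), tss = integer(),
                  strand = character(), gene_id = character()))
  }
  lineno <- seq_along(parts)
  chrom <- vapply(parts, `[[`, "", 1)
  start <- parse_bed_int(vapply(parts, `[[`, "", 2), "start", lineno)
  end <- parse_bed_int(vapply(parts, `[[`, "", 3), "end", lineno)
  gene_id <- vapply(parts, `[[`, "", 4)
  strand <- vapply(parts, `[[`, "", 6)
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0) {
    stop_validation(
      sprintf("invalid interval (need 0 <= start < end) at BED line %d",
              bad[1]),
      "rareniche_format_error"
    )
  }
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0) {
    stop_validation(
      sprintf("invalid strand '%s' at BED line %d", strand[bad[1]], bad[1]),
      "rareniche_format_error"
    )
  }
  tibble(
    chrom = chrom,
    tss = ifelse(strand == "+", start, end - 1L),
    strand = strand,
    gene_id = gene_id
  )
}

#' Write peak intervals as BED
#'
#' Columns written: chrom, start, end, name (generated if absent), score.
#'
#' @param peaks Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_intervals <- function(peaks, path) {
  name <- peaks$name %||% sprintf("peak_%04d", seq_len(nrow(peaks)))
  score <- peaks$score %||% rep(0, nrow(peaks))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", peaks$chrom, peaks$start,
                   peaks$end, name, format(score, trim = TRUE, digits = 15))
  writeLines(lines, path)
  invisible(path)
}

#' Write TSS records as single-base BED6 intervals
#'
#' Each TSS is written as the 1 bp interval `[tss, tss + 1)`, which
#' round-trips through [read_tss_bed()] on either strand.
#'
#' @param tss TSS tibble (`chrom`, `tss`, `strand`, `gene_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(tss, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", tss$chrom, tss$tss,
                   tss$tss + 1L, tss$gene_id, tss$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' @param path TSV with header; requires `gene_id` and `logFC`, and at least
#'   one of `pvalue` / `fdr`.
#' @return Validated tibble.
#' @export
read_deg_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  missing <- setdiff(c("gene_id", "logFC"), names(tab))
  if (length(missing) > 0) {
    stop_validation(
      sprintf("missing required column(s): %s",
              paste(missing, collapse = ", ")),
      "rareniche_format_error"
    )
  }
  if (!any(c("pvalue", "fdr") %in% names(tab))) {
    stop_validation("need at least one of columns 'pvalue' or 'fdr'",
                    "rareniche_format_error")
  }
  if (anyDuplicated(tab$gene_id)) {
    stop_validation("duplicate gene_id values", "rareniche_format_error")
  }
  for (nm in intersect(c("pvalue", "fdr"), names(tab))) {
    if (any(tab[[nm]] <= 0 | tab[[nm]] > 1)) {
      stop_validation(sprintf("column '%s' must lie in (0, 1]", nm),
                      "rareniche_format_error")
    }
  }
  tab
}
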