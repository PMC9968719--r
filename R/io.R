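#' Read and write omics intensity matrices as TSV
#'
#' The on-disk format is a plain TSV: a `feature_id` column, optional feature
#' annotation columns, then one numeric column per sample. Missing cells are
#' empty. `writeOmicsMatrix()` prepends a single comment line recording the
#' modification layer and which columns are annotations, so a written file
#' round-trips exactly; files from other tools can name their annotation
#' columns via `annotationCols`.
#'
#' @param path file path.
#' @param modification layer label used when the file does not carry one.
#' @param annotationCols character vector of annotation column names, used only
#'   when the file has no header comment.
#' @return `readOmicsMatrix()` returns an [OmicsMatrix-class];
#'   `writeOmicsMatrix()` returns `path` invisibly.
#' @examples
#' m <- OmicsMatrix(matrix(c(1, NA, 3, 4), 2, 2,
#'                  dimnames = list(c("f1", "f2"), c("s1", "s2"))))
#' tf <- tempfile(fileext = ".tsv")
#' writeOmicsMatrix(m, tf)
#' m2 <- readOmicsMatrix(tf)
#' identical(intensities(m), intensities(m2))
#' @export
readOmicsMatrix <- function(path, modification = "phospho",
                            annotationCols = character()) {
  first <- readLines(path, n = 1L)
  hasHeader <- startsWith(first, "#")
  if (hasHeader) {
    mod <- sub(".*modification=([^ \t]+).*", "\\1", first)
    annoSpec <- sub(".*annotations=([^ \t]*).*", "\\1", first)
    annotationCols <- if (nzchar(annoSpec) && annoSpec != first)
      strsplit(annoSpec, ",", fixed = TRUE)[[1]] else character()
    if (mod != first) modification <- mod
  }
  # header read raw to detect duplicate sample columns before make.unique
  hdr <- strsplit(readLines(path, n = if (hasHeader) 2L else 1L)[if (hasHeader) 2L else 1L],
                  "\t", fixed = TRUE)[[1]]
  dup <- hdr[duplicated(hdr)]
  if (length(dup))
    stop("duplicated column id(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(df))
    stop("first column must be 'feature_id'")
  fid <- as.character(df$feature_id)
  if (anyDuplicated(fid))
    stop("duplicated feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  sampleCols <- setdiff(names(df), c("feature_id", annotationCols))
  vals <- as.matrix(df[sampleCols])
  for (j in seq_along(sampleCols)) {
    col <- df[[sampleCols[j]]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s'",
                     bad[1], sampleCols[j]))
      vals[, j] <- num
    }
  }
  storage.mode(vals) <- "double"
  rownames(vals) <- fid
  anno <- if (length(annotationCols)) df[annotationCols] else NULL
  OmicsMatrix(vals, featureAnnotations = anno, modification = modification)
}

#' @rdname readOmicsMatrix
#' @param x an [OmicsMatrix-class].
#' @export
writeOmicsMatrix <- function(x, path) {
  stopifnot(is(x, "OmicsMatrix"))
  anno <- as.data.frame(featureAnnotations(x))
  annoCols <- colnames(anno)
  out <- data.frame(feature_id = featureIds(x), check.names = FALSE)
  if (length(annoCols)) out <- cbind(out, anno)
  out <- cbind(out, as.data.frame(intensities(x), check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# PhosphoStrat OmicsMatrix modification=%s annotations=%s",
                     x@modification, paste(annoCols, collapse = ",")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read and write feature sets in GMT format
#'
#' One set per line: set name, description, then member feature ids, all
#' tab-separated. Used for kinase-substrate maps and annotation term sets.
#'
#' @param path file path.
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of per-set descriptions.
#' @return `readGmt()` returns a named list of character vectors.
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeGmt(list(CDK1 = c("p1", "p2")), tf)
#' readGmt(tf)
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicated set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets
}

#' @rdname readGmt
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write per-sample cohort metadata
#'
#' A TSV with a mandatory `sample_id` column and the standard cohort columns
#' (`centre`, `tissue`, `karyotype`, `kmt2a_partner`, `qc_flags`, `split`,
#' `group`). `qc_flags` holds comma-separated flag names (empty = clean).
#'
#' @param path file path.
#' @param meta a data.frame of metadata.
#' @return `readSampleMetadata()` returns a data.frame.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "NA")
  if (!"sample_id" %in% names(df)) stop("metadata must have a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!is.null(df$qc_flags)) df$qc_flags[is.na(df$qc_flags)] <- ""
  df
}

#' @rdname readSampleMetadata
#' @export
writeSampleMetadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write long-format drug screen tables
#'
#' Columns: `drug`, `sample`, `dose_index`, `concentration` (molar), `signal`
#' (luminescence), `well_type` (`drug`, `vehicle`, `positive`, `untreated`)
#' and `day` (0 or 3). Control and untreated wells carry `NA` drug and dose.
#'
#' @param path file path.
#' @param screen a data.frame as produced by [simulateScreen()].
#' @return `readScreen()` returns a data.frame.
#' @export
readScreen <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("drug", "sample", "dose_index", "concentration", "signal",
            "well_type", "day")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("screen table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname readScreen
#' @export
writeScreen <- function(screen, path) {
  utils::write.table(screen, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
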