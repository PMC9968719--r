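#' Apply cohort quality-control exclusion rules
#'
#' Removes every sample carrying at least one QC flag and reports how many
#' samples each exclusion reason touched. A sample with several flags is
#' excluded once but counted under each of its reasons, mirroring cohort
#' reports where per-reason counts can exceed the number of excluded samples.
#' The operation is idempotent: re-applying it to the retained set removes
#' nothing further.
#'
#' @param meta metadata data.frame with `sample_id` and `qc_flags` columns
#'   (comma-separated flag names, empty string or `NA` = clean). Recognised
#'   flags are `mislabelled`, `high_rbc`, `high_tcell`, `low_viability`, but
#'   any non-empty flag excludes.
#' @return A list with `retained` (metadata rows that pass), `excluded`
#'   (rows that fail), and `report` (named integer vector of per-reason
#'   counts plus `n_excluded` and `n_retained`).
#' @examples
#' meta <- data.frame(sample_id = c("a", "b", "c"),
#'                    qc_flags = c("", "high_tcell", "low_viability,high_tcell"))
#' applyQC(meta)$report
#' @export
applyQC <- function(meta) {
  stopifnot(is.data.frame(meta), "sample_id" %in% names(meta))
  flags <- if (is.null(meta$qc_flags)) rep("", nrow(meta)) else meta$qc_flags
  flags[is.na(flags)] <- ""
  flagList <- strsplit(flags, ",", fixed = TRUE)
  flagList <- lapply(flagList, function(f) trimws(f[nzchar(trimws(f))]))
  bad <- lengths(flagList) > 0L
  reasons <- unlist(flagList)
  report <- if (length(reasons)) table(reasons) else table(character())
  report <- stats::setNames(as.integer(report), names(report))
  report <- c(report, n_excluded = sum(bad), n_retained = sum(!bad))
  list(retained = meta[!bad, , drop = FALSE],
       excluded = meta[bad, , drop = FALSE],
       report = report)
}

#' Derive QC flags from numeric metadata columns
#'
#' The exclusion rules consume pre-computed boolean flags; this helper turns
#' user-chosen thresholds on cytometry/viability columns into those flags.
#' Thresholds are deliberately not defaulted — cut-offs are a cohort-level
#' decision.
#'
#' @param meta metadata data.frame.
#' @param rules named list mapping a flag name to a predicate of one metadata
#'   row, e.g. `list(low_viability = function(m) m$viability < 60)`. Each
#'   predicate receives the full data.frame and must return a logical vector.
#' @return `meta` with its `qc_flags` column rebuilt from the rules (existing
#'   flags are preserved and new ones appended, without duplicates).
#' @examples
#' meta <- data.frame(sample_id = c("a", "b"), viability = c(90, 40),
#'                    qc_flags = "")
#' flagQC(meta, list(low_viability = function(m) m$viability < 60))$qc_flags
#' @export
flagQC <- function(meta, rules) {
  stopifnot(is.list(rules), !is.null(names(rules)), all(nzchar(names(rules))))
  existing <- if (is.null(meta$qc_flags)) rep("", nrow(meta)) else meta$qc_flags
  existing[is.na(existing)] <- ""
  flagList <- lapply(strsplit(existing, ",", fixed = TRUE),
                     function(f) trimws(f[nzchar(trimws(f))]))
  for (flag in names(rules)) {
    hit <- rules[[flag]](meta)
    if (!is.logical(hit) || length(hit) != nrow(meta))
      stop("rule '", flag, "' must return one logical per sample")
    hit[is.na(hit)] <- FALSE
    flagList[hit] <- lapply(flagList[hit], function(f) unique(c(f, flag)))
  }
  meta$qc_flags <- vapply(flagList, paste, "", collapse = ",")
  meta
}

#' Median-center the sample columns of an intensity matrix
#'
#' With `method = "median_center"`, subtracts each sample column's median over
#' its observed values, so every column's observed median becomes exactly 0;
#' missing cells are untouched and within-column differences are preserved.
#' `method = "none"` is the identity.
#'
#' @param x an [OmicsMatrix-class].
#' @param method `"median_center"` or `"none"`.
#' @return An [OmicsMatrix-class] with transformed intensities.
#' @examples
#' m <- OmicsMatrix(matrix(c(1, 2, 3, 10, 20, 30), 3, 2,
#'                  dimnames = list(paste0("f", 1:3), c("s1", "s2"))))
#' intensities(normalizeIntensities(m))
#' @export
normalizeIntensities <- function(x, method = c("median_center", "none")) {
  method <- match.arg(method)
  if (method == "none") return(x)
  v <- intensities(x)
  allMissing <- colSums(!is.na(v)) == 0L
  if (any(allMissing))
    stop("sample(s) with no observed values: ",
         paste(colnames(v)[allMissing], collapse = ", "))
  med <- apply(v, 2L, stats::median, na.rm = TRUE)
  assays(x)[["log2intensity"]] <- sweep(v, 2L, med, "-")
  x
}
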