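# File formats: dosage TSV (markers as rows, metadata columns first),
# phenotype records CSV/TSV with a configurable column map, and a VCF 4.2
# export carrying expected dosages in a DS FORMAT field.

#' Write an expected-dosage matrix as TSV
#'
#' Markers as rows with columns `marker_id`, `chrom`, `pos`, `annotated`,
#' then one column per individual; dosages rounded to five decimals and
#' missing values written as `NA`.  The round trip through
#' [read_dosage_tsv()] is lossless at that precision.
#'
#' @param dm a `dosage_matrix`.
#' @param path output file.
#' @export
write_dosage_tsv <- function(dm, path) {
  stopifnot(inherits(dm, "dosage_matrix"))
  df <- cbind(dm$marker_info[, c("marker_id", "chrom", "pos", "annotated")],
              as.data.frame(t(round(dm$values, 5L))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#populations\t",
                    paste(dm$populations, collapse = "\t")), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = "NA"))
  invisible(path)
}

#' Read an expected-dosage matrix from TSV
#'
#' @param path file written by [write_dosage_tsv()] (or matching its
#'   layout: metadata columns `marker_id`, `chrom`, `pos`, optionally
#'   `annotated`, then individual columns; an optional leading
#'   `#populations` line).
#' @return a `dosage_matrix`.
#' @export
read_dosage_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  pops <- NULL
  skip <- 0L
  if (startsWith(first, "#populations")) {
    pops <- strsplit(first, "\t", fixed = TRUE)[[1L]][-1L]
    skip <- 1L
  }
  df <- read.delim(path, skip = skip, stringsAsFactors = FALSE,
                   check.names = FALSE)
  req <- c("marker_id", "chrom", "pos")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop(sprintf("missing metadata column(s): %s",
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(df$marker_id)) stop("duplicate marker ids")
  meta_cols <- intersect(c("marker_id", "chrom", "pos", "annotated"),
                         names(df))
  ind_cols <- setdiff(names(df), meta_cols)
  vals <- t(as.matrix(df[, ind_cols, drop = FALSE]))
  colnames(vals) <- df$marker_id
  bad <- which(!is.na(vals) & (vals < 0 | vals > 2), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("dosage outside [0,2]: individual '%s', marker '%s'",
                 rownames(vals)[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  mi <- data.frame(marker_id = df$marker_id, chrom = as.character(df$chrom),
                   pos = as.integer(df$pos),
                   annotated = if ("annotated" %in% names(df))
                     as.logical(df$annotated) else !is.na(df$chrom),
                   stringsAsFactors = FALSE)
  if (is.null(pops)) pops <- rep("pop1", nrow(vals))
  names(pops) <- rownames(vals)
  new_dosage_matrix(vals, mi, pops)
}

#' Read phenotype records with a configurable column map
#'
#' @param path CSV or TSV file (delimiter inferred from the extension,
#'   `.csv` vs anything else).
#' @param column_map named character vector mapping the standard record
#'   fields (`family`, `block`, `year`, `value`, and optionally
#'   `population`, `location`, `trait`, `plant`, `row`, `col`, `level`) to
#'   the file's column names; identity by default.
#' @param level record level (`"plant"` or `"plot"`) when the file has no
#'   `level` column.
#' @return data.frame of typed records.
#' @export
read_phenotypes <- function(path, column_map = NULL,
                            level = c("plant", "plot")) {
  level <- match.arg(level)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(df))
        stop(sprintf("mapped column '%s' (for '%s') not in file", src, std))
      names(df)[names(df) == src] <- std
    }
  }
  required <- c("family", "block", "year", "value")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop(sprintf("missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  df$year <- as.integer(df$year)
  df$value <- as.numeric(df$value)
  if (!"level" %in% names(df)) df$level <- level
  df
}

#' Export an expected-dosage matrix as VCF 4.2 with a DS field
#'
#' One record per marker, positions 1-based and sorted within chromosome,
#' genotypes uncalled (`./.`) with the expected dosage in the `DS` FORMAT
#' field at five decimals.
#'
#' @param dm a `dosage_matrix` with chromosome/position metadata.
#' @param path output file.
#' @export
export_vcf_dosage <- function(dm, path) {
  stopifnot(inherits(dm, "dosage_matrix"))
  mi <- dm$marker_info
  if (anyNA(mi$chrom) || anyNA(mi$pos))
    stop("VCF export requires chromosome and position for every marker")
  ord <- order(mi$chrom, mi$pos)
  ids <- rownames(dm$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=gsld",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Expected alternate allele dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
             con)
  for (j in ord) {
    ds <- dm$values[, j]
    ds_str <- ifelse(is.na(ds), "./.:.",
                     paste0("./.:", formatC(round(ds, 5L), format = "fg",
                                            digits = 6L)))
    writeLines(paste(c(mi$chrom[j], mi$pos[j], mi$marker_id[j], "N", "A",
                       ".", "PASS", ".", "GT:DS", ds_str),
                     collapse = "\t"), con)
  }
  invisible(path)
}
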