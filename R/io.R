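# Readers and writers for abundance tables, taxonomy aggregation, and
# reservoir-size estimation from data.

#' Read a taxa-by-times abundance table
#'
#' Reads a TSV or CSV table with taxa as rows and sampling times as columns;
#' the first column holds taxon identifiers. Values may be counts or
#' relative abundances: every column is normalized to sum to 1, and the
#' normalization is verified. Sampling times are treated as equally spaced.
#'
#' @param path Path to the table.
#' @param sep Field separator; inferred from the file extension when
#'   \code{NULL} (",\" for .csv, tab otherwise).
#' @param detect Detection threshold for presence calls.
#' @return A \code{"cr_series"} object.
#' @export
read_abundance_table <- function(path, sep = NULL, detect = 1e-4) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- tryCatch(
    read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e)))
  if (nrow(tab) == 0 || ncol(tab) < 2) stop("empty table in '", path, "'")
  taxa <- as.character(tab[[1]])
  x <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("non-numeric or missing values in '", path, "'")
  if (any(x < 0)) stop("negative abundances in '", path, "'")
  cs <- colSums(x)
  if (any(cs == 0)) {
    stop("empty sample: column(s) ",
         paste(which(cs == 0), collapse = ", "), " sum to zero")
  }
  x <- sweep(x, 2, cs, "/")
  if (any(abs(colSums(x) - 1) > 1e-6)) stop("column normalization failed")
  cr_series(x, detect = detect, taxa_ids = taxa,
            meta = list(source = path))
}

#' Write an abundance time series as TSV
#'
#' Rows are taxa, columns are sampling times with a header row of time
#' indices, and the first column holds the taxon label. Round-trips through
#' [read_abundance_table()] losslessly (to 1e-12).
#'
#' @param series A \code{"cr_series"} object.
#' @param path Output path.
#' @export
write_abundance_table <- function(series, path) {
  series <- as_cr_series(series)
  tab <- data.frame(taxon = series$taxa_ids,
                    format(series$x, digits = 17, scientific = TRUE,
                           trim = TRUE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- c("taxon", seq_len(ncol(series$x)))
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Aggregate an abundance series to a taxonomic rank
#'
#' Sums feature (OTU/ASV) abundances within each lineage at the target rank.
#' Features absent from the taxonomy table, or lacking an assignment at the
#' target rank, are pooled into one \code{"unclassified"} row (or dropped
#' with \code{unclassified = "drop"}). Column sums are preserved exactly
#' when pooling.
#'
#' @param series A \code{"cr_series"} of feature-level abundances.
#' @param taxonomy Data frame with a \code{feature} column of identifiers
#'   plus one column per rank (\code{kingdom} ... \code{genus}).
#' @param rank Target rank, one of the taxonomy's rank columns.
#' @param unclassified \code{"pool"} (default) or \code{"drop"}.
#' @return A \code{"cr_series"} aggregated at the target rank.
#' @export
aggregate_taxonomy <- function(series, taxonomy, rank,
                               unclassified = c("pool", "drop")) {
  series <- as_cr_series(series)
  unclassified <- match.arg(unclassified)
  if (!"feature" %in% names(taxonomy))
    stop("taxonomy must have a 'feature' column")
  if (!rank %in% names(taxonomy) || !rank %in% RANKS)
    stop("unknown rank '", rank, "'")
  lineage <- taxonomy[[rank]][match(series$taxa_ids, taxonomy$feature)]
  lineage[is.na(lineage) | lineage == ""] <- NA_character_
  if (unclassified == "pool") {
    lineage[is.na(lineage)] <- "unclassified"
  } else {
    keep <- !is.na(lineage)
    series$x <- series$x[keep, , drop = FALSE]
    lineage <- lineage[keep]
  }
  agg <- rowsum(series$x, group = lineage)
  cr_series(agg, detect = series$detect, taxa_ids = rownames(agg),
            meta = c(series$meta, list(rank = rank)))
}

#' Estimate the reservoir size N from a time series
#'
#' The reservoir size is estimated from data as the number of taxa present
#' (above the detection threshold) at one or more sampling times.
#'
#' @param series A \code{"cr_series"} object.
#' @return Integer count.
#' @export
estimate_N <- function(series) {
  series <- as_cr_series(series)
  sum(rowSums(series$present) > 0)
}
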