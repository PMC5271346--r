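#' Construct a taxon-by-sample count table
#'
#' The universal input of the package: an integer matrix of sequence counts
#' with samples as rows and taxa as columns. Counts stay integers throughout;
#' relative abundance is always computed on demand (the longitudinal models
#' need raw counts and per-sample depths, not proportions).
#'
#' Empty samples are rejected at construction because every downstream
#' statistic (relative abundance, diversity, turnover) conditions on a
#' positive sequencing depth.
#'
#' @param counts numeric matrix (samples x taxa) of non-negative integers.
#' @param sample_ids,taxon_ids identifier vectors; default to the dimnames of
#'   `counts`. Must be unique.
#' @param rare_taxon name of a collapsed "rare" pseudo-taxon column, if one is
#'   present (set by [collapse_rare()]); `NULL` otherwise. The rare column is
#'   an ordinary taxon for all diversity computations.
#' @return An object of class `taxon_count_table`: a list with elements
#'   `counts` (integer matrix with sample/taxon dimnames) and `rare_taxon`.
#' @seealso [read_count_table()], [relative_abundance()], [collapse_rare()]
#' @examples
#' tab <- taxon_count_table(rbind(a = c(30, 70), b = c(10, 90)),
#'                          taxon_ids = c("Staphylococcus", "Ureaplasma"))
#' relative_abundance(tab)
#' @export
taxon_count_table <- function(counts, sample_ids = rownames(counts),
                              taxon_ids = colnames(counts), rare_taxon = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("T", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (length(sample_ids) != nrow(counts))
    stop("length of 'sample_ids' does not match the number of rows")
  if (length(taxon_ids) != ncol(counts))
    stop("length of 'taxon_ids' does not match the number of columns")
  if (!is.numeric(counts))
    stop("counts must be numeric")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(taxon_ids))
    stop("duplicated taxon id(s): ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  if (anyNA(counts))
    stop("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count for sample '%s', taxon '%s'",
                 sample_ids[bad[1]], taxon_ids[bad[2]]))
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count for sample '%s', taxon '%s'",
                 sample_ids[bad[1]], taxon_ids[bad[2]]))
  }
  storage.mode(counts) <- "integer"
  empty <- rowSums(counts) == 0L
  if (any(empty))
    stop("empty sample(s) with zero total count: ",
         paste(sample_ids[empty], collapse = ", "))
  dimnames(counts) <- list(sample_ids, taxon_ids)
  if (!is.null(rare_taxon) && !rare_taxon %in% taxon_ids)
    stop("rare_taxon '", rare_taxon, "' is not among the taxon ids")
  structure(list(counts = counts, rare_taxon = rare_taxon),
            class = "taxon_count_table")
}

#' @export
print.taxon_count_table <- function(x, ...) {
  cat(sprintf("taxon_count_table: %d samples x %d taxa\n",
              nrow(x$counts), ncol(x$counts)))
  depths <- rowSums(x$counts)
  cat(sprintf("  depth: min %d, median %s, max %d\n",
              min(depths), format(stats::median(depths)), max(depths)))
  if (!is.null(x$rare_taxon))
    cat(sprintf("  collapsed rare pseudo-taxon: '%s'\n", x$rare_taxon))
  invisible(x)
}

#' @rdname taxon_count_table
#' @param x object to test.
#' @export
is_taxon_count_table <- function(x) inherits(x, "taxon_count_table")

#' Number of samples / taxa in a count table
#' @param x a `taxon_count_table`.
#' @return integer.
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname n_samples
#' @export
n_taxa <- function(x) ncol(x$counts)

#' Read a taxon count table from disk
#'
#' Two on-disk layouts are supported. `format = "tsv"` expects a tab-delimited
#' matrix whose first column holds sample ids and whose header row holds taxon
#' ids (one row per sample). A transposed file (taxa as rows) is only accepted
#' when `transposed = TRUE`; the orientation is never guessed. `format =
#' "biom"` reads a BIOM file through the biomformat package (observations =
#' taxa, columns = samples, the BIOM convention) and transposes it into the
#' samples-by-taxa orientation used here.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"biom"`.
#' @param transposed for `"tsv"`: set `TRUE` when rows are taxa and columns
#'   are samples.
#' @return a [taxon_count_table()].
#' @export
read_count_table <- function(path, format = c("tsv", "biom"),
                             transposed = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    return(taxon_count_table(t(m)))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2)
    stop("malformed count table '", path,
         "': expected an id column plus at least one count column")
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(raw[-1], is.numeric, logical(1)))[1]
    stop(sprintf("malformed count table '%s': column '%s' is not numeric",
                 path, colnames(raw)[-1][bad]))
  }
  rownames(m) <- ids
  if (transposed) m <- t(m)
  taxon_count_table(m)
}

#' Write a taxon count table as TSV
#'
#' Inverse of [read_count_table()] for the `"tsv"` layout.
#'
#' @param x a `taxon_count_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample relative abundance (percent)
#'
#' Converts counts to relative abundance: a taxon's count divided by the
#' sample's total count, times 100. This is the depth normalization used for
#' all descriptive displays and for the rare-taxon rule.
#'
#' @param x a `taxon_count_table`, or a counts matrix (samples x taxa).
#' @return numeric matrix of percentages; every row sums to 100.
#' @export
relative_abundance <- function(x) {
  m <- if (is_taxon_count_table(x)) x$counts else as.matrix(x)
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("zero total count for sample(s): ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  sweep(m, 1, tot, "/") * 100
}

#' Collapse uniformly rare taxa into a single pseudo-taxon
#'
#' Taxa whose relative abundance is below `threshold_pct` percent in *every*
#' sample are summed into one column labelled `rare_label`, appended after the
#' retained taxa. A taxon that clears the threshold in even one sample is
#' retained. Per-sample totals are conserved exactly (integer arithmetic). If
#' no taxon qualifies the table is returned unchanged, without an all-zero
#' rare column.
#'
#' The rare pseudo-taxon is flagged in the result (`$rare_taxon`) but is
#' treated as an ordinary taxon by the diversity and turnover statistics.
#'
#' @param x a `taxon_count_table`.
#' @param threshold_pct rarity threshold in percent (default 1).
#' @param rare_label name for the pseudo-taxon.
#' @return a `taxon_count_table`.
#' @export
collapse_rare <- function(x, threshold_pct = 1, rare_label = "rare") {
  stopifnot(is_taxon_count_table(x), threshold_pct > 0)
  ra <- relative_abundance(x)
  rare <- apply(ra < threshold_pct, 2, all)
  if (!any(rare)) return(x)
  kept <- x$counts[, !rare, drop = FALSE]
  rare_counts <- as.integer(rowSums(x$counts[, rare, drop = FALSE]))
  m <- cbind(kept, rare_counts)
  colnames(m) <- c(colnames(kept), rare_label)
  taxon_count_table(m, rare_taxon = rare_label)
}
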