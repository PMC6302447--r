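#' Construct a physicochemical property table
#'
#' A property table assigns each di- or tri-nucleotide a numeric value for
#' every property (index). These values drive the correlation factors of the
#' pseudo nucleotide composition encoders. Columns are z-scored across the
#' alphabet (population moments: mean 0, variance 1 over the 16 or 64
#' oligonucleotides), the usual convention before computing correlation
#' factors, so only each index's relative profile matters.
#'
#' @param values numeric matrix; rownames are the oligonucleotides (all 16
#'   dinucleotides or all 64 trinucleotides), colnames the property names.
#' @param standardize standardize columns now (default TRUE).
#' @return object of class `property_table` with elements `alphabet`
#'   (`"di"` or `"tri"`), `values` (standardized matrix), `standardized`.
#' @export
property_table <- function(values, standardize = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) stop("values must be a numeric matrix")
  k <- if (nrow(values) == 16L) 2L else if (nrow(values) == 64L) 3L else
    stop("property table must have 16 (di) or 64 (tri) rows")
  oligos <- kmer_strings(k)
  if (is.null(rownames(values)) || !setequal(rownames(values), oligos)) {
    stop(sprintf("rownames must be exactly the %d %s-nucleotides",
                 length(oligos), if (k == 2L) "di" else "tri"))
  }
  values <- values[oligos, , drop = FALSE]
  if (is.null(colnames(values))) colnames(values) <- paste0("P", seq_len(ncol(values)))
  tab <- structure(list(alphabet = if (k == 2L) "di" else "tri",
                        values = values, standardized = FALSE),
                   class = "property_table")
  if (standardize) standardize_property_table(tab) else tab
}

#' Standardize a property table
#'
#' Rescales each property column to mean 0 and (population) variance 1 across
#' its alphabet. Idempotent; a constant column is an error because it carries
#' no information and would divide by zero.
#'
#' @param tab a [property_table()].
#' @return the standardized table.
#' @export
standardize_property_table <- function(tab) {
  stopifnot(inherits(tab, "property_table"))
  v <- tab$values
  n <- nrow(v)
  mu <- colMeans(v)
  sig <- sqrt(colMeans(sweep(v, 2, mu)^2))  # population sd
  if (any(sig < 1e-12)) {
    stop(sprintf("degenerate property '%s': constant across the alphabet",
                 colnames(v)[which(sig < 1e-12)[1L]]))
  }
  tab$values <- sweep(sweep(v, 2, mu), 2, sig, "/")
  tab$standardized <- TRUE
  tab
}

#' Load a property table from TSV
#'
#' First column = oligonucleotide, remaining columns = one property each
#' (header row gives property names).
#'
#' @param path TSV file.
#' @param standardize standardize after loading (default TRUE).
#' @return a [property_table()].
#' @export
load_property_table <- function(path, standardize = TRUE) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- toupper(df[[1]])
  storage.mode(m) <- "double"
  property_table(m, standardize = standardize)
}

#' Default property tables
#'
#' The package ships synthetic index tables (6 dinucleotide properties
#' P1..P6, 12 trinucleotide properties T1..T12) under `inst/extdata/` with
#' the dimensionality the pseudo-composition encoders expect. The values are
#' fixed arbitrary draws, not measured physicochemical indices: they exercise
#' the correlation machinery and pin the feature dimensions, but users
#' analysing real data should load measured index sets (twist, tilt, roll,
#' ...) with [load_property_table()].
#'
#' @param alphabet `"di"` or `"tri"`.
#' @return a standardized [property_table()].
#' @export
default_property_table <- function(alphabet = c("di", "tri")) {
  alphabet <- match.arg(alphabet)
  .cache_get(paste0("props_", alphabet), function() {
    f <- system.file("extdata",
                     sprintf("%snucleotide_properties_synthetic.tsv", alphabet),
                     package = "srnaens", mustWork = TRUE)
    load_property_table(f)
  })
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("<property_table> %s-nucleotide, %d properties (%s)%s\n",
              x$alphabet, ncol(x$values),
              paste(colnames(x$values), collapse = ", "),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}
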