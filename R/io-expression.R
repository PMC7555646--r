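#' Construct an expression matrix with replicate metadata
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param condition Character vector of per-sample condition labels (tissue,
#'   or `"genotype:time"` for time courses).
#' @param replicate Integer vector of per-sample replicate indices.
#' @return An `expression_matrix`: list with `values` and a `samples` data
#'   frame (`sample_id`, `condition`, `replicate`).
#' @export
expression_matrix <- function(values, condition, replicate) {
  values <- as.matrix(values)
  if (length(condition) != ncol(values) || length(replicate) != ncol(values))
    stop("condition/replicate length must match number of columns")
  if (anyNA(values)) stop("expression values contain NA/NaN")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(rownames(values))) stop("values must have gene row names")
  sample_id <- paste0(condition, "_r", replicate)
  colnames(values) <- sample_id
  structure(list(values = values,
                 samples = data.frame(sample_id = sample_id,
                                      condition = as.character(condition),
                                      replicate = as.integer(replicate),
                                      stringsAsFactors = FALSE)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d conditions)\n",
              nrow(x$values), ncol(x$values), length(unique(x$samples$condition))))
  invisible(x)
}

#' Read an expression matrix TSV with a two-row header
#'
#' The expected format carries sample metadata in two leading header rows:
#' line 1 starts with `#condition` followed by one condition label per
#' sample column; line 2 starts with `#replicate` followed by replicate
#' indices; subsequent rows are `gene_id` followed by non-negative values.
#'
#' @param path Path to the TSV.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("expression TSV needs 2 header rows and data")
  h1 <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  h2 <- strsplit(lines[2L], "\t", fixed = TRUE)[[1]]
  if (h1[1L] != "#condition" || h2[1L] != "#replicate")
    stop("expected '#condition' and '#replicate' header rows")
  condition <- h1[-1L]
  replicate <- as.integer(h2[-1L])
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  genes <- vapply(body, `[[`, character(1), 1L)
  vals <- t(vapply(body, function(f) as.numeric(f[-1L]),
                   numeric(length(condition))))
  if (length(condition) == 1L) vals <- matrix(vals, ncol = 1L)
  rownames(vals) <- genes
  if (anyNA(vals)) stop("expression TSV contains missing values")
  expression_matrix(vals, condition, replicate)
}

#' Write an expression matrix in the two-row-header TSV format
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#condition", em$samples$condition), collapse = "\t"), con)
  writeLines(paste(c("#replicate", em$samples$replicate), collapse = "\t"), con)
  for (i in seq_len(nrow(em$values))) {
    writeLines(paste(c(rownames(em$values)[i],
                       format(em$values[i, ], trim = TRUE, digits = 15,
                              scientific = FALSE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
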