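#' Expression matrix container
#'
#' A genes x time-points numeric matrix tagged with the metadata needed by the
#' decay/abundance pipeline: strain, condition, experiment type and value scale.
#' Row names are gene identifiers; column names are sampling times in minutes.
#'
#' @param values numeric matrix, genes in rows, time points in columns.
#' @param times numeric vector of sampling times (minutes), strictly increasing.
#' @param gene_ids character vector of gene identifiers (defaults to rownames).
#' @param strain one of `"wild_type"`, `"mutant"`.
#' @param condition one of `"reference"`, `"oxidative"`, `"mms_like"`.
#' @param experiment one of `"decay"`, `"abundance"`.
#' @param scale one of `"linear_intensity"`, `"log2_to_t0"`.
#' @return An object of class `expression_matrix` (a numeric matrix with
#'   metadata attributes).
#' @export
expression_matrix <- function(values, times,
                              gene_ids = rownames(values),
                              strain = c("wild_type", "mutant"),
                              condition = c("reference", "oxidative", "mms_like"),
                              experiment = c("decay", "abundance"),
                              scale = c("linear_intensity", "log2_to_t0")) {
  strain <- match.arg(strain)
  condition <- match.arg(condition)
  experiment <- match.arg(experiment)
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  times <- as.numeric(times)
  if (length(times) != ncol(values))
    stop("length(times) must equal ncol(values)")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (is.null(gene_ids))
    gene_ids <- paste0("g", seq_len(nrow(values)))
  if (length(gene_ids) != nrow(values))
    stop("gene_ids must have one entry per row")
  if (scale == "linear_intensity" && any(values < 0, na.rm = TRUE))
    stop("linear_intensity values must be non-negative")
  if (scale == "log2_to_t0" && any(abs(values[, 1]) > 1e-8, na.rm = TRUE))
    stop("log2_to_t0 matrices must have a zero first column")
  dimnames(values) <- list(gene_ids, format(times, trim = TRUE))
  structure(values,
            times = times, strain = strain, condition = condition,
            experiment = experiment, scale = scale,
            class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d times [%s, %s, %s, %s]\n",
              nrow(x), ncol(x), attr(x, "strain"), attr(x, "condition"),
              attr(x, "experiment"), attr(x, "scale")))
  cat("times (min):", paste(attr(x, "times"), collapse = ", "), "\n")
  n <- min(4L, nrow(x))
  print(unclass(x)[seq_len(n), , drop = FALSE])
  if (nrow(x) > n) cat("...", nrow(x) - n, "more genes\n")
  invisible(x)
}

#' Times of an expression matrix
#' @param x an `expression_matrix`.
#' @return numeric vector of sampling times in minutes.
#' @export
em_times <- function(x) attr(x, "times")

# rebuild an expression_matrix with new values and possibly new metadata
em_update <- function(x, values, gene_ids = rownames(values), scale = attr(x, "scale")) {
  expression_matrix(values, attr(x, "times"), gene_ids = gene_ids,
                    strain = attr(x, "strain"), condition = attr(x, "condition"),
                    experiment = attr(x, "experiment"), scale = scale)
}

#' Write an expression matrix as TSV
#'
#' Layout: first column `gene_id`, remaining columns are times in minutes.
#' Metadata tags are written as `#key: value` header comment lines so that a
#' round trip through [read_expression_tsv()] restores the object.
#'
#' @param x an `expression_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in c("strain", "condition", "experiment", "scale"))
    writeLines(sprintf("#%s: %s", key, attr(x, key)), con)
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(format(df, digits = 15, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_tsv()]
#' @param path TSV file path.
#' @return An `expression_matrix`.
#' @export
read_expression_tsv <- function(path) {
  header <- readLines(path, n = 10L)
  meta <- header[startsWith(header, "#")]
  tags <- list(strain = "wild_type", condition = "reference",
               experiment = "decay", scale = "linear_intensity")
  for (line in meta) {
    kv <- strsplit(sub("^#", "", line), ":\\s*")[[1]]
    if (length(kv) == 2 && kv[1] %in% names(tags)) tags[[kv[1]]] <- kv[2]
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene_id
  expression_matrix(values, as.numeric(colnames(values)), gene_ids = df$gene_id,
                    strain = tags$strain, condition = tags$condition,
                    experiment = tags$experiment, scale = tags$scale)
}
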