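# All tabular outputs are TAB-separated UTF-8 with "." decimals; floats
# are serialized with 12 significant digits so write/read round-trips
# are stable.
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.12g", x))
}

.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- .fmt_num(out[[j]])
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read a log2 expression matrix as TSV
#'
#' Probesets in rows, samples in columns; the first column
#' (`probeset_id`) holds the row identifiers. Values round-trip at 12
#' significant digits. The reader rejects duplicated probeset or sample
#' ids and reports the location of any non-numeric cell.
#'
#' @param matrix numeric matrix with dimnames.
#' @param path file path.
#' @return `write_expression_matrix` the path, invisibly;
#'   `read_expression_matrix` the numeric matrix.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(probeset_id = rownames(matrix),
                   apply(matrix, 2, .fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "probeset_id") {
    stop("first column must be 'probeset_id'")
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicated probeset id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicated sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  m <- matrix(NA_real_, length(ids), length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) & df[[j + 1]] != "NA")
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   df[[j + 1]][bad[1]], bad[1], samples[j]))
    }
    m[, j] <- v
  }
  if (anyNA(m)) stop("missing values in expression matrix")
  m
}

#' Write / read a sample design table as TSV
#'
#' Columns: sample_id, sex, genotype, stage, replicate.
#' @param design data.frame.
#' @param path file path.
#' @export
write_sample_design <- function(design, path) .write_tsv(design, path)

#' @rdname write_sample_design
#' @export
read_sample_design <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "genotype", "stage", "replicate")
  if (!all(need %in% names(df))) {
    stop("design must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in design")
  key <- df[, c("sex", "genotype", "stage", "replicate")]
  if (anyDuplicated(key)) stop("duplicated (sex, genotype, stage, replicate) rows")
  df$replicate <- as.integer(df$replicate)
  df
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name TAB description TAB member ids. Empty member
#' lists are rejected; duplicate members within a line are deduplicated
#' with a warning.
#'
#' @param programs a [gene_program()] or list of them.
#' @param path file path.
#' @param level level to assign to programs read from file.
#' @return `read_gene_sets` a named list of [gene_program()]s.
#' @export
write_gene_sets <- function(programs, path) {
  if (inherits(programs, "gene_program")) programs <- list(programs)
  lines <- vapply(programs, function(p) {
    paste(c(p$name, p$provenance %||% "", p$members), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_gene_sets
#' @export
read_gene_sets <- function(path, level = c("gene", "probeset")) {
  level <- match.arg(level)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("malformed GMT line ", i, ": need name, description and >=1 member")
    }
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop("malformed GMT line ", i, ": empty member list")
    }
    if (anyDuplicated(members)) {
      warning("GMT line ", i, " (", parts[1], "): duplicate members deduplicated")
      members <- unique(members)
    }
    out[[parts[1]]] <- gene_program(parts[1], members, level = level,
                                    provenance = parts[2])
  }
  out
}

#' Write / read NanoString count tables as CSV
#'
#' Columns: probe_id, probe_class, sample_id, count. The reader
#' validates probe classes, non-negative counts and record uniqueness.
#'
#' @param counts long count data.frame.
#' @param path file path.
#' @export
write_nanostring_counts <- function(counts, path) {
  write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_nanostring_counts
#' @export
read_nanostring_counts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.numeric(df$count)) stop("count column must be numeric")
  validate_nanostring_counts(df)
}

#' Write a generic result table as TSV
#'
#' @param table data.frame.
#' @param path file path.
#' @export
write_result_table <- function(table, path) .write_tsv(table, path)
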