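#' Expression matrix container
#'
#' An expression matrix is a plain numeric matrix (features in rows, samples
#' in columns) carrying a `platform` attribute that records the measurement
#' scale: `"counts"` for raw sequencing counts, `"intensity"` for log-scale
#' microarray intensities, and `"normalized"` for values that have been put
#' through a normalizing transform (and are therefore on a log-like scale).
#'
#' @param values numeric matrix with unique rownames (feature ids) and unique
#'   colnames (sample ids).
#' @param platform one of `"counts"`, `"intensity"`, `"normalized"`.
#' @return the matrix with class `expr_matrix` prepended and the platform
#'   attribute set.
#' @export
expr_matrix <- function(values, platform = c("counts", "intensity", "normalized")) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have feature rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite")
  if (platform == "counts" && (any(values < 0) || any(values != round(values))))
    stop("counts must be nonnegative integers")
  structure(values, platform = platform,
            class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples [%s]\n",
              nrow(x), ncol(x), platform_of(x)))
  invisible(x)
}

#' Platform tag of an expression matrix
#' @param x an `expr_matrix` (or a matrix with a `platform` attribute).
#' @return the platform string; `"normalized"` if the attribute is absent.
#' @export
platform_of <- function(x) {
  p <- attr(x, "platform")
  if (is.null(p)) "normalized" else p
}

# strip the class/attribute for internal arithmetic
as_plain_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "platform") <- NULL
  y
}

#' Read an expression matrix from TSV/CSV
#'
#' First column holds the feature ids, the header row the sample ids.
#' The field separator is taken from the file extension (`.csv` means comma,
#' anything else tab).
#'
#' @param path file path.
#' @param platform platform tag to attach (see [expr_matrix()]).
#' @return an [expr_matrix()].
#' @export
read_expression <- function(path, platform = c("counts", "intensity", "normalized")) {
  platform <- match.arg(platform)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature id(s) in ", path, ": ", paste(dup, collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1))))
    stop("non-numeric expression cells in ", path)
  m <- as.matrix(vals)
  rownames(m) <- ids
  expr_matrix(m, platform)
}

#' Write an expression matrix to TSV
#' @param x an [expr_matrix()] or plain matrix with dimnames.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), as_plain_matrix(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample annotations
#'
#' Annotations are a data frame with columns `sample_id`, `subtype`
#' (EMT / MSI / TP53+ / TP53- / NA), `age` (years), `sex` (male / female),
#' `time` (follow-up), `event` (0/1) and optional `stage`.
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  validate_annotations(df)
  df
}

#' @rdname read_annotations
#' @param ann annotation data frame.
#' @export
write_annotations <- function(ann, path) {
  validate_annotations(ann)
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_annotations <- function(ann) {
  need <- c("sample_id", "subtype", "age", "sex")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample ids in annotations")
  if ("event" %in% names(ann) && !all(ann$event %in% c(0, 1, NA)))
    stop("event must be 0/1")
  if (any(!is.na(ann$age) & ann$age <= 0)) stop("age must be positive")
  invisible(TRUE)
}

#' Read a gene network from an edge-list TSV or SIF file
#'
#' Edge lists have two (optionally three: a confidence score) columns; SIF
#' rows are `node relation node [node ...]`. The result is a simple
#' undirected [igraph::graph] (self loops and duplicate edges dropped).
#'
#' @param path file path; `.sif` selects SIF parsing.
#' @return an undirected igraph object.
#' @export
read_network <- function(path) {
  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    el <- do.call(rbind, lapply(strsplit(lines, "[\t ]+"), function(f) {
      if (length(f) < 3L) return(NULL)
      cbind(f[1L], f[-(1:2)])
    }))
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
    el <- as.matrix(df[, 1:2])
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Write a gene network
#' @param g igraph object.
#' @param path output path.
#' @param format `"tsv"` (2-column edge list with header) or `"sif"`.
#' @param relation SIF relation tag.
#' @export
write_network <- function(g, path, format = c("tsv", "sif"), relation = "pp") {
  format <- match.arg(format)
  el <- igraph::as_edgelist(g)
  if (format == "tsv") {
    utils::write.table(data.frame(source = el[, 1], target = el[, 2]),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(paste(el[, 1], relation, el[, 2], sep = "\t"), path)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT path (set name, description, then member ids per line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t")
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, character(1), 1L))
}

#' Read / write a miRNA-target table
#'
#' Columns: `mirna`, `gene`, `validated` (logical).
#' @param path file path.
#' @return data frame.
#' @export
read_target_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("mirna", "gene") %in% names(df)))
    stop("target table needs 'mirna' and 'gene' columns")
  if (is.null(df$validated)) df$validated <- TRUE
  df
}

#' @rdname read_target_table
#' @param targets target table data frame.
#' @export
write_target_table <- function(targets, path) {
  utils::write.table(targets, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
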