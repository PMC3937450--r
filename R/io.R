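# sniff the field separator of a delimited text file (tab canonical,
# comma accepted)
sniff_sep <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else "\t"
}

#' Read an expression matrix from TSV/CSV
#'
#' Samples in rows, features in columns, header row of feature labels; an
#' optional first column of sample identifiers is auto-detected (non-numeric
#' first column). Missing or non-numeric cells are an error.
#'
#' @param path File path.
#' @return Numeric matrix (samples x features) with dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) >= 2 && !is.numeric(df[[1]])) {
    rn <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
    rownames(df) <- rn
  }
  nonnum <- !vapply(df, is.numeric, logical(1))
  if (any(nonnum)) {
    stop("non-numeric values in column(s): ",
         paste(names(df)[nonnum], collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(df)
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop("missing value at row ", idx[1], ", column '",
         colnames(x)[idx[2]], "' of ", path, call. = FALSE)
  }
  as_expression_matrix(x)
}

#' Write an expression matrix as TSV
#'
#' @param x Samples x features matrix or data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  x <- as_expression_matrix(x)
  df <- data.frame(sample = if (is.null(rownames(x)))
    paste0("s", seq_len(nrow(x))) else rownames(x),
    x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network from an adjacency matrix or edge list file
#'
#' `format = "adjacency"`: square numeric table, optional header row plus
#' first label column (auto-detected). `format = "edgelist"`: columns
#' `node1`, `node2`, `weight`; duplicate pairs are an error, missing pairs
#' get weight 0.
#'
#' @param path File path.
#' @param format `"adjacency"` (default) or `"edgelist"`.
#' @return A `netsi_network`.
#' @export
read_network <- function(path, format = c("adjacency", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sniff_sep(path)
  if (format == "adjacency") {
    first <- strsplit(readLines(path, n = 1L, warn = FALSE), sep, fixed = TRUE)[[1]]
    has_header <- anyNA(suppressWarnings(as.numeric(first)))
    df <- utils::read.table(path, header = has_header, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    labels <- NULL
    if (ncol(df) == nrow(df) + 1 && !is.numeric(df[[1]])) {
      labels <- as.character(df[[1]])
      df <- df[, -1, drop = FALSE]
    }
    a <- as.matrix(df)
    if (is.null(labels) && has_header) labels <- colnames(df)
    as_network(`dimnames<-`(a, NULL), labels)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3) stop("edge list needs columns node1, node2, weight",
                           call. = FALSE)
    n1 <- as.character(df[[1]])
    n2 <- as.character(df[[2]])
    w <- as.numeric(df[[3]])
    key <- paste(pmin(n1, n2), pmax(n1, n2))
    if (anyDuplicated(key)) {
      stop("duplicate node pair(s) in edge list: ",
           paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
    }
    labels <- sort(unique(c(n1, n2)))
    a <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
    for (r in seq_along(w)) {
      a[n1[r], n2[r]] <- w[r]
      a[n2[r], n1[r]] <- w[r]
    }
    as_network(a)
  }
}

#' Write a network to TSV
#'
#' Adjacency output is a labelled square table (weights at full double
#' precision, lossless round trip); edge-list output has columns `node1`,
#' `node2`, `weight` for nonzero pairs.
#'
#' @param net A `netsi_network`.
#' @param path Output path.
#' @param format `"adjacency"` (default) or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("adjacency", "edgelist")) {
  format <- match.arg(format)
  net <- as_network(net)
  if (format == "adjacency") {
    a <- unclass(net)
    df <- data.frame(node = rownames(a),
                     format(a, digits = 17, trim = TRUE, scientific = TRUE),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    el <- tidy.netsi_network(net)
    utils::write.table(
      data.frame(node1 = el$from, node2 = el$to,
                 weight = format(el$weight, digits = 17, trim = TRUE)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
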