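.detectDelim <- function(line, delimiter) {
  if (delimiter != "auto") return(delimiter)
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

#' Read a labeled expression matrix
#'
#' Reads rectangular delimited text with a header row of variable ids and a
#' leading column of observation ids. The delimiter is auto-detected between
#' tab and comma unless given. With \code{orientation = "columns"} the file
#' stores observations in columns (e.g. probes x samples for sample
#' clustering) and is transposed on read, so the returned matrix always has
#' observations in rows.
#'
#' @param path file path.
#' @param delimiter \code{"auto"} (default), \code{"\t"} or \code{","}.
#' @param orientation \code{"rows"} if observations are file rows (default),
#'   \code{"columns"} if they are file columns.
#' @return numeric matrix with row and column names.
#' @examples
#' f <- tempfile()
#' writeExpressionMatrix(matrix(1:4, 2, dimnames = list(c("o1", "o2"),
#'                                                      c("v1", "v2"))), f)
#' readExpressionMatrix(f)
#' @export
readExpressionMatrix <- function(path, delimiter = "auto",
                                 orientation = c("rows", "columns")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("matrix file needs a header and data rows")
  sep <- .detectDelim(lines[1], delimiter)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1]]
  ncolData <- length(header) - 1L
  if (ncolData < 1L) stop("no data columns found")
  colIds <- header[-1]
  rowIds <- character(length(fields) - 1L)
  vals <- matrix(NA_real_, length(fields) - 1L, ncolData)
  for (i in seq_along(fields)[-1]) {
    f <- fields[[i]]
    if (length(f) != length(header))
      stop(sprintf("ragged row at line %d: %d fields, expected %d",
                   i, length(f), length(header)))
    rowIds[i - 1L] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v))
      stop(sprintf("non-numeric cell at line %d, column '%s'",
                   i, colIds[which(is.na(v))[1]]))
    vals[i - 1L, ] <- v
  }
  if (anyDuplicated(rowIds)) stop("duplicate row ids")
  if (anyDuplicated(colIds)) stop("duplicate column ids")
  dimnames(vals) <- list(rowIds, colIds)
  if (orientation == "columns") vals <- t(vals)
  vals
}

#' @param X labeled numeric matrix to write (observations in rows).
#' @param sep field delimiter.
#' @rdname readExpressionMatrix
#' @export
writeExpressionMatrix <- function(X, path, sep = "\t") {
  stopifnot(is.matrix(X))
  if (is.null(rownames(X))) rownames(X) <- sprintf("obs%d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read flat partitions
#'
#' Two-column delimited text (id, cluster label), one observation per row, in
#' a deterministic (input) order.
#'
#' @param partition named factor or vector of cluster labels.
#' @param path file path.
#' @param sep field delimiter.
#' @return \code{readPartition} returns a named factor.
#' @examples
#' f <- tempfile()
#' writePartition(c(s1 = 1, s2 = 1, s3 = 2), f)
#' readPartition(f)
#' @export
writePartition <- function(partition, path, sep = "\t") {
  ids <- names(partition) %||% sprintf("obs%d", seq_along(partition))
  utils::write.table(
    data.frame(id = ids, cluster = as.character(partition)),
    path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePartition
#' @export
readPartition <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character")
  structure(factor(df$cluster), names = df$id)
}

#' Write the dendrogram as annotated Newick
#'
#' Serializes the fitted tree in Newick format. Leaves carry the observation
#' ids; every internal node carries its posterior merge probability r to six
#' decimals in a bracketed comment, and branch lengths encode the
#' dissimilarity height 1 - r (child heights subtracted, floored at zero, so
#' the file stays a valid tree through non-monotone stretches).
#'
#' @param object a \code{\link{GBHCFit}}.
#' @param path file path.
#' @return the path, invisibly.
#' @examples
#' sim <- simulateScenario1(n = 20, d = 4, k = 2, seed = 1)
#' fit <- gbhc(sim$data)
#' f <- tempfile(fileext = ".nwk")
#' writeDendrogram(fit, f)
#' readLines(f)
#' @export
writeDendrogram <- function(object, path) {
  stopifnot(methods::is(object, "GBHCFit"))
  nodes <- object@nodes
  labs <- object@labels
  height <- ifelse(nodes$left == 0L, 0, 1 - nodes$r)
  fmt <- function(id) {
    if (nodes$left[id] == 0L) return(labs[id])
    l <- nodes$left[id]; r <- nodes$right[id]
    bl <- function(child) max(0, height[id] - height[child])
    sprintf("(%s:%.6f,%s:%.6f)[&r=%.6f]",
            fmt(l), bl(l), fmt(r), bl(r), nodes$r[id])
  }
  writeLines(paste0(fmt(nrow(nodes)), ";"), path)
  invisible(path)
}

#' Read functional-class annotations
#'
#' Two-column delimited text (id, class), one row per (id, class) pair;
#' ids may repeat to attach several classes.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return named list mapping each id to its character vector of classes,
#'   suitable for \code{\link{bhi}}.
#' @examples
#' f <- tempfile()
#' writeLines(c("id\tclass", "g1\tGO:1", "g1\tGO:2", "g2\tGO:1"), f)
#' readAnnotations(f)
#' @export
readAnnotations <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("annotation file needs two columns (id, class)")
  split(df[[2]], df[[1]])
}
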