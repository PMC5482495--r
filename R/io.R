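#' Read and write genes x compounds score/FD matrices as TSV
#'
#' The on-disk format is a tab-separated table with one header row of
#' compound ids and a first column of gene ids.  A configurable token
#' (default `"NA"`) marks missing entries.  Lines starting with `#` are
#' treated as comments and skipped.  Writing then reading reproduces finite
#' values bit-exactly and preserves the missing mask.
#'
#' @param path File path.
#' @param missing Token marking a missing value.
#' @return `read_fd_matrix()`: numeric matrix with gene row names and
#'   compound column names.
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' m <- matrix(c(0.5, NA, -1, 2, 0, 3), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
#' write_fd_matrix(m, p)
#' identical(read_fd_matrix(p), m)
#' @export
read_fd_matrix <- function(path, missing = "NA") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 1L) stop("empty matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  ncol_expect <- length(header)
  body <- fields[-1L]
  widths <- lengths(body)
  bad <- which(widths != ncol_expect)
  if (length(bad))
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 bad[1L] + 1L, ncol_expect, widths[bad[1L]]))
  genes <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  compounds <- header[-1L]
  cells <- t(vapply(body, function(f) f[-1L], character(ncol_expect - 1L)))
  # column-count 1 edge: vapply returns a vector
  if (ncol_expect == 2L) cells <- matrix(cells, ncol = 1L)
  vals <- suppressWarnings(as.numeric(cells))
  miss <- cells == missing
  if (any(is.na(vals) & !miss))
    stop("non-numeric cell(s) that are not the missing token '",
         missing, "' in ", path)
  vals[miss] <- NA_real_
  matrix(vals, nrow = length(genes),
         dimnames = list(genes, compounds))
}

#' @param x Numeric matrix (or `score_matrix`) to write.
#' @param comment Optional comment lines written with a leading `#`
#'   (e.g. method/provenance for score matrices).
#' @rdname read_fd_matrix
#' @export
write_fd_matrix <- function(x, path, missing = "NA", comment = NULL) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  if (inherits(x, "score_matrix"))
    writeLines(sprintf("# method=%s orientation=%s", attr(x, "method"),
                       score_orientation(x)), con)
  writeLines(paste(c("gene", colnames(x)), collapse = "\t"), con)
  cells <- format(unclass(x), digits = 17, trim = TRUE, scientific = FALSE)
  cells[is.na(x)] <- missing
  writeLines(paste(rownames(x), apply(cells, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a score matrix TSV, restoring its method/orientation tags
#'
#' Companion to [write_fd_matrix()]: parses the `# method=... orientation=...`
#' comment line written for [score_matrix()] objects; a file without one is
#' read as a low-is-hit FD matrix.
#'
#' @inheritParams read_fd_matrix
#' @return A [score_matrix()].
#' @export
read_score_matrix <- function(path, missing = "NA") {
  x <- read_fd_matrix(path, missing = missing)
  method <- "fd"
  orientation <- "low"
  for (ln in grep("^#", readLines(path, n = 10L), value = TRUE)) {
    m <- regmatches(ln, regexec("method=(\\S+) orientation=(\\S+)", ln))[[1L]]
    if (length(m) == 3L) {
      method <- m[2L]
      orientation <- m[3L]
    }
  }
  score_matrix(x, method = method, orientation = orientation)
}

#' Read a compound-target benchmark table
#'
#' Expects a TSV with columns `compound`, `gene`, `confidence` (header
#' optional but recommended).  Pairs below the confidence threshold are
#' dropped; the STITCH-style convention keeps pairs with confidence exactly
#' at the threshold (the default 0.4 excludes strictly lower-confidence
#' interactions).
#'
#' @param path File path.
#' @param min_confidence Threshold in \[0, 1\]; pairs with
#'   `confidence < min_confidence` are removed.
#' @return A `data.frame` with columns `compound`, `gene`, `confidence`,
#'   deduplicated on (compound, gene); attribute `n_filtered` records the
#'   number of pairs removed by the threshold.
#' @export
read_benchmark <- function(path, min_confidence = 0.4) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"),
                          col.names = c("compound", "gene", "confidence"))
  if (nrow(df) == 0L) {
    warning("empty benchmark file: ", path)
    attr(df, "n_filtered") <- 0L
    return(df)
  }
  if (any(df$confidence < 0 | df$confidence > 1))
    stop("confidence values outside [0, 1] in ", path)
  keep <- df$confidence >= min_confidence
  n_filtered <- sum(!keep)
  if (n_filtered)
    message(n_filtered, " benchmark pair(s) below confidence ",
            min_confidence, " removed")
  df <- df[keep, , drop = FALSE]
  dup <- duplicated(df[c("compound", "gene")])
  if (any(dup)) df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_filtered") <- n_filtered
  df
}

#' Write a benchmark table
#' @param bench Data frame with columns compound, gene, confidence.
#' @rdname read_benchmark
#' @export
write_benchmark <- function(bench, path) {
  utils::write.table(bench[c("compound", "gene", "confidence")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, all
#' tab-separated.  Duplicate members are collapsed.
#'
#' @param path File path.
#' @return Named list of character vectors (the sets, in file order), with
#'   a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 fields (need name, description, >=1 member)",
                 short[1L]))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(fields, `[[`, "", 2L), names(sets))
  sets
}

#' @param sets Named list of character vectors.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}
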