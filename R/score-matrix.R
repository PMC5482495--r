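#' Tag a genes x compounds matrix as a score matrix
#'
#' All scoring methods return plain numeric matrices (rows = genes, columns
#' = compounds, `NA` = missing) tagged with the method name and the hit
#' orientation: `"low"` when low scores flag candidate targets (FD and all
#' GIT variants) or `"high"` when high scores do (the rho-score).
#'
#' @param x Numeric matrix with gene row names and compound column names.
#' @param method Character tag, e.g. `"git_hip"`.
#' @param orientation `"low"` or `"high"`.
#' @param q,order Optional provenance: neighborhood truncation and
#'   propagation order used.
#' @return `x` with class `score_matrix` and attributes set.
#' @export
score_matrix <- function(x, method, orientation = c("low", "high"),
                         q = NULL, order = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("scores must be numeric")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("score matrix needs gene row names and compound column names")
  orientation <- match.arg(orientation)
  structure(x,
            method = method, orientation = orientation,
            q = q, order = order,
            class = c("score_matrix", class(x)))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix [%s, %s-is-hit]: %d genes x %d compounds",
              attr(x, "method"), attr(x, "orientation"), nrow(x), ncol(x)))
  if (!is.null(attr(x, "q"))) cat(sprintf(", q = %s", attr(x, "q")))
  if (!is.null(attr(x, "order"))) cat(sprintf(", order = %d", attr(x, "order")))
  cat(sprintf("; %d missing entries\n", sum(is.na(x))))
  print(unclass(x)[seq_len(min(5L, nrow(x))), seq_len(min(5L, ncol(x))),
                   drop = FALSE], ...)
  if (nrow(x) > 5L || ncol(x) > 5L) cat("...\n")
  invisible(x)
}

score_orientation <- function(x) {
  o <- attr(x, "orientation")
  if (is.null(o)) "low" else o
}

# keep attributes through subsetting while the result is still a matrix
#' @export
`[.score_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out))
    out <- structure(out, method = attr(x, "method"),
                     orientation = attr(x, "orientation"),
                     q = attr(x, "q"), order = attr(x, "order"),
                     class = class(x))
  out
}
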