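#' Construct a growth table
#'
#' A growth table holds raw growth-defect measurements of deletion strains
#' (rows) under treatment and control conditions (columns), the input to
#' [compute_fd()].
#'
#' @param values Numeric matrix of nonnegative growth measurements, rows
#'   named by strain/gene id, columns by condition id. `NA` marks a missing
#'   measurement.
#' @param controls Logical vector, one entry per column, `TRUE` for
#'   no-treatment control conditions.
#' @return An object of class `growth_table`.
#' @examples
#' g <- growth_table(
#'   matrix(c(1, 1, 0.5, 2), 2, 2,
#'          dimnames = list(c("YFG1", "YFG2"), c("ctrl", "drugA"))),
#'   controls = c(TRUE, FALSE))
#' compute_fd(g)
#' @export
growth_table <- function(values, controls) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have strain row names and condition column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate strain ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (length(controls) != ncol(values))
    stop("'controls' must have one entry per condition")
  controls <- as.logical(controls)
  if (any(values < 0, na.rm = TRUE))
    stop("growth values must be nonnegative")
  structure(list(values = values, controls = controls),
            class = "growth_table")
}

#' @export
print.growth_table <- function(x, ...) {
  cat(sprintf("growth_table: %d strains x %d conditions (%d controls)\n",
              nrow(x$values), ncol(x$values), sum(x$controls)))
  invisible(x)
}

#' Fitness-defect (FD) scores from raw growth measurements
#'
#' The FD-score of strain i under compound c is the log-ratio of its growth
#' defect under treatment to its mean growth defect across control
#' conditions: `FD_ic = log(r_ic / rbar_i)`.  Low (negative) FD means the
#' strain is hypersensitive to the compound, flagging a putative
#' compound-gene interaction.
#'
#' Entries where `r_ic` or `rbar_i` is missing or nonpositive become `NA`
#' (never infinite).  Control means use the arithmetic mean over the
#' included control conditions, ignoring missing values.
#'
#' @param growth A [growth_table()].
#' @param log_base Base of the logarithm; 2 by default. Downstream scores
#'   are covariant with the base, so this only rescales.
#' @param control_include Optional logical vector over conditions; controls
#'   with `FALSE` are excluded from the per-strain control mean.
#' @return Numeric matrix of FD-scores (genes x compounds); control columns
#'   are dropped. Carries class `fd_matrix` via [score_matrix()] semantics:
#'   plain matrix, `NA` for missing.
#' @seealso [git_hip()], [rho_score()]
#' @export
compute_fd <- function(growth, log_base = 2, control_include = NULL) {
  stopifnot(inherits(growth, "growth_table"))
  if (log_base <= 0 || log_base == 1)
    stop("'log_base' must be positive and != 1")
  ctrl <- growth$controls
  if (!is.null(control_include)) {
    if (length(control_include) != length(ctrl))
      stop("'control_include' must have one entry per condition")
    ctrl <- ctrl & control_include
  }
  if (!any(ctrl))
    stop("no control conditions available for the control mean")
  vals <- growth$values
  cvals <- vals[, ctrl, drop = FALSE]
  rbar <- rowMeans(cvals, na.rm = TRUE)          # NaN if all controls missing
  no_ctrl <- !is.finite(rbar)
  if (any(no_ctrl)) {
    warning("all control measurements missing for strain(s): ",
            paste(rownames(vals)[no_ctrl], collapse = ", "),
            "; their FD rows are all-missing")
    rbar[no_ctrl] <- NA_real_
  }
  rbar[!is.na(rbar) & rbar <= 0] <- NA_real_     # nonpositive mean -> missing
  treat <- vals[, !growth$controls, drop = FALSE]
  treat[treat <= 0] <- NA_real_                  # nonpositive ratio -> missing
  fd <- log(treat / rbar, base = log_base)
  score_matrix(fd, method = "fd", orientation = "low")
}
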