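# Metadata projection: the experiment-by-component weighting matrix
# M = V_d M_d, and its product with the binary class-by-experiment label
# indicator P to give the class-by-component metadata matrix P_d = P M.

#' Experiment-by-component weighting matrix
#'
#' `weights = experiment_modes %*% mixing`: each row gives the weighting of
#' every component in one experiment's modeled-activation image.
#'
#' @param experiment_modes `e x d` matrix of scaled experiment-mode
#'   singular vectors (from [reduce_svd()] / a `decomposition`).
#' @param mixing `d x d` mixing matrix of the decomposition.
#' @return Numeric matrix `e x d` of class `experiment_weights`.
#' @export
experiment_weights <- function(experiment_modes, mixing) {
  experiment_modes <- as.matrix(experiment_modes)
  mixing <- as.matrix(mixing)
  if (ncol(experiment_modes) != nrow(mixing) || nrow(mixing) != ncol(mixing))
    stopf("shape mismatch: experiment_modes is %d x %d but mixing is %d x %d",
          nrow(experiment_modes), ncol(experiment_modes),
          nrow(mixing), ncol(mixing))
  w <- experiment_modes %*% mixing
  class(w) <- c("experiment_weights", class(w))
  w
}

#' Project metadata labels onto components
#'
#' `values = label_matrix %*% weights`: the row for a class is the sum of
#' the weight rows of the experiments carrying that class, quantifying how
#' strongly the class relates to each component.  Binary indicators are
#' the intended input; fractional label weights are accepted (weighted
#' sum) as an extension.
#'
#' @param label_matrix `n classes x e experiments` indicator matrix.
#' @param weights `e x d` [experiment_weights()].
#' @param normalize divide each class row by its label count (off by
#'   default; the projection is reported unnormalized, a per-frequency
#'   normalization is provided for sensitivity analysis).
#' @param provenance optional list (seed, corpus id, ...) carried along.
#' @return A `metadata_matrix`: list with `values` (`n x d`),
#'   `class_names`, `d`, `provenance`.
#' @export
project_metadata <- function(label_matrix, weights, normalize = FALSE,
                             provenance = list()) {
  P <- as.matrix(label_matrix)
  W <- unclass(as.matrix(weights))
  if (ncol(P) != nrow(W))
    stopf("shape mismatch: label_matrix has %d experiments but weights has %d rows",
          ncol(P), nrow(W))
  vals <- P %*% W
  if (normalize) {
    counts <- rowSums(P)
    vals <- vals / ifelse(counts > 0, counts, 1)
  }
  structure(
    list(
      values = vals,
      class_names = rownames(P) %||% sprintf("class%03d", seq_len(nrow(P))),
      d = ncol(W),
      provenance = provenance
    ),
    class = "metadata_matrix"
  )
}

#' @export
print.metadata_matrix <- function(x, ...) {
  cat(sprintf("<metadata_matrix> %d classes x %d components\n",
              nrow(x$values), x$d))
  invisible(x)
}

#' Write a metadata matrix as CSV
#'
#' Classes as rows, components as columns; provenance (d, seed, ...) is
#' written as `#`-prefixed header lines before the table.
#'
#' @param meta a `metadata_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata_matrix <- function(meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# d=%d", meta$d), con)
  for (nm in names(meta$provenance))
    writeLines(sprintf("# %s=%s", nm, meta$provenance[[nm]]), con)
  df <- data.frame(class = meta$class_names, meta$values, check.names = FALSE)
  colnames(df)[-1] <- sprintf("component%02d", seq_len(meta$d))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
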