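# The metadata label space of a coordinate-database corpus: experiments
# carry labels from two taxonomy fields, paradigm class (the task
# performed during acquisition) and behavioral domain (the category of
# cognitive process isolated by the contrast).

#' The combined metadata class space
#'
#' Generic placeholder names for the standard two-field taxonomy used to
#' label coordinate-database experiments: `n_paradigm` paradigm classes
#' plus `n_behavioral` behavioral domains.  The defaults are the field
#' sizes of the BrainMap Scribe taxonomy (75 paradigm classes, 50
#' behavioral domains); the class *names* here are placeholders, as the
#' taxonomy's content is external to this package.
#'
#' @param n_paradigm number of paradigm classes (default 75).
#' @param n_behavioral number of behavioral domains (default 50).
#' @return Data frame with columns `class` (generic name) and `field`
#'   (`"paradigm"` or `"behavioral_domain"`); the combined class count is
#'   its row count.
#' @export
metadata_class_space <- function(n_paradigm = 75, n_behavioral = 50) {
  rbind(
    data.frame(class = sprintf("paradigm%03d", seq_len(n_paradigm)),
               field = "paradigm"),
    data.frame(class = sprintf("domain%03d", seq_len(n_behavioral)),
               field = "behavioral_domain")
  )
}
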