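# Contact-preservation predictor: an interface substitution that still
# makes atom contacts across the interface in the paralogue model is
# predicted to maintain the interaction; any substitution that does not is
# predicted to alter it. Predictions are evaluated against observed
# interaction status with conserved interaction as the positive class.

#' Does a substituted interface residue keep atom contacts across the
#' interface?
#'
#' Checks, in the paralogue model (same coordinate frame as the template),
#' whether any atom of the substituted residue contacts any atom of the
#' partner chain under the same van der Waals + margin criterion used for
#' interface detection. A substitution to a gap (deletion) never preserves
#' the contact.
#'
#' @param model paralogue [complex_structure()] superimposed on the
#'   template frame.
#' @param chain chain carrying the substitution.
#' @param partner_chain the chain across the interface.
#' @param residue_index substituted residue (1-based).
#' @param from_type,to_type residue types (one-letter; `to_type = "-"` for
#'   a deletion).
#' @param margin contact margin in Angstroms (default 0.5) -- one source of
#'   truth with [detect_atom_contacts()].
#' @return List of class `contact_outcome`: `chain`, `residue_index`,
#'   `from_type`, `to_type`, `preserved`, `n_contacts`.
#' @export
substitution_contact_outcome <- function(model, chain, partner_chain,
                                         residue_index, from_type = NA,
                                         to_type = NA, margin = 0.5) {
  if (identical(to_type, "-")) {
    return(structure(list(chain = chain, residue_index = residue_index,
                          from_type = from_type, to_type = to_type,
                          preserved = FALSE, n_contacts = 0L),
                     class = "contact_outcome"))
  }
  at <- model$atoms
  if (!any(at$chain_id == chain & at$residue_index == residue_index))
    stop("residue ", chain, ":", residue_index, " absent from model")
  contacts <- detect_atom_contacts(model, chain, partner_chain,
                                   margin = margin)
  n <- sum(contacts$residue_a == residue_index)
  structure(list(chain = chain, residue_index = residue_index,
                 from_type = from_type, to_type = to_type,
                 preserved = n > 0, n_contacts = as.integer(n)),
            class = "contact_outcome")
}

#' Predict interaction conservation from substitution contact outcomes
#'
#' Diverged as soon as one substitution fails to maintain its atom
#' contacts; conserved otherwise, including the no-substitution case.
#'
#' @param outcomes list of `contact_outcome` objects (possibly empty) for
#'   one pair/interface.
#' @return `"conserved"` or `"diverged"`.
#' @export
predict_interaction_conservation <- function(outcomes) {
  preserved <- vapply(outcomes, function(o) isTRUE(o$preserved), logical(1))
  if (length(preserved) && any(!preserved)) "diverged" else "conserved"
}

#' Evaluate interaction-conservation predictions
#'
#' Contingency counts and precision/recall/F-score with conserved
#' interaction as the positive class; zero-denominator metrics are 0 by
#' convention.
#'
#' @param predicted,observed equal-length vectors of `"conserved"` /
#'   `"diverged"`.
#' @return List of class `classification_evaluation`: `tp`, `fp`, `fn`,
#'   `tn`, `precision`, `recall`, `f_score`.
#' @export
evaluate_predictions <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed differ in length")
  lv <- c("conserved", "diverged")
  if (!all(predicted %in% lv) || !all(observed %in% lv))
    stop("labels must be 'conserved' or 'diverged'")
  tp <- sum(predicted == "conserved" & observed == "conserved")
  fp <- sum(predicted == "conserved" & observed == "diverged")
  fn <- sum(predicted == "diverged" & observed == "conserved")
  tn <- sum(predicted == "diverged" & observed == "diverged")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f_score = f),
            class = "classification_evaluation")
}

#' @export
print.classification_evaluation <- function(x, ...) {
  cat("classification (positive = conserved interaction):\n",
      sprintf("  tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn),
      sprintf("  precision=%.3f recall=%.3f F=%.3f (%.1f)\n",
              x$precision, x$recall, x$f_score, round(x$f_score, 1)),
      sep = "")
  invisible(x)
}

#' Write predictions and their evaluation
#'
#' @param pair_ids,predicted,observed equal-length vectors.
#' @param tsv_path predictions TSV (pair, predicted, observed).
#' @param json_path evaluation JSON (tp, fp, fn, tn, precision, recall,
#'   f_score).
#' @return The `classification_evaluation`, invisibly.
#' @export
write_prediction_report <- function(pair_ids, predicted, observed,
                                    tsv_path, json_path) {
  utils::write.table(data.frame(pair = pair_ids, predicted = predicted,
                                observed = observed),
                     tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- evaluate_predictions(predicted, observed)
  jsonlite::write_json(unclass(ev), json_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(ev)
}
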