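# The six treatment strategies: adjuvant duration crossed with the drug
# sequence given on recurrence/progression.

#' Health states of the cohort model
#'
#' Eight states: four no-recurrence states distinguishing adjuvant history
#' (never treated, on adjuvant imatinib, completed the course, discontinued
#' for toxicity), three metastatic-recurrence treatment lines (imatinib,
#' sunitinib, best supportive care) and absorbing death. The no-recurrence
#' split is needed because the treatment sequence after recurrence depends
#' on adjuvant history.
#'
#' @return Character vector of state names, in canonical order.
#' @export
gist_states <- function() {
  c("NoRec_NoAdj", "NoRec_OnAdj", "NoRec_Completed", "NoRec_Discontinued",
    "Rec_Imatinib", "Rec_Sunitinib", "Rec_BSC", "Dead")
}

.rec_state_for <- function(line) {
  switch(line,
         Imatinib = "Rec_Imatinib",
         Sunitinib = "Rec_Sunitinib",
         BSC = "Rec_BSC",
         stop("unknown treatment line '", line, "'"))
}

#' Build one of the six treatment strategies
#'
#' Encodes the alternative pathways compared by the analysis:
#' * Option 1 (current practice): no adjuvant therapy; on recurrence
#'   imatinib, then best supportive care (BSC) on progression.
#' * Option 2.1 / 2.2: adjuvant imatinib for 1 / 3 years. Recurrence during
#'   adjuvant therapy goes straight to BSC; recurrence after completion is
#'   treated with imatinib, then BSC.
#' * Option 3.1 / 3.2: adjuvant imatinib for 1 / 3 years. Recurrence during
#'   adjuvant therapy gets sunitinib, then BSC; recurrence after completion
#'   gets imatinib, then sunitinib, then BSC.
#' * Option 4: no adjuvant therapy; imatinib, then sunitinib, then BSC.
#'
#' Patients who discontinue adjuvant imatinib (toxicity) and later recur
#' follow the during-adjuvant sequence: they are imatinib-intolerant, so
#' re-treatment with imatinib is excluded.
#'
#' @param option_id One of `"1"`, `"2.1"`, `"2.2"`, `"3.1"`, `"3.2"`, `"4"`
#'   (numeric accepted).
#' @return Object of class `gist_strategy` with fields `option_id`,
#'   `adjuvant_months`, `during_sequence`, `after_sequence`, `hr_param`.
#' @export
make_strategy <- function(option_id) {
  id <- as.character(option_id)
  defs <- list(
    "1"   = list(adj = 0,  during = NULL,
                 after = c("Imatinib", "BSC")),
    "2.1" = list(adj = 12, during = c("BSC"),
                 after = c("Imatinib", "BSC")),
    "2.2" = list(adj = 36, during = c("BSC"),
                 after = c("Imatinib", "BSC")),
    "3.1" = list(adj = 12, during = c("Sunitinib", "BSC"),
                 after = c("Imatinib", "Sunitinib", "BSC")),
    "3.2" = list(adj = 36, during = c("Sunitinib", "BSC"),
                 after = c("Imatinib", "Sunitinib", "BSC")),
    "4"   = list(adj = 0,  during = NULL,
                 after = c("Imatinib", "Sunitinib", "BSC"))
  )
  if (!id %in% names(defs)) {
    stop("unknown option '", id, "'; valid options: ",
         paste(names(defs), collapse = ", "))
  }
  d <- defs[[id]]
  if (!is.null(d$during) && d$during[length(d$during)] != "BSC") {
    stop("internal: during-adjuvant sequence must end in BSC")
  }
  structure(list(
    option_id = id,
    adjuvant_months = d$adj,
    during_sequence = d$during,
    after_sequence = d$after,
    hr_param = if (d$adj == 12) "hr_adjuvant_1yr"
               else if (d$adj == 36) "hr_adjuvant_3yr" else NA_character_,
    start_state = if (d$adj > 0) "NoRec_OnAdj" else "NoRec_NoAdj"
  ), class = "gist_strategy")
}

#' @export
print.gist_strategy <- function(x, ...) {
  cat(sprintf("Option %s: adjuvant imatinib %s; recurrence after adjuvant/none: %s%s\n",
              x$option_id,
              if (x$adjuvant_months == 0) "none" else paste(x$adjuvant_months, "months"),
              paste(x$after_sequence, collapse = " -> "),
              if (is.null(x$during_sequence)) ""
              else paste0("; during adjuvant: ",
                          paste(x$during_sequence, collapse = " -> "))))
  invisible(x)
}

#' All six strategies
#'
#' @return Named list of `gist_strategy` objects.
#' @export
all_strategies <- function() {
  ids <- c("1", "4", "2.1", "2.2", "3.1", "3.2")
  stats::setNames(lapply(ids, make_strategy), ids)
}
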