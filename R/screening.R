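# Four-step prescription-simplification screen:
#   1. main-component membership (e.g. from HPLC-reported constituents)
#   2. Lipinski Rule of Five drug-likeness
#   3. HIA and BBB positive-probability gates
#   4. compound-disease enrichment significance (q < q*)
# A compound is retained iff it passes all four. "Ineligible" (missing
# data) is distinct from "fail" so curation gaps stay visible; ineligible
# gates yield NA flags and the compound is not retained.

#' Lipinski Rule-of-Five gate
#'
#' Strict inequalities, exactly: MW < 500, AlogP < 5, H-bond donors < 5,
#' H-bond acceptors < 10. Any missing field makes the compound ineligible
#' (`NA`), not a pass.
#'
#' @param mw molecular weight in Da (or a list/data.frame row with fields
#'   `mw`, `alogp`, `hbd`, `hba`).
#' @param alogp AlogP partition estimate.
#' @param hbd H-bond donor count.
#' @param hba H-bond acceptor count.
#' @return logical (vectorized): `TRUE` pass, `FALSE` fail, `NA`
#'   ineligible.
#' @export
lipinski_pass <- function(mw, alogp = NULL, hbd = NULL, hba = NULL) {
  if (is.list(mw)) {
    p <- mw
    alogp <- p$alogp; hbd <- p$hbd; hba <- p$hba; mw <- p$mw
  }
  mw < 500 & alogp < 5 & hbd < 5 & hba < 10
}

#' HIA/BBB admission gate
#'
#' Passes when both the human-intestinal-absorption and blood-brain-barrier
#' positive probabilities reach the threshold (boundary inclusive). Missing
#' probabilities make the compound ineligible (`NA`).
#'
#' @param hia_prob HIA positive probability in `[0,1]` (or a list with
#'   `hia_prob`, `bbb_prob`).
#' @param bbb_prob BBB positive probability in `[0,1]`.
#' @param threshold positive-call cutoff, default 0.5.
#' @return logical (vectorized): `TRUE`/`FALSE`/`NA`.
#' @export
admet_gate <- function(hia_prob, bbb_prob = NULL, threshold = 0.5) {
  if (is.list(hia_prob)) {
    s <- hia_prob
    bbb_prob <- s$bbb_prob; hia_prob <- s$hia_prob
  }
  hia_prob >= threshold & bbb_prob >= threshold
}

#' Four-step active-ingredient screen
#'
#' Applies the full prescription-simplification screen to a compound table
#' and reports a per-compound audit trail: every gate is evaluated for every
#' compound (when computable), and a compound is retained iff all four are
#' `TRUE`. The gates are a pure conjunction, so their order is immaterial.
#'
#' @param main_components character vector of compound ids reported as main
#'   constituents (step 1). Ids absent from `compounds` are dropped with a
#'   warning.
#' @param compounds compound data.frame ([read_compound_table()] columns).
#' @param enrichment an `enrichment_result`
#'   ([compound_disease_enrichment()]) or any data.frame with
#'   `compound_id` and `q`; compounds missing from it have an ineligible
#'   step 4.
#' @param admet_threshold HIA/BBB positive-call cutoff (default 0.5).
#' @param q_star enrichment significance level (default 0.05).
#' @return a `screen_report` data.frame, one row per input compound:
#'   `compound_id`, `name`, the four step flags, and `retained`. Attributes
#'   record the parameters and the retained id set.
#' @export
four_step_screen <- function(main_components, compounds, enrichment,
                             admet_threshold = 0.5, q_star = 0.05) {
  main_components <- unique(as.character(main_components))
  missing_mc <- setdiff(main_components, compounds$compound_id)
  if (length(missing_mc) > 0)
    warning("main component(s) absent from compound table, excluded: ",
            paste(missing_mc, collapse = ", "), call. = FALSE)

  q_of <- stats::setNames(enrichment$q, enrichment$compound_id)

  step1 <- compounds$compound_id %in% main_components
  step2 <- lipinski_pass(compounds$mw, compounds$alogp,
                         compounds$hbd, compounds$hba)
  step3 <- admet_gate(compounds$hia_prob, compounds$bbb_prob,
                      threshold = admet_threshold)
  q <- unname(q_of[compounds$compound_id])
  step4 <- q < q_star

  retained <- step1 & !is.na(step2) & step2 & !is.na(step3) & step3 &
    !is.na(step4) & step4
  out <- data.frame(compound_id = compounds$compound_id,
                    name = compounds$name,
                    step1_main_component = step1,
                    step2_ro5 = step2,
                    step3_admet = step3,
                    q = q,
                    step4_enrichment = step4,
                    retained = retained,
                    stringsAsFactors = FALSE)
  attr(out, "retained_ids") <- out$compound_id[out$retained]
  attr(out, "params") <- list(admet_threshold = admet_threshold,
                              q_star = q_star,
                              n_main_components = length(main_components))
  class(out) <- c("screen_report", "data.frame")
  out
}

#' @export
print.screen_report <- function(x, ...) {
  p <- attr(x, "params")
  cat("<screen_report> ", nrow(x), " compounds screened; ",
      sum(x$retained), " retained\n", sep = "")
  cat(sprintf("  gates: main components (n = %d) -> RO5 (strict) -> HIA/BBB >= %.2f -> q < %.2g\n",
              p$n_main_components, p$admet_threshold, p$q_star))
  cat("  step passes: ", sum(x$step1_main_component), " / ",
      sum(x$step2_ro5, na.rm = TRUE), " / ",
      sum(x$step3_admet, na.rm = TRUE), " / ",
      sum(x$step4_enrichment, na.rm = TRUE), "\n", sep = "")
  if (sum(x$retained) > 0)
    cat("  retained:", paste(x$name[x$retained], collapse = ", "), "\n")
  invisible(x)
}
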