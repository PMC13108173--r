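#' Sign-only direction call for cross-cohort validation
#'
#' External validation of age trends compares only the direction of the
#' fitted coefficient — Up/Down for expression, Hyper/Hypo for promoter
#' methylation — because modest cohort sizes and small per-year effects
#' make significance-based replication uninformative. Missing or
#' exactly-zero coefficients yield `NA` (no direction).
#'
#' @param coef numeric vector of age coefficients.
#' @param layer `"expression"` or `"methylation"`.
#' @return character vector of calls (`Up`/`Down`, `Hyper`/`Hypo`, or
#'   `NA`).
#' @export
call_direction <- function(coef, layer = c("expression", "methylation")) {
  layer <- match.arg(layer)
  labs <- if (layer == "expression") c("Up", "Down") else c("Hyper", "Hypo")
  out <- rep(NA_character_, length(coef))
  out[!is.na(coef) & coef > 0] <- labs[1]
  out[!is.na(coef) & coef < 0] <- labs[2]
  if (any(!is.na(coef) & coef == 0)) {
    message(sum(!is.na(coef) & coef == 0),
            " exactly-zero coefficient(s) have no direction; set to NA")
  }
  out
}

#' Compare direction calls between two cohorts
#'
#' Produces one validation record per primary-cohort call. A record is
#' concordant (`"Yes"`) only when the external cohort has a defined call
#' for the same miRNA and layer and it is identical; an `NA` on either
#' side yields `"No"`.
#'
#' @param primary data.frame with `base_id`, `layer`, `call`.
#' @param external data.frame with the same columns.
#' @return data.frame: `base_id`, `layer`, `primary_call`,
#'   `external_call`, `concordant` (`"Yes"`/`"No"`).
#' @export
compare_directions <- function(primary, external) {
  stopifnot(all(c("base_id", "layer", "call") %in% names(primary)),
            all(c("base_id", "layer", "call") %in% names(external)))
  key_p <- paste(primary$base_id, primary$layer)
  key_e <- paste(external$base_id, external$layer)
  ext <- external$call[match(key_p, key_e)]
  out <- data.frame(
    base_id = primary$base_id,
    layer = primary$layer,
    primary_call = primary$call,
    external_call = ext,
    stringsAsFactors = FALSE
  )
  out$concordant <- ifelse(!is.na(out$primary_call) & !is.na(ext) &
                             out$primary_call == ext, "Yes", "No")
  out
}

#' Tally direction-validation outcomes per layer
#'
#' Splits the "No" rows into truly opposite calls and missing-data rows
#' so that discordance is distinguishable from lack of coverage:
#' `n_yes` (identical defined calls), `n_no_opposite` (both defined,
#' different), `n_na` (either call missing). Percentages are relative to
#' the layer's total record count.
#'
#' @param records data.frame from [compare_directions()].
#' @return data.frame with one row per layer: `layer`, `n_yes`,
#'   `n_no_opposite`, `n_na`, `n_total`, `pct_yes`, `pct_no_opposite`,
#'   `pct_na`.
#' @export
summarize_validation <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(layer = character(0), n_yes = integer(0),
                      n_no_opposite = integer(0), n_na = integer(0),
                      n_total = integer(0), pct_yes = numeric(0),
                      pct_no_opposite = numeric(0), pct_na = numeric(0),
                      stringsAsFactors = FALSE))
  }
  sp <- split(records, records$layer)
  rows <- lapply(names(sp), function(ly) {
    r <- sp[[ly]]
    na <- is.na(r$primary_call) | is.na(r$external_call)
    yes <- !na & r$primary_call == r$external_call
    opp <- !na & !yes
    n <- nrow(r)
    data.frame(layer = ly, n_yes = sum(yes), n_no_opposite = sum(opp),
               n_na = sum(na), n_total = n,
               pct_yes = 100 * sum(yes) / n,
               pct_no_opposite = 100 * sum(opp) / n,
               pct_na = 100 * sum(na) / n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an external-cohort direction table
#'
#' Accepts either a pre-called direction TSV (columns `mirna_id`,
#' `expr_direction`, `meth_status`, `NA` allowed) or a fitted-results
#' TSV with coefficient columns (`expr_coef`, `meth_coef`), in which
#' case [call_direction()] is applied. Identifiers are harmonized.
#'
#' @param path TSV file path.
#' @return data.frame in [compare_directions()] long format: `base_id`,
#'   `layer`, `call`.
#' @export
read_external_directions <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("mirna_id" %in% names(d))
  base <- harmonize_mirna_id(d$mirna_id)
  if (all(c("expr_coef", "meth_coef") %in% names(d))) {
    expr_call <- call_direction(d$expr_coef, "expression")
    meth_call <- call_direction(d$meth_coef, "methylation")
  } else if (all(c("expr_direction", "meth_status") %in% names(d))) {
    expr_call <- ifelse(d$expr_direction %in% c("Up", "Down"),
                        d$expr_direction, NA_character_)
    meth_call <- ifelse(d$meth_status %in% c("Hyper", "Hypo"),
                        d$meth_status, NA_character_)
  } else {
    stop("need either expr_coef/meth_coef or expr_direction/meth_status ",
         "columns in ", path)
  }
  rbind(
    data.frame(base_id = base, layer = "expression", call = expr_call,
               stringsAsFactors = FALSE),
    data.frame(base_id = base, layer = "methylation", call = meth_call,
               stringsAsFactors = FALSE)
  )
}
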