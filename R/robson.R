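# WHO Robson ten-group classification.
#
# Standard precedence: multiple pregnancy (8), transverse/oblique lie
# (9), breech (6 nulliparous / 7 multiparous, no gestational-age
# restriction), preterm cephalic singleton (10), then cephalic term
# singletons 1-5 by parity, previous CS and onset of labour. Term is
# taken as >= 37 completed weeks (259 days). Group 5 includes all
# onsets. Records missing a needed field are labelled "unclassifiable"
# rather than erroring.

#' Classify deliveries into Robson groups
#'
#' @param records data frame with `plurality`, `presentation`,
#'   `parity_class`, `ga_days`, `onset`.
#' @return character vector: `"1"` to `"10"` or `"unclassifiable"`.
#' @export
classify_robson <- function(records) {
  n <- nrow(records)
  plur <- records$plurality
  pres <- records$presentation
  par <- records$parity_class
  ga <- records$ga_days
  onset <- records$onset
  out <- rep(NA_character_, n)

  bad <- is_missing_val(plur) | is_missing_val(pres) | is_missing_val(par) |
    is_missing_val(ga) | is_missing_val(onset) |
    !(pres %in% c("cephalic", "breech", "other")) |
    !(par %in% c("nulliparous", "multi_no_cs", "multi_prev_cs")) |
    !(onset %in% c("spontaneous", "induced", "prelabour_cs"))
  out[bad] <- "unclassifiable"

  todo <- which(!bad)
  g <- integer(length(todo))
  plur <- plur[todo]; pres <- pres[todo]; par <- par[todo]
  ga <- ga[todo]; onset <- onset[todo]
  nulli <- par == "nulliparous"
  prev_cs <- par == "multi_prev_cs"
  term <- ga >= 259

  g[plur >= 2] <- 8L
  left <- g == 0L
  g[left & pres == "other"] <- 9L
  left <- g == 0L
  g[left & pres == "breech" & nulli] <- 6L
  g[left & pres == "breech" & !nulli] <- 7L
  left <- g == 0L  # cephalic singletons from here
  g[left & !term] <- 10L
  left <- g == 0L  # term cephalic singletons
  g[left & prev_cs] <- 5L
  left <- g == 0L
  g[left & nulli & onset == "spontaneous"] <- 1L
  g[left & nulli & onset != "spontaneous"] <- 2L
  left <- g == 0L
  g[left & onset == "spontaneous"] <- 3L
  g[left & onset != "spontaneous"] <- 4L

  out[todo] <- as.character(g)
  out
}

#' Split classified records into the analysis strata
#'
#' Builds one dataset per requested Robson group; each carries a
#' `covariates` attribute with the reduced covariate set (parity,
#' gestational-age class, induction and breech are dropped, since they
#' define the strata). Empty strata are omitted with a warning.
#'
#' @param records birth-record data frame.
#' @param groups integer vector of Robson groups (default `c(1, 3, 5, 6)`).
#' @param labels optional precomputed [classify_robson()] labels.
#' @return named list of data frames (names `"1"`, `"3"`, ...).
#' @export
stratify_robson <- function(records, groups = c(1L, 3L, 5L, 6L),
                            labels = NULL) {
  labels <- labels %||% classify_robson(records)
  stopifnot(length(labels) == nrow(records))
  out <- list()
  for (gr in as.character(groups)) {
    sel <- which(labels == gr)
    if (length(sel) == 0L) {
      warning("Robson group ", gr, " is empty; stratum omitted",
              call. = FALSE)
      next
    }
    str <- records[sel, , drop = FALSE]
    attr(str, "covariates") <- stratified_covariates()
    attr(str, "robson_group") <- gr
    out[[gr]] <- str
  }
  out
}
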