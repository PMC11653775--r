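#' Annual flow fractions of the caries stock-and-flow model
#'
#' Constructs the set of six annual transition fractions that govern the
#' flows between the model's five compartments: caries development
#' (`f_dev`, out of the caries-free stock), restoration, endodontic
#' treatment and tooth loss (`f_restore`, `f_endo`, `f_loss`, three
#' competing outflows of the untreated-caries stock), and recurrent caries
#' from the two treated stocks (`f_rec_restore`, `f_rec_endo`), which
#' return persons to the untreated-caries pool — the model's two
#' reinforcing feedback loops.
#'
#' All fractions are per-year probabilities applied to the start-of-year
#' stock. The three outflows of the untreated stock must jointly satisfy
#' `f_restore + f_endo + f_loss <= 1`, otherwise a single annual step could
#' drain more persons than the stock holds.
#'
#' @param f_dev Annual fraction of caries-free persons developing caries.
#' @param f_restore Annual fraction of untreated-caries persons receiving a
#'   restoration.
#' @param f_endo Annual fraction of untreated-caries persons receiving
#'   endodontic treatment.
#' @param f_loss Annual fraction of untreated-caries persons progressing to
#'   tooth loss.
#' @param f_rec_restore Annual fraction of restored persons developing
#'   recurrent caries.
#' @param f_rec_endo Annual fraction of endodontically treated persons
#'   developing recurrent caries.
#' @return An object of class `flow_fractions`: a named numeric vector with
#'   the six fractions.
#' @examples
#' fr <- flow_fractions(f_dev = 0.18, f_restore = 0.12, f_endo = 0.01,
#'                      f_loss = 0.15)
#' fr
#' @export
flow_fractions <- function(f_dev = 0, f_restore = 0, f_endo = 0, f_loss = 0,
                           f_rec_restore = 0, f_rec_endo = 0) {
  x <- c(f_dev = f_dev, f_restore = f_restore, f_endo = f_endo,
         f_loss = f_loss, f_rec_restore = f_rec_restore,
         f_rec_endo = f_rec_endo)
  structure(x, class = "flow_fractions")
}

#' @rdname flow_fractions
#' @format NULL
#' @export
fraction_names <- function() {
  c("f_dev", "f_restore", "f_endo", "f_loss", "f_rec_restore", "f_rec_endo")
}

#' Validate a set of flow fractions
#'
#' Checks that every fraction lies in \[0, 1\] and that the three outflows
#' of the untreated-caries stock do not jointly exceed 1.
#'
#' @param fractions A [flow_fractions()] object or a named numeric vector
#'   with the six fraction names.
#' @return The validated `flow_fractions` object, invisibly usable in
#'   pipelines; errors on violation.
#' @export
validate_fractions <- function(fractions) {
  fractions <- as_flow_fractions(fractions)
  if (any(!is.finite(fractions))) {
    stop("flow fractions must be finite numbers", call. = FALSE)
  }
  bad <- fractions < 0 | fractions > 1
  if (any(bad)) {
    stop("flow fractions out of [0, 1]: ",
         paste(names(fractions)[bad], collapse = ", "), call. = FALSE)
  }
  s <- fractions[["f_restore"]] + fractions[["f_endo"]] + fractions[["f_loss"]]
  if (s > 1 + 1e-12) {
    stop(sprintf(
      "f_restore + f_endo + f_loss = %.6f exceeds 1: outflows would drain more than the untreated-caries stock",
      s), call. = FALSE)
  }
  fractions
}

# Coerce a named numeric vector/list to flow_fractions, checking names only.
as_flow_fractions <- function(x) {
  if (inherits(x, "flow_fractions")) return(x)
  x <- unlist(x)
  missing_nm <- setdiff(fraction_names(), names(x))
  if (length(missing_nm) > 0) {
    stop("missing flow fractions: ", paste(missing_nm, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(x), fraction_names())
  if (length(extra) > 0) {
    stop("unknown flow fractions: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  structure(x[fraction_names()], class = "flow_fractions")
}

#' @export
print.flow_fractions <- function(x, ...) {
  cat("Annual flow fractions:\n")
  print(unclass(x), ...)
  invisible(x)
}
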