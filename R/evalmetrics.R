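#' Confusion counts for growth predictions
#'
#' @param TP,FP,TN,FN nonnegative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Compare predicted growth against observations
#'
#' Binary analysis of carbon-source growth: the model predicts growth when its
#' optimum exceeds `growth_tol`; observations are yes/no per substrate. Each
#' matched substrate lands in exactly one of TP / FP / TN / FN (TP: both model
#' and data indicate growth; FP: model grows without experimental support; TN:
#' both agree on no growth; FN: data show growth the model cannot reproduce).
#'
#' @param predictions named numeric vector, substrate -> predicted mu (h^-1);
#'   `NA` counts as no growth (substrate absent from the model).
#' @param observations data frame with columns `substrate` and
#'   `observed_growth` (logical or 0/1).
#' @param growth_tol growth threshold on mu.
#' @return A `confusion_counts` object with a `per_substrate` attribute.
#' @export
compare_growth <- function(predictions, observations, growth_tol = 1e-6) {
  stopifnot(is.data.frame(observations),
            all(c("substrate", "observed_growth") %in% names(observations)))
  common <- intersect(observations$substrate, names(predictions))
  unmatched <- setdiff(union(observations$substrate, names(predictions)), common)
  if (length(unmatched))
    warning("substrates without a counterpart: ",
            paste(unmatched, collapse = ", "))
  if (!length(common)) stop("no substrate matches between predictions and observations",
                            call. = FALSE)
  obs <- observations[match(common, observations$substrate), ]
  pred_grow <- !is.na(predictions[common]) & predictions[common] > growth_tol
  obs_grow <- as.logical(obs$observed_growth)
  outcome <- ifelse(pred_grow & obs_grow, "TP",
             ifelse(pred_grow & !obs_grow, "FP",
             ifelse(!pred_grow & !obs_grow, "TN", "FN")))
  cc <- confusion_counts(sum(outcome == "TP"), sum(outcome == "FP"),
                         sum(outcome == "TN"), sum(outcome == "FN"))
  attr(cc, "per_substrate") <- data.frame(substrate = common,
                                          predicted_mu = unname(predictions[common]),
                                          predicted_growth = pred_grow,
                                          observed_growth = obs_grow,
                                          outcome = outcome,
                                          stringsAsFactors = FALSE)
  cc
}

#' F-score of growth predictions
#'
#' F = TP / (TP + (FP + FN) / 2), the harmonic mean of precision and recall.
#'
#' @param counts a `confusion_counts` object.
#' @return F in [0, 1]; `NA` with a warning when TP + FP + FN = 0.
#' @export
f_score <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  denom <- counts$TP + (counts$FP + counts$FN) / 2
  if (denom == 0) {
    warning("F-score undefined: TP + FP + FN = 0")
    return(NA_real_)
  }
  counts$TP / denom
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). When any
#' factor of the denominator is zero the conventional value 0 is returned,
#' flagged with the attribute `degenerate = TRUE`.
#'
#' @param counts a `confusion_counts` object.
#' @return MCC in [-1, 1].
#' @export
mcc <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    factors <- c(TP + FP, TP + FN, TN + FP, TN + FN)
    if (any(factors == 0)) {
      out <- 0
      attr(out, "degenerate") <- TRUE
      return(out)
    }
    (TP * TN - FP * FN) / sqrt(prod(factors))
  })
}

#' RMSE between predicted and observed growth rates
#'
#' @param predicted named numeric vector, substrate -> predicted mu.
#' @param observed named numeric vector, substrate -> measured rate (h^-1).
#' @return Root-mean-square error over the paired substrates.
#' @export
rmse_growth <- function(predicted, observed) {
  common <- intersect(names(predicted), names(observed))
  common <- common[!is.na(predicted[common]) & !is.na(observed[common])]
  if (!length(common)) stop("no paired growth rates", call. = FALSE)
  sqrt(mean((predicted[common] - observed[common])^2))
}

#' Read a growth phenotype table from TSV
#'
#' Expected columns: `substrate`, `observed_growth` (0/1), optional
#' `observed_rate`.
#'
#' @param path TSV path.
#' @return A data frame.
#' @export
read_phenotype_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("substrate", "observed_growth")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("phenotype table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$observed_growth <- as.logical(as.integer(df$observed_growth))
  df
}
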